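#!/usr/bin/env Rscript
# Run the imaging pipeline for every synthetic patient: probabilistic
# tractography from the SOZ sphere to the thalamus, 95%-mass-thresholded
# probability map, VTA from the patient's electrode and stimulation
# setting, then the two engagement metrics (activated proportion and peak
# connection probability inside the VTA).

library(thalnet)

cfg <- phantom_config(cohort_size = 12, seed = 42)
res <- run_all(cfg, out_dir = "results/run_seed42", n_select = 300,
               write_imaging = FALSE)

dir.create("results", showWarnings = FALSE)
write.csv(res$cohort, "results/phantom_cohort.csv", row.names = FALSE)

cat("Per-patient engagement (300 streamlines/SOZ, seed 42):\n")
print(res$cohort[, c("patient_id", "n_activated", "proportion",
                     "true_proportion", "peak_probability", "reduction",
                     "response")], digits = 3)
cat(sprintf("\nMeasured vs ground-truth proportion: max gap %.3f\n",
            max(abs(res$cohort$proportion - res$cohort$true_proportion))))
cat("Wrote results/phantom_cohort.csv\n")
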