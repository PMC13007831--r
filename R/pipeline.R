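#' Run the full phantom pipeline end to end
#'
#' simulate -> track -> probability map -> VTA -> engagement metrics ->
#' outcome statistics, for every patient of a synthetic cohort, writing all
#' stage outputs (NIfTI, TCK, CSV, JSON) under a run directory together with
#' a manifest recording the seed and an md5 checksum per artifact. Reruns
#' with the same config reproduce identical checksums.
#'
#' @param config `thalnet_phantom_config`; `config$seed` drives every random
#'   draw (phantom geometry draws, tracking, outcome noise).
#' @param out_dir run directory (created if missing).
#' @param n_select streamlines to request per SOZ bundle.
#' @param write_imaging write per-patient NIfTI/TCK artifacts (disable to
#'   keep quick runs small).
#' @return List with `cohort` (measured + simulated per-patient table),
#'   `stats` (Spearman and group comparison), `manifest_path`.
#' @export
run_all <- function(config = phantom_config(), out_dir = tempfile("run"),
                    n_select = 500L, write_imaging = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_cohort(config)
  rows <- vector("list", config$cohort_size)
  for (i in seq_len(config$cohort_size)) {
    m <- measure_patient(config, i, n_select = n_select,
                         out_dir = if (write_imaging) out_dir else NULL)
    rows[[i]] <- data.frame(patient_id = i,
                            n_total = m$activation$n_total,
                            n_activated = m$activation$n_activated,
                            proportion = m$activation$proportion,
                            percent = m$activation$percent_rounded,
                            peak_probability = m$peak$peak,
                            true_proportion = gen$cohort$true_proportion[i],
                            reduction = gen$cohort$reduction[i],
                            response = gen$cohort$response[i],
                            stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  sp <- tryCatch(spearman_test(cohort$proportion, cohort$reduction),
                 error = function(e) list(error = conditionMessage(e)))
  grp <- tryCatch(run_group_comparison(cohort),
                  error = function(e) list(error = conditionMessage(e)))
  stats <- list(spearman = sp, group_comparison = grp)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- write_manifest(out_dir, config)
  list(cohort = cohort, stats = stats, manifest_path = manifest)
}

#' Measure one phantom patient with the full imaging pipeline
#'
#' Builds the patient's phantom, tracks every SOZ bundle to the thalamus,
#' merges the tracts, forms the thresholded probability map, computes the
#' VTA from the patient's electrode and setting, and evaluates both
#' engagement metrics.
#'
#' @param config `thalnet_phantom_config`.
#' @param patient_index patient slot (drives the electrode offset).
#' @param n_select streamlines per bundle.
#' @param out_dir if non-NULL, write this patient's artifacts there.
#' @return List: `activation`, `peak`, `tract`, `probmap`, `vta`, `phantom`.
#' @export
measure_patient <- function(config, patient_index, n_select = 500L,
                            out_dir = NULL) {
  ph <- build_phantom(config, patient_index)
  params <- tracking_params(n_select = n_select,
                            seed = config$seed * 1000L + patient_index)
  tracts <- lapply(names(ph$soz_masks), function(nm) {
    track_soz_to_thalamus(ph$field, ph$soz_masks[[nm]], ph$thalamus,
                          ph$brainstem, params, soz_id = nm)
  })
  merged <- merge_tracts(tracts)
  pm <- threshold_map(tract_to_probability_map(merged, ph$grid), 0.95)
  vta <- compute_vta(ph$electrode, ph$setting, ph$grid, ph$labels,
                     E_star = config$outcome$E_star)
  act <- proportion_activated(merged, vta)
  pk <- peak_probability_in_vta(pm, vta)
  if (!is.null(out_dir)) {
    pdir <- file.path(out_dir, sprintf("patient_%02d", patient_index))
    dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
    write_volume(ph$labels, file.path(pdir, "labels.nii.gz"))
    write_tck(merged, file.path(pdir, "tract.tck"))
    write_volume(pm, file.path(pdir, "probmap.nii.gz"))
    write_volume(vta, file.path(pdir, "vta.nii.gz"))
  }
  list(activation = act, peak = pk, tract = merged, probmap = pm, vta = vta,
       phantom = ph)
}

write_manifest <- function(out_dir, config) {
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  sums <- as.vector(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(seed = config$seed,
                   cohort_size = config$cohort_size,
                   artifacts = stats::setNames(as.list(sums), files))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}
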