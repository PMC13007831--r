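---
title: "Quantifying SOZ-thalamus tract engagement by responsive neurostimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SOZ-thalamus tract engagement by responsive neurostimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalnet)
```

## The question

Thalamic responsive neurostimulation (RNS) treats drug-refractory epilepsy
by stimulating a thalamic target, traditionally chosen by nucleus (ANT for
limbic/temporal networks, CM for frontal/sensorimotor ones). The analysis
this package implements asks a network question instead: does clinical
benefit track how much of the *structural connection between the seizure
onset zone (SOZ) and the thalamus* the stimulation actually engages?

Two engagement measures operationalize this:

1. **Activated tract proportion** — the fraction of SOZ-to-thalamus
   streamlines that pass through the stimulation's volume of tissue
   activated (VTA), pooled over sides and SOZs into one number per patient,
   correlated with percent seizure reduction (Spearman, two-tailed).
2. **Peak connection probability inside the VTA** — the maximum of the
   tract's probability-of-connectivity map over the VTA voxels, compared
   between responders (>50% seizure reduction) and pooled
   partial/nonresponders (Mann-Whitney U).

Because the source cohort's imaging is not publicly deposited, the imaging
stack runs on synthetic phantoms with known geometric ground truth, while
the cohort-level statistics are recomputed from the published per-patient
tables shipped in `inst/extdata/`.

## The pipeline and its models

### Coordinates and containers

All voxel grids carry a 4x4 affine mapping **0-based** voxel indices
(voxel-center convention) to RAS mm. A world point belongs to the voxel
whose center is nearest, rounding half up — one unambiguous convention used
by every intersection test in the package. Volumes round-trip through
NIfTI-1, streamlines through the binary `.tck` format, tables through CSV.

### Orientation-field phantoms

A phantom patient consists of:

* a label map with cortex, white matter, a brainstem column, and a reduced
  thalamic segmentation (ANT, CM, MD, Pulv and a remainder compartment) —
  only these nuclei are discussed in thalamic neuromodulation targeting,
  and the label dictionary is open so finer parcellations can be added;
* cortical SOZ spheres of 10 mm radius (the segmentation convention for
  sEEG-defined onset zones: the contact's cortical neighborhood plus its
  adjacent white matter);
* white-matter bundles modeled as 3 mm-radius tubes around cubic-spline
  (or, for corner-heavy routes, piecewise-linear) centerlines running from
  each SOZ into a target nucleus. Voxels inside a tube carry an orientation
  lobe along the local centerline tangent with amplitude 1.0; everything
  else carries lobes of amplitude 0.05 — deliberately *below* the 0.1
  tracking cutoff, so tracking cannot leave the planted anatomy and the
  tracker's behavior is fully predictable;
* a quadripolar depth electrode (3.5 mm center-to-center contact spacing,
  contact 1 most distal) inserted along the first bundle's thalamic end,
  displaced laterally from the bundle axis by a per-patient offset.

The electrode offset is the *only* per-patient variable: it controls how
much of the bundle cross-section the stimulation reaches, which isolates
the engagement metrics from tract-geometry variation.

### Tracking

Probabilistic streamline tractography seeds uniformly inside the SOZ mask
and integrates bidirectionally (SOZ regions include white matter, and
fibers have no preferred direction; two passes with opposed initial
directions are concatenated). At each 0.5 mm step the candidate lobes of
the nearest voxel are those with amplitude at or above the cutoff (default
0.1) and axis within 45 degrees of the incoming direction; the next
direction is drawn with probability proportional to amplitude. Streamlines
terminate on grid exit, absent candidates, or a 250 mm length cap. A
streamline is retained only if it visits the thalamus waypoint mask, and is
rejected *whole* — not truncated — if either endpoint lies in the brainstem
mask, since trajectories terminating in the brainstem are not
SOZ-to-thalamus connections. Generation stops at `n_select` retained
streamlines (default 5000 per SOZ) or after `max_attempts` seeds. On fields
with a single supra-cutoff lobe per voxel the tracker reduces to
deterministic path-following, which the tests exploit as an oracle.

Step size, angle threshold and directionality are not pinned down by the
reference workflow ("default parameters" of a standard CSD run); the
values above are typical probabilistic-tracking defaults and all are
exposed in `tracking_params()`.

### Probability maps and the 95% threshold

The probability of connectivity at a voxel is the fraction of the tract's
streamlines visiting it (distinct-streamline counting, so values live in
[0, 1]). "Thresholding at 95% probability of connectivity" is read as a
*mass* threshold: voxels are ranked by visitation and the smallest
top-ranked set holding 95% of total visitation mass is kept, discarding
the diffuse 5% tail. This reading is consistent with reported peak values
well below 1 and with standard track-density practice; the alternative
reading (zeroing the bottom 5% of values) remains available as a
configuration. Two numerical details make the operation well-behaved:
ties at the boundary value are all retained, and the raw map's total
visitation is carried on the object so re-thresholding an already
thresholded map is exactly idempotent.

### Electric field and VTA

The stimulation field uses analytic point-source superposition: each
active contact is a point current source, cathodes share the (negative)
set amplitude and anodes the positive return, and

$$\mathbf{E}(\mathbf{r}) = \sum_k \frac{I_k\,(\mathbf{r}-\mathbf{c}_k)}
{4\pi\,\sigma(\mathbf{r})\,\lVert\mathbf{r}-\mathbf{c}_k\rVert^3},$$

with the scalar conductivity sampled from the tissue label at the
evaluation point (0.33 S/m gray, 0.14 S/m white — the standard values;
these constants are sometimes misprinted as S/mm, a reading available
behind a flag but yielding sub-0.1 mm activation volumes, three orders of
magnitude below reported per-side VTAs of 88-746 mm^3). The binary VTA is
the set of voxels whose center field magnitude reaches 0.2 V/mm. This is
deliberately not a finite-element four-compartment model: the analytic
form is verifiable against a closed-form sphere (for a monopole,
$r^* = \sqrt{I/(4\pi\sigma E^*)}$, e.g. 2.38 mm for 2 mA in white matter)
and the module interface leaves room for a FEM backend. Pulse width and
frequency are carried as metadata only; the threshold is fixed at
0.2 V/mm as in the reference workflow, with a pulse-width-dependent
threshold left as a configuration hook. Field evaluation exactly at a
contact center is capped (default 1000 V/mm) rather than infinite.

Stimulation settings parse from the cohort table's compact notation
(`"L: +-00 2 R: 0+-0 .5"`): four polarity characters for contacts 1-4 and
a trailing amplitude in mA per side. Whether printed amplitudes are
per-contact or totals is not recoverable from the source; they are read as
total cathodic current split equally among same-polarity contacts.

### Engagement metrics

A streamline is "activated" if any of its points falls in a VTA voxel
(an any-point rule; a minimum-traversal-length rule would be a stricter
alternative but none is specified by the reference analysis). Percent
values round half away from zero, matching the cohort table (4.696% prints
as 5). Per-side results pool as summed counts
$\sum n_{act} / \sum n_{tot}$; the peak probability pools as the maximum
across sides. The peak is taken on the *thresholded* map, which the
reference workflow computes before peak capture; the raw-map option is
retained.

The convergent/transthalamic pattern classifier reconstructs a qualitative
taxonomy and is explicitly heuristic: each tract's dominant nucleus is the
named nucleus (the remainder compartment does not count) containing most
of its thalamic visits; two or more tracts sharing a dominant nucleus is
"convergent"; differing dominant nuclei with touching thalamic visitation
masks is "transthalamic"; one tract is "single"; anything else is
"unclassified".

### Outcome model of the synthetic cohort

Observed seizure reduction is
$\mathrm{clamp}_{[0,100]}\!\left(\frac{100}{1+e^{-k(p - p_0)}} +
\varepsilon\right)$, $\varepsilon \sim N(0, \sigma^2)$, a monotone link
from the true activation proportion $p$ (computed in closed form as the
overlap area of the bundle's cross-section disc and the activation disc at
the electrode's offset, divided by the bundle cross-section). Defaults
were fixed once from the study conditions: electrode offsets uniform on
1.5-4.5 mm and a 2 mA bipolar setting make noise-free proportions span
about 0.005-0.27, the range observed in the published cohort (0.047-0.29);
midpoint $p_0 = 0.12$ and steepness $k = 25$ map that span onto 0-100%
reduction; noise sd 15 percentage points reflects the reliability of
self-reported seizure frequencies. With these conditions a 12-patient
cohort yields a significant positive Spearman correlation in about 97-99%
of replicates, and null cohorts (zero steepness) reject at the nominal 5%
within the t-approximation's small-sample tolerance.

### Statistics

The cohort statistics implement the exact conventions the analysis needs:

* **Spearman**: average ranks for ties, rho as Pearson correlation of rank
  vectors, two-sided p from the t approximation with n-2 df, exhaustive
  permutation optionally for n <= 8.
* **Mann-Whitney U**: rank-sum U with average-rank ties; exact two-sided p
  by enumerating all $\binom{n_a+n_b}{n_a}$ group assignments up to
  n = 20 (792 assignments for the 7-vs-5 comparison), normal approximation
  with tie and continuity corrections beyond.
* Reductions are $\max(0, 100(pre-post)/pre)$ — worsening clamps to zero,
  as the cohort table does. Response boundaries: >50% responder, 25-50%
  partial (both boundary values partial), <25% nonresponder. IQRs use
  linear-interpolation (type 7) percentiles.

Base R's `cor.test` and `wilcox.test` serve as independent cross-checks in
the test suite on tie-free inputs; they are not the implementation because
neither exposes exact p values under ties with these conventions.

## What the phantoms do and do not show

The phantoms validate the *pipeline*: coordinate handling, tracking
fidelity (oracle agreement within 2 voxels), VTA geometry (closed-form
agreement within 10% at 0.25 mm voxels), mass accounting of probability
maps, metric monotonicity, and recovery of a planted monotone
effect. They do not emulate real diffusion MRI: there is no noise in the
orientation field, no crossing-fiber ambiguity outside planted crossings,
no partial-volume effects, and no lesioned anatomy. Passing tests
therefore show the method measures what it claims on known geometry — not
that tractography of clinical DWI is unbiased. Likewise the group medians
and p values of the source cohort's probability-peak analysis depend on
unpublished per-patient imaging and are *not* reproduced; the packaged
tables support exactly the recomputable quantities (percent column,
response split, mean age, activation-reduction correlation).

## Numerical choices and problem sizes

Default analysis runs use 64^3 voxel grids at 1 mm, 300 requested
streamlines per SOZ in the scripted analyses (5000 in the tracking
defaults, matching the reference protocol), and 0.25 mm grids for
closed-form VTA checks; the scripted analyses complete in about a minute.
Determinism is end-to-end: a single config seed drives phantom draws,
per-patient tracking substreams, and outcome noise, and rerunning a
pipeline reproduces identical artifact checksums (manifest-verified).
Degenerate inputs are defined behaviors, not crashes: empty seed
territory yields an empty tract with a warning, zero amplitude yields an
empty VTA, an empty tract-VTA intersection yields peak 0, and constant
vectors make the rank correlation error out rather than return NaN.

## Known limitations

* The point-source field ignores electrode encapsulation, the insulating
  shaft, and anisotropic conductivity; absolute VTA volumes are
  order-of-magnitude comparable (tens to hundreds of mm^3 over the 0.5-6
  mA range) but not FEM-accurate.
* Nearest-voxel orientation lookup (no interpolation) quantizes curved
  bundles; near tube edges and sharp corners a small fraction of
  streamlines terminates early. Tests budget for this with the 2-voxel
  oracle tolerance.
* The pattern classifier formalizes a taxonomy its source describes only
  qualitatively; its labels are reported as heuristic.
* With 12 patients the Spearman t approximation is slightly liberal
  (null rejection near 5.5% rather than 5.0%); the exact-permutation
  option is limited to n <= 8 by cost.
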