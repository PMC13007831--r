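#' Proportion of SOZ streamlines activated by stimulation
#'
#' A streamline counts as activated when any of its points falls inside a
#' VTA voxel. The rounded percent uses half-away-from-zero rounding, the
#' convention of the cohort table (e.g. 4.696% prints as 5).
#'
#' @param tract merged `thalnet_tract` (n_retained >= 1).
#' @param vta `thalnet_vta` in the same coordinate space.
#' @return List with `n_total`, `n_activated`, `proportion`,
#'   `percent_rounded`.
#' @export
proportion_activated <- function(tract, vta) {
  if (tract$n_retained < 1L) stop("tract has no streamlines")
  act <- vapply(tract$streamlines, function(s) {
    idx <- voxel_linear_index(vta, nearest_voxel(vta, s))
    idx <- idx[!is.na(idx)]
    any(vta$values[idx])
  }, logical(1))
  n_act <- sum(act)
  activation_metrics(tract$n_retained, n_act)
}

activation_metrics <- function(n_total, n_activated) {
  prop <- n_activated / n_total
  structure(list(n_total = as.integer(n_total),
                 n_activated = as.integer(n_activated),
                 proportion = prop,
                 percent_rounded = round_half_up(100 * prop)),
            class = "thalnet_activation")
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Highest connection probability inside the VTA
#'
#' The peak of the (thresholded) probability map over the VTA voxels; an
#' empty intersection gives 0. Ties are broken toward the lowest linear
#' voxel index.
#'
#' @param pm `thalnet_probmap` (thresholded by convention; a raw map works).
#' @param vta `thalnet_vta` on the same grid.
#' @return List with `peak` in `[0, 1]` and `voxel` (0-based ijk or NA).
#' @export
peak_probability_in_vta <- function(pm, vta) {
  stopifnot(all(pm$shape == vta$shape))
  sel <- which(vta$values & pm$values > 0)
  if (length(sel) == 0L)
    return(structure(list(peak = 0, voxel = rep(NA_integer_, 3)),
                     class = "thalnet_peak"))
  vals <- pm$values[sel]
  best <- sel[which.max(vals)]   # which.max takes the first (lowest index)
  d <- pm$shape
  i0 <- best - 1L
  vox <- c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  structure(list(peak = max(vals), voxel = as.integer(vox)),
            class = "thalnet_peak")
}

#' Pool per-side engagement metrics into one value per patient
#'
#' Activation pools as a ratio of summed counts; the peak probability pools
#' as the maximum across sides/VTAs.
#'
#' @param activations list of activation metric lists.
#' @param peaks list of peak results (optional).
#' @return List with `activation` and `peak` entries.
#' @export
aggregate_patient <- function(activations, peaks = NULL) {
  if (length(activations) == 0L) stop("no per-side metrics to aggregate")
  act <- activation_metrics(
    sum(vapply(activations, `[[`, 0L, "n_total")),
    sum(vapply(activations, `[[`, 0L, "n_activated")))
  pk <- NULL
  if (!is.null(peaks) && length(peaks)) {
    vals <- vapply(peaks, `[[`, 0, "peak")
    pk <- peaks[[which.max(vals)]]
  }
  list(activation = act, peak = pk)
}

#' Classify the multi-SOZ connectivity pattern
#'
#' A heuristic reconstruction of the qualitative taxonomy: each tract's
#' dominant nucleus is the thalamic label whose voxels it visits most;
#' `convergent` when two or more tracts share a dominant nucleus,
#' `transthalamic` when the dominant nuclei differ but the tracts' thalamic
#' visitation masks touch (share at least one voxel), `single` for a lone
#' tract, `unclassified` otherwise.
#'
#' @param tracts list of per-SOZ `thalnet_tract` (each nonempty).
#' @param labels `thalnet_labelmap` containing thalamic nucleus labels.
#' @return List with `pattern` and per-tract `dominant_nucleus`.
#' @export
classify_pattern <- function(tracts, labels) {
  stopifnot(inherits(labels, "thalnet_labelmap"))
  thal_ids <- thalamic_label_ids(labels$labels)
  if (length(thal_ids) == 0L)
    stop("label map has no thalamic nucleus labels")
  if (any(vapply(tracts, `[[`, 0, "n_retained") == 0))
    stop("classify_pattern requires nonempty tracts")
  visits <- lapply(tracts, function(tr) {
    idx <- unlist(lapply(tr$streamlines, function(s) {
      voxel_linear_index(labels, nearest_voxel(labels, s))
    }))
    idx <- idx[!is.na(idx)]
    idx[labels$values[idx] %in% thal_ids]
  })
  nucleus_ids <- thalamic_label_ids(labels$labels, nuclei_only = TRUE)
  dominant <- vapply(visits, function(ix) {
    # dominance is judged among the named nuclei; the remainder compartment
    # a tract crosses on the way in does not count
    ix <- ix[labels$values[ix] %in% nucleus_ids]
    if (length(ix) == 0L) return(NA_character_)
    tab <- table(labels$values[ix])
    id <- as.integer(names(tab)[which.max(tab)])
    names(labels$labels)[match(id, labels$labels)]
  }, character(1))
  if (length(tracts) == 1L)
    return(list(pattern = "single", dominant_nucleus = dominant))
  pattern <- "unclassified"
  if (anyDuplicated(stats::na.omit(dominant))) {
    pattern <- "convergent"
  } else if (!anyNA(dominant)) {
    touch <- FALSE
    uv <- lapply(visits, unique)
    for (a in seq_along(uv)) for (b in seq_along(uv)) {
      if (a < b && length(intersect(uv[[a]], uv[[b]]))) touch <- TRUE
    }
    if (touch) pattern <- "transthalamic"
  }
  list(pattern = pattern, dominant_nucleus = dominant)
}
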