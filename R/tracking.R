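#' Per-voxel fiber orientation field
#'
#' The synthetic counterpart of a fiber-orientation-distribution (FOD) image:
#' each voxel carries up to `L` axial lobes, a unit direction plus a
#' non-negative amplitude. Tracking treats lobe amplitude the way FOD
#' amplitude is used by probabilistic tractography — as the sampling weight
#' and the cutoff criterion.
#'
#' @param dirs numeric array `[nx, ny, nz, L, 3]` of lobe directions
#'   (unit-norm wherever the amplitude is nonzero).
#' @param amps numeric array `[nx, ny, nz, L]` of lobe amplitudes.
#' @param affine 4x4 voxel-to-world matrix.
#' @return `thalnet_field`.
#' @export
orientation_field <- function(dirs, amps, affine = diag(4)) {
  stopifnot(length(dim(amps)) == 4L, length(dim(dirs)) == 5L,
            all(dim(dirs)[1:4] == dim(amps)), dim(dirs)[5] == 3L)
  if (!all(is.finite(amps)) || any(amps < 0))
    stop("amplitudes must be finite and non-negative")
  n <- sqrt(apply(dirs^2, 1:4, sum))
  active <- amps > 0
  if (any(abs(n[active] - 1) > 1e-6))
    stop("active lobe directions must be unit-norm")
  structure(list(dirs = dirs, amps = amps, affine = as.matrix(affine),
                 shape = dim(amps)[1:3], n_lobes = dim(amps)[4]),
            class = "thalnet_field")
}

#' Tracking parameters
#'
#' Defaults mirror a routine probabilistic run at this scale: 5000
#' streamlines per seed region with an FOD amplitude cutoff of 0.1; step
#' 0.5 mm, 45 degrees maximal turning per step, 250 mm length cap, and up to
#' 20 x n_select seeding attempts.
#'
#' @param n_select streamlines to retain per seed region.
#' @param amplitude_cutoff minimal lobe amplitude for propagation.
#' @param step_mm integration step (must not exceed the voxel size).
#' @param max_angle_deg maximal turning angle per step.
#' @param max_length_mm length cap per direction of integration.
#' @param max_attempts total seeding attempts before giving up.
#' @param seed RNG seed for this tracking run (NULL = leave RNG state alone).
#' @return `thalnet_tracking_params` list.
#' @export
tracking_params <- function(n_select = 5000L, amplitude_cutoff = 0.1,
                            step_mm = 0.5, max_angle_deg = 45,
                            max_length_mm = 250,
                            max_attempts = 20L * n_select,
                            seed = NULL) {
  stopifnot(n_select >= 1L, amplitude_cutoff > 0, step_mm > 0,
            max_angle_deg > 0, max_angle_deg < 90, max_length_mm > 0)
  structure(list(n_select = as.integer(n_select),
                 amplitude_cutoff = amplitude_cutoff, step_mm = step_mm,
                 max_angle_deg = max_angle_deg, max_length_mm = max_length_mm,
                 max_attempts = as.integer(max_attempts), seed = seed),
            class = "thalnet_tracking_params")
}

#' Probabilistic tractography from an SOZ seed to the thalamus
#'
#' Seeds uniformly within the seed mask and integrates bidirectionally
#' through the orientation field (candidate lobes: amplitude at or above the
#' cutoff and axis within the turning cone; sampled proportionally to
#' amplitude). A generated streamline is retained only if it visits the
#' thalamus waypoint mask, and is rejected whole if either endpoint lies in
#' the brainstem exclusion mask. Generation stops at `n_select` retained
#' streamlines or `max_attempts` seeds.
#'
#' @param field `thalnet_field`.
#' @param seed_mask,thalamus_mask,brainstem_mask `thalnet_mask` on the field
#'   grid (`brainstem_mask` may be NULL for no exclusion).
#' @param params `thalnet_tracking_params`.
#' @param soz_id,side provenance recorded on the tract.
#' @return `thalnet_tract`; 0 retained streamlines gives a warning, not an
#'   error.
#' @export
track_soz_to_thalamus <- function(field, seed_mask, thalamus_mask,
                                  brainstem_mask = NULL,
                                  params = tracking_params(),
                                  soz_id = "SOZ", side = NA_character_) {
  stopifnot(inherits(field, "thalnet_field"),
            all(seed_mask$shape == field$shape),
            all(thalamus_mask$shape == field$shape))
  if (step_exceeds_voxel(field, params$step_mm))
    stop("step_mm exceeds the smallest voxel dimension")
  seeds <- which(seed_mask$values, arr.ind = TRUE) - 1L
  if (nrow(seeds) == 0L) stop("seed mask is empty")
  bs <- if (is.null(brainstem_mask)) {
    array(FALSE, dim = field$shape)
  } else {
    stopifnot(all(brainstem_mask$shape == field$shape))
    brainstem_mask$values
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  res <- .track_cpp(as.integer(c(field$shape, field$n_lobes)),
                    as.numeric(field$amps), as.numeric(field$dirs),
                    field$affine, seeds,
                    as.logical(thalamus_mask$values), as.logical(bs),
                    params$step_mm, params$amplitude_cutoff,
                    params$max_angle_deg, params$max_length_mm,
                    params$n_select, params$max_attempts)
  if (res$n_retained == 0L)
    warning("no streamlines retained from seed region '", soz_id, "'")
  out <- tract(res$streamlines, soz_id = soz_id, side = side,
               n_requested = params$n_select)
  out$attempts <- res$attempts
  out
}

step_exceeds_voxel <- function(field, step_mm) {
  vs <- sqrt(colSums(field$affine[1:3, 1:3]^2))
  step_mm > min(vs) + 1e-9
}
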