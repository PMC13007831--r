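#' Probability-of-connectivity maps
#'
#' The probability of connectivity at a voxel is the fraction of the tract's
#' streamlines that visit it (distinct-streamline counting: a streamline
#' crossing a voxel twice counts once), so values live in [0, 1] and the
#' densest core of the bundle approaches 1.
#'
#' @param tract `thalnet_tract` with `n_retained >= 1`.
#' @param grid `thalnet_volume` (or mask/label map) defining the voxel grid.
#' @return `thalnet_probmap`: a volume of visitation fractions with
#'   `threshold_mass = NA` and `kind = "raw"`, plus the per-voxel distinct
#'   visit counts in `$counts`.
#' @export
tract_to_probability_map <- function(tract, grid) {
  stopifnot(inherits(tract, "thalnet_tract"))
  if (tract$n_retained < 1L) stop("cannot map an empty tract")
  counts <- array(0L, dim = grid$shape)
  for (s in tract$streamlines) {
    idx <- voxel_linear_index(grid, nearest_voxel(grid, s))
    idx <- unique(idx[!is.na(idx)])
    counts[idx] <- counts[idx] + 1L
  }
  pm <- volume(counts / tract$n_retained, grid$affine)
  pm$counts <- counts
  pm$n_retained <- tract$n_retained
  pm$total_visits <- sum(as.numeric(counts))
  pm$threshold_mass <- NA_real_
  pm$kind <- "raw"
  class(pm) <- c("thalnet_probmap", class(pm))
  pm
}

#' Mass-threshold a probability map at 95%
#'
#' Voxels are ranked by visitation value; the smallest top-ranked set whose
#' summed visitation counts reach `mass` of the total is retained and the
#' diffuse tail is zeroed. Ties at the boundary value are all retained, which
#' makes the operation idempotent.
#'
#' @param pm raw `thalnet_probmap`.
#' @param mass fraction of total visitation mass to retain, in (0, 1].
#' @return Thresholded `thalnet_probmap` (`kind = "thresholded"`).
#' @export
threshold_map <- function(pm, mass = 0.95) {
  stopifnot(inherits(pm, "thalnet_probmap"))
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass > 1)
    stop("mass must lie in (0, 1]")
  counts <- pm$counts
  # mass is always taken against the raw map's total visitation, carried on
  # the object, so thresholding an already-thresholded map is a no-op
  total <- if (!is.null(pm$total_visits)) pm$total_visits
           else sum(as.numeric(counts))
  nz <- which(counts > 0L)
  ord <- nz[order(counts[nz], decreasing = TRUE)]
  cum <- cumsum(as.numeric(counts[ord]))
  k <- which(cum >= mass * total)[1]
  boundary <- counts[ord[k]]
  keep <- counts >= boundary          # ties at the boundary all retained
  out <- pm
  out$values[!keep] <- 0
  out$counts[!keep] <- 0L
  out$threshold_mass <- mass
  out$kind <- "thresholded"
  out
}
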