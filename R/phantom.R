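#' Synthetic-patient phantom configuration
#'
#' Defines the study-like conditions the phantoms emulate: cortical SOZ
#' spheres of ~10 mm radius connected to thalamic nuclei by curved tube
#' bundles embedded in an orientation field, a reduced thalamic label set
#' (ANT, CM, MD, Pulv plus a remainder), a brainstem exclusion region,
#' quadripolar 3.5-mm-spacing depth electrodes at the bundle's thalamic end,
#' and a monotone outcome model (scaled logistic link from activation
#' proportion to expected seizure reduction, Gaussian noise, clamped to
#' [0, 100]). Per-patient variation comes from the electrode's lateral
#' offset from the bundle, so the engagement metrics are exercised under a
#' known geometric ground truth.
#'
#' @param shape grid dimensions (voxels).
#' @param voxel_mm isotropic voxel size.
#' @param soz_radius_mm SOZ sphere radius.
#' @param tube_radius_mm bundle tube radius.
#' @param bundles list of bundle specs: `list(name=, soz_center=, via=
#'   (optional matrix/vector of intermediate control points), target=
#'   nucleus name or explicit end point)`.
#' @param electrode list: `spacing_mm`, `polarity`, `amplitude_mA`,
#'   `offset_range_mm` (uniform range of the lateral electrode offset).
#' @param outcome list: `midpoint`, `steepness` (logistic link on the
#'   activation proportion, in proportion units), `noise_sd` (percentage
#'   points), `E_star`.
#' @param cohort_size number of synthetic patients.
#' @param seed integer driving every random draw of the phantom.
#' @return `thalnet_phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 64L, 64L), voxel_mm = 1,
                           soz_radius_mm = 10, tube_radius_mm = 3,
                           bundles = default_bundles(),
                           electrode = list(spacing_mm = 3.5,
                                            polarity = "+-00",
                                            amplitude_mA = 2,
                                            offset_range_mm = c(1.5, 4.5)),
                           outcome = list(midpoint = 0.12, steepness = 25,
                                          noise_sd = 15, E_star = 0.2),
                           cohort_size = 12L, seed = 1L) {
  stopifnot(soz_radius_mm > 0, tube_radius_mm > 0, cohort_size >= 1L,
            outcome$noise_sd >= 0, length(shape) == 3L, all(shape > 0))
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 soz_radius_mm = soz_radius_mm,
                 tube_radius_mm = tube_radius_mm, bundles = bundles,
                 electrode = electrode, outcome = outcome,
                 cohort_size = as.integer(cohort_size),
                 seed = as.integer(seed)),
            class = "thalnet_phantom_config")
}

#' Default single-bundle spec (one SOZ into CM)
#' @return List of bundle specs.
#' @export
default_bundles <- function() {
  list(list(name = "SOZ1_CM", soz_center = c(14, 32, 52),
            via = c(22, 32, 42), target = "CM", side = "R"))
}

#' Bundle specs emulating a convergent two-SOZ patient (both into CM)
#' @return List of bundle specs.
#' @export
convergent_bundles <- function() {
  list(list(name = "SOZ1_CM", soz_center = c(14, 32, 52),
            via = c(22, 30, 42), target = "CM", side = "R"),
       list(name = "SOZ3_CM", soz_center = c(32, 50, 50),
            via = c(34, 40, 40), target = "CM", side = "R"))
}

#' Bundle specs emulating a transthalamic two-SOZ patient (ANT and Pulv
#' with adjoining thalamic routes)
#' @return List of bundle specs.
#' @export
transthalamic_bundles <- function() {
  list(list(name = "SOZ1_ANT", soz_center = c(14, 32, 52),
            via = c(20, 36, 44), target = "ANT", side = "R"),
       list(name = "SOZ2_Pulv", soz_center = c(50, 32, 52),
            via = rbind(c(40, 36, 42), c(33, 37, 36)), target = "Pulv",
            side = "R"))
}

#' Bundle spec that crosses the thalamus and terminates in the brainstem
#' @return List with one bundle spec.
#' @export
brainstem_routed_bundles <- function() {
  # the curve is completed above the thalamus so the transthalamic descent
  # into the brainstem is straight: streamlines that survive the bend all
  # terminate in the brainstem label
  list(list(name = "SOZ1_brainstem", soz_center = c(14, 32, 52),
            via = rbind(c(24, 30.5, 47), c(29, 29, 44.5), c(31.5, 28.2, 41.5),
                        c(32, 28, 38)),
            target = c(32, 28, 8), side = "R", interp = "linear",
            radius = 2))
}

# fixed anatomy of the standard phantom, in mm for a given config
phantom_layout <- function(config) {
  list(nuclei = list(ANT = c(27, 37, 36), CM = c(36, 28, 32),
                     MD = c(30, 33, 31), Pulv = c(38, 37, 30)),
       nucleus_radius = 3.5,
       thal_center = c(32, 32, 32), thal_semiaxes = c(10, 9, 8),
       brain_center = c(32, 32, 36), brain_semiaxes = c(28, 28, 26),
       brainstem_center_xy = c(32, 27), brainstem_radius = 7,
       brainstem_z = c(2, 12))
}

sphere_voxels <- function(grid, center, radius) {
  d <- grid$shape
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  ctr <- voxel_to_world(grid, ijk)
  which(rowSums(sweep(ctr, 2, center)^2) <= radius^2)
}

ellipsoid_voxels <- function(grid, center, semi) {
  d <- grid$shape
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  ctr <- voxel_to_world(grid, ijk)
  u <- sweep(sweep(ctr, 2, center), 2, semi, "/")
  which(rowSums(u^2) <= 1)
}

# cubic-spline centerline through control points, resampled at ~ds mm,
# with unit tangents
spline_centerline <- function(ctrl, ds = 0.5, method = c("spline", "linear")) {
  ctrl <- as.matrix(ctrl)
  method <- match.arg(method)
  if (nrow(ctrl) == 2L || method == "linear") {
    # piecewise-straight polyline
    pts <- do.call(rbind, lapply(seq_len(nrow(ctrl) - 1L), function(i) {
      a <- ctrl[i, ]; b <- ctrl[i + 1L, ]
      len <- sqrt(sum((b - a)^2))
      tt <- seq(0, 1, length.out = max(2L, ceiling(len / ds) + 1L))
      if (i < nrow(ctrl) - 1L) tt <- tt[-length(tt)]
      outer(1 - tt, a) + outer(tt, b)
    }))
  } else {
    s <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
    ss <- seq(0, max(s), by = ds)
    pts <- vapply(1:3, function(c_) {
      stats::spline(s, ctrl[, c_], xout = ss, method = "natural")$y
    }, numeric(length(ss)))
  }
  tang <- rbind(pts[2, ] - pts[1, ], (pts[-1, , drop = FALSE] -
                pts[-nrow(pts), , drop = FALSE]))
  tang <- tang / sqrt(rowSums(tang^2))
  list(points = pts, tangents = tang)
}

# resolve a bundle spec to its control-point matrix, extending 3 mm beyond
# the target so streamlines penetrate the nucleus
bundle_control_points <- function(spec, layout) {
  target <- if (is.character(spec$target)) layout$nuclei[[spec$target]]
            else spec$target
  if (is.null(target)) stop("unknown bundle target for '", spec$name, "'")
  via <- spec$via
  ctrl <- rbind(spec$soz_center,
                if (!is.null(via)) rbind3(via),
                target)
  cl <- spline_centerline(ctrl, method = bundle_interp(spec))
  last_t <- cl$tangents[nrow(cl$tangents), ]
  rbind(ctrl, target + 3 * last_t)
}

bundle_interp <- function(spec) {
  if (is.null(spec$interp)) "spline" else spec$interp
}

#' Build one synthetic patient
#'
#' Assembles the label map, the orientation field (tangent lobes of
#' amplitude 1 inside each bundle tube, isotropic 0.05-amplitude lobes —
#' below the 0.1 tracking cutoff — elsewhere), the SOZ/thalamus/brainstem
#' masks, the electrode at the first bundle's thalamic end (lateral offset
#' taken from the patient's slot in the cohort's offset draw), and the
#' geometric ground truth.
#'
#' @param config `thalnet_phantom_config`.
#' @param patient_index which patient's electrode offset to use.
#' @return `thalnet_phantom` list: `labels`, `field`, `soz_masks`,
#'   `thalamus`, `brainstem`, `electrode`, `setting`, `bundles` (centerline
#'   samples/tangents), `true_proportion`, `offset_mm`.
#' @export
build_phantom <- function(config, patient_index = 1L) {
  layout <- phantom_layout(config)
  aff <- diag(c(rep(config$voxel_mm, 3), 1))
  d <- config$shape
  grid <- volume(array(0, dim = d), aff)

  labs <- array(0L, dim = d)
  dict <- default_labels()
  labs[ellipsoid_voxels(grid, layout$brain_center, layout$brain_semiaxes)] <-
    dict[["white_matter"]]
  thal_idx <- ellipsoid_voxels(grid, layout$thal_center, layout$thal_semiaxes)
  labs[thal_idx] <- dict[["thal_other"]]
  for (nm in names(layout$nuclei)) {
    idx <- sphere_voxels(grid, layout$nuclei[[nm]], layout$nucleus_radius)
    labs[intersect(idx, thal_idx)] <- dict[[nm]]
  }
  # brainstem column
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  ctr <- voxel_to_world(grid, ijk)
  bs_idx <- which((ctr[, 1] - layout$brainstem_center_xy[1])^2 +
                  (ctr[, 2] - layout$brainstem_center_xy[2])^2 <=
                  layout$brainstem_radius^2 &
                  ctr[, 3] >= layout$brainstem_z[1] &
                  ctr[, 3] <= layout$brainstem_z[2])
  labs[bs_idx] <- dict[["brainstem"]]

  soz_masks <- list()
  for (b in config$bundles) {
    idx <- sphere_voxels(grid, b$soz_center, config$soz_radius_mm)
    labs[setdiff(idx, bs_idx)] <- dict[["cortex"]]
    m <- array(FALSE, dim = d); m[idx] <- TRUE
    soz_masks[[b$name]] <- mask(m, aff)
  }

  # orientation field: up to 3 lobes; background low-amplitude isotropic
  nl <- 3L
  amps <- array(0, dim = c(d, nl))
  dirs <- array(0, dim = c(d, nl, 3))
  nvox <- prod(d)
  bundles <- list()
  for (b in config$bundles) {
    ctrl <- bundle_control_points(b, layout)
    cl <- spline_centerline(ctrl, method = bundle_interp(b))
    pts <- cl$points
    vox <- world_to_voxel(grid, pts)
    if (any(vox < -0.5) || any(sweep(vox, 2, d - 0.5) >= 0))
      stop("bundle '", b$name, "' leaves the grid")
    tube_r <- if (is.null(b$radius)) config$tube_radius_mm else b$radius
    st <- stamp_tube(d, grid, pts, cl$tangents, tube_r)
    # place this bundle's tangents in the first free lobe slot per voxel
    for (r in seq_along(st$voxels)) {
      v <- st$voxels[r]
      slot <- which(amps[v + (0:(nl - 1)) * nvox] == 0)[1]
      if (is.na(slot)) next
      amps[v + (slot - 1L) * nvox] <- 1
      off <- v + (slot - 1L) * nvox
      dirs[off] <- st$tangents[r, 1]
      dirs[off + nl * nvox] <- st$tangents[r, 2]
      dirs[off + 2L * nl * nvox] <- st$tangents[r, 3]
    }
    bundles[[b$name]] <- list(spec = b, centerline = pts,
                              tangents = cl$tangents)
  }
  bg <- which(amps[, , , 1] == 0)
  amps[bg] <- 0.05
  dirs_bg1 <- bg                       # lobe 1, component x
  dirs[dirs_bg1] <- 1
  field <- orientation_field(dirs, amps, aff)

  thal_mask <- array(FALSE, dim = d); thal_mask[thal_idx] <- TRUE
  bs_mask <- array(FALSE, dim = d); bs_mask[bs_idx] <- TRUE

  # electrode at the first bundle's thalamic end, offset laterally
  offs <- patient_offsets(config)
  d_off <- offs[((patient_index - 1L) %% config$cohort_size) + 1L]
  b1 <- bundles[[1]]
  n_end <- nrow(b1$centerline)
  p_end <- b1$centerline[n_end, ]
  t_end <- b1$tangents[n_end, ]
  normal <- orthonormal_to(t_end)
  elec <- electrode_model(p_end - config$electrode$spacing_mm * t_end +
                            d_off * normal,
                          t_end, spacing_mm = config$electrode$spacing_mm,
                          side = config$bundles[[1]]$side)
  setting <- stim_setting(config$electrode$polarity,
                          config$electrode$amplitude_mA,
                          side = config$bundles[[1]]$side)

  structure(list(grid = grid,
                 labels = label_map(labs, aff, dict),
                 field = field,
                 soz_masks = soz_masks,
                 thalamus = mask(thal_mask, aff),
                 brainstem = mask(bs_mask, aff),
                 electrode = elec, setting = setting,
                 bundles = bundles,
                 offset_mm = d_off,
                 true_proportion = true_activation_proportion(config, d_off),
                 config = config, patient_index = patient_index),
            class = "thalnet_phantom")
}

# voxels within `radius` of the sampled centerline, with the tangent of the
# nearest centerline sample
stamp_tube <- function(d, grid, pts, tangents, radius) {
  nvox <- prod(d)
  best_d2 <- rep(Inf, nvox)
  best_r <- rep(0L, nvox)
  vs <- voxel_size(grid)
  rv <- ceiling(radius / min(vs)) + 1L
  box <- as.matrix(expand.grid(-rv:rv, -rv:rv, -rv:rv))
  for (r in seq_len(nrow(pts))) {
    c_vox <- floor(world_to_voxel(grid, pts[r, ]) + 0.5)
    cand <- sweep(box, 2, c_vox, "+")
    ok <- cand[, 1] >= 0 & cand[, 1] < d[1] & cand[, 2] >= 0 &
          cand[, 2] < d[2] & cand[, 3] >= 0 & cand[, 3] < d[3]
    cand <- cand[ok, , drop = FALSE]
    ctrs <- voxel_to_world(grid, cand)
    d2 <- rowSums(sweep(ctrs, 2, pts[r, ])^2)
    near <- d2 <= radius^2 + 1e-9   # keep exact-boundary voxels consistently
    if (!any(near)) next
    lin <- cand[near, 1] + d[1] * (cand[near, 2] + d[2] * cand[near, 3]) + 1
    d2n <- d2[near]
    upd <- d2n < best_d2[lin]
    best_d2[lin[upd]] <- d2n[upd]
    best_r[lin[upd]] <- r
  }
  sel <- which(best_r > 0L)
  list(voxels = sel, tangents = tangents[best_r[sel], , drop = FALSE])
}

orthonormal_to <- function(t) {
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n <- ref - sum(ref * t) * t
  n / sqrt(sum(n^2))
}

# per-patient electrode offsets, a deterministic function of the config seed
patient_offsets <- function(config) {
  r <- config$electrode$offset_range_mm
  withr_seed(config$seed, stats::runif(config$cohort_size, r[1], r[2]))
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Point-source activation radius (mm) for a stimulation setting
#'
#' Closed form for a monopole in a homogeneous medium: the distance at which
#' the field magnitude equals the threshold, r* = sqrt(I / (4 pi sigma E*)).
#'
#' @param amplitude_mA cathodic current (single cathode).
#' @param sigma_S_per_m conductivity.
#' @param E_star threshold in V/mm.
#' @return Radius in mm.
#' @export
activation_radius_mm <- function(amplitude_mA, sigma_S_per_m = 0.14,
                                 E_star = 0.2) {
  sqrt(amplitude_mA / (4 * pi * sigma_S_per_m * E_star))
}

#' Overlap area of two discs (mm^2)
#'
#' Geometric primitive behind the phantom's ground-truth activation
#' proportion: fibers fill the bundle's cross-section disc of radius `R`,
#' and a fiber is activated when its lateral position falls within the
#' activation disc of radius `r` whose center is offset `d` from the bundle
#' axis.
#'
#' @param R,r disc radii.
#' @param d center separation.
#' @return Overlap area.
#' @export
disc_overlap_area <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(pi * min(R, r)^2)
  r^2 * acos((d^2 + r^2 - R^2) / (2 * d * r)) +
    R^2 * acos((d^2 + R^2 - r^2) / (2 * d * R)) -
    0.5 * sqrt((-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R))
}

#' Geometric ground-truth activation proportion for an electrode offset
#'
#' @param config `thalnet_phantom_config`.
#' @param offset_mm lateral electrode offset(s) from the bundle axis.
#' @return Proportion(s) in [0, 1].
#' @export
true_activation_proportion <- function(config, offset_mm) {
  # the electrode's neighborhood is thalamic gray matter, so the activation
  # radius uses the gray-matter conductivity
  rstar <- activation_radius_mm(config$electrode$amplitude_mA,
                                sigma_S_per_m = 0.33,
                                E_star = config$outcome$E_star)
  R <- config$tube_radius_mm
  vapply(offset_mm, function(d_) {
    disc_overlap_area(R, rstar, d_) / (pi * R^2)
  }, numeric(1))
}

#' Ground-truth activation proportion from ideal bundle fibers
#'
#' Independent of the tracker: lays a regular grid of lateral offsets over
#' the bundle's cross-section disc, transports each offset along the
#' centerline (parallel transport of the normal frame), and reports the
#' fraction of these ideal fibers whose path enters the VTA region. This is
#' the geometric reference the tracked-and-counted activation proportion is
#' validated against.
#'
#' @param phantom `thalnet_phantom`.
#' @param vta `thalnet_vta` on the phantom grid.
#' @param spacing_mm offset-grid spacing over the cross-section.
#' @return Proportion in [0, 1].
#' @export
geometric_activation_proportion <- function(phantom, vta, spacing_mm = 0.5) {
  R <- phantom$config$tube_radius_mm
  g <- seq(-R, R, by = spacing_mm)
  offs <- as.matrix(expand.grid(u = g, v = g))
  offs <- offs[rowSums(offs^2) <= R^2, , drop = FALSE]
  hits <- 0L
  for (b in phantom$bundles) {
    cl <- b$centerline
    tg <- b$tangents
    n <- nrow(cl)
    # parallel-transported orthonormal frame along the centerline
    e1 <- matrix(0, n, 3); e2 <- matrix(0, n, 3)
    e1[1, ] <- orthonormal_to(tg[1, ])
    e2[1, ] <- cross3(tg[1, ], e1[1, ])
    for (i in 2:n) {
      e1[i, ] <- transport_vec(e1[i - 1, ], tg[i - 1, ], tg[i, ])
      e2[i, ] <- cross3(tg[i, ], e1[i, ])
    }
    for (r in seq_len(nrow(offs))) {
      fiber <- cl + offs[r, 1] * e1 + offs[r, 2] * e2
      idx <- voxel_linear_index(vta, nearest_voxel(vta, fiber))
      idx <- idx[!is.na(idx)]
      if (any(vta$values[idx])) hits <- hits + 1L
    }
  }
  hits / (nrow(offs) * length(phantom$bundles))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotate v by the minimal rotation taking unit vector t0 to t1
transport_vec <- function(v, t0, t1) {
  c_ <- sum(t0 * t1)
  if (c_ > 1 - 1e-12) return(v)
  ax <- cross3(t0, t1)
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  vpar <- sum(v * ax) * ax
  vperp <- v - vpar
  w <- cross3(ax, vperp)
  vpar + vperp * c_ + w * s
}

#' Expected seizure reduction for an activation proportion (noise-free)
#'
#' Scaled logistic link: 100 / (1 + exp(-steepness * (p - midpoint))).
#'
#' @param proportion activation proportion(s).
#' @param outcome outcome-parameter list (see [phantom_config()]).
#' @return Expected reduction percent.
#' @export
expected_reduction <- function(proportion,
                               outcome = phantom_config()$outcome) {
  100 / (1 + exp(-outcome$steepness * (proportion - outcome$midpoint)))
}

#' Simulate observed reductions from activation proportions
#'
#' Applies the logistic link, adds Gaussian noise and clamps to [0, 100].
#' With `noise_sd = 0` the result is a strictly increasing function of the
#' proportion (before clamping saturates).
#'
#' @param proportion activation proportions.
#' @param outcome outcome-parameter list.
#' @return Observed reduction percents.
#' @export
simulate_outcomes <- function(proportion,
                              outcome = phantom_config()$outcome) {
  mu <- expected_reduction(proportion, outcome)
  pmin(100, pmax(0, mu + stats::rnorm(length(mu), 0, outcome$noise_sd)))
}

#' Generate a synthetic cohort table with ground truth
#'
#' Draws each patient's electrode offset, converts it to the geometric
#' activation proportion, and passes it through the outcome model. The
#' imaging objects for any patient are reproducible via
#' [build_phantom()] with the same config.
#'
#' @param config `thalnet_phantom_config`.
#' @return List: `cohort` (data frame: patient_id, offset_mm,
#'   true_proportion, expected_reduction, reduction, response),
#'   `ground_truth` (list with the per-patient geometric quantities),
#'   `config`.
#' @export
generate_cohort <- function(config = phantom_config()) {
  offs <- patient_offsets(config)
  p_true <- true_activation_proportion(config, offs)
  mu <- expected_reduction(p_true, config$outcome)
  red <- withr_seed(config$seed + 1L,
                    simulate_outcomes(p_true, config$outcome))
  cohort <- data.frame(patient_id = seq_len(config$cohort_size),
                       offset_mm = offs,
                       true_proportion = p_true,
                       expected_reduction = mu,
                       reduction = red,
                       response = classify_response(red),
                       stringsAsFactors = FALSE)
  list(cohort = cohort,
       ground_truth = list(offsets_mm = offs, true_proportion = p_true,
                           expected_reduction = mu,
                           activation_radius_mm = activation_radius_mm(
                             config$electrode$amplitude_mA,
                             sigma_S_per_m = 0.33,
                             E_star = config$outcome$E_star)),
       config = config)
}
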