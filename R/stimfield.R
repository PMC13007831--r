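#' Quadripolar depth-electrode model
#'
#' Contacts are modeled as points along the electrode axis; contact 1 is the
#' most distal (at the tip position) and spacing is center-to-center.
#'
#' @param tip_mm distal-tip position (mm, world space).
#' @param direction unit 3-vector from tip toward the electrode shaft.
#' @param spacing_mm center-to-center contact spacing (3.5 mm leads used for
#'   thalamic RNS).
#' @param n_contacts number of contacts.
#' @param side "L" or "R".
#' @return `thalnet_electrode` with a `contacts` matrix (one row per contact).
#' @export
electrode_model <- function(tip_mm, direction, spacing_mm = 3.5,
                            n_contacts = 4L, side = NA_character_) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) {
    if (nrm == 0) stop("electrode direction must be nonzero")
    direction <- direction / nrm
  }
  stopifnot(spacing_mm > 0, n_contacts >= 1L)
  k <- seq_len(n_contacts) - 1L
  contacts <- t(vapply(k, function(i) tip_mm + i * spacing_mm * direction,
                       numeric(3)))
  structure(list(tip_mm = as.numeric(tip_mm), direction = direction,
                 spacing_mm = spacing_mm, n_contacts = as.integer(n_contacts),
                 contacts = contacts, side = side),
            class = "thalnet_electrode")
}

#' One stimulation setting
#'
#' @param polarity length-4 string over `+`, `-`, `0` giving the polarity of
#'   contacts 1-4 (contact 1 most distal); the Unicode minus is accepted.
#' @param amplitude_mA total cathodic current in mA.
#' @param side "L" or "R".
#' @param pulse_width_us,frequency_Hz carried as metadata; the field model
#'   does not use them.
#' @return `thalnet_stim_setting`.
#' @export
stim_setting <- function(polarity, amplitude_mA, side = NA_character_,
                         pulse_width_us = NA_real_, frequency_Hz = NA_real_) {
  polarity <- normalize_polarity(polarity)
  pol <- strsplit(polarity, "")[[1]]
  if (length(pol) != 4L)
    stop("polarity string must have exactly 4 characters, got '", polarity, "'")
  if (!all(pol %in% c("+", "-", "0")))
    stop("polarity characters must be +, - or 0")
  if (!is.finite(amplitude_mA) || amplitude_mA < 0)
    stop("amplitude must be a non-negative number of mA")
  if (amplitude_mA > 0 && !any(pol == "-"))
    stop("a nonzero amplitude requires at least one cathode")
  structure(list(polarity = pol, amplitude_mA = amplitude_mA, side = side,
                 pulse_width_us = pulse_width_us, frequency_Hz = frequency_Hz),
            class = "thalnet_stim_setting")
}

normalize_polarity <- function(s) {
  # tables print the Unicode minus sign
  gsub("−", "-", s)
}

#' Parse the per-side stimulation notation of the cohort table
#'
#' The notation gives, per side, the polarity of the four contacts followed
#' by the amplitude in mA, e.g. `"L: +-00 2 R: 0+-0 .5"`.
#'
#' @param text nonempty setting string.
#' @return Named list of `thalnet_stim_setting`, one per side present.
#' @export
parse_stim_string <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("stimulation string must be a nonempty character scalar")
  text <- normalize_polarity(text)
  pat <- "([LR])\\s*:\\s*(\\S+)\\s+(\\S+)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    stop("stimulation parse error at position 1: expected 'L:' or 'R:' in '",
         text, "'")
  res <- list()
  groups <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  for (g in groups) {
    parts <- regmatches(g, regexec(pat, g, perl = TRUE))[[1]]
    side <- parts[2]; pol <- parts[3]; amp_txt <- parts[4]
    if (nchar(pol) != 4L)
      stop("stimulation parse error near '", g, "': polarity string '", pol,
           "' is not length 4")
    amp <- suppressWarnings(as.numeric(amp_txt))
    if (is.na(amp))
      stop("stimulation parse error near '", g, "': missing or non-numeric ",
           "amplitude '", amp_txt, "'")
    res[[side]] <- stim_setting(pol, amp, side = side)
  }
  res
}

#' Tissue conductivity model
#'
#' Standard gray/white scalar conductivities. The values 0.33 and 0.14 are
#' interpreted in S/m (the conventional units for these constants); a
#' literal-S/mm reading is available behind `units` for sensitivity checks
#' but produces sub-0.1 mm activation volumes.
#'
#' @param sigma_gray,sigma_white conductivities.
#' @param units "S/m" (default) or "S/mm".
#' @return `thalnet_conductivity`.
#' @export
conductivity_model <- function(sigma_gray = 0.33, sigma_white = 0.14,
                               units = c("S/m", "S/mm")) {
  units <- match.arg(units)
  stopifnot(sigma_gray > 0, sigma_white > 0)
  scale <- if (units == "S/mm") 1000 else 1   # to S/m
  structure(list(sigma_gray = sigma_gray * scale,
                 sigma_white = sigma_white * scale, units = units),
            class = "thalnet_conductivity")
}

# signed current (A) per contact: cathodes share -amplitude, anodes +amplitude
contact_currents_A <- function(setting) {
  pol <- setting$polarity
  I <- numeric(length(pol))
  if (setting$amplitude_mA == 0) return(I)
  ncat <- sum(pol == "-"); nan_ <- sum(pol == "+")
  I[pol == "-"] <- -setting$amplitude_mA * 1e-3 / ncat
  if (nan_ > 0) I[pol == "+"] <- setting$amplitude_mA * 1e-3 / nan_
  I
}

# scalar conductivity (S/m) at world points given the tissue labels:
# cortex and thalamic nuclei count as gray matter, everything else as white
conductivity_at <- function(points_mm, labels, conductivity) {
  if (is.null(labels))
    return(rep(conductivity$sigma_white, nrow(rbind3(points_mm))))
  idx <- voxel_linear_index(labels, nearest_voxel(labels, points_mm))
  lab <- rep(0L, length(idx))
  lab[!is.na(idx)] <- labels$values[idx[!is.na(idx)]]
  gray_ids <- c(labels$labels[["cortex"]], thalamic_label_ids(labels$labels))
  ifelse(lab %in% gray_ids, conductivity$sigma_gray, conductivity$sigma_white)
}

#' Electric-field magnitude of a stimulation setting (V/mm)
#'
#' Analytic point-source superposition in a locally sampled scalar medium:
#' each active contact contributes I_k (r - c_k) / (4 pi sigma(r) |r - c_k|^3)
#' and the vector sum's magnitude is reported in V/mm. Points that coincide
#' with a contact center are capped at `cap_V_per_mm` rather than infinity.
#'
#' @param electrode `thalnet_electrode`.
#' @param setting `thalnet_stim_setting`.
#' @param points_mm 3-vector or n x 3 matrix of evaluation points.
#' @param labels `thalnet_labelmap` for tissue lookup (NULL = all white
#'   matter).
#' @param conductivity `thalnet_conductivity`.
#' @param cap_V_per_mm cap applied at (numerically) singular points.
#' @return Numeric vector of |E| in V/mm.
#' @export
electric_field_magnitude <- function(electrode, setting, points_mm,
                                     labels = NULL,
                                     conductivity = conductivity_model(),
                                     cap_V_per_mm = 1e3) {
  p <- rbind3(points_mm)
  I <- contact_currents_A(setting)
  if (all(I == 0)) return(rep(0, nrow(p)))
  sigma <- conductivity_at(p, labels, conductivity)
  E <- matrix(0, nrow(p), 3)
  at_contact <- rep(FALSE, nrow(p))
  for (k in seq_len(electrode$n_contacts)) {
    if (I[k] == 0) next
    d <- sweep(p, 2, electrode$contacts[k, ])      # mm
    r2 <- rowSums(d^2)                             # mm^2
    r <- sqrt(r2)
    at_contact <- at_contact | r2 < 1e-12
    # I/(4 pi sigma r^2) with r in m gives V/m; converting to V/mm and r^2
    # from mm^2 to m^2 leaves a net factor of 1e3 on the mm expression
    coef <- ifelse(r > 0, I[k] * 1e3 / (4 * pi * sigma * r2 * r), 0)
    E <- E + d * coef
  }
  mag <- sqrt(rowSums(E^2))
  mag[at_contact] <- cap_V_per_mm
  pmin(mag, cap_V_per_mm)
}

#' Volume of tissue activated (VTA)
#'
#' Evaluates the field magnitude at every voxel center of `grid` and keeps
#' the voxels at or above the threshold `E_star` (0.2 V/mm by default), the
#' binary VTA. An amplitude of 0 gives an empty VTA.
#'
#' @param electrode `thalnet_electrode`.
#' @param setting `thalnet_stim_setting`.
#' @param grid `thalnet_volume` (or mask / label map) defining the voxels.
#' @param labels optional `thalnet_labelmap` for conductivity lookup.
#' @param conductivity `thalnet_conductivity`.
#' @param E_star field threshold in V/mm.
#' @return `thalnet_vta`: a mask with `volume_mm3`, `E_star` and `setting`.
#' @export
compute_vta <- function(electrode, setting, grid, labels = NULL,
                        conductivity = conductivity_model(), E_star = 0.2) {
  active <- contact_currents_A(setting) != 0
  check_rows <- if (any(active)) electrode$contacts[active, , drop = FALSE]
                else electrode$contacts[1, , drop = FALSE]
  iv <- nearest_voxel(grid, check_rows)
  if (any(is.na(voxel_linear_index(grid, iv))))
    stop("electrode contacts fall outside the grid")
  d <- grid$shape
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  centers <- voxel_to_world(grid, ijk)
  mag <- electric_field_magnitude(electrode, setting, centers, labels,
                                  conductivity)
  inside <- array(mag >= E_star, dim = d)
  if (setting$amplitude_mA == 0) inside[] <- FALSE
  v <- mask(inside, grid$affine)
  v$volume_mm3 <- sum(inside) * voxel_volume_mm3(grid)
  v$E_star <- E_star
  v$setting <- setting
  class(v) <- c("thalnet_vta", class(v))
  v
}

#' Union of per-side VTAs
#'
#' Bilateral stimulation pools the two sides' activation volumes into one
#' per-patient VTA (voxelwise union).
#'
#' @param vtas nonempty list of `thalnet_vta` on one grid.
#' @return Merged `thalnet_vta`.
#' @export
merge_vtas <- function(vtas) {
  if (length(vtas) == 0L) stop("merge_vtas: empty list")
  stopifnot(all(vapply(vtas, inherits, TRUE, "thalnet_vta")))
  ref <- vtas[[1]]
  acc <- Reduce(`|`, lapply(vtas, `[[`, "values"))
  out <- mask(acc, ref$affine)
  out$volume_mm3 <- sum(acc) * voxel_volume_mm3(ref)
  out$E_star <- ref$E_star
  out$setting <- lapply(vtas, `[[`, "setting")
  class(out) <- c("thalnet_vta", class(out))
  out
}
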