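#' 3-D scalar volume with a voxel-to-world affine
#'
#' A `thalnet_volume` is the basic voxel grid shared by every stage of the
#' analysis: a 3-D array of values plus a 4x4 affine mapping *0-based* voxel
#' indices (voxel-center convention) to RAS world coordinates in mm.
#'
#' @param values 3-D numeric, integer or logical array.
#' @param affine 4x4 invertible matrix, voxel (0-based) to mm.
#' @return An object of class `thalnet_volume` with fields `values`, `affine`
#'   and `shape`.
#' @export
volume <- function(values, affine = diag(4)) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12)
    stop("affine is singular")
  if (!all(is.finite(values)))
    stop("values must be finite")
  structure(list(values = values, affine = affine, shape = dim(values)),
            class = "thalnet_volume")
}

#' @export
print.thalnet_volume <- function(x, ...) {
  cat(sprintf("<thalnet_volume %s, voxel %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(voxel_size(x), 3), collapse = "x")))
  invisible(x)
}

#' Binary mask on a reference grid
#'
#' @param values logical 3-D array (or coercible).
#' @param affine voxel-to-world affine, or a `thalnet_volume` whose grid the
#'   mask lives on.
#' @return `thalnet_mask`, a `thalnet_volume` with logical values.
#' @export
mask <- function(values, affine = diag(4)) {
  if (inherits(affine, "thalnet_volume")) affine <- affine$affine
  v <- volume(array(as.logical(values), dim = dim(values)), affine)
  class(v) <- c("thalnet_mask", class(v))
  v
}

#' Integer label map with a label dictionary
#'
#' Labels used throughout the phantoms: background (0), cortex, white_matter,
#' brainstem, and the thalamic nuclei ANT, CM, MD, Pulv plus `thal_other`.
#' The dictionary is open: any id -> name mapping covering every nonzero
#' voxel is accepted.
#'
#' @param values integer 3-D array of label ids.
#' @param affine voxel-to-world affine, or a reference `thalnet_volume`.
#' @param labels named integer vector, names are label names.
#' @return `thalnet_labelmap`.
#' @export
label_map <- function(values, affine = diag(4), labels = default_labels()) {
  if (inherits(affine, "thalnet_volume")) affine <- affine$affine
  storage.mode(values) <- "integer"
  v <- volume(values, affine)
  present <- setdiff(unique(as.vector(values)), 0L)
  missing <- setdiff(present, labels)
  if (length(missing))
    stop("label ids not in dictionary: ", paste(missing, collapse = ", "))
  v$labels <- labels
  class(v) <- c("thalnet_labelmap", class(v))
  v
}

#' Default label dictionary
#'
#' @return Named integer vector of label ids.
#' @export
default_labels <- function() {
  c(background = 0L, cortex = 1L, white_matter = 2L, brainstem = 3L,
    ANT = 10L, CM = 11L, MD = 12L, Pulv = 13L, thal_other = 14L)
}

#' Thalamic label ids within a dictionary
#'
#' @param labels named integer vector (a label dictionary).
#' @param nuclei_only drop the `thal_other` remainder compartment, keeping
#'   only named nuclei.
#' @return Integer ids of the thalamic labels present.
#' @export
thalamic_label_ids <- function(labels = default_labels(),
                               nuclei_only = FALSE) {
  wanted <- c("ANT", "CM", "MD", "Pulv", if (!nuclei_only) "thal_other")
  unname(labels[names(labels) %in% wanted])
}

#' Physical voxel dimensions of a volume (mm)
#' @param vol `thalnet_volume`.
#' @return Length-3 numeric, mm per voxel along each axis.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Voxel volume in mm^3
#' @param vol `thalnet_volume`.
#' @return Scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' Map world (mm) points to continuous 0-based voxel coordinates
#'
#' @param vol `thalnet_volume` carrying the grid.
#' @param points_mm 3-vector or n x 3 matrix of mm coordinates.
#' @return Same shape as the input, continuous voxel coordinates.
#' @export
world_to_voxel <- function(vol, points_mm) {
  p <- rbind3(points_mm)
  inv <- solve(vol$affine)
  out <- t(inv %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  if (is.null(dim(points_mm))) drop(out) else out
}

#' Map 0-based voxel coordinates to world mm
#' @param vol `thalnet_volume`.
#' @param ijk 3-vector or n x 3 matrix of (continuous) voxel coordinates.
#' @return mm coordinates, same shape.
#' @export
voxel_to_world <- function(vol, ijk) {
  p <- rbind3(ijk)
  out <- t(vol$affine %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  if (is.null(dim(ijk))) drop(out) else out
}

#' Nearest voxel index for world points (round half up)
#' @param vol `thalnet_volume`.
#' @param points_mm mm coordinates.
#' @return Integer 0-based voxel indices, rows matching the input points.
#' @export
nearest_voxel <- function(vol, points_mm) {
  v <- rbind3(world_to_voxel(vol, points_mm))
  storage.mode(v) <- "double"
  iv <- floor(v + 0.5)
  storage.mode(iv) <- "integer"
  iv
}

# coerce a 3-vector or n x 3 matrix to matrix form
rbind3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

# linear index (1-based) into vol$values for integer 0-based ijk rows,
# NA outside the grid
voxel_linear_index <- function(vol, ijk) {
  ijk <- rbind3(ijk)
  d <- vol$shape
  ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
        ijk[, 2] >= 0 & ijk[, 2] < d[2] &
        ijk[, 3] >= 0 & ijk[, 3] < d[3]
  idx <- ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3]) + 1
  idx[!ok] <- NA_integer_
  idx
}

#' Write a volume to NIfTI-1
#'
#' Integer-valued volumes (labels, masks) are stored as int32 so labels
#' round-trip bit-exactly; real volumes as float64.
#'
#' @param vol `thalnet_volume` (mask / label map included).
#' @param path output path, conventionally `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vals <- vol$values
  if (is.logical(vals) || inherits(vol, "thalnet_labelmap")) {
    storage.mode(vals) <- "integer"
    dtype <- "int32"
  } else if (is.integer(vals)) {
    dtype <- "int32"
  } else {
    dtype <- "double"
  }
  img <- RNifti::asNifti(vals, datatype = dtype)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Validates the header magic before handing the file to the NIfTI reader so
#' that malformed files fail with a named header field rather than a partial
#' object.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param as one of "volume", "mask", "labelmap".
#' @param labels label dictionary when `as = "labelmap"`.
#' @return `thalnet_volume` / `thalnet_mask` / `thalnet_labelmap`.
#' @export
read_volume <- function(path, as = c("volume", "mask", "labelmap"),
                        labels = default_labels()) {
  as <- match.arg(as)
  check_nifti_magic(path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))[1:4, 1:4]
  vals <- as.array(img)
  vals <- array(as.vector(vals), dim = dim(vals)[1:3])  # drop image attrs
  switch(as,
    volume = volume(vals, aff),
    mask = mask(vals != 0, aff),
    labelmap = label_map(array(as.integer(round(vals)), dim = dim(vals)),
                         aff, labels))
}

check_nifti_magic <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    stop("NIfTI parse error in '", basename(path),
         "': header truncated (sizeof_hdr region incomplete)")
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = "little")
  if (!sizeof_hdr %in% c(348L, 1543569408L))  # little- or big-endian 348
    stop("NIfTI parse error in '", basename(path),
         "': sizeof_hdr is ", sizeof_hdr, ", expected 348")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("NIfTI parse error in '", basename(path),
         "': magic field is '", magic, "', expected 'n+1' or 'ni1'")
  invisible(TRUE)
}
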