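#' Streamlines and MRtrix .tck round-trip
#'
#' A streamline is an n x 3 matrix of ordered mm coordinates (n >= 2) with a
#' `step_mm` attribute; a tract is a list of streamlines plus provenance
#' (which SOZ region and hemisphere it was seeded from) and the
#' requested/retained streamline counts.
#'
#' @name streamlines
NULL

#' Construct a streamline
#'
#' @param points n x 3 matrix of mm coordinates, n >= 2.
#' @param step_mm nominal step length; consecutive points must be within 10%
#'   of it (endpoints of a step chain excepted when the last step is short).
#' @param check validate spacing against `step_mm`.
#' @return The matrix with class `thalnet_streamline`.
#' @export
streamline <- function(points, step_mm = NULL, check = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("a streamline needs >= 2 points in 3 columns")
  if (!all(is.finite(points))) stop("streamline coordinates must be finite")
  d <- sqrt(rowSums(diff(points)^2))
  if (is.null(step_mm)) step_mm <- stats::median(d)
  if (check && any(abs(d - step_mm) > 0.1 * step_mm))
    stop("consecutive-point spacing deviates more than 10% from step length")
  structure(points, step_mm = step_mm, class = c("thalnet_streamline", "matrix"))
}

#' Bundle retained streamlines into a tract
#'
#' @param streamlines list of point matrices.
#' @param soz_id identifier of the seed SOZ region.
#' @param side "L" or "R".
#' @param n_requested number of streamlines asked of the tracker.
#' @return `thalnet_tract` with `n_retained = length(streamlines)`.
#' @export
tract <- function(streamlines, soz_id = "SOZ", side = NA_character_,
                  n_requested = length(streamlines)) {
  structure(list(streamlines = streamlines,
                 provenance = data.frame(soz_id = soz_id, side = side,
                                         stringsAsFactors = FALSE),
                 n_requested = n_requested,
                 n_retained = length(streamlines)),
            class = "thalnet_tract")
}

#' @export
print.thalnet_tract <- function(x, ...) {
  cat(sprintf("<thalnet_tract %d/%d streamlines from %s>\n",
              x$n_retained, x$n_requested,
              paste(x$provenance$soz_id, collapse = "+")))
  invisible(x)
}

#' Merge per-SOZ tracts into one tract per patient
#'
#' Multiple SOZ tracts (unilateral or bilateral) are pooled into a single
#' streamline set; counts add and provenance rows are concatenated.
#'
#' @param tracts nonempty list of `thalnet_tract`.
#' @return A single merged `thalnet_tract`.
#' @export
merge_tracts <- function(tracts) {
  if (length(tracts) == 0L) stop("merge_tracts: empty tract list")
  stopifnot(all(vapply(tracts, inherits, TRUE, "thalnet_tract")))
  out <- tract(do.call(c, lapply(tracts, `[[`, "streamlines")))
  out$provenance <- do.call(rbind, lapply(tracts, `[[`, "provenance"))
  out$n_requested <- sum(vapply(tracts, `[[`, 0, "n_requested"))
  out$n_retained <- sum(vapply(tracts, `[[`, 0, "n_retained"))
  stopifnot(out$n_retained == length(out$streamlines))
  out
}

#' Write streamlines to an MRtrix .tck file
#'
#' Float32 little-endian triplets, streamlines delimited by a NaN triplet and
#' the stream terminated by an Inf triplet, as the format defines. An empty
#' set writes a valid zero-track file.
#'
#' @param streamlines list of n x 3 mm coordinate matrices, or a
#'   `thalnet_tract`.
#' @param path output path (.tck).
#' @return `path`, invisibly.
#' @export
write_tck <- function(streamlines, path) {
  if (inherits(streamlines, "thalnet_tract"))
    streamlines <- streamlines$streamlines
  fixed <- c("mrtrix tracks",
             "datatype: Float32LE",
             sprintf("count: %d", length(streamlines)))
  # the 'file: . <offset>' line changes its own length with the offset value;
  # iterate until self-consistent
  offset <- 0L
  repeat {
    hdr <- paste0(paste(c(fixed, sprintf("file: . %d", offset), "END"),
                        collapse = "\n"), "\n")
    need <- nchar(hdr, type = "bytes")
    if (need == offset) break
    offset <- need
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in streamlines) {
    writeBin(as.vector(t(as.matrix(s))), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRtrix .tck file
#'
#' @param path .tck file.
#' @return List of n x 3 coordinate matrices (possibly empty).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(first, "mrtrix tracks"))
    stop("TCK parse error in '", basename(path),
         "': missing 'mrtrix tracks' signature")
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L)
      stop("TCK parse error in '", basename(path), "': header lacks END")
    if (ln == "END") break
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) fields[[kv[2]]] <- kv[3]
  }
  dt <- fields[["datatype"]]
  if (is.null(dt) || !dt %in% c("Float32LE", "Float32BE"))
    stop("TCK parse error in '", basename(path), "': unsupported datatype '",
         if (is.null(dt)) "<missing>" else dt, "'")
  endian <- if (dt == "Float32LE") "little" else "big"
  off <- as.integer(sub("^\\.\\s+", "", fields[["file"]]))
  seek(con, off)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L, endian = endian)
  pts <- matrix(raw, ncol = 3L, byrow = TRUE)
  inf_at <- which(is.infinite(pts[, 1]))
  if (length(inf_at)) pts <- pts[seq_len(inf_at[1] - 1L), , drop = FALSE]
  sep <- which(is.nan(pts[, 1]))
  starts <- c(1L, sep + 1L)
  ends <- c(sep - 1L, nrow(pts))
  keep <- starts <= ends
  mapply(function(a, b) pts[a:b, , drop = FALSE],
         starts[keep], ends[keep], SIMPLIFY = FALSE)
}
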