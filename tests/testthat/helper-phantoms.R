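# Small synthetic fields and an independent path-following oracle used
# across the tracking / probmap / metrics tests.

# Straight single-lobe corridor along +x: every corridor voxel has exactly
# one supra-cutoff lobe (amplitude 1, direction +x); everything else sits
# below the 0.1 cutoff. The "thalamus" is the far end of the corridor.
corridor_phantom <- function(len = 40L, width = 11L, amp_bg = 0.05) {
  d <- c(len, width, width)
  mid <- (width - 1) / 2
  amps <- array(amp_bg, dim = c(d, 1L))
  dirs <- array(0, dim = c(d, 1L, 3L))
  dirs[, , , 1, 1] <- 1                      # background lobes point +x too
  corr <- expand.grid(i = 0:(len - 1), j = (mid - 2):(mid + 2),
                      k = (mid - 2):(mid + 2))
  for (r in seq_len(nrow(corr)))
    amps[corr$i[r] + 1, corr$j[r] + 1, corr$k[r] + 1, 1] <- 1
  field <- orientation_field(dirs, amps)

  seed <- array(FALSE, dim = d)
  seed[2, mid + 1, mid + 1] <- TRUE
  thal <- array(FALSE, dim = d)
  thal[(len - 3):len, (mid - 2):(mid + 3), (mid - 2):(mid + 3)] <- TRUE
  list(field = field,
       seed = mask(seed), thalamus = mask(thal),
       grid = volume(array(0, dim = d)))
}

# Independent deterministic integrator: at each step take the (single)
# supra-cutoff lobe of the nearest voxel, sign-aligned with the incoming
# direction. Written against the rule, not against the tracker code.
follow_field <- function(field, start, dir, step = 0.5, cutoff = 0.1,
                         max_steps = 600L) {
  grid <- volume(array(0, dim = field$shape), field$affine)
  p <- start
  d <- dir / sqrt(sum(dir^2))
  path <- matrix(p, 1, 3)
  for (s in seq_len(max_steps)) {
    q <- p + step * d
    v <- nearest_voxel(grid, q)
    if (any(v < 0) || any(v >= field$shape)) break
    amps <- field$amps[v[1] + 1, v[2] + 1, v[3] + 1, ]
    l <- which(amps >= cutoff)
    if (length(l) == 0L) break
    l <- l[which.max(amps[l])]
    lobe <- field$dirs[v[1] + 1, v[2] + 1, v[3] + 1, l, ]
    if (sum(lobe * d) < 0) lobe <- -lobe
    d <- lobe
    p <- p + step * d
    path <- rbind(path, p)
  }
  path
}

# max distance from each point of `pts` to the polyline sample set `ref`
max_point_set_distance <- function(pts, ref) {
  max(vapply(seq_len(nrow(pts)), function(i) {
    min(sqrt(rowSums(sweep(ref, 2, pts[i, ])^2)))
  }, numeric(1)))
}

# a tract built directly from raw point matrices (no tracker involved)
toy_tract <- function(streamlines, ...) tract(streamlines, ...)
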