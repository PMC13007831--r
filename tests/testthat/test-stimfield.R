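test_that("stimulation strings parse to per-side contact settings", {
  s <- parse_stim_string("R: 0+−0 .5")        # Unicode minus, as printed
  expect_named(s, "R")
  expect_equal(s$R$polarity, c("0", "+", "-", "0"))
  expect_equal(s$R$amplitude_mA, 0.5)

  s2 <- parse_stim_string("L: +-00 2 R: +-00 2")
  expect_named(s2, c("L", "R"))
  expect_equal(s2$L$amplitude_mA, 2)
  expect_equal(s2$R$polarity, c("+", "-", "0", "0"))

  s3 <- parse_stim_string("L: +-+- 4")
  expect_equal(s3$L$polarity, c("+", "-", "+", "-"))
  expect_equal(s3$L$amplitude_mA, 4)

  s4 <- parse_stim_string("L: 0000 0")
  expect_equal(s4$L$amplitude_mA, 0)

  expect_error(parse_stim_string("L: +-0 2"), "length 4|parse")
  expect_error(parse_stim_string("L: +-00 x"), "amplitude")
  expect_error(parse_stim_string("whatever"), "parse error")
  expect_error(stim_setting("+x00", 1), "characters")
  expect_error(stim_setting("+000", 1), "cathode")
})

test_that("the point-source field matches the closed form and scales linearly", {
  el <- electrode_model(c(0, 0, 0), c(0, 0, 1))
  st <- stim_setting("-000", 2)
  sig <- conductivity_model()          # white-matter sigma applies: no labels
  rstar <- sqrt(2 / (4 * pi * 0.14 * 0.2))   # mm, amplitude in mA
  expect_equal(rstar, 2.384, tolerance = 1e-3)
  for (r in c(1, rstar, 4)) {
    E <- electric_field_magnitude(el, st, c(r, 0, 0), conductivity = sig)
    expect_equal(E, 2e-3 * 1e3 / (4 * pi * 0.14 * r^2), tolerance = 1e-9)
  }
  # linear in amplitude
  E1 <- electric_field_magnitude(el, stim_setting("-000", 1), c(3, 1, 2))
  E4 <- electric_field_magnitude(el, stim_setting("-000", 4), c(3, 1, 2))
  expect_equal(E4, 4 * E1)
  # zero amplitude: zero field
  expect_equal(electric_field_magnitude(el, stim_setting("0000", 0),
                                        rbind(c(1, 1, 1), c(5, 0, 0))),
               c(0, 0))
  # capped, not infinite, at a contact center
  expect_equal(electric_field_magnitude(el, st, c(0, 0, 0)), 1e3)
})

test_that("bipolar fields are symmetric across the perpendicular bisector", {
  el <- electrode_model(c(0, 0, -1.75), c(0, 0, 1))  # contacts at z -1.75/+1.75
  st <- stim_setting("+-00", 2)
  for (xy in list(c(1, 0), c(2, 3), c(0.5, -1))) {
    above <- electric_field_magnitude(el, st, c(xy, 2.5))
    below <- electric_field_magnitude(el, st, c(xy, -2.5))
    expect_equal(above, below, tolerance = 1e-9)
  }
})

test_that("VTA volume approaches the analytic activation sphere as voxels shrink", {
  rstar <- activation_radius_mm(2, 0.14, 0.2)
  target <- 4 / 3 * pi * rstar^3
  # generic (off-lattice) contact position so no voxel size is accidentally
  # aligned with the activation sphere
  tip <- c(0.13, 0.07, -0.11)
  errs <- vapply(c(1.0, 0.5, 0.25), function(h) {
    n <- ceiling(8 / h); if (n %% 2 == 0) n <- n + 1
    aff <- diag(c(h, h, h, 1)); aff[1:3, 4] <- -(n - 1) / 2 * h
    g <- volume(array(0, dim = c(n, n, n)), aff)
    el <- electrode_model(tip, c(0, 0, 1))
    vta <- compute_vta(el, stim_setting("-000", 2), g)
    abs(vta$volume_mm3 - target) / target
  }, numeric(1))
  expect_lt(errs[3], 0.10)
  expect_lt(errs[3], errs[1])
})

test_that("VTAs are empty at zero amplitude and grow with amplitude", {
  aff <- diag(c(0.5, 0.5, 0.5, 1)); aff[1:3, 4] <- -8
  g <- volume(array(0, dim = c(33, 33, 33)), aff)
  el <- electrode_model(c(0, 0, -5.25), c(0, 0, 1))
  v0 <- compute_vta(el, stim_setting("0000", 0), g)
  expect_equal(v0$volume_mm3, 0)
  v2 <- compute_vta(el, stim_setting("+-+-", 2), g)
  v4 <- compute_vta(el, stim_setting("+-+-", 4), g)
  expect_gt(v2$volume_mm3, 0)
  expect_gt(v4$volume_mm3, v2$volume_mm3)
  expect_error(compute_vta(electrode_model(c(99, 0, 0), c(0, 0, 1)),
                           stim_setting("-000", 1), g), "outside")
})

test_that("single-side VTA volumes for 0.5-6 mA stay in a plausible band", {
  aff <- diag(c(0.5, 0.5, 0.5, 1)); aff[1:3, 4] <- -10
  g <- volume(array(0, dim = c(41, 41, 41)), aff)
  el <- electrode_model(c(0, 0, -5.25), c(0, 0, 1))
  cases <- list(c("0+-0", 0.5), c("+-00", 2), c("+-+-", 4), c("+-+-", 6))
  for (cs in cases) {
    v <- compute_vta(el, stim_setting(cs[[1]], as.numeric(cs[[2]])), g)
    expect_gte(v$volume_mm3, 10)
    expect_lte(v$volume_mm3, 2000)
  }
})

test_that("a literal S/mm conductivity reading collapses the VTA", {
  aff <- diag(c(0.25, 0.25, 0.25, 1)); aff[1:3, 4] <- -4
  g <- volume(array(0, dim = c(33, 33, 33)), aff)
  el <- electrode_model(c(0, 0, 0), c(0, 0, 1))
  st <- stim_setting("-000", 2)
  v_std <- compute_vta(el, st, g)
  v_lit <- compute_vta(el, st, g,
                       conductivity = conductivity_model(units = "S/mm"))
  # radius shrinks by sqrt(1000): nothing but (at most) the contact voxel
  expect_lt(v_lit$volume_mm3, 0.1)
  expect_gt(v_std$volume_mm3, 50)
})

test_that("VTA unions add disjoint volumes and absorb overlaps", {
  aff <- diag(c(0.5, 0.5, 0.5, 1)); aff[1:3, 4] <- -10
  g <- volume(array(0, dim = c(41, 41, 41)), aff)
  st <- stim_setting("-000", 1)
  vl <- compute_vta(electrode_model(c(-5, 0, 0), c(0, 0, 1)), st, g)
  vr <- compute_vta(electrode_model(c(5, 0, 0), c(0, 0, 1)), st, g)
  m <- merge_vtas(list(vl, vr))
  expect_equal(m$volume_mm3, vl$volume_mm3 + vr$volume_mm3)
  expect_equal(merge_vtas(list(vl, vl))$volume_mm3, vl$volume_mm3)
  vo <- compute_vta(electrode_model(c(-4.5, 0, 0), c(0, 0, 1)),
                    stim_setting("-000", 4), g)
  vo2 <- compute_vta(electrode_model(c(-2.5, 0, 0), c(0, 0, 1)),
                     stim_setting("-000", 4), g)
  mo <- merge_vtas(list(vo, vo2))
  expect_lt(mo$volume_mm3, vo$volume_mm3 + vo2$volume_mm3)
  expect_error(merge_vtas(list()), "empty")
})
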