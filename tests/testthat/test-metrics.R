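# a VTA object over an arbitrary boolean array, for metric tests
toy_vta <- function(values, affine = diag(4)) {
  v <- mask(values, affine)
  v$volume_mm3 <- sum(values)
  v$E_star <- 0.2
  class(v) <- c("thalnet_vta", class(v))
  v
}

test_that("activation counts, proportion and rounding follow the table rules", {
  g <- array(FALSE, dim = c(8, 8, 8))
  g[5:8, , ] <- TRUE                       # VTA = half space x >= 4
  vta <- toy_vta(g)
  sls <- c(lapply(1:3, function(i) cbind(seq(5, 7, 0.5), i, i)),   # inside
           lapply(1:5, function(i) cbind(seq(0, 2, 0.5), i, i)))   # outside
  tr <- toy_tract(sls)
  am <- proportion_activated(tr, vta)
  expect_equal(am$n_total, 8L)
  expect_equal(am$n_activated, 3L)
  expect_equal(am$proportion, 3 / 8)
  expect_equal(am$percent_rounded, 38)     # 37.5 rounds half away from zero

  # an empty VTA activates nothing
  none <- toy_vta(array(FALSE, dim = c(8, 8, 8)))
  am0 <- proportion_activated(tr, none)
  expect_equal(am0$n_activated, 0L)
  expect_equal(am0$percent_rounded, 0)
  expect_error(proportion_activated(toy_tract(list()), vta), "no streamlines")
})

test_that("activation is monotone under VTA enlargement", {
  set.seed(3)
  sls <- replicate(40, cbind(seq(0.5, 7, 0.5), runif(1, 1, 7),
                             runif(1, 1, 7)), simplify = FALSE)
  tr <- toy_tract(sls)
  small <- array(FALSE, dim = c(8, 8, 8)); small[4, 4, 4] <- TRUE
  big <- small; big[3:6, 3:6, 3:6] <- TRUE
  n_small <- proportion_activated(tr, toy_vta(small))$n_activated
  n_big <- proportion_activated(tr, toy_vta(big))$n_activated
  expect_gte(n_big, n_small)
})

test_that("tracked proportion agrees with the geometric fiber ground truth", {
  cfg <- phantom_config(cohort_size = 3, seed = 2)
  for (i in c(1L, 2L)) {
    m <- measure_patient(cfg, i, n_select = 250)
    gt <- geometric_activation_proportion(m$phantom, m$vta)
    expect_lt(abs(m$activation$proportion - gt), 0.1)
  }
})

test_that("peak probability in the VTA takes the masked maximum", {
  g <- volume(array(0, dim = c(8, 8, 8)))
  tr <- toy_tract(c(replicate(6, rbind(c(2, 2, 2), c(2.4, 2, 2)),
                              simplify = FALSE),
                    replicate(3, rbind(c(4, 4, 4), c(4.4, 4, 4)),
                              simplify = FALSE),
                    replicate(1, rbind(c(6, 6, 6), c(6.4, 6, 6)),
                              simplify = FALSE)))
  pm <- tract_to_probability_map(tr, g)      # values .6, .3, .1

  all_in <- toy_vta(array(TRUE, dim = c(8, 8, 8)))
  expect_equal(peak_probability_in_vta(pm, all_in)$peak, 0.6)

  disjoint <- array(FALSE, dim = c(8, 8, 8)); disjoint[8, 8, 8] <- TRUE
  expect_equal(peak_probability_in_vta(pm, toy_vta(disjoint))$peak, 0)

  three <- array(FALSE, dim = c(8, 8, 8))
  three[5, 5, 5] <- TRUE; three[7, 7, 7] <- TRUE; three[1, 1, 1] <- TRUE
  pk <- peak_probability_in_vta(pm, toy_vta(three))
  expect_equal(pk$peak, 0.3)                 # max over exactly those voxels
  expect_equal(pk$voxel, c(4L, 4L, 4L))

  # monotone under VTA inclusion
  bigger <- three; bigger[3, 3, 3] <- TRUE
  expect_gte(peak_probability_in_vta(pm, toy_vta(bigger))$peak, pk$peak)
})

test_that("per-side metrics pool as summed counts and max peak", {
  a1 <- thalnet:::activation_metrics(5000, 500)
  a2 <- thalnet:::activation_metrics(5000, 300)
  agg <- aggregate_patient(list(a1, a2),
                           list(list(peak = 0.23), list(peak = 0.11)))
  expect_equal(agg$activation$proportion, 0.08)
  expect_equal(agg$activation$n_total, 10000L)
  expect_equal(agg$peak$peak, 0.23)
  one <- aggregate_patient(list(a1))
  expect_equal(one$activation$proportion, 0.1)
  expect_error(aggregate_patient(list()), "aggregate")
})

test_that("connectivity patterns classify as convergent / transthalamic / single", {
  conv_cfg <- phantom_config(bundles = convergent_bundles(),
                             cohort_size = 1, seed = 12)
  ph <- build_phantom(conv_cfg, 1)
  params <- tracking_params(n_select = 120, max_attempts = 12000, seed = 61)
  tracts <- lapply(names(ph$soz_masks), function(nm)
    track_soz_to_thalamus(ph$field, ph$soz_masks[[nm]], ph$thalamus,
                          ph$brainstem, params, soz_id = nm))
  res <- classify_pattern(tracts, ph$labels)
  expect_equal(res$pattern, "convergent")
  expect_true(all(res$dominant_nucleus == "CM"))

  tt_cfg <- phantom_config(bundles = transthalamic_bundles(),
                           cohort_size = 1, seed = 12)
  ph2 <- build_phantom(tt_cfg, 1)
  tracts2 <- lapply(names(ph2$soz_masks), function(nm)
    track_soz_to_thalamus(ph2$field, ph2$soz_masks[[nm]], ph2$thalamus,
                          ph2$brainstem, params, soz_id = nm))
  res2 <- classify_pattern(tracts2, ph2$labels)
  expect_equal(res2$pattern, "transthalamic")
  expect_setequal(res2$dominant_nucleus, c("ANT", "Pulv"))

  expect_equal(classify_pattern(tracts[1], ph$labels)$pattern, "single")
  bad <- label_map(array(0L, dim = ph$labels$shape), ph$labels$affine,
                   labels = c(background = 0L, cortex = 1L))
  expect_error(classify_pattern(tracts, bad), "thalamic")
})
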