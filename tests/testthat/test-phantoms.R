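# Synthetic phantom cohorts: determinism, noise statistics, analytic atrophy
# ground truth, cohort-level artifacts (upgrade, missingness, clinical).

test_that("make_phantom: noiseless limit, determinism, noise statistics", {
  ph0 <- tiny_phantom(seed = 1, noise_sd = 0, n = 24)
  lab <- ph0$atlas$data
  means <- c(0, 40, 120, 80, 80, 80)
  expect_identical(ph0$volume$data, array(means[lab + 1L], dim(lab)))

  a <- make_phantom(phantom_spec(noise_sd = 5, seed = 7))
  b <- make_phantom(phantom_spec(noise_sd = 5, seed = 7))
  expect_identical(a$volume$data, b$volume$data)

  # per-class sample SD within 10% of the nominal 5
  for (l in c(1, 2, 3)) {
    s <- sd(a$volume$data[a$atlas$data == l])
    expect_gt(s, 4.5); expect_lt(s, 5.5)
  }
  expect_error(phantom_spec(grid_shape = c(8, 32, 32)), "degenerate")
})

test_that("zero-rate noiseless series is exactly visit-invariant", {
  ph <- tiny_phantom(seed = 2, noise_sd = 0, n = 24)
  mdl <- atrophy_model(rate_sd = c(cingulate_analog = 0,
                                   precentral_analog = 0))
  st <- simulate_subject_series(ph, ph$atlas, mdl, seed = 3,
                                rates = c(cingulate_analog = 0,
                                          precentral_analog = 0),
                                n_lesions = 0)
  expect_equal(st$series$times, c(0, 1, 2, 3, 5))   # the study schedule
  for (v in st$series$volumes)
    expect_equal(v$data, ph$volume$data, tolerance = 1e-12)
  for (f in st$truth$fields)
    expect_equal(max(abs(f$disp)), 0)
})

test_that("truth Jacobian integrals equal the cumulative volume factors", {
  ph <- tiny_phantom(seed = 2, noise_sd = 0, n = 32)
  mdl <- atrophy_model()
  st <- simulate_subject_series(ph, ph$atlas, mdl, seed = 3,
                                rates = c(cingulate_analog = -0.02,
                                          precentral_analog = -0.005),
                                n_lesions = 0)
  atlas <- ph$atlas
  i5 <- which(st$series$times == 5)
  # linear model: factor at year 5 = 1 - 0.02*5 = 0.90
  expect_equal(st$truth$factors["cingulate_analog", i5], 0.90,
               tolerance = 1e-12, ignore_attr = TRUE)
  jt <- st$truth$jacobians[[i5]]
  expect_equal(mean(jt$data[atlas$data == 4]), 0.90, tolerance = 0.01)
  expect_equal(mean(jt$data[atlas$data == 5]), 0.975, tolerance = 0.01)
  # every visit, both regions (property over the series)
  for (vi in seq_along(st$series$times)) {
    for (rl in c(4, 5)) {
      nm <- c("cingulate_analog", "precentral_analog")[rl - 3]
      expect_equal(mean(st$truth$jacobians[[vi]]$data[atlas$data == rl]),
                   unname(st$truth$factors[nm, vi]), tolerance = 0.01)
    }
  }
  # the stored truth field reproduces the same Jacobians numerically
  jd <- jacobian_determinant(st$truth$fields[[i5]])
  expect_equal(mean(jd$data[atlas$data == 4]), 0.90, tolerance = 0.015)
})

test_that("impossible cumulative factors and out-of-range rates are rejected", {
  ph <- tiny_phantom(seed = 2, noise_sd = 0, n = 24)
  mdl <- atrophy_model()
  expect_error(simulate_subject_series(ph, ph$atlas, mdl, seed = 1,
                                       rates = c(cingulate_analog = -0.3,
                                                 precentral_analog = 0)),
               "factor <= 0")
  expect_error(atrophy_model(patient_rates = c(a = 0.7),
                             control_rates = c(a = 0)), "rates")
  expect_error(atrophy_model(patient_rates = c(a = -0.01),
                             control_rates = c(a = -0.02)), "control")
})

test_that("cohort: upgrade flags, missingness floor, determinism", {
  co <- simulate_cohort(3, 2, seed = 5, spec = phantom_spec(c(24, 24, 24),
                                                            seed = 5),
                        missingness_rate = 0)
  # upgrade at year 2.5: visits {3, 5} flagged -> 40% of a full schedule,
  # the regime of the study's "41% acquired after the upgrade"
  for (s in co$subjects) {
    expect_identical(s$upgrade, s$times >= 2.5)
    expect_equal(mean(s$upgrade), 0.4)
  }
  # upgrade beyond study end: no flags
  co2 <- simulate_cohort(2, 2, seed = 5, upgrade_year = Inf,
                         spec = phantom_spec(c(24, 24, 24), seed = 5),
                         missingness_rate = 0)
  expect_false(any(vapply(co2$subjects, function(s) any(s$upgrade), TRUE)))

  # heavy missingness never leaves a subject under 2 visits
  co3 <- suppressMessages(
    simulate_cohort(3, 2, seed = 6, missingness_rate = 0.8,
                    spec = phantom_spec(c(24, 24, 24), seed = 6)))
  expect_true(all(vapply(co3$subjects, function(s) length(s$times), 0) >= 2))
  expect_true(all(vapply(co3$subjects, function(s) 0 %in% s$times, TRUE)))

  # fixed seed reproduces the cohort bit-identically
  coA <- simulate_cohort(2, 2, seed = 9,
                         spec = phantom_spec(c(24, 24, 24), seed = 9))
  coB <- simulate_cohort(2, 2, seed = 9,
                         spec = phantom_spec(c(24, 24, 24), seed = 9))
  expect_identical(coA$subjects$P01$volumes[[2]]$data,
                   coB$subjects$P01$volumes[[2]]$data)
  expect_identical(coA$clinical, coB$clinical)
})

test_that("clinical generation: EDSS grid, coupling structure", {
  co <- simulate_cohort(4, 2, seed = 11,
                        spec = phantom_spec(c(24, 24, 24), seed = 11))
  grid <- longvbm:::edss_grid()
  expect_true(all(co$clinical$edss %in% grid))
  expect_true(all(co$clinical$t2_lesion_load_ml >= 0))
  # zero coupling gain: MSFC slope independent of the atrophy rate by
  # construction (regression coefficient exactly the noise draw)
  cc <- clinical_coupling(gain = 0, noise_sd = 0.05)
  set.seed(1)
  rec1 <- longvbm:::make_clinical_records(c(0, 1, 2), "patient", cc, -0.02,
                                          rep(FALSE, 3))
  set.seed(1)
  rec2 <- longvbm:::make_clinical_records(c(0, 1, 2), "patient", cc, -0.40,
                                          rep(FALSE, 3))
  expect_identical(rec1$msfc, rec2$msfc)
})

test_that("cohort round-trips through the on-disk representation", {
  co <- simulate_cohort(2, 2, seed = 13,
                        spec = phantom_spec(c(16, 16, 16), seed = 13))
  dir <- tempfile()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- longvbm:::load_cohort_from_manifest(
    file.path(dir, "manifest.csv"), file.path(dir, "clinical.csv"))
  expect_setequal(names(back$subjects), names(co$subjects))
  s0 <- co$subjects$C01; s1 <- back$subjects$C01
  expect_equal(s1$times, s0$times)
  expect_lt(max(abs(s1$volumes[[1]]$data - s0$volumes[[1]]$data)), 1e-4)
  unlink(dir, recursive = TRUE)
})
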