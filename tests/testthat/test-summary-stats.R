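# First-level voxel-wise slopes/quadratics, EDSS steps, clinical slopes.

series_of <- function(f, times, dm = c(6, 6, 6)) {
  lapply(times, function(t) vol_of(array(f(t), dm)))
}

test_that("fit_voxelwise_slope: closed forms and the oracle", {
  times <- c(0, 1, 2, 3, 5)
  same <- series_of(function(t) 2, times)
  expect_lt(max(abs(fit_voxelwise_slope(same, times)$volume$data)), 1e-12)

  lin <- series_of(function(t) 2 - 0.1 * t, times)
  sl <- fit_voxelwise_slope(lin, times)
  expect_lt(max(abs(sl$volume$data + 0.1)), 1e-12)
  expect_equal(sl$kind, "slope")
  expect_equal(sl$n_visits, 5L)

  # noisy voxel series match the normal-equations oracle
  set.seed(1)
  dm <- c(5, 5, 5)
  noisy <- lapply(times, function(t) vol_of(array(rnorm(125), dm)))
  got <- fit_voxelwise_slope(noisy, times)$volume$data
  for (v in c(1, 37, 125)) {
    y <- vapply(noisy, function(im) im$data[[v]], 0)
    expect_equal(got[[v]], oracle_slope(y, times), tolerance = 1e-12)
  }
  expect_error(fit_voxelwise_slope(series_of(function(t) t, c(2, 2)),
                                   c(2, 2)), "times")
})

test_that("fit_voxelwise_quadratic: closed forms and the oracle", {
  times <- c(0, 1, 2, 3, 5)
  lin <- series_of(function(t) 1 + 0.3 * t, times)
  expect_lt(max(abs(fit_voxelwise_quadratic(lin, times)$volume$data)), 1e-12)

  sq <- series_of(function(t) t^2, times)
  expect_lt(max(abs(fit_voxelwise_quadratic(sq, times)$volume$data - 1)),
            1e-12)

  set.seed(2)
  noisy <- lapply(times, function(t) vol_of(array(rnorm(27), c(3, 3, 3))))
  got <- fit_voxelwise_quadratic(noisy, times)$volume$data
  for (v in c(1, 14, 27)) {
    y <- vapply(noisy, function(im) im$data[[v]], 0)
    expect_equal(got[[v]], oracle_quadratic(y, times), tolerance = 1e-10)
  }
  expect_error(fit_voxelwise_quadratic(noisy[1:2], times[1:2]), "distinct")
})

test_that("slope estimator is linear in the data", {
  times <- c(0, 1, 3, 5)
  set.seed(3)
  y1 <- lapply(times, function(t) vol_of(array(rnorm(27), c(3, 3, 3))))
  y2 <- lapply(times, function(t) vol_of(array(rnorm(27), c(3, 3, 3))))
  mix <- lapply(1:4, function(i) vol_of(2 * y1[[i]]$data - 3 * y2[[i]]$data))
  s1 <- fit_voxelwise_slope(y1, times)$volume$data
  s2 <- fit_voxelwise_slope(y2, times)$volume$data
  sm <- fit_voxelwise_slope(mix, times)$volume$data
  expect_equal(sm, 2 * s1 - 3 * s2, tolerance = 1e-12)
})

test_that("edss_to_steps maps the ordinal grid", {
  expect_equal(edss_to_steps(c(4, 4, 4)) - edss_to_steps(c(4, 4, 4)),
               c(0, 0, 0))
  expect_equal(edss_to_steps(4.5) - edss_to_steps(4), 1)   # adjacent points
  grid <- longvbm:::edss_grid()
  ranks <- edss_to_steps(grid)
  expect_length(unique(ranks), 20)
  expect_true(all(diff(ranks) == 1))
  expect_equal(ranks[1], 0)
  expect_equal(ranks[length(ranks)], 19)
  expect_error(edss_to_steps(c(1, 0.5)), "off-grid")
})

test_that("clinical_slope: closed forms and oracle", {
  times <- c(0, 1, 2, 3, 5)
  # the patient-progression regime: MSFC falling 0.25/yr
  expect_equal(clinical_slope(-1.2 - 0.25 * times, times), -0.25,
               tolerance = 1e-12)
  expect_equal(clinical_slope(rep(3, 5), times), 0)
  set.seed(4)
  y <- rnorm(5)
  expect_equal(clinical_slope(y, times), oracle_slope(y, times),
               tolerance = 1e-12)
})

test_that("ROI fractional rate is recovered within 30% at 5% noise", {
  # three full within-subject runs on 32^3 phantoms (cohort-level contract:
  # per-subject recovery varies with the noise realisation, the mean is what
  # the two-level approach consumes)
  ph <- tiny_phantom(seed = 31, noise_sd = 5, n = 32)
  mdl <- atrophy_model(rate_sd = c(cingulate_analog = 0,
                                   precentral_analog = 0))
  reg <- ph$atlas$data == 4
  frac <- vapply(1:3, function(k) {
    st <- simulate_subject_series(ph, ph$atlas, mdl, seed = 31 + k,
                                  group = "patient",
                                  rates = c(cingulate_analog = -0.02,
                                            precentral_analog = -0.005),
                                  upgrade_year = 2.5)
    prep <- preprocess_series(st$series)
    wst <- suppressWarnings(build_median_template(prep))
    tmpl <- wst$template
    bm <- extract_brain(tmpl)
    bm2 <- longvbm:::like_volume(
      as.numeric(bm$data > 0.5 & tmpl$data > 0.05 * max(tmpl$data)), tmpl)
    seg <- segment_template(tmpl, 3, bm2)
    pm <- vapply(seq_along(st$series$times), function(vi) {
      al <- resample_rigid(prep[[vi]], tmpl, wst$transforms[[vi]])
      jac <- jacobian_determinant(hdw_register(al, tmpl))
      mean(pseudo_timepoint(seg$gm, jac)$data[reg])
    }, 0)
    clinical_slope(pm, st$series$times) / pm[1]
  }, 0)
  expect_lt(abs(mean(frac) - (-0.02)), 0.3 * 0.02)
})

test_that("slope images are robust to deleting one interior visit", {
  times <- c(0, 1, 2, 3, 5)
  ph <- tiny_phantom(seed = 33, noise_sd = 0, n = 24)
  gm <- vol_of((ph$atlas$data >= 3) * 1)
  make_series <- function(seed) {
    set.seed(seed)
    lapply(times, function(t) {
      j <- 1 - 0.02 * t * (ph$atlas$data == 4) +
        array(rnorm(length(gm$data), 0, 0.01), dim(gm$data))
      vol_of(gm$data * j)
    })
  }
  s1 <- make_series(1); s2 <- make_series(2)
  full1 <- fit_voxelwise_slope(s1, times)$volume$data
  full2 <- fit_voxelwise_slope(s2, times)$volume$data
  run_sd <- sd(full1 - full2)
  drop2 <- fit_voxelwise_slope(s1[-3], times[-3])$volume$data
  expect_lt(sd(drop2 - full1), 3 * run_sd)
})
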