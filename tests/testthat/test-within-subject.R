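# Median templates, demons HDW registration, Jacobians, segmentation,
# pseudo-time-points.

test_that("median template: degenerate and identical-visit cases", {
  ph <- tiny_phantom(seed = 1, noise_sd = 0, n = 24)
  one <- build_median_template(list(ph$volume))
  expect_identical(one$template$data, ph$volume$data)
  expect_equal(one$iterations, 1L)

  three <- build_median_template(rep(list(ph$volume), 3), normalize = FALSE)
  expect_equal(three$template$data, ph$volume$data, tolerance = 1e-9)
  for (tr in three$transforms) {
    expect_lt(max(abs(tr$params[4:6])), 0.01)
    expect_lt(max(abs(tr$params[1:3])) * 180 / pi, 0.01)
  }
})

test_that("median template is invariant to visit order", {
  co <- simulate_cohort(2, 2, seed = 21,
                        spec = phantom_spec(c(24, 24, 24), seed = 21),
                        missingness_rate = 0)
  vols <- preprocess_series(co$subjects$P01)
  t1 <- suppressWarnings(build_median_template(vols))
  t2 <- suppressWarnings(build_median_template(rev(vols)))
  expect_lt(mean(abs(t1$template$data - t2$template$data)), 1e-6)
})

test_that("median template beats the mean template on outlier visits", {
  ph <- tiny_phantom(seed = 2, noise_sd = 5, n = 24)
  vols <- lapply(1:5, function(i)
    vol_of(ph$volume$data + array(rnorm(length(ph$volume$data), 0, 2),
                                  dim(ph$volume$data))))
  med0 <- longvbm:::voxelwise_median(vols, vols[[1]])
  mean0 <- voxelwise_mean(vols)
  out <- vols
  out[[3]] <- vol_of(out[[3]]$data * 1.5)   # 50% intensity-scaled outlier
  med1 <- longvbm:::voxelwise_median(out, out[[1]])
  mean1 <- voxelwise_mean(out)
  expect_lt(mean(abs(med1$data - med0$data)),
            mean(abs(mean1$data - mean0$data)))
})

test_that("hdw_register: identity input, recovery, regularisation", {
  ph <- tiny_phantom(seed = 3, noise_sd = 0, n = 32)
  f0 <- hdw_register(ph$volume, ph$volume)
  expect_lt(max(abs(f0$disp)) / min(ph$volume$voxel_mm), 0.1)

  # visit synthesized with region volume factor 0.90 at year 5
  mdl <- atrophy_model()
  st <- simulate_subject_series(ph, ph$atlas, mdl, seed = 4,
                                rates = c(cingulate_analog = -0.02,
                                          precentral_analog = 0),
                                n_lesions = 0)
  i5 <- which(st$series$times == 5)
  fld <- hdw_register(st$series$volumes[[i5]], ph$volume)
  jac <- jacobian_determinant(fld)
  reg <- ph$atlas$data == 4
  expect_gte(mean(jac$data[reg]), 0.87)
  expect_lte(mean(jac$data[reg]), 0.93)
  expect_lte(mean(jac$data <= 0), 0.001)    # near-diffeomorphic contract

  # stronger regularisation produces a smoother (lower-energy) field
  f_hi <- hdw_register(st$series$volumes[[i5]], ph$volume, reg_param = 40)
  expect_lt(membrane_energy(f_hi), membrane_energy(fld))
})

test_that("jacobian_determinant matches closed forms and the oracle", {
  dm <- c(10, 10, 10)
  vox <- c(2, 2, 2)
  zero <- array(0, c(dm, 3))
  ref <- vol_of(array(0, dm), vox)
  jid <- jacobian_determinant(longvbm:::new_deformation_field(zero, ref))
  expect_identical(unique(as.numeric(jid$data)), 1)

  # uniform linear scaling u(x) = 0.1 x  ->  det = 1.1^3 everywhere
  g <- longvbm:::index_grid(dm)
  lin <- array(0, c(dm, 3))
  for (c3 in 1:3) lin[, , , c3] <- array(0.1 * g[, c3] * vox[c3], dm)
  jl <- jacobian_determinant(longvbm:::new_deformation_field(lin, ref))
  expect_lt(max(abs(jl$data - 1.1^3)), 1e-10)

  # random smooth field on 8^3 vs the explicit per-voxel determinant oracle
  set.seed(5)
  dm8 <- c(8, 8, 8)
  fld <- array(0, c(dm8, 3))
  for (c3 in 1:3)
    fld[, , , c3] <- longvbm:::gauss_blur_arr(
      array(rnorm(prod(dm8), 0, 0.8), dm8), 1.2)
  ref8 <- vol_of(array(0, dm8), c(1.5, 2, 2.5))
  got <- jacobian_determinant(
    longvbm:::new_deformation_field(fld, ref8))$data
  expect_lt(max(abs(got - oracle_jacobian(fld, c(1.5, 2, 2.5)))), 1e-10)
})

test_that("segment_template: separated, noisy and normalisation contracts", {
  ph0 <- tiny_phantom(seed = 6, noise_sd = 0, n = 24)
  brain <- vol_of((ph0$atlas$data > 0) * 1)
  seg0 <- segment_template(ph0$volume, 3, brain)
  lab_true <- pmin(ph0$atlas$data, 3)   # GM labels 3..5 share intensity 80
  # T1 ascending convention: csf < gm < wm; truth classes 1=csf 2=wm 3..=gm
  post <- vapply(seg0[c("csf", "gm", "wm")],
                 function(v) as.numeric(v$data), numeric(length(lab_true)))
  hard <- max.col(post)
  # posterior-column order is csf, gm, wm; atlas labels are csf=1, wm=2, gm=3
  want <- c(1, 3, 2)[pmax(lab_true, 1)]
  bm <- brain$data > 0.5
  expect_equal(mean(hard[bm] == want[bm]), 1)

  ph <- tiny_phantom(seed = 6, noise_sd = 8, n = 24)  # 20% of the 40 gap
  seg <- segment_template(ph$volume, 3, brain)
  post <- vapply(seg[c("csf", "gm", "wm")],
                 function(v) as.numeric(v$data), numeric(length(lab_true)))
  hard <- max.col(post)
  expect_gte(mean(hard[bm] == want[bm]), 0.99)
  sums <- post[bm, 1] + post[bm, 2] + post[bm, 3]
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("pseudo_timepoint products and volume bookkeeping", {
  ph <- tiny_phantom(seed = 7, noise_sd = 0, n = 24)
  gm <- vol_of((ph$atlas$data >= 3) * 1)
  ones <- vol_of(array(1, dim(gm$data)))
  expect_identical(pseudo_timepoint(gm, ones)$data, gm$data)
  jac <- vol_of(array(1, dim(gm$data)))
  jac$data[ph$atlas$data == 4] <- 0.9
  pt <- pseudo_timepoint(gm, jac)
  expect_true(all(pt$data[ph$atlas$data == 4] == 0.9))
  expect_error(pseudo_timepoint(gm, vol_of(array(1, c(16, 16, 16)))),
               "grid")

  # noiseless subject: total pseudo-GM volume tracks the true GM volume
  mdl <- atrophy_model()
  ph32 <- tiny_phantom(seed = 8, noise_sd = 0, n = 32)
  st <- simulate_subject_series(ph32, ph32$atlas, mdl, seed = 9,
                                rates = c(cingulate_analog = -0.02,
                                          precentral_analog = -0.005),
                                n_lesions = 0)
  gm32 <- vol_of((ph32$atlas$data >= 3) * 1)
  i5 <- which(st$series$times == 5)
  fld <- hdw_register(st$series$volumes[[i5]], ph32$volume)
  pt5 <- pseudo_timepoint(gm32, jacobian_determinant(fld))
  voxvol_ml <- prod(ph32$volume$voxel_mm) / 1000
  expect_equal(sum(pt5$data) * voxvol_ml, st$truth$gm_volume[i5],
               tolerance = 0.03)
})
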