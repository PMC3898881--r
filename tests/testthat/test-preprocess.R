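# Rigid coregistration, lesion filling, non-uniformity correction, brain
# extraction.

test_that("rigid_coregister recovers identity and known translations", {
  ph <- tiny_phantom(seed = 3, noise_sd = 5, n = 24)
  vol <- ph$volume
  tr0 <- rigid_coregister(vol, vol)
  expect_lt(max(abs(tr0$params[4:6])), 0.1)                  # mm
  expect_lt(max(abs(tr0$params[1:3])) * 180 / pi, 0.1)       # deg
  # metric at the optimum is no worse than at identity
  expect_lte(attr(tr0, "metric_value"), attr(tr0, "metric_identity"))

  # fixed = moving shifted by (3, -2, 1) mm in world space
  A <- vol$affine; A[1:3, 4] <- A[1:3, 4] + c(3, -2, 1)
  fixed <- as_volume(vol$data, affine = A)
  tr <- rigid_coregister(vol, fixed)
  expect_lt(max(abs(tr$params[4:6] - c(3, -2, 1))), 0.5)
  expect_lte(attr(tr, "metric_value"), attr(tr, "metric_identity"))

  expect_error(rigid_coregister(vol_of(array(1, c(16, 16, 16))),
                                vol_of(array(1, c(16, 16, 16)))), "flat")
})

test_that("mutual information metric also aligns the phantom", {
  ph <- tiny_phantom(seed = 4, noise_sd = 5, n = 24)
  vol <- ph$volume
  A <- vol$affine; A[1:3, 4] <- A[1:3, 4] + c(2, 0, -2)
  fixed <- as_volume(vol$data, affine = A)
  tr <- rigid_coregister(vol, fixed, metric = "mutual_information")
  expect_lt(max(abs(tr$params[4:6] - c(2, 0, -2))), 0.75)
})

test_that("rigid registration is inverse-consistent", {
  ph <- tiny_phantom(seed = 5, noise_sd = 5, n = 24)
  vol <- ph$volume
  A <- vol$affine; A[1:3, 4] <- A[1:3, 4] + c(1.5, -1, 2)
  other <- as_volume(vol$data, affine = A)
  fw <- rigid_coregister(vol, other)
  bw <- rigid_coregister(other, vol)
  comp <- compose_rigid(bw, fw)$matrix
  # displacement of the composed map at brain voxels
  brain <- which(ph$atlas$data > 0)
  g <- longvbm:::index_grid(dim(vol$data))[brain, , drop = FALSE]
  w <- t(vol$affine %*% t(cbind(g, 1)))[, 1:3]
  w2 <- t(comp %*% t(cbind(w, 1)))[, 1:3]
  expect_lt(max(sqrt(rowSums((w2 - w)^2))), 0.5)
})

test_that("fill_lesions fills from the normal-WM model and nothing else", {
  ph <- tiny_phantom(seed = 6, noise_sd = 5, n = 24)
  img <- ph$volume
  wm <- ph$atlas$data == 2
  # 50-voxel lesion inside WM at WM mean - 30%
  les <- array(FALSE, dim(wm))
  wm_idx <- which(wm)
  les[wm_idx[1000:1049]] <- TRUE
  lesioned <- img$data
  lesioned[les] <- mean(img$data[wm]) * 0.7
  lvol <- vol_of(lesioned); lesv <- vol_of(les * 1)
  wmv <- vol_of((wm & !les) * 1)
  filled <- fill_lesions(lvol, lesv, wmv, seed = 2)
  wm_mean <- mean(img$data[wm & !les]); wm_sd <- sd(img$data[wm & !les])
  expect_lt(abs(mean(filled$data[les]) - wm_mean), 2 * wm_sd)
  # voxels outside the lesion are untouched, exactly
  expect_identical(filled$data[!les], lesioned[!les])
  # empty lesion mask: output identical to input
  expect_identical(fill_lesions(lvol, vol_of(les * 0), wmv)$data, lvol$data)
  # no normal WM to sample from
  expect_error(fill_lesions(lvol, vol_of(wm * 1), vol_of(wm * 0)), "WM")
})

test_that("correct_nonuniformity recovers applied bias and preserves mean", {
  ph <- tiny_phantom(seed = 7, noise_sd = 5, n = 24)
  img <- ph$volume
  brain <- vol_of((ph$atlas$data > 0) * 1)
  bm <- brain$data > 0.5

  # bias-free image passes through within 1% voxel-wise (brain voxels)
  out0 <- suppressMessages(correct_nonuniformity(img, 2, brain))
  rel <- abs(out0$data[bm] - img$data[bm]) / pmax(abs(img$data[bm]), 1)
  expect_lt(quantile(rel, 0.99), 0.01)

  # known linear bias: residual bias SD under 20% of the applied SD
  dm <- dim(img$data)
  gx <- (slice.index(img$data, 1) - 1) / (dm[1] - 1)
  bias <- 0.85 + 0.3 * gx
  biased <- vol_of(img$data * bias)
  out <- suppressMessages(correct_nonuniformity(biased, 2, brain))
  ratio <- out$data[bm] / img$data[bm]
  expect_lt(sd(ratio), 0.2 * sd(bias[bm]))
  # mean brain intensity preserved to 0.1%
  expect_lt(abs(mean(out$data[bm]) / mean(biased$data[bm]) - 1), 1e-3)
})

test_that("extract_brain matches phantom support", {
  ph0 <- tiny_phantom(seed = 8, noise_sd = 0, n = 24)
  mask <- extract_brain(ph0$volume)
  expect_identical(mask$data > 0.5, ph0$atlas$data > 0)

  ph <- tiny_phantom(seed = 8, noise_sd = 5, n = 24)
  m2 <- extract_brain(ph$volume)$data > 0.5
  truth <- ph$atlas$data > 0
  dice <- 2 * sum(m2 & truth) / (sum(m2) + sum(truth))
  expect_gte(dice, 0.98)

  expect_error(extract_brain(vol_of(array(3, c(16, 16, 16)))), "constant")
})
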