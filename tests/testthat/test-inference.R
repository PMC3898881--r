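# GLM t maps, TFCE, permutation FWE.

mk_imgs <- function(Y, dm) {
  lapply(seq_len(nrow(Y)), function(i) vol_of(array(Y[i, ], dm)))
}

test_that("glm_t_map equals textbook formulas", {
  set.seed(1)
  dm <- c(4, 4, 4)
  n <- 8
  Y <- matrix(rnorm(n * prod(dm)), n)
  imgs <- mk_imgs(Y, dm)
  mask <- vol_of(array(1, dm))

  # one-sample t at every voxel
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  tmap <- glm_t_map(imgs, X, 1, mask)
  want <- colMeans(Y) / (apply(Y, 2, sd) / sqrt(n))
  expect_lt(max(abs(as.numeric(tmap$data) - want)), 1e-10)

  # a nuisance column orthogonal to both contrast and data leaves the
  # contrast estimate, residuals and error-variance structure unchanged;
  # the only change is the residual df, a known deterministic factor
  z <- rep(c(1, -1), n / 2)
  Yp <- Y - outer(z, colSums(z * Y) / sum(z * z))   # orthogonalised data
  t1 <- glm_t_map(mk_imgs(Yp, dm), X, 1, mask)
  t2 <- glm_t_map(mk_imgs(Yp, dm), cbind(X, z = z), c(1, 0), mask)
  expect_equal(as.numeric(t2$data),
               as.numeric(t1$data) * sqrt((n - 2) / (n - 1)),
               tolerance = 1e-10)

  # two groups with identical values: t exactly 0
  Yc <- rbind(Y[1:4, ], Y[1:4, ])
  d <- make_design(data.frame(group = rep(c("patient", "control"),
                                          each = 4)))
  t0 <- glm_t_map(mk_imgs(Yc, dm), d, d$contrasts$patient_gt_control, mask)
  expect_lt(max(abs(t0$data)), 1e-10)

  expect_error(glm_t_map(imgs, cbind(X, X), c(1, 0), mask), "rank")
})

test_that("two-sample t path matches the pooled-variance oracle", {
  set.seed(2)
  dm <- c(3, 3, 3)
  Y <- matrix(rnorm(6 * 27), 6)
  g <- c(1, 1, 1, 0, 0, 0)
  d <- make_design(data.frame(group = ifelse(g == 1, "patient", "control")))
  mask <- vol_of(array(1, dm))
  tmap <- glm_t_map(mk_imgs(Y, dm), d, d$contrasts$patient_gt_control, mask)
  expect_lt(max(abs(as.numeric(tmap$data) - oracle_two_sample_t(Y, g))),
            1e-10)
})

test_that("tfce: closed form, zeros, oracle, monotonicity", {
  dm <- c(12, 12, 12)
  expect_true(all(tfce(array(0, dm), dh = 0.1) == 0))
  expect_error(tfce(array(1, dm), dh = -1), "dh")

  # uniform 3x3x3 cluster of height 3: integral sqrt(27) * 9 = 46.765
  stat <- array(0, dm)
  stat[5:7, 5:7, 5:7] <- 3
  enh <- tfce(stat, E = 0.5, H = 2, dh = 0.01)
  expect_equal(enh[6, 6, 6], sqrt(27) * 9, tolerance = 0.01 * sqrt(27) * 9)
  expect_true(all(abs(enh[stat == 3] - enh[6, 6, 6]) < 1e-9))

  # random image vs the igraph component-labelling oracle
  set.seed(3)
  stat <- array(pmax(0, rnorm(prod(dm), 0.3, 1)), dm)
  dh <- max(stat) / 30
  got <- tfce(stat, dh = dh)
  want <- oracle_tfce(stat, dh = dh)
  expect_lt(max(abs(got - want)), 1e-8)

  # monotonicity with identical support topology: scaling up heights only
  got2 <- tfce(stat * 1.3, dh = dh)
  expect_true(all(got2 - got > -1e-12))
})

test_that("exhaustive two-sample relabelling matches brute force exactly", {
  set.seed(4)
  dm <- c(4, 4, 4)
  n1 <- 3; n0 <- 3
  Y <- matrix(rnorm((n1 + n0) * prod(dm)), n1 + n0)
  Y[1:3, 1:20] <- Y[1:3, 1:20] + 2     # a real group effect at some voxels
  g <- c(1, 1, 1, 0, 0, 0)
  d <- make_design(data.frame(group = ifelse(g == 1, "patient", "control")))
  mask <- vol_of(array(1, dm))
  expect_message(
    pr <- permutation_fwe(mk_imgs(Y, dm), d, d$contrasts$patient_gt_control,
                          mask, n_perm = 100, enhance = "none", seed = 1),
    "20 group relabellings")
  expect_true(pr$exhaustive)
  expect_equal(pr$n_perm, 20)

  # oracle: max-t over all C(6,3) labelings, p = b / 20
  sets <- combn(6, 3)
  maxes <- apply(sets, 2, function(s) {
    gg <- integer(6); gg[s] <- 1
    max(oracle_two_sample_t(Y, gg))
  })
  tobs <- oracle_two_sample_t(Y, g)
  pwant <- vapply(tobs, function(v) mean(maxes >= v - 1e-12), 0)
  expect_equal(as.numeric(pr$fwe_p$data), pwant, tolerance = 1e-12)
  expect_true(all(pr$fwe_p$data >= 1 / 20))
})

test_that("exhaustive sign-flip matches brute force exactly", {
  set.seed(5)
  dm <- c(3, 3, 3)
  n <- 6
  Y <- matrix(rnorm(n * prod(dm), 0.4), n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  mask <- vol_of(array(1, dm))
  expect_message(
    pr <- permutation_fwe(mk_imgs(Y, dm), X, 1, mask, n_perm = 100,
                          enhance = "none", seed = 1, scheme = "signflip"),
    "64 sign-flips")
  expect_equal(pr$n_perm, 64)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  maxes <- apply(signs, 1, function(s) {
    Ys <- s * Y
    max(colMeans(Ys) / (apply(Ys, 2, sd) / sqrt(n)))
  })
  tobs <- colMeans(Y) / (apply(Y, 2, sd) / sqrt(n))
  pwant <- vapply(tobs, function(v) mean(maxes >= v - 1e-12), 0)
  expect_equal(as.numeric(pr$fwe_p$data), pwant, tolerance = 1e-12)
})

test_that("degenerate and sampled-permutation conventions", {
  dm <- c(3, 3, 3)
  const <- rep(list(vol_of(array(2, dm))), 6)
  dct <- make_design(data.frame(group = rep(c("patient", "control"),
                                            each = 3)))
  mask <- vol_of(array(1, dm))
  pr <- suppressMessages(permutation_fwe(const, dct,
                                         dct$contrasts$patient_gt_control,
                                         mask, n_perm = 50,
                                         enhance = "none"))
  expect_true(all(pr$fwe_p$data == 1))
  expect_equal(sum(pr$sig_mask$data), 0)

  # sampled path: p never 0 and bounded below by 1/(n_perm + 1)
  set.seed(6)
  Y <- matrix(rnorm(12 * prod(dm), 1), 12)
  pr2 <- permutation_fwe(mk_imgs(Y, dm), matrix(1, 12, 1,
                           dimnames = list(NULL, "intercept")),
                         1, mask, n_perm = 99, enhance = "tfce", seed = 2,
                         scheme = "signflip")
  expect_false(pr2$exhaustive)
  expect_gte(min(pr2$fwe_p$data), 1 / 100)
})

test_that("Freedman-Lane handles nuisance covariates sensibly", {
  set.seed(7)
  dm <- c(3, 3, 3)
  n <- 10
  age <- rnorm(n, 45, 8)
  g <- rep(c("patient", "control"), each = n / 2)
  Y <- matrix(rnorm(n * prod(dm)), n) + outer(0.05 * (age - 45),
                                              rep(1, prod(dm)))
  d <- make_design(data.frame(group = g, age = age), nuisance = "age")
  mask <- vol_of(array(1, dm))
  pr <- permutation_fwe(mk_imgs(Y, dm), d, d$contrasts$patient_gt_control,
                        mask, n_perm = 200, enhance = "none", seed = 3)
  expect_match(pr$scheme, "freedman-lane")
  # null data: nothing significant at alpha = 0.05 in this single draw with
  # a strong age confound handled by residualisation
  expect_gt(min(pr$fwe_p$data), 0.05)
})

test_that("paired baseline subtraction: zeros, exhaustiveness, exclusion", {
  dm <- c(4, 4, 4)
  mask <- vol_of(array(1, dm))
  mk_sub <- function(delta, times = c(0, 1, 5)) {
    base <- array(1, dm)
    list(times = times,
         maps = lapply(seq_along(times), function(i)
           vol_of(base - (times[i] == 5) * delta)))
  }
  subs <- lapply(1:6, function(i) mk_sub(array(0, dm)))
  names(subs) <- paste0("P", 1:6)
  pr <- suppressMessages(
    paired_baseline_subtraction_test(subs, 5, mask, n_perm = 100))
  expect_equal(sum(pr$sig_mask$data), 0)
  expect_true(pr$exhaustive)     # 2^6 = 64 <= 100
  expect_equal(pr$n_perm, 64)
  expect_equal(pr$enhance, "none")

  # subject without the target year is excluded with a log
  subs$P7 <- mk_sub(array(0, dm), times = c(0, 1, 3))
  expect_message(
    paired_baseline_subtraction_test(subs, 5, mask, n_perm = 50),
    "excluding P7")
})
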