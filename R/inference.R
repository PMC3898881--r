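## Second level: voxel-wise GLM t maps, threshold-free cluster enhancement,
## max-statistic permutation FWE (sign-flip / relabelling / Freedman-Lane),
## and the post-hoc baseline-subtraction analysis.

#' Second-level design matrix
#'
#' One row per subject: group indicator plus nuisance covariates (age, sex,
#' baseline total GM volume, scanner-upgrade proportion, ...). Nuisance
#' columns are mean-centred; the design must be full column rank.
#'
#' @param covariates data frame, one row per subject.
#' @param group_col name of the group factor column (NULL for one-sample
#'   designs).
#' @param nuisance character vector of nuisance column names (factors are
#'   expanded; all columns mean-centred).
#' @return List with `X` (matrix with intercept), `contrast` helpers
#'   `patient_gt_control` / `intercept`, and column names.
#' @export
make_design <- function(covariates, group_col = "group",
                        nuisance = character(0)) {
  n <- nrow(covariates)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(group_col)) {
    gr <- covariates[[group_col]]
    ind <- as.numeric(gr == "patient")
    X <- cbind(X, patient = ind - mean(ind))
  }
  for (nm in nuisance) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v))
      v <- as.numeric(factor(v)) - 1
    if (sd(v) == 0) {
      message("make_design: dropping constant nuisance covariate '", nm, "'")
      next
    }
    X <- cbind(X, scale(v, center = TRUE, scale = FALSE))
    colnames(X)[ncol(X)] <- nm
  }
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  contrasts <- list()
  if (!is.null(group_col))
    contrasts$patient_gt_control <-
      setNames(as.numeric(colnames(X) == "patient"), colnames(X))
  contrasts$intercept <-
    setNames(as.numeric(colnames(X) == "intercept"), colnames(X))
  list(X = X, contrasts = contrasts)
}

## Stack summary images / volumes into an n x V matrix over the mask.
stack_images <- function(images, mask) {
  vols <- lapply(images, function(im)
    if (inherits(im, "summary_image")) im$volume else im)
  sel <- which(mask$data > 0.5)
  t(vapply(vols, function(v) as.numeric(v$data)[sel],
           numeric(length(sel))))
}

## Vectorised OLS t statistics: Y (n x V), X (n x p), contrast length p.
glm_t_stats <- function(Y, X, contrast) {
  n <- nrow(X); p <- qr(X)$rank
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)           # p x V
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  se <- sqrt(as.numeric(t(contrast) %*% XtXi %*% contrast) * sigma2)
  tval <- as.numeric(crossprod(contrast, B)) / se
  tval[se == 0] <- 0
  tval
}

#' Voxel-wise GLM t-statistic map
#'
#' Fits the second-level OLS model at every masked voxel and returns the
#' t map for the requested contrast:
#' `t = c'b / sqrt(c'(X'X)^-1 c * sigma^2)` with `n - rank(X)` df.
#'
#' @param summary_images list of `summary_image`s or `vbm_volume`s (one per
#'   subject, rows of the design).
#' @param design output of [make_design()] or a plain design matrix.
#' @param contrast numeric contrast vector (length = columns of X).
#' @param mask binary `vbm_volume`.
#' @return t-statistic `vbm_volume` (0 outside the mask).
#' @export
glm_t_map <- function(summary_images, design, contrast, mask) {
  X <- if (is.list(design) && !is.null(design$X)) design$X else design
  stopifnot(length(summary_images) == nrow(X),
            length(contrast) == ncol(X))
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix")
  Y <- stack_images(summary_images, mask)
  tval <- glm_t_stats(Y, X, contrast)
  ref <- if (inherits(summary_images[[1]], "summary_image"))
    summary_images[[1]]$volume else summary_images[[1]]
  out <- array(0, dim(ref$data))
  out[mask$data > 0.5] <- tval
  like_volume(out, ref)
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_{h = dh, 2dh, ... <= stat(v)} e(h, v)^E * h^H * dh` where
#' `e(h, v)` is the voxel count of the connected suprathreshold component at
#' height `h` containing `v`. Positive tail only: test the negative tail by
#' negating the contrast. Defaults E = 0.5, H = 2, 26-connectivity,
#' `dh = max(stat)/100` are the conventional TFCE settings.
#'
#' @param stat statistic `vbm_volume` (or 3-D array).
#' @param E,H extent and height exponents.
#' @param dh threshold step (NULL = max/100).
#' @param connectivity 6, 18 or 26.
#' @return Enhanced `vbm_volume` (or array, matching the input).
#' @export
tfce <- function(stat, E = 0.5, H = 2, dh = NULL, connectivity = 26L) {
  arr <- if (is_volume(stat)) stat$data else stat
  if (is.null(dh)) {
    mx <- max(arr)
    if (mx <= 0) dh <- 1 else dh <- mx / 100
  }
  if (dh <= 0) stop("dh must be positive")
  out <- array(tfce_cpp(as.numeric(arr), dim(arr), E, H, dh,
                        as.integer(connectivity)), dim(arr))
  if (is_volume(stat)) like_volume(out, stat) else out
}

## Enumerate permutation schemes. Returns a list of either sign vectors
## (n of +-1) or row-permutation index vectors.
enumerate_signflips <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  # put the identity (all +1) first
  id <- which(rowSums(m == 1) == n)
  lapply(c(id, setdiff(seq_len(nrow(m)), id)), function(i) m[i, ])
}

enumerate_two_group <- function(group01) {
  n <- length(group01)
  n1 <- sum(group01 == 1)
  sets <- combn(n, n1)
  ones_obs <- which(group01 == 1)
  zeros_obs <- which(group01 == 0)
  obs_col <- which(colSums(sets == matrix(ones_obs, n1, ncol(sets))) == n1)
  perms <- lapply(seq_len(ncol(sets)), function(j) {
    g <- integer(n); g[sets[, j]] <- 1L
    # residual-row permutation whose effective labelling is g
    q <- integer(n)
    q[g == 1] <- ones_obs
    q[g == 0] <- zeros_obs
    order(q)
  })
  c(perms[obs_col], perms[-obs_col])
}

#' Max-statistic permutation FWE inference
#'
#' Second-level permutation test with family-wise-error correction by the
#' max-statistic method, optionally TFCE-enhanced. Nuisance covariates are
#' handled by Freedman-Lane residualisation: the reduced (nuisance-only)
#' model is fitted, its residuals are permuted (sign-flipped for one-sample
#' symmetric nulls, relabelled for group comparisons), the fitted nuisance
#' part is added back, and the full-model statistic is recomputed. When the
#' number of distinct permutations does not exceed `n_perm` the scheme is
#' enumerated exhaustively (logged) and p-values are exact (`b / N`);
#' otherwise `n_perm` random permutations are drawn and
#' `p = (1 + b) / (n_perm + 1)` so p is never 0.
#'
#' @param summary_images list of `summary_image`s / `vbm_volume`s.
#' @param design [make_design()] output or design matrix.
#' @param contrast numeric contrast vector.
#' @param mask binary `vbm_volume`.
#' @param n_perm requested number of permutations (study setting: 5000).
#' @param enhance `"tfce"` or `"none"` (raw voxel-wise max-t FWE).
#' @param alpha significance level for the reported mask.
#' @param seed RNG seed, recorded in the result.
#' @param scheme `"auto"`, `"signflip"` or `"relabel"`.
#' @param E,H,connectivity TFCE settings.
#' @return A `permutation_result`: observed stat/enhanced volumes, null max
#'   sample, FWE p `vbm_volume`, significance mask at `alpha`, scheme
#'   metadata.
#' @export
permutation_fwe <- function(summary_images, design, contrast, mask,
                            n_perm = 5000L, enhance = c("tfce", "none"),
                            alpha = 0.05, seed = 1L,
                            scheme = c("auto", "signflip", "relabel"),
                            E = 0.5, H = 2, connectivity = 26L) {
  enhance <- match.arg(enhance)
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1)
  X <- if (is.list(design) && !is.null(design$X)) design$X else design
  stopifnot(length(summary_images) == nrow(X))
  Y <- stack_images(summary_images, mask)
  n <- nrow(Y)
  cnz <- which(contrast != 0)
  if (scheme == "auto") {
    scheme <- if (length(cnz) == 1 && colnames(X)[cnz] == "intercept")
      "signflip" else "relabel"
  }
  # Freedman-Lane split: nuisance = columns not involved in the contrast
  Z <- X[, -cnz, drop = FALSE]
  if (ncol(Z) > 0) {
    Gz <- Z %*% solve(crossprod(Z), t(Z))
    Yfit <- Gz %*% Y
    E_res <- Y - Yfit
  } else {
    Yfit <- matrix(0, n, ncol(Y))
    E_res <- Y
  }

  exhaustive <- FALSE
  perms <- NULL
  if (scheme == "signflip") {
    if (n <= 30 && 2^n <= n_perm) {
      perms <- enumerate_signflips(n)
      exhaustive <- TRUE
      message("permutation_fwe: enumerating all ", 2^n,
              " sign-flips exhaustively")
    }
  } else {
    # a two-group contrast has C(n, n1) distinct labellings; with nuisance
    # covariates each labelling is realised by one representative
    # residual-row permutation (Freedman-Lane)
    is_two_group <- length(cnz) == 1 && length(unique(X[, cnz[1]])) == 2
    if (is_two_group) {
      grp01 <- as.numeric(X[, cnz[1]] > mean(X[, cnz[1]]))
      if (choose(n, sum(grp01 == 1)) <= n_perm) {
        perms <- enumerate_two_group(grp01)
        exhaustive <- TRUE
        message("permutation_fwe: enumerating all ", length(perms),
                " group relabellings exhaustively")
      }
    }
  }
  if (!exhaustive) {
    # identity first, then n_perm random draws: the observed labelling is
    # always part of the null sample and p >= 1/(n_perm + 1)
    set.seed(seed)
    perms <- vector("list", n_perm + 1L)
    perms[[1]] <- if (scheme == "signflip") rep(1, n) else seq_len(n)
    for (b in seq_len(n_perm) + 1L)
      perms[[b]] <- if (scheme == "signflip")
        sample(c(-1, 1), n, replace = TRUE) else sample(n)
  }

  dm <- dim(mask$data)
  sel <- mask$data > 0.5
  enhance_fun <- function(tvec) {
    if (enhance == "none") return(tvec)
    arr <- array(0, dm)
    arr[sel] <- tvec
    mx <- max(arr)
    dh <- if (mx > 0) mx / 100 else 1
    tfce_cpp(as.numeric(pmax(arr, 0)), dm, E, H, dh,
             as.integer(connectivity))[sel]
  }

  stat_for <- function(p) {
    Ystar <- if (scheme == "signflip") Yfit + p * E_res
             else Yfit + E_res[p, , drop = FALSE]
    glm_t_stats(Ystar, X, contrast)
  }
  obs_t <- glm_t_stats(Y, X, contrast)
  obs_enh <- enhance_fun(obs_t)
  # permutation 1 is the observed labelling in both schemes, so the null
  # max sample always contains the observed dataset:
  # exhaustive  -> p = b / N (exact);
  # sampled     -> p = (1 + b_rest) / (n_perm + 1)  (never 0)
  null_max <- vapply(perms, function(p) max(enhance_fun(stat_for(p))),
                     numeric(1))
  B <- length(perms)
  srt <- sort(null_max)
  counts <- B - findInterval(obs_enh - 1e-12, srt)
  pvals <- counts / B
  pvol <- array(1, dm); pvol[sel] <- pvals
  tvol <- array(0, dm); tvol[sel] <- obs_t
  evol <- array(0, dm); evol[sel] <- obs_enh
  structure(list(stat = like_volume(tvol, mask),
                 enhanced = like_volume(evol, mask),
                 null_max = null_max,
                 fwe_p = like_volume(pvol, mask),
                 sig_mask = like_volume(array(as.numeric(pvol <= alpha &
                                                           sel), dm), mask),
                 n_perm = B, alpha = alpha, seed = seed,
                 scheme = if (ncol(Z) > 0) paste0("freedman-lane/", scheme)
                          else scheme,
                 exhaustive = exhaustive, enhance = enhance),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> scheme=", x$scheme,
      if (x$exhaustive) " (exhaustive)", ", B=", x$n_perm,
      ", enhance=", x$enhance,
      ", significant voxels at alpha=", x$alpha, ": ",
      sum(x$sig_mask$data > 0), "\n", sep = "")
  invisible(x)
}

#' Post-hoc year-by-year baseline subtraction test
#'
#' For subjects with complete visit schedules, subtracts the baseline
#' pseudo-time-point from the target-year one and tests the differences
#' against zero with a sign-flip one-sample permutation test, voxel-wise
#' max-statistic FWE, and no TFCE (matching the post-hoc convention).
#' Subjects missing the target year are excluded with a log message.
#'
#' @param pseudo_by_subject named list; per subject a list with `times` and
#'   `maps` (group-space pseudo-time-point `vbm_volume`s).
#' @param target_year follow-up year to contrast against baseline.
#' @param mask binary `vbm_volume`.
#' @param n_perm,alpha,seed as in [permutation_fwe()].
#' @param direction `"decrease"` tests baseline > follow-up (GM loss).
#' @return A `permutation_result`.
#' @export
paired_baseline_subtraction_test <- function(pseudo_by_subject, target_year,
                                             mask, n_perm = 5000L,
                                             alpha = 0.05, seed = 1L,
                                             direction = c("decrease",
                                                           "increase")) {
  direction <- match.arg(direction)
  diffs <- list()
  for (id in names(pseudo_by_subject)) {
    s <- pseudo_by_subject[[id]]
    i0 <- which(s$times == 0)
    it <- which(s$times == target_year)
    if (length(i0) != 1 || length(it) != 1) {
      message("paired_baseline_subtraction_test: excluding ", id,
              " (missing baseline or year ", target_year, ")")
      next
    }
    d <- s$maps[[i0]]$data - s$maps[[it]]$data     # baseline - follow-up
    if (direction == "increase") d <- -d
    diffs[[id]] <- like_volume(d, mask)
  }
  if (length(diffs) < 2)
    stop("fewer than 2 complete-data subjects for year ", target_year)
  X <- matrix(1, length(diffs), 1, dimnames = list(NULL, "intercept"))
  permutation_fwe(diffs, X, contrast = 1, mask = mask, n_perm = n_perm,
                  enhance = "none", alpha = alpha, seed = seed,
                  scheme = "signflip")
}
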