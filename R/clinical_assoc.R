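## Associations between regional atrophy rates and clinical outcomes:
## ROI mean rates, Box-Cox normalisation, (partial) correlations, outlier
## flagging, one-sample progression tests.

#' Mean rate over an atlas label
#'
#' Mean of a slope image over `{atlas == label}` intersected with the
#' explicit analysis mask.
#'
#' @param slope_image `summary_image` or `vbm_volume` in group space.
#' @param atlas labelled `vbm_volume` in group space.
#' @param label integer label or region name (resolved via the atlas'
#'   `regions` attribute).
#' @param mask optional binary `vbm_volume` (default: whole grid).
#' @return Mean rate (scalar).
#' @export
roi_rate <- function(slope_image, atlas, label, mask = NULL) {
  vol <- if (inherits(slope_image, "summary_image")) slope_image$volume
         else slope_image
  if (is.character(label)) {
    reg <- attr(atlas, "regions")
    if (is.null(reg) || !(label %in% reg$name))
      stop("unknown region name: ", label)
    label <- reg$label[reg$name == label]
  }
  sel <- atlas$data == label
  if (!is.null(mask)) sel <- sel & mask$data > 0.5
  if (!any(sel)) stop("empty ROI: label ", label,
                      " does not intersect the mask")
  mean(vol$data[sel])
}

#' Shifted Box-Cox transform
#'
#' `y = ((x + shift)^lambda - 1) / lambda` (log for lambda = 0), with
#' `lambda = "mle"` maximising the profile log-likelihood. The default shift
#' of 10 is the convention used for MSFC scores (which are negative
#' z-composites).
#'
#' @param values numeric vector with `values + shift > 0`.
#' @param shift shift parameter.
#' @param lambda numeric exponent or `"mle"`.
#' @return Transformed vector with attribute `lambda`.
#' @export
boxcox_shift <- function(values, shift = 10, lambda = "mle") {
  x <- values + shift
  if (any(x <= 0)) stop("values + shift must be positive for Box-Cox")
  if (identical(lambda, "mle")) {
    n <- length(x)
    profll <- function(l) {
      y <- if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * sum(log(x))
    }
    lambda <- optimize(profll, c(-3, 3), maximum = TRUE)$maximum
  }
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  attr(y, "lambda") <- lambda
  y
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return List `r`, `p` (two-sided, n - 2 df), `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Partial correlation adjusting for one covariate
#'
#' Correlation of the residuals of `x` and `y` after regressing each on
#' `[1, z]`; p-value with n - 3 df.
#'
#' @param x,y,z numeric vectors, length >= 4.
#' @return List `r`, `p`, `n`.
#' @export
partial_corr <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(x) == length(z), length(x) >= 4)
  if (sd(z) == 0) stop("covariate collinear with intercept")
  n <- length(x)
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
    stop("zero residual variance: partial correlation undefined")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  tstat <- r * sqrt((n - 3) / max(1e-300, 1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 3), n = n)
}

#' Flag bivariate outliers by studentized residuals
#'
#' Externally studentized residuals from the `y ~ x` fit; indices with
#' `|r_i| > cutoff` (default 3) are flagged. Association analyses report
#' results both with and without flagged points.
#'
#' @param x,y numeric vectors, length >= 5.
#' @param cutoff studentized-residual threshold.
#' @return Integer index vector (possibly empty).
#' @export
flag_outliers <- function(x, y, cutoff = 3) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  fit <- lm(y ~ x)
  rs <- rstudent(fit)
  unname(which(abs(rs) > cutoff))
}

#' Correlation report with and without flagged outliers
#'
#' @param x,y numeric vectors.
#' @param cutoff outlier threshold passed to [flag_outliers()].
#' @return List `all` (r, p, n), `without_outliers`, `outliers` (indices).
#' @export
correlation_with_outlier_report <- function(x, y, cutoff = 3) {
  out <- if (length(x) >= 5) flag_outliers(x, y, cutoff) else integer(0)
  full <- pearson_corr(x, y)
  trimmed <- if (length(out) > 0 && length(x) - length(out) >= 3)
    pearson_corr(x[-out], y[-out]) else full
  list(all = full, without_outliers = trimmed, outliers = out)
}

#' One-sample progression test
#'
#' Standard one-sample t-test of per-subject clinical slopes against the
#' null hypothesis of no progression (mean 0), two-sided.
#'
#' @param slopes numeric vector, length >= 2, non-constant.
#' @return List `t`, `p`, `df`, `mean`, `sd`.
#' @export
one_sample_progression_test <- function(slopes) {
  n <- length(slopes)
  stopifnot(n >= 2)
  s <- sd(slopes)
  if (s == 0) {
    if (mean(slopes) == 0) return(list(t = 0, p = 1, df = n - 1,
                                       mean = 0, sd = 0))
    stop("zero variance with nonzero mean: t undefined")
  }
  tstat <- mean(slopes) / (s / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), n - 1), df = n - 1,
       mean = mean(slopes), sd = s)
}
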