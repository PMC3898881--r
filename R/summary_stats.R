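## First level of the two-level summary-statistic approach: per-subject
## voxel-wise slope and quadratic-term images, clinical slopes, EDSS steps.

new_summary_image <- function(vol, subject = NA_character_, n_visits = NA,
                              kind = c("slope", "quadratic"),
                              covariates = NULL) {
  structure(list(volume = vol, subject = subject, n_visits = n_visits,
                 kind = match.arg(kind), covariates = covariates),
            class = "summary_image")
}

#' @export
print.summary_image <- function(x, ...) {
  cat("<summary_image> ", x$kind, " map, subject ", x$subject, ", ",
      x$n_visits, " visits\n", sep = "")
  invisible(x)
}

#' Voxel-wise linear rate-of-change image
#'
#' Ordinary least-squares slope against acquisition time at each voxel, using
#' whatever visits the subject has (minimum 2 distinct times). This is the
#' per-subject summary statistic carried to the second level.
#'
#' @param pseudo_timepoints list of group-space `vbm_volume`s, one per visit.
#' @param times acquisition times in years, aligned with the list.
#' @param subject optional subject id recorded in the result.
#' @param covariates optional named list recorded in the result.
#' @return A `summary_image` (kind `"slope"`, units per year).
#' @export
fit_voxelwise_slope <- function(pseudo_timepoints, times,
                                subject = NA_character_, covariates = NULL) {
  stopifnot(length(pseudo_timepoints) == length(times),
            length(times) >= 2)
  if (length(unique(times)) < 2)
    stop("all acquisition times equal: slope undefined")
  ref <- pseudo_timepoints[[1]]
  Y <- vapply(pseudo_timepoints, function(v) as.numeric(v$data),
              numeric(length(ref$data)))
  tc <- times - mean(times)
  slope <- as.numeric(Y %*% tc) / sum(tc^2)
  new_summary_image(like_volume(array(slope, dim(ref$data)), ref),
                    subject, length(times), "slope", covariates)
}

#' Voxel-wise quadratic-term image
#'
#' Coefficient of t^2 from a degree-2 polynomial least-squares fit at each
#' voxel; requires at least 3 distinct times (subjects below that are
#' excluded from the quadratic analysis upstream).
#'
#' @inheritParams fit_voxelwise_slope
#' @return A `summary_image` (kind `"quadratic"`, units per year^2).
#' @export
fit_voxelwise_quadratic <- function(pseudo_timepoints, times,
                                    subject = NA_character_,
                                    covariates = NULL) {
  stopifnot(length(pseudo_timepoints) == length(times))
  if (length(unique(times)) < 3)
    stop("fewer than 3 distinct times: quadratic term not estimable")
  ref <- pseudo_timepoints[[1]]
  Y <- vapply(pseudo_timepoints, function(v) as.numeric(v$data),
              numeric(length(ref$data)))
  X <- cbind(1, times, times^2)
  co <- t(solve(crossprod(X), t(Y %*% X)))   # V x 3
  new_summary_image(like_volume(array(co[, 3], dim(ref$data)), ref),
                    subject, length(times), "quadratic", covariates)
}

#' Convert EDSS scores to ordinal EDSS steps
#'
#' The legal EDSS grid {0, 1, 1.5, 2, ..., 10} is mapped to its ordinal rank
#' (0 -> 0, 1 -> 1, 1.5 -> 2, ..., 10 -> 19); differences of ranks are
#' "steps". Off-grid values are rejected.
#'
#' @param edss_values numeric vector on the legal grid.
#' @return Integer ranks, same length.
#' @export
edss_to_steps <- function(edss_values) {
  g <- edss_grid()
  idx <- match(edss_values, g)
  if (anyNA(idx))
    stop("off-grid EDSS value(s): ",
         paste(edss_values[is.na(idx)], collapse = ", "))
  idx - 1L
}

#' Annual rate of change of a clinical score
#'
#' OLS slope of score against time (years); used for EDSS steps, MSFC and T2
#' lesion load alike.
#'
#' @param scores numeric scores per visit.
#' @param times visit times in years (at least 2 distinct).
#' @return Slope (score units per year).
#' @export
clinical_slope <- function(scores, times) {
  stopifnot(length(scores) == length(times), length(times) >= 2)
  if (length(unique(times)) < 2)
    stop("all visit times equal: slope undefined")
  tc <- times - mean(times)
  sum(tc * (scores - mean(scores))) / sum(tc^2)
}

#' Per-subject clinical slopes table
#'
#' EDSS-step, MSFC and T2 lesion-load slopes per subject from a long-format
#' clinical table (columns `subject`, `time_years`, `edss`, `msfc`,
#' `t2_lesion_load_ml`).
#'
#' @param clinical long-format data frame.
#' @return Data frame keyed by subject: `edss_step_slope`, `msfc_slope`,
#'   `t2ll_slope`.
#' @export
clinical_slopes_table <- function(clinical) {
  out <- lapply(split(clinical, clinical$subject), function(d) {
    data.frame(subject = d$subject[1],
               edss_step_slope = clinical_slope(edss_to_steps(d$edss),
                                                d$time_years),
               msfc_slope = clinical_slope(d$msfc, d$time_years),
               t2ll_slope = clinical_slope(d$t2_lesion_load_ml,
                                           d$time_years),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
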