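## Calibration utilities: fast null datasets for validating the permutation
## machinery's error control at simulation scale.

#' Null first-level datasets without the registration cost
#'
#' Builds a zero-atrophy cohort's slope images directly: the phantom's GM
#' probability map is multiplied by per-visit "Jacobian" maps equal to 1 plus
#' smooth zero-mean noise (emulating the only component registration
#' contributes under the null), smoothed, and reduced to per-subject OLS
#' slope images. Group labels carry no signal, so the result is exchangeable
#' by construction — the input the family-wise error rate of
#' [permutation_fwe()] is validated against. The registration path itself is
#' validated separately on phantoms with known atrophy.
#'
#' @param n_per_group subjects per group.
#' @param spec a [phantom_spec()] (geometry source; noise fields are drawn
#'   here, not taken from the phantom intensities).
#' @param visit_times acquisition schedule in years.
#' @param jac_noise_sd SD of the smooth multiplicative volume noise
#'   (default 0.02, the scale of demons registration noise on these
#'   phantoms).
#' @param fwhm_mm smoothing applied to the pseudo-time-points.
#' @param seed integer seed.
#' @return List: `slope_images`, `mask` (explicit GM mask), `covariates`
#'   (subject, group), `design` ready for [permutation_fwe()].
#' @export
simulate_null_summary_cohort <- function(n_per_group = 4,
                                         spec = phantom_spec(c(24, 24, 24)),
                                         visit_times = c(0, 1, 2, 3, 5),
                                         jac_noise_sd = 0.02,
                                         fwhm_mm = 8, seed = 1L) {
  set.seed(seed)
  atlas <- spec$region_atlas
  dm <- dim(atlas$data)
  vox <- spec$voxel_size_mm
  gm <- gauss_blur_arr((atlas$data >= 3) * 1, 0.8)
  gm_vol <- as_volume(gm, voxel_mm = vox)
  sm_gm <- gaussian_smooth(gm_vol, fwhm_mm)
  mask <- make_explicit_mask(list(sm_gm))
  n <- 2L * n_per_group
  groups <- rep(c("patient", "control"), each = n_per_group)
  slope_images <- vector("list", n)
  for (s in seq_len(n)) {
    maps <- lapply(visit_times, function(t) {
      noise <- gauss_blur_arr(array(rnorm(prod(dm)), dm), 1.5)
      jac <- 1 + noise * (jac_noise_sd / sd(noise))
      gaussian_smooth(as_volume(gm * jac, voxel_mm = vox), fwhm_mm)
    })
    slope_images[[s]] <- fit_voxelwise_slope(maps, visit_times,
                                             subject = paste0("S", s))
  }
  names(slope_images) <- paste0("S", seq_len(n))
  cov <- data.frame(subject = names(slope_images), group = groups,
                    stringsAsFactors = FALSE)
  list(slope_images = slope_images, mask = mask, covariates = cov,
       design = make_design(cov))
}
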