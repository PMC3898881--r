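## Step 7: balanced group-average template, normalisation of pseudo-time-
## points WITHOUT modulation, Gaussian smoothing, explicit GM mask.

## 7-parameter affine (rigid + isotropic log-scale) about a centre.
affine7_matrix <- function(params, centre_mm) {
  M <- rigid_transform(params[1:6], centre_mm)$matrix
  s <- exp(params[7])
  S <- diag(4)
  S[1:3, 1:3] <- diag(rep(s, 3))
  S[1:3, 4] <- centre_mm - s * centre_mm
  M %*% S
}

affine_coregister <- function(moving, fixed, init = rep(0, 7), maxit = 300) {
  fx <- gauss_blur_arr(fixed$data, 1)
  mv <- gauss_blur_arr(moving$data, 1)
  ctr <- volume_centre_mm(fixed)
  m_w2v <- world_to_vox(moving)
  f_v2w <- vox_to_world(fixed)
  fdim <- dim(fixed$data); mdim <- dim(moving$data)
  fvec <- as.numeric(fx); mvec <- as.numeric(mv)
  obj <- function(p) {
    A <- affine7_matrix(p, ctr)
    M <- (m_w2v %*% solve(A) %*% f_v2w)[1:3, , drop = FALSE]
    ssd_affine_cpp(fvec, fdim, mvec, mdim, M, integer(0))
  }
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(parscale = c(rep(0.02, 3), rep(1, 3), 0.02),
                              maxit = maxit, reltol = 1e-10))
  list(params = fit$par, matrix = affine7_matrix(fit$par, ctr),
       value = fit$value)
}

#' Subject-to-group warp
#'
#' Maps a group-grid point `x` (world mm) to the subject point
#' `A %*% (x + u(x))`: non-rigid displacement `u` on the group grid followed
#' by the affine `A` (group-world to subject-world).
#'
#' @param affine 4x4 matrix (group-world to subject-world).
#' @param field optional `deformation_field` on the group grid (NULL =
#'   affine only).
#' @param ref group-space reference `vbm_volume`.
#' @return A `group_warp` object.
#' @export
group_warp <- function(affine = diag(4), field = NULL, ref) {
  structure(list(affine = affine, field = field, ref_affine = ref$affine,
                 ref_dim = dim(ref$data)),
            class = "group_warp")
}

warp_source_world <- function(warp) {
  dm <- warp$ref_dim
  g <- index_grid(dm)
  world <- t(warp$ref_affine %*% t(cbind(g, 1)))[, 1:3, drop = FALSE]
  if (!is.null(warp$field)) {
    world <- world + cbind(as.numeric(warp$field$disp[, , , 1]),
                           as.numeric(warp$field$disp[, , , 2]),
                           as.numeric(warp$field$disp[, , , 3]))
  }
  t(warp$affine %*% t(cbind(world, 1)))[, 1:3, drop = FALSE]
}

#' Build the study-specific group template
#'
#' The construction set is balanced: all control maps plus an equal-sized
#' random patient subset (seeded); when the patient group is the smaller one
#' all patients are used and the imbalance is logged. The template is an
#' iterative register-and-average (affine, then a mild non-rigid refinement);
#' warps to the final template are then estimated for every subject,
#' including those outside the construction set.
#'
#' @param subject_gm_maps named list of GM probability `vbm_volume`s, one per
#'   subject, on a common grid.
#' @param groups character vector (`"patient"`/`"control"`) aligned with the
#'   maps.
#' @param seed integer seed for the balanced patient selection.
#' @param n_average_iter register-and-average iterations.
#' @param nonrigid also estimate a demons refinement per subject.
#' @param reg_param,n_iter non-rigid settings (see [hdw_register()]).
#' @return A `group_template`: `template`, named `warps`, `balanced_subjects`,
#'   `seed`.
#' @export
build_group_template <- function(subject_gm_maps, groups, seed = 1L,
                                 n_average_iter = 2L, nonrigid = TRUE,
                                 reg_param = 8, n_iter = 4L) {
  stopifnot(length(subject_gm_maps) == length(groups))
  ids <- names(subject_gm_maps)
  if (is.null(ids)) ids <- as.character(seq_along(subject_gm_maps))
  pat <- ids[groups == "patient"]; ctl <- ids[groups == "control"]
  stopifnot(length(pat) >= 2, length(ctl) >= 2)
  set.seed(seed)
  if (length(pat) < length(ctl)) {
    message("build_group_template: patient group smaller than control ",
            "group; using all ", length(pat), " patients")
    bal <- c(ctl, pat)
  } else {
    bal <- c(ctl, sort(sample(pat, length(ctl))))
  }
  ref <- subject_gm_maps[[1]]
  tmpl <- voxelwise_mean(subject_gm_maps[bal])
  aff_params <- setNames(rep(list(rep(0, 7)), length(bal)), bal)
  for (it in seq_len(n_average_iter)) {
    resampled <- list()
    for (id in bal) {
      fit <- affine_coregister(subject_gm_maps[[id]], tmpl,
                               init = aff_params[[id]])
      aff_params[[id]] <- fit$params
      resampled[[id]] <- resample_world_affine(subject_gm_maps[[id]], tmpl,
                                               solve(fit$matrix))
    }
    tmpl <- voxelwise_mean(resampled)
  }
  ctr <- volume_centre_mm(tmpl)
  warps <- list()
  for (id in ids) {
    init <- if (id %in% bal) aff_params[[id]] else rep(0, 7)
    fit <- affine_coregister(subject_gm_maps[[id]], tmpl, init = init)
    A <- solve(fit$matrix)   # group-world -> subject-world
    field <- NULL
    if (nonrigid) {
      aligned <- resample_world_affine(subject_gm_maps[[id]], tmpl, A)
      field <- hdw_register(aligned, tmpl, reg_param = reg_param,
                            n_iter = n_iter, inner = 3L)
    }
    warps[[id]] <- group_warp(A, field, tmpl)
  }
  structure(list(template = tmpl, warps = warps, balanced_subjects = bal,
                 seed = seed),
            class = "group_template")
}

#' Normalise an image to group space (no modulation)
#'
#' Resamples through the subject's warp with trilinear interpolation and
#' deliberately applies NO Jacobian modulation, so within-subject ratios of
#' pseudo-time-point values are preserved at corresponding points.
#'
#' @param image subject-space `vbm_volume`.
#' @param warp the subject's `group_warp`.
#' @return `vbm_volume` on the group grid.
#' @export
normalize_to_group <- function(image, warp) {
  stopifnot(inherits(warp, "group_warp"), is_volume(image))
  src_world <- warp_source_world(warp)
  src_vox <- t(world_to_vox(image) %*% t(cbind(src_world, 1)))[, 1:3,
                                                               drop = FALSE]
  out <- array(resample_at_vox(image, src_vox), warp$ref_dim)
  as_volume(out, affine = warp$ref_affine)
}

#' Gaussian smoothing
#'
#' Separable Gaussian with sigma = FWHM / (2 sqrt(2 ln 2)) per axis in mm,
#' converted to voxels; half-sample reflecting boundaries (mass-conserving).
#' The default 8 mm FWHM is the pipeline's stated smoothing.
#'
#' @param image `vbm_volume`.
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @return Smoothed `vbm_volume`.
#' @export
gaussian_smooth <- function(image, fwhm_mm = 8) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(image)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / image$voxel_mm
  like_volume(gauss_blur_arr(image$data, sigma_vox), image)
}

#' Explicit GM analysis mask
#'
#' Averages the (smoothed, group-space) GM probability maps, thresholds at
#' the Otsu bimodal-gap value, and keeps the largest connected component.
#'
#' @param smoothed_gm_templates list of `vbm_volume`s.
#' @return Binary `vbm_volume` mask.
#' @export
make_explicit_mask <- function(smoothed_gm_templates) {
  stopifnot(length(smoothed_gm_templates) >= 1)
  avg <- voxelwise_mean(smoothed_gm_templates)
  if (max(avg$data) <= 0) stop("all GM maps are zero: empty explicit mask")
  thr <- otsu_threshold(avg$data)
  m <- avg$data > thr
  if (!any(m)) stop("empty explicit mask after thresholding")
  like_volume(as.numeric(largest_component(m)), avg)
}
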