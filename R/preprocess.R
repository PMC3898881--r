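## Step 1-2 preprocessing: rigid coregistration, lesion filling,
## non-uniformity correction, brain extraction.

#' Rigid (6-parameter) world-coordinate transform
#'
#' Rotations (radians, applied as Rz Ry Rx about `centre_mm`) followed by a
#' translation (mm). Acts on world coordinates, mapping moving-space points to
#' fixed-space points.
#'
#' @param params numeric length 6: `rx, ry, rz, tx, ty, tz`.
#' @param centre_mm rotation centre in world mm.
#' @return A `rigid_transform` (carries the 4x4 homogeneous matrix).
#' @export
rigid_transform <- function(params = rep(0, 6), centre_mm = c(0, 0, 0)) {
  stopifnot(length(params) == 6)
  r <- params[1:3]
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- params[4:6] + centre_mm - R %*% centre_mm
  structure(list(params = params, centre_mm = centre_mm, matrix = M),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rot(deg):",
      paste(signif(x$params[1:3] * 180 / pi, 3), collapse = ", "),
      " trans(mm):", paste(signif(x$params[4:6], 3), collapse = ", "), "\n")
  invisible(x)
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform` holding the composed matrix.
#' @export
compose_rigid <- function(a, b) {
  M <- a$matrix %*% b$matrix
  structure(list(params = NULL, centre_mm = NULL, matrix = M),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param x a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(x) {
  structure(list(params = NULL, centre_mm = NULL, matrix = solve(x$matrix)),
            class = "rigid_transform")
}

volume_centre_mm <- function(vol) {
  as.numeric(vol$affine %*% c((dim(vol$data) - 1) / 2, 1))[1:3]
}

#' Resample a moving volume into a fixed grid through a rigid transform
#'
#' `transform` maps moving-world to fixed-world; sampling pulls back through
#' its inverse with trilinear interpolation (zero outside the field of view).
#'
#' @param moving,fixed `vbm_volume`s.
#' @param transform a `rigid_transform` (default identity).
#' @return Resampled `vbm_volume` on the fixed grid.
#' @export
resample_rigid <- function(moving, fixed, transform = rigid_transform()) {
  resample_world_affine(moving, fixed, solve(transform$matrix))
}

#' Rigid coregistration
#'
#' Estimates the 6-parameter rigid transform aligning `moving` to `fixed` by
#' derivative-free optimisation (Nelder-Mead with parameter scaling) of
#' either the sum-of-squared-differences or the mutual information of the
#' 32-bin joint intensity histogram. Images are pre-smoothed (1 voxel sigma)
#' for basin widening; the returned transform maps moving-world to
#' fixed-world.
#'
#' @param moving,fixed `vbm_volume`s with overlapping fields of view.
#' @param metric `"ssd"` or `"mutual_information"`.
#' @param init optional initial parameter vector (length 6).
#' @param maxit optimiser iteration cap.
#' @return A `rigid_transform` with attributes `metric_value` (at optimum)
#'   and `metric_identity`.
#' @export
rigid_coregister <- function(moving, fixed,
                             metric = c("ssd", "mutual_information"),
                             init = rep(0, 6), maxit = 400) {
  metric <- match.arg(metric)
  if (sd(fixed$data) == 0 || sd(moving$data) == 0)
    stop("flat-intensity image: registration metric undefined")
  fx <- gauss_blur_arr(fixed$data, 1)
  mv <- gauss_blur_arr(moving$data, 1)
  fvol <- like_volume(fx, fixed)
  ctr <- volume_centre_mm(fixed)
  m_w2v <- world_to_vox(moving)
  f_v2w <- vox_to_world(fixed)
  mask <- integer(0)
  fdim <- dim(fixed$data); mdim <- dim(moving$data)
  fvec <- as.numeric(fx); mvec <- as.numeric(mv)
  obj <- function(p, stride = 1L) {
    Tm <- rigid_transform(p, ctr)$matrix
    M <- (m_w2v %*% solve(Tm) %*% f_v2w)[1:3, , drop = FALSE]
    if (metric == "ssd")
      ssd_affine_cpp(fvec, fdim, mvec, mdim, M, mask, stride)
    else
      neg_mi_affine_cpp(fvec, fdim, mvec, mdim, M, mask, 32L)
  }
  v_id <- obj(rep(0, 6))
  # coarse stage on a stride-2 voxel lattice, fine polish at full resolution
  fit <- optim(init, obj, stride = 2L, method = "Nelder-Mead",
               control = list(parscale = c(rep(0.02, 3), rep(1, 3)),
                              maxit = maxit, reltol = 1e-9))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(parscale = c(rep(0.005, 3), rep(0.25, 3)),
                              maxit = maxit, reltol = 1e-12))
  out <- rigid_transform(fit$par, ctr)
  attr(out, "metric_value") <- fit$value
  attr(out, "metric_identity") <- v_id
  attr(out, "metric") <- metric
  out
}

#' Fill WM lesions with normal-appearing white matter intensities
#'
#' Lesion voxels are replaced by draws from the normal-WM intensity model
#' (mean and SD of non-lesion WM voxels) and the fill is smoothed with a
#' 1-voxel Gaussian so it blends at the boundary. No voxel outside the lesion
#' mask is changed.
#'
#' @param t1 intensity `vbm_volume`.
#' @param lesion_mask,wm_mask binary `vbm_volume`s on the same grid; the WM
#'   mask should exclude lesion voxels.
#' @param seed RNG seed for the fill draws.
#' @return Filled `vbm_volume`.
#' @export
fill_lesions <- function(t1, lesion_mask, wm_mask, seed = 1L) {
  stopifnot(same_grid(t1, lesion_mask), same_grid(t1, wm_mask))
  les <- lesion_mask$data > 0.5
  wm <- wm_mask$data > 0.5 & !les
  if (!any(wm)) stop("empty WM mask: no normal WM to sample fill from")
  if (!any(les)) return(t1)
  if (sum(les) > 0.5 * max(1, sum(wm_mask$data > 0.5) + sum(les)))
    warning("lesion mask covers > 50% of WM; fill statistics unreliable")
  set.seed(seed)
  mu <- mean(t1$data[wm]); s <- sd(t1$data[wm])
  filled <- t1$data
  filled[les] <- rnorm(sum(les), mu, s)
  sm <- gauss_blur_arr(filled, 1)
  out <- t1$data
  out[les] <- sm[les]
  like_volume(out, t1)
}

## Ridge-regularised log-domain polynomial field fit over one or more
## reference-voxel classes (shared field, per-class intercepts). Returns the
## log field evaluated on the whole grid.
ridge_field <- function(basis, img, class_sels) {
  sel <- unlist(class_sels)
  cls <- rep(seq_along(class_sels), lengths(class_sels))
  B <- basis[sel, -1, drop = FALSE]
  y <- log(pmax(img[sel], 1e-6))
  mu_b <- colMeans(B)
  sd_b <- pmax(apply(B, 2, sd), 1e-9)
  Bs <- sweep(sweep(B, 2, mu_b), 2, sd_b, `/`)
  D <- outer(cls, seq_along(class_sels), `==`) * 1
  X <- cbind(D, Bs)
  lambda <- c(rep(0, ncol(D)), rep(0.01 * length(sel), ncol(Bs)))
  co_all <- solve(crossprod(X) + diag(lambda), crossprod(X, y))
  co <- as.numeric(co_all[-seq_len(ncol(D))] / sd_b)
  as.numeric(basis[, -1, drop = FALSE] %*% co)
}

#' Polynomial non-uniformity correction
#'
#' Estimates a low-order multiplicative bias field in two ridge-regularised
#' log-domain passes: first on the brightest tissue class alone (robust to
#' the uncorrected field), then, after dividing that estimate out, jointly
#' on the two brightest classes with per-class intercepts (their wide
#' spatial support stabilises the polynomial at the brain periphery). The
#' total field is divided out inside the brain and the mean brain intensity
#' is preserved.
#'
#' @param image intensity `vbm_volume`.
#' @param order total polynomial degree, 1..4.
#' @param brain_mask optional binary `vbm_volume` (default: nonzero voxels).
#' @return Corrected `vbm_volume` with attribute `bias_field`.
#' @export
correct_nonuniformity <- function(image, order = 2L, brain_mask = NULL) {
  stopifnot(order >= 1, order <= 4)
  brain <- if (is.null(brain_mask)) image$data > 0.1 * max(image$data)
           else brain_mask$data > 0.5
  dm <- dim(image$data)
  vals <- image$data[brain]
  shift <- 0
  if (any(vals <= 0)) {
    shift <- abs(min(vals)) + 1e-3 * diff(range(vals))
    message("correct_nonuniformity: nonpositive intensities; ",
            "using shifted-log fallback")
  }
  g <- index_grid(dm)
  xn <- sweep(sweep(g, 2, (dm - 1) / 2, `-`), 2, pmax(1, (dm - 1) / 2), `/`)
  basis <- matrix(1, nrow(xn), 1)
  for (d in seq_len(order)) {
    pows <- expand.grid(i = 0:d, j = 0:d, k = 0:d)
    pows <- pows[rowSums(pows) == d, , drop = FALSE]
    for (p in seq_len(nrow(pows)))
      basis <- cbind(basis, xn[, 1]^pows$i[p] * xn[, 2]^pows$j[p] *
                            xn[, 3]^pows$k[p])
  }
  fit_field <- function(work) {
    # pass 1: bright class only (classification is bias-robust enough to
    # find it), ridge-regularised; removes the bulk of the field
    wvals <- work[brain]
    thr <- otsu_threshold(wvals)
    f1 <- ridge_field(basis, work, list(which(brain & work >= thr)))
    corrected <- work / array(exp(f1 - mean(f1[brain])), dm)
    # pass 2: with the bulk gone, split the two brightest classes cleanly
    # (WM and GM in T1-like contrast) and refit with per-class intercepts;
    # the wider spatial support pins the polynomial at the periphery
    cvals <- corrected[brain]
    thr <- otsu_threshold(cvals)
    lowvals <- cvals[cvals < thr]
    thr2 <- if (length(unique(lowvals)) > 1) otsu_threshold(lowvals)
            else -Inf
    sel_hi <- which(brain & corrected >= thr)
    sel_mid <- which(brain & corrected >= thr2 & corrected < thr)
    f2 <- ridge_field(basis, corrected, list(sel_hi, sel_mid))
    f1 + f2
  }
  logfield <- fit_field(image$data + shift)
  field <- array(exp(logfield - mean(logfield[as.logical(brain)])), dm)
  out <- image$data
  out[brain] <- (image$data[brain] + shift) / field[brain] - shift
  sc <- mean(image$data[brain]) / mean(out[brain])
  out[brain] <- out[brain] * sc
  res <- like_volume(out, image)
  attr(res, "bias_field") <- field
  res
}

#' Brain extraction
#'
#' Otsu foreground threshold, largest 26-connected component, morphological
#' closing (1-voxel dilation + erosion), and interior hole filling.
#'
#' @param image intensity `vbm_volume`.
#' @return Binary `vbm_volume` mask.
#' @export
extract_brain <- function(image) {
  if (sd(image$data) == 0) stop("constant image: brain extraction undefined")
  thr <- otsu_threshold(image$data)
  fg <- image$data > thr
  if (!any(fg)) stop("empty brain mask after thresholding")
  fg <- largest_component(fg)
  # cross-element closing: smooths ragged edges without inflating a convex
  # digital surface (the box element adds corner voxels on spheres)
  fg <- erode_arr(dilate_arr(fg, 1, 6L), 1, 6L)
  # fill interior holes (e.g. dark CSF): background is the border-connected
  # complement component
  bg <- !fg
  lab <- array(label_components_cpp(as.integer(bg), dim(bg), 6L), dim(bg))
  border_labs <- setdiff(unique(c(lab[1, , ], lab[dim(bg)[1], , ],
                                  lab[, 1, ], lab[, dim(bg)[2], ],
                                  lab[, , 1], lab[, , dim(bg)[3]])), 0L)
  hole <- bg & !array(lab %in% border_labs, dim(bg))
  fg[hole] <- TRUE
  like_volume(as.numeric(fg), image)
}
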