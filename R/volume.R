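#' @useDynLib longvbm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif median sd var lm rstudent coef
#'   pt qt optimize quantile complete.cases setNames
#' @importFrom utils combn read.csv write.csv head
NULL

#' 3-D scalar volume with world geometry
#'
#' The basic container carried through the whole pipeline: a 3-D numeric array
#' plus a 4x4 grid-to-world affine (homogeneous, mm). Voxel indices are 0-based
#' in world mapping: `world = affine %*% c(i, j, k, 1)`.
#'
#' @param data 3-D numeric array.
#' @param voxel_mm positive length-3 voxel size in mm (used when `affine` is
#'   NULL to build an axis-aligned affine centred on the origin given).
#' @param affine optional 4x4 grid-to-world matrix; overrides `voxel_mm`
#'   placement (its voxel size is then derived from column norms).
#' @param origin_mm world coordinate of voxel (0,0,0) (default 0,0,0).
#' @return A `vbm_volume` object.
#' @export
as_volume <- function(data, voxel_mm = c(1, 1, 1), affine = NULL,
                      origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(voxel_mm)
    affine[1:3, 4] <- origin_mm
  } else {
    stopifnot(all(dim(affine) == c(4, 4)))
    voxel_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm),
                 affine = affine),
            class = "vbm_volume")
}

#' @export
print.vbm_volume <- function(x, ...) {
  cat("<vbm_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, ", paste(signif(x$voxel_mm, 4), collapse = "x"),
      " mm; range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.vbm_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "vbm_volume")

## Build a volume on the same grid/affine as `ref` with new data.
like_volume <- function(data, ref) {
  as_volume(array(data, dim(ref$data)), affine = ref$affine)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) < 1e-6
}

## Voxel (0-based) -> world, and inverse, as 4x4 matrices.
vox_to_world <- function(vol) vol$affine
world_to_vox <- function(vol) solve(vol$affine)

## 0-based voxel index grid as an N x 3 matrix (x fastest), cached per call
## site by the small dims used here.
index_grid <- function(dm) {
  cbind(
    rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3]),
    rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
    rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2])
  )
}

## Resample `src` (vbm_volume) onto the grid of `ref` through a 4x4 world
## map W taking ref-world points to src-world points. Trilinear, zero padded.
resample_world_affine <- function(src, ref, W = diag(4)) {
  M <- (world_to_vox(src) %*% W %*% vox_to_world(ref))[1:3, , drop = FALSE]
  out <- resample_affine_cpp(as.numeric(src$data), dim(src$data),
                             dim(ref$data), M)
  like_volume(out, ref)
}

## Resample src at continuous 0-based voxel coordinates of src itself.
resample_at_vox <- function(src, coords) {
  resample_coords_cpp(as.numeric(src$data), dim(src$data), coords)
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 I/O. No NIfTI reader exists in the offline R library set,
# so the format is implemented here directly (348-byte header, sform affine,
# float32 output; common integer/float datatypes on input; .gz transparent).
# ---------------------------------------------------------------------------

#' Write a volume as NIfTI-1
#'
#' Single-file `.nii` (or `.nii.gz`), float32, little-endian, sform affine.
#'
#' @param vol a `vbm_volume`.
#' @param path output file path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(is_volume(vol))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  dm <- dim(vol$data)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # unused
  wi(c(3, dm, 1, 1, 1, 1), 2)                  # dim[8]
  writeBin(raw(14), con)                       # intent_p*, intent_code
  wi(16, 2)                                    # datatype = float32
  wi(32, 2)                                    # bitpix
  wi(0, 2)                                     # slice_start
  wf(c(1, vol$voxel_mm, 1, 1, 1, 1))           # pixdim[8]
  wf(352)                                      # vox_offset
  wf(1); wf(0)                                 # scl_slope, scl_inter
  wi(0, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt
  wf(c(0, 0))                                  # cal_max, cal_min
  wf(c(0, 0)); wi(c(0, 0), 4)                  # slice_duration, toffset, glmax/min
  writeBin(raw(104), con)                      # descrip + aux_file
  wi(0, 2); wi(1, 2)                           # qform_code=0, sform_code=1
  wf(rep(0, 6))                                # quatern b,c,d + qoffset x,y,z
  wf(t(vol$affine[1:3, ]))                     # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)
  writeBin(raw(4), con)                        # extension flag
  wf(as.numeric(vol$data))
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports 3-D single-file NIfTI-1 with datatypes uint8/int16/int32/
#' float32/float64, sform (preferred) or pixdim geometry, and gzip.
#'
#' @param path file path.
#' @return A `vbm_volume`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n, size = 4) readBin(con, "numeric", n = n, size = size,
                                      endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L))
    stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36)
  dm <- ri(8, 2)
  ndim <- dm[1]
  if (ndim < 3) stop("expected a 3-D volume in ", path)
  shape <- dm[2:4]
  if (ndim > 3 && any(dm[5:(1 + ndim)] > 1))
    stop("only 3-D volumes are supported: ", path)
  readBin(con, "raw", 14)
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  readBin(con, "raw", 4)   # slice_end, slice_code, xyzt_units
  rf(2); rf(2); ri(2, 4)
  readBin(con, "raw", 104)
  ri(1, 2); sform_code <- ri(1, 2)
  rf(6)
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16 + 4 + 4)
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16" = rf(n),
    "64" = rf(n, size = 8),
    stop("unsupported NIfTI datatype ", datatype))
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  if (is.na(scl_inter)) scl_inter <- 0
  vals <- vals * scl_slope + scl_inter
  aff <- diag(4)
  if (sform_code > 0) {
    aff[1:3, ] <- srow
  } else {
    aff[1:3, 1:3] <- diag(pixdim[2:4])
  }
  as_volume(array(vals, shape), affine = aff)
}

# ---------------------------------------------------------------------------
# Shared array utilities: Otsu threshold, separable Gaussian, morphology.
# ---------------------------------------------------------------------------

## Otsu's between-class-variance threshold on a numeric sample.
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[1] == r[2]) stop("constant intensities: Otsu threshold undefined")
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

## Half-sample reflected index (scipy 'reflect'): ... c b a | a b c ...
reflect_index <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  ifelse(i < n, i + 1L, 2L * n - i)
}

## Separable Gaussian blur of a 3-D array, sigma per axis in voxels,
## half-sample reflecting boundaries (mass-conserving for symmetric kernels).
gauss_blur_arr <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)
  array(gauss_blur_cpp(as.numeric(a), dim(a), sigma), dim(a))
}

## Binary dilation/erosion, `iter` times. `connectivity` 26 gives the 3x3x3
## box structuring element, 6 the cross (which closes digital-sphere
## surfaces without inflating them).
dilate_arr <- function(m, iter = 1L, connectivity = 26L) {
  dm <- dim(m)
  for (rep in seq_len(iter)) {
    out <- m
    for (d in 1:3) {
      n <- dm[d]
      lo <- pmax(seq_len(n) - 1L, 1L)
      hi <- pmin(seq_len(n) + 1L, n)
      src <- if (connectivity == 6L) m else out
      out <- out | switch(d,
        src[lo, , , drop = FALSE] | src[hi, , , drop = FALSE],
        src[, lo, , drop = FALSE] | src[, hi, , drop = FALSE],
        src[, , lo, drop = FALSE] | src[, , hi, drop = FALSE])
      if (connectivity != 6L) m <- out
    }
    m <- out
  }
  m
}

erode_arr <- function(m, iter = 1L, connectivity = 26L)
  !dilate_arr(!m, iter, connectivity)

## Largest connected component of a logical array (26-connectivity).
largest_component <- function(m, connectivity = 26L) {
  lab <- label_components_cpp(as.integer(m), dim(m), connectivity)
  if (max(lab) == 0L) stop("empty mask: no components")
  keep <- which.max(tabulate(lab[lab > 0L]))
  array(lab == keep, dim(m))
}
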