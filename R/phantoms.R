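## Synthetic longitudinal phantom cohorts with analytically known regional
## atrophy. Atrophy is applied as smooth radial contraction fields whose
## Jacobian determinant is exact inside each designated region, so every
## downstream estimate (deformation fields, Jacobians, pseudo-time-point
## volumes, slopes) has a closed-form truth to be checked against.

#' Phantom specification
#'
#' Describes the static anatomy of a synthetic brain: grid, voxel size, a
#' labelled region atlas (0 = background, 1 = CSF, 2 = WM, 3..K = GM regions),
#' per-class mean intensities (T1-like: CSF < GM < WM), Gaussian noise SD and
#' the fractional amplitude of a smooth multiplicative intensity
#' non-uniformity field.
#'
#' @param grid_shape integer length-3, at least 16 per axis.
#' @param voxel_size_mm positive length-3 (mm).
#' @param region_atlas optional labelled atlas volume; default built by
#'   [default_atlas()].
#' @param tissue_means named intensity per label `1..K` (default CSF 40,
#'   WM 120, GM regions 80).
#' @param noise_sd Gaussian noise SD in intensity units (default 5, about 5%
#'   of parenchymal intensity).
#' @param bias_amplitude fractional amplitude of the low-order polynomial
#'   bias field (default 0).
#' @param seed integer RNG seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32),
                         voxel_size_mm = c(2, 2, 2),
                         region_atlas = NULL,
                         tissue_means = NULL,
                         noise_sd = 5,
                         bias_amplitude = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, length(voxel_size_mm) == 3,
            all(voxel_size_mm > 0), noise_sd >= 0, bias_amplitude >= 0)
  if (any(grid_shape < 16))
    stop("degenerate grid: phantom requires >= 16 voxels per axis")
  if (is.null(region_atlas))
    region_atlas <- default_atlas(grid_shape, voxel_size_mm)
  labels <- sort(unique(as.integer(region_atlas$data)))
  if (!identical(labels, seq(0L, max(labels))))
    stop("region labels must be contiguous integers starting at 0")
  K <- max(labels)
  if (is.null(tissue_means)) {
    tissue_means <- c(40, 120, rep(80, max(0L, K - 2L)))[seq_len(K)]
    names(tissue_means) <- as.character(seq_len(K))
  }
  if (length(tissue_means) < K)
    stop("every labelled class needs a tissue mean (labels 1..", K, ")")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 region_atlas = region_atlas,
                 tissue_means = as.numeric(tissue_means),
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom atlas
#'
#' Spherical "brain" with a central CSF compartment, a WM bulk, a cortical GM
#' shell (label 3), and two designated deep GM disease regions: a fast
#' "cingulate analog" (label 4) and a slow "precentral analog" (label 5),
#' standing in for the real study's anatomical labels. Atrophy-field geometry
#' (centre, core radius, transition radius) is stored in
#' `attr(, "atrophy_geom")`.
#'
#' @param grid_shape integer length-3.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @return Integer-labelled `vbm_volume` with attributes `regions` and
#'   `atrophy_geom`.
#' @export
default_atlas <- function(grid_shape = c(32, 32, 32),
                          voxel_size_mm = c(2, 2, 2)) {
  dm <- as.integer(grid_shape)
  extent <- dm * voxel_size_mm
  centre <- (dm - 1) / 2 * voxel_size_mm
  g <- index_grid(dm)
  world <- sweep(g, 2, voxel_size_mm, `*`)
  rel <- sweep(world, 2, centre, `-`)
  r <- sqrt(rowSums(rel^2))
  brain_r <- 0.44 * min(extent)
  lab <- integer(nrow(g))
  lab[r <= brain_r] <- 2L                       # WM bulk
  lab[r <= 0.18 * brain_r] <- 1L                # central CSF
  lab[r > 0.82 * brain_r & r <= brain_r] <- 3L  # cortical GM shell
  u <- c(1, 1, 0) / sqrt(2)
  # disease-region geometry scales with brain size (8/12 mm and 6.5/10.5 mm
  # radii at the default 32^3 x 2 mm grid); cores are placed clear of both
  # the CSF compartment and the cortical shell so the analytic contraction
  # deforms only WM around them
  geom <- data.frame(
    label = c(4L, 5L),
    name = c("cingulate_analog", "precentral_analog"),
    a_mm = c(0.284, 0.2307) * brain_r,
    b_mm = c(0.426, 0.3728) * brain_r,
    stringsAsFactors = FALSE)
  centres <- rbind(centre + 0.48 * brain_r * u,
                   centre - 0.48 * brain_r * u)
  geom$cx <- centres[, 1]; geom$cy <- centres[, 2]; geom$cz <- centres[, 3]
  for (i in seq_len(nrow(geom))) {
    d <- sqrt(rowSums(sweep(world, 2, centres[i, ], `-`)^2))
    lab[d <= geom$a_mm[i] & lab == 2L] <- geom$label[i]
  }
  atlas <- as_volume(array(lab, dm), voxel_mm = voxel_size_mm)
  attr(atlas, "regions") <- data.frame(
    label = 1:5,
    name = c("csf", "wm", "cortex", "cingulate_analog", "precentral_analog"),
    stringsAsFactors = FALSE)
  attr(atlas, "atrophy_geom") <- geom
  atlas
}

## Smooth multiplicative bias field in [1-amp, 1+amp], deterministic given the
## current RNG state: random first/second-order polynomial in centred
## normalised coordinates.
polynomial_bias_field <- function(dm, amplitude) {
  if (amplitude <= 0) return(array(1, dm))
  g <- index_grid(dm)
  xn <- sweep(sweep(g, 2, (dm - 1) / 2, `-`), 2, (dm - 1) / 2, `/`)
  basis <- cbind(xn, xn^2, xn[, 1] * xn[, 2], xn[, 1] * xn[, 3],
                 xn[, 2] * xn[, 3])
  co <- rnorm(ncol(basis))
  f <- as.numeric(basis %*% co)
  f <- f / max(abs(f))
  array(1 + amplitude * f, dm)
}

## Noise-free tissue-mean image for a label array.
tissue_image <- function(lab_arr, tissue_means) {
  means <- c(0, tissue_means)   # label 0 = background 0
  array(means[lab_arr + 1L], dim(lab_arr))
}

#' Generate a baseline phantom image
#'
#' Tissue class means plus a smooth multiplicative bias field plus i.i.d.
#' Gaussian noise; deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `volume` (intensity `vbm_volume`) and `atlas`
#'   (the labelled atlas).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  lab <- spec$region_atlas$data
  clean <- tissue_image(lab, spec$tissue_means)
  bias <- polynomial_bias_field(dim(clean), spec$bias_amplitude)
  img <- clean * bias
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
  out <- list(volume = as_volume(img, voxel_mm = spec$voxel_size_mm,
                                 affine = spec$region_atlas$affine),
              atlas = spec$region_atlas)
  attr(out, "spec") <- spec
  out
}

#' Regional atrophy model
#'
#' Annual fractional volume-change rates for the designated disease regions,
#' separately for patients and controls, with optional between-subject rate
#' SD and a delayed-onset mode (cumulative factor
#' `1 + rate * max(0, t - onset)`; `onset = 0` is the default constant-rate
#' linear model matching the first-level linear fit).
#'
#' @param patient_rates named numeric, fraction/year (negative = loss).
#' @param control_rates named numeric, same regions.
#' @param rate_sd between-subject SD of the patient rates (recycled).
#' @param control_rate_sd between-subject SD for controls (defaults to
#'   `rate_sd`; set 0 for a strictly atrophy-free control group).
#' @param onset_years delay before atrophy starts (0 = linear).
#' @return An `atrophy_model`.
#' @export
atrophy_model <- function(patient_rates = c(cingulate_analog = -0.02,
                                            precentral_analog = -0.005),
                          control_rates = c(cingulate_analog = 0,
                                            precentral_analog = 0),
                          rate_sd = c(cingulate_analog = 0.004,
                                      precentral_analog = 0.002),
                          control_rate_sd = rate_sd,
                          onset_years = 0) {
  stopifnot(identical(names(patient_rates), names(control_rates)))
  if (any(abs(c(patient_rates, control_rates)) >= 0.5))
    stop("annual rates must lie in (-0.5, 0.5)")
  if (any(abs(control_rates) > abs(patient_rates) + 1e-12))
    stop("control rate magnitudes must not exceed patient rates")
  rate_sd <- rep(rate_sd, length.out = length(patient_rates))
  names(rate_sd) <- names(patient_rates)
  control_rate_sd <- rep(control_rate_sd, length.out = length(patient_rates))
  names(control_rate_sd) <- names(patient_rates)
  structure(list(patient_rates = patient_rates,
                 control_rates = control_rates,
                 rate_sd = rate_sd, control_rate_sd = control_rate_sd,
                 onset_years = onset_years),
            class = "atrophy_model")
}

cumulative_factor <- function(rate, t, onset = 0) 1 + rate * pmax(0, t - onset)

## Radial contraction profile for one region: forward map rho(r) taking a
## template radius to the deformed radius, uniform scale s = f^(1/3) inside
## the core (exact Jacobian f), C1 cubic-Hermite decay to identity at b.
radial_profile <- function(f, a, b) {
  s <- f^(1 / 3)
  rho <- function(r) {
    out <- r
    core <- r <= a
    out[core] <- s * r[core]
    tz <- r > a & r < b
    if (any(tz)) {
      tt <- (r[tz] - a) / (b - a)
      h00 <- (1 + 2 * tt) * (1 - tt)^2
      h10 <- tt * (1 - tt)^2
      d <- (s - 1) * a * h00 + (s - 1) * (b - a) * h10
      out[tz] <- r[tz] + d
    }
    out
  }
  drho <- function(r) {
    out <- rep(1, length(r))
    out[r <= a] <- s
    tz <- r > a & r < b
    if (any(tz)) {
      tt <- (r[tz] - a) / (b - a)
      dh00 <- (6 * tt^2 - 6 * tt) / (b - a)
      dh10 <- (3 * tt^2 - 4 * tt + 1) / (b - a)
      out[tz] <- 1 + (s - 1) * a * dh00 + (s - 1) * (b - a) * dh10
    }
    out
  }
  list(rho = rho, drho = drho, s = s, a = a, b = b)
}

## Forward displacement (mm), analytic Jacobian, and inverse-map source
## coordinates (mm) for a set of regional factors on one grid.
## `world` is the N x 3 world-coordinate matrix of the grid.
radial_warp <- function(world, geom, factors) {
  n <- nrow(world)
  disp <- matrix(0, n, 3)
  jac <- rep(1, n)
  src <- world
  for (i in seq_len(nrow(geom))) {
    f <- factors[geom$name[i]]
    if (abs(f - 1) < 1e-12) next
    if (f <= 0) stop("cumulative volume factor <= 0 for region ",
                     geom$name[i])
    pr <- radial_profile(f, geom$a_mm[i], geom$b_mm[i])
    ctr <- c(geom$cx[i], geom$cy[i], geom$cz[i])
    rel <- sweep(world, 2, ctr, `-`)
    r <- sqrt(rowSums(rel^2))
    inside <- r < pr$b & r > 1e-9
    if (any(inside)) {
      rr <- r[inside]
      rho_r <- pr$rho(rr)
      scale <- rho_r / rr
      disp[inside, ] <- disp[inside, ] + rel[inside, ] * (scale - 1)
      jac[inside] <- jac[inside] * pr$drho(rr) * scale^2
      # inverse by monotone interpolation of the sampled forward profile
      rg <- seq(0, pr$b, length.out = 2048)
      rinv <- stats::approx(pr$rho(rg), rg, xout = rr, rule = 2)$y
      src[inside, ] <- sweep(rel[inside, ] * (rinv / rr), 2, ctr, `+`)
    }
    centred <- r <= 1e-9
    jac[centred] <- jac[centred] * f
  }
  list(disp = disp, jac = jac, src = src)
}

new_deformation_field <- function(disp4d, ref, reg_param = NA, iters = NA) {
  structure(list(disp = disp4d, voxel_mm = ref$voxel_mm,
                 affine = ref$affine, reg_param = reg_param,
                 iterations = iters),
            class = "deformation_field")
}

#' Simulate one subject's longitudinal series
#'
#' Each visit is the baseline phantom resampled through an analytically
#' synthesized diffeomorphic contraction whose regional mean Jacobian equals
#' the atrophy model's cumulative volume factor; WM lesions, bias field,
#' scanner-upgrade intensity shift and fresh Gaussian noise are then applied.
#' The exact forward deformation field and Jacobian map of every visit are
#' returned as ground truth.
#'
#' @param phantom output of [make_phantom()] (list `volume`, `atlas`).
#' @param atlas labelled atlas (defaults to `phantom$atlas`).
#' @param model an [atrophy_model()].
#' @param visit_times sorted nominal visit times in years
#'   (default `c(0, 1, 2, 3, 5)`, the study schedule).
#' @param missing subset of `visit_times` to drop (at least 2 must remain).
#' @param seed integer seed.
#' @param group `"patient"` or `"control"` (selects the model's rates).
#' @param rates optional named per-region rates overriding the model draw.
#' @param upgrade_year visits at or after this time get the multiplicative
#'   `upgrade_shift` and `upgrade = TRUE` (default `Inf`, i.e. none).
#' @param upgrade_shift fractional intensity shift after upgrade.
#' @param jitter_mm global subject translation (mm) emulating positioning.
#' @param n_lesions number of spherical WM lesions.
#' @return List with `series` (a `subject_series`) and `truth`.
#' @export
simulate_subject_series <- function(phantom, atlas = phantom$atlas, model,
                                    visit_times = c(0, 1, 2, 3, 5),
                                    missing = numeric(0), seed = 1L,
                                    group = c("patient", "control"),
                                    rates = NULL,
                                    upgrade_year = Inf, upgrade_shift = 0.05,
                                    jitter_mm = c(0, 0, 0), n_lesions = 3L) {
  group <- match.arg(group)
  stopifnot(!is.unsorted(visit_times))
  times <- setdiff(visit_times, missing)
  if (length(times) < 2) stop("fewer than 2 retained visits")
  set.seed(seed)
  geom <- attr(atlas, "atrophy_geom")
  if (is.null(rates)) {
    mu <- if (group == "patient") model$patient_rates else model$control_rates
    rsd <- if (group == "patient") model$rate_sd else model$control_rate_sd
    rates <- mu + rnorm(length(mu), 0, rsd)
    names(rates) <- names(mu)
  }
  if (any(abs(rates) >= 0.5)) stop("annual rates must lie in (-0.5, 0.5)")
  for (t in times)
    if (any(cumulative_factor(rates, t, model$onset_years) <= 0))
      stop("cumulative volume factor <= 0 at year ", t)

  spec_vox <- phantom$volume$voxel_mm
  dm <- dim(phantom$volume$data)
  lab <- atlas$data
  world <- sweep(index_grid(dm), 2, spec_vox, `*`)
  spec <- attr(phantom, "spec")
  if (is.null(spec))
    stop("phantom must come from make_phantom() (missing spec attribute)")
  clean <- tissue_image(lab, spec$tissue_means)
  noise_sd <- spec$noise_sd
  bias <- polynomial_bias_field(dm, spec$bias_amplitude)

  # static WM lesions, away from the atrophy transition zones
  lesion_mask <- array(FALSE, dm)
  wm_idx <- which(lab == 2L)
  if (n_lesions > 0 && length(wm_idx) > 0) {
    dmin <- rep(Inf, nrow(world))
    for (i in seq_len(nrow(geom)))
      dmin <- pmin(dmin, sqrt(rowSums(sweep(world, 2,
        c(geom$cx[i], geom$cy[i], geom$cz[i]), `-`)^2)) - geom$b_mm[i])
    ok <- wm_idx[dmin[wm_idx] > 2]
    if (length(ok) >= n_lesions) {
      centres <- world[sample(ok, n_lesions), , drop = FALSE]
      for (i in seq_len(n_lesions)) {
        d <- sqrt(rowSums(sweep(world, 2, centres[i, ], `-`)^2))
        lesion_mask[d <= runif(1, 2.5, 4.5) & lab == 2L] <- TRUE
      }
    }
  }

  region_names <- geom$name
  volumes <- list(); lesions <- list(); fields <- list(); jacs <- list()
  upgrade <- logical(length(times))
  factors <- matrix(NA_real_, nrow(geom), length(times),
                    dimnames = list(region_names, paste0("y", times)))
  voxvol_ml <- prod(spec_vox) / 1000
  base_region_vol <- vapply(geom$label, function(l) sum(lab == l), 0) *
    voxvol_ml
  names(base_region_vol) <- region_names
  gm_labels <- setdiff(sort(unique(as.integer(lab))), c(0L, 1L, 2L))
  base_gm_vol <- sum(lab %in% gm_labels) * voxvol_ml
  gm_volume <- numeric(length(times))

  for (vi in seq_along(times)) {
    t <- times[vi]
    f <- cumulative_factor(rates, t, model$onset_years)
    names(f) <- names(rates)
    factors[, vi] <- f[region_names]
    rw <- radial_warp(world, geom, f)
    src_world <- sweep(rw$src, 2, jitter_mm, `+`)
    src_vox <- sweep(src_world, 2, spec_vox, `/`)
    img <- array(resample_at_vox(as_volume(clean, voxel_mm = spec_vox),
                                 src_vox), dm)
    les_t <- lesion_mask
    if (any(les_t)) {
      wm_mean <- mean(clean[lab == 2L])
      img[les_t] <- wm_mean * 0.7
    }
    img <- img * bias
    up <- is.finite(upgrade_year) && t >= upgrade_year
    if (up) img <- img * (1 + upgrade_shift)
    if (noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, noise_sd), dm)
    volumes[[vi]] <- as_volume(img, affine = phantom$volume$affine)
    lesions[[vi]] <- like_volume(as.numeric(les_t), volumes[[vi]])
    upgrade[vi] <- up
    fields[[vi]] <- new_deformation_field(
      array(rw$disp, c(dm, 3)), phantom$volume)
    jacs[[vi]] <- like_volume(rw$jac, phantom$volume)
    # true GM volume: each GM region scaled by its factor, cortex unscaled
    gm_volume[vi] <- base_gm_vol +
      sum(base_region_vol * (factors[, vi] - 1))
  }

  series <- structure(list(times = times, volumes = volumes,
                           lesion_masks = lesions, upgrade = upgrade,
                           group = group, clinical = NULL),
                      class = "subject_series")
  truth <- list(rates = rates, factors = factors, fields = fields,
                jacobians = jacs, gm_volume = gm_volume,
                baseline_region_vol = base_region_vol,
                jitter_mm = jitter_mm, lesion_mask = lesion_mask)
  list(series = series, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_tissue_means <- function(lab) {
  K <- max(lab)
  c(40, 120, rep(80, max(0L, K - 2L)))[seq_len(K)]
}

## EDSS legal ordinal grid: 0, then 1 to 10 in half steps.
edss_grid <- function() c(0, seq(1, 10, by = 0.5))

round_to_edss <- function(x) {
  g <- edss_grid()
  g[pmax(1, pmin(length(g), vapply(x, function(v) which.min(abs(g - v)), 0L)))]
}

#' Tune the clinical coupling for a target correlation
#'
#' Chooses the gain of the MSFC-slope coupling so that the analytic Pearson
#' correlation between a subject's designated-region atrophy rate and their
#' year-`horizon` MSFC equals `r_target`, given the rate SD and the
#' non-atrophy variance sources (baseline MSFC SD, slope noise, visit noise).
#'
#' @param r_target desired correlation (default 0.5, the regime of the
#'   association the pipeline is validated against).
#' @param rate_sd between-subject SD of the coupled region's rate.
#' @param horizon outcome year (default 5).
#' @param slope_noise_sd SD of the non-atrophy component of the MSFC slope.
#' @param msfc0_sd between-subject SD of baseline MSFC.
#' @param visit_noise_sd per-visit MSFC measurement noise SD.
#' @param msfc0_mean baseline MSFC mean (patients).
#' @param mean_rate mean coupled-region rate (sets the intercept so the mean
#'   slope is `mean_slope`).
#' @param mean_slope mean MSFC slope per year (default -0.25, the patient
#'   progression regime).
#' @return A `clinical_coupling` list (intercept, gain, noise_sd, ...).
#' @export
tune_clinical_coupling <- function(r_target = 0.5, rate_sd = 0.004,
                                   horizon = 5, slope_noise_sd = 0.05,
                                   msfc0_sd = 1.0, visit_noise_sd = 0.2,
                                   msfc0_mean = -1.2, mean_rate = -0.02,
                                   mean_slope = -0.25) {
  stopifnot(r_target > 0, r_target < 1)
  nvar <- msfc0_sd^2 + horizon^2 * slope_noise_sd^2 + visit_noise_sd^2
  A <- sqrt(nvar) * r_target / sqrt(1 - r_target^2)
  gain <- A / (horizon * rate_sd)
  clinical_coupling(intercept = mean_slope - gain * mean_rate, gain = gain,
                    noise_sd = slope_noise_sd, msfc0_mean = msfc0_mean,
                    msfc0_sd = msfc0_sd, visit_noise_sd = visit_noise_sd)
}

#' Clinical coupling parameters
#'
#' MSFC slope per subject = `intercept + gain * rate + N(0, noise_sd)`, where
#' `rate` is the subject's true designated-region atrophy rate; MSFC at visit
#' t = baseline + slope * t + visit noise.
#'
#' @param intercept,gain,noise_sd slope model parameters.
#' @param msfc0_mean,msfc0_sd baseline MSFC distribution (patients).
#' @param visit_noise_sd per-visit measurement noise SD.
#' @param coupled_region region whose rate drives the outcome.
#' @return A `clinical_coupling` list.
#' @export
clinical_coupling <- function(intercept = -0.25, gain = 0, noise_sd = 0.05,
                              msfc0_mean = -1.2, msfc0_sd = 1.0,
                              visit_noise_sd = 0.2,
                              coupled_region = "cingulate_analog") {
  list(intercept = intercept, gain = gain, noise_sd = noise_sd,
       msfc0_mean = msfc0_mean, msfc0_sd = msfc0_sd,
       visit_noise_sd = visit_noise_sd, coupled_region = coupled_region)
}

## Per-visit clinical record for one subject given true slopes.
make_clinical_records <- function(times, group, coupling, rate, upgrade) {
  patient <- group == "patient"
  msfc_slope <- if (patient)
    coupling$intercept + coupling$gain * rate +
      rnorm(1, 0, coupling$noise_sd)
  else rnorm(1, 0, coupling$noise_sd)
  msfc0 <- if (patient) rnorm(1, coupling$msfc0_mean, coupling$msfc0_sd)
           else rnorm(1, 0, 0.3)
  edss_slope <- if (patient) max(-0.4, rnorm(1, 0.36, 0.71)) else 0
  edss0 <- if (patient) round_to_edss(runif(1, 1.5, 6)) else 0
  t2ll_slope <- if (patient) rnorm(1, 2.59, 3.41) else 0
  t2ll0 <- if (patient) max(0.5, rnorm(1, 10, 5)) else 0
  msfc <- msfc0 + msfc_slope * times +
    rnorm(length(times), 0, coupling$visit_noise_sd)
  edss <- round_to_edss(pmin(10, pmax(0, edss0 + edss_slope * times +
                                        rnorm(length(times), 0, 0.3))))
  if (!patient) edss <- rep(0, length(times))
  t2ll <- pmax(0, t2ll0 + t2ll_slope * times)
  # components loosely consistent with the composite (z-score convention)
  twt <- 5 + 2 * (-msfc) + rnorm(length(times), 0, 0.5)
  pasat <- pmax(0, round(45 + 8 * msfc + rnorm(length(times), 0, 3)))
  nhpt <- 20 + 4 * (-msfc) + rnorm(length(times), 0, 1)
  data.frame(time_years = times, edss = edss, msfc = msfc, twt = twt,
             pasat = pasat, nhpt = nhpt, t2_lesion_load_ml = t2ll,
             upgrade = upgrade)
}

#' Simulate a full longitudinal cohort
#'
#' Two groups with the study's visit schedule, random missing visits
#' (baseline always kept, every subject retains at least 2 visits — violating
#' draws are redrawn and logged), a mid-study scanner upgrade applying a
#' global intensity shift, and clinical scores coupled to the designated
#' region's true atrophy rate.
#'
#' @param n_patients,n_controls group sizes (at least 2 each).
#' @param model an [atrophy_model()].
#' @param missingness_rate per-visit dropout probability for follow-ups.
#' @param upgrade_year scanner upgrade time (default 2.5: visits at years 3
#'   and 5 are post-upgrade, 40% of a complete schedule).
#' @param clinical_coupling a [clinical_coupling()] list.
#' @param seed integer seed.
#' @param spec a [phantom_spec()] shared by all subjects.
#' @param visit_times nominal schedule.
#' @param jitter_sd_mm SD of the per-subject global translation (mm).
#' @param upgrade_shift fractional post-upgrade intensity change.
#' @return A `vbm_cohort`: list of `subjects` (subject_series), `truth`,
#'   `covariates` data frame, and `clinical` long-format data frame.
#' @export
simulate_cohort <- function(n_patients, n_controls,
                            model = atrophy_model(),
                            missingness_rate = 0.15,
                            upgrade_year = 2.5,
                            clinical_coupling = tune_clinical_coupling(),
                            seed = 1L,
                            spec = phantom_spec(seed = seed,
                                                bias_amplitude = 0.1),
                            visit_times = c(0, 1, 2, 3, 5),
                            jitter_sd_mm = 1.0,
                            upgrade_shift = 0.05) {
  stopifnot(n_patients >= 2, n_controls >= 2)
  set.seed(seed)
  phantom <- make_phantom(spec)
  groups <- c(rep("patient", n_patients), rep("control", n_controls))
  ids <- sprintf("%s%02d", ifelse(groups == "patient", "P", "C"),
                 c(seq_len(n_patients), seq_len(n_controls)))
  subjects <- list(); truths <- list()
  cov_rows <- list(); clin_rows <- list()
  redrawn <- 0L
  for (si in seq_along(ids)) {
    repeat {
      drop <- visit_times[-1][runif(length(visit_times) - 1) <
                                missingness_rate]
      if (length(visit_times) - length(drop) >= 2) break
      redrawn <- redrawn + 1L
    }
    jit <- rnorm(3, 0, jitter_sd_mm)
    sub_seed <- (seed * 1000L + si) %% .Machine$integer.max
    st <- simulate_subject_series(phantom, phantom$atlas, model,
                                  visit_times = visit_times, missing = drop,
                                  seed = sub_seed, group = groups[si],
                                  upgrade_year = upgrade_year,
                                  upgrade_shift = upgrade_shift,
                                  jitter_mm = jit)
    set.seed(sub_seed + 500L)
    age <- if (groups[si] == "patient") rnorm(1, 42.8, 11) else
      rnorm(1, 37.6, 9.4)
    sex <- if (runif(1) < ifelse(groups[si] == "patient", 0.33, 0.47))
      "F" else "M"
    rate <- st$truth$rates[[clinical_coupling$coupled_region]]
    clin <- make_clinical_records(st$series$times, groups[si],
                                  clinical_coupling, rate,
                                  st$series$upgrade)
    st$series$clinical <- clin
    st$series$id <- ids[si]
    st$series$age <- age
    st$series$sex <- sex
    subjects[[ids[si]]] <- st$series
    truths[[ids[si]]] <- st$truth
    cov_rows[[si]] <- data.frame(subject = ids[si], group = groups[si],
                                 age = age, sex = sex,
                                 upgrade_prop = mean(st$series$upgrade),
                                 stringsAsFactors = FALSE)
    clin_rows[[si]] <- cbind(subject = ids[si], clin)
  }
  if (redrawn > 0)
    message("simulate_cohort: redrew missingness for ", redrawn,
            " subject draw(s) leaving < 2 visits")
  structure(list(subjects = subjects,
                 truth = truths,
                 phantom = phantom,
                 atlas = phantom$atlas,
                 covariates = do.call(rbind, cov_rows),
                 clinical = do.call(rbind, clin_rows),
                 model = model,
                 coupling = clinical_coupling,
                 seed = seed),
            class = "vbm_cohort")
}

#' Write a cohort to disk
#'
#' One NIfTI per visit plus per-visit lesion masks, a cohort manifest CSV
#' (subject, group, visit, time_years, path, upgrade_flag, age, sex), a
#' clinical CSV and a ground-truth JSON.
#'
#' @param cohort a `vbm_cohort`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in names(cohort$subjects)) {
    s <- cohort$subjects[[id]]
    for (vi in seq_along(s$times)) {
      p <- file.path(dir, sprintf("%s_y%g.nii", id, s$times[vi]))
      write_nifti(s$volumes[[vi]], p)
      lp <- file.path(dir, sprintf("%s_y%g_lesion.nii", id, s$times[vi]))
      write_nifti(s$lesion_masks[[vi]], lp)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = id, group = s$group, visit = vi,
        time_years = s$times[vi], path = p, lesion_path = lp,
        upgrade_flag = s$upgrade[vi], age = s$age, sex = s$sex,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  truth <- lapply(cohort$truth, function(tr)
    list(rates = as.list(tr$rates),
         factors = as.data.frame(tr$factors),
         gm_volume_ml = tr$gm_volume,
         baseline_region_vol_ml = as.list(tr$baseline_region_vol),
         jitter_mm = tr$jitter_mm))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
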