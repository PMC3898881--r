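## End-to-end orchestration: configuration, staged execution, provenance.

#' Pipeline run configuration
#'
#' Defaults follow the study's stated settings: HDW regularisation parameter
#' 4 with 8 iterations, 8 mm FWHM smoothing, 5000 permutations, alpha 0.05.
#' Every numeric setting and every seed is recorded in the provenance JSON,
#' making a run exactly repeatable.
#'
#' @param cohort optional in-memory `vbm_cohort` (else `manifest` is read).
#' @param manifest path to a cohort manifest CSV (see [write_cohort()]).
#' @param clinical_csv path to the clinical CSV when using a manifest.
#' @param out_dir output directory (NULL = in-memory only).
#' @param reg_param,n_iter HDW settings.
#' @param fwhm_mm smoothing FWHM.
#' @param n_perm,alpha second-level permutation settings.
#' @param seeds named list: `cohort`, `balanced`, `permutation`.
#' @param nonuniformity_order polynomial order for bias correction.
#' @param do_slope,do_quadratic,do_posthoc,do_clinical analysis toggles.
#' @param posthoc_years follow-up years for the baseline-subtraction test.
#' @param median_max_iter,median_tol within-subject template settings.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(cohort = NULL, manifest = NULL,
                            clinical_csv = NULL, out_dir = NULL,
                            reg_param = 4, n_iter = 8L, fwhm_mm = 8,
                            n_perm = 5000L, alpha = 0.05,
                            seeds = list(cohort = 1L, balanced = 1L,
                                         permutation = 1L),
                            nonuniformity_order = 2L,
                            do_slope = TRUE, do_quadratic = TRUE,
                            do_posthoc = FALSE, do_clinical = TRUE,
                            posthoc_years = 5,
                            median_max_iter = 5L, median_tol = 0.01,
                            run_until = c("all", "preprocess",
                                          "within_subject", "group",
                                          "first_level", "second_level",
                                          "clinical")) {
  run_until <- match.arg(run_until)
  cfg <- list(cohort = cohort, manifest = manifest,
              clinical_csv = clinical_csv, out_dir = out_dir,
              reg_param = reg_param, n_iter = as.integer(n_iter),
              fwhm_mm = fwhm_mm, n_perm = as.integer(n_perm), alpha = alpha,
              seeds = seeds, nonuniformity_order = nonuniformity_order,
              do_slope = do_slope, do_quadratic = do_quadratic,
              do_posthoc = do_posthoc, do_clinical = do_clinical,
              posthoc_years = posthoc_years,
              median_max_iter = as.integer(median_max_iter),
              median_tol = median_tol, run_until = run_until)
  stopifnot(!is.null(cfg$cohort) || !is.null(cfg$manifest))
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage_guard <- function(stage, subject = NULL, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "'",
         if (!is.null(subject)) paste0(" (subject ", subject, ")"),
         " failed: ", conditionMessage(e), call. = FALSE))
}

load_cohort_from_manifest <- function(manifest, clinical_csv) {
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  subjects <- list()
  for (id in unique(man$subject)) {
    rows <- man[man$subject == id, ]
    rows <- rows[order(rows$time_years), ]
    subjects[[id]] <- structure(list(
      id = id, group = rows$group[1], times = rows$time_years,
      volumes = lapply(rows$path, read_nifti),
      lesion_masks = lapply(rows$lesion_path, read_nifti),
      upgrade = as.logical(rows$upgrade_flag),
      age = rows$age[1], sex = rows$sex[1], clinical = NULL),
      class = "subject_series")
  }
  clinical <- if (!is.null(clinical_csv))
    read.csv(clinical_csv, stringsAsFactors = FALSE) else NULL
  cov <- unique(man[, c("subject", "group", "age", "sex")])
  up <- vapply(split(man$upgrade_flag, man$subject)[cov$subject], mean, 0)
  cov$upgrade_prop <- up
  structure(list(subjects = subjects, truth = NULL, phantom = NULL,
                 atlas = NULL, covariates = cov, clinical = clinical),
            class = "vbm_cohort")
}

#' Run the full longitudinal VBM pipeline
#'
#' Executes, in order: preprocessing (lesion filling, non-uniformity
#' correction, brain extraction); within-subject median template, HDW,
#' Jacobians, segmentation, pseudo-time-points; group template,
#' normalisation without modulation, smoothing, explicit GM mask; first-level
#' slope (and quadratic) images; second-level permutation inference with
#' TFCE; optional post-hoc baseline subtraction; clinical statistics. Any
#' stage failure halts with the stage name and subject id; outputs of
#' completed stages are retained in the returned object.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage timings.
#' @return A `pipeline_result` list (templates, fields, Jacobians,
#'   pseudo-time-points, slope images, stat maps, tables, provenance).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[3]
  timings <- c()
  tick <- function(stage, start) {
    el <- round(proc.time()[3] - start, 2)
    timings[[stage]] <<- el
    if (verbose) message(sprintf("[%s] %.2fs", stage, el))
  }
  res <- list(config = config)

  t0 <- proc.time()[3]
  cohort <- if (!is.null(config$cohort)) config$cohort else
    stage_guard("load", NULL,
                load_cohort_from_manifest(config$manifest,
                                          config$clinical_csv))
  ids <- names(cohort$subjects)
  tick("load", t0)

  # --- preprocess ----------------------------------------------------------
  t0 <- proc.time()[3]
  prep <- list()
  for (id in ids) {
    s <- cohort$subjects[[id]]
    prep[[id]] <- stage_guard("preprocess", id, {
      lapply(seq_along(s$times), function(vi) {
        img <- s$volumes[[vi]]
        brain <- extract_brain(img)
        # WM proxy mask: brightest class inside the brain (T1-like)
        thr <- otsu_threshold(img$data[brain$data > 0.5])
        wm <- like_volume(as.numeric(img$data >= thr &
                                       brain$data > 0.5), img)
        les <- s$lesion_masks[[vi]]
        filled <- if (!is.null(les) && any(les$data > 0.5))
          fill_lesions(img, les, wm) else img
        corr <- correct_nonuniformity(filled, config$nonuniformity_order,
                                      brain)
        like_volume(corr$data * (brain$data > 0.5), corr)
      })
    })
  }
  tick("preprocess", t0)
  finish <- function(extra) {
    out <- c(res, extra, list(timings = timings))
    class(out) <- "pipeline_result"
    out
  }
  if (identical(config$run_until, "preprocess"))
    return(finish(list(preprocessed = prep)))

  # --- within-subject ------------------------------------------------------
  t0 <- proc.time()[3]
  within <- list()
  for (id in ids) {
    s <- cohort$subjects[[id]]
    within[[id]] <- stage_guard("within_subject", id, {
      wst <- build_median_template(prep[[id]],
                                   max_iter = config$median_max_iter,
                                   tol = config$median_tol)
      tmpl <- wst$template
      brain <- extract_brain(tmpl)
      # gate out near-zero rim voxels the morphological closing pulls in,
      # so the mixture's lowest class is CSF rather than masked background
      seg_mask <- like_volume(
        as.numeric(brain$data > 0.5 &
                     tmpl$data > 0.05 * max(tmpl$data)), tmpl)
      seg <- segment_template(tmpl, 3L, seg_mask)
      maps <- list(); jacs <- list(); fields <- list()
      for (vi in seq_along(s$times)) {
        aligned <- resample_rigid(prep[[id]][[vi]], tmpl,
                                  wst$transforms[[vi]])
        fld <- hdw_register(aligned, tmpl, reg_param = config$reg_param,
                            n_iter = config$n_iter)
        jac <- jacobian_determinant(fld)
        fields[[vi]] <- fld
        jacs[[vi]] <- jac
        maps[[vi]] <- pseudo_timepoint(seg$gm, jac)
      }
      list(template = wst, gm = seg$gm, segmentation = seg,
           fields = fields, jacobians = jacs, pseudo = maps,
           times = s$times)
    })
  }
  tick("within_subject", t0)
  if (identical(config$run_until, "within_subject"))
    return(finish(list(preprocessed = prep, within = within)))

  # --- group space ---------------------------------------------------------
  t0 <- proc.time()[3]
  groups <- cohort$covariates$group[match(ids, cohort$covariates$subject)]
  gt <- stage_guard("group_template", NULL, {
    gm_maps <- lapply(within, function(w) w$gm)
    build_group_template(gm_maps, groups, seed = config$seeds$balanced)
  })
  norm_raw <- list()     # unsmoothed: ROI-level analyses
  norm_smooth <- list()  # smoothed: voxel-wise inference
  gm_group <- list()
  for (id in ids) {
    norm_raw[[id]] <- stage_guard("normalise", id, {
      lapply(within[[id]]$pseudo, function(p)
        normalize_to_group(p, gt$warps[[id]]))
    })
    norm_smooth[[id]] <- lapply(norm_raw[[id]], gaussian_smooth,
                                fwhm_mm = config$fwhm_mm)
    gm_group[[id]] <- gaussian_smooth(
      normalize_to_group(within[[id]]$gm, gt$warps[[id]]), config$fwhm_mm)
  }
  mask <- stage_guard("explicit_mask", NULL, make_explicit_mask(gm_group))
  tick("group_space", t0)
  if (identical(config$run_until, "group"))
    return(finish(list(preprocessed = prep, within = within,
                       group_template = gt, mask = mask,
                       normalized = norm_smooth,
                       normalized_raw = norm_raw)))

  # --- first level ---------------------------------------------------------
  t0 <- proc.time()[3]
  voxvol_ml <- prod(gt$template$voxel_mm) / 1000
  slope_images <- list(); quad_images <- list(); roi_slope_images <- list()
  baseline_gm <- numeric(length(ids)); names(baseline_gm) <- ids
  for (id in ids) {
    w <- within[[id]]
    baseline_gm[id] <- sum(norm_smooth[[id]][[1]]$data) * voxvol_ml
    if (config$do_slope) {
      slope_images[[id]] <- stage_guard("first_level", id,
        fit_voxelwise_slope(norm_smooth[[id]], w$times, subject = id))
      # ROI analyses pool spatially themselves; they use unsmoothed maps
      roi_slope_images[[id]] <- stage_guard("first_level", id,
        fit_voxelwise_slope(norm_raw[[id]], w$times, subject = id))
    }
    if (config$do_quadratic && length(unique(w$times)) >= 3)
      quad_images[[id]] <- stage_guard("first_level", id,
        fit_voxelwise_quadratic(norm_smooth[[id]], w$times, subject = id))
  }
  tick("first_level", t0)
  if (identical(config$run_until, "first_level"))
    return(finish(list(preprocessed = prep, within = within,
                       group_template = gt, mask = mask,
                       normalized = norm_smooth,
                       normalized_raw = norm_raw,
                       slope_images = slope_images,
                       roi_slope_images = roi_slope_images,
                       quadratic_images = quad_images)))

  # --- second level --------------------------------------------------------
  t0 <- proc.time()[3]
  cov <- cohort$covariates[match(ids, cohort$covariates$subject), ]
  cov$baseline_gm <- baseline_gm[ids]
  nuis <- c("age", "sex", "baseline_gm", "upgrade_prop")
  # keep at least 2 residual df: trim nuisance covariates on tiny cohorts
  keep <- max(0L, min(length(nuis), length(ids) - 4L))
  if (keep < length(nuis))
    message("run_pipeline: only ", length(ids), " subjects; using ",
            keep, " of ", length(nuis), " nuisance covariates")
  design <- make_design(cov, group_col = "group",
                        nuisance = nuis[seq_len(keep)])
  second <- list()
  if (config$do_slope && length(slope_images) == length(ids)) {
    # atrophy = negative slope; "patients faster" = negative patient effect
    con <- -design$contrasts$patient_gt_control
    second$two_sample_slope <- stage_guard("second_level", NULL,
      permutation_fwe(slope_images[ids], design, con, mask,
                      n_perm = config$n_perm, enhance = "tfce",
                      alpha = config$alpha,
                      seed = config$seeds$permutation))
  }
  if (config$do_quadratic && length(quad_images) >= 4) {
    qids <- names(quad_images)
    qcov <- cov[match(qids, cov$subject), ]
    qdes <- make_design(qcov, group_col = "group",
                        nuisance = c("age", "sex"))
    second$two_sample_quadratic <- stage_guard("second_level", NULL,
      permutation_fwe(quad_images[qids], qdes,
                      -qdes$contrasts$patient_gt_control, mask,
                      n_perm = config$n_perm, enhance = "tfce",
                      alpha = config$alpha,
                      seed = config$seeds$permutation))
  }
  if (config$do_posthoc) {
    complete <- ids[vapply(ids, function(id)
      all(config$posthoc_years %in% within[[id]]$times) &&
        0 %in% within[[id]]$times, TRUE)]
    complete <- complete[groups[match(complete, ids)] == "patient"]
    if (length(complete) >= 2) {
      pb <- lapply(complete, function(id)
        list(times = within[[id]]$times, maps = norm_smooth[[id]]))
      names(pb) <- complete
      second$posthoc <- lapply(config$posthoc_years, function(yy)
        stage_guard("posthoc", NULL,
          paired_baseline_subtraction_test(pb, yy, mask,
                                           n_perm = config$n_perm,
                                           alpha = config$alpha,
                                           seed = config$seeds$permutation)))
      names(second$posthoc) <- paste0("year", config$posthoc_years)
    }
  }
  tick("second_level", t0)

  # --- clinical ------------------------------------------------------------
  t0 <- proc.time()[3]
  clinical <- NULL
  if (config$do_clinical && !is.null(cohort$clinical)) {
    clinical <- stage_guard("clinical", NULL, {
      slopes <- clinical_slopes_table(cohort$clinical)
      pat <- cohort$covariates$subject[cohort$covariates$group == "patient"]
      prog <- list(
        edss = one_sample_progression_test(
          slopes$edss_step_slope[slopes$subject %in% pat]),
        msfc = one_sample_progression_test(
          slopes$msfc_slope[slopes$subject %in% pat]))
      assoc <- NULL
      if (!is.null(cohort$atlas) && length(roi_slope_images) > 0 &&
          sum(pat %in% names(roi_slope_images)) >= 3) {
        atlas_g <- cohort$atlas   # group space approximates phantom space
        rates <- vapply(pat[pat %in% names(roi_slope_images)], function(id)
          roi_rate(roi_slope_images[[id]], atlas_g, "cingulate_analog",
                   mask), 0)
        y5 <- vapply(names(rates), function(id) {
          d <- cohort$clinical[cohort$clinical$subject == id, ]
          i <- which(d$time_years == max(d$time_years))
          d$msfc[i]
        }, 0)
        bc <- boxcox_shift(y5, shift = 10)
        assoc <- list(
          roi_rates = rates,
          report = correlation_with_outlier_report(rates, as.numeric(bc)),
          partial = tryCatch(
            partial_corr(rates, as.numeric(bc),
                         baseline_gm[names(rates)]),
            error = function(e) NULL))
      }
      list(slopes = slopes, progression = prog, association = assoc)
    })
  }
  tick("clinical", t0)

  res <- c(res, list(preprocessed = prep, within = within,
                     group_template = gt, mask = mask,
                     normalized = norm_smooth,
                     normalized_raw = norm_raw,
                     slope_images = slope_images,
                     roi_slope_images = roi_slope_images,
                     quadratic_images = quad_images,
                     design = design, second_level = second,
                     clinical = clinical, timings = timings))
  class(res) <- "pipeline_result"

  if (!is.null(config$out_dir))
    stage_guard("write_outputs", NULL, write_pipeline_outputs(res))
  if (verbose)
    message(sprintf("pipeline complete in %.1fs",
                    proc.time()[3] - t_all))
  res
}

write_pipeline_outputs <- function(res) {
  dir <- res$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(res$within)
  for (id in ids) {
    sd <- file.path(dir, id)
    dir.create(sd, showWarnings = FALSE)
    write_nifti(res$within[[id]]$template$template,
                file.path(sd, "template.nii"))
    write_nifti(res$within[[id]]$gm, file.path(sd, "gm.nii"))
    for (vi in seq_along(res$within[[id]]$times)) {
      write_nifti(res$within[[id]]$jacobians[[vi]],
                  file.path(sd, sprintf("jacobian_v%d.nii", vi)))
      write_nifti(res$normalized[[id]][[vi]],
                  file.path(sd, sprintf("pseudo_group_v%d.nii", vi)))
    }
    if (!is.null(res$slope_images[[id]]))
      write_nifti(res$slope_images[[id]]$volume,
                  file.path(sd, "slope.nii"))
  }
  write_nifti(res$group_template$template, file.path(dir, "group_template.nii"))
  write_nifti(res$mask, file.path(dir, "explicit_mask.nii"))
  if (!is.null(res$second_level$two_sample_slope)) {
    pr <- res$second_level$two_sample_slope
    write_nifti(pr$stat, file.path(dir, "two_sample_t.nii"))
    write_nifti(pr$enhanced, file.path(dir, "two_sample_tfce.nii"))
    write_nifti(pr$fwe_p, file.path(dir, "two_sample_fwe_p.nii"))
    write_nifti(pr$sig_mask, file.path(dir, "two_sample_sig.nii"))
  }
  if (!is.null(res$clinical))
    write.csv(res$clinical$slopes, file.path(dir, "clinical_slopes.csv"),
              row.names = FALSE)
  prov <- res$config
  prov$cohort <- NULL
  jsonlite::write_json(
    list(config = prov, timings = as.list(res$timings),
         balanced_subjects = res$group_template$balanced_subjects,
         package_version = as.character(utils::packageVersion("longvbm"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, null = "null")
  invisible(dir)
}
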