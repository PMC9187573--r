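# Orchestration: run one subject end-to-end through the imaging chain
# (ADC -> core; DSC -> maps -> relative maps -> hypoperfusion; mismatch
# ROIs; longitudinal features), and run a whole cohort into the two-arm
# comparison table. Every tunable threshold lives in one config object.

#' Pipeline run configuration
#'
#' Collects every stage configuration and every clinically meaningful
#' threshold in one serializable object; its hash is recorded in all
#' provenance output so a result can always be traced to its settings.
#'
#' @param seg A [segmentation_config()].
#' @param deconv A [deconv_config()].
#' @param acq An [acquisition_params()].
#' @param tmax_threshold Lower rTmax threshold (s, inclusive) of the
#'   hypoperfusion ROI.
#' @param n_baseline_frames Pre-bolus frames for the DSC `S0` estimate.
#' @param alpha Two-sided significance level of the group comparisons.
#' @param nihss_improvement NIHSS drop (points) defining early clinical
#'   improvement.
#' @param test_plan Variable-to-test mapping for [build_group_table()].
#' @return A `run_config` list.
#' @export
run_config <- function(seg = segmentation_config(),
                       deconv = deconv_config(),
                       acq = acquisition_params(),
                       tmax_threshold = 6,
                       n_baseline_frames = 6,
                       alpha = 0.05,
                       nihss_improvement = 4,
                       test_plan = default_test_plan()) {
  structure(list(seg = seg, deconv = deconv, acq = acq,
                 tmax_threshold = tmax_threshold,
                 n_baseline_frames = n_baseline_frames,
                 alpha = alpha, nihss_improvement = nihss_improvement,
                 test_plan = test_plan),
            class = "run_config")
}

#' MD5 hash of a run configuration
#' @param config A [run_config()].
#' @return Hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Run one subject through the full imaging chain
#'
#' ADC computation from the DWI pair, brain masking, hemisphere split, CSF
#' exclusion, perfusion deconvolution at both timepoints, contralateral
#' normalisation, infarct-core and hypoperfusion segmentation at baseline,
#' mismatch ROI construction, and per-ROI longitudinal feature extraction
#' (baseline ROIs applied at both timepoints; the synthetic timepoints
#' share one grid, so inter-timepoint registration is the identity).
#'
#' @param subject A `subject_dataset` from [synthesize_subject()], or any
#'   list with the same structure built from file inputs.
#' @param config A [run_config()].
#' @return List with `features` (one-row data.frame, clinical covariates
#'   appended), `rois`, `adc` / `adc_followup`, `brain`, `hemis`, `csf`,
#'   `maps` / `maps_followup`, `relative` / `relative_followup` and
#'   `provenance`.
#' @export
run_subject <- function(subject, config = run_config()) {
  adc_b <- compute_adc(subject$baseline$dwi_b0, subject$baseline$dwi_b1000)
  adc_f <- compute_adc(subject$followup$dwi_b0, subject$followup$dwi_b1000)
  brain <- brain_mask_from_adc(adc_b)
  hemis <- split_hemispheres(brain, subject$spec$affected_side)
  csf <- segment_csf(adc_b, brain, config$seg)
  maps_b <- compute_perfusion_maps(subject$baseline$dsc, subject$baseline$aif,
                                   brain, config$deconv,
                                   config$n_baseline_frames)
  rel_b <- relative_maps(maps_b, hemis, csf)
  maps_f <- compute_perfusion_maps(subject$followup$dsc, subject$followup$aif,
                                   brain, config$deconv,
                                   config$n_baseline_frames)
  rel_f <- relative_maps(maps_f, hemis, csf)
  core <- segment_core(adc_b, brain, config$seg)
  hypo <- segment_hypoperfusion(rel_b$rtmax, brain, config$seg,
                                threshold = config$tmax_threshold)
  rois <- derive_rois(core, hypo, hemis, csf)
  feats <- extract_subject_features(rois, rel_b, rel_f, adc_b, adc_f)
  if (!is.null(subject$clinical)) {
    feats <- cbind(subject$clinical, feats)
    feats$improved <- clinical_improvement(feats$nihss_baseline,
                                           feats$nihss_3h,
                                           config$nihss_improvement)
  }
  list(features = feats, rois = rois,
       adc = adc_b, adc_followup = adc_f,
       brain = brain, hemis = hemis, csf = csf,
       maps = maps_b, maps_followup = maps_f,
       relative = rel_b, relative_followup = rel_f,
       provenance = list(config_hash = config_hash(config),
                         seed = subject$seed))
}

#' Run a cohort end-to-end
#'
#' With `imaging = TRUE` every subject is rendered to image data with
#' [synthesize_subject()] and processed with [run_subject()]; a failing
#' subject is recorded and skipped, never aborts the cohort (partial
#' cohorts are the norm in acute stroke imaging). With `imaging = FALSE`
#' (default) the cohort's drawn feature table is used directly, which is
#' the appropriate scale for statistical calibration studies.
#'
#' @param cohort A `cohort` from [synthesize_cohort()].
#' @param config A [run_config()].
#' @param imaging Render and process image data per subject?
#' @return List with `features`, `comparisons` (from
#'   [build_group_table()]; `NULL` with a warning when an arm has fewer
#'   than 2 analysable subjects), `failures` and `provenance`.
#' @export
run_cohort <- function(cohort, config = run_config(), imaging = FALSE) {
  failures <- list()
  if (imaging) {
    if (is.null(cohort$subjects))
      stop("cohort carries no subject specifications")
    rows <- list()
    for (i in seq_along(cohort$subjects)) {
      id <- cohort$features$subject[i]
      res <- tryCatch({
        subj <- synthesize_subject(cohort$subjects[[i]],
                                   seed = (cohort$seed %% 214748L) * 10000L + i)
        r <- run_subject(subj, config)
        r$features$subject <- id
        r$features$arm <- cohort$subjects[[i]]$arm
        r$features
      }, error = function(e) {
        failures[[id]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
    if (!length(rows)) stop("all subjects failed")
    features <- do.call(rbind, rows)
  } else {
    features <- cohort$features
  }
  comparisons <- NULL
  if (min(sum(features$arm == "theophylline"),
          sum(features$arm == "control")) >= 2) {
    comparisons <- build_group_table(features, config$test_plan)
  } else {
    warning("fewer than 2 subjects per arm: statistics skipped")
  }
  list(features = features, comparisons = comparisons,
       failures = failures,
       provenance = list(config_hash = config_hash(config),
                         seed = cohort$seed,
                         n_failed = length(failures)))
}

#' Write the outputs of a subject run to a directory
#'
#' NIfTI volumes for ADC and the perfusion maps, uint8 NIfTI masks for the
#' ROIs, the features as CSV, and a JSON provenance sidecar.
#'
#' @param result Output of [run_subject()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(result$adc, file.path(dir, "adc.nii.gz"))
  for (m in c("cbf", "cbv", "mtt", "tmax")) {
    write_volume(result$maps[[m]], file.path(dir, paste0(m, ".nii.gz")))
  }
  for (r in c("core", "penumbra", "unaffected", "hypoperfusion")) {
    write_mask(result$rois[[r]], file.path(dir, paste0(r, "_mask.nii.gz")))
  }
  utils::write.csv(result$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(result$provenance, auto_unbox = TRUE),
             file.path(dir, "provenance.json"))
  invisible(dir)
}
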