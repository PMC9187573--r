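# Mismatch stage: contralateral normalisation, hypoperfusion / penumbra /
# unaffected ROI construction, per-ROI longitudinal feature extraction.

#' Mean of a map over the contralateral reference region
#'
#' The normalisation reference is the hemisphere opposite the lesion,
#' excluding CSF and invalid voxels.
#'
#' @param map A [scalar_volume()].
#' @param hemis A `hemisphere_partition` from [split_hemispheres()].
#' @param csf CSF [binary_mask()].
#' @return Scalar reference mean.
#' @export
contralateral_reference <- function(map, hemis, csf) {
  ref <- contralateral_hemisphere(hemis)$values & !csf$values
  if (!any(ref)) stop("empty contralateral reference region")
  v <- map$values[ref]
  if (all(is.na(v))) stop("contralateral reference has no valid voxels")
  mean(v, na.rm = TRUE)
}

#' Normalise a map against a reference value
#'
#' Division for the flow/volume parameters (rCBF, rCBV), subtraction for
#' the temporal parameters (rMTT, rTmax).
#'
#' @param map A [scalar_volume()].
#' @param reference Scalar reference (contralateral mean); must be positive
#'   in `"divide"` mode.
#' @param mode `"divide"` or `"subtract"`.
#' @return Relative [scalar_volume()].
#' @export
relative_map <- function(map, reference, mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  if (mode == "divide" && reference <= 0)
    stop("divide mode requires a positive reference")
  v <- if (mode == "divide") map$values / reference
       else map$values - reference
  units <- if (mode == "divide") "dimensionless" else map$units
  scalar_volume(v, map$spacing_mm, units = units)
}

#' Contralateral-normalised relative perfusion maps
#'
#' Applies the per-parameter convention: rCBF and rCBV by division, rMTT
#' and rTmax by subtraction of the contralateral (non-CSF) mean.
#'
#' @param maps A `perfusion_maps` bundle from [compute_perfusion_maps()].
#' @param hemis A `hemisphere_partition`.
#' @param csf CSF [binary_mask()].
#' @return A `relative_maps` list of [scalar_volume()]s `rcbf`, `rcbv`,
#'   `rmtt`, `rtmax`, plus the `references` used.
#' @export
relative_maps <- function(maps, hemis, csf) {
  refs <- list(cbf = contralateral_reference(maps$cbf, hemis, csf),
               cbv = contralateral_reference(maps$cbv, hemis, csf),
               mtt = contralateral_reference(maps$mtt, hemis, csf),
               tmax = contralateral_reference(maps$tmax, hemis, csf))
  structure(list(rcbf = relative_map(maps$cbf, refs$cbf, "divide"),
                 rcbv = relative_map(maps$cbv, refs$cbv, "divide"),
                 rmtt = relative_map(maps$mtt, refs$mtt, "subtract"),
                 rtmax = relative_map(maps$tmax, refs$tmax, "subtract"),
                 references = refs),
            class = "relative_maps")
}

#' Segment hypoperfused tissue on the rTmax map
#'
#' Volume growing with the inclusive rule `rtmax >= threshold` (default
#' 6 s) over the brain mask. With the contralateral Tmax close to bolus
#' arrival, thresholding the relative map matches the conventional
#' absolute Tmax > 6 s rule. An empty result is valid.
#'
#' @param rtmax rTmax [scalar_volume()] in seconds.
#' @param brain Brain [binary_mask()].
#' @param cfg A [segmentation_config()] (connectivity, minimum component).
#' @param threshold Lower Tmax threshold in seconds, inclusive.
#' @return Hypoperfusion [binary_mask()].
#' @export
segment_hypoperfusion <- function(rtmax, brain, cfg = segmentation_config(),
                                  threshold = 6) {
  pred <- !is.na(rtmax$values) & rtmax$values >= threshold & brain$values
  grow_region(rtmax, pred, cfg = cfg)
}

#' Derive the core / penumbra / unaffected tissue partition
#'
#' Set arithmetic of the perfusion-diffusion mismatch: the penumbra is the
#' hypoperfusion ROI minus the infarct core; the unaffected ROI is the
#' affected-hemisphere brain minus core and penumbra. CSF is removed from
#' all three tissue ROIs, so that core, penumbra and unaffected tissue
#' partition the affected-hemisphere brain outside CSF. Core voxels
#' outside the affected hemisphere are clipped with a warning.
#'
#' @param core Infarct core [binary_mask()] (from [segment_core()]).
#' @param hypoperfusion Hypoperfusion [binary_mask()] (from
#'   [segment_hypoperfusion()]).
#' @param hemis A `hemisphere_partition`.
#' @param csf CSF [binary_mask()].
#' @return A `tissue_rois` list with masks `core`, `penumbra`,
#'   `unaffected`, `hypoperfusion`.
#' @export
derive_rois <- function(core, hypoperfusion, hemis, csf) {
  aff <- affected_hemisphere(hemis)$values
  sp <- core$spacing_mm
  cr <- core$values & !csf$values
  if (any(cr & !aff)) {
    warning("core voxels outside the affected hemisphere were clipped")
    cr <- cr & aff
  }
  hypo <- hypoperfusion$values & aff & !csf$values
  pen <- hypo & !cr
  unaff <- aff & !cr & !pen & !csf$values
  structure(list(core = binary_mask(cr, sp),
                 penumbra = binary_mask(pen, sp),
                 unaffected = binary_mask(unaff, sp),
                 hypoperfusion = binary_mask(hypoperfusion$values, sp)),
            class = "tissue_rois")
}

#' Mean of a map over an ROI
#'
#' Arithmetic mean over the ROI voxels; invalid (`NA`) voxels are excluded
#' and counted. An empty ROI yields `NA` (reported as missing; the subject
#' is still processed).
#'
#' @param map A [scalar_volume()].
#' @param roi A [binary_mask()] on the same grid.
#' @return Scalar mean, with attribute `n_invalid` (excluded voxels).
#' @export
roi_mean <- function(map, roi) {
  stopifnot(identical(dim(map$values), dim(roi$values)))
  v <- map$values[roi$values]
  if (length(v) == 0 || all(is.na(v))) {
    return(structure(NA_real_, n_invalid = sum(is.na(v))))
  }
  structure(mean(v, na.rm = TRUE), n_invalid = sum(is.na(v)))
}

feature_params <- c("rcbf", "rcbv", "rmtt", "adc")
feature_rois <- c("core", "penumbra", "unaffected")

#' Extract per-ROI longitudinal features for one subject
#'
#' Means of rCBF, rCBV, rMTT and ADC over the baseline core, penumbra and
#' unaffected ROIs at both timepoints, their follow-up-minus-baseline
#' deltas, and ROI volumes in mL. The baseline ROIs are applied unchanged
#' to the follow-up maps (tissue fate is tracked in the regions defined at
#' presentation; ROIs are never re-segmented at follow-up). ADC features
#' are reported in units of 1e-6 mm^2/s, the scale conventional in stroke
#' imaging tables.
#'
#' @param rois Baseline `tissue_rois` from [derive_rois()].
#' @param rel_baseline,rel_followup `relative_maps` bundles for the two
#'   timepoints, on the baseline grid.
#' @param adc_baseline,adc_followup ADC [scalar_volume()]s (mm^2/s).
#' @return One-row `data.frame` with columns
#'   `<roi>_<param>_<baseline|followup|delta>` and `<roi>_volume_ml`.
#' @export
extract_subject_features <- function(rois, rel_baseline, rel_followup,
                                     adc_baseline, adc_followup) {
  grids_ok <- identical(dim(adc_baseline$values), dim(adc_followup$values)) &&
    identical(dim(adc_baseline$values), dim(rois$core$values))
  if (!grids_ok) stop("follow-up maps must live on the baseline grid")
  pick <- function(bundle, adc, param) {
    if (param == "adc") adc else bundle[[param]]
  }
  out <- list()
  for (roi in feature_rois) {
    m <- rois[[roi]]
    for (param in feature_params) {
      scale <- if (param == "adc") 1e6 else 1
      b <- as.numeric(roi_mean(pick(rel_baseline, adc_baseline, param), m)) * scale
      f <- as.numeric(roi_mean(pick(rel_followup, adc_followup, param), m)) * scale
      out[[paste(roi, param, "baseline", sep = "_")]] <- b
      out[[paste(roi, param, "followup", sep = "_")]] <- f
      out[[paste(roi, param, "delta", sep = "_")]] <- f - b
    }
    out[[paste0(roi, "_volume_ml")]] <- mask_volume_ml(m)
  }
  as.data.frame(out)
}
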