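# Diffusion stage: ADC mapping, CSF exclusion, volume-growing core
# segmentation.

#' Segmentation configuration
#'
#' Thresholds and connectivity rules used by the diffusion and mismatch
#' segmentation stages.
#'
#' @param adc_core_upper Upper ADC threshold (mm^2/s) for the infarct core;
#'   the conservative default 550e-6 keeps penumbral tissue out of the core.
#' @param adc_csf_lower Lower ADC threshold (mm^2/s) above which a brain
#'   voxel is labelled CSF.
#' @param connectivity Neighbourhood for region growing: 6 (faces) or 26
#'   (faces, edges, corners).
#' @param min_component_voxels Connected components smaller than this are
#'   discarded, suppressing isolated noise voxels.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(adc_core_upper = 550e-6,
                                adc_csf_lower = 2000e-6,
                                connectivity = 26,
                                min_component_voxels = 5) {
  if (!(adc_core_upper > 0 && adc_core_upper < adc_csf_lower))
    stop("need 0 < adc_core_upper < adc_csf_lower")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  structure(list(adc_core_upper = adc_core_upper,
                 adc_csf_lower = adc_csf_lower,
                 connectivity = as.integer(connectivity),
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "segmentation_config")
}

#' Apparent diffusion coefficient from a DWI pair
#'
#' Computes `adc = ln(b0 / b1000) / b` voxelwise from the two diffusion
#' weightings. Voxels where the diffusion-weighted signal is not attenuated
#' (`b1000 >= b0`) are clamped to 0; voxels with non-positive signal in
#' either weighting are invalid (`NA`).
#'
#' @param b0,b1000 [scalar_volume()]s of the unweighted and
#'   diffusion-weighted signal on one grid.
#' @param b Diffusion weighting difference in s/mm^2 (default 1000).
#' @return ADC [scalar_volume()] in mm^2/s.
#' @export
compute_adc <- function(b0, b1000, b = 1000) {
  if (!same_grid(b0, b1000)) stop("b0 and b1000 grids differ")
  if (b <= 0) stop("b must be positive")
  s0 <- b0$values
  s1 <- b1000$values
  adc <- array(NA_real_, dim(s0))
  ok <- !is.na(s0) & !is.na(s1) & s0 > 0 & s1 > 0
  adc[ok] <- log(s0[ok] / s1[ok]) / b
  adc[ok & s1 >= s0] <- 0
  scalar_volume(adc, spacing_mm = b0$spacing_mm, units = "mm^2/s")
}

#' Segment cerebrospinal fluid on an ADC map
#'
#' CSF has a much higher apparent diffusion than parenchyma; brain voxels
#' with `adc > adc_csf_lower` are labelled CSF. CSF is excluded from the
#' contralateral normalisation reference and from the unaffected-tissue ROI.
#'
#' @param adc ADC [scalar_volume()].
#' @param brain Brain [binary_mask()].
#' @param cfg A [segmentation_config()].
#' @return CSF [binary_mask()].
#' @export
segment_csf <- function(adc, brain, cfg = segmentation_config()) {
  v <- adc$values
  m <- brain$values & !is.na(v) & v > cfg$adc_csf_lower
  binary_mask(m, spacing_mm = adc$spacing_mm)
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

#' Label connected components of a logical array
#'
#' Breadth-first flood fill over the chosen neighbourhood.
#'
#' @param mask 3D logical array (`NA` treated as `FALSE`).
#' @param connectivity 6 or 26.
#' @return Integer array of component labels; 0 outside the mask.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as.array(mask)
  mask[is.na(mask)] <- FALSE
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- neighbor_offsets(connectivity)
  todo <- which(mask)
  cur <- 0L
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    frontier <- start
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nb <- co[rep(seq_len(nrow(co)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(co)), , drop = FALSE]
      inb <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
             nb[, 2] >= 1 & nb[, 2] <= d[2] &
             nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[inb, , drop = FALSE]
      li <- unique(nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L))
      li <- li[mask[li] & lab[li] == 0L]
      lab[li] <- cur
      frontier <- li
    }
  }
  lab
}

#' Volume growing over a threshold predicate
#'
#' Grows regions of predicate-satisfying voxels from seed voxels through the
#' configured neighbourhood; components smaller than
#' `cfg$min_component_voxels` are dropped. With `seeds = NULL` every
#' qualifying voxel seeds itself, turning the interactive workflow into a
#' deterministic one while honouring the same threshold rule.
#'
#' @param volume A [scalar_volume()].
#' @param predicate Function mapping the value array to a logical array, or
#'   a precomputed logical array; `NA` counts as `FALSE`.
#' @param seeds Optional n x 3 matrix of 1-based voxel indices; each seed
#'   must satisfy the predicate.
#' @param cfg A [segmentation_config()].
#' @return Grown [binary_mask()].
#' @export
grow_region <- function(volume, predicate, seeds = NULL,
                        cfg = segmentation_config()) {
  pred <- if (is.function(predicate)) predicate(volume$values) else predicate
  pred <- as.array(pred)
  pred[is.na(pred)] <- FALSE
  stopifnot(identical(dim(pred), dim(volume$values)))
  lab <- label_components(pred, cfg$connectivity)
  keep <- which(tabulate(lab) >= cfg$min_component_voxels)
  if (!is.null(seeds)) {
    seeds <- matrix(as.integer(seeds), ncol = 3)
    sl <- seeds[, 1] + dim(pred)[1] * (seeds[, 2] - 1L) +
      dim(pred)[1] * dim(pred)[2] * (seeds[, 3] - 1L)
    if (!all(pred[sl])) stop("seed voxel violates the predicate")
    keep <- intersect(keep, unique(lab[sl]))
  }
  out <- array(lab != 0L & lab %in% keep, dim(pred))
  binary_mask(out, spacing_mm = volume$spacing_mm)
}

#' Segment the infarct core on an ADC map
#'
#' Volume growing with the rule `0 < adc <= adc_core_upper`, restricted to
#' the brain mask. An empty core (no voxel below the threshold) is a valid
#' result, not an error.
#'
#' @param adc ADC [scalar_volume()] in mm^2/s.
#' @param brain Brain [binary_mask()].
#' @param cfg A [segmentation_config()].
#' @param seeds Optional seed voxels (n x 3 indices) for parity with a
#'   semi-automatic workflow; default grows from every qualifying voxel.
#' @return Infarct core [binary_mask()].
#' @export
segment_core <- function(adc, brain, cfg = segmentation_config(),
                         seeds = NULL) {
  pred <- !is.na(adc$values) & adc$values > 0 &
    adc$values <= cfg$adc_core_upper & brain$values
  grow_region(adc, pred, seeds = seeds, cfg = cfg)
}
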