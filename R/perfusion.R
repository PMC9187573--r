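# Perfusion quantification: DSC signal to concentration, block-circulant
# truncated-SVD deconvolution, and CBF/CBV/MTT/Tmax parameter maps.

#' Deconvolution configuration
#'
#' @param svd_threshold Truncation threshold as a fraction of the largest
#'   singular value of the circulant AIF matrix; singular values below
#'   `svd_threshold * sigma_max` are zeroed. Default 0.15.
#' @param pad_factor Zero-padding factor (>= 2) of the circulant system;
#'   padding to `pad_factor * n` makes the deconvolution delay-insensitive.
#' @param cbv_area_rule Quadrature for the area ratio; `"trapezoid"`.
#' @param mtt_rule `"central_volume"`: MTT = CBV/CBF, robust under
#'   truncation oscillations of the residue estimate.
#' @return A `deconv_config` list.
#' @export
deconv_config <- function(svd_threshold = 0.15, pad_factor = 2,
                          cbv_area_rule = "trapezoid",
                          mtt_rule = "central_volume") {
  if (!(svd_threshold > 0 && svd_threshold < 1))
    stop("svd_threshold must be in (0, 1)")
  if (pad_factor < 2) stop("pad_factor must be >= 2")
  cbv_area_rule <- match.arg(cbv_area_rule, "trapezoid")
  mtt_rule <- match.arg(mtt_rule, "central_volume")
  structure(list(svd_threshold = svd_threshold,
                 pad_factor = as.integer(pad_factor),
                 cbv_area_rule = cbv_area_rule, mtt_rule = mtt_rule),
            class = "deconv_config")
}

#' Convert a DSC signal series to contrast concentration
#'
#' `C(t) = -ln(S(t)/S0) / (k * TE)`, with the pre-bolus baseline `S0`
#' estimated voxelwise as the mean of the first `n_baseline_frames` frames.
#' Voxels with non-positive signal anywhere (background, signal voids) are
#' flagged invalid (`NA` over the whole curve), never silently zeroed.
#'
#' @param series A [dynamic_series()].
#' @param n_baseline_frames Number of pre-bolus frames (>= 3) used for the
#'   `S0` estimate.
#' @return List with `conc` (4D concentration array, `NA` rows for invalid
#'   voxels) and `s0` (3D baseline-signal array).
#' @export
signal_to_concentration <- function(series, n_baseline_frames = 6) {
  if (n_baseline_frames < 3) stop("n_baseline_frames must be >= 3")
  p <- series$params
  sig <- series$signal
  d <- dim(sig)
  nvox <- prod(d[1:3])
  smat <- matrix(sig, nvox, d[4])
  s0 <- rowMeans(smat[, seq_len(n_baseline_frames), drop = FALSE])
  valid <- s0 > 0 & apply(smat > 0, 1, all)
  cmat <- matrix(NA_real_, nvox, d[4])
  cmat[valid, ] <- -log(smat[valid, , drop = FALSE] / s0[valid]) /
    (p$k_conversion * p$te_s)
  list(conc = array(cmat, d), s0 = array(s0, d[1:3]))
}

#' Block-circulant truncated-SVD deconvolution operator
#'
#' Builds the circulant convolution matrix of the zero-padded AIF (scaled
#' by TR) and its truncated-SVD pseudo-inverse. The operator is the same
#' for every voxel sharing the AIF, so it is computed once and reused.
#'
#' @param aif A [concentration_curve()] with positive area.
#' @param cfg A [deconv_config()].
#' @return List with the padded length `L`, original length `n`, the
#'   forward matrix `A`, the pseudo-inverse `pinv`, and the singular values.
#' @export
deconv_operator <- function(aif, cfg = deconv_config()) {
  n <- length(aif$values)
  if (curve_area(aif$values, aif$tr_s) <= 0) stop("AIF area must be positive")
  L <- cfg$pad_factor * n
  a <- c(aif$values, numeric(L - n)) * aif$tr_s
  i <- matrix(seq_len(L), L, L)
  A <- matrix(a[((i - t(i)) %% L) + 1L], L, L)
  s <- svd(A)
  keep <- s$d >= cfg$svd_threshold * s$d[1]
  if (!any(keep)) stop("all singular values below the truncation cutoff")
  dinv <- ifelse(keep, 1 / s$d, 0)
  pinv <- s$v %*% (t(s$u) * dinv)
  list(L = L, n = n, tr_s = aif$tr_s, A = A, pinv = pinv,
       singular_values = s$d, kept = keep)
}

#' Deconvolve one tissue curve against the AIF
#'
#' Solves the circulant convolution system `A k = C` for the scaled residue
#' function `k(t) = CBF * R(t)` by truncated SVD, zeroing singular values
#' below `svd_threshold * sigma_max`. Curves are zero-padded to
#' `pad_factor * n`, which makes the estimate insensitive to bolus delay
#' (delayed arrivals wrap instead of being clipped).
#'
#' @param C_voxel Tissue concentration curve (length n numeric).
#' @param aif A [concentration_curve()] on the same time grid.
#' @param cfg A [deconv_config()].
#' @param op Optional precomputed [deconv_operator()] for `aif`/`cfg`.
#' @return Numeric `k(t)` of padded length `pad_factor * n`.
#' @export
deconvolve_svd_circulant <- function(C_voxel, aif, cfg = deconv_config(),
                                     op = NULL) {
  if (is.null(op)) op <- deconv_operator(aif, cfg)
  if (length(C_voxel) != op$n) stop("curve length does not match the AIF")
  drop(op$pinv %*% c(C_voxel, numeric(op$L - op$n)))
}

#' Perfusion parameters from a deconvolved residue curve
#'
#' `CBF = max_t k(t)` (floored at 0), `Tmax = TR * argmax_t k(t)`,
#' `CBV = area(C)/area(AIF)` by trapezoidal quadrature, and
#' `MTT = CBV/CBF` by the central volume theorem. Negative `k` samples are
#' retained when locating the maximum. A vanishing CBF leaves MTT
#' undefined (`NA`).
#'
#' @param k Deconvolved curve from [deconvolve_svd_circulant()].
#' @param C Tissue concentration curve (length n).
#' @param aif A [concentration_curve()].
#' @param cfg A [deconv_config()].
#' @return List with `cbf`, `cbv`, `mtt` (s) and `tmax` (s).
#' @export
perfusion_parameters <- function(k, C, aif, cfg = deconv_config()) {
  area_aif <- curve_area(aif$values, aif$tr_s)
  if (area_aif <= 0) stop("zero AIF area")
  imax <- which.max(k)
  cbf <- max(k[imax], 0)
  cbv <- curve_area(C, aif$tr_s) / area_aif
  mtt <- if (cbf > 0) cbv / cbf else NA_real_
  list(cbf = cbf, cbv = cbv, mtt = mtt, tmax = (imax - 1) * aif$tr_s)
}

#' Compute CBF/CBV/MTT/Tmax maps over a brain mask
#'
#' Applies [signal_to_concentration()], the shared block-circulant
#' deconvolution operator and [perfusion_parameters()] to every brain
#' voxel. Per-voxel failures (non-positive signal) are flagged invalid in
#' the output maps; they never abort the volume.
#'
#' @param series A [dynamic_series()].
#' @param aif A [concentration_curve()] on the series' time grid.
#' @param brain Brain [binary_mask()].
#' @param cfg A [deconv_config()].
#' @param n_baseline_frames Pre-bolus frames for the `S0` estimate.
#' @return A `perfusion_maps` list of [scalar_volume()]s `cbf`, `cbv`,
#'   `mtt` (s) and `tmax` (s), `NA` outside the brain and at invalid
#'   voxels.
#' @export
compute_perfusion_maps <- function(series, aif, brain,
                                   cfg = deconv_config(),
                                   n_baseline_frames = 6) {
  d <- dim(series$signal)
  stopifnot(identical(d[1:3], dim(brain$values)))
  sc <- signal_to_concentration(series, n_baseline_frames)
  nvox <- prod(d[1:3])
  cmat <- matrix(sc$conc, nvox, d[4])
  idx <- which(brain$values)
  ok <- idx[!is.na(cmat[idx, 1])]
  op <- deconv_operator(aif, cfg)
  Cs <- t(cmat[ok, , drop = FALSE])            # n x nvox
  K <- op$pinv %*% rbind(Cs, matrix(0, op$L - op$n, length(ok)))
  imax <- max.col(t(K), ties.method = "first")
  cbf <- pmax(K[cbind(imax, seq_along(ok))], 0)
  w <- rep(aif$tr_s, op$n)
  w[c(1, op$n)] <- aif$tr_s / 2                # trapezoid weights
  cbv <- as.numeric(w %*% Cs) / curve_area(aif$values, aif$tr_s)
  mtt <- ifelse(cbf > 0, cbv / cbf, NA_real_)
  tmax <- (imax - 1) * aif$tr_s
  blank <- array(NA_real_, d[1:3])
  mk <- function(x, units) {
    v <- blank
    v[ok] <- x
    scalar_volume(v, series$spacing_mm, units = units)
  }
  structure(list(cbf = mk(cbf, "a.u."), cbv = mk(cbv, "dimensionless"),
                 mtt = mk(mtt, "s"), tmax = mk(tmax, "s")),
            class = "perfusion_maps")
}
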