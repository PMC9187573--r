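# Forward DSC / DWI signal models used by the digital phantom and inverted
# by the perfusion stage. Indicator-dilution theory: the tissue
# concentration is C(t) = CBF * (AIF (*) R)(t - delay), with residue
# function R(0) = 1, nonincreasing, integral R = MTT, so that
# area(C)/area(AIF) = CBF * MTT = CBV (central volume theorem).

#' DSC/DWI acquisition parameters
#'
#' @param tr_s Sampling interval of the dynamic series in seconds.
#' @param te_s Echo time in seconds.
#' @param n_timepoints Number of dynamic frames (>= 20); `tr_s *
#'   n_timepoints` must cover the full bolus passage.
#' @param b_values DWI b-values in s/mm^2, default `c(0, 1000)`.
#' @param k_conversion Proportionality constant of the signal-to-
#'   concentration model; it cancels in all contralateral-normalised maps
#'   and defaults to 1.
#' @return An `acquisition_params` list.
#' @export
acquisition_params <- function(tr_s = 1.5, te_s = 0.03, n_timepoints = 60,
                               b_values = c(0, 1000), k_conversion = 1) {
  if (tr_s <= 0 || te_s <= 0 || k_conversion <= 0)
    stop("tr_s, te_s and k_conversion must be positive")
  if (n_timepoints < 20) stop("n_timepoints must be >= 20")
  if (any(b_values < 0)) stop("b-values must be nonnegative")
  structure(list(tr_s = tr_s, te_s = te_s,
                 n_timepoints = as.integer(n_timepoints),
                 b_values = b_values, k_conversion = k_conversion),
            class = "acquisition_params")
}

#' Time grid of an acquisition
#' @param params An [acquisition_params()].
#' @return Numeric vector `0, tr_s, ..., (n-1)*tr_s` in seconds.
#' @export
time_grid <- function(params) (seq_len(params$n_timepoints) - 1) * params$tr_s

#' Construct a concentration curve
#'
#' @param values Nonnegative concentrations sampled on the series' time
#'   grid (arbitrary units).
#' @param tr_s Sampling interval in seconds.
#' @return A `concentration_curve` with elements `values` and `tr_s`.
#' @export
concentration_curve <- function(values, tr_s) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("concentration values must be finite and nonnegative")
  if (curve_area(values, tr_s) <= 0) stop("curve area must be positive")
  structure(list(values = values, tr_s = tr_s), class = "concentration_curve")
}

# trapezoidal area of a regularly sampled curve
curve_area <- function(values, tr_s) {
  if (length(values) < 2) return(0)
  pracma::trapz(seq_along(values), values) * tr_s
}

#' Construct a 4D dynamic susceptibility contrast series
#'
#' @param signal 4D array (x, y, z, t) of MR signal; positive inside the
#'   brain, 0 in background.
#' @param params An [acquisition_params()].
#' @param spacing_mm Voxel spacing in mm.
#' @return A `dynamic_series`.
#' @export
dynamic_series <- function(signal, params, spacing_mm = c(1, 1, 1)) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L) stop("'signal' must be a 4D array")
  if (dim(signal)[4] != params$n_timepoints)
    stop("4th dimension must equal params$n_timepoints")
  structure(list(signal = signal, params = params,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "dynamic_series")
}

#' Read a 4D NIfTI file as a dynamic series
#' @param path Path to a 4D NIfTI file.
#' @param params An [acquisition_params()] describing the acquisition.
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(path, params) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4D series")
  dynamic_series(as.array(img), params,
                 spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Gamma-variate arterial input function
#'
#' Standard bolus model `c(t) = amplitude * (t - t0)^alpha *
#' exp(-(t - t0)/beta)` for `t > t0`, 0 before, sampled at the series TR.
#' It stands in for a manually identified arterial curve. The analytic area
#' is `amplitude * beta^(alpha+1) * Gamma(alpha+1)`; if the sampled window
#' truncates more than 5% of it the series is too short and an error is
#' raised.
#'
#' @param params An [acquisition_params()].
#' @param t0 Bolus arrival time in s (>= 0); the default leaves six clean pre-bolus frames at TR 1.5 s.
#' @param alpha Shape parameter (> 0); peak at `t0 + alpha*beta`.
#' @param beta Scale parameter in s (> 0).
#' @param amplitude Peak scaling (> 0), arbitrary concentration units.
#' @return A [concentration_curve()].
#' @export
gamma_variate_aif <- function(params, t0 = 10, alpha = 3, beta = 1,
                              amplitude = 1) {
  if (alpha <= 0 || beta <= 0 || t0 < 0)
    stop("need alpha > 0, beta > 0, t0 >= 0")
  t <- time_grid(params)
  u <- pmax(t - t0, 0)
  v <- amplitude * u^alpha * exp(-u / beta)
  analytic <- amplitude * beta^(alpha + 1) * gamma(alpha + 1)
  if (curve_area(v, params$tr_s) < 0.95 * analytic)
    stop("series too short: >5% of the analytic bolus area is truncated")
  concentration_curve(v, params$tr_s)
}

#' Tissue residue function sampled on a time grid
#'
#' `R(0) = 1`, nonincreasing, with integral equal to the mean transit time:
#' exponential `exp(-t/mtt)` or boxcar (1 for `t < mtt`).
#'
#' @param model `"exponential"` or `"boxcar"`.
#' @param mtt Mean transit time in seconds; must be at least one TR to be
#'   resolvable on the grid.
#' @param params An [acquisition_params()].
#' @return Numeric vector over the series' time grid.
#' @export
residue_curve <- function(model = c("exponential", "boxcar"), mtt, params) {
  model <- match.arg(model)
  if (mtt < params$tr_s)
    stop("mtt below the temporal resolution (TR) is unresolvable")
  residue_at(model, mtt, time_grid(params))
}

residue_at <- function(model, mtt, t) {
  switch(model,
         exponential = exp(-t / mtt),
         boxcar = as.numeric(t < mtt))
}

#' Forward tissue concentration curve
#'
#' Convolves the AIF with a scaled residue function and applies a bolus
#' delay: `C(t) = cbf * (AIF (*) R)(t - delay)`. The convolution is carried
#' out on a fine grid (`tr_s / oversample`) and resampled to the series TR,
#' so that the discrete area ratio `area(C)/area(AIF)` matches `cbf * mtt =
#' cbv` to well within 2%. The delay must be an integer multiple of TR so
#' that the ground-truth Tmax is grid-exact.
#'
#' @param cbf Flow scale (>= 0; units 1/s on the relative scale used here).
#' @param mtt Mean transit time in s.
#' @param delay Bolus delay in s, an integer multiple of `params$tr_s`.
#' @param aif A [concentration_curve()].
#' @param model Residue model, `"exponential"` or `"boxcar"`.
#' @param params An [acquisition_params()].
#' @param oversample Fine-grid refinement factor for the convolution.
#' @return Numeric concentration curve on the series' time grid.
#' @export
tissue_concentration <- function(cbf, mtt, delay, aif,
                                 model = "exponential", params,
                                 oversample = 20) {
  if (cbf < 0) stop("negative cbf")
  m <- delay / params$tr_s
  if (abs(m - round(m)) > 1e-9)
    stop("delay must be an integer multiple of TR")
  m <- as.integer(round(m))
  n <- params$n_timepoints
  if (cbf == 0) return(numeric(n))
  dt <- params$tr_s / oversample
  tf <- seq(0, (n - 1) * params$tr_s, by = dt)
  aif_f <- stats::approx(time_grid(params), aif$values, xout = tf,
                         rule = 2)$y
  r_f <- residue_at(model, mtt, tf)
  conv <- stats::convolve(aif_f, rev(r_f), type = "open")[seq_along(tf)]
  cf <- cbf * dt * conv
  if (m > 0) cf <- c(numeric(m * oversample), cf)[seq_along(tf)]
  cf[seq(1, by = oversample, length.out = n)]
}

#' DSC signal from a concentration curve
#'
#' Standard susceptibility model `S(t) = s0 * exp(-k * TE * C(t))`; its
#' inverse lives in [signal_to_concentration()].
#'
#' @param C Concentration curve (numeric vector or array).
#' @param s0 Pre-bolus baseline signal (> 0); scalar or array conformable
#'   with `C`.
#' @param params An [acquisition_params()].
#' @return Signal with the shape of `C`.
#' @export
concentration_to_signal <- function(C, s0, params) {
  if (any(s0 <= 0)) stop("s0 must be positive")
  s0 * exp(-params$k_conversion * params$te_s * C)
}

#' Synthesize a DWI pair from a ground-truth ADC map
#'
#' `b1000 = b0 * exp(-b * adc)` voxelwise, with optional Rician noise at a
#' stated signal-to-noise ratio (`sigma = s0_b0 / snr` on both channels).
#' Background (invalid ADC) voxels get zero signal.
#'
#' @param adc Ground-truth ADC [scalar_volume()] in mm^2/s.
#' @param s0_b0 Unweighted signal level in the object.
#' @param params An [acquisition_params()] (supplies the b-values).
#' @param snr Signal-to-noise ratio on the b0 image; `Inf` (default)
#'   disables noise.
#' @return List with [scalar_volume()]s `b0` and `b1000`.
#' @export
synthesize_dwi <- function(adc, s0_b0 = 1000, params = acquisition_params(),
                           snr = Inf) {
  if (any(adc$values < 0, na.rm = TRUE)) stop("adc must be nonnegative")
  b <- max(params$b_values)
  fg <- !is.na(adc$values)
  b0 <- array(0, dim(adc$values))
  b0[fg] <- s0_b0
  b1000 <- array(0, dim(adc$values))
  b1000[fg] <- s0_b0 * exp(-b * adc$values[fg])
  if (is.finite(snr)) {
    sigma <- s0_b0 / snr
    b0 <- rician(b0, sigma)
    b1000 <- rician(b1000, sigma)
  }
  list(b0 = scalar_volume(b0, adc$spacing_mm, units = "a.u."),
       b1000 = scalar_volume(b1000, adc$spacing_mm, units = "a.u."))
}

rician <- function(x, sigma) {
  n <- length(x)
  sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}
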