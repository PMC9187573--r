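# Digital stroke phantom: DWI + DSC datasets with known hemodynamic ground
# truth, and a two-arm cohort simulator matching the study design
# (13 active vs 11 control subjects, two imaging timepoints 3 h apart).

#' Phantom specification
#'
#' Geometry and hemodynamic levels of a digital stroke subject. The brain
#' is a head-centred ellipsoid; the infarct core and penumbra are nested
#' spheres in the affected hemisphere; two symmetric periventricular boxes
#' model CSF. Default tissue levels (relative CBV scale, unaffected = 1):
#' unaffected `cbv 1.0, mtt 4 s, delay 0`; penumbra `cbv 1.1, mtt 8 s,
#' delay 7.5 s` (Tmax surrogate beyond the 6 s hypoperfusion threshold);
#' core `cbv 0.9, mtt 7.2 s, delay 9 s` (i.e. CBF halved relative to
#' unaffected tissue) with ADC 450e-6 mm^2/s, below the 550e-6 core
#' threshold. CBF is always derived as `cbv/mtt`, so the central volume
#' theorem holds exactly in every ground truth. Delays are integer
#' multiples of TR, making the true Tmax grid-exact.
#'
#' @param dim Grid extents (x = left-right first).
#' @param spacing_mm Voxel spacing in mm.
#' @param affected_side `"left"` or `"right"`.
#' @param core_radius,penumbra_radius Lesion radii in voxels (penumbra
#'   sphere encloses the core sphere).
#' @param levels Named list of tissue levels, each with `cbv`, `mtt` (s),
#'   `delay` (s) and `adc` (mm^2/s); names `unaffected`, `penumbra`,
#'   `core`, `csf`.
#' @param arm Treatment arm, `"theophylline"` or `"control"`; selects the
#'   default follow-up effect sizes.
#' @param deltas Optional per-subject follow-up changes as a data.frame
#'   with columns `roi`, `param`, `delta` (defaults to the arm means of
#'   [effect_table_default()]).
#' @param recanalized Logical; if `TRUE` the follow-up delay is reset to 0
#'   and MTT to the unaffected level (reperfusion).
#' @param dwi_snr DWI signal-to-noise ratio; `Inf` disables noise.
#' @param conc_noise_sd SD of additive Gaussian noise on the tissue
#'   concentration curves; 0 disables noise.
#' @param params An [acquisition_params()].
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(32, 32, 16), spacing_mm = c(2, 2, 4),
                         affected_side = "left",
                         core_radius = 3, penumbra_radius = 5.5,
                         levels = phantom_levels_default(),
                         arm = "theophylline", deltas = NULL,
                         recanalized = FALSE,
                         dwi_snr = Inf, conc_noise_sd = 0,
                         params = acquisition_params()) {
  if (penumbra_radius <= core_radius)
    stop("penumbra_radius must exceed core_radius")
  structure(list(dim = as.integer(dim), spacing_mm = spacing_mm,
                 affected_side = affected_side,
                 core_radius = core_radius,
                 penumbra_radius = penumbra_radius,
                 levels = levels, arm = arm, deltas = deltas,
                 recanalized = recanalized, dwi_snr = dwi_snr,
                 conc_noise_sd = conc_noise_sd, params = params),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
phantom_levels_default <- function() {
  list(unaffected = list(cbv = 1.0, mtt = 4.0, delay = 0.0, adc = 820e-6),
       penumbra   = list(cbv = 1.1, mtt = 8.0, delay = 7.5, adc = 800e-6),
       core       = list(cbv = 0.9, mtt = 7.2, delay = 9.0, adc = 450e-6),
       csf        = list(cbv = 1.0, mtt = 4.0, delay = 0.0, adc = 3000e-6))
}

sphere_mask <- function(d, center, radius) {
  x <- slice.index(array(0, d), 1)
  y <- slice.index(array(0, d), 2)
  z <- slice.index(array(0, d), 3)
  (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= radius^2
}

#' Ground-truth maps and masks of a phantom subject
#'
#' Builds the tissue-class geometry and the piecewise-constant hemodynamic
#' and ADC ground truth for one timepoint. `cbf = cbv/mtt` voxelwise by
#' construction.
#'
#' @param spec A [phantom_spec()].
#' @param timepoint `"baseline"` or `"followup"`; the follow-up truth
#'   applies the arm-dependent deltas (and reperfusion when
#'   `spec$recanalized`) to the hemodynamic levels, leaving the geometry
#'   unchanged.
#' @return A `ground_truth` list: scalar volumes `cbf`, `cbv`, `mtt`,
#'   `delay`, `adc`; masks `core_mask`, `penumbra_mask`, `csf_mask`,
#'   `brain_mask`; the integer `class` array (0 background, 1 unaffected,
#'   2 penumbra, 3 core, 4 csf) and the `levels` used.
#' @export
synthesize_truth <- function(spec, timepoint = c("baseline", "followup")) {
  timepoint <- match.arg(timepoint)
  d <- spec$dim
  sp <- spec$spacing_mm
  center <- (d + 1) / 2
  semi <- (d - 4) / 2
  x <- slice.index(array(0, d), 1)
  y <- slice.index(array(0, d), 2)
  z <- slice.index(array(0, d), 3)
  brain <- ((x - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 +
    ((z - center[3]) / semi[3])^2 <= 1
  nx_left <- ceiling(d[1] / 2)
  csf <- brain &
    ((x >= nx_left - 2 & x <= nx_left) | (x >= nx_left + 1 & x <= nx_left + 3)) &
    abs(y - center[2]) <= 3 & abs(z - center[3]) <= 2
  lx <- if (spec$affected_side == "left") round(center[1] - d[1] / 4)
        else round(center[1] + d[1] / 4)
  lesion_center <- c(lx, round(center[2]), round(center[3]))
  core <- sphere_mask(d, lesion_center, spec$core_radius) & brain & !csf
  pen <- sphere_mask(d, lesion_center, spec$penumbra_radius) & brain &
    !csf & !core
  aff <- if (spec$affected_side == "left") x <= nx_left else x > nx_left
  if (any((core | pen) & !aff)) stop("lesion exceeds the affected hemisphere")

  lv <- spec$levels
  if (timepoint == "followup") lv <- followup_levels(spec)
  cls <- array(0L, d)
  cls[brain] <- 1L
  cls[pen] <- 2L
  cls[core] <- 3L
  cls[csf] <- 4L
  fill <- function(field) {
    v <- array(NA_real_, d)
    for (i in seq_along(class_names)) {
      v[cls == i] <- lv[[class_names[i]]][[field]]
    }
    v
  }
  cbv <- fill("cbv")
  mtt <- fill("mtt")
  truth <- list(
    cbf = scalar_volume(cbv / mtt, sp, "1/s"),
    cbv = scalar_volume(cbv, sp, "dimensionless"),
    mtt = scalar_volume(mtt, sp, "s"),
    delay = scalar_volume(fill("delay"), sp, "s"),
    adc = scalar_volume(fill("adc"), sp, "mm^2/s"),
    core_mask = binary_mask(core, sp),
    penumbra_mask = binary_mask(pen, sp),
    csf_mask = binary_mask(csf, sp),
    brain_mask = binary_mask(brain, sp),
    class = cls, levels = lv,
    residue_model = "exponential")
  class(truth) <- "ground_truth"
  truth
}

class_names <- c("unaffected", "penumbra", "core", "csf")

# Follow-up tissue levels. Deltas are configured on the reported relative
# scale (rCBV ratio, rMTT difference, ADC in 1e-6 mm^2/s), so lesion levels
# are set relative to the *follow-up* unaffected (reference) level: the
# extracted relative change then equals the configured delta. CBF always
# follows from the central volume theorem. Recanalized subjects have the
# lesion delay reset to 0 and MTT to the unaffected level (reperfusion).
followup_levels <- function(spec) {
  lv0 <- spec$levels
  lv <- lv0
  del <- spec$deltas
  if (is.null(del)) del <- arm_mean_deltas(spec$arm)
  g <- function(roi, param) {
    r <- del$delta[del$roi == roi & del$param == param]
    if (length(r) != 1) stop("deltas must have one row per roi x param")
    r
  }
  mtt_floor <- spec$params$tr_s + 0.5
  lv$unaffected$cbv <- max(lv0$unaffected$cbv + g("unaffected", "rcbv"), 0.05)
  lv$unaffected$mtt <- max(lv0$unaffected$mtt + g("unaffected", "rmtt"),
                           mtt_floor)
  lv$unaffected$adc <- max(lv0$unaffected$adc + g("unaffected", "adc") * 1e-6,
                           100e-6)
  for (roi in c("core", "penumbra")) {
    rcbv0 <- lv0[[roi]]$cbv / lv0$unaffected$cbv
    lv[[roi]]$cbv <- max((rcbv0 + g(roi, "rcbv")) * lv$unaffected$cbv, 0.05)
    lv[[roi]]$adc <- max(lv0[[roi]]$adc + g(roi, "adc") * 1e-6, 100e-6)
    if (spec$recanalized) {
      lv[[roi]]$mtt <- lv$unaffected$mtt
      lv[[roi]]$delay <- 0
    } else {
      rmtt0 <- lv0[[roi]]$mtt - lv0$unaffected$mtt
      lv[[roi]]$mtt <- max(lv$unaffected$mtt + rmtt0 + g(roi, "rmtt"),
                           mtt_floor)
    }
  }
  lv$csf$cbv <- lv$unaffected$cbv
  lv$csf$mtt <- lv$unaffected$mtt
  lv
}

arm_mean_deltas <- function(arm) {
  et <- effect_table_default()
  et <- et[et$arm == arm & et$param != "rcbf", ]
  data.frame(roi = et$roi, param = et$param, delta = et$delta_mean)
}

#' Synthesize the DSC series of one timepoint
#'
#' Tissue curves are generated per tissue class with the forward model
#' [tissue_concentration()], converted to signal with
#' [concentration_to_signal()] (baseline signal `s0`), with optional
#' Gaussian noise on the concentration curves. Background voxels carry
#' zero signal.
#'
#' @param truth A `ground_truth` from [synthesize_truth()].
#' @param aif A [concentration_curve()].
#' @param params An [acquisition_params()].
#' @param s0 Pre-bolus tissue signal level.
#' @param conc_noise_sd Gaussian noise SD on concentration curves.
#' @return A [dynamic_series()].
#' @export
synthesize_dsc <- function(truth, aif, params, s0 = 100,
                           conc_noise_sd = 0) {
  d <- dim(truth$class)
  n <- params$n_timepoints
  conc <- array(0, c(d, n))
  idx4 <- function(m3) which(array(m3, c(d, n)))  # recycle mask over time
  for (i in seq_along(class_names)) {
    m <- truth$class == i
    if (!any(m)) next
    lv <- truth$levels[[class_names[i]]]
    curve <- tissue_concentration(lv$cbv / lv$mtt, lv$mtt, lv$delay, aif,
                                  model = truth$residue_model, params)
    conc[idx4(m)] <- rep(curve, each = sum(m))
  }
  if (conc_noise_sd > 0) {
    inb <- array(truth$brain_mask$values, c(d, n))
    conc[inb] <- conc[inb] + stats::rnorm(sum(inb), 0, conc_noise_sd)
  }
  sig <- array(0, c(d, n))
  inb <- array(truth$brain_mask$values, c(d, n))
  sig[inb] <- concentration_to_signal(conc[inb], s0, params)
  dynamic_series(sig, params, spacing_mm = truth$brain_mask$spacing_mm)
}

#' Synthesize a complete two-timepoint subject
#'
#' Generates ground truth, DWI pair, DSC series and AIF at baseline and
#' 3-h follow-up on one shared grid, plus clinical covariates. Follow-up
#' differs from baseline only in hemodynamics and ADC (simulating
#' reperfusion and lesion evolution), never in geometry. Deterministic
#' given `spec` and `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for all noise draws.
#' @param clinical Optional list of clinical covariates (`nihss_baseline`,
#'   `nihss_3h`, `hr_change_bpm`, `recanalized`); defaults are drawn from
#'   the cohort clinical model.
#' @return A `subject_dataset`: lists `baseline` and `followup` (each with
#'   `dwi_b0`, `dwi_b1000`, `dsc`, `aif`), `truth` (per timepoint),
#'   `clinical`, `spec` and `seed`.
#' @export
synthesize_subject <- function(spec = phantom_spec(), seed = 1,
                               clinical = NULL) {
  set.seed(seed)
  params <- spec$params
  aif <- gamma_variate_aif(params)
  tp <- function(timepoint) {
    truth <- synthesize_truth(spec, timepoint)
    dwi <- synthesize_dwi(truth$adc, s0_b0 = 1000, params = params,
                          snr = spec$dwi_snr)
    dsc <- synthesize_dsc(truth, aif, params,
                          conc_noise_sd = spec$conc_noise_sd)
    list(truth = truth, dwi_b0 = dwi$b0, dwi_b1000 = dwi$b1000,
         dsc = dsc, aif = aif)
  }
  b <- tp("baseline")
  f <- tp("followup")
  if (is.null(clinical)) {
    clinical <- draw_clinical(spec$arm, recanalized = spec$recanalized)
  }
  structure(list(
    baseline = b[c("dwi_b0", "dwi_b1000", "dsc", "aif")],
    followup = f[c("dwi_b0", "dwi_b1000", "dsc", "aif")],
    truth = list(baseline = b$truth, followup = f$truth),
    clinical = clinical, spec = spec, seed = seed),
    class = "subject_dataset")
}

#' Study effect table
#'
#' Per-arm, per-ROI, per-parameter means and SDs of the relative perfusion
#' parameters and ADC: the baseline level and the 0 h to 3 h change. These
#' defaults transcribe the two-arm stroke study the generator emulates
#' (13 theophylline vs 11 control subjects); ADC entries are on the 1e-6
#' mm^2/s scale. All cohort simulations are driven by this single editable
#' table.
#'
#' @return `data.frame` with columns `roi`, `param`, `arm`,
#'   `baseline_mean`, `baseline_sd`, `delta_mean`, `delta_sd`.
#' @export
effect_table_default <- function() {
  rows <- rbind(
    c("core", "rcbf", "theophylline", 0.67, 0.28, 0.21, 0.33),
    c("core", "rcbf", "control",      0.50, 0.13, 0.27, 0.36),
    c("core", "rcbv", "theophylline", 0.93, 0.27, 0.05, 0.18),
    c("core", "rcbv", "control",      0.86, 0.22, -0.14, 0.24),
    c("core", "rmtt", "theophylline", 4.7, 3.6, -2.82, 4.26),
    c("core", "rmtt", "control",      6.5, 3.8, -5.32, 4.43),
    c("core", "adc", "theophylline",  449, 24, 201, 101),
    c("core", "adc", "control",       450, 27, 159, 110),
    c("penumbra", "rcbf", "theophylline", 0.70, 0.21, 0.11, 0.21),
    c("penumbra", "rcbf", "control",      0.63, 0.17, 0.17, 0.16),
    c("penumbra", "rcbv", "theophylline", 1.14, 0.31, -0.17, 0.25),
    c("penumbra", "rcbv", "control",      1.01, 0.31, -0.08, 0.20),
    c("penumbra", "rmtt", "theophylline", 6.02, 3.17, -3.80, 4.17),
    c("penumbra", "rmtt", "control",      5.68, 3.17, -3.35, 3.16),
    c("penumbra", "adc", "theophylline",  823, 179, -53, 195),
    c("penumbra", "adc", "control",       762, 62, -22, 29),
    c("unaffected", "rcbf", "theophylline", 1.01, 0.07, -0.02, 0.05),
    c("unaffected", "rcbf", "control",      1.02, 0.04, -0.04, 0.04),
    c("unaffected", "rcbv", "theophylline", 1.06, 0.09, -0.04, 0.07),
    c("unaffected", "rcbv", "control",      1.07, 0.09, -0.08, 0.07),
    c("unaffected", "rmtt", "theophylline", 0.34, 0.64, 0.00, 0.64),
    c("unaffected", "rmtt", "control",      0.35, 0.60, -0.22, 0.54),
    c("unaffected", "adc", "theophylline",  826, 46, -29, 54),
    c("unaffected", "adc", "control",       843, 84, -40, 78))
  out <- data.frame(roi = rows[, 1], param = rows[, 2], arm = rows[, 3],
                    baseline_mean = as.numeric(rows[, 4]),
                    baseline_sd = as.numeric(rows[, 5]),
                    delta_mean = as.numeric(rows[, 6]),
                    delta_sd = as.numeric(rows[, 7]))
  out
}

#' Null-effect variant of the study effect table
#'
#' Both arms share the active arm's distributions (identical means and
#' SDs), giving cohorts in which every between-arm comparison is null;
#' used for type-I-error calibration.
#'
#' @param effect_table An effect table as from [effect_table_default()].
#' @return The modified effect table.
#' @export
effect_table_null <- function(effect_table = effect_table_default()) {
  theo <- effect_table[effect_table$arm == "theophylline", ]
  ctrl <- theo
  ctrl$arm <- "control"
  rbind(theo, ctrl)
}

# Clinical covariate model: heart-rate change N(+11, 26) vs N(-9, 14) bpm;
# NIHSS around the observed arm means; large-vessel occlusion and
# recanalization frequencies as observed (7/13 with LVO, all recanalized,
# vs 4/11 with LVO, half recanalized).
draw_clinical <- function(arm, n = 1, recanalized = NULL) {
  theo <- arm == "theophylline"
  hr <- stats::rnorm(n, if (theo) 11 else -9, if (theo) 26 else 14)
  nihss_b <- pmin(pmax(round(stats::rnorm(n, if (theo) 9 else 7,
                                          if (theo) 4 else 3)), 0L), 42L)
  nihss_3h <- pmin(pmax(nihss_b - round(stats::rnorm(n, 0, 2.5)), 0L), 42L)
  lvo <- stats::runif(n) < if (theo) 7 / 13 else 4 / 11
  if (is.null(recanalized)) {
    recanalized <- lvo & (theo | stats::runif(n) < 0.5)
  }
  data.frame(arm = arm, nihss_baseline = as.integer(nihss_b),
             nihss_3h = as.integer(nihss_3h), hr_change_bpm = hr,
             lvo = lvo, recanalized = recanalized)
}

#' Simulate a two-arm cohort
#'
#' Draws per-subject baseline levels and 0 h to 3 h changes from
#' `Normal(mean, SD)` per arm, ROI and parameter according to the effect
#' table, together with clinical covariates, and returns both a features
#' table (one row per subject, columns `<roi>_<param>_<baseline|followup|
#' delta>`) and per-subject phantom specifications that can be rendered to
#' full image data with [synthesize_subject()].
#'
#' @param n_theo,n_ctrl Arm sizes (>= 2); defaults 13 and 11 mirror the
#'   study.
#' @param effect_table Effect table as from [effect_table_default()].
#' @param seed Integer seed.
#' @param include_subjects If `TRUE` (default), attach a `subjects` list of
#'   [phantom_spec()]s carrying each subject's drawn deltas; disable for
#'   large calibration cohorts where only the features are needed.
#' @return A `cohort` list with `features` (data.frame) and `subjects`.
#' @export
synthesize_cohort <- function(n_theo = 13, n_ctrl = 11,
                              effect_table = effect_table_default(),
                              seed = 1, include_subjects = TRUE) {
  if (n_theo < 2 || n_ctrl < 2) stop("arm sizes must be >= 2")
  if (any(effect_table$baseline_sd <= 0) || any(effect_table$delta_sd <= 0))
    stop("non-positive SDs in the effect table")
  set.seed(seed)
  arms <- c(rep("theophylline", n_theo), rep("control", n_ctrl))
  n <- length(arms)
  feats <- data.frame(subject = sprintf("S%03d", seq_len(n)), arm = arms)
  cols <- unique(effect_table[, c("roi", "param")])
  for (k in seq_len(nrow(cols))) {
    roi <- cols$roi[k]; param <- cols$param[k]
    b <- numeric(n); dl <- numeric(n)
    for (arm in c("theophylline", "control")) {
      row <- effect_table[effect_table$roi == roi &
                          effect_table$param == param &
                          effect_table$arm == arm, ]
      sel <- arms == arm
      b[sel] <- stats::rnorm(sum(sel), row$baseline_mean, row$baseline_sd)
      dl[sel] <- stats::rnorm(sum(sel), row$delta_mean, row$delta_sd)
    }
    feats[[paste(roi, param, "baseline", sep = "_")]] <- b
    feats[[paste(roi, param, "followup", sep = "_")]] <- b + dl
    feats[[paste(roi, param, "delta", sep = "_")]] <- dl
  }
  clin <- rbind(draw_clinical("theophylline", n_theo),
                draw_clinical("control", n_ctrl))
  feats <- cbind(feats, clin[, setdiff(names(clin), "arm")])
  subjects <- NULL
  if (include_subjects) {
    subjects <- lapply(seq_len(n), function(i) {
      del <- expand.grid(roi = c("core", "penumbra", "unaffected"),
                         param = c("rcbv", "rmtt", "adc"),
                         stringsAsFactors = FALSE)
      del$delta <- vapply(seq_len(nrow(del)), function(j) {
        feats[[paste(del$roi[j], del$param[j], "delta", sep = "_")]][i]
      }, numeric(1))
      phantom_spec(arm = arms[i], deltas = del,
                   recanalized = feats$recanalized[i])
    })
  }
  structure(list(features = feats, subjects = subjects, seed = seed),
            class = "cohort")
}
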