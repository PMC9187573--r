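test_that("contralateral reference excludes CSF and matches brute force", {
  set.seed(8)
  d <- c(10, 10, 6)
  brain <- binary_mask(array(TRUE, d))
  h <- split_hemispheres(brain, "left")
  csf <- binary_mask(array(runif(prod(d)) < 0.1, d))

  const <- scalar_volume(array(5, d))
  expect_equal(contralateral_reference(const, h, csf), 5)

  # wild CSF values never perturb the reference
  v <- array(5, d)
  v[csf$values] <- 1e6
  expect_equal(contralateral_reference(scalar_volume(v), h, csf), 5)

  for (i in 1:5) {
    vol <- scalar_volume(array(rnorm(prod(d)), d))
    ref_mask <- contralateral_hemisphere(h)$values & !csf$values
    expect_equal(contralateral_reference(vol, h, csf),
                 brute_masked_mean(vol$values, ref_mask))
  }
})

test_that("relative maps follow the divide/subtract convention exactly", {
  d <- c(8, 8, 4)
  m <- scalar_volume(array(4, d))
  expect_equal(relative_map(m, 4, "divide")$values, array(1, d))
  expect_equal(relative_map(m, 4, "subtract")$values, array(0, d))
  expect_error(relative_map(m, 0, "divide"), "positive")

  # normalising the contralateral hemisphere by its own mean is exact
  subj <- synthesize_subject(phantom_spec(), seed = 5)
  res <- run_subject(subj)
  ref <- contralateral_hemisphere(res$hemis)$values & !res$csf$values
  expect_equal(mean(res$relative$rcbf$values[ref], na.rm = TRUE), 1)
  expect_equal(mean(res$relative$rmtt$values[ref], na.rm = TRUE), 0)
  # unaffected tissue on a symmetric phantom sits at unity rCBF
  expect_equal(res$features$unaffected_rcbf_baseline, 1, tolerance = 0.02)
})

test_that("hypoperfusion thresholding is inclusive at exactly 6 s", {
  d <- c(8, 8, 4)
  v <- array(0, d)
  v[2:4, 2:4, 2] <- 6.0        # 9 voxels exactly at threshold
  v[6, 6, 3] <- 10             # isolated, below the component floor
  rtmax <- scalar_volume(v, units = "s")
  brain <- binary_mask(array(TRUE, d))
  got <- segment_hypoperfusion(rtmax, brain)
  expect_equal(mask_count(got), 9)
  expect_true(all(got$values[2:4, 2:4, 2]))

  empty <- segment_hypoperfusion(scalar_volume(array(0, d)), brain)
  expect_equal(mask_count(empty), 0)
})

test_that("ROI algebra matches the quoted set arithmetic", {
  d <- c(4, 10, 1)                        # left hemisphere = x 1..2, 20 vox
  grid <- function(coords) {
    m <- array(FALSE, d)
    if (nrow(coords)) m[coords] <- TRUE
    binary_mask(m)
  }
  left_cells <- as.matrix(expand.grid(1:2, 1:5, 1))  # 10 affected voxels
  hypo <- grid(left_cells)
  core <- grid(left_cells[1:4, , drop = FALSE])
  csf <- grid(left_cells[0, , drop = FALSE])
  brain <- binary_mask(array(TRUE, d))
  h <- split_hemispheres(brain, "left")
  rois <- derive_rois(core, hypo, h, csf)
  expect_equal(mask_count(rois$core), 4)
  expect_equal(mask_count(rois$penumbra), 6)
  expect_equal(mask_count(rois$unaffected), 10)

  # hypoperfusion equal to the core leaves no penumbra
  rois2 <- derive_rois(core, core, h, csf)
  expect_equal(mask_count(rois2$penumbra), 0)

  # core voxels outside the affected hemisphere are clipped with a warning
  stray <- grid(rbind(left_cells[1:4, ], c(4, 1, 1)))
  expect_warning(rois3 <- derive_rois(stray, hypo, h, csf), "clipped")
  expect_equal(mask_count(rois3$core), 4)
})

test_that("ROI partition invariants hold on random geometry", {
  set.seed(12)
  for (i in 1:100) {
    d <- c(12, 10, 6)
    brain <- random_mask(d, 4)
    if (mask_count(brain) == 0) next
    h <- split_hemispheres(brain, sample(c("left", "right"), 1))
    aff <- affected_hemisphere(h)$values
    csf <- binary_mask(brain$values & array(runif(prod(d)) < 0.08, d))
    core <- binary_mask(aff & array(runif(prod(d)) < 0.2, d))
    hypo <- binary_mask(aff & (core$values | array(runif(prod(d)) < 0.3, d)))
    rois <- derive_rois(core, hypo, h, csf)
    expect_equal(sum(rois$core$values & rois$penumbra$values), 0)
    expect_equal(sum(rois$core$values & rois$unaffected$values), 0)
    expect_equal(sum(rois$penumbra$values & rois$unaffected$values), 0)
    expect_identical(rois$core$values | rois$penumbra$values |
                       rois$unaffected$values,
                     aff & brain$values & !csf$values)
  }
})

test_that("ROI means are additive and equal the brute-force scan", {
  set.seed(4)
  d <- c(8, 8, 4)
  vol <- scalar_volume(array(rnorm(prod(d), 10), d))
  a <- binary_mask(array(runif(prod(d)) < 0.3, d))
  b <- binary_mask(array(runif(prod(d)) < 0.3, d) & !a$values)
  expect_equal(as.numeric(roi_mean(vol, a)),
               brute_masked_mean(vol$values, a$values))
  u <- binary_mask(a$values | b$values)
  na_ <- mask_count(a); nb <- mask_count(b)
  expect_equal(as.numeric(roi_mean(vol, u)),
               (na_ * as.numeric(roi_mean(vol, a)) +
                  nb * as.numeric(roi_mean(vol, b))) / (na_ + nb))
  expect_equal(as.numeric(roi_mean(scalar_volume(array(7, d)), a)), 7)
  empty <- binary_mask(array(FALSE, d))
  expect_true(is.na(roi_mean(vol, empty)))
})

test_that("feature extraction applies baseline ROIs at both timepoints", {
  subj <- synthesize_subject(phantom_spec(), seed = 13)
  res <- run_subject(subj)

  # identical follow-up maps give exactly zero deltas
  same <- extract_subject_features(res$rois, res$relative, res$relative,
                                   res$adc, res$adc)
  for (col in grep("_delta$", names(same), value = TRUE)) {
    expect_equal(same[[col]], 0)
  }

  # volumes: voxel count times voxel volume
  expect_equal(res$features$core_volume_ml,
               mask_count(res$rois$core) * prod(c(2, 2, 4)) / 1000)

  # the follow-up core (ADC partially normalised) differs from the
  # baseline core, yet the extracted features are computed on the baseline
  # ROIs only: re-segmenting at 3 h would have changed the ADC mean
  core_3h <- segment_core(res$adc_followup, res$brain)
  expect_false(identical(core_3h$values, res$rois$core$values))
  rois_3h <- res$rois
  rois_3h$core <- core_3h
  feats_resegmented <- extract_subject_features(rois_3h, res$relative,
                                                res$relative_followup,
                                                res$adc, res$adc_followup)
  feats_baseline <- extract_subject_features(res$rois, res$relative,
                                             res$relative_followup,
                                             res$adc, res$adc_followup)
  expect_false(isTRUE(all.equal(feats_resegmented$core_adc_followup,
                                feats_baseline$core_adc_followup)))
  expect_equal(feats_baseline$core_adc_baseline,
               res$features$core_adc_baseline)

  # grid mismatch is an error
  small <- scalar_volume(array(1, c(4, 4, 4)))
  expect_error(extract_subject_features(res$rois, res$relative,
                                        res$relative_followup,
                                        res$adc, small),
               "grid")
})
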