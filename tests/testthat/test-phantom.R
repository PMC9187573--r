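test_that("ground truth satisfies the central-volume and geometry invariants", {
  for (tp in c("baseline", "followup")) {
    truth <- synthesize_truth(phantom_spec(), tp)
    fg <- !is.na(truth$mtt$values)
    expect_equal(max(abs(truth$mtt$values[fg] -
                           truth$cbv$values[fg] / truth$cbf$values[fg])), 0)
    expect_true(all(truth$core_mask$values <= truth$brain_mask$values))
    expect_true(all(truth$penumbra_mask$values <= truth$brain_mask$values))
    expect_equal(sum(truth$core_mask$values & truth$penumbra_mask$values), 0)
    expect_true(all(truth$adc$values[truth$csf_mask$values] > 2000e-6))
  }
  # the acute core sits below the segmentation threshold at baseline;
  # at follow-up the lesion ADC may normalise above it
  acute <- synthesize_truth(phantom_spec(), "baseline")
  expect_true(all(acute$adc$values[acute$core_mask$values] < 550e-6))
  # geometry is shared between timepoints; only tissue levels move
  b <- synthesize_truth(phantom_spec(), "baseline")
  f <- synthesize_truth(phantom_spec(), "followup")
  expect_identical(b$class, f$class)
  expect_false(identical(b$cbv$values, f$cbv$values))
})

test_that("lesions larger than the hemisphere are rejected", {
  expect_error(synthesize_truth(phantom_spec(core_radius = 10,
                                             penumbra_radius = 14)),
               "hemisphere")
  expect_error(phantom_spec(core_radius = 5, penumbra_radius = 4), "exceed")
})

test_that("subject synthesis is deterministic and honours the configured
           lesion physiology", {
  s1 <- synthesize_subject(phantom_spec(dwi_snr = 20, conc_noise_sd = 0.005),
                           seed = 9)
  s2 <- synthesize_subject(phantom_spec(dwi_snr = 20, conc_noise_sd = 0.005),
                           seed = 9)
  expect_identical(s1$baseline$dsc$signal, s2$baseline$dsc$signal)
  expect_identical(s1$baseline$dwi_b1000$values, s2$baseline$dwi_b1000$values)
  expect_identical(s1$clinical, s2$clinical)
  s3 <- synthesize_subject(phantom_spec(dwi_snr = 20), seed = 10)
  expect_false(identical(s1$baseline$dwi_b1000$values,
                         s3$baseline$dwi_b1000$values))

  truth <- s1$truth$baseline
  expect_true(all(truth$adc$values[truth$core_mask$values] < 550e-6))
  # core flow is half the unaffected flow by construction
  lv <- truth$levels
  expect_equal((lv$core$cbv / lv$core$mtt) /
                 (lv$unaffected$cbv / lv$unaffected$mtt), 0.5,
               tolerance = 1e-12)
})

test_that("noiseless end-to-end run recovers the configured core physiology", {
  subj <- synthesize_subject(phantom_spec(), seed = 21)
  res <- run_subject(subj)
  lv <- subj$truth$baseline$levels
  # relative CBV against the ground-truth contralateral ratio
  expect_lt(abs(res$features$core_rcbv_baseline -
                  lv$core$cbv / lv$unaffected$cbv), 0.05)
  # follow-up change matches the configured arm effect
  et <- effect_table_default()
  configured <- et$delta_mean[et$roi == "core" & et$param == "rcbv" &
                                et$arm == "theophylline"]
  expect_lt(abs(res$features$core_rcbv_delta - configured), 0.01)
})

test_that("recanalized follow-up resets delay and transit time", {
  spec <- phantom_spec(recanalized = TRUE)
  f <- synthesize_truth(spec, "followup")
  expect_equal(f$levels$core$delay, 0)
  expect_equal(f$levels$penumbra$delay, 0)
  expect_equal(f$levels$core$mtt, f$levels$unaffected$mtt)
})

test_that("cohort generator is reproducible with the requested arm sizes", {
  co1 <- synthesize_cohort(n_theo = 5, n_ctrl = 4, seed = 3)
  co2 <- synthesize_cohort(n_theo = 5, n_ctrl = 4, seed = 3)
  expect_identical(co1$features, co2$features)
  expect_equal(sum(co1$features$arm == "theophylline"), 5)
  expect_equal(sum(co1$features$arm == "control"), 4)
  expect_length(co1$subjects, 9)
  expect_error(synthesize_cohort(n_theo = 1), "arm sizes")
  bad <- effect_table_default()
  bad$delta_sd[1] <- 0
  expect_error(synthesize_cohort(effect_table = bad), "non-positive")
})

test_that("cohort draws reproduce the configured effect distributions", {
  co <- synthesize_cohort(n_theo = 10000, n_ctrl = 2, seed = 17,
                          include_subjects = FALSE)
  theo <- co$features[co$features$arm == "theophylline", ]
  # law of large numbers against the configured table
  expect_lt(abs(mean(theo$core_rcbv_delta) - 0.05), 0.01)
  expect_lt(abs(sd(theo$core_rcbv_delta) - 0.18),
            3 * 0.18 / sqrt(2 * 10000))
  expect_lt(abs(mean(theo$core_rcbv_baseline) - 0.93),
            3 * 0.27 / sqrt(10000))
  expect_lt(abs(mean(theo$hr_change_bpm) - 11), 3 * 26 / sqrt(10000))
  # follow-up minus baseline is the drawn delta, exactly
  expect_equal(theo$core_rcbv_followup - theo$core_rcbv_baseline,
               theo$core_rcbv_delta)
})
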