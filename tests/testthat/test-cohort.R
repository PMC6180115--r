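test_that("ROI median is robust, permutation-invariant and NaN-aware", {
  mk <- function(v) parametric_map(matrix(v, 1), "x", "", matrix(TRUE, 1, 3))
  expect_equal(roi_median(mk(c(1, 2, 100))), 2)
  expect_equal(roi_median(mk(c(100, 1, 2))), 2)
  expect_equal(roi_median(mk(c(7, 7, 7))), 7)
  # missing pixels are ignored
  m <- parametric_map(matrix(c(1, NaN, 3, NaN), 2), "x", "",
                      matrix(TRUE, 2, 2))
  expect_equal(roi_median(m), 2)
  empty <- parametric_map(matrix(NaN, 2, 2), "x", "", matrix(TRUE, 2, 2))
  expect_message(v <- roi_median(empty), "no valid pixels")
  expect_true(is.na(v))
})

test_that("caliper volume follows V = w^2 l / 2", {
  expect_equal(tumor_volume(10, 6), 180)
  expect_equal(tumor_volume(5, 5), 62.5)
  # asymmetric in l and w
  expect_false(isTRUE(all.equal(tumor_volume(10, 6),
                                suppressWarnings(tumor_volume(6, 10)))))
  expect_warning(tumor_volume(6, 10), "maximal")
  expect_error(tumor_volume(0, 1), "positive")
})

test_that("percent change is zero at baseline and exact elsewhere", {
  rec <- data.frame(subject = rep("S1", 3), timepoint = c(0, 24, 72),
                    adc = c(100, 100, 141.5))
  pc <- percent_change(rec, "adc")
  expect_equal(pc$pct_change, c(0, 0, 41.5))
  # zero baseline -> NA with a message
  rec2 <- data.frame(subject = "S2", timepoint = c(0, 72), adc = c(0, 5))
  expect_message(pc2 <- percent_change(rec2, "adc"), "zero baseline")
  expect_true(all(is.na(pc2$pct_change)))
})

test_that("effect model is monotone in dose for the sensitive type at 72 h", {
  em <- default_effect_model()
  s72 <- em[em$tumor_type == "sensitive" & em$timepoint == 72, ]
  s72 <- s72[order(s72$dose), ]
  expect_true(all(diff(s72$amide_mult) > 0))
  expect_true(all(diff(s72$amine_mult) > 0))
  r72 <- em[em$tumor_type == "resistant" & em$timepoint == 72, ]
  # weaker dose response in the resistant type
  expect_lt(max(r72$amide_mult) - 1, (max(s72$amide_mult) - 1) / 3)
  # low-dose growth stimulation: volume multiplier at 8 exceeds vehicle
  expect_gt(s72$volume_mult[s72$dose == 8], s72$volume_mult[s72$dose == 0])
})

test_that("record-level cohort simulation honors design and null contract", {
  rec <- simulate_cohort(tumor_types = "sensitive", doses = c(0, 9.5),
                         n_per_group = 4, images = FALSE, seed = 2,
                         effect_model = default_effect_model(null = TRUE))
  expect_equal(nrow(rec), 2 * 4 * 3)
  expect_true(all(table(rec$subject) == 3))
  # null effect model: group means differ only by noise (few percent)
  m72 <- tapply(rec$amide_area[rec$timepoint == 72],
                rec$dose[rec$timepoint == 72], mean)
  expect_lt(abs(diff(m72)) / m72[1], 0.1)
  expect_error(simulate_cohort(doses = c(0, 3.3), images = FALSE),
               "unknown dose")
  expect_error(simulate_cohort(n_per_group = 0), "at least one subject")
  # low-dose arm: positive mean relative volume change at 72 h
  rec2 <- simulate_cohort(tumor_types = "sensitive", doses = 8,
                          n_per_group = 6, images = FALSE, seed = 3)
  pc <- percent_change(rec2, "volume_mm3")
  expect_gt(mean(pc$pct_change[pc$timepoint == 72]), 0)
})

test_that("group contrasts flag an extreme shift and report both families", {
  set.seed(91)
  rec <- simulate_cohort(tumor_types = "sensitive", doses = c(0, 8, 9.5, 11),
                         n_per_group = 5, images = FALSE, seed = 4,
                         effect_model = default_effect_model(null = TRUE))
  # inject a 10-sd shift into the 11 mg/kg group at 72 h
  sel <- rec$dose == 11 & rec$timepoint == 72
  rec$amide_area[sel] <- rec$amide_area[sel] * 3
  gc <- group_contrasts(rec, "amide_area")
  p_extreme <- gc$between$p_value[gc$between$dose == 11 & gc$between$timepoint == 72]
  expect_lt(p_extreme, 1e-4)
  expect_true(all(c("dose", "timepoint", "p_value") %in% names(gc$between)))
  expect_true(any(grepl("dose_f", gc$anova$term)))
  expect_equal(gc$alpha, 0.05)
})

test_that("dose correlation returns +/-1 for perfectly monotone group means", {
  rec <- expand.grid(subject = NA, tumor_type = "sensitive",
                     dose = c(0, 8, 9.5, 11), timepoint = c(0, 72))
  rec$subject <- paste0("S", rep(1:4, 2))
  rec$amide_area <- ifelse(rec$timepoint == 0, 1, 1 + 0.02 * rec$dose)
  dc <- dose_correlation(rec, "amide_area", "sensitive", 72)
  expect_equal(dc$rho, 1)
  rec$amide_area <- ifelse(rec$timepoint == 0, 1, 1 - 0.02 * rec$dose)
  expect_equal(dose_correlation(rec, "amide_area", "sensitive", 72)$rho, -1)
  # constant input -> undefined, reported as missing
  rec$amide_area <- 1
  expect_message(dc0 <- dose_correlation(rec, "amide_area", "sensitive", 72),
                 "constant")
  expect_true(is.na(dc0$rho))
})
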