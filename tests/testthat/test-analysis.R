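test_that("metrics of a synthetic triangular curve are exact", {
  probes <- seq(0, 175, by = 5)
  rate <- pmax(0, 20 * (1 - abs(probes - 90) / 20))  # half-height at +/-10
  curve <- structure(list(orientation = probes, rate = rate, neuron_id = 1,
                          condition = "x"), class = "tuning_curve")
  m <- tuning_metrics(curve, reference_orientation = 90)
  expect_equal(m$amplitude, 20)
  expect_equal(m$width, 20)          # FWHM of the triangle
  expect_equal(m$ratio_R, 1)         # amplitude / width, exactly
  expect_equal(m$preferred, 90)
  expect_equal(m$slope_at_reference, 0)  # symmetric peak
  expect_true(m$responsive)
})

test_that("flat or silent curves are flagged undefined, not zero-divided", {
  probes <- seq(0, 165, by = 15)
  silent <- structure(list(orientation = probes, rate = rep(0, 12)),
                      class = "tuning_curve")
  m <- tuning_metrics(silent)
  expect_false(m$responsive)
  expect_true(is.na(m$amplitude) && is.na(m$width) && is.na(m$ratio_R))
  cls <- classify_change(m, m)
  expect_true(is.na(cls))
  expect_match(attr(cls, "reason"), "unresponsive")
})

test_that("change classification follows the reduction/sharpening rules", {
  probes <- seq(0, 175, by = 5)
  base <- tuning_metrics(gauss_curve(probes, amp = 30, sd_deg = 12), 90)
  # identical curves: no change
  expect_identical(classify_change(base, base), "none")
  # amplitude -30%, width -30%: pure scaling, slope at the (peak) reference
  # stays ~0 -> reduction
  red <- tuning_metrics(gauss_curve(probes, amp = 21, sd_deg = 8.4), 90)
  expect_identical(classify_change(base, red), "reduction")
  # flank neuron at 99: the trained orientation 90 lies on its flank
  base_f <- tuning_metrics(gauss_curve(probes, center = 99, amp = 30,
                                       sd_deg = 12), 90)
  # amplitude -10%, width -35%: steeper flank at the reference -> sharpening
  shp <- tuning_metrics(gauss_curve(probes, center = 99, amp = 27,
                                    sd_deg = 7.8), 90)
  expect_identical(classify_change(base_f, shp), "sharpening")
  # every responsive comparison maps to exactly one label
  for (cmp in list(c(30, 12), c(25, 12), c(30, 9), c(20, 11)))
    expect_true(classify_change(
      base, tuning_metrics(gauss_curve(probes, amp = cmp[1],
                                       sd_deg = cmp[2]), 90)) %in%
        c("reduction", "sharpening", "none"))
})

test_that("ratio R equals amplitude over width by construction", {
  probes <- seq(0, 175, by = 5)
  m <- tuning_metrics(gauss_curve(probes, amp = 17, sd_deg = 9), 90)
  expect_identical(m$ratio_R, m$amplitude / m$width)
})

test_that("grid refinement moves width and slope by less than 10%", {
  coarse <- seq(0, 171, by = 9)
  fine <- seq(0, 175.5, by = 4.5)
  mc <- tuning_metrics(gauss_curve(coarse, center = 72, amp = 30,
                                   sd_deg = 12), 90)
  mf <- tuning_metrics(gauss_curve(fine, center = 72, amp = 30,
                                   sd_deg = 12), 90)
  expect_lt(abs(mc$width - mf$width) / mf$width, 0.1)
  expect_lt(abs(mc$slope_at_reference - mf$slope_at_reference) /
              abs(mf$slope_at_reference), 0.1)
})

test_that("preference stability detects shifts beyond tolerance", {
  probes <- seq(0, 165, by = 15)
  mk <- function(centers, cond) {
    rates <- t(vapply(centers,
                      function(cc) gauss_curve(probes, center = cc)$rate,
                      numeric(length(probes))))
    structure(list(rates = rates, probes = probes,
                   neuron_ids = seq_along(centers), condition = cond,
                   fb_drive = rep(0, length(probes))),
              class = "tuning_set")
  }
  before <- mk(c(30, 60, 90, 120), "before")
  same <- mk(c(30, 60, 90, 120), "after")
  st <- preference_stability(before, same)
  expect_equal(st$fraction_stable, 1)
  expect_equal(st$n_responsive, 4)
  # shift all preferred orientations by two grid steps: flagged unstable
  shifted <- mk(c(60, 90, 120, 150), "after")
  st2 <- preference_stability(before, shifted)
  expect_equal(st2$fraction_stable, 0)
})

test_that("io_function and population_response run on the fixture", {
  f <- fix_net()
  io_with <- io_function(f$net, c(0, 2.5), with_recurrence = TRUE,
                         probe_spec = f$stim)
  io_without <- io_function(f$net, c(0, 2.5), with_recurrence = FALSE,
                            probe_spec = f$stim)
  # zero input -> spontaneous (zero) rate in both conditions
  expect_equal(io_with$rate[1], 0)
  expect_equal(io_without$rate[1], 0)
  expect_true(all(diff(io_with$rate) >= 0))
  pr <- population_response(f$net, f$stim, with_recurrence = FALSE)
  expect_length(pr, f$net$n_v1_e)
})
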