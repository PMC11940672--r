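test_that("an empty vial with no medium scatter yields a dark spectrum", {
  cfg <- noise_off(medium_scatter_cells_equiv = 0)
  st <- culture_state(biomass_cells_per_ul = 0)
  sp <- simulate_spectrum(st, default_led_bank()[["led615"]], 1,
                          config = cfg, noise = FALSE)
  expect_true(all(sp$intensities == 0))
})

test_that("forward model is exactly linear in exposure below saturation", {
  cfg <- noise_off()
  st <- culture_state(biomass_cells_per_ul = 150)
  ch <- default_led_bank()[["led615"]]
  s1 <- simulate_spectrum(st, ch, 0.1, config = cfg, noise = FALSE)
  s2 <- simulate_spectrum(st, ch, 5, config = cfg, noise = FALSE)
  expect_false(any(s2$saturated))
  expect_equal(s2$intensities, 50 * s1$intensities, tolerance = 1e-12)
})

test_that("doubling biomass doubles the scattered LED-band integral", {
  cfg <- noise_off(medium_scatter_cells_equiv = 0)
  ch <- default_led_bank()[["led615"]]
  mk <- function(b) {
    st <- culture_state(biomass_cells_per_ul = b,
                        pigment_per_cell = c(phycocyanin = 0,
                                             chlorophyll = 0))
    band_integral(simulate_spectrum(st, ch, 0.1, config = cfg,
                                    noise = FALSE), led_band(615))
  }
  expect_equal(mk(400), 2 * mk(200), tolerance = 1e-9)
})

test_that("LED-band integral increases strictly with total particle density", {
  cfg <- noise_off()
  ch <- default_led_bank()[["led615"]]
  vals <- vapply(c(0, 50, 150, 400, 900), function(b)
    band_integral(simulate_spectrum(culture_state(biomass_cells_per_ul = b),
                                    ch, 0.1, config = cfg, noise = FALSE),
                  led_band(615)),
    numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the simulated long exposure saturates the LED peak as intended", {
  # dense culture: the excitation line clips at the long exposure but is
  # cleanly resolved at the short one -- the premise of the dual capture
  st <- culture_state(biomass_cells_per_ul = 500)
  ch <- default_led_bank()[["led615"]]
  long <- simulate_spectrum(st, ch, 5, noise = FALSE)
  short <- simulate_spectrum(st, ch, 0.1, noise = FALSE)
  expect_gt(sum(long$saturated), 0)
  expect_equal(sum(short$saturated), 0)
  pk <- find_peak(long, phycocyanin_band(),
                  exclude_mask = mask_saturated(long))
  expect_lt(abs(pk$wavelength_nm - 657), 1.5)
})

test_that("backend enforces LED and photoperiod mutual exclusion", {
  bk <- phantom_backend(noise_off("growth"))
  set_led(bk, "led615", TRUE)
  expect_error(set_led(bk, "led451", TRUE), "already on")
  expect_error(set_photoperiod_lights(bk, TRUE), "excitation LED is on")
  set_led(bk, "led615", FALSE)
  set_photoperiod_lights(bk, TRUE)
  expect_error(set_led(bk, "led615", TRUE), "photoperiod lights on")
  expect_error(set_led(bk, "nope", TRUE), "unknown LED")
})

test_that("calibration series grows monotonically with concentration", {
  set.seed(7)
  cal <- generate_calibration_series(c(0, 25, 50, 100, 200), n_blanks = 3,
                                     config = noise_off())
  expect_true(all(diff(cal$calibration$index) > 0))
  expect_equal(cal$calibration$concentration, c(0, 25, 50, 100, 200))
})

test_that("all-zero concentrations reproduce the blank distribution", {
  set.seed(11)
  cal <- generate_calibration_series(rep(0, 6), n_blanks = 6)
  both <- c(cal$calibration$index, cal$blanks)
  se <- stats::sd(both) / sqrt(6)
  expect_lt(abs(mean(cal$calibration$index) - mean(cal$blanks)), 3 * sqrt(2) * se)
})

test_that("blank means agree across disjoint seeds within 3 standard errors", {
  set.seed(21)
  b1 <- generate_calibration_series(0, n_blanks = 30)$blanks
  set.seed(22)
  b2 <- generate_calibration_series(0, n_blanks = 30)$blanks
  se <- sqrt(stats::var(b1) / 30 + stats::var(b2) / 30)
  expect_lt(abs(mean(b1) - mean(b2)), 3 * se)
})
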