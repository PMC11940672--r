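test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(650, 651), c(1, 2, 3), 1), "equal length")
  expect_error(spectrum(c(651, 650), c(1, 2), 1), "strictly increasing")
  expect_error(spectrum(c(650, 651), c(1, 2), 0), "positive")
  expect_error(spectrum(c(650, 651), c(-1, 2), 1), "non-negative")
  expect_error(spectrum(c(650, 651), c(1, 70000), 1, 65535), "exceed")
  s <- spectrum(c(650, 651), c(1, 65535), 1, 65535)
  expect_identical(s$saturated, c(FALSE, TRUE))
})

test_that("mask_saturated compares against the fractional full scale", {
  s <- spectrum(1:4, c(10, 65535, 65535, 40), 1, 65535)
  expect_identical(mask_saturated(s, 1), c(FALSE, TRUE, TRUE, FALSE))
  z <- spectrum(1:3, c(0, 0, 0), 1)
  expect_identical(mask_saturated(z, 0.5), rep(FALSE, 3))
  # 0.9 * 65535 = 58981.5 by direct arithmetic
  s2 <- spectrum(1:3, c(100, 59000, 65000), 1, 65535)
  expect_identical(mask_saturated(s2, 0.9), c(FALSE, TRUE, TRUE))
  expect_error(mask_saturated(s, 0), "in \\(0, 1\\]")
})

test_that("band_integral is the trapezoid over in-band unmasked samples", {
  s <- spectrum(c(650, 651, 652), c(10, 20, 10), 1)
  expect_equal(band_integral(s, band(650, 652)), 30)  # (10+20)/2 + (20+10)/2
  z <- spectrum(c(650, 651, 652), c(0, 0, 0), 1)
  expect_equal(band_integral(z, band(650, 652)), 0)
  # a single unmasked sample cannot support an integral
  expect_equal(band_integral(s, band(650, 652),
                             exclude_mask = c(TRUE, FALSE, TRUE)), 0)
  expect_error(band_integral(s, band(600, 700)), "outside")
})

test_that("band_integral tracks a dense-grid oracle within 2% for Gaussians", {
  for (center in c(640, 657, 673)) {
    s <- gauss_spectrum(center, fwhm_nm = 25)
    got <- band_integral(s, band(center - 20, center + 20))
    dense <- seq(center - 20, center + 20, by = 0.01)
    sigma <- 25 / (2 * sqrt(2 * log(2)))
    oracle <- pracma::trapz(dense,
                            1000 * exp(-(dense - center)^2 / (2 * sigma^2)))
    expect_lt(abs(got - oracle) / oracle, 0.02)
  }
})

test_that("normalize_exposure rescales linearly and preserves saturation", {
  s <- spectrum(1:5, rep(50, 5), 0.1)
  out <- normalize_exposure(s, 1)
  expect_equal(out$intensities, rep(500, 5))
  expect_equal(out$exposure_s, 1)
  expect_equal(normalize_exposure(s, 0.1), s)      # identity
  s2 <- spectrum(1:3, rep(200, 3), 5)
  expect_equal(normalize_exposure(s2, 0.1)$intensities, rep(4, 3))
  # saturated samples are carried, not rescaled into fake counts
  s3 <- spectrum(1:3, c(100, 65535, 100), 1, 65535)
  out3 <- normalize_exposure(s3, 2)
  expect_equal(out3$intensities, c(200, 65535, 200))
  expect_identical(out3$saturated, c(FALSE, TRUE, FALSE))
  expect_error(normalize_exposure(s, -1), "positive")
})

test_that("find_peak refines an interior maximum by parabolic interpolation", {
  # off-grid Gaussian centres on the 1.5 nm grid; dense-grid argmax oracle
  for (center in c(657, 657.4, 656.3)) {
    s <- gauss_spectrum(center, fwhm_nm = 25)
    pk <- find_peak(s, band(630, 700))
    expect_lt(abs(pk$wavelength_nm - center), 0.2)
  }
})

test_that("find_peak boundary, tie-break and degenerate contracts hold", {
  grid <- seq(600, 700, by = 1)
  ramp <- spectrum(grid, seq_along(grid), 1)
  expect_equal(find_peak(ramp, band(640, 660))$wavelength_nm, 660)
  y <- rep(1, length(grid)); y[grid == 650] <- 5; y[grid == 660] <- 5
  two <- spectrum(grid, y, 1)
  expect_equal(find_peak(two, band(600, 700))$wavelength_nm, 650)
  s <- gauss_spectrum(657)
  expect_error(find_peak(s, band(656, 658)), "at least 3")
})

test_that("fluorescence_index is the per-second band ratio", {
  grid <- seq(600, 700, by = 1)
  short <- spectrum(grid, rep(100, length(grid)), 0.1)  # LED area 1000/10 nm
  long <- spectrum(grid, rep(50, length(grid)), 5)      # fluor area 500/10 nm
  pair <- measurement_pair("none", short, long)
  got <- fluorescence_index(pair, fluor_band = band(650, 660),
                            led_bnd = band(610, 620))
  expect_equal(got, (500 / 5) / (1000 / 0.1))           # 0.01
  # zero fluorescence with a positive LED peak
  zero_long <- spectrum(grid, rep(0, length(grid)), 5)
  expect_equal(fluorescence_index(measurement_pair("none", short, zero_long),
                                  fluor_band = band(650, 660),
                                  led_bnd = band(610, 620)), 0)
})

test_that("fluorescence_index error contracts: dead LED peak, saturated band", {
  grid <- seq(600, 700, by = 1)
  short0 <- spectrum(grid, rep(0, length(grid)), 0.1)
  long <- spectrum(grid, rep(50, length(grid)), 5)
  expect_error(fluorescence_index(measurement_pair("none", short0, long),
                                  fluor_band = band(650, 660),
                                  led_bnd = band(610, 620)),
               "not positive")
  sat <- spectrum(grid, rep(65535, length(grid)), 5, 65535)
  short <- spectrum(grid, rep(100, length(grid)), 0.1)
  expect_error(fluorescence_index(measurement_pair("none", short, sat),
                                  fluor_band = band(650, 660),
                                  led_bnd = band(610, 620)),
               "saturated")
})

test_that("fluorescence_index is invariant under common detector gain", {
  s <- culture_state(biomass_cells_per_ul = 150)
  ch <- default_led_bank()[["led615"]]
  short <- simulate_spectrum(s, ch, 0.1, noise = FALSE)
  long <- simulate_spectrum(s, ch, 5, noise = FALSE)
  gain <- 3.7
  scale <- function(sp) {
    sp$intensities <- sp$intensities * gain
    sp$saturation_counts <- sp$saturation_counts * gain
    sp
  }
  i1 <- fluorescence_index(measurement_pair("led615", short, long,
                                            led_peak_nm = 615))
  i2 <- fluorescence_index(measurement_pair("led615", scale(short),
                                            scale(long), led_peak_nm = 615))
  expect_equal(i1, i2, tolerance = 1e-12)
})
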