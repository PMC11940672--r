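# shared fixtures, built in code

default_grid <- function() spectrometer()$grid_nm

# noiseless Gaussian emission line sampled on a grid
gauss_spectrum <- function(center_nm, fwhm_nm = 25, height = 1000,
                           grid = default_grid(), exposure_s = 1,
                           saturation = 65535) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  spectrum(grid, height * exp(-(grid - center_nm)^2 / (2 * sigma^2)),
           exposure_s, saturation_counts = saturation)
}

# scenario config with every noise source off
noise_off <- function(scenario = "calibration", ...)
  scenario_config(scenario, read_noise_sd = 0, shot_noise = FALSE,
                  od_noise_sd = 0, ...)

# noise-free expected fluorescence index of a state under one LED
expected_index <- function(state, config = noise_off(),
                           led_id = "led615", short_s = 0.1, long_s = 5) {
  ch <- default_led_bank()[[led_id]]
  sS <- simulate_spectrum(state, ch, short_s, config = config, noise = FALSE)
  sL <- simulate_spectrum(state, ch, long_s, config = config, noise = FALSE)
  pair <- measurement_pair(led_id, sS, sL, led_peak_nm = ch$peak_nm)
  fluorescence_index(pair)
}
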