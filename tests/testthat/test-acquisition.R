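test_that("a six-LED round yields six pairs and restores every job", {
  bk <- phantom_backend(noise_off("growth"))
  set_photoperiod_lights(bk, TRUE)          # mid-photoperiod
  pre <- jobs_state(bk)
  pairs <- measurement_round(bk, names(bk$bank))
  expect_length(pairs, 6)
  expect_length(attr(pairs, "failures"), 0)
  expect_identical(jobs_state(bk), pre)     # OD running again, lights back on
  for (p in pairs) {
    expect_s3_class(p, "measurement_pair")
    expect_lt(p$short$exposure_s, p$long$exposure_s)
    expect_identical(p$short$led_id, p$led_id)
    expect_identical(p$long$led_id, p$led_id)
  }
  expect_identical(vapply(pairs, function(p) p$led_id, character(1)),
                   names(bk$bank))          # LED order preserved
})

test_that("round preconditions: empty LED list and unknown ids change nothing", {
  bk <- phantom_backend(noise_off("growth"))
  pre <- jobs_state(bk)
  expect_error(measurement_round(bk, character(0)), "at least one")
  expect_error(measurement_round(bk, c("led615", "led999")), "unknown LED")
  expect_identical(jobs_state(bk), pre)
  expect_length(bk$events, 0)               # nothing was switched
})

test_that("a capture failure mid-round keeps completed pairs and restores", {
  # fail the 5th capture = short exposure of LED 3 of 6
  bk <- phantom_backend(noise_off("growth"),
                        fault = list(op = "capture", count = 5))
  pre <- jobs_state(bk)
  pairs <- measurement_round(bk, names(bk$bank))
  expect_length(pairs, 2)
  expect_match(attr(pairs, "failures"), "led586")
  expect_identical(jobs_state(bk), pre)
  expect_null(bk$active_led)
})

test_that("no two light sources are ever on together during a round", {
  bk <- phantom_backend(noise_off("growth"))
  set_photoperiod_lights(bk, TRUE)
  invisible(measurement_round(bk, names(bk$bank)))
  on_now <- character(0)
  lights <- "off"
  for (ev in bk$events) {
    parts <- strsplit(ev$event, ":")[[1]]
    if (parts[1] == "led") {
      if (parts[3] == "on") on_now <- union(on_now, parts[2])
      else on_now <- setdiff(on_now, parts[2])
    } else if (parts[1] == "lights") lights <- parts[2]
    expect_lte(length(on_now), 1)
    expect_false(length(on_now) > 0 && lights == "on")
  }
})

test_that("monitor executes the scheduled number of rounds", {
  bk <- phantom_backend(noise_off("growth"))
  run <- run_monitor(bk, duration_h = 24, schedule_interval_min = 60,
                     leds = "led615")
  expect_equal(run$n_rounds, 24)
  expect_equal(nrow(run$fluor), 24)
  expect_true(all(diff(run$fluor$time_h) > 0))
  expect_gt(nrow(run$od), 24 * 700)     # ~5 s cadence between rounds
  expect_error(run_monitor(bk, duration_h = 1,
                           schedule_interval_min = 0.2),
               "must exceed the round duration")
})

test_that("noise-free growth run gives a non-decreasing fluorescence index", {
  bk <- phantom_backend(noise_off("growth"))
  run <- run_monitor(bk, duration_h = 48, schedule_interval_min = 60,
                     leds = "led615")
  expect_equal(nrow(run$fluor), 48)
  expect_true(all(diff(run$fluor$index) >= -1e-12))
  expect_gt(theil_sen_slope(run$fluor$time_h, run$fluor$index), 0)
})

test_that("every persisted long spectrum has a same-round short partner", {
  dir <- withr::local_tempdir()
  bk <- phantom_backend(noise_off("growth"))
  invisible(run_monitor(bk, duration_h = 3, schedule_interval_min = 60,
                        leds = c("led615", "led451"), sink = dir))
  spectra <- list.files(file.path(dir, "spectra"), pattern = "\\.csv$")
  longs <- grep("_long", spectra, value = TRUE)
  expect_length(longs, 6)
  expect_true(all(sub("_long", "_short", longs) %in% spectra))
  for (f in longs) {
    sp_long <- read_spectrum(file.path(dir, "spectra", f))
    sp_short <- read_spectrum(file.path(dir, "spectra",
                                        sub("_long", "_short", f)))
    expect_identical(sp_long$led_id, sp_short$led_id)
  }
})
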