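#' Simulate a 90-degree-geometry detector spectrum
#'
#' Optical forward model of the vial as seen by the fibre-coupled
#' spectrometer. Expected counts are linear in exposure time and are the sum
#' of two terms:
#' \itemize{
#'   \item elastic scattering of the excitation LED line by all particles in
#'     the beam (target cells, contaminants and a fixed medium/vial floor),
#'     linear in total particle density;
#'   \item Gaussian pigment emission bands, proportional to biomass, pigment
#'     content per cell, the transient yield modifier and the
#'     LED/absorption-band overlap ([excitation_efficiency()]).
#' }
#' Poisson shot noise and Gaussian read noise are applied when enabled, and
#' counts are clipped at the detector ceiling (clipped samples are flagged
#' saturated).
#'
#' @param state A [culture_state()].
#' @param channel A [led_channel()], or `NULL` for a dark capture.
#' @param exposure_s Exposure time (s), `> 0`.
#' @param detector A [spectrometer()].
#' @param config A [scenario_config()] supplying the optical constants
#'   (`scatter_coeff`, `medium_scatter_cells_equiv`) and noise parameters.
#' @param pigments Named list of [fluorophore()] objects; names must match
#'   `state$pigment_per_cell`. Default [vivo_pigments()].
#' @param noise Logical master switch; `FALSE` forces a noise-free spectrum
#'   regardless of `config`.
#' @return A [spectrum()] stamped with the state clock and LED id.
#' @export
simulate_spectrum <- function(state, channel, exposure_s,
                              detector = spectrometer(),
                              config = scenario_config("calibration"),
                              pigments = vivo_pigments(),
                              noise = TRUE) {
  stopifnot(inherits(state, "culture_state"), exposure_s > 0,
            inherits(detector, "spectrometer"))
  grid <- detector$grid_nm
  expected <- numeric(length(grid))
  led_on <- !is.null(channel) && channel$enabled
  if (led_on) {
    total_particles <- state$biomass_cells_per_ul +
      state$contaminant_cells_per_ul + config$medium_scatter_cells_equiv
    expected <- config$scatter_coeff * total_particles *
      led_emission(channel, grid)
    for (nm in names(state$pigment_per_cell)) {
      fl <- pigments[[nm]]
      if (is.null(fl)) next
      amp <- fl$brightness * state$pigment_per_cell[[nm]] *
        state$biomass_cells_per_ul * state$yield_modifier *
        excitation_efficiency(fl, channel)
      if (amp > 0) {
        sig <- fwhm_to_sigma(fl$emission_width_nm)
        expected <- expected +
          amp * exp(-(grid - fl$emission_max_nm)^2 / (2 * sig^2))
      }
    }
    expected <- expected * exposure_s
  }
  counts <- expected
  if (isTRUE(noise)) {
    if (isTRUE(config$shot_noise)) counts <- stats::rpois(length(counts),
                                                          counts)
    if (config$read_noise_sd > 0)
      counts <- counts + stats::rnorm(length(counts), 0,
                                      config$read_noise_sd)
  }
  counts <- pmin(pmax(counts, 0), detector$saturation_counts)
  spectrum(grid, counts, exposure_s,
           saturation_counts = detector$saturation_counts,
           timestamp = state$time_h,
           led_id = if (led_on) channel$led_id else "none")
}

# ---- simulated instrument backend ------------------------------------------

#' Simulated photobioreactor backend
#'
#' Implements the instrument interface (LED switching, photoperiod lights,
#' OD job pause/resume, spectral capture, OD readout) against the optical
#' forward model and culture dynamics, on a simulated clock. A real-hardware
#' backend would provide the same generics.
#'
#' Mutual exclusion is enforced at the driver level: at most one excitation
#' LED can be on, and never together with the photoperiod lights.
#'
#' @param config A [scenario_config()].
#' @param state Initial [culture_state()]; contamination runs are seeded
#'   with `config$contaminant_seed_cells_per_ul` on the first step.
#' @param detector A [spectrometer()].
#' @param bank Named list of [led_channel()]s; default [default_led_bank()].
#' @param pigments Pigment set for the forward model.
#' @param stirring_rpm Stirrer speed, must lie in \[100, 1000\] RPM.
#' @param photoperiod_schedule Named numeric `c(light =, dark =)` summing to
#'   24 h; default 16:8.
#' @param fault Optional fault injection: `list(op =, count =)` makes the
#'   `count`-th invocation of `op` (one of `"set_led_on"`, `"set_led_off"`,
#'   `"capture"`, `"pause_od"`, `"resume_od"`, `"set_lights"`) fail.
#' @return An environment of class `"phantom_backend"`.
#' @export
phantom_backend <- function(config = scenario_config("growth"),
                            state = culture_state(),
                            detector = spectrometer(),
                            bank = default_led_bank(),
                            pigments = vivo_pigments(),
                            stirring_rpm = 500,
                            photoperiod_schedule = c(light = 16, dark = 8),
                            fault = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(state, "culture_state"))
  if (stirring_rpm < 100 || stirring_rpm > 1000)
    stop("stirring_rpm must lie in [100, 1000]")
  if (!isTRUE(all.equal(sum(photoperiod_schedule), 24)))
    stop("photoperiod hours must sum to 24")
  bk <- new.env(parent = emptyenv())
  bk$config <- config
  bk$state <- state
  bk$detector <- detector
  bk$bank <- bank
  bk$pigments <- pigments
  bk$jobs <- list(od_job = "running", photoperiod_lights = "off",
                  stirring_rpm = stirring_rpm,
                  photoperiod_schedule = photoperiod_schedule)
  bk$active_led <- NULL
  bk$events <- list()
  bk$od_times <- numeric(0)
  bk$od_values <- numeric(0)
  bk$fault <- fault
  bk$fault_counts <- new.env(parent = emptyenv())
  class(bk) <- "phantom_backend"
  bk
}

bk_event <- function(bk, what) {
  bk$events[[length(bk$events) + 1L]] <-
    list(time_h = bk$state$time_h, event = what)
  invisible(NULL)
}

bk_maybe_fail <- function(bk, op) {
  f <- bk$fault
  if (is.null(f) || !identical(f$op, op)) return(invisible(NULL))
  n <- (if (is.null(bk$fault_counts[[op]])) 0L else bk$fault_counts[[op]]) + 1L
  bk$fault_counts[[op]] <- n
  if (n == f$count) stop("injected fault in ", op, " (invocation ", n, ")")
  invisible(NULL)
}

#' @rdname instrument-interface
#' @export
set_led <- function(backend, led_id, on) UseMethod("set_led")

#' @rdname instrument-interface
#' @export
set_photoperiod_lights <- function(backend, on)
  UseMethod("set_photoperiod_lights")

#' @rdname instrument-interface
#' @export
pause_od <- function(backend) UseMethod("pause_od")

#' @rdname instrument-interface
#' @export
resume_od <- function(backend) UseMethod("resume_od")

#' @rdname instrument-interface
#' @export
capture <- function(backend, exposure_s) UseMethod("capture")

#' @rdname instrument-interface
#' @export
od_reading <- function(backend) UseMethod("od_reading")

#' @rdname instrument-interface
#' @export
jobs_state <- function(backend) UseMethod("jobs_state")

#' @rdname instrument-interface
#' @export
advance_clock <- function(backend, dt_h, record_od = TRUE)
  UseMethod("advance_clock")

#' Instrument interface
#'
#' The driver contract shared by the simulated backend and any real-hardware
#' backend: switch one excitation LED at a time, gate the photoperiod
#' lights, pause/resume the optical-density job, capture a spectrum at a
#' given exposure, read OD, report job state, and (simulated backends only)
#' advance the clock, stepping the culture dynamics and logging OD at the
#' 5-second instrument cadence.
#'
#' @param backend A backend object, e.g. [phantom_backend()].
#' @param led_id LED channel identifier.
#' @param on Logical switch state.
#' @param exposure_s Capture exposure (s).
#' @param dt_h Simulated hours to advance.
#' @param record_od Log OD readings while advancing.
#' @name instrument-interface
NULL

#' @export
set_led.phantom_backend <- function(backend, led_id, on) {
  if (!led_id %in% names(backend$bank)) stop("unknown LED id: ", led_id)
  bk_maybe_fail(backend, if (on) "set_led_on" else "set_led_off")
  if (on) {
    if (!is.null(backend$active_led) &&
        !identical(backend$active_led, led_id))
      stop("another excitation LED is already on: ", backend$active_led)
    if (backend$jobs$photoperiod_lights == "on")
      stop("cannot drive an excitation LED with the photoperiod lights on")
    backend$active_led <- led_id
  } else if (identical(backend$active_led, led_id)) {
    backend$active_led <- NULL
  }
  bk_event(backend, paste0("led:", led_id, ":", if (on) "on" else "off"))
  invisible(backend)
}

#' @export
set_photoperiod_lights.phantom_backend <- function(backend, on) {
  bk_maybe_fail(backend, "set_lights")
  if (on && !is.null(backend$active_led))
    stop("cannot switch photoperiod lights on while an excitation LED is on")
  backend$jobs$photoperiod_lights <- if (on) "on" else "off"
  bk_event(backend, paste0("lights:", if (on) "on" else "off"))
  invisible(backend)
}

#' @export
pause_od.phantom_backend <- function(backend) {
  bk_maybe_fail(backend, "pause_od")
  backend$jobs$od_job <- "paused"
  bk_event(backend, "od:paused")
  invisible(backend)
}

#' @export
resume_od.phantom_backend <- function(backend) {
  bk_maybe_fail(backend, "resume_od")
  backend$jobs$od_job <- "running"
  bk_event(backend, "od:running")
  invisible(backend)
}

#' @export
capture.phantom_backend <- function(backend, exposure_s) {
  bk_maybe_fail(backend, "capture")
  ch <- if (is.null(backend$active_led)) NULL else
    backend$bank[[backend$active_led]]
  sp <- simulate_spectrum(backend$state, ch, exposure_s,
                          detector = backend$detector,
                          config = backend$config,
                          pigments = backend$pigments)
  backend$state$time_h <- backend$state$time_h + exposure_s / 3600
  sp
}

#' @export
od_reading.phantom_backend <- function(backend) {
  read_od(backend$state, od_gain = backend$config$od_gain,
          noise_sd = backend$config$od_noise_sd)
}

#' @export
jobs_state.phantom_backend <- function(backend) backend$jobs

#' @export
advance_clock.phantom_backend <- function(backend, dt_h, record_od = TRUE) {
  stopifnot(dt_h > 0)
  cfg <- backend$config
  step <- cfg$dt_h
  n_steps <- max(1L, round(dt_h / step))
  step <- dt_h / n_steps
  od_per_step <- max(1L, round(step * 720))  # 5 s instrument cadence
  for (i in seq_len(n_steps)) {
    backend$state <- step_culture(backend$state, cfg, step)
    if (record_od && backend$jobs$od_job == "running") {
      base <- cfg$od_gain * (backend$state$biomass_cells_per_ul +
                               backend$state$contaminant_cells_per_ul)
      vals <- base + if (cfg$od_noise_sd > 0)
        stats::rnorm(od_per_step, 0, cfg$od_noise_sd) else 0
      times <- backend$state$time_h - step +
        step * seq_len(od_per_step) / od_per_step
      backend$od_times <- c(backend$od_times, times)
      backend$od_values <- c(backend$od_values, vals)
    }
    # photoperiod lights follow the programmed light:dark schedule
    sched <- backend$jobs$photoperiod_schedule
    in_light <- (backend$state$time_h %% 24) < sched[["light"]]
    backend$jobs$photoperiod_lights <- if (in_light) "on" else "off"
  }
  invisible(backend)
}

# ---- calibration ------------------------------------------------------------

#' Generate a fluorescence calibration series
#'
#' Runs the full dual-exposure acquisition pipeline on vials prepared at
#' known cell concentrations (default pigment load) plus blank replicates
#' (medium only), and returns the scattering-corrected fluorescence index
#' for each. Input for [estimate_lod()].
#'
#' @param concentrations Cell concentrations (cells/uL), `>= 0`.
#' @param n_blanks Number of blank replicates, `>= 3`.
#' @param config A [scenario_config()]; the calibration scenario is forced.
#' @param led_id Excitation channel; default `"led615"` (phycocyanin).
#' @param detector,bank,pigments Instrument definition as in
#'   [phantom_backend()].
#' @param short_s,long_s Dual exposures (s).
#' @param fluor_band Emission integration window.
#' @return List with `calibration` (data.frame of `concentration`, `index`),
#'   `blanks` (numeric vector), `led_id` and `seed`.
#' @export
generate_calibration_series <- function(concentrations, n_blanks = 10,
                                        config = scenario_config("calibration"),
                                        led_id = "led615",
                                        detector = spectrometer(),
                                        bank = default_led_bank(),
                                        pigments = vivo_pigments(),
                                        short_s = 0.1, long_s = 5,
                                        fluor_band = phycocyanin_band()) {
  stopifnot(all(concentrations >= 0), n_blanks >= 3)
  config$scenario <- "calibration"
  one_index <- function(conc) {
    st <- culture_state(biomass_cells_per_ul = conc)
    bk <- phantom_backend(config = config, state = st, detector = detector,
                          bank = bank, pigments = pigments)
    pair <- measurement_round(bk, led_id, short_s = short_s,
                              long_s = long_s)[[1]]
    fluorescence_index(pair, fluor_band = fluor_band)
  }
  idx <- vapply(concentrations, one_index, numeric(1))
  blanks <- vapply(rep(0, n_blanks), one_index, numeric(1))
  list(calibration = data.frame(concentration = concentrations, index = idx),
       blanks = blanks, led_id = led_id, seed = config$seed)
}
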