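#' Dual-exposure measurement pair
#'
#' The two captures taken for one excitation LED in one measurement round: a
#' short exposure resolving the scattered LED peak (which saturates at the
#' long exposure) and a long exposure resolving the much weaker fluorescence.
#'
#' @param led_id Excitation channel identifier shared by both spectra.
#' @param short,long [spectrum()] objects; `short$exposure_s` must be less
#'   than `long$exposure_s` and both must share the LED id and grid.
#' @param round_index Measurement-round counter.
#' @param timestamp Round timestamp (simulated hours).
#' @param led_peak_nm Optional LED peak wavelength, letting
#'   [fluorescence_index()] derive its default LED window.
#' @return An object of class `"measurement_pair"`.
#' @export
measurement_pair <- function(led_id, short, long, round_index = NA_integer_,
                             timestamp = NA_real_, led_peak_nm = NULL) {
  stopifnot(inherits(short, "spectrum"), inherits(long, "spectrum"))
  if (!(short$exposure_s < long$exposure_s))
    stop("short exposure must be shorter than the long exposure")
  if (!identical(short$led_id, led_id) || !identical(long$led_id, led_id))
    stop("both spectra must carry led_id '", led_id, "'")
  if (!isTRUE(all.equal(short$wavelengths_nm, long$wavelengths_nm)))
    stop("short and long spectra must share the wavelength grid")
  structure(list(led_id = led_id, short = short, long = long,
                 round_index = round_index, timestamp = timestamp,
                 led_peak_nm = led_peak_nm),
            class = "measurement_pair")
}

#' Run one measurement round
#'
#' The acquisition protocol for a single round: pause the optical-density
#' job and force the photoperiod lights off, then drive each requested LED
#' strictly one at a time, capturing the short/long exposure pair for each,
#' and finally restore the jobs and light state. Restoration is guaranteed
#' even when a capture fails; on failure the round is aborted, pairs
#' completed so far are kept, and the failure is recorded in the
#' `"failures"` attribute of the result.
#'
#' @param backend An instrument backend (see [instrument-interface]).
#' @param leds Character vector of LED ids to drive, in order.
#' @param short_s Short (excitation-peak) exposure, default 0.1 s.
#' @param long_s Long (fluorescence) exposure, default 5 s.
#' @param round_index Round counter stamped on the pairs.
#' @return List of [measurement_pair()]s in LED order, with attribute
#'   `"failures"` (character vector of failure messages, possibly empty).
#' @export
measurement_round <- function(backend, leds, short_s = 0.1, long_s = 5,
                              round_index = 1L) {
  if (length(leds) == 0) stop("leds must name at least one channel")
  if (!(short_s > 0 && long_s > short_s))
    stop("exposures must satisfy 0 < short_s < long_s")
  bank <- backend$bank
  unknown <- setdiff(leds, names(bank))
  if (length(unknown))
    stop("unknown LED id(s): ", paste(unknown, collapse = ", "))

  pre_jobs <- jobs_state(backend)
  od_was_running <- pre_jobs$od_job == "running"
  lights_were_on <- pre_jobs$photoperiod_lights == "on"
  if (od_was_running) pause_od(backend)
  # guaranteed restoration, whatever happens mid-round
  on.exit({
    if (!is.null(backend$active_led))
      try(set_led(backend, backend$active_led, FALSE), silent = TRUE)
    try(set_photoperiod_lights(backend, lights_were_on), silent = TRUE)
    if (od_was_running) try(resume_od(backend), silent = TRUE)
  }, add = TRUE)
  if (lights_were_on) set_photoperiod_lights(backend, FALSE)

  pairs <- list()
  failures <- character(0)
  for (id in leds) {
    t0 <- backend$state$time_h
    ok <- tryCatch({
      set_led(backend, id, TRUE)
      short <- capture(backend, short_s)
      long <- capture(backend, long_s)
      set_led(backend, id, FALSE)
      pairs[[length(pairs) + 1L]] <-
        measurement_pair(id, short, long, round_index = round_index,
                         timestamp = t0,
                         led_peak_nm = bank[[id]]$peak_nm)
      TRUE
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("round %d led %s: %s", round_index, id,
                             conditionMessage(e)))
      FALSE
    })
    if (!ok) break  # abort the round; completed pairs are kept
  }
  attr(pairs, "failures") <- failures
  pairs
}

#' Run the scheduled fluorescence monitor
#'
#' Executes measurement rounds at a fixed cadence on the simulated clock,
#' computing the scattering-corrected fluorescence index after each round
#' and logging optical density between rounds at the 5-second instrument
#' cadence. When `sink` names a directory, every spectrum, the index
#' time-series, the OD log, a config snapshot and the run log are persisted
#' there (see [export_run()] for the layout).
#'
#' @param backend An instrument backend (see [instrument-interface]).
#' @param duration_h Total simulated run time (h).
#' @param schedule_interval_min Minutes between round starts; must exceed
#'   the round duration. Default 60.
#' @param leds LED ids per round; default all enabled channels in the bank.
#' @param short_s,long_s Dual exposures (s).
#' @param fluor_band Emission window for the index; default
#'   [phycocyanin_band()].
#' @param sink Optional output directory.
#' @return An object of class `"phycomon_run"`: list with `fluor`
#'   (data.frame `time_h`, `round`, `led_id`, `index`), `od` (data.frame
#'   `time_h`, `od`), `failures`, `n_rounds`, `leds` and the backend
#'   `config`.
#' @export
run_monitor <- function(backend, duration_h, schedule_interval_min = 60,
                        leds = NULL, short_s = 0.1, long_s = 5,
                        fluor_band = phycocyanin_band(), sink = NULL) {
  if (is.null(leds))
    leds <- names(Filter(function(ch) ch$enabled, backend$bank))
  round_duration_s <- length(leds) * (short_s + long_s)
  if (schedule_interval_min * 60 <= round_duration_s)
    stop("schedule interval (", schedule_interval_min,
         " min) must exceed the round duration (", round_duration_s, " s)")
  interval_h <- schedule_interval_min / 60
  if (!is.null(sink)) {
    dir.create(file.path(sink, "spectra"), recursive = TRUE,
               showWarnings = FALSE)
  }
  log_lines <- character(0)
  logf <- function(round, fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[t=%0.3f h] [round %d] %s",
                                       backend$state$time_h, round,
                                       sprintf(fmt, ...)))
  }
  fluor <- list()
  failures <- character(0)
  round_idx <- 0L
  t_next <- 0
  while (t_next < duration_h) {
    round_idx <- round_idx + 1L
    logf(round_idx, "starting measurement round (%d LEDs)", length(leds))
    pairs <- measurement_round(backend, leds, short_s = short_s,
                               long_s = long_s, round_index = round_idx)
    fl <- attr(pairs, "failures")
    if (length(fl)) {
      failures <- c(failures, fl)
      for (msg in fl) logf(round_idx, "FAILURE %s", msg)
    }
    for (pair in pairs) {
      idx <- tryCatch(fluorescence_index(pair, fluor_band = fluor_band),
                      error = function(e) {
                        logf(round_idx, "index failed for %s: %s",
                             pair$led_id, conditionMessage(e))
                        NA_real_
                      })
      fluor[[length(fluor) + 1L]] <-
        data.frame(time_h = pair$timestamp, round = round_idx,
                   led_id = pair$led_id, index = idx)
      if (!is.null(sink)) write_pair(pair, file.path(sink, "spectra"))
    }
    logf(round_idx, "round complete (%d/%d pairs)", length(pairs),
         length(leds))
    advance_clock(backend, interval_h)
    t_next <- t_next + interval_h
  }
  run <- structure(
    list(fluor = if (length(fluor)) do.call(rbind, fluor) else
           data.frame(time_h = numeric(0), round = integer(0),
                      led_id = character(0), index = numeric(0)),
         od = data.frame(time_h = backend$od_times, od = backend$od_values),
         failures = failures, n_rounds = round_idx, leds = leds,
         config = backend$config, log = log_lines),
    class = "phycomon_run")
  if (!is.null(sink)) write_run(run, sink)
  run
}

#' @export
print.phycomon_run <- function(x, ...) {
  cat(sprintf("<phycomon_run> %d rounds | %d index values | %d OD readings | %d failures\n",
              x$n_rounds, nrow(x$fluor), nrow(x$od), length(x$failures)))
  invisible(x)
}
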