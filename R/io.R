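fmt9 <- function(x) formatC(x, digits = 9, format = "g")

#' Write a spectrum as CSV plus JSON metadata sidecar
#'
#' The CSV carries `wavelength_nm,intensity` at 9 significant digits
#' (round-trip safe); acquisition metadata (exposure, LED id, timestamp,
#' detector ceiling) goes into `<path>.json`.
#'
#' @param spec A [spectrum()].
#' @param path CSV file path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  df <- data.frame(wavelength_nm = fmt9(spec$wavelengths_nm),
                   intensity = fmt9(spec$intensities))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(exposure_s = spec$exposure_s,
               saturation_counts = spec$saturation_counts,
               timestamp = spec$timestamp, led_id = spec$led_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path CSV file path with its `.json` sidecar alongside.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spectrum(df$wavelength_nm, df$intensity, meta$exposure_s,
           saturation_counts = meta$saturation_counts,
           timestamp = meta$timestamp, led_id = meta$led_id)
}

write_pair <- function(pair, dir) {
  base <- sprintf("%03d_%s", pair$round_index, pair$led_id)
  write_spectrum(pair$short, file.path(dir, paste0(base, "_short.csv")))
  write_spectrum(pair$long, file.path(dir, paste0(base, "_long.csv")))
  invisible(base)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fl <- run$fluor
  fl$index <- fmt9(fl$index)
  fl$time_h <- fmt9(fl$time_h)
  utils::write.csv(fl, file.path(dir, "fluorescence_index.csv"),
                   row.names = FALSE, quote = FALSE)
  od <- run$od
  od$time_h <- fmt9(od$time_h)
  od$od <- fmt9(od$od)
  utils::write.csv(od, file.path(dir, "od_readings.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(unclass(run$config), file.path(dir, "run_config.yaml"))
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Export / manifest a run directory
#'
#' Verifies the deterministic artifact layout written by [run_monitor()]
#' (`spectra/<round>_<led>_<short|long>.csv` with JSON sidecars,
#' `fluorescence_index.csv`, `od_readings.csv`, `run_config.yaml`,
#' `run.log`) and writes `manifest.json` listing every artifact plus any
#' incomplete rounds (rounds whose persisted spectra lack a short/long
#' partner, e.g. after an aborted round). Re-running the export is
#' idempotent.
#'
#' @param rundir Run directory.
#' @return The manifest (list), invisibly.
#' @export
export_run <- function(rundir) {
  if (!dir.exists(rundir)) stop("run directory not found: ", rundir)
  files <- sort(list.files(rundir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  spectra <- grep("^spectra/.*\\.csv$", files, value = TRUE)
  key <- sub("_(short|long)\\.csv$", "", basename(spectra))
  incomplete <- sort(unique(key[table(key)[key] != 2]))
  logfile <- file.path(rundir, "run.log")
  if (file.exists(logfile)) {
    fails <- grep("FAILURE", readLines(logfile), value = TRUE)
    incomplete <- c(incomplete, sub(".*FAILURE ", "", fails))
  }
  manifest <- list(files = files,
                   n_spectra = length(spectra),
                   incomplete_rounds = incomplete,
                   complete = length(incomplete) == 0)
  jsonlite::write_json(manifest, file.path(rundir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# ---- run configuration ------------------------------------------------------

default_run_config <- function() {
  list(
    scenario = "growth",
    seed = 1L,
    interval_min = 60,
    duration_h = 24,
    leds = NULL,            # NULL -> full default bank
    measure_leds = "led615",
    outdir = NULL,
    exposures = list(short_s = 0.1, long_s = 5.0),
    spectrometer = list(range_nm = c(225, 1000), step_nm = 1.5,
                        saturation_counts = 65535),
    bands = list(fluor_lo_nm = 640, fluor_hi_nm = 680,
                 led_half_width_nm = 10),
    initial = list(biomass_cells_per_ul = 200,
                   contaminant_cells_per_ul = 0),
    dynamics = list()       # overrides for scenario_config()
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])) && nm != "dynamics" && nm != "leds")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Assemble and validate a run configuration
#'
#' Fills every omitted field with its default (the six-channel LED bank,
#' 225--1000 nm / 1.5 nm spectrometer, 0.1 s / 5 s exposures, 60 min
#' schedule, 640--680 nm phycocyanin window) and validates the result.
#' Unknown keys are rejected.
#'
#' @param ... Named overrides of the default fields (schema: `scenario`, `seed`,
#'   `interval_min`, `duration_h`, `leds`, `measure_leds`, `outdir`,
#'   `exposures`, `spectrometer`, `bands`, `initial`, `dynamics`).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- merge_config(default_run_config(), list(...))
  with(cfg$exposures, {
    if (!(short_s > 0 && long_s > 0))
      stop("config field exposures: both exposures must be positive")
    if (short_s >= long_s)
      stop("config field exposures: short_s must be less than long_s")
  })
  sp <- cfg$spectrometer
  if (sp$step_nm <= 0) stop("config field spectrometer.step_nm must be > 0")
  if (sp$range_nm[1] < 225 || sp$range_nm[2] > 1000)
    stop("config field spectrometer.range_nm must lie within 225-1000 nm")
  if (cfg$bands$fluor_lo_nm >= cfg$bands$fluor_hi_nm)
    stop("config field bands: fluor_lo_nm must be below fluor_hi_nm")
  if (cfg$interval_min <= 0)
    stop("config field interval_min must be positive")
  cfg$scenario <- match.arg(cfg$scenario,
                            c("growth", "photoinhibition", "contamination",
                              "calibration"))
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file; any subset of the [run_config()] fields.
#' @return A validated [run_config()] with defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  do.call(run_config, user)
}

config_bank <- function(cfg) {
  if (is.null(cfg$leds)) return(default_led_bank())
  bank <- lapply(cfg$leds, function(l)
    led_channel(l$id, l$peak_nm, l$radiant_power_mw,
                fwhm_nm = if (is.null(l$fwhm_nm)) 20 else l$fwhm_nm,
                enabled = if (is.null(l$enabled)) TRUE else l$enabled))
  names(bank) <- vapply(bank, function(ch) ch$led_id, character(1))
  bank
}

config_backend <- function(cfg) {
  scn <- do.call(scenario_config,
                 c(list(scenario = cfg$scenario, seed = cfg$seed),
                   cfg$dynamics))
  det <- spectrometer(range_nm = cfg$spectrometer$range_nm,
                      step_nm = cfg$spectrometer$step_nm,
                      saturation_counts = cfg$spectrometer$saturation_counts)
  st <- culture_state(
    biomass_cells_per_ul = cfg$initial$biomass_cells_per_ul,
    contaminant_cells_per_ul = cfg$initial$contaminant_cells_per_ul)
  phantom_backend(config = scn, state = st, detector = det,
                  bank = config_bank(cfg))
}

#' Simulate a complete monitored run from a configuration
#'
#' Seeds the RNG from the config, builds the simulated backend and executes
#' [run_monitor()]. Identical configuration and seed give byte-identical
#' persisted artifacts.
#'
#' @param cfg A [run_config()] (or the path of a YAML file).
#' @param sink Output directory; defaults to `cfg$outdir` (no persistence
#'   when both are `NULL`).
#' @return The `"phycomon_run"` object.
#' @export
simulate_run <- function(cfg, sink = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(sink)) sink <- cfg$outdir
  set.seed(cfg$seed)
  backend <- config_backend(cfg)
  run_monitor(backend,
              duration_h = cfg$duration_h,
              schedule_interval_min = cfg$interval_min,
              leds = cfg$measure_leds,
              short_s = cfg$exposures$short_s,
              long_s = cfg$exposures$long_s,
              fluor_band = band(cfg$bands$fluor_lo_nm,
                                cfg$bands$fluor_hi_nm),
              sink = sink)
}

#' Read a persisted run back as a joint series
#'
#' Reads `fluorescence_index.csv` and `od_readings.csv` from a run
#' directory and assembles the [fluor_series()] for one LED.
#'
#' @param rundir Run directory written by [run_monitor()]/[simulate_run()].
#' @param led_id Channel to extract; default `"led615"`.
#' @return A [fluor_series()].
#' @export
read_run_series <- function(rundir, led_id = "led615") {
  fl <- utils::read.csv(file.path(rundir, "fluorescence_index.csv"))
  od <- utils::read.csv(file.path(rundir, "od_readings.csv"))
  fl <- fl[fl$led_id == led_id & !is.na(fl$index), ]
  if (nrow(fl) == 0) stop("no index values for LED ", led_id)
  odv <- if (nrow(od) >= 2)
    stats::approx(od$time_h, od$od, xout = fl$time_h, rule = 2)$y
  else rep(NA_real_, nrow(fl))
  fluor_series(fl$time_h, fl$index, odv, led_id = led_id)
}

#' Trend plot of a monitored run
#'
#' Static two-panel plot (normalized OD and normalized fluorescence index
#' against time) of the kind used to judge culture health at a glance.
#' Requires ggplot2.
#'
#' @param series A [fluor_series()].
#' @param file Optional output file (PNG/SVG/PDF by extension).
#' @return The ggplot object, invisibly.
#' @export
plot_series <- function(series, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_series requires the ggplot2 package")
  ns <- normalize_series(series)
  df <- rbind(
    data.frame(time_h = ns$times_h, value = ns$od_values,
               trace = "normalized OD"),
    data.frame(time_h = ns$times_h, value = ns$index_values,
               trace = "normalized fluorescence"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~trace, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "relative value",
                  title = paste("Culture trend,", series$led_id)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 5)
  invisible(p)
}
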