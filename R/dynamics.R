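#' Culture state
#'
#' The instantaneous state of the vial contents, advanced by [step_culture()]
#' and rendered into spectra by [simulate_spectrum()]. Pigment contents are
#' relative to a healthy culture (1 = healthy load per cell).
#'
#' @param biomass_cells_per_ul Target-organism density (cells/uL).
#' @param pigment_per_cell Named numeric vector of relative pigment content
#'   per cell; names must match the pigment set used by the forward model.
#' @param contaminant_cells_per_ul Density of non-fluorescent contaminating
#'   scatterers (cells/uL).
#' @param yield_modifier Dimensionless transient fluorescence-yield factor
#'   (`>= 0`; 1 = baseline quantum yield).
#' @param time_h Culture clock in hours.
#' @return An object of class `"culture_state"`.
#' @export
culture_state <- function(biomass_cells_per_ul = 200,
                          pigment_per_cell = c(phycocyanin = 1,
                                               chlorophyll = 1),
                          contaminant_cells_per_ul = 0,
                          yield_modifier = 1, time_h = 0) {
  stopifnot(biomass_cells_per_ul >= 0, all(pigment_per_cell >= 0),
            contaminant_cells_per_ul >= 0, yield_modifier >= 0)
  structure(list(biomass_cells_per_ul = biomass_cells_per_ul,
                 pigment_per_cell = pigment_per_cell,
                 contaminant_cells_per_ul = contaminant_cells_per_ul,
                 yield_modifier = yield_modifier,
                 time_h = time_h),
            class = "culture_state")
}

#' Scenario configuration for the culture dynamics
#'
#' Bundles the kinetic parameters of the four supported scenarios together
#' with the optical and noise parameters of the simulated instrument.
#'
#' Scenarios:
#' \describe{
#'   \item{growth}{logistic biomass growth, constant pigments, yield 1.}
#'   \item{photoinhibition}{under irradiance above `critical_irradiance_umol`
#'     the fluorescence yield shows a transient pulse
#'     `1 + A (1 - exp(-k_r t)) exp(-k_y t)` while pigment per cell decays
#'     exponentially; biomass declines once the phycocyanin load drops below
#'     `viability_fraction`.}
#'   \item{contamination}{target biomass static, pigment per cell decays,
#'     and a non-fluorescent contaminant grows logistically, contributing to
#'     scattering (and hence OD) only.}
#'   \item{calibration}{static state (no dynamics).}
#' }
#'
#' @param scenario One of `"growth"`, `"photoinhibition"`,
#'   `"contamination"`, `"calibration"`.
#' @param growth_rate_per_h Logistic growth rate of the target organism
#'   (1/h); default 0.03 (doubling time roughly one day).
#' @param carrying_capacity Logistic carrying capacity (cells/uL).
#' @param irradiance_umol Photon flux (umol photons m^-2 s^-1); defaults to
#'   60 except for the photoinhibition scenario, which defaults to 300.
#' @param critical_irradiance_umol Threshold above which photoinhibition
#'   kinetics act; default 150.
#' @param pigment_decay_per_h Exponential pigment degradation rate (1/h)
#'   under photoinhibition or contamination stress; default 0.18.
#' @param yield_pulse_amplitude Amplitude A of the transient yield pulse.
#' @param yield_pulse_rise_per_h Rise rate k_r of the yield pulse (1/h).
#' @param yield_pulse_decay_per_h Decay rate k_y of the yield pulse (1/h).
#' @param viability_fraction Phycocyanin load (relative to healthy) below
#'   which cells start dying; default 0.3.
#' @param death_rate_per_h Exponential biomass decline rate once viability
#'   is lost (1/h); default 0.05.
#' @param contaminant_growth_rate_per_h Logistic growth rate of the
#'   contaminant (1/h); default 0.25 (fast heterotroph).
#' @param contaminant_seed_cells_per_ul Contaminant inoculum applied when a
#'   contamination run starts; default 5.
#' @param scatter_coeff Scattered counts per second per mW/nm of LED
#'   spectral density per cell/uL; default 2.
#' @param medium_scatter_cells_equiv Scattering of the blank culture medium
#'   and vial, expressed as an equivalent particle density (cells/uL);
#'   default 50.
#' @param read_noise_sd Gaussian detector read noise (counts); default 5.
#' @param shot_noise Logical, Poisson shot noise on expected counts.
#' @param od_gain OD reading per cell/uL of total particle density.
#' @param od_noise_sd Gaussian noise on OD readings (a.u.).
#' @param dt_h Forward-Euler time step (h); default 0.1.
#' @param seed RNG seed recorded with every run.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("growth", "photoinhibition",
                                         "contamination", "calibration"),
                            growth_rate_per_h = 0.03,
                            carrying_capacity = 2000,
                            irradiance_umol = NULL,
                            critical_irradiance_umol = 150,
                            pigment_decay_per_h = 0.18,
                            yield_pulse_amplitude = 0.6,
                            yield_pulse_rise_per_h = 1.5,
                            yield_pulse_decay_per_h = 0.3,
                            viability_fraction = 0.3,
                            death_rate_per_h = 0.05,
                            contaminant_growth_rate_per_h = 0.25,
                            contaminant_seed_cells_per_ul = 5,
                            scatter_coeff = 2,
                            medium_scatter_cells_equiv = 50,
                            read_noise_sd = 5,
                            shot_noise = TRUE,
                            od_gain = 0.001,
                            od_noise_sd = 0.002,
                            dt_h = 0.1,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(irradiance_umol))
    irradiance_umol <- if (scenario == "photoinhibition") 300 else 60
  cfg <- list(scenario = scenario,
              growth_rate_per_h = growth_rate_per_h,
              carrying_capacity = carrying_capacity,
              irradiance_umol = irradiance_umol,
              critical_irradiance_umol = critical_irradiance_umol,
              pigment_decay_per_h = pigment_decay_per_h,
              yield_pulse_amplitude = yield_pulse_amplitude,
              yield_pulse_rise_per_h = yield_pulse_rise_per_h,
              yield_pulse_decay_per_h = yield_pulse_decay_per_h,
              viability_fraction = viability_fraction,
              death_rate_per_h = death_rate_per_h,
              contaminant_growth_rate_per_h = contaminant_growth_rate_per_h,
              contaminant_seed_cells_per_ul = contaminant_seed_cells_per_ul,
              scatter_coeff = scatter_coeff,
              medium_scatter_cells_equiv = medium_scatter_cells_equiv,
              read_noise_sd = read_noise_sd,
              shot_noise = shot_noise,
              od_gain = od_gain,
              od_noise_sd = od_noise_sd,
              dt_h = dt_h,
              seed = seed)
  rates <- cfg[grepl("_per_h$|^scatter_coeff$|^od_gain$", names(cfg))]
  if (any(unlist(rates) < 0)) stop("rates must be non-negative")
  if (carrying_capacity <= 0) stop("carrying_capacity must be positive")
  structure(cfg, class = "scenario_config")
}

#' Transient fluorescence-yield pulse under photoinhibition
#'
#' `1 + A (1 - exp(-k_r t)) exp(-k_y t)`: unity at stress onset, a rise over
#' the first hours (excess absorbed energy re-emitted as fluorescence while
#' photochemical quenching fails), then relaxation back to baseline.
#'
#' @param t_h Hours since stress onset.
#' @param config A [scenario_config()].
#' @return Dimensionless yield factor `>= 1`.
#' @export
yield_pulse <- function(t_h, config) {
  1 + config$yield_pulse_amplitude *
    (1 - exp(-config$yield_pulse_rise_per_h * t_h)) *
    exp(-config$yield_pulse_decay_per_h * t_h)
}

#' Advance the culture state by one time step
#'
#' Forward-Euler update of the scenario kinetics described in
#' [scenario_config()]; the discretization error is O(dt). All densities
#' and pigment contents stay non-negative.
#'
#' @param state A [culture_state()].
#' @param config A [scenario_config()].
#' @param dt_h Time step in hours, `> 0`; defaults to `config$dt_h`.
#' @return The updated [culture_state()] with `time_h` advanced.
#' @export
step_culture <- function(state, config, dt_h = config$dt_h) {
  stopifnot(inherits(state, "culture_state"),
            inherits(config, "scenario_config"), dt_h > 0)
  B <- state$biomass_cells_per_ul
  P <- state$pigment_per_cell
  C <- state$contaminant_cells_per_ul
  t1 <- state$time_h + dt_h
  K <- config$carrying_capacity
  switch(config$scenario,
    growth = {
      B <- B + config$growth_rate_per_h * B * (1 - B / K) * dt_h
      state$yield_modifier <- 1
    },
    photoinhibition = {
      if (config$irradiance_umol > config$critical_irradiance_umol) {
        P <- P * pmax(0, 1 - config$pigment_decay_per_h * dt_h)
        state$yield_modifier <- yield_pulse(t1, config)
        if (P[["phycocyanin"]] < config$viability_fraction)
          B <- B * max(0, 1 - config$death_rate_per_h * dt_h)
      } else {
        B <- B + config$growth_rate_per_h * B * (1 - B / K) * dt_h
        state$yield_modifier <- 1
      }
    },
    contamination = {
      P <- P * pmax(0, 1 - config$pigment_decay_per_h * dt_h)
      if (C <= 0) C <- config$contaminant_seed_cells_per_ul
      C <- C + config$contaminant_growth_rate_per_h * C * (1 - C / K) * dt_h
      state$yield_modifier <- 1
    },
    calibration = {},
    stop("unknown scenario: ", config$scenario)
  )
  state$biomass_cells_per_ul <- max(0, B)
  state$pigment_per_cell <- pmax(P, 0)
  state$contaminant_cells_per_ul <- max(0, C)
  state$time_h <- t1
  state
}

#' Optical-density reading of the current state
#'
#' Near-infrared scattering turbidity: linear in the total particle density
#' and blind to whether the scatterer is the target organism or a
#' contaminant, plus Gaussian sensor noise. An empty vial reads 0 (readings
#' are blank-referenced).
#'
#' @param state A [culture_state()].
#' @param od_gain Reading per cell/uL; default 0.001.
#' @param noise_sd Gaussian noise SD (a.u.); default 0 (noise-free).
#' @return A single OD reading (arbitrary units).
#' @export
read_od <- function(state, od_gain = 0.001, noise_sd = 0) {
  stopifnot(inherits(state, "culture_state"))
  total <- state$biomass_cells_per_ul + state$contaminant_cells_per_ul
  od_gain * total + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
}
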