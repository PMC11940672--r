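#' Virtual spectrometer definition
#'
#' Default parameters mirror a compact CCD fluorescence spectrometer:
#' detection range 225--1000 nm, 1.5 nm spectral resolution, 16-bit counts.
#'
#' @param range_nm Length-2 numeric, detection range in nm.
#' @param step_nm Grid step (spectral resolution) in nm.
#' @param saturation_counts Detector full scale.
#' @return An object of class `"spectrometer"` with a precomputed grid.
#' @export
spectrometer <- function(range_nm = c(225, 1000), step_nm = 1.5,
                         saturation_counts = 65535) {
  stopifnot(length(range_nm) == 2, range_nm[1] < range_nm[2], step_nm > 0)
  structure(list(range_nm = as.numeric(range_nm),
                 step_nm = as.numeric(step_nm),
                 saturation_counts = as.numeric(saturation_counts),
                 grid_nm = seq(range_nm[1], range_nm[2], by = step_nm)),
            class = "spectrometer")
}

#' Excitation LED channel
#'
#' @param led_id Channel identifier.
#' @param peak_nm Emission peak wavelength (nm).
#' @param fwhm_nm Spectral full width at half maximum (nm); default 20.
#' @param radiant_power_mw Radiant power in mW.
#' @param enabled Logical; disabled channels emit nothing.
#' @return An object of class `"led_channel"`.
#' @export
led_channel <- function(led_id, peak_nm, radiant_power_mw, fwhm_nm = 20,
                        enabled = TRUE) {
  stopifnot(peak_nm > 0, fwhm_nm > 0, radiant_power_mw > 0)
  structure(list(led_id = as.character(led_id), peak_nm = as.numeric(peak_nm),
                 fwhm_nm = as.numeric(fwhm_nm),
                 radiant_power_mw = as.numeric(radiant_power_mw),
                 enabled = isTRUE(enabled)),
            class = "led_channel")
}

#' The six-channel high-power excitation LED bank
#'
#' Peaks 657, 615, 586, 520, 451 and 373 nm with radiant powers 450, 334,
#' 242, 270, 600 and 930 mW, spanning the visible/near-UV range so that the
#' major phytoplankton fluorophores can each be excited near their
#' absorption maximum.
#'
#' @param fwhm_nm Spectral width assigned to every channel (nm); default 20.
#' @return A named list of [led_channel()] objects.
#' @export
default_led_bank <- function(fwhm_nm = 20) {
  peaks <- c(657, 615, 586, 520, 451, 373)
  powers <- c(450, 334, 242, 270, 600, 930)
  ids <- paste0("led", peaks)
  bank <- Map(function(id, p, w) led_channel(id, p, w, fwhm_nm = fwhm_nm),
              ids, peaks, powers)
  names(bank) <- ids
  bank
}

#' Fluorophore reference entry
#'
#' Excitation and emission are modelled as Gaussian bands. A fluorophore may
#' carry several excitation maxima; the first is the primary one (weight 1),
#' later ones are secondary (weight 0.5) in the excitation-overlap model.
#'
#' @param name Fluorophore name.
#' @param excitation_max_nm Numeric vector of excitation maxima, primary
#'   first.
#' @param emission_max_nm Emission maximum (nm); must exceed the primary
#'   excitation maximum (Stokes shift).
#' @param excitation_width_nm FWHM of each excitation band (nm); default 25.
#' @param emission_width_nm FWHM of the emission band (nm); default 25.
#' @param brightness Relative emitted counts per unit pigment per unit
#'   excitation overlap; default 1.
#' @return An object of class `"fluorophore"`.
#' @export
fluorophore <- function(name, excitation_max_nm, emission_max_nm,
                        excitation_width_nm = 25, emission_width_nm = 25,
                        brightness = 1) {
  stopifnot(all(excitation_max_nm > 0), emission_max_nm > 0,
            excitation_width_nm > 0, emission_width_nm > 0, brightness >= 0)
  if (emission_max_nm <= excitation_max_nm[1])
    stop("emission_max_nm must exceed the primary excitation maximum")
  structure(list(name = name,
                 excitation_max_nm = as.numeric(excitation_max_nm),
                 excitation_width_nm = as.numeric(excitation_width_nm),
                 emission_max_nm = as.numeric(emission_max_nm),
                 emission_width_nm = as.numeric(emission_width_nm),
                 brightness = as.numeric(brightness)),
            class = "fluorophore")
}

#' Reference table of tested fluorophores
#'
#' Literature excitation/emission maxima for the five fluorophores used to
#' validate the instrument: quinine (349/461 nm), rhodamine 6G (525/548),
#' rhodamine B (546/567), phycocyanin (620/650) and chlorophyll a (429 and
#' 661/673; 429 is the primary maximum).
#'
#' @return A named list of [fluorophore()] objects.
#' @export
fluorophore_table <- function() {
  list(
    quinine = fluorophore("quinine", 349, 461, emission_width_nm = 60),
    rhodamine_6g = fluorophore("rhodamine_6g", 525, 548,
                               emission_width_nm = 30),
    rhodamine_b = fluorophore("rhodamine_b", 546, 567,
                              emission_width_nm = 30),
    phycocyanin = fluorophore("phycocyanin", 620, 650,
                              emission_width_nm = 25),
    chlorophyll = fluorophore("chlorophyll", c(429, 661), 673,
                              emission_width_nm = 30)
  )
}

#' In-vivo pigment set used by the culture simulator
#'
#' Inside intact cyanobacterial cells the phycocyanin emission observed
#' through the instrument peaks near 657 nm (red-shifted from the 650 nm
#' in-vitro value by phycobilisome energy coupling), with a weaker
#' chlorophyll a contribution near 700 nm.
#'
#' @return A named list of [fluorophore()] objects keyed by pigment name.
#' @export
vivo_pigments <- function() {
  list(
    phycocyanin = fluorophore("phycocyanin", 620, 657,
                              excitation_width_nm = 25,
                              emission_width_nm = 25, brightness = 1),
    chlorophyll = fluorophore("chlorophyll", c(429, 661), 695,
                              excitation_width_nm = 30,
                              emission_width_nm = 30, brightness = 0.25)
  )
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Spectral emission profile of an LED channel
#'
#' Gaussian line shape centred at the channel peak with the channel FWHM,
#' scaled so that the integral over wavelength equals the radiant power
#' (unit-area Gaussian times power). Disabled channels emit nothing.
#'
#' @param channel A [led_channel()].
#' @param grid_nm Wavelength grid (nm).
#' @return Numeric vector of spectral radiant power density (mW/nm) on the
#'   grid.
#' @export
led_emission <- function(channel, grid_nm) {
  stopifnot(inherits(channel, "led_channel"))
  if (!channel$enabled) return(numeric(length(grid_nm)) * 0)
  sigma <- fwhm_to_sigma(channel$fwhm_nm)
  channel$radiant_power_mw * stats::dnorm(grid_nm, channel$peak_nm, sigma)
}

#' Excitation efficiency of a fluorophore under an LED channel
#'
#' Overlap integral of the channel's unit-area spectral profile with the
#' fluorophore's unit-peak Gaussian excitation band(s); the primary maximum
#' is weighted 1, secondary maxima 0.5. Evaluated in closed form (integral
#' of a Gaussian density against a Gaussian bump), so the result is exact
#' and lies in \[0, 1\] for single-band fluorophores, decreasing monotonically
#' with the LED-to-absorption-peak distance.
#'
#' @param fluor A [fluorophore()].
#' @param channel A [led_channel()].
#' @return Dimensionless overlap efficiency.
#' @export
excitation_efficiency <- function(fluor, channel) {
  stopifnot(inherits(fluor, "fluorophore"), inherits(channel, "led_channel"))
  sl <- fwhm_to_sigma(channel$fwhm_nm)
  sf <- fwhm_to_sigma(fluor$excitation_width_nm)
  w <- c(1, rep(0.5, length(fluor$excitation_max_nm) - 1))
  s2 <- sl^2 + sf^2
  eff <- sum(w * sf / sqrt(s2) *
               exp(-(channel$peak_nm - fluor$excitation_max_nm)^2 / (2 * s2)))
  min(eff, 1)
}
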