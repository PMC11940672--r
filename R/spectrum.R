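#' Detector spectrum
#'
#' The atom of all spectral processing: a sampled intensity trace on a
#' strictly ascending wavelength grid, together with the exposure time it was
#' captured at, the detector full-scale ceiling, an acquisition timestamp
#' (simulated hours into the run) and the identifier of the excitation LED
#' that was on during the capture (`"none"` for dark/ambient captures).
#'
#' A logical `saturated` vector marks samples recorded at (or rescaled from)
#' full scale; such samples are invalid for quantitation and every downstream
#' operator can exclude them.
#'
#' @param wavelengths_nm Strictly increasing numeric grid, in nm.
#' @param intensities Detector counts, same length as `wavelengths_nm`.
#' @param exposure_s Exposure time in seconds, `> 0`.
#' @param saturation_counts Detector full scale in counts.
#' @param timestamp Acquisition time (simulated hours); free-form scalar.
#' @param led_id Identifier of the active excitation channel, or `"none"`.
#' @param saturated Optional logical vector; defaults to
#'   `intensities >= saturation_counts`.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths_nm, intensities, exposure_s,
                     saturation_counts = 65535, timestamp = NA_real_,
                     led_id = "none", saturated = NULL) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensities <- as.numeric(intensities)
  if (length(wavelengths_nm) != length(intensities))
    stop("wavelengths_nm and intensities must have equal length")
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0))
    stop("wavelengths_nm must be strictly increasing")
  if (!is.numeric(exposure_s) || length(exposure_s) != 1 || exposure_s <= 0)
    stop("exposure_s must be a single positive number")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (any(intensities > saturation_counts, na.rm = TRUE))
    stop("intensities must not exceed saturation_counts")
  if (is.null(saturated)) saturated <- intensities >= saturation_counts
  structure(
    list(wavelengths_nm = wavelengths_nm,
         intensities = intensities,
         exposure_s = as.numeric(exposure_s),
         saturation_counts = as.numeric(saturation_counts),
         timestamp = timestamp,
         led_id = led_id,
         saturated = as.logical(saturated)),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- if (length(x$wavelengths_nm))
    sprintf("%.1f-%.1f nm (%d samples)", min(x$wavelengths_nm),
            max(x$wavelengths_nm), length(x$wavelengths_nm)) else "empty"
  cat(sprintf("<spectrum> %s | exposure %g s | led %s | %d saturated\n",
              rng, x$exposure_s, x$led_id, sum(x$saturated)))
  invisible(x)
}

#' Wavelength band
#'
#' A closed wavelength interval `[lo_nm, hi_nm]` used as an integration
#' window, e.g. the scattered-LED peak window or the phycocyanin emission
#' region around 657 nm.
#'
#' @param lo_nm,hi_nm Band bounds in nm, `lo_nm < hi_nm`.
#' @return An object of class `"band"`.
#' @export
band <- function(lo_nm, hi_nm) {
  if (!(is.numeric(lo_nm) && is.numeric(hi_nm) && lo_nm < hi_nm))
    stop("band requires numeric lo_nm < hi_nm")
  structure(list(lo_nm = as.numeric(lo_nm), hi_nm = as.numeric(hi_nm)),
            class = "band")
}

#' Default phycocyanin emission integration window (nm)
#'
#' 640--680 nm: centred near the in-vivo phycocyanin peak (~657 nm) and
#' clear of the 615 nm excitation-LED window.
#' @return A [band()].
#' @export
phycocyanin_band <- function() band(640, 680)

#' Integration window around an LED excitation peak
#'
#' @param peak_nm LED peak wavelength (nm).
#' @param half_width_nm Half-width of the window; default 10 nm.
#' @return A [band()] spanning `peak_nm +/- half_width_nm`.
#' @export
led_band <- function(peak_nm, half_width_nm = 10)
  band(peak_nm - half_width_nm, peak_nm + half_width_nm)

#' Flag samples at or near detector full scale
#'
#' @param spec A [spectrum()].
#' @param threshold_fraction Fraction of full scale in `(0, 1]` above which a
#'   sample counts as saturated. Default 0.98.
#' @return Logical vector, `TRUE` where
#'   `intensity >= threshold_fraction * saturation_counts`.
#' @export
mask_saturated <- function(spec, threshold_fraction = 0.98) {
  stopifnot(inherits(spec, "spectrum"))
  if (!(threshold_fraction > 0 && threshold_fraction <= 1))
    stop("threshold_fraction must be in (0, 1]")
  spec$intensities >= threshold_fraction * spec$saturation_counts
}

#' Trapezoidal band integral of a spectrum
#'
#' Integrates intensity over the samples falling inside a band, after
#' removing excluded (e.g. saturated) samples. With fewer than two usable
#' samples the integral is defined as 0.
#'
#' @param spec A [spectrum()].
#' @param bnd A [band()] inside the spectrum's wavelength range.
#' @param exclude_mask Optional logical vector (same length as the spectrum):
#'   `TRUE` samples are removed before integration.
#' @return Integral in counts * nm.
#' @export
band_integral <- function(spec, bnd, exclude_mask = NULL) {
  stopifnot(inherits(spec, "spectrum"), inherits(bnd, "band"))
  wl <- spec$wavelengths_nm
  if (bnd$lo_nm < min(wl) || bnd$hi_nm > max(wl))
    stop("band [", bnd$lo_nm, ", ", bnd$hi_nm,
         "] lies outside the spectrum range")
  keep <- wl >= bnd$lo_nm & wl <= bnd$hi_nm
  if (!is.null(exclude_mask)) {
    if (length(exclude_mask) != length(wl))
      stop("exclude_mask length must match the spectrum")
    keep <- keep & !exclude_mask
  }
  if (sum(keep) < 2) return(0)
  pracma::trapz(wl[keep], spec$intensities[keep])
}

#' Rescale a spectrum to a reference exposure time
#'
#' The detector response is linear in exposure time, so counts can be put on
#' a common exposure scale by multiplying with `target_exposure_s /
#' exposure_s`. Saturated samples hold no quantitative information and are
#' carried unchanged with their saturation flag intact rather than being
#' rescaled into fictitious counts.
#'
#' @param spec A [spectrum()].
#' @param target_exposure_s Target exposure in seconds, `> 0`.
#' @return A new [spectrum()] at the target exposure.
#' @export
normalize_exposure <- function(spec, target_exposure_s) {
  stopifnot(inherits(spec, "spectrum"))
  if (!is.numeric(target_exposure_s) || length(target_exposure_s) != 1 ||
      target_exposure_s <= 0)
    stop("target_exposure_s must be a single positive number")
  scale <- target_exposure_s / spec$exposure_s
  out <- spec
  out$intensities <- ifelse(spec$saturated, spec$intensities,
                            spec$intensities * scale)
  out$exposure_s <- target_exposure_s
  out
}

#' Locate the peak of a spectrum inside a search band
#'
#' Finds the maximum unmasked sample inside the band and, when the maximum is
#' interior with two usable neighbours, refines the location by three-point
#' parabolic interpolation. Ties break toward the shorter wavelength.
#'
#' @param spec A [spectrum()].
#' @param search_band A [band()].
#' @param exclude_mask Optional logical exclusion vector (e.g. from
#'   [mask_saturated()]).
#' @return A list with `wavelength_nm` and `height_counts`.
#' @export
find_peak <- function(spec, search_band, exclude_mask = NULL) {
  stopifnot(inherits(spec, "spectrum"), inherits(search_band, "band"))
  wl <- spec$wavelengths_nm
  keep <- wl >= search_band$lo_nm & wl <= search_band$hi_nm
  if (!is.null(exclude_mask)) {
    if (length(exclude_mask) != length(wl))
      stop("exclude_mask length must match the spectrum")
    keep <- keep & !exclude_mask
  }
  idx <- which(keep)
  if (length(idx) < 3)
    stop("find_peak needs at least 3 usable samples in the search band")
  y <- spec$intensities[idx]
  imax <- idx[which.max(y)]  # which.max -> first max -> shorter wavelength
  peak_wl <- wl[imax]
  peak_y <- spec$intensities[imax]
  # parabolic refinement only when both grid neighbours are usable
  pos <- match(imax, idx)
  if (pos > 1 && pos < length(idx) &&
      idx[pos - 1] == imax - 1 && idx[pos + 1] == imax + 1) {
    y0 <- spec$intensities[imax - 1]
    y1 <- peak_y
    y2 <- spec$intensities[imax + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) {  # strict local max; flat tops keep the grid sample
      delta <- 0.5 * (y0 - y2) / denom
      h <- wl[imax + 1] - wl[imax]
      peak_wl <- wl[imax] + delta * h
      peak_y <- y1 - 0.25 * (y0 - y2) * delta
    }
  }
  list(wavelength_nm = peak_wl, height_counts = peak_y)
}

#' Scattering-corrected fluorescence index from a dual-exposure pair
#'
#' Normalizes the fluorescence band of the long-exposure capture against the
#' scattered excitation-LED peak of the short-exposure capture, cancelling
#' the density-dependent scattering common to both. Both quantities are put
#' on a per-second-of-exposure scale first, so the index is a dimensionless
#' ratio invariant under common detector gain and exposure changes.
#'
#' Two normalization modes are provided: `"area"` (default) divides band
#' integrals; `"height"` divides peak heights located inside each band.
#'
#' @param pair A [measurement_pair()].
#' @param fluor_band [band()] integrated on the long-exposure spectrum;
#'   default [phycocyanin_band()].
#' @param led_bnd [band()] integrated on the short-exposure spectrum; default
#'   is the active LED's peak +/- 10 nm inferred from `pair$led_peak_nm` and
#'   must be supplied when that is absent.
#' @param mode `"area"` or `"height"`.
#' @param saturation_threshold Fraction of full scale treated as saturated;
#'   default 0.98.
#' @return Dimensionless fluorescence index (single number).
#' @export
fluorescence_index <- function(pair, fluor_band = phycocyanin_band(),
                               led_bnd = NULL, mode = c("area", "height"),
                               saturation_threshold = 0.98) {
  stopifnot(inherits(pair, "measurement_pair"))
  mode <- match.arg(mode)
  if (is.null(led_bnd)) {
    if (is.null(pair$led_peak_nm))
      stop("led_bnd must be given when the pair carries no LED peak")
    led_bnd <- led_band(pair$led_peak_nm)
  }
  short <- pair$short
  long <- pair$long
  m_short <- mask_saturated(short, saturation_threshold) | short$saturated
  m_long <- mask_saturated(long, saturation_threshold) | long$saturated

  in_fluor <- long$wavelengths_nm >= fluor_band$lo_nm &
    long$wavelengths_nm <= fluor_band$hi_nm
  if (any(in_fluor) && all(m_long[in_fluor]))
    stop("fluorescence band is fully saturated")

  if (mode == "area") {
    led_q <- band_integral(short, led_bnd, exclude_mask = m_short)
    fluor_q <- band_integral(long, fluor_band, exclude_mask = m_long)
  } else {
    led_q <- find_peak(short, led_bnd, exclude_mask = m_short)$height_counts
    fluor_q <- find_peak(long, fluor_band, exclude_mask = m_long)$height_counts
  }
  led_rate <- led_q / short$exposure_s
  if (led_rate <= 0)
    stop("LED-peak integral is not positive; normalization undefined")
  (fluor_q / long$exposure_s) / led_rate
}
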