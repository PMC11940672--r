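#' Joint fluorescence/OD time series
#'
#' Timestamped scattering-corrected fluorescence-index values for one
#' excitation channel, paired with the optical-density readings interpolated
#' to the same round times. The input to [classify_trend()].
#'
#' @param times_h Strictly increasing round times (h).
#' @param index_values Fluorescence index per round.
#' @param od_values OD at the round times (same length).
#' @param led_id Excitation channel the indices belong to.
#' @return An object of class `"fluor_series"`.
#' @export
fluor_series <- function(times_h, index_values, od_values,
                         led_id = "led615") {
  stopifnot(length(times_h) == length(index_values),
            length(times_h) == length(od_values))
  if (length(times_h) > 1 && any(diff(times_h) <= 0))
    stop("times_h must be strictly increasing")
  structure(list(times_h = as.numeric(times_h),
                 index_values = as.numeric(index_values),
                 od_values = as.numeric(od_values),
                 led_id = led_id),
            class = "fluor_series")
}

#' Extract the joint series for one LED from a monitor run
#'
#' @param run A `"phycomon_run"` from [run_monitor()].
#' @param led_id Channel to extract; default `"led615"`.
#' @return A [fluor_series()] with OD linearly interpolated at round times.
#' @export
run_series <- function(run, led_id = "led615") {
  stopifnot(inherits(run, "phycomon_run"))
  fl <- run$fluor[run$fluor$led_id == led_id & !is.na(run$fluor$index), ]
  if (nrow(fl) == 0) stop("no index values for LED ", led_id)
  od <- if (nrow(run$od) >= 2)
    stats::approx(run$od$time_h, run$od$od, xout = fl$time_h, rule = 2)$y
  else rep(NA_real_, nrow(fl))
  fluor_series(fl$time_h, fl$index, od, led_id = led_id)
}

#' Normalize a series to its initial value
#'
#' Both OD and fluorescence traces are reported relative to the culture's
#' starting point, so different runs and channels are comparable. When the
#' first value is not positive the series falls back to normalization by
#' its maximum, with a warning.
#'
#' @param series A [fluor_series()], or a bare numeric vector.
#' @return The input rescaled so its first (finite, positive) element is 1.
#' @export
normalize_series <- function(series) {
  norm_vec <- function(v) {
    first <- v[is.finite(v)][1]
    if (is.na(first) || first <= 0) {
      warning("first value not positive; falling back to max-normalization")
      m <- max(v[is.finite(v)])
      if (!is.finite(m) || m <= 0) return(v)
      return(v / m)
    }
    v / first
  }
  if (inherits(series, "fluor_series")) {
    series$index_values <- norm_vec(series$index_values)
    series$od_values <- norm_vec(series$od_values)
    series
  } else norm_vec(as.numeric(series))
}

#' Theil-Sen slope
#'
#' Median of all pairwise slopes; robust against individual outlying rounds.
#'
#' @param t,y Numeric vectors of equal length (>= 2).
#' @return Slope in units of `y` per unit of `t`.
#' @export
theil_sen_slope <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2)
  dt <- outer(t, t, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dt) & dt != 0
  stats::median(dy[keep] / dt[keep], na.rm = TRUE)
}

sign_with_band <- function(slope, threshold) {
  if (!is.finite(slope) || abs(slope) <= threshold) 0L
  else if (slope > 0) 1L else -1L
}

label_from_signs <- function(od_sign, f_sign) {
  if (od_sign > 0 && f_sign > 0) "healthy_growth"
  else if (od_sign > 0 && f_sign < 0) "contamination"
  else if (od_sign < 0 && f_sign < 0) "degradation"
  else "indeterminate"
}

#' Classify the culture trend from joint OD and fluorescence series
#'
#' Computes robust (Theil-Sen) slopes of the initial-value-normalized OD and
#' fluorescence traces over the trailing window and applies the sign logic
#' of joint turbidity/pigment monitoring: rising OD with rising fluorescence
#' is healthy growth of the target organism; rising OD with falling
#' fluorescence means the new biomass is not the fluorescent target, i.e.
#' contamination; falling OD with falling fluorescence indicates culture
#' degradation (e.g. photoinhibition). Slopes within `+/- slope_threshold`
#' count as flat, giving an indeterminate verdict.
#'
#' @param series A [fluor_series()] (at least 4 points spanning at least two
#'   windows' worth of time... in practice >= 4 points and a positive time
#'   span).
#' @param window_h Trailing-window width (h) over which slopes are taken;
#'   default 24.
#' @param slope_threshold Flat band, in normalized units per hour; default
#'   0.002.
#' @return An object of class `"trend_verdict"`: `label`, `od_slope`,
#'   `fluor_slope`, `od_slope_sign`, `fluor_slope_sign`, `onset_h`,
#'   `confidence`.
#' @export
classify_trend <- function(series, window_h = 24, slope_threshold = 0.002) {
  stopifnot(inherits(series, "fluor_series"))
  n <- length(series$times_h)
  if (n < 4) stop("classify_trend needs at least 4 points")
  ns <- normalize_series(series)
  t <- ns$times_h
  odv <- ns$od_values
  fv <- ns$index_values

  window_signs <- function(end_idx) {
    keep <- t > t[end_idx] - window_h & t <= t[end_idx]
    if (sum(keep) < 4) return(NULL)
    c(od = sign_with_band(theil_sen_slope(t[keep], odv[keep]),
                          slope_threshold),
      f = sign_with_band(theil_sen_slope(t[keep], fv[keep]),
                         slope_threshold))
  }
  final <- window_signs(n)
  if (is.null(final)) stop("classify_trend needs at least 4 points in the ",
                           "trailing window")
  label <- label_from_signs(final[["od"]], final[["f"]])

  # earliest time from which every trailing-window sign pattern matches
  onset_h <- NA_real_
  if (label != "indeterminate") {
    match_from <- vapply(seq_len(n), function(i) {
      s <- window_signs(i)
      !is.null(s) && identical(s, final)
    }, logical(1))
    persistent <- rev(cumprod(rev(match_from))) == 1
    if (any(persistent & match_from)) onset_h <- t[which(persistent)[1]]
  }

  # agreement of the pairwise slopes with the final verdict's signs
  conf_of <- function(y, s) {
    dt <- outer(t, t, "-"); dy <- outer(y, y, "-")
    keep <- upper.tri(dt) & dt != 0
    sl <- dy[keep] / dt[keep]
    if (s == 0) mean(abs(sl) <= slope_threshold)
    else mean(sign(sl) == s)
  }
  confidence <- min(conf_of(odv, final[["od"]]), conf_of(fv, final[["f"]]))

  structure(list(label = label,
                 od_slope = theil_sen_slope(t, odv),
                 fluor_slope = theil_sen_slope(t, fv),
                 od_slope_sign = final[["od"]],
                 fluor_slope_sign = final[["f"]],
                 onset_h = onset_h,
                 confidence = confidence),
            class = "trend_verdict")
}

#' @export
print.trend_verdict <- function(x, ...) {
  cat(sprintf("<trend_verdict> %s (OD %s, fluorescence %s; confidence %.2f%s)\n",
              x$label, c("falling", "flat", "rising")[x$od_slope_sign + 2],
              c("falling", "flat", "rising")[x$fluor_slope_sign + 2],
              x$confidence,
              if (is.na(x$onset_h)) "" else sprintf("; onset %.1f h",
                                                    x$onset_h)))
  invisible(x)
}

#' Pick the excitation LED for a fluorophore
#'
#' Returns the channel whose emission peak lies closest to the fluorophore's
#' primary (first-listed) excitation maximum; ties break toward the
#' shorter-wavelength LED. Secondary excitation maxima are ignored: the
#' primary maximum carries the strongest absorption, so chlorophyll (429 nm
#' primary, 661 nm secondary) is paired with the 451 nm channel rather than
#' the nearer-to-secondary 657 nm channel.
#'
#' @param fluor A [fluorophore()].
#' @param bank Non-empty list of [led_channel()]s; default
#'   [default_led_bank()].
#' @return The selected [led_channel()].
#' @export
select_excitation_led <- function(fluor, bank = default_led_bank()) {
  stopifnot(inherits(fluor, "fluorophore"))
  if (length(bank) == 0) stop("LED bank is empty")
  peaks <- vapply(bank, function(ch) ch$peak_nm, numeric(1))
  d <- abs(peaks - fluor$excitation_max_nm[1])
  best <- which(d == min(d))
  bank[[best[which.min(peaks[best])]]]  # tie -> shorter wavelength
}

#' Estimate the limit of detection from a calibration series
#'
#' Fits an ordinary least-squares line `index = a + b * concentration` and
#' applies the blank-based convention `LoD = k * sd(blanks) / b` with
#' `k = 3.3` (ICH-style; `k = 3` selectable). Valid only over the
#' near-linear low-concentration range of the response.
#'
#' @param calibration Data frame with columns `concentration` and `index`
#'   (at least 3 distinct concentrations), or the list returned by
#'   [generate_calibration_series()].
#' @param blanks Numeric vector of blank-replicate indices (>= 3), taken
#'   from the calibration list when omitted.
#' @param k Multiplier on the blank SD; `3.3` (default) or `3`.
#' @return An object of class `"lod_estimate"`: `lod_cells_per_ul`, `slope`,
#'   `intercept`, `r_squared`, `blank_sd`, `k`, `n_cal`, `n_blanks`.
#' @export
estimate_lod <- function(calibration, blanks = NULL, k = 3.3) {
  if (is.list(calibration) && !is.data.frame(calibration) &&
      !is.null(calibration$calibration)) {
    if (is.null(blanks)) blanks <- calibration$blanks
    calibration <- calibration$calibration
  }
  stopifnot(is.data.frame(calibration),
            all(c("concentration", "index") %in% names(calibration)))
  if (length(unique(calibration$concentration)) < 3)
    stop("need at least 3 distinct calibration concentrations")
  if (is.null(blanks) || length(blanks) < 3)
    stop("need at least 3 blank replicates")
  k <- match.arg(as.character(k), c("3.3", "3"))
  k <- as.numeric(k)
  fit <- stats::lm(index ~ concentration, data = calibration)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope is not positive; signal does not increase ",
         "with concentration")
  blank_sd <- stats::sd(blanks)
  ss_tot <- sum((calibration$index - mean(calibration$index))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(list(lod_cells_per_ul = k * blank_sd / slope,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 blank_sd = blank_sd, k = k,
                 n_cal = nrow(calibration), n_blanks = length(blanks)),
            class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat(sprintf("<lod_estimate> LoD %.3g cells/uL (k = %.1f, blank SD %.3g, slope %.3g, R^2 %.3f)\n",
              x$lod_cells_per_ul, x$k, x$blank_sd, x$slope, x$r_squared))
  invisible(x)
}

#' Empirical (Monte-Carlo) limit of detection
#'
#' Brute-force alternative to the blank-SD convention: the smallest
#' concentration on a ladder whose simulated index distribution exceeds the
#' 99th percentile of the blank distribution in at least `power` of the
#' replicates.
#'
#' @param ladder Increasing candidate concentrations (cells/uL).
#' @param n_rep Replicates per concentration (and blanks); default 500.
#' @param power Required detection rate; default 0.95.
#' @param ... Passed to [generate_calibration_series()] (config, bands,
#'   exposures, instrument definition).
#' @return The smallest detectable ladder concentration (cells/uL), or `NA`
#'   if none reaches the required power.
#' @export
empirical_lod <- function(ladder, n_rep = 500, power = 0.95, ...) {
  stopifnot(all(diff(ladder) > 0), all(ladder > 0))
  blanks <- generate_calibration_series(rep(0, n_rep), n_blanks = 3,
                                        ...)$calibration$index
  crit <- stats::quantile(blanks, 0.99, names = FALSE)
  for (conc in ladder) {
    idx <- generate_calibration_series(rep(conc, n_rep), n_blanks = 3,
                                       ...)$calibration$index
    if (mean(idx > crit) >= power) return(conc)
  }
  NA_real_
}
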