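#' Construct a uniformly sampled pressure waveform
#'
#' Low-level constructor validating the invariants every pulse consumer
#' relies on: a uniform time grid (relative jitter below 1e-12), finite
#' samples, and at least 16 samples per period of the stated center
#' frequency.  Compression-positive sign convention: `p > 0` denotes
#' compression, and the peak negative pressure is the magnitude of the most
#' negative sample.
#'
#' @param t time, s (uniform grid).
#' @param p acoustic pressure, Pa.
#' @param center_frequency carrier frequency, Hz.  If `NA`, it is estimated
#'   as the peak of the magnitude spectrum (rectangular-windowed FFT).
#' @param label free-text label.
#' @return An object of class `pressure_pulse` with fields `t`, `p`,
#'   `center_frequency`, `sampling_rate`, `label`.
#' @seealso [tone_burst()] to synthesize a burst from scratch.
#' @export
pressure_pulse <- function(t, p, center_frequency = NA_real_, label = "") {
  stopifnot(length(t) == length(p), length(t) >= 2L)
  if (any(!is.finite(p)) || any(!is.finite(t))) {
    stop("pressure waveform contains non-finite samples")
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-12 * max(abs(t[length(t)]), dt[1])) {
    stop("time grid is not uniform")
  }
  fs <- 1 / dt[1]
  if (is.na(center_frequency)) {
    center_frequency <- .spectral_peak_frequency(p, fs)
  }
  if (fs < 16 * center_frequency) {
    stop(sprintf(
      "undersampled waveform: sampling rate %g Hz gives fewer than 16 samples per period at %g Hz (Nyquist margin rule: fs >= 16 * center_frequency)",
      fs, center_frequency))
  }
  structure(
    list(t = as.numeric(t), p = as.numeric(p),
         center_frequency = center_frequency, sampling_rate = fs,
         label = label),
    class = "pressure_pulse"
  )
}

#' @export
print.pressure_pulse <- function(x, ...) {
  cat(sprintf(
    "<pressure_pulse> %s%d samples @ %g MHz fs, f0 = %g MHz, %.3g us, PNP %.4g MPa\n",
    if (nzchar(x$label)) paste0(x$label, ": ") else "",
    length(x$p), x$sampling_rate / 1e6, x$center_frequency / 1e6,
    pulse_duration(x) * 1e6, max(0, -min(x$p)) / 1e6))
  invisible(x)
}

# Peak of the rectangular-windowed magnitude spectrum (positive freqs only).
.spectral_peak_frequency <- function(p, fs) {
  n <- length(p)
  amp <- Mod(fft(p))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * fs / n
  keep <- freq > 0
  freq[keep][which.max(amp[keep])]
}

#' Pulse duration in seconds
#'
#' Total span of the sampled waveform (n samples / sampling rate).
#' @param pulse a [pressure_pulse()].
#' @return Duration, s.
#' @export
pulse_duration <- function(pulse) {
  length(pulse$p) / pulse$sampling_rate
}

# Cosine-taper (Tukey) window; alpha = 0 rectangular, alpha = 1 full Hann.
tukey_window <- function(n, alpha = 0.25) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  if (alpha == 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / alpha + 1)))
  w
}

#' Synthesize a tone-burst pressure pulse
#'
#' Generates a sine burst at `center_frequency` with the requested peak
#' negative pressure, optionally shaped by a Tukey (cosine-taper) envelope.
#' The default Tukey taper (`alpha = 0.25`) limits spectral splatter while
#' keeping the stated PNP over the flat three quarters of the burst.
#'
#' @param center_frequency carrier frequency, Hz.
#' @param duration burst duration, s; `duration * center_frequency` must be
#'   >= 1 (at least one carrier cycle).
#' @param pnp peak negative pressure, Pa (>= 0).
#' @param envelope `"tukey"` (default) or `"rectangular"`.
#' @param alpha Tukey taper fraction (ignored for a rectangular envelope).
#' @param sampling_rate sampling rate, Hz; must be >= 16 * `center_frequency`.
#' @param label free-text label.
#' @return A [pressure_pulse()].
#' @examples
#' tp <- tone_burst(1.8e6, 20e-6, 0.268e6)      # the treatment burst
#' round(min(tp$p) / 1e6, 3)                    # -0.268 MPa
#' @export
tone_burst <- function(center_frequency, duration, pnp,
                       envelope = c("tukey", "rectangular"), alpha = 0.25,
                       sampling_rate = 64 * center_frequency, label = "") {
  envelope <- match.arg(envelope)
  stopifnot(center_frequency > 0, duration > 0, pnp >= 0)
  if (duration * center_frequency < 1) {
    stop("burst must contain at least one carrier cycle (duration * center_frequency >= 1)")
  }
  if (sampling_rate < 16 * center_frequency) {
    stop(sprintf(
      "undersampled request: sampling_rate %g Hz < 16 * center_frequency (%g Hz); the Nyquist margin rule requires >= 16 samples per period",
      sampling_rate, 16 * center_frequency))
  }
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  env <- if (envelope == "tukey") tukey_window(n, alpha) else rep(1, n)
  p <- pnp * env * sin(2 * pi * center_frequency * t)
  pressure_pulse(t, p, center_frequency = center_frequency, label = label)
}

#' Acoustic-output metrics of a pulse
#'
#' Computes the regulatory acoustic-output quantities from a sampled pulse:
#' peak negative/positive pressure, mechanical index
#' \eqn{MI = PNP[\mathrm{MPa}] / \sqrt{f_c[\mathrm{MHz}]}}, pulse-average
#' intensity \eqn{I_{SPPA} = \frac{1}{T}\int p(t)^2/(\rho c)\,dt} (W/cm^2)
#' and temporal-average intensity
#' \eqn{I_{SPTA} = I_{SPPA} \times duty \times 1000} (mW/cm^2).
#'
#' The duty cycle defaults to `duration * prf` but may be supplied directly
#' via `duty_cycle` when reproducing published settings in which the printed
#' duty does not follow from cycles times PRF.
#'
#' @param pulse a [pressure_pulse()].
#' @param prf pulse repetition frequency, Hz; may be `NULL` if `duty_cycle`
#'   is supplied or only per-pulse metrics are wanted.
#' @param duty_cycle optional duty-cycle fraction overriding `duration * prf`.
#' @param rho medium density, kg/m^3 (plane-wave impedance).
#' @param c medium sound speed, m/s.
#' @return An object of class `pulse_metrics`: list with `pnp` (Pa), `ppp`
#'   (Pa), `mi`, `duration` (s), `duty_cycle`, `i_sppa` (W/cm^2), `i_spta`
#'   (mW/cm^2).
#' @examples
#' tp <- tone_burst(1.8e6, 20e-6, 0.268e6)
#' round(pulse_metrics(tp)$mi, 2)   # 0.20
#' @export
pulse_metrics <- function(pulse, prf = NULL, duty_cycle = NULL,
                          rho = 1000, c = 1480) {
  stopifnot(inherits(pulse, "pressure_pulse"))
  duration <- pulse_duration(pulse)
  if (is.null(duty_cycle)) {
    duty_cycle <- if (is.null(prf)) NA_real_ else duration * prf
  }
  if (!is.na(duty_cycle) && (duty_cycle < 0 || duty_cycle > 1)) {
    stop(sprintf("duty cycle %g outside [0, 1] (prf * duration must be <= 1)",
                 duty_cycle))
  }
  pnp <- max(0, -min(pulse$p))
  ppp <- max(0, max(pulse$p))
  mi <- (pnp / 1e6) / sqrt(pulse$center_frequency / 1e6)
  i_sppa <- mean(pulse$p^2) / (rho * c) / 1e4           # W/m^2 -> W/cm^2
  i_spta <- if (is.na(duty_cycle)) NA_real_ else i_sppa * duty_cycle * 1000
  structure(
    list(pnp = pnp, ppp = ppp, mi = mi, duration = duration,
         duty_cycle = duty_cycle, i_sppa = i_sppa, i_spta = i_spta),
    class = "pulse_metrics"
  )
}

#' @export
print.pulse_metrics <- function(x, ...) {
  cat(sprintf(
    "<pulse_metrics> PNP %.4g MPa, MI %.3g, I_SPPA %.4g W/cm^2, I_SPTA %s mW/cm^2 (duty %s)\n",
    x$pnp / 1e6, x$mi, x$i_sppa,
    if (is.na(x$i_spta)) "NA" else sprintf("%.4g", x$i_spta),
    if (is.na(x$duty_cycle)) "NA" else sprintf("%.3g%%", 100 * x$duty_cycle)))
  invisible(x)
}

#' Syringe-pump flow-rate conversion
#'
#' Delivered flow rate of an oscillating perfusion pump fitted with a 1 mL
#' syringe: the pump setting (mL/min) times the syringe flow multiplier,
#' reported to the nearest integer microlitre per minute.
#'
#' @param pump_ml_min pump setting, mL/min.
#' @param multiplier syringe flow multiplier (default 0.058 for a 1 mL
#'   syringe).
#' @return Delivered rate, integer uL/min.
#' @examples
#' delivered_flow_ul_min(0.4)  # 23
#' @export
delivered_flow_ul_min <- function(pump_ml_min, multiplier = 0.058) {
  stopifnot(pump_ml_min >= 0, multiplier > 0)
  as.integer(round(pump_ml_min * multiplier * 1000))
}

#' Read and write waveform files
#'
#' Waveforms are stored as 2-column delimited text with header
#' `time_s,pressure_pa`, with pulse metadata (center frequency, PRF, label)
#' in a JSON sidecar named `<path>.json`.
#'
#' @param pulse a [pressure_pulse()].
#' @param path CSV file path.
#' @param prf optional pulse repetition frequency stored in the sidecar.
#' @return `write_pulse()` returns `path` invisibly; `read_pulse()` returns
#'   a [pressure_pulse()].
#' @export
write_pulse <- function(pulse, path, prf = NULL) {
  stopifnot(inherits(pulse, "pressure_pulse"))
  write.csv(data.frame(time_s = pulse$t, pressure_pa = pulse$p),
            path, row.names = FALSE)
  meta <- list(center_frequency_hz = pulse$center_frequency,
               label = pulse$label)
  if (!is.null(prf)) meta$prf_hz <- prf
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pulse
#' @export
read_pulse <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "pressure_pa") %in% names(df)))
  sidecar <- paste0(path, ".json")
  f0 <- NA_real_
  label <- ""
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$center_frequency_hz)) f0 <- meta$center_frequency_hz
    if (!is.null(meta$label)) label <- meta$label
  }
  pressure_pulse(df$time_s, df$pressure_pa, center_frequency = f0,
                 label = label)
}
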