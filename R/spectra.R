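#' A set of replicate pulse-echo / PCD waveforms
#'
#' Container for replicate receive waveforms recorded at a fixed condition:
#' either a background ("baseline", no bubbles) or a bubble ("sample")
#' measurement, labelled by mechanical index (cavitation runs) or
#' concentration (attenuation runs).  All replicates must share length and
#' sampling rate.
#'
#' @param waves numeric matrix, one column per replicate, or a list of
#'   equal-length numeric vectors.
#' @param sampling_rate sampling rate, Hz.
#' @param role `"baseline"` or `"sample"`.
#' @param mi_label mechanical index of the driving pulse (optional).
#' @param concentration_label bubble concentration, particles/mL (optional).
#' @return An object of class `waveform_set`.
#' @export
waveform_set <- function(waves, sampling_rate, role = c("sample", "baseline"),
                         mi_label = NA_real_, concentration_label = NA_real_) {
  role <- match.arg(role)
  if (is.list(waves) && !is.matrix(waves)) {
    lens <- lengths(waves)
    if (length(unique(lens)) != 1L) {
      stop("replicates have mixed lengths")
    }
    waves <- do.call(cbind, waves)
  }
  stopifnot(is.matrix(waves), ncol(waves) >= 1L, nrow(waves) >= 2L,
            sampling_rate > 0)
  structure(
    list(waves = waves, sampling_rate = sampling_rate, role = role,
         mi_label = mi_label, concentration_label = concentration_label),
    class = "waveform_set"
  )
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set> %s: %d replicates x %d samples @ %g MHz\n",
              x$role, ncol(x$waves), nrow(x$waves), x$sampling_rate / 1e6))
  invisible(x)
}

#' Replicate-averaged power spectrum
#'
#' One-sided periodogram (rectangular window) of each replicate, averaged
#' arithmetically across replicates in linear power.  The dB convention
#' used downstream (re max of the paired baseline) is recorded by the
#' functions that apply it.
#'
#' @param set a [waveform_set()].
#' @return An object of class `power_spectrum`: data.frame-backed list with
#'   `frequency` (Hz, f > 0 bins up to Nyquist) and `power` (linear, mean
#'   over replicates), plus `sampling_rate`, `n_replicates`, `role`.
#' @export
averaged_power_spectrum <- function(set) {
  stopifnot(inherits(set, "waveform_set"))
  n <- nrow(set$waves)
  nf <- floor(n / 2)
  freq <- (seq_len(nf)) * set$sampling_rate / n   # skip DC
  pow <- rowMeans(vapply(seq_len(ncol(set$waves)), function(j) {
    (Mod(fft(set$waves[, j]))^2 / n)[2:(nf + 1)]
  }, numeric(nf)))
  structure(
    list(frequency = freq, power = pow, sampling_rate = set$sampling_rate,
         n_replicates = ncol(set$waves), role = set$role),
    class = "power_spectrum"
  )
}

.check_same_grid <- function(a, b) {
  if (length(a$frequency) != length(b$frequency) ||
      max(abs(a$frequency - b$frequency)) > 1e-6 * max(b$frequency)) {
    stop("frequency grids do not match")
  }
}

#' Attenuation spectrum from baseline and sample waveform sets
#'
#' Power-spectral deficit of the bubble measurement relative to the
#' bubble-free baseline, converted to dB and divided by the round-trip
#' acoustic path (default 8 cm: twice the 4 cm sample chamber):
#' \eqn{A(f) = [P_{base}(f) - P_{sample}(f)]_{dB} / path}.
#'
#' @param baseline,sample [waveform_set()]s (or pre-computed
#'   `power_spectrum` objects) on identical grids.
#' @param path_cm acoustic path length, cm.
#' @return An object of class `attenuation_spectrum`: `frequency` (Hz),
#'   `attenuation` (dB/cm), `path_cm`.
#' @export
attenuation_spectrum <- function(baseline, sample, path_cm = 8) {
  if (inherits(baseline, "waveform_set")) baseline <- averaged_power_spectrum(baseline)
  if (inherits(sample, "waveform_set")) sample <- averaged_power_spectrum(sample)
  stopifnot(inherits(baseline, "power_spectrum"),
            inherits(sample, "power_spectrum"), path_cm > 0)
  .check_same_grid(baseline, sample)
  att_db <- 10 * log10(baseline$power / sample$power)
  structure(
    list(frequency = baseline$frequency, attenuation = att_db / path_cm,
         path_cm = path_cm),
    class = "attenuation_spectrum"
  )
}

#' @export
print.attenuation_spectrum <- function(x, ...) {
  cat(sprintf(
    "<attenuation_spectrum> %d bins, %.3g-%.3g MHz, path %g cm, peak %.3g dB/cm\n",
    length(x$frequency), min(x$frequency) / 1e6, max(x$frequency) / 1e6,
    x$path_cm, max(x$attenuation)))
  invisible(x)
}

#' Bulk resonance peak of an attenuation spectrum
#'
#' Frequency of highest attenuation within a band (the bulk resonance
#' frequency of the suspension).  Ties resolve to the lowest frequency; a
#' peak on the band edge is returned without extrapolation.
#'
#' @param spec an [attenuation_spectrum()].
#' @param band length-2 numeric, Hz; must intersect the spectrum.
#' @return List with `f_peak` (Hz) and `a_peak` (dB/cm).
#' @export
resonance_peak <- function(spec, band = range(spec$frequency)) {
  stopifnot(inherits(spec, "attenuation_spectrum"), length(band) == 2L)
  sel <- spec$frequency >= band[1] & spec$frequency <= band[2]
  if (!any(sel)) stop("band does not intersect the spectrum")
  f <- spec$frequency[sel]
  a <- spec$attenuation[sel]
  i <- which(a == max(a))[1L]     # lowest frequency on ties
  list(f_peak = f[i], a_peak = a[i])
}

#' Subharmonic magnitude and spectral integral of a cavitation recording
#'
#' Background-subtracted cavitation metrics: the subharmonic magnitude is
#' the peak of the dB difference spectrum within its band (default 400-600
#' kHz); the spectral integral is the trapezoidal integral of the linear
#' power difference over its band (default 0.2-10 MHz), reported on a dB
#' scale as `10 log10(1 + I / I_ref)` with `I_ref` the background power
#' integrated over the same band, so that identical spectra sit at the 0 dB
#' floor.  Content outside both bands does not affect either metric.
#'
#' @param with_bubbles,without_bubbles [waveform_set()]s or
#'   `power_spectrum` objects on identical grids.
#' @param subharmonic_band,integral_band length-2 bands, Hz; must lie
#'   within the spectral grid.
#' @return List with `subharmonic_db` and `spectral_integral_db`.
#' @export
band_metrics <- function(with_bubbles, without_bubbles,
                         subharmonic_band = c(400e3, 600e3),
                         integral_band = c(200e3, 10e6)) {
  if (inherits(with_bubbles, "waveform_set")) {
    with_bubbles <- averaged_power_spectrum(with_bubbles)
  }
  if (inherits(without_bubbles, "waveform_set")) {
    without_bubbles <- averaged_power_spectrum(without_bubbles)
  }
  .check_same_grid(with_bubbles, without_bubbles)
  f <- with_bubbles$frequency
  for (band in list(subharmonic_band, integral_band)) {
    if (band[1] < min(f) || band[2] > max(f)) {
      stop("requested band extends outside the spectral grid")
    }
  }
  sub_sel <- f >= subharmonic_band[1] & f <= subharmonic_band[2]
  diff_db <- 10 * log10(with_bubbles$power / without_bubbles$power)
  subharmonic_db <- max(diff_db[sub_sel])

  int_sel <- f >= integral_band[1] & f <= integral_band[2]
  lin_diff <- pmax(with_bubbles$power[int_sel] - without_bubbles$power[int_sel], 0)
  i_lin <- pracma::trapz(f[int_sel], lin_diff)
  i_ref <- pracma::trapz(f[int_sel], without_bubbles$power[int_sel])
  list(subharmonic_db = subharmonic_db,
       spectral_integral_db = 10 * log10(1 + i_lin / i_ref))
}
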