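#' Generate a synthetic optically sized bubble population
#'
#' Draws lognormal diameters with a given median and d90/d10 polydispersity
#' (log-scale sigma = `log(psd) / (2 * qnorm(0.9))`, since
#' `d90/d10 = exp(2 * 1.2816 * sigma)` for a lognormal), then back-computes
#' the per-particle area (`pi d^2 / 4`) and a maximum diameter from a
#' Beta-distributed roundness draw, mimicking a segmented microscopy
#' particle table.  Identical arguments (including `seed`) give bit-identical
#' output.
#'
#' @param median_diameter median diameter, um.
#' @param psd_d90_d10 target d90/d10 ratio (>= 1).
#' @param n number of particles (>= 1).
#' @param seed integer seed.
#' @param roundness_shape Beta shape parameters (length 2) for the
#'   roundness draw; the default gives mean ~ 0.94 as seen optically.
#' @param minutes,dilution metadata columns copied into the table.
#' @return data.frame with columns `area_um2`, `max_diam_um`,
#'   `equiv_diam_um`, `minutes`, `dilution`.
#' @examples
#' pop <- gen_population(1.9, 2.06, n = 1000, seed = 7)
#' summarize_population(pop)$psd_count   # ~ 2.06
#' @export
gen_population <- function(median_diameter, psd_d90_d10, n, seed,
                           roundness_shape = c(45, 3),
                           minutes = 0, dilution = 100) {
  stopifnot(median_diameter > 0, psd_d90_d10 >= 1, n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  sdlog <- log(psd_d90_d10) / (2 * qnorm(0.9))
  d <- if (sdlog == 0) rep(median_diameter, n) else {
    rlnorm(n, meanlog = log(median_diameter), sdlog = sdlog)
  }
  roundness <- rbeta(n, roundness_shape[1], roundness_shape[2])
  data.frame(
    area_um2 = pi * d^2 / 4,
    max_diam_um = d / roundness,
    equiv_diam_um = d,
    minutes = minutes,
    dilution = dilution
  )
}

# save/restore the global RNG state so generators are pure functions of
# their seed and do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate baseline/sample waveform sets with an imprinted attenuation
#'
#' Emulates a pulse-echo attenuation measurement: a deterministic broadband
#' reference pulse (Gaussian-enveloped click) is the baseline; the sample
#' replicates are the baseline filtered in the frequency domain so that the
#' power-spectral deficit equals `attenuation_profile(f) * path_cm` dB.
#' Replicate-to-replicate variability is Gaussian in dB (sd `noise_db`),
#' applied per frequency bin, matching how spectral noise presents in such
#' measurements.  [attenuation_spectrum()] applied to the pair recovers the
#' profile.
#'
#' @param attenuation_profile function of frequency (Hz) returning dB/cm
#'   (>= 0).
#' @param noise_db per-bin spectral noise, dB (0 = noiseless).
#' @param n_replicates replicates per set.
#' @param seed integer seed.
#' @param sampling_rate sampling rate, Hz.
#' @param n_samples samples per waveform; the default (512 at 50 MHz, a
#'   ~10 us gated echo window) mirrors a pulse-echo record gated around the
#'   reflector echo.
#' @param path_cm acoustic path imprinted, cm.
#' @param pulse_center,pulse_bw center and Gaussian spectral sigma (both
#'   Hz) of the broadband reference click; the defaults excite
#'   0.2-10 MHz, the band the analysis stages use.
#' @return List with elements `baseline` and `sample`, both
#'   [waveform_set()]s.
#' @examples
#' ws <- gen_waveform_set(function(f) rep(2, length(f)), 0, 3, seed = 1)
#' spec <- attenuation_spectrum(ws$baseline, ws$sample)
#' @export
gen_waveform_set <- function(attenuation_profile, noise_db = 0,
                             n_replicates = 15, seed = 1,
                             sampling_rate = 50e6, n_samples = 512,
                             path_cm = 8,
                             pulse_center = 4e6, pulse_bw = 2.5e6) {
  stopifnot(is.function(attenuation_profile), n_replicates >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n <- n_samples
  t <- (seq_len(n) - 1) / sampling_rate
  t0 <- n / sampling_rate / 4
  envelope <- exp(-0.5 * ((t - t0) * 2 * pi * pulse_bw)^2)
  base <- envelope * sin(2 * pi * pulse_center * (t - t0))

  nf <- floor(n / 2)
  freq_pos <- seq_len(nf) * sampling_rate / n   # bins 2..nf+1

  # frequency-domain amplitude multiplier with conjugate symmetry
  apply_db <- function(wave, db_pos) {
    spec <- fft(wave)
    mult <- rep(1, n)
    mult[2:(nf + 1)] <- 10^(-db_pos / 20)
    if (n %% 2 == 0) {
      mult[seq(n, n - nf + 2)] <- mult[2:nf]     # mirror (skip Nyquist)
    } else {
      mult[seq(n, n - nf + 1)] <- mult[2:(nf + 1)]
    }
    Re(fft(spec * mult, inverse = TRUE)) / n
  }

  a_db <- attenuation_profile(freq_pos) * path_cm
  if (any(a_db < 0)) stop("attenuation profile must be >= 0")
  make_set <- function(extra_db, role) {
    waves <- vapply(seq_len(n_replicates), function(k) {
      eps <- if (noise_db > 0) rnorm(nf, 0, noise_db) else rep(0, nf)
      apply_db(base, extra_db + eps)
    }, numeric(n))
    waveform_set(waves, sampling_rate, role = role)
  }
  list(baseline = make_set(rep(0, nf), "baseline"),
       sample = make_set(a_db, "sample"))
}

#' Generate a synthetic MI-response sweep
#'
#' Evaluates the [fourpl()] curve on an MI grid and adds seeded Gaussian
#' noise (in dB, the response scale) per replicate, emulating a cavitation
#' threshold sweep.
#'
#' @param a,d,b,c 4PL parameters (see [fourpl()]).
#' @param mi_grid increasing vector of MI values.
#' @param noise_db Gaussian noise sd on the response, dB.
#' @param n_reps replicates per MI.
#' @param seed integer seed.
#' @return data.frame with columns `mi`, `response`, `rep`.
#' @examples
#' r <- gen_mi_response(0, -30, 8, 0.44, seq(0.01, 1.2, 0.05), 1, 3, seed = 2)
#' fit_4pl(r)[[1]]$c   # ~ 0.44
#' @export
gen_mi_response <- function(a, d, b, c, mi_grid, noise_db = 0, n_reps = 1,
                            seed = 1) {
  stopifnot(all(diff(mi_grid) > 0), n_reps >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  truth <- fourpl(mi_grid, a, d, b, c)
  do.call(rbind, lapply(seq_len(n_reps), function(k) {
    data.frame(mi = mi_grid,
               response = truth + if (noise_db > 0) {
                 rnorm(length(mi_grid), 0, noise_db)
               } else 0,
               rep = k)
  }))
}

#' Generate a saturating calcein dose-response table
#'
#' Hill-type surface in (intensity, concentration):
#' `pct = Emax * C / (C + EC50(I))` with
#' `EC50(I) = ec50 * exp(-gain * I)` (half-maximal concentration decreasing
#' with intensity), plus seeded Gaussian noise in percentage points,
#' clipped to \[0, 100\].
#'
#' @param agent_params named list per agent, each with `emax` (%, <= 100),
#'   `ec50` (particles/mL at zero intensity) and `gain` (1/(mW/cm^2)).
#' @param intensities,concentrations measured levels (mW/cm^2,
#'   particles/mL).
#' @param noise_sd Gaussian noise, percentage points.
#' @param n_reps replicates per condition.
#' @param seed integer seed.
#' @return A response table data.frame (`agent`, `i_spta_mw_cm2`,
#'   `conc_ppml`, `pct_positive`, `rep`).
#' @examples
#' tab <- gen_response_surface(
#'   list(SonoVue = list(emax = 92, ec50 = 1e6, gain = 0.05)),
#'   intensities = c(3, 50, 358), concentrations = c(0.28e6, 2.8e6, 6.5e6),
#'   noise_sd = 0, n_reps = 1, seed = 1)
#' @export
gen_response_surface <- function(agent_params, intensities, concentrations,
                                 noise_sd = 0, n_reps = 3, seed = 1) {
  stopifnot(is.list(agent_params), length(agent_params) >= 1L,
            !is.null(names(agent_params)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  rows <- list()
  for (ag in names(agent_params)) {
    p <- agent_params[[ag]]
    stopifnot(p$emax <= 100)
    for (I in intensities) {
      ec50_i <- p$ec50 * exp(-p$gain * I)
      for (C in concentrations) {
        mu <- p$emax * C / (C + ec50_i)
        for (k in seq_len(n_reps)) {
          val <- mu + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
          rows[[length(rows) + 1L]] <- data.frame(
            agent = ag, i_spta_mw_cm2 = I, conc_ppml = C,
            pct_positive = min(100, max(0, val)), rep = k)
        }
      }
    }
  }
  do.call(rbind, rows)
}
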