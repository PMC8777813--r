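#' Per-particle metrics from optical segmentation
#'
#' Equivalent diameter of a particle treated as a circle of the same area,
#' \eqn{d_{eq} = 2\sqrt{A/\pi}}, and roundness as the ratio of equivalent
#' to maximum diameter (capped at 1).
#'
#' @param area_um2 particle area, um^2 (vectorized, > 0).
#' @param max_diam_um maximum diameter, um (> 0).
#' @return data.frame with `equiv_diam_um` and `roundness`.
#' @examples
#' particle_metrics(pi, 2)   # d_eq = 2, roundness = 1
#' @export
particle_metrics <- function(area_um2, max_diam_um) {
  stopifnot(length(area_um2) == length(max_diam_um),
            all(area_um2 > 0), all(max_diam_um > 0))
  d_eq <- 2 * sqrt(area_um2 / pi)
  data.frame(equiv_diam_um = d_eq,
             roundness = pmin(1, d_eq / max_diam_um))
}

# Linear interpolation of the weighted empirical CDF.
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  if (length(x) == 1L) return(rep(x, length(probs)))
  approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Summarize an optically sized particle population
#'
#' Applies the minimum-diameter cutoff, builds count- and volume-normalized
#' histograms on a fixed bin width (bins are left-closed
#' `[k*bin, (k+1)*bin)`, labelled by their centers, each summing to 100%),
#' and reports percentiles (d10/d50/d90, by linear interpolation of the
#' weighted empirical CDF), the d90/d10 polydispersity index, geometric and
#' arithmetic mean diameter with SEM pooled over all particles, mean
#' roundness, and concentration
#' `(surviving count / fov_volume) * dilution`.
#' Volume weights are proportional to \eqn{d^3}.
#'
#' @param table data.frame with columns `area_um2` (or `equiv_diam_um`
#'   directly), `max_diam_um`, and optionally `minutes`, `dilution`.
#' @param min_diameter cutoff diameter, um; particles below it are
#'   excluded (default 0.7, the optical resolution limit).
#' @param bin histogram bin width, um (default 0.1).
#' @param fov_volume imaging field-of-view volume, mL (default 6.2e-6).
#' @param dilution dilution factor; defaults to the table's `dilution`
#'   column (must then be constant), else 1.
#' @return An object of class `size_summary`: histograms, per-normalization
#'   d10/d50/d90 and psd, `geometric_mean`, `mean`, `sem`, `mean_roundness`,
#'   `concentration` (particles/mL), `n`, and the retained diameters.
#' @examples
#' pop <- gen_population(1.7, 2.46, n = 500, seed = 1)
#' s <- summarize_population(pop)
#' s$psd_count
#' @export
summarize_population <- function(table, min_diameter = 0.7, bin = 0.1,
                                 fov_volume = 6.2e-6, dilution = NULL) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  if (!"equiv_diam_um" %in% names(table)) {
    stopifnot("area_um2" %in% names(table))
    table$equiv_diam_um <- 2 * sqrt(table$area_um2 / pi)
  }
  if (is.null(dilution)) {
    if ("dilution" %in% names(table)) {
      dilution <- unique(table$dilution)
      if (length(dilution) != 1L) {
        stop("table mixes dilution factors; pass `dilution` explicitly")
      }
    } else {
      dilution <- 1
    }
  }
  keep <- table$equiv_diam_um >= min_diameter
  if (!any(keep)) {
    stop(sprintf("no particles survive the %g um minimum-diameter cutoff",
                 min_diameter))
  }
  d <- table$equiv_diam_um[keep]
  roundness <- if ("max_diam_um" %in% names(table)) {
    pmin(1, d / table$max_diam_um[keep])
  } else {
    rep(NA_real_, length(d))
  }
  n <- length(d)
  w_count <- rep(1 / n, n)
  w_vol <- d^3 / sum(d^3)

  idx <- floor(d / bin)                      # left-closed bins
  centers <- (sort(unique(idx)) + 0.5) * bin
  hist_for <- function(w) {
    pct <- vapply(sort(unique(idx)), function(k) sum(w[idx == k]), 0) * 100
    data.frame(bin_center = centers, pct = pct)
  }
  q_count <- weighted_quantile(d, w_count, c(0.1, 0.5, 0.9))
  q_vol <- weighted_quantile(d, w_vol, c(0.1, 0.5, 0.9))

  structure(
    list(
      count_hist = hist_for(w_count),
      volume_hist = hist_for(w_vol),
      d10_count = q_count[1], d50_count = q_count[2], d90_count = q_count[3],
      d10_volume = q_vol[1], d50_volume = q_vol[2], d90_volume = q_vol[3],
      psd_count = q_count[3] / q_count[1],
      psd_volume = q_vol[3] / q_vol[1],
      geometric_mean = exp(mean(log(d))),
      mean = mean(d), sem = sd(d) / sqrt(n),
      mean_roundness = mean(roundness),
      concentration = n / fov_volume * dilution,
      n = n, bin = bin, min_diameter = min_diameter,
      diameters = d),
    class = "size_summary"
  )
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf(
    "<size_summary> n = %d, d50 %.3g um (count) / %.3g um (volume), PSD %.3g / %.3g, conc %.3g ppmL\n",
    x$n, x$d50_count, x$d50_volume, x$psd_count, x$psd_volume,
    x$concentration))
  invisible(x)
}

#' Compare a fresh and an aged population summary
#'
#' Percent change in concentration, mean diameter and mean roundness
#' between two [summarize_population()] results (same binning), plus a
#' Welch (unequal-variance) two-sample comparison of the diameters.
#'
#' @param fresh,aged `size_summary` objects.
#' @return List with `concentration_change_pct`, `mean_diameter_change_pct`,
#'   `roundness_change_pct`, `p_value`, and the underlying `t_test`.
#' @examples
#' fresh <- summarize_population(gen_population(1.7, 2.46, 300, seed = 1))
#' aged  <- summarize_population(gen_population(1.9, 2.46, 300, seed = 2))
#' stability_compare(fresh, aged)$mean_diameter_change_pct
#' @export
stability_compare <- function(fresh, aged) {
  stopifnot(inherits(fresh, "size_summary"), inherits(aged, "size_summary"))
  if (fresh$bin != aged$bin) stop("summaries use different bin widths")
  pct <- function(a, b) 100 * (b - a) / a
  identical_d <- length(fresh$diameters) == length(aged$diameters) &&
    all(fresh$diameters == aged$diameters)
  tt <- if (identical_d) NULL else t.test(aged$diameters, fresh$diameters)
  list(
    concentration_change_pct = pct(fresh$concentration, aged$concentration),
    mean_diameter_change_pct = pct(fresh$mean, aged$mean),
    roundness_change_pct = pct(fresh$mean_roundness, aged$mean_roundness),
    p_value = if (is.null(tt)) 1 else tt$p.value,
    t_test = tt
  )
}

#' Cross-sectional-area-matched concentration
#'
#' Concentration at which another agent presents the same total
#' cross-sectional area per mL as a reference agent at `ref_conc`:
#' `ref_conc * <d^2>_ref / <d^2>_other`, with count-weighted mean squared
#' diameters.
#'
#' @param ref_dist,other_dist `size_summary` objects.
#' @param ref_conc reference concentration, particles/mL.
#' @return Matched concentration, particles/mL.
#' @export
area_matched_concentration <- function(ref_dist, ref_conc, other_dist) {
  stopifnot(inherits(ref_dist, "size_summary"),
            inherits(other_dist, "size_summary"), ref_conc > 0)
  ref_conc * mean(ref_dist$diameters^2) / mean(other_dist$diameters^2)
}

#' Read a particle table from delimited text
#'
#' Expects a header `area_um2,max_diam_um,minutes,dilution` (extra columns
#' are kept).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_particle_table <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("area_um2", "max_diam_um") %in% names(df)))
  df
}
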