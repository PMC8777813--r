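#' Sweep the bubble model over an equilibrium-radius grid
#'
#' Runs [simulate_bubble()] for every `R0` on a regular grid (default
#' 0.35-10 um in 50 nm steps, 194 points) and records, per radius, the
#' oscillation amplitude (absolute and percent of equilibrium diameter) and
#' the peak radiated pressures at an observation distance `r_obs` (default
#' 7 um, a capillary-wall distance).  Collapse-flagged points carry `NA`
#' metrics and are counted in the `n_masked` field instead of being
#' fabricated.
#'
#' @param shell a [shell_params()].
#' @param medium a [medium()].
#' @param pulse a [pressure_pulse()].
#' @param r0_min,r0_max,step grid bounds and spacing, m.
#' @param r_obs radiated-pressure observation distance, m.
#' @param ... further arguments passed to [simulate_bubble()].
#' @return An object of class `radius_sweep`: data.frame-backed list with
#'   `r0` (m), `osc_amp_abs` (m), `osc_amp_pct` (%), `pnp_obs` (Pa),
#'   `ppp_obs` (Pa), `collapsed` (logical), plus fields `shell`, `r_obs`,
#'   `n_masked`.
#' @seealso [sweep_peak()] for the maximum-amplitude summary,
#'   [weight_sweep()] for size-distribution weighting.
#' @export
sweep_radii <- function(shell, medium, pulse,
                        r0_min = 0.35e-6, r0_max = 10e-6, step = 50e-9,
                        r_obs = 7e-6, ...) {
  stopifnot(r0_min > 0, r0_max > r0_min, step > 0)
  r0_grid <- seq(r0_min, r0_max, by = step)
  n <- length(r0_grid)
  osc_abs <- osc_pct <- pnp <- ppp <- rep(NA_real_, n)
  collapsed <- logical(n)
  for (i in seq_len(n)) {
    traj <- simulate_bubble(r0_grid[i], shell, medium, pulse, ...)
    collapsed[i] <- traj$collapsed
    if (!traj$collapsed) {
      amp <- oscillation_amplitude(traj)
      osc_abs[i] <- amp[["absolute"]]
      osc_pct[i] <- amp[["percent"]]
      if (r_obs > max(traj$R)) {
        rp <- radiated_pressure(traj, r_obs)
        pnp[i] <- rp$pnp
        ppp[i] <- rp$ppp
      }
    }
  }
  structure(
    list(r0 = r0_grid, osc_amp_abs = osc_abs, osc_amp_pct = osc_pct,
         pnp_obs = pnp, ppp_obs = ppp, collapsed = collapsed,
         shell = shell, r_obs = r_obs, n_masked = sum(collapsed)),
    class = "radius_sweep"
  )
}

#' @export
print.radius_sweep <- function(x, ...) {
  pk <- sweep_peak(x)
  cat(sprintf(
    "<radius_sweep> %s: %d R0 points (%.3g-%.3g um), max osc %.3g%% at R0 = %.3g um, %d masked\n",
    x$shell$name, length(x$r0), min(x$r0) * 1e6, max(x$r0) * 1e6,
    pk$osc_amp_pct, pk$r0 * 1e6, x$n_masked))
  invisible(x)
}

#' Maximum oscillation amplitude over a sweep
#'
#' Largest percent oscillation amplitude on the grid and the radius
#' attaining it (ties broken toward the smallest `R0`).
#'
#' @param sweep a `radius_sweep`.
#' @return List with `r0` (m), `osc_amp_pct` (%), `osc_amp_abs` (m).
#' @export
sweep_peak <- function(sweep) {
  stopifnot(inherits(sweep, "radius_sweep"))
  ok <- !is.na(sweep$osc_amp_pct)
  if (!any(ok)) stop("all sweep points are masked")
  pct <- sweep$osc_amp_pct[ok]
  i <- which(pct == max(pct))[1L]   # smallest R0 on ties (grid is increasing)
  list(r0 = sweep$r0[ok][i], osc_amp_pct = pct[i],
       osc_amp_abs = sweep$osc_amp_abs[ok][i])
}

#' Weight sweep metrics by a measured size distribution
#'
#' Multiplies a sweep metric, as a function of bubble diameter
#' (`d = 2 * R0`), by the count- or volume-occupancy-normalized size
#' distribution of an agent, and sums over histogram bins to give the
#' distribution-weighted area under the curve.  The metric is linearly
#' interpolated from the sweep grid onto the histogram bin centers; because
#' the weights sum to 1, the AUC of a constant unit metric is 1 under either
#' normalization.
#'
#' @param sweep a `radius_sweep`.
#' @param dist a [size_summary()].
#' @param normalization `"count"` or `"volume"`.
#' @param metric which sweep column to weight: `"osc_amp_pct"`,
#'   `"osc_amp_abs"`, `"pnp_obs"` or `"ppp_obs"`.
#' @param max_uncovered maximum tolerated distribution mass (fraction)
#'   outside the sweep's diameter coverage.
#' @return An object of class `weighted_summary`: list with `d` (bin center
#'   diameters, um), `weight`, `metric`, `weighted` (= weight * metric),
#'   `auc`, `normalization`, `metric_name`, `agent`.
#' @examples
#' \donttest{
#' pop <- gen_population(1.7, 2.46, n = 2000, seed = 1)
#' dist <- summarize_population(pop)
#' sv <- default_agents()$SonoVue
#' sw <- sweep_radii(sv, mouse_blood(), tone_burst(1.8e6, 5e-6, 0.268e6),
#'                   r0_min = 0.35e-6, r0_max = 6e-6, step = 0.25e-6)
#' weight_sweep(sw, dist, "count")$auc
#' }
#' @export
weight_sweep <- function(sweep, dist,
                         normalization = c("count", "volume"),
                         metric = c("osc_amp_pct", "osc_amp_abs",
                                    "pnp_obs", "ppp_obs"),
                         max_uncovered = 0.01) {
  stopifnot(inherits(sweep, "radius_sweep"), inherits(dist, "size_summary"))
  normalization <- match.arg(normalization)
  metric <- match.arg(metric)
  hist <- if (normalization == "count") dist$count_hist else dist$volume_hist
  d <- hist$bin_center                       # um
  w <- hist$pct / 100
  d_grid <- 2 * sweep$r0 * 1e6               # sweep diameters, um
  ok <- !is.na(sweep[[metric]])
  inside <- d >= min(d_grid[ok]) & d <= max(d_grid[ok])
  uncovered <- sum(w[!inside])
  if (uncovered > max_uncovered) {
    stop(sprintf(
      "%.2g%% of the %s-normalized distribution mass lies outside the sweep's diameter coverage [%.3g, %.3g] um",
      100 * uncovered, normalization, min(d_grid[ok]), max(d_grid[ok])))
  }
  m <- rep(0, length(d))
  m[inside] <- approx(d_grid[ok], sweep[[metric]][ok], xout = d[inside])$y
  structure(
    list(d = d, weight = w, metric = m, weighted = w * m,
         auc = sum(w * m), normalization = normalization,
         metric_name = metric, agent = sweep$shell$name),
    class = "weighted_summary"
  )
}

#' @export
print.weighted_summary <- function(x, ...) {
  cat(sprintf("<weighted_summary> %s, %s-normalized %s: AUC = %.4g\n",
              x$agent, x$normalization, x$metric_name, x$auc))
  invisible(x)
}

#' Write a sweep to delimited text
#'
#' Columns `r0_um, osc_amp_um, osc_amp_pct, pnp7_mpa, ppp7_mpa, collapsed`,
#' plus a JSON summary sidecar (`<path>.json`) with the peak amplitude and
#' masked-point count.
#'
#' @param sweep a `radius_sweep`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "radius_sweep"))
  df <- data.frame(
    r0_um = sweep$r0 * 1e6,
    osc_amp_um = sweep$osc_amp_abs * 1e6,
    osc_amp_pct = sweep$osc_amp_pct,
    pnp7_mpa = sweep$pnp_obs / 1e6,
    ppp7_mpa = sweep$ppp_obs / 1e6,
    collapsed = sweep$collapsed)
  write.csv(df, path, row.names = FALSE)
  pk <- sweep_peak(sweep)
  jsonlite::write_json(
    list(agent = sweep$shell$name, n_points = length(sweep$r0),
         n_masked = sweep$n_masked, r_obs_um = sweep$r_obs * 1e6,
         peak_osc_amp_pct = pk$osc_amp_pct, peak_r0_um = pk$r0 * 1e6),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
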