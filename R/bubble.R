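#' Equilibrium gas pressure of an encapsulated bubble
#'
#' Closure making the rest radius a fixed point of the bubble model with no
#' driving: \eqn{p_g = p_0 + 2\sigma/R_0 - p_v}.  With this value and
#' `pac = 0` the model right-hand side vanishes at `R = R0`.
#'
#' @param R0 equilibrium radius, m (> 0).
#' @param shell a [shell_params()].
#' @param medium a [medium()].
#' @return Gas pressure, Pa.
#' @examples
#' sv <- shell_params("SonoVue", 0.22, 1.0934, 0.052)
#' equilibrium_gas_pressure(1e-6, sv, mouse_blood())  # 199058 Pa
#' @export
equilibrium_gas_pressure <- function(R0, shell, medium) {
  stopifnot(R0 > 0, inherits(shell, "shell_params"), inherits(medium, "medium"))
  pg <- medium$p0 + 2 * shell$sigma / R0 - medium$pv
  if (pg <= 0) {
    stop(sprintf("unphysical parameter set: equilibrium gas pressure %g Pa <= 0", pg))
  }
  pg
}

#' Dimensionless damping coefficient
#'
#' Viscous plus re-radiation damping of a bubble oscillating at angular
#' frequency `omega`:
#' \eqn{\delta_t = 4\mu/(\rho \omega R_0^2) + \omega R_0 / c}.
#' Thermal damping is deliberately not modelled.
#'
#' @param omega angular frequency, rad/s (> 0).
#' @param R0 equilibrium radius, m (> 0).
#' @param medium a [medium()].
#' @return Total damping coefficient (dimensionless).
#' @examples
#' damping_coefficient(2 * pi * 1.8e6, 1e-6, mouse_blood())  # ~ 2.01
#' @export
damping_coefficient <- function(omega, R0, medium) {
  stopifnot(omega > 0, R0 > 0, inherits(medium, "medium"))
  4 * medium$mu / (medium$rho * omega * R0^2) + omega * R0 / medium$c
}

#' Linearized natural frequency of the bubble model
#'
#' Undamped eigenfrequency obtained by linearizing the implemented
#' right-hand side about `R = R0` (with `pg` from
#' [equilibrium_gas_pressure()]):
#' \deqn{f_0 = \frac{1}{2\pi}\sqrt{\frac{3\gamma p_g - 2\sigma/R_0 + 2\chi/R_0}{\rho R_0^2}}.}
#' The shell term \eqn{-2\chi(1/R_0 - 1/R)} contributes \eqn{2\chi/R_0} to
#' the restoring stiffness.
#'
#' @inheritParams equilibrium_gas_pressure
#' @return Natural frequency, Hz.
#' @export
natural_frequency <- function(R0, shell, medium) {
  pg <- equilibrium_gas_pressure(R0, shell, medium)
  k <- 3 * shell$gamma * pg - 2 * shell$sigma / R0 + 2 * shell$chi / R0
  if (k <= 0) stop("no oscillatory linear mode: non-positive stiffness")
  sqrt(k / (medium$rho * R0^2)) / (2 * pi)
}

#' Simulate one encapsulated bubble under a driving pulse
#'
#' Integrates the modified Rayleigh-Plesset equation for a shell-stabilized
#' microbubble,
#' \deqn{\ddot R = \frac{1}{\rho R}\Big[-\tfrac{3}{2}\rho \dot R^2
#'   + p_g (R_0/R)^{3\gamma} + p_v - p_0 - \frac{2\sigma}{R}
#'   - 2\chi\Big(\frac{1}{R_0}-\frac{1}{R}\Big)
#'   - \delta_t \omega \rho R \dot R - p_{ac}(t)\Big],}
#' from rest (`R(0) = R0`, `Rdot(0) = 0`).  The ambient `-p0` term and the
#' closure \eqn{p_g = p_0 + 2\sigma/R_0 - p_v} make `R0` an exact rest state
#' with no driving.  `omega` in the damping term is the single scalar
#' `2 * pi * pulse$center_frequency`.  Integration uses `deSolve::lsodar`
#' (adaptive, automatic stiff/non-stiff switching) with a compiled
#' right-hand side; the driving pressure is linearly interpolated from the
#' pulse samples.  If the radius falls below `R0/100` the integration halts
#' and the trajectory is flagged as a collapse rather than returned as
#' converged.
#'
#' @param R0 equilibrium radius, m; must lie in \[0.1, 50\] um.
#' @param shell a [shell_params()].
#' @param medium a [medium()].
#' @param pulse a [pressure_pulse()] driving the bubble.
#' @param rtol,atol solver relative / absolute (m) tolerances.
#' @param points_per_period output samples per carrier period (>= 32).
#' @param collapse_fraction collapse-guard threshold as a fraction of `R0`.
#' @return An object of class `radius_trajectory`: list with `t` (s), `R`
#'   (m), `Rdot` (m/s), `Rddot` (m/s^2, from the model RHS), `R0`, `shell`,
#'   `medium`, `omega`, `collapsed` (logical), `label`.
#' @examples
#' \donttest{
#' sv <- default_agents()$SonoVue
#' tp <- tone_burst(1.8e6, 5e-6, 50e3)
#' traj <- simulate_bubble(2e-6, sv, mouse_blood(), tp)
#' oscillation_amplitude(traj)
#' }
#' @export
simulate_bubble <- function(R0, shell, medium, pulse,
                            rtol = 1e-8, atol = 1e-12,
                            points_per_period = 32,
                            collapse_fraction = 0.01) {
  stopifnot(inherits(shell, "shell_params"), inherits(medium, "medium"),
            inherits(pulse, "pressure_pulse"), points_per_period >= 32)
  if (R0 < 0.1e-6 || R0 > 50e-6) {
    stop("R0 outside the supported range [0.1, 50] um")
  }
  pg <- equilibrium_gas_pressure(R0, shell, medium)
  omega <- 2 * pi * pulse$center_frequency
  delta_t <- damping_coefficient(omega, R0, medium)

  parms <- c(rho = medium$rho, pg = pg, pv = medium$pv, p0 = medium$p0,
             sigma = shell$sigma, chi = shell$chi, gam3 = 3 * shell$gamma,
             dcoef = delta_t * omega * medium$rho, R0 = R0,
             rmin = collapse_fraction * R0)

  t_end <- pulse$t[length(pulse$t)]
  dt_out <- 1 / (points_per_period * pulse$center_frequency)
  times <- seq(0, t_end, by = dt_out)
  forcing <- cbind(pulse$t, pulse$p)

  sol <- deSolve::lsodar(
    y = c(R = R0, Rdot = 0), times = times,
    func = "sonosim_deriv", parms = parms, dllname = "sonosim",
    initfunc = "sonosim_init", initforc = "sonosim_forc",
    forcings = forcing, fcontrol = list(method = "linear", rule = 2),
    rootfunc = "sonosim_root", nroot = 1L,
    rtol = rtol, atol = atol, maxsteps = 1e5)

  collapsed <- !is.null(attr(sol, "iroot")) &&
    nrow(sol) < length(times) && sol[nrow(sol), "R"] <= 2 * collapse_fraction * R0
  t_sol <- sol[, "time"]
  R <- sol[, "R"]
  Rdot <- sol[, "Rdot"]
  pac <- approx(pulse$t, pulse$p, xout = t_sol, rule = 2)$y
  Rddot <- .model_rddot(R, Rdot, pac, parms)

  structure(
    list(t = t_sol, R = R, Rdot = Rdot, Rddot = Rddot, R0 = R0,
         shell = shell, medium = medium, omega = omega,
         collapsed = collapsed, label = pulse$label),
    class = "radius_trajectory"
  )
}

# Model RHS re-evaluated in R (vectorized); used for the radiated-pressure
# acceleration so it matches the integrated dynamics exactly.
.model_rddot <- function(R, Rdot, pac, parms) {
  bracket <- -1.5 * parms[["rho"]] * Rdot^2 +
    parms[["pg"]] * (parms[["R0"]] / R)^parms[["gam3"]] +
    parms[["pv"]] - parms[["p0"]] -
    2 * parms[["sigma"]] / R -
    2 * parms[["chi"]] * (1 / parms[["R0"]] - 1 / R) -
    parms[["dcoef"]] * R * Rdot - pac
  bracket / (parms[["rho"]] * R)
}

#' @export
print.radius_trajectory <- function(x, ...) {
  amp <- oscillation_amplitude(x)
  cat(sprintf(
    "<radius_trajectory> %s R0 = %.3g um, %d steps over %.3g us, osc %.3g%%%s\n",
    x$shell$name, x$R0 * 1e6, length(x$t), diff(range(x$t)) * 1e6,
    amp[["percent"]], if (x$collapsed) " [COLLAPSED]" else ""))
  invisible(x)
}

#' Oscillation amplitude of a trajectory
#'
#' Difference between the maximum and minimum bubble diameter, absolute and
#' as a percentage of the equilibrium diameter:
#' `absolute = 2 * (max R - min R)`, `percent = absolute / (2 R0) * 100`.
#'
#' @param traj a `radius_trajectory`.
#' @return Named numeric vector `c(absolute = , percent = )` (m, %).
#' @export
oscillation_amplitude <- function(traj) {
  stopifnot(inherits(traj, "radius_trajectory"), length(traj$R) >= 1L)
  absolute <- 2 * (max(traj$R) - min(traj$R))
  c(absolute = absolute, percent = absolute / (2 * traj$R0) * 100)
}

#' Pressure radiated by an oscillating bubble
#'
#' Acoustic pressure at distance `r` from the bubble center,
#' \eqn{p(r, t) = \rho (R^2 \ddot R + 2 R \dot R^2) / r}, with the
#' acceleration evaluated from the model right-hand side (not by numerical
#' differencing).  The explicit `1/r` dependence makes the field obey the
#' spherical spreading law exactly.
#'
#' @param traj a `radius_trajectory`.
#' @param r observation distance from the bubble center, m; must exceed the
#'   maximum instantaneous radius.
#' @return List with `t` (s), `p` (Pa), and peak magnitudes `pnp`, `ppp`
#'   (Pa).
#' @examples
#' \donttest{
#' sv <- default_agents()$SonoVue
#' traj <- simulate_bubble(2e-6, sv, mouse_blood(), tone_burst(1.8e6, 5e-6, 50e3))
#' radiated_pressure(traj, 7e-6)$pnp
#' }
#' @export
radiated_pressure <- function(traj, r = 7e-6) {
  stopifnot(inherits(traj, "radius_trajectory"))
  if (r <= max(traj$R)) {
    stop(sprintf(
      "observation distance %g m lies inside the bubble (max R = %g m)",
      r, max(traj$R)))
  }
  p <- traj$medium$rho * (traj$R^2 * traj$Rddot + 2 * traj$R * traj$Rdot^2) / r
  list(t = traj$t, p = p, pnp = max(0, -min(p)), ppp = max(0, max(p)))
}
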