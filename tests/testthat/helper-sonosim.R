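# Shared fixtures: the three clinical agents, mouse-blood medium, and the
# synthesized treatment burst (built once per test run).
agents <- default_agents()
blood <- mouse_blood()

treatment_pulse <- function(duration = 20e-6, pnp = 0.268e6) {
  tone_burst(1.8e6, duration, pnp, envelope = "tukey", alpha = 0.25)
}

# hand-built trajectory for closed-form checks (prescribed motion, not a
# solver product)
prescribed_trajectory <- function(R0, eps, omega, t, shell = agents$SonoVue,
                                  med = blood) {
  structure(
    list(t = t,
         R = R0 * (1 + eps * sin(omega * t)),
         Rdot = R0 * eps * omega * cos(omega * t),
         Rddot = -R0 * eps * omega^2 * sin(omega * t),
         R0 = R0, shell = shell, medium = med, omega = omega,
         collapsed = FALSE, label = "prescribed"),
    class = "radius_trajectory")
}

# minimal synthetic sweep / size-summary objects for weighting arithmetic
fake_sweep <- function(r0_um, metric_vals,
                       metric = "osc_amp_pct", agent = "Fake") {
  n <- length(r0_um)
  out <- list(r0 = r0_um * 1e-6,
              osc_amp_abs = rep(0, n), osc_amp_pct = rep(0, n),
              pnp_obs = rep(0, n), ppp_obs = rep(0, n),
              collapsed = rep(FALSE, n),
              shell = shell_params(agent, 0.2, 1.1, 0.05),
              r_obs = 7e-6, n_masked = 0L)
  out[[metric]] <- metric_vals
  structure(out, class = "radius_sweep")
}

fake_dist <- function(bin_center_um, pct) {
  h <- data.frame(bin_center = bin_center_um, pct = pct)
  structure(list(count_hist = h, volume_hist = h, bin = 0.1,
                 diameters = bin_center_um, n = length(bin_center_um)),
            class = "size_summary")
}
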