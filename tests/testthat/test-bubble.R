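test_that("equilibrium gas pressure follows the Laplace closure", {
  sv <- agents$SonoVue
  expect_equal(equilibrium_gas_pressure(1e-6, sv, blood),
               101325 + 2 * 0.052 / 1e-6 - 6267)   # 199058 Pa
  # Laplace term vanishes without surface tension / vapour pressure
  dry <- medium(pv = 1e-12)
  flat <- shell_params("flat", chi = 0.2, gamma = 1.1, sigma = 0)
  expect_equal(equilibrium_gas_pressure(1e-6, flat, dry), dry$p0,
               tolerance = 1e-10)
  # R0 -> infinity asymptote: p0 - pv
  expect_equal(equilibrium_gas_pressure(49e-6, sv, blood),
               blood$p0 - blood$pv, tolerance = 0.05)
  # unphysical set rejected
  expect_error(equilibrium_gas_pressure(1e-6, flat, medium(pv = 2e5)),
               "unphysical")
})

test_that("damping coefficient components have the right magnitudes and scaling", {
  om <- 2 * pi * 1.8e6
  expect_equal(damping_coefficient(om, 1e-6, blood), 2.013, tolerance = 0.001)
  # doubling R0: viscous term quarters, radiation term doubles
  visc <- function(R0) 4 * blood$mu / (blood$rho * om * R0^2)
  rad <- function(R0) om * R0 / blood$c
  expect_equal(damping_coefficient(om, 2e-6, blood),
               visc(1e-6) / 4 + rad(1e-6) * 2, tolerance = 1e-12)
})

test_that("R0 is an exact rest state with no driving (all agents)", {
  quiet <- tone_burst(1.8e6, 20e-6, 0)
  for (ag in names(agents)) {
    for (r0 in c(0.5, 1, 2, 5) * 1e-6) {
      traj <- simulate_bubble(r0, agents[[ag]], blood, quiet)
      expect_lt(max(abs(traj$R - r0)) / r0, 1e-6,
                label = sprintf("%s R0=%g fixed-point deviation", ag, r0))
      expect_false(traj$collapsed)
    }
  }
})

test_that("low-amplitude response peaks at the linearized natural frequency", {
  # 1 kPa drive on a 4 um SonoVue bubble (damping ~0.28, peak shift ~2%)
  r0 <- 4e-6
  f0 <- natural_frequency(r0, agents$SonoVue, blood)
  freqs <- f0 * seq(0.7, 1.3, by = 0.025)
  amp <- vapply(freqs, function(f) {
    tr <- simulate_bubble(r0, agents$SonoVue, blood,
                          tone_burst(f, 25 / f, 1e3))
    oscillation_amplitude(tr)[["percent"]]
  }, 0)
  f_peak <- freqs[which.max(amp)]
  expect_lt(abs(f_peak - f0) / f0, 0.05)
})

test_that("oscillation amplitude reports diameter excursion", {
  t <- seq(0, 10e-6, length.out = 4000)
  traj <- prescribed_trajectory(2e-6, 0.1, 2 * pi * 2e6, t)
  amp <- oscillation_amplitude(traj)
  # Dmax - Dmin = 2 * (Rmax - Rmin) = 0.4 R0 -> 20% of D0
  expect_equal(amp[["absolute"]], 0.4 * 2e-6, tolerance = 1e-4)
  expect_equal(amp[["percent"]], 20, tolerance = 0.01)
  # constant radius -> zero
  still <- prescribed_trajectory(2e-6, 0, 2 * pi * 2e6, t)
  expect_equal(unname(oscillation_amplitude(still)), c(0, 0))
})

test_that("radiated pressure matches the small-amplitude closed form and 1/r law", {
  t <- seq(0, 10e-6, length.out = 8000)
  R0 <- 2e-6
  eps <- 1e-3
  Om <- 2 * pi * 2e6
  traj <- prescribed_trajectory(R0, eps, Om, t)
  r <- 7e-6
  rp <- radiated_pressure(traj, r)
  analytic <- -blood$rho * R0^3 * eps * Om^2 * sin(Om * t) / r
  expect_lt(max(abs(rp$p - analytic)) / max(abs(analytic)), 5 * eps)
  # spherical spreading: halving r doubles the field exactly
  rp2 <- radiated_pressure(traj, r / 2)
  expect_equal(rp2$p, 2 * rp$p, tolerance = 1e-12)
  # static bubble radiates nothing
  still <- prescribed_trajectory(R0, 0, Om, t)
  expect_true(all(radiated_pressure(still, r)$p == 0))
  # observation point inside the bubble is rejected
  expect_error(radiated_pressure(traj, 1e-6), "inside")
})

test_that("percent amplitude is non-decreasing in drive pressure", {
  for (ag in names(agents)) {
    amps <- vapply(c(1, 5, 10, 20, 50) * 1e3, function(pnp) {
      tr <- simulate_bubble(2e-6, agents[[ag]], blood,
                            tone_burst(1.8e6, 10e-6, pnp))
      oscillation_amplitude(tr)[["percent"]]
    }, 0)
    expect_true(all(diff(amps) > -1e-6), label = paste(ag, "monotone in PNP"))
  }
})

test_that("collapse guard halts and flags instead of returning garbage", {
  tr <- simulate_bubble(2e-6, agents$SonoVue, blood,
                        tone_burst(1.8e6, 10e-6, 3e6))
  expect_true(tr$collapsed)
  expect_lte(min(tr$R), 0.021 * 2e-6)
  expect_lt(max(tr$t), 10e-6)      # halted early
})

test_that("solution is converged at the default tolerances", {
  tp <- treatment_pulse(duration = 5e-6)
  a1 <- oscillation_amplitude(
    simulate_bubble(2e-6, agents$SonoVue, blood, tp, rtol = 1e-8))[["percent"]]
  a2 <- oscillation_amplitude(
    simulate_bubble(2e-6, agents$SonoVue, blood, tp, rtol = 5e-9))[["percent"]]
  expect_lt(abs(a1 - a2), 0.1)
})

test_that("out-of-range equilibrium radii are rejected", {
  expect_error(simulate_bubble(0.05e-6, agents$SonoVue, blood,
                               tone_burst(1.8e6, 2e-6, 0)), "range")
})
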