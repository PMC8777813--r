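test_that("equivalent diameter and roundness follow the circle convention", {
  pm <- particle_metrics(c(pi, pi, 1e-8), c(2, 4, 1))
  expect_equal(pm$equiv_diam_um[1], 2)
  expect_equal(pm$roundness[1], 1)
  expect_equal(pm$roundness[2], 0.5)
  expect_lt(pm$equiv_diam_um[3], 1e-3)     # area -> 0 implies d_eq -> 0
})

test_that("population summary: weights, concentration and histogram closure", {
  tab <- data.frame(area_um2 = pi * c(1, 2)^2 / 4, max_diam_um = c(1, 2) / 0.9,
                    dilution = 1)
  s <- summarize_population(tab, fov_volume = 6.2e-6)
  # diameters {1, 2}: volume weights {1/9, 8/9}
  expect_equal(s$volume_hist$pct, c(100 / 9, 800 / 9), tolerance = 1e-9)
  expect_equal(sum(s$count_hist$pct), 100, tolerance = 1e-9)
  expect_equal(sum(s$volume_hist$pct), 100, tolerance = 1e-9)

  # 62 particles, fov 6.2e-6 mL, dilution 100 -> 1e9 particles/mL
  tab62 <- data.frame(area_um2 = rep(pi / 4 * 4, 62),
                      max_diam_um = rep(2, 62), dilution = 100)
  expect_equal(summarize_population(tab62)$concentration, 1e9)

  # monodisperse population: psd exactly 1 under both normalizations
  expect_equal(summarize_population(tab62)$psd_count, 1)
  expect_equal(summarize_population(tab62)$psd_volume, 1)

  # cutoff exclusion and empty rejection
  small <- data.frame(area_um2 = pi * 0.25^2 / 4, max_diam_um = 0.3)
  expect_error(summarize_population(small), "0.7")
})

test_that("volume-weighted median dominates the count median; psd is scale-free", {
  for (seed in 1:4) {
    pop <- gen_population(1.7, 2.46, n = 800, seed = seed)
    s <- summarize_population(pop, min_diameter = 0)
    expect_gte(s$d50_volume, s$d50_count)
    # multiplying all diameters by k leaves d90/d10 unchanged
    pop_k <- pop
    pop_k$area_um2 <- pop$area_um2 * 9
    pop_k$max_diam_um <- pop$max_diam_um * 3
    pop_k$equiv_diam_um <- NULL
    sk <- summarize_population(pop_k, min_diameter = 0)
    expect_equal(sk$psd_count, s$psd_count, tolerance = 1e-6)
  }
})

test_that("concentration is linear in dilution and count", {
  pop <- gen_population(2, 2, n = 200, seed = 1)
  s1 <- summarize_population(pop, dilution = 100)
  s2 <- summarize_population(pop, dilution = 500)
  expect_equal(s2$concentration / s1$concentration, 5)
  s3 <- summarize_population(pop[1:100, ], dilution = 100)
  expect_equal(s1$concentration / s3$concentration,
               s1$n / s3$n, tolerance = 1e-12)
})

test_that("stability comparison detects generated degradation", {
  fresh <- summarize_population(gen_population(1.7, 2.46, 400, seed = 11))
  # identical summaries: no change anywhere
  same <- stability_compare(fresh, fresh)
  expect_equal(same$concentration_change_pct, 0)
  expect_equal(same$mean_diameter_change_pct, 0)

  # halved concentration, like a lipid agent 30 min after reconstitution
  aged_tab <- gen_population(1.7, 2.46, 200, seed = 12)
  aged <- summarize_population(aged_tab)
  cmp <- stability_compare(fresh, aged)
  expect_equal(cmp$concentration_change_pct, -50, tolerance = 0.01)

  # mean diameter drift 2.51 -> 3.20 um is detected at n >= 200/arm
  sdlog <- log(2.46) / (2 * qnorm(0.9))
  sd_to_med <- exp(-sdlog^2 / 2)   # lognormal mean -> median factor
  f2 <- summarize_population(gen_population(2.51 * sd_to_med, 2.46, 300, seed = 13))
  a2 <- summarize_population(gen_population(3.20 * sd_to_med, 2.46, 300, seed = 14))
  cmp2 <- stability_compare(f2, a2)
  expect_gt(cmp2$mean_diameter_change_pct, 0)
  expect_lt(cmp2$p_value, 0.05)
})

test_that("area matching follows the mean squared diameter ratio", {
  ref <- summarize_population(gen_population(1.9, 2.06, 500, seed = 21))
  expect_equal(area_matched_concentration(ref, 2e5, ref), 2e5)

  # doubling every diameter scales the matched concentration by 1/4
  tab <- gen_population(1.9, 2.06, 500, seed = 22)
  tab2 <- tab
  tab2$area_um2 <- tab$area_um2 * 4
  tab2$max_diam_um <- tab$max_diam_um * 2
  tab2$equiv_diam_um <- NULL
  s1 <- summarize_population(tab)
  s2 <- summarize_population(tab2)
  expect_equal(area_matched_concentration(s1, 1e6, s2), 0.25e6,
               tolerance = 0.02)   # cutoff excludes a few small particles

  # lognormal moment oracle: E[d^2] = median^2 * exp(2 sdlog^2)
  n <- 4e4
  pa <- summarize_population(gen_population(2.2, 2.2, n, seed = 23),
                             min_diameter = 0)
  pb <- summarize_population(gen_population(2.4, 2.2, n, seed = 24),
                             min_diameter = 0)
  sdlog <- log(2.2) / (2 * qnorm(0.9))
  expected_ratio <- (2.2^2 * exp(2 * sdlog^2)) / (2.4^2 * exp(2 * sdlog^2))
  expect_equal(area_matched_concentration(pa, 1, pb), expected_ratio,
               tolerance = 0.03)
})

test_that("particle tables round-trip through delimited text", {
  pop <- gen_population(1.7, 2.46, 50, seed = 31)
  path <- file.path(tempdir(), "particles.csv")
  write.csv(pop, path, row.names = FALSE)
  back <- read_particle_table(path)
  expect_equal(back$area_um2, pop$area_um2, tolerance = 1e-9)
  unlink(path)
})
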