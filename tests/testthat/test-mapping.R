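paper_intensities <- c(3, 50, 358)               # plate-sonicator I_SPTA levels
paper_concs <- c(0.28e6, 2.8e6, 4.6e6, 6.5e6)    # in vitro concentrations

test_that("interpolated surfaces pass through the replicate means", {
  tab <- gen_response_surface(
    list(A = list(emax = 90, ec50 = 2e6, gain = 0.01)),
    paper_intensities, paper_concs, noise_sd = 3, n_reps = 3, seed = 2)
  surf <- interpolate_surface(tab, "A", paper_intensities, paper_concs)
  for (i in seq_along(paper_intensities)) {
    for (j in seq_along(paper_concs)) {
      sel <- tab$i_spta_mw_cm2 == paper_intensities[i] &
        tab$conc_ppml == paper_concs[j]
      expect_equal(surf$values[i, j], mean(tab$pct_positive[sel]),
                   tolerance = 1e-9)
    }
  }
})

test_that("a constant response table yields a constant surface", {
  tab <- expand.grid(i_spta_mw_cm2 = paper_intensities,
                     conc_ppml = paper_concs)
  tab$agent <- "A"
  tab$pct_positive <- 55
  surf <- interpolate_surface(tab, "A", seq(3, 358, length.out = 11),
                              10^seq(log10(0.28e6), log10(6.5e6),
                                     length.out = 9))
  expect_equal(range(surf$values), c(55, 55), tolerance = 1e-9)
})

test_that("mid-grid interpolation tracks a smooth Hill surface", {
  par <- list(A = list(emax = 95, ec50 = 3e6, gain = 0.008))
  tab <- gen_response_surface(par, paper_intensities, paper_concs,
                              noise_sd = 0, n_reps = 1, seed = 3)
  int_q <- c(20, 150, 250)
  conc_q <- c(1e6, 3.5e6, 5.5e6)
  surf <- interpolate_surface(tab, "A", int_q, conc_q)
  for (i in seq_along(int_q)) {
    for (j in seq_along(conc_q)) {
      truth <- with(par$A,
                    emax * conc_q[j] / (conc_q[j] + ec50 * exp(-gain * int_q[i])))
      expect_lt(abs(surf$values[i, j] - truth), 5)
    }
  }
  expect_error(interpolate_surface(tab, "A", c(1, 100), conc_q), "outside")
})

test_that("best-agent map finds dominance regions and analytic crossovers", {
  # uniformly dominant agent
  tab <- gen_response_surface(
    list(Hi = list(emax = 90, ec50 = 1e6, gain = 0.01),
         Lo = list(emax = 40, ec50 = 1e6, gain = 0.01)),
    paper_intensities, paper_concs, noise_sd = 0, n_reps = 1, seed = 4)
  g_i <- seq(3, 358, length.out = 15)
  g_c <- 10^seq(log10(0.28e6), log10(6.5e6), length.out = 12)
  bm <- best_agent_map(tab, g_i, g_c)
  expect_true(all(bm$winner == "Hi"))
  expect_true(all(bm$margin > 0))

  # equal-Emax pair crossing at I* = log(ec50_B/ec50_A)/(gain_B - gain_A)
  # = 15 mW/cm^2, the boundary separating the low- and high-intensity
  # dominance regions
  cross <- gen_response_surface(
    list(SonoVue = list(emax = 94, ec50 = 2e6, gain = 0.02),
         Sonazoid = list(emax = 94, ec50 = 2e6 * exp(0.15), gain = 0.03)),
    c(3, 16, 50, 358), paper_concs, noise_sd = 0, n_reps = 1, seed = 5)
  gi <- seq(3, 358, length.out = 72)
  bm2 <- best_agent_map(cross, gi, g_c)
  # below the crossover SonoVue wins, above it Sonazoid
  low_rows <- gi < 15 - diff(gi[1:2])
  high_rows <- gi > 15 + diff(gi[1:2])
  expect_true(all(bm2$winner[low_rows, ] == "SonoVue"))
  expect_true(all(bm2$winner[high_rows, ] == "Sonazoid"))
})

test_that("maps are invariant to shared offsets and agent relabeling", {
  tab <- gen_response_surface(
    list(A = list(emax = 70, ec50 = 2e6, gain = 0.004),
         B = list(emax = 60, ec50 = 1e6, gain = 0.006)),
    paper_intensities, paper_concs, noise_sd = 0, n_reps = 1, seed = 6)
  g_i <- seq(3, 358, length.out = 10)
  g_c <- 10^seq(log10(0.28e6), log10(6.5e6), length.out = 8)
  surfs <- lapply(setNames(c("A", "B"), c("A", "B")), function(ag) {
    interpolate_surface(tab, ag, g_i, g_c)
  })
  bm <- best_agent_map(surfs)
  shifted <- lapply(surfs, function(s) { s$values <- s$values + 7; s })
  bm_shift <- best_agent_map(shifted)
  expect_identical(bm_shift$winner, bm$winner)
  expect_equal(bm_shift$margin, bm$margin, tolerance = 1e-9)
  relabeled <- setNames(surfs[c("B", "A")], c("B", "A"))
  bm_rel <- best_agent_map(relabeled)
  expect_equal(sort(unique(as.vector(bm_rel$winner))),
               sort(unique(as.vector(bm$winner))))
  expect_equal(bm_rel$margin, bm$margin, tolerance = 1e-9)
})

test_that("exact ties list all winners with zero margin", {
  f <- function(v) structure(list(intensity = 1:2, concentration = 1:2,
                                  values = matrix(v, 2, 2), agent = "x"),
                             class = "response_surface")
  bm <- best_agent_map(list(A = f(50), B = f(50)))
  expect_true(all(bm$winner == "A|B"))
  expect_true(all(bm$margin == 0))
})
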