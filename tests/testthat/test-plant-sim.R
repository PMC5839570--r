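test_that("strong acid/base pH: limits, neutrality, bisection oracle", {
  expect_equal(ph_strong(0.1, 0), 1.000, tolerance = 1e-6)
  expect_equal(ph_strong(0, 0.1), 13.000, tolerance = 1e-6)
  expect_equal(ph_strong(0.05, 0.05), 7.000, tolerance = 1e-9)
  expect_equal(ph_strong(0, 0), 7.000, tolerance = 1e-9)

  # brute-force bisection on the charge balance as an independent oracle
  bisect_ph <- function(C_a, C_b, Kw = 1e-14) {
    f <- function(H) H^2 + (C_b - C_a) * H - Kw
    lo <- 1e-16; hi <- 10
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    -log10(sqrt(lo * hi))
  }
  cases <- rbind(c(0.1, 0.15), c(0.1, 0.0999), c(1e-8, 0), c(0, 1e-8),
                 c(0.02, 0.1), c(0.3, 0.01))
  for (i in seq_len(nrow(cases)))
    expect_equal(ph_strong(cases[i, 1], cases[i, 2]),
                 bisect_ph(cases[i, 1], cases[i, 2]), tolerance = 1e-10)

  # charge balance residual of the returned root
  for (i in seq_len(nrow(cases))) {
    H <- 10^-ph_strong(cases[i, 1], cases[i, 2])
    expect_lt(abs(H^2 + (cases[i, 2] - cases[i, 1]) * H - 1e-14) /
                max(H^2, 1e-14), 1e-9)
  }

  # monotone: decreasing in acid, increasing in base
  grid <- seq(0, 0.2, by = 1e-3)
  expect_true(all(diff(ph_strong(0.1, grid)) > 0))
  expect_true(all(diff(ph_strong(grid, 0.1)) < 0))
  # continuous through equivalence: on a fine grid around C_a = C_b the
  # curve moves smoothly (each 1e-9 M step changes pH by well under 0.001)
  fine <- 0.1 + seq(-5e-9, 5e-9, by = 1e-10)
  expect_lt(max(abs(diff(ph_strong(0.1, fine)))), 1e-3)
})

test_that("plant steps conserve moles and apply exact generation", {
  # inert vessel: nothing changes but the clock
  p0 <- plant_state(volume_l = 1, init_ph = 7, kinetics = NULL,
                    electrode_tau = 0, noise_sd = 0, transition_prob = 0)
  p1 <- plant_step(p0, 5)
  expect_equal(p1$acid_mol, p0$acid_mol)
  expect_equal(p1$base_mol, p0$base_mol)
  expect_equal(p1$volume_l, p0$volume_l)
  expect_equal(p1$t, 5)
  expect_equal(p1$measured_ph, 7, tolerance = 1e-9)

  # a dose moves true pH exactly as the closed-form recomputation says
  p <- plant_state(volume_l = 2.5, init_ph = 10.55, kinetics = NULL,
                   electrode_tau = 0, noise_sd = 0)
  p2 <- plant_step(p, 1, added_ml = 2, molarity = 0.5)
  oracle <- ph_strong(p$acid_mol / (p$volume_l + 0.002),
                      (p$base_mol + 0.002 * 0.5) / (p$volume_l + 0.002))
  expect_equal(plant_true_ph(p2), oracle, tolerance = 1e-12)
  expect_equal(p2$volume_l, 2.502)

  # exponential generation integrates exactly (closed form vs fine stepping)
  kin <- tempo_kinetics(r_fast = 2e-4, tau_fast = 600, r_slow = 1.5e-6,
                        duration = 1000)
  pg <- plant_state(volume_l = 2.5, init_ph = 10.55, kinetics = kin,
                    electrode_tau = 0, noise_sd = 0)
  one_big <- plant_step(pg, 100)
  many_small <- pg
  for (i in 1:1000) many_small <- plant_step(many_small, 0.1)
  expect_equal(one_big$acid_mol, many_small$acid_mol, tolerance = 1e-12)
  # analytic integral
  expect_equal(one_big$acid_mol - pg$acid_mol,
               2e-4 * 600 * (1 - exp(-100 / 600)) + 1.5e-6 * 100,
               tolerance = 1e-12)
  # generation stops at 'duration'
  pstop <- plant_step(pg, 1000)
  pstop2 <- plant_step(pstop, 500)
  expect_equal(pstop2$acid_mol, pstop$acid_mol)
})

test_that("electrode behaves as a first-order lag", {
  p <- plant_state(volume_l = 1, init_ph = 5, kinetics = NULL,
                   electrode_tau = 30, noise_sd = 0)
  # step the true pH up by one unit via instantaneous composition change
  p$acid_mol <- 1e-6 * p$volume_l        # pH 6 henceforth
  for (i in 1:30) p <- plant_step(p, 1)
  expect_equal((p$measured_ph - 5) / (6 - 5), 1 - exp(-1), tolerance = 0.02)
})

test_that("virtual pumps: nominal delivery, dead time, noise ordering", {
  s <- syringe_pump_spec(syringe_inner_diameter = 20, syringe_capacity = 20)
  expect_equal(virtual_syringe_deliver(s, 1000, noise = FALSE),
               1000 * ml_per_step(s))

  p9 <- peristaltic_pump_spec(8.167e-4, "9V")
  expect_equal(virtual_peristaltic_deliver(p9, 30, noise = TRUE), 0) # < dead time
  p12 <- peristaltic_pump_spec(8.167e-4, "12V")
  expect_equal(virtual_peristaltic_deliver(p12, 612.2, noise = FALSE),
               0.5, tolerance = 1e-4)

  # delivering 45 ml in small doses spreads more than in large doses,
  # and 9V spreads more than 12V (Monte-Carlo, fixed seed)
  total_spread <- function(spec, unit) {
    n <- round(45 / unit)
    rt <- as.numeric(volume_to_runtime(spec, unit))
    totals <- vapply(1:60, function(i)
      sum(vapply(seq_len(n), function(j)
        virtual_peristaltic_deliver(spec, rt), numeric(1))),
      numeric(1))
    stats::sd(totals)
  }
  set.seed(31)
  spread_small_9 <- total_spread(p9, 0.1)
  spread_large_9 <- total_spread(p9, 1.5)
  spread_small_12 <- total_spread(p12, 0.1)
  expect_gt(spread_small_9, spread_large_9)
  expect_gt(spread_small_9, spread_small_12)

  # per-dose relative spread ordering too
  rel_spread <- function(spec, unit) {
    rt <- as.numeric(volume_to_runtime(spec, unit))
    doses <- vapply(1:300, function(i)
      virtual_peristaltic_deliver(spec, rt), numeric(1))
    stats::sd(doses) / mean(doses)
  }
  expect_gt(rel_spread(p9, 0.1), rel_spread(p9, 1.5))
})

test_that("frame emission: round trip, forced transitions, corruption rate", {
  sc <- scenario("inert")
  plant <- sc$plant
  plant$measured_ph <- 10.553
  f <- emit_frame(plant, sc$geometry, sc$style, transition_prob = 0)
  expect_equal(decode_display(f, sc$cal)$value, 10.553)

  # every frame invalid at probability 1
  for (i in 1:10) {
    f <- emit_frame(plant, sc$geometry, sc$style, transition_prob = 1)
    expect_false(decode_display(f, sc$cal)$valid)
  }

  # corruption frequency matches the configured probability
  set.seed(13)
  n <- 2000
  invalid <- vapply(seq_len(n), function(i) {
    f <- emit_frame(plant, sc$geometry, sc$style, transition_prob = 0.1)
    !decode_display(f, sc$cal)$valid
  }, logical(1))
  expect_equal(mean(invalid), 0.1, tolerance = 0.2)
  expect_true(abs(mean(invalid) - 0.1) < 3 * sqrt(0.1 * 0.9 / n))
})
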