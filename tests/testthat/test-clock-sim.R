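test_that("the effective circadian period reflects entrainment limits and demultiplication", {
  cfg <- sim_config()
  # LD 6:6 entrains every second cycle (frequency demultiplication)
  expect_equal(effective_circadian_period(light_regime(12), cfg), 24)
  expect_equal(effective_circadian_period(light_regime(24), cfg), 24)
  expect_equal(effective_circadian_period(light_regime(22), cfg), 22)
  expect_equal(effective_circadian_period(light_regime(26), cfg), 26)
  # the range of entrainment is half-open [20, 28): 28 h and 30 h fail
  expect_null(effective_circadian_period(light_regime(28), cfg))
  expect_null(effective_circadian_period(light_regime(30), cfg))
  # constant conditions free-run at the intrinsic period
  expect_equal(effective_circadian_period(light_regime(mode = "LL"), cfg),
               cfg$circadian_intrinsic_period)
})

test_that("predicted semilunar periods follow each architecture", {
  cfg <- sim_config(counter_target_C = 15)
  expect_equal(expected_semilunar_period("counter", light_regime(26), cfg),
               16.25)   # 15 * 26 / 24
  expect_null(expected_semilunar_period("counter", light_regime(30), cfg))
  expect_equal(expected_semilunar_period("oscillator", light_regime(22), cfg),
               15)      # independent of T
  # beat at T = 23.2, k = 24.8: 23.2 * 24.8 / (2 * 1.6) = 179.8 h
  expect_equal(expected_semilunar_period("beat", light_regime(23.2), cfg),
               179.8 / 24, tolerance = 1e-12)
  cfg_k <- sim_config(beat_k = 24.8)
  expect_error(expected_semilunar_period("beat", light_regime(24.8), cfg_k),
               "undefined")
})

test_that("simulation is deterministic given the configuration", {
  cfg <- sim_config(seed = 7, n_individuals = 150)
  a <- simulate_population(cfg, light_regime(24))
  b <- simulate_population(cfg, light_regime(24))
  expect_identical(a$daily$counts, b$daily$counts)
  expect_identical(a$hourly$counts, b$hourly$counts)
  c2 <- simulate_population(sim_config(seed = 8, n_individuals = 150),
                            light_regime(24))
  expect_false(identical(a$daily$counts, c2$daily$counts))
})

test_that("a counting clock's estimated period scales linearly with T", {
  # C = 13: expected periods 13 * T / 24; slope of estimates on T ~ 13/24
  taus <- NULL
  for (seed in 1:5) {
    for (T in c(22, 24, 26)) {
      pop <- simulate_population(sim_config(seed = seed), light_regime(T))
      est <- estimate_period(window_semilunar(pop$daily))
      taus <- rbind(taus, data.frame(T = T, tau = est$tau_integrated,
                                     p = est$p_fisher))
    }
  }
  expect_true(all(taus$p < 0.05))
  expect_true(all(taus$T != 24 | (taus$tau >= 12 & taus$tau <= 14)))
  fit <- summary(lm(tau ~ T, data = taus))
  slope <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(slope - 13 / 24), 2 * max(se, 0.02))
})

test_that("an independent oscillator's period ignores T-cycle length", {
  taus <- NULL
  for (seed in 1:5) {
    for (T in c(22, 24, 26)) {
      pop <- simulate_population(sim_config("oscillator", seed = seed),
                                 light_regime(T))
      est <- estimate_period(window_semilunar(pop$daily))
      taus <- rbind(taus, data.frame(T = T, tau = est$tau_integrated))
    }
  }
  fit <- summary(lm(tau ~ T, data = taus))
  ci <- fit$coefficients[2, 1] + c(-2, 2) * fit$coefficients[2, 2]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
  expect_true(all(abs(taus$tau - 15) < 1.5))
})

test_that("the beat architecture is exquisitely sensitive to T-cycle length", {
  # T = 24, k = 24.8: envelope 15.5 d, recoverable from the daily series
  e24 <- estimate_period(window_semilunar(
    simulate_beat_population(sim_config("beat", seed = 2),
                             light_regime(24))$daily))
  expect_lt(abs(e24$tau_integrated - 15.5), 1.5)
  expect_lt(e24$p_fisher, 0.01)
  # T = 22, k = 25: envelope 22*25/(2*3) = 91.7 h; the per-cycle daily
  # census aliases so short a beat, so read it from the hourly series
  pop22 <- simulate_beat_population(sim_config("beat", beat_k = 25, seed = 3),
                                    light_regime(22))
  ls22 <- lomb_scargle(pop22$hourly, 48, 200)
  expect_lt(abs(ls22$best_period / 24 - beat_period(22, 25)), 0.5)
  # sensitivity: the two periods differ by far more than 5 days
  expect_gt(abs(e24$tau_integrated - ls22$best_period / 24), 5)
  # zero tidal amplitude degenerates to a pure circadian series: the
  # spectral power at the beat period collapses relative to the full beat
  power_at <- function(amp) {
    d <- window_semilunar(
      simulate_beat_population(sim_config("beat", seed = 4),
                               light_regime(24),
                               tidal_amplitude = amp)$daily)
    ls <- lomb_scargle(d, 3, 35)
    max(ls$statistic[abs(ls$period_grid - 15.5) < 1])
  }
  expect_gt(power_at(1) / power_at(0), 5)
  expect_error(simulate_beat_population(sim_config("beat", beat_k = 24),
                                        light_regime(24)), "undefined")
  expect_error(simulate_beat_population(sim_config("counter"),
                                        light_regime(24)), "beat")
})

test_that("under LD 6:6 emergence uses only one of the two lights-off transitions", {
  pop <- simulate_population(sim_config(seed = 5), light_regime(12))
  prof24 <- hourly_profile(zt_align(pop$hourly), 24)
  prof12 <- hourly_profile(zt_align(pop$hourly), 12)
  # folded at 24 h the profile is concentrated in one window;
  # folded at 12 h it cannot be better concentrated (no 12-h rhythm)
  conc <- function(p) max(p) / sum(p)
  expect_gt(conc(prof24), 0.9 * conc(prof12))
  # emergence gates span at most emergence_gate_width consecutive hours
  expect_lte(sum(prof24 > 0), 1 + ceiling(sim_config()$emergence_gate_width))
})

test_that("constant light separates counter and oscillator architectures", {
  # counter with a desynchronized circadian clock loses both rhythms
  pc <- simulate_population(sim_config(ll_phase_diffusion_sd = 3, seed = 6),
                            light_regime(mode = "LL"))
  expect_gt(estimate_period(window_semilunar(pc$daily))$p_fisher, 0.05)
  expect_gt(estimate_period(pc$hourly)$p_fisher, 0.05)
  # an independent oscillator keeps its daily rhythm while the hourly
  # rhythm vanishes: the discriminating contrast
  po <- simulate_population(sim_config("oscillator",
                                       ll_phase_diffusion_sd = 3, seed = 5),
                            light_regime(mode = "LL"))
  eo <- estimate_period(window_semilunar(po$daily))
  expect_lt(eo$p_fisher, 0.05)
  expect_lt(abs(eo$tau_integrated - 15), 1.5)
  expect_gt(estimate_period(po$hourly)$p_fisher, 0.05)
})
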