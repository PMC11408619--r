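test_that("no-transition limit gives a flat trace with zero events", {
  m <- kinetic_model(k_unfold0 = 1e-15)
  p <- protocol_ramp(n_cycles = 2, noise_sd = 0)
  sim <- simulate_ramp_trace(m, p)
  expect_equal(nrow(sim$events), 0L)
  # extension is the pure compliance baseline
  expect_lt(max(abs(sim$trace$extension - 0.2 * sim$trace$force)), 1e-12)
})

test_that("ramp rupture forces match a 10x finer-step CTMC oracle", {
  m <- control_model()
  med_at <- function(rate, seed) {
    set.seed(seed)
    p <- protocol_ramp(n_cycles = 200, sample_rate = rate, noise_sd = 0)
    sim <- simulate_ramp_trace(m, p)
    un <- sim$events[sim$events$direction == "unfold", ]
    un <- un[!duplicated(un$cycle_index), ]
    median(un$force)
  }
  coarse <- med_at(30, 11)
  fine <- med_at(300, 12)   # 10x finer time step
  expect_lt(abs(coarse - fine), 0.75)  # ~3 sigma of the median difference
  expect_gt(coarse, 5); expect_lt(coarse, 15)
})

test_that("saturating pseudoknot-inducer gives a bimodal rupture distribution", {
  set.seed(5)
  m <- pk_model(K_D = 50e-9)
  p <- protocol_ramp(n_cycles = 150, noise_sd = 0)
  sim <- simulate_ramp_trace(m, p, concentration = 50e-9)  # p_pk = 0.5
  un <- sim$events[sim$events$direction == "unfold", ]
  # the two sub-populations: pre-pseudoknot around 9 pN, pseudoknot ~18 pN
  lo <- un$force[un$force < 13.5]; hi <- un$force[un$force >= 13.5]
  expect_gt(length(lo), 0.2 * nrow(un))
  expect_gt(length(hi), 0.2 * nrow(un))
  expect_lt(abs(median(lo) - 9), 2)
  expect_gt(median(hi), 15)
})

test_that("constant-force dwell means match the Bell rates (Gillespie)", {
  set.seed(21)
  m <- control_model()
  hold <- 6
  p <- protocol_constant_force(hold_force = hold, hold_duration = 15000,
                               sample_rate = 5, noise_sd = 0)
  sim <- simulate_constant_force_trace(m, p)
  dw <- sim$dwells[!sim$dwells$censored, ]
  fold <- dw$duration[dw$state == "folded"]
  unf <- dw$duration[dw$state == "unfolded"]
  expect_gt(length(fold), 400)
  tau_fold <- 1 / bell_rate(hold, m$k_unfold0, m$x_unfold, m$kBT)
  tau_unf <- 1 / bell_rate(hold, m$k_fold0, m$x_fold, m$kBT, sign = -1)
  expect_lt(abs(mean(fold) - tau_fold), 3 * tau_fold / sqrt(length(fold)))
  expect_lt(abs(mean(unf) - tau_unf), 3 * tau_unf / sqrt(length(unf)))
  # dwell marginals are exponential
  expect_gt(ks.test(fold, "pexp", 1 / mean(fold))$p.value, 0.01)
})

test_that("fixed seed gives bit-identical output", {
  m <- stabilizer_model()
  p <- protocol_ramp(n_cycles = 3, seed = 99)
  a <- simulate_ramp_trace(m, p, concentration = 1e-4)
  b <- simulate_ramp_trace(m, p, concentration = 1e-4)
  expect_identical(a$trace$extension, b$trace$extension)
  expect_identical(a$events, b$events)
  pc <- protocol_constant_force(hold_duration = 60, seed = 7)
  a2 <- simulate_constant_force_trace(m, pc, concentration = 1e-4)
  b2 <- simulate_constant_force_trace(m, pc, concentration = 1e-4)
  expect_identical(a2$trace$extension, b2$trace$extension)
  expect_identical(a2$dwells, b2$dwells)
})

test_that("excessive rates trigger the resolution guard", {
  m <- kinetic_model(k_unfold0 = 50)   # hazard >> 1 per sample at high force
  p <- protocol_ramp(n_cycles = 1)
  set.seed(1)
  expect_error(simulate_ramp_trace(m, p), "resolution")
})

test_that("ligand factors are monotone in concentration as designed", {
  ms <- stabilizer_model()
  mp <- pk_model()
  cc <- 10^seq(-7, -1, length.out = 25)
  su <- vapply(cc, function(x) smfs:::ligand_unfold_factor(ms, x), 0)
  sf <- vapply(cc, function(x) smfs:::ligand_fold_factor(ms, x), 0)
  pp <- vapply(cc, function(x) smfs:::pk_probability(mp, x), 0)
  expect_true(all(diff(su) <= 0))        # unfolding rate non-increasing
  expect_true(all(diff(sf) >= 0))        # refolding rate non-decreasing
  expect_true(all(diff(pp) >= 0))        # pseudoknot commitment non-decreasing
  expect_equal(smfs:::ligand_unfold_factor(ms, 0), 1)
  expect_equal(smfs:::pk_probability(mp, 0), 0)
})

test_that("titration simulator reproduces the named curves", {
  concs <- seq(0, 250e-6, length.out = 10)
  exact <- simulate_titration(
    "one_site_total",
    list(B_max = 1000, K_D = 20e-6, ns_slope = 0, background = 100),
    concs, noise_cv = 0)
  expect_equal(exact$signal,
               1000 * concs / (20e-6 + concs) + 100, tolerance = 1e-12)
  term <- simulate_titration("termination",
                             list(e_min = 0.2, e_max = 0.8, T_50 = 1e-5),
                             concs, noise_cv = 0)
  expect_equal(term$signal[1], 0.2)
  expect_error(simulate_titration("sigmoid5", list(), concs), "unknown")
  a <- simulate_titration("mfs_saturation", list(u = 1, b = 1.3, K_D = 1e-4),
                          concs, noise_cv = 0.05, n_replicates = 2, seed = 4)
  b <- simulate_titration("mfs_saturation", list(u = 1, b = 1.3, K_D = 1e-4),
                          concs, noise_cv = 0.05, n_replicates = 2, seed = 4)
  expect_identical(a, b)
})
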