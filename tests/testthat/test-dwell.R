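test_that("noise exclusion filters artifact spikes and dead traces", {
  set.seed(12)
  m <- control_model()
  p <- protocol_constant_force(hold_force = 6, hold_duration = 240)
  sim <- simulate_constant_force_trace(m, p)
  expect_true(exclude_noisy(sim$trace, m$delta_L)$pass)
  # a 40 nm artifact spike violates the 2x-structure-length range rule
  spiky <- sim$trace
  spiky$extension[3000:3005] <- spiky$extension[3000:3005] + 40
  res <- exclude_noisy(spiky, m$delta_L)
  expect_false(res$pass)
  expect_match(res$reasons, "range", all = FALSE)
  # a flat trace never responds to force: excluded
  flat <- mfs_trace((0:2999) / 30, rnorm(3000, 0, 2), rep(6, 3000), "f",
                    condition_label("control"), 30)
  res2 <- exclude_noisy(flat, 15)
  expect_false(res2$pass)
  expect_match(res2$reasons, "response", all = FALSE)
  expect_error(exclude_noisy(sim$trace, 15, window = 1e5), "window")
})

test_that("state assignment recovers the hidden path", {
  # zero noise: exact recovery
  set.seed(13)
  m <- control_model()
  p0 <- protocol_constant_force(hold_force = 6, hold_duration = 300,
                                noise_sd = 1e-6)
  sim0 <- simulate_constant_force_trace(m, p0)
  path0 <- assign_states(sim0$trace)
  expect_equal(path0$states, as.integer(sim0$states == 1L))
  expect_lt(abs(path0$level_unfolded - path0$level_folded - m$delta_L), 0.5)
  # SNR = 5 (delta 15 nm, noise 3 nm): >= 99% per-sample agreement
  p1 <- protocol_constant_force(hold_force = 6, hold_duration = 600,
                                noise_sd = 3)
  sim1 <- simulate_constant_force_trace(m, p1)
  path1 <- assign_states(sim1$trace)
  expect_gt(mean(path1$states == as.integer(sim1$states == 1L)), 0.99)
  # unimodal trace: no two-state structure resolved
  uni <- mfs_trace((0:999) / 30, rnorm(1000, 0, 2), rep(6, 1000), "u",
                   condition_label("control"), 30)
  expect_error(assign_states(uni), "two-state")
})

test_that("dwell extraction is exact run-length arithmetic", {
  # the F F F U U F F example at 30 Hz
  states <- c(0L, 0L, 0L, 1L, 1L, 0L, 0L)
  dw <- extract_dwells(states, sample_rate = 30)
  expect_equal(dw$state, c("folded", "unfolded", "folded"))
  expect_equal(dw$duration, c(3, 2, 2) / 30)
  expect_equal(dw$censored, c(TRUE, FALSE, TRUE))
  # conservation and transition count on a simulated path
  set.seed(14)
  sim <- simulate_constant_force_trace(
    control_model(), protocol_constant_force(hold_force = 6,
                                             hold_duration = 200))
  path <- assign_states(sim$trace)
  dw2 <- extract_dwells(path)
  expect_equal(sum(dw2$duration), trace_duration(sim$trace))
  expect_equal(nrow(dw2), sum(diff(path$states) != 0) + 1L)
  # dwell durations are quantized at the acquisition rate
  expect_true(all(abs(dw2$duration * 30 - round(dw2$duration * 30)) < 1e-9))
})

test_that("single-exponential MLE equals the sample mean in closed form", {
  set.seed(15)
  t <- rexp(200, 0.4)
  scan <- fit_exp_mixture(t, k_max = 1L)
  expect_lt(abs(scan$fits[[1]]$lifetimes - mean(t)), 1e-9)
  expect_equal(scan$fits[[1]]$weights, 1)
  expect_error(fit_exp_mixture(t[1:5]), "at least 10")
})

test_that("BIC selects the planted mixture order", {
  # single-exponential data must not be over-fitted (<= 10% of runs)
  k1_wins <- vapply(1:25, function(s) {
    set.seed(1000 + s)
    t <- rexp(500, 1)
    suppressWarnings(
      fit_exp_mixture(t, k_max = 2L, n_starts = 8L, seed = s)$best_k) == 1L
  }, TRUE)
  expect_gte(mean(k1_wins), 0.9)
  # a planted (1 s, 10 s) 50/50 mixture is detected
  k2_wins <- vapply(1:25, function(s) {
    set.seed(2000 + s)
    t <- c(rexp(250, 1), rexp(250, 0.1))
    suppressWarnings(
      fit_exp_mixture(t, k_max = 2L, n_starts = 8L, seed = s)$best_k) == 2L
  }, TRUE)
  expect_gte(mean(k2_wins), 0.9)
  # parameter recovery on one large planted sample
  set.seed(16)
  t <- c(rexp(1500, 1), rexp(1500, 0.1))
  fit <- fit_exp_mixture(t, k_max = 2L, seed = 1)$fits[[2]]
  expect_lt(abs(fit$lifetimes[1] - 1), 0.15)
  expect_lt(abs(fit$lifetimes[2] - 10), 1.2)
  expect_lt(abs(fit$weights[2] - 0.5), 0.06)
})

test_that("rate aggregation normalizes each molecule by its own control", {
  set.seed(17)
  mk_dwells <- function(rate_fold, rate_unf, n = 400) {
    data.frame(state = rep(c("folded", "unfolded"), each = n),
               start = 0, duration = c(rexp(n, rate_fold), rexp(n, rate_unf)),
               censored = FALSE)
  }
  rows <- list()
  for (b in c("m1", "m2", "m3")) {
    rows[[length(rows) + 1L]] <- summarize_dwells(
      mk_dwells(1, 1), b, condition_label("control"), mixture = "never")
    # treatment halves the unfolding rate (folded lifetimes double)
    rows[[length(rows) + 1L]] <- summarize_dwells(
      mk_dwells(0.5, 1), b, condition_label("compound4", 5e-4),
      mixture = "never")
  }
  agg <- aggregate_rates(do.call(rbind, rows))
  ctrl <- agg$by_condition[agg$by_condition$condition_ligand == "control", ]
  trt <- agg$by_condition[agg$by_condition$condition_ligand == "compound4", ]
  expect_equal(ctrl$mean_norm_log_unfold, 0)   # control against itself
  expect_equal(ctrl$mean_norm_log_refold, 0)
  # -ln 2 within 3 standard errors of the mean
  se <- trt$sd_norm_log_unfold / sqrt(trt$n_molecules)
  expect_lt(abs(trt$mean_norm_log_unfold + log(2)), 3 * se + 0.05)
  # a bead without control is dropped with a warning
  orphan <- summarize_dwells(mk_dwells(1, 1), "m9",
                             condition_label("compound4", 5e-4),
                             mixture = "never")
  expect_warning(aggregate_rates(rbind(do.call(rbind, rows), orphan)), "m9")
})

test_that("stable-fold occupancy recovers a planted saturation curve", {
  set.seed(18)
  K_D <- 50e-9
  concs <- c(10, 25, 50, 100, 250) * 1e-9
  rows <- list()
  for (b in c("m1", "m2", "m3")) {
    rows[[length(rows) + 1L]] <- summarize_dwells(
      data.frame(state = rep(c("folded", "unfolded"), each = 300), start = 0,
                 duration = c(rexp(300, 1), rexp(300, 1)), censored = FALSE),
      b, condition_label("control"), mixture = "auto", seed = 3)
    for (cc in concs) {
      p_pk <- cc / (cc + K_D)
      n <- 400
      pk <- runif(n) < p_pk
      fold <- ifelse(pk, rexp(n, 0.1), rexp(n, 1))
      rows[[length(rows) + 1L]] <- summarize_dwells(
        data.frame(state = rep(c("folded", "unfolded"), each = n), start = 0,
                   duration = c(fold, rexp(n, 1)), censored = FALSE),
        b, condition_label("preq1", cc), mixture = "auto", seed = 3)
    }
  }
  summaries <- do.call(rbind, rows)
  # control stays single-exponential: zero long-component weight
  ctrl <- summaries[summaries$condition_ligand == "control", ]
  expect_true(all(ctrl$mixture_k == 1L))
  expect_true(all(ctrl$long_component_weight == 0))
  # short component tracks the control lifetime
  trt <- summaries[summaries$condition_ligand == "preq1", ]
  expect_lt(abs(median(trt$tau_short, na.rm = TRUE) - 1), 0.25)
  occ <- occupancy_vs_concentration(summaries)
  expect_equal(nrow(occ), 6L)
  planted <- concs / (concs + K_D)
  got <- occ$mean_long_weight[match(concs, occ$concentration)]
  expect_lt(max(abs(got - planted)), 0.12)
  fit <- attr(occ, "fit")
  expect_false(is.null(fit))
  expect_lt(abs(fit$params$K_D - K_D), 3 * max(fit$std_errors$K_D, 0.2 * K_D))
})
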