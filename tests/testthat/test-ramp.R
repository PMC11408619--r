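test_that("Brownian QC passes nominal noise and fails inflated noise", {
  m <- control_model()
  p_ok <- protocol_ramp(n_cycles = 5, noise_sd = 0, brownian_noise = TRUE,
                        seed = 31)
  sim <- simulate_ramp_trace(m, p_ok)
  qc <- qc_brownian(sim$trace, tether_length = m$tether_length)
  expect_true(qc$pass)
  # a quiescent 20 pN hold with Brownian-consistent noise passes;
  # the same hold with 5x the noise amplitude (25x variance) fails
  set.seed(32)
  n <- 900
  sd_brown <- sqrt(m$kBT * m$tether_length / 20)
  hold <- function(scale) {
    mfs_trace((seq_len(n) - 1) / 30, rnorm(n, 0, scale * sd_brown),
              rep(20, n), "h", condition_label("control"), 30)
  }
  expect_true(qc_brownian(hold(1), tether_length = m$tether_length)$pass)
  expect_false(qc_brownian(hold(5), tether_length = m$tether_length)$pass)
  short <- mfs_trace((0:5) / 30, rnorm(6), rep(20, 6), "s",
                     condition_label("control"), 30)
  expect_error(qc_brownian(short), "window")
})

test_that("cycle segmentation recovers the protocol exactly", {
  set.seed(8)
  p <- protocol_ramp(n_cycles = 50)
  sim <- simulate_ramp_trace(control_model(), p)
  cyc <- segment_cycles(sim$trace)
  expect_equal(nrow(cyc), 50L)
  expect_false(attr(cyc, "truncated"))
  # boundaries within one sample of ground truth
  expect_lte(max(abs(cyc$up_start - sim$cycles$up_start)), 1L)
  expect_lte(max(abs(cyc$up_end - sim$cycles$up_end)), 1L)
  expect_lte(max(abs(cyc$down_end - sim$cycles$down_end)), 1L)

  # truncated final half-cycle: 49 complete cycles, remainder flagged
  half <- sim$trace
  cut <- sim$cycles$up_end[50]   # stop at the 50th peak
  half$time <- half$time[1:cut]; half$extension <- half$extension[1:cut]
  half$force <- half$force[1:cut]; half$cycle_id <- half$cycle_id[1:cut]
  cyc2 <- segment_cycles(half)
  expect_equal(nrow(cyc2), 49L)
  expect_true(attr(cyc2, "truncated"))

  flat <- mfs_trace((0:99) / 30, rnorm(100), rep(5, 100), "f",
                    condition_label("control"), 30)
  expect_warning(cyc3 <- segment_cycles(flat), "no ramp|fewer than")
  expect_equal(nrow(cyc3), 0L)
})

test_that("noise-free event detection is exact for both methods", {
  fx <- make_step_cycle(unfold_at = 8, refold_at = 4, delta = 15)
  for (meth in c("cluster", "changepoint")) {
    ev <- detect_events(fx$trace, fx$cycles, method = meth)
    expect_equal(nrow(ev), 2L, info = meth)
    un <- ev[ev$direction == "unfold", ]
    re <- ev[ev$direction == "refold", ]
    expect_equal(un$force, fx$truth$unfold_force, tolerance = 1e-12)
    expect_lt(abs(un$size - 15), 1e-9)
    expect_equal(re$force, fx$truth$refold_force, tolerance = 1e-12)
    expect_lt(abs(re$size - 15), 1e-9)
  }
  # an all-noise phase yields an empty event list, not an error
  set.seed(40)
  noise <- fx$trace
  noise$extension <- rnorm(length(noise$extension), 0, 2)
  ev0 <- detect_events(noise, fx$cycles, method = "cluster")
  expect_equal(nrow(ev0), 0L)
})

test_that("structure stats are exact arithmetic over the event table", {
  cycles <- data.frame(cycle_index = 1:30)
  set.seed(2)
  ev <- data.frame(
    bead_id = "b", cycle_index = rep(1:27, each = 2),
    direction = rep(c("unfold", "refold"), 27),
    force = runif(54, 4, 12), size = runif(54, 10, 20),
    time = seq_len(54))
  st <- compute_structure_stats(ev, cycles, "b", condition_label("control"))
  expect_equal(st$n_cycles_analyzable, 30L)
  expect_equal(st$n_cycles_with_unfold, 27L)
  expect_equal(st$unfold_fraction, 0.9)
  expect_equal(st$median_unfold_force,
               median(ev$force[ev$direction == "unfold"]))
  expect_equal(st$median_refold_force,
               median(ev$force[ev$direction == "refold"]))
  expect_equal(st$median_unfold_size,
               median(ev$size[ev$direction == "unfold"]))
  # no events: medians flagged NA, fraction 0
  st0 <- compute_structure_stats(ev[0, ], cycles, "b",
                                 condition_label("control"))
  expect_true(is.na(st0$median_unfold_force))
  expect_equal(st0$unfold_fraction, 0)
})

test_that("structure selection classifies planted pass/fail labels exactly", {
  set.seed(3)
  mk <- function(bead, force, size, n_cyc, frac, ligs = c("control", "compound4")) {
    do.call(rbind, lapply(ligs, function(lg) {
      data.frame(bead_id = bead, condition_ligand = lg,
                 condition_conc_molar = if (lg == "control") 0 else 5e-4,
                 n_cycles_analyzable = n_cyc,
                 n_cycles_with_unfold = round(frac * n_cyc),
                 median_unfold_force = force, median_refold_force = force / 2,
                 median_unfold_size = size, unfold_fraction = frac)
    }))
  }
  crit <- selection_criteria()
  stats <- rbind(
    mk("pass1", 9, 15, 30, 0.95),
    mk("pass2", 5, 10, 21, 0.85),          # exactly at window edges: pass
    mk("lowF", 4.2, 15, 30, 0.95),          # force below window
    mk("bigSize", 9, 27, 30, 0.95),         # size above window
    mk("fewCycles", 9, 15, 10, 0.95),       # 10 cycles: rejected
    mk("boundary80", 9, 15, 30, 0.80),      # exactly 80%: strict >, rejected
    mk("absent", 9, 15, 30, 0.95, "control")  # only 1 of 2 conditions
  )
  sel <- select_structures(stats, crit)
  got <- setNames(sel$selected, sel$bead_id)
  expect_true(got[["pass1"]]); expect_true(got[["pass2"]])
  expect_false(got[["lowF"]]); expect_false(got[["bigSize"]])
  expect_false(got[["fewCycles"]]); expect_false(got[["boundary80"]])
  expect_false(got[["absent"]])
  # per-criterion verdicts name the failing rule
  expect_false(sel$cycles[sel$bead_id == "fewCycles"])
  expect_false(sel$unfold_fraction[sel$bead_id == "boundary80"])
  expect_false(sel$presence[sel$bead_id == "absent"])
  expect_error(select_structures(stats[stats$condition_ligand != "control", ],
                                 crit), "control")
})

test_that("force normalization divides by control medians and round-trips", {
  stats <- data.frame(bead_id = c("a", "b"), condition_ligand = "control",
                      condition_conc_molar = 0, n_cycles_analyzable = 30,
                      n_cycles_with_unfold = 30,
                      median_unfold_force = c(8, 10),
                      median_refold_force = c(4, 5),
                      median_unfold_size = 15, unfold_fraction = 1)
  set.seed(4)
  ev <- data.frame(bead_id = rep(c("a", "b"), each = 40),
                   cycle_index = rep(1:40, 2),
                   direction = rep(c("unfold", "refold"), 40),
                   force = runif(80, 3, 12), size = 15, time = 1:80,
                   condition_ligand = "control", condition_conc_molar = 0)
  nrm <- normalize_forces(ev, stats)
  ref <- ifelse(nrm$direction == "unfold",
                c(a = 8, b = 10)[nrm$bead_id], c(a = 4, b = 5)[nrm$bead_id])
  expect_equal(nrm$force_norm, nrm$force / unname(ref))
  expect_equal(nrm$force_norm * unname(ref), nrm$force)  # de-normalization
  # control events of a bead normalized by their own median: median exactly 1
  evc <- ev[ev$bead_id == "a" & ev$direction == "unfold", ]
  stats2 <- stats
  stats2$median_unfold_force[1] <- median(evc$force)
  nc <- normalize_forces(evc, stats2)
  expect_equal(median(nc$force_norm), 1)
  # a bead without control medians is excluded with a warning
  stats3 <- stats; stats3$median_unfold_force[2] <- NA
  expect_warning(n3 <- normalize_forces(ev, stats3), "control median")
  expect_false(any(n3$bead_id == "b" & n3$direction == "unfold"))
})

test_that("high-force fraction follows the 95th-percentile construction", {
  set.seed(6)
  mk_stats <- function(lig, conc, n, n_un) {
    data.frame(bead_id = "b", condition_ligand = lig,
               condition_conc_molar = conc, n_cycles_analyzable = n,
               n_cycles_with_unfold = n_un, median_unfold_force = 1,
               median_refold_force = 1, median_unfold_size = 15,
               unfold_fraction = n_un / n)
  }
  mk_ev <- function(lig, conc, f) {
    data.frame(bead_id = "b", cycle_index = seq_along(f),
               direction = "unfold", force = f, size = 15,
               time = seq_along(f), condition_ligand = lig,
               condition_conc_molar = conc, force_norm = f)
  }
  ctrl_f <- rnorm(500, 1, 0.1)
  # planted mixture: 60% control-like, 40% high-force population
  mix_f <- c(rnorm(300, 1, 0.1), rnorm(200, 2, 0.1))
  stats <- rbind(mk_stats("control", 0, 500, 500),
                 mk_stats("preq1", 1e-7, 500, 500))
  ev <- rbind(mk_ev("control", 0, ctrl_f), mk_ev("preq1", 1e-7, mix_f))
  hf <- high_force_fraction(ev, stats)
  ctrl_row <- hf[hf$condition_ligand == "control", ]
  trt_row <- hf[hf$condition_ligand == "preq1", ]
  # control: by percentile construction ~5% exceed the threshold
  expect_lt(abs(ctrl_row$fraction_high_force - 0.05), 0.01)
  # planted mixture: ~0.4 + 0.05 * 0.6 within binomial error (3 sigma ~ 0.066)
  expect_lt(abs(trt_row$fraction_high_force - 0.43), 0.07)
  # no-unfold cycles enter the numerator and denominator
  stats2 <- rbind(mk_stats("control", 0, 500, 500),
                  mk_stats("preq1", 1e-7, 600, 500))
  hf2 <- high_force_fraction(ev, stats2)
  t2 <- hf2[hf2$condition_ligand == "preq1", ]
  expect_equal(t2$n_no_unfold, 100)
  expect_equal(t2$fraction_high_force, (t2$n_over + 100) / 600)
  # invariance under a uniform monotone force rescaling
  ev3 <- ev; ev3$force_norm <- ev3$force_norm * 3.7
  hf3 <- high_force_fraction(ev3, stats)
  expect_equal(hf3$fraction_high_force, hf$fraction_high_force)
  expect_error(high_force_fraction(ev[1:10, ], stats), "20")
})

test_that("saturation fit inverts its own model and flags degeneracy", {
  x <- c(0, 10^seq(-5, -2.3, length.out = 11))
  y <- (1 + 1.3 * x / 1e-4) / (1 + x / 1e-4)
  f <- fit_saturation(x, y)
  expect_lt(abs(f$params$K_D - 1e-4) / 1e-4, 1e-6)
  expect_lt(abs(f$params$u - 1), 1e-6)
  expect_lt(abs(f$params$b - 1.3), 1e-6)
  # limits: y(0) = u and y(x >> K_D) -> b
  cv <- function(xx) (f$params$u + f$params$b * xx / f$params$K_D) /
    (1 + xx / f$params$K_D)
  expect_equal(cv(0), f$params$u)
  expect_lt(abs(cv(1e6 * f$params$K_D) - f$params$b), 1e-5 * abs(f$params$b))
  # flat curve is flagged non-identifiable
  set.seed(7)
  ff <- fit_saturation(x, rep(2, 12) + rnorm(12, 0, 1e-4))
  expect_true("non_identifiable" %in% ff$flags)
  expect_error(fit_saturation(c(0, 1e-5, 2e-5), c(1, 1, 1)), "4 distinct")
})

test_that("peak-median follows the dominant mode, ignoring a minor one", {
  set.seed(9)
  x <- c(rnorm(400, 1, 0.08), rnorm(100, 2, 0.08))
  pm <- peak_median_force(x)
  expect_lt(abs(pm - 1), 0.05)
  expect_true(is.na(peak_median_force(c(1, 2))))
})
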