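#' Two-state Bell-Evans kinetic model with ligand action
#'
#' Parameterizes the folding kinetics of a bead-tethered RNA structure under
#' force. Unfolding and refolding rates follow Bell-Evans kinetics,
#' \eqn{k_u(F) = k_{u0} e^{F x_u / k_BT}} and
#' \eqn{k_f(F) = k_{f0} e^{-F x_f / k_BT}}. Ligand acts in one of two modes:
#'
#' * `kinetic_stabilizer` — the ligand reduces the unfolding rate saturably,
#'   \eqn{k_u \to k_u / (1 + (g-1) c/(c+K_D))} with `g =
#'   stabilization_factor`, and (optionally) speeds refolding by the analogous
#'   factor `fold_enhancement_factor` with half-saturation `K_D_fold`. This
#'   emulates stabilization of a partially folded (pre-pseudoknot) state.
#' * `pseudoknot_inducer` — on each refolding event the molecule commits to a
#'   far more stable fold (the ligand-bound pseudoknot) with probability
#'   \eqn{c/(c+K_D)}; that state unfolds with its own Bell parameters
#'   (`pk_k_unfold0`, `pk_x_unfold`). This emulates thermodynamic induction
#'   of a persistent pseudoknot by the cognate ligand.
#'
#' Extension is modeled as `baseline + compliance * F` plus `delta_L` when
#' unfolded, with Gaussian measurement noise added at emission time.
#' `tether_length` feeds the Brownian component of that noise (variance
#' `kBT * tether_length / F`).
#'
#' Default Bell parameters put the control median unfolding force near 9 pN
#' (inside the 5-15 pN analysis window) and the median refolding force near
#' 3 pN on a 1 pN/s ramp, with a folded/unfolded equilibrium near 6 pN.
#'
#' @param k_unfold0 Zero-force unfolding rate of the pre-pseudoknot state (1/s).
#' @param x_unfold Distance to the unfolding transition state (nm).
#' @param k_fold0 Zero-force folding rate (1/s).
#' @param x_fold Distance to the folding transition state (nm).
#' @param delta_L Extension change on unfolding (nm).
#' @param kBT Thermal energy (pN nm); default 4.07 (22 degrees C).
#' @param ligand_mode `"none"`, `"kinetic_stabilizer"` or `"pseudoknot_inducer"`.
#' @param K_D_ligand Ligand half-saturation (molar) for the primary effect.
#' @param stabilization_factor Maximal fold-reduction of the unfolding rate
#'   (kinetic_stabilizer mode), >= 1.
#' @param fold_enhancement_factor Maximal fold-increase of the refolding rate
#'   (kinetic_stabilizer mode), >= 1; 1 disables the refold effect.
#' @param K_D_fold Half-saturation for the refold effect (molar); defaults to
#'   `K_D_ligand`.
#' @param pk_k_unfold0,pk_x_unfold Bell parameters of the pseudoknot state
#'   (pseudoknot_inducer mode). Defaults put its unfolding peak near 18 pN.
#' @param baseline Extension offset at zero force (nm).
#' @param compliance Linear tether compliance (nm/pN).
#' @param tether_length Tether extension estimate used for Brownian noise (nm).
#' @return An object of class `smfs_kinetic_model`.
#' @export
kinetic_model <- function(k_unfold0 = 0.004, x_unfold = 2,
                          k_fold0 = 30, x_fold = 4,
                          delta_L = 15, kBT = 4.07,
                          ligand_mode = c("none", "kinetic_stabilizer",
                                          "pseudoknot_inducer"),
                          K_D_ligand = NA_real_,
                          stabilization_factor = 2,
                          fold_enhancement_factor = 1,
                          K_D_fold = K_D_ligand,
                          pk_k_unfold0 = 0.002, pk_x_unfold = 1,
                          baseline = 0, compliance = 0.2,
                          tether_length = 40) {
  ligand_mode <- match.arg(ligand_mode)
  stopifnot(k_unfold0 > 0, k_fold0 > 0, pk_k_unfold0 > 0,
            x_unfold > 0, x_fold > 0, kBT > 0, delta_L > 0,
            stabilization_factor >= 1, fold_enhancement_factor >= 1,
            tether_length > 0)
  if (ligand_mode != "none" && (is.na(K_D_ligand) || K_D_ligand <= 0)) {
    stop("K_D_ligand must be set (> 0) when ligand_mode != 'none'")
  }
  structure(
    list(k_unfold0 = k_unfold0, x_unfold = x_unfold, k_fold0 = k_fold0,
         x_fold = x_fold, delta_L = delta_L, kBT = kBT,
         ligand_mode = ligand_mode, K_D_ligand = K_D_ligand,
         stabilization_factor = stabilization_factor,
         fold_enhancement_factor = fold_enhancement_factor,
         K_D_fold = K_D_fold, pk_k_unfold0 = pk_k_unfold0,
         pk_x_unfold = pk_x_unfold, baseline = baseline,
         compliance = compliance, tether_length = tether_length),
    class = "smfs_kinetic_model"
  )
}

#' Bell-Evans rate at force F
#' @param force Force (pN), vectorized.
#' @param k0 Zero-force rate (1/s).
#' @param x Transition-state distance (nm); positive for unfolding, use the
#'   negative branch via `sign`.
#' @param kBT Thermal energy (pN nm).
#' @param sign `+1` for force-accelerated (unfolding), `-1` for
#'   force-decelerated (folding) transitions.
#' @return Rate(s) in 1/s.
#' @export
bell_rate <- function(force, k0, x, kBT, sign = 1) {
  k0 * exp(sign * force * x / kBT)
}

# saturable concentration factors --------------------------------------------

ligand_unfold_factor <- function(model, concentration) {
  if (model$ligand_mode != "kinetic_stabilizer" || concentration <= 0) return(1)
  h <- concentration / (concentration + model$K_D_ligand)
  1 / (1 + (model$stabilization_factor - 1) * h)
}

ligand_fold_factor <- function(model, concentration) {
  if (model$ligand_mode != "kinetic_stabilizer" || concentration <= 0 ||
      model$fold_enhancement_factor <= 1) return(1)
  h <- concentration / (concentration + model$K_D_fold)
  1 + (model$fold_enhancement_factor - 1) * h
}

pk_probability <- function(model, concentration) {
  if (model$ligand_mode != "pseudoknot_inducer" || concentration <= 0) return(0)
  concentration / (concentration + model$K_D_ligand)
}

#' Closed-form median rupture force on a linear force ramp
#'
#' For Bell kinetics \eqn{k(F) = k_0 e^{F x / k_BT}} under a loading rate
#' `ramp_rate`, the median rupture force is
#' \eqn{(k_BT/x)\,\ln(1 + \ln 2 \cdot x\,r/(k_BT\,k_0))}. Used as an
#' independent check on the simulator and to choose defaults.
#'
#' @param k0,x,kBT Bell parameters as in [bell_rate()].
#' @param ramp_rate Loading rate (pN/s).
#' @return Median rupture force (pN).
#' @export
ramp_median_force <- function(k0, x, kBT, ramp_rate) {
  (kBT / x) * log1p(log(2) * x * ramp_rate / (kBT * k0))
}

#' Half-saturation planted in the median-force dose response
#'
#' In kinetic_stabilizer mode the median unfolding force shifts by
#' \eqn{(k_BT/x_u)\,\ln(1 + (g-1)c/(c+K_D))}; this shift reaches half its
#' maximum \eqn{(k_BT/x_u)\ln g} exactly at \eqn{c = K_D/\sqrt{g}}. To plant
#' a desired half-saturation concentration (an EC50) in the simulated
#' response, set \eqn{K_D = EC_{50}\sqrt{g}}.
#'
#' @param ec50 Target half-saturation concentration (molar).
#' @param factor The saturable factor `g` (stabilization or fold-enhancement).
#' @return The `K_D` to hand to [kinetic_model()].
#' @export
kd_for_half_saturation <- function(ec50, factor) {
  stopifnot(ec50 > 0, factor > 1)
  ec50 * sqrt(factor)
}

# protocols -------------------------------------------------------------------

#' Force-ramp protocol
#'
#' Defaults mirror a typical MFS ramp experiment: 1 to 25 pN triangular
#' ramps at 1 pN/s, 50 cycles, sampled at 30 Hz.
#'
#' @param f_min,f_max Ramp endpoints (pN).
#' @param ramp_rate Loading rate (pN/s).
#' @param n_cycles Number of up/down cycles.
#' @param sample_rate Acquisition rate (Hz).
#' @param noise_sd Force-independent tracking-noise SD (nm).
#' @param brownian_noise Add force-dependent Brownian noise with variance
#'   `kBT * tether_length / F` on top of the tracking noise (default
#'   `FALSE`: constant 2 nm tracking noise is the reference regime).
#' @param seed Optional integer seed; when set, simulation output is
#'   bit-reproducible.
#' @return An `smfs_protocol` list with `kind = "ramp"`.
#' @export
protocol_ramp <- function(f_min = 1, f_max = 25, ramp_rate = 1,
                          n_cycles = 50, sample_rate = 30,
                          noise_sd = 2, brownian_noise = FALSE, seed = NULL) {
  stopifnot(f_min < f_max, ramp_rate > 0, n_cycles >= 1, sample_rate > 0,
            noise_sd >= 0)
  structure(list(kind = "ramp", f_min = f_min, f_max = f_max,
                 ramp_rate = ramp_rate, n_cycles = as.integer(n_cycles),
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 brownian_noise = brownian_noise, seed = seed),
            class = "smfs_protocol")
}

#' Constant-force protocol
#'
#' Defaults emulate a constant-force recording near the folded/unfolded
#' equilibrium (about 6 pN for the default kinetic model): 30 min at 30 Hz.
#'
#' @param hold_force Applied force (pN).
#' @param hold_duration Recording length (s).
#' @inheritParams protocol_ramp
#' @return An `smfs_protocol` list with `kind = "constant_force"`.
#' @export
protocol_constant_force <- function(hold_force = 6, hold_duration = 1800,
                                    sample_rate = 30, noise_sd = 2,
                                    brownian_noise = FALSE, seed = NULL) {
  stopifnot(hold_force > 0, hold_duration > 0, sample_rate > 0, noise_sd >= 0)
  structure(list(kind = "constant_force", hold_force = hold_force,
                 hold_duration = hold_duration, sample_rate = sample_rate,
                 noise_sd = noise_sd, brownian_noise = brownian_noise,
                 seed = seed),
            class = "smfs_protocol")
}

.emission_noise_sd <- function(model, protocol, force) {
  v <- rep(protocol$noise_sd^2, length(force))
  if (isTRUE(protocol$brownian_noise)) {
    v <- v + model$kBT * model$tether_length / pmax(force, 0.5)
  }
  sqrt(v)
}

.condition_for_mode <- function(model, concentration) {
  lig <- switch(model$ligand_mode,
                none = "control",
                kinetic_stabilizer = "compound4",
                pseudoknot_inducer = "preq1")
  if (concentration <= 0) condition_label("control", 0)
  else condition_label(lig, concentration)
}

# ramp simulation --------------------------------------------------------------

.ramp_force_profile <- function(protocol) {
  n_up <- max(2L, round((protocol$f_max - protocol$f_min) /
                          protocol$ramp_rate * protocol$sample_rate))
  f_up <- seq(protocol$f_min, protocol$f_max, length.out = n_up)
  f_cycle <- c(f_up, rev(f_up)[-1L][-(n_up - 1L)])  # drop repeated endpoints
  n_cyc <- length(f_cycle)
  force <- rep(f_cycle, protocol$n_cycles)
  cycle_id <- rep(seq_len(protocol$n_cycles), each = n_cyc)
  cycles <- data.frame(
    cycle_index = seq_len(protocol$n_cycles),
    up_start = (seq_len(protocol$n_cycles) - 1L) * n_cyc + 1L,
    up_end = (seq_len(protocol$n_cycles) - 1L) * n_cyc + n_up,
    down_start = (seq_len(protocol$n_cycles) - 1L) * n_cyc + n_up + 1L,
    down_end = seq_len(protocol$n_cycles) * n_cyc,
    f_min = protocol$f_min, f_max = protocol$f_max
  )
  list(force = force, cycle_id = cycle_id, cycles = cycles)
}

#' Simulate a force-ramp trace
#'
#' Evolves the folded/unfolded hidden state as a time-inhomogeneous two-state
#' (three-state in pseudoknot_inducer mode) Markov chain discretized at the
#' sampling rate, with per-sample transition probability
#' \eqn{1 - e^{-k(F)\Delta t}}. Extension is the force-dependent baseline plus
#' `delta_L` when unfolded plus Gaussian noise. The ground-truth event list
#' and state path are returned alongside the trace for oracle testing.
#'
#' @param model A [kinetic_model()].
#' @param protocol A [protocol_ramp()].
#' @param concentration Ligand concentration (molar).
#' @param bead_id Identifier for the generated trace.
#' @param force_scale Calibration factor applied to the *true* force driving
#'   the kinetics (the recorded force stays nominal); emulates bead-to-bead
#'   magnetism differences that per-bead normalization must remove.
#' @return A list with elements `trace` ([mfs_trace()]), `events` (data.frame of
#'   ground-truth jumps: direction, force, size, time, cycle_index,
#'   from_pseudoknot), `states` (per-sample hidden state: 0 folded, 1
#'   unfolded, 2 pseudoknot) and `cycles` (ground-truth cycle index ranges).
#' @export
simulate_ramp_trace <- function(model, protocol, concentration = 0,
                                bead_id = "bead1", force_scale = 1) {
  stopifnot(inherits(model, "smfs_kinetic_model"),
            identical(protocol$kind, "ramp"), concentration >= 0)
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  prof <- .ramp_force_profile(protocol)
  f_true <- prof$force * force_scale
  dt <- 1 / protocol$sample_rate
  ku <- bell_rate(f_true, model$k_unfold0, model$x_unfold, model$kBT) *
    ligand_unfold_factor(model, concentration)
  kpk <- bell_rate(f_true, model$pk_k_unfold0, model$pk_x_unfold, model$kBT)
  kf <- bell_rate(f_true, model$k_fold0, model$x_fold, model$kBT, sign = -1) *
    ligand_fold_factor(model, concentration)
  ppk <- rep(pk_probability(model, concentration), length(f_true))
  states <- .ctmc_step_path(ku, kpk, kf, ppk, dt, 0L)
  .check_resolution(states, ku, kpk, kf, dt)
  ext <- model$baseline + model$compliance * prof$force +
    model$delta_L * (states == 1L)
  sd_i <- .emission_noise_sd(model, protocol, prof$force)
  ext <- ext + stats::rnorm(length(ext), 0, sd_i)
  tr <- mfs_trace(time = (seq_along(prof$force) - 1L) * dt, extension = ext,
              force = prof$force, bead_id = bead_id,
              condition = .condition_for_mode(model, concentration),
              sample_rate = protocol$sample_rate, cycle_id = prof$cycle_id)
  list(trace = tr, events = .events_from_states(states, tr, model),
       states = states, cycles = prof$cycles)
}

.check_resolution <- function(states, ku, kpk, kf, dt) {
  k_occ <- ifelse(states == 0L, ku, ifelse(states == 1L, kf, kpk))
  if (max(k_occ) * dt > 1) {
    stop("resolution error: occupied-state hazard exceeds 0.5 per sample; ",
         "use a finer time step (higher sample_rate) or slower kinetics")
  }
}

.events_from_states <- function(states, tr, model) {
  n <- length(states)
  i <- which(states[-1L] != states[-n]) + 1L
  if (!length(i)) {
    return(data.frame(direction = character(), force = numeric(),
                      size = numeric(), time = numeric(),
                      cycle_index = integer(), from_pseudoknot = logical()))
  }
  from <- states[i - 1L]
  to <- states[i]
  data.frame(
    direction = ifelse(to == 1L, "unfold", "refold"),
    force = tr$force[i], size = model$delta_L, time = tr$time[i],
    cycle_index = if (is.null(tr$cycle_id)) NA_integer_ else tr$cycle_id[i],
    from_pseudoknot = (from == 2L) | (to == 2L)
  )
}

# constant-force simulation ----------------------------------------------------

#' Simulate a constant-force trace (Gillespie)
#'
#' Samples the exact continuous-time dwell sequence at fixed force with
#' exponential holding times, then emits noisy extension samples at the
#' protocol's acquisition rate. The ground-truth dwell table (folded /
#' unfolded, with censoring flags on the first and last residences) and the
#' per-sample state path are returned for oracle testing.
#'
#' @inheritParams simulate_ramp_trace
#' @param protocol A [protocol_constant_force()].
#' @return A list with `trace`, `dwells` (state, start, duration, censored,
#'   pseudoknot), and `states` (per-sample hidden state).
#' @export
simulate_constant_force_trace <- function(model, protocol, concentration = 0,
                                          bead_id = "bead1",
                                          force_scale = 1) {
  stopifnot(inherits(model, "smfs_kinetic_model"),
            identical(protocol$kind, "constant_force"), concentration >= 0)
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  f_true <- protocol$hold_force * force_scale
  ku <- bell_rate(f_true, model$k_unfold0, model$x_unfold, model$kBT) *
    ligand_unfold_factor(model, concentration)
  kpk <- bell_rate(f_true, model$pk_k_unfold0, model$pk_x_unfold, model$kBT)
  kf <- bell_rate(f_true, model$k_fold0, model$x_fold, model$kBT, sign = -1) *
    ligand_fold_factor(model, concentration)
  ppk <- pk_probability(model, concentration)
  # Gillespie: state 0 folded(pre), 1 unfolded, 2 folded(pk)
  t_now <- 0; s <- 0L; i <- 0L
  cap <- 1024L
  st <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  while (t_now < protocol$hold_duration) {
    rate <- c(ku, kf, kpk)[s + 1L]
    dwell <- stats::rexp(1L, rate)
    i <- i + 1L
    if (i > cap) {
      cap <- 2L * cap
      length(st) <- cap; length(t0) <- cap; length(t1) <- cap
    }
    st[i] <- s; t0[i] <- t_now
    t1[i] <- min(t_now + dwell, protocol$hold_duration)
    t_now <- t_now + dwell
    s <- if (s == 1L) {
      if (stats::runif(1L) < ppk) 2L else 0L
    } else 1L
  }
  st <- st[seq_len(i)]; t0 <- t0[seq_len(i)]; t1 <- t1[seq_len(i)]
  dwells <- data.frame(
    state = ifelse(st == 1L, "unfolded", "folded"),
    start = t0, duration = t1 - t0,
    censored = seq_along(st) %in% c(1L, length(st)),
    pseudoknot = st == 2L
  )
  n <- floor(protocol$hold_duration * protocol$sample_rate)
  t_samp <- (seq_len(n) - 1L) / protocol$sample_rate
  states <- st[findInterval(t_samp, t0)]
  ext <- model$baseline + model$compliance * protocol$hold_force +
    model$delta_L * (states == 1L)
  sd_i <- .emission_noise_sd(model, protocol,
                             rep(protocol$hold_force, n))
  ext <- ext + stats::rnorm(n, 0, sd_i)
  tr <- mfs_trace(time = t_samp, extension = ext,
              force = rep(protocol$hold_force, n), bead_id = bead_id,
              condition = .condition_for_mode(model, concentration),
              sample_rate = protocol$sample_rate)
  list(trace = tr, dwells = dwells, states = states)
}

# titrations -------------------------------------------------------------------

.titration_curves <- list(
  mfs_saturation = function(x, p) (p[["u"]] + p[["b"]] * x / p[["K_D"]]) /
    (1 + x / p[["K_D"]]),
  one_site_total = function(x, p) p[["B_max"]] * x / (p[["K_D"]] + x) +
    p[["ns_slope"]] * x + p[["background"]],
  termination = function(x, p) p[["e_min"]] +
    (p[["e_max"]] - p[["e_min"]]) * x / (p[["T_50"]] + x)
)

#' Simulate a titration table
#'
#' Draws signal values from one of the package's dose-response models with
#' multiplicative Gaussian noise, for testing the fitters.
#'
#' @param model `"mfs_saturation"` (params u, b, K_D), `"one_site_total"`
#'   (B_max, K_D, ns_slope, background) or `"termination"`
#'   (e_min, e_max, T_50).
#' @param true_params Named list/vector of the model's parameters.
#' @param concentrations Molar concentrations (>= 0).
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param n_replicates Replicates per concentration.
#' @param seed Optional seed for reproducibility.
#' @return data.frame with columns concentration, signal, replicate.
#' @export
simulate_titration <- function(model, true_params, concentrations,
                               noise_cv = 0, n_replicates = 1, seed = NULL) {
  if (!model %in% names(.titration_curves)) {
    stop("unknown titration model: ", model)
  }
  stopifnot(all(concentrations >= 0), noise_cv >= 0, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  curve <- .titration_curves[[model]]
  x <- rep(concentrations, times = n_replicates)
  rep_id <- rep(seq_len(n_replicates), each = length(concentrations))
  y <- curve(x, as.list(true_params))
  if (noise_cv > 0) y <- y * (1 + stats::rnorm(length(y), 0, noise_cv))
  data.frame(concentration = x, signal = y, replicate = rep_id)
}

# cohorts ----------------------------------------------------------------------

#' Simulate a multi-bead, multi-condition ramp cohort
#'
#' For each bead, draws a molecule-specific unfolding size from
#' `delta_L_range` and a bead-specific force-calibration factor from
#' `force_scale_range`, then records one ramp trace per condition (a control
#' plus each requested concentration). This reproduces the study design in
#' which every structure is measured first in carrier-only buffer and then
#' under increasing ligand.
#'
#' @param model A [kinetic_model()] (its `delta_L` is overridden per bead).
#' @param protocol A [protocol_ramp()].
#' @param concentrations Ligand concentrations (molar), excluding the control.
#' @param n_beads Number of beads/molecules.
#' @param delta_L_range Per-molecule unfolding-size range (nm).
#' @param force_scale_range Bead calibration-factor range.
#' @param seed Optional seed.
#' @return A list with one element per bead: `bead_id`, `delta_L`,
#'   `force_scale` and `runs`, a list of [simulate_ramp_trace()] results
#'   keyed by concentration (control first, named `"0"`).
#' @export
simulate_ramp_cohort <- function(model, protocol, concentrations,
                                 n_beads = 20,
                                 delta_L_range = c(12, 22),
                                 force_scale_range = c(0.92, 1.08),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_beads), function(b) {
    dl <- stats::runif(1, delta_L_range[1], delta_L_range[2])
    fs <- stats::runif(1, force_scale_range[1], force_scale_range[2])
    m <- model
    m$delta_L <- dl
    id <- sprintf("bead%03d", b)
    runs <- lapply(c(0, concentrations), function(conc) {
      simulate_ramp_trace(m, protocol, concentration = conc,
                          bead_id = id, force_scale = fs)
    })
    names(runs) <- as.character(c(0, concentrations))
    list(bead_id = id, delta_L = dl, force_scale = fs, runs = runs)
  })
}
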