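# sliding-window range via the two-pass (van Herk) running-extremum trick
.sliding_range <- function(x, w) {
  n <- length(x)
  if (w > n) stop("window longer than trace")
  pad <- ceiling(n / w) * w - n
  xm <- matrix(c(x, rep(x[n], pad)), nrow = w)
  fmax <- apply(xm, 2L, cummax); bmax <- apply(xm[w:1, , drop = FALSE], 2L, cummax)[w:1, , drop = FALSE]
  fmin <- apply(xm, 2L, cummin); bmin <- apply(xm[w:1, , drop = FALSE], 2L, cummin)[w:1, , drop = FALSE]
  fmax <- as.vector(fmax); bmax <- as.vector(bmax)
  fmin <- as.vector(fmin); bmin <- as.vector(bmin)
  i <- seq_len(n - w + 1L)
  smax <- pmax(bmax[i], fmax[i + w - 1L])
  smin <- pmin(bmin[i], fmin[i + w - 1L])
  smax - smin
}

#' Noise exclusion for constant-force traces
#'
#' A recording is excluded when the peak-to-peak extension range within any
#' sliding window exceeds twice the expected length of the structure
#' (tracking artifacts, bead sticking), when the structure never transitions
#' under force, or (for cognate-ligand conditions) when it never visits the
#' folded state.
#'
#' @param trace An [mfs_trace()] object at constant force.
#' @param expected_structure_length Expected unfolding length (nm).
#' @param window Sliding-window length (s), default 1.
#' @param require_transitions Fail traces with no folding/unfolding activity.
#' @return A list with `pass` and a character vector `reasons` (empty when
#'   passing).
#' @export
exclude_noisy <- function(trace, expected_structure_length, window = 1,
                          require_transitions = TRUE) {
  stopifnot(expected_structure_length > 0, window > 0)
  w <- round(window * trace$sample_rate)
  if (w > length(trace$extension)) stop("window longer than trace")
  reasons <- character()
  rng <- .sliding_range(trace$extension, w)
  if (max(rng) > 2 * expected_structure_length) {
    reasons <- c(reasons, sprintf(
      "extension range %.1f nm exceeds 2 x expected length (%.1f nm) within a %g s window",
      max(rng), 2 * expected_structure_length, window))
  }
  if (require_transitions) {
    sm <- stats::runmed(trace$extension,
                        .odd(max(3L, round(0.33 * trace$sample_rate))))
    spread <- diff(stats::quantile(sm, c(0.1, 0.9), names = FALSE))
    if (spread < 0.6 * expected_structure_length) {
      reasons <- c(reasons,
                   "no folding/unfolding response to the applied force")
    } else {
      midpoint <- mean(stats::quantile(sm, c(0.1, 0.9), names = FALSE))
      crossings <- sum(diff(sm > midpoint) != 0)
      if (crossings < 2L) {
        reasons <- c(reasons,
                     "no folding/unfolding response to the applied force")
      } else if (trace$condition$ligand == "preq1") {
        frac_folded <- mean(sm < midpoint)
        if (frac_folded < 0.01) {
          reasons <- c(reasons, "never formed a stable folded structure")
        }
      }
    }
  }
  list(pass = !length(reasons), reasons = unique(reasons))
}

.odd <- function(k) if (k %% 2L == 0L) k + 1L else k

#' Assign a folded/unfolded state to each sample
#'
#' The two emission levels are located as the two dominant modes of the
#' extension density (Gaussian KDE); each sample is then decoded by a
#' two-state Viterbi pass with Gaussian emissions at those levels (a common
#' SD estimated from within-mode samples) and a symmetric switching prior.
#' Runs shorter than `min_dwell_samples` are merged into their neighbors
#' (events faster than two samples are unresolvable at the acquisition
#' rate).
#'
#' @param trace An [mfs_trace()] object at constant force.
#' @param p_switch Per-sample switching prior (default 0.01).
#' @param min_dwell_samples Minimum run length retained (default 2).
#' @param min_separation Minimum level separation (nm); closer density modes
#'   are merged into one emission level.
#' @return An `smfs_state_path`: list with `states` (integer, 0 folded / 1
#'   unfolded per sample), `level_folded`, `level_unfolded`, `sd`,
#'   `p_switch`, `sample_rate`.
#' @export
assign_states <- function(trace, p_switch = 0.01, min_dwell_samples = 2L,
                          min_separation = 5) {
  x <- trace$extension
  d <- stats::density(x, n = 512L)
  pk <- .local_maxima(d$y)
  pk <- pk[d$y[pk] >= 0.05 * max(d$y)]
  pk <- .merge_close_modes(d, pk, min_separation)
  pk <- pk[order(d$y[pk], decreasing = TRUE)]
  if (length(pk) < 2L) {
    stop(sprintf("bead %s: no two-state structure resolved (unimodal extension)",
                 trace$bead_id))
  }
  mu <- sort(d$x[pk[1:2]])
  mid <- mean(mu)
  in0 <- x < mid & x > mu[1L] - (mid - mu[1L])
  in1 <- x >= mid & x < mu[2L] + (mu[2L] - mid)
  sd_hat <- sqrt(mean(c((x[in0] - mu[1L])^2, (x[in1] - mu[2L])^2)))
  sd_hat <- max(sd_hat, 1e-9 * max(1, diff(mu)))
  states <- .viterbi_two_state(x, mu[1L], mu[2L], sd_hat, p_switch)
  states <- .merge_short_runs(states, min_dwell_samples)
  structure(list(states = states, level_folded = mu[1L],
                 level_unfolded = mu[2L], sd = sd_hat, p_switch = p_switch,
                 sample_rate = trace$sample_rate),
            class = "smfs_state_path")
}

.merge_short_runs <- function(states, min_len) {
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1L) return(states)
    short <- which(r$lengths < min_len)
    if (!length(short)) return(states)
    j <- short[which.min(r$lengths[short])]
    r$values[j] <- if (j == 1L) r$values[2L] else r$values[j - 1L]
    states <- inverse.rle(r)
  }
}

#' Extract dwell segments from a state path
#'
#' Run-length encodes the per-sample state path into residence segments.
#' Durations are run length divided by the sampling rate; the first and last
#' segments are flagged censored (their true extent is unobserved).
#'
#' @param path An `smfs_state_path` from [assign_states()], or an integer
#'   vector of states (then `sample_rate` is required).
#' @param sample_rate Samples per second.
#' @return data.frame: `state` (`"folded"`/`"unfolded"`), `start` (s),
#'   `duration` (s), `censored`.
#' @export
extract_dwells <- function(path, sample_rate = NULL) {
  if (inherits(path, "smfs_state_path")) {
    states <- path$states
    if (is.null(sample_rate)) sample_rate <- path$sample_rate
  } else {
    states <- as.integer(path)
    if (is.null(sample_rate)) stop("sample_rate required for a bare state vector")
  }
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_seg <- length(r$lengths)
  data.frame(
    state = ifelse(r$values == 1L, "unfolded", "folded"),
    start = (starts - 1L) / sample_rate,
    duration = r$lengths / sample_rate,
    censored = seq_len(n_seg) %in% c(1L, n_seg)
  )
}

# --- exponential mixture MLE --------------------------------------------------

.expmix_loglik <- function(t, tau, w) {
  dens <- vapply(seq_along(tau),
                 function(j) w[j] / tau[j] * exp(-t / tau[j]),
                 numeric(length(t)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(t))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

.expmix_em <- function(t, k, tau0, w0, max_iter = 2000, tol = 1e-9) {
  tau <- tau0; w <- w0
  ll_old <- -Inf
  floor_tau <- min(t) / 10
  for (it in seq_len(max_iter)) {
    comp <- vapply(seq_len(k), function(j) w[j] / tau[j] * exp(-t / tau[j]),
                   numeric(length(t)))
    if (is.null(dim(comp))) comp <- matrix(comp, nrow = length(t))
    tot <- pmax(rowSums(comp), 1e-300)
    resp <- comp / tot
    nk <- colSums(resp)
    w <- nk / length(t)
    tau <- pmax(colSums(resp * t) / pmax(nk, 1e-300), floor_tau)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      return(list(tau = tau, w = w, loglik = ll, converged = TRUE))
    }
    ll_old <- ll
  }
  list(tau = tau, w = w, loglik = ll_old, converged = FALSE)
}

#' Exponential-mixture maximum likelihood for dwell times
#'
#' Fits mixtures of one up to `k_max` exponential lifetime distributions to
#' a sample of dwell durations by EM (multistart), and selects the model
#' order by the Bayesian information criterion
#' \eqn{BIC = -2\,\ell + p \ln n} with \eqn{p = 2k - 1} free parameters
#' (k lifetimes, k-1 weights). The single-exponential MLE is the closed-form
#' sample mean. Censored dwells are excluded by default.
#'
#' @param dwells Either a numeric vector of durations (s) or an
#'   [extract_dwells()] data.frame (then `state` selects which residences).
#' @param state When `dwells` is a data.frame: `"folded"` or `"unfolded"`.
#' @param k_max Largest model order tried (1-3).
#' @param n_starts EM restarts per model order (default 20).
#' @param seed Optional seed for the restarts.
#' @param include_censored Keep censored dwells (default drops them).
#' @return An object of class `smfs_expmix_scan`: list with `fits` (one
#'   `smfs_expmix` per k: `n_components`, `lifetimes` ascending, `weights`,
#'   `loglik`, `bic`, `n_dwells`), `best` (minimum-BIC fit) and `best_k`.
#' @export
fit_exp_mixture <- function(dwells, state = "folded", k_max = 3L,
                            n_starts = 20L, seed = NULL,
                            include_censored = FALSE) {
  if (is.data.frame(dwells)) {
    keep <- dwells$state == state
    if (!include_censored) keep <- keep & !dwells$censored
    t <- dwells$duration[keep]
  } else {
    t <- as.numeric(dwells)
  }
  t <- t[is.finite(t) & t > 0]
  if (length(t) < 10L) {
    stop("need at least 10 uncensored dwells to fit (have ", length(t), ")")
  }
  stopifnot(k_max >= 1L, k_max <= 3L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(t)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    if (k == 1L) {
      tau <- mean(t)                      # closed-form MLE
      ll <- .expmix_loglik(t, tau, 1)
      fits[[k]] <- list(n_components = 1L, lifetimes = tau, weights = 1,
                        loglik = ll, bic = -2 * ll + 1 * log(n),
                        n_dwells = n, converged = TRUE)
    } else {
      best <- NULL
      any_conv <- FALSE
      qs <- stats::quantile(t, probs = seq(0.1, 0.9, length.out = k),
                            names = FALSE)
      for (s in seq_len(n_starts)) {
        tau0 <- if (s == 1L) qs else qs * exp(stats::runif(k, -1.5, 1.5))
        w0 <- stats::runif(k, 0.2, 1); w0 <- w0 / sum(w0)
        f <- .expmix_em(t, k, tau0, w0)
        any_conv <- any_conv || f$converged
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      if (!any_conv) {
        warning("EM did not converge for k = ", k,
                " after ", n_starts, " restarts; reporting best found")
      }
      ord <- order(best$tau)
      ll <- best$loglik
      fits[[k]] <- list(n_components = k, lifetimes = best$tau[ord],
                        weights = best$w[ord], loglik = ll,
                        bic = -2 * ll + (2 * k - 1) * log(n),
                        n_dwells = n, converged = any_conv)
    }
    class(fits[[k]]) <- "smfs_expmix"
  }
  bics <- vapply(fits, function(f) f$bic, 0)
  structure(list(fits = fits, best = fits[[which.min(bics)]],
                 best_k = which.min(bics)),
            class = "smfs_expmix_scan")
}

#' @export
print.smfs_expmix <- function(x, ...) {
  cat(sprintf("<exp mixture> k=%d, n=%d, BIC=%.2f\n",
              x$n_components, x$n_dwells, x$bic))
  for (j in seq_len(x$n_components)) {
    cat(sprintf("  tau=%.4g s (w=%.3f)\n", x$lifetimes[j], x$weights[j]))
  }
  invisible(x)
}

#' @export
print.smfs_expmix_scan <- function(x, ...) {
  cat(sprintf("<exp mixture scan> best k = %d by BIC\n", x$best_k))
  print(x$best)
  invisible(x)
}

# --- per-molecule summaries and aggregation ----------------------------------

#' Summarize one molecule's constant-force kinetics
#'
#' Computes the per-state mean observed lifetimes and the corresponding log
#' rates, log(1/lifetime). For conditions where the folded-state lifetimes
#' are a two-component mixture (cognate-ligand conditions), the MLE
#' component lifetimes and weights are used instead of the pooled mean, and
#' the weight of the longer-lived component is reported as the stable-fold
#' (pseudoknot) occupancy.
#'
#' @param dwells [extract_dwells()] table for one molecule/condition.
#' @param bead_id,condition Metadata.
#' @param mixture `"never"` (pooled means), `"always"` (force a k<=2 mixture
#'   on folded dwells), or `"auto"` (use the mixture when BIC selects k=2).
#' @param seed Seed for mixture restarts.
#' @return One-row data.frame: `bead_id`, `condition_ligand`,
#'   `condition_conc_molar`, `mean_folded_lifetime`,
#'   `mean_unfolded_lifetime`, `log_unfold_rate`, `log_refold_rate`,
#'   `tau_short`, `tau_long`, `long_component_weight`, `mixture_k`.
#' @export
summarize_dwells <- function(dwells, bead_id, condition,
                             mixture = c("auto", "never", "always"),
                             seed = NULL) {
  mixture <- match.arg(mixture)
  fold <- dwells$duration[dwells$state == "folded" & !dwells$censored]
  unf <- dwells$duration[dwells$state == "unfolded" & !dwells$censored]
  mf <- if (length(fold)) mean(fold) else NA_real_
  mu <- if (length(unf)) mean(unf) else NA_real_
  tau_s <- NA_real_; tau_l <- NA_real_; wl <- 0; k_sel <- 1L
  log_unfold <- if (is.na(mf)) NA_real_ else log(1 / mf)
  if (mixture != "never" && length(fold) >= 10L) {
    scan <- fit_exp_mixture(fold, k_max = 2L, seed = seed)
    use <- if (mixture == "always") scan$fits[[2L]] else scan$best
    if (use$n_components == 2L) {
      k_sel <- 2L
      tau_s <- use$lifetimes[1L]; tau_l <- use$lifetimes[2L]
      wl <- use$weights[2L]
      log_unfold <- log(1 / tau_s)  # rate of the short-lived (pre-fold) state
    }
  }
  data.frame(bead_id = bead_id,
             condition_ligand = condition$ligand,
             condition_conc_molar = condition$concentration,
             mean_folded_lifetime = mf, mean_unfolded_lifetime = mu,
             log_unfold_rate = log_unfold,
             log_refold_rate = if (is.na(mu)) NA_real_ else log(1 / mu),
             tau_short = tau_s, tau_long = tau_l,
             long_component_weight = wl, mixture_k = k_sel)
}

#' Aggregate log rates across molecules with per-bead control normalization
#'
#' Paramagnetic beads differ slightly in magnetism, so absolute rates are
#' not comparable across molecules; log rates scale linearly with force
#' (Kramers-Bell), so subtracting each molecule's own control log rate
#' removes the bead-specific offset. Normalized log rates are then averaged
#' across molecules per condition.
#'
#' @param summaries Row-bound [summarize_dwells()] output across beads and
#'   conditions.
#' @param control_ligand Ligand label of the control condition.
#' @return A list with `per_bead` (adds `normalized_log_unfold_rate`,
#'   `normalized_log_refold_rate`) and `by_condition` (mean and SD of the
#'   normalized log rates and of the long-component weight, with molecule
#'   counts). Beads without a control are dropped with a warning.
#' @export
aggregate_rates <- function(summaries, control_ligand = "control") {
  ctrl <- summaries[summaries$condition_ligand == control_ligand, ,
                    drop = FALSE]
  cu <- stats::setNames(ctrl$log_unfold_rate, ctrl$bead_id)
  cr <- stats::setNames(ctrl$log_refold_rate, ctrl$bead_id)
  have <- summaries$bead_id %in% ctrl$bead_id
  if (any(!have)) {
    warning("dropping bead(s) without control condition: ",
            paste(unique(summaries$bead_id[!have]), collapse = ", "))
  }
  per <- summaries[have, , drop = FALSE]
  per$normalized_log_unfold_rate <- per$log_unfold_rate - cu[per$bead_id]
  per$normalized_log_refold_rate <- per$log_refold_rate - cr[per$bead_id]
  key <- paste(per$condition_ligand, per$condition_conc_molar)
  agg <- lapply(split(per, key), function(d) {
    data.frame(condition_ligand = d$condition_ligand[1L],
               condition_conc_molar = d$condition_conc_molar[1L],
               n_molecules = nrow(d),
               mean_norm_log_unfold = mean(d$normalized_log_unfold_rate,
                                           na.rm = TRUE),
               sd_norm_log_unfold = stats::sd(d$normalized_log_unfold_rate),
               mean_norm_log_refold = mean(d$normalized_log_refold_rate,
                                           na.rm = TRUE),
               sd_norm_log_refold = stats::sd(d$normalized_log_refold_rate),
               mean_long_weight = mean(d$long_component_weight, na.rm = TRUE),
               sd_long_weight = stats::sd(d$long_component_weight))
  })
  by_condition <- do.call(rbind, agg)
  rownames(by_condition) <- NULL
  by_condition <- by_condition[order(by_condition$condition_conc_molar), ]
  list(per_bead = per, by_condition = by_condition)
}

#' Stable-fold occupancy as a function of ligand concentration
#'
#' Tabulates the weight of the longer-lifetime folded component (the
#' ligand-stabilized pseudoknot) against concentration and, when enough
#' concentrations are available, fits the saturation model
#' \eqn{y = (u + b\,x/K_D)/(1 + x/K_D)} to estimate the half-saturation.
#'
#' @param summaries Row-bound [summarize_dwells()] output.
#' @param fit Fit the saturation curve (default `TRUE` when >= 4 distinct
#'   concentrations have two-component fits).
#' @return data.frame (concentration, mean/sd long-component weight,
#'   n_molecules) with attribute `fit` (a [fit_saturation()] result or
#'   `NULL`) and attribute `note` when no condition selected k = 2.
#' @export
occupancy_vs_concentration <- function(summaries, fit = TRUE) {
  key <- summaries$condition_conc_molar
  tab <- lapply(split(summaries, key), function(d) {
    data.frame(concentration = d$condition_conc_molar[1L],
               mean_long_weight = mean(d$long_component_weight, na.rm = TRUE),
               sd_long_weight = stats::sd(d$long_component_weight),
               n_molecules = nrow(d),
               any_two_component = any(d$mixture_k == 2L))
  })
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  tab <- tab[order(tab$concentration), ]
  if (!any(tab$any_two_component)) {
    out <- tab[0L, ]
    attr(out, "note") <- "single-exponential model selected everywhere; no stable-fold component"
    return(out)
  }
  fit_obj <- NULL
  if (fit && sum(tab$any_two_component | tab$concentration == 0) >= 4L) {
    fit_obj <- tryCatch(
      fit_saturation(tab$concentration, tab$mean_long_weight),
      error = function(e) NULL)
  }
  attr(tab, "fit") <- fit_obj
  tab
}
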