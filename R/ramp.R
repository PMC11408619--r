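#' Brownian-noise quality control for a trace
#'
#' Beads are analyzable only if their positional variance is roughly the
#' noise expected from Brownian motion of the tethered bead; excessive
#' tracking noise or a detached bead inflates it. Within each quiescent
#' high-force window the extension is linearly detrended and its variance
#' compared to the expected Brownian variance `kBT * tether_length / F`.
#' The trace fails if a majority of windows fall outside
#' `[1/tolerance_factor, tolerance_factor]` times the expectation.
#'
#' @param trace An [mfs_trace()] object.
#' @param tolerance_factor Acceptance band half-width as a variance ratio
#'   (>= 1); default 2.
#' @param tether_length Tether extension estimate (nm) entering the expected
#'   variance.
#' @param kBT Thermal energy (pN nm).
#' @param window Window length (s).
#' @param min_force_frac Samples with force above this fraction of the
#'   maximum force define the high-force windows.
#' @return A list with `pass` (logical) and `windows`, a data.frame of
#'   per-window observed/expected variance ratios.
#' @export
qc_brownian <- function(trace, tolerance_factor = 2, tether_length = 40,
                        kBT = 4.07, window = 1, min_force_frac = 0.75) {
  stopifnot(tolerance_factor >= 1, tether_length > 0)
  n_win <- max(2L, round(window * trace$sample_rate))
  if (length(trace$time) < n_win) {
    stop(sprintf("bead %s: trace shorter than one QC window", trace$bead_id))
  }
  hi <- trace$force >= min_force_frac * max(trace$force)
  runs <- rle(hi)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in which(runs$values & runs$lengths >= n_win)) {
    i0 <- starts[r]
    n_chunks <- floor(runs$lengths[r] / n_win)
    for (ch in seq_len(n_chunks)) {
      idx <- i0 + (ch - 1L) * n_win + seq_len(n_win) - 1L
      tt <- trace$time[idx]
      fit <- stats::lm.fit(cbind(1, tt - tt[1L]), trace$extension[idx])
      v_obs <- sum(fit$residuals^2) / (n_win - 2L)
      f_mean <- mean(trace$force[idx])
      v_exp <- kBT * tether_length / f_mean
      out[[length(out) + 1L]] <- data.frame(
        start = tt[1L], force = f_mean,
        var_observed = v_obs, var_expected = v_exp,
        ratio = v_obs / v_exp)
    }
  }
  if (!length(out)) {
    stop(sprintf("bead %s: no high-force window available for QC",
                 trace$bead_id))
  }
  windows <- do.call(rbind, out)
  ok <- windows$ratio >= 1 / tolerance_factor &
    windows$ratio <= tolerance_factor
  list(pass = mean(ok) > 0.5, windows = windows)
}

#' Segment a ramp trace into force cycles
#'
#' Locates ramp cycles as alternating minima and maxima of the
#' median-filtered force signal. Every sample between consecutive force
#' minima belongs to exactly one cycle; a trailing incomplete half-cycle is
#' flagged and not returned as a cycle.
#'
#' @param trace An [mfs_trace()] object whose force is a repeated up/down ramp.
#' @param smooth_window Median-filter length (s) applied to the force before
#'   extremum search.
#' @return A data.frame with one row per complete cycle: `cycle_index`,
#'   `up_start`, `up_end`, `down_start`, `down_end` (sample indices),
#'   `f_min`, `f_max`. Attribute `truncated` is `TRUE` when a trailing
#'   partial cycle was discarded. Zero rows (with a warning) when no
#'   complete ramp is present.
#' @export
segment_cycles <- function(trace, smooth_window = 0.5) {
  f <- trace$force
  k <- max(3L, round(smooth_window * trace$sample_rate))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(f) %% 2L == 1L) length(f) else length(f) - 1L)
  fs <- stats::runmed(f, k)
  lo <- min(fs); hi <- max(fs)
  if (hi - lo < .Machine$double.eps^0.5) {
    warning("force profile is flat; no ramp cycles found")
    return(.empty_cycles())
  }
  lo_band <- lo + 0.2 * (hi - lo)
  hi_band <- hi - 0.2 * (hi - lo)
  minima <- .band_extrema(f, fs <= lo_band, which.min)
  maxima <- .band_extrema(f, fs >= hi_band, which.max)
  # boundaries: minima; a terminal low run counts as a closing boundary
  if (length(minima) < 2L || !length(maxima)) {
    warning("fewer than one complete ramp cycle in trace")
    return(.empty_cycles())
  }
  rows <- list()
  truncated <- FALSE
  for (j in seq_len(length(minima) - 1L)) {
    b0 <- minima[j]; b1 <- minima[j + 1L]
    mx <- maxima[maxima > b0 & maxima < b1]
    if (length(mx) != 1L) { truncated <- TRUE; next }
    rows[[length(rows) + 1L]] <- data.frame(
      cycle_index = length(rows) + 1L,
      up_start = b0, up_end = mx, down_start = mx + 1L, down_end = b1 - 1L,
      f_min = f[b0], f_max = f[mx])
  }
  # samples after the last boundary form a partial cycle
  if (max(minima) < length(f) && any(maxima > max(minima))) truncated <- TRUE
  if (!length(rows)) {
    warning("fewer than one complete ramp cycle in trace")
    return(.empty_cycles())
  }
  out <- do.call(rbind, rows)
  attr(out, "truncated") <- truncated
  out
}

.empty_cycles <- function() {
  data.frame(cycle_index = integer(), up_start = integer(),
             up_end = integer(), down_start = integer(),
             down_end = integer(), f_min = numeric(), f_max = numeric())
}

.band_extrema <- function(fs, in_band, pick) {
  runs <- rle(in_band)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- integer()
  for (r in which(runs$values)) {
    seg <- starts[r]:ends[r]
    idx <- c(idx, seg[pick(fs[seg])])
  }
  idx
}

# --- event detection ---------------------------------------------------------

#' Detect unfolding/refolding events in ramp cycles
#'
#' For each ramp phase (rising force: unfolding candidates; falling force:
#' refolding candidates) abrupt jumps in bead Z-position are located either
#' by density clustering of the force-extension points (`method =
#' "cluster"`, the production detector) or by exhaustive least-squares
#' changepoint segmentation with a BIC stop (`method = "changepoint"`, the
#' independent oracle). By default at most one unfolding and one refolding
#' event is reported per cycle (the largest jump); `multi = TRUE` reports
#' every jump above `min_size`.
#'
#' The cluster detector removes a robust linear force-extension trend, finds
#' the density modes of the residual extension (Gaussian KDE), assigns each
#' point to a mode basin, orders the resulting clusters along the phase, and
#' emits an event at each persistent cluster boundary whose extension offset
#' (difference of the per-cluster linear trends at the boundary force)
#' exceeds `min_size`. A phase whose residual is unimodal yields no events.
#'
#' @param trace An [mfs_trace()] object.
#' @param cycles Cycle table from [segment_cycles()] (or simulator ground
#'   truth).
#' @param method `"cluster"` or `"changepoint"`.
#' @param min_size Minimum jump size (nm), default 5.
#' @param min_cluster Minimum points per cluster, default 10.
#' @param multi Report all jumps instead of the largest per phase.
#' @param smooth Median-filter length (s) applied to the extension within
#'   each phase before detection; suppresses Brownian noise while leaving
#'   step edges in place.
#' @return data.frame of events: `bead_id`, `cycle_index`, `direction`
#'   (`"unfold"`/`"refold"`), `force` (pN), `size` (nm), `time` (s).
#' @export
detect_events <- function(trace, cycles, method = c("cluster", "changepoint"),
                          min_size = 5, min_cluster = 10, multi = FALSE,
                          smooth = 0.33) {
  method <- match.arg(method)
  w <- max(1L, round(smooth * trace$sample_rate))
  if (w %% 2L == 0L) w <- w + 1L
  out <- list()
  for (j in seq_len(nrow(cycles))) {
    cy <- cycles[j, ]
    for (phase in c("up", "down")) {
      idx <- if (phase == "up") cy$up_start:cy$up_end
             else cy$down_start:cy$down_end
      if (length(idx) < 30L) next
      e_s <- if (w >= 3L && w < length(idx)) {
        stats::runmed(trace$extension[idx], w)
      } else trace$extension[idx]
      ev <- .phase_events(trace$force[idx], e_s,
                          trace$time[idx], method, min_size, min_cluster, w)
      if (is.null(ev) || !nrow(ev)) next
      ev$direction <- if (phase == "up") "unfold" else "refold"
      if (!multi && nrow(ev) > 1L) {
        # largest jump wins; near-ties (within 2 nm) break to the earliest
        cand <- ev[ev$size >= max(ev$size) - 2, , drop = FALSE]
        ev <- cand[which.min(cand$time), , drop = FALSE]
      }
      ev$cycle_index <- cy$cycle_index
      out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out)) {
    return(data.frame(bead_id = character(), cycle_index = integer(),
                      direction = character(), force = numeric(),
                      size = numeric(), time = numeric()))
  }
  ev <- do.call(rbind, out)
  data.frame(bead_id = trace$bead_id, cycle_index = ev$cycle_index,
             direction = ev$direction, force = ev$force, size = ev$size,
             time = ev$time)
}

# robust slope: median of chunk-wise OLS slopes (a jump corrupts one chunk)
.robust_slope <- function(f, e, n_chunks = 8L) {
  n <- length(f)
  br <- floor(seq(1L, n + 1L, length.out = n_chunks + 1L))
  sl <- vapply(seq_len(n_chunks), function(i) {
    ii <- br[i]:(br[i + 1L] - 1L)
    if (length(ii) < 4L || stats::var(f[ii]) == 0) return(NA_real_)
    stats::cov(f[ii], e[ii]) / stats::var(f[ii])
  }, 0)
  s <- stats::median(sl, na.rm = TRUE)
  if (is.na(s)) 0 else s
}

.phase_events <- function(f, e, tt, method, min_size, min_cluster, w = 1L) {
  b <- .robust_slope(f, e)
  r <- e - b * f
  if (method == "changepoint") {
    cp <- .binseg_bic(r, min_seg = max(5L, w), n_eff_div = w)
    if (!length(cp)) return(NULL)
    bounds <- c(0L, sort(cp), length(r))
    n_seg <- length(bounds) - 1L
    seg_idx <- lapply(seq_len(n_seg), function(i) {
      a <- bounds[i] + 1L; b2 <- bounds[i + 1L]
      len <- b2 - a + 1L
      trim <- min(w, (len - 1L) %/% 3L)
      if (i > 1L) a <- a + trim
      if (i < n_seg) b2 <- b2 - trim
      a:b2
    })
    # refit a pooled within-segment slope (common compliance, per-segment
    # intercepts); the initial robust slope has ~0.05 nm/pN error which,
    # over the ~12 pN between segment centroids, would bias jump sizes
    num <- 0; den <- 0
    for (ii in seg_idx) {
      if (length(ii) >= 4L && stats::var(f[ii]) > 0) {
        num <- num + stats::cov(f[ii], r[ii]) * (length(ii) - 1L)
        den <- den + stats::var(f[ii]) * (length(ii) - 1L)
      }
    }
    b_ref <- if (den > 0) num / den else 0
    means <- vapply(seg_idx, function(ii) {
      mean(r[ii]) - b_ref * mean(f[ii])
    }, 0)
    jumps <- diff(means)
    keep <- which(abs(jumps) >= min_size & .jump_sign_ok(f, sort(cp), jumps))
    if (!length(keep)) return(NULL)
    ci <- sort(cp)[keep] + 1L  # first sample of the new level
    return(data.frame(force = f[ci], size = abs(jumps[keep]), time = tt[ci]))
  }
  .cluster_events(f, r, tt, min_size, min_cluster, w)
}

# an unfolding (up phase, force increasing in time) adds extension going
# forward in time; a refolding (down phase, force decreasing) removes it.
# In both cases the high-force side of the boundary has the larger residual.
.jump_sign_ok <- function(f, cp, jumps) {
  increasing <- f[length(f)] > f[1L]
  if (increasing) jumps > 0 else jumps < 0
}

.binseg_bic <- function(r, min_seg = 5L, n_eff_div = 1L) {
  n <- length(r)
  n_eff <- max(8L, floor(n / n_eff_div))
  segs <- list(c(1L, n))
  cps <- integer()
  rss <- function(a, b) {
    x <- r[a:b]; sum((x - mean(x))^2)
  }
  total <- rss(1L, n)
  bic <- n_eff * log(total / n + 1e-300) + log(n_eff)
  repeat {
    best <- NULL
    for (si in seq_along(segs)) {
      a <- segs[[si]][1L]; b <- segs[[si]][2L]
      if (b - a + 1L < 2L * min_seg) next
      sp <- .best_split(r, a, b, min_seg)
      if (is.null(sp)) next
      if (is.null(best) || sp$gain > best$gain) {
        best <- c(sp, list(si = si))
      }
    }
    if (is.null(best)) break
    new_total <- total - best$gain
    k <- length(cps) + 1L
    new_bic <- n_eff * log(new_total / n + 1e-300) + (2 * k + 1) * log(n_eff)
    if (new_bic >= bic) break
    bic <- new_bic; total <- new_total
    a <- segs[[best$si]][1L]; b <- segs[[best$si]][2L]
    segs[[best$si]] <- c(a, best$cp)
    segs[[length(segs) + 1L]] <- c(best$cp + 1L, b)
    cps <- c(cps, best$cp)
  }
  cps
}

# exhaustive O(n) single-split search on [a, b] via cumulative sums
.best_split <- function(r, a, b, min_seg) {
  x <- r[a:b]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  i <- min_seg:(n - min_seg)
  rss_l <- cs2[i] - cs[i]^2 / i
  rss_r <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  rss0 <- cs2[n] - cs[n]^2 / n
  gain <- rss0 - (rss_l + rss_r)
  j <- which.max(gain)
  if (!is.finite(gain[j]) || gain[j] <= 0) return(NULL)
  list(cp = a + i[j] - 1L, gain = gain[j])
}

# plateau-tolerant interior local maxima of a density grid
.local_maxima <- function(y) {
  r <- rle(y)
  v <- r$values
  m <- length(v)
  if (m < 2L) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  left <- c(-Inf, v[-m])
  right <- c(v[-1L], -Inf)
  is_pk <- v > left & v > right
  as.integer(floor((starts[is_pk] + ends[is_pk]) / 2))
}

# merge density modes closer than min_sep: levels closer than the minimum
# jump size are one state, not two (prevents micro-mode fragmentation when
# the KDE bandwidth is small)
.merge_close_modes <- function(d, peaks, min_sep) {
  while (length(peaks) >= 2L) {
    gaps <- diff(d$x[peaks])
    j <- which.min(gaps)
    if (gaps[j] >= min_sep) break
    drop <- if (d$y[peaks[j]] < d$y[peaks[j + 1L]]) j else j + 1L
    peaks <- peaks[-drop]
  }
  peaks
}

.cluster_events <- function(f, r, tt, min_size, min_cluster, w = 1L) {
  n <- length(r)
  d <- tryCatch(stats::density(r, n = 512L), error = function(e) NULL)
  if (is.null(d)) return(NULL)
  y <- d$y
  peaks <- .local_maxima(y)
  peaks <- peaks[y[peaks] >= 0.05 * max(y)]
  peaks <- .merge_close_modes(d, peaks, min_size)
  if (length(peaks) < 2L) return(NULL)
  # valleys between retained peaks split the residual axis into basins
  valleys <- vapply(seq_len(length(peaks) - 1L), function(i) {
    seg <- peaks[i]:peaks[i + 1L]
    d$x[seg[which.min(y[seg])]]
  }, 0)
  lab <- findInterval(r, valleys) + 1L
  sizes <- tabulate(lab, nbins = length(peaks))
  keep <- which(sizes >= min_cluster)
  if (length(keep) < 2L) return(NULL)
  # reassign points of dropped basins to the nearest kept mode
  mode_x <- d$x[peaks]
  lab <- keep[max.col(-abs(outer(r, mode_x[keep], "-")), "first")]
  # order clusters along time; find persistent label switches
  lab_s <- stats::runmed(lab, min(9L, if (n %% 2L) n else n - 1L))
  sw <- which(lab_s[-1L] != lab_s[-n]) + 1L
  if (!length(sw)) return(NULL)
  # per-cluster linear force-extension trend, excluding a guard zone around
  # each switch where the median filter blends the two levels
  guard <- rep(FALSE, n)
  for (ci in sw) {
    guard[max(1L, ci - w):min(n, ci + w)] <- TRUE
  }
  fits <- lapply(keep, function(k) {
    ii <- lab == k & !guard
    if (sum(ii) < 3L) ii <- lab == k
    if (stats::var(f[ii]) == 0) c(mean(r[ii]), 0)
    else {
      b <- stats::cov(f[ii], r[ii]) / stats::var(f[ii])
      c(mean(r[ii]) - b * mean(f[ii]), b)
    }
  })
  names(fits) <- as.character(keep)
  # local level at the boundary: median of the nearest cluster samples
  # outside the guard zone, detrended to the boundary force with the
  # cluster's slope
  local_level <- function(k, side, ci, fb) {
    cf <- fits[[as.character(k)]]
    if (is.null(cf)) return(NA_real_)
    idx <- if (side == "left") seq_len(max(ci - w - 1L, 0L))
           else if (ci + w + 1L <= n) (ci + w + 1L):n else integer()
    idx <- idx[lab_s[idx] == k]
    if (!length(idx)) return(cf[1L] + cf[2L] * fb)
    idx <- if (side == "left") utils::tail(idx, 45L) else utils::head(idx, 45L)
    stats::median(r[idx] - cf[2L] * (f[idx] - fb))
  }
  out <- list()
  for (ci in sw) {
    k0 <- lab_s[ci - 1L]; k1 <- lab_s[ci]
    fb <- f[ci]
    l0 <- local_level(k0, "left", ci, fb)
    l1 <- local_level(k1, "right", ci, fb)
    if (is.na(l0) || is.na(l1)) next
    off <- l1 - l0
    increasing <- f[n] > f[1L]
    signed_ok <- if (increasing) off > 0 else off < 0
    if (abs(off) >= min_size && signed_ok) {
      out[[length(out) + 1L]] <- data.frame(force = fb, size = abs(off),
                                            time = tt[ci])
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# --- structure statistics and selection --------------------------------------

#' Per-bead, per-condition structure statistics
#'
#' Summarizes detected events over a condition's ramp cycles: analyzable
#' cycle count, cycles with an unfolding event, and median unfolding /
#' refolding forces and unfolding size. Cycles without any event count as
#' analyzable (the structure stayed folded).
#'
#' @param events Event table from [detect_events()].
#' @param cycles Cycle table for the same recording.
#' @param bead_id,condition Metadata carried into the output.
#' @return One-row data.frame with fields `bead_id`, `condition_ligand`,
#'   `condition_conc_molar`, `n_cycles_analyzable`, `n_cycles_with_unfold`,
#'   `median_unfold_force`, `median_refold_force`, `median_unfold_size`,
#'   `unfold_fraction`. Medians are `NA` (flagged) when no events exist.
#' @export
compute_structure_stats <- function(events, cycles, bead_id, condition) {
  un <- events[events$direction == "unfold", , drop = FALSE]
  re <- events[events$direction == "refold", , drop = FALSE]
  n_cy <- nrow(cycles)
  n_un <- length(unique(un$cycle_index))
  data.frame(
    bead_id = bead_id,
    condition_ligand = condition$ligand,
    condition_conc_molar = condition$concentration,
    n_cycles_analyzable = n_cy,
    n_cycles_with_unfold = n_un,
    median_unfold_force = if (nrow(un)) stats::median(un$force) else NA_real_,
    median_refold_force = if (nrow(re)) stats::median(re$force) else NA_real_,
    median_unfold_size = if (nrow(un)) stats::median(un$size) else NA_real_,
    unfold_fraction = if (n_cy) n_un / n_cy else 0
  )
}

#' Selection criteria for analyzable RNA structures
#'
#' Defaults encode the analysis windows used to define an analyzable
#' structure: control-condition unfolding force within 5-15 pN and size
#' within 10-25 nm, more than 20 analyzable cycles, an unfolding event in
#' strictly more than 80% of cycles, and presence in more than half of the
#' tested conditions.
#'
#' @param unfold_force_window pN interval.
#' @param unfold_size_window nm interval.
#' @param min_cycles Minimum analyzable cycles (pass requires
#'   `n > min_cycles - 1`).
#' @param min_unfold_fraction Strict lower bound on the unfolding proportion.
#' @param min_condition_presence Strict lower bound on the fraction of
#'   conditions in which the bead appears.
#' @return An `smfs_criteria` list.
#' @export
selection_criteria <- function(unfold_force_window = c(5, 15),
                               unfold_size_window = c(10, 25),
                               min_cycles = 21L,
                               min_unfold_fraction = 0.8,
                               min_condition_presence = 0.5) {
  stopifnot(diff(unfold_force_window) > 0, diff(unfold_size_window) > 0,
            min_unfold_fraction > 0, min_unfold_fraction <= 1,
            min_condition_presence > 0, min_condition_presence <= 1)
  structure(list(unfold_force_window = unfold_force_window,
                 unfold_size_window = unfold_size_window,
                 min_cycles = as.integer(min_cycles),
                 min_unfold_fraction = min_unfold_fraction,
                 min_condition_presence = min_condition_presence),
            class = "smfs_criteria")
}

#' Select analyzable structures across conditions
#'
#' Applies [selection_criteria()] to a table of per-bead, per-condition
#' structure statistics. All windowed checks use the bead's control
#' condition; the presence check counts the fraction of distinct conditions
#' in which the bead was recorded.
#'
#' @param stats Row-bound output of [compute_structure_stats()] across beads
#'   and conditions.
#' @param criteria An [selection_criteria()] object.
#' @param control_ligand Ligand label of the control condition.
#' @return data.frame with one row per bead: per-criterion logical verdicts
#'   (`force_window`, `size_window`, `cycles`, `unfold_fraction`,
#'   `presence`) and the overall `selected` flag.
#' @export
select_structures <- function(stats, criteria = selection_criteria(),
                              control_ligand = "control") {
  ctrl <- stats[stats$condition_ligand == control_ligand, , drop = FALSE]
  if (!nrow(ctrl)) stop("no control condition present in stats table")
  conds <- unique(paste(stats$condition_ligand, stats$condition_conc_molar))
  n_cond <- length(conds)
  beads <- unique(stats$bead_id)
  rows <- lapply(beads, function(b) {
    cb <- ctrl[ctrl$bead_id == b, , drop = FALSE]
    present <- length(unique(paste(
      stats$condition_ligand[stats$bead_id == b],
      stats$condition_conc_molar[stats$bead_id == b]))) / n_cond
    if (!nrow(cb)) {
      return(data.frame(bead_id = b, force_window = FALSE,
                        size_window = FALSE, cycles = FALSE,
                        unfold_fraction = FALSE,
                        presence = present > criteria$min_condition_presence,
                        selected = FALSE))
    }
    cb <- cb[1L, ]
    fw <- !is.na(cb$median_unfold_force) &&
      cb$median_unfold_force >= criteria$unfold_force_window[1L] &&
      cb$median_unfold_force <= criteria$unfold_force_window[2L]
    sw <- !is.na(cb$median_unfold_size) &&
      cb$median_unfold_size >= criteria$unfold_size_window[1L] &&
      cb$median_unfold_size <= criteria$unfold_size_window[2L]
    cyc <- cb$n_cycles_analyzable > criteria$min_cycles - 1L
    uf <- cb$unfold_fraction > criteria$min_unfold_fraction
    pres <- present > criteria$min_condition_presence
    data.frame(bead_id = b, force_window = fw, size_window = sw,
               cycles = cyc, unfold_fraction = uf, presence = pres,
               selected = fw && sw && cyc && uf && pres)
  })
  do.call(rbind, rows)
}

#' Normalize event forces by each bead's control medians
#'
#' Divides every unfolding force by the same bead's control median unfolding
#' force, and every refolding force by the control median refolding force,
#' yielding dimensionless normalized forces (control medians map to 1 by
#' construction). Beads without a defined control median are dropped with a
#' warning.
#'
#' @param events Event table ([detect_events()] output, any conditions) with
#'   a `condition_conc_molar`/`condition_ligand` annotation or paired with
#'   `stats`.
#' @param stats Structure-statistics table containing the control rows.
#' @param control_ligand Ligand label of the control condition.
#' @return `events` with an additional `force_norm` column.
#' @export
normalize_forces <- function(events, stats, control_ligand = "control") {
  ctrl <- stats[stats$condition_ligand == control_ligand, , drop = FALSE]
  med_un <- stats::setNames(ctrl$median_unfold_force, ctrl$bead_id)
  med_re <- stats::setNames(ctrl$median_refold_force, ctrl$bead_id)
  ref <- ifelse(events$direction == "unfold",
                med_un[events$bead_id], med_re[events$bead_id])
  bad <- is.na(ref) | ref <= 0
  if (any(bad)) {
    warning(sprintf(
      "excluding %d event(s) from bead(s) without a control median: %s",
      sum(bad), paste(unique(events$bead_id[bad]), collapse = ", ")))
  }
  events <- events[!bad, , drop = FALSE]
  events$force_norm <- events$force / ref[!bad]
  events
}

#' Fraction of high-force cycles per condition
#'
#' The threshold is the 95th percentile (linear-interpolation convention) of
#' the control condition's normalized unfolding forces. For each condition
#' the fraction of analyzable cycles whose normalized unfolding force
#' exceeds the threshold, or that contained no unfolding event at all, is
#' reported. Cycles that never unfold are evidence of a very stable fold and
#' count toward the numerator.
#'
#' @param norm_events Normalized event table from [normalize_forces()], with
#'   `condition_ligand` and `condition_conc_molar` columns.
#' @param stats Structure-statistics table (provides per-condition analyzable
#'   and unfolded cycle counts).
#' @param control_ligand Ligand label of the control condition.
#' @param percentile Threshold percentile of the control distribution.
#' @return data.frame per condition: `condition_ligand`,
#'   `condition_conc_molar`, `n_cycles`, `n_over`, `n_no_unfold`,
#'   `fraction_high_force` (`NA`, flagged, for empty conditions), plus the
#'   `threshold` attribute.
#' @export
high_force_fraction <- function(norm_events, stats,
                                control_ligand = "control",
                                percentile = 0.95) {
  un <- norm_events[norm_events$direction == "unfold", , drop = FALSE]
  ctrl <- un[un$condition_ligand == control_ligand, , drop = FALSE]
  if (nrow(ctrl) < 20L) {
    stop("control distribution must contain at least 20 unfolding events")
  }
  thr <- unname(stats::quantile(ctrl$force_norm, percentile, type = 7))
  key <- function(d) paste(d$condition_ligand, d$condition_conc_molar)
  conds <- unique(stats[, c("condition_ligand", "condition_conc_molar")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    kc <- key(conds[i, ])
    st <- stats[key(stats) == kc, , drop = FALSE]
    ev <- un[key(un) == kc, , drop = FALSE]
    n_cy <- sum(st$n_cycles_analyzable)
    n_no <- sum(st$n_cycles_analyzable - st$n_cycles_with_unfold)
    n_over <- sum(ev$force_norm > thr)
    data.frame(condition_ligand = conds$condition_ligand[i],
               condition_conc_molar = conds$condition_conc_molar[i],
               n_cycles = n_cy, n_over = n_over, n_no_unfold = n_no,
               fraction_high_force =
                 if (n_cy > 0) (n_over + n_no) / n_cy else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}

#' Median force at the maximum peak of a force distribution
#'
#' Locates the modal peak of a (normalized) force sample by Gaussian kernel
#' density estimation with Silverman's bandwidth, then returns the median of
#' the observations within one bandwidth of the peak. This summarizes the
#' dominant population while ignoring a secondary high-force population.
#'
#' @param forces Numeric vector of (normalized) forces.
#' @return The peak-median (same units as input); `NA` for fewer than 5
#'   observations.
#' @export
peak_median_force <- function(forces) {
  forces <- forces[is.finite(forces)]
  if (length(forces) < 5L) return(NA_real_)
  d <- stats::density(forces, bw = "nrd0")
  m <- d$x[which.max(d$y)]
  sel <- forces >= m - d$bw & forces <= m + d$bw
  if (!any(sel)) return(m)
  stats::median(forces[sel])
}
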