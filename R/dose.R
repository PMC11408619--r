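.new_dose_fit <- function(model, params, std_errors, concentrations,
                          residual_norm, flags = character(), fit = NULL) {
  structure(list(model = model, params = params, std_errors = std_errors,
                 concentrations = concentrations,
                 residual_norm = residual_norm, flags = flags, fit = fit),
            class = "smfs_dose_fit")
}

#' @export
print.smfs_dose_fit <- function(x, ...) {
  cat(sprintf("<dose-response fit: %s>\n", x$model))
  for (p in names(x$params)) {
    cat(sprintf("  %-10s %.6g (SE %.3g)\n", p, x$params[[p]],
                x$std_errors[[p]]))
  }
  cat(sprintf("  residual norm %.4g over %d points\n", x$residual_norm,
              length(x$concentrations)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# multistart scaffold: profile the half-saturation constant over a decade
# grid (the remaining parameters are conditionally linear), then polish the
# best start with Levenberg-Marquardt.
.kd_grid <- function(x, n = 25L) {
  xp <- x[x > 0]
  if (!length(xp)) stop("need at least one positive concentration")
  10^seq(log10(min(xp)) - 2, log10(max(xp)) + 2, length.out = n)
}

.nls_polish <- function(formula, data, start, lower, upper) {
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
}

.vcov_named <- function(fit) {
  v <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(v)) return(NULL)
  if (is.null(dimnames(v))) {
    dimnames(v) <- list(names(stats::coef(fit)), names(stats::coef(fit)))
  }
  v
}

.se_from_fit <- function(fit, nm) {
  se <- rep(NA_real_, length(nm))
  names(se) <- nm
  v <- .vcov_named(fit)
  if (!is.null(v)) se[colnames(v)] <- sqrt(pmax(diag(v), 0))
  se
}

#' Fit the MFS saturation dose-response model
#'
#' Nonlinear least squares of \eqn{y = (u + b\,x/K_D)/(1 + x/K_D)}: `u` is
#' the response at zero ligand, `b` the response at saturation and `K_D` the
#' half-saturation constant (the EC50 of the response). The half-saturation
#' is profiled over a decade grid (u, b are conditionally linear) before a
#' Levenberg-Marquardt polish, making the fit robust to poor starts. The fit
#' is flagged `non_identifiable` when `|b - u| < 2 SE(b - u)` (a flat
#' curve carries no information about `K_D`).
#'
#' @param x Concentrations (molar), at least 4 distinct values including a
#'   zero or near-zero point.
#' @param y Responses.
#' @param init Optional named starting values (`u`, `b`, `K_D`).
#' @return An `smfs_dose_fit` with `model = "mfs_saturation"`.
#' @export
fit_saturation <- function(x, y, init = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  dat <- data.frame(x = x, y = y)
  starts <- list()
  if (!is.null(init)) starts[[1L]] <- as.list(init)
  for (K in .kd_grid(x)) {
    h <- (x / K) / (1 + x / K)
    cf <- unname(stats::lm.fit(cbind(1 - h, h), y)$coefficients)
    starts[[length(starts) + 1L]] <- list(u = cf[1L], b = cf[2L], K_D = K)
  }
  best <- NULL; best_rss <- Inf
  for (s in starts) {
    if (!all(is.finite(unlist(s))) || s$K_D <= 0) next
    f <- .nls_polish(y ~ (u + b * x / K_D) / (1 + x / K_D), dat,
                     start = s, lower = c(-Inf, -Inf, 1e-300),
                     upper = c(Inf, Inf, Inf))
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (rss < best_rss) { best <- f; best_rss <- rss }
  }
  if (is.null(best)) {
    grid_rss <- min(vapply(starts, function(s) {
      h <- (x / s$K_D) / (1 + x / s$K_D)
      sum((y - (s$u * (1 - h) + s$b * h))^2)
    }, 0), na.rm = TRUE)
    stop(sprintf(
      "saturation fit failed to converge from any start (best residual sum of squares %.4g)",
      grid_rss))
  }
  cf <- stats::coef(best)
  se <- .se_from_fit(best, c("u", "b", "K_D"))
  flags <- character()
  v <- .vcov_named(best)
  if (!is.null(v)) {
    se_diff <- sqrt(max(v["b", "b"] + v["u", "u"] - 2 * v["b", "u"], 0))
    if (abs(cf[["b"]] - cf[["u"]]) < 2 * se_diff) {
      flags <- c(flags, "non_identifiable")
    }
  }
  .new_dose_fit("mfs_saturation",
                params = as.list(cf), std_errors = as.list(se),
                concentrations = x, residual_norm = sqrt(best_rss),
                flags = flags, fit = best)
}

#' Fit a one-site total binding model
#'
#' Least squares of
#' \eqn{signal = B_{max}\,x/(K_D + x) + ns\_slope \cdot x + background}: a
#' single saturable site plus (optionally) a linear nonspecific term, the
#' convention of "one-site total binding" in common curve-fitting software.
#' Set `fix_ns = TRUE` for the specific-only variant (`ns_slope = 0`).
#'
#' @param table A titration data.frame with columns `concentration` and
#'   `signal` (e.g. from [simulate_titration()]), or a numeric vector of
#'   concentrations when `signal` is given.
#' @param signal Responses, when `table` is a concentration vector.
#' @param fix_ns Constrain the nonspecific slope to zero.
#' @return An `smfs_dose_fit` with `model = "one_site_total"` and params
#'   `B_max`, `K_D`, `ns_slope`, `background`. Flag `not_saturated` when the
#'   fitted `K_D` exceeds the largest tested concentration.
#' @export
fit_one_site_total <- function(table, signal = NULL, fix_ns = FALSE) {
  if (is.data.frame(table)) {
    x <- table$concentration; y <- table$signal
  } else {
    x <- table; y <- signal
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 5L) stop("need at least 5 distinct concentrations")
  dat <- data.frame(x = x, y = y)
  best <- NULL; best_rss <- Inf
  for (K in .kd_grid(x)) {
    h <- x / (K + x)
    basis <- if (fix_ns) cbind(h, 1) else cbind(h, x, 1)
    cf <- unname(stats::lm.fit(basis, y)$coefficients)
    st <- if (fix_ns) list(B_max = cf[1L], background = cf[2L], K_D = K)
          else list(B_max = cf[1L], ns_slope = cf[2L], background = cf[3L],
                    K_D = K)
    if (!all(is.finite(unlist(st)))) next
    form <- if (fix_ns) y ~ B_max * x / (K_D + x) + background
            else y ~ B_max * x / (K_D + x) + ns_slope * x + background
    low <- if (fix_ns) c(-Inf, -Inf, 1e-300) else c(-Inf, -Inf, -Inf, 1e-300)
    f <- .nls_polish(form, dat, start = st, lower = low,
                     upper = rep(Inf, length(st)))
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (rss < best_rss) { best <- f; best_rss <- rss }
  }
  if (is.null(best)) stop("one-site total binding fit failed to converge")
  cf <- as.list(stats::coef(best))
  if (fix_ns) cf$ns_slope <- 0
  nm <- c("B_max", "K_D", "ns_slope", "background")
  se <- as.list(.se_from_fit(best, names(stats::coef(best))))
  if (fix_ns) se$ns_slope <- 0
  flags <- character()
  if (cf$K_D > max(x)) flags <- c(flags, "not_saturated")
  .new_dose_fit("one_site_total", params = cf[nm], std_errors = se[nm],
                concentrations = x, residual_norm = sqrt(best_rss),
                flags = flags, fit = best)
}

#' Transcription termination efficiency from gel band intensities
#'
#' The fraction of transcripts terminated at the riboswitch:
#' terminated band intensity divided by total (terminated + read-through)
#' intensity, per lane.
#'
#' @param terminated Terminated-band intensity (a.u., >= 0), vectorized.
#' @param readthrough Read-through-band intensity (a.u., >= 0).
#' @return Termination efficiency in `[0, 1]`.
#' @export
termination_efficiency <- function(terminated, readthrough) {
  if (any(terminated < 0 | readthrough < 0, na.rm = TRUE)) {
    stop("band intensities must be non-negative")
  }
  tot <- terminated + readthrough
  if (any(tot == 0, na.rm = TRUE)) {
    stop("terminated + readthrough must be positive in every lane")
  }
  terminated / tot
}

#' Fit the termination-efficiency dose-response (T50)
#'
#' Least squares of
#' \eqn{e(x) = e_{min} + (e_{max} - e_{min})\,x/(T_{50} + x)}; `T_50` is the
#' ligand concentration of half-maximal termination. Replicates are fitted
#' pooled; parameter uncertainty is reported both from the Jacobian and from
#' a seeded residual bootstrap (`boot_se`), mirroring replicate-scatter
#' error bars. The direction of the curve is free (`e_min`/`e_max` may
#' order either way).
#'
#' @param concentration Concentrations (molar), >= 5 distinct values.
#' @param efficiency Termination efficiencies in `[0, 1]`.
#' @param n_boot Residual-bootstrap resamples for `boot_se` (0 disables).
#' @param seed Seed for the bootstrap.
#' @return An `smfs_dose_fit` with `model = "termination"`, params `e_min`,
#'   `e_max`, `T_50`, and an extra element `boot_se`. Flag `not_saturated`
#'   when `T_50` exceeds the largest tested concentration (no saturation in
#'   range).
#' @export
fit_t50 <- function(concentration, efficiency, n_boot = 1000L, seed = NULL) {
  x <- concentration; y <- efficiency
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 5L) stop("need at least 5 distinct concentrations")
  if (any(y < -0.05 | y > 1.05)) {
    stop("efficiencies must lie in [0, 1]")
  }
  dat <- data.frame(x = x, y = y)
  best <- NULL; best_rss <- Inf
  for (K in .kd_grid(x)) {
    h <- x / (K + x)
    cf <- unname(stats::lm.fit(cbind(1 - h, h), y)$coefficients)
    st <- list(e_min = cf[1L], e_max = cf[2L], T_50 = K)
    if (!all(is.finite(unlist(st)))) next
    f <- .nls_polish(y ~ e_min + (e_max - e_min) * x / (T_50 + x), dat,
                     start = st, lower = c(-Inf, -Inf, 1e-300),
                     upper = c(Inf, Inf, Inf))
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (rss < best_rss) { best <- f; best_rss <- rss }
  }
  if (is.null(best)) stop("termination fit failed to converge")
  cf <- stats::coef(best)
  se <- .se_from_fit(best, c("e_min", "e_max", "T_50"))
  boot_se <- NULL
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    res <- stats::residuals(best)
    yhat <- stats::fitted(best)
    t50s <- rep(NA_real_, n_boot)
    for (bi in seq_len(n_boot)) {
      yb <- yhat + sample(res, replace = TRUE)
      fb <- .nls_polish(yb ~ e_min + (e_max - e_min) * x / (T_50 + x),
                        data.frame(x = x, yb = yb),
                        start = as.list(cf), lower = c(-Inf, -Inf, 1e-300),
                        upper = c(Inf, Inf, Inf))
      if (!is.null(fb)) t50s[bi] <- stats::coef(fb)[["T_50"]]
    }
    boot_se <- stats::sd(t50s, na.rm = TRUE)
  }
  flags <- character()
  if (cf[["T_50"]] > max(x)) flags <- c(flags, "not_saturated")
  out <- .new_dose_fit("termination", params = as.list(cf),
                       std_errors = as.list(se), concentrations = x,
                       residual_norm = sqrt(best_rss), flags = flags,
                       fit = best)
  out$boot_se <- boot_se
  out
}
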