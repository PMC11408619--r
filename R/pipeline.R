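#' Full ramp-experiment analysis for a cohort of traces
#'
#' Runs the complete force-ramp pipeline on a collection of single-bead
#' traces spanning conditions: cycle segmentation, event detection,
#' per-bead/condition structure statistics, structure selection on the
#' control condition, per-bead force normalization, the per-structure
#' peak-median dose response with its saturation fit, and the high-force
#' cycle fraction per condition.
#'
#' @param traces List of [mfs_trace()] objects (one per bead and condition).
#' @param criteria [selection_criteria()] to apply.
#' @param method Event-detection method (`"cluster"` or `"changepoint"`).
#' @param control_ligand Ligand label of the control condition.
#' @param fit_dose Fit saturation curves to the per-structure responses
#'   (needs >= 4 distinct concentrations).
#' @return A list: `stats` (per bead x condition), `selection` (per-bead
#'   verdicts), `events` (normalized event table, selected beads only),
#'   `dose` (per bead x condition peak-median normalized forces, unfold and
#'   refold), `high_force` (per-condition high-force fractions),
#'   `fit_unfold`, `fit_refold` ([fit_saturation()] results or `NULL`),
#'   `exclusions` (per-bead reason log).
#' @export
analyze_ramp_cohort <- function(traces, criteria = selection_criteria(),
                                method = "cluster",
                                control_ligand = "control",
                                fit_dose = TRUE) {
  stats_rows <- list(); ev_rows <- list()
  for (tr in traces) {
    cycles <- segment_cycles(tr)
    ev <- detect_events(tr, cycles, method = method)
    st <- compute_structure_stats(ev, cycles, tr$bead_id, tr$condition)
    stats_rows[[length(stats_rows) + 1L]] <- st
    if (nrow(ev)) {
      ev$condition_ligand <- tr$condition$ligand
      ev$condition_conc_molar <- tr$condition$concentration
      ev_rows[[length(ev_rows) + 1L]] <- ev
    }
  }
  stats <- do.call(rbind, stats_rows)
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else NULL
  selection <- select_structures(stats, criteria, control_ligand)
  sel_ids <- selection$bead_id[selection$selected]
  exclusions <- selection[!selection$selected, , drop = FALSE]
  stats_sel <- stats[stats$bead_id %in% sel_ids, , drop = FALSE]
  if (is.null(events) || !length(sel_ids)) {
    return(list(stats = stats, selection = selection, events = NULL,
                dose = NULL, high_force = NULL, fit_unfold = NULL,
                fit_refold = NULL, exclusions = exclusions))
  }
  events_sel <- events[events$bead_id %in% sel_ids, , drop = FALSE]
  events_norm <- normalize_forces(events_sel, stats_sel, control_ligand)
  # per-structure peak-median normalized force vs concentration
  key <- paste(events_norm$bead_id, events_norm$condition_conc_molar,
               events_norm$direction)
  dose <- lapply(split(events_norm, key), function(d) {
    data.frame(bead_id = d$bead_id[1L], direction = d$direction[1L],
               concentration = d$condition_conc_molar[1L],
               response = peak_median_force(d$force_norm),
               n_events = nrow(d))
  })
  dose <- do.call(rbind, dose)
  rownames(dose) <- NULL
  hff <- tryCatch(
    high_force_fraction(events_norm, stats_sel, control_ligand),
    error = function(e) NULL)
  fit_un <- fit_re <- NULL
  if (fit_dose) {
    fit_for <- function(dir) {
      d <- dose[dose$direction == dir & is.finite(dose$response), ,
                drop = FALSE]
      if (length(unique(d$concentration)) < 4L) return(NULL)
      tryCatch(fit_saturation(d$concentration, d$response),
               error = function(e) NULL)
    }
    fit_un <- fit_for("unfold")
    fit_re <- fit_for("refold")
  }
  list(stats = stats, selection = selection, events = events_norm,
       dose = dose, high_force = hff, fit_unfold = fit_un,
       fit_refold = fit_re, exclusions = exclusions)
}

#' Full constant-force analysis for a cohort of traces
#'
#' Runs noise exclusion, two-state assignment, dwell extraction and
#' per-molecule kinetic summaries over constant-force recordings, then
#' aggregates control-normalized log rates and the stable-fold occupancy
#' across molecules.
#'
#' @param traces List of [mfs_trace()] objects at constant force.
#' @param expected_structure_length Expected unfolding length (nm) for the
#'   noise filter.
#' @param mixture Passed to [summarize_dwells()].
#' @param control_ligand Control condition label.
#' @param seed Seed for mixture-fit restarts.
#' @return A list: `summaries` (per molecule x condition), `rates`
#'   ([aggregate_rates()] output), `occupancy`
#'   ([occupancy_vs_concentration()] table), `exclusions` (bead, reason).
#' @export
analyze_dwell_cohort <- function(traces, expected_structure_length = 15,
                                 mixture = "auto",
                                 control_ligand = "control", seed = NULL) {
  rows <- list(); excl <- list()
  for (tr in traces) {
    qc <- exclude_noisy(tr, expected_structure_length)
    if (!qc$pass) {
      excl[[length(excl) + 1L]] <- data.frame(
        bead_id = tr$bead_id,
        condition_ligand = tr$condition$ligand,
        condition_conc_molar = tr$condition$concentration,
        reason = paste(qc$reasons, collapse = "; "))
      next
    }
    path <- tryCatch(assign_states(tr), error = function(e) NULL)
    if (is.null(path)) {
      excl[[length(excl) + 1L]] <- data.frame(
        bead_id = tr$bead_id,
        condition_ligand = tr$condition$ligand,
        condition_conc_molar = tr$condition$concentration,
        reason = "no two-state structure resolved")
      next
    }
    dw <- extract_dwells(path)
    rows[[length(rows) + 1L]] <-
      summarize_dwells(dw, tr$bead_id, tr$condition, mixture = mixture,
                       seed = seed)
  }
  if (!length(rows)) stop("no analyzable constant-force traces")
  summaries <- do.call(rbind, rows)
  rates <- aggregate_rates(summaries, control_ligand)
  occupancy <- occupancy_vs_concentration(summaries)
  list(summaries = summaries, rates = rates, occupancy = occupancy,
       exclusions = if (length(excl)) do.call(rbind, excl) else NULL)
}

# --- configured pipeline ------------------------------------------------------

.config_error <- function(...) stop(sprintf(...), call. = FALSE)

#' Run a configured analysis pipeline
#'
#' Executes a simulate-then-analyze (or load-then-analyze) run from a
#' configuration list or YAML file and writes the result tables and a run
#' manifest to an output directory. Given identical configuration and seed
#' the outputs are byte-identical.
#'
#' Configuration fields: `seed` (integer), `analysis` (`"ramp"` or
#' `"dwell"`), `control_ligand`, either `input` (a trace CSV readable by
#' [read_traces()]) or `simulate` (fields `mode`, `K_D_ligand`,
#' `concentrations`, `n_beads`, and optional [kinetic_model()] /
#' [protocol_ramp()] overrides under `model` and `protocol`), and optional
#' `criteria` overrides for [selection_criteria()].
#'
#' @param config A list or path to a YAML file.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$output_dir`.
#' @return Invisibly, the analysis result list, with `manifest` attached.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out_dir)) out_dir <- config$output_dir
  if (is.null(out_dir)) .config_error("config error: no output directory")
  analysis <- config$analysis %||% "ramp"
  if (!analysis %in% c("ramp", "dwell")) {
    .config_error("config error: unknown analysis kind '%s'", analysis)
  }
  control_ligand <- config$control_ligand %||% "control"
  seed <- config$seed %||% 1L
  # -- assemble traces (validated before any computation) --
  if (!is.null(config$input)) {
    if (!file.exists(config$input)) {
      .config_error("config error: input file '%s' does not exist",
                    config$input)
    }
    traces <- read_traces(config$input)
  } else if (!is.null(config$simulate)) {
    traces <- .simulate_from_config(config$simulate, analysis, seed)
  } else {
    .config_error("config error: neither 'input' nor 'simulate' given")
  }
  ligs <- vapply(traces, function(tr) tr$condition$ligand, "")
  if (!any(ligs == control_ligand)) {
    .config_error("config error: no '%s' condition among the inputs",
                  control_ligand)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  crit <- do.call(selection_criteria, config$criteria %||% list())
  set.seed(seed)
  if (analysis == "ramp") {
    res <- analyze_ramp_cohort(traces, criteria = crit,
                               control_ligand = control_ligand)
    utils::write.csv(res$stats, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    if (!is.null(res$events)) {
      utils::write.csv(res$events, file.path(out_dir, "events.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(res$selection, file.path(out_dir, "selection.csv"),
                     row.names = FALSE)
    if (!is.null(res$dose)) {
      utils::write.csv(res$dose, file.path(out_dir, "dose.csv"),
                       row.names = FALSE)
    }
    fits <- list(
      unfold = if (!is.null(res$fit_unfold))
        res$fit_unfold$params else NULL,
      refold = if (!is.null(res$fit_refold))
        res$fit_refold$params else NULL)
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    res <- analyze_dwell_cohort(traces, control_ligand = control_ligand,
                                seed = seed)
    utils::write.csv(res$summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(res$rates$by_condition,
                     file.path(out_dir, "rates.csv"), row.names = FALSE)
    if (nrow(res$occupancy)) {
      utils::write.csv(res$occupancy, file.path(out_dir, "occupancy.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$exclusions)) {
      utils::write.csv(res$exclusions, file.path(out_dir, "exclusions.csv"),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    package = "smfs",
    version = as.character(utils::packageVersion("smfs")),
    seed = seed, analysis = analysis, control_ligand = control_ligand,
    criteria = unclass(crit), n_traces = length(traces))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(res, "manifest") <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.simulate_from_config <- function(sim, analysis, seed) {
  mode <- sim$mode %||% "none"
  model_args <- sim$model %||% list()
  model_args$ligand_mode <- mode
  if (!is.null(sim$K_D_ligand)) model_args$K_D_ligand <- sim$K_D_ligand
  model <- do.call(kinetic_model, model_args)
  concs <- unlist(sim$concentrations) %||% numeric()
  n_beads <- sim$n_beads %||% 5L
  set.seed(seed)
  if (analysis == "ramp") {
    proto <- do.call(protocol_ramp, sim$protocol %||% list())
    cohort <- simulate_ramp_cohort(model, proto, concs, n_beads = n_beads)
    unlist(lapply(cohort, function(b) {
      lapply(b$runs, function(r) r$trace)
    }), recursive = FALSE)
  } else {
    proto <- do.call(protocol_constant_force, sim$protocol %||% list())
    out <- list()
    for (b in seq_len(n_beads)) {
      id <- sprintf("bead%03d", b)
      fs <- stats::runif(1, 0.95, 1.05)
      for (conc in c(0, concs)) {
        out[[length(out) + 1L]] <- simulate_constant_force_trace(
          model, proto, concentration = conc, bead_id = id,
          force_scale = fs)$trace
      }
    }
    out
  }
}

# --- figure-style summaries ---------------------------------------------------

#' Plot a normalized force distribution by condition
#'
#' Kernel-density overlay of normalized unfolding (or refolding) forces per
#' condition, the standard summary of a ramp experiment. Requires ggplot2.
#'
#' @param events Normalized event table from [normalize_forces()] or
#'   [analyze_ramp_cohort()].
#' @param direction `"unfold"` or `"refold"`.
#' @return A ggplot object.
#' @export
plot_force_distribution <- function(events, direction = "unfold") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- events[events$direction == direction, , drop = FALSE]
  d$condition <- paste(d$condition_ligand, signif(d$condition_conc_molar, 3))
  ggplot2::ggplot(d, ggplot2::aes(x = force_norm, colour = condition)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "normalized force", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a fitted dose-response curve
#'
#' Data points and the fitted saturation curve for any `smfs_dose_fit`.
#'
#' @param fit An `smfs_dose_fit`.
#' @param y Observed responses (same order as `fit$concentrations`).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(fit, y = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  x <- fit$concentrations
  xs <- exp(seq(log(max(min(x[x > 0]) / 10, 1e-12)), log(max(x) * 10),
                length.out = 200))
  curve_fun <- .titration_curves[[fit$model]]
  p <- fit$params
  if (fit$model == "termination") names(p) <- c("e_min", "e_max", "T_50")
  dd <- data.frame(x = xs, y = curve_fun(xs, p))
  g <- ggplot2::ggplot(dd, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (M)", y = "response") +
    ggplot2::theme_minimal()
  if (!is.null(y)) {
    g <- g + ggplot2::geom_point(
      data = data.frame(x = x, y = y),
      ggplot2::aes(x = x, y = y))
  }
  g
}

#' Plot dwell-time survival curves
#'
#' Empirical survival of dwell durations per state on a log-linear scale,
#' where a single-exponential population is a straight line.
#'
#' @param dwells [extract_dwells()] table.
#' @return A ggplot object.
#' @export
plot_dwell_survival <- function(dwells) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- dwells[!dwells$censored, , drop = FALSE]
  d <- d[order(d$state, d$duration), ]
  d$surv <- stats::ave(d$duration, d$state,
                       FUN = function(t) 1 - (seq_along(t) - 1) / length(t))
  ggplot2::ggplot(d, ggplot2::aes(x = duration, y = surv, colour = state)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dwell time (s)", y = "survival") +
    ggplot2::theme_minimal()
}
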