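#' Condition label for a measured molecule
#'
#' A condition pairs a ligand identity with a concentration and replicate
#' index. The control condition (buffer + DMSO carrier) carries concentration
#' zero by definition.
#'
#' @param ligand One of `"control"`, `"compound4"`, `"preq1"`, `"other"`.
#' @param concentration Ligand concentration in molar units (0 for control).
#' @param replicate Integer replicate index.
#' @return An object of class `smfs_condition`.
#' @export
condition_label <- function(ligand = c("control", "compound4", "preq1", "other"),
                            concentration = 0, replicate = 1L) {
  ligand <- match.arg(ligand)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0) {
    stop("'concentration' must be a single non-negative number (molar)")
  }
  if (ligand == "control" && concentration != 0) {
    stop("control condition implies concentration = 0")
  }
  structure(
    list(ligand = ligand, concentration = concentration,
         replicate = as.integer(replicate)),
    class = "smfs_condition"
  )
}

#' @export
format.smfs_condition <- function(x, ...) {
  if (x$ligand == "control") return("control")
  sprintf("%s @ %.3g M (rep %d)", x$ligand, x$concentration, x$replicate)
}

#' @export
print.smfs_condition <- function(x, ...) {
  cat("<condition>", format(x), "\n")
  invisible(x)
}

#' Single-bead force spectroscopy trace
#'
#' A trace is one bead's record of time, extension (bead Z-position) and
#' applied magnetic force, with its acquisition rate and condition metadata.
#' Extension is in nm, force in pN, time in seconds; the time base must be
#' uniform at `sample_rate`.
#'
#' @param time Numeric vector of sample times (s), strictly increasing and
#'   uniformly spaced.
#' @param extension Numeric vector of bead Z-positions (nm).
#' @param force Numeric vector of applied forces (pN), all non-negative.
#' @param bead_id Character scalar identifying the bead/molecule.
#' @param condition An [condition_label()] object.
#' @param sample_rate Acquisition rate in Hz.
#' @param cycle_id Optional integer vector assigning each sample to a ramp
#'   cycle (`NA` for samples outside any cycle).
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `smfs_trace`.
#' @export
mfs_trace <- function(time, extension, force, bead_id, condition,
                  sample_rate, cycle_id = NULL, validate = TRUE) {
  obj <- structure(
    list(time = as.numeric(time), extension = as.numeric(extension),
         force = as.numeric(force), bead_id = as.character(bead_id),
         condition = condition, sample_rate = as.numeric(sample_rate),
         cycle_id = if (is.null(cycle_id)) NULL else as.integer(cycle_id)),
    class = "smfs_trace"
  )
  if (validate) validate_trace(obj)
  obj
}

#' Validate a trace's invariants
#'
#' Checks array lengths, strict monotonicity and uniformity of the time base
#' (sample interval within 1% of 1/sample_rate), non-negative forces and a
#' positive sample rate. Errors identify the offending bead.
#'
#' @param x An `smfs_trace`.
#' @return `x`, invisibly, if valid.
#' @export
validate_trace <- function(x) {
  stopifnot(inherits(x, "smfs_trace"))
  id <- x$bead_id
  n <- length(x$time)
  if (length(x$extension) != n || length(x$force) != n) {
    stop(sprintf("bead %s: time/extension/force lengths differ", id))
  }
  if (!is.null(x$cycle_id) && length(x$cycle_id) != n) {
    stop(sprintf("bead %s: cycle_id length differs from time", id))
  }
  if (n < 2L) stop(sprintf("bead %s: trace has fewer than 2 samples", id))
  if (!is.numeric(x$sample_rate) || x$sample_rate <= 0) {
    stop(sprintf("bead %s: sample_rate must be > 0", id))
  }
  dt <- diff(x$time)
  if (any(dt <= 0)) {
    stop(sprintf("bead %s: time must be strictly increasing", id))
  }
  dt0 <- 1 / x$sample_rate
  if (any(abs(dt - dt0) > 0.01 * dt0)) {
    stop(sprintf("bead %s: sampling not uniform at %g Hz", id, x$sample_rate))
  }
  if (any(x$force < 0)) {
    stop(sprintf("bead %s: force must be >= 0 everywhere", id))
  }
  if (!inherits(x$condition, "smfs_condition")) {
    stop(sprintf("bead %s: condition must be a condition_label()", id))
  }
  invisible(x)
}

#' @export
print.smfs_trace <- function(x, ...) {
  cat(sprintf("<smfs_trace> bead %s, %s\n", x$bead_id, format(x$condition)))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), force %.2f-%.2f pN\n",
              length(x$time), x$sample_rate, diff(range(x$time)),
              min(x$force), max(x$force)))
  if (!is.null(x$cycle_id)) {
    cat(sprintf("  %d annotated ramp cycles\n",
                length(unique(stats::na.omit(x$cycle_id)))))
  }
  invisible(x)
}

#' Duration of a trace in seconds
#' @param x An `smfs_trace`.
#' @return Length of the record in seconds (n samples / sample_rate).
#' @export
trace_duration <- function(x) length(x$time) / x$sample_rate

.trace_csv_cols <- c("bead_id", "condition_ligand", "condition_conc_molar",
                     "cycle_id", "time_s", "extension_nm", "force_pn")

#' Read traces from file
#'
#' Reads the package's tabular trace format: one row per sample with columns
#' `bead_id, condition_ligand, condition_conc_molar, cycle_id, time_s,
#' extension_nm, force_pn` (UTF-8 CSV, '.' decimal separator). One trace is
#' returned per bead/condition pair; all trace invariants are validated and
#' violations are reported with the bead id. Units are fixed at ingest
#' (s, nm, pN, molar) by the column naming.
#'
#' @param path Path to the file.
#' @param format Only `"csv"` is supported.
#' @return A list of [mfs_trace()] objects.
#' @export
read_traces <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 trace files are not supported by this build; use format = 'csv'")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trace_csv_cols, names(df))
  if (length(missing)) {
    stop("trace file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  key <- paste(df$bead_id, df$condition_ligand, df$condition_conc_molar,
               sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    dt <- stats::median(diff(sub$time_s))
    cond <- condition_label(sub$condition_ligand[1L],
                            sub$condition_conc_molar[1L])
    mfs_trace(time = sub$time_s, extension = sub$extension_nm,
          force = sub$force_pn, bead_id = sub$bead_id[1L],
          condition = cond, sample_rate = 1 / dt,
          cycle_id = sub$cycle_id)
  })
  names(out) <- NULL
  out[order(vapply(out, function(tr) tr$bead_id, ""))]
}

#' Write traces to file
#'
#' Inverse of [read_traces()]: serializes a collection of traces to the
#' package CSV dialect. Round-tripping preserves all arrays to better than
#' 1e-9 nm and the condition metadata exactly.
#'
#' @param traces Non-empty list of [mfs_trace()] objects.
#' @param path Output path.
#' @param format Only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 trace files are not supported by this build; use format = 'csv'")
  }
  if (inherits(traces, "smfs_trace")) traces <- list(traces)
  if (!length(traces)) stop("'traces' must be a non-empty list of traces")
  rows <- lapply(traces, function(tr) {
    validate_trace(tr)
    data.frame(
      bead_id = tr$bead_id,
      condition_ligand = tr$condition$ligand,
      condition_conc_molar = tr$condition$concentration,
      cycle_id = if (is.null(tr$cycle_id)) NA_integer_ else tr$cycle_id,
      time_s = tr$time, extension_nm = tr$extension, force_pn = tr$force
    )
  })
  df <- do.call(rbind, rows)
  # full precision so the round-trip is an identity to < 1e-9
  df$time_s <- formatC(df$time_s, format = "g", digits = 17)
  df$extension_nm <- formatC(df$extension_nm, format = "g", digits = 17)
  df$force_pn <- formatC(df$force_pn, format = "g", digits = 17)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write traces to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
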