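#' Construct an ingestion log for one patient
#'
#' An ingestion log is the raw record produced by a digital medicine system for
#' a single patient: a dosing schedule (interval `tau`, anchored at the first
#' scheduled dose) and the timestamps at which the system registered an
#' ingestion ("observed ingestions").
#'
#' @param patient_id Opaque patient identifier (coerced to character).
#' @param times Observed ingestion timestamps: `POSIXct`, or strings parseable
#'   as ISO-8601 (`"2023-01-01 12:00:00"` / `"2023-01-01T12:00:00"`). Must be
#'   nondecreasing.
#' @param tau Dosing interval in hours; once-daily dosing is `tau = 24`.
#' @param anchor Timestamp of the first scheduled dose. Defaults to the first
#'   observed ingestion.
#' @param covariates Optional named list of patient covariates (diagnosis,
#'   disease duration, dose, ...).
#' @return An object of class `"ingestion_log"`.
#' @seealso [derive_sequence()], [read_ingestion_logs()]
#' @export
ingestion_log <- function(patient_id, times, tau = 24, anchor = NULL,
                          covariates = NULL) {
  times <- parse_timestamps(times)
  if (anyNA(times)) stopf("unparseable timestamp in log for patient %s", patient_id)
  if (is.unsorted(as.numeric(times))) {
    stopf("observed_times must be nondecreasing (patient %s)", patient_id)
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stopf("tau must be a single positive number of hours (patient %s)", patient_id)
  }
  anchor <- if (is.null(anchor)) times[1L] else parse_timestamps(anchor)
  if (anyNA(anchor)) stopf("unparseable anchor for patient %s", patient_id)
  if (length(times) &&
      as.numeric(difftime(times[1L], anchor, units = "hours")) < -tau / 2) {
    stopf("timestamps precede schedule_anchor - tau/2 (patient %s)", patient_id)
  }
  structure(
    list(patient_id = as.character(patient_id), times = times, tau = tau,
         anchor = anchor, covariates = covariates),
    class = "ingestion_log")
}

#' @export
print.ingestion_log <- function(x, ...) {
  cat(sprintf("<ingestion_log> patient %s: %d observed ingestion(s), tau = %g h\n",
              x$patient_id, length(x$times), x$tau))
  invisible(x)
}

parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- rep(as.POSIXct(NA), length(x))
  for (f in fmts) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = f)
  }
  out
}

#' Read per-patient ingestion logs from CSV
#'
#' Expects a header `patient_id,timestamp` with optional `tau_hours` and
#' `anchor` columns (constant within patient). Timestamps are ISO-8601.
#' An optional covariates CSV (keyed by `patient_id`) is attached to each log.
#'
#' @param path Path to the ingestion-event CSV.
#' @param covariates_path Optional path to a covariates CSV.
#' @param tau Default dosing interval in hours for patients without a
#'   `tau_hours` column.
#' @param skip_bad If `TRUE`, rows with unparseable timestamps are dropped with
#'   a warning listing their line numbers; if `FALSE` (default) any bad row
#'   aborts the read.
#' @return Named list of [ingestion_log()] objects, one per patient.
#' @export
read_ingestion_logs <- function(path, covariates_path = NULL, tau = 24,
                                skip_bad = FALSE) {
  if (!file.exists(path)) stopf("input file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "timestamp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stopf("format error: missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warnf("empty ingestion-log file: %s", path)
    return(structure(list(), names = character()))
  }
  parsed <- parse_timestamps(df$timestamp)
  bad <- which(is.na(parsed))
  if (length(bad)) {
    # +1 for the header line so reported numbers match the file on disk
    msg <- sprintf("unparseable timestamp(s) at line(s): %s",
                   paste(bad + 1L, collapse = ", "))
    if (!skip_bad) stopf("%s", msg)
    warnf("%s (rows dropped)", msg)
    df <- df[-bad, , drop = FALSE]
    parsed <- parsed[-bad]
  }
  covs <- NULL
  if (!is.null(covariates_path)) {
    covs <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
    if (!"patient_id" %in% names(covs)) {
      stopf("format error: covariates file lacks patient_id column")
    }
  }
  ids <- unique(as.character(df$patient_id))
  logs <- lapply(ids, function(id) {
    rows <- which(as.character(df$patient_id) == id)
    tms <- sort(parsed[rows])
    tau_i <- if ("tau_hours" %in% names(df)) df$tau_hours[rows[1L]] else tau
    anc <- if ("anchor" %in% names(df)) df$anchor[rows[1L]] else NULL
    cv <- NULL
    if (!is.null(covs)) {
      hit <- which(as.character(covs$patient_id) == id)
      if (length(hit)) cv <- as.list(covs[hit[1L], setdiff(names(covs), "patient_id")])
    }
    ingestion_log(id, tms, tau = tau_i, anchor = anc, covariates = cv)
  })
  names(logs) <- ids
  logs
}

new_dose_seq <- function(patient_id, events, deviations, excess, tau,
                         first_slot = 0L) {
  stopifnot(all(events %in% c("S", "F")))
  n_total <- length(events)
  ns <- sum(events == "S")
  if (events[1L] != "S" || events[n_total] != "S") {
    stopf("dose-event sequence must start and end with S (patient %s)", patient_id)
  }
  if (length(deviations) != ns) {
    stopf("one timing deviation per S event required (patient %s)", patient_id)
  }
  if (any(abs(deviations) > tau / 2 + 1e-9)) {
    stopf("|delta| exceeds tau/2 (patient %s)", patient_id)
  }
  if (length(excess) != ns || any(excess < 0)) {
    stopf("excess_daily_counts must be one nonnegative count per S day (patient %s)",
          patient_id)
  }
  structure(
    list(patient_id = as.character(patient_id), events = events,
         deviations = as.numeric(deviations), excess_daily_counts = as.integer(excess),
         n_total = n_total, oip = ns / n_total, tau = tau,
         first_slot = as.integer(first_slot)),
    class = "dose_seq")
}

#' @export
print.dose_seq <- function(x, ...) {
  cat(sprintf("<dose_seq> patient %s: %s\n", x$patient_id,
              paste(x$events, collapse = "")))
  cat(sprintf("  n_total = %d, OIP = %.3f, excess events = %d\n",
              x$n_total, x$oip, sum(x$excess_daily_counts)))
  invisible(x)
}

#' Derive the dose-event sequence from an ingestion log
#'
#' Maps each observed ingestion to its nearest scheduled opportunity and builds
#' the binary success/failure sequence spanning the observed ingestion duration
#' (first to last observed ingestion, inclusive). The first ingestion of each
#' calendar day fills its opportunity slot (`S`); additional same-day ingestions
#' are excess dosing events and do not enter the Markov sequence. Opportunities
#' with no assigned ingestion are failures (`F`). Timing deviations
#' `delta = actual - nearest expected time` (hours) are recorded for each
#' slot-filling ingestion; ties at exactly `tau/2` break toward the earlier
#' opportunity.
#'
#' Patients with fewer than two observed ingestions cannot anchor an observed
#' ingestion duration and are rejected with an exclusion error (condition class
#' `"dosechain_exclusion"`).
#'
#' @param log An [ingestion_log()].
#' @return An object of class `"dose_seq"` with fields `events` (`"S"`/`"F"`),
#'   `deviations` (hours, one per `S`), `excess_daily_counts` (one per `S` day),
#'   `n_total`, `oip`, `tau`.
#' @export
derive_sequence <- function(log) {
  stopifnot(inherits(log, "ingestion_log"))
  if (length(log$times) < 2L) {
    cond <- structure(
      class = c("dosechain_exclusion", "error", "condition"),
      list(message = sprintf(
        "patient %s excluded: fewer than 2 observed ingestions (took only %d dose)",
        log$patient_id, length(log$times)), call = NULL))
    stop(cond)
  }
  h <- as.numeric(difftime(log$times, log$anchor, units = "hours"))
  day <- as.Date(log$times, tz = "UTC")
  first_of_day <- !duplicated(day)
  # nearest opportunity; tie at exactly tau/2 breaks toward the earlier slot
  slot_of <- function(hh) as.integer(ceiling(hh / log$tau - 0.5))
  filled <- integer(0)      # absolute slot index -> filled
  dev_by_slot <- numeric(0) # parallel deviations
  excess_by_slot <- integer(0)
  cur_j <- 0L # index into `filled` of the slot owning the current calendar day
  for (i in seq_along(h)) {
    if (first_of_day[i]) {
      k <- slot_of(h[i])
      if (k %in% filled) {
        # defensive: two calendar days mapping to one slot; later one is excess
        cur_j <- match(k, filled)
        excess_by_slot[cur_j] <- excess_by_slot[cur_j] + 1L
      } else {
        filled <- c(filled, k)
        dev_by_slot <- c(dev_by_slot, h[i] - k * log$tau)
        excess_by_slot <- c(excess_by_slot, 0L)
        cur_j <- length(filled)
      }
    } else {
      # same-day repeat: excess dosing event on the day whose slot it follows
      excess_by_slot[cur_j] <- excess_by_slot[cur_j] + 1L
    }
  }
  ord <- order(filled)
  filled <- filled[ord]; dev_by_slot <- dev_by_slot[ord]
  excess_by_slot <- excess_by_slot[ord]
  if (length(filled) < 2L) {
    cond <- structure(
      class = c("dosechain_exclusion", "error", "condition"),
      list(message = sprintf(
        "patient %s excluded: fewer than 2 distinct dosing opportunities observed",
        log$patient_id), call = NULL))
    stop(cond)
  }
  span <- filled[1L]:filled[length(filled)]
  events <- ifelse(span %in% filled, "S", "F")
  new_dose_seq(log$patient_id, events, dev_by_slot, excess_by_slot, log$tau,
               first_slot = filled[1L])
}

#' Observed ingestion percent of a dose-event sequence
#'
#' The fraction of scheduled dosing opportunities within the observed ingestion
#' duration at which an ingestion was observed. Multiply by 100 to report as a
#' percent.
#'
#' @param seq A `"dose_seq"` object.
#' @return Fraction in (0, 1].
#' @export
compute_oip <- function(seq) {
  stopifnot(inherits(seq, "dose_seq"))
  sum(seq$events == "S") / seq$n_total
}

#' Convert timing deviations to angles
#'
#' Maps a timing deviation `delta` (hours) to the angle
#' `theta = 2 * pi * delta / tau`, the angular position of the ingestion within
#' its dosing interval. With `|delta| <= tau/2`, `theta` lies in `[-pi, pi]`.
#'
#' @param deviations Numeric vector of deviations in hours.
#' @param tau Dosing interval in hours.
#' @return Numeric vector of angles in radians.
#' @export
timing_deviations_to_angles <- function(deviations, tau) {
  if (any(abs(deviations) > tau / 2 + 1e-9)) {
    stopf("invariant violation: |delta| > tau/2")
  }
  2 * pi * deviations / tau
}

#' Write derived dose-event sequences to CSV
#'
#' One row per dosing opportunity:
#' `patient_id,day_index,event,delta_hours,excess_count`.
#'
#' @param seqs List of `"dose_seq"` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  rows <- lapply(seqs, function(s) {
    is_s <- s$events == "S"
    delta <- rep(NA_real_, s$n_total); delta[is_s] <- s$deviations
    exc <- rep(NA_integer_, s$n_total); exc[is_s] <- s$excess_daily_counts
    data.frame(patient_id = s$patient_id, day_index = seq_len(s$n_total),
               event = s$events, delta_hours = delta, excess_count = exc,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read derived dose-event sequences from CSV
#'
#' Inverse of [write_sequences()].
#'
#' @param path CSV path written by [write_sequences()].
#' @param tau Dosing interval in hours.
#' @return Named list of `"dose_seq"` objects.
#' @export
read_sequences <- function(path, tau = 24) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(as.character(df$patient_id))
  out <- lapply(ids, function(id) {
    d <- df[as.character(df$patient_id) == id, , drop = FALSE]
    d <- d[order(d$day_index), , drop = FALSE]
    is_s <- d$event == "S"
    new_dose_seq(id, d$event, d$delta_hours[is_s],
                 ifelse(is.na(d$excess_count[is_s]), 0L, d$excess_count[is_s]),
                 tau)
  })
  names(out) <- ids
  out
}
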