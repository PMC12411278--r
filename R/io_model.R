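## Canonical data model for trial-structured DNMS recordings.
##
## Time convention: milliseconds from trial start (t = 0 at recording
## onset), all windows half-open [a, b).  Recordings start 1 s before the
## first odor, so odor1_onset is 1000 ms by convention; odors last 1 s and
## are separated by a 5 s delay.  Traces are sampled at 1 kHz, so sample
## i (1-based) covers [i-1, i) ms and spike times are frame-aligned
## integers.

#' Construct one DNMS trial
#'
#' @param dff Fluorescence-ratio trace (unitless), one sample per ms.
#' @param spike_times Strictly increasing spike times (ms from trial start).
#' @param locomotion Locomotion signal (a.u.), same length as \code{dff}.
#' @param odor1_id,odor2_id Odor identities, \code{"A"} or \code{"B"}.
#' @param odor1_onset,odor1_offset,odor2_onset,odor2_offset Event times (ms).
#' @param response_window_end End of the response window (ms) = trial length.
#' @param licks Optional lick times (ms).
#' @param stim_window Optional \code{c(onset, offset)} ms for optogenetic
#'   trials.
#' @return A \code{trial_record} object.
#' @export
trial_record <- function(dff, spike_times, locomotion,
                         odor1_id, odor2_id,
                         odor1_onset = 1000, odor1_offset = 2000,
                         odor2_onset = 7000, odor2_offset = 8000,
                         response_window_end = length(dff),
                         licks = NULL, stim_window = NULL) {
  tr <- structure(
    list(dff = as.numeric(dff),
         spike_times = as.numeric(spike_times),
         locomotion = as.numeric(locomotion),
         odor1_id = as.character(odor1_id), odor2_id = as.character(odor2_id),
         odor1_onset = odor1_onset, odor1_offset = odor1_offset,
         odor2_onset = odor2_onset, odor2_offset = odor2_offset,
         response_window_end = response_window_end,
         licks = if (is.null(licks)) NULL else as.numeric(licks),
         stim_window = stim_window),
    class = "trial_record")
  tr
}

validate_trial <- function(tr, where = "trial") {
  err <- function(field, msg)
    stop(sprintf("validation error in %s, field '%s': %s", where, field, msg),
         call. = FALSE)
  if (!length(tr$dff)) err("dff", "empty trace")
  if (length(tr$dff) != length(tr$locomotion))
    err("locomotion", "dff and locomotion lengths differ")
  st <- tr$spike_times
  if (length(st)) {
    if (any(diff(st) <= 0)) err("spike_times", "not strictly increasing")
    if (any(st < 0) || any(st >= length(tr$dff)))
      err("spike_times", "outside [0, trial length)")
  }
  if (!tr$odor1_id %in% c("A", "B")) err("odor1_id", "must be 'A' or 'B'")
  if (!tr$odor2_id %in% c("A", "B")) err("odor2_id", "must be 'A' or 'B'")
  if (tr$odor1_onset != 1000)
    err("odor1_onset", "must be 1000 ms (recording starts 1 s pre-odor)")
  if (tr$odor1_offset - tr$odor1_onset != 1000 ||
      tr$odor2_offset - tr$odor2_onset != 1000)
    err("odor durations", "odor cues must last 1000 ms")
  if (tr$odor2_onset - tr$odor1_offset != 5000)
    err("delay", "odor2_onset - odor1_offset must be 5000 ms")
  invisible(tr)
}

#' Construct a cell-session (one cell, one day)
#'
#' @param trials List of [trial_record()] objects, in chronological order.
#' @param cell_id,mouse_id Identifiers.
#' @param cell_class One of \code{"PV"}, \code{"SST"}, \code{"PYR"},
#'   \code{"UNIT"}.
#' @param training_state \code{"naive"} or \code{"trained"}.
#' @param session_index Non-negative day ordinal.
#' @param sample_rate Sampling rate in Hz (1000 for voltage imaging).
#' @return A \code{cell_session} object (validated).
#' @export
cell_session <- function(trials, cell_id, mouse_id = "m0",
                         cell_class = c("PV", "SST", "PYR", "UNIT"),
                         training_state = c("trained", "naive"),
                         session_index = 0L, sample_rate = 1000) {
  cell_class <- match.arg(cell_class)
  training_state <- match.arg(training_state)
  s <- structure(
    list(cell_id = as.character(cell_id), mouse_id = as.character(mouse_id),
         cell_class = cell_class, training_state = training_state,
         session_index = as.integer(session_index),
         sample_rate = sample_rate, trials = trials),
    class = "cell_session")
  validate_session(s)
}

#' Validate a cell_session against the data-model invariants
#'
#' @param s A \code{cell_session}.
#' @return \code{s}, invisibly, or an error naming the offending trial and
#'   field.
#' @export
validate_session <- function(s) {
  if (!inherits(s, "cell_session")) stop("not a cell_session")
  if (!length(s$trials)) stop("validation error: session has 0 trials")
  if (s$session_index < 0) stop("validation error: negative session_index")
  for (i in seq_along(s$trials))
    validate_trial(s$trials[[i]], where = sprintf("trial %d", i))
  invisible(s)
}

#' @export
print.cell_session <- function(x, ...) {
  cat(sprintf("<cell_session> %s (%s, %s) day %d: %d trials, %d spikes\n",
              x$cell_id, x$cell_class, x$training_state, x$session_index,
              length(x$trials),
              sum(vapply(x$trials, function(t) length(t$spike_times), 0))))
  invisible(x)
}

#' Analysis axis over (part of) a trial
#'
#' The default axis spans the odor-delay interval: first-odor onset through
#' the end of the delay (6 s), in 100-ms half-open bins.
#'
#' @param start_ms,end_ms Interval bounds (ms from trial start).
#' @param bin_ms Bin width in ms; must divide the interval length.
#' @return An \code{odor_delay_axis} object with \code{n_bins} and bin edges.
#' @export
odor_delay_axis <- function(start_ms = 1000, end_ms = 7000, bin_ms = 100) {
  len <- end_ms - start_ms
  if (len <= 0 || len %% bin_ms != 0)
    stop("axis length must be a positive multiple of bin_ms")
  structure(list(start_ms = start_ms, end_ms = end_ms, bin_ms = bin_ms,
                 n_bins = as.integer(len / bin_ms),
                 edges = seq(start_ms, end_ms, by = bin_ms)),
            class = "odor_delay_axis")
}

## ---- persistence -----------------------------------------------------------
## JSON layout mirroring a /meta + /trials/<k> group tree.  Numeric payloads
## are serialised at full precision so save/load round-trips are lossless
## to the double's printed representation.

#' Save a cell_session to disk
#'
#' Writes a structured JSON file (\code{meta} block plus one object per
#' trial).  Optional fields are encoded by absence.  Output is
#' deterministic: saving the same session twice yields byte-identical files.
#'
#' @param session A validated \code{cell_session}.
#' @param path Output file path.
#' @export
save_session <- function(session, path) {
  validate_session(session)
  trials <- lapply(session$trials, function(tr) {
    o <- list(dff = tr$dff, locomotion = tr$locomotion,
              spike_times = tr$spike_times,
              odor1_id = tr$odor1_id, odor2_id = tr$odor2_id,
              odor1_onset = tr$odor1_onset, odor1_offset = tr$odor1_offset,
              odor2_onset = tr$odor2_onset, odor2_offset = tr$odor2_offset,
              response_window_end = tr$response_window_end)
    if (!is.null(tr$licks)) o$licks <- tr$licks
    if (!is.null(tr$stim_window)) o$stim_window <- tr$stim_window
    o
  })
  obj <- list(meta = list(cell_id = session$cell_id,
                          mouse_id = session$mouse_id,
                          cell_class = session$cell_class,
                          training_state = session$training_state,
                          session_index = session$session_index,
                          sample_rate = session$sample_rate),
              trials = trials)
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a cell_session from disk
#'
#' @param path File written by [save_session()].
#' @return A validated \code{cell_session}; malformed files raise a
#'   structured format error, invariant violations a validation error.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                  error = function(e) stop("format error: not a session file (",
                                           conditionMessage(e), ")", call. = FALSE))
  for (grp in c("meta", "trials"))
    if (is.null(obj[[grp]])) stop("format error: missing group '", grp, "'")
  m <- obj$meta
  for (ds in c("cell_id", "cell_class", "training_state", "session_index",
               "sample_rate"))
    if (is.null(m[[ds]])) stop("format error: missing meta dataset '", ds, "'")
  trials <- lapply(obj$trials, function(o) {
    for (ds in c("dff", "locomotion", "spike_times", "odor1_id"))
      if (is.null(o[[ds]])) stop("format error: missing trial dataset '", ds, "'")
    trial_record(dff = unlist(o$dff), spike_times = unlist(o$spike_times),
                 locomotion = unlist(o$locomotion),
                 odor1_id = o$odor1_id, odor2_id = o$odor2_id,
                 odor1_onset = o$odor1_onset, odor1_offset = o$odor1_offset,
                 odor2_onset = o$odor2_onset, odor2_offset = o$odor2_offset,
                 response_window_end = o$response_window_end,
                 licks = if (is.null(o$licks)) NULL else unlist(o$licks),
                 stim_window = if (is.null(o$stim_window)) NULL else
                   unlist(o$stim_window))
  })
  cell_session(trials, cell_id = m$cell_id, mouse_id = m$mouse_id,
               cell_class = m$cell_class, training_state = m$training_state,
               session_index = m$session_index, sample_rate = m$sample_rate)
}

#' Concatenate partial recordings of the same cell-session
#'
#' Sets of trials recorded back-to-back from one cell on one day are
#' treated as a single continuous recording.
#'
#' @param parts List of \code{cell_session} objects sharing
#'   \code{cell_id}, \code{session_index} and \code{sample_rate}.
#' @return One \code{cell_session} with all trials in order.
#' @export
concatenate_recordings <- function(parts) {
  stopifnot(length(parts) >= 1)
  ref <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(p$cell_id, ref$cell_id) ||
        !identical(p$session_index, ref$session_index) ||
        !identical(p$sample_rate, ref$sample_rate))
      stop("cannot concatenate: mismatched cell_id/session_index/sample_rate")
  }
  out <- ref
  out$trials <- do.call(c, lapply(parts, `[[`, "trials"))
  validate_session(out)
}
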