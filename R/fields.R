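## Temporal firing-field detection over the odor-delay interval with a
## per-trial circular-shift permutation null, field classification and
## odor selectivity.

circular_shift_row <- function(r, s) {
  n <- length(r)
  r[((seq_len(n) - 1 - s) %% n) + 1]
}

## max-of-mean statistic under per-trial independent circular shifts
shuffle_null_max <- function(rates, n_shuffles, max_shift) {
  n_bins <- ncol(rates)
  n_tr <- nrow(rates)
  shifts <- matrix(sample(seq(-max_shift, max_shift),
                          n_tr * n_shuffles, replace = TRUE),
                   nrow = n_tr)
  acc <- matrix(0, nrow = n_shuffles, ncol = n_bins)
  cols <- matrix(seq_len(n_bins), nrow = n_shuffles, ncol = n_bins,
                 byrow = TRUE)
  for (i in seq_len(n_tr)) {
    idx <- ((cols - 1 - shifts[i, ]) %% n_bins) + 1
    acc <- acc + matrix(rates[i, ][idx], nrow = n_shuffles)
  }
  apply(acc / n_tr, 1, max)
}

#' Detect a temporal firing field
#'
#' Rates are binned (100 ms default), smoothed, z-scored per trial over
#' the odor-delay axis and split by first-odor identity.  The observed
#' statistic per odor is the maximum over bins of the trial-mean rate; the
#' null shifts each trial's rate vector circularly by an independent
#' random number of bins up to +-(axis/2), 1000 times.  A field is
#' significant iff the observed maximum exceeds the null's 95th
#' percentile (strictly).  Cells significant for both odors are
#' non-odor-specific; their final bin is the mean of the two per-odor bins
#' when those are closer than 1 s, else the bin with the larger maximum.
#' Initially odor-specific cells with |SI| < 0.42 are reclassified as
#' non-odor-specific.  No-field cells get the argmax bin of the all-trial
#' mean.
#'
#' @param session A \code{cell_session} with >= 2 trials per odor.
#' @param axis Analysis axis ([odor_delay_axis()]).
#' @param n_shuffles,percentile Null size and significance percentile.
#' @param seed Optional RNG seed for the shuffles.
#' @param smooth Rate-conditioning front end: \code{"ma5"} (five-point
#'   moving average; voltage imaging), \code{"gauss300"} (300-ms Gaussian
#'   window; extracellular) or \code{"none"} (pre-conditioned signals,
#'   e.g. deconvolved calcium).
#' @param si_threshold Odor-specificity cutoff on |SI|.
#' @return A \code{field_result}: \code{per_odor} (significant, field_bin,
#'   max_mean_rate, null 95th percentile per odor), \code{category},
#'   \code{final_field_bin}, \code{field_kind} ("odor"/"delay"),
#'   \code{SI}, and the per-odor field-bin rates \code{R_fA}, \code{R_fB}.
#' @export
detect_fields <- function(session, axis = odor_delay_axis(),
                          n_shuffles = 1000, percentile = 95, seed = NULL,
                          smooth = c("ma5", "gauss300", "none"),
                          si_threshold = 0.42) {
  smooth <- match.arg(smooth)
  if (!is.null(seed)) set.seed(seed)
  sp <- switch(smooth, ma5 = 5, gauss300 = 0, none = 0)
  rm_raw <- bin_rates(session, axis, smooth_points = 0, zscore = FALSE)
  raw <- rm_raw$rates
  cond <- raw
  if (smooth == "ma5") cond <- t(apply(raw, 1, moving_average, n = 5))
  if (smooth == "gauss300")
    cond <- t(apply(raw, 1, gaussian_smooth,
                    window = max(3, round(300 / axis$bin_ms))))
  z <- t(apply(cond, 1, function(r) {
    s <- stats::sd(r)
    if (s > 0) (r - mean(r)) / s else r - mean(r)
  }))
  odor <- rm_raw$odor1
  if (sum(odor == "A") < 2 || sum(odor == "B") < 2)
    stop("need >= 2 trials per odor")
  if (all(raw == 0)) {
    warning("degenerate all-zero rates: no-field")
    return(structure(list(per_odor = NULL, category = "no-field",
                          final_field_bin = 1L, field_kind = "odor",
                          SI = NA_real_, R_fA = 0, R_fB = 0),
                     class = "field_result"))
  }
  max_shift <- floor(axis$n_bins / 2)
  per_odor <- list()
  for (o in c("A", "B")) {
    zi <- z[odor == o, , drop = FALSE]
    m <- colMeans(zi)
    obs <- max(m)
    bin <- which.max(m) # earliest on ties
    null <- shuffle_null_max(zi, n_shuffles, max_shift)
    thr <- stats::quantile(null, percentile / 100, names = FALSE)
    per_odor[[o]] <- list(significant = obs > thr, field_bin = bin,
                          max_mean_rate = obs, null_percentile = thr)
  }
  sA <- per_odor$A$significant; sB <- per_odor$B$significant
  bA <- per_odor$A$field_bin; bB <- per_odor$B$field_bin
  if (sA && sB) {
    category <- "non-odor-specific"
    if (abs(bA - bB) * axis$bin_ms < 1000) {
      final_bin <- as.integer(round(mean(c(bA, bB))))
    } else {
      final_bin <- if (per_odor$A$max_mean_rate >= per_odor$B$max_mean_rate)
        bA else bB
    }
  } else if (sA || sB) {
    category <- if (sA) "odorA-specific" else "odorB-specific"
    final_bin <- if (sA) bA else bB
  } else {
    category <- "no-field"
    final_bin <- which.max(colMeans(z))
  }
  ## SI from raw-scale (Hz) conditioned rates at the final field bin
  rate_at <- function(o) mean(cond[odor == o, final_bin])
  R_fA <- rate_at("A"); R_fB <- rate_at("B")
  SI <- selectivity_index(R_fA, R_fB)
  if (category %in% c("odorA-specific", "odorB-specific") &&
      (is.na(SI) || abs(SI) < si_threshold))
    category <- "non-odor-specific"
  kind <- odor_or_delay(final_bin, axis, session$trials[[1]])
  structure(list(per_odor = per_odor, category = category,
                 final_field_bin = as.integer(final_bin), field_kind = kind,
                 SI = SI, R_fA = R_fA, R_fB = R_fB, axis = axis),
            class = "field_result")
}

odor_or_delay <- function(bin, axis, trial) {
  t0 <- axis$start_ms + (bin - 1) * axis$bin_ms
  if (t0 >= trial$odor1_onset && t0 < trial$odor1_offset) "odor" else "delay"
}

#' @export
print.field_result <- function(x, ...) {
  cat(sprintf("<field_result> %s; bin %d (%s); SI = %.3f\n",
              x$category, x$final_field_bin, x$field_kind, x$SI))
  invisible(x)
}

#' Selectivity index
#'
#' SI = (R_A - R_B) / (R_A + R_B) from the field-bin mean rates of the two
#' odors; in [-1, 1], positive for odor-A preference.
#'
#' @param R_fA,R_fB Non-negative mean rates at the field bin.
#' @return SI, or \code{NA} when both rates are zero.
#' @export
selectivity_index <- function(R_fA, R_fB) {
  if (R_fA < 0 || R_fB < 0) stop("rates must be non-negative")
  if (R_fA + R_fB == 0) return(NA_real_)
  (R_fA - R_fB) / (R_fA + R_fB)
}

#' Chance selectivity distribution
#'
#' SI recomputed between two random trial splits (equal size on average,
#' each side non-empty), repeated \code{n_rep} times, at the cell's field
#' bin.
#'
#' @param session A \code{cell_session}.
#' @param field A \code{field_result} (for the field bin and conditioning).
#' @param axis Analysis axis.
#' @param n_rep Number of random splits.
#' @param seed Optional seed.
#' @return Numeric vector of chance SI values (NA splits dropped).
#' @export
chance_selectivity <- function(session, field, axis = odor_delay_axis(),
                               n_rep = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rm_raw <- bin_rates(session, axis, smooth_points = 5)
  r_bin <- rm_raw$rates[, field$final_field_bin]
  ntr <- length(r_bin)
  out <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    repeat {
      g <- stats::runif(ntr) < 0.5
      if (any(g) && any(!g)) break
    }
    out[k] <- selectivity_index(mean(r_bin[g]), mean(r_bin[!g]))
  }
  out[!is.na(out)]
}

#' Per-segment firing-rate changes
#'
#' Trial-averaged relative change of the mean rate in each trial segment
#' (first odor, delay, second odor, response window) versus the 0.8 s
#' pre-odor baseline.
#'
#' @param session A \code{cell_session}.
#' @return Named vector of relative changes; trials with a zero baseline
#'   rate are excluded with a warning.
#' @export
rate_change_segments <- function(session) {
  segs <- function(tr) rbind(
    baseline = c(tr$odor1_onset - 800, tr$odor1_onset),
    first_odor = c(tr$odor1_onset, tr$odor1_offset),
    delay = c(tr$odor1_offset, tr$odor2_onset),
    second_odor = c(tr$odor2_onset, tr$odor2_offset),
    response = c(tr$odor2_offset, tr$response_window_end))
  per_trial <- lapply(session$trials, function(tr) {
    s <- segs(tr)
    rates <- apply(s, 1, function(w)
      sum(tr$spike_times >= w[1] & tr$spike_times < w[2]) /
        ((w[2] - w[1]) / 1000))
    if (rates["baseline"] == 0) return(NULL)
    (rates[-1] - rates["baseline"]) / rates["baseline"]
  })
  ok <- !vapply(per_trial, is.null, TRUE)
  if (any(!ok)) warning(sum(!ok), " trial(s) with zero baseline rate excluded")
  if (!any(ok)) stop("all trials have zero baseline rate")
  colMeans(do.call(rbind, per_trial[ok]))
}
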