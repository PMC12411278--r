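## Cross-session stability: odor-field turnover and trial-pair rate
## correlations across days.

#' Field turnover rates across tracked sessions
#'
#' For every consecutive session pair (d-1, d) over cells imaged on both
#' days: stable = % of day-d odor-field cells that already had a field on
#' d-1; inflow = % of day-d field cells that had none on d-1 (stable +
#' inflow = 100); outflow = % of day-(d-1) field cells that lost their
#' field on d.  Cells tracked for more than two sessions contribute each
#' consecutive pair independently.
#'
#' @param field_table data.frame with columns \code{cell_id},
#'   \code{session_index}, \code{has_odor_field} (logical).  Delay-field
#'   to odor-field transitions count as inflow (fields are classified
#'   upstream).
#' @return A \code{turnover_result} data.frame, one row per session pair,
#'   with percentages and their denominators; pairs with no tracked cells
#'   are skipped with a warning.
#' @export
turnover_rates <- function(field_table) {
  stopifnot(all(c("cell_id", "session_index", "has_odor_field") %in%
                  names(field_table)))
  sessions <- sort(unique(field_table$session_index))
  if (length(sessions) < 2) stop("need >= 2 sessions")
  rows <- list()
  for (d in sessions[-1]) {
    prev <- field_table[field_table$session_index == d - 1, ]
    curr <- field_table[field_table$session_index == d, ]
    tracked <- intersect(prev$cell_id, curr$cell_id)
    if (!length(tracked)) {
      warning("no tracked cells for session pair ", d - 1, "-", d)
      next
    }
    fp <- prev$has_odor_field[match(tracked, prev$cell_id)]
    fc <- curr$has_odor_field[match(tracked, curr$cell_id)]
    n_curr_field <- sum(fc)
    n_prev_field <- sum(fp)
    rows[[length(rows) + 1]] <- data.frame(
      prev_session = d - 1, session = d,
      stable_pct = if (n_curr_field) 100 * sum(fc & fp) / n_curr_field else NA,
      inflow_pct = if (n_curr_field) 100 * sum(fc & !fp) / n_curr_field else NA,
      outflow_pct = if (n_prev_field) 100 * sum(fp & !fc) / n_prev_field else NA,
      n_field_curr = n_curr_field, n_field_prev = n_prev_field,
      n_tracked = length(tracked))
  }
  if (!length(rows)) stop("no session pair with tracked cells")
  out <- do.call(rbind, rows)
  class(out) <- c("turnover_result", class(out))
  out
}

#' Cross-session firing-rate correlation
#'
#' Firing rates over the odor-delay interval are z-scored per trial;
#' Pearson correlation is computed for all pairs of trials between the two
#' sessions and averaged.
#'
#' @param sessA,sessB \code{cell_session} objects for the same cell.
#' @param axis Analysis axis.
#' @param smooth_points Rate smoothing before z-scoring (5-point default).
#' @return A list: \code{mean_r}, \code{n_pairs}, \code{session_distance}
#'   (days), \code{label} (\code{"trained-trained"} or \code{"pre-post"}).
#' @export
cross_session_correlation <- function(sessA, sessB, axis = odor_delay_axis(),
                                      smooth_points = 5) {
  if (!identical(sessA$cell_id, sessB$cell_id))
    stop("sessions are from different cells")
  za <- bin_rates(sessA, axis, smooth_points, zscore = TRUE)$rates
  zb <- bin_rates(sessB, axis, smooth_points, zscore = TRUE)$rates
  ok_a <- apply(za, 1, stats::sd) > 0
  ok_b <- apply(zb, 1, stats::sd) > 0
  if (!any(ok_a) || !any(ok_b)) stop("no non-constant trials to correlate")
  cc <- stats::cor(t(za[ok_a, , drop = FALSE]), t(zb[ok_b, , drop = FALSE]))
  list(mean_r = mean(cc), n_pairs = length(cc),
       session_distance = abs(sessB$session_index - sessA$session_index),
       label = if (sessA$training_state == sessB$training_state)
         paste0(sessA$training_state, "-", sessB$training_state)
       else "pre-post")
}

#' Cohort-level trend of correlation versus session distance
#'
#' Spearman rank correlation between mean pairwise trial correlations and
#' the distance (days) between the two sessions.
#'
#' @param corr_table data.frame with \code{mean_r} and
#'   \code{session_distance} columns (one row per session pair).
#' @return Spearman rho.
#' @export
cross_day_distance_trend <- function(corr_table) {
  stats::cor(corr_table$mean_r, corr_table$session_distance,
             method = "spearman")
}
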