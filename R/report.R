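## Cohort-level summary assembly from per-cell stage outputs.

#' Build a cohort summary from stage outputs
#'
#' Joins the per-cell CSV tables written by the pipeline stages and
#' computes cohort aggregates per cell class: the field-category taxonomy
#' (percentages summing to 100), mean |SI|, hyperpolarization occurrence
#' and amplitude, decoding summaries, and the turnover table.  Writes
#' \code{summary.json} and \code{summary.csv} into the directory.
#'
#' @param results_dir Directory containing \code{fields.csv} (required)
#'   and optionally \code{hyperpol.csv}, \code{decode.csv},
#'   \code{turnover.csv}, \code{metrics.csv}.
#' @param write If TRUE (default), write the summary files.
#' @return A \code{cohort_summary} list: \code{by_class} data.frame plus
#'   any optional blocks found.
#' @export
build_summary <- function(results_dir, write = TRUE) {
  need <- file.path(results_dir, "fields.csv")
  if (!file.exists(need))
    stop("missing table fields.csv: run the `fields` stage first")
  fields <- utils::read.csv(need, stringsAsFactors = FALSE)
  cats <- c("odorA-specific", "odorB-specific", "non-odor-specific", "no-field")
  by_class <- do.call(rbind, lapply(split(fields, fields$cell_class),
                                    function(d) {
    pct <- vapply(cats, function(ct) 100 * mean(d$category == ct), 0)
    data.frame(cell_class = d$cell_class[1], n_cells = nrow(d),
               pct_field = 100 * mean(d$category != "no-field"),
               pct_odorA = pct[1], pct_odorB = pct[2],
               pct_nonspecific = pct[3], pct_nofield = pct[4],
               mean_abs_si = mean(abs(d$SI), na.rm = TRUE))
  }))
  rownames(by_class) <- NULL
  out <- list(by_class = by_class)
  opt <- function(name) {
    p <- file.path(results_dir, name)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  hp <- opt("hyperpol.csv")
  if (!is.null(hp))
    out$hyperpol <- data.frame(
      mean_occurrence = mean(hp$occurrence_rate),
      mean_amplitude = mean(hp$mean_amplitude, na.rm = TRUE),
      mean_onset = mean(hp$mean_onset, na.rm = TRUE),
      mean_duration = mean(hp$mean_duration, na.rm = TRUE))
  dc <- opt("decode.csv")
  if (!is.null(dc))
    out$decoding <- data.frame(
      mean_time_error_s = mean(dc$time_error_s),
      mean_odor_accuracy = mean(dc$odor_accuracy),
      mean_chance_error_s = mean(dc$chance_time_error_s))
  tv <- opt("turnover.csv")
  if (!is.null(tv)) out$turnover <- tv
  if (write) {
    json <- jsonlite::toJSON(out, digits = NA, dataframe = "rows", na = "null")
    writeLines(json, file.path(results_dir, "summary.json"), useBytes = TRUE)
    utils::write.csv(by_class, file.path(results_dir, "summary.csv"),
                     row.names = FALSE)
  }
  structure(out, class = "cohort_summary")
}
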