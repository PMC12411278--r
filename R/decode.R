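## Bayesian decoding of odor-specific time from single-cell spiking.
##
## Time space is the odor-delay axis doubled: the mean rate template over
## odor-A trials concatenated with that over odor-B trials.  Decoding a
## bin into the first half reads out "time t of an odor-A trial", into the
## second half "time t of an odor-B trial".  Emissions are Poisson with
## per-bin rate tau * R_m(t); a Gaussian continuity prior (sigma = 3 s)
## links consecutive decoded bins.

#' Fit the concatenated-template Bayesian decoder
#'
#' The first two-thirds of trials train the template, the final one-third
#' are held out for decoding.  Recordings with fewer than 10 trials or
#' fewer than 2 training trials of an odor are ineligible.  Per-trial
#' rates (100-ms bins, five-point smoothed) are scaled so each trial's
#' maximum equals the maximum over all trials; extended-axis bins with no
#' activity in either odor group are discarded.
#'
#' @param session A \code{cell_session}.
#' @param axis Analysis axis.
#' @param tau_s Bin duration in seconds (0.1).
#' @param sigma_s Continuity scale in seconds (3).
#' @param eps Rate floor (Hz) so the Poisson term is defined at zero-rate
#'   bins.
#' @return A \code{decoder_model}: \code{R_m} (rate template over retained
#'   extended bins), \code{K} (prior, sums to 1), \code{ext_bin}
#'   (retained extended-bin indices), \code{orig_bin}, \code{half}
#'   (\code{"A"}/\code{"B"}), test-set counts and odors, and the axis.
#' @export
fit_decoder <- function(session, axis = odor_delay_axis(), tau_s = 0.1,
                        sigma_s = 3, eps = 1e-6) {
  ntr <- length(session$trials)
  odor <- vapply(session$trials, `[[`, "", "odor1_id")
  n_train <- floor(2 * ntr / 3)
  if (ntr < 10 || sum(odor[1:n_train] == "A") < 2 ||
      sum(odor[1:n_train] == "B") < 2)
    stop("ineligible recording: need >= 10 trials and >= 2 training trials per odor")
  counts <- bin_rates(session, axis, smooth_points = 0)$rates *
    (axis$bin_ms / 1000) # back to counts
  sm <- t(apply(counts / (axis$bin_ms / 1000), 1, moving_average, n = 5))
  train <- seq_len(n_train)
  gmax <- max(sm[train, ])
  scaled <- sm[train, , drop = FALSE]
  keep_tr <- apply(scaled, 1, max) > 0
  scaled <- scaled[keep_tr, , drop = FALSE] *
    (gmax / apply(scaled[keep_tr, , drop = FALSE], 1, max))
  otr <- odor[train][keep_tr]
  if (sum(otr == "A") < 2 || sum(otr == "B") < 2)
    stop("ineligible recording: zero-activity training trials leave < 2 per odor")
  mA <- colMeans(scaled[otr == "A", , drop = FALSE])
  mB <- colMeans(scaled[otr == "B", , drop = FALSE])
  nb <- axis$n_bins
  ## drop original-axis bins with no activity in either training group
  active <- colSums(counts[train, , drop = FALSE]) > 0
  ext_bin <- c(seq_len(nb), nb + seq_len(nb))[c(active, active)]
  R_m <- pmax(c(mA, mB)[c(active, active)], eps)
  pA <- mean(otr == "A")
  K <- c(rep(pA, sum(active)), rep(1 - pA, sum(active)))
  K <- K / sum(K)
  test <- setdiff(seq_len(ntr), train)
  structure(list(R_m = R_m, K = K, tau_s = tau_s, sigma_s = sigma_s,
                 ext_bin = ext_bin,
                 orig_bin = ((ext_bin - 1) %% nb) + 1,
                 half = ifelse(ext_bin <= nb, "A", "B"),
                 axis = axis, n_dropped = sum(!active),
                 test_counts = counts[test, , drop = FALSE],
                 test_odor = odor[test]),
            class = "decoder_model")
}

#' Decode one trial's bin sequence
#'
#' At each time step the decoded bin maximises
#' K(t) * Poisson(s_j | tau R_m(t)) * exp(-(t - T_prev)^2 / (2 sigma^2))
#' over the retained extended-axis bins (ties broken towards the earliest
#' bin; the continuity term is omitted at the first step; the
#' normalisation constant does not affect the argmax).
#'
#' @param model A \code{decoder_model}.
#' @param counts Spike counts per original-axis bin for the decoded trial.
#' @return Integer vector of decoded extended-axis bin indices, one per
#'   time step.
#' @export
decode_trial <- function(model, counts) {
  if (length(counts) != model$axis$n_bins)
    stop("decoded trial not binned on the model's axis")
  lr <- log(model$tau_s * model$R_m)
  base <- log(model$K) - model$tau_s * model$R_m
  sig_bins <- model$sigma_s / model$tau_s
  pos <- model$ext_bin
  out <- integer(length(counts))
  prev <- NA_integer_
  for (j in seq_along(counts)) {
    lp <- base + counts[j] * lr
    if (!is.na(prev)) lp <- lp - (pos - prev)^2 / (2 * sig_bins^2)
    prev <- pos[which.max(lp)]
    out[j] <- prev
  }
  out
}

#' Evaluate decoding on the held-out trials
#'
#' Computes the decoded-time error (mean absolute within-trial time
#' distance, irrespective of initiating odor) and odor-decoding accuracy
#' (decoded bin in the correct half), plus chance distributions from
#' circular-shift surrogates of each decoded trial.
#'
#' @param model A \code{decoder_model} with held-out trials.
#' @param seed Optional seed for the surrogates.
#' @param n_surrogates Number of circular-shift repetitions (500).
#' @return A \code{decode_result}: \code{time_error_s},
#'   \code{odor_accuracy}, \code{decoded} (bin sequences), and
#'   \code{chance} (vectors of surrogate mean errors and accuracies).
#' @export
evaluate_decoding <- function(model, seed = NULL, n_surrogates = 500) {
  if (!is.null(seed)) set.seed(seed)
  nt <- nrow(model$test_counts)
  if (nt < 1) stop("no held-out trials")
  nb <- model$axis$n_bins
  bin_s <- model$tau_s
  score <- function(counts_mat, odors) {
    errs <- accs <- numeric(nrow(counts_mat))
    dec <- vector("list", nrow(counts_mat))
    for (i in seq_len(nrow(counts_mat))) {
      d <- decode_trial(model, counts_mat[i, ])
      orig <- ((d - 1) %% nb) + 1
      errs[i] <- mean(abs(orig - seq_len(nb))) * bin_s
      accs[i] <- mean((d <= nb) == (odors[i] == "A"))
      dec[[i]] <- d
    }
    list(err = mean(errs), acc = mean(accs), dec = dec)
  }
  obs <- score(model$test_counts, model$test_odor)
  ch_err <- ch_acc <- numeric(n_surrogates)
  for (k in seq_len(n_surrogates)) {
    shifted <- model$test_counts
    for (i in seq_len(nt)) {
      s <- sample.int(nb - 1, 1)
      shifted[i, ] <- circular_shift_row(shifted[i, ], s)
    }
    sc <- score(shifted, model$test_odor)
    ch_err[k] <- sc$err; ch_acc[k] <- sc$acc
  }
  structure(list(time_error_s = obs$err, odor_accuracy = obs$acc,
                 decoded = obs$dec,
                 chance = list(time_error_s = ch_err,
                               odor_accuracy = ch_acc)),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "<decode_result> time error %.2f s (chance %.2f), odor accuracy %.2f\n",
    x$time_error_s, mean(x$chance$time_error_s), x$odor_accuracy))
  invisible(x)
}
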