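## Minimal DSP toolkit: Butterworth design via zpk + bilinear transform,
## zero-phase filtering, analytic signal, tapers and smoothing kernels.
## No signal-processing package is assumed; the recursive core is in C++.

#' @useDynLib voltfield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## polynomial coefficients (descending powers) from roots, real output
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  Re(p)
}

#' Butterworth IIR filter design
#'
#' Designs digital Butterworth filters by the standard analog-prototype /
#' bilinear-transform route (matching SciPy's \code{butter}).
#'
#' @param n Filter order (of the analog prototype; band filters have final
#'   order \code{2n}).
#' @param w Cutoff frequency in Hz (length 1 for low/high, length 2 for
#'   pass/stop).
#' @param fs Sampling rate in Hz.
#' @param type One of \code{"low"}, \code{"high"}, \code{"pass"}, \code{"stop"}.
#' @return A list with numerator \code{b} and denominator \code{a}
#'   coefficients (\code{a[1] == 1}).
#' @export
butter_filter <- function(n, w, fs, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  stopifnot(n >= 1, all(w > 0), all(w < fs / 2))
  Wn <- w / (fs / 2)
  ## analog lowpass prototype: left-half-plane poles on the unit circle,
  ## no zeros, gain 1
  k0 <- seq_len(n)
  p <- exp(1i * pi * (2 * k0 + n - 1) / (2 * n))
  z <- complex(0)
  k <- 1
  fs2 <- 2
  warped <- 2 * fs2 * tan(pi * Wn / 2)
  if (type %in% c("low", "high")) {
    wo <- warped
    if (type == "low") {
      p <- wo * p
      k <- k * wo^n
    } else {
      ## prod(-p) = 1 for the Butterworth prototype, so the gain stays 1
      p <- wo / p
      z <- rep(0 + 0i, n)
    }
  } else {
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    if (type == "pass") {
      pl <- p * bw / 2
      p <- c(pl + sqrt(pl^2 - wo^2), pl - sqrt(pl^2 - wo^2))
      z <- rep(0 + 0i, n)
      k <- k * bw^n
    } else {
      pl <- (bw / 2) / p
      p <- c(pl + sqrt(pl^2 - wo^2), pl - sqrt(pl^2 - wo^2))
      z <- rep(c(1i * wo, -1i * wo), n)
    }
  }
  ## bilinear transform at fs2
  fs4 <- 2 * fs2
  degree <- length(p) - length(z)
  zz <- (fs4 + z) / (fs4 - z)
  pz <- (fs4 + p) / (fs4 - p)
  kz <- k * Re(prod(fs4 - z) / prod(fs4 - p))
  zz <- c(zz, rep(-1 + 0i, degree))
  b <- kz * poly_from_roots(zz)
  a <- poly_from_roots(pz)
  list(b = b / a[1], a = a / a[1])
}

## steady-state filter state for a unit-amplitude input (scipy lfilter_zi)
lfilter_zi <- function(b, a) {
  nfilt <- max(length(b), length(a))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  if (nfilt == 1) return(numeric(0))
  ## companion matrix of a
  comp <- rbind(-a[-1], cbind(diag(nfilt - 2), 0))
  IminusA <- diag(nfilt - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(IminusA, B))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forwards and backwards with odd-reflection padding and
#' steady-state initial conditions, so filter transients do not contaminate
#' the trace edges.
#'
#' @param coef List with \code{b}, \code{a} (e.g. from [butter_filter()]).
#' @param x Numeric vector.
#' @return Filtered vector, same length as \code{x}.
#' @export
filtfilt2 <- function(coef, x) {
  b <- coef$b; a <- coef$a
  nfilt <- max(length(b), length(a))
  npad <- 3 * (nfilt - 1)
  if (length(x) <= npad)
    stop("signal too short for zero-phase filtering (need > ", npad, " samples)")
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - npad)]
  xp <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(y)
  y <- iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[seq(npad + 1, npad + length(x))]
}

#' Analytic signal via the Hilbert transform
#'
#' @param x Real-valued vector.
#' @return Complex vector \code{x + i*H(x)}.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Centred moving average with shrinking edge windows
#'
#' A first-order Savitzky-Golay smoother evaluated at the window centre is
#' exactly the window mean, so this one routine serves both the
#' "five-point moving-average" and "first-order Savitzky-Golay" smoothing
#' steps of the pipeline.
#'
#' @param x Numeric vector.
#' @param n Odd window length in samples.
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(x, n) {
  stopifnot(n >= 1)
  if (n == 1) return(x)
  half <- floor(n / 2)
  cs <- cumsum(c(0, x))
  len <- length(x)
  lo <- pmax(seq_len(len) - half, 1)
  hi <- pmin(seq_len(len) + half, len)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Gaussian-weighted moving average
#'
#' @param x Numeric vector.
#' @param window Window length in samples; the kernel is a Gaussian with
#'   \code{sd = window/5} truncated to the window, renormalised at edges.
#' @return Smoothed vector.
#' @export
gaussian_smooth <- function(x, window) {
  half <- floor(window / 2)
  sdv <- window / 5
  k <- exp(-((-half):half)^2 / (2 * sdv^2))
  n <- length(x)
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, n), rev(k), type = "open")
  idx <- (half + 1):(half + n)
  num[idx] / den[idx]
}

## magnitude response of an IIR filter at frequency f (Hz)
iir_gain <- function(coef, f, fs) {
  hb <- vapply(f, function(fi) {
    wi <- exp(-1i * 2 * pi * fi / fs)
    sum(coef$b * wi^(seq_along(coef$b) - 1)) /
      sum(coef$a * wi^(seq_along(coef$a) - 1))
  }, complex(1))
  Mod(hb)
}

## Kaiser taper (beta fixed by caller); besselI(nu = 0) is in base R
kaiser_window <- function(n, beta) {
  m <- n - 1
  k <- 0:m
  besselI(beta * sqrt(1 - ((2 * k - m) / m)^2), 0) / besselI(beta, 0)
}

#' 1/f ("pink") noise
#'
#' FFT-shaped Gaussian noise with amplitude proportional to 1/sqrt(f)
#' between \code{f_lo} and \code{f_hi}, scaled to unit standard deviation.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param f_lo,f_hi Shaping band (Hz); power is zero outside.
#' @return Numeric vector with sd 1 (up to sampling error).
#' @export
pink_noise <- function(n, fs = 1000, f_lo = 0.5, f_hi = 200) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs - fs / n, length.out = n)
  f <- pmin(f, fs - f) # two-sided frequency axis
  amp <- ifelse(f >= f_lo & f <= f_hi, 1 / sqrt(f), 0)
  x <- Re(stats::fft(W * amp, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

#' Draw von Mises variates
#'
#' Best-Fisher (1979) rejection sampler.
#'
#' @param n Number of draws.
#' @param mu Mean direction (rad).
#' @param kappa Concentration (>= 0); 0 gives the uniform circle.
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap_angle(out + mu)
}

#' @rdname circular_stats
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Circular statistics
#'
#' \code{circ_r} is the mean resultant vector length; \code{circ_mean} the
#' mean direction; circular variance is \code{1 - circ_r}.
#'
#' @param theta Angles in radians.
#' @return \code{circ_r}: value in [0, 1]; \code{circ_mean}: angle in
#'   (-pi, pi]; \code{wrap_angle}: angles wrapped into (-pi, pi].
#' @name circular_stats
#' @export
circ_r <- function(theta) Mod(mean(exp(1i * theta)))

#' @rdname circular_stats
#' @export
circ_mean <- function(theta) wrap_angle(Arg(mean(exp(1i * theta))))

## half-open interval membership in ms-sample space (1-based index of t ms
## from trial start is t + 1)
ms_index <- function(t_ms) as.integer(round(t_ms)) + 1L

## merge sorted intervals [start, end) closer than gap; drop shorter than min_len
merge_intervals <- function(mat, gap = 0, min_len = 0) {
  if (is.null(mat) || nrow(mat) == 0) return(matrix(numeric(0), ncol = 2))
  o <- order(mat[, 1])
  mat <- mat[o, , drop = FALSE]
  out <- mat[1, , drop = FALSE]
  if (nrow(mat) > 1) {
    for (i in 2:nrow(mat)) {
      if (mat[i, 1] - out[nrow(out), 2] < gap) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], mat[i, 2])
      } else {
        out <- rbind(out, mat[i, , drop = FALSE])
      }
    }
  }
  out[out[, 2] - out[, 1] >= min_len, , drop = FALSE]
}

## runs of TRUE in a logical vector, as [start, end) 0-based offsets
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  keep <- r$values
  cbind(starts[keep], ends[keep])
}
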