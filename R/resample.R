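#' Resample a signal to the video frame rate
#'
#' Band-limited (anti-aliased) rate conversion used to bring pressure and
#' sound onto the time grid of the video before frame-synchronous
#' analysis. The conversion is performed in the frequency domain: the
#' signal is extended by odd reflection at both ends (suppressing edge
#' ringing), transformed, its spectrum truncated at the output Nyquist
#' (ideal anti-aliasing low-pass) or zero-padded, and inverse-transformed
#' on a grid whose spacing is exactly `1 / fps`. Padding lengths are chosen
#' so output samples fall exactly on the times `t0 + k / fps`; DC gain is
#' exactly 1, so constants are preserved.
#'
#' Requires the rate ratio `fps / fs` to be rational with a moderate
#' denominator (always true for the integer acquisition/frame rates used
#' in practice).
#'
#' @param x numeric vector or `signal_trace`.
#' @param fs input sampling rate, Hz.
#' @param fps output rate, Hz; must not exceed `fs`.
#' @param t0 time of the first sample (preserved in the output).
#' @return The resampled signal, of length `ceiling(length(x) * fps / fs)`;
#'   a `signal_trace` input yields a trace of the same class at rate `fps`.
#' @export
resample_to_framerate <- function(x, fs = trace_fs(x), fps,
                                  t0 = if (inherits(x, "signal_trace"))
                                    trace_t0(x) else 0) {
  force(fs); force(t0)
  if (fps > fs) stop("invalid parameter: fps exceeds the input rate")
  cls <- class(x)
  unit <- attr(x, "unit")
  xv <- as.numeric(x)
  n <- length(xv)
  n_out <- ceiling(n * fps / fs)
  if (abs(fps - fs) < 1e-9) {
    y <- xv
  } else {
    pq <- rational_ratio(fps, fs)
    p <- pq[1]; q <- pq[2]
    # head pad: multiple of q so that npad * p / q is an integer number of
    # output samples; tail pad tuned so the padded length is q times a
    # 5-smooth integer (fast FFT) and divisible by q.
    npad <- as.integer(q * ceiling(min(n - 1, max(64, n %/% 8)) / q))
    npad <- min(npad, as.integer(q * ((n - 1) %/% q)))
    target <- n + 2L * npad
    M <- stats::nextn(as.integer(ceiling(target / q)), c(2, 3, 5))
    L <- as.integer(M * q)
    tail_pad <- L - n - npad
    head <- if (npad > 0) 2 * xv[1] - xv[(npad + 1):2] else numeric(0)
    tl <- if (tail_pad > 0) {
      reps <- mirror_extend(xv, tail_pad)
      reps
    } else numeric(0)
    xp <- c(head, xv, tl)
    L_out <- as.integer(round(L * p / q))
    X <- stats::fft(xp)
    Y <- complex(length.out = L_out)
    keep <- min(L, L_out)
    half <- (keep - 1L) %/% 2L
    Y[1] <- X[1]
    if (half > 0) {
      Y[2:(half + 1L)] <- X[2:(half + 1L)]
      Y[(L_out - half + 1L):L_out] <- X[(L - half + 1L):L]
    }
    if (keep %% 2L == 0L) {
      # split the Nyquist bin symmetrically
      ny <- keep %/% 2L + 1L
      if (L_out > L) {
        Y[ny] <- X[ny] / 2
        Y[L_out - keep %/% 2L + 1L] <- X[ny] / 2
      } else {
        Y[ny] <- Re(X[ny] + X[L - keep + ny]) / 2
      }
    }
    y_full <- Re(stats::fft(Y, inverse = TRUE)) / L
    off <- as.integer(round(npad * p / q))
    y <- y_full[off + seq_len(min(n_out, L_out - off))]
    if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  }
  if (inherits(x, "signal_trace")) {
    structure(y, fs = fps, t0 = t0, unit = unit, class = cls)
  } else y
}

# continue a signal smoothly for m samples by odd reflection about its
# last sample, repeating the (reflected) signal if m > n - 1
mirror_extend <- function(x, m) {
  n <- length(x)
  out <- numeric(0)
  cur <- x
  while (length(out) < m) {
    refl <- 2 * cur[length(cur)] - rev(cur)[-1]
    if (!length(refl)) refl <- rep(cur[length(cur)], m)
    out <- c(out, refl)
    cur <- refl
  }
  out[seq_len(m)]
}

rational_ratio <- function(fps, fs, max_den = 100000L) {
  # exact for integer rates; continued-fraction fallback otherwise
  if (abs(fps - round(fps)) < 1e-9 && abs(fs - round(fs)) < 1e-9) {
    a <- as.integer(round(fps)); b <- as.integer(round(fs))
    g <- gcd_int(a, b)
    return(c(a %/% g, b %/% g))
  }
  r <- fps / fs
  best <- c(1L, 1L)
  err <- Inf
  for (den in 1:1000) {
    num <- round(r * den)
    e <- abs(r - num / den)
    if (e < err) { err <- e; best <- c(as.integer(num), as.integer(den)) }
    if (err < 1e-12) break
  }
  best
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}
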