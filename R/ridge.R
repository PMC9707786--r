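#' Fundamental frequency by spectrogram ridge tracking
#'
#' For fundamentals above a quarter of the sampling rate the yin estimator
#' fails; the fundamental is instead tracked as a time-frequency ridge on
#' the spectrogram (nfft 2048, 50% overlap, Hamming window). The ridge is
#' the path through the spectrogram maximizing the summed log-magnitude
#' minus a per-step penalty proportional to the frequency jump between
#' consecutive columns, solved exactly by dynamic programming. The penalty
#' keeps the ridge on one partial when several of comparable power are
#' present and suppresses bin-to-bin oscillation; ridge frequencies are
#' refined to sub-bin precision by parabolic interpolation of the
#' log-magnitude across adjacent bins.
#'
#' @param x numeric signal or `sound_trace`.
#' @param fs sampling rate, Hz.
#' @param nfft FFT length (default 2048).
#' @param overlap overlap between consecutive windows, samples (default
#'   `nfft / 2`).
#' @param penalty jump penalty, log-magnitude units per bin of frequency
#'   change per column (default 0.5).
#' @param max_jump_bins largest allowed bin jump per column (default 64).
#' @param fmin,fmax optional frequency band restricting the search, Hz.
#' @param power_floor minimum ridge power (magnitude squared) for a valid
#'   column (default 0).
#' @param t0 time of the first sample, s.
#' @return An `fo_track` (see [yin_f0()]) with `engine = "ridge"`;
#'   `aperiodicity` is 0 by convention for this engine.
#' @export
ridge_f0 <- function(x, fs = trace_fs(x), nfft = 2048L,
                     overlap = nfft %/% 2L, penalty = 0.5,
                     max_jump_bins = 64L, fmin = 0, fmax = fs / 2,
                     power_floor = 0,
                     t0 = if (inherits(x, "signal_trace")) trace_t0(x) else 0) {
  force(fs); force(t0)
  x <- as.numeric(x)
  if (length(x) < nfft) stop("invalid parameter: signal shorter than nfft")
  sg <- signal::specgram(x, n = nfft, Fs = fs,
                         window = signal::hamming(nfft), overlap = overlap)
  S <- abs(sg$S)
  freq <- as.numeric(sg$f)
  band <- which(freq >= fmin & freq <= fmax)
  S <- S[band, , drop = FALSE]
  freq <- freq[band]
  logS <- log(S + 1e-12)
  nb <- nrow(logS); nt <- ncol(logS)
  mj <- min(max_jump_bins, nb - 1L)
  cost <- logS[, 1]
  ptr <- matrix(0L, nb, nt)
  for (col in 2:nt) {
    best <- rep(-Inf, nb)
    from <- integer(nb)
    for (k in (-mj):mj) {
      # transition from bin j-k (previous column) to bin j
      src <- seq_len(nb) - k
      okk <- src >= 1L & src <= nb
      cand <- rep(-Inf, nb)
      cand[okk] <- cost[src[okk]] - penalty * abs(k)
      upd <- cand > best
      best[upd] <- cand[upd]
      from[upd] <- src[upd]
    }
    cost <- logS[, col] + best
    ptr[, col] <- from
  }
  path <- integer(nt)
  path[nt] <- which.max(cost)
  for (col in nt:2) path[col - 1L] <- ptr[path[col], col]
  # sub-bin refinement
  dfreq <- if (nb > 1) freq[2] - freq[1] else 0
  f0 <- numeric(nt); pw <- numeric(nt)
  for (col in seq_len(nt)) {
    j <- path[col]
    off <- 0
    if (j > 1L && j < nb) {
      a <- logS[j - 1L, col]; b <- logS[j, col]; cc <- logS[j + 1L, col]
      den <- a - 2 * b + cc
      if (abs(den) > 1e-12) off <- max(-0.5, min(0.5, 0.5 * (a - cc) / den))
    }
    f0[col] <- freq[j] + off * dfreq
    pw[col] <- S[j, col]^2
  }
  valid <- pw >= power_floor & f0 > 0
  # specgram timestamps the window start; report window centers
  out <- data.frame(time = t0 + as.numeric(sg$t) + (nfft / 2 - 1) / fs,
                    f0 = f0,
                    aperiodicity = 0, power = pw, valid = valid)
  structure(out, fs = fs, engine = "ridge",
            params = list(nfft = nfft, overlap = overlap, penalty = penalty,
                          max_jump_bins = max_jump_bins, fmin = fmin,
                          fmax = fmax, power_floor = power_floor),
            class = c("fo_track", "data.frame"))
}

#' Choose the f0 engine for a signal
#'
#' The yin estimator is reliable only up to a quarter of the sampling
#' rate; for expected fundamentals above `fs / 4` the spectrogram ridge
#' tracker is used instead. The boundary itself (`max f0 == fs / 4`)
#' selects yin.
#'
#' @param f0_expected_range numeric length-2, Hz.
#' @param fs sampling rate the estimator will run at, Hz.
#' @return `"yin"` or `"ridge"`.
#' @export
select_engine <- function(f0_expected_range, fs) {
  if (max(f0_expected_range) <= fs / 4) "yin" else "ridge"
}
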