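#' Default EEG frequency-band definitions
#'
#' Delta 0.5-4, Theta 4-7, Alpha 8-15, Beta 16-31, GammaLow 32-45 Hz.
#' Bands are half-open `[lo, hi)` so a boundary bin is counted once
#' (4 Hz belongs to Theta).
#'
#' @return Data frame with columns `name`, `lo`, `hi`.
#' @export
default_bands <- function() {
  data.frame(name = c("Delta", "Theta", "Alpha", "Beta", "GammaLow"),
             lo = c(0.5, 4, 8, 16, 32),
             hi = c(4, 7, 15, 31, 45))
}

#' One-sided periodogram of a frame
#'
#' The frame is demeaned, Hann-tapered by default, and Fourier transformed;
#' powers are scaled so that the sum over all bins equals the taper-corrected
#' signal variance (power, not density).
#'
#' @param frame Numeric vector (one analysis window).
#' @param fs Sampling rate in Hz.
#' @param taper `"hann"` (default) or `"rect"`.
#' @return List with `freq` (Hz) and `power` per bin.
#' @export
compute_psd <- function(frame, fs, taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  if (!all(is.finite(frame))) stop("non-finite samples")
  n <- length(frame)
  x <- frame - mean(frame)
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
       else rep(1, n)
  xw <- x * w
  X <- stats::fft(xw)
  nb <- n %/% 2 + 1
  p <- Mod(X[1:nb])^2 / (n * sum(w^2))   # Parseval: sum(p) = taper-corrected var
  # double interior bins so the one-sided sum equals total power
  if (n %% 2 == 0) p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]
  else p[2:nb] <- 2 * p[2:nb]
  list(freq = (0:(nb - 1)) * fs / n, power = p)
}

#' Band power in decibels
#'
#' `10 * log10` of the summed bin powers in the half-open interval
#' `[lo, hi)`, floored at -300 dB for zero power.
#'
#' @param psd Output of [compute_psd()].
#' @param lo,hi Band edges in Hz.
#' @return Power in dB.
#' @export
band_power_db <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq < hi
  if (!any(sel)) stop("empty band: no bins in [", lo, ", ", hi, ")")
  p <- sum(psd$power[sel])
  if (p <= 0) return(-300)
  max(10 * log10(p), -300)
}

#' Band-power time series at the window cadence
#'
#' Computes the periodogram of every analysis window (batched FFT) and the dB
#' power of each requested band, aligned row-for-row with the BAF windows.
#'
#' @param rec An `eeg_recording`.
#' @param bands Band definition data frame (default [default_bands()]).
#' @param n_win,hop Windowing parameters.
#' @param taper Taper passed through to the periodogram.
#' @return Data frame with `t_s` and one dB column per band.
#' @export
band_power_series <- function(rec, bands = default_bands(), n_win = 2048,
                              hop = 500, taper = "hann") {
  ws <- segment_windows(rec, n_win, hop)
  n <- ws$n_win
  idx <- outer(seq_len(n), ws$starts, `+`)
  M <- matrix(rec$samples[idx], nrow = n)
  M <- sweep(M, 2, colMeans(M))
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
       else rep(1, n)
  X <- stats::mvfft(M * w)
  nb <- n %/% 2 + 1
  P <- Mod(X[1:nb, , drop = FALSE])^2 / (n * sum(w^2))
  if (n %% 2 == 0) P[2:(nb - 1), ] <- 2 * P[2:(nb - 1), ]
  freq <- (0:(nb - 1)) * rec$fs / n
  out <- data.frame(t_s = ws$t_center_s)
  for (i in seq_len(nrow(bands))) {
    sel <- freq >= bands$lo[i] & freq < bands$hi[i]
    p <- colSums(P[sel, , drop = FALSE])
    out[[bands$name[i]]] <- ifelse(p <= 0, -300, pmax(10 * log10(p), -300))
  }
  out
}
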