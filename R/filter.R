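#' Design a Butterworth bandpass filter
#'
#' Analog Butterworth lowpass prototype of the given order, transformed to a
#' bandpass and discretised with the bilinear transform (edge frequencies
#' prewarped).  The result is returned as second-order sections, which stay
#' numerically well conditioned even for passbands reaching far below the
#' Nyquist frequency (0.3 Hz at 200 Hz sampling).
#'
#' @param low,high passband edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order prototype order; the bandpass has `2 * order` poles.
#' @return object of class `pd_sos`: list with `sos` (sections x 6 matrix,
#'   columns b0 b1 b2 a0 a1 a2) and the design parameters.
#' @export
butter_bandpass <- function(low, high, fs, order = 4L) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low)
    pd_stop("need 0 < low < high", "pdmil_error_filter_design")
  if (high >= fs / 2)
    pd_stop(sprintf("high edge %g Hz is at or above Nyquist (%g Hz)",
                    high, fs / 2), "pdmil_error_filter_design")
  if (order < 1) pd_stop("order must be >= 1", "pdmil_error_filter_design")

  # analog lowpass prototype poles on the unit Butterworth circle
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))

  # prewarped edges and lowpass -> bandpass transform (zpk form)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  plp <- p * bw / 2
  pbp <- c(plp + sqrt(plp^2 - w0^2), plp - sqrt(plp^2 - w0^2))
  zbp <- rep(0 + 0i, order)                 # order zeros at s = 0
  gain <- bw^order

  # bilinear transform; degree deficit becomes zeros at z = -1
  zd <- (fs2 + zbp) / (fs2 - zbp)
  pdg <- (fs2 + pbp) / (fs2 - pbp)
  gain_d <- gain * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  zd <- c(zd, rep(-1 + 0i, length(pbp) - length(zbp)))

  sos <- zpk_to_sos(zd, pdg, gain_d)
  structure(list(sos = sos, low = low, high = high, fs = fs, order = order),
            class = "pd_sos")
}

# Pair conjugate poles/zeros into biquads.  Bandpass-specific but general
# enough for any conjugate-symmetric zpk set of even degree.
zpk_to_sos <- function(z, p, k) {
  pair_conj <- function(v) {
    pos <- v[Im(v) > 1e-12]
    real <- sort(Re(v[abs(Im(v)) <= 1e-12]))
    pairs <- lapply(pos, function(x) c(x, Conj(x)))
    if (length(real) %% 2 != 0)
      pd_stop("unpaired real root in filter design", "pdmil_error_filter_design")
    if (length(real) > 0)
      pairs <- c(pairs, lapply(seq(1, length(real), by = 2),
                               function(i) complex(real = real[i + 0:1])))
    pairs
  }
  zp <- pair_conj(z)
  pp <- pair_conj(p)
  if (length(zp) != length(pp))
    pd_stop("zero/pole section mismatch", "pdmil_error_filter_design")
  ns <- length(pp)
  sos <- matrix(0, ns, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (i in seq_len(ns)) {
    zz <- zp[[i]]; ppi <- pp[[i]]
    sos[i, 1:3] <- Re(c(1, -(zz[1] + zz[2]), zz[1] * zz[2]))
    sos[i, 4:6] <- Re(c(1, -(ppi[1] + ppi[2]), ppi[1] * ppi[2]))
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# complex frequency response of an sos cascade at frequencies f (Hz)
sos_freq_response <- function(filt, f) {
  w <- 2 * pi * f / filt$fs
  zi <- exp(-1i * w)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(filt$sos))) {
    s <- filt$sos[i, ]
    h <- h * (s[1] + s[2] * zi + s[3] * zi^2) /
      (s[4] + s[5] * zi + s[6] * zi^2)
  }
  h
}

# apply an sos filter to a numeric vector (causal, single pass)
apply_sos <- function(filt, x) sosfilt_cpp(filt$sos, as.numeric(x))
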