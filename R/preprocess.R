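#' Preprocess a continuous recording
#'
#' Applies the standard signal chain: 50-Hz notch, 1-Hz high-pass and 30-Hz
#' low-pass filtering (all linear-phase Hamming-window FIR, applied
#' zero-phase so ERP latencies are not distorted), offline re-referencing to
#' the mean of the two mastoids (M1/M2), and downsampling to 250 Hz. The
#' reference channels are retained. The three filters are linear and
#' zero-phase, so their composition is order-independent; they are applied
#' in a single FFT pass using the product of their zero-phase transfer
#' functions, which is numerically identical to sequential filtering.
#'
#' @param raw An `lg_recording` (1000-Hz simulator output, or real data in
#'   the same container).
#' @param notch_hz,highpass_hz,lowpass_hz Filter frequencies (Hz).
#' @param notch_halfwidth_hz Half width of the notch stop band (Hz).
#' @param downsample_to Target sampling rate (Hz); must divide `raw$srate`.
#' @return An `lg_recording` at `downsample_to` Hz, re-referenced to the
#'   mastoid mean.
#' @export
filter_chain <- function(raw, notch_hz = 50, highpass_hz = 1, lowpass_hz = 30,
                         notch_halfwidth_hz = 2, downsample_to = 250) {
  stopifnot(inherits(raw, "lg_recording"))
  srate <- raw$srate
  if (srate %% downsample_to != 0)
    stopf("srate (%g) must be a multiple of downsample_to (%g)", srate, downsample_to)
  mon <- raw$montage
  if (!all(c("M1", "M2") %in% mon$labels))
    stopf("montage lacks mastoid channels M1/M2 required for re-referencing")

  X <- raw$data
  n <- ncol(X)
  nyq <- srate / 2
  # Long kernels give ~1-Hz transition bands; attenuation checked in tests.
  k_notch <- signal::fir1(3300, c(notch_hz - notch_halfwidth_hz,
                                  notch_hz + notch_halfwidth_hz) / nyq, "stop")
  k_hp <- signal::fir1(3300, highpass_hz / nyq, "high")
  k_lp <- signal::fir1(440, lowpass_hz / nyq, "low")

  nfft <- stats::nextn(n + 8192, 2)
  H <- zero_phase_response(k_notch, nfft) *
    zero_phase_response(k_hp, nfft) *
    zero_phase_response(k_lp, nfft)
  # Work in samples x channels orientation (contiguous columns) and filter
  # two channels per FFT pass: with a real transfer function, the real and
  # imaginary parts of the packed signal are filtered independently.
  Xt <- t(X)
  pad <- numeric(nfft - n)
  n_ch <- ncol(Xt)
  ch <- 1L
  while (ch <= n_ch) {
    if (ch + 1L <= n_ch) {
      xf <- fft(complex(real = c(Xt[, ch], pad),
                        imaginary = c(Xt[, ch + 1L], pad)))
      y <- fft(xf * H, inverse = TRUE)[seq_len(n)] / nfft
      Xt[, ch] <- Re(y)
      Xt[, ch + 1L] <- Im(y)
    } else {
      xf <- fft(c(Xt[, ch], pad))
      Xt[, ch] <- Re(fft(xf * H, inverse = TRUE))[seq_len(n)] / nfft
    }
    ch <- ch + 2L
  }

  m12 <- match(c("M1", "M2"), colnames(Xt))
  Xt <- Xt - (Xt[, m12[1]] + Xt[, m12[2]]) / 2

  dec <- srate / downsample_to
  X <- t(Xt[seq(1, n, by = dec), , drop = FALSE])

  structure(list(data = X, srate = downsample_to, montage = mon,
                 events = raw$events, reference = "M1/M2 mean",
                 condition = raw$condition),
            class = "lg_recording")
}

# Real-valued zero-phase transfer function of a symmetric (linear-phase type
# I) FIR kernel on an nfft grid: the kernel's DFT with its group delay
# (L-1)/2 samples compensated.
zero_phase_response <- function(kernel, nfft) {
  L <- length(kernel)
  Hf <- fft(c(kernel, numeric(nfft - L)))
  omega <- 2 * pi * (seq_len(nfft) - 1) / nfft
  Re(Hf * exp(1i * omega * (L - 1) / 2))
}
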