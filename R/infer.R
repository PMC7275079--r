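#' Multichannel time-series container
#'
#' @param samples Numeric matrix, channels x samples (voltages in
#'   arbitrary units).
#' @param rate Sampling rate in samples per second (> 0).
#' @return An object of class `multichannel_series`.
#' @export
multichannel_series <- function(samples, rate) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), rate > 0, !anyNA(samples))
  structure(list(samples = samples, rate = rate),
            class = "multichannel_series")
}

#' Functional-network inference configuration
#'
#' Defaults follow the recording pipeline the method was designed for:
#' zero-phase band-pass 4-50 Hz (order-1000 FIR applied forward and
#' reverse), 1 s windows with 0.5 s overlap, per-window per-channel
#' standardization, maximum cross-correlation over lags up to 0.2 s,
#' and Benjamini-Hochberg FDR at 0.05 within each window (two-sided
#' normal reference scaled by the dataset-wide average variance of the
#' cross-correlation across lags, Bonferroni-corrected over the lags
#' examined).  No re-referencing is applied.
#'
#' @param rate Sampling rate (Hz).
#' @param band Pass band in Hz, inside `(0, rate / 2)`.
#' @param fir_order FIR filter order.
#' @param window Window length in seconds.
#' @param overlap Window overlap in seconds (`window > overlap >= 0`).
#' @param max_lag Maximum cross-correlation lag in seconds.
#' @param fdr_q FDR level per window.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(rate, band = c(4, 50), fir_order = 1000L,
                             window = 1, overlap = 0.5, max_lag = 0.2,
                             fdr_q = 0.05) {
  stopifnot(rate > 0, length(band) == 2L, band[1] > 0, band[2] > band[1],
            band[2] < rate / 2, window > overlap, overlap >= 0)
  structure(list(rate = rate, band = band, fir_order = as.integer(fir_order),
                 window = window, overlap = overlap, max_lag = max_lag,
                 fdr_q = fdr_q),
            class = "inference_config")
}

#' Zero-phase FIR band-pass filter
#'
#' Designs a length `order + 1` FIR band-pass with [signal::fir1()] and
#' applies it forward and reverse (via FFT convolution), giving zero
#' phase and twice the single-pass stop-band attenuation.
#'
#' @param x Numeric vector, or channels x samples matrix (filtered
#'   row-wise).
#' @param rate Sampling rate in Hz.
#' @param band Pass band in Hz.
#' @param order FIR order.
#' @return Filtered data, same shape as `x`.
#' @export
bandpass_filter <- function(x, rate, band = c(4, 50), order = 1000L) {
  taps <- signal::fir1(order, band / (rate / 2), type = "pass")
  if (is.matrix(x)) {
    t(apply(x, 1L, fftfilt_filtfilt, taps = taps))
  } else {
    fftfilt_filtfilt(x, taps)
  }
}

# forward-reverse FIR by FFT convolution; keeps the zero-phase
# alignment of filtfilt without its state-space overhead
fftfilt_filtfilt <- function(x, taps) {
  n <- length(x)
  L <- length(taps)
  nfft <- stats::nextn(n + 2L * (L - 1L), 2)
  H <- fft(c(taps, rep(0, nfft - L)))
  pass <- function(sig) {
    X <- fft(c(sig, rep(0, nfft - length(sig))))
    Re(fft(X * H, inverse = TRUE)) / nfft
  }
  fwd <- pass(x)[seq_len(n + L - 1L)]
  rev_out <- pass(rev(fwd))
  # group delay (L-1)/2 per pass cancels: take the centered n samples
  full <- rev(rev_out[seq_len(n + 2L * (L - 1L))])
  full[seq.int(L, length.out = n)]
}

#' Filter, window, and standardize a multichannel series
#'
#' Band-pass filters each channel (zero phase), cuts the record into
#' `window`-second windows hopped by `window - overlap` seconds
#' (trailing partial windows are dropped, not padded), and standardizes
#' each channel within each window to zero mean and unit variance
#' (population denominator).  Channels that are flat within a window
#' are flagged and later excluded from that window's edges.
#'
#' @param series A [multichannel_series()].
#' @param config An [inference_config()].
#' @return List of class `preprocessed_windows`: `windows` (array
#'   `channels x window_samples x n_windows`), `flagged` (logical
#'   `channels x n_windows`), plus geometry fields.
#' @export
preprocess <- function(series, config) {
  stopifnot(inherits(series, "multichannel_series"),
            inherits(config, "inference_config"))
  x <- series$samples
  rate <- series$rate
  wlen <- round(config$window * rate)
  hop <- round((config$window - config$overlap) * rate)
  nsamp <- ncol(x)
  if (nsamp < wlen) stop("series shorter than one window")
  nwin <- (nsamp - wlen) %/% hop + 1L
  xf <- bandpass_filter(x, rate, config$band, config$fir_order)
  if (!is.matrix(xf)) xf <- matrix(xf, nrow = 1L)
  nch <- nrow(xf)
  win <- array(0, c(nch, wlen, nwin))
  flagged <- matrix(FALSE, nch, nwin)
  for (w in seq_len(nwin)) {
    idx <- ((w - 1L) * hop + 1L):((w - 1L) * hop + wlen)
    seg <- xf[, idx, drop = FALSE]
    mu <- rowMeans(seg)
    seg <- seg - mu
    s <- sqrt(rowMeans(seg^2))
    flat <- s < 1e-12
    s[flat] <- 1
    flagged[flat, w] <- TRUE
    win[, , w] <- seg / s
  }
  structure(list(windows = win, flagged = flagged, rate = rate,
                 wlen = wlen, hop = hop, n_windows = nwin,
                 n_channels = nch, config = config),
            class = "preprocessed_windows")
}

#' Significant cross-correlation functional networks
#'
#' For every window and channel pair, the statistic is the maximum over
#' lags `|l| <= max_lag` of the absolute normalized cross-correlation.
#' Each statistic is referred to a zero-mean normal whose variance is
#' the dataset-wide average (over all pairs and windows) of the
#' variance of the cross-correlation across lags, with a Bonferroni
#' correction for the number of lags examined; pairs passing
#' Benjamini-Hochberg FDR at `fdr_q` within the window become edges.
#' One layer per window; the pipeline is deterministic.
#'
#' @param pre A [preprocess()] result.
#' @param config An [inference_config()] (defaults to the one recorded
#'   during preprocessing).
#' @return A [layered_graph()] with `p` = channels, `N` = windows; the
#'   null scale used is attached as attribute `null_sd`.
#' @export
correlation_network <- function(pre, config = pre$config) {
  stopifnot(inherits(pre, "preprocessed_windows"))
  nch <- pre$n_channels
  nwin <- pre$n_windows
  wlen <- pre$wlen
  if (nch < 2L) {
    return(layered_graph(max(nch, 1L),
                         replicate(nwin, matrix(integer(0), ncol = 2L),
                                   simplify = FALSE)))
  }
  L <- round(config$max_lag * pre$rate)
  nfft <- stats::nextn(wlen + L, 2)
  pairs <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  np <- nrow(pairs)
  lag_rows <- c(nfft - (L:1) + 1L, 1L:(L + 1L))  # lags -L..0..L
  stat <- matrix(0, np, nwin)
  lag_var <- matrix(0, np, nwin)
  for (w in seq_len(nwin)) {
    X <- t(pre$windows[, , w])            # wlen x nch
    F <- mvfft(rbind(X, matrix(0, nfft - wlen, nch)))
    M <- F[, pairs[, 1L], drop = FALSE] * Conj(F[, pairs[, 2L], drop = FALSE])
    cc <- Re(mvfft(M, inverse = TRUE)) / nfft / wlen
    ccl <- cc[lag_rows, , drop = FALSE]   # (2L+1) x np cross-correlations
    stat[, w] <- apply(abs(ccl), 2L, max)
    lag_var[, w] <- apply(ccl, 2L, stats::var)
  }
  null_sd <- sqrt(mean(lag_var))
  n_lags <- 2L * L + 1L
  layers <- vector("list", nwin)
  for (w in seq_len(nwin)) {
    p_raw <- pmin(1, 2 * pnorm(-stat[, w] / null_sd) * n_lags)
    ok <- !(pre$flagged[pairs[, 1L], w] | pre$flagged[pairs[, 2L], w])
    p_raw[!ok] <- 1
    sig <- p.adjust(p_raw, method = "BH") <= config$fdr_q
    layers[[w]] <- cbind(pairs[sig, 1L] - 1L, pairs[sig, 2L] - 1L)
  }
  out <- layered_graph(nch, layers)
  attr(out, "null_sd") <- null_sd
  out
}

#' One-call functional-network inference
#'
#' [preprocess()] followed by [correlation_network()].
#'
#' @param series A [multichannel_series()].
#' @param config An [inference_config()].
#' @return A [layered_graph()], one layer per window.
#' @export
infer_functional_networks <- function(series, config) {
  correlation_network(preprocess(series, config), config)
}
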