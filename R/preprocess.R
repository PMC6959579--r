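# Epoch extraction, zero-phase band-pass filtering, filter-bank
# decomposition and sub-band fusion.

#' Preprocessing configuration
#'
#' @param tw analysis window length Tw in seconds (> 0).
#' @param latency visual latency in seconds; epochs are taken from the
#'   interval \[latency, latency + tw\] with stimulus onset at time 0.
#' @param band band-pass corners in Hz, default `c(6, 90)`: the passband of
#'   the Chebyshev Type II design, whose stopband edges sit 2 Hz below and
#'   10 Hz above (the margins customary in filter-bank SSVEP pipelines).
#' @param channels optional channel subset (indices) applied before any
#'   filtering; `NULL` keeps all channels.
#' @param order IIR filter order per filtering direction (default 6).
#' @param rs stopband attenuation in dB (default 40).
#' @param filter_first if `TRUE`, band-pass the full continuous trial before
#'   extracting the epoch (fewer edge artifacts); default `FALSE` filters the
#'   extracted epoch, the conventional order for offline SSVEP pipelines.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(tw, latency = 0.14, band = c(6, 90),
                              channels = NULL, order = 6, rs = 40,
                              filter_first = FALSE) {
  if (tw <= 0) stop("invalid argument: tw must be positive")
  if (latency < 0) stop("invalid argument: latency must be >= 0")
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2])
    stop("invalid argument: band must satisfy 0 < low < high")
  structure(
    list(tw = tw, latency = latency, band = band, channels = channels,
         order = order, rs = rs, filter_first = filter_first),
    class = "preprocess_config"
  )
}

#' Filter-bank configuration
#'
#' Sub-band n spans `n * low_base` to `high` Hz; sub-band features are fused
#' with weights `w(n) = n^(-a) + b`, reflecting the decreasing SNR of higher
#' SSVEP harmonics.
#'
#' @param n_subbands number of sub-bands N.
#' @param low_base base low cut-off in Hz (sub-band n starts at `n * low_base`).
#' @param high common high cut-off in Hz.
#' @param a,b fusion-weight parameters (defaults 1 and 0 give weights
#'   1, 1/2, 1/3, ...).
#' @return object of class `filter_bank_config`.
#' @export
filter_bank_config <- function(n_subbands = 4, low_base = 8, high = 70,
                               a = 1, b = 0) {
  if (n_subbands < 1) stop("invalid argument: n_subbands must be >= 1")
  if (n_subbands * low_base >= high)
    stop("invalid argument: n * low_base must stay below the high cut-off for every sub-band")
  w <- seq_len(n_subbands)^(-a) + b
  if (any(!is.finite(w)) || any(w <= 0))
    stop("invalid argument: sub-band weights must be finite and positive")
  structure(
    list(n_subbands = as.integer(n_subbands), low_base = low_base,
         high = high, a = a, b = b),
    class = "filter_bank_config"
  )
}

#' Sub-band fusion weights
#' @param fb a [filter_bank_config()].
#' @return numeric vector `n^(-a) + b`, n = 1..N.
#' @export
subband_weights <- function(fb) {
  seq_len(fb$n_subbands)^(-fb$a) + fb$b
}

#' Extract the analysis epoch from a trial
#'
#' Takes `round(tw * fs)` samples starting `round(latency * fs)` samples
#' after stimulus onset (sample 1 of the input), i.e. the window
#' \[latency, latency + tw\] that skips the visual-pathway delay.
#'
#' @param trial numeric matrix `M x n_samples`, onset at the first sample.
#' @param fs sampling rate in Hz.
#' @param tw window length in seconds.
#' @param latency latency in seconds (default 0.14).
#' @return matrix `M x round(tw * fs)`.
#' @export
extract_epoch <- function(trial, fs, tw, latency = 0.14) {
  trial <- as.matrix(trial)
  start <- round(latency * fs)
  nt <- round(tw * fs)
  if (start + nt > ncol(trial))
    stop("invalid argument: latency + tw window exceeds trial length")
  trial[, (start + 1):(start + nt), drop = FALSE]
}

# Chebyshev Type II band-pass design. `band` gives the passband corners;
# the design places the stopband edges 2 Hz below / 10 Hz above (clipped
# to the feasible range), the margins customary in filter-bank SSVEP
# pipelines, so stimulus fundamentals sitting right at a sub-band corner
# keep unit gain.
design_bandpass <- function(band, fs, order = 6, rs = 40) {
  nyq <- fs / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("invalid argument: band infeasible for this sampling rate")
  stop_lo <- max(band[1] - 2, band[1] / 2)
  stop_hi <- min(band[2] + 10, (band[2] + nyq) / 2, 0.99 * nyq)
  fl <- signal::cheby2(order, rs, c(stop_lo, stop_hi) / nyq, type = "pass")
  list(b = fl$b, a = fl$a)
}

# Zero-phase forward-backward IIR filtering of one vector with
# odd-reflection padding; pad length min(3 * order, n - 1) keeps short
# epochs (0.2 s windows) filterable.
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  npad <- min(3 * (max(length(a), length(b)) - 1), n - 1)
  if (npad < 1) stop("invalid argument: epoch too short to filter")
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  y <- c(pre, x, post)
  y <- as.numeric(signal::filter(b, a, y))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase band-pass filter an epoch
#'
#' Chebyshev Type II IIR filtering applied forward and backward (zero net
#' group delay) to every channel.
#'
#' @param epoch numeric matrix `M x Nt` (a vector is treated as one channel).
#' @param band passband corners in Hz.
#' @param fs sampling rate in Hz.
#' @param order,rs design parameters as in [preprocess_config()].
#' @return filtered epoch, same shape.
#' @export
bandpass <- function(epoch, band, fs, order = 6, rs = 40) {
  vec <- is.null(dim(epoch))
  epoch <- if (vec) matrix(epoch, 1) else as.matrix(epoch)
  d <- design_bandpass(band, fs, order, rs)
  out <- t(apply(epoch, 1, function(x) filtfilt_zp(d$b, d$a, x)))
  if (vec) drop(out) else out
}

#' Decompose an epoch into filter-bank sub-bands
#'
#' @param epoch numeric matrix `M x Nt`.
#' @param fb a [filter_bank_config()].
#' @param fs sampling rate in Hz.
#' @param order,rs filter design parameters.
#' @return list of `N` filtered epochs, sub-band n band-passed on
#'   `[n * low_base, high]` Hz.
#' @export
filterbank <- function(epoch, fb, fs, order = 6, rs = 40) {
  stopifnot(inherits(fb, "filter_bank_config"))
  if (fb$high >= fs / 2)
    stop("invalid argument: filter bank infeasible for this sampling rate")
  lapply(seq_len(fb$n_subbands), function(n) {
    bandpass(epoch, c(n * fb$low_base, fb$high), fs, order, rs)
  })
}

#' Fuse per-sub-band features
#'
#' Weighted sum over sub-bands with weights `n^(-a) + b`: with the defaults
#' a = 1, b = 0 the weights are 1, 1/2, 1/3, ...
#'
#' @param rho per-sub-band feature values: a length-N vector, or an
#'   `N x K` matrix fused column-wise.
#' @param fb a [filter_bank_config()].
#' @return fused scalar (or length-K vector).
#' @export
subband_fuse <- function(rho, fb) {
  stopifnot(inherits(fb, "filter_bank_config"))
  w <- subband_weights(fb)
  if (is.matrix(rho)) {
    if (nrow(rho) != fb$n_subbands)
      stop("invalid argument: rho must have one row per sub-band")
    return(drop(crossprod(rho, w)))
  }
  if (length(rho) != fb$n_subbands)
    stop("invalid argument: rho must have one value per sub-band")
  sum(w * rho)
}

#' Circularly shift a trial to change its apparent stimulus phase
#'
#' Delays the signal circularly by `round(fs * delta_phi / (2 * pi * f))`
#' samples — the standard trick for re-coding the phase interval of a
#' JFPM dataset (e.g. from the acquired 0.5*pi spacing to the 0.35*pi
#' spacing that maximizes separability).
#'
#' @param trial numeric matrix `M x Nt` or vector.
#' @param f stimulus frequency in Hz (> 0).
#' @param delta_phi phase change in radians.
#' @param fs sampling rate in Hz.
#' @return shifted trial, same shape.
#' @export
circular_phase_shift <- function(trial, f, delta_phi, fs) {
  if (f <= 0) stop("invalid argument: f must be positive")
  vec <- is.null(dim(trial))
  trial <- if (vec) matrix(trial, 1) else as.matrix(trial)
  n <- ncol(trial)
  shift <- round(fs * delta_phi / (2 * pi * f)) %% n
  idx <- ((seq_len(n) - 1 - shift) %% n) + 1
  out <- trial[, idx, drop = FALSE]
  if (vec) drop(out) else out
}

#' Prepare an epoch set for decoding
#'
#' Applies channel selection, latency-aware epoch extraction and zero-phase
#' filtering (single band, or a filter bank) to every trial, yielding the
#' representation all decoders consume.
#'
#' @param es an [epoch_set()].
#' @param pp a [preprocess_config()].
#' @param fb optional [filter_bank_config()]; if `NULL` a single band
#'   (`pp$band`) is used.
#' @return object of class `prepared_epochs`: a list with `subbands` (list of
#'   `n_trials x M x Nt` arrays), `labels`, `blocks`, `fs`, `layout`, `fb`,
#'   `tw`.
#' @export
prepare_epochs <- function(es, pp, fb = NULL) {
  stopifnot(inherits(es, "epoch_set"), inherits(pp, "preprocess_config"))
  data <- es$data
  if (!is.null(pp$channels)) data <- data[, pp$channels, , drop = FALSE]
  n <- dim(data)[1L]
  m <- dim(data)[2L]
  nt <- round(pp$tw * es$fs)
  bands <- if (is.null(fb)) list(pp$band) else
    lapply(seq_len(fb$n_subbands), function(s) c(s * fb$low_base, fb$high))
  designs <- lapply(bands, design_bandpass, fs = es$fs,
                    order = pp$order, rs = pp$rs)
  subbands <- lapply(designs, function(d) array(0, dim = c(n, m, nt)))
  for (i in seq_len(n)) {
    tr <- trial_matrix(data, i)
    if (pp$filter_first) {
      for (s in seq_along(designs)) {
        ftr <- t(apply(tr, 1, function(x)
          filtfilt_zp(designs[[s]]$b, designs[[s]]$a, x)))
        subbands[[s]][i, , ] <- extract_epoch(ftr, es$fs, pp$tw, pp$latency)
      }
    } else {
      ep <- extract_epoch(tr, es$fs, pp$tw, pp$latency)
      for (s in seq_along(designs)) {
        subbands[[s]][i, , ] <- t(apply(ep, 1, function(x)
          filtfilt_zp(designs[[s]]$b, designs[[s]]$a, x)))
      }
    }
  }
  structure(
    list(subbands = subbands, labels = es$labels, blocks = es$blocks,
         fs = es$fs, layout = es$layout, fb = fb, tw = pp$tw),
    class = "prepared_epochs"
  )
}

# fusion weights for a prepared set: filter-bank weights or scalar 1
prepared_weights <- function(prep) {
  if (is.null(prep$fb)) 1 else subband_weights(prep$fb)
}
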