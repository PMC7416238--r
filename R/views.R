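#' EEG segment container
#'
#' One windowed multichannel EEG epoch: a channels-by-time numeric matrix
#' sampled at `sampling_rate` Hz. The downstream spectral and time-frequency
#' views assume a 1-second window (time length equal to the sampling rate),
#' the configuration under which the frequency grid has 1 Hz spacing.
#'
#' @param samples Numeric `channels x time` matrix (default geometry
#'   23 x 256).
#' @param sampling_rate Sampling rate in Hz, default 256.
#' @param segment_id Optional identifier.
#' @param label Optional class label (0 = non-seizure, 1 = seizure).
#' @return An object of class `"eeg_segment"`.
#' @export
eeg_segment <- function(samples, sampling_rate = 256, segment_id = NULL,
                        label = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("'samples' must be a numeric channels x time matrix", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("EEG samples must be finite", call. = FALSE)
  if (sampling_rate <= 0) stop("'sampling_rate' must be positive", call. = FALSE)
  if (!is.null(label) && !label %in% c(0, 1))
    stop("'label' must be 0 or 1", call. = FALSE)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 segment_id = segment_id, label = label),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("EEG segment%s: %d channels x %d samples @ %g Hz%s\n",
              if (is.null(x$segment_id)) "" else paste0(" ", x$segment_id),
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              if (is.null(x$label)) "" else
                sprintf(" (label %d)", as.integer(x$label))))
  invisible(x)
}

as_eeg_segment <- function(x) {
  if (inherits(x, "eeg_segment")) x else eeg_segment(as.matrix(x))
}

check_one_second_window <- function(segment) {
  n <- ncol(segment$samples)
  if (n != segment$sampling_rate || n != round(n))
    stop(sprintf(paste("spectral and time-frequency views require a 1-second",
                       "window at an integer sampling rate (got %d samples",
                       "at %g Hz)"), n, segment$sampling_rate), call. = FALSE)
  invisible(TRUE)
}

#' Time-domain view
#'
#' The raw signal itself: the time view passes the channels-by-time matrix
#' through unchanged.
#'
#' @param segment An [eeg_segment()].
#' @return The `channels x time` matrix of raw samples.
#' @export
time_view <- function(segment) {
  as_eeg_segment(segment)$samples
}

#' Spectral view: per-channel Fourier magnitudes at 4-30 Hz
#'
#' One-sided DFT magnitude of each channel at the integer frequencies
#' 4, 5, ..., 30 Hz — the band where seizure spectral energy concentrates.
#' With a 1-second window the DFT bins fall exactly on integer frequencies,
#' giving 27 columns.
#'
#' @param segment An [eeg_segment()] with a 1-second window.
#' @param band Two-element integer vector, inclusive frequency band in Hz.
#'   Default `c(4, 30)`.
#' @return Nonnegative `channels x 27` matrix (for the default band).
#' @export
spectral_view <- function(segment, band = c(4, 30)) {
  segment <- as_eeg_segment(segment)
  check_one_second_window(segment)
  nyq <- floor(segment$sampling_rate / 2)
  if (band[1L] < 0 || band[2L] > nyq || band[1L] > band[2L])
    stop("'band' must lie within [0, Nyquist]", call. = FALSE)
  FT <- stats::mvfft(t(segment$samples))       # time x channels
  bins <- seq.int(band[1L], band[2L]) + 1L     # bin k+1 holds k Hz
  t(Mod(FT[bins, , drop = FALSE]))
}

#' Time-frequency view: wavelet-packet subband envelopes
#'
#' A level-6 wavelet packet decomposition (periodized Daubechies db4 filter
#' bank) splits each channel's 256-sample window into 64 uniform 2 Hz
#' subbands. The 14 subbands covering 4-32 Hz are retained; each subband's 4
#' coefficients are nearest-neighbour upsampled to the 256-point time axis
#' and their magnitudes taken, yielding a `256 x channels x 14` array where
#' subband k spans `[4 + 2k, 6 + 2k)` Hz.
#'
#' @param segment An [eeg_segment()] with a 256-sample window at 256 Hz.
#' @return Nonnegative array of dimension `256 x channels x 14`.
#' @export
timefreq_view <- function(segment) {
  segment <- as_eeg_segment(segment)
  check_one_second_window(segment)
  if (ncol(segment$samples) != 256L)
    stop("the time-frequency view requires 256 samples at 256 Hz",
         call. = FALSE)
  n_ch <- nrow(segment$samples)
  level <- 6L
  keep <- 2:15                                  # 2 Hz bands: [4,6) .. [30,32)
  out <- array(0, dim = c(256L, n_ch, length(keep)))
  for (ch in seq_len(n_ch)) {
    nodes <- wpd_periodic(segment$samples[ch, ], level)   # natural order
    for (j in seq_along(keep)) {
      nat <- freq_rank_to_natural(keep[j])                # Gray-code map
      coefs <- nodes[[nat + 1L]]                          # 4 coefficients
      out[, ch, j] <- abs(rep(coefs, each = 256L %/% length(coefs)))
    }
  }
  out
}

## Daubechies db4 (8-tap) orthonormal scaling filter; sums to sqrt(2).
DB4_LO <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)
DB4_HI <- rev(DB4_LO) * c(1, -1, 1, -1, 1, -1, 1, -1)   # QMF pair

## One periodized analysis step: circular convolution + dyadic decimation.
dwt_step <- function(x, h) {
  L <- length(x); n2 <- L %/% 2L
  idx <- outer(seq_len(length(h)) - 1L, (seq_len(n2) - 1L) * 2L, `+`) %% L + 1L
  as.numeric(crossprod(matrix(x[idx], nrow = length(h)), h))
}

## Full wavelet packet tree at the given level, nodes in natural
## (filter-path) order: index bits record the low/high choices top-down.
wpd_periodic <- function(x, level) {
  nodes <- list(as.numeric(x))
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (k in seq_along(nodes)) {
      nxt[[2L * k - 1L]] <- dwt_step(nodes[[k]], DB4_LO)
      nxt[[2L * k]]      <- dwt_step(nodes[[k]], DB4_HI)
    }
    nodes <- nxt
  }
  nodes
}

## Natural-order index (0-based) of the node occupying frequency rank r
## (0-based, low to high). High-pass branches mirror the child order, so the
## map is the binary-reflected Gray code.
freq_rank_to_natural <- function(r) {
  bitwXor(as.integer(r), bitwShiftR(as.integer(r), 1L))
}

#' Build the three-view dataset from EEG segments
#'
#' Applies [time_view()], [spectral_view()] and [timefreq_view()] to each
#' segment and flattens the results row-major into one feature row per
#' segment, in the fixed view order (time, spectral, time-frequency):
#' per-view widths 5888, 621 and 82432 for the default 23 x 256 geometry.
#'
#' @param segments A list of [eeg_segment()]s with identical geometry.
#' @return A [multiview_dataset] with 3 views; if any segment carries a
#'   label, the full label vector is attached as attribute `"labels"`.
#' @export
build_views <- function(segments) {
  if (!length(segments)) stop("'segments' must be non-empty", call. = FALSE)
  segments <- lapply(segments, as_eeg_segment)
  shp <- dim(segments[[1L]]$samples)
  for (s in segments)
    if (!identical(dim(s$samples), shp))
      stop("all segments must share the same channels x time shape",
           call. = FALSE)
  tv <- t(vapply(segments, function(s) flatten_rowmajor(time_view(s)),
                 numeric(prod(shp))))
  sv <- t(vapply(segments, function(s) flatten_rowmajor(spectral_view(s)),
                 numeric(shp[1L] * 27L)))
  fv <- t(vapply(segments, function(s) flatten_rowmajor(timefreq_view(s)),
                 numeric(256L * shp[1L] * 14L)))
  ids <- vapply(seq_along(segments), function(i) {
    id <- segments[[i]]$segment_id
    if (is.null(id)) paste0("seg", i) else as.character(id)
  }, "")
  ds <- multiview_dataset(list(time = tv, spectral = sv, timefreq = fv),
                          sample_ids = ids)
  labels <- vapply(segments, function(s)
    if (is.null(s$label)) NA_integer_ else as.integer(s$label), 0L)
  if (any(!is.na(labels))) attr(ds, "labels") <- labels
  ds
}

## Row-major flatten: the first array index varies slowest.
flatten_rowmajor <- function(a) {
  if (is.matrix(a)) as.numeric(t(a))
  else as.numeric(aperm(a, rev(seq_along(dim(a)))))
}
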