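#' Raw EMG recording
#'
#' @param samples voltage samples (consistent arbitrary units).
#' @param fs sampling rate (Hz).
#' @param channel_id opaque channel label.
#' @return An object of class `emg_record`.
#' @export
emg_record <- function(samples, fs, channel_id = "emg") {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("emg_record: fs must be a positive number", call. = FALSE)
  }
  if (length(samples) < 2 || !all(is.finite(samples))) {
    stop("emg_record: need >= 2 finite samples", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 channel_id = as.character(channel_id)),
            class = "emg_record")
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("emg_record '%s': %d samples @ %g Hz (%.2f s)\n",
              x$channel_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' One-sided EMG power spectrum
#'
#' @param freqs strictly increasing frequency-bin centres (Hz).
#' @param power non-negative power per bin.
#' @return An object of class `power_spectrum` with elements `freqs`,
#'   `power` and the bin count `M`.
#' @export
power_spectrum <- function(freqs, power) {
  if (length(freqs) != length(power)) {
    stop("power_spectrum: freqs and power lengths differ", call. = FALSE)
  }
  if (any(diff(freqs) <= 0)) {
    stop("power_spectrum: freqs must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(power)) || any(power < 0)) {
    stop("power_spectrum: power must be finite and non-negative",
         call. = FALSE)
  }
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 M = length(freqs)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power_spectrum: %d bins, %.3g..%.3g Hz, total power %.4g\n",
              x$M, min(x$freqs), max(x$freqs), sum(x$power)))
  invisible(x)
}

#' Welch averaged-periodogram power spectrum of an EMG record
#'
#' Splits the record into Hann-tapered, mean-detrended segments with the
#' given overlap, and averages the one-sided periodograms. Scaling is such
#' that the summed bin powers approximate the signal variance (Parseval).
#'
#' @param rec an [emg_record()].
#' @param window_s segment length (s); default 1.
#' @param overlap fractional overlap between segments in `[0, 1)`;
#'   default 0.5.
#' @return A [power_spectrum()] with bins from 0 to `fs/2`.
#' @export
compute_psd <- function(rec, window_s = 1, overlap = 0.5) {
  stopifnot(inherits(rec, "emg_record"))
  n <- round(window_s * rec$fs)
  if (n < 8) {
    stop("compute_psd: window must contain at least 8 samples",
         call. = FALSE)
  }
  if (length(rec$samples) < n) {
    stop("compute_psd: record shorter than one window", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) {
    stop("compute_psd: overlap must be in [0, 1)", call. = FALSE)
  }
  w <- as.numeric(signal::hanning(n))
  wss <- sum(w^2)
  hop <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, length(rec$samples) - n + 1L, by = hop)
  half <- n %/% 2 + 1L
  acc <- numeric(half)
  for (s in starts) {
    x <- rec$samples[s:(s + n - 1L)]
    y <- w * (x - mean(x))
    X <- stats::fft(y)
    p <- Mod(X[1:half])^2 / (n * wss)
    # fold negative frequencies into the one-sided spectrum
    dbl <- 2:(half - if (n %% 2 == 0) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  power_spectrum(freqs = (0:(half - 1L)) * rec$fs / n,
                 power = acc / length(starts))
}

#' Mean frequency (MNF) of a power spectrum
#'
#' The power-weighted average frequency
#' `sum(f_j P_j) / sum(P_j)`. Falls with muscle fatigue as the EMG
#' spectrum compresses toward low frequencies.
#'
#' @param ps a [power_spectrum()] with positive total power.
#' @return Mean frequency (Hz).
#' @export
mnf <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  tot <- sum(ps$power)
  if (tot <= 0) {
    stop("mnf: zero total power, feature undefined", call. = FALSE)
  }
  sum(ps$freqs * ps$power) / tot
}

#' Mean power (MNP) of a power spectrum
#'
#' The average bin power `sum(P_j) / M`. Rises with fatigue as the EMG
#' amplitude grows.
#'
#' @param ps a [power_spectrum()].
#' @return Mean power (same units as the spectrum).
#' @export
mnp <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  sum(ps$power) / ps$M
}

#' Frequency-band specification for the frequency ratio
#'
#' In `"fixed"` mode the low band is `[LLC, ULC)` and the high band
#' `[LHC, UHC)` (half-open, bin-centre inclusion). In `"mnf_split"` mode
#' (default) the cutoffs are ignored and the bands are derived from the
#' spectrum itself: low below its MNF, high at or above it, so no
#' subject-specific calibration is needed.
#'
#' @param LLC,ULC low-band lower/upper cutoff (Hz).
#' @param LHC,UHC high-band lower/upper cutoff (Hz).
#' @param mode `"mnf_split"` or `"fixed"`.
#' @return An object of class `fr_bands`.
#' @export
fr_bands <- function(LLC = NULL, ULC = NULL, LHC = NULL, UHC = NULL,
                     mode = c("mnf_split", "fixed")) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(LLC) || is.null(ULC) || is.null(LHC) || is.null(UHC)) {
      stop("fr_bands: fixed mode requires all four cutoffs", call. = FALSE)
    }
    if (!(LLC < ULC && ULC <= LHC && LHC < UHC)) {
      stop("fr_bands: need LLC < ULC <= LHC < UHC", call. = FALSE)
    }
  }
  structure(list(LLC = LLC, ULC = ULC, LHC = LHC, UHC = UHC, mode = mode),
            class = "fr_bands")
}

#' Frequency ratio (FR) of a power spectrum
#'
#' Ratio of low-band to high-band spectral power,
#' `sum(P_j, low band) / sum(P_j, high band)`. Rises with fatigue. Bands
#' come from a [fr_bands()] specification.
#'
#' @param ps a [power_spectrum()].
#' @param bands a [fr_bands()]; default MNF-split bands.
#' @return Dimensionless ratio.
#' @export
fr <- function(ps, bands = fr_bands()) {
  stopifnot(inherits(ps, "power_spectrum"), inherits(bands, "fr_bands"))
  if (bands$mode == "mnf_split") {
    split <- mnf(ps)
    low <- ps$freqs < split
    high <- ps$freqs >= split
  } else {
    low <- ps$freqs >= bands$LLC & ps$freqs < bands$ULC
    high <- ps$freqs >= bands$LHC & ps$freqs < bands$UHC
  }
  denom <- sum(ps$power[high])
  if (denom <= 0) {
    stop("fr: zero high-band power, feature undefined", call. = FALSE)
  }
  sum(ps$power[low]) / denom
}

#' Power spectrum ratio (PSR)
#'
#' Energy in a window of `n` bins either side of the peak-power frequency
#' (PKF) bin, relative to total spectral energy:
#' `sum(P_j, j = f0-n .. f0+n) / sum(P_j)`, the window clipped to the
#' spectrum. Always in `[0, 1]`; ties at the maximum resolve to the
#' lowest-frequency bin.
#'
#' @param ps a [power_spectrum()] with positive total power.
#' @param n integral limit (bins), `n >= 0`.
#' @return Ratio in `[0, 1]`.
#' @export
psr <- function(ps, n) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (n < 0) stop("psr: n must be >= 0", call. = FALSE)
  tot <- sum(ps$power)
  if (tot <= 0) {
    stop("psr: zero total power, feature undefined", call. = FALSE)
  }
  f0 <- which.max(ps$power)  # first maximum on ties
  idx <- max(1L, f0 - n):min(ps$M, f0 + n)
  sum(ps$power[idx]) / tot
}

#' All four frequency-domain fatigue features of one EMG record
#'
#' Composes [compute_psd()] with [mnf()], [mnp()], [fr()] and [psr()].
#' The PSR integral limit is given in Hz (`psr_halfwidth_hz`, default 10)
#' and converted to bins at the spectrum's resolution.
#'
#' @inheritParams compute_psd
#' @param bands a [fr_bands()] specification for the frequency ratio.
#' @param psr_halfwidth_hz half-width of the PSR peak window (Hz).
#' @return An object of class `emg_features`: list with `mnf` (Hz),
#'   `mnp`, `fr`, `psr`.
#' @export
extract_features <- function(rec, window_s = 1, overlap = 0.5,
                             bands = fr_bands(), psr_halfwidth_hz = 10) {
  ps <- compute_psd(rec, window_s = window_s, overlap = overlap)
  df <- ps$freqs[2] - ps$freqs[1]
  structure(list(mnf = mnf(ps), mnp = mnp(ps), fr = fr(ps, bands),
                 psr = psr(ps, round(psr_halfwidth_hz / df))),
            class = "emg_features")
}

#' @export
print.emg_features <- function(x, ...) {
  cat(sprintf("emg_features: mnf=%.2f Hz, mnp=%.4g, fr=%.3f, psr=%.3f\n",
              x$mnf, x$mnp, x$fr, x$psr))
  invisible(x)
}

#' Windowed fatigue features over a session
#'
#' Slides an analysis window over the record and extracts the feature
#' vector from each window's periodogram, producing the time course the
#' fatigue classifier consumes.
#'
#' @inheritParams extract_features
#' @return Data frame with columns `window_start_s`, `mnf_hz`, `mnp`,
#'   `fr`, `psr`.
#' @export
windowed_features <- function(rec, window_s = 1, overlap = 0.5,
                              bands = fr_bands(), psr_halfwidth_hz = 10) {
  stopifnot(inherits(rec, "emg_record"))
  n <- round(window_s * rec$fs)
  if (length(rec$samples) < n) {
    stop("windowed_features: record shorter than one window", call. = FALSE)
  }
  hop <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, length(rec$samples) - n + 1L, by = hop)
  rows <- lapply(starts, function(s) {
    sub <- emg_record(rec$samples[s:(s + n - 1L)], rec$fs, rec$channel_id)
    fv <- tryCatch(
      extract_features(sub, window_s = window_s, overlap = 0,
                       bands = bands, psr_halfwidth_hz = psr_halfwidth_hz),
      error = function(e) {
        stop(sprintf("windowed_features: window %d (t=%.3f s): %s",
                     which(starts == s), (s - 1) / rec$fs,
                     conditionMessage(e)), call. = FALSE)
      })
    data.frame(window_start_s = (s - 1) / rec$fs,
               mnf_hz = fv$mnf, mnp = fv$mnp, fr = fv$fr, psr = fv$psr)
  })
  do.call(rbind, rows)
}

#' Optional EMG preprocessing: band-pass and mains notch
#'
#' Zero-phase 4th-order Butterworth band-pass plus an optional narrow
#' band-stop around the mains frequency. Off by default throughout the
#' package; intended for recorded (not synthetic) EMG.
#'
#' @param rec an [emg_record()].
#' @param bandpass length-2 band edges (Hz); default `c(20, 450)`.
#' @param notch_hz mains frequency to suppress, or `NULL` to skip.
#' @param notch_halfwidth_hz half-width of the band-stop (Hz).
#' @return A filtered [emg_record()].
#' @export
emg_preprocess <- function(rec, bandpass = c(20, 450), notch_hz = NULL,
                           notch_halfwidth_hz = 1) {
  stopifnot(inherits(rec, "emg_record"))
  nyq <- rec$fs / 2
  x <- rec$samples
  if (!is.null(bandpass)) {
    bf <- signal::butter(4, pmin(bandpass / nyq, 0.999), type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  if (!is.null(notch_hz)) {
    edges <- c(notch_hz - notch_halfwidth_hz, notch_hz + notch_halfwidth_hz)
    nf <- signal::butter(2, pmin(edges / nyq, 0.999), type = "stop")
    x <- signal::filtfilt(nf, x)
  }
  emg_record(x, rec$fs, rec$channel_id)
}
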