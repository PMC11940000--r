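#' Configuration for the sEMG conditioning chain
#'
#' The chain is: band-pass (25--500 Hz, order-4 Butterworth) -> full-wave
#' rectification -> low-pass (8 Hz, order-4 Butterworth) -> Gaussian smoothing
#' -> per-subject MVC normalization. Filters are applied zero-phase
#' (forward-backward) by default, so the envelope is not delayed.
#'
#' @param bandpass_low_hz Band-pass low edge in Hz (default 25).
#' @param bandpass_high_hz Band-pass high edge in Hz (default 500). When this
#'   reaches or exceeds the Nyquist frequency at apply time, the design edge
#'   is capped at 0.99 x Nyquist with a warning.
#' @param bandpass_order Butterworth design order of the band-pass (default 4).
#' @param lowpass_cut_hz Low-pass cutoff in Hz (default 8).
#' @param lowpass_order Butterworth design order of the low-pass (default 4).
#' @param gaussian_sigma_s Gaussian smoothing kernel standard deviation in
#'   seconds (default 0.05). The kernel is truncated at +/- 4 sigma,
#'   renormalized to unit sum, and applied with reflection padding.
#' @param zero_phase Apply filters forward-backward (default `TRUE`).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(bandpass_low_hz = 25, bandpass_high_hz = 500,
                              bandpass_order = 4, lowpass_cut_hz = 8,
                              lowpass_order = 4, gaussian_sigma_s = 0.05,
                              zero_phase = TRUE) {
  if (bandpass_low_hz <= 0 || bandpass_low_hz >= bandpass_high_hz) {
    stop("require 0 < bandpass_low_hz < bandpass_high_hz", call. = FALSE)
  }
  if (gaussian_sigma_s <= 0) stop("gaussian_sigma_s must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "preprocess_config")
}

# Apply an IIR filter per channel, zero-phase (forward-backward) or one-way.
.apply_filter <- function(filt, x, zero_phase) {
  out <- .iir_mat_cpp(as.numeric(filt$b), as.numeric(filt$a), x, zero_phase)
  dimnames(out) <- dimnames(x)
  out
}

# Band edge capped below Nyquist; warns when the configured edge is infeasible.
.bandpass_edges <- function(fs, config) {
  nyq <- fs / 2
  high <- config$bandpass_high_hz
  if (high >= nyq) {
    high <- 0.99 * nyq
    warning(sprintf(
      "band-pass high edge %g Hz is at or above Nyquist (%g Hz); capping design edge at %g Hz",
      config$bandpass_high_hz, nyq, high), call. = FALSE)
  }
  c(config$bandpass_low_hz, high)
}

#' Band-pass filter a multichannel EMG matrix
#'
#' Order-`bandpass_order` Butterworth band-pass between the configured edges,
#' applied per channel (zero-phase by default). Rejects DC and out-of-band
#' energy.
#'
#' @param x Numeric matrix, channels x frames.
#' @param fs Sampling frequency in Hz; must exceed twice the low edge.
#' @param config A [preprocess_config()].
#' @return Matrix of the same shape.
#' @export
bandpass <- function(x, fs, config = preprocess_config()) {
  if (fs <= 2 * config$bandpass_low_hz) {
    stop(sprintf("fs = %g Hz too low for a %g Hz band-pass low edge", fs,
                 config$bandpass_low_hz), call. = FALSE)
  }
  edges <- .bandpass_edges(fs, config)
  filt <- signal::butter(config$bandpass_order, edges / (fs / 2), type = "pass")
  .apply_filter(filt, x, config$zero_phase)
}

#' Full-wave rectification
#'
#' @param x Numeric matrix.
#' @return `abs(x)`, same shape.
#' @export
rectify <- function(x) abs(x)

#' Low-pass filter (envelope extraction)
#'
#' Order-`lowpass_order` Butterworth low-pass at `lowpass_cut_hz`, per channel.
#'
#' @inheritParams bandpass
#' @return Matrix of the same shape.
#' @export
lowpass <- function(x, fs, config = preprocess_config()) {
  if (fs <= 2 * config$lowpass_cut_hz) {
    stop(sprintf("fs = %g Hz too low for a %g Hz low-pass cutoff", fs,
                 config$lowpass_cut_hz), call. = FALSE)
  }
  filt <- signal::butter(config$lowpass_order, config$lowpass_cut_hz / (fs / 2),
                         type = "low")
  .apply_filter(filt, x, config$zero_phase)
}

# Unit-sum Gaussian kernel truncated at +/- 4 sigma (sigma in frames).
.gaussian_kernel <- function(sigma_frames) {
  half <- max(1L, ceiling(4 * sigma_frames))
  k <- stats::dnorm(-half:half, sd = sigma_frames)
  k / sum(k)
}

#' Gaussian smoothing of a multichannel envelope
#'
#' Convolution with a unit-sum Gaussian kernel (sd `sigma_s` seconds,
#' truncated at +/- 4 sigma), edges handled by reflection padding. Non-negative
#' input gives non-negative output and constants are preserved exactly.
#'
#' @param x Numeric matrix, channels x frames.
#' @param fs Sampling frequency in Hz.
#' @param sigma_s Kernel standard deviation in seconds (> 0).
#' @return Matrix of the same shape.
#' @export
gaussian_smooth <- function(x, fs, sigma_s = 0.05) {
  if (sigma_s <= 0) stop("sigma_s must be > 0", call. = FALSE)
  k <- .gaussian_kernel(sigma_s * fs)
  out <- .fir_reflect_cpp(x, k)
  dimnames(out) <- dimnames(x)
  out
}

# The conditioning chain without normalization.
.condition <- function(emg, fs, config) {
  x <- bandpass(emg, fs, config)
  x <- rectify(x)
  x <- lowpass(x, fs, config)
  gaussian_smooth(x, fs, config$gaussian_sigma_s)
}

#' Compute a subject's MVC normalization profile
#'
#' Per channel, the maximum of the conditioned (band-passed, rectified,
#' low-passed, smoothed) amplitude over the subject's MVC movements and all of
#' the subject's recordings, so numerator and denominator of the later
#' normalization are commensurate.
#'
#' @param subject_recordings List of [raw_recording()] for one subject.
#' @param mvc_movements Optional list of channels x frames matrices recorded
#'   during the MVC protocol (same sampling rate as the recordings).
#' @param config A [preprocess_config()].
#' @return An [mvc_profile()].
#' @export
compute_mvc_profile <- function(subject_recordings, mvc_movements = list(),
                                config = preprocess_config()) {
  if (!length(subject_recordings) && !length(mvc_movements)) {
    stop("need at least one recording or MVC movement", call. = FALSE)
  }
  participant <- if (length(subject_recordings)) {
    subject_recordings[[1]]$participant
  } else NA_integer_
  cmax <- rep(0, 7)
  for (rec in subject_recordings) {
    env <- .condition(rec$emg, rec$sampling_rate_hz, config)
    cmax <- pmax(cmax, apply(env, 1, max))
  }
  if (length(mvc_movements)) {
    fs <- if (length(subject_recordings)) subject_recordings[[1]]$sampling_rate_hz else
      stop("MVC movements need a recording to supply the sampling rate", call. = FALSE)
    for (m in mvc_movements) {
      env <- .condition(m, fs, config)
      cmax <- pmax(cmax, apply(env, 1, max))
    }
  }
  if (any(cmax <= 0)) {
    stop("channel(s) ", paste(which(cmax <= 0), collapse = ", "),
         " have zero maximum amplitude; MVC normalization undefined", call. = FALSE)
  }
  mvc_profile(participant, cmax)
}

#' Normalize a conditioned EMG matrix by an MVC profile
#'
#' Divides channel `c` by `profile$channel_max[c]`. With a profile computed
#' including the recording itself, the output maximum is bounded by 1.
#'
#' @param x Numeric matrix, channels x frames (conditioned envelope).
#' @param profile An [mvc_profile()] with strictly positive denominators.
#' @return Matrix of the same shape, dimensionless.
#' @export
normalize_by_mvc <- function(x, profile) {
  if (any(profile$channel_max <= 0)) {
    stop("MVC profile contains a non-positive denominator", call. = FALSE)
  }
  x / profile$channel_max
}

#' Run the full conditioning chain on one recording
#'
#' Band-pass -> rectify -> low-pass -> Gaussian smoothing -> MVC
#' normalization, in that exact order. Shape-preserving.
#'
#' @param recording A [raw_recording()].
#' @param profile The subject's [mvc_profile()] on the conditioned scale (see
#'   [compute_mvc_profile()]).
#' @param config A [preprocess_config()].
#' @return The recording with `emg` replaced by the normalized envelope.
#' @export
preprocess <- function(recording, profile, config = preprocess_config()) {
  env <- .condition(recording$emg, recording$sampling_rate_hz, config)
  recording$emg <- normalize_by_mvc(env, profile)
  recording
}
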