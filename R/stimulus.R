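#' Audio clip container
#'
#' A light container for audio in linear amplitude units: `samples` is a
#' numeric vector (mono) or an n-by-2 matrix (stereo / dichotic), `sample_rate`
#' is in Hz.
#'
#' @param samples numeric vector or 2-column numeric matrix of amplitudes.
#' @param sample_rate sampling rate in Hz (> 0).
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stop_("samples must be numeric")
  if (is.matrix(samples) && ncol(samples) != 2L) stop_("matrix samples must have 2 columns")
  if (!all(is.finite(samples))) stop_("samples must be finite")
  assert_scalar_number(sample_rate, "sample_rate")
  if (sample_rate <= 0) stop_("sample_rate must be > 0")
  structure(list(samples = samples, sample_rate = sample_rate), class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  n <- NROW(x$samples)
  ch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  cat(sprintf("<audio_clip> %d samples, %d channel(s), %g Hz (%.3f s)\n",
              n, ch, x$sample_rate, n / x$sample_rate))
  invisible(x)
}

n_samples <- function(clip) NROW(clip$samples)

#' Mean-square power of a clip
#'
#' Average of the squared amplitudes over all samples (and channels), in
#' linear units squared. This is the reference power used to scale the
#' masking noise to a target signal-to-noise ratio.
#'
#' @param clip an [audio_clip()].
#' @return Mean-square power, a positive scalar.
#' @export
measure_power <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  if (n_samples(clip) == 0L) stop_("cannot measure the power of an empty clip")
  p <- mean(clip$samples^2)
  if (p == 0) stop_("clip is silent (all-zero); power-based SNR scaling is undefined")
  p
}

#' Embed a clip in Gaussian white noise at a target SNR
#'
#' Measures the clip's mean-square power P and adds zero-mean Gaussian white
#' noise with population variance `P / 10^(snr_db/10)`, the simultaneous-
#' masking construction used for the speech-in-noise stimuli (default 10 dB).
#' The realized sample variance of a finite noise draw deviates slightly
#' from the population target; use [realized_snr()] to quantify it.
#'
#' @param clip an [audio_clip()]; must not be silent.
#' @param snr_db target signal-to-noise ratio in dB (default 10).
#' @param noise_seed integer seed for the noise realization.
#' @return A new `audio_clip` of the same length, rate and channel layout.
#' @export
mix_noise_at_snr <- function(clip, snr_db = 10, noise_seed = 1L) {
  assert_scalar_number(snr_db, "snr_db")
  p <- measure_power(clip)
  sigma <- sqrt(p / 10^(snr_db / 10))
  noise <- with_seed(noise_seed, rnorm(length(clip$samples), sd = sigma))
  out <- clip$samples + noise
  if (is.matrix(clip$samples)) dim(out) <- dim(clip$samples)
  audio_clip(out, clip$sample_rate)
}

#' Realized SNR of a noisy clip against its clean original
#'
#' Recovers the injected noise as `noisy - signal` and returns
#' `10 * log10(P_signal / P_noise)` with both powers measured from the
#' waveforms. Returns `Inf` when the residual noise is exactly zero.
#'
#' @param signal the clean [audio_clip()].
#' @param noisy the noise-embedded clip; same length and rate.
#' @return SNR in dB.
#' @export
realized_snr <- function(signal, noisy) {
  stopifnot(inherits(signal, "audio_clip"), inherits(noisy, "audio_clip"))
  if (length(signal$samples) != length(noisy$samples)) {
    stop_("signal and noisy clips differ in length (%d vs %d samples)",
          n_samples(signal), n_samples(noisy))
  }
  if (signal$sample_rate != noisy$sample_rate) stop_("sample rates differ")
  p_sig <- measure_power(signal)
  p_noise <- mean((noisy$samples - signal$samples)^2)
  if (p_noise == 0) return(Inf)
  10 * log10(p_sig / p_noise)
}

#' Trim a clip to a fixed duration
#'
#' Keeps the first `floor(duration_ms * rate / 1000)` samples, the
#' trimming applied to every masked stimulus (default 3,000 ms). Clips
#' shorter than the target are an error unless `pad = TRUE`, in which case
#' zeros are appended at the tail.
#'
#' @param clip an [audio_clip()].
#' @param duration_ms target duration in milliseconds (default 3000).
#' @param pad pad short clips with trailing zeros instead of erroring.
#' @return The trimmed (or padded) `audio_clip`.
#' @export
trim_clip <- function(clip, duration_ms = 3000, pad = FALSE) {
  stopifnot(inherits(clip, "audio_clip"))
  assert_scalar_number(duration_ms, "duration_ms")
  n_target <- floor(duration_ms * clip$sample_rate / 1000)
  n <- n_samples(clip)
  if (n < n_target && !pad) {
    stop_("clip is %d samples but %d are required; set pad = TRUE to zero-pad", n, n_target)
  }
  take <- function(ch) {
    out <- ch[seq_len(min(n, n_target))]
    if (length(out) < n_target) out <- c(out, numeric(n_target - length(out)))
    out
  }
  s <- if (is.matrix(clip$samples)) cbind(take(clip$samples[, 1]), take(clip$samples[, 2]))
       else take(clip$samples)
  audio_clip(s, clip$sample_rate)
}

#' Dichotic headphone-screening stimuli
#'
#' Generates the two classic stereo probes used to verify true binaural
#' headphone presentation. `"antiphase_tone"` is a pure tone whose right
#' channel is the exact polarity inversion of the left, so the channels
#' cancel over a loudspeaker but not over headphones. `"huggins_pitch"` is
#' one white-noise realization sent to both ears except for a narrow band
#' around `freq_hz` whose phase is shifted by pi in the right channel; the
#' faint pitch at `freq_hz` is audible only dichotically.
#'
#' @param kind `"antiphase_tone"` or `"huggins_pitch"`.
#' @param freq_hz tone frequency or Huggins band center in Hz (defaults:
#'   200 Hz tone, 600 Hz band); must be below the Nyquist frequency.
#' @param band_rel half-width of the phase-shifted band as a fraction of
#'   `freq_hz` (default 0.06).
#' @param duration_ms stimulus duration (default 1000 ms).
#' @param sample_rate sampling rate in Hz (default 44100).
#' @param amplitude peak amplitude of the tone (ignored for Huggins).
#' @param seed noise seed for the Huggins stimulus.
#' @return A 2-channel [audio_clip()].
#' @export
make_screening_pair <- function(kind = c("antiphase_tone", "huggins_pitch"),
                                freq_hz = NULL, band_rel = 0.06,
                                duration_ms = 1000, sample_rate = 44100,
                                amplitude = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  freq_hz <- freq_hz %||% switch(kind, antiphase_tone = 200, huggins_pitch = 600)
  assert_scalar_number(freq_hz, "freq_hz")
  if (freq_hz <= 0 || freq_hz >= sample_rate / 2) {
    stop_("freq_hz (%g) must lie in (0, Nyquist = %g)", freq_hz, sample_rate / 2)
  }
  n <- floor(duration_ms * sample_rate / 1000)
  if (kind == "antiphase_tone") {
    t <- (seq_len(n) - 1) / sample_rate
    left <- amplitude * sin(2 * pi * freq_hz * t)
    return(audio_clip(cbind(left, -left), sample_rate))
  }
  # Huggins pitch: interaural phase shift of pi restricted to a narrow band
  left <- with_seed(seed, rnorm(n))
  spec <- fft(left)
  freqs <- (seq_len(n) - 1) * sample_rate / n
  lo <- freq_hz * (1 - band_rel)
  hi <- freq_hz * (1 + band_rel)
  band <- (freqs >= lo & freqs <= hi) | (freqs >= sample_rate - hi & freqs <= sample_rate - lo)
  spec_r <- spec
  spec_r[band] <- -spec_r[band]  # phase shift of pi, magnitude untouched
  right <- Re(fft(spec_r, inverse = TRUE)) / n
  audio_clip(cbind(left, right), sample_rate)
}

#' Prepare a batch of speech-in-noise stimuli
#'
#' For every catalog row with a readable WAV file: read the clip, embed it
#' in white noise at `snr_db` (noise seed derived per stimulus from the
#' master seed), trim to `duration_ms`, and write the result to `out_dir`.
#' Returns a manifest with the per-file realized SNR.
#'
#' @param catalog a catalog data frame with a `wav_path` column.
#' @param out_dir output directory (created if needed).
#' @param snr_db target SNR in dB (default 10).
#' @param duration_ms trim duration (default 3000 ms).
#' @param seed master seed for the noise streams.
#' @param pad zero-pad clips shorter than `duration_ms`.
#' @return A manifest data frame: `stimulus_id`, `out_path`, `realized_snr_db`.
#' @export
prepare_stimuli <- function(catalog, out_dir, snr_db = 10, duration_ms = 3000,
                            seed = 1L, pad = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    src <- catalog$wav_path[i]
    if (is.na(src) || !file.exists(src)) {
      stop_("no WAV file for stimulus %s (%s)", catalog$stimulus_id[i], src)
    }
    clip <- read_wav(src)
    noisy <- mix_noise_at_snr(clip, snr_db,
                              noise_seed = derive_seed(seed, "noise", catalog$stimulus_id[i]))
    trimmed <- trim_clip(noisy, duration_ms, pad = pad)
    out_path <- file.path(out_dir, paste0(catalog$stimulus_id[i], ".wav"))
    write_wav(trimmed, out_path)
    snr <- realized_snr(trim_clip(clip, duration_ms, pad = pad), trimmed)
    data.frame(stimulus_id = catalog$stimulus_id[i], out_path = out_path,
               realized_snr_db = snr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
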