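#' Default lever-click waveform template
#'
#' A short broadband transient modelling the acoustic fingerprint of a
#' single lever depression: an exponentially decaying sinusoid (3 ms
#' decay, 4 kHz centre frequency by default) with an instantaneous attack.
#'
#' @param sample_rate_hz Sample rate.
#' @param dur_s Template duration in seconds.
#' @param freq_hz Centre frequency.
#' @param decay_s Exponential amplitude decay time constant.
#' @return Numeric amplitude vector in `[-1, 1]`.
#' @export
click_template <- function(sample_rate_hz = 44100, dur_s = 0.008,
                           freq_hz = 4000, decay_s = 0.003) {
  t <- seq(0, dur_s, by = 1 / sample_rate_hz)
  exp(-t / decay_s) * sin(2 * pi * freq_hz * t)
}

#' Synthesise session audio with press clicks at known times
#'
#' Builds a mono audio trace containing a click at each press time over
#' Gaussian background noise. Optional lever-bounce artefacts insert a
#' reduced-amplitude copy of the click 2–5 ms after each true onset, which
#' the detector must reject. The true onset list is carried on the trace
#' for validation.
#'
#' @param press_times_s Sorted press onset times, seconds.
#' @param duration_s Trace duration; defaults to last press + 0.5 s.
#' @param template Click waveform (see [click_template()]).
#' @param click_amp Peak click amplitude.
#' @param noise_rms RMS of the Gaussian background noise.
#' @param bounce If `TRUE`, add one bounce artefact per press.
#' @param bounce_amp Relative amplitude of bounce artefacts.
#' @param sample_rate_hz Sample rate (>= 8000).
#' @param seed Integer seed; the trace is deterministic given the seed.
#' @return An `audio_trace` list: `samples`, `sample_rate_hz`,
#'   `truth_onsets_s`.
#' @export
synthesize_session_audio <- function(press_times_s, duration_s = NULL,
                                     template = NULL, click_amp = 0.8,
                                     noise_rms = 0.02, bounce = FALSE,
                                     bounce_amp = 0.4,
                                     sample_rate_hz = 44100, seed = 1L) {
  if (is.unsorted(press_times_s)) stop("press_times_s must be sorted")
  if (sample_rate_hz < 8000) stop("sample_rate_hz must be >= 8000")
  if (is.null(template)) template <- click_template(sample_rate_hz)
  if (is.null(duration_s))
    duration_s <- (if (length(press_times_s)) max(press_times_s) else 0) + 0.5
  n <- ceiling(duration_s * sample_rate_hz)
  with_seed(seed, {
    x <- stats::rnorm(n, sd = noise_rms)
    place <- function(t0, amp) {
      i0 <- round(t0 * sample_rate_hz) + 1
      idx <- i0:min(n, i0 + length(template) - 1)
      if (length(idx) > 0 && idx[1] <= n)
        x[idx] <<- x[idx] + amp * template[seq_along(idx)]
    }
    for (t0 in press_times_s) place(t0, click_amp)
    if (bounce) {
      lag <- stats::runif(length(press_times_s), 0.002, 0.005)
      for (k in seq_along(press_times_s))
        place(press_times_s[k] + lag[k], click_amp * bounce_amp)
    }
    structure(list(samples = pmax(-1, pmin(1, x)),
                   sample_rate_hz = sample_rate_hz,
                   truth_onsets_s = press_times_s),
              class = "audio_trace")
  })
}

#' Short-time magnitude spectrogram
#'
#' Frames the signal, applies a window, and returns the magnitude of the
#' discrete Fourier transform of each frame (non-negative frequencies).
#' With a rectangular window and non-overlapping frames the squared
#' magnitudes conserve total signal energy (Parseval).
#'
#' @param trace An `audio_trace` (or plain numeric vector with
#'   `sample_rate_hz` supplied).
#' @param window_s Frame length in seconds.
#' @param hop_s Hop between frame starts, seconds (`<= window_s`).
#' @param window `"hann"` or `"rect"`.
#' @param sample_rate_hz Sample rate when `trace` is a bare vector.
#' @return List with `time_s` (frame centres), `freq_hz`, and `magnitude`
#'   (frequency x time matrix).
#' @export
spectrogram <- function(trace, window_s = 0.01, hop_s = 0.005,
                        window = c("hann", "rect"), sample_rate_hz = NULL) {
  window <- match.arg(window)
  if (inherits(trace, "audio_trace")) {
    x <- trace$samples; sr <- trace$sample_rate_hz
  } else {
    x <- trace
    sr <- sample_rate_hz
    if (is.null(sr)) stop("sample_rate_hz needed for a bare vector")
  }
  nwin <- max(2, round(window_s * sr))
  nhop <- max(1, round(hop_s * sr))
  if (nhop > nwin) stop("hop_s must not exceed window_s")
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / nwin) else rep(1, nwin)
  starts <- seq(1, length(x) - nwin + 1, by = nhop)
  if (length(starts) == 0) stop("trace shorter than one window")
  nf <- floor(nwin / 2) + 1
  mag <- vapply(starts, function(s) {
    Mod(stats::fft(x[s:(s + nwin - 1)] * w))[1:nf]
  }, numeric(nf))
  list(time_s = (starts - 1 + nwin / 2) / sr,
       freq_hz = (0:(nf - 1)) * sr / nwin,
       magnitude = mag)
}

# Band-limited smoothed envelope used by the onset detector.
band_envelope <- function(x, sr, band_hz, smooth_s = 5e-4) {
  ny <- sr / 2
  if (band_hz[1] <= 0 || band_hz[2] >= ny || band_hz[1] >= band_hz[2])
    stop("band must lie strictly inside (0, Nyquist)")
  b <- signal::butter(4, band_hz / ny, type = "pass")
  y <- signal::filtfilt(b, x)
  k <- max(1, round(smooth_s * sr))
  as.numeric(stats::filter(abs(y), rep(1 / k, k), sides = 2, circular = TRUE))
}

#' Detect lever-press onsets in session audio
#'
#' Computes a band-limited energy envelope (zero-phase Butterworth
#' band-pass, rectified and smoothed), thresholds it adaptively at the
#' envelope median plus `k_mad` robust SDs (MAD-based), and reports one
#' onset per supra-threshold burst. A refractory window after each onset
#' suppresses lever-bounce artefacts, which trail the true strike by a few
#' milliseconds. Each onset is placed at the envelope's rise through the
#' threshold; its score is the envelope peak within the refractory window.
#'
#' @param trace An `audio_trace`.
#' @param band_hz Length-2 pass band in Hz (must lie within Nyquist).
#' @param k_mad Threshold height in MADs above the median (default 6).
#' @param threshold Absolute envelope threshold overriding the adaptive
#'   rule, or `NULL`.
#' @param refractory_s Minimum onset separation, seconds (default 0.02).
#' @return Data frame with `time_s` (onset) and `score`, onsets strictly
#'   increasing.
#' @export
detect_press_onsets <- function(trace, band_hz = c(2000, 6000), k_mad = 6,
                                threshold = NULL, refractory_s = 0.02) {
  stopifnot(inherits(trace, "audio_trace"))
  sr <- trace$sample_rate_hz
  env <- band_envelope(trace$samples, sr, band_hz)
  thr <- if (is.null(threshold))
    stats::median(env) + k_mad * stats::mad(env) else threshold
  above <- env > thr
  rises <- which(above & !c(FALSE, above[-length(above)]))
  if (length(rises) == 0)
    return(data.frame(time_s = numeric(0), score = numeric(0)))
  nref <- round(refractory_s * sr)
  keep <- numeric(0)
  last <- -Inf
  for (r in rises) {
    if (r - last > nref) { keep <- c(keep, r); last <- r }
  }
  score <- vapply(keep, function(r)
    max(env[r:min(length(env), r + nref)]), 0)
  data.frame(time_s = (keep - 1) / sr, score = score)
}

#' Inter-press intervals and speed of a press burst
#'
#' @param onsets_s Onset times in seconds (>= 2), or the data frame from
#'   [detect_press_onsets()].
#' @return List with `ipis_s` (successive differences) and `speed_pps`
#'   (`(n - 1) / (t_last - t_first)` presses per second).
#' @export
burst_ipis <- function(onsets_s) {
  if (is.data.frame(onsets_s)) onsets_s <- onsets_s$time_s
  if (length(onsets_s) < 2) stop("need at least 2 onsets")
  list(ipis_s = diff(onsets_s),
       speed_pps = (length(onsets_s) - 1) /
         (onsets_s[length(onsets_s)] - onsets_s[1]))
}

#' Quantisation bias of timestamped inter-press intervals
#'
#' Timestamp-based recording floors event times to a grid (10 ms in the
#' apparatus), which biases short inter-press intervals downwards and
#' piles very short intervals onto the first grid steps. Compares the
#' distribution of true IPIs with their floor-quantised counterparts at
#' grid resolution.
#'
#' @param true_ipis_s True interval values, seconds.
#' @param grid_s Grid step in seconds (default 0.01).
#' @param max_s Histogram upper limit (default: cover the data).
#' @return List with `histogram` (data frame `bin_left_s`, `count_true`,
#'   `count_quantised`), `pileup_quantised` (quantised IPIs landing at 0
#'   or 1 grid steps) and `pileup_true` (true IPIs below 2 grid steps).
#' @export
quantization_bias <- function(true_ipis_s, grid_s = 0.01, max_s = NULL) {
  if (grid_s <= 0) stop("grid_s must be > 0")
  q <- floor(true_ipis_s / grid_s) * grid_s
  if (is.null(max_s)) max_s <- max(true_ipis_s, grid_s) + grid_s
  edges <- seq(0, max_s + grid_s, by = grid_s)
  h <- function(v) {
    idx <- findInterval(v, edges, rightmost.closed = FALSE)
    tabulate(idx[idx >= 1 & idx <= length(edges) - 1],
             nbins = length(edges) - 1)
  }
  list(histogram = data.frame(bin_left_s = edges[-length(edges)],
                              count_true = h(true_ipis_s),
                              count_quantised = h(q)),
       pileup_quantised = sum(q < 2 * grid_s - 1e-12),
       pileup_true = sum(true_ipis_s < 2 * grid_s))
}

#' Write a mono PCM-16 WAV file
#'
#' Minimal canonical RIFF/WAVE writer (16-bit PCM, one channel). The
#' installed stack provides no WAV reader, so the 44-byte canonical header
#' is written directly.
#'
#' @param trace An `audio_trace` or numeric vector in `[-1, 1]`.
#' @param path Output path.
#' @param sample_rate_hz Sample rate when `trace` is a bare vector.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(trace, path, sample_rate_hz = NULL) {
  if (inherits(trace, "audio_trace")) {
    x <- trace$samples; sr <- trace$sample_rate_hz
  } else {
    x <- trace; sr <- sample_rate_hz
    if (is.null(sr)) stop("sample_rate_hz needed for a bare vector")
  }
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(pcm)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # fmt chunk size
  writeBin(c(1L, 1L), con, size = 2, endian = "little")   # PCM, mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")  # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(pcm)), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM-16 WAV file
#'
#' @param path Path to a WAV file written by [write_wav()] or any
#'   canonical 16-bit PCM mono WAV.
#' @return An `audio_trace` (without truth onsets).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sr <- NULL; bits <- NULL; nchan <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      nchan <- fmt[2]
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      bits <- ba_bits[2]
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      samples <- readBin(con, integer(), n = sz / 2, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(sr) || is.null(samples)) stop("incomplete WAV file: ", path)
  if (!identical(nchan, 1L) || !identical(bits, 16L))
    stop("only 16-bit PCM mono WAV is supported")
  structure(list(samples = samples / 32767, sample_rate_hz = sr,
                 truth_onsets_s = NULL), class = "audio_trace")
}
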