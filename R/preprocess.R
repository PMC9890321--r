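#' Spectrogram preprocessing configuration
#'
#' Parameters for turning an annotated vocal unit's audio into the
#' standardised 64x64 log-Mel spectrogram used for latent-space projection:
#' a zero-phase Butterworth band-pass (0.4-8 kHz, the band holding most
#' spectral content of the repertoire), a short-time Fourier transform, a Mel
#' filterbank over the same band, logarithmic amplitude compression, and
#' log-rescaling of the time axis before zero-padding.
#'
#' @param band_low,band_high Band-pass edges in Hz.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective roll-off is doubled).
#' @param window_length STFT window length in samples (Hann window).
#' @param hop_length STFT hop in samples.
#' @param n_mel Number of Mel bands (the output frequency dimension).
#' @param out_bins Output time dimension.
#' @param log_floor Amplitude floor for the `log1p(x / log_floor)`
#'   compression, on the linear STFT magnitude scale.
#' @param time_ref Small-duration anchor tau (seconds) of the log time map:
#'   a unit of duration d occupies `64 * log(1 + d/tau) / log(1 + D/tau)`
#'   time columns, D being the longest duration in the dataset.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 400, band_high = 8000,
                              filter_order = 5, window_length = 512,
                              hop_length = 128, n_mel = 64, out_bins = 64,
                              log_floor = 1e-2, time_ref = 0.01) {
  if (band_low >= band_high) stop("config error: band_low must be < band_high")
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = filter_order, window_length = window_length,
                 hop_length = hop_length, n_mel = n_mel, out_bins = out_bins,
                 log_floor = log_floor, time_ref = time_ref),
            class = "preprocess_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param x Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param cfg A [preprocess_config()].
#' @return Filtered waveform of the same length.
#' @export
bandpass <- function(x, sample_rate, cfg = preprocess_config()) {
  nyq <- sample_rate / 2
  if (cfg$band_high >= nyq)
    stop("config error: band_high (", cfg$band_high,
         " Hz) must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$band_low, cfg$band_high) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# n_mel x n_fft_bins triangular filterbank over [band_low, band_high];
# bin frequencies follow the one-sided STFT convention (DC included,
# Nyquist excluded) of signal::specgram
mel_filterbank <- function(cfg, sample_rate) {
  n_bins <- cfg$window_length %/% 2
  freqs <- (seq_len(n_bins) - 1) * sample_rate / cfg$window_length
  mel_pts <- mel_to_hz(seq(hz_to_mel(cfg$band_low), hz_to_mel(cfg$band_high),
                           length.out = cfg$n_mel + 2))
  fb <- matrix(0, cfg$n_mel, n_bins)
  for (m in seq_len(cfg$n_mel)) {
    lo <- mel_pts[m]; ctr <- mel_pts[m + 1]; hi <- mel_pts[m + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# center frequencies of the Mel bands (Hz)
mel_centers <- function(cfg) {
  mel_to_hz(seq(hz_to_mel(cfg$band_low), hz_to_mel(cfg$band_high),
                length.out = cfg$n_mel + 2))[2:(cfg$n_mel + 1)]
}

#' Standardised log-Mel spectrogram of one vocal unit
#'
#' Cuts the unit from the (already band-passed) recording, computes the
#' one-sided STFT magnitude, applies the Mel filterbank, compresses
#' amplitudes with `log1p(x / log_floor)`, rescales the time axis so the
#' displayed width is proportional to the log of the unit's duration relative
#' to `ref_duration` (the longest unit of the dataset spans all columns), and
#' zero-pads on the right to `n_mel x out_bins`.
#'
#' @param x Band-passed waveform of the whole recording.
#' @param sample_rate Sampling rate in Hz.
#' @param start,end Unit boundaries in seconds.
#' @param cfg A [preprocess_config()].
#' @param ref_duration Anchor duration D in seconds (defaults to the unit's
#'   own duration, which then fills all time columns).
#' @return A 64x64 non-negative matrix (frequency x time; row 1 = lowest
#'   Mel band), with attributes `duration` and `support` (occupied columns).
#' @export
unit_spectrogram <- function(x, sample_rate, start, end,
                             cfg = preprocess_config(),
                             ref_duration = end - start) {
  i0 <- max(1L, floor(start * sample_rate) + 1L)
  i1 <- min(length(x), ceiling(end * sample_rate))
  seg <- x[i0:i1]
  if (length(seg) < cfg$window_length)
    stop("degenerate unit: ", length(seg), " samples is shorter than one ",
         cfg$window_length, "-sample analysis window")
  sp <- signal::specgram(seg, n = cfg$window_length, Fs = sample_rate,
                         window = signal::hanning(cfg$window_length),
                         overlap = cfg$window_length - cfg$hop_length)
  mag <- abs(sp$S)                       # n_bins x frames
  mel <- mel_filterbank(cfg, sample_rate) %*% mag
  mel <- log1p(mel / cfg$log_floor)

  dur <- end - start
  w <- time_support_bins(dur, ref_duration, cfg)
  out <- matrix(0, cfg$n_mel, cfg$out_bins)
  out[, seq_len(w)] <- resample_columns(mel, w)
  attr(out, "duration") <- dur
  attr(out, "support") <- w
  out
}

# number of time columns for a unit of duration d (monotone in d;
# d == ref fills all columns)
time_support_bins <- function(d, ref, cfg) {
  if (ref <= 0) return(1L)
  d <- min(d, ref)
  max(1L, as.integer(round(cfg$out_bins * log1p(d / cfg$time_ref) /
                             log1p(ref / cfg$time_ref))))
}

# linear interpolation of matrix columns to a new width
resample_columns <- function(m, w) {
  tc <- ncol(m)
  if (tc == w) return(m)
  if (tc == 1) return(m[, rep(1, w), drop = FALSE])
  at <- seq(1, tc, length.out = w)
  t(apply(m, 1, function(row) stats::approx(seq_len(tc), row, xout = at)$y))
}

#' Build a flattened spectrogram dataset at one combinatorial level
#'
#' For every unit at `level` in every annotated recording, computes the
#' standardised spectrogram (see [unit_spectrogram()]) and flattens it into a
#' 4096-component feature row, joined with the predictor labels used in
#' cluster evaluation: hand label (segment class, or simplified call label),
#' call composition group, positional category (segment level), caller
#' identity, group identity, study site and sex. Units shorter than one
#' analysis window are skipped with a warning.
#'
#' @param ann_list List of [annotation_set()] objects.
#' @param audio Either a named list of waveforms (names = recording ids) or a
#'   directory containing `<recording_id>.wav` files.
#' @param level `"segment"` or `"call"`.
#' @param cfg A [preprocess_config()].
#' @return Object of class `spectrogram_dataset`: list with `features`
#'   (n x 4096 matrix), `labels` (data frame), `level`, `ref_duration`,
#'   `config`.
#' @export
build_dataset <- function(ann_list, audio, level = c("segment", "call"),
                          cfg = preprocess_config()) {
  level <- match.arg(level)
  if (inherits(ann_list, "annotation_set")) ann_list <- list(ann_list)
  if (!length(ann_list) || !sum(vapply(ann_list, function(a)
    nrow(if (level == "segment") a$segments else a$calls), integer(1)))) {
    warning("empty corpus: no units at level '", level, "'")
    return(structure(list(features = matrix(numeric(0), 0,
                                            cfg$n_mel * cfg$out_bins),
                          labels = empty_label_df(), level = level,
                          ref_duration = NA_real_, config = cfg),
                     class = "spectrogram_dataset"))
  }

  waves <- load_audio(ann_list, audio)
  for (id in names(waves))
    waves[[id]]$samples <- bandpass(waves[[id]]$samples,
                                    waves[[id]]$sample_rate, cfg)

  ref_duration <- max(unlist(lapply(ann_list, function(a) {
    df <- if (level == "segment") a$segments else a$calls
    if (nrow(df)) df$end - df$start else numeric(0)
  })))

  rows <- list(); labs <- list(); skipped <- 0L
  for (ann in ann_list) {
    id <- ann$meta$recording_id
    wav <- waves[[id]]
    df <- if (level == "segment") ann$segments else ann$calls
    ldf <- unit_label_df(ann, level)
    for (i in seq_len(nrow(df))) {
      m <- tryCatch(
        unit_spectrogram(wav$samples, wav$sample_rate, df$start[i], df$end[i],
                         cfg, ref_duration),
        error = function(e) e)
      if (inherits(m, "error")) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- as.numeric(m)
      ldf$duration[i] <- df$end[i] - df$start[i]
      labs[[length(labs) + 1L]] <- ldf[i, , drop = FALSE]
    }
  }
  if (skipped) warning(skipped, " degenerate unit(s) skipped at level '",
                       level, "'")
  labels <- do.call(rbind, labs)
  rownames(labels) <- NULL
  structure(list(features = do.call(rbind, rows), labels = labels,
                 level = level, ref_duration = ref_duration, config = cfg),
            class = "spectrogram_dataset")
}

empty_label_df <- function() {
  data.frame(unit_ref = character(0), label = character(0),
             call_group = character(0), position_category = character(0),
             individual = character(0), group = character(0),
             site = character(0), sex = character(0), duration = numeric(0),
             stringsAsFactors = FALSE)
}

unit_label_df <- function(ann, level) {
  df <- if (level == "segment") ann$segments else ann$calls
  n <- nrow(df)
  seg_seqs <- derive_sequences(ann, "segment")
  if (level == "segment") {
    label <- df$label
    parent <- containing_unit(ann$segments, ann$calls, ann$tol %||% 1e-3)
    call_group <- vapply(parent, function(ci) assign_call_group(seg_seqs[[ci]]),
                         character(1))
    poscat <- rep(NA_character_, n)
    for (cls in intersect(unique(label), c("LH", "NL", "DS", "SH"))) {
      pc <- assign_position_category(ann, cls)
      poscat[pc$segment] <- pc$category
    }
  } else {
    label <- vapply(seg_seqs, simplify_call_label, character(1))
    call_group <- vapply(seg_seqs, assign_call_group, character(1))
    poscat <- rep(NA_character_, n)
  }
  data.frame(unit_ref = sprintf("%s:%s:%03d", ann$meta$recording_id, level,
                                seq_len(n)),
             label = label, call_group = call_group,
             position_category = poscat,
             individual = ann$meta$individual_id, group = ann$meta$group_id,
             site = ann$meta$site, sex = ann$meta$sex,
             duration = rep(NA_real_, n), stringsAsFactors = FALSE)
}

load_audio <- function(ann_list, audio) {
  ids <- unique(vapply(ann_list, function(a) a$meta$recording_id,
                       character(1)))
  if (is.character(audio) && length(audio) == 1) {
    waves <- list()
    for (id in ids) {
      p <- file.path(audio, paste0(id, ".wav"))
      if (!file.exists(p))
        stop("I/O error: no audio file for recording '", id, "' (", p, ")")
      waves[[id]] <- read_wav(p)
    }
    waves
  } else {
    miss <- setdiff(ids, names(audio))
    if (length(miss))
      stop("I/O error: no audio supplied for recording(s): ",
           paste(miss, collapse = ", "))
    lapply(audio[ids], function(w) {
      if (is.list(w)) w else list(samples = w, sample_rate = 44100L)
    })
  }
}

#' @export
print.spectrogram_dataset <- function(x, ...) {
  cat(sprintf("<spectrogram_dataset> level %s: %d units x %d features\n",
              x$level, nrow(x$features), ncol(x$features)))
  invisible(x)
}
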