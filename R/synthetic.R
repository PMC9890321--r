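#' Default two-level transition structure of the synthetic generator
#'
#' The default segment-to-segment matrix encodes the strongly directional
#' within-call grammar of the repertoire (LH only ever to DS; NL mostly to
#' DS; DS mostly to SH; SH spread over all classes), and the call-group
#' matrix the between-call grammar over the three broad composition groups.
#'
#' @return A row-stochastic matrix.
#' @export
default_segment_transition <- function() {
  a <- c("DS", "LH", "NL", "SH")
  m <- matrix(0, 4, 4, dimnames = list(from = a, to = a))
  m["DS", ] <- c(DS = 0.07, LH = 0.18, NL = 0.00, SH = 0.75)
  m["LH", ] <- c(DS = 1.00, LH = 0.00, NL = 0.00, SH = 0.00)
  m["NL", ] <- c(DS = 0.80, LH = 0.00, NL = 0.00, SH = 0.20)
  m["SH", ] <- c(DS = 0.49, LH = 0.23, NL = 0.01, SH = 0.27)
  m
}

#' @rdname default_segment_transition
#' @export
default_call_group_transition <- function() {
  g <- c("other", "LH-containing", "lone-NL")
  m <- matrix(0, 3, 3, dimnames = list(from = g, to = g))
  m["other", ] <- c(0.34, 0.65, 0.01)
  m["LH-containing", ] <- c(0.67, 0.33, 0.00)
  m["lone-NL", ] <- c(1.00, 0.00, 0.00)
  m
}

default_acoustics <- function() {
  list(DS = list(type = "sweep", f_start = 4000, f_end = 1500,
                 dur_mean = 0.15, dur_sd = 0.03),
       LH = list(type = "tone", freq = 2200, dur_mean = 0.35, dur_sd = 0.05),
       SH = list(type = "tone", freq = 4200, dur_mean = 0.08, dur_sd = 0.015),
       NL = list(type = "noise", band = c(800, 2800),
                 dur_mean = 0.20, dur_sd = 0.04))
}

#' Specification of a synthetic two-level combinatorial corpus
#'
#' Defines the ground truth from which [sample_sequences()] draws a corpus:
#' a first-order segment chain forming calls, a first-order call-group chain
#' forming combinations, call and combination length distributions, the
#' three-scale silence regime (between-segment at most 0.025 s, between-call
#' well under the 0.5 s combination threshold, between-combination above
#' 1 s), and parametric per-class acoustics (down sweep, long tone, short
#' tone, band-limited noise) inside the 0.4-8 kHz analysis band. Defaults
#' mirror the field corpus the package is designed around: 222 combinations
#' from 23 individuals in 16 groups across 2 sites, calls of 1-7 segments,
#' combinations of 2-5 calls.
#'
#' @param n_combinations Number of combinations to generate.
#' @param n_individuals,n_groups Corpus composition; individuals are assigned
#'   round-robin to groups, groups split evenly over the two sites.
#' @param segment_transition Row-stochastic matrix over
#'   `{DS, LH, NL, SH}`.
#' @param initial_distribution Start distribution of the segment chain.
#' @param call_group_transition Row-stochastic matrix over the three call
#'   groups, or `NULL` to sample calls unconditionally from the segment
#'   chain (call groups then emerge rather than being imposed).
#' @param call_group_initial Start distribution over call groups.
#' @param call_length_range,combination_length_range Inclusive length bounds
#'   (defaults 1-7 segments, 2-5 calls).
#' @param call_length_decay,combination_length_decay Geometric decay of the
#'   truncated length distributions (defaults give mean call length ~2.4
#'   segments and mean combination length ~2.5 calls).
#' @param gap_segment,gap_call Lists `(mean, sd, min, max)` of the truncated
#'   normal silence distributions (seconds).
#' @param gap_combination Range (seconds) of the uniform inter-combination
#'   silence.
#' @param acoustics Per-class signal parameters; see
#'   [default_acoustics-related][default_segment_transition] defaults.
#' @param female_fraction Fraction of individuals that are female.
#' @param individual_weights Optional sampling weights over individuals (an
#'   over-representation mode for testing subsampling guards); `NULL` =
#'   uniform.
#' @param sample_rate Audio sampling rate in Hz.
#' @param seed Integer seed; all downstream sampling and rendering derives
#'   from it.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_combinations = 222L, n_individuals = 23L,
                           n_groups = 16L,
                           segment_transition = default_segment_transition(),
                           initial_distribution = c(DS = 0.368, LH = 0.160,
                                                    NL = 0.136, SH = 0.336),
                           call_group_transition =
                             default_call_group_transition(),
                           call_group_initial = c(other = 0.55,
                                                  `LH-containing` = 0.35,
                                                  `lone-NL` = 0.10),
                           call_length_range = c(1L, 7L),
                           call_length_decay = 0.62,
                           combination_length_range = c(2L, 5L),
                           combination_length_decay = 0.4,
                           gap_segment = list(mean = 0.008, sd = 0.006,
                                              min = 0.001, max = 0.025),
                           gap_call = list(mean = 0.113, sd = 0.09,
                                           min = 0.03, max = 0.5),
                           gap_combination = c(1.2, 2.0),
                           acoustics = default_acoustics(),
                           female_fraction = 0.65,
                           individual_weights = NULL,
                           sample_rate = 44100L, seed = 1L) {
  spec <- structure(as.list(environment()), class = "generator_spec")
  validate_generator_spec(spec)
  spec
}

validate_generator_spec <- function(spec) {
  check_stochastic <- function(m, what) {
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-8))
      stop("spec error: ", what, " rows must sum to 1")
  }
  check_stochastic(spec$segment_transition, "segment_transition")
  if (!is.null(spec$call_group_transition))
    check_stochastic(spec$call_group_transition, "call_group_transition")
  if (abs(sum(spec$initial_distribution) - 1) > 1e-8)
    stop("spec error: initial_distribution must sum to 1")
  if (spec$call_length_range[1] < 1 || spec$call_length_range[2] > 7)
    stop("spec error: call lengths must lie in [1, 7]")
  if (spec$combination_length_range[1] < 2 ||
      spec$combination_length_range[2] > 5)
    stop("spec error: combination lengths must lie in [2, 5]")
  if (!(spec$gap_segment$max < spec$gap_call$max &&
        spec$gap_call$max < spec$gap_combination[1]))
    stop("spec error: gap scales must be ordered segment < call < combination")
  invisible(spec)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
      x <- NA_real_
    }
    out[i] <- if (is.na(x)) (lo + hi) / 2 else x
  }
  out
}

draw_length <- function(range, decay) {
  ks <- range[1]:range[2]
  sample(ks, 1, prob = decay^(ks - ks[1]))
}

draw_chain <- function(len, trans, init) {
  a <- colnames(trans)
  s <- character(len)
  s[1] <- sample(a, 1, prob = init)
  for (i in seq_len(len - 1)) {
    pr <- trans[s[i], ]
    if (sum(pr) <= 0)
      stop("spec error: absorbing state '", s[i],
           "' cannot reach the requested length")
    s[i + 1] <- sample(a, 1, prob = pr)
  }
  s
}

draw_call_of_group <- function(group, spec) {
  for (try in 1:1000) {
    if (group == "lone-NL") return("NL")
    len <- draw_length(spec$call_length_range, spec$call_length_decay)
    s <- draw_chain(len, spec$segment_transition, spec$initial_distribution)
    if (assign_call_group(s) == group) return(s)
  }
  stop("spec error: could not generate a call of group '", group,
       "' under the segment chain (check the transition structure)")
}

#' Sample a ground-truth corpus manifest from a generator spec
#'
#' Draws combinations of calls of segments from the two-level first-order
#' chain, lays out all unit boundaries on the audio time axis (quantised to
#' the sample grid) under the spec's silence regime, and records the full
#' ground truth: every unit's label, level, times and parent links, the
#' per-individual assignment, and the realized transition counts at both
#' levels (recomputed from the unit list, so the manifest is
#' self-consistent).
#'
#' @param spec A [generator_spec()].
#' @return Object of class `corpus_manifest`: list with `units` (one row per
#'   segment), `recordings` (metadata rows), `realized_segment` /
#'   `realized_call` ([count_transitions()] results, `NULL` for an empty
#'   corpus), and `spec`.
#' @export
sample_sequences <- function(spec) {
  validate_generator_spec(spec)
  set.seed(spec$seed)
  fs <- spec$sample_rate
  q <- function(x) round(x * fs) / fs          # snap to sample grid

  n_ind <- spec$n_individuals
  ind_ids <- sprintf("ind%02d", seq_len(n_ind))
  grp_of <- ((seq_len(n_ind) - 1L) %% spec$n_groups) + 1L
  grp_ids <- sprintf("grp%02d", grp_of)
  site_of <- ifelse(grp_of <= ceiling(spec$n_groups / 2), "site A", "site B")
  sex_of <- ifelse(seq_len(n_ind) <= round(spec$female_fraction * n_ind),
                   "F", "M")
  recordings <- data.frame(recording_id = sprintf("rec%02d", seq_len(n_ind)),
                           individual_id = ind_ids, group_id = grp_ids,
                           site = site_of, sex = sex_of,
                           stringsAsFactors = FALSE)

  units <- list()
  cursor <- stats::setNames(rep(0.5, n_ind), ind_ids) # per-recording clock
  call_id <- 0L; seg_id <- 0L
  for (cb in seq_len(spec$n_combinations)) {
    ind <- sample.int(n_ind, 1, prob = spec$individual_weights)
    L <- draw_length(spec$combination_length_range,
                     spec$combination_length_decay)
    if (is.null(spec$call_group_transition)) {
      calls <- lapply(seq_len(L), function(i)
        draw_chain(draw_length(spec$call_length_range,
                               spec$call_length_decay),
                   spec$segment_transition, spec$initial_distribution))
      groups <- vapply(calls, assign_call_group, character(1))
    } else {
      groups <- draw_chain(L, spec$call_group_transition,
                           spec$call_group_initial)
      calls <- lapply(groups, draw_call_of_group, spec = spec)
    }

    t <- unname(cursor[ind]) + if (cursor[ind] > 0.5)
      stats::runif(1, spec$gap_combination[1], spec$gap_combination[2]) else 0
    for (ca in seq_along(calls)) {
      call_id <- call_id + 1L
      if (ca > 1)
        t <- t + rtrunc_norm(1, spec$gap_call$mean, spec$gap_call$sd,
                             spec$gap_call$min, spec$gap_call$max)
      segs <- calls[[ca]]
      for (sg in seq_along(segs)) {
        seg_id <- seg_id + 1L
        if (sg > 1)
          t <- t + rtrunc_norm(1, spec$gap_segment$mean, spec$gap_segment$sd,
                               spec$gap_segment$min, spec$gap_segment$max)
        ac <- spec$acoustics[[segs[sg]]]
        dur <- max(0.04, rtrunc_norm(1, ac$dur_mean, ac$dur_sd,
                                     ac$dur_mean - 2 * ac$dur_sd,
                                     ac$dur_mean + 2 * ac$dur_sd))
        start <- q(t); end <- q(t + dur)
        units[[seg_id]] <- data.frame(
          recording_id = recordings$recording_id[ind],
          individual_id = ind_ids[ind], group_id = grp_ids[ind],
          site = site_of[ind], sex = sex_of[ind],
          comb_id = cb, call_id = call_id, seg_id = seg_id,
          label = segs[sg], call_group = groups[ca],
          start = start, end = end,
          freq_shift = 0, band_shift = 0, amp_scale = 1,
          stringsAsFactors = FALSE)
        t <- end
      }
    }
    cursor[ind] <- t
  }

  units <- if (length(units)) do.call(rbind, units) else
    data.frame(recording_id = character(0), individual_id = character(0),
               group_id = character(0), site = character(0),
               sex = character(0), comb_id = integer(0),
               call_id = integer(0), seg_id = integer(0),
               label = character(0), call_group = character(0),
               start = numeric(0), end = numeric(0), freq_shift = numeric(0),
               band_shift = numeric(0), amp_scale = numeric(0),
               stringsAsFactors = FALSE)
  manifest <- structure(list(units = units, recordings = recordings,
                             spec = spec),
                        class = "corpus_manifest")
  manifest$realized_segment <- if (nrow(units))
    count_transitions(manifest_corpus(manifest, "segment")) else NULL
  manifest$realized_call <- if (nrow(units))
    count_transitions(manifest_corpus(manifest, "call")) else NULL
  manifest
}

#' @export
print.corpus_manifest <- function(x, ...) {
  cat(sprintf("<corpus_manifest> %d segments, %d calls, %d combinations, %d recordings\n",
              nrow(x$units), length(unique(x$units$call_id)),
              length(unique(x$units$comb_id)), nrow(x$recordings)))
  invisible(x)
}

#' Ground-truth sequence corpus of a manifest
#'
#' @param manifest A [sample_sequences()] manifest.
#' @param level `"segment"` (segment sequences per call) or `"call"`
#'   (call-group sequences per combination).
#' @return A [sequence_corpus()].
#' @export
manifest_corpus <- function(manifest, level = c("segment", "call")) {
  level <- match.arg(level)
  u <- manifest$units[order(manifest$units$seg_id), ]
  if (level == "segment") {
    sequence_corpus(unname(split(u$label, u$call_id)),
                    alphabet = c("DS", "LH", "NL", "SH"),
                    level = "segment->call")
  } else {
    first <- u[!duplicated(u$call_id), ]
    sequence_corpus(unname(split(first$call_group, first$comb_id)),
                    alphabet = c("other", "LH-containing", "lone-NL"),
                    level = "call->combination")
  }
}

#' Positional category of each manifest segment
#'
#' Same rules as [assign_position_category()], computed on the ground-truth
#' parent links: LH is `"precedes-DS"` when the next segment in the call is a
#' DS, else `"call-final-or-lone"`; other classes are `"lone"` when they
#' solely comprise the call, else `"combined"`.
#'
#' @param manifest A [sample_sequences()] manifest.
#' @return Character vector along `manifest$units`.
#' @export
manifest_position_category <- function(manifest) {
  u <- manifest$units
  vapply(seq_len(nrow(u)), function(i) {
    sibs <- which(u$call_id == u$call_id[i])
    pos <- match(i, sibs)
    if (u$label[i] == "LH") {
      nxt <- if (pos < length(sibs)) u$label[sibs[pos + 1]] else NA
      if (identical(nxt, "DS")) "precedes-DS" else "call-final-or-lone"
    } else if (length(sibs) == 1) "lone" else "combined"
  }, character(1))
}

#' Inject coarticulation-like acoustic shifts into a manifest
#'
#' Modifies the rendering parameters of segments matching a
#' (class, positional-category) rule, emulating coarticulation: the acoustic
#' form of a unit depends on its arrangement relative to neighbours. E.g.
#' shifting LH segments that precede a DS by +800 Hz makes the within-class
#' projection separate into two position-defined clusters.
#'
#' @param manifest A [sample_sequences()] manifest.
#' @param rule List of rules, each a list with `class`, `category`, and any
#'   of `freq_shift` (Hz, tones/sweeps), `band_shift` (Hz, noise bands),
#'   `amp_scale` (multiplicative). An empty list leaves the manifest
#'   unchanged.
#' @return The modified manifest.
#' @export
inject_coarticulation <- function(manifest, rule) {
  if (!length(rule)) return(manifest)
  poscat <- manifest_position_category(manifest)
  for (r in rule) {
    if (!r$class %in% c("DS", "LH", "NL", "SH"))
      stop("label error: unknown segment class '", r$class, "'")
    hit <- manifest$units$label == r$class & poscat == r$category
    if (!is.null(r$freq_shift))
      manifest$units$freq_shift[hit] <- manifest$units$freq_shift[hit] +
        r$freq_shift
    if (!is.null(r$band_shift))
      manifest$units$band_shift[hit] <- manifest$units$band_shift[hit] +
        r$band_shift
    if (!is.null(r$amp_scale))
      manifest$units$amp_scale[hit] <- manifest$units$amp_scale[hit] *
        r$amp_scale
  }
  manifest
}

synth_segment_wave <- function(label, dur, fs, ac, freq_shift = 0,
                               band_shift = 0, amp_scale = 1) {
  n <- max(1L, round(dur * fs))
  t <- (seq_len(n) - 1) / fs
  x <- switch(ac$type,
    sweep = {
      f <- seq(ac$f_start + freq_shift, ac$f_end + freq_shift, length.out = n)
      sin(2 * pi * cumsum(f) / fs)
    },
    tone = sin(2 * pi * (ac$freq + freq_shift) * t),
    noise = {
      band <- ac$band + band_shift
      bf <- signal::butter(4, band / (fs / 2), type = "pass")
      z <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
      z / max(abs(z), 1e-9)
    })
  ramp <- min(n %/% 2, round(0.005 * fs))
  env <- rep(1, n)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[seq_len(ramp)] <- up
    env[n - ramp + seq_len(ramp)] <- rev(up)
  }
  0.6 * amp_scale * x * env
}

#' Render a manifest to WAV + TextGrid files
#'
#' Synthesises one WAV recording per individual (DS as a descending frequency
#' sweep, LH as a long tone, SH as a short tone, NL as band-limited noise,
#' each with a 5 ms raised-cosine onset/offset), writes the three-tier
#' TextGrid per recording (call tier labels are simplified segment
#' compositions, combination tier labels join their call labels), the
#' metadata CSV and a manifest JSON. Byte-identical output for identical
#' spec + seed.
#'
#' @param manifest A [sample_sequences()] manifest.
#' @param spec The [generator_spec()] it was drawn from.
#' @param dir Output directory (created if needed).
#' @return List with `dir`, `wav`, `textgrid`, `metadata`, `manifest` file
#'   paths, invisibly.
#' @export
render_audio <- function(manifest, spec = manifest$spec, dir) {
  fs <- spec$sample_rate
  if (any(vapply(spec$acoustics, function(a)
    max(unlist(a[c("f_start", "f_end", "freq", "band")]), 0), numeric(1)) >=
    fs / 2))
    stop("spec error: class frequency at or above Nyquist")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed + 1L)

  u <- manifest$units
  wavs <- character(0); grids <- character(0)
  used <- unique(u$recording_id)
  for (rid in used) {
    ru <- u[u$recording_id == rid, ]
    n <- round((max(ru$end) + 0.5) * fs)
    x <- numeric(n)
    for (i in seq_len(nrow(ru))) {
      w <- synth_segment_wave(ru$label[i], ru$end[i] - ru$start[i], fs,
                              spec$acoustics[[ru$label[i]]],
                              ru$freq_shift[i], ru$band_shift[i],
                              ru$amp_scale[i])
      at <- round(ru$start[i] * fs)
      x[at + seq_along(w)] <- x[at + seq_along(w)] + w
    }
    wav_path <- file.path(dir, paste0(rid, ".wav"))
    write_wav(x, fs, wav_path)
    ann <- annotation_from_manifest(manifest, rid)
    grid_path <- file.path(dir, paste0(rid, ".TextGrid"))
    write_textgrid(ann, grid_path)
    wavs <- c(wavs, wav_path); grids <- c(grids, grid_path)
  }
  meta_path <- file.path(dir, "metadata.csv")
  write_metadata_csv(manifest$recordings[manifest$recordings$recording_id %in%
                                           used, ], meta_path)
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(units = manifest$units,
                            recordings = manifest$recordings),
                       man_path, digits = NA)
  invisible(list(dir = dir, wav = wavs, textgrid = grids,
                 metadata = meta_path, manifest = man_path))
}

#' Ground-truth annotation set of one rendered recording
#'
#' @param manifest A [sample_sequences()] manifest.
#' @param recording_id Recording to extract.
#' @return An [annotation_set()].
#' @export
annotation_from_manifest <- function(manifest, recording_id) {
  ru <- manifest$units[manifest$units$recording_id == recording_id, ]
  if (!nrow(ru)) stop("no units for recording '", recording_id, "'")
  mrow <- manifest$recordings[manifest$recordings$recording_id ==
                                recording_id, ]
  meta <- recording_meta(mrow$recording_id, mrow$individual_id,
                         mrow$group_id, mrow$site, mrow$sex,
                         manifest$spec$sample_rate)
  segs <- data.frame(label = ru$label, start = ru$start, end = ru$end,
                     stringsAsFactors = FALSE)
  call_rows <- lapply(split(seq_len(nrow(ru)), ru$call_id), function(idx)
    data.frame(label = simplify_call_label(ru$label[idx]),
               start = min(ru$start[idx]), end = max(ru$end[idx]),
               stringsAsFactors = FALSE))
  calls <- do.call(rbind, call_rows)
  comb_rows <- lapply(split(seq_len(nrow(ru)), ru$comb_id), function(idx) {
    labs <- vapply(split(ru$label[idx], ru$call_id[idx]),
                   simplify_call_label, character(1))
    data.frame(label = paste(labs, collapse = " "),
               start = min(ru$start[idx]), end = max(ru$end[idx]),
               stringsAsFactors = FALSE)
  })
  combs <- do.call(rbind, comb_rows)
  annotation_set(meta, segs, calls, combs)
}
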