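#' @keywords internal
default_tier_names <- function() {
  c(combination = "combination", call = "call", segment = "segment")
}

#' Read a Praat TextGrid annotation into an annotation set
#'
#' Parses a long-format TextGrid holding three interval tiers — one per
#' combinatorial level (combination, call, segment) — and assembles an
#' [annotation_set()]. Intervals with blank labels are skipped. Where two
#' consecutive units on a tier overlap by up to `overlap_tol` seconds (as
#' happens when boundaries are placed where a spectral intersection ceases),
#' the earlier unit is truncated at the later unit's start.
#'
#' @param path Path to a long-format `.TextGrid` file.
#' @param meta A [recording_meta()] object for the recording.
#' @param tier_names Named character vector mapping levels
#'   (`combination`, `call`, `segment`) to tier names in the file.
#' @param overlap_tol Maximum tolerated overlap between consecutive units on a
#'   tier, in seconds (default 1 ms); larger overlaps are an error.
#' @return An [annotation_set()].
#' @export
read_textgrid <- function(path, meta, tier_names = default_tier_names(),
                          overlap_tol = 1e-3) {
  if (!file.exists(path)) stop("TextGrid not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("TextGrid", lines, fixed = TRUE)))
    stop("not a TextGrid file: ", path)
  tiers <- parse_textgrid_tiers(lines)

  needed <- c("combination", "call", "segment")
  units <- list()
  for (lv in needed) {
    tname <- tier_names[[lv]]
    idx <- which(vapply(tiers, function(t) identical(t$name, tname), logical(1)))
    if (length(idx) == 0)
      stop("hierarchy error: TextGrid lacks tier '", tname, "' (level ", lv, ")")
    iv <- tiers[[idx[1]]]$intervals
    iv <- iv[nzchar(trimws(iv$text)), , drop = FALSE]
    if (nrow(iv) && any(iv$xmax <= iv$xmin))
      stop("format error: interval with end <= start on tier '", tname, "'")
    df <- data.frame(label = trimws(iv$text), start = iv$xmin, end = iv$xmax,
                     stringsAsFactors = FALSE)
    df <- df[order(df$start), , drop = FALSE]
    df <- resolve_overlaps(df, overlap_tol, tname)
    rownames(df) <- NULL
    units[[lv]] <- df
  }
  annotation_set(meta = meta, segments = units$segment, calls = units$call,
                 combinations = units$combination)
}

# Truncate <= tol overlaps (earlier unit cut at later unit's start);
# larger overlaps violate the non-overlap invariant.
resolve_overlaps <- function(df, tol, tier) {
  if (nrow(df) < 2) return(df)
  for (i in seq_len(nrow(df) - 1)) {
    ov <- df$end[i] - df$start[i + 1]
    if (ov > tol)
      stop("format error: overlapping units on tier '", tier, "' (",
           signif(ov, 3), " s)")
    if (ov > 0) df$end[i] <- df$start[i + 1]
  }
  df
}

parse_textgrid_tiers <- function(lines) {
  item_at <- grep("^\\s*item\\s*\\[[0-9]+\\]:", lines)
  tiers <- list()
  bounds <- c(item_at, length(lines) + 1L)
  for (k in seq_along(item_at)) {
    block <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    name <- tg_field_chr(block, "name")
    xmins <- tg_field_num_all(block, "xmin")
    xmaxs <- tg_field_num_all(block, "xmax")
    texts <- tg_field_chr_all(block, "text")
    # first xmin/xmax pair is the tier extent
    n <- length(texts)
    iv <- data.frame(xmin = xmins[seq_len(n) + 1L],
                     xmax = xmaxs[seq_len(n) + 1L],
                     text = texts, stringsAsFactors = FALSE)
    tiers[[k]] <- list(name = name, intervals = iv)
  }
  tiers
}

tg_field_chr <- function(block, field) {
  ln <- grep(paste0("^\\s*", field, "\\s*="), block, value = TRUE)
  if (!length(ln)) return(NA_character_)
  sub('^[^"]*"(.*)"\\s*$', "\\1", ln[1])
}

tg_field_chr_all <- function(block, field) {
  ln <- grep(paste0("^\\s*", field, "\\s*="), block, value = TRUE)
  sub('^[^"]*"(.*)"\\s*$', "\\1", ln)
}

tg_field_num_all <- function(block, field) {
  ln <- grep(paste0("^\\s*", field, "\\s*="), block, value = TRUE)
  as.numeric(sub(paste0("^\\s*", field, "\\s*=\\s*([-0-9.eE+]+).*$"), "\\1", ln))
}

#' Write an annotation set as a Praat TextGrid
#'
#' Serialises the three levels of an [annotation_set()] to a long-format
#' TextGrid with one interval tier per level. Gaps between labelled units are
#' written as empty intervals so the file is valid Praat input. Refuses to
#' write a set that violates the hierarchy invariants.
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @param tier_names Named character vector as in [read_textgrid()].
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(ann, path, tier_names = default_tier_names()) {
  validate_annotation_set(ann)
  levels <- list(combination = ann$combinations, call = ann$calls,
                 segment = ann$segments)
  xmax <- max(c(vapply(levels, function(d) if (nrow(d)) max(d$end) else 0,
                       numeric(1)), 1e-3))

  num <- function(x) sprintf("%.10f", x)
  out <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
           "xmin = 0", paste0("xmax = ", num(xmax)),
           "tiers? <exists>", paste0("size = ", length(levels)), "item []:")
  for (k in seq_along(levels)) {
    lv <- names(levels)[k]
    df <- levels[[lv]]
    iv <- tier_intervals(df, xmax)
    out <- c(out,
             sprintf("    item [%d]:", k),
             '        class = "IntervalTier"',
             sprintf('        name = "%s"', tier_names[[lv]]),
             "        xmin = 0",
             paste0("        xmax = ", num(xmax)),
             paste0("        intervals: size = ", nrow(iv)))
    for (i in seq_len(nrow(iv))) {
      out <- c(out,
               sprintf("        intervals [%d]:", i),
               paste0("            xmin = ", num(iv$xmin[i])),
               paste0("            xmax = ", num(iv$xmax[i])),
               sprintf('            text = "%s"', iv$text[i]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# fill gaps with empty intervals so intervals tile [0, xmax]
tier_intervals <- function(df, xmax) {
  if (!nrow(df))
    return(data.frame(xmin = 0, xmax = xmax, text = "",
                      stringsAsFactors = FALSE))
  iv <- data.frame(xmin = numeric(0), xmax = numeric(0), text = character(0),
                   stringsAsFactors = FALSE)
  cur <- 0
  for (i in seq_len(nrow(df))) {
    if (df$start[i] > cur)
      iv <- rbind(iv, data.frame(xmin = cur, xmax = df$start[i], text = ""))
    iv <- rbind(iv, data.frame(xmin = df$start[i], xmax = df$end[i],
                               text = df$label[i]))
    cur <- df$end[i]
  }
  if (cur < xmax)
    iv <- rbind(iv, data.frame(xmin = cur, xmax = xmax, text = ""))
  iv
}
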