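#' Sequence corpus at one combinatorial level
#'
#' A set of ordered label sequences — segment sequences forming calls
#' (within-call level) or call sequences forming combinations (between-call
#' level) — over a fixed alphabet of unit classes.
#'
#' @param sequences List of non-empty character vectors.
#' @param alphabet Ordered character vector of allowed tokens; defaults to
#'   the sorted set of tokens present.
#' @param level Free-text description of the level
#'   (e.g. `"segment->call"`, `"call->combination"`).
#' @return Object of class `sequence_corpus`.
#' @export
sequence_corpus <- function(sequences, alphabet = NULL,
                            level = "segment->call") {
  sequences <- lapply(sequences, as.character)
  if (!length(sequences)) stop("corpus must contain at least one sequence")
  if (any(vapply(sequences, length, integer(1)) == 0))
    stop("sequences must be non-empty")
  tokens <- unlist(sequences)
  if (is.null(alphabet)) alphabet <- sort(unique(tokens))
  bad <- setdiff(tokens, alphabet)
  if (length(bad))
    stop("label error: token(s) outside alphabet: ",
         paste(unique(bad), collapse = ", "))
  structure(list(sequences = sequences, alphabet = alphabet, level = level),
            class = "sequence_corpus")
}

#' @export
print.sequence_corpus <- function(x, ...) {
  cat(sprintf("<sequence_corpus> %s: %d sequences, %d tokens, alphabet {%s}\n",
              x$level, length(x$sequences), length(unlist(x$sequences)),
              paste(x$alphabet, collapse = ", ")))
  invisible(x)
}

# flattened view used by the counting and randomization internals
corpus_index <- function(corpus) {
  lens <- vapply(corpus$sequences, length, integer(1))
  tokens <- match(unlist(corpus$sequences), corpus$alphabet)
  ends <- cumsum(lens)
  from_idx <- setdiff(seq_along(tokens), ends) # every non-final slot
  list(tokens = tokens, lens = lens, from_idx = from_idx,
       to_idx = from_idx + 1L, k = length(corpus$alphabet))
}

count_matrix <- function(from, to, k) {
  matrix(tabulate((from - 1L) * k + to, nbins = k * k), k, k, byrow = TRUE)
}

row_normalize <- function(counts) {
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- 0
  probs
}

#' First-order forward transition matrix of a corpus
#'
#' Counts adjacent ordered token pairs within each sequence (no
#' cross-sequence pairs and no artificial start/end tokens) and row-normalises
#' to forward transition probabilities P(next = j | current = i). States with
#' no outgoing transition keep an all-zero probability row.
#'
#' @param corpus A [sequence_corpus()].
#' @return Object of class `transition_matrix`: list with `counts` and
#'   `probs` (|A| x |A| matrices, rows = preceding unit), `alphabet`.
#' @export
count_transitions <- function(corpus) {
  ci <- corpus_index(corpus)
  counts <- count_matrix(ci$tokens[ci$from_idx], ci$tokens[ci$to_idx], ci$k)
  dimnames(counts) <- list(from = corpus$alphabet, to = corpus$alphabet)
  probs <- row_normalize(counts)
  structure(list(counts = counts, probs = probs, alphabet = corpus$alphabet),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("<transition_matrix> forward probabilities P(row -> column):\n")
  print(round(x$probs, digits))
  invisible(x)
}

#' Frequency-preserving randomization of a corpus
#'
#' Randomly reassigns the corpus tokens to sequence slots by a uniform
#' permutation, preserving both each token type's total frequency and the
#' multiset of sequence lengths. This is the null model for the transition
#' permutation test: any first-order sequential structure is destroyed while
#' unit usage and sequence sizes are kept.
#'
#' @param corpus A [sequence_corpus()].
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return A randomized `sequence_corpus`.
#' @export
randomize_corpus <- function(corpus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tokens <- unlist(corpus$sequences)
  lens <- vapply(corpus$sequences, length, integer(1))
  shuffled <- sample(tokens)
  sequence_corpus(unname(split(shuffled, rep(seq_along(lens), lens))),
                  alphabet = corpus$alphabet, level = corpus$level)
}

#' Monte-Carlo permutation test of first-order transition probabilities
#'
#' Tests each observed forward transition probability against a null
#' distribution built by repeatedly randomizing the assignment of units to
#' sequences ([randomize_corpus()]) and recomputing the probability matrix.
#' Per cell, significance is the relative ranking of the observed probability
#' among its null sample: the observed value is flagged at level `alpha` when
#' it falls outside the central `1 - alpha` mass of the null (two-tailed).
#' The two-tailed p-value is twice the smaller tail proportion (ties counted
#' into the tail, which is conservative), capped at 1 and floored at
#' `1/(n_iter + 1)` — the Monte-Carlo resolution.
#'
#' Cells whose preceding state has no outgoing transition in a null draw are
#' undefined for that draw; cells undefined in every draw (or in the observed
#' data) are reported as `NA` and flagged in `undefined`.
#'
#' @param corpus A [sequence_corpus()].
#' @param n_iter Number of randomized iterations (default 10000).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param seed Integer seed; the test is deterministic given it.
#' @param keep_null If `TRUE` (default) the per-cell null samples are stored
#'   in the result (`n_iter` x |A|^2).
#' @return Object of class `transition_test`: `observed`
#'   ([count_transitions()] result), `p_two_tailed`, `significant`,
#'   `undefined`, `null_quantiles` (2.5/50/97.5%), `null_samples` (optional),
#'   `n_iter`, `alpha`, `seed`.
#' @export
permutation_test <- function(corpus, n_iter = 10000L, alpha = 0.05,
                             seed = 42L, keep_null = TRUE) {
  if (n_iter < 1) stop("parameter error: n_iter must be >= 1")
  observed <- count_transitions(corpus)
  ci <- corpus_index(corpus)
  k <- ci$k

  set.seed(seed)
  null <- matrix(NA_real_, n_iter, k * k) # column = cell (row-major from,to)
  for (it in seq_len(n_iter)) {
    perm <- ci$tokens[sample.int(length(ci$tokens))]
    counts <- count_matrix(perm[ci$from_idx], perm[ci$to_idx], k)
    probs <- row_normalize(counts)
    probs[rowSums(counts) == 0, ] <- NA_real_ # undefined rows this draw
    null[it, ] <- as.numeric(t(probs))
  }

  obs_vec <- as.numeric(t(observed$probs))
  obs_def <- rep(rowSums(observed$counts) > 0, each = k)
  p <- rep(NA_real_, k * k)
  sig <- rep(NA, k * k)
  for (cell in seq_len(k * k)) {
    v <- null[, cell]
    v <- v[!is.na(v)]
    if (!length(v) || !obs_def[cell]) next
    m <- length(v)
    pl <- sum(v <= obs_vec[cell]) / m
    pg <- sum(v >= obs_vec[cell]) / m
    p[cell] <- max(min(1, 2 * min(pl, pg)), 1 / (m + 1))
    sig[cell] <- (pl < alpha / 2) || (pg < alpha / 2)
  }

  shape <- function(x) matrix(x, k, k, byrow = TRUE,
                              dimnames = dimnames(observed$counts))
  qs <- apply(null, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE, type = 1)
  structure(list(observed = observed,
                 p_two_tailed = shape(p),
                 significant = shape(sig),
                 undefined = shape(is.na(p)),
                 null_quantiles = list(lower = shape(qs[1, ]),
                                       median = shape(qs[2, ]),
                                       upper = shape(qs[3, ])),
                 null_samples = if (keep_null) null else NULL,
                 n_iter = as.integer(n_iter), alpha = alpha,
                 seed = as.integer(seed), level = corpus$level),
            class = "transition_test")
}

#' @export
print.transition_test <- function(x, digits = 3, ...) {
  cat(sprintf("<transition_test> %s: %d iterations, alpha = %g, seed = %d\n",
              x$level, x$n_iter, x$alpha, x$seed))
  cat("observed P(row -> column), '*' = significant:\n")
  k <- length(x$observed$alphabet)
  disp <- matrix(sprintf("%.*f%s", digits, x$observed$probs,
                         ifelse(!is.na(x$significant) & x$significant,
                                "*", " ")),
                 k, k, dimnames = dimnames(x$observed$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
summary.transition_test <- function(object, ...) {
  df <- as_edge_table(object)
  cat(sprintf("Transition test (%s), %d iterations:\n", object$level,
              object$n_iter))
  print(df[df$count > 0 | !is.na(df$p), ], row.names = FALSE)
  invisible(df)
}

as_edge_table <- function(result) {
  k <- length(result$observed$alphabet)
  a <- result$observed$alphabet
  data.frame(from = rep(a, each = k), to = rep(a, k),
             count = as.integer(t(result$observed$counts)),
             probability = as.numeric(t(result$observed$probs)),
             p = as.numeric(t(result$p_two_tailed)),
             significant = as.logical(t(result$significant)),
             stringsAsFactors = FALSE)
}

#' Export a transition test as a graph edge list
#'
#' Writes one row per ordered state pair (zeros included) with the observed
#' count, probability, Monte-Carlo p-value and significance flag — the data
#' behind a transition graph whose edge opacity scales with probability.
#' Optionally renders the graph to a PNG or PDF.
#'
#' @param result A [permutation_test()] result.
#' @param path Output CSV path.
#' @param plot_path Optional `.png` or `.pdf` path for a rendered graph.
#' @return The edge table, invisibly.
#' @export
export_transition_graph <- function(result, path, plot_path = NULL) {
  if (!length(result$observed$alphabet)) stop("empty alphabet")
  df <- as_edge_table(result)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(plot_path)) {
    if (grepl("\\.pdf$", plot_path)) grDevices::pdf(plot_path, 6, 6)
    else grDevices::png(plot_path, 800, 800)
    plot_transition_graph(result)
    grDevices::dev.off()
  }
  invisible(df)
}

#' @rdname export_transition_graph
#' @export
plot_transition_graph <- function(result) {
  a <- result$observed$alphabet
  k <- length(a)
  th <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  xy <- cbind(cos(th), sin(th))
  graphics::plot(xy, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", pch = 21, cex = 4,
                 bg = "grey85")
  df <- as_edge_table(result)
  for (r in seq_len(nrow(df))) {
    if (df$count[r] == 0) next
    i <- match(df$from[r], a); j <- match(df$to[r], a)
    op <- 0.15 + 0.85 * df$probability[r]
    if (i == j) {
      graphics::points(xy[i, 1] * 1.22, xy[i, 2] * 1.22, cex = 3.5,
                       col = grDevices::rgb(0, 0, 0, op))
    } else {
      v <- xy[j, ] - xy[i, ]
      graphics::arrows(xy[i, 1] + 0.14 * v[1], xy[i, 2] + 0.14 * v[2],
                       xy[j, 1] - 0.14 * v[1], xy[j, 2] - 0.14 * v[2],
                       col = grDevices::rgb(0, 0, 0, op), lwd = 1 + 3 *
                         df$probability[r], length = 0.1)
    }
    lab <- sprintf("%.2f%s", df$probability[r],
                   ifelse(isTRUE(df$significant[r]), "*", ""))
    graphics::text((xy[i, 1] + xy[j, 1]) / 2 * 1.08,
                   (xy[i, 2] + xy[j, 2]) / 2 * 1.08, lab, cex = 0.8)
  }
  graphics::text(xy * 1.0, labels = a, font = 2)
  invisible(result)
}
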