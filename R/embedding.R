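#' Project a spectrogram dataset into 2-D latent space
#'
#' UMAP projection of the flattened spectrograms, each time-frequency bin
#' treated as an independent dimension. Defaults follow common practice for
#' clustering vocal repertoires: `n_neighbors = 15`, `min_dist = 0`
#' (recommended for cluster evaluation), Euclidean metric. Deterministic
#' given `(data, seed, params)`.
#'
#' @param data A `spectrogram_dataset` (see [build_dataset()]) or a numeric
#'   matrix of feature rows.
#' @param seed Integer seed for the stochastic layout optimisation.
#' @param n_neighbors,min_dist,metric UMAP parameters.
#' @param init Layout initialisation (default `"pca"`: the spectral
#'   initialisation fragments layouts when well-separated classes make the
#'   neighbour graph disconnected).
#' @return Object of class `embedding_result`: `coords` (n x 2), `unit_refs`,
#'   `labels` (predictor data frame, if available), `seed`, `params`.
#' @export
project <- function(data, seed = 42L, n_neighbors = 15L, min_dist = 0,
                    metric = "euclidean", init = "pca") {
  x <- if (inherits(data, "spectrogram_dataset")) data$features else
    as.matrix(data)
  labels <- if (inherits(data, "spectrogram_dataset")) data$labels else NULL
  if (nrow(x) < 10) stop("parameter error: need at least 10 rows to project")
  if (nrow(x) <= n_neighbors)
    stop("parameter error: n_neighbors (", n_neighbors,
         ") must be smaller than the number of rows (", nrow(x), ")")
  if (anyNA(x)) stop("missing features are not allowed")
  if (all(abs(sweep(x, 2, x[1, ])) < 1e-12)) {
    # all rows identical: the geometry is degenerate and any layout is
    # arbitrary, so collapse every point to the origin
    coords <- matrix(0, nrow(x), 2)
    return(structure(list(coords = coords,
                          unit_refs = labels$unit_ref %||%
                            as.character(seq_len(nrow(x))),
                          labels = labels, seed = as.integer(seed),
                          params = list(n_neighbors = n_neighbors,
                                        min_dist = min_dist, metric = metric,
                                        init = init)),
                     class = "embedding_result"))
  }
  run_umap <- function(ini) {
    set.seed(seed)
    # the unscaled PCA init intentionally keeps the data's global scale
    # (scaling it down compresses between-class structure), so uwot's
    # init-scale advisory does not apply here
    withCallingHandlers(
      uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                 metric = metric, init = ini, n_threads = 1,
                 n_sgd_threads = 1, batch = FALSE),
      warning = function(w) {
        if (grepl("Initial embedding standard deviation", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  # PCA init fails on (near-)degenerate inputs such as all-identical rows;
  # fall back to a seeded random layout there
  coords <- tryCatch(run_umap(init), error = function(e) run_umap("random"))
  structure(list(coords = unname(coords),
                 unit_refs = labels$unit_ref %||% as.character(seq_len(nrow(x))),
                 labels = labels, seed = as.integer(seed),
                 params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                               metric = metric, init = init)),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d points, seed %d (n_neighbors = %d, min_dist = %g)\n",
              nrow(x$coords), x$seed, x$params$n_neighbors, x$params$min_dist))
  invisible(x)
}

check_labels <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels must have one entry per embedded point")
  tab <- table(labels)
  if (length(tab) < 2)
    stop("undefined-score error: silhouette needs at least 2 classes")
  if (any(tab < 2))
    stop("undefined-score error: every class needs at least 2 members (",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  labels
}

#' Silhouette score of a predictor on a projection
#'
#' Per-point silhouette coefficients of the 2-D embedding coordinates under
#' the class labels of one predictor; the summary score S is their mean, on a
#' scale from -1 (inadequate description) through 0 (overlapping clusters)
#' to 1 (perfect separation by class).
#'
#' @param emb An [embedding_result][project()], or an n x 2 coordinate matrix.
#' @param labels Class label per point.
#' @param predictor Name used in reports.
#' @return Object of class `cluster_eval`: `predictor`, `S`,
#'   `per_point_silhouette`, `n`, and (filled by [permuted_label_test()])
#'   `H`, `df`, `p`.
#' @export
silhouette_by_predictor <- function(emb, labels, predictor = "label") {
  coords <- if (inherits(emb, "embedding_result")) emb$coords else
    as.matrix(emb)
  labels <- check_labels(labels, nrow(coords))
  widths <- silhouette_widths(coords, labels)
  structure(list(predictor = predictor, S = mean(widths),
                 per_point_silhouette = widths, n = length(widths),
                 H = NA_real_, df = NA_integer_, p = NA_real_),
            class = "cluster_eval")
}

silhouette_widths <- function(coords, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dist = stats::dist(coords))
  as.numeric(sil[, "sil_width"])
}

#' Permuted-label test of a predictor's silhouette structure
#'
#' Compares the per-point silhouette coefficients under the true labels with
#' those obtained after randomly permuting the labels (the layout expected by
#' chance), using the Kruskal-Wallis rank test. A small p indicates the
#' predictor describes the layout better (or worse) than a random labelling.
#'
#' @inheritParams silhouette_by_predictor
#' @param n_perm Number of random label permutations pooled into the null
#'   group (default 1, matching the paired observed-vs-permuted design).
#' @param seed Integer seed for the permutations.
#' @return A `cluster_eval` with `S` (true-label score), `S_permuted` (mean
#'   permuted score), `H`, `df` and `p`.
#' @export
permuted_label_test <- function(emb, labels, n_perm = 1L, seed = 42L,
                                predictor = "label") {
  if (n_perm < 1) stop("parameter error: n_perm must be >= 1")
  coords <- if (inherits(emb, "embedding_result")) emb$coords else
    as.matrix(emb)
  labels <- check_labels(labels, nrow(coords))
  obs <- silhouette_widths(coords, labels)
  set.seed(seed)
  perm <- unlist(lapply(seq_len(n_perm), function(k)
    silhouette_widths(coords, sample(labels))))
  kw <- stats::kruskal.test(list(observed = obs, permuted = perm))
  structure(list(predictor = predictor, S = mean(obs),
                 S_permuted = mean(perm), per_point_silhouette = obs,
                 n = length(obs), H = unname(kw$statistic),
                 df = unname(kw$parameter), p = kw$p.value,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "cluster_eval")
}

#' @export
print.cluster_eval <- function(x, ...) {
  cat(sprintf("<cluster_eval> predictor '%s': S = %.3f (n = %d)",
              x$predictor, x$S, x$n))
  if (!is.na(x$H))
    cat(sprintf(", H(%d) = %.3f, p = %.3g", x$df, x$H, x$p))
  cat("\n")
  invisible(x)
}

#' Evaluate several predictors on one shared projection
#'
#' Runs [permuted_label_test()] for each predictor column and returns a tidy
#' evaluation table. Predictors whose labels cannot support a silhouette
#' (fewer than two classes with two members each) are reported with NA
#' scores. The table also carries per-individual point counts so
#' over-representation of any one caller is visible.
#'
#' @param emb An [embedding_result][project()] carrying a `labels` data frame.
#' @param predictors Character vector of label columns to evaluate.
#' @param seed Integer seed.
#' @return Object of class `predictor_evaluation`: list with `table` (one row
#'   per predictor: `predictor`, `S`, `H`, `df`, `p`, `n`) and
#'   `individual_counts`.
#' @export
evaluate_predictors <- function(emb, predictors = c("label", "individual",
                                                    "group", "site", "sex"),
                                seed = 42L) {
  stopifnot(inherits(emb, "embedding_result"), !is.null(emb$labels))
  rows <- lapply(predictors, function(p) {
    res <- tryCatch(permuted_label_test(emb, emb$labels[[p]], seed = seed,
                                        predictor = p),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(predictor = p, S = NA_real_, H = NA_real_, df = NA_integer_,
                 p = NA_real_, n = nrow(emb$coords))
    else
      data.frame(predictor = p, S = res$S, H = res$H, df = res$df, p = res$p,
                 n = res$n)
  })
  structure(list(table = do.call(rbind, rows),
                 individual_counts = table(emb$labels$individual)),
            class = "predictor_evaluation")
}

#' @export
print.predictor_evaluation <- function(x, ...) {
  cat("<predictor_evaluation>\n")
  print(x$table, row.names = FALSE)
  cat("points per individual:\n")
  print(x$individual_counts)
  invisible(x)
}

#' Balance a dataset by downsampling each class to the smallest class
#'
#' Each class of `class_column` is downsampled without replacement to the
#' count of the smallest class, removing class-imbalance bias from a
#' projection. Deterministic given `seed`.
#'
#' @param data A `spectrogram_dataset`.
#' @param class_column Label column defining the classes.
#' @param seed Integer seed.
#' @return A `spectrogram_dataset` with equal class counts.
#' @export
balanced_subsample <- function(data, class_column = "label", seed = 42L) {
  stopifnot(inherits(data, "spectrogram_dataset"))
  cls <- data$labels[[class_column]]
  tab <- table(cls)
  if (any(tab == 0) || !length(tab)) stop("every class must be non-empty")
  m <- min(tab)
  set.seed(seed)
  keep <- sort(unlist(lapply(split(seq_along(cls), cls), function(idx)
    if (length(idx) > m) sample(idx, m) else idx)))
  data$features <- data$features[keep, , drop = FALSE]
  data$labels <- data$labels[keep, , drop = FALSE]
  rownames(data$labels) <- NULL
  data
}
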