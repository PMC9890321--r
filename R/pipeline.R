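#' Read an annotated corpus directory
#'
#' Expects `metadata.csv` (see [read_metadata_csv()]) plus one
#' `<recording_id>.TextGrid` and `<recording_id>.wav` per row.
#'
#' @param dir Corpus directory.
#' @param tier_names Tier-name mapping passed to [read_textgrid()].
#' @return List with `annotations` (list of [annotation_set()]) and
#'   `audio_dir`.
#' @export
read_corpus <- function(dir, tier_names = default_tier_names()) {
  if (!dir.exists(dir)) stop("I/O error: corpus directory not found: ", dir)
  meta <- read_metadata_csv(file.path(dir, "metadata.csv"))
  anns <- lapply(seq_len(nrow(meta)), function(i) {
    m <- recording_meta(meta$recording_id[i], meta$individual_id[i],
                        meta$group_id[i], meta$site[i], meta$sex[i])
    read_textgrid(file.path(dir, paste0(meta$recording_id[i], ".TextGrid")),
                  m, tier_names = tier_names)
  })
  list(annotations = anns, audio_dir = dir)
}

#' Cap over-represented individuals by random combination subsampling
#'
#' Individuals contributing more combinations than `cap` are randomly
#' downsampled to `cap` combinations (selection seeded); calls and segments
#' inside dropped combinations are removed with them. Other individuals are
#' untouched. This guards the cluster evaluations and transition tests
#' against bias from a few prolific callers.
#'
#' @param ann_list List of [annotation_set()] objects.
#' @param cap Maximum combinations per individual (>= 1).
#' @param seed Integer seed.
#' @return The subsampled list of annotation sets.
#' @export
cap_overrepresented <- function(ann_list, cap, seed = 42L) {
  stopifnot(cap >= 1)
  if (inherits(ann_list, "annotation_set")) ann_list <- list(ann_list)
  # global inventory of combinations per individual
  inv <- do.call(rbind, lapply(seq_along(ann_list), function(ai) {
    ann <- ann_list[[ai]]
    if (!nrow(ann$combinations)) return(NULL)
    data.frame(ann = ai, comb = seq_len(nrow(ann$combinations)),
               individual = ann$meta$individual_id, stringsAsFactors = FALSE)
  }))
  if (is.null(inv)) return(ann_list)
  set.seed(seed)
  drop <- do.call(rbind, lapply(split(inv, inv$individual), function(d) {
    if (nrow(d) <= cap) return(NULL)
    d[-sample(seq_len(nrow(d)), cap), , drop = FALSE]
  }))
  if (is.null(drop)) return(ann_list)
  for (ai in unique(drop$ann)) {
    ann <- ann_list[[ai]]
    kill <- drop$comb[drop$ann == ai]
    spans <- ann$combinations[kill, , drop = FALSE]
    tol <- ann$tol %||% 1e-3
    inside <- function(df) {
      hit <- rep(FALSE, nrow(df))
      for (i in seq_len(nrow(spans)))
        hit <- hit | (df$start >= spans$start[i] - tol &
                        df$end <= spans$end[i] + tol)
      hit
    }
    ann$segments <- ann$segments[!inside(ann$segments), , drop = FALSE]
    ann$calls <- ann$calls[!inside(ann$calls), , drop = FALSE]
    ann$combinations <- ann$combinations[-kill, , drop = FALSE]
    ann_list[[ai]] <- validate_annotation_set(ann)
  }
  ann_list
}

#' Default full-pipeline configuration
#'
#' @param input_dir Corpus directory (see [read_corpus()]).
#' @param out_dir Results directory.
#' @param combination_threshold,combination_tolerance Silence rule for
#'   [group_into_combinations()] when a corpus lacks a combination tier.
#' @param cap Optional per-individual combination cap
#'   ([cap_overrepresented()]); `NULL` = off.
#' @param relabel Segment label merge applied on ingest.
#' @param preprocess A [preprocess_config()].
#' @param n_perm,n_iter,alpha Permuted-label and transition-test parameters.
#' @param call_tokens Token type at the call level (`"group"` or
#'   `"simplified"`).
#' @param seed Master seed recorded in, and used throughout, the bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir = file.path(input_dir,
                                                           "results"),
                            combination_threshold = 0.5,
                            combination_tolerance = 0.15, cap = NULL,
                            relabel = c(HL = "LH", US = "SH"),
                            preprocess = preprocess_config(), n_perm = 1L,
                            n_iter = 10000L, alpha = 0.05,
                            call_tokens = "group", seed = 42L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full multi-level combinatoriality analysis
#'
#' Orchestrates ingest, segment relabelling, optional over-representation
#' capping, gap statistics, spectrogram preprocessing, latent-space
#' projection with predictor evaluation (hand label, caller identity, group,
#' site, sex) at segment and call level, within-class positional evaluations
#' for LH and NL, and transition permutation tests at both combinatorial
#' levels. All tables are written as CSV under `cfg$out_dir` together with a
#' JSON manifest of every seed and parameter used.
#'
#' @param cfg A [pipeline_config()], or a path to a YAML file with its
#'   fields.
#' @return The results bundle (named list), invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) {
    y <- yaml::read_yaml(cfg)
    y$preprocess <- do.call(preprocess_config, y$preprocess %||% list())
    cfg <- do.call(pipeline_config, y)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  corpus <- stage("ingest", read_corpus(cfg$input_dir))
  anns <- lapply(corpus$annotations, relabel_segments, mapping = cfg$relabel)
  anns <- lapply(anns, function(ann) {
    if (!nrow(ann$combinations) && nrow(ann$calls)) {
      ann$combinations <- group_into_combinations(
        ann$calls, cfg$combination_threshold,
        cfg$combination_tolerance)[, c("label", "start", "end")]
      validate_annotation_set(ann)
    }
    ann
  })
  if (!is.null(cfg$cap))
    anns <- stage("subsample", cap_overrepresented(anns, cfg$cap, cfg$seed))

  gaps <- stage("gaps", list(
    between_segment = gap_statistics(anns, "between-segment"),
    between_call = gap_statistics(anns, "between-call")))

  seg_data <- stage("preprocess",
                    build_dataset(anns, corpus$audio_dir, "segment",
                                  cfg$preprocess))
  call_data <- stage("preprocess",
                     build_dataset(anns, corpus$audio_dir, "call",
                                   cfg$preprocess))

  preds <- c("label", "individual", "group", "site", "sex")
  seg_emb <- stage("embed", project(seg_data, seed = cfg$seed))
  seg_eval <- stage("evaluate",
                    evaluate_predictors(seg_emb, preds, seed = cfg$seed))
  call_emb <- stage("embed", project(call_data, seed = cfg$seed))
  call_eval <- stage("evaluate",
                     evaluate_predictors(call_emb, c("call_group",
                                                     preds[-1]),
                                         seed = cfg$seed))

  within <- stage("within-class", lapply(c(LH = "LH", NL = "NL"),
                                         within_class_eval, data = seg_data,
                                         cfg = cfg))

  seg_seqs <- unlist(lapply(anns, derive_sequences, level = "segment"),
                     recursive = FALSE)
  call_seqs <- unlist(lapply(anns, derive_sequences, level = "call",
                             call_labels = cfg$call_tokens),
                      recursive = FALSE)
  seg_test <- stage("transitions", permutation_test(
    sequence_corpus(seg_seqs, level = "segment->call"),
    n_iter = cfg$n_iter, alpha = cfg$alpha, seed = cfg$seed,
    keep_null = FALSE))
  call_test <- stage("transitions", permutation_test(
    sequence_corpus(call_seqs, level = "call->combination"),
    n_iter = cfg$n_iter, alpha = cfg$alpha, seed = cfg$seed,
    keep_null = FALSE))

  bundle <- list(gaps = gaps, segment_dataset = seg_data,
                 call_dataset = call_data, segment_embedding = seg_emb,
                 call_embedding = call_emb, segment_evaluation = seg_eval,
                 call_evaluation = call_eval, within_class = within,
                 segment_transitions = seg_test,
                 call_transitions = call_test, config = cfg)
  stage("write", write_bundle(bundle, cfg))
  invisible(bundle)
}

within_class_eval <- function(cls, data, cfg) {
  idx <- which(data$labels$label == cls &
                 !is.na(data$labels$position_category))
  if (length(idx) <= max(10, 15) ||
      length(unique(data$labels$position_category[idx])) < 2 ||
      min(table(data$labels$position_category[idx])) < 2)
    return(NULL)
  sub <- data
  sub$features <- data$features[idx, , drop = FALSE]
  sub$labels <- data$labels[idx, , drop = FALSE]
  emb <- project(sub, seed = cfg$seed,
                 n_neighbors = min(15L, length(idx) - 1L))
  permuted_label_test(emb, sub$labels$position_category, n_perm = cfg$n_perm,
                      seed = cfg$seed, predictor = "position_category")
}

write_bundle <- function(bundle, cfg) {
  out <- cfg$out_dir
  gtab <- do.call(rbind, lapply(bundle$gaps, function(g)
    data.frame(level = g$level, n = g$n, mean = g$mean, sd = g$sd,
               max = g$max)))
  utils::write.csv(gtab, file.path(out, "gap_statistics.csv"),
                   row.names = FALSE)
  for (lv in c("segment", "call")) {
    emb <- bundle[[paste0(lv, "_embedding")]]
    utils::write.csv(data.frame(unit_ref = emb$unit_refs,
                                x = emb$coords[, 1], y = emb$coords[, 2]),
                     file.path(out, paste0(lv, "_coordinates.csv")),
                     row.names = FALSE)
    utils::write.csv(bundle[[paste0(lv, "_evaluation")]]$table,
                     file.path(out, paste0(lv, "_evaluation.csv")),
                     row.names = FALSE)
    export_transition_graph(bundle[[paste0(lv, "_transitions")]],
                            file.path(out, paste0(lv, "_transitions.csv")))
  }
  wc <- bundle$within_class
  wc_tab <- do.call(rbind, lapply(names(wc), function(nm) {
    if (is.null(wc[[nm]])) return(NULL)
    data.frame(class = nm, S = wc[[nm]]$S, H = wc[[nm]]$H, df = wc[[nm]]$df,
               p = wc[[nm]]$p, n = wc[[nm]]$n)
  }))
  if (!is.null(wc_tab))
    utils::write.csv(wc_tab, file.path(out, "within_class_evaluation.csv"),
                     row.names = FALSE)
  manifest <- list(
    seed = cfg$seed, n_iter = cfg$n_iter, n_perm = cfg$n_perm,
    alpha = cfg$alpha,
    combination_threshold = cfg$combination_threshold,
    combination_tolerance = cfg$combination_tolerance,
    cap = cfg$cap, relabel = as.list(cfg$relabel),
    preprocess = unclass(cfg$preprocess),
    embedding = bundle$segment_embedding$params,
    n_units = list(segments = nrow(bundle$segment_dataset$features),
                   calls = nrow(bundle$call_dataset$features)),
    per_individual = as.list(table(bundle$segment_dataset$labels$individual)))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
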