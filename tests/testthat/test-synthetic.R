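test_that("the generator spec enforces its structural invariants", {
  expect_s3_class(generator_spec(n_combinations = 1), "generator_spec")
  bad <- default_segment_transition()
  bad["DS", "DS"] <- 0.5
  expect_error(generator_spec(segment_transition = bad), "sum to 1")
  expect_error(generator_spec(call_length_range = c(1, 9)), "\\[1, 7\\]")
  expect_error(generator_spec(combination_length_range = c(1, 5)),
               "\\[2, 5\\]")
  expect_error(generator_spec(gap_segment = list(mean = 0.7, sd = 0.1,
                                                 min = 0.6, max = 0.8)),
               "ordered")
})

test_that("sampled manifests honour the length and hierarchy bounds", {
  spec <- generator_spec(n_combinations = 30, n_individuals = 4,
                         n_groups = 2, seed = 3)
  man <- sample_sequences(spec)
  u <- man$units
  call_len <- table(u$call_id)
  expect_true(all(call_len >= 1 & call_len <= 7))
  comb_len <- tapply(u$call_id, u$comb_id, function(x) length(unique(x)))
  expect_true(all(comb_len >= 2 & comb_len <= 5))
  expect_setequal(unique(u$label), c("DS", "LH", "NL", "SH"))
  # group labels match the composition of their calls
  first <- u[!duplicated(u$call_id), ]
  comp <- tapply(u$label, u$call_id, function(s) assign_call_group(s))
  expect_equal(as.character(comp[as.character(first$call_id)]),
               first$call_group)

  # empty corpus
  man0 <- sample_sequences(generator_spec(n_combinations = 0))
  expect_equal(nrow(man0$units), 0L)
  expect_null(man0$realized_segment)
})

test_that("a degenerate single-state chain yields constant sequences", {
  tr <- default_segment_transition() * 0
  tr["DS", "DS"] <- 1
  tr["LH", "DS"] <- 1; tr["NL", "DS"] <- 1; tr["SH", "DS"] <- 1
  spec <- generator_spec(n_combinations = 5, n_individuals = 2, n_groups = 2,
                         segment_transition = tr,
                         initial_distribution = c(DS = 1, LH = 0, NL = 0,
                                                  SH = 0),
                         call_group_transition = NULL, seed = 4)
  man <- sample_sequences(spec)
  expect_true(all(man$units$label == "DS"))
})

test_that("rendering is byte-deterministic given spec and seed", {
  spec <- generator_spec(n_combinations = 6, n_individuals = 2, n_groups = 2,
                         seed = 9)
  man <- sample_sequences(spec)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  render_audio(man, spec, d1)
  render_audio(man, spec, d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("parsed rendered corpora close the loop with the manifest", {
  fx <- fixture_corpus("base", coart = coart_rules())
  anns <- fx$corpus$annotations
  # transition-count closure at both levels, exactly
  seg_seqs <- unlist(lapply(anns, derive_sequences, level = "segment"),
                     recursive = FALSE)
  seg_tm <- count_transitions(sequence_corpus(seg_seqs,
                                              alphabet = c("DS", "LH", "NL",
                                                           "SH")))
  expect_identical(seg_tm$counts, fx$manifest$realized_segment$counts)
  call_seqs <- unlist(lapply(anns, derive_sequences, level = "call"),
                      recursive = FALSE)
  call_tm <- count_transitions(sequence_corpus(
    call_seqs, alphabet = c("other", "LH-containing", "lone-NL")))
  expect_identical(call_tm$counts, fx$manifest$realized_call$counts)
  # unit counts
  expect_equal(sum(vapply(anns, function(a) nrow(a$segments), integer(1))),
               nrow(fx$manifest$units))
})

test_that("rendered corpora respect the three-scale silence regime", {
  fx <- fixture_corpus("base", coart = coart_rules())
  anns <- fx$corpus$annotations
  grid <- 1.5 / fx$spec$sample_rate # boundary quantisation slack
  gs <- gap_statistics(anns, "between-segment")
  expect_lte(gs$max, fx$spec$gap_segment$max + grid)
  gc <- gap_statistics(anns, "between-call")
  expect_lte(gc$max, fx$spec$gap_call$max + grid)
  # combination grouping at the 0.5 s rule recovers the manifest partition
  for (ann in anns) {
    rec <- group_into_combinations(ann$calls, 0.5, 0.15)
    expect_equal(rec$start, ann$combinations$start, tolerance = 1e-6)
    expect_equal(rec$end, ann$combinations$end, tolerance = 1e-6)
  }
})

test_that("coarticulation rules shift only the targeted units", {
  spec <- generator_spec(n_combinations = 20, n_individuals = 3,
                         n_groups = 2, seed = 6)
  man <- sample_sequences(spec)
  expect_identical(inject_coarticulation(man, list()), man)
  mod <- inject_coarticulation(man, list(list(class = "LH",
                                              category = "precedes-DS",
                                              freq_shift = 800)))
  poscat <- manifest_position_category(man)
  hit <- man$units$label == "LH" & poscat == "precedes-DS"
  expect_true(any(hit))
  expect_true(all(mod$units$freq_shift[hit] == 800))
  expect_true(all(mod$units$freq_shift[!hit] == 0))
  expect_error(inject_coarticulation(man, list(list(class = "QQ",
                                                    category = "lone"))),
               "label error")
})

test_that("out-of-band class frequencies are refused at render time", {
  spec <- generator_spec(n_combinations = 2, n_individuals = 2, n_groups = 2,
                         seed = 2)
  spec$acoustics$LH$freq <- 30000
  man <- sample_sequences(generator_spec(n_combinations = 2,
                                         n_individuals = 2, n_groups = 2,
                                         seed = 2))
  expect_error(render_audio(man, spec, tempfile()), "Nyquist")
})
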