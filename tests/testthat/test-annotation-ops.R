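test_that("segment relabelling merges sparse classes and keeps the rest", {
  meta <- recording_meta("r", "i", "g")
  segments <- data.frame(label = c("HL", "US", "DS"),
                         start = c(0.1, 0.25, 0.4), end = c(0.2, 0.35, 0.5))
  calls <- data.frame(label = "c", start = 0.1, end = 0.5)
  ann <- annotation_set(meta, segments, calls)
  out <- relabel_segments(ann)
  expect_equal(out$segments$label, c("LH", "SH", "DS"))
  expect_equal(out$segments$start, ann$segments$start)
  expect_error(relabel_segments(ann, c(HL = "LH"), strict = TRUE),
               "label error")
})

test_that("calls are grouped into combinations by the silence rule", {
  calls <- data.frame(label = c("a", "b", "c"),
                      start = c(0, 1.1, 2.5), end = c(1, 2.2, 3.0))
  # gaps 0.1 and 0.3: one combination of all three calls
  one <- group_into_combinations(calls, threshold = 0.5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_calls, 3L)
  expect_equal(one$start, 0)
  expect_equal(one$end, 3.0)

  # gaps 0.1 and 1.2: two-call combination, third call discrete
  calls2 <- data.frame(label = c("a", "b", "c"),
                       start = c(0, 1.1, 3.4), end = c(1, 2.2, 4.0))
  two <- group_into_combinations(calls2, threshold = 0.5)
  expect_equal(nrow(two), 1L)
  expect_equal(two$n_calls, 2L)
  expect_equal(two$end, 2.2)

  # a single call yields no combination
  expect_equal(nrow(group_into_combinations(calls[1, ])), 0L)

  # a gap just inside threshold + tolerance is still merged
  calls3 <- data.frame(label = c("a", "b"), start = c(0, 1.6),
                       end = c(1, 2.0))
  expect_equal(nrow(group_into_combinations(calls3, 0.5, 0.15)), 1L)
  expect_equal(nrow(group_into_combinations(calls3, 0.5, 0)), 0L)

  expect_error(group_into_combinations(calls[c(2, 1, 3), ]), "ordering")
})

test_that("sequences are derived per parent unit in time order", {
  ann <- tiny_annotation()
  seqs <- derive_sequences(ann, "segment")
  expect_equal(seqs, list(c("NL", "DS"), c("LH", "DS")))
  cseqs <- derive_sequences(ann, "call", call_labels = "group")
  expect_equal(cseqs, list(c("other", "LH-containing")))
  cseqs2 <- derive_sequences(ann, "call", call_labels = "simplified")
  expect_equal(cseqs2, list(c("NL-DS", "LH-DS")))
})

test_that("gap statistics cover abutting, constant and mixed regimes", {
  meta <- recording_meta("r", "i", "g")
  # abutting segments: zero gap
  segs <- data.frame(label = c("DS", "SH"), start = c(0.1, 0.3),
                     end = c(0.3, 0.4))
  ann <- annotation_set(meta, segs,
                        data.frame(label = "c", start = 0.1, end = 0.4))
  g <- gap_statistics(ann, "between-segment")
  expect_equal(g$gaps, 0)
  expect_equal(g$max, 0)

  # constant 0.02 s gaps: mean == max == 0.02
  segs2 <- data.frame(label = c("DS", "SH", "DS"),
                      start = c(0.1, 0.32, 0.54), end = c(0.3, 0.52, 0.74))
  ann2 <- annotation_set(meta, segs2,
                         data.frame(label = "c", start = 0.1, end = 0.74))
  g2 <- gap_statistics(ann2, "between-segment")
  expect_equal(g2$mean, 0.02)
  expect_equal(g2$max, 0.02)
  expect_equal(g2$n, 2L)

  # between-call gaps pooled over recordings, inside combinations only
  g3 <- gap_statistics(list(tiny_annotation(), tiny_annotation()),
                       "between-call")
  expect_equal(g3$gaps, c(0.4, 0.4))
  expect_equal(g3$sd, 0)
})

test_that("call labels collapse consecutive repeats only", {
  expect_equal(simplify_call_label(c("SH", "SH", "SH", "LH")), "SH-LH")
  expect_equal(simplify_call_label("NL"), "NL")
  expect_equal(simplify_call_label(c("DS", "SH", "DS")), "DS-SH-DS")
  expect_error(simplify_call_label(character(0)), "input error")
})

test_that("call groups partition all calls into exactly three classes", {
  expect_equal(assign_call_group(c("SH", "DS", "LH")), "LH-containing")
  expect_equal(assign_call_group(c("SH", "NL", "DS")), "other")
  expect_equal(assign_call_group("NL"), "lone-NL")
  expect_equal(assign_call_group(c("NL", "NL")), "other")
  expect_error(assign_call_group(c("XX")), "label error")
  # exhaustive and mutually exclusive over random sequences
  set.seed(1)
  for (i in 1:50) {
    s <- sample(c("DS", "LH", "NL", "SH"), sample(1:7, 1), replace = TRUE)
    expect_true(assign_call_group(s) %in%
                  c("LH-containing", "lone-NL", "other"))
  }
})

test_that("positional categories follow the within-call arrangement rules", {
  meta <- recording_meta("r", "i", "g")
  segs <- data.frame(label = c("LH", "DS", "LH", "NL", "NL", "DS"),
                     start = c(0.1, 0.31, 0.6, 1.2, 1.8, 2.01),
                     end = c(0.3, 0.5, 0.8, 1.4, 2.0, 2.2))
  calls <- data.frame(label = c("a", "b", "c", "d"),
                      start = c(0.1, 0.6, 1.2, 1.8),
                      end = c(0.5, 0.8, 1.4, 2.2))
  ann <- annotation_set(meta, segs, calls)
  lh <- assign_position_category(ann, "LH")
  expect_equal(lh$category, c("precedes-DS", "call-final-or-lone"))
  nl <- assign_position_category(ann, "NL")
  expect_equal(nl$category, c("lone", "combined"))
  expect_equal(nrow(assign_position_category(ann, "SH")), 0L)
})
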