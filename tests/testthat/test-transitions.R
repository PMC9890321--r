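test_that("transition counting matches hand enumeration", {
  corp <- sequence_corpus(list(c("A", "B", "A"), c("B", "A")))
  tm <- count_transitions(corp)
  expect_equal(tm$counts["A", "B"], 1L)
  expect_equal(tm$counts["B", "A"], 2L)
  expect_equal(tm$probs["A", "B"], 1)
  expect_equal(tm$probs["B", "A"], 1)
  expect_equal(sum(tm$counts), 3L)

  # all length-1 sequences: no transitions at all
  tm0 <- count_transitions(sequence_corpus(list("A", "B", "A")))
  expect_true(all(tm0$counts == 0))
  expect_true(all(tm0$probs == 0))

  expect_error(sequence_corpus(list(c("A", "Z")), alphabet = c("A", "B")),
               "label error")
  expect_error(sequence_corpus(list(character(0))), "non-empty")
})

test_that("randomization preserves token and length multisets", {
  corp <- sequence_corpus(list(c("A", "B", "A", "C"), c("B", "A"), "C",
                               c("C", "B", "B")))
  for (s in 1:20) {
    r <- randomize_corpus(corp, seed = s)
    expect_equal(sort(unlist(r$sequences)), sort(unlist(corp$sequences)))
    expect_equal(sort(lengths(r$sequences)), sort(lengths(corp$sequences)))
  }
  # degenerate all-identical corpus is invariant
  same <- sequence_corpus(list(c("A", "A"), c("A", "A", "A")))
  r <- randomize_corpus(same, seed = 1)
  expect_equal(r$sequences, same$sequences)
})

test_that("Monte-Carlo p-values agree with the exhaustive-enumeration oracle", {
  # {A,A,B,B} into two length-2 sequences: 6 distinct assignments
  tokens <- c("A", "A", "B", "B")
  lens <- c(2L, 2L)
  corp <- sequence_corpus(list(c("A", "B"), c("A", "B")))
  res <- permutation_test(corp, n_iter = 10000, seed = 21)
  tol <- 2 / sqrt(10000)
  for (from in c("A", "B")) for (to in c("A", "B")) {
    if (is.na(res$p_two_tailed[from, to])) next
    ex <- oracle_exact_test(tokens, lens, from, to,
                            res$observed$probs[from, to])
    expect_lt(abs(res$p_two_tailed[from, to] - max(ex$p, 1 / (10000 + 1))),
              tol, label = sprintf("|p - exact| [%s->%s]", from, to))
  }

  # a larger multiset with length-3 sequences
  tokens2 <- c("A", "A", "A", "B", "B", "C")
  corp2 <- sequence_corpus(list(c("A", "B", "A"), c("C", "B", "A")))
  res2 <- permutation_test(corp2, n_iter = 10000, seed = 22)
  for (from in c("A", "B", "C")) for (to in c("A", "B", "C")) {
    if (is.na(res2$p_two_tailed[from, to])) next
    ex <- oracle_exact_test(tokens2, c(3L, 3L), from, to,
                            res2$observed$probs[from, to])
    expect_lt(abs(res2$p_two_tailed[from, to] - max(ex$p, 1 / (10000 + 1))),
              tol, label = sprintf("|p - exact| [%s->%s]", from, to))
  }
})

test_that("the Monte-Carlo floor and determinism contracts hold", {
  corp <- sequence_corpus(list(c("A", "B", "A"), c("B", "A"), c("A", "B")))
  res <- permutation_test(corp, n_iter = 100, seed = 5)
  ok <- !is.na(res$p_two_tailed)
  expect_true(all(res$p_two_tailed[ok] >= 1 / 101))
  expect_true(all(res$p_two_tailed[ok] <= 1))
  res2 <- permutation_test(corp, n_iter = 100, seed = 5)
  expect_identical(res$p_two_tailed, res2$p_two_tailed)
  expect_error(permutation_test(corp, n_iter = 0), "n_iter")
})

test_that("a forbidden transition in a structured corpus is detected", {
  # generator never produces A -> A; under random assignment it would be common
  set.seed(31)
  seqs <- replicate(120, {
    len <- sample(2:6, 1)
    s <- character(len)
    s[1] <- sample(c("A", "B"), 1)
    for (i in seq_len(len - 1))
      s[i + 1] <- if (s[i] == "A") "B" else sample(c("A", "B"), 1)
    s
  }, simplify = FALSE)
  corp <- sequence_corpus(seqs)
  res <- permutation_test(corp, n_iter = 2000, seed = 32)
  expect_equal(res$observed$probs["A", "A"], 0)
  expect_true(res$significant["A", "A"])
  expect_lt(res$p_two_tailed["A", "A"], 0.05)
})

test_that("an observed value at the null median is not significant", {
  # balanced unstructured corpus: every observed cell sits inside the null
  set.seed(33)
  seqs <- split(sample(rep(c("A", "B"), 60)), rep(1:40, each = 3))
  corp <- sequence_corpus(seqs)
  res <- permutation_test(corp, n_iter = 2000, seed = 34)
  mid <- abs(res$observed$probs - res$null_quantiles$median) < 0.02
  expect_true(all(!res$significant[mid & !is.na(res$significant)]))
  expect_true(all(res$p_two_tailed[mid & !res$undefined] > 0.5))
})

test_that("states absent from a level are reported as undefined", {
  corp <- sequence_corpus(list(c("A", "B"), c("B", "A")),
                          alphabet = c("A", "B", "C"))
  res <- permutation_test(corp, n_iter = 200, seed = 7)
  expect_true(all(res$undefined["C", ]))
  expect_true(all(is.na(res$p_two_tailed["C", ])))
})

test_that("the exported edge list mirrors the matrices", {
  corp <- sequence_corpus(list(c("A", "B", "A"), c("B", "A")))
  res <- permutation_test(corp, n_iter = 200, seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  edges <- export_transition_graph(res, p)
  expect_equal(nrow(edges), 4L)
  back <- read.csv(p)
  expect_equal(back$probability,
               as.numeric(t(res$observed$probs)))
  expect_equal(back$count, as.integer(t(res$observed$counts)))

  png_path <- withr::local_tempfile(fileext = ".png")
  export_transition_graph(res, p, plot_path = png_path)
  expect_true(file.size(png_path) > 0)
})
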