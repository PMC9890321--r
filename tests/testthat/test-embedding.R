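test_that("projection is deterministic and separates distant classes", {
  set.seed(7)
  a <- matrix(rnorm(40 * 20, mean = 0), ncol = 20)
  b <- matrix(rnorm(40 * 20, mean = 8), ncol = 20)
  x <- rbind(a, b)
  lab <- rep(c("a", "b"), each = 40)

  e1 <- project(x, seed = 3)
  e2 <- project(x, seed = 3)
  expect_identical(e1$coords, e2$coords)

  cen <- rbind(colMeans(e1$coords[lab == "a", ]),
               colMeans(e1$coords[lab == "b", ]))
  spread <- max(tapply(seq_along(lab), lab, function(i)
    mean(sqrt(rowSums(sweep(e1$coords[i, ], 2, colMeans(e1$coords[i, ]))^2)))))
  expect_gt(sqrt(sum((cen[1, ] - cen[2, ])^2)), spread)

  expect_error(project(x[1:5, ]), "at least 10 rows")
  expect_error(project(x[1:12, ], n_neighbors = 15), "n_neighbors")
})

test_that("identical rows collapse to coincident coordinates", {
  x <- matrix(rep(rnorm(20), each = 30), nrow = 30)
  emb <- project(x, seed = 1)
  expect_equal(max(stats::dist(emb$coords)), 0)
})

test_that("silhouette behaves at its limits and under rigid motion", {
  # two tight point-masses far apart: S -> 1
  co <- rbind(matrix(rnorm(40, sd = 1e-3), ncol = 2),
              matrix(rnorm(40, sd = 1e-3) + 100, ncol = 2))
  lab <- rep(c("a", "b"), each = 20)
  expect_gt(silhouette_by_predictor(co, lab)$S, 0.99)

  # invariance under rotation + translation
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  set.seed(2)
  co2 <- matrix(rnorm(200), ncol = 2)
  lab2 <- rep(c("a", "b"), 50)
  s_orig <- silhouette_by_predictor(co2, lab2)$S
  s_moved <- silhouette_by_predictor(sweep(co2 %*% rot, 2, c(5, -3), "+"),
                                     lab2)$S
  expect_equal(s_orig, s_moved, tolerance = 1e-12)

  # random labels on one blob: S near 0 (Monte-Carlo at n = 1000)
  set.seed(4)
  blob <- matrix(rnorm(2000), ncol = 2)
  s_null <- silhouette_by_predictor(blob, sample(rep(c("a", "b"), 500)))$S
  expect_lt(abs(s_null), 0.05)

  expect_error(silhouette_by_predictor(co, rep("a", 40)), "2 classes")
})

test_that("the permuted-label H equals the rank-formula statistic", {
  set.seed(5)
  co <- rbind(matrix(rnorm(60, sd = 0.5), ncol = 2),
              matrix(rnorm(60, sd = 0.5) + 4, ncol = 2))
  lab <- rep(c("a", "b"), each = 30)
  res <- permuted_label_test(co, lab, n_perm = 1, seed = 9)
  # recompute the permuted widths exactly as the test does, then apply the
  # hand rank formula
  obs <- res$per_point_silhouette
  set.seed(9)
  perm_lab <- sample(lab)
  perm <- as.numeric(cluster::silhouette(as.integer(factor(perm_lab)),
                                         dist = stats::dist(co))[, 3])
  expect_equal(res$H, oracle_kw_H(obs, perm), tolerance = 1e-10)
  expect_equal(res$df, 1L)
  expect_lt(res$p, 0.001) # strong structure vs its own permutation
})

test_that("testing a random labelling against permutations is null", {
  set.seed(6)
  co <- matrix(rnorm(400), ncol = 2)
  lab <- sample(rep(c("a", "b"), each = 100))
  res <- permuted_label_test(co, lab, seed = 11)
  expect_gt(res$p, 0.05)
  expect_lt(abs(res$S), 0.1)
})

test_that("permuted-label p-values are uniform under the null", {
  set.seed(3)
  coords <- matrix(rnorm(120), ncol = 2)
  ps <- vapply(1:200, function(i) {
    lab <- sample(rep(c("a", "b"), each = 30))
    permuted_label_test(coords, lab, seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("balanced subsampling equalises class counts deterministically", {
  fx <- fixture_corpus("base", coart = coart_rules())
  ds <- build_dataset(fx$corpus$annotations, fx$corpus$audio_dir, "segment")
  bal <- balanced_subsample(ds, "label", seed = 8)
  tab <- table(bal$labels$label)
  expect_true(all(tab == min(table(ds$labels$label))))
  bal2 <- balanced_subsample(ds, "label", seed = 8)
  expect_identical(bal$labels$unit_ref, bal2$labels$unit_ref)
  # already-balanced input comes back with the same rows
  re <- balanced_subsample(bal, "label", seed = 1)
  expect_setequal(re$labels$unit_ref, bal$labels$unit_ref)
})

test_that("predictor evaluation reports per-individual counts", {
  set.seed(12)
  n <- 60
  ds <- structure(list(
    features = matrix(rnorm(n * 20), ncol = 20) +
      outer(rep(c(0, 6), each = n / 2), rep(1, 20)),
    labels = data.frame(unit_ref = as.character(1:n),
                        label = rep(c("x", "y"), each = n / 2),
                        individual = rep(c("i1", "i2", "i3"), n / 3),
                        stringsAsFactors = FALSE),
    level = "segment"), class = "spectrogram_dataset")
  emb <- project(ds, seed = 2)
  ev <- evaluate_predictors(emb, c("label", "individual"), seed = 2)
  expect_equal(nrow(ev$table), 2L)
  expect_equal(sum(ev$individual_counts), n)
  expect_gt(ev$table$S[ev$table$predictor == "label"], 0.5)
})
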