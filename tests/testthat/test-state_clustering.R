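test_that("k-means recovers well-separated blobs exactly", {
  blobs <- make_blobs(k = 4, per = 30, sep = 40, sd = 0.5, seed = 2)
  model <- fit_states(blobs$x, k = 4, seed = 1)
  expect_true(perfect_match(model$labels, blobs$labels))
  expect_equal(ari(model$labels, blobs$labels), 1)
})

test_that("state fitting is deterministic and validates its inputs", {
  blobs <- make_blobs(k = 3, per = 20, seed = 5)
  m1 <- fit_states(blobs$x, k = 3, seed = 7)
  m2 <- fit_states(blobs$x, k = 3, seed = 7)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$centroids, m2$centroids)

  m_one <- fit_states(blobs$x, k = 1, seed = 1)
  expect_true(all(m_one$labels == 0))
  expect_error(fit_states(blobs$x[1:3, ], k = 5, seed = 1), "exceeds")
  expect_true(all(m1$labels %in% 0:2))
})

test_that("inertia is non-increasing in k on a fixed matrix", {
  blobs <- make_blobs(k = 6, per = 25, sep = 10, sd = 2, seed = 3)
  inertias <- vapply(2:10, function(k) fit_states(blobs$x, k, seed = 1)$inertia, 0)
  expect_true(all(diff(inertias) <= 1e-8))
})

test_that("nearest-centroid prediction reproduces training labels", {
  blobs <- make_blobs(k = 3, per = 20, seed = 8)
  model <- fit_states(blobs$x, k = 3, seed = 2)
  expect_equal(predict(model, blobs$x), model$labels)
})

test_that("the 2-D embedding is reproducible, per-row, and independent of clustering", {
  blobs <- make_blobs(k = 3, per = 15, seed = 4)
  labels_before <- fit_states(blobs$x, k = 3, seed = 9)$labels
  emb <- embed_2d(blobs$x, seed = 42)
  expect_equal(dim(emb), c(nrow(blobs$x), 2))
  emb2 <- embed_2d(blobs$x, seed = 42)
  expect_identical(emb, emb2)
  labels_after <- fit_states(blobs$x, k = 3, seed = 9)$labels
  expect_identical(labels_before, labels_after)
  expect_error(embed_2d(blobs$x[1:2, ]), "3 rows")
})

make_assignment <- function(rank_diff, cluster, recording = "r1") {
  structure(data.frame(recording = recording,
                       frame = seq_along(cluster),
                       cluster = cluster, rank_diff = rank_diff,
                       stringsAsFactors = FALSE),
            class = c("state_assignment", "data.frame"))
}

test_that("percent enrichment follows the share-difference formula", {
  # identical cluster shares across strata -> all zeros
  a <- make_assignment(rank_diff = rep(c(1, 2), each = 4),
                       cluster = rep(c(0, 0, 1, 1), 2))
  enr <- percent_enriched(a)
  expect_equal(unname(enr$enrichment), matrix(0, 2, 2))

  # all rank-diff-3 frames in cluster 4 which holds 25% of all frames:
  # enrichment = 1 - 0.25 = 0.75
  rd <- c(rep(1, 9), rep(3, 3))
  cl <- c(rep(0, 9), rep(4, 3))
  enr2 <- percent_enriched(make_assignment(rd, cl))
  expect_equal(enr2$enrichment["3", "4"], 1 - 3 / 12)
  expect_equal(enr2$enrichment["3", "0"], 0 - 9 / 12)

  # every row sums to zero; all entries within [-1, 1]
  set.seed(31)
  for (i in 1:20) {
    n <- 200
    a_rand <- make_assignment(sample(1:3, n, replace = TRUE),
                              sample(0:5, n, replace = TRUE))
    e <- percent_enriched(a_rand)
    expect_equal(unname(rowSums(e$enrichment)), rep(0, nrow(e$enrichment)),
                 tolerance = 1e-12)
    expect_true(all(e$enrichment >= -1 & e$enrichment <= 1))
    expect_equal(sum(e$n_ij), e$N)
  }

  # a requested stratum with no frames is NA and flagged, not silently zero
  expect_warning(e3 <- percent_enriched(make_assignment(rep(1, 5), rep(0, 5)),
                                        strata = c(1, 3)), "zero frames")
  expect_true(all(is.na(e3$enrichment["3", ])))

  # frames without rank metadata are excluded
  a_na <- make_assignment(c(1, 1, NA, NA), c(0, 1, 0, 1))
  expect_equal(percent_enriched(a_na)$N, 2)
})

test_that("cluster distributions are per-recording fractions summing to one", {
  a <- make_assignment(rank_diff = NA,
                       cluster = c(2, 2, 2, 0, 1, 1),
                       recording = rep(c("r1", "r2"), each = 3))
  d <- cluster_distribution(a)
  expect_equal(unname(rowSums(d)), c(1, 1))
  expect_equal(d["r1", "2"], 1)
  expect_equal(d["r1", "0"], 0)
  expect_equal(d["r2", "1"], 2 / 3)

  # recordings with equal label multisets give identical rows
  b <- make_assignment(rank_diff = NA,
                       cluster = c(0, 1, 1, 1, 1, 0),
                       recording = rep(c("rA", "rB"), each = 3))
  db <- cluster_distribution(b)
  expect_equal(unname(db["rA", ]), unname(db["rB", ]))
})

test_that("cluster frame sampling is capped, unique, and reproducible", {
  a <- make_assignment(rank_diff = NA, cluster = c(rep(0, 1000), rep(1, 50)))
  s <- sample_cluster_frames(a, n = 600, seed = 3)
  expect_equal(nrow(s[["0"]]), 600)
  expect_equal(anyDuplicated(s[["0"]]$frame), 0)
  expect_equal(nrow(s[["1"]]), 50) # exhausted cluster returns all rows
  s2 <- sample_cluster_frames(a, n = 600, seed = 3)
  expect_identical(s, s2)
  s3 <- sample_cluster_frames(a, n = 600, seed = 4)
  expect_false(identical(s[["0"]], s3[["0"]]))
  expect_error(sample_cluster_frames(a, n = 0), ">= 1")
})

test_that("state assignment joins provenance with rank metadata", {
  blobs <- make_blobs(k = 2, per = 10, seed = 6)
  fm <- structure(list(x = blobs$x,
                       provenance = data.frame(
                         recording = rep(c("r1", "r2"), each = 10),
                         frame = rep(seq(1, 28, 3), 2)),
                       step = 3),
                  class = "feature_matrix")
  model <- fit_states(fm, k = 2, seed = 1)
  ranks <- data.frame(recording = c("r1", "r2"), rank_a = c(1, 1),
                      rank_b = c(2, 4))
  a <- state_assignment(model, ranks = ranks)
  expect_equal(unique(a$rank_diff[a$recording == "r1"]), 1)
  expect_equal(unique(a$rank_diff[a$recording == "r2"]), 3)
  expect_equal(nrow(a), 20)
})
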