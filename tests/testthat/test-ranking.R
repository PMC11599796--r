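test_that("David's scores match hand-evaluated small cases", {
  # A beats B 3-0: P_AB = 1, w = (1, 0), w2 = (0, 0), l = (0, 1),
  # l2 = (0, 0) -> DS = (+1, -1)
  d <- david_scores(dyad_matches("urine", 3, 0))
  expect_equal(unname(d$ds), c(1, -1))
  # 1-1 split: symmetric, DS = (0, 0)
  d2 <- david_scores(dyad_matches("urine", 1, 1))
  expect_equal(unname(d2$ds), c(0, 0))
  # ties never enter the win matrix
  d3 <- david_scores(dyad_matches("urine", 3, 0, ties = 4))
  expect_equal(d3$alpha["A", "B"], 3L)
  expect_equal(sum(d3$alpha), 3)
  expect_equal(unname(d3$ds), c(1, -1))
})

test_that("David's scores agree with the brute-force oracle on exhaustive small win matrices", {
  # exhaustive n = 2: all count pairs 0..3
  for (ab in 0:3) for (ba in 0:3) {
    if (ab + ba == 0) next
    alpha <- matrix(c(0, ba, ab, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    expect_equal(unname(david_scores(alpha)$ds), david_oracle(alpha),
                 tolerance = 1e-12)
  }
  # exhaustive n = 3 with counts 0..2 over the 6 off-diagonal cells
  grid <- expand.grid(rep(list(0:2), 6))
  ids <- c("a", "b", "c")
  for (r in seq_len(nrow(grid))) {
    v <- as.integer(grid[r, ])
    if (sum(v) == 0) next
    alpha <- matrix(0L, 3, 3, dimnames = list(ids, ids))
    alpha[upper.tri(alpha)] <- v[1:3]
    alpha[lower.tri(alpha)] <- v[4:6]
    expect_equal(unname(david_scores(alpha)$ds), david_oracle(alpha),
                 tolerance = 1e-12)
  }
  # random n = 4 matrices, counts 0..3
  set.seed(9)
  for (i in 1:200) {
    alpha <- matrix(sample(0:3, 16, replace = TRUE), 4, 4,
                    dimnames = list(letters[1:4], letters[1:4]))
    diag(alpha) <- 0L
    if (sum(alpha) == 0) next
    expect_equal(unname(david_scores(alpha)$ds), david_oracle(alpha),
                 tolerance = 1e-12)
  }
})

test_that("David's scores sum to zero and are scale-invariant on fully interacting groups", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(3:5, 1)
    alpha <- matrix(sample(0:3, n * n, replace = TRUE), n, n,
                    dimnames = list(paste0("m", 1:n), paste0("m", 1:n)))
    diag(alpha) <- 0L
    # force every dyad to interact
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (alpha[a, b] + alpha[b, a] == 0) alpha[a, b] <- 1L
    }
    ds <- david_scores(alpha)$ds
    expect_equal(sum(ds), 0, tolerance = 1e-10)
    # multiplying all dyad counts by a common factor leaves P, hence DS, alone
    expect_equal(david_scores(alpha * 3L)$ds, ds, tolerance = 1e-12)
  }
  expect_error(david_scores(dyad_matches("urine", 0, 0, ties = 3)),
               "unmeasurable")
})

test_that("directional consistency index matches counting oracle and extremes", {
  # fully unidirectional dyads -> 1
  uni <- matrix(c(0, 0, 0, 3, 0, 0, 2, 4, 0), 3, 3)
  expect_equal(dci(uni), 1)
  # perfectly bidirectional dyads -> 0
  bi <- matrix(c(0, 2, 1, 2, 0, 3, 1, 3, 0), 3, 3)
  expect_equal(dci(bi), 0)
  # toy table: dyads (5,1) and (2,2) -> (7 - 3) / 10
  toy <- matrix(0, 3, 3)
  toy[1, 2] <- 5; toy[2, 1] <- 1; toy[1, 3] <- 2; toy[3, 1] <- 2
  expect_equal(dci(toy), 0.4)
  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:5, 1)
    alpha <- matrix(sample(0:4, n * n, replace = TRUE), n, n)
    diag(alpha) <- 0L
    if (sum(alpha) == 0) next
    val <- dci(alpha)
    expect_equal(val, dci_oracle(alpha), tolerance = 1e-12)
    expect_gte(val, 0); expect_lte(val, 1)
    # invariant under relabeling
    perm <- sample(n)
    expect_equal(dci(alpha[perm, perm]), val, tolerance = 1e-12)
  }
  expect_error(dci(matrix(0, 3, 3)), "unmeasurable")
})

test_that("urine outcome applies the 5-spot and 20 percent tie rules", {
  expect_equal(urine_outcome(100, 50), "A_WINS")
  expect_equal(urine_outcome(10, 8), "TIE")       # diff 2 < 5
  expect_equal(urine_outcome(0, 0), "TIE")
  expect_equal(urine_outcome(104, 100), "TIE")    # diff 4 < 5
  # diff 5 passes the spot rule but 5/105 < 20% -> still a tie
  expect_equal(urine_outcome(100, 105), "TIE")
  # diff 5 out of max 25 is exactly 20%: not "<20%", so decisive
  expect_equal(urine_outcome(25, 20), "A_WINS")
  expect_equal(urine_outcome(20, 25), "B_WINS")
  # diff 5 out of max 26 is below 20%: tie
  expect_equal(urine_outcome(26, 21), "TIE")
  expect_error(urine_outcome(-1, 3), "non-negative")
})

test_that("reward match outcome counts decisive trials with a deterministic tie-break", {
  expect_equal(reward_match_outcome(c(rep("m1", 12), rep("m2", 7)), "m1", "m2"),
               "A_WINS")
  expect_equal(reward_match_outcome(c(rep("m1", 5), rep("m2", 5)), "m1", "m2"),
               "A_WINS") # equal counts -> lower identifier
  expect_equal(reward_match_outcome(c(rep("m1", 5), rep("m2", 5)), "m2", "m1"),
               "B_WINS") # same animals, same winner
  expect_equal(reward_match_outcome(rep(NA, 4), "m1", "m2"), "TIE")
  # ties excluded from the denominator: 3 vs 2 decisive with 10 ties
  expect_equal(reward_match_outcome(c(rep("m2", 3), rep("m1", 2), rep(NA, 10)),
                                    "m1", "m2"), "B_WINS")
  expect_error(reward_match_outcome(character(0), "m1", "m2"), "at least one")
  expect_error(reward_match_outcome("m9", "m1", "m2"), "competitors")
})

test_that("dyad stability thresholds are assay-specific and inclusive", {
  # tube: 6 of 8 same winner = 75% exactly -> stable (inclusive)
  expect_equal(classify_dyad_stability(dyad_matches("tube", 6, 2))$status, "STABLE")
  expect_equal(classify_dyad_stability(dyad_matches("tube", 5, 3))$status, "UNSTABLE")
  st <- classify_dyad_stability(dyad_matches("tube", 6, 2))
  expect_equal(st$dominant_id, "A")
  expect_true(is.na(classify_dyad_stability(dyad_matches("tube", 5, 3))$dominant_id))

  # agonistic: < 3 interactions unmeasurable; 3 of 4 = 75% stable
  expect_equal(classify_dyad_stability(dyad_matches("agonistic", 2, 0))$status,
               "UNMEASURABLE")
  expect_equal(classify_dyad_stability(dyad_matches("agonistic", 3, 1))$status,
               "STABLE")
  expect_equal(classify_dyad_stability(dyad_matches("agonistic", 2, 2))$status,
               "UNSTABLE")

  # urine: all decisive with the same winner; any tie breaks stability
  expect_equal(classify_dyad_stability(dyad_matches("urine", 2, 0))$status, "STABLE")
  expect_equal(classify_dyad_stability(dyad_matches("urine", 2, 0, ties = 1))$status,
               "UNSTABLE")
  expect_equal(classify_dyad_stability(dyad_matches("urine", 1, 1))$status, "UNSTABLE")

  # reward: 60% of decisive trials, ties excluded: 3 of 5 decisive = 60%
  expect_equal(classify_dyad_stability(dyad_matches("reward", 3, 2, ties = 6))$status,
               "STABLE")
  expect_equal(classify_dyad_stability(dyad_matches("reward", 5, 4))$status,
               "UNSTABLE") # 5/9 < 60%
  expect_equal(classify_dyad_stability(dyad_matches("reward", 0, 0, ties = 5))$status,
               "UNMEASURABLE")

  mixed <- rbind(as.data.frame(dyad_matches("tube", 1, 0)),
                 as.data.frame(dyad_matches("urine", 1, 0)))
  expect_error(classify_dyad_stability(mixed), "mixed assays")
})

test_that("stability tables cover every dyad in every assay", {
  gen <- generate_matches(hierarchy_config(
    n_animals = 4, beta = 5, tie_prob = 0.1, trials_per_dyad = 8,
    assays = c(tube = FALSE, urine = FALSE), seed = 4))
  tab <- dyad_stability_table(gen$matches)
  expect_equal(nrow(tab), 2 * choose(4, 2))
  expect_true(all(tab$status %in% c("STABLE", "UNSTABLE", "UNMEASURABLE")))
  expect_true(all(!is.na(tab$dominant_id) == (tab$status == "STABLE")))
})
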