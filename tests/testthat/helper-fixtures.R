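# Shared fixtures, built in code.

# Random valid match table for round-trip / property tests.
random_matches <- function(n = 20, seed = 1) {
  set.seed(seed)
  ids <- c("a1", "b2", "c3", "d4")
  pairs <- t(replicate(n, sample(ids, 2)))
  match_records(
    assay = sample(c("agonistic", "urine", "tube", "reward"), n, replace = TRUE),
    cage = "cageX",
    order = sample(1000, n),
    id_a = pairs[, 1], id_b = pairs[, 2],
    outcome = sample(c("A_WINS", "B_WINS", "TIE"), n, replace = TRUE),
    count_a = ifelse(runif(n) < 0.5, NA, sample(0:50, n, replace = TRUE)),
    count_b = ifelse(runif(n) < 0.5, NA, sample(0:50, n, replace = TRUE)))
}

# Dyad match set with a prescribed number of wins for each animal (tube-style).
dyad_matches <- function(assay, wins_a, wins_b, ties = 0) {
  n <- wins_a + wins_b + ties
  match_records(assay = assay, cage = "c", order = seq_len(n),
                id_a = "A", id_b = "B",
                outcome = c(rep("A_WINS", wins_a), rep("B_WINS", wins_b),
                            rep("TIE", ties)))
}

# Independent brute-force David's score oracle: plain loops over the
# definition, no shared code with the implementation.
david_oracle <- function(alpha) {
  n <- nrow(alpha)
  p <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    tot <- alpha[i, j] + alpha[j, i]
    if (i != j && tot > 0) p[i, j] <- alpha[i, j] / tot
  }
  w <- numeric(n); l <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    w[i] <- w[i] + p[i, j]
    l[i] <- l[i] + p[j, i]
  }
  w2 <- numeric(n); l2 <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    w2[i] <- w2[i] + p[i, j] * w[j]
    l2[i] <- l2[i] + p[j, i] * l[j]
  }
  w + w2 - l - l2
}

# Brute-force DCI oracle: count per-dyad majority/minority directions.
dci_oracle <- function(alpha) {
  n <- nrow(alpha)
  h <- 0; l <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    h <- h + max(alpha[i, j], alpha[j, i])
    l <- l + min(alpha[i, j], alpha[j, i])
  }
  (h - l) / (h + l)
}

# A stationary two-animal recording with every node at fixed positions.
static_recording <- function(frames = 10, port = c(0, 0),
                             nose1 = c(10, 40), thorax1 = c(10, 65),
                             nose2 = c(60, 80), thorax2 = c(60, 105)) {
  coords <- array(NA_real_, c(2, 6, frames, 2))
  put <- function(a, node, xy) {
    k <- match(node, c("nose", "forehead", "left_ear", "right_ear",
                       "thorax", "tail_base"))
    coords[a, k, , 1] <<- xy[1]
    coords[a, k, , 2] <<- xy[2]
  }
  fill_skel <- function(a, nose, thorax) {
    dirv <- (nose - thorax) / sqrt(sum((nose - thorax)^2))
    perp <- c(-dirv[2], dirv[1])
    put(a, "nose", nose)
    put(a, "forehead", thorax + 15 * dirv)
    put(a, "left_ear", thorax + 15 * dirv + 8 * perp)
    put(a, "right_ear", thorax + 15 * dirv - 8 * perp)
    put(a, "thorax", thorax)
    put(a, "tail_base", thorax - 30 * dirv)
  }
  fill_skel(1, nose1, thorax1)
  fill_skel(2, nose2, thorax2)
  pose_recording(coords, port = port, fps = 30, id = "static")
}

# Swap the two animals' coordinate blocks.
swap_animals <- function(rec) {
  rec$coords <- rec$coords[c(2, 1), , , , drop = FALSE]
  dimnames(rec$coords)[[1]] <- c("animal1", "animal2")
  rec
}

# Well-separated Gaussian blobs for clustering tests.
make_blobs <- function(k = 8, per = 40, sep = 40, sd = 0.5, d = 7, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  x <- do.call(rbind, lapply(1:k, function(i) {
    sweep(matrix(rnorm(per * d, sd = sd), per, d), 2, centers[i, ], "+")
  }))
  list(x = x, labels = rep(1:k, each = per))
}

# Exhaustive best-permutation label agreement (tiny k only).
perfect_match <- function(labels, truth) {
  k <- length(unique(truth))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  uls <- sort(unique(labels))
  if (length(uls) != k) return(FALSE)
  for (p in perms(sort(unique(truth)))) {
    mapped <- p[match(labels, uls)]
    if (all(mapped == truth)) return(TRUE)
  }
  FALSE
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
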