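# David's score, directional consistency, per-assay outcome rules, and dyad
# stability classification.

#' Win matrix from match records
#'
#' Counts decisive outcomes into a square matrix `alpha` with
#' `alpha[i, j]` = number of wins of animal i over animal j. Ties contribute
#' nothing (David's score is defined on decisive dyadic outcomes only).
#'
#' @param matches a `match_records` data frame for one assay and cage.
#' @param animals optional full roster; defaults to the animals appearing in
#'   `matches`.
#' @return Integer matrix with zero diagonal.
#' @export
win_matrix <- function(matches, animals = NULL) {
  matches <- as.data.frame(matches)
  ids <- sort(unique(c(matches$id_a, matches$id_b, animals)))
  alpha <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  dec <- matches[matches$outcome != "TIE", , drop = FALSE]
  for (i in seq_len(nrow(dec))) {
    w <- if (dec$outcome[i] == "A_WINS") dec$id_a[i] else dec$id_b[i]
    l <- if (dec$outcome[i] == "A_WINS") dec$id_b[i] else dec$id_a[i]
    alpha[w, l] <- alpha[w, l] + 1L
  }
  alpha
}

#' David's scores for one assay and cage
#'
#' David's score ranks each animal by its dyadic win proportions, weighted
#' by the strength of its opponents. With `P[i, j] = alpha[i, j] /
#' (alpha[i, j] + alpha[j, i])` for dyads that interacted (non-interacting
#' dyads contribute 0):
#' `w = rowSums(P)`, `w2 = P %*% w`, `l = colSums(P)`, `l2 = t(P) %*% l`,
#' and `DS = w + w2 - l - l2`. Over a fully interacting group the scores
#' sum to zero.
#'
#' @param matches a `match_records` data frame for one assay and cage, or a
#'   win matrix as returned by [win_matrix()].
#' @param animals optional full roster.
#' @return An object of class `david_scores`: list with `alpha`, `p`, `w`,
#'   `w2`, `l`, `l2`, `ds` and dense `rank` (1 = highest DS).
#' @examples
#' m <- match_records("urine", "c1", 1:3, "a", "b", rep("A_WINS", 3))
#' david_scores(m)$ds  # c(a = 1, b = -1)
#' @export
david_scores <- function(matches, animals = NULL) {
  alpha <- if (is.matrix(matches)) {
    storage.mode(matches) <- "integer"
    matches
  } else {
    win_matrix(matches, animals)
  }
  if (nrow(alpha) < 2) stop_validation("David's score needs at least 2 animals")
  if (any(diag(alpha) != 0)) stop_validation("win matrix must have zero diagonal")
  n_dyad <- alpha + t(alpha)
  if (all(n_dyad == 0)) {
    stop_unmeasurable("no decisive interactions: David's scores are unmeasurable")
  }
  p <- ifelse(n_dyad > 0, alpha / ifelse(n_dyad > 0, n_dyad, 1), 0)
  w <- rowSums(p)
  w2 <- as.vector(p %*% w)
  l <- colSums(p)
  l2 <- as.vector(t(p) %*% l)
  ds <- setNames(w + w2 - l - l2, rownames(alpha))
  structure(list(alpha = alpha, p = p,
                 w = setNames(w, rownames(alpha)),
                 w2 = setNames(w2, rownames(alpha)),
                 l = setNames(l, rownames(alpha)),
                 l2 = setNames(l2, rownames(alpha)),
                 ds = ds, rank = simplify_ranks(ds)),
            class = "david_scores")
}

#' @export
print.david_scores <- function(x, ...) {
  cat("David's scores (", sum(x$alpha), " decisive interactions)\n", sep = "")
  print(data.frame(w = round(x$w, 3), l = round(x$l, 3),
                   DS = round(x$ds, 3), rank = x$rank), ...)
  invisible(x)
}

#' Directional consistency index
#'
#' For each dyad, let H be the number of interactions in the dyad's more
#' frequent direction and L the reverse; the index is
#' `(sum(H) - sum(L)) / (sum(H) + sum(L))`. 1 means every dyad is fully
#' unidirectional; 0 means every dyad is perfectly bidirectional. Ties are
#' directionless and excluded.
#'
#' @param matches a `match_records` data frame for one assay and cage, or a
#'   win matrix.
#' @return A number in `[0, 1]`.
#' @export
dci <- function(matches) {
  alpha <- if (is.matrix(matches)) matches else win_matrix(matches)
  if (sum(alpha) == 0) {
    stop_unmeasurable("no decisive interactions: DCI is unmeasurable")
  }
  up <- alpha[upper.tri(alpha)]
  dn <- t(alpha)[upper.tri(alpha)]
  h <- sum(pmax(up, dn)); l <- sum(pmin(up, dn))
  (h - l) / (h + l)
}

#' Urine-marking match outcome
#'
#' The animal depositing more urine spots wins, with a tie rule for small
#' differences: a match is tied when the counts differ by fewer than 5
#' spots, or by less than 20% of the larger count. Comparisons use integer
#' arithmetic so the 20% boundary is exact.
#'
#' @param spots_a,spots_b non-negative spot counts.
#' @param min_spot_diff absolute-difference tie threshold (default 5).
#' @param min_frac_diff relative-difference tie threshold (default 0.2),
#'   denominated by the larger count.
#' @return `"A_WINS"`, `"B_WINS"` or `"TIE"`.
#' @examples
#' urine_outcome(100, 50)  # A_WINS
#' urine_outcome(10, 8)    # TIE: difference 2 < 5
#' @export
urine_outcome <- function(spots_a, spots_b, min_spot_diff = 5,
                          min_frac_diff = 0.2) {
  if (spots_a < 0 || spots_b < 0) stop_validation("counts must be non-negative")
  a <- as.integer(spots_a); b <- as.integer(spots_b)
  d <- abs(a - b); m <- max(a, b)
  if (m == 0L) return("TIE")
  if (d < min_spot_diff) return("TIE")
  # d / m < frac, kept exact for integer counts by clearing denominators:
  # with frac = p / 1e9 (p integral for any threshold given to 9 decimals),
  # d / m < frac  <=>  d * 1e9 < p * m, an integer comparison.
  p <- round(min_frac_diff * 1e9)
  if (d * 1e9 < p * m) return("TIE")
  if (a > b) "A_WINS" else "B_WINS"
}

#' Reward-competition match outcome from trial winners
#'
#' Tied trials are excluded; the animal winning more than 50% of the
#' decisive trials wins the match. With equally many decisive wins the
#' match is assigned deterministically to the animal with the lower
#' identifier; with no decisive trials at all the match is a tie.
#'
#' @param winners character vector of per-trial winner identifiers, with
#'   `NA` (or `"tie"`) marking tied trials.
#' @param id_a,id_b the two competitors.
#' @return `"A_WINS"`, `"B_WINS"` or `"TIE"`.
#' @export
reward_match_outcome <- function(winners, id_a, id_b) {
  if (length(winners) < 1) stop_validation("at least one trial required")
  w <- as.character(winners)
  w[tolower(w) %in% c("tie", "na")] <- NA
  dec <- w[!is.na(w)]
  if (!all(dec %in% c(id_a, id_b))) {
    stop_validation("trial winners must be one of the two competitors or a tie")
  }
  n_a <- sum(dec == id_a); n_b <- sum(dec == id_b)
  if (n_a + n_b == 0) return("TIE")
  if (n_a > n_b) return("A_WINS")
  if (n_b > n_a) return("B_WINS")
  # equal decisive counts: deterministic assignment by identifier
  if (id_a < id_b) "A_WINS" else "B_WINS"
}

#' Classify the stability of one dyad in one assay
#'
#' Assay-specific criteria (thresholds inclusive):
#' * `agonistic` — unmeasurable with fewer than 3 interactions; stable when
#'   at least 75% of interactions were initiated (won) by the same animal.
#' * `urine` — stable only when every trial was decisive with the same
#'   winner; unmeasurable with no trials.
#' * `tube` — stable when at least 75% of matches had the same winner.
#' * `reward` — stable when at least 60% of decisive trials (tied matches
#'   excluded) had the same winner; unmeasurable with no decisive trials.
#'
#' @param matches a `match_records` data frame containing one dyad's
#'   matches in one assay.
#' @param thresholds named list overriding the per-assay same-winner
#'   fractions (`agonistic = 0.75, tube = 0.75, reward = 0.6`) and the
#'   agonistic minimum interaction count (`agonistic_min_n = 3`).
#' @return A one-row data frame of class `dyad_status` with columns
#'   `id_a, id_b, assay, n_interactions, same_winner_fraction, status,
#'   dominant_id`. `status` is `"STABLE"`, `"UNSTABLE"` or `"UNMEASURABLE"`;
#'   `dominant_id` is defined only for stable dyads.
#' @export
classify_dyad_stability <- function(matches, thresholds = list()) {
  thr <- utils::modifyList(
    list(agonistic = 0.75, tube = 0.75, reward = 0.6, agonistic_min_n = 3),
    thresholds)
  matches <- as.data.frame(matches)
  if (nrow(matches) == 0) stop_validation("no matches supplied")
  assay <- unique(matches$assay)
  if (length(assay) != 1) stop_validation("mixed assays in stability input")
  ids <- sort(unique(c(matches$id_a, matches$id_b)))
  if (length(ids) != 2) stop_validation("stability input must contain one dyad")
  winners <- ifelse(matches$outcome == "A_WINS", matches$id_a,
                    ifelse(matches$outcome == "B_WINS", matches$id_b, NA))
  n <- nrow(matches)
  n1 <- sum(winners == ids[1], na.rm = TRUE)
  n2 <- sum(winners == ids[2], na.rm = TRUE)
  top_id <- if (n1 >= n2) ids[1] else ids[2]

  res <- function(status, frac, dom) {
    out <- data.frame(id_a = ids[1], id_b = ids[2], assay = assay,
                      n_interactions = n, same_winner_fraction = frac,
                      status = status,
                      dominant_id = if (status == "STABLE") dom else NA_character_,
                      stringsAsFactors = FALSE)
    class(out) <- c("dyad_status", "data.frame")
    out
  }

  if (assay == "agonistic") {
    if (n < thr$agonistic_min_n) return(res("UNMEASURABLE", NA_real_, NA))
    frac <- max(n1, n2) / n
    res(if (frac >= thr$agonistic) "STABLE" else "UNSTABLE", frac, top_id)
  } else if (assay == "urine") {
    if (n == 0) return(res("UNMEASURABLE", NA_real_, NA))
    frac <- max(n1, n2) / n
    stable <- !anyNA(winners) && (n1 == n || n2 == n)
    res(if (stable) "STABLE" else "UNSTABLE", frac, top_id)
  } else if (assay == "tube") {
    frac <- max(n1, n2) / n
    res(if (frac >= thr$tube) "STABLE" else "UNSTABLE", frac, top_id)
  } else { # reward: fraction over decisive trials only
    dec <- n1 + n2
    if (dec == 0) return(res("UNMEASURABLE", NA_real_, NA))
    frac <- max(n1, n2) / dec
    res(if (frac >= thr$reward) "STABLE" else "UNSTABLE", frac, top_id)
  }
}

#' Stability classification for every dyad in a match table
#'
#' Applies [classify_dyad_stability()] to each `(assay, cage, dyad)` group.
#'
#' @param matches a `match_records` data frame (any mix of assays/cages).
#' @param thresholds see [classify_dyad_stability()].
#' @return A `dyad_status` data frame, one row per dyad per assay, with a
#'   `cage` column.
#' @export
dyad_stability_table <- function(matches, thresholds = list()) {
  matches <- as.data.frame(matches)
  pair <- t(apply(cbind(matches$id_a, matches$id_b), 1, sort))
  key <- paste(matches$assay, matches$cage, pair[, 1], pair[, 2], sep = "\r")
  out <- lapply(split(seq_len(nrow(matches)), key), function(idx) {
    st <- classify_dyad_stability(matches[idx, , drop = FALSE], thresholds)
    st$cage <- matches$cage[idx[1]]
    st
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("dyad_status", "data.frame")
  out
}
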