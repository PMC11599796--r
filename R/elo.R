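# Elo rating with ties. Each contest transfers K * (S - E) points between
# the two opponents, where E is the logistic expected score and S is 1 / 0 /
# 0.5 for win / loss / tie, so the update is exactly zero-sum and ties pull
# both animals toward their expectation. Chosen over David's score when ties
# and temporal order matter, and because animals that never fight keep an
# interpretable baseline.

#' Elo configuration
#'
#' @param k_factor step size of rating changes per match (default 20).
#' @param scale logistic scale of the expected-score curve in rating points
#'   (default 400): a `scale`-point advantage gives 10:1 expected odds.
#' @param baseline starting rating for every animal (default 1000).
#' @return A list of class `elo_config`.
#' @export
elo_config <- function(k_factor = 20, scale = 400, baseline = 1000) {
  if (!is.numeric(k_factor) || k_factor <= 0) stop_validation("k_factor must be > 0")
  if (!is.numeric(scale) || scale <= 0) stop_validation("scale must be > 0")
  structure(list(k_factor = k_factor, scale = scale, baseline = baseline),
            class = "elo_config")
}

#' Expected win probability under the Elo model
#'
#' `1 / (1 + 10^((r_b - r_a) / scale))`: the probability that the first
#' animal wins given the current ratings. Satisfies
#' `elo_expected(a, b) + elo_expected(b, a) == 1`.
#'
#' @param r_a,r_b current ratings of the two opponents.
#' @param cfg an [elo_config()].
#' @return Probability in `(0, 1)`.
#' @examples
#' elo_expected(1400, 1000)  # 10/11
#' @export
elo_expected <- function(r_a, r_b, cfg = elo_config()) {
  stopifnot(is.finite(r_a), is.finite(r_b))
  1 / (1 + 10^((r_b - r_a) / cfg$scale))
}

#' One Elo update
#'
#' @param r_a,r_b pre-match ratings.
#' @param outcome `"A_WINS"`, `"B_WINS"` or `"TIE"`.
#' @param cfg an [elo_config()].
#' @return Numeric vector of the two post-match ratings. The sum of ratings
#'   is conserved exactly.
#' @export
elo_update <- function(r_a, r_b, outcome, cfg = elo_config()) {
  outcome <- normalize_outcome(outcome)
  s_a <- c(A_WINS = 1, B_WINS = 0, TIE = 0.5)[[outcome]]
  e_a <- elo_expected(r_a, r_b, cfg)
  delta <- cfg$k_factor * (s_a - e_a)
  c(r_a + delta, r_b - delta)
}

#' Elo rating trajectories for one assay and cage
#'
#' Folds [elo_update()] over a chronologically ordered match stream. All
#' animals start at the configured baseline; an animal's rating changes only
#' at matches it takes part in, and animals listed in `animals` but never
#' matched keep the baseline. Ties update both parties with score 0.5.
#'
#' @param matches a `match_records` data frame for a single assay and cage,
#'   sorted by `order` (the constructor's sort order).
#' @param animals optional character vector of all cage members, so that
#'   unmatched animals appear with the baseline rating.
#' @param cfg an [elo_config()].
#' @return An object of class `elo_ratings`: a list with `final` (named
#'   numeric vector of final ratings), `rank` (dense 1 = highest, ties
#'   broken by identifier), `history` (data frame of per-match post-match
#'   ratings), and `cfg`.
#' @examples
#' m <- match_records("tube", "c1", 1:2, c("a", "b"), c("b", "a"),
#'                    c("A_WINS", "A_WINS"))
#' fit <- elo_ratings(m)
#' fit$final
#' @export
elo_ratings <- function(matches, animals = NULL, cfg = elo_config()) {
  matches <- as.data.frame(matches)
  if (nrow(matches) > 0) {
    if (length(unique(matches$assay)) > 1 || length(unique(matches$cage)) > 1) {
      stop_validation("elo_ratings expects matches from a single assay and cage")
    }
    if (is.unsorted(matches$order, strictly = TRUE)) {
      stop_validation("matches must be sorted by order")
    }
  }
  ids <- sort(unique(c(matches$id_a, matches$id_b, animals)))
  if (length(ids) == 0) stop_validation("no animals")
  ratings <- setNames(rep(cfg$baseline, length(ids)), ids)
  n <- nrow(matches)
  s_tab <- c(A_WINS = 1, B_WINS = 0, TIE = 0.5)
  ia <- match(matches$id_a, ids); ib <- match(matches$id_b, ids)
  s_a <- unname(s_tab[matches$outcome])
  h_order <- integer(2 * n); h_id <- character(2 * n); h_rating <- numeric(2 * n)
  for (i in seq_len(n)) {
    r_a <- ratings[ia[i]]; r_b <- ratings[ib[i]]
    delta <- cfg$k_factor * (s_a[i] - 1 / (1 + 10^((r_b - r_a) / cfg$scale)))
    ratings[ia[i]] <- r_a + delta
    ratings[ib[i]] <- r_b - delta
    h_order[2 * i - 1] <- h_order[2 * i] <- matches$order[i]
    h_id[2 * i - 1] <- matches$id_a[i]; h_id[2 * i] <- matches$id_b[i]
    h_rating[2 * i - 1] <- r_a + delta; h_rating[2 * i] <- r_b - delta
  }
  hist <- data.frame(order = h_order, id = h_id, rating = h_rating,
                     stringsAsFactors = FALSE)
  structure(list(final = ratings,
                 rank = simplify_ranks(ratings),
                 history = hist,
                 cfg = cfg,
                 assay = if (n) matches$assay[1] else NA_character_,
                 cage = if (n) matches$cage[1] else NA_character_),
            class = "elo_ratings")
}

#' @export
print.elo_ratings <- function(x, ...) {
  cat("Elo ratings (K =", x$cfg$k_factor, ", scale =", x$cfg$scale,
      ", baseline =", x$cfg$baseline, ")\n")
  if (!is.na(x$assay)) cat("assay:", x$assay, " cage:", x$cage, "\n")
  df <- data.frame(final = round(x$final, 1), rank = x$rank)
  print(df, ...)
  invisible(x)
}

#' @export
summary.elo_ratings <- function(object, ...) {
  cat("Matches folded:", nrow(object$history) / 2, "\n")
  print(object)
}

#' Plot Elo trajectories
#'
#' Rating of each animal against match order, one line per animal.
#'
#' @param x an `elo_ratings` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.elo_ratings <- function(x, ...) {
  ids <- names(x$final)
  orders <- sort(unique(x$history$order))
  traj <- matrix(x$cfg$baseline, nrow = length(orders) + 1, ncol = length(ids),
                 dimnames = list(NULL, ids))
  for (j in seq_along(orders)) {
    rows <- x$history[x$history$order == orders[j], ]
    traj[j + 1, ] <- traj[j, ]
    traj[j + 1, rows$id] <- rows$rating
  }
  cols <- hcl.colors(length(ids), "Dark 3")
  matplot(c(0, seq_along(orders)), traj, type = "l", lty = 1, col = cols,
          xlab = "match", ylab = "Elo rating", ...)
  legend("topleft", legend = ids, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Simplify scores to dense 1..n ranks
#'
#' Rank 1 is the highest score. Equal scores are broken deterministically by
#' animal identifier (alphabetical), so the result is always a permutation
#' of `1..n`.
#'
#' @param scores named numeric vector of per-animal scores.
#' @return Named integer vector of ranks.
#' @export
simplify_ranks <- function(scores) {
  if (length(scores) == 0) stop_validation("empty score vector")
  if (is.null(names(scores)) || anyNA(names(scores))) {
    stop_validation("scores must be named by animal identifier")
  }
  ord <- order(-scores, names(scores))
  setNames(order(ord), names(scores))[names(scores)]
}
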