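# Cross-assay comparison: correlation matrices of dominance scores and
# maintenance/reversal of relative rank among dyads stable in two assays.

#' Assemble a score panel
#'
#' @param scores data frame with columns `animal, assay, score` and
#'   optionally `group` (e.g., strain). Each animal appears at most once
#'   per assay.
#' @return A data frame of class `score_panel`.
#' @export
score_panel <- function(scores) {
  df <- as.data.frame(scores)
  for (col in c("animal", "assay", "score")) {
    if (is.null(df[[col]])) stop_validation("score panel missing column: ", col)
  }
  if (is.null(df$group)) df$group <- "all"
  key <- paste(df$animal, df$assay)
  if (anyDuplicated(key)) {
    stop_validation("animal appears more than once in an assay: ",
                    paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  class(df) <- c("score_panel", "data.frame")
  df
}

#' Cross-assay correlation matrix of dominance scores
#'
#' Pearson correlations between each pair of assays' per-animal scores,
#' computed on pairwise-complete animals within one group. Entries with
#' fewer than `min_n` complete pairs are left `NA` and flagged. P-values
#' can be adjusted for the number of off-diagonal comparisons.
#'
#' @param panel a [score_panel()].
#' @param group which group to analyze (default: the panel's first group).
#' @param min_n minimum complete pairs per entry (default 3).
#' @param p_adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"holm"`; use `"none"` to disable).
#' @return An object of class `score_cor_matrix`: list of symmetric
#'   matrices `r`, `p` (adjusted), `n`, plus `group` and `flagged` (assay
#'   pairs with insufficient data).
#' @export
score_correlation_matrix <- function(panel, group = NULL, min_n = 3,
                                     p_adjust = "holm") {
  df <- as.data.frame(panel)
  group <- group %||% df$group[1]
  df <- df[df$group == group, , drop = FALSE]
  if (nrow(df) == 0) stop_validation("no scores for group ", group)
  assays <- unique(df$assay)
  animals <- unique(df$animal)
  wide <- matrix(NA_real_, length(animals), length(assays),
                 dimnames = list(animals, assays))
  wide[cbind(match(df$animal, animals), match(df$assay, assays))] <- df$score
  k <- length(assays)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(assays, assays))
  n <- matrix(0L, k, k, dimnames = list(assays, assays))
  diag(r) <- 1; diag(p) <- 0
  diag(n) <- colSums(!is.na(wide))
  flagged <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- complete.cases(wide[, c(i, j)])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < min_n) {
      flagged <- c(flagged, paste(assays[i], "vs", assays[j]))
      next
    }
    ct <- cor.test(wide[ok, i], wide[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  if (p_adjust != "none" && k > 1) {
    up <- upper.tri(p)
    p[up] <- p.adjust(p[up], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(r = r, p = p, n = n, group = group, flagged = flagged,
                 p_adjust = p_adjust),
            class = "score_cor_matrix")
}

#' @export
print.score_cor_matrix <- function(x, ...) {
  cat("Dominance score correlations, group:", x$group,
      "(p adjust:", x$p_adjust, ")\n")
  print(round(x$r, 3), ...)
  if (length(x$flagged)) {
    cat("insufficient data:", paste(x$flagged, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Rank maintenance and reversal among stable dyads
#'
#' For each dyad classified stable in both of two assays, compares the
#' dominant animal across assays: identical dominants maintain relative
#' rank, opposite dominants reverse it. Dyads stable in at most one assay
#' are excluded from the maintained/reversed counts and reported
#' separately. `maintained + reversed` equals the number of stable-in-both
#' dyads exactly.
#'
#' @param stability_1,stability_2 `dyad_status` data frames for the two
#'   assays (e.g., from [dyad_stability_table()]); dyads are matched on the
#'   unordered id pair (and cage when present).
#' @return A data frame of class `reversal_summary` with one row per group
#'   if a `group` column is present, else one row: columns
#'   `assay_1, assay_2, stable_both, maintained, reversed, excluded`.
#' @export
rank_reversals <- function(stability_1, stability_2) {
  s1 <- as.data.frame(stability_1); s2 <- as.data.frame(stability_2)
  dyad_key <- function(s) {
    pair <- t(apply(cbind(s$id_a, s$id_b), 1, sort))
    cage <- if (!is.null(s$cage)) s$cage else ""
    paste(cage, pair[, 1], pair[, 2], sep = "\r")
  }
  k1 <- dyad_key(s1); k2 <- dyad_key(s2)
  all_keys <- union(k1, k2)
  st1 <- s1$status[match(all_keys, k1)]
  st2 <- s2$status[match(all_keys, k2)]
  both <- !is.na(st1) & st1 == "STABLE" & !is.na(st2) & st2 == "STABLE"
  dom1 <- s1$dominant_id[match(all_keys, k1)]
  dom2 <- s2$dominant_id[match(all_keys, k2)]
  maintained <- sum(both & dom1 == dom2, na.rm = TRUE)
  reversed <- sum(both & dom1 != dom2, na.rm = TRUE)
  out <- data.frame(
    assay_1 = s1$assay[1], assay_2 = s2$assay[1],
    stable_both = sum(both), maintained = maintained, reversed = reversed,
    excluded = length(all_keys) - sum(both), stringsAsFactors = FALSE)
  class(out) <- c("reversal_summary", "data.frame")
  out
}

#' Compare reversal proportions between two groups
#'
#' Thin wrapper over [stats::fisher.test()] on the 2 x 2 table of
#' maintained vs reversed counts for two groups.
#'
#' @param summary_a,summary_b `reversal_summary` rows for the two groups.
#' @return The `htest` object from `fisher.test`.
#' @export
reversal_fisher_test <- function(summary_a, summary_b) {
  tab <- rbind(c(summary_a$maintained, summary_a$reversed),
               c(summary_b$maintained, summary_b$reversed))
  fisher.test(tab)
}
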