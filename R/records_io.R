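# Match records and ethogram event tables: the tabular inputs that feed the
# dominance-scoring stage. Match tables are CSV with columns
# assay, cage, order, id_a, id_b, outcome, count_a, count_b; ethogram tables
# are CSV with trial_id, subject, behavior, start_s, stop_s plus a trials
# table with trial_id, start_s, stop_s (the shape a BORIS export reduces to
# after column mapping).

ASSAYS <- c("agonistic", "urine", "tube", "reward")
OUTCOMES <- c("A_WINS", "B_WINS", "TIE")
BEHAVIORS <- c("push", "resist", "retreat_contact", "retreat_passive")

MATCH_COLUMNS <- c("assay", "cage", "order", "id_a", "id_b",
                   "outcome", "count_a", "count_b")

#' Construct a table of dyadic match records
#'
#' A match record describes one dyadic contest in one assay: which two
#' animals met, in what chronological order within their cage, and who won
#' (or whether the contest tied). Optional per-animal counts carry
#' assay-specific magnitudes such as urine spots or rewards won.
#'
#' @param assay character vector; one of `"agonistic"`, `"urine"`, `"tube"`,
#'   `"reward"`.
#' @param cage cage identifiers.
#' @param order non-negative integers giving chronological order within each
#'   `(assay, cage)` group.
#' @param id_a,id_b animal identifiers; must differ within a row.
#' @param outcome `"A_WINS"`, `"B_WINS"` or `"TIE"` (the short forms
#'   `"a"`, `"b"`, `"tie"` are accepted case-insensitively).
#' @param count_a,count_b optional non-negative integer counts (`NA` = absent).
#' @return A `data.frame` of class `match_records`, sorted by
#'   `(assay, cage, order)`.
#' @examples
#' m <- match_records(assay = "tube", cage = "c1", order = 1:2,
#'                    id_a = "m1", id_b = "m2",
#'                    outcome = c("A_WINS", "TIE"))
#' m
#' @export
match_records <- function(assay, cage, order, id_a, id_b, outcome,
                          count_a = NA_integer_, count_b = NA_integer_) {
  df <- data.frame(
    assay = as.character(assay), cage = as.character(cage),
    order = as.integer(order),
    id_a = as.character(id_a), id_b = as.character(id_b),
    outcome = normalize_outcome(outcome),
    count_a = as.integer(count_a), count_b = as.integer(count_b),
    stringsAsFactors = FALSE
  )
  validate_match_records(df)
}

normalize_outcome <- function(x) {
  x <- tolower(as.character(x))
  out <- c(a = "A_WINS", a_wins = "A_WINS",
           b = "B_WINS", b_wins = "B_WINS",
           tie = "TIE")[x]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop_format("unrecognized outcome value(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

validate_match_records <- function(df) {
  if (!all(df$assay %in% ASSAYS)) {
    bad <- setdiff(unique(df$assay), ASSAYS)
    stop_format("unknown assay value(s): ", paste(bad, collapse = ", "))
  }
  if (any(df$id_a == df$id_b)) {
    stop_validation("id_a and id_b must differ (rows ",
                    paste(which(df$id_a == df$id_b), collapse = ", "), ")")
  }
  if (any(df$order < 0, na.rm = TRUE) || anyNA(df$order)) {
    stop_validation("order must be a non-negative integer")
  }
  if (any(!is.na(df$count_a) & df$count_a < 0) ||
      any(!is.na(df$count_b) & df$count_b < 0)) {
    stop_validation("counts must be non-negative")
  }
  # duplicate chronological slots within a group are ambiguous
  key <- paste(df$assay, df$cage, df$order)
  if (anyDuplicated(key)) {
    stop_validation("duplicate (assay, cage, order) rows: ",
                    paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df <- df[order(df$assay, df$cage, df$order), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("match_records", "data.frame")
  df
}

#' Read dyadic match records from CSV
#'
#' @param path path to a CSV file with header columns `assay, cage, order,
#'   id_a, id_b, outcome, count_a, count_b` (the two count columns may be
#'   omitted; empty strings mean absent). Outcome values `a`, `b`, `tie`
#'   are accepted case-insensitively.
#' @return A `match_records` data frame sorted by `(assay, cage, order)`.
#' @seealso [write_matches()]
#' @export
read_matches <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- setdiff(MATCH_COLUMNS, c("count_a", "count_b"))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_format("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(df$count_a)) df$count_a <- NA
  if (is.null(df$count_b)) df$count_b <- NA
  to_count <- function(x) {
    x[x == ""] <- NA
    suppressWarnings(as.integer(x))
  }
  ord <- suppressWarnings(as.integer(df$order))
  bad <- which(is.na(ord) & nzchar(df$order))
  if (length(bad)) {
    # +1 for the header line so the message points at the file line
    stop_format("malformed order value at line(s): ",
                paste(bad + 1L, collapse = ", "))
  }
  match_records(assay = df$assay, cage = df$cage, order = ord,
                id_a = df$id_a, id_b = df$id_b, outcome = df$outcome,
                count_a = to_count(df$count_a), count_b = to_count(df$count_b))
}

#' Write dyadic match records to CSV
#'
#' Emits the same comma-separated dialect [read_matches()] reads, so
#' write-then-read is the identity on valid record tables. Absent counts
#' are written as empty fields. Output is byte-stable for fixed input.
#'
#' @param records a `match_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(records, path) {
  records <- validate_match_records(as.data.frame(records))
  out <- records[, MATCH_COLUMNS]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct ethogram events
#'
#' One row per scored behavior bout: which animal, which behavior, and the
#' bout's start/stop in seconds from the session clock.
#'
#' @param subject animal identifiers.
#' @param behavior one of `"push"`, `"resist"`, `"retreat_contact"`,
#'   `"retreat_passive"`.
#' @param start_s,stop_s bout boundaries in seconds; `start_s < stop_s`.
#' @return A `data.frame` of class `ethogram_events`.
#' @export
ethogram_events <- function(subject, behavior, start_s, stop_s) {
  df <- data.frame(subject = as.character(subject),
                   behavior = as.character(behavior),
                   start_s = as.numeric(start_s),
                   stop_s = as.numeric(stop_s),
                   stringsAsFactors = FALSE)
  if (!all(df$behavior %in% BEHAVIORS)) {
    stop_format("unknown behavior value(s): ",
                paste(setdiff(unique(df$behavior), BEHAVIORS), collapse = ", "))
  }
  if (any(!(df$start_s >= 0 & df$start_s < df$stop_s))) {
    stop_validation("events require 0 <= start_s < stop_s")
  }
  class(df) <- c("ethogram_events", "data.frame")
  df
}

#' Read ethogram event and trial tables from CSV
#'
#' @param events_path CSV with columns `trial_id, subject, behavior,
#'   start_s, stop_s`.
#' @param trials_path CSV with columns `trial_id, start_s, stop_s`.
#' @return A list with elements `events` (an `ethogram_events` data frame
#'   with a `trial_id` column) and `trials` (a data frame of trial windows).
#' @export
read_ethogram <- function(events_path, trials_path) {
  ev <- read.csv(events_path, stringsAsFactors = FALSE)
  tr <- read.csv(trials_path, stringsAsFactors = FALSE)
  for (col in c("trial_id", "subject", "behavior", "start_s", "stop_s")) {
    if (is.null(ev[[col]])) stop_format("events table missing column: ", col)
  }
  for (col in c("trial_id", "start_s", "stop_s")) {
    if (is.null(tr[[col]])) stop_format("trials table missing column: ", col)
  }
  events <- ethogram_events(ev$subject, ev$behavior, ev$start_s, ev$stop_s)
  events$trial_id <- as.character(ev$trial_id)
  trials <- data.frame(trial_id = as.character(tr$trial_id),
                       start_s = as.numeric(tr$start_s),
                       stop_s = as.numeric(tr$stop_s),
                       stringsAsFactors = FALSE)
  if (any(trials$stop_s <= trials$start_s)) {
    stop_validation("trials require stop_s > start_s")
  }
  list(events = events, trials = trials)
}

# Union length of a set of intervals given as a 2-column matrix [start, stop].
interval_union_length <- function(ivs) {
  if (nrow(ivs) == 0) return(0)
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  total <- 0
  cur_start <- ivs[1, 1]; cur_stop <- ivs[1, 2]
  if (nrow(ivs) > 1) {
    for (i in 2:nrow(ivs)) {
      if (ivs[i, 1] > cur_stop) {
        total <- total + (cur_stop - cur_start)
        cur_start <- ivs[i, 1]; cur_stop <- ivs[i, 2]
      } else {
        cur_stop <- max(cur_stop, ivs[i, 2])
      }
    }
  }
  total + (cur_stop - cur_start)
}

#' Fraction of a trial spent in a behavior
#'
#' Computes the fraction of a trial's duration during which the subject
#' displayed a behavior. Bouts are clipped to the trial window and
#' overlapping bouts of the same behavior are merged (unioned) before
#' summing, so double-scored overlap cannot push the fraction above 1.
#'
#' @param events an `ethogram_events` data frame (one subject's events, or
#'   pass `subject` to filter).
#' @param trial_start_s,trial_stop_s trial window in seconds;
#'   `trial_stop_s > trial_start_s`.
#' @param behavior the behavior to aggregate.
#' @param subject optional subject filter applied to `events`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' ev <- ethogram_events("m1", c("push", "push"), c(0, 4), c(6, 10))
#' ethogram_percent_time(ev, 0, 20, "push")  # union [0,10] / 20 = 0.5
#' @export
ethogram_percent_time <- function(events, trial_start_s, trial_stop_s,
                                  behavior, subject = NULL) {
  if (!behavior %in% BEHAVIORS) {
    stop_format("unknown behavior: ", behavior)
  }
  dur <- trial_stop_s - trial_start_s
  if (!is.finite(dur) || dur <= 0) {
    stop_validation("trial duration must be positive")
  }
  df <- as.data.frame(events)
  if (!is.null(subject)) df <- df[df$subject == subject, , drop = FALSE]
  df <- df[df$behavior == behavior, , drop = FALSE]
  if (nrow(df) == 0) return(0)
  start <- pmax(df$start_s, trial_start_s)
  stop <- pmin(df$stop_s, trial_stop_s)
  keep <- stop > start
  if (!any(keep)) return(0)
  interval_union_length(cbind(start[keep], stop[keep])) / dur
}
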