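# Date-ordered per-player per-season injury sequences and the
# transition pairs consumed by the Markov estimator. Seasons are treated
# independently: no pair ever crosses a season or player boundary.

#' Build per-player per-season injury sequences
#'
#' Groups preprocessed records by player and season, orders each group
#' by injury date (ties broken by original input row order, which is
#' stable), and keeps groups with at least two injuries. Same-day
#' injuries trigger a warning, since their relative order is an input
#' artefact rather than observed chronology.
#'
#' @param records Preprocessed `injury_records` (seasons resolved).
#' @return A tibble of the input records with `seq_id` (one per
#'   player-season), `seq_pos` (1-based position within the sequence)
#'   and `seq_len` columns, ordered by sequence and position.
#' @export
build_sequences <- function(records) {
  if (any(is.na(records$season_label))) {
    stop("unresolved season_label; run preprocess() or resolve_seasons() first",
         call. = FALSE)
  }
  if (!(".row" %in% names(records))) records$.row <- seq_len(nrow(records))
  out <- tibble::as_tibble(records)
  out <- out[order(out$player_id, out$season_label, out$injury_date, out$.row),
             , drop = FALSE]
  key <- paste(out$player_id, out$season_label, sep = "\r")
  runs <- rle(key)$lengths  # groups contiguous after the sort
  out$seq_len <- rep.int(runs, runs)
  out$seq_pos <- sequence(runs)
  out <- out[out$seq_len >= 2, , drop = FALSE]
  key <- key[rep.int(runs >= 2, runs)]
  out$seq_id <- match(key, unique(key))
  dup_day <- anyDuplicated(paste(key, out$injury_date)) > 0
  if (dup_day) {
    warning("same-day injuries present; within-day order follows input row order",
            call. = FALSE)
  }
  class(out) <- c("injury_sequences", class(out))
  out
}

#' Extract within-season injury transitions
#'
#' Under chain semantics (the default) a sequence `[I1, I2, ..., Ik]`
#' yields the consecutive pairs `(I1 -> I2), ..., (I(k-1) -> Ik)`: every
#' injury except the last serves as the initial injury of exactly one
#' transition, to its first subsequent injury. The number of transitions
#' therefore equals the number of subsequent injuries,
#' `sum(length - 1)` over sequences. Under star semantics only the
#' season's first injury emits a transition (to its immediate
#' successor), one per sequence — a stricter sensitivity variant.
#'
#' @param sequences Output of [build_sequences()].
#' @param semantics `"chain"` (default) or `"star"`.
#' @return A tibble with one row per transition: `player_id`,
#'   `season_label`, `gap_days`, and the `from_`/`to_` prefixed state
#'   fields (`body_part`, `nature`, `category`, `date`).
#' @export
extract_transitions <- function(sequences, semantics = c("chain", "star")) {
  semantics <- match.arg(semantics)
  s <- tibble::as_tibble(sequences)
  s <- dplyr::arrange(s, .data$seq_id, .data$seq_pos)
  from_sel <- if (semantics == "chain") s$seq_pos < s$seq_len else s$seq_pos == 1
  to_sel <- if (semantics == "chain") s$seq_pos > 1 else s$seq_pos == 2
  from <- s[from_sel, , drop = FALSE]
  to <- s[to_sel, , drop = FALSE]
  stopifnot(nrow(from) == nrow(to), all(from$seq_id == to$seq_id))
  tibble::tibble(
    player_id = from$player_id,
    season_label = from$season_label,
    from_body_part = from$body_part,
    from_nature = from$nature,
    from_category = from$category,
    from_date = from$injury_date,
    to_body_part = to$body_part,
    to_nature = to$nature,
    to_category = to$category,
    to_date = to$injury_date,
    gap_days = as.integer(to$injury_date - from$injury_date)
  )
}

#' Write the transitions table
#'
#' One row per transition, the audit-trail intermediate between the
#' sequence builder and the estimator.
#'
#' @param transitions Output of [extract_transitions()].
#' @param path Destination path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(transitions, path, delim = ",") {
  out <- transitions
  out$from_date <- format(out$from_date, "%Y-%m-%d")
  out$to_date <- format(out$to_date, "%Y-%m-%d")
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
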