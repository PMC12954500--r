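# Binomial proportion confidence intervals and cohort-level summary
# statistics.
#
# The Wald (normal-approximation) interval p +/- z*sqrt(p(1-p)/n) is the
# default: at the global denominator it reproduces the published
# half-widths cell for cell. Wilson's score interval is available for
# small counts, where the Wald interval is known to misbehave (zero
# width at p = 0, overshoot near the boundaries).

#' Wald half-width of a binomial proportion interval
#'
#' `z * sqrt(p * (1 - p) / n)` with `z` the standard-normal quantile at
#' `(1 + confidence) / 2` (1.959964 at 95%).
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param n Denominator(s), at least 1.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @return Half-width(s) in probability units.
#' @examples
#' wald_halfwidth(0.075, 1599)  # 0.0129: a 7.5% +/- 1.29% cell
#' @export
wald_halfwidth <- function(p, n, confidence = 0.95) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1), confidence > 0, confidence < 1)
  z <- stats::qnorm((1 + confidence) / 2)
  z * sqrt(p * (1 - p) / n)
}

wilson_interval <- function(p, n, confidence = 0.95) {
  z <- stats::qnorm((1 + confidence) / 2)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Attach binomial confidence intervals to transition estimates
#'
#' Adds `half_width`, `ci_low` and `ci_high` columns, clipped to
#' `[0, 1]`. Wald intervals are symmetric about `p` before clipping;
#' Wilson intervals are asymmetric but always contain `p`.
#'
#' @param estimates A `transition_estimates` tibble (columns `p`,
#'   `n_denominator`).
#' @param method `"wald"` (default) or `"wilson"`.
#' @param confidence Confidence level; default 0.95.
#' @return The estimates with `ci_method`, `half_width`, `ci_low`,
#'   `ci_high` columns.
#' @export
attach_cis <- function(estimates, method = c("wald", "wilson"),
                       confidence = 0.95) {
  method <- match.arg(method)
  p <- estimates$p
  n <- estimates$n_denominator
  if (method == "wald") {
    hw <- wald_halfwidth(p, n, confidence)
    low <- pmax(0, p - hw)
    high <- pmin(1, p + hw)
  } else {
    wi <- wilson_interval(p, n, confidence)
    low <- wi$low
    high <- wi$high
    hw <- (high - low) / 2
  }
  estimates$ci_method <- method
  estimates$half_width <- hw
  estimates$ci_low <- low
  estimates$ci_high <- high
  estimates
}

#' Cohort-level summary of the subsequent-injury analysis
#'
#' Headline statistics: total recorded injuries (the pre-exclusion
#' base), number of subsequent injuries (= transitions under chain
#' semantics), their share, the number of players with at least one
#' subsequent injury, the mean and SD of subsequent injuries per
#' player-season (over player-seasons with at least one, by default),
#' and the body-part distribution of all recorded injuries.
#'
#' @param records_raw The record set before exclusions (the reporting
#'   base for totals and the body-part distribution).
#' @param transitions Transitions extracted from the cleaned records.
#' @param per_season_base `"with_subsequent"` (default) averages over
#'   player-seasons that have at least one subsequent injury;
#'   `"all"` averages over every player-season present in `records_raw`
#'   (seasons resolved from dates where missing).
#' @param season_start_month Used to resolve seasons for the `"all"`
#'   base.
#' @return A `cohort_summary` list; see fields in the description.
#' @export
cohort_summary <- function(records_raw, transitions,
                           per_season_base = c("with_subsequent", "all"),
                           season_start_month = 7) {
  per_season_base <- match.arg(per_season_base)
  n_injuries <- nrow(records_raw)
  n_subsequent <- nrow(transitions)
  per_ps <- dplyr::count(transitions, .data$player_id, .data$season_label)
  if (per_season_base == "all") {
    raw <- resolve_seasons(tibble::as_tibble(records_raw), season_start_month)
    all_ps <- dplyr::distinct(raw, .data$player_id, .data$season_label)
    per_ps <- dplyr::left_join(all_ps, per_ps,
                               by = c("player_id", "season_label"))
    per_ps$n[is.na(per_ps$n)] <- 0L
  }
  bp <- if ("body_part_unsided" %in% names(records_raw)) {
    records_raw$body_part_unsided
  } else {
    records_raw$body_part
  }
  bp <- bp[!is.na(bp) & bp != ""]
  dist <- sort(100 * table(bp) / length(bp), decreasing = TRUE)
  structure(list(
    n_injuries = n_injuries,
    n_subsequent = n_subsequent,
    subsequent_share = if (n_injuries > 0) n_subsequent / n_injuries else NA_real_,
    n_players_with_subsequent = dplyr::n_distinct(transitions$player_id),
    mean_subsequent_per_player_season =
      if (nrow(per_ps) > 0) mean(per_ps$n) else NA_real_,
    sd_subsequent_per_player_season =
      if (nrow(per_ps) > 1) stats::sd(per_ps$n) else NA_real_,
    per_season_base = per_season_base,
    body_part_distribution = stats::setNames(as.numeric(dist), names(dist))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  injuries recorded:            %d\n", x$n_injuries))
  cat(sprintf("  subsequent injuries:          %d (%.1f%%)\n",
              x$n_subsequent, 100 * x$subsequent_share))
  cat(sprintf("  players with >=1 subsequent:  %d\n",
              x$n_players_with_subsequent))
  if (!is.na(x$mean_subsequent_per_player_season)) {
    cat(sprintf("  subsequent per player-season: %.1f (+/- %.1f) [base: %s]\n",
                x$mean_subsequent_per_player_season,
                x$sd_subsequent_per_player_season %||% NA_real_,
                x$per_season_base))
  }
  top <- utils::head(x$body_part_distribution, 5)
  cat("  top body parts: ",
      paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
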