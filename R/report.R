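# Rendering: transition-probability matrices, CI tables, heatmaps, and
# the end-to-end pipeline driver. Tabular outputs are the source of
# truth; figures are optional derived artifacts and never contain a
# number absent from a table.

fmt_pct <- function(p, digits = 1) {
  formatC(100 * p, format = "f", digits = digits)
}

#' Transition-probability matrix report
#'
#' Wide matrix with from-states as rows and to-states as columns, cells
#' the transition probability in percent (one decimal). Cells removed
#' by the reporting threshold (or never observed) are blank. Optionally
#' renders a heatmap whose fill is monotone in probability.
#'
#' @param estimates A filtered `transition_estimates` tibble.
#' @param file Optional CSV destination for the matrix.
#' @param plot_file Optional PNG destination for the heatmap.
#' @return The percent-formatted character matrix, invisibly. Empty
#'   estimate set: a warning and an empty matrix, no figure.
#' @export
matrix_report <- function(estimates, file = NULL, plot_file = NULL) {
  if (nrow(estimates) == 0) {
    warning("no estimates to report", call. = FALSE)
    m <- matrix(character(0), 0, 0)
    if (!is.null(file)) {
      readr::write_csv(tibble::tibble(from_state = character(0)), file)
    }
    return(invisible(m))
  }
  states_from <- sort(unique(estimates$from_state))
  states_to <- sort(unique(estimates$to_state))
  m <- matrix("", length(states_from), length(states_to),
              dimnames = list(from = states_from, to = states_to))
  m[cbind(match(estimates$from_state, states_from),
          match(estimates$to_state, states_to))] <- fmt_pct(estimates$p)
  if (!is.null(file)) {
    out <- tibble::as_tibble(m, rownames = "from_state")
    readr::write_csv(out, file)
  }
  if (!is.null(plot_file)) {
    df <- estimates
    g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$to_state,
                                          y = .data$from_state,
                                          fill = .data$p)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = fmt_pct(.data$p)), size = 2.5) +
      ggplot2::scale_fill_gradient(low = "#deebf7", high = "#08519c",
                                   labels = function(x) paste0(100 * x, "%")) +
      ggplot2::scale_y_discrete(limits = rev(states_from)) +
      ggplot2::labs(x = "subsequent injury state", y = "initial injury state",
                    fill = "probability") +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    ggplot2::ggsave(plot_file, g,
                    width = 2 + 0.35 * length(states_to),
                    height = 1.5 + 0.3 * length(states_from), limitsize = FALSE)
  }
  invisible(m)
}

#' Confidence-interval report
#'
#' One row per transition with the interval bounds and the point
#' estimate in percent (two decimals), plus a compact
#' `"low / point / high"` display column.
#'
#' @param estimates A `transition_estimates` tibble with CIs attached
#'   (see [attach_cis()]).
#' @param file Optional CSV destination.
#' @return A tibble with `from_state`, `to_state`, `low_pct`,
#'   `point_pct`, `high_pct`, `display`.
#' @export
ci_report <- function(estimates, file = NULL) {
  if (!("ci_low" %in% names(estimates))) {
    stop("attach_cis() must be applied before ci_report()", call. = FALSE)
  }
  if (nrow(estimates) == 0) warning("no estimates to report", call. = FALSE)
  out <- tibble::tibble(
    from_state = estimates$from_state,
    to_state = estimates$to_state,
    low_pct = as.numeric(fmt_pct(estimates$ci_low, 2)),
    point_pct = as.numeric(fmt_pct(estimates$p, 2)),
    high_pct = as.numeric(fmt_pct(estimates$ci_high, 2))
  )
  out$display <- sprintf("%.2f / %.2f / %.2f",
                         out$low_pct, out$point_pct, out$high_pct)
  if (!is.null(file)) readr::write_csv(out, file)
  out
}

#' Run the whole subsequent-injury analysis pipeline
#'
#' Preprocess -> sequences -> transitions -> counts -> estimates -> CIs
#' -> reports, writing every artifact (preprocess report, transitions
#' table, estimate tables per scenario, cohort summary, manifest, log)
#' into `output_dir`. Deterministic for a fixed input and configuration.
#'
#' @param records An `injury_records` tibble (raw, pre-cleaning).
#' @param output_dir Directory created if needed.
#' @param map Optional [normalization_map()].
#' @param level `"part_nature"` or `"categorization"`.
#' @param denominator `"global"` or `"row"`.
#' @param min_p Reporting threshold (default 0.002).
#' @param ci_method,confidence Passed to [attach_cis()].
#' @param semantics Transition semantics, `"chain"` or `"star"`.
#' @param drop_unknown_contact,drop_exacerbations,season_start_month
#'   Passed to [preprocess()].
#' @param plots Also render heatmaps (default off).
#' @return Invisibly, a list with `records_clean`, `preprocess_report`,
#'   `transitions`, `estimates` (unfiltered, CIs attached),
#'   `estimates_reported` (threshold applied), `summary`, and the paths
#'   written.
#' @export
run_pipeline <- function(records, output_dir,
                         map = NULL,
                         level = c("part_nature", "categorization"),
                         denominator = c("global", "row"),
                         min_p = 0.002,
                         ci_method = "wald", confidence = 0.95,
                         semantics = "chain",
                         drop_unknown_contact = FALSE,
                         drop_exacerbations = FALSE,
                         season_start_month = 7,
                         plots = FALSE) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  say("stage records: %d records in", nrow(records))

  pp <- preprocess(records, map = map,
                   drop_unknown_contact = drop_unknown_contact,
                   drop_exacerbations = drop_exacerbations,
                   season_start_month = season_start_month)
  say("stage preprocess: %d -> %d (%s)", pp$report$before, pp$report$after,
      paste(sprintf("%s -%d", names(pp$report$removed), pp$report$removed),
            collapse = ", "))

  seqs <- withCallingHandlers(
    build_sequences(pp$records),
    warning = function(w) {
      say("warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  say("stage sequences: %d records in %d player-season sequences",
      nrow(seqs), length(unique(seqs$seq_id)))

  transitions <- extract_transitions(seqs, semantics = semantics)
  say("stage transitions: %d transitions (%s semantics)",
      nrow(transitions), semantics)
  write_transitions(transitions, file.path(output_dir, "transitions.csv"))

  counts <- count_transitions(transitions, level = level)
  est <- estimate_probabilities(counts, denominator = denominator)
  est <- attach_cis(est, method = ci_method, confidence = confidence)
  say("stage estimates: %d observed (from,to) pairs, level %s, denominator %s",
      nrow(est), level, denominator)

  reported <- filter_transitions(est, min_p = min_p)
  say("stage filter: %d pairs at p >= %g", nrow(reported), min_p)
  readr::write_csv(est, file.path(output_dir, "estimates_full.csv"))
  readr::write_csv(reported, file.path(output_dir, "estimates_reported.csv"))

  scen_set <- if (level == "part_nature") {
    c(same_part_same_nature = "scenario1_same_part_same_nature",
      same_part_diff_nature = "scenario2_same_part_diff_nature",
      any = "scenario3_any")
  } else c(any = "categorization")
  paths <- character(0)
  for (sc in names(scen_set)) {
    sub <- scenario_table(reported, sc)
    stem <- file.path(output_dir, scen_set[[sc]])
    matrix_report(sub, file = paste0(stem, "_matrix.csv"),
                  plot_file = if (plots && nrow(sub) > 0) {
                    paste0(stem, "_heatmap.png")
                  } else NULL)
    ci_report(sub, file = paste0(stem, "_ci.csv"))
    paths <- c(paths, paste0(stem, "_matrix.csv"), paste0(stem, "_ci.csv"))
  }

  # summary base: all recorded injuries, with consistent naming so the
  # body-part distribution aggregates label variants correctly
  summary <- cohort_summary(normalize_labels(records, map), transitions,
                            season_start_month = season_start_month)
  jsonlite::write_json(
    list(n_injuries = summary$n_injuries,
         n_subsequent = summary$n_subsequent,
         subsequent_share = summary$subsequent_share,
         n_players_with_subsequent = summary$n_players_with_subsequent,
         mean_subsequent_per_player_season = summary$mean_subsequent_per_player_season,
         sd_subsequent_per_player_season = summary$sd_subsequent_per_player_season,
         body_part_distribution = as.list(summary$body_part_distribution)),
    file.path(output_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")

  report_df <- tibble::tibble(rule = names(pp$report$removed),
                              removed = as.integer(pp$report$removed))
  readr::write_csv(report_df, file.path(output_dir, "preprocess_report.csv"))

  manifest <- list(
    package = "injurychain",
    version = as.character(utils::packageVersion("injurychain")),
    stages = c("records", "preprocess", "sequences", "transitions",
               "estimates", "reports"),
    parameters = list(level = level, denominator = denominator, min_p = min_p,
                      ci_method = ci_method, confidence = confidence,
                      semantics = semantics,
                      drop_unknown_contact = drop_unknown_contact,
                      drop_exacerbations = drop_exacerbations,
                      season_start_month = season_start_month)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(output_dir, "pipeline.log"))

  invisible(list(
    records_clean = pp$records,
    preprocess_report = pp$report,
    transitions = transitions,
    counts = counts,
    estimates = est,
    estimates_reported = reported,
    summary = summary,
    output_dir = output_dir
  ))
}
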