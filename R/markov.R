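# First-order Markov machinery: injury states, transition counting,
# probability estimation under the two denominator conventions, the
# three-scenario classification, and the reporting threshold.
#
# A state is either a side-qualified body part crossed with the tissue
# nature ("Thigh|L : muscle") or a specific diagnosis categorisation
# label ("Hamstring Muscle Injury"). The denominator convention matters:
# `global` divides each cell count by the total number of transitions
# (all probabilities sum to 1); `row` divides by the transitions leaving
# the from-state (each occupied row sums to 1, the conditional kernel).

#' Injury state labels for records or transition endpoints
#'
#' At the `part_nature` level the state is the side-qualified body part
#' combined with the injury nature; at the `categorization` level it is
#' the specific diagnosis label. Records with no category (or one in the
#' exclusion list, by default "Unsure" and "Others") have no
#' categorization-level state and return `NA`.
#'
#' @param body_part,nature,category Character vectors (recycled
#'   together); `category` only used at the categorization level.
#' @param level `"part_nature"` or `"categorization"`.
#' @param category_exclude Category labels excluded from
#'   categorization-level analysis.
#' @return Character vector of state labels (`NA` where excluded).
#' @export
state_label <- function(body_part, nature, category = NULL,
                        level = c("part_nature", "categorization"),
                        category_exclude = c("Unsure", "Others")) {
  level <- match.arg(level)
  if (level == "part_nature") {
    out <- paste(body_part, nature, sep = " : ")
    out[is.na(body_part) | is.na(nature) | body_part == "" | nature == ""] <-
      NA_character_
    out
  } else {
    out <- category
    out[!is.na(out) & out %in% category_exclude] <- NA_character_
    out
  }
}

#' State of each record in a record set
#'
#' Convenience wrapper over [state_label()] for an `injury_records`
#' tibble (body parts must already be side-qualified for the
#' part_nature level to mirror the analysis states).
#'
#' @inheritParams state_label
#' @param records An `injury_records` tibble.
#' @return Character vector, one state per record.
#' @export
record_states <- function(records, level = c("part_nature", "categorization"),
                          category_exclude = c("Unsure", "Others")) {
  level <- match.arg(level)
  state_label(records$body_part, records$nature, records$category,
              level = level, category_exclude = category_exclude)
}

#' Count transitions between injury states
#'
#' Tallies transitions by (from-state, to-state). At the categorization
#' level, transitions whose endpoints lack a usable category (missing,
#' or in the exclusion list) are dropped before counting, so the total
#' may be smaller than the number of input transitions.
#'
#' @param transitions Output of [extract_transitions()].
#' @param level `"part_nature"` (default) or `"categorization"`.
#' @param category_exclude Passed to [state_label()].
#' @return A `transition_counts` object: list with `level`, `states`
#'   (sorted state labels), `counts` (square integer matrix) and
#'   `total` (= `sum(counts)`).
#' @export
count_transitions <- function(transitions,
                              level = c("part_nature", "categorization"),
                              category_exclude = c("Unsure", "Others")) {
  level <- match.arg(level)
  from <- state_label(transitions$from_body_part, transitions$from_nature,
                      transitions$from_category, level, category_exclude)
  to <- state_label(transitions$to_body_part, transitions$to_nature,
                    transitions$to_category, level, category_exclude)
  keep <- !is.na(from) & !is.na(to)
  from <- from[keep]; to <- to[keep]
  states <- sort(unique(c(from, to)))
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(from = states, to = states))
  if (length(from) > 0) {
    tab <- table(factor(from, levels = states), factor(to, levels = states))
    counts[] <- as.integer(tab)
  }
  structure(list(level = level, states = states, counts = counts,
                 total = length(from)),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf("<transition_counts: %d states, %d transitions (%s level)>\n",
              length(x$states), x$total, x$level))
  invisible(x)
}

#' Estimate transition probabilities
#'
#' Two denominator conventions are supported. `global` divides each cell
#' count by the total number of transitions, so the probabilities of all
#' pairs sum to 1 — this convention reproduces published figures whose
#' confidence intervals use the overall subsequent-injury count as the
#' sample size. `row` divides by the number of transitions leaving the
#' from-state, giving the conditional (row-stochastic) Markov kernel:
#' each occupied row sums to 1.
#'
#' Only observed (count > 0) pairs are returned; unobserved pairs carry
#' probability 0 under either convention.
#'
#' @param counts A `transition_counts` object.
#' @param denominator `"global"` (default) or `"row"`.
#' @return A `transition_estimates` tibble: `from_state`, `to_state`,
#'   `count`, `denominator`, `n_denominator`, `p`, plus `scenario` for
#'   part_nature-level counts.
#' @export
estimate_probabilities <- function(counts, denominator = c("global", "row")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(counts, "transition_counts"))
  if (counts$total == 0 && denominator == "global") {
    stop("no transitions: global probabilities undefined", call. = FALSE)
  }
  idx <- which(counts$counts > 0, arr.ind = TRUE)
  from_state <- counts$states[idx[, 1]]
  to_state <- counts$states[idx[, 2]]
  n_cell <- counts$counts[idx]
  n_den <- if (denominator == "global") {
    rep(counts$total, length(n_cell))
  } else {
    unname(rowSums(counts$counts)[idx[, 1]])
  }
  est <- tibble::tibble(
    from_state = from_state, to_state = to_state,
    count = as.integer(n_cell),
    denominator = denominator,
    n_denominator = as.integer(n_den),
    p = n_cell / n_den
  )
  est <- dplyr::arrange(est, .data$from_state, .data$to_state)
  if (counts$level == "part_nature") {
    est$scenario <- classify_scenario(est$from_state, est$to_state)
  } else {
    est$scenario <- "any"
  }
  attr(est, "level") <- counts$level
  class(est) <- c("transition_estimates", class(est))
  est
}

split_state <- function(state) {
  pos <- regexpr(" : ", state, fixed = TRUE)
  if (any(pos < 0 & !is.na(state))) {
    stop("not a part_nature state label: ",
         paste(utils::head(state[pos < 0], 3), collapse = ", "), call. = FALSE)
  }
  list(body_part = substr(state, 1, pos - 1),
       nature = substr(state, pos + 3, nchar(state)))
}

#' Classify a transition into the subsequent-injury scenarios
#'
#' The three standard scenarios: a subsequent injury to the same body
#' part with the same nature (`same_part_same_nature`, the re-injury
#' case), to the same body part with a different nature
#' (`same_part_diff_nature`), and to a different body part
#' (`different_part`). Every transition belongs to the catch-all
#' scenario "any"; the first two are disjoint and together cover exactly
#' the same-body-part transitions. Inputs must be part_nature-level
#' state labels — the taxonomy is anatomical.
#'
#' @param from_state,to_state Part_nature state labels (vectors).
#' @return Character vector: `"same_part_same_nature"`,
#'   `"same_part_diff_nature"` or `"different_part"`.
#' @export
classify_scenario <- function(from_state, to_state) {
  f <- split_state(from_state)
  t <- split_state(to_state)
  dplyr::case_when(
    f$body_part == t$body_part & f$nature == t$nature ~ "same_part_same_nature",
    f$body_part == t$body_part ~ "same_part_diff_nature",
    TRUE ~ "different_part"
  )
}

#' Apply the reporting probability threshold
#'
#' Removes estimates whose probability is strictly below `min_p`
#' (default 0.002, i.e. 0.2%): a presentation-layer filter for
#' clinically meaningful patterns. Counts, totals and denominators are
#' always computed before filtering, so filtering never changes any
#' retained estimate.
#'
#' @param estimates A `transition_estimates` tibble.
#' @param min_p Minimum retained probability; `p == min_p` survives.
#' @return The retained subset.
#' @export
filter_transitions <- function(estimates, min_p = 0.002) {
  estimates[estimates$p >= min_p, , drop = FALSE]
}

#' Restrict estimates to one subsequent-injury scenario
#'
#' @param estimates A `transition_estimates` tibble (scenario column
#'   populated).
#' @param scenario `"same_part_same_nature"`, `"same_part_diff_nature"`,
#'   `"different_part"`, or `"any"` (returns everything).
#' @return The subset for that scenario.
#' @export
scenario_table <- function(estimates,
                           scenario = c("any", "same_part_same_nature",
                                        "same_part_diff_nature",
                                        "different_part")) {
  scenario <- match.arg(scenario)
  if (scenario == "any") return(estimates)
  estimates[estimates$scenario == scenario, , drop = FALSE]
}
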