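test_that("state labels combine side-qualified body part and nature", {
  expect_equal(state_label("Thigh|L", "muscle"), "Thigh|L : muscle")
  expect_true(state_label("Thigh|L", "muscle") != state_label("Thigh|R", "muscle"))
  expect_equal(state_label("x", "y", "Hamstring Muscle Injury",
                           level = "categorization"),
               "Hamstring Muscle Injury")
  # records without a usable category have no categorization-level state
  expect_true(is.na(state_label("x", "y", "Unsure", level = "categorization")))
  expect_true(is.na(state_label("x", "y", "Others", level = "categorization")))
  expect_true(is.na(state_label("x", "y", NA, level = "categorization")))
  expect_equal(state_label("x", "y", "Unsure", level = "categorization",
                           category_exclude = character(0)), "Unsure")
})

toy_transitions <- function() {
  tibble::tibble(
    player_id = "P1", season_label = "2015-16",
    from_body_part = c("A", "A", "A", "B"),
    from_nature = "muscle",
    from_category = c("CatA", "CatA", "CatA", "Unsure"),
    from_date = as.Date("2015-09-01"),
    to_body_part = c("B", "B", "C", "C"),
    to_nature = "muscle",
    to_category = c("CatB", "CatB", "CatC", "CatC"),
    to_date = as.Date("2015-10-01"),
    gap_days = 30L
  )
}

test_that("transition counting tallies (from, to) pairs", {
  m <- count_transitions(toy_transitions())
  expect_equal(m$total, 4)
  expect_equal(m$counts["A : muscle", "B : muscle"], 2)
  expect_equal(m$counts["A : muscle", "C : muscle"], 1)
  expect_equal(m$counts["B : muscle", "C : muscle"], 1)
  expect_equal(sum(m$counts), m$total)
  empty <- count_transitions(toy_transitions()[0, ])
  expect_equal(empty$total, 0)
  expect_equal(sum(empty$counts), 0)
})

test_that("categorization-level counting drops excluded endpoints", {
  m <- count_transitions(toy_transitions(), level = "categorization")
  # the B -> C transition has from_category "Unsure" and is excluded
  expect_equal(m$total, 3)
  expect_false("Unsure" %in% m$states)
  expect_equal(m$counts["CatA", "CatB"], 2)
})

test_that("counts equal a brute-force tally on random transitions", {
  set.seed(99)
  states <- c("S1", "S2", "S3", "S4")
  tr <- tibble::tibble(
    player_id = "P", season_label = "s",
    from_body_part = sample(states, 100, TRUE), from_nature = "n",
    from_category = NA_character_, from_date = as.Date("2015-09-01"),
    to_body_part = sample(states, 100, TRUE), to_nature = "n",
    to_category = NA_character_, to_date = as.Date("2015-09-02"),
    gap_days = 1L)
  m <- count_transitions(tr)
  bf <- bf_count_matrix(paste(tr$from_body_part, "n", sep = " : "),
                        paste(tr$to_body_part, "n", sep = " : "))
  expect_identical(unname(m$counts[rownames(bf), colnames(bf)]),
                   unname(matrix(as.integer(bf), nrow(bf))))
  expect_equal(rownames(m$counts), rownames(bf))
})

test_that("probability estimation honours both denominator conventions", {
  tr <- toy_transitions()
  m <- count_transitions(tr)
  g <- estimate_probabilities(m, "global")
  expect_equal(g$p[g$from_state == "A : muscle" & g$to_state == "B : muscle"],
               0.5)
  expect_equal(sort(g$p), sort(c(0.5, 0.25, 0.25)))
  expect_equal(sum(g$p), 1)
  expect_true(all(g$n_denominator == 4))
  r <- estimate_probabilities(m, "row")
  expect_equal(r$p[r$from_state == "A : muscle" & r$to_state == "B : muscle"],
               2 / 3)
  expect_equal(r$p[r$from_state == "B : muscle"], 1)
  rowsum <- tapply(r$p, r$from_state, sum)
  expect_true(all(abs(rowsum - 1) < 1e-12))
  # a 120-count cell over 1,599 total is 7.5% under the global convention
  expect_equal(120 / 1599, 0.0750, tolerance = 1e-3)
  expect_error(estimate_probabilities(count_transitions(tr[0, ]), "global"),
               "no transitions")
})

test_that("scenario classification follows the three-scenario taxonomy", {
  expect_equal(classify_scenario("Thigh|L : muscle", "Thigh|L : muscle"),
               "same_part_same_nature")
  expect_equal(classify_scenario("Hip and Groin|R : muscle",
                                 "Hip and Groin|R : tendon"),
               "same_part_diff_nature")
  expect_equal(classify_scenario("Ankle|L : ligament", "Thigh|L : muscle"),
               "different_part")
  # side-qualified parts differ: not the same body part
  expect_equal(classify_scenario("Thigh|L : muscle", "Thigh|R : muscle"),
               "different_part")
  expect_error(classify_scenario("Hamstring Muscle Injury", "ACL"),
               "part_nature")
})

test_that("scenarios partition every transition set", {
  coh <- generate_cohort(small_noisy_config(), seed = 8)
  pp <- preprocess(coh$records, map = coh$truth$normalization_map)
  tr <- extract_transitions(suppressWarnings(build_sequences(pp$records)))
  est <- estimate_probabilities(count_transitions(tr), "global")
  s1 <- scenario_table(est, "same_part_same_nature")
  s2 <- scenario_table(est, "same_part_diff_nature")
  s3 <- scenario_table(est, "different_part")
  all_est <- scenario_table(est, "any")
  expect_equal(nrow(s1) + nrow(s2) + nrow(s3), nrow(est))
  expect_equal(nrow(all_est), nrow(est))
  expect_equal(length(intersect(paste(s1$from_state, s1$to_state),
                                paste(s2$from_state, s2$to_state))), 0)
  # scenario 1 and 2 together are exactly the same-body-part pairs
  same_part <- est[split_part(est$from_state) == split_part(est$to_state), ]
  expect_setequal(paste(c(s1$from_state, s2$from_state),
                        c(s1$to_state, s2$to_state)),
                  paste(same_part$from_state, same_part$to_state))
})

test_that("the reporting threshold keeps p >= 0.002 and filters below", {
  est <- tibble::tibble(
    from_state = c("a", "b", "c"), to_state = "z",
    count = c(1L, 2L, 50L), denominator = "global",
    n_denominator = 1000L, p = c(0.0019, 0.002, 0.05),
    scenario = "different_part")
  kept <- filter_transitions(est)
  expect_equal(kept$from_state, c("b", "c"))
  expect_equal(nrow(filter_transitions(est[0, ])), 0)
  # filtering is presentation-only: retained rows are unchanged
  expect_equal(kept$p, est$p[2:3])
  expect_equal(kept$n_denominator, est$n_denominator[2:3])
})

test_that("estimates match the brute-force oracle on random cohorts", {
  for (seed in c(21, 22, 23)) {
    coh <- generate_cohort(small_noisy_config(), seed = seed)
    pp <- preprocess(coh$records, map = coh$truth$normalization_map)
    tr <- extract_transitions(suppressWarnings(build_sequences(pp$records)))
    m <- count_transitions(tr)
    bf <- bf_analysis(pp$records)
    expect_identical(unname(m$counts[rownames(bf$counts), colnames(bf$counts)]),
                     unname(matrix(as.integer(bf$counts), nrow(bf$counts))))
    g <- estimate_probabilities(m, "global")
    r <- estimate_probabilities(m, "row")
    for (k in seq_len(nrow(g))) {
      expect_identical(g$p[k], bf$global[g$from_state[k], g$to_state[k]])
    }
    for (k in seq_len(nrow(r))) {
      expect_identical(r$p[k], bf$row[r$from_state[k], r$to_state[k]])
    }
  }
})
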