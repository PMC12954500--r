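# Small record builders used across the suite. All fixtures are built
# in code; nothing is read from disk unless a test writes it first.

rec_row <- function(player_id = "P1", injury_date = "2015-09-01",
                    season_label = NA_character_, body_part = "Thigh",
                    side = "left", nature = "muscle",
                    category = NA_character_, onset = "sudden",
                    severity_days = 7L, contact = "no", context = "match",
                    recurrence_class = "index") {
  data.frame(player_id = player_id, injury_date = injury_date,
             season_label = season_label, body_part = body_part,
             side = side, nature = nature, category = category,
             onset = onset, severity_days = severity_days, contact = contact,
             context = context, recurrence_class = recurrence_class,
             stringsAsFactors = FALSE)
}

make_records <- function(...) {
  as_injury_records(do.call(rbind, list(...)))
}

split_part <- function(state) sub(" : .*$", "", state)

# a small cohort config used for randomized property tests: noisy but
# cheap (a few hundred records)
small_noisy_config <- function(...) {
  cohort_config(
    n_players = 120,
    seasons = c("2015-16", "2016-17"),
    injuries_per_player_season = list(dist = "poisson", lambda = 0.7),
    contact_rate = 0.06,
    missing_field_prob = 0.02,
    label_noise_prob = 0.2,
    category_unsure_prob = 0.05,
    ...
  )
}
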