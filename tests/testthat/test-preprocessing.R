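test_that("label normalisation applies the map and is idempotent", {
  map <- normalization_map(body_part = c("Thigh muscles" = "Thigh",
                                         "thigh" = "Thigh"))
  rs <- as_injury_records(rbind(rec_row("P1", body_part = "Thigh muscles"),
                                rec_row("P2", body_part = "Thigh")))
  out <- normalize_labels(rs, map)
  expect_equal(out$body_part, c("Thigh", "Thigh"))
  expect_identical(normalize_labels(out, map)$body_part, out$body_part)
})

test_that("unmapped labels warn in lax mode and abort in strict mode", {
  rs <- as_injury_records(rec_row(body_part = "Shin"))
  lax <- normalization_map(body_part = c("thigh" = "Thigh"))
  expect_warning(out <- normalize_labels(rs, lax), "Shin")
  expect_equal(out$body_part, "Shin")
  strict <- normalization_map(body_part = c("thigh" = "Thigh"), strict = TRUE)
  expect_error(normalize_labels(rs, strict), "Shin")
})

test_that("a non-idempotent map is rejected at construction", {
  expect_error(normalization_map(body_part = c("thigh" = "Thigh",
                                               "Thigh" = "Upper Leg")),
               "idempotent")
})

test_that("normalisation maps round-trip through the key/value file format", {
  map <- normalization_map(body_part = c("thigh" = "Thigh"),
                           nature = c("Muscle" = "muscle", "MUSCLE" = "muscle"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "body_part\tthigh\tThigh",
               "nature\tMuscle\tmuscle", "nature\tMUSCLE\tmuscle"), path)
  back <- read_normalization_map(path)
  expect_equal(back$entries$body_part, map$entries$body_part)
  expect_equal(back$entries$nature, map$entries$nature)
})

test_that("records missing only non-core fields survive the core-field rule", {
  rs <- as_injury_records(rbind(
    rec_row("P1"), rec_row("", body_part = "Knee"),
    rec_row("P3", body_part = ""), rec_row("P4", side = NA_character_)))
  out <- drop_missing_core(rs)
  expect_equal(nrow(out$records), 2)
  expect_equal(out$report$removed[["missing_core"]], 2)
  expect_true("P4" %in% out$records$player_id)  # side is not a core field
})

test_that("contact exclusion removes caused-by-contact, keeps unknown by default", {
  rows <- do.call(rbind, c(
    lapply(1:4, function(i) rec_row(paste0("C", i), contact = "yes")),
    lapply(1:4, function(i) rec_row(paste0("N", i), contact = "no")),
    lapply(1:2, function(i) rec_row(paste0("U", i), contact = "unknown"))))
  rs <- as_injury_records(rows)
  out <- drop_contact(rs)
  expect_equal(nrow(out$records), 6)
  expect_false(any(out$records$contact == "yes"))
  expect_true(any(out$records$contact == "unknown"))
  strict <- drop_contact(rs, drop_unknown = TRUE)
  expect_equal(nrow(strict$records), 4)
  all_contact <- as_injury_records(rec_row(contact = "yes"))
  expect_equal(nrow(drop_contact(all_contact)$records), 0)
})

test_that("side merging yields distinct side-qualified body parts", {
  rs <- as_injury_records(rbind(
    rec_row("P1", body_part = "Thigh", side = "left"),
    rec_row("P2", body_part = "Thigh", side = "right"),
    rec_row("P3", body_part = "Ankle", side = "unspecified"),
    rec_row("P4", body_part = "Knee", side = "bilateral")))
  out <- merge_side_into_body_part(rs)
  expect_equal(out$body_part, c("Thigh|L", "Thigh|R", "Ankle|U", "Knee|B"))
  expect_equal(out$body_part_unsided, c("Thigh", "Thigh", "Ankle", "Knee"))
  expect_identical(merge_side_into_body_part(out)$body_part, out$body_part)
})

test_that("single-injury player-seasons are removed per season, not per player", {
  rs <- as_injury_records(rbind(
    rec_row("P1", "2015-09-01", season_label = "2015-16"),
    rec_row("P1", "2015-10-01", season_label = "2015-16"),
    rec_row("P1", "2016-09-01", season_label = "2016-17"),
    rec_row("P2", "2015-09-01", season_label = "2015-16")))
  out <- drop_single_injury_player_seasons(rs)
  expect_equal(nrow(out$records), 2)
  expect_true(all(out$records$player_id == "P1" &
                    out$records$season_label == "2015-16"))
  expect_equal(out$report$removed[["single_injury_player_season"]], 2)
  # brute-force check: surviving groups all have >= 2 members
  key <- paste(out$records$player_id, out$records$season_label)
  expect_true(all(table(key) >= 2))
})

test_that("seasons spanning calendar years derive from the start month", {
  d <- as.Date(c("2015-07-01", "2015-12-31", "2016-03-15", "2016-06-30",
                 "2016-07-01"))
  expect_equal(derive_season(d), c("2015-16", "2015-16", "2015-16", "2015-16",
                                   "2016-17"))
  expect_equal(derive_season(as.Date("2016-01-15"), season_start_month = 1),
               "2016-17")
})

test_that("the full pipeline applies rules in order and attributes each removal once", {
  map <- normalization_map(body_part = c("thigh" = "Thigh"))
  rows <- rbind(
    rec_row("P1", "2015-09-01", body_part = "thigh"),       # kept (pairs with next)
    rec_row("P1", "2015-10-01"),                            # kept
    rec_row("P2", "2015-09-01", contact = "yes"),           # contact rule (also single)
    rec_row("P3", "2015-09-01", body_part = ""),            # missing-core rule
    rec_row("P4", "2015-09-01"),                            # single-injury rule
    rec_row("P5", "2015-09-01"),                            # kept pair
    rec_row("P5", "2015-11-01"),                            # kept pair
    rec_row("P6", "2015-09-01"),                            # becomes single after
    rec_row("P6", "2015-10-01", contact = "yes"))           #   its partner's removal
  rs <- as_injury_records(rows)
  out <- preprocess(rs, map = map)
  expect_equal(out$report$before, 9)
  expect_equal(out$report$removed[["missing_core"]], 1)
  expect_equal(out$report$removed[["contact"]], 2)
  expect_equal(out$report$removed[["single_injury_player_season"]], 2)
  expect_equal(out$report$after, nrow(out$records))
  expect_equal(out$report$before - out$report$after, sum(out$report$removed))
  expect_setequal(unique(out$records$player_id), c("P1", "P5"))
  expect_true(all(grepl("\\|[LRBU]$", out$records$body_part)))
  # a contact injury that is also its player's only injury goes to the
  # contact rule, by rule order
  solo <- as_injury_records(rec_row("P9", contact = "yes"))
  solo_out <- preprocess(solo)
  expect_equal(solo_out$report$removed[["contact"]], 1)
  expect_equal(solo_out$report$removed[["single_injury_player_season"]], 0)
})

test_that("preprocessing is idempotent", {
  set.seed(42)
  coh <- generate_cohort(small_noisy_config(), seed = 5)
  once <- preprocess(coh$records, map = coh$truth$normalization_map)
  twice <- preprocess(once$records, map = coh$truth$normalization_map)
  expect_equal(tibble::as_tibble(twice$records), tibble::as_tibble(once$records))
  expect_equal(sum(twice$report$removed), 0)
})

test_that("exacerbation exclusion is available as an explicit option", {
  rs <- as_injury_records(rbind(
    rec_row("P1", "2015-09-01"),
    rec_row("P1", "2015-09-20", recurrence_class = "exacerbation"),
    rec_row("P1", "2015-11-01")))
  default <- preprocess(rs)
  expect_equal(nrow(default$records), 3)
  strict <- preprocess(rs, drop_exacerbations = TRUE)
  expect_equal(nrow(strict$records), 2)
  expect_equal(strict$report$removed[["exacerbation"]], 1)
})
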