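# Cleaning and exclusion rules that turn a raw record set into the
# analysis-ready dataset: consistent naming, removal of records with a
# missing player or body part, exclusion of contact injuries,
# side-qualified body parts, and removal of single-injury player-seasons.

#' Label normalisation map
#'
#' Exact-match mapping from raw labels to canonical labels, kept
#' separately for body part, nature and diagnosis category. Canonical
#' labels must be fixed points of their own map (idempotence), which is
#' checked at construction.
#'
#' @param body_part,nature,category Named character vectors,
#'   `c(raw = "canonical", ...)`.
#' @param strict If `TRUE`, labels absent from the map are an error when
#'   the map is applied; otherwise they pass through with a warning.
#' @return A `normalization_map` object.
#' @examples
#' normalization_map(body_part = c("Thigh muscles" = "Thigh"))
#' @export
normalization_map <- function(body_part = character(), nature = character(),
                              category = character(), strict = FALSE) {
  entries <- list(body_part = body_part, nature = nature, category = category)
  for (field in names(entries)) {
    m <- entries[[field]]
    if (length(m) == 0) next
    if (is.null(names(m)) || any(names(m) == "")) {
      stop("normalization entries for ", field, " must be named (raw = canonical)",
           call. = FALSE)
    }
    canon <- unique(unname(m))
    mapped <- canon %in% names(m)
    moved <- m[canon[mapped]] != canon[mapped]
    if (any(moved)) {
      stop("normalization map for ", field, " is not idempotent: canonical ",
           "label(s) ", paste(canon[mapped][moved], collapse = ", "),
           " are themselves remapped", call. = FALSE)
    }
  }
  structure(list(entries = entries, strict = strict),
            class = "normalization_map")
}

#' Read a normalisation map from a key/value file
#'
#' Plain-text format: one `field<TAB>raw<TAB>canonical` triple per line
#' (`field` one of body_part/nature/category); lines starting with `#`
#' are comments.
#'
#' @param path File path.
#' @param strict Passed to [normalization_map()].
#' @return A `normalization_map`.
#' @export
read_normalization_map <- function(path, strict = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) stop("malformed map line(s): ", paste(which(bad), collapse = ", "),
                     call. = FALSE)
  m <- do.call(rbind, parts)
  entry <- function(field) {
    sel <- m[, 1] == field
    stats::setNames(m[sel, 3], m[sel, 2])
  }
  normalization_map(body_part = entry("body_part"), nature = entry("nature"),
                    category = entry("category"), strict = strict)
}

apply_map_field <- function(x, m, field, strict) {
  if (length(m) == 0) return(x)
  hit <- !is.na(x) & x %in% names(m)
  out <- x
  out[hit] <- unname(m[x[hit]])
  unmapped <- unique(x[!hit & !is.na(x) & x != "" & !(x %in% unname(m))])
  if (length(unmapped) > 0) {
    if (strict) {
      stop("unmapped ", field, " label(s): ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    }
    warning("unmapped ", field, " label(s) passed through: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  out
}

#' Normalise body-part, nature and category labels
#'
#' Applies the exact-match map to the three label fields so that naming
#' is consistent across the dataset. In strict mode an unmapped label is
#' fatal (all offenders listed); otherwise unmapped labels pass through
#' with one warning per field.
#'
#' @param records An `injury_records` tibble.
#' @param map A [normalization_map()]; `NULL` is a no-op.
#' @return The records with canonical labels.
#' @export
normalize_labels <- function(records, map) {
  if (is.null(map)) return(records)
  stopifnot(inherits(map, "normalization_map"))
  e <- map$entries
  if ("body_part_unsided" %in% names(records)) {
    # already side-merged: the unqualified label lives in the audit
    # column and the side-qualified tokens are left untouched
    records$body_part_unsided <- apply_map_field(records$body_part_unsided,
                                                 e$body_part, "body_part",
                                                 map$strict)
  } else {
    records$body_part <- apply_map_field(records$body_part, e$body_part,
                                         "body_part", map$strict)
  }
  records$nature <- apply_map_field(records$nature, e$nature,
                                    "nature", map$strict)
  records$category <- apply_map_field(records$category, e$category,
                                      "category", map$strict)
  records
}

new_preprocess_report <- function(before, removed) {
  structure(list(
    before = before,
    removed = removed,
    after = before - sum(removed)
  ), class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report: %d -> %d records>\n", x$before, x$after))
  for (rule in names(x$removed)) {
    cat(sprintf("  %-28s -%d\n", rule, x$removed[[rule]]))
  }
  invisible(x)
}

#' Drop records with a missing player identifier or body part
#'
#' These two fields are required to decide whether a previous injury
#' exists for the player, so records lacking either are removed.
#'
#' @param records An `injury_records` tibble.
#' @return `list(records = , report = )`; the report counts removals.
#' @export
drop_missing_core <- function(records) {
  keep <- records$player_id != "" & records$body_part != ""
  list(records = records[keep, , drop = FALSE],
       report = new_preprocess_report(length(keep),
                                      c(missing_core = sum(!keep))))
}

#' Drop contact-caused injuries
#'
#' Removes records whose injury was caused by contact. Records with an
#' unknown contact mechanism are retained by default: the exclusion rule
#' targets injuries caused by contact, not injuries of unknown
#' mechanism. Set `drop_unknown = TRUE` for the strict reading.
#'
#' @param records An `injury_records` tibble.
#' @param drop_unknown Also remove `contact = "unknown"` records.
#' @return `list(records = , report = )`.
#' @export
drop_contact <- function(records, drop_unknown = FALSE) {
  drop <- records$contact == "yes"
  if (drop_unknown) drop <- drop | records$contact == "unknown"
  list(records = records[!drop, , drop = FALSE],
       report = new_preprocess_report(length(drop),
                                      c(contact = sum(drop))))
}

#' Drop exacerbation records
#'
#' Optionally removes recurrences recorded before return to play
#' (`recurrence_class = "exacerbation"`). Off by default: exacerbations
#' are ordinary records unless explicitly excluded.
#'
#' @param records An `injury_records` tibble.
#' @return `list(records = , report = )`.
#' @export
drop_exacerbation_records <- function(records) {
  drop <- records$recurrence_class == "exacerbation"
  list(records = records[!drop, , drop = FALSE],
       report = new_preprocess_report(length(drop),
                                      c(exacerbation = sum(drop))))
}

#' Fold the side field into the body part
#'
#' Replaces `body_part` with a side-qualified token (`"Thigh|L"`,
#' `"Thigh|R"`, `"Knee|B"` for bilateral, `"Ankle|U"` for unspecified) so
#' that the left and right instances of a body part are distinct injury
#' states. The unqualified label is preserved in `body_part_unsided` for
#' audit; applying the operation twice is a no-op.
#'
#' @param records An `injury_records` tibble with normalised labels.
#' @return The records with side-qualified `body_part`.
#' @export
merge_side_into_body_part <- function(records) {
  if ("body_part_unsided" %in% names(records)) return(records)
  code <- c(left = "L", right = "R", bilateral = "B", unspecified = "U")
  records$body_part_unsided <- records$body_part
  has_part <- records$body_part != ""
  records$body_part[has_part] <- paste0(records$body_part[has_part], "|",
                                        code[records$side[has_part]])
  records
}

#' Derive the season label from the injury date
#'
#' Seasons span calendar years (default start month July), so an injury
#' in 2015-09 belongs to "2015-16" and one in 2016-03 also to "2015-16".
#'
#' @param dates A Date vector.
#' @param season_start_month Integer month (1-12) the season starts in.
#' @return Character season labels like `"2015-16"`.
#' @export
derive_season <- function(dates, season_start_month = 7) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  start <- ifelse(m >= season_start_month, y, y - 1L)
  sprintf("%d-%02d", start, (start + 1L) %% 100L)
}

resolve_seasons <- function(records, season_start_month = 7) {
  miss <- is.na(records$season_label)
  if (any(miss)) {
    if (any(is.na(records$injury_date[miss]))) {
      stop("cannot resolve season: records with neither season_label nor date",
           call. = FALSE)
    }
    records$season_label[miss] <-
      derive_season(records$injury_date[miss], season_start_month)
  }
  records
}

#' Drop player-seasons with a single injury
#'
#' A player with only one injury in a season has no previous injury in
#' that season, so the record cannot participate in any within-season
#' transition and is removed. Applied repeatedly until no group of size
#' one remains (a fixed point is reached after one pass, since removing
#' a whole group cannot shrink another group).
#'
#' @param records An `injury_records` tibble with resolved seasons.
#' @return `list(records = , report = )`.
#' @export
drop_single_injury_player_seasons <- function(records) {
  before <- nrow(records)
  repeat {
    key <- paste(records$player_id, records$season_label, sep = "\r")
    sizes <- table(key)
    singles <- names(sizes)[sizes < 2]
    if (length(singles) == 0) break
    records <- records[!(key %in% singles), , drop = FALSE]
  }
  list(records = records,
       report = new_preprocess_report(before,
                                      c(single_injury_player_season = before - nrow(records))))
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: label normalisation, removal of records missing a
#' player id or body part, exclusion of contact injuries (optionally
#' exacerbations), side-merging of body parts, season resolution, and
#' removal of single-injury player-seasons. The single-injury rule runs
#' last because earlier exclusions can reduce a player-season to one
#' record. Each removed record is attributed to exactly one rule, so the
#' per-rule removals sum to `before - after`; the pipeline is idempotent.
#'
#' @param records An `injury_records` tibble.
#' @param map Optional [normalization_map()].
#' @param drop_unknown_contact Also exclude `contact = "unknown"`.
#' @param drop_exacerbations Also exclude exacerbation recurrences.
#' @param season_start_month Month the season starts in (default July).
#' @return `list(records = , report = )` where the report aggregates the
#'   per-rule removal counts.
#' @export
preprocess <- function(records, map = NULL, drop_unknown_contact = FALSE,
                       drop_exacerbations = FALSE, season_start_month = 7) {
  before <- nrow(records)
  records <- normalize_labels(records, map)
  s1 <- drop_missing_core(records)
  s2 <- drop_contact(s1$records, drop_unknown = drop_unknown_contact)
  records <- s2$records
  removed <- c(s1$report$removed, s2$report$removed)
  if (drop_exacerbations) {
    s2b <- drop_exacerbation_records(records)
    records <- s2b$records
    removed <- c(removed, s2b$report$removed)
  }
  records <- merge_side_into_body_part(records)
  records <- resolve_seasons(records, season_start_month)
  s3 <- drop_single_injury_player_seasons(records)
  removed <- c(removed, s3$report$removed)
  list(records = s3$records,
       report = new_preprocess_report(before, removed))
}
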