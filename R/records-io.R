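# Reading, validating and writing consensus-style time-loss injury records.

# Canonical column order for serialised record tables. Also the default
# header names expected on input (remappable via injury_schema()).
IC_COLUMNS <- c(
  "player_id", "injury_date", "season_label", "body_part", "side",
  "nature", "category", "onset", "severity_days", "contact", "context",
  "recurrence_class"
)

IC_ENUMS <- list(
  side             = c("left", "right", "bilateral", "unspecified"),
  onset            = c("sudden", "gradual"),
  contact          = c("yes", "no", "unknown"),
  context          = c("training", "match", "not_applicable"),
  recurrence_class = c("index", "reinjury", "exacerbation", "unknown")
)

# Enum columns that may legitimately be absent from an input file; they
# default to the listed token.
IC_ENUM_DEFAULTS <- c(
  side = "unspecified", onset = "sudden", contact = "unknown",
  context = "not_applicable", recurrence_class = "unknown"
)

#' Column-name schema for injury record files
#'
#' Maps the canonical field names used throughout the package to the
#' column headers of a particular export. Only fields whose header
#' differs from the canonical name need to be given.
#'
#' @param ... Named character scalars, e.g. `player_id = "Player ID"`.
#' @param date_formats Character vector of date formats tried in order
#'   when parsing `injury_date`. Defaults to ISO (`"%Y-%m-%d"`) only;
#'   additional formats are opt-in so that parsing stays deterministic.
#' @return A named list of class `injury_schema`.
#' @examples
#' injury_schema(player_id = "Player ID", body_part = "Body Part")
#' @export
injury_schema <- function(..., date_formats = "%Y-%m-%d") {
  override <- list(...)
  bad <- setdiff(names(override), IC_COLUMNS)
  if (length(bad) > 0) {
    stop("unknown record fields in schema: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mapping <- stats::setNames(as.list(IC_COLUMNS), IC_COLUMNS)
  mapping[names(override)] <- override
  structure(list(mapping = mapping, date_formats = date_formats),
            class = "injury_schema")
}

ic_parse_date <- function(x, formats) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  for (fmt in formats) {
    todo <- is.na(out) & !is.na(x) & nzchar(x)
    if (!any(todo)) break
    parsed <- as.Date(x[todo], format = fmt)
    # as.Date() silently rolls some impossible dates to NA already; guard
    # against format-dependent reinterpretation by round-tripping.
    ok <- !is.na(parsed) & format(parsed, fmt) == x[todo]
    parsed[!ok] <- as.Date(NA)
    out[todo] <- parsed
  }
  out
}

ic_canonical_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("", "na")] <- NA_character_
  # common synonyms seen in surveillance exports
  x[x == "l"] <- "left"
  x[x == "r"] <- "right"
  x[x %in% c("b", "both")] <- "bilateral"
  x[x == "u"] <- "unspecified"
  x[x %in% c("n/a", "na.")] <- "not applicable"
  gsub("[ -]", "_", x)
}

new_injury_records <- function(df, provenance) {
  df <- tibble::as_tibble(df)
  attr(df, "provenance") <- provenance
  class(df) <- c("injury_records", class(df))
  df
}

#' @export
print.injury_records <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<injury_records: %d records>\n", nrow(x)))
  if (!is.null(prov)) {
    cat(sprintf("  source: %s (%s), rows read %d, accepted %d, rejected %d\n",
                prov$source %||% "<in memory>", prov$dialect %||% "none",
                prov$rows_read %||% nrow(x),
                prov$accepted %||% nrow(x), prov$rejected %||% 0L))
  }
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble an injury record set from a data frame
#'
#' Coerces a data frame with canonical column names into the validated
#' tibble used by the rest of the pipeline. Row-level problems (bad
#' dates, unknown enum tokens) reject the offending row, never the whole
#' set; rejection reasons are kept in the provenance attribute.
#'
#' @param df Data frame with (a subset of) the canonical columns; see
#'   [injury_schema()] for the field list.
#' @param source,dialect Provenance strings recorded on the result.
#' @param date_formats Date formats tried in order for `injury_date`.
#' @return An `injury_records` tibble. `provenance(x)` lists rows read,
#'   accepted and rejected with per-row reasons.
#' @export
as_injury_records <- function(df, source = "<in memory>",
                              dialect = "none",
                              date_formats = "%Y-%m-%d") {
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  for (col in setdiff(IC_COLUMNS, names(df))) {
    df[[col]] <- if (col == "severity_days") NA_integer_ else NA_character_
  }
  out <- tibble::tibble(
    player_id    = trimws(as.character(df$player_id)),
    injury_date  = ic_parse_date(df$injury_date, date_formats),
    season_label = trimws(as.character(df$season_label)),
    body_part    = trimws(as.character(df$body_part)),
    side         = ic_canonical_token(df$side),
    nature       = trimws(as.character(df$nature)),
    category     = trimws(as.character(df$category)),
    onset        = ic_canonical_token(df$onset),
    severity_days = suppressWarnings(as.integer(df$severity_days)),
    contact      = ic_canonical_token(df$contact),
    context      = ic_canonical_token(df$context),
    recurrence_class = ic_canonical_token(df$recurrence_class),
    .row         = seq_len(n)
  )
  out$player_id[is.na(out$player_id)] <- ""
  out$body_part[is.na(out$body_part)] <- ""
  out$season_label[out$season_label %in% ""] <- NA_character_
  out$category[out$category %in% ""] <- NA_character_

  reject_reason <- rep(NA_character_, n)
  had_date <- !is.na(trimws(as.character(df$injury_date))) &
    nzchar(trimws(as.character(df$injury_date)))
  reject_reason[is.na(out$injury_date)] <- ifelse(
    had_date[is.na(out$injury_date)], "bad date", "missing date")
  for (col in names(IC_ENUMS)) {
    vals <- out[[col]]
    vals[is.na(vals)] <- IC_ENUM_DEFAULTS[[col]]
    bad <- !(vals %in% IC_ENUMS[[col]])
    reject_reason[bad & is.na(reject_reason)] <- paste("bad", col)
    out[[col]] <- vals
  }
  bad_sev <- !is.na(df$severity_days) & is.na(out$severity_days)
  reject_reason[bad_sev & is.na(reject_reason)] <- "bad severity_days"

  keep <- is.na(reject_reason)
  rejects <- tibble::tibble(
    row = which(!keep),
    reason = reject_reason[!keep]
  )
  provenance <- list(
    source = source, dialect = dialect,
    rows_read = n, accepted = sum(keep), rejected = sum(!keep),
    rejects = rejects
  )
  new_injury_records(out[keep, , drop = FALSE], provenance)
}

#' Read injury surveillance records
#'
#' Reads one-injury-per-row tabular records from a delimited text file or
#' a spreadsheet workbook, applies the column-name schema, and performs
#' row-level parsing. Rows with an unparseable date or enum token are
#' rejected (and logged in the provenance), not fatal; a missing file or
#' a missing mandatory column is fatal.
#'
#' @param path Path to the input file.
#' @param dialect `"delimited"` (default) or `"spreadsheet"`.
#' @param schema An [injury_schema()] mapping canonical field names to
#'   the file's column headers.
#' @param delim Field delimiter for the delimited dialect.
#' @param sheet Sheet name or index for the spreadsheet dialect.
#' @return An `injury_records` tibble with provenance.
#' @seealso [write_injury_records()], [validate_injury_records()]
#' @export
read_injury_records <- function(path,
                                dialect = c("delimited", "spreadsheet"),
                                schema = injury_schema(),
                                delim = ",", sheet = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  stopifnot(inherits(schema, "injury_schema"))
  raw <- switch(dialect,
    delimited = readr::read_delim(
      path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    ),
    spreadsheet = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("the spreadsheet dialect requires the 'readxl' package",
             call. = FALSE)
      }
      readxl::read_excel(path, sheet = sheet,
                         col_types = "text", .name_repair = "minimal")
    }
  )
  mapping <- schema$mapping
  # mandatory mapped columns: those whose mapped header must exist
  mandatory <- c("player_id", "injury_date", "body_part", "nature")
  missing_cols <- vapply(mandatory,
                         function(f) !(mapping[[f]] %in% names(raw)),
                         logical(1))
  if (any(missing_cols)) {
    stop("mapped column(s) absent from header: ",
         paste(unlist(mapping[mandatory[missing_cols]]), collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(.rows = nrow(raw))
  for (f in IC_COLUMNS) {
    hdr <- mapping[[f]]
    df[[f]] <- if (hdr %in% names(raw)) raw[[hdr]] else NA_character_
  }
  as_injury_records(df, source = path, dialect = dialect,
                    date_formats = schema$date_formats)
}

#' Write injury records to a delimited file
#'
#' Serialises records in the canonical column order with enum fields as
#' lowercase tokens and ISO dates, so that
#' `read_injury_records(write_injury_records(x))` reproduces every field.
#' Spreadsheet output is not supported; the delimited layout is the
#' canonical on-disk form.
#'
#' @param records An `injury_records` tibble.
#' @param path Destination path.
#' @param dialect Only `"delimited"` is supported for output.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_injury_records <- function(records, path, dialect = "delimited",
                                 delim = ",") {
  if (!identical(dialect, "delimited")) {
    stop("only the delimited dialect is supported for output", call. = FALSE)
  }
  out <- tibble::as_tibble(records)[, intersect(IC_COLUMNS, names(records))]
  out$injury_date <- format(out$injury_date, "%Y-%m-%d")
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Provenance of a record set
#'
#' @param records An `injury_records` tibble.
#' @return A list with `source`, `dialect`, `rows_read`, `accepted`,
#'   `rejected` and a `rejects` tibble (row index + reason).
#' @export
provenance <- function(records) attr(records, "provenance")

#' Validate injury records against the field invariants
#'
#' Pure report: checks each record against the invariants (non-negative
#' severity, date inside the study window, non-empty player and body
#' part) without modifying the record set.
#'
#' @param records An `injury_records` tibble.
#' @param window Optional length-2 Date vector `c(start, end)` of the
#'   study window.
#' @return A tibble with one row per violation: `rule`, `row` (position
#'   in `records`) and `detail`.
#' @export
validate_injury_records <- function(records, window = NULL) {
  v <- list()
  add <- function(rule, rows, detail) {
    if (length(rows) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(rule = rule, row = rows,
                                            detail = detail)
    }
  }
  add("negative_severity", which(!is.na(records$severity_days) &
                                   records$severity_days < 0),
      "severity_days < 0")
  add("missing_player_id", which(records$player_id == ""), "empty player_id")
  add("missing_body_part", which(records$body_part == ""), "empty body_part")
  if (!is.null(window)) {
    window <- as.Date(window)
    stopifnot(length(window) == 2)
    add("out_of_window",
        which(records$injury_date < window[1] | records$injury_date > window[2]),
        sprintf("outside [%s, %s]", window[1], window[2]))
  }
  if (length(v) == 0) {
    tibble::tibble(rule = character(), row = integer(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}
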