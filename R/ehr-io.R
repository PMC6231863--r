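#' @importFrom rlang .data
NULL

# Table schemas for the five flat EHR extracts. Each schema lists required
# columns, which are timestamps, which are constrained enumerations, which
# are logical, and the primary key (if any). `optional` columns may be
# blank ("" or NA) on a row.
.ehr_schemas <- list(
  orders = list(
    columns = c("order_id", "patient_id", "ed_encounter_id", "order_type",
                "status", "order_datetime", "site_id"),
    timestamps = "order_datetime",
    enums = list(
      order_type = c("CTPA", "CTA_ABD_PELVIS", "OTHER"),
      status = c("COMPLETED", "CANCELLED", "DISCONTINUED")
    ),
    logicals = character(),
    key = "order_id",
    optional = character()
  ),
  ed_encounters = list(
    columns = c("ed_encounter_id", "patient_id", "arrival_datetime",
                "disposition"),
    timestamps = "arrival_datetime",
    enums = list(disposition = c("ADMITTED", "DISCHARGED_FROM_ED")),
    logicals = character(),
    key = "ed_encounter_id",
    optional = character()
  ),
  admissions = list(
    columns = c("admission_id", "patient_id", "source_ed_encounter_id",
                "admit_datetime", "discharge_datetime"),
    timestamps = c("admit_datetime", "discharge_datetime"),
    enums = list(),
    logicals = character(),
    key = "admission_id",
    optional = "source_ed_encounter_id"
  ),
  diagnoses = list(
    columns = c("admission_id", "icd_code", "icd_version", "rank"),
    timestamps = character(),
    enums = list(
      icd_version = c("ICD9", "ICD10"),
      rank = c("PRIMARY", "SECONDARY")
    ),
    logicals = character(),
    key = NULL,
    optional = character()
  ),
  gold_labels = list(
    columns = c("order_id", "chart_review_pe_positive"),
    timestamps = character(),
    enums = list(),
    logicals = "chart_review_pe_positive",
    key = "order_id",
    optional = character()
  )
)

#' Kinds of EHR tables the package reads and writes
#'
#' @return Character vector of the five table kinds.
#' @export
ehr_table_kinds <- function() names(.ehr_schemas)

#' Read and validate one EHR extract table
#'
#' Reads a comma-delimited UTF-8 file with a header row and validates every
#' row against the schema of the given table kind: required columns must be
#' present, timestamps must parse (ISO-8601, site-local wall clock),
#' enumerated columns must take allowed values (matched case-insensitively,
#' optionally through a synonym map), and primary keys must be unique.
#' Validation is total: a row is either accepted or produces an error that
#' names the row and the offending column; rows are never silently dropped.
#' Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param kind One of [ehr_table_kinds()]: `"orders"`, `"ed_encounters"`,
#'   `"admissions"`, `"diagnoses"`, `"gold_labels"`.
#' @param synonyms Optional named list: for an enumerated column, a named
#'   character vector mapping site-specific raw values (matched
#'   case-insensitively) to canonical enumeration values, e.g.
#'   `list(status = c(canceled = "CANCELLED"))`.
#' @return A tibble with canonical column types: timestamps as `POSIXct`,
#'   enumerations as upper-case character, logicals as logical.
#' @export
read_ehr_table <- function(path, kind, synonyms = NULL) {
  kind <- match.arg(kind, ehr_table_kinds())
  if (!file.exists(path)) {
    abort_io(sprintf("File not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  validate_ehr_table(raw, kind, synonyms = synonyms,
                     context = basename(path))
}

#' Validate an in-memory EHR table
#'
#' Applies the same schema validation as [read_ehr_table()] to a data frame
#' already in memory (all columns may be character; types are coerced).
#'
#' @param x A data frame.
#' @inheritParams read_ehr_table
#' @param context Label used in error messages (e.g. a file name).
#' @return A validated tibble.
#' @export
validate_ehr_table <- function(x, kind, synonyms = NULL, context = kind) {
  kind <- match.arg(kind, ehr_table_kinds())
  sch <- .ehr_schemas[[kind]]
  x <- tibble::as_tibble(x)

  missing_cols <- setdiff(sch$columns, names(x))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "%s: missing required column(s): %s",
      context, paste(missing_cols, collapse = ", ")
    ))
  }
  x <- x[sch$columns]

  required <- setdiff(sch$columns, sch$optional)
  for (col in required) {
    vals <- x[[col]]
    if (is.character(vals)) vals <- trimws(vals)
    bad <- if (is.character(vals)) which(is.na(vals) | vals == "") else which(is.na(vals))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "%s: column `%s` is missing/empty at row(s) %s.",
        context, col, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
  }

  for (col in sch$timestamps) {
    parsed <- parse_wallclock(as.character(x[[col]]))
    bad <- which(is.na(parsed) & !(col %in% sch$optional & is.na(x[[col]])))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "%s: column `%s` has unparseable timestamp(s) at row(s) %s (expected ISO-8601).",
        context, col, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
    x[[col]] <- parsed
  }

  for (col in names(sch$enums)) {
    allowed <- sch$enums[[col]]
    vals <- toupper(trimws(as.character(x[[col]])))
    syn <- synonyms[[col]]
    if (!is.null(syn)) {
      names(syn) <- toupper(names(syn))
      hit <- match(vals, names(syn))
      vals[!is.na(hit)] <- toupper(unname(syn[hit[!is.na(hit)]]))
    }
    bad <- which(!(vals %in% allowed))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "%s: column `%s` has value(s) outside {%s} at row(s) %s (got %s).",
        context, col, paste(allowed, collapse = ", "),
        paste(utils::head(bad, 5), collapse = ", "),
        paste(unique(utils::head(x[[col]][bad], 5)), collapse = ", ")
      ))
    }
    x[[col]] <- vals
  }

  for (col in sch$logicals) {
    vals <- toupper(trimws(as.character(x[[col]])))
    map <- c("TRUE" = TRUE, "T" = TRUE, "1" = TRUE, "YES" = TRUE,
             "FALSE" = FALSE, "F" = FALSE, "0" = FALSE, "NO" = FALSE)
    hit <- match(vals, names(map))
    bad <- which(is.na(hit))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "%s: column `%s` must be boolean at row(s) %s.",
        context, col, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
    x[[col]] <- unname(map[hit])
  }

  if (!is.null(sch$key)) {
    dup <- x[[sch$key]][duplicated(x[[sch$key]])]
    if (length(dup) > 0) {
      abort_integrity(sprintf(
        "%s: duplicate %s value(s): %s",
        context, sch$key, paste(unique(utils::head(dup, 5)), collapse = ", ")
      ))
    }
  }

  if (kind == "admissions") {
    blank <- is.na(x$source_ed_encounter_id) |
      trimws(x$source_ed_encounter_id) == ""
    x$source_ed_encounter_id[blank] <- NA_character_
    bad <- which(x$admit_datetime > x$discharge_datetime)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "%s: admit_datetime after discharge_datetime at row(s) %s.",
        context, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
  }

  x
}

#' Write an EHR table to CSV
#'
#' Writes a validated table so that reading it back with [read_ehr_table()]
#' reproduces it field-for-field (timestamps serialized as ISO-8601 local
#' wall-clock, diagnosis codes verbatim).
#'
#' @param x A tibble as produced by [read_ehr_table()] / the cohort
#'   generator.
#' @param path Output CSV path.
#' @param kind One of [ehr_table_kinds()].
#' @return `path`, invisibly.
#' @export
write_ehr_table <- function(x, path, kind) {
  kind <- match.arg(kind, ehr_table_kinds())
  sch <- .ehr_schemas[[kind]]
  missing_cols <- setdiff(sch$columns, names(x))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "Cannot write %s table: missing column(s) %s",
      kind, paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(x)[sch$columns]
  for (col in sch$timestamps) {
    if (inherits(out[[col]], "POSIXct")) {
      out[[col]] <- format_wallclock(out[[col]])
    }
  }
  for (col in sch$logicals) {
    out[[col]] <- ifelse(out[[col]], "true", "false")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Assemble and cross-validate a full EHR cohort
#'
#' Bundles the four core tables (plus optional gold-standard labels) and
#' enforces the referential invariants that single-table validation cannot
#' see: an admission's `source_ed_encounter_id`, when present, must refer
#' to an existing ED encounter of the same patient; every diagnosis must
#' refer to an existing admission; every gold label must refer to an
#' existing order, at most once.
#'
#' @param orders,ed_encounters,admissions,diagnoses Validated tables (see
#'   [read_ehr_table()]).
#' @param gold_labels Optional validated label table, or `NULL`.
#' @return An object of class `ehr_cohort`: a list with the five tables.
#' @export
ehr_cohort <- function(orders, ed_encounters, admissions, diagnoses,
                       gold_labels = NULL) {
  orders <- validate_ehr_table(orders, "orders")
  ed_encounters <- validate_ehr_table(ed_encounters, "ed_encounters")
  admissions <- validate_ehr_table(admissions, "admissions")
  diagnoses <- validate_ehr_table(diagnoses, "diagnoses")
  if (!is.null(gold_labels)) {
    gold_labels <- validate_ehr_table(gold_labels, "gold_labels")
  }

  src <- admissions$source_ed_encounter_id
  linked <- !is.na(src)
  enc_idx <- match(src[linked], ed_encounters$ed_encounter_id)
  if (anyNA(enc_idx)) {
    abort_integrity(sprintf(
      "admissions: source_ed_encounter_id refers to unknown encounter(s): %s",
      paste(utils::head(unique(src[linked][is.na(enc_idx)]), 5), collapse = ", ")
    ))
  }
  mism <- admissions$patient_id[linked] != ed_encounters$patient_id[enc_idx]
  if (any(mism)) {
    abort_integrity(sprintf(
      "admissions: admission(s) %s linked to an ED encounter of a different patient.",
      paste(utils::head(admissions$admission_id[linked][mism], 5), collapse = ", ")
    ))
  }

  orphan <- setdiff(diagnoses$admission_id, admissions$admission_id)
  if (length(orphan) > 0) {
    abort_integrity(sprintf(
      "diagnoses: admission_id(s) with no admission record: %s",
      paste(utils::head(orphan, 5), collapse = ", ")
    ))
  }

  if (!is.null(gold_labels)) {
    orphan <- setdiff(gold_labels$order_id, orders$order_id)
    if (length(orphan) > 0) {
      abort_integrity(sprintf(
        "gold_labels: order_id(s) with no order record: %s",
        paste(utils::head(orphan, 5), collapse = ", ")
      ))
    }
  }

  structure(
    list(orders = orders, ed_encounters = ed_encounters,
         admissions = admissions, diagnoses = diagnoses,
         gold_labels = gold_labels),
    class = "ehr_cohort"
  )
}

#' Read a full cohort from a directory or config
#'
#' @param dir Directory containing `orders.csv`, `ed_encounters.csv`,
#'   `admissions.csv`, `diagnoses.csv`, and optionally `gold_labels.csv`.
#' @param synonyms See [read_ehr_table()].
#' @return An `ehr_cohort`.
#' @export
read_ehr_cohort <- function(dir, synonyms = NULL) {
  p <- function(f) file.path(dir, f)
  labels <- NULL
  if (file.exists(p("gold_labels.csv"))) {
    labels <- read_ehr_table(p("gold_labels.csv"), "gold_labels", synonyms)
  }
  ehr_cohort(
    orders = read_ehr_table(p("orders.csv"), "orders", synonyms),
    ed_encounters = read_ehr_table(p("ed_encounters.csv"), "ed_encounters", synonyms),
    admissions = read_ehr_table(p("admissions.csv"), "admissions", synonyms),
    diagnoses = read_ehr_table(p("diagnoses.csv"), "diagnoses", synonyms),
    gold_labels = labels
  )
}

#' Write a full cohort to a directory
#'
#' @param cohort An `ehr_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ehr_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ehr_table(cohort$orders, file.path(dir, "orders.csv"), "orders")
  write_ehr_table(cohort$ed_encounters, file.path(dir, "ed_encounters.csv"),
                  "ed_encounters")
  write_ehr_table(cohort$admissions, file.path(dir, "admissions.csv"),
                  "admissions")
  write_ehr_table(cohort$diagnoses, file.path(dir, "diagnoses.csv"),
                  "diagnoses")
  if (!is.null(cohort$gold_labels)) {
    write_ehr_table(cohort$gold_labels, file.path(dir, "gold_labels.csv"),
                    "gold_labels")
  }
  invisible(dir)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort>\n")
  cat("  orders:        ", nrow(x$orders), "\n")
  cat("  ed_encounters: ", nrow(x$ed_encounters), "\n")
  cat("  admissions:    ", nrow(x$admissions), "\n")
  cat("  diagnoses:     ", nrow(x$diagnoses), "\n")
  cat("  gold_labels:   ",
      if (is.null(x$gold_labels)) "none" else nrow(x$gold_labels), "\n")
  invisible(x)
}
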