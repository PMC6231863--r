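#' Normalize an ICD diagnosis code
#'
#' Canonicalizes ICD-9-CM / ICD-10-CM codes so that membership tests are
#' invariant to dotting, case, and surrounding whitespace: the code is
#' whitespace-stripped, upper-cased, and the dot is removed
#' (`"415.19"` becomes `"41519"`, `"i26.99"` becomes `"I2699"`).
#' The transformation is deterministic and idempotent.
#'
#' @param x Character vector of raw codes.
#' @return Character vector of normalized codes, same length as `x`.
#' @examples
#' normalize_icd_code(c("415.19", " i26.99 "))
#' @export
normalize_icd_code <- function(x) {
  if (!is.character(x)) {
    abort_validation("ICD codes must be character strings.")
  }
  out <- gsub(".", "", toupper(trimws(x)), fixed = TRUE)
  bad <- which(is.na(out) | out == "")
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "ICD codes must be non-empty; element(s) %s are empty or missing.",
      paste(bad, collapse = ", ")
    ))
  }
  out
}

#' Pulmonary-embolism discharge-code set
#'
#' Bundles the ICD-9-CM and ICD-10-CM code lists that define a
#' pulmonary-embolism discharge diagnosis. The default is the frozen PE
#' definition used throughout this package: five ICD-9-CM codes
#' (415.0, 415.11, 415.12, 415.13, 415.19) and eight ICD-10-CM codes
#' (I26.0, I26.01, I26.02, I26.09, I26.9, I26.90, I26.92, I26.99).
#' Codes are stored normalized (dotless, upper case); matching is exact
#' membership with no hierarchical prefix expansion, because the definition
#' enumerates parents (I26.0, I26.9) and children explicitly.
#'
#' @param icd9 Character vector of ICD-9-CM codes (any dotting/case).
#' @param icd10 Character vector of ICD-10-CM codes.
#' @param name Label for the code set.
#' @return An object of class `pe_codeset` with elements `icd9`, `icd10`
#'   (normalized character vectors) and `name`.
#' @examples
#' cs <- pe_codeset()
#' length(cs$icd9)   # 5
#' length(cs$icd10)  # 8
#' @export
pe_codeset <- function(icd9 = .pe_default_icd9,
                       icd10 = .pe_default_icd10,
                       name = "pulmonary_embolism_default") {
  icd9 <- unique(normalize_icd_code(icd9))
  icd10 <- unique(normalize_icd_code(icd10))
  if (length(icd9) == 0 || length(icd10) == 0) {
    abort_validation("A code set needs at least one code per ICD version.")
  }
  structure(
    list(icd9 = icd9, icd10 = icd10, name = as.character(name)[1]),
    class = "pe_codeset"
  )
}

.pe_default_icd9 <- c("415.0", "415.11", "415.12", "415.13", "415.19")
.pe_default_icd10 <- c(
  "I26.0", "I26.01", "I26.02", "I26.09",
  "I26.9", "I26.90", "I26.92", "I26.99"
)

#' @export
print.pe_codeset <- function(x, ...) {
  cat("<pe_codeset> ", x$name, "\n", sep = "")
  cat("  ICD-9-CM  (", length(x$icd9), "): ",
      paste(x$icd9, collapse = ", "), "\n", sep = "")
  cat("  ICD-10-CM (", length(x$icd10), "): ",
      paste(x$icd10, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Test codes for pulmonary-embolism membership
#'
#' Vectorized exact-membership test: a code is a PE code iff its normalized
#' form is in the code set for the stated ICD version.
#'
#' @param code Character vector of ICD codes (any dotting/case).
#' @param version Character vector, `"ICD9"` or `"ICD10"`, recycled against
#'   `code` if length 1.
#' @param codeset A [pe_codeset()].
#' @return Logical vector.
#' @examples
#' is_pe_code("415.19", "ICD9")
#' is_pe_code("I26.90", "ICD10")
#' is_pe_code("415.1", "ICD9")   # FALSE: no prefix expansion
#' @export
is_pe_code <- function(code, version, codeset = pe_codeset()) {
  stopifnot(inherits(codeset, "pe_codeset"))
  if (length(version) == 1) version <- rep(version, length(code))
  if (length(version) != length(code)) {
    abort_validation("`code` and `version` must have matching lengths.")
  }
  version <- toupper(trimws(version))
  unknown <- setdiff(unique(version), c("ICD9", "ICD10"))
  if (length(unknown) > 0) {
    abort_validation(sprintf(
      "Unknown ICD version(s): %s (expected ICD9 or ICD10).",
      paste(unknown, collapse = ", ")
    ))
  }
  norm <- normalize_icd_code(code)
  ifelse(version == "ICD9", norm %in% codeset$icd9, norm %in% codeset$icd10)
}

#' Read a code-set override from a YAML/JSON config
#'
#' Reads the optional `codesets:` section (`icd9:` and `icd10:` lists) of a
#' configuration file and returns a [pe_codeset()]. Absent sections fall
#' back to the frozen PE default.
#'
#' @param path Path to a YAML (or JSON) file.
#' @return A `pe_codeset`.
#' @export
read_codeset_config <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("Config file not found: %s", path))
  }
  cfg <- yaml::read_yaml(path)
  cs <- cfg$codesets
  pe_codeset(
    icd9 = if (!is.null(cs$icd9)) as.character(cs$icd9) else .pe_default_icd9,
    icd10 = if (!is.null(cs$icd10)) as.character(cs$icd10) else .pe_default_icd10,
    name = if (!is.null(cs$name)) cs$name else "config_codeset"
  )
}
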