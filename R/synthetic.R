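# Filler (non-PE) discharge codes given to admissions so that negative
# records look like real coded stays. Checked against the PE set at
# generation time; a collision is a programming error.
.filler_icd10 <- c("J18.9", "N17.9", "R07.9", "I10", "E11.9", "J44.1",
                   "K92.2", "A41.9")
.filler_icd9 <- c("486", "584.9", "786.50", "401.9", "250.00", "491.21")

#' Per-site specification for the synthetic cohort generator
#'
#' Describes one emergency department site-month: how many completed CTPA
#' orders to generate, how many cancelled/discontinued ones, how many
#' patients get a same-day CTA of the abdomen/pelvis (and are therefore
#' excluded from the yield denominator), how many analyzable orders are
#' chart-review positive, and how many of those positives are discharged
#' directly from the ED with no inpatient admission — the discordance
#' mechanism by which admission-linked classification misses a true PE.
#'
#' @param site_id Site label.
#' @param n_completed_ctpa Completed CTPA orders (before exclusion).
#' @param n_chart_positive Chart-review-positive analyzable orders.
#' @param n_cancelled_or_discontinued Cancelled/discontinued CTPA orders
#'   (never counted in the yield).
#' @param n_same_day_cta_pairs Completed CTPA orders whose patient also has
#'   a completed same-day CTA abdomen/pelvis (excluded from analysis).
#' @param n_positive_discharged_from_ed Chart positives discharged directly
#'   from the ED (no admission, so computed-negative).
#' @param n_negative_unlinked Chart-negative analyzable orders with no
#'   admission (ED discharges after a negative scan).
#' @param icd_version_mix Fraction of linked positives coded in ICD-10-CM
#'   (the rest in ICD-9-CM).
#' @param rank_mix Fraction of PE codes entered as SECONDARY diagnoses.
#' @param month_start First day of the site's one-month window
#'   (`"YYYY-MM-DD"`); timestamps are drawn uniformly within the month.
#' @return A `site_spec` list.
#' @export
site_spec <- function(site_id,
                      n_completed_ctpa,
                      n_chart_positive,
                      n_cancelled_or_discontinued = 0,
                      n_same_day_cta_pairs = 0,
                      n_positive_discharged_from_ed = 0,
                      n_negative_unlinked = 0,
                      icd_version_mix = 0.5,
                      rank_mix = 0.5,
                      month_start = "2016-04-01") {
  s <- list(
    site_id = as.character(site_id),
    n_completed_ctpa = as.integer(n_completed_ctpa),
    n_chart_positive = as.integer(n_chart_positive),
    n_cancelled_or_discontinued = as.integer(n_cancelled_or_discontinued),
    n_same_day_cta_pairs = as.integer(n_same_day_cta_pairs),
    n_positive_discharged_from_ed = as.integer(n_positive_discharged_from_ed),
    n_negative_unlinked = as.integer(n_negative_unlinked),
    icd_version_mix = as.numeric(icd_version_mix),
    rank_mix = as.numeric(rank_mix),
    month_start = as.character(month_start)
  )
  class(s) <- "site_spec"
  validate_site_spec(s)
  s
}

validate_site_spec <- function(s) {
  counts <- unlist(s[startsWith(names(s), "n_")])
  if (any(counts < 0)) {
    abort_validation(sprintf("Site %s: counts must be non-negative.", s$site_id))
  }
  n_analyzable <- s$n_completed_ctpa - s$n_same_day_cta_pairs
  if (s$n_same_day_cta_pairs > s$n_completed_ctpa) {
    abort_validation(sprintf(
      "Site %s: same-day CTA pairs (%d) exceed completed CTPA orders (%d).",
      s$site_id, s$n_same_day_cta_pairs, s$n_completed_ctpa))
  }
  if (s$n_chart_positive > n_analyzable) {
    abort_validation(sprintf(
      "Site %s: chart positives (%d) exceed analyzable orders (%d).",
      s$site_id, s$n_chart_positive, n_analyzable))
  }
  if (s$n_positive_discharged_from_ed > s$n_chart_positive) {
    abort_validation(sprintf(
      "Site %s: ED-discharge positives (%d) exceed chart positives (%d).",
      s$site_id, s$n_positive_discharged_from_ed, s$n_chart_positive))
  }
  if (s$n_negative_unlinked > n_analyzable - s$n_chart_positive) {
    abort_validation(sprintf(
      "Site %s: unlinked negatives (%d) exceed chart negatives (%d).",
      s$site_id, s$n_negative_unlinked, n_analyzable - s$n_chart_positive))
  }
  if (s$icd_version_mix < 0 || s$icd_version_mix > 1 ||
      s$rank_mix < 0 || s$rank_mix > 1) {
    abort_validation(sprintf("Site %s: mixes must lie in [0, 1].", s$site_id))
  }
  if (is.na(as.Date(s$month_start, optional = TRUE))) {
    abort_validation(sprintf("Site %s: month_start must be YYYY-MM-DD.", s$site_id))
  }
  invisible(s)
}

#' Multi-site cohort specification
#'
#' @param sites A list of [site_spec()] objects with distinct `site_id`s.
#' @param random_seed Integer seed; equal (spec, seed) pairs regenerate
#'   byte-identical tables.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(sites, random_seed = 1L) {
  if (inherits(sites, "site_spec")) sites <- list(sites)
  stopifnot(length(sites) >= 1, all(vapply(sites, inherits, TRUE, "site_spec")))
  ids <- vapply(sites, `[[`, "", "site_id")
  if (anyDuplicated(ids)) abort_validation("Duplicate site_id in cohort spec.")
  lapply(sites, validate_site_spec)
  structure(list(sites = sites, random_seed = as.integer(random_seed)),
            class = "cohort_spec")
}

#' Generate a synthetic EHR cohort
#'
#' Materializes the five flat tables for a [cohort_spec()] with exactly the
#' requested counts: running [ctpa_yield()] on the output gives
#' `n_analyzable = n_completed_ctpa - n_same_day_cta_pairs` per site and a
#' numerator of `n_chart_positive - n_positive_discharged_from_ed`;
#' gold-standard labels mark all chart positives. Linked positive
#' admissions carry one PE code drawn from the default code set according
#' to `icd_version_mix` and `rank_mix`; every admission also carries filler
#' non-PE codes. Order timestamps fall uniformly within each site's month.
#' Randomness affects identifiers, timestamps, which orders take which
#' role, and code choices — never the counts. The same (spec, seed) pair
#' regenerates identical tables.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the spec's `random_seed`.
#' @return An [ehr_cohort()] whose `spec` attribute holds `spec`.
#' @export
generate_cohort <- function(spec, seed = spec$random_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  stopifnot(!any(normalize_icd_code(c(.filler_icd9, .filler_icd10)) %in%
                   c(pe_codeset()$icd9, pe_codeset()$icd10)))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  parts <- lapply(spec$sites, generate_site_tables)
  bind <- function(field) dplyr::bind_rows(lapply(parts, `[[`, field))
  cohort <- ehr_cohort(
    orders = bind("orders"),
    ed_encounters = bind("ed_encounters"),
    admissions = bind("admissions"),
    diagnoses = bind("diagnoses"),
    gold_labels = bind("gold_labels")
  )
  attr(cohort, "spec") <- spec
  cohort
}

# One site-month of tables. Each CTPA order gets its own patient and ED
# encounter; the unit of analysis downstream is the order, so sharing
# patients across orders would only complicate the count bookkeeping
# without changing what the pipeline is exercised on.
generate_site_tables <- function(s) {
  month_start <- as.POSIXct(paste0(s$month_start, "T00:00:00"), tz = "UTC")
  month_secs <- 30 * 86400
  rand_time <- function(n) month_start + floor(stats::runif(n, 0, month_secs))

  n_ctpa <- s$n_completed_ctpa
  n_extra <- s$n_cancelled_or_discontinued
  n_total <- n_ctpa + n_extra
  sid <- s$site_id

  order_id <- sprintf("%s-O%05d", sid, seq_len(n_total))
  patient_id <- sprintf("%s-P%05d", sid, seq_len(n_total))
  encounter_id <- sprintf("%s-E%05d", sid, seq_len(n_total))
  order_time <- rand_time(n_total)

  ctpa_idx <- seq_len(n_ctpa)
  extra_idx <- setdiff(seq_len(n_total), ctpa_idx)

  # role assignment among completed CTPA orders; sample_vec avoids the
  # base-R surprise of sample(x, k) on length-1 x
  sample_vec <- function(x, k) x[sample.int(length(x), k)]
  excluded <- sort(sample_vec(ctpa_idx, s$n_same_day_cta_pairs))
  analyzable <- setdiff(ctpa_idx, excluded)
  positive <- sort(sample_vec(analyzable, s$n_chart_positive))
  ed_discharge_pos <- sort(sample_vec(positive, s$n_positive_discharged_from_ed))
  negative <- setdiff(analyzable, positive)
  unlinked_neg <- sort(sample_vec(negative, s$n_negative_unlinked))
  unlinked <- c(ed_discharge_pos, unlinked_neg, extra_idx)
  admitted <- setdiff(c(ctpa_idx, extra_idx), unlinked)

  orders <- tibble::tibble(
    order_id = order_id,
    patient_id = patient_id,
    ed_encounter_id = encounter_id,
    order_type = "CTPA",
    status = c(rep("COMPLETED", n_ctpa),
               sample(c("CANCELLED", "DISCONTINUED"), n_extra, replace = TRUE)),
    order_datetime = order_time,
    site_id = sid
  )

  # companion same-day CTA abdomen/pelvis orders for the excluded patients:
  # drawn uniformly within the same calendar day as the CTPA, so the
  # patient-level same-day pairing always holds
  if (length(excluded) > 0) {
    day_start <- as.POSIXct(paste0(as.Date(order_time[excluded], tz = "UTC"),
                                   "T00:00:00"), tz = "UTC")
    cta <- tibble::tibble(
      order_id = sprintf("%s-O%05d", sid, n_total + seq_along(excluded)),
      patient_id = patient_id[excluded],
      ed_encounter_id = encounter_id[excluded],
      order_type = "CTA_ABD_PELVIS",
      status = "COMPLETED",
      order_datetime = day_start + floor(stats::runif(length(excluded), 0, 86400)),
      site_id = sid
    )
    orders <- dplyr::bind_rows(orders, cta)
  }

  ed_encounters <- tibble::tibble(
    ed_encounter_id = encounter_id,
    patient_id = patient_id,
    arrival_datetime = order_time - floor(stats::runif(n_total, 1800, 6 * 3600)),
    disposition = ifelse(seq_len(n_total) %in% admitted,
                         "ADMITTED", "DISCHARGED_FROM_ED")
  )

  admitted <- sort(admitted)
  n_adm <- length(admitted)
  admissions <- tibble::tibble(
    admission_id = sprintf("%s-A%05d", sid, seq_len(n_adm)),
    patient_id = patient_id[admitted],
    source_ed_encounter_id = encounter_id[admitted],
    admit_datetime = order_time[admitted] + floor(stats::runif(n_adm, 3600, 12 * 3600)),
    discharge_datetime = NA
  )
  admissions$discharge_datetime <-
    admissions$admit_datetime + floor(stats::runif(n_adm, 1, 7) * 86400)

  # diagnoses: every admission gets 1-3 filler codes; admissions of linked
  # chart-positive orders additionally get exactly one PE code
  diag_list <- list()
  for (j in seq_len(n_adm)) {
    k <- sample(1:3, 1)
    use9 <- stats::runif(k) < 0.2
    diag_list[[j]] <- tibble::tibble(
      admission_id = admissions$admission_id[j],
      icd_code = ifelse(use9, sample(.filler_icd9, k, replace = TRUE),
                        sample(.filler_icd10, k, replace = TRUE)),
      icd_version = ifelse(use9, "ICD9", "ICD10"),
      rank = c("PRIMARY", rep("SECONDARY", k - 1))
    )
  }
  linked_pos <- setdiff(positive, ed_discharge_pos)
  if (length(linked_pos) > 0) {
    adm_of <- admissions$admission_id[match(encounter_id[linked_pos],
                                            admissions$source_ed_encounter_id)]
    use10 <- stats::runif(length(linked_pos)) < s$icd_version_mix
    secondary <- stats::runif(length(linked_pos)) < s$rank_mix
    cs <- pe_codeset()
    pe_rows <- tibble::tibble(
      admission_id = adm_of,
      icd_code = ifelse(use10,
                        sample(cs$icd10, length(linked_pos), replace = TRUE),
                        sample(cs$icd9, length(linked_pos), replace = TRUE)),
      icd_version = ifelse(use10, "ICD10", "ICD9"),
      rank = ifelse(secondary, "SECONDARY", "PRIMARY")
    )
    diag_list <- c(diag_list, list(pe_rows))
  }
  diagnoses <- dplyr::bind_rows(diag_list)

  gold_labels <- tibble::tibble(
    order_id = order_id[sort(analyzable)],
    chart_review_pe_positive = sort(analyzable) %in% positive
  )

  list(orders = orders, ed_encounters = ed_encounters,
       admissions = admissions, diagnoses = diagnoses,
       gold_labels = gold_labels)
}

#' Frozen two-site validation preset
#'
#' The canonical two-site emergency-department scenario used as the
#' package's reference fixture: site NSUH (one month, April 2016) with 229
#' completed CTPA orders of which 26 are excluded for a same-day CTA of the
#' abdomen/pelvis, leaving 203 analyzable, 19 chart-positive, one of them
#' discharged directly from the ED; site LIJMC (one month, November 2016)
#' with 146 analyzable orders and 9 chart positives, all admitted. Overall:
#' 375 raw completed orders, 26 excluded, 349 analyzable, 28 chart
#' positives of which the pipeline captures 27. The split of the 26
#' exclusions across sites is a convention of the preset (all at NSUH);
#' cancelled/discontinued counts are likewise representative conventions.
#' Positive admissions are coded in ICD-10-CM, the coding system in use
#' for discharges in 2016.
#'
#' @param random_seed Seed for the generator (default 2016).
#' @return A [cohort_spec()].
#' @examples
#' cohort <- generate_cohort(two_site_preset())
#' ctpa_yield(cohort)  # 27/349 = 7.7%
#' @export
two_site_preset <- function(random_seed = 2016L) {
  cohort_spec(
    sites = list(
      site_spec("NSUH",
                n_completed_ctpa = 229,
                n_chart_positive = 19,
                n_cancelled_or_discontinued = 14,
                n_same_day_cta_pairs = 26,
                n_positive_discharged_from_ed = 1,
                n_negative_unlinked = 110,
                icd_version_mix = 1,
                rank_mix = 0.3,
                month_start = "2016-04-01"),
      site_spec("LIJMC",
                n_completed_ctpa = 146,
                n_chart_positive = 9,
                n_cancelled_or_discontinued = 9,
                n_same_day_cta_pairs = 0,
                n_positive_discharged_from_ed = 0,
                n_negative_unlinked = 80,
                icd_version_mix = 1,
                rank_mix = 0.3,
                month_start = "2016-11-01")
    ),
    random_seed = random_seed
  )
}

#' Read a cohort spec from YAML
#'
#' The YAML mirrors [cohort_spec()]: a `random_seed` and a `sites:` list
#' whose entries carry the [site_spec()] fields.
#'
#' @param path Path to a YAML file.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("Spec file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$sites)) abort_schema("Cohort spec YAML needs a `sites:` list.")
  sites <- lapply(y$sites, function(s) do.call(site_spec, s))
  cohort_spec(sites, random_seed = if (is.null(y$random_seed)) 1L else y$random_seed)
}
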