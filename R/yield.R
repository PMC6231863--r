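#' Select completed ED CTPA orders
#'
#' Retains orders with `order_type == "CTPA"` and `status == "COMPLETED"`,
#' dropping cancelled/discontinued CTPA orders and all non-CTPA orders.
#' Input row order is preserved.
#'
#' @param orders A validated orders table.
#' @return A tibble, subset of `orders`.
#' @export
select_completed_ed_ctpa <- function(orders) {
  orders[orders$order_type == "CTPA" & orders$status == "COMPLETED", ,
         drop = FALSE]
}

#' Exclude CTPA orders paired with a same-day CTA of the abdomen and pelvis
#'
#' A completed CTPA ordered on the same calendar day as a completed CT
#' angiography of the abdomen and pelvis for the same patient is taken to
#' have been performed under an aortic-dissection rule-out protocol rather
#' than to evaluate PE, and is excluded from the yield denominator. The
#' pairing is at patient level: one same-day CTA excludes all of that
#' patient's CTPA orders on that day. Only COMPLETED CTA orders trigger
#' exclusion. "Same day" means equal calendar date of `order_datetime`
#' (site-local wall clock).
#'
#' @param ctpa_orders Completed CTPA orders (a subset of
#'   [select_completed_ed_ctpa()] output).
#' @param all_orders The full orders table, searched for CTA abdomen/pelvis
#'   orders.
#' @return A list with elements `retained` and `excluded`, partitioning
#'   `ctpa_orders`.
#' @export
exclude_same_day_cta <- function(ctpa_orders, all_orders) {
  cta <- all_orders[all_orders$order_type == "CTA_ABD_PELVIS" &
                      all_orders$status == "COMPLETED", , drop = FALSE]
  cta_key <- paste(cta$patient_id, as.Date(cta$order_datetime, tz = "UTC"))
  ctpa_key <- paste(ctpa_orders$patient_id,
                    as.Date(ctpa_orders$order_datetime, tz = "UTC"))
  hit <- ctpa_key %in% cta_key
  list(
    retained = ctpa_orders[!hit, , drop = FALSE],
    excluded = ctpa_orders[hit, , drop = FALSE]
  )
}

#' Link one ED CTPA order to an inpatient admission
#'
#' Linkage prefers the explicit encounter key: the admission whose
#' `source_ed_encounter_id` equals the order's `ed_encounter_id`. When no
#' admission carries that key, it falls back to the earliest same-patient
#' admission whose `admit_datetime` lies within
#' `[order_datetime, order_datetime + linkage_window_hours]`. If neither
#' exists the order is unlinked (`NA`) — the ED-discharge case, in which a
#' patient treated and released directly from the ED can never acquire an
#' inpatient discharge code. Ties on identical `admit_datetime` in the
#' fallback are broken by smallest `admission_id`, with a warning.
#'
#' @param order A single-row orders tibble.
#' @param encounters The ED encounters table (contextual; linkage itself
#'   uses the keys carried on orders and admissions).
#' @param admissions The admissions table.
#' @param linkage_window_hours Fallback window in hours (default 48, wide
#'   enough to span overnight ED boarding).
#' @return An `admission_id` string, or `NA_character_` if unlinked.
#' @export
link_order_to_admission <- function(order, encounters, admissions,
                                    linkage_window_hours = 48) {
  stopifnot(nrow(order) == 1)
  by_key <- admissions[!is.na(admissions$source_ed_encounter_id) &
                         admissions$source_ed_encounter_id == order$ed_encounter_id, ,
                       drop = FALSE]
  if (nrow(by_key) > 1) {
    abort_integrity(sprintf(
      "Encounter %s is claimed by multiple admissions: %s",
      order$ed_encounter_id, paste(by_key$admission_id, collapse = ", ")
    ))
  }
  if (nrow(by_key) == 1) {
    return(by_key$admission_id)
  }
  lo <- order$order_datetime
  hi <- lo + linkage_window_hours * 3600
  cand <- admissions[admissions$patient_id == order$patient_id &
                       admissions$admit_datetime >= lo &
                       admissions$admit_datetime <= hi, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(NA_character_)
  }
  cand <- cand[order(cand$admit_datetime, cand$admission_id), , drop = FALSE]
  if (nrow(cand) > 1 && cand$admit_datetime[1] == cand$admit_datetime[2]) {
    warning(sprintf(
      "Order %s: tied admit times; linking to smallest admission_id (%s).",
      order$order_id, cand$admission_id[1]
    ), call. = FALSE)
  }
  cand$admission_id[1]
}

#' Classify analyzable CTPA orders as PE-positive or negative
#'
#' An order is computed-PE-positive iff it links to an inpatient admission
#' and at least one of that admission's discharge diagnoses — primary or
#' secondary — is a PE code of its ICD version under `codeset`. Unlinked
#' orders (ED discharges) are always negative.
#'
#' @param orders Analyzable CTPA orders (post selection and exclusion).
#' @param encounters ED encounters table.
#' @param admissions Admissions table.
#' @param diagnoses Discharge diagnoses table.
#' @param codeset A [pe_codeset()].
#' @param linkage_window_hours See [link_order_to_admission()].
#' @return A tibble with one row per order: `order_id`,
#'   `linked_admission_id` (`NA` when unlinked), `computed_pe_positive`.
#' @export
classify_orders_pe <- function(orders, encounters, admissions, diagnoses,
                               codeset = pe_codeset(),
                               linkage_window_hours = 48) {
  n <- nrow(orders)
  linked <- character(n)
  for (i in seq_len(n)) {
    linked[i] <- link_order_to_admission(orders[i, , drop = FALSE],
                                         encounters, admissions,
                                         linkage_window_hours)
  }
  pe_adm <- character(0)
  if (nrow(diagnoses) > 0) {
    hit <- is_pe_code(diagnoses$icd_code, diagnoses$icd_version, codeset)
    pe_adm <- unique(diagnoses$admission_id[hit])
  }
  tibble::tibble(
    order_id = orders$order_id,
    linked_admission_id = linked,
    computed_pe_positive = !is.na(linked) & linked %in% pe_adm
  )
}

#' Cohort accounting for yield computation
#'
#' Tracks, overall and per site, the raw completed CTPA count, the number
#' excluded for a same-day CTA of the abdomen/pelvis, and the analyzable
#' remainder (`n_analyzable = n_raw_completed_ctpa - n_excluded_same_day_cta`).
#'
#' @param raw Completed CTPA orders before exclusion.
#' @param excluded The excluded subset.
#' @return An object of class `cohort_accounting`: counts plus a `per_site`
#'   tibble.
#' @export
cohort_accounting <- function(raw, excluded) {
  sites <- sort(unique(raw$site_id))
  per_site <- tibble::tibble(
    site_id = sites,
    n_raw_completed_ctpa = vapply(sites, function(s) sum(raw$site_id == s),
                                  0L, USE.NAMES = FALSE),
    n_excluded_same_day_cta = vapply(sites, function(s) sum(excluded$site_id == s),
                                     0L, USE.NAMES = FALSE)
  )
  per_site$n_analyzable <-
    per_site$n_raw_completed_ctpa - per_site$n_excluded_same_day_cta
  structure(
    list(
      n_raw_completed_ctpa = nrow(raw),
      n_excluded_same_day_cta = nrow(excluded),
      n_analyzable = nrow(raw) - nrow(excluded),
      per_site = per_site
    ),
    class = "cohort_accounting"
  )
}

#' Compute CTPA yield from order classifications
#'
#' Yield is the number of computed-PE-positive orders divided by the number
#' of analyzable completed CTPA orders. With an empty denominator the yield
#' is flagged undefined (`NA`) rather than erroring. The unit of analysis
#' is the order, not the patient.
#'
#' @param classifications Output of [classify_orders_pe()]; one row per
#'   analyzable order. Must carry a `site_id` column or be accompanied by
#'   orders via the `orders` argument for the per-site split.
#' @param accounting A [cohort_accounting()].
#' @param orders The analyzable orders (for the per-site split); optional
#'   if `classifications` has `site_id`.
#' @return An object of class `ctpa_yield_result` with `numerator`,
#'   `denominator`, `yield_fraction`, `accounting`, and a `per_site` tibble.
#' @export
compute_yield <- function(classifications, accounting, orders = NULL) {
  stopifnot(inherits(accounting, "cohort_accounting"))
  if (!("site_id" %in% names(classifications))) {
    if (is.null(orders)) {
      abort_validation(
        "Need `site_id` on classifications or the `orders` table for the per-site split.")
    }
    classifications$site_id <-
      orders$site_id[match(classifications$order_id, orders$order_id)]
  }
  if (nrow(classifications) != accounting$n_analyzable) {
    abort_validation(sprintf(
      "Expected one classification per analyzable order (%d), got %d.",
      accounting$n_analyzable, nrow(classifications)
    ))
  }
  numerator <- sum(classifications$computed_pe_positive)
  denominator <- accounting$n_analyzable
  per_site <- dplyr::summarise(
    dplyr::group_by(classifications, .data$site_id),
    numerator = sum(.data$computed_pe_positive),
    denominator = dplyr::n(),
    .groups = "drop"
  )
  per_site$yield_fraction <- ifelse(per_site$denominator > 0,
                                    per_site$numerator / per_site$denominator,
                                    NA_real_)
  structure(
    list(
      numerator = numerator,
      denominator = denominator,
      yield_fraction = if (denominator > 0) numerator / denominator else NA_real_,
      accounting = accounting,
      per_site = per_site,
      classifications = classifications
    ),
    class = "ctpa_yield_result"
  )
}

#' @export
print.ctpa_yield_result <- function(x, ...) {
  acc <- x$accounting
  cat("<ctpa_yield_result>\n")
  cat(sprintf("  completed ED CTPA orders: %d (excluded for same-day CTA abd/pelvis: %d)\n",
              acc$n_raw_completed_ctpa, acc$n_excluded_same_day_cta))
  cat(sprintf("  analyzable orders:        %d\n", acc$n_analyzable))
  if (is.na(x$yield_fraction)) {
    cat("  yield: undefined (no analyzable orders)\n")
  } else {
    cat(sprintf("  yield: %.1f%% (%d/%d)\n",
                100 * x$yield_fraction, x$numerator, x$denominator))
    for (i in seq_len(nrow(x$per_site))) {
      r <- x$per_site[i, ]
      cat(sprintf("    %s: %.1f%% (%d/%d)\n", r$site_id,
                  100 * r$yield_fraction, r$numerator, r$denominator))
    }
  }
  invisible(x)
}

#' Run the full CTPA yield pipeline on a cohort
#'
#' Applies the complete algorithm: select completed ED CTPA orders, exclude
#' those with a same-day CTA of the abdomen/pelvis for the same patient,
#' link each remaining order to an inpatient admission (encounter key, then
#' time-window fallback), classify PE by discharge diagnosis code-set
#' membership, and compute overall and per-site yield with full exclusion
#' accounting.
#'
#' @param cohort An [ehr_cohort()].
#' @param codeset A [pe_codeset()] (default: the frozen PE definition).
#' @param linkage_window_hours Fallback linkage window (default 48 h).
#' @return A `ctpa_yield_result`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(sites = list(
#'   site_spec("A", n_completed_ctpa = 20, n_chart_positive = 2))))
#' ctpa_yield(cohort)
#' @export
ctpa_yield <- function(cohort, codeset = pe_codeset(),
                       linkage_window_hours = 48) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  completed <- select_completed_ed_ctpa(cohort$orders)
  split <- exclude_same_day_cta(completed, cohort$orders)
  acc <- cohort_accounting(completed, split$excluded)
  cls <- classify_orders_pe(split$retained, cohort$ed_encounters,
                            cohort$admissions, cohort$diagnoses,
                            codeset, linkage_window_hours)
  compute_yield(cls, acc, orders = split$retained)
}
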