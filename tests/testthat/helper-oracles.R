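# Independent brute-force oracles, deliberately written as naive loops over
# raw rows so they share no code path with the package implementation.

# Yield by direct enumeration of every (order, admission, diagnosis) triple.
brute_force_yield <- function(cohort, codeset = pe_codeset(),
                              window_hours = 48) {
  ord <- as.data.frame(cohort$orders)
  adm <- as.data.frame(cohort$admissions)
  dx <- as.data.frame(cohort$diagnoses)

  completed <- ord[ord$order_type == "CTPA" & ord$status == "COMPLETED", ]
  keep <- rep(TRUE, nrow(completed))
  for (i in seq_len(nrow(completed))) {
    for (j in seq_len(nrow(ord))) {
      if (ord$order_type[j] == "CTA_ABD_PELVIS" &&
          ord$status[j] == "COMPLETED" &&
          ord$patient_id[j] == completed$patient_id[i] &&
          as.Date(ord$order_datetime[j], tz = "UTC") ==
            as.Date(completed$order_datetime[i], tz = "UTC")) {
        keep[i] <- FALSE
      }
    }
  }
  analyzable <- completed[keep, ]

  n_pos <- 0L
  for (i in seq_len(nrow(analyzable))) {
    linked <- NA_character_
    for (j in seq_len(nrow(adm))) {
      if (!is.na(adm$source_ed_encounter_id[j]) &&
          adm$source_ed_encounter_id[j] == analyzable$ed_encounter_id[i]) {
        linked <- adm$admission_id[j]
      }
    }
    if (is.na(linked)) {
      best <- NULL
      for (j in seq_len(nrow(adm))) {
        if (adm$patient_id[j] == analyzable$patient_id[i] &&
            adm$admit_datetime[j] >= analyzable$order_datetime[i] &&
            adm$admit_datetime[j] <=
              analyzable$order_datetime[i] + window_hours * 3600) {
          if (is.null(best) ||
              adm$admit_datetime[j] < adm$admit_datetime[best] ||
              (adm$admit_datetime[j] == adm$admit_datetime[best] &&
                 adm$admission_id[j] < adm$admission_id[best])) {
            best <- j
          }
        }
      }
      if (!is.null(best)) linked <- adm$admission_id[best]
    }
    if (!is.na(linked)) {
      for (j in seq_len(nrow(dx))) {
        if (dx$admission_id[j] == linked &&
            is_pe_code(dx$icd_code[j], dx$icd_version[j], codeset)) {
          n_pos <- n_pos + 1L
          break
        }
      }
    }
  }
  list(
    n_raw = nrow(completed),
    n_excluded = sum(!keep),
    n_analyzable = nrow(analyzable),
    numerator = n_pos
  )
}

# Kappa via the explicit 2x2 expected table, summed cell by cell.
brute_force_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  obs <- matrix(c(a, c, b, d), 2, 2)
  row_m <- rowSums(obs)
  col_m <- colSums(obs)
  expected <- outer(row_m, col_m) / n
  p_o <- sum(diag(obs)) / n
  p_e <- sum(diag(expected)) / n
  (p_o - p_e) / (1 - p_e)
}

# Two-sided exact binomial p by enumeration of the full outcome space
# (point probabilities at or below the observed one, the convention used
# for small-sample tests of a fair coin).
enumerate_binom_p <- function(b, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[b + 1] * (1 + 1e-7)])
}

# Random feasible site spec on a small cohort.
rand_site_spec <- function(site_id = "S1", month_start = "2016-04-01") {
  n_ctpa <- sample(4:40, 1)
  n_pairs <- sample(0:min(5, n_ctpa), 1)
  n_analyzable <- n_ctpa - n_pairs
  n_pos <- sample(0:min(6, n_analyzable), 1)
  n_ed_pos <- sample(0:n_pos, 1)
  n_neg_unlinked <- sample(0:(n_analyzable - n_pos), 1)
  site_spec(site_id,
            n_completed_ctpa = n_ctpa,
            n_chart_positive = n_pos,
            n_cancelled_or_discontinued = sample(0:4, 1),
            n_same_day_cta_pairs = n_pairs,
            n_positive_discharged_from_ed = n_ed_pos,
            n_negative_unlinked = n_neg_unlinked,
            icd_version_mix = runif(1),
            rank_mix = runif(1),
            month_start = month_start)
}

# Tiny hand-built cohort: three completed CTPA orders (one PE-positive via
# an admitted stay, one negative admitted, one ED discharge), one cancelled
# CTPA, one same-day CTA pair.
mini_cohort <- function() {
  orders <- tibble::tibble(
    order_id = c("O1", "O2", "O3", "O4", "O5", "O6"),
    patient_id = c("P1", "P2", "P3", "P4", "P5", "P4"),
    ed_encounter_id = c("E1", "E2", "E3", "E4", "E5", "E4"),
    order_type = c("CTPA", "CTPA", "CTPA", "CTPA", "CTPA", "CTA_ABD_PELVIS"),
    status = c("COMPLETED", "COMPLETED", "COMPLETED", "COMPLETED",
               "CANCELLED", "COMPLETED"),
    order_datetime = as.POSIXct(
      c("2016-04-03 10:00:00", "2016-04-04 11:00:00", "2016-04-05 12:00:00",
        "2016-04-06 09:00:00", "2016-04-07 08:00:00", "2016-04-06 10:30:00"),
      tz = "UTC"),
    site_id = "A"
  )
  encounters <- tibble::tibble(
    ed_encounter_id = c("E1", "E2", "E3", "E4", "E5"),
    patient_id = c("P1", "P2", "P3", "P4", "P5"),
    arrival_datetime = orders$order_datetime[1:5] - 3600,
    disposition = c("ADMITTED", "ADMITTED", "DISCHARGED_FROM_ED",
                    "ADMITTED", "DISCHARGED_FROM_ED")
  )
  admissions <- tibble::tibble(
    admission_id = c("A1", "A2", "A3"),
    patient_id = c("P1", "P2", "P4"),
    source_ed_encounter_id = c("E1", "E2", "E4"),
    admit_datetime = orders$order_datetime[c(1, 2, 4)] + 7200,
    discharge_datetime = orders$order_datetime[c(1, 2, 4)] + 3 * 86400
  )
  diagnoses <- tibble::tibble(
    admission_id = c("A1", "A1", "A2", "A3"),
    icd_code = c("J18.9", "I26.99", "N17.9", "J18.9"),
    icd_version = c("ICD10", "ICD10", "ICD10", "ICD10"),
    rank = c("PRIMARY", "SECONDARY", "PRIMARY", "PRIMARY")
  )
  labels <- tibble::tibble(
    order_id = c("O1", "O2", "O3"),
    chart_review_pe_positive = c(TRUE, FALSE, TRUE)
  )
  ehr_cohort(orders, encounters, admissions, diagnoses, labels)
}
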