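test_that("only completed CTPA orders enter the cohort", {
  co <- mini_cohort()
  sel <- select_completed_ed_ctpa(co$orders)
  expect_setequal(sel$order_id, c("O1", "O2", "O3", "O4"))
  expect_equal(nrow(select_completed_ed_ctpa(co$orders[0, ])), 0)

  all_ctpa <- co$orders[co$orders$order_type == "CTPA" &
                          co$orders$status == "COMPLETED", ]
  expect_equal(select_completed_ed_ctpa(all_ctpa), all_ctpa)
})

test_that("same-day CTA abdomen/pelvis exclusion pairs at patient + calendar-date level", {
  co <- mini_cohort()
  sel <- select_completed_ed_ctpa(co$orders)
  split <- exclude_same_day_cta(sel, co$orders)
  expect_equal(split$excluded$order_id, "O4")
  expect_setequal(split$retained$order_id, c("O1", "O2", "O3"))
  expect_equal(nrow(split$retained) + nrow(split$excluded), nrow(sel))

  # next-day CTA does not exclude
  shifted <- co$orders
  shifted$order_datetime[shifted$order_id == "O6"] <-
    as.POSIXct("2016-04-07 00:05:00", tz = "UTC")
  split2 <- exclude_same_day_cta(sel, shifted)
  expect_equal(nrow(split2$excluded), 0)

  # a cancelled CTA does not exclude
  cancelled <- co$orders
  cancelled$status[cancelled$order_id == "O6"] <- "CANCELLED"
  split3 <- exclude_same_day_cta(sel, cancelled)
  expect_equal(nrow(split3$excluded), 0)
})

test_that("linkage prefers the encounter key, then the earliest in-window admission", {
  co <- mini_cohort()
  o1 <- co$orders[co$orders$order_id == "O1", ]
  expect_equal(link_order_to_admission(o1, co$ed_encounters, co$admissions), "A1")

  # ED discharge with no admission stays unlinked
  o3 <- co$orders[co$orders$order_id == "O3", ]
  expect_true(is.na(link_order_to_admission(o3, co$ed_encounters, co$admissions)))

  # fallback: two same-patient admissions at +6h and +200h, 48h window
  adm <- tibble::tibble(
    admission_id = c("B1", "B2"),
    patient_id = "P3",
    source_ed_encounter_id = NA_character_,
    admit_datetime = o3$order_datetime + c(6, 200) * 3600,
    discharge_datetime = o3$order_datetime + c(6, 200) * 3600 + 86400
  )
  expect_equal(link_order_to_admission(o3, co$ed_encounters, adm), "B1")

  # outside-window admission only -> unlinked
  expect_true(is.na(link_order_to_admission(o3, co$ed_encounters, adm[2, ])))

  # tie on admit time breaks to the smallest admission_id, with a warning
  adm_tie <- adm
  adm_tie$admit_datetime <- o3$order_datetime + 6 * 3600
  expect_warning(
    hit <- link_order_to_admission(o3, co$ed_encounters, adm_tie),
    "tied")
  expect_equal(hit, "B1")

  # duplicate encounter claims are an integrity error
  adm_dup <- dplyr::bind_rows(co$admissions, co$admissions[1, ])
  adm_dup$admission_id[4] <- "A9"
  expect_error(link_order_to_admission(o1, co$ed_encounters, adm_dup),
               class = "ctpa_integrity_error")
})

test_that("PE classification needs a linked admission and a code-set hit at any rank", {
  co <- mini_cohort()
  sel <- exclude_same_day_cta(select_completed_ed_ctpa(co$orders), co$orders)
  cls <- classify_orders_pe(sel$retained, co$ed_encounters, co$admissions,
                            co$diagnoses)
  got <- setNames(cls$computed_pe_positive, cls$order_id)
  expect_true(got[["O1"]])   # secondary I26.99 on linked admission
  expect_false(got[["O2"]])  # linked, but only non-PE codes
  expect_false(got[["O3"]])  # chart-positive but discharged from the ED
  expect_true(is.na(cls$linked_admission_id[cls$order_id == "O3"]))
})

test_that("yield assembles counts with exact accounting and per-site partition", {
  co <- mini_cohort()
  y <- ctpa_yield(co)
  expect_equal(y$accounting$n_raw_completed_ctpa, 4)
  expect_equal(y$accounting$n_excluded_same_day_cta, 1)
  expect_equal(y$accounting$n_analyzable, 3)
  expect_equal(y$numerator, 1)
  expect_equal(y$denominator, 3)
  expect_equal(y$yield_fraction, 1 / 3)
  expect_equal(sum(y$per_site$numerator), y$numerator)
  expect_equal(sum(y$per_site$denominator), y$denominator)
})

test_that("an empty cohort gives an explicitly undefined yield, not a crash", {
  co <- mini_cohort()
  empty <- ehr_cohort(co$orders[0, ], co$ed_encounters[0, ],
                      co$admissions[0, ], co$diagnoses[0, ])
  y <- ctpa_yield(empty)
  expect_equal(y$denominator, 0)
  expect_true(is.na(y$yield_fraction))
})

test_that("yield is invariant to input row order", {
  spec <- cohort_spec(list(
    site_spec("A", n_completed_ctpa = 15, n_chart_positive = 3,
              n_same_day_cta_pairs = 2, n_positive_discharged_from_ed = 1,
              n_negative_unlinked = 4, n_cancelled_or_discontinued = 2),
    site_spec("B", n_completed_ctpa = 10, n_chart_positive = 1,
              month_start = "2016-11-01")), random_seed = 11)
  co <- generate_cohort(spec)
  y1 <- ctpa_yield(co)
  set.seed(99)
  shuf <- ehr_cohort(
    co$orders[sample(nrow(co$orders)), ],
    co$ed_encounters[sample(nrow(co$ed_encounters)), ],
    co$admissions[sample(nrow(co$admissions)), ],
    co$diagnoses[sample(nrow(co$diagnoses)), ],
    co$gold_labels[sample(nrow(co$gold_labels)), ]
  )
  y2 <- ctpa_yield(shuf)
  expect_equal(y2$numerator, y1$numerator)
  expect_equal(y2$denominator, y1$denominator)
  expect_equal(y2$accounting$n_excluded_same_day_cta,
               y1$accounting$n_excluded_same_day_cta)
  expect_equal(dplyr::arrange(y2$per_site, site_id),
               dplyr::arrange(y1$per_site, site_id))
})

test_that("pipeline matches the brute-force triple enumeration on small cohorts", {
  for (seed in 1:8) {
    spec <- cohort_spec(list(rand_site_spec()), random_seed = seed)
    # keep the oracle cohorts tiny
    s <- spec$sites[[1]]
    if (s$n_completed_ctpa > 20) {
      spec <- cohort_spec(list(site_spec(
        "S1", n_completed_ctpa = 18,
        n_chart_positive = min(s$n_chart_positive, 4),
        n_cancelled_or_discontinued = s$n_cancelled_or_discontinued,
        n_same_day_cta_pairs = min(s$n_same_day_cta_pairs, 3),
        n_positive_discharged_from_ed = min(s$n_positive_discharged_from_ed,
                                            min(s$n_chart_positive, 4)),
        n_negative_unlinked = min(s$n_negative_unlinked, 5),
        icd_version_mix = s$icd_version_mix, rank_mix = s$rank_mix)),
        random_seed = seed)
    }
    co <- generate_cohort(spec)
    y <- ctpa_yield(co)
    bf <- brute_force_yield(co)
    expect_equal(y$accounting$n_raw_completed_ctpa, bf$n_raw)
    expect_equal(y$accounting$n_excluded_same_day_cta, bf$n_excluded)
    expect_equal(y$denominator, bf$n_analyzable)
    expect_equal(y$numerator, bf$numerator)
  }
})

test_that("adding a PE code never decreases the numerator; removing an admission never increases it", {
  spec <- cohort_spec(list(
    site_spec("A", n_completed_ctpa = 20, n_chart_positive = 3,
              n_negative_unlinked = 5)), random_seed = 5)
  co <- generate_cohort(spec)
  base <- ctpa_yield(co)$numerator

  # add a PE code to a linked, currently negative admission
  neg_cls <- ctpa_yield(co)$classifications
  neg_adm <- neg_cls$linked_admission_id[!neg_cls$computed_pe_positive &
                                           !is.na(neg_cls$linked_admission_id)][1]
  dx_plus <- dplyr::bind_rows(co$diagnoses, tibble::tibble(
    admission_id = neg_adm, icd_code = "I26.99",
    icd_version = "ICD10", rank = "SECONDARY"))
  co_plus <- ehr_cohort(co$orders, co$ed_encounters, co$admissions, dx_plus,
                        co$gold_labels)
  expect_gte(ctpa_yield(co_plus)$numerator, base)
  expect_equal(ctpa_yield(co_plus)$numerator, base + 1)

  # remove a positive admission (and its diagnoses)
  pos_adm <- neg_cls$linked_admission_id[neg_cls$computed_pe_positive][1]
  co_minus <- ehr_cohort(
    co$orders, co$ed_encounters,
    co$admissions[co$admissions$admission_id != pos_adm, ],
    co$diagnoses[co$diagnoses$admission_id != pos_adm, ],
    co$gold_labels)
  expect_lte(ctpa_yield(co_minus)$numerator, base)
})
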