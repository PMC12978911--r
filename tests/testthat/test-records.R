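# Eligibility engine, adjudication rules, aggregation and the 2x2 helpers.

test_that("each exclusion criterion fires on its matching record", {
  fx <- eligibility_fixture()
  res <- filter_eligible(fx$prescriptions, fx$drug_orders)
  dec <- res$decisions

  expect_equal(sum(dec$eligible), 1L)
  expect_true(dec$eligible[dec$record_id == "r_clean"])
  expected <- c(r_age = "under_18", r_preg = "pregnant_or_lactating",
                r_nocef = "no_ceftriaxone",
                r_other = "other_infection_antibiotics",
                r_compl = "complicated")
  got <- setNames(dec$primary_reason[match(names(expected), dec$record_id)],
                  names(expected))
  expect_equal(got, expected)

  flow <- res$flow
  tallies <- colSums(flow[, paste0("excluded_",
                                   crtadhere:::EXCLUSION_REASONS)])
  expect_equal(unname(tallies), rep(1, 5))
  expect_equal(sum(flow$screened), 6)
  expect_equal(sum(flow$eligible), 1)
})

test_that("empty input yields zero decisions and all-zero flow", {
  fx <- eligibility_fixture()
  res <- filter_eligible(fx$prescriptions[0, ], fx$drug_orders[0, ])
  expect_equal(nrow(res$decisions), 0L)
  expect_true(all(res$flow$screened == 0))
  expect_true(all(res$flow$eligible == 0))
})

test_that("first-match ordering sets the primary reason, all recorded", {
  rec <- make_rx("r_multi", patient_age = 16L,
                 diagnosis = "complicated_gonorrhea")
  res <- filter_eligible(rec, make_order("r_multi"))
  dec <- res$decisions
  expect_false(dec$eligible)
  expect_equal(dec$primary_reason, "under_18")
  expect_setequal(dec$reasons[[1]], c("under_18", "complicated"))
})

test_that("filtering is idempotent on the eligible subset", {
  tr <- generate_trial(trial_preset("four_province_trial"), seed = 11)
  res <- filter_eligible(tr$prescriptions, tr$drug_orders)
  keep <- res$decisions$record_id[res$decisions$eligible]
  rec2 <- tr$prescriptions[tr$prescriptions$record_id %in% keep, ]
  res2 <- filter_eligible(rec2, tr$drug_orders)
  expect_true(all(res2$decisions$eligible))
})

test_that("malformed records raise errors naming record and field, or are
           counted when strict = FALSE", {
  rec <- make_rx("r_bad")
  rec$patient_age <- NA_integer_
  expect_error(filter_eligible(rec, make_order("r_bad")),
               "r_bad.*patient_age", class = "crtadhere_validation_error")

  res <- filter_eligible(rec, make_order("r_bad"), strict = FALSE)
  expect_equal(sum(res$flow$invalid), 1L)
  expect_equal(nrow(res$decisions), 0L)
})

test_that("adherence requires a single 1000 mg IM ceftriaxone dose", {
  cases <- list(
    list(order = make_order("r1"), adherent = TRUE),
    list(order = make_order("r1", dose_mg = 2000), adherent = FALSE),
    list(order = make_order("r1", n_administrations = 3L),
         adherent = FALSE),
    list(order = make_order("r1", route = "IV"), adherent = FALSE),
    list(order = make_order("r1", dose_mg = 500), adherent = FALSE)
  )
  for (cs in cases) {
    rec <- make_rx("r1")
    dec <- filter_eligible(rec, cs$order)$decisions
    call <- adjudicate_adherence(rec, cs$order, dec)
    expect_equal(call$adherent, cs$adherent)
  }
})

test_that("missing route is nonadherent-by-deviation with a warning", {
  rec <- make_rx("r1")
  ord <- make_order("r1")
  ord$route <- NA_character_
  dec <- filter_eligible(rec, ord)$decisions
  expect_warning(call <- adjudicate_adherence(rec, ord, dec),
                 "missing route")
  expect_false(call$adherent)
})

test_that("an extra gonorrhea antibiotic is a flagged-ambiguous deviation", {
  rec <- make_rx("r1")
  ord <- rbind(make_order("r1"),
               make_order("r1", drug_name = "azithromycin", dose_mg = 1000,
                          route = "oral"))
  dec <- filter_eligible(rec, ord)$decisions
  call <- adjudicate_adherence(rec, ord, dec)
  expect_false(call$adherent)
  expect_true(call$ambiguous_extra_antibiotic)
})

test_that("adjudicating an ineligible record is a contract violation", {
  rec <- make_rx("r1", patient_age = 16L)
  ord <- make_order("r1")
  dec <- filter_eligible(rec, ord)$decisions
  expect_error(adjudicate_adherence(rec, ord, dec),
               "ineligible", class = "crtadhere_validation_error")
})

test_that("reviewer overrides surface as disagreements, not resolutions", {
  rec <- make_rx("r1")
  ord <- make_order("r1")
  dec <- filter_eligible(rec, ord)$decisions
  ov <- data.frame(record_id = "r1", adherent_override = FALSE)
  call <- adjudicate_adherence(rec, ord, dec, overrides = ov)
  expect_true(call$adherent)       # rule engine's call stands
  expect_true(call$disagreement)
})

test_that("drug-name matching is case-insensitive and synonym-driven", {
  rec <- make_rx("r1")
  ord <- make_order("r1", drug_name = "CefTriaXone Sodium")
  dec <- filter_eligible(rec, ord)$decisions
  expect_true(dec$eligible)
  dec2 <- filter_eligible(rec, ord, synonyms = "rocephin")$decisions
  expect_false(dec2$eligible)
  expect_equal(dec2$primary_reason, "no_ceftriaxone")
})

test_that("adherence_table counts, flags empty clusters, and is additive", {
  rec <- rbind(
    make_rx("a1"), make_rx("a2"), make_rx("a3"),
    make_rx("b1", cluster_id = "H02", arm = "intervention")
  )
  ord <- rbind(make_order("a1"), make_order("a2"),
               make_order("a3", dose_mg = 2000), make_order("b1"))
  dec <- filter_eligible(rec, ord)$decisions
  calls <- adjudicate_adherence(rec, ord, dec)
  tab <- adherence_table(rec, dec, calls)

  h1 <- tab[tab$cluster_id == "H01" & tab$period == "baseline", ]
  expect_equal(h1$o, 2L); expect_equal(h1$n, 3L)
  h1e <- tab[tab$cluster_id == "H01" & tab$period == "endline", ]
  expect_equal(h1e$n, 0L); expect_true(h1e$empty)
  # per-cluster counts partition the global eligible count
  expect_equal(sum(tab$n), sum(dec$eligible))
  expect_equal(sum(tab$o), sum(calls$adherent))
})

test_that("percentages print with half-away rounding and dropped .0", {
  expect_equal(report_percentage(1415, 2897), "48.8%")
  expect_equal(report_percentage(1240, 2954), "42%")
  expect_equal(report_percentage(0, 10), "0%")
  expect_equal(report_percentage(1, 3, decimals = 2), "33.33%")
  expect_error(report_percentage(1, 0), "denominator",
               class = "crtadhere_computation_error")
})

test_that("crude odds ratio matches hand computation with Woolf CI", {
  res <- crude_odds_ratio(194, 122, 540, 668)
  expect_equal(res$or, 194 * 668 / (122 * 540))
  se <- sqrt(1 / 194 + 1 / 122 + 1 / 540 + 1 / 668)
  expect_equal(res$ci,
               exp(log(res$or) + c(-1, 1) * qnorm(0.975) * se))
  expect_lt(res$p, 0.001)

  sym <- crude_odds_ratio(10, 10, 10, 10)
  expect_equal(sym$or, 1)
  expect_true(sym$ci[1] < 1 && sym$ci[2] > 1)

  corr <- crude_odds_ratio(0, 5, 5, 5)
  expect_equal(corr$or, (0.5 * 5.5) / (5.5 * 5.5))
  expect_true(corr$corrected)

  expect_error(crude_odds_ratio(0, 0, 5, 5), "margin",
               class = "crtadhere_computation_error")
})

test_that("reciprocal 2x2 tables give exactly reciprocal odds ratios", {
  set.seed(7)
  for (i in 1:20) {
    cells <- sample(1:200, 4)
    f <- crude_odds_ratio(cells[1], cells[2], cells[3], cells[4])
    b <- crude_odds_ratio(cells[2], cells[1], cells[4], cells[3])
    expect_equal(f$or * b$or, 1)
  }
})
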