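## Prescription-record data model: validation, eligibility filtering,
## adherence adjudication, flow accounting, and the 2x2 building blocks of
## the physician-factor screen.
##
## Records are relational: one data.frame of prescriptions (one row per
## dispensed treatment event) and one of drug orders (one row per drug on a
## prescription, keyed by record_id).

ARMS <- c("control", "intervention")
PERIODS <- c("baseline", "endline")
DIAGNOSES <- c("uncomplicated_gonorrhea", "complicated_gonorrhea")
ROUTES <- c("IM", "IV", "oral", "other")
INDICATIONS <- c("gonorrhea", "other_infection")

## Exclusion criteria in adjudication order; the first match is the primary
## reason recorded in flow tallies.
EXCLUSION_REASONS <- c(
  "under_18", "pregnant_or_lactating", "no_ceftriaxone",
  "other_infection_antibiotics", "complicated"
)

PRESCRIPTION_REQUIRED <- c(
  "record_id", "cluster_id", "stratum", "arm", "period", "patient_age",
  "patient_sex", "pregnant_or_lactating", "diagnosis", "physician_id"
)

DRUG_ORDER_REQUIRED <- c(
  "record_id", "drug_name", "dose_mg", "route", "n_administrations",
  "indication"
)

#' Default ceftriaxone synonym list
#'
#' Drug names extracted from hospital information systems are
#' dialect-ridden; matching is case-insensitive against this configurable
#' list. Trade-name placeholders can be appended by the caller.
#'
#' @return Character vector of names normalized to lower case.
#' @export
ceftriaxone_synonyms <- function() {
  c("ceftriaxone", "ceftriaxone sodium", "rocephin")
}

normalize_drug_name <- function(x) {
  tolower(trimws(as.character(x)))
}

is_ceftriaxone <- function(drug_name, synonyms = ceftriaxone_synonyms()) {
  normalize_drug_name(drug_name) %in% normalize_drug_name(synonyms)
}

#' Validate prescription and drug-order tables
#'
#' Checks the required column set, per-record missingness of required
#' fields, enum membership and basic invariants (non-negative age, positive
#' doses, administrations >= 1, consistent (cluster, stratum, arm) labels).
#'
#' @param prescriptions Data frame, one row per prescription.
#' @param drug_orders Data frame, one row per drug order, keyed by
#'   `record_id`.
#' @param strict If `TRUE` (default) the first malformed record raises a
#'   validation error naming the record and field; if `FALSE` all problems
#'   are collected and returned so callers can count unusable (for example
#'   illegible) records in the flow report.
#' @return A list with `problems` (data.frame of record_id/field/issue) and
#'   `invalid_ids` (record ids failing validation).
#' @export
validate_prescriptions <- function(prescriptions, drug_orders,
                                   strict = TRUE) {
  check_columns(prescriptions, PRESCRIPTION_REQUIRED, "prescriptions")
  check_columns(drug_orders, DRUG_ORDER_REQUIRED, "drug_orders")

  if (anyDuplicated(prescriptions$record_id)) {
    abort_validation(sprintf(
      "duplicate record_id: %s",
      prescriptions$record_id[duplicated(prescriptions$record_id)][1]))
  }

  problems <- list()
  add <- function(id, field, issue) {
    problems[[length(problems) + 1L]] <<- data.frame(
      record_id = as.character(id), field = field, issue = issue,
      stringsAsFactors = FALSE
    )
  }

  for (f in PRESCRIPTION_REQUIRED) {
    bad <- is.na(prescriptions[[f]])
    if (f %in% c("record_id", "cluster_id", "stratum", "physician_id")) {
      bad <- bad | !nzchar(as.character(prescriptions[[f]]))
    }
    for (id in prescriptions$record_id[bad]) add(id, f, "missing")
  }
  ok_age <- !is.na(prescriptions$patient_age)
  for (id in prescriptions$record_id[ok_age & prescriptions$patient_age < 0])
    add(id, "patient_age", "negative")

  check_enum(prescriptions$arm, ARMS, "prescriptions$arm")
  check_enum(prescriptions$period, PERIODS, "prescriptions$period")
  check_enum(prescriptions$diagnosis, DIAGNOSES, "prescriptions$diagnosis")
  check_enum(drug_orders$route, ROUTES, "drug_orders$route")
  check_enum(drug_orders$indication, INDICATIONS, "drug_orders$indication")

  bad_dose <- !is.na(drug_orders$dose_mg) & drug_orders$dose_mg <= 0
  for (id in unique(drug_orders$record_id[bad_dose]))
    add(id, "dose_mg", "non-positive")
  bad_adm <- !is.na(drug_orders$n_administrations) &
    drug_orders$n_administrations < 1
  for (id in unique(drug_orders$record_id[bad_adm]))
    add(id, "n_administrations", "less than 1")

  ## (cluster_id, stratum, arm) must be constant within a cluster
  key <- unique(prescriptions[!is.na(prescriptions$cluster_id),
                              c("cluster_id", "stratum", "arm")])
  dup <- key$cluster_id[duplicated(key$cluster_id)]
  if (length(dup)) {
    abort_validation(sprintf(
      "inconsistent (stratum, arm) labels within cluster(s): %s",
      paste(unique(dup), collapse = ", ")
    ))
  }

  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(record_id = character(), field = character(),
               issue = character(), stringsAsFactors = FALSE)
  if (strict && nrow(problems)) {
    abort_validation(sprintf(
      "malformed record %s: field '%s' %s",
      problems$record_id[1], problems$field[1], problems$issue[1]
    ))
  }
  list(problems = problems, invalid_ids = unique(problems$record_id))
}

#' Apply the five eligibility exclusion criteria
#'
#' A prescription is excluded if the patient was under 18, pregnant or
#' lactating, received no ceftriaxone, was treated with antibiotics for
#' other infections, or was diagnosed with complicated gonorrhea. Criteria
#' are evaluated in that order; the first match is the primary reason used
#' in flow tallies, and all matching reasons are recorded.
#'
#' @inheritParams validate_prescriptions
#' @param synonyms Ceftriaxone synonym list for drug-name matching.
#' @param strict Passed to [validate_prescriptions()]; with `strict =
#'   FALSE`, records failing validation are counted as `invalid` in the
#'   flow report and receive no eligibility decision.
#' @return A list of class `"crt_eligibility"`: `decisions` (record_id,
#'   eligible, primary_reason, reasons), `flow` (a [flow_counts()] table)
#'   and `problems` from validation.
#' @examples
#' tr <- generate_trial(trial_preset("null_trial"), seed = 1)
#' elig <- filter_eligible(tr$prescriptions, tr$drug_orders)
#' table(elig$decisions$eligible)
#' @export
filter_eligible <- function(prescriptions, drug_orders,
                            synonyms = ceftriaxone_synonyms(),
                            strict = TRUE) {
  val <- validate_prescriptions(prescriptions, drug_orders, strict = strict)
  valid <- !(prescriptions$record_id %in% val$invalid_ids)
  rec <- prescriptions[valid, , drop = FALSE]

  if (nrow(rec)) {
    ord <- drug_orders[drug_orders$record_id %in% rec$record_id, ,
                       drop = FALSE]
    cef_ids <- unique(ord$record_id[is_ceftriaxone(ord$drug_name, synonyms)])
    other_ids <- unique(ord$record_id[ord$indication == "other_infection"])

    crit <- cbind(
      under_18 = rec$patient_age < 18,
      pregnant_or_lactating = rec$pregnant_or_lactating,
      no_ceftriaxone = !(rec$record_id %in% cef_ids),
      other_infection_antibiotics = rec$record_id %in% other_ids,
      complicated = rec$diagnosis == "complicated_gonorrhea"
    )
    eligible <- rowSums(crit) == 0L
    primary <- apply(crit, 1L, function(z)
      if (any(z)) EXCLUSION_REASONS[which(z)[1L]] else NA_character_)
    reasons <- apply(crit, 1L, function(z) EXCLUSION_REASONS[z],
                     simplify = FALSE)
    decisions <- data.frame(
      record_id = rec$record_id, eligible = eligible,
      primary_reason = primary, stringsAsFactors = FALSE
    )
    decisions$reasons <- reasons
  } else {
    decisions <- data.frame(record_id = character(), eligible = logical(),
                            primary_reason = character(),
                            stringsAsFactors = FALSE)
    decisions$reasons <- list()
  }

  flow <- flow_counts(prescriptions, decisions, val$invalid_ids)
  structure(list(decisions = decisions, flow = flow,
                 problems = val$problems),
            class = "crt_eligibility")
}

#' Tabulate trial flow per arm and period
#'
#' Counts screened, invalid (failed validation), excluded per primary
#' reason, and eligible prescriptions for every (arm, period) cell, the
#' numbers a CONSORT-style trial profile reports. Conservation holds by
#' construction: screened = invalid + eligible + sum of exclusions.
#'
#' @param prescriptions Prescription table (all screened records).
#' @param decisions Decision table from [filter_eligible()].
#' @param invalid_ids Record ids that failed validation.
#' @return Data frame with one row per (arm, period).
#' @export
flow_counts <- function(prescriptions, decisions,
                        invalid_ids = character()) {
  cells <- expand.grid(arm = ARMS, period = PERIODS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dec_primary <- decisions$primary_reason[match(prescriptions$record_id,
                                                decisions$record_id)]
  dec_elig <- decisions$eligible[match(prescriptions$record_id,
                                       decisions$record_id)]
  invalid <- prescriptions$record_id %in% invalid_ids
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    in_cell <- !is.na(prescriptions$arm) & !is.na(prescriptions$period) &
      prescriptions$arm == cells$arm[i] &
      prescriptions$period == cells$period[i]
    ## records with a blanked arm/period can only be invalid; they are
    ## reported in the totals row of the rendered diagram
    excl <- vapply(EXCLUSION_REASONS, function(r)
      sum(in_cell & !invalid & !is.na(dec_primary) & dec_primary == r,
          na.rm = TRUE), integer(1))
    data.frame(
      arm = cells$arm[i], period = cells$period[i],
      screened = sum(in_cell),
      invalid = sum(in_cell & invalid),
      t(excl),
      eligible = sum(in_cell & !invalid & dec_elig, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[seq_along(EXCLUSION_REASONS) + 4L] <-
    paste0("excluded_", EXCLUSION_REASONS)
  out
}

#' Adjudicate guideline adherence of eligible prescriptions
#'
#' The guideline regimen for uncomplicated gonorrhea is a single 1 g (1000
#' mg) intramuscular dose of ceftriaxone; any deviation is nonadherence. A
#' record is adherent iff its ceftriaxone orders consist of exactly one
#' order with one administration of 1000 mg by the IM route, and it carries
#' no additional antibiotic order. Records with a missing route are
#' nonadherent-by-deviation with a warning. An extra antibiotic indicated
#' for gonorrhea (rather than another infection, which triggers exclusion
#' upstream) is treated as a deviation and flagged as ambiguous in the
#' output.
#'
#' Dual review is modeled by an optional `overrides` table of second
#' reviewer calls; disagreements with the rule engine are surfaced in the
#' `disagreement` column, never silently resolved.
#'
#' @inheritParams filter_eligible
#' @param decisions Eligibility decisions from [filter_eligible()]. Calling
#'   on a record adjudged ineligible is a contract violation and errors.
#' @param overrides Optional data frame (`record_id`, `adherent_override`)
#'   of independent second-reviewer calls.
#' @return Data frame: `record_id`, `adherent`, `ambiguous_extra_antibiotic`,
#'   and `disagreement` when overrides are supplied.
#' @export
adjudicate_adherence <- function(prescriptions, drug_orders, decisions,
                                 synonyms = ceftriaxone_synonyms(),
                                 overrides = NULL) {
  elig_ids <- decisions$record_id[decisions$eligible]
  extra <- setdiff(prescriptions$record_id, decisions$record_id)
  if (length(extra)) {
    abort_validation(sprintf(
      "no eligibility decision for record(s): %s",
      paste(utils::head(extra, 3), collapse = ", ")
    ))
  }
  inelig <- setdiff(prescriptions$record_id, elig_ids)
  if (length(inelig)) {
    abort_validation(sprintf(
      "adjudication requested for ineligible record(s): %s",
      paste(utils::head(inelig, 3), collapse = ", ")
    ))
  }
  rec_ids <- prescriptions$record_id
  ord <- drug_orders[drug_orders$record_id %in% rec_ids, , drop = FALSE]
  cef <- is_ceftriaxone(ord$drug_name, synonyms)

  n_cef <- tabulate_by(ord$record_id[cef], rec_ids)
  n_other <- tabulate_by(ord$record_id[!cef], rec_ids)

  cef_ord <- ord[cef, , drop = FALSE]
  route_missing <- is.na(cef_ord$route)
  ok_regimen <- !route_missing & cef_ord$route == "IM" &
    cef_ord$dose_mg == 1000 & cef_ord$n_administrations == 1
  n_ok <- tabulate_by(cef_ord$record_id[ok_regimen], rec_ids)

  if (any(route_missing)) {
    warning(sprintf(
      "%d ceftriaxone order(s) with missing route classified as deviation",
      sum(route_missing)
    ), call. = FALSE)
  }

  adherent <- n_cef == 1L & n_ok == 1L & n_other == 0L
  out <- data.frame(
    record_id = rec_ids,
    adherent = adherent,
    ambiguous_extra_antibiotic = adherent_ambiguity(n_cef, n_ok, n_other),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    check_columns(overrides, c("record_id", "adherent_override"), "overrides")
    ov <- overrides$adherent_override[match(rec_ids, overrides$record_id)]
    out$disagreement <- !is.na(ov) & ov != out$adherent
  }
  out
}

## Extra gonorrhea-indicated antibiotic alongside a guideline-conforming
## ceftriaxone order: classified nonadherent, but the guideline is silent,
## so the call is flagged for review.
adherent_ambiguity <- function(n_cef, n_ok, n_other) {
  n_cef == 1L & n_ok == 1L & n_other > 0L
}

tabulate_by <- function(ids, universe) {
  out <- table(factor(ids, levels = universe))
  as.integer(out)
}

#' Aggregate adherence calls into per-cluster, per-period summaries
#'
#' Builds the cluster-level summary table the trial analysis consumes: per
#' (cluster, period), the adherent count `o`, the eligible denominator `n`
#' and the observed proportion `p`. Clusters present in the record table
#' but with no eligible records in a period are retained with `n = 0` and
#' flagged, so downstream analysis can report them as dropped.
#'
#' @param prescriptions Prescription table.
#' @param decisions Eligibility decisions from [filter_eligible()].
#' @param calls Adherence calls from [adjudicate_adherence()] on the
#'   eligible subset.
#' @return Data frame: cluster_id, stratum, arm, period, o, n, p, empty.
#' @export
adherence_table <- function(prescriptions, decisions, calls) {
  elig_ids <- decisions$record_id[decisions$eligible]
  missing_calls <- setdiff(elig_ids, calls$record_id)
  if (length(missing_calls)) {
    abort_validation(sprintf(
      "eligible record(s) without adherence call: %s",
      paste(utils::head(missing_calls, 3), collapse = ", ")
    ))
  }
  clusters <- unique(prescriptions[!is.na(prescriptions$cluster_id),
                                   c("cluster_id", "stratum", "arm")])
  grid <- merge(clusters, data.frame(period = PERIODS), by = NULL)
  is_elig <- prescriptions$record_id %in% elig_ids
  adh <- calls$adherent[match(prescriptions$record_id, calls$record_id)]
  key_all <- paste(prescriptions$cluster_id, prescriptions$period)
  key_grid <- paste(grid$cluster_id, grid$period)
  n <- vapply(seq_len(nrow(grid)), function(i)
    sum(is_elig & key_all == key_grid[i]), integer(1))
  o <- vapply(seq_len(nrow(grid)), function(i)
    sum(is_elig & key_all == key_grid[i] & adh, na.rm = TRUE), integer(1))
  out <- data.frame(
    cluster_id = grid$cluster_id, stratum = grid$stratum, arm = grid$arm,
    period = grid$period, o = o, n = n,
    p = ifelse(n > 0, o / n, NA_real_),
    empty = n == 0L,
    stringsAsFactors = FALSE
  )
  out[order(out$stratum, out$arm, out$cluster_id, out$period), ,
      drop = FALSE]
}

#' Format a percentage the way trial reports print it
#'
#' Computes `100 * numerator / denominator`, rounds half away from zero to
#' `decimals` places, and drops a trailing ".0" when `decimals = 1` (so
#' 41.98% prints as "42%", matching the usual reporting convention).
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be
#'   positive.
#' @param decimals Decimal places to keep (default 1).
#' @return A string such as `"48.8%"`.
#' @examples
#' report_percentage(1415, 2897) # "48.8%"
#' report_percentage(1240, 2954) # "42%"
#' @export
report_percentage <- function(numerator, denominator, decimals = 1L) {
  if (length(denominator) != 1L || is.na(denominator) || denominator <= 0)
    abort_computation("percentage undefined: denominator must be positive")
  value <- round_half_away(100 * numerator / denominator, decimals)
  s <- formatC(value, format = "f", digits = decimals)
  if (decimals == 1L) s <- sub("\\.0$", "", s)
  paste0(s, "%")
}

#' Crude odds ratio from a 2x2 table
#'
#' The univariate screening step of the physician-factor analysis: for a
#' table with cells a, b (outcome rows) and c, d, the odds ratio is
#' `(a*d)/(b*c)` with a Woolf (log) confidence interval and a Wald test on
#' the log odds ratio. When any cell is zero the Haldane–Anscombe
#' correction adds 0.5 to all four cells for the OR and CI.
#'
#' @param a,b,c,d Non-negative cell counts (a/c one column, b/d the other).
#' @param conf.level Confidence level for the Woolf interval.
#' @return List: `or`, `ci` (length 2), `p`, `corrected` (whether the 0.5
#'   correction was applied).
#' @examples
#' crude_odds_ratio(194, 122, 540, 668)$or # about 1.97
#' @export
crude_odds_ratio <- function(a, b, c, d, conf.level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    abort_validation("2x2 cells must be non-negative counts")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    abort_computation("degenerate 2x2 table: a zero row or column margin")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  list(or = or, ci = ci, p = p, corrected = corrected)
}
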