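## The primary-outcome analysis as one fitting function: filter ->
## adjudicate -> cluster summaries -> covariate model -> residuals ->
## stratified effect estimates and within-arm paired tests, on an
## intention-to-treat basis (clusters analyzed under their original
## allocation labels).

#' Fit the full cluster-level adherence analysis
#'
#' Runs the complete primary-outcome pipeline on prescription-level data:
#' eligibility filtering under the five exclusion criteria, adjudication of
#' the single-1g-IM-ceftriaxone guideline, aggregation to per-cluster
#' adherence proportions, unadjusted stratified risk-ratio and
#' risk-difference estimates comparing arms at endline, covariate-adjusted
#' analogues via ratio/difference residuals from an individual-level
#' logistic model excluding the treatment arm, and within-arm paired
#' t-tests of change from baseline.
#'
#' @param prescriptions,drug_orders,physicians The three input tables (see
#'   [generate_trial()] for the schema; `physicians` may be `NULL` when the
#'   physician covariates are not requested).
#' @param alpha Two-sided significance level.
#' @param adjust Also compute the covariate-adjusted estimates?
#' @param covariates Covariate set for the individual-level model.
#'   Covariates constant in the data are dropped with a message.
#' @param synonyms Ceftriaxone synonym list.
#' @param strict If `FALSE`, records failing validation are counted as
#'   invalid instead of raising an error.
#' @param small_stratum Passed to [stratified_risk_ratio()].
#' @return An object of class `"crt_analysis"` with components `effects`
#'   (crt_effect objects: `rr`, `rd`, and when adjusted `rr_adj`,
#'   `rd_adj`), `paired` (per-arm change tests), `summaries`, `flow`,
#'   `rates` (per arm and period), `model`, and bookkeeping counts.
#' @examples
#' tr <- generate_trial(trial_preset("null_trial"), seed = 42)
#' fit <- crt_analysis(tr$prescriptions, tr$drug_orders, tr$physicians)
#' fit$effects$rr
#' @export
crt_analysis <- function(prescriptions, drug_orders, physicians = NULL,
                         alpha = 0.05, adjust = TRUE,
                         covariates = c("stratum", "p_baseline",
                                        "patient_sex", "patient_age",
                                        "physician_sex", "department"),
                         synonyms = ceftriaxone_synonyms(),
                         strict = TRUE,
                         small_stratum = c("error", "merge")) {
  small_stratum <- match.arg(small_stratum)
  stage <- function(what, expr) {
    tryCatch(expr, crtadhere_error = function(e) {
      abort(sprintf("[%s] %s", what, conditionMessage(e)), class(e)[1])
    })
  }

  elig <- stage("filter", filter_eligible(prescriptions, drug_orders,
                                          synonyms, strict = strict))
  elig_ids <- elig$decisions$record_id[elig$decisions$eligible]
  rec_elig <- prescriptions[prescriptions$record_id %in% elig_ids, ,
                            drop = FALSE]
  calls <- stage("adjudicate",
                 adjudicate_adherence(rec_elig, drug_orders,
                                      elig$decisions, synonyms))
  summaries <- stage("aggregate",
                     adherence_table(prescriptions, elig$decisions, calls))

  ## endline analysis table with the baseline cluster outcome attached
  base <- summaries[summaries$period == "baseline", , drop = FALSE]
  end <- summaries[summaries$period == "endline", , drop = FALSE]
  pb <- base$p[match(end$cluster_id, base$cluster_id)]
  if (anyNA(pb)) {
    ## clusters without baseline data take their stratum's mean baseline
    strat_mean <- tapply(base$p[base$n > 0], base$stratum[base$n > 0], mean)
    fill <- as.numeric(strat_mean[end$stratum])
    fill[is.na(fill)] <- mean(base$p[base$n > 0])
    pb[is.na(pb)] <- fill[is.na(pb)]
  }
  end$p_baseline <- pb

  effects <- list(
    rr = stage("estimate", stratified_risk_ratio(
      end, use_residuals = FALSE, alpha = alpha,
      small_stratum = small_stratum)),
    rd = stage("estimate", stratified_risk_difference(
      end, use_residuals = FALSE, alpha = alpha,
      small_stratum = small_stratum))
  )

  model <- NULL
  if (adjust) {
    indiv <- rec_elig[rec_elig$period == "endline", , drop = FALSE]
    indiv$adherent <- calls$adherent[match(indiv$record_id,
                                           calls$record_id)]
    indiv$p_baseline <- end$p_baseline[match(indiv$cluster_id,
                                             end$cluster_id)]
    if (!is.null(physicians)) {
      m <- match(indiv$physician_id, physicians$physician_id)
      indiv$physician_sex <- physicians$sex[m]
      indiv$department <- physicians$department[m]
    }
    use <- covariates[covariates %in% names(indiv)]
    skipped <- setdiff(covariates, use)
    constant <- use[vapply(use, function(cv)
      length(unique(indiv[[cv]])) < 2L, logical(1))]
    if (length(constant) || length(skipped)) {
      message("covariates dropped (constant or unavailable): ",
              paste(c(skipped, constant), collapse = ", "))
      use <- setdiff(use, constant)
    }
    model <- stage("model", fit_covariate_model(indiv, covariates = use))
    end <- stage("residualize", residualize(end, model))
    effects$rr_adj <- stage("estimate", stratified_risk_ratio(
      end, use_residuals = TRUE, alpha = alpha,
      small_stratum = small_stratum))
    effects$rd_adj <- stage("estimate", stratified_risk_difference(
      end, use_residuals = TRUE, alpha = alpha,
      small_stratum = small_stratum))
  }

  paired <- lapply(stats::setNames(ARMS, ARMS), function(a)
    tryCatch(paired_change_test(summaries, a, alpha),
             crtadhere_error = function(e) NULL))

  ## per arm x period adherence rates from eligible counts
  key <- interaction(summaries$arm, summaries$period)
  rates <- do.call(rbind, lapply(split(summaries, key), function(s)
    data.frame(arm = s$arm[1], period = s$period[1],
               adherent = sum(s$o), eligible = sum(s$n),
               rate = if (sum(s$n) > 0) sum(s$o) / sum(s$n) else NA_real_,
               stringsAsFactors = FALSE)))
  rownames(rates) <- NULL

  structure(list(
    effects = effects,
    paired = paired,
    summaries = summaries,
    endline = end,
    flow = elig$flow,
    rates = rates,
    model = model,
    decisions = elig$decisions,
    calls = calls,
    alpha = alpha,
    n_ambiguous = sum(calls$ambiguous_extra_antibiotic),
    call = match.call()
  ), class = "crt_analysis")
}

#' @export
print.crt_analysis <- function(x, digits = 3, ...) {
  cat("Stratified cluster-randomized adherence analysis\n")
  nclus <- length(unique(x$summaries$cluster_id))
  cat(sprintf("  %d clusters, %d strata; %d eligible prescriptions\n",
              nclus, length(unique(x$summaries$stratum)),
              sum(x$summaries$n)))
  for (i in seq_len(nrow(x$rates))) {
    r <- x$rates[i, ]
    if (r$eligible > 0)
      cat(sprintf("  %s %s adherence: %d/%d (%s)\n", r$arm, r$period,
                  r$adherent, r$eligible,
                  report_percentage(r$adherent, r$eligible)))
  }
  cat("\n")
  for (e in x$effects) print(e, digits = digits)
  invisible(x)
}

#' @export
summary.crt_analysis <- function(object, ...) {
  eff <- do.call(rbind, lapply(names(object$effects), function(nm) {
    e <- object$effects[[nm]]
    data.frame(estimate = nm, scale = e$scale, adjusted = e$adjusted,
               point = e$point, ci_low = e$ci[1], ci_high = e$ci[2],
               t = e$t, df = e$df, p = e$p, stringsAsFactors = FALSE)
  }))
  paired <- do.call(rbind, lapply(object$paired, function(pt) {
    if (is.null(pt)) return(NULL)
    data.frame(arm = pt$arm, mean_diff = pt$mean_diff,
               ci_low = pt$ci[1], ci_high = pt$ci[2], p = pt$p,
               n_clusters = pt$n_clusters, stringsAsFactors = FALSE)
  }))
  out <- list(effects = eff, paired = paired, rates = object$rates,
              strata = object$effects$rr$strata, flow = object$flow,
              n_ambiguous = object$n_ambiguous)
  class(out) <- "summary.crt_analysis"
  out
}

#' @export
print.summary.crt_analysis <- function(x, digits = 3, ...) {
  cat("Effect estimates (intervention vs control, endline):\n")
  print(format(x$effects, digits = digits), row.names = FALSE)
  if (!is.null(x$paired)) {
    cat("\nWithin-arm change from baseline (paired t):\n")
    print(format(x$paired, digits = digits), row.names = FALSE)
  }
  cat("\nAdherence rates:\n")
  print(format(x$rates, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.crt_analysis <- function(object, ...) {
  out <- vapply(object$effects, function(e)
    if (e$scale == "ratio") e$log_point else e$point, numeric(1))
  names(out) <- sub("^rr", "log_rr", names(out))
  out
}

#' @export
confint.crt_analysis <- function(object, parm, level, ...) {
  out <- t(vapply(object$effects, function(e) e$ci, numeric(2)))
  colnames(out) <- paste0(
    format(100 * c(object$alpha / 2, 1 - object$alpha / 2)), " %")
  out
}

#' @export
plot.crt_analysis <- function(x, ...) {
  s <- x$summaries[x$summaries$n > 0, , drop = FALSE]
  s$at <- as.integer(factor(s$period, PERIODS)) +
    ifelse(s$arm == "intervention", 0.18, -0.18)
  graphics::plot(
    s$at, s$p, xlim = c(0.5, 2.5), ylim = c(0, 1), xaxt = "n",
    xlab = "period", ylab = "cluster adherence proportion",
    pch = ifelse(s$arm == "intervention", 19, 1), ...
  )
  graphics::axis(1, at = 1:2, labels = PERIODS)
  for (a in ARMS) {
    m <- tapply(s$p[s$arm == a], s$period[s$arm == a], mean)
    graphics::lines(1:2 + if (a == "intervention") 0.18 else -0.18,
                    m[PERIODS], lty = if (a == "intervention") 1 else 2)
  }
  graphics::legend("topleft", legend = ARMS, pch = c(1, 19),
                   lty = c(2, 1), bty = "n")
  invisible(x)
}
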