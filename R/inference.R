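## Primary-outcome inference for stratified cluster-randomized trials by
## cluster-level summaries: stratum-specific risk ratios as ratios of
## geometric mean cluster risks (differences of mean log risks), pooled by
## inverse-variance weights, with an approximate SE and a stratified
## two-tailed t-test; a risk-difference analogue on the untransformed
## proportions; and covariate adjustment through cluster-specific ratio (or
## difference) residuals from an individual-level logistic model that
## excludes the treatment arm.

## Continuity substitution for zero- or full-event clusters: p~ = (o +
## 0.5)/(n + 1). Applied only where a log is taken.
continuity_adjust <- function(o, n) {
  edge <- o == 0L | o == n
  p <- ifelse(edge, (o + 0.5) / (n + 1), o / n)
  attr(p, "n_substituted") <- sum(edge)
  p
}

#' Log-transform cluster-level risks
#'
#' Computes the log cluster proportion used by the geometric-mean risk
#' ratio analysis, substituting `(o + 0.5)/(n + 1)` for zero- and
#' full-event clusters so the log is finite. Clusters with `n = 0` are
#' dropped with a warning; the drop and substitution counts are attached as
#' attributes.
#'
#' @param summaries Cluster summary table from [adherence_table()] (or any
#'   data frame with `o`, `n` columns).
#' @return The table, minus empty clusters, with columns `p_tilde` and `l`
#'   (= log p_tilde) appended; attributes `n_dropped`, `n_substituted`.
#' @export
log_cluster_risks <- function(summaries) {
  check_columns(summaries, c("o", "n"), "summaries")
  drop <- summaries$n == 0L
  if (any(drop)) {
    warning(sprintf("%d cluster-period(s) with no eligible records dropped",
                    sum(drop)), call. = FALSE)
  }
  out <- summaries[!drop, , drop = FALSE]
  pt <- continuity_adjust(out$o, out$n)
  out$p_tilde <- as.numeric(pt)
  out$l <- log(out$p_tilde)
  attr(out, "n_dropped") <- sum(drop)
  attr(out, "n_substituted") <- attr(pt, "n_substituted")
  out
}

## Merge strata that have fewer than 2 clusters in an arm into the smallest
## other stratum (by total clusters), repeatedly. Only used when the caller
## opts in; the default is a hard error because merging changes the
## estimand.
merge_small_strata <- function(summaries) {
  repeat {
    tab <- table(summaries$stratum, summaries$arm)
    if (nrow(tab) <= 1L) return(summaries)
    bad <- rownames(tab)[apply(tab < 2L, 1L, any)]
    if (!length(bad)) return(summaries)
    sizes <- rowSums(tab)
    others <- setdiff(rownames(tab), bad[1L])
    target <- others[which.min(sizes[others])]
    summaries$stratum[summaries$stratum == bad[1L]] <- target
  }
}

## Shared engine behind the ratio- and difference-scale estimates.
stratified_effect <- function(summaries, scale, use_residuals, alpha,
                              small_stratum) {
  check_columns(summaries, c("cluster_id", "stratum", "arm", "o", "n"),
                "summaries")
  check_enum(summaries$arm, ARMS, "summaries$arm")
  n_dropped <- sum(summaries$n == 0L)
  s <- summaries[summaries$n > 0L, , drop = FALSE]
  if (use_residuals && !("r" %in% names(s) && "d" %in% names(s)))
    abort_validation("use_residuals = TRUE requires residualized summaries")

  tab <- table(s$stratum, s$arm)
  if (ncol(tab) < 2L || any(tab < 2L)) {
    if (small_stratum == "merge") {
      s <- merge_small_strata(s)
      tab <- table(s$stratum, s$arm)
    }
    if (ncol(tab) < 2L || any(tab < 2L))
      abort_computation(
        "every stratum needs >= 2 clusters per arm (see small_stratum)")
  }

  n_sub <- 0L
  if (scale == "ratio") {
    if (use_residuals) {
      y <- log(s$r)
    } else {
      pt <- continuity_adjust(s$o, s$n)
      n_sub <- attr(pt, "n_substituted")
      y <- log(as.numeric(pt))
    }
  } else {
    y <- if (use_residuals) s$d else s$o / s$n
  }

  ## Stratum arm means and the within-arm scatter pooled ACROSS strata: a
  ## common variance s^2 on sum(c1j + c0j - 2) df stabilizes the
  ## inverse-variance weights when each stratum alone offers few df, which
  ## would otherwise make the test anti-conservative.
  strata <- sort(unique(s$stratum))
  per <- lapply(strata, function(st) {
    i1 <- s$stratum == st & s$arm == "intervention"
    i0 <- s$stratum == st & s$arm == "control"
    c1 <- sum(i1); c0 <- sum(i0)
    m1 <- mean(y[i1]); m0 <- mean(y[i0])
    data.frame(stratum = st, c1 = c1, c0 = c0, effect = m1 - m0,
               ss = sum((y[i1] - m1)^2) + sum((y[i0] - m0)^2),
               cc = 1 / c1 + 1 / c0, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  df <- sum(per$c1 + per$c0 - 2L)
  s2 <- sum(per$ss) / df
  per$v <- s2 * per$cc
  per$ss <- NULL; per$cc <- NULL

  ## weights inversely proportional to the stratum variances; with the
  ## common s^2 they reduce to cluster-count weights and stay defined in
  ## the degenerate zero-scatter case
  inv_cc <- per$c1 * per$c0 / (per$c1 + per$c0)
  per$w <- inv_cc / sum(inv_cc)
  point <- sum(per$w * per$effect)

  degenerate <- s2 == 0
  if (degenerate) {
    ## identical cluster outcomes within every arm: the point estimate is
    ## defined, the uncertainty is not
    warning("zero within-arm variance everywhere; SE and p undefined",
            call. = FALSE)
    se <- 0; tstat <- NA_real_; p <- NA_real_
    ci <- c(point, point)
  } else {
    se <- sqrt(1 / sum(1 / per$v))
    tstat <- point / se
    p <- 2 * stats::pt(-abs(tstat), df)
    ci <- point + c(-1, 1) * stats::qt(1 - alpha / 2, df) * se
  }

  est <- list(
    scale = scale,
    point = if (scale == "ratio") exp(point) else point,
    log_point = if (scale == "ratio") point else NULL,
    se = se,
    ci = if (scale == "ratio") exp(ci) else ci,
    t = tstat, df = df, p = p, alpha = alpha,
    adjusted = use_residuals,
    strata = per,
    n_dropped = n_dropped,
    n_substituted = n_sub,
    degenerate = degenerate
  )
  class(est) <- "crt_effect"
  est
}

#' Stratified risk ratio from cluster-level summaries
#'
#' For each stratum the log risk ratio is the difference between arm means
#' of log cluster risks — equivalently the log ratio of geometric mean
#' risks. Its variance is `v_j = s^2 (1/c1j + 1/c0j)`, where `s^2` is the
#' within-arm sample variance of the log risks pooled across strata on
#' `sum_j (c1j + c0j - 2)` degrees of freedom (a common variance keeps the
#' weights stable when each stratum alone has few clusters). Stratum
#' estimates are averaged with weights inversely proportional to `v_j`;
#' the pooled SE is `sqrt(1 / sum(1/v_j))`, and inference uses a
#' stratified two-tailed t-test on those degrees of freedom.
#'
#' With `use_residuals = TRUE` the same machinery runs on the log ratio
#' residuals from [residualize()], giving the covariate-adjusted estimate.
#'
#' @param summaries Cluster summary table (one row per cluster for the
#'   period under analysis), from [adherence_table()] and optionally
#'   [residualize()].
#' @param use_residuals Analyze ratio residuals instead of raw proportions.
#' @param alpha Two-sided level for the confidence interval.
#' @param small_stratum What to do with a stratum having fewer than 2
#'   clusters in an arm: `"error"` (default; merging silently would change
#'   the estimand) or `"merge"` into the smallest other stratum.
#' @return An object of class `"crt_effect"`.
#' @examples
#' s <- data.frame(cluster_id = 1:4, stratum = "A",
#'                 arm = rep(c("intervention", "control"), each = 2),
#'                 o = c(6, 4, 3, 2), n = 10)
#' stratified_risk_ratio(s)$point # 2
#' @export
stratified_risk_ratio <- function(summaries, use_residuals = FALSE,
                                  alpha = 0.05,
                                  small_stratum = c("error", "merge")) {
  stratified_effect(summaries, "ratio", use_residuals, alpha,
                    match.arg(small_stratum))
}

#' Stratified risk difference from cluster-level summaries
#'
#' Identical machinery to [stratified_risk_ratio()] applied to the
#' untransformed cluster proportions (or, with `use_residuals = TRUE`, the
#' difference residuals `(o - e)/n`), yielding an absolute risk difference
#' with CI and stratified t-test.
#'
#' @inheritParams stratified_risk_ratio
#' @return An object of class `"crt_effect"`.
#' @export
stratified_risk_difference <- function(summaries, use_residuals = FALSE,
                                       alpha = 0.05,
                                       small_stratum = c("error", "merge")) {
  stratified_effect(summaries, "difference", use_residuals, alpha,
                    match.arg(small_stratum))
}

#' @export
print.crt_effect <- function(x, digits = 3, ...) {
  lab <- if (x$scale == "ratio") "Risk ratio" else "Risk difference"
  adj <- if (x$adjusted) " (covariate-adjusted)" else ""
  cat(sprintf("%s%s: %.*f, %d%% CI %.*f to %.*f\n", lab, adj,
              digits, x$point, round(100 * (1 - x$alpha)),
              digits, x$ci[1], digits, x$ci[2]))
  if (is.na(x$t)) {
    cat("  degenerate: zero between-cluster variance, p undefined\n")
  } else {
    cat(sprintf("  stratified t = %.*f on %d df, p = %.4g\n",
                digits, x$t, x$df, x$p))
  }
  invisible(x)
}

#' @export
coef.crt_effect <- function(object, ...) {
  v <- if (object$scale == "ratio") object$log_point else object$point
  names(v) <- if (object$scale == "ratio") "log risk ratio" else
    "risk difference"
  v
}

#' @export
confint.crt_effect <- function(object, parm, level, ...) {
  out <- matrix(object$ci, nrow = 1)
  rownames(out) <- if (object$scale == "ratio") "risk ratio" else
    "risk difference"
  colnames(out) <- paste0(
    format(100 * c(object$alpha / 2, 1 - object$alpha / 2)), " %")
  out
}

#' Fit the individual-level covariate model (treatment arm excluded)
#'
#' Maximum-likelihood logistic regression of the individual adherence
#' indicator on the covariates of interest — never including the treatment
#' arm — fitted by iteratively reweighted least squares. The fit is
#' declared converged when the largest absolute component of the score
#' vector is below `1e-8` within 50 iterations. The fitted probabilities
#' feed [residualize()].
#'
#' @param individuals Data frame of eligible individuals with a logical or
#'   0/1 `adherent` column, a `cluster_id` column, and the covariates.
#' @param covariates Character vector of covariate column names. Default
#'   mirrors the trial's adjustment set: stratum, cluster baseline outcome,
#'   patient sex and age, physician sex and department.
#' @param formula Optional formula overriding `covariates` (response must
#'   be `adherent`).
#' @return Object of class `"crt_covmodel"`: coefficients, fitted
#'   probabilities, per-individual `cluster_id`, convergence metadata.
#' @export
fit_covariate_model <- function(individuals,
                                covariates = c("stratum", "p_baseline",
                                               "patient_sex", "patient_age",
                                               "physician_sex",
                                               "department"),
                                formula = NULL) {
  check_columns(individuals, c("adherent", "cluster_id"), "individuals")
  individuals <- as.data.frame(individuals)
  rownames(individuals) <- NULL   # so model-frame row names index rows
  if (is.null(formula)) {
    check_columns(individuals, covariates, "individuals")
    if (any(c("arm", "period") %in% covariates))
      abort_validation("the covariate model must exclude the treatment arm")
    rhs <- if (length(covariates)) paste(covariates, collapse = " + ")
           else "1"
    formula <- stats::as.formula(paste("adherent ~", rhs))
  }
  if ("arm" %in% all.vars(formula))
    abort_validation("the covariate model must exclude the treatment arm")
  fit <- stats::glm(formula, family = stats::binomial(), data = individuals,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 50))
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    abort_computation(sprintf(
      "rank-deficient design: aliased term(s) %s",
      paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  X <- stats::model.matrix(fit)
  mu <- stats::fitted(fit)
  y <- fit$y
  score <- drop(crossprod(X, y - mu))
  max_score <- max(abs(score))
  converged <- fit$converged && max_score < 1e-8
  ## huge coefficients with a non-converged fit or boundary fitted
  ## probabilities mean the likelihood has no interior maximum
  boundary <- any(mu < 1e-8 | mu > 1 - 1e-8)
  if (any(abs(cf) > 15) && (!converged || boundary)) {
    abort_computation(sprintf(
      "separation detected for term(s): %s",
      paste(names(cf)[abs(cf) > 15], collapse = ", ")))
  }
  structure(list(
    coefficients = cf,
    fitted = mu,
    cluster_id = individuals$cluster_id[as.integer(rownames(X))],
    formula = formula,
    iterations = fit$iter,
    max_score = max_score,
    converged = converged,
    n = length(mu),
    events = sum(y)
  ), class = "crt_covmodel")
}

#' @export
print.crt_covmodel <- function(x, ...) {
  cat(sprintf(
    "Individual-level covariate model (logistic, arm excluded)\n  %s\n",
    deparse(x$formula)))
  cat(sprintf("  n = %d, events = %d, iterations = %d, max|score| = %.2g\n",
              x$n, x$events, x$iterations, x$max_score))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Attach model-predicted counts and residuals to cluster summaries
#'
#' For each cluster, `e` is the sum of the model's fitted probabilities
#' over that cluster's individuals; the ratio residual is `r = o/e` and the
#' difference residual `d = (o - e)/n`. For zero- and full-event clusters
#' the ratio residual uses the same continuity-adjusted count as the
#' log-risk transform (`r = p_tilde * n / e`) so that an intercept-only
#' model reproduces the unadjusted analysis exactly. The intercept score
#' equation guarantees `sum(e) = sum(o)` over the modeled clusters.
#'
#' @param summaries Cluster summary table covering exactly the individuals
#'   the model was fitted on.
#' @param model A `"crt_covmodel"` from [fit_covariate_model()].
#' @return `summaries` with columns `e`, `r`, `d` filled.
#' @export
residualize <- function(summaries, model) {
  stopifnot(inherits(model, "crt_covmodel"))
  check_columns(summaries, c("cluster_id", "o", "n"), "summaries")
  e_by <- tapply(model$fitted, model$cluster_id, sum)
  e <- as.numeric(e_by[match(summaries$cluster_id, names(e_by))])
  if (anyNA(e[summaries$n > 0]))
    abort_validation("model does not cover every non-empty cluster")
  n_model <- tapply(rep(1, length(model$fitted)), model$cluster_id, sum)
  nm <- as.numeric(n_model[match(summaries$cluster_id, names(n_model))])
  if (any(summaries$n > 0 & nm != summaries$n))
    abort_validation(
      "summaries and model cover different individuals per cluster")
  if (any(!is.na(e) & e <= 0))
    abort_computation("non-positive predicted count")
  pt <- continuity_adjust(summaries$o, summaries$n)
  summaries$e <- e
  summaries$r <- as.numeric(pt) * summaries$n / e
  summaries$d <- (summaries$o - e) / summaries$n
  summaries
}

#' Paired t-test of within-arm change in cluster proportions
#'
#' Classical paired t-test on per-cluster (endline minus baseline)
#' adherence proportions within one arm, on `clusters - 1` degrees of
#' freedom. With zero variance of the differences the mean change is
#' returned with the p-value undefined and a flag set.
#'
#' @param summaries Cluster summary table containing both periods.
#' @param arm `"control"` or `"intervention"`.
#' @param alpha Two-sided level for the CI.
#' @return List: `arm`, `mean_diff`, `ci`, `t`, `df`, `p`, `n_clusters`,
#'   `zero_variance`.
#' @export
paired_change_test <- function(summaries, arm = c("control", "intervention"),
                               alpha = 0.05) {
  arm <- match.arg(arm)
  check_columns(summaries, c("cluster_id", "arm", "period", "o", "n"),
                "summaries")
  s <- summaries[summaries$arm == arm & summaries$n > 0, , drop = FALSE]
  base <- s[s$period == "baseline", ]
  end <- s[s$period == "endline", ]
  common <- intersect(base$cluster_id, end$cluster_id)
  if (length(common) < 2L)
    abort_computation("paired test needs >= 2 clusters with both periods")
  pb <- base$o[match(common, base$cluster_id)] /
    base$n[match(common, base$cluster_id)]
  pe <- end$o[match(common, end$cluster_id)] /
    end$n[match(common, end$cluster_id)]
  diff <- pe - pb
  m <- mean(diff)
  if (stats::sd(diff) <= 1e-10) {
    return(list(arm = arm, mean_diff = m, ci = c(m, m), t = NA_real_,
                df = length(diff) - 1L, p = NA_real_,
                n_clusters = length(diff), zero_variance = TRUE))
  }
  tt <- stats::t.test(diff, conf.level = 1 - alpha)
  list(arm = arm, mean_diff = m, ci = as.numeric(tt$conf.int),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_clusters = length(diff), zero_variance = FALSE)
}
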