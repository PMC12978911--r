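# Cluster-level stratified estimation: log transform, geometric-mean risk
# ratio, risk difference, covariate model, residuals, paired tests.

two_by_two_summaries <- function() {
  data.frame(cluster_id = paste0("c", 1:4), stratum = "A",
             arm = rep(c("intervention", "control"), each = 2),
             o = c(6, 4, 3, 2), n = 10, stringsAsFactors = FALSE)
}

test_that("log transform applies the continuity substitution and drops
           empty clusters", {
  s <- data.frame(cluster_id = 1:3, o = c(5, 0, 0), n = c(10, 9, 0))
  expect_warning(out <- log_cluster_risks(s), "dropped")
  expect_equal(out$l[1], log(0.5))
  expect_equal(out$l[2], log(0.5 / 10))   # (0 + 0.5)/(9 + 1)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(attr(out, "n_substituted"), 1L)
})

test_that("the geometric-mean risk ratio matches hand computation", {
  est <- stratified_risk_ratio(two_by_two_summaries())
  expect_equal(est$point, sqrt(0.6 * 0.4) / sqrt(0.3 * 0.2))
  expect_equal(est$point, 2)
  expect_equal(est$df, 2L)
  expect_equal(sum(est$strata$w), 1)
})

test_that("the risk difference matches hand computation", {
  est <- stratified_risk_difference(two_by_two_summaries())
  expect_equal(est$point, 0.5 - 0.25)
  expect_equal(est$df, 2L)
})

test_that("identical arms give a degenerate null estimate", {
  s <- data.frame(cluster_id = 1:4, stratum = "A",
                  arm = rep(c("intervention", "control"), each = 2),
                  o = 5, n = 10)
  expect_warning(rr <- stratified_risk_ratio(s), "zero within-arm")
  expect_equal(rr$point, 1)
  expect_true(is.na(rr$p))
  expect_true(rr$degenerate)
})

test_that("strata sharing a common effect pool to that effect", {
  s <- rbind(two_by_two_summaries(),
             within(two_by_two_summaries(), {
               cluster_id <- paste0("d", 1:4); stratum <- "B"
               o <- c(8, 6, 4, 3); n <- 20  # 0.4/0.3 vs 0.2/0.15 -> RR 2
             }))
  est <- stratified_risk_ratio(s)
  expect_equal(est$point, 2)
  expect_equal(est$df, 4L)
})

test_that("estimates match an independent spreadsheet-style recomputation
           on a 6-cluster two-stratum instance", {
  s <- data.frame(
    cluster_id = paste0("c", 1:10),
    stratum = rep(c("A", "B"), c(4, 6)),
    arm = c("intervention", "intervention", "control", "control",
            "intervention", "intervention", "intervention",
            "control", "control", "control"),
    o = c(12, 9, 7, 5, 20, 14, 17, 9, 12, 8),
    n = c(30, 28, 25, 27, 40, 35, 38, 33, 36, 31)
  )
  # flat recomputation, no shared code with stratified_effect
  l <- log(s$o / s$n)
  hand <- list(eff = c(), ss = 0, df = 0, cc = c())
  for (st in c("A", "B")) {
    y1 <- l[s$stratum == st & s$arm == "intervention"]
    y0 <- l[s$stratum == st & s$arm == "control"]
    hand$eff <- c(hand$eff, mean(y1) - mean(y0))
    hand$ss <- hand$ss + sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)
    hand$df <- hand$df + length(y1) + length(y0) - 2
    hand$cc <- c(hand$cc, 1 / length(y1) + 1 / length(y0))
  }
  v <- (hand$ss / hand$df) * hand$cc
  w <- (1 / v) / sum(1 / v)
  logrr <- sum(w * hand$eff)
  se <- sqrt(1 / sum(1 / v))

  est <- stratified_risk_ratio(s)
  expect_equal(log(est$point), logrr)
  expect_equal(est$se, se)
  expect_equal(est$t, logrr / se)
  expect_equal(est$df, hand$df)
  expect_equal(est$ci,
               exp(logrr + c(-1, 1) * qt(0.975, hand$df) * se))
})

test_that("swapping arm labels inverts the ratio and negates the
           difference with identical p-values", {
  set.seed(31)
  for (rep in 1:5) {
    s <- data.frame(
      cluster_id = 1:12, stratum = rep(c("A", "B"), each = 6),
      arm = rep(rep(c("intervention", "control"), each = 3), 2),
      n = 50, o = rbinom(12, 50, 0.4)
    )
    s$o <- pmax(s$o, 1)  # keep away from the continuity edge
    sw <- s
    sw$arm <- ifelse(s$arm == "control", "intervention", "control")
    rr <- stratified_risk_ratio(s); rrs <- stratified_risk_ratio(sw)
    expect_equal(rr$point * rrs$point, 1)
    expect_equal(rr$p, rrs$p)
    rd <- stratified_risk_difference(s)
    rds <- stratified_risk_difference(sw)
    expect_equal(rd$point, -rds$point)
    expect_equal(abs(rd$t), abs(rds$t))
  }
})

test_that("under-filled strata error by default and can be merged on
           request", {
  s <- rbind(two_by_two_summaries(),
             data.frame(cluster_id = "e1", stratum = "C",
                        arm = "intervention", o = 3, n = 10))
  expect_error(stratified_risk_ratio(s), "2 clusters",
               class = "crtadhere_computation_error")
  est <- stratified_risk_ratio(s, small_stratum = "merge")
  expect_equal(nrow(est$strata), 1L)
})

test_that("intercept-only logistic fit returns the sample proportion", {
  ind <- data.frame(adherent = rep(c(TRUE, FALSE), c(12, 18)),
                    cluster_id = rep(c("a", "b"), 15))
  m <- fit_covariate_model(ind, covariates = character(0))
  expect_equal(unique(round(m$fitted, 12)), 0.4)
  expect_true(m$converged)
  expect_lt(m$max_score, 1e-8)
})

test_that("a single binary covariate recovers the 2x2 odds ratio", {
  # nonadherent/adherent x age<35/>=35 from the univariate screen
  ind <- data.frame(
    adherent = rep(c(FALSE, TRUE, FALSE, TRUE), c(194, 122, 540, 668)),
    young = rep(c(TRUE, TRUE, FALSE, FALSE), c(194, 122, 540, 668)),
    cluster_id = "h"
  )
  m <- fit_covariate_model(ind, covariates = "young")
  or_young_nonadherence <- exp(-unname(m$coefficients["youngTRUE"]))
  expect_equal(or_young_nonadherence,
               crude_odds_ratio(194, 122, 540, 668)$or,
               tolerance = 1e-9)
})

test_that("a balanced null covariate gets a zero slope", {
  ind <- data.frame(
    adherent = rep(c(TRUE, FALSE, TRUE, FALSE), each = 25),
    x = rep(c(0, 0, 1, 1), each = 25),
    cluster_id = "h"
  )
  m <- fit_covariate_model(ind, covariates = "x")
  expect_equal(unname(m$coefficients["x"]), 0, tolerance = 1e-10)
})

test_that("the covariate model refuses the treatment arm and flags
           separation and aliasing", {
  ind <- data.frame(adherent = c(TRUE, FALSE), cluster_id = "h",
                    arm = c("a", "b"))
  expect_error(fit_covariate_model(ind, covariates = "arm"),
               "exclude", class = "crtadhere_validation_error")

  sep <- data.frame(adherent = rep(c(TRUE, FALSE), each = 20),
                    z = rep(c(1, 0), each = 20), cluster_id = "h")
  expect_error(suppressWarnings(fit_covariate_model(sep, covariates = "z")),
               "separation", class = "crtadhere_computation_error")

  ali <- data.frame(adherent = rep(c(TRUE, FALSE), 10),
                    a = rep(c(1, 0), 10), b = rep(c(0, 1), 10),
                    cluster_id = "h")
  expect_error(
    suppressWarnings(fit_covariate_model(ali, covariates = c("a", "b"))),
    "aliased", class = "crtadhere_computation_error")
})

test_that("residualizing with an intercept-only model gives r = p/pbar and
           conserves predicted counts", {
  s <- two_by_two_summaries()
  ind <- data.frame(
    adherent = unlist(mapply(function(o, n) rep(c(TRUE, FALSE), c(o, n - o)),
                             s$o, s$n, SIMPLIFY = FALSE)),
    cluster_id = rep(s$cluster_id, s$n)
  )
  m <- fit_covariate_model(ind, covariates = character(0))
  rs <- residualize(s, m)
  pbar <- sum(s$o) / sum(s$n)
  expect_equal(rs$r, (s$o / s$n) / pbar)
  expect_equal(rs$d, s$o / s$n - pbar)
  expect_equal(sum(rs$e), sum(s$o))  # intercept score equation
})

test_that("residuals are invariant to duplicating every individual", {
  s <- two_by_two_summaries()
  mk <- function(times) {
    ind <- data.frame(
      adherent = unlist(mapply(function(o, n)
        rep(c(TRUE, FALSE), c(o, n - o)), s$o, s$n, SIMPLIFY = FALSE)),
      cluster_id = rep(s$cluster_id, s$n)
    )
    ind[rep(seq_len(nrow(ind)), times), ]
  }
  s2 <- s; s2$o <- 2 * s$o; s2$n <- 2 * s$n
  r1 <- residualize(s, fit_covariate_model(mk(1), covariates = character(0)))
  r2 <- residualize(s2, fit_covariate_model(mk(2), covariates = character(0)))
  expect_equal(r1$r, r2$r)
})

test_that("paired change tests match hand-computed cases", {
  mk <- function(pb, pe) {
    k <- length(pb)
    data.frame(cluster_id = rep(seq_len(k), 2),
               arm = "control",
               period = rep(c("baseline", "endline"), each = k),
               o = round(c(pb, pe) * 100), n = 100)
  }
  sym <- paired_change_test(mk(c(0.4, 0.6), c(0.5, 0.5)), "control")
  expect_equal(sym$mean_diff, 0)
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  const <- paired_change_test(mk(c(0.2, 0.3, 0.4), c(0.4, 0.5, 0.6)),
                              "control")
  expect_true(const$zero_variance)
  expect_equal(const$mean_diff, 0.2)
  expect_true(is.na(const$p))

  two <- paired_change_test(mk(c(0.3, 0.3), c(0.4, 0.6)), "control")
  expect_equal(two$mean_diff, 0.2)
  expect_equal(two$t, 2)      # se = 0.1 with s = 0.1 * sqrt(2)
  expect_equal(two$df, 1)
})
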