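## Design of cluster-randomized trials with binary outcomes: sample size
## from a between-cluster coefficient of variation (the unmatched
## cluster-level formula of the Hayes–Bennett tradition), its power
## inversion, and stratified 1:1 randomization with allocation concealment.

#' Specify a cluster-randomized design
#'
#' @param pi0,pi1 True outcome proportions in the control and intervention
#'   arms, both in (0, 1).
#' @param n_per_cluster Expected individuals per cluster before data loss.
#' @param k Between-cluster coefficient of variation of the true cluster
#'   proportions (SD divided by mean), `>= 0`.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param loss_fraction Anticipated fraction of individual records unusable
#'   (for example illegible prescriptions), in \[0, 1); applied to
#'   `n_per_cluster`, not to the cluster count.
#' @param n_strata Number of randomization strata.
#' @return An object of class `"design_spec"`.
#' @export
design_spec <- function(pi0, pi1, n_per_cluster, k = 0, alpha = 0.05,
                        power = 0.9, loss_fraction = 0, n_strata = 1L) {
  stopifnot(length(pi0) == 1L, length(pi1) == 1L)
  if (!(pi0 > 0 && pi0 < 1 && pi1 > 0 && pi1 < 1))
    abort_validation("pi0 and pi1 must lie in (0, 1)")
  if (!(alpha > 0 && alpha < 1 && power > 0 && power < 1))
    abort_validation("alpha and power must lie in (0, 1)")
  if (k < 0) abort_validation("k must be >= 0")
  if (loss_fraction < 0 || loss_fraction >= 1)
    abort_validation("loss_fraction must lie in [0, 1)")
  if (n_per_cluster * (1 - loss_fraction) <= 0)
    abort_validation("effective cluster size must be positive")
  if (n_strata < 1) abort_validation("n_strata must be >= 1")
  structure(list(
    pi0 = pi0, pi1 = pi1, n_per_cluster = n_per_cluster, k = k,
    alpha = alpha, power = power, loss_fraction = loss_fraction,
    n_strata = as.integer(n_strata)
  ), class = "design_spec")
}

## Common variance kernel of the formula: pi0*q0/n + pi1*q1/n + k^2*(pi0^2
## + pi1^2), with n the effective individuals per cluster.
design_varsum <- function(spec) {
  n <- spec$n_per_cluster * (1 - spec$loss_fraction)
  with(spec, pi0 * (1 - pi0) / n + pi1 * (1 - pi1) / n +
         k^2 * (pi0^2 + pi1^2))
}

#' Clusters per arm required for a target power
#'
#' Unmatched cluster-level sample-size formula for comparing two
#' proportions with between-cluster variability expressed as a coefficient
#' of variation `k`:
#' \deqn{c = 1 + (z_{\alpha/2} + z_\beta)^2
#'   \frac{\pi_0(1-\pi_0)/n + \pi_1(1-\pi_1)/n + k^2(\pi_0^2+\pi_1^2)}
#'        {(\pi_0 - \pi_1)^2}}
#' with `n` the effective individuals per cluster after data loss. The
#' leading "+1" compensates for the degrees of freedom lost to estimating
#' between-cluster variation with few clusters. Standard-normal quantiles
#' are used throughout, per convention.
#'
#' With `per_stratum = TRUE` the returned count is an allocation target for
#' each stratum (total = 2 c x strata); otherwise a single overall size
#' (total = 2 c).
#'
#' @param spec A [design_spec()].
#' @param per_stratum Size each stratum separately? Default `FALSE`.
#' @return Object of class `"design_result"`: `clusters_per_arm` (integer,
#'   at least 2), `c_exact` (unrounded formula value), `total_clusters`,
#'   `achieved_power` at the returned size, and `effective_n`.
#' @examples
#' spec <- design_spec(0.378, 0.478, n_per_cluster = 100, k = 0.1,
#'                     loss_fraction = 0.1)
#' clusters_required(spec)$clusters_per_arm # 11
#' @export
clusters_required <- function(spec, per_stratum = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$pi0 == spec$pi1)
    abort_validation("pi0 = pi1: no detectable effect to size for")
  zq <- stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
  c_exact <- 1 + zq^2 * design_varsum(spec) / (spec$pi0 - spec$pi1)^2
  c_int <- max(2L, as.integer(ceiling(c_exact - 1e-12)))
  total <- if (per_stratum) 2L * c_int * spec$n_strata else 2L * c_int
  structure(list(
    clusters_per_arm = c_int,
    c_exact = c_exact,
    total_clusters = total,
    per_stratum = per_stratum,
    achieved_power = power_given_clusters(spec, c_int),
    effective_n = spec$n_per_cluster * (1 - spec$loss_fraction),
    spec = spec
  ), class = "design_result")
}

#' Power achieved by a given number of clusters per arm
#'
#' Inverts the sample-size identity for \eqn{z_\beta}:
#' \deqn{z_\beta = \sqrt{(c - 1)(\pi_0-\pi_1)^2 / V} - z_{\alpha/2}}
#' where V is the variance kernel of [clusters_required()], and returns
#' \eqn{\Phi(z_\beta)}. Round-trips with [clusters_required()].
#'
#' @inheritParams clusters_required
#' @param clusters_per_arm Integer, at least 2.
#' @return Power as a probability.
#' @export
power_given_clusters <- function(spec, clusters_per_arm) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$pi0 == spec$pi1)
    abort_validation("pi0 = pi1: no detectable effect")
  if (clusters_per_arm < 2)
    abort_validation("clusters_per_arm must be >= 2")
  zb <- sqrt((clusters_per_arm - 1) * (spec$pi0 - spec$pi1)^2 /
               design_varsum(spec)) - stats::qnorm(1 - spec$alpha / 2)
  stats::pnorm(zb)
}

#' @export
print.design_result <- function(x, ...) {
  cat("Cluster-randomized design (coefficient-of-variation formula)\n")
  cat(sprintf("  pi0 = %.3f, pi1 = %.3f, k = %.3f, alpha = %.3f\n",
              x$spec$pi0, x$spec$pi1, x$spec$k, x$spec$alpha))
  cat(sprintf("  effective individuals/cluster: %.1f\n", x$effective_n))
  cat(sprintf("  clusters per arm: %d (formula value %.2f)%s\n",
              x$clusters_per_arm, x$c_exact,
              if (x$per_stratum) " per stratum" else ""))
  cat(sprintf("  total clusters: %d\n", x$total_clusters))
  cat(sprintf("  achieved power: %.3f (target %.2f)\n",
              x$achieved_power, x$spec$power))
  invisible(x)
}

#' Stratified 1:1 randomization with concealment
#'
#' Assigns half of each stratum's clusters to each arm with a seeded
#' computer-generated sequence. Generation and disclosure are separate
#' steps: the returned object prints only stratum counts; the assignment
#' table is released by [reveal_allocation()].
#'
#' @param clusters Data frame with columns `cluster_id` and `stratum`, or a
#'   named list of cluster-id vectors (names = strata).
#' @param seed Integer seed making the sequence reproducible.
#' @param odd_rule How to split a stratum with an odd number of clusters:
#'   `"error"` (default) or `"extra_to_control"`.
#' @return Object of class `"crt_allocation"`.
#' @export
allocate_clusters <- function(clusters, seed,
                              odd_rule = c("error", "extra_to_control")) {
  odd_rule <- match.arg(odd_rule)
  if (is.list(clusters) && !is.data.frame(clusters)) {
    clusters <- data.frame(
      cluster_id = unlist(clusters, use.names = FALSE),
      stratum = rep(names(clusters), lengths(clusters)),
      stringsAsFactors = FALSE
    )
  }
  check_columns(clusters, c("cluster_id", "stratum"), "clusters")
  if (anyDuplicated(clusters$cluster_id))
    abort_validation("duplicate cluster_id in roster")
  strata <- unique(clusters$stratum)
  if (any(!nzchar(strata)) || any(is.na(strata)) || nrow(clusters) == 0)
    abort_validation("empty stratum in roster")
  assign_one <- function(ids) {
    m <- length(ids)
    if (m == 0) abort_validation("empty stratum in roster")
    if (m %% 2 == 1 && odd_rule == "error")
      abort_validation(sprintf(
        "stratum with odd cluster count (%d); set odd_rule", m))
    n_int <- m %/% 2          # remainder goes to control
    shuffled <- ids[sample.int(m)]
    data.frame(
      cluster_id = shuffled,
      arm = rep(c("intervention", "control"), c(n_int, m - n_int)),
      stringsAsFactors = FALSE
    )
  }
  assignments <- with_seed(seed, {
    out <- lapply(strata, function(s)
      cbind(stratum = s,
            assign_one(clusters$cluster_id[clusters$stratum == s])))
    do.call(rbind, out)
  })
  structure(list(assignments = assignments, seed = seed,
                 odd_rule = odd_rule),
            class = "crt_allocation")
}

#' @export
print.crt_allocation <- function(x, ...) {
  cat("Sealed stratified allocation (use reveal_allocation() to disclose)\n")
  tab <- table(x$assignments$stratum, x$assignments$arm)
  print(tab)
  invisible(x)
}

#' Disclose a sealed allocation
#'
#' @param allocation A `"crt_allocation"` from [allocate_clusters()].
#' @return Data frame with `stratum`, `cluster_id`, `arm`.
#' @export
reveal_allocation <- function(allocation) {
  stopifnot(inherits(allocation, "crt_allocation"))
  allocation$assignments
}
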