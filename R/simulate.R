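## Synthetic-trial generator. Emulates the statistical structure the
## cluster-level analysis assumes: province strata with heterogeneous
## baseline adherence, multiplicative gamma between-cluster variation
## parameterized by a coefficient of variation of true proportions, an
## intervention effect on the risk-ratio scale, physician covariate effects
## on the odds scale, ineligible-record contamination matching the five
## exclusion criteria, and two periods per cluster. Every latent quantity
## is stored in a truth record for parameter-recovery studies.

## Physician covariate sampling frequencies, patterned on a typical
## multi-department STD-care physician roster.
PHYSICIAN_FREQS <- list(
  sex = c(male = 0.46, female = 0.54),
  age_group = c(under_35 = 0.37, `35_and_over` = 0.63),
  degree = c(postgrad_and_above = 0.37, undergrad_and_below = 0.63),
  department = c(dermatology = 0.24, obgyn = 0.28, urology = 0.24,
                 andrology = 0.04, std = 0.20),
  service_years_band = c(le5 = 0.26, `6_10` = 0.21, ge11 = 0.53),
  title = c(chief = 0.12, associate_chief = 0.28, in_charge = 0.39,
            resident = 0.21),
  cases_last_3mo_band = c(lt5 = 0.98, ge5 = 0.02),
  prior_training = c(`TRUE` = 0.60, `FALSE` = 0.40)
)

#' Configure a synthetic cluster-randomized adherence trial
#'
#' @param strata Data frame with columns `name`, `baseline_p` (control-arm
#'   true adherence proportion, in (0,1)) and optionally `drift`
#'   (multiplicative endline shift of the control arm; default 0).
#' @param clusters_per_arm_per_stratum Clusters randomized to each arm in
#'   each stratum.
#' @param prescriptions_per_cluster Mean of the Poisson count of screened
#'   prescriptions per cluster and period.
#' @param true_rr Intervention/control risk ratio applied to cluster
#'   geometric-mean risks at endline.
#' @param k Between-cluster coefficient of variation of the true cluster
#'   proportions.
#' @param physician_effects Named numeric vector of odds ratios on
#'   nonadherence, named `"covariate:level"` (for example
#'   `c("age_group:under_35" = 2.6)`). Effects are centered on the
#'   physician sampling frequencies so the cluster-level risk-scale
#'   estimand remains `true_rr`.
#' @param ineligible_fractions Named numeric vector of contamination
#'   probabilities per exclusion reason (names from
#'   `under_18, pregnant_or_lactating, no_ceftriaxone,
#'   other_infection_antibiotics, complicated`).
#' @param loss_fraction Fraction of records later made illegible by
#'   [corrupt_records()]; stored for pipeline use, not applied here.
#' @param physicians_per_cluster Physicians enrolled per cluster.
#' @param seed Default seed used when the generator is called without one.
#' @return Object of class `"sim_config"`.
#' @export
trial_config <- function(strata,
                         clusters_per_arm_per_stratum = 9L,
                         prescriptions_per_cluster = 100,
                         true_rr = 1,
                         k = 0.1,
                         physician_effects = NULL,
                         ineligible_fractions = NULL,
                         loss_fraction = 0,
                         physicians_per_cluster = 10L,
                         seed = NULL) {
  check_columns(strata, c("name", "baseline_p"), "strata")
  if (!("drift" %in% names(strata))) strata$drift <- 0
  if (any(strata$baseline_p <= 0 | strata$baseline_p >= 1))
    abort_validation("baseline_p must lie in (0, 1)")
  if (true_rr <= 0) abort_validation("true_rr must be positive")
  if (k < 0) abort_validation("k must be >= 0")
  inel <- rep(0, length(EXCLUSION_REASONS))
  names(inel) <- EXCLUSION_REASONS
  if (!is.null(ineligible_fractions)) {
    bad <- setdiff(names(ineligible_fractions), EXCLUSION_REASONS)
    if (length(bad))
      abort_validation(sprintf("unknown exclusion reason(s): %s",
                               paste(bad, collapse = ", ")))
    inel[names(ineligible_fractions)] <- ineligible_fractions
  }
  if (any(inel < 0) || sum(inel) >= 1)
    abort_validation("ineligible_fractions must be >= 0 and sum to < 1")
  if (loss_fraction < 0 || loss_fraction >= 1)
    abort_validation("loss_fraction must lie in [0, 1)")
  ## expected endline intervention proportion must stay inside (0, 1)
  exp_p <- max(strata$baseline_p * (1 + strata$drift)) * true_rr
  if (exp_p >= 1)
    abort_validation(sprintf(
      "config implies expected proportion %.2f >= 1", exp_p))
  structure(list(
    strata = strata,
    clusters_per_arm_per_stratum = as.integer(clusters_per_arm_per_stratum),
    prescriptions_per_cluster = prescriptions_per_cluster,
    true_rr = true_rr, k = k,
    physician_effects = physician_effects,
    ineligible_fractions = inel,
    loss_fraction = loss_fraction,
    physicians_per_cluster = as.integer(physicians_per_cluster),
    seed = seed
  ), class = "sim_config")
}

#' Named preset trial configurations
#'
#' `"four_province_trial"`: four province strata with baseline adherence
#' 4%, 49%, 72% and 77%, 9 clusters per arm per stratum (72 clusters), ~100
#' prescriptions per cluster, k = 0.1, generative risk ratio 1.12 and
#' ineligible-record contamination of roughly half of screened records.
#' `"yunnan_low_baseline"`: a single low-baseline stratum (4%) where the
#' intervention lifts adherence to about 19%. `"null_trial"`: two strata,
#' k = 0.25, 9 clusters per arm per stratum, no contamination, risk ratio 1
#' — the null generator used for type-I-error studies.
#'
#' @param name Preset name.
#' @return A [trial_config()] object.
#' @export
trial_preset <- function(name = c("four_province_trial",
                                  "yunnan_low_baseline", "null_trial")) {
  name <- match.arg(name)
  switch(name,
    four_province_trial = trial_config(
      strata = data.frame(
        name = c("Yunnan", "Zhejiang", "Guangdong", "Hainan"),
        baseline_p = c(0.04, 0.49, 0.72, 0.77)
      ),
      clusters_per_arm_per_stratum = 9L,
      prescriptions_per_cluster = 100,
      true_rr = 1.12, k = 0.1,
      physician_effects = c("age_group:under_35" = 2.0,
                            "degree:undergrad_and_below" = 2.0,
                            "department:dermatology" = 3.0),
      ineligible_fractions = c(under_18 = 0.03,
                               pregnant_or_lactating = 0.03,
                               no_ceftriaxone = 0.30,
                               other_infection_antibiotics = 0.08,
                               complicated = 0.04),
      loss_fraction = 0.10
    ),
    yunnan_low_baseline = trial_config(
      strata = data.frame(name = "Yunnan", baseline_p = 0.04),
      clusters_per_arm_per_stratum = 9L,
      prescriptions_per_cluster = 100,
      true_rr = 4.75, k = 0.1
    ),
    null_trial = trial_config(
      strata = data.frame(name = c("A", "B"), baseline_p = c(0.30, 0.55)),
      clusters_per_arm_per_stratum = 9L,
      prescriptions_per_cluster = 100,
      true_rr = 1, k = 0.25
    )
  )
}

## Latent cluster table: per cluster, the gamma mixing factor and the true
## proportions per period. eps guards the (0,1) truncation.
latent_clusters <- function(config, eps = 0.005) {
  st <- config$strata
  cpa <- config$clusters_per_arm_per_stratum
  grid <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    data.frame(
      stratum = st$name[i],
      arm = rep(c("control", "intervention"), each = cpa),
      idx = c(seq_len(cpa), seq_len(cpa)),
      baseline_p = st$baseline_p[i],
      drift = st$drift[i],
      stringsAsFactors = FALSE
    )
  }))
  grid$cluster_id <- sprintf("%s_%s_%02d", grid$stratum,
                             substr(grid$arm, 1, 3), grid$idx)
  k <- config$k
  grid$G <- if (k > 0) stats::rgamma(nrow(grid), shape = 1 / k^2,
                                     rate = 1 / k^2) else rep(1, nrow(grid))
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
  raw_base <- grid$baseline_p * grid$G
  raw_end <- grid$baseline_p * grid$G * (1 + grid$drift) *
    ifelse(grid$arm == "intervention", config$true_rr, 1)
  grid$p_true_baseline <- clamp(raw_base)
  grid$p_true_endline <- clamp(raw_end)
  grid$truncated <- raw_base != grid$p_true_baseline |
    raw_end != grid$p_true_endline
  grid
}

sample_level <- function(freqs, n) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

## Centered per-physician log-odds offsets on nonadherence, converted to
## adherence scale (negated), so the marginal cluster risk stays on target.
physician_offsets <- function(physicians, effects) {
  if (is.null(effects) || !length(effects))
    return(rep(0, nrow(physicians)))
  off <- rep(0, nrow(physicians))
  for (nm in names(effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !(parts[1] %in% names(PHYSICIAN_FREQS)))
      abort_validation(sprintf(
        "physician effect name '%s' is not 'covariate:level'", nm))
    freqs <- PHYSICIAN_FREQS[[parts[1]]]
    if (!(parts[2] %in% names(freqs)))
      abort_validation(sprintf("unknown level '%s' for %s",
                               parts[2], parts[1]))
    lor <- log(effects[[nm]])
    centered <- (physicians[[parts[1]]] == parts[2]) * lor -
      freqs[[parts[2]]] * lor
    off <- off + centered
  }
  -off   # effects are on NONadherence odds; adherence offset is negated
}

#' Generate a complete synthetic trial
#'
#' Draws latent cluster proportions `p = clamp(p_stratum * G * RR^(arm x
#' endline))` with `G` i.i.d. gamma (mean 1, CV `k`), enrolls physicians
#' with covariates drawn from roster-like frequencies, and emits one
#' prescription table and one drug-order table per the records-module
#' schema, plus a truth record of every latent quantity. Ineligible
#' records are injected with the attributes that trigger each configured
#' exclusion reason. Deterministic given `seed`.
#'
#' @param config A [trial_config()] or preset name.
#' @param seed Integer seed (falls back to `config$seed`).
#' @return List of class `"sim_trial"`: `prescriptions`, `drug_orders`,
#'   `physicians`, `truth`.
#' @export
generate_trial <- function(config, seed = NULL) {
  if (is.character(config)) config <- trial_preset(config)
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) abort_validation("a seed is required")
  with_seed(seed, generate_trial_impl(config, seed))
}

generate_trial_impl <- function(config, seed) {
  clusters <- latent_clusters(config)
  nc <- nrow(clusters)

  ## physicians
  npc <- config$physicians_per_cluster
  ph <- data.frame(
    physician_id = sprintf("ph_%s_%02d",
                           rep(clusters$cluster_id, each = npc),
                           rep(seq_len(npc), nc)),
    cluster_id = rep(clusters$cluster_id, each = npc),
    stringsAsFactors = FALSE
  )
  for (cov in names(PHYSICIAN_FREQS)) {
    ph[[cov]] <- sample_level(PHYSICIAN_FREQS[[cov]], nrow(ph))
  }
  ph$prior_training <- ph$prior_training == "TRUE"
  ph$offset <- physician_offsets(ph, config$physician_effects)

  ## prescriptions: one block per (cluster, period)
  cell <- rbind(
    data.frame(ci = seq_len(nc), period = "baseline",
               p = clusters$p_true_baseline, stringsAsFactors = FALSE),
    data.frame(ci = seq_len(nc), period = "endline",
               p = clusters$p_true_endline, stringsAsFactors = FALSE)
  )
  counts <- stats::rpois(nrow(cell), config$prescriptions_per_cluster)
  ci <- rep(cell$ci, counts)
  n_rec <- length(ci)
  rec <- data.frame(
    record_id = sprintf("rx_%06d", seq_len(n_rec)),
    cluster_id = clusters$cluster_id[ci],
    stratum = clusters$stratum[ci],
    arm = clusters$arm[ci],
    period = rep(cell$period, counts),
    stringsAsFactors = FALSE
  )
  p_cluster <- rep(cell$p, counts)

  ## eligibility contamination: categorical draw per record
  inel <- config$ineligible_fractions
  cat_probs <- c(inel, eligible = 1 - sum(inel))
  category <- sample(names(cat_probs), n_rec, replace = TRUE,
                     prob = cat_probs)

  ## patient attributes (defaults describe an eligible adult male/female
  ## uncomplicated case; contamination overrides below)
  rec$patient_age <- sample(18:60, n_rec, replace = TRUE)
  rec$patient_sex <- sample(c("male", "female"), n_rec, replace = TRUE,
                            prob = c(0.75, 0.25))
  rec$pregnant_or_lactating <- FALSE
  rec$diagnosis <- "uncomplicated_gonorrhea"

  is_u18 <- category == "under_18"
  rec$patient_age[is_u18] <- sample(14:17, sum(is_u18), replace = TRUE)
  is_preg <- category == "pregnant_or_lactating"
  rec$patient_sex[is_preg] <- "female"
  rec$pregnant_or_lactating[is_preg] <- TRUE
  rec$diagnosis[category == "complicated"] <- "complicated_gonorrhea"

  ## physician assignment within cluster
  pick <- sample.int(npc, n_rec, replace = TRUE)
  rec$physician_id <- sprintf("ph_%s_%02d", rec$cluster_id, pick)
  ph_offset <- ph$offset[match(rec$physician_id, ph$physician_id)]

  ## adherence for records that will be eligible
  eligible <- category == "eligible"
  p_indiv <- stats::plogis(stats::qlogis(p_cluster) + ph_offset)
  adherent <- eligible & stats::runif(n_rec) < p_indiv

  orders <- build_drug_orders(rec$record_id, category, adherent)

  truth <- list(
    config = config, seed = seed,
    clusters = clusters,
    true_rr = config$true_rr,
    physician_effects = config$physician_effects,
    physician_log_or_nonadherence =
      if (is.null(config$physician_effects)) NULL
      else log(config$physician_effects),
    n_truncated = sum(clusters$truncated),
    category = stats::setNames(category, rec$record_id),
    adherent = stats::setNames(adherent, rec$record_id)
  )
  ph$offset <- NULL
  structure(list(prescriptions = rec, drug_orders = orders,
                 physicians = ph, truth = truth),
            class = "sim_trial")
}

## Drug orders implied by each record's contamination category and, for
## eligible records, its adherence. Nonadherent regimens deviate in dose,
## schedule, route, or carry an extra antibiotic.
build_drug_orders <- function(record_id, category, adherent) {
  n <- length(record_id)
  drug <- rep("ceftriaxone", n)
  dose <- rep(1000, n)
  route <- rep("IM", n)
  n_adm <- rep(1L, n)
  indication <- rep("gonorrhea", n)

  no_cef <- category == "no_ceftriaxone"
  drug[no_cef] <- "azithromycin"
  dose[no_cef] <- 2000
  route[no_cef] <- "oral"

  dev_pool <- which(category == "eligible" & !adherent)
  if (length(dev_pool)) {
    kind <- sample(5L, length(dev_pool), replace = TRUE)
    dose[dev_pool[kind == 1L]] <- 2000
    n_adm[dev_pool[kind == 2L]] <- 3L
    route[dev_pool[kind == 3L]] <- "IV"
    dose[dev_pool[kind == 4L]] <- 500
    ## kind 5: guideline ceftriaxone plus an extra gonorrhea-indicated
    ## antibiotic (the flagged-ambiguous deviation)
  } else {
    kind <- integer(0)
  }

  main <- data.frame(
    record_id = record_id, drug_name = drug, dose_mg = dose, route = route,
    n_administrations = n_adm, indication = indication,
    stringsAsFactors = FALSE
  )
  extra <- list()
  oth <- which(category == "other_infection_antibiotics")
  if (length(oth)) {
    extra$other <- data.frame(
      record_id = record_id[oth], drug_name = "doxycycline", dose_mg = 100,
      route = "oral", n_administrations = 14L,
      indication = "other_infection", stringsAsFactors = FALSE
    )
  }
  dual <- dev_pool[kind == 5L]
  if (length(dual)) {
    extra$dual <- data.frame(
      record_id = record_id[dual], drug_name = "azithromycin",
      dose_mg = 1000, route = "oral", n_administrations = 1L,
      indication = "gonorrhea", stringsAsFactors = FALSE
    )
  }
  out <- rbind(main, do.call(rbind, unname(extra)))
  out[order(out$record_id), , drop = FALSE]
}

#' Simulate cluster-level summaries directly
#'
#' Fast path through the same latent law as [generate_trial()]: draws the
#' latent cluster proportions and then binomial adherent counts `o ~
#' Bin(n, p)` with `n ~ Poisson(prescriptions_per_cluster)`, skipping
#' record-level attributes. Used for Monte-Carlo studies of the
#' cluster-level estimator, where only (o, n) per cluster matter.
#'
#' @inheritParams generate_trial
#' @return List: `summaries` (both periods) and `clusters` (latent table).
#' @export
simulate_summaries <- function(config, seed = NULL) {
  if (is.character(config)) config <- trial_preset(config)
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) abort_validation("a seed is required")
  with_seed(seed, {
    clusters <- latent_clusters(config)
    nc <- nrow(clusters)
    mk <- function(period, p) {
      n <- stats::rpois(nc, config$prescriptions_per_cluster)
      o <- stats::rbinom(nc, n, p)
      data.frame(cluster_id = clusters$cluster_id,
                 stratum = clusters$stratum, arm = clusters$arm,
                 period = period, o = o, n = n,
                 p = ifelse(n > 0, o / n, NA_real_), empty = n == 0L,
                 stringsAsFactors = FALSE)
    }
    list(summaries = rbind(mk("baseline", clusters$p_true_baseline),
                           mk("endline", clusters$p_true_endline)),
         clusters = clusters)
  })
}

#' Blank fields to emulate illegible records
#'
#' Picks `round(loss_fraction * n)` prescriptions and blanks one required
#' field in each, so they fail records-module validation and are counted in
#' the flow report as invalid.
#'
#' @param prescriptions Prescription table.
#' @param loss_fraction Fraction of records to corrupt, in \[0, 1).
#' @param seed Integer seed.
#' @return The table with fields set to `NA` in the chosen records.
#' @export
corrupt_records <- function(prescriptions, loss_fraction, seed) {
  if (loss_fraction < 0 || loss_fraction >= 1)
    abort_validation("loss_fraction must lie in [0, 1)")
  m <- round(loss_fraction * nrow(prescriptions))
  if (m == 0) return(prescriptions)
  with_seed(seed, {
    rows <- sample.int(nrow(prescriptions), m)
    field <- sample(c("patient_age", "patient_sex", "diagnosis"), m,
                    replace = TRUE)
    for (f in unique(field)) {
      prescriptions[[f]][rows[field == f]] <- NA
    }
    prescriptions
  })
}
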