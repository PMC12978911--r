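## End-to-end pipeline and report rendering: simulate (or load) -> filter
## -> analyze -> report, with a CONSORT-style text flow diagram, JSON and
## text report writers, and a provenance block echoing config and seed.

#' Render a CONSORT-style text flow diagram
#'
#' One panel per (arm, period) showing screened, invalid, per-reason
#' excluded and eligible counts. The panel numbers must conserve (screened
#' = invalid + eligible + sum of exclusions); violation is an internal
#' consistency error.
#'
#' @param flow Flow-count table from [flow_counts()].
#' @return A single string (the diagram), invisibly printed with `cat()`
#'   by the caller.
#' @export
render_flow_diagram <- function(flow) {
  excl_cols <- paste0("excluded_", EXCLUSION_REASONS)
  check_columns(flow, c("arm", "period", "screened", "invalid", excl_cols,
                        "eligible"), "flow")
  tot_excl <- rowSums(flow[, excl_cols, drop = FALSE])
  if (any(flow$screened != flow$invalid + flow$eligible + tot_excl))
    abort_computation("flow counts do not conserve: screened != parts")
  panel <- function(i) {
    f <- flow[i, ]
    lines <- c(
      sprintf("[%s / %s]", f$arm, f$period),
      sprintf("  screened: %d", f$screened),
      if (f$screened == 0) "  (no prescriptions)" else c(
        sprintf("  invalid (unreadable): %d", f$invalid),
        sprintf("  excluded: %d", tot_excl[i]),
        sprintf("    %-28s %d", paste0(EXCLUSION_REASONS, ":"),
                unlist(f[excl_cols])),
        sprintf("  eligible: %d", f$eligible)
      )
    )
    paste(lines, collapse = "\n")
  }
  ord <- order(match(flow$period, PERIODS), match(flow$arm, ARMS))
  paste(vapply(ord, panel, character(1)), collapse = "\n\n")
}

#' Assemble a trial report
#'
#' Collects flow counts, adherence rates (with their printed percentage
#' strings derived from the same counts), per-stratum estimates, effect
#' estimates and paired change tests from a fitted [crt_analysis()], plus
#' a provenance block.
#'
#' @param fit A `"crt_analysis"` object.
#' @param config The run configuration to echo (any list).
#' @param seed The seed to echo.
#' @return Object of class `"crt_report"`.
#' @export
trial_report <- function(fit, config = NULL, seed = NULL) {
  stopifnot(inherits(fit, "crt_analysis"))
  rates <- fit$rates
  rates$percent <- ifelse(
    rates$eligible > 0,
    vapply(seq_len(nrow(rates)), function(i)
      report_percentage(rates$adherent[i], rates$eligible[i]),
      character(1)),
    NA_character_)
  effects <- lapply(fit$effects, function(e)
    list(scale = e$scale, adjusted = e$adjusted, point = e$point,
         se = e$se, ci_low = e$ci[1], ci_high = e$ci[2], t = e$t,
         df = e$df, p = e$p))
  structure(list(
    flow = fit$flow,
    rates = rates,
    strata = lapply(fit$effects, function(e) e$strata),
    effects = effects,
    paired = fit$paired,
    n_ambiguous = fit$n_ambiguous,
    provenance = list(
      package = "crtadhere",
      version = as.character(utils::packageVersion("crtadhere")),
      seed = seed,
      alpha = fit$alpha,
      config = config
    )
  ), class = "crt_report")
}

#' @export
print.crt_report <- function(x, ...) {
  cat("=== Trial profile ===\n")
  cat(render_flow_diagram(x$flow), "\n\n")
  cat("=== Adherence rates ===\n")
  for (i in seq_len(nrow(x$rates))) {
    r <- x$rates[i, ]
    if (!is.na(r$percent))
      cat(sprintf("  %s %s: %d/%d (%s)\n", r$arm, r$period, r$adherent,
                  r$eligible, r$percent))
  }
  cat("\n=== Effect estimates ===\n")
  for (e in x$effects) {
    lab <- if (e$scale == "ratio") "risk ratio" else "risk difference"
    adj <- if (e$adjusted) ", adjusted" else ""
    cat(sprintf("  %s%s: %.3f (%.3f to %.3f), p = %.3g\n", lab, adj,
                e$point, e$ci_low, e$ci_high, e$p))
  }
  for (pt in x$paired) {
    if (is.null(pt)) next
    cat(sprintf(
      "  %s arm change: %.1f%% (%.1f%% to %.1f%%), p = %.3g (paired t)\n",
      pt$arm, 100 * pt$mean_diff, 100 * pt$ci[1], 100 * pt$ci[2], pt$p))
  }
  if (x$n_ambiguous > 0)
    cat(sprintf("\n%d adherence call(s) flagged ambiguous (extra antibiotic)\n",
                x$n_ambiguous))
  cat(sprintf("\nprovenance: %s %s, seed %s\n", x$provenance$package,
              x$provenance$version,
              x$provenance$seed %||% "<none>"))
  invisible(x)
}

#' Write a report as JSON and text
#'
#' @param report A `"crt_report"`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "crt_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  txt_path <- file.path(dir, "report.txt")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  writeLines(utils::capture.output(print(report)), txt_path)
  invisible(c(json = json_path, text = txt_path))
}

#' Read trial tables from delimited text
#'
#' Reads the prescriptions, drug-orders and optional physicians tables
#' (comma-delimited, UTF-8, header row) and coerces column types to the
#' records-module schema.
#'
#' @param prescriptions,drug_orders,physicians File paths (`physicians`
#'   may be `NULL`).
#' @return List of data frames.
#' @export
read_trial_tables <- function(prescriptions, drug_orders,
                              physicians = NULL) {
  for (p in c(prescriptions, drug_orders, physicians)) {
    if (!file.exists(p))
      abort_validation(sprintf("input file not found: %s", p))
  }
  rd <- function(path) utils::read.csv(path, stringsAsFactors = FALSE,
                                       fileEncoding = "UTF-8")
  rec <- rd(prescriptions)
  check_columns(rec, PRESCRIPTION_REQUIRED, "prescriptions")
  rec$pregnant_or_lactating <- as.logical(rec$pregnant_or_lactating)
  ord <- rd(drug_orders)
  check_columns(ord, DRUG_ORDER_REQUIRED, "drug_orders")
  ph <- if (!is.null(physicians)) rd(physicians) else NULL
  list(prescriptions = rec, drug_orders = ord, physicians = ph)
}

#' Write trial tables as delimited text
#'
#' @param trial A `"sim_trial"` from [generate_trial()] (or any list with
#'   the three tables).
#' @param dir Output directory.
#' @param truth Also write the truth record as JSON?
#' @return Invisibly, the paths written.
#' @export
write_trial_tables <- function(trial, dir, truth = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    prescriptions = file.path(dir, "prescriptions.csv"),
    drug_orders = file.path(dir, "drug_orders.csv"),
    physicians = file.path(dir, "physicians.csv")
  )
  utils::write.csv(trial$prescriptions, paths["prescriptions"],
                   row.names = FALSE)
  utils::write.csv(trial$drug_orders, paths["drug_orders"],
                   row.names = FALSE)
  utils::write.csv(trial$physicians, paths["physicians"],
                   row.names = FALSE)
  if (truth && !is.null(trial$truth)) {
    tp <- file.path(dir, "truth.json")
    tr <- trial$truth
    tr$config$strata <- as.list(tr$config$strata)
    tr$category <- NULL; tr$adherent <- NULL  # bulky per-record latents
    jsonlite::write_json(tr, tp, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    paths <- c(paths, truth = tp)
  }
  invisible(paths)
}

#' Run the full trial workflow from a configuration
#'
#' One deterministic invocation of simulate (or load) -> corrupt (when a
#' loss fraction is configured) -> filter -> analyze -> report. The
#' configuration is a list (or a YAML file path) with either `preset`
#' (plus optional `seed`) or an `inputs` list of CSV paths, and optional
#' `alpha`, `adjust`, `covariates`, `small_stratum`, `strict`,
#' `apply_loss`, `out_dir`.
#'
#' @param config List or YAML file path.
#' @return A `"crt_report"`; reports are also written to `out_dir` when
#'   configured.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort_validation(sprintf("config file not found: %s", config))
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_validation("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed
  if (!is.null(config$preset)) {
    if (is.null(seed)) abort_validation("simulation requires a seed")
    trial <- generate_trial(trial_preset(config$preset), seed = seed)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (is.null(inp$prescriptions) || is.null(inp$drug_orders))
      abort_validation(
        "config$inputs needs prescriptions and drug_orders paths")
    trial <- read_trial_tables(inp$prescriptions, inp$drug_orders,
                               inp$physicians)
  } else {
    abort_validation("config must name a preset or input files")
  }
  strict <- config$strict %||% TRUE
  rec <- trial$prescriptions
  if (isTRUE(config$apply_loss)) {
    lf <- trial$truth$config$loss_fraction %||% config$loss_fraction %||% 0
    if (lf > 0) {
      if (is.null(seed)) abort_validation("loss corruption requires a seed")
      rec <- corrupt_records(rec, lf, seed = seed + 1L)
      strict <- FALSE
    }
  }
  fit <- crt_analysis(
    rec, trial$drug_orders, trial$physicians,
    alpha = config$alpha %||% 0.05,
    adjust = config$adjust %||% TRUE,
    covariates = config$covariates %||% c("stratum", "p_baseline",
                                          "patient_sex", "patient_age",
                                          "physician_sex", "department"),
    strict = strict,
    small_stratum = config$small_stratum %||% "error"
  )
  report <- trial_report(fit, config = config, seed = seed)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}
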