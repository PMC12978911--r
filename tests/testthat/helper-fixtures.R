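# Fixture builders shared across test files. All fixtures are constructed
# in code; nothing is read from disk.

# One prescription row with sensible defaults; override any field.
make_rx <- function(record_id, ...) {
  defaults <- list(
    record_id = record_id, cluster_id = "H01", stratum = "A",
    arm = "control", period = "baseline", patient_age = 30L,
    patient_sex = "male", pregnant_or_lactating = FALSE,
    diagnosis = "uncomplicated_gonorrhea", physician_id = "ph1"
  )
  over <- list(...)
  defaults[names(over)] <- over
  as.data.frame(defaults, stringsAsFactors = FALSE)
}

make_order <- function(record_id, drug_name = "ceftriaxone",
                       dose_mg = 1000, route = "IM",
                       n_administrations = 1L, indication = "gonorrhea") {
  data.frame(record_id = record_id, drug_name = drug_name,
             dose_mg = dose_mg, route = route,
             n_administrations = n_administrations,
             indication = indication, stringsAsFactors = FALSE)
}

# Six constructed records: five violating exactly one exclusion criterion
# (age 16; pregnant; azithromycin only; ceftriaxone plus doxycycline for
# another infection; disseminated infection) plus one clean record.
eligibility_fixture <- function() {
  rec <- rbind(
    make_rx("r_clean"),
    make_rx("r_age", patient_age = 16L),
    make_rx("r_preg", patient_sex = "female",
            pregnant_or_lactating = TRUE),
    make_rx("r_nocef"),
    make_rx("r_other"),
    make_rx("r_compl", diagnosis = "complicated_gonorrhea")
  )
  ord <- rbind(
    make_order("r_clean"),
    make_order("r_age"),
    make_order("r_preg"),
    make_order("r_nocef", drug_name = "azithromycin", dose_mg = 2000,
               route = "oral"),
    make_order("r_other"),
    make_order("r_other", drug_name = "doxycycline", dose_mg = 100,
               route = "oral", n_administrations = 14L,
               indication = "other_infection"),
    make_order("r_compl")
  )
  list(prescriptions = rec, drug_orders = ord)
}

# Small full-trial config used where speed matters more than realism.
small_config <- function(true_rr = 1, k = 0.2, seed = NULL) {
  trial_config(
    strata = data.frame(name = c("A", "B"), baseline_p = c(0.3, 0.5)),
    clusters_per_arm_per_stratum = 3L,
    prescriptions_per_cluster = 40,
    true_rr = true_rr, k = k, seed = seed
  )
}

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
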