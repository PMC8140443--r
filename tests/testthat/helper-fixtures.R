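# shared fixtures: tiny hand-built cohorts and closed-form oracles

empty_events <- function() {
  list(
    diagnoses = tibble::tibble(patient_id = character(), code_system = character(),
                               code = character(), date = as.Date(character())),
    labs = tibble::tibble(patient_id = character(), analyte = character(),
                          value = numeric(), units = character(),
                          date = as.Date(character())),
    medications = tibble::tibble(patient_id = character(), drug_class = character(),
                                 route = character(), date = as.Date(character())),
    procedures = tibble::tibble(patient_id = character(), code = character(),
                                date = as.Date(character()), is_amputation = integer())
  )
}

# a ten-patient cohort exercising each rule type; every patient carries an
# anchoring osteomyelitis diagnosis on 2012-03-01 unless noted
mini_cohort <- function() {
  ev <- empty_events()
  ids <- sprintf("P%02d", 1:10)
  patients <- tibble::tibble(
    patient_id = ids,
    age_years = c(40, 55, 62, 48, 70, 35, 51, 66, 44, 58),
    sex = rep(c("female", "male"), 5),
    stratum = rep(c("A", "B"), each = 5))

  anchor <- as.Date("2012-03-01")
  dx <- tibble::tibble(
    patient_id = ids, code_system = "ICD10", code = "M86.9", date = anchor)
  # P02: diabetes code; P03: PVD; P04: sepsis; P05: septic arthritis too
  dx <- dplyr::bind_rows(
    dx,
    tibble::tibble(patient_id = "P02", code_system = "ICD10", code = "E11.9",
                   date = anchor - 100),
    tibble::tibble(patient_id = "P03", code_system = "ICD9", code = "443.9",
                   date = anchor - 30),
    tibble::tibble(patient_id = "P04", code_system = "ICD10", code = "A41.9",
                   date = anchor + 2),
    tibble::tibble(patient_id = "P05", code_system = "ICD10", code = "M00.9",
                   date = anchor + 10))
  # P01: diabetic by max HbA1c exactly 6.5; P06 stays below threshold
  labs <- tibble::tibble(
    patient_id = c("P01", "P01", "P06"), analyte = "hba1c",
    value = c(5.9, 6.5, 6.4), units = "%",
    date = anchor + c(-10, 5, 0))
  # P07: diabetes med; P08: systemic antibiotic; P09: topical decoy
  meds <- tibble::tibble(
    patient_id = c("P07", "P08", "P09"),
    drug_class = c("metformin", "cephalosporin", "cephalosporin"),
    route = c("oral", "intravenous", "topical"),
    date = anchor + c(-5, 1, 1))
  # P05: amputation at day 30 (in window); P10: surgery at day 120 (out)
  procs <- tibble::tibble(
    patient_id = c("P05", "P10"), code = c("27590", "27301"),
    date = anchor + c(30, 120), is_amputation = c(1L, 0L))

  cohort_dataset(patients, dx, labs, meds, procs)
}

# closed-form 2x2 oracle: cross-product OR and Wald CI from cell counts
# (a = exposed events, b = exposed non-events, c = unexposed events,
#  d = unexposed non-events)
oracle_or_2x2 <- function(a, b, c, d, conf = 0.95) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se), se = se)
}

# element matrix for a 2x2 design: strata "exp"/"ref", single element "y"
matrix_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(a + b + c + d)),
    stratum = c(rep("exp", a + b), rep("ref", c + d)),
    age_years = 50, sex = "female",
    y = c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d)))
}

# minimal one-element continuum spec for estimation-level tests
toy_spec <- function() {
  continuum_spec(
    name = "toy",
    phases = list(phase("only", list(
      element_rule("y", code_criteria = list(code_criterion("ICD10", "X")))))),
    index_element = "y")
}
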