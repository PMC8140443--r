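#' Build a synthetic-cohort configuration
#'
#' A `sim_config` fixes the generative model of a synthetic hospital cohort:
#' stratum mixture (labels, proportions, per-stratum age distributions and
#' female probability), and per element a logistic model — target prevalence
#' in the reference stratum, per-stratum log odds ratios (0 for the
#' reference), and linear age and sex (male) effects. Element intercepts are
#' not supplied: they are calibrated at simulation time so the realized
#' reference-stratum prevalence matches its target (see
#' [calibrate_intercept()]).
#'
#' An element may declare `subset_of = "<parent element>"`: it is then drawn
#' conditionally inside the parent (by thinning with
#' `plogis(lp_child) / plogis(lp_parent)`), which keeps the child's marginal
#' model exactly logistic while guaranteeing containment — used for
#' amputation within any-surgical-procedure. Elements are otherwise
#' conditionally independent given covariates; an optional shared
#' patient-level normal frailty (`frailty_sd > 0`) on every linear predictor
#' induces positive dependence between elements.
#'
#' @param n_patients Number of patients.
#' @param strata Tibble with columns `label`, `proportion` (summing to 1),
#'   `age_mean`, `age_sd`, `sex_female_prob`.
#' @param reference Label of the generator's reference stratum (log-OR 0).
#' @param elements Named list (one entry per cycle element, in cycle order);
#'   each entry a list with `target_prevalence_reference`,
#'   `log_or_by_stratum` (named, non-reference strata),
#'   `log_or_age_per_year`, `log_or_sex_male`, optional `subset_of`.
#' @param frailty_sd Standard deviation of the shared patient-level frailty
#'   (default 0 = conditional independence).
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients, strata, reference, elements,
                       frailty_sd = 0, seed = 1L) {
  strata <- tibble::as_tibble(strata)
  stopifnot(all(c("label", "proportion", "age_mean", "age_sd",
                  "sex_female_prob") %in% names(strata)))
  if (abs(sum(strata$proportion) - 1) > 1e-8)
    stop("stratum proportions must sum to 1", call. = FALSE)
  if (!reference %in% strata$label)
    stop("reference '", reference, "' is not a stratum label", call. = FALSE)
  for (id in names(elements)) {
    el <- elements[[id]]
    p <- el$target_prevalence_reference
    if (!is.numeric(p) || p <= 0 || p >= 1)
      stop("element '", id, "': target prevalence must be in (0, 1)",
           call. = FALSE)
    others <- setdiff(strata$label, reference)
    if (!setequal(names(el$log_or_by_stratum), others))
      stop("element '", id,
           "': log_or_by_stratum must name every non-reference stratum",
           call. = FALSE)
    if (!is.null(el$subset_of) && !el$subset_of %in% names(elements))
      stop("element '", id, "': subset_of parent '", el$subset_of,
           "' is not an element", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), strata = strata,
         reference = reference, elements = elements,
         frailty_sd = as.numeric(frailty_sd), seed = as.integer(seed)),
    class = "sim_config")
}

# Table-1-shaped stratum mixture: five race/ethnicity groups with the
# published proportions, age means/SDs, and the cohort-wide female fraction
default_sim_strata <- function() {
  tibble::tibble(
    label = c("hispanic_latinx", "white_nh", "native_american",
              "two_or_more_api_other", "african_american_nh"),
    proportion = c(0.402, 0.350, 0.177, 0.045, 0.026),
    age_mean = c(52.3, 56.3, 50.9, 54.6, 53.4),
    age_sd = c(15.8, 14.3, 14.6, 16.3, 13.7),
    sex_female_prob = rep(0.317, 5))
}

# published per-element odds ratios by group (reference: white_nh), used as
# the emulation scenario's stratum effects
table2_or <- function() {
  g <- c("hispanic_latinx", "native_american", "african_american_nh",
         "two_or_more_api_other")
  list(
    diabetes_mellitus = stats::setNames(c(2.04, 3.59, 2.70, 1.72), g),
    peripheral_vascular_disease = stats::setNames(c(1.45, 2.50, 4.96, 0.70), g),
    osteomyelitis = stats::setNames(c(1.28, 1.43, 0.79, 2.39), g),
    multiple_infections = stats::setNames(c(1.08, 1.59, 0.28, 1.01), g),
    sepsis = stats::setNames(c(0.96, 1.48, 1.40, 1.19), g),
    antibiotics = stats::setNames(c(1.43, 0.94, 2.08, 1.25), g),
    surgical_procedure = stats::setNames(c(1.02, 1.28, 1.19, 1.06), g),
    amputation = stats::setNames(c(1.48, 1.02, 2.74, 0.97), g))
}

#' Packaged emulation scenario shaped like the published cohort
#'
#' Five race/ethnicity strata with the published mixture proportions and age
#' distributions, and per-element stratum log odds ratios set to the natural
#' logs of the published adjusted point estimates. This is an *emulation
#' scenario* for demos and recovery tests — the reference-stratum target
#' prevalences and covariate effects are plausible values chosen for this
#' package, not a reproduction of the source study, whose patient-level data
#' are not public.
#'
#' @param n_patients Cohort size (default 1648, the published cohort's N).
#' @param seed Integer seed.
#' @param frailty_sd Shared-frailty SD (default 0).
#' @return A `sim_config`.
#' @export
sim_config_table2 <- function(n_patients = 1648L, seed = 1L,
                              frailty_sd = 0) {
  prev <- c(diabetes_mellitus = 0.30, peripheral_vascular_disease = 0.06,
            osteomyelitis = 0.45, multiple_infections = 0.10,
            sepsis = 0.25, antibiotics = 0.80,
            surgical_procedure = 0.35, amputation = 0.08)
  age_eff <- c(diabetes_mellitus = 0.03, peripheral_vascular_disease = 0.04,
               osteomyelitis = 0.01, multiple_infections = 0,
               sepsis = 0.02, antibiotics = 0,
               surgical_procedure = 0.015, amputation = 0.015)
  sex_eff <- c(diabetes_mellitus = 0.10, peripheral_vascular_disease = 0.20,
               osteomyelitis = 0.20, multiple_infections = 0.10,
               sepsis = 0.10, antibiotics = 0,
               surgical_procedure = 0.15, amputation = 0.15)
  ors <- table2_or()
  elements <- purrr::imap(ors, function(or, id) {
    list(target_prevalence_reference = unname(prev[id]),
         log_or_by_stratum = log(or),
         log_or_age_per_year = unname(age_eff[id]),
         log_or_sex_male = unname(sex_eff[id]),
         subset_of = if (id == "amputation") "surgical_procedure")
  })
  sim_config(n_patients, default_sim_strata(), reference = "white_nh",
             elements = elements, frailty_sd = frailty_sd, seed = seed)
}

#' Packaged null scenario: no disparities
#'
#' Same cohort shape as [sim_config_table2()] but every stratum log odds
#' ratio is 0, so any detected disparity is a false positive; used for
#' type-I-error and confidence-interval-coverage checks.
#'
#' @inheritParams sim_config_table2
#' @return A `sim_config`.
#' @export
sim_config_null <- function(n_patients = 1648L, seed = 1L, frailty_sd = 0) {
  cfg <- sim_config_table2(n_patients, seed, frailty_sd)
  cfg$elements <- purrr::map(cfg$elements, function(el) {
    el$log_or_by_stratum[] <- 0
    el
  })
  cfg
}

#' Calibrate a logistic intercept to a target prevalence
#'
#' Finds `b0` by bisection such that
#' `mean(plogis(b0 + lp))` over the supplied linear-predictor sample equals
#' the target within 1e-6. The mean is monotone increasing in `b0`, so the
#' root is unique.
#'
#' @param target Target prevalence in (0, 1).
#' @param lp Numeric vector: the non-intercept linear predictor for each
#'   subject in the calibration sample.
#' @return The calibrated intercept (length-1 numeric).
#' @export
calibrate_intercept <- function(target, lp) {
  stopifnot(is.numeric(target), length(target) == 1L)
  if (target <= 0 || target >= 1)
    stop("target prevalence must be in (0, 1)", call. = FALSE)
  if (!length(lp) || any(!is.finite(lp)))
    stop("calibration sample is empty or non-finite; cannot bracket target",
         call. = FALSE)
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("target prevalence is unbracketable on the calibration sample",
         call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-9 || (hi - lo) < 1e-13) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  mid
}

# truncated-normal ages (>= lower) by rejection, vectorized
rtruncnorm_lower <- function(n, mean, sd, lower = 18) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower))
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  x
}

rdate <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + floor(stats::runif(n) * (as.numeric(to - from) + 1L))
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Samples strata by their mixture proportions, ages from per-stratum
#' normals truncated at 18 (rejection sampling), and sex by per-stratum
#' probability; draws each element TRUE with probability
#' `plogis(b0 + bg + b_age age + b_sex male [+ frailty])` with `b0`
#' calibrated to the reference-stratum target prevalence; then materializes
#' the boolean truths into raw, dated EHR-style events that the default
#' musculoskeletal continuum rules recover exactly: diabetes becomes a
#' diagnosis code, a high HbA1c, or a diabetes medication (one mechanism
#' chosen at random); every patient receives at least one
#' musculoskeletal-infection diagnosis (cohort inclusion) whose earliest
#' date is the index infection date; surgical events fall inside the 0–90
#' day window (and decoy procedures outside it); systemic antimicrobials
#' carry a non-topical route (decoy topicals appear for antibiotic-negative
#' patients).
#'
#' Identical seeds give byte-identical cohorts. The ground truth is emitted
#' alongside the cohort and is never consumed by the analysis path.
#'
#' @param config A [sim_config()].
#' @return A list with components `cohort` (a [cohort_dataset()]) and
#'   `truth` (list: `elements` tibble of per-patient booleans,
#'   `coefficients` tibble of realized model coefficients).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  st <- config$strata

  patient_id <- sprintf("P%05d", seq_len(n))
  stratum <- sample(st$label, n, replace = TRUE, prob = st$proportion)
  si <- match(stratum, st$label)
  age <- round(rtruncnorm_lower(n, st$age_mean[si], st$age_sd[si]), 1)
  sex <- ifelse(stats::runif(n) < st$sex_female_prob[si], "female", "male")
  male <- as.integer(sex == "male")
  frailty <- if (config$frailty_sd > 0)
    stats::rnorm(n, 0, config$frailty_sd) else numeric(n)

  ref <- config$reference
  is_ref <- stratum == ref

  # element truths: marginal logistic draws; subset_of children are thinned
  # inside their parent so containment holds and both marginals stay logistic
  truth <- list()
  lps <- list()
  coefs <- list()
  for (id in names(config$elements)) {
    el <- config$elements[[id]]
    bg <- c(stats::setNames(0, ref), el$log_or_by_stratum)
    lp <- unname(bg[stratum]) + el$log_or_age_per_year * age +
      el$log_or_sex_male * male + frailty
    b0 <- calibrate_intercept(el$target_prevalence_reference, lp[is_ref])
    lps[[id]] <- b0 + lp
    coefs[[id]] <- tibble::tibble(
      element_id = id,
      term = c("intercept", "age_years", "sex_male",
               paste0("stratum:", names(el$log_or_by_stratum))),
      value = c(b0, el$log_or_age_per_year, el$log_or_sex_male,
                unname(el$log_or_by_stratum)))
  }
  for (id in names(config$elements)) {
    el <- config$elements[[id]]
    p <- stats::plogis(lps[[id]])
    if (is.null(el$subset_of)) {
      truth[[id]] <- stats::runif(n) < p
    } else {
      p_parent <- stats::plogis(lps[[el$subset_of]])
      q <- p / p_parent
      if (any(q > 1 + 1e-12))
        stop("element '", id, "': child probability exceeds parent '",
             el$subset_of, "' for some patients; subset model is infeasible",
             call. = FALSE)
      parent <- truth[[el$subset_of]]
      if (is.null(parent))
        stop("subset_of parent '", el$subset_of,
             "' must be listed before '", id, "'", call. = FALSE)
      truth[[id]] <- parent & (stats::runif(n) < pmin(q, 1))
    }
  }

  index_date <- rdate(n, "2010-01-01", "2015-12-31")
  ev <- simulate_events(patient_id, truth, index_date)

  cohort <- cohort_dataset(
    patients = tibble::tibble(patient_id = patient_id, age_years = age,
                              sex = sex, stratum = stratum),
    diagnoses = ev$diagnoses, labs = ev$labs,
    medications = ev$medications, procedures = ev$procedures,
    provenance = list(source = "carecycle::simulate_cohort",
                      seed = config$seed, n_patients = n,
                      frailty_sd = config$frailty_sd))
  list(cohort = cohort,
       truth = list(
         elements = dplyr::bind_cols(
           tibble::tibble(patient_id = patient_id),
           tibble::as_tibble(truth)),
         coefficients = dplyr::bind_rows(coefs)))
}

# materialize boolean truths as raw dated events consistent with the
# default musculoskeletal spec; exact (noise-free) so phenotyping recovers
# the truth table verbatim
simulate_events <- function(patient_id, truth, index_date) {
  n <- length(patient_id)
  dx <- list(); lb <- list(); md <- list(); pr <- list()
  t2 <- function(pid, sys, code, date)
    tibble::tibble(patient_id = pid, code_system = sys, code = code,
                   date = as.character(date))

  # anchoring musculoskeletal infection diagnoses; earliest is at the index
  # date for every patient so inclusion always holds
  osteo <- truth$osteomyelitis
  multi <- truth$multiple_infections
  osteo_code <- ifelse(stats::runif(n) < 0.5, "M86.9", "730.20")
  osteo_sys <- ifelse(stringr::str_starts(osteo_code, "M"), "ICD10", "ICD9")
  sa_code <- ifelse(stats::runif(n) < 0.5, "M00.9", "711.00")
  sa_sys <- ifelse(stringr::str_starts(sa_code, "M"), "ICD10", "ICD9")
  im_code <- ifelse(stats::runif(n) < 0.5, "M60.00", "728.86")
  im_sys <- ifelse(stringr::str_starts(im_code, "M"), "ICD10", "ICD9")
  pick_sa <- stats::runif(n) < 0.5        # coin for choosing SA vs IM
  second_offset <- floor(stats::runif(n) * 31)

  first_is_osteo <- osteo
  # second infection only when the multiple-infections truth demands it
  emit_second <- multi
  sa_first <- !osteo & (multi | pick_sa)   # SA leads when osteo is absent
  im_first <- !osteo & !sa_first

  dx$osteo <- t2(patient_id[first_is_osteo], osteo_sys[first_is_osteo],
                 osteo_code[first_is_osteo], index_date[first_is_osteo])
  dx$sa1 <- t2(patient_id[sa_first], sa_sys[sa_first], sa_code[sa_first],
               index_date[sa_first])
  dx$im1 <- t2(patient_id[im_first], im_sys[im_first], im_code[im_first],
               index_date[im_first])
  # the second infection type for multiple-infection patients
  sec_sa <- emit_second & osteo & pick_sa      # osteo + SA
  sec_im <- emit_second & osteo & !pick_sa     # osteo + IM
  sec_im2 <- emit_second & !osteo              # SA + IM
  dx$sa2 <- t2(patient_id[sec_sa], sa_sys[sec_sa], sa_code[sec_sa],
               index_date[sec_sa] + second_offset[sec_sa])
  dx$im2 <- t2(patient_id[sec_im], im_sys[sec_im], im_code[sec_im],
               index_date[sec_im] + second_offset[sec_im])
  dx$im3 <- t2(patient_id[sec_im2], im_sys[sec_im2], im_code[sec_im2],
               index_date[sec_im2] + second_offset[sec_im2])

  # diabetes: one mechanism drawn per TRUE patient
  dm <- truth$diabetes_mellitus
  mech <- sample(c("code", "lab", "med"), n, replace = TRUE)
  ddate <- index_date - floor(stats::runif(n) * 365)
  w <- dm & mech == "code"
  dm_code <- ifelse(stats::runif(n) < 0.5, "E11.9", "250.00")
  dm_sys <- ifelse(stringr::str_starts(dm_code, "E"), "ICD10", "ICD9")
  dx$dm <- t2(patient_id[w], dm_sys[w], dm_code[w], ddate[w])
  w <- dm & mech == "lab"
  lb$dm <- tibble::tibble(patient_id = patient_id[w], analyte = "hba1c",
                          value = round(6.5 + stats::runif(sum(w)) * 5, 1),
                          units = "%", date = as.character(ddate[w]))
  # normal-range decoy HbA1c for a fraction of diabetes-negative patients
  w <- !dm & stats::runif(n) < 0.4
  lb$decoy <- tibble::tibble(patient_id = patient_id[w], analyte = "hba1c",
                             value = round(4.5 + stats::runif(sum(w)) * 1.9, 1),
                             units = "%", date = as.character(ddate[w]))
  w <- dm & mech == "med"
  dm_meds <- c("insulin", "metformin", "sulfonylurea")
  md$dm <- tibble::tibble(patient_id = patient_id[w],
                          drug_class = sample(dm_meds, sum(w), replace = TRUE),
                          route = "oral", date = as.character(ddate[w]))

  # peripheral vascular disease and sepsis: plain diagnosis codes
  w <- truth$peripheral_vascular_disease
  pvd_code <- ifelse(stats::runif(n) < 0.5, "I70.2", "443.9")
  pvd_sys <- ifelse(stringr::str_starts(pvd_code, "I"), "ICD10", "ICD9")
  dx$pvd <- t2(patient_id[w], pvd_sys[w], pvd_code[w], ddate[w])
  w <- truth$sepsis
  sep_code <- ifelse(stats::runif(n) < 0.5, "A41.9", "038.9")
  sep_sys <- ifelse(stringr::str_starts(sep_code, "A"), "ICD10", "ICD9")
  dx$sepsis <- t2(patient_id[w], sep_sys[w], sep_code[w],
                  index_date[w] + floor(stats::runif(sum(w)) * 11))

  # systemic antibiotics; topical decoys for a fraction of negatives
  ab_classes <- c("penicillin", "cephalosporin", "fluoroquinolone",
                  "glycopeptide")
  w <- truth$antibiotics
  md$ab <- tibble::tibble(
    patient_id = patient_id[w],
    drug_class = sample(ab_classes, sum(w), replace = TRUE),
    route = sample(c("intravenous", "oral"), sum(w), replace = TRUE),
    date = as.character(index_date[w] + floor(stats::runif(sum(w)) * 14)))
  w <- !truth$antibiotics & stats::runif(n) < 0.1
  md$ab_decoy <- tibble::tibble(
    patient_id = patient_id[w],
    drug_class = sample(ab_classes, sum(w), replace = TRUE),
    route = "topical",
    date = as.character(index_date[w] + floor(stats::runif(sum(w)) * 14)))

  # surgery within the 0-90 day window; amputation flagged; decoy
  # out-of-window procedures for a fraction of surgery-negative patients
  surg <- truth$surgical_procedure
  amp <- truth$amputation
  surg_date <- index_date + floor(stats::runif(n) * 91)
  w <- surg & !amp
  pr$surg <- tibble::tibble(patient_id = patient_id[w], code = "27301",
                            date = as.character(surg_date[w]),
                            is_amputation = 0L)
  w <- amp
  pr$amp <- tibble::tibble(patient_id = patient_id[w], code = "27590",
                           date = as.character(surg_date[w]),
                           is_amputation = 1L)
  w <- !surg & stats::runif(n) < 0.2
  pr$decoy <- tibble::tibble(
    patient_id = patient_id[w], code = "27301",
    date = as.character(index_date[w] + 91L +
                          floor(stats::runif(sum(w)) * 90)),
    is_amputation = 0L)

  list(diagnoses = dplyr::bind_rows(dx) |>
         dplyr::mutate(date = as.character(date)),
       labs = dplyr::bind_rows(lb),
       medications = dplyr::bind_rows(md),
       procedures = dplyr::bind_rows(pr))
}

#' Simulation study: parameter recovery across replicates
#'
#' Runs simulate → phenotype → estimate for `n_replicates` independent
#' cohorts (replicate seeds are `config$seed + 1 ... + n_replicates`) and
#' summarises, per stratum-by-element: the mean and SD of the estimated log
#' odds ratio, bias against the generator's truth, the Monte-Carlo standard
#' error of the mean, confidence-interval coverage of the truth, the
#' significance rate, and the degenerate-fit rate.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of replicates (>= 2).
#' @param spec Continuum spec used for phenotyping and estimation.
#' @param alpha Significance level passed to [estimate_continuum()].
#' @return Tibble with one row per stratum-by-element.
#' @export
recovery_report <- function(config, n_replicates,
                            spec = default_msk_spec(), alpha = 0.05) {
  if (n_replicates < 2L)
    stop("recovery needs at least 2 replicates", call. = FALSE)
  truth_tbl <- dplyr::bind_rows(purrr::imap(config$elements, function(el, id)
    tibble::tibble(element_id = id,
                   stratum = names(el$log_or_by_stratum),
                   truth_lnor = unname(el$log_or_by_stratum))))

  per_rep <- purrr::map(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    sim <- simulate_cohort(cfg)
    mat <- suppressMessages(derive_element_matrix(sim$cohort, spec))
    est <- suppressMessages(
      estimate_continuum(mat, spec, alpha = alpha,
                         reference = config$reference))
    est$results |>
      dplyr::filter(!.data$is_reference) |>
      dplyr::mutate(replicate = i)
  })

  dplyr::bind_rows(per_rep) |>
    dplyr::left_join(truth_tbl, by = c("element_id", "stratum")) |>
    dplyr::group_by(.data$element_id, .data$stratum, .data$truth_lnor) |>
    dplyr::summarise(
      n_fits = sum(!.data$degenerate),
      mean_lnor = mean(log(.data$or[!.data$degenerate])),
      sd_lnor = stats::sd(log(.data$or[!.data$degenerate])),
      bias = .data$mean_lnor - .data$truth_lnor[1L],
      mc_se = .data$sd_lnor / sqrt(.data$n_fits),
      coverage = mean(.data$ci_low[!.data$degenerate] <=
                        exp(.data$truth_lnor[1L]) &
                        .data$ci_high[!.data$degenerate] >=
                        exp(.data$truth_lnor[1L])),
      significance_rate = mean(.data$significant),
      degenerate_rate = mean(.data$degenerate),
      .groups = "drop") |>
    dplyr::ungroup()
}
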