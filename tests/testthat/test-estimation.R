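test_that("reference selection minimizes crude odds with lexicographic ties", {
  mk <- function(stratum, y) tibble::tibble(
    patient_id = sprintf("P%03d", seq_along(stratum)), stratum = stratum,
    age_years = 50, sex = "female", dm = y)

  # crude odds A: 10/20 = 0.5, B: 16/20 = 0.8, C: 24/20 = 1.2
  m <- mk(rep(c("A", "B", "C"), times = c(30, 36, 44)),
          c(rep(TRUE, 10), rep(FALSE, 20), rep(TRUE, 16), rep(FALSE, 20),
            rep(TRUE, 24), rep(FALSE, 20)))
  expect_equal(select_reference_stratum(m, "dm"), "A")

  # tie at 0.5 between B and A -> lexicographically first
  m2 <- mk(rep(c("B", "A"), each = 30),
           rep(c(TRUE, FALSE, TRUE, FALSE), times = c(10, 20, 10, 20)))
  expect_equal(select_reference_stratum(m2, "dm"), "A")

  expect_error(select_reference_stratum(m[m$stratum == "A", ], "dm"),
               "two strata")
  m3 <- mk(rep(c("A", "B"), each = 5), rep(TRUE, 10))
  expect_error(select_reference_stratum(m3, "dm"), "constant")
})

test_that("a stratum with infinite crude odds is never selected", {
  m <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:40),
    stratum = rep(c("A", "B"), each = 20),
    age_years = 50, sex = "male",
    dm = c(rep(TRUE, 20),                 # A: all TRUE -> infinite odds
           rep(c(TRUE, FALSE), 10)))     # B: odds 1
  expect_equal(select_reference_stratum(m, "dm"), "B")
})

test_that("2x2 logistic fit equals the cross-product-ratio oracle", {
  # worked example: a=20, b=30, c=10, d=40 -> OR = (20*40)/(30*10) = 2.667
  oracle <- oracle_or_2x2(20, 30, 10, 40)
  expect_equal(oracle$or, 2 + 2 / 3, tolerance = 1e-12)
  expect_equal(round(oracle$ci_low, 3), 1.090)
  expect_equal(round(oracle$ci_high, 3), 6.524)

  fit <- fit_element_model(matrix_2x2(20, 30, 10, 40), "y",
                           reference = "ref", covariates = character())
  exp_row <- fit[fit$stratum == "exp", ]
  expect_equal(exp_row$or, oracle$or, tolerance = 1e-6)
  expect_equal(exp_row$ci_low, oracle$ci_low, tolerance = 1e-6)
  expect_equal(exp_row$ci_high, oracle$ci_high, tolerance = 1e-6)

  # randomized tables keep the equivalence
  set.seed(404)
  for (i in 1:25) {
    cells <- sample(3:60, 4L, replace = TRUE)
    o <- oracle_or_2x2(cells[1], cells[2], cells[3], cells[4])
    f <- fit_element_model(matrix_2x2(cells[1], cells[2], cells[3], cells[4]),
                           "y", reference = "ref", covariates = character())
    f <- f[f$stratum == "exp", ]
    expect_equal(f$or, o$or, tolerance = 1e-6)
    expect_equal(f$ci_low, o$ci_low, tolerance = 1e-6)
    expect_equal(f$ci_high, o$ci_high, tolerance = 1e-6)
  }
})

test_that("swapping the reference inverts the odds ratio", {
  m <- matrix_2x2(22, 18, 13, 47)
  f1 <- fit_element_model(m, "y", reference = "ref",
                          covariates = character())
  f2 <- fit_element_model(m, "y", reference = "exp",
                          covariates = character())
  or1 <- f1$or[f1$stratum == "exp"]
  or2 <- f2$or[f2$stratum == "ref"]
  expect_equal(or1, 1 / or2, tolerance = 1e-9)
})

test_that("shifting age by a constant leaves stratum ORs unchanged", {
  sim <- simulate_cohort(sim_config_table2(n_patients = 600L, seed = 13L))
  spec <- default_msk_spec()
  mat <- suppressMessages(derive_element_matrix(sim$cohort, spec))
  f1 <- fit_element_model(mat, "diabetes_mellitus", reference = "white_nh")
  mat2 <- dplyr::mutate(mat, age_years = age_years + 100)
  f2 <- fit_element_model(mat2, "diabetes_mellitus", reference = "white_nh")
  expect_equal(f1$or, f2$or, tolerance = 1e-8)
})

test_that("reference rows and degenerate strata are flagged honestly", {
  m <- matrix_2x2(20, 30, 10, 40)
  fit <- fit_element_model(m, "y", reference = "ref",
                           covariates = character())
  ref_row <- fit[fit$is_reference, ]
  expect_equal(ref_row$stratum, "ref")
  expect_identical(ref_row$or, 1)

  # a third stratum with zero events: separation, degenerate, no finite CI
  m3 <- dplyr::bind_rows(m, tibble::tibble(
    patient_id = sprintf("Z%03d", 1:25), stratum = "zero",
    age_years = 50, sex = "female", y = FALSE))
  fit3 <- fit_element_model(m3, "y", reference = "ref",
                            covariates = character())
  zero <- fit3[fit3$stratum == "zero", ]
  expect_true(zero$degenerate)
  expect_true(is.na(zero$or) && is.na(zero$ci_low) && is.na(zero$ci_high))
  expect_false(zero$significant)
  # the informative stratum is unaffected
  expect_equal(fit3$or[fit3$stratum == "exp"],
               fit$or[fit$stratum == "exp"], tolerance = 1e-6)

  expect_error(
    fit_element_model(dplyr::mutate(m, y = FALSE), "y", reference = "ref",
                      covariates = character()),
    "uninformative")
})

test_that("estimate_continuum covers every stratum-element pair and honors alpha", {
  spec <- default_msk_spec()
  sim <- simulate_cohort(sim_config_table2(n_patients = 900L, seed = 17L))
  mat <- suppressMessages(derive_element_matrix(sim$cohort, spec))
  est <- suppressMessages(estimate_continuum(mat, spec))

  n_strata <- dplyr::n_distinct(mat$stratum)
  expect_s3_class(est, "continuum_estimates")
  expect_equal(nrow(est$results), n_strata * 8L)
  expect_equal(length(est$models), 8L)
  expect_setequal(unique(est$results$element_id), continuum_elements(spec))
  expect_true(all(est$results$or[est$results$is_reference] == 1))

  # stricter alpha widens intervals: significant set can only shrink, and
  # stored intervals are 99% ones
  est99 <- suppressMessages(estimate_continuum(mat, spec, alpha = 0.01))
  expect_true(all(est$results$significant | !est99$results$significant))
  informative <- !est$results$is_reference & !est$results$degenerate
  expect_true(all(est99$results$ci_low[informative] <=
                    est$results$ci_low[informative] + 1e-12))
  expect_equal(est99$results$significant[informative],
               est99$results$ci_low[informative] > 1 |
                 est99$results$ci_high[informative] < 1)

  # tidy/glance accessors
  expect_identical(tidy(est), est$results)
  g <- glance(est)
  expect_equal(g$n_strata, n_strata)
  expect_equal(g$n_elements, 8L)
})

test_that("cohort descriptives reproduce counts, percents, and tests", {
  counts <- c(a = 662L, b = 577L, c = 292L, d = 74L, e = 43L)
  set.seed(5)
  mat <- tibble::tibble(
    patient_id = sprintf("P%04d", 1:1648),
    stratum = rep(names(counts), counts),
    age_years = stats::rnorm(1648, 54, 15),
    sex = c(rep("female", 522), rep("male", 1126))[sample(1648)])
  d <- describe_cohort(mat)
  expect_equal(d$n_total, 1648L)
  expect_equal(sum(d$by_stratum$n), 1648L)
  expect_equal(round(d$by_stratum$percent, 1), c(40.2, 35.0, 17.7, 4.5, 2.6))
  expect_equal(sum(d$by_stratum$percent), 100)

  # identical age distribution across strata -> F = 0
  ages <- rep(c(40, 50, 60, 70), length.out = 412)
  flat <- tibble::tibble(
    patient_id = sprintf("Q%04d", 1:1648),
    stratum = rep(c("a", "b", "c", "d"), each = 412),
    age_years = rep(ages, 4L),
    sex = rep(rep(c("female", "male"), times = c(130, 282)), 4L))
  dflat <- describe_cohort(flat)
  expect_equal(dflat$age_anova$statistic, 0, tolerance = 1e-10)
  # sex proportions identical by construction -> chi-square ~ 0
  expect_equal(dflat$sex_chisq$statistic, 0, tolerance = 1e-10)

  expect_warning(describe_cohort(mat[mat$stratum == "a", ]),
                 "single stratum")
})
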