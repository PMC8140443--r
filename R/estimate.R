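#' Select the reference stratum by lowest crude odds of the index element
#'
#' The reference category for all odds ratios is the stratum with the lowest
#' crude odds (TRUE count / FALSE count) of the continuum's index element.
#' Crude (unadjusted) odds are used so the reference is fixed before any
#' model is fit; ties are broken lexicographically by stratum label. A
#' stratum in which every patient has the index element (infinite odds) can
#' never be the minimum unless all strata are infinite, which is an error.
#'
#' @param matrix Element-matrix tibble.
#' @param index_element Element id used for selection.
#' @return The reference stratum label (length-1 character).
#' @export
select_reference_stratum <- function(matrix, index_element) {
  if (!index_element %in% names(matrix))
    stop("index element '", index_element, "' is not a matrix column",
         call. = FALSE)
  if (dplyr::n_distinct(matrix$stratum) < 2L)
    stop("reference selection needs at least two strata", call. = FALSE)
  y <- matrix[[index_element]]
  if (all(y) || all(!y))
    stop("index element '", index_element,
         "' is constant in the cohort; crude odds are undefined",
         call. = FALSE)
  odds <- matrix |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(odds = sum(.data[[index_element]]) /
                       sum(!.data[[index_element]]),
                     .groups = "drop") |>
    dplyr::arrange(.data$odds, .data$stratum)
  if (!is.finite(odds$odds[1L]))
    stop("every stratum has infinite crude odds of '", index_element, "'",
         call. = FALSE)
  odds$stratum[1L]
}

# rows usable for model fitting: complete covariates, binary sex when used
model_frame <- function(matrix, element_id, covariates) {
  df <- matrix
  n0 <- nrow(df)
  if ("sex" %in% covariates) {
    df <- df[df$sex %in% c("female", "male") & !is.na(df$sex), , drop = FALSE]
    if (nrow(df) < n0)
      log_info("excluding %d patient(s) with sex outside {female, male}",
               n0 - nrow(df))
  }
  num_cov <- setdiff(covariates, "sex")
  for (v in num_cov) df <- df[!is.na(df[[v]]), , drop = FALSE]
  if (nrow(df) < n0)
    log_info("element %s: %d of %d patients enter the model (complete cases)",
             element_id, nrow(df), n0)
  df
}

#' Fit the covariate-adjusted logistic model for one element
#'
#' Fits a single maximum-likelihood logistic regression
#' `logit P(element = 1) = b0 + sum_g bg [stratum = g] + b_age age + b_sex [male]`
#' with strata dummy-coded against the reference, and returns one row per
#' stratum: `OR = exp(bg)` with a two-sided Wald confidence interval
#' `exp(bg +/- z SE)` and Wald p-value. The reference row carries OR exactly
#' 1 and `is_reference = TRUE`. Complete-case analysis: rows with missing
#' covariates (or non-binary sex) are dropped with a logged count. IRLS runs
#' to a relative deviance-change tolerance of 1e-14 (at most 100
#' iterations), tight enough that Wald intervals agree with closed-form
#' contingency-table results to about 1e-6 relative;
#' separation or non-convergence is flagged `degenerate` — no finite
#' interval is fabricated.
#'
#' @param matrix Element-matrix tibble.
#' @param element_id Outcome element.
#' @param reference Reference stratum label.
#' @param covariates Adjustment covariates; default `c("age_years", "sex")`.
#'   Use `character()` for an unadjusted fit.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return Tibble with columns `stratum`, `element_id`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `significant`, `n_stratum`, `n_events_stratum`,
#'   `degenerate`, `is_reference`, plus a `converged` attribute.
#' @export
fit_element_model <- function(matrix, element_id, reference,
                              covariates = c("age_years", "sex"),
                              conf_level = 0.95) {
  df <- model_frame(matrix, element_id, covariates)
  y <- df[[element_id]]
  if (all(y) || all(!y))
    stop("element '", element_id,
         "' is constant in the cohort (uninformative); no model can be fit",
         call. = FALSE)
  if (!reference %in% df$stratum)
    stop("reference stratum '", reference, "' not present", call. = FALSE)

  strata <- sort(unique(df$stratum))
  df$stratum_f <- factor(df$stratum, levels = c(reference,
                                                setdiff(strata, reference)))
  if ("sex" %in% covariates)
    df$sex <- factor(df$sex, levels = c("female", "male"))

  rhs <- paste(c("stratum_f", covariates), collapse = " + ")
  fml <- stats::as.formula(paste0("`", element_id, "` ~ ", rhs))
  separation_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-14, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separation_warned <<- TRUE
      invokeRestart("muffleWarning")
    })

  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  counts <- df |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_stratum = dplyr::n(),
                     n_events_stratum = sum(.data[[element_id]]),
                     .groups = "drop")

  rows <- purrr::map_dfr(levels(df$stratum_f), function(g) {
    ct <- counts[counts$stratum == g, ]
    if (g == reference)
      return(tibble::tibble(
        stratum = g, element_id = element_id, or = 1, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, significant = FALSE,
        n_stratum = ct$n_stratum, n_events_stratum = ct$n_events_stratum,
        degenerate = FALSE, is_reference = TRUE))
    term <- paste0("stratum_f", g)
    b <- unname(cf[term]); s <- unname(se[term])
    # separation within this stratum: no events or all events, or an SE that
    # has blown up during IRLS
    degenerate <- !fit$converged || is.na(b) || is.na(s) ||
      ct$n_events_stratum == 0L || ct$n_events_stratum == ct$n_stratum ||
      s > 50 || abs(b) > 15
    if (degenerate)
      tibble::tibble(
        stratum = g, element_id = element_id, or = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        significant = FALSE, n_stratum = ct$n_stratum,
        n_events_stratum = ct$n_events_stratum, degenerate = TRUE,
        is_reference = FALSE)
    else
      tibble::tibble(
        stratum = g, element_id = element_id, or = exp(b),
        ci_low = exp(b - z * s), ci_high = exp(b + z * s),
        p_value = 2 * stats::pnorm(-abs(b / s)),
        significant = exp(b - z * s) > 1 | exp(b + z * s) < 1,
        n_stratum = ct$n_stratum, n_events_stratum = ct$n_events_stratum,
        degenerate = FALSE, is_reference = FALSE)
  })
  attr(rows, "converged") <- fit$converged && !separation_warned
  attr(rows, "n_model") <- nrow(df)
  rows
}

#' Estimate the full continuum: adjusted odds ratios for every element
#'
#' Selects the reference stratum from the crude odds of the spec's index
#' element (or per-stratum adjusted odds when
#' `reference_method = "adjusted"`), fits one covariate-adjusted logistic
#' model per cycle element (8 for the default spec), and assembles the
#' per-stratum, per-element odds-ratio surface. An element is flagged
#' significant when its `100 (1 - alpha)`% Wald interval excludes 1.00. No
#' multiple-testing correction is applied; each comparison is tested at
#' `alpha`.
#'
#' @param matrix Element-matrix tibble from [derive_element_matrix()].
#' @param spec The `continuum_spec` the matrix was derived from.
#' @param covariates Adjustment covariates (default age and sex).
#' @param alpha Significance level (default 0.05).
#' @param reference Optional explicit reference stratum label; overrides
#'   selection.
#' @param reference_method `"crude"` (default) or `"adjusted"` odds of the
#'   index element for reference selection.
#' @return An object of class `continuum_estimates`.
#' @export
estimate_continuum <- function(matrix, spec,
                               covariates = c("age_years", "sex"),
                               alpha = 0.05, reference = NULL,
                               reference_method = c("crude", "adjusted")) {
  reference_method <- match.arg(reference_method)
  elements <- continuum_elements(spec)
  missing_cols <- setdiff(elements, names(matrix))
  if (length(missing_cols))
    stop("matrix lacks element column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  if (is.null(reference)) {
    reference <- if (reference_method == "crude")
      select_reference_stratum(matrix, spec$index_element)
    else
      select_reference_adjusted(matrix, spec$index_element, covariates)
  }

  results <- list()
  models <- list()
  for (el in elements) {
    rows <- tryCatch(
      fit_element_model(matrix, el, reference, covariates,
                        conf_level = 1 - alpha),
      error = function(e)
        stop("element '", el, "': ", conditionMessage(e), call. = FALSE))
    models[[el]] <- list(element_id = el, n_model = attr(rows, "n_model"),
                         converged = attr(rows, "converged"))
    results[[el]] <- rows
  }

  results <- dplyr::bind_rows(results) |>
    dplyr::mutate(element_id = factor(.data$element_id, levels = elements)) |>
    dplyr::arrange(.data$element_id, .data$is_reference, .data$stratum) |>
    dplyr::mutate(element_id = as.character(.data$element_id))

  structure(
    list(spec_name = spec$name,
         reference_stratum = reference,
         covariates = covariates,
         alpha = alpha,
         element_order = elements,
         strata = sort(unique(matrix$stratum)),
         results = results,
         models = unname(models)),
    class = "continuum_estimates")
}

# reference selection on ADJUSTED odds: per-stratum coefficient from one
# covariate-adjusted fit of the index element (temporary baseline = first
# stratum alphabetically); argmin of the stratum log-odds offsets
select_reference_adjusted <- function(matrix, index_element, covariates) {
  strata <- sort(unique(matrix$stratum))
  fitted <- fit_element_model(matrix, index_element, reference = strata[1L],
                              covariates = covariates)
  beta <- stats::setNames(log(fitted$or), fitted$stratum)
  beta[strata[1L]] <- 0
  names(sort(beta))[1L]
}

#' Table-1-style cohort descriptives
#'
#' Per-stratum n and percent, age mean/median/SD, a one-way ANOVA F-test for
#' age across strata, and a Pearson chi-square test of sex by stratum
#' (restricted to female/male rows). Strata are ordered by descending size.
#'
#' @param matrix Element-matrix tibble (or any tibble with `stratum`,
#'   `age_years`, `sex`).
#' @return An object of class `cohort_descriptives`; see [tidy()] and
#'   [glance()] methods.
#' @export
describe_cohort <- function(matrix) {
  n_total <- nrow(matrix)
  by_stratum <- matrix |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      percent = 100 * dplyr::n() / n_total,
      age_mean = mean(.data$age_years, na.rm = TRUE),
      age_median = stats::median(.data$age_years, na.rm = TRUE),
      age_sd = stats::sd(.data$age_years, na.rm = TRUE),
      pct_female = 100 * mean(.data$sex == "female", na.rm = TRUE),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$stratum)

  multi <- nrow(by_stratum) >= 2L
  if (!multi)
    warning("single stratum: across-strata comparisons omitted",
            call. = FALSE)

  age_anova <- if (multi && stats::var(matrix$age_years, na.rm = TRUE) > 0) {
    av <- stats::aov(age_years ~ stratum, data = matrix)
    s <- summary(av)[[1L]]
    list(statistic = s[["F value"]][1L], p_value = s[["Pr(>F)"]][1L],
         df = unname(s[["Df"]][1:2]))
  } else if (multi) {
    list(statistic = 0, p_value = 1,
         df = c(nrow(by_stratum) - 1L, n_total - nrow(by_stratum)))
  } else list(statistic = NA_real_, p_value = NA_real_, df = NA)

  sex_chisq <- if (multi) {
    mm <- matrix[matrix$sex %in% c("female", "male"), , drop = FALSE]
    ct <- suppressWarnings(
      stats::chisq.test(table(mm$sex, mm$stratum), correct = FALSE))
    list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
         df = unname(ct$parameter))
  } else list(statistic = NA_real_, p_value = NA_real_, df = NA)

  structure(
    list(n_total = n_total, by_stratum = by_stratum,
         age_anova = age_anova, sex_chisq = sex_chisq),
    class = "cohort_descriptives")
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  cat(sprintf("<cohort_descriptives> N = %d\n", x$n_total))
  shown <- x$by_stratum |>
    dplyr::mutate(dplyr::across(dplyr::where(is.double), ~ round(.x, 1)))
  print(shown, n = Inf)
  if (is.finite(x$age_anova$statistic %||% NA))
    cat(sprintf("age across strata: ANOVA F = %.2f, p = %.4g\n",
                x$age_anova$statistic, x$age_anova$p_value))
  if (is.finite(x$sex_chisq$statistic %||% NA))
    cat(sprintf("sex across strata: chi-square = %.2f (df %d), p = %.4g\n",
                x$sex_chisq$statistic, x$sex_chisq$df, x$sex_chisq$p_value))
  invisible(x)
}

#' @export
print.continuum_estimates <- function(x, ...) {
  cat(sprintf("<continuum_estimates> %s\n", x$spec_name))
  cat(sprintf("  reference stratum: %s | adjusted for: %s | alpha = %g\n",
              x$reference_stratum,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(none)",
              x$alpha))
  print(x$results, n = Inf)
  invisible(x)
}

#' Tidy a continuum-estimates object
#'
#' @param x A `continuum_estimates` object.
#' @param ... Unused.
#' @return The long-form results tibble (one row per stratum-by-element).
#' @export
tidy.continuum_estimates <- function(x, ...) x$results

#' One-row summary of a continuum-estimates object
#'
#' @param x A `continuum_estimates` object.
#' @param ... Unused.
#' @return A one-row tibble: spec name, reference stratum, counts of strata,
#'   elements, significant and degenerate results, alpha.
#' @export
glance.continuum_estimates <- function(x, ...) {
  tibble::tibble(
    spec_name = x$spec_name,
    reference_stratum = x$reference_stratum,
    n_strata = length(x$strata),
    n_elements = length(x$element_order),
    n_significant = sum(x$results$significant),
    n_degenerate = sum(x$results$degenerate),
    alpha = x$alpha)
}

#' @rdname tidy.continuum_estimates
#' @export
tidy.cohort_descriptives <- function(x, ...) x$by_stratum

#' @rdname glance.continuum_estimates
#' @export
glance.cohort_descriptives <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    n_strata = nrow(x$by_stratum),
    age_anova_f = x$age_anova$statistic,
    age_anova_p = x$age_anova$p_value,
    sex_chisq = x$sex_chisq$statistic,
    sex_chisq_p = x$sex_chisq$p_value)
}
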