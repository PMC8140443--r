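#' Match normalized codes against a code criterion
#'
#' A code satisfies the criterion iff it was recorded in the criterion's code
#' system and starts with any of its prefixes (`NULL` prefixes match any
#' code). Codes are expected normalized; raw codes are normalized defensively.
#'
#' @param code Character vector of codes.
#' @param criterion A [code_criterion()].
#' @param code_system Character vector (recycled) giving the system each code
#'   was recorded in.
#' @return Logical vector.
#' @export
match_code <- function(code, criterion, code_system = criterion$code_system) {
  code <- normalize_code(code)
  system_ok <- code_system == criterion$code_system
  if (is.null(criterion$prefixes)) return(system_ok & !is.na(code))
  hit <- rep(FALSE, length(code))
  for (p in criterion$prefixes)
    hit <- hit | stringr::str_starts(code, stringr::fixed(p))
  system_ok & hit
}

#' Index infection date for every cohort patient
#'
#' The index infection date anchors the post-diagnosis time windows (e.g. the
#' 90-day surgical window): it is the EARLIEST diagnosis date among the
#' spec's anchor elements (for the default model: osteomyelitis, septic
#' arthritis, infectious myositis). Patients with no qualifying diagnosis get
#' `NA` and fail cohort inclusion in [derive_element_matrix()].
#'
#' @param cohort A [cohort_dataset()].
#' @param spec A `continuum_spec` with non-empty `anchor_elements`.
#' @return Tibble with columns `patient_id`, `index_date` (`NA` when absent).
#' @export
index_infection_date <- function(cohort, spec) {
  if (!length(spec$anchor_elements))
    stop("spec has no anchor_elements; cannot derive an index infection date",
         call. = FALSE)
  rules <- all_rules(spec)[spec$anchor_elements]
  dx <- cohort$diagnoses
  hit <- rep(FALSE, nrow(dx))
  for (r in rules)
    for (cc in r$code_criteria)
      if (cc$code_system %in% c("ICD9", "ICD10"))
        hit <- hit | match_code(dx$code, cc, dx$code_system)
  anchors <- dx[hit, c("patient_id", "date")] |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(index_date = min(.data$date), .groups = "drop")
  cohort$patients |>
    dplyr::select("patient_id") |>
    dplyr::left_join(anchors, by = "patient_id")
}

#' Is an event date inside an anchored time window?
#'
#' Both bounds are inclusive: TRUE iff
#' `anchor + start_offset_days <= event_date <= anchor + end_offset_days`.
#'
#' @param event_date,anchor Date vectors (recycled).
#' @param window A [time_window()].
#' @return Logical vector; `NA` anchors yield FALSE.
#' @export
within_window <- function(event_date, anchor, window) {
  ok <- event_date >= anchor + window$start_offset_days &
    event_date <= anchor + window$end_offset_days
  ok & !is.na(ok)
}

# restrict dated events to a rule's window (no-op when rule has no window)
apply_window <- function(events, rule, anchor_dates) {
  if (is.null(rule$window)) return(events)
  if (is.null(anchor_dates))
    stop(sprintf("element '%s' has a time window but no anchor dates given",
                 rule$element_id), call. = FALSE)
  ev <- dplyr::left_join(events, anchor_dates, by = "patient_id")
  ev[within_window(ev$date, ev$index_date, rule$window),
     names(events), drop = FALSE]
}

#' Evaluate one element rule for every cohort patient
#'
#' Disjunction semantics: the element is TRUE iff any code, lab, or
#' medication criterion is satisfied. Lab criteria apply their aggregation
#' (max/min/any) over the patient's results for the analyte in the
#' criterion's units — results in other units are skipped with a warning —
#' then the comparator. Composite rules are TRUE iff at least `min_count`
#' member elements are TRUE in `resolved`. Windowed code criteria only count
#' events inside the anchored window.
#'
#' @param cohort A [cohort_dataset()].
#' @param rule An [element_rule()].
#' @param anchor_dates Tibble `patient_id`/`index_date` from
#'   [index_infection_date()]; required when the rule is windowed.
#' @param resolved Named list or tibble of logical vectors for already
#'   resolved elements; required for composite rules.
#' @return Logical vector named by `patient_id`, in patients-table order.
#' @export
evaluate_rule <- function(cohort, rule, anchor_dates = NULL,
                          resolved = NULL) {
  ids <- cohort$patients$patient_id
  result <- stats::setNames(rep(FALSE, length(ids)), ids)

  if (!is.null(rule$composite)) {
    comp <- rule$composite
    missing <- setdiff(comp$member_elements, names(resolved))
    if (length(missing))
      stop(sprintf("composite element '%s' references unresolved member(s): %s",
                   rule$element_id, paste(missing, collapse = ", ")),
           call. = FALSE)
    counts <- Reduce(`+`, purrr::map(comp$member_elements,
                                     ~ as.integer(resolved[[.x]])))
    return(stats::setNames(counts >= comp$min_count, ids))
  }

  mark <- function(pids) result[unique(pids)] <<- TRUE

  for (cc in rule$code_criteria) {
    events <- if (cc$code_system == "procedure") {
      pr <- cohort$procedures
      if (cc$require_amputation)
        pr <- pr[!is.na(pr$is_amputation) & pr$is_amputation == 1L, ,
                 drop = FALSE]
      hit <- match_code(pr$code, cc, "procedure")
      pr[hit, c("patient_id", "date"), drop = FALSE]
    } else {
      dx <- cohort$diagnoses
      hit <- match_code(dx$code, cc, dx$code_system)
      dx[hit, c("patient_id", "date"), drop = FALSE]
    }
    events <- apply_window(events, rule, anchor_dates)
    mark(events$patient_id)
  }

  for (lc in rule$lab_criteria) {
    lb <- cohort$labs[cohort$labs$analyte == lc$analyte, , drop = FALSE]
    unit_ok <- lb$units == lc$units
    if (any(!unit_ok))
      warning(sprintf(
        "skipping %d '%s' lab result(s) recorded in units other than '%s' (found: %s)",
        sum(!unit_ok), lc$analyte, lc$units,
        paste(unique(lb$units[!unit_ok]), collapse = ", ")), call. = FALSE)
    lb <- lb[unit_ok & !is.na(lb$value), , drop = FALSE]
    if (nrow(lb)) {
      agg <- lb |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::summarise(stat = switch(lc$aggregation,
                                       max = max(.data$value),
                                       min = min(.data$value),
                                       any = NA_real_),
                         any_hit = switch(lc$comparator,
                                          ge = any(.data$value >= lc$threshold),
                                          le = any(.data$value <= lc$threshold)),
                         .groups = "drop")
      ok <- if (lc$aggregation == "any") agg$any_hit
      else switch(lc$comparator,
                  ge = agg$stat >= lc$threshold,
                  le = agg$stat <= lc$threshold)
      mark(agg$patient_id[ok])
    }
  }

  for (mc in rule$med_criteria) {
    md <- cohort$medications
    hit <- tolower(md$drug_class) %in% mc$drug_classes
    if ("route" %in% names(md) && length(mc$exclude_routes))
      hit <- hit & !(tolower(md$route) %in% mc$exclude_routes &
                       !is.na(md$route))
    mark(md$patient_id[hit])
  }

  result
}

#' Derive the patient-by-element indicator matrix
#'
#' Applies every element rule of the spec to the cohort: patients lacking any
#' anchoring musculoskeletal-infection diagnosis are excluded first (cohort
#' inclusion criterion, logged), atomic elements (cycle and helper) are
#' evaluated next, and composite elements last in one topological pass. The
#' result is a tibble with one row per included patient — `patient_id`,
#' `stratum`, `age_years`, `sex`, then one logical column per cycle element
#' in clockwise axis order — a deterministic function of (cohort, spec).
#'
#' @param cohort A [cohort_dataset()].
#' @param spec A valid `continuum_spec`.
#' @return Element-matrix tibble.
#' @export
derive_element_matrix <- function(cohort, spec) {
  if (!nrow(cohort$patients))
    stop("cohort has no patients", call. = FALSE)
  assert_valid_spec(spec)

  anchor_dates <- index_infection_date(cohort, spec)
  excluded <- anchor_dates$patient_id[is.na(anchor_dates$index_date)]
  if (length(excluded))
    log_info("excluding %d patient(s) without a qualifying infection diagnosis",
             length(excluded))
  keep <- setdiff(cohort$patients$patient_id, excluded)
  if (!length(keep))
    stop("no patients satisfy the cohort inclusion criteria", call. = FALSE)
  cohort$patients <- cohort$patients[cohort$patients$patient_id %in% keep, ,
                                     drop = FALSE]
  anchor_dates <- anchor_dates[anchor_dates$patient_id %in% keep, ,
                               drop = FALSE]

  rules <- all_rules(spec)
  atomic <- rules[purrr::map_lgl(rules, ~ is.null(.x$composite))]
  composite <- rules[purrr::map_lgl(rules, ~ !is.null(.x$composite))]

  resolved <- list()
  for (r in atomic)
    resolved[[r$element_id]] <- evaluate_rule(cohort, r, anchor_dates)
  for (r in composite)
    resolved[[r$element_id]] <- evaluate_rule(cohort, r, anchor_dates,
                                              resolved)

  cycle <- continuum_elements(spec)
  for (id in cycle)
    log_info("element %-28s: %d of %d patients TRUE", id,
             sum(resolved[[id]]), length(keep))

  dplyr::bind_cols(
    cohort$patients[, c("patient_id", "stratum", "age_years", "sex")],
    tibble::as_tibble(resolved[cycle])
  )
}
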