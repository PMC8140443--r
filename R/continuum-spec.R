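#' Build a cyclical continuum specification
#'
#' A continuum specification arranges clinical *phases* around a closed cycle,
#' each phase holding one or more *elements* of care (risk factors, outcomes,
#' interventions) with declarative classification rules. Phase order and the
#' order of elements within phases define the clockwise axis order used
#' everywhere downstream: the element-matrix columns, the estimates table, and
#' the radar axes.
#'
#' @param name Short name for the continuum model.
#' @param phases List of [phase()] objects, in cycle order.
#' @param index_element Element id whose crude odds select the reference
#'   stratum (see [select_reference_stratum()]).
#' @param helper_elements Optional list of atomic [element_rule()]s that are
#'   evaluated so composite elements and the infection anchor can refer to
#'   them, but that do not appear as axes of the cycle (e.g. septic arthritis
#'   feeding a "two or more infection types" composite).
#' @param anchor_elements Character vector of element ids (cycle or helper)
#'   whose earliest diagnosis date defines each patient's index infection
#'   date; patients with no qualifying diagnosis fail cohort inclusion.
#' @param spec_version Schema version string written to serialized files.
#'
#' @return An object of class `continuum_spec`.
#' @seealso [default_msk_spec()], [validate_spec()], [load_continuum_spec()]
#' @export
continuum_spec <- function(name, phases, index_element,
                           helper_elements = list(),
                           anchor_elements = character(),
                           spec_version = "1") {
  spec <- structure(
    list(
      name = as.character(name),
      spec_version = as.character(spec_version),
      phases = phases,
      index_element = as.character(index_element),
      helper_elements = helper_elements,
      anchor_elements = as.character(anchor_elements)
    ),
    class = "continuum_spec"
  )
  spec
}

#' Define one phase of a continuum
#'
#' @param label Phase label (e.g. "primary risk factors").
#' @param elements List of [element_rule()]s in clockwise order.
#' @return An object of class `continuum_phase`.
#' @export
phase <- function(label, elements) {
  structure(list(label = as.character(label), elements = elements),
            class = "continuum_phase")
}

#' Define the classification rule for one element of care
#'
#' An element is TRUE for a patient iff at least one of its criteria is
#' satisfied (a disjunction), with one exception: an element carrying a
#' [composite_criterion()] is defined by the composite alone and may not mix
#' in other criteria. A [time_window()] constrains which dated diagnosis or
#' procedure events may satisfy the code criteria.
#'
#' @param element_id Unique identifier (snake_case by convention).
#' @param code_criteria List of [code_criterion()].
#' @param lab_criteria List of [lab_criterion()].
#' @param med_criteria List of [med_criterion()].
#' @param composite A [composite_criterion()] or NULL.
#' @param window A [time_window()] or NULL.
#' @return An object of class `element_rule`.
#' @export
element_rule <- function(element_id, code_criteria = list(),
                         lab_criteria = list(), med_criteria = list(),
                         composite = NULL, window = NULL) {
  structure(
    list(element_id = as.character(element_id),
         code_criteria = code_criteria,
         lab_criteria = lab_criteria,
         med_criteria = med_criteria,
         composite = composite,
         window = window),
    class = "element_rule"
  )
}

#' Criterion matching diagnosis or procedure codes by prefix
#'
#' Codes are compared after normalization (dots stripped, upper-cased); a code
#' satisfies the criterion iff it starts with any listed prefix and was
#' recorded in the same code system. `prefixes = NULL` matches *any* code of
#' the system (used for "any surgical procedure"). `require_amputation` keeps
#' only procedure rows explicitly flagged as amputations, since amputation
#' code systems vary across sites.
#'
#' @param code_system One of `"ICD9"`, `"ICD10"`, `"procedure"`.
#' @param prefixes Character vector of code prefixes, or NULL for match-any.
#' @param require_amputation For `code_system = "procedure"` only: restrict to
#'   rows with `is_amputation = 1`.
#' @return An object of class `code_criterion`.
#' @export
code_criterion <- function(code_system, prefixes = NULL,
                           require_amputation = FALSE) {
  structure(
    list(code_system = as.character(code_system),
         prefixes = if (is.null(prefixes)) NULL else
           normalize_code(as.character(prefixes)),
         require_amputation = isTRUE(require_amputation)),
    class = "code_criterion"
  )
}

#' Criterion on laboratory results
#'
#' The aggregation is applied over all of a patient's results for the analyte
#' (in the stated units) and the aggregate is compared against the threshold,
#' e.g. maximum hemoglobin A1c >= 6.5%. Results recorded in other units are
#' skipped with a warning rather than silently converted.
#'
#' @param analyte Analyte name as recorded in the labs table.
#' @param aggregation `"max"`, `"min"`, or `"any"` (any single result).
#' @param comparator `"ge"` or `"le"`.
#' @param threshold Finite numeric threshold.
#' @param units Required units string (default `"%"`).
#' @return An object of class `lab_criterion`.
#' @export
lab_criterion <- function(analyte, aggregation = c("max", "min", "any"),
                          comparator = c("ge", "le"), threshold,
                          units = "%") {
  structure(
    list(analyte = as.character(analyte),
         aggregation = match.arg(aggregation),
         comparator = match.arg(comparator),
         threshold = as.numeric(threshold),
         units = as.character(units)),
    class = "lab_criterion"
  )
}

#' Criterion on medication prescriptions
#'
#' Satisfied iff the patient has at least one medication row whose drug class
#' is in `drug_classes`, excluding rows whose route (when recorded) is listed
#' in `exclude_routes` — e.g. systemic antimicrobials exclude topical routes.
#'
#' @param drug_classes Character vector of drug-class labels (matched
#'   case-insensitively and exactly).
#' @param exclude_routes Routes to exclude, default `"topical"`.
#' @return An object of class `med_criterion`.
#' @export
med_criterion <- function(drug_classes, exclude_routes = "topical") {
  structure(
    list(drug_classes = tolower(as.character(drug_classes)),
         exclude_routes = tolower(as.character(exclude_routes))),
    class = "med_criterion"
  )
}

#' Composite criterion over previously resolved elements
#'
#' TRUE iff at least `min_count` of the member elements are TRUE for the
#' patient. Members must be atomic elements (no composite-of-composite), so
#' composites are well-defined in a single topological pass after all atomic
#' elements.
#'
#' @param member_elements Character vector of element ids.
#' @param min_count Positive integer, at most `length(member_elements)`.
#' @return An object of class `composite_criterion`.
#' @export
composite_criterion <- function(member_elements, min_count = 2L) {
  structure(
    list(member_elements = as.character(member_elements),
         min_count = as.integer(min_count)),
    class = "composite_criterion"
  )
}

#' Time window anchored at the index infection date
#'
#' Both offsets are in days and both bounds are inclusive: an event qualifies
#' iff `anchor + start_offset_days <= event_date <= anchor + end_offset_days`.
#' "Three months" is fixed as 90 days because calendar-month arithmetic is
#' locale-ambiguous.
#'
#' @param anchor Only `"index_infection_date"` is supported.
#' @param start_offset_days,end_offset_days Integer day offsets.
#' @return An object of class `time_window`.
#' @export
time_window <- function(anchor = "index_infection_date",
                        start_offset_days = 0L, end_offset_days = 90L) {
  structure(
    list(anchor = as.character(anchor),
         start_offset_days = as.integer(start_offset_days),
         end_offset_days = as.integer(end_offset_days)),
    class = "time_window"
  )
}

#' Cycle element ids of a continuum spec, in clockwise axis order
#'
#' @param spec A `continuum_spec`.
#' @param helpers Include helper elements (appended after cycle elements)?
#' @return Character vector of element ids.
#' @export
continuum_elements <- function(spec, helpers = FALSE) {
  ids <- unlist(purrr::map(spec$phases, function(ph)
    purrr::map_chr(ph$elements, "element_id")), use.names = FALSE)
  if (helpers)
    ids <- c(ids, purrr::map_chr(spec$helper_elements, "element_id"))
  ids
}

#' Phase label for each cycle element
#'
#' @param spec A `continuum_spec`.
#' @return Tibble with columns `element_id`, `phase`.
#' @export
continuum_phases <- function(spec) {
  purrr::map_dfr(spec$phases, function(ph)
    tibble::tibble(element_id = purrr::map_chr(ph$elements, "element_id"),
                   phase = ph$label))
}

# all element rules keyed by id (cycle first, then helpers)
all_rules <- function(spec) {
  rules <- c(unlist(purrr::map(spec$phases, "elements"), recursive = FALSE),
             spec$helper_elements)
  stats::setNames(rules, purrr::map_chr(rules, "element_id"))
}

#' Validate a continuum specification
#'
#' Validation is total: malformed specs yield findings, never errors. Each
#' finding carries a machine-readable `code`, the `path` of the offending
#' phase/element, and a human-readable `message`. A spec is valid iff the
#' report has zero rows.
#'
#' @param spec A `continuum_spec`.
#' @return Tibble with columns `code`, `path`, `message`.
#' @export
validate_spec <- function(spec) {
  findings <- list()
  add <- function(code, path, message) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(code = code, path = path, message = message)
  }

  if (!length(spec$phases))
    add("empty_spec", "phases", "spec has no phases")

  for (i in seq_along(spec$phases)) {
    ph <- spec$phases[[i]]
    if (!length(ph$elements))
      add("empty_phase", paste0("phases[", i, "]"),
          sprintf("phase '%s' has no elements", ph$label))
  }

  rules <- all_rules(spec)
  ids <- names(rules)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup)
    add("duplicate_element", d,
        sprintf("element id '%s' is defined more than once", d))

  if (length(spec$phases) &&
      !spec$index_element %in% continuum_elements(spec))
    add("unknown_index_element", spec$index_element,
        sprintf("index_element '%s' is not a cycle element",
                spec$index_element))

  atomic_ids <- ids[purrr::map_lgl(rules, ~ is.null(.x$composite))]
  for (id in ids) {
    r <- rules[[id]]
    n_atomic <- length(r$code_criteria) + length(r$lab_criteria) +
      length(r$med_criteria)
    if (is.null(r$composite) && n_atomic == 0L)
      add("no_criteria", id, sprintf("element '%s' has no criteria", id))
    if (!is.null(r$composite)) {
      if (n_atomic > 0L)
        add("mixed_composite", id,
            sprintf("composite element '%s' also lists atomic criteria", id))
      comp <- r$composite
      for (m in comp$member_elements) {
        if (!m %in% ids)
          add("unresolved_reference", id,
              sprintf("composite member '%s' is not a defined element", m))
        else if (!m %in% atomic_ids)
          add("composite_of_composite", id,
              sprintf("composite member '%s' is itself composite", m))
      }
      if (comp$min_count < 1L || comp$min_count > length(comp$member_elements))
        add("bad_min_count", id,
            sprintf("min_count %d outside 1..%d", comp$min_count,
                    length(comp$member_elements)))
    }
    for (cc in r$code_criteria) {
      if (!cc$code_system %in% c("ICD9", "ICD10", "procedure"))
        add("bad_code_system", id,
            sprintf("unknown code system '%s'", cc$code_system))
      if (!is.null(cc$prefixes) && any(!nzchar(cc$prefixes)))
        add("empty_prefix", id, "code prefix is empty after normalization")
    }
    for (lc in r$lab_criteria) {
      if (!is.finite(lc$threshold))
        add("nonfinite_threshold", id,
            sprintf("lab threshold for '%s' is not finite", lc$analyte))
    }
    if (!is.null(r$window)) {
      if (r$window$anchor != "index_infection_date")
        add("bad_anchor", id,
            sprintf("unsupported window anchor '%s'", r$window$anchor))
      if (r$window$start_offset_days > r$window$end_offset_days)
        add("inverted_window", id,
            sprintf("window start offset %d exceeds end offset %d",
                    r$window$start_offset_days, r$window$end_offset_days))
    }
  }

  for (a in spec$anchor_elements) {
    if (!a %in% ids)
      add("unknown_anchor_element", a,
          sprintf("anchor element '%s' is not defined", a))
  }

  if (length(findings)) dplyr::bind_rows(findings)
  else tibble::tibble(code = character(), path = character(),
                      message = character())
}

# stop with a readable message when a spec is invalid
assert_valid_spec <- function(spec) {
  rep <- validate_spec(spec)
  if (nrow(rep) > 0L)
    stop("invalid continuum spec:\n",
         paste0("  [", rep$code, "] ", rep$path, ": ", rep$message,
                collapse = "\n"),
         call. = FALSE)
  invisible(spec)
}

#' The default musculoskeletal-infection continuum
#'
#' Four clinical phases with two elements each, arranged clockwise:
#' primary risk factors (diabetes mellitus, peripheral vascular disease),
#' secondary risk factors (osteomyelitis, two-or-more infection types),
#' infection-related outcomes (sepsis, systemic antibiotics), and surgical
#' interventions (any surgical procedure, amputation). Diabetes is satisfied
#' by any diabetes diagnosis code, a maximum hemoglobin A1c >= 6.5%, or a
#' prescription for a diabetes medication. Surgical procedure and amputation
#' only count events within 0--90 days (inclusive) of the index infection
#' date, the earliest musculoskeletal-infection diagnosis. The reference
#' stratum is selected by the lowest crude odds of the index element,
#' diabetes mellitus.
#'
#' The shipped ICD-9/ICD-10 prefix lists and drug-class vocabularies are
#' ILLUSTRATIVE defaults for testing and demonstration; sites must supply
#' their own curated code sets for real analyses.
#'
#' @return A validated `continuum_spec` with 8 cycle elements in 4 phases.
#' @export
default_msk_spec <- function() {
  spec <- continuum_spec(
    name = "msk_infection_continuum",
    phases = list(
      phase("primary risk factors", list(
        element_rule(
          "diabetes_mellitus",
          code_criteria = list(
            code_criterion("ICD9", c("249", "250")),
            code_criterion("ICD10", c("E08", "E09", "E10", "E11", "E13"))),
          lab_criteria = list(
            lab_criterion("hba1c", "max", "ge", 6.5, units = "%")),
          med_criteria = list(
            med_criterion(c("insulin", "metformin", "sulfonylurea",
                            "thiazolidinedione", "dpp4_inhibitor",
                            "glp1_agonist", "sglt2_inhibitor")))),
        element_rule(
          "peripheral_vascular_disease",
          code_criteria = list(
            code_criterion("ICD9", c("4439", "440")),
            code_criterion("ICD10", c("I70", "I739")))))),
      phase("secondary risk factors", list(
        element_rule(
          "osteomyelitis",
          code_criteria = list(
            code_criterion("ICD9", "730"),
            code_criterion("ICD10", "M86"))),
        element_rule(
          "multiple_infections",
          composite = composite_criterion(
            c("osteomyelitis", "septic_arthritis", "infectious_myositis"),
            min_count = 2L)))),
      phase("infection-related outcomes", list(
        element_rule(
          "sepsis",
          code_criteria = list(
            code_criterion("ICD9", c("038", "99591", "99592")),
            code_criterion("ICD10", c("A40", "A41", "R652")))),
        element_rule(
          "antibiotics",
          med_criteria = list(
            med_criterion(c("penicillin", "cephalosporin", "fluoroquinolone",
                            "glycopeptide", "macrolide", "tetracycline",
                            "carbapenem", "aminoglycoside", "lincosamide",
                            "oxazolidinone", "sulfonamide_antibiotic"),
                          exclude_routes = "topical"))))),
      phase("surgical interventions", list(
        element_rule(
          "surgical_procedure",
          code_criteria = list(code_criterion("procedure", NULL)),
          window = time_window("index_infection_date", 0L, 90L)),
        element_rule(
          "amputation",
          code_criteria = list(
            code_criterion("procedure", NULL, require_amputation = TRUE)),
          window = time_window("index_infection_date", 0L, 90L))))
    ),
    index_element = "diabetes_mellitus",
    helper_elements = list(
      element_rule(
        "septic_arthritis",
        code_criteria = list(
          code_criterion("ICD9", "711"),
          code_criterion("ICD10", "M00"))),
      element_rule(
        "infectious_myositis",
        code_criteria = list(
          code_criterion("ICD9", "72886"),
          code_criterion("ICD10", "M600")))
    ),
    anchor_elements = c("osteomyelitis", "septic_arthritis",
                        "infectious_myositis")
  )
  assert_valid_spec(spec)
}

#' @export
print.continuum_spec <- function(x, ...) {
  cat(sprintf("<continuum_spec> %s (schema v%s)\n", x$name, x$spec_version))
  for (ph in x$phases) {
    cat(sprintf("  phase: %s\n", ph$label))
    for (el in ph$elements) cat(sprintf("    - %s\n", el$element_id))
  }
  cat(sprintf("  index element: %s\n", x$index_element))
  if (length(x$helper_elements))
    cat("  helpers:", paste(purrr::map_chr(x$helper_elements, "element_id"),
                            collapse = ", "), "\n")
  invisible(x)
}

# ---- YAML serialization -----------------------------------------------------

criterion_to_list <- function(x) {
  out <- unclass(x)
  out[!purrr::map_lgl(out, is.null)]
}

rule_to_list <- function(r) {
  out <- list(element_id = r$element_id)
  if (length(r$code_criteria))
    out$code_criteria <- purrr::map(r$code_criteria, criterion_to_list)
  if (length(r$lab_criteria))
    out$lab_criteria <- purrr::map(r$lab_criteria, criterion_to_list)
  if (length(r$med_criteria))
    out$med_criteria <- purrr::map(r$med_criteria, criterion_to_list)
  if (!is.null(r$composite)) out$composite <- criterion_to_list(r$composite)
  if (!is.null(r$window)) out$window <- criterion_to_list(r$window)
  out
}

rule_from_list <- function(x) {
  element_rule(
    element_id = x$element_id,
    code_criteria = purrr::map(x$code_criteria %||% list(), function(cc)
      code_criterion(cc$code_system, cc$prefixes,
                     isTRUE(cc$require_amputation))),
    lab_criteria = purrr::map(x$lab_criteria %||% list(), function(lc)
      lab_criterion(lc$analyte, lc$aggregation, lc$comparator, lc$threshold,
                    lc$units %||% "%")),
    med_criteria = purrr::map(x$med_criteria %||% list(), function(mc)
      med_criterion(mc$drug_classes, mc$exclude_routes %||% character())),
    composite = if (!is.null(x$composite))
      composite_criterion(x$composite$member_elements, x$composite$min_count),
    window = if (!is.null(x$window))
      time_window(x$window$anchor, x$window$start_offset_days,
                  x$window$end_offset_days)
  )
}

#' Write a continuum spec to a YAML file
#'
#' @param spec A `continuum_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_continuum_spec <- function(spec, path) {
  doc <- list(
    spec_version = spec$spec_version,
    name = spec$name,
    index_element = spec$index_element,
    anchor_elements = as.list(spec$anchor_elements),
    phases = purrr::map(spec$phases, function(ph)
      list(label = ph$label,
           elements = purrr::map(ph$elements, rule_to_list))),
    helper_elements = purrr::map(spec$helper_elements, rule_to_list)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load and validate a continuum spec from a YAML file
#'
#' Ordering in the file (phases, elements within phases) is preserved and
#' defines the cycle's clockwise axis order. The file must follow the schema
#' written by [write_continuum_spec()]; the packaged reference copy of the
#' default musculoskeletal model is at
#' `system.file("extdata", "msk_continuum.yaml", package = "carecycle")`.
#'
#' @param path Path to a YAML continuum definition.
#' @return A validated `continuum_spec`.
#' @export
load_continuum_spec <- function(path) {
  if (!file.exists(path))
    stop("continuum spec file not found: ", path, call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("failed to parse continuum spec '", path, "': ",
         conditionMessage(e), call. = FALSE))
  for (fld in c("name", "index_element", "phases"))
    if (is.null(doc[[fld]]))
      stop("continuum spec '", path, "' is missing field '", fld, "'",
           call. = FALSE)
  spec <- continuum_spec(
    name = doc$name,
    phases = purrr::map(doc$phases, function(ph)
      phase(ph$label, purrr::map(ph$elements, rule_from_list))),
    index_element = doc$index_element,
    helper_elements = purrr::map(doc$helper_elements %||% list(),
                                 rule_from_list),
    anchor_elements = unlist(doc$anchor_elements %||% character()),
    spec_version = doc$spec_version %||% "1"
  )
  assert_valid_spec(spec)
}
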