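# estimates object built directly, without fitting, for geometry tests
manual_estimates <- function(ors, strata = names(ors[[1]]),
                             reference = "ref", alpha = 0.05) {
  elements <- names(ors)
  rows <- purrr::imap_dfr(ors, function(v, el) {
    tibble::tibble(
      stratum = c(reference, names(v)), element_id = el,
      or = c(1, unname(v)),
      ci_low = c(NA, unname(v) * 0.8), ci_high = c(NA, unname(v) * 1.25),
      p_value = c(NA, rep(0.5, length(v))),
      significant = c(FALSE, unname(v) * 0.8 > 1 | unname(v) * 1.25 < 1),
      n_stratum = 100L, n_events_stratum = 50L,
      degenerate = c(FALSE, is.na(unname(v))),
      is_reference = c(TRUE, rep(FALSE, length(v))))
  })
  structure(
    list(spec_name = "msk_infection_continuum", reference_stratum = reference,
         covariates = c("age_years", "sex"), alpha = alpha,
         element_order = elements, strata = c(reference, strata),
         results = dplyr::mutate(rows, or = ifelse(degenerate, NA, or))),
    class = "continuum_estimates")
}

spec8 <- default_msk_spec()
els <- continuum_elements(spec8)

test_that("polar layout: equally spaced clockwise axes from 12 o'clock", {
  ors <- purrr::map(stats::setNames(els, els),
                    ~ c(A = 1.5, B = 0.8))
  est <- manual_estimates(ors)
  layout <- to_polar_layout(spec8, est)

  expect_length(layout$angles_deg, 8L)
  expect_equal(layout$angles_deg[1], 90)                 # 12 o'clock
  expect_equal(unique(diff(layout$angles_deg)), -45)     # clockwise, 45 deg
  expect_equal(layout$elements, els)

  # OR = 1 sits at transformed radius 0, the centre of the symmetric range
  expect_equal(log(1), 0)
  expect_equal(mean(layout$radial_limits), 0)
  expect_equal(carecycle:::lnor_to_radius(0, layout, 100), 50)

  # natural-log transform: OR 2.74 maps to radial value ln(2.74)
  expect_equal(log(2.74), 1.0080, tolerance = 1e-4)

  # range covers observations, padded to a power-of-two ring
  expect_true(all(abs(log(c(1.5, 0.8))) <= layout$radial_limits[2]))
  expect_equal(layout$radial_limits[2], log(2))
  expect_true(1 %in% layout$ticks_or)

  # all-degenerate estimates cannot be laid out
  est_d <- manual_estimates(purrr::map(ors, ~ c(A = NA_real_)))
  expect_error(to_polar_layout(spec8, est_d), "degenerate")
})

test_that("radial range padding respects large odds ratios", {
  ors <- purrr::map(stats::setNames(els, els), ~ c(A = 1.2))
  ors$amputation <- c(A = 5.2)                      # ln 5.2 ~ 1.65
  layout <- to_polar_layout(spec8, manual_estimates(ors))
  expect_equal(layout$radial_limits[2], 3 * log(2))  # next ring: OR 8
  expect_true(all(c(0.25, 0.5, 1, 2, 4, 8) %in% layout$ticks_or))
})

test_that("identical estimates render byte-identical SVG", {
  ors <- purrr::map(stats::setNames(els, els),
                    ~ c(A = 1.4, B = 0.7, C = 2.1, D = 1.0))
  est <- manual_estimates(ors)
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_radar(est, f1, spec = spec8)
  render_radar(est, f2, spec = spec8)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("SVG polygon vertices match recomputed polar geometry within 0.5 px", {
  skip_if_not_installed("xml2")
  ors <- purrr::map(stats::setNames(seq_along(els), els),
                    ~ c(A = 0.6 + 0.2 * .x, B = 1.1))
  est <- manual_estimates(ors)
  layout <- to_polar_layout(spec8, est)
  path <- withr::local_tempfile(fileext = ".svg")
  render_radar(est, path, spec = spec8, strata = c("A", "B"))

  doc <- xml2::read_xml(path)
  polys <- xml2::xml_find_all(doc, "//*[@class='continuum-polygon']")
  expect_length(polys, 2L)

  # panel A is the first panel: centre derived from the documented layout
  panel_w <- 320; r_px <- 100
  cx <- panel_w / 2; cy <- 30 + r_px + 30
  th <- layout$angles_deg * pi / 180
  ors_A <- purrr::map_dbl(ors, "A")
  r <- carecycle:::lnor_to_radius(log(ors_A), layout, r_px)
  expected <- cbind(cx + r * cos(th), cy - r * sin(th))

  pts <- xml2::xml_attr(polys[[1]], "points")
  got <- do.call(rbind, lapply(strsplit(strsplit(pts, " ")[[1]], ","),
                               as.numeric))
  expect_equal(dim(got), dim(expected))
  expect_true(max(abs(got - expected)) < 0.5)
})

test_that("panels, unit polygons, significance marks, and gaps behave", {
  # every OR = 1: the polygon coincides with the reference ring
  unit <- manual_estimates(purrr::map(stats::setNames(els, els), ~ c(A = 1)))
  layout <- to_polar_layout(spec8, unit)
  path <- withr::local_tempfile(fileext = ".svg")
  render_radar(unit, path, spec = spec8)
  svg <- readLines(path)
  r_ring <- carecycle:::lnor_to_radius(0, layout, 100)
  poly <- grep('class="continuum-polygon"', svg, value = TRUE)
  pts <- sub('.*points="([^"]+)".*', "\\1", poly)
  got <- do.call(rbind, lapply(strsplit(strsplit(pts, " ")[[1]], ","),
                               as.numeric))
  radii <- sqrt((got[, 1] - 160)^2 + (got[, 2] - 160)^2)
  expect_true(max(abs(radii - r_ring)) < 0.5)

  # four panels for a five-stratum estimate set
  ors <- purrr::map(stats::setNames(els, els),
                    ~ c(A = 1.4, B = 0.7, C = 2.1, D = 1.0))
  est <- manual_estimates(ors)
  render_radar(est, path, spec = spec8)
  svg <- paste(readLines(path), collapse = "\n")
  expect_equal(lengths(regmatches(svg, gregexpr('font-weight="bold"', svg))),
               4L)

  # significant elements get an asterisked axis label: CI (1.10, 2.00) vs
  # CI (0.69, 1.52)
  sig <- manual_estimates(purrr::map(stats::setNames(els, els), ~ c(A = 1.1)))
  sig$results$ci_low <- ifelse(sig$results$is_reference, NA, 1.10)
  sig$results$ci_high <- ifelse(sig$results$is_reference, NA, 2.00)
  sig$results$significant <- !sig$results$is_reference
  sig$results$significant[sig$results$element_id == "sepsis"] <- FALSE
  render_radar(sig, path, spec = spec8)
  svg <- paste(readLines(path), collapse = "\n")
  expect_true(grepl("amputation\\*", svg))
  expect_false(grepl("sepsis\\*", svg))

  # a degenerate element breaks the polygon into polylines with a note
  gap <- manual_estimates(purrr::map(stats::setNames(els, els), ~ c(A = 1.3)))
  gap$results$or[gap$results$element_id == "sepsis" &
                   !gap$results$is_reference] <- NA
  gap$results$degenerate[gap$results$element_id == "sepsis" &
                           !gap$results$is_reference] <- TRUE
  render_radar(gap, path, spec = spec8)
  svg <- paste(readLines(path), collapse = "\n")
  expect_true(grepl("<polyline", svg))
  expect_false(grepl("<polygon", svg))
  expect_true(grepl("degenerate fit", svg))

  expect_error(render_radar(est, path, spec = spec8, strata = "nope"),
               "unknown stratum")
})

test_that("png rendering and autoplot produce output without error", {
  ors <- purrr::map(stats::setNames(els, els), ~ c(A = 1.4, B = 0.7))
  est <- manual_estimates(ors)
  png_path <- withr::local_tempfile(fileext = ".png")
  render_radar(est, png_path, spec = spec8, format = "png")
  expect_gt(file.size(png_path), 0)

  p <- autoplot(est)
  expect_s3_class(p, "ggplot")
})
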