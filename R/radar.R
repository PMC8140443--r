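#' Polar layout for a cyclical continuum figure
#'
#' Computes the shared geometry of a radar figure: one axis per cycle
#' element, equally spaced (360 / n degrees apart), the first element at 12
#' o'clock and order proceeding clockwise; a natural-log radial transform
#' with the OR = 1 ring at radius zero of the transformed scale; and a
#' radial range symmetric about zero covering all observed ln(OR), padded
#' outward to the nearest power-of-two tick. Tick rings are drawn at
#' OR in \{0.25, 0.5, 1, 2, 4, 8\} intersected with the range (extended by
#' further powers of two when estimates fall outside). All panels drawn from
#' one layout share the same radial scale, so figures are comparable across
#' strata.
#'
#' @param spec The `continuum_spec` (defines axis order and phase arcs).
#' @param estimates A `continuum_estimates` object.
#' @return An object of class `radar_layout`.
#' @export
to_polar_layout <- function(spec, estimates) {
  elements <- continuum_elements(spec)
  res <- estimates$results[!estimates$results$is_reference, , drop = FALSE]
  lnor <- log(res$or[!res$degenerate & !is.na(res$or)])
  if (!length(lnor))
    stop("all estimates are degenerate; no radar layout can be built",
         call. = FALSE)

  n <- length(elements)
  step <- 360 / n
  angles <- 90 - (seq_len(n) - 1L) * step  # degrees, clockwise from 12:00

  # symmetric radial limit, padded to the nearest power-of-two OR ring
  span <- max(abs(lnor), log(2))
  rmax <- log(2) * ceiling(span / log(2) - 1e-9)
  tick_or <- c(0.25, 0.5, 1, 2, 4, 8)
  k_max <- round(rmax / log(2))
  if (k_max > 3L)           # estimates beyond OR 8: extend by powers of two
    tick_or <- c(tick_or, 2^seq(4L, k_max), 2^-seq(4L, k_max))
  tick_or <- sort(tick_or[abs(log(tick_or)) <= rmax + 1e-9])

  phases <- continuum_phases(spec)
  phase_arcs <- phases |>
    dplyr::mutate(angle = angles[match(.data$element_id, elements)]) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(start_deg = max(.data$angle) + step / 2,
                     end_deg = min(.data$angle) - step / 2,
                     mid_deg = mean(.data$angle), .groups = "drop")

  structure(
    list(elements = elements, angles_deg = angles,
         radial_limits = c(-rmax, rmax), ticks_or = tick_or,
         phase_arcs = phase_arcs, transform = "natural log"),
    class = "radar_layout")
}

#' @export
print.radar_layout <- function(x, ...) {
  cat(sprintf("<radar_layout> %d axes, %s scale, OR range [%.3g, %.3g]\n",
              length(x$elements), x$transform,
              exp(x$radial_limits[1L]), exp(x$radial_limits[2L])))
  cat("  tick rings at OR:", paste(x$ticks_or, collapse = ", "), "\n")
  invisible(x)
}

# affine map from ln(OR) to pixel radius (0 at centre, r_px at outer ring)
lnor_to_radius <- function(lnor, layout, r_px) {
  (lnor - layout$radial_limits[1L]) / diff(layout$radial_limits) * r_px
}

fmt2 <- function(x) sprintf("%.2f", x)

# maximal runs of TRUE positions around a circle (indices in walking order);
# assumes not all TRUE
circular_runs <- function(ok) {
  n <- length(ok)
  if (!any(ok)) return(list())
  start <- which(!ok)[1L]                  # rotate so a FALSE comes first
  order <- ((start:(start + n - 1L) - 1L) %% n) + 1L
  runs <- list(); cur <- integer()
  for (i in order) {
    if (ok[i]) cur <- c(cur, i)
    else { if (length(cur)) runs[[length(runs) + 1L]] <- cur; cur <- integer() }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# one radar panel as a character vector of SVG fragments
radar_panel_svg <- function(est, layout, stratum, ox, oy, panel_w, panel_h,
                            r_px, annotate_values, color) {
  cx <- ox + panel_w / 2
  cy <- oy + 30 + r_px + 30
  th <- layout$angles_deg * pi / 180
  out <- character()
  add <- function(...) out <<- c(out, sprintf(...))

  add('<text x="%s" y="%s" text-anchor="middle" font-size="13" font-weight="bold">%s</text>',
      fmt2(cx), fmt2(oy + 18), svg_escape(stratum))

  for (t in layout$ticks_or) {
    r <- lnor_to_radius(log(t), layout, r_px)
    if (abs(t - 1) < 1e-12)
      add('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#555555" stroke-width="1.2" stroke-dasharray="4 3"/>',
          fmt2(cx), fmt2(cy), fmt2(r))
    else
      add('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#dddddd" stroke-width="0.8"/>',
          fmt2(cx), fmt2(cy), fmt2(r))
    add('<text x="%s" y="%s" font-size="7" fill="#888888">%s</text>',
        fmt2(cx + 2), fmt2(cy - r - 2), sub("\\.?0+$", "", sprintf("%.2f", t)))
  }

  res <- est$results[est$results$stratum == stratum, , drop = FALSE]
  res <- res[match(layout$elements, res$element_id), , drop = FALSE]

  for (i in seq_along(layout$elements)) {
    x2 <- cx + r_px * cos(th[i]); y2 <- cy - r_px * sin(th[i])
    add('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#cccccc" stroke-width="0.6"/>',
        fmt2(cx), fmt2(cy), fmt2(x2), fmt2(y2))
    lab <- layout$elements[i]
    if (isTRUE(res$significant[i])) lab <- paste0(lab, "*")
    lx <- cx + (r_px + 12) * cos(th[i]); ly <- cy - (r_px + 12) * sin(th[i])
    anchor <- if (abs(cos(th[i])) < 0.3) "middle"
    else if (cos(th[i]) > 0) "start" else "end"
    add('<text x="%s" y="%s" text-anchor="%s" font-size="8">%s</text>',
        fmt2(lx), fmt2(ly + 3), anchor, svg_escape(lab))
  }

  ok <- !res$degenerate & !is.na(res$or)
  r_v <- ifelse(ok, lnor_to_radius(log(res$or), layout, r_px), NA_real_)
  vx <- cx + r_v * cos(th); vy <- cy - r_v * sin(th)

  if (all(ok)) {
    pts <- paste(fmt2(vx), fmt2(vy), sep = ",", collapse = " ")
    add('<polygon class="continuum-polygon" id="poly-%s" points="%s" fill="%s" fill-opacity="0.15" stroke="%s" stroke-width="1.8"/>',
        gsub("[^A-Za-z0-9_-]", "_", stratum), pts, color, color)
  } else {
    # degenerate estimates break the polygon: draw maximal circular runs of
    # adjacent defined vertices as open polylines
    for (run in circular_runs(ok)) {
      if (length(run) < 2L) next
      pts <- paste(fmt2(vx[run]), fmt2(vy[run]), sep = ",", collapse = " ")
      add('<polyline class="continuum-polygon" points="%s" fill="none" stroke="%s" stroke-width="1.8"/>',
          pts, color)
    }
    add('<text x="%s" y="%s" font-size="7" fill="#888888">gaps: estimate unavailable (degenerate fit)</text>',
        fmt2(ox + 8), fmt2(oy + panel_h - 6))
  }

  for (i in which(ok)) {
    add('<circle cx="%s" cy="%s" r="2.2" fill="%s"/>',
        fmt2(vx[i]), fmt2(vy[i]), color)
    if (annotate_values)
      add('<text x="%s" y="%s" font-size="7" fill="#333333">%s</text>',
          fmt2(vx[i] + 4), fmt2(vy[i] - 4), sprintf("%.2f", res$or[i]))
  }
  out
}

#' Render cyclical continuum radar maps
#'
#' Draws one radar panel per requested stratum (default: every non-reference
#' stratum, mirroring a stratified disparity figure), arranged on a grid in a
#' single file. All panels share the layout's radial scale; the OR = 1
#' reference ring is dashed and visually distinct; axis labels of elements
#' whose confidence interval excludes 1.00 are suffixed with `*`; degenerate
#' estimates are drawn as gaps in the polygon rather than fabricated null
#' values. The SVG output is fully deterministic — identical estimates yield
#' byte-identical files.
#'
#' @param est A `continuum_estimates` object.
#' @param path Output file path.
#' @param spec Continuum spec (defaults to rebuilding the axis order stored
#'   in `est`); pass the spec used for estimation to get phase arcs.
#' @param layout Optional precomputed [to_polar_layout()] result.
#' @param strata Strata to draw; default all non-reference strata.
#' @param format `"svg"` (deterministic, primary) or `"png"`.
#' @param annotate_values Print the OR value at each vertex?
#' @param color Polygon color (colorblind-safe default).
#' @return `path`, invisibly.
#' @export
render_radar <- function(est, path, spec = NULL, layout = NULL,
                         strata = NULL, format = c("svg", "png"),
                         annotate_values = FALSE, color = "#0072B2") {
  format <- match.arg(format)
  stopifnot(inherits(est, "continuum_estimates"))
  if (is.null(layout)) {
    if (is.null(spec))
      stop("either `spec` or a precomputed `layout` is required",
           call. = FALSE)
    layout <- to_polar_layout(spec, est)
  }
  if (is.null(strata))
    strata <- setdiff(est$strata, est$reference_stratum)
  unknown <- setdiff(strata, est$strata)
  if (length(unknown))
    stop("unknown stratum: ", paste(unknown, collapse = ", "), call. = FALSE)

  panel_w <- 320; panel_h <- 330; r_px <- 100
  ncol <- min(2L, length(strata))
  nrow <- ceiling(length(strata) / ncol)
  fig_w <- panel_w * ncol
  fig_h <- panel_h * nrow + 40

  if (format == "png") {
    render_radar_png(est, path, layout, strata, annotate_values, color,
                     fig_w, fig_h, panel_w, panel_h, r_px, ncol)
    return(invisible(path))
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d" font-family="Helvetica, Arial, sans-serif">',
            fig_w, fig_h, fig_w, fig_h),
    sprintf('<rect width="%d" height="%d" fill="#ffffff"/>', fig_w, fig_h))
  for (k in seq_along(strata)) {
    ox <- ((k - 1L) %% ncol) * panel_w
    oy <- ((k - 1L) %/% ncol) * panel_h
    lines <- c(lines,
               radar_panel_svg(est, layout, strata[k], ox, oy, panel_w,
                               panel_h, r_px, annotate_values, color))
  }
  caption <- sprintf(
    "Odds ratios vs reference stratum '%s'%s; natural log radial scale; * = %d%% CI excludes 1.00",
    est$reference_stratum,
    if (length(est$covariates))
      paste0(", adjusted for ", paste(est$covariates, collapse = " and "))
    else "",
    round(100 * (1 - est$alpha)))
  lines <- c(lines,
             sprintf('<text x="%s" y="%s" font-size="9" fill="#444444">%s</text>',
                     fmt2(10), fmt2(fig_h - 12), svg_escape(caption)),
             '</svg>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# raster rendering of the same geometry via the png device
render_radar_png <- function(est, path, layout, strata, annotate_values,
                             color, fig_w, fig_h, panel_w, panel_h, r_px,
                             ncol) {
  grDevices::png(path, width = fig_w, height = fig_h, res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NULL, xlim = c(0, fig_w), ylim = c(fig_h, 0), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  th <- layout$angles_deg * pi / 180
  for (k in seq_along(strata)) {
    ox <- ((k - 1L) %% ncol) * panel_w
    oy <- ((k - 1L) %/% ncol) * panel_h
    cx <- ox + panel_w / 2; cy <- oy + 30 + r_px + 30
    graphics::text(cx, oy + 18, strata[k], font = 2, cex = 0.9)
    for (t in layout$ticks_or) {
      r <- lnor_to_radius(log(t), layout, r_px)
      a <- seq(0, 2 * pi, length.out = 181L)
      graphics::lines(cx + r * cos(a), cy - r * sin(a),
                      col = if (abs(t - 1) < 1e-12) "#555555" else "#dddddd",
                      lty = if (abs(t - 1) < 1e-12) 2L else 1L)
    }
    res <- est$results[est$results$stratum == strata[k], , drop = FALSE]
    res <- res[match(layout$elements, res$element_id), , drop = FALSE]
    for (i in seq_along(layout$elements)) {
      graphics::segments(cx, cy, cx + r_px * cos(th[i]),
                         cy - r_px * sin(th[i]), col = "#cccccc")
      lab <- layout$elements[i]
      if (isTRUE(res$significant[i])) lab <- paste0(lab, "*")
      graphics::text(cx + (r_px + 14) * cos(th[i]),
                     cy - (r_px + 14) * sin(th[i]), lab, cex = 0.5)
    }
    ok <- !res$degenerate & !is.na(res$or)
    r_v <- ifelse(ok, lnor_to_radius(log(res$or), layout, r_px), NA_real_)
    vx <- cx + r_v * cos(th); vy <- cy - r_v * sin(th)
    if (all(ok)) graphics::polygon(vx, vy, border = color, lwd = 2)
    else graphics::lines(vx, vy, col = color, lwd = 2)
    graphics::points(vx[ok], vy[ok], pch = 16, col = color, cex = 0.6)
    if (annotate_values)
      graphics::text(vx[ok] + 6, vy[ok] - 6, sprintf("%.2f", res$or[ok]),
                     cex = 0.5)
  }
}

#' Radar-style ggplot of continuum estimates
#'
#' A tidyverse-facing view of the same figure: ln(OR) polygons on polar
#' coordinates, one facet per non-reference stratum, dashed ring at OR = 1,
#' asterisked axis labels for significant elements. For publication-grade
#' deterministic output use [render_radar()].
#'
#' @param object A `continuum_estimates` object.
#' @param strata Strata to draw (default all non-reference).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.continuum_estimates <- function(object, strata = NULL, ...) {
  if (is.null(strata))
    strata <- setdiff(object$strata, object$reference_stratum)
  df <- object$results |>
    dplyr::filter(.data$stratum %in% strata, !.data$degenerate,
                  !.data$is_reference) |>
    dplyr::mutate(
      element_id = factor(.data$element_id, levels = object$element_order),
      lnor = log(.data$or))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$element_id, y = .data$lnor,
                                   group = .data$stratum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_polygon(fill = "#0072B2", alpha = 0.15,
                          color = "#0072B2", linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant),
                        color = "#0072B2", size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 8),
                                name = "CI excludes 1") +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = NULL, y = "ln(odds ratio)",
                  caption = sprintf("reference stratum: %s",
                                    object$reference_stratum)) +
    ggplot2::theme_minimal()
}
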