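#' Rendering specification
#'
#' Visual contract for the compass and its charts: band colors, canvas size,
#' and the width of the inner-edge minimum marker. SVG is the canonical
#' output (deterministic, parseable); PNG is derived from the same geometry
#' with base graphics.
#'
#' @param format `"svg"` or `"png"`.
#' @param size Canvas size in pixels (square canvas for the compass).
#' @param palette Named colors for `red`, `orange`, `green` and `missing`
#'   (neutral for unscorable areas/domains).
#' @param marker_frac Inner minimum-value band width as a fraction of the
#'   sector's radial extent, in (0, 0.5).
#' @param legend Draw a band legend (default `TRUE`).
#' @return List of class `rc_render_spec`.
#' @export
render_spec <- function(format = c("svg", "png"), size = 600,
                        palette = c(red = "#D62728", orange = "#FF7F0E",
                                    green = "#2CA02C", missing = "#BFBFBF"),
                        marker_frac = 0.18, legend = TRUE) {
  format <- match.arg(format)
  need <- c("red", "orange", "green", "missing")
  if (!all(need %in% names(palette)))
    rc_config_error(sprintf("palette must name all of: %s",
                            paste(need, collapse = ", ")))
  if (marker_frac <= 0 || marker_frac >= 0.5)
    rc_config_error("marker_frac must be in (0, 0.5)")
  structure(list(format = format, size = size, palette = palette,
                 marker_frac = marker_frac, legend = legend),
            class = "rc_render_spec")
}

fmt <- function(x) sprintf("%.3f", x)

band_fill <- function(b, spec) {
  fill <- spec$palette[b]
  if (any(is.na(fill)))
    rc_config_error(sprintf("palette has no color for band '%s'",
                            b[is.na(fill)][1L]))
  unname(fill)
}

# Annular-wedge path between radii r0 < r1 over [a0, a1] (radians, clockwise
# from 12 o'clock).
wedge_path <- function(cx, cy, r0, r1, a0, a1) {
  pt <- function(r, a) c(cx + r * sin(a), cy - r * cos(a))
  p1 <- pt(r1, a0); p2 <- pt(r1, a1); p3 <- pt(r0, a1); p4 <- pt(r0, a0)
  large <- if ((a1 - a0) > pi) 1 else 0
  paste0("M", fmt(p1[1]), ",", fmt(p1[2]),
         " A", fmt(r1), ",", fmt(r1), " 0 ", large, ",1 ",
         fmt(p2[1]), ",", fmt(p2[2]),
         " L", fmt(p3[1]), ",", fmt(p3[2]),
         " A", fmt(r0), ",", fmt(r0), " 0 ", large, ",0 ",
         fmt(p4[1]), ",", fmt(p4[2]), " Z")
}

svg_open <- function(w, h) {
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
                   "height=\"%d\" viewBox=\"0 0 %d %d\">"),
            round(w), round(h), round(w), round(h)))
}

svg_text <- function(x, y, s, size = 12, anchor = "middle") {
  sprintf(paste0("<text x=\"%s\" y=\"%s\" font-size=\"%d\" ",
                 "font-family=\"sans-serif\" text-anchor=\"%s\">%s</text>"),
          fmt(x), fmt(y), size, anchor, xml_escape(s))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

legend_svg <- function(spec, x, y) {
  entries <- c(red = "0-30 worst", orange = "30-70", green = "70-100 best",
               missing = "not scored")
  out <- character(0)
  for (i in seq_along(entries)) {
    b <- names(entries)[i]
    out <- c(out,
      sprintf(paste0("<rect id=\"legend-%s\" x=\"%s\" y=\"%s\" width=\"14\" ",
                     "height=\"14\" fill=\"%s\"/>"),
              b, fmt(x), fmt(y + 20 * (i - 1)), band_fill(b, spec)),
      svg_text(x + 20, y + 20 * (i - 1) + 11, entries[[i]], 11, "start"))
  }
  out
}

compass_geometry <- function(snapshot, spec) {
  s <- spec$size
  cx <- s / 2; cy <- s / 2
  r_out <- 0.40 * s
  r_in <- 0.08 * s
  r_marker <- r_in + spec$marker_frac * (r_out - r_in)
  n <- nrow(snapshot$areas)
  step <- 2 * pi / n
  list(cx = cx, cy = cy, r_out = r_out, r_in = r_in, r_marker = r_marker,
       a0 = (seq_len(n) - 1) * step, a1 = seq_len(n) * step, step = step)
}

#' Render the compass graph
#'
#' Draws one annular sector per area, clockwise from 12 o'clock in mapping
#' order. The sector fill is the color band of the area mean; the inner-edge
#' band is the color of the lowest member domain, so a single severe problem
#' stays visible inside an otherwise good area. Missing areas render in the
#' neutral color. Vector output is deterministic: fixed element order,
#' stable ids (`sector-<area>`, `marker-<area>`), fixed-precision
#' coordinates.
#'
#' @param snapshot An `rc_snapshot`.
#' @param spec A [render_spec()].
#' @param path Output file; required for PNG, optional for SVG.
#' @return The SVG document as a character scalar (invisibly); for PNG, the
#'   path.
#' @export
render_compass <- function(snapshot, spec = render_spec(), path = NULL) {
  stopifnot(inherits(snapshot, "rc_snapshot"))
  if (spec$format == "png") return(render_compass_png(snapshot, spec, path))
  g <- compass_geometry(snapshot, spec)
  out <- svg_open(spec$size, spec$size)
  out <- c(out, sprintf("<title>compass %s %s</title>",
                        xml_escape(snapshot$respondent_id),
                        xml_escape(snapshot$timepoint)))
  for (i in seq_len(nrow(snapshot$areas))) {
    a <- snapshot$areas[i, ]
    fill_area <- band_fill(a$area_band, spec)
    fill_min <- band_fill(a$min_band, spec)
    out <- c(out,
      sprintf("<path id=\"sector-%s\" d=\"%s\" fill=\"%s\" stroke=\"#FFFFFF\" stroke-width=\"2\"/>",
              a$area_id,
              wedge_path(g$cx, g$cy, g$r_marker, g$r_out, g$a0[i], g$a1[i]),
              fill_area),
      sprintf("<path id=\"marker-%s\" d=\"%s\" fill=\"%s\" stroke=\"#FFFFFF\" stroke-width=\"1\"/>",
              a$area_id,
              wedge_path(g$cx, g$cy, g$r_in, g$r_marker, g$a0[i], g$a1[i]),
              fill_min))
    mid <- (g$a0[i] + g$a1[i]) / 2
    out <- c(out, svg_text(g$cx + (g$r_out + 0.05 * spec$size) * sin(mid),
                           g$cy - (g$r_out + 0.05 * spec$size) * cos(mid) + 4,
                           a$name, 12))
  }
  if (spec$legend) out <- c(out, legend_svg(spec, 10, 10))
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) writeLines(doc, path, useBytes = TRUE)
  invisible(doc)
}

render_compass_png <- function(snapshot, spec, path) {
  if (is.null(path)) rc_config_error("PNG output requires a file path")
  g <- compass_geometry(snapshot, spec)
  grDevices::png(path, width = spec$size, height = spec$size)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, spec$size), ylim = c(spec$size, 0),
                        asp = 1)
  arc <- function(r, a0, a1) {
    aa <- seq(a0, a1, length.out = 64)
    cbind(g$cx + r * sin(aa), g$cy - r * cos(aa))
  }
  for (i in seq_len(nrow(snapshot$areas))) {
    a <- snapshot$areas[i, ]
    ring <- function(r0, r1, col) {
      xy <- rbind(arc(r1, g$a0[i], g$a1[i]), arc(r0, g$a1[i], g$a0[i]))
      graphics::polygon(xy[, 1], xy[, 2], col = col, border = "white")
    }
    ring(g$r_marker, g$r_out, band_fill(a$area_band, spec))
    ring(g$r_in, g$r_marker, band_fill(a$min_band, spec))
    mid <- (g$a0[i] + g$a1[i]) / 2
    graphics::text(g$cx + (g$r_out + 0.05 * spec$size) * sin(mid),
                   g$cy - (g$r_out + 0.05 * spec$size) * cos(mid),
                   a$name, cex = 0.9)
  }
  invisible(path)
}

#' Render per-area domain bar charts
#'
#' One bar per member domain of the chosen area, height equal to the
#' normalized score on a fixed 0-100 axis, filled with the domain's band
#' color; unscorable domains draw as neutral dashed outlines at zero height
#' and the axis never rescales.
#'
#' @param snapshot An `rc_snapshot`.
#' @param area_id Area to chart.
#' @param spec A [render_spec()].
#' @param path Optional output file.
#' @return SVG document (invisibly), or the path for PNG.
#' @export
render_domain_bars <- function(snapshot, area_id, spec = render_spec(),
                               path = NULL) {
  stopifnot(inherits(snapshot, "rc_snapshot"))
  d <- snapshot$domains[snapshot$domains$area_id == area_id, , drop = FALSE]
  if (nrow(d) == 0L)
    rc_validation_error(sprintf("snapshot has no area '%s'", area_id))
  if (spec$format == "png") return(render_bars_png(d, area_id, spec, path))
  w <- spec$size; h <- round(0.6 * spec$size)
  m <- 50                                   # margins
  plot_h <- h - 2 * m
  bar_w <- (w - 2 * m) / nrow(d) * 0.6
  gap <- (w - 2 * m) / nrow(d)
  out <- svg_open(w, h)
  out <- c(out, sprintf("<title>domains %s</title>", xml_escape(area_id)))
  # y axis, 0-100 fixed
  out <- c(out, sprintf(
    "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#000000\"/>",
    fmt(m), fmt(m), fmt(m), fmt(h - m)))
  for (tick in seq(0, 100, 25)) {
    y <- h - m - plot_h * tick / 100
    out <- c(out, sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#000000\"/>",
      fmt(m - 4), fmt(y), fmt(m), fmt(y)),
      svg_text(m - 8, y + 4, as.character(tick), 10, "end"))
  }
  for (i in seq_len(nrow(d))) {
    x <- m + gap * (i - 1) + (gap - bar_w) / 2
    id <- paste0("bar-", d$instrument_id[i], "-", d$domain_id[i])
    if (d$missing[i]) {
      out <- c(out, sprintf(paste0(
        "<rect id=\"%s\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" ",
        "fill=\"%s\" stroke=\"#808080\" stroke-dasharray=\"4,3\" ",
        "data-score=\"missing\"/>"),
        id, fmt(x), fmt(m), fmt(bar_w), fmt(plot_h),
        band_fill("missing", spec)))
    } else {
      bh <- plot_h * d$normalized[i] / 100
      out <- c(out, sprintf(paste0(
        "<rect id=\"%s\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" ",
        "fill=\"%s\" data-score=\"%s\"/>"),
        id, fmt(x), fmt(h - m - bh), fmt(bar_w), fmt(bh),
        band_fill(d$band[i], spec), fmt(d$normalized[i])))
    }
    out <- c(out, svg_text(x + bar_w / 2, h - m + 16, d$domain_id[i], 10))
  }
  if (spec$legend) out <- c(out, legend_svg(spec, w - 130, 10))
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) writeLines(doc, path, useBytes = TRUE)
  invisible(doc)
}

render_bars_png <- function(d, area_id, spec, path) {
  if (is.null(path)) rc_config_error("PNG output requires a file path")
  grDevices::png(path, width = spec$size, height = round(0.6 * spec$size))
  on.exit(grDevices::dev.off())
  heights <- ifelse(d$missing, 0, d$normalized)
  cols <- ifelse(d$missing, band_fill("missing", spec),
                 vapply(d$band, band_fill, "", spec = spec))
  graphics::barplot(heights, names.arg = d$domain_id, col = cols,
                    ylim = c(0, 100), main = area_id, las = 2)
  invisible(path)
}

#' Render the cohort extent/frequency chart
#'
#' One row per domain, ordered worst median first: a horizontal bar of the
#' median (0 = worst outcome / unmet need, 100 = best / no need) colored by
#' its band, whiskers spanning the 25-75% interquartile range, and the
#' impairment frequency annotated as `"k/n, p%"` at the row's right edge.
#'
#' @param summary An `rc_cohort_summary`.
#' @param spec A [render_spec()].
#' @param path Optional output file.
#' @return SVG document (invisibly), or the path for PNG.
#' @export
render_group_chart <- function(summary, spec = render_spec(), path = NULL) {
  rows <- extent_frequency_table(summary)
  w <- spec$size
  row_h <- 22
  m_left <- 170; m_right <- 110; m_top <- 30; m_bot <- 30
  h <- m_top + m_bot + row_h * nrow(rows)
  plot_w <- w - m_left - m_right
  xpos <- function(v) m_left + plot_w * v / 100
  out <- svg_open(w, h)
  out <- c(out, "<title>cohort extent and frequency</title>")
  for (tick in seq(0, 100, 25)) {
    out <- c(out, sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#DDDDDD\"/>",
      fmt(xpos(tick)), fmt(m_top), fmt(xpos(tick)), fmt(h - m_bot)),
      svg_text(xpos(tick), m_top - 8, as.character(tick), 10))
  }
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    y <- m_top + row_h * (i - 1) + 3
    bh <- row_h - 8
    id <- paste0("row-", r$instrument_id, "-", r$domain_id)
    out <- c(out,
      svg_text(m_left - 8, y + bh - 3, r$label, 11, "end"),
      sprintf(paste0("<rect id=\"%s\" x=\"%s\" y=\"%s\" width=\"%s\" ",
                     "height=\"%s\" fill=\"%s\" data-median=\"%s\"/>"),
              id, fmt(xpos(0)), fmt(y), fmt(plot_w * r$median / 100),
              fmt(bh), band_fill(band(r$median), spec), fmt(r$median)),
      sprintf(paste0("<line id=\"iqr-%s-%s\" x1=\"%s\" y1=\"%s\" x2=\"%s\" ",
                     "y2=\"%s\" stroke=\"#000000\" stroke-width=\"2\"/>"),
              r$instrument_id, r$domain_id,
              fmt(xpos(r$q25)), fmt(y + bh / 2), fmt(xpos(r$q75)),
              fmt(y + bh / 2)),
      sprintf(paste0("<text id=\"freq-%s-%s\" x=\"%s\" y=\"%s\" ",
                     "font-size=\"11\" font-family=\"sans-serif\" ",
                     "text-anchor=\"start\">%d/%d, %d%%</text>"),
              r$instrument_id, r$domain_id, fmt(w - m_right + 8),
              fmt(y + bh - 3), r$impaired_n, r$n_scored, r$percent))
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (spec$format == "png") return(render_group_png(rows, spec, path))
  if (!is.null(path)) writeLines(doc, path, useBytes = TRUE)
  invisible(doc)
}

render_group_png <- function(rows, spec, path) {
  if (is.null(path)) rc_config_error("PNG output requires a file path")
  grDevices::png(path, width = spec$size, height = spec$size)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 10, 2, 6))
  cols <- vapply(band(rows$median), band_fill, "", spec = spec)
  ys <- graphics::barplot(rev(rows$median), names.arg = rev(rows$label),
                          col = rev(cols), horiz = TRUE, xlim = c(0, 100),
                          las = 1, cex.names = 0.7)
  graphics::segments(rev(rows$q25), ys, rev(rows$q75), ys, lwd = 2)
  graphics::mtext(rev(sprintf("%d/%d, %d%%", rows$impaired_n, rows$n_scored,
                              rows$percent)),
                  side = 4, at = ys, las = 1, cex = 0.7, line = 0.5)
  invisible(path)
}
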