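#' Glyph geometry of the activity chronology chart
#'
#' Computes the drawing geometry shared by all output formats: one row per
#' subtype ordered by activity peak (oldest on top), the oval body spanning
#' the central 75\% interval, a line spanning 95\%, and whisker caps at 99\%
#' of the activity density, with the relative time axis mapped so the union
#' of 99\% intervals fills the drawing width.
#'
#' @param est A \code{tint_activity} from [fit_activity()].
#' @param width,row_height,margin Pixel dimensions.
#' @return A list with \code{rows} (data frame: type, y, cx, x75l/r, x95l/r,
#'   x99l/r), the x-axis mapping \code{xmap} and overall \code{width}/
#'   \code{height}. Horizontal half-extents are proportional to
#'   1.150349, 1.959964 and 2.575829 times the activity spread.
#' @export
chart_geometry <- function(est, width = 760, row_height = 26, margin = 90) {
  stopifnot(nrow(est) >= 1L)
  est <- est[order(est$peak), , drop = FALSE]
  t0 <- min(est$lo99); t1 <- max(est$hi99)
  if (t1 <= t0) t1 <- t0 + 1
  xmap <- function(t) margin + (t - t0) / (t1 - t0) * (width - 2 * margin)
  y <- 30 + row_height * (seq_len(nrow(est)) - 0.5)
  rows <- data.frame(
    type = est$type, y = y,
    cx = xmap(est$peak),
    x75l = xmap(est$lo75), x75r = xmap(est$hi75),
    x95l = xmap(est$lo95), x95r = xmap(est$hi95),
    x99l = xmap(est$lo99), x99r = xmap(est$hi99),
    stringsAsFactors = FALSE
  )
  list(rows = rows, xmap = xmap, t0 = t0, t1 = t1,
       width = width, height = 30 + row_height * nrow(est) + 50,
       row_height = row_height, margin = margin)
}

# deterministic color from the subtype name (stable across runs/platforms)
type_color <- function(name) {
  h <- vapply(name, function(s)
    sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 360, numeric(1))
  grDevices::hsv(h / 360, 0.55, 0.75)
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the activity chronology chart
#'
#' Draws the classic TinT chronology panel: one glyph per subtype, sorted by
#' activity peak, the oval encompassing 75\%, vertical lines 95\%, and the
#' line ends 99\% of the probable activity period, over a relative time
#' scale. Optional highlight groups are drawn as grey boxes around their
#' member rows. SVG is the primary format (deterministic, text-only);
#' PNG and PostScript are rendered through the corresponding graphics
#' devices from the same geometry.
#'
#' @param est A \code{tint_activity}.
#' @param file Output path; when \code{NULL} (SVG only) the SVG document is
#'   returned as a character string.
#' @param format One of \code{"svg"}, \code{"png"}, \code{"ps"}.
#' @param highlight_groups Named list of subtype vectors to box, e.g.
#'   \code{list("taxon-specific" = c("AluYRa", "AluYRbcd"))}.
#' @param width,row_height Pixel dimensions.
#' @return Invisibly `file`, or the SVG string when \code{file} is
#'   \code{NULL}.
#' @export
render_chart <- function(est, file = NULL, format = c("svg", "png", "ps"),
                         highlight_groups = NULL, width = 760,
                         row_height = 26) {
  if (length(format) > 1L) format <- format[1]
  if (!format %in% c("svg", "png", "ps"))
    stop_config(sprintf("unknown chart format '%s'; supported formats: svg, png, ps", format))
  if (nrow(est) == 0L) stop_data("no activity estimates to render")
  if (!is.null(highlight_groups)) {
    unknown <- setdiff(unlist(highlight_groups), est$type)
    if (length(unknown))
      stop_config(sprintf("highlighted subtype(s) not in estimates: %s",
                          paste(unknown, collapse = ", ")))
  }
  g <- chart_geometry(est, width = width, row_height = row_height)

  if (format == "svg") {
    doc <- svg_chart(g, highlight_groups)
    if (is.null(file)) return(doc)
    writeLines(doc, file)
    return(invisible(file))
  }
  if (is.null(file)) stop_config("a file path is required for png/ps output")
  if (format == "png") {
    grDevices::png(file, width = g$width, height = g$height)
  } else {
    grDevices::postscript(file, width = g$width / 72, height = g$height / 72,
                          paper = "special", horizontal = FALSE)
  }
  on.exit(grDevices::dev.off())
  draw_chart_base(g, highlight_groups)
  invisible(file)
}

svg_chart <- function(g, highlight_groups) {
  r <- g$rows
  col <- type_color(r$type)
  ry <- g$row_height * 0.32
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                   g$width, g$height, g$width, g$height),
           sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>',
                   g$width, g$height))

  if (!is.null(highlight_groups)) {
    for (nm in names(highlight_groups)) {
      yy <- r$y[r$type %in% highlight_groups[[nm]]]
      if (!length(yy)) next
      out <- c(out, sprintf(
        '<rect class="tint-group" data-group="%s" x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="#dddddd" stroke="#999999"/>',
        svg_escape(nm), g$margin - 6, min(yy) - g$row_height / 2,
        g$width - 2 * g$margin + 12, max(yy) - min(yy) + g$row_height))
    }
  }

  for (i in seq_len(nrow(r))) {
    cap <- g$row_height * 0.18
    tick <- g$row_height * 0.30
    out <- c(out,
      sprintf('<g class="tint-glyph" data-type="%s">', svg_escape(r$type[i])),
      sprintf('<line class="range99" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-width="1.2"/>',
              r$x99l[i], r$y[i], r$x99r[i], r$y[i], col[i]),
      sprintf('<line class="cap99" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-width="1.2"/>',
              r$x99l[i], r$y[i] - cap, r$x99l[i], r$y[i] + cap, col[i]),
      sprintf('<line class="cap99" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-width="1.2"/>',
              r$x99r[i], r$y[i] - cap, r$x99r[i], r$y[i] + cap, col[i]),
      sprintf('<line class="tick95" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-width="1.4"/>',
              r$x95l[i], r$y[i] - tick, r$x95l[i], r$y[i] + tick, col[i]),
      sprintf('<line class="tick95" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-width="1.4"/>',
              r$x95r[i], r$y[i] - tick, r$x95r[i], r$y[i] + tick, col[i]),
      sprintf('<ellipse class="core75" cx="%.3f" cy="%.3f" rx="%.3f" ry="%.3f" fill="%s" fill-opacity="0.75" stroke="%s"/>',
              r$cx[i], r$y[i], (r$x75r[i] - r$x75l[i]) / 2, ry, col[i], col[i]),
      sprintf('<text class="label" x="%.3f" y="%.3f" font-size="12" font-family="sans-serif" text-anchor="end">%s</text>',
              g$margin - 12, r$y[i] + 4, svg_escape(r$type[i])),
      '</g>')
  }

  ay <- g$height - 28
  ticks <- seq(0, 1, by = 0.25)
  tx <- g$margin + ticks * (g$width - 2 * g$margin)
  out <- c(out,
           sprintf('<g class="tint-axis"><line x1="%.2f" y1="%d" x2="%.2f" y2="%d" stroke="black"/>',
                   g$margin, ay, g$width - g$margin, ay),
           sprintf('<line x1="%.2f" y1="%d" x2="%.2f" y2="%d" stroke="black"/>',
                   tx, ay, tx, ay + 5),
           sprintf('<text x="%.2f" y="%d" font-size="10" font-family="sans-serif" text-anchor="middle">%.2f</text>',
                   tx, ay + 17, ticks),
           sprintf('<text x="%.2f" y="%d" font-size="11" font-family="sans-serif" text-anchor="middle">relative time scale</text>',
                   g$width / 2, ay + 32),
           '</g>', '</svg>')
  paste(out, collapse = "\n")
}

draw_chart_base <- function(g, highlight_groups) {
  r <- g$rows
  col <- type_color(r$type)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NULL, xlim = c(0, g$width), ylim = c(g$height, 0),
                 axes = FALSE, xlab = "", ylab = "", xaxs = "i", yaxs = "i")
  if (!is.null(highlight_groups)) {
    for (nm in names(highlight_groups)) {
      yy <- r$y[r$type %in% highlight_groups[[nm]]]
      if (!length(yy)) next
      graphics::rect(g$margin - 6, min(yy) - g$row_height / 2,
                     g$width - g$margin + 6, max(yy) + g$row_height / 2,
                     col = "#dddddd", border = "#999999")
    }
  }
  ry <- g$row_height * 0.32
  for (i in seq_len(nrow(r))) {
    graphics::segments(r$x99l[i], r$y[i], r$x99r[i], r$y[i], col = col[i])
    graphics::segments(c(r$x99l[i], r$x99r[i]), r$y[i] - 4,
                       c(r$x99l[i], r$x99r[i]), r$y[i] + 4, col = col[i])
    graphics::segments(c(r$x95l[i], r$x95r[i]), r$y[i] - 7,
                       c(r$x95l[i], r$x95r[i]), r$y[i] + 7, col = col[i])
    th <- seq(0, 2 * pi, length.out = 60)
    graphics::polygon(r$cx[i] + (r$x75r[i] - r$x75l[i]) / 2 * cos(th),
                      r$y[i] + ry * sin(th), col = col[i], border = col[i])
    graphics::text(g$margin - 12, r$y[i], r$type[i], adj = 1, cex = 0.8)
  }
  ay <- g$height - 28
  graphics::segments(g$margin, ay, g$width - g$margin, ay)
  ticks <- seq(0, 1, by = 0.25)
  tx <- g$margin + ticks * (g$width - 2 * g$margin)
  graphics::segments(tx, ay, tx, ay + 5)
  graphics::text(tx, ay + 14, sprintf("%.2f", ticks), cex = 0.7)
}
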