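#' Build the geometry of a forest plot
#'
#' Resolves study rows and the pooled summary into the scatter-plot
#' geometry of a forest plot: display-scaled abscissae, asymmetric
#' error-bar deltas expressed as differences to the point estimate, ordinal
#' row positions with the first input study topmost and the summary at the
#' bottom (ordinate 1), a vertical summary reference line, the summary
#' diamond, and the axis window, tick interval and scale. All geometry is
#' available in the returned object for headless inspection; [render_forest()]
#' draws it.
#'
#' Error-bar deltas are `display - lower CI` and `upper CI - display`, so
#' asymmetric intervals render faithfully. Ordinates are 1-based integers
#' increasing upward: studies occupy `k+1 .. 2` in input order and the
#' summary sits at 1.
#'
#' When no axis window is given, the window defaults to
#' `[floor(min displayed CI), ceil(max displayed CI)]` padded by one tick,
#' with the tick interval chosen from `{1, 2, 5} x 10^m` so the unpadded
#' span holds 5-10 ticks. Values outside the configured window are clipped
#' at draw time with a warning naming the study.
#'
#' @param studies Data frame with columns `label`, `estimate`, `ci_lower`,
#'   `ci_upper` (raw scale; each CI must bracket its estimate).
#' @param summary Numeric vector or list with `estimate`, `ci_lower`,
#'   `ci_upper` for the pooled result, or a [pool_fixed()]/[pool_random()]
#'   `pooled_result`.
#' @param display `"percent"` (multiplier 100, the convention for rate
#'   data) or `"raw"` (multiplier 1).
#' @param axis_min,axis_max,tick Optional axis window and tick interval in
#'   display units.
#' @param log_scale Logical; logarithmic axis (for ratio-type data).
#'   Requires a strictly positive window and values.
#' @param paper_style Logical; draw the summary as a plain marker with an
#'   error bar instead of the CI-spanning diamond.
#' @param summary_label Label for the summary row, default `"Summary"`.
#' @param marker_weights Optional per-study weights; when given, marker
#'   areas are drawn proportional to weight (equal sizes by default).
#' @return A `forest_spec` list with elements `rows`, `summary_row`,
#'   `summary_line`, `axis`, `multiplier`, `k`, `paper_style`,
#'   `marker_weights`.
#' @examples
#' fit <- meta_analysis(example_studies())
#' spec <- build_plot_spec(estimates_table(fit), fit$random,
#'                         axis_min = 10, axis_max = 28, tick = 2)
#' spec$axis
#' @export
build_plot_spec <- function(studies, summary,
                            display = c("percent", "raw"),
                            axis_min = NULL, axis_max = NULL, tick = NULL,
                            log_scale = FALSE, paper_style = FALSE,
                            summary_label = "Summary",
                            marker_weights = NULL) {
  display <- match.arg(display)
  mult <- if (display == "percent") 100 else 1
  need <- c("label", "estimate", "ci_lower", "ci_upper")
  if (!all(need %in% names(studies))) {
    stop("studies must have columns label, estimate, ci_lower, ci_upper",
         call. = FALSE)
  }
  k <- nrow(studies)
  if (k < 1) stop("need at least one study", call. = FALSE)
  if (any(studies$ci_lower > studies$estimate) ||
      any(studies$estimate > studies$ci_upper)) {
    stop("each confidence interval must bracket its estimate", call. = FALSE)
  }
  if (inherits(summary, "pooled_result")) {
    summary <- c(estimate = summary$es_bar, ci_lower = summary$ci_lower,
                 ci_upper = summary$ci_upper)
  }
  summary <- as.list(summary)
  if (!all(c("estimate", "ci_lower", "ci_upper") %in% names(summary))) {
    stop("summary needs estimate, ci_lower, ci_upper", call. = FALSE)
  }

  rows <- data.frame(
    label = studies$label,
    display = studies$estimate * mult,
    lower_delta = (studies$estimate - studies$ci_lower) * mult,
    upper_delta = (studies$ci_upper - studies$estimate) * mult,
    ordinate = seq(k + 1L, 2L),  # first input study topmost
    stringsAsFactors = FALSE
  )
  summary_row <- list(
    label = summary_label,
    display = summary$estimate * mult,
    ci_lower = summary$ci_lower * mult,
    ci_upper = summary$ci_upper * mult,
    ordinate = 1L
  )

  all_lo <- c(rows$display - rows$lower_delta, summary_row$ci_lower)
  all_hi <- c(rows$display + rows$upper_delta, summary_row$ci_upper)
  axis <- resolve_axis(axis_min, axis_max, tick, min(all_lo), max(all_hi),
                       log_scale)
  if (log_scale && (axis$min <= 0 || any(all_lo <= 0))) {
    stop("logarithmic scale requires strictly positive axis window and values",
         call. = FALSE)
  }

  structure(list(
    rows = rows, summary_row = summary_row,
    summary_line = list(x = summary_row$display, y0 = 0.5, y1 = k + 1.5),
    axis = axis, multiplier = mult, k = k, paper_style = isTRUE(paper_style),
    marker_weights = marker_weights
  ), class = "forest_spec")
}

resolve_axis <- function(axis_min, axis_max, tick, lo, hi, log_scale) {
  auto <- is.null(axis_min) || is.null(axis_max)
  if (auto) {
    wmin <- floor(lo); wmax <- ceiling(hi)
    if (wmax <= wmin) wmax <- wmin + 1
    span <- wmax - wmin
    if (is.null(tick)) {
      cand <- sort(as.vector(outer(c(1, 2, 5), 10^(-6:6))))
      tick <- cand[which(span / cand <= 9)[1]]  # at most 10, at least ~5 ticks
    }
    wmin <- wmin - tick; wmax <- wmax + tick    # pad by one tick
    axis_min <- if (log_scale) max(wmin, lo / 2) else wmin
    axis_max <- wmax
  } else if (is.null(tick)) {
    span <- axis_max - axis_min
    cand <- sort(as.vector(outer(c(1, 2, 5), 10^(-6:6))))
    tick <- cand[which(span / cand <= 9)[1]]
  }
  if (axis_min >= axis_max) stop("axis min must be below axis max", call. = FALSE)
  list(min = axis_min, max = axis_max, tick = tick,
       scale = if (log_scale) "logarithmic" else "linear",
       ticks = seq(axis_min, axis_max, by = tick))
}

# Pixel transforms shared by the SVG and table renderers.
forest_layout <- function(spec, width = 640, row_h = 28,
                          margin = c(top = 20, right = 24, bottom = 44,
                                     left = 40), x_offset = 0) {
  plot_w <- width - margin[["left"]] - margin[["right"]]
  plot_h <- (spec$k + 1) * row_h
  height <- margin[["top"]] + plot_h + margin[["bottom"]]
  ax <- spec$axis
  tx <- function(x) if (ax$scale == "logarithmic") log10(x) else x
  umin <- tx(ax$min); umax <- tx(ax$max)
  list(
    width = width, height = height, plot_w = plot_w, plot_h = plot_h,
    plot_x = x_offset + margin[["left"]], plot_y = margin[["top"]],
    xpix = function(x) x_offset + margin[["left"]] +
      (tx(x) - umin) / (umax - umin) * plot_w,
    ypix = function(o) margin[["top"]] +
      (spec$k + 1.5 - o) / (spec$k + 1) * plot_h
  )
}

#' Render a forest plot to SVG or PNG
#'
#' Draws a [build_plot_spec()] geometry: one square marker per study with a
#' horizontal error bar of the stored deltas, the pooled summary as a
#' diamond whose horizontal vertices sit at the CI bounds (half-height 0.3
#' row units), a vertical reference line at the summary value, and the
#' configured axis. Study labels are not drawn on the y axis; use
#' [compose_with_table()] for the labelled presentation.
#'
#' SVG output is written with exact coordinates and machine-readable
#' metadata (`data-*` attributes on the root element record the axis window
#' and plot box), so the geometry can be parsed back losslessly. Any point
#' or error-bar end outside the axis window is clipped to the window edge
#' with a warning naming the study.
#'
#' @param spec A `forest_spec`.
#' @param path Output file path.
#' @param format `"svg"` (default) or `"png"`.
#' @param width Figure width in pixels.
#' @return `path`, invisibly.
#' @export
render_forest <- function(spec, path, format = c("svg", "png"), width = 640) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "forest_spec"))
  if (format == "svg") {
    doc <- forest_svg(spec, width = width)
    xml2::write_xml(doc, path)
  } else {
    grDevices::png(path, width = width,
                   height = forest_layout(spec, width)$height, res = 96)
    on.exit(grDevices::dev.off())
    forest_base_plot(spec)
  }
  invisible(path)
}

fmt <- function(x) sprintf("%.17g", x)

clip_warn <- function(x, lo, hi, label, what) {
  if (x < lo || x > hi) {
    warning("study '", label, "': ", what, " ", signif(x, 6),
            " outside axis window [", lo, ", ", hi, "], clipped",
            call. = FALSE)
    return(min(max(x, lo), hi))
  }
  x
}

forest_svg <- function(spec, width = 640, x_offset = 0, doc = NULL,
                       lay = NULL) {
  if (is.null(lay)) lay <- forest_layout(spec, width, x_offset = x_offset)
  if (is.null(doc)) {
    doc <- xml2::read_xml(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d"/>',
      ceiling(lay$width), ceiling(lay$height)))
  }
  root <- xml2::xml_root(doc)
  ax <- spec$axis
  meta_attrs <- c(
    "data-axis-min" = fmt(ax$min), "data-axis-max" = fmt(ax$max),
    "data-axis-tick" = fmt(ax$tick), "data-axis-scale" = ax$scale,
    "data-multiplier" = fmt(spec$multiplier), "data-k" = as.character(spec$k),
    "data-plot-x" = fmt(lay$plot_x), "data-plot-width" = fmt(lay$plot_w),
    "data-plot-y" = fmt(lay$plot_y), "data-plot-height" = fmt(lay$plot_h))
  for (nm in names(meta_attrs)) xml2::xml_set_attr(root, nm, meta_attrs[[nm]])
  add <- function(name, attrs) {
    node <- xml2::xml_add_child(root, name)
    xml2::xml_set_attrs(node, attrs)
    node
  }
  lo <- ax$min; hi <- ax$max

  # summary reference line (behind the markers)
  sx <- lay$xpix(clip_warn(spec$summary_line$x, lo, hi,
                           spec$summary_row$label, "summary value"))
  add("line", c(class = "summary-line",
                x1 = fmt(sx), x2 = fmt(sx),
                y1 = fmt(lay$ypix(spec$summary_line$y0)),
                y2 = fmt(lay$ypix(spec$summary_line$y1)),
                stroke = "#555555", "stroke-dasharray" = "4 3"))

  # per-study markers and error bars
  wts <- spec$marker_weights
  half <- if (is.null(wts)) rep(4.5, spec$k)
          else 2.5 + 5 * sqrt(wts / max(wts))
  for (i in seq_len(spec$k)) {
    r <- spec$rows[i, ]
    y <- lay$ypix(r$ordinate)
    xc <- clip_warn(r$display, lo, hi, r$label, "estimate")
    xl <- clip_warn(r$display - r$lower_delta, lo, hi, r$label, "lower bound")
    xu <- clip_warn(r$display + r$upper_delta, lo, hi, r$label, "upper bound")
    add("line", c(class = "errorbar-lower", "data-label" = r$label,
                  x1 = fmt(lay$xpix(xl)), x2 = fmt(lay$xpix(xc)),
                  y1 = fmt(y), y2 = fmt(y), stroke = "black"))
    add("line", c(class = "errorbar-upper", "data-label" = r$label,
                  x1 = fmt(lay$xpix(xc)), x2 = fmt(lay$xpix(xu)),
                  y1 = fmt(y), y2 = fmt(y), stroke = "black"))
    for (end in c(xl, xu)) {
      add("line", c(class = "errorbar-cap",
                    x1 = fmt(lay$xpix(end)), x2 = fmt(lay$xpix(end)),
                    y1 = fmt(y - 3.5), y2 = fmt(y + 3.5), stroke = "black"))
    }
    h <- half[i]
    add("rect", c(class = "study-marker", "data-label" = r$label,
                  "data-ordinate" = fmt(r$ordinate),
                  x = fmt(lay$xpix(xc) - h), y = fmt(y - h),
                  width = fmt(2 * h), height = fmt(2 * h), fill = "#2b4c7e"))
  }

  # summary row
  s <- spec$summary_row
  ys <- lay$ypix(s$ordinate)
  sl <- clip_warn(s$ci_lower, lo, hi, s$label, "lower bound")
  su <- clip_warn(s$ci_upper, lo, hi, s$label, "upper bound")
  sc <- clip_warn(s$display, lo, hi, s$label, "estimate")
  if (spec$paper_style) {
    add("line", c(class = "summary-errorbar",
                  x1 = fmt(lay$xpix(sl)), x2 = fmt(lay$xpix(su)),
                  y1 = fmt(ys), y2 = fmt(ys), stroke = "black"))
    dh <- 6
    add("polygon", c(class = "summary-diamond", "data-style" = "marker",
                     points = paste(
                       paste0(fmt(lay$xpix(sc) - dh), ",", fmt(ys)),
                       paste0(fmt(lay$xpix(sc)), ",", fmt(ys - dh)),
                       paste0(fmt(lay$xpix(sc) + dh), ",", fmt(ys)),
                       paste0(fmt(lay$xpix(sc)), ",", fmt(ys + dh))),
                     fill = "black"))
  } else {
    dh <- 0.3 * (lay$plot_h / (spec$k + 1))  # 0.3 row units
    add("polygon", c(class = "summary-diamond", "data-style" = "ci-span",
                     "data-center" = fmt(sc),
                     points = paste(
                       paste0(fmt(lay$xpix(sl)), ",", fmt(ys)),
                       paste0(fmt(lay$xpix(sc)), ",", fmt(ys - dh)),
                       paste0(fmt(lay$xpix(su)), ",", fmt(ys)),
                       paste0(fmt(lay$xpix(sc)), ",", fmt(ys + dh))),
                     fill = "black"))
  }

  # x axis with ticks and labels; no y-axis labels by design
  ybase <- lay$ypix(0.5)
  add("line", c(class = "axis", x1 = fmt(lay$xpix(lo)), x2 = fmt(lay$xpix(hi)),
                y1 = fmt(ybase), y2 = fmt(ybase), stroke = "black"))
  for (t in ax$ticks) {
    xt <- lay$xpix(t)
    add("line", c(class = "axis-tick", "data-value" = fmt(t),
                  x1 = fmt(xt), x2 = fmt(xt),
                  y1 = fmt(ybase), y2 = fmt(ybase + 5), stroke = "black"))
    lab <- add("text", c(class = "axis-label", x = fmt(xt),
                         y = fmt(ybase + 18), "text-anchor" = "middle",
                         "font-size" = "11"))
    xml2::xml_set_text(lab, format(t, trim = TRUE))
  }
  doc
}

# Base-graphics rendering used for the PNG route; same geometry in data
# coordinates.
forest_base_plot <- function(spec) {
  ax <- spec$axis
  logx <- ax$scale == "logarithmic"
  graphics::par(mar = c(4, 1, 1, 1))
  graphics::plot.new()
  graphics::plot.window(xlim = c(ax$min, ax$max),
                        ylim = c(0.5, spec$k + 1.5),
                        log = if (logx) "x" else "")
  graphics::abline(v = spec$summary_line$x, lty = 2, col = "grey40")
  with(spec$rows, {
    graphics::segments(display - lower_delta, ordinate,
                       display + upper_delta, ordinate)
    graphics::points(display, ordinate, pch = 15, col = "#2b4c7e", cex = 1.1)
  })
  s <- spec$summary_row
  if (spec$paper_style) {
    graphics::segments(s$ci_lower, s$ordinate, s$ci_upper, s$ordinate)
    graphics::points(s$display, s$ordinate, pch = 18, cex = 1.6)
  } else {
    graphics::polygon(c(s$ci_lower, s$display, s$ci_upper, s$display),
                      s$ordinate + c(0, 0.3, 0, -0.3), col = "black")
  }
  graphics::axis(1, at = ax$ticks)
}

#' Compose a forest plot beside a study table
#'
#' The recommended presentation: a single SVG figure with left-hand text
#' columns (label, events, total, estimate with CI) whose rows are
#' vertically centred on the corresponding plot rows, and the forest plot
#' on the right. Rows must align one-to-one with the plot ordinates: `k`
#' study rows plus the summary row.
#'
#' @param spec A `forest_spec`.
#' @param table Data frame with one row per study in the same order as
#'   `spec$rows`, columns `label`, `estimate`, `ci_lower`, `ci_upper` and
#'   optionally `events`, `total` (omitted from the figure when absent).
#' @param path Output SVG path.
#' @param width Total figure width in pixels.
#' @return `path`, invisibly.
#' @export
compose_with_table <- function(spec, table, path, width = 960) {
  stopifnot(inherits(spec, "forest_spec"))
  if (nrow(table) != spec$k) {
    stop("table has ", nrow(table), " rows but the plot has ", spec$k,
         " study ordinates", call. = FALSE)
  }
  has_counts <- all(c("events", "total") %in% names(table)) &&
    !all(is.na(table$events))
  ci_text <- function(est, lo, hi) {
    sprintf("%.1f [%.1f, %.1f]", est * spec$multiplier,
            lo * spec$multiplier, hi * spec$multiplier)
  }
  cols <- list(list(name = "Study", get = function(i) table$label[i]))
  if (has_counts) {
    cols <- c(cols, list(
      list(name = "Events", get = function(i) format(table$events[i])),
      list(name = "Total", get = function(i) format(table$total[i]))))
  }
  cols <- c(cols, list(list(
    name = "Estimate [CI]",
    get = function(i) ci_text(table$estimate[i], table$ci_lower[i],
                              table$ci_upper[i]))))

  table_w <- if (has_counts) 360 else 280
  plot_width <- width - table_w
  lay <- forest_layout(spec, plot_width, x_offset = table_w)
  doc <- xml2::read_xml(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d"/>',
    width, ceiling(lay$height)))
  forest_svg(spec, doc = doc, lay = lay)
  root <- xml2::xml_root(doc)

  xs <- cumsum(c(10, if (has_counts) c(110, 70, 70) else 110))
  add_text <- function(x, y, txt, class, ordinate = NULL, bold = FALSE) {
    node <- xml2::xml_add_child(root, "text")
    attrs <- c(class = class, x = fmt(x), y = fmt(y + 4), "font-size" = "12")
    if (bold) attrs <- c(attrs, "font-weight" = "bold")
    if (!is.null(ordinate)) attrs <- c(attrs, "data-ordinate" = fmt(ordinate))
    xml2::xml_set_attrs(node, attrs)
    xml2::xml_set_text(node, txt)
    node
  }
  for (j in seq_along(cols)) {
    add_text(xs[j], lay$plot_y - 6, cols[[j]]$name, "table-header",
             bold = TRUE)
  }
  for (i in seq_len(spec$k)) {
    y <- lay$ypix(spec$rows$ordinate[i])
    for (j in seq_along(cols)) {
      add_text(xs[j], y, cols[[j]]$get(i), "table-cell",
               ordinate = spec$rows$ordinate[i])
    }
  }
  s <- spec$summary_row
  ys <- lay$ypix(s$ordinate)
  add_text(xs[1], ys, s$label, "table-cell", ordinate = s$ordinate,
           bold = TRUE)
  add_text(xs[length(xs)], ys,
           sprintf("%.1f [%.1f, %.1f]", s$display, s$ci_lower, s$ci_upper),
           "table-cell", ordinate = s$ordinate, bold = TRUE)

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Study table on the estimate/CI scale from a pooled result's inputs
#'
#' Helper producing the `label`, `estimate`, `ci_lower`, `ci_upper` rows
#' that [build_plot_spec()] consumes, from a fitted [meta_analysis()] model
#' or pooled result: per-study normal confidence intervals
#' `es -/+ z * se` at the result's alpha.
#'
#' @param x A `descmeta` fit or `pooled_result`... the per-study estimates
#'   are taken from the fit's `estimates` table.
#' @param estimates Effect-estimate table; required when `x` is a
#'   `pooled_result` created directly.
#' @return Data frame with `label`, `events`, `total` (when known),
#'   `estimate`, `ci_lower`, `ci_upper`.
#' @export
estimates_table <- function(x, estimates = NULL) {
  if (inherits(x, "descmeta")) {
    estimates <- x$estimates
    alpha <- x$alpha
    counts <- x$studies
  } else if (inherits(x, "pooled_result")) {
    if (is.null(estimates)) {
      stop("supply the effect_estimate table alongside a pooled_result",
           call. = FALSE)
    }
    alpha <- x$alpha
    counts <- NULL
  } else {
    stop("x must be a descmeta fit or pooled_result", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  out <- data.frame(label = estimates$label,
                    estimate = estimates$es,
                    ci_lower = estimates$es - z * estimates$se,
                    ci_upper = estimates$es + z * estimates$se,
                    stringsAsFactors = FALSE)
  if (!is.null(counts) && all(c("events", "total") %in% names(counts))) {
    out$events <- counts$events
    out$total <- counts$total
    out <- out[, c("label", "events", "total",
                   "estimate", "ci_lower", "ci_upper")]
  }
  out
}
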