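study_rows <- function() {
  data.frame(label = c("A", "B", "C"),
             estimate = c(0.20, 0.15, 0.25),
             ci_lower = c(0.15, 0.11, 0.18),
             ci_upper = c(0.27, 0.20, 0.33),
             stringsAsFactors = FALSE)
}

summary_row <- c(estimate = 0.19, ci_lower = 0.165, ci_upper = 0.215)

test_that("plot geometry uses percent display and delta-to-the-mean bars", {
  spec <- build_plot_spec(study_rows(), summary_row)
  expect_equal(spec$rows$display[1], 20)
  expect_equal(spec$rows$lower_delta[1], 5)
  expect_equal(spec$rows$upper_delta[1], 7)
  expect_equal(spec$summary_row$display, 19)
  expect_equal(spec$summary_line$x, 19)
  expect_equal(spec$summary_line$y0, 0.5)
  expect_equal(spec$summary_line$y1, 4.5)
})

test_that("ordinates run top-down in input order with the summary at 1", {
  spec <- build_plot_spec(study_rows(), summary_row)
  expect_equal(spec$rows$ordinate, c(4, 3, 2))
  expect_equal(spec$summary_row$ordinate, 1)
  ten <- data.frame(label = letters[1:10], estimate = seq(0.11, 0.25, length.out = 10))
  ten$ci_lower <- ten$estimate - 0.02
  ten$ci_upper <- ten$estimate + 0.02
  spec10 <- build_plot_spec(ten, summary_row)
  expect_equal(spec10$rows$ordinate, 11:2)
  expect_equal(spec10$summary_row$ordinate, 1)
})

test_that("the default axis window brackets the displayed CIs with round ticks", {
  spec <- build_plot_spec(study_rows(), summary_row)
  ax <- spec$axis
  # raw window [floor(11), ceil(33)] padded by one tick
  expect_equal(ax$tick, 5)
  expect_equal(ax$min, 11 - 5)
  expect_equal(ax$max, 33 + 5)
  expect_true(all(diff(ax$ticks) == ax$tick))
  expect_equal(ax$scale, "linear")
})

test_that("a hand-picked 10-28 window with tick 2 yields exactly 10 ticks", {
  spec <- build_plot_spec(study_rows(), summary_row,
                          axis_min = 10, axis_max = 28, tick = 2)
  expect_equal(spec$axis$ticks, seq(10, 28, 2))
  expect_length(spec$axis$ticks, 10)
})

test_that("log scale is recorded and guards against non-positive windows", {
  spec <- build_plot_spec(study_rows(), summary_row, log_scale = TRUE)
  expect_equal(spec$axis$scale, "logarithmic")
  expect_error(build_plot_spec(study_rows(), summary_row, log_scale = TRUE,
                               axis_min = 0, axis_max = 30, tick = 5),
               "positive")
})

test_that("invalid inputs are rejected", {
  bad <- study_rows(); bad$ci_lower[2] <- 0.16
  expect_error(build_plot_spec(bad, summary_row), "bracket")
  expect_error(build_plot_spec(study_rows()[0, ], summary_row), "at least one")
})

test_that("the SVG contains one element set per study plus the summary", {
  spec <- build_plot_spec(study_rows(), summary_row)
  path <- tempfile(fileext = ".svg")
  render_forest(spec, path)
  doc <- xml2::read_xml(path)
  expect_length(svg_nodes(doc, "study-marker"), 3)
  expect_length(svg_nodes(doc, "errorbar-lower"), 3)
  expect_length(svg_nodes(doc, "errorbar-upper"), 3)
  expect_length(svg_nodes(doc, "summary-diamond"), 1)
  expect_length(svg_nodes(doc, "summary-line"), 1)
  expect_length(svg_nodes(doc, "axis-tick"), length(spec$axis$ticks))
  # no y-axis labels: the only text nodes are x-axis labels
  texts <- xml2::xml_find_all(doc, "//*[local-name()='text']")
  expect_true(all(xml2::xml_attr(texts, "class") == "axis-label"))
})

test_that("error-bar extents parsed from the SVG equal the displayed CIs", {
  spec <- build_plot_spec(study_rows(), summary_row)
  path <- tempfile(fileext = ".svg")
  render_forest(spec, path)
  doc <- xml2::read_xml(path)
  inv <- svg_inverter(doc)
  lows <- inv(svg_attr_num(svg_nodes(doc, "errorbar-lower"), "x1"))
  highs <- inv(svg_attr_num(svg_nodes(doc, "errorbar-upper"), "x2"))
  expect_equal(lows, spec$rows$display - spec$rows$lower_delta,
               tolerance = 1e-9)
  expect_equal(highs, spec$rows$display + spec$rows$upper_delta,
               tolerance = 1e-9)
  # visual order: larger ordinate drawn higher (smaller pixel y)
  ys <- svg_attr_num(svg_nodes(doc, "errorbar-lower"), "y1")
  expect_true(all(diff(ys) > 0))          # input order top to bottom
  marker_y <- svg_attr_num(svg_nodes(doc, "study-marker"), "y")
  diamond_pts <- xml2::xml_attr(svg_nodes(doc, "summary-diamond"), "points")
  dia_y <- max(as.numeric(sub(".*,", "", strsplit(diamond_pts, " ")[[1]])))
  expect_true(all(dia_y > marker_y))      # summary lowest on the canvas
})

test_that("the summary diamond spans the CI and centres on the estimate", {
  spec <- build_plot_spec(study_rows(), summary_row)
  path <- tempfile(fileext = ".svg")
  render_forest(spec, path)
  doc <- xml2::read_xml(path)
  inv <- svg_inverter(doc)
  pts <- strsplit(xml2::xml_attr(svg_nodes(doc, "summary-diamond"), "points"),
                  " ")[[1]]
  xy <- do.call(rbind, lapply(strsplit(pts, ","), as.numeric))
  xs <- sort(inv(xy[, 1]))
  expect_equal(xs[1], spec$summary_row$ci_lower, tolerance = 1e-9)
  expect_equal(xs[4], spec$summary_row$ci_upper, tolerance = 1e-9)
  expect_equal(xs[2], spec$summary_row$display, tolerance = 1e-9)
  expect_equal(xs[3], spec$summary_row$display, tolerance = 1e-9)
  # vertical summary line sits at the summary value
  line_x <- inv(svg_attr_num(svg_nodes(doc, "summary-line"), "x1"))
  expect_equal(line_x, spec$summary_row$display, tolerance = 1e-9)
})

test_that("paper-style summary uses a marker with an error bar instead", {
  spec <- build_plot_spec(study_rows(), summary_row, paper_style = TRUE)
  path <- tempfile(fileext = ".svg")
  render_forest(spec, path)
  doc <- xml2::read_xml(path)
  expect_length(svg_nodes(doc, "summary-errorbar"), 1)
  dia <- svg_nodes(doc, "summary-diamond")
  expect_equal(xml2::xml_attr(dia, "data-style"), "marker")
})

test_that("display multiplier rescales abscissae by exactly 100", {
  raw <- build_plot_spec(study_rows(), summary_row, display = "raw")
  pct <- build_plot_spec(study_rows(), summary_row, display = "percent")
  expect_equal(pct$rows$display, raw$rows$display * 100)
  expect_equal(pct$rows$lower_delta, raw$rows$lower_delta * 100)
  expect_equal(pct$rows$upper_delta, raw$rows$upper_delta * 100)
  expect_equal(pct$summary_row$display, raw$summary_row$display * 100)
  # with the window scaled alongside, pixel geometry is unchanged
  raw2 <- build_plot_spec(study_rows(), summary_row, display = "raw",
                          axis_min = 0.10, axis_max = 0.28, tick = 0.02)
  pct2 <- build_plot_spec(study_rows(), summary_row, display = "percent",
                          axis_min = 10, axis_max = 28, tick = 2)
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  suppressWarnings({render_forest(raw2, p1); render_forest(pct2, p2)})
  x_of <- function(p) svg_attr_num(svg_nodes(xml2::read_xml(p),
                                             "errorbar-lower"), "x2")
  expect_equal(x_of(p1), x_of(p2), tolerance = 1e-9)
})

test_that("points outside the axis window are clipped with a loud warning", {
  spec <- build_plot_spec(study_rows(), summary_row,
                          axis_min = 12, axis_max = 26, tick = 2)
  path <- tempfile(fileext = ".svg")
  warns <- capture_warnings(render_forest(spec, path))
  expect_true(any(grepl("study 'A'.*clipped", warns)))
  expect_true(any(grepl("study 'C'.*clipped", warns)))
})

test_that("PNG rendering writes a non-empty file", {
  spec <- build_plot_spec(study_rows(), summary_row)
  path <- tempfile(fileext = ".png")
  render_forest(spec, path, format = "png")
  expect_true(file.exists(path))
  expect_gt(file.size(path), 100)
})

test_that("the composed figure aligns table rows with plot ordinates", {
  fit <- meta_analysis(example_studies())
  spec <- build_plot_spec(estimates_table(fit), fit$random)
  path <- tempfile(fileext = ".svg")
  compose_with_table(spec, estimates_table(fit), path)
  doc <- xml2::read_xml(path)
  cells <- svg_nodes(doc, "table-cell")
  # 10 studies x 4 columns + 2 summary cells
  expect_length(cells, 42)
  ords <- svg_attr_num(cells, "data-ordinate")
  expect_setequal(unique(ords), 1:11)
  # row centres coincide with marker centres within half a row unit (14 px)
  markers <- svg_nodes(doc, "study-marker")
  m_y <- svg_attr_num(markers, "y") + svg_attr_num(markers, "height") / 2
  m_ord <- svg_attr_num(markers, "data-ordinate")
  for (i in seq_along(m_ord)) {
    cell_y <- svg_attr_num(cells[ords == m_ord[i]], "y")
    expect_true(all(abs(cell_y - m_y[i]) <= 14))
  }
  expect_error(compose_with_table(spec, estimates_table(fit)[1:5, ],
                                  tempfile()), "ordinates")
})

test_that("precomputed-mode tables omit the count columns", {
  rows <- study_rows()
  spec <- build_plot_spec(rows, summary_row)
  path <- tempfile(fileext = ".svg")
  compose_with_table(spec, rows, path)
  doc <- xml2::read_xml(path)
  headers <- xml2::xml_text(svg_nodes(doc, "table-header"))
  expect_false(any(grepl("Events|Total", headers)))
})
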