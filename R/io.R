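#' Read a study table from a CSV file
#'
#' Reads a comma-separated, UTF-8, header-required study table. Counts mode
#' needs columns `study` (or `label`), `events`, `total`; precomputed mode
#' needs `study`, `estimate`, `ci_lower`, `ci_upper` (optional `ci_level`).
#' Every validation error cites the offending data row number. Duplicate
#' study labels are rejected.
#'
#' @param path CSV file path.
#' @param effect_mode `"counts"` or `"precomputed"`; default infers from
#'   the header.
#' @return A validated study table (data frame) with a `label` column;
#'   the number of studies `k` is `nrow()` and is reported in a message.
#' @export
read_studies <- function(path, effect_mode = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("input file has no data rows: ", path, call. = FALSE)
  names(raw)[names(raw) == "study"] <- "label"
  if (!"label" %in% names(raw)) {
    stop("input must have a 'study' (or 'label') column", call. = FALSE)
  }
  if (is.null(effect_mode)) {
    effect_mode <- if (all(c("events", "total") %in% names(raw)))
      "counts" else "precomputed"
  }
  effect_mode <- match.arg(effect_mode, c("counts", "precomputed"))
  need <- if (effect_mode == "counts") c("events", "total")
          else c("estimate", "ci_lower", "ci_upper")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(effect_mode, " mode requires column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    bad <- which(!is.na(raw[[col]]) & !is.numeric(raw[[col]]) |
                   is.na(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad) > 0) {
      stop("row ", bad[1], ": non-numeric value in column '", col, "'",
           call. = FALSE)
    }
    raw[[col]] <- as.numeric(raw[[col]])
  }
  dup <- duplicated(raw$label)
  if (any(dup)) {
    stop("row ", which(dup)[1], ": duplicate study label '",
         raw$label[which(dup)[1]], "'", call. = FALSE)
  }
  if (effect_mode == "counts") {
    bad <- which(raw$events < 0 | raw$total < 1 | raw$events > raw$total)
    if (length(bad) > 0) {
      stop("row ", bad[1], " (study '", raw$label[bad[1]],
           "'): requires 0 <= events <= total with total >= 1",
           call. = FALSE)
    }
  } else {
    bad <- which(raw$ci_lower > raw$estimate | raw$estimate > raw$ci_upper)
    if (length(bad) > 0) {
      stop("row ", bad[1], " (study '", raw$label[bad[1]],
           "'): confidence interval must bracket the estimate", call. = FALSE)
    }
  }
  message("read ", nrow(raw), " studies (k = ", nrow(raw), ") from ", path)
  raw
}

#' Write analysis results to CSV or JSON
#'
#' Serialises a [meta_analysis()] fit so every intermediate quantity of the
#' pooling pipeline can be audited: the per-study columns `es`, `se`,
#' `var`, `w`, `w*es`, `w*es^2`, `w^2` plus the random-effects weight
#' `w_v`, a sums row, and a summary block with Q, df, I-squared, the
#' between-study variance `v`, and both pooled results with confidence
#' intervals. Leave-one-out tables are appended when present.
#'
#' JSON output round-trips through [read_results()].
#'
#' @param results A `descmeta` fit.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default infers from the extension.
#' @param digits Significant digits for CSV output (default 6); JSON keeps
#'   full precision.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = NULL, digits = 6) {
  stopifnot(inherits(results, "descmeta"))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  obj <- results_record(results)
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    sig <- function(x) ifelse(is.na(x), "", formatC(x, digits = digits,
                                                    format = "g"))
    tab <- obj$studies
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], sig)
    utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
    sums <- obj$sums
    writeLines(paste(c("sums", vapply(sums[-1], sig, character(1))),
                     collapse = ","), con)
    writeLines("", con)
    writeLines("section,model,quantity,value", con)
    emit <- function(model, quantity, value) {
      writeLines(paste("summary", model, quantity, sig(value), sep = ","), con)
    }
    for (model in c("fixed", "random")) {
      p <- obj[[model]]
      if (is.null(p)) next
      for (q in c("es_bar", "se_bar", "ci_lower", "ci_upper", "v")) {
        emit(model, q, p[[q]])
      }
      for (q in c("Q", "df", "I2", "p_value", "critical_value")) {
        emit(model, paste0("het_", q), p$het[[q]])
      }
    }
    if (!is.null(obj$sensitivity)) {
      for (model in names(obj$sensitivity)) {
        writeLines("", con)
        writeLines(paste0("leave_one_out_", model,
                          ",omitted,es_bar,ci_lower,ci_upper"), con)
        for (row in obj$sensitivity[[model]]) {
          writeLines(paste("", row$omitted, sig(row$es_bar),
                           sig(row$ci_lower), sig(row$ci_upper), sep = ","),
                     con)
        }
      }
    }
  }
  invisible(path)
}

# Plain-list form of a fit: the JSON schema and the CSV section source.
results_record <- function(results) {
  est <- results$estimates
  tab <- data.frame(label = est$label, es = est$es, se = est$se,
                    var = est$var, w = est$w, w_es = est$w_es,
                    w_es2 = est$w_es2, w2 = est$w2,
                    stringsAsFactors = FALSE)
  if (!is.null(results$random)) tab$w_v <- results$random$weights
  sums <- c(label = "sums", as.list(colSums(tab[, -1, drop = FALSE])))
  pool_block <- function(p) {
    if (is.null(p)) return(NULL)
    list(model = p$model, k = p$k, es_bar = p$es_bar, se_bar = p$se_bar,
         ci_lower = p$ci_lower, ci_upper = p$ci_upper, v = p$v,
         v_raw = p$v_raw, alpha = p$alpha,
         het = p$het[c("Q", "df", "I2", "I2_raw", "p_value",
                       "critical_value", "applicable")])
  }
  loo_block <- function(loo) {
    if (is.null(loo)) return(NULL)
    lapply(loo, function(e) list(omitted = e$omitted,
                                 es_bar = e$result$es_bar,
                                 ci_lower = e$result$ci_lower,
                                 ci_upper = e$result$ci_upper,
                                 v = e$result$v))
  }
  list(k = results$k, alpha = results$alpha, studies = tab, sums = sums,
       fixed = pool_block(results$fixed), random = pool_block(results$random),
       sensitivity = if (is.null(results$sensitivity)) NULL else
         lapply(results$sensitivity, loo_block))
}

#' Read back a JSON results file
#'
#' Parses the JSON written by [write_results()] into the same plain-list
#' structure, for round-trip checks and downstream consumption.
#'
#' @param path JSON results path.
#' @return A list mirroring the serialised record.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
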