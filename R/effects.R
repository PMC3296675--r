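#' Effect size of a single-group rate or prevalence
#'
#' Computes the per-study effect size for descriptive data: the rate
#' `es = events/total`, its standard error `se = es / sqrt(es * total)`
#' (algebraically `sqrt(events)/total`, the formula used by Comprehensive
#' Meta-Analysis for rates), the variance `se^2`, the inverse-variance
#' weight `w = 1/var`, and the derived products `w*es`, `w*es^2`, `w^2`
#' needed for heterogeneity statistics.
#'
#' The default standard error is the rate formula. `se_formula = "binomial"`
#' gives the exact binomial standard error `sqrt(es * (1 - es) / total)`
#' instead; the two agree closely for small rates.
#'
#' `events = 0` or `events = total` make the rate standard error degenerate
#' (zero weight is undefined), so such records are rejected with an error
#' unless they are first adjusted with [apply_zero_correction()].
#'
#' @param events Non-negative integer event count.
#' @param total Positive integer number of subjects.
#' @param label Study label carried through to the result.
#' @param se_formula `"cma-rate"` (default) or `"binomial"`.
#' @return A one-row `effect_estimate` data frame with columns
#'   `label`, `es`, `se`, `var`, `w`, `w_es`, `w_es2`, `w2`.
#' @examples
#' rate_effect(25, 100)          # es = 0.25, se = 0.05, w = 400
#' rate_effect(100, 400)         # es = 0.25, se = 0.025, w = 1600
#' @seealso [precomputed_effect()], [apply_zero_correction()]
#' @export
rate_effect <- function(events, total, label = NA_character_,
                        se_formula = c("cma-rate", "binomial")) {
  se_formula <- match.arg(se_formula)
  if (length(events) != 1L || length(total) != 1L) {
    stop("rate_effect() takes scalar counts; see effect_estimates() for tables",
         call. = FALSE)
  }
  if (!is.finite(total) || total <= 0) {
    stop("study ", format_label(label), ": total must be a positive count",
         call. = FALSE)
  }
  if (!is.finite(events) || events < 0 || events > total) {
    stop("study ", format_label(label),
         ": events must satisfy 0 <= events <= total", call. = FALSE)
  }
  if (events == 0 || events == total) {
    stop("study ", format_label(label), ": events = ", events, " of ", total,
         " gives a degenerate standard error; enable the continuity ",
         "correction (zero_correction / apply_zero_correction) or drop the study",
         call. = FALSE)
  }
  es <- events / total
  se <- switch(se_formula,
    "cma-rate" = es / sqrt(es * total),
    "binomial" = sqrt(es * (1 - es) / total)
  )
  new_effect_estimate(label, es, se)
}

#' Effect estimate from a pre-computed estimate and confidence interval
#'
#' Entry path for studies already analysed elsewhere: the standard error is
#' recovered from the confidence-interval width as
#' `se = (ci_upper - ci_lower) / (2 * z)` with `z` the exact standard-normal
#' quantile at `(1 + ci_level)/2`. A warning is issued when the interval is
#' asymmetric about the estimate by more than 1% of its width; the
#' full-width formula is used regardless.
#'
#' @param estimate Point estimate (a proportion for descriptive data, but any
#'   scale the confidence interval matches is accepted).
#' @param ci_lower,ci_upper Confidence bounds with
#'   `ci_lower <= estimate <= ci_upper`.
#' @param ci_level Confidence level as a fraction, default `0.95`.
#' @inheritParams rate_effect
#' @return A one-row `effect_estimate` data frame (see [rate_effect()]).
#' @examples
#' precomputed_effect(0.20, 0.10, 0.30)  # se ~ 0.051021
#' @export
precomputed_effect <- function(estimate, ci_lower, ci_upper, ci_level = 0.95,
                               label = NA_character_) {
  if (!is.finite(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  }
  if (!(is.finite(estimate) && is.finite(ci_lower) && is.finite(ci_upper))) {
    stop("study ", format_label(label), ": non-numeric estimate or CI bound",
         call. = FALSE)
  }
  if (ci_lower > estimate || estimate > ci_upper) {
    stop("study ", format_label(label),
         ": confidence interval must bracket the estimate ",
         "(ci_lower <= estimate <= ci_upper)", call. = FALSE)
  }
  width <- ci_upper - ci_lower
  if (width <= 0) {
    stop("study ", format_label(label),
         ": zero-width confidence interval implies infinite weight",
         call. = FALSE)
  }
  midpoint <- (ci_lower + ci_upper) / 2
  if (abs(midpoint - estimate) > 0.01 * width) {
    warning("study ", format_label(label), ": confidence interval is ",
            "asymmetric about the estimate; standard error taken from the ",
            "full interval width", call. = FALSE)
  }
  z <- stats::qnorm((1 + ci_level) / 2)
  new_effect_estimate(label, estimate, width / (2 * z))
}

#' Continuity correction for zero or full event counts
#'
#' The rate standard-error formula is undefined when `events = 0` and the
#' weight degenerates when `events = total`. This correction adds
#' `increment` to the events and `2 * increment` to the total, but only in
#' those boundary cases; interior counts pass through unchanged. Each
#' corrected study is reported with a message.
#'
#' @param events,total Study counts.
#' @param increment Positive correction increment, default `0.5`.
#' @param label Study label used in the log message.
#' @return A named numeric vector `c(events = ..., total = ...)`.
#' @examples
#' apply_zero_correction(0, 50)    # c(events = 0.5, total = 51)
#' apply_zero_correction(25, 100)  # unchanged
#' @export
apply_zero_correction <- function(events, total, increment = 0.5,
                                  label = NA_character_) {
  if (!is.finite(increment) || increment <= 0) {
    stop("increment must be > 0", call. = FALSE)
  }
  if (events == 0 || events == total) {
    message("continuity correction applied to study ", format_label(label),
            ": events ", events, " -> ", events + increment,
            ", total ", total, " -> ", total + 2 * increment)
    c(events = events + increment, total = total + 2 * increment)
  } else {
    c(events = events, total = total)
  }
}

#' Convert a study table into effect estimates
#'
#' Applies [rate_effect()] (counts mode) or [precomputed_effect()]
#' (precomputed mode) row by row to a validated study table such as the one
#' returned by [read_studies()] or [simulate_studies()].
#'
#' @param studies Data frame with columns `label`, `events`, `total`
#'   (counts mode) or `label`, `estimate`, `ci_lower`, `ci_upper` and
#'   optionally `ci_level` (precomputed mode).
#' @param effect_mode `"counts"` or `"precomputed"`; defaults to whichever
#'   set of columns is present.
#' @param se_formula Passed to [rate_effect()].
#' @param zero_correction `NULL`/`FALSE` to reject boundary counts (default),
#'   or a positive increment enabling the continuity correction.
#' @return An `effect_estimate` data frame with one row per study.
#' @examples
#' effect_estimates(example_studies())
#' @export
effect_estimates <- function(studies, effect_mode = NULL,
                             se_formula = c("cma-rate", "binomial"),
                             zero_correction = NULL) {
  se_formula <- match.arg(se_formula)
  if (is.null(effect_mode)) {
    effect_mode <- if (all(c("events", "total") %in% names(studies)))
      "counts" else "precomputed"
  }
  effect_mode <- match.arg(effect_mode, c("counts", "precomputed"))
  if (nrow(studies) < 1L) stop("no studies supplied", call. = FALSE)
  correct <- !is.null(zero_correction) && !identical(zero_correction, FALSE)
  increment <- if (correct && is.numeric(zero_correction))
    zero_correction else 0.5

  rows <- lapply(seq_len(nrow(studies)), function(i) {
    row <- studies[i, ]
    if (effect_mode == "counts") {
      ev <- row$events; n <- row$total
      if (correct) {
        adj <- apply_zero_correction(ev, n, increment, label = row$label)
        ev <- adj[["events"]]; n <- adj[["total"]]
      }
      rate_effect(ev, n, label = row$label, se_formula = se_formula)
    } else {
      level <- if ("ci_level" %in% names(row) && is.finite(row$ci_level))
        row$ci_level else 0.95
      precomputed_effect(row$estimate, row$ci_lower, row$ci_upper,
                         ci_level = level, label = row$label)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

# Constructor: fills var, w and the three derived products from (es, se).
new_effect_estimate <- function(label, es, se) {
  if (!is.finite(se) || se <= 0) {
    stop("study ", format_label(label), ": standard error must be positive",
         call. = FALSE)
  }
  v <- se^2
  w <- 1 / v
  out <- data.frame(
    label = as.character(label), es = es, se = se, var = v,
    w = w, w_es = w * es, w_es2 = w * es^2, w2 = w^2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("effect_estimate", "data.frame")
  out
}

format_label <- function(label) {
  if (length(label) != 1L || is.na(label)) "<unnamed>" else paste0("'", label, "'")
}
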