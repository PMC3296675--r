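#' Weighted column sums of an effect-estimate table
#'
#' Sums the inverse-variance weight columns study by study in input order:
#' `sum(w)`, `sum(w*es)`, `sum(w*es^2)` and `sum(w^2)`. These four sums
#' drive the pooled estimate, its standard error and Cochran's Q.
#' Accumulation uses R's long-double summation, so results are reproducible
#' across runs on the same platform.
#'
#' @param estimates An `effect_estimate` data frame ([effect_estimates()]).
#' @return Named numeric vector `c(w, w_es, w_es2, w2)`.
#' @export
weighted_sums <- function(estimates) {
  check_estimates(estimates, k_min = 1L)
  c(w = sum(estimates$w), w_es = sum(estimates$w_es),
    w_es2 = sum(estimates$w_es2), w2 = sum(estimates$w2))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w*es^2) - (sum(w*es))^2 / sum(w)`, the weighted sum of squared
#' deviations of the study effects from the pooled effect. Negative
#' round-off is clamped to zero.
#'
#' @param sums Named sums from [weighted_sums()].
#' @return Q (non-negative scalar).
#' @export
cochran_q <- function(sums) {
  if (!is.numeric(sums) || !all(c("w", "w_es", "w_es2") %in% names(sums))) {
    stop("sums must come from weighted_sums()", call. = FALSE)
  }
  if (sums[["w"]] <= 0) stop("sum of weights must be positive", call. = FALSE)
  q <- sums[["w_es2"]] - sums[["w_es"]]^2 / sums[["w"]]
  max(q, 0)
}

#' I-squared heterogeneity percentage
#'
#' `I2 = (Q - df)/Q * 100` with `df = k - 1`: the percentage of total
#' variability across effect sizes attributable to between-study
#' heterogeneity rather than sampling error. The raw value can be negative
#' when `Q < df`; the reported `I2` is clamped to `[0, 100]`.
#'
#' @param Q Cochran's Q.
#' @param k Number of studies (`k >= 2`; `k < 2` returns `NA` markers).
#' @return List with `I2` (clamped) and `I2_raw`.
#' @export
i_squared <- function(Q, k) {
  if (k < 2L) return(list(I2 = NA_real_, I2_raw = NA_real_))
  if (Q < 0) stop("Q must be non-negative", call. = FALSE)
  raw <- if (Q > 0) (Q - (k - 1)) / Q * 100 else 0
  list(I2 = min(max(raw, 0), 100), I2_raw = raw)
}

#' Chi-square reference for the Q test
#'
#' Returns the upper-`alpha` critical value of the chi-square distribution
#' at `df` degrees of freedom, and (when `Q` is supplied) the upper-tail
#' p-value of the observed Q — the classical table look-up the Q test is
#' referred to, computed exactly.
#'
#' @param df Degrees of freedom, `k - 1 >= 1`.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param Q Optional observed Q for the p-value.
#' @return List with `critical_value` and `p_value` (`NA` when `Q` missing).
#' @examples
#' q_reference(df = 9)$critical_value  # 16.919
#' @export
q_reference <- function(df, alpha = 0.05, Q = NULL) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  list(
    critical_value = stats::qchisq(1 - alpha, df = df),
    p_value = if (is.null(Q)) NA_real_
              else stats::pchisq(Q, df = df, lower.tail = FALSE)
  )
}

# Heterogeneity block computed from an estimate table with the weights it
# carries; used for both the fixed-weight test and the post-adjustment
# diagnostic under random-effects weights.
heterogeneity_stats <- function(estimates, alpha = 0.05) {
  k <- nrow(estimates)
  if (k < 2L) {
    return(structure(list(Q = NA_real_, df = NA_integer_, I2 = NA_real_,
                          I2_raw = NA_real_, p_value = NA_real_,
                          critical_value = NA_real_, alpha = alpha,
                          applicable = FALSE),
                     class = "heterogeneity_stats"))
  }
  sums <- weighted_sums(estimates)
  Q <- cochran_q(sums)
  i2 <- i_squared(Q, k)
  ref <- q_reference(df = k - 1L, alpha = alpha, Q = Q)
  structure(list(Q = Q, df = k - 1L, I2 = i2$I2, I2_raw = i2$I2_raw,
                 p_value = ref$p_value, critical_value = ref$critical_value,
                 alpha = alpha, applicable = TRUE),
            class = "heterogeneity_stats")
}

#' Fixed-effect pooled estimate
#'
#' Inverse-variance pooling under the fixed-effect model: the pooled
#' estimate is `sum(w*es)/sum(w)`, its standard error `sqrt(1/sum(w))`, and
#' the confidence interval `es_bar -/+ z * se_bar` with the exact normal
#' quantile at the stated level (1.959964 at the default `alpha = 0.05`).
#' Cochran's Q, I-squared, the chi-square p-value and critical value are
#' attached, computed with the fixed weights.
#'
#' With a single study the pooled result is the study itself and the
#' heterogeneity block is marked not applicable.
#'
#' @param estimates An `effect_estimate` data frame.
#' @param alpha Significance level for the confidence interval and Q test.
#' @return A `pooled_result` list: `model`, `k`, `es_bar`, `se_bar`,
#'   `ci_lower`, `ci_upper`, `v` (0 for fixed), `v_raw`, `weights`, `het`,
#'   `alpha`.
#' @examples
#' est <- effect_estimates(example_studies())
#' pool_fixed(est)
#' @export
pool_fixed <- function(estimates, alpha = 0.05) {
  check_estimates(estimates, k_min = 1L)
  sums <- weighted_sums(estimates)
  new_pooled_result(
    model = "fixed", estimates = estimates, weights = estimates$w,
    es_bar = sums[["w_es"]] / sums[["w"]], se_bar = sqrt(1 / sums[["w"]]),
    v = 0, v_raw = 0, alpha = alpha,
    het = heterogeneity_stats(estimates, alpha = alpha)
  )
}

#' DerSimonian-Laird between-study variance constant
#'
#' The moment estimator of the between-study variance (usually written
#' tau-squared; `v` here):
#' `v = (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w))`,
#' clamped to zero when `Q < k - 1`. The raw (possibly negative) value is
#' also returned.
#'
#' @inheritParams pool_fixed
#' @return List with `v` (clamped) and `v_raw`.
#' @export
dl_constant <- function(estimates) {
  check_estimates(estimates, k_min = 1L)
  k <- nrow(estimates)
  if (k < 2L) return(list(v = NA_real_, v_raw = NA_real_))
  sums <- weighted_sums(estimates)
  Q <- cochran_q(sums)
  denom <- sums[["w"]] - sums[["w2"]] / sums[["w"]]
  if (denom <= 0) {
    stop("degenerate weights: sum(w) - sum(w^2)/sum(w) must be positive",
         call. = FALSE)
  }
  raw <- (Q - (k - 1)) / denom
  list(v = max(raw, 0), v_raw = raw)
}

#' Random-effects pooled estimate (DerSimonian-Laird)
#'
#' Each study's weight is adjusted with the between-study variance constant
#' from [dl_constant()]: `w_v = 1/(se^2 + v)`. Pooling then repeats the
#' fixed-effect arithmetic with the adjusted weights, which widens the
#' confidence interval whenever `v > 0`. The attached heterogeneity block is
#' re-computed with the adjusted weights — the spreadsheet tradition's
#' post-adjustment diagnostic — and is labelled as such
#' (`het$diagnostic = TRUE`); it is not an inferential test.
#'
#' When `v = 0` the result coincides with [pool_fixed()] apart from the
#' model tag.
#'
#' @inheritParams pool_fixed
#' @return A `pooled_result` list (see [pool_fixed()]) carrying `v`.
#' @export
pool_random <- function(estimates, alpha = 0.05) {
  check_estimates(estimates, k_min = 2L)
  vv <- dl_constant(estimates)
  adjusted <- estimates
  adjusted$w <- 1 / (estimates$se^2 + vv$v)
  adjusted$w_es <- adjusted$w * adjusted$es
  adjusted$w_es2 <- adjusted$w * adjusted$es^2
  adjusted$w2 <- adjusted$w^2
  sums <- weighted_sums(adjusted)
  het <- heterogeneity_stats(adjusted, alpha = alpha)
  het$diagnostic <- TRUE
  new_pooled_result(
    model = "random", estimates = estimates, weights = adjusted$w,
    es_bar = sums[["w_es"]] / sums[["w"]], se_bar = sqrt(1 / sums[["w"]]),
    v = vv$v, v_raw = vv$v_raw, alpha = alpha, het = het
  )
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools `k` times, each time omitting one study, using the full model
#' pipeline (the between-study variance is re-estimated on each subset
#' under the random-effects model). Requires `k >= 3` so every subset still
#' supports the model.
#'
#' @inheritParams pool_fixed
#' @param model `"fixed"` or `"random"`.
#' @return A list of length `k`; element `i` has `omitted` (the label) and
#'   `result` (the [pool_fixed()]/[pool_random()] output on the subset).
#' @export
leave_one_out <- function(estimates, model = c("fixed", "random"),
                          alpha = 0.05) {
  model <- match.arg(model)
  check_estimates(estimates, k_min = 3L)
  pool <- if (model == "fixed") pool_fixed else pool_random
  lapply(seq_len(nrow(estimates)), function(i) {
    subset <- estimates[-i, , drop = FALSE]
    class(subset) <- c("effect_estimate", "data.frame")
    list(omitted = estimates$label[i], result = pool(subset, alpha = alpha))
  })
}

#' Run a complete meta-analysis on a study table
#'
#' Convenience pipeline: converts the study table to effect estimates
#' ([effect_estimates()]), pools under the fixed-effect and/or
#' DerSimonian-Laird random-effects model, and optionally attaches
#' leave-one-out sensitivity tables.
#'
#' @param studies Study table (see [effect_estimates()]).
#' @param model `"both"` (default), `"fixed"` or `"random"`.
#' @param alpha Significance level, default 0.05.
#' @param leave_one_out Logical; add sensitivity tables (needs `k >= 3`).
#' @inheritParams effect_estimates
#' @return A `descmeta` list with `studies`, `estimates`, `k`, `fixed`,
#'   `random`, `sensitivity`, `alpha`.
#' @examples
#' fit <- meta_analysis(example_studies())
#' print(fit)
#' @export
meta_analysis <- function(studies, model = c("both", "fixed", "random"),
                          alpha = 0.05, leave_one_out = FALSE,
                          effect_mode = NULL,
                          se_formula = c("cma-rate", "binomial"),
                          zero_correction = NULL) {
  model <- match.arg(model)
  se_formula <- match.arg(se_formula)
  estimates <- effect_estimates(studies, effect_mode = effect_mode,
                                se_formula = se_formula,
                                zero_correction = zero_correction)
  out <- list(studies = studies, estimates = estimates, k = nrow(estimates),
              alpha = alpha, fixed = NULL, random = NULL, sensitivity = NULL)
  if (model %in% c("both", "fixed")) {
    out$fixed <- pool_fixed(estimates, alpha = alpha)
  }
  if (model %in% c("both", "random")) {
    out$random <- if (nrow(estimates) >= 2L) pool_random(estimates, alpha = alpha)
                  else pool_fixed(estimates, alpha = alpha)
  }
  if (leave_one_out) {
    out$sensitivity <- list()
    if (!is.null(out$fixed)) {
      out$sensitivity$fixed <- leave_one_out(estimates, "fixed", alpha = alpha)
    }
    if (!is.null(out$random) && nrow(estimates) >= 3L) {
      out$sensitivity$random <- leave_one_out(estimates, "random", alpha = alpha)
    }
  }
  class(out) <- "descmeta"
  out
}

new_pooled_result <- function(model, estimates, weights, es_bar, se_bar,
                              v, v_raw, alpha, het) {
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(
    model = model, k = nrow(estimates), es_bar = es_bar, se_bar = se_bar,
    ci_lower = es_bar - z * se_bar, ci_upper = es_bar + z * se_bar,
    v = v, v_raw = v_raw, labels = estimates$label, weights = weights,
    het = het, alpha = alpha
  ), class = "pooled_result")
}

check_estimates <- function(estimates, k_min) {
  if (!is.data.frame(estimates) ||
      !all(c("label", "es", "se", "var", "w", "w_es", "w_es2", "w2")
           %in% names(estimates))) {
    stop("estimates must be an effect_estimate table from effect_estimates()",
         call. = FALSE)
  }
  if (nrow(estimates) < k_min) {
    stop("need at least ", k_min, " studies, got ", nrow(estimates),
         call. = FALSE)
  }
  if (!all(is.finite(estimates$w)) || any(estimates$w <= 0)) {
    stop("all study weights must be finite and positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.pooled_result <- function(x, digits = 6, ...) {
  cat(sprintf("%s-effect%s pooled estimate (k = %d)\n",
              if (x$model == "fixed") "Fixed" else "Random",
              if (x$model == "random") "s" else "", x$k))
  cat(sprintf("  es = %.*g  se = %.*g  %g%% CI [%.*g, %.*g]\n",
              digits, x$es_bar, digits, x$se_bar, 100 * (1 - x$alpha),
              digits, x$ci_lower, digits, x$ci_upper))
  if (x$model == "random") {
    cat(sprintf("  between-study variance v = %.*g (raw %.*g)\n",
                digits, x$v, digits, x$v_raw))
  }
  if (isTRUE(x$het$applicable)) {
    cat(sprintf("  %sQ = %.*g (df = %d, p = %.3g), I2 = %.1f%%\n",
                if (isTRUE(x$het$diagnostic)) "post-adjustment diagnostic: " else "",
                digits, x$het$Q, x$het$df, x$het$p_value, x$het$I2))
  }
  invisible(x)
}

#' @export
print.descmeta <- function(x, ...) {
  cat("Meta-analysis of", x$k, "single-group studies\n\n")
  if (!is.null(x$fixed)) { print(x$fixed); cat("\n") }
  if (!is.null(x$random)) print(x$random)
  if (!is.null(x$sensitivity)) {
    cat("\nLeave-one-out sensitivity tables attached ($sensitivity)\n")
  }
  invisible(x)
}
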