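#' Simulate single-group studies with known truth
#'
#' Generates `k` studies under the random-effects premise: each study draws
#' a true proportion `p_i` from a normal distribution centred at `true_p`
#' with standard deviation `between_sd` (on the proportion scale by
#' default, or on the logit scale), a denominator `n_i` uniform over
#' `n_range`, and `events_i ~ Binomial(n_i, p_i)`. With `between_sd = 0`
#' all studies share `true_p` and any dispersion is sampling error alone.
#'
#' True proportions are truncated to `[0.001, 0.999]` so the rate
#' standard-error formula stays defined; a message reports how many draws
#' were truncated. The generator never touches the global random state: it
#' runs under `withr::with_seed(seed, ...)`.
#'
#' @param k Number of studies.
#' @param n_range Integer vector `c(min, max)` for per-study denominators
#'   (`min >= 10`).
#' @param true_p Mean true proportion, in (0, 1).
#' @param between_sd Between-study standard deviation of the true
#'   proportion (>= 0).
#' @param heterogeneity_scale `"proportion"` (default) or `"logit"`:
#'   the scale on which the between-study normal is drawn.
#' @param seed Integer seed; required, for full reproducibility.
#' @return A study table (data frame) with columns `label`, `events`,
#'   `total` and attributes `true_p` (the per-study truths) and `config`.
#' @examples
#' simulate_studies(k = 10, seed = 42)
#' @export
simulate_studies <- function(k = 10, n_range = c(150, 600), true_p = 0.19,
                             between_sd = 0.03,
                             heterogeneity_scale = c("proportion", "logit"),
                             seed) {
  heterogeneity_scale <- match.arg(heterogeneity_scale)
  if (missing(seed) || !is.finite(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (true_p <= 0 || true_p >= 1) stop("true_p must be in (0, 1)", call. = FALSE)
  if (between_sd < 0) stop("between_sd must be >= 0", call. = FALSE)
  if (length(n_range) != 2L || n_range[1] < 10 || n_range[2] < n_range[1]) {
    stop("n_range must be c(min, max) with min >= 10", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    p_i <- if (heterogeneity_scale == "proportion") {
      stats::rnorm(k, mean = true_p, sd = between_sd)
    } else {
      stats::plogis(stats::rnorm(k, mean = stats::qlogis(true_p),
                                 sd = between_sd))
    }
    truncated <- sum(p_i < 0.001 | p_i > 0.999)
    if (truncated > 0) {
      message(truncated, " true proportion draw(s) truncated to [0.001, 0.999]")
    }
    p_i <- pmin(pmax(p_i, 0.001), 0.999)
    n_i <- if (n_range[1] == n_range[2]) rep(n_range[1], k)
           else sample(seq(n_range[1], n_range[2]), k, replace = TRUE)
    events <- stats::rbinom(k, size = n_i, prob = p_i)
    out <- data.frame(label = sprintf("study_%02d", seq_len(k)),
                      events = events, total = n_i,
                      stringsAsFactors = FALSE)
    attr(out, "true_p") <- p_i
    attr(out, "config") <- list(k = k, n_range = n_range, true_p = true_p,
                                between_sd = between_sd,
                                heterogeneity_scale = heterogeneity_scale,
                                seed = as.integer(seed))
    out
  })
}

#' Frozen ten-study example dataset
#'
#' A fixed synthetic table of ten studies emulating the regime of the
#' classical spreadsheet worked example for rate data: rates between about
#' 13% and 27%, denominators of a few hundred, and moderate fixed-effect
#' heterogeneity (Q above the 16.919 critical value at 9 degrees of
#' freedom, I-squared near 50%), so the random-effects interval is visibly
#' wider than the fixed-effect one. The counts are synthetic — generated
#' once from the binomial model behind [simulate_studies()] and then
#' frozen — and are version-controlled, not re-drawn at run time.
#'
#' @return A study table with columns `label`, `events`, `total`.
#' @examples
#' meta_analysis(example_studies())
#' @export
example_studies <- function() {
  data.frame(
    label = sprintf("study_%02d", 1:10),
    events = c(40L, 84L, 39L, 30L, 87L, 87L, 84L, 86L, 47L, 40L),
    total = c(216L, 447L, 154L, 234L, 418L, 496L, 566L, 457L, 233L, 151L),
    stringsAsFactors = FALSE
  )
}
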