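# Build an effect-estimate table directly from (es, se), independently of
# the package's own constructors, so pooling tests do not depend on the
# effects module.
make_estimates <- function(es, se, labels = sprintf("s%02d", seq_along(es))) {
  se <- rep_len(se, length(es))
  w <- 1 / se^2
  out <- data.frame(label = labels, es = es, se = se, var = se^2,
                    w = w, w_es = w * es, w_es2 = w * es^2, w2 = w^2,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

# Random small pooling instance for property tests.
random_instance <- function(k = sample(2:12, 1)) {
  es <- runif(k, 0.05, 0.9)
  se <- runif(k, 0.01, 0.2)
  make_estimates(es, se)
}

# Independent weighted-least-squares minimizer of sum(w * (es - mu)^2):
# QR-based lm fit, a route disjoint from the package's ratio-of-sums.
wls_oracle <- function(est) {
  unname(stats::coef(stats::lm(es ~ 1, data = est, weights = est$w))[1])
}

# SVG helpers: invert the pixel transform recorded in the root metadata.
svg_inverter <- function(doc) {
  r <- xml2::xml_root(doc)
  num <- function(a) as.numeric(xml2::xml_attr(r, a))
  amin <- num("data-axis-min"); amax <- num("data-axis-max")
  px <- num("data-plot-x"); pw <- num("data-plot-width")
  logscale <- identical(xml2::xml_attr(r, "data-axis-scale"), "logarithmic")
  function(p) {
    u <- if (logscale) log10(amin) + (p - px) / pw * (log10(amax) - log10(amin))
         else amin + (p - px) / pw * (amax - amin)
    if (logscale) 10^u else u
  }
}

svg_nodes <- function(doc, class) {
  xml2::xml_find_all(doc, sprintf("//*[@class='%s']", class))
}

svg_attr_num <- function(nodes, attr) as.numeric(xml2::xml_attr(nodes, attr))
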