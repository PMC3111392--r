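#' Likelihood-ratio chi-square test of nested fixed-effect structures
#'
#' Fits the full and the reduced fixed-effect structure to the same Ct data
#' by maximum likelihood (REML criteria are not comparable across different
#' fixed-effect structures) and refers twice the log-likelihood difference
#' to the chi-square distribution with degrees of freedom equal to the
#' number of dropped terms. A trivially negative difference within
#' numerical tolerance is clamped to zero.
#'
#' @param data Long-format Ct data (see [fit_mixed_model()]).
#' @param full_terms,reduced_terms Term label sets; `reduced_terms` must be
#'   a strict subset of `full_terms`.
#' @return An object of class `lrt_result`: `statistic`, `df`, `p_value`,
#'   `terms_dropped`, and the two ML log-likelihoods.
#' @examples
#' d <- generate_ct_dataset(effect_spec(delta_tau = 1), seed = 2)
#' likelihood_ratio_test(d, ct_terms(), setdiff(ct_terms(), "gene:hormone"))
#' @export
likelihood_ratio_test <- function(data, full_terms, reduced_terms) {
  if (!all(reduced_terms %in% full_terms) ||
      length(reduced_terms) >= length(full_terms)) {
    stop("`reduced_terms` must be a strict subset of `full_terms`",
         call. = FALSE)
  }
  ll_full <- ml_loglik(data, full_terms)
  ll_red <- ml_loglik(data, reduced_terms)
  stat <- max(0, 2 * (ll_full - ll_red))
  df <- length(full_terms) - length(reduced_terms)
  structure(list(
    statistic = stat,
    df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    terms_dropped = setdiff(full_terms, reduced_terms),
    loglik_full = ll_full,
    loglik_reduced = ll_red
  ), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT dropping {%s}: chisq = %.4f, df = %d, p = %.4g\n",
              paste(x$terms_dropped, collapse = ", "),
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# ML-only fit: a single profiled optimization, used in the test loops.
ml_loglik <- function(data, terms) {
  validate_ct_data(data)
  prep <- prep_lmm(data, terms)
  optimize_profile(prep, reml = FALSE, list(tol = 1e-10))$value
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, the r-th adjusted value is
#' \eqn{\min_{s \ge r} \min(1, p_{(s)} m / s)}, returned in the original
#' input order.
#'
#' @param p_values Numeric vector of p-values, all in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must all be finite and in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}
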