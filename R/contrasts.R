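#' Delta-delta-Ct contrast with fold change, CI and direction
#'
#' Extracts one of the reportable contrasts from a fitted Ct mixed model
#' and expresses it on the fold-change scale. Because a higher Ct means
#' lower expression, the log2 fold change is the negative of the
#' delta-delta-Ct value; `direction` is `Up` when expression is higher in
#' the knockout (or with testosterone), `Down` when lower, `none` for an
#' exactly null contrast.
#'
#' Contrast definitions (in terms of fitted coefficients):
#' * `genotype_within_placebo` - `gene:genotype`
#' * `genotype_within_T` - `gene:genotype + gene:genotype:hormone`
#' * `hormone_within_WT` - `gene:hormone`
#' * `hormone_within_KO` - `gene:hormone + gene:genotype:hormone`
#' * `genotype_effect` / `hormone_effect` - `gene:genotype` / `gene:hormone`
#'   from a model fitted *without* the three-way term (or from an intact
#'   2x2 fit, where `genotype_effect` is the only genotype contrast).
#'
#' The fold change is \eqn{2^{|\Delta\Delta C_t|}} (always >= 1) and the
#' 95% CI exponentiates the symmetric interval
#' \eqn{|\Delta\Delta C_t| \mp z\,\mathrm{se}}; the lower bound may fall
#' below 1 for weak contrasts.
#'
#' @param fit A converged [fit_mixed_model()] result containing the
#'   coefficients the label needs.
#' @param label One of the six contrast labels above.
#' @param z Normal quantile for the CI (default 1.959964, i.e. 95%).
#' @return A one-row `data.frame` of class `ddct_contrast` with columns
#'   `label`, `ddct`, `se` (cycles), `log2fc`, `fc`, `ci_low`, `ci_high`
#'   (fold scale) and `direction`.
#' @examples
#' d <- generate_ct_dataset(effect_spec(delta_gamma = -log2(14.03)), seed = 1)
#' ddct_contrast(fit_mixed_model(d), "genotype_within_placebo")
#' @export
ddct_contrast <- function(fit, label, z = 1.959964) {
  if (!inherits(fit, "ct_lmm")) {
    stop("`fit` must be a ct_lmm object", call. = FALSE)
  }
  if (!isTRUE(fit$converged)) {
    stop("cannot form contrasts from a non-converged fit", call. = FALSE)
  }
  needed <- contrast_coefs(label)
  absent <- setdiff(needed, names(fit$coefficients))
  if (length(absent)) {
    stop(sprintf("contrast '%s' needs term(s) not in the fitted model: %s",
                 label, paste(absent, collapse = ", ")), call. = FALSE)
  }
  w <- as.numeric(names(fit$coefficients) %in% needed)
  ddct <- sum(w * fit$coefficients)
  se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
  new_ddct_contrast(label, ddct, se, z)
}

contrast_coefs <- function(label) {
  switch(label,
    genotype_within_placebo = "gene:genotype",
    genotype_within_T = c("gene:genotype", "gene:genotype:hormone"),
    hormone_within_WT = "gene:hormone",
    hormone_within_KO = c("gene:hormone", "gene:genotype:hormone"),
    genotype_effect = "gene:genotype",
    hormone_effect = "gene:hormone",
    stop("unknown contrast label: ", label, call. = FALSE)
  )
}

new_ddct_contrast <- function(label, ddct, se, z = 1.959964) {
  log2fc <- -ddct
  fc <- 2^abs(log2fc)
  out <- data.frame(
    label = label,
    ddct = ddct,
    se = se,
    log2fc = log2fc,
    fc = fc,
    ci_low = 2^(abs(ddct) - z * se),
    ci_high = 2^(abs(ddct) + z * se),
    direction = if (ddct == 0) "none" else if (ddct < 0) "Up" else "Down",
    stringsAsFactors = FALSE
  )
  class(out) <- c("ddct_contrast", "data.frame")
  out
}

#' Classify a gene into the four regulation classes
#'
#' Applies a fixed decision procedure to one test gene paired with one
#' loading control, measured over the full factorial
#' (gene x genotype x hormone) design:
#'
#' 1. Likelihood-ratio test of the three-way `gene:genotype:hormone` term
#'    (full model vs full minus three-way, both ML). Significant at `alpha`
#'    => `both_interacting`; the four within-group contrasts are reported.
#' 2. Otherwise, from the no-three-way model, drop `gene:genotype` and
#'    `gene:hormone` in separate LRTs: both significant =>
#'    `both_independent`; only `gene:hormone` => `hormone_only`; only
#'    `gene:genotype` => `genotype_only`; neither => `none`.
#'
#' The omnibus p-value is the joint LRT of all three gene-interaction terms
#' (df = 3), i.e. of any genotype- or hormone-linked expression difference
#' of the test gene relative to the control. `passes_fc_filter` records
#' whether any reported contrast has a fold change (rounded to 2 decimals)
#' at or above `fc_threshold`.
#'
#' @param data Long-format Ct data for one gene/control pairing covering
#'   the full 2x2x2 design.
#' @param alpha Significance level for each LRT (default 0.05).
#' @param fc_threshold Fold-change reporting filter (default 1.5, applied
#'   inclusively to the 2-decimal rounded estimate).
#' @param arm Label of the knockout arm being analyzed (e.g. `"GKO"`,
#'   `"KKO"`), carried into reports.
#' @param z CI quantile, see [ddct_contrast()].
#' @return An object of class `regulation_call`: `gene`, `loading_control`,
#'   `genotype_arm`, `reg_class`, `omnibus_p`, `omnibus_p_adj` (`NA` until
#'   [adjust_regulation_calls()]), `term_p` (named p-values of the
#'   three-way and the two two-way LRTs), `contrasts` (the supporting
#'   [ddct_contrast()] rows) and `passes_fc_filter`.
#' @seealso [report_tables()], [adjust_regulation_calls()]
#' @examples
#' d <- generate_ct_dataset(effect_spec(delta_tau = log2(2.33)), seed = 3)
#' classify_regulation(d, arm = "KKO")
#' @export
classify_regulation <- function(data, alpha = 0.05, fc_threshold = 1.5,
                                arm = NA_character_, z = 1.959964) {
  validate_ct_data(data)
  if (infer_design(data) != "factorial_2x2x2" ||
      length(unique(data$hormone)) < 2 ||
      length(unique(data$genotype)) < 2 ||
      length(unique(data$role)) < 2) {
    stop("classification needs the full gene x genotype x hormone design",
         call. = FALSE)
  }
  full <- ct_terms()
  no3 <- setdiff(full, "gene:genotype:hormone")
  base <- setdiff(full, c("gene:genotype", "gene:hormone",
                          "gene:genotype:hormone"))
  # shared ML log-likelihoods (the full and no-three-way fits feed
  # several of the nested comparisons)
  ll <- list(
    full = ml_loglik(data, full),
    no3 = ml_loglik(data, no3),
    no3_gg = ml_loglik(data, setdiff(no3, "gene:genotype")),
    no3_gh = ml_loglik(data, setdiff(no3, "gene:hormone")),
    base = ml_loglik(data, base)
  )
  lrt <- function(lf, lr, dropped) {
    stat <- max(0, 2 * (lf - lr))
    df <- length(dropped)
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         terms_dropped = dropped)
  }
  p3 <- lrt(ll$full, ll$no3, "gene:genotype:hormone")
  pgg <- lrt(ll$no3, ll$no3_gg, "gene:genotype")
  pgh <- lrt(ll$no3, ll$no3_gh, "gene:hormone")
  omnibus <- lrt(ll$full, ll$base,
                 c("gene:genotype", "gene:hormone",
                   "gene:genotype:hormone"))

  if (p3$p_value < alpha) {
    reg_class <- "both_interacting"
    fit <- fit_mixed_model(data, full, "REML")
    labels <- c("genotype_within_placebo", "genotype_within_T",
                "hormone_within_WT", "hormone_within_KO")
  } else {
    sig_gg <- pgg$p_value < alpha
    sig_gh <- pgh$p_value < alpha
    reg_class <- if (sig_gg && sig_gh) "both_independent"
      else if (sig_gh) "hormone_only"
      else if (sig_gg) "genotype_only"
      else "none"
    fit <- fit_mixed_model(data, no3, "REML")
    labels <- switch(reg_class,
      both_independent = c("genotype_effect", "hormone_effect"),
      hormone_only = "hormone_effect",
      genotype_only = "genotype_effect",
      none = c("genotype_effect", "hormone_effect")
    )
  }
  contrasts <- do.call(rbind, lapply(labels, function(l) {
    ddct_contrast(fit, l, z = z)
  }))
  structure(list(
    gene = unique(data$gene[data$role == "test"])[1],
    loading_control = unique(data$gene[data$role == "loading_control"])[1],
    genotype_arm = arm,
    reg_class = reg_class,
    omnibus_p = omnibus$p_value,
    omnibus_p_adj = NA_real_,
    term_p = c(three_way = p3$p_value, gene_genotype = pgg$p_value,
               gene_hormone = pgh$p_value),
    contrasts = contrasts,
    passes_fc_filter = any(round(contrasts$fc, 2) >= fc_threshold),
    alpha = alpha,
    fc_threshold = fc_threshold
  ), class = "regulation_call")
}

#' @export
print.regulation_call <- function(x, ...) {
  cat(sprintf("%s (control %s, arm %s): %s\n", x$gene, x$loading_control,
              x$genotype_arm, x$reg_class))
  cat(sprintf("  omnibus p = %.3g (BH-adjusted: %s)\n", x$omnibus_p,
              ifelse(is.na(x$omnibus_p_adj), "not yet adjusted",
                     format(x$omnibus_p_adj, digits = 3))))
  print(x$contrasts)
  invisible(x)
}

#' Adjust omnibus p-values across a family of regulation calls
#'
#' Applies Benjamini-Hochberg adjustment to the omnibus p-values of the
#' calls in one analysis family (all genes analyzed against one loading
#' control within one knockout arm) and fills their `omnibus_p_adj` slots.
#'
#' @param calls List of [classify_regulation()] results.
#' @return The list with `omnibus_p_adj` populated.
#' @export
adjust_regulation_calls <- function(calls) {
  stopifnot(all(vapply(calls, inherits, logical(1), "regulation_call")))
  adj <- benjamini_hochberg(vapply(calls, `[[`, numeric(1), "omnibus_p"))
  for (i in seq_along(calls)) calls[[i]]$omnibus_p_adj <- adj[i]
  calls
}
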