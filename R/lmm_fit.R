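#' @title Linear mixed-effects model for factorial Ct data
#'
#' @description
#' Fits the Gaussian model
#' \deqn{y = X\beta + Z\alpha + \varepsilon,\qquad
#'       \alpha \sim N(0, \sigma_\alpha^2 I),\;
#'       \varepsilon \sim N(0, \sigma_\varepsilon^2 I)}
#' with a single random intercept per animal, by direct maximization of the
#' REML or ML criterion profiled over the variance ratio
#' \eqn{\lambda = \sigma_\alpha^2 / \sigma_\varepsilon^2}. Because the model
#' has exactly one variance ratio, the profiled criterion is one-dimensional
#' in \eqn{\log\lambda} and is maximized by Brent's method on a bracketed
#' interval (\eqn{\lambda \in [10^{-8}, 10^8]}), with the boundary
#' \eqn{\lambda = 0} (no animal variance) evaluated explicitly so that
#' \eqn{\hat\sigma_\alpha} is constrained non-negative by construction.
#' Fixed effects are the generalized least squares solution at the optimum
#' and their covariance is the GLS covariance there.
#'
#' Fixed-effect terms use a reference-cell (treatment-contrast)
#' parameterization with `loading_control` / `wild_type` / `placebo` as
#' reference levels, so coefficients are directly the planted quantities of
#' [effect_spec()]: `gene:genotype` is the gene-by-genotype interaction
#' whose negative is the knockout log2 fold change in the placebo arm, etc.
#'
#' Both the REML and the ML criterion are maximized (each by its own 1-D
#' search); the reported coefficients and variance components come from the
#' requested `criterion`, while `ml_loglik` always refers to the ML optimum
#' so that likelihood-ratio comparisons of fixed-effect structures are
#' valid.
#'
#' @param data Long-format Ct data as produced by [generate_ct_dataset()]
#'   or [read_ct_table()]: columns `role`, `genotype`, `hormone`, `animal`,
#'   `ct` (plus `gene`, `rep`, unused here). All `ct` must be finite.
#' @param terms Character vector of fixed-effect term labels among
#'   `r paste0('\x60', ct_terms(), '\x60', collapse = ", ")`; the intercept
#'   is always included. `NULL` uses every term supported by the design
#'   (all seven for a factorial dataset, `gene`, `genotype` and
#'   `gene:genotype` for an intact one).
#' @param criterion `"REML"` (default, for reported estimates) or `"ML"`
#'   (for likelihood-ratio comparisons).
#' @param control List of optimizer settings: `tol` (relative criterion
#'   tolerance of the Brent search, default `1e-10`) and `maxit`
#'   (default 200).
#' @return An object of class `ct_lmm` with elements `coefficients` (named,
#'   cycles), `vcov` (GLS covariance, cycles^2), `sigma_alpha`, `sigma_eps`
#'   (cycles), `lambda`, `reml_loglik`, `ml_loglik`, `n_obs`, `n_animals`,
#'   `terms`, `design`, `criterion` and `converged`.
#' @seealso [likelihood_ratio_test()], [ddct_contrast()]
#' @examples
#' d <- generate_ct_dataset(effect_spec(delta_gamma = -2), seed = 1)
#' fit <- fit_mixed_model(d)
#' coef(fit)
#' @export
fit_mixed_model <- function(data, terms = NULL,
                            criterion = c("REML", "ML"),
                            control = list()) {
  criterion <- match.arg(criterion)
  ctrl <- utils::modifyList(list(tol = 1e-10, maxit = 200), control)
  validate_ct_data(data)
  design <- infer_design(data)
  if (is.null(terms)) terms <- default_terms(design)
  prep <- prep_lmm(data, terms)

  opt_reml <- optimize_profile(prep, reml = TRUE, ctrl)
  opt_ml <- optimize_profile(prep, reml = FALSE, ctrl)
  opt <- if (criterion == "REML") opt_reml else opt_ml

  at <- profile_eval(opt$lambda, prep, reml = (criterion == "REML"),
                     full = TRUE)
  structure(list(
    coefficients = at$beta,
    vcov = at$vcov,
    sigma_alpha = sqrt(opt$lambda * at$sigma2),
    sigma_eps = sqrt(at$sigma2),
    lambda = opt$lambda,
    reml_loglik = opt_reml$value,
    ml_loglik = opt_ml$value,
    n_obs = prep$n,
    n_animals = prep$G,
    terms = terms,
    design = design,
    criterion = criterion,
    converged = opt$converged && opt_ml$converged
  ), class = "ct_lmm")
}

#' @export
print.ct_lmm <- function(x, ...) {
  cat(sprintf("Ct linear mixed model (%s, %s design)\n", x$criterion,
              x$design))
  cat(sprintf("  %d observations, %d animals\n", x$n_obs, x$n_animals))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se)
  print(round(tab, 4))
  cat(sprintf("  sigma_alpha = %.4f, sigma_eps = %.4f cycles\n",
              x$sigma_alpha, x$sigma_eps))
  cat(sprintf("  REML loglik %.4f, ML loglik %.4f\n",
              x$reml_loglik, x$ml_loglik))
  invisible(x)
}

#' @export
coef.ct_lmm <- function(object, ...) object$coefficients

#' @export
vcov.ct_lmm <- function(object, ...) object$vcov

#' @export
logLik.ct_lmm <- function(object, ...) {
  ll <- if (object$criterion == "REML") object$reml_loglik else
    object$ml_loglik
  structure(ll, df = length(object$coefficients) + 2L, class = "logLik")
}

#' Fixed-effect term labels of the factorial Ct model
#'
#' @return Character vector of the seven term labels (intercept excluded).
#' @export
ct_terms <- function() {
  c("gene", "genotype", "hormone", "gene:genotype", "gene:hormone",
    "genotype:hormone", "gene:genotype:hormone")
}

default_terms <- function(design) {
  if (design == "intact_2x2") c("gene", "genotype", "gene:genotype")
  else ct_terms()
}

infer_design <- function(data) {
  if (any(data$hormone == "not_applicable")) "intact_2x2" else
    "factorial_2x2x2"
}

# Validation shared by the reader and the fitter.
validate_ct_data <- function(data) {
  req <- c("gene", "role", "genotype", "hormone", "animal", "rep", "ct")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("Ct data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(data$ct) || any(!is.finite(data$ct))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(data$ct))))
    stop("non-finite ct value(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; non-detects are not supported", call. = FALSE)
  }
  chk <- function(col, levels) {
    bad <- setdiff(unique(data[[col]]), levels)
    if (length(bad)) {
      stop(sprintf("unknown %s level(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  chk("role", c("loading_control", "test"))
  chk("genotype", c("wild_type", "knockout"))
  chk("hormone", c("placebo", "testosterone", "not_applicable"))
  if (any(data$hormone == "not_applicable") &&
      !all(data$hormone == "not_applicable")) {
    stop("hormone = not_applicable may not be mixed with implant arms",
         call. = FALSE)
  }
  # animals must be nested within (genotype, hormone) cells
  cell <- paste(data$genotype, data$hormone)
  if (any(tapply(cell, data$animal, function(x) length(unique(x))) > 1)) {
    stop("animal identifiers recur across (genotype, hormone) cells",
         call. = FALSE)
  }
  invisible(data)
}

# Design matrix under the treatment-contrast parameterization.
build_design_matrix <- function(data, terms) {
  unknown <- setdiff(terms, ct_terms())
  if (length(unknown)) {
    stop("unknown model term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  t_ <- as.numeric(data$role == "test")
  g_ <- as.numeric(data$genotype == "knockout")
  h_ <- as.numeric(data$hormone == "testosterone")
  cols <- list(
    "(Intercept)" = rep(1, nrow(data)),
    "gene" = t_, "genotype" = g_, "hormone" = h_,
    "gene:genotype" = t_ * g_, "gene:hormone" = t_ * h_,
    "genotype:hormone" = g_ * h_, "gene:genotype:hormone" = t_ * g_ * h_
  )
  keep <- c("(Intercept)", intersect(ct_terms(), terms))
  X <- do.call(cbind, cols[keep])
  colnames(X) <- keep
  X
}

# Precompute the per-animal sufficient statistics of the profiled criterion.
prep_lmm <- function(data, terms) {
  X <- build_design_matrix(data, terms)
  y <- data$ct
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design: term(s) not identifiable from the data: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  grp <- factor(data$animal, levels = unique(data$animal))
  G <- nlevels(grp)
  if (G < 2) stop("at least 2 animals are required", call. = FALSE)
  idx <- split(seq_along(y), grp)
  p <- ncol(X)
  M <- vapply(idx, function(i) colSums(X[i, , drop = FALSE]), numeric(p))
  u <- vapply(idx, function(i) sum(y[i]), numeric(1))
  ng <- lengths(idx)
  list(XtX = crossprod(X), Xty = drop(crossprod(X, y)),
       yty = sum(y * y), M = M, u = u, ng = ng,
       n = length(y), p = p, G = G, names = colnames(X))
}

# Profiled (restricted) log-likelihood at a given variance ratio lambda.
# The animal structure makes V = I + lambda * Z Z' block diagonal with
# blocks I + lambda * J, so V^{-1} and log|V| have closed forms per animal.
profile_eval <- function(lambda, prep, reml, full = FALSE) {
  cg <- lambda / (1 + lambda * prep$ng)
  A <- prep$XtX - prep$M %*% (cg * t(prep$M))
  b <- prep$Xty - drop(prep$M %*% (cg * prep$u))
  q <- prep$yty - sum(cg * prep$u^2)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(if (full) NULL else -Inf)
  beta <- backsolve(R, forwardsolve(t(R), b))
  rVr <- max(q - sum(b * beta), 1e-300)
  logdetV <- sum(log1p(lambda * prep$ng))
  n <- prep$n; p <- prep$p
  if (reml) {
    s2 <- rVr / (n - p)
    logdetA <- 2 * sum(log(diag(R)))
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + logdetV + logdetA)
  } else {
    s2 <- rVr / n
    ll <- -0.5 * (n * (log(2 * pi * s2) + 1) + logdetV)
  }
  if (!full) return(ll)
  Ainv <- chol2inv(R)
  s2_reml <- rVr / (n - p)  # covariance always uses the REML-scale variance
  vc <- if (reml) s2 * Ainv else s2_reml * Ainv
  dimnames(vc) <- list(prep$names, prep$names)
  names(beta) <- prep$names
  list(beta = beta, sigma2 = s2, vcov = vc, loglik = ll)
}

# Brent search over log(lambda) plus an explicit lambda = 0 boundary check.
optimize_profile <- function(prep, reml, ctrl) {
  f <- function(loglam) profile_eval(exp(loglam), prep, reml)
  lo <- log(1e-8); hi <- log(1e8)
  # criterion is locally quadratic in log(lambda): an x-tolerance of
  # sqrt(tol) bounds the criterion error by ~tol
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                         tol = max(sqrt(ctrl$tol), 1e-8))
  cand <- list(c(lambda = exp(opt$maximum), value = opt$objective),
               c(lambda = 0, value = profile_eval(0, prep, reml)))
  best <- cand[[which.max(vapply(cand, `[`, numeric(1), "value"))]]
  if (!is.finite(best[["value"]])) {
    stop("mixed-model fit failed to converge: non-finite criterion",
         call. = FALSE)
  }
  list(lambda = best[["lambda"]], value = best[["value"]], converged = TRUE)
}
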