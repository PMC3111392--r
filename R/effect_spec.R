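#' Ground-truth effect specification for simulated Ct data
#'
#' Bundles the fixed effects and variance components of the factorial
#' Ct model used by [generate_ct_dataset()]. Effects are expressed in Ct
#' cycles under a reference-cell (treatment-contrast) parameterization with
#' `loading_control` / `wild_type` / `placebo` as the reference levels, so
#' each planted value maps one-to-one onto a fitted model coefficient.
#'
#' The expected Ct of an observation is
#' \deqn{\mu + \delta t + \gamma g + \tau h + \delta\gamma\, t g +
#'       \delta\tau\, t h + \gamma\tau\, g h + \delta\gamma\tau\, t g h}
#' where \eqn{t}, \eqn{g}, \eqn{h} indicate test gene, knockout genotype and
#' testosterone arm. On top sit a Gaussian animal random intercept
#' (SD `sigma_alpha`) and independent technical noise (SD `sigma_eps`).
#'
#' In the `intact_2x2` design (no castration/implant arm) the hormone factor
#' is absent: `tau` and every interaction containing it must be zero and the
#' simulated `hormone` column is `not_applicable`.
#'
#' @param mu Baseline Ct level (cycles) of the reference cell.
#' @param delta Gene-role offset (test vs loading control), cycles.
#' @param gamma Genotype offset (knockout vs wild type), cycles.
#' @param tau Hormone offset (testosterone vs placebo), cycles.
#' @param delta_gamma,delta_tau,gamma_tau,delta_gamma_tau Interaction
#'   offsets, cycles. `delta_gamma` is the gene-by-genotype term whose
#'   negative is the log2 fold change of the knockout in the placebo arm.
#' @param sigma_alpha Animal random-intercept SD, cycles (>= 0).
#' @param sigma_eps Technical-replicate SD, cycles (>= 0).
#' @param n_animals_per_cell Animals per (genotype, hormone) cell (>= 1).
#' @param n_tech_reps Technical replicates per animal per gene role (>= 1).
#' @param design `"factorial_2x2x2"` (castrate placebo/testosterone arms) or
#'   `"intact_2x2"` (gene x genotype only).
#' @return An object of class `effect_spec`.
#' @seealso [generate_ct_dataset()]
#' @examples
#' spec <- effect_spec(mu = 20, delta_gamma = -log2(14.03))
#' spec
#' @export
effect_spec <- function(mu = 20, delta = 0, gamma = 0, tau = 0,
                        delta_gamma = 0, delta_tau = 0, gamma_tau = 0,
                        delta_gamma_tau = 0,
                        sigma_alpha = 0.15, sigma_eps = 0.3,
                        n_animals_per_cell = 3, n_tech_reps = 4,
                        design = c("factorial_2x2x2", "intact_2x2")) {
  design <- match.arg(design)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
    as.numeric(x)
  }
  spec <- list(
    mu = num1(mu, "mu"), delta = num1(delta, "delta"),
    gamma = num1(gamma, "gamma"), tau = num1(tau, "tau"),
    delta_gamma = num1(delta_gamma, "delta_gamma"),
    delta_tau = num1(delta_tau, "delta_tau"),
    gamma_tau = num1(gamma_tau, "gamma_tau"),
    delta_gamma_tau = num1(delta_gamma_tau, "delta_gamma_tau"),
    sigma_alpha = num1(sigma_alpha, "sigma_alpha"),
    sigma_eps = num1(sigma_eps, "sigma_eps"),
    n_animals_per_cell = num1(n_animals_per_cell, "n_animals_per_cell"),
    n_tech_reps = num1(n_tech_reps, "n_tech_reps"),
    design = design
  )
  class(spec) <- "effect_spec"
  validate_effect_spec(spec)
  spec
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("Ct effect specification (", x$design, ")\n", sep = "")
  eff <- unlist(x[c("mu", "delta", "gamma", "tau", "delta_gamma",
                    "delta_tau", "gamma_tau", "delta_gamma_tau")])
  cat("  fixed effects (cycles):\n")
  print(round(eff, 4))
  cat(sprintf("  sigma_alpha = %.4g, sigma_eps = %.4g cycles\n",
              x$sigma_alpha, x$sigma_eps))
  cat(sprintf("  %d animal(s) per cell, %d technical rep(s)\n",
              x$n_animals_per_cell, x$n_tech_reps))
  invisible(x)
}

validate_effect_spec <- function(spec) {
  if (spec$sigma_alpha < 0) {
    stop("invalid effect_spec: sigma_alpha must be >= 0", call. = FALSE)
  }
  if (spec$sigma_eps < 0) {
    stop("invalid effect_spec: sigma_eps must be >= 0", call. = FALSE)
  }
  if (spec$n_animals_per_cell < 1 ||
      spec$n_animals_per_cell != round(spec$n_animals_per_cell)) {
    stop("invalid effect_spec: n_animals_per_cell must be an integer >= 1",
         call. = FALSE)
  }
  if (spec$n_tech_reps < 1 || spec$n_tech_reps != round(spec$n_tech_reps)) {
    stop("invalid effect_spec: n_tech_reps must be an integer >= 1",
         call. = FALSE)
  }
  if (spec$design == "intact_2x2") {
    hterms <- c("tau", "delta_tau", "gamma_tau", "delta_gamma_tau")
    bad <- hterms[vapply(spec[hterms], function(v) v != 0, logical(1))]
    if (length(bad)) {
      stop("invalid effect_spec: in an intact_2x2 design the term(s) ",
           paste(bad, collapse = ", "), " must be exactly 0", call. = FALSE)
    }
  }
  invisible(spec)
}
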