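planted_spec <- effect_spec(mu = 21, delta = 2, gamma = 0.3, tau = -0.2,
                            delta_gamma = -1.2, delta_tau = 0.8,
                            gamma_tau = 0.1, delta_gamma_tau = 0.5,
                            sigma_alpha = 0.4, sigma_eps = 0.3)
planted_vec <- c("(Intercept)" = 21, "gene" = 2, "genotype" = 0.3,
                 "hormone" = -0.2, "gene:genotype" = -1.2,
                 "gene:hormone" = 0.8, "genotype:hormone" = 0.1,
                 "gene:genotype:hormone" = 0.5)

test_that("noise-free data recover the planted coefficients exactly", {
  spec <- effect_spec(mu = 21, delta = 2, gamma = 0.3, tau = -0.2,
                      delta_gamma = -1.2, delta_tau = 0.8,
                      gamma_tau = 0.1, delta_gamma_tau = 0.5,
                      sigma_alpha = 0, sigma_eps = 1e-8)  # tiny jitter
  d <- generate_ct_dataset(spec, seed = 1)
  fit <- fit_mixed_model(d)
  expect_lt(max(abs(fit$coefficients - planted_vec)), 1e-6)
})

test_that("the profiled optimum beats an exhaustive variance grid", {
  spec <- effect_spec(mu = 20, delta = 1, delta_gamma = -1,
                      sigma_alpha = 0.4, sigma_eps = 0.3,
                      n_animals_per_cell = 2, n_tech_reps = 2)
  d <- generate_ct_dataset(spec, seed = 17)
  fit <- fit_mixed_model(d)
  grid_best <- grid_search_reml(d, n_grid = 120)
  expect_gte(fit$reml_loglik, grid_best - 1e-4)
  expect_lt(fit$reml_loglik - grid_best, 0.05)  # grid coarseness bound
})

test_that("balanced-design estimates equal cell-mean contrasts", {
  d <- generate_ct_dataset(planted_spec, seed = 23)
  fit <- fit_mixed_model(d)
  m <- function(role, g, h) cell_mean(d, role, g, h)
  # treatment-contrast closed forms from the 8 cell means
  dct <- function(g, h) m("test", g, h) - m("loading_control", g, h)
  expected <- c(
    m("loading_control", "wild_type", "placebo"),
    dct("wild_type", "placebo"),
    m("loading_control", "knockout", "placebo") -
      m("loading_control", "wild_type", "placebo"),
    m("loading_control", "wild_type", "testosterone") -
      m("loading_control", "wild_type", "placebo"),
    dct("knockout", "placebo") - dct("wild_type", "placebo"),
    dct("wild_type", "testosterone") - dct("wild_type", "placebo"),
    (m("loading_control", "knockout", "testosterone") -
       m("loading_control", "wild_type", "testosterone")) -
      (m("loading_control", "knockout", "placebo") -
         m("loading_control", "wild_type", "placebo")),
    (dct("knockout", "testosterone") - dct("wild_type", "testosterone")) -
      (dct("knockout", "placebo") - dct("wild_type", "placebo"))
  )
  expect_equal(unname(fit$coefficients), expected, tolerance = 1e-8)
})

test_that("estimates, variance components and logliks match lme4", {
  skip_if_not_installed("lme4")
  d <- generate_ct_dataset(planted_spec, seed = 7)
  fit <- fit_mixed_model(d)
  t_ <- as.numeric(d$role == "test")
  g_ <- as.numeric(d$genotype == "knockout")
  h_ <- as.numeric(d$hormone == "testosterone")
  lf <- lme4::lmer(ct ~ t_ * g_ * h_ + (1 | animal), data = d, REML = TRUE)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(lf)),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma_alpha, vc$sdcor[1], tolerance = 1e-4)
  expect_equal(fit$sigma_eps, vc$sdcor[2], tolerance = 1e-4)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(lf)),
               tolerance = 1e-6)
  expect_equal(unname(as.matrix(fit$vcov)),
               unname(as.matrix(stats::vcov(lf))), tolerance = 1e-4)
  mlf <- lme4::lmer(ct ~ t_ * g_ * h_ + (1 | animal), data = d,
                    REML = FALSE)
  expect_equal(fit$ml_loglik, as.numeric(stats::logLik(mlf)),
               tolerance = 1e-6)
})

test_that("the coefficient covariance is symmetric positive semidefinite", {
  for (s in 1:5) {
    d <- generate_ct_dataset(planted_spec, seed = 100 + s)
    fit <- fit_mixed_model(d)
    expect_equal(fit$vcov, t(fit$vcov))
    expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-12))
    expect_gt(fit$sigma_eps, 0)
    expect_gte(fit$sigma_alpha, 0)
  }
})

test_that("sigma_alpha shrinks to the boundary when there is no animal variance", {
  est <- vapply(1:200, function(s) {
    d <- generate_ct_dataset(effect_spec(sigma_alpha = 0, sigma_eps = 0.3,
                                         n_animals_per_cell = 3),
                             seed = 2000 + s)
    fit_mixed_model(d)$sigma_alpha
  }, numeric(1))
  expect_true(all(est >= 0))
  expect_lt(stats::median(est), 0.05)
})

test_that("unsupported designs raise identifiability errors naming the term", {
  d <- generate_ct_dataset(effect_spec(design = "intact_2x2"), seed = 1)
  expect_error(fit_mixed_model(d, ct_terms()), "hormone")
  d2 <- generate_ct_dataset(effect_spec(), seed = 1)
  d2 <- d2[d2$hormone == "placebo", ]
  expect_error(fit_mixed_model(d2, ct_terms()), "hormone")
})

test_that("non-finite Ct values are rejected, never imputed", {
  d <- generate_ct_dataset(effect_spec(), seed = 1)
  d$ct[5] <- NA
  expect_error(fit_mixed_model(d), "non-finite")
  d$ct[5] <- Inf
  expect_error(fit_mixed_model(d), "non-finite")
})
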