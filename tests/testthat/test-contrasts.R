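test_that("fold change, CI and direction follow the ddCt formulas", {
  # a -3.8105-cycle contrast is a 14.03-fold up-regulation
  up <- qpcrlmm:::new_ddct_contrast("genotype_effect", -3.8105, 1e-12)
  expect_equal(up$fc, 2^3.8105, tolerance = 1e-10)
  expect_equal(round(up$fc, 2), 14.03)
  expect_equal(up$direction, "Up")

  none <- qpcrlmm:::new_ddct_contrast("genotype_effect", 0, 0.5)
  expect_equal(none$fc, 1)
  expect_equal(none$direction, "none")

  down <- qpcrlmm:::new_ddct_contrast("hormone_effect", 1, 0.1)
  expect_equal(down$fc, 2)
  expect_equal(down$ci_low, 2^0.804, tolerance = 1e-4)
  expect_equal(down$ci_high, 2^1.196, tolerance = 1e-4)
  expect_equal(down$direction, "Down")
  # CI width identity on the log2 scale
  expect_equal(log2(down$ci_high) - log2(down$ci_low),
               2 * 1.959964 * 0.1, tolerance = 1e-10)
})

test_that("noise-free contrasts equal the planted effect combinations", {
  spec <- effect_spec(mu = 20, delta = 1.5, gamma = 0.2, tau = 0.1,
                      delta_gamma = -0.9, delta_tau = 1.3,
                      gamma_tau = -0.2, delta_gamma_tau = 0.7,
                      sigma_alpha = 0, sigma_eps = 1e-8)
  d <- generate_ct_dataset(spec, seed = 2)
  fit <- fit_mixed_model(d)
  planted <- c(genotype_within_placebo = -0.9,
               genotype_within_T = -0.9 + 0.7,
               hormone_within_WT = 1.3,
               hormone_within_KO = 1.3 + 0.7)
  for (lab in names(planted)) {
    ct <- ddct_contrast(fit, lab)
    expect_equal(ct$ddct, unname(planted[lab]), tolerance = 1e-6)
    expect_equal(ct$fc, 2^abs(planted[lab]), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
  fit2 <- fit_mixed_model(d, setdiff(ct_terms(), "gene:genotype:hormone"))
  expect_error(ddct_contrast(fit2, "genotype_within_T"),
               "gene:genotype:hormone")
})

test_that("contrast labels map onto the documented coefficient sets", {
  expect_equal(qpcrlmm:::contrast_coefs("hormone_within_KO"),
               c("gene:hormone", "gene:genotype:hormone"))
  expect_error(ddct_contrast(structure(list(), class = "ct_lmm"), "x"),
               "converged|label")
})

test_that("planted single-effect genes are classified into their class", {
  # a 2.33-fold hormonal down-regulation is called hormone-only, and a
  # 1.50-fold genotype up-regulation genotype-only, in the large majority
  # of replicates
  hits_h <- 0; hits_g <- 0
  for (s in 1:21) {
    dh <- generate_ct_dataset(effect_spec(delta_tau = log2(2.33)),
                              seed = 400 + s)
    ch <- classify_regulation(dh)
    hits_h <- hits_h + (ch$reg_class == "hormone_only")
    if (s == 1) {
      expect_equal(ch$contrasts$label, "hormone_effect")
      expect_equal(ch$contrasts$direction, "Down")
      expect_equal(ch$contrasts$fc, 2.33, tolerance = 0.2)
    }
    dg <- generate_ct_dataset(effect_spec(delta_gamma = -log2(1.5)),
                              seed = 500 + s)
    hits_g <- hits_g + (classify_regulation(dg)$reg_class ==
                          "genotype_only")
  }
  expect_gt(hits_h / 21, 0.5)
  expect_gt(hits_g / 21, 0.5)
})

test_that("a three-way interaction forces the interacting class and layout", {
  d <- generate_ct_dataset(
    effect_spec(delta_gamma = log2(1.3),
                delta_gamma_tau = log2(4.3) - log2(1.3)),
    seed = 9)
  call <- classify_regulation(d, arm = "KKO")
  expect_equal(call$reg_class, "both_interacting")
  expect_setequal(call$contrasts$label,
                  c("genotype_within_placebo", "genotype_within_T",
                    "hormone_within_WT", "hormone_within_KO"))
  expect_true(call$passes_fc_filter)
})

test_that("a null gene is usually classified as none, never spuriously interacting", {
  classes <- vapply(1:60, function(s) {
    d <- generate_ct_dataset(effect_spec(), seed = 700 + s)
    classify_regulation(d)$reg_class
  }, character(1))
  # each nuisance test rejects ~5% of the time, so 'none' is expected in
  # roughly (1 - alpha_eff)^3 ~ 84% of null replicates
  expect_gt(mean(classes == "none"), 0.7)
})

test_that("classification requires the full factorial design", {
  d <- generate_ct_dataset(effect_spec(), seed = 1)
  expect_error(classify_regulation(d[d$hormone == "placebo", ]), "design")
  d2 <- generate_ct_dataset(effect_spec(design = "intact_2x2"), seed = 1)
  expect_error(classify_regulation(d2), "design")
})

test_that("omnibus p-values are BH-adjusted across a call family", {
  calls <- lapply(1:4, function(s) {
    d <- generate_ct_dataset(effect_spec(delta_tau = 0.5 * (s %% 2)),
                             seed = 800 + s, gene = paste0("G", s))
    classify_regulation(d)
  })
  adjusted <- adjust_regulation_calls(calls)
  p <- vapply(calls, `[[`, numeric(1), "omnibus_p")
  expect_equal(vapply(adjusted, `[[`, numeric(1), "omnibus_p_adj"),
               benjamini_hochberg(p))
})

test_that("matched loading controls give consistent fold estimates", {
  # two controls with identical stability: log2 fold differences should
  # stay within two pooled SEs in about 95% of replicates
  ok <- 0; n_rep <- 100
  spec <- effect_spec(delta_gamma = -1)
  for (s in seq_len(n_rep)) {
    d1 <- generate_ct_dataset(spec, seed = 9000 + 2 * s, control = "Gapdh")
    d2 <- generate_ct_dataset(spec, seed = 9001 + 2 * s, control = "18S")
    no3 <- setdiff(ct_terms(), "gene:genotype:hormone")
    c1 <- ddct_contrast(fit_mixed_model(d1, no3), "genotype_effect")
    c2 <- ddct_contrast(fit_mixed_model(d2, no3), "genotype_effect")
    pooled <- sqrt(c1$se^2 + c2$se^2)
    ok <- ok + (abs(c1$log2fc - c2$log2fc) < 2 * pooled)
  }
  expect_gte(ok / n_rep, 0.90)
})
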