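# Per-effect LRTs, AICc, the pleiotropy-versus-close-linkage search, and the
# QTL-by-environment equality test.

two_trait_setup <- function(seed, qtl, effects, n = 220) {
  sc <- scenario_spec(n_chr = 2, markers_per_chr = 6, spacing = 10, n = n,
                      u = c(0, 0), traits = c("T1", "T2"), qtl = qtl,
                      effects = effects,
                      Sigma = matrix(c(1, .2, .2, 1), 2, 2))
  cross <- simulate_cross(sc, seed)
  grid <- genome_grid(cross$map, 2)
  probs <- conditional_qtl_probs(cross$map, cross$geno, grid)
  list(cross = cross, probs = probs, grid = grid)
}

test_that("AICc has the printed form and penalizes extra parameters", {
  expect_equal(aicc(-100, 0, 50), 200)
  k <- 3; n <- 40; ll <- -75
  expect_equal(aicc(ll, k, n), -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  expect_gt(aicc(ll, 1, 30), -2 * ll + 2)   # corrected > plain AIC for k >= 1
  expect_error(aicc(-10, 10, 11), "n > k")
  # one extra position parameter between linked and pleiotropic models
  expect_equal(aicc(ll, k + 1, n) - aicc(ll, k, n),
               2 + 2 * ((k + 1) * (k + 2) - k * (k + 1) * (n - k - 1) /
                          (n - k - 2)) / (n - k - 2), tolerance = 1)
})

test_that("effect LRT is zero when masking an effect whose MLE is zero, chi-square sized otherwise", {
  st <- two_trait_setup(606, data.frame(chr = 1, pos = 25),
                        matrix(c(0.8, 0), 2, 1))
  cfg <- select_config()
  model <- qtl_model(chr = "1", pos = 24)
  fit <- mtmim:::refit_model(model, st$probs, st$cross$pheno, cfg)
  sel <- list(model = model, fit = fit)
  res2 <- effect_lrt(sel, qtl = 1, traits = 2, st$probs, st$cross$pheno, cfg)
  expect_equal(res2$df, 1)
  expect_lt(res2$lrt, qchisq(0.99, 1))      # true zero effect: small LRT
  res1 <- effect_lrt(sel, qtl = 1, traits = 1, st$probs, st$cross$pheno, cfg)
  expect_gt(res1$lrt, qchisq(0.999, 1))     # strong true effect
  resb <- effect_lrt(sel, qtl = 1, traits = 1:2, st$probs, st$cross$pheno, cfg)
  expect_equal(resb$df, 2)
  expect_gte(resb$lrt, res1$lrt - 1e-6)     # nesting
})

test_that("masking an effect fitted at (numerically) zero leaves the likelihood unchanged", {
  st <- two_trait_setup(616, data.frame(chr = 1, pos = 25),
                        matrix(c(0.8, 0), 2, 1), n = 150)
  cfg <- select_config()
  # fit with trait-2 effect already masked; then 'test' an exact-zero effect
  model <- qtl_model(chr = "1", pos = 24,
                     mask = matrix(c(FALSE, TRUE), 2, 1))
  fit <- mtmim:::refit_model(model, st$probs, st$cross$pheno, cfg)
  full <- qtl_model(chr = "1", pos = 24)
  ffull <- mtmim:::refit_model(full, st$probs, st$cross$pheno, cfg,
                               init = fit$params)
  expect_gte(ffull$loglik, fit$loglik - 1e-8)
})

test_that("pleiotropy search: diagonal reproduces the 1D profile and a pleiotropic QTL is retained", {
  st <- two_trait_setup(626, data.frame(chr = 1, pos = 25),
                        matrix(c(0.7, 0.7), 2, 1), n = 250)
  cfg <- select_config(eps = 1e-5)
  model <- qtl_model(chr = "1", pos = 24)
  fit <- mtmim:::refit_model(model, st$probs, st$cross$pheno, cfg)
  sel <- list(model = model, fit = fit)
  res <- pleiotropy_vs_linkage_test(sel, 1, st$probs, st$cross$pheno,
                                    window = 12, config = cfg)
  # diagonal entries are single-locus pleiotropic fits = 1D profile
  rows <- mtmim:::reposition_rows(st$probs, model, 1, cfg)
  rows <- rows[abs(st$grid$pos[rows] - 24) <= 12]
  f0 <- mtmim:::refit_model(qtl_model(), st$probs, st$cross$pheno, cfg)
  for (k in c(1, length(rows))) {
    f1 <- mtmim:::refit_model(qtl_model(chr = "1", pos = st$grid$pos[rows[k]]),
                              st$probs, st$cross$pheno, cfg)
    expect_equal(res$diag_loglik[k], f1$loglik, tolerance = 1e-4)
  }
  # truly pleiotropic: LRT small, both criteria usually retain pleiotropy
  expect_lt(res$lrt, qchisq(0.999, 1))
  expect_equal(res$p_value, pchisq(max(res$lrt, 0), 1, lower.tail = FALSE))
  expect_true(is.finite(res$aicc_pleio) && is.finite(res$aicc_linked))
  # linked model never beats pleiotropic by less than the boundary value
  expect_gte(res$linked_loglik, res$pleio_loglik - 2)
})

test_that("closely linked nonpleiotropic architecture yields a larger pleiotropy LRT than a pleiotropic one", {
  # two loci 10 cM apart, each affecting one trait (the hard alternative)
  st_link <- two_trait_setup(636, data.frame(chr = c(1, 1), pos = c(20, 30)),
                             matrix(c(0.9, 0, 0, 0.9), 2, 2), n = 300)
  cfg <- select_config(eps = 1e-5)
  model <- qtl_model(chr = "1", pos = 24)   # fitted as one pleiotropic QTL
  fit <- mtmim:::refit_model(model, st_link$probs, st_link$cross$pheno, cfg)
  sel <- list(model = model, fit = fit)
  res_link <- pleiotropy_vs_linkage_test(sel, 1, st_link$probs,
                                         st_link$cross$pheno,
                                         window = 14, config = cfg)
  st_pl <- two_trait_setup(646, data.frame(chr = 1, pos = 25),
                           matrix(c(0.9, 0.9), 2, 1), n = 300)
  fit_pl <- mtmim:::refit_model(model, st_pl$probs, st_pl$cross$pheno, cfg)
  res_pl <- pleiotropy_vs_linkage_test(list(model = model, fit = fit_pl),
                                       1, st_pl$probs, st_pl$cross$pheno,
                                       window = 14, config = cfg)
  expect_gt(res_link$lrt, res_pl$lrt)
  # the linked fit separates the two positions
  expect_gt(abs(diff(res_link$linked_pos)), 2)
})

test_that("QTL-by-environment equality constraint: df, nesting, and power direction", {
  cfg <- select_config()
  # equal effects across environments: LRT small
  st_eq <- two_trait_setup(656, data.frame(chr = 1, pos = 25),
                           matrix(c(0.6, 0.6), 2, 1), n = 250)
  model <- qtl_model(chr = "1", pos = 24)
  fit <- mtmim:::refit_model(model, st_eq$probs, st_eq$cross$pheno, cfg)
  res <- qtl_by_environment_test(list(model = model, fit = fit), 1, 1:2,
                                 st_eq$probs, st_eq$cross$pheno, cfg)
  expect_equal(res$df, 1)
  expect_gte(res$lrt, 0)
  expect_lt(res$lrt, qchisq(0.999, 1))
  expect_equal(res$fit0$params$B[1, 1], res$fit0$params$B[2, 1],
               tolerance = 1e-9)
  # very different effects: LRT large
  st_ne <- two_trait_setup(666, data.frame(chr = 1, pos = 25),
                           matrix(c(0.9, 0), 2, 1), n = 250)
  fit_ne <- mtmim:::refit_model(model, st_ne$probs, st_ne$cross$pheno, cfg)
  res_ne <- qtl_by_environment_test(list(model = model, fit = fit_ne), 1, 1:2,
                                    st_ne$probs, st_ne$cross$pheno, cfg)
  expect_gt(res_ne$lrt, qchisq(0.99, 1))
  expect_error(qtl_by_environment_test(list(model = model, fit = fit_ne),
                                       1, 1, st_ne$probs,
                                       st_ne$cross$pheno, cfg), ">= 2")
})
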