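# ECM and GEM-NR estimation: E/CM step contracts, ascent, constraint
# preservation, oracle equivalences, and the analytic derivative bundle.

test_that("E-step posteriors are proper and reduce to the prior in degenerate cases", {
  ri <- random_instance(21, T = 2, m = 2, n = 50)
  des <- build_design(ri$model, ri$probs)
  par <- mtmim:::default_init(des, ri$Y)
  # identical component means (B = 0): posteriors equal priors
  es <- e_step(par, des, ri$Y)
  expect_equal(es$posterior, des$P, tolerance = 1e-12)
  expect_equal(rowSums(es$posterior), rep(1, 50))
  # degenerate priors propagate unchanged for any parameters
  des_m <- build_design(qtl_model(chr = "1", pos = 10), ri$probs)
  par_m <- model_parameters(par$u, matrix(c(.4, -.2), 2, 1), par$Sigma)
  es_m <- e_step(par_m, des_m, ri$Y)
  expect_equal(es_m$posterior, des_m$P, tolerance = 1e-12)
})

test_that("null-model CM step is the complete-data Gaussian MLE", {
  ri <- random_instance(22, T = 3, m = 0, n = 45)
  des <- build_design(qtl_model(), ri$probs)
  par <- model_parameters(c(9, 9, 9), matrix(0, 3, 0), diag(3))
  up <- cm_step(par, matrix(1, 45, 1), des, ri$Y)
  expect_equal(up$u, unname(colMeans(ri$Y)))
  expect_equal(unname(up$Sigma), unname(cov(ri$Y) * 44 / 45))
  fit <- ecm_fit(des, ri$Y, fit_config(eps = 1e-9))
  expect_lte(fit$iterations, 2)
})

test_that("fully informative genotypes give the multivariate regression MLE", {
  ri <- random_instance(23, T = 2, m = 2, n = 90)
  model <- qtl_model(chr = c("1", "2"), pos = c(10, 10))  # typed markers
  des <- build_design(model, ri$probs)
  fit <- ecm_fit(des, ri$Y, fit_config(eps = 1e-10, max_iter = 5000))
  X <- cbind(cockerham_code(ri$cross$geno[, 2]),
             cockerham_code(ri$cross$geno[, 5]))
  ora <- ols_oracle(ri$Y, X)
  expect_equal(unname(fit$params$B), unname(ora$B), tolerance = 1e-5)
  expect_equal(unname(fit$params$u), unname(ora$u), tolerance = 1e-5)
  expect_equal(unname(fit$params$Sigma), unname(ora$Sigma), tolerance = 1e-5)
  expect_equal(fit$loglik, ora$loglik, tolerance = 1e-7)
})

test_that("ECM log-likelihood is nondecreasing on random instances and masks are exact", {
  for (seed in 1:100) {
    ri <- random_instance(300 + seed, T = 2, m = (seed %% 2) + 1, n = 40)
    mask <- matrix(FALSE, 2, ri$model$m)
    if (seed %% 3 == 0) mask[1, 1] <- TRUE
    model <- qtl_model(ri$model$chr, ri$model$pos, mask = mask)
    des <- build_design(model, ri$probs)
    fit <- ecm_fit(des, ri$Y, fit_config(eps = 1e-5, max_iter = 200))
    expect_true(all(diff(fit$trace) > -1e-8))
    expect_true(all(fit$params$B[mask] == 0))
  }
})

test_that("parameter recovery at the true positions on an SI replicate", {
  sc <- builtin_scenarios()$SI
  cross <- simulate_cross(sc, 77)
  grid <- genome_grid(cross$map, 1)
  probs <- conditional_qtl_probs(cross$map, cross$geno, grid)
  model <- qtl_model(chr = as.character(sc$qtl$chr), pos = sc$qtl$pos)
  fit <- ecm_fit(build_design(model, probs), cross$pheno,
                 fit_config(eps = 1e-6))
  # each of the 15 effects is 0.52; sampling SE ~ 0.066 at n = 300
  expect_true(all(abs(fit$params$B - 0.52) < 4 * 0.07))
  expect_equal(unname(fit$params$u), c(30, 35, 30), tolerance = 0.02)
})

test_that("GEM-NR matches ECM at the optimum and its trace is nondecreasing", {
  ri <- random_instance(31, T = 3, m = 2, n = 120)
  des <- build_design(ri$model, ri$probs)
  cfg <- fit_config(eps = 1e-7)
  f_ecm <- ecm_fit(des, ri$Y, cfg)
  f_gem <- gem_nr_fit(des, ri$Y, fit_config(eps = 1e-7, algorithm = "GEM-NR"))
  expect_gte(f_gem$loglik, f_ecm$loglik - 1e-6)
  expect_equal(unname(f_gem$params$B), unname(f_ecm$params$B),
               tolerance = 5e-4)
  expect_equal(unname(f_gem$params$u), unname(f_ecm$params$u),
               tolerance = 5e-4)
  expect_true(all(diff(f_gem$trace) > -1e-7))
})

test_that("Q_c derivatives match central finite differences", {
  ri <- random_instance(41, T = 2, m = 2, n = 50)
  model <- qtl_model(ri$model$chr, ri$model$pos,
                     epistasis = data.frame(q1 = 1, q2 = 2))
  des <- build_design(model, ri$probs, prune = 0)
  par <- model_parameters(colMeans(ri$Y) + 0.1,
                          matrix(c(.3, -.2, .1, .4, .05, -.1), 2, 3),
                          cov(ri$Y))
  es <- e_step(par, des, ri$Y)
  qd <- qc_derivatives(par, es$posterior, des, ri$Y)
  fmap <- mtmim:::free_map(mtmim:::effect_groups(model, 2), 2)
  th0 <- mtmim:::pack_free(par, fmap)
  qc_fun <- function(th) {
    pp <- mtmim:::unpack_free(th, fmap, 3, 2)
    Pi <- es$posterior
    tot <- 0
    for (j in seq_len(ncol(des$P))) {
      mu <- as.numeric(pp$u + pp$B %*% des$Z[, j])
      lp <- ifelse(des$P[, j] > 0, log(des$P[, j]), 0)
      tot <- tot + sum(Pi[, j] * (lp + ldmvnorm(ri$Y, mu, pp$Sigma)))
    }
    tot
  }
  g_num <- vapply(seq_along(th0), function(i) {
    h <- 1e-5 * max(1, abs(th0[i])); e <- replace(numeric(length(th0)), i, h)
    (qc_fun(th0 + e) - qc_fun(th0 - e)) / (2 * h)
  }, numeric(1))
  g_an <- mtmim:::aggregate_free(qd$gradient, fmap)
  expect_equal(g_an, g_num, tolerance = 1e-5)
  # the mean-block second derivative is exactly -n * Sigma^{-1}
  H <- mtmim:::aggregate_free2(qd$hessian, fmap)
  iu <- length(fmap$eff_labels) + seq_len(2)
  expect_equal(H[iu, iu], unname(-nrow(ri$Y) * solve(par$Sigma)),
               tolerance = 1e-10)
  # full Hessian vs finite differences of the gradient
  H_num <- vapply(seq_along(th0), function(i) {
    h <- 1e-5 * max(1, abs(th0[i])); e <- replace(numeric(length(th0)), i, h)
    es2 <- es  # posterior fixed
    gp <- qc_derivatives(mtmim:::unpack_free(th0 + e, fmap, 3, 2),
                         es2$posterior, des, ri$Y)$gradient
    gm <- qc_derivatives(mtmim:::unpack_free(th0 - e, fmap, 3, 2),
                         es2$posterior, des, ri$Y)$gradient
    (mtmim:::aggregate_free(gp, fmap) - mtmim:::aggregate_free(gm, fmap)) / (2 * h)
  }, numeric(length(th0)))
  expect_equal(H, 0.5 * (H_num + t(H_num)), tolerance = 1e-4)
  # at an ECM fixed point the Q_c gradient vanishes
  fit <- ecm_fit(des, ri$Y, fit_config(eps = 1e-11, max_iter = 10000))
  esf <- e_step(fit$params, des, ri$Y)
  gf <- qc_derivatives(fit$params, esf$posterior, des, ri$Y)$gradient
  expect_lt(max(abs(mtmim:::aggregate_free(gf, fmap))), 1e-3)
})

test_that("observed information matches finite differences of the mixture likelihood", {
  ri <- random_instance(43, T = 2, m = 1, n = 60)
  des <- build_design(ri$model, ri$probs, prune = 0)
  fit <- ecm_fit(des, ri$Y, fit_config(eps = 1e-8))
  par <- fit$params
  fmap <- mtmim:::free_map(mtmim:::effect_groups(ri$model, 2), 2)
  th0 <- mtmim:::pack_free(par, fmap)
  ll_fun <- function(th)
    mt_loglik(mtmim:::unpack_free(th, fmap, 1, 2), des, ri$Y)
  Io <- observed_information(par, des, ri$Y)
  expect_equal(Io, t(Io), tolerance = 1e-10)
  H_num <- matrix(0, length(th0), length(th0))
  hstep <- 5e-4
  for (i in seq_along(th0)) for (k in seq_len(i)) {
    hi <- hstep * max(1, abs(th0[i])); hk <- hstep * max(1, abs(th0[k]))
    ei <- replace(numeric(length(th0)), i, hi)
    ek <- replace(numeric(length(th0)), k, hk)
    H_num[i, k] <- H_num[k, i] <-
      (ll_fun(th0 + ei + ek) - ll_fun(th0 + ei - ek) -
         ll_fun(th0 - ei + ek) + ll_fun(th0 - ei - ek)) / (4 * hi * hk)
  }
  expect_equal(unname(-Io), H_num, tolerance = 1e-4 * max(abs(H_num)))
  # null model: the mean block is exactly n * Sigma^{-1}
  des0 <- build_design(qtl_model(), ri$probs)
  fit0 <- ecm_fit(des0, ri$Y, fit_config(eps = 1e-10))
  I0 <- observed_information(fit0$params, des0, ri$Y)
  expect_equal(I0[1:2, 1:2], nrow(ri$Y) * solve(fit0$params$Sigma),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(I0[1:2, 3:5]), matrix(0, 2, 3), tolerance = 1e-6)
})

test_that("equality-shared effects are honored by the CM step", {
  ri <- random_instance(51, T = 2, m = 1, n = 80)
  share <- matrix(0L, 2, 1); share[, 1] <- 1L
  model <- qtl_model(ri$model$chr, ri$model$pos, share = share)
  des <- build_design(model, ri$probs)
  fit <- ecm_fit(des, ri$Y, fit_config(eps = 1e-8))
  expect_equal(fit$params$B[1, 1], fit$params$B[2, 1], tolerance = 1e-10)
  free_fit <- ecm_fit(build_design(ri$model, ri$probs), ri$Y,
                      fit_config(eps = 1e-8))
  expect_gte(free_fit$loglik, fit$loglik - 1e-8)
})
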