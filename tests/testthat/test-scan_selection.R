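# Genome scan, forward selection, position optimization and LOD support
# intervals.

test_that("scan statistics are nonnegative and exclusions are honored", {
  ri <- random_instance(71, T = 2, m = 1, n = 80)
  des0 <- build_design(ri$model, ri$probs)
  fit0 <- ecm_fit(des0, ri$Y, fit_config(eps = 1e-6))
  cfg <- select_config(eps_scan = 1e-4)
  prof <- genome_scan(fit0, ri$probs, ri$Y, cfg)
  grid <- ri$grid
  near <- grid$chr == ri$model$chr[1] &
    abs(grid$pos - ri$model$pos[1]) <= cfg$radius
  expect_true(all(prof$excluded[near]))
  expect_true(all(is.na(prof$lrt[prof$excluded])))
  expect_true(all(prof$lrt[!prof$excluded] > -1e-6, na.rm = TRUE))
  expect_equal(prof$lod, prof$lrt / (2 * log(10)))
})

test_that("null-position LRT over replicates behaves like chi-square with T df", {
  # fixed unlinked position, null data: 2 log LR ~ chi^2_T asymptotically
  T <- 2
  lrts <- vapply(1:60, function(b) {
    sc <- scenario_spec(n_chr = 1, markers_per_chr = 4, spacing = 10, n = 120,
                        u = c(0, 0), traits = c("T1", "T2"),
                        qtl = data.frame(chr = integer(0), pos = numeric(0)),
                        effects = matrix(0, 2, 0), Sigma = diag(2))
    cross <- simulate_cross(sc, 8000 + b)
    grid <- genome_grid(cross$map, 5)
    probs <- conditional_qtl_probs(cross$map, cross$geno, grid)
    f0 <- ecm_fit(build_design(qtl_model(), probs), cross$pheno,
                  fit_config(eps = 1e-7))
    f1 <- ecm_fit(build_design(qtl_model(chr = "1", pos = 15), probs),
                  cross$pheno, fit_config(eps = 1e-7))
    2 * (f1$loglik - f0$loglik)
  }, numeric(1))
  expect_true(all(lrts > -1e-8))
  expect_equal(mean(lrts), T, tolerance = 0.35 * T)
  ks <- suppressWarnings(ks.test(lrts, "pchisq", df = T))
  expect_gt(ks$p.value, 0.01)
})

test_that("LOD support intervals follow the drop rule", {
  pos <- seq(0, 40, by = 2)
  lod <- 5 - abs(pos - 20) / 4        # drops 0.5 per grid step
  iv <- lod_support_interval(pos, lod, 20, d = 1.5)
  expect_equal(c(iv$lo, iv$hi), c(14, 26))
  expect_equal(iv$length, 12)
  # flat profile spans the whole scanned segment
  ivf <- lod_support_interval(pos, rep(2, length(pos)), 20, d = 1)
  expect_equal(c(ivf$lo, ivf$hi), c(0, 40))
  # sharp peak: single point, reported with the grid resolution window
  spike <- rep(0, length(pos)); spike[11] <- 9
  ivs <- lod_support_interval(pos, spike, 20, d = 1.5)
  expect_equal(c(ivs$lo, ivs$hi), c(20, 20))
  expect_equal(ivs$length, 2)
  expect_error(lod_support_interval(pos, lod, 20, d = 0), "positive")
  expect_error(lod_support_interval(pos, lod, 21, d = 1), "profile position")
  # interval always contains the peak and respects contiguity through NA
  lodna <- lod; lodna[8] <- NA
  ivna <- lod_support_interval(pos, lodna, 20, d = 1.5)
  expect_gte(ivna$lo, pos[9])
})

test_that("forward selection on a strong single-QTL dataset finds it and is deterministic", {
  sc <- scenario_spec(n_chr = 2, markers_per_chr = 5, spacing = 10, n = 200,
                      u = c(10, 20), traits = c("T1", "T2"),
                      qtl = data.frame(chr = 1, pos = 15),
                      effects = matrix(c(0.9, 0.7), 2, 1), Sigma = diag(2))
  cross <- simulate_cross(sc, 303)
  grid <- genome_grid(cross$map, 2)
  probs <- conditional_qtl_probs(cross$map, cross$geno, grid)
  cfg <- select_config(alpha = 0.05, n_resample = 300, seed = 11)
  sel1 <- forward_select(probs, cross$pheno, cfg)
  sel2 <- forward_select(probs, cross$pheno, cfg)
  expect_identical(sel1$model$pos, sel2$model$pos)
  expect_identical(sel1$steps, sel2$steps)
  expect_gte(sel1$model$m, 1)
  expect_equal(sel1$model$chr[1], "1")
  expect_lt(abs(sel1$model$pos[1] - 15), 10)
  # both effects should survive pruning at these effect sizes
  expect_equal(sel1$steps$pattern[1], "11")
  # log-likelihood grows along the forward path
  des0 <- build_design(qtl_model(), probs)
  ll0 <- ecm_fit(des0, cross$pheno)$loglik
  expect_gt(sel1$fit$loglik, ll0)
})

test_that("position optimization never lowers the likelihood and searches whole chromosome without neighbors", {
  sc <- scenario_spec(n_chr = 1, markers_per_chr = 9, spacing = 10, n = 250,
                      u = c(0, 0), traits = c("T1", "T2"),
                      qtl = data.frame(chr = 1, pos = 43),
                      effects = matrix(c(0.8, 0.6), 2, 1), Sigma = diag(2))
  cross <- simulate_cross(sc, 404)
  grid <- genome_grid(cross$map, 2)
  probs <- conditional_qtl_probs(cross$map, cross$geno, grid)
  cfg <- select_config()
  # deliberately mislocalized model
  model <- qtl_model(chr = "1", pos = 20)
  fit <- mtmim:::refit_model(model, probs, cross$pheno, cfg)
  sel <- list(model = model, fit = fit)
  rows <- mtmim:::reposition_rows(probs, model, 1, cfg)
  expect_equal(sort(grid$pos[rows]), grid$pos[grid$chr == "1"])
  opt <- optimize_positions(sel, probs, cross$pheno, cfg)
  expect_gte(opt$fit$loglik, fit$loglik - 1e-6)
  expect_lt(abs(opt$model$pos[1] - 43), 12)
})

test_that("selected-QTL intervals contain the mapped position", {
  sc <- scenario_spec(n_chr = 2, markers_per_chr = 5, spacing = 10, n = 150,
                      u = c(0, 0), traits = c("T1", "T2"),
                      qtl = data.frame(chr = c(1, 2), pos = c(15, 25)),
                      effects = matrix(c(0.8, 0.8, 0, 0.9), 2, 2),
                      Sigma = diag(2))
  cross <- simulate_cross(sc, 505)
  an <- mtmim_analysis(cross$map, cross$geno, cross$pheno, step = 2,
                       config = select_config(alpha = 0.10,
                                              n_resample = 200, seed = 3))
  iv <- an$intervals
  if (nrow(iv) > 0) {
    expect_true(all(iv$lo <= iv$pos & iv$pos <= iv$hi))
    expect_true(all(iv$length >= 0))
  }
})
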