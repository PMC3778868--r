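# Hypothesis tests on a fitted MTMIM model: per-effect LRTs, pleiotropy
# versus close linkage (two-dimensional position search), AICc, and
# QTL-by-environment interaction under design I (same genotypes, trait
# states as environments).

#' Corrected Akaike information criterion
#'
#' `AICc = -2 l + 2 k + 2 k (k + 1) / (n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters (QTL positions count as parameters).
#' @param n sample size; must exceed `k + 1`.
#' @return scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Likelihood-ratio test of QTL effects
#'
#' Refits the model with the selected effects constrained to zero and
#' compares by a chi-square LRT with one degree of freedom per constrained
#' effect.
#'
#' @param selection a [forward_select()] result (or list with `model`,
#'   `fit`).
#' @param qtl index of the tested QTL column (may also be `m + k` for the
#'   k-th epistatic column).
#' @param traits trait indices whose effects are constrained.
#' @param probs,Y data as in [forward_select()].
#' @param config a [select_config()].
#' @return list with `lrt`, `df`, `p_value`, `fit0` (constrained fit).
#' @export
effect_lrt <- function(selection, qtl, traits, probs, Y,
                       config = select_config()) {
  model <- selection$model
  T <- ncol(Y)
  mask <- if (is.null(model$mask)) matrix(FALSE, T, model$s) else model$mask
  if (any(mask[traits, qtl]))
    stop("tested effects must be unmasked in the current model")
  mask0 <- mask
  mask0[traits, qtl] <- TRUE
  m0 <- qtl_model(model$chr, model$pos, epistasis = model$epistasis,
                  mask = mask0, share = model$share)
  fit0 <- refit_model(m0, probs, Y, config, init = selection$fit$params)
  lrt <- max(0, 2 * (selection$fit$loglik - fit0$loglik))
  df <- length(traits)
  list(lrt = lrt, df = df, p_value = pchisq(lrt, df, lower.tail = FALSE),
       fit0 = fit0)
}

#' Pleiotropy versus closely linked nonpleiotropic QTL
#'
#' Tests whether a pleiotropic QTL in a bivariate model is better explained
#' by two closely linked loci, each affecting one trait. A two-dimensional
#' grid search over position pairs in a window around the pleiotropic
#' position fits, for every admissible pair, the model whose first new locus
#' affects trait 1 only and second affects trait 2 only (other QTL held at
#' their positions and constraint patterns). The maximum-likelihood pair is
#' compared with the pleiotropic fit by `LRT = 2 [l(linked) - l(pleio)]`
#' against chi-square(1) (one extra position parameter), and by AICc.
#' Pairs lying strictly inside one marker interval are outside the model's
#' assumptions and are skipped; diagonal entries are evaluated as
#' single-locus pleiotropic fits, so the search's diagonal reproduces the
#' one-dimensional profile.
#'
#' @param selection a [forward_select()] result for a two-trait model.
#' @param qtl index of the tested QTL.
#' @param probs,Y data as in [forward_select()].
#' @param window half-width of the search window in cM (default 15).
#' @param level significance level of the LRT criterion (default 0.05).
#' @param config a [select_config()].
#' @return list of class `"pleiotropy_test"`: pleiotropic and linked
#'   log-likelihoods and positions, `lrt`, `p_value`, AICc for both models
#'   and per-criterion decisions.
#' @export
pleiotropy_vs_linkage_test <- function(selection, qtl, probs, Y,
                                       window = 15, level = 0.05,
                                       config = select_config()) {
  model <- selection$model
  T <- ncol(Y)
  if (T != 2)
    stop("the pleiotropy-versus-linkage search is defined for two traits")
  mask <- if (is.null(model$mask)) matrix(FALSE, T, model$s) else model$mask
  if (any(mask[, qtl]))
    stop("tested QTL must have unmasked effects on both traits")
  grid <- attr(probs, "grid")
  rows <- reposition_rows(probs, model, qtl, config)
  rows <- rows[abs(grid$pos[rows] - model$pos[qtl]) <= window]
  if (length(rows) < 2) stop("search window contains fewer than 2 positions")
  others <- setdiff(seq_len(model$m), qtl)
  base_chr <- model$chr[others]
  base_pos <- model$pos[others]
  base_mask <- mask[, others, drop = FALSE]
  # pleiotropic model: single locus, both effects free; diagonal of search
  diag_ll <- rep(NA_real_, length(rows))
  best5 <- NULL
  for (k in seq_along(rows)) {
    m5 <- qtl_model(c(base_chr, grid$chr[rows[k]]),
                    c(base_pos, grid$pos[rows[k]]),
                    mask = cbind(base_mask, c(FALSE, FALSE)))
    f5 <- refit_model(m5, probs, Y, config, init = NULL)
    diag_ll[k] <- f5$loglik
    if (is.null(best5) || f5$loglik > best5$loglik)
      best5 <- list(loglik = f5$loglik, pos = grid$pos[rows[k]], fit = f5)
  }
  # off-diagonal: locus at l3 affects trait 1 only, locus at l4 trait 2 only
  best6 <- NULL
  for (k3 in seq_along(rows)) for (k4 in seq_along(rows)) {
    if (k3 == k4) next
    l3 <- rows[k3]; l4 <- rows[k4]
    if (same_open_interval(grid_to_map(grid), grid$chr[l3], grid$pos[l3],
                           grid$chr[l4], grid$pos[l4])) next
    m6 <- qtl_model(c(base_chr, grid$chr[l3], grid$chr[l4]),
                    c(base_pos, grid$pos[l3], grid$pos[l4]),
                    mask = cbind(base_mask, c(FALSE, TRUE), c(TRUE, FALSE)))
    f6 <- tryCatch(refit_model(m6, probs, Y, config, init = NULL),
                   error = function(e) NULL)
    if (is.null(f6)) next
    if (is.null(best6) || f6$loglik > best6$loglik)
      best6 <- list(loglik = f6$loglik, pos3 = grid$pos[l3],
                    pos4 = grid$pos[l4], fit = f6)
  }
  if (is.null(best6)) stop("no admissible nonpleiotropic position pair")
  n <- nrow(Y)
  k5 <- n_free_parameters(best5$fit$design$model, T) + model$m
  k6 <- n_free_parameters(best6$fit$design$model, T) + model$m + 1
  lrt <- 2 * (best6$loglik - best5$loglik)
  aic5 <- aicc(best5$loglik, k5, n)
  aic6 <- aicc(best6$loglik, k6, n)
  structure(list(qtl = qtl, pleio_loglik = best5$loglik,
                 pleio_pos = best5$pos,
                 linked_loglik = best6$loglik,
                 linked_pos = c(best6$pos3, best6$pos4),
                 lrt = lrt,
                 p_value = pchisq(max(lrt, 0), 1, lower.tail = FALSE),
                 aicc_pleio = aic5, aicc_linked = aic6,
                 reject_pleiotropy_lrt = lrt > qchisq(1 - level, 1),
                 reject_pleiotropy_aicc = aic6 < aic5,
                 diag_loglik = diag_ll),
            class = "pleiotropy_test")
}

#' QTL-by-environment interaction test (design I)
#'
#' With trait states read as environments (the same genotypes measured in
#' each environment), tests whether the main effect of one QTL is common
#' across a subset of environments: the constrained fit shares one effect
#' parameter across the subset (equality handled by effect-sharing groups in
#' the CM step) and is compared by a chi-square LRT with `|S| - 1` degrees
#' of freedom.
#'
#' @param selection a [forward_select()] result.
#' @param qtl tested QTL index.
#' @param envs environment (trait) indices sharing the effect; length >= 2.
#' @param probs,Y data as in [forward_select()].
#' @param config a [select_config()].
#' @return list with `lrt`, `df`, `p_value` and the constrained fit.
#' @export
qtl_by_environment_test <- function(selection, qtl, envs, probs, Y,
                                    config = select_config()) {
  if (length(envs) < 2) stop("the environment subset must have >= 2 elements")
  model <- selection$model
  T <- ncol(Y)
  mask <- if (is.null(model$mask)) matrix(FALSE, T, model$s) else model$mask
  if (any(mask[envs, qtl]))
    stop("tested effects must be unmasked in the current model")
  share <- if (is.null(model$share)) matrix(0L, T, model$s) else model$share
  share[envs, qtl] <- max(share) + 1L
  m0 <- qtl_model(model$chr, model$pos, epistasis = model$epistasis,
                  mask = mask, share = share)
  fit0 <- refit_model(m0, probs, Y, config, init = selection$fit$params)
  lrt <- max(0, 2 * (selection$fit$loglik - fit0$loglik))
  df <- length(envs) - 1
  list(lrt = lrt, df = df, p_value = pchisq(lrt, df, lower.tail = FALSE),
       fit0 = fit0)
}
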