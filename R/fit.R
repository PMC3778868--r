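#' Fitting configuration
#'
#' @param eps convergence tolerance on the log-likelihood increment
#'   (default 1e-4, absolute scale).
#' @param relative if `TRUE` the stopping rule divides the increment by
#'   `|loglik|` (the alternative printed rule); absolute is the default
#'   because at typical sample sizes a relative 1e-4 rule stops far too
#'   early for LOD-profile work.
#' @param max_iter maximum ECM iterations (default 2000).
#' @param algorithm `"ECM"` or `"GEM-NR"`.
#' @param warmup ECM iterations run before each Newton-Raphson phase of
#'   GEM-NR (default 5).
#' @param max_halvings step-size halvings allowed per NR step (default 5).
#' @param max_fallbacks ECM fallback blocks allowed in GEM-NR before
#'   returning the best iterate flagged non-converged (default 50).
#' @param max_nr maximum NR iterations (default 200).
#' @param prune mixing-probability pruning threshold (default 1e-10).
#' @return a list of class `"fit_config"`.
#' @export
fit_config <- function(eps = 1e-4, relative = FALSE, max_iter = 2000,
                       algorithm = c("ECM", "GEM-NR"), warmup = 5,
                       max_halvings = 5, max_fallbacks = 50, max_nr = 200,
                       prune = 1e-10) {
  stopifnot(eps > 0, warmup >= 1)
  structure(list(eps = eps, relative = relative, max_iter = max_iter,
                 algorithm = match.arg(algorithm), warmup = warmup,
                 max_halvings = max_halvings, max_fallbacks = max_fallbacks,
                 max_nr = max_nr, prune = prune),
            class = "fit_config")
}

default_init <- function(design, Y) {
  T <- ncol(Y)
  n <- nrow(Y)
  model_parameters(u = colMeans(Y),
                   B = matrix(0, T, design$model$s),
                   Sigma = cov(Y) * (n - 1) / n)
}

#' E-step: posterior joint-genotype probabilities
#'
#' Updates the posterior probabilities of the joint QTL genotypes for each
#' subject, `Pi_ij` proportional to `p_ij * phi(y_i | u + B Z_j, Sigma)`.
#' The prior `p_ij` (not the previous posterior) enters each update.
#'
#' @inheritParams mt_loglik
#' @return list with `posterior` (`n x 2^m`) and `loglik`.
#' @export
e_step <- function(params, design, Y) {
  .estep_cpp(t(Y), design$P, design$Z, params$u, params$B, params$Sigma)
}

#' CM-step: conditional-maximization parameter updates
#'
#' One sweep of conditional maximizations of the expected complete-data
#' log-likelihood: the trait means, then the residual covariance, then each
#' effect column in turn (element-wise coordinate updates when a column has
#' masked or shared entries, so constraints are respected exactly).
#'
#' @inheritParams mt_loglik
#' @param posterior the `n x 2^m` posterior matrix from [e_step()].
#' @return updated [model_parameters()].
#' @export
cm_step <- function(params, posterior, design, Y) {
  group <- effect_groups(design$model, ncol(Y))
  res <- .cm_step_cpp(t(Y), design$Z, group, posterior,
                      params$u, params$B, params$Sigma)
  model_parameters(res$u, res$B, res$Sigma)
}

new_fit <- function(params, design, loglik, trace, iterations, converged,
                    algorithm, posterior = NULL) {
  structure(list(params = params, design = design, loglik = loglik,
                 trace = trace, iterations = iterations,
                 converged = converged, algorithm = algorithm,
                 posterior = posterior),
            class = "mtmim_fit")
}

#' @export
print.mtmim_fit <- function(x, ...) {
  cat(x$algorithm, "fit:", x$design$model$m, "QTL, loglik",
      format(x$loglik), "in", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Maximum-likelihood fit by expectation-conditional maximization
#'
#' Alternates [e_step()] and [cm_step()] until the log-likelihood increment
#' falls below the tolerance. Initial values: sample means, sample
#' covariance (maximum-likelihood divisor), all effects zero — unless a
#' warm start is supplied.
#'
#' @inheritParams mt_loglik
#' @param config a [fit_config()].
#' @param init optional [model_parameters()] warm start.
#' @param keep_trace record the log-likelihood at every iteration.
#' @return an object of class `"mtmim_fit"`.
#' @export
ecm_fit <- function(design, Y, config = fit_config(), init = NULL,
                    keep_trace = TRUE) {
  if (is.null(init)) init <- default_init(design, Y)
  group <- effect_groups(design$model, ncol(Y))
  res <- .ecm_fit_cpp(t(Y), design$P, design$Z, group,
                      init$u, init$B, init$Sigma,
                      config$eps, as.integer(config$max_iter),
                      config$relative, keep_trace)
  new_fit(model_parameters(res$u, res$B, res$Sigma), design, res$loglik,
          res$trace, res$iterations, res$converged, "ECM", res$posterior)
}

#' Maximum-likelihood fit by the hybrid EM/Newton-Raphson algorithm
#'
#' Runs a few ECM iterations to approach the optimum, then Newton-Raphson
#' steps on the expected complete-data log-likelihood with a step size
#' `kappa` starting at 1 and halved (up to `max_halvings` times) whenever the
#' observed log-likelihood would decrease or the covariance update would
#' leave the positive-definite cone; when all halvings fail, the algorithm
#' falls back to another ECM block. The observed log-likelihood is
#' nondecreasing across accepted steps.
#'
#' @inheritParams ecm_fit
#' @return an object of class `"mtmim_fit"` (algorithm `"GEM-NR"`).
#' @export
gem_nr_fit <- function(design, Y, config = fit_config(algorithm = "GEM-NR"),
                       init = NULL) {
  if (is.null(init)) init <- default_init(design, Y)
  group <- effect_groups(design$model, ncol(Y))
  fmap <- free_map(group, ncol(Y))
  params <- init
  trace <- numeric(0)
  ll <- -Inf
  fallbacks <- 0L
  converged <- FALSE
  iters <- 0L
  repeat {
    # ECM warm-up block
    warm <- .ecm_fit_cpp(t(Y), design$P, design$Z, group,
                         params$u, params$B, params$Sigma,
                         config$eps, as.integer(config$warmup),
                         config$relative, TRUE)
    params <- model_parameters(warm$u, warm$B, warm$Sigma)
    trace <- c(trace, warm$trace)
    iters <- iters + warm$iterations
    ll <- mt_loglik(params, design, Y)
    if (isTRUE(warm$converged)) { converged <- TRUE; break }
    # NR phase
    nr_ok <- TRUE
    while (iters < config$max_iter) {
      es <- e_step(params, design, Y)
      ll <- es$loglik
      qd <- qc_derivatives(params, es$posterior, design, Y)
      g <- aggregate_free(qd$gradient, fmap)
      H <- aggregate_free2(qd$hessian, fmap)
      ch <- tryCatch(chol(-H), error = function(e) NULL)
      if (is.null(ch)) { nr_ok <- FALSE; break }
      delta <- backsolve(ch, forwardsolve(t(ch), g))
      kappa <- 1
      accepted <- FALSE
      for (h in 0:config$max_halvings) {
        cand <- unpack_free(pack_free(params, fmap) + kappa * delta,
                            fmap, design$model$s, ncol(Y))
        ll_new <- tryCatch(mt_loglik(cand, design, Y),
                           error = function(e) -Inf)
        if (is.finite(ll_new) && ll_new > ll) {
          accepted <- TRUE
          break
        }
        kappa <- kappa / 2
      }
      if (!accepted) { nr_ok <- FALSE; break }
      iters <- iters + 1L
      trace <- c(trace, ll_new)
      params <- cand
      denom <- if (config$relative) abs(ll) else 1
      improved <- ll_new - ll
      ll <- ll_new
      if (improved < config$eps * denom) { converged <- TRUE; break }
    }
    if (converged || iters >= config$max_iter) break
    if (!nr_ok) {
      fallbacks <- fallbacks + 1L
      if (fallbacks > config$max_fallbacks) break
    }
  }
  new_fit(params, design, ll, trace, iters, converged, "GEM-NR")
}

# ---- free-parameter packing ------------------------------------------------

# mapping between the full entry set (all B entries, u, vech(Sigma)) and the
# free parameter vector: masked B entries dropped, shared entries collapsed
free_map <- function(group, T) {
  s <- ncol(group)
  cols <- list()
  labels <- character(0)
  if (s > 0) for (b in seq_len(s)) {
    g <- group[, b]
    for (t in seq_len(T)) {
      if (g[t] < 0L) next
      if (g[t] > 0L) {
        lab <- paste0("B", b, ".g", g[t])
        if (lab %in% labels) {
          cols[[match(lab, labels)]] <- c(cols[[match(lab, labels)]],
                                          (b - 1L) * T + t)
          next
        }
      } else lab <- paste0("B", b, ".", t)
      labels <- c(labels, lab)
      cols[[length(labels)]] <- (b - 1L) * T + t
    }
  }
  n_eff_entries <- T * s
  npair <- T * (T + 1L) / 2L
  pairs <- which(lower.tri(diag(T), diag = TRUE), arr.ind = TRUE)
  list(T = T, s = s, eff_cols = cols, eff_labels = labels,
       n_eff_entries = n_eff_entries,
       n_free = length(cols) + T + npair,
       pairs = pairs, npair = npair)
}

pack_free <- function(params, fmap) {
  bvec <- as.numeric(params$B)
  eff <- vapply(fmap$eff_cols, function(ix) bvec[ix[1]], numeric(1))
  sig <- params$Sigma[fmap$pairs]
  c(eff, params$u, sig)
}

unpack_free <- function(theta, fmap, s, T) {
  k <- length(fmap$eff_cols)
  bvec <- numeric(T * s)
  for (i in seq_along(fmap$eff_cols)) bvec[fmap$eff_cols[[i]]] <- theta[i]
  u <- theta[k + seq_len(T)]
  sig <- theta[k + T + seq_len(fmap$npair)]
  Sigma <- matrix(0, T, T)
  Sigma[fmap$pairs] <- sig
  Sigma <- Sigma + t(Sigma) - diag(diag(Sigma))
  model_parameters(u, matrix(bvec, T, s), Sigma)
}

# gradient over full entries -> gradient over free parameters
aggregate_free <- function(g_full, fmap) {
  k <- length(fmap$eff_cols)
  eff <- vapply(fmap$eff_cols, function(ix) sum(g_full[ix]), numeric(1))
  c(eff, g_full[fmap$n_eff_entries + seq_len(fmap$T + fmap$npair)])
}

aggregate_free2 <- function(H_full, fmap) {
  n_rest <- fmap$T + fmap$npair
  A <- matrix(0, fmap$n_eff_entries + n_rest, length(fmap$eff_cols) + n_rest)
  for (i in seq_along(fmap$eff_cols)) A[fmap$eff_cols[[i]], i] <- 1
  for (i in seq_len(n_rest))
    A[fmap$n_eff_entries + i, length(fmap$eff_cols) + i] <- 1
  t(A) %*% H_full %*% A
}
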