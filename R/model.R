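#' QTL model specification
#'
#' Positions of `m` putative QTL (grid points), optional epistatic pairs, and
#' an optional zero-constraint mask on the `T x s` effect matrix
#' (`s = m + p`). Masked entries are held exactly at zero throughout fitting;
#' this is how per-trait pruned effects and nonpleiotropic models are
#' represented. An optional `share` matrix (same shape, integer codes) makes
#' entries of one column with equal positive code share a single parameter
#' (used for QTL-by-environment equality constraints).
#'
#' @param chr,pos chromosome ids and cM positions of the QTL.
#' @param epistasis optional `data.frame` with integer columns `q1 < q2`
#'   indexing QTL; each row adds one epistatic effect column.
#' @param mask optional `T x s` logical matrix, `TRUE` = effect fixed at 0.
#' @param share optional `T x s` integer matrix of equality-group codes
#'   (0 = unshared).
#' @return an object of class `"qtl_model"`.
#' @export
qtl_model <- function(chr = character(0), pos = numeric(0), epistasis = NULL,
                      mask = NULL, share = NULL) {
  m <- length(pos)
  if (length(chr) != m) stop("chr and pos must have equal length")
  if (!is.null(epistasis)) {
    epistasis <- as.data.frame(epistasis)
    if (nrow(epistasis) > 0 &&
        (any(epistasis$q1 >= epistasis$q2) ||
         any(c(epistasis$q1, epistasis$q2) > m) ||
         any(c(epistasis$q1, epistasis$q2) < 1)))
      stop("epistatic pairs must satisfy 1 <= q1 < q2 <= m")
  }
  p <- if (is.null(epistasis)) 0L else nrow(epistasis)
  s <- m + p
  if (!is.null(mask) && ncol(mask) != s)
    stop("mask must have m + p = ", s, " columns")
  structure(list(chr = as.character(chr), pos = as.numeric(pos),
                 epistasis = epistasis, mask = mask, share = share,
                 m = m, p = p, s = s),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat("QTL model:", x$m, "QTL,", x$p, "epistatic term(s)\n")
  if (x$m > 0)
    print(data.frame(chr = x$chr, pos = x$pos))
  invisible(x)
}

# number of free parameters (effects after mask/share + means + covariance)
n_free_parameters <- function(model, T) {
  s <- model$s
  group <- effect_groups(model, T)
  k_eff <- 0L
  if (s > 0) for (b in seq_len(s)) {
    g <- group[, b]
    k_eff <- k_eff + sum(g == 0L) + length(unique(g[g > 0L]))
  }
  k_eff + T + T * (T + 1L) / 2L
}

# T x s integer codes for the CM step: -1 masked, 0 free, >0 shared
effect_groups <- function(model, T) {
  s <- model$s
  g <- matrix(0L, T, max(s, 1L))[, seq_len(s), drop = FALSE]
  if (!is.null(model$share)) g <- matrix(as.integer(model$share), T, s)
  if (!is.null(model$mask)) g[model$mask] <- -1L
  g
}

# coded-genotype design over the 2^m joint genotypes, locus 1 fastest
design_Z <- function(model) {
  m <- model$m
  J <- 2L^m
  Z <- matrix(0, model$s, J)
  if (m > 0) {
    for (r in seq_len(m)) {
      bit <- bitwAnd(bitwShiftR(0:(J - 1L), r - 1L), 1L)
      Z[r, ] <- ifelse(bit == 0L, 0.5, -0.5)
    }
    if (model$p > 0)
      for (k in seq_len(model$p))
        Z[m + k, ] <- Z[model$epistasis$q1[k], ] * Z[model$epistasis$q2[k], ]
  }
  Z
}

#' Mixture design for a QTL model
#'
#' Combines the Cockerham coded-genotype matrix `Z` (`s x 2^m`, joint
#' genotypes enumerated with locus 1 fastest) with the per-subject prior
#' mixing probabilities from [joint_genotype_probs()].
#'
#' @param model a [qtl_model()].
#' @param probs a [conditional_qtl_probs()] table covering the model's
#'   positions.
#' @param prune pruning threshold passed to [joint_genotype_probs()].
#' @return a list of class `"mixture_design"` with elements `Z`, `P`, `model`
#'   and `grid_idx`.
#' @export
build_design <- function(model, probs, prune = 1e-10) {
  grid <- attr(probs, "grid")
  idx <- if (model$m > 0)
    vapply(seq_len(model$m),
           function(r) grid_index(grid, model$chr[r], model$pos[r]),
           integer(1))
  else integer(0)
  P <- joint_genotype_probs(probs, idx, prune = prune)
  structure(list(Z = design_Z(model), P = P, model = model, grid_idx = idx),
            class = "mixture_design")
}

#' Model parameters
#'
#' @param u trait means (length T).
#' @param B `T x s` effect matrix (main-effect columns then epistatic).
#' @param Sigma `T x T` residual covariance (symmetric positive definite).
#' @return a list of class `"model_parameters"`.
#' @export
model_parameters <- function(u, B, Sigma) {
  u <- as.numeric(u)
  B <- as.matrix(B)
  Sigma <- as.matrix(Sigma)
  if (nrow(B) != length(u) && ncol(B) > 0)
    stop("B must have one row per trait")
  if (!isTRUE(all.equal(unname(Sigma), unname(t(Sigma)), tolerance = 1e-8)))
    stop("Sigma must be symmetric")
  structure(list(u = u, B = B, Sigma = Sigma), class = "model_parameters")
}

#' Mixture log-likelihood
#'
#' Log-likelihood of the phenotypes under the multivariate-normal mixture
#' over joint QTL genotypes, evaluated with per-subject log-sum-exp for
#' numerical stability.
#'
#' @param params a [model_parameters()] object.
#' @param design a [build_design()] object.
#' @param Y `n x T` phenotype matrix.
#' @return scalar log-likelihood.
#' @export
mt_loglik <- function(params, design, Y) {
  .mix_loglik_cpp(t(Y), design$P, design$Z, params$u, params$B, params$Sigma)
}
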