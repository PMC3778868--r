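# Analytic first/second derivatives of the mixture log-likelihood and of the
# expected complete-data log-likelihood Q_c.
#
# Full-entry parameter ordering used throughout:
#   [ vec(B) column-major (T*s) | u (T) | unique Sigma entries, lower
#     triangle including the diagonal, column-major ]
# Off-diagonal covariance parameters are directional derivatives along the
# symmetric basis J_{ul} (1 at (u,l) and (l,u)), matching finite differences
# that perturb both symmetric entries together.

sigma_pairs <- function(T) which(lower.tri(diag(T), diag = TRUE), arr.ind = TRUE)

# shared intermediate quantities; per_subject adds the stacks needed for
# per-subject scores and the efficient-score scan
ll_pieces <- function(params, P, Z, Y, per_subject = FALSE) {
  Yt <- t(Y)
  T <- nrow(Yt); n <- ncol(Yt)
  s <- nrow(Z); J <- ncol(P)
  u <- params$u; B <- params$B; Sigma <- params$Sigma
  Siginv <- solve(Sigma)
  es <- .estep_cpp(Yt, P, Z, u, B, Sigma)
  Pi <- es$posterior
  C <- Yt - u
  if (s > 0) {
    ZP <- Z %*% t(Pi)                  # s x n
    w <- colSums(Pi)
    ZWZ <- Z %*% (w * t(Z))            # s x s
    Nmat <- C %*% t(ZP) - B %*% ZWZ    # T x s
    R <- C - B %*% ZP                  # T x n, sum_j Pi T_ij
  } else {
    ZP <- matrix(0, 0, n); w <- colSums(Pi); ZWZ <- matrix(0, 0, 0)
    Nmat <- matrix(0, T, 0); R <- C
  }
  Ttot <- rowSums(R)
  pairs <- sigma_pairs(T)
  npair <- nrow(pairs)
  # loop over components
  Gflat <- matrix(0, T * T, J)         # per-component sum_i Pi_ij T T'
  Gi <- if (per_subject) matrix(0, T * T, n) else NULL
  Ab <- if (per_subject && s > 0)
    lapply(seq_len(s), function(b) matrix(0, T * T, n)) else NULL
  a_arr <- lapply(seq_len(npair), function(k) matrix(0, n, J))
  ii1 <- rep(seq_len(T), times = T)
  ii2 <- rep(seq_len(T), each = T)
  means <- matrix(u, T, J)
  if (s > 0) means <- means + B %*% Z
  for (j in seq_len(J)) {
    A <- Yt - means[, j]
    wj <- Pi[, j]
    AAw <- (A[ii1, , drop = FALSE] * A[ii2, , drop = FALSE])
    Gflat[, j] <- AAw %*% wj
    if (per_subject) {
      AwP <- sweep(AAw, 2, wj, "*")
      Gi <- Gi + AwP
      if (s > 0) for (b in seq_len(s))
        Ab[[b]] <- Ab[[b]] + AwP * Z[b, j]
    }
    V <- Siginv %*% A
    for (k in seq_len(npair)) {
      uu <- pairs[k, 1]; ll <- pairs[k, 2]
      a_arr[[k]][, j] <- if (uu == ll)
        0.5 * (V[uu, ]^2 - Siginv[uu, uu])
      else V[uu, ] * V[ll, ] - Siginv[uu, ll]
    }
  }
  Gtot <- matrix(Gflat %*% rep(1, J), T, T)
  abar <- lapply(a_arr, function(a) rowSums(Pi * a))
  # pair-weighted sums
  K1b <- lapply(seq_len(npair), function(k) matrix(0, T, max(s, 1)))
  K1u <- lapply(seq_len(npair), function(k) numeric(T))
  K1S <- lapply(seq_len(npair), function(k) matrix(0, T, T))
  Kp <- if (per_subject)
    lapply(seq_len(npair), function(k) matrix(0, T, n)) else NULL
  for (j in seq_len(J)) {
    A <- Yt - means[, j]
    V <- Siginv %*% A
    for (k in seq_len(npair)) {
      wk <- Pi[, j] * (a_arr[[k]][, j] - abar[[k]])
      Awk <- A %*% wk
      if (s > 0) K1b[[k]] <- K1b[[k]] + Awk %*% t(Z[, j, drop = FALSE])
      K1u[[k]] <- K1u[[k]] + as.numeric(Awk)
      K1S[[k]] <- K1S[[k]] +
        0.5 * (sweep(A, 2, wk, "*") %*% t(V) - sum(wk) * diag(T))
      if (per_subject) Kp[[k]] <- Kp[[k]] + sweep(A, 2, wk, "*")
    }
  }
  Dtheta <- NULL
  if (s > 0) {
    Dtheta <- lapply(seq_len(s), function(b) {
      Mb <- (sweep(Z, 2, Z[b, ], "*")) %*% t(Pi)   # s x n
      sweep(C, 2, ZP[b, ], "*") - B %*% Mb
    })
  }
  list(T = T, n = n, s = s, J = J, Pi = Pi, loglik = es$loglik,
       Siginv = Siginv, C = C, ZP = ZP, w = w, ZWZ = ZWZ, Nmat = Nmat,
       R = R, Ttot = Ttot, Gtot = Gtot, Gflat = Gflat,
       pairs = pairs, npair = npair,
       K1b = K1b, K1u = K1u, K1S = K1S, Kp = Kp,
       Dtheta = Dtheta, Gi = Gi, Ab = Ab, Z = Z, P = P)
}

# entry index helpers
idx_B <- function(T, s) seq_len(T * s)
idx_u <- function(T, s) T * s + seq_len(T)
idx_sig <- function(T, s, npair) T * s + T + seq_len(npair)

# gradient of the observed-data log-likelihood over full entries
ll_gradient <- function(pc) {
  T <- pc$T; s <- pc$s
  gB <- if (s > 0) as.numeric(pc$Siginv %*% pc$Nmat) else numeric(0)
  gu <- as.numeric(pc$Siginv %*% pc$Ttot)
  D <- 0.5 * (pc$Siginv %*% pc$Gtot %*% pc$Siginv - pc$n * pc$Siginv)
  gs <- vapply(seq_len(pc$npair), function(k) {
    uu <- pc$pairs[k, 1]; ll <- pc$pairs[k, 2]
    if (uu == ll) D[uu, uu] else 2 * D[uu, ll]
  }, numeric(1))
  c(gB, gu, gs)
}

# per-subject gradient contributions (columns sum to ll_gradient)
ll_gradient_subjects <- function(pc) {
  T <- pc$T; s <- pc$s; n <- pc$n
  out <- matrix(0, T * s + T + pc$npair, n)
  if (s > 0) for (b in seq_len(s))
    out[(b - 1) * T + seq_len(T), ] <- pc$Siginv %*% pc$Dtheta[[b]]
  out[T * s + seq_len(T), ] <- pc$Siginv %*% pc$R
  SS <- kronecker(pc$Siginv, pc$Siginv) %*% pc$Gi    # vec(Siginv G_i Siginv)
  for (k in seq_len(pc$npair)) {
    uu <- pc$pairs[k, 1]; ll <- pc$pairs[k, 2]
    v <- 0.5 * (SS[(ll - 1) * T + uu, ] - pc$Siginv[uu, ll])
    out[T * s + T + k, ] <- if (uu == ll) v else 2 * v
  }
  out
}

# full Hessian of the observed-data log-likelihood over entries
ll_hessian <- function(pc) {
  T <- pc$T; s <- pc$s; n <- pc$n
  Si <- pc$Siginv
  npar <- T * s + T + pc$npair
  H <- matrix(0, npar, npar)
  iB <- function(b) (b - 1) * T + seq_len(T)
  iu <- T * s + seq_len(T)
  isg <- function(k) T * s + T + k
  if (s > 0) {
    for (b in seq_len(s)) for (k in seq_len(b)) {
      t1 <- matrix(pc$Gflat %*% (pc$Z[b, ] * pc$Z[k, ]), T, T)
      blk <- Si %*% t1 %*% Si -
        Si %*% (pc$Dtheta[[b]] %*% t(pc$Dtheta[[k]])) %*% Si -
        Si * pc$ZWZ[b, k]
      H[iB(b), iB(k)] <- blk
      if (k < b) H[iB(k), iB(b)] <- t(blk)
    }
    for (b in seq_len(s)) {
      t1 <- matrix(pc$Gflat %*% pc$Z[b, ], T, T)
      blk <- Si %*% t1 %*% Si -
        Si %*% (pc$Dtheta[[b]] %*% t(pc$R)) %*% Si -
        Si * sum(pc$ZP[b, ])
      H[iB(b), iu] <- blk
      H[iu, iB(b)] <- t(blk)
    }
  }
  H[iu, iu] <- Si %*% pc$Gtot %*% Si -
    Si %*% (pc$R %*% t(pc$R)) %*% Si - n * Si
  for (k in seq_len(pc$npair)) {
    uu <- pc$pairs[k, 1]; ll <- pc$pairs[k, 2]
    J <- matrix(0, T, T); J[uu, ll] <- J[ll, uu] <- 1
    SJS <- Si %*% J %*% Si
    if (s > 0) for (b in seq_len(s)) {
      v <- Si %*% pc$K1b[[k]][, b] - SJS %*% pc$Nmat[, b]
      H[isg(k), iB(b)] <- v
      H[iB(b), isg(k)] <- v
    }
    v <- Si %*% pc$K1u[[k]] - SJS %*% pc$Ttot
    H[isg(k), iu] <- v
    H[iu, isg(k)] <- v
    E <- Si %*% pc$K1S[[k]] + 0.5 * n * SJS -
      0.5 * SJS %*% pc$Gtot %*% Si - 0.5 * Si %*% pc$Gtot %*% SJS
    for (k2 in seq_len(pc$npair)) {
      u2 <- pc$pairs[k2, 1]; l2 <- pc$pairs[k2, 2]
      H[isg(k), isg(k2)] <- if (u2 == l2) E[u2, u2] else 2 * E[u2, l2]
    }
  }
  0.5 * (H + t(H))
}

#' Derivatives of the expected complete-data log-likelihood
#'
#' Analytic gradient and Hessian of `Q_c` (the posterior-weighted
#' complete-data log-likelihood) with respect to all effect entries, trait
#' means and unique residual-covariance entries, evaluated at the current
#' parameters with the posterior held fixed. These drive the Newton-Raphson
#' phase of [gem_nr_fit()].
#'
#' @inheritParams cm_step
#' @return list with `gradient` (full-entry vector) and `hessian`
#'   (full-entry matrix).
#' @export
qc_derivatives <- function(params, posterior, design, Y) {
  Yt <- t(Y)
  T <- nrow(Yt); n <- ncol(Yt)
  Z <- design$Z; s <- nrow(Z)
  Pi <- posterior
  Siginv <- solve(params$Sigma)
  C <- Yt - params$u
  if (s > 0) {
    ZP <- Z %*% t(Pi)
    w <- colSums(Pi)
    ZWZ <- Z %*% (w * t(Z))
    Nmat <- C %*% t(ZP) - params$B %*% ZWZ
    R <- C - params$B %*% ZP
    Gtot <- C %*% t(C) - C %*% t(params$B %*% ZP) -
      (params$B %*% ZP) %*% t(C) + params$B %*% ZWZ %*% t(params$B)
  } else {
    ZP <- matrix(0, 0, n); ZWZ <- matrix(0, 0, 0)
    Nmat <- matrix(0, T, 0); R <- C
    Gtot <- C %*% t(C)
  }
  Ttot <- rowSums(R)
  pairs <- sigma_pairs(T)
  npair <- nrow(pairs)
  gB <- if (s > 0) as.numeric(Siginv %*% Nmat) else numeric(0)
  gu <- as.numeric(Siginv %*% Ttot)
  D <- 0.5 * (Siginv %*% Gtot %*% Siginv - n * Siginv)
  gs <- vapply(seq_len(npair), function(k) {
    uu <- pairs[k, 1]; ll <- pairs[k, 2]
    if (uu == ll) D[uu, uu] else 2 * D[uu, ll]
  }, numeric(1))
  g <- c(gB, gu, gs)
  npar <- T * s + T + npair
  H <- matrix(0, npar, npar)
  iu <- T * s + seq_len(T)
  if (s > 0) {
    H[seq_len(T * s), seq_len(T * s)] <- -kronecker(ZWZ, Siginv)
    for (b in seq_len(s)) {
      blk <- -Siginv * sum(ZP[b, ])
      H[(b - 1) * T + seq_len(T), iu] <- blk
      H[iu, (b - 1) * T + seq_len(T)] <- blk
    }
  }
  H[iu, iu] <- -n * Siginv
  for (k in seq_len(npair)) {
    uu <- pairs[k, 1]; ll <- pairs[k, 2]
    J <- matrix(0, T, T); J[uu, ll] <- J[ll, uu] <- 1
    SJS <- Siginv %*% J %*% Siginv
    if (s > 0) for (b in seq_len(s)) {
      v <- -SJS %*% Nmat[, b]
      H[T * s + T + k, (b - 1) * T + seq_len(T)] <- v
      H[(b - 1) * T + seq_len(T), T * s + T + k] <- v
    }
    v <- -SJS %*% Ttot
    H[T * s + T + k, iu] <- v
    H[iu, T * s + T + k] <- v
    E <- 0.5 * n * SJS - 0.5 * SJS %*% Gtot %*% Siginv -
      0.5 * Siginv %*% Gtot %*% SJS
    for (k2 in seq_len(npair)) {
      u2 <- pairs[k2, 1]; l2 <- pairs[k2, 2]
      H[T * s + T + k, T * s + T + k2] <- if (u2 == l2) E[u2, u2] else 2 * E[u2, l2]
    }
  }
  list(gradient = g, hessian = 0.5 * (H + t(H)))
}

#' Observed information matrix
#'
#' Negative Hessian of the observed-data (mixture) log-likelihood over the
#' free parameters, assembled from the analytic second-derivative blocks.
#' At the MLE its inverse estimates the sampling covariance of the
#' parameter estimates.
#'
#' @inheritParams mt_loglik
#' @return symmetric matrix over the free parameters, with parameter labels
#'   in `dimnames`.
#' @export
observed_information <- function(params, design, Y) {
  pc <- ll_pieces(params, design$P, design$Z, Y, per_subject = TRUE)
  group <- effect_groups(design$model, ncol(Y))
  fmap <- free_map(group, ncol(Y))
  H <- aggregate_free2(ll_hessian(pc), fmap)
  lab <- c(fmap$eff_labels, paste0("u", seq_len(fmap$T)),
           paste0("S", pc$pairs[, 1], ".", pc$pairs[, 2]))
  dimnames(H) <- list(lab, lab)
  -H
}
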