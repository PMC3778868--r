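# Efficient scores for testing a new pleiotropic QTL against a fitted
# nuisance model, and the Gaussian-multiplier resampling threshold.
#
# For the m-th QTL entering at position l with effects theta_m = 0, the
# per-subject efficient score is
#   U_i(l) = dl_i/dtheta_m - H[theta_m, eta] H[eta, eta]^{-1} dl_i/deta
# with all derivatives of the mixture log-likelihood evaluated at the H0 MLE.
# Because the tested effects are zero under H0, the mixture factorizes over
# the new locus and every (theta_m, .) Hessian block is a weighted sum
# sum_i xtil_i(l) * F_i of per-subject matrices F_i that do not depend on l,
# where xtil_i(l) = E[coded genotype | markers] = q_i(l) - 1/2. The stacks
# F_i are precomputed once per nuisance model ("score prep") and every grid
# position then costs one matrix product.

free_A <- function(fmap) {
  n_rest <- fmap$T + fmap$npair
  A <- matrix(0, fmap$n_eff_entries + n_rest, length(fmap$eff_cols) + n_rest)
  for (i in seq_along(fmap$eff_cols)) A[fmap$eff_cols[[i]], i] <- 1
  for (i in seq_len(n_rest))
    A[fmap$n_eff_entries + i, length(fmap$eff_cols) + i] <- 1
  A
}

#' Precompute per-subject score ingredients for a nuisance model
#'
#' @param h0_fit an [ecm_fit()]/[gem_nr_fit()] result for the current
#'   (nuisance) model, at its MLE.
#' @param Y `n x T` phenotype matrix used for the fit.
#' @return an object of class `"score_prep"` consumed by
#'   [efficient_scores()] and [score_scan()].
#' @export
score_prep <- function(h0_fit, Y) {
  design <- h0_fit$design
  params <- h0_fit$params
  T <- ncol(Y)
  pc <- ll_pieces(params, design$P, design$Z, Y, per_subject = TRUE)
  group <- effect_groups(design$model, T)
  fmap <- free_map(group, T)
  A <- free_A(fmap)
  gi <- t(A) %*% ll_gradient_subjects(pc)          # nfree x n
  Heta <- t(A) %*% ll_hessian(pc) %*% A            # nfree x nfree
  Si <- pc$Siginv
  n <- pc$n
  s <- pc$s
  SR <- Si %*% pc$R                                # T x n (raw score factor)
  ii1 <- rep(seq_len(T), times = T)
  ii2 <- rep(seq_len(T), each = T)
  KSS <- kronecker(Si, Si)
  vecSi <- as.numeric(Si)
  nfull <- T * s + T + pc$npair
  # F stack: dim (T * nfull) x n, full-entry columns
  Full <- matrix(0, T * nfull, n)
  put <- function(entry, block) {
    # block: T x n values of the theta_m-row vector for this entry
    Full_rows <- (entry - 1) * T + seq_len(T)
    Full[Full_rows, ] <<- block
  }
  if (s > 0) for (b in seq_len(s)) {
    SAS <- KSS %*% pc$Ab[[b]]                      # vec(Si A_ib Si)
    SDb <- Si %*% pc$Dtheta[[b]]
    Fb <- SAS - SR[ii1, , drop = FALSE] * SDb[ii2, , drop = FALSE] -
      outer(vecSi, pc$ZP[b, ])
    for (tt in seq_len(T))
      put((b - 1) * T + tt, Fb[(tt - 1) * T + seq_len(T), , drop = FALSE])
  }
  Fu <- KSS %*% pc$Gi - SR[ii1, , drop = FALSE] * SR[ii2, , drop = FALSE] -
    matrix(vecSi, T * T, n)
  for (tt in seq_len(T))
    put(T * s + tt, Fu[(tt - 1) * T + seq_len(T), , drop = FALSE])
  for (k in seq_len(pc$npair)) {
    uu <- pc$pairs[k, 1]; ll <- pc$pairs[k, 2]
    Jm <- matrix(0, T, T); Jm[uu, ll] <- Jm[ll, uu] <- 1
    SJS <- Si %*% Jm %*% Si
    put(T * s + T + k, Si %*% pc$Kp[[k]] - SJS %*% pc$R)
  }
  # aggregate entry columns to free parameters: for each subject the
  # (T x nfull) matrix times A; done via sparse accumulation
  nfree <- ncol(A)
  Fmat <- matrix(0, T * nfree, n)
  for (pfree in seq_len(nfree)) {
    rows_out <- (pfree - 1) * T + seq_len(T)
    ents <- which(A[, pfree] != 0)
    acc <- matrix(0, T, n)
    for (e in ents) acc <- acc + Full[(e - 1) * T + seq_len(T), , drop = FALSE]
    Fmat[rows_out, ] <- acc
  }
  structure(list(T = T, n = n, nfree = nfree, SR = SR, gi = gi,
                 Heta = Heta, Fmat = Fmat, loglik = pc$loglik),
            class = "score_prep")
}

#' Per-subject efficient scores at one test position
#'
#' @param prep a [score_prep()] object for the nuisance model.
#' @param q length-`n` vector of conditional QQ probabilities at the test
#'   position (one column of [conditional_qtl_probs()]).
#' @return list with `Ui` (`T x n` per-subject scores), `U` (their sum),
#'   `V` (`sum_i Ui Ui'`) and the score statistic `S = U' V^{-1} U`.
#' @export
efficient_scores <- function(prep, q) {
  xt <- q - 0.5
  T <- prep$T
  Htm <- matrix(prep$Fmat %*% xt, T, prep$nfree)
  W <- t(solve(prep$Heta, t(Htm)))
  Ui <- sweep(prep$SR, 2, xt, "*") - W %*% prep$gi
  U <- rowSums(Ui)
  V <- tcrossprod(Ui)
  S <- tryCatch(as.numeric(t(U) %*% solve(V, U)), error = function(e) NA_real_)
  list(Ui = Ui, U = U, V = V, S = S)
}

#' Efficient scores across a set of genome positions
#'
#' Vectorized version of [efficient_scores()] over many grid positions
#' (typically the admissible scan positions of one forward-selection step).
#'
#' @param prep a [score_prep()] object.
#' @param Q `n x H` matrix of conditional QQ probabilities, one column per
#'   test position.
#' @return object of class `"score_scan"`: per-position score statistics
#'   `S`, the stacked per-subject scores, and per-position `V` matrices.
#' @export
score_scan <- function(prep, Q) {
  H <- ncol(Q)
  T <- prep$T
  n <- prep$n
  X <- Q - 0.5                                      # n x H
  HtmAll <- prep$Fmat %*% X                         # (T*nfree) x H
  He_chol <- tryCatch(chol(-prep$Heta), error = function(e) NULL)
  Ustack <- matrix(0, H * T, n)
  S <- numeric(H)
  Vlist <- vector("list", H)
  ok <- logical(H)
  for (l in seq_len(H)) {
    Htm <- matrix(HtmAll[, l], T, prep$nfree)
    W <- if (!is.null(He_chol)) {
      -t(backsolve(He_chol, forwardsolve(t(He_chol), t(Htm))))
    } else t(solve(prep$Heta, t(Htm)))
    Ui <- sweep(prep$SR, 2, X[, l], "*") - W %*% prep$gi
    Ustack[(l - 1) * T + seq_len(T), ] <- Ui
    U <- rowSums(Ui)
    V <- tcrossprod(Ui)
    Vlist[[l]] <- V
    S[l] <- tryCatch(as.numeric(t(U) %*% solve(V, U)), error = function(e) NA_real_)
    ok[l] <- is.finite(S[l])
  }
  structure(list(S = S, Ustack = Ustack, V = Vlist, ok = ok, T = T, n = n,
                 H = H),
            class = "score_scan")
}

#' Genome-wide threshold by Gaussian-multiplier score resampling
#'
#' Implements the resampling scheme: draw `z_i ~ N(0,1)` once per resample
#' (shared across all positions, which induces the genome-wide dependence),
#' form `U*(l) = sum_i U_i(l) z_i` and `S*(l) = U*' V(l)^{-1} U*`, take the
#' genome-wide maximum, and repeat `N` times. The threshold at level `alpha`
#' is the `100(1-alpha)` percentile (order statistic) of the `N` maxima.
#'
#' @param scan a [score_scan()] over all admissible positions.
#' @param N number of resamples (default 1000; a warning below 100).
#' @param alpha significance level(s).
#' @param seed integer seed for the multiplier draws.
#' @return object of class `"threshold_result"` with sorted maxima and a
#'   `thresholds` table; `threshold(res, alpha)` interpolates further levels.
#' @export
resample_threshold <- function(scan, N = 1000, alpha = c(0.01, 0.05, 0.10),
                               seed = 1) {
  if (N < 100) warning("fewer than 100 resamples gives unstable thresholds")
  set.seed(seed)
  n <- scan$n
  T <- scan$T
  keep <- which(scan$ok)
  if (length(keep) == 0) stop("no position with invertible score covariance")
  Zm <- matrix(rnorm(n * N), n, N)
  Ustar <- scan$Ustack %*% Zm                       # (H*T) x N
  Smax <- rep(-Inf, N)
  for (l in keep) {
    B <- Ustar[(l - 1) * T + seq_len(T), , drop = FALSE]
    q <- colSums(B * solve(scan$V[[l]], B))
    Smax <- pmax(Smax, q)
  }
  maxima <- sort(Smax)
  thr <- vapply(alpha, function(a) maxima[ceiling((1 - a) * N)], numeric(1))
  structure(list(maxima = maxima, N = N,
                 thresholds = data.frame(alpha = alpha, threshold = thr),
                 seed = seed, n_positions = length(keep),
                 n_skipped = scan$H - length(keep)),
            class = "threshold_result")
}

#' Threshold at arbitrary levels
#'
#' @param res a [resample_threshold()] result.
#' @param alpha level(s).
#' @return threshold value(s), the `100(1-alpha)` percentile of the maxima.
#' @export
threshold_at <- function(res, alpha) {
  vapply(alpha, function(a) res$maxima[ceiling((1 - a) * res$N)], numeric(1))
}
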