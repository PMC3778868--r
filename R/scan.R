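# Genome-wide LRT scan for one additional pleiotropic QTL, and the
# admissibility rules shared by scanning, model optimization and the
# pleiotropy search.

#' Selection configuration
#'
#' @param alpha genome-wide significance level (default 0.10).
#' @param n_resample score resamples per threshold (default 1000).
#' @param radius exclusion radius around QTL already in the model, cM
#'   (default 5).
#' @param max_qtl hard cap on model size (default 10).
#' @param d LOD-drop for support intervals (default 1.5).
#' @param eps,max_iter tolerance and iteration cap for full refits.
#' @param eps_scan,maxit_scan looser settings used per scan position.
#' @param prune mixing-probability pruning threshold.
#' @param criterion compare the genome-wide threshold against the maximum
#'   `"lrt"` (default, the literal procedure) or the maximum `"score"`.
#' @param seed base seed for the resampling thresholds (step `k` uses
#'   `seed + k - 1`).
#' @return a list of class `"select_config"`.
#' @export
select_config <- function(alpha = 0.10, n_resample = 1000, radius = 5,
                          max_qtl = 10, d = 1.5, eps = 1e-4, max_iter = 2000,
                          eps_scan = 1e-3, maxit_scan = 200, prune = 1e-10,
                          criterion = c("lrt", "score"), seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, n_resample = n_resample, radius = radius,
                 max_qtl = max_qtl, d = d, eps = eps, max_iter = max_iter,
                 eps_scan = eps_scan, maxit_scan = maxit_scan, prune = prune,
                 criterion = match.arg(criterion), seed = as.integer(seed)),
            class = "select_config")
}

# grid rows admissible for a new QTL given the current model: outside the
# exclusion radius of every current QTL and not strictly inside a marker
# interval already holding one
admissible_positions <- function(probs, model, radius = 5) {
  grid <- attr(probs, "grid")
  ok <- rep(TRUE, nrow(grid))
  if (model$m > 0) for (r in seq_len(model$m)) {
    same <- grid$chr == model$chr[r]
    ok[same & abs(grid$pos - model$pos[r]) <= radius] <- FALSE
    pi_r <- position_interval(grid_to_map(grid), model$chr[r], model$pos[r])
    if (!pi_r$at_marker)
      ok[same & grid$interval == pi_r$interval & !grid$is_marker] <- FALSE
  }
  ok
}

# reconstruct a minimal linkage_map view from a grid (marker rows)
grid_to_map <- function(grid) {
  mk <- grid[grid$is_marker, , drop = FALSE]
  linkage_map(marker = paste0("m", seq_len(nrow(mk))), chr = mk$chr,
              pos = mk$pos)
}

# internal scan engine: fits the (m+1)-QTL model at each admissible grid row,
# warm-started along each chromosome; returns LRT profile and argmax fit
scan_positions <- function(fit0, probs, rows, config) {
  grid <- attr(probs, "grid")
  model0 <- fit0$design$model
  P0 <- fit0$design$P
  T <- length(fit0$params$u)
  m1 <- model0$m + 1L
  Z1 <- design_Z(qtl_model(chr = rep("x", m1), pos = seq_len(m1)))
  if (model0$p > 0)
    stop("scanning with epistatic terms in the base model is not supported")
  group0 <- effect_groups(model0, T)
  group1 <- cbind(group0, rep(0L, T))
  base_par <- list(u = fit0$params$u, B = cbind(fit0$params$B, 0),
                   Sigma = fit0$params$Sigma)
  lrt <- rep(NA_real_, length(rows))
  conv <- rep(FALSE, length(rows))
  best <- NULL
  warm <- base_par
  last_chr <- ""
  for (k in seq_along(rows)) {
    l <- rows[k]
    if (grid$chr[l] != last_chr) { warm <- base_par; last_chr <- grid$chr[l] }
    q <- probs[, l]
    P1 <- cbind(P0 * q, P0 * (1 - q))
    if (config$prune > 0) {
      P1[P1 < config$prune] <- 0
      P1 <- P1 / rowSums(P1)
    }
    res <- tryCatch(
      .ecm_fit_cpp(attr(probs, "Yt"), P1, Z1, group1,
                   warm$u, warm$B, warm$Sigma,
                   config$eps_scan, as.integer(config$maxit_scan),
                   FALSE, FALSE),
      error = function(e) NULL)
    if (is.null(res)) next
    warm <- list(u = res$u, B = res$B, Sigma = res$Sigma)
    lrt[k] <- 2 * (res$loglik - fit0$loglik)
    conv[k] <- res$converged
    if (is.null(best) || lrt[k] > best$lrt)
      best <- list(lrt = lrt[k], row = l, u = res$u, B = res$B,
                   Sigma = res$Sigma)
  }
  list(lrt = lrt, converged = conv, best = best)
}

#' Genome scan for one additional pleiotropic QTL
#'
#' At every admissible grid position, fits the model extending the current
#' one by a putative pleiotropic QTL (unconstrained effects on all traits)
#' and records `LRT = 2 [l(H1) - l(H0)]` and `LOD = LRT / (2 ln 10)`.
#' Positions within the exclusion radius of a current QTL, or sharing its
#' marker interval, carry no statistic.
#'
#' @param fit0 fitted current model (an `"mtmim_fit"` for the H0 model).
#' @param probs a [conditional_qtl_probs()] table.
#' @param Y `n x T` phenotype matrix.
#' @param config a [select_config()].
#' @return a `data.frame` of class `"scan_profile"` (`chr`, `pos`, `lrt`,
#'   `lod`, `excluded`, `converged`) with the argmax fit in
#'   `attr(, "best")`.
#' @export
genome_scan <- function(fit0, probs, Y, config = select_config()) {
  grid <- attr(probs, "grid")
  attr(probs, "Yt") <- t(Y)
  ok <- admissible_positions(probs, fit0$design$model, config$radius)
  rows <- which(ok)
  sc <- scan_positions(fit0, probs, rows, config)
  out <- data.frame(chr = grid$chr, pos = grid$pos,
                    lrt = NA_real_, lod = NA_real_,
                    excluded = !ok, converged = NA)
  out$lrt[rows] <- sc$lrt
  out$lod <- out$lrt / (2 * log(10))
  out$converged[rows] <- sc$converged
  attr(out, "best") <- sc$best
  class(out) <- c("scan_profile", "data.frame")
  out
}

#' LOD-d support interval
#'
#' The maximal contiguous set of profile positions containing the peak whose
#' LOD stays within `d` of the peak LOD. Intervals never cross chromosome
#' boundaries (profiles are per-chromosome regions).
#'
#' @param pos,lod profile positions (cM, one chromosome, increasing) and LOD
#'   values; positions with `NA` LOD break contiguity.
#' @param peak_pos position of the mapped QTL (must be a profile position).
#' @param d positive LOD drop (default 1.5).
#' @return list with `lo`, `hi` (cM bounds) and `length`; a single-point
#'   interval reports the grid resolution window as its length.
#' @export
lod_support_interval <- function(pos, lod, peak_pos, d = 1.5) {
  if (d <= 0) stop("d must be positive")
  i0 <- which(abs(pos - peak_pos) < 1e-8)
  if (length(i0) != 1) stop("peak position is not a profile position")
  cut <- lod[i0] - d
  ok <- !is.na(lod) & lod >= cut
  lo <- i0
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i0
  while (hi < length(pos) && ok[hi + 1]) hi <- hi + 1
  len <- pos[hi] - pos[lo]
  if (len == 0) len <- if (length(pos) > 1) min(diff(pos)) else 0
  list(lo = pos[lo], hi = pos[hi], length = len)
}
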