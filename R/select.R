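# Forward selection with score-based thresholds and per-trait effect
# pruning, position optimization, and per-QTL LOD profiles.

refit_model <- function(model, probs, Y, config, init = NULL) {
  des <- build_design(model, probs, prune = config$prune)
  ecm_fit(des, Y, fit_config(eps = config$eps, max_iter = config$max_iter,
                             prune = config$prune),
          init = init, keep_trace = FALSE)
}

#' Forward selection of a multiple-QTL model
#'
#' Builds a model QTL by QTL: at each step the genome is scanned for the
#' best additional pleiotropic QTL, its maximum LRT is compared against the
#' genome-wide score-resampling threshold at level `alpha` (recomputed at
#' every step, since the efficient scores depend on the current nuisance
#' model), and an accepted QTL then has each per-trait effect tested by a
#' chi-square(1) LRT at the Bonferroni-corrected level `alpha / T`;
#' nonsignificant effects are masked to zero and the model refit. Selection
#' stops when no position passes, when a new QTL loses all its effects in
#' pruning, or at `max_qtl`.
#'
#' @param probs a [conditional_qtl_probs()] table.
#' @param Y `n x T` phenotype matrix.
#' @param config a [select_config()].
#' @return list of class `"mtmim_selection"`: `model`, `fit`, and a
#'   `steps` data.frame (per step: position, max statistic, threshold,
#'   decision, retained-trait pattern).
#' @export
forward_select <- function(probs, Y, config = select_config()) {
  T <- ncol(Y)
  grid <- attr(probs, "grid")
  model <- qtl_model()
  fit <- refit_model(model, probs, Y, config)
  steps <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (model$m >= config$max_qtl) break
    ok <- admissible_positions(probs, model, config$radius)
    if (!any(ok)) break
    rows <- which(ok)
    attr(probs, "Yt") <- t(Y)
    sc <- scan_positions(fit, probs, rows, config)
    if (is.null(sc$best)) break
    prep <- score_prep(fit, Y)
    sscan <- score_scan(prep, probs[, rows, drop = FALSE])
    thr <- resample_threshold(sscan, N = config$n_resample,
                              alpha = config$alpha,
                              seed = config$seed + step - 1L)
    cutoff <- thr$thresholds$threshold[1]
    stat <- if (config$criterion == "lrt") sc$best$lrt
            else max(sscan$S, na.rm = TRUE)
    rec <- data.frame(step = step, chr = grid$chr[sc$best$row],
                      pos = grid$pos[sc$best$row], max_lrt = sc$best$lrt,
                      statistic = stat, threshold = cutoff,
                      accepted = stat > cutoff,
                      pattern = NA_character_,
                      stringsAsFactors = FALSE)
    if (stat <= cutoff) { steps[[step]] <- rec; break }
    # accept the QTL and refit fully
    cand <- qtl_model(chr = c(model$chr, grid$chr[sc$best$row]),
                      pos = c(model$pos, grid$pos[sc$best$row]),
                      mask = if (is.null(model$mask)) NULL
                             else cbind(model$mask, FALSE))
    warm <- model_parameters(sc$best$u, sc$best$B, sc$best$Sigma)
    fit_c <- refit_model(cand, probs, Y, config, init = warm)
    # per-trait pruning of the new QTL's effects
    keep <- rep(TRUE, T)
    mask_c <- if (is.null(cand$mask)) matrix(FALSE, T, cand$s) else cand$mask
    for (t in seq_len(T)) {
      mk <- mask_c
      mk[t, cand$m] <- TRUE
      mfit <- refit_model(qtl_model(cand$chr, cand$pos, mask = mk),
                          probs, Y, config, init = fit_c$params)
      lrt_t <- 2 * (fit_c$loglik - mfit$loglik)
      keep[t] <- lrt_t > qchisq(1 - config$alpha / T, 1)
    }
    if (!any(keep)) {
      # accepted position retains no single-trait effect: do not add it
      rec$accepted <- FALSE
      rec$pattern <- paste(rep(0L, T), collapse = "")
      steps[[step]] <- rec
      break
    }
    mask_c[!keep, cand$m] <- TRUE
    model <- qtl_model(cand$chr, cand$pos, mask = mask_c)
    fit <- refit_model(model, probs, Y, config, init = fit_c$params)
    rec$pattern <- paste(as.integer(keep), collapse = "")
    steps[[step]] <- rec
  }
  structure(list(model = model, fit = fit,
                 steps = do.call(rbind, steps), config = config),
            class = "mtmim_selection")
}

# region of grid rows searched when repositioning QTL r: its chromosome,
# bounded by neighboring QTL minus the exclusion radius
reposition_rows <- function(probs, model, r, config) {
  grid <- attr(probs, "grid")
  cc <- model$chr[r]
  lo <- -Inf; hi <- Inf
  others <- setdiff(seq_len(model$m), r)
  for (o in others) if (model$chr[o] == cc) {
    if (model$pos[o] < model$pos[r])
      lo <- max(lo, model$pos[o] + config$radius)
    if (model$pos[o] > model$pos[r])
      hi <- min(hi, model$pos[o] - config$radius)
  }
  rows <- which(grid$chr == cc & grid$pos >= lo & grid$pos <= hi)
  # drop rows sharing an open marker interval with another QTL
  sub <- qtl_model(model$chr[others], model$pos[others])
  keep <- admissible_positions(probs, sub, config$radius)
  rows[keep[rows]]
}

#' Optimize QTL positions
#'
#' One pass over the QTL in the model: each in turn has its effects removed,
#' the region bounded by its neighboring QTL (minus the exclusion radius; to
#' the chromosome ends otherwise) is re-scanned with the QTL's constraint
#' pattern preserved, the QTL moves to the maximum-LRT position, and all
#' parameters are refit.
#'
#' @param selection a [forward_select()] result (or compatible list with
#'   `model` and `fit`).
#' @param probs a [conditional_qtl_probs()] table.
#' @param Y phenotype matrix.
#' @param config a [select_config()].
#' @return updated selection object (same shape).
#' @export
optimize_positions <- function(selection, probs, Y, config = select_config()) {
  model <- selection$model
  fit <- selection$fit
  grid <- attr(probs, "grid")
  if (model$m == 0) return(selection)
  for (r in seq_len(model$m)) {
    prof <- qtl_profile_r(model, fit, probs, Y, r, config)
    if (is.null(prof) || all(is.na(prof$lrt))) next
    best <- which.max(prof$lrt)
    new_pos <- prof$pos[best]
    if (abs(new_pos - model$pos[r]) > 1e-8) {
      model$pos[r] <- new_pos
      fit <- refit_model(model, probs, Y, config, init = fit$params)
    }
  }
  selection$model <- model
  selection$fit <- fit
  selection
}

# LRT profile for QTL r over its reposition region, holding the other QTL
# fixed; used both for optimization and for LOD support intervals
qtl_profile_r <- function(model, fit, probs, Y, r, config) {
  rows <- reposition_rows(probs, model, r, config)
  if (length(rows) == 0) return(NULL)
  grid <- attr(probs, "grid")
  others <- setdiff(seq_len(model$m), r)
  mask_full <- if (is.null(model$mask)) matrix(FALSE, ncol(Y), model$s)
               else model$mask
  m0 <- qtl_model(model$chr[others], model$pos[others],
                  mask = mask_full[, others, drop = FALSE])
  init0 <- model_parameters(fit$params$u,
                            fit$params$B[, others, drop = FALSE],
                            fit$params$Sigma)
  fit0 <- refit_model(m0, probs, Y, config, init = init0)
  T <- ncol(Y)
  lrt <- rep(NA_real_, length(rows))
  # scan with the QTL's own mask pattern appended last
  P0 <- fit0$design$P
  m1 <- m0$m + 1L
  Z1 <- design_Z(qtl_model(chr = rep("x", m1), pos = seq_len(m1)))
  group1 <- cbind(effect_groups(m0, T),
                  ifelse(mask_full[, r], -1L, 0L))
  warm <- list(u = fit0$params$u, B = cbind(fit0$params$B, 0),
               Sigma = fit0$params$Sigma)
  Yt <- t(Y)
  for (k in seq_along(rows)) {
    q <- probs[, rows[k]]
    P1 <- cbind(P0 * q, P0 * (1 - q))
    if (config$prune > 0) {
      P1[P1 < config$prune] <- 0
      P1 <- P1 / rowSums(P1)
    }
    res <- tryCatch(
      .ecm_fit_cpp(Yt, P1, Z1, group1, warm$u, warm$B, warm$Sigma,
                   config$eps_scan, as.integer(config$maxit_scan),
                   FALSE, FALSE),
      error = function(e) NULL)
    if (is.null(res)) next
    warm <- list(u = res$u, B = res$B, Sigma = res$Sigma)
    lrt[k] <- 2 * (res$loglik - fit0$loglik)
  }
  data.frame(chr = grid$chr[rows], pos = grid$pos[rows], lrt = lrt,
             lod = lrt / (2 * log(10)))
}

#' Per-QTL LOD profiles and support intervals
#'
#' For each QTL of a fitted model, recomputes its LRT profile (other QTL
#' fixed, the QTL's constraint pattern preserved) over its chromosome region
#' and derives the LOD-`d` support interval around the mapped position.
#'
#' @inheritParams optimize_positions
#' @param d LOD drop (default from `config`).
#' @return `data.frame` with one row per QTL: `chr`, `pos`, `lo`, `hi`,
#'   `length`, `lod_peak`; profiles in `attr(, "profiles")`.
#' @export
qtl_intervals <- function(selection, probs, Y, config = select_config(),
                          d = config$d) {
  model <- selection$model
  fit <- selection$fit
  if (model$m == 0)
    return(data.frame(chr = character(0), pos = numeric(0), lo = numeric(0),
                      hi = numeric(0), length = numeric(0),
                      lod_peak = numeric(0)))
  profs <- vector("list", model$m)
  out <- vector("list", model$m)
  for (r in seq_len(model$m)) {
    prof <- qtl_profile_r(model, fit, probs, Y, r, config)
    profs[[r]] <- prof
    iv <- lod_support_interval(prof$pos, prof$lod, model$pos[r], d)
    peak_lod <- prof$lod[abs(prof$pos - model$pos[r]) < 1e-8]
    out[[r]] <- data.frame(chr = model$chr[r], pos = model$pos[r],
                           lo = iv$lo, hi = iv$hi, length = iv$length,
                           lod_peak = peak_lod, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "profiles") <- profs
  res
}

#' Full MTMIM analysis of a backcross dataset
#'
#' Convenience pipeline: evaluation grid, HMM conditional probabilities,
#' forward selection with score-based thresholds, one position-optimization
#' pass, and LOD support intervals.
#'
#' @param map a [linkage_map()].
#' @param geno a [bc_genotypes()] matrix.
#' @param Y `n x T` phenotype matrix.
#' @param step grid step in cM.
#' @param config a [select_config()].
#' @return list of class `"mtmim_analysis"`: `selection` (model + fit),
#'   `intervals`, `probs`, `grid`, `config`.
#' @export
mtmim_analysis <- function(map, geno, Y, step = 1, config = select_config()) {
  grid <- genome_grid(map, step)
  probs <- conditional_qtl_probs(map, geno, grid)
  sel <- forward_select(probs, Y, config)
  sel <- optimize_positions(sel, probs, Y, config)
  ivs <- qtl_intervals(sel, probs, Y, config)
  structure(list(selection = sel, intervals = ivs, probs = probs,
                 grid = grid, config = config),
            class = "mtmim_analysis")
}

#' @export
print.mtmim_selection <- function(x, ...) {
  cat("MTMIM forward selection:", x$model$m, "QTL, loglik",
      format(x$fit$loglik), "\n")
  if (!is.null(x$steps)) print(x$steps)
  invisible(x)
}
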