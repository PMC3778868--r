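# Genotypic variance-covariance decomposition and the simulation-study
# evaluation metrics (FDR, power, coverage, interval lengths, means,
# model size, trait-subset power decomposition).

#' Genotypic variance-covariance decomposition
#'
#' Decomposes the genotypic covariance between traits into per-QTL(-pair)
#' contributions under the Cockerham backcross coding: a locus has variance
#' 1/4, and two linked loci at recombination fraction `r` have covariance
#' `(1 - 2 r) / 4` (zero across chromosomes). The total genotypic matrix is
#' `G = sum_r G_rr + 2 sum_{r<l} sym(G_rl)` and the phenotypic matrix is
#' `Sigma_p = G + Sigma_e`.
#'
#' @param params fitted [model_parameters()] (main effects only).
#' @param model the fitted [qtl_model()].
#' @return list of class `"vcov_decomposition"`: `G`, `Sigma_p`, `Sigma_e`,
#'   and `blocks` (list over ordered pairs `r <= l` of `T x T` matrices).
#' @export
genotypic_vcov <- function(params, model) {
  if (model$p > 0)
    stop("epistatic variance decomposition is not supported")
  T <- length(params$u)
  m <- model$m
  blocks <- list()
  G <- matrix(0, T, T)
  if (m > 0) for (r in seq_len(m)) for (l in r:m) {
    if (r == l) cv <- 0.25
    else if (model$chr[r] != model$chr[l]) cv <- 0
    else cv <- (1 - 2 * haldane(abs(model$pos[r] - model$pos[l]))) / 4
    blk <- tcrossprod(params$B[, r], params$B[, l]) * cv
    blocks[[paste(r, l, sep = ":")]] <- blk
    G <- G + if (r == l) blk else blk + t(blk)
  }
  structure(list(G = G, Sigma_e = params$Sigma,
                 Sigma_p = G + params$Sigma, blocks = blocks),
            class = "vcov_decomposition")
}

#' Match mapped QTL to simulated QTL
#'
#' Pairs every mapped QTL with its closest simulated QTL (distance infinite
#' across chromosomes); a mapped QTL is *matched* when its LOD-`d` support
#' interval contains the paired QTL's position, and a simulated QTL is
#' *identified* when at least one matched mapped QTL pairs to it.
#'
#' @param mapped `data.frame` with columns `chr`, `pos`, `lo`, `hi` (one row
#'   per mapped QTL; `lo`/`hi` are the support-interval bounds).
#' @param truth `data.frame` with columns `chr`, `pos` (simulated QTL).
#' @return list with `mapped` (adds `paired`, `matched`) and `truth` (adds
#'   `identified`, `closest_mapped` — index of the closest matched mapped
#'   QTL, NA when unidentified).
#' @export
match_qtl <- function(mapped, truth) {
  nm <- nrow(mapped)
  nt <- nrow(truth)
  mapped$paired <- NA_integer_
  mapped$matched <- FALSE
  if (nm > 0 && nt > 0) {
    for (i in seq_len(nm)) {
      same <- which(as.character(truth$chr) == as.character(mapped$chr[i]))
      if (length(same) == 0) next
      dd <- abs(truth$pos[same] - mapped$pos[i])
      j <- same[which.min(dd)]
      mapped$paired[i] <- j
      mapped$matched[i] <- truth$pos[j] >= mapped$lo[i] &&
        truth$pos[j] <= mapped$hi[i]
    }
  }
  truth$identified <- FALSE
  truth$closest_mapped <- NA_integer_
  if (nt > 0) for (j in seq_len(nt)) {
    cand <- which(mapped$matched & mapped$paired == j)
    if (length(cand) > 0) {
      truth$identified[j] <- TRUE
      dd <- abs(mapped$pos[cand] - truth$pos[j])
      truth$closest_mapped[j] <- cand[which.min(dd)]
    }
  }
  list(mapped = mapped, truth = truth)
}

#' Run one simulated replicate through the MTMIM pipeline
#'
#' Simulates a dataset from a scenario, runs forward selection with a
#' score-based threshold, optimizes positions and computes LOD-`d` support
#' intervals at one or more `d` levels.
#'
#' @param spec a [scenario_spec()].
#' @param seed replicate seed (drives both the data and the resampling
#'   thresholds).
#' @param config a [select_config()]; its `seed` is overridden by `seed`.
#' @param step grid step in cM.
#' @param d_levels LOD-drop levels for support intervals.
#' @return list with `mapped` (chr, pos, pattern, effect estimates),
#'   `intervals` (per d level), `truth`, `steps`, `loglik`.
#' @export
run_scenario_replicate <- function(spec, seed, config = select_config(),
                                   step = 2, d_levels = 1.5) {
  config$seed <- as.integer(seed)
  cross <- simulate_cross(spec, seed)
  grid <- genome_grid(cross$map, step)
  probs <- conditional_qtl_probs(cross$map, cross$geno, grid)
  sel <- forward_select(probs, cross$pheno, config)
  sel <- optimize_positions(sel, probs, cross$pheno, config)
  model <- sel$model
  T <- ncol(cross$pheno)
  ivs <- NULL
  if (model$m > 0) {
    base <- qtl_intervals(sel, probs, cross$pheno, config, d = d_levels[1])
    profs <- attr(base, "profiles")
    ivs <- do.call(rbind, lapply(seq_along(d_levels), function(k) {
      dd <- d_levels[k]
      do.call(rbind, lapply(seq_len(model$m), function(r) {
        iv <- lod_support_interval(profs[[r]]$pos, profs[[r]]$lod,
                                   model$pos[r], dd)
        data.frame(qtl = r, d = dd, chr = model$chr[r], pos = model$pos[r],
                   lo = iv$lo, hi = iv$hi, length = iv$length,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  mask <- if (is.null(model$mask)) matrix(FALSE, T, model$s) else model$mask
  pattern <- if (model$m > 0)
    apply(!mask, 2, function(z) paste(as.integer(z), collapse = ""))
  else character(0)
  mapped <- data.frame(chr = model$chr, pos = model$pos,
                       pattern = pattern, stringsAsFactors = FALSE)
  if (model$m > 0) {
    eff <- t(sel$fit$params$B)
    colnames(eff) <- paste0("b", seq_len(T))
    mapped <- cbind(mapped, eff)
  }
  list(mapped = mapped, intervals = ivs,
       truth = data.frame(chr = as.character(spec$qtl$chr),
                          pos = spec$qtl$pos, stringsAsFactors = FALSE),
       steps = sel$steps, loglik = sel$fit$loglik, seed = seed)
}

#' Summarize a set of simulated replicates
#'
#' Computes the evaluation metrics over replicates produced by
#' [run_scenario_replicate()]: false discovery rate (per replicate and
#' overall; replicates with no mapped QTL contribute 0), per-QTL power,
#' support-interval coverage (denominator: replicates where the QTL is
#' paired), mean interval length, mean position and mean effects over the
#' identification set, model-size distribution, and the decomposition of
#' power by retained-trait pattern.
#'
#' @param reps list of [run_scenario_replicate()] results.
#' @param d the LOD-drop level at which to match (must be among the
#'   replicates' `d_levels`).
#' @return list of class `"mtmim_evaluation"` with elements `per_qtl`,
#'   `fdr`, `model_size`, `patterns`.
#' @export
evaluate_replicates <- function(reps, d = 1.5) {
  R <- length(reps)
  truth <- reps[[1]]$truth
  nt <- nrow(truth)
  fdr_b <- numeric(R)
  sizes <- integer(R)
  identified <- matrix(FALSE, R, nt)
  paired <- matrix(FALSE, R, nt)
  pos_hat <- matrix(NA_real_, R, nt)
  len_hat <- matrix(NA_real_, R, nt)
  patt <- matrix(NA_character_, R, nt)
  eff_list <- vector("list", R)
  for (b in seq_len(R)) {
    rep_b <- reps[[b]]
    eff_list[[b]] <- vector("list", nt)
    iv <- rep_b$intervals
    m <- nrow(rep_b$mapped)
    sizes[b] <- m
    if (m == 0) { fdr_b[b] <- 0; next }
    ivd <- iv[iv$d == d, , drop = FALSE]
    mapped <- data.frame(chr = rep_b$mapped$chr, pos = rep_b$mapped$pos,
                         lo = ivd$lo[match(seq_len(m), ivd$qtl)],
                         hi = ivd$hi[match(seq_len(m), ivd$qtl)],
                         stringsAsFactors = FALSE)
    mm <- match_qtl(mapped, truth)
    fdr_b[b] <- sum(!mm$mapped$matched) / m
    for (j in seq_len(nt)) {
      paired[b, j] <- any(!is.na(mm$mapped$paired) & mm$mapped$paired == j)
      identified[b, j] <- mm$truth$identified[j]
      if (identified[b, j]) {
        i <- mm$truth$closest_mapped[j]
        pos_hat[b, j] <- mapped$pos[i]
        len_hat[b, j] <- ivd$length[ivd$qtl == i]
        patt[b, j] <- rep_b$mapped$pattern[i]
        eff_list[[b]][[j]] <- as.numeric(
          rep_b$mapped[i, grep("^b", names(rep_b$mapped)), drop = TRUE])
      }
    }
  }
  per_qtl <- data.frame(
    qtl = seq_len(nt), chr = truth$chr, pos = truth$pos,
    power = colMeans(identified),
    coverage = colSums(identified) / pmax(colSums(paired), 1),
    n_paired = colSums(paired),
    mean_length = apply(len_hat, 2, mean, na.rm = TRUE),
    mean_pos = apply(pos_hat, 2, mean, na.rm = TRUE))
  T <- if (any(sizes > 0))
    length(grep("^b", names(reps[[which(sizes > 0)[1]]]$mapped)))
  else 1L
  mean_eff <- matrix(NA_real_, nt, T)
  for (j in seq_len(nt)) {
    es <- do.call(rbind, lapply(seq_len(R), function(b) eff_list[[b]][[j]]))
    if (!is.null(es)) mean_eff[j, ] <- colMeans(es)
  }
  patterns <- lapply(seq_len(nt), function(j) {
    tb <- table(patt[, j], useNA = "no")
    if (length(tb) == 0) return(NULL)
    data.frame(pattern = names(tb), freq = as.integer(tb),
               share = as.integer(tb) / R)
  })
  structure(list(per_qtl = per_qtl, mean_effects = mean_eff,
                 fdr = mean(fdr_b), fdr_b = fdr_b,
                 model_size = table(sizes), patterns = patterns,
                 d = d, R = R),
            class = "mtmim_evaluation")
}

#' @export
print.mtmim_evaluation <- function(x, ...) {
  cat("Evaluation over", x$R, "replicates (LOD-", x$d, " matching)\n", sep = "")
  print(x$per_qtl, digits = 3)
  cat("FDR:", format(x$fdr, digits = 3), "\n")
  invisible(x)
}
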