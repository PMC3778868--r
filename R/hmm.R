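#' Conditional QTL genotype probabilities on a genome grid
#'
#' For every subject and every grid position, the probability that a putative
#' backcross locus at that position has genotype QQ, conditional on the
#' nearest informative flanking markers under a no-interference Markov chain
#' along the chromosome with Haldane recombination. Missing marker genotypes
#' are skipped (the chain conditions on the nearest typed markers on each
#' side); a position with no typed marker on either side gets the
#' unconditional backcross probability 1/2.
#'
#' @param map a [linkage_map()].
#' @param geno a [bc_genotypes()] matrix for the same map.
#' @param grid a [genome_grid()] built from the same map.
#' @return an `n x H` matrix of class `"cond_probs"` (subjects in rows, grid
#'   positions in columns) with the grid attached as an attribute.
#' @export
conditional_qtl_probs <- function(map, geno, grid) {
  n <- nrow(geno)
  H <- nrow(grid)
  out <- matrix(NA_real_, n, H)
  for (cc in unique(map$chr)) {
    midx <- which(map$chr == cc)
    mp <- map$pos[midx]
    M <- length(mp)
    G <- geno[, midx, drop = FALSE]
    typed <- !is.na(G)
    # nearest typed marker index at or left / at or right of marker k
    L <- matrix(0L, n, M)
    R <- matrix(0L, n, M)
    L[, 1] <- ifelse(typed[, 1], 1L, 0L)
    for (k in seq_len(M)[-1]) L[, k] <- ifelse(typed[, k], k, L[, k - 1L])
    R[, M] <- ifelse(typed[, M], M, 0L)
    for (k in rev(seq_len(M - 1L))) R[, k] <- ifelse(typed[, k], k, R[, k + 1L])
    gidx <- which(grid$chr == cc)
    for (h in gidx) {
      p <- grid$pos[h]
      k <- findInterval(p, mp, rightmost.closed = TRUE)
      li <- L[, k]
      ri <- if (k < M) R[, k + 1L] else rep(0L, n)
      # left factor a = P(X = QQ | left marker); 1/2 when uninformative
      a <- rep(0.5, n)
      hasL <- li > 0L
      if (any(hasL)) {
        rl <- haldane(p - mp[li[hasL]])
        gl <- G[cbind(which(hasL), li[hasL])]
        a[hasL] <- ifelse(gl == 1L, 1 - rl, rl)
      }
      # right factors b = P(right marker | X = QQ), bq = P(right | X = Qq)
      b <- rep(1, n)
      bq <- rep(1, n)
      hasR <- ri > 0L
      if (any(hasR)) {
        rr <- haldane(mp[ri[hasR]] - p)
        gr <- G[cbind(which(hasR), ri[hasR])]
        b[hasR] <- ifelse(gr == 1L, 1 - rr, rr)
        bq[hasR] <- ifelse(gr == 1L, rr, 1 - rr)
      }
      out[, h] <- a * b / (a * b + (1 - a) * bq)
    }
  }
  structure(out, grid = grid, class = c("cond_probs", "matrix", "array"))
}

#' Joint QTL genotype mixing probabilities
#'
#' Multiplies per-locus conditional probabilities into prior mixing
#' probabilities over the `2^m` joint genotypes of `m` putative QTL, assuming
#' conditional independence of loci given their flanking markers (valid when
#' no two loci share a marker interval). Joint genotypes are enumerated with
#' locus 1 cycling fastest: component `j` assigns locus `r` the genotype QQ
#' when bit `r - 1` of `j - 1` is 0, Qq when it is 1.
#'
#' @param probs a [conditional_qtl_probs()] table.
#' @param positions integer vector of grid row indices, one per locus.
#' @param prune probabilities below this threshold are set to zero and the
#'   rows renormalized (default 1e-10; 0 disables pruning).
#' @return an `n x 2^m` matrix of mixing probabilities, rows summing to one.
#' @export
joint_genotype_probs <- function(probs, positions, prune = 1e-10) {
  grid <- attr(probs, "grid")
  m <- length(positions)
  n <- nrow(probs)
  if (m == 0) return(matrix(1, n, 1))
  if (m > 1) {
    for (r1 in seq_len(m - 1)) for (r2 in seq(r1 + 1, m)) {
      i1 <- positions[r1]; i2 <- positions[r2]
      if (grid$chr[i1] == grid$chr[i2]) {
        if (abs(grid$pos[i1] - grid$pos[i2]) < 1e-8)
          stop("two QTL at the same position")
        iv1 <- grid$interval[i1]; iv2 <- grid$interval[i2]
        if (iv1 == iv2 && !grid$is_marker[i1] && !grid$is_marker[i2])
          stop("two QTL positions inside one marker interval: ",
               "the product-form mixing probabilities do not apply")
      }
    }
  }
  P <- matrix(1, n, 1)
  for (r in seq_len(m)) {
    q <- probs[, positions[r]]
    P <- cbind(P * q, P * (1 - q))
  }
  if (prune > 0) {
    P[P < prune] <- 0
    P <- P / rowSums(P)
  }
  P
}
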