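#' Simulate backcross genotypes
#'
#' Generates marker genotypes for `spec$n` subjects by a Markov chain along
#' each chromosome: the first locus is Bernoulli(1/2) and each subsequent
#' locus flips with the Haldane recombination fraction of the inter-locus
#' distance (no interference). The latent genotypes at the scenario's true
#' QTL positions are realized on the same chain (exact linkage with the
#' flanking markers) and attached as attribute `"qtl_geno"` for phenotype
#' simulation.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return a [bc_genotypes()] matrix with attribute `"qtl_geno"`
#'   (`n x m` matrix of 1 = QQ / 0 = Qq at the true QTL).
#' @export
simulate_genotypes <- function(spec, seed) {
  set.seed(seed)
  map <- scenario_map(spec)
  n <- spec$n
  m <- nrow(spec$qtl)
  G <- matrix(NA_integer_, n, nrow(map))
  Q <- matrix(NA_integer_, n, m)
  for (cc in seq_len(spec$n_chr)) {
    midx <- which(map$chr == as.character(cc))
    mpos <- map$pos[midx]
    qidx <- if (m > 0) which(spec$qtl$chr == cc) else integer(0)
    qpos <- spec$qtl$pos[qidx]
    loci <- sort(unique(c(mpos, qpos)))
    x <- rbinom(n, 1L, 0.5)
    for (k in seq_along(loci)) {
      if (k > 1) {
        r <- haldane(loci[k] - loci[k - 1])
        flip <- rbinom(n, 1L, r)
        x <- as.integer(xor(x, flip))
      }
      hit_m <- which(abs(mpos - loci[k]) < 1e-9)
      if (length(hit_m)) G[, midx[hit_m]] <- x
      hit_q <- which(abs(qpos - loci[k]) < 1e-9)
      if (length(hit_q)) Q[, qidx[hit_q]] <- x
    }
  }
  out <- bc_genotypes(G, map)
  attr(out, "qtl_geno") <- Q
  out
}

#' Simulate multi-trait phenotypes
#'
#' Draws `y_i = u + B x_i (+ epistatic terms) + e_i` with
#' `e_i ~ MVN(0, Sigma)`, using the latent QTL genotypes realized by
#' [simulate_genotypes()] (not imputed from markers).
#'
#' @param spec a [scenario_spec()].
#' @param geno genotypes from [simulate_genotypes()] for the same spec.
#' @param seed integer seed for the residual draw.
#' @return an `n x T` phenotype matrix (subjects in rows, traits in columns).
#' @export
simulate_phenotypes <- function(spec, geno, seed) {
  set.seed(seed)
  Q <- attr(geno, "qtl_geno")
  if (is.null(Q))
    stop("genotypes lack latent QTL genotypes; use simulate_genotypes()")
  n <- nrow(geno)
  T <- length(spec$u)
  m <- nrow(spec$qtl)
  mu <- matrix(spec$u, n, T, byrow = TRUE)
  if (m > 0) {
    X <- matrix(cockerham_code(as.vector(Q)), n, m)
    mu <- mu + X %*% t(spec$effects)
    if (!is.null(spec$epistasis) && nrow(spec$epistasis) > 0) {
      ep <- spec$epistasis
      W <- as.matrix(ep[, spec$traits, drop = FALSE])
      for (k in seq_len(nrow(ep)))
        mu <- mu + outer(X[, ep$q1[k]] * X[, ep$q2[k]], W[k, ])
    }
  }
  E <- matrix(rnorm(n * T), n, T) %*% chol(spec$Sigma)
  Y <- mu + E
  colnames(Y) <- spec$traits
  Y
}

#' Simulate a complete backcross dataset
#'
#' One master seed drives two deterministic sub-streams (`2 * seed` for
#' genotypes, `2 * seed + 1` for phenotypes) so phenotypes can be re-simulated
#' on fixed genotypes.
#'
#' @param spec a [scenario_spec()].
#' @param seed master integer seed (keep below 2^30).
#' @return a list of class `"sim_cross"` with elements `map`, `geno`, `pheno`,
#'   `spec` and `seed`.
#' @export
simulate_cross <- function(spec, seed) {
  geno <- simulate_genotypes(spec, 2L * as.integer(seed))
  pheno <- simulate_phenotypes(spec, geno, 2L * as.integer(seed) + 1L)
  structure(list(map = attr(geno, "map"), geno = geno, pheno = pheno,
                 spec = spec, seed = seed),
            class = "sim_cross")
}
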