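# Independent oracles used across the test suite. These deliberately use
# brute-force enumeration / closed forms, never the package's own fast paths.

# Brute-force chain enumeration on one chromosome: probability that the
# locus at `target` is QQ (=1) given observed marker genotypes.
#   loci_pos: marker positions (cM); obs: vector of 0/1/NA at those markers.
bf_cond_prob <- function(loci_pos, obs, target) {
  all_pos <- sort(unique(c(loci_pos, target)))
  K <- length(all_pos)
  num <- 0
  den <- 0
  for (code in 0:(2^K - 1)) {
    g <- bitwAnd(bitwShiftR(code, 0:(K - 1)), 1L)
    p <- 0.5
    for (k in 2:K) {
      r <- haldane(all_pos[k] - all_pos[k - 1])
      p <- p * if (g[k] == g[k - 1]) 1 - r else r
    }
    consistent <- TRUE
    for (i in seq_along(loci_pos)) {
      if (is.na(obs[i])) next
      if (g[which(all_pos == loci_pos[i])] != obs[i]) consistent <- FALSE
    }
    if (!consistent) next
    den <- den + p
    if (g[which(all_pos == target)] == 1L) num <- num + p
  }
  num / den
}

# Brute-force joint distribution of genotypes at several target loci on one
# chromosome given observed markers; returns probabilities over the
# lexicographic (locus 1 fastest, 0 = QQ) component order used by the package.
bf_joint_probs <- function(loci_pos, obs, targets) {
  all_pos <- sort(unique(c(loci_pos, targets)))
  K <- length(all_pos)
  m <- length(targets)
  out <- numeric(2^m)
  den <- 0
  for (code in 0:(2^K - 1)) {
    g <- bitwAnd(bitwShiftR(code, 0:(K - 1)), 1L)
    p <- 0.5
    for (k in 2:K) {
      r <- haldane(all_pos[k] - all_pos[k - 1])
      p <- p * if (g[k] == g[k - 1]) 1 - r else r
    }
    consistent <- TRUE
    for (i in seq_along(loci_pos)) {
      if (is.na(obs[i])) next
      if (g[which(all_pos == loci_pos[i])] != obs[i]) consistent <- FALSE
    }
    if (!consistent) next
    den <- den + p
    comp <- 1L
    for (r in seq_len(m)) {
      gr <- g[which(all_pos == targets[r])]
      if (gr == 0L) comp <- comp + 2L^(r - 1L)   # 0 = Qq bit set
    }
    out[comp] <- out[comp] + p
  }
  out / den
}

# multivariate normal log-density, plain R
ldmvnorm <- function(Y, mu, Sigma) {
  T <- ncol(Y)
  ctr <- sweep(Y, 2, mu)
  q <- rowSums((ctr %*% solve(Sigma)) * ctr)
  -0.5 * (T * log(2 * pi) + as.numeric(determinant(Sigma)$modulus) + q)
}

# multivariate least-squares oracle: ML estimates for Y = u + X B' + E
ols_oracle <- function(Y, X) {
  n <- nrow(Y)
  fitlm <- lm(Y ~ X)
  B <- t(coef(fitlm)[-1, , drop = FALSE])
  u <- coef(fitlm)[1, ]
  Sigma <- crossprod(residuals(fitlm)) / n
  mu <- matrix(u, n, ncol(Y), byrow = TRUE) + X %*% t(B)
  ll <- sum(ldmvnorm(Y - X %*% t(B), u, Sigma))
  list(u = u, B = B, Sigma = Sigma, loglik = ll)
}

# small random mixture instance for property tests
random_instance <- function(seed, T = 2, m = 1, n = 60) {
  set.seed(seed)
  u <- rnorm(T)
  qtl <- data.frame(chr = sample(1:2, m, replace = (m > 2)),
                    pos = runif(m, 2, 18))
  # keep loci in distinct chromosomes when possible to avoid shared intervals
  if (m == 2) qtl$chr <- c(1, 2)
  A <- matrix(rnorm(T * T, sd = 0.4), T, T)
  Sigma <- crossprod(A) + diag(T)
  spec <- scenario_spec(n_chr = 2, markers_per_chr = 3, spacing = 10, n = n,
                        traits = paste0("T", 1:T), u = u, qtl = qtl,
                        effects = matrix(rnorm(T * m, sd = 0.5), T, m),
                        Sigma = Sigma, name = "rand")
  cross <- simulate_cross(spec, seed + 1)
  grid <- genome_grid(cross$map, 2)
  probs <- conditional_qtl_probs(cross$map, cross$geno, grid)
  model <- qtl_model(chr = as.character(qtl$chr),
                     pos = pmin(pmax(2 * round(qtl$pos / 2), 0), 20))
  list(spec = spec, cross = cross, grid = grid, probs = probs, model = model,
       Y = cross$pheno)
}
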