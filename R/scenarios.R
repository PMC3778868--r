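#' Simulation scenario specification
#'
#' Describes a backcross simulation: the map blueprint, sample size, trait
#' architecture (means, per-QTL effect matrix, optional epistatic effects)
#' and the residual covariance. Effects are in trait units per coded-genotype
#' unit (Cockerham +-1/2 coding).
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers per chromosome.
#' @param spacing marker spacing in cM.
#' @param n number of backcross subjects.
#' @param traits trait names (length T).
#' @param u trait means (length T).
#' @param qtl `data.frame` with columns `chr` (chromosome index) and `pos`
#'   (cM); may have zero rows.
#' @param effects `T x m` matrix of main effects (columns follow `qtl` rows).
#' @param epistasis optional `data.frame` with columns `q1`, `q2` (QTL
#'   indices) plus one effect column per trait.
#' @param Sigma `T x T` residual covariance, symmetric positive definite.
#' @param h2 optional per-trait heritabilities (documentation only; the
#'   operative parameters are `effects` and `Sigma`).
#' @param name scenario label.
#' @return an object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(n_chr = 6, markers_per_chr = 9, spacing = 10,
                          n = 300, traits = paste0("T", seq_along(u)),
                          u, qtl, effects, epistasis = NULL, Sigma,
                          h2 = NULL, name = "custom") {
  u <- as.numeric(u)
  T <- length(u)
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma))) ||
      any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("Sigma must be symmetric positive definite")
  qtl <- as.data.frame(qtl)
  m <- nrow(qtl)
  effects <- matrix(as.numeric(effects), nrow = T)
  if (ncol(effects) != m)
    stop("effects must have one column per QTL")
  span <- (markers_per_chr - 1) * spacing
  if (m > 0 && (any(qtl$pos < 0) || any(qtl$pos > span) ||
                any(qtl$chr < 1) || any(qtl$chr > n_chr)))
    stop("QTL positions must lie within the map span")
  structure(list(n_chr = n_chr, markers_per_chr = markers_per_chr,
                 spacing = spacing, n = n, traits = traits, u = u,
                 qtl = qtl, effects = effects, epistasis = epistasis,
                 Sigma = Sigma, h2 = h2, name = name),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario", x$name, ":", x$n, "subjects,", length(x$u), "traits,",
      nrow(x$qtl), "QTL on", x$n_chr, "chromosomes\n")
  invisible(x)
}

#' Linkage map of a scenario
#'
#' @param spec a [scenario_spec()].
#' @return the [linkage_map()] implied by the map blueprint.
#' @export
scenario_map <- function(spec) {
  M <- spec$markers_per_chr
  chr <- rep(seq_len(spec$n_chr), each = M)
  pos <- rep(spec$spacing * (seq_len(M) - 1), spec$n_chr)
  linkage_map(marker = sprintf("C%dM%d", chr, rep(seq_len(M), spec$n_chr)),
              chr = chr, pos = pos)
}

#' Built-in simulation scenarios
#'
#' The four genetic architectures used in the package's evaluation study:
#' six chromosomes with nine markers at 10 cM spacing, 300 subjects.
#' `S0` has three traits and no QTL (null model for error-rate studies).
#' `SI` has five unlinked QTL, each with effect 0.52 on all three traits.
#' `SII` mixes QTL affecting one, two or three traits. `SIII` has two traits
#' with two closely linked nonpleiotropic pairs and one pleiotropic QTL.
#'
#' @return named list of [scenario_spec()] objects `S0`, `SI`, `SII`, `SIII`.
#' @export
builtin_scenarios <- function() {
  Sig3 <- matrix(c(1, 0.2, 0,
                   0.2, 1, -0.2,
                   0, -0.2, 1), 3, 3, byrow = TRUE)
  Sig2 <- matrix(c(1, 0.2,
                   0.2, 1), 2, 2, byrow = TRUE)
  qtl5 <- data.frame(chr = c(1, 2, 3, 5, 6), pos = c(23, 15, 45, 67, 53))
  list(
    S0 = scenario_spec(u = c(30, 35, 30),
                       qtl = data.frame(chr = integer(0), pos = numeric(0)),
                       effects = matrix(0, 3, 0), Sigma = Sig3,
                       h2 = c(0, 0, 0), name = "S0"),
    SI = scenario_spec(u = c(30, 35, 30), qtl = qtl5,
                       effects = matrix(0.52, 3, 5), Sigma = Sig3,
                       h2 = c(25, 25, 25), name = "SI"),
    SII = scenario_spec(u = c(30, 35, 30), qtl = qtl5,
                        effects = rbind(c(0.52, 0.52, 0.52, 0.52, 0.52),
                                        c(0,    0.54, 0.54, 0.54, 0),
                                        c(0,    0,    0.46, 0,    0)),
                        Sigma = Sig3, h2 = c(25, 18, 5), name = "SII"),
    SIII = scenario_spec(u = c(30, 35),
                         qtl = data.frame(chr = c(1, 1, 3, 6, 6),
                                          pos = c(23, 33, 45, 38, 53)),
                         effects = rbind(c(0.54, 0,    0.54, 0,    0.54),
                                         c(0,    0.54, 0.54, 0.54, 0)),
                         Sigma = Sig2, h2 = c(18, 18), name = "SIII")
  )
}
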