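---
title: "Multiple-trait multiple-interval mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-trait multiple-interval mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Quantitative traits measured on the same backcross population are usually
mapped one at a time, although correlated traits share genetic and
environmental structure. `mtmim` fits all traits jointly in a multiple-QTL
model, which (i) borrows strength across traits in detection, (ii) makes
hypotheses about *pleiotropy* (one locus, several traits) versus *close
linkage* (several one-trait loci) testable, (iii) supports
QTL-by-environment tests when the "traits" are one trait measured in
several environments, and (iv) yields a decomposition of the genotypic
covariance between traits into per-QTL contributions.

# Model

For subject $i$ with trait vector $y_i \in \mathbb{R}^T$ and $m$ putative
QTL at positions $\lambda = (\lambda_1,\dots,\lambda_m)$,

$$ y_i = u + B\, x_i + e_i, \qquad e_i \sim \mathrm{MVN}_T(0, \Sigma_e), $$

where $x_{ir} \in \{+\tfrac12, -\tfrac12\}$ codes the (unobserved) backcross
genotype at QTL $r$ (Cockerham coding; a locus then has genotypic variance
$1/4$), optional epistatic columns carry products $x_{ir} x_{il}$, and $B$
is the $T \times s$ effect matrix. Entries of $B$ may be *masked* (held
exactly at zero) — this is how per-trait pruned effects and nonpleiotropic
models are represented — or *shared* within a column (equality constraints
for QTL-by-environment tests).

QTL genotypes are unobserved; conditional on flanking marker genotypes a
no-interference Markov chain with Haldane recombination
$r = (1 - e^{-2d})/2$ gives each subject per-locus probabilities
$P(QQ \mid \text{markers})$, and — assuming at most one QTL per marker
interval — the joint probabilities over the $2^m$ genotype combinations are
products of the per-locus ones. Missing marker genotypes are skipped: each
position conditions on the nearest *informative* flanking markers, which is
exact under the Markov chain. The likelihood is a $2^m$-component
multivariate-normal mixture per subject; the package evaluates it with
per-subject log-sum-exp, enumerates components with locus 1 cycling
fastest, and prunes mixing probabilities below `1e-10` (renormalizing) —
the threshold is configurable and pruning at 0 reproduces the exact
likelihood to machine precision.

# Estimation

**ECM.** The E-step computes posterior genotype probabilities
$\Pi_{ij} \propto p_{ij}\,\phi(y_i \mid u + B Z_{[\cdot,j]}, \Sigma_e)$,
always mixing with the prior $p_{ij}$. The CM sweep updates $u$, then
$\Sigma_e$, then each column of $B$; a column with masked or shared entries
is updated entry-by-entry (coordinate ascent), each update being the exact
conditional maximizer given all other current values — this preserves the
EM ascent property, which the test suite verifies on randomized instances.

**GEM-NR.** After a short ECM warm-up (5 iterations by default),
Newton-Raphson steps are taken on the expected complete-data log-likelihood
$Q_c$ using its analytic gradient and Hessian over the free parameters
(masked entries excluded; $\Sigma_e$ parameterized by its unique lower
triangle, off-diagonal derivatives taken along the symmetric basis). A step
size $\kappa$ starts at 1 and is halved (at most 5 times) whenever the
observed log-likelihood would decrease or $\Sigma_e$ would leave the
positive-definite cone; if halving fails, the algorithm falls back to an
ECM block. Total fallbacks are capped (default 50), after which the best
iterate is returned flagged non-converged — this guards the corner case
where halving fails immediately after every fallback. Both fitters agree to
three decimals on fixed data and GEM-NR typically needs far fewer
iterations.

**Stopping rule.** The default rule stops when the log-likelihood increment
falls below `eps = 1e-4` on the *absolute* scale. A relative variant
(increment divided by $|\ell|$) is available, but with typical sample sizes
($|\ell| \approx 10^3$) a relative `1e-4` rule stops at increments around
$0.1$ — far too coarse for LOD-profile work — so absolute is the default.
Genome-scan positions use a looser `eps_scan = 1e-3` with warm starts
carried along each chromosome (the converged parameters of the previous
grid position), and accepted models are refit at the full tolerance.

**Initialization.** Sample means, the maximum-likelihood sample covariance
and $B = 0$, unless a warm start is given. Warm starts are made feasible
first (masked entries zeroed, shared entries averaged) so the first CM
sweep is already a true conditional maximization.

# Genome-wide threshold by score resampling

To test a new pleiotropic QTL at position $l$ with effects
$\theta_m = 0$ against the current (nuisance) model, the per-subject
efficient score is the nuisance-projected gradient
$\hat U_i(l) = \partial \ell_i/\partial \theta_m - H_{\theta_m \eta}
H_{\eta\eta}^{-1}\, \partial \ell_i/\partial \eta$, all derivatives of the
mixture log-likelihood evaluated at the H0 MLE, and
$S(l) = \hat U' \hat V^{-1} \hat U$ with
$\hat V = \sum_i \hat U_i \hat U_i'$. Because the tested effects are zero
under H0, the mixture factorizes over the new locus and every
$(\theta_m, \cdot)$ Hessian block is $\sum_i \tilde x_i(l) F_i$ with
$\tilde x_i(l) = P_i(QQ \mid \text{markers}) - 1/2$ and subject matrices
$F_i$ independent of $l$; the package precomputes the $F_i$ once per
nuisance model so a whole-genome score scan costs a single matrix product.
The factorized scores equal the direct nuisance-partitioned construction to
machine precision (tested).

The null distribution of the genome-wide maximum is approximated by
Gaussian-multiplier resampling: draw $z_i \sim N(0,1)$ *once per resample*
(shared across positions — this is what preserves the genome-wide
dependence), form $U^*(l) = \sum_i \hat U_i(l) z_i$,
$S^*(l) = U^{*\prime} \hat V(l)^{-1} U^*$, record $\max_l S^*(l)$, and take
the $100(1-\alpha)$ percentile (order statistic) of $N$ maxima. The
threshold is recomputed at every forward-selection step, since
$\hat U_i(l)$ depends on the current nuisance model. During selection the
maximum *LRT* is compared against this threshold (score and LRT are
asymptotically equivalent); comparing the maximum score instead is exposed
as an option.

# Model selection

Forward selection starts from the no-QTL model. Each step scans all grid
positions outside a 5-cM exclusion radius of current QTL (and outside
their open marker intervals, where the product-form mixing probabilities do
not apply), takes the maximum-LRT position, and accepts it if the LRT
exceeds the resampled threshold at the genome-wide level $\alpha$
(default 10%). An accepted QTL's per-trait effects are then tested
individually against $\chi^2_1$ at the Bonferroni level $\alpha/T$;
nonsignificant effects are masked and the model refit once (earlier
acceptances are not revisited). If *all* effects of a new QTL are pruned
the position is not added and selection stops. After selection, one
optimization pass revisits each QTL in turn: its effects are removed, the
region bounded by neighboring QTL (minus the radius; chromosome ends
otherwise) is re-scanned with the QTL's constraint pattern preserved, and
the QTL moves to the new argmax. Ties at a maximum resolve to the lowest
chromosome, then lowest position (the scan visits positions in that order).

LOD-$d$ support intervals ($\mathrm{LOD} = \mathrm{LRT}/(2\ln 10)$;
$d = 1.5$ by default) are the maximal contiguous profile region around the
mapped position within $d$ of its LOD; they never cross chromosome
boundaries, and a single-point interval reports the grid resolution window
as its length.

# Pleiotropy versus close linkage, and QTL-by-environment

For a bivariate model, a mapped pleiotropic QTL is tested against two
closely linked one-trait loci by a two-dimensional grid search over
position pairs $(\lambda_3, \lambda_4)$ in a window (default $\pm 15$ cM,
clipped at neighbors' buffers and chromosome ends). Each off-diagonal pair
fits the model with the trait-2 effect masked at $\lambda_3$ and the
trait-1 effect masked at $\lambda_4$; diagonal entries are evaluated as
single-locus pleiotropic fits, so the search's diagonal reproduces the
one-dimensional profile. Pairs lying strictly inside one marker interval
violate the product-form assumption and are skipped. The criterion is
$\mathrm{LRT} = 2[\ell_{\text{linked}} - \ell_{\text{pleio}}]$ against
$\chi^2_1$ at 5% (the linked model spends one extra position parameter;
effect counts are equal), with AICc
($-2\ell + 2k + 2k(k+1)/(n-k-1)$, positions counted as parameters)
reported alongside. Because the discrete search excludes same-interval
pairs, the linked maximum can in principle fall below the pleiotropic
likelihood; a negative LRT simply retains pleiotropy.

QTL-by-environment tests (design I: the same genotypes phenotyped in every
environment, trait states = environments) constrain one QTL's effect to be
equal across an environment subset $S$ via effect-sharing groups in the CM
step — a design-matrix reparameterization rather than Lagrange multipliers,
so the ECM machinery applies unchanged — and compare by $\chi^2$ with
$|S| - 1$ degrees of freedom.

# Genotypic variance decomposition

With main effects only, QTL $r$ contributes
$G_{rr} = B_{[\cdot,r]} B_{[\cdot,r]}'/4$ and a linked pair $(r,l)$ on one
chromosome contributes the cross term
$G_{rl} = B_{[\cdot,r]} B_{[\cdot,l]}' (1 - 2 r_{rl})/4$ (zero across
chromosomes), where $r_{rl}$ is the Haldane recombination fraction of
their distance; $G = \sum_r G_{rr} + 2\sum_{r<l}\mathrm{sym}(G_{rl})$ and
$\Sigma_p = G + \Sigma_e$. The backcross covariance $(1-2r)/4$ is the
standard two-locus result; the test suite validates the whole decomposition
against exhaustive enumeration of joint genotypes weighted by chain
probabilities. Epistatic contributions are declined with an explicit error.

# The simulator and the evaluation study

`builtin_scenarios()` returns the four architectures of the package's
evaluation study — six chromosomes, nine markers at 10 cM, $n = 300$:
`S0` (three traits, no QTL), `SI` (five unlinked QTL, effect 0.52 on all
three traits, heritability 25% per trait), `SII` (QTL affecting one, two or
three traits), and `SIII` (two traits, two closely linked nonpleiotropic
pairs at 10 and 15 cM separation plus one pleiotropic QTL). Genotypes are
simulated as a Markov chain along each chromosome (first locus
Bernoulli(1/2), flips with the Haldane fraction of the spacing); the
latent QTL genotypes are realized *on the same chain*, in exact linkage
with their flanking markers — the generative model the linear model
assumes — rather than drawn from conditional probabilities. One master
seed splits into deterministic genotype (`2*seed`) and phenotype
(`2*seed+1`) streams so phenotypes can be re-simulated on fixed genotypes.

What the simulator does *not* emulate: genotyping errors, missing marker
data patterns of real studies, selective genotyping, non-Gaussian
residuals, segregation distortion. Passing tests on simulated data
therefore demonstrate correctness of the machinery under the model's own
assumptions, not robustness to their violation.

**Problem sizes.** The reproduction study in `scripts/acceptance.R` runs
100 replicates each of SI and SII on the 1-cM scan grid with 300 score
resamples at the 10% genome-wide level with LOD-1.5 matching; the testthat
acceptance blocks use 30 replicates (SI/SII, 1-cM grid) and 80 null
replicates (S0, 2-cM grid) with $\pm 2$ standard-error Monte-Carlo bands at
those counts. These sizes were fixed once as desk-scale renditions of the
full study (which used 500 evaluation replicates); binomial Monte-Carlo
error at 100 replicates is about $\pm 4$ percentage points on a 78% power
and smaller near the extremes. The SIII pleiotropy-rejection suite is exercised at
unit-test scale (single datasets probing both a true pleiotropic and a
true linked architecture) rather than as a replicate study, which at full
scale is not desk-scale.

# Numerical choices and degenerate inputs

* Mixture densities in log space with per-subject log-sum-exp; an all-zero
  posterior row raises an explicit underflow error.
* `-H(Q_c)` is factorized by Cholesky; failure (not positive definite)
  triggers the ECM fallback rather than a crash. NR steps that break the
  positive definiteness of $\Sigma_e$ are treated like likelihood
  decreases ($\kappa$-halving).
* A scan position whose fit fails is flagged and skipped; a position with
  singular $\hat V(l)$ is skipped in the resampling maximum.
* Degenerate designs (a component weight column that is identically zero,
  two QTL in one marker interval, missing genotype passed to the coding
  function) raise named errors.
* Replicates with zero mapped QTL contribute a false-discovery rate of 0
  (the alternative — excluding them — changes the mean only through the
  denominator and both counts are available from `fdr_b`).
* Mean-position/effect/length summaries use the LOD-1.5 identification
  set by default.

# Known limitations

Backcross populations only (the design abstraction — coded-genotype matrix
plus transition probabilities — is the single extension point for F2/RIL);
no interference models or sex-specific maps; no covariates beyond the
intercept; no automated epistasis scan (epistatic terms can be added to a
fitted model and tested); support intervals are grid-quantized; the
pleiotropy search is bivariate, as is its usual application.
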