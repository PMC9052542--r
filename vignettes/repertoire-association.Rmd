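---
title: "Mixed-effects score tests for TCR repertoire association"
author: "tcrhom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-effects score tests for TCR repertoire association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrhom)
```

## The problem

High-throughput sequencing recovers, for every subject, the set of unique
TCR beta-chain CDR3 amino-acid sequences together with their clone counts.
Linking this *repertoire* to a clinical phenotype is awkward for standard
regression: every subject carries a different number of different
sequences, so there is no common feature space, and much of the signal is
hidden in sequence similarity rather than in anything easily tabulated.

`tcrhom` addresses this with a generalized linear mixed model.  For subject
$i$ with covariates $X_i$ (intercept plus $q$ confounders), repertoire
$R_i$, and phenotype $y_i$:

$$E(y_i) = \pi\left(\beta^\top X_i + \eta^\top W^\top f(R_i) + h(R_i)\right),$$

where $\pi$ is the identity link for continuous traits and the logistic
link for binary traits.  The model splits the repertoire signal in two:

* **Explicit features** (fixed effect).  $f(R_i)$ is the vector of the 20
  amino-acid proportions, abundance weighted: the count of residue $j$ is
  $g_j(R_i) = \sum_k w_{i,k} \cdot \#\{j \in a_{i,k}\}$ over the unique
  sequences $a_{i,k}$ with clone counts $w_{i,k}$, normalized to sum to 1.
  The $p \times r$ matrix $W$ ($r < p$) injects prior biochemistry; the
  default is the Kyte–Doolittle hydropathy scale, so
  $W^\top f(R_i)$ is the repertoire's proportion-weighted hydrophobicity.
* **Hidden features** (random effect).  $h(R_i)$ is a subject-level random
  effect with $h \sim N(0, \tau^2 S)$, where $S$ is a repertoire-homology
  kernel built from pairwise sequence alignment (below).  It absorbs
  sequence information that no explicit feature captures.

The null hypothesis of no association is $\eta = 0$ and $\tau^2 = 0$.

## The homology kernel

Sequence-level homology starts from the optimal Needleman–Wunsch global
alignment score $d(a, b)$ under BLOSUM62 or PAM250 with an affine gap
penalty, and is normalized to

$$s(a, b) = \frac{d(a, b)}{\sqrt{d(a, a)\, d(b, b)}},$$

so $s(a, a) = 1$ and $s \le 1$; $s$ may be negative when the raw alignment
score is, and negative values are kept — they are informative about strong
dissimilarity.

Subject-level homology aggregates best matches, weighted by clone counts,
in both directions:

$$S_{ij} = \frac{\sum_k w_{i,k} \max_l s(a_{i,k}, a_{j,l})
  + \sum_l w_{j,l} \max_k s(a_{i,k}, a_{j,l})}
  {\sum_k w_{i,k} + \sum_l w_{j,l}}.$$

The denominator is the unique affine normalization under which $S$ is
symmetric and $S_{ii} = 1$ for arbitrary clone counts (within a subject
every sequence's best match is itself, with $s = 1$), so the diagonal is
set to 1 analytically.  Because max–average aggregation does not guarantee
positive semi-definiteness, `psdProject()` eigendecomposes $S$, zeroes
negative eigenvalues and reconstructs; the repair report (how many
eigenvalues were clipped, the most negative one) travels with the kernel.
In simulated cohorts of the sizes used here the raw kernel is typically
already PSD, so the projection is usually the identity.

**Gap penalties.**  The aligner charges a gap of length $L$ as
`gapOpen + (L-1) * gapExtend`, with defaults 10 and 0.5 — the EMBOSS
needle defaults, the most widely recognized "default" pairing for
BLOSUM62/PAM250 global alignment.  Both are exposed in
`substitutionScheme()`, and results shift only mildly under other
reasonable choices because the normalization in $s$ absorbs scale.
Substitution matrices are taken from the Biostrings collection, restricted
to the 20 standard residues.  The alignment core is compiled (Rcpp)
because a cohort kernel needs $O(n^2 \bar m^2)$ alignments; it is verified
in the test suite against an exhaustive-path oracle and against
`Biostrings::pairwiseAlignment()` under the matching gap convention.

## The two score tests

Both tests are score tests, so only null models are ever fitted.

**Fixed effect.**  Under the joint null, with $\tilde\mu$ the fitted means
of the covariate-only null model,

$$U_\eta = \sum_i W^\top f(R_i)(y_i - \tilde\mu_i), \qquad
\tilde\Sigma = G^\top \tilde\Gamma G, \qquad
\tilde\Gamma = \tilde\Omega - \tilde\Omega X (X^\top \tilde\Omega X)^{-1}
X^\top \tilde\Omega,$$

where $\tilde\Omega$ is the diagonal working-weight matrix (constant
residual variance $\frac1n \sum_i (y_i - \tilde\mu_i)^2$ for continuous
traits, $\tilde\mu_i(1 - \tilde\mu_i)$ for binary) and $G$ stacks
$W^\top f(R_i)$.  $U_\eta^\top \tilde\Sigma^{-1} U_\eta$ is asymptotically
$\chi^2_r$.

**Random effect.**  Testing $\tau^2 = 0$ scores against the *extended*
null in which $\eta$ is free: the null design is $Z = [X \mid G]$ (for the
homology-only comparison model, $Z = X$).  For continuous traits, with
$P_0$ the residual projection of $Z$, $d = q + 1 + r$ and
$\hat\sigma^2 = \mathrm{RSS}/(n-d)$,

$$Q = \frac{(y-\hat\mu)^\top S (y-\hat\mu) - \mathrm{tr}(SP_0)\hat\sigma^2}
 {\sqrt{2\hat\sigma^4\left[\mathrm{tr}(SP_0SP_0)
   - \mathrm{tr}(SP_0)^2/(n-d)\right]}}$$

is asymptotically standard normal.  For binary traits the logistic fit is
linearised through its IRLS working responses: with
$\hat\Omega = \mathrm{diag}(\hat\mu_i(1-\hat\mu_i))$, the same formula is
applied to $Z^\dagger = \hat\Omega^{1/2} Z$ and working residuals
$\hat\Omega^{-1/2}(y - \hat\mu)$.  Setting $\hat\Omega = \hat\sigma^2 I$
in the daggered formulas recovers the continuous ones, which the test
suite checks against an independent dense-matrix implementation.

Because the fixed-effect score conditions on the covariate-only fit and
the variance-component score conditions on the feature-extended fit, the
two statistics are independent under the null; the package combines their
p-values with Fisher's statistic $-2(\log p_\eta + \log p_{\tau^2})$
referred to $\chi^2_4$ (two independent p-values, hence four degrees of
freedom).  Independence is verified empirically in the acceptance suite
(null correlation within $\pm 0.05$, combined p-value uniform by
Kolmogorov–Smirnov).

## Numerical choices

* **One-sided p for $Q$.**  $\tau^2 \ge 0$, so only inflation of the
  quadratic form above its null mean is evidence against the null; the
  default p-value is the upper normal tail, with `alternative =
  "two.sided"` exposed for users who prefer the agnostic convention.
* **IRLS.**  Logistic null fits use `stats::glm.fit` with convergence
  tolerance $10^{-10}$ and at most 100 iterations; non-convergence
  (typically separation) is an error, not a silent result.  Fitted
  probabilities are clamped to $[10^{-10}, 1-10^{-10}]$ before entering
  working weights so the working residuals cannot blow up.
* **Degenerate kernels.**  When $S = I$ (or $S$ acts as the identity on
  the residual space of $Z$), both the numerator and the variance of $Q$
  are identically zero; the 0/0 resolves analytically to $Q = 0$,
  $p = 0.5$, and the package returns exactly that instead of failing.
  Any other zero-variance configuration is a hard error.
* **Conditioning.**  $\tilde\Sigma$ is inverted through a symmetric solve
  guarded by an eigenvalue check against the unprojected scale
  $G^\top \tilde\Omega G$, so features that are constant or lie in the
  covariate span produce a clear error rather than an unstable statistic.
* **PSD repair tolerance.**  Eigenvalues above $-10^{-10}$ count as zero;
  only negative eigenvalues are clipped — small positive ones are kept, as
  truncating them would discard genuine between-subject structure.

## The repertoire simulator

The simulator generates the data the statistical machinery is calibrated
on, emulating the structure of beta-chain CDR3 extracts:

* a sequence is head + middle + tail: heads CASS/CASR/CSAR/CAST with
  probabilities 0.7/0.1/0.1/0.1, tails YF/FF/HF/TF with probabilities
  0.4/0.4/0.1/0.1, middles of 4–10 residues uniform over the 20 amino
  acids; 0, 1 or 2 extra residues are inserted at uniform positions
  (mimicking P/N nucleotide addition), giving lengths 10–18.  The
  insertion-count law, the inserted-residue law and the insertion
  positions are uniform — the maximum-entropy choice where no finer
  convention exists;
* per subject, 2–25 unique sequences (uniform) with clone counts 1–5
  (uniform);
* covariates $X_1 \sim \mathrm{Bernoulli}(0.5)$, $X_2 \sim N(0,1)$ with
  $\beta = (0.1, 0.5, -0.4)$; traits follow the mixed model with
  scenario-specific effects — under `fixed_only`, $\eta = 1.6$ (binary) /
  $0.8$ (continuous); under `random_only`, $\tau^2 = 8$ / $0.8$; under
  `both`, $\eta = 1, \tau^2 = 6$ / $\eta = 0.5, \tau^2 = 0.6$;
* binary traits are redrawn (the trait only, never the design or the
  random effect) until each class holds at least 10% of subjects, so the
  logistic fits never face pathological imbalance.

What the simulator does **not** emulate: V/D/J segment usage and its
linkage to the head motifs, nucleotide-level recombination, sequencing
depth and PCR amplification noise in the clone counts, the heavy-tailed
clone-size distributions of real repertoires, or shared public clones
across subjects.  Calibration and power results on simulated cohorts
therefore demonstrate the statistical machinery under the stated
generative model, not performance guarantees on any particular clinical
dataset.

## Study sizes used in the package's own checks

The acceptance suite and `scripts/acceptance.R` run desk-scale versions
of the full calibration studies: type-I error on cohorts of $n = 200$
with 2,000 trait replicates in a fixed-cohort design (repertoires,
covariates and kernels drawn once; the trait redrawn each replicate), and
power at $n = 150$ with 300 replicates per scenario.  These sizes give
binomial Monte-Carlo standard errors of about 0.005 at the 0.05 level and
about 0.03 on power estimates, tight enough to confirm nominal type-I
error and the qualitative power ordering of the five methods (composition
test, kernel-only tests under each substitution matrix, combined tests).
Per-replicate cohort regeneration (`fixedCohort = FALSE`) is the faithful
default for standalone studies; the fixed-cohort mode is the labelled
speed approximation.

## A worked run

```{r example}
set.seed(1)
rs <- simulateRepertoireSet(80)
X <- simulateCovariates(80)
kern <- psdProject(buildKernel(rs, substitutionScheme("BLOSUM62")))
G <- weightedFeatures(featureMatrix(rs))
y <- simulateTrait(X, G, traitType = "binary", eta = 1,
                   tau2 = 6, kernelRoot = tcrhom:::.kernelRoot(kern))
tcrAssocTest(rs, X, y, traitType = "binary", kernel = kern)
```

## Limitations

* The score statistics are asymptotic; at small $n$ (a few dozen) the
  normal approximation for $Q$ is visibly skewed and p-values near the
  tail should be treated with caution.  The binary-trait linearisation
  adds a further layer of approximation on top of the continuous case.
* The model tests association only.  Because the random effect has no
  explicit features, coefficients cannot be estimated and the fitted
  object cannot predict outcomes for new subjects.
* Alignment-based homology is one choice of kernel; the
  `SubstitutionScheme` interface accepts custom matrices, but
  alternative sequence distances (e.g. motif- or k-mer-based) are not
  implemented.
* Survival phenotypes must be dichotomised by the user; there is no
  proportional-hazards variant.
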