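---
title: "Semi-parametric outcome prediction from TCR repertoires: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-parametric outcome prediction from TCR repertoires: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

A T-cell receptor (TCR) repertoire is one individual's collection of unique
beta-chain CDR3 amino-acid sequences together with their clonal abundances,
$R_i = \{(a_{ij}, w_{ij});\, j = 1, \dots, m_i\}$. Repertoires are
unstructured: sequence sets barely overlap between individuals, so there is
no fixed design matrix to feed a standard regression. `tcrkern` predicts a
continuous or binary clinical outcome $Y_i$ from $R_i$ together with
adjusting covariates $X_i$ (age, sex, lab values, ...) by combining two
complementary representations of the repertoire:

1. **Extracted features.** Amino-acid $k$-mers are counted across all
   sequences of a repertoire (each occurrence weighted by the clone's
   abundance by default), giving a sparse non-negative matrix $Z$. This
   captures explicit, local sequence content.
2. **Hidden features.** Whatever $k$-mers miss — conformation, long-range
   residue interactions — is modeled non-parametrically as a function
   $h(\cdot)$ living in the RKHS of a repertoire-homology kernel.

The model is the semi-parametric GLM

$$E(Y_i) = \pi\!\left(\beta_0 + X_i^T\beta + Z_i^T\gamma + h(R_i)\right),$$

with $\pi$ the identity (continuous) or logistic (binary) link. By the
representer theorem $h(R_i) = K_i^T\alpha$, where $K$ is the kernel matrix
over the training cohort.

## The repertoire-homology kernel

Sequence-level similarity is a global (Needleman–Wunsch) alignment score
under BLOSUM62 or PAM250 with affine gap penalties (a gap of length $L$
costs `gap_open` + $L\cdot$`gap_extend`; defaults 10 and 1), normalized as
$s(a,b) = S(a,b)/\sqrt{S(a,a)\,S(b,b)}$ and clamped to $[-1, 1]$, so that
$s(a,a) = 1$. Repertoire-level homology is the abundance-weighted
best-match average

$$k(R_i, R_{i'}) = \frac{\sum_j w_{ij} \max_{j'} s(a_{ij}, a_{i'j'}) +
\sum_{j'} w_{i'j'} \max_{j} s(a_{ij}, a_{i'j'})}
{\sum_j w_{ij} + \sum_{j'} w_{i'j'}},$$

which is symmetric, equals 1 on identical repertoires, and is invariant to
rescaling all abundances jointly. (It is *not* invariant to rescaling one
repertoire alone: the two directional sums share one weight pool. Counts
and relative frequencies therefore give slightly different kernels, and
either is acceptable input.) The matrix $K$ built from this homology is not
guaranteed positive semi-definite, so it is eigendecomposed and its negative
eigenvalues truncated at zero (`psd_project()`); the number of truncated
eigenvalues and the most negative one are recorded on the object. Hard
truncation (rather than shifting the whole spectrum) was chosen because it
is a genuine low-rank projection: it is idempotent and it is the closest PSD
matrix in Frobenius norm. Cross-kernels used at prediction time are left
unprojected, since projection is only defined for the square training block;
this asymmetry is deliberate and documented here.

Normalization choices: the default self-normalized similarity makes
$k(R,R)=1$ and the whole pipeline scale-free; raw alignment scores are
available (`normalize = FALSE`) for users matching other homology
implementations. The alignment flavor and gap penalties are a declared
convention, not a claim of equivalence to any particular external tool.

## Feature construction and screening

- **Counting.** A sequence of length $L$ contributes its $L-k+1$ windows;
  $k$ between 2 and 5 is practical ($20^k$ grows fast). Abundance weighting
  is the default (mirroring the kernel's use of $w_{ij}$) and can be
  disabled.
- **Scaling.** Each column of $Z$ is divided by its 0.75 quantile, computed
  with type-7 linear interpolation (the `stats::quantile()` default; the
  rule is declared and tested). Columns whose quantile is zero fall back to
  the column maximum, then to 1 — degenerate columns are passed through
  rather than erroring. Two modes exist: the all-entries quantile (used in
  the simulation pipeline) and the non-zero-entries quantile (the
  convention for sparse real-data matrices); both record their factors so
  prediction-time features can be put on the training scale.
- **Prevalence filter.** $k$-mers present in fewer than 5% of individuals
  are dropped (boundary kept). Prevalence across individuals — rather than
  mean relative frequency — is the implemented reading of the 5% rule; the
  threshold is a parameter.
- **Sure-independence screening.** Columns are ranked by absolute Pearson
  correlation with the outcome (0/1 for binary; zero-variance columns get
  correlation 0 and rank last; ties break lexicographically) and the top
  $d = \lfloor n/(2\ln n)\rfloor$ kept — the canonical SIS statistic and
  dimension with the natural log.

## Estimation

**Continuous outcomes** minimize
$\sum_i (Y_i - \beta_0 - X_i^T\beta - Z_i^T\gamma - K_i^T\alpha)^2 +
\lambda_0|\gamma|_1 + \lambda_1 \alpha^T K \alpha$ by alternating:

1. With $\alpha$ fixed, a lasso of $Y - K^T\alpha$ on $[X, Z]$; the
   intercept and covariates are never penalized. Features with zero
   coefficients are dropped permanently, so the support can only shrink.
2. With the parametric part fixed, the closed form
   $\hat\alpha = (\lambda_1 I + K)^{-1}(Y - \hat\beta_0 - X\hat\beta -
   Z\hat\gamma)$, with $\lambda_1 = (p^{(t)} + r + 1)/n$ recomputed from
   the current support size $p^{(t)}$ — the penalty relaxes as the model
   simplifies.
3. Training MSE; iteration stops when its change is below `eps` (default
   1e-4) or after `max_iter` (default 20) rounds.

**Binary outcomes** replace step 1 by an iteratively reweighted scheme:
the working response $Y_w = \Delta + (Y - \pi(\Delta))/(\pi(\Delta)(1 -
\pi(\Delta)))$ and weights $\nu_i = \pi(\Delta_i)(1 - \pi(\Delta_i))$ are
computed at the current linear predictor $\Delta$, a weighted lasso is fit, and the
kernel coefficients come from $\hat\alpha = (\lambda I + \Omega^{1/2}
K)^{-1}\Omega^{1/2}(Y_w - \hat\beta_0 - X\hat\beta - Z\hat\gamma)$.
The working-response probabilities are trimmed at $[0.01, 0.99]$
(`prob_clip`), the standard IRLS safeguard: it bounds the working
residual by $1/0.01 \approx 100$ and the weights below by $\approx
0.01$, so a single saturated misclassified observation cannot inject an
arbitrarily large pseudo-observation that the kernel step would absorb
and amplify (without trimming the alternating loop can visibly diverge).
The cross-entropy used for convergence is computed from untrimmed
probabilities.
That system is implemented exactly as written even though
$\Omega^{1/2} K$ is not symmetric; a config option
(`alpha_solver = "symmetric"`) offers the symmetrized variant
$(\lambda I + \Omega^{1/2} K \Omega^{1/2})^{-1}$, whose linear system is
symmetric positive definite by construction — the written form is
ambiguous about the grouping and we make no claim about which reading is
canonical. In our experiments the as-written form is the stabler of the
two inside the alternating loop and is the default.
Initialization is an L1-penalized logistic regression of $Y$ on $[X, Z]$;
convergence is tracked on the training cross-entropy.

Numerical choices worth knowing:

- $\lambda_0/\lambda_2$ are chosen once, by 10-fold cross-validation on the
  first-iteration penalized regression, then held fixed; re-tuning each
  iteration would destabilize the shrinking support. CV folds are drawn
  from the session RNG (pass `seed` for strict reproducibility).
- glmnet internally rescales observation weights to mean 1 and penalty
  factors to sum to the number of variables. Both rescalings are
  neutralized, so `lambda` always means the same per-coefficient L1
  penalty, at every iteration, whatever the support size. This is what
  makes the binary fit with an inert kernel agree with a direct penalized
  logistic regression at the same `lambda`.
- If the lasso empties the support, iteration continues with $p^{(t)} = 0$:
  the model degrades gracefully to covariates plus kernel.
- The alternating scheme has no monotonicity guarantee; the loss trace is
  recorded on the model object and may wiggle.
- With $\lambda_1 > 0$ and PSD $K$, the $\alpha$-system is always
  nonsingular.

**Prediction** for a new individual extracts exactly the selected $k$-mers
from the new repertoire (absent ones contribute 0), applies the stored
column scales, computes the cross-homology to the training repertoires, and
evaluates $\hat\beta_0 + X^T\hat\beta + Z^T\hat\gamma + K^T\hat\alpha$
(then the logistic link and a 0.5 threshold for binary outcomes).

## The synthetic pool and what it does (not) show

Real repertoire pools with linked outcomes are controlled-access, so the
package ships a generator that every experiment (and every test) runs on.
Default pool: 1,000 individuals, 10–60 unique clones each, CDR3 lengths
8–20, interior residues from a fixed glycine/serine-skewed frequency
table, abundances Zipf(1.5) on 2–50 (the shallow counts typical of
RNA-seq-extracted repertoires; the floor at 2 means the pool passes the
quality filter by construction). Two structural features matter:

- **Conserved flanks.** Each clone draws its first and last residues from
  small V/J-style motif pools (`CASS/CASR/CAST/CAIS` ×
  `QYF/QFF/EAFF/YTF`, geometrically decreasing usage). Flank-derived
  $k$-mers are therefore frequent in *every* individual — as CAS/ASS/QYF
  are in real beta-chain data — with correlated but not identical
  columns.
- **Public templates.** Half of each repertoire (configurable) consists
  of lightly mutated copies (0–2 interior substitutions) of a global set
  of 150 template sequences, drawn with latent-cluster-specific
  preferences (5 clusters). This emulates public clonotypes and
  convergent motifs and is what gives the homology kernel genuine
  between-individual structure; with fully private repertoires the
  kernel is near-diagonal and the hidden effect is unlearnable by
  construction.

The generator reproduces the *statistical shape* the method consumes. It
does **not** emulate V(D)J recombination mechanics, germline allele
frequencies, thymic selection, or disease-associated clonal expansion;
passing tests demonstrate correctness of the machinery and qualitative
method behavior, not clinical performance on real cohorts.

Outcome generation mirrors the kernel model: one covariate
$X_1 \sim N(0,1)$ with $\beta_0 = 2$, $\beta_1 = -1$; the 6 most frequent
$k$-mers get coefficients $c_0 \cdot U(-1,1)$. "Most frequent" is ranked
on raw counts: ranking after quantile scaling (available via
`rank_causal_after_scaling = TRUE`) would favor sparse columns whose
small 0.75 quantile inflates them enormously — "most frequent" would
degenerate into "most heterogeneous" and the causal term would dwarf
every other effect. Hidden effects
$h \sim N(0, \tau K)$ are drawn through the truncated eigenfactorization
(well-defined even when the raw $K$ is indefinite), with $\tau = 5$ as the
default scale; continuous noise is $N(0,1)$ — the identity-link model
implies additive error whose variance is a declared choice ($\sigma = 1$,
configurable). $K$ for generation is built on train and test jointly
(test-side hidden effects must exist to be predicted); each method then
sees only its training block. Binary replicates are accepted only when the
case proportion lies in $[0.3, 0.7]$, redrawing everything otherwise (at
most 100 times). Sampling is without replacement within a replicate, with
replacement across replicates.

## Benchmarks, problem sizes, and runtime design

`run_benchmark()` compares, per replicate: the covariates-only GLM
(`basic_glm`), penalized regressions on the screened $k$-mers
(`tcr_lasso`, `tcr_ridge`), and the full semi-parametric model under
BLOSUM62 (`tcrpred_B`) or PAM250 (`tcrpred_P`). Binary outcomes are scored
by classification error at 0.5 and midrank AUC, continuous ones by MSE.
Everything is deterministic given the config seed.

Pairwise repertoire alignment dominates the cost, so the kernel is cached
at the pool level: each pair of pool individuals is aligned at most once
per substitution matrix across all replicates, and the inner scorer is
compiled (an affine-gap Needleman–Wunsch with a fixed-size fast path for
CDR3-length sequences). The packaged experiments are sized for a desk
machine as the package's own defaults: the shipped acceptance experiments
use a 600-individual pool for the support-recovery study (50 replicates at
$n = 500$) and the method-ordering study (25 replicates at
$n_{train} = n_{test} = 150$), and the reproduction script uses a
400-individual pool with 8 binary and 5 continuous replicates at
$n = 100 + 100$. Full-scale studies (500 replicates at $n = 500 + 500$ on
a cohort-derived pool of thousands) use the identical code path — only the
configuration differs.

## Known limitations

- Only beta-chain CDR3 amino-acid repertoires; no nucleotide-level input,
  no alpha/gamma/delta chains, no CDR1/CDR2 or TCRdist-style metrics.
- No survival outcomes (dichotomize first, as is common practice), no
  coefficient inference/p-values, no multi-kernel learning.
- The kernel step scales quadratically in cohort size and clone counts;
  cohorts of a few thousand individuals are practical, biobank scale is
  not.
- Gapped $k$-mers, reduced alphabets and position-specific features are out
  of scope, though arbitrary named non-negative feature columns can be
  appended to a `tcr_features` object by hand.
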