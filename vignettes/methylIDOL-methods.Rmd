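---
title: "Reference-based blood deconvolution and IDOL library optimization: models and design"
author: "methylIDOL maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based blood deconvolution and IDOL library optimization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylIDOL)
```

# The problem

A whole-blood DNA methylation profile is a mixture: the beta value observed
at a CpG is, to good approximation, the average of the cell-type-specific
methylation states weighted by the DNA fractions the constituent leukocyte
populations contribute. Epigenome-wide association studies must separate
shifts in cell composition from within-cell methylation change, and
reference-based deconvolution does so by regressing each blood sample onto
a *signature matrix* of mean methylation profiles measured in purified cell
populations — here the six canonical adult leukocyte subtypes: neutrophils
(Neu), monocytes (Mono), B cells (Bcell), CD4+ T cells (CD4T), CD8+ T cells
(CD8T) and natural killer cells (NK).

The quality of the estimates depends almost entirely on *which probes* make
up the signature. This package implements both classical rank-based probe
selection and IDOL, an iterative search that optimizes the probe library
directly for deconvolution accuracy on training mixtures with known
composition, together with three deconvolution back-ends and the evaluation
statistics used to compare them.

# Models and procedures

## The mixing model

For sample $i$ with cell-type fractions $\omega_i \in \mathbb{R}^K$
($\omega_{ik} \ge 0$) and a signature matrix $S$ (probes $\times$ K, each
entry the mean beta of that cell type's reference replicates), the observed
beta vector over the library probes is modelled as
$y_i \approx S\,\omega_i$. Beta values are bounded in $[0,1]$, so every
convex combination of valid profiles is again a valid profile; the model is
exact when mixtures are formed by pooling DNA.

## Probe selection

For every probe and every cell type $k$, `computeTStats()` computes a
two-sample t-statistic comparing cell type $k$ against all other reference
samples pooled. The pooled-variance (classical) statistic is the default —
it matches the row-test lineage of the array-analysis packages this
workflow descends from — with Welch's statistic available via
`var.equal = FALSE`. Positive $t$ means hypermethylated in $k$.

* **Automatic selection** (`selectAutomatic()`): the top
  `nPerDirection = 50` hyper- and hypomethylated probes per cell type,
  union over cell types — the familiar 600-probe library for $K = 6$.
* **Candidate pool** (`buildCandidatePool()`): the same construction at
  depth $L/2 = 75$ per direction, giving up to $L \cdot K = 900$ unique
  candidates that form the IDOL search space.

Ties at a rank boundary are broken by ascending probe identifier so results
are platform-independent. When one probe tops the list for two cell types
the union keeps the entry with the larger $|t|$ (then lexicographic cell
type); library sizes may therefore fall below $2nK$ on real data, and the
round figures (600, 900) assume disjoint per-type rankings. Probes missing
in at least half the replicates of any cell type are excluded from
selection: their group means are no longer comparable across types. No
multiple-testing correction is applied — selection is rank-based, not
threshold-based.

## Deconvolution back-ends

* **CP/QP** (`deconvolveCPQP()`): per sample, the quadratic program
  $\min_\omega \|y - S\omega\|^2$ s.t. $\omega \ge 0$,
  $\sum_k \omega_k \le 1$, solved with `quadprog::solve.QP`. The
  *inequality* sum constraint deliberately permits unmodelled cell mass;
  `normalize = TRUE` rescales rows to sum 1 for ratio work. When the
  quadratic form is numerically rank-deficient (collinear cell types, or
  fewer probes than cell types during leave-one-out rescoring) a ridge of
  `qpTolerance` (default $10^{-9}$, scaled by the diagonal) restores
  positive definiteness; genuine collinearity additionally raises a
  warning.
* **RPC** (`deconvolveRPC()`): Huber M-estimation regression
  (`MASS::rlm`, tuning constant $k = 1.345$, the standard 95%-efficiency
  choice) of the sample on the signature columns, negative coefficients
  truncated to zero, rows renormalized. When a fit is numerically perfect
  the M-estimator has no residual scale to work with, and the ordinary
  least-squares solution (which it would reproduce) is returned directly.
* **nu-SVR** (`deconvolveSVR()`): a linear-kernel support-vector
  regression in the CIBERSORT style: signature and sample are z-scored
  over the library probes, each $\nu \in \{0.25, 0.5, 0.75\}$ is fitted
  and the one with the lowest reconstruction RMSE kept, then truncation
  and renormalization as for RPC. No permutation p-values or quantile
  normalization — the back-end serves as a comparator.

Probes missing in a sample are dropped for that sample only
(pairwise-complete), mirroring the behaviour of the reference pipelines.
The unconstrained back-ends are only identified up to scale, so they always
renormalize; CP/QP reports raw fractions by default because whether
published constrained-projection estimates were renormalized before
accuracy statistics is ambiguous — both forms are exposed.

## IDOL

`idolOptimize()` searches the candidate pool for a probe subset of fixed
size that minimizes deconvolution error on training mixtures with known
composition (simulated here; flow-sorted truth enters through the same
interface). Every candidate starts with selection weight 1; each iteration

1. samples `size` candidates without replacement with probability
   proportional to the weights,
2. scores the sampled library: CP/QP estimates for the training mixtures,
   then per-cell-type $R^2$ (squared Pearson correlation) and RMSE, with
   mean RMSE across cell types as the primary objective and mean $R^2$ as
   tie-break,
3. computes leave-one-out contributions
   $\Delta_j = \mathrm{RMSE}(\mathcal{L}) -
   \mathrm{RMSE}(\mathcal{L}\setminus\{j\})$ for every sampled probe, and
4. updates weights multiplicatively: helpful probes ($\Delta_j < 0$)
   $\times\, 1.2$ capped at 1, harmful probes ($\Delta_j > 0$)
   $\times\, 0.8$ floored at 0.05, so no candidate is ever excluded
   outright.

The published description of this search states the qualitative rule —
selection probabilities rise for probes that help and fall for probes that
hurt — but not a formula; the bounded multiplicative update above is this
package's concrete choice, kept deliberately simple, exposed through
`idolConfig()` and isolated in `updateWeights()` so an alternative rule is
a one-function replacement. Convergence is operationalized as a fixed
budget (500 iterations by default) with best-so-far tracking rather than a
stopping criterion; the best library is totally ordered by (mean RMSE,
−mean $R^2$, lexicographic probe set) so ties cannot make a run
irreproducible. `idolSizeSweep()` re-runs the search independently per
library size (50–800 by 50 by default) and chooses the smallest size whose
best mean RMSE is within `plateauTolerance` (0.1 percentage points) of the
overall minimum — accuracy plateaus once the informative probes are
covered, and smaller libraries are preferred on the plateau.
`restrictToProbes()` filters the pool to a platform whitelist before
optimization, which is how a legacy-array-compatible library is obtained.

## Evaluation statistics

`performanceStats()` reports per-cell-type $R^2$ and RMSE; $R^2$ is the
squared Pearson correlation of estimated versus true fractions (the
regression-through-scatter usage), with $1 - SS_{res}/SS_{tot}$ available
as an option. RMSE, error tables, Bland–Altman mean differences and limits
of agreement (`blandAltman()`, mean $\pm 1.96\,SD$) are reported in
percentage points, the scale on which such results are customarily quoted.
`pairedT()` tests estimates against truth per cell type or globally;
zero-variance differences with non-zero mean are an exact bias and are
reported as a flagged infinite-$t$ result rather than an error.
`bartlettAcrossMethods()` (variance homogeneity of error distributions)
and `libraryContextChisq()` (omnibus Pearson chi-squared on
libraries-by-annotation-category counts, no continuity correction) wrap
the base-R tests; `cellRatios()` computes the clinically interpreted
lineage ratios NLR $= \mathrm{Neu}/(\mathrm{Bcell} + \mathrm{CD4T} +
\mathrm{CD8T} + \mathrm{NK})$, CD4T/CD8T, (CD8T+Mono)/NK and CD8T/Bcell,
flagging zero denominators as missing instead of returning infinities.

# The synthetic-data generator

`simulateReference()` emulates a sorted-reference experiment: latent
per-cell-type mean methylomes in which background probes share one mean per
probe drawn from a bimodal beta mixture (half $\mathrm{Beta}(2,10)$, half
$\mathrm{Beta}(10,2)$ — the mostly-unmethylated / mostly-methylated modes
of real methylomes), and planted DMRs where the focal cell type's mean is
offset by exactly `delta` (default 0.5 on the beta scale, the magnitude of
strong leukocyte lineage markers) in the stated direction. Replicate
betas are $\mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ draws around the latent
mean: beta-distributed noise keeps support in $[0,1]$ by construction,
with precision $\phi = 200$ by default (a per-probe SD of about 0.035 at
$\mu = 0.5$, in the range of array technical noise for purified
populations). The default design is six replicates per cell type with
`replicates = c(CD4T = 7)` available to mirror a typical reference
experiment.

`dirichletDesign()` draws known mixing proportions from a six-component
Dirichlet: design A symmetric (near-equal fractions, `alphaScale = 50`),
design B centred on a blood-realistic mean profile (Neu 0.55, CD4T 0.16,
CD8T 0.09, Mono 0.09, NK 0.06, Bcell 0.05 — a package decision
approximating adult peripheral blood, configurable). Both designs share
total concentration $K \cdot alphaScale$ so their dispersions are
comparable. Two sets of six reproduce the canonical twelve-mixture
training design. `simulateMixtures()` mixes *latent means*, not noisy
replicates — pooling DNA averages true methylation states, and measurement
noise happens once, at array readout — then adds beta-precision noise;
$\phi = \infty$ yields exact convex combinations for oracle tests.

What the generator does **not** emulate: probe-type (Type I/II) chemistry
differences, batch and slide effects, SNP-contaminated probes, cell-purity
imperfections, or nucleated red blood cells. Passing recovery tests on
these simulations therefore demonstrates correctness of the estimation
machinery under the stated mixing model, not robustness to real-array
artefacts — inputs are expected to be comparably preprocessed
(background-corrected/normalized) before they reach this package, and
reference and target must come through the same preprocessing.

# Numerical choices and degenerate inputs

* Out-of-range betas are rejected with the offending probe and sample
  named, never clamped: silent clamping hides upstream normalization bugs.
* Zero pooled variance with zero mean difference gives $t = 0$; with a
  non-zero difference it gives a signed infinity, which ranks the probe
  above all finite statistics (a perfect separator).
* Probes absent in half a cell type's replicates are dropped from
  selection; signature means use pairwise-complete values.
* The QP ridge, the perfect-fit OLS fallback in RPC, and the flagged
  infinite-$t$ paired test are described above; Bartlett refuses
  zero-variance groups, and ratio denominators of zero yield `NA`.

# Problem sizes used in the tests

The shipped test- and acceptance-suites run the full loop at desk scale:
references of 250–5000 probes, planted-DMR libraries up to 1200 probes,
twelve training mixtures, exhaustive search over all $\binom{12}{6} = 924$
subsets of a 12-candidate pool as the IDOL oracle, 10-seed comparisons of
IDOL against automatic selection on 60-candidate decoy-laden pools, and
100-table random checks of every statistic against direct textbook
formulas. These sizes were chosen so the whole suite exercises every code
path in minutes; the algorithms themselves are the same at array scale,
where a full 500-iteration sweep over sizes 50–800 is an overnight batch
job and is driven through the same functions (or the command-line script
in `inst/scripts/methylIDOL-cli.R`).

# Known limitations

* The weight-update constants (1.2 / 0.8 / 0.05) are documented defaults,
  not published values; conclusions about IDOL's *relative* advantage are
  insensitive to them in our tests, but absolute convergence speed is not.
* $R^2$ as squared correlation is blind to calibration (a biased but
  correlated estimator scores 1); RMSE and the paired tests carry the
  calibration information, which is why the optimizer ranks on RMSE.
* nu-SVR coefficients are taken from the z-scored problem, as in the
  CIBERSORT lineage; they are relative weights and only meaningful after
  renormalization.
* With fewer probes than cell types the CP/QP solution is
  ridge-regularized and not unique in the null space; leave-one-out scores
  remain well-defined, but such libraries should not be used for real
  estimation.
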