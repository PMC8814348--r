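---
title: "Evaluating hospital environments for infection risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating hospital environments for infection risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nimcdm)
```

`nimcdm` chains three expert-elicitation methods into one evaluation
pipeline: exploratory factor analysis (EFA) to build a hierarchical criterion
framework, DEMATEL with an ANP limit supermatrix (DANP) to weight criteria
that influence one another, and TOPSIS to rank alternative buildings. This
vignette explains the model behind each stage, the tunable parameters and
their defaults, what the synthetic-data generators do and do not emulate, and
the numerical choices made where the methods literature leaves options open.

## 1. Framework construction by EFA

**Model.** Respondents rate candidate design criteria on a 1–5 Likert scale.
Assuming m latent common factors drive the responses, the item correlation
matrix **R** (Pearson, complete cases) is decomposed into eigenvalues
λ₁ > … > λₚ and eigenvectors β, loadings a_ik = √λ_k · β_ik. Components with
λ > 1 are retained (Kaiser criterion, strict inequality — an identity
correlation matrix retains nothing and errors). With two or more retained
components, varimax rotation with Kaiser row normalization is applied; each
item is then assigned to the factor holding its maximum absolute rotated
loading, and items whose maximum absolute loading is below 0.6 are deleted.
Reliability is reported as Cronbach's α (overall and per dimension), the
overall KMO sampling adequacy from anti-image partial correlations, and the
cumulative explained variance 100·Σλ_retained / p.

**Parameters.** `eigen_threshold = 1` (dimensionless; raising it extracts
fewer, stronger factors), `cutoff = 0.6` on absolute loadings (the
conventional "strong loading" bar for short expert questionnaires). Missing
responses are handled by listwise deletion, the classical EFA default, which
keeps **R** a genuine correlation matrix at the cost of discarding partial
respondents; with the panel sizes involved here (about 100 respondents, a
few percent missingness) the loss is small.

**Numerical choices.** Extraction is by principal components of the
correlation matrix (not principal-axis factoring), matching the way short
criterion questionnaires are usually condensed. Varimax uses
`stats::varimax` with `eps = 1e-8`. Because eigenvectors are sign-arbitrary,
every loading column is flipped so its largest-magnitude entry is positive,
making results deterministic across eigen-solvers. Assignment ties at equal
absolute loading resolve to the first factor; the assignment is idempotent
and invariant to factor relabeling (checked by test).

## 2. Influence weighting by DEMATEL and the DANP supermatrix

**Direct influence and consensus.** H experts each fill an n × n matrix E
with integer scores 0–4 (0 = no influence, 4 = very high), zero diagonal;
nonzero diagonals in input files are zeroed with a warning rather than
rejected, since a self-influence entry is always a recording artifact on
this scale. The elementwise mean is **A**. Consensus is the average gap
ratio: the mean over off-diagonal cells of |a_ij(H) − a_ij(H−1)| / a_ij(H),
in percent, where a(H) and a(H−1) are the cumulative means with and without
the final expert. Cells whose full-panel mean is zero admit no relative gap;
they are skipped and counted in the report instead of being treated as 0/0.
Below 5% the panel is declared stable; the pipeline halts otherwise, since
weights from a non-consensual panel are not interpretable.

**Total influence.** **A** is scaled by b = min(1/max row sum, 1/max column
sum), making every row and column sum of **D** = b·**A** at most 1. The
total influence **T** = **D** + **D**² + … = **D**(**I** − **D**)⁻¹ exists
when the spectral radius of **D** is below 1; the package checks this
explicitly and raises a non-convergence error for degenerate (permutation-
like) surveys rather than returning a misleading inverse. Row sums o and
column sums r give each criterion's INRM coordinates: prominence o + r and
relation o − r (net dispatcher above zero, net receiver below). These axes
are the standard DEMATEL convention. INRM edges are those t_ij strictly
above a threshold, by default the mean off-diagonal t_ij — a simple,
scale-free rule that typically keeps the strongest third of arrows;
it is configurable because no canonical rule exists.

**Supermatrix and weights.** **T** is normalized within each
(row-dimension, column-dimension) block by block row sums; the unweighted
supermatrix W^α is its transpose, so each column distributes one unit of
weight. With several dimensions, the dimension-level influence matrix (block
means of **T**) is row-normalized and block (i, j) of W^α is multiplied by
the normalized influence of dimension j on i — the orientation is pinned by
requiring the weighted supermatrix to stay column-stochastic, which the
printed formulations of the method leave ambiguous. The limit of W^z is
computed by repeated squaring to max-norm tolerance 1e-9 (deterministic and
fast: z doubles each step). Two degenerate cases are handled explicitly
rather than silently: a period-2 cycle (e.g. a permutation supermatrix) is
detected by comparing the converged power with one further multiplication
and resolved by the Cesàro average of the two accumulation points; a
reducible supermatrix whose limit columns disagree is flagged and the column
average used. Global weights sum to 1; dimension-local weights are member
sums; criterion-local weights are global weights rescaled within each
dimension.

**Per-dimension versus pooled.** The pipeline default runs DEMATEL/DANP
independently within each dimension (two 4 × 4 analyses for the bundled
framework), because EFA with orthogonal rotation constructs dimensions to be
mutually independent — cross-dimension influence is undefined in that model,
and the case-study weights indeed sum to 1 within each dimension. A pooled
mode (one n × n analysis across all criteria, with dimension weighting) is
available via `mode = "pooled"` for frameworks where cross-dimension
influence is meaningful.

## 3. Ranking by TOPSIS

Expert 0–10 score tables are averaged elementwise (arithmetic mean — the
least-assumption aggregator for interchangeable experts) into the decision
matrix X. Each criterion column is divided by its Euclidean norm, multiplied
by its weight, and the positive/negative ideals are the per-criterion
extrema over alternatives — maximum/minimum for benefit criteria, reversed
for cost criteria. All bundled criteria are benefit attributes (a higher
expert score means better infection-risk performance), so the cost set is
empty by default but supported. Relative proximity is R = d⁻/(d⁺ + d⁻) with
Euclidean separations; alternatives are ranked by decreasing R with ties
broken by input order (stable). If every alternative is identical, d⁺ = d⁻ =
0; R is then defined as 0.5 and flagged degenerate instead of raising, so
batch runs over pathological synthetic inputs survive. Reports print 3
decimals; JSON output keeps full precision.

## 4. What the synthetic generators emulate

The generators reproduce the *shape* of the elicitation, with known ground
truth:

- `gen_likert_panel()`: latent factor scores × planted loading pattern +
  Gaussian noise, standardized per item and discretized at fixed symmetric
  thresholds z = −1.5, −0.5, 0.5, 1.5 into the five categories, then masked
  missing at a fixed rate. The fixed thresholds make the mapping reproducible
  and symmetric; they imply roughly 7/24/38/24/7% category frequencies under
  the latent normal.
- `gen_influence_survey()`: each expert equals the ground-truth 0–4 matrix
  except that any off-diagonal cell independently deviates by ±1 with
  probability `disagreement`, clamped to the scale — the simplest
  integer-preserving noise model.
- `gen_performance_scores()`: ground-truth qualities in [0, 10] plus
  Gaussian noise, clamped.

Default study conditions (`default_simulation_specs()`) mirror the scale of
a realistic elicitation: 103 Likert respondents over 8 items with two
planted factors (salient loadings 0.8, noise sd 0.5, 2% missingness), 34
influence experts per dimension with 2% cell disagreement, and 15 scoring
experts with noise sd 1 over three alternatives.

What they do **not** emulate: acquiescence and halo biases, ordinal
response styles, correlated expert errors (shared schools of thought),
respondent covariates, and non-normal latent traits. Passing
parameter-recovery tests therefore demonstrates that the estimation
machinery is correct, not that real expert panels satisfy these assumptions.

## 5. Verification strategy and problem sizes

Every stage is tested against an independent oracle rather than against
itself: Pearson correlations against explicit pairwise sums; Cronbach's α
against the direct variance formula; **T** = **D**(**I** − **D**)⁻¹ against
the truncated power series Σ_{q≤200} **D**^q on 100 random 8 × 8 surveys
(agreement within 1e-8); limit weights against plain power iteration (within
1e-6); TOPSIS against hand-solved dominant/degenerate cases and the bundled
published table (all six proximities within the 0.005 print-rounding
tolerance). Recovery properties use 100 seeds at n = 500 respondents for the
EFA stage and H = 34 experts for consensus — sizes chosen to make the
statistical guarantees (≥ 95% recovery) sharp while keeping the whole suite
around a few seconds.

## 6. Known limitations

- Dimensions produced by orthogonal EFA cannot exhibit cross-dimension
  influence; the per-dimension default inherits that assumption.
- TOPSIS aggregates additively; strongly interacting criteria would call
  for a non-additive (e.g. fuzzy-integral) evaluator.
- The consensus gap ratio depends on expert ordering (it compares the panel
  with and without the final expert); it is a stability heuristic, not an
  exchangeable-agreement statistic.
- Published reliability statistics of a specific survey (α, KMO, explained
  variance) cannot be recomputed without the raw panel; the package instead
  verifies its reliability computations on synthetic panels with known
  structure.
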