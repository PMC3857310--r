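---
title: "Methods: divergence analysis of duplicated gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence analysis of duplicated gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paradiverge)
```

This vignette records the modelling choices behind `paradiverge`: what the
two pipelines assume, which tunable parameters matter and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and the numerical decisions a maintainer would otherwise have to
reverse-engineer from the code.

## Inputs and coordinate conventions

The package analyses an *aligned* amino-acid FASTA (gap `-`, ambiguity
`X`) together with a binary Newick topology per cluster. Alignments and
topologies are inputs, never computed here: alignment software and tree
inference both involve modelling decisions that belong upstream.

Site coordinates are 1-based and reported relative to a chosen reference
sequence (for gene families with a well-studied human member, that
member): reference-residue columns get consecutive integers starting at 1,
and columns where the reference itself is gapped get insertion labels
`"<previous site>+<offset>"` (`"0+1"` before the first residue). Keeping
insertion columns — rather than dropping them — means hydropathy-profile
columns and divergence sites stay aligned across all modules. How such
columns should be labelled is genuinely open (tools differ and rarely
document it); the previous+offset scheme is this package's convention.

Polytomies are rejected rather than auto-resolved because per-site
parsimony counts depend on the topology: a silent arbitrary resolution
would change downstream θ estimates invisibly. Lowercase residues are
uppercased on load since public database translations mix cases.

## Hydropathy profiles

Residues map to Kyte–Doolittle hydropathy values and are normalized
linearly onto [0, 1]. Normalization uses the scale's *fixed* global range
[−4.5, 4.5] (arginine to isoleucine), not the per-dataset min/max, for two
reasons: it makes 0.5 the neutral-hydropathy midpoint — consistent with the
convention that gap and ambiguous positions take exactly 0.5 — and it makes
profiles comparable across datasets. Per-dataset rescaling is available
behind `build_profiles(rescale = "data")` but is not the default. No
sliding-window smoothing is applied; the representation is strictly
per-site.

## Hierarchical clustering and the inconsistency cut

Profiles are compared under four pairwise distances (cityblock,
correlation, cosine, euclidean) and clustered by unweighted average
linkage. Two diagnostics drive interpretation:

* **Cophenetic correlation** between original and dendrogram-implied
  distances; values above ~0.95 indicate the tree is a faithful summary.
* **Inconsistency coefficient** per link, `Y = (h − mean(S)) / sd(S)`,
  where the comparison set S holds the link's height plus the heights of
  non-leaf links up to `depth − 1` levels below it, and `sd` is the sample
  (n−1) standard deviation. Depth 2 (a link and its immediate child links)
  is the default. The sample-sd convention matters: it is what makes the
  supremum over two-height comparison sets exactly 1/√2 ≈ 0.707, the
  baseline against which the cutoff is chosen. The default cutoff 0.8 sits
  deliberately just above that baseline: chain-like links can never be
  split, only links standing well above *both* of their child links can.

A cluster is a maximal subtree all of whose links satisfy `Y ≤ cutoff`
(leaves stranded under inconsistent links become singletons), with labels
numbered by first leaf appearance. This cut rule has a property worth
stating plainly: whenever a link joins two child links of much lower,
similar heights, `Y → 2/√3 ≈ 1.15 > 0.8`, so large homogeneous groups that
agglomerate in a balanced way are split into small fragments even when the
group structure is obvious to the eye. Only subtrees whose links each have
at most one link child — including any group of ≤ 3 members — are immune
(their comparison sets hold ≤ 2 heights, so `Y ≤ 0.707`). This is a
property of the statistic, not a defect of the implementation (the
partition and coefficients were verified against an independent reference
implementation of the same MATLAB-convention statistic), and it is why
analyses at this cutoff typically report broad clusters *plus* split-off
singletons. The package's partition-recovery tests therefore use 3-member
groups, where exact recovery is well-defined; with larger groups the cut
refines the true partition rather than reproducing it, and the discriminant
stage is the appropriate arbiter of group membership.

Degenerate profiles (zero variance under correlation, zero norm under
cosine — e.g. all-gap fragments) get distance 1 to everything with a
warning rather than aborting the run.

## Stepwise discriminant validation

Cluster assignments are validated by linear discriminant analysis with
stepwise variable selection under the Mahalanobis criterion: at each step
the candidate column maximizing the *smallest* pairwise Mahalanobis D²
between group means enters, provided its partial F-to-enter exceeds
`f_enter`; after each entry any variable whose F-to-remove drops below
`f_remove` leaves. The partial F is the classical increment form for the
closest pair's Hotelling T²,

    F = (n − g − p) · (T²_{p+1} − T²_p) / (n − g + T²_p),
    T² = n_i n_j / (n_i + n_j) · D²,

with p the number of variables already entered. Commercial stepwise
implementations differ in un-documented details of this statistic;
the form above is documented here and in the code, and correctness is
established through properties (affine invariance of D², agreement of the
classification stage with a textbook LDA implementation, chance-level
accuracy under label permutation) rather than bit-matching any particular
program. Thresholds default to 3.84 / 2.71, the conventional defaults.

Classification uses Fisher's linear functions with the pooled within-group
covariance and by-size priors (`s_k(x) = μ_kᵀΣ⁻¹x − ½μ_kᵀΣ⁻¹μ_k + ln
π_k`); posteriors are the softmax of the scores; argmax ties break by
group order. Leave-one-out cross-validation keeps the variable set fixed
from the full fit (re-selection per fold is available via
`refit_selection = TRUE` but is off by default, matching the convention of
reporting "cross-validated grouped cases" for the selected model);
means, covariance and priors are re-estimated per fold. When no variable
passes entry — the correct outcome for unseparated groups —
`fit_stepwise()` raises an empty-model error, and `cross_validate_loo()`
falls back to a priors-only classifier so a chance-level accuracy is still
reported. One pathology deserves a note: with *exactly equal* group sizes
the leave-one-out majority classifier is always wrong (deleting a case
makes its own group the smaller one), so chance-level benchmarks should
use unequal sizes.

## The functional-divergence model

Per-site minimum substitution counts come from Fitch parsimony on each
cluster's subtree, with `-`/`X` treated as wildcards that never force a
change. The two clusters' counts are modelled as a two-state mixture:

* **F₀** (probability 1 − θ): one rate `r ~ Gamma(α, α)` shared by both
  clusters, counts `X_c | r ~ Poisson(d_c r)` — marginally a bivariate
  negative binomial with common gamma frailty, rates perfectly correlated.
* **F₁** (probability θ): the two rates drawn independently from the same
  gamma — a product of two univariate negative binomials.

θ = 1 − r_λ is then exactly the complement of the between-cluster rate
correlation. The phrase "hidden Markov model" sometimes attached to the
site-posterior machinery in this literature is implemented here as an
independent two-state mixture — there is no chain along sites; nothing in
the likelihood couples neighbouring columns, and treating sites as
exchangeable is the standard assumption of the rate-correlation framework.

All four parameters (θ, α, d₁, d₂) are estimated jointly by ML: θ
box-constrained to [0, 1] (L-BFGS-B, three starting values of θ), α and
the depths on the log scale, depths initialized at the per-cluster mean
counts. The null (θ = 0) is fitted by Nelder-Mead and polished from the
alternative's nuisance parameters so δ = 2(log L₁ − log L₀) can never
reflect a worse null optimum; a numerically boundary θ̂ collapses to the
null exactly, giving δ = 0 and all-zero posteriors. δ is referred to χ²₁
at 0.05. Because θ = 0 is on the boundary, that reference is conservative
(the null simulations in the test suite reject well below 5%); the
boundary-corrected ½χ²₀ + ½χ²₁ p-value is reported alongside. The standard
error of θ̂ comes from the observed information (numerical Hessian at the
optimum), with a profile-curvature fallback when the Hessian is
near-singular; on the boundary the SE is reported as `NA` and flagged.

Site posteriors are `p_i = θP₁ / ((1−θ)P₀ + θP₁)`; the "baseline
posterior" — the value shared by the majority of sites — is operationalized
as the posterior of the modal count pattern. A posterior cutoff of 0.7 for
flagging candidate divergent sites is equivalent to a posterior-odds
cutoff of 7/3 ≈ 2.33. For efficiency the likelihood is evaluated over
unique count patterns with multiplicities, which is exact and makes θ̂
literally invariant to site permutation.

Multi-cluster studies run all pairwise comparisons
(`pairwise_divergence()`), as divergence tables are conventionally
reported.

## Synthetic generators and what the tests mean

Three generators produce data with exactly the structure the models
assume, each a pure function of its arguments including the seed:

* `simulate_count_pairs()` — the gamma–Poisson two-state scheme itself.
* `simulate_cluster_alignment()` — a root sequence shared by both clusters
  (they are paralogs) evolved down each topology under an
  equal-exchangeability Poisson substitution process with per-site rates
  from the F₀/F₁ scheme; no indels (gap handling is exercised by fixtures
  with hand-placed gaps). A substitution event redraws the residue from
  the equilibrium frequencies.
* `simulate_profile_groups()` — informative columns carry per-column
  random permutations of `g` equally spaced group levels spanning
  `separation` around 0.5; Gaussian noise `spread` is added and values
  clipped to [0, 1]. Every group pair then differs on every informative
  column (by at least `separation/(g−1)`), which keeps all four distance
  metrics — including the shape-based correlation and cosine — sensitive
  to the same structure.

Passing tests on these generators show that the estimators recover the
parameters of *their own* generating model and that the pipeline stages
compose correctly. They do not show robustness to what real alignments
add: among-site compositional heterogeneity, indels and alignment error,
substitution-matrix structure (the simulator is equal-exchangeability, not
JTT/Dayhoff-like), shared phylogenetic correlation between the clusters'
depths, or parsimony undercounting on deep trees — the last visibly
biases θ̂ downward in the README's worked example. Table-style values from
any particular empirical study additionally depend on that study's exact
sequence sets and software internals, and are reproducible only to within
those tolerances.

Problem sizes in the test suite and acceptance script were chosen as
typical desk-scale study conditions: 500–1000 sites per fit, 50 replicates
per condition for recovery error and test size, profile groups of 3×3 (for
partition recovery) and 3×20 (for discriminant accuracy) over 50–60
columns.

## Known limitations

* Type-II divergence (shifted amino-acid property states at conserved
  rates) is out of scope, as are codon-level selection tests and ancestral
  sequence reconstruction (reconstructed ancestors are accepted as plain
  input sequences for classification).
* Fitch counts are minimum counts; no correction for multiple hits is
  applied, so depths d and θ are underestimated on deep trees.
* α is assumed shared between clusters and states within one pairwise
  comparison; per-cluster shapes are not modelled.
* The stepwise F statistic follows the documented closest-pair increment
  convention; other stepwise implementations may select slightly different
  variable sets on marginal data.
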