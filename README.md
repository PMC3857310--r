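# paradiverge

Divergence analysis for paralogous gene clusters created by gene or whole
genome duplication — for molecular evolutionists who want to ask, of a pair
of duplicate gene clusters (say a fish-specific duplicate pair and the
single-copy gene of lobe-finned vertebrates), two questions:

1. **Functional divergence** — have site-specific evolutionary rates shifted
   between the clusters (type-I functional divergence: a site constrained in
   one copy but free to vary in the other)?
2. **Structural divergence** — do the encoded proteins fall into distinct
   structural groups when represented by their hydropathy profiles, and do
   held-out sequences (for example reconstructed ancestors) classify into
   those groups?

## The models

**Functional divergence.** For each alignment column, the minimum number of
amino-acid substitutions on each cluster's subtree is obtained by Fitch
parsimony, giving count pairs (X₁ᵢ, X₂ᵢ). Site rates r are
Gamma(α, α)-distributed (mean 1). With probability 1 − θ a site keeps one
shared rate in both clusters (state F₀, rates perfectly correlated); with
probability θ its rates are drawn independently (state F₁). Counts are
Poisson(d·r) with cluster depths d₁, d₂. Marginally,

    P₀(x₁, x₂) = Γ(α+x₁+x₂)/(Γ(α)·x₁!·x₂!) · (α/s)^α (d₁/s)^{x₁} (d₂/s)^{x₂},   s = α+d₁+d₂
    P₁(x₁, x₂) = NB(x₁; α, d₁) · NB(x₂; α, d₂)

and the log-likelihood Σᵢ log[(1−θ)P₀ + θP₁] is maximized over (θ, α, d₁,
d₂). θ = 1 − r_λ is the complement of the between-cluster rate correlation:
θ = 0 means fully correlated rates (no functional divergence). The LRT
statistic δ = 2(log L₁ − log L₀), with L₀ the θ = 0 fit, is referred to
χ²₁ at 0.05 (conservative at the θ = 0 boundary; a boundary-corrected
p-value is also reported). Per-site posteriors P(F₁ | Xᵢ) and posterior
odds pᵢ/(1−pᵢ) flag candidate divergent sites — posterior 0.7 corresponds
to odds 7/3 ≈ 2.33.

**Structural divergence.** Sequences are mapped to Kyte–Doolittle
hydropathy profiles normalized linearly from the scale range [−4.5, 4.5]
onto [0, 1], with alignment gaps and ambiguous residues fixed at the
neutral midpoint 0.5. Profiles are clustered by average linkage under four
pairwise distances (cityblock, correlation, cosine, euclidean); tree
faithfulness is checked by the cophenetic correlation coefficient, and
clusters are cut where the inconsistency coefficient (depth 2) exceeds 0.8
— a threshold chosen above the 1/√2 ≈ 0.707 supremum attainable by a
two-height comparison set. Cluster assignments are then validated by
stepwise linear discriminant analysis: variables enter to maximize the
smallest pairwise Mahalanobis D² between group means (entry F ≥ 3.84,
removal F < 2.71), priors follow group sizes, and performance is reported
as the percentage of original and of leave-one-out cross-validated cases
correctly classified.

Synthetic generators (`simulate_count_pairs`, `simulate_cluster_alignment`,
`simulate_profile_groups`) produce data with exactly the structure these
models assume, so the whole pipeline is testable end to end without any
sequence downloads.

## Worked example

```r
library(paradiverge)

# --- functional divergence on simulated paralog clusters -------------------
tr1 <- ape::read.tree(text = paste0(
  "(((a1:0.4,a2:0.4):0.2,(a3:0.4,a4:0.4):0.2):0.2,",
  "((a5:0.4,a6:0.4):0.2,(a7:0.4,a8:0.4):0.2):0.2);"))
tr2 <- tr1; tr2$tip.label <- sub("a", "b", tr1$tip.label)

sim <- simulate_cluster_alignment(tr1, tr2, n_columns = 400,
                                  theta = 0.6, alpha = 0.5, seed = 42)
x1 <- site_substitution_counts(tr1, sim$alignment, sim$members1)
x2 <- site_substitution_counts(tr2, sim$alignment, sim$members2)
fit <- fit_type1_divergence(x1, x2)
fit
#> Type-I functional divergence fit (400 sites)
#>   theta = 0.447 (SE 0.063)   alpha = 1.063
#>   d1 = 2.242   d2 = 2.249
#>   delta (LRT) = 83.216, p = 7.357e-20 (boundary-corrected 3.679e-20) *
#>   baseline posterior = 0.296
```

θ̂ = 0.447 says roughly 45% of sites are estimated to have uncorrelated
rates between the clusters (the parsimony counts undercount multiple hits
on these fairly deep 8-leaf trees, so θ̂ sits below the generating 0.6);
δ = 83.2 far exceeds the χ²₁ 5% critical value 3.84, so rate correlation
between the clusters is decisively rejected. Candidate divergent sites:

```r
prof <- site_posterior_profile(fit, cutoff_posterior = 0.7)
sum(prof$above_cutoff)
#> [1] 62
```

```r
# --- structural divergence on simulated profile groups ---------------------
pro <- simulate_profile_groups(c(3, 3, 3), 60, separation = 0.6,
                               spread = 0.05, seed = 42)
cluster_profiles(pro$profiles)
#> cityblock   cophenetic r = 0.9759, 3 cluster(s)
#> correlation cophenetic r = 0.9942, 3 cluster(s)
#> cosine      cophenetic r = 0.9679, 3 cluster(s)
#> euclidean   cophenetic r = 0.9823, 3 cluster(s)

big <- simulate_profile_groups(c(20, 20, 20), 50, separation = 0.6,
                               spread = 0.05, seed = 42)
cross_validate_loo(big$profiles, big$labels)
#> Original grouped cases correct: 100.0%
#> Cross-validated (LOO) correct:  100.0%
```

All four distance metrics agree on the three simulated groups, every
dendrogram is a faithful representation of its distances (cophenetic
r > 0.95), and the discriminant validation classifies 100% of cases both
with and without leave-one-out.

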