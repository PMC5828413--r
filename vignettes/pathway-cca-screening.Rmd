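---
title: "Pathway-level coexpression screening by canonical correlation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level coexpression screening by canonical correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcca)
```

## Why set-level coexpression

A coexpression network thresholded on pairwise Pearson correlation can
only see pathways whose individual genes track individual disease genes.
A pathway that responds *as a unit* — many genes each contributing a weak,
coherent signal — is invisible to it. Canonical correlation analysis (CCA)
closes that gap: it finds the linear combination of pathway-gene
expression profiles maximally correlated with a linear combination of
disease-gene profiles, so the screen's unit of inference is the gene set,
not the gene pair. `pathcca` implements this screen together with the
single-gene network baseline it is meant to be compared against.

## The model and its assumptions

Let **M** be the experiments × p matrix of disease-gene profiles and
**N** the experiments × q matrix of one pathway's profiles, both column
z-scored (sample, n−1, denominator throughout). With within-set
correlation matrices R₁₁, R₂₂ and cross-correlation R₁₂, the canonical
pairs are obtained from the singular value decomposition of the whitened
cross-correlation

$$K = R_{11}^{-1/2}\, R_{12}\, R_{22}^{-1/2}, \qquad K = U D V^{\top},$$

with coefficients $A = R_{11}^{-1/2} U$, $B = R_{22}^{-1/2} V$ and
canonical correlations the singular values, clipped to [0, 1]. Variates
are rescaled to unit sample variance, so the structure loadings
$t(A)R_{11}$ and $t(B)R_{22}$ are exactly the correlations between each
variate and each standardised gene (a test enforces this identity to
1e−8).

Significance uses Bartlett's large-sample chi-square approximation to
Wilks' Λ. For pair k,
$\Lambda_k = \prod_{i \ge k} (1 - r_i^2)$,
$\chi^2_k = -(n - 1 - (p+q+1)/2)\,\ln\Lambda_k$ on $(p-k+1)(q-k+1)$
degrees of freedom. The approximation assumes n well above p + q (the
function warns otherwise) and approximate multivariate normality; on the
synthetic Gaussian compendia the suite verifies a 5% nominal level is held
within the binomial 99% envelope over replicate null simulations.

The coverage statistics are variance-extracted indices: the mean squared
structure loading of a set's genes on one canonical pair, `S_a` for the
pathway side and `S_b` for the disease side. Both lie in [0, 1]; a large
`r` with tiny `S_a` means a single pathway gene drives the correlation,
which is exactly the situation the screen is designed to discount.

### Which pair, and why the statistics are first-pair only

Summing squared loadings over *all* pairs of a full-rank decomposition
forces the statistic to 1 for every set, which carries no information.
`pathcca` therefore computes `r`, the p-value, `S_a` and `S_b` on the
first canonical pair; the `pair` argument of `screen_pathways()` and
`variance_extracted()` exposes other pairs for exploratory use. The
screen likewise thresholds only the first pair and records the rest.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r_min` | 0.5 | minimum first canonical correlation (unitless, [0,1]) |
| `p_max` | 0.001 | maximum Bartlett first-pair p-value |
| `sa_min`, `sb_min` | 0.15 | minimum variance extracted, pathway / disease side |
| `min_pathway_genes` | 10 | measured-gene floor (inclusive) for a pathway to enter |
| network `r_min` | 0.6 | Pearson edge threshold of the baseline network |
| network `mode` | `"signed"` | threshold on r (default) or on \|r\| |
| `ridge` | 0 | diagonal ridge before whitening, for n close to p |

The default threshold set is deliberately the loosest of the published
combinations so that borderline pathways surface and can be re-filtered
with the stricter `"methods"` preset (0.6 / 1e−5 / 0.3 / 0.15) or the
`"results"` preset (0.5 / 0.001 / 0.2 / 0.2); thresholds are mandatory,
inspectable configuration rather than hidden constants. The size filter
is inclusive (≥ 10 measured genes) because informative 10-gene pathways
exist and CCA with n in the thousands is comfortable at q = 10. The
network threshold is read as signed correlation — negative coexpression is
plausibly informative but is opt-in via `mode = "absolute"`.

Representative genes: a passing pathway reports
round-half-away-from-zero(n_genes × S_a) genes (at least one), ranked by
absolute first-pair canonical coefficient with ties broken by ascending
gene id. Coefficients — not loadings — are the default ranking because
the coefficient is what defines the variate; `representative_by =
"loadings"` switches to the correlation-based ranking. Scaling by the
pathway-side `S_a` (not `S_b`) is deliberate: it is the only choice under
which the rule reproduces all seven published worked-example counts, and
it reads naturally as "the fraction of the pathway the variate covers".

## The synthetic compendium

`generate_compendium()` draws, per experiment, a standard-normal shared
factor (or several, if `loading_strength` is a vector) plus one private
factor per unlinked pathway. A disease gene or linked-pathway gene is
`w·f_shared + ε`, an unlinked-pathway gene is `w·f_private + ε`, a
background gene is pure noise, with ε ~ N(0, σ²). Closed forms make the
planted signal checkable: two signal genes correlate at
ρ = w²/(w² + σ²) (`theoretical_gene_correlation()`), and two sets of p
and q signal genes have population first canonical correlation
w²/√((w² + σ²/p)(w² + σ²/q)) (`theoretical_canonical_correlation()`),
attained by the set means. Defaults w = 1, σ = 1 put per-gene correlation
at 0.5 — below a 0.6 network threshold, so set-level signal exists where
single-gene edges are borderline, which is the regime the screen is for —
and 100 background genes give the network stage realistic sparsity.

What the generator does *not* emulate: microarray normalisation
artifacts, batch effects, heavy-tailed or count-like expression,
overlapping pathways, and correlated noise across experiments. Passing
tests therefore demonstrate correctness of the machinery under a
Gaussian latent-factor model, not robustness to real-compendium
pathologies; on real data the Bartlett p-values in particular inherit the
normality assumption.

## Numerical choices

- **Whitening tolerance.** Eigenvalues below 1e−10 × the largest are
  discarded, so rank-deficient sets (duplicated or collinear genes) are
  whitened on their informative subspace; an optional ridge is exposed
  for compendia with n < p rather than silently regularising.
- **Sign convention.** The SVD leaves each pair's sign free. The
  first-set coefficient column is flipped so its largest-magnitude entry
  is positive and the paired second-set column flips with it, keeping
  cor(U_k, V_k) = +r_k and making outputs run-to-run deterministic.
- **Degenerate inputs.** Constant genes are an error in `zscore_columns()`
  and are dropped (with a warning and log entry) by the callers that own
  the data: silent zero-variance columns would corrupt correlation
  matrices. A pathway whose decomposition fails is recorded as a failed
  row, never an abort of the whole screen.
- **Ties.** Representative-gene ties on |coefficient| and hub-degree ties
  break by ascending gene id; components order by size then smallest
  member id; writers emit rows in deterministic order — identical inputs
  give byte-identical files, including the run log (which records
  parameters, seed, versions and exclusions, but no timestamps).
- **Multiple testing.** The screen thresholds raw p-values, matching the
  screen's definition; Benjamini–Hochberg q-values are reported as an
  extra column for the reader but never gate a record.

## Validation strategy and problem sizes

The suite validates each stage against an independent route: the first
canonical correlation against brute-force maximisation of corr(Ma, Nb)
over spherical angles (50 random instances, p, q ≤ 3, n ≤ 12, agreement
to 1e−6); Bartlett statistics against hand-evaluated closed forms;
hypergeometric p-values against exhaustive enumeration on universes of
≤ 12 genes; and the full screen against the generator's planted truth —
recovery of the population canonical correlation within ±0.05 at
n = 5000 with 10 + 10 genes, null calibration over 100–200 replicates at
n = 500 with 5 + 5 genes, and exact identification of a single linked
pathway among five at n = 2000. These sizes keep the whole suite under a
minute while leaving the asymptotic approximations comfortably valid.

## Known limitations

- CCA is unregularised; with q approaching n the leading canonical
  correlation is upward-biased and the screen's p-values optimistic. The
  ridge option mitigates but does not remove this; sparse/regularised CCA
  is out of scope.
- The screen assumes gene ids in the expression table, GMT and disease
  list already agree; no identifier mapping is attempted.
- Enrichment uses the union of measured pathway genes as the default
  background; with a biased compendium a user-supplied background is the
  better choice.
- Permutation p-values (an alternative to Bartlett's approximation for
  non-Gaussian data) are not implemented.
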