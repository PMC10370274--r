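---
title: "Joint analysis of multi-trait GWAS summary statistics with functional annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint analysis of multi-trait GWAS summary statistics with functional annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiograph)
```

## The problem

Genome-wide association studies report, for each SNP `t` and each phenotype
`i`, an association p-value `p_it`. Single-trait analyses leave power on the
table when phenotypes share genetic architecture (pleiotropy), and they say
nothing about *which* tissues or cell types the associated variants act
through. pleiograph addresses both at once: it jointly models the summary
statistics of `n` phenotypes, estimates a **phenotype graph** whose edges
denote genetic correlation, scores the relevance of binary **functional
annotations** per phenotype, and produces FDR-controlled association and
pleiotropy calls — all from one posterior.

## The model

P-values are transformed to z-scores `y_it = Φ⁻¹(1 − p_it)`. Each entry
carries a latent association indicator `e_it ∈ {0, 1}` with a two-component
emission:

* associated (`e_it = 1`): `y_it ~ LN(μ_i, σ_i²)` — associated SNPs have
  small p-values, hence positive z-scores, which the lognormal encodes
  through its positive support;
* null (`e_it = 0`): `y_it ~ N(0, 1)`.

Across phenotypes, the vector `e_t` follows an auto-logistic Markov random
field whose intercept is shifted by the SNP's annotations:

```
p(e_t | ·) ∝ exp{ Σ_i (α_i + Σ_m γ_im a_mt) e_i + Σ_{i<j} β_ij e_i e_j }
```

* `α_i` sets the baseline association propensity of phenotype `i`;
* `γ_im ≥ 0` is the boost a SNP gets for phenotype `i` when carrying
  annotation `m` — annotations can support, never penalize, association;
* `β_ij > 0` couples phenotypes `i` and `j` along the edges of a graph `G`
  that is itself estimated.

The normalizing constant is a sum over all `2^n` indicator vectors and
depends on `α`, `γ`, `β` and the annotation pattern, so it cannot be
ignored in their updates. pleiograph enumerates it exactly in log space,
once per *distinct annotation row pattern* (at most `2^M` and usually far
fewer), and refuses models with `n` above `n_max` (default 15) rather than
approximate silently.

Spike-and-slab priors drive both structure decisions:

* `β_ij ~ E(i,j) · Γ(a_β, b_β) + (1 − E(i,j)) · δ₀`, with edge indicators
  `E(i,j)` Bernoulli — uniform 0.5 by default, or 0.8/0.2 for pairs
  inside/outside a user-supplied prior graph;
* `γ_im ~ u_im · Γ(a_γ, b_γ) + (1 − u_im) · δ₀`, `u_im ~ Bern(p_u)`,
  `p_u ~ Beta(1, 1)`.

Remaining priors are weakly informative: `μ_i ~ N(0, 10⁴)`,
`α_i ~ N(0, 10⁴)`, `σ_i² ~ IG(0.5, 0.5)` (shape/rate). The slab shape/rate
(4, 2) keeps included coefficients away from zero, so inclusion is a
meaningful structural statement. All are exposed through `pleio_hyper()`.

## Inference

`pleio_fit()` runs a Metropolis-within-Gibbs sampler, one sweep being

1. `e` — exact Gibbs. Because SNPs are independent given the parameters,
   column `i` of `e` is resampled jointly over SNPs from its logistic full
   conditional (the normalizing constant cancels), sequentially over
   phenotypes.
2. `(μ_i, σ_i²)` — conjugate draws from the log-scale values of the
   currently associated SNPs (prior draws when a phenotype has none).
3. `α_i` — Gaussian random-walk Metropolis; the change in the summed log
   normalizing constant is recomputed exactly.
4. `(β_ij, E(i,j))` per pair — with probability ½ a log-scale random walk
   within the current model (only if the edge exists), otherwise a
   birth/death move. Births propose `β` from the slab, so the slab density
   cancels and acceptance depends only on the likelihood and the
   edge-prior odds; deaths are the reverse.
5. `(γ_im, u_im)` per phenotype–annotation pair — same scheme, with the
   Bernoulli(`p_u`) inclusion odds, and proposals confined to `γ > 0`.
6. `p_u` — conjugate Beta draw.

Step sizes adapt toward a 0.35 acceptance rate during burn-in only
(Robbins–Monro on the log scale, frozen afterwards so detailed balance
holds over the retained samples). A single seeded generator drives the
whole chain in the fixed order above, so a seed plus identical inputs
reproduces every output bit for bit.

Defaults are 10,000 sweeps, 5,000 burn-in, thinning 5. Posterior summaries
(edge probabilities, sign probabilities for β and γ, per-SNP marginal and
pairwise association probabilities, and thinned parameter traces) are
accumulated at the thinned post-burn-in sweeps; accumulating at every sweep
changes nothing statistically at these chain lengths and costs about a
third more time.

## Decisions and FDR control

* **Graph**: an edge is called when `p(E(i,j) | Y) > 0.5` *and*
  `p(β_ij > 0 | Y) > 0.95` (both strict; `decide_graph()`).
* **Annotations**: annotation `m` matters for phenotype `i` when
  `p(γ_im > 0 | Y) > 0.95` (`decide_annotations()`), where the
  probability is the post-burn-in fraction of samples with `γ_im > 0`
  (exclusion counts as not positive).
* **Association / pleiotropy**: `fdr_select()` ranks SNPs by posterior
  association probability and keeps the largest prefix whose mean
  local FDR (mean of one minus the probability) stays at or below the
  nominal level — the direct posterior probability approach. Pleiotropy
  uses the accumulated joint probability that all indicators in a set are
  one; all pairs are accumulated by default, larger sets on request via
  `pleio_control(joint_sets = )`.

## The simulator and what it does (not) emulate

`sim_scenario()` defaults to the study design used throughout the package's
calibration: six phenotypes, 200,000 SNPs, a five-edge graph (P1–P2, P1–P3,
P2–P3, P3–P4, P4–P5) with β = (4.0, 1.8, 2.3, 2.5, 5.0), intercepts
α = (−4.7, −3.0, −5.5, −4.8, −3.6, −2.5), five annotations each marking
exactly 10% of SNPs, γ = 1 linking annotation 1 to P1–P3 and γ = 2 linking
annotation 2 to P4–P6, μ = (1.05, 0.9, 1.0, 1.0, 1.05, 0.95) and
σ = (0.4, 0.3, 0.35, 0.3, 0.45, 0.4). Latent indicators are drawn by 1,000
single-site Gibbs sweeps from an all-zero start under the
annotation-modified kernel — the same kernel code the sampler uses, so
generator/model consistency is structural, and the stated γ values actually
shape the data. P6 is deliberately instructive: it shares annotation 2 with
P4 and P5 but has no graph edge, so a model that ignores annotations
misattributes the shared enrichment to spurious P4–P6/P5–P6 edges, which is
exactly what the package's acceptance checks look for.

The "10% of SNPs" is implemented as exactly `round(0.1 T)` ones per column
(not i.i.d. Bernoulli), making column sums deterministic and testable.

What the simulator does **not** emulate: linkage disequilibrium between
SNPs (the model assumes independence; `thin_snps()` is the practical
mitigation on real data), sample overlap between cohorts
(`decorrelate_zscores()` handles that at preprocessing time), effect
directionality, and minor-allele-frequency structure. Tests passing on
simulated data therefore certify the estimator under the model's own
assumptions, not robustness to LD misspecification.

## Numerical and design choices

* **p-value clipping**: to `[1e−300, 1 − 1e−16]` before the quantile
  transform, so `y` is finite even for p = 0 or 1; the transform is
  evaluated as `qnorm(p, lower.tail = FALSE)` to avoid cancellation.
* **Binarization** of annotation scores is strict (`score > cutoff`, cutoff
  0.5 by default).
* **Decorrelation** uses the symmetric eigendecomposition inverse square
  root of the sample correlation matrix; eigenvalues below 1e−10 raise a
  singularity error. The transform is applied on the standardized scale
  and the original column locations/scales are restored: correlation is
  invariant to per-column affine maps, so the output correlation is exactly
  the identity and the operation is idempotent, while coinciding with the
  plain `C^{−1/2} Y` map for (approximately standardized) z-score columns.
  The correlation matrix is estimated from all SNPs in the analysis set,
  and decorrelation is intended after missingness filtering and thinning,
  immediately before fitting.
* **Latent generation vs. fitting**: the simulator generates `e` under the
  annotation-modified kernel. The alternative — generating without the
  annotation terms while quoting nonzero γ — would make the γ values inert
  and the annotation-aware model unfalsifiable on its own data.
* **Degenerate inputs**: phenotypes whose z-scores are all ≤ 0 keep
  `e = 0` throughout (lognormal support); a fit with zero SNPs reduces to
  prior sampling (used by the test suite to verify the chain against prior
  moments); duplicated columns fail decorrelation with the offending
  eigenvalue reported.
* **Ties** in `fdr_select()` are broken by input order (stable sort).

## Problem sizes used in the packaged studies

The calibration studies shipped with the package (test suite and
`scripts/acceptance.R`) run the default scenario scaled to 20,000 SNPs with
10,000 sweeps (5,000 burn-in) for the annotation-aware fit, and 6,000
sweeps (3,000 burn-in) for the annotation-free and shuffled-annotation
comparison fits, whose posteriors are simpler (no γ block). At these sizes
the three fits take roughly ten minutes combined on one core. The full
200,000-SNP design behaves identically and scales linearly in T.

## Known limitations

* Exact enumeration restricts the phenotype count (`n_max` = 15 by
  default, 2^15 states); larger panels need approximate constants, which
  the package deliberately does not provide.
* The per-SNP independence assumption means dense LD regions should be
  thinned or clumped upstream.
* P-values carry no effect direction; protective vs. risk alleles are not
  distinguished.
* For phenotypes whose signal distribution overlaps the null heavily
  (small μ relative to σ), the soft labelling of borderline SNPs trades μ
  slightly down against σ slightly up at moderate T; marginal credible
  intervals for such a σ can sit a hair off the generating value even
  though the joint posterior is consistent. The coverage checks in the
  test suite exercise exactly this regime.
* Per-iteration cost grows with the number of distinct annotation
  patterns (≤ 2^M), so many annotations with little overlap structure slow
  the α/β/γ updates.
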