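---
title: "Methods: trans-ancestry fine-mapping and target-gene nomination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-ancestry fine-mapping and target-gene nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmapr)
```

## Overview

`transmapr` implements a complete desk-scale version of a trans-ancestry
GWAS fine-mapping and target-gene nomination analysis: region
aggregation, summary-statistics conditional analysis, a forward stepwise
search for independent association signals with cross-ancestry
meta-analysis, credible causal variant (CCV) sets, cis-eQTL/mQTL
meta-analysis, SMR colocalization, and a point-based regulatory evidence
score. This vignette documents the statistical model behind each stage,
the tunable parameters and their defaults, the design decisions taken
where the procedure was genuinely open, and what the synthetic-data
generator does and does not emulate.

## Conditional analysis from summary statistics

The engine reconstructs multi-variant regression from marginal summary
statistics plus an LD reference panel. For variant $j$ with marginal
effect $b_j$, standard error $se_j$, sample size $N_j$ and panel allele
variance $v_j$, define $D_j = (N_j-1)\,v_j$. With centred genotypes,

$$\mathbf{X}'\mathbf{X} \approx R \circ \sqrt{D D'}, \qquad
  (\mathbf{X}'\mathbf{y})_j = D_j b_j,$$

where $R$ is the panel correlation matrix. The phenotypic sum of squares
is estimated per variant from the marginal fit,
$\hat{y}'y_j = se_j^2 D_j (N_j-2) + b_j^2 D_j$, and the median across the
region's variants is used. The conditional effect of a target given a
conditioning set is the Schur-complement solution of the joint system;
its standard error uses the residual variance of the reconstructed joint
fit with the ordinary least squares degrees of freedom
($N - k - 2$ for $k$ conditioning variants, a target and an intercept).

Numerical choices:

* **Allele variances.** When the panel is backed by dosages the
  *empirical* dosage variances are used; these equal $2f(1-f)$ in
  expectation under Hardy–Weinberg equilibrium but make the
  reconstruction exact when the analysis cohort serves as its own panel.
  This identity is the engine's core oracle: on a simulated quantitative
  cohort (n = 2000, 50 variants) the conditional betas and SEs match an
  exact joint `lm()` fit to well within 1%. Correlation-only panels fall
  back to $2f(1-f)$.
* **Collinearity mask.** Targets with panel $r^2 > 0.9$ to any
  conditioning variant, or with a numerically degenerate conditional
  variance, are reported as not estimable rather than extrapolated.
* **Ridge.** A relative ridge of $10^{-8}$ is added to the diagonal of
  the reconstructed $\mathbf{X}'\mathbf{X}$; a singular system after
  regularisation is an error naming the conditioning set.
* **Binary traits.** Case-control effects are treated on the linear
  approximation scale, the standard practice when conditioning
  case-control summary statistics.
* **Extreme significance.** All p-values are carried as $-\log_{10} p$
  computed in log space, so signals beyond double-precision underflow
  ($|z| \gtrsim 40$) remain ordered and comparable; threshold rules are
  applied on the log scale.

## Stepwise search, stabilisation, classification

Thresholds (all defaults of `fm_thresholds()`, surfaced as constants):

| parameter | default | role |
|---|---|---|
| `p_enter` | 1e-6 | conditional p to accept an independent signal |
| `trans_inclusion_p` | 0.05 | marginal p required in *both* populations (trans mode) |
| `ancestry_inclusion_p` | 1e-4 | marginal p required in the analysed population |
| `maf` | 0.01 | minor-allele-frequency floor |
| `sharing_r2` | 0.1 | LD r² above which leads are the same signal / not novel |
| `ccv_factor` | 100 | conditional-p ratio defining CCV membership |
| `collinearity` | 0.9 | panel r² mask in conditional analysis |

The trans-ancestry search seeds with the most significant
inverse-variance-weighted meta-analysis of the two populations' marginal
statistics, conditions each population separately on the current index
set, meta-analyses the conditioned results, and accepts the smallest
conditional p while it stays below `p_enter`. Ties are broken
deterministically: smaller p, then larger $|z|$, then smaller position.
Index stabilisation re-selects each signal's index given the others in
round-robin sweeps until a fixed point, with a cap of 20 sweeps and an
explicit non-convergence flag.

Design decisions where the procedure was open:

* **Eligibility universe for CCVs** equals the discovery-mode filters
  (MAF and marginal inclusion p), keeping discovery and credible sets
  consistent. A consequence worth knowing: trans-ancestry CCV sets tend
  to be smaller than single-ancestry ones partly because the "p < 0.05
  in both populations" filter is itself a sharper sieve.
* **Trans-mode CCV conditioning** meta-analyses per-population
  conditional results for every signal scope; whether ancestry-specific
  co-located signals should instead condition within one population is
  ambiguous, and the per-scope choice is applied uniformly.
* **Variants absent from one population** cannot be trans-mode indices
  or trans-mode CCVs (no meta-analysable conditional statistic exists);
  they remain eligible in ancestry-specific scopes. Absent variants
  contribute $r^2 = 0$ to sharing and novelty rules.

## QTL scan and meta-analysis

Expression matrices are filtered to genes with ≥ 0.1 TPM in ≥ 20% of
samples *and* ≥ 6 unnormalised reads in ≥ 20% of samples (boundaries
inclusive), quantile-normalised across samples against the average
empirical distribution (`limma::normalizeQuantiles`), then transformed
per gene by the rank-based inverse normal transform
$\Phi^{-1}((r - 0.5)/n)$ with average ranks for ties — the offset is a
documented choice, as is the normalisation target.

The cis scan fits OLS of each normalised trait on each variant dosage
within 1 Mb (inclusive, variant-to-TSS for expression, variant-to-CpG for
methylation), adjusting for the dataset's covariates; p-values are
t-based. Datasets are combined by the sample-size-weighted z-score
$z = \sum_i z_i \sqrt{N_i} / \sqrt{\sum_i N_i}$ with
$z_i = \Phi^{-1}(p_i/2)\,\mathrm{sign}(b_i)$. Note that this convention
gives $z$ the sign *opposite* to the effect; it cancels in every
two-sided test, and `p_to_z(..., convention = "standard")` emits the
conventional sign for export. Combined p-values are Bonferroni-adjusted
within each independent signal's family of tests, separately per trait
kind (expression vs methylation) — the per-kind family is a documented
choice, adjustable through the family column passed to
`bonferroni_per_family()`.

## SMR colocalization

For instrument $z$-statistics $Z_{zy}$ (GWAS) and $Z_{zx}$ (QTL meta),

$$T_{SMR} = \frac{Z_{zy}^2 Z_{zx}^2}{Z_{zy}^2 + Z_{zx}^2} \sim \chi^2_1 .$$

The instrument for each (signal, trait) pair is the signal's index
variant, and the QTL side is the meta-analysed $z$ — not a re-selected
top cis variant and not a single best dataset; both are deliberate,
matching the per-index testing scheme of the surrounding analysis. No
heterogeneity (HEIDI-style) filtering is applied. $T_{SMR}$ is symmetric,
bounded by $\min(Z_{zy}^2, Z_{zx}^2)$, and saturates at the GWAS
chi-square as the QTL association strengthens, so a colocalization call
can never be more significant than its weaker leg.

## Evidence scoring and the credible gene set

Distal links require the CCV inside an interaction anchor that overlaps
an H3K27ac peak while the partner anchor overlaps the gene's promoter;
requiring the CCV to sit in the *enhancer-like* anchor (not merely any
anchor) is a documented choice. The promoter window is strand-aware,
TSS − 100 bp upstream to TSS + 1000 bp downstream; the two distances can
be flipped via arguments since the window's phrasing is ambiguous in
common usage. Scores: distal 2 (experimental) / 1 (computational) / 3
(both), +1 genomic-feature overlap, +1 for ≥ 2 interactions, +1 driver,
range 0-6; proximal 1 (TF binding) + 1 (driver), range 0-2; coding 1
(deleterious missense, nonsense, or predicted splice alteration — all
three classes score equally, since the 0-2 range admits no larger award)
+ 1 (driver), range 0-2.

Down-weighting: a lack of expression multiplies proximal and coding
scores by 0.1; for distal links the penalty magnitude (TAD separation or
lack of expression) is not quantified anywhere authoritative, and the
same factor 0.1 is adopted for consistency (configurable via `penalty`).
TAD separation is assessed as a boundary-interval *midpoint* strictly
between CCV and TSS. Per (signal, gene), the maximum score over the
signal's CCVs is used. Confident targets require distal > 4, proximal
> 1 or coding > 1 — strict inequalities. The credible set keeps
protein-coding genes outside the MHC (GRCh37 chr6:28,477,797-33,448,354
by default), resolves multi-candidate signals to the highest prior tier
(A > B > C) or keeps all candidates when none is tiered, and keeps
single-candidate signals unconditionally; the operation is idempotent.

## The synthetic-data generator

Haplotypes are latent AR(1) Gaussians with adjacent correlation
`ld_decay`, thresholded at per-population allele-frequency quantiles and
summed to dosages (a Gaussian copula). This induces a controllable,
monotonically decaying LD structure — verified against a
numeric-integration orthant-probability oracle — without a coalescent
simulator. Per-population frequencies are drawn independently, so
ancestry-enriched and effectively population-specific variants arise
naturally. Phenotypes follow a liability model; binary traits threshold
the liability at its empirical quantile, so the realised case fraction is
exact. Summary statistics use exact OLS (quantitative) or a logistic
score test with one-step log-odds estimates (binary), with monomorphic
and perfectly separating variants excluded and logged.

What the generator does **not** emulate: realistic recombination maps or
demography, imputation uncertainty, genotyping error, allele-coding
heterogeneity between studies (all simulated variants share one coding,
so harmonisation paths are exercised by dedicated unit fixtures instead),
polygenic background, and genome-scale ancestry structure. On that last
point, the QTL datasets carry five independent Gaussian covariates as
stand-ins for genotype principal components: PCs computed from a single
simulated region would load on the cis variants themselves and absorb
real cis effects, which is an artefact of desk scale, not of real
analyses. Passing tests therefore demonstrate the statistical machinery
under the assumed model, not robustness to the artefacts of real cohort
data.

Generated coordinates are 1-based variant positions; BED/BEDPE fixtures
are written 0-based half-open per the format standards, and a variant at
1-based position $p$ overlaps $[s, e)$ iff $s \le p-1 < e$ — both
directions of the conversion are pinned by tests against a brute-force
all-pairs oracle.

## Problem sizes used by the test-suite

Simulation-backed checks run at sizes chosen to give the relevant
statistics adequate power while keeping the default suite comfortably
reproducible on one core: the conditional-vs-OLS identity at n = 2000
with 50 variants; signal recovery and the trans-vs-single-ancestry CCV
comparison over 100 seeded replicates at n = 20,000 per population with
50 variants; type-I calibration over 1000 (marginal test) and 500 (cis
scan) replicates; SMR power and calibration over 100-200 replicates.
All replicate loops fix their seeds, so the suite is deterministic.

## Known limitations

* The conditional engine assumes the LD panel matches the GWAS
  population; panel mismatch inflates conditional estimates and is not
  modelled or corrected.
* Fixed-effects meta-analysis only; no heterogeneity statistics.
* No Bayesian fine-mapping (posterior inclusion probabilities, SuSiE-style
  sets); the CCV construction is the conditional-p ratio rule.
* Chromosome X and random-effects scenarios are out of scope.
* The interface runs one region per call (`finemap_region()`); genome-wide
  orchestration is a thin loop the caller owns, apart from the bundled
  single-region `run_pipeline()` demonstration.
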