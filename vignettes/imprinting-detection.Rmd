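---
title: "Detecting genomic imprinting from reciprocal-cross RNA-seq: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic imprinting from reciprocal-cross RNA-seq: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical method, the
synthetic benchmark it is tested on, and the design decisions taken where
more than one reasonable choice existed.

## 1. The statistical model

### Data and null hypothesis

The unit of analysis is a per-gene allelic count table: for each gene and
each reciprocal cross (A×B and B×A), the number of exonic-SNP reads
assignable to the maternal and to the paternal allele. Imprinting is a
*parent-of-origin* effect — it points the same way in both crosses —
whereas a strain effect follows the allele and reverses between crosses.
Analysing the two crosses jointly with the cross as a blocking factor
separates the two.

The null expectation depends on the tissue's genome dosage. In diploid
tissue an unimprinted gene is expected at a 1:1 maternal:paternal read
ratio; in the triploid endosperm (two maternal genomes, one paternal) at
2:1, i.e. a maternal read proportion of 2/3. `test_config()` takes this
as `null_maternal_prop`, and the CLI accepts it as a ratio string
(`--null-ratio 2:1`).

### Paired negative binomial GLM

For gene $g$ and column $j$ (2 crosses × 2 parents = 4 columns):

$$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g), \qquad
\log \mu_{gj} = \beta_{g0} + \beta_{g,\mathrm{cross}(j)} +
\beta_{g,\mathrm{parent}} \cdot 1[\mathrm{maternal}(j)] + o_j,$$

where $o_j$ is a log effective-library-size offset and
$\mathrm{Var}(y) = \mu + \phi\mu^2$. The two allelic counts of one cross
are paired samples sharing a cross effect. The parent coefficient is
tested with a likelihood-ratio chi-squared test on one degree of
freedom (two-sided); Benjamini–Hochberg FDR below `fdr_level` together
with the sign of the coefficient yields the MEG/PEG call.

### How the 2:1 expectation enters

Two modes are provided (`normalization` in `test_config()`):

* **`"tmm"` (default).** Offsets are `log(N_j f_j)` with TMM
  normalization factors $f_j$. When most genes follow the null ratio,
  the trimmed mean of per-gene log-ratios keeps the maternal:paternal
  effective-library-size ratio of each cross at the genome-wide allelic
  ratio (≈2 in endosperm), so $\beta_{\mathrm{parent}}$ is the *deviation*
  from that expectation. This inherits TMM's robustness to composition
  bias but assumes imprinted genes are a small minority.
* **`"offset"`.** The null ratio is imposed explicitly:
  maternal columns receive offset $\log(L_c \cdot 2p_0)$ and paternal
  columns $\log(L_c \cdot 2(1-p_0))$ with $L_c$ half the cross's total.
  Use this when the genome-wide 2:1 assumption is doubtful (e.g. heavy
  maternal tissue contamination). On clean simulated tables the two
  modes agree closely (tested).

TMM itself follows the published defaults: 30% two-sided trim on
log-ratios, 5% on average log abundance, delta-method precision
weights, reference column chosen as the one whose upper-quartile
expression rate is closest to the mean; factors are rescaled to
geometric mean 1. One numerical detail matters for exact agreement with
the reference implementation: A-values are computed as the *mean of the
two log rates*, not as half the log of their product, so that ties rank
identically at the trim boundaries.

### Dispersion estimation

With two crosses the model leaves a single residual degree of freedom
per gene, so per-gene dispersion estimates are useless without sharing
information. The engine implements the standard three-tier Cox–Reid
adjusted profile likelihood (APL) scheme:

* **common**: maximize the genes' summed APL over a single $\phi$
  (searched on $[10^{-6}, 20]$);
* **trended**: genes are grouped into abundance bins (about one bin per
  100 genes, at most 30), a common dispersion is maximized per bin, and
  $\log\phi$ is interpolated across abundance with a natural spline
  (constant beyond the end bins);
* **tagwise** (default): each gene's APL is evaluated on an 11-point
  grid of $\mathrm{trend}_g \cdot 2^{\delta}$, $\delta \in [-6, 6]$, and
  the gene maximizes its own APL plus `prior_df / df_residual` times the
  grid-averaged APL of all genes — empirical-Bayes shrinkage toward the
  trend. The continuous maximum is found by quadratic interpolation
  around the best grid point.

`prior_df` defaults to 10. This is a tunable: with only one residual
degree of freedom the shrinkage prior dominates, which is exactly what
makes the test usable at $n = 2$ crosses, but it also means the tagwise
estimates are closer to the trend than in deeply replicated designs.
`prior_df = Inf` reproduces the trend exactly (tested). The GLM fitter
is an IRLS vectorized across genes (all genes share the design matrix),
with step halving whenever a step would increase the deviance, at most
50 iterations, relative deviance tolerance $10^{-8}$; non-converged
genes are flagged and get `NA` p-values.

Validation: the LRT statistic matches an independent per-gene Poisson
GLM fit (`stats::glm`) to $10^{-6}$ when $\phi \to 0$; TMM factors and
dispersion estimates are cross-checked against an independent
established implementation in the test suite; and on null-only
simulations the type-I error at $p < 0.05$ for well-covered genes
(≥100 counts) is near nominal (measured 0.059 in the acceptance test).

### Baseline callers

Two count-test baselines share the same FDR/classification stage:

* **Fisher-summed** — two-sided Fisher's exact test of the 2×2 table
  `[observed maternal, observed paternal; expected maternal, expected
  paternal]`, counts summed over the crosses, the expected column
  apportioning the same total at the null ratio with
  `expected maternal = round(total * p0)`. The rounding convention is
  documented and tested at boundaries; genes with zero total get
  $p = 1$ and a flag.
* **Fisher-combined** — the same test per cross, combined by Stouffer's
  method with equal weights: $z_i = \Phi^{-1}(1-p_i)$,
  $Z = \sum z_i/\sqrt{k}$, $p = 1 - \Phi(Z)$. P-values of 0 are clipped
  to the smallest positive double and values of 1 to $1 - 10^{-12}$.
  Combining *two-sided* p-values naively cannot distinguish consistent
  from opposite-direction imbalance, so a strain-biased gene (allelic
  excess flipping between crosses) can still reach significance; a
  direction-aware variant (`directional = TRUE`, z-scores signed by
  each cross's maternal excess) is provided and tested. The naive
  two-sided combination is the default because it is how such
  combination is typically applied in practice.

These baselines model counts as exact given the margins and therefore
ignore biological overdispersion — their false-positive behaviour at
high counts and low power at moderate counts is precisely what the
benchmark quantifies.

## 2. The synthetic benchmark

### What the generator emulates

`sim_config()` + `simulate_imprinting()` generate allelic count tables
with the statistical structure the test assumes:

* per-gene log2 baseline expression $\beta_0 \sim N(\texttt{intercept\_mean},
  \texttt{intercept\_sd})$, defaults $N(2, 3)$;
* totals per cross $\sim \mathrm{NB}(\mu = 2^{\beta_0},
  \phi = 4/\mu + 0.1)$ — the documented default mean–dispersion trend of
  the generator this design is modelled on; no differential expression
  between crosses, no outliers, equal library sizes;
* 200 spiked imprinted genes: 50 strong MEGs (99% maternal reads), 50
  weak MEGs (85%), 50 strong PEGs (34%), 50 weak PEGs (48%); all other
  genes at the 2/3 null;
* allelic sampling: maternal count $\sim \mathrm{Binomial}(\mathrm{total},
  p_{\mathrm{true}})$, paternal the exact remainder (conservation is
  asserted cell-by-cell in the tests);
* optionally, `n_bias_genes` strain-biased genes whose first-parent
  allele is expressed `bias_factor`-fold higher per genome copy, giving
  opposite maternal-fraction shifts in the two crosses — the confounder
  that distinguishes parent-of-origin from strain effects.

### Which genes get spiked

The benchmark's sensitivity denominator is the number of spiked genes.
Under the default expression distribution roughly half of all genes
fall below the 10-read filter and are unassessable by *any* caller;
spiking those genes would measure assay coverage, not method
sensitivity. By default (`spike_pool = "expressed"`) the 200 spiked
genes are therefore drawn uniformly from the genes whose simulated
totals pass the `min_total` filter, so every spiked gene is assessable
and true positive rates compare callers on a common footing.
`spike_pool = "all"` restores unrestricted uniform spiking.

### What the generator does not emulate

Passing benchmarks on these tables shows correct statistical behaviour
under the model's own assumptions. Real data additionally contain:
SNP-level structure (genes differ in informative-SNP number and
coverage; the generator works at gene level), read-mapping bias toward
the reference allele (addressed upstream by `mask_reference()`, not
simulated), maternal seed-coat contamination (shifts the effective null
away from 2:1; not simulated, and no contamination filter is included),
library-preparation batch effects, and biological variation beyond the
NB dispersion trend. Benchmark numbers here are therefore upper bounds
on real-data performance.

### Benchmark metrics

`evaluate_calls()` scores detections against the truth (spiked genes
called in either direction are true positives; filtered-out genes count
as missed), `roc_curve()` sweeps all score thresholds with ties grouped
(genes removed by the count filter get score 1 so they are never
called), `binned_tpr()` reports TPR/FPR within rank-based count
quartiles (ties at a boundary go to the lower bin, deterministically),
`concordance()` computes Venn regions by inclusion–exclusion and
pairwise Jaccard indices, and `saturation()` re-runs the whole pipeline
on binomially thinned counts (the subsampling unit is the count cell;
per-replicate seeds derive from a master seed; thinning at proportion 1
is the identity and reproduces the full run bit-for-bit, which is
asserted in the tests). `top_n()` ranks candidates by p-value, then
absolute effect, then gene id — a total, deterministic order — with the
conventional maternal-fraction windows (≥85% for MEGs, ≤50% for PEGs)
available for between-dataset comparisons.

## 3. Numerical and edge-case choices

* **Genes with an all-zero parent.** The parent coefficient diverges;
  the LRT still converges (the deviance is bounded), so the p-value is
  kept from the untouched likelihood while the *reported*
  `log2_fold_effect` is recomputed once from a fit with 0.5 added to
  every count of that gene — finite effect sizes for display without
  touching the test.
* **BH ties and NA.** `bh_fdr()` wraps the standard step-up adjustment;
  `NA` p-values (non-converged genes) propagate as `NA` and are excluded
  from the number of tests. Ranking ties in `top_n()` break by gene id.
* **Batched linear algebra.** The per-gene 3×3 normal equations are
  solved by Gaussian elimination vectorized over genes with pivots
  clamped at $10^{-12}$; the log-determinant of the weighted information
  (needed for the Cox–Reid adjustment) falls out of the same
  elimination.
* **Counting rules.** Only uniquely mapped reads (NH tag = 1, or MAPQ ≥
  20 when NH is absent); SNP bases below phred 20 are ignored; bases
  matching neither allele are tallied separately; one allele
  observation per read *pair* — among a fragment's usable (read, SNP)
  bases the leftmost SNP wins, and mates covering the same SNP count
  once — preventing pseudo-replication; indels and multiallelic VCF
  records are skipped with a tally; SNPs overlapping no gene or more
  than one gene are dropped with a tally. Genes with fewer than 10
  allelic reads summed over both crosses are discarded (inclusive
  boundary: exactly 10 is kept). Coordinates are 1-based closed
  (VCF/GFF convention) throughout the R interfaces.
* **Duplicates.** No read deduplication by default (`dedup = FALSE`);
  flagged duplicates can be dropped via the flag, since whether PCR
  duplicates should be removed from quantitative allele counts is
  protocol-dependent.

## 4. Problem sizes used by the test suite

The acceptance checks run the benchmark at full scale — 15,000 genes,
two crosses, 200 spike-ins, five seeds, for all three callers — which
completes in a few minutes on one CPU. Unit and property tests use
smaller tables (500–3,000 genes) chosen to keep each check sharp: large
enough for the asserted statistical tolerances (e.g. 3-SE moment
checks, dispersion recovery within 20%), small enough to run in
seconds.

## 5. Known limitations

* With two crosses and no replicates the residual df is 1; the test
  leans heavily on the dispersion prior. More replicates (the design
  accepts any number of crosses ≥ 2) directly improve dispersion
  estimation and power.
* The TMM mode assumes imprinted genes are a minority; for tissues or
  selections where that fails, use the explicit-offset mode.
* The benchmark's absolute detection numbers depend strongly on the
  simulated expression distribution (`intercept_mean`, `intercept_sd`):
  with the default $N(2,3)$ log2 baselines, counts are modest and weak
  spike-ins (especially 48% maternal vs the 2/3 null) are hard for all
  callers; sensitivity comparisons between callers are far more stable
  than absolute rates.
* No seed-coat/contamination filtering, no gene-set enrichment, no
  covariates beyond the cross blocking factor.
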