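---
title: "Models and methods behind islandadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind islandadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`islandadapt` is a pipeline for detecting adaptive genetic variation in
structured natural populations — the situation typical of endemic island
trees sampled at a handful of sites — and for projecting how far allele
frequencies at climate-associated loci would have to move to track future
climates. This vignette describes the statistical models, the choices made
where the design was genuinely open, and what the synthetic-data generator
does and does not emulate.

## Data model

The central object is a `genotype_matrix`: an `n x S` integer matrix of
ALT-allele dosages (0/1/2, `NA` for a missing call) with 1-based SNP
coordinates, single-base alleles, and a population label per sample.
Dosages come from unphased diploid GT calls; `/` and `|` separators are
treated identically because nothing downstream uses phase (LD is computed
on genotype dosages throughout). `NA` is the missing sentinel and is
excluded from every sum. Interval outputs (sweep regions) are written as
0-based half-open BED; positions stay 1-based internally to match VCF
bit-for-bit on a round trip. REF is treated as the ancestral allele where a
derived/ancestral distinction matters; a folded mode is available where
that assumption is unwanted.

Environmental data form an `env_table`: one sites-by-variables matrix per
scenario (`current` plus e.g. `ssp126`, `ssp585`), aligned on site and
variable names. Sites correspond to populations — one sampling location
per population.

## SNP filters

`filter_missing_maf()` removes SNPs with genotype missing rate above 0.1,
then SNPs with minor allele frequency below 0.05 (computed on non-missing
genotypes of the survivors). The order missingness → MAF → LD pruning is a
convention; each step is exposed separately so any order can be run.

`ld_prune()` reimplements windowed pairwise pruning (the `indep-pairwise
50 10 0.1` idiom): windows of 50 SNPs advanced by 10, and while any kept
pair in a window exceeds r² = 0.1, one member is dropped. r² is the squared
Pearson correlation of dosage vectors over pairwise-complete samples —
genotype LD, not haplotype LD, because inputs are unphased. The command
this emulates does not document its tie-breaking, so a deterministic rule
was fixed: offending pairs are resolved highest-r² first, the lower-MAF
member is dropped, and an exact MAF tie drops the later-positioned SNP.
The guaranteed post-condition (no within-window kept pair above the
threshold) is what tests assert by brute force.

## Composite sweep statistic

The scan combines the three classic signatures of a completed hard sweep
into one per-window score, `mu = mu_var * mu_sfs * mu_ld`, over sliding
windows of `W = 50` SNPs advanced one SNP at a time:

* **`mu_var`** (polymorphism deficit): `((p_W - p_1)/R) * (S/W)` where the
  window's SNPs span `p_W - p_1` bp of a chromosome with `S` SNPs over `R`
  bp. Neutral expectation ~1; a window whose 50 SNPs stretch over many bp
  marks a diversity trough.
* **`mu_sfs`** (spectrum shift): the fraction of window SNPs in the
  extreme derived-frequency classes (count ≤ 1 or ≥ n−1 of n haplotypes);
  a folded variant uses minor-allele counts.
* **`mu_ld`** (LD pattern): the window is split in half at its middle SNP;
  the score is the mean within-half pairwise r² divided by the mean
  cross-half r² (+ a 1e-6 guard). High LD on each flank with low LD across
  the old selected site is the post-sweep pattern.

These concrete factor definitions are this package's contract: they were
chosen to have interpretable neutral scales (≈1, [0,1], ratio ≈1) and to be
verifiable against naive per-window recomputation to 1e-12, which the test
suite does. Windows are assigned to their SNP-span midpoint; significance
is a genome-wide empirical quantile (top 0.05% by default) and significant
windows with overlapping SNP spans merge into candidate regions. The scan
mean-imputes missing dosages within windows; monomorphic pairs contribute
r² = 0.

The optimized scan precomputes a lag-banded r² matrix and per-lag
cumulative sums, so a chromosome costs O(S·W·n) rather than O(S·W²·n).

In the orchestrated pipeline the scan runs on the missingness-filtered but
MAF-unfiltered, unpruned SNP set: a MAF ≥ 0.05 filter at 30 samples empties
the singleton classes `mu_sfs` counts, and LD pruning removes exactly the
flanking-LD pattern `mu_ld` measures. The MAF-filtered, pruned set feeds
the association and RONA stages instead.

## Latent-factor association tests

For each environmental variable, each SNP's (mean-imputed) dosage is
regressed on an intercept, the standardized variable, and `K` latent
factors (default `K = 4`). Factors are the top left singular vectors of
the centered genotype matrix, scaled by their singular values, with signs
fixed deterministically.

One choice deserves emphasis. With site-level environments, the
environmental gradient across a handful of demes lies inside the span of
the deme-structure axes, and factors estimated by plain SVD will absorb a
genuine environmental signal: in our own benchmarks the first factor
captured 96% of a strongly planted gradient and drove power to zero at any
effect size. Joint-estimation latent-factor models resolve this
identifiability by attributing variance shared between the tested variable
and the factors to the variable. `fit_association()` adopts the same
convention: the factors are orthogonalized against the tested variable
before entering the model. The cost is that structure lying exactly along
the gradient is not corrected by the factors; that residual confounding is
handled by the genomic-inflation calibration below. This combination
recovered planted associations with power ≈ 0.8–0.9 at empirical FDR ≈
0.03–0.05 in the structured benchmarks, while iid null environments stay
calibrated (Kolmogorov–Smirnov statistic < 0.01 on 10^4 null SNPs).

Calibration: per variable, `lambda = median(z^2) / qchisq(0.5, 1)` and
calibrated p-values are the upper chi-square tail of `z^2 / lambda`. With
site-level environments and few sites, lambda is typically well above 1
(cluster-correlated residuals); median-scaling restores the bulk of the
null. q-values use Storey's procedure (pi0 from a 0.05–0.95 lambda grid
with cubic-spline smoothing); below 100 p-values the pi0 estimate is
unstable, so the procedure falls back to Benjamini–Hochberg. A SNP is a
candidate when its per-variable q-value is below 1%; the per-variable rule
(rather than pooling variables) matches how per-variable candidate counts
are usually reported, and the union across variables is reported
separately. Candidate positions are binned into 1-Mb windows per
chromosome and per-chromosome totals are tested for correlation with
chromosome span.

Zero-variance SNPs get p = 1 by convention; a constant environmental
variable is an error naming the variable.

## Risk of non-adaptedness

`prune_env()` first reduces redundancy: while any variable pair exceeds
|r| = 0.8 across sites, the worst pair is resolved by dropping its
lower-priority member. Priorities are user scores where available
(e.g. model contributions from a species-distribution analysis); without
scores, the variable with lower mean |r| against the others is kept, and
exact ties drop the lexicographically later name — fully deterministic.

For each candidate SNP of each retained variable, allele frequency
(per population by default, dosage/2 per individual optionally) is
regressed on the present-day value of the variable. RONA for a population
and variable is the r²-weighted mean over SNPs of |predicted future −
predicted current| frequency at that population's site, with predictions
clipped to [0, 1]. r² weighting is the default because fit quality is the
natural confidence weight and per-variable mean r² is part of the standard
report; uniform weighting is available for sensitivity analysis. With one
site per population, per-individual RONA within a population equals the
population value, so both units are offered and coincide in that limit.
RONA is invariant to affine rescaling of an environmental variable applied
to both layers — units of measurement cannot matter — and the tests assert
this to 1e-10.

## Synthetic-data generator

The generator produces data carrying exactly the structure the analysis
assumes, so that power and error rates are measurable against known truth.

* **Structure**: Balding–Nichols sampling — per SNP an ancestral frequency
  `p0 ~ U(0.05, 0.95)`, deme frequencies `Beta(p0(1-F)/F, (1-p0)(1-F)/F)`
  with `F` the target F_ST, binomial genotypes. Defaults (5 demes of 6
  diploids) mirror a small island resequencing design. Weir–Cockerham
  estimates recover the target within ±0.02 at 20k SNPs (asserted for
  F_ST ∈ {0.05, 0.1, 0.2}).
* **Environmental association**: chosen loci have deme frequencies
  regenerated as `clamp(p0 + b · z(e), 0.02, 0.98)` with `z` the
  standardized site variable. The default slope magnitude `b ∈ [0.35,
  0.55]` per environmental SD makes planted loci strongly clinal — deme
  frequencies traverse most of the polymorphic range across the gradient,
  the regime the candidate-detection step targets; weaker slopes are a
  config away. Clamping keeps planted loci polymorphic; where the clamp
  binds, the realized relation is sigmoid rather than linear, which is
  also the realistic shape of a steep cline.
* **Sweeps**: a forward Wright–Fisher simulation (compiled core) with
  infinite-sites mutation, uniform recombination and multiplicative
  selection, so sweep signatures arise mechanistically rather than being
  imposed. The beneficial allele enters as a single copy after a 10N
  neutral burn-in; losses restart from the saved burn-in state
  (conditioning on fixation by rejection), and haplotypes are sampled at
  fixation and paired into diploids. Desk-scale parameters: N = 200
  diploids stands in for a much larger natural population, with the
  mutation rate scaled up (default 3400×, giving θ ≈ 2.2e-3/bp, a
  realistic magnitude for outcrossing trees) so the population mutation
  rate stays sensible; recombination defaults to 6e-7/bp, putting the
  hitchhiking footprint `s/(r·ln 2Ns)` near 28 kb. Neutral runs match
  Watterson's expected segregating-site count within a few percent
  (asserted within 15% over 15 replicates).

What the generator does **not** emulate: admixture and isolation-by-
distance (demes are exchangeable), linked background selection, SNP
ascertainment bias, genotyping error, and spatial autocorrelation of the
environment beyond a single correlation parameter. Passing benchmarks on
these data therefore demonstrate correctness of the machinery and
calibration under the stated model, not performance guarantees on any
particular empirical dataset.

A known limitation worth stating plainly: at the benchmark's weak-sweep
strength (2Ns = 20 with N = 200, s = 0.05 on a 200-kb chromosome), single
realizations of the neutral coalescent produce diversity dips comparable
to the true sweep trough. Even an oracle that scans for the minimum
nucleotide diversity window localizes the selected site within 25 kb in
only ~85–90% of replicates; the composite `mu` statistic achieves roughly
72–75%. Localization improves rapidly with stronger selection or larger
simulated populations.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use the scales at which the
benchmarks were designed: 5,000-SNP chromosomes for oracle-equality
checks, 20 sweep replicates of 200 kb, ten 10,000-SNP / 300-sample GEA
replicates, and 15 neutral Watterson replicates. All generators are pure
functions of an integer seed; the pipeline derives fixed per-stage
substreams from one global seed, records it in every output header, and
reruns resume from existing stage outputs. Degenerate inputs follow
explicit conventions rather than erroring where a convention is standard:
monomorphic SNPs give r² = 0 in LD computations and p = 1 in association
tests; all-missing groups give `NA` frequencies; chromosomes shorter than
one window are skipped with a warning.
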