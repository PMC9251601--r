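---
title: "TriOmicNet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TriOmicNet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

TriOmicNet integrates three omics layers measured on a common panel of
plant accessions — SNP genotypes, a pan-transcriptome expression matrix
(FPKM-like) and metabolite-signature abundances — into a tripartite
metabolite–gene–eQTL regulatory network. This vignette explains the
statistical machinery, the tunable parameters, what the synthetic
generator does and does not emulate, and the design decisions taken
where the procedure left genuine freedom. It states no empirical result
that the package's tests do not themselves compute.

## The analysis model

**Population-genetics layer.** Variants are filtered on minor-allele
frequency (keep MAF ≥ 0.05, computed on non-missing dosages) and
missingness (keep ≤ 0.3), the standard `maf`/`geno` semantics with
keep-at-boundary. LD pruning follows the sliding-window greedy scheme
(`50 10 0.2`): within a window of 50 consecutive retained SNPs, while
any pair has squared Pearson dosage correlation above 0.2, the
lower-MAF member is removed (ties broken toward the later position) and
the window slides by 10. Because a fixed-step slide does not by itself
guarantee that *every* window of 50 consecutive survivors is clean, a
final step-1 sweep runs until stable; `verifyLdPrune()` re-checks the
post-condition exhaustively. Missing dosages are mean-imputed
(`imputeMean()`) before correlation, PCA, kinship and association —
a deliberate, simple stand-in for model-based genotype imputation,
which is out of scope.

Genotype PCA standardises each SNP column to centre $2\hat p$ and scale
$\sqrt{2\hat p(1-\hat p)}$ and takes the top components of the singular
value decomposition; component signs are fixed so the
largest-magnitude loading is positive, making results reproducible
across BLAS implementations. Kinship is the VanRaden genomic
relationship matrix $K = ZZ^\top / 2\sum_j \hat p_j(1-\hat p_j)$ with
$Z$ the column-centred dosages; any symmetric PSD relatedness estimator
would preserve the mixed-model contract, and VanRaden is the common
default. Two-population differentiation is the per-SNP Weir–Cockerham
$\hat\theta$ with its $a$, $b$, $c$ variance components reported;
monomorphic SNPs are flagged undefined rather than dropped, and a
Hudson estimator is available as an independent cross-check. For a SNP
fixed for alternate alleles in the two groups, $b$ and $c$ vanish
identically and $\hat\theta = 1$ exactly, whatever the group sizes.

**Expression and metabolite layers.** Genes with mean abundance below
1 are removed before differential testing (`filterLowExpression()`).
Presence classification uses a strict `> 0` presence rule: *core* =
present in all $n$ accessions, *near-core* = present in more than
$\lfloor 0.95\,n\rfloor$, *rare* = present in fewer than
$\lceil 0.05\,n\rceil$, *accession-specific* = exactly one, *silent* =
none; for $n = 134$ the integer cutoffs are "> 127" and "< 7".
Abundance classes are per accession: HEG at FPKM ≥ 20, MEG at
5 ≤ FPKM < 20, LEG below 5. ePAVs are genes expressed (strictly
positive) in one pure group and in no accession of the other; the
default demands presence in 100% of the carrier group
(`min_carrier_frac = 1`) because "expressed only in" is ambiguous
about carrier completeness — the looser reading is one argument away.

Differential expression operates on $\log_2(x+1)$ abundances with an
unequal-variance Welch $t$-test and the gate
$|\mathrm{lfc}| \ge 2 \wedge p < 0.01$ (raw $p$ by default,
Benjamini–Hochberg selectable). This is a deliberate substitution: the
original count-model engine needs read counts, which do not exist at
the FPKM layer this package consumes; the contract preserved here is
the thresholding logic, not any particular engine's gene list.
Differentially accumulated metabolite signatures (DAS) require
detection in strictly more than 8 accessions, a raw-abundance
group-mean fold change > 2 or < 0.5, and a two-sided pooled-variance
$t$-test $p < 0.01$; fold changes are computed on raw abundances (the
transform was not specified; raw is the conservative literal reading)
and a zero denominator yields an infinite, still-callable fold change.

**Association layers.** The GLM scan is OLS of the trait on intercept,
dosage and the first 5 genotype PCs, with a two-sided $t$-test on the
dosage coefficient; monomorphic or degenerate SNPs report effect 0,
SE $\infty$, $p = 1$. The MLM is
$y = W\alpha + x s + u + \varepsilon$, $u \sim N(0,\sigma_g^2 K)$,
$\varepsilon \sim N(0,\sigma_e^2 I)$, with 3 PC covariates. The
variance ratio $\lambda = \sigma_g^2/\sigma_e^2$ is estimated once per
trait by REML under the no-SNP null — spectral decomposition of $K$
plus one-dimensional Brent-style optimisation of the profiled
restricted likelihood — and reused for every SNP (the P3D
approximation), after which each SNP is a generalised least-squares
test with $V$ fixed. With $K = I$ the GLS collapses to OLS and the MLM
reproduces the GLM exactly; this identity is a standing test.
Significance thresholds are empirical: the trait is permuted 100
times, the genome-wide minimum $p$ recorded per permutation, and the
cutoff is the $\alpha = 0.05$ order-statistic quantile of the minima
(seeded, stored, deterministic). A Bonferroni cutoff
($\alpha/M$) is the fast alternative and the default for the
transcriptome-scale eQTL stage, where per-gene permutation is
supported but expensive.

Metabolite traits are $\log_{10}$-transformed before GWAS and QTT by
default (mass-spectrometry intensities are heavy-tailed; the flag is
`log10_metabolites`). QTT regression fits each metabolite on
$\log_2(\text{expression}+1)$ of one gene plus 3 genotype PCs and
keeps gene coefficients with $p < 0.01$. eQTL scanning treats each
gene's $\log_2(x+1)$ expression as a GWAS trait under a configurable
model set (default GLM + MLM, both required for co-identification; the
original multi-model intersection included a third, iterative model
that is out of scope here, so the co-identification rule is
parameterised via `min_models`). A (gene, SNP) pair is *cis* when the
SNP sits on the gene's chromosome strictly less than 100 kb from the
gene interval (distance 0 inside the gene, else the gap to the nearer
boundary — the anchor point was unspecified, boundary distance is the
documented choice), *trans* otherwise, *unassigned* for unplaced
genes.

**Network layer.** A candidate pair (metabolite $m$, gene $g$)
requires both a GWAS signal — $g$'s interval overlapping
$[s - 1.5\,\mathrm{Mb},\, s + 1.5\,\mathrm{Mb}]$ for at least one SNP
$s$ significant for $m$ (interval overlap, not gene-start containment)
— and QTT membership of $(m, g)$. Pleiotropic genes associate with
strictly more than 10 distinct metabolites; candidate-gene-rich eQTLs
link to strictly more than 10 distinct candidate genes (both
strict-greater, per the phrasing they implement). Dual-role genes are
candidates that host an eQTL SNP inside their own interval — the
assignment rule for "genes that are both candidates and eQTLs" was
never stated, so strict containment is the default with a configurable
flank. The typed graph (metabolite / gene / eQTL-SNP nodes;
gene–metabolite and eQTL–gene edges with cis/trans labels) is built on
igraph with referential integrity enforced; GraphML is the round-trip
format of record, SIF and node/edge TSVs are emitted alongside. The
summary reports the rich-eQTL share as
$100 \times \text{rich}/\text{total eQTLs}$ rounded to one decimal
(e.g. 303 of 3407 → 8.9), undefined when there are no eQTLs. Every
emitted predicate is re-testable from stored evidence
(`verifyCandidatePairs()`, `verifyAnnotations()`), and the test-suite
re-tests them on every pipeline run.

## The synthetic generator

`simulatePopulation()` produces datasets with known ground truth under
the minimal statistical structure the downstream procedures assume; it
makes no claim to emulate any real plant's biology.

*Genotypes* follow the Balding–Nichols construction: ancestral
frequency $p \sim U(0.05, 0.95)$, subpopulation frequencies
$\sim \mathrm{Beta}(p(1-F)/F,\, (1-p)(1-F)/F)$ with drift $F = 0.15$,
pure accessions drawing dosages $\mathrm{Bin}(2, p_k)$ and admixed
accessions drawing from $a\,p_A + (1-a)\,p_B$ with per-accession
admixture $a \sim U(0,1)$. The default panel mirrors the downstream
contrast design: 134 accessions, pure groups of 12 (A) and 19 (B), the
rest admixed; 10 000 SNPs on 5 chromosomes of 20 Mb; 2% of genotype
calls missing at random.

*Expression* is log-normal per gene (baseline $\log_2$ mean
$\sim N(2, 1.5)$), with accession-level biological SD 0.6 and
replicate SD 0.5 on the $\log_2$ scale; three replicates are averaged
on the abundance scale, matching the convention of averaging
biological replicates per accession. 10% of genes are "sparse"
(stochastically present) to exercise the presence classes, and 5% are
unplaced. Planted structure: 30 ePAVs (exact zeros in the non-carrier
pure group), 30 DEGs (log2 shift 3 between pure groups, scaled by
ancestry in admixed accessions), 20 cis- and 10 trans-eQTLs whose
effects add $\beta z$ (standardised dosage) on the log scale, with
$\beta$ set so the SNP explains 30% of accession-level expression
variance. Planted features are drawn from placed, non-sparse genes
with baseline $\log_2$ mean ≥ 2: near the detection floor the
$\log_2(x+1)$ analysis scale compresses any planted shift below
recoverability, so a "planted log2FC" is only well-defined away from
the floor — the same reason real differential calls presume expressed
genes.

*Metabolites* are log-normal ($\log_2$ means $\sim N(5,1)$, SD 1)
with planted links realised as a Gaussian linear model on the
$\log_2$-abundance scale: 15 metabolites load on the
standardised log-expression of planted cis-eQTL genes and 5 on SNP
dosages (each link explaining 50% of the metabolite's log-variance),
10 metabolites carry a direct group shift of 2.5 log2 units, 5% of
entries are masked missing-at-random as "not detected", and 5
signatures are detectable in only a handful of accessions to exercise
the DAS eligibility rule. Modelling the "weighted sum plus Gaussian
noise" on the log scale (with abundance $= 2^{\text{predictor}}$)
keeps abundances positive and makes ratio-based fold changes
meaningful.

What the generator does **not** emulate: linkage disequilibrium blocks
and recombination maps (SNPs are exchangeable given the frequency
model), isoform structure, count-level sampling noise, batch effects,
detection-limit censoring (missingness is random, not
intensity-dependent), and any real metabolic pathway topology. Passing
planted-truth tests therefore demonstrates the correctness and power
of the inference machinery under its own assumptions — not performance
on real population data, where LD in particular will spread
association signals across many linked SNPs.

## Numerical choices and degenerate inputs

- Regression scans run through a vectorised Frisch–Waugh–Lovell path;
  a residual SNP variance below $10^{-10} n$ marks a degenerate test
  (effect 0, SE $\infty$, $p = 1$). $p$-values are floored at the
  smallest positive double so they remain in $(0, 1]$.
- REML optimises $\log\lambda$ on $[\log 10^{-6}, \log 10^{6}]$;
  kinship eigenvalues are clipped at zero after a PSD check that
  rejects matrices with eigenvalues below $-10^{-6}$ of the largest.
- Zero-variance genes in both groups with equal means get $p = 1$ by
  convention; with unequal means, the smallest representable $p$.
- The permutation-threshold quantile is the order statistic
  (`type = 1`), so `alpha = 1` returns the maximum of the minima and
  thresholds are monotone in `alpha`.
- Empirical-quantile and fold-change boundaries are all strict or
  keep-at-threshold exactly as documented per operation; boundary
  semantics are asserted in the unit tests.
- All randomness flows from explicit seeds; stage sub-seeds are
  derived from the master seed by a fixed affine map below $2^{31}$.

## Problem sizes in the test-suite

The package's own validation uses desk-scale datasets chosen to keep
the full suite fast while preserving the contrast design: most unit
tests run on 60-accession panels (pure groups still 12 vs 19) with
400–800 SNPs, the planted-truth recovery study runs the full default
generator (134 accessions, 10 000 SNPs, 2 000 genes) over 10 seeds,
and the confounding-control study uses 10 structured-null simulations
(heritability 0.6 backgrounds drawn from the realised kinship) at
2 000 SNPs. End-to-end pipeline checks use 400-SNP/80-gene
configurations with Bonferroni metabolite-GWAS thresholds; the
permutation machinery is exercised separately at full scale.

## Known limitations

- The DEG engine is a Welch test on transformed abundances, not a
  count model; with genuine read counts a negative-binomial engine
  would be preferable and its thresholds drop in unchanged.
- P3D estimates variance components once per trait; per-SNP exact
  mixed models would be slower and differ slightly for large-effect
  SNPs.
- The multi-model co-identification here spans GLM and MLM only; an
  iterative fixed-and-random-effect third model is out of scope, so
  co-identified sets are systematically more conservative than a
  three-model union-of-pairs rule.
- Mean imputation attenuates association signals at high-missingness
  SNPs relative to model-based imputation.
- Group labels are taken as input; the package does not infer
  population structure assignments (trees, admixture proportions).
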