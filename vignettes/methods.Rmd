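---
title: "Methods: somatic and transgenerational methylation deviations in an F2 intercross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic and transgenerational methylation deviations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The design and its model

`epideviate` analyses gene-body CG methylation (gbM) in a cross between two
inbred lines, here called northern (N) and southern (S). Because the lines
are inbred, each CG site carries one binary epiallele per line, and an F2
individual inherits a diplotype of epialleles determined entirely by its
local ancestry (NN, NS or SS) and the F1's per-allele states. The analysis
rests on three empirical premises, all testable inside the package:

1. **mCG is meiotically stable.** The inherited state is the default;
   deviations are rare. This is what makes "reads that disagree with the
   inherited state" a phenotype rather than noise.
2. **Local ancestry is inferable** from shallow sequencing at SNP markers,
   because F2 ancestry tracts are tens of centiMorgans long.
3. **The F1 epigenotype is inferable from F2 segregation**: pooling read
   counts across F2 individuals homozygous NN at a site measures the F1's
   N-allele state (and SS the S allele), without any allele-specific read
   assignment.

Given the inherited diplotype, two deviation phenotypes are defined per
region (gene or 500-kb window) and individual as read-weighted averages:

* **gain** = Σ mc / Σ total over sites inherited unmethylated on *both*
  alleles,
* **loss** = 1 − Σ mc / Σ total over sites inherited methylated on both
  alleles.

Individuals heterozygous for methylation state at a site (NS ancestry at a
heterozygous F1 site) are excluded there: their expected methylation is 50%
and neither phenotype is identifiable from unassigned reads. 500-kb windows
average over roughly 10^4 cytosines, matching the scale of per-read rates in
the 10^-4..10^-1 range.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| state-call cut-off | 0.5 | fraction | published classification rule; a level exactly at the cut-off is *ambiguous* (the source analysis states no tie rule; ties are excluded downstream) |
| `min_coverage` | 3 | reads | minimum evidence for a state call; the source is silent, exposed as configuration |
| non-conversion rate | 0.003 | fraction | measured on unmethylated chloroplast control DNA (99.7% conversion) |
| non-conversion α | 0.05 | — | one-sided exact binomial test P(X ≥ mc) < α keeps mc, else 0 |
| `min_individuals` | 10 | individuals | per homozygous ancestry class for F1 allele calls; F2 designs of n ≈ 300 give ~75 per class, so this is permissive |
| window size | 500 000 | bp | tiled from position 1, final partial window kept (source silent on remainders) |
| marker error rate | 0.01 | per read | HMM emission error; sequencing + mapping error on bisulfite-converted reads |
| stability bounds | 0.2 / 0.35 | mean gain / loss per site | published filters for epimutation-rate estimation |
| generations | 2 | — | a grandparent-vs-F1 state difference reflects two meioses |
| rotations | 1000 | — | significance threshold = 99% quantile of null maxima |

The non-conversion filter is applied to **gains only**. Losses would need
the symmetric over-conversion correction, for which no usable rate estimate
exists; loss estimates therefore include an unknown additive artefact
component, which is one reason the package treats gains and losses as
different phenomena throughout.

# The ancestry HMM

States (NN, NS, SS) evolve along each chromosome with transition matrix
built from the recombination fraction r of each marker interval (Haldane
inverse of the cM distance; two independent meioses, so NN→NS is 2r(1−r)
etc.). Emissions are binomial: a read reports the N allele with probability
1−e (NN), 1/2 (NS), e (SS). The published description calls the model
"multinomial"; for biallelic SNP markers the multinomial over read types
reduces to this binomial, which is this package's documented choice. The
initial distribution is the F2 expectation (¼, ½, ¼); chromosomes restart
independently. Posteriors come from scaled forward–backward, the reported
path from Viterbi, and crossovers are counted as MAP state changes.

Per-site ancestry between markers is taken from the nearest marker; if the
two flanking markers disagree, the site is set missing (a crossover lies
nearby and its position within the interval is unknown). How the original
analysis interpolated is unstated; nearest-marker is conservative and costs
only the sites inside crossover intervals.

# The binomial null model

For deviation fractions x_ij = f_ij/n_ij the null of independent per-cell
(per-read) mutation is simulated by redrawing reads as Binomial(n_ij, p_ij)
with p_ij = x̄_i· + x̄_·j, clipped to [0, 1]. Two caveats are inherited from
the published formulation and documented rather than silently fixed: the
additive p double-counts the grand mean (each margin already contains it),
and p can exceed 1 before clipping. Both make the null slightly
over-dispersed; the package's calibration test therefore compares data
*regenerated from the null with the same marginals*, where the identity is
exact. Missing cells are excluded with per-row/per-column denominators. The
diagnostic reports the fraction of sites whose between-individual variance
exceeds the null's 97.5% quantile (sectored/clonal deviations would inflate
it) or falls below the 2.5% quantile (deviations shared across individuals —
the qualitative signature of losses — deflate it).

# QTL mapping and variance partitioning

Window phenotypes are regressed on expected genotype covariates
(Haley–Knott): additive a = p(NN) − p(SS), dominance d = p(NS) from the HMM
posteriors. The null model is y ~ 1 + T (growth temperature); the additive
model adds a + d; the full model adds a×T + d×T, so
LOD_full − LOD_additive tests genotype-by-temperature interaction.
Dominance is always carried (2-df QTL) so that recessive alleles are
detectable. Trans-acting modifiers affect windows genome-wide, so evidence
is aggregated by summing per-window LOD at each marker.

**Genome rotation.** The published threshold procedure "permutes LOD scores
and performs genome rotations". Rotating the window→genome assignment
cannot be the operative mechanism for the aggregate statistic: the
aggregate sums every window's LOD at every marker, and is invariant to
window relabelling. This package rotates in the individual dimension
instead: each null replicate circularly shifts the phenotype rows against
the genotype rows (within temperature groups, preserving the
phenotype–temperature link), recomputes the aggregate scan and records its
genome-wide maximum. This preserves marker LD and the correlation structure
among window phenotypes while breaking genotype–phenotype association —
the properties the rotation wording is after. Plain individual-label
permutation is available as an alternative. The "1% FDR" of the source is
implemented as the 99% quantile of the max-statistic null, i.e. a
FWER-style threshold; this is a documented divergence from the FDR wording.

Variance shares for y = G_cis + T + Σ G_QTLi + G_cis×T + Σ G_QTLi×T + ε
use sequential sums of squares averaged over all admissible term orderings
(interactions entering after their main effects) — an LMG-style
decomposition, chosen because the factors are correlated and the source
specifies a mixed-model fitter but no partition rule. Shares are reported
as fractions of total phenotypic variance; the residual is RSS_full/TSS.

**Localisation power.** A planted additive QTL explaining 5% of variance at
n = 308 yields an expected peak LOD around 3.4, barely above genome-wide
noise maxima: in the package's own simulations the genome-wide peak falls
within 10 cM of the true locus only about half the time and on the wrong
chromosome in roughly a sixth of replicates. Tests therefore check sharp
(±10 cM) localisation at a 25%-VE QTL and only chromosome-level
localisation at 5%; the variance partition, evaluated at the true locus, is
the accurate quantity at 5% VE.

# What the simulator emulates — and what it does not

The generator reproduces the study design it validates against: two parental
lines with binary states (25% of sites methylated in ≥1 line, 45% of those
differing, 70% of differing sites methylated only in N); an F1/F2 pedigree
with Haldane crossovers (1 Morgan per chromosome — the source gives no map
length); per-generation epimutation (defaults 0.04% gains, 0.2% losses);
somatic deviations drawn independently per read with base rates 0.09%
(gains) and 7.3% (losses) and multiplicative modifiers — pericentromere
×2.8 (gains), CGT context ×1.22 (losses), N-origin alleles ×1.29 (gains),
S-origin alleles ×1.02 (losses), differential sites ×10 (gains) and ×2
(losses); trans QTL as genotype-dependent rate multipliers calibrated
analytically to a requested variance explained (formula documented at
`qtl_delta`); Poisson read depth (mean 5 — per-site depth is not reported
numerically in the source, so this is a stated guess); and 0.3%
non-conversion. Over-conversion defaults to 0 because no usable rate
estimate exists.

Deliberately **not** simulated: clonal/sectored somatic structure (the
independence null is the stated model for gains, and sector geometry is
unidentifiable at this design's power); allele-specific read assignment;
alignment and coverage artefacts; siRNA/RdDM dynamics; gene models (the
mapped phenotypes are windows; per-gene aggregation is exercised with
synthetic gene assignments in tests). A green recovery test therefore
establishes estimator correctness *under the stated generative model*, not
robustness to artefacts the model excludes.

Recovery frames make two documented simplifications. Gain frames set
non-conversion to 0 (keeping the filter active): at Poisson-5 coverage a
single non-converted read passes the per-cell binomial test, so a 0.3%
background would otherwise triple a 0.09% signal — at realistic per-site
depths the filter is applied to much deeper counts. Stratified-fold frames
use true local ancestry so they isolate the stratified estimator; the HMM
path is separately validated to ≥98% marker accuracy at 1× coverage and is
used end-to-end in the mean-deviation and epimutation frames. The
SS-vs-NN loss frame fixes 200,000 observations and uses 20× coverage,
because a 2% fold excess is at the edge of resolution there; its acceptance
check is CI coverage, not point agreement.

# Epimutation rates

Grand-parental states are called from pooled parental replicates; F1 allele
states from pooled homozygous F2 individuals; any discordance reflects a
change somewhere along two generations, so counts are divided by 2. Gains
are normalised by informative sites unmethylated in the grandparent and
losses by methylated ones (the at-risk denominators); this deviates from a
single-denominator reading of the rate definition and is what makes the
single-class recovery frames well-defined. The stability filters (mean
somatic gain < 0.2 and loss < 0.35 per site, plus unambiguous calls in both
generations) remove residual grand-parental heterozygosity and cryptic
copy-number pseudo-heterozygosity by exclusion rather than modelling.

# Numerical choices

* Exact binomial tails via `pbinom(mc − 1, n, rate, lower.tail = FALSE)`;
  the filter is monotone in mc by construction.
* HMM in scaled probability space (forward–backward) and log space
  (Viterbi); zero-depth markers contribute log 1.
* LOD values are clamped at 0 and nesting (LOD_full ≥ LOD_additive) holds
  to 1e-8; singular marker designs fall back to the null model and are
  reported as skipped.
* Scan internals cache thin-QR factors of all marker designs stacked into
  one matrix, so a rotation replicate is a single matrix product.
* Bootstrap CIs resample individuals (1000 by default) from per-individual
  per-stratum count sums; the source reports no interval procedure.
* All randomness flows from a single integer seed; identical seeds give
  byte-identical scenario files.

# Known limitations

Losses include an unquantified over-conversion artefact; the package
reports them as measured. The epimutation estimator attributes changes to
a two-generation window without locating them. Direction-of-cross
asymmetries observed in the original data are treated as data anomalies,
not reproduced. The CLI and pipeline orchestrate single-machine runs only.
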