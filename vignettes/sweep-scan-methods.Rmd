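---
title: "Methods: windowed diversity, Fst and joint-tail sweep scanning"
author: "sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed diversity, Fst and joint-tail sweep scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it computes,
the assumptions behind them, the parameters that matter, and the design
choices made where more than one defensible option existed. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The scan model

The scan targets the classical signature of a recent selective sweep: in
the population where a beneficial allele rose, linked neutral diversity is
locally depressed, while allele-frequency differentiation against
unaffected populations is locally elevated. Two windowed statistics carry
the signal.

**Nucleotide diversity.** At a biallelic site with ALT allele count $a$
among $n$ non-missing alleles, the pair-counting estimator is

$$\pi = \frac{2\,a\,(n-a)}{n\,(n-1)},$$

the fraction of unordered haplotype pairs differing at the site —
equivalently $\sum_{ij} x_i x_j d_{ij}$ over haplotype frequencies with
$d_{ij}\in\{0,1\}$. Genotypes are treated as unphased; for a biallelic
site, allele counting and pair counting coincide, so no phasing is needed.
Windowed $\theta_\pi$ sums per-site $\pi$ over the SNPs in a window and
divides by window length in bp (invariant positions contribute zero). No
additional sample-size correction is layered on top: the plug-in
pair-counting form above is used verbatim so that the brute-force oracles
in the test suite match to machine precision.

**Fst.** The Hudson-style estimator
$F_{st} = (\pi_{between}-\pi_{within})/\pi_{between}$, with
$\pi_{within}$ the *unweighted* mean of the two within-population average
pairwise differences (the standard convention when no weights are stated)
and $\pi_{between} = p_A(1-p_B)+p_B(1-p_A)$ the average difference across
all inter-population haplotype pairs. Both components are summed across
the sites of a window, and the ratio is taken last — the "weighted" ratio
of sums, which is robust in sparse windows where a mean of per-site ratios
would be dominated by low-information sites. The genome-wide value is the
same ratio over genome-summed components; it is invariant to chromosome
relabelling.

One finite-sample subtlety: $\pi_{within}$ uses the unbiased
$n(n-1)$ pair denominator while $\pi_{between}$ has no self-pair term, so
two *identical finite samples* give a small negative Fst of order
$-1/(2n-1)$ rather than exactly zero; it vanishes with sample size and is
the expected behaviour of this estimator, not an error.

**θπ ratio.** Per window, $\theta_{\pi,A}/\theta_{\pi,B}$ with A the
control/reference group and B the target/case group, so a sweep in B
inflates the ratio. Because published comparisons report both elevated and
depressed ratio tails depending on which group is the numerator, the
orientation is always explicit in the comparison configuration and both
tails can be requested. Windows with $\theta_{\pi,B}=0$ are flagged
undefined — not infinite — and are excluded from the empirical
distribution rather than imputed.

## Window selection, regions, sharing

Windows are fixed-size (default 20,000 bp) at starts $0, s, 2s, \dots$
(default step $s$ = 5,000 bp), per chromosome, dropping trailing partial
windows. Thresholds are **nearest-rank empirical quantiles**: the right
5% tail selects the top $\lceil 0.05\,N\rceil$ finite values and reports
the smallest selected value, so thresholds are attained data values (the
style in which such scans report cutoffs like "Fst > 0.29"), with no
interpolation. Printed thresholds from any particular dataset are
properties of that dataset; the package always recomputes them.

A window is selected iff its Fst is in the right tail *and* its ratio is
in the requested tail; the joint condition can only shrink the selected
set, so the selected fraction never exceeds the tail fraction. Selected
windows that overlap or touch are merged into maximal half-open regions.
Genes overlap regions under a ≥ 1 bp rule, with GFF3's 1-based closed
intervals converted to the package's internal 0-based half-open
convention at the boundary.

Across comparisons, "shared" regions are the maximal intervals covered by
the merged regions of *every* comparison (≥ 1 bp intersection). Strict
interval equality was rejected as the sharing rule because sliding-window
phasing makes exact coordinates fragile; coverage intersection is
commutative and associative, which the tests assert. The full Venn
partition (counts of maximal intervals and of genes per membership
pattern) is emitted alongside.

Whether tail quantiles should be computed per chromosome or pooled across
the genome is not determined by the method itself; the package pools,
which keeps thresholds stable for short chromosomes.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
external data, and its defaults are the study conditions of the package's
own acceptance checks.

- Site positions are uniform (sorted) along each chromosome; counts are
  allocated to chromosomes proportionally to length.
- Ancestral ALT frequencies follow a neutral-SFS-like law: the ancestral
  allele count $i \in \{1,\dots,2N-1\}$ is drawn with probability
  $\propto 1/i$ over the pooled haploid count $2N$, so every emitted site
  is polymorphic in the ancestral pool and rare variants dominate, as in
  real data.
- Populations diverge under the **Balding–Nichols** model: population
  frequency $\sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with divergence
  parameter $F$ (`background_fst`). This is the simplest generator whose
  expected Hudson Fst equals a tunable constant, which the calibration
  tests exploit ($F = 0.05$, 2,000 sites, 2 × 20 diploids, 20 seeds).
- A sweep displaces the target population's frequency toward the nearer
  of $\{0,1\}$ by the exact closed form
  $q' = \tfrac12\left(1 \pm \sqrt{1-4(1-r)q(1-q)}\right)$, so expected
  heterozygosity inside the interval is multiplied by exactly $1-r$
  (`diversity_reduction`). Frequency displacement was chosen over
  forward simulation because it creates precisely the low-π/high-Fst
  signature the scan targets at desk scale, with an analytically known
  effect size.
- Genotypes are binomial draws given the population frequency; QD/FS/MQ
  and GQ annotations are drawn so a configurable fraction (default 2%)
  fails each hard-filter clause, exercising the filter stage.
- A binary phenotype is driven by causal SNPs inside a designated sweep:
  carriers of ≥ 1 derived allele are cases with probability equal to the
  penetrance, non-carriers with probability one minus it. Causal sites
  are the segregating sites in the interval with pooled MAF nearest 0.5
  — the most informative choice, emulating a common large-effect variant
  such as a horn-morphology locus. Effect sizes in the source study are
  unpublished, so these are explicit knobs, not estimates of any real
  population.
- All randomness flows through one seeded generator that saves and
  restores the caller's RNG state; a config seed fully determines every
  output byte, including the written VCF/GFF3/FASTA/TSV/JSON fixture set
  (`write_cohort()`, whose FASTA is forced to agree with every VCF REF
  allele and whose tiled gene models have frame-consistent CDS).

What the generator deliberately does **not** emulate: linkage
disequilibrium between simulated sites (sites are independent given
population frequencies), recombination maps, mutation-rate heterogeneity,
indels/SVs, and sequencing reads. Consequently, passing scan tests show
that the selection machinery finds frequency-displacement signatures at
the simulated divergence and depth — not that it is calibrated for the LD
structure of real genomes. Haplotype-level components (EM, D′/r², blocks)
are therefore tested against separately constructed haplotype-pair draws
with known composition, where recovery is measured against the realized
gamete frequencies of each sample (the identifiable quantity), not the
generating probabilities.

## Filtering and annotation

Hard filters apply the conventional variant-caller expression
`QD < 2.0 || FS > 60.0 || MQ < 40.0` at site level and mask genotypes
with `GQ < 20`. All inequalities are strict exactly as printed, so
boundary values pass; sites missing an INFO annotation fail closed. The
caller-side SNP-cluster clause (a window-based cluster filter) has no
published semantics precise enough to reproduce, so it is recorded in the
filter log as not applied rather than guessed at. Filtering is
idempotent. MAF is computed over non-missing alleles with all samples
pooled, and removal is strictly below the threshold. Multi-allelic
records are excluded (not split) and logged: every downstream statistic
assumes biallelic sites, and splitting would manufacture artificial
haplotypes.

Genic classification assigns exactly one label per site with precedence
exonic > UTR > intronic > upstream > downstream > intergenic; the
upstream/downstream flank is 1,000 bp, the conventional annotator
default, configurable. UTR is operationalized as gene body outside the
CDS span, since the gene models carry gene and CDS features.
Consequence calls rebuild the codon containing each CDS site from the
reference (reverse-complemented on minus-strand genes, CDS segments
spliced in transcription order), substitute the ALT base and translate
both codons with the standard genetic code; a REF/FASTA mismatch is a
hard error naming the site. The tests check this against an independent
oracle that translates the entire CDS protein for both alleles.

## Structure, association, haplotypes, enrichment

**Distances and trees.** The allele-sharing distance (per-site score 1,
0.5 or 0 for identical genotypes, one shared allele, opposite
homozygotes; averaged over co-typed sites) is standard for SNP NJ trees
and robust to missingness, which a raw Hamming distance is not. NJ uses
the Saitou–Nei agglomeration; taxa are sorted lexicographically first so
input order cannot change tie resolution, and negative branch lengths are
clamped to zero. Site-bootstrap support is available (default 100
replicates, a desk-scale choice). PCA standardizes dosages by
$\sqrt{2p(1-p)}$ — the GRM convention of GCTA-class tools — sets missing
standardized entries to zero, eigendecomposes the sample covariance and
fixes each component's sign so its largest-magnitude loading is positive.

**Association.** The per-SNP test is the allelic 2 × 2 Pearson chi-square
(1 df, no continuity correction), replaced by Fisher's exact test when
any expected cell is below 5, with BH adjustment across tested SNPs;
genotype count tables are emitted alongside for transparency. The allelic
test was chosen because published per-SNP p-values of this kind rarely
name a genotype model; note it assumes pooled Hardy–Weinberg proportions
and is mildly anticonservative under population structure (Wahlund
excess homozygosity) — the null-phenotype tests therefore bound rather
than pin its size, and structured cohorts should treat borderline
p-values with care.

**Haplotypes and LD.** Haplotype frequencies over $k \le 8$ SNPs are
estimated by EM on the multinomial haplotype-pair likelihood under
Hardy–Weinberg pairing (the study data such follow-ups use are unphased).
The E-step distributes each multi-heterozygous genotype over compatible
phase resolutions proportionally to current frequency products; the
M-step re-estimates frequencies; convergence is a log-likelihood gain
below $10^{-8}$, with the monotonicity of the likelihood asserted at
every iteration (a decrease is treated as a bug, not a warning). Five
starts (one uniform, four random) guard against local optima and the
best likelihood is kept. Haplotypes at frequency ≥ $10^{-3}$ are reported
as "identified" — the operational meaning of statements like "four
haplotypes were identified". Samples missing a genotype at any block SNP
are excluded from the fit. Pairwise D′ and r² come from 2-SNP EM fits
($D = p_{AB}-p_Ap_B$, $D' = |D|/D_{max}$, $r^2 = D^2/(p_A(1-p_A)p_B(1-p_B))$);
a block is the maximal run of consecutive SNPs with all pairwise
$r^2 \ge 0.5$ (threshold configurable, ties leftmost) — a deliberately
simple, reproducible rule standing in for unstated block heuristics.

**Enrichment.** One-sided hypergeometric over-representation
($p = P(X \ge k)$ with universe $N$, pathway $K$, candidates $n$), BH
adjustment across pathways, significance at $q \le 0.05$ inclusive. The
default universe is all genes in the gene model, overridable — enrichment
backgrounds are the most common source of irreproducible pathway claims,
so the choice is explicit. Depletion is not tested.

## Problem sizes and determinism

The test-suite and acceptance-script scales are the package's chosen
study conditions: 2 × 20 diploids and 2,000 neutral sites for Fst
calibration (20 seeds); a 200-kb, 80%-reduction sweep on a 5-Mb
chromosome with 5,000 sites for recovery and null control (20 seeds
each); 3-SNP/4-haplotype blocks with 200 diploids for EM recovery (100
replicates); 6-taxon additive matrices for NJ (10 replicates); 500
replicates for the enrichment null; 2 × 50 diploids for association
power (20 seeds). Every stochastic component takes an explicit seed, and
the pipeline's summary JSON is byte-identical across reruns of the same
config.

## Known limitations

- Independent-site simulation cannot exercise LD-aware behaviour of the
  scan itself; sweep recovery rates measured here do not transfer
  directly to organisms with strong local LD.
- The allelic association test is approximate under structure (above);
  no covariate-adjusted model is provided.
- The EM haplotype space is capped at $2^8$; larger blocks should be
  pre-pruned.
- Gene-set enrichment results depend entirely on the user-supplied
  gene-set file and universe; the package ships no database content.
- Maximum-likelihood phylogenetics and Bayesian admixture estimation are
  out of scope by design; the NJ tree and PCA are descriptive summaries.
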