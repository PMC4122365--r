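---
title: "Fixed-difference scanning of pooled evolve-and-resequence data: models and methods"
author: "poolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-difference scanning of pooled evolve-and-resequence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The experimental design being analysed

In an evolve-and-resequence (E&R) experiment, replicate populations founded
from a common panel of isogenic lines are selected for many generations,
after which pooled DNA from each population is short-read sequenced. poolscan
analyses the three-pool variant of this design: one unselected control pool
(C1) and two independently selected replicate pools (H1, H2). Because the
replicates share only the selective regime — drift is independent between
them — a variant driven to fixation by selection should be fixed in *both*
selected pools while remaining rare in the control, whereas drift produces
discordant patterns. Every statistic in the package is built on that
contrast.

The units of analysis are per-site pooled read counts. A pooled read count
is a noisy estimate of the population allele frequency; the package never
attempts genotype reconstruction.

## Evaluable loci

Pool-seq read data is uneven, and calling at poorly covered or badly mapped
sites produces artifacts. A site is **evaluable** only when, in *all three*
pools, it has:

* read depth ≥ 10 (`min_depth`),
* consensus base quality ≥ 20 (`min_baseq`),
* best read mapping quality ≥ 40 (`min_bestq`).

All downstream statistics — calling, FDR estimation, per-arm summaries —
are restricted to evaluable loci. The thresholds are exposed in
`quality_thresholds()`; the defaults are the conventional pool-seq values
for ~15–20× data and correspond to a raw error bound of 1% (Q20) per base
call and essentially unique mappings (Q40).

## Fixed-difference SNP calling

At an evaluable site, let `f_p(b)` be the frequency of base `b` in pool `p`,
computed as count over the sum of A/C/G/T counts (reads carrying a deletion
or an N do not dilute the denominator; a `freq_denominator = "depth"` toggle
uses raw depth instead, since either convention is defensible). The control
consensus is the majority base of C1, with ties broken toward the reference
— a deliberately conservative rule that suppresses calls at ambiguous
control sites. A SNP is called when each selected pool has a candidate base
(its majority base — unique because the fixation threshold exceeds 50%)
that:

1. differs from the reference base *and* from the control consensus,
2. reaches frequency ≥ 0.90 in its own selected pool (`fix_threshold`),
3. has frequency ≤ 0.10 in the control (`rare_threshold`).

Identity of the H1 and H2 alleles is recorded (`h_identity`) but not
required by default: concordance of the two replicates is an *observable*,
and on strong-selection simulations the identity fraction among calls is
100% without ever being imposed (the acceptance suite measures exactly
this). When the two selected pools fix different non-reference,
non-control bases — possible only at tri-allelic evaluable sites — the call
is emitted with `h_identity = FALSE` and both alleles recorded; note that a
single per-pool frequency pair cannot then refer to one shared allele, so
`freq_H1`/`freq_H2` each refer to the pool's own fixed base.

## Small-indel calling

Indel evidence is strand-resolved read support for an insertion or deletion
event at a site. The call requires, at an evaluable site:

1. a strand-support type in each selected pool: `"*"` (at least one
   supporting read on each strand) or `"+"` (at least two supporting reads
   on one strand);
2. depth ≥ 10 in both selected pools (an explicit coverage criterion,
   independent of the mask's threshold);
3. event support ≥ 90% of reads in both selected pools;
4. control support of at most `control_absence_max_reads` reads (default 0
   — "absent from the control"). How strictly absence should be
   operationalized is genuinely open, so the bound is a config knob.

The call's type is `"*"` only when both selected pools have two-strand
support. Because single-base indels inside homopolymer runs are the classic
short-read artifact, `flag_homopolymer()` marks calls whose event sequence
is a single repeated base adjacent to (within 1 bp of) a reference run of
that base of length ≥ `min_run` (default 5). Flagged calls are annotated,
never dropped: run-length 5 separates most polymerase slippage contexts
from unproblematic sequence, but the cost of the flag is zero while silent
removal is not auditable.

## Reciprocal-replicate FDR

Since H1 and H2 differ from each other only by drift and sampling, applying
the *discovery* criterion between them estimates how often chance alone
produces a fixed-vs-rare pattern: a locus counts when one selected pool's
majority base differs from the reference at frequency ≥ 0.90 while that
base is ≤ 0.10 in the *other* selected pool. Both directions are scanned
and a locus counts once. The reported FDR divides this count by the number
of called SNPs (default) or by the number of evaluable loci
(`denominator = "evaluable"`); both denominators are offered because the
natural scale of the estimate depends on how it is used.

One property matters for interpretation, and the package's null simulations
quantify it: under pure drift the reciprocal (discordant) pattern is
strictly *more* probable than the pattern a false call requires — the false
call needs concordant near-fixation of the same allele in both selected
pools *plus* rarity in the control, while a reciprocal locus needs only one
fixation and one rarity. The estimator is therefore conservative: it
upper-bounds the realized false-discovery rate rather than estimating it
unbiasedly. The acceptance suite contains a calibration check comparing the
mean reciprocal estimate with the realized false-call rate over 50
drift-only experiments; the measured gap (reciprocal rate of order 2×10⁻³
per evaluable locus against a realized false-call rate near zero) is the
quantitative form of this bias, and the check is expected to reflect it.
Treat the reported FDR as a guarantee ("no worse than"), not a point
estimate.

## Extended genes, regions, coding effects

Variants are annotated against gene models widened by a `flank` of 2000 bp
on each side ("extended genes"), capturing proximal regulatory sequence.
The flank is a command-level parameter; 2 kb is the package default.
Within each extended span a strand-aware six-way partition is built —
upstream, 5′ UTR, CDS exon, intron, 3′ UTR, downstream — that tiles the
span exactly once per gene. UTRs are inferred as exon-minus-CDS when the
annotation has no explicit UTR features. A call maps to *every* gene whose
extended span contains it; overlapping genes are never merged, and a
multi-gene call contributes one polymorphism to each gene's tally. Calls in
no extended gene are kept in an explicit intergenic bucket so counts are
conserved.

Coding effects are classified by reconstructing the affected codon from the
spliced CDS (strand-aware, frame from segment order), substituting the
alternate base (complemented on the minus strand), and comparing
translations under the standard genetic code: synonymous, nonsynonymous,
nonsense (gained stop), lost-stop. A destroyed start codon (e.g. ATG→CTG)
is classified nonsynonymous by the plain codon table — deliberately so; the
package does not model alternative initiation.

## Density and enrichment statistics

The genome-wide polymorphism density is
`mu = (polymorphisms mapped to extended genes) / (total extended-gene length in kb)`.
To stay consistent with per-gene counting, the default denominator sums
per-gene extended lengths with overlaps double-counted; a non-redundant
union denominator is available (`nonredundant = TRUE`). Per-gene densities
are reported as multiples of `mu`, and gene lists can be filtered at any
multiple (2µ, 3µ, 10µ) or absolute density (e.g. ≥ 0.9/kb).

Two hypergeometric tests are provided. The **locus-level** test asks
whether polymorphic positions concentrate in a target set's extended genes:
of `N` positions in the universe's extended genes, `K` lie in the target's;
`n` positions are polymorphic, `k` of them in the target. Positions are
deduplicated within a set (the unit is the genomic position); a toggle
restricts the position universe to evaluable loci when a pool table is
supplied, since whether "loci" should mean all positions or evaluable ones
is unstated in general. The **gene-level** test is the classic overlap
test between a polymorphic gene set and a target set within a declared gene
universe. Both report the upper tail `P(X ≥ k)`; across many pathway sets,
Benjamini–Hochberg q-values are reported alongside raw p, with raw p as the
primary output.

`hypergeom_upper_tail()` sums the probability mass in log space
(`lchoose` plus incremental log-sum-exp), so tail probabilities in the
10⁻³⁰ range retain full relative precision; the suite verifies agreement
with exact integer summation for N ≤ 30 and with R's independent `phyper`
implementation to ≤ 10⁻¹⁰ relative error over the full N ≤ 60 grid.

## The synthetic-data generator

The simulator emulates the resequencing design end-to-end so every stage of
the pipeline can be scored against known truth.

**Founders.** A panel of 27 isogenic lines (configurable) carries
polymorphic sites scattered uniformly at a chosen density (default in the
pipeline demo: 2 sites/kb). Each neutral site has its derived allele in
`k ~ Uniform{1..13}` founder lines, spanning the frequency spectrum
attainable with 27 lines; starting frequency is `p0 = k/27`. **Selected
sites carry their derived allele in a single founder line.** This is a
design statement about the biology of the experiment, not a convenience:
the fixed-vs-rare contrast only exists for adaptive variants that start
rare, because an unselected control keeps a mid-frequency variant at mid
frequency, placing it outside the ≤ 10% control criterion no matter how
strongly the selected populations respond. A configurable fraction of
sites (default 5%) are single-base indels, modelled as duplication or
deletion of the reference base at the site so the event sequence is always
derivable from the reference.

**Evolution.** Each of the three populations evolves independently from
`p0` by Wright–Fisher binomial sampling of `2N` gametes per generation,
with selection entering through the expected frequency
`p' = p(1+s)/(1+ps)`; the control has `s = 0` everywhere. Sites evolve
independently (free recombination) — the calling statistics are all
per-site, so linkage matters only for clustering questions the package does
not address. The per-chamber effective population size is not something the
emulated design pins down, so `pop_size` is a free parameter (calibration
runs in the test suite use Ne = 500).

**Pools.** Sequencing pools of 100 males + 100 females (configurable) are
drawn without replacement, making pooled allele counts hypergeometric:
2 copies per individual on autosomes, and `2·females + males` copies on the
X (males hemizygous). X copy number is modelled because chromosome-level
normalization is part of the analysis; hemizygosity is applied at the
pool-sampling step only, not during evolution.

**Sequencing.** Per site and pool: depth ~ Poisson(`mean_depth`); each read
samples its allele from the pooled frequency; with probability `base_error`
(default 0.005) the reported base flips to a uniformly chosen other base.
Deletion-carrying reads report no base (so base counts sum to depth minus
deletion support — the dialect's invariant); insertion reads report the
reference base; indel support splits between strands by fair coin. Quality
fields are drawn per site and pool: base quality ~ round N(35, 5), best
read quality ~ round N(50, 10), clamped at zero. These defaults produce a
realistic *mixture* of passing and failing sites around the 20/40 masking
thresholds — about 60% of loci are evaluable in all three pools at 15–20×,
comparable to the ~50% evaluable fraction typical of real pool-seq data at
similar depth.

**Truth table.** Each simulated site records `p0`, the true final frequency
per population, the selected flag, and `expected_callable`: whether the
site satisfies the calling definition *on true population frequencies* —
the fixed/rare thresholds for SNP sites, and fixation plus exact control
absence (true control frequency 0) for indel sites, mirroring each variant
type's own control criterion.

**What passing tests do and do not show.** The generator draws site
frequencies independently, emits symmetric single-base errors, has no
alignment step, no reference bias, no copy-number variation, no correlated
quality artifacts, and no linkage by default. Tests passing on this
substrate validate the *statistical logic* of the pipeline — masking,
calling arithmetic, FDR construction, annotation geometry, enrichment
probability — not robustness to alignment artifacts or demographic model
misspecification in real data.

## Recall, and what bounds it

Recall of planted sweeps is defined over targets the design can expose:
planted loci that are **evaluable** (the caller never sees masked loci; the
quality-emission model itself leaves ~40% of loci masked) and
**expected-callable** (over 180 generations at moderate Ne, a noticeable
fraction of initially-rare planted alleles drift above the 10% threshold in
the control population — by the fixed-difference *definition* those loci
are not callable, regardless of caller quality). Within that denominator the
remaining misses are read-level sampling at the control boundary: at 20×, a
control allele at true frequency 0.08 exceeds the ≤ 10% read criterion
(≥ 3 of 20 reads) roughly a quarter of the time. The acceptance suite
measures recall ≥ 95% over 100 replicate experiments at s = 0.2,
Ne = 500, G = 180, 20×; at that replication the Monte-Carlo standard error
of the recall estimate (~0.6%) is small against the margin being asserted,
which it is not at a handful of replicates.

## Enrichment power simulations

Power is assessed by planting polymorphic positions with 5× preference into
one designated pathway of a 10-pathway, 200-gene synthetic annotation. The
planting model is stratified: the target-vs-rest split is binomial with
odds `fold·K : (N−K)`, positions uniform without replacement within each
stratum — the standard operationalization of "fold-times preferential"
(exact weighted sampling without replacement over ~10⁶ positions is
Wallenius-type and computationally disproportionate for no inferential
gain). Specificity is checked on a *conditional* position space: everything
outside the planted set's extended spans. This matters for two reasons:
with a fixed polymorphism budget the planted excess mechanically depletes
every other set, making naive off-target p-values conservative rather than
uniform; and neighbouring extended genes overlap the planted spans (2 kb
flanks against 500 bp intergenic gaps in the synthetic annotation), so the
exclusion must be applied to the position universe, not just to the calls.
Within the conditional space the non-target draw is exactly uniform and an
unplanted pathway's upper-tail p is null-distributed, which the suite
verifies with a Kolmogorov–Smirnov test.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive in every file format (GFF3/VCF
  convention); interval arithmetic is done through IRanges.
* A pool with zero base-count denominator yields undefined frequencies and
  can never satisfy a calling criterion.
* Majority-base ties break toward the reference (control consensus) —
  conservative; the fixed-allele candidate is unique since
  `fix_threshold > 0.5` is enforced.
* `P(X ≥ k)` returns exactly 1 for `k ≤ 0`; argument bounds are validated,
  not clamped.
* Zero reciprocal loci give FDR 0; reciprocal loci with a zero denominator
  raise an error rather than returning infinity.
* All randomness flows from explicit seeds; the pipeline derives per-stage
  substreams from one global seed, so a run directory is reproduced
  byte-identically from (config, seed).

## Problem sizes used by the test suite

The suite simulates 100 kb genomes at 2 polymorphic sites/kb (200 sites),
Ne = 500, 180 generations, 15–20× depth; 50 drift-only experiments for null
calibration, 100 selection experiments for recall, 100 planting rounds for
enrichment power; caller/oracle equivalence is exhaustive over all 753,571
three-pool count configurations to depth 12, and hypergeometric agreement
is exhaustive over the N ≤ 60 grid (~1.2 million tail evaluations). These
sizes give each stochastic assertion a Monte-Carlo error well inside its
stated tolerance while keeping a full run of the suite in the minutes
range.

## Known limitations

* Frequencies are treated as read proportions; no model-based
  allele-frequency estimation (and none of the CMH/quasi-binomial family of
  pool-seq tests — the fixed-difference criterion is the method).
* Single-base indels only; no multi-base or complex events.
* Transcript-isoform-aware effect prediction, splice-site and regulatory
  motif classes are out of scope; one transcript per gene is assumed.
* The reciprocal FDR is conservative by construction (see above).
* The simulator's independence assumptions (sites, reads, qualities) are
  idealizations; see "What passing tests do and do not show".
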