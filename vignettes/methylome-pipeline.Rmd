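---
title: "Methods: methylome characterization and expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome characterization and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdpipe)
```

`mbdpipe` implements the analysis layer of a two-organ MBD-seq methylome
comparison: peak annotation and density normalization, metagene
profiling, CpG-island (CGI) detection and methylation calling,
differential methylation with gene-level aggregation, and a resampling
test for the overlap between differentially methylated and differentially
expressed genes. This vignette records the models behind each stage, the
parameters that matter, the numerical decisions, and what the synthetic
data generator does and does not emulate.

## Coordinate conventions

Every interval inside the package is 0-based half-open (`[start, end)`,
the BED convention). GFF3 input and output (1-based inclusive) is
converted at the reader/writer boundary and nowhere else; a shared
validation helper asserts `0 <= start < end <= chromosome length` on
every interval entering a module. Peaks are unstranded (MBD pull-down has
no strand information); genes are stranded and strand is honoured
wherever gene geometry matters.

## Peak annotation and density normalizations

Each base of the genome is assigned to exactly one region category given
the annotation and a `region_config()`:

* **exon** — inside an annotated exon;
* **intron** — inside a gene body but not an exon;
* **promoter** — within `promoter_bp` (default 2,000 bp) upstream of the
  CDS start, strand-aware; the promoter is anchored at the CDS start
  because the annotations this pipeline targets lack reliable TSS/UTR
  models;
* **downstream** — within `downstream_bp` (default 2,000 bp) past the CDS
  end; a single downstream category is used instead of a 3′ UTR for the
  same annotation-quality reason;
* **distal** — within `distal_bp` (default 10,000 bp) beyond the promoter
  or downstream flank;
* **intergenic** — everything else.

When a base qualifies for several categories (through one gene or through
neighbours), the first match in the priority order
`exon > intron > promoter > downstream > distal` wins, so genic signal is
not diluted by a neighbouring gene's flank. The order is a config field,
not a constant. Because the masks partition the genome, category bp
counts always sum to the peak length — an invariant the test suite checks
on random peak sets.

Region density for an organ is
`peak bp in category / mean region length / total peak count`, with fixed
flank categories using their configured extents as "mean length" and the
exon/intron means taken over the annotation. A category with no annotated
regions is reported `NA` (undefined), never 0. Per-chromosome density is
`(peaks on chromosome / length in Mbp / total peaks in replicate) x 1e4`;
the x10,000 is a display convention and cancels in all comparisons. The
normalization by *peak count* (not read count) follows the published
figure convention this pipeline mirrors; callers with per-sample read
totals can rescale externally since the ratio is linear in the
denominator.

Organ comparisons (chromosome density, methylated-CGI density, and DMR
depth) all reduce to the same statistic: a two-sided two-sample Student
*t*-test per feature across replicates with Benjamini–Hochberg adjustment
across features (`row_t_test()` + `p.adjust(, "BH")`). The classic
pooled-variance form is the default to match the named method; Welch is a
flag. Features where both groups have zero variance and equal means
return p = 1 (no evidence) rather than an error; zero variance with
unequal means returns p = 0.

## Metagene profile

Genes are mapped to 80 normalized positions: 20 fixed-width windows over
the 2 kb upstream flank, 40 equal windows over the body (CDS start to CDS
end), 20 windows over the downstream flank, position 1 always 5′.
Minus-strand genes are computed in genomic order and reversed, which
makes strand-flip symmetry exact (a property test mirrors an entire
chromosome and compares profiles bit for bit). Window boundaries use
floored integer breaks, so bodies not divisible by 40 get windows
differing by at most 1 bp. Genes shorter than 40 bp cannot form 40
windows and are excluded. Flank windows running off a chromosome
contribute only their in-bounds bases; a window with no in-bounds base
contributes nothing for that gene. Depth can be a per-base coverage track
(bedGraph) or the binary peak-presence track, which is what peak-only
input supports; `scale_factor` hosts library-size normalization (e.g.
total signal / 1e6) so the profile function itself stays an exact
geometric average.

## CpG-island detection

Islands are defined by three criteria — length strictly greater than
200 bp, GC fraction ≥ 0.5, observed/expected CpG ratio ≥ 0.6 — applied
through the classic sliding-window scheme: slide a 200-bp window in 1-bp
steps, mark windows passing both composition criteria, merge
overlapping/adjacent passing windows, then trim each merged candidate one
base from *both* ends until its full extent passes both criteria, and
keep candidates still longer than 200 bp. The observed/expected ratio is
the standard `(N_CpG × L) / (N_C × N_G)`, taken as 0 when the window has
no C or no G. Windows containing `N` never pass: ambiguity cannot certify
GC content. The implementation is a cumulative-sum scan (O(1) per window
and per trim step); the test suite holds it to exact agreement with a
brute-force enumerate-merge-trim oracle on sequences up to 5 kb.

Two consequences of the strict length rule are worth knowing. An isolated
single passing window yields a 200-bp candidate and is rejected, so
"every passing window lies inside a reported island" holds only for
islands comfortably longer than the window — the regime the planted
islands occupy. And merging extends a true island by up to ~150 bp of
partially overlapping windows on each side before trimming, so detected
islands are slightly wider than planted ones; the recovery check
therefore uses 80% reciprocal overlap.

## CGI methylation calls

An island is methylated in a sample when at least 90% of its length
(inclusive threshold) is covered by the union of the sample's peaks —
coverage is a union, never a sum, so stacked peaks do not double-count.
The 90% is `threshold` in `call_methylated()`. An organ-level call is a
replicate consensus; the default is majority (≥ half of replicates), with
`any`/`all` available because three-animal designs do not determine the
rule. Rates are reported overall and per chromosome, the latter also per
Mbp for density-style comparisons, and chromosomes with no islands are
omitted with a warning rather than silently reported as zero.

## Differential methylation and DMGs

No published description fixes the DMR unit, so the package defines it:
candidate regions are the union-merge (book-ended intervals merged) of
every sample's peaks across both organs, each region summarized per
sample as mean per-base depth normalized by total signal / 1e6. Testing
is the shared *t* + BH machinery on `log2(depth + 0.5)`; depth noise from
enrichment sequencing is multiplicative (the generator plants lognormal
noise), and on the log scale the Student test is exact, which keeps the
planted-recovery behaviour stable at 3-vs-3 replicates. Raw-scale testing
is a flag (`log2_transform = FALSE`), and the pseudocount only matters
for empty regions. A DMR is a region with BH-adjusted p below
`alpha = 0.05`, directed toward the organ with the larger mean.

A DMR supports every gene whose body it overlaps by ≥ 1 bp (overlap, not
containment — one region can support several genes, and several regions
one gene). A gene's direction is the majority of its supporting DMRs;
exact ties put the gene in both directional lists, forming the "shared"
class, and the summary applies inclusion–exclusion
(`n_unique = n_a + n_b − n_shared`).

## Overlap testing (jackknife and its closed form)

The enrichment of an observed overlap between two gene lists is judged
against a resampling null: each simulation draws two independent uniform
subsets of the observed sizes from an N-gene universe and records their
intersection size. Conditioned on the first subset, that intersection is
exactly hypergeometric, so the default engine draws intersection sizes
directly (`rhyper`), which is distributionally identical to materializing
subsets and orders of magnitude faster; materialized-subset sampling
remains available (`method = "subset"`) and the tests verify the two
agree. The analytic moments (`hypergeometric_oracle()`) are
`mean = n_A n_B / N` and `sd = sqrt(mean (N−n_A)/N (N−n_B)/(N−1))`,
checked against exhaustive subset enumeration for small N.

Two p-values are reported: the one-sided empirical
`(1 + #{sim ≥ obs}) / (n_sims + 1)`, floored at `1/(n_sims+1)` by
construction, and the two-sided Gaussian tail of
`z = (obs − mean)/sd` — published resampling p-values far below the
empirical floor can only come from a parametric tail, so both views are
kept, and depletion (observed below expectation) is flagged through the
Gaussian tail. `directional_correlation()` runs the four pairings
hyper×over, hypo×under (positive correlation) and hyper×under, hypo×over
(negative correlation), requiring the directional lists to be disjoint
within methylation and within expression.

When reproducing published overlap statistics the universe size N must be
known; it is recoverable as `n_A n_B / mean` from reported simulation
means, and the package leaves N a required argument rather than guessing.
For fresh analyses N defaults naturally to the number of genes in the
annotation.

## The synthetic study and what it shows

`synthetic_config()` freezes the study conditions the tests run under:

| parameter | default | rationale |
|---|---|---|
| genome | 4 × 300 kb | desk-scale, multi-chromosome |
| background GC | 0.40, CpG-depleted | mammalian-like; depletion keeps spurious islands rare |
| planted CGIs | 10 × 2,000 bp, GC ≈ 0.85, obs/exp ≈ 1.3 | well inside the detection criteria; 2 kb keeps 80% reciprocal recovery attainable given ~150 bp merge widening |
| genes | 120, 1.5–4 kb, ≥ 4 kb gaps | room for 2 kb flanks without overlap |
| replicates | 3 per organ | the three-animal design |
| baseline regions | ~300 shared, depth ~ lognormal(log 10, σ = 0.2) | shared peak architecture, multiplicative noise |
| planted DMRs | 20 at 8× depth, half per organ | large effect so 3-vs-3 recovery is stable, mirroring small-n designs |
| DEGs | 60 significant (FDR < 1e-4), coupling ρ = 0.6 | a strong planted hypo-methylation → over-expression link |

Coupling-detection runs use a larger, sequence-free configuration (5,000
genes on 4 × 12 Mb, 400 planted DMRs so ~200 hypo-methylated genes, 1,000
DEGs) because overlap tests need a universe large enough for the
hypergeometric null to have resolution. Each generator stage draws from
its own stream (master seed + fixed offset), so regenerating one file
never perturbs another, and a fixed seed reproduces every output byte for
byte.

The generator emulates peak architecture, replicate noise, planted
differential signal and list-level expression coupling. It does **not**
emulate read-level sampling, fragment-size effects, CpG-density-dependent
MBD affinity, correlated placement of peaks over CGIs, batch effects, or
annotation error — so green recovery tests demonstrate that the
*inference machinery* is correct under its stated noise model, not that
the pipeline is robust to every artefact of real MBD-seq data.

## Problem sizes and runtime

The shipped test suite and the acceptance script run at the sizes above:
100,000 simulations per overlap test, 1,000 regions × 20 seeds for null
FDR calibration, 5 seeds for recovery checks. These sizes put Monte-Carlo
error well below the assertion tolerances (4 standard errors for
simulated means, binomial 4σ for the null p-value rate) while the whole
suite stays inside a workstation minute-scale budget.

## Known limitations

* The DMR unit (union-merged peak regions) is this package's definition;
  fixed windows or per-peak testing would give different region counts.
* Organ-level CGI calls and gene direction ties are resolved by
  documented conventions (majority; both-lists) that a specific study may
  define differently.
* The promoter is CDS-anchored; with TSS-bearing annotations a TSS
  anchor would be preferable.
* With only peak-level input, metagene and depth matrices use binary
  peak presence, which flattens within-peak depth structure.
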