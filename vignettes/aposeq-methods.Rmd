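---
title: "aposeq: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aposeq: models, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

aposeq packages the computational stages needed to dissect apospory loci in
a polyploid apomict by comparing a parent genotype against deletion
mutants. This vignette is the package's own account of the underlying
models and of the choices made where the design was genuinely open. All
genomic coordinates are 0-based half-open internally; GFF3 and SAM
conventions are restored at the I/O boundary. The package-wide fold-change
sign convention is `log2fc = log2(reference / comparison)`.

## Genotype calling and deletion scenarios

Per site, the two site alleles (major/minor) are defined from allele counts
pooled over all samples. A sample with zero depth is `--`; below
`min_depth` (default 8 reads) it is `NA`; with minor-allele frequency at
least `maf_min` (0.25) it is heterozygous `AB`; at most `hom_err_max`
(0.05) it is homozygous `AA`, reported as `A-` for the parent when no
second allele is seen in any sample; frequencies between the two cutoffs
are ambiguous (`NA`). Only the 0.25 MAF rule is dictated by the study
design; `min_depth` and `hom_err_max` are conventional RNA-seq genotyping
guards — at depth 8 and a 1 % sequencing error rate the chance of two
same-base errors (which would push a site past `hom_err_max`) is already
negligible, while depth below 8 cannot distinguish AB from AA reliably.

Scenario 1 (loss of one homeologous copy) requires the parent `AB` and
every mutant `AA` for the *same* retained allele, which must be one of the
parent's two alleles. Scenario 2 (loss of a hemizygous gene) requires the
parent `A-` and every mutant `--`; when sites are mapped to genes, the
absence-of-reads condition is enforced across *all* of a gene's covered
sites (`max_stray_reads`, default 0, tolerates contamination if raised).
The two parent patterns are mutually exclusive, so no site can support both
scenarios. Candidates are summarised per gene or contig, ranked by
supporting-site count with lexicographic tie-breaks; `min_support` defaults
to 1 because nothing in the study design fixes how many corroborating SNPs
defined a reported contig.

## Small RNA placement and annotation

Tags are kept when 18–25 nt long and seen at least `min_tag_count` (5)
times in some sample; the count filter is `>= 5` by default because the
stricter "more than five" variant appears only once in the protocol the
package follows, and both are exposed through `min_tag_count`. Placement
allows up to 2 substitutions plus at most one internal microindel of 1–2
nt, on both strands, reporting *all* qualifying placements. The compiled
aligner is seed-and-extend: each tag is split into four blocks, so any
qualifying placement (at most 3 edit events) leaves one block event-free,
and that block's leading 4-mer indexes candidate starts; candidates are
verified directly against the definition. Per (start, strand) one alignment
is recorded, preferring substitution-only over indel interpretations, then
fewest substitutions, then the shorter indel, with a genome-insertion
checked before a genome-deletion. `N` never matches. A brute-force
full-scan oracle in the test suite checks exact equality of placements.

A placement is assigned to a gene by its 5′-most base (start on `+`,
`end − 1` on `-`): deterministic, order-free, and well-defined for reads
straddling a boundary. Class precedence is gene body (CDS blocks plus the
introns between them) over UTRs over the strand-relative ±500 bp flanks. A
placement inside two genes' extended regions is counted for both and
flagged ambiguous (`unique_gene = TRUE` drops such placements instead);
counting every placement of a multi-placed tag, rather than once, is the
default because the upstream alignment policy allows multi-locus reads —
both behaviours are auditable from the assignment table.

## MIRNA hairpin acceptance

Candidate arms are distinct tags perfectly placed (0 mismatches, no indel)
on the same contig and strand with 5′-start distance ≤ 400 bp (inclusive —
the window is stated only as "within 400 bp", and the inclusive reading is
the weaker assumption) and non-overlapping spans. Acceptance requires:

1. duplex paired fraction ≥ `duplex_min_paired` (0.6), scored by
   Watson–Crick plus G:U wobble complementarity of the left arm against the
   reversed right arm over a ±2 nt offset scan;
2. an inter-arm loop of at least `min_loop` (3) nt;
3. a contiguous helix of ≥ 7 base pairs within the best duplex;
4. ≥ 3/4 of left-arm bases pairable into the right arm under a
   Nussinov-style recursion restricted to inter-arm pairs (maximum
   non-crossing pairing, bulges free).

Two of these deserve comment. Maximum-cardinality folding of the *whole*
precursor was evaluated and rejected as the arm test: with wobble pairs a
random precursor admits so many maximum structures that a traceback can
nearly always route the left arm onto the right arm — the criterion passes
vacuously and carries no discrimination. The helix rule is the structural
criterion that actually separates real duplexes from chance complementarity:
real miR/miR\* duplexes pair in long helices with isolated defects, and the
generator's construction guarantee (a star arm with at most 2 injected
mismatches) leaves a contiguous run of at least ⌈19/3⌉ = 7 pairs in the
worst case, which fixes the threshold a priori. Likewise the 3/4 inter-arm
bound sits below the construction's worst case of 19/21 ≈ 0.90. Under these
rules every implanted locus is accepted, while the pooled acceptance rate
on shuffled-genome controls stays below 1 %. Energy-based folding is
deliberately out of scope; the exported `nussinov_pairs()` (min loop 3,
exact by enumeration oracle) keeps the package self-contained.

## Differential expression

`tmm_factors()` implements trimmed-mean-of-M normalisation: per-gene log
ratios against a reference sample (chosen by the upper-quartile rule when
unspecified), doubly trimmed — 30 % per tail on M, 5 % per tail on A — and
combined with inverse asymptotic-variance weights; factors are rescaled to
geometric mean 1. The test suite checks identity and globally-scaled
libraries exactly and agreement with an independent implementation to
3 decimal places on spiked matrices.

`nb_exact_test()` compares group sums of counts equalised to a common
effective library size under a shared-mean NB model
(`variance = μ + φμ²`): conditional on the total `t`, the two-sided
*p*-value sums every outcome of the group-A sum whose conditional
probability does not exceed the observed one. At `φ = 0` this reduces
exactly to the binomial split, which the tests verify by exhaustive
enumeration. With replicates in both groups the common dispersion is the
unweighted mean of per-(gene, group) moment estimates `(s² − m)/m²` at mean
≥ 10 — individually these are extremely noisy at n = 2, but their sampling
variance is nearly constant for well-expressed genes, so the plain mean is
close to the optimal combination (an m⁴-weighted regression was tried and
discarded: it is dominated by a handful of the most-expressed genes and
swung by a factor of two across seeds). Without replicates a fixed 0.1 is
used. Benjamini–Hochberg adjustment is the step-up procedure, checked
against hand-computed vectors and `p.adjust`.

mRNA calls use the inclusive thresholds adjusted *p* ≤ 0.01 and
|log2fc| ≥ 1. Small RNA contrasts (single replicates in the study design)
default to fold-only calling with pseudocount 1 on normalised counts,
|log2((a+1)/(b+1))| > 1 strictly. Flags are invariant under global
rescaling of all libraries *up to discreteness*: pseudocounts and the
rounding of equalised counts can move a gene sitting exactly on a decision
boundary, and a depth change legitimately changes the evidence an exact
test sees, so the property test asserts invariance away from the
boundaries and fold-change agreement to 0.01.

### Benchmark design for parameter recovery

The recovery benchmark implants 4-fold changes (log2fc ±2) at dispersion
0.1 with 2 replicates per group. Power at the study thresholds is governed
by the BH cutoff: at high expression the log-ratio SD saturates near
`sqrt(2φ/n) ≈ 0.32` (natural log), an effect z of ~4.4, so the panel must
put the BH threshold's z below ~3.2 for power comfortably above 0.8. The
benchmark therefore uses 2000 genes with 400 implanted (20 % DE, cutoff
z ≈ 3.1, predicted power ≈ 0.9), balanced 200 up / 200 down — balance keeps
TMM's majority-non-DE, symmetric assumption valid (one-directional implants
measurably shift the factors and absorb signal) — and means log-uniform on
[200, 2000]. Measured power is 0.86–0.90 with empirical FDR ≤ 0.03 across
unselected seeds.

## GO enrichment

Gene models map many-to-one onto reference-species orthologs. In weighted
mode each annotated gene contributes its ortholog's multiplicity `m`
(computed within the background universe) to every term of that ortholog,
and the same weighting defines the totals; the upper-tail hypergeometric is
then taken over these weighted "annotated units". This mirrors the count
multiplication the pipeline is built around, but it is worth being explicit
that inflating counts by multiplicity overstates the effective sample size,
so weighted *p*-values are optimistic; `weighted = FALSE` gives the
standard one-gene-one-unit test, and with all multiplicities 1 the two are
identical (a tested equivalence). Terms are flat labels — no GO-hierarchy
propagation — and no multiple-testing correction is applied to enrichment
*p*-values by default; the 1e−5 cutoff is inclusive, reading the threshold
"P ≤ log10-5" as *p* ≤ 1e−5.

## Integration and qPCR

Directional overlaps partition the intersection of two differential lists
by sign agreement (a tested conservation property), with genes in only one
list reported as exclusive. Complementary targets are genes differential in
both an mRNA and a small RNA contrast with opposite signs — e.g. more 24-nt
small RNAs and less transcript in a mutant, the RdDM-like signature.
Cross-referencing counts list membership over an explicitly supplied list
universe (the published analysis pooled an unstated set of comparisons, so
the universe is an input, not a constant). Shared-fraction percentages are
rounded half-up to one decimal to match printed style.

ΔΔCt: technical replicates are averaged before biological-replicate
statistics (the study reports "the average of two biological and two
technical replicates", implying nesting); ΔCt = Ct_target − Ct_reference
per (group, biological replicate); log2fc = ΔCt_control − ΔCt_test.
Significance needs fold > 1.5 (strict) *and* t-test *p* < 0.05 on the
replicate ΔCt values. The t-test is unpaired by default: the study's
methods text says paired while its result tables are footnoted unpaired,
an unresolvable contradiction, so both are exposed via `paired=`. With
noise-free input the generator/analyser round trip is exact (fold 8 →
log2fc 3, SD 0); at Ct noise SD 0.2 and 3 replicates, 4-fold genes are
flagged with power ≥ 0.9 and null genes at ≤ 5 %.

## Assembly redundancy

A 100-bp k-mer is redundant when another k-mer at a separated coordinate
lies within Hamming distance 2. The pigeonhole search splits each k-mer
into `max_hamming + 1` segments; any within-distance partner shares at
least one segment verbatim, so candidates come from shared-segment groups
and are verified by direct Hamming count — exact, and tested against the
all-pairs scan. Because overlapping k-mers of any repeat trivially match
at small shifts, partners must be at least `min_separation` (default k)
apart on the same contig; strand handling is forward-only by default with
`both_strands = TRUE` adding reverse-complement partners. Both choices are
exposed because the original computation specifies neither.

## The synthetic-data generator

The generator emulates the study design: a heterozygous parent ("R35") and
two mutants ("m115", "m134") sharing deletion sets (the marker screen
required loss in both); negative-binomial mRNA counts with 2 replicates per
group; small RNA populations with plant-style 21/24-nt bimodal length mixes
in which the ovary profile doubles the 22-nt share relative to leaf;
hairpin loci whose arms match the genome perfectly within 400 bp; 24-nt
siRNA tags tiling target gene bodies with a per-genotype intensity
multiplier (the real ovule-tissue dilution of AI-cell signal is not
modelled — the multiplier is an explicit knob); and Ct tables with
`Ct = baseline − log2(expression) + noise`. Homeolog pairs are represented
as two haplotype sequences of one locus — the FASTA carries haplotype A and
the truth table the k alternate alleles — rather than as a physical second
gene copy, which would add multi-mapping ambiguity the recovery invariants
do not model. Genes are laid out with ≥ 1100 bp gaps so 500 bp extended
regions stay disjoint; default desk scale is 2 × 200 kb contigs and 200
genes.

All generators are pure functions of (parameters, seed) and restore the
caller's RNG state. What passing tests show about real data is accordingly
limited: uniform base composition, disjoint genes, error-free tag
provenance and a single shared dispersion are all idealisations; the suite
demonstrates correctness of the implemented rules and recoverability under
the stated noise models, not robustness to genomic repeat structure,
contamination or index-hopping.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale instances chosen so every stage is
exercised end to end: deletion recovery on the full 200-gene default
(sensitivity ≥ 0.95 and FDR ≤ 0.05 at depth 30, error 0.01; exact at error
0), exact-test calibration on 2000 null features, the DE benchmark above,
small RNA populations of 5–50 k reads on 2 × 60 kb genomes, 10
shuffled-genome control seeds for the hairpin false-accept rate, and 2 kb
oracle instances for the aligner and redundancy profiler. Ties are broken
deterministically everywhere (lexicographic ids, first-offset preference in
the duplex scan, substitution-before-indel in the aligner); percentages
round half-up; hypergeometric and binomial tails are computed from exact
pmfs, and the conditional NB pmf is normalised in log space.

## Known limitations

* The aligner requires tags ≥ 16 nt (the four-block seed needs 4-mers);
  the 18-nt filter makes this moot in the pipeline.
* Weighted GO enrichment inherits the statistical caveat above.
* sRNA differential calling has no replication-based error control, by
  design fidelity; treat the fold-only flags as descriptive.
* The exact test conditions on equalised, rounded counts; for very shallow
  libraries the rounding loss is visible (and is why the calibration suite
  uses moderate depths).
* SAM support is the minimal text subset needed for pileups (no BAM, no
  paired-end awareness beyond flags, insertions contribute no counts).
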