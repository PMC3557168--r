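---
title: "SNP discovery from reduced-representation libraries and validation by genotyping-by-sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP discovery from reduced-representation libraries and validation by genotyping-by-sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrlsnp)
```

## The problem

Reduced-representation libraries (RRLs) concentrate sequencing depth on a
reproducible subset of a genome: genomic DNA is digested with a frequent
cutter (here MseI, recognition site TTAA, cut one base into the motif), a
narrow fragment-size window (350–425 bp) is excised, and the fragment pool
is sequenced for each genotype. Mapping those reads onto a reference
assembly and examining every covered position yields candidate
single-nucleotide polymorphisms (SNPs) between inbred genotypes — at a
fraction of the cost of whole-genome resequencing, and with enough depth
per covered site for confident homozygous calls.

`rrlsnp` implements that workflow end to end for site-level input
(samtools text pileup columns): per-genotype consensus calling with a
conservative filter stack, genome-binned coverage statistics, SNP
characterization, and validation of candidates by segregation in a
recombinant inbred line (RIL) population genotyped by sequencing (GBS).
A built-in simulator generates references, digests, pileups and RIL
populations with exported truth sets, so every stage is testable against
known ground truth.

## The caller and its filter stack

At each covered site the consensus base is the most frequent base among
the calls. A site is a candidate SNP when the consensus differs from the
reference base; ties yield no call, and sites whose reference base is N
are skipped. The material is inbred, so no heterozygous genotypes are
called — the consensus-ratio filter enforces near-fixed alleles.

A candidate passes discovery iff it clears all of:

| filter        | default | meaning |
|---------------|---------|---------|
| minimum depth | ≥ 3 reads | noise floor for a homozygous call |
| maximum depth | ≤ X̄ + 2s  | per-genotype cutoff against repeats/paralogs |
| consensus ratio | ≥ 0.9   | fraction of calls supporting the consensus |
| site quality  | ≥ 20    | mean Phred quality of consensus-supporting calls |
| homopolymer   | run ≥ 3 | inside or abutting a reference homopolymer |
| adjacency     | gap < 2 bp | both members of a close pair removed |

X̄ and s are the mean and *population* standard deviation of depth over
covered positions (≥ 1 read) of that genotype's own mapping — a
descriptive cutoff, divided by n so it is exactly reproducible from the
depth table. Sites absent from the pileup are uncovered and contribute
nothing.

Decisions worth stating explicitly, because the workflow they come from
leaves them open:

* **Quality.** The historical pipeline thresholded a SAMtools-era
  consensus quality that is not reproducible outside that software. Here
  site quality is the mean Phred base quality of consensus-supporting
  calls, additionally capped by the root-mean-square mapping quality when
  a 7-column pileup provides one. The threshold (20) is configurable.
* **Adjacency.** "Removal of very close SNPs" does not say whether one or
  both members go; both are removed, symmetrically, and removal
  propagates through chains of close candidates. The adjacency test is
  evaluated over *all* candidates of a genotype, before the other filters
  thin them — this makes the staged pipeline exactly equal to evaluating
  every filter independently at every position, which is how the test
  suite's brute-force oracle checks it.
* **Homopolymers.** The test is on the reference sequence only: a
  candidate is removed when the maximal run containing its position, or
  the run immediately adjacent on either side, reaches the threshold
  length. Run identity with either allele is not required.
* **Ties.** Two bases with equal top counts yield no call rather than an
  arbitrary tie-break.
* **Multi-allelic locations.** When different genotypes carry different
  alternate alleles at one location, one record keeps all of them; the
  first genotype's allele (input order) represents the record in
  substitution-class tallies, and the number of such sites is reported.

Indels are out of scope throughout: pileup indel runs are parsed and
discarded, and the deletion placeholder `*` counts toward site depth
(the depth filters reflect mapped coverage) but never toward allele
counts (ratios reflect base evidence).

## Coordinates and bins

All external formats keep their native conventions — pileup, GFF3 and VCF
are 1-based, BED-like tables 0-based half-open — and are converted at the
I/O boundary to a single internal 0-based half-open convention, which
eliminates off-by-one drift. Reported SNP positions are contig-local and
1-based.

Genome-wide statistics use the *concatenated* coordinate system: contigs
in input order, each starting at the cumulative length of its
predecessors. Fixed-width bins (default 0.5 Mbp) partition that axis;
the last bin keeps its true (shorter) width rather than being padded.
Per bin, MCP is the percentage of positions covered by ≥ 1 read and MRD
the mean depth over covered positions only; an uncovered bin reports MRD
0 with a covered-flag of `FALSE`. Genome-equivalent coverage
(X = total read bases / genome size) uses the *estimated* genome size
(370 Mbp by default) — deliberately a different constant from the loaded
assembly length that serves as the MCP/rate denominator, since an
assembly is usually shorter than the genome it samples; both are
configurable.

## Validation by segregation

Candidates from a two-parent comparison are checked against a RIL
population derived from those parents. Each line's allele at each locus
is called with the same depth/ratio/quality criteria as discovery; a
residual heterozygous line fails the ratio criterion and yields a missing
call, consistent with the homozygous-call model. Each locus is then:

* **validated** — both parental alleles carried by ≥ 2 lines
  (`min_minor_lines`, configurable). Segregation is direct evidence, so
  no coverage quorum is required.
* **non-validated** — at least `floor(0.9 × N)` lines informative (86 of
  96) but only one parental allele reaches the two-line mark: the
  population does not segregate, so the original candidate was a false
  positive.
* **ineligible** — anything else (too few informative lines to decide).

The two-line minimum treats a single discordant line as a likely
sequencing artifact rather than evidence of segregation; alleles matching
neither parent are tallied separately and excluded from both parental
counts. The validation rate is computed over eligible loci only:
100 · validated / (validated + non-validated). With 4,706 validated and
157 non-validated loci this is `r round(validation_rate(4706, 157), 1)`%.

## The simulator

`sim_config()` defaults encode the study conditions this package
emulates: eight inbred genotypes (the first being the reference line
itself, carrying no variants), an MseI digest with 350–425 bp size
selection, SNP density 1.7 × 10⁻⁴ per bp per genotype (0.17 SNPs/Kbp),
mean site depth 10, and a 96-line F6 RIL population — five selfing
generations after F1, hence residual heterozygosity (1/2)⁵ = 3.125% per
locus. Values the study does not pin down were chosen once as field-
plausible: GC fraction 0.39 (typical plant nuclear genome), negative-
binomial depth with size 8 (overdispersed, as RRL coverage is), base
error rate 0.002 with a Phred-30 ± 3 quality model, and a 0.65
transition share among implanted substitutions (the transition excess
plant SNP surveys report).

Reads are not modeled individually: every downstream computation consumes
pileup columns, so the simulator emits site-level depth and calls
directly. Per-site depth is negative binomial (`depth_dispersion` 0 gives
constant depth, `Inf` Poisson); each call flips to a uniformly chosen
different base with the error probability; only positions inside selected
fragments are covered. The in-silico digest cuts at *every* motif
occurrence, including overlapping ones, one base into the motif (T^TAA,
standard MseI enzymology; the cut offset affects fragment lengths by ±1
only). RIL loci are inherited independently (unlinked-marker model);
heterozygous cells are emitted as missing in the call matrix, with the
mask returned so tests can assert that treatment.

Implants can be constrained to be *caller-recoverable by design*:
restricted to selected fragments, outside homopolymer contexts, spaced
≥ 3 bp. Under those constraints with error-free reads and constant depth
10, discovery recovers the truth set exactly (sensitivity 1, FDR 0) —
the end-to-end acceptance property. What passing those tests does **not**
show about real data: the simulator has no quality-by-cycle error
structure, no adapter or duplicate artifacts, no alignment ambiguity or
paralog collapse (the very phenomena the maximum-depth filter targets in
real mappings), no linkage between RIL loci, and i.i.d. base composition
rather than real repeat structure.

## Numerical choices and degenerate inputs

* Population (divide-by-n) standard deviation for the depth cutoff;
  documented so X̄ + 2s is reproducible from the depth table.
* Empty pileup → depth summary with `n_covered` 0 and `NA` moments;
  empty SNP set → all-zero report and header-only tables; a genotype with
  zero observations is excluded from discovery with a warning.
* SNPs on contigs absent from the gene annotation are counted intergenic,
  with a warning giving the count.
* Zero eligible loci → validation rate `NA`, flagged in the summary.
* All simulator randomness flows from one top-level seed, split per stage
  by a deterministic hash, and the caller's RNG state is restored
  afterwards; identical seeds give byte-identical outputs.

## Problem sizes in the shipped tests

The test suite and the acceptance script run simulations of 10 kb–500 kb
genomes (2–5 contigs, 1–4 genotypes), chosen as the smallest instances on
which every property is informative: the brute-force filter oracle runs
on 10 kb instances, end-to-end recovery on a 300–400 kb genome with
~1,000–2,000 implanted variants, and residual heterozygosity on ≥ 10⁴
loci × 96 lines. The published-scale numbers (55,465 SNPs on a 318 Mbp
assembly) depend on the original raw sequence archive and are recomputed
only at the arithmetic level, from the published summary tables shipped
under `inst/extdata/`.

## Known limitations

* Substitutions only; no indel or structural-variant calling.
* No genotype-likelihood model: calls are consensus-threshold based,
  appropriate for inbred material and deep RRL coverage, conservative
  elsewhere.
* The genic/intergenic rate denominators are measured from the supplied
  annotation (union of gene intervals over the loaded reference);
  published per-region denominators from other annotations will differ.
* Pileup parsing covers the 6- and 7-column text dialects; BAM/CRAM must
  be reduced to text pileup upstream.
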