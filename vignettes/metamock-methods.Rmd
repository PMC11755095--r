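---
title: "Simulating shotgun metagenomes with metamock: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating shotgun metagenomes with metamock: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamock)
```

## The problem

Benchmarking metagenomic software — taxonomic profilers, read mappers,
assemblers — needs samples where the truth is known exactly: which organism
each read came from, where on its genome, and what the community composition
was. metamock generates such samples *in silico*: it turns a community
specification into per-genome coverage depths, simulates short or long reads
with a parametric error model, and emits anonymized FASTQ, a ground-truth
SAM/BAM, and CAMI biobox taxonomic profiles.

A central modeling point is the difference between two abundance notions:

* **sequence abundance** — a taxon's share of the *reads* (what a profiler
  sees in raw counts); at a fixed organism count it scales with genome size;
* **taxonomic abundance** — a taxon's share of *organisms*, proxied here by
  its share of coverage depth; genome-size-normalized.

Conflating the two biases benchmarks: at equal organism counts, a 2 Mb genome
yields twice the reads of a 1 Mb genome. metamock therefore writes *both*
profiles for every sample, and its community design layer accepts either
notion as input.

## Community design

Each community entry is a `(genome, quantity, unit)` triple with unit one of
`reads`, `bases`, `coverage`, `seq_abundance`, `tax_abundance`. All units are
normalized to fold-coverage depths $c_i$ against genome lengths $L_i$:

* `coverage`: $c_i = q_i$;
* `bases`: $c_i = q_i / L_i$;
* `reads`: $c_i = q_i \cdot \ell / L_i$ with $\ell$ the per-read footprint
  (one mate's length for paired reads — read counts are individual reads, not
  pairs, matching FASTQ record counting);
* `seq_abundance`: fractions $f_i = q_i/\sum q$ define read counts
  $f_i \cdot R$ against the read budget $R$, then as `reads`;
* `tax_abundance`: fractions $f_i$ define depths $c_i = f_i \cdot C$ with
  $C = B / \sum_i f_i L_i$, so the total simulated bases equal the base
  budget $B$ and the depth *shares* equal the input fractions exactly.

Integer read counts are apportioned by **largest-remainder (Hamilton)
rounding**, ties broken by input order: totals are conserved exactly and the
result is deterministic. In paired mode apportionment happens in fragment
units (two reads each) so every genome gets an even read count and the FASTQ
record total still equals the plan exactly.

Random community structure uses either even fractions $1/n$ or a log-normal
species-abundance distribution, $a_i \propto \exp(\mathcal N(\mu, \sigma))$,
the conventional model for uneven microbial communities; defaults are
$\mu = 1$, $\sigma = 2$, a common choice for community simulation, and both
are configurable.

Technical replicates perturb each entry's quantity by an additive
$\mathcal N(0, \mathrm{sd})$ draw truncated at zero, applied **independently
per genome**, before unit conversion. Additive noise on the stated quantity
is the most literal reading of "standard deviation of the genome quantity
value"; a multiplicative log-normal alternative was considered and rejected
for simplicity. With sd $= 0$ (the default) replicates share identical
depths and differ only in their child seeds, i.e. in the genomic origin of
the reads.

## Read simulation

Multi-contig genomes are split and each contig simulated independently, with
the genome's read budget allocated across contigs proportionally to length
(largest remainder again) — this is what makes sampling uniform across the
genome. Contigs shorter than the read length are excluded from allocation
with a warning rather than causing an error.

**Short reads** are Illumina-like: fixed length, uniform start positions,
fair-coin strand. Paired mode draws insert sizes
$\mathcal N(\mu_I, \sigma_I)$ truncated (clamped) to
$[\text{read length}, \text{contig length}]$ — clamping rather than rejection
keeps the draw deterministic and single-pass — and emits FR ("innie") pairs:
mate 1 reads the fragment's 5' end, mate 2 the 3' end reverse-complemented.
Each base is substituted independently with probability `sub_rate`, uniformly
among the three alternatives. Qualities follow a linear Phred ramp
`q_start` → `q_end`; the error model is intentionally decoupled from the
quality string (qualities never influence error placement). The model is
parametric rather than trained on empirical profile tables; profile support
is an extension point, not a feature.

**Long reads** draw lengths from a log-normal, truncated to
$[\text{min length}, \text{contig length}]$, and walk the reference
positionwise: deletion (skip a reference base), insertion (emit a random
base), substitution, or match, with configurable rates summing to $< 1$.
Qualities are constant.

**Ground truth.** Every read carries a truth record: contig, 0-based start,
strand, and an extended-CIGAR edit sequence over `{=, X, I, D}` in reference
orientation. `check_truth()` re-walks each alignment against the reference
and verifies that match segments agree, substitution positions differ, and
the ops consume the read exactly; the SAM writer collapses `=/X` to `M` and
sets proper pair flags. N handling: reads may overlap N runs; sampled N
positions stay N (a substitution landing on an N is recorded as a match) and
receive ordinary qualities.

**Determinism.** All randomness flows from one master seed through a
deterministic child-seed scheme keyed by (sample, replicate, genome, contig,
stage) — a string-fold hash modulo a Mersenne prime, exact in double
precision. Per-contig streams therefore do not depend on execution order,
and an entire run is byte-identical under the same config and seed.

## Sample assembly and profiles

Per-contig streams are concatenated, shuffled at fragment granularity
(mates always move together — shuffling mates independently would break
pairing), and anonymized: read $i$ (1-based fragment index in final order)
becomes `"i"` or `"i/1"`/`"i/2"`. The original-to-anonymous name map is
written only on request, since it de-anonymizes the sample; truth is meant
to flow through the SAM, not through names. Shuffling is an in-memory
permutation, sized for desk-scale samples.

Realized statistics are recomputed from the truth records (read counts per
genome; depth as reference-consumed bases — matches, mismatches *and*
deletions — over genome length), then projected through the taxonomy onto
the seven canonical ranks (superkingdom through species; "kingdom" in common
usage maps to biobox `superkingdom`). The sequence-abundance profile weights
genomes by reads, the taxonomic-abundance profile by depth; both are written
in CAMI biobox format (version string 0.9.1, configurable). Lineage gaps are
skipped, not padded with placeholder taxids; zero-abundance taxa are
omitted; genomes below species rank aggregate to species.

## Assembly ranking

The offline selection component orders assembly metadata rows by RefSeq
category (reference, representative, uncategorized), assembly status
(complete, chromosome, scaffold, contig), then BUSCO and checkM completeness
descending — BUSCO first, matching the order the metrics are conventionally
listed — with accession as a terminal tie-break so the order is total.
Missing completeness scores sort after any present value: absence of
evidence is not completeness zero. The policy's key order is configurable;
`top_n_per_rank()` groups records by their ancestor at any profiled rank and
keeps the best $n$ per group (e.g. ten best genomes per genus). The
equivalent network-download stage of a production workflow is out of scope;
the module consumes offline tables.

## The synthetic-data generator

`make_fixtures()` builds everything the pipeline needs without network
access: i.i.d. base-composition genomes at a target GC (realized GC is
Binomial, so tests can check calibration against the exact 3σ band), a
complete seven-rank synthetic taxonomy, seeded metadata tables exercising
every ranking branch, an example community table, and four miniature
body-site-style abundance templates (gut, oral, skin, vaginal) that are
explicitly artificial stand-ins.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: genome composition structure (repeats, GC skew,
codon bias), sequencer-specific error profiles (position- and
context-dependent error rates, quality miscalibration), GC amplification
bias, chimeras and duplicates, and realistic community phylogenies. The
test suite demonstrates that the machinery is *correct and calibrated under
its own model*, not that the model reproduces any particular instrument.

## Numerical choices and problem sizes

* Largest-remainder rounding everywhere an integer allocation must conserve
  a total; ties by input order.
* Insert-size and read-length truncation by clamping, not rejection.
* The long-read footprint used by `reads_for_depth()` is the analytic mean
  of the below-truncated log-normal,
  $a\,F(a) + e^{\mu+\sigma^2/2}\,\Phi\!\big((\mu+\sigma^2-\log a)/\sigma\big)$
  with $a$ the minimum length; the contig-length upper clamp is ignored
  there, so genomes whose contigs are comparable to the mean read length
  realize slightly higher depth than requested.
* Degenerate inputs: empty FASTA records, all-zero quantities, rate sums
  $\ge 1$, and unknown category/status tokens are classed errors; too-short
  contigs are warnings.
* IUPAC ambiguity codes beyond N are mapped to N by default (configurable to
  reject), and soft-masking case is not preserved.

The shipped tests and the acceptance script run at deliberately desk-scale
sizes — genomes of 10 kb–2 Mb, samples of $10^3$–$5\times10^4$ reads,
$10^6$-base error-calibration runs, 500-record ranking oracles — chosen so
the full suite completes in about a minute while every statistical check
still has the power its 3σ or 5% band requires.

## Known limitations

Substitution-only short reads (no indels); no chimeras, PCR duplicates, or
GC bias; no circular-genome handling (fragments never span contig ends); no
empirical error-profile training; profiles stop at species (no strain rows);
shuffling holds the sample in memory.
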