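# metamock

Simulated shotgun metagenomes with exact ground truth, for benchmarking
taxonomic profilers, read mappers and metagenome pipelines.

Real metagenomic samples are expensive to sequence and their true
composition is never fully known, which makes them poor material for
validating software. metamock builds mock samples entirely *in silico*:
you describe a community — which genomes, in what amounts, in whichever
unit is natural — and it produces compressed, shuffled, anonymized FASTQ
reads together with a ground-truth SAM/BAM recording every read's origin
and edits, plus CAMI biobox taxonomic profiles.

## The model in brief

Per-genome quantities $q_i$ in any supported unit (`reads`, `bases`,
`coverage`, `seq_abundance`, `tax_abundance`) are normalized to coverage
depths $c_i$ against genome lengths $L_i$; for taxonomic abundances with
fractions $f_i$ and base budget $B$,

$$c_i = f_i \cdot \frac{B}{\sum_j f_j L_j},$$

so depth shares equal the input fractions and total bases equal $B$.
Integer read counts are apportioned by largest-remainder rounding (totals
conserve exactly). Reads are simulated per contig — budgets split across
contigs proportionally to length for uniform genome sampling — with an
Illumina-like short-read model (fixed length, FR pairs, Normal insert
sizes, uniform per-base substitutions, linear quality ramp) or a long-read
model (log-normal lengths, positionwise substitution/insertion/deletion).
Every sample gets two profiles, because the two abundance notions differ
whenever genome sizes differ:

* **sequence abundance** — share of reads (scales with genome size);
* **taxonomic abundance** — share of organisms, proxied by coverage depth.

A separate component ranks genome assemblies from offline metadata tables
(RefSeq category > assembly status > BUSCO > checkM, accession tie-break),
with optional top-n selection per taxonomic rank.

## Worked example

Everything below runs offline; `make_fixtures()` generates synthetic
genomes, a seven-rank taxonomy and an example community table.

```r
library(metamock)

fx <- make_fixtures("mm_example", n_genomes = 3, genome_length = 20000, seed = 1)
cfg <- list(community = fx$community, manifest = fx$manifest,
            taxonomy = fx$taxonomy, output_dir = "mm_out",
            seed = 42, total_bases = 2e5,
            short = list(read_length = 100L, paired = TRUE,
                         insert_mean = 300, insert_sd = 25,
                         sub_rate = 0.001))
res <- run_simulation(cfg)
res$sample1$plan
#>   genome_id coverage_depth expected_reads expected_bases
#> 1   SYNG001       3.333333            668          66800
#> 2   SYNG002       3.333333            666          66600
#> 3   SYNG003       3.333333            666          66600
res$sample1$stats
#>   genome_id taxid read_count mean_depth
#> 1   SYNG001    33        668       3.34
#> 2   SYNG002    34        666       3.33
#> 3   SYNG003    35        666       3.33
```

The community table asked for equal taxonomic abundances on three equally
sized 20 kb genomes with a 200 kb base budget: each genome is planned at
depth 200000 / 60000 = 3.33×, the 2000-read budget is split 668/666/666 by
largest remainder, and the realized statistics (recomputed from the truth
records, not copied from the plan) match it. The output directory contains
`sample1_R1.fastq.gz`, `sample1_R2.fastq.gz`, `sample1.truth.sam`, the
realized-stats TSV, a `run_manifest.yaml`, and both profiles; the
sequence-abundance profile at species rank reads

```
33  species  2|10|11|12|13|30|33  Bacteria|...|Synthomonas_1 sp1  33.400000
34  species  2|20|21|22|23|31|34  Bacteria|...|Synthomonas_2 sp2  33.300000
35  species  2|10|11|12|13|32|35  Bacteria|...|Synthomonas_3 sp3  33.300000
```

— equal within read-rounding, as designed. With genomes of *unequal* size
the two profile flavors separate: at equal taxonomic abundance a 2 Mb
genome receives twice the reads of a 1 Mb genome (66.7% vs 33.3% sequence
abundance, 50/50 taxonomic abundance).

A thin command-line wrapper with `simulate`, `design`, `rank` and
`fixtures` subcommands is installed at `inst/scripts/metamock`.

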