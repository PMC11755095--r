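# Shared fixtures and independent oracles used across test files.

tiny_tax <- function(...) make_synthetic_taxonomy(...)

# Independent brute-force comparator for assembly ranking: compares two
# records field by field in the documented policy order, never touching
# the package's key machinery.
oracle_compare_records <- function(a, b) {
  cat_lv <- c(reference = 1, representative = 2, na = 3)
  st_lv <- c(complete = 1, chromosome = 2, scaffold = 3, contig = 4)
  if (cat_lv[[a$refseq_category]] != cat_lv[[b$refseq_category]])
    return(sign(cat_lv[[a$refseq_category]] - cat_lv[[b$refseq_category]]))
  if (st_lv[[a$assembly_status]] != st_lv[[b$assembly_status]])
    return(sign(st_lv[[a$assembly_status]] - st_lv[[b$assembly_status]]))
  for (col in c("busco_completeness", "checkm_completeness")) {
    av <- a[[col]]; bv <- b[[col]]
    if (is.na(av) && !is.na(bv)) return(1)
    if (!is.na(av) && is.na(bv)) return(-1)
    if (!is.na(av) && !is.na(bv) && av != bv) return(sign(bv - av))
  }
  if (a$accession < b$accession) -1 else if (a$accession > b$accession) 1 else 0
}

# Stable insertion sort driven by the pairwise comparator.
oracle_sort_records <- function(tab) {
  n <- nrow(tab)
  rows <- lapply(seq_len(n), function(i) as.list(tab[i, ]))
  idx <- seq_len(n)
  for (i in seq_len(n)[-1]) {
    j <- i
    while (j > 1 &&
           oracle_compare_records(rows[[idx[j - 1]]], rows[[idx[j]]]) > 0) {
      tmp <- idx[j - 1]; idx[j - 1] <- idx[j]; idx[j] <- tmp
      j <- j - 1
    }
  }
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mismatch fraction between simulated reads and the reference, computed
# positionwise from coordinates only (not from the recorded edit ops).
observed_mismatch_rate <- function(stream, contigs) {
  mism <- 0L; total <- 0L
  for (i in seq_len(nrow(stream))) {
    ref <- contigs[[paste0(stream$genome_id[i], "|", stream$contig_id[i])]]
    q <- stream$sequence[i]
    if (stream$strand[i] == "-")
      q <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    r <- substring(ref$sequence, stream$start[i] + 1,
                   stream$start[i] + nchar(q))
    qs <- utf8ToInt(q); rs <- utf8ToInt(r)
    mism <- mism + sum(qs != rs)
    total <- total + length(qs)
  }
  mism / total
}
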