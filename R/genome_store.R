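# Genome store: FASTA ingestion, contig-level access, synthetic genomes.

#' Construct a contig
#'
#' A contig is the unit of read simulation: an id plus an uppercase DNA
#' sequence over {A,C,G,T,N}.
#'
#' @param id non-empty character scalar.
#' @param sequence DNA character scalar; uppercased on construction.
#' @return an object of class `mm_contig` with fields `id`, `sequence`,
#'   `length`.
#' @export
contig <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    mm_stop("mm_format_error", "contig id must be a non-empty string")
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence))
    mm_stop("mm_format_error", "contig '", id, "' has an empty sequence")
  if (grepl("[^ACGTN]", sequence))
    mm_stop("mm_format_error", "contig '", id,
            "' contains characters outside {A,C,G,T,N}")
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "mm_contig")
}

#' Construct a genome from contigs
#'
#' @param genome_id accession-like identifier.
#' @param taxid positive integer NCBI-style taxon id.
#' @param contigs list of [contig()] objects with unique ids.
#' @return an object of class `mm_genome` with fields `genome_id`,
#'   `taxid`, `contigs` (named list) and `total_length`.
#' @export
genome <- function(genome_id, taxid, contigs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1, nzchar(genome_id))
  taxid <- as.integer(taxid)
  if (is.na(taxid) || taxid <= 0L)
    mm_stop("mm_format_error", "genome '", genome_id, "': taxid must be a positive integer")
  if (length(contigs) < 1)
    mm_stop("mm_format_error", "genome '", genome_id, "' has no contigs")
  ids <- vapply(contigs, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    mm_stop("mm_format_error", "genome '", genome_id, "': duplicate contig ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(contigs) <- ids
  structure(list(genome_id = genome_id, taxid = taxid, contigs = contigs,
                 total_length = sum(vapply(contigs, `[[`, integer(1), "length"))),
            class = "mm_genome")
}

#' @export
print.mm_genome <- function(x, ...) {
  cat(sprintf("<mm_genome> %s  taxid=%d  %d contig(s), %s bp\n",
              x$genome_id, x$taxid, length(x$contigs),
              format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Read contigs from a FASTA file
#'
#' Reads a (possibly gzip-compressed) FASTA file into a list of contigs.
#' Sequences are uppercased; soft-masking is not preserved.  IUPAC
#' ambiguity codes other than N are either mapped to N
#' (`ambiguous = "map"`, the default) or rejected (`ambiguous = "error"`).
#'
#' @param path FASTA file, plain or gzipped.
#' @param ambiguous `"map"` or `"error"`; policy for non-ACGTN letters.
#' @return list of [contig()] objects in file order.
#' @export
read_fasta <- function(path, ambiguous = c("map", "error")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path))
    mm_stop("mm_io_error", "FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e)
                     mm_stop("mm_format_error", "cannot parse FASTA '", path, "': ",
                             conditionMessage(e)))
  if (length(seqs) == 0)
    mm_stop("mm_format_error", "FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    mm_stop("mm_format_error", "duplicate FASTA ids in '", path, "': ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chr <- toupper(as.character(seqs))
  if (any(nchar(chr) == 0))
    mm_stop("mm_format_error", "empty sequence under header '",
            ids[which(nchar(chr) == 0)[1]], "' in '", path, "'")
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    if (ambiguous == "error")
      mm_stop("mm_format_error", "non-ACGTN characters in '", path,
              "' (record ", ids[which(bad)[1]], ")")
    chr[bad] <- gsub("[^ACGTN]", "N", chr[bad])
  }
  unname(Map(contig, ids, chr))
}

#' Read one genome (FASTA + identity) into a genome object
#'
#' @inheritParams read_fasta
#' @param genome_id identifier for the genome.
#' @param taxid positive integer taxon id.
#' @export
read_genome <- function(path, genome_id, taxid, ambiguous = "map") {
  genome(genome_id, taxid, read_fasta(path, ambiguous = ambiguous))
}

#' Write contigs or a genome to FASTA
#'
#' @param x an `mm_genome` or list of `mm_contig`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fasta <- function(x, path) {
  contigs <- if (inherits(x, "mm_genome")) x$contigs else x
  seqs <- Biostrings::DNAStringSet(vapply(contigs, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(contigs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Split a genome into its contigs
#'
#' Order-preserving decomposition; the unit handed to the per-contig
#' read simulators.
#'
#' @param g an `mm_genome`.
#' @return named list of `mm_contig`, in genome order.
#' @export
split_contigs <- function(g) {
  stopifnot(inherits(g, "mm_genome"))
  g$contigs
}

#' Generate a synthetic genome
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1-gc)/2, so the realized GC count is Binomial(length, gc).  Contig
#' lengths partition `length` as evenly as largest-remainder
#' apportionment allows.  Deterministic for a given seed.
#'
#' @param length total genome length in bases.
#' @param gc target GC fraction in [0, 1].
#' @param n_contigs number of contigs (>= 1, <= length).
#' @param seed integer seed.
#' @param genome_id,taxid identity of the synthetic genome.
#' @return an `mm_genome`.
#' @export
#' @examples
#' g <- make_synthetic_genome(1000, gc = 0.5, n_contigs = 2, seed = 7)
make_synthetic_genome <- function(length, gc = 0.5, n_contigs = 1L, seed = 1L,
                                  genome_id = "SYN", taxid = 1L) {
  length <- as.integer(length); n_contigs <- as.integer(n_contigs)
  if (n_contigs < 1L || length < n_contigs)
    mm_stop("mm_argument_error", "need length >= n_contigs >= 1")
  if (gc < 0 || gc > 1)
    mm_stop("mm_argument_error", "gc must be in [0, 1]")
  lens <- largest_remainder(rep(1, n_contigs), length)
  with_seed(seed, {
    contigs <- lapply(seq_len(n_contigs), function(i) {
      bases <- sample(DNA_BASES, lens[i], replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      contig(sprintf("%s_ctg%d", genome_id, i), paste(bases, collapse = ""))
    })
    genome(genome_id, taxid, contigs)
  })
}

#' Read a genome manifest table
#'
#' A manifest is a TSV with columns `genome_id`, `taxid`, `fasta_path`.
#' Relative FASTA paths are resolved against the manifest's directory.
#'
#' @param path manifest TSV.
#' @return list of `mm_genome`, named by genome_id.
#' @export
read_genome_manifest <- function(path) {
  if (!file.exists(path)) mm_stop("mm_io_error", "manifest not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "taxid", "fasta_path")
  if (!all(need %in% names(tab)))
    mm_stop("mm_format_error", "manifest must have columns: ",
            paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  gs <- lapply(seq_len(nrow(tab)), function(i) {
    fp <- tab$fasta_path[i]
    if (!file.exists(fp)) fp <- file.path(base, fp)
    read_genome(fp, tab$genome_id[i], tab$taxid[i])
  })
  names(gs) <- tab$genome_id
  gs
}
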