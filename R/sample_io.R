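# Sample assembly: concatenation, shuffling, anonymization, FASTQ and
# ground-truth SAM/BAM output, realized per-genome statistics.

#' Concatenate per-contig read streams
#'
#' @param streams list of `mm_reads` streams sharing the same mode.
#' @return one `mm_reads` stream; stream order then within-stream order.
#' @export
concatenate_streams <- function(streams) {
  streams <- Filter(function(s) !is.null(s), streams)
  if (length(streams) == 0) return(empty_stream(FALSE))
  modes <- unique(vapply(streams, is_paired, logical(1)))
  if (length(modes) > 1)
    mm_stop("mm_argument_error", "cannot concatenate paired and single streams")
  out <- do.call(rbind, lapply(streams, as.data.frame))
  rownames(out) <- NULL
  read_stream(out, modes)
}

#' Shuffle reads (fragments move together)
#'
#' Applies a seeded permutation at fragment granularity: in paired mode
#' both mates move together and keep their within-fragment order, so
#' downstream analyses see no trace of the per-contig generation order.
#'
#' @param stream an `mm_reads` stream.
#' @param seed integer seed.
#' @return the permuted stream.
#' @export
shuffle_reads <- function(stream, seed) {
  if (nrow(stream) == 0) return(stream)
  frag_keys <- unique(stream$frag)
  perm <- with_seed(seed, sample.int(length(frag_keys)))
  ord <- order(match(stream$frag, frag_keys[perm]),
               stream$mate)
  out <- stream[ord, , drop = FALSE]
  rownames(out) <- NULL
  read_stream(out, is_paired(stream))
}

#' Anonymize read names
#'
#' Replaces every read name by its 1-based fragment index in the
#' (already final) stream order, with `/1`//`/2` mate suffixes in paired
#' mode, so no output header reveals the source genome or contig.
#'
#' @param stream an `mm_reads` stream in final order.
#' @return list with elements `stream` (renamed) and `name_map`
#'   (data.frame original -> anonymous).
#' @export
anonymize_reads <- function(stream) {
  if (nrow(stream) == 0)
    return(list(stream = stream,
                name_map = data.frame(original = character(),
                                      anonymous = character())))
  frag_idx <- match(stream$frag, unique(stream$frag))
  new_names <- if (is_paired(stream))
    paste0(frag_idx, "/", stream$mate) else as.character(frag_idx)
  map <- data.frame(original = stream$name, anonymous = new_names,
                    stringsAsFactors = FALSE)
  out <- stream
  out$name <- new_names
  out$frag <- as.character(frag_idx)
  list(stream = read_stream(out, is_paired(stream)), name_map = map)
}

#' Write a read stream to FASTQ
#'
#' Standard 4-line records, Phred+33, gzip-compressed by default.
#' Paired streams are written as two synchronized files (mate 1 to
#' `paths[1]`, mate 2 to `paths[2]`).
#'
#' @param stream an `mm_reads` stream.
#' @param paths one path (single) or two (paired).
#' @param compress gzip the output (default TRUE).
#' @return the paths, invisibly.
#' @export
write_fastq <- function(stream, paths, compress = TRUE) {
  write_one <- function(df, path) {
    dna <- Biostrings::DNAStringSet(df$sequence)
    names(dna) <- df$name
    qual <- Biostrings::BStringSet(df$qualities)
    withCallingHandlers(
      tryCatch(
        Biostrings::writeXStringSet(dna, path, format = "fastq",
                                    qualities = qual, compress = compress),
        error = function(e)
          mm_stop("mm_io_error", "cannot write FASTQ '", path, "': ",
                  conditionMessage(e))),
      warning = function(w) {
        # Biostrings warns when it drops (empty) mcols on conversion
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  if (is_paired(stream)) {
    if (length(paths) != 2)
      mm_stop("mm_argument_error", "paired output needs two FASTQ paths")
    write_one(stream[stream$mate == 1L, , drop = FALSE], paths[1])
    write_one(stream[stream$mate == 2L, , drop = FALSE], paths[2])
  } else {
    write_one(as.data.frame(stream), paths[1])
  }
  invisible(paths)
}

#' Read a FASTQ file (plain or gzip) into a name/sequence/quality table
#'
#' @param path FASTQ file.
#' @return data.frame with columns `name`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  withCallingHandlers({
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    data.frame(name = names(x),
               sequence = as.character(x),
               qualities = as.character(Biostrings::quality(x)),
               stringsAsFactors = FALSE)
  }, warning = function(w) {
    # Biostrings warns about dropping (empty) mcols on conversion
    if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Truth ops (=/X/I/D) -> SAM CIGAR (M/I/D), merging =/X runs into M.
ops_to_cigar <- function(ops) {
  vapply(ops_tokens(ops), function(tk) {
    lens <- as.integer(substring(tk, 1, nchar(tk) - 1L))
    op <- substring(tk, nchar(tk), nchar(tk))
    op[op %in% c("=", "X")] <- "M"
    r <- rle(op)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    merged <- vapply(seq_along(r$values),
                     function(j) sum(lens[starts[j]:ends[j]]), integer(1))
    paste0(merged, r$values, collapse = "")
  }, character(1))
}

#' Write the ground-truth alignment as SAM (optionally BAM)
#'
#' One reference per contig, named `genome_id|contig_id`; one record per
#' read with 1-based POS, CIGAR derived from the truth ops, and
#' reverse-strand / mate flags.  SEQ and QUAL are stored in reference
#' orientation, as the SAM specification requires.  When `bam = TRUE`
#' the SAM is coordinate-sorted and converted with Rsamtools.
#'
#' @param stream an `mm_reads` stream (names already final).
#' @param genomes list of `mm_genome` covering every read's origin.
#' @param path output SAM path.
#' @param bam also produce a sorted, indexed BAM next to `path`.
#' @param sep separator in reference names (default `"|"`).
#' @return path of the SAM (or BAM) file, invisibly.
#' @export
write_truth_alignment <- function(stream, genomes, path, bam = FALSE,
                                  sep = "|") {
  idx <- contig_index(genomes, sep = sep)
  refs <- paste0(stream$genome_id, sep, stream$contig_id)
  unknown <- setdiff(unique(refs), names(idx))
  if (length(unknown))
    mm_stop("mm_consistency_error", "truth records reference unknown contigs: ",
            paste(unknown, collapse = ", "))

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              vapply(names(idx), function(nm)
                sprintf("@SQ\tSN:%s\tLN:%d", nm, idx[[nm]]$length),
                character(1)))

  if (nrow(stream) > 0) {
    qname <- sub("/[12]$", "", stream$name)
    neg <- stream$strand == "-"
    flag <- ifelse(neg, 16L, 0L)
    seqo <- stream$sequence
    qualo <- stream$qualities
    if (any(neg)) {
      seqo[neg] <- revcomp(seqo[neg])
      qualo[neg] <- vapply(qualo[neg], function(q)
        intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
    }
    pos <- stream$start + 1L
    cigar <- ops_to_cigar(stream$ops)
    rnext <- rep("*", nrow(stream)); pnext <- rep(0L, nrow(stream))
    tlen <- rep(0L, nrow(stream))
    if (is_paired(stream)) {
      flag <- flag + 1L + 2L + ifelse(stream$mate == 1L, 64L, 128L)
      # mates are adjacent rows sharing `frag`; look the other mate up
      o <- order(stream$frag, stream$mate)
      back <- integer(nrow(stream))
      back[o] <- seq_len(nrow(stream))
      mate_of <- integer(nrow(stream))
      mate_of[o[seq(1, length(o), 2)]] <- o[seq(2, length(o), 2)]
      mate_of[o[seq(2, length(o), 2)]] <- o[seq(1, length(o), 2)]
      flag <- flag + ifelse(stream$strand[mate_of] == "-", 32L, 0L)
      rnext <- ifelse(refs[mate_of] == refs, "=", refs[mate_of])
      pnext <- stream$start[mate_of] + 1L
      ref_len <- ops_ref_len(stream$ops)
      lo <- pmin(stream$start, stream$start[mate_of])
      hi <- pmax(stream$start + ref_len,
                 stream$start[mate_of] + ops_ref_len(stream$ops[mate_of]))
      span <- hi - lo
      tlen <- ifelse(stream$start < stream$start[mate_of], span,
              ifelse(stream$start > stream$start[mate_of], -span,
              ifelse(stream$mate == 1L, span, -span)))
    }
    records <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                       qname, flag, refs, pos, 60L, cigar,
                       rnext, pnext, tlen, seqo, qualo)
  } else records <- character(0)

  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(header, records), con)
  close(con); on.exit()

  if (bam) {
    bam_path <- Rsamtools::asBam(path,
                                 destination = sub("\\.sam$", "", path),
                                 overwrite = TRUE, indexDestination = TRUE)
    return(invisible(bam_path))
  }
  invisible(path)
}

#' Realized per-genome statistics from truth records
#'
#' The simulator's analogue of coverage extraction from a BAM:
#' `read_count` is the number of truth records per genome and
#' `mean_depth` the reference bases they consume (matches, mismatches
#' and deletions) divided by the genome length.  Genomes present in the
#' design but receiving zero reads are retained with zeros.
#'
#' @param stream an `mm_reads` stream (the sample's truth records).
#' @param genome_lengths named vector genome_id -> bases; its names
#'   define the rows of the result.
#' @param taxids optional named vector genome_id -> taxid, carried
#'   through for profiling.
#' @return data.frame with columns `genome_id`, `taxid` (if given),
#'   `read_count`, `mean_depth`.
#' @export
realized_stats <- function(stream, genome_lengths, taxids = NULL) {
  ids <- names(genome_lengths)
  rc <- integer(length(ids)); rb <- numeric(length(ids))
  if (nrow(stream) > 0) {
    ref_len <- ops_ref_len(stream$ops)
    agg_n <- tapply(rep(1L, nrow(stream)), stream$genome_id, sum)
    agg_b <- tapply(ref_len, stream$genome_id, sum)
    hit <- match(names(agg_n), ids)
    rc[hit] <- as.integer(agg_n)
    rb[hit] <- as.numeric(agg_b[names(agg_n)])
  }
  out <- data.frame(genome_id = ids, read_count = rc,
                    mean_depth = rb / as.double(genome_lengths),
                    stringsAsFactors = FALSE)
  if (!is.null(taxids)) out$taxid <- as.integer(taxids[ids])
  out[, c("genome_id", if (!is.null(taxids)) "taxid", "read_count",
          "mean_depth")]
}
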