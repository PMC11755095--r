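# Read simulation: short (single/paired) and long reads per contig with a
# parametric error model, uniform genome sampling, and exact ground truth.
#
# A "read stream" is a data.frame of class mm_reads with one row per read:
#   name       read name ("<frag>" or "<frag>/1", "<frag>/2")
#   sequence   bases as sequenced (minus-strand reads are reverse-complemented)
#   qualities  Phred+33 string, same length as sequence
#   genome_id, contig_id, start (0-based leftmost on reference), strand,
#   ops        extended-CIGAR truth ops over {=, X, I, D} in reference
#              orientation (X = substitution),
#   aligned_length (query length), mate (0 single, 1/2 paired),
#   frag       fragment key (mates share it; shuffling moves fragments)
# and an attribute paired = TRUE/FALSE.

read_stream <- function(df, paired) {
  structure(df, class = c("mm_reads", "data.frame"), paired = isTRUE(paired))
}

empty_stream <- function(paired = FALSE) {
  read_stream(data.frame(name = character(), sequence = character(),
                         qualities = character(), genome_id = character(),
                         contig_id = character(), start = integer(),
                         strand = character(), ops = character(),
                         aligned_length = integer(), mate = integer(),
                         frag = character(), stringsAsFactors = FALSE),
              paired)
}

is_paired <- function(stream) isTRUE(attr(stream, "paired"))

#' Short-read simulation parameters
#'
#' An Illumina-like parametric model: fixed read length, optional FR
#' ("innie") mate pairs with Normal insert sizes, a uniform per-base
#' substitution rate, and a linear Phred quality ramp from `q_start` at
#' the 5' end to `q_end` at the 3' end.  Quality values do not influence
#' error placement.
#'
#' @param read_length read length in bases.
#' @param paired simulate mate pairs.
#' @param insert_mean,insert_sd fragment (insert) size Normal parameters,
#'   bases; inserts are truncated to [read_length, contig_length].
#' @param sub_rate per-base substitution probability in [0, 1).
#' @param q_start,q_end Phred qualities at read start/end.
#' @return object of class `mm_short_params`.
#' @export
short_read_params <- function(read_length = 150L, paired = FALSE,
                              insert_mean = 400, insert_sd = 25,
                              sub_rate = 0.001, q_start = 37L, q_end = 30L) {
  read_length <- as.integer(read_length)
  if (read_length < 1L) mm_stop("mm_argument_error", "read_length must be >= 1")
  if (sub_rate < 0 || sub_rate >= 1)
    mm_stop("mm_argument_error", "sub_rate must be in [0, 1)")
  if (paired && insert_mean < read_length)
    mm_stop("mm_argument_error", "paired mode requires insert_mean >= read_length")
  if (insert_sd < 0) mm_stop("mm_argument_error", "insert_sd must be >= 0")
  structure(list(read_length = read_length, paired = isTRUE(paired),
                 insert_mean = as.double(insert_mean),
                 insert_sd = as.double(insert_sd),
                 sub_rate = as.double(sub_rate),
                 q_start = as.integer(q_start), q_end = as.integer(q_end)),
            class = "mm_short_params")
}

#' Long-read simulation parameters
#'
#' Log-normal read lengths with positionwise substitution, insertion and
#' deletion errors at configurable rates, and a constant Phred quality.
#'
#' @param length_log_mean,length_log_sd log-scale mean / sd of read
#'   length (bases); lengths are truncated to [min_length, contig_length].
#' @param sub_rate,ins_rate,del_rate per-position error rates; their sum
#'   must be < 1 (all zero gives perfect reads).
#' @param min_length minimum read length, bases.
#' @param quality constant Phred quality assigned to every base.
#' @return object of class `mm_long_params`.
#' @export
long_read_params <- function(length_log_mean = 8.5, length_log_sd = 0.45,
                             sub_rate = 0.01, ins_rate = 0.005,
                             del_rate = 0.005, min_length = 200L,
                             quality = 12L) {
  if (length_log_sd <= 0)
    mm_stop("mm_argument_error", "length_log_sd must be > 0")
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || sum(rates) >= 1)
    mm_stop("mm_argument_error",
            "error rates must be non-negative and sum to < 1")
  min_length <- as.integer(min_length)
  if (min_length < 1L) mm_stop("mm_argument_error", "min_length must be >= 1")
  structure(list(length_log_mean = as.double(length_log_mean),
                 length_log_sd = as.double(length_log_sd),
                 sub_rate = as.double(sub_rate), ins_rate = as.double(ins_rate),
                 del_rate = as.double(del_rate), min_length = min_length,
                 quality = as.integer(quality)),
            class = "mm_long_params")
}

#' Allocate a read total across contigs proportionally to length
#'
#' Largest-remainder apportionment so reads sample the genome uniformly
#' and the per-genome total is conserved exactly.
#'
#' @param total_reads non-negative integer.
#' @param contig_lengths positive integer vector.
#' @return integer vector summing to `total_reads`.
#' @export
#' @examples
#' allocate_reads_per_contig(10, c(600, 400))      # 6 4
#' allocate_reads_per_contig(7, c(500, 300, 200))  # 4 2 1
allocate_reads_per_contig <- function(total_reads, contig_lengths) {
  if (length(contig_lengths) < 1)
    mm_stop("mm_argument_error", "no contigs to allocate reads to")
  if (any(contig_lengths <= 0))
    mm_stop("mm_argument_error", "contig lengths must be positive")
  if (total_reads < 0)
    mm_stop("mm_argument_error", "total_reads must be >= 0")
  largest_remainder(contig_lengths, total_reads)
}

# Extended-CIGAR helpers ----------------------------------------------------

ops_tokens <- function(ops) {
  regmatches(ops, gregexpr("[0-9]+[=XID]", ops))
}

ops_len_by <- function(ops, which_ops) {
  vapply(ops_tokens(ops), function(tok) {
    op <- substring(tok, nchar(tok), nchar(tok))
    sum(as.integer(substring(tok, 1, nchar(tok) - 1L))[op %in% which_ops])
  }, numeric(1))
}

#' Reference bases consumed by each truth record
#' @noRd
ops_ref_len <- function(ops) ops_len_by(ops, c("=", "X", "D"))

#' Query (read) bases consumed by each truth record
#' @noRd
ops_query_len <- function(ops) ops_len_by(ops, c("=", "X", "I"))

ops_from_flags <- function(flags) {
  r <- rle(flags)
  paste0(r$lengths, r$values, collapse = "")
}

# Apply independent per-base substitutions to reference-orientation
# fragments.  Positions whose reference base is N are left untouched (an
# N stays N and is recorded as a match).  Must run inside with_seed().
apply_substitutions <- function(seqs, sub_rate) {
  L <- nchar(seqs)
  ops <- sprintf("%d=", L)
  if (sub_rate <= 0 || length(seqs) == 0)
    return(list(seqs = seqs, ops = ops))
  k <- stats::rbinom(length(seqs), L, sub_rate)
  for (i in which(k > 0)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sort(sample.int(L[i], k[i]))
    pos <- pos[ch[pos] != "N"]
    if (!length(pos)) next
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(ch, collapse = "")
    flags <- rep("=", L[i]); flags[pos] <- "X"
    ops[i] <- ops_from_flags(flags)
  }
  list(seqs = seqs, ops = ops)
}

#' Simulate short reads from one contig
#'
#' Fragment start positions are uniform over the valid range and strands
#' are a fair coin.  In paired mode the insert length is drawn
#' Normal(insert_mean, insert_sd) truncated to [read_length,
#' contig_length]; mate 1 reads the fragment's 5' end and mate 2 its 3'
#' end reverse-complemented (FR orientation), with `/1`//`/2` name
#' suffixes.  Substitutions hit each base independently with probability
#' `sub_rate`, uniformly among the three alternative bases; the truth
#' ops record them in reference orientation.  Deterministic under
#' `seed`.
#'
#' A contig shorter than the read length yields an empty stream with a
#' warning rather than an error.
#'
#' @param ctg an [contig()].
#' @param n_reads number of reads (counted individually: an odd paired
#'   request is rounded down to a whole number of fragments).
#' @param params [short_read_params()].
#' @param seed integer seed.
#' @param genome_id genome identifier recorded in the truth.
#' @return an `mm_reads` stream.
#' @export
simulate_short <- function(ctg, n_reads, params, seed, genome_id = "") {
  stopifnot(inherits(ctg, "mm_contig"), inherits(params, "mm_short_params"))
  n_reads <- as.integer(n_reads)
  L <- ctg$length; rl <- params$read_length
  if (n_reads <= 0L) return(empty_stream(params$paired))
  if (L < rl) {
    warning(sprintf("contig '%s' (%d bp) shorter than read length %d: skipped",
                    ctg$id, L, rl))
    return(empty_stream(params$paired))
  }
  qual <- quality_ramp(rl, params$q_start, params$q_end)

  with_seed(seed, {
    if (!params$paired) {
      starts0 <- sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L
      strand <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
      frags <- substring(ctg$sequence, starts0 + 1L, starts0 + rl)
      err <- apply_substitutions(frags, params$sub_rate)
      seqs <- err$seqs
      neg <- strand == "-"
      if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
      key <- sprintf("%s|%s|%d", genome_id, ctg$id, seq_len(n_reads))
      df <- data.frame(name = key, sequence = seqs,
                       qualities = rep(qual, n_reads),
                       genome_id = genome_id, contig_id = ctg$id,
                       start = starts0, strand = strand, ops = err$ops,
                       aligned_length = rl, mate = 0L, frag = key,
                       stringsAsFactors = FALSE)
      return(read_stream(df, FALSE))
    }

    nf <- n_reads %/% 2L
    if (n_reads %% 2L == 1L)
      warning("odd paired read count; simulating ", nf, " fragments")
    if (nf == 0L) return(empty_stream(TRUE))
    isize <- as.integer(round(stats::rnorm(nf, params$insert_mean,
                                           params$insert_sd)))
    isize <- pmin(pmax(isize, rl), L)
    starts0 <- as.integer(floor(stats::runif(nf) * (L - isize + 1)))
    flip <- stats::runif(nf) < 0.5     # TRUE: mate1 is the minus-strand mate

    left0 <- starts0
    right0 <- starts0 + isize - rl
    lfrag <- substring(ctg$sequence, left0 + 1L, left0 + rl)
    rfrag <- substring(ctg$sequence, right0 + 1L, right0 + rl)
    lerr <- apply_substitutions(lfrag, params$sub_rate)
    rerr <- apply_substitutions(rfrag, params$sub_rate)

    # plus-strand mate emits the reference-orientation sequence; the
    # minus-strand mate (always the fragment's other end) is revcomped
    lseq <- lerr$seqs
    rseq <- revcomp(rerr$seqs)
    # when flipped, mate1 is the right/- read and mate2 the left/+ read
    m1_start <- ifelse(flip, right0, left0)
    m2_start <- ifelse(flip, left0, right0)
    m1_strand <- ifelse(flip, "-", "+")
    m2_strand <- ifelse(flip, "+", "-")
    m1_seq <- ifelse(flip, rseq, lseq)
    m2_seq <- ifelse(flip, lseq, rseq)
    m1_ops <- ifelse(flip, rerr$ops, lerr$ops)
    m2_ops <- ifelse(flip, lerr$ops, rerr$ops)

    key <- sprintf("%s|%s|%d", genome_id, ctg$id, seq_len(nf))
    idx <- rep(seq_len(nf), each = 2L)
    m <- rep(c(1L, 2L), nf)
    df <- data.frame(
      name = paste0(key[idx], "/", m),
      sequence = ifelse(m == 1L, m1_seq[idx], m2_seq[idx]),
      qualities = qual,
      genome_id = genome_id, contig_id = ctg$id,
      start = ifelse(m == 1L, m1_start[idx], m2_start[idx]),
      strand = ifelse(m == 1L, m1_strand[idx], m2_strand[idx]),
      ops = ifelse(m == 1L, m1_ops[idx], m2_ops[idx]),
      aligned_length = rl, mate = m, frag = key[idx],
      stringsAsFactors = FALSE)
    read_stream(df, TRUE)
  })
}

# Draw one long read's op sequence for a target query length.  Returns a
# character vector over {=, X, I, D}; must run inside with_seed().
draw_long_ops <- function(lq, sub, ins, del) {
  opv <- character(0)
  qc <- 0L
  while (qc < lq) {
    m <- ceiling((lq - qc + 20) / max(1 - del, 1e-9)) + 30L
    u <- stats::runif(m)
    blk <- ifelse(u < del, "D",
           ifelse(u < del + ins, "I",
           ifelse(u < del + ins + sub, "X", "=")))
    opv <- c(opv, blk)
    qc <- sum(opv != "D")
  }
  qcum <- cumsum(opv != "D")
  opv[seq_len(which(qcum == lq)[1])]
}

#' Simulate long reads from one contig
#'
#' Read lengths are log-normal, truncated to [min_length,
#' contig_length].  Errors are applied positionwise while walking the
#' reference: a deletion skips a reference base, an insertion emits a
#' random base without consuming reference, a substitution emits one of
#' the three alternative bases.  The full edit sequence is recorded in
#' the truth ops.  Qualities are constant.  Deterministic under `seed`.
#'
#' @param ctg an [contig()].
#' @param n_reads number of reads.
#' @param params [long_read_params()].
#' @param seed integer seed.
#' @param genome_id genome identifier recorded in the truth.
#' @return an `mm_reads` stream.
#' @export
simulate_long <- function(ctg, n_reads, params, seed, genome_id = "") {
  stopifnot(inherits(ctg, "mm_contig"), inherits(params, "mm_long_params"))
  n_reads <- as.integer(n_reads)
  L <- ctg$length
  if (n_reads <= 0L) return(empty_stream(FALSE))
  if (L < params$min_length) {
    warning(sprintf("contig '%s' (%d bp) shorter than min_length %d: skipped",
                    ctg$id, L, params$min_length))
    return(empty_stream(FALSE))
  }
  qc_char <- substr(phred_to_char(params$quality), 1, 1)

  with_seed(seed, {
    lq <- as.integer(round(stats::rlnorm(n_reads, params$length_log_mean,
                                         params$length_log_sd)))
    lq <- pmin(pmax(lq, params$min_length), L)
    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      opv <- draw_long_ops(lq[i], params$sub_rate, params$ins_rate,
                           params$del_rate)
      ref_flag <- opv != "I"
      # trim ops that would walk off the contig
      rcum <- cumsum(ref_flag)
      if (rcum[length(rcum)] > L) {
        keep <- rcum <= L
        opv <- opv[keep]; ref_flag <- ref_flag[keep]
        rcum <- rcum[keep]
      }
      ref_len <- rcum[length(rcum)]
      start0 <- sample.int(L - ref_len + 1L, 1L) - 1L
      refch <- strsplit(substring(ctg$sequence, start0 + 1L,
                                  start0 + ref_len), "", fixed = TRUE)[[1]]

      rch <- character(length(opv))
      rch[ref_flag] <- refch[rcum[ref_flag]]
      # a substitution at an N reference base stays N -> relabel as match
      fixN <- opv == "X" & rch == "N"
      opv[fixN] <- "="
      out <- rch
      xi <- which(opv == "X")
      if (length(xi))
        out[xi] <- vapply(rch[xi],
                          function(b) sample(setdiff(DNA_BASES, b), 1L),
                          character(1), USE.NAMES = FALSE)
      ii <- which(opv == "I")
      if (length(ii)) out[ii] <- sample(DNA_BASES, length(ii), replace = TRUE)
      qseq <- paste(out[opv != "D"], collapse = "")
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      seq_out <- if (strand == "-") revcomp(qseq) else qseq
      qlen <- nchar(qseq)
      key <- sprintf("%s|%s|%d", genome_id, ctg$id, i)
      rows[[i]] <- data.frame(name = key, sequence = seq_out,
                              qualities = strrep(qc_char, qlen),
                              genome_id = genome_id, contig_id = ctg$id,
                              start = start0, strand = strand,
                              ops = ops_from_flags(opv),
                              aligned_length = qlen, mate = 0L, frag = key,
                              stringsAsFactors = FALSE)
    }
    read_stream(do.call(rbind, rows), FALSE)
  })
}

#' Read count achieving a target coverage depth
#'
#' For short reads the per-read footprint is the read length (paired
#' counts are individual reads, rounded down to an even number); for
#' long reads it is the mean of the length distribution truncated below
#' at `min_length`.
#'
#' @param depth target fold coverage (>= 0).
#' @param genome_length genome size in bases.
#' @param params [short_read_params()] or [long_read_params()].
#' @return integer read count.
#' @export
#' @examples
#' reads_for_depth(1, 1000, short_read_params(read_length = 100))  # 10
reads_for_depth <- function(depth, genome_length, params) {
  if (depth < 0) mm_stop("mm_argument_error", "depth must be >= 0")
  if (depth == 0) return(0L)
  fp <- expected_read_footprint(params)
  n <- round(depth * genome_length / fp)
  if (inherits(params, "mm_short_params") && params$paired)
    n <- n - n %% 2
  as.integer(n)
}

#' Expected bases consumed per read under a parameter set
#' @param params [short_read_params()] or [long_read_params()].
#' @return expected read length in bases.
#' @export
expected_read_footprint <- function(params) {
  if (inherits(params, "mm_short_params")) return(as.double(params$read_length))
  if (inherits(params, "mm_long_params")) {
    a <- params$min_length
    mu <- params$length_log_mean; s <- params$length_log_sd
    # E[max(X, a)] for X ~ lognormal(mu, s): lower-truncation by clamping
    a * stats::plnorm(a, mu, s) +
      exp(mu + s^2 / 2) * stats::pnorm((mu + s^2 - log(a)) / s)
  } else mm_stop("mm_argument_error", "unknown parameter class")
}

#' Verify truth records against the reference
#'
#' Reconstructs each read's alignment from (contig sequence, start,
#' strand, ops) and checks that the emitted sequence is consistent:
#' match segments equal the reference, substitution positions differ,
#' and the query/reference lengths implied by the ops are consumed
#' exactly.
#'
#' @param stream an `mm_reads` stream.
#' @param contigs named list of `mm_contig`, keyed `genome_id|contig_id`
#'   (see [contig_index()]).
#' @return logical vector, one entry per read.
#' @export
check_truth <- function(stream, contigs) {
  toks <- ops_tokens(stream$ops)
  vapply(seq_len(nrow(stream)), function(i) {
    ref <- contigs[[paste0(stream$genome_id[i], "|", stream$contig_id[i])]]
    if (is.null(ref)) return(FALSE)
    q <- stream$sequence[i]
    if (stream$strand[i] == "-") q <- revcomp(q)
    tk <- toks[[i]]
    lens <- as.integer(substring(tk, 1, nchar(tk) - 1L))
    op <- substring(tk, nchar(tk), nchar(tk))
    rpos <- stream$start[i]          # 0-based walker on reference
    qpos <- 0L
    if (rpos + sum(lens[op %in% c("=", "X", "D")]) > ref$length) return(FALSE)
    for (j in seq_along(op)) {
      n <- lens[j]
      if (op[j] == "=") {
        if (substring(ref$sequence, rpos + 1L, rpos + n) !=
            substring(q, qpos + 1L, qpos + n)) return(FALSE)
        rpos <- rpos + n; qpos <- qpos + n
      } else if (op[j] == "X") {
        rs <- strsplit(substring(ref$sequence, rpos + 1L, rpos + n), "")[[1]]
        qs <- strsplit(substring(q, qpos + 1L, qpos + n), "")[[1]]
        if (any(rs == qs)) return(FALSE)
        rpos <- rpos + n; qpos <- qpos + n
      } else if (op[j] == "I") {
        qpos <- qpos + n
      } else if (op[j] == "D") {
        rpos <- rpos + n
      } else return(FALSE)
    }
    qpos == nchar(q)
  }, logical(1))
}

#' Index contigs of several genomes by "genome_id|contig_id"
#'
#' @param genomes list of `mm_genome`.
#' @param sep separator between genome and contig id.
#' @return named list of `mm_contig`.
#' @export
contig_index <- function(genomes, sep = "|") {
  out <- list()
  for (g in genomes)
    for (ct in g$contigs)
      out[[paste0(g$genome_id, sep, ct$id)]] <- ct
  out
}
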