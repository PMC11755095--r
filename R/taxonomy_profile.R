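# Taxonomy resolution and CAMI biobox profiles with both sequence-
# abundance (read share) and taxonomic-abundance (depth share) flavors.

#' Ranks profiled in biobox output, root to leaf
#' @export
BIOBOX_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                  "genus", "species")

#' Read a taxonomy table
#'
#' A minimal NCBI-dump-like dialect: TSV with columns `taxid`, `parent`,
#' `rank`, `name`.  The root is the node whose parent equals its own
#' taxid (or 0/NA).  Ranks outside the seven profiled ranks are carried
#' but skipped in lineages.
#'
#' @param path TSV file.
#' @return object of class `mm_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) mm_stop("mm_io_error", "taxonomy not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxid", "parent", "rank", "name")
  if (!all(need %in% names(tab)))
    mm_stop("mm_format_error", "taxonomy table must have columns: ",
            paste(need, collapse = ", "))
  taxonomy_table(tab)
}

#' Build a taxonomy from a data.frame
#'
#' @param tab data.frame with columns `taxid`, `parent`, `rank`, `name`.
#' @return object of class `mm_taxonomy` (the validated table plus
#'   lookup maps).
#' @export
taxonomy_table <- function(tab) {
  tab$taxid <- as.integer(tab$taxid)
  tab$parent <- as.integer(tab$parent)
  if (anyDuplicated(tab$taxid))
    mm_stop("mm_format_error", "duplicate taxids in taxonomy")
  key <- as.character(tab$taxid)
  structure(list(table = tab,
                 parent = stats::setNames(tab$parent, key),
                 rank = stats::setNames(tab$rank, key),
                 name = stats::setNames(tab$name, key)),
            class = "mm_taxonomy")
}

#' Write a taxonomy table to TSV
#' @param tax an `mm_taxonomy`.
#' @param path output TSV.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Resolve the profiled lineage of a taxon
#'
#' Walks parent links from the taxon to the root and returns the nodes
#' at recognized ranks, ordered root -> leaf.  Missing intermediate
#' ranks are skipped, not padded.
#'
#' @param taxid integer taxon id present in the taxonomy.
#' @param tax an `mm_taxonomy`.
#' @return data.frame with columns `rank`, `taxid`, `name`.
#' @export
lineage <- function(taxid, tax) {
  key <- as.character(taxid)
  if (is.na(tax$parent[key]))
    mm_stop("mm_lookup_error", "taxid ", taxid, " not in taxonomy")
  chain <- integer(0)
  cur <- as.integer(taxid)
  for (step in seq_len(length(tax$parent) + 1L)) {
    chain <- c(cur, chain)
    p <- tax$parent[as.character(cur)]
    if (is.na(p))
      mm_stop("mm_lookup_error", "broken parent link at taxid ", cur)
    if (p == cur || p == 0L) break
    if (p %in% chain)
      mm_stop("mm_taxonomy_error", "cycle detected at taxid ", cur)
    cur <- p
  }
  if (!(tax$parent[as.character(chain[1])] %in% c(chain[1], 0L)))
    mm_stop("mm_taxonomy_error", "parent chain does not reach a root from ",
            taxid)
  rk <- tax$rank[as.character(chain)]
  keep <- rk %in% BIOBOX_RANKS
  out <- data.frame(rank = unname(rk[keep]), taxid = chain[keep],
                    name = unname(tax$name[as.character(chain[keep])]),
                    stringsAsFactors = FALSE)
  out[order(match(out$rank, BIOBOX_RANKS)), , drop = FALSE]
}

new_profile <- function(sample_id, flavor, rows) {
  structure(list(sample_id = sample_id, flavor = flavor, rows = rows),
            class = "mm_profile")
}

#' Build dual-flavor taxonomic profiles from realized statistics
#'
#' For every profiled rank, a taxon's *sequence-abundance* percentage is
#' 100 x (reads of genomes whose lineage passes through it) / (all
#' reads); its *taxonomic-abundance* percentage uses mean coverage depth
#' in place of reads.  The two flavors differ whenever genome sizes
#' differ — the distinction that motivates reporting both.  Genomes
#' sharing a taxid aggregate; zero-abundance taxa are omitted.
#'
#' @param stats data.frame with columns `taxid`, `read_count`,
#'   `mean_depth` (one row per genome, as from [realized_stats()]).
#' @param tax an `mm_taxonomy`.
#' @param sample_id recorded in both profiles.
#' @return list with elements `sequence` and `taxonomic`, each an
#'   `mm_profile` whose `rows` have columns `taxid`, `rank`, `taxpath`,
#'   `taxpathsn`, `percentage`.
#' @export
build_profiles <- function(stats, tax, sample_id = "sample") {
  stopifnot(is.data.frame(stats),
            all(c("taxid", "read_count", "mean_depth") %in% names(stats)))
  if (nrow(stats) == 0 || all(stats$read_count == 0))
    mm_stop("mm_argument_error", "no reads to profile")
  bad <- stats$taxid[is.na(tax$parent[as.character(stats$taxid)])]
  if (length(bad))
    mm_stop("mm_lookup_error", "taxids absent from taxonomy: ",
            paste(unique(bad), collapse = ", "))

  lins <- lapply(unique(stats$taxid), lineage, tax = tax)
  names(lins) <- as.character(unique(stats$taxid))

  tot_reads <- sum(stats$read_count)
  tot_depth <- sum(stats$mean_depth)

  acc <- new.env(parent = emptyenv())   # key: rank|taxid -> accumulated row
  for (i in seq_len(nrow(stats))) {
    lin <- lins[[as.character(stats$taxid[i])]]
    if (nrow(lin) == 0) next
    for (j in seq_len(nrow(lin))) {
      key <- paste0(lin$rank[j], "|", lin$taxid[j])
      cur <- if (!is.null(acc[[key]])) acc[[key]] else
        list(taxid = lin$taxid[j], rank = lin$rank[j],
             taxpath = paste(lin$taxid[seq_len(j)], collapse = "|"),
             taxpathsn = paste(lin$name[seq_len(j)], collapse = "|"),
             reads = 0, depth = 0)
      cur$reads <- cur$reads + stats$read_count[i]
      cur$depth <- cur$depth + stats$mean_depth[i]
      acc[[key]] <- cur
    }
  }
  rows <- do.call(rbind, lapply(ls(acc), function(k) {
    x <- acc[[k]]
    data.frame(taxid = x$taxid, rank = x$rank, taxpath = x$taxpath,
               taxpathsn = x$taxpathsn, reads = x$reads, depth = x$depth,
               stringsAsFactors = FALSE)
  }))

  finish <- function(weight, total, flavor) {
    r <- rows
    r$percentage <- 100 * r[[weight]] / total
    r <- r[r$percentage > 0,
           c("taxid", "rank", "taxpath", "taxpathsn", "percentage")]
    r <- r[order(match(r$rank, BIOBOX_RANKS), -r$percentage, r$taxid), ]
    rownames(r) <- NULL
    new_profile(sample_id, flavor, r)
  }
  list(sequence = finish("reads", tot_reads, "sequence"),
       taxonomic = finish("depth", tot_depth, "taxonomic"))
}

#' Write a profile in CAMI biobox format
#'
#' Emits the `@SampleID`, `@Version`, `@Ranks` headers, the `@@` column
#' line, and tab-separated rows ordered by rank then descending
#' percentage, with percentages printed to six decimals.
#'
#' @param profile an `mm_profile`.
#' @param path output file.
#' @param version biobox version string (default "0.9.1").
#' @return the path, invisibly.
#' @export
write_biobox <- function(profile, path, version = "0.9.1") {
  stopifnot(inherits(profile, "mm_profile"))
  r <- profile$rows
  lines <- c(paste0("@SampleID:", profile$sample_id),
             paste0("@Version:", version),
             paste0("@Ranks:", paste(BIOBOX_RANKS, collapse = "|")),
             "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
             sprintf("%d\t%s\t%s\t%s\t%.6f",
                     r$taxid, r$rank, r$taxpath, r$taxpathsn, r$percentage))
  tryCatch(writeLines(lines, path),
           error = function(e)
             mm_stop("mm_io_error", "cannot write biobox '", path, "': ",
                     conditionMessage(e)))
  invisible(path)
}

#' Read a CAMI biobox profile
#'
#' @param path biobox file written by [write_biobox()] or compatible.
#' @param flavor flavor label to attach (`"sequence"` or `"taxonomic"`).
#' @return an `mm_profile`.
#' @export
read_biobox <- function(path, flavor = "sequence") {
  if (!file.exists(path)) mm_stop("mm_io_error", "profile not found: ", path)
  lines <- readLines(path)
  sid <- sub("^@SampleID:", "", grep("^@SampleID:", lines, value = TRUE)[1])
  data_lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (length(data_lines) == 0)
    return(new_profile(sid, flavor,
                       data.frame(taxid = integer(), rank = character(),
                                  taxpath = character(),
                                  taxpathsn = character(),
                                  percentage = numeric())))
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  rows <- data.frame(taxid = as.integer(vapply(parts, `[`, "", 1)),
                     rank = vapply(parts, `[`, "", 2),
                     taxpath = vapply(parts, `[`, "", 3),
                     taxpathsn = vapply(parts, `[`, "", 4),
                     percentage = as.numeric(vapply(parts, `[`, "", 5)),
                     stringsAsFactors = FALSE)
  new_profile(sid, flavor, rows)
}

#' Per-rank percentage sums of a profile
#'
#' Convenience check that each profiled rank's nonzero percentages sum
#' to 100 (up to printing precision) when every genome has a full
#' lineage.
#'
#' @param profile an `mm_profile`.
#' @return named numeric vector, one sum per rank present.
#' @export
profile_rank_sums <- function(profile) {
  vapply(split(profile$rows$percentage, profile$rows$rank), sum, numeric(1))
}
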