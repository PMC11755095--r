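# Assembly ranking and selection from offline metadata tables.

REFSEQ_CATEGORIES <- c("reference", "representative", "na")
ASSEMBLY_STATUSES <- c("complete", "chromosome", "scaffold", "contig")

#' Default assembly ranking policy
#'
#' Assemblies are compared by RefSeq category (reference before
#' representative before uncategorized), then assembly status (complete,
#' chromosome, scaffold, contig), then BUSCO completeness descending,
#' then checkM completeness descending — genomes with high BUSCO and
#' checkM scores rank higher — with accession as the terminal
#' alphabetical tie-break so the order is total.  Missing completeness
#' scores sort after any present value.
#'
#' @param keys character vector naming the sort keys in order; a subset
#'   or permutation of `c("refseq_category", "assembly_status",
#'   "busco_completeness", "checkm_completeness")`.  `"accession"` is
#'   always appended as the final key.
#' @return object of class `mm_policy`.
#' @export
ranking_policy <- function(keys = c("refseq_category", "assembly_status",
                                    "busco_completeness",
                                    "checkm_completeness")) {
  allowed <- c("refseq_category", "assembly_status", "busco_completeness",
               "checkm_completeness")
  if (!all(keys %in% allowed))
    mm_stop("mm_argument_error", "unknown ranking keys: ",
            paste(setdiff(keys, allowed), collapse = ", "))
  structure(list(keys = c(keys, "accession")), class = "mm_policy")
}

#' Read an assembly metadata table
#'
#' TSV with columns `accession`, `taxid`, `refseq_category` (reference /
#' representative / na), `assembly_status` (complete / chromosome /
#' scaffold / contig), `busco_completeness`, `checkm_completeness`
#' (percent in [0, 100], empty or NA when not measured).
#'
#' @param path TSV file.
#' @return validated data.frame of class `mm_assemblies`.
#' @export
read_assembly_metadata <- function(path) {
  if (!file.exists(path)) mm_stop("mm_io_error", "metadata table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  assembly_records(tab)
}

#' Validate a data.frame of assembly records
#'
#' @param tab data.frame with the columns of [read_assembly_metadata()].
#' @return the validated table, class `mm_assemblies`.
#' @export
assembly_records <- function(tab) {
  need <- c("accession", "taxid", "refseq_category", "assembly_status",
            "busco_completeness", "checkm_completeness")
  if (!all(need %in% names(tab)))
    mm_stop("mm_format_error", "metadata needs columns: ",
            paste(need, collapse = ", "))
  tab$refseq_category <- tolower(ifelse(is.na(tab$refseq_category), "na",
                                        tab$refseq_category))
  tab$assembly_status <- tolower(tab$assembly_status)
  bad <- which(!(tab$refseq_category %in% REFSEQ_CATEGORIES))
  if (length(bad))
    mm_stop("mm_parse_error", "row ", bad[1], ": unknown refseq_category '",
            tab$refseq_category[bad[1]], "'")
  bad <- which(!(tab$assembly_status %in% ASSEMBLY_STATUSES))
  if (length(bad))
    mm_stop("mm_parse_error", "row ", bad[1], ": unknown assembly_status '",
            tab$assembly_status[bad[1]], "'")
  for (col in c("busco_completeness", "checkm_completeness")) {
    v <- tab[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      mm_stop("mm_parse_error", col, " outside [0, 100]")
  }
  tab$taxid <- as.integer(tab$taxid)
  class(tab) <- c("mm_assemblies", "data.frame")
  tab
}

# Numeric sort keys (ascending; missing scores map to +Inf = last).
policy_keys <- function(tab, policy) {
  lapply(policy$keys, function(k) switch(k,
    refseq_category = match(tab$refseq_category, REFSEQ_CATEGORIES),
    assembly_status = match(tab$assembly_status, ASSEMBLY_STATUSES),
    busco_completeness = ifelse(is.na(tab$busco_completeness), Inf,
                                -tab$busco_completeness),
    checkm_completeness = ifelse(is.na(tab$checkm_completeness), Inf,
                                 -tab$checkm_completeness),
    accession = tab$accession))
}

#' Rank assembly records
#'
#' Stable total order under the policy; the result is a permutation of
#' the input with a 1-based `rank` column prepended.
#'
#' @param tab an `mm_assemblies` table (or compatible data.frame).
#' @param policy a [ranking_policy()].
#' @return the reordered table with a `rank` column.
#' @export
rank_assemblies <- function(tab, policy = ranking_policy()) {
  if (!inherits(tab, "mm_assemblies")) tab <- assembly_records(tab)
  if (nrow(tab) == 0) mm_stop("mm_argument_error", "no assembly records")
  ord <- do.call(order, policy_keys(tab, policy))
  out <- tab[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Select the top n assemblies per taxonomic group
#'
#' Groups records by their ancestor at the given rank (records whose
#' lineage lacks that rank fall into an `"unresolved"` group), ranks
#' each group independently, and keeps the best `n` — e.g. the ten
#' best-ranking genomes per genus.
#'
#' @param tab an `mm_assemblies` table.
#' @param tax an `mm_taxonomy` resolving the records' taxids.
#' @param rank grouping rank, one of the seven profiled ranks.
#' @param n maximum records kept per group.
#' @param policy a [ranking_policy()].
#' @return named list, group taxid (or "unresolved") -> ranked table of
#'   at most `n` rows.
#' @export
top_n_per_rank <- function(tab, tax, rank = "genus", n = 10L,
                           policy = ranking_policy()) {
  if (!(rank %in% BIOBOX_RANKS))
    mm_stop("mm_argument_error", "unknown rank '", rank, "'")
  if (n < 1) mm_stop("mm_argument_error", "n must be >= 1")
  if (!inherits(tab, "mm_assemblies")) tab <- assembly_records(tab)
  anc <- vapply(tab$taxid, function(t) {
    lin <- tryCatch(lineage(t, tax), error = function(e) NULL)
    if (is.null(lin)) return("unresolved")
    hit <- lin$taxid[lin$rank == rank]
    if (length(hit)) as.character(hit[1]) else "unresolved"
  }, character(1))
  lapply(split(tab, anc), function(grp)
    utils::head(rank_assemblies(grp, policy), n))
}

#' Filter assembly records by quality constraints
#'
#' Order-preserving subset.  `min_busco` / `min_checkm` drop rows whose
#' score is missing when `drop_missing` is TRUE (absence of evidence is
#' not treated as completeness 0 by default).
#'
#' @param tab an `mm_assemblies` table.
#' @param category keep only these RefSeq categories (NULL: no filter).
#' @param status keep only these assembly statuses (NULL: no filter).
#' @param min_busco,min_checkm minimum completeness scores (NULL: no filter).
#' @param drop_missing drop rows with missing scores when a minimum is
#'   set (default TRUE).
#' @return the filtered table; a warning is issued if empty.
#' @export
filter_assemblies <- function(tab, category = NULL, status = NULL,
                              min_busco = NULL, min_checkm = NULL,
                              drop_missing = TRUE) {
  if (!inherits(tab, "mm_assemblies")) tab <- assembly_records(tab)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(category)) keep <- keep & tab$refseq_category %in% category
  if (!is.null(status)) keep <- keep & tab$assembly_status %in% status
  score_keep <- function(v, minimum) {
    if (drop_missing) !is.na(v) & v >= minimum
    else is.na(v) | v >= minimum
  }
  if (!is.null(min_busco)) keep <- keep & score_keep(tab$busco_completeness, min_busco)
  if (!is.null(min_checkm)) keep <- keep & score_keep(tab$checkm_completeness, min_checkm)
  out <- tab[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("filter_assemblies(): no records pass the constraints")
  rownames(out) <- NULL
  out
}
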