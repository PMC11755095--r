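# Community design: quantities in any unit -> per-genome coverage depths
# and integer read budgets; even / log-normal abundance draws; replicates.

QUANTITY_UNITS <- c("reads", "bases", "coverage", "seq_abundance", "tax_abundance")

#' Construct a community design
#'
#' The simulator's input contract: one sample, a set of genomes with
#' quantities in a single unit, optional sequencing budgets, and a
#' replicate specification.
#'
#' @param sample_id sample name.
#' @param entries data.frame with columns `genome_id`, `quantity`
#'   (non-negative), `unit` (one of reads, bases, coverage,
#'   seq_abundance, tax_abundance).
#' @param total_reads total read budget; required when unit is
#'   `seq_abundance`.
#' @param total_bases total base budget; required when unit is
#'   `tax_abundance`.
#' @param seed master seed for the sample.
#' @param n_replicates number of technical replicates (default 1).
#' @param replicate_sd standard deviation of the per-genome quantity
#'   perturbation between replicates (default 0: replicates differ only
#'   by their child seeds).
#' @return an object of class `mm_design`.
#' @export
community_design <- function(sample_id, entries, total_reads = NULL,
                             total_bases = NULL, seed = 1L,
                             n_replicates = 1L, replicate_sd = 0) {
  stopifnot(is.data.frame(entries),
            all(c("genome_id", "quantity", "unit") %in% names(entries)))
  if (nrow(entries) == 0)
    mm_stop("mm_argument_error", "community has no entries")
  if (any(entries$quantity < 0))
    mm_stop("mm_argument_error", "quantities must be non-negative")
  if (!all(entries$unit %in% QUANTITY_UNITS))
    mm_stop("mm_argument_error", "unknown unit(s): ",
            paste(setdiff(entries$unit, QUANTITY_UNITS), collapse = ", "))
  if (length(unique(entries$unit)) > 1 &&
      any(entries$unit %in% c("seq_abundance", "tax_abundance")))
    mm_stop("mm_argument_error",
            "abundance units cannot be mixed with other units in one sample")
  if (any(entries$unit == "seq_abundance") && is.null(total_reads))
    mm_stop("mm_argument_error", "unit seq_abundance requires total_reads")
  if (any(entries$unit == "tax_abundance") && is.null(total_bases))
    mm_stop("mm_argument_error", "unit tax_abundance requires total_bases")
  if (all(entries$quantity == 0))
    mm_stop("mm_argument_error", "all quantities are zero")
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    mm_stop("mm_argument_error", "n_replicates must be >= 1")
  if (replicate_sd < 0)
    mm_stop("mm_argument_error", "replicate_sd must be >= 0")
  structure(list(sample_id = sample_id,
                 entries = entries[, c("genome_id", "quantity", "unit")],
                 total_reads = if (!is.null(total_reads)) as.double(total_reads),
                 total_bases = if (!is.null(total_bases)) as.double(total_bases),
                 seed = as.integer(seed), n_replicates = n_replicates,
                 replicate_sd = as.double(replicate_sd)),
            class = "mm_design")
}

#' Even abundance fractions
#'
#' @param genome_ids non-empty character vector.
#' @return numeric vector of 1/n for each genome, named by genome_id.
#' @export
draw_even <- function(genome_ids) {
  n <- length(genome_ids)
  if (n < 1) mm_stop("mm_argument_error", "draw_even(): empty genome list")
  stats::setNames(rep(1 / n, n), genome_ids)
}

#' Log-normal abundance fractions
#'
#' Draws exp(Normal(mu, sigma)) per genome and normalizes to sum 1 —
#' the species-abundance distribution conventionally used to model
#' uneven microbial communities.  The unnormalized draws are attached
#' as attribute `"raw"` so their log-moments remain inspectable.
#'
#' @param genome_ids non-empty character vector.
#' @param mu mean of log-abundance (default 1).
#' @param sigma standard deviation of log-abundance, > 0 (default 2).
#' @param seed integer seed.
#' @return named numeric vector summing to 1, attribute `raw` holding
#'   the unnormalized draws.
#' @export
draw_lognormal <- function(genome_ids, mu = 1, sigma = 2, seed = 1L) {
  if (length(genome_ids) < 1)
    mm_stop("mm_argument_error", "draw_lognormal(): empty genome list")
  if (sigma <= 0)
    mm_stop("mm_argument_error", "draw_lognormal(): sigma must be > 0")
  raw <- with_seed(seed, stats::rlnorm(length(genome_ids), mu, sigma))
  out <- stats::setNames(raw / sum(raw), genome_ids)
  attr(out, "raw") <- raw
  out
}

#' Convert a community design to a coverage plan
#'
#' Normalizes per-genome quantities to fold-coverage depths:
#' \itemize{
#'   \item `coverage`: used as given;
#'   \item `bases`: depth = bases / genome_length;
#'   \item `reads`: depth = reads * read_footprint / genome_length
#'     (a paired count is in individual reads; footprint is one mate's
#'     length);
#'   \item `seq_abundance`: fractions normalized to 1, reads_i =
#'     fraction_i * total_reads, then as `reads`;
#'   \item `tax_abundance`: fractions normalized to 1, depth_i =
#'     fraction_i * C_tot with C_tot = total_bases /
#'     sum_i(fraction_i * length_i), so simulated bases total
#'     `total_bases` and depth shares equal the input fractions.
#' }
#' Integer read counts are apportioned by largest-remainder rounding so
#' the sample total matches the read budget exactly when one is implied;
#' with `paired = TRUE` apportionment happens in fragment units (2 reads
#' each) so every genome receives an even read count.
#'
#' @param design an [community_design()] object.
#' @param genome_lengths named numeric vector, genome_id -> bases.
#' @param read_footprint bases consumed per read (one mate's length for
#'   paired short reads; expected read length for long reads).
#' @param paired logical; allocate reads in mate pairs.
#' @param replicate_index integer tag recorded in the plan.
#' @param seed seed recorded in the plan (defaults to the design's).
#' @return an `mm_plan`: data.frame with columns `genome_id`,
#'   `coverage_depth`, `expected_reads`, `expected_bases`, and
#'   attributes `sample_id`, `replicate_index`, `seed`, `paired`,
#'   `read_footprint`.
#' @export
to_coverage <- function(design, genome_lengths, read_footprint,
                        paired = FALSE, replicate_index = 1L, seed = NULL) {
  stopifnot(inherits(design, "mm_design"), read_footprint >= 1)
  e <- design$entries
  missing <- setdiff(e$genome_id, names(genome_lengths))
  if (length(missing))
    mm_stop("mm_lookup_error", "no genome length for: ",
            paste(missing, collapse = ", "))
  len <- as.double(genome_lengths[e$genome_id])
  q <- as.double(e$quantity)
  if (all(q == 0)) mm_stop("mm_argument_error", "all quantities are zero")

  unit <- e$unit
  depth <- numeric(nrow(e))
  budget_reads <- NA_real_     # exact read budget, when one is implied
  for (u in unique(unit)) {
    i <- unit == u
    depth[i] <- switch(u,
      coverage = q[i],
      bases    = q[i] / len[i],
      reads    = q[i] * read_footprint / len[i],
      seq_abundance = {
        frac <- q[i] / sum(q[i])
        frac * design$total_reads * read_footprint / len[i]
      },
      tax_abundance = {
        frac <- q[i] / sum(q[i])
        c_tot <- design$total_bases / sum(frac * len[i])
        frac * c_tot
      })
  }
  if (identical(unique(unit), "seq_abundance")) budget_reads <- design$total_reads
  if (identical(unique(unit), "reads"))         budget_reads <- sum(q)

  reads_real <- depth * len / read_footprint
  if (paired) {
    frag_budget <- if (!is.na(budget_reads)) floor(budget_reads / 2)
                   else round(sum(reads_real) / 2)
    frags <- largest_remainder(reads_real, frag_budget)
    expected_reads <- 2L * frags
  } else {
    total <- if (!is.na(budget_reads)) budget_reads else round(sum(reads_real))
    expected_reads <- largest_remainder(reads_real, total)
  }
  plan <- data.frame(genome_id = e$genome_id,
                     coverage_depth = depth,
                     expected_reads = expected_reads,
                     expected_bases = as.double(expected_reads) * read_footprint,
                     stringsAsFactors = FALSE)
  structure(plan, class = c("mm_plan", "data.frame"),
            sample_id = design$sample_id,
            replicate_index = as.integer(replicate_index),
            seed = if (is.null(seed)) design$seed else as.integer(seed),
            paired = paired, read_footprint = as.double(read_footprint))
}

#' Expand a design into per-replicate coverage plans
#'
#' Technical replicates of one designed metagenome.  Replicate r
#' perturbs each entry's quantity by an independent Normal(0,
#' replicate_sd) draw, truncated at zero, before unit conversion; each
#' replicate receives a distinct deterministic child seed.  With
#' `replicate_sd = 0` (the default) all replicates share identical
#' depths and differ only in their seeds, hence in the genomic origin
#' of the simulated reads.
#'
#' @inheritParams to_coverage
#' @return list of `mm_plan`, length `design$n_replicates`.
#' @export
expand_replicates <- function(design, genome_lengths, read_footprint,
                              paired = FALSE) {
  stopifnot(inherits(design, "mm_design"))
  lapply(seq_len(design$n_replicates), function(r) {
    rep_seed <- child_seed(design$seed, design$sample_id, "replicate", r)
    d <- design
    if (design$replicate_sd > 0) {
      noise <- with_seed(child_seed(rep_seed, "quantity_noise"),
                         stats::rnorm(nrow(d$entries), 0, design$replicate_sd))
      d$entries$quantity <- pmax(0, d$entries$quantity + noise)
      if (all(d$entries$quantity == 0)) d$entries$quantity <- design$entries$quantity
    }
    to_coverage(d, genome_lengths, read_footprint, paired = paired,
                replicate_index = r, seed = rep_seed)
  })
}

#' Read a community table
#'
#' TSV with columns `sample_id`, `genome_id`, `quantity`, `unit`; one
#' design per sample_id.
#'
#' @param path TSV file.
#' @param ... passed to [community_design()] (budgets, seed, replicates).
#' @return named list of `mm_design`, one per sample.
#' @export
read_community_table <- function(path, ...) {
  if (!file.exists(path)) mm_stop("mm_io_error", "community table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genome_id", "quantity", "unit")
  if (!all(need %in% names(tab)))
    mm_stop("mm_format_error", "community table must have columns: ",
            paste(need, collapse = ", "))
  lapply(split(tab, tab$sample_id), function(s)
    community_design(s$sample_id[1], s, ...))
}
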