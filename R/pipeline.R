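# In-process pipeline: config -> community design -> per-contig read
# simulation -> sample assembly -> profiles, in one deterministic run.

default_config <- function() {
  list(simulator = "short",
       short = list(read_length = 150L, paired = FALSE, insert_mean = 400,
                    insert_sd = 25, sub_rate = 0.001, q_start = 37L,
                    q_end = 30L),
       long = list(length_log_mean = 8.5, length_log_sd = 0.45,
                   sub_rate = 0.01, ins_rate = 0.005, del_rate = 0.005,
                   min_length = 200L, quality = 12L),
       total_reads = NULL, total_bases = NULL,
       n_replicates = 1L, replicate_sd = 0,
       compress = TRUE, emit_sam = TRUE, emit_bam = FALSE,
       emit_name_map = FALSE, ref_sep = "|", threads = 1L)
}

#' Load and validate a run configuration
#'
#' A configuration is a YAML file or named list with at least
#' `community` (community table TSV), `manifest` (genome manifest TSV),
#' `taxonomy` (taxonomy TSV) and `output_dir`; optional keys override
#' the defaults: `simulator` ("short"/"long"), `short`/`long` parameter
#' blocks, `total_reads`, `total_bases`, `seed`, `n_replicates`,
#' `replicate_sd`, `compress`, `emit_sam`, `emit_bam`, `emit_name_map`.
#' Referenced paths are checked before any simulation starts; a missing
#' seed is drawn once and recorded in the run manifest.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list of class `mm_config`.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) mm_stop("mm_io_error", "config not found: ", config)
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    for (k in c("community", "manifest", "taxonomy"))
      if (!is.null(config[[k]]) && !file.exists(config[[k]]))
        config[[k]] <- file.path(base, config[[k]])
  }
  cfg <- utils::modifyList(default_config(), config)
  for (k in c("community", "manifest", "taxonomy", "output_dir"))
    if (is.null(cfg[[k]]))
      mm_stop("mm_config_error", "config is missing required key '", k, "'")
  for (k in c("community", "manifest", "taxonomy"))
    if (!file.exists(cfg[[k]]))
      mm_stop("mm_config_error", "config ", k, " path does not exist: ", cfg[[k]])
  if (!(cfg$simulator %in% c("short", "long")))
    mm_stop("mm_config_error", "simulator must be 'short' or 'long'")
  if (is.null(cfg$seed)) cfg$seed <- sample.int(.Machine$integer.max, 1)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("mm_config", "list"))
}

sim_params_from_config <- function(cfg) {
  if (cfg$simulator == "short") do.call(short_read_params, cfg$short)
  else do.call(long_read_params, cfg$long)
}

#' Simulate one sample replicate from a coverage plan
#'
#' The core per-sample path: allocate each genome's read budget across
#' its contigs proportionally to length (largest remainder), simulate
#' per contig under deterministic child seeds, concatenate, shuffle,
#' anonymize.  Contigs shorter than the read length are excluded from
#' allocation with a warning.
#'
#' @param plan an `mm_plan` from [to_coverage()] / [expand_replicates()].
#' @param genomes named list of `mm_genome` (names = genome_id).
#' @param params [short_read_params()] or [long_read_params()].
#' @return list with `stream` (anonymized `mm_reads`) and `name_map`.
#' @export
simulate_plan <- function(plan, genomes, params) {
  paired <- inherits(params, "mm_short_params") && params$paired
  seed <- attr(plan, "seed")
  min_len <- if (inherits(params, "mm_short_params")) params$read_length
             else params$min_length
  streams <- list()
  for (i in seq_len(nrow(plan))) {
    gid <- plan$genome_id[i]
    n <- plan$expected_reads[i]
    if (n == 0L) next
    g <- genomes[[gid]]
    if (is.null(g)) mm_stop("mm_lookup_error", "genome not in manifest: ", gid)
    ctgs <- g$contigs
    ok <- vapply(ctgs, function(ct) ct$length >= min_len, logical(1))
    if (!any(ok))
      mm_stop("mm_argument_error", "genome ", gid,
              " has no contig long enough to simulate from")
    if (!all(ok))
      warning("genome ", gid, ": ", sum(!ok),
              " contig(s) shorter than the read length excluded from allocation")
    ctgs <- ctgs[ok]
    lens <- vapply(ctgs, `[[`, integer(1), "length")
    alloc <- if (paired)
      2L * allocate_reads_per_contig(n %/% 2L, lens)
    else allocate_reads_per_contig(n, lens)
    for (j in seq_along(ctgs)) {
      if (alloc[j] == 0L) next
      cseed <- child_seed(seed, gid, ctgs[[j]]$id)
      s <- if (inherits(params, "mm_short_params"))
        simulate_short(ctgs[[j]], alloc[j], params, cseed, genome_id = gid)
      else simulate_long(ctgs[[j]], alloc[j], params, cseed, genome_id = gid)
      streams[[length(streams) + 1L]] <- s
    }
  }
  if (length(streams) == 0)
    mm_stop("mm_argument_error", "plan produced no reads")
  merged <- concatenate_streams(streams)
  shuffled <- shuffle_reads(merged, child_seed(seed, "shuffle"))
  anonymize_reads(shuffled)
}

#' Run the full simulation pipeline
#'
#' Design -> allocation -> simulation -> assembly -> profiles, for every
#' sample in the community table and every replicate.  Writes per
#' sample-replicate: FASTQ (gzip by default), optional ground-truth
#' SAM/BAM, a realized-stats TSV, sequence- and taxonomic-abundance
#' biobox profiles, plus a machine-readable run manifest
#' (`run_manifest.yaml`) capturing inputs, parameters and seeds.
#'
#' @param config YAML path or list; see [load_config()].
#' @return (invisibly) list of per-sample-replicate results: paths and
#'   in-memory `stats`, `plan`, `profiles`.
#' @export
run_simulation <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  genomes <- read_genome_manifest(cfg$manifest)
  tax <- read_taxonomy(cfg$taxonomy)
  params <- sim_params_from_config(cfg)
  paired <- inherits(params, "mm_short_params") && params$paired
  footprint <- expected_read_footprint(params)
  glens <- vapply(genomes, `[[`, integer(1), "total_length")
  gtax <- vapply(genomes, `[[`, integer(1), "taxid")

  designs <- read_community_table(cfg$community,
                                  total_reads = cfg$total_reads,
                                  total_bases = cfg$total_bases,
                                  seed = cfg$seed,
                                  n_replicates = cfg$n_replicates,
                                  replicate_sd = cfg$replicate_sd)

  results <- list()
  for (design in designs) {
    plans <- expand_replicates(design, glens, footprint, paired = paired)
    for (plan in plans) {
      r <- attr(plan, "replicate_index")
      tag <- if (design$n_replicates > 1)
        sprintf("%s_rep%d", design$sample_id, r) else design$sample_id
      sim <- simulate_plan(plan, genomes, params)
      ext <- if (cfg$compress) ".fastq.gz" else ".fastq"
      fq <- if (paired)
        file.path(cfg$output_dir, paste0(tag, c("_R1", "_R2"), ext))
      else file.path(cfg$output_dir, paste0(tag, ext))
      write_fastq(sim$stream, fq, compress = cfg$compress)

      out <- list(sample_id = design$sample_id, replicate = r, tag = tag,
                  fastq = fq, plan = plan)
      if (isTRUE(cfg$emit_sam) || isTRUE(cfg$emit_bam)) {
        sam <- file.path(cfg$output_dir, paste0(tag, ".truth.sam"))
        out$truth <- write_truth_alignment(sim$stream, genomes, sam,
                                           bam = isTRUE(cfg$emit_bam),
                                           sep = cfg$ref_sep)
      }
      if (isTRUE(cfg$emit_name_map)) {
        nm <- file.path(cfg$output_dir, paste0(tag, ".name_map.tsv"))
        utils::write.table(sim$name_map, nm, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        out$name_map <- nm
      }
      stats <- realized_stats(sim$stream, glens, taxids = gtax)
      stats_path <- file.path(cfg$output_dir, paste0(tag, ".stats.tsv"))
      utils::write.table(stats, stats_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$stats_path <- stats_path; out$stats <- stats

      profs <- build_profiles(stats, tax, sample_id = tag)
      out$profile_sequence <- file.path(cfg$output_dir,
                                        paste0(tag, ".seq_abundance.profile.txt"))
      out$profile_taxonomic <- file.path(cfg$output_dir,
                                         paste0(tag, ".tax_abundance.profile.txt"))
      write_biobox(profs$sequence, out$profile_sequence)
      write_biobox(profs$taxonomic, out$profile_taxonomic)
      out$profiles <- profs
      results[[tag]] <- out
    }
  }

  manifest <- list(package = "metamock",
                   version = as.character(utils::packageVersion("metamock")),
                   seed = cfg$seed,
                   simulator = cfg$simulator,
                   params = cfg[[cfg$simulator]],
                   inputs = cfg[c("community", "manifest", "taxonomy")],
                   n_replicates = cfg$n_replicates,
                   replicate_sd = cfg$replicate_sd,
                   outputs = lapply(results, function(x)
                     x[intersect(c("fastq", "truth", "stats_path",
                                   "profile_sequence", "profile_taxonomic",
                                   "name_map"), names(x))]))
  yaml::write_yaml(manifest, file.path(cfg$output_dir, "run_manifest.yaml"))
  invisible(results)
}

#' Resolve a community table to a coverage-plan TSV
#'
#' The standalone design step: reads a community table (or takes an
#' `mm_design`), converts to coverage, and writes one row per genome and
#' replicate.
#'
#' @param community community table TSV path or an `mm_design`.
#' @param genome_lengths named vector genome_id -> bases.
#' @param out output TSV path (NULL: no file).
#' @param read_footprint bases per read (default 150).
#' @param paired allocate reads in pairs.
#' @param ... passed to [community_design()] via [read_community_table()].
#' @return data.frame of all plans, invisibly when `out` is given.
#' @export
design_community <- function(community, genome_lengths, out = NULL,
                             read_footprint = 150, paired = FALSE, ...) {
  designs <- if (inherits(community, "mm_design")) list(community)
             else read_community_table(community, ...)
  all_plans <- do.call(rbind, lapply(designs, function(d) {
    plans <- expand_replicates(d, genome_lengths, read_footprint,
                               paired = paired)
    do.call(rbind, lapply(plans, function(p)
      cbind(sample_id = attr(p, "sample_id"),
            replicate = attr(p, "replicate_index"),
            as.data.frame(p), seed = attr(p, "seed"))))
  }))
  rownames(all_plans) <- NULL
  if (!is.null(out)) {
    utils::write.table(all_plans, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(all_plans))
  }
  all_plans
}

#' Rank (and optionally select) assemblies from a metadata table
#'
#' The standalone selection step: reads a metadata TSV, applies
#' constraints, ranks under the policy, and either returns the full
#' ranked table or the top-n per taxonomic group.
#'
#' @param metadata metadata TSV path or `mm_assemblies` table.
#' @param out output TSV path (NULL: no file).
#' @param tax an `mm_taxonomy`; required when `rank` is given.
#' @param rank optional grouping rank (e.g. "genus") for per-group caps.
#' @param n records kept per group when `rank` is given (default 10).
#' @param policy a [ranking_policy()].
#' @param ... constraints passed to [filter_assemblies()].
#' @return ranked data.frame (with `group_taxid` column when grouped).
#' @export
rank_assembly_table <- function(metadata, out = NULL, tax = NULL,
                                rank = NULL, n = 10L,
                                policy = ranking_policy(), ...) {
  tab <- if (is.character(metadata)) read_assembly_metadata(metadata)
         else assembly_records(metadata)
  if (length(list(...))) tab <- filter_assemblies(tab, ...)
  if (is.null(rank)) {
    res <- rank_assemblies(tab, policy)
  } else {
    if (is.null(tax))
      mm_stop("mm_argument_error", "per-rank selection needs a taxonomy")
    groups <- top_n_per_rank(tab, tax, rank = rank, n = n, policy = policy)
    res <- do.call(rbind, lapply(names(groups), function(g)
      cbind(group_taxid = g, groups[[g]])))
    rownames(res) <- NULL
  }
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}
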