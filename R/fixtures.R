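# Fixture generation: synthetic genomes, taxonomy, assembly metadata,
# community tables and miniature body-site-style templates, so the full
# pipeline runs and is testable without any network access.

#' Build a small synthetic taxonomy
#'
#' A complete seven-rank tree: `n_species` species distributed over
#' `n_genera` genera under a fixed chain of higher ranks per phylum.
#' Taxids are deterministic small integers; names are synthetic.
#'
#' @param n_species number of species leaves.
#' @param n_genera number of genera (species assigned round-robin).
#' @param n_phyla number of phyla (genera assigned round-robin).
#' @return an `mm_taxonomy`.
#' @export
make_synthetic_taxonomy <- function(n_species = 6L, n_genera = 3L,
                                    n_phyla = 2L) {
  stopifnot(n_species >= 1, n_genera >= 1, n_phyla >= 1,
            n_genera <= n_species, n_phyla <= n_genera)
  rows <- list(list(taxid = 1L, parent = 1L, rank = "no rank", name = "root"),
               list(taxid = 2L, parent = 1L, rank = "superkingdom",
                    name = "Bacteria"))
  nid <- 10L
  phyla <- integer(n_phyla); fam_of_genus <- integer(n_genera)
  for (p in seq_len(n_phyla)) {
    ids <- nid + 0:3; nid <- nid + 10L
    phyla[p] <- ids[1]
    rows <- c(rows, list(
      list(taxid = ids[1], parent = 2L, rank = "phylum",
           name = sprintf("Synthophyla_%d", p)),
      list(taxid = ids[2], parent = ids[1], rank = "class",
           name = sprintf("Synthoclassia_%d", p)),
      list(taxid = ids[3], parent = ids[2], rank = "order",
           name = sprintf("Synthorales_%d", p)),
      list(taxid = ids[4], parent = ids[3], rank = "family",
           name = sprintf("Synthaceae_%d", p))))
  }
  genus_ids <- integer(n_genera)
  for (g in seq_len(n_genera)) {
    p <- ((g - 1L) %% n_phyla) + 1L
    genus_ids[g] <- nid
    rows <- c(rows, list(list(taxid = nid, parent = phyla[p] + 3L,
                              rank = "genus",
                              name = sprintf("Synthomonas_%d", g))))
    nid <- nid + 1L
  }
  species_ids <- integer(n_species)
  for (s in seq_len(n_species)) {
    g <- ((s - 1L) %% n_genera) + 1L
    species_ids[s] <- nid
    rows <- c(rows, list(list(taxid = nid, parent = genus_ids[g],
                              rank = "species",
                              name = sprintf("Synthomonas_%d sp%d", g, s))))
    nid <- nid + 1L
  }
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  tx <- taxonomy_table(tab)
  attr(tx, "species_ids") <- species_ids
  attr(tx, "genus_ids") <- genus_ids
  tx
}

#' Generate a synthetic assembly metadata table
#'
#' Random but seeded records over the given taxids, mixing RefSeq
#' categories, assembly statuses and BUSCO/checkM scores (with a share
#' of missing scores) — exercises every branch of the ranking policy.
#'
#' @param taxids taxids to draw records for (recycled).
#' @param n number of records.
#' @param seed integer seed.
#' @return an `mm_assemblies` table.
#' @export
make_synthetic_metadata <- function(taxids, n = 50L, seed = 1L) {
  with_seed(seed, {
    tab <- data.frame(
      accession = sprintf("GCF_%06d.1", sample.int(999999L, n)),
      taxid = sample(rep_len(taxids, n)),
      refseq_category = sample(REFSEQ_CATEGORIES, n, replace = TRUE,
                               prob = c(0.1, 0.3, 0.6)),
      assembly_status = sample(ASSEMBLY_STATUSES, n, replace = TRUE),
      busco_completeness = round(stats::runif(n, 55, 100), 2),
      checkm_completeness = round(stats::runif(n, 55, 100), 2),
      stringsAsFactors = FALSE)
    tab$busco_completeness[stats::runif(n) < 0.15] <- NA
    tab$checkm_completeness[stats::runif(n) < 0.15] <- NA
    assembly_records(tab)
  })
}

#' Write a complete self-contained fixture set
#'
#' Produces, under `dir`: synthetic genome FASTAs plus a manifest, a
#' taxonomy TSV, an assembly metadata TSV, an example community table,
#' and miniature abundance templates loosely styled after human
#' body-site communities (gut, oral, skin, vaginal) — artificial
#' stand-ins, not curated real-world profiles.  Deterministic under
#' `seed`.
#'
#' @param dir output directory (created if needed).
#' @param n_genomes number of genomes.
#' @param genome_length bases per genome (recycled).
#' @param n_contigs contigs per genome (recycled).
#' @param seed integer seed.
#' @return list with the paths written (`manifest`, `taxonomy`,
#'   `metadata`, `community`, `templates`) and the genome list.
#' @export
make_fixtures <- function(dir, n_genomes = 3L, genome_length = 50000L,
                          n_contigs = 2L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tax <- make_synthetic_taxonomy(n_species = max(n_genomes, 4L))
  species <- attr(tax, "species_ids")
  glen <- rep_len(genome_length, n_genomes)
  nctg <- rep_len(n_contigs, n_genomes)
  genomes <- lapply(seq_len(n_genomes), function(i)
    make_synthetic_genome(glen[i], gc = 0.45 + 0.05 * (i %% 3),
                          n_contigs = nctg[i],
                          seed = child_seed(seed, "genome", i),
                          genome_id = sprintf("SYNG%03d", i),
                          taxid = species[i]))
  fasta_paths <- vapply(genomes, function(g) {
    p <- file.path(dir, paste0(g$genome_id, ".fasta"))
    write_fasta(g, p)
    p
  }, character(1))

  manifest <- file.path(dir, "genomes.tsv")
  utils::write.table(
    data.frame(genome_id = vapply(genomes, `[[`, "", "genome_id"),
               taxid = vapply(genomes, `[[`, 1L, "taxid"),
               fasta_path = basename(fasta_paths)),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)

  taxonomy_path <- file.path(dir, "taxonomy.tsv")
  write_taxonomy(tax, taxonomy_path)

  metadata_path <- file.path(dir, "assemblies.tsv")
  meta <- make_synthetic_metadata(species, n = 12L * length(species),
                                  seed = child_seed(seed, "metadata"))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  community_path <- file.path(dir, "community.tsv")
  utils::write.table(
    data.frame(sample_id = "sample1",
               genome_id = vapply(genomes, `[[`, "", "genome_id"),
               quantity = rep(1, n_genomes),
               unit = "tax_abundance"),
    community_path, sep = "\t", quote = FALSE, row.names = FALSE)

  templates <- file.path(dir, "templates")
  dir.create(templates, showWarnings = FALSE)
  sites <- c("gut", "oral", "skin", "vaginal")
  template_paths <- vapply(seq_along(sites), function(k) {
    frac <- draw_lognormal(as.character(species), mu = 1, sigma = 1.5,
                           seed = child_seed(seed, "template", sites[k]))
    p <- file.path(templates, paste0(sites[k], "_synthetic_template.tsv"))
    utils::write.table(data.frame(taxid = species,
                                  tax_abundance = round(unname(frac), 8)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))

  list(manifest = manifest, taxonomy = taxonomy_path,
       metadata = metadata_path, community = community_path,
       templates = template_paths, genomes = genomes, dir = dir)
}
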