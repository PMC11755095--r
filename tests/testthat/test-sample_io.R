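mk_stream <- function(n = 20, seed = 1, paired = FALSE, genome_id = "G1",
                      len = 5000) {
  g <- make_synthetic_genome(len, seed = seed + 1000, genome_id = genome_id,
                             taxid = 30L)
  p <- short_read_params(read_length = 50, paired = paired,
                         insert_mean = 200, insert_sd = 10, sub_rate = 0.01)
  simulate_short(g$contigs[[1]], n, p, seed = seed, genome_id = genome_id)
}

test_that("concatenation conserves reads and rejects mixed modes", {
  a <- mk_stream(10, 1); b <- mk_stream(14, 2, genome_id = "G2")
  cc <- concatenate_streams(list(a, b))
  expect_equal(nrow(cc), 24)
  expect_identical(cc$name, c(a$name, b$name))
  # empty stream contributes nothing
  cc2 <- concatenate_streams(list(a, mk_stream(0, 3)))
  expect_equal(nrow(cc2), nrow(a))
  expect_error(concatenate_streams(list(a, mk_stream(10, 4, paired = TRUE))),
               class = "mm_argument_error")
})

test_that("shuffling is a seeded fragment-level permutation", {
  s <- concatenate_streams(list(mk_stream(600, 1), mk_stream(400, 2, genome_id = "G2")))
  sh1 <- shuffle_reads(s, seed = 5)
  sh2 <- shuffle_reads(s, seed = 5)
  expect_identical(as.data.frame(sh1), as.data.frame(sh2))
  expect_false(identical(sh1$name, s$name))           # order actually changed
  expect_identical(sort(sh1$name), sort(s$name))      # multiset conserved

  # paired: mates move together, mate order preserved
  sp <- mk_stream(100, 3, paired = TRUE)
  shp <- shuffle_reads(sp, seed = 6)
  odd <- shp[seq(1, nrow(shp), 2), ]; even <- shp[seq(2, nrow(shp), 2), ]
  expect_identical(odd$frag, even$frag)
  expect_true(all(odd$mate == 1L & even$mate == 2L))
})

test_that("anonymization assigns fragment indices and leaks nothing", {
  s <- shuffle_reads(mk_stream(30, 1), seed = 2)
  an <- anonymize_reads(s)
  expect_identical(an$stream$name, as.character(1:30))
  expect_identical(an$name_map$original, s$name)

  sp <- shuffle_reads(mk_stream(8, 2, paired = TRUE), seed = 3)
  anp <- anonymize_reads(sp)
  expect_identical(anp$stream$name, paste0(rep(1:4, each = 2), "/", c(1, 2)))

  # no output name contains any genome or contig id substring
  expect_false(any(grepl("G1|ctg", anp$stream$name)))
})

test_that("FASTQ output round-trips and is gzip by default", {
  s <- anonymize_reads(shuffle_reads(mk_stream(25, 4), seed = 1))$stream
  path <- tempfile(fileext = ".fastq.gz")
  write_fastq(s, path)
  magic <- readBin(path, "raw", 2)
  expect_identical(magic, as.raw(c(0x1f, 0x8b)))
  back <- read_fastq(path)
  expect_identical(back$name, s$name)
  expect_identical(back$sequence, s$sequence)
  expect_identical(back$qualities, s$qualities)

  # paired output: synchronized fragment indices record-for-record
  sp <- anonymize_reads(shuffle_reads(mk_stream(40, 5, paired = TRUE), 2))$stream
  p1 <- tempfile(fileext = "_1.fastq.gz"); p2 <- tempfile(fileext = "_2.fastq.gz")
  write_fastq(sp, c(p1, p2))
  r1 <- read_fastq(p1); r2 <- read_fastq(p2)
  expect_equal(nrow(r1), nrow(r2))
  expect_identical(sub("/1$", "", r1$name), sub("/2$", "", r2$name))
})

test_that("truth SAM uses 1-based coordinates and correct CIGARs", {
  g <- make_synthetic_genome(2000, seed = 7, genome_id = "GS", taxid = 31L)
  df <- data.frame(name = c("1", "2"),
                   sequence = c(substr(g$contigs[[1]]$sequence, 42, 141),
                                paste0(substr(g$contigs[[1]]$sequence, 1, 50),
                                       substr(g$contigs[[1]]$sequence, 53, 100))),
                   qualities = strrep("I", c(100, 98)),
                   genome_id = "GS", contig_id = "GS_ctg1",
                   start = c(41L, 0L), strand = "+",
                   ops = c("100=", "50=2D48="),
                   aligned_length = c(100L, 98L), mate = 0L,
                   frag = c("1", "2"), stringsAsFactors = FALSE)
  stream <- structure(df, class = c("mm_reads", "data.frame"), paired = FALSE)
  sam <- tempfile(fileext = ".sam")
  write_truth_alignment(stream, list(g), sam)
  lines <- readLines(sam)
  recs <- lines[!grepl("^@", lines)]
  f1 <- strsplit(recs[1], "\t")[[1]]
  expect_equal(as.integer(f1[4]), 42)         # POS = 0-based start + 1
  expect_equal(f1[6], "100M")
  f2 <- strsplit(recs[2], "\t")[[1]]
  expect_equal(f2[6], "50M2D48M")

  # unknown contig -> consistency error
  bad <- stream; bad$contig_id <- "nope"
  expect_error(write_truth_alignment(bad, list(g), tempfile()),
               class = "mm_consistency_error")
})

test_that("truth SAM passes an independent validator (paired, with errors)", {
  g <- make_synthetic_genome(20000, seed = 8, genome_id = "GV", taxid = 32L)
  p <- short_read_params(read_length = 100, paired = TRUE, insert_mean = 300,
                         insert_sd = 25, sub_rate = 0.02)
  s <- simulate_short(g$contigs[[1]], 400, p, seed = 9, genome_id = "GV")
  s <- anonymize_reads(shuffle_reads(s, 1))$stream
  sam <- tempfile(fileext = ".sam")
  write_truth_alignment(s, list(g), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  expect_true(file.exists(bam))
  counted <- Rsamtools::countBam(bam)$records
  expect_equal(counted, nrow(s))
})

test_that("realized statistics recompute depth from reference-consumed bases", {
  g <- make_synthetic_genome(1000, seed = 10, genome_id = "GR", taxid = 33L)
  p <- short_read_params(read_length = 100, sub_rate = 0)
  s <- simulate_short(g$contigs[[1]], 10, p, seed = 11, genome_id = "GR")
  st <- realized_stats(s, c(GR = 1000, GZ = 500), taxids = c(GR = 33L, GZ = 34L))
  expect_equal(st$read_count, c(10L, 0L))
  expect_equal(st$mean_depth, c(1.0, 0.0))     # zero-read genome retained

  # with deletions, depth counts match + deleted reference bases
  df <- s[1, ]
  df$ops <- "50=10D50="
  df$sequence <- paste0(substr(g$contigs[[1]]$sequence, df$start + 1, df$start + 50),
                        substr(g$contigs[[1]]$sequence, df$start + 61, df$start + 110))
  dstream <- structure(df, class = c("mm_reads", "data.frame"), paired = FALSE)
  std <- realized_stats(dstream, c(GR = 1000))
  expect_equal(std$mean_depth[1], 110 / 1000)  # brute-force: 50+10+50
})
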