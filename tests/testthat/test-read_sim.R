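ctg100k <- make_synthetic_genome(100000, gc = 0.5, seed = 101,
                                 genome_id = "RS")$contigs[[1]]

test_that("reads are allocated across contigs by largest remainder", {
  expect_equal(allocate_reads_per_contig(10, 1000), 10L)
  expect_equal(allocate_reads_per_contig(10, c(600, 400)), c(6L, 4L))
  expect_equal(allocate_reads_per_contig(7, c(500, 300, 200)), c(4L, 2L, 1L))
  expect_equal(sum(allocate_reads_per_contig(1234, c(17, 5, 91, 3))), 1234L)
  expect_error(allocate_reads_per_contig(5, integer(0)),
               class = "mm_argument_error")
})

test_that("error-free short reads are exact substrings with exact truth", {
  p <- short_read_params(read_length = 100, sub_rate = 0)
  s <- simulate_short(ctg100k, 50, p, seed = 1, genome_id = "RS")
  expect_equal(nrow(s), 50)
  expect_true(all(nchar(s$sequence) == 100))
  expect_true(all(nchar(s$qualities) == 100))
  expect_true(all(s$ops == "100="))
  idx <- list(`RS|RS_ctg1` = ctg100k)
  expect_true(all(check_truth(s, idx)))
  expect_true(all(c("+", "-") %in% s$strand))

  # depth arithmetic: 10 x 100 bp on 1000 bases = depth exactly 1
  small <- contig("c", substr(ctg100k$sequence, 1, 1000))
  s2 <- simulate_short(small, 10, p, seed = 2, genome_id = "g")
  expect_equal(sum(nchar(s2$sequence)) / 1000, 1.0)
})

test_that("substitution rate is calibrated (binomial oracle)", {
  p <- short_read_params(read_length = 100, sub_rate = 0.1)
  s <- simulate_short(ctg100k, 200, p, seed = 3, genome_id = "RS")
  # >= 20,000 simulated bases; mismatches counted from coordinates alone
  rate <- observed_mismatch_rate(s, list(`RS|RS_ctg1` = ctg100k))
  expect_gt(rate, 0.09)
  expect_lt(rate, 0.11)
  expect_true(all(check_truth(s, list(`RS|RS_ctg1` = ctg100k))))
})

test_that("paired simulation respects FR orientation and pairing", {
  p <- short_read_params(read_length = 100, paired = TRUE,
                         insert_mean = 300, insert_sd = 20, sub_rate = 0)
  s <- simulate_short(ctg100k, 200, p, seed = 4, genome_id = "RS")
  expect_equal(nrow(s), 200)
  m1 <- s[s$mate == 1L, ]; m2 <- s[s$mate == 2L, ]
  expect_equal(m1$frag, m2$frag)
  expect_true(all(m1$strand != m2$strand))          # FR: opposite strands
  expect_true(all(grepl("/1$", m1$name)) && all(grepl("/2$", m2$name)))
  # the plus-strand mate lies left of the minus-strand mate (innie)
  plus_start <- ifelse(m1$strand == "+", m1$start, m2$start)
  minus_start <- ifelse(m1$strand == "-", m1$start, m2$start)
  expect_true(all(plus_start <= minus_start))
  expect_true(all(check_truth(s, list(`RS|RS_ctg1` = ctg100k))))
})

test_that("short simulation is seed-stable and skips too-short contigs", {
  p <- short_read_params(read_length = 100, sub_rate = 0.02)
  a <- simulate_short(ctg100k, 100, p, seed = 9, genome_id = "RS")
  b <- simulate_short(ctg100k, 100, p, seed = 9, genome_id = "RS")
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_short(ctg100k, 100, p, seed = 10, genome_id = "RS")
  expect_false(identical(a$sequence, c2$sequence))

  stub <- contig("stub", "ACGTACGT")
  expect_warning(out <- simulate_short(stub, 5, p, seed = 1), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("long reads honor length and indel models", {
  # perfect long reads are exact substrings with a single match op
  p0 <- long_read_params(sub_rate = 0, ins_rate = 0, del_rate = 0,
                         length_log_mean = 7, length_log_sd = 0.3,
                         min_length = 100)
  s0 <- simulate_long(ctg100k, 30, p0, seed = 5, genome_id = "RS")
  expect_true(all(grepl("^[0-9]+=$", s0$ops)))
  idx <- list(`RS|RS_ctg1` = ctg100k)
  expect_true(all(check_truth(s0, idx)))

  # deletion-rate binomial oracle over >= 1e5 reference bases
  pd <- long_read_params(sub_rate = 0, ins_rate = 0, del_rate = 0.1,
                         length_log_mean = 8, length_log_sd = 0.2,
                         min_length = 200)
  sd_ <- simulate_long(ctg100k, 60, pd, seed = 6, genome_id = "RS")
  toks <- regmatches(sd_$ops, gregexpr("[0-9]+[=XID]", sd_$ops))
  del <- sum(vapply(toks, function(tk) {
    op <- substring(tk, nchar(tk), nchar(tk))
    sum(as.integer(substring(tk, 1, nchar(tk) - 1))[op == "D"])
  }, numeric(1)))
  ref <- sum(vapply(toks, function(tk) {
    op <- substring(tk, nchar(tk), nchar(tk))
    sum(as.integer(substring(tk, 1, nchar(tk) - 1))[op %in% c("=", "X", "D")])
  }, numeric(1)))
  expect_gt(ref, 1e5)
  expect_lt(abs(del / ref - 0.1), 3 * sqrt(0.1 * 0.9 / ref))
  expect_true(all(check_truth(sd_, idx)))

  # length moment recovery (log scale) on a wide contig
  pl <- long_read_params(sub_rate = 0, ins_rate = 0, del_rate = 0,
                         length_log_mean = 8, length_log_sd = 0.4,
                         min_length = 10)
  sl <- simulate_long(ctg100k, 5000, pl, seed = 7, genome_id = "RS")
  ll <- log(sl$aligned_length)
  expect_lt(abs(mean(ll) - 8) / 8, 0.05)
  expect_lt(abs(sd(ll) - 0.4) / 0.4, 0.05)

  expect_error(long_read_params(sub_rate = 0.5, ins_rate = 0.3, del_rate = 0.3),
               class = "mm_argument_error")
})

test_that("reads_for_depth bridges depth to read counts", {
  expect_equal(reads_for_depth(1, 1000, short_read_params(read_length = 100)), 10L)
  expect_equal(reads_for_depth(0, 1e6, short_read_params()), 0L)
  p <- short_read_params(read_length = 100, paired = TRUE, insert_mean = 300)
  expect_equal(reads_for_depth(10, 100000, p), 10000L)
  expect_equal(reads_for_depth(10, 100000, p) %% 2, 0)

  # long-read footprint: clamped-lognormal mean, sanity against simulation
  pl <- long_read_params(length_log_mean = 8, length_log_sd = 0.4,
                         min_length = 10)
  fp <- expected_read_footprint(pl)
  expect_equal(fp, exp(8 + 0.4^2 / 2), tolerance = 0.01)  # clamp negligible
})

test_that("read sampling is uniform across the genome", {
  p <- short_read_params(read_length = 100, sub_rate = 0)
  n <- reads_for_depth(20, ctg100k$length, p)   # depth 20 on 100 kb
  s <- simulate_short(ctg100k, n, p, seed = 8, genome_id = "RS")
  bins <- cut(s$start, breaks = seq(0, ctg100k$length, by = 10000),
              include.lowest = TRUE, right = FALSE)
  counts <- as.integer(table(bins))
  expected <- n / 10
  sigma <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(counts - expected) < 5 * sigma))
})
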