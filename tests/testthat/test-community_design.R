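entries <- function(ids, q, unit) {
  data.frame(genome_id = ids, quantity = q, unit = unit,
             stringsAsFactors = FALSE)
}

test_that("even and lognormal draws behave as distributions", {
  expect_equal(unname(draw_even(letters[1:4])), rep(0.25, 4))
  expect_equal(unname(draw_even("g")), 1)
  expect_equal(sum(draw_even(letters[1:3])), 1, tolerance = 1e-12)
  expect_error(draw_even(character(0)), class = "mm_argument_error")

  a <- draw_lognormal(letters[1:5], seed = 42)
  b <- draw_lognormal(letters[1:5], seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_error(draw_lognormal(letters[1:3], sigma = 0),
               class = "mm_argument_error")

  # sigma -> 0 limit approaches even fractions
  tiny <- draw_lognormal(letters[1:6], mu = 1, sigma = 1e-8, seed = 1)
  expect_equal(unname(tiny), rep(1 / 6, 6), tolerance = 1e-6,
               ignore_attr = TRUE)

  # moment recovery on the raw (unnormalized) draws
  x <- draw_lognormal(as.character(1:10000), mu = 1, sigma = 2, seed = 99)
  lr <- log(attr(x, "raw"))
  expect_lt(abs(mean(lr) - 1) / 1, 0.05)
  expect_lt(abs(sd(lr) - 2) / 2, 0.05)
})

test_that("to_coverage implements every unit's semantics", {
  lens <- c(A = 100000, B = 2e6, C = 1e6)

  d <- community_design("s", entries("A", 5, "coverage"))
  expect_equal(to_coverage(d, lens, 100)$coverage_depth, 5)

  d <- community_design("s", entries("A", 2000, "reads"))
  p <- to_coverage(d, lens, 100)
  expect_equal(p$coverage_depth, 2)               # 2000*100/100000
  expect_equal(p$expected_reads, 2000L)           # identity up to rounding

  d <- community_design("s", entries("A", 300000, "bases"))
  expect_equal(to_coverage(d, lens, 100)$coverage_depth, 3)

  # tax_abundance worked example: fractions (.5,.5), lengths 1e6/2e6,
  # total 3e6 bases -> C_tot = 2, depths (1,1), read shares (1/3, 2/3)
  d <- community_design("s", entries(c("C", "B"), c(0.5, 0.5), "tax_abundance"),
                        total_bases = 3e6)
  p <- to_coverage(d, lens, 100)
  expect_equal(p$coverage_depth, c(1, 1), tolerance = 1e-12)
  expect_equal(p$expected_reads / sum(p$expected_reads), c(1 / 3, 2 / 3),
               tolerance = 1e-9)
  expect_equal(sum(p$expected_bases), 3e6)

  # seq_abundance: read shares equal the input fractions exactly
  d <- community_design("s", entries(c("B", "C"), c(0.25, 0.75), "seq_abundance"),
                        total_reads = 10000)
  p <- to_coverage(d, lens, 100)
  expect_equal(sum(p$expected_reads), 10000L)
  expect_equal(p$expected_reads / 10000, c(0.25, 0.75))

  expect_error(to_coverage(community_design("s", entries("ZZ", 1, "coverage")),
                           lens, 100),
               class = "mm_lookup_error")
  expect_error(community_design("s", entries("A", 0, "coverage")),
               class = "mm_argument_error")
})

test_that("design contracts are enforced", {
  expect_error(community_design("s", entries("A", 1, "seq_abundance")),
               class = "mm_argument_error")   # needs total_reads
  expect_error(community_design("s", entries("A", 1, "tax_abundance")),
               class = "mm_argument_error")   # needs total_bases
  expect_error(community_design("s", entries("A", -1, "reads")),
               class = "mm_argument_error")
  expect_error(community_design("s", entries("A", 1, "furlongs")),
               class = "mm_argument_error")
  expect_error(community_design("s", entries("A", 1, "coverage"),
                                n_replicates = 0),
               class = "mm_argument_error")
})

test_that("conservation and fidelity invariants hold across units", {
  lens <- c(A = 123457, B = 765432, C = 333333)
  fp <- 150
  units <- list(
    community_design("s", entries(names(lens), c(2, 5, 1), "coverage")),
    community_design("s", entries(names(lens), c(1e5, 4e5, 2e5), "bases")),
    community_design("s", entries(names(lens), c(1000, 2000, 500), "reads")),
    community_design("s", entries(names(lens), c(0.2, 0.5, 0.3), "seq_abundance"),
                     total_reads = 9000),
    community_design("s", entries(names(lens), c(0.2, 0.3, 0.5), "tax_abundance"),
                     total_bases = 5e6))
  for (d in units) {
    p <- to_coverage(d, lens, fp)
    implied <- sum(p$coverage_depth * lens[p$genome_id])
    realized <- sum(p$expected_reads) * fp
    expect_lt(abs(realized - implied), nrow(p) * fp)
  }

  # taxonomic-abundance fidelity: depth shares equal normalized input
  d <- units[[5]]
  p <- to_coverage(d, lens, fp)
  expect_equal(p$coverage_depth / sum(p$coverage_depth), c(0.2, 0.3, 0.5),
               tolerance = 1e-9)
  # and the base budget is met
  expect_equal(sum(p$coverage_depth * lens[p$genome_id]), 5e6,
               tolerance = 1e-6)

  # paired allocation: every genome's count is even, total preserved
  p2 <- to_coverage(units[[4]], lens, fp, paired = TRUE)
  expect_true(all(p2$expected_reads %% 2 == 0))
  expect_equal(sum(p2$expected_reads), 9000)
})

test_that("replicates perturb quantities deterministically and never go negative", {
  lens <- c(A = 50000, B = 80000)
  d <- community_design("s", entries(names(lens), c(3, 4), "coverage"),
                        seed = 11, n_replicates = 3, replicate_sd = 0)
  plans <- expand_replicates(d, lens, 100)
  expect_length(plans, 3)
  depths <- vapply(plans, function(p) p$coverage_depth, numeric(2))
  expect_true(all(depths == depths[, 1]))        # sd = 0: identical depths
  seeds <- vapply(plans, attr, integer(1), "seed")
  expect_length(unique(seeds), 3)                # distinct child seeds

  plans2 <- expand_replicates(d, lens, 100)
  expect_identical(seeds, vapply(plans2, attr, integer(1), "seed"))

  # truncation at zero under violent noise, checked over the whole draw set
  dn <- community_design("s", entries(names(lens), c(1, 1), "coverage"),
                         seed = 5, n_replicates = 500, replicate_sd = 10)
  pn <- expand_replicates(dn, lens, 100)
  all_depths <- unlist(lapply(pn, function(p) p$coverage_depth))
  expect_true(all(all_depths >= 0))
  expect_true(sd(all_depths) > 1)                # noise actually applied
})
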