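test_that("seed extraction strides and adds a flush-right seed, skipping N", {
  s <- extract_seeds("ATGTATGT", 4, 4)
  expect_identical(s$offset, c(0L, 4L))
  expect_identical(s$seed, c("ATGT", "ATGT"))

  s <- extract_seeds("ATGTATG", 4, 4)
  expect_identical(s$offset, c(0L, 3L))
  expect_identical(s$seed, c("ATGT", "TATG"))

  s <- extract_seeds("ATNTATGT", 4, 4)
  expect_identical(s$offset, 4L)
  expect_identical(s$seed, "ATGT")

  expect_identical(nrow(extract_seeds("ATG", 4)), 0L)
})

test_that("candidate voting merges diagonals and skips repeat seeds", {
  # genome with 'ATGTA' at two distant spots in converted space
  g <- tiny_genome(chr1 = "ATGTAAAAAAATGTAAAAAAAAAAAAAAAAAAAAAAAAAA")
  idx <- build_genome_index(g, seed_len = 5)
  seeds <- data.frame(offset = 0L, seed = "ATGTA", stringsAsFactors = FALSE)
  cand <- collect_candidates(idx, seeds, max_seed_hits = 1000, max_d = 2)
  expect_identical(cand$concat_pos, c(0L, 10L))
  expect_identical(cand$votes, c(1L, 1L))

  # two seeds voting for the same diagonal accumulate
  seeds2 <- data.frame(offset = c(0L, 6L), seed = c("AAAAAA", "AAAAAA"))
  g2 <- tiny_genome(chr1 = "AAAAAAAAAAAATTTTTTTTTTTTTTTTTTTT")
  idx2 <- build_genome_index(g2, seed_len = 6)
  cand2 <- collect_candidates(idx2, data.frame(offset = c(0L, 6L),
                                               seed = c("AAAAAA", "AAAAAA")),
                              max_seed_hits = 1000, max_d = 1)
  expect_identical(cand2$votes[1], 2L)

  # a seed above the hit cap contributes nothing
  cand3 <- collect_candidates(idx2, seeds2, max_seed_hits = 2, max_d = 1)
  expect_identical(nrow(cand3), 0L)
})

test_that("banded edit distance handles identity, all-indel and out-of-band cases", {
  expect_identical(banded_edit_distance("ACGT", "ACGT", 2)$distance, 0)
  expect_identical(banded_edit_distance("", "ABC", 3)$distance, 3)
  expect_identical(banded_edit_distance("ATGT", "AGT", 2)$distance, 1)
  expect_identical(banded_edit_distance("ATGT", "CCCC", 2)$distance, Inf)
  expect_null(banded_edit_distance("ATGT", "CCCC", 2)$script)
})

test_that("banded distance agrees with the full DP whenever it is in band", {
  set.seed(99)
  for (i in 1:300) {
    la <- sample(0:30, 1); lb <- sample(0:30, 1)
    a <- if (la) random_dna(la) else ""
    b <- if (lb) random_dna(lb) else ""
    max_d <- sample(0:6, 1)
    truth <- full_dp_distance(a, b)
    got <- banded_edit_distance(a, b, max_d)$distance
    if (truth <= max_d) expect_equal(got, truth) else expect_identical(got, Inf)
  }
})

test_that("edit scripts are consistent with the reported distance", {
  set.seed(7)
  for (i in 1:100) {
    a <- random_dna(sample(5:25, 1))
    b <- random_dna(sample(5:25, 1))
    res <- banded_edit_distance(a, b, 6)
    if (is.infinite(res$distance)) next
    ops <- paste(rep(res$script$op, res$script$length), collapse = "")
    counts <- apply_script(ops, a, b)  # errors if ops disagree with bases
    expect_identical(counts$subs + counts$indels, as.integer(res$distance))
  }
})

test_that("error-free reads are recovered uniquely at their true locus", {
  set.seed(21)
  g <- random_genome(c(chr1 = 100000))
  me <- simulate_methylome(g, 0, 0, 0)
  sim <- simulate_reads(g, me, 3000, 30, sub_rate = 0, indel_rate = 0,
                        conversion_rate = 1)
  idx <- build_genome_index(g)
  aln <- align_reads(sim$reads, idx, aligner_params(read_len = 30))
  ev <- evaluate_mapping(aln, sim$truth, tolerance_bp = 0)
  expect_gte(ev$pct_correct, 0.99)
  # exact loci, not merely within tolerance
  m <- match(sim$truth$read_id, aln$read_id)
  uq <- aln$status[m] == "unique"
  expect_true(all(aln$pos[m][uq] == sim$truth$pos[uq]))
})

test_that("Watson- and Crick-origin reads map with symmetric accuracy", {
  set.seed(31)
  g <- random_genome(c(chr1 = 100000))
  me <- simulate_methylome(g, 0.8, 0.3, 0.05)
  sim <- simulate_reads(g, me, 4000, 100, sub_rate = 0.01, indel_rate = 0.01,
                        conversion_rate = 0.99)
  idx <- build_genome_index(g)
  aln <- align_reads(sim$reads, idx)
  acc <- vapply(c("+", "-"), function(std) {
    tr <- sim$truth[sim$truth$strand == std, ]
    evaluate_mapping(aln[aln$read_id %in% tr$read_id, ], tr)$pct_correct
  }, numeric(1))
  n <- min(table(sim$truth$strand))
  se <- sqrt(mean(acc) * (1 - mean(acc)) / n)
  expect_lt(abs(acc[1] - acc[2]), 4 * se + 1e-9)
})

test_that("reads of Ns or too-short reads are unmapped", {
  g <- random_genome(c(chr1 = 5000))
  idx <- build_genome_index(g)
  reads <- data.frame(read_id = c("n", "short"),
                      seq = c(strrep("N", 30), "ACGT"),
                      stringsAsFactors = FALSE)
  aln <- align_reads(reads, idx)
  expect_identical(aln$status, c("unmapped", "unmapped"))
})

test_that("the reverse complement of a Watson segment maps to '-'", {
  set.seed(8)
  g <- random_genome(c(chr1 = 20000))
  idx <- build_genome_index(g)
  seg <- substring(g$seqs[["chr1"]], 501, 560)
  aln <- align_read("rc", reverse_complement(seg), idx,
                    aligner_params(read_len = 60))
  expect_identical(aln$status, "unique")
  expect_identical(aln$strand, "-")
  expect_identical(aln$pos, 500L)
  expect_identical(aln$edit_distance, 0L)
})
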