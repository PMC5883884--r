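test_that("per-cycle mismatch rates count true mismatches only", {
  set.seed(41)
  g <- bs_genome(c(chr1 = random_dna(500)))
  seg <- function(a, len) substring(g$seqs[[1]], a + 1, a + len)
  perfect <- do.call(rbind, lapply(1:10, function(i)
    manual_alignment(paste0("p", i), seg(10 * i, 4), "chr1",
                     10 * i, "+", "MMMM")))
  prof <- mismatch_by_position(perfect, g)
  expect_true(all(prof$mismatch_rate == 0))
  expect_identical(prof$n_observations, rep(10L, 4))

  # one read with a substitution at cycle 2 among the 10 perfect ones
  rd <- strsplit(seg(200, 4), "")[[1]]
  rd[2] <- setdiff(c("A", "C", "G", "T"), c(rd[2], "T"))[1]
  bad <- manual_alignment("bad", paste(rd, collapse = ""), "chr1", 200, "+",
                          paste0("M", "X", "MM"))
  prof2 <- mismatch_by_position(rbind(perfect, bad), g)
  expect_equal(prof2$mismatch_rate[2], 1 / 11)
  expect_true(all(prof2$mismatch_rate[-2] == 0))
})

test_that("conversion events never count as cycle mismatches", {
  g <- tiny_genome(chr1 = "CCCCCCCC")
  aln <- manual_alignment("conv", "TTTTTTTT", "chr1", 0, "+", strrep("M", 8))
  prof <- mismatch_by_position(aln, g)
  expect_true(all(prof$mismatch_rate == 0))
  expect_identical(prof$n_observations, rep(1L, 8))
})

test_that("conversion efficiency is the converted fraction on the spike-in", {
  tab <- data.frame(
    chrom = rep("lambda", 10), pos = 1:10 * 3, strand = "+",
    context = rep(c("CG", "CHH"), 5), dinucleotide = "CA",
    meth_count = c(5, rep(0, 9)), total_count = rep(10, 10),
    stringsAsFactors = FALSE
  )
  eff <- conversion_efficiency(tab, "lambda")
  expect_identical(eff$converted, 95)
  expect_identical(eff$unconverted, 5)
  expect_equal(eff$efficiency, 0.95)

  tab$meth_count <- 0
  expect_equal(conversion_efficiency(tab, "lambda")$efficiency, 1.0)
  expect_error(conversion_efficiency(tab, "phiX"), "no spike-in coverage")
  eff_ch <- conversion_efficiency(tab, "lambda", ch_only = TRUE)
  expect_identical(eff_ch$converted + eff_ch$unconverted, 50)
})

test_that("window levels are pooled counts, not means of site levels", {
  tab <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 5000L), strand = "+",
    context = "CG", dinucleotide = "CG",
    meth_count = c(1L, 0L, 1L), total_count = c(1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  w <- genome_windows(tab, 1000)
  expect_identical(nrow(w), 2L)
  expect_equal(w$level[w$window_start == 0], 0.5)     # (1+0)/(1+1)
  expect_equal(w$level[w$window_start == 5000], 0.5)  # 1/2 alone in window
  expect_identical(nrow(genome_windows(tab[0, ], 1000)), 0L)
})

test_that("a chromosome-sized window reproduces the chromosome-wide level", {
  set.seed(43)
  tab <- data.frame(
    chrom = "chr1", pos = sort(sample(0:9999, 200)), strand = "+",
    context = sample(c("CG", "CHG", "CHH"), 200, replace = TRUE),
    dinucleotide = "CG",
    meth_count = rbinom(200, 5, 0.3), total_count = 5L,
    stringsAsFactors = FALSE
  )
  w <- genome_windows(tab, 10000)
  for (ctx in unique(tab$context)) {
    sub <- tab[tab$context == ctx, ]
    expect_equal(w$level[w$context == ctx],
                 sum(sub$meth_count) / sum(sub$total_count))
  }
})

test_that("efficiency equals one minus the spike-in chromosome level", {
  set.seed(47)
  tab <- data.frame(
    chrom = "lambda", pos = sort(sample(0:47999, 300)), strand = "+",
    context = sample(c("CG", "CHG", "CHH"), 300, replace = TRUE),
    dinucleotide = "CG",
    meth_count = rbinom(300, 4, 0.01), total_count = 4L,
    stringsAsFactors = FALSE
  )
  eff <- conversion_efficiency(tab, "lambda")$efficiency
  w <- genome_windows(tab, 48000)
  pooled <- sum(w$meth_count) / sum(w$total_count)
  expect_equal(eff, 1 - pooled)
})

test_that("metaplot bins pool counts and mirror by feature strand", {
  tab <- data.frame(
    chrom = "chr1",
    pos = c(500L, 1500L, 2500L), strand = "+",
    context = "CG", dinucleotide = "CG",
    meth_count = c(2L, 4L, 0L), total_count = c(2L, 4L, 4L),
    stringsAsFactors = FALSE
  )
  feats <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                      strand = "+", stringsAsFactors = FALSE)
  mp <- metaplot(tab, feats, body_bins = 10, flank_bp = 1000, flank_bins = 5)
  pr <- mp$profile[mp$profile$context == "CG", ]
  expect_identical(mp$n_bins, 20L)
  # site at 1500 is fully methylated, mid-body
  expect_equal(pr$level[pr$bin == 11], 1.0)
  # upstream site 500 -> flank bin 3; downstream 2500 -> bin 18
  expect_equal(pr$level[pr$bin == 3], 1.0)
  expect_equal(pr$level[pr$bin == 18], 0.0)

  feats$strand <- "-"
  mp2 <- metaplot(tab, feats, body_bins = 10, flank_bp = 1000, flank_bins = 5)
  pr2 <- mp2$profile[mp2$profile$context == "CG", ]
  expect_equal(pr2$level, rev(pr$level))
  expect_equal(pr2$total_count, rev(pr$total_count))

  expect_error(metaplot(tab, feats[0, ]), "empty feature set")
})

test_that("a flat simulated methylome gives a flat metagene profile", {
  set.seed(53)
  p_cg <- 0.8
  tab <- data.frame(
    chrom = "chr1", pos = sort(sample(0:49999, 3000)), strand = "+",
    context = "CG", dinucleotide = "CG",
    meth_count = rbinom(3000, 10, p_cg), total_count = 10L,
    stringsAsFactors = FALSE
  )
  feats <- data.frame(chrom = "chr1", start = c(10000L, 30000L),
                      end = c(15000L, 38000L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  mp <- metaplot(tab, feats, body_bins = 10, flank_bp = 2000, flank_bins = 4)
  pr <- mp$profile[mp$profile$context == "CG" & mp$profile$total_count > 0, ]
  se <- sqrt(p_cg * (1 - p_cg) / pr$total_count)
  expect_true(all(abs(pr$level - p_cg) < 4 * se))
})
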