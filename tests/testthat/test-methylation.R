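test_that("cytosine context classification follows CG/CHG/CHH rules", {
  expect_identical(cytosine_context(tiny_genome(chr1 = "ACGT"), "chr1", 1, "+"),
                   list(context = "CG", dinucleotide = "CG"))
  expect_identical(cytosine_context(tiny_genome(chr1 = "ACAGT"), "chr1", 1, "+"),
                   list(context = "CHG", dinucleotide = "CA"))
  expect_identical(cytosine_context(tiny_genome(chr1 = "ACAAT"), "chr1", 1, "+"),
                   list(context = "CHH", dinucleotide = "CA"))
  # Crick strand: Watson G at 2 is a Crick C whose next base is the
  # complement of Watson position 1
  expect_identical(cytosine_context(tiny_genome(chr1 = "ACGT"), "chr1", 2, "-"),
                   list(context = "CG", dinucleotide = "CG"))
  # N in the window
  expect_true(is.na(cytosine_context(tiny_genome(chr1 = "ACNGT"),
                                     "chr1", 1, "+")$context))
  expect_error(cytosine_context(tiny_genome(chr1 = "ACGT"), "chr1", 0, "+"),
               "not a cytosine")
})

test_that("every cytosine gets exactly one context and CG sites pair", {
  set.seed(19)
  g <- bs_genome(c(c1 = random_dna(500)))
  ch <- strsplit(g$seqs[[1]], "")[[1]]
  for (std in c("+", "-")) {
    pos <- which(ch == if (std == "+") "C" else "G") - 1L
    ctx <- bsalign3:::context_batch(g, rep(1L, length(pos)), pos,
                                    rep(std, length(pos)))$context
    # each site is classified once; NA only at chromosome edges here
    interior <- if (std == "+") pos < 498 else pos > 1
    expect_true(all(!is.na(ctx[interior])))
    expect_true(all(ctx[interior] %in% c("CG", "CHG", "CHH")))
  }
  plus_cg <- sum(bsalign3:::context_batch(
    g, rep(1L, sum(ch == "C")), which(ch == "C") - 1L,
    rep("+", sum(ch == "C")))$context == "CG", na.rm = TRUE)
  minus_cg <- sum(bsalign3:::context_batch(
    g, rep(1L, sum(ch == "G")), which(ch == "G") - 1L,
    rep("-", sum(ch == "G")))$context == "CG", na.rm = TRUE)
  expect_identical(plus_cg, minus_cg)  # CG dinucleotides are palindromic
})

test_that("methylation calls count retained and converted cytosines", {
  g <- tiny_genome(chr1 = "ACGT")
  aln1 <- manual_alignment("r1", "ACGT", "chr1", 0, "+", "MMMM")
  t1 <- call_methylation(aln1, g)
  expect_identical(nrow(t1), 1L)
  expect_identical(t1$pos, 1L)
  expect_identical(t1$context, "CG")
  expect_identical(t1$meth_count, 1L)
  expect_identical(t1$total_count, 1L)

  aln2 <- manual_alignment("r2", "ATGT", "chr1", 0, "+", "MMMM")
  t2 <- call_methylation(aln2, g)
  expect_identical(t2$meth_count, 0L)
  expect_identical(t2$total_count, 1L)

  t3 <- call_methylation(rbind(aln1, aln2), g)
  expect_identical(t3$meth_count, 1L)
  expect_identical(t3$total_count, 2L)
  expect_identical(t3$meth_count / t3$total_count, 0.5)
})

test_that("non-C/T read bases and indel columns are not called", {
  g <- tiny_genome(chr1 = "ACGTACGT")
  # read base G over the genome C: neither meth nor unmeth
  alnG <- manual_alignment("g", "AGGT", "chr1", 0, "+", "MXMM")
  expect_identical(nrow(call_methylation(alnG, g)), 0L)
  # genome C skipped by a deletion is not called
  alnD <- manual_alignment("d", "AGT", "chr1", 0, "+", "MDMM")
  expect_identical(nrow(call_methylation(alnD, g)), 0L)
})

test_that("'-' strand calls are made in the Crick frame", {
  g <- tiny_genome(chr1 = "ACGT")
  # Crick read across the CG: origin-frame seq revcomp(ACGT)=ACGT, its C
  # sits on the Watson G at pos 2
  aln <- manual_alignment("m", "ACGT", "chr1", 0, "-", "MMMM")
  tab <- call_methylation(aln, g)
  expect_identical(tab$pos, 2L)
  expect_identical(tab$strand, "-")
  expect_identical(tab$context, "CG")
  expect_identical(tab$meth_count, 1L)
})

test_that("CGmap rows follow the 8-column MethGo dialect", {
  g <- tiny_genome(chr1 = "ACGT")
  aln <- rbind(manual_alignment("r1", "ACGT", "chr1", 0, "+", "MMMM"),
               manual_alignment("r2", "ATGT", "chr1", 0, "+", "MMMM"),
               manual_alignment("r3", "ACGT", "chr1", 0, "-", "MMMM"))
  tab <- call_methylation(aln, g)
  path <- tempfile(fileext = ".CGmap")
  write_cgmap(tab, path)
  lines <- readLines(path)
  expect_identical(lines[1], "chr1\tC\t2\tCG\tCG\t0.50\t1\t2")
  expect_identical(lines[2], "chr1\tG\t3\tCG\tCG\t1.00\t1\t1")

  empty <- tempfile(fileext = ".CGmap")
  write_cgmap(call_methylation(aln[0, ], g), empty)
  expect_identical(length(readLines(empty)), 0L)

  back <- read_cgmap(path, g)
  expect_identical(back$pos, tab$pos)
  expect_identical(back$meth_count, tab$meth_count)
  expect_identical(back$strand, tab$strand)
})

test_that("pileup totals match a brute-force oracle on simulated reads", {
  set.seed(29)
  g <- random_genome(c(chr1 = 2000))
  me <- simulate_methylome(g, 0.7, 0.4, 0.1)
  sim <- simulate_reads(g, me, 80, 50, sub_rate = 0, indel_rate = 0,
                        conversion_rate = 0.95)
  idx <- build_genome_index(g)
  aln <- align_reads(sim$reads, idx, aligner_params(read_len = 50))
  aln <- aln[aln$status == "unique", ]
  tab <- call_methylation(aln, g)

  # oracle: walk each read base-by-base against the reference
  exp_total <- 0L
  ch <- strsplit(g$seqs[[1]], "")[[1]]
  for (i in seq_len(nrow(aln))) {
    rd <- strsplit(aln$effective_seq[i], "")[[1]]
    for (k in seq_along(rd)) {
      wpos <- if (aln$strand[i] == "+") aln$pos[i] + k - 1 else
        aln$pos[i] + length(rd) - k
      ref <- if (aln$strand[i] == "+") ch[wpos + 1] else
        chartr("ACGT", "TGCA", ch[wpos + 1])
      edge <- if (aln$strand[i] == "+") wpos >= length(ch) - 2 else wpos <= 1
      if (edge) next  # NA-context sites at chromosome edges are dropped
      if (ref == "C" && rd[k] %in% c("C", "T")) exp_total <- exp_total + 1L
    }
  }
  expect_identical(sum(tab$total_count), exp_total)
})

test_that("called levels recover the simulated methylation probabilities", {
  set.seed(37)
  g <- random_genome(c(chr1 = 30000))
  p <- c(CG = 0.8, CHG = 0.3, CHH = 0.05)
  me <- simulate_methylome(g, p["CG"], p["CHG"], p["CHH"])
  sim <- simulate_reads(g, me, 3000, 100, sub_rate = 0, indel_rate = 0,
                        conversion_rate = 1)
  idx <- build_genome_index(g)
  aln <- align_reads(sim$reads, idx)
  tab <- call_methylation(aln[aln$status == "unique", ], g)
  for (ctx in names(p)) {
    sub <- tab[tab$context == ctx, ]
    level <- sum(sub$meth_count) / sum(sub$total_count)
    se <- pooled_level_se(p[[ctx]], sub$total_count)
    expect_lt(abs(level - p[[ctx]]), 3 * se)
  }
})
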