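# plain full-count oracle for the bisulfite-aware recount
full_recount <- function(ref, rd, ops) {
  ch <- strsplit(ops, "")[[1]]
  ri <- ti <- 0L; mm <- conv <- 0L
  for (op in ch) {
    if (op == "M" || op == "X") {
      ri <- ri + 1L; ti <- ti + 1L
      rb <- substring(rd, ri, ri); tb <- substring(ref, ti, ti)
      if (tb == rb) next
      if (tb == "C" && rb == "T") conv <- conv + 1L else mm <- mm + 1L
    } else if (op == "I") { ri <- ri + 1L; mm <- mm + 1L
    } else { ti <- ti + 1L; mm <- mm + 1L }
  }
  list(mm = mm, conv = conv)
}

test_that("bisulfite recount is asymmetric: genome-C/read-T is free", {
  g <- tiny_genome(chr1 = "ACGT")
  r <- recount_mismatches("r1", "ATGT", "chr1", 0, "+", "MMMM", g, 4)
  expect_identical(r$bis_mismatches, 0L)
  expect_identical(r$conversions, 1L)
  expect_true(r$accepted)

  g2 <- tiny_genome(chr1 = "ATGT")
  r2 <- recount_mismatches("r1", "ACGT", "chr1", 0, "+", "MMMM", g2, 4)
  expect_identical(r2$bis_mismatches, 1L)
  expect_identical(r2$conversions, 0L)
})

test_that("the conversion check runs in the Crick frame for '-' reads", {
  # Watson GGGG -> Crick CCCC; a '-' read TTTT is all conversions
  g <- tiny_genome(chr1 = "GGGG")
  r <- recount_mismatches("r1", "TTTT", "chr1", 0, "-", "MMMM", g, 4)
  expect_identical(r$bis_mismatches, 0L)
  expect_identical(r$conversions, 4L)
  # and a '+' read TTTT over GGGG is 4 real mismatches
  r2 <- recount_mismatches("r2", "TTTT", "chr1", 0, "+", "MMMM", g, 8)
  expect_identical(r2$bis_mismatches, 4L)
})

test_that("recount stops early once the mismatch bound is exceeded", {
  g <- tiny_genome(chr1 = "AAAA")
  r <- recount_mismatches("r1", "GGGG", "chr1", 0, "+", "MMMM", g, 1)
  expect_false(r$accepted)
  expect_lte(r$positions_evaluated, 3L)
  expect_identical(r$bis_mismatches, 2L)
})

test_that("accepted recounts are independent of the visit order", {
  set.seed(13)
  g <- bs_genome(c(chr1 = random_dna(200)))
  ref <- substring(g$seqs[["chr1"]], 51, 100)
  for (salt in c("a", "b", "c", "longer-read-name-99")) {
    rd <- strsplit(ref, "")[[1]]
    rd[10] <- "A"; rd[40] <- "G"
    rd <- paste(rd, collapse = "")
    r <- recount_mismatches(salt, rd, "chr1", 50, "+", strrep("M", 50), g, 10)
    oracle <- full_recount(ref, rd, strrep("M", 50))
    expect_identical(r$bis_mismatches, oracle$mm)
    expect_identical(r$conversions, oracle$conv)
    expect_true(r$accepted)
  }
})

test_that("early-stop verdicts agree with the full-count oracle", {
  set.seed(17)
  for (i in 1:200) {
    L <- sample(10:40, 1)
    ref <- random_dna(L)
    rd <- strsplit(ref, "")[[1]]
    nerr <- sample(0:6, 1)
    if (nerr > 0) {
      at <- sample(L, nerr)
      rd[at] <- vapply(rd[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    rd <- paste(rd, collapse = "")
    g <- bs_genome(c(chr1 = ref))
    max_mm <- sample(0:4, 1)
    r <- recount_mismatches(paste0("case", i), rd, "chr1", 0, "+",
                            strrep("M", L), g, max_mm)
    oracle <- full_recount(ref, rd, strrep("M", L))
    expect_identical(r$accepted, oracle$mm <= max_mm)
    if (r$accepted) {
      expect_identical(r$bis_mismatches, oracle$mm)
      expect_identical(r$conversions, oracle$conv)
    }
  }
})

test_that("indels count toward the recount bound", {
  g <- tiny_genome(chr1 = "ACGTACGT")
  # read matches but skips one reference base (D) and adds one (I)
  r <- recount_mismatches("r1", "ACGACGTT", "chr1", 0, "+", "MMMDMMMMI", g, 4)
  expect_identical(r$bis_mismatches, 2L)
})

test_that("SAM records follow the conventions and round-trip", {
  set.seed(23)
  g <- bs_genome(c(chr1 = random_dna(100)))
  seqp <- substring(g$seqs[["chr1"]], 8, 27)
  aln <- rbind(
    manual_alignment("plus", seqp, "chr1", 7, "+", strrep("M", 20)),
    manual_alignment("minus", origin_sequence(g, "chr1", 30, "-", 20),
                     "chr1", 30, "-", strrep("M", 20)),
    manual_alignment("lost", strrep("N", 20), NA, NA, NA, NA,
                     status = "unmapped"),
    manual_alignment("ambi", seqp, NA, NA, NA, NA, status = "multiple")
  )
  aln <- recount_alignments_or_na(aln, g, 4)
  sam <- tempfile(fileext = ".sam")
  emit_sam(aln, g, sam)
  lines <- readLines(sam)
  expect_true(any(startsWith(lines, "@SQ\tSN:chr1\tLN:100")))
  rec <- strsplit(grep("^@", lines, value = TRUE, invert = TRUE), "\t")
  names(rec) <- vapply(rec, `[[`, character(1), 1)
  expect_identical(rec$plus[2], "0")
  expect_identical(rec$plus[4], "8")           # 1-based POS
  expect_identical(rec$minus[2], "16")
  expect_identical(rec$minus[10],              # SEQ flipped to reference-forward
                   substring(g$seqs[["chr1"]], 31, 50))
  expect_identical(rec$lost[2], "4")
  expect_identical(rec$lost[3], "*")
  expect_identical(rec$lost[4], "0")
  expect_true(any(grepl("XR:Z:ambiguous", lines)))
  expect_true(any(grepl("XO:Z:\\+W", lines)))
  expect_true(any(grepl("XO:Z:-C", lines)))

  back <- read_sam(sam)
  m <- match(aln$read_id, back$read_id)
  expect_identical(back$status[m], c("unique", "unique", "unmapped", "multiple"))
  expect_identical(back$pos[m][1:2], c(7L, 30L))
  expect_identical(back$strand[m][1:2], c("+", "-"))
  expect_identical(back$effective_seq[m][1:2], aln$effective_seq[1:2])
})
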