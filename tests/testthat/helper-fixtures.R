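# Shared fixtures: tiny genomes and a full-DP edit-distance oracle.

tiny_genome <- function(...) bs_genome(c(...))

# independent oracle: unrestricted Levenshtein distance via utils::adist
full_dp_distance <- function(a, b) {
  drop(utils::adist(a, b))
}

# brute-force origin-strand sequence for a simulated read locus
origin_sequence <- function(genome, chrom, pos, strand, len) {
  s <- substring(genome$seqs[[chrom]], pos + 1L, pos + len)
  if (strand == "-") reverse_complement(s) else s
}

# apply an expanded op string to a query, returning the implied target and
# the (subs, indels) counts -- used to check script consistency
apply_script <- function(ops, query, target) {
  ch <- strsplit(ops, "")[[1]]
  qi <- ti <- 0L
  subs <- indels <- 0L
  for (op in ch) {
    if (op == "M" || op == "X") {
      qi <- qi + 1L; ti <- ti + 1L
      if (op == "X") subs <- subs + 1L
      if ((substring(query, qi, qi) == substring(target, ti, ti)) != (op == "M"))
        stop("op ", op, " disagrees with sequences at query pos ", qi)
    } else if (op == "I") {
      qi <- qi + 1L; indels <- indels + 1L
    } else if (op == "D") {
      ti <- ti + 1L; indels <- indels + 1L
    } else stop("unknown op ", op)
  }
  stopifnot(qi == nchar(query), ti == nchar(target))
  list(subs = subs, indels = indels)
}

# Binomial SE of a coverage-weighted pooled methylation level. At full
# conversion every call at a site repeats the site's Bernoulli state, so the
# effective sample size is (sum c)^2 / sum(c^2), not the raw call count.
pooled_level_se <- function(p, totals) {
  sqrt(p * (1 - p) * sum(totals^2)) / sum(totals)
}

# recount unique rows, leaving non-unique rows with NA report columns
recount_alignments_or_na <- function(aln, genome, max_mm) {
  for (col in c("bis_mismatches", "conversions", "positions_evaluated"))
    aln[[col]] <- NA_integer_
  aln$accepted <- NA
  uq <- aln$status == "unique"
  if (any(uq)) {
    rec <- recount_alignments(aln[uq, , drop = FALSE], genome, max_mm)
    cols <- c("bis_mismatches", "conversions", "positions_evaluated", "accepted")
    aln[uq, cols] <- rec[, cols]
  }
  aln
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal hand-built alignments data.frame accepted by the downstream ops
manual_alignment <- function(read_id, seq, chrom, pos, strand, script,
                             status = "unique") {
  data.frame(read_id = read_id, status = status, chrom = chrom,
             pos = as.integer(pos), strand = strand,
             edit_distance = 0L, second_best = NA_integer_,
             script = script, span = nchar(gsub("[^MXD]", "", script)),
             effective_seq = seq, flipped = FALSE,
             stringsAsFactors = FALSE)
}
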