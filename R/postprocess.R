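#' Bisulfite-aware mismatch recount
#'
#' Re-counts mismatches in the original (unconverted) base space, in the
#' read's origin-strand frame: equal bases match; a genome C read as T is a
#' conversion event, not a mismatch; a read C over a genome T is a real
#' mismatch (the asymmetry of bisulfite chemistry); every other inequality
#' is a mismatch and indel columns count one mismatch per base. Positions
#' are visited in a pseudo-random order seeded from a stable hash of the
#' read id, stopping as soon as the count exceeds \code{max_mismatches}; the
#' final count for accepted reads is order-independent.
#'
#' @param alignments data.frame from [align_reads()] restricted to rows to
#'   recount (status \code{unique}).
#' @param genome the unconverted reference, a [bs_genome()].
#' @param max_mismatches upper bound; defaults to the aligner's edit bound.
#' @return \code{alignments} with added columns \code{bis_mismatches},
#'   \code{conversions}, \code{positions_evaluated}, \code{accepted}.
#' @export
recount_alignments <- function(alignments, genome, max_mismatches) {
  stopifnot(inherits(genome, "bs_genome"))
  if (nrow(alignments) == 0L) {
    alignments$bis_mismatches <- integer(0)
    alignments$conversions <- integer(0)
    alignments$positions_evaluated <- integer(0)
    alignments$accepted <- logical(0)
    return(alignments)
  }
  if (anyNA(alignments$script))
    stop("recount requires uniquely placed alignments with edit scripts")
  chrom_idx <- match(alignments$chrom, genome$names)
  rep <- recount_batch(alignments$effective_seq, alignments$read_id,
                       chrom_idx, alignments$pos, alignments$strand,
                       alignments$script, unname(genome$seqs),
                       as.integer(max_mismatches))
  cbind(alignments, rep)
}

#' @rdname recount_alignments
#' @param read_id,original_seq,chrom,pos,strand,script fields of one
#'   alignment: origin-strand read sequence, 0-based Watson-leftmost
#'   position and expanded op string over M/X/I/D.
#' @return \code{recount_mismatches}: one-row data.frame with
#'   \code{bis_mismatches}, \code{conversions}, \code{positions_evaluated},
#'   \code{accepted}.
#' @export
recount_mismatches <- function(read_id, original_seq, chrom, pos, strand,
                               script, genome, max_mismatches) {
  stopifnot(inherits(genome, "bs_genome"))
  recount_batch(original_seq, read_id, match(chrom, genome$names),
                as.integer(pos), strand, script, unname(genome$seqs),
                as.integer(max_mismatches))
}

#' Write alignments to SAM
#'
#' Unique accepted alignments get FLAG 0/16 by strand, 1-based POS, a CIGAR
#' with substitutions folded into M, \code{NM} (bisulfite-aware mismatches,
#' indels included) and custom tags \code{XO} (origin strand, \code{"+W"} /
#' \code{"-C"}), \code{XM} (bisulfite-aware mismatches) and \code{XC}
#' (conversion events). Everything else is emitted unmapped (FLAG 4) with a
#' reason in \code{XR} (\code{ambiguous}, \code{no_alignment},
#' \code{recount_fail}, \code{discarded}).
#'
#' @param alignments data.frame from [recount_alignments()] (all reads, any
#'   status; recount columns may be absent for non-unique rows).
#' @param genome the reference [bs_genome()] (for the header).
#' @param path output SAM path.
#' @return \code{path}, invisibly.
#' @export
emit_sam <- function(alignments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", genome$names, "\tLN:", unname(genome$lengths)),
           "@PG\tID:bsalign3\tPN:bsalign3")
  n <- nrow(alignments)
  if (is.null(alignments$accepted)) alignments$accepted <- rep(TRUE, n)
  alignments$accepted[is.na(alignments$accepted)] <- TRUE
  ok <- alignments$status == "unique" & alignments$accepted
  qual <- if (!is.null(alignments$qual)) alignments$qual else
    strrep("I", nchar(alignments$effective_seq))

  flag <- ifelse(ok, ifelse(alignments$strand == "-", 16L, 0L), 4L)
  rname <- ifelse(ok, alignments$chrom, "*")
  posn <- ifelse(ok, alignments$pos + 1L, 0L)
  mapq <- ifelse(ok, 42L, 0L)
  cigar <- ifelse(ok, script_to_cigar(alignments$script), "*")
  # SEQ in reference-forward orientation
  seq_out <- alignments$effective_seq
  qual_out <- qual
  neg <- ok & alignments$strand == "-"
  if (any(neg)) {
    seq_out[neg] <- reverse_complement(seq_out[neg])
    qual_out[neg] <- vapply(strsplit(qual_out[neg], ""), function(q)
      paste(rev(q), collapse = ""), character(1))
  }
  tags <- character(n)
  xo <- ifelse(alignments$strand == "-", "-C", "+W")
  mm <- if (!is.null(alignments$bis_mismatches)) alignments$bis_mismatches else
    rep(NA_integer_, n)
  cv <- if (!is.null(alignments$conversions)) alignments$conversions else
    rep(NA_integer_, n)
  tags[ok] <- paste0("NM:i:", mm[ok], "\tXO:Z:", xo[ok],
                     "\tXM:i:", mm[ok], "\tXC:i:", cv[ok])
  reason <- ifelse(alignments$status == "multiple", "ambiguous",
            ifelse(alignments$status == "discarded", "discarded",
            ifelse(alignments$status == "unique", "recount_fail",
                   "no_alignment")))
  tags[!ok] <- paste0("XR:Z:", reason[!ok])
  lines <- paste(alignments$read_id, flag, rname, posn, mapq, cigar,
                 "*", 0L, 0L, seq_out, qual_out, tags, sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file written by this pipeline
#'
#' Parses the text dialect produced by [emit_sam()], recovering locus,
#' strand-of-origin and the custom tags, with sequences restored to the
#' origin-strand frame.
#'
#' @param path SAM path.
#' @return data.frame with \code{read_id}, \code{flag}, \code{status},
#'   \code{chrom}, \code{pos} (0-based), \code{strand},
#'   \code{effective_seq}, \code{script}, \code{bis_mismatches},
#'   \code{conversions}, \code{reason}.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(read_id = character(), flag = integer(),
                      status = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      effective_seq = character(), script = character(),
                      bis_mismatches = integer(), conversions = integer(),
                      reason = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  tagstr <- vapply(f, function(x) paste(x[-seq_len(11L)], collapse = "\t"),
                   character(1))
  tagval <- function(tag) {
    m <- regmatches(tagstr, regexpr(paste0(tag, ":[ZiA]:[^\t]+"), tagstr))
    out <- rep(NA_character_, length(tagstr))
    out[grepl(paste0(tag, ":"), tagstr)] <- sub("^[A-Z]{2}:[ZiA]:", "", m)
    out
  }
  mapped <- !bitwAnd(flag, 4L)
  strand <- ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                   NA_character_)
  seq_fwd <- get(10)
  eff <- seq_fwd
  neg <- mapped & strand == "-"
  eff[neg] <- reverse_complement(seq_fwd[neg])
  reason <- tagval("XR")
  status <- ifelse(mapped, "unique",
            ifelse(reason == "ambiguous", "multiple",
            ifelse(reason == "discarded", "discarded", "unmapped")))
  cigar <- get(6)
  data.frame(
    read_id = get(1), flag = flag, status = status,
    chrom = ifelse(mapped, get(3), NA_character_),
    pos = ifelse(mapped, as.integer(get(4)) - 1L, NA_integer_),
    strand = strand, effective_seq = eff,
    script = ifelse(mapped, cigar_to_ops(cigar), NA_character_),
    bis_mismatches = suppressWarnings(as.integer(tagval("XM"))),
    conversions = suppressWarnings(as.integer(tagval("XC"))),
    reason = reason, stringsAsFactors = FALSE
  )
}

# CIGAR -> expanded op string (M/I/D; X already folded into M)
cigar_to_ops <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_character_)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    paste(rep(chartr("=X", "MM", ops), lens), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
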