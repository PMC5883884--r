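#' Build a three-letter genome index
#'
#' Concatenates the C-to-T converted Watson strand of every chromosome and
#' the C-to-T converted Crick strand (reverse complement), in chromosome
#' order (all Watson blocks first, then all Crick blocks), and indexes every
#' \code{seed_len}-mer of the concatenation that contains no N. A single
#' index serves both strands, so each read needs one in-silico conversion
#' and one lookup pass.
#'
#' @param genome a [bs_genome()].
#' @param seed_len seed length in bp (1..32; 8..32 is the sensible range,
#'   default 20 — long seeds keep false-positive hits rare).
#' @param max_seed_hits seeds occurring more often than this are kept in the
#'   index but skipped by the aligner (query-time repeat masking).
#' @return An object of class \code{three_letter_index}.
#' @export
build_genome_index <- function(genome, seed_len = 20L, max_seed_hits = 1000L) {
  stopifnot(inherits(genome, "bs_genome"))
  seed_len <- as.integer(seed_len)
  if (seed_len < 1L || seed_len > 32L) stop("seed_len must be in 1..32")
  if (length(genome$names) == 0L) stop("empty genome")

  short <- genome$lengths < seed_len
  if (any(short)) {
    warning("skipping chromosome(s) shorter than seed_len: ",
            paste(genome$names[short], collapse = ", "))
    genome <- bs_genome(genome$seqs[!short])
    if (length(genome$names) == 0L) stop("no chromosome is >= seed_len")
  }

  watson <- bisulfite_convert(genome$seqs, "C2T")
  crick <- bisulfite_convert(reverse_complement(genome$seqs), "C2T")
  lens <- unname(genome$lengths)
  total <- sum(lens)
  watson_offset <- cumsum(c(0L, lens))[seq_along(lens)]
  crick_offset <- total + watson_offset
  block_table <- data.frame(
    chrom = genome$names, length = lens,
    watson_offset = watson_offset, crick_offset = crick_offset,
    stringsAsFactors = FALSE
  )
  concat <- paste0(paste(watson, collapse = ""), paste(crick, collapse = ""))

  idx <- structure(
    list(
      seed_len = seed_len,
      max_seed_hits = as.integer(max_seed_hits),
      genome = genome,
      block_table = block_table,
      concat_len = 2L * total,
      checksum = genome_checksum(genome),
      .cache = new.env(parent = emptyenv())
    ),
    class = "three_letter_index"
  )
  idx$.cache$concat <- concat
  idx$.cache$ptr <- tl_index_build(concat, block_bounds(idx)$start,
                                   block_bounds(idx)$end, seed_len)
  idx
}

# blocks in concat order: watson blocks then crick blocks
block_bounds <- function(index) {
  bt <- index$block_table
  start <- c(bt$watson_offset, bt$crick_offset)
  list(start = as.integer(start), end = as.integer(start + c(bt$length, bt$length)))
}

genome_checksum <- function(genome) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste0(genome$names, ":", genome$seqs), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.three_letter_index <- function(x, ...) {
  cat("three_letter_index: seed_len", x$seed_len, "|",
      nrow(x$block_table), "chromosome(s) |", x$concat_len, "bp concatenated\n")
  invisible(x)
}

#' Converted concatenated sequence of an index
#'
#' @param index a \code{three_letter_index}.
#' @return single string: C2T-converted Watson+Crick concatenation.
#' @export
index_concat_seq <- function(index) {
  if (is.null(index$.cache$concat)) {
    watson <- bisulfite_convert(index$genome$seqs, "C2T")
    crick <- bisulfite_convert(reverse_complement(index$genome$seqs), "C2T")
    index$.cache$concat <- paste0(paste(watson, collapse = ""),
                                  paste(crick, collapse = ""))
  }
  index$.cache$concat
}

# external pointer to the C++ index, rebuilt after (de)serialization
index_ptr <- function(index) {
  p <- index$.cache$ptr
  if (is.null(p) || identical(p, methods::new("externalptr"))) {
    bb <- block_bounds(index)
    p <- tl_index_build(index_concat_seq(index), bb$start, bb$end,
                        index$seed_len)
    index$.cache$ptr <- p
  }
  p
}

#' Exact seed lookup
#'
#' @param index a \code{three_letter_index}.
#' @param seed string of length \code{index$seed_len}.
#' @return sorted integer vector of 0-based start positions in the
#'   concatenated converted sequence (empty when absent).
#' @export
lookup_seed <- function(index, seed) {
  if (nchar(seed) != index$seed_len)
    stop("seed must have length ", index$seed_len)
  sort(tl_lookup(index_ptr(index), toupper(seed)))
}

#' Map a concatenated-coordinate interval to a genomic locus
#'
#' Watson-block hits give strand \code{'+'} with \code{pos = concat_pos -
#' watson_offset}; Crick-block hits give strand \code{'-'} with \code{pos =
#' chrom_length - (concat_pos - crick_offset) - aln_len} (leftmost Watson
#' coordinate). Intervals straddling a block boundary are rejected.
#'
#' @param index a \code{three_letter_index}.
#' @param concat_pos 0-based start in the concatenation.
#' @param aln_len interval length (bp), >= 1.
#' @return list with \code{chrom}, \code{pos} (0-based Watson-leftmost) and
#'   \code{strand}.
#' @export
concat_to_genomic <- function(index, concat_pos, aln_len) {
  res <- concat_to_genomic_batch(index, concat_pos, aln_len)
  if (is.na(res$chrom[1L]))
    stop("no-locus: interval straddles a block boundary or is out of range")
  list(chrom = res$chrom[1L], pos = res$pos[1L], strand = res$strand[1L])
}

# vectorized version; invalid intervals yield NA rows
concat_to_genomic_batch <- function(index, concat_pos, aln_len) {
  bt <- index$block_table
  n_chrom <- nrow(bt)
  starts <- c(bt$watson_offset, bt$crick_offset)
  lens <- rep(bt$length, 2L)
  blk <- findInterval(concat_pos, starts)
  ok <- !is.na(concat_pos) & blk >= 1L & aln_len >= 1L
  ok[ok] <- concat_pos[ok] + aln_len[ok] <= starts[blk[ok]] + lens[blk[ok]]
  chrom <- rep(NA_character_, length(concat_pos))
  pos <- rep(NA_integer_, length(concat_pos))
  strand <- rep(NA_character_, length(concat_pos))
  if (any(ok)) {
    b <- blk[ok]
    watson <- b <= n_chrom
    ci <- ifelse(watson, b, b - n_chrom)
    off <- concat_pos[ok] - starts[b]
    chrom[ok] <- bt$chrom[ci]
    pos[ok] <- ifelse(watson, off, bt$length[ci] - off - aln_len[ok])
    strand[ok] <- ifelse(watson, "+", "-")
  }
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             chrom_idx = ifelse(ok, ifelse(blk <= n_chrom, blk, blk - n_chrom),
                                NA_integer_),
             stringsAsFactors = FALSE)
}

#' Save / load an index directory
#'
#' The on-disk form is plain text: a JSON manifest (seed length, checksum,
#' block table) plus the genome FASTA; the packed seed map is rebuilt on
#' load, bit-identically (the build is deterministic).
#'
#' @param index a \code{three_letter_index}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly (\code{save_index}); the index
#'   (\code{load_index}).
#' @export
save_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "bsalign3-index-v1",
    seed_len = index$seed_len,
    max_seed_hits = index$max_seed_hits,
    checksum = index$checksum,
    block_table = index$block_table
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_genome_fasta(index$genome, file.path(dir, "genome.fa"))
  invisible(dir)
}

#' @rdname save_index
#' @export
load_index <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "bsalign3-index-v1"))
    stop("not a bsalign3 index directory: ", dir)
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  idx <- build_genome_index(genome, seed_len = manifest$seed_len,
                            max_seed_hits = manifest$max_seed_hits)
  if (!identical(idx$checksum, manifest$checksum))
    stop("index genome checksum mismatch in ", dir)
  idx
}
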