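#' Genome container
#'
#' A minimal in-memory genome: named uppercase DNA strings over
#' \code{A,C,G,T,N}. Chromosome names must be unique.
#'
#' @param seqs named character vector of chromosome sequences.
#' @return An object of class \code{bs_genome} with elements \code{names},
#'   \code{seqs} (named character) and \code{lengths} (named integer).
#' @examples
#' g <- bs_genome(c(chr1 = "ACGTACGT"))
#' g$lengths
#' @export
bs_genome <- function(seqs) {
  if (length(seqs) == 0L) stop("empty genome")
  nm <- names(seqs)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("chromosome names must be present and unique")
  seqs <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("invalid-alphabet: chromosome '", nm[which(bad)[1L]],
         "' contains non-ACGTN characters")
  names(seqs) <- nm
  structure(
    list(names = nm, seqs = seqs, lengths = setNames(nchar(seqs), nm)),
    class = "bs_genome"
  )
}

#' @export
print.bs_genome <- function(x, ...) {
  cat("bs_genome:", length(x$names), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file (may be gzipped, multi-record, wrapped lines).
#' @return A [bs_genome()] object.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # FASTA headers: keep the first word as the chromosome name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bs_genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome a [bs_genome()].
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Generate a random genome
#'
#' Uniform A/C/G/T sequence, optionally with N stretches, as a fixture
#' factory so no external reference is needed. Uses the current RNG state;
#' call \code{set.seed()} first for reproducibility.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_stretches number of N runs to place per chromosome.
#' @param n_stretch_len length of each N run.
#' @return A [bs_genome()].
#' @export
random_genome <- function(chrom_lengths, n_stretches = 0L, n_stretch_len = 50L) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  seqs <- vapply(chrom_lengths, function(L) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (n_stretches > 0L && L > n_stretch_len) {
      for (i in seq_len(n_stretches)) {
        st <- sample.int(L - n_stretch_len, 1L)
        s[st:(st + n_stretch_len - 1L)] <- "N"
      }
    }
    paste(s, collapse = "")
  }, character(1))
  bs_genome(seqs)
}

#' Reverse complement
#'
#' @param seqs character vector of DNA sequences.
#' @return character vector of reverse complements (N preserved).
#' @export
reverse_complement <- function(seqs) {
  revcomp_cpp(as.character(seqs))
}

#' In-silico bisulfite conversion
#'
#' \code{C2T} replaces every C with T; \code{G2A} every G with A. All other
#' characters (including N) are preserved; length is preserved.
#'
#' @param seq character vector of DNA sequences over \code{A,C,G,T,N}.
#' @param mode \code{"C2T"} or \code{"G2A"}.
#' @return converted character vector.
#' @examples
#' bisulfite_convert("ACGT", "C2T")  # "ATGT"
#' bisulfite_convert("ACGT", "G2A")  # "ACAT"
#' @export
bisulfite_convert <- function(seq, mode = c("C2T", "G2A")) {
  mode <- match.arg(mode)
  seq <- toupper(as.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("invalid-alphabet: sequence contains non-ACGTN characters")
  if (mode == "C2T") chartr("C", "T", seq) else chartr("G", "A", seq)
}
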