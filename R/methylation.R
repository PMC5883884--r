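#' Cytosine sequence context
#'
#' Classifies a cytosine by its two downstream bases on its own strand:
#' next base G gives CG; next base H (A, C or T) then G gives CHG; two H
#' bases give CHH; any N (or running off the chromosome) gives NA. The
#' dinucleotide is the C plus its next origin-strand base. For strand
#' \code{'-'} the cytosine is a Watson G and downstream bases are the
#' complements of the preceding Watson bases.
#'
#' @param genome a [bs_genome()].
#' @param chrom chromosome name.
#' @param pos 0-based Watson coordinate.
#' @param strand \code{'+'} (Watson C) or \code{'-'} (Watson G).
#' @return list with \code{context} (\code{"CG"}, \code{"CHG"},
#'   \code{"CHH"} or \code{NA}) and \code{dinucleotide}.
#' @examples
#' g <- bs_genome(c(chr1 = "ACGT"))
#' cytosine_context(g, "chr1", 1, "+")  # CG
#' @export
cytosine_context <- function(genome, chrom, pos, strand) {
  ci <- match(chrom, genome$names)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  res <- context_batch(genome, rep(ci, length(pos)), pos, strand,
                       check = TRUE)
  if (length(pos) == 1L)
    list(context = res$context, dinucleotide = res$dinucleotide)
  else res
}

# vectorized context assignment; check=TRUE errors on non-cytosine positions
context_batch <- function(genome, chrom_idx, pos, strand, check = FALSE) {
  base_at <- function(ci, p) {
    out <- rep(NA_character_, length(p))
    ok <- !is.na(p) & p >= 0L & p < genome$lengths[ci]
    if (any(ok))
      out[ok] <- substring(genome$seqs[ci[ok]], p[ok] + 1L, p[ok] + 1L)
    out
  }
  plus <- strand == "+"
  b0 <- base_at(chrom_idx, pos)
  if (check) {
    want <- ifelse(plus, "C", "G")
    if (any(is.na(b0) | b0 != want))
      stop("position is not a cytosine on the requested strand")
  }
  step <- ifelse(plus, 1L, -1L)
  b1 <- base_at(chrom_idx, pos + step)
  b2 <- base_at(chrom_idx, pos + 2L * step)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b1[!plus] <- comp[b1[!plus]]
  b2[!plus] <- comp[b2[!plus]]
  isH <- function(b) !is.na(b) & b %in% c("A", "C", "T")
  ctx <- rep(NA_character_, length(pos))
  ctx[!is.na(b1) & b1 == "G"] <- "CG"
  chg <- isH(b1) & !is.na(b2) & b2 == "G"
  ctx[chg] <- "CHG"
  chh <- isH(b1) & isH(b2)
  ctx[chh] <- "CHH"
  dinuc <- ifelse(is.na(b1) | b1 == "N", NA_character_, paste0("C", b1))
  data.frame(context = ctx, dinucleotide = dinuc, stringsAsFactors = FALSE)
}

#' Call per-cytosine methylation
#'
#' Pileup over unique accepted alignments, on each read's origin strand:
#' at every aligned genome cytosine a retained read C counts as a
#' methylated call and a read T as an unmethylated call; other read bases
#' and indel-covered positions are ignored. Context is assigned from the
#' reference; sites with NA context (N within 2 bp downstream) are dropped.
#'
#' @param x alignments data.frame (from [recount_alignments()] or
#'   [align_reads()]) or the path of a SAM file written by [emit_sam()].
#' @param genome the reference [bs_genome()].
#' @param min_cov minimum total count for a site to be reported.
#' @return A \code{meth_table}: data.frame with \code{chrom}, \code{pos}
#'   (0-based Watson coordinate), \code{strand}, \code{context},
#'   \code{dinucleotide}, \code{meth_count}, \code{total_count}, sorted by
#'   chromosome then position.
#' @export
call_methylation <- function(x, genome, min_cov = 1L) {
  stopifnot(inherits(genome, "bs_genome"))
  if (is.character(x)) x <- read_sam(x)
  if (is.null(x$accepted)) x$accepted <- rep(TRUE, nrow(x))
  x$accepted[is.na(x$accepted)] <- TRUE
  use <- x$status == "unique" & x$accepted & !is.na(x$script)
  x <- x[use, , drop = FALSE]
  if (nrow(x) == 0L) return(empty_meth_table())
  chrom_idx <- match(x$chrom, genome$names)
  if (anyNA(chrom_idx))
    stop("alignment references unknown chromosome: ",
         x$chrom[which(is.na(chrom_idx))[1L]])
  p <- pileup_batch(x$effective_seq, chrom_idx, x$pos, x$strand, x$script,
                    unname(genome$seqs))
  ctx <- context_batch(genome, p$chrom_idx, p$pos, p$strand)
  tab <- data.frame(
    chrom = genome$names[p$chrom_idx], pos = p$pos, strand = p$strand,
    context = ctx$context, dinucleotide = ctx$dinucleotide,
    meth_count = p$meth_count, total_count = p$total_count,
    stringsAsFactors = FALSE
  )
  tab <- tab[!is.na(tab$context) & tab$total_count >= min_cov, , drop = FALSE]
  tab <- tab[order(match(tab$chrom, genome$names), tab$pos, tab$strand), ,
             drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("meth_table", "data.frame")
  tab
}

empty_meth_table <- function() {
  tab <- data.frame(chrom = character(), pos = integer(),
                    strand = character(), context = character(),
                    dinucleotide = character(), meth_count = integer(),
                    total_count = integer(), stringsAsFactors = FALSE)
  class(tab) <- c("meth_table", "data.frame")
  tab
}

#' Write a CGmap file
#'
#' Tab-delimited, header-less, one row per covered cytosine: chromosome;
#' Watson-strand nucleotide (\code{C} for \code{'+'} sites, \code{G} for
#' \code{'-'}); 1-based position; context; dinucleotide; methylation level;
#' methylated count; total count — the 8-column dialect consumed by
#' MethGo-class downstream tools.
#'
#' @param table a \code{meth_table} from [call_methylation()].
#' @param path output path (".gz" writes gzip).
#' @return \code{path}, invisibly.
#' @export
write_cgmap <- function(table, path) {
  lvl <- ifelse(table$total_count > 0,
                table$meth_count / table$total_count, 0)
  out <- data.frame(
    chrom = table$chrom,
    nuc = ifelse(table$strand == "+", "C", "G"),
    pos = table$pos + 1L,
    context = table$context,
    dinucleotide = table$dinucleotide,
    level = formatC(lvl, format = "f", digits = 2),
    meth_count = table$meth_count,
    total_count = table$total_count,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a CGmap file
#'
#' @param path CGmap path (gzip allowed).
#' @param genome optional [bs_genome()] used to restore chromosome sort
#'   order.
#' @return a \code{meth_table} (positions converted back to 0-based).
#' @export
read_cgmap <- function(path, genome = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = c(1, 2, 4, 5)))
  if (nrow(dt) == 0L) return(empty_meth_table())
  tab <- data.frame(
    chrom = dt[[1]], pos = as.integer(dt[[3]]) - 1L,
    strand = ifelse(dt[[2]] == "C", "+", "-"),
    context = dt[[4]], dinucleotide = dt[[5]],
    meth_count = as.integer(dt[[7]]), total_count = as.integer(dt[[8]]),
    stringsAsFactors = FALSE
  )
  if (!is.null(genome))
    tab <- tab[order(match(tab$chrom, genome$names), tab$pos, tab$strand), ,
               drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("meth_table", "data.frame")
  tab
}
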