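#' Simulate a methylome
#'
#' Draws an independent Bernoulli methylation state for every non-N
#' cytosine on both strands, with per-context probabilities.
#'
#' @param genome a [bs_genome()].
#' @param p_cg,p_chg,p_chh methylation probabilities per context in [0,1];
#'   cytosines with NA context use \code{p_chh}.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return object of class \code{bs_methylome}: per chromosome, integer
#'   vectors \code{watson} and \code{crick} indexed by Watson coordinate
#'   (-1 = no cytosine on that strand, 0 = unmethylated, 1 = methylated).
#' @export
simulate_methylome <- function(genome, p_cg, p_chg, p_chh, seed = NULL) {
  stopifnot(all(c(p_cg, p_chg, p_chh) >= 0), all(c(p_cg, p_chg, p_chh) <= 1))
  if (!is.null(seed)) set.seed(seed)
  states <- lapply(seq_along(genome$names), function(ci) {
    L <- genome$lengths[ci]
    ch <- strsplit(genome$seqs[ci], "")[[1]]
    out <- list()
    for (std in c("+", "-")) {
      pos <- which(ch == if (std == "+") "C" else "G") - 1L
      st <- rep(-1L, L)
      if (length(pos) > 0L) {
        ctx <- context_batch(genome, rep(ci, length(pos)), pos,
                             rep(std, length(pos)))$context
        p <- ifelse(is.na(ctx), p_chh,
                    ifelse(ctx == "CG", p_cg, ifelse(ctx == "CHG", p_chg, p_chh)))
        st[pos + 1L] <- rbinom(length(pos), 1L, p)
      }
      out[[if (std == "+") "watson" else "crick"]] <- st
    }
    out
  })
  names(states) <- genome$names
  structure(list(states = states, genome_names = genome$names),
            class = "bs_methylome")
}

#' @export
print.bs_methylome <- function(x, ...) {
  n <- sum(vapply(x$states, function(s)
    sum(s$watson >= 0L) + sum(s$crick >= 0L), numeric(1)))
  cat("bs_methylome:", length(x$states), "chromosome(s),", n, "cytosines\n")
  invisible(x)
}

#' Simulate bisulfite reads with ground truth
#'
#' For each read: the origin is uniform over non-N loci and both strands;
#' the origin-strand sequence is extracted; each unmethylated C becomes T
#' with probability \code{conversion_rate} (methylated Cs are retained);
#' then per base a substitution with \code{sub_rate} (uniform other base)
#' and with \code{indel_rate} a single-base insertion (random base) or
#' deletion (equal odds). Qualities are constant \code{'I'}. The truth
#' ledger records the leftmost Watson coordinate of the pre-error locus.
#' Fully reproducible from \code{seed}.
#'
#' @param genome a [bs_genome()].
#' @param methylome from [simulate_methylome()].
#' @param n_reads number of reads, > 0.
#' @param read_len read length (<= min chromosome length).
#' @param sub_rate per-base substitution rate.
#' @param indel_rate per-base single-base insertion/deletion rate.
#' @param conversion_rate bisulfite conversion rate for unmethylated Cs.
#' @param directional if \code{FALSE}, half the reads are emitted as PCR
#'   complements (reverse complement of the bisulfite strand).
#' @param seed optional integer seed.
#' @param fastq,truth_path optional output paths (FASTQ; TSV truth ledger
#'   with columns read_id, chrom, pos, strand, n_subs, n_indels).
#' @return list with \code{reads} (data.frame \code{read_id}, \code{seq},
#'   \code{qual}) and \code{truth} (data.frame \code{read_id},
#'   \code{chrom}, \code{pos}, \code{strand}, \code{n_subs},
#'   \code{n_indels}).
#' @export
simulate_reads <- function(genome, methylome, n_reads, read_len = 100L,
                           sub_rate = 0.01, indel_rate = 0,
                           conversion_rate = 0.99, directional = TRUE,
                           seed = NULL, fastq = NULL, truth_path = NULL) {
  if (n_reads <= 0L) stop("n_reads must be > 0")
  stopifnot(all(c(sub_rate, indel_rate, conversion_rate) >= 0),
            all(c(sub_rate, indel_rate, conversion_rate) <= 1))
  if (!is.null(seed)) set.seed(seed)
  ws <- lapply(methylome$states, `[[`, "watson")
  cs <- lapply(methylome$states, `[[`, "crick")
  sim <- simulate_reads_cpp(unname(genome$seqs), unname(ws), unname(cs),
                            as.integer(n_reads), as.integer(read_len),
                            sub_rate, indel_rate, conversion_rate,
                            directional)
  reads <- data.frame(read_id = sim$read_id, seq = sim$seq,
                      qual = strrep("I", nchar(sim$seq)),
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = sim$read_id,
                      chrom = genome$names[sim$chrom_idx],
                      pos = sim$pos, strand = sim$strand,
                      n_subs = sim$n_subs, n_indels = sim$n_indels,
                      stringsAsFactors = FALSE)
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth_path))
    data.table::fwrite(truth, truth_path, sep = "\t")
  list(reads = reads, truth = truth)
}

#' Read a truth ledger written by [simulate_reads()]
#'
#' @param path TSV truth file.
#' @return truth data.frame.
#' @export
read_truth <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  colClasses = list(character = c("read_id", "chrom", "strand"))))
}

#' Score mapping accuracy against simulation truth
#'
#' A read counts as correct iff it is uniquely mapped on the same
#' chromosome and strand within \code{tolerance_bp} of its true leftmost
#' Watson coordinate (the tolerance absorbs indel-induced shifts).
#' Mapability counts reads placed at all (unique or ambiguous).
#'
#' @param x alignments data.frame or SAM path.
#' @param truth truth data.frame or TSV path from [simulate_reads()].
#' @param tolerance_bp positional tolerance in bp.
#' @return list with \code{n_reads}, \code{n_mapped}, \code{n_correct},
#'   \code{mapability}, \code{pct_correct} (both as fractions in [0,1]).
#' @export
evaluate_mapping <- function(x, truth, tolerance_bp = 5L) {
  if (is.character(x)) x <- read_sam(x)
  if (is.character(truth)) truth <- read_truth(truth)
  if (!all(x$read_id %in% truth$read_id))
    stop("contaminated evaluation: SAM contains read ids absent from truth")
  m <- match(truth$read_id, x$read_id)
  status <- ifelse(is.na(m), "unmapped", x$status[m])
  mapped <- status %in% c("unique", "multiple")
  correct <- status == "unique" &
    !is.na(x$chrom[m]) & x$chrom[m] == truth$chrom &
    x$strand[m] == truth$strand &
    abs(x$pos[m] - truth$pos) <= tolerance_bp
  correct[is.na(correct)] <- FALSE
  n <- nrow(truth)
  list(n_reads = n, n_mapped = sum(mapped), n_correct = sum(correct),
       mapability = sum(mapped) / n, pct_correct = sum(correct) / n)
}
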