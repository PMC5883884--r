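#' Aligner parameters
#'
#' @param read_len typical read length, used for the edit-distance default.
#' @param max_edit_distance maximum edit distance in three-letter space;
#'   default \code{max(6, ceiling(0.07 * read_len))}, sized so that reads
#'   carrying the error load of a high-indel library (2.5 indels + ~1
#'   substitution per 100 bp) are still accepted.
#' @param uniqueness_gap a best hit is unique only if the runner-up is at
#'   least this many edits worse.
#' @param stride seed spacing; default = seed length (non-overlapping seeds
#'   plus one flush-right seed).
#' @param max_seed_hits seeds with more hits than this are skipped (repeat
#'   masking at query time).
#' @param max_candidates candidates evaluated per read, in vote order.
#' @return list of aligner parameters.
#' @export
aligner_params <- function(read_len = 100L, max_edit_distance = NULL,
                           uniqueness_gap = 2L, stride = NULL,
                           max_seed_hits = 1000L, max_candidates = 50L) {
  if (is.null(max_edit_distance))
    max_edit_distance <- max(6L, as.integer(ceiling(0.07 * read_len)))
  list(max_edit_distance = as.integer(max_edit_distance),
       uniqueness_gap = as.integer(uniqueness_gap),
       stride = if (is.null(stride)) NULL else as.integer(stride),
       max_seed_hits = as.integer(max_seed_hits),
       max_candidates = as.integer(max_candidates))
}

#' Extract seeds from a converted read
#'
#' Seeds at offsets 0, stride, 2*stride, ... plus one flush-right seed
#' ending at the last base; seeds containing N are skipped.
#'
#' @param converted_seq C2T-converted read sequence.
#' @param seed_len seed length.
#' @param stride offset step (default \code{seed_len}).
#' @return data.frame with \code{offset} (0-based) and \code{seed}; empty
#'   when the read is shorter than \code{seed_len}.
#' @export
extract_seeds <- function(converted_seq, seed_len, stride = seed_len) {
  m <- nchar(converted_seq)
  if (m < seed_len)
    return(data.frame(offset = integer(), seed = character(),
                      stringsAsFactors = FALSE))
  offs <- seq(0L, m - seed_len, by = stride)
  if (offs[length(offs)] != m - seed_len) offs <- c(offs, m - seed_len)
  seeds <- substring(converted_seq, offs + 1L, offs + seed_len)
  keep <- !grepl("N", seeds, fixed = TRUE)
  data.frame(offset = as.integer(offs[keep]), seed = seeds[keep],
             stringsAsFactors = FALSE)
}

#' Collect candidate loci from seed hits
#'
#' Each hit at concatenated position p with read offset o votes for diagonal
#' p - o; diagonals within \code{max_d} of each other are merged into one
#' candidate (the diagonal with the most votes represents the cluster).
#' Seeds whose hit list exceeds \code{max_seed_hits} contribute nothing.
#'
#' @param index a \code{three_letter_index}.
#' @param seeds data.frame from [extract_seeds()].
#' @param max_seed_hits repeat-seed cutoff.
#' @param max_d diagonal merge tolerance (the aligner's edit bound).
#' @return data.frame with \code{concat_pos} and \code{votes}, sorted by
#'   votes descending then position ascending.
#' @export
collect_candidates <- function(index, seeds, max_seed_hits = 1000L, max_d = 4L) {
  diags <- integer(0)
  for (i in seq_len(nrow(seeds))) {
    hits <- lookup_seed(index, seeds$seed[i])
    if (length(hits) == 0L || length(hits) > max_seed_hits) next
    diags <- c(diags, hits - seeds$offset[i])
  }
  if (length(diags) == 0L)
    return(data.frame(concat_pos = integer(), votes = integer()))
  diags <- sort(diags)
  grp <- cumsum(c(1L, diff(diags) > max_d))
  cand <- do.call(rbind, lapply(split(diags, grp), function(d) {
    tab <- table(d)
    votes <- max(tab)
    best <- as.integer(names(tab)[tab == votes][1L])
    data.frame(concat_pos = best, votes = as.integer(votes))
  }))
  cand <- cand[order(-cand$votes, cand$concat_pos), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Banded edit distance (Ukkonen cutoff)
#'
#' Unit-cost Levenshtein distance restricted to the diagonal band
#' \code{|i - j| <= max_d}; returns \code{Inf} when the distance exceeds
#' \code{max_d}, and otherwise agrees with the full O(nm) dynamic program.
#'
#' @param query,target DNA strings.
#' @param max_d band half-width / distance cutoff, >= 0.
#' @return list with \code{distance} (number or \code{Inf}) and
#'   \code{script}: a data.frame of run-length (op, length) pairs over
#'   M (match), X (substitution), I (insertion in query), D (deletion from
#'   query), or \code{NULL} when \code{distance} is \code{Inf}.
#' @export
banded_edit_distance <- function(query, target, max_d) {
  res <- banded_levenshtein_cpp(query, target, as.integer(max_d))
  if (is.infinite(res$distance))
    return(list(distance = Inf, script = NULL))
  list(distance = res$distance, script = ops_to_script(res$ops))
}

# expanded op string -> run-length data.frame
ops_to_script <- function(ops) {
  if (is.na(ops) || nchar(ops) == 0L)
    return(data.frame(op = character(), length = integer(),
                      stringsAsFactors = FALSE))
  ch <- strsplit(ops, "")[[1]]
  r <- rle(ch)
  data.frame(op = r$values, length = r$lengths, stringsAsFactors = FALSE)
}

script_to_cigar <- function(ops) {
  # X folds into M for SAM
  vapply(ops, function(o) {
    if (is.na(o)) return(NA_character_)
    ch <- chartr("X", "M", o)
    r <- rle(strsplit(ch, "")[[1]])
    paste0(r$lengths, r$values, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Align converted reads against a three-letter index
#'
#' Seed-and-extend: seeds are looked up in the single Watson+Crick index,
#' hits vote for diagonals, and candidates are extended with a banded
#' semi-global edit-distance kernel (read end-to-end, free target offset
#' within the candidate window). Candidates are evaluated in vote order with
#' an early stop on a perfect hit; the best and runner-up distances decide
#' unique / multiple / unmapped status. In non-directional mode the read's
#' reverse complement is also queried in C2T space and the better route
#' wins; such reads are flipped into their origin-strand frame in the
#' returned \code{effective_seq}.
#'
#' @param reads data.frame with \code{read_id}, \code{seq} and optionally
#'   \code{qual} and \code{discarded}.
#' @param index a \code{three_letter_index}.
#' @param params from [aligner_params()].
#' @param directional if \code{FALSE}, also try the complementary route.
#' @return data.frame with one row per read: \code{read_id}, \code{status}
#'   (\code{unique}/\code{multiple}/\code{unmapped}/\code{discarded}),
#'   \code{chrom}, \code{pos} (0-based Watson-leftmost), \code{strand},
#'   \code{edit_distance}, \code{second_best}, \code{script} (expanded op
#'   string), \code{span}, \code{effective_seq}, \code{flipped}.
#' @export
align_reads <- function(reads, index, params = aligner_params(),
                        directional = TRUE) {
  n <- nrow(reads)
  stride <- if (is.null(params$stride)) index$seed_len else params$stride
  discarded <- if (!is.null(reads$discarded)) reads$discarded else rep(FALSE, n)

  run_batch <- function(seqs) {
    conv <- bisulfite_convert(seqs, "C2T")
    tl_align_batch(index_ptr(index), conv, stride,
                   params$max_edit_distance, params$uniqueness_gap,
                   params$max_seed_hits, params$max_candidates)
  }
  res <- run_batch(reads$seq)
  flipped <- rep(FALSE, n)
  eff_seq <- reads$seq
  if (!directional) {
    rc <- reverse_complement(reads$seq)
    res2 <- run_batch(rc)
    d1 <- ifelse(is.na(res$distance), Inf, res$distance)
    d2 <- ifelse(is.na(res2$distance), Inf, res2$distance)
    use2 <- (res$status == 2L & res2$status != 2L) |
      (res$status != 2L & res2$status != 2L & d2 < d1)
    for (f in c("status", "concat_start", "span", "distance",
                "second_best", "script"))
      res[[f]][use2] <- res2[[f]][use2]
    flipped[use2] <- TRUE
    eff_seq[use2] <- rc[use2]
  }

  loc <- concat_to_genomic_batch(index, res$concat_start, res$span)
  status <- c("unique", "multiple", "unmapped")[res$status + 1L]
  # a placement whose window straddled a block boundary has no locus
  bad <- status != "unmapped" & is.na(loc$chrom)
  status[bad] <- "unmapped"
  status[discarded] <- "discarded"
  mapped <- status %in% c("unique", "multiple")
  out <- data.frame(
    read_id = reads$read_id,
    status = status,
    chrom = ifelse(mapped, loc$chrom, NA_character_),
    chrom_idx = ifelse(mapped, loc$chrom_idx, NA_integer_),
    pos = ifelse(mapped, loc$pos, NA_integer_),
    strand = ifelse(mapped, loc$strand, NA_character_),
    edit_distance = ifelse(mapped, res$distance, NA_integer_),
    second_best = res$second_best,
    script = ifelse(mapped, res$script, NA_character_),
    span = ifelse(mapped, res$span, NA_integer_),
    effective_seq = eff_seq,
    flipped = flipped,
    stringsAsFactors = FALSE
  )
  if (!is.null(reads$qual)) out$qual <- reads$qual
  out
}

#' Align a single read
#'
#' Convenience wrapper over [align_reads()].
#'
#' @param read_id read identifier.
#' @param seq read sequence (original, unconverted).
#' @inheritParams align_reads
#' @return one-row data.frame as in [align_reads()].
#' @export
align_read <- function(read_id, seq, index, params = aligner_params(),
                       directional = TRUE) {
  align_reads(data.frame(read_id = read_id, seq = seq,
                         stringsAsFactors = FALSE),
              index, params, directional)
}
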