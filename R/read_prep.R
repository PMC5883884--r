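#' Read a FASTQ file
#'
#' Strict 4-line-record parser (gzip supported). Malformed records are
#' reported with their record index.
#'
#' @param path FASTQ file.
#' @return data.frame with \code{read_id}, \code{seq}, \code{qual}.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count ", length(lines), " not a multiple of 4")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(read_id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad) > 0L)
    stop("malformed FASTQ record at index ", bad[1L])
  data.frame(
    read_id = sub("\\s.*$", "", substring(hdr, 2L)),
    seq = toupper(seq), qual = qual, stringsAsFactors = FALSE
  )
}

#' Write a FASTQ file
#'
#' @param reads data.frame with \code{read_id}, \code{seq}, \code{qual}.
#' @param path output path (".gz" suffix writes gzip).
#' @export
write_fastq <- function(reads, path) {
  rec <- paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", reads$qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Trim a 3' adapter from reads
#'
#' Removes the longest read suffix that matches a prefix of the adapter with
#' at least \code{min_overlap} bases and at most 10\% mismatches (no
#' indels); a semi-global suffix/prefix scan. Reads shorter than
#' \code{min_read_len} after trimming are flagged \code{discarded}.
#'
#' @param reads data.frame with \code{read_id}, \code{seq} and optionally
#'   \code{qual} (trimmed in lockstep).
#' @param adapter adapter sequence (default: Illumina TruSeq read-1 prefix).
#' @param min_overlap minimum suffix/prefix overlap, >= 1.
#' @param min_read_len reads shorter than this after trimming are discarded.
#' @return \code{reads} with trimmed \code{seq}/\code{qual} and a logical
#'   \code{discarded} column.
#' @export
trim_adapter <- function(reads, adapter = "AGATCGGAAGAGC", min_overlap = 3L,
                         min_read_len = 20L) {
  stopifnot(min_overlap >= 1L)
  if (nrow(reads) == 0L) {
    reads$discarded <- logical(0)
    return(reads)
  }
  keep <- trim_adapter_batch(reads$seq, toupper(adapter),
                             as.integer(min_overlap), 0.10)
  reads$seq <- substring(reads$seq, 1L, keep)
  if (!is.null(reads$qual)) reads$qual <- substring(reads$qual, 1L, keep)
  reads$discarded <- keep < min_read_len
  reads
}

#' In-silico read conversion
#'
#' Delegates to [bisulfite_convert()]. Directional libraries use C2T for all
#' reads; in non-directional mode the complementary-strand route additionally
#' queries the read's reverse complement in C2T space (equivalent to G2A on
#' the read itself) and the better alignment wins.
#'
#' @inheritParams bisulfite_convert
#' @param orientation \code{"C2T"} or \code{"G2A"}.
#' @export
convert_read <- function(seq, orientation = c("C2T", "G2A")) {
  bisulfite_convert(seq, match.arg(orientation))
}

#' Split a FASTQ file into chunks
#'
#' Records are partitioned contiguously and in order, so the concatenation
#' of the chunk files reproduces the input record stream exactly. Per-read
#' downstream results are chunk-invariant (per-read deterministic RNG).
#'
#' @param path input FASTQ (gzip allowed).
#' @param n_chunks number of chunks, >= 1.
#' @param out_dir directory for chunk files.
#' @return character vector of chunk file paths.
#' @export
chunk_fastq <- function(path, n_chunks, out_dir = tempfile("chunks")) {
  stopifnot(n_chunks >= 1L)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4")
  n <- length(lines) %/% 4L
  # validate before splitting so errors carry a record index
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0L) stop("malformed FASTQ record at index ", bad[1L])
  n_chunks <- min(as.integer(n_chunks), max(n, 1L))
  sizes <- rep(n %/% n_chunks, n_chunks)
  rem <- n %% n_chunks
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  paths <- file.path(out_dir, sprintf("chunk_%03d.fq", seq_len(n_chunks)))
  for (i in seq_len(n_chunks)) {
    if (sizes[i] == 0L) {
      writeLines(character(0), paths[i])
    } else {
      li <- ((starts[i] - 1L) * 4L + 1L):(ends[i] * 4L)
      writeLines(lines[li], paths[i])
    }
  }
  paths
}
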