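#' Pipeline configuration
#'
#' Collects all module parameters with defaults. Serializes losslessly to
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param fasta reference FASTA path (or leave NULL and pass a genome to
#'   [run_pipeline()]).
#' @param fastq reads FASTQ path.
#' @param out_dir output directory.
#' @param seed_len,max_seed_hits index parameters ([build_genome_index()]).
#' @param stride,max_edit_distance,uniqueness_gap,max_candidates aligner
#'   parameters ([aligner_params()]).
#' @param adapter,min_overlap,min_read_len trimming parameters
#'   ([trim_adapter()]); set \code{adapter = NA} to skip trimming.
#' @param max_mismatches recount bound; \code{NULL} uses the aligner's edit
#'   bound.
#' @param chunks number of read chunks processed independently.
#' @param directional library protocol.
#' @param spike_chrom optional unmethylated spike-in chromosome name for
#'   conversion-efficiency estimation.
#' @param window_bp genome-wide methylation window size.
#' @param min_cov minimum coverage for CGmap sites.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(fasta = NULL, fastq = NULL, out_dir = "bsalign3_out",
                            seed_len = 20L, max_seed_hits = 1000L,
                            stride = NULL, max_edit_distance = NULL,
                            uniqueness_gap = 2L, max_candidates = 50L,
                            adapter = "AGATCGGAAGAGC", min_overlap = 3L,
                            min_read_len = 20L, max_mismatches = NULL,
                            chunks = 1L, directional = TRUE,
                            spike_chrom = NULL, window_bp = 10000L,
                            min_cov = 1L) {
  cfg <- list(fasta = fasta, fastq = fastq, out_dir = out_dir,
              seed_len = as.integer(seed_len),
              max_seed_hits = as.integer(max_seed_hits),
              stride = if (is.null(stride)) NULL else as.integer(stride),
              max_edit_distance = if (is.null(max_edit_distance)) NULL else
                as.integer(max_edit_distance),
              uniqueness_gap = as.integer(uniqueness_gap),
              max_candidates = as.integer(max_candidates),
              adapter = adapter, min_overlap = as.integer(min_overlap),
              min_read_len = as.integer(min_read_len),
              max_mismatches = if (is.null(max_mismatches)) NULL else
                as.integer(max_mismatches),
              chunks = as.integer(chunks), directional = directional,
              spike_chrom = spike_chrom, window_bp = as.integer(window_bp),
              min_cov = as.integer(min_cov))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full pipeline
#'
#' index -> trim -> convert -> align -> bisulfite-aware recount -> SAM ->
#' methylation calling -> CGmap -> QC tables. Reads are processed in
#' \code{config$chunks} independent chunks; per-read determinism (aligner
#' and recount RNG seeded per read id) makes the outputs identical for any
#' chunk count.
#'
#' @param config from [pipeline_config()].
#' @param genome optional pre-loaded [bs_genome()] (overrides
#'   \code{config$fasta}).
#' @param reads optional pre-loaded reads data.frame (overrides
#'   \code{config$fastq}).
#' @param index optional pre-built \code{three_letter_index}.
#' @return list with \code{sam}, \code{cgmap}, \code{report} (paths and the
#'   run-report list), plus the in-memory \code{alignments} and
#'   \code{meth_table}.
#' @export
run_pipeline <- function(config = pipeline_config(), genome = NULL,
                         reads = NULL, index = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(genome))
    genome <- stage("genome", read_genome_fasta(config$fasta))
  if (is.null(index))
    index <- stage("index",
                   build_genome_index(genome, seed_len = config$seed_len,
                                      max_seed_hits = config$max_seed_hits))
  if (is.null(reads))
    reads <- stage("reads", read_fastq(config$fastq))
  n_in <- nrow(reads)

  params <- aligner_params(
    read_len = if (n_in > 0L) max(nchar(reads$seq)) else 100L,
    max_edit_distance = config$max_edit_distance,
    uniqueness_gap = config$uniqueness_gap, stride = config$stride,
    max_seed_hits = config$max_seed_hits,
    max_candidates = config$max_candidates)
  max_mm <- if (is.null(config$max_mismatches)) params$max_edit_distance else
    config$max_mismatches

  # contiguous chunking; per-read determinism makes this order-invariant
  n_chunks <- max(1L, min(config$chunks, max(n_in, 1L)))
  sizes <- rep(n_in %/% n_chunks, n_chunks)
  rem <- n_in %% n_chunks
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)

  process_chunk <- function(i) {
    if (sizes[i] == 0L) return(NULL)
    chunk <- reads[starts[i]:ends[i], , drop = FALSE]
    if (!is.null(config$adapter) && !is.na(config$adapter))
      chunk <- stage("trim",
                     trim_adapter(chunk, config$adapter, config$min_overlap,
                                  config$min_read_len))
    aln <- stage("align",
                 align_reads(chunk, index, params,
                             directional = config$directional))
    for (col in c("bis_mismatches", "conversions", "positions_evaluated"))
      aln[[col]] <- NA_integer_
    aln$accepted <- NA
    uq <- aln$status == "unique"
    if (any(uq)) {
      rec <- stage("recount",
                   recount_alignments(aln[uq, , drop = FALSE], genome, max_mm))
      cols <- c("bis_mismatches", "conversions", "positions_evaluated",
                "accepted")
      aln[uq, cols] <- rec[, cols]
    }
    aln
  }
  alignments <- do.call(rbind, Filter(Negate(is.null),
                                      lapply(seq_len(n_chunks), process_chunk)))
  if (is.null(alignments)) stop("pipeline stage 'align' failed: no reads")

  sam_path <- file.path(config$out_dir, "alignments.sam")
  stage("sam", emit_sam(alignments, genome, sam_path))

  meth <- stage("call", call_methylation(alignments, genome,
                                         min_cov = config$min_cov))
  cgmap_path <- file.path(config$out_dir, "sample.CGmap")
  stage("cgmap", write_cgmap(meth, cgmap_path))

  qc_profile <- stage("qc", mismatch_by_position(alignments, genome))
  data.table::fwrite(qc_profile,
                     file.path(config$out_dir, "mismatch_profile.tsv"),
                     sep = "\t")
  windows <- stage("windows", genome_windows(meth, config$window_bp))
  data.table::fwrite(windows,
                     file.path(config$out_dir, "methylation_windows.tsv"),
                     sep = "\t")

  conv <- NULL
  if (!is.null(config$spike_chrom))
    conv <- stage("conversion",
                  conversion_efficiency(meth, config$spike_chrom))

  n_disc <- sum(alignments$status == "discarded")
  n_uni <- sum(alignments$status == "unique" &
                 (is.na(alignments$accepted) | alignments$accepted))
  n_fail <- sum(alignments$status == "unique" &
                  !is.na(alignments$accepted) & !alignments$accepted)
  n_multi <- sum(alignments$status == "multiple")
  n_unmap <- sum(alignments$status == "unmapped") + n_fail
  report <- list(
    reads_in = n_in, discarded = n_disc, mapped_unique = n_uni,
    mapped_multiple = n_multi, unmapped = n_unmap,
    recount_rejected = n_fail,
    conversion_efficiency = if (is.null(conv)) NULL else conv$efficiency,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  stopifnot(n_disc + n_uni + n_multi + n_unmap == n_in)  # read conservation
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(sam = sam_path, cgmap = cgmap_path,
       report = report, alignments = alignments, meth_table = meth)
}
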