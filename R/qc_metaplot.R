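#' Per-cycle mismatch profile
#'
#' Average rate of bisulfite-aware mismatch per read position (sequencing
#' cycle) over unique alignments; conversion events are not mismatches.
#' Reads from the Crick strand are indexed in their original machine-cycle
#' order.
#'
#' @param x alignments data.frame or SAM path (see [call_methylation()]).
#' @param genome the reference [bs_genome()].
#' @param max_len longest read length to profile.
#' @return data.frame with \code{cycle} (1-based), \code{mismatch_rate}
#'   (NA where no read covers the cycle) and \code{n_observations}.
#' @export
mismatch_by_position <- function(x, genome, max_len = 200L) {
  stopifnot(inherits(genome, "bs_genome"))
  if (is.character(x)) x <- read_sam(x)
  if (is.null(x$accepted)) x$accepted <- rep(TRUE, nrow(x))
  x$accepted[is.na(x$accepted)] <- TRUE
  x <- x[x$status == "unique" & x$accepted & !is.na(x$script), , drop = FALSE]
  if (nrow(x) == 0L)
    return(data.frame(cycle = integer(), mismatch_rate = numeric(),
                      n_observations = integer()))
  prof <- mismatch_profile_cpp(x$effective_seq,
                               match(x$chrom, genome$names), x$pos,
                               x$strand, x$script, unname(genome$seqs),
                               as.integer(max_len))
  keep <- seq_len(max(which(prof$coverage > 0L), 0L))
  data.frame(
    cycle = keep,
    mismatch_rate = ifelse(prof$coverage[keep] > 0L,
                           prof$mismatches[keep] / prof$coverage[keep], NA_real_),
    n_observations = prof$coverage[keep]
  )
}

#' Bisulfite conversion efficiency from a spike-in chromosome
#'
#' Over all covered cytosines of an unmethylated spike-in (e.g. lambda
#' phage), every T call is a successful conversion and every C call a
#' failed one: efficiency = converted / (converted + unconverted).
#'
#' @param table a \code{meth_table}.
#' @param spike_chrom spike-in chromosome name.
#' @param ch_only if \code{TRUE}, restrict to CHG+CHH sites.
#' @return list with \code{converted}, \code{unconverted},
#'   \code{efficiency}.
#' @export
conversion_efficiency <- function(table, spike_chrom, ch_only = FALSE) {
  sub <- table[table$chrom == spike_chrom, , drop = FALSE]
  if (ch_only) sub <- sub[sub$context %in% c("CHG", "CHH"), , drop = FALSE]
  if (nrow(sub) == 0L || sum(sub$total_count) == 0L)
    stop("no spike-in coverage on chromosome '", spike_chrom, "'")
  unconverted <- sum(sub$meth_count)
  converted <- sum(sub$total_count) - unconverted
  list(converted = converted, unconverted = unconverted,
       efficiency = converted / (converted + unconverted))
}

#' Genome-wide methylation in tiling windows
#'
#' Non-overlapping windows of \code{window_bp}; the window level is the
#' pooled ratio sum(meth)/sum(total) per context (count-weighted, not
#' mean-of-site-levels). Windows with no covered sites are absent.
#'
#' @param table a \code{meth_table}.
#' @param window_bp window size in bp, >= 1.
#' @return data.frame with \code{chrom}, \code{window_start} (0-based),
#'   \code{context}, \code{level}, \code{n_sites}, \code{meth_count},
#'   \code{total_count}.
#' @export
genome_windows <- function(table, window_bp) {
  stopifnot(window_bp >= 1)
  if (nrow(table) == 0L)
    return(data.frame(chrom = character(), window_start = integer(),
                      context = character(), level = numeric(),
                      n_sites = integer(), meth_count = integer(),
                      total_count = integer()))
  dt <- data.table::as.data.table(table)
  dt$window_start <- (dt$pos %/% as.integer(window_bp)) * as.integer(window_bp)
  agg <- dt[, list(meth_count = sum(meth_count),
                   total_count = sum(total_count),
                   n_sites = .N),
            by = c("chrom", "window_start", "context")]
  agg$level <- agg$meth_count / agg$total_count
  out <- as.data.frame(agg[order(chrom, window_start, context)])
  out[, c("chrom", "window_start", "context", "level", "n_sites",
          "meth_count", "total_count")]
}

#' Metagene methylation profile
#'
#' Features are scaled into \code{body_bins} equal fractions with fixed-bp
#' flanks split into \code{flank_bins}; minus-strand features are mirrored
#' so bin 1 is always the upstream flank end. Bin values are pooled
#' count-weighted ratios per context across all features.
#'
#' @param table a \code{meth_table}.
#' @param features data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{strand}, or a GRanges, or a GFF3/BED
#'   file path (read via \pkg{rtracklayer}).
#' @param body_bins bins across the feature body.
#' @param flank_bp flank size in bp on each side.
#' @param flank_bins bins per flank.
#' @return object of class \code{metaplot_profile}: list with
#'   \code{profile} (data.frame \code{bin}, \code{zone}, \code{context},
#'   \code{level}, \code{total_count}), \code{n_bins}, \code{body_bins},
#'   \code{flank_bp}, \code{flank_bins}, \code{n_features}.
#' @export
metaplot <- function(table, features, body_bins = 60L, flank_bp = 2000L,
                     flank_bins = 20L) {
  features <- as_feature_df(features)
  if (nrow(features) == 0L) stop("empty feature set")
  body_bins <- as.integer(body_bins)
  flank_bins <- as.integer(flank_bins)
  n_bins <- 2L * flank_bins + body_bins
  fw <- flank_bp / flank_bins
  acc_m <- acc_t <- list(CG = numeric(n_bins), CHG = numeric(n_bins),
                         CHH = numeric(n_bins))
  dropped <- 0L
  for (i in seq_len(nrow(features))) {
    fchrom <- features$chrom[i]
    fs <- features$start[i]; fe <- features$end[i]
    if (fe <= fs) { dropped <- dropped + 1L; next }
    sub <- table[table$chrom == fchrom & table$pos >= fs - flank_bp &
                   table$pos < fe + flank_bp, , drop = FALSE]
    if (nrow(sub) == 0L) next
    p <- sub$pos
    bin <- integer(nrow(sub))
    up <- p < fs
    dn <- p >= fe
    body <- !up & !dn
    bin[up] <- pmin(flank_bins - 1L, floor((p[up] - (fs - flank_bp)) / fw))
    bin[body] <- flank_bins + pmin(body_bins - 1L,
                                   floor((p[body] - fs) / (fe - fs) * body_bins))
    bin[dn] <- flank_bins + body_bins +
      pmin(flank_bins - 1L, floor((p[dn] - fe) / fw))
    if (identical(features$strand[i], "-")) bin <- n_bins - 1L - bin
    for (ctx in c("CG", "CHG", "CHH")) {
      sel <- sub$context == ctx
      if (!any(sel)) next
      bm <- tapply(sub$meth_count[sel], bin[sel], sum)
      bt <- tapply(sub$total_count[sel], bin[sel], sum)
      ii <- as.integer(names(bm)) + 1L
      acc_m[[ctx]][ii] <- acc_m[[ctx]][ii] + bm
      acc_t[[ctx]][ii] <- acc_t[[ctx]][ii] + bt
    }
  }
  if (dropped > 0L) warning(dropped, " feature(s) skipped (empty interval)")
  zone <- c(rep("upstream", flank_bins), rep("body", body_bins),
            rep("downstream", flank_bins))
  prof <- do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(ctx) {
    data.frame(bin = seq_len(n_bins), zone = zone, context = ctx,
               level = ifelse(acc_t[[ctx]] > 0, acc_m[[ctx]] / acc_t[[ctx]],
                              NA_real_),
               total_count = acc_t[[ctx]], stringsAsFactors = FALSE)
  }))
  structure(list(profile = prof, n_bins = n_bins, body_bins = body_bins,
                 flank_bp = flank_bp, flank_bins = flank_bins,
                 n_features = nrow(features)),
            class = "metaplot_profile")
}

as_feature_df <- function(features) {
  if (is.character(features) && length(features) == 1L) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading feature files requires the rtracklayer package")
    features <- rtracklayer::import(features)
  }
  if (methods::is(features, "GRanges")) {
    df <- as.data.frame(features)
    features <- data.frame(
      chrom = as.character(df$seqnames),
      start = df$start - 1L,  # to 0-based half-open
      end = df$end,
      strand = as.character(df$strand),
      stringsAsFactors = FALSE
    )
    features$strand[features$strand == "*"] <- "+"
  }
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(features)))
  features
}

#' @export
print.metaplot_profile <- function(x, ...) {
  cat("metaplot_profile:", x$n_features, "feature(s),", x$n_bins,
      "bins (", x$flank_bins, "flank +", x$body_bins, "body +",
      x$flank_bins, "flank )\n")
  invisible(x)
}

#' Plot helpers (thin layers over the tabular outputs)
#'
#' Render the tabular QC outputs to PNG. The tables are the tested surface;
#' these functions only draw them.
#'
#' @param profile a \code{metaplot_profile} or mismatch-profile data.frame.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
plot_metaplot <- function(profile, path) {
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  pr <- profile$profile
  cols <- c(CG = "#1b9e77", CHG = "#d95f02", CHH = "#7570b3")
  plot(NA, xlim = c(1, profile$n_bins), ylim = c(0, 1),
       xlab = "bin (upstream | body | downstream)",
       ylab = "mean methylation level", main = "Metagene methylation")
  for (ctx in names(cols)) {
    sub <- pr[pr$context == ctx, ]
    graphics::lines(sub$bin, sub$level, col = cols[[ctx]], lwd = 2)
  }
  graphics::abline(v = c(profile$flank_bins + 0.5,
                         profile$flank_bins + profile$body_bins + 0.5),
                   lty = 2, col = "grey50")
  graphics::legend("topright", names(cols), col = cols, lwd = 2, bty = "n")
  invisible(path)
}

#' @rdname plot_metaplot
#' @export
plot_mismatch_profile <- function(profile, path) {
  grDevices::png(path, width = 900, height = 400)
  on.exit(grDevices::dev.off())
  plot(profile$cycle, profile$mismatch_rate, type = "h", lwd = 3,
       col = "#d95f02", xlab = "sequencing cycle", ylab = "mismatch rate",
       main = "Bisulfite-aware mismatch rate by cycle")
  invisible(path)
}
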