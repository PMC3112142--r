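#' Per-base depth of unique reads over target regions
#'
#' Computes, for every target base, the number of uniquely aligned reads whose
#' span covers it. Both mates of a pair are counted individually; spans are
#' clipped to the target intervals, so reads straddling a target edge
#' contribute only their in-target bases.
#'
#' @param accepted Accepted alignments (long format, one row per mate, columns
#'   `chrom`, `pos` 0-based, plus anything else) — e.g.
#'   `map_and_pair()$accepted`.
#' @param targets A [GenomicRanges::GRanges] of target regions.
#' @param read_length Read length in bases.
#' @return An object of class `depth_track`: list with `coverage` (an
#'   [IRanges::RleList] over the full chromosomes) and `targets`.
#' @export
compute_depth <- function(accepted, targets, read_length = 50L) {
  if (nrow(accepted) == 0L) {
    cov <- IRanges::RleList(lapply(
      stats::setNames(nm = unique(as.character(GenomicRanges::seqnames(targets)))),
      function(x) S4Vectors::Rle(0L, max(GenomicRanges::end(targets)))))
    return(structure(list(coverage = cov, targets = targets),
                     class = "depth_track"))
  }
  spans <- GenomicRanges::GRanges(
    seqnames = accepted$chrom,
    ranges = IRanges::IRanges(start = accepted$pos + 1L, width = read_length))
  maxend <- max(GenomicRanges::end(spans), GenomicRanges::end(targets))
  cov <- GenomicRanges::coverage(
    spans, width = stats::setNames(
      rep(maxend, length(unique(as.character(GenomicRanges::seqnames(spans))))),
      unique(as.character(GenomicRanges::seqnames(spans)))))
  structure(list(coverage = cov, targets = targets), class = "depth_track")
}

# depth values over target bases, as one integer vector
target_depths <- function(track) {
  tg <- track$targets
  out <- integer(0)
  for (chr in unique(as.character(GenomicRanges::seqnames(tg)))) {
    if (!chr %in% names(track$coverage)) next
    sub <- tg[as.character(GenomicRanges::seqnames(tg)) == chr]
    v <- IRanges::Views(track$coverage[[chr]],
                        start = GenomicRanges::start(sub),
                        end = GenomicRanges::end(sub))
    out <- c(out, unlist(lapply(v, as.integer), use.names = FALSE))
  }
  out
}

#' Summarize target coverage
#'
#' Mean fold coverage is defined as total sequenced read bases divided by
#' total target size (`read_count * read_length / target_bases`), reported
#' rounded to the nearest integer; the observed mean of per-base depths is
#' also returned. Fraction covered is the share of target bases with depth at
#' least `min_depth`.
#'
#' @param track A `depth_track` from [compute_depth()] (may be `NULL` when
#'   only the mean-fold formula is needed).
#' @param targets Target `GRanges`, or a total target size in bases.
#' @param read_count Number of (unique, accepted) reads.
#' @param read_length Read length in bases.
#' @param min_depth Depth threshold for "covered" (default 1).
#' @return A list of class `coverage_summary`: `mean_fold` (rounded),
#'   `mean_fold_raw`, `mean_depth_observed`, `fraction_covered`,
#'   `percent_covered` (whole percent), `target_bases`, `read_count`,
#'   `read_length`.
#' @examples
#' summarize_coverage(NULL, 504000, read_count = 3.1e6, read_length = 50)$mean_fold
#' @export
summarize_coverage <- function(track, targets, read_count, read_length = 50L,
                               min_depth = 1L) {
  target_bases <- if (methods::is(targets, "GRanges")) {
    sum(GenomicRanges::width(GenomicRanges::reduce(targets)))
  } else {
    as.numeric(targets)
  }
  if (!isTRUE(target_bases > 0))
    stop("summarize_coverage: target size must be positive", call. = FALSE)
  raw <- read_count * read_length / target_bases
  frac <- NA_real_
  mean_obs <- NA_real_
  if (!is.null(track)) {
    d <- target_depths(track)
    frac <- mean(d >= min_depth)
    mean_obs <- mean(d)
  }
  structure(list(mean_fold = as.integer(round_half_up(raw)),
                 mean_fold_raw = raw,
                 mean_depth_observed = mean_obs,
                 fraction_covered = frac,
                 percent_covered = if (is.na(frac)) NA_real_
                                   else round_half_up(100 * frac),
                 target_bases = target_bases,
                 read_count = read_count,
                 read_length = read_length),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("Coverage summary: %d-fold mean (%.1f raw) over %s target bases\n",
              x$mean_fold, x$mean_fold_raw, format(x$target_bases, big.mark = ",")))
  if (!is.na(x$fraction_covered))
    cat(sprintf("  target coverage: %.0f%% of bases at depth >= 1 (observed mean depth %.1f)\n",
                100 * x$fraction_covered, x$mean_depth_observed))
  invisible(x)
}

#' Enrichment fold versus random sequencing
#'
#' The observed on-target read fraction divided by the fraction expected if
#' reads were distributed uniformly over the genome:
#' `(on_target/total) / (target_size/genome_size)`.
#'
#' @param on_target_reads,total_mapped_reads Read counts.
#' @param target_size,genome_size Sizes in bases.
#' @return A single fold value.
#' @examples
#' enrichment_fold(500, 1000, 1000, 1e6)   # 500
#' @export
enrichment_fold <- function(on_target_reads, total_mapped_reads,
                            target_size, genome_size) {
  if (total_mapped_reads <= 0)
    stop("enrichment_fold: total_mapped_reads must be positive", call. = FALSE)
  if (target_size <= 0 || target_size > genome_size)
    stop("enrichment_fold: need 0 < target_size <= genome_size", call. = FALSE)
  (on_target_reads / total_mapped_reads) / (target_size / genome_size)
}

#' Count reads overlapping the targets
#'
#' @param accepted Accepted alignments (long format).
#' @param targets Target `GRanges`.
#' @param read_length Read length.
#' @return Number of reads whose span overlaps any target base.
#' @export
count_on_target <- function(accepted, targets, read_length = 50L) {
  if (nrow(accepted) == 0L) return(0L)
  spans <- GenomicRanges::GRanges(
    accepted$chrom,
    IRanges::IRanges(start = accepted$pos + 1L, width = read_length))
  sum(GenomicRanges::countOverlaps(spans, targets) > 0L)
}

#' Export a depth track as BEDGraph
#'
#' @param track A `depth_track`.
#' @param path Output path.
#' @param targets_only Restrict the export to target intervals.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path, targets_only = TRUE) {
  gr <- GenomicRanges::bindAsGRanges(score = track$coverage)
  if (targets_only) {
    hits <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(track$targets))
    gr <- GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(hits)],
      GenomicRanges::reduce(track$targets)[S4Vectors::subjectHits(hits)])
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Per-exon depth table for plotting
#'
#' One row per target base: position and depth, labelled by gene/exon —
#' the data behind a coverage plot of an exon across samples.
#'
#' @param track A `depth_track`.
#' @return A data.frame with `chrom`, `pos` (1-based), `gene`, `exon`, `depth`.
#' @export
exon_depth_table <- function(track) {
  tg <- track$targets
  rows <- lapply(seq_along(tg), function(i) {
    chr <- as.character(GenomicRanges::seqnames(tg))[i]
    p <- GenomicRanges::start(tg)[i]:GenomicRanges::end(tg)[i]
    d <- as.integer(IRanges::Views(track$coverage[[chr]],
                                   start = GenomicRanges::start(tg)[i],
                                   end = GenomicRanges::end(tg)[i])[[1]])
    data.frame(chrom = chr, pos = p,
               gene = tg$gene[i] %||% NA_character_,
               exon = tg$exon[i] %||% NA_integer_,
               depth = d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
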