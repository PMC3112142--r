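PILEUP_COUNT_COLS <- as.vector(outer(c("A", "C", "G", "T"), c("fwd", "rev"),
                                     paste, sep = "_"))

#' Build a strand-split pileup over target bases
#'
#' Tallies, for each covered target base, the aligned read bases split by the
#' strand of the alignment (minus-strand reads contribute their
#' reverse-complemented, reference-oriented bases). 'N' calls in reads are not
#' counted. This is the strand-split count model of the tumor-normal
#' comparison tables: one column per position with per-base
#' forward/reverse counts.
#'
#' @param accepted Accepted alignments in long format (columns `chrom`, `pos`
#'   0-based, `strand`, `seq`), e.g. `map_and_pair()$accepted`.
#' @param reference A `capture_reference` or named character vector.
#' @param targets Target `GRanges`; only target positions are reported.
#' @return A `pileup` data.frame: `chrom`, `pos` (1-based), `ref`, the eight
#'   strand-split counts `A_fwd`, `A_rev`, ..., `T_rev`, and `depth`.
#' @export
build_pileup <- function(accepted, reference, targets) {
  chroms <- reference_chroms(reference)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0),
                      stringsAsFactors = FALSE)
  for (cc in PILEUP_COUNT_COLS) empty[[cc]] <- integer(0)
  empty$depth <- integer(0)
  if (nrow(accepted) == 0L) return(structure(empty, class = c("pileup", "data.frame")))
  if (!all(accepted$chrom %in% names(chroms)))
    stop("build_pileup: alignment chromosome absent from the reference",
         call. = FALSE)

  rl <- nchar(accepted$seq[1])
  aligned <- accepted$seq
  neg <- accepted$strand == "-"
  if (any(neg)) aligned[neg] <- revcomp_chr(aligned[neg])

  n <- nrow(accepted)
  dt <- data.table::data.table(
    chrom = rep(accepted$chrom, each = rl),
    pos = rep(accepted$pos + 1L, each = rl) + rep.int(0:(rl - 1L), n),
    base = unlist(strsplit(aligned, "", fixed = TRUE), use.names = FALSE),
    strand = rep(ifelse(neg, "rev", "fwd"), each = rl))
  dt <- dt[base != "N"]

  # restrict to target bases
  tdt <- data.table::data.table(
    chrom = rep(as.character(GenomicRanges::seqnames(targets)),
                GenomicRanges::width(targets)),
    pos = unlist(mapply(seq, GenomicRanges::start(targets),
                        GenomicRanges::end(targets), SIMPLIFY = FALSE),
                 use.names = FALSE))
  data.table::setkey(tdt, chrom, pos)
  dt <- dt[tdt, on = c("chrom", "pos"), nomatch = NULL]

  cnt <- dt[, .N, by = c("chrom", "pos", "base", "strand")]
  wide <- data.table::dcast(cnt, chrom + pos ~ base + strand,
                            value.var = "N", fill = 0L)
  for (cc in PILEUP_COUNT_COLS)
    if (is.null(wide[[cc]])) wide[[cc]] <- 0L
  data.table::setkey(wide, chrom, pos)
  out <- as.data.frame(wide[, c("chrom", "pos", PILEUP_COUNT_COLS), with = FALSE])
  out$depth <- as.integer(rowSums(out[, PILEUP_COUNT_COLS]))
  refb <- character(nrow(out))
  for (chr in unique(out$chrom)) {
    i <- out$chrom == chr
    refb[i] <- substring(chroms[[chr]], out$pos[i], out$pos[i])
  }
  out <- cbind(out[, c("chrom", "pos")], ref = refb,
               out[, c(PILEUP_COUNT_COLS, "depth")])
  structure(out, class = c("pileup", "data.frame"))
}

#' Read a strand-split pileup table
#'
#' Ingests a TSV in the published tumor-normal comparison layout: one row per
#' (site, sample) with columns `A`, `C`, `G`, `T` holding strand-split counts
#' as `"fwd;rev"`, plus `chrom`, `pos`, `ref` and any identifying columns
#' (patient, gene, sample/tissue, printed coverage, printed genotype). Count
#' sums are compared against a printed `coverage` column when present; rows
#' where they disagree are flagged, not corrected.
#'
#' @param path TSV path.
#' @return A `pileup` data.frame with the eight strand-split count columns,
#'   `depth` (recomputed from the counts), any extra identifying columns, and
#'   `depth_mismatch` when a printed `coverage` column disagrees with the
#'   count sum.
#' @export
read_pileup_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (b in c("A", "C", "G", "T")) {
    if (!b %in% names(df))
      stop("read_pileup_table: missing count column '", b, "'", call. = FALSE)
    parts <- strsplit(as.character(df[[b]]), ";", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop("read_pileup_table: malformed strand-split entry in column '", b,
           "', row ", which(bad)[1], call. = FALSE)
    df[[paste0(b, "_fwd")]] <- as.integer(vapply(parts, `[`, "", 1L))
    df[[paste0(b, "_rev")]] <- as.integer(vapply(parts, `[`, "", 2L))
    df[[b]] <- NULL
  }
  df$depth <- as.integer(rowSums(df[, PILEUP_COUNT_COLS]))
  if ("coverage" %in% names(df))
    df$depth_mismatch <- df$coverage != df$depth
  structure(df, class = c("pileup", "data.frame"))
}

#' Call diploid genotypes from strand-split pileup columns
#'
#' Alleles are ranked by their total (forward + reverse) count; the minor
#' fraction is the second-ranked allele's count divided by the column depth.
#' A site is heterozygous when the minor fraction is at least
#' `het_min_fraction` (default 0.20), otherwise homozygous for the top allele.
#' The genotype string lists the called alleles in descending count order
#' (ties broken alphabetically). One-strand support is allowed — there is no
#' strand-balance filter — and calls are invariant under swapping forward and
#' reverse counts. Columns where a third allele also exceeds the
#' heterozygosity threshold trigger a warning and are called from the top two
#' alleles.
#'
#' @param pileup A `pileup` data.frame (from [build_pileup()] or
#'   [read_pileup_table()]).
#' @param het_min_fraction Minor-allele fraction at or above which a site is
#'   called heterozygous (default 0.20).
#' @param high_above Depth above which a call is high-confidence (default 50).
#' @return A `genotype_calls` data.frame: the input identifying columns plus
#'   `genotype`, `a1`, `a2`, `zygosity` (`hom_ref`/`het`/`hom_alt`),
#'   `minor_fraction`, `depth`, `confidence`.
#' @examples
#' col <- data.frame(chrom = "12", pos = 56310248, ref = "C",
#'                   A_fwd = 30, A_rev = 70, C_fwd = 0, C_rev = 54,
#'                   G_fwd = 0, G_rev = 0, T_fwd = 0, T_rev = 0)
#' call_genotypes(col)$genotype   # "AC"
#' @export
call_genotypes <- function(pileup, het_min_fraction = 0.20, high_above = 50L) {
  stopifnot(all(PILEUP_COUNT_COLS %in% names(pileup)))
  if (nrow(pileup) == 0L) {
    out <- pileup
    for (cc in c("genotype", "a1", "a2", "zygosity", "confidence")) out[[cc]] <- character(0)
    out$minor_fraction <- numeric(0)
    return(structure(out, class = c("genotype_calls", "data.frame")))
  }
  tot <- cbind(A = pileup$A_fwd + pileup$A_rev,
               C = pileup$C_fwd + pileup$C_rev,
               G = pileup$G_fwd + pileup$G_rev,
               T = pileup$T_fwd + pileup$T_rev)
  depth <- as.integer(rowSums(tot))
  if (any(depth == 0L))
    stop("call_genotypes: zero-depth pileup column (no-call); filter first",
         call. = FALSE)
  i1 <- max.col(tot, ties.method = "first")
  c1 <- tot[cbind(seq_len(nrow(tot)), i1)]
  tot2 <- tot
  tot2[cbind(seq_len(nrow(tot)), i1)] <- -1L
  i2 <- max.col(tot2, ties.method = "first")
  c2 <- tot[cbind(seq_len(nrow(tot)), i2)]
  tot3 <- tot2
  tot3[cbind(seq_len(nrow(tot)), i2)] <- -1L
  c3 <- tot[cbind(seq_len(nrow(tot)), max.col(tot3, ties.method = "first"))]

  minor_fraction <- c2 / depth
  het <- c2 > 0L & minor_fraction >= het_min_fraction
  if (any(c3 / depth >= het_min_fraction))
    warning("call_genotypes: ", sum(c3 / depth >= het_min_fraction),
            " column(s) have a third allele above the heterozygosity ",
            "threshold; called from the top two alleles", call. = FALSE)

  b1 <- DNA_BASES[i1]
  b2 <- DNA_BASES[i2]
  a1 <- b1
  a2 <- ifelse(het, b2, b1)
  genotype <- paste0(a1, a2)
  zygosity <- ifelse(het, "het",
                     ifelse(b1 == as.character(pileup$ref), "hom_ref", "hom_alt"))
  out <- pileup
  out$genotype <- genotype
  out$a1 <- a1
  out$a2 <- a2
  out$zygosity <- zygosity
  out$minor_fraction <- minor_fraction
  out$depth <- depth
  out$confidence <- ifelse(depth > high_above, "high", "low")
  structure(as.data.frame(out), class = c("genotype_calls", "data.frame"))
}

#' @rdname call_genotypes
#' @param column A single pileup row (data.frame or named list/vector with the
#'   eight strand-split counts and `ref`).
#' @export
call_genotype <- function(column, het_min_fraction = 0.20, high_above = 50L) {
  call_genotypes(as.data.frame(as.list(column)),
                 het_min_fraction = het_min_fraction, high_above = high_above)
}

#' Depth-tier confidence filter
#'
#' Removes calls below the minimum depth and assigns coverage-confidence
#' tiers: depth strictly greater than `high_above` is high confidence, depth
#' strictly below `drop_below` is removed, anything between (bounds included)
#' is kept at low confidence.
#'
#' @param calls A `genotype_calls` data.frame.
#' @param drop_below Calls with depth strictly below this are removed
#'   (default 10).
#' @param high_above Calls with depth strictly above this are high confidence
#'   (default 50).
#' @return The filtered calls with a `confidence` column; attribute
#'   `filter_tally` records `n_in`, `n_removed`, `n_high`, `n_low`.
#' @export
confidence_filter <- function(calls, drop_below = 10L, high_above = 50L) {
  keep <- calls$depth >= drop_below
  out <- calls[keep, , drop = FALSE]
  out$confidence <- ifelse(out$depth > high_above, "high", "low")
  attr(out, "filter_tally") <- c(n_in = nrow(calls),
                                 n_removed = sum(!keep),
                                 n_high = sum(out$confidence == "high"),
                                 n_low = sum(out$confidence == "low"))
  out
}

#' Emit variant records from genotype calls
#'
#' One record per non-homozygous-reference call. The alternate allele(s) are
#' the called alleles differing from the reference; the first listed alternate
#' (the better-supported one) defines the variant key `chrom:pos:alt` used by
#' all set operations. A genomic-change notation `g.<pos><ref>><alt>` is
#' attached, and a gene assignment when `targets` carries gene metadata.
#'
#' @param calls A `genotype_calls` data.frame (post [confidence_filter()]).
#' @param sample_id Sample identifier stored on each record.
#' @param targets Optional `GRanges` with a `gene` column for gene assignment.
#' @return A `variant_records` data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `genotype`, `zygosity`, `depth`, `confidence`, `gene`,
#'   `rsid` (NA until annotated), `hgvs_g`, `key`.
#' @export
emit_variants <- function(calls, sample_id, targets = NULL) {
  v <- calls[calls$zygosity != "hom_ref", , drop = FALSE]
  alts <- character(nrow(v))
  alt1 <- character(nrow(v))
  if (nrow(v)) {
    for (i in seq_len(nrow(v))) {
      aa <- unique(c(v$a1[i], v$a2[i]))
      aa <- aa[aa != v$ref[i]]
      alt1[i] <- aa[1]
      alts[i] <- paste(aa, collapse = ",")
    }
  }
  gene <- rep(NA_character_, nrow(v))
  if (!is.null(targets) && !is.null(targets$gene) && nrow(v)) {
    gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr, targets, select = "first")
    gene[!is.na(hits)] <- targets$gene[hits[!is.na(hits)]]
  }
  out <- data.frame(chrom = as.character(v$chrom), pos = v$pos,
                    ref = as.character(v$ref),
                    alt = alts, sample_id = rep(sample_id, nrow(v)),
                    genotype = v$genotype, zygosity = v$zygosity,
                    depth = v$depth, confidence = v$confidence,
                    gene = gene, rsid = rep(NA_character_, nrow(v)),
                    hgvs_g = sprintf("g.%d%s>%s", v$pos, v$ref, alt1),
                    key = sprintf("%s:%d:%s", v$chrom, v$pos, alt1),
                    stringsAsFactors = FALSE)
  structure(out, class = c("variant_records", "data.frame"))
}

#' Write variant records as minimal VCF v4
#'
#' CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO plus a single-sample GT column.
#' FILTER is `PASS` for high-confidence calls and `low_conf` otherwise; INFO
#' carries `DP`. Heterozygous calls involving the reference are `0/1`,
#' homozygous alternate `1/1`, heterozygous for two alternates `1/2`.
#'
#' @param variants A `variant_records` data.frame (one sample).
#' @param path Output path.
#' @param sample_id Sample column header (default taken from the records).
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, path, sample_id = NULL) {
  sample_id <- sample_id %||%
    (if (nrow(variants)) variants$sample_id[1] else "SAMPLE")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FILTER=<ID=low_conf,Description=\"Depth at or below the high-confidence threshold\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_id)), con)
  if (nrow(variants)) {
    nalt <- lengths(strsplit(variants$alt, ",", fixed = TRUE))
    gt <- ifelse(variants$zygosity == "hom_alt", "1/1",
                 ifelse(nalt > 1L, "1/2", "0/1"))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\tDP=%d\tGT\t%s",
                       variants$chrom, variants$pos,
                       ifelse(is.na(variants$rsid), ".", variants$rsid),
                       variants$ref, variants$alt,
                       ifelse(variants$confidence == "high", "PASS", "low_conf"),
                       variants$depth, gt), con)
  }
  invisible(path)
}

#' Write / read the package's variant TSV
#'
#' A lossless tab-separated representation of `variant_records`, usable as the
#' exchange format between pipeline stages.
#'
#' @param variants A `variant_records` data.frame.
#' @param path File path.
#' @return `write_variant_table()` the path invisibly; `read_variant_table()`
#'   a `variant_records` data.frame.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  structure(df, class = c("variant_records", "data.frame"))
}

#' Write calls in the strand-split table layout
#'
#' One row per (site, sample) with `"fwd;rev"` count entries — the layout of
#' the published tumor-normal comparison table.
#'
#' @param calls A `genotype_calls` data.frame.
#' @param path Output path.
#' @param extra_cols Identifying columns to carry through (kept when present).
#' @return The path, invisibly.
#' @export
write_pileup_table <- function(calls, path,
                               extra_cols = c("patient", "gene", "sample",
                                              "tissue")) {
  keep <- intersect(c(extra_cols, "chrom", "pos", "ref"), names(calls))
  out <- calls[, keep, drop = FALSE]
  out$coverage <- calls$depth
  for (b in c("A", "C", "G", "T"))
    out[[b]] <- sprintf("%d;%d", calls[[paste0(b, "_fwd")]],
                        calls[[paste0(b, "_rev")]])
  if (!is.null(calls$genotype)) out$genotype <- calls$genotype
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
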