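#' Remove read pairs with ambiguous nucleotide calls
#'
#' A pair is removed when either mate carries three or more 'N' calls; pairs
#' whose mates each have at most two 'N' are kept. The whole pair is dropped
#' because all downstream logic is pair-based.
#'
#' @param pairs A read-pair data.frame (`id`, `seq1`, `seq2`, ...), e.g. from
#'   [read_fastq_pairs()] or a `read_set$pairs`.
#' @param max_n Maximum tolerated 'N' calls per mate (default 2, i.e. remove
#'   at 3 or more).
#' @return A list with `kept` (the surviving pairs), `removed` (count of pairs
#'   dropped) and `n_in`.
#' @examples
#' p <- data.frame(id = c("a", "b"),
#'                 seq1 = c("ACGTNNNACG", "ACGTACGTAC"),
#'                 seq2 = c("ACGTACGTAC", "ACGTACGTAC"))
#' filter_ambiguous(p)$removed   # 1
#' @export
filter_ambiguous <- function(pairs, max_n = 2L) {
  stopifnot(all(c("id", "seq1", "seq2") %in% names(pairs)))
  n1 <- Biostrings::letterFrequency(Biostrings::DNAStringSet(pairs$seq1), "N")[, 1]
  n2 <- Biostrings::letterFrequency(Biostrings::DNAStringSet(pairs$seq2), "N")[, 1]
  keep <- n1 <= max_n & n2 <= max_n
  list(kept = pairs[keep, , drop = FALSE],
       removed = sum(!keep),
       n_in = nrow(pairs))
}

#' Map reads by exhaustive ungapped scan with a mismatch budget
#'
#' Finds, for each read, every ungapped placement on either strand of the
#' reference with at most `max_mismatch` mismatches (an 'N' in the read
#' mismatches every reference base). A read is `unique` when a single placement
#' attains the minimal mismatch count, `multi` when two or more placements tie
#' at the minimum (with `strict = TRUE`, when any second placement is within
#' the budget at all), and `unmapped` when no placement is within budget. The
#' search is seed-accelerated but exhaustively equivalent to scanning every
#' offset.
#'
#' @param seqs Character vector of read sequences (A/C/G/T/N).
#' @param reference A `capture_reference`, a named character vector of
#'   chromosome sequences, or a single sequence string.
#' @param max_mismatch Mismatch budget (default 3).
#' @param strict Tie semantics for `multi` status (see above).
#' @param ids Optional read identifiers.
#' @return A data.frame of alignments: `id`, `chrom`, `pos` (0-based leftmost),
#'   `strand`, `mismatches`, `status`, `n_best`, `n_hits`.
#' @examples
#' ref <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
#' rd <- substring(ref, 101, 150)
#' map_reads(rd, ref)[, c("pos", "strand", "mismatches", "status")]
#' @export
map_reads <- function(seqs, reference, max_mismatch = 3L, strict = FALSE,
                      ids = NULL) {
  chroms <- reference_chroms(reference)
  n <- length(seqs)
  per <- lapply(seq_along(chroms), function(ci) {
    res <- .map_reads_cpp(toupper(seqs), chroms[[ci]],
                          max_mm = as.integer(max_mismatch),
                          strict_multi = strict)
    res$chrom <- rep(names(chroms)[ci], nrow(res))
    res
  })
  # combine across chromosomes: best stratum wins; ties across chroms -> multi
  best <- per[[1]]
  if (length(per) > 1L) {
    for (ci in 2:length(per)) {
      b <- per[[ci]]
      bmm <- ifelse(is.na(best$mismatches), max_mismatch + 1L, best$mismatches)
      cmm <- ifelse(is.na(b$mismatches), max_mismatch + 1L, b$mismatches)
      take <- cmm < bmm
      tie <- cmm == bmm & cmm <= max_mismatch
      best$n_hits <- best$n_hits + b$n_hits
      best$n_best[tie] <- best$n_best[tie] + b$n_best[tie]
      for (col in c("pos", "strand", "mismatches", "chrom"))
        best[[col]][take] <- b[[col]][take]
      best$n_best[take] <- b$n_best[take]
      mapped <- best$n_hits > 0L
      multi <- if (strict) best$n_hits > 1L else best$n_best > 1L
      best$status <- ifelse(!mapped, "unmapped", ifelse(multi, "multi", "unique"))
    }
  }
  data.frame(id = ids %||% as.character(seq_len(n)),
             chrom = ifelse(best$status == "unmapped", NA_character_, best$chrom),
             pos = best$pos, strand = best$strand,
             mismatches = best$mismatches, status = best$status,
             n_best = best$n_best, n_hits = best$n_hits,
             stringsAsFactors = FALSE)
}

#' @rdname map_reads
#' @param seq A single read sequence.
#' @return `map_read()` returns a one-row alignment data.frame.
#' @export
map_read <- function(seq, reference, max_mismatch = 3L, strict = FALSE) {
  map_reads(seq, reference, max_mismatch = max_mismatch, strict = strict)
}

reference_chroms <- function(reference) {
  if (inherits(reference, "capture_reference"))
    return(stats::setNames(list(reference$seq), reference$seqname))
  if (methods::is(reference, "DNAStringSet"))
    return(stats::setNames(as.list(as.character(reference)), names(reference)))
  if (is.character(reference)) {
    nm <- names(reference) %||% paste0("chr", seq_along(reference))
    nm[nm == ""] <- paste0("chr", which(nm == ""))
    return(stats::setNames(as.list(unname(reference)), nm))
  }
  stop("map_reads: unsupported reference type", call. = FALSE)
}

#' Accept or reject an aligned read pair
#'
#' A pair is accepted when both alignments are unique, on the same chromosome,
#' on opposite strands in inward (FR) orientation (the '+' strand mate
#' leftmost), and the outer fragment length — leftmost read start to rightmost
#' mate end, inclusive — lies within `insert_range` (bounds inclusive).
#'
#' @param a1,a2 One-row alignment data.frames (as returned by [map_reads()]).
#' @param insert_range Inclusive fragment-length bounds, default `c(100, 500)`.
#' @param read_length Read length used to compute the fragment end.
#' @return A list with `accepted` (logical), `fragment_length` (NA when
#'   rejected early), and `reason` (`"ok"`, or one of `non_unique`,
#'   `diff_chrom`, `same_strand`, `outward`, `too_short`, `too_long`).
#' @export
pair_filter <- function(a1, a2, insert_range = c(100L, 500L),
                        read_length = 50L) {
  res <- accept_pairs(
    data.frame(id = "p", chrom1 = a1$chrom, pos1 = a1$pos, strand1 = a1$strand,
               status1 = a1$status, chrom2 = a2$chrom, pos2 = a2$pos,
               strand2 = a2$strand, status2 = a2$status,
               stringsAsFactors = FALSE),
    insert_range = insert_range, read_length = read_length)
  list(accepted = res$reason == "ok",
       fragment_length = res$fragment_length,
       reason = res$reason)
}

#' Vectorized paired-end acceptance
#'
#' Applies the [pair_filter()] rules to a table of mate alignments.
#'
#' @param mates A data.frame with columns `id`, `chrom1`, `pos1`, `strand1`,
#'   `status1`, `chrom2`, `pos2`, `strand2`, `status2`.
#' @inheritParams pair_filter
#' @return `mates` with added `fragment_length` and `reason` columns;
#'   `reason == "ok"` marks accepted pairs.
#' @export
accept_pairs <- function(mates, insert_range = c(100L, 500L),
                         read_length = 50L) {
  n <- nrow(mates)
  reason <- rep("ok", n)
  frag <- rep(NA_integer_, n)

  nonuniq <- mates$status1 != "unique" | mates$status2 != "unique"
  reason[nonuniq] <- "non_unique"
  ok <- !nonuniq

  diffchr <- ok & (mates$chrom1 != mates$chrom2)
  reason[diffchr] <- "diff_chrom"
  ok <- ok & !diffchr

  same <- ok & (mates$strand1 == mates$strand2)
  reason[same] <- "same_strand"
  ok <- ok & !same

  # outer fragment: start of '+' mate to end (exclusive) of '-' mate
  plus_pos <- ifelse(mates$strand1 == "+", mates$pos1, mates$pos2)
  minus_pos <- ifelse(mates$strand1 == "-", mates$pos1, mates$pos2)
  outward <- ok & (minus_pos < plus_pos)
  reason[outward] <- "outward"
  ok <- ok & !outward

  fl <- (minus_pos + read_length) - plus_pos
  frag[ok] <- fl[ok]
  short <- ok & fl < insert_range[1]
  long <- ok & fl > insert_range[2]
  reason[short] <- "too_short"
  reason[long] <- "too_long"

  mates$fragment_length <- frag
  mates$reason <- reason
  mates
}

#' Map and pair-filter a read-pair table
#'
#' Convenience stage: maps both mates of every pair, applies paired-end
#' acceptance, and returns the accepted alignments in long format (one row per
#' mate) ready for depth and pileup computation, along with filter tallies.
#'
#' @param pairs A read-pair data.frame (post-QC).
#' @param reference Reference (see [map_reads()]).
#' @param max_mismatch Mismatch budget per mate.
#' @param insert_range,read_length Passed to [accept_pairs()].
#' @param strict Tie semantics, see [map_reads()].
#' @return A list: `accepted` (data.frame `id`, `mate`, `chrom`, `pos`,
#'   `strand`, `mismatches`, `seq`), `pair_table` (per-pair reasons), and
#'   `tally` (named counts of rejection reasons).
#' @export
map_and_pair <- function(pairs, reference, max_mismatch = 3L,
                         insert_range = c(100L, 500L), read_length = NULL,
                         strict = FALSE) {
  if (is.null(read_length)) read_length <- nchar(pairs$seq1[1])
  al1 <- map_reads(pairs$seq1, reference, max_mismatch, strict, ids = pairs$id)
  al2 <- map_reads(pairs$seq2, reference, max_mismatch, strict, ids = pairs$id)
  mates <- data.frame(id = pairs$id,
                      chrom1 = al1$chrom, pos1 = al1$pos, strand1 = al1$strand,
                      status1 = al1$status,
                      chrom2 = al2$chrom, pos2 = al2$pos, strand2 = al2$strand,
                      status2 = al2$status, stringsAsFactors = FALSE)
  mates <- accept_pairs(mates, insert_range = insert_range,
                        read_length = read_length)
  okidx <- which(mates$reason == "ok")
  accepted <- data.frame(
    id = rep(pairs$id[okidx], 2L),
    mate = rep(1:2, each = length(okidx)),
    chrom = c(mates$chrom1[okidx], mates$chrom2[okidx]),
    pos = c(mates$pos1[okidx], mates$pos2[okidx]),
    strand = c(mates$strand1[okidx], mates$strand2[okidx]),
    mismatches = c(al1$mismatches[okidx], al2$mismatches[okidx]),
    seq = c(pairs$seq1[okidx], pairs$seq2[okidx]),
    stringsAsFactors = FALSE)
  list(accepted = accepted,
       pair_table = mates,
       tally = c(table(mates$reason)))
}

#' Import alignments from a SAM file
#'
#' Converts primary mapped SAM records to the internal alignment table.
#' Records flagged secondary or supplementary, and primary records with
#' mapping quality 0, are marked `multi`; unmapped records are `unmapped`.
#' SAM 1-based positions are converted to the internal 0-based convention.
#'
#' @param path Path to a SAM file with `@SQ` headers.
#' @return An alignment data.frame as from [map_reads()] (with `mate` from the
#'   first/last-segment flags when present); `n_hits`/`n_best` are NA.
#' @export
read_sam <- function(path) {
  hdr <- readLines(path, n = 50L)
  if (!any(startsWith(hdr, "@SQ")))
    stop("read_sam: missing @SQ header in ", path, call. = FALSE)
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0L)
    return(data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      mismatches = integer(0), status = character(0),
                      mate = integer(0), stringsAsFactors = FALSE))
  unmapped <- bitwAnd(x$flag, 4L) != 0L
  secondary <- bitwAnd(x$flag, 256L) != 0L | bitwAnd(x$flag, 2048L) != 0L
  multi <- !unmapped & (secondary | (!is.na(x$mapq) & x$mapq == 0L))
  status <- ifelse(unmapped, "unmapped", ifelse(multi, "multi", "unique"))
  mate <- ifelse(bitwAnd(x$flag, 128L) != 0L, 2L, 1L)
  data.frame(id = x$qname,
             chrom = ifelse(unmapped, NA_character_, as.character(x$rname)),
             pos = ifelse(unmapped, NA_integer_, x$pos - 1L),
             strand = ifelse(unmapped, NA_character_, as.character(x$strand)),
             mismatches = NA_integer_,
             status = status, mate = mate, stringsAsFactors = FALSE)
}
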