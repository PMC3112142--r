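# Independent brute-force oracles and small shared fixtures.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

revcomp1 <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Brute-force ungapped mapper: scores every offset on both strands.
oracle_map <- function(read, ref, max_mm = 3L) {
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(refv)
  L <- nchar(read)
  all_hits <- NULL
  if (L <= n) {
    noff <- n - L + 1L
    for (strand in c("+", "-")) {
      s <- if (strand == "+") read else revcomp1(read)
      rv <- strsplit(s, "", fixed = TRUE)[[1]]
      valid <- rv %in% c("A", "C", "G", "T")
      match_mat <- vapply(seq_len(L), function(j)
        refv[j:(j + noff - 1L)] == rv[j] & valid[j], logical(noff))
      if (noff == 1L) match_mat <- matrix(match_mat, nrow = 1L)
      mm <- L - rowSums(match_mat)
      keep <- which(mm <= max_mm)
      if (length(keep))
        all_hits <- rbind(all_hits,
                          data.frame(pos = keep - 1L, strand = strand,
                                     mm = mm[keep]))
    }
  }
  if (is.null(all_hits) || nrow(all_hits) == 0L)
    return(list(status = "unmapped", pos = NA_integer_, strand = NA_character_,
                mismatches = NA_integer_, n_best = 0L, n_hits = 0L))
  best <- min(all_hits$mm)
  at_best <- all_hits[all_hits$mm == best, , drop = FALSE]
  list(status = if (nrow(at_best) > 1L) "multi" else "unique",
       pos = at_best$pos[1], strand = at_best$strand[1],
       mismatches = best, n_best = nrow(at_best), n_hits = nrow(all_hits))
}

# Per-base depth recount by scanning every read against every target base.
oracle_depth <- function(accepted, targets, read_length) {
  tg_start <- GenomicRanges::start(targets)
  tg_end <- GenomicRanges::end(targets)
  pos <- unlist(mapply(seq, tg_start, tg_end, SIMPLIFY = FALSE))
  depth <- integer(length(pos))
  for (i in seq_len(nrow(accepted))) {
    s <- accepted$pos[i] + 1L
    e <- s + read_length - 1L
    depth <- depth + (pos >= s & pos <= e)
  }
  data.frame(pos = pos, depth = depth)
}

# Per-position, per-base, per-strand recount for pileup verification.
oracle_pileup_count <- function(accepted, position) {
  counts <- matrix(0L, nrow = 4, ncol = 2,
                   dimnames = list(c("A", "C", "G", "T"), c("fwd", "rev")))
  for (i in seq_len(nrow(accepted))) {
    s <- accepted$pos[i] + 1L
    rl <- nchar(accepted$seq[i])
    if (position < s || position > s + rl - 1L) next
    aligned <- if (accepted$strand[i] == "-") revcomp1(accepted$seq[i]) else accepted$seq[i]
    b <- substring(aligned, position - s + 1L, position - s + 1L)
    if (b %in% rownames(counts))
      counts[b, if (accepted$strand[i] == "-") "rev" else "fwd"] <-
        counts[b, if (accepted$strand[i] == "-") "rev" else "fwd"] + 1L
  }
  counts
}

# Brute-force set partition.
oracle_partition <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- unique(c(a, b))
  ina <- vapply(u, function(x) any(a == x), logical(1))
  inb <- vapply(u, function(x) any(b == x), logical(1))
  c(only_a = sum(ina & !inb), only_b = sum(!ina & inb), both = sum(ina & inb))
}

extdata <- function(f) system.file("extdata", f, package = "captureSNP")

target_depths_df <- function(track) {
  td <- exon_depth_table(track)
  data.frame(pos = td$pos, depth = td$depth)
}

# Small simulated experiment shared by several test files (cheap to rebuild).
tiny_config <- function(...) {
  base <- list(reference_length = 60000L, n_genes = 5L, exons_per_gene = 4L,
               exon_length_range = c(100L, 300L), target_fraction = 0.10,
               snp_density = 5, n_read_pairs = 2000L, seed = 11L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}
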