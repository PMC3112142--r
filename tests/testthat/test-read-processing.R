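test_that("ambiguous-call filter removes pairs at 3 or more N in either mate", {
  p <- data.frame(id = c("a", "b", "c", "d"),
                  seq1 = c("ACGTNNNACG",          # 3 N in mate 1
                           "ACGTACGTAC",
                           "ACNTACNTAC",          # 2 N -> kept
                           "ACGTACGTAC"),
                  seq2 = c("ACGTACGTAC",
                           "ACGTACGTAC",
                           "ACGTACGTAC",
                           "NNNNACGTAC"),         # 4 N in mate 2
                  stringsAsFactors = FALSE)
  res <- filter_ambiguous(p)
  expect_identical(res$kept$id, c("b", "c"))
  expect_equal(res$removed, 2L)
  expect_equal(res$n_in, 4L)
})

test_that("map_read handles exact, mutated, unmappable and decoy reads", {
  set.seed(42)
  ref <- random_seq(2000)
  rd <- substring(ref, 501, 550)
  al <- map_read(rd, ref)
  expect_equal(al$status, "unique")
  expect_equal(al$pos, 500L)
  expect_equal(al$mismatches, 0L)
  expect_equal(al$strand, "+")

  # reverse-complement read maps to the minus strand at the same locus
  alr <- map_read(revcomp1(rd), ref)
  expect_equal(alr$strand, "-")
  expect_equal(alr$pos, 500L)

  # 4 substitutions exceed the budget
  rd4 <- rd
  for (i in c(5, 15, 25, 35))
    substring(rd4, i, i) <- setdiff(c("A", "C", "G", "T"),
                                    substring(rd4, i, i))[1]
  expect_equal(map_read(rd4, ref)$status, "unmapped")
  # 3 substitutions are still within budget
  rd3 <- rd
  for (i in c(5, 15, 25))
    substring(rd3, i, i) <- setdiff(c("A", "C", "G", "T"),
                                    substring(rd3, i, i))[1]
  expect_equal(map_read(rd3, ref)$status, "unique")
  expect_equal(map_read(rd3, ref)$mismatches, 3L)

  # duplicated segment -> multi
  dup <- paste0(ref, substring(ref, 401, 700))
  expect_equal(map_read(rd, dup)$status, "multi")

  # read longer than the reference is unmapped, not an error
  expect_equal(map_reads(random_seq(100), random_seq(60))$status, "unmapped")
})

test_that("mapper is exhaustively equivalent to the brute-force Hamming scan", {
  set.seed(7)
  for (case in 1:60) {
    refl <- sample(300:1200, 1)
    ref <- random_seq(refl)
    kind <- case %% 4
    if (kind == 0) {
      rd <- random_seq(50)                       # random, usually unmapped
    } else {
      st <- sample(refl - 49, 1)
      rd <- substring(ref, st, st + 49)
      nmut <- sample(0:4, 1)
      if (nmut > 0)
        for (i in sample(50, nmut))
          substring(rd, i, i) <- sample(setdiff(c("A", "C", "G", "T", "N"),
                                                substring(rd, i, i)), 1)
      if (kind == 2) rd <- revcomp1(rd)
    }
    got <- map_reads(rd, ref)
    want <- oracle_map(rd, ref)
    expect_equal(got$status, want$status, info = paste("case", case))
    expect_equal(got$n_best, want$n_best, info = paste("case", case))
    expect_equal(got$n_hits, want$n_hits, info = paste("case", case))
    if (want$status == "unique") {
      expect_equal(got$pos, want$pos, info = paste("case", case))
      expect_equal(got$strand, want$strand, info = paste("case", case))
      expect_equal(got$mismatches, want$mismatches, info = paste("case", case))
    }
  }
})

test_that("short reads take the full-scan path and agree with the oracle", {
  set.seed(8)
  ref <- random_seq(800)
  for (i in 1:20) {
    L <- sample(20:47, 1)                        # below the seeded-path length
    st <- sample(800 - L, 1)
    rd <- substring(ref, st, st + L - 1L)
    if (i %% 2 == 0)
      substring(rd, sample(L, 1), sample(L, 1)) <- "N"
    got <- map_reads(rd, ref)
    want <- oracle_map(rd, ref)
    expect_equal(got$status, want$status)
    expect_equal(got$n_hits, want$n_hits)
  }
})

test_that("pair acceptance enforces orientation and inclusive fragment bounds", {
  mk <- function(pos, strand, status = "unique", chrom = "c1")
    data.frame(chrom = chrom, pos = pos, strand = strand, status = status,
               stringsAsFactors = FALSE)
  # + at 1000, - mate ending at 1299 (0-based end-exclusive 1300): fragment 300
  r <- pair_filter(mk(1000, "+"), mk(1250, "-"))
  expect_true(r$accepted)
  expect_equal(r$fragment_length, 300L)
  # inclusive boundaries
  expect_true(pair_filter(mk(1000, "+"), mk(1050, "-"))$accepted)      # 100
  expect_equal(pair_filter(mk(1000, "+"), mk(1050, "-"))$fragment_length, 100L)
  expect_true(pair_filter(mk(1000, "+"), mk(1450, "-"))$accepted)      # 500
  expect_equal(pair_filter(mk(1000, "+"), mk(1049, "-"))$reason, "too_short")
  expect_equal(pair_filter(mk(1000, "+"), mk(1550, "-"))$reason, "too_long")
  expect_equal(pair_filter(mk(1000, "+"), mk(1250, "+"))$reason, "same_strand")
  expect_equal(pair_filter(mk(1250, "+"), mk(1000, "-"))$reason, "outward")
  expect_equal(pair_filter(mk(1000, "+"), mk(1250, "-", chrom = "c2"))$reason,
               "diff_chrom")
  expect_equal(pair_filter(mk(1000, "+", status = "multi"),
                           mk(1250, "-"))$reason, "non_unique")
  # mate order must not matter: minus mate given first
  r2 <- pair_filter(mk(1250, "-"), mk(1000, "+"))
  expect_true(r2$accepted)
  expect_equal(r2$fragment_length, 300L)
})

test_that("accepted error-free pairs map back to their true origin", {
  cfg <- tiny_config(error_rate = 0, n_artifact_rate = 0,
                     decoy_duplications = 0L, n_read_pairs = 800L)
  ref <- generate_reference(cfg)
  tr <- plant_variants(ref, cfg)
  rs <- simulate_reads(ref, tr, cfg, tissue = "normal")
  mp <- map_and_pair(rs$pairs, ref)
  ok <- mp$pair_table[mp$pair_table$reason == "ok", ]
  expect_gt(nrow(ok), 700)
  origin <- rs$origin[match(ok$id, rs$origin$id), ]
  plus_pos <- ifelse(ok$strand1 == "+", ok$pos1, ok$pos2)
  expect_true(all(plus_pos + 1L == origin$start))
  expect_true(all(ok$fragment_length == origin$insert))
})

test_that("decoy-duplicated loci yield multi-status reads that are excluded", {
  cfg <- tiny_config(error_rate = 0, n_artifact_rate = 0,
                     decoy_duplications = 3L, n_read_pairs = 600L)
  ref <- generate_reference(cfg)
  expect_gt(length(ref$decoys), 0L)
  tr <- plant_variants(ref, cfg)
  rs <- simulate_reads(ref, tr, cfg, tissue = "normal")
  al <- map_reads(rs$pairs$seq1, ref, ids = rs$pairs$id)
  # reads wholly inside a decoy source exon must be multi
  src <- ref$targets[ref$decoys$source_exon[1]]
  w <- min(GenomicRanges::width(src), 500L)
  inside <- rs$origin$start >= GenomicRanges::start(src) &
    rs$origin$start + cfg$read_length - 1L <= GenomicRanges::start(src) + w - 1L
  if (any(inside))
    expect_true(all(al$status[inside] == "multi"))
  expect_gt(sum(al$status == "multi"), 0L)
})

test_that("QC order is observationally irrelevant to the accepted set", {
  cfg <- tiny_config(n_artifact_rate = 0.3, n_read_pairs = 300L)
  ref <- generate_reference(cfg)
  tr <- plant_variants(ref, cfg)
  rs <- simulate_reads(ref, tr, cfg, tissue = "normal")
  qc_first <- map_and_pair(filter_ambiguous(rs$pairs)$kept, ref)
  map_first <- map_and_pair(rs$pairs, ref)
  keep_ids <- filter_ambiguous(rs$pairs)$kept$id
  a <- qc_first$pair_table$id[qc_first$pair_table$reason == "ok"]
  b <- map_first$pair_table$id[map_first$pair_table$reason == "ok"]
  expect_identical(a, intersect(b, keep_ids))
})

test_that("read_sam converts coordinates, flags and rejects headerless input", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1", 0, "chr1", 101, 60, "50M", "*", 0, 0,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
    paste("r2", 16, "chr1", 201, 60, "50M", "*", 0, 0,
          paste(rep("C", 50), collapse = ""), "*", sep = "\t"),
    paste("r3", 256, "chr1", 301, 60, "50M", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r4", 0, "chr1", 401, 0, "50M", "*", 0, 0,
          paste(rep("G", 50), collapse = ""), "*", sep = "\t"),
    paste("r5", 4, "*", 0, 0, "*", "*", 0, 0,
          paste(rep("T", 50), collapse = ""), "*", sep = "\t")), sam)
  al <- read_sam(sam)
  expect_equal(al$pos[al$id == "r1"], 100L)
  expect_equal(al$strand[al$id == "r1"], "+")
  expect_equal(al$strand[al$id == "r2"], "-")
  expect_equal(al$status[al$id == "r3"], "multi")   # secondary flag
  expect_equal(al$status[al$id == "r4"], "multi")   # MAPQ 0
  expect_equal(al$status[al$id == "r5"], "unmapped")

  empty <- file.path(d, "empty.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000"), empty)
  expect_equal(nrow(read_sam(empty)), 0L)

  bad <- file.path(d, "bad.sam")
  writeLines("r1\t0\tchr1\t1\t60\t50M\t*\t0\t0\tACGT\t*", bad)
  expect_error(read_sam(bad), "@SQ")
})
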