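published <- read_pileup_table(extdata("tumor_normal_site_counts.tsv"))
pub_calls <- call_genotypes(published)

test_that("tumor-normal comparison flags the published genotype differences", {
  leu <- pub_calls[published$tissue == "Leu", ]
  tu <- pub_calls[published$tissue == "Tu", ]
  cand <- compare_tumor_normal(leu, tu, patient = "AB")
  expect_equal(nrow(cand), 7L)
  expect_true(all(cand$interpretation == "loh_or_hom"))
  b4 <- cand[cand$pos == 56310248 & cand$chrom == "12", ]
  expect_equal(b4$normal_genotype, "AC")
  expect_equal(b4$tumor_genotype, "AA")
})

test_that("identical genotypes and shallow sites yield no candidates", {
  leu <- pub_calls[published$tissue == "Leu", ]
  expect_equal(nrow(compare_tumor_normal(leu, leu)), 0L)
  # depth gate: strictly greater than min_depth in BOTH samples
  tu <- pub_calls[published$tissue == "Tu", ]
  cand <- compare_tumor_normal(leu, tu, min_depth = 52L)
  expect_false(any(cand$normal_depth <= 52L))
  expect_equal(nrow(cand), 6L)   # MDM1 leukocyte depth 52 drops out
})

test_that("unordered genotype comparison ignores allele order", {
  a <- data.frame(chrom = "1", pos = 1L, ref = "A", genotype = "AG",
                  a1 = "A", a2 = "G", zygosity = "het", depth = 100L,
                  stringsAsFactors = FALSE)
  b <- a; b$genotype <- "GA"; b$a1 <- "G"; b$a2 <- "A"
  expect_equal(nrow(compare_tumor_normal(a, b)), 0L)
})

test_that("overlap percentages reproduce all six published comparisons", {
  tab <- read.table(extdata("sample_overlap_counts.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  got <- mapply(function(a, b, n) overlap_stats(a, b, n)$percent,
                tab$only_1, tab$only_2, tab$both)
  expect_equal(unname(got), tab$percent)
  expect_equal(unname(got), c(19.4, 25.9, 18.5, 17.3, 16.1, 18.6))
})

test_that("pairwise overlap matches brute-force set partition on random sets", {
  set.seed(21)
  for (i in 1:50) {
    universe <- sprintf("1:%d:A", 1:60)
    a <- sample(universe, sample(0:40, 1))
    b <- sample(universe, sample(0:40, 1))
    got <- pairwise_overlap(a, b)
    want <- oracle_partition(a, b)
    expect_equal(got$only_a, unname(want["only_a"]))
    expect_equal(got$only_b, unname(want["only_b"]))
    expect_equal(got$both, unname(want["both"]))
    tot <- sum(want)
    if (tot > 0)
      expect_equal(got$percent, round(100 * want[["both"]] / tot + 1e-12, 1))
  }
  expect_equal(pairwise_overlap(c("x", "y"), c("x", "y"))$percent, 100.0)
  expect_equal(pairwise_overlap(c("x"), c("y"))$percent, 0.0)
})

test_that("venn regions enumerate membership patterns and conserve the union", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:4, 1)
    sets <- lapply(seq_len(n), function(j)
      sample(sprintf("k%02d", 1:30), sample(0:20, 1)))
    names(sets) <- paste0("s", seq_len(n))
    vc <- venn_counts(sets)
    expect_equal(nrow(vc), 2^n - 1L)
    expect_equal(sum(vc$count), length(unique(unlist(sets))))
    # cross-check each region by direct membership enumeration
    for (r in seq_len(nrow(vc))) {
      inset <- unlist(vc[r, seq_len(n)])
      members <- Reduce(intersect, sets[inset])
      for (s in sets[!inset]) members <- setdiff(members, s)
      expect_equal(vc$count[r], length(members))
    }
    # pairwise both equals the marginal over venn regions containing both sets
    ov <- pairwise_overlap(sets[[1]], sets[[2]])
    expect_equal(ov$both, sum(vc$count[vc[[1]] & vc[[2]]]))
  }
  # four identical singletons: only the centre region is occupied
  four <- rep(list("k"), 4)
  names(four) <- letters[1:4]
  vc <- venn_counts(four)
  expect_equal(vc$count[vc$pattern == "1111"], 1L)
  expect_equal(sum(vc$count), 1L)
  # an empty set among four empties every region that requires it
  four$b <- character(0)
  vc2 <- venn_counts(four)
  expect_true(all(vc2$count[vc2$b] == 0L))
  expect_error(venn_counts(rep(list("k"), 5)), "4 sets")
})

test_that("known-SNP annotation is allele-aware with position fallback", {
  tab <- read_annotation_table(extdata("gwas_catalog_synthetic.tsv"))
  v <- data.frame(chrom = c("11", "11", "20"), pos = c(27679916L, 27679916L, 61780283L),
                  ref = c("C", "C", "G"), alt = c("T", "G", "A"),
                  sample_id = "s", gene = NA, rsid = NA_character_,
                  key = c("11:27679916:T", "11:27679916:G", "20:61780283:A"),
                  stringsAsFactors = FALSE)
  ann <- annotate_known(v, tab)
  expect_equal(ann$known, c(TRUE, FALSE, TRUE))      # same pos, wrong alt -> novel
  expect_equal(ann$rsid[1], "rs6265")
  expect_match(ann$trait[3], "glioma")
  posann <- annotate_known(v, tab, by = "position")
  expect_true(all(posann$known))
  tally <- attr(ann, "annotation_tally")
  expect_equal(unname(tally["known"] + tally["novel"]), nrow(v))
  # duplicate keys are a load error
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tpos\tref\talt",
               "rs1\t1\t100\tA\tG", "rs2\t1\t100\tA\tG"), f)
  expect_error(read_annotation_table(f), "duplicate")
})

test_that("gene summary reports the share of listed genes carrying a SNP", {
  genes <- read_gene_list(extdata("antigen_genes_synthetic.txt"))
  expect_length(genes, 21L)
  # a cohort where all listed genes but one carry at least one SNP
  v <- data.frame(gene = rep(genes[-21], times = 2))
  gs <- gene_summary(v, genes)
  expect_equal(gs$n_with_snp, 20L)
  expect_equal(gs$percent, 95.2)
  expect_equal(gene_summary(data.frame(gene = character(0)), genes)$percent, 0)
  expect_error(gene_summary(v, character(0)), "empty")
  # brute-force cross-check on random assignments
  set.seed(41)
  for (i in 1:10) {
    vv <- data.frame(gene = sample(c(genes, "OTHER"), 30, replace = TRUE))
    gs2 <- gene_summary(vv, genes)
    expect_equal(gs2$n_with_snp, sum(vapply(genes, function(g)
      any(vv$gene == g), logical(1))))
  }
})

test_that("haplotype encoding emits minor/major binary code without phasing", {
  def <- read_haplotype_def(extdata("sart1_haplotype_synthetic.tsv"))
  hom <- function(x) x
  gt <- data.frame(rsid = def$rsid,
                   a1 = c(def$minor[1:2], def$major[3:4]),
                   a2 = c(def$minor[1:2], def$major[3:4]),
                   stringsAsFactors = FALSE)
  expect_equal(encode_haplotype(gt, def), "1100")
  gt0 <- data.frame(rsid = def$rsid, a1 = def$major, a2 = def$major)
  expect_equal(encode_haplotype(gt0, def), "0000")
  # heterozygous site -> unphased
  gth <- gt; gth$a2[1] <- def$major[1]
  expect_equal(encode_haplotype(gth, def), "unphased")
  # non-listed allele -> inconsistent
  gtx <- gt; gtx$a1[2] <- gtx$a2[2] <- setdiff(c("A", "C", "G", "T"),
                                               c(def$minor[2], def$major[2]))[1]
  expect_equal(encode_haplotype(gtx, def), "inconsistent")
  # missing call errors with the offending rsid
  expect_error(encode_haplotype(gt[-2, ], def), def$rsid[2])
  # order-preserving: permuting the definition permutes the code identically
  perm <- c(3, 1, 4, 2)
  expect_equal(encode_haplotype(gt, def[perm, ]),
               paste(strsplit("1100", "")[[1]][perm], collapse = ""))
})

test_that("cohort genotype frequencies reproduce the verification-cohort split", {
  g <- rep(c("hom_major", "het", "hom_minor"), c(7, 2, 1))
  f <- cohort_genotype_freq(g)
  expect_equal(f$percent, c(70, 20, 10))
  expect_equal(sum(f$count), 10L)
  f2 <- cohort_genotype_freq(rep("hom_major", 5))
  expect_equal(f2$percent, c(100, 0, 0))
  expect_error(cohort_genotype_freq(character(0)), "empty")
  expect_error(cohort_genotype_freq("wildtype"), "unknown")
  set.seed(51)
  for (i in 1:10) {
    g <- sample(c("hom_major", "het", "hom_minor"), sample(1:40, 1),
                replace = TRUE)
    f <- cohort_genotype_freq(g)
    expect_equal(f$count, c(sum(g == "hom_major"), sum(g == "het"),
                            sum(g == "hom_minor")))
  }
})

test_that("variant keys round-trip through the TSV and VCF interfaces", {
  v <- data.frame(chrom = "1", pos = c(100L, 200L), ref = c("C", "G"),
                  alt = c("A", "T"), sample_id = "s1", genotype = c("AC", "TT"),
                  zygosity = c("het", "hom_alt"), depth = c(80L, 90L),
                  confidence = "high", gene = NA_character_,
                  rsid = NA_character_, hgvs_g = c("g.100C>A", "g.200G>T"),
                  key = c("1:100:A", "1:200:T"), stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, tsv)
  expect_equal(read_variant_keys(tsv), v$key)
  if (requireNamespace("vcfR", quietly = TRUE)) {
    vcf <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(v, vcf)
    expect_equal(read_variant_keys(vcf), v$key)
  }
})
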