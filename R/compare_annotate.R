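#' Tumor-normal genotype-difference (LOH candidate) detection
#'
#' Compares the genotype calls of a patient's normal (leukocyte) and tumor
#' samples at positions confidently called in both (by default depth strictly
#' above 50 in both samples) and reports every position where the unordered
#' allele pairs differ. A difference is classified `loh_or_hom` when the
#' normal is heterozygous and the tumor homozygous for one of the normal's two
#' alleles — the read-count signature of loss of heterozygosity, which is
#' indistinguishable from true homozygosity (or hemizygosity) without copy
#' number information; anything else is `other_diff`.
#'
#' @param normal_calls,tumor_calls `genotype_calls` data.frames for the two
#'   tissues of one patient.
#' @param patient Patient identifier.
#' @param min_depth Both samples must have depth strictly greater than this
#'   (default 50).
#' @return A `loh_candidates` data.frame: `patient`, `chrom`, `pos`, `gene`
#'   (when available), `ref`, `normal_genotype`, `tumor_genotype`,
#'   `normal_depth`, `tumor_depth`, `interpretation`.
#' @export
compare_tumor_normal <- function(normal_calls, tumor_calls, patient = "A",
                                 min_depth = 50L) {
  key <- c("chrom", "pos")
  m <- merge(as.data.frame(normal_calls), as.data.frame(tumor_calls),
             by = key, suffixes = c(".n", ".t"))
  m <- m[m$depth.n > min_depth & m$depth.t > min_depth, , drop = FALSE]
  gset <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2))
  differ <- gset(m$a1.n, m$a2.n) != gset(m$a1.t, m$a2.t)
  m <- m[differ, , drop = FALSE]
  loh <- m$zygosity.n == "het" &
    m$a1.t == m$a2.t &
    (m$a1.t == m$a1.n | m$a1.t == m$a2.n)
  gene <- if ("gene.n" %in% names(m)) m$gene.n else rep(NA_character_, nrow(m))
  structure(data.frame(patient = rep(patient, nrow(m)),
                       chrom = m$chrom, pos = m$pos, gene = gene,
                       ref = as.character(m$ref.n),
                       normal_genotype = m$genotype.n,
                       tumor_genotype = m$genotype.t,
                       normal_depth = m$depth.n, tumor_depth = m$depth.t,
                       interpretation = ifelse(loh, "loh_or_hom", "other_diff"),
                       stringsAsFactors = FALSE),
            class = c("loh_candidates", "data.frame"))
}

#' Pairwise overlap statistics of two variant sets
#'
#' Partitions two variant key sets into exclusive and shared counts and
#' reports the overlap percentage with the union as denominator:
#' `100 * both / (only_a + only_b + both)`, rounded half-up to one decimal.
#'
#' @param set_a,set_b Character vectors of variant keys (`chrom:pos:alt`).
#' @return An `overlap_stats` list: `only_a`, `only_b`, `both`, `percent`.
#' @examples
#' pairwise_overlap(c("1:10:A", "1:20:C"), c("1:20:C", "2:5:G"))$percent  # 33.3
#' overlap_stats(1924, 1517, 829)$percent                                # 19.4
#' @export
pairwise_overlap <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  both <- sum(a %in% b)
  overlap_stats(length(a) - both, length(b) - both, both)
}

#' @rdname pairwise_overlap
#' @param only_a,only_b,both Partition counts (exclusive to each set, shared).
#' @export
overlap_stats <- function(only_a, only_b, both) {
  tot <- only_a + only_b + both
  structure(list(only_a = only_a, only_b = only_b, both = both,
                 percent = if (tot == 0) 0 else
                   round_half_up(100 * both / tot, 1)),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("Overlap: %d | shared %d | %d  (%.1f%%)\n",
              x$only_a, x$both, x$only_b, x$percent))
  invisible(x)
}

#' Venn region counts for up to four variant sets
#'
#' Counts the elements of every non-empty membership pattern among 2-4 named
#' sets; region counts sum to the size of the union.
#'
#' @param sets A named list of 2-4 character vectors of variant keys.
#' @return A data.frame with one row per membership pattern: one logical
#'   column per set, `pattern` (e.g. `"1100"`), and `count`.
#' @export
venn_counts <- function(sets) {
  n <- length(sets)
  if (n < 2L || n > 4L)
    stop("venn_counts: between 2 and 4 sets are supported", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_len(n))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  pat <- expand.grid(rep(list(c(TRUE, FALSE)), n))[-(2^n), , drop = FALSE]
  names(pat) <- names(sets)
  pat <- pat[do.call(order, lapply(rev(seq_len(n)), function(i) -pat[[i]])), ,
             drop = FALSE]
  pattern_str <- apply(pat, 1, function(r) paste(as.integer(r), collapse = ""))
  elem_pat <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  counts <- vapply(pattern_str, function(p) sum(elem_pat == p), integer(1))
  out <- cbind(pat, pattern = pattern_str, count = unname(counts))
  rownames(out) <- NULL
  out
}

#' Load an annotation table (dbSNP or GWAS-catalog snapshot)
#'
#' Reads a user-supplied TSV with columns `rsid`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, and optionally `trait` or `gene`. Duplicate `(chrom, pos,
#' alt)` keys are a load error.
#'
#' @param path TSV path.
#' @return An `annotation_table` data.frame with a precomputed `key` column.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("rsid", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("read_annotation_table: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$key <- sprintf("%s:%d:%s", df$chrom, df$pos, df$alt)
  if (anyDuplicated(df$key))
    stop("read_annotation_table: duplicate (chrom, pos, alt) keys: ",
         df$key[duplicated(df$key)][1], call. = FALSE)
  structure(df, class = c("annotation_table", "data.frame"))
}

#' Annotate variants against a known-SNP table
#'
#' Matches variant records against an annotation table. Matching is
#' allele-aware by default — a variant is "known" only when its alternate
#' allele matches the table entry at that position — with position-only
#' matching available.
#'
#' @param variants A `variant_records` data.frame.
#' @param table An `annotation_table` from [read_annotation_table()].
#' @param by `"allele"` (match on chrom, pos and alt) or `"position"`.
#' @return The variants with `rsid` filled for matches and a logical `known`
#'   column; attribute `annotation_tally` holds known/novel counts.
#' @export
annotate_known <- function(variants, table, by = c("allele", "position")) {
  by <- match.arg(by)
  if (by == "allele") {
    idx <- match(variants$key, table$key)
  } else {
    idx <- match(sprintf("%s:%d", variants$chrom, variants$pos),
                 sprintf("%s:%d", table$chrom, table$pos))
  }
  variants$rsid <- ifelse(is.na(idx), NA_character_, table$rsid[idx])
  variants$known <- !is.na(idx)
  if ("trait" %in% names(table))
    variants$trait <- ifelse(is.na(idx), NA_character_, table$trait[idx])
  attr(variants, "annotation_tally") <- c(known = sum(variants$known),
                                          novel = sum(!variants$known))
  variants
}

#' Gene-level SNP presence summary
#'
#' For a list of genes of interest (for instance tumor-associated antigen
#' genes), flags each gene carrying at least one SNP in any sample and reports
#' the percentage of listed genes hit, rounded half-up to one decimal.
#'
#' @param variants A `variant_records` data.frame (all samples pooled) with a
#'   `gene` column.
#' @param genes Character vector of gene names.
#' @return A list: `table` (data.frame `gene`, `n_snps`, `has_snp`),
#'   `n_genes`, `n_with_snp`, `percent`.
#' @examples
#' v <- data.frame(gene = c("G1", "G1", "G2"))
#' gene_summary(v, c("G1", "G2", "G3"))$percent   # 66.7
#' @export
gene_summary <- function(variants, genes) {
  if (length(genes) == 0L)
    stop("gene_summary: empty gene list", call. = FALSE)
  n_snps <- vapply(genes, function(g)
    sum(!is.na(variants$gene) & variants$gene == g), integer(1))
  has <- n_snps > 0L
  list(table = data.frame(gene = genes, n_snps = unname(n_snps),
                          has_snp = unname(has), stringsAsFactors = FALSE),
       n_genes = length(genes),
       n_with_snp = sum(has),
       percent = round_half_up(100 * sum(has) / length(genes), 1))
}

#' Read a plain-text gene list
#'
#' One gene name per line; `#` comment lines and blank lines are skipped.
#'
#' @param path File path.
#' @return Character vector of gene names.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a haplotype definition
#'
#' TSV with columns `rsid`, `minor`, `major` giving, in order, the sites of a
#' haplotype and their minor/major alleles.
#'
#' @param path TSV path.
#' @return A `haplotype_def` data.frame.
#' @export
read_haplotype_def <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("rsid", "minor", "major") %in% names(df)))
    stop("read_haplotype_def: need columns rsid, minor, major", call. = FALSE)
  if (any(df$minor == df$major))
    stop("read_haplotype_def: minor and major alleles must differ", call. = FALSE)
  structure(df, class = c("haplotype_def", "data.frame"))
}

#' Encode a sample's genotypes as a binary minor/major haplotype string
#'
#' For each site of the definition (in order): `1` when the sample is
#' homozygous for the minor allele, `0` when homozygous for the major allele.
#' No phasing is attempted: if any site is heterozygous the result is
#' `"unphased"`, and if any site carries an allele not listed in the
#' definition it is `"inconsistent"`.
#'
#' @param genotypes A data.frame with columns `rsid`, `a1`, `a2` (one row per
#'   genotyped site of the sample).
#' @param def A `haplotype_def` (columns `rsid`, `minor`, `major`).
#' @return A string such as `"1100"`, or `"unphased"` / `"inconsistent"`.
#' @examples
#' def <- data.frame(rsid = c("rs660118", "rs679581", "rs754532", "rs735942"),
#'                   minor = c("C", "C", "G", "A"),
#'                   major = c("G", "T", "A", "G"))
#' gt <- data.frame(rsid = def$rsid,
#'                  a1 = c("C", "C", "A", "G"), a2 = c("C", "C", "A", "G"))
#' encode_haplotype(gt, def)   # "1100"
#' @export
encode_haplotype <- function(genotypes, def) {
  idx <- match(def$rsid, genotypes$rsid)
  if (anyNA(idx))
    stop("encode_haplotype: no genotype call for site(s): ",
         paste(def$rsid[is.na(idx)], collapse = ", "), call. = FALSE)
  a1 <- genotypes$a1[idx]
  a2 <- genotypes$a2[idx]
  if (any(a1 != a2)) return("unphased")
  if (any(a1 != def$minor & a1 != def$major)) return("inconsistent")
  paste(as.integer(a1 == def$minor), collapse = "")
}

#' Cohort genotype frequencies
#'
#' Tabulates a cohort's genotype classes and reports percentages rounded
#' half-up to the nearest whole percent.
#'
#' @param genotypes Character vector with entries `"hom_major"`, `"het"`,
#'   `"hom_minor"`.
#' @return A data.frame with `genotype`, `count`, `percent` (rows in the
#'   order hom_major, het, hom_minor).
#' @examples
#' cohort_genotype_freq(rep(c("hom_major", "het", "hom_minor"), c(7, 2, 1)))
#' @export
cohort_genotype_freq <- function(genotypes) {
  if (length(genotypes) == 0L)
    stop("cohort_genotype_freq: empty cohort", call. = FALSE)
  lv <- c("hom_major", "het", "hom_minor")
  bad <- setdiff(unique(genotypes), lv)
  if (length(bad))
    stop("cohort_genotype_freq: unknown genotype class '", bad[1], "'",
         call. = FALSE)
  cnt <- table(factor(genotypes, levels = lv))
  data.frame(genotype = lv, count = as.integer(cnt),
             percent = round_half_up(100 * as.integer(cnt) / length(genotypes)),
             stringsAsFactors = FALSE)
}

#' Read variant sets for overlap analysis
#'
#' Accepts the package's variant TSV (via [read_variant_table()]) or a VCF
#' (requires the `vcfR` package); returns the variant keys `chrom:pos:alt`
#' (first alternate allele).
#'
#' @param path Path to a `.tsv` variant table or a `.vcf` file.
#' @return Character vector of variant keys.
#' @export
read_variant_keys <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("read_variant_keys: reading VCF requires the 'vcfR' package",
           call. = FALSE)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    alt1 <- sub(",.*$", "", fix[, "ALT"])
    return(sprintf("%s:%s:%s", fix[, "CHROM"], fix[, "POS"], alt1))
  }
  read_variant_table(path)$key
}
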