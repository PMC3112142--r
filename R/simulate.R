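#' Generate a synthetic reference genome with exonic capture targets
#'
#' Builds a random reference sequence and a set of disjoint, sorted exonic
#' target regions whose total size matches `target_fraction` of the reference.
#' Genes are laid out in consecutive territories; exon lengths are drawn from
#' `exon_length_range` and rescaled so the realized target fraction tracks the
#' request. Optionally copies target segments into off-target sequence
#' ("decoys") so that reads from the duplicated loci become multi-mappers.
#'
#' All randomness comes from a single seeded stream; draws occur in a fixed,
#' documented order (reference bases, exon lengths, exon placement per gene,
#' decoy source/destination), so a given `sim_config` is byte-reproducible.
#'
#' @param config A [sim_config()].
#' @return An object of class `capture_reference`: a list with `seq` (character
#'   reference sequence), `seqname`, `targets` (a [GenomicRanges::GRanges] with
#'   `gene` and `exon` metadata), `decoys` (destination intervals of duplicated
#'   segments) and `config`.
#' @examples
#' ref <- generate_reference(sim_config(reference_length = 50000, n_genes = 4,
#'                                      n_read_pairs = 100))
#' sum(GenomicRanges::width(ref$targets)) / ref$config$reference_length
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$reference_length
  seq_chars <- sample(DNA_BASES, L, replace = TRUE)

  n_exons <- config$n_genes * config$exons_per_gene
  lens <- sample(seq(config$exon_length_range[1], config$exon_length_range[2]),
                 n_exons, replace = TRUE)
  desired <- round(config$target_fraction * L)
  lens <- pmax(30L, as.integer(round(lens * desired / sum(lens))))

  territory <- L %/% config$n_genes
  starts <- integer(n_exons)
  k <- config$exons_per_gene
  for (g in seq_len(config$n_genes)) {
    idx <- ((g - 1L) * k + 1L):(g * k)
    glens <- lens[idx]
    free <- territory - sum(glens)
    if (free < (k + 1L) * 20L)
      stop("generate_reference: target_fraction infeasible for the requested ",
           "exon geometry (gene territory of ", territory,
           " bp cannot hold ", sum(glens), " target bases)", call. = FALSE)
    w <- runif(k + 1L)
    gaps <- floor(w / sum(w) * free)
    s <- (g - 1L) * territory
    for (j in seq_len(k)) {
      s <- s + gaps[j]
      starts[idx[j]] <- s + 1L       # 1-based
      s <- s + glens[j]
    }
  }
  targets <- GenomicRanges::GRanges(
    seqnames = "sim1",
    ranges = IRanges::IRanges(start = starts, width = lens),
    gene = sprintf("GENE%03d", rep(seq_len(config$n_genes), each = k)),
    exon = rep(seq_len(k), config$n_genes)
  )
  targets <- GenomicRanges::sort(targets)

  # decoy duplications: copy a target segment into off-target sequence so the
  # source locus is no longer uniquely mappable
  decoys <- GenomicRanges::GRanges()
  if (config$decoy_duplications > 0L) {
    src_idx <- sample(length(targets), config$decoy_duplications, replace = TRUE)
    dec_start <- integer(0); dec_width <- integer(0); dec_src <- integer(0)
    occupied <- targets
    for (d in seq_len(config$decoy_duplications)) {
      e <- targets[src_idx[d]]
      wdt <- min(GenomicRanges::width(e), 500L)
      placed <- FALSE
      for (try in 1:100) {
        cand <- sample(L - wdt, 1L)
        cg <- GenomicRanges::GRanges("sim1", IRanges::IRanges(cand, width = wdt))
        if (length(GenomicRanges::findOverlaps(cg, occupied)) == 0L) {
          seq_chars[cand:(cand + wdt - 1L)] <-
            seq_chars[GenomicRanges::start(e):(GenomicRanges::start(e) + wdt - 1L)]
          dec_start <- c(dec_start, cand); dec_width <- c(dec_width, wdt)
          dec_src <- c(dec_src, src_idx[d])
          occupied <- c(occupied, cg)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        warning("generate_reference: could not place decoy ", d, call. = FALSE)
    }
    if (length(dec_start))
      decoys <- GenomicRanges::GRanges("sim1",
                                       IRanges::IRanges(dec_start, width = dec_width),
                                       source_exon = dec_src)
  }

  structure(list(seq = paste(seq_chars, collapse = ""),
                 seqname = "sim1",
                 targets = targets,
                 decoys = decoys,
                 config = config),
            class = "capture_reference")
}

#' Tile capture probes across target exons
#'
#' Places fixed-length oligonucleotide probes at a regular step across each
#' exon, alternating strand between consecutive probes (the sense/antisense
#' tiling used on capture microarrays). Exons whose regular tiling would yield
#' fewer than `min_probes_per_exon` probes are tiled more densely: probe starts
#' are respaced evenly so that the minimum count is met. Exons shorter than the
#' probe length are covered by probes extending symmetrically into flanking
#' sequence (disable with `allow_flank = FALSE`).
#'
#' @param targets A [GenomicRanges::GRanges] of target exons.
#' @param step Probe start spacing in bases (default 11).
#' @param probe_length Probe length in bases (default 50).
#' @param min_probes_per_exon Minimum probes per exon (default 20).
#' @param allow_flank Allow probes to extend past exon edges for short exons.
#' @return A `GRanges` of probes with alternating strand and a `probe_id`
#'   column; probe coordinates may extend past exon boundaries for short exons.
#' @examples
#' tg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, width = 500))
#' pr <- design_probes(tg)
#' length(pr)   # floor((500 - 50) / 11) + 1 = 41
#' @export
design_probes <- function(targets, step = 11L, probe_length = 50L,
                          min_probes_per_exon = 20L, allow_flank = TRUE) {
  stopifnot(step >= 1L, probe_length >= 1L, min_probes_per_exon >= 1L)
  if (length(targets) == 0L)
    return(GenomicRanges::GRanges())
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    w <- GenomicRanges::width(targets)[i]
    s <- GenomicRanges::start(targets)[i]
    if (w >= probe_length) {
      n_reg <- (w - probe_length) %/% step + 1L
      if (n_reg >= min_probes_per_exon) {
        starts <- s + step * (seq_len(n_reg) - 1L)
      } else {
        # small exon: tile more densely so the minimum count is met
        starts <- s + as.integer(round(seq(0, w - probe_length,
                                           length.out = min_probes_per_exon)))
      }
    } else {
      if (!allow_flank)
        stop("design_probes: exon ", i, " (", w, " bp at ",
             GenomicRanges::seqnames(targets)[i], ":", s,
             ") is shorter than the probe length and flanking is disabled",
             call. = FALSE)
      s0 <- max(1L, s - as.integer(ceiling((probe_length - w) / 2)))
      starts <- rep(s0, min_probes_per_exon)
    }
    n <- length(starts)
    out[[i]] <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(targets)[i],
      ranges = IRanges::IRanges(starts, width = probe_length),
      strand = rep(c("+", "-"), length.out = n),
      exon_index = i
    )
  }
  pr <- do.call(c, out)
  pr$probe_id <- sprintf("probe%06d", seq_along(pr))
  pr
}

#' Plant germline variants and tumor LOH events with known ground truth
#'
#' Samples variant positions uniformly within the target regions (plus an
#' optional off-target share), assigns each an alternate allele, a germline
#' zygosity (heterozygous with probability `het_fraction`, otherwise homozygous
#' alternate) and, for heterozygous sites, a tumor loss-of-heterozygosity event
#' with probability `loh_fraction`. LOH retains one of the two germline alleles
#' chosen uniformly, so the tumor may revert to homozygous reference.
#'
#' @param reference A `capture_reference` from [generate_reference()].
#' @param config A [sim_config()]; uses `snp_density`, `het_fraction`,
#'   `loh_fraction`, `off_target_snp_fraction` and a seed derived from
#'   `config$seed`.
#' @return A `ground_truth` data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `normal_a1`, `normal_a2`, `tumor_a1`, `tumor_a2`, `het`
#'   (germline heterozygous), `loh`, `on_target`.
#' @export
plant_variants <- function(reference, config = reference$config) {
  stopifnot(inherits(reference, "capture_reference"))
  if (config$snp_density <= 0)
    stop("plant_variants: snp_density must be positive", call. = FALSE)
  set.seed(child_seed(config$seed, 1L))

  tpos <- unlist(mapply(seq,
                        GenomicRanges::start(reference$targets),
                        GenomicRanges::end(reference$targets),
                        SIMPLIFY = FALSE), use.names = FALSE)
  n_on <- max(1L, round(config$snp_density * length(tpos) / 1000))
  pos_on <- sort(sample(tpos, min(n_on, length(tpos))))

  n_off <- round(config$off_target_snp_fraction * length(pos_on))
  pos_off <- integer(0)
  if (n_off > 0L) {
    offpool <- setdiff(seq_len(config$reference_length), tpos)
    pos_off <- sort(sample(offpool, min(n_off, length(offpool))))
  }
  pos <- c(pos_on, pos_off)
  on_target <- c(rep(TRUE, length(pos_on)), rep(FALSE, length(pos_off)))
  ord <- order(pos)
  pos <- pos[ord]; on_target <- on_target[ord]

  n <- length(pos)
  refb <- substring(reference$seq, pos, pos)
  alt_choice <- sample.int(3L, n, replace = TRUE)
  alt <- vapply(seq_len(n),
                function(i) setdiff(DNA_BASES, refb[i])[alt_choice[i]],
                character(1))
  het <- runif(n) < config$het_fraction
  normal_a1 <- ifelse(het, refb, alt)
  normal_a2 <- alt
  loh <- het & (runif(n) < config$loh_fraction)
  keep_first <- sample(c(TRUE, FALSE), n, replace = TRUE)
  tumor_a1 <- ifelse(loh, ifelse(keep_first, normal_a1, normal_a2), normal_a1)
  tumor_a2 <- ifelse(loh, tumor_a1, normal_a2)

  structure(data.frame(chrom = reference$seqname, pos = pos, ref = refb,
                       alt = alt, normal_a1 = normal_a1, normal_a2 = normal_a2,
                       tumor_a1 = tumor_a1, tumor_a2 = tumor_a2,
                       het = het, loh = loh, on_target = on_target,
                       stringsAsFactors = FALSE),
            class = c("ground_truth", "data.frame"))
}

# Apply one haplotype's alleles to the reference string.
haplotype_seq <- function(reference, pos, alleles) {
  x <- strsplit(reference$seq, "", fixed = TRUE)[[1]]
  x[pos] <- alleles
  paste(x, collapse = "")
}

#' Simulate paired-end capture-sequencing reads for one sample
#'
#' Draws fragments of outer length uniform in `insert_range`, anchored on
#' target bases except for an `off_target_fraction` of fragments placed
#' strictly outside the targets. Each fragment comes from one of the two
#' haplotypes of the requested tissue (uniformly), read 1 is the leading
#' `read_length` bases of the forward strand, read 2 the reverse complement of
#' the trailing bases (FR orientation). Per-base substitution errors occur at
#' `error_rate`; with probability `n_artifact_rate` a read receives three 'N'
#' calls (the ambiguous-call artifact the downstream QC removes).
#'
#' @param reference A `capture_reference`.
#' @param truth A `ground_truth` from [plant_variants()].
#' @param config A [sim_config()].
#' @param tissue `"normal"` or `"tumor"`: which genotype columns of `truth`
#'   the haplotypes carry.
#' @param sample_id Prefix for read names.
#' @param seed Seed for this sample's read stream (default derived from
#'   `config$seed` and tissue).
#' @return An object of class `read_set`: list with `pairs` (data.frame `id`,
#'   `seq1`, `seq2`, `qual1`, `qual2`) and `origin` (data.frame `id`, `start`
#'   1-based fragment start, `insert`, `on_target`, `hap`).
#' @export
simulate_reads <- function(reference, truth, config = reference$config,
                           tissue = c("normal", "tumor"),
                           sample_id = paste0("S_", tissue),
                           seed = NULL) {
  stopifnot(inherits(reference, "capture_reference"),
            inherits(truth, "ground_truth"))
  tissue <- match.arg(tissue)
  if (is.null(seed))
    seed <- child_seed(config$seed, if (tissue == "normal") 2L else 3L)
  set.seed(seed)

  rl <- config$read_length
  L <- nchar(reference$seq)
  n <- config$n_read_pairs
  if (config$insert_range[2] > L)
    stop("simulate_reads: maximum fragment length exceeds the reference",
         call. = FALSE)

  a1 <- if (tissue == "normal") truth$normal_a1 else truth$tumor_a1
  a2 <- if (tissue == "normal") truth$normal_a2 else truth$tumor_a2
  hap1 <- haplotype_seq(reference, truth$pos, a1)
  hap2 <- haplotype_seq(reference, truth$pos, a2)

  # draw order: inserts, on/off flags, anchors+offsets, off-target rejection,
  # haplotypes, error positions, error bases, artifact flags, artifact positions
  inserts <- sample(seq(config$insert_range[1], config$insert_range[2]),
                    n, replace = TRUE)
  on_flag <- runif(n) < (1 - config$off_target_fraction)

  tpos <- unlist(mapply(seq,
                        GenomicRanges::start(reference$targets),
                        GenomicRanges::end(reference$targets),
                        SIMPLIFY = FALSE), use.names = FALSE)
  start <- integer(n)
  n_on <- sum(on_flag)
  if (n_on > 0L) {
    anchors <- sample(tpos, n_on, replace = TRUE)
    offs <- floor(runif(n_on) * inserts[on_flag])
    start[on_flag] <- pmin(pmax(anchors - offs, 1L), L - inserts[on_flag] + 1L)
  }
  if (n_on < n) {
    # place off-target fragments uniformly over all positions disjoint from
    # the targets: pick an inter-target gap weighted by its number of valid
    # offsets for the fragment's length
    idx <- which(!on_flag)
    tgt <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(reference$targets),
                                            GenomicRanges::end(reference$targets)))
    gapsIR <- IRanges::gaps(tgt, start = 1L, end = L)
    gs <- IRanges::start(gapsIR)
    gw <- IRanges::width(gapsIR)
    for (len in sort(unique(inserts[idx]))) {
      jj <- idx[inserts[idx] == len]
      ok <- which(gw >= len)
      if (length(ok) == 0L)
        stop("simulate_reads: no off-target gap can hold a fragment of ",
             len, " bp (targets too dense)", call. = FALSE)
      w <- gw[ok] - len + 1L
      gsel <- ok[sample.int(length(ok), length(jj), replace = TRUE, prob = w)]
      start[jj] <- gs[gsel] + floor(runif(length(jj)) * (gw[gsel] - len + 1L))
    }
  }

  hap <- sample(1:2, n, replace = TRUE)
  frag_end <- start + inserts - 1L
  frag <- character(n)
  frag[hap == 1L] <- substring(hap1, start[hap == 1L], frag_end[hap == 1L])
  frag[hap == 2L] <- substring(hap2, start[hap == 2L], frag_end[hap == 2L])

  seq1 <- substring(frag, 1L, rl)
  seq2 <- revcomp_chr(substring(frag, inserts - rl + 1L, inserts))
  reads <- c(seq1, seq2)   # 1..n = mate 1, n+1..2n = mate 2

  # substitution errors
  if (config$error_rate > 0) {
    hit <- which(runif(2L * n * rl) < config$error_rate)
    if (length(hit)) {
      ridx <- (hit - 1L) %/% rl + 1L
      bidx <- (hit - 1L) %% rl + 1L
      old <- substring(reads[ridx], bidx, bidx)
      pick <- sample.int(3L, length(hit), replace = TRUE)
      for (j in seq_along(hit)) {
        nb <- setdiff(DNA_BASES, old[j])[pick[j]]
        substring(reads[ridx[j]], bidx[j], bidx[j]) <- nb
      }
    }
  }

  # ambiguous-call artifacts: three N substitutions in an affected read
  if (config$n_artifact_rate > 0) {
    art <- which(runif(2L * n) < config$n_artifact_rate)
    for (j in art) {
      p <- sample(rl, 3L)
      for (q in p) substring(reads[j], q, q) <- "N"
    }
  }

  ids <- sprintf("%s_%07d", sample_id, seq_len(n))
  qual <- strrep(rawToChar(as.raw(33L + config$base_quality)), rl)
  pairs <- data.frame(id = ids,
                      seq1 = reads[seq_len(n)],
                      seq2 = reads[n + seq_len(n)],
                      qual1 = qual, qual2 = qual,
                      stringsAsFactors = FALSE)
  origin <- data.frame(id = ids, start = start, insert = inserts,
                       on_target = on_flag, hap = hap,
                       stringsAsFactors = FALSE)
  structure(list(pairs = pairs, origin = origin,
                 sample_id = sample_id, tissue = tissue),
            class = "read_set")
}

#' Simulate a full tumor/leukocyte capture experiment
#'
#' Generates one shared reference and capture design, then for each patient an
#' independent germline variant set with tumor LOH events, and paired-end read
#' sets for the leukocyte (normal) and tumor tissues.
#'
#' @param config A [sim_config()].
#' @param patients Character vector of patient identifiers.
#' @return A list with `reference`, `truth` (per patient), `reads` (per
#'   sample), and a `sample_sheet` data.frame (`sample_id`, `patient`,
#'   `tissue`).
#' @export
simulate_experiment <- function(config = sim_config(), patients = c("A", "B")) {
  reference <- generate_reference(config)
  truth <- list(); reads <- list()
  sheet <- data.frame(sample_id = character(0), patient = character(0),
                      tissue = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(patients)) {
    p <- patients[i]
    pcfg <- config
    pcfg$seed <- child_seed(config$seed, 10L + i)
    truth[[p]] <- plant_variants(reference, pcfg)
    for (tis in c("normal", "tumor")) {
      sid <- paste0("patient", p, "_", if (tis == "normal") "leuko" else "tumor")
      reads[[sid]] <- simulate_reads(reference, truth[[p]], config,
                                     tissue = tis, sample_id = sid,
                                     seed = child_seed(config$seed,
                                                       100L + 10L * i +
                                                         (tis == "tumor")))
      sheet <- rbind(sheet, data.frame(sample_id = sid, patient = p,
                                       tissue = if (tis == "normal") "leukocyte" else "tumor",
                                       stringsAsFactors = FALSE))
    }
  }
  list(reference = reference, truth = truth, reads = reads,
       sample_sheet = sheet, config = config)
}

# ---- writers -----------------------------------------------------------------

#' Write simulator outputs in standard formats
#'
#' `write_reference_fasta()` writes the reference as FASTA; `write_targets_bed()`
#' and `write_probes_bed()` write 0-based half-open BED (probes carry a strand
#' column); `write_fastq_pairs()` writes the two mate FASTQ files (Phred+33);
#' `write_ground_truth()` writes the planted-variant table as TSV.
#'
#' @param reference A `capture_reference`.
#' @param path,prefix Output path (or path prefix for FASTQ pairs).
#' @return The written path(s), invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  dna <- Biostrings::DNAStringSet(stats::setNames(reference$seq, reference$seqname))
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @param gr A `GRanges` of targets or probes.
#' @export
write_targets_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$gene)) gr$gene else ".",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
write_probes_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = gr$probe_id,
                   score = 0L,
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @param reads A `read_set`.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_set"))
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    sq <- Biostrings::DNAStringSet(reads$pairs[[paste0("seq", m)]])
    names(sq) <- paste0(reads$pairs$id, "/", m)
    qu <- Biostrings::PhredQuality(reads$pairs[[paste0("qual", m)]])
    qsq <- Biostrings::QualityScaledDNAStringSet(sq, qu)
    Biostrings::writeQualityScaledXStringSet(qsq, filepath = paths[m])
  }
  invisible(paths)
}

#' @rdname write_reference_fasta
#' @param truth A `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param file1,file2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A data.frame with `id`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @export
read_fastq_pairs <- function(file1, file2) {
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file2))
  id1 <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  id2 <- sub("/[12]$", "", sub("\\s.*$", "", names(r2)))
  if (length(r1) != length(r2) || !all(id1 == id2))
    stop("read_fastq_pairs: mate files are not in matching order", call. = FALSE)
  data.frame(id = id1,
             seq1 = as.character(r1), seq2 = as.character(r2),
             qual1 = as.character(Biostrings::quality(r1)),
             qual2 = as.character(Biostrings::quality(r2)),
             stringsAsFactors = FALSE, row.names = NULL)
}
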