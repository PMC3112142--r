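#' Pipeline configuration
#'
#' Bundles the simulation (or input paths), every analysis threshold, and the
#' sample layout for an end-to-end run. Thresholds default to the package's
#' calibrated values: heterozygosity at minor fraction 0.20, calls below depth
#' 10 removed, high confidence above depth 50, tumor-normal comparison gated
#' at depth above 50 in both tissues, mismatch budget 3, fragment bounds
#' 100-500 bp inclusive.
#'
#' @param sim A [sim_config()] describing the synthetic experiment (the
#'   pipeline can also be driven stage-by-stage on user data via the
#'   individual functions).
#' @param patients Patient identifiers; each contributes a leukocyte and a
#'   tumor sample.
#' @param het_min_fraction,drop_below,high_above,compare_min_depth,max_mismatch
#'   Analysis thresholds (see the stage functions).
#' @param out_dir Output directory for [write_outputs()] (`NULL` = no files).
#' @param annotation Optional path to a known-SNP table
#'   ([read_annotation_table()]).
#' @param gene_list Optional character vector of genes for [gene_summary()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), patients = c("A", "B"),
                            het_min_fraction = 0.20, drop_below = 10L,
                            high_above = 50L, compare_min_depth = 50L,
                            max_mismatch = 3L, out_dir = NULL,
                            annotation = NULL, gene_list = NULL) {
  structure(list(sim = sim, patients = patients,
                 het_min_fraction = het_min_fraction,
                 drop_below = drop_below, high_above = high_above,
                 compare_min_depth = compare_min_depth,
                 max_mismatch = max_mismatch, out_dir = out_dir,
                 annotation = annotation, gene_list = gene_list),
            class = "pipeline_config")
}

#' Run the end-to-end capture-SNP pipeline on simulated data
#'
#' Simulates the experiment, then for every sample: ambiguous-call QC, unique
#' ungapped mapping, paired-end acceptance, target depth, strand-split pileup,
#' genotype calling and depth-tier filtering, variant emission; then per
#' patient the tumor-normal comparison, and across samples the pairwise
#' overlap and Venn statistics (plus optional known-SNP annotation and gene
#' summary). Every filter's input/output counts are recorded in the run log.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `experiment` (simulated inputs incl.
#'   ground truth), `samples` (per sample: `qc`, `tally`, `accepted` counts,
#'   `coverage`, `calls`, `variants`), `loh` (per patient), `overlap_table`,
#'   `venn`, `gene_summary`, `log` (data.frame of stage counts), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  exp <- simulate_experiment(config$sim, patients = config$patients)
  if (!all(c("leukocyte", "tumor") %in% exp$sample_sheet$tissue))
    stop("run_pipeline: sample sheet must pair tumor and leukocyte tissues",
         call. = FALSE)
  ref <- exp$reference
  targets <- ref$targets
  rl <- config$sim$read_length

  log_rows <- list()
  note <- function(sample, stage, n_in, n_out) {
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(sample = sample, stage = stage, n_in = n_in, n_out = n_out,
                 n_removed = n_in - n_out, stringsAsFactors = FALSE)
  }

  samples <- list()
  for (sid in exp$sample_sheet$sample_id) {
    rs <- exp$reads[[sid]]
    qc <- filter_ambiguous(rs$pairs)
    note(sid, "qc_ambiguous_n", qc$n_in, nrow(qc$kept))

    mp <- map_and_pair(qc$kept, ref, max_mismatch = config$max_mismatch,
                       insert_range = config$sim$insert_range,
                       read_length = rl)
    note(sid, "pair_acceptance", nrow(qc$kept), sum(mp$pair_table$reason == "ok"))

    track <- compute_depth(mp$accepted, targets, read_length = rl)
    covsum <- summarize_coverage(track, targets,
                                 read_count = nrow(mp$accepted),
                                 read_length = rl)
    on_tgt <- count_on_target(mp$accepted, targets, read_length = rl)
    enr <- enrichment_fold(on_tgt, max(nrow(mp$accepted), 1L),
                           sum(GenomicRanges::width(GenomicRanges::reduce(targets))),
                           config$sim$reference_length)

    pu <- build_pileup(mp$accepted, ref, targets)
    calls <- call_genotypes(pu, het_min_fraction = config$het_min_fraction,
                            high_above = config$high_above)
    kept <- confidence_filter(calls, drop_below = config$drop_below,
                              high_above = config$high_above)
    note(sid, "depth_filter", nrow(calls), nrow(kept))
    variants <- emit_variants(kept, sample_id = sid, targets = targets)
    note(sid, "variants_emitted", nrow(kept), nrow(variants))

    samples[[sid]] <- list(qc = qc, tally = mp$tally,
                           n_accepted_pairs = sum(mp$pair_table$reason == "ok"),
                           accepted = mp$accepted, depth_track = track,
                           coverage = covsum, on_target_reads = on_tgt,
                           enrichment_fold = enr,
                           calls = kept, variants = variants)
  }

  loh <- list()
  for (p in config$patients) {
    sheet <- exp$sample_sheet[exp$sample_sheet$patient == p, ]
    nsid <- sheet$sample_id[sheet$tissue == "leukocyte"]
    tsid <- sheet$sample_id[sheet$tissue == "tumor"]
    if (length(nsid) != 1L || length(tsid) != 1L)
      stop("run_pipeline: patient ", p, " lacks a tumor/leukocyte pair",
           call. = FALSE)
    loh[[p]] <- compare_tumor_normal(samples[[nsid]]$calls,
                                     samples[[tsid]]$calls,
                                     patient = p,
                                     min_depth = config$compare_min_depth)
  }

  keysets <- lapply(samples, function(s) s$variants$key)
  ids <- names(keysets)
  pairs <- utils::combn(ids, 2L)
  overlap_table <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    ov <- pairwise_overlap(keysets[[pairs[1, j]]], keysets[[pairs[2, j]]])
    data.frame(sample1 = pairs[1, j], sample2 = pairs[2, j],
               only_1 = ov$only_a, only_2 = ov$only_b, both = ov$both,
               overlap_percent = ov$percent, stringsAsFactors = FALSE)
  }))
  venn <- if (length(keysets) >= 2L && length(keysets) <= 4L)
    venn_counts(keysets) else NULL

  all_variants <- do.call(rbind, lapply(samples, function(s) s$variants))
  rownames(all_variants) <- NULL
  if (!is.null(config$annotation)) {
    tab <- read_annotation_table(config$annotation)
    all_variants <- annotate_known(all_variants, tab)
  }
  gs <- if (!is.null(config$gene_list))
    gene_summary(all_variants, config$gene_list) else NULL

  res <- structure(list(experiment = exp, samples = samples, loh = loh,
                        overlap_table = overlap_table, venn = venn,
                        all_variants = all_variants, gene_summary = gs,
                        log = do.call(rbind, log_rows), config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_outputs(res, config$out_dir)
  res
}

#' Write the pipeline's report bundle
#'
#' Emits, under `out_dir`: per-sample VCF and depth BEDGraph, a per-sample SNP
#' summary TSV (overall and target-gene counts, known counts when annotated),
#' the pairwise-overlap TSV, the tumor-normal candidate table (strand-split
#' layout), Venn region counts, the run log, and a machine-readable JSON
#' summary.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("write_outputs: cannot create output directory ", out_dir, call. = FALSE)
  paths <- character(0)
  w <- function(p) { paths <<- c(paths, p); p }

  for (sid in names(result$samples)) {
    s <- result$samples[[sid]]
    write_vcf(s$variants, w(file.path(out_dir, paste0(sid, ".vcf"))), sid)
    write_bedgraph(s$depth_track, w(file.path(out_dir, paste0(sid, ".bedgraph"))))
  }

  summ <- do.call(rbind, lapply(names(result$samples), function(sid) {
    v <- result$samples[[sid]]$variants
    known <- if ("known" %in% names(result$all_variants)) {
      av <- result$all_variants[result$all_variants$sample_id == sid, ]
      c(sum(av$known), sum(av$known & !is.na(av$gene)))
    } else c(NA_integer_, NA_integer_)
    data.frame(sample_id = sid,
               n_snps = nrow(v),
               n_snps_known = known[1],
               n_snps_target_genes = sum(!is.na(v$gene)),
               n_snps_target_genes_known = known[2],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(summ, w(file.path(out_dir, "snp_summary.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$overlap_table,
                     w(file.path(out_dir, "overlap.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  loh_all <- do.call(rbind, result$loh)
  rownames(loh_all) <- NULL
  utils::write.table(loh_all, w(file.path(out_dir, "loh_candidates.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$venn))
    utils::write.table(result$venn, w(file.path(out_dir, "venn_counts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$log, w(file.path(out_dir, "run_log.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  js <- list(samples = summ,
             overlap = result$overlap_table,
             loh_candidates = nrow(loh_all),
             coverage = lapply(result$samples, function(s)
               list(mean_fold = s$coverage$mean_fold,
                    fraction_covered = s$coverage$fraction_covered,
                    enrichment_fold = s$enrichment_fold)))
  if (!is.null(result$gene_summary))
    js$gene_summary_percent <- result$gene_summary$percent
  jsonlite::write_json(js, w(file.path(out_dir, "summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("capture-SNP pipeline result\n")
  cat(sprintf("  samples: %s\n", paste(names(x$samples), collapse = ", ")))
  for (sid in names(x$samples)) {
    s <- x$samples[[sid]]
    cat(sprintf("  %s: %d accepted pairs, mean fold %d, %d variants\n",
                sid, s$n_accepted_pairs, s$coverage$mean_fold,
                nrow(s$variants)))
  }
  nloh <- sum(vapply(x$loh, nrow, integer(1)))
  cat(sprintf("  tumor-normal genotype differences: %d\n", nloh))
  invisible(x)
}

#' Compare pipeline calls against the planted ground truth
#'
#' For parameter-recovery evaluation on simulated data: at every planted site
#' called in a sample, checks whether the called unordered allele pair equals
#' the planted genotype, and reports LOH detection against the planted LOH
#' events.
#'
#' @param result A `pipeline_result`.
#' @param min_depth Restrict genotype concordance to calls with depth at
#'   least this (default 50, the high-confidence regime).
#' @return A list with per-sample genotype concordance (`n_called`,
#'   `n_correct`, `rate`) and per-patient LOH recovery (`n_planted`,
#'   `n_detected`, `rate`, `false_candidates`).
#' @export
evaluate_against_truth <- function(result, min_depth = 50L) {
  exp <- result$experiment
  gt_pair <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2))
  genotype <- list()
  for (i in seq_len(nrow(exp$sample_sheet))) {
    sid <- exp$sample_sheet$sample_id[i]
    p <- exp$sample_sheet$patient[i]
    tis <- exp$sample_sheet$tissue[i]
    tr <- exp$truth[[p]]
    truth_a1 <- if (tis == "tumor") tr$tumor_a1 else tr$normal_a1
    truth_a2 <- if (tis == "tumor") tr$tumor_a2 else tr$normal_a2
    calls <- result$samples[[sid]]$calls
    m <- merge(data.frame(pos = tr$pos, truth = gt_pair(truth_a1, truth_a2)),
               data.frame(pos = calls$pos, called = gt_pair(calls$a1, calls$a2),
                          depth = calls$depth),
               by = "pos")
    m <- m[m$depth >= min_depth, ]
    genotype[[sid]] <- list(n_called = nrow(m),
                            n_correct = sum(m$truth == m$called),
                            rate = if (nrow(m)) mean(m$truth == m$called) else NA_real_)
  }
  loh <- list()
  for (p in unique(exp$sample_sheet$patient)) {
    tr <- exp$truth[[p]]
    cand <- result$loh[[p]]
    # planted LOH events where the tumor genotype actually differs from normal
    # (retaining, at depth, only sites confidently called in both samples)
    nsid <- exp$sample_sheet$sample_id[exp$sample_sheet$patient == p &
                                         exp$sample_sheet$tissue == "leukocyte"]
    tsid <- exp$sample_sheet$sample_id[exp$sample_sheet$patient == p &
                                         exp$sample_sheet$tissue == "tumor"]
    ncalls <- result$samples[[nsid]]$calls
    tcalls <- result$samples[[tsid]]$calls
    dn <- ncalls$depth[match(tr$pos, ncalls$pos)]
    dt <- tcalls$depth[match(tr$pos, tcalls$pos)]
    eligible <- tr$loh & !is.na(dn) & !is.na(dt) & dn > min_depth & dt > min_depth
    detected <- tr$pos[eligible] %in% cand$pos
    loh[[p]] <- list(n_planted = sum(eligible),
                     n_detected = sum(detected),
                     rate = if (sum(eligible)) mean(detected) else NA_real_,
                     false_candidates = sum(!cand$pos %in% tr$pos[tr$loh]))
  }
  list(genotype = genotype, loh = loh)
}
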