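#' Simulation configuration for a synthetic capture-resequencing experiment
#'
#' Bundles every knob of the synthetic-data generator: the reference and target
#' geometry, planted-variant parameters, tumor loss-of-heterozygosity (LOH)
#' rate, and the paired-end read model. Defaults describe a small but realistic
#' hybridization-capture experiment: 50 bp paired-end reads with outer fragment
#' lengths of 100-500 bp (the geometry of early Illumina capture studies), a
#' per-base substitution error rate of 0.5%, and a capture design placing about
#' 10% of a 500 kb reference into exonic target regions.
#'
#' @param reference_length Reference length in bases.
#' @param n_genes Number of simulated genes.
#' @param exons_per_gene Exons per gene; targets are exons.
#' @param exon_length_range Length-2 integer vector, exon length bounds (bases).
#'   Drawn lengths are rescaled so total target size matches `target_fraction`.
#' @param target_fraction Proportion of the reference covered by target exons.
#' @param snp_density Planted variants per kilobase of target sequence.
#' @param het_fraction Proportion of planted variants that are heterozygous in
#'   the germline (normal) genome.
#' @param loh_fraction Proportion of heterozygous sites converted to homozygous
#'   in the tumor (LOH); the retained allele is chosen uniformly.
#' @param off_target_snp_fraction Additional variants planted outside targets,
#'   as a fraction of the on-target count.
#' @param read_length Read length in bases (default 50).
#' @param insert_range Length-2 vector, outer fragment length bounds in bases
#'   (leftmost read start to rightmost mate end), default 100-500.
#' @param n_read_pairs Read pairs per sample.
#' @param error_rate Per-base substitution error probability.
#' @param n_artifact_rate Probability that a read is corrupted with 3 'N' calls
#'   (the ambiguous-call artifact removed by read QC).
#' @param off_target_fraction Proportion of fragments drawn strictly outside
#'   the target regions.
#' @param decoy_duplications Number of target segments copied into off-target
#'   sequence, creating multi-mapping reads.
#' @param base_quality Constant Phred quality written to FASTQ (Phred+33).
#' @param seed Integer seed; a given configuration is byte-reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(reference_length = 50000, n_genes = 4, n_read_pairs = 500)
#' cfg$target_fraction
#' @export
sim_config <- function(reference_length = 500000L,
                       n_genes = 24L,
                       exons_per_gene = 8L,
                       exon_length_range = c(100L, 400L),
                       target_fraction = 0.10,
                       snp_density = 2,
                       het_fraction = 0.65,
                       loh_fraction = 0.30,
                       off_target_snp_fraction = 0,
                       read_length = 50L,
                       insert_range = c(100L, 500L),
                       n_read_pairs = 20000L,
                       error_rate = 0.005,
                       n_artifact_rate = 0.01,
                       off_target_fraction = 0.10,
                       decoy_duplications = 2L,
                       base_quality = 30L,
                       seed = 1L) {
  cfg <- list(
    reference_length = as.integer(reference_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length_range = as.integer(exon_length_range),
    target_fraction = target_fraction,
    snp_density = snp_density,
    het_fraction = het_fraction,
    loh_fraction = loh_fraction,
    off_target_snp_fraction = off_target_snp_fraction,
    read_length = as.integer(read_length),
    insert_range = as.integer(insert_range),
    n_read_pairs = as.integer(n_read_pairs),
    error_rate = error_rate,
    n_artifact_rate = n_artifact_rate,
    off_target_fraction = off_target_fraction,
    decoy_duplications = as.integer(decoy_duplications),
    base_quality = as.integer(base_quality),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  props <- c("target_fraction", "het_fraction", "loh_fraction", "error_rate",
             "n_artifact_rate", "off_target_fraction", "off_target_snp_fraction")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("sim_config: '", p, "' must be a single proportion in [0, 1]", call. = FALSE)
  }
  if (cfg$reference_length < 1000L)
    stop("sim_config: reference_length must be at least 1000 bases", call. = FALSE)
  if (length(cfg$exon_length_range) != 2L || diff(cfg$exon_length_range) < 0)
    stop("sim_config: exon_length_range must be c(min, max) with min <= max", call. = FALSE)
  if (length(cfg$insert_range) != 2L || diff(cfg$insert_range) < 0)
    stop("sim_config: insert_range must be c(min, max) with min <= max", call. = FALSE)
  if (cfg$insert_range[1] < cfg$read_length)
    stop("sim_config: minimum fragment length must be >= read_length", call. = FALSE)
  if (cfg$read_length < 20L)
    stop("sim_config: read_length must be >= 20", call. = FALSE)
  if (cfg$n_genes < 1L || cfg$exons_per_gene < 1L || cfg$n_read_pairs < 1L)
    stop("sim_config: counts must be positive", call. = FALSE)
  # exon geometry must fit the genome
  max_exon_total <- cfg$exon_length_range[2] * cfg$exons_per_gene * cfg$n_genes
  if (cfg$reference_length < max_exon_total * cfg$target_fraction)
    stop("sim_config: reference too short for the requested exon geometry", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Capture-experiment simulation configuration\n")
  cat(sprintf("  reference: %d bp, %d genes x %d exons (target fraction %.3f)\n",
              x$reference_length, x$n_genes, x$exons_per_gene, x$target_fraction))
  cat(sprintf("  variants: %.2g / kb target, het %.2f, LOH %.2f\n",
              x$snp_density, x$het_fraction, x$loh_fraction))
  cat(sprintf("  reads: %d pairs x %d bp, fragments %d-%d bp, error %.3g, off-target %.2f\n",
              x$n_read_pairs, x$read_length, x$insert_range[1], x$insert_range[2],
              x$error_rate, x$off_target_fraction))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Derive a child seed for an independent stage stream; stays inside 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 97 + k) %% 2147483647)
}
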