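#' Configuration for the damage/repair forward simulator
#'
#' Bundles every tunable of the synthetic-data generator: genome geometry,
#' base composition, per-GG-site damage rate, strand-specific repair kinetics,
#' assay read emission, and RNA-seq noise. Defaults describe a small
#' mammalian-like study: a few hundred kilobases of ~42% GC sequence, genes of
#' 2-8 kb, a 4 h treatment-to-harvest interval, excised oligomers of 21-31 nt,
#' and 50 nt single-end damage reads.
#'
#' @param n_chromosomes Number of nuclear chromosomes.
#' @param chrom_length Length of each nuclear chromosome (bp).
#' @param n_genes Number of non-overlapping genes to place.
#' @param gene_length_range Integer vector of length 2, min/max gene length (bp).
#' @param gc_content Fraction of G+C in simulated sequence, in (0, 1].
#' @param expression_shape Gamma shape for per-gene expression levels
#'   (mean fixed at 1); small values give a wide dynamic range.
#' @param damage_rate Expected number of lesions per GG dinucleotide site
#'   (Poisson mean), uniform across the genome.
#' @param tcr_rate_coef Transcription-coupled repair rate per hour per unit
#'   expression, acting on the transcribed strand only.
#' @param gr_rate_ts,gr_rate_nts Global repair rate per hour on the transcribed
#'   / non-transcribed (and intergenic) strand.
#' @param T_hours Time from treatment to harvest, hours.
#' @param xr_len_range Excised-oligomer length range (nt), inclusive.
#' @param background_read_fraction Fraction of emitted reads drawn at uniform
#'   random genomic positions rather than from lesions.
#' @param n_reads_per_assay Reads emitted per assay per sample.
#' @param rnaseq_dispersion Negative-binomial size parameter (inverse
#'   dispersion; variance = mu + mu^2 / size). Large values approach Poisson
#'   counts.
#' @param rnaseq_library_size Expected RNA-seq reads per sample.
#' @param n_rnaseq_samples Number of RNA-seq replicates to emit.
#' @param damage_read_length Fixed damage-read length (nt).
#' @param xr_window_delta Width (hours) of the snapshot window before
#'   `T_hours` from which excision events are sampled.
#' @param mito_length Length of the small mitochondria-like chromosome (bp);
#'   0 disables it.
#' @param mapq_fail_fraction Fraction of emitted reads given a failing mapping
#'   quality (<= 20).
#' @param seed Master seed; every stochastic operation derives a labelled
#'   sub-stream from it.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 10, chrom_length = 50000, seed = 7)
#' cfg$damage_rate
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 300000,
                       n_genes = 60,
                       gene_length_range = c(2000, 8000),
                       gc_content = 0.42,
                       expression_shape = 0.6,
                       damage_rate = 0.5,
                       tcr_rate_coef = 0.1,
                       gr_rate_ts = 0.02,
                       gr_rate_nts = 0.02,
                       T_hours = 4,
                       xr_len_range = c(21, 31),
                       background_read_fraction = 0.05,
                       n_reads_per_assay = 50000,
                       rnaseq_dispersion = 10,
                       rnaseq_library_size = 1e6,
                       n_rnaseq_samples = 2,
                       damage_read_length = 50,
                       xr_window_delta = 0.25,
                       mito_length = 16000,
                       mapq_fail_fraction = 0,
                       seed = 1) {
  config <- list(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    n_genes = n_genes, gene_length_range = as.integer(gene_length_range),
    gc_content = gc_content, expression_shape = expression_shape,
    damage_rate = damage_rate, tcr_rate_coef = tcr_rate_coef,
    gr_rate_ts = gr_rate_ts, gr_rate_nts = gr_rate_nts,
    T_hours = T_hours, xr_len_range = as.integer(xr_len_range),
    background_read_fraction = background_read_fraction,
    n_reads_per_assay = n_reads_per_assay,
    rnaseq_dispersion = rnaseq_dispersion,
    rnaseq_library_size = rnaseq_library_size,
    n_rnaseq_samples = n_rnaseq_samples,
    damage_read_length = as.integer(damage_read_length),
    xr_window_delta = xr_window_delta,
    mito_length = as.integer(mito_length),
    mapq_fail_fraction = mapq_fail_fraction,
    seed = seed
  )
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

#' Validate a simulator configuration
#'
#' Checks every invariant the generator relies on (non-negative rates, sane
#' length ranges, feasible gene packing, fractions in range) and aborts with
#' the full list of violations.
#'
#' @param config A [sim_config()] object or bare list with the same fields.
#' @return `config`, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  problems <- sim_config_problems(config)
  if (length(problems) > 0) {
    abort(paste0("invalid simulator configuration:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  invisible(config)
}

sim_config_problems <- function(config) {
  p <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) p <<- c(p, msg)
  chk(is_count(config$n_chromosomes) && config$n_chromosomes >= 1,
      "n_chromosomes must be a positive integer")
  chk(is_count(config$chrom_length) && config$chrom_length >= 1000,
      "chrom_length must be an integer >= 1000")
  chk(is_count(config$n_genes), "n_genes must be a non-negative integer")
  chk(length(config$gene_length_range) == 2 &&
        config$gene_length_range[1] <= config$gene_length_range[2] &&
        config$gene_length_range[1] >= 100,
      "gene_length_range must be an increasing pair of lengths >= 100")
  chk(config$gc_content > 0 && config$gc_content <= 1,
      "gc_content must be in (0, 1]")
  chk(config$expression_shape > 0, "expression_shape must be > 0")
  for (r in c("damage_rate", "tcr_rate_coef", "gr_rate_ts", "gr_rate_nts")) {
    chk(is.numeric(config[[r]]) && config[[r]] >= 0,
        sprintf("%s must be >= 0", r))
  }
  chk(config$T_hours > 0, "T_hours must be > 0")
  chk(length(config$xr_len_range) == 2 &&
        config$xr_len_range[1] <= config$xr_len_range[2] &&
        config$xr_len_range[1] >= 1 &&
        config$xr_len_range[2] <= config$chrom_length,
      "xr_len_range must be within [1, chrom_length] and increasing")
  chk(config$background_read_fraction >= 0 &&
        config$background_read_fraction < 1,
      "background_read_fraction must be in [0, 1)")
  chk(is_count(config$n_reads_per_assay), "n_reads_per_assay must be a count")
  chk(config$rnaseq_dispersion > 0, "rnaseq_dispersion must be > 0")
  chk(config$rnaseq_library_size > 0, "rnaseq_library_size must be > 0")
  chk(is_count(config$n_rnaseq_samples) && config$n_rnaseq_samples >= 1,
      "n_rnaseq_samples must be a positive integer")
  chk(is_count(config$damage_read_length) && config$damage_read_length >= 10,
      "damage_read_length must be an integer >= 10")
  chk(config$xr_window_delta > 0 && config$xr_window_delta <= config$T_hours,
      "xr_window_delta must be in (0, T_hours]")
  chk(is_count(config$mito_length), "mito_length must be a count (0 disables)")
  chk(config$mapq_fail_fraction >= 0 && config$mapq_fail_fraction < 1,
      "mapq_fail_fraction must be in [0, 1)")
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single number")
  # packing feasibility: genes (with 1 bp spacers and 200 bp edge margins)
  # must fit on the nuclear chromosomes
  if (is_count(config$n_genes) && config$n_genes > 0 &&
      length(config$gene_length_range) == 2) {
    per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
    need <- per_chrom * (config$gene_length_range[2] + 1) + 400
    chk(need <= config$chrom_length,
        sprintf("infeasible packing: up to %d genes of <= %d bp cannot fit a %d bp chromosome",
                per_chrom, config$gene_length_range[2], config$chrom_length))
  }
  p
}
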