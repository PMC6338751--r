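# All genomic GG dinucleotide sites, strand-resolved.
# A site is recorded by the 0-based position of the 5' G *on the damaged
# strand*: for a + site with GG at plus-coordinates (p, p+1) this is p; for a
# - site (CC at plus-coordinates (p, p+1), i.e. GG on the reverse complement)
# the 5' G sits at the higher coordinate p+1.
gg_sites <- function(genome, chroms = NULL) {
  chroms <- chroms %||% names(genome)
  out <- lapply(chroms, function(chr) {
    plus <- Biostrings::start(Biostrings::matchPattern("GG", genome[[chr]]))
    minus <- Biostrings::start(Biostrings::matchPattern("CC", genome[[chr]]))
    bind_rows(
      tibble(chrom = chr, strand = "+", lesion_start = plus - 1L),
      tibble(chrom = chr, strand = "-", lesion_start = minus)
    )
  })
  bind_rows(out)
}

# Map point positions onto (non-overlapping) genes; NA when intergenic.
locate_in_genes <- function(positions, genes) {
  gene_idx <- rep(NA_integer_, nrow(positions))
  if (nrow(positions) > 0 && nrow(genes) > 0) {
    gr_genes <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    gr_pos <- GenomicRanges::GRanges(
      positions$chrom, IRanges::IRanges(positions$lesion_start + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(gr_pos, gr_genes,
                                      ignore.strand = TRUE, select = "first")
    gene_idx <- as.integer(ov)
  }
  gene_idx
}

lesion_rates <- function(strand_class, gene_idx, is_mito, genes, expression,
                         config) {
  gr_ts <- if ("gr_rate_ts" %in% names(genes)) genes$gr_rate_ts else
    rep(config$gr_rate_ts, nrow(genes))
  gr_nts <- if ("gr_rate_nts" %in% names(genes)) genes$gr_rate_nts else
    rep(config$gr_rate_nts, nrow(genes))
  e <- expression[genes$gene_id]
  rate <- rep(config$gr_rate_nts, length(strand_class))
  ts <- !is.na(gene_idx) & strand_class == "TS"
  nts <- !is.na(gene_idx) & strand_class == "NTS"
  rate[ts] <- config$tcr_rate_coef * e[gene_idx[ts]] + gr_ts[gene_idx[ts]]
  rate[nts] <- gr_nts[gene_idx[nts]]
  rate[is_mito] <- 0  # mitochondria lack nucleotide excision repair
  rate
}

#' Simulate lesion deposition and strand-specific repair kinetics
#'
#' Deposits Pt-d(GpG) lesions uniformly across the genome -- every GG site
#' receives a Poisson(`damage_rate`) number of lesions, independent of strand,
#' position and transcription -- then draws an exponential repair waiting time
#' per lesion with a strand-specific rate: `tcr_rate_coef * expression +
#' gr_rate_ts` on the transcribed strand of a gene, `gr_rate_nts` on the
#' non-transcribed strand and in intergenic sequence, and 0 on
#' mitochondria-like chromosomes (which lack excision repair). A lesion is
#' repaired by harvest when its waiting time is at most `T_hours`.
#'
#' Per-gene rate overrides are honoured via optional `gr_rate_ts` /
#' `gr_rate_nts` columns on `genes` (used e.g. to couple global repair to a
#' chromatin-openness covariate).
#'
#' @param genome [Biostrings::DNAStringSet] from [simulate_genome()].
#' @param genes Gene model tibble.
#' @param expression Named per-gene expression vector ([simulate_expression()]).
#' @param config A [sim_config()].
#' @param sample Sample label; also salts the random sub-stream so replicates
#'   are independent yet reproducible.
#' @param damage_multiplier Scales `damage_rate` for this sample (organ-level
#'   damage differences).
#' @return List with `lesions` (tibble: `lesion_id`, `chrom`, `strand`,
#'   `lesion_start`, `gene_id`, `strand_class`, `rate`, `repair_time`,
#'   `repaired_by_T`, `sample`) and `kinetics` (tibble per gene x strand:
#'   expected `total_damage`, `rate`, `repaired_fraction_by_T`,
#'   `instantaneous_repair_at_T`).
#' @export
simulate_lesions <- function(genome, genes, expression, config,
                             sample = "S1", damage_multiplier = 1) {
  validate_sim_config(config)
  if (nrow(genes) > 0 && !all(genes$gene_id %in% names(expression))) {
    abort("expression must be named and cover every gene")
  }
  if (any(expression < 0)) abort("expression must be >= 0")
  mito_chroms <- names(genome)[startsWith(names(genome), "chrM") |
                                 names(genome) == "MT"]
  d <- config$damage_rate * damage_multiplier

  lesions <- with_substream(config$seed, paste0("lesions:", sample), {
    sites <- gg_sites(genome)
    k <- rpois(nrow(sites), d)
    lesions <- sites[rep(seq_len(nrow(sites)), k), , drop = FALSE]
    gene_idx <- locate_in_genes(lesions, genes)
    strand_class <- assign_strand_class(
      lesions$strand,
      ifelse(is.na(gene_idx), "+", genes$strand[gene_idx]),
      in_gene = !is.na(gene_idx))
    is_mito <- lesions$chrom %in% mito_chroms
    rate <- lesion_rates(strand_class, gene_idx, is_mito, genes, expression,
                         config)
    repair_time <- rep(Inf, nrow(lesions))
    pos_rate <- rate > 0
    repair_time[pos_rate] <- rexp(sum(pos_rate), rate[pos_rate])
    lesions |>
      mutate(
        lesion_id = sprintf("L%08d", row_number()),
        gene_id = ifelse(is.na(gene_idx), NA_character_,
                         genes$gene_id[gene_idx]),
        strand_class = strand_class,
        rate = rate,
        repair_time = repair_time,
        repaired_by_T = repair_time <= config$T_hours,
        sample = sample
      ) |>
      select("lesion_id", "chrom", "strand", "lesion_start", "gene_id",
             "strand_class", "rate", "repair_time", "repaired_by_T", "sample")
  })

  kinetics <- repair_kinetics(genes, expression, config, damage_multiplier)
  list(lesions = lesions, kinetics = kinetics)
}

#' Expected damage and repair kinetics per gene and strand
#'
#' Closed-form truth for the simulator's kinetic model: expected total lesion
#' load `damage_rate * gg` per strand, the fraction repaired by harvest
#' `1 - exp(-rate * T)`, and the expected instantaneous excision rate at
#' harvest `total * rate * exp(-rate * T)` (the quantity an excision-repair
#' snapshot assay is proportional to).
#'
#' @inheritParams simulate_lesions
#' @return Tibble per gene x strand class.
#' @export
repair_kinetics <- function(genes, expression, config, damage_multiplier = 1) {
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), strand_class = character(),
                  total_damage = numeric(), rate = numeric(),
                  repaired_fraction_by_T = numeric(),
                  instantaneous_repair_at_T = numeric()))
  }
  gr_ts <- if ("gr_rate_ts" %in% names(genes)) genes$gr_rate_ts else
    rep(config$gr_rate_ts, nrow(genes))
  gr_nts <- if ("gr_rate_nts" %in% names(genes)) genes$gr_rate_nts else
    rep(config$gr_rate_nts, nrow(genes))
  d <- config$damage_rate * damage_multiplier
  e <- unname(expression[genes$gene_id])
  bind_rows(
    tibble(gene_id = genes$gene_id, strand_class = "TS",
           total_damage = d * genes$gg_ts,
           rate = config$tcr_rate_coef * e + gr_ts),
    tibble(gene_id = genes$gene_id, strand_class = "NTS",
           total_damage = d * genes$gg_nts,
           rate = gr_nts)
  ) |>
    mutate(
      repaired_fraction_by_T = 1 - exp(-.data$rate * config$T_hours),
      instantaneous_repair_at_T =
        .data$total_damage * .data$rate * exp(-.data$rate * config$T_hours)
    ) |>
    arrange(.data$gene_id, dplyr::desc(.data$strand_class))
}
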