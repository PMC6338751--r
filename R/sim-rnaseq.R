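#' Emit negative-binomial RNA-seq gene counts
#'
#' Counts are negative-binomial with mean proportional to
#' `expression * gene length`, scaled so each sample's expected total equals
#' `rnaseq_library_size`, with size parameter `rnaseq_dispersion`
#' (variance = mu + mu^2 / size). Genes with zero expression always get zero
#' counts. Deterministic given the configuration seed.
#'
#' @param expression Named per-gene expression vector.
#' @param genes Gene model tibble (uses `gene_id` and `length`).
#' @param config A [sim_config()].
#' @param samples Sample labels; default `rna_1 ... rna_n` per
#'   `config$n_rnaseq_samples`.
#' @return Long tibble (`gene_id`, `sample`, `count`).
#' @export
emit_rnaseq_counts <- function(expression, genes, config, samples = NULL) {
  validate_sim_config(config)
  samples <- samples %||% paste0("rna_", seq_len(config$n_rnaseq_samples))
  e <- unname(expression[genes$gene_id])
  mass <- e * genes$length
  mu <- if (sum(mass) > 0) config$rnaseq_library_size * mass / sum(mass)
  else rep(0, nrow(genes))
  with_substream(config$seed, "rnaseq", {
    out <- lapply(samples, function(s) {
      cnt <- integer(nrow(genes))
      pos <- mu > 0
      cnt[pos] <- rnbinom(sum(pos), mu = mu[pos],
                          size = config$rnaseq_dispersion)
      tibble(gene_id = genes$gene_id, sample = s, count = cnt)
    })
    bind_rows(out)
  })
}

#' Simulate a complete strand-resolved damage/repair study
#'
#' One call producing everything the downstream pipeline consumes, with known
#' truth: genome and gene model, per-gene expression, lesion histories under
#' the kinetic model, Damage-seq and XR-seq reads per sample, and RNA-seq
#' counts.
#'
#' @param config A [sim_config()].
#' @param samples Character vector of treated-sample labels (one Damage-seq
#'   and one XR-seq library each).
#' @param damage_multipliers Per-sample damage-rate multipliers (recycled).
#' @return List with `genome`, `genes`, `expression`, `lesions`, `kinetics`,
#'   `damage_reads`, `xr_reads`, `rnaseq` and the `config` used.
#' @export
simulate_dataset <- function(config = sim_config(), samples = "S1",
                             damage_multipliers = 1) {
  validate_sim_config(config)
  damage_multipliers <- rep_len(damage_multipliers, length(samples))
  gen <- simulate_genome(config)
  expression <- simulate_expression(gen$genes, config)
  lesions <- list(); damage_reads <- list(); xr_reads <- list()
  kinetics <- NULL
  for (i in seq_along(samples)) {
    s <- samples[i]
    sim <- simulate_lesions(gen$genome, gen$genes, expression, config,
                            sample = s, damage_multiplier = damage_multipliers[i])
    lesions[[s]] <- sim$lesions
    if (i == 1) kinetics <- sim$kinetics
    damage_reads[[s]] <- emit_damage_reads(sim$lesions, gen$genome, config,
                                           sample = s)
    xr_reads[[s]] <- emit_xr_reads(sim$lesions, gen$genome, config, sample = s)
  }
  list(
    genome = gen$genome, genes = gen$genes, expression = expression,
    lesions = bind_rows(lesions), kinetics = kinetics,
    damage_reads = bind_rows(damage_reads), xr_reads = bind_rows(xr_reads),
    rnaseq = emit_rnaseq_counts(expression, gen$genes, config),
    config = config
  )
}
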