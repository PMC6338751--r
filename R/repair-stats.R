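# Strand-asymmetry statistics.
#
# Under the kinetic model, damage remaining at harvest on the NTS is nearly
# the total induced damage (global repair removes a negligible share), while
# the TS has additionally lost the transcription-coupled share. The fraction
# of total TS damage removed by TCR by harvest is therefore estimated by
# 1 - Damage_TS / Damage_NTS on normalized counts.

#' TCR-fraction estimator
#'
#' Estimates the proportion of total induced damage on the transcribed strand
#' removed by transcription-coupled repair by harvest as
#' `1 - damage_ts / damage_nts`, valid when global repair removes a
#' negligible share of total damage. Values can be negative from sampling
#' noise and are reported unclipped (use `pmax(., 0)` for a clipped view);
#' `NA` where `damage_nts` is zero.
#'
#' @param damage_ts,damage_nts Normalized damage values (TS and NTS).
#' @return Numeric vector of estimates (at most 1).
#' @examples
#' tcr_fraction(0.5, 1)  # 0.5
#' @export
tcr_fraction <- function(damage_ts, damage_nts) {
  if (any(damage_ts < 0, na.rm = TRUE) || any(damage_nts < 0, na.rm = TRUE)) {
    abort("normalized damage values must be non-negative")
  }
  ifelse(damage_nts == 0, NA_real_, 1 - damage_ts / damage_nts)
}

#' Per-gene repair estimates from normalized matrices
#'
#' Averages normalized values across samples per (gene, strand) and derives
#' the TCR fraction (unclipped and clipped at 0) plus the TS/(TS+NTS) ratios
#' for damage and repair.
#'
#' @param normalized_damage,normalized_xr Results of [normalize_counts()].
#' @return Tibble of class `repair_estimates`, one row per gene:
#'   `damage_ts`, `damage_nts`, `xr_ts`, `xr_nts`, `tcr_fraction`,
#'   `tcr_fraction_clipped`, `damage_ratio`, `xr_ratio`.
#' @export
repair_estimates <- function(normalized_damage, normalized_xr) {
  avg <- function(df, prefix) {
    df |>
      group_by(.data$gene_id, .data$strand_class) |>
      summarise(value = mean(.data$normalized), .groups = "drop") |>
      mutate(strand_class = tolower(.data$strand_class)) |>
      tidyr::pivot_wider(names_from = "strand_class", values_from = "value",
                         names_prefix = paste0(prefix, "_"))
  }
  out <- inner_join(avg(normalized_damage, "damage"), avg(normalized_xr, "xr"),
                    by = "gene_id") |>
    mutate(
      tcr_fraction = tcr_fraction(.data$damage_ts, .data$damage_nts),
      tcr_fraction_clipped = pmax(.data$tcr_fraction, 0),
      damage_ratio = ts_ratio(.data$damage_ts, .data$damage_nts),
      xr_ratio = ts_ratio(.data$xr_ts, .data$xr_nts)
    )
  class(out) <- c("repair_estimates", class(out))
  out
}

#' @export
glance.repair_estimates <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    mean_tcr_fraction = mean(x$tcr_fraction, na.rm = TRUE),
    median_damage_ratio = median(x$damage_ratio, na.rm = TRUE),
    median_xr_ratio = median(x$xr_ratio, na.rm = TRUE)
  )
}

#' Stratify damage and repair by gene-expression quantile
#'
#' Ranks genes by expression, splits them into `n_bins` equal-count bins, and
#' summarises `log2(normalized + 1)` per bin for every (assay, strand class),
#' averaging replicates within gene first. Gene-wise Spearman correlations
#' between expression and each (assay, strand class) value accompany the
#' profile. Constant expression is flagged (`NA` correlations, stable-order
#' bins) rather than silently ranked.
#'
#' @param expression Tibble (`gene_id`, `expression`) or named vector.
#' @param normalized Named list of [normalize_counts()] results, e.g.
#'   `list(damage = ..., xr = ...)`.
#' @param n_bins Number of expression bins (>= 2).
#' @return Object of class `quantile_profile`: list with `bins` (per bin x
#'   assay x strand class mean log value), `correlations` (Spearman rho per
#'   assay x strand class), `gene_values`, and `n_bins`. [tidy()] returns the
#'   bins, [glance()] the correlations in one row, [autoplot()] the figure.
#' @export
quantile_stratify <- function(expression, normalized, n_bins = 10) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (!is.data.frame(expression)) {
    expression <- tibble(gene_id = names(expression),
                         expression = unname(expression))
  }
  assert_cols(expression, c("gene_id", "expression"), "expression")
  values <- purrr::imap(normalized, function(df, nm) {
    df |>
      group_by(.data$gene_id, .data$strand_class) |>
      summarise(value = mean(log2(.data$normalized + 1)), .groups = "drop") |>
      mutate(assay = nm)
  }) |> bind_rows()
  gene_values <- inner_join(values, expression, by = "gene_id")
  if (nrow(gene_values) == 0) abort("no genes shared between inputs")
  constant <- length(unique(gene_values$expression)) == 1
  if (constant) {
    warn("expression is constant across genes; bins use stable order and correlations are NA")
  }
  n_genes <- length(unique(gene_values$gene_id))
  if (n_genes < n_bins) abort("fewer genes than bins")

  binned <- gene_values |>
    group_by(.data$assay, .data$strand_class) |>
    arrange(.data$expression, .by_group = TRUE) |>
    mutate(bin = ntile(row_number(), n_bins)) |>
    ungroup()
  bins <- binned |>
    group_by(.data$assay, .data$strand_class, .data$bin) |>
    summarise(n_genes = n(),
              mean_expression = mean(.data$expression),
              mean_log_value = mean(.data$value), .groups = "drop")
  correlations <- gene_values |>
    group_by(.data$assay, .data$strand_class) |>
    summarise(
      rho = if (constant) NA_real_ else
        suppressWarnings(cor(.data$expression, .data$value,
                             method = "spearman")),
      .groups = "drop")
  structure(list(bins = bins, correlations = correlations,
                 gene_values = gene_values, n_bins = n_bins),
            class = "quantile_profile")
}

#' @export
tidy.quantile_profile <- function(x, ...) x$bins

#' @export
glance.quantile_profile <- function(x, ...) {
  wide <- x$correlations |>
    mutate(name = paste0("rho_", .data$assay, "_", tolower(.data$strand_class))) |>
    select("name", "rho") |>
    tidyr::pivot_wider(names_from = "name", values_from = "rho")
  dplyr::bind_cols(tibble(n_bins = x$n_bins,
                          n_genes = length(unique(x$gene_values$gene_id))),
                   wide)
}

#' @export
print.quantile_profile <- function(x, ...) {
  cat(sprintf("Expression-quantile profile: %d bins, %d genes\n", x$n_bins,
              length(unique(x$gene_values$gene_id))))
  print(x$correlations)
  invisible(x)
}

#' Relative damage across samples against a pseudo-reference
#'
#' Infers each sample's relative damage load as the median over genes of its
#' depth- and GG-adjusted count divided by a pseudo-reference (the per-gene
#' geometric mean of adjusted counts across samples, over genes positive in
#' every sample), rescaled so the sample mean is 1. Intended for raw NTS
#' Damage-seq counts, where repair removes a negligible share of damage.
#'
#' `library_sizes` must be a depth-proportional measure (e.g. total sequenced
#' reads): a genome-uniform damage change and a sequencing-depth change scale
#' filtered counts identically, so they are separable only through an
#' external depth measure. With it, doubling one sample's depth leaves its
#' relative damage unchanged.
#'
#' @param counts Long tibble (`gene_id`, `sample`, `count`) of raw NTS counts.
#' @param gg Named per-gene GG counts (NTS strand); optional -- it cancels in
#'   the ratio but is accepted for interface symmetry.
#' @param library_sizes Named per-sample depth measure; default all equal.
#' @return Tibble (`sample`, `relative_damage`), mean 1.
#' @export
relative_damage <- function(counts, gg = NULL, library_sizes = NULL) {
  assert_cols(counts, c("gene_id", "sample", "count"), "counts")
  samples <- sort(unique(counts$sample))
  if (length(samples) < 2) abort("relative damage needs at least 2 samples")
  lib <- library_sizes %||% setNames(rep(1, length(samples)), samples)
  if (!all(samples %in% names(lib))) {
    abort("library_sizes missing for some samples")
  }
  lib <- lib[samples] / geomean(lib[samples])
  counts <- as_tibble(counts) |>
    group_by(.data$gene_id, .data$sample) |>
    summarise(count = sum(.data$count), .groups = "drop")
  m <- counts_to_matrix(counts)[, samples, drop = FALSE]
  m <- sweep(m, 2, lib, "/")
  if (!is.null(gg)) {
    ids <- rownames(m)
    if (!all(ids %in% names(gg))) abort("gg missing for some genes")
    if (any(gg[ids] <= 0)) abort("gg must be positive")
    m <- m / gg[ids]
  }
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) abort("no gene has positive counts in every sample")
  ref <- apply(m[keep, , drop = FALSE], 1, geomean)
  med <- apply(m[keep, , drop = FALSE], 2, function(col) median(col / ref))
  tibble(sample = samples, relative_damage = unname(med / mean(med)))
}

#' GG-signature background contrast between genome compartments
#'
#' Evaluates [gg_signature_fraction()] separately on mitochondria-like and
#' nuclear chromosomes. A chance-level mitochondrial fraction against a high
#' nuclear fraction indicates the mitochondrial reads are background -- the
#' expected pattern for excision-repair assays, mitochondria lacking
#' nucleotide excision repair.
#'
#' @inheritParams gg_signature_fraction
#' @param mito_chroms Chromosome names treated as mitochondrial.
#' @return Tibble with one row per compartment (`mito`, `nuclear`):
#'   `n_reads`, `n_gg`, `fraction` (NA for an empty compartment).
#' @export
mito_background_contrast <- function(reads, genome, assay = c("damage", "xr"),
                                     mito_chroms = c("chrM", "MT")) {
  assay <- match.arg(assay)
  mito <- intersect(names(genome), mito_chroms)
  nuclear <- setdiff(names(genome), mito_chroms)
  bind_rows(
    mutate(gg_signature_fraction(reads, genome, assay, chroms = mito),
           compartment = "mito"),
    mutate(gg_signature_fraction(reads, genome, assay, chroms = nuclear),
           compartment = "nuclear")
  ) |>
    select("compartment", "n_reads", "n_gg", "fraction")
}
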