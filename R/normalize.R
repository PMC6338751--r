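# Library-size and target-density normalization.

counts_to_matrix <- function(counts, value_col = "count") {
  assert_cols(counts, c("gene_id", "sample", value_col), "counts")
  key <- if ("strand_class" %in% names(counts)) {
    paste(counts$gene_id, counts$strand_class, sep = "|")
  } else counts$gene_id
  wide <- tibble(key = key, sample = counts$sample,
                 value = counts[[value_col]]) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "value",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$key
  m
}

#' Median-of-ratios library size factors
#'
#' DESeq-style size factors: the pseudo-reference is the per-row geometric
#' mean across samples over rows with all-positive counts, and each sample's
#' factor is the median over those rows of count / pseudo-reference. Factors
#' are reported unscaled (identical samples get factor 1 automatically when
#' their counts match the pseudo-reference scale; a single sample gets 1).
#'
#' @param counts Long tibble (`gene_id`, optionally `strand_class`, `sample`,
#'   `count`) or a numeric matrix with samples in columns.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  if (ncol(m) == 1) return(setNames(1, colnames(m)))
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) {
    abort("no row has positive counts in every sample; consider adding a pseudocount")
  }
  ref <- apply(m[keep, , drop = FALSE], 1, geomean)
  sf <- apply(m[keep, , drop = FALSE], 2, function(col) median(col / ref))
  setNames(sf, colnames(m))
}

#' Normalize strand-resolved counts by depth and target density
#'
#' Divides each raw count by its sample's size factor and the gene-strand
#' target density: in `"gg"` mode the number of GG dinucleotides on the
#' matching strand (TS counts by `gg_ts`, NTS by `gg_nts`) -- the assays
#' target Pt-d(GpG), so GG content, not length, is the exposure; in
#' `"length"` mode the gene length in kb. Cells with a zero denominator are
#' dropped and tallied in the `dropped` attribute. The transformation is
#' exactly invertible: `normalized * size_factor * denominator` reproduces
#' the raw count.
#'
#' @param counts Strand count tibble ([build_count_matrix()]).
#' @param sf Named size-factor vector ([size_factors()]).
#' @param gene_model Gene model tibble ([annotate_genes()]).
#' @param mode `"gg"` or `"length"`.
#' @return Tibble `gene_id`, `strand_class`, `sample`, `count`, `denominator`,
#'   `size_factor`, `normalized`; attribute `dropped` counts removed cells.
#' @export
normalize_counts <- function(counts, sf, gene_model, mode = c("gg", "length")) {
  mode <- match.arg(mode)
  assert_cols(counts, c("gene_id", "strand_class", "sample", "count"),
              "counts")
  assert_cols(gene_model, c("gene_id", "gg_ts", "gg_nts", "length"),
              "gene_model")
  if (!all(counts$sample %in% names(sf))) {
    abort("size factors missing for some samples")
  }
  if (any(sf <= 0)) abort("size factors must be positive")
  denom <- gene_model |>
    select("gene_id", "gg_ts", "gg_nts", "length") |>
    tidyr::pivot_longer(c("gg_ts", "gg_nts"), names_to = "strand_class",
                        values_to = "gg") |>
    mutate(strand_class = ifelse(.data$strand_class == "gg_ts", "TS", "NTS"))
  out <- as_tibble(counts) |>
    inner_join(denom, by = c("gene_id", "strand_class")) |>
    mutate(
      denominator = if (mode == "gg") .data$gg else .data$length / 1000,
      size_factor = unname(sf[.data$sample])
    ) |>
    select(-"gg", -"length")
  dropped <- sum(out$denominator == 0)
  out <- out |>
    filter(.data$denominator > 0) |>
    mutate(normalized = .data$count / (.data$size_factor * .data$denominator))
  structure(out, dropped = dropped, mode = mode)
}

#' RPKM normalization
#'
#' Reads per kilobase of gene per million mapped reads:
#' `count / (length/1e3) / (sample_total/1e6)`.
#'
#' @param counts Long tibble (`gene_id`, `sample`, `count`).
#' @param gene_lengths Named vector of gene lengths (bp).
#' @return Input tibble with an `rpkm` column.
#' @export
rpkm <- function(counts, gene_lengths) {
  assert_cols(counts, c("gene_id", "sample", "count"), "counts")
  if (!all(counts$gene_id %in% names(gene_lengths))) {
    abort("gene_lengths missing for some genes")
  }
  if (any(gene_lengths <= 0)) abort("gene lengths must be positive")
  as_tibble(counts) |>
    group_by(.data$sample) |>
    mutate(total = sum(.data$count)) |>
    ungroup() |>
    mutate(rpkm = {
      if (any(.data$total == 0)) abort("sample with zero total counts")
      .data$count / (unname(gene_lengths[.data$gene_id]) / 1e3) /
        (.data$total / 1e6)
    }) |>
    select(-"total")
}

#' Strand ratio TS/(TS+NTS)
#'
#' The share of signal on the transcribed strand; bounded in \[0, 1\] and
#' invariant to any bias shared by the two strands of a gene (library size,
#' GG content, delivery efficiency, pull-down efficiency). `NA` when both
#' strands are zero.
#'
#' @param ts,nts Non-negative numeric vectors.
#' @return Numeric vector of ratios.
#' @examples
#' ts_ratio(5, 5)  # 0.5
#' @export
ts_ratio <- function(ts, nts) {
  if (any(ts < 0, na.rm = TRUE) || any(nts < 0, na.rm = TRUE)) {
    abort("ts and nts must be non-negative")
  }
  ifelse(ts + nts == 0, NA_real_, ts / (ts + nts))
}

#' Gene-level quality control
#'
#' Retains genes that (i) have expression in at least one RNA-seq sample,
#' (ii) are present in all three assays' tables, (iii) carry at least
#' `min_gg` GG dinucleotides on the TS or the NTS, (iv) are shorter than
#' `max_length` bp (strict), and (v) have at least `min_reads` reads in total
#' across samples in each assay (RNA-seq, Damage-seq, XR-seq separately).
#'
#' @param gene_model Gene model tibble.
#' @param rnaseq Long RNA-seq counts (`gene_id`, `sample`, `count`).
#' @param damage_counts,xr_counts Strand count tibbles.
#' @param min_gg,max_length,min_reads QC thresholds.
#' @return Tibble per gene: failure flags per criterion and overall `pass`
#'   (a gene passes iff it fails zero criteria).
#' @export
qc_filter <- function(gene_model, rnaseq, damage_counts, xr_counts,
                      min_gg = 10, max_length = 1e5, min_reads = 20) {
  assert_cols(gene_model, c("gene_id", "length", "gg_ts", "gg_nts"),
              "gene_model")
  tot <- function(df) {
    df |> group_by(.data$gene_id) |>
      summarise(total = sum(.data$count), .groups = "drop")
  }
  rna_tot <- tot(rnaseq)
  dmg_tot <- tot(damage_counts)
  xr_tot <- tot(xr_counts)
  expressed <- rnaseq |>
    group_by(.data$gene_id) |>
    summarise(expressed = any(.data$count > 0), .groups = "drop")
  gene_model |>
    select("gene_id", "length", "gg_ts", "gg_nts") |>
    left_join(expressed, by = "gene_id") |>
    left_join(rename(rna_tot, rna_total = "total"), by = "gene_id") |>
    left_join(rename(dmg_tot, dmg_total = "total"), by = "gene_id") |>
    left_join(rename(xr_tot, xr_total = "total"), by = "gene_id") |>
    mutate(
      fail_no_expression = !tidyr::replace_na(.data$expressed, FALSE),
      fail_unmatched_id = is.na(.data$rna_total) | is.na(.data$dmg_total) |
        is.na(.data$xr_total),
      fail_gg = !(.data$gg_ts >= min_gg | .data$gg_nts >= min_gg),
      fail_length = !(.data$length < max_length),
      fail_reads = tidyr::replace_na(.data$rna_total, 0) < min_reads |
        tidyr::replace_na(.data$dmg_total, 0) < min_reads |
        tidyr::replace_na(.data$xr_total, 0) < min_reads,
      pass = !(.data$fail_no_expression | .data$fail_unmatched_id |
                 .data$fail_gg | .data$fail_length | .data$fail_reads)
    ) |>
    select("gene_id", dplyr::starts_with("fail_"), "pass")
}
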