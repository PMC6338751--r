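# Epigenomic track aggregation and association.

#' Aggregate an interval signal track over genes
#'
#' Coverage-weighted mean intensity of track intervals over each gene's
#' territory, with uncovered bases contributing 0: the sum of
#' `overlap_width * intensity` divided by the territory width. Territory is
#' the gene body by default, or a strand-aware promoter window of
#' `promoter_window` bp either side of the TSS (gene start for `+` genes,
#' gene end for `-` genes), clipped to the chromosome.
#'
#' @param track Tibble (`chrom`, `start`, `end`, `intensity`), 0-based
#'   half-open, finite intensities.
#' @param genes Gene model tibble.
#' @param region_mode `"body"` or `"promoter"`.
#' @param promoter_window Half-width (bp) of the promoter window.
#' @param chrom_lengths Optional named lengths for clipping promoter windows.
#' @return Tibble (`gene_id`, `signal`); genes without overlap get 0.
#' @export
gene_track_signal <- function(track, genes, region_mode = c("body", "promoter"),
                              promoter_window = 1000, chrom_lengths = NULL) {
  region_mode <- match.arg(region_mode)
  assert_cols(track, c("chrom", "start", "end", "intensity"), "track")
  assert_cols(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  if (any(!is.finite(track$intensity))) abort("track intensities must be finite")
  if (any(track$start >= track$end) || any(track$start < 0)) {
    abort("malformed track intervals")
  }
  if (region_mode == "body") {
    regions <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                      start = genes$start, end = genes$end)
  } else {
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    start <- pmax(tss - promoter_window, 0)
    end <- tss + promoter_window
    if (!is.null(chrom_lengths)) {
      end <- pmin(end, unname(chrom_lengths[genes$chrom]))
    }
    regions <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                      start = as.integer(start), end = as.integer(end))
  }
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
  gr_trk <- GenomicRanges::GRanges(track$chrom,
                                   IRanges::IRanges(track$start + 1L,
                                                    track$end))
  ov <- GenomicRanges::findOverlaps(gr_reg, gr_trk)
  w <- GenomicRanges::width(IRanges::pintersect(
    gr_reg[S4Vectors::queryHits(ov)], gr_trk[S4Vectors::subjectHits(ov)]))
  contrib <- tibble(gene_id = regions$gene_id[S4Vectors::queryHits(ov)],
                    mass = w * track$intensity[S4Vectors::subjectHits(ov)]) |>
    group_by(.data$gene_id) |>
    summarise(mass = sum(.data$mass), .groups = "drop")
  regions |>
    left_join(contrib, by = "gene_id") |>
    mutate(signal = tidyr::replace_na(.data$mass, 0) /
             (.data$end - .data$start)) |>
    select("gene_id", "signal")
}

#' Correlate per-gene marker signals with damage/repair quantities
#'
#' Spearman correlation (rho, two-sided p, Benjamini-Hochberg adjusted p)
#' between each epigenomic marker and each damage/repair quantity over a gene
#' subset -- intended for genes whose expression is not perturbed by
#' treatment, so pre-existing chromatin profiles are interpretable.
#'
#' @param signals Long tibble (`gene_id`, `marker`, `signal`), e.g. stacked
#'   [gene_track_signal()] results.
#' @param targets Tibble with `gene_id` and one column per quantity
#'   (e.g. [repair_estimates()] columns plus expression).
#' @param gene_subset Optional character vector restricting the genes used.
#' @return Tibble (`marker`, `quantity`, `n`, `rho`, `p_value`, `p_adj`);
#'   `NA` statistics when fewer than 3 genes are available.
#' @export
marker_correlations <- function(signals, targets, gene_subset = NULL) {
  assert_cols(signals, c("gene_id", "marker", "signal"), "signals")
  assert_cols(targets, "gene_id", "targets")
  if (!is.null(gene_subset)) {
    signals <- filter(signals, .data$gene_id %in% gene_subset)
    targets <- filter(targets, .data$gene_id %in% gene_subset)
  }
  quantities <- setdiff(names(targets), "gene_id")
  grid <- tidyr::expand_grid(marker = unique(signals$marker),
                             quantity = quantities)
  out <- purrr::pmap(grid, function(marker, quantity) {
    df <- signals |>
      filter(.data$marker == !!marker) |>
      inner_join(select(targets, "gene_id", value = all_of(quantity)),
                 by = "gene_id") |>
      filter(!is.na(.data$signal), !is.na(.data$value))
    if (nrow(df) < 3) {
      return(tibble(marker = marker, quantity = quantity, n = nrow(df),
                    rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(df$signal, df$value, method = "spearman",
                                    exact = FALSE))
    tibble(marker = marker, quantity = quantity, n = nrow(df),
           rho = unname(ct$estimate), p_value = ct$p.value)
  }) |> bind_rows()
  mutate(out, p_adj = p.adjust(.data$p_value, method = "BH"))
}
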