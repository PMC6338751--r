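#' Count GG dinucleotides on one strand of a sequence
#'
#' Counts overlapping occurrences of the GG dinucleotide on the given strand
#' of a plus-strand sequence. On the minus strand this equals the number of
#' overlapping CC occurrences in the plus-strand sequence (GG on the reverse
#' complement). `N` bases never match, and counting is overlapping, so
#' `"GGG"` contains two GG sites.
#'
#' @param sequence Character vector of DNA sequences (plus-strand).
#' @param strand `"+"` or `"-"` (recycled against `sequence`).
#' @return Integer vector of counts.
#' @examples
#' count_gg("GGG", "+")   # 2
#' count_gg("CCCC", "-")  # 3
#' @export
count_gg <- function(sequence, strand = "+") {
  stopifnot(all(strand %in% c("+", "-")))
  if (length(sequence) == 0) return(integer())
  seqs <- Biostrings::DNAStringSet(toupper(sequence))
  gg <- Biostrings::vcountPattern("GG", seqs)
  cc <- Biostrings::vcountPattern("CC", seqs)
  strand <- rep_len(strand, length(sequence))
  ifelse(strand == "+", gg, cc)
}

#' Annotate gene intervals with strand-resolved GG content
#'
#' Computes, for each gene, the number of GG dinucleotide sites on its
#' transcribed strand (TS, the template strand, antisense to the mRNA) and its
#' non-transcribed strand (NTS, the coding strand), plus a mitochondrial flag
#' from the chromosome name. These per-strand GG counts are the normalization
#' denominators for Pt-d(GpG) damage and repair counts.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param genome A [Biostrings::DNAStringSet] of chromosome sequences.
#' @param mito_chroms Chromosome names treated as mitochondrial.
#' @return A tibble (the gene model): input columns plus `length`, `gg_ts`,
#'   `gg_nts`, `is_mito`.
#' @export
annotate_genes <- function(genes, genome, mito_chroms = c("chrM", "MT")) {
  assert_cols(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  if (nrow(genes) == 0) {
    return(mutate(as_tibble(genes), length = integer(), gg_ts = integer(),
                  gg_nts = integer(), is_mito = logical()))
  }
  if (!all(genes$chrom %in% names(genome))) {
    abort("genes reference chromosomes absent from the genome")
  }
  lens <- genome_lengths(genome)
  if (any(genes$start < 0 | genes$end > lens[genes$chrom] |
            genes$start >= genes$end)) {
    abort("gene intervals out of chromosome bounds or empty")
  }
  genes <- as_tibble(genes)
  seqs <- character(nrow(genes))
  for (chr in unique(genes$chrom)) {
    i <- which(genes$chrom == chr)
    at <- IRanges::IRanges(genes$start[i] + 1L, genes$end[i])
    seqs[i] <- as.character(Biostrings::extractAt(genome[[chr]], at))
  }
  gg_plus <- count_gg(seqs, "+")
  gg_minus <- count_gg(seqs, "-")
  genes |>
    mutate(
      length = .data$end - .data$start,
      # NTS = coding strand = the annotated gene strand; TS = template strand
      gg_nts = ifelse(.data$strand == "+", gg_plus, gg_minus),
      gg_ts = ifelse(.data$strand == "+", gg_minus, gg_plus),
      is_mito = .data$chrom %in% mito_chroms
    )
}

#' Classify a lesion strand relative to a gene
#'
#' The transcribed strand (TS) is the template strand, antisense to the mRNA:
#' a lesion is on the TS when its strand is *opposite* the gene's annotated
#' strand, and on the NTS when it matches. Positions outside the gene's
#' half-open interval are intergenic.
#'
#' @param lesion_strand,gene_strand Character vectors of `"+"`/`"-"`.
#' @param in_gene Logical vector; `FALSE` yields `"intergenic"`.
#' @return Character vector in `{"TS", "NTS", "intergenic"}`.
#' @examples
#' assign_strand_class("-", "+")  # TS
#' assign_strand_class("+", "+")  # NTS
#' @export
assign_strand_class <- function(lesion_strand, gene_strand, in_gene = TRUE) {
  n <- max(length(lesion_strand), length(gene_strand), length(in_gene))
  lesion_strand <- rep_len(lesion_strand, n)
  gene_strand <- rep_len(gene_strand, n)
  in_gene <- rep_len(in_gene, n)
  as.character(ifelse(!in_gene, "intergenic",
                      ifelse(lesion_strand == gene_strand, "NTS", "TS")))
}

check_nonoverlapping <- function(genes) {
  bad <- genes |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(ov = any(.data$start[-1] < .data$end[-n()]), .groups = "drop")
  any(bad$ov, na.rm = TRUE)
}

#' Build a strand-resolved count matrix from lesion calls
#'
#' Assigns each lesion call to the gene whose interval contains it, classifies
#' it as TS or NTS relative to that gene, and tallies counts per
#' (gene, strand class, sample). Calls outside every gene are tallied as
#' intergenic per sample; totals are conserved. Overlapping gene annotations
#' are refused unless `overlap_policy = "nearest_tss"`, which assigns a call
#' hitting several genes to the gene with the nearest transcription start.
#'
#' @param calls Tibble of lesion calls with columns `chrom`, `strand`,
#'   `lesion_start`, and optionally `sample` (defaults to `"S1"`).
#' @param genes Gene model from [annotate_genes()].
#' @param assay Label stored on the result (`"damage"` or `"xr"`).
#' @param overlap_policy `"error"` (default) or `"nearest_tss"`.
#' @return Tibble with columns `gene_id`, `strand_class`, `sample`, `count`
#'   covering the full gene x {TS, NTS} x sample grid, with attribute
#'   `totals` (per-sample tibble of assigned, intergenic and total calls)
#'   retrievable via [count_totals()], and attribute `assay`.
#' @export
build_count_matrix <- function(calls, genes, assay = "damage",
                               overlap_policy = c("error", "nearest_tss")) {
  overlap_policy <- match.arg(overlap_policy)
  assert_cols(calls, c("chrom", "strand", "lesion_start"), "calls")
  assert_cols(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  calls <- as_tibble(calls)
  if (!"sample" %in% names(calls)) calls$sample <- "S1"
  samples <- sort(unique(calls$sample))
  if (length(samples) == 0) samples <- "S1"

  if (nrow(genes) > 0 && check_nonoverlapping(genes) &&
      overlap_policy == "error") {
    abort("gene intervals overlap; rerun with overlap_policy = \"nearest_tss\"")
  }

  hits <- tibble(call = integer(), gene = integer())
  if (nrow(calls) > 0 && nrow(genes) > 0) {
    gr_genes <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    gr_calls <- GenomicRanges::GRanges(
      calls$chrom, IRanges::IRanges(calls$lesion_start + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(gr_calls, gr_genes, ignore.strand = TRUE)
    hits <- tibble(call = S4Vectors::queryHits(ov),
                   gene = S4Vectors::subjectHits(ov))
    if (overlap_policy == "nearest_tss" && nrow(hits) > 0) {
      tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
      hits <- hits |>
        mutate(dist = abs(calls$lesion_start[.data$call] - tss[.data$gene])) |>
        group_by(.data$call) |>
        slice_min(.data$dist, n = 1, with_ties = FALSE) |>
        ungroup() |>
        select(-"dist")
    }
  }

  assigned <- hits |>
    mutate(
      gene_id = genes$gene_id[.data$gene],
      sample = calls$sample[.data$call],
      strand_class = assign_strand_class(calls$strand[.data$call],
                                         genes$strand[.data$gene])
    ) |>
    count(.data$gene_id, .data$strand_class, .data$sample, name = "count")

  grid <- tidyr::expand_grid(gene_id = genes$gene_id,
                             strand_class = c("TS", "NTS"),
                             sample = samples)
  counts <- grid |>
    left_join(assigned, by = c("gene_id", "strand_class", "sample")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L))

  per_sample_assigned <- counts |>
    group_by(.data$sample) |>
    summarise(assigned = sum(.data$count), .groups = "drop")
  totals <- calls |>
    count(.data$sample, name = "total") |>
    tidyr::complete(sample = samples, fill = list(total = 0L)) |>
    left_join(per_sample_assigned, by = "sample") |>
    mutate(assigned = tidyr::replace_na(.data$assigned, 0L),
           intergenic = .data$total - .data$assigned)

  structure(counts, totals = totals, assay = assay,
            class = c("strand_counts", class(counts)))
}

#' Per-sample call totals of a strand count matrix
#'
#' @param counts Result of [build_count_matrix()].
#' @return Tibble with per-sample `total`, `assigned` and `intergenic` calls.
#' @export
count_totals <- function(counts) {
  attr(counts, "totals")
}
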