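# Small fixture configurations used across test files.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 1, chrom_length = 50000, n_genes = 8,
         gene_length_range = c(1500, 3000), n_reads_per_assay = 4000,
         mito_length = 8000, seed = 11),
    list(...))
  do.call(sim_config, args)
}

random_genome <- function(len = 20000, gc = 0.42, seed = 5, n_chrom = 2) {
  withr::with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(n_chrom), function(i)
      paste(sample(names(probs), len, TRUE, probs), collapse = ""),
      character(1))
    Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(n_chrom))))
  })
}

qc_toy <- function() {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    length = c(rep(5000L, 7), 100000L, 99999L, 5000L),
    gg_ts = c(rep(50L, 5), 9L, 10L, 50L, 50L, 50L),
    gg_nts = c(rep(60L, 5), 9L, 9L, 60L, 60L, 60L))
  rna <- tidyr::expand_grid(gene_id = genes$gene_id, sample = c("r1", "r2")) |>
    dplyr::mutate(count = 30L)
  rna$count[rna$gene_id == "g02"] <- 0L            # no expression
  dmg <- tidyr::expand_grid(gene_id = genes$gene_id,
                            strand_class = c("TS", "NTS"),
                            sample = c("d1", "d2")) |>
    dplyr::mutate(count = 10L)
  xr <- dmg
  xr$count[xr$gene_id == "g04"] <- c(5L, 5L, 5L, 4L)  # 19 total XR reads
  dmg <- dplyr::filter(dmg, gene_id != "g03")          # unmatched id
  list(genes = genes, rna = rna, dmg = dmg, xr = xr)
}
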