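random_dna <- function(len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
}

#' Simulate a small genome with non-overlapping, strand-balanced genes
#'
#' Draws iid sequence at the configured GC content, places `n_genes`
#' non-overlapping genes (alternating strands, so both orientations are
#' present) across the nuclear chromosomes with random intergenic gaps and a
#' 200 bp margin from chromosome ends, and appends one small
#' mitochondria-like chromosome (`chrM`) carrying no genes. Gene sequence is
#' redrawn until every gene carries at least 10 GG dinucleotides on each
#' strand, so all genes are usable damage targets. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a [Biostrings::DNAStringSet]) and `genes`
#'   (the annotated gene model tibble from [annotate_genes()]).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "genome", {
    chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
    chrs <- lapply(chrom_names, function(nm)
      random_dna(config$chrom_length, config$gc_content))
    names(chrs) <- chrom_names

    genes <- tibble(gene_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character())
    if (config$n_genes > 0) {
      gene_chrom <- chrom_names[((seq_len(config$n_genes) - 1) %%
                                   config$n_chromosomes) + 1]
      gene_len <- sample_int_range(config$gene_length_range[1],
                                   config$gene_length_range[2],
                                   config$n_genes)
      gene_strand <- rep(c("+", "-"), length.out = config$n_genes)
      rows <- list()
      margin <- 200L
      for (chr in chrom_names) {
        idx <- which(gene_chrom == chr)
        if (length(idx) == 0) next
        lens <- gene_len[idx]
        free <- config$chrom_length - 2L * margin - sum(lens) - length(idx)
        if (free < 0) abort("infeasible packing: genes exceed chromosome")
        gaps <- as.vector(stats::rmultinom(1, free,
                                           rep(1, length(idx) + 1)))
        starts <- margin + cumsum(c(0L, lens + 1L))[seq_along(idx)] +
          cumsum(gaps)[seq_along(idx)]
        rows[[chr]] <- tibble(
          gene_id = sprintf("gene_%04d", idx),
          chrom = chr,
          start = as.integer(starts),
          end = as.integer(starts + lens),
          strand = gene_strand[idx]
        )
      }
      genes <- arrange(bind_rows(rows), .data$gene_id)
    }

    # guarantee >= 10 GG per strand per gene by redrawing gene sequence
    if (nrow(genes) > 0) {
      for (i in seq_len(nrow(genes))) {
        chr <- genes$chrom[i]
        len <- genes$end[i] - genes$start[i]
        for (attempt in seq_len(100)) {
          seq_i <- substr0(chrs[[chr]], genes$start[i], genes$end[i])
          if (count_gg(seq_i, "+") >= 10 && count_gg(seq_i, "-") >= 10) break
          if (attempt == 100) {
            abort("could not draw a gene with >= 10 GG per strand; raise gc_content or gene length")
          }
          substr(chrs[[chr]], genes$start[i] + 1, genes$end[i]) <-
            random_dna(len, config$gc_content)
        }
      }
    }

    if (config$mito_length > 0) {
      chrs[["chrM"]] <- random_dna(config$mito_length, config$gc_content)
    }
    genome <- Biostrings::DNAStringSet(unlist(chrs))
    list(genome = genome, genes = annotate_genes(genes, genome))
  })
}

#' Simulate per-gene expression levels
#'
#' Gamma-distributed expression with mean 1 and the configured shape; small
#' shapes give the long-tailed dynamic range typical of RNA-seq.
#'
#' @param genes Gene model tibble.
#' @param config A [sim_config()].
#' @return Named numeric vector of expression levels, one per gene.
#' @export
simulate_expression <- function(genes, config) {
  validate_sim_config(config)
  with_substream(config$seed, "expression", {
    e <- rgamma(nrow(genes), shape = config$expression_shape,
                rate = config$expression_shape)
    setNames(e, genes$gene_id)
  })
}
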