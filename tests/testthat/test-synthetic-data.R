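test_that("genome simulation is deterministic and respects its contract", {
  cfg <- tiny_config()
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)

  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  write_genome(a$genome, fa1); write_genome(b$genome, fa2)
  expect_identical(readLines(fa1), readLines(fa2))

  # non-overlapping, strand-balanced, >= 10 GG per strand, mito flagged
  g <- a$genes |> dplyr::arrange(chrom, start)
  by_chrom <- split(g, g$chrom)
  for (df in by_chrom) {
    if (nrow(df) > 1) expect_true(all(df$start[-1] >= df$end[-nrow(df)]))
  }
  expect_setequal(unique(g$strand), c("+", "-"))
  expect_true(all(g$gg_ts >= 10 & g$gg_nts >= 10))
  expect_true("chrM" %in% names(a$genome))
  expect_false(any(g$is_mito))
})

test_that("stored GG counts match a brute-force scan, including pure-GC sequence", {
  cfg <- tiny_config(gc_content = 1.0, gene_length_range = c(500, 800),
                     chrom_length = 20000, n_genes = 4)
  gen <- simulate_genome(cfg)
  expect_false(grepl("[AT]", as.character(gen$genome[["chr1"]])))
  gs <- as.character(gen$genome)
  for (i in seq_len(nrow(gen$genes))) {
    seq_i <- substring(gs[gen$genes$chrom[i]], gen$genes$start[i] + 1,
                       gen$genes$end[i])
    plus <- oracle_count_gg(seq_i, "+")
    minus <- oracle_count_gg(seq_i, "-")
    if (gen$genes$strand[i] == "+") {
      expect_identical(gen$genes$gg_nts[i], plus)
      expect_identical(gen$genes$gg_ts[i], minus)
    } else {
      expect_identical(gen$genes$gg_nts[i], minus)
      expect_identical(gen$genes$gg_ts[i], plus)
    }
  }
})

test_that("zero genes yields a valid genome with an empty annotation", {
  cfg <- tiny_config(n_genes = 0)
  gen <- simulate_genome(cfg)
  expect_s4_class(gen$genome, "DNAStringSet")
  expect_equal(nrow(gen$genes), 0)
  expect_true(all(c("gene_id", "gg_ts", "gg_nts", "is_mito") %in%
                    names(gen$genes)))
})

test_that("infeasible gene packing is a configuration error", {
  expect_error(sim_config(n_genes = 50, chrom_length = 10000,
                          gene_length_range = c(2000, 3000)),
               "infeasible packing")
})

test_that("lesion counts follow the uniform Poisson damage model", {
  cfg <- tiny_config(damage_rate = 0.1, tcr_rate_coef = 0, gr_rate_ts = 0,
                     gr_rate_nts = 0, mito_length = 0)
  gen <- simulate_genome(cfg)
  e <- simulate_expression(gen$genes, cfg)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)

  # no repair at zero rates
  expect_false(any(sim$lesions$repaired_by_T))
  expect_true(all(sim$lesions$repair_time == Inf))

  # total lesions within 3 sigma of damage_rate * (number of GG sites)
  gs <- as.character(gen$genome)
  n_sites <- sum(vapply(gs, oracle_count_gg, integer(1), strand = "+")) +
    sum(vapply(gs, oracle_count_gg, integer(1), strand = "-"))
  expected <- cfg$damage_rate * n_sites
  expect_lt(abs(nrow(sim$lesions) - expected), 3 * sqrt(expected))

  # every lesion sits on a genuine GG site of the damaged strand
  idx <- sample.int(nrow(sim$lesions), 200)
  for (i in idx) {
    chrom <- sim$lesions$chrom[i]; p <- sim$lesions$lesion_start[i]
    if (sim$lesions$strand[i] == "+") {
      expect_identical(unname(substring(gs[chrom], p + 1, p + 2)), "GG")
    } else {
      expect_identical(unname(substring(gs[chrom], p, p + 1)), "CC")
    }
  }
})

test_that("saturating TCR repairs essentially all TS lesions of expressed genes", {
  cfg <- tiny_config(tcr_rate_coef = 50, gr_rate_ts = 0, gr_rate_nts = 0)
  gen <- simulate_genome(cfg)
  e <- setNames(rep(1, nrow(gen$genes)), gen$genes$gene_id)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  kin_ts <- dplyr::filter(sim$kinetics, strand_class == "TS")
  expect_true(all(kin_ts$repaired_fraction_by_T > 0.999))
  ts <- dplyr::filter(sim$lesions, strand_class == "TS")
  expect_gt(mean(ts$repaired_by_T), 0.999)
  nts <- dplyr::filter(sim$lesions, strand_class == "NTS")
  expect_false(any(nts$repaired_by_T))
})

test_that("unrepaired lesion loads are consistent with the closed-form kinetics", {
  cfg <- tiny_config(damage_rate = 1, tcr_rate_coef = 0.2, gr_rate_ts = 0.02,
                     gr_rate_nts = 0.02, chrom_length = 80000, n_genes = 10)
  gen <- simulate_genome(cfg)
  e <- simulate_expression(gen$genes, cfg)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  observed <- sim$lesions |>
    dplyr::filter(!is.na(gene_id), !repaired_by_T) |>
    dplyr::count(gene_id, strand_class, name = "unrepaired")
  truth <- sim$kinetics |>
    dplyr::mutate(expected = total_damage * (1 - repaired_fraction_by_T)) |>
    dplyr::left_join(observed, by = c("gene_id", "strand_class")) |>
    dplyr::mutate(unrepaired = dplyr::coalesce(unrepaired, 0L))
  expect_true(all(abs(truth$unrepaired - truth$expected) <=
                    3 * sqrt(truth$expected) + 1))
})

test_that("strand asymmetry: expressed genes keep less TS than NTS damage", {
  cfg <- tiny_config(damage_rate = 1, tcr_rate_coef = 0.3, gr_rate_ts = 0.01,
                     gr_rate_nts = 0.01)
  gen <- simulate_genome(cfg)
  e <- setNames(rep(2, nrow(gen$genes)), gen$genes$gene_id)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  kin <- sim$kinetics |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "strand_class",
                       values_from = "repaired_fraction_by_T")
  expect_true(all(kin$TS >= kin$NTS))
  load <- sim$lesions |>
    dplyr::filter(!is.na(gene_id), !repaired_by_T) |>
    dplyr::count(gene_id, strand_class) |>
    tidyr::pivot_wider(names_from = "strand_class", values_from = "n",
                       values_fill = 0)
  expect_lt(sum(load$TS), sum(load$NTS))
})

test_that("XR read lengths stay inside the configured oligomer range", {
  cfg <- tiny_config(damage_rate = 1, background_read_fraction = 0.2,
                     n_reads_per_assay = 3000)
  gen <- simulate_genome(cfg)
  e <- simulate_expression(gen$genes, cfg)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  xr <- emit_xr_reads(sim$lesions, gen$genome, cfg)
  lens <- xr$end - xr$start
  expect_true(all(lens >= 21 & lens <= 31))
})

test_that("RNA-seq emission is reproducible, silences zero-expression genes, and approaches Poisson at large size", {
  cfg <- tiny_config()
  gen <- simulate_genome(cfg)
  e <- simulate_expression(gen$genes, cfg)
  e[1] <- 0
  a <- emit_rnaseq_counts(e, gen$genes, cfg)
  b <- emit_rnaseq_counts(e, gen$genes, cfg)
  expect_identical(a, b)
  expect_true(all(dplyr::filter(a, gene_id == names(e)[1])$count == 0))

  # moment check in the large-size (Poisson) limit: 1e4 draws of one gene
  cfg2 <- tiny_config(rnaseq_dispersion = 1e6, rnaseq_library_size = 50 * 8)
  many <- emit_rnaseq_counts(setNames(rep(1, nrow(gen$genes)), gen$genes$gene_id),
                             gen$genes, cfg2,
                             samples = sprintf("s%04d", 1:1250))
  ratio <- many |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(r = stats::var(count) / mean(count)) |>
    dplyr::pull(r)
  expect_true(all(abs(ratio - 1) < 0.25))
})

test_that("the whole simulated dataset is reproducible from its seed", {
  cfg <- tiny_config(n_reads_per_assay = 1000)
  a <- simulate_dataset(cfg, samples = c("S1", "S2"))
  b <- simulate_dataset(cfg, samples = c("S1", "S2"))
  expect_identical(a$damage_reads, b$damage_reads)
  expect_identical(a$xr_reads, b$xr_reads)
  expect_identical(a$rnaseq, b$rnaseq)
  # different samples draw from different sub-streams
  s1 <- dplyr::filter(a$damage_reads, sample == "S1")
  s2 <- dplyr::filter(a$damage_reads, sample == "S2")
  expect_false(identical(s1$start, s2$start))
})
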