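test_that("tcr_fraction follows its definition and edge cases", {
  expect_equal(tcr_fraction(0.5, 1.0), 0.5)
  expect_equal(tcr_fraction(1.0, 1.0), 0.0)
  expect_true(is.na(tcr_fraction(0.2, 0)))
  expect_error(tcr_fraction(-1, 2), "non-negative")
  expect_lt(tcr_fraction(0.1, 0.5), 1)
})

test_that("tcr_fraction recovers the simulated TS repaired fraction", {
  # genes with known repaired fractions via expression = -log(1-f)/(k*T)
  f <- seq(0, 0.85, length.out = 60)
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 150000, n_genes = 60,
                    gene_length_range = c(3500, 3500), gc_content = 0.5,
                    damage_rate = 1.4, tcr_rate_coef = 0.25,
                    gr_rate_ts = 0, gr_rate_nts = 0, mito_length = 0,
                    seed = 21)
  gen <- simulate_genome(cfg)
  e <- setNames(-log(1 - f) / (cfg$tcr_rate_coef * cfg$T_hours),
                gen$genes$gene_id)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  counts <- sim$lesions |>
    dplyr::filter(!repaired_by_T, !is.na(gene_id)) |>
    dplyr::count(gene_id, strand_class) |>
    tidyr::pivot_wider(names_from = strand_class, values_from = n,
                       values_fill = 0)
  est <- dplyr::left_join(counts, gen$genes, by = "gene_id") |>
    dplyr::mutate(est = tcr_fraction(TS / gg_ts, NTS / gg_nts),
                  truth = f[match(gene_id, gen$genes$gene_id)])
  expect_lt(mean(abs(est$est - est$truth)), 0.1)
  expect_gt(cor(est$est, est$truth, method = "spearman"), 0.9)
})

test_that("xr read counts track instantaneous repair at harvest", {
  # heavy lesion loads per gene so the excision snapshot is rank-stable
  cfg <- tiny_config(damage_rate = 6, tcr_rate_coef = 0.1,
                     gr_rate_ts = 0.02, gr_rate_nts = 0.02,
                     chrom_length = 400000, n_genes = 30, gc_content = 0.5,
                     gene_length_range = c(8000, 8000),
                     n_reads_per_assay = 100000,
                     background_read_fraction = 0)
  gen <- simulate_genome(cfg)
  e <- simulate_expression(gen$genes, cfg)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  xr <- emit_xr_reads(sim$lesions, gen$genome, cfg)
  calls <- filter_xr_reads(xr, gen$genome)
  counts <- build_count_matrix(calls, gen$genes, assay = "xr") |>
    dplyr::filter(strand_class == "TS")
  truth <- dplyr::filter(sim$kinetics, strand_class == "TS")
  j <- dplyr::inner_join(tibble::as_tibble(counts), truth,
                         by = c("gene_id", "strand_class"))
  expect_gt(cor(j$count, j$instantaneous_repair_at_T, method = "spearman"),
            0.9)
})

test_that("quantile profiles are permutation invariant with near-equal bins", {
  cfg <- tiny_config(n_genes = 8)
  gen <- simulate_genome(cfg)
  e <- simulate_expression(gen$genes, cfg)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  calls <- dplyr::mutate(dplyr::filter(sim$lesions, !repaired_by_T),
                         sample = "S1")
  counts <- build_count_matrix(calls, gen$genes)
  nm <- normalize_counts(counts, size_factors(counts), gen$genes)
  expr_tbl <- tibble::tibble(gene_id = names(e), expression = unname(e))

  p1 <- quantile_stratify(expr_tbl, list(damage = nm), n_bins = 4)
  perm <- withr::with_seed(2, expr_tbl[sample.int(nrow(expr_tbl)), ])
  p2 <- quantile_stratify(perm, list(damage = nm), n_bins = 4)
  expect_equal(tidy(p1), tidy(p2))
  expect_equal(p1$correlations, p2$correlations)
  sizes <- tidy(p1)$n_genes
  expect_lte(max(sizes) - min(sizes), 1)

  expect_error(quantile_stratify(expr_tbl, list(damage = nm), n_bins = 1),
               "n_bins")
  expect_warning(
    const <- quantile_stratify(dplyr::mutate(expr_tbl, expression = 1),
                               list(damage = nm), n_bins = 4),
    "constant")
  expect_true(all(is.na(const$correlations$rho)))
})

test_that("relative damage is 1 for identical samples and exactly depth-invariant", {
  m <- withr::with_seed(3, matrix(rpois(400, 80) + 1, ncol = 4,
                                  dimnames = list(sprintf("g%03d", 1:100),
                                                  c("A", "B", "C", "D"))))
  m[, "B"] <- m[, "A"]; m[, "C"] <- m[, "A"]; m[, "D"] <- m[, "A"]
  long <- tibble::as_tibble(m, rownames = "gene_id") |>
    tidyr::pivot_longer(-gene_id, names_to = "sample", values_to = "count")
  rd <- relative_damage(long)
  expect_equal(rd$relative_damage, rep(1, 4))

  # doubling one sample's counts with a doubled library size changes nothing
  doubled <- dplyr::mutate(long, count = ifelse(sample == "B", count * 2L,
                                                count))
  rd2 <- relative_damage(doubled,
                         library_sizes = c(A = 1, B = 2, C = 1, D = 1))
  expect_equal(rd2$relative_damage, rd$relative_damage, tolerance = 1e-12)

  expect_error(relative_damage(dplyr::filter(long, sample == "A")),
               "2 samples")
})

test_that("mito contrast separates compartments and handles empties", {
  cfg <- tiny_config(damage_rate = 1, background_read_fraction = 0.05)
  gen <- simulate_genome(cfg)
  e <- simulate_expression(gen$genes, cfg)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  xr <- emit_xr_reads(sim$lesions, gen$genome, cfg, n_reads = 20000)
  ctr <- mito_background_contrast(xr, gen$genome, "xr")
  mito <- ctr$fraction[ctr$compartment == "mito"]
  nuc <- ctr$fraction[ctr$compartment == "nuclear"]
  # mitochondria lack excision repair: only chance-level background there
  expect_lt(mito, 0.4)
  expect_gt(nuc, 0.9)

  only_nuc <- dplyr::filter(xr, chrom != "chrM")
  ctr2 <- mito_background_contrast(only_nuc, gen$genome, "xr")
  expect_true(is.na(ctr2$fraction[ctr2$compartment == "mito"]))
  only_mito <- dplyr::filter(xr, chrom == "chrM")
  ctr3 <- mito_background_contrast(only_mito, gen$genome, "xr")
  expect_true(is.na(ctr3$fraction[ctr3$compartment == "nuclear"]))
})

test_that("gene track signal computes coverage-weighted means with strand-aware promoters", {
  genes <- tibble::tibble(gene_id = c("p", "m"), chrom = "chr1",
                          start = c(1000L, 5000L), end = c(2000L, 6000L),
                          strand = c("+", "-"))
  uniform <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L,
                            intensity = 3.5)
  expect_equal(gene_track_signal(uniform, genes)$signal, c(3.5, 3.5))

  half <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1500L,
                         intensity = 2)
  sig <- gene_track_signal(half, genes)
  expect_equal(sig$signal[sig$gene_id == "p"], 1.0)  # half covered at 2
  expect_equal(sig$signal[sig$gene_id == "m"], 0)    # no overlap -> 0

  # promoter window sits at the TSS: start for +, end for -
  at_plus_tss <- tibble::tibble(chrom = "chr1", start = 900L, end = 1100L,
                                intensity = 1)
  prom <- gene_track_signal(at_plus_tss, genes, region_mode = "promoter",
                            promoter_window = 100)
  expect_gt(prom$signal[prom$gene_id == "p"], 0.9)
  expect_equal(prom$signal[prom$gene_id == "m"], 0)
  at_minus_tss <- tibble::tibble(chrom = "chr1", start = 5900L, end = 6100L,
                                 intensity = 1)
  prom2 <- gene_track_signal(at_minus_tss, genes, region_mode = "promoter",
                             promoter_window = 100)
  expect_equal(prom2$signal[prom2$gene_id == "p"], 0)
  expect_gt(prom2$signal[prom2$gene_id == "m"], 0.9)

  expect_error(gene_track_signal(dplyr::mutate(uniform, end = -1L), genes),
               "malformed")
})

test_that("marker correlations recover ranks, stay null under independence, and respect small n", {
  genes <- sprintf("g%03d", 1:80)
  withr::with_seed(12, {
    x <- runif(80)
    noise <- runif(80)
  })
  signals <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes, marker = "openness", signal = x),
    tibble::tibble(gene_id = genes, marker = "random", signal = noise))
  targets <- tibble::tibble(gene_id = genes, monotone = exp(3 * x))
  out <- marker_correlations(signals, targets)
  expect_equal(out$rho[out$marker == "openness"], 1)
  expect_lt(abs(out$rho[out$marker == "random"]), 0.3)
  expect_true(all(c("p_value", "p_adj") %in% names(out)))

  few <- marker_correlations(signals, targets, gene_subset = genes[1:2])
  expect_true(all(is.na(few$rho)))
})

test_that("per-gene repair rates coupled to openness surface in NTS repair", {
  cfg <- tiny_config(n_genes = 30, chrom_length = 400000, damage_rate = 6,
                     gene_length_range = c(8000, 8000), gc_content = 0.5,
                     tcr_rate_coef = 0, n_reads_per_assay = 60000,
                     background_read_fraction = 0)
  gen <- simulate_genome(cfg)
  openness <- withr::with_seed(5, runif(nrow(gen$genes), 0.2, 1))
  genes <- dplyr::mutate(gen$genes, gr_rate_nts = 0.15 * openness,
                         gr_rate_ts = 0.15 * openness)
  e <- setNames(rep(1, nrow(genes)), genes$gene_id)
  sim <- simulate_lesions(gen$genome, genes, e, cfg)
  xr <- emit_xr_reads(sim$lesions, gen$genome, cfg)
  counts <- build_count_matrix(filter_xr_reads(xr, gen$genome), genes,
                               assay = "xr")
  nts <- dplyr::filter(tibble::as_tibble(counts), strand_class == "NTS")
  j <- dplyr::left_join(nts, tibble::tibble(gene_id = genes$gene_id,
                                            openness = openness),
                        by = "gene_id")
  expect_gt(cor(j$openness, j$count / genes$gg_nts[match(j$gene_id, genes$gene_id)],
                method = "spearman"), 0.5)
})

test_that("repair_estimates ties the pieces together with glance support", {
  cfg <- tiny_config(damage_rate = 1)
  sim <- simulate_dataset(cfg)
  dmg <- build_count_matrix(filter_damage_reads(sim$damage_reads, sim$genome),
                            sim$genes)
  xr <- build_count_matrix(filter_xr_reads(sim$xr_reads, sim$genome),
                           sim$genes, assay = "xr")
  est <- repair_estimates(
    normalize_counts(dmg, size_factors(dmg), sim$genes),
    normalize_counts(xr, size_factors(xr), sim$genes))
  expect_true(all(est$damage_ratio >= 0 & est$damage_ratio <= 1, na.rm = TRUE))
  expect_true(all(est$tcr_fraction <= 1, na.rm = TRUE))
  expect_true(all(est$tcr_fraction_clipped >= 0, na.rm = TRUE))
  g <- glance(est)
  expect_identical(g$n_genes, nrow(est))
})
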