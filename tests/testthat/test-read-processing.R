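manual_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("damage filter applies the strict mapq and 5'-upstream GG rules", {
  # chr: positions 98,99 (0-based) are G,G
  chr <- paste0(strrep("A", 98), "GG", strrep("T", 100))
  genome <- manual_genome(c(chr1 = chr))
  reads <- tibble::tibble(
    chrom = "chr1", start = c(100L, 100L, 100L, 50L, 0L),
    end = c(150L, 150L, 150L, 100L, 40L),
    strand = "+", mapq = c(21L, 20L, 30L, 30L, 30L),
    read_id = sprintf("r%d", 1:5))
  calls <- filter_damage_reads(reads, genome)
  rej <- filter_rejections(calls)

  expect_setequal(calls$read_id, c("r1", "r3"))           # mapq 20 rejected
  expect_true(all(calls$lesion_start == 98L))
  expect_identical(calls$dinucleotide, rep("GG", 2))
  expect_identical(rej$n[rej$cause == "mapq"], 1L)        # r2
  expect_identical(rej$n[rej$cause == "non_gg"], 1L)      # r4
  expect_identical(rej$n[rej$cause == "out_of_bounds"], 1L)  # r5 (5' window)
  expect_identical(attr(calls, "n_accepted") + sum(rej$n),
                   attr(calls, "n_input"))
})

test_that("minus-strand damage reads localize the lesion downstream of the alignment end", {
  # - lesion occupying plus-coords (60, 61) means CC there; read ends at 60
  chr <- paste0(strrep("A", 60), "CC", strrep("T", 100))
  genome <- manual_genome(c(chr1 = chr))
  reads <- tibble::tibble(chrom = "chr1", start = 10L, end = 60L,
                          strand = "-", mapq = 30L, read_id = "m1")
  calls <- filter_damage_reads(reads, genome)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$lesion_start, 61L)  # the 5' G on the damaged strand
})

test_that("xr filter enforces oligomer length bounds and the 5-8 window", {
  # place GG so that positions 6-7 from the 3' end of a length-26 + read match
  # read [start, end): 3' end at end-1; position k maps to coord end-k
  end <- 80L; start <- end - 26L
  chr_chars <- rep("A", 200)
  chr_chars[(end - 7 + 1):(end - 6 + 1)] <- "G"  # coords end-7, end-6 => pos 7,6
  genome <- manual_genome(c(chr1 = paste(chr_chars, collapse = "")))
  ok <- tibble::tibble(chrom = "chr1", start = start, end = end,
                       strand = "+", mapq = 30L, read_id = "ok")
  too_short <- dplyr::mutate(ok, start = end - 20L, read_id = "short")
  too_long <- dplyr::mutate(ok, start = end - 32L, read_id = "long")
  calls <- filter_xr_reads(dplyr::bind_rows(ok, too_short, too_long), genome)
  rej <- filter_rejections(calls)
  expect_identical(calls$read_id, "ok")
  expect_identical(calls$lesion_start, end - 7L)  # 5' G of the pair
  expect_identical(rej$n[rej$cause == "length"], 2L)
})

test_that("xr lesion goes to the 3'-most GG when the window holds several", {
  # GGG at plus-coords (end-7, end-6, end-5): pairs at positions (7,6) and (6,5)
  end <- 80L
  chr_chars <- rep("A", 200)
  chr_chars[(end - 7 + 1):(end - 5 + 1)] <- "G"
  genome <- manual_genome(c(chr1 = paste(chr_chars, collapse = "")))
  reads <- tibble::tibble(chrom = "chr1", start = end - 26L, end = end,
                          strand = "+", mapq = 30L, read_id = "g3")
  calls <- filter_xr_reads(reads, genome)
  expect_identical(calls$lesion_start, end - 6L)  # 3'-most pair, its 5' G
})

test_that("filters agree exactly with the brute-force oracle on 1e4 random reads", {
  genome <- random_genome(len = 30000, gc = 0.45, seed = 91)
  for (assay in c("damage", "xr")) {
    reads <- random_reads(genome, 10000, assay, seed = 17)
    calls <- if (assay == "damage") filter_damage_reads(reads, genome)
    else filter_xr_reads(reads, genome)
    oracle <- oracle_filter(reads, genome, assay)

    expect_setequal(calls$read_id, oracle$read_id[is.na(oracle$cause)])
    joined <- dplyr::inner_join(
      calls, dplyr::filter(oracle, is.na(cause)), by = "read_id",
      suffix = c("", ".oracle"))
    expect_identical(joined$lesion_start, joined$lesion_start.oracle)

    rej <- filter_rejections(calls)
    oracle_rej <- dplyr::count(
      dplyr::filter(oracle, !is.na(cause)), cause, name = "n_oracle")
    cmp <- dplyr::left_join(rej, oracle_rej, by = "cause") |>
      dplyr::mutate(n_oracle = dplyr::coalesce(n_oracle, 0L))
    expect_identical(cmp$n, cmp$n_oracle)
  }
})

test_that("filter decisions are order-invariant pure functions", {
  genome <- random_genome(len = 10000, seed = 3)
  reads <- random_reads(genome, 500, "xr", seed = 8)
  perm <- withr::with_seed(1, sample.int(nrow(reads)))
  a <- filter_xr_reads(reads, genome)
  b <- filter_xr_reads(reads[perm, ], genome)
  expect_identical(dplyr::arrange(tibble::as_tibble(a), read_id),
                   dplyr::arrange(tibble::as_tibble(b), read_id))
  expect_identical(filter_rejections(a), filter_rejections(b))
})

test_that("gg signature fraction is composition-only and handles edge cases", {
  cfg <- tiny_config(background_read_fraction = 0, mapq_fail_fraction = 0.3,
                     damage_rate = 1)
  gen <- simulate_genome(cfg)
  e <- simulate_expression(gen$genes, cfg)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  reads <- emit_damage_reads(sim$lesions, gen$genome, cfg, n_reads = 2000)
  frac <- gg_signature_fraction(reads, gen$genome, "damage")
  expect_equal(frac$fraction, 1.0)  # mapq failures still carry the signature

  empty <- gg_signature_fraction(reads, gen$genome, "damage",
                                 chroms = "chrM"[FALSE])
  expect_true(is.na(empty$fraction))
})

test_that("pure-background libraries show the genomic chance GG rate", {
  cfg <- tiny_config(damage_rate = 0.5, chrom_length = 40000, mito_length = 0)
  gen <- simulate_genome(cfg)
  e <- simulate_expression(gen$genes, cfg)
  sim <- simulate_lesions(gen$genome, gen$genes, e, cfg)
  reads <- emit_damage_reads(sim$lesions, gen$genome, cfg, n_reads = 6000,
                             background_read_fraction = 0.999999)
  reads <- dplyr::filter(reads, origin == "background")
  frac <- gg_signature_fraction(reads, gen$genome, "damage")

  # analytic chance of the 2-mer signature at a uniform position/strand
  gs <- as.character(gen$genome)
  n_pairs <- sum(nchar(gs) - 1)
  q <- (sum(vapply(gs, oracle_count_gg, integer(1), "+")) +
          sum(vapply(gs, oracle_count_gg, integer(1), "-"))) / (2 * n_pairs)
  se <- sqrt(q * (1 - q) / frac$n_reads)
  expect_lt(abs(frac$fraction - q), 4 * se + 0.01)
})
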