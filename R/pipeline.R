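# End-to-end orchestration: simulate/load -> filter -> count -> normalize ->
# analyze, with a reproducibility manifest.

default_run_config <- function() {
  list(
    seed = 1,
    samples = "S1",
    damage_multipliers = 1,
    normalization_mode = "gg",
    n_bins = 10,
    promoter_window = 1000,
    mito_chroms = c("chrM", "MT"),
    mapq_cutoff = 20,
    xr_len_range = c(21, 31),
    simulate = NULL,
    inputs = NULL
  )
}

#' Load (and complete) a pipeline run configuration
#'
#' @param config A named list, or the path of a YAML file holding one.
#' @return The configuration merged over defaults.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- utils::modifyList(default_run_config(), config)
  out
}

#' Validate a pipeline run configuration
#'
#' Checks stage parameters against each module's preconditions and verifies
#' that every referenced input path exists, before any compute happens.
#'
#' @param config Run configuration (list or YAML path; see [run_pipeline()]).
#' @return Tibble of violations (`field`, `problem`); zero rows when valid.
#' @export
validate_run_config <- function(config) {
  config <- load_run_config(config)
  v <- list()
  bad <- function(field, problem) v[[length(v) + 1]] <<- tibble(
    field = field, problem = problem)
  if (is.null(config$simulate) && is.null(config$inputs)) {
    bad("simulate/inputs", "provide either a `simulate` block or an `inputs` block")
  }
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    cfg <- try(do.call(sim_config, sim_args), silent = TRUE)
    if (inherits(cfg, "try-error")) {
      bad("simulate", conditionMessage(attr(cfg, "condition")))
    }
  }
  if (!is.null(config$inputs)) {
    paths <- unlist(config$inputs[c("genome", "genes", "rnaseq")], use.names = TRUE)
    paths <- c(paths, unlist(config$inputs$damage_reads),
               unlist(config$inputs$xr_reads), unlist(config$inputs$tracks))
    for (p in paths) {
      if (!file.exists(p)) bad("inputs", sprintf("missing file: %s", p))
    }
  }
  if (!is_count(config$n_bins) || config$n_bins < 2) {
    bad("n_bins", "must be an integer >= 2")
  }
  if (length(config$xr_len_range) != 2 ||
      config$xr_len_range[1] > config$xr_len_range[2] ||
      config$xr_len_range[1] < 1) {
    bad("xr_len_range", "must be an increasing pair of positive lengths")
  }
  if (!is.numeric(config$mapq_cutoff) || config$mapq_cutoff < 0) {
    bad("mapq_cutoff", "must be a non-negative number")
  }
  if (!config$normalization_mode %in% c("gg", "length")) {
    bad("normalization_mode", "must be \"gg\" or \"length\"")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    bad("seed", "must be a single number")
  }
  if (length(v) == 0) {
    tibble(field = character(), problem = character())
  } else bind_rows(v)
}

write_stage <- function(df, outdir, name) {
  readr::write_tsv(df, file.path(outdir, name))
}

#' Run the full strand-resolved damage/repair pipeline
#'
#' Executes simulate (or load) -> filter -> count -> normalize -> analyze and
#' writes every stage's table plus a reproducibility manifest to `outdir`.
#' The configuration is a named list (or YAML path) with either a `simulate`
#' block (arguments to [sim_config()]) or an `inputs` block of file paths
#' (`genome` FASTA, `genes` BED6/GFF3, per-sample `damage_reads` and
#' `xr_reads` SAM/BAM/BED, `rnaseq` TSV, optional named `tracks`), plus
#' stage parameters (`samples`, `damage_multipliers`, `normalization_mode`,
#' `n_bins`, `promoter_window`, `mito_chroms`, `mapq_cutoff`,
#' `xr_len_range`, `seed`). Reruns with an identical configuration reproduce
#' identical outputs.
#'
#' @param config Run configuration (list or YAML path).
#' @param outdir Output directory (created; existing tables overwritten).
#' @return Invisibly, a list with every stage's result and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  config <- load_run_config(config)
  violations <- validate_run_config(config)
  if (nrow(violations) > 0) {
    abort(paste0("invalid run configuration:\n",
                 paste0("- ", violations$field, ": ", violations$problem,
                        collapse = "\n")))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tallies <- list()

  # --- stage: simulate or load ------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    sim_cfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(sim_cfg, samples = config$samples,
                            damage_multipliers = config$damage_multipliers)
    genome <- sim$genome
    genes <- sim$genes
    rnaseq <- sim$rnaseq
    damage_reads <- sim$damage_reads
    xr_reads <- sim$xr_reads
    write_genome(genome, file.path(outdir, "genome.fa"))
    write_genes_bed(genes, file.path(outdir, "genes.bed"))
    write_stage(sim$lesions, outdir, "lesion_truth.tsv")
    write_stage(sim$kinetics, outdir, "kinetics.tsv")
    for (s in config$samples) {
      for (assay in c("damage", "xr")) {
        rd <- filter(if (assay == "damage") damage_reads else xr_reads,
                     .data$sample == s)
        write_reads(rd, genome,
                    sam_path = file.path(outdir, sprintf("%s_%s.sam", assay, s)),
                    bed_path = file.path(outdir, sprintf("%s_%s.bed", assay, s)))
      }
    }
    readr::write_tsv(
      tidyr::pivot_wider(rnaseq, names_from = "sample",
                         values_from = "count"),
      file.path(outdir, "rnaseq_counts.tsv"))
  } else {
    genome <- read_genome(config$inputs$genome)
    genes <- annotate_genes(read_genes(config$inputs$genes), genome,
                            mito_chroms = config$mito_chroms)
    rnaseq <- read_rnaseq_counts(config$inputs$rnaseq)
    load_reads <- function(paths, assay) {
      purrr::imap(paths, function(p, s) {
        mutate(read_aligned_reads(p), sample = s, assay = assay)
      }) |> bind_rows()
    }
    damage_reads <- load_reads(config$inputs$damage_reads, "damage")
    xr_reads <- load_reads(config$inputs$xr_reads, "xr")
  }
  write_stage(genes, outdir, "gene_model.tsv")

  # --- stage: filter ----------------------------------------------------
  filter_one <- function(reads, assay) {
    split(reads, reads$sample) |>
      purrr::imap(function(rd, s) {
        calls <- if (assay == "damage") {
          filter_damage_reads(rd, genome, mapq_cutoff = config$mapq_cutoff)
        } else {
          filter_xr_reads(rd, genome, mapq_cutoff = config$mapq_cutoff,
                          len_range = config$xr_len_range)
        }
        tallies[[paste(assay, s, sep = ":")]] <<- list(
          input = attr(calls, "n_input"), accepted = attr(calls, "n_accepted"),
          rejected = setNames(as.list(filter_rejections(calls)$n),
                              as.character(filter_rejections(calls)$cause)))
        calls
      }) |> bind_rows()
  }
  damage_calls <- filter_one(damage_reads, "damage")
  xr_calls <- filter_one(xr_reads, "xr")
  write_stage(damage_calls, outdir, "lesions_damage.tsv")
  write_stage(xr_calls, outdir, "lesions_xr.tsv")

  # --- stage: count -----------------------------------------------------
  damage_counts <- build_count_matrix(damage_calls, genes, assay = "damage")
  xr_counts <- build_count_matrix(xr_calls, genes, assay = "xr")
  write_stage(damage_counts, outdir, "counts_damage.tsv")
  write_stage(xr_counts, outdir, "counts_xr.tsv")

  # --- stage: normalize -------------------------------------------------
  sf_damage <- size_factors(damage_counts)
  sf_xr <- size_factors(xr_counts)
  norm_damage <- normalize_counts(damage_counts, sf_damage, genes,
                                  mode = config$normalization_mode)
  norm_xr <- normalize_counts(xr_counts, sf_xr, genes,
                              mode = config$normalization_mode)
  rpkm_tbl <- rpkm(rnaseq, setNames(genes$length, genes$gene_id))
  qc <- qc_filter(genes, rnaseq, damage_counts, xr_counts)
  tallies$qc <- list(genes = nrow(qc), passing = sum(qc$pass))
  write_stage(tibble(sample = names(sf_damage), damage = unname(sf_damage),
                     xr = unname(sf_xr[names(sf_damage)])),
              outdir, "size_factors.tsv")
  write_stage(norm_damage, outdir, "normalized_damage.tsv")
  write_stage(norm_xr, outdir, "normalized_xr.tsv")
  write_stage(rpkm_tbl, outdir, "rpkm.tsv")
  write_stage(qc, outdir, "qc_report.tsv")

  # --- stage: analyze ---------------------------------------------------
  passing <- qc$gene_id[qc$pass]
  keep <- function(df) filter(df, .data$gene_id %in% passing)
  estimates <- repair_estimates(keep(norm_damage), keep(norm_xr))
  expression <- rpkm_tbl |>
    group_by(.data$gene_id) |>
    summarise(expression = mean(.data$rpkm), .groups = "drop") |>
    filter(.data$gene_id %in% passing)
  profile <- if (length(passing) >= config$n_bins) {
    quantile_stratify(expression,
                      list(damage = keep(norm_damage), xr = keep(norm_xr)),
                      n_bins = config$n_bins)
  } else NULL
  reldmg <- if (length(config$samples) >= 2) {
    nts_raw <- filter(damage_counts, .data$strand_class == "NTS",
                      .data$gene_id %in% passing)
    totals <- count_totals(damage_counts)
    relative_damage(nts_raw, gg = setNames(genes$gg_nts, genes$gene_id),
                    library_sizes = setNames(totals$total, totals$sample))
  } else NULL
  mito <- bind_rows(
    mutate(mito_background_contrast(damage_reads, genome, "damage",
                                    config$mito_chroms), assay = "damage"),
    mutate(mito_background_contrast(xr_reads, genome, "xr",
                                    config$mito_chroms), assay = "xr"))
  correlations <- NULL
  if (!is.null(config$inputs$tracks)) {
    signals <- purrr::imap(config$inputs$tracks, function(p, nm) {
      mutate(gene_track_signal(read_track(p), genes), marker = nm)
    }) |> bind_rows()
    targets <- estimates |>
      select("gene_id", "damage_ts", "damage_nts", "xr_ts", "xr_nts",
             "tcr_fraction") |>
      left_join(expression, by = "gene_id")
    correlations <- marker_correlations(signals, targets,
                                        gene_subset = passing)
    write_stage(correlations, outdir, "marker_correlations.tsv")
  }
  write_stage(estimates, outdir, "repair_estimates.tsv")
  if (!is.null(profile)) write_stage(tidy(profile), outdir,
                                     "quantile_profile.tsv")
  if (!is.null(reldmg)) write_stage(reldmg, outdir, "relative_damage.tsv")
  write_stage(mito, outdir, "mito_contrast.tsv")

  # --- manifest ---------------------------------------------------------
  input_files <- if (!is.null(config$inputs)) {
    fs <- unlist(config$inputs, use.names = TRUE)
    as.list(tools::md5sum(fs))
  } else NULL
  manifest <- list(
    package = "strandrepair",
    version = as.character(utils::packageVersion("strandrepair")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("inputs"))],
    input_checksums = input_files,
    tallies = tallies
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    genome = genome, genes = genes, rnaseq = rnaseq,
    damage_calls = damage_calls, xr_calls = xr_calls,
    damage_counts = damage_counts, xr_counts = xr_counts,
    size_factors = list(damage = sf_damage, xr = sf_xr),
    normalized = list(damage = norm_damage, xr = norm_xr),
    rpkm = rpkm_tbl, qc = qc, estimates = estimates, profile = profile,
    relative_damage = reldmg, mito_contrast = mito,
    marker_correlations = correlations, manifest = manifest
  ))
}
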