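# Independent brute-force oracles. These deliberately avoid the package's
# vectorized genome-window arithmetic: each read is re-examined one at a time
# through its read-oriented sequence built with Biostrings.

oracle_read_seq <- function(genome, chrom, start, end, strand) {
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# Damage-seq: the 2 bases immediately upstream of the 5' end in read
# orientation must be GG on the damaged strand.
oracle_damage_one <- function(genome, chrom, start, end, strand, mapq,
                              mapq_cutoff = 20) {
  len <- length(genome[[chrom]])
  if (mapq <= mapq_cutoff) return(list(cause = "mapq"))
  if (start < 0 || end > len) return(list(cause = "out_of_bounds"))
  if (strand == "+") {
    if (start - 2 < 0) return(list(cause = "out_of_bounds"))
    up <- oracle_read_seq(genome, chrom, start - 2L, start, "+")
    if (up == "GG") return(list(cause = NA_character_, lesion_start = start - 2L))
  } else {
    if (end + 2 > len) return(list(cause = "out_of_bounds"))
    up <- oracle_read_seq(genome, chrom, end, end + 2L, "-")
    if (up == "GG") return(list(cause = NA_character_, lesion_start = end + 1L))
  }
  list(cause = "non_gg")
}

# XR-seq: length 21-31 and GG within positions 5-8 from the 3' end
# (3'-terminal base = position 1); lesion = 3'-most occurrence.
oracle_xr_one <- function(genome, chrom, start, end, strand, mapq,
                          mapq_cutoff = 20, len_range = c(21, 31)) {
  len <- length(genome[[chrom]])
  L <- end - start
  if (mapq <= mapq_cutoff) return(list(cause = "mapq"))
  if (L < len_range[1] || L > len_range[2]) return(list(cause = "length"))
  if (start < 0 || end > len) return(list(cause = "out_of_bounds"))
  if (strand == "+" && end - 8 < 0) return(list(cause = "out_of_bounds"))
  if (strand == "-" && start + 8 > len) return(list(cause = "out_of_bounds"))
  r <- strsplit(oracle_read_seq(genome, chrom, start, end, strand), "")[[1]]
  for (k in 5:7) {
    # 5' G at position k+1 from the 3' end, 3' G at position k
    if (r[L - k] == "G" && r[L - k + 1] == "G") {
      lesion <- if (strand == "+") end - k - 1L else start + k
      return(list(cause = NA_character_, lesion_start = as.integer(lesion)))
    }
  }
  list(cause = "non_gg")
}

oracle_filter <- function(reads, genome, assay) {
  fun <- if (assay == "damage") oracle_damage_one else oracle_xr_one
  res <- lapply(seq_len(nrow(reads)), function(i) {
    fun(genome, reads$chrom[i], reads$start[i], reads$end[i],
        reads$strand[i], reads$mapq[i])
  })
  tibble::tibble(
    read_id = reads$read_id,
    cause = vapply(res, function(x) x$cause, character(1)),
    lesion_start = vapply(res, function(x)
      if (is.na(x$cause)) x$lesion_start else NA_integer_, integer(1))
  )
}

# Overlapping-dinucleotide scan, position by position.
oracle_count_gg <- function(sequence, strand) {
  chars <- strsplit(sequence, "")[[1]]
  if (strand == "-") {
    chars <- rev(chartr("ACGT", "TGCA", chars))
  }
  if (length(chars) < 2) return(0L)
  sum(chars[-length(chars)] == "G" & chars[-1] == "G")
}

random_reads <- function(genome, n, assay, seed) {
  withr::with_seed(seed, {
    lens <- setNames(Biostrings::width(genome), names(genome))
    chrom <- sample(names(genome), n, replace = TRUE)
    L <- if (assay == "damage") rep(50L, n) else sample(15:40, n, TRUE)
    start <- vapply(seq_len(n), function(i)
      sample.int(lens[chrom[i]] - L[i], 1) - 1L, integer(1))
    tibble::tibble(
      chrom = chrom, start = start, end = start + L,
      strand = sample(c("+", "-"), n, TRUE),
      mapq = sample(0:60, n, TRUE),
      read_id = sprintf("r%05d", seq_len(n))
    )
  })
}
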