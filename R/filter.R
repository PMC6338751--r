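# Positional Pt-d(GpG) signature filters.
#
# Both assays localize the lesion from read geometry against the reference:
#  * Damage-seq: the damaged GG occupies the 2 bp immediately upstream of the
#    read's 5' end in read orientation (the polymerase stalls 3' of the
#    adduct). For a + read [start, end) that is genome[start-2, start); for a
#    - read it is the reverse complement of genome[end, end+2).
#  * XR-seq: the excised oligomer carries the GG 5-8 nt upstream of the 3'
#    end (3'-terminal base = position 1); the filter scans the 4-mer at
#    positions 5-8 for a GG and assigns the lesion to the 3'-most occurrence.
#
# Rejection causes are mutually exclusive with precedence
# mapq -> length -> out-of-bounds -> non-GG (cheap tests first).

validate_reads <- function(reads, genome) {
  assert_cols(reads, c("chrom", "start", "end", "strand", "mapq", "read_id"),
              "reads")
  if (!all(reads$chrom %in% names(genome))) {
    abort("reads reference chromosomes absent from the genome")
  }
  if (any(reads$start >= reads$end)) abort("reads must satisfy start < end")
  if (!all(reads$strand %in% c("+", "-"))) abort("read strand must be + or -")
  as_tibble(reads)
}

finish_filter <- function(reads, cause, lesion_start, assay) {
  accepted <- is.na(cause)
  calls <- reads[accepted, , drop = FALSE] |>
    mutate(lesion_start = as.integer(lesion_start[accepted]),
           dinucleotide = "GG") |>
    select(all_of(intersect(
      c("read_id", "chrom", "strand", "lesion_start", "dinucleotide",
        "mapq", "sample", "lesion_id", "origin"),
      c(names(reads), "lesion_start", "dinucleotide"))))
  tally <- tibble(cause = factor(cause[!accepted],
                                 levels = c("mapq", "length", "out_of_bounds",
                                            "non_gg"))) |>
    count(.data$cause, .drop = FALSE, name = "n")
  structure(calls,
            rejections = tally,
            n_input = nrow(reads), n_accepted = sum(accepted), assay = assay,
            class = c("lesion_calls", class(calls)))
}

#' Filter Damage-seq reads by the positional GG signature
#'
#' Accepts a read iff its mapping quality exceeds `mapq_cutoff` (strict) and
#' the 2 bases immediately upstream of its 5' end in read orientation are GG
#' on the damaged strand, then localizes the lesion at the 5'-most G of that
#' dinucleotide. Rejections are tallied by mutually exclusive cause with
#' precedence mapq, out-of-bounds, non-GG.
#'
#' @param reads Tibble of aligned reads: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `mapq`, `read_id`; extra columns (`sample`,
#'   simulator truth) are carried through.
#' @param genome [Biostrings::DNAStringSet] covering all read chromosomes.
#' @param mapq_cutoff Reads must have `mapq > mapq_cutoff`.
#' @return Tibble of accepted lesion calls (`read_id`, `chrom`, `strand`,
#'   `lesion_start`, `dinucleotide`, ...) with attributes `rejections`
#'   (see [filter_rejections()]), `n_input` and `n_accepted`.
#' @export
filter_damage_reads <- function(reads, genome, mapq_cutoff = 20) {
  reads <- validate_reads(reads, genome)
  lens <- genome_lengths(genome)
  gs <- genome_strings(genome)
  n <- nrow(reads)
  cause <- rep(NA_character_, n)
  plus <- reads$strand == "+"

  cause[reads$mapq <= mapq_cutoff] <- "mapq"
  oob <- ifelse(plus, reads$start - 2L < 0L,
                reads$end + 2L > lens[reads$chrom]) |
    reads$start < 0L | reads$end > lens[reads$chrom]
  cause[is.na(cause) & oob] <- "out_of_bounds"

  dinuc <- rep(NA_character_, n)
  todo <- is.na(cause)
  dinuc[todo & plus] <- substr0(gs[reads$chrom[todo & plus]],
                                reads$start[todo & plus] - 2L,
                                reads$start[todo & plus])
  dinuc[todo & !plus] <- substr0(gs[reads$chrom[todo & !plus]],
                                 reads$end[todo & !plus],
                                 reads$end[todo & !plus] + 2L)
  hit <- ifelse(plus, dinuc == "GG", dinuc == "CC")
  cause[todo & !hit] <- "non_gg"

  lesion_start <- ifelse(plus, reads$start - 2L, reads$end + 1L)
  finish_filter(reads, cause, lesion_start, "damage")
}

# Locate the 3'-most GG inside the positions 5-8 window; returns the
# 0-based lesion_start (5' G on the damaged strand) or NA.
xr_window_lesion <- function(chrom_string, start, end, plus) {
  if (plus) {
    w <- substr0(chrom_string, end - 8L, end - 4L)
    occ <- which(vapply(1:3, function(i) substr(w, i, i + 1L) == "GG",
                        logical(1)))
    if (length(occ) == 0) return(NA_integer_)
    end - 9L + max(occ)
  } else {
    w <- substr0(chrom_string, start + 4L, start + 8L)
    occ <- which(vapply(1:3, function(i) substr(w, i, i + 1L) == "CC",
                        logical(1)))
    if (length(occ) == 0) return(NA_integer_)
    start + 4L + min(occ)
  }
}

#' Filter XR-seq reads by length and the positional GG signature
#'
#' Accepts a read iff its mapping quality exceeds `mapq_cutoff`, its aligned
#' length is within `len_range` (21-31 nt, the excised-oligomer range), and
#' the 4-mer occupying positions 5-8 counted from the 3' end (3'-terminal
#' base = position 1) in read orientation contains GG. The lesion is assigned
#' to the 5'-most G of the 3'-most GG occurrence in that window. Rejection
#' precedence: mapq, length, out-of-bounds, non-GG.
#'
#' @inheritParams filter_damage_reads
#' @param len_range Inclusive aligned-length bounds.
#' @return As [filter_damage_reads()].
#' @export
filter_xr_reads <- function(reads, genome, mapq_cutoff = 20,
                            len_range = c(21, 31)) {
  reads <- validate_reads(reads, genome)
  lens <- genome_lengths(genome)
  gs <- genome_strings(genome)
  n <- nrow(reads)
  cause <- rep(NA_character_, n)
  plus <- reads$strand == "+"
  rlen <- reads$end - reads$start

  cause[reads$mapq <= mapq_cutoff] <- "mapq"
  cause[is.na(cause) & (rlen < len_range[1] | rlen > len_range[2])] <- "length"
  oob <- ifelse(plus, reads$end - 8L < 0L, reads$start + 8L > lens[reads$chrom]) |
    reads$start < 0L | reads$end > lens[reads$chrom]
  cause[is.na(cause) & oob] <- "out_of_bounds"

  lesion_start <- rep(NA_integer_, n)
  todo <- which(is.na(cause))
  w_plus <- substr0(gs[reads$chrom], reads$end - 8L, reads$end - 4L)
  w_minus <- substr0(gs[reads$chrom], reads$start + 4L, reads$start + 8L)
  w <- ifelse(plus, w_plus, w_minus)
  pat <- ifelse(plus, "GG", "CC")
  occ <- cbind(substr(w, 1L, 2L) == pat,
               substr(w, 2L, 3L) == pat,
               substr(w, 3L, 4L) == pat)
  for (i in todo) {
    hits <- which(occ[i, ])
    if (length(hits) == 0) {
      cause[i] <- "non_gg"
    } else if (plus[i]) {
      lesion_start[i] <- reads$end[i] - 9L + max(hits)
    } else {
      lesion_start[i] <- reads$start[i] + 4L + min(hits)
    }
  }
  finish_filter(reads, cause, lesion_start, "xr")
}

#' Rejection tally of a filtering step
#'
#' @param calls Result of [filter_damage_reads()] or [filter_xr_reads()].
#' @return Tibble of rejection counts by mutually exclusive `cause`
#'   (`mapq`, `length`, `out_of_bounds`, `non_gg`); accepted and input totals
#'   are on the calls object as attributes `n_accepted` and `n_input`.
#' @export
filter_rejections <- function(calls) {
  attr(calls, "rejections")
}

#' Fraction of reads carrying the assay's GG signature
#'
#' A composition-only diagnostic: evaluates the positional GG signature test
#' (no mapping-quality or length filtering) on all reads overlapping the given
#' chromosomes. Reads whose signature window leaves the chromosome count as
#' lacking the signature. On real data this contrasts lesion-derived libraries
#' (high fraction) with background such as mitochondrial XR-seq reads
#' (chance-level fraction).
#'
#' @param reads Read tibble.
#' @param genome [Biostrings::DNAStringSet].
#' @param assay `"damage"` (2 bp window upstream of the 5' end must equal GG)
#'   or `"xr"` (positions 5-8 from the 3' end must contain GG).
#' @param chroms Optional chromosome subset.
#' @return One-row tibble: `n_reads`, `n_gg`, `fraction` (NA when no reads).
#' @export
gg_signature_fraction <- function(reads, genome, assay = c("damage", "xr"),
                                  chroms = NULL) {
  assay <- match.arg(assay)
  reads <- validate_reads(reads, genome)
  if (!is.null(chroms)) reads <- filter(reads, .data$chrom %in% chroms)
  if (nrow(reads) == 0) {
    return(tibble(n_reads = 0L, n_gg = NA_integer_, fraction = NA_real_))
  }
  gs <- genome_strings(genome)
  lens <- genome_lengths(genome)
  plus <- reads$strand == "+"
  if (assay == "damage") {
    ok_bounds <- ifelse(plus, reads$start >= 2L,
                        reads$end + 2L <= lens[reads$chrom])
    dinuc <- ifelse(plus,
                    substr0(gs[reads$chrom], reads$start - 2L, reads$start),
                    substr0(gs[reads$chrom], reads$end, reads$end + 2L))
    hit <- ok_bounds & ifelse(plus, dinuc == "GG", dinuc == "CC")
  } else {
    ok_bounds <- ifelse(plus, reads$end >= 8L,
                        reads$start + 8L <= lens[reads$chrom])
    w <- ifelse(plus,
                substr0(gs[reads$chrom], reads$end - 8L, reads$end - 4L),
                substr0(gs[reads$chrom], reads$start + 4L, reads$start + 8L))
    pat <- ifelse(plus, "GG", "CC")
    hit <- ok_bounds & (substr(w, 1, 2) == pat | substr(w, 2, 3) == pat |
                          substr(w, 3, 4) == pat)
  }
  tibble(n_reads = nrow(reads), n_gg = sum(hit),
         fraction = sum(hit) / nrow(reads))
}
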