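# Read-level forward models for the two assays.
#
# Coordinate conventions (0-based half-open throughout):
#  * A lesion is indexed by the position of its 5' G on the damaged strand:
#    a + lesion with GG at plus-coords (g, g+1) has lesion_start g; a - lesion
#    (CC at plus-coords (q-1, q)) has lesion_start q.
#  * Damage-seq: the polymerase stops immediately 3' of the adduct, so the
#    read's 5' end sits just downstream of the lesion and the GG occupies the
#    2 bp immediately upstream of the 5' end in read orientation.
#    + lesion g  -> read [g+2, g+2+L);   - lesion q -> read [q-1-L, q-1).
#  * XR-seq: the excised oligomer carries the lesion near its 3' end; with the
#    3'-terminal base as position 1, the lesion's 3' G sits at position
#    k in {5,6,7} so the GG lies inside the 5-8 window.
#    + lesion g, placement k -> read [g+1+k-L, g+1+k);
#    - lesion q, placement k -> read [q-k, q-k+L).

new_reads <- function(chrom, start, end, strand, mapq, read_id, lesion_id,
                      origin, sample, assay) {
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
         strand = strand, mapq = as.integer(mapq), read_id = read_id,
         lesion_id = lesion_id, origin = origin, sample = sample,
         assay = assay)
}

draw_mapq <- function(n, config) {
  mapq <- rep(30L, n)
  if (config$mapq_fail_fraction > 0 && n > 0) {
    fail <- runif(n) < config$mapq_fail_fraction
    mapq[fail] <- 20L
  }
  mapq
}

# Uniform random background reads of length `len` (vector ok), placed so the
# signature window stays in bounds; positions are unconstrained otherwise, so
# they carry the GG signature at the genomic chance rate.
background_reads <- function(n, genome, len, chroms = NULL) {
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  chroms <- chroms %||% names(genome)
  lens <- genome_lengths(genome)[chroms]
  len <- rep_len(len, n)
  chrom <- sample(chroms, n, replace = TRUE, prob = lens)
  lo <- 2L
  hi <- lens[chrom] - len - 2L
  if (any(hi < lo)) abort("background reads do not fit the shortest chromosome")
  start <- lo + floor(runif(n) * (hi - lo + 1))
  tibble(chrom = chrom, start = as.integer(start),
         end = as.integer(start + len),
         strand = sample(c("+", "-"), n, replace = TRUE))
}

n_background <- function(n_signal, frac) {
  if (frac <= 0) return(0L)
  if (frac >= 1) abort("background_read_fraction must be < 1 when emitting")
  rbinom(1, size = round(n_signal / (1 - frac)), prob = frac)
}

#' Emit Damage-seq reads from unrepaired lesions
#'
#' Samples unrepaired lesions (those still present at harvest) and emits one
#' fixed-length read per draw on the damaged strand, 5' end immediately 3' of
#' the lesion, so the Pt-d(GpG) dinucleotide occupies the 2 bp just upstream
#' of the read's 5' end in read orientation. A configurable fraction of reads
#' is background: uniform random positions carrying the signature only at
#' chance rate. Lesions whose read would overrun a chromosome end are excluded
#' from the pool (resampled), keeping positional signatures exact.
#'
#' @param lesions Lesion tibble from [simulate_lesions()].
#' @param genome [Biostrings::DNAStringSet].
#' @param config A [sim_config()].
#' @param n_reads Total reads to emit (default `config$n_reads_per_assay`).
#'   Ignored when `capture` is given.
#' @param background_read_fraction Overrides `config$background_read_fraction`.
#' @param capture Per-lesion capture probability; when set, each eligible
#'   unrepaired lesion independently yields one read with this probability
#'   (read yield then scales with the lesion load, emulating a fixed-efficiency
#'   library rather than fixed sequencing depth).
#' @param sample Sample label (also salts the random sub-stream).
#' @return Read tibble (`chrom`, `start`, `end`, `strand`, `mapq`, `read_id`,
#'   `lesion_id`, `origin`, `sample`, `assay`); coordinates 0-based half-open.
#' @export
emit_damage_reads <- function(lesions, genome, config, n_reads = NULL,
                              background_read_fraction = NULL, capture = NULL,
                              sample = "S1") {
  validate_sim_config(config)
  bg_frac <- background_read_fraction %||% config$background_read_fraction
  L <- config$damage_read_length
  lens <- genome_lengths(genome)

  with_substream(config$seed, paste0("damage_reads:", sample), {
    pool <- lesions |>
      filter(!.data$repaired_by_T) |>
      filter(ifelse(.data$strand == "+",
                    .data$lesion_start + 2L + L <= lens[.data$chrom],
                    .data$lesion_start >= L + 1L))
    if (is.null(capture)) {
      n_reads <- n_reads %||% config$n_reads_per_assay
      n_bg <- rbinom(1, n_reads, bg_frac)
      n_sig <- n_reads - n_bg
      if (n_sig > 0 && nrow(pool) == 0) {
        abort("no unrepaired lesions to sample damage reads from")
      }
      idx <- if (n_sig > 0) sample.int(nrow(pool), n_sig, replace = TRUE)
      else integer()
    } else {
      idx <- which(runif(nrow(pool)) < capture)
      n_bg <- n_background(length(idx), bg_frac)
    }
    sig <- pool[idx, , drop = FALSE]
    sig_start <- ifelse(sig$strand == "+", sig$lesion_start + 2L,
                        sig$lesion_start - 1L - L)
    sig_reads <- new_reads(sig$chrom, sig_start, sig_start + L, sig$strand,
                           mapq = 30L, read_id = NA_character_,
                           lesion_id = sig$lesion_id, origin = "lesion",
                           sample = sample, assay = "damage")
    bg <- background_reads(n_bg, genome, L)
    bg_reads <- new_reads(bg$chrom, bg$start, bg$end, bg$strand, mapq = 30L,
                          read_id = NA_character_, lesion_id = NA_character_,
                          origin = "background", sample = sample,
                          assay = "damage")
    reads <- bind_rows(sig_reads, bg_reads)
    reads$mapq <- draw_mapq(nrow(reads), config)
    reads$read_id <- sprintf("%s_d_%07d", sample, seq_len(nrow(reads)))
    reads
  })
}

# Valid XR placements k in {5,6,7} for a lesion: those under which the
# localization rule (3'-most GG in the 5-8 window) recovers the truth.
# k = 5 puts the lesion at the 3'-most slot and is always valid.
xr_valid_placements <- function(lesions, gs) {
  n <- nrow(lesions)
  valid <- matrix(FALSE, n, 3, dimnames = list(NULL, c("5", "6", "7")))
  valid[, "5"] <- TRUE
  if (n == 0) return(valid)
  chr <- gs[lesions$chrom]
  plus <- lesions$strand == "+"
  g <- lesions$lesion_start
  for (k in c(6L, 7L)) {
    # + strand: window coords [g+k-7, g+k-3); lesion GG at string index 8-k;
    # valid iff no GG occurrence at a larger index.
    w_plus <- substr0(chr, g + k - 7L, g + k - 3L)
    # - strand: window coords [q-k+4, q-k+8); lesion CC at index k-4;
    # valid iff no CC occurrence at a smaller index.
    w_minus <- substr0(chr, g - k + 4L, g - k + 8L)
    w <- ifelse(plus, w_plus, w_minus)
    pat <- ifelse(plus, "GG", "CC")
    at <- function(i) substr(w, i, i + 1L) == pat
    lesion_i <- ifelse(plus, 8L - k, k - 4L)
    occ <- cbind(at(1L), at(2L), at(3L))
    later <- vapply(seq_len(n), function(j) {
      others <- which(occ[j, ])
      if (plus[j]) any(others > lesion_i[j]) else any(others < lesion_i[j])
    }, logical(1))
    valid[, as.character(k)] <- !later
  }
  valid
}

#' Emit XR-seq reads from lesions excised near harvest
#'
#' Takes a snapshot of ongoing excision repair: lesions whose repair time
#' falls in the window `(T - xr_window_delta, T]` form the sampling pool (the
#' pool size is thereby proportional to remaining lesions times the repair
#' rate). Each emitted oligomer read has length uniform in `xr_len_range` and
#' is placed on the damaged strand so the lesion's GG falls 5-8 nt upstream of
#' the 3' end; the placement offset is drawn uniformly from the offsets under
#' which the 3'-most-GG localization rule recovers the true lesion (offset 5
#' always qualifies), so round trips are exact.
#'
#' @inheritParams emit_damage_reads
#' @return Read tibble as in [emit_damage_reads()], with `assay = "xr"`.
#' @export
emit_xr_reads <- function(lesions, genome, config, n_reads = NULL,
                          background_read_fraction = NULL, capture = NULL,
                          sample = "S1") {
  validate_sim_config(config)
  bg_frac <- background_read_fraction %||% config$background_read_fraction
  lens <- genome_lengths(genome)
  gs <- genome_strings(genome)
  Lmax <- config$xr_len_range[2]

  with_substream(config$seed, paste0("xr_reads:", sample), {
    pool <- lesions |>
      filter(.data$repair_time > config$T_hours - config$xr_window_delta,
             .data$repair_time <= config$T_hours) |>
      filter(.data$lesion_start >= Lmax + 8L,
             .data$lesion_start <= lens[.data$chrom] - Lmax - 8L)
    if (is.null(capture)) {
      n_reads <- n_reads %||% config$n_reads_per_assay
      n_bg <- rbinom(1, n_reads, bg_frac)
      n_sig <- n_reads - n_bg
      if (n_sig > 0 && nrow(pool) == 0) {
        abort("no lesions repaired in the snapshot window; raise repair rates or the window width")
      }
      idx <- if (n_sig > 0) sample.int(nrow(pool), n_sig, replace = TRUE)
      else integer()
    } else {
      idx <- which(runif(nrow(pool)) < capture)
      n_bg <- n_background(length(idx), bg_frac)
    }

    valid <- xr_valid_placements(pool, gs)
    sig <- pool[idx, , drop = FALSE]
    v <- valid[idx, , drop = FALSE]
    nv <- rowSums(v)
    pick <- floor(runif(nrow(sig)) * nv) + 1
    k <- vapply(seq_len(nrow(sig)), function(j) {
      c(5L, 6L, 7L)[which(v[j, ])[pick[j]]]
    }, integer(1))
    L <- sample_int_range(config$xr_len_range[1], config$xr_len_range[2],
                          nrow(sig))
    sig_start <- ifelse(sig$strand == "+",
                        sig$lesion_start + 1L + k - L,
                        sig$lesion_start - k)
    sig_reads <- new_reads(sig$chrom, sig_start, sig_start + L, sig$strand,
                           mapq = 30L, read_id = NA_character_,
                           lesion_id = sig$lesion_id, origin = "lesion",
                           sample = sample, assay = "xr")
    bg_len <- sample_int_range(config$xr_len_range[1], config$xr_len_range[2],
                               n_bg)
    bg <- background_reads(n_bg, genome, bg_len + 8L)
    if (n_bg > 0) bg$end <- bg$start + bg_len  # length in range; margin kept
    bg_reads <- new_reads(bg$chrom, bg$start, bg$end, bg$strand, mapq = 30L,
                          read_id = NA_character_, lesion_id = NA_character_,
                          origin = "background", sample = sample, assay = "xr")
    reads <- bind_rows(sig_reads, bg_reads)
    reads$mapq <- draw_mapq(nrow(reads), config)
    reads$read_id <- sprintf("%s_x_%07d", sample, seq_len(nrow(reads)))
    reads
  })
}
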