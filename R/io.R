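# Readers/writers for the standard formats the pipeline touches.
# All tibble coordinates are 0-based half-open; BED is native, SAM (1-based)
# and GRanges (1-based closed) are converted at the boundary.

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Write a genome to 60-column wrapped FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60)
  invisible(path)
}

#' Read gene intervals from BED6 or GFF3
#'
#' BED6 name and strand columns populate `gene_id` and `strand`; for GFF3,
#' records with type `gene` are used and `gene_id` comes from the `ID` or
#' `gene_id` attribute.
#'
#' @param path BED or GFF3 file (format chosen by extension unless given).
#' @param format `"bed"`, `"gff3"` or `"auto"`.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) gr$ID else gr$gene_id
  } else {
    ids <- gr$name
  }
  tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write gene intervals as BED6
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param path Output file.
#' @export
write_genes_bed <- function(genes, path) {
  readr::write_tsv(
    tibble(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
           genes$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Read aligned reads from SAM/BAM or BED6(+mapq)
#'
#' SAM/BAM is read through Rsamtools (CIGAR-aware reference span, 1-based
#' converted to 0-based half-open; unmapped reads dropped). BED6 uses the
#' score column as mapping quality.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"bed"`.
#' @return Read tibble (`chrom`, `start`, `end`, `strand`, `mapq`, `read_id`).
#' @export
read_aligned_reads <- function(path, format = c("auto", "sam", "bam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam", "bed")) ext else
      abort("cannot infer read format; pass `format`")
  }
  if (format == "bed") {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                              "read_id", "mapq", "strand"),
                          col_types = "ciicic", progress = FALSE)
    return(select(df, "chrom", "start", "end", "strand", "mapq", "read_id"))
  }
  bam_path <- if (format == "sam") {
    Rsamtools::asBam(path, file.path(tempdir(), basename(tools::file_path_sans_ext(path))),
                     overwrite = TRUE, indexDestination = FALSE)
  } else path
  b <- Rsamtools::scanBam(
    bam_path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "strand", "mapq", "cigar"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  tibble(
    chrom = as.character(b$rname),
    start = b$pos - 1L,
    end = b$pos - 1L + as.integer(width),
    strand = as.character(b$strand),
    mapq = as.integer(b$mapq),
    read_id = b$qname
  )
}

#' Write reads as SAM (with @SQ headers) and a BED6 mirror
#'
#' The SAM file carries the aligned sequence from the reference (reverse
#' complemented for minus-strand reads) and a full-match CIGAR; the BED6
#' mirror stores the read id (or originating lesion id when known) in the
#' name column and the mapping quality in the score column.
#'
#' @param reads Read tibble.
#' @param genome [Biostrings::DNAStringSet] (for headers and sequence).
#' @param sam_path,bed_path Output files (either may be `NULL` to skip).
#' @export
write_reads <- function(reads, genome, sam_path = NULL, bed_path = NULL) {
  if (!is.null(sam_path)) {
    gs <- genome_strings(genome)
    seqs <- substr0(gs[reads$chrom], reads$start, reads$end)
    minus <- reads$strand == "-"
    if (any(minus)) seqs[minus] <- reverse_complement_chr(seqs[minus])
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                        genome_lengths(genome)))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                    reads$read_id, ifelse(minus, 16L, 0L), reads$chrom,
                    reads$start + 1L, reads$mapq, reads$end - reads$start,
                    seqs)
    writeLines(c(header, body), sam_path)
  }
  if (!is.null(bed_path)) {
    name <- if ("lesion_id" %in% names(reads)) {
      ifelse(is.na(reads$lesion_id), reads$read_id, reads$lesion_id)
    } else reads$read_id
    readr::write_tsv(tibble(reads$chrom, reads$start, reads$end, name,
                            reads$mapq, reads$strand),
                     bed_path, col_names = FALSE)
  }
  invisible(reads)
}

#' Read an intensity track from bedGraph or BED
#'
#' bedGraph's fourth column, or BED's score column, becomes `intensity`.
#'
#' @param path bedGraph (4 columns) or BED (>= 5 columns) file.
#' @return Tibble (`chrom`, `start`, `end`, `intensity`).
#' @export
read_track <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "track",
                        progress = FALSE, show_col_types = FALSE)
  if (ncol(df) == 4) {
    setNames(df, c("chrom", "start", "end", "intensity"))
  } else if (ncol(df) >= 5) {
    setNames(df[, c(1, 2, 3, 5)], c("chrom", "start", "end", "intensity"))
  } else {
    abort("track file must have 4 (bedGraph) or >= 5 (BED) columns")
  }
}

#' Read RNA-seq gene counts from TSV
#'
#' Accepts wide (gene_id column plus one column per sample) or long
#' (`gene_id`, `sample`, `count`) layouts.
#'
#' @param path TSV file.
#' @return Long tibble (`gene_id`, `sample`, `count`).
#' @export
read_rnaseq_counts <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (all(c("gene_id", "sample", "count") %in% names(df))) {
    return(select(df, "gene_id", "sample", "count"))
  }
  assert_cols(df, "gene_id", "RNA-seq table")
  tidyr::pivot_longer(df, -"gene_id", names_to = "sample",
                      values_to = "count")
}
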