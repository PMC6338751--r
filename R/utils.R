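# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed and a fixed label.
# All stochastic operations draw from their own labelled sub-stream so that
# adding or reordering one stage never perturbs another.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes) * 7919)
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, label, code) {
  withr::with_seed(substream_seed(seed, label), code)
}

# Geometric mean; 0 if any element is 0 (callers usually exclude such rows).
geomean <- function(x) exp(mean(log(x)))

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s must contain column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
}

# Named character vector of chromosome sequences for fast substring lookups.
genome_strings <- function(genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  setNames(as.character(genome), names(genome))
}

genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

# 1-based inclusive substring on a 0-based half-open interval [start, end).
substr0 <- function(chrom_string, start, end) {
  substring(chrom_string, start + 1, end)
}

# Uniform integers in [lo, hi]; safe when lo == hi (unlike sample(seq(...))).
sample_int_range <- function(lo, hi, n) {
  vals <- seq.int(lo, hi)
  vals[sample.int(length(vals), n, replace = TRUE)]
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
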