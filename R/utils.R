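#' Reverse complement of DNA strings
#'
#' @param x character vector over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings; N never matches.
hamming <- function(a, b) {
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  if (length(va) != length(vb)) stop("hamming: unequal lengths")
  n_code <- utf8ToInt("N")
  sum(va != vb | va == n_code | vb == n_code)
}

# random DNA string(s); uses the current RNG stream
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# substring by 0-based half-open interval
substr0 <- function(seq, start, end) substr(seq, start + 1L, end)

# overwrite part of a sequence at 0-based position
implant0 <- function(seq, start, piece) {
  substr(seq, start + 1L, start + nchar(piece)) <- piece
  seq
}

# round half-up to `digits` decimals (printed-style rounding)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    stop("'", name, "' must be a positive integer scalar")
}
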