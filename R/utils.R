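#' @useDynLib stemmiR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Convert sequences to the package's canonical RNA alphabet
#'
#' All sequences are stored internally as uppercase RNA letters (A/C/G/U);
#' DNA input (T) is accepted anywhere and converted on ingest.
#'
#' @param x character vector of nucleotide sequences (DNA or RNA letters).
#' @return character vector in uppercase RNA letters.
#' @export
as_rna <- function(x) chartr("tT", "uU", toupper(x))

#' Convert sequences to DNA letters (U -> T)
#' @param x character vector of nucleotide sequences.
#' @return character vector in uppercase DNA letters.
#' @export
as_dna <- function(x) chartr("uU", "tT", toupper(x))

#' Reverse complement
#'
#' Works on either alphabet and returns the same alphabet it was given
#' (sequences containing U are complemented as RNA).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  is_rna <- grepl("U", toupper(x), fixed = TRUE) | !grepl("T", toupper(x), fixed = TRUE)
  comp <- chartr("ACGTUacgtu", "TGCAATGCAA", x)
  out <- vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
  out[is_rna] <- chartr("T", "U", out[is_rna])
  out
}

# Hamming distance between two equal-length strings; Inf if lengths differ.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(charToRaw(a) != charToRaw(b))
}

# Vectorized hamming of one string against a vector of equal-length strings.
hamming_vec <- function(a, bs) {
  ra <- charToRaw(a)
  vapply(bs, function(b) {
    rb <- charToRaw(b)
    if (length(rb) != length(ra)) return(Inf)
    sum(ra != rb)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a FASTA file as a named character vector (RNA letters)
#' @param path FASTA file path.
#' @return named character vector of sequences in RNA letters.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  stats::setNames(as_rna(as.character(ss)), names(ss))
}

#' Write a named character vector of sequences as FASTA (DNA letters)
#' @param seqs named character vector.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(as_dna(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Derive a stream-specific RNG seed below 2^31 from a base seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1013L + as.integer(stream) * 7919L) %% 2147483399L
}

random_seq <- function(n, len, bases = RNA_BASES, prob = NULL) {
  vapply(seq_len(n), function(i) {
    paste(sample(bases, len[min(i, length(len))], replace = TRUE, prob = prob),
          collapse = "")
  }, "")
}
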