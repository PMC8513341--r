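#' Cleaning configuration
#'
#' Parameters for [clean_reads()]: the retained insert length range, the 3'
#' adapter and how much of its prefix must match, and the low-complexity
#' ("junk") rule. An insert is junk when a single nucleotide makes up at
#' least `junk_mono_frac` of it, or a mono-/di-nucleotide repeat covers at
#' least `junk_repeat_frac` of it, or it contains symbols outside A/C/G/T/U.
#'
#' @param min_len,max_len retained insert length bounds in nt (18-25).
#' @param adapter 3' adapter sequence.
#' @param adapter_min_match length of the adapter prefix that must be found
#'   (exact or one mismatch) at the insert's 3' end.
#' @param junk_mono_frac,junk_repeat_frac junk-rule thresholds.
#' @return a `cleaning_config` list.
#' @export
cleaning_config <- function(min_len = 18L, max_len = 25L,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            adapter_min_match = 8L,
                            junk_mono_frac = 0.8,
                            junk_repeat_frac = 0.9) {
  stopifnot(min_len > 0, min_len <= max_len, adapter_min_match >= 4)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 adapter = toupper(adapter),
                 adapter_min_match = as.integer(adapter_min_match),
                 junk_mono_frac = junk_mono_frac,
                 junk_repeat_frac = junk_repeat_frac),
            class = "cleaning_config")
}

# TRUE where the insert fails the low-complexity rule
is_junk <- function(inserts, config) {
  n <- nchar(inserts)
  junk <- rep(FALSE, length(inserts))
  has_bad <- grepl("[^ACGTU]", inserts)
  junk <- junk | has_bad
  up <- as_dna(inserts)
  for (b in c("A", "C", "G", "T")) {
    cnt <- nchar(up) - nchar(gsub(b, "", up, fixed = TRUE))
    junk <- junk | (cnt >= config$junk_mono_frac * n)
  }
  dinucs <- c("AC", "AG", "AT", "CA", "CG", "CT",
              "GA", "GC", "GT", "TA", "TC", "TG")
  for (d in dinucs) {
    m <- regexpr(paste0("(?:", d, ")+"), up)
    len <- attr(m, "match.length")
    len[m < 0] <- 0L
    junk <- junk | (len >= config$junk_repeat_frac * n)
  }
  junk
}

#' Clean a small-RNA FASTQ library
#'
#' Locates the 3' adapter (first `adapter_min_match` bases of the adapter,
#' exact or one mismatch, leftmost occurrence), trims it, discards adapter
#' dimers (zero-length inserts) and inserts outside the 18-25 nt range
#' (tallied together, as sequencing reports conventionally merge them),
#' flags low-complexity junk, and collapses the surviving inserts into a
#' unique-sequence count table.
#'
#' @param fastq path to a FASTQ file (Phred+33; qualities are ignored).
#' @param config a [cleaning_config()].
#' @param library library identifier; defaults to the file name.
#' @return a list of class `cleaned_library`: `reads` (data frame `sequence`
#'   in RNA letters, `count`) and `stats` (one-row data frame: `library`,
#'   `raw_reads`, `adaptor_and_length_removed`, `junk_reads`, `clean_reads`).
#' @export
clean_reads <- function(fastq, config = cleaning_config(),
                        library = sub("\\.(fastq|fq)(\\.gz)?$", "",
                                      basename(fastq))) {
  ss <- tryCatch(Biostrings::readBStringSet(fastq, format = "fastq"),
                 error = function(e) stop("malformed FASTQ in ", fastq, ": ",
                                          conditionMessage(e)))
  reads <- toupper(as.character(ss))
  raw_n <- length(reads)
  if (raw_n == 0)
    return(list(reads = data.frame(sequence = character(), count = integer()),
                stats = data.frame(library = library, raw_reads = 0L,
                                   adaptor_and_length_removed = 0L,
                                   junk_reads = 0L, clean_reads = 0L)))
  probe <- substr(as_dna(config$adapter), 1, config$adapter_min_match)
  hits <- Biostrings::vmatchPattern(probe, Biostrings::BStringSet(reads),
                                    max.mismatch = 1)
  first <- vapply(Biostrings::startIndex(hits), function(s)
    if (is.null(s) || length(s) == 0) NA_integer_ else min(s), 0L)
  insert_len <- ifelse(is.na(first), nchar(reads), first - 1L)
  inserts <- substr(reads, 1, insert_len)

  is_dimer <- insert_len == 0L
  bad_len <- !is_dimer & (insert_len < config$min_len |
                            insert_len > config$max_len)
  junk <- rep(FALSE, raw_n)
  cand <- !(is_dimer | bad_len)
  junk[cand] <- is_junk(inserts[cand], config)
  clean <- cand & !junk

  tab <- table(as_rna(inserts[clean]))
  stats <- data.frame(library = library, raw_reads = raw_n,
                      adaptor_and_length_removed = sum(is_dimer | bad_len),
                      junk_reads = sum(junk), clean_reads = sum(clean),
                      stringsAsFactors = FALSE)
  reads_df <- data.frame(sequence = names(tab),
                         count = as.integer(tab),
                         stringsAsFactors = FALSE)
  structure(list(reads = reads_df, stats = stats), class = "cleaned_library")
}

#' @export
print.cleaned_library <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "Cleaned library %s: %s raw; %s adaptor/length, %s junk, %s clean (%d unique)\n",
    s$library, format(s$raw_reads, big.mark = ","),
    format(s$adaptor_and_length_removed, big.mark = ","),
    format(s$junk_reads, big.mark = ","),
    format(s$clean_reads, big.mark = ","), nrow(x$reads)))
  invisible(x)
}

#' Length distribution of a unique-read set
#'
#' @param reads data frame with columns `sequence` and `count` (one library),
#'   or a `cleaned_library`.
#' @param weighting `"unique"` (each distinct sequence once) or
#'   `"abundance"` (weighted by count).
#' @param range length range to report over (zero mass outside observed
#'   lengths).
#' @return named numeric vector of proportions over `range`, summing to 1.
#' @export
length_distribution <- function(reads, weighting = c("unique", "abundance"),
                                range = 18:25) {
  weighting <- match.arg(weighting)
  if (inherits(reads, "cleaned_library")) reads <- reads$reads
  if (nrow(reads) == 0) stop("empty read set")
  len <- nchar(reads$sequence)
  w <- if (weighting == "unique") rep(1, nrow(reads)) else reads$count
  tot <- tapply(w, factor(len, levels = range), sum, default = 0)
  out <- as.numeric(tot) / sum(w)
  names(out) <- range
  out
}

#' First-nucleotide and positional nucleotide biases
#'
#' @param sequences character vector of mature miRNA sequences (RNA letters).
#' @return list with `first_by_length` (length x base matrix of first-
#'   nucleotide frequencies, rows summing to 1) and `by_position` (position x
#'   base matrix over positions 1..max length, rows summing to 1 over the
#'   sequences long enough to reach that position).
#' @export
nucleotide_bias <- function(sequences) {
  sequences <- as_rna(sequences)
  stopifnot(length(sequences) > 0, all(nchar(sequences) > 0))
  lens <- nchar(sequences)
  first <- substr(sequences, 1, 1)
  fb <- table(factor(lens), factor(first, levels = RNA_BASES))
  first_by_length <- sweep(unclass(fb), 1, pmax(rowSums(fb), 1), "/")
  maxl <- max(lens)
  by_position <- t(vapply(seq_len(maxl), function(p) {
    ch <- substr(sequences[lens >= p], p, p)
    tb <- table(factor(ch, levels = RNA_BASES))
    as.numeric(tb) / sum(tb)
  }, numeric(4)))
  colnames(by_position) <- RNA_BASES
  rownames(by_position) <- seq_len(maxl)
  list(first_by_length = first_by_length, by_position = by_position)
}

#' Summarize per-library sequencing statistics
#'
#' Totals and averages over a set of library cleaning statistics, in the
#' layout of a sequencing-summary table: total/average raw and clean reads
#' and the overall percentage of reads surviving cleaning.
#'
#' @param stats data frame with columns `library`, `raw_reads`,
#'   `adaptor_and_length_removed`, `junk_reads`, `clean_reads` (one row per
#'   library), e.g. row-bound from [clean_reads()] outputs.
#' @return list of class `library_summary`: `n_libraries`, `total_raw`,
#'   `total_adaptor_length`, `total_junk`, `total_clean`, `average_raw`,
#'   `average_clean` (exact means), and `percent_clean`
#'   (100 * total_clean / total_raw).
#' @export
summarize_libraries <- function(stats) {
  stopifnot(nrow(stats) >= 1)
  out <- list(n_libraries = nrow(stats),
              total_raw = sum(as.numeric(stats$raw_reads)),
              total_adaptor_length = sum(as.numeric(stats$adaptor_and_length_removed)),
              total_junk = sum(as.numeric(stats$junk_reads)),
              total_clean = sum(as.numeric(stats$clean_reads)),
              average_raw = mean(as.numeric(stats$raw_reads)),
              average_clean = mean(as.numeric(stats$clean_reads)))
  out$percent_clean <- if (out$total_raw > 0)
    100 * out$total_clean / out$total_raw else 0
  class(out) <- "library_summary"
  out
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf("%d libraries: %s raw, %s clean (%.2f%%); avg %s raw / %s clean per library\n",
              x$n_libraries,
              format(x$total_raw, big.mark = ",", scientific = FALSE),
              format(x$total_clean, big.mark = ",", scientific = FALSE),
              x$percent_clean,
              format(round(x$average_raw), big.mark = ",", scientific = FALSE),
              format(round(x$average_clean), big.mark = ",",
                     scientific = FALSE)))
  invisible(x)
}

#' Published per-library sequencing statistics fixture
#'
#' Reads the packaged per-library sequencing summary of the yellowhorn
#' high-/low-oil seed-development study (16 libraries) used to validate the
#' bookkeeping invariants of [summarize_libraries()].
#'
#' @return data frame with columns `library`, `raw_reads`,
#'   `adaptor_and_length_removed`, `junk_reads`, `clean_reads`.
#' @export
published_library_stats <- function() {
  path <- system.file("extdata", "yellowhorn_library_stats.tsv",
                      package = "stemmiR", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
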