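#' Build a k-mer index over a reference set
#'
#' Indexes every k-mer of every reference on both strands (minus-strand
#' k-mers are taken from the reverse complement and mapped back to forward
#' coordinates). K-mers containing ambiguous symbols are skipped; ambiguity
#' codes never match.
#'
#' @param references named character vector of reference sequences, or a
#'   path to a FASTA file.
#' @param k seed length in nt (>= 8). The default of 9 guarantees, by the
#'   pigeonhole principle, that every end-to-end placement with at most one
#'   mismatch of a read of >= 2k nt is recovered from an exact seed.
#' @return an object of class `kmer_index`.
#' @export
build_index <- function(references, k = 9L) {
  if (is.character(references) && length(references) == 1 &&
      file.exists(references))
    references <- read_fasta(references)
  k <- as.integer(k)
  if (k < 8) stop("seed length k must be >= 8")
  if (length(references) == 0 || any(nchar(references) == 0))
    stop("references must be non-empty sequences")
  if (is.null(names(references)) || anyDuplicated(names(references)))
    stop("references must have unique names")
  references <- as_rna(references)

  keys <- character(0); refi <- integer(0); pos <- integer(0)
  strand <- character(0)
  for (ri in seq_along(references)) {
    for (sd in c("+", "-")) {
      s <- if (sd == "+") references[[ri]] else revcomp(references[[ri]])
      L <- nchar(s)
      if (L < k) next
      starts <- seq_len(L - k + 1L)
      km <- substring(s, starts, starts + k - 1L)
      ok <- !grepl("[^ACGU]", km)
      keys <- c(keys, km[ok])
      refi <- c(refi, rep.int(ri, sum(ok)))
      pos <- c(pos, starts[ok])
      strand <- c(strand, rep.int(sd, sum(ok)))
    }
  }
  ht <- new.env(hash = TRUE, parent = emptyenv(), size = length(keys))
  idx <- seq_along(keys)
  for (grp in split(idx, keys)) assign(keys[grp[1]], grp, envir = ht)
  structure(list(ht = ht, refi = refi, pos = pos, strand = strand,
                 references = references, rc = revcomp(references), k = k,
                 n_seeds = length(keys)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: %d reference(s), k = %d, %d indexed seeds\n",
              length(x$references), x$k, x$n_seeds))
  invisible(x)
}

lookup_seed <- function(index, kmer) {
  v <- get0(kmer, envir = index$ht, inherits = FALSE)
  if (is.null(v)) integer(0) else v
}

#' Align a read end-to-end with at most one mismatch
#'
#' Returns every ungapped end-to-end placement of the read on either strand
#' of the indexed references with at most one mismatch, found by exact-seed
#' lookup at disjoint offsets followed by full-length verification.
#'
#' @param read read sequence (18-25 nt typical; must be at least `k` nt).
#' @param index a [build_index()] object.
#' @param max_mismatch maximum mismatches over the whole read (0 or 1).
#' @return data frame of hits sorted by (reference, start, strand): columns
#'   `read`, `reference`, `start` (0-based), `end` (half-open), `strand`,
#'   `mismatches`. Zero rows when the read does not place.
#' @export
align_read <- function(read, index, max_mismatch = 1L) {
  read <- as_rna(read)
  L <- nchar(read)
  k <- index$k
  if (L < k) stop("read shorter than seed length ", k)
  offs <- unique(c(seq(0L, L - k, by = k), L - k))
  seeds <- substring(read, offs + 1L, offs + k)
  cand <- list()
  for (si in seq_along(seeds)) {
    for (j in lookup_seed(index, seeds[si])) {
      # seed begins at read offset offs[si]; placement start on the indexed
      # strand's coordinates:
      st <- index$pos[j] - offs[si]
      ref_len <- nchar(index$references[[index$refi[j]]])
      if (st < 1L || st + L - 1L > ref_len) next
      cand[[length(cand) + 1L]] <- c(index$refi[j], st,
                                     if (index$strand[j] == "+") 1L else 2L)
    }
  }
  if (length(cand) == 0)
    return(empty_hits(read))
  cand <- unique(do.call(rbind, cand))
  rows <- list()
  for (ci in seq_len(nrow(cand))) {
    ri <- cand[ci, 1]; st <- cand[ci, 2]; sd <- cand[ci, 3]
    refseq <- index$references[[ri]]
    s <- if (sd == 1L) refseq else index$rc[[ri]]
    win <- substr(s, st, st + L - 1L)
    if (grepl("[^ACGU]", win)) next
    mm <- hamming(read, win)
    if (mm <= max_mismatch) {
      # map minus-strand coordinates back to forward strand
      if (sd == 1L) {
        fstart <- st - 1L
      } else {
        fstart <- nchar(refseq) - (st + L - 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read = read, reference = names(index$references)[ri],
        start = fstart, end = fstart + L,
        strand = if (sd == 1L) "+" else "-", mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_hits(read))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$reference, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function(read = character(0)) {
  data.frame(read = character(0), reference = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mismatches = integer(0), stringsAsFactors = FALSE)
}

#' Align many reads, returning one combined hit table
#' @param reads character vector of read sequences.
#' @param index a [build_index()] object.
#' @param max_mismatch maximum mismatches per read.
#' @return combined hit data frame (see [align_read()]).
#' @export
align_reads <- function(reads, index, max_mismatch = 1L) {
  hits <- lapply(reads, align_read, index = index,
                 max_mismatch = max_mismatch)
  out <- do.call(rbind, hits)
  if (is.null(out)) empty_hits() else out
}

#' Locate a precursor sequence in the genome by local alignment
#'
#' Seed-and-extend localization: Smith-Waterman local alignment of the query
#' against each contig and its reverse complement, reported when the aligned
#' region covers at least `min_coverage` of the query at `min_identity`
#' identity.
#'
#' @param query precursor sequence (>= 50 nt).
#' @param genome named character vector of contigs (or FASTA path).
#' @param min_identity minimum matches / aligned-query-length (default 0.9).
#' @param min_coverage minimum aligned fraction of the query (default 0.9).
#' @return data frame of loci: `reference`, `start` (0-based), `end`
#'   (half-open, forward coordinates), `strand`, `identity`. Zero rows when
#'   no locus qualifies.
#' @export
locate_precursor <- function(query, genome, min_identity = 0.9,
                             min_coverage = 0.9) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_fasta(genome)
  query <- as_dna(query)
  if (nchar(query) < 50) stop("query must be at least 50 nt")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  q <- Biostrings::DNAString(query)
  rows <- list()
  for (ri in seq_along(genome)) {
    for (sd in c("+", "-")) {
      subj <- if (sd == "+") as_dna(genome[[ri]]) else
        as_dna(revcomp(genome[[ri]]))
      aln <- Biostrings::pairwiseAlignment(
        q, Biostrings::DNAString(subj), type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      qr <- Biostrings::pattern(aln)
      alen <- Biostrings::width(qr@range)
      cov <- alen / nchar(query)
      ident <- Biostrings::nmatch(aln) / max(Biostrings::nchar(aln), 1)
      if (cov >= min_coverage && ident >= min_identity) {
        sr <- Biostrings::subject(aln)@range
        st <- Biostrings::start(sr); en <- Biostrings::end(sr)
        if (sd == "+") {
          fstart <- st - 1L; fend <- en
        } else {
          L <- nchar(genome[[ri]])
          fstart <- L - en; fend <- L - st + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          reference = names(genome)[ri], start = fstart, end = fend,
          strand = sd, identity = ident, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(reference = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$reference, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export alignment hits as BED6
#' @param hits hit data frame from [align_read()]/[align_reads()].
#' @param path output file.
#' @param score value for the BED score column (recycled).
#' @return invisibly, `path`.
#' @export
hits_to_bed <- function(hits, path, score = 0L) {
  bed <- data.frame(chrom = hits$reference, start = hits$start,
                    end = hits$end, name = hits$read, score = score,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
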