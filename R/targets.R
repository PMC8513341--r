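#' Score a miRNA against one candidate target site
#'
#' Plant-style complementarity penalty (the scheme popularized by plant
#' target-prediction tools): each mismatch costs 1, each G:U wobble 0.5,
#' each gap 1, and every cost is doubled when the miRNA position lies in
#' 2-13 from the miRNA 5' end. The site is the transcript subsequence
#' (5'->3') the miRNA binds antiparallel; its length may differ from the
#' miRNA's by at most one (a single gap).
#'
#' @param mirna mature miRNA sequence (RNA or DNA letters).
#' @param site transcript site sequence (length within +-1 of the miRNA's).
#' @param weights list of scoring weights: `mismatch`, `wobble`, `gap`,
#'   `seed_lo`, `seed_hi`, `seed_mult`.
#' @return list: `score`, `mismatches`, `wobbles`, `gaps`.
#' @export
score_target_site <- function(mirna, site, weights = target_weights()) {
  r <- .score_site(as_rna(mirna), as_rna(site), weights$mismatch,
                   weights$wobble, weights$gap, weights$seed_lo,
                   weights$seed_hi, weights$seed_mult)
  if (is.na(r$score))
    stop("site length must be within 1 nt of the miRNA length")
  r
}

#' Target-site scoring weights
#' @param mismatch,wobble,gap per-event penalties.
#' @param seed_lo,seed_hi miRNA position range whose penalties are doubled.
#' @param seed_mult multiplier applied inside that range.
#' @return list of weights.
#' @export
target_weights <- function(mismatch = 1, wobble = 0.5, gap = 1,
                           seed_lo = 2, seed_hi = 13, seed_mult = 2) {
  list(mismatch = mismatch, wobble = wobble, gap = gap, seed_lo = seed_lo,
       seed_hi = seed_hi, seed_mult = seed_mult)
}

#' Scan transcripts for miRNA target sites
#'
#' Every transcript window of length L-1, L, L+1 (L = miRNA length) is
#' scored with [score_target_site()]; windows scoring at or below the
#' cutoff are reported, sorted by (miRNA, transcript, score). No windows
#' are merged, so the output equals exhaustive enumeration under the same
#' scorer.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences (or a
#'   FASTA path).
#' @param cutoff maximum penalty score of a reported site (default 4).
#' @param weights a [target_weights()] list.
#' @return data frame of class `target_sites`: `mirna`, `transcript`,
#'   `start`, `end` (1-based inclusive), `score`, `mismatches`, `wobbles`,
#'   `gaps`.
#' @export
scan_transcripts <- function(mirnas, transcripts, cutoff = 4,
                             weights = target_weights()) {
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts))
    transcripts <- read_fasta(transcripts)
  if (length(mirnas) == 0 || length(transcripts) == 0)
    stop("mirnas and transcripts must be non-empty")
  rows <- list()
  for (mi in seq_along(mirnas)) {
    m <- as_rna(mirnas[[mi]])
    for (ti in seq_along(transcripts)) {
      hits <- .scan_one(m, as_rna(transcripts[[ti]]), cutoff,
                        weights$mismatch, weights$wobble, weights$gap,
                        weights$seed_lo, weights$seed_hi, weights$seed_mult)
      if (nrow(hits) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = names(mirnas)[mi], transcript = names(transcripts)[ti],
          start = as.integer(hits[, "start"]), end = as.integer(hits[, "end"]),
          score = hits[, "score"],
          mismatches = as.integer(hits[, "mismatches"]),
          wobbles = as.integer(hits[, "wobbles"]),
          gaps = as.integer(hits[, "gaps"]), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), transcript = character(0),
               start = integer(0), end = integer(0), score = numeric(0),
               mismatches = integer(0), wobbles = integer(0),
               gaps = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$transcript, out$score, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_sites", "data.frame")
  out
}

#' Hypergeometric term enrichment
#'
#' One-sided upper-tail hypergeometric test per term: the probability of
#' observing at least the query's overlap with the term, given the term's
#' size in the universe. Equivalent to a one-sided Fisher exact test on the
#' 2x2 table.
#'
#' @param query character vector of query genes (must lie in the universe).
#' @param annotation data frame with columns `gene` and `term` (and
#'   optionally `name`).
#' @param universe gene universe; defaults to all annotated genes.
#' @param alpha enrichment threshold on the raw P-value.
#' @return data frame of class `term_enrichment`: `term`, `term_size`,
#'   `overlap`, `query_size`, `universe_size`, `p_value`, `padj` (BH),
#'   `enriched`.
#' @export
hypergeometric_enrichment <- function(query, annotation,
                                      universe = unique(annotation$gene),
                                      alpha = 0.05) {
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must be contained in the universe")
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  dropped <- setdiff(unique(annotation$term), unique(ann$term))
  if (length(dropped))
    warning("terms absent from the universe skipped: ",
            paste(dropped, collapse = ", "))
  N <- length(universe)
  q <- length(query)
  terms <- split(unique(ann[c("gene", "term")])$gene,
                 unique(ann[c("gene", "term")])$term)
  rows <- lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- length(intersect(terms[[tm]], query))
    p <- stats::phyper(k - 1, K, N - K, q, lower.tail = FALSE)
    data.frame(term = tm, term_size = K, overlap = k, query_size = q,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p_value, "BH")
  out$enriched <- out$p_value < alpha
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_enrichment", "data.frame")
  out
}
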