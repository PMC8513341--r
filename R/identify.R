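#' Identify known miRNAs in a unique-read count matrix
#'
#' A unique sequence is called a known miRNA when it matches a database
#' mature end-to-end with at most one mismatch, or lies within a database
#' precursor with at most one mismatch. Counts of all read variants assigned
#' to the same mature are summed; each variant is assigned to the mature
#' with the fewest mismatches. Precursors of matched matures are localized
#' on the genome with [locate_precursor()] when a genome is supplied.
#'
#' @param counts integer matrix, unique sequences (RNA letters) x libraries.
#' @param mature_db named character vector of database mature sequences.
#' @param precursor_db optional named character vector of precursors.
#' @param precursor_info optional data frame linking `precursor_id` to
#'   `mature_id` (plus `mature_offset`, `mature_length`), as produced by
#'   [generate_reference()]; used to credit precursor-internal matches.
#' @param genome optional named character vector of contigs for precursor
#'   localization.
#' @return list of class `known_mirnas`: `mirnas` (data frame `id`,
#'   `sequence`, `source`), `counts` (miRNA x library matrix),
#'   `assigned` (unique sequences consumed), `loci` (precursor genomic
#'   loci, when a genome was given).
#' @export
identify_known <- function(counts, mature_db, precursor_db = NULL,
                           precursor_info = NULL, genome = NULL) {
  if (length(mature_db) == 0) stop("mature database is empty")
  seqs <- rownames(counts)
  mat_len <- nchar(mature_db)
  assign_id <- rep(NA_character_, length(seqs))
  assign_mm <- rep(Inf, length(seqs))
  for (si in seq_along(seqs)) {
    s <- seqs[si]
    cand <- which(mat_len == nchar(s))
    if (length(cand)) {
      mm <- hamming_vec(s, mature_db[cand])
      ok <- which(mm <= 1)
      if (length(ok)) {
        best <- ok[which.min(mm[ok])]
        assign_id[si] <- names(mature_db)[cand[best]]
        assign_mm[si] <- mm[ok[which.min(mm[ok])]]
      }
    }
  }
  # precursor-internal matches for still-unassigned sequences
  if (!is.null(precursor_db) && length(precursor_db) > 0 &&
      !is.null(precursor_info)) {
    un <- which(is.na(assign_id))
    if (length(un)) {
      pidx <- build_index(precursor_db)
      for (si in un) {
        hits <- align_read(seqs[si], pidx, max_mismatch = 1L)
        hits <- hits[hits$strand == "+", , drop = FALSE]
        if (nrow(hits) == 0) next
        # only placements overlapping the annotated mature arm are credited
        # to the known mature; opposite-arm placements are left for
        # detect_opposite_arm()
        info <- precursor_info[match(hits$reference,
                                     precursor_info$precursor_id), ]
        ovl <- !is.na(info$mature_id) &
          hits$start < info$mature_offset + info$mature_length &
          hits$end > info$mature_offset
        hits <- hits[ovl, , drop = FALSE]
        if (nrow(hits)) {
          h <- hits[which.min(hits$mismatches), ]
          mid <- precursor_info$mature_id[match(h$reference,
                                                precursor_info$precursor_id)]
          assign_id[si] <- mid
          assign_mm[si] <- h$mismatches
        }
      }
    }
  }
  keep <- !is.na(assign_id)
  ids <- sort(unique(assign_id[keep]))
  cmat <- matrix(0, nrow = length(ids), ncol = ncol(counts),
                 dimnames = list(ids, colnames(counts)))
  for (si in which(keep))
    cmat[assign_id[si], ] <- cmat[assign_id[si], ] + counts[si, ]
  loci <- NULL
  if (!is.null(genome) && !is.null(precursor_db) &&
      !is.null(precursor_info) && length(ids)) {
    pre_ids <- precursor_info$precursor_id[
      precursor_info$mature_id %in% ids]
    loci <- do.call(rbind, lapply(pre_ids, function(p) {
      lo <- locate_precursor(precursor_db[[p]], genome)
      if (nrow(lo)) cbind(precursor_id = p, lo) else NULL
    }))
  }
  structure(list(
    mirnas = data.frame(id = ids,
                        sequence = unname(mature_db[ids]),
                        source = "known_db", stringsAsFactors = FALSE),
    counts = cmat, assigned = seqs[keep], loci = loci),
    class = "known_mirnas")
}

#' @export
print.known_mirnas <- function(x, ...) {
  cat(sprintf("%d known miRNAs identified (%d read variants assigned)\n",
              nrow(x$mirnas), length(x$assigned)))
  invisible(x)
}

#' Detect opposite-arm (p5/p3) miRNA species
#'
#' Sequences that map within a known precursor (at most one mismatch) but do
#' not overlap its annotated mature arm are new opposite-arm species,
#' labelled `p5` or `p3` by which side of the precursor's terminal loop they
#' lie on (the precursor is folded to locate the loop).
#'
#' @param counts unique-sequence x library count matrix (sequences not
#'   already consumed by [identify_known()]).
#' @param precursor_db named character vector of precursors.
#' @param precursor_info data frame with `precursor_id`, `mature_id`,
#'   `mature_offset` (0-based), `mature_length`.
#' @return list of class `opposite_arm`: `mirnas` (data frame `id`,
#'   `sequence`, `source` in `opposite_arm_p5`/`opposite_arm_p3`,
#'   `precursor_id`), `counts`, `assigned`.
#' @export
detect_opposite_arm <- function(counts, precursor_db, precursor_info) {
  seqs <- rownames(counts)
  pidx <- build_index(precursor_db)
  folds <- new.env(parent = emptyenv())
  rows <- list(); rcounts <- list(); assigned <- character(0)
  for (si in seq_along(seqs)) {
    hits <- align_read(seqs[si], pidx, max_mismatch = 1L)
    hits <- hits[hits$strand == "+", , drop = FALSE]
    if (nrow(hits) == 0) next
    h <- hits[which.min(hits$mismatches), ]
    info <- precursor_info[match(h$reference, precursor_info$precursor_id), ]
    m0 <- info$mature_offset; m1 <- m0 + info$mature_length # 0-based half-open
    if (h$start < m1 && h$end > m0) next  # overlaps the annotated mature
    f <- get0(h$reference, envir = folds)
    if (is.null(f)) {
      f <- fold_hairpin(precursor_db[[h$reference]])
      pm <- parse_structure(f, c(1L, nchar(f$sequence)))
      f <- list(loop = pm$loop)
      assign(h$reference, f, envir = folds)
    }
    if (any(is.na(f$loop))) {
      warning("precursor ", h$reference, " has no resolvable loop; skipped")
      next
    }
    side <- if (h$end <= f$loop[1]) "p5"
            else if (h$start >= f$loop[2] - 1L) "p3"
            else next # straddles the loop: not an arm-derived species
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(info$mature_id, "-", side), sequence = seqs[si],
      source = paste0("opposite_arm_", side),
      precursor_id = h$reference, stringsAsFactors = FALSE)
    rcounts[[length(rcounts) + 1L]] <- counts[si, ]
    assigned <- c(assigned, seqs[si])
  }
  if (length(rows) == 0)
    return(structure(list(mirnas = data.frame(id = character(0),
                                              sequence = character(0),
                                              source = character(0),
                                              precursor_id = character(0)),
                          counts = matrix(0, 0, ncol(counts),
                                          dimnames = list(NULL,
                                                          colnames(counts))),
                          assigned = character(0)),
                     class = "opposite_arm"))
  mir <- do.call(rbind, rows)
  cm <- do.call(rbind, rcounts)
  # sum variants assigned to the same opposite-arm id
  agg <- rowsum(cm, mir$id)
  mir <- mir[!duplicated(mir$id), , drop = FALSE]
  mir <- mir[order(mir$id), , drop = FALSE]
  structure(list(mirnas = mir, counts = agg[mir$id, , drop = FALSE],
                 assigned = assigned),
            class = "opposite_arm")
}

#' Discover novel miRNAs from genome-mapped reads
#'
#' Remaining unannotated sequences are aligned to the genome (at most one
#' mismatch, both strands); around each hit a 120 nt flanked window is
#' extracted, folded, decomposed, and screened by the eleven hairpin
#' criteria. Accepted candidates are deduplicated by mature sequence and
#' named in genomic order.
#'
#' @param counts unique-sequence x library count matrix of unannotated,
#'   non-known sequences.
#' @param genome_index [build_index()] over the genome.
#' @param genome named character vector of contigs.
#' @param criteria a [hairpin_criteria()].
#' @param prefix id prefix for accepted novel miRNAs.
#' @return list of class `novel_mirnas`: `mirnas` (data frame `id`,
#'   `sequence`, `contig`, `start`, `end`, `strand`, `mfe`, the eleven
#'   measures, `verdict`), `counts` (novel x library), `candidates` (all
#'   evaluated windows incl. rejected ones).
#' @export
discover_novel <- function(counts, genome_index, genome,
                           criteria = hairpin_criteria(),
                           prefix = "Xso-miRn") {
  seqs <- rownames(counts)
  cand_rows <- list()
  for (si in seq_along(seqs)) {
    hits <- align_read(seqs[si], genome_index, max_mismatch = 1L)
    if (nrow(hits) == 0) next
    for (hi in seq_len(nrow(hits))) {
      h <- hits[hi, ]
      win <- extract_hairpin_window(h, genome)
      fr <- fold_hairpin(win$sequence)
      ms <- parse_structure(fr, win$mature_interval)
      ev <- evaluate_hairpin_criteria(ms, criteria)
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        sequence = seqs[si], contig = h$reference, start = h$start,
        end = h$end, strand = h$strand, mfe = ms$mfe,
        stem_bp = ms$stem_bp, max_stem_bulge_nt = ms$max_stem_bulge_nt,
        hairpin_len = ms$hairpin_len, loop_len = ms$loop_len,
        max_mature_bulge_nt = ms$max_mature_bulge_nt,
        mature_biased_errors = ms$mature_biased_errors,
        mature_biased_bulges = ms$mature_biased_bulges,
        mature_errors = ms$mature_errors, mature_bp = ms$mature_bp,
        mature_in_stem_pct = ms$mature_in_stem_pct,
        verdict = ev$verdict, stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(sequence = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mfe = numeric(0), verdict = logical(0))
  accepted <- candidates[candidates$verdict, , drop = FALSE]
  named <- name_novel(accepted, prefix = prefix)
  cmat <- matrix(0, nrow = nrow(named), ncol = ncol(counts),
                 dimnames = list(named$id, colnames(counts)))
  for (i in seq_len(nrow(named)))
    cmat[i, ] <- colSums(counts[seqs == named$sequence[i], , drop = FALSE])
  structure(list(mirnas = named, counts = cmat, candidates = candidates),
            class = "novel_mirnas")
}

#' @export
print.novel_mirnas <- function(x, ...) {
  cat(sprintf("%d novel miRNAs accepted out of %d evaluated windows\n",
              nrow(x$mirnas), nrow(x$candidates)))
  invisible(x)
}

#' Name accepted novel miRNA candidates
#'
#' Deduplicates accepted candidates by mature sequence (keeping each
#' sequence's first locus in genomic order) and assigns sequential ids in
#' (contig, start) order, independent of input order.
#'
#' @param accepted data frame of accepted candidates with columns
#'   `sequence`, `contig`, `start`, `end`, `strand` (plus any measures).
#' @param prefix id prefix; ids are `<prefix>1 .. <prefix>N`.
#' @return the deduplicated data frame with an `id` column prepended.
#' @export
name_novel <- function(accepted, prefix = "Xso-miRn") {
  if (nrow(accepted) == 0)
    return(cbind(data.frame(id = character(0)), accepted))
  ord <- order(accepted$contig, accepted$start, accepted$strand)
  acc <- accepted[ord, , drop = FALSE]
  acc <- acc[!duplicated(acc$sequence), , drop = FALSE]
  acc <- acc[order(acc$contig, acc$start, acc$strand), , drop = FALSE]
  out <- cbind(data.frame(id = paste0(prefix, seq_len(nrow(acc))),
                          stringsAsFactors = FALSE), acc)
  rownames(out) <- NULL
  out
}
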