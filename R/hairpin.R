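#' Fold an RNA sequence into a secondary structure
#'
#' Default backend is the package's energy-minimizing base-pair dynamic
#' program (per-pair energies with a stacking bonus; deterministic and
#' dependency-free). When the ViennaRNA `RNAfold` executable is on the PATH
#' it can be selected as a full thermodynamic backend.
#'
#' @param sequence RNA (or DNA) sequence; non-ACGU symbols are forced
#'   unpaired. Must be non-empty.
#' @param backend `"builtin"` or `"rnafold"`.
#' @return list of class `fold_result`: `sequence`, `structure`
#'   (dot-bracket), `mfe` (kcal/mol, <= 0), `backend`.
#' @export
fold_hairpin <- function(sequence, backend = c("builtin", "rnafold")) {
  backend <- match.arg(backend)
  sequence <- as_rna(sequence)
  if (nchar(sequence) == 0) stop("empty sequence")
  if (backend == "rnafold") {
    exe <- Sys.which("RNAfold")
    if (exe == "") stop("RNAfold executable not found on PATH")
    out <- system2(exe, c("--noPS"), input = sequence, stdout = TRUE)
    line <- out[2]
    structure_db <- sub("^([().]+).*$", "\\1", line)
    mfe <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
  } else {
    r <- .fold_dp(sequence)
    structure_db <- r$structure
    mfe <- r$mfe
  }
  structure(list(sequence = sequence, structure = structure_db, mfe = mfe,
                 backend = backend), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, sprintf(" (%.1f kcal/mol, %s)\n",
                                             x$mfe, x$backend), sep = "")
  invisible(x)
}

# Pair table from a dot-bracket string: integer vector, pt[i] = partner of i
# (1-based) or 0 if unpaired. Errors on unbalanced structures.
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  st <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") st <- c(st, i)
    else if (ch[i] == ")") {
      if (length(st) == 0) stop("unbalanced dot-bracket structure")
      j <- st[length(st)]
      st <- st[-length(st)]
      pt[i] <- j; pt[j] <- i
    } else if (ch[i] != ".") stop("invalid structure symbol '", ch[i], "'")
  }
  if (length(st) > 0) stop("unbalanced dot-bracket structure")
  pt
}

#' The eleven hairpin acceptance thresholds
#'
#' Structural criteria a candidate stem-loop must satisfy to be called a
#' novel miRNA precursor: (1) no stem bulge longer than 12 nt; (2) at least
#' 16 base pairs in the stem; (3) folding free energy at most -15 kcal/mol;
#' (4) hairpin (stems + terminal loop) at least 50 nt; (5) terminal loop at
#' most 200 nt; (6) no bulge in the mature region longer than 4 nt; (7) at
#' most 2 biased errors in one bulge in the mature region; (8) at most 2
#' biased bulges in the mature region; (9) at most 4 errors in the mature
#' region; (10) at least 12 base pairs in the mature region; (11) at least
#' 80% of the mature region within the stem.
#'
#' @param max_stem_bulge_nt,min_stem_bp,max_mfe,min_hairpin_len,max_loop_len,max_mature_bulge_nt,max_mature_biased_errors,max_mature_biased_bulges,max_mature_errors,min_mature_bp,min_mature_in_stem_pct thresholds as above.
#' @return a `hairpin_criteria` list.
#' @export
hairpin_criteria <- function(max_stem_bulge_nt = 12, min_stem_bp = 16,
                             max_mfe = -15, min_hairpin_len = 50,
                             max_loop_len = 200, max_mature_bulge_nt = 4,
                             max_mature_biased_errors = 2,
                             max_mature_biased_bulges = 2,
                             max_mature_errors = 4, min_mature_bp = 12,
                             min_mature_in_stem_pct = 80) {
  structure(list(max_stem_bulge_nt = max_stem_bulge_nt,
                 min_stem_bp = min_stem_bp, max_mfe = max_mfe,
                 min_hairpin_len = min_hairpin_len,
                 max_loop_len = max_loop_len,
                 max_mature_bulge_nt = max_mature_bulge_nt,
                 max_mature_biased_errors = max_mature_biased_errors,
                 max_mature_biased_bulges = max_mature_biased_bulges,
                 max_mature_errors = max_mature_errors,
                 min_mature_bp = min_mature_bp,
                 min_mature_in_stem_pct = min_mature_in_stem_pct),
            class = "hairpin_criteria")
}

#' Decompose a folded window around a mature interval
#'
#' Anchors on the hairpin loop nearest the mature, walks the enclosing stem
#' ladder outwards until the first branch point, and measures the eleven
#' criterion quantities: the terminal loop is the unpaired span inside the
#' innermost ladder pair; a bulge is a maximal unpaired run between
#' consecutive ladder pairs (biased when confined to one arm); mature errors
#' are unpaired mature positions; the mature-in-stem percentage is the share
#' of mature positions lying within the ladder's span.
#'
#' @param fold a `fold_result` (or a list with `structure` and `mfe`).
#' @param mature_interval integer c(start, end), 1-based inclusive, of the
#'   mature within the folded window.
#' @return list of class `hairpin_measures` with the measured values
#'   (`stem_bp`, `max_stem_bulge_nt`, `mfe`, `hairpin_len`, `loop_len`,
#'   `max_mature_bulge_nt`, `mature_biased_errors`, `mature_biased_bulges`,
#'   `mature_errors`, `mature_bp`, `mature_in_stem_pct`) plus the ladder's
#'   outer span. Structures with no base pairs report failing sentinels.
#' @export
parse_structure <- function(fold, mature_interval) {
  db <- fold$structure
  mfe <- if (is.null(fold$mfe)) NA_real_ else fold$mfe
  n <- nchar(db)
  ms <- as.integer(mature_interval[1]); me <- as.integer(mature_interval[2])
  if (ms < 1 || me > n || ms > me)
    stop("mature interval outside the folded window")
  pt <- pair_table(db)
  mlen <- me - ms + 1L
  fail <- structure(list(stem_bp = 0L, max_stem_bulge_nt = Inf, mfe = mfe,
                         hairpin_len = 0L, loop_len = Inf,
                         max_mature_bulge_nt = Inf,
                         mature_biased_errors = Inf,
                         mature_biased_bulges = Inf, mature_errors = mlen,
                         mature_bp = 0L, mature_in_stem_pct = 0,
                         stem_start = NA_integer_, stem_end = NA_integer_,
                         loop = c(NA_integer_, NA_integer_)),
                    class = "hairpin_measures")
  paired <- which(pt > 0)
  if (length(paired) == 0) return(fail)

  # hairpin loops: pairs (i, j = pt[i]) with no paired position inside
  opens <- which(pt > seq_len(n))
  hloops <- opens[vapply(opens, function(i) {
    j <- pt[i]
    j - i - 1L >= 0L && !any(pt[(i + 1L):(j - 1L)] > 0)
  }, TRUE)]
  if (length(hloops) == 0) return(fail)
  # nearest hairpin loop to the mature (distance between intervals)
  d <- vapply(hloops, function(i) {
    j <- pt[i]
    max(0L, max(ms - j, i - me))
  }, 0L)
  i0 <- hloops[which.min(d)]
  j0 <- pt[i0]

  # extend the ladder outwards until a branch point
  lad_i <- i0; lad_j <- j0
  a <- i0; b <- j0
  repeat {
    # next enclosing pair: the nearest opening position before a whose
    # partner lies beyond b, with only unpaired positions in between
    a2 <- a - 1L; found <- FALSE
    while (a2 >= 1L) {
      if (pt[a2] > 0) {
        if (pt[a2] > b) {
          b2 <- pt[a2]
          gap5 <- if (a2 + 1L <= a - 1L) any(pt[(a2 + 1L):(a - 1L)] > 0) else FALSE
          gap3 <- if (b + 1L <= b2 - 1L) any(pt[(b + 1L):(b2 - 1L)] > 0) else FALSE
          if (!gap5 && !gap3) found <- TRUE
        }
        break
      }
      a2 <- a2 - 1L
    }
    if (!found) break
    lad_i <- c(lad_i, a2); lad_j <- c(lad_j, pt[a2])
    a <- a2; b <- pt[a2]
  }
  stem_bp <- length(lad_i)
  a_out <- min(lad_i); b_out <- max(lad_j)
  stem_pos <- c(a_out:i0, j0:b_out)

  # bulges between consecutive ladder pairs (innermost -> outermost)
  ord <- order(lad_i, decreasing = TRUE) # from outer? lad_i descending = outward
  li <- sort(lad_i) # ascending: outermost first on 5' arm
  lj <- pt[li]
  bulges <- list()
  if (stem_bp >= 2) {
    for (k in seq_len(stem_bp - 1L)) {
      u5 <- (li[k] + 1L):(li[k + 1L] - 1L)
      u5 <- u5[u5 <= li[k + 1L] - 1L & u5 >= li[k] + 1L]
      if (li[k + 1L] - li[k] == 1L) u5 <- integer(0)
      u3 <- if (lj[k] - lj[k + 1L] == 1L) integer(0) else
        (lj[k + 1L] + 1L):(lj[k] - 1L)
      if (length(u5) + length(u3) > 0)
        bulges[[length(bulges) + 1L]] <-
          list(pos5 = u5, pos3 = u3,
               biased = xor(length(u5) > 0, length(u3) > 0))
    }
  }
  max_stem_bulge <- if (length(bulges) == 0) 0L else
    max(vapply(bulges, function(bl) max(length(bl$pos5), length(bl$pos3)), 0L))

  hairpin_len <- b_out - a_out + 1L
  loop_len <- j0 - i0 - 1L

  # mature measures
  mpos <- ms:me
  in_stem <- mpos >= a_out & mpos <= b_out &
    (mpos <= i0 | mpos >= j0)
  mature_in_stem_pct <- 100 * sum(in_stem) / mlen
  mature_errors <- sum(pt[mpos] == 0)
  mature_bp <- sum(pt[mpos] > 0)
  # maximal runs of consecutive unpaired mature positions
  unp <- pt[mpos] == 0
  runs <- rle(unp)
  max_mature_bulge <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  # biased bulges intersecting the mature; count mature positions therein
  biased_overlaps <- vapply(bulges, function(bl) {
    if (!bl$biased) return(0L)
    sum(c(bl$pos5, bl$pos3) %in% mpos)
  }, 0L)
  mature_biased_bulges <- sum(biased_overlaps > 0)
  mature_biased_errors <- if (length(biased_overlaps) == 0) 0L else
    max(biased_overlaps)

  structure(list(stem_bp = stem_bp, max_stem_bulge_nt = max_stem_bulge,
                 mfe = mfe, hairpin_len = hairpin_len, loop_len = loop_len,
                 max_mature_bulge_nt = max_mature_bulge,
                 mature_biased_errors = mature_biased_errors,
                 mature_biased_bulges = mature_biased_bulges,
                 mature_errors = mature_errors, mature_bp = mature_bp,
                 mature_in_stem_pct = mature_in_stem_pct,
                 stem_start = a_out, stem_end = b_out,
                 loop = c(i0, j0)),
            class = "hairpin_measures")
}

#' Evaluate the eleven hairpin criteria
#'
#' @param measures a `hairpin_measures` list from [parse_structure()].
#' @param criteria a [hairpin_criteria()] threshold set.
#' @return list: `flags` (named logical, one per criterion) and `verdict`
#'   (TRUE iff all eleven hold).
#' @export
evaluate_hairpin_criteria <- function(measures, criteria = hairpin_criteria()) {
  m <- measures; cr <- criteria
  flags <- c(
    max_stem_bulge_nt = m$max_stem_bulge_nt <= cr$max_stem_bulge_nt,
    min_stem_bp = m$stem_bp >= cr$min_stem_bp,
    max_mfe = !is.na(m$mfe) && m$mfe <= cr$max_mfe,
    min_hairpin_len = m$hairpin_len >= cr$min_hairpin_len,
    max_loop_len = m$loop_len <= cr$max_loop_len,
    max_mature_bulge_nt = m$max_mature_bulge_nt <= cr$max_mature_bulge_nt,
    max_mature_biased_errors = m$mature_biased_errors <= cr$max_mature_biased_errors,
    max_mature_biased_bulges = m$mature_biased_bulges <= cr$max_mature_biased_bulges,
    max_mature_errors = m$mature_errors <= cr$max_mature_errors,
    min_mature_bp = m$mature_bp >= cr$min_mature_bp,
    min_mature_in_stem_pct = m$mature_in_stem_pct >= cr$min_mature_in_stem_pct)
  list(flags = flags, verdict = all(flags))
}

#' Extract the genomic hairpin window around an aligned read
#'
#' 120 nt upstream + the read locus + 120 nt downstream on the read's
#' strand; minus-strand hits return the reverse complement of the forward
#' slice. Truncated at contig ends.
#'
#' @param hit one row of an [align_read()] hit table.
#' @param genome named character vector of contigs.
#' @return list: `sequence` (window, RNA letters, read-strand orientation),
#'   `mature_interval` (1-based inclusive position of the read within the
#'   window), `reference`, `win_start`/`win_end` (0-based half-open forward
#'   coordinates), `strand`.
#' @export
extract_hairpin_window <- function(hit, genome, flank = 120L) {
  ctg <- genome[[hit$reference]]
  L <- nchar(ctg)
  ws <- max(0L, hit$start - flank)          # 0-based
  we <- min(L, hit$end + flank)
  fwd <- substr(ctg, ws + 1L, we)
  if (hit$strand == "+") {
    seqw <- fwd
    m1 <- hit$start - ws + 1L
  } else {
    seqw <- revcomp(fwd)
    m1 <- we - hit$end + 1L
  }
  list(sequence = as_rna(seqw),
       mature_interval = c(m1, m1 + (hit$end - hit$start) - 1L),
       reference = hit$reference, win_start = ws, win_end = we,
       strand = hit$strand)
}
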