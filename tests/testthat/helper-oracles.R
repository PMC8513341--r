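# Independent reference implementations used to cross-check the package.
# These deliberately use the most direct (often brute-force) formulation.

# every end-to-end ungapped placement of `read` with <= mm mismatches, both
# strands, by scanning every window of every reference
brute_force_align <- function(read, references, mm = 1L) {
  rows <- list()
  L <- nchar(read)
  for (rn in names(references)) {
    refseq <- references[[rn]]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") refseq else revcomp(refseq)
      if (nchar(s) < L) next
      for (st in seq_len(nchar(s) - L + 1L)) {
        win <- substr(s, st, st + L - 1L)
        if (grepl("[^ACGU]", win)) next
        d <- sum(charToRaw(read) != charToRaw(win))
        if (d <= mm) {
          fstart <- if (strand == "+") st - 1L else nchar(s) - (st + L - 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            read = read, reference = rn, start = fstart, end = fstart + L,
            strand = strand, mismatches = d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(read = character(0), reference = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$reference, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive minimum-energy fold over all non-crossing pairings (min loop 3),
# same energy model as the package's DP; feasible to ~14 nt
enumerate_fold_mfe <- function(seq, e_gc = -3, e_au = -2, e_gu = -1,
                               stack = -1, min_loop = 3) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  pe <- function(a, b) {
    k <- paste0(a, b)
    if (k %in% c("GC", "CG")) return(e_gc)
    if (k %in% c("AU", "UA")) return(e_au)
    if (k %in% c("GU", "UG")) return(e_gu)
    NA_real_
  }
  structures <- function(i, j) {
    if (i >= j) return(list(list()))
    out <- structures(i + 1L, j) # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (k > j) break
      if (is.na(pe(s[i], s[k]))) next
      left <- structures(i + 1L, k - 1L)
      right <- structures(k + 1L, j)
      for (a in left) for (b in right)
        out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
    }
    out
  }
  best <- 0
  for (st in structures(1L, length(s))) {
    if (length(st) == 0) next
    pairs <- do.call(rbind, st)
    en <- sum(mapply(function(a, b) pe(s[a], s[b]), pairs[, 1], pairs[, 2]))
    has_inner <- mapply(function(a, b) {
      any(pairs[, 1] == a + 1 & pairs[, 2] == b - 1)
    }, pairs[, 1], pairs[, 2])
    en <- en + stack * sum(has_inner)
    best <- min(best, en)
  }
  best
}

# Build a random hairpin dot-bracket with known ground truth: a ladder of
# `blocks` paired segments separated by bulges/internal loops, around a
# terminal loop. Returns the structure plus the constructed measures.
construct_hairpin_db <- function(blocks = 3, block_bp = c(8, 14),
                                 bulge_max = 5, loop_len = 8) {
  bps <- sample(block_bp[1]:block_bp[2], blocks, replace = TRUE)
  # gap between consecutive blocks: (u5, u3) with at least one positive
  gaps <- lapply(seq_len(max(blocks - 1, 0)), function(i) {
    repeat {
      g <- c(sample(0:bulge_max, 1), sample(0:bulge_max, 1))
      if (sum(g) > 0) return(g)
    }
  })
  left <- character(0); right <- character(0)
  for (b in seq_len(blocks)) {
    left <- c(left, rep("(", bps[b]))
    right <- c(rep(")", bps[b]), right)
    if (b < blocks) {
      left <- c(left, rep(".", gaps[[b]][1]))
      right <- c(rep(".", gaps[[b]][2]), right)
    }
  }
  db <- paste(c(left, rep(".", loop_len), right), collapse = "")
  u5 <- vapply(gaps, `[`, 0L, 1)
  u3 <- vapply(gaps, `[`, 0L, 2)
  list(db = db,
       stem_bp = sum(bps),
       loop_len = loop_len,
       hairpin_len = nchar(db),
       max_bulge = if (blocks > 1) max(pmax(u5, u3)) else 0L,
       biased = if (blocks > 1) xor(u5 > 0, u3 > 0) else logical(0),
       gap_u5 = u5, gap_u3 = u3, block_bp = bps)
}

# straightforward second implementation of the stem-ladder decomposition for
# single-hairpin structures (no multiloops): pairs sorted outermost-first
reparse_simple_hairpin <- function(db, mature_interval) {
  ch <- strsplit(db, "")[[1]]
  st <- integer(0); pairs <- list()
  pt <- integer(length(ch))
  for (i in seq_along(ch)) {
    if (ch[i] == "(") st <- c(st, i)
    if (ch[i] == ")") {
      j <- st[length(st)]; st <- st[-length(st)]
      pairs[[length(pairs) + 1L]] <- c(j, i)
      pt[i] <- j; pt[j] <- i
    }
  }
  P <- do.call(rbind, pairs)
  P <- P[order(P[, 1]), , drop = FALSE]
  stem_bp <- nrow(P)
  a_out <- P[1, 1]; b_out <- P[1, 2]
  i0 <- P[stem_bp, 1]; j0 <- P[stem_bp, 2]
  loop_len <- j0 - i0 - 1L
  hairpin_len <- b_out - a_out + 1L
  max_bulge <- 0L; biased_bulges <- list()
  if (stem_bp > 1) {
    for (k in seq_len(stem_bp - 1L)) {
      u5 <- P[k + 1, 1] - P[k, 1] - 1L
      u3 <- P[k, 2] - P[k + 1, 2] - 1L
      if (u5 + u3 > 0) {
        max_bulge <- max(max_bulge, u5, u3)
        if (xor(u5 > 0, u3 > 0)) {
          pos <- if (u5 > 0) (P[k, 1] + 1L):(P[k + 1, 1] - 1L)
                 else (P[k + 1, 2] + 1L):(P[k, 2] - 1L)
          biased_bulges[[length(biased_bulges) + 1L]] <- pos
        }
      }
    }
  }
  mpos <- mature_interval[1]:mature_interval[2]
  unp <- pt[mpos] == 0
  r <- rle(unp)
  in_stem <- mpos >= a_out & mpos <= b_out & (mpos <= i0 | mpos >= j0)
  bov <- vapply(biased_bulges, function(p) sum(p %in% mpos), 0L)
  list(stem_bp = stem_bp, loop_len = loop_len, hairpin_len = hairpin_len,
       max_stem_bulge_nt = max_bulge,
       mature_errors = sum(unp), mature_bp = sum(!unp),
       max_mature_bulge_nt = if (any(r$values)) max(r$lengths[r$values]) else 0L,
       mature_in_stem_pct = 100 * mean(in_stem),
       mature_biased_bulges = sum(bov > 0),
       mature_biased_errors = if (length(bov)) max(bov) else 0L)
}

# closed-form pooled-variance t statistic
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# closed-form one-way ANOVA F
anova_f <- function(groups) {
  n <- sum(lengths(groups)); k <- length(groups)
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  (ssb / (k - 1)) / (ssw / (n - k))
}
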