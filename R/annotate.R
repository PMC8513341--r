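ANNOTATION_HIERARCHY <- c("rRNA", "tRNA", "snRNA", "snoRNA", "other_Rfam",
                          "repeat")

#' Partition unique reads into ncRNA/repeat categories
#'
#' Each unique sequence is matched (end-to-end, at most one mismatch, both
#' strands) against the contaminant references; a sequence hitting more than
#' one class is assigned by a fixed most-conserved-first hierarchy
#' (rRNA > tRNA > snRNA > snoRNA > other_Rfam > repeat). Non-hitting
#' sequences are `unannotated` and carried forward to miRNA identification.
#'
#' Contaminant reads are matched as substrings of the class references (an
#' 18-25 nt fragment of an rRNA maps within it), so hits are found with the
#' seed index rather than equal-length comparison.
#'
#' @param reads data frame `sequence`/`count`, or a `cleaned_library`.
#' @param contaminant_index [build_index()] over the contaminant references.
#' @param classes data frame mapping reference `id` to `class` (one of the
#'   hierarchy names); references absent from it count as `other_Rfam`.
#' @param hierarchy category precedence, highest first.
#' @return list of class `srna_annotation`: `assignment` (data frame
#'   `sequence`, `count`, `category`), `table` (category counts and
#'   percentages on the abundance scale), and `unannotated` (the forwarded
#'   subset of `reads`).
#' @export
classify_reads <- function(reads, contaminant_index, classes,
                           hierarchy = ANNOTATION_HIERARCHY) {
  if (inherits(reads, "cleaned_library")) reads <- reads$reads
  category <- rep("unannotated", nrow(reads))
  if (nrow(reads) > 0) {
    cls_of <- stats::setNames(classes$class, classes$id)
    for (i in seq_len(nrow(reads))) {
      hits <- align_read(reads$sequence[i], contaminant_index,
                         max_mismatch = 1L)
      if (nrow(hits) == 0) next
      hit_cls <- cls_of[hits$reference]
      hit_cls[is.na(hit_cls)] <- "other_Rfam"
      ranks <- match(hit_cls, hierarchy)
      category[i] <- hierarchy[min(ranks, na.rm = TRUE)]
    }
  }
  assignment <- data.frame(sequence = reads$sequence, count = reads$count,
                           category = category, stringsAsFactors = FALSE)
  lev <- c(hierarchy, "unannotated")
  counts <- tapply(assignment$count, factor(assignment$category, lev),
                   sum, default = 0)
  tab <- data.frame(category = lev, reads = as.numeric(counts),
                    percent = if (sum(counts) > 0)
                      100 * as.numeric(counts) / sum(counts) else 0,
                    stringsAsFactors = FALSE)
  structure(list(assignment = assignment, table = tab,
                 unannotated = reads[category == "unannotated", ,
                                     drop = FALSE]),
            class = "srna_annotation")
}

#' @export
print.srna_annotation <- function(x, ...) {
  cat("sRNA category assignment (abundance basis):\n")
  t <- x$table[x$table$reads > 0, ]
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-12s %10d  (%.2f%%)\n", t$category[i],
                as.integer(t$reads[i]), t$percent[i]))
  invisible(x)
}
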