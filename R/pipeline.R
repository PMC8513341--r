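#' Merge cleaned libraries into a unique-sequence count matrix
#'
#' @param cleaned list of `cleaned_library` objects (one per library).
#' @return integer matrix, union of unique sequences x libraries.
#' @export
merge_libraries <- function(cleaned) {
  libs <- vapply(cleaned, function(x) x$stats$library, "")
  seqs <- sort(unique(unlist(lapply(cleaned, function(x) x$reads$sequence))))
  m <- matrix(0L, nrow = length(seqs), ncol = length(libs),
              dimnames = list(seqs, libs))
  for (i in seq_along(cleaned)) {
    r <- cleaned[[i]]$reads
    m[r$sequence, i] <- r$count
  }
  m
}

#' Run the full small-RNA analysis on a set of FASTQ libraries
#'
#' Cleaning and collapsing, ncRNA/repeat classification, known miRNA
#' identification, opposite-arm detection, novel miRNA discovery through
#' the eleven-criterion hairpin screen, median-reference regression
#' normalization, and (optionally) pairwise t-tests between lines at each
#' stage plus per-line stage ANOVA.
#'
#' @param fastq_paths named character vector of FASTQ files (names are
#'   library ids) or the data frame returned by [simulate_libraries()].
#' @param genome named character vector of contigs (or FASTA path).
#' @param mature_db,precursor_db,precursor_info known-miRNA databases (see
#'   [identify_known()]).
#' @param contaminants named character vector of ncRNA/repeat references.
#' @param contaminant_info data frame `id`/`class` for the references.
#' @param design optional data frame `library`/`line`/`stage`/`replicate`
#'   enabling the differential-expression stage.
#' @param cleaning a [cleaning_config()].
#' @param criteria a [hairpin_criteria()].
#' @param de a [de_config()].
#' @return list of class `srna_pipeline` with elements `stats`, `summary`,
#'   `counts` (unique sequences), `annotation`, `known`, `opposite`,
#'   `novel`, `expression` (miRNA x library raw), `norm` (`mrn_fit`),
#'   `de` (list of `mirna_de` tables), `pca`.
#' @export
run_srna_pipeline <- function(fastq_paths, genome, mature_db, precursor_db,
                              precursor_info, contaminants, contaminant_info,
                              design = NULL,
                              cleaning = cleaning_config(),
                              criteria = hairpin_criteria(),
                              de = de_config()) {
  if (is.data.frame(fastq_paths)) {
    design <- if (is.null(design)) fastq_paths else design
    fastq_paths <- stats::setNames(fastq_paths$path, fastq_paths$library)
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_fasta(genome)

  cleaned <- lapply(names(fastq_paths), function(lib)
    clean_reads(fastq_paths[[lib]], cleaning, library = lib))
  stats <- do.call(rbind, lapply(cleaned, function(x) x$stats))
  counts <- merge_libraries(cleaned)

  contaminant_index <- build_index(contaminants)
  ann <- classify_reads(data.frame(sequence = rownames(counts),
                                   count = rowSums(counts),
                                   stringsAsFactors = FALSE),
                        contaminant_index, contaminant_info)
  unann <- counts[ann$assignment$category == "unannotated", , drop = FALSE]

  known <- identify_known(unann, mature_db, precursor_db, precursor_info,
                          genome = NULL)
  rest <- unann[!(rownames(unann) %in% known$assigned), , drop = FALSE]
  opp <- detect_opposite_arm(rest, precursor_db, precursor_info)
  rest <- rest[!(rownames(rest) %in% opp$assigned), , drop = FALSE]

  genome_index <- build_index(genome)
  novel <- discover_novel(rest, genome_index, genome, criteria)

  expression <- rbind(known$counts, opp$counts, novel$counts)
  norm <- tryCatch(normalize_counts(expression),
                   error = function(e) NULL)

  de_res <- NULL; pca <- NULL
  if (!is.null(design) && !is.null(norm)) {
    nm <- norm$normalized
    de_res <- list()
    for (st in unique(design$stage)) {
      a <- design$library[design$line == "HO" & design$stage == st]
      b <- design$library[design$line == "LO" & design$stage == st]
      if (length(a) >= 2 && length(b) >= 2)
        de_res[[sprintf("HO%s_vs_LO%s", st, st)]] <-
          pairwise_ttest(nm, a, b, de,
                         contrast = sprintf("HO%s_vs_LO%s", st, st))
    }
    for (ln in unique(design$line)) {
      grp <- split(design$library[design$line == ln],
                   design$stage[design$line == ln])
      if (length(grp) >= 2 && all(lengths(grp) >= 2))
        de_res[[paste0(ln, "_stages")]] <-
          stage_anova(nm, lapply(grp, function(g) match(g, colnames(nm))),
                      de, contrast = paste0(ln, "_stages"))
    }
    if (ncol(nm) >= 3) pca <- sample_pca(nm)
  }

  structure(list(stats = stats, summary = summarize_libraries(stats),
                 counts = counts, annotation = ann, known = known,
                 opposite = opp, novel = novel, expression = expression,
                 norm = norm, de = de_res, pca = pca),
            class = "srna_pipeline")
}

#' @export
print.srna_pipeline <- function(x, ...) {
  print(x$summary)
  print(x$annotation)
  print(x$known)
  print(x$novel)
  if (!is.null(x$norm))
    cat(sprintf("normalized with factors in [%.3f, %.3f]\n",
                min(x$norm$factors), max(x$norm$factors)))
  if (!is.null(x$de))
    for (nm in names(x$de))
      cat(sprintf("  %s: %d significant miRNAs\n", nm,
                  sum(x$de[[nm]]$significant)))
  invisible(x)
}
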