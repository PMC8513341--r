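#' Configuration for the synthetic small-RNA study generator
#'
#' Builds the parameter set for [generate_reference()] and
#' [simulate_libraries()]. Defaults emulate a two-line (HO/LO, high/low oil)
#' by four-stage (40/54/68/81 days after anthesis) seed-development design
#' with two biological replicates per sample, i.e. 16 single-end 50 bp
#' libraries.
#'
#' @param genome_length total genome length in nt (split into `n_contigs`
#'   contigs). Must be large enough to place all planted loci with >= 120 nt
#'   flanks.
#' @param n_contigs number of genome contigs.
#' @param n_known_mirnas number of miRNAs present in the mature/precursor
#'   databases (and planted in the genome).
#' @param n_novel_mirnas number of genome-only miRNA loci (absent from the
#'   databases) whose hairpins satisfy all eleven structural criteria by
#'   construction.
#' @param n_decoys number of planted decoy windows that violate the hairpin
#'   criteria (half structurally unpairable, half random certified-failing).
#' @param n_contaminant_refs named counts of reference sequences per
#'   contaminant class (`rRNA`, `tRNA`, `snRNA`, `snoRNA`, `repeat`).
#' @param n_transcripts number of transcript sequences carrying planted
#'   miRNA target sites.
#' @param library_design data frame with columns `line`, `stage`,
#'   `replicate`; one row per library.
#' @param reads_per_library reads simulated per library (library size is
#'   realized exactly).
#' @param adapter_sequence 3' adapter ligated to every insert (default: the
#'   standard TruSeq small-RNA 3' adapter).
#' @param contaminant_fraction,adapter_dimer_fraction,junk_fraction expected
#'   proportions of contaminant-derived reads, adapter-dimer reads and
#'   low-complexity junk reads; the remainder are miRNA-derived. Must sum to
#'   at most 1.
#' @param base_abundance_log_mean,base_abundance_log_sd log-normal
#'   (natural-log) parameters of per-miRNA expected counts per library.
#' @param nb_dispersion negative-binomial dispersion of per-library counts
#'   around each miRNA's expected abundance.
#' @param planted_log2fc absolute log2 fold change planted on differentially
#'   expressed miRNAs.
#' @param de_fraction fraction of miRNAs planted as differentially expressed
#'   per contrast (between-line, and late-vs-early stage; disjoint subsets).
#' @param mature_lengths,mature_length_probs mature length distribution
#'   (24-nt dominated, as in plant embryo sRNA populations).
#' @param first_u_prob probability that a mature starts with 5' U.
#' @param seed integer RNG seed; all outputs are deterministic given it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 200000L,
                       n_contigs = 4L,
                       n_known_mirnas = 30L,
                       n_novel_mirnas = 20L,
                       n_decoys = 20L,
                       n_contaminant_refs = c(rRNA = 5L, tRNA = 5L,
                                              snRNA = 5L, snoRNA = 5L,
                                              `repeat` = 5L),
                       n_transcripts = 50L,
                       library_design = default_library_design(),
                       reads_per_library = 50000L,
                       adapter_sequence = "TGGAATTCTCGGGTGCCAAGG",
                       contaminant_fraction = 0.10,
                       adapter_dimer_fraction = 0.05,
                       junk_fraction = 0.02,
                       base_abundance_log_mean = log(150),
                       base_abundance_log_sd = 1.0,
                       nb_dispersion = 0.05,
                       planted_log2fc = 2,
                       de_fraction = 0.2,
                       mature_lengths = 20:24,
                       mature_length_probs = c(0.05, 0.15, 0.05, 0.05, 0.70),
                       first_u_prob = 0.8,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_contigs = as.integer(n_contigs),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_novel_mirnas = as.integer(n_novel_mirnas),
              n_decoys = as.integer(n_decoys),
              n_contaminant_refs = n_contaminant_refs,
              n_transcripts = as.integer(n_transcripts),
              library_design = library_design,
              reads_per_library = as.integer(reads_per_library),
              adapter_sequence = toupper(adapter_sequence),
              contaminant_fraction = contaminant_fraction,
              adapter_dimer_fraction = adapter_dimer_fraction,
              junk_fraction = junk_fraction,
              base_abundance_log_mean = base_abundance_log_mean,
              base_abundance_log_sd = base_abundance_log_sd,
              nb_dispersion = nb_dispersion,
              planted_log2fc = planted_log2fc,
              de_fraction = de_fraction,
              mature_lengths = as.integer(mature_lengths),
              mature_length_probs = mature_length_probs,
              first_u_prob = first_u_prob,
              seed = as.integer(seed))
  fr <- c(cfg$contaminant_fraction, cfg$adapter_dimer_fraction,
          cfg$junk_fraction, cfg$de_fraction, cfg$first_u_prob)
  if (any(fr < 0 | fr > 1))
    stop("all fractions must lie in [0, 1]")
  if (cfg$contaminant_fraction + cfg$adapter_dimer_fraction +
      cfg$junk_fraction > 1)
    stop("read-class fractions must sum to at most 1")
  if (cfg$reads_per_library <= 0)
    stop("reads_per_library must be positive")
  if (!all(c("line", "stage", "replicate") %in% names(cfg$library_design)))
    stop("library_design needs columns line, stage, replicate")
  n_loci <- cfg$n_known_mirnas + cfg$n_novel_mirnas + cfg$n_decoys
  # each locus needs its sequence (< ~320 nt) plus 120 nt flanks either side
  if (cfg$genome_length < n_loci * 600L)
    stop("genome_length too small to place ", n_loci,
         " loci with 120 nt flanks; need at least ", n_loci * 600L, " nt")
  class(cfg) <- "sim_config"
  cfg
}

#' Default 16-library design: 2 lines x 4 stages x 2 replicates
#' @return data frame with columns `line`, `stage`, `replicate`, `library`.
#' @export
default_library_design <- function() {
  d <- expand.grid(replicate = 1:2, stage = c(40L, 54L, 68L, 81L),
                   line = c("HO", "LO"), stringsAsFactors = FALSE)
  d <- d[, c("line", "stage", "replicate")]
  d$library <- sprintf("%s%d_%d", d$line, d$stage, d$replicate)
  d
}

# Build a perfect-stem hairpin around a mature sequence.
# Returns precursor sequence plus the mature's 0-based offset within it.
# A 2-nt bulge is inserted into the star arm for realism when `bulge`.
build_hairpin <- function(mature, arm = c("p5", "p3"), bulge = TRUE) {
  arm <- match.arg(arm)
  ext <- random_seq(1, 8)
  loop <- paste(sample(c("A", "C"), 10, replace = TRUE), collapse = "")
  lm <- nchar(mature)
  if (arm == "p5") {
    star <- revcomp(paste0(ext, mature))
    if (bulge) {
      at <- sample(3:(nchar(star) - 3), 1)
      star <- paste0(substr(star, 1, at), random_seq(1, 2),
                     substr(star, at + 1, nchar(star)))
    }
    pre <- paste0(ext, mature, loop, star)
    off <- 8L
  } else {
    star <- revcomp(mature)
    if (bulge) {
      at <- sample(3:(lm - 3), 1)
      star <- paste0(substr(star, 1, at), random_seq(1, 2),
                     substr(star, at + 1, nchar(star)))
    }
    pre <- paste0(ext, star, loop, mature, revcomp(ext))
    off <- 8L + nchar(star) + 10L
  }
  list(seq = pre, mature_offset = off, arm = arm)
}

sample_matures <- function(n, cfg) {
  lens <- sample(cfg$mature_lengths, n, replace = TRUE,
                 prob = cfg$mature_length_probs)
  vapply(seq_len(n), function(i) {
    first <- if (stats::runif(1) < cfg$first_u_prob) "U"
             else sample(c("A", "C", "G"), 1)
    paste0(first, random_seq(1, lens[i] - 1L))
  }, "")
}

#' Generate the synthetic reference bundle
#'
#' Builds, deterministically from `config$seed`: a multi-contig genome with
#' planted known/novel miRNA hairpin loci and criteria-violating decoy
#' windows (all with >= 120 nt flanks), mature and precursor databases for
#' the known miRNAs, contaminant ncRNA/repeat references, transcripts with
#' planted miRNA target sites (perfect complements carrying 0-3 scored
#' defects outside the doubled 2-13 region), a gene-to-term annotation map,
#' and the ground-truth tables needed to validate every downstream stage.
#'
#' Every planted novel hairpin is re-folded and re-measured during
#' construction and is regenerated (bounded retries) until it satisfies all
#' eleven structural criteria; decoys are certified to violate them.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `srna_sim`: a list with elements `config`,
#'   `genome`, `mature_db`, `precursor_db`, `precursor_info`, `contaminants`,
#'   `contaminant_info`, `transcripts`, `annotation`, and `truth` (loci,
#'   per-miRNA base means, DE flags, planted target sites).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  cfg <- config
  n_mir <- cfg$n_known_mirnas + cfg$n_novel_mirnas

  matures <- unique(sample_matures(n_mir * 2L, cfg))
  tries <- 0L
  while (length(matures) < n_mir && tries < 10L) {
    matures <- unique(c(matures, sample_matures(n_mir, cfg)))
    tries <- tries + 1L
  }
  if (length(matures) < n_mir)
    stop("could not draw ", n_mir, " distinct mature sequences")
  matures <- matures[seq_len(n_mir)]
  known_ids <- sprintf("pmi-miR%03d", seq_len(cfg$n_known_mirnas))
  novel_ids <- if (cfg$n_novel_mirnas > 0)
    sprintf("novel-locus%03d", seq_len(cfg$n_novel_mirnas)) else character()
  ids <- c(known_ids, novel_ids)
  classes <- rep(c("known", "novel"),
                 c(cfg$n_known_mirnas, cfg$n_novel_mirnas))

  crit <- hairpin_criteria()
  hairpins <- vector("list", n_mir)
  for (i in seq_len(n_mir)) {
    arm <- sample(c("p5", "p3"), 1)
    for (try in 1:30) {
      hp <- build_hairpin(matures[i], arm = arm)
      fr <- fold_hairpin(hp$seq)
      ms <- parse_structure(fr, c(hp$mature_offset + 1L,
                                  hp$mature_offset + nchar(matures[i])))
      ev <- evaluate_hairpin_criteria(ms, crit)
      if (ev$verdict) break
      if (try == 30)
        stop("failed to construct a criteria-passing hairpin for locus ", i)
    }
    hairpins[[i]] <- hp
  }

  # star (opposite-arm) species for the known precursors: a 21-nt read from
  # the arm across the terminal loop from the annotated mature
  stars <- do.call(rbind, lapply(seq_len(cfg$n_known_mirnas), function(i) {
    hp <- hairpins[[i]]
    lm <- nchar(matures[i])
    if (hp$arm == "p5") {
      s0 <- 8L + lm + 10L
      star <- substr(hp$seq, s0 + 1L, s0 + 21L)
      side <- "p3"
    } else {
      star <- substr(hp$seq, 9L, 29L)
      side <- "p5"
    }
    data.frame(mature_id = sprintf("pmi-miR%03d", i),
               sequence = star, side = side, stringsAsFactors = FALSE)
  }))
  if (!is.null(stars)) {
    stars$id <- paste0(stars$mature_id, "-star")
  } else {
    stars <- data.frame(mature_id = character(0), sequence = character(0),
                        side = character(0), id = character(0))
  }

  # decoys: first half structurally unpairable (A/G alphabet only, so no
  # canonical or wobble pair can form), second half random windows certified
  # at build time to violate at least one criterion.
  n_dec <- cfg$n_decoys
  decoy_ids <- if (n_dec > 0) sprintf("decoy%03d", seq_len(n_dec)) else character()
  decoys <- vector("list", n_dec)
  for (i in seq_len(n_dec)) {
    if (i <= ceiling(n_dec / 2)) {
      mat <- random_seq(1, 21, bases = c("A", "G"))
      ctx5 <- random_seq(1, 130, bases = c("A", "G"))
      ctx3 <- random_seq(1, 130, bases = c("A", "G"))
      decoys[[i]] <- list(seq = paste0(ctx5, mat, ctx3), mature = mat,
                          mature_offset = 130L, kind = "unpairable")
    } else {
      ok <- FALSE
      for (try in 1:30) {
        mat <- random_seq(1, 21)
        ctx5 <- random_seq(1, 130)
        ctx3 <- random_seq(1, 130)
        win <- paste0(substr(ctx5, 11, 130), mat, substr(ctx3, 1, 120))
        fr <- fold_hairpin(win)
        ms <- parse_structure(fr, c(121L, 141L))
        if (!evaluate_hairpin_criteria(ms, crit)$verdict) { ok <- TRUE; break }
      }
      if (!ok) stop("failed to construct a criteria-violating decoy window")
      decoys[[i]] <- list(seq = paste0(ctx5, mat, ctx3), mature = mat,
                          mature_offset = 130L, kind = "random_fail")
    }
  }

  # genome assembly: random background contigs, loci planted in evenly
  # spaced slots with jitter and >= 120 nt flanks
  contig_len <- cfg$genome_length %/% cfg$n_contigs
  contigs <- stats::setNames(random_seq(cfg$n_contigs, rep(contig_len,
                                                           cfg$n_contigs)),
                             sprintf("contig%d", seq_len(cfg$n_contigs)))
  inserts <- c(lapply(seq_len(n_mir), function(i) {
    list(id = ids[i], class = classes[i], seq = hairpins[[i]]$seq,
         mature = matures[i], mature_offset = hairpins[[i]]$mature_offset,
         arm = hairpins[[i]]$arm)
  }), lapply(seq_len(n_dec), function(i) {
    list(id = decoy_ids[i], class = "decoy", seq = decoys[[i]]$seq,
         mature = decoys[[i]]$mature,
         mature_offset = decoys[[i]]$mature_offset, arm = NA_character_)
  }))
  inserts <- inserts[sample(length(inserts))]
  n_ins <- length(inserts)
  per_contig <- split(seq_len(n_ins),
                      rep(seq_len(cfg$n_contigs), length.out = n_ins))
  loci <- vector("list", n_ins)
  for (ci in seq_len(cfg$n_contigs)) {
    idx <- per_contig[[ci]]
    if (length(idx) == 0) next
    usable <- contig_len - 300L
    slot_w <- usable %/% length(idx)
    max_w <- max(vapply(inserts[idx], function(x) nchar(x$seq), 0L))
    if (slot_w < max_w + 260L)
      stop("cannot place ", length(idx), " loci in contig ", ci,
           ": slots of ", slot_w, " nt are narrower than locus + 120 nt flanks")
    for (k in seq_along(idx)) {
      ins <- inserts[[idx[k]]]
      w <- nchar(ins$seq)
      jitter <- sample.int(max(slot_w - w - 10L, 1L), 1)
      start <- 150L + (k - 1L) * slot_w + jitter # 1-based
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "+") ins$seq else revcomp(ins$seq)
      ctg <- contigs[[ci]]
      contigs[[ci]] <- paste0(substr(ctg, 1, start - 1L), planted,
                              substr(ctg, start + w, contig_len))
      if (strand == "+") {
        m_start <- start + ins$mature_offset
      } else {
        m_start <- start + w - ins$mature_offset - nchar(ins$mature)
      }
      loci[[idx[k]]] <- data.frame(
        id = ins$id, class = ins$class,
        contig = names(contigs)[ci],
        start = start - 1L, end = start - 1L + w, strand = strand,
        arm = ins$arm, mature_seq = ins$mature,
        mature_start = m_start - 1L,
        mature_end = m_start - 1L + nchar(ins$mature),
        precursor_seq = ins$seq, stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, loci)

  mature_db <- stats::setNames(matures[seq_len(cfg$n_known_mirnas)], known_ids)
  pre_ids <- sub("miR", "MIR", known_ids)
  precursor_db <- stats::setNames(
    vapply(hairpins[seq_len(cfg$n_known_mirnas)], `[[`, "", "seq"), pre_ids)
  precursor_info <- data.frame(
    precursor_id = pre_ids, mature_id = known_ids,
    mature_offset = vapply(hairpins[seq_len(cfg$n_known_mirnas)], `[[`, 0L,
                           "mature_offset"),
    mature_length = nchar(mature_db),
    arm = vapply(hairpins[seq_len(cfg$n_known_mirnas)], `[[`, "", "arm"),
    stringsAsFactors = FALSE)

  contam_classes <- rep(names(cfg$n_contaminant_refs), cfg$n_contaminant_refs)
  contam_ids <- unlist(lapply(names(cfg$n_contaminant_refs), function(cl)
    sprintf("%s_%d", cl, seq_len(cfg$n_contaminant_refs[[cl]]))))
  contaminants <- stats::setNames(
    random_seq(length(contam_ids), sample(80:150, length(contam_ids),
                                          replace = TRUE)), contam_ids)
  contaminant_info <- data.frame(id = contam_ids, class = contam_classes,
                                 stringsAsFactors = FALSE)

  # DE planting: disjoint subsets for between-line and late-vs-early effects
  n_de <- round(cfg$de_fraction * n_mir)
  de_pool <- sample(ids, min(2L * n_de, n_mir))
  line_de <- de_pool[seq_len(min(n_de, length(de_pool)))]
  stage_de <- setdiff(de_pool, line_de)
  de_sign <- stats::setNames(sample(c(1, -1), length(c(line_de, stage_de)),
                                    replace = TRUE), c(line_de, stage_de))
  base_means <- stats::setNames(
    stats::rlnorm(n_mir, cfg$base_abundance_log_mean,
                  cfg$base_abundance_log_sd), ids)
  # depth floor on DE miRNAs so planted effects are detectable at this depth
  floor_mean <- 200 * 2^abs(cfg$planted_log2fc) / 2
  base_means[c(line_de, stage_de)] <- pmax(base_means[c(line_de, stage_de)],
                                           floor_mean)
  decoy_means <- stats::setNames(rep(30, n_dec), decoy_ids)

  design <- cfg$library_design
  if (is.null(design$library))
    design$library <- sprintf("%s%d_%d", design$line, design$stage,
                              design$replicate)
  mu <- matrix(base_means, nrow = n_mir, ncol = nrow(design),
               dimnames = list(ids, design$library))
  for (m in line_de)
    mu[m, design$line == "HO"] <- mu[m, design$line == "HO"] *
      2^(de_sign[m] * cfg$planted_log2fc)
  for (m in stage_de)
    mu[m, design$stage >= 68] <- mu[m, design$stage >= 68] *
      2^(de_sign[m] * cfg$planted_log2fc)

  de <- rbind(
    if (length(line_de)) data.frame(id = line_de, contrast = "HO_vs_LO",
                                    log2fc = de_sign[line_de] * cfg$planted_log2fc,
                                    stringsAsFactors = FALSE),
    if (length(stage_de)) data.frame(id = stage_de, contrast = "late_vs_early",
                                     log2fc = de_sign[stage_de] * cfg$planted_log2fc,
                                     stringsAsFactors = FALSE))

  # transcripts with planted target sites
  tx_ids <- sprintf("tx%04d", seq_len(cfg$n_transcripts))
  tx_len <- sample(300:500, cfg$n_transcripts, replace = TRUE)
  transcripts <- stats::setNames(random_seq(cfg$n_transcripts, tx_len), tx_ids)
  targeted <- unique(c(line_de, stage_de,
                       sample(ids, min(10L, n_mir))))
  tgt_rows <- list()
  for (m in targeted) {
    tx <- sample(tx_ids, 1)
    mat <- c(mature_db, stats::setNames(
      matures[-seq_len(cfg$n_known_mirnas)], novel_ids))[[m]]
    nd <- sample(0:3, 1)
    site <- make_target_site(mat, nd)
    pos <- sample.int(nchar(transcripts[[tx]]) - nchar(site$seq) - 10L, 1) + 5L
    transcripts[[tx]] <- paste0(substr(transcripts[[tx]], 1, pos - 1L),
                                site$seq,
                                substr(transcripts[[tx]],
                                       pos + nchar(site$seq),
                                       nchar(transcripts[[tx]])))
    tgt_rows[[length(tgt_rows) + 1L]] <-
      data.frame(mirna = m, transcript = tx, start = pos,
                 end = pos + nchar(site$seq) - 1L,
                 expected_score = site$score, stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, tgt_rows)

  # annotation map; one term enriched among targeted transcripts
  go_terms <- sprintf("GO:%07d", 1:10)
  kegg_terms <- sprintf("ko%05d", 1:5)
  all_terms <- c(go_terms, kegg_terms)
  ann <- do.call(rbind, lapply(tx_ids, function(g) {
    data.frame(gene = g,
               term = sample(all_terms, sample(1:3, 1)),
               stringsAsFactors = FALSE)
  }))
  enr_term <- "GO:1000001"
  tgt_tx <- unique(targets$transcript)
  enr_genes <- unique(c(sample(tgt_tx, ceiling(0.8 * length(tgt_tx))),
                        sample(setdiff(tx_ids, tgt_tx),
                               ceiling(0.1 * (cfg$n_transcripts - length(tgt_tx))))))
  ann <- rbind(ann, data.frame(gene = enr_genes, term = enr_term,
                               stringsAsFactors = FALSE))
  ann <- unique(ann)
  ann$name <- paste("term", ann$term)
  rownames(ann) <- NULL

  out <- list(config = cfg, genome = contigs, mature_db = mature_db,
              precursor_db = precursor_db, precursor_info = precursor_info,
              contaminants = contaminants,
              contaminant_info = contaminant_info,
              transcripts = transcripts, annotation = ann,
              truth = list(loci = loci, base_means = base_means,
                           decoy_means = decoy_means, stars = stars,
                           star_mean = 25,
                           expected_mu = mu, de = de, targets = targets,
                           enriched_term = enr_term, design = design))
  class(out) <- "srna_sim"
  out
}

# Build a target site as the reverse complement of a mature, then introduce
# `n_defects` scored defects (mismatch 1 or G:U wobble 0.5) at miRNA
# positions outside the doubled 2..13 region; returns the site and its exact
# expected penalty score.
make_target_site <- function(mature, n_defects = 0) {
  lm <- nchar(mature)
  site <- strsplit(revcomp(mature), "")[[1]]
  mir <- strsplit(mature, "")[[1]]
  score <- 0
  if (n_defects > 0) {
    pool <- setdiff(14:lm, integer(0))
    pos <- sample(pool, min(n_defects, length(pool)))
    for (i in pos) {
      j <- lm - i + 1L # site index pairing miRNA position i
      if (mir[i] == "G" && stats::runif(1) < 0.5) {
        site[j] <- "U"; score <- score + 0.5        # wobble G:U
      } else if (mir[i] == "U" && stats::runif(1) < 0.5) {
        site[j] <- "G"; score <- score + 0.5        # wobble U:G
      } else {
        bad <- setdiff(RNA_BASES, c(site[j], switch(mir[i],
          A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")))
        site[j] <- sample(bad, 1); score <- score + 1
      }
    }
  }
  list(seq = paste(site, collapse = ""), score = score)
}

#' @export
print.srna_sim <- function(x, ...) {
  cat("Synthetic sRNA study reference bundle\n")
  cat(sprintf("  genome: %d contigs, %s nt total\n", length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ",")))
  cat(sprintf("  planted loci: %d known, %d novel, %d decoy\n",
              sum(x$truth$loci$class == "known"),
              sum(x$truth$loci$class == "novel"),
              sum(x$truth$loci$class == "decoy")))
  cat(sprintf("  contaminant refs: %d; transcripts: %d; libraries: %d\n",
              length(x$contaminants), length(x$transcripts),
              nrow(x$config$library_design)))
  invisible(x)
}

#' Simulate FASTQ libraries from a reference bundle
#'
#' Each read is an insert (a planted mature, a contaminant fragment, a
#' low-complexity junk sequence, or nothing for an adapter dimer) with the 3'
#' adapter appended, padded and truncated to 50 nt, with constant Phred+33
#' Q35 qualities. Per-miRNA counts follow a gamma-weighted multinomial (so
#' marginal counts are negative-binomial around the planted means, with the
#' planted log2 fold changes applied to DE miRNAs), and each library's size
#' equals `reads_per_library` exactly.
#'
#' @param sim an `srna_sim` bundle from [generate_reference()].
#' @param dir output directory for the FASTQ files (created if needed).
#' @return data frame with one row per library: `library`, `line`, `stage`,
#'   `replicate`, `path`, and realized per-class read counts; the realized
#'   per-mature insert counts are attached as attribute `mirna_counts`
#'   (matrix miRNA x library).
#' @export
simulate_libraries <- function(sim, dir) {
  stopifnot(inherits(sim, "srna_sim"))
  cfg <- sim$config
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  design <- sim$truth$design
  mu <- rbind(sim$truth$expected_mu,
              matrix(sim$truth$decoy_means, nrow = length(sim$truth$decoy_means),
                     ncol = nrow(design),
                     dimnames = list(names(sim$truth$decoy_means),
                                     design$library)),
              matrix(sim$truth$star_mean, nrow = nrow(sim$truth$stars),
                     ncol = nrow(design),
                     dimnames = list(sim$truth$stars$id, design$library)))
  mat_seqs <- c(stats::setNames(sim$truth$loci$mature_seq, sim$truth$loci$id),
                stats::setNames(sim$truth$stars$sequence, sim$truth$stars$id))
  mat_seqs <- mat_seqs[rownames(mu)]
  filler <- "ATCTCGTATGCCGTCTTCTGCTTGAAAAAAAAAAAAAAAAAAAAAAAAAA"
  adapter <- cfg$adapter_sequence
  contam <- as_dna(sim$contaminants)
  counts <- matrix(0L, nrow = nrow(mu), ncol = nrow(design),
                   dimnames = dimnames(mu))
  rows <- vector("list", nrow(design))
  for (li in seq_len(nrow(design))) {
    set.seed(derive_seed(cfg$seed, 100L + li))
    n <- cfg$reads_per_library
    cls <- stats::rmultinom(1, n, c(dimer = cfg$adapter_dimer_fraction,
                                    junk = cfg$junk_fraction,
                                    contaminant = cfg$contaminant_fraction,
                                    mirna = 1 - cfg$adapter_dimer_fraction -
                                      cfg$junk_fraction -
                                      cfg$contaminant_fraction))[, 1]
    # miRNA inserts: gamma-weighted multinomial ~ negative binomial marginals
    w <- stats::rgamma(nrow(mu), shape = 1 / cfg$nb_dispersion,
                       scale = mu[, li] * cfg$nb_dispersion)
    mir_idx <- sample.int(nrow(mu), cls["mirna"], replace = TRUE,
                          prob = w / sum(w))
    tab <- tabulate(mir_idx, nbins = nrow(mu))
    counts[, li] <- tab
    mir_inserts <- as_dna(mat_seqs[mir_idx])
    # contaminant fragments
    c_ref <- sample(seq_along(contam), cls["contaminant"], replace = TRUE)
    c_len <- sample(18:25, cls["contaminant"], replace = TRUE)
    c_start <- floor(stats::runif(cls["contaminant"]) *
                       (nchar(contam)[c_ref] - c_len + 1L)) + 1L
    contam_inserts <- substr(contam[c_ref], c_start, c_start + c_len - 1L)
    # junk: homopolymer-dominated and dinucleotide repeats
    nj <- cls[["junk"]]
    junk_inserts <- character(nj)
    if (nj > 0) {
      half <- nj %/% 2L
      for (i in seq_len(nj)) {
        len <- sample(18:25, 1)
        if (i <= half) {
          b <- sample(c("A", "C", "G", "T"), 1)
          s <- rep(b, len)
          s[sample.int(len, 1)] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
          junk_inserts[i] <- paste(s, collapse = "")
        } else {
          d <- sample(c("A", "C", "G", "T"), 2, replace = FALSE)
          junk_inserts[i] <- substr(paste(rep(paste(d, collapse = ""), 13),
                                          collapse = ""), 1, len)
        }
      }
    }
    inserts <- c(rep("", cls[["dimer"]]), junk_inserts,
                 unname(contam_inserts), unname(mir_inserts))
    inserts <- inserts[sample.int(length(inserts))]
    reads <- substr(paste0(inserts, adapter, filler), 1, 50)
    lib <- design$library[li]
    path <- file.path(dir, paste0(lib, ".fastq"))
    qual <- strrep(rawToChar(as.raw(35L + 33L)), 50)
    con <- file(path, "wb")
    writeLines(paste0("@", lib, ":", seq_along(reads), "\n", reads, "\n+\n",
                      qual), con, sep = "\n")
    close(con)
    rows[[li]] <- data.frame(library = lib, line = design$line[li],
                             stage = design$stage[li],
                             replicate = design$replicate[li], path = path,
                             n_reads = n, n_dimer = cls[["dimer"]],
                             n_junk = cls[["junk"]],
                             n_contaminant = cls[["contaminant"]],
                             n_mirna = cls[["mirna"]],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "mirna_counts") <- counts
  out
}

#' Write the reference bundle to plain-text files
#'
#' Writes the genome, mature/precursor databases, contaminant references and
#' transcripts as FASTA, the annotation map and truth tables as TSV, and the
#' configuration as a key-value file.
#'
#' @param sim an `srna_sim` bundle.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_reference <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_fasta(sim$mature_db, file.path(dir, "mature_db.fa"))
  write_fasta(sim$precursor_db, file.path(dir, "precursor_db.fa"))
  write_fasta(sim$contaminants, file.path(dir, "contaminants.fa"))
  write_fasta(sim$transcripts, file.path(dir, "transcripts.fa"))
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$loci, file.path(dir, "truth_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$de, file.path(dir, "truth_de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfgv <- sim$config[!vapply(sim$config, is.data.frame, TRUE)]
  writeLines(paste0(names(cfgv), "=",
                    vapply(cfgv, function(v) paste(v, collapse = ","), "")),
             file.path(dir, "config.txt"))
  invisible(dir)
}
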