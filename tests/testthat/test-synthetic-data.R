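test_that("generation is deterministic and respects the empty-novel case", {
  cfg <- small_config(seed = 7L)
  s1 <- generate_reference(cfg)
  s2 <- generate_reference(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth$loci, s2$truth$loci)
  d1 <- file.path(tempdir(), "ref1"); d2 <- file.path(tempdir(), "ref2")
  write_reference(s1, d1); write_reference(s2, d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))

  s0 <- generate_reference(small_config(seed = 7L, n_novel_mirnas = 0L))
  expect_equal(sum(s0$truth$loci$class == "novel"), 0L)
  expect_equal(length(s0$precursor_db), s0$config$n_known_mirnas)
})

test_that("planted matures are 18-25 nt and hairpins pass all 11 criteria", {
  sim <- generate_reference(small_config(seed = 13L))
  loci <- sim$truth$loci
  expect_true(all(nchar(loci$mature_seq) >= 18 & nchar(loci$mature_seq) <= 25))
  crit <- hairpin_criteria()
  for (i in which(loci$class %in% c("known", "novel"))) {
    row <- loci[i, ]
    win <- extract_hairpin_window(
      data.frame(reference = row$contig, start = row$mature_start,
                 end = row$mature_end, strand = row$strand), sim$genome)
    expect_equal(substr(win$sequence, win$mature_interval[1],
                        win$mature_interval[2]), row$mature_seq)
    ev <- evaluate_hairpin_criteria(
      parse_structure(fold_hairpin(win$sequence), win$mature_interval), crit)
    expect_true(ev$verdict, info = row$id)
  }
  for (i in which(loci$class == "decoy")) {
    row <- loci[i, ]
    win <- extract_hairpin_window(
      data.frame(reference = row$contig, start = row$mature_start,
                 end = row$mature_end, strand = row$strand), sim$genome)
    ev <- evaluate_hairpin_criteria(
      parse_structure(fold_hairpin(win$sequence), win$mature_interval), crit)
    expect_false(ev$verdict, info = row$id)
  }
})

test_that("library simulation realizes sizes exactly and class fractions binomially", {
  cfg <- small_config(seed = 4L, reads_per_library = 20000L,
                      library_design = default_library_design()[1:2, ])
  sim <- generate_reference(cfg)
  libs <- simulate_libraries(sim, file.path(tempdir(), "fq_frac"))
  for (i in seq_len(nrow(libs))) {
    n <- length(readLines(libs$path[i])) / 4L
    expect_equal(n, cfg$reads_per_library)
    for (frac in list(c("n_dimer", cfg$adapter_dimer_fraction),
                      c("n_junk", cfg$junk_fraction),
                      c("n_contaminant", cfg$contaminant_fraction))) {
      p <- as.numeric(frac[2])
      se <- sqrt(p * (1 - p) * cfg$reads_per_library)
      expect_lt(abs(libs[[frac[1]]][i] - p * cfg$reads_per_library), 3 * se)
    }
  }
  # same seed gives byte-identical FASTQ output
  libs2 <- simulate_libraries(sim, file.path(tempdir(), "fq_frac2"))
  expect_identical(readLines(libs$path[1]), readLines(libs2$path[1]))
})

test_that("degenerate mixture yields only locus-derived inserts", {
  cfg <- small_config(seed = 5L, contaminant_fraction = 0,
                      adapter_dimer_fraction = 0, junk_fraction = 0,
                      library_design = default_library_design()[1, , drop = FALSE],
                      reads_per_library = 1000L)
  sim <- generate_reference(cfg)
  libs <- simulate_libraries(sim, file.path(tempdir(), "fq_pure"))
  cl <- clean_reads(libs$path[1], cleaning_config(), library = "pure")
  planted <- c(sim$truth$loci$mature_seq, sim$truth$stars$sequence)
  expect_true(all(cl$reads$sequence %in% planted))
})

test_that("planted fold changes are realized in expected count ratios", {
  # Monte-Carlo over seeds: realized mean counts for a between-line DE miRNA
  # differ ~4-fold between lines at log2fc = 2
  cfg <- small_config(seed = 10L, reads_per_library = 50000L)
  sim <- generate_reference(cfg)
  de <- sim$truth$de[sim$truth$de$contrast == "HO_vs_LO", ]
  expect_gt(nrow(de), 0)
  libs <- simulate_libraries(sim, file.path(tempdir(), "fq_fc"))
  cn <- attr(libs, "mirna_counts")
  dsg <- sim$truth$design
  for (k in seq_len(min(2, nrow(de)))) {
    m <- de$id[k]
    ratio <- mean(cn[m, dsg$line == "HO"]) / mean(cn[m, dsg$line == "LO"])
    expected <- 2^de$log2fc[k]
    expect_gt(ratio, expected / 2)
    expect_lt(ratio, expected * 2)
  }
})

test_that("planted length distribution and 5'-U bias surface in the profiles", {
  cfg <- small_config(seed = 71L, n_known_mirnas = 40L, n_novel_mirnas = 0L,
                      n_decoys = 0L, first_u_prob = 1)
  sim <- generate_reference(cfg)
  known <- sim$truth$loci[sim$truth$loci$class == "known", ]
  d <- length_distribution(data.frame(sequence = known$mature_seq,
                                      count = 1L), "unique")
  n <- nrow(known)
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(d[["24"]] - 0.7), 3 * se)
  b <- nucleotide_bias(known$mature_seq)
  expect_equal(unname(b$by_position[1, "U"]), 1)
  expect_true(all(b$first_by_length[, "U"] == 1))
})
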