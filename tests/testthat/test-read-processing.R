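test_that("cleaning partitions a hand-audited fixture correctly", {
  # 12 reads: 3 adapter dimers, 2 short (17 nt), 1 long (26 nt),
  # 1 homopolymer junk, 5 valid inserts
  valid <- c("ACGTGACTGATCGATCGATCG", "TGCATGCTAGCTAGCTAA",
             "CCGATCGATCGTAGCTAGCTAGCTA", "GATTACAGATTACAGATTACA",
             "TTGACCGATGCCGATCGAT")
  inserts <- c(rep("", 3),
               substr(valid[1], 1, 17), substr(valid[2], 1, 17),
               paste0(valid[3], "C"),         # 26 nt
               strrep("A", 21),               # homopolymer junk
               valid)
  fq <- write_test_fastq(inserts, tempfile(fileext = ".fastq"))
  cl <- clean_reads(fq, cleaning_config(), library = "fixture")
  s <- cl$stats
  expect_equal(s$raw_reads, 12L)
  expect_equal(s$clean_reads, 5L)
  expect_equal(s$adaptor_and_length_removed, 6L) # 3 dimers + 2 short + 1 long
  expect_equal(s$junk_reads, 1L)
  expect_equal(s$raw_reads,
               s$adaptor_and_length_removed + s$junk_reads + s$clean_reads)
  # collapsing preserves abundance and canonicalizes to RNA letters
  expect_equal(sum(cl$reads$count), s$clean_reads)
  expect_setequal(cl$reads$sequence, chartr("T", "U", valid))
})

test_that("length boundaries: 18 and 25 retained, 17 and 26 removed", {
  base <- strrep("ACGU", 10)
  for (len in c(17L, 18L, 25L, 26L)) {
    fq <- write_test_fastq(chartr("U", "T", substr(base, 1, len)),
                           tempfile(fileext = ".fastq"))
    cl <- clean_reads(fq, cleaning_config(), library = "b")
    expect_equal(cl$stats$clean_reads, as.integer(len >= 18 && len <= 25),
                 info = paste("insert length", len))
  }
})

test_that("cleaning is idempotent on already-clean inserts", {
  set.seed(5)
  inserts <- unique(random_rna(40, 21))
  fq1 <- write_test_fastq(chartr("U", "T", inserts),
                          tempfile(fileext = ".fastq"))
  cl1 <- clean_reads(fq1, cleaning_config(), library = "a")
  fq2 <- write_test_fastq(
    chartr("U", "T", rep(cl1$reads$sequence, cl1$reads$count)),
    tempfile(fileext = ".fastq"))
  cl2 <- clean_reads(fq2, cleaning_config(), library = "a")
  expect_equal(cl2$reads[order(cl2$reads$sequence), ],
               cl1$reads[order(cl1$reads$sequence), ],
               ignore_attr = TRUE)
  expect_equal(cl2$stats$junk_reads, 0L)
  expect_equal(cl2$stats$adaptor_and_length_removed, 0L)
})

test_that("length_distribution handles trivial and weighted cases", {
  one <- data.frame(sequence = strrep("A", 24), count = 7L)
  expect_equal(unname(length_distribution(one)[["24"]]), 1.0)
  two <- data.frame(sequence = c(strrep("A", 21), strrep("C", 24)),
                    count = c(1L, 3L))
  d <- length_distribution(two, "unique")
  expect_equal(unname(d[c("21", "24")]), c(0.5, 0.5))
  da <- length_distribution(two, "abundance")
  expect_equal(unname(da[c("21", "24")]), c(0.25, 0.75))
  expect_equal(sum(d), 1)
  expect_error(length_distribution(two[0, ]), "empty")
})

test_that("nucleotide bias frequencies are normalized and reflect inputs", {
  b <- nucleotide_bias(c("UAGC", "AAGC", "UUGC"))
  expect_equal(rowSums(b$first_by_length)[["4"]], 1)
  expect_equal(unname(b$first_by_length["4", "U"]), 2 / 3)
  expect_equal(rowSums(b$by_position), rep(1, 4), ignore_attr = TRUE)
  u <- nucleotide_bias(c("A", "C", "G", "U"))
  expect_equal(unname(u$by_position[1, ]), rep(0.25, 4))
})

test_that("library summary totals are exact sums and zero-safe", {
  z <- data.frame(library = "z", raw_reads = 0L,
                  adaptor_and_length_removed = 0L, junk_reads = 0L,
                  clean_reads = 0L)
  sz <- summarize_libraries(z)
  expect_equal(sz$total_raw, 0)
  expect_equal(sz$percent_clean, 0)

  set.seed(9)
  st <- data.frame(library = paste0("l", 1:4),
                   raw_reads = sample.int(1e6, 4),
                   adaptor_and_length_removed = sample.int(1e4, 4),
                   junk_reads = sample.int(1e3, 4),
                   clean_reads = sample.int(1e5, 4))
  sm <- summarize_libraries(st)
  expect_equal(sm$total_raw, sum(st$raw_reads))
  expect_equal(sm$average_clean, mean(st$clean_reads))
  expect_equal(sm$percent_clean, 100 * sum(st$clean_reads) / sum(st$raw_reads))
})

test_that("simulated library statistics recount from the FASTQ files", {
  cfg <- small_config(seed = 21L,
                      library_design = default_library_design()[1:4, ])
  sim <- generate_reference(cfg)
  libs <- simulate_libraries(sim, tempdir())
  cleaned <- lapply(seq_len(nrow(libs)), function(i)
    clean_reads(libs$path[i], cleaning_config(), library = libs$library[i]))
  st <- do.call(rbind, lapply(cleaned, `[[`, "stats"))
  # conservation per library, and totals equal an independent recount
  expect_true(all(st$raw_reads == st$adaptor_and_length_removed +
                    st$junk_reads + st$clean_reads))
  nrec <- vapply(libs$path, function(p) length(readLines(p)) / 4L, 0)
  expect_equal(st$raw_reads, unname(as.integer(nrec)))
  expect_equal(summarize_libraries(st)$total_raw, sum(nrec))
})
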