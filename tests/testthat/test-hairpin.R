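test_that("constructed perfect stem measures exactly", {
  # 25-bp perfect stem, 8-nt loop; mature = first 20 positions (fully paired)
  db <- paste0(strrep("(", 25), strrep(".", 8), strrep(")", 25))
  ms <- parse_structure(list(structure = db, mfe = -40), c(1L, 20L))
  expect_equal(ms$stem_bp, 25L)
  expect_equal(ms$max_stem_bulge_nt, 0L)
  expect_equal(ms$loop_len, 8L)
  expect_equal(ms$hairpin_len, 58L)
  expect_equal(ms$mature_errors, 0L)
  expect_equal(ms$mature_bp, 20L)
  expect_equal(ms$mature_in_stem_pct, 100)
  ev <- evaluate_hairpin_criteria(ms)
  expect_true(ev$verdict)
  expect_length(ev$flags, 11L)

  # one 13-nt bulge on the 5' arm is measured as 13 and fails criterion 1
  db2 <- paste0(strrep("(", 10), strrep(".", 13), strrep("(", 10),
                strrep(".", 6), strrep(")", 20))
  ms2 <- parse_structure(list(structure = db2, mfe = -40), c(1L, 10L))
  expect_equal(ms2$max_stem_bulge_nt, 13L)
  ev2 <- evaluate_hairpin_criteria(ms2)
  expect_false(ev2$flags[["max_stem_bulge_nt"]])
})

test_that("boundary thresholds reject exactly as specified", {
  base <- list(stem_bp = 20L, max_stem_bulge_nt = 0L, mfe = -40,
               hairpin_len = 60L, loop_len = 8L, max_mature_bulge_nt = 0L,
               mature_biased_errors = 0L, mature_biased_bulges = 0L,
               mature_errors = 0L, mature_bp = 20L, mature_in_stem_pct = 100)
  ok <- evaluate_hairpin_criteria(base)
  expect_true(ok$verdict)
  mfe_fail <- base; mfe_fail$mfe <- -14.9
  r <- evaluate_hairpin_criteria(mfe_fail)
  expect_false(r$verdict)
  expect_false(r$flags[["max_mfe"]])
  expect_true(evaluate_hairpin_criteria(within(base, mfe <- -15))$verdict)
  stem_fail <- base; stem_fail$stem_bp <- 15L
  r2 <- evaluate_hairpin_criteria(stem_fail)
  expect_false(r2$flags[["min_stem_bp"]])
  expect_true(evaluate_hairpin_criteria(within(base, stem_bp <- 16L))$verdict)
})

test_that("measures agree with an independent re-implementation on 50 constructions", {
  set.seed(77)
  for (i in 1:50) {
    h <- construct_hairpin_db(blocks = sample(1:4, 1))
    n <- nchar(h$db)
    # mature: 20 positions starting inside the 5' arm
    mstart <- sample(1:4, 1)
    mi <- c(mstart, mstart + 19L)
    ms <- parse_structure(list(structure = h$db, mfe = -30), mi)
    ref <- reparse_simple_hairpin(h$db, mi)
    for (field in names(ref))
      expect_equal(ms[[field]], ref[[field]],
                   info = sprintf("case %d field %s", i, field))
    # construction truth for global stem measures
    expect_equal(ms$stem_bp, h$stem_bp)
    expect_equal(ms$loop_len, h$loop_len)
    expect_equal(ms$hairpin_len, h$hairpin_len)
    expect_equal(ms$max_stem_bulge_nt, h$max_bulge)
  }
})

test_that("hand-verified decompositions", {
  # ((((....)))) : 4-bp stem, 4-nt loop
  m <- parse_structure(list(structure = "((((....))))", mfe = -10), c(1L, 4L))
  expect_equal(c(m$stem_bp, m$loop_len, m$hairpin_len), c(4L, 4L, 12L))
  # ((..((....))..)): 2+2 ladder, symmetric 2/2 internal loop (not biased)
  m2 <- parse_structure(list(structure = "((..((....))..))", mfe = -10),
                        c(1L, 6L))
  expect_equal(m2$stem_bp, 4L)
  expect_equal(m2$max_stem_bulge_nt, 2L)
  expect_equal(m2$mature_biased_bulges, 0L)
  expect_equal(m2$mature_errors, 2L)
  # ((.((....)))) : 1-nt biased bulge on the 5' arm touching the mature
  m3 <- parse_structure(list(structure = "((.((....))))", mfe = -10),
                        c(1L, 5L))
  expect_equal(m3$max_stem_bulge_nt, 1L)
  expect_equal(m3$mature_biased_bulges, 1L)
  expect_equal(m3$mature_biased_errors, 1L)
  # unpaired structure reports failing sentinels
  m4 <- parse_structure(list(structure = "............", mfe = 0), c(1L, 6L))
  expect_equal(m4$stem_bp, 0L)
  expect_false(evaluate_hairpin_criteria(m4)$verdict)
  # multiloop: ladder stops at the branch point
  db5 <- "((((((....))((....))))))"
  m5 <- parse_structure(list(structure = db5, mfe = -20), c(5L, 10L))
  expect_equal(m5$stem_bp, 2L) # the 2 pairs of the left branch stem
  expect_equal(m5$loop_len, 4L)
})

test_that("measures are invariant to window mirroring", {
  mirror <- function(db) chartr("()", ")(",
                                paste(rev(strsplit(db, "")[[1]]), collapse = ""))
  set.seed(15)
  for (i in 1:10) {
    h <- construct_hairpin_db(blocks = sample(1:3, 1))
    n <- nchar(h$db)
    mi <- c(2L, 21L)
    a <- parse_structure(list(structure = h$db, mfe = -30), mi)
    b <- parse_structure(list(structure = mirror(h$db), mfe = -30),
                         c(n - mi[2] + 1L, n - mi[1] + 1L))
    for (field in c("stem_bp", "loop_len", "hairpin_len",
                    "max_stem_bulge_nt", "mature_errors", "mature_bp",
                    "max_mature_bulge_nt", "mature_in_stem_pct",
                    "mature_biased_bulges", "mature_biased_errors"))
      expect_equal(a[[field]], b[[field]], info = field)
  }
})

test_that("window extraction arithmetic, truncation and strand handling", {
  set.seed(44)
  contig <- random_rna(1, 10000)
  genome <- c(chr = contig)
  hit <- data.frame(reference = "chr", start = 500L, end = 521L,
                    strand = "+")
  w <- extract_hairpin_window(hit, genome)
  expect_equal(c(w$win_start, w$win_end), c(380L, 641L))
  expect_equal(nchar(w$sequence), 261L)
  expect_equal(substr(w$sequence, w$mature_interval[1], w$mature_interval[2]),
               substr(contig, 501, 521))

  hit2 <- data.frame(reference = "chr", start = 10L, end = 31L, strand = "+")
  w2 <- extract_hairpin_window(hit2, genome)
  expect_equal(w2$win_start, 0L)
  expect_equal(nchar(w2$sequence), 151L)

  hit3 <- data.frame(reference = "chr", start = 500L, end = 521L,
                     strand = "-")
  w3 <- extract_hairpin_window(hit3, genome)
  expect_equal(w3$sequence, revcomp(substr(contig, 381, 641)))
  expect_equal(substr(w3$sequence, w3$mature_interval[1],
                      w3$mature_interval[2]),
               revcomp(substr(contig, 501, 521)))
})
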