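test_that("site scoring follows the plant penalty arithmetic", {
  mir <- "UGACUAGCUAGCUAGCUAGCA" # 21 nt
  perfect <- revcomp(mir)
  s0 <- score_target_site(mir, perfect)
  expect_equal(s0$score, 0)
  expect_equal(s0$mismatches + s0$wobbles + s0$gaps, 0)

  # single G:U wobble at miRNA position 10 (inside 2-13): 0.5 * 2 = 1
  mir_w <- mir
  substr(mir_w, 10, 10) <- "G"
  site <- strsplit(revcomp(mir_w), "")[[1]]
  site[21 - 10 + 1] <- "U" # pairs miRNA position 10 with U instead of C
  s1 <- score_target_site(mir_w, paste(site, collapse = ""))
  expect_equal(s1$score, 1.0)
  expect_equal(s1$wobbles, 1L)

  # mismatch at position 16 (1.0) plus wobble at position 5 (0.5 * 2)
  mir2 <- mir
  substr(mir2, 5, 5) <- "G"
  site2 <- strsplit(revcomp(mir2), "")[[1]]
  site2[21 - 5 + 1] <- "U"                       # wobble at position 5
  site2[21 - 16 + 1] <- as_rna(c(A = "C", C = "A", G = "G", U = "U")[[
    substr(mir2, 16, 16)]])                      # non-pairing base at 16
  s2 <- score_target_site(mir2, paste(site2, collapse = ""))
  expect_equal(s2$score, 2.0)
  expect_equal(s2$mismatches, 1L)
  expect_equal(s2$wobbles, 1L)

  # a single gap costs 1 (doubled inside the 2-13 region)
  s3 <- score_target_site(mir, substr(perfect, 2, 21))
  expect_equal(s3$gaps, 1L)
  expect_lte(s3$score, 2.0)
})

test_that("scoring is invariant to reading the duplex from the other end", {
  # Reversing (without complementing) both strands swaps which sequence is
  # called the guide but leaves every base pair, and its distance from the
  # guide 5' end, unchanged; complementing would turn G:U wobbles into A:C
  # mismatches and so cannot preserve the score.
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  set.seed(55)
  for (i in 1:20) {
    mir <- random_rna(1, 21)
    site <- random_rna(1, 21)
    a <- score_target_site(mir, site)$score
    b <- score_target_site(rev_str(site), rev_str(mir))$score
    expect_equal(a, b)
  }
  # wobble symmetry: G:U and U:G both cost 0.5 (doubled in the 2-13 region)
  mirG <- paste0("G", strrep("A", 20))
  siteU <- strsplit(revcomp(mirG), "")[[1]]; siteU[21] <- "U"
  expect_equal(score_target_site(mirG, paste(siteU, collapse = ""))$score, 0.5)
  mirU <- paste0("U", strrep("A", 20))
  siteG <- strsplit(revcomp(mirU), "")[[1]]; siteG[21] <- "G"
  expect_equal(score_target_site(mirU, paste(siteG, collapse = ""))$score, 0.5)
})

test_that("transcript scanning equals exhaustive window enumeration", {
  set.seed(56)
  mir <- random_rna(1, 21)
  # transcript with two degraded complements (4 and 6 mutations) plus
  # random background, so windows fall on both sides of the cutoff
  degrade <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(seq_along(ch), k)
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A", "C", "G", "U"), b), 1), "")
    paste(ch, collapse = "")
  }
  tx <- c(t1 = paste0(random_rna(1, 60), degrade(revcomp(mir), 4),
                      random_rna(1, 60), degrade(revcomp(mir), 6),
                      random_rna(1, 40)))
  cutoff <- 8
  got <- scan_transcripts(c(m1 = mir), tx, cutoff = cutoff)
  expect_gt(nrow(got), 0)
  rows <- list()
  for (wl in 20:22) {
    for (st in seq_len(nchar(tx[[1]]) - wl + 1L)) {
      sc <- score_target_site(mir, substr(tx[[1]], st, st + wl - 1L))$score
      if (sc <= cutoff)
        rows[[length(rows) + 1L]] <- data.frame(start = st,
                                                end = st + wl - 1L,
                                                score = sc)
    }
  }
  want <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), score = numeric(0))
  expect_equal(nrow(got), nrow(want))
  key <- function(d) sort(paste(d$start, d$end, d$score))
  expect_equal(key(got), key(want))

  # planted exact complement is recovered with score 0
  tx2 <- c(t2 = paste0(random_rna(1, 50), revcomp(mir), random_rna(1, 50)))
  hit <- scan_transcripts(c(m1 = mir), tx2, cutoff = 4)
  expect_true(any(hit$score == 0 & hit$start == 51))

  # cutoff monotonicity: sites at cutoff 3 are a subset of cutoff 4
  s3 <- scan_transcripts(c(m1 = mir), tx, cutoff = 3)
  s4 <- scan_transcripts(c(m1 = mir), tx, cutoff = 4)
  expect_true(all(key(s3) %in% key(s4)))
})

test_that("planted sites with score <= 3 are all recovered at cutoff 4", {
  cfg <- small_config(seed = 66L)
  sim <- generate_reference(cfg)
  tgt <- sim$truth$targets
  mir_seqs <- setNames(sim$truth$loci$mature_seq, sim$truth$loci$id)
  hits <- scan_transcripts(mir_seqs[unique(tgt$mirna)], sim$transcripts,
                           cutoff = 4)
  for (i in seq_len(nrow(tgt))) {
    found <- hits[hits$mirna == tgt$mirna[i] &
                    hits$transcript == tgt$transcript[i] &
                    hits$start >= tgt$start[i] - 1 &
                    hits$end <= tgt$end[i] + 1, ]
    expect_gte(nrow(found), 1)
    expect_lte(min(found$score), tgt$expected_score[i])
  }
})

test_that("hypergeometric enrichment equals closed form and Fisher's exact", {
  ann <- data.frame(gene = paste0("g", 1:20),
                    term = rep("T1", 20))
  ann$term[6:20] <- "T2"
  # term of size 5, query of size 5, full overlap: P = 1 / choose(20, 5)
  r <- hypergeometric_enrichment(paste0("g", 1:5), ann)
  expect_equal(r$p_value[r$term == "T1"], 1 / choose(20, 5))
  expect_true(r$enriched[r$term == "T1"])
  # query = universe gives P = 1 for every term
  r2 <- hypergeometric_enrichment(paste0("g", 1:20), ann)
  expect_true(all(r2$p_value == 1))

  set.seed(58)
  for (i in 1:100) {
    N <- sample(20:200, 1)
    K <- sample(1:(N - 1), 1)
    q <- sample(1:(N - 1), 1)
    genes <- paste0("g", 1:N)
    ann_i <- data.frame(gene = genes,
                        term = c(rep("T", K), rep("bg", N - K)))
    query <- sample(genes, q)
    r <- hypergeometric_enrichment(query, ann_i)
    k <- sum(query %in% genes[1:K])
    ft <- fisher.test(matrix(c(k, K - k, q - k, N - K - (q - k)), 2),
                      alternative = "greater")
    expect_equal(r$p_value[r$term == "T"], ft$p.value, tolerance = 1e-12)
  }

  expect_error(hypergeometric_enrichment("zz", ann), "universe")
})

test_that("enrichment P never increases as overlap grows at fixed margins", {
  N <- 50; K <- 10; q <- 10
  p <- vapply(0:q, function(k)
    phyper(k - 1, K, N - K, q, lower.tail = FALSE), 0)
  expect_true(all(diff(p) <= 0))
  ann <- data.frame(gene = paste0("g", 1:N),
                    term = c(rep("T", K), rep("bg", N - K)))
  p_obs <- vapply(c(2, 5, 8), function(k) {
    query <- c(paste0("g", 1:k), paste0("g", (K + 1):(K + q - k)))
    r <- hypergeometric_enrichment(query, ann)
    r$p_value[r$term == "T"]
  }, 0)
  expect_true(all(diff(p_obs) <= 0))
})
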