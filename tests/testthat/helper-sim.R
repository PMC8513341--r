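# small study configuration used across tests (fast to generate and run)
small_config <- function(seed = 42L, ...) {
  defaults <- list(genome_length = 30000L, n_contigs = 2L,
                   n_known_mirnas = 6L, n_novel_mirnas = 4L, n_decoys = 4L,
                   n_contaminant_refs = c(rRNA = 2L, tRNA = 2L, snRNA = 2L,
                                          snoRNA = 2L, `repeat` = 2L),
                   n_transcripts = 10L, reads_per_library = 3000L,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# write a FASTQ file from insert sequences (DNA letters), appending the
# adapter and padding/truncating to 50 nt, constant Q35 qualities
write_test_fastq <- function(inserts, path,
                             adapter = "TGGAATTCTCGGGTGCCAAGG") {
  reads <- substr(paste0(inserts, adapter,
                         strrep("A", 50)), 1, 50)
  qual <- strrep(rawToChar(as.raw(68L)), 50)
  writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n", qual),
             path)
  path
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    "")
}
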