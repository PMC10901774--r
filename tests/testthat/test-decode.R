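q_at <- function(q, n) strrep(rawToChar(as.raw(33L + q)), n)

test_that("3' quality trimming matches a direct per-base scan", {
  seqs <- c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC")
  quals <- c(q_at(37, 10),                       # pristine
             q_at(2, 10),                        # hopeless
             paste0(q_at(37, 5), q_at(10, 5)))   # exactly last 5 low
  tr <- trim_reads(seqs, quals, q_threshold = 20L, min_len = 4L)
  # oracle: scan each quality string from the 3' end
  oracle_len <- vapply(quals, function(q) {
    v <- utf8ToInt(q) - 33L
    n <- length(v)
    while (n > 0L && v[n] < 20L) n <- n - 1L
    n
  }, integer(1))
  expect_equal(nchar(tr$seqs), unname(oracle_len))
  expect_identical(tr$seqs[1], seqs[1])
  expect_false(tr$keep[2])
  expect_identical(tr$seqs[3], "ACGTA")
})

test_that("flank extraction recovers inserts in both orientations", {
  d <- toy_design()
  ins <- encode_peptide(c("WAL", "LAW"), d)
  reads <- paste0(d$flank5, ins, d$flank3)
  expect_identical(extract_inserts(reads, d), ins)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))
  expect_identical(extract_inserts(rc, d), ins)

  # one substitution per flank tolerated; two rejected
  mut1 <- reads[1]
  substr(mut1, 1, 1) <- "T"
  expect_identical(extract_inserts(mut1, d), ins[1])
  mut2 <- mut1
  substr(mut2, 2, 2) <- "C"
  expect_true(is.na(extract_inserts(mut2, d)))
})

test_that("translation gate rejects stops and non-members, diverts spike", {
  d1 <- toy_design(npos = 1L, alphabet = "W")
  r <- translate_inserts("TGG", d1)
  expect_identical(r$peptide, "W")

  d <- toy_design()
  r <- translate_inserts(c("TAAGCTGCT", "TGGGCTGCT"), d)
  expect_identical(r$reason[1], "stop_codon")
  expect_identical(r$peptide[2], "WAA")

  # fixed-position violation -> not_in_design
  df <- toy_design(npos = 3L, fixed = 2L, fixed_residue = "A")
  r <- translate_inserts(encode_peptide("WAL", d), df)  # W at fixed A? no: pos2=A ok
  expect_identical(r$peptide, "WAL")
  r2 <- translate_inserts(paste0("TGG", "TGG", "CTG"), df)  # WWL: pos2 W != A
  expect_identical(r2$reason, "not_in_design")

  # spike diverted before the design gate, with 1-mismatch fallback
  sp <- d$spike_in_dna
  near <- sp
  substr(near, 5, 5) <- "C"
  r3 <- translate_inserts(c(sp, near), d)
  expect_true(all(r3$is_spike))

  # wrong length
  r4 <- translate_inserts("TGGGC", d)
  expect_identical(r4$reason, "length_mismatch")
})

test_that("translation agrees with a standard-code oracle on random inserts", {
  d <- default_design()
  set.seed(21)
  n <- 1000L
  bases <- c("A", "C", "G", "T")
  inserts <- vapply(seq_len(n), function(i)
    paste(sample(bases, 36L, replace = TRUE), collapse = ""), character(1))
  res <- translate_inserts(inserts, d)
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(min(n, 1000L))) {
    codons <- substring(inserts[i], seq(1, 34, 3), seq(3, 36, 3))
    aa <- paste(code[codons], collapse = "")
    if (res$is_spike[i]) next
    if (grepl("*", aa, fixed = TRUE)) {
      expect_identical(res$reason[i], "stop_codon")
    } else if (matches_design(aa, d)) {
      expect_identical(res$peptide[i], aa)
    } else {
      expect_identical(res$reason[i], "not_in_design")
    }
  }
})

test_that("decode reproduces the simulator's draws exactly at epsilon 0", {
  d <- default_design()
  pop <- sample_background(d, 300L, seed = 31)
  pop <- plant_families(pop, example_families("mdm2"), d, seed = 32)
  lay <- screen_layout(c(50, 800), n_replicates = 1L, n_blanks = 1L,
                       reads_per_well = 2000L)
  sim <- simulate_screen(pop, lay, d, beta = 30, epsilon = 0,
                         outdir = tempfile(), seed = 33)
  cm <- tally_screen(sim$sample_sheet, d)
  drawn <- sim$counts[rowSums(sim$counts) > 0, , drop = FALSE]
  drawn <- drawn[order(rownames(drawn), method = "radix"), ]
  expect_identical(unname(cm$counts), unname(drawn))
  expect_identical(rownames(cm$counts), rownames(drawn))
  expect_equal(unname(cm$spike_counts), unname(sim$spike_counts))
  expect_true(all(cm$rejected == 0L))
})

test_that("conservation holds under errors, rc reads and low-quality tails", {
  d <- default_design()
  pop <- sample_background(d, 200L, seed = 41)
  lay <- screen_layout(c(50, 800), n_replicates = 1L, n_blanks = 1L,
                       reads_per_well = 1500L)
  sim <- simulate_screen(pop, lay, d, beta = 10, epsilon = 0.02,
                         rc_fraction = 0.3, lowq_tail_prob = 0.2,
                         outdir = tempfile(), seed = 42)
  cm <- tally_screen(sim$sample_sheet, d)
  # conservation is asserted inside the constructor; check the numbers too
  expect_equal(unname(colSums(cm$counts) + cm$spike_counts +
                        colSums(cm$rejected)),
               unname(as.numeric(cm$total_reads)))
  expect_equal(unname(cm$total_reads), lay$reads)
  # with 2% per-base errors some reads must fall in each failure bucket
  expect_gt(sum(cm$rejected), 0)
})

test_that("degenerate wells decode cleanly", {
  d <- toy_design()
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  w <- decode_well(empty, d)
  expect_equal(w$total, 0L)
  expect_length(w$peptide_counts, 0L)

  # duplicate reads of one member tally to a single row
  ins <- encode_peptide("WAL", d)
  read <- paste0(d$flank5, ins, d$flank3)
  fq <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@r", 1:4), rep(read, 4), "+",
                             rep(q_at(37, nchar(read)), 4))), fq)
  w2 <- decode_well(fq, d)
  expect_identical(w2$peptide_counts, c(WAL = 4L))
})

test_that("count matrix construction rejects broken conservation", {
  counts <- matrix(5L, 1, 1, dimnames = list("WAL", "s1"))
  expect_error(
    new_count_matrix(counts, c(s1 = 1L),
                     matrix(0L, 1, 1, dimnames = list("low_quality", "s1")),
                     c(s1 = 99L),
                     data.frame(sample_id = "s1", role = "blank",
                                concentration_nM = 0, replicate = 1),
                     "SPIKE"),
    "conservation")
})
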