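test_that("spike-in normalization is a per-sample ratio", {
  counts <- matrix(c(10L, 70L), 1, 2, dimnames = list("WAL", c("s1", "s2")))
  cm <- cm_manual(counts, c(s1 = 100L, s2 = 700L), c("blank", "bait"),
                  c(0, 800))
  norm <- normalize_counts(cm)
  expect_equal(unname(norm$values["WAL", ]), c(0.1, 0.1))
})

test_that("normalization excludes zero-spike samples with a warning", {
  counts <- matrix(c(10L, 10L), 1, 2, dimnames = list("WAL", c("s1", "s2")))
  cm <- cm_manual(counts, c(s1 = 100L, s2 = 0L), c("blank", "bait"), c(0, 800))
  expect_warning(norm <- normalize_counts(cm), "zero spike-in")
  expect_equal(colnames(norm$values), "s1")
})

test_that("Hit Strength arithmetic and the 0.5 blank substitution", {
  # high-conc normalized 0.2, blank normalized 0.05 -> HS 4
  counts <- matrix(c(5L, 20L), 1, 2, dimnames = list("WAL", c("b1", "h1")))
  cm <- cm_manual(counts, c(b1 = 100L, h1 = 100L), c("blank", "bait"),
                  c(0, 800))
  hs <- hit_strength(normalize_counts(cm))
  expect_equal(unname(hs["WAL"]), 4)

  # zero blank counts: denominator becomes 0.5 / spike
  counts0 <- matrix(c(0L, 20L), 1, 2, dimnames = list("WAL", c("b1", "h1")))
  cm0 <- cm_manual(counts0, c(b1 = 100L, h1 = 50L), c("blank", "bait"),
                   c(0, 800))
  hs0 <- hit_strength(normalize_counts(cm0))
  expect_equal(unname(hs0["WAL"]), (20 / 50) / (0.5 / 100))
  expect_true(all(is.finite(hs0)))

  # the substitution touches only zeros
  eff <- effective_blank_counts(matrix(c(0L, 3L, 0L, 7L), 2, 2))
  expect_equal(as.vector(eff), c(0.5, 3, 0.5, 7))
})

test_that("the spike-in's Hit Strength is exactly 1 in any screen", {
  d <- default_design()
  for (s in 1:3) {
    pop <- sample_background(d, 300L, seed = s)
    sim <- simulate_counts(pop, default_layout(reads = 5000L),
                           beta = sample(c(0, 50), 1), seed = s + 50)
    h <- call_hits(cm_from_sim(sim))
    expect_identical(h$hit_strength[h$is_spike], 1)
    expect_false(any(h$is_hit & h$is_spike))
  }
})

test_that("Hit Strength is invariant to per-sample count scaling", {
  d <- default_design()
  pop <- sample_background(d, 200L, seed = 61)
  pop <- plant_families(pop, example_families("mdm2")[1], d, seed = 62)
  sim <- simulate_counts(pop, default_layout(reads = 4000L), beta = 50,
                         seed = 63)
  h1 <- call_hits(cm_from_sim(sim))
  # multiply one sample's raw counts (spike included) by 7
  sim$counts[, 3] <- sim$counts[, 3] * 7L
  sim$spike_counts[3] <- sim$spike_counts[3] * 7L
  sim$layout$reads[3] <- sim$layout$reads[3] * 7L
  h7 <- call_hits(cm_from_sim(sim))
  expect_equal(h7$hit_strength, h1$hit_strength)
})

test_that("dose-response statistic ranks level means against concentration", {
  mk_norm <- function(vals) {
    # one peptide across 1 blank + 4 bait levels, single replicate each
    counts <- matrix(as.integer(vals), 1, 5,
                     dimnames = list("WAL", paste0("s", 1:5)))
    cm <- cm_manual(counts, setNames(rep(100L, 5), paste0("s", 1:5)),
                    c("blank", rep("bait", 4)), c(0, 12.5, 50, 200, 800))
    normalize_counts(cm)
  }
  up <- dose_response(mk_norm(c(0, 10, 20, 30, 40)))
  expect_equal(up$dose_rho, 1.0)
  expect_true(up$dose_pass)

  flat <- dose_response(mk_norm(c(5, 5, 5, 5, 5)))
  expect_equal(flat$dose_rho, 0)
  expect_false(flat$dose_pass)

  down <- dose_response(mk_norm(c(40, 30, 20, 10, 0)))
  expect_equal(down$dose_rho, -1.0)
})

test_that("dose-response degrades gracefully below 3 levels", {
  counts <- matrix(c(1L, 5L), 1, 2, dimnames = list("WAL", c("b", "h")))
  cm <- cm_manual(counts, c(b = 10L, h = 10L), c("blank", "bait"), c(0, 800))
  expect_warning(dr <- dose_response(normalize_counts(cm)), "fewer than 3")
  expect_true(dr$dose_pass)
  expect_true(is.na(dr$dose_rho))
})

test_that("a strongly enriched mid-series binder passes the gate", {
  d <- default_design()
  pass <- vapply(1:10, function(s) {
    pop <- sample_background(d, 500L, seed = s)
    pop <- plant_families(
      pop, list(binder_family("B", "LWESAFDSYIAQ", kd_nM = 100,
                              n_members = 1L, substitution_rate = 0)),
      d, seed = s + 10)
    sim <- simulate_counts(pop, default_layout(reads = 20000L), beta = 50,
                           seed = s + 20)
    h <- call_hits(cm_from_sim(sim))
    h$is_hit[h$peptide == "LWESAFDSYIAQ"]
  }, logical(1))
  expect_true(all(pass))
})

test_that("null calibration: beta 0 leaves under 1% of sequences at HS >= 5", {
  d <- default_design()
  frac <- vapply(1:10, function(s) {
    pop <- sample_background(d, 5000L, seed = s)
    sim <- simulate_counts(pop, default_layout(reads = 20000L), beta = 0,
                           seed = s + 100)
    h <- call_hits(cm_from_sim(sim))
    mean(h$hit_strength[!h$is_spike] >= 5)
  }, numeric(1))
  expect_true(all(frac < 0.01))
})

test_that("lower Kd gives higher mean Hit Strength", {
  d <- default_design()
  fams <- list(binder_family("tight", "LWESAFDSYIAQ", kd_nM = 25,
                             n_members = 1L, substitution_rate = 0),
               binder_family("mid", "WAFSIDLSEVMT", kd_nM = 100,
                             n_members = 1L, substitution_rate = 0),
               binder_family("weak", "WDYSLFMSQRHN", kd_nM = 400,
                             n_members = 1L, substitution_rate = 0))
  mean_hs <- matrix(NA_real_, 5, 3)
  for (s in 1:5) {
    pop <- sample_background(d, 500L, seed = s + 200)
    pop <- plant_families(pop, fams, d, seed = s + 210)
    sim <- simulate_counts(pop, default_layout(reads = 20000L), beta = 50,
                           seed = s + 220)
    h <- call_hits(cm_from_sim(sim))
    mean_hs[s, ] <- h$hit_strength[match(c("LWESAFDSYIAQ", "WAFSIDLSEVMT",
                                           "WDYSLFMSQRHN"), h$peptide)]
  }
  avg <- colMeans(mean_hs)
  expect_true(avg[1] > avg[2] && avg[2] > avg[3])
})

test_that("hit table export echoes thresholds and per-sample values", {
  d <- default_design()
  pop <- sample_background(d, 100L, seed = 71)
  sim <- simulate_counts(pop, default_layout(reads = 2000L), beta = 0,
                         seed = 72)
  h <- call_hits(cm_from_sim(sim), hs_min = 7, min_reads = 3L)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_hit_table(h, tsv, js)
  out <- read.delim(tsv)
  expect_true(all(c("peptide", "hit_strength", "dose_rho", "is_hit")
                  %in% names(out)))
  expect_equal(sum(grepl("^norm_", names(out))), ncol(attr(h, "normalized")))
  th <- jsonlite::read_json(js)
  expect_equal(th$hs_min, 7)
  expect_equal(th$min_reads, 3)
})
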