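test_that("peptide distance: identity, symmetry, bounds", {
  d <- default_design()
  set.seed(81)
  peps <- sample_members(d, 40L)
  for (metric in c("blosum", "hamming")) {
    D <- peptide_distance(peps, d, metric)
    expect_equal(unname(diag(D)), rep(0, length(peps)))
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
    # symmetry against direct per-pair recomputation
    sim <- mipd:::scaled_similarity(d, metric)
    vp <- mipd:::variable_positions(d)
    for (k in 1:100) {
      ij <- sample(length(peps), 2L)
      a <- strsplit(peps[ij[1]], "")[[1]]
      b <- strsplit(peps[ij[2]], "")[[1]]
      dd <- 1 - mean(vapply(vp, function(j) sim[a[j], b[j]], numeric(1)))
      expect_equal(D[ij[1], ij[2]], dd, ignore_attr = TRUE)
      expect_equal(D[ij[2], ij[1]], D[ij[1], ij[2]], ignore_attr = TRUE)
    }
    expect_error(peptide_distance(c("WAL", "WALL"), d), "length")
  }
})

test_that("distance endpoints: all-minimum-similarity pairs score 1", {
  d <- toy_design(npos = 2L, alphabet = c("W", "A", "L"))
  # hamming: every variable position different -> 1
  Dh <- peptide_distance(c("WW", "AL"), d, metric = "hamming")
  expect_equal(Dh[1, 2], 1)
  # blosum: pick the least-similar rescaled pair for every position
  sim <- mipd:::scaled_similarity(d, "blosum")
  worst <- which(sim == min(sim), arr.ind = TRUE)[1, ]
  a <- paste(rep(rownames(sim)[worst[1]], 2), collapse = "")
  b <- paste(rep(colnames(sim)[worst[2]], 2), collapse = "")
  Db <- peptide_distance(c(a, b), d, metric = "blosum")
  expect_equal(Db[1, 2], 1)
})

test_that("single hit clusters to a singleton; order never matters", {
  d <- default_design()
  one <- cluster_hits("LWESAFDSYIAQ", d)
  expect_length(one$families, 0L)
  expect_equal(one$singletons, "LWESAFDSYIAQ")
  expect_error(cluster_hits(character(0), d), "empty hit set")

  set.seed(91)
  pop <- sample_background(d, 50L, seed = 91)
  fams <- example_families("mdm2")
  planted <- plant_families(pop, fams, d, seed = 92)
  hits <- planted$peptide[!is.na(planted$family_id)]
  f1 <- cluster_hits(hits, d)
  f2 <- cluster_hits(rev(hits), d)
  f3 <- cluster_hits(sample(hits), d)
  part <- function(x) lapply(x$families, `[[`, "members")
  expect_identical(part(f1), part(f2))
  expect_identical(part(f1), part(f3))
})

test_that("planted families are recovered with ARI >= 0.9 over 10 seeds", {
  skip_if_not_installed("mclust")
  d <- default_design()
  fams <- example_families("mdm2")
  for (s in 1:10) {
    pop <- sample_background(d, 100L, seed = s + 300)
    planted <- plant_families(pop, fams, d, seed = s + 310)
    tr <- planted[!is.na(planted$family_id), ]
    res <- cluster_hits(tr$peptide, d)
    expect_length(res$families, 3L)
    got <- rep("singleton", nrow(tr))
    names(got) <- tr$peptide
    for (f in res$families) got[f$members] <- f$family_id
    ari <- mclust::adjustedRandIndex(got, tr$family_id)
    expect_gte(ari, 0.9)
  }
})

test_that("consensus and logo: one-hot, uniform and tie-break behavior", {
  d <- default_design()
  # identical members -> one-hot columns, consensus = member
  cl <- consensus_logo(rep("LWESAFDSYIAQ", 4L), d)
  expect_identical(cl$consensus, "LWESAFDSYIAQ")
  expect_true(all(apply(cl$logo, 2, max) == 1))
  expect_equal(unname(colSums(cl$logo)), rep(1, 12))
  # one-hot variable column carries log2(16) = 4 bits
  expect_equal(unname(cl$ic[1]), 4)
  # fixed positions have |A| = 1 -> 0 bits
  expect_equal(unname(cl$ic[c(4, 8)]), c(0, 0))
  expect_equal(cl$fixed_mask, c(F, F, F, T, F, F, F, T, F, F, F, F),
               ignore_attr = TRUE)

  # uniform usage over the 16-letter alphabet -> 0 bits
  members <- paste0(d$alphabet, "WE", "S", "AFD", "S", "YIAQ")
  cu <- consensus_logo(members, d)
  expect_equal(unname(cu$ic[1]), 0)
  expect_equal(unname(cu$logo[, 1]), rep(1 / 16, 16))
  # modal tie at position 1 resolves to the earliest alphabet letter
  expect_identical(substr(cu$consensus, 1, 1), d$alphabet[1])
})

test_that("logo columns always sum to 1 and IC stays within bounds", {
  d <- default_design()
  set.seed(101)
  for (rep in 1:5) {
    members <- sample_members(d, sample(2:20, 1))
    cl <- consensus_logo(members, d)
    expect_equal(unname(colSums(cl$logo)), rep(1, 12), tolerance = 1e-9)
    expect_true(all(cl$ic >= -1e-12 & cl$ic <= log2(16) + 1e-12))
    expect_true(matches_design(cl$consensus, d))
  }
})

test_that("family outputs land on disk in the documented layout", {
  d <- default_design()
  pop <- sample_background(d, 50L, seed = 111)
  planted <- plant_families(pop, example_families("chip"), d, seed = 112)
  tr <- planted[!is.na(planted$family_id), ]
  res <- cluster_hits(tr$peptide, d,
                      hs = setNames(runif(nrow(tr), 1, 50), tr$peptide))
  out <- tempfile()
  write_families(res, out)
  fam_tab <- read.delim(file.path(out, "families.tsv"))
  expect_setequal(fam_tab$peptide, c(unlist(lapply(res$families, `[[`,
                                                   "members")),
                                     res$singletons))
  cons <- Biostrings::readAAStringSet(file.path(out, "consensus.fasta"))
  expect_length(cons, length(res$families))
  logo <- read.delim(file.path(out, "logo_F1.tsv"))
  expect_equal(nrow(logo), 17L)  # 16 residues + fixed-position mask row
  expect_equal(unname(colSums(logo[1:16, -1])), rep(1, 12), tolerance = 1e-9)
})
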