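#' Describe a planted binder family for simulation
#'
#' A planted family is a consensus design member plus mutational neighbors,
#' with a dissociation constant that drives enrichment through single-site
#' Langmuir occupancy theta = C / (C + Kd).
#'
#' @param family_id label for the family in the truth table
#' @param consensus design-member peptide at the family center
#' @param kd_nM dissociation constant in nM (> 0)
#' @param n_members number of members drawn around the consensus
#' @param substitution_rate per-variable-position probability that a member
#'   deviates from the consensus (fixed positions never mutate); in [0, 1)
#' @param abundance_scale pre-selection abundance multiplier relative to the
#'   mean background abundance
#' @return a \code{binder_family} specification
#' @export
binder_family <- function(family_id, consensus, kd_nM, n_members = 20L,
                          substitution_rate = 0.1, abundance_scale = 1) {
  stopifnot(kd_nM > 0, substitution_rate >= 0, substitution_rate < 1,
            n_members >= 1, abundance_scale > 0)
  structure(list(family_id = family_id, consensus = toupper(consensus),
                 kd_nM = kd_nM, n_members = as.integer(n_members),
                 substitution_rate = substitution_rate,
                 abundance_scale = abundance_scale),
            class = "binder_family")
}

#' Sample a log-normal background population
#'
#' Draws distinct design members with log-normal relative abundances
#' normalized to sum to 1, emulating the skewed pre-selection composition of
#' a phage library.
#'
#' @param design a \code{library_design}
#' @param n_sequences number of distinct background members (must not exceed
#'   [theoretical_diversity()])
#' @param lognormal_mu,lognormal_sigma log-scale mean and sd of abundances;
#'   \code{sigma = 0} gives a flat population
#' @param seed RNG seed
#' @return a population data frame with columns \code{peptide},
#'   \code{abundance}, \code{family_id} (NA for background), \code{kd_nM} (NA)
#' @export
sample_background <- function(design, n_sequences, lognormal_mu = 0,
                              lognormal_sigma = 1, seed = 1L) {
  if (n_sequences > theoretical_diversity(design))
    stop("n_sequences exceeds the design's theoretical diversity")
  set.seed(seed)
  peps <- unique(sample_members(design, n_sequences))
  while (length(peps) < n_sequences) {
    peps <- unique(c(peps, sample_members(design, n_sequences - length(peps))))
  }
  ab <- rlnorm(n_sequences, lognormal_mu, lognormal_sigma)
  data.frame(peptide = peps, abundance = ab / sum(ab),
             family_id = NA_character_, kd_nM = NA_real_,
             stringsAsFactors = FALSE)
}

# mutate a consensus at variable positions with the given per-position rate;
# replacement drawn uniformly from the allowed set minus the current residue
mutate_members <- function(consensus, n, rate, design) {
  res <- matrix(rep(strsplit(consensus, "")[[1]], each = n), nrow = n)
  for (j in variable_positions(design)) {
    hit <- runif(n) < rate
    if (any(hit)) {
      allowed <- design$positions[[j]]$allowed
      res[hit, j] <- vapply(res[hit, j], function(cur) {
        alt <- setdiff(allowed, cur)
        if (length(alt) == 0L) cur else sample(alt, 1L)
      }, character(1))
    }
  }
  apply(res, 1L, paste, collapse = "")
}

#' Plant binder families into a background population
#'
#' Each family contributes \code{n_members} sequences obtained by mutating
#' the consensus at variable positions with \code{substitution_rate}; fixed
#' positions are never touched, so all members remain design members. Each
#' planted member receives abundance \code{abundance_scale} times the mean
#' background abundance; the whole population is then renormalized. Duplicate
#' draws of the same member collapse to one row with summed abundance. If a
#' member collides with a sequence already owned by another family, the
#' earlier assignment wins with a warning (disjoint consensus neighborhoods
#' never collide).
#'
#' @param population a background population from [sample_background()]
#' @param families list of [binder_family()] specifications
#' @param design the \code{library_design}
#' @param seed RNG seed
#' @return the augmented population; the truth table is the subset of rows
#'   with non-NA \code{family_id}
#' @export
plant_families <- function(population, families, design, seed = 1L) {
  set.seed(seed)
  mean_ab <- 1 / nrow(population)
  planted <- lapply(families, function(f) {
    if (!matches_design(f$consensus, design))
      stop("family '", f$family_id, "' consensus is not a design member")
    members <- mutate_members(f$consensus, f$n_members, f$substitution_rate,
                              design)
    data.frame(peptide = members,
               abundance = f$abundance_scale * mean_ab,
               family_id = f$family_id, kd_nM = f$kd_nM,
               stringsAsFactors = FALSE)
  })
  pop <- rbind(population, do.call(rbind, planted))
  # collapse duplicates: abundances sum; family label wins over background NA
  agg_ab <- tapply(pop$abundance, pop$peptide, sum)
  fam <- tapply(pop$family_id, pop$peptide, function(v) {
    v <- v[!is.na(v)]
    if (length(unique(v)) > 1L)
      warning("sequence assigned to multiple families; keeping the first")
    if (length(v) == 0L) NA_character_ else v[[1L]]
  })
  kd <- tapply(pop$kd_nM, pop$peptide, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else v[[1L]]
  })
  peps <- sort(names(agg_ab), method = "radix")
  out <- data.frame(peptide = peps,
                    abundance = as.numeric(agg_ab[peps]),
                    family_id = as.character(fam[peps]),
                    kd_nM = as.numeric(kd[peps]),
                    stringsAsFactors = FALSE)
  out$abundance <- out$abundance / sum(out$abundance)
  rownames(out) <- NULL
  out
}

#' Lay out the wells of a screen
#'
#' Builds the well table of a single-round screen: blank (no-bait) wells plus
#' a bait concentration series with replicates, all receiving the spike-in at
#' a target expected read fraction.
#'
#' @param concentrations_nM distinct bait concentrations (nM); at least two
#'   so that a dose-response over bait concentration is evaluable
#' @param n_replicates replicates per concentration (and blanks)
#' @param n_blanks number of blank wells (at least one)
#' @param reads_per_well sequencing depth per well
#' @param spike_in_fraction expected spike-in read fraction per well, in
#'   (0, 0.5)
#' @return a \code{screen_layout} data frame with columns \code{sample_id},
#'   \code{role}, \code{concentration_nM}, \code{replicate}, \code{reads}
#' @export
screen_layout <- function(concentrations_nM, n_replicates = 2L,
                          n_blanks = 2L, reads_per_well = 20000L,
                          spike_in_fraction = 0.05) {
  concentrations_nM <- sort(unique(concentrations_nM))
  if (n_blanks < 1L) stop("at least one blank well is required")
  if (length(concentrations_nM) < 2L)
    stop("at least two distinct bait concentrations are required")
  if (any(concentrations_nM <= 0)) stop("bait concentrations must be > 0")
  if (spike_in_fraction <= 0 || spike_in_fraction >= 0.5)
    stop("spike_in_fraction must lie in (0, 0.5)")
  blanks <- data.frame(
    sample_id = sprintf("blank_r%d", seq_len(n_blanks)), role = "blank",
    concentration_nM = 0, replicate = seq_len(n_blanks),
    stringsAsFactors = FALSE)
  baits <- expand.grid(replicate = seq_len(n_replicates),
                       concentration_nM = concentrations_nM)
  baits <- data.frame(
    sample_id = sprintf("c%04g_r%d", baits$concentration_nM, baits$replicate),
    role = "bait", concentration_nM = baits$concentration_nM,
    replicate = baits$replicate, stringsAsFactors = FALSE)
  layout <- rbind(blanks, baits)
  layout$reads <- as.integer(reads_per_well)
  attr(layout, "spike_in_fraction") <- spike_in_fraction
  class(layout) <- c("screen_layout", "data.frame")
  layout
}

# per-well multinomial weights: background a_s, planted a_s * (1 + beta*theta)
well_weights <- function(population, concentration_nM, beta) {
  theta <- ifelse(is.na(population$kd_nM), 0,
                  concentration_nM / (concentration_nM + population$kd_nM))
  population$abundance * (1 + beta * theta)
}

#' Draw per-well counts from the enrichment model
#'
#' One selection round: in a well at bait concentration C, a planted member
#' with dissociation constant Kd is captured with relative weight
#' a * (1 + beta * theta), theta = C/(C + Kd) (theta = 0 in blanks);
#' background members keep weight a. The spike-in joins the same multinomial
#' draw with weight chosen so its expected read fraction equals the layout's
#' \code{spike_in_fraction}.
#'
#' @param population population with planted families ([plant_families()])
#' @param layout a [screen_layout()]
#' @param beta capture gain (dimensionless, >= 0); 0 disables enrichment
#' @param seed RNG seed
#' @return list with integer \code{counts} (peptides x wells, rownames =
#'   peptides), \code{spike_counts} per well, and the \code{layout}
#' @export
simulate_counts <- function(population, layout, beta = 50, seed = 1L) {
  stopifnot(beta >= 0)
  set.seed(seed)
  f <- attr(layout, "spike_in_fraction")
  counts <- matrix(0L, nrow = nrow(population), ncol = nrow(layout),
                   dimnames = list(population$peptide, layout$sample_id))
  spike_counts <- setNames(integer(nrow(layout)), layout$sample_id)
  for (i in seq_len(nrow(layout))) {
    if (layout$reads[i] == 0L) stop("zero reads requested for well ",
                                    layout$sample_id[i])
    w <- well_weights(population, layout$concentration_nM[i], beta)
    w_spike <- f / (1 - f) * sum(w)
    draw <- rmultinom(1L, layout$reads[i], c(w, w_spike))[, 1L]
    counts[, i] <- draw[seq_len(nrow(population))]
    spike_counts[i] <- draw[nrow(population) + 1L]
  }
  list(counts = counts, spike_counts = spike_counts, layout = layout)
}

# substitute sequencing errors in place on equal-length reads
inject_errors <- function(reads, epsilon) {
  if (epsilon <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads[1L])
  m <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
              nrow = length(reads), byrow = TRUE)
  pos <- which(runif(length(m)) < epsilon)
  if (length(pos) > 0L) {
    bases <- c("A", "C", "G", "T")
    cur <- match(m[pos], bases)
    m[pos] <- bases[((cur - 1L + sample(1:3, length(pos), replace = TRUE)) %% 4L) + 1L]
  }
  apply(m, 1L, paste, collapse = "")
}

#' Simulate a full screen to FASTQ
#'
#' Draws per-well counts with [simulate_counts()], expands them into reads
#' (flank5 + codon-encoded insert + flank3; the spike-in uses its own insert),
#' applies optional per-base substitution errors, reverse-complement
#' orientation, and low-quality 3' tails, and writes one FASTQ per well plus
#' a sample sheet, a truth table and a JSON manifest. Identical seed and
#' configuration give byte-identical outputs.
#'
#' @inheritParams simulate_counts
#' @param design the \code{library_design}
#' @param epsilon per-base substitution error probability, in [0, 0.25)
#' @param rc_fraction fraction of reads emitted reverse-complemented
#' @param lowq_tail_prob probability a read receives an 8-base random tail at
#'   quality 2 (exercises quality trimming)
#' @param outdir output directory (created if needed)
#' @return list with \code{sample_sheet} path, \code{truth} path,
#'   \code{manifest} path, the drawn \code{counts} and \code{spike_counts}
#' @export
simulate_screen <- function(population, layout, design, beta = 50,
                            epsilon = 0, rc_fraction = 0,
                            lowq_tail_prob = 0, outdir, seed = 1L) {
  stopifnot(epsilon >= 0, epsilon < 0.25)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(population, layout, beta = beta, seed = seed)
  set.seed(derive_seed(seed, 1L))
  insert_of <- encode_peptide(population$peptide, design)
  q37 <- rawToChar(as.raw(33L + 37L))
  q2 <- rawToChar(as.raw(33L + 2L))
  layout$fastq <- file.path(outdir, paste0(layout$sample_id, ".fastq"))
  for (i in seq_len(nrow(layout))) {
    n_pep <- sim$counts[, i]
    seqs <- c(rep(paste0(design$flank5, insert_of, design$flank3), n_pep),
              rep(paste0(design$flank5, design$spike_in_dna, design$flank3),
                  sim$spike_counts[i]))
    seqs <- inject_errors(seqs, epsilon)
    if (rc_fraction > 0) {
      flip <- runif(length(seqs)) < rc_fraction
      if (any(flip))
        seqs[flip] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[flip])))
    }
    quals <- strrep(q37, nchar(seqs))
    if (lowq_tail_prob > 0) {
      tail_on <- runif(length(seqs)) < lowq_tail_prob
      if (any(tail_on)) {
        junk <- vapply(seq_len(sum(tail_on)), function(k)
          paste(sample(c("A", "C", "G", "T"), 8L, replace = TRUE),
                collapse = ""), character(1))
        seqs[tail_on] <- paste0(seqs[tail_on], junk)
        quals[tail_on] <- paste0(quals[tail_on], strrep(q2, 8L))
      }
    }
    ord <- sample(length(seqs))
    ids <- paste0("@", layout$sample_id[i], ":", seq_along(seqs))
    writeLines(as.vector(rbind(ids, seqs[ord], "+", quals[ord])),
               layout$fastq[i])
  }
  sheet_path <- file.path(outdir, "samples.csv")
  write.csv(as.data.frame(layout)[, c("sample_id", "role", "concentration_nM",
                                      "replicate", "fastq")],
            sheet_path, row.names = FALSE, quote = FALSE)
  truth <- population[!is.na(population$family_id),
                      c("peptide", "family_id", "kd_nM")]
  truth$is_spike <- logical(nrow(truth))
  truth <- rbind(truth, data.frame(peptide = design$spike_in_label,
                                   family_id = NA_character_, kd_nM = NA_real_,
                                   is_spike = TRUE))
  truth_path <- file.path(outdir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(design = design$name, seed = seed, beta = beta,
                   epsilon = epsilon, rc_fraction = rc_fraction,
                   lowq_tail_prob = lowq_tail_prob,
                   spike_in_fraction = attr(layout, "spike_in_fraction"),
                   wells = nrow(layout), reads = sum(layout$reads))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  list(sample_sheet = sheet_path, truth = truth_path, manifest = manifest_path,
       counts = sim$counts, spike_counts = sim$spike_counts, layout = layout)
}

#' Example planted-family sets
#'
#' Ready-made three-family configurations used by the worked examples: an
#' MDM2-like set whose consensuses carry the N-terminal tryptophan anchor
#' typical of alpha-helical MDM2 binders, and a CHIP-like set with terminal
#' carboxylate residues echoing the C-terminal aspartate of chaperone tails
#' recognized by the CHIP TPR domain. Dissociation constants are spread
#' across the default concentration series.
#'
#' @param target \code{"mdm2"} or \code{"chip"}
#' @return list of three [binder_family()] objects
#' @export
example_families <- function(target = c("mdm2", "chip")) {
  target <- match.arg(target)
  if (target == "mdm2") {
    list(binder_family("MDM2.C1", "LWESAFDSYIAQ", kd_nM = 25),
         binder_family("MDM2.C2", "WAFSIDLSEVMT", kd_nM = 100),
         binder_family("MDM2.C3", "WDYSLFMSQRHN", kd_nM = 400))
  } else {
    list(binder_family("CHIP.C1", "ADDSFWLSTIVE", kd_nM = 25),
         binder_family("CHIP.C2", "DEASLWFSVMTH", kd_nM = 100),
         binder_family("CHIP.C3", "EFVSAILSWQTD", kd_nM = 400))
  }
}
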