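#' Run a screen analysis end to end
#'
#' Orchestrates the whole pipeline into one reproducible run: optional
#' synthetic-screen simulation (or a user sample sheet over existing FASTQ),
#' decoding into counts, spike-in normalization and hit calling, family
#' clustering with logos, and the D-candidate synthesis report. All
#' intermediate files are plain TSV/CSV/FASTA/FASTQ so any stage can be
#' rerun standalone; a JSON manifest records every parameter, the seed, and
#' per-stage record counts. The same config and seed give byte-identical
#' outputs. A single top-level seed fans out to deterministic per-stage
#' child seeds so stages can be reproduced in isolation.
#'
#' @param design a \code{library_design} (default [default_design()])
#' @param sample_sheet path to a sample sheet over existing FASTQ; exactly
#'   one of \code{sample_sheet} and \code{simulation} must be given
#' @param simulation list describing a synthetic screen:
#'   \code{families} (list of [binder_family()]), \code{n_background},
#'   \code{lognormal_sigma}, \code{layout} (a [screen_layout()]),
#'   \code{beta}, \code{epsilon}, and optional \code{rc_fraction},
#'   \code{lowq_tail_prob}
#' @param outdir output directory
#' @param seed top-level RNG seed (mandatory when simulating)
#' @param hitcall list of hit-calling thresholds passed to [call_hits()]
#' @param cluster list of clustering parameters passed to [cluster_hits()]
#' @param substitute_met_nle apply the Met-to-Nle rule in the candidate
#'   report?
#' @return (invisibly) list with the \code{count_matrix}, \code{hit_table},
#'   \code{binder_families}, candidate report and output paths
#' @export
run_screen <- function(design = default_design(), sample_sheet = NULL,
                       simulation = NULL, outdir, seed = 1L,
                       hitcall = list(), cluster = list(),
                       substitute_met_nle = FALSE) {
  if (is.null(sample_sheet) == is.null(simulation))
    stop("config error: provide exactly one of sample_sheet or simulation")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage_counts <- list()

  if (!is.null(simulation)) {
    sim <- withCallingHandlers(
      simulate_from_config(design, simulation, file.path(outdir, "sim"), seed),
      error = function(e) stop("stage 'simulate' failed: ",
                               conditionMessage(e), call. = FALSE))
    sample_sheet <- sim$sample_sheet
    stage_counts$simulated_reads <- sum(sim$counts) + sum(sim$spike_counts)
  }

  cm <- tryCatch(tally_screen(sample_sheet, design),
                 error = function(e) stop("stage 'decode' failed: ",
                                          conditionMessage(e), call. = FALSE))
  write_counts(cm, file.path(outdir, "counts.tsv"),
               file.path(outdir, "rejections.tsv"))
  stage_counts$decoded_total <- sum(cm$total_reads)
  stage_counts$decoded_assigned <- sum(cm$counts)
  stage_counts$decoded_spike <- sum(cm$spike_counts)
  stage_counts$decoded_rejected <- sum(cm$rejected)

  hits <- tryCatch(do.call(call_hits, c(list(cm), hitcall)),
                   error = function(e) stop("stage 'hitcall' failed: ",
                                            conditionMessage(e), call. = FALSE))
  write_hit_table(hits, file.path(outdir, "hits.tsv"),
                  file.path(outdir, "thresholds.json"))
  stage_counts$hits <- sum(hits$is_hit)

  fams <- NULL
  report <- NULL
  if (sum(hits$is_hit) > 0L) {
    fams <- tryCatch(do.call(cluster_hits, c(list(hits, design), cluster)),
                     error = function(e) stop("stage 'cluster' failed: ",
                                              conditionMessage(e),
                                              call. = FALSE))
    write_families(fams, outdir)
    stage_counts$families <- length(fams$families)
    stage_counts$singletons <- length(fams$singletons)
    if (length(fams$families) > 0L) {
      report <- synthesis_report(fams, substitute_met_nle)
      write_candidates(report, file.path(outdir, "candidates.tsv"),
                       file.path(outdir, "candidates.fasta"))
      stage_counts$candidates <- nrow(report)
    }
  } else {
    # empty families file so downstream consumers always find it
    write.table(data.frame(peptide = character(0), family_id = character(0),
                           hit_strength = numeric(0)),
                file.path(outdir, "families.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    stage_counts$families <- 0L
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mipd")),
    design = design$name, seed = seed,
    hitcall = attr(hits, "thresholds"),
    cluster = if (!is.null(fams)) fams$params else NULL,
    substitute_met_nle = substitute_met_nle,
    stage_counts = stage_counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(counts = cm, hits = hits, families = fams,
                 candidates = report, outdir = outdir,
                 manifest = file.path(outdir, "manifest.json")))
}

# build population + layout from a simulation config block and simulate
simulate_from_config <- function(design, cfg, outdir, seed) {
  defaults <- list(n_background = 5000L, lognormal_mu = 0, lognormal_sigma = 1,
                   beta = 50, epsilon = 0, rc_fraction = 0,
                   lowq_tail_prob = 0, families = list(),
                   layout = screen_layout(c(12.5, 50, 200, 800)))
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  pop <- sample_background(design, cfg$n_background, cfg$lognormal_mu,
                           cfg$lognormal_sigma, seed = derive_seed(seed, 10L))
  if (length(cfg$families) > 0L)
    pop <- plant_families(pop, cfg$families, design,
                          seed = derive_seed(seed, 11L))
  simulate_screen(pop, cfg$layout, design, beta = cfg$beta,
                  epsilon = cfg$epsilon, rc_fraction = cfg$rc_fraction,
                  lowq_tail_prob = cfg$lowq_tail_prob, outdir = outdir,
                  seed = derive_seed(seed, 12L))
}

#' Read a run configuration file
#'
#' YAML run configuration for [run_screen()]: a \code{design} path plus
#' exactly one of \code{sample_sheet} or a \code{simulation} block
#' (\code{target} selecting [example_families()], or explicit families with
#' \code{family_id}, \code{consensus}, \code{kd_nM}, ...), along with
#' optional \code{hitcall} and \code{cluster} threshold blocks.
#'
#' @param path YAML file
#' @return list of arguments for [run_screen()]
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  args <- list()
  args$design <- if (is.null(doc$design)) default_design()
                 else load_design(doc$design)
  if (!is.null(doc$sample_sheet)) args$sample_sheet <- doc$sample_sheet
  if (!is.null(doc$simulation)) {
    sim <- doc$simulation
    if (!is.null(sim$target)) {
      sim$families <- example_families(sim$target)
      sim$target <- NULL
    } else if (!is.null(sim$families)) {
      sim$families <- lapply(sim$families, function(f)
        do.call(binder_family, f))
    }
    if (!is.null(sim$layout)) sim$layout <- do.call(screen_layout, sim$layout)
    args$simulation <- sim
  }
  if (!is.null(doc$hitcall)) args$hitcall <- doc$hitcall
  if (!is.null(doc$cluster)) args$cluster <- doc$cluster
  if (!is.null(doc$substitute_met_nle))
    args$substitute_met_nle <- doc$substitute_met_nle
  args
}
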