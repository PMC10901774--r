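#' Spike-in normalization of screen counts
#'
#' Divides every peptide's raw count in a sample by that sample's spike-in
#' count, yielding abundances in units of reads per spike-in read that are
#' comparable across wells regardless of sequencing depth. A sample whose
#' spike-in count is zero cannot be normalized; it is excluded with a
#' warning.
#'
#' @param x a \code{count_matrix}
#' @return list with \code{values} (numeric matrix, peptides x valid
#'   samples), \code{samples} (sheet rows for valid samples) and
#'   \code{spike_counts}
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  valid <- x$spike_counts > 0
  if (!all(valid))
    warning("excluding sample(s) with zero spike-in count: ",
            paste(names(x$spike_counts)[!valid], collapse = ", "))
  if (!any(valid)) stop("no sample has a positive spike-in count")
  values <- sweep(x$counts[, valid, drop = FALSE], 2L,
                  x$spike_counts[valid], "/")
  list(values = values, samples = x$samples[valid, , drop = FALSE],
       spike_counts = x$spike_counts[valid])
}

#' Blank counts as they enter the Hit Strength denominator
#'
#' The fold-change denominator uses blank raw counts with the zero-count
#' substitution: a blank count of 0 is replaced by 0.5 before dividing by
#' that blank's spike-in count, so Hit Strength stays finite for sequences
#' absent from the blanks. Non-zero counts are untouched.
#'
#' @param counts integer matrix of blank raw counts (peptides x blank
#'   samples)
#' @param pseudocount value substituted for zeros (default 0.5)
#' @return numeric matrix of effective blank counts
#' @export
effective_blank_counts <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  out <- counts * 1.0
  out[counts == 0] <- pseudocount
  out
}

# sample-sheet helpers
blank_samples <- function(samples)
  samples$sample_id[samples$role == "blank" | samples$concentration_nM == 0]
highest_conc_samples <- function(samples) {
  bait <- samples[samples$concentration_nM > 0, , drop = FALSE]
  bait$sample_id[bait$concentration_nM == max(bait$concentration_nM)]
}

#' Hit Strength: normalized fold change over blanks
#'
#' For each sequence, the fold change between its mean spike-in-normalized
#' count across the highest-bait-concentration replicates and its mean
#' normalized count across the blank replicates, where zero blank counts are
#' substituted with \code{pseudocount} (per replicate, before normalization)
#' so the denominator is never zero.
#'
#' @param norm output of [normalize_counts()]
#' @param pseudocount blank zero-count substitution (default 0.5)
#' @return named numeric vector of Hit Strength values, finite for every
#'   peptide
#' @export
hit_strength <- function(norm, pseudocount = 0.5) {
  blanks <- intersect(blank_samples(norm$samples), colnames(norm$values))
  high <- intersect(highest_conc_samples(norm$samples), colnames(norm$values))
  if (length(blanks) == 0L) stop("no valid blank sample")
  if (length(high) == 0L) stop("no valid highest-concentration sample")
  num <- rowMeans(norm$values[, high, drop = FALSE])
  raw_blank <- sweep(norm$values[, blanks, drop = FALSE], 2L,
                     norm$spike_counts[blanks], "*")
  eff <- effective_blank_counts(round(raw_blank), pseudocount)
  den <- rowMeans(sweep(eff, 2L, norm$spike_counts[blanks], "/"))
  num / den
}

#' Dose-response statistic over the concentration series
#'
#' Rank correlation (Spearman, ties mid-ranked) between each sequence's
#' per-concentration-level mean normalized count and the concentration rank,
#' blank wells included as concentration 0. A genuine binder's occupancy
#' grows monotonically with bait concentration, so its statistic approaches
#' 1; a flat profile (all ties) scores 0.
#'
#' @param norm output of [normalize_counts()]
#' @param min_rho pass threshold on the rank correlation (default 0.8)
#' @return data frame with \code{dose_rho} and logical \code{dose_pass}; if
#'   fewer than 3 concentration levels are available the gate degrades to
#'   pass-all with a warning
#' @export
dose_response <- function(norm, min_rho = 0.8) {
  conc <- norm$samples$concentration_nM[match(colnames(norm$values),
                                              norm$samples$sample_id)]
  levels <- sort(unique(conc))
  if (length(levels) < 3L) {
    warning("fewer than 3 concentration levels: dose-response not ",
            "evaluable, gate degrades to Hit Strength only")
    return(data.frame(peptide = rownames(norm$values), dose_rho = NA_real_,
                      dose_pass = TRUE, stringsAsFactors = FALSE))
  }
  level_means <- vapply(levels, function(cc)
    rowMeans(norm$values[, conc == cc, drop = FALSE]),
    numeric(nrow(norm$values)))
  if (is.null(dim(level_means)))  # single peptide: keep the matrix shape
    level_means <- matrix(level_means, nrow = 1L)
  rk <- t(apply(level_means, 1L, rank))
  rho <- suppressWarnings(
    as.numeric(cor(t(rk), seq_along(levels), method = "pearson")))
  rho[is.na(rho)] <- 0  # constant profile: all ties, no dose response
  data.frame(peptide = rownames(norm$values), dose_rho = rho,
             dose_pass = rho >= min_rho, stringsAsFactors = FALSE)
}

#' Call hits from a decoded screen
#'
#' The full hit-calling stage: spike-in normalization, Hit Strength with the
#' blank pseudocount, the dose-response gate, and a minimum raw-count filter
#' at the highest bait concentration. A sequence is a hit iff it passes all
#' three gates; the spike-in itself (whose Hit Strength is identically 1) is
#' tracked as a row but never called.
#'
#' @param x a \code{count_matrix}
#' @param pseudocount blank zero-count substitution (default 0.5)
#' @param hs_min Hit Strength threshold (default 5)
#' @param min_rho dose-response rank-correlation threshold (default 0.8)
#' @param min_reads minimum summed raw count across highest-concentration
#'   replicates (default 5)
#' @return a \code{hit_table}: data frame with one row per peptide (plus the
#'   spike-in) and columns \code{peptide}, \code{is_spike},
#'   \code{hit_strength}, \code{dose_rho}, \code{high_count}, pass flags and
#'   \code{is_hit}; thresholds are attached as attributes
#' @export
call_hits <- function(x, pseudocount = 0.5, hs_min = 5, min_rho = 0.8,
                      min_reads = 5L) {
  stopifnot(inherits(x, "count_matrix"))
  aug <- x
  aug$counts <- rbind(x$counts,
                      matrix(x$spike_counts, nrow = 1,
                             dimnames = list(x$spike_label, NULL)))
  norm <- normalize_counts(aug)
  hs <- hit_strength(norm, pseudocount)
  dr <- dose_response(norm, min_rho)
  high <- intersect(highest_conc_samples(norm$samples), colnames(norm$values))
  high_count <- rowSums(aug$counts[, high, drop = FALSE])
  is_spike <- rownames(norm$values) == x$spike_label
  tab <- data.frame(
    peptide = rownames(norm$values), is_spike = is_spike,
    hit_strength = as.numeric(hs), dose_rho = dr$dose_rho,
    high_count = as.numeric(high_count),
    passes_hs = as.numeric(hs) >= hs_min, dose_pass = dr$dose_pass,
    stringsAsFactors = FALSE)
  tab$is_hit <- tab$passes_hs & tab$dose_pass &
    tab$high_count >= min_reads & !tab$is_spike
  rownames(tab) <- NULL
  structure(tab,
            thresholds = list(pseudocount = pseudocount, hs_min = hs_min,
                              min_rho = min_rho, min_reads = min_reads),
            normalized = norm$values, samples = norm$samples,
            class = c("hit_table", "data.frame"))
}

#' @export
print.hit_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("Hit table: ", sum(!x$is_spike), " sequences, ", sum(x$is_hit),
      " hits (HS >= ", th$hs_min, ", dose rho >= ", th$min_rho,
      ", reads >= ", th$min_reads, ")\n", sep = "")
  hits <- x[x$is_hit, c("peptide", "hit_strength", "dose_rho", "high_count")]
  hits <- hits[order(-hits$hit_strength), ]
  print.data.frame(head(hits, 10L), row.names = FALSE, digits = 3)
  if (nrow(hits) > 10L) cat("... and", nrow(hits) - 10L, "more\n")
  invisible(x)
}

#' @export
summary.hit_table <- function(object, ...) {
  th <- attr(object, "thresholds")
  cat("Sequences:", sum(!object$is_spike), "\n")
  cat("Pass Hit Strength >=", th$hs_min, ":",
      sum(object$passes_hs & !object$is_spike), "\n")
  cat("Pass dose-response >=", th$min_rho, ":",
      sum(object$dose_pass & !object$is_spike), "\n")
  cat("Hits:", sum(object$is_hit), "\n")
  invisible(object)
}

#' Write the hit table with per-sample counts and normalized values
#'
#' @param x a \code{hit_table}
#' @param file output TSV path
#' @param thresholds_file optional JSON sidecar echoing the thresholds
#' @export
write_hit_table <- function(x, file, thresholds_file = NULL) {
  norm <- attr(x, "normalized")
  out <- cbind(x, setNames(as.data.frame(norm, row.names = NULL),
                           paste0("norm_", colnames(norm))))
  write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(thresholds_file))
    jsonlite::write_json(attr(x, "thresholds"), thresholds_file,
                         auto_unbox = TRUE, digits = NA)
  invisible(file)
}
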