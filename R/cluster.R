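# similarity over the design alphabet, affinely rescaled so every residue's
# self-similarity is 1 and the least-similar pair scores 0
scaled_similarity <- function(design, metric = c("blosum", "hamming")) {
  metric <- match.arg(metric)
  ab <- design$alphabet
  if (metric == "hamming") {
    sim <- diag(length(ab))
    dimnames(sim) <- list(ab, ab)
    return(sim)
  }
  blosum <- get_blosum62()[ab, ab]
  norm <- blosum / sqrt(outer(diag(blosum), diag(blosum)))
  lo <- min(norm)
  (norm - lo) / (1 - lo)
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Pairwise peptide dissimilarity over variable positions
#'
#' For equal-length design members, d(a, b) = 1 - mean over variable
#' positions of a substitution-matrix similarity rescaled to [0, 1]
#' (self-similarity 1, least-similar residue pair 0). Fixed positions are
#' identical by construction and are excluded. The metric satisfies
#' identity (d(a,a) = 0), symmetry and boundedness in [0, 1]; it need not
#' satisfy the triangle inequality.
#'
#' @param peptides character vector of design members (all one length)
#' @param design the \code{library_design}
#' @param metric \code{"blosum"} (rescaled BLOSUM62 similarity, default) or
#'   \code{"hamming"} (identity similarity)
#' @return symmetric numeric matrix of dissimilarities in [0, 1]
#' @export
peptide_distance <- function(peptides, design,
                             metric = c("blosum", "hamming")) {
  if (length(unique(nchar(peptides))) > 1L)
    stop("peptides must all have the design length")
  sim <- scaled_similarity(design, metric)
  vp <- variable_positions(design)
  chars <- do.call(rbind, strsplit(peptides, "", fixed = TRUE))
  n <- length(peptides)
  d <- matrix(0, n, n, dimnames = list(peptides, peptides))
  for (j in vp) {
    idx <- match(chars[, j], rownames(sim))
    d <- d + (1 - sim[idx, idx, drop = FALSE])
  }
  d <- d / length(vp)
  d
}

#' Cluster hit peptides into binder families
#'
#' Average-linkage agglomerative clustering on [peptide_distance()], cut at
#' a fixed dissimilarity height. Clusters smaller than
#' \code{min_family_size} are reported as singletons rather than families.
#' Family labels are assigned deterministically (by decreasing size, ties by
#' the lexicographically smallest member), so the partition is invariant to
#' the input order of peptides.
#'
#' @param hits a \code{hit_table} (its \code{is_hit} rows are clustered) or a
#'   character vector of peptides
#' @param design the \code{library_design}
#' @param metric distance metric, see [peptide_distance()]
#' @param linkage agglomeration method for [stats::hclust()]
#' @param cut_height flat-cut dissimilarity (default 0.5)
#' @param min_family_size smallest cluster reported as a family (default 3)
#' @param hs optional named Hit Strength vector (taken from the hit table
#'   when \code{hits} is one)
#' @return a \code{binder_families} object: per-family members, Hit
#'   Strengths, consensus and logo matrix, plus singleton peptides
#' @export
cluster_hits <- function(hits, design, metric = c("blosum", "hamming"),
                         linkage = "average", cut_height = 0.5,
                         min_family_size = 3L, hs = NULL) {
  if (inherits(hits, "hit_table")) {
    sel <- hits[hits$is_hit, , drop = FALSE]
    peptides <- sel$peptide
    hs <- setNames(sel$hit_strength, sel$peptide)
  } else {
    peptides <- as.character(hits)
    if (is.null(hs)) hs <- setNames(rep(NA_real_, length(peptides)), peptides)
  }
  if (length(peptides) == 0L) stop("empty hit set: nothing to cluster")
  ord <- order(peptides, method = "radix")
  peptides <- peptides[ord]
  if (length(peptides) == 1L) {
    membership <- setNames(1L, peptides)
  } else {
    d <- peptide_distance(peptides, design, metric)
    tree <- stats::hclust(stats::as.dist(d), method = linkage)
    membership <- stats::cutree(tree, h = cut_height)
    names(membership) <- peptides
  }
  sizes <- table(membership)
  real <- names(sizes)[sizes >= min_family_size]
  fam_members <- lapply(real, function(k) names(membership)[membership == k])
  # deterministic labels: by size desc, then smallest member
  if (length(fam_members) > 0L) {
    key <- vapply(fam_members, function(m) m[[1L]], character(1))
    o <- order(-vapply(fam_members, length, integer(1)), key, method = "radix")
    fam_members <- fam_members[o]
  }
  families <- lapply(seq_along(fam_members), function(i) {
    m <- fam_members[[i]]
    cl <- consensus_logo(m, design)
    list(family_id = sprintf("F%d", i), members = m,
         hs = unname(hs[m]), consensus = cl$consensus, logo = cl$logo,
         ic = cl$ic, fixed_mask = cl$fixed_mask)
  })
  singletons <- setdiff(peptides, unlist(fam_members))
  structure(list(families = families, singletons = lex_sort(singletons),
                 design = design,
                 params = list(metric = match.arg(metric), linkage = linkage,
                               cut_height = cut_height,
                               min_family_size = min_family_size)),
            class = "binder_families")
}

#' Consensus and logo matrix of a peptide family
#'
#' The consensus takes the modal residue at each position (ties broken by
#' design-alphabet order); the logo matrix gives per-position residue
#' frequencies over the design alphabet (columns sum to 1). Per-position
#' information content is IC_j = log2 |A_j| + sum_r p_jr log2 p_jr with
#' 0 log 0 = 0 and A_j the position's allowed set, so a uniformly used
#' position scores 0 bits and an invariant position log2 |A_j| bits.
#'
#' @param members character vector of equal-length design members
#' @param design the \code{library_design}
#' @param weights optional non-negative member weights (e.g. normalized
#'   abundances); default unweighted
#' @return list with \code{consensus}, \code{logo} (alphabet x positions),
#'   \code{ic} (bits per position) and logical \code{fixed_mask}
#' @export
consensus_logo <- function(members, design, weights = NULL) {
  if (length(members) == 0L) stop("empty family")
  if (is.null(weights)) weights <- rep(1, length(members))
  stopifnot(length(weights) == length(members), all(weights >= 0),
            sum(weights) > 0)
  npos <- length(design$positions)
  chars <- do.call(rbind, strsplit(members, "", fixed = TRUE))
  ab <- design$alphabet
  logo <- matrix(0, nrow = length(ab), ncol = npos,
                 dimnames = list(ab, seq_len(npos)))
  for (j in seq_len(npos)) {
    w <- tapply(weights, factor(chars[, j], levels = ab), sum)
    w[is.na(w)] <- 0
    logo[, j] <- w / sum(w)
  }
  consensus <- paste(vapply(seq_len(npos), function(j) {
    ab[which.max(logo[, j])]  # which.max takes the first = alphabet order
  }, character(1)), collapse = "")
  asize <- vapply(design$positions, function(p)
    if (p$type == "fixed") 1L else length(p$allowed), integer(1))
  ic <- vapply(seq_len(npos), function(j) {
    p <- logo[, j]
    p <- p[p > 0]
    log2(asize[j]) + sum(p * log2(p))
  }, numeric(1))
  fixed_mask <- vapply(design$positions, function(p) p$type == "fixed",
                       logical(1))
  list(consensus = consensus, logo = logo, ic = ic, fixed_mask = fixed_mask)
}

#' @export
print.binder_families <- function(x, ...) {
  cat("Binder families: ", length(x$families), " (",
      length(x$singletons), " singletons)\n", sep = "")
  for (f in x$families) {
    cat("  ", f$family_id, ": ", length(f$members), " members, consensus ",
        f$consensus, sep = "")
    if (!all(is.na(f$hs)))
      cat(", median HS ", signif(median(f$hs, na.rm = TRUE), 3), sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Plot per-position information content of a family logo
#'
#' Base-graphics bar plot of information content (bits) per position; fixed
#' scaffold positions are drawn in grey, variable positions in black.
#'
#' @param x a \code{binder_families} object
#' @param family index or family_id of the family to plot
#' @param ... passed to [graphics::barplot()]
#' @export
plot.binder_families <- function(x, family = 1L, ...) {
  f <- if (is.character(family)) {
    ids <- vapply(x$families, `[[`, character(1), "family_id")
    x$families[[match(family, ids)]]
  } else x$families[[family]]
  cols <- ifelse(f$fixed_mask, "grey70", "grey20")
  graphics::barplot(f$ic, names.arg = seq_along(f$ic), col = cols,
                    xlab = "position", ylab = "information (bits)",
                    main = paste0(f$family_id, "  ", f$consensus), ...)
  invisible(x)
}

#' Write family outputs
#'
#' Emits a families TSV (peptide, family_id, hit_strength; singletons
#' labelled \code{singleton}), a consensus FASTA, and one logo-matrix TSV per
#' family (rows = alphabet, columns = positions, position-specific
#' probability matrix layout, with a fixed-position mask row).
#'
#' @param x a \code{binder_families} object
#' @param dir output directory
#' @export
write_families <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, c(
    lapply(x$families, function(f)
      data.frame(peptide = f$members, family_id = f$family_id,
                 hit_strength = f$hs, stringsAsFactors = FALSE)),
    list(if (length(x$singletons) > 0L)
      data.frame(peptide = x$singletons, family_id = "singleton",
                 hit_strength = NA_real_, stringsAsFactors = FALSE))))
  write.table(rows, file.path(dir, "families.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (length(x$families) > 0L) {
    cons <- Biostrings::AAStringSet(
      setNames(vapply(x$families, `[[`, character(1), "consensus"),
               vapply(x$families, `[[`, character(1), "family_id")))
    Biostrings::writeXStringSet(cons, file.path(dir, "consensus.fasta"))
    for (f in x$families) {
      tab <- rbind(f$logo, fixed = as.numeric(f$fixed_mask))
      df <- data.frame(residue = rownames(tab), tab, check.names = FALSE,
                       row.names = NULL)
      write.table(df, file.path(dir, paste0("logo_", f$family_id, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
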