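#' Chiral peptide representation
#'
#' A peptide as an ordered list of residue tokens with per-residue chirality.
#' Rendering follows the mirror-image display convention: upper-case letters
#' for L residues, lower-case for D residues, and the bracketed token
#' \code{[nle]} for D-norleucine (brackets keep parsing unambiguous, since
#' n, l and e are themselves valid residue letters). Glycine is achiral but
#' is rendered lower-case in a D context for string consistency.
#'
#' @param tokens character vector of residue tokens (one-letter codes or
#'   \code{"nle"})
#' @param chirality character vector over \code{"L"}, \code{"D"},
#'   \code{"achiral"}
#' @param label optional name
#' @param staple_positions optional metadata pair
#' @return a \code{chiral_peptide}
#' @export
chiral_peptide <- function(tokens, chirality, label = "",
                           staple_positions = NULL) {
  stopifnot(length(tokens) == length(chirality),
            all(chirality %in% c("L", "D", "achiral")))
  bad <- !(toupper(tokens) %in% CANONICAL_AA | tokens == "nle")
  if (any(bad))
    stop("unknown residue token(s): ", paste(tokens[bad], collapse = ","))
  structure(list(tokens = tokens, chirality = chirality, label = label,
                 staple_positions = staple_positions),
            class = "chiral_peptide")
}

#' Mirror an L-peptide into its D-enantiomer sequence
#'
#' The mirror-image principle: a D-peptide binding the natural L-protein is
#' the chirality-inverted copy (same residue order, NOT retro-inverso) of an
#' L-peptide selected against the D-protein. Optionally substitutes every
#' methionine with norleucine, the isostere used at synthesis to avoid
#' side-chain oxidation.
#'
#' @param peptide upper-case L-sequence
#' @param substitute_met_nle replace M with the \code{nle} token?
#' @param label,staple_positions carried into the result
#' @return a D [chiral_peptide()]
#' @export
to_d <- function(peptide, substitute_met_nle = FALSE, label = "",
                 staple_positions = NULL) {
  tokens <- toupper(strsplit(peptide, "", fixed = TRUE)[[1L]])
  bad <- !tokens %in% CANONICAL_AA
  if (any(bad))
    stop("unknown residue letter(s): ", paste(tokens[bad], collapse = ","))
  chirality <- ifelse(tokens == "G", "achiral", "D")
  tokens <- tolower(tokens)
  if (substitute_met_nle) tokens[tokens == "m"] <- "nle"
  chiral_peptide(tokens, chirality, label, staple_positions)
}

#' Recover the L-sequence from a D chiral peptide
#'
#' Inverse of [to_d()] when no synthesis substitution was applied;
#' substituted tokens (norleucine) have no unique L precursor and raise an
#' error naming the position.
#'
#' @param x a \code{chiral_peptide}
#' @return upper-case L-sequence string
#' @export
to_l <- function(x) {
  stopifnot(inherits(x, "chiral_peptide"))
  sub <- which(nchar(x$tokens) > 1L)
  if (length(sub) > 0L)
    stop("non-invertible substituted token(s) at position(s): ",
         paste(sub, collapse = ","))
  paste(toupper(x$tokens), collapse = "")
}

#' Render a chiral peptide as a string
#'
#' L residues upper-case, D (and achiral-in-D-context) residues lower-case,
#' multi-letter tokens bracketed. [parse_chiral()] inverts this exactly.
#'
#' @param x a \code{chiral_peptide}
#' @param ... ignored
#' @export
format.chiral_peptide <- function(x, ...) {
  paste(vapply(seq_along(x$tokens), function(i) {
    tok <- x$tokens[i]
    if (nchar(tok) > 1L) paste0("[", tok, "]")
    else if (x$chirality[i] == "L") toupper(tok) else tolower(tok)
  }, character(1)), collapse = "")
}

#' @export
print.chiral_peptide <- function(x, ...) {
  cat(format(x))
  if (nzchar(x$label)) cat("  (", x$label, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Parse a rendered chiral-peptide string
#'
#' @param s string as produced by [format.chiral_peptide()]
#' @param label optional name
#' @return a \code{chiral_peptide}
#' @export
parse_chiral <- function(s, label = "") {
  toks <- regmatches(s, gregexpr("\\[[a-z]+\\]|[A-Za-z]", s))[[1L]]
  tokens <- character(length(toks))
  chirality <- character(length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (startsWith(t, "[")) {
      tokens[i] <- substr(t, 2L, nchar(t) - 1L)
      chirality[i] <- "D"
    } else if (t == toupper(t)) {
      tokens[i] <- t
      chirality[i] <- if (t == "G") "achiral" else "L"
    } else {
      tokens[i] <- t
      chirality[i] <- if (t == "g") "achiral" else "D"
    }
  }
  chiral_peptide(tokens, chirality, label)
}

#' D-candidate synthesis report for binder families
#'
#' For each family, renders the consensus and the top-Hit-Strength member as
#' D-peptide synthesis candidates, with staple metadata and a note recording
#' any Met-to-Nle substitution.
#'
#' @param families a \code{binder_families} object
#' @param substitute_met_nle apply the Met-to-Nle synthesis substitution?
#' @return data frame with columns \code{family_id}, \code{kind}
#'   (\code{consensus} or \code{top_hit}), \code{l_sequence},
#'   \code{d_candidate}, \code{hit_strength}, \code{staple_positions},
#'   \code{note}
#' @export
synthesis_report <- function(families, substitute_met_nle = FALSE) {
  stopifnot(inherits(families, "binder_families"))
  if (length(families$families) == 0L) stop("no families to report")
  staple <- families$design$staple_positions
  staple_str <- if (is.null(staple)) "" else paste(staple, collapse = ",")
  rows <- lapply(families$families, function(f) {
    top <- if (all(is.na(f$hs))) f$members[[1L]]
           else f$members[[which.max(f$hs)]]
    entries <- list(list(kind = "consensus", seq = f$consensus, hs = NA_real_),
                    list(kind = "top_hit", seq = top,
                         hs = suppressWarnings(max(f$hs))))
    do.call(rbind, lapply(entries, function(e) {
      d <- to_d(e$seq, substitute_met_nle, label = f$family_id,
                staple_positions = staple)
      data.frame(family_id = f$family_id, kind = e$kind,
                 l_sequence = e$seq, d_candidate = format(d),
                 hit_strength = e$hs, staple_positions = staple_str,
                 note = if (substitute_met_nle && grepl("M", e$seq, fixed = TRUE))
                   "Met->Nle substituted" else "",
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the D-candidate report
#'
#' Writes the candidates TSV and a FASTA-like file whose record headers
#' carry a chirality tag (\code{chirality=D}).
#'
#' @param report output of [synthesis_report()]
#' @param file TSV path
#' @param fasta_file optional FASTA-like path
#' @export
write_candidates <- function(report, file, fasta_file = NULL) {
  write.table(report, file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(fasta_file)) {
    lines <- unlist(lapply(seq_len(nrow(report)), function(i)
      c(sprintf(">%s_%s chirality=D staple=%s", report$family_id[i],
                report$kind[i], report$staple_positions[i]),
        report$d_candidate[i])))
    writeLines(lines, fasta_file)
  }
  invisible(file)
}
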