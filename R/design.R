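#' @importFrom stats cor median rlnorm rmultinom runif setNames
#' @importFrom utils read.csv write.csv write.table head modifyList
NULL

CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load and validate a stapled-peptide library design
#'
#' Reads a YAML library-design document describing the displayed scaffold:
#' the allowed amino-acid alphabet with one trimer codon per residue (the
#' library is built from whole-codon trimer phosphoramidite blocks, so each
#' residue maps to exactly one codon), the ordered peptide positions (fixed
#' residue or variable over a subset of the alphabet), the constant DNA
#' flanks bounding the insert, optional staple positions (metadata only; no
#' cross-link chemistry is modeled), and the spike-in insert used for
#' cross-well normalization.
#'
#' Validation enforces: alphabet letters are canonical and unique; the codon
#' map covers exactly the alphabet with distinct ACGT trimers that translate
#' (standard genetic code) back to their residue; every variable position has
#' a non-empty allowed set; flanks are non-empty DNA and neither contains the
#' other; the spike-in insert has the insert length and does NOT translate to
#' a library member (it must stay outside the design so its counts never mix
#' with library counts).
#'
#' @param path path to a YAML design document. Keys: \code{name},
#'   \code{alphabet}, \code{codon_map}, \code{positions} (list of
#'   \code{fixed: X} or \code{variable: [..]} / \code{variable: all}),
#'   \code{flank5}, \code{flank3}, \code{staple_positions} (optional),
#'   \code{spike_in_dna}, \code{spike_in_label}.
#' @return a validated \code{library_design} object.
#' @export
load_design <- function(path) {
  doc <- yaml::read_yaml(path)
  required <- c("name", "alphabet", "codon_map", "positions",
                "flank5", "flank3", "spike_in_dna")
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0L)
    stop("design document missing field(s): ", paste(missing, collapse = ", "))

  alphabet <- toupper(unlist(doc$alphabet))
  codon_map <- vapply(doc$codon_map, toupper, character(1))
  positions <- lapply(doc$positions, function(p) {
    if (!is.null(p$fixed)) {
      list(type = "fixed", residue = toupper(p$fixed))
    } else if (!is.null(p$variable)) {
      allowed <- if (identical(p$variable, "all")) alphabet
                 else toupper(unlist(p$variable))
      list(type = "variable", allowed = allowed)
    } else {
      stop("each position must be 'fixed' or 'variable'")
    }
  })
  new_library_design(
    name = doc$name, alphabet = alphabet, codon_map = codon_map,
    positions = positions, flank5 = toupper(doc$flank5),
    flank3 = toupper(doc$flank3),
    staple_positions = if (is.null(doc$staple_positions)) NULL
                       else as.integer(unlist(doc$staple_positions)),
    spike_in_dna = toupper(doc$spike_in_dna),
    spike_in_label = if (is.null(doc$spike_in_label)) "SPIKE"
                     else doc$spike_in_label)
}

#' Construct a library design from components
#'
#' Lower-level constructor behind [load_design()]; performs full validation.
#' @inheritParams load_design
#' @param name,alphabet,codon_map,positions,flank5,flank3 design components
#' @param staple_positions optional integer pair, metadata only
#' @param spike_in_dna,spike_in_label spike-in insert DNA and its row label
#' @return a \code{library_design} object
#' @export
new_library_design <- function(name, alphabet, codon_map, positions,
                               flank5, flank3, staple_positions = NULL,
                               spike_in_dna, spike_in_label = "SPIKE") {
  bad <- setdiff(alphabet, CANONICAL_AA)
  if (length(bad) > 0L)
    stop("invalid residue letter(s) in alphabet: ", paste(bad, collapse = ","))
  if (anyDuplicated(alphabet))
    stop("alphabet letters must be unique")
  if (!setequal(names(codon_map), alphabet))
    stop("codon_map keys must equal the alphabet exactly")
  codon_map <- codon_map[alphabet]  # design-alphabet order throughout
  if (any(nchar(codon_map) != 3L) || any(grepl("[^ACGT]", codon_map)))
    stop("codons must be length-3 over {A,C,G,T}")
  if (anyDuplicated(codon_map))
    stop("codon collision: codons must be pairwise distinct")
  tr <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(unname(codon_map)), no.init.codon = TRUE))
  if (!identical(tr, unname(alphabet)))
    stop("codon(s) do not translate to their residue: ",
         paste(alphabet[tr != alphabet], collapse = ","))

  for (i in seq_along(positions)) {
    p <- positions[[i]]
    if (p$type == "fixed") {
      if (!p$residue %in% alphabet)
        stop("fixed residue at position ", i, " not in alphabet")
    } else {
      if (length(p$allowed) == 0L)
        stop("variable position ", i, " has an empty allowed set")
      if (!all(p$allowed %in% alphabet))
        stop("variable position ", i, " allows residues outside the alphabet")
    }
  }
  if (nchar(flank5) == 0L || nchar(flank3) == 0L)
    stop("flank5 and flank3 must be non-empty")
  if (grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3))
    stop("flanks must be DNA over {A,C,G,T}")
  if (grepl(flank5, flank3, fixed = TRUE) || grepl(flank3, flank5, fixed = TRUE))
    stop("flank5 and flank3 must not contain one another")
  if (!is.null(staple_positions)) {
    if (length(staple_positions) != 2L ||
        any(staple_positions < 1L | staple_positions > length(positions)))
      stop("staple_positions must be a pair of position indices")
  }
  if (nchar(spike_in_dna) != 3L * length(positions))
    stop("spike_in_dna must have the insert length (3 x design length)")
  if (grepl("[^ACGT]", spike_in_dna))
    stop("spike_in_dna must be DNA over {A,C,G,T}")

  design <- structure(
    list(name = name, alphabet = alphabet, codon_map = codon_map,
         positions = positions, flank5 = flank5, flank3 = flank3,
         staple_positions = staple_positions, spike_in_dna = spike_in_dna,
         spike_in_label = spike_in_label),
    class = "library_design")

  spike_pep <- as.character(Biostrings::translate(
    Biostrings::DNAString(spike_in_dna), no.init.codon = TRUE))
  if (matches_design(spike_pep, design))
    stop("spike-in insert translates to a design member; ",
         "the spike-in must not be a library member")
  design
}

#' Default 12-position fixture design
#'
#' A synthetic stand-in for the screened library (whose exact scaffold is
#' proprietary): 12 peptide positions, positions 4 and 8 fixed to serine and
#' recorded as the staple pair, the remaining 10 positions variable over the
#' 16-letter alphabet (20 canonical residues minus C, K, P and G, matching
#' the trimer-codon library chemistry that omits those codons).
#'
#' @return a \code{library_design}
#' @export
default_design <- function() {
  load_design(system.file("extdata", "default_design.yaml", package = "mipd",
                          mustWork = TRUE))
}

#' @export
print.library_design <- function(x, ...) {
  nvar <- sum(vapply(x$positions, function(p) p$type == "variable", logical(1)))
  cat("Library design '", x$name, "'\n", sep = "")
  cat("  positions: ", length(x$positions), " (", nvar, " variable, ",
      length(x$positions) - nvar, " fixed)\n", sep = "")
  cat("  alphabet:  ", paste(x$alphabet, collapse = ""), "\n", sep = "")
  cat("  diversity: ", format(theoretical_diversity(x), big.mark = ","),
      "\n", sep = "")
  if (!is.null(x$staple_positions))
    cat("  staple at positions ", paste(x$staple_positions, collapse = ","),
        " (metadata only)\n", sep = "")
  invisible(x)
}

#' Design-space size of a library
#'
#' Product over variable positions of their allowed-set sizes; fixed
#' positions contribute a factor of 1. This is the theoretical sequence
#' space, not the transformant count of any physical library.
#'
#' @param design a \code{library_design}
#' @return a numeric count (may exceed integer range)
#' @export
theoretical_diversity <- function(design) {
  stopifnot(inherits(design, "library_design"))
  prod(vapply(design$positions, function(p)
    if (p$type == "variable") length(p$allowed) else 1, numeric(1)))
}

#' Test peptides for library-design membership
#'
#' A peptide matches the design iff its length equals the design length,
#' every fixed position carries exactly its fixed residue, and every
#' variable position's residue lies in that position's allowed set. This is
#' the membership rule used to filter decoded reads.
#'
#' @param peptides character vector of peptide sequences
#' @param design a \code{library_design}
#' @return logical vector; never errors on non-matching input
#' @export
matches_design <- function(peptides, design) {
  stopifnot(inherits(design, "library_design"))
  npos <- length(design$positions)
  ok <- !is.na(peptides) & nchar(peptides) == npos
  if (!any(ok)) return(ok)
  mat <- do.call(rbind, strsplit(peptides[ok], "", fixed = TRUE))
  keep <- rep(TRUE, nrow(mat))
  for (i in seq_len(npos)) {
    p <- design$positions[[i]]
    keep <- keep & if (p$type == "fixed") mat[, i] == p$residue
                   else mat[, i] %in% p$allowed
  }
  ok[ok] <- keep
  ok
}

#' Encode design-member peptides as insert DNA
#'
#' Inverse of translation under the design's one-codon-per-residue trimer
#' map. Errors if any peptide is not a design member.
#'
#' @inheritParams matches_design
#' @return character vector of DNA inserts (3 x design length each)
#' @export
encode_peptide <- function(peptides, design) {
  if (!all(matches_design(peptides, design)))
    stop("peptide(s) do not match the design: ",
         paste(head(peptides[!matches_design(peptides, design)], 3L),
               collapse = ", "))
  vapply(strsplit(peptides, "", fixed = TRUE),
         function(rr) paste(design$codon_map[rr], collapse = ""),
         character(1))
}

#' Sample random design members
#'
#' Draws peptides uniformly over the design space (each variable position
#' uniform over its allowed set).
#'
#' @param design a \code{library_design}
#' @param n number of peptides (with replacement; may repeat)
#' @return character vector of design members
#' @export
sample_members <- function(design, n) {
  cols <- lapply(design$positions, function(p) {
    if (p$type == "fixed") rep(p$residue, n)
    else sample(p$allowed, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

#' Write design members to FASTA
#'
#' Exports peptides either as amino-acid FASTA or as their DNA insert with
#' the design flanks attached.
#'
#' @inheritParams matches_design
#' @param file output path
#' @param what \code{"peptide"} or \code{"dna"}
#' @export
write_members_fasta <- function(peptides, design, file,
                                what = c("peptide", "dna")) {
  what <- match.arg(what)
  nm <- if (is.null(names(peptides))) peptides else names(peptides)
  if (what == "peptide") {
    set <- Biostrings::AAStringSet(setNames(peptides, nm))
  } else {
    ins <- encode_peptide(peptides, design)
    set <- Biostrings::DNAStringSet(
      setNames(paste0(design$flank5, ins, design$flank3), nm))
  }
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

# positions helper: indices of variable positions
variable_positions <- function(design) {
  which(vapply(design$positions, function(p) p$type == "variable", logical(1)))
}
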