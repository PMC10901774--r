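REJECT_REASONS <- c("low_quality", "flank_not_found", "length_mismatch",
                    "stop_codon", "not_in_design")

#' Quality-trim reads at the 3' end
#'
#' Removes trailing bases whose Phred quality is below \code{q_threshold}
#' (a simple, order-independent 3' running trim). Reads whose trimmed length
#' falls below \code{min_len} are flagged for rejection as
#' \code{low_quality}.
#'
#' @param seqs,quals character vectors of read sequences and Phred+33
#'   quality strings
#' @param q_threshold minimum retained Phred quality (default Q20)
#' @param min_len minimal decodable length (flanks plus insert)
#' @return list with trimmed \code{seqs} and logical \code{keep}
#' @export
trim_reads <- function(seqs, quals, q_threshold = 20L, min_len = 0L) {
  if (length(seqs) == 0L)
    return(list(seqs = character(0), keep = logical(0)))
  phred <- rawToChar(as.raw(33:126))
  marks <- paste(ifelse(seq(0L, 93L) >= q_threshold, "1", "0"), collapse = "")
  marked <- chartr(phred, marks, quals)
  trail <- attr(regexpr("0*$", marked), "match.length")
  newlen <- nchar(seqs) - trail
  list(seqs = substr(seqs, 1L, newlen), keep = newlen >= min_len)
}

# first flank5/flank3 pair in each subject; returns insert substring or NA
locate_inserts <- function(subject, design, mm) {
  n <- length(subject)
  if (n == 0L) return(character(0))
  s5 <- Biostrings::startIndex(
    Biostrings::vmatchPattern(design$flank5, subject, max.mismatch = mm))
  s3 <- Biostrings::startIndex(
    Biostrings::vmatchPattern(design$flank3, subject, max.mismatch = mm))
  n5 <- nchar(design$flank5)
  bounds <- mapply(function(a, b) {
    if (is.null(a) || is.null(b)) return(c(NA_integer_, NA_integer_))
    e5 <- a[[1L]] + n5 - 1L
    b2 <- b[b > e5]
    if (length(b2) == 0L) return(c(NA_integer_, NA_integer_))
    c(e5 + 1L, b2[[1L]] - 1L)
  }, s5, s3)
  out <- rep(NA_character_, n)
  got <- !is.na(bounds[1L, ])
  if (any(got)) {
    strs <- as.character(subject[got])
    out[got] <- substr(strs, bounds[1L, got], bounds[2L, got])
  }
  out
}

#' Extract DNA inserts between the design flanks
#'
#' Locates \code{flank5} then \code{flank3} in each trimmed read, allowing up
#' to \code{max_flank_mismatches} substitutions per flank (no indels: trimer
#' inserts make indels unrecoverable anyway). The forward orientation is
#' tried first; reads without a forward flank pair are retried as reverse
#' complements, and a read matching both ways counts as forward.
#'
#' @param seqs character vector of trimmed reads
#' @param design the \code{library_design}
#' @param max_flank_mismatches per-flank substitution allowance
#' @return character vector of inserts, \code{NA} where no flank pair was
#'   found (reason \code{flank_not_found})
#' @export
extract_inserts <- function(seqs, design, max_flank_mismatches = 1L) {
  if (length(seqs) == 0L) return(character(0))
  subject <- Biostrings::DNAStringSet(seqs)
  ins <- locate_inserts(subject, design, max_flank_mismatches)
  miss <- is.na(ins)
  if (any(miss)) {
    rc <- Biostrings::reverseComplement(subject[miss])
    ins[miss] <- locate_inserts(rc, design, max_flank_mismatches)
  }
  ins
}

#' Translate inserts and gate on the library design
#'
#' Standard-genetic-code translation of each insert, then the design
#' membership gate. Inserts whose length is not 3 x design length are
#' rejected as \code{length_mismatch}; any stop codon rejects the read
#' (\code{stop_codon}); translated peptides outside the design are
#' \code{not_in_design}. Inserts matching the spike-in DNA (exactly, or
#' within one substitution as an error fallback) are diverted to the spike
#' channel before translation and never enter the peptide matrix.
#'
#' @param inserts character vector of DNA inserts (NA allowed, passed through
#'   as \code{flank_not_found})
#' @param design the \code{library_design}
#' @return list with \code{peptide} (NA unless accepted), logical
#'   \code{is_spike}, and \code{reason} (NA where accepted or spike)
#' @export
translate_inserts <- function(inserts, design) {
  n <- length(inserts)
  peptide <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  is_spike <- rep(FALSE, n)
  reason[is.na(inserts)] <- "flank_not_found"
  len_ok <- !is.na(inserts) & nchar(inserts) == nchar(design$spike_in_dna)
  reason[!is.na(inserts) & !len_ok] <- "length_mismatch"
  if (any(len_ok)) {
    idx <- which(len_ok)
    spike_chars <- strsplit(design$spike_in_dna, "", fixed = TRUE)[[1L]]
    mm <- colSums(matrix(unlist(strsplit(inserts[idx], "", fixed = TRUE)),
                         nrow = length(spike_chars)) != spike_chars)
    is_spike[idx] <- mm <= 1L
    keep <- idx[mm > 1L]
    if (length(keep) > 0L) {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(inserts[keep]), no.init.codon = TRUE))
      stopped <- grepl("*", aa, fixed = TRUE)
      reason[keep[stopped]] <- "stop_codon"
      ok <- keep[!stopped]
      if (length(ok) > 0L) {
        good <- matches_design(aa[!stopped], design)
        peptide[ok[good]] <- aa[!stopped][good]
        reason[ok[!good]] <- "not_in_design"
      }
    }
  }
  list(peptide = peptide, is_spike = is_spike, reason = reason)
}

#' Decode one sequencing well
#'
#' Full per-well decode: FASTQ input, quality trimming, flank location,
#' spike-in diversion, translation and design filtering, tallying of unique
#' peptides and of rejection reasons. Conservation holds by construction:
#' assigned + spike + rejected = total reads.
#'
#' @param fastq path to a FASTQ (optionally gzipped) file
#' @param design the \code{library_design}
#' @param q_threshold 3' trim quality threshold
#' @param max_flank_mismatches per-flank substitution allowance
#' @return list with \code{peptide_counts} (named integer), \code{spike},
#'   \code{rejected} (named integer over rejection reasons), \code{total}
#' @export
decode_well <- function(fastq, design, q_threshold = 20L,
                        max_flank_mismatches = 1L) {
  # the reader warns about dropping its own internal metadata columns
  reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
  seqs <- as.character(reads)
  quals <- as.character(Biostrings::quality(reads))
  total <- length(seqs)
  rejected <- setNames(integer(length(REJECT_REASONS)), REJECT_REASONS)
  min_len <- nchar(design$flank5) + nchar(design$flank3) +
    3L * length(design$positions)
  tr <- trim_reads(seqs, quals, q_threshold, min_len)
  rejected["low_quality"] <- sum(!tr$keep)
  ins <- extract_inserts(tr$seqs[tr$keep], design, max_flank_mismatches)
  res <- translate_inserts(ins, design)
  for (r in c("flank_not_found", "length_mismatch", "stop_codon",
              "not_in_design"))
    rejected[r] <- rejected[r] + sum(res$reason == r, na.rm = TRUE)
  accepted <- res$peptide[!is.na(res$peptide)]
  counts <- table(accepted)
  list(peptide_counts = setNames(as.integer(counts), names(counts)),
       spike = sum(res$is_spike), rejected = rejected, total = total)
}

#' Tally a whole screen into a count matrix
#'
#' Decodes every well listed in the sample sheet and assembles the unique
#' peptide x sample count matrix, per-sample spike-in counts, and the
#' rejection ledger. Peptide rows are sorted lexicographically (C locale) for
#' determinism.
#'
#' @param sample_sheet path to a CSV with columns \code{sample_id},
#'   \code{role}, \code{concentration_nM}, \code{replicate}, \code{fastq},
#'   or an equivalent data frame
#' @inheritParams decode_well
#' @return a \code{count_matrix} object
#' @export
tally_screen <- function(sample_sheet, design, q_threshold = 20L,
                         max_flank_mismatches = 1L) {
  sheet <- if (is.character(sample_sheet)) {
    read.csv(sample_sheet, stringsAsFactors = FALSE)
  } else as.data.frame(sample_sheet)
  need <- c("sample_id", "role", "concentration_nM", "replicate", "fastq")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  missing <- !file.exists(sheet$fastq)
  if (any(missing))
    stop("FASTQ not found for sample(s): ",
         paste(sheet$sample_id[missing], collapse = ", "))
  wells <- lapply(sheet$fastq, decode_well, design = design,
                  q_threshold = q_threshold,
                  max_flank_mismatches = max_flank_mismatches)
  peptides <- lex_sort(unique(unlist(lapply(wells, function(w)
    names(w$peptide_counts)))))
  counts <- matrix(0L, nrow = length(peptides), ncol = nrow(sheet),
                   dimnames = list(peptides, sheet$sample_id))
  rejected <- matrix(0L, nrow = length(REJECT_REASONS), ncol = nrow(sheet),
                     dimnames = list(REJECT_REASONS, sheet$sample_id))
  spike <- setNames(integer(nrow(sheet)), sheet$sample_id)
  total <- setNames(integer(nrow(sheet)), sheet$sample_id)
  for (i in seq_along(wells)) {
    w <- wells[[i]]
    counts[names(w$peptide_counts), i] <- w$peptide_counts
    rejected[, i] <- w$rejected
    spike[i] <- w$spike
    total[i] <- w$total
  }
  new_count_matrix(counts, spike, rejected, total, sheet,
                   design$spike_in_label)
}

#' Construct a count matrix object
#'
#' Container for decoded screen counts. The conservation invariant
#' (assigned + spike + rejected = total, per sample) is checked on
#' construction.
#'
#' @param counts integer matrix, peptides x samples
#' @param spike_counts,total_reads named integer vectors per sample
#' @param rejected integer matrix, rejection reasons x samples
#' @param samples the sample sheet data frame
#' @param spike_label label of the spike-in row in exports
#' @return a \code{count_matrix}
#' @export
new_count_matrix <- function(counts, spike_counts, rejected, total_reads,
                             samples, spike_label = "SPIKE") {
  stopifnot(all(counts >= 0), all(spike_counts >= 0), all(rejected >= 0))
  if (!isTRUE(all.equal(unname(colSums(counts) + spike_counts +
                                 colSums(rejected)),
                        unname(as.numeric(total_reads)))))
    stop("count conservation violated: assigned + spike + rejected != total")
  structure(list(counts = counts, spike_counts = spike_counts,
                 rejected = rejected, total_reads = total_reads,
                 samples = samples, spike_label = spike_label),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Screen count matrix: ", nrow(x$counts), " unique peptides x ",
      ncol(x$counts), " samples\n", sep = "")
  cat("  total reads:   ", sum(x$total_reads), "\n", sep = "")
  cat("  assigned:      ", sum(x$counts), "\n", sep = "")
  cat("  spike-in:      ", sum(x$spike_counts), "\n", sep = "")
  cat("  rejected:      ", sum(x$rejected), "\n", sep = "")
  invisible(x)
}

#' Write counts and the rejection ledger to TSV
#'
#' The counts table carries one row per peptide plus a final spike-in row
#' labelled by the design's spike-in label.
#'
#' @param x a \code{count_matrix}
#' @param counts_file,rejections_file output paths
#' @export
write_counts <- function(x, counts_file, rejections_file = NULL) {
  tab <- rbind(x$counts, matrix(x$spike_counts, nrow = 1,
                                dimnames = list(x$spike_label, NULL)))
  df <- data.frame(peptide = rownames(tab), tab, check.names = FALSE,
                   row.names = NULL)
  write.table(df, counts_file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(rejections_file)) {
    rej <- data.frame(reason = rownames(x$rejected), x$rejected,
                      check.names = FALSE, row.names = NULL)
    write.table(rej, rejections_file, sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(counts_file)
}
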