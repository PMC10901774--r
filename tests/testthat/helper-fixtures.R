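# small designs and screens built in code for the tests

# toy design: npos positions (optionally some fixed), tiny alphabet,
# spike-in = poly-AAA insert translating to poly-K (outside any alphabet here)
toy_design <- function(npos = 3L, alphabet = c("W", "A", "L"),
                       fixed = integer(0), fixed_residue = "A",
                       allowed = NULL) {
  codons <- c(W = "TGG", A = "GCT", L = "CTG", E = "GAA", D = "GAT",
              S = "AGC", F = "TTT", M = "ATG", Y = "TAT", V = "GTT")
  positions <- lapply(seq_len(npos), function(i) {
    if (i %in% fixed) list(fixed = fixed_residue)
    else if (is.null(allowed)) list(variable = "all")
    else list(variable = as.list(allowed[[min(i, length(allowed))]]))
  })
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    name = "toy", alphabet = as.list(alphabet),
    codon_map = as.list(codons[alphabet]),
    positions = positions,
    flank5 = "CTACGGATCA", flank3 = "TGACCTGTTA",
    spike_in_dna = strrep("AAA", npos),
    spike_in_label = "SPIKE"), path)
  load_design(path)
}

# enumerate every member of a small design (oracle for diversity/matching)
enumerate_members <- function(design) {
  sets <- lapply(design$positions, function(p)
    if (p$type == "fixed") p$residue else p$allowed)
  do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
}

# assemble a count_matrix directly from a simulate_counts() draw
cm_from_sim <- function(sim, spike_label = "SPIKE") {
  reasons <- c("low_quality", "flank_not_found", "length_mismatch",
               "stop_codon", "not_in_design")
  new_count_matrix(
    sim$counts, sim$spike_counts,
    matrix(0L, length(reasons), ncol(sim$counts),
           dimnames = list(reasons, colnames(sim$counts))),
    colSums(sim$counts) + sim$spike_counts,
    as.data.frame(sim$layout), spike_label)
}

# hand-build a count_matrix from a counts matrix + sample roles
cm_manual <- function(counts, spike_counts, roles, conc) {
  reasons <- c("low_quality", "flank_not_found", "length_mismatch",
               "stop_codon", "not_in_design")
  samples <- data.frame(sample_id = colnames(counts), role = roles,
                        concentration_nM = conc,
                        replicate = seq_len(ncol(counts)),
                        stringsAsFactors = FALSE)
  new_count_matrix(counts, spike_counts,
                   matrix(0L, length(reasons), ncol(counts),
                          dimnames = list(reasons, colnames(counts))),
                   colSums(counts) + spike_counts, samples, "SPIKE")
}

default_layout <- function(reads = 20000L)
  screen_layout(c(12.5, 50, 200, 800), reads_per_well = reads)
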