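# deterministic child seeds so stages can be rerun in isolation;
# kept well inside 32-bit integer range
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * stage) %% 2147483647)
}

# C-locale lexicographic sort for reproducible row order
lex_sort <- function(x) sort(x, method = "radix")
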