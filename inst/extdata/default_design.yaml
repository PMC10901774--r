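# Default synthetic 12-position stapled-peptide library design.
# Alphabet: 20 canonical residues minus C, K, P, G (trimer-codon library
# chemistry omits those codons). One trimer codon per residue. Positions 4
# and 8 are fixed serines recorded as the staple attachment pair (metadata
# only). The spike-in insert translates to GKGKGKGKGKGK, which contains
# excluded residues and therefore can never be a library member.
name: helix12-synthetic
alphabet: ["A", "D", "E", "F", "H", "I", "L", "M", "N", "Q", "R", "S", "T", "V", "W", "Y"]
codon_map:
  "A": GCT
  "D": GAT
  "E": GAA
  "F": TTT
  "H": CAT
  "I": ATT
  "L": CTG
  "M": ATG
  "N": AAT
  "Q": CAG
  "R": CGT
  "S": AGC
  "T": ACT
  "V": GTT
  "W": TGG
  "Y": TAT
positions:
  - {variable: all}
  - {variable: all}
  - {variable: all}
  - {fixed: S}
  - {variable: all}
  - {variable: all}
  - {variable: all}
  - {fixed: S}
  - {variable: all}
  - {variable: all}
  - {variable: all}
  - {variable: all}
staple_positions: [4, 8]
flank5: CATGCCATGGCT
flank3: GGTGGAGGTTCG
spike_in_dna: GGTAAAGGTAAAGGTAAAGGTAAAGGTAAAGGTAAA
spike_in_label: SPIKE
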