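---
title: "Decoding mirror-image phage display screens with mipd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding mirror-image phage display screens with mipd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipd)
```

## The problem

Mirror-image phage display turns the chirality of biology into a discovery
tool. A peptide phage library — here, stapled α-helical peptides encoded by
trimer codons — is panned against a chemically synthesized D-enantiomer of
the target protein. Because the interaction of an L-peptide with a
D-protein is geometrically identical to that of the mirrored D-peptide with
the natural L-protein, every selected L-sequence defines a D-peptide
candidate that is essentially invisible to proteases. The computational
task is to go from per-well sequencing reads to a short list of D-peptide
synthesis candidates, and that is the whole of what `mipd` does.

A screen consists of wells that differ only in bait concentration: blank
wells (beads, no bait) and a concentration series with replicates. Phage
retained on the beads are sequenced per well, together with a spike-in — a
known sequence that is deliberately *not* a library member — added in equal
amount to every well at denaturation, which makes read counts comparable
across wells.

## The library model

A `library_design` fixes what counts as a library member: an ordered list
of positions, each fixed to one residue or variable over an allowed subset
of the alphabet; one trimer codon per residue (the library is synthesized
from whole-codon building blocks, so the codon map is a bijection); the
constant DNA flanks around the insert; and the spike-in insert. The default
alphabet is the 16 canonical residues excluding cysteine, lysine, proline
and glycine, mirroring the codon exclusions of the trimer chemistry. The
codons themselves are not dictated by the chemistry as far as the analysis
is concerned, so the default design fixes one common codon per residue in
its config file rather than in code.

The screened library's real scaffold is proprietary; the default design is
an explicitly synthetic stand-in: 12 positions with positions 4 and 8 fixed
(serine) and recorded as the staple pair. Staples are bookkeeping only — no
cross-link chemistry or helicity constraint is modeled, they simply travel
through reports so fixed positions can be grayed out in logos. Peptide
positions are 1-based everywhere a user sees them; DNA offsets are 0-based
half-open internally.

## Decoding

Decoding is deliberately boring and fully accounted: every read ends up in
exactly one of six buckets, and the conservation identity
`assigned + spike + rejected = total` is asserted per well at construction
of every count matrix.

* **Quality trimming** removes 3' bases below Q20 (a simple running trim —
  deterministic and order-independent; the trimming rule is a parameter,
  not an inference about any particular pipeline). Reads shorter than
  flanks + insert after trimming are rejected as `low_quality`.
* **Flank location** finds the 5' then the 3' flank allowing at most one
  substitution each (`max_flank_mismatches`), in forward orientation first,
  then on the reverse complement; a read matching both ways counts as
  forward. Indels are not searched for: with whole-codon inserts a single
  indel destroys the frame and the read is unrecoverable anyway.
* **Spike-in diversion** happens at the DNA level before translation —
  exact insert match, then a one-mismatch fallback so sequencing errors do
  not leak spike reads into the rejection ledger.
* **Translation** uses the standard genetic code; any stop codon rejects
  the read (`stop_codon`), and translated peptides failing the design gate
  are `not_in_design`. Rejections are data, never exceptions.

## Hit calling

Normalized abundance is raw count divided by the well's spike-in count; a
well with zero spike-in reads cannot be normalized and is excluded with a
warning. Hit Strength is the fold change between the mean normalized count
across highest-concentration replicates and the mean across blanks, with
one numerical guard: a blank *raw count* of zero is replaced by 0.5 before
dividing by that blank's spike-in count. The substitution is applied per
replicate, before averaging — reading "a count of 0.5" literally as a
count, not a normalized value — and only in blanks: a zero at the highest
concentration legitimately gives HS = 0. Two consequences worth knowing:
HS is exactly 1 for the spike-in in every screen, and HS is invariant to
rescaling any well's counts (spike included), which is the entire point of
spike normalization.

The dose-response gate is this package's own construction (the selection
readout is semi-quantitative in concentration, but no published rule
exists): the Spearman rank correlation, ties mid-ranked, between per-level
mean normalized counts and concentration rank, blanks included as level 0.
A flat profile is all ties and scores 0 by convention. The gate passes at
rho ≥ 0.8 by default and needs at least three levels; with fewer it
degrades to HS-only with a warning. A sequence is a hit when it passes
HS ≥ 5, the dose gate, and carries at least `min_reads = 5` raw reads
summed over the highest-concentration replicates (the count floor is read
as a total across replicates; a per-replicate reading would only be
stricter). All three thresholds are arguments, not constants, because no
screen publishes them; the defaults are calibrated only in the sense that
the null simulation (below) keeps the fraction of background sequences at
HS ≥ 5 under 1%.

One behavior of spike normalization deserves a note. Because the spike-in
is drawn from the same read pool at a fixed expected fraction, normalized
counts are compositional: when strong binders soak up read share at high
bait concentration, a *saturated* binder's normalized count can flatten or
dip at the top of the series even though its occupancy rose. With planted
families at ~1% of the population this is negligible; at tens of percent it
can cost a near-saturating binder the dose gate. That is a property of the
readout, not a bug in the statistic.

## Clustering and logos

Hits are clustered on a per-position dissimilarity over variable positions
only: BLOSUM62 similarities are first normalized as
S(a,b)/sqrt(S(a,a)S(b,b)) so self-similarity is 1, then affinely rescaled
over the design alphabet so the least-similar pair scores 0; the distance
is one minus the positional mean. It satisfies identity, symmetry and
boundedness in [0,1] but not the triangle inequality — acceptable for
average-linkage agglomeration, which never needs it. Hamming distance is
available as an alternative. The tree is cut at 0.5; clusters below 3
members are reported as singletons, not families. Input order cannot
matter: peptides are sorted before clustering and family labels are
assigned by decreasing size with lexicographic tie-break.

Logos are per-position residue frequencies over the design alphabet
(columns sum to 1), consensus is the per-position mode with ties broken by
alphabet order, and information content is
IC_j = log2 |A_j| + Σ p log2 p with 0·log 0 = 0, so a uniformly used
variable position scores 0 bits and an invariant one log2 16 = 4 bits;
fixed positions have |A| = 1 and always 0 bits. Abundance weighting of
logos is available but off by default.

## Mirroring

`to_d()` inverts chirality residue-by-residue in the original order — this
is *not* retro-inverso; the sequence is never reversed. Rendering follows
the field's convention of lower-case letters for D-residues; glycine is
achiral but rendered lower-case in a D context for string consistency.
The optional Met→Nle substitution replaces methionine with its
oxidation-resistant isostere norleucine at synthesis. Norleucine has no
single-letter code, so it is rendered as the bracketed token `[nle]`: an
inline `nle` would be indistinguishable from the residues Asn-Leu-Glu, and
bracketing keeps `parse_chiral(format(x))` an exact inverse. Substituted
tokens have no unique L-precursor, so `to_l()` refuses them by position.

## Structural utilities

`mirror_structure()` reflects coordinates through the yz-plane; any other
mirror differs only by a proper rotation, so fixing one plane keeps outputs
reproducible. Reflection is verified (and tested) as an isometry, an
involution, and a sign-flipper of signed tetrad volumes. Handedness of
α-helices is classified from virtual torsions over consecutive Cα
quadruples — robust to missing backbone atoms, unlike phi/psi — with the
median compared against symmetric windows: right for [+30°, +70°], left
for [−70°, −30°], else `none`; the ideal α-helix sits near +50°. Traces
with non-physical Cα spacing (outside 2.0–4.5 Å) refuse classification.
Reflected files keep their residue names and chirality labels untouched and
carry a header remark marking them as mirrored.

## The synthetic screen generator

The generator exists so that every claim the pipeline makes can be tested
against a known truth. It emulates: a log-normal background population
(default σ = 1, a heavily skewed but not pathological library
composition); planted binder families as mutational clouds around a
consensus (default 20 members at a per-variable-position substitution rate
of 0.1, fixed positions never mutated); single-round selection in which a
binder's capture weight is a·(1 + β·θ) with Langmuir occupancy
θ = C/(C + K_D), θ = 0 in blanks; a spike-in included in the same
multinomial draw with weight set to hit the target expected read fraction
(default 5%), so spike counts carry realistic noise rather than being
appended deterministically; uniform Q37 qualities with optional low-quality
tails, substitution errors and reverse-complement reads to exercise the
decoder; and byte-identical outputs under a fixed seed, with one top-level
seed fanning out deterministically to per-stage child seeds.

The default study conditions are 5,000 background members, three families
with K_D = 25, 100 and 400 nM spread across a 12.5–800 nM four-point
concentration series, β = 50, two blanks and two replicates per
concentration at 20,000 reads per well. No quantitative enrichment
magnitude has been published for such screens; β = 50 is a fixture choice
producing hit-strength ranges (tens) compatible with a screen in which
hits are clearly separated from background, and K_D values were placed to
straddle the series, not to estimate any real binder.

What the generator does *not* emulate — and therefore what passing tests do
not certify about real data: PCR and polymerase bias, indels, chimeras,
paired-end artifacts, well-to-well contamination, phage propagation
fitness effects, avidity, and any relationship between the planted K_D
scale and laboratory affinities. Amplification between rounds is absent by
design (single-round screens).

## Numerical choices and degenerate inputs

Zero-read wells decode to all-zero columns; empty hit sets refuse to
cluster with a clear error; a single hit is a singleton; constant
dose-response profiles score 0, not NA; zero-spike wells are excluded, and
hit calling proceeds on the remaining wells. All row orders are C-locale
lexicographic, all ties break by design-alphabet order, and every RNG draw
descends from the run seed, so identical configs are byte-identical.

Test problem sizes are chosen to exercise the stated conditions while
keeping the suite quick: the acceptance-style screens run the full 5,000
member × 200,000 read configuration; property suites (null calibration,
K_D monotonicity, family recovery) use 10 seeds at the same well layout
with backgrounds of 100–5,000 as appropriate to the property; the whole
suite runs in about a minute.

## Limitations

The pipeline estimates no affinities: Hit Strength is a semi-quantitative
enrichment readout, and calibrating it against K_D would require a
replicate-null and titration model the screen format does not provide. No
FDR is attached to hit calls for the same reason. The clustering distance,
linkage, cut height and all thresholds are declared defaults, not inferred
ones, and should be revisited per screen; the dose-response rule in
particular is one reasonable choice among several. Structure utilities
classify handedness only — they do not superpose, score contacts, or
validate binding poses.
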