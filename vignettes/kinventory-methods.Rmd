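---
title: "Methods: building and stress-testing a K+ transporter inventory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and stress-testing a K+ transporter inventory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinventory)
```

`kinventory` turns the standard recipe for cataloguing a plant K⁺
transporter complement — motif screening, curation, clade placement,
duplication dating, exon-structure comparison, ortholog clustering and
expression modelling — into one deterministic, tested pipeline. This
vignette records the methods, the tunable parameters and their defaults,
the numerical choices, and what the synthetic benchmarks do and do not
demonstrate.

## The screening model

Candidates are found by scanning the proteome with eleven degenerate
protein motifs: five diagnostic of HAK/KT/KUP, three of the K⁺ channel
pore region (the first of which spans the TVGYGD selectivity filter), two
of HKT, and one of KEA. The motif dialect is PROSITE-like: bracket groups
are residue alternatives (with or without commas), `x` matches any single
residue, and `x(n)` is a bounded run. Two readings in the printed library
required a decision (see below). The KEA repeat `x(n)` carries no
published bound, so the library defaults to 1–30 residues — the matcher must terminate, and
30 residues spans plausible inter-motif linkers; both bounds are
configurable (`x_n_min`, `x_n_max`). Two readings of the shipped library
strings were genuinely open and are documented rather than guessed
silently: the space inside motifs 1 and 3 (e.g. `[A,G] [D,S,G]`) is read
as plain adjacency, not an elided wildcard, and the stray opening
parenthesis at the head of the KEA motif is treated as a typographical
artifact and stripped by the loader.

The scanner compiles each parsed pattern to an anchored regular expression
wrapped in a zero-width lookahead, which yields one match per start
position at C speed; gap quantifiers are lazy, so the shortest admissible
gap is reported at each start (with multiple gaps, the leftmost gap is
minimized first). An `all` mode enumerates every admissible gap
combination by recursion where exhaustiveness matters more than speed. The
ambiguity letter `X` is accepted in input and matches wildcard and gap
positions only, never a residue set — a conservative reading that can only
lose borderline matches, never invent them. Coordinates are 0-based
half-open internally; every report writer emits 1-based inclusive columns.

A sequence becomes a family candidate when it matches a minimum number of
distinct motifs of that family: by default 2 of 5 for HAK/KT/KUP, 2 of 3
for the channel families, 2 of 2 for HKT, and 1 of 1 for KEA (which has a
single motif). Motif-screening protocols in this literature state no
explicit count rule, so these policies are configuration, not doctrine. The voltage-gated and
TPK/KCO screens share the three pore-region motifs; how to separate them
is genuinely open, and the package adopts the tandem-pore heuristic: a
chain carrying two or more pore-motif hits is a TPK/KCO candidate, a
single-pore chain a voltage-gated one. Residual multi-family candidacies
are resolved per sequence by most distinct motifs, then larger span, then
family name, and all candidacies are retained in the output with verdicts
— nothing is deleted.

Curation uses the outermost-motif span: the distance from the first to the
last family-motif hit. A candidate is kept iff its span is at least a
fraction (default 0.70) of the mean span of reference family members
scanned with the same library. The boundary is inclusive — the rule
discards strictly shorter sequences — so a candidate at exactly 70% of the
reference mean survives. Kept candidates are annotated with length,
average-mass molecular weight (residue masses plus one water), isoelectric
point, and a transmembrane-segment count. The pI solves the
Henderson–Hasselbalch net-charge equation over the termini and the D, E,
C, Y, H, K, R side chains by bisection to 0.01 pH units, against a fixed
pKa table shipped as a data file so results are bit-reproducible. The TMD
count is a Kyte–Doolittle heuristic — non-overlapping runs of 19-residue
windows with mean hydropathy ≥ 1.6, merging runs closer than 5 residues —
a deterministic, self-contained annotation whose role is order-of-magnitude
sanity (polytopic transporter vs soluble decoy), not topology prediction.

## Clades, duplication, structure, orthologs, expression

**Clades.** Queries are placed by distance, not likelihood: p-distances
with pairwise gap deletion feed Saitou–Nei neighbor joining (via
`ape::nj`; negative branch-length estimates are clamped to zero and the
clamped total recorded), and each query leaf takes the clade label of the
nearest reference leaf by patristic distance, with exact ties broken by
the smaller enclosing clade and then lexicographically. Maximum-likelihood
inference and bootstrap support are deliberately out of scope; clade
delimitation from a tree has no canonical support threshold, so
nearest-reference assignment is the documented surrogate.
Multiple-sequence alignment is likewise out of scope: the module consumes
a user-supplied alignment (the synthetic clade generator produces
substitution-only sequences that are aligned by construction).

**Duplication.** Pairs on one chromosome separated by at most 5
intervening genes (configurable) are tandem; otherwise a pair is segmental
iff both genes fall inside the two regions of a declared duplicated block.
Blocks are an input, not an inference — synteny detection is a documented
limitation. Among Ks estimators the package uses Nei–Gojobori (1986),
chosen for its closed form and hand-checkable counts:
fractional synonymous sites per codon (changes to stop codons count as
nonsynonymous), equal-weight pathway averaging for codons differing at
several positions (pathways through stop codons are excluded; if all are,
every pathway is used), and the Jukes–Cantor correction
d = −(3/4)·ln(1 − 4p/3). Proportions ≥ 0.75 make the correction undefined
and raise a typed `ng86_saturation` condition; block means exclude and
count saturated pairs. Codon alignment is back-threaded from the BLOSUM62
protein global alignment with gapped codon columns dropped pairwise. Ages
are T = Ks/2λ; two published clock rates ship as presets (`fast` =
1.5 × 10⁻⁸, the classic eudicot rate, and `slow` = 6.1 × 10⁻⁹, the
legume-calibrated rate) since either appears in duplication-dating work on
legumes; the slower rate is the default.

**Gene structure.** Only CDS features contribute — conserved exon lengths
in family studies are coding lengths; GFF3 1-based closed coordinates become 0-based half-open at parse
time, the longest-CDS isoform is taken per gene (configurable to first),
and intron phases follow phaseᵢ = (Σ first i exon lengths) mod 3 — the
"splice phase" is read as intron phase. Two exons match iff their lengths
are equal (a ±k nt tolerance exists, default 0) and their flanking phase
contexts agree, with terminal exons only matching terminal exons on that
side; pair comparison is a longest common subsequence under that match
relation, so matches are order-preserving. A family-conserved exon is a
(length, phase-context) key carried by at least a fraction of members —
default 0.9, chosen because family-wide conservation is typically reported
as "all members except" one or two named genes — with absentees listed.

**Orthologs.** "Similarity" is implemented as global percent identity
(Needleman–Wunsch, BLOSUM62, gap open 10 / extend 1, identity over
alignment length including gaps), the threshold is strict (> 80), and
clusters are connected components of the identity graph; the Venn summary
counts clusters per species-membership pattern. Raising the threshold can
only split clusters, never merge them, which the suite checks as a
property.

**Expression.** A gene is expressed if any condition exceeds 1 TPM
(strict, so exactly 1.0 fails); per family and clade the model reports the
argmax of TPM over (gene, condition) among expressed genes, breaking ties
by lexicographic gene id then condition order and flagging them; clades
with nothing expressed are reported as "no expression" rather than
dropped. The treated-vs-mock contrast is log₂((t+1)/(m+1)) with a fixed
pseudo-count; TPM values are used as given, with no re-normalization,
matching their descriptive use. The condition set is data-driven: the
loader accepts any condition labels rather than enforcing a fixed stage
count (public root-hair time courses label their treated/mock conditions
inconsistently).

## What the generators emulate — and what they do not

Every pipeline input can be generated with planted truth, and each
generator is seed-deterministic with its parameters logged in the truth
object.

* `simulate_proteome()` builds members as random flanks around strings
  sampled from each family's motif languages at realistic spacings
  (inter-motif linkers of 30–60 aa; defaults sized 29/16/9/4/12 across the
  five families, 70 genes total), truncated decoys carrying the same
  motifs at compressed spacings (well under 70% of the reference span),
  and random decoys. Two construction rules keep the truth exact rather
  than merely likely: random decoys are resampled until they contain no
  motif match at all, and member flanks/linkers are resampled until the
  scanned hit set equals the planted set — on a uniform background the
  single-motif KEA pattern would otherwise appear spontaneously about
  once per 8,000 residues. KEA gap linkers exclude D/E so the scanner's
  shortest-gap match reports exactly the planted gap. Reference sets use
  fixed canonical spacing.
* `simulate_duplicated_cds()` evolves a stop-free random ancestor by a
  Poisson number of synonymous-only single-nucleotide events (expectation
  k*·S), choosing uniformly among the available synonymous changes so the
  event rate per synonymous site is k*; synonymous events can never create
  a stop. The Jukes–Cantor inversion is exact for 4-fold sites and
  slightly mismatched for 2-fold sites, which contribute about 20% of
  synonymous sites in random sequence — the residual bias stays within a
  few percent up to k* = 0.4, inside the 10% recovery tolerance the
  suite enforces.
* `simulate_gene_models()` interleaves family template exons (defaults
  260/52/254 nt, with 98/57/185, 150/147 and 68/53/89 as the other family
  profiles) with pair-specific spacer exons whose lengths are multiples of
  3, so template phase contexts are identical family-wide; the last spacer
  adjusts the total to a multiple of 3. Perturbation lengthens one
  template exon by 3 nt in a chosen number of members — frame-preserving,
  so only the perturbed exon's family fraction drops. The perturbation
  parameter is a member count rather than a rate so the planted truth is
  exact.
* `simulate_tpm()` draws a log-normal background (median ≈ 2 TPM,
  sdlog 0.5 — moderate biological spread), silences a fraction of genes
  (all cells < 1), and plants each maximum as boost × the clade's
  background maximum (boost 50), which guarantees the planted cell is its
  clade's argmax.
* `simulate_clade_sequences()` and `simulate_ortholog_families()` generate
  substitution-only descendants of clade/family ancestors (defaults:
  within-clade divergence 0.05 vs ancestor divergence 0.25, i.e. > 3×
  separation; ortholog families at ~95% within / far below threshold
  between).

These generators emulate the *statistical structure the analysis assumes*
— motif-bearing members against motif-free background, clock-like
synonymous divergence, frame-consistent exon templates, clear clade
separation, planted expression maxima. They do not emulate indels within
motifs, compositional bias, alternative isoforms, saturated or
rate-variable sites, reticulate clade boundaries, or count noise beyond
the log-normal. Passing the suite therefore demonstrates correctness of
the implemented operations and the pipeline's determinism, not robustness
to every pathology of real proteomes; on real data the screening policies,
span fraction and thresholds remain scientific choices for the user.

## Numerical choices and degenerate inputs

Bisection for pI runs on pH 0–14 to tolerance 0.01. NJ tie-breaking
follows the deterministic order of `ape::nj`, so identical input always
yields an identical tree. Identity and p-distance matrices are exactly
symmetric by construction; the NJ wrapper rejects asymmetric input and
fewer than 3 taxa. Empty sequences scan to empty hit lists; an empty
reference set is an error, as is a gene missing from the order index, an
all-gap alignment pair, or a CDS with internal stops. Orphan CDS features
in GFF3 warn and skip; malformed lines error with their line number.
Sequence ids must be unique everywhere. All randomness flows from one
root seed; each pipeline stage derives its own sub-seed (kept below 2³¹)
so adding a stage never perturbs the others, and rerunning a configuration
reproduces every report table byte-for-byte.

## Problem sizes used by the test suite

The suite verifies the scanner against a brute-force oracle on 1,000
random instances (sequences ≤ 200 aa); screening on the full 340-sequence
study conditions over 5 seeds; Ks recovery on 100 replicates of 300
codons at k* ∈ {0.05, 0.1, 0.2, 0.4} (≤ 10% relative bias, mean Ka
< 0.005, dating within the same tolerance); NJ on 100 random additive
trees of ≤ 8 taxa (exact topology); clade recovery ≥ 95% at 3×
separation; conserved-exon fractions of exactly 1.0 and 0.9 with the
perturbed member named; exact 2-cluster recovery at the 80% threshold with
order-invariance; recovery of all 6 planted expression maxima; and
byte-identical reruns of the full pipeline. These sizes were chosen as the
smallest at which the statistical checks are stable.

## Known limitations

Synteny blocks are consumed, never inferred. No multiple-sequence
alignment or ML phylogenetics. The NG86 estimator saturates at p ≥ 0.75
and is reported as such rather than extrapolated. The TMD count is a
hydropathy heuristic, not an HMM. Exon matching at tolerance 0 treats a
1-nt indel as a mismatch (the tolerance parameter exists for "slightly
variable" families). Expression models are descriptive argmax summaries —
no replicate structure, hence no differential-expression statistics.
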