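---
title: "Methods: comparative mitogenomics and distance-based delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics and distance-based delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodelim)
```

## Scope and record model

`mitodelim` covers the descriptive-comparative stages of a mitogenome study:
per-region composition and strand skew, codon usage, pairwise distances with
threshold-based species delimitation, and construction of codon-position
filtered supermatrices. Heavy inference (ML/Bayesian tree estimation, model
selection, divergence dating) is deliberately out of scope: those stages are
runs of dedicated external tools, while everything here is exactly
recomputable and therefore testable.

A record is a plain list — id, upper-cased sequence over `{A,C,G,T,N}`, a
circular flag, and a feature table (name, kind, 1-based inclusive start/end
on the published strand, strand `H`/`L`, optional anticodon). Features that
wrap the circular origin are stored as two segments. Coordinate conversion
is confined to the I/O layer; everything downstream works on extracted
sense-strand sequences. The written strand is called `H`/`+` by convention
of the published record orientation; no attempt is made to infer the
biological heavy strand.

`N` counts toward feature and genome lengths but is excluded from every
composition denominator, which keeps skews well defined on partially
ambiguous sequences.

## Composition and skew

For a base tally (A, T, G, C):

- A+T% = 100·(A+T)/(A+T+G+C)
- AT skew = (A−T)/(A+T), GC skew = (G−C)/(G+C)

A zero denominator yields `NA` rather than an error (degenerate but legal
input). Strand-class regions (`PCG +`, `PCG −`, ...) concatenate the
*gene-oriented* sequences of the matching features: minus-strand genes are
reverse complemented first. Under this convention minus-strand PCGs show a
positive GC skew while plus-strand PCGs are negative — the sign structure
reported for mayfly mitogenomes — whereas slicing the published strand
directly would flip the pattern. The whole genome is counted as written.
Reports round A+T% to 1 decimal and skews to 3 decimals (the printed
convention); all internal values are full precision.

## Codon usage

Translation and synonymous families follow the invertebrate mitochondrial
code (NCBI table 5: AGA/AGG = Ser, ATA = Met, TGA = Trp; stops TAA/TAG).
Grouping synonymous families by amino acid makes Leu a 6-codon and Ser an
8-codon family; single-codon families under this code do not exist, but any
family observed exactly uniformly has RSCU 1 throughout. RSCU for codon c in
family F is count(c)·|F|/Σ count(F); stop codons are excluded, and an
unobserved family is `NA` (undefined), not zero. Counts are pooled across
the 13 PCGs per genome — the convention of published per-genome RSCU
figures; the pooling convention is not stated in most papers, and a
per-gene long format is available behind a flag.

Start codons are flagged canonical on the mitochondrial ATN pattern. Stops:
a final TAA/TAG with length ≡ 0 (mod 3) is complete; a trailing `T`/`TA`
(length ≡ 1 or 2) is an incomplete stop, completed to TAA by transcript
polyadenylation; anything else is reported `non-canonical` rather than
rejected, since real annotations contain oddities.

## Distances and delimitation

The default model is the uncorrected p-distance with *pairwise deletion*: a
site contributes only when both sequences carry an unambiguous base. The
published whole-mitogenome distance tables this package targets print plain
percentages, which matches p-distance; the distance software setting behind
such tables is typically unstated, so K2P
(d = −½·ln((1−2P−Q)·√(1−2Q)), P/Q transition/transversion fractions) is
provided for sensitivity analysis. K2P returns `NA` (an explicit undefined
marker) when a log argument is non-positive — saturation — rather than a
number or an error.

Delimitation takes the connected components of the graph with edges
d < t_intra (single linkage, strict inequality so the threshold itself
separates). The default t_intra = 0.07 is the upper bound of the 1–7%
intraspecific divergence band typically reported for insect mitogenomes;
it is a convention, not an estimate, and is configurable. A pair split
across clusters is flagged `cryptic_candidate` only when both records share
a user-supplied morphospecies label — "cryptic" means morphologically
identical *and* genetically divergent; without morphology metadata the
honest flag is `distinct`. Evidence distances (per-cluster maximum within,
per-cluster-pair minimum between) are reported so a verdict can be checked
against the matrix by eye.

The shipped 6-taxon Vietnamellidae matrix is a fixture of printed 3-decimal
values. Its off-diagonal mean is 15.5867%, which agrees with the published
15.58% at the printed resolution but not digit-for-digit (the source
presumably averaged unrounded distances); the acceptance test asserts
agreement at one unit in the last printed place, while min (0.1%) and max
(21.1%) reproduce exactly.

## PCG12 and neighbor joining

`build_pcg12()` filters in-frame per-gene alignments to codon positions
{1,2} (or any subset of 1:3) and concatenates in the fixed genome order
ND2, COI, COII, ATP8, ATP6, COIII, ND3, ND5, ND4, ND4L, ND6, CytB, ND1, so
partition tables are deterministic. A taxon missing a gene gets an all-gap
block with a warning, not an error (public records vary in completeness); a
block length not divisible by 3 is an error naming the gene. The package
does not align: simulator output is alignment-free by construction (no
indels), and real genes must be aligned externally.

Neighbor joining follows Saitou–Nei with the standard Q-criterion,
deterministic tie-breaking (first minimal pair in label order), and negative
branch lengths clamped to zero with the deficit moved to the sibling so the
joined pair's path length is preserved. On additive matrices NJ recovers the
generating tree exactly; the tests verify this against path distances from
independently simulated random trees. `clade_check()` asks whether a label
set forms one side of an edge bipartition of the unrooted tree, which makes
singletons, tip complements and the full set trivially true.

## The simulator's stated world

Defaults emulate the composition regime of AT-rich mayfly mitogenomes:

- genome ≈ 15.6 kb; gene lengths scaled from typical insect values, control
  region drawn uniformly on 900–1020 bp (bracketing the 911 / 1015 bp
  observed in the motivating genomes); 0–5 bp intergenic spacers;
- written-strand stationary frequencies derived from A+T = 0.705,
  AT skew = −0.083, GC skew = −0.208 — i.e. A 32.3%, T 38.2%, G 11.7%,
  C 17.8%;
- HKY substitution with κ = 4 (typical insect mitochondrial
  transition/transversion ratio), normalized to 1 substitution/site at rate
  multiplier 1; codon positions evolve at relative rates (1, 1, 5), making
  third positions saturate first; non-coding sites at rate 1;
- canonical 37-gene order starting trnI–trnQ–trnM–ND2; ATN starts, TAA
  stops, with COII, ND5 and CytB carrying truncated `T` stops (the set
  observed in these mayflies); reading frames are protected by reverting
  substitutions that would create internal stops, and starts/stops are held
  fixed (purifying selection);
- a fixed seed makes all outputs byte-identical; the caller's RNG stream is
  restored afterwards.

Ground truth includes the tree, pairwise path lengths, and closed-form
expected p-distances: per rate class c with multiplier m_c and site share
w_c, E[p] = Σ_c w_c · (1 − Σ_i π_i P_ii(d·m_c)) from the HKY transition
matrix; `expected_p_distance()` also exposes the Jukes–Cantor special case
¾·(1 − e^(−4d/3)).

What the generator does *not* emulate — so a green test does not establish
robustness to it: indels and alignment error (real full-genome distances
depend on alignment choices), rate variation beyond the three codon-position
classes, amino-acid-level selection, gene rearrangement, and the
replication-asymmetry mutation pressure that makes real AT skew negative on
*both* PCG strand classes; with a single written-strand stationary
distribution the simulated sense AT skew flips sign on minus-strand genes
even though the GC-skew sign pattern is reproduced.

## Numerical and design choices

- Rounding for report tables is half-away-from-zero, matching how the
  printed tables appear to round negative skews.
- Undefined statistics (zero denominators, saturated K2P, unobserved RSCU
  families) are `NA` markers; operations that cannot proceed on `NA` inputs
  (delimitation, NJ) fail with the offending pairs named.
- Distance model choice for reproducing published tables is left to the
  user (`--model p|k2p`); exact reproduction is validated against the
  shipped fixture, not against re-derived alignments, because the original
  alignment and model settings are unstated.
- GenBank parsing is a minimal flat-file reader covering CDS/tRNA/rRNA/
  D-loop/misc-feature records with `complement`/`join` locations — the
  subset mitogenome records use — and it round-trips the package's writer
  exactly; it is not a general GenBank parser.
- A CDS whose length is not divisible by 3 is legal only when flagged
  incomplete-stop; the reader infers the flag from length, the writer
  records it as a note.

## Known limitations

- Delimitation is a fixed-threshold heuristic; it is sensitive to t_intra
  near cluster boundaries and makes no model-based claim (no GMYC/bPTP).
- Whole-genome distances on real data require an external alignment; the
  package computes distances, not alignments.
- The NJ tree is a distance-based stand-in for likelihood/Bayesian
  inference, suitable for topology sanity checks, not support estimation.
- Intergenic-nucleotide reporting exists but is validated only against the
  simulator, not against published per-gene appendix tables.
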