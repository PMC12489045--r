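---
title: "Methods: product-read profiling, oligomer geometry, and ncRNA conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: product-read profiling, oligomer geometry, and ncRNA conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drtkit)
```

`drtkit` quantifies the three computational signatures of a poly(dA)-
synthesizing, ncRNA-dependent defense reverse transcriptase: poly(A)
enrichment in sequenced cDNA products, the 90°→120° inter-unit angle
expansion that accompanies the tetramer-to-hexamer transition, and a
conserved uracil tract in the ncRNA. This vignette describes the models
and procedures, the parameters that matter, the synthetic-data
generator's assumptions, and the numerical choices — in the package's
own words, so a maintainer can tell deliberate decisions from
accidents.

## Read model and the product-characterization path

The read path assumes a library that mixes two classes:

* **Product reads**: homopolymeric poly(dA) molecules. The generator
  models their length as geometric on {1, 2, …} with mean `mu_core`
  (default 30 nt) — memoryless and single-parameter, which is the
  least-informative choice for a processive polymerase with a constant
  per-base stop probability; nothing in the data model depends on this
  law beyond the analytic prevalence expectation `P(core ≥ t) =
  (1 − 1/μ)^(t−1)` used in tests.
* **Contaminant reads**: substrings of a host reference at uniform
  start, at a fixed `contaminant_read_length` (default 100 nt). Host
  reads come off a sequencer at full read length; product reads are
  short because the molecule itself is short. This asymmetry is what
  makes an error-free contaminant reliably identifiable by the k-mer
  classifier.

With probability `p_tail` (default 0.3) a product read carries a 3'
poly(C) tail, geometric with mean `mu_tail` (default 8 nt), emulating
template-independent terminal transferase addition. Noise is applied
after assembly — substitutions at `sub_error_rate` (default 0.01,
uniformly to a different base), then N-masking at `n_rate` (default
0.001) — so truth labels always describe the pre-noise structure.
Qualities are uniform `"I"`: the simulator does not model quality and
no analysis stage reads it. One integer seed drives a single RNG
stream; a fixed seed gives byte-identical output.

What the generator does **not** emulate: indel errors, quality decay
along the read, adapter sequence, PCR duplication structure, or any
sequence bias in the host beyond its own composition. Passing tests
therefore demonstrate that the operators measure what they claim on
data with known structure — not that real libraries are this clean.

### Triage

`triage_reads()` is a deliberate desk-scale surrogate for an external
aligner, not a reproduction of one: a read is mapped when it shares at
least `min_hits` k-mers (default 2) of length `k` (default 15) with the
reference or its reverse complement. k = 15 makes chance matches
against a kilobase-scale reference vanishingly rare (4^15 ≈ 10^9),
while a 100-nt read with one substitution still carries dozens of
intact reference 15-mers; `min_hits = 2` suppresses single spurious
seeds. k-mers containing N never match. A read matching several
references is assigned to the first in configuration order and counted
once. The SAM route (`read_sam_unmapped()`) accepts any aligner's
output instead; only primary records are used, and the unmapped bit
(0x4) decides membership.

### Tail trimming

`trim_polyc_tail()` removes the longest 3'-terminal window that (i) has
length ≥ `min_tail`, (ii) contains ≤ `max_mismatch` non-C bases, and
(iii) ends in C (the read's final base). Defaults `min_tail = 5`,
`max_mismatch = 1`: five consecutive C's are already unlikely
(~0.1%) at the end of a random read, and one mismatch tolerates a
single sequencing error inside a genuine tail. The rule is idempotent
by construction — maximality forces the base preceding a removed tail
to be non-C, so a second pass never finds a window. A read whose whole
sequence qualifies is dropped (and counted) rather than emptied. Note
the mismatch budget lets the window cross one core base: a tailed
poly(A) read loses its last core A. The prevalence consequences are
small and are part of what the recovery tests measure. 5'-mode trimming
(poly-G heads of reverse-complemented libraries) reuses the same
machinery on the reverse complement.

### Profiles

Homopolymer spectra use **read-level counting**: a read counts at most
once per (base, threshold) cell, because prevalences are reported as a
percentage of total read count; run-level counting (`count = "runs"`)
is available as a diagnostic. Thresholds default to 5–40 nt in steps of
5. Positional composition (default up to 122 nt from the 5' end,
normalized per-position by coverage) and the pooled composition are
computed **after** trimming by default in `run_pipeline()` — trimming
precedes re-evaluation in the procedure the pipeline mirrors, and
untrimmed composition is reported alongside in the trim report. N CPM
uses a read-count denominator (`total N / total reads × 10⁶`), which
makes it invariant under read-set duplication but not comparable across
libraries with different read lengths — the definition is deliberate.

### Clustering and motif input

"Identity" means exact full-length string identity (consistent with
counting *identical copies*); near-identity clustering is out of scope.
Clustering operates on trimmed reads, since tails would otherwise split
clusters of the same core. The poly(A) filter threshold defaults to a
10-nt A-run; the copy filter defaults to 10. Filter-then-cluster and
cluster-then-filter commute under exact identity (tested both ways).
The package writes the motif-discovery input FASTA with copy counts in
the record ids and recommends — but never runs — the external MEME
call (ZOOPS, width 35–40).

## Geometry: inter-unit angles

A dimer unit's **frame** is its centroid plus a directed axis: the
first principal direction of its representative atoms (Cα for amino
acids, P for nucleotides), signed so it points from the first toward
the last residue. Directedness matters: undirected axes fold every
angle to ≤ 90° and could not distinguish 120° from 60°. The default
`unit_pca` mode uses all of the unit's atoms because helix boundaries
are often not known for a new deposition; `helix` mode takes an
explicit residue range when they are.

Angles are measured **after projection into the assembly plane** (the
least-variance direction of all coordinates), matching how such angles
are read off a top view; unprojected 3D angles between tilted axes
would not be symmetry-forced to 120° even in a perfect C3 arrangement.
Adjacency is the angular order of unit centroids about the plane
normal, cyclic for three or more units. Classification applies windows
to the **median** adjacent angle: tetramer-like `[75°, 105°)`,
hexamer-like `[105°, 135°]` — ±15° margins around the 90° and 120°
reference geometries, configurable.

Numerical notes. The angle itself uses `atan2(|a×b|, a·b)`, stable near
0° and 180° where `acos` loses precision. A projection shorter than
1e-6 (axis essentially perpendicular to the plane) is an error, not a
number. Plane fitting errors out when the two minor variance directions
are isotropic (relative singular-value gap < 1e-9), where a normal is
meaningless. The principal direction of a *finite helix* carries a
small intrinsic tilt (≈0.4° for a 20-residue ideal α-helix) from the
cross-covariance between the axial coordinate and the unfinished
radial turn; the synthetic assembly generator therefore defaults to
radius-0 rods, for which round-trips are exact to machine precision,
and tests assert helix-mode recovery at degree-scale rather than
machine-scale tolerances. Identical units related by in-plane rotation
recover their requested angles exactly regardless.

## ncRNA conservation

Upstream extraction takes BED-convention coordinates (0-based
half-open; everything else in the package is 1-based, converted only at
this boundary) and is strand-aware; the default length is 300 nt, a
window comfortably containing a ~190-nt ncRNA plus margin. The anchor
is whatever feature start the caller supplies — gene versus CDS start
is a data question the caller must settle, and the coordinates used are
echoed into the run report.

Gap stripping keeps exactly the columns where the designated reference
row is ungapped, so output columns are reference positions; it is
idempotent. Per-column frequencies follow the sequence-logo convention:
gaps (and N) are excluded from the denominator, with the gap fraction
reported separately; information content is `2 + Σ p log₂ p` bits,
without small-sample correction (none is standard for this display; at
the n = 100 scale the correction `3/(2 ln2 · n)` ≈ 0.02 bits is
negligible). All-gap columns get IC 0 by convention and an `NA`
consensus. Conserved tracts are maximal runs of ≥ `min_len` columns
whose top-base frequency reaches `min_consensus` (defaults 4 and 0.95:
a four-column tract at 95% consensus arises by chance with probability
≈ 0 in a 100-sequence family mutated at 30%). The internal alphabet is
DNA throughout; `rna = TRUE` maps T→U for display only.

The family generator mutates i.i.d. per position outside a conserved
mask (default positions 124–127, set to T in the default reference —
the uracil tract in RNA space). It does not model covariation,
indels within homologs, or phylogenetic correlation; a real homolog set
is not an i.i.d. sample, so conservation estimates on real alignments
carry the usual phylogenetic caveats the simulator cannot expose.

## Problem sizes and determinism

The test suite and acceptance script run at the scale the analyses are
defined at: 10,000 reads for recovery and triage-agreement checks
(binomial 3σ bands), 1,000 random 100-mers for the exact run-detection
oracle, 100-sequence families for conservation, and 2–4-unit synthetic
assemblies for geometry — a few tens of seconds in total. Every
stochastic stage takes an explicit integer seed; identical
configuration plus seed reproduces byte-identical outputs, which the
pipeline tests assert literally on the written files.

## Known limitations

* The k-mer triage is a classifier, not an aligner: no gapped
  alignment, no mapping quality, and its mapped/unmapped boundary will
  not exactly match any particular aligner's.
* Exact-identity clustering fragments under indel errors; the package
  intentionally does not attempt near-identity clustering.
* Geometry assumes units that are at least roughly planar as an
  assembly; strongly non-planar oligomers would need a different
  adjacency notion.
* The conservation profile treats alignment columns as given; alignment
  errors propagate.
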