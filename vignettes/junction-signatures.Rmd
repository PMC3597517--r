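---
title: "Breakpoint junction signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint junction signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionsig)
```

## The scientific problem

Non-recurrent deletions — copy-number losses with scattered, patient-specific
breakpoints — cannot be explained by recombination between flanking low-copy
repeats the way recurrent genomic disorders can. When such a deletion is
delineated to base-pair resolution, the only remaining evidence about the
repair event that produced it is the *junction signature*: the sequence
context where the proximal and distal flanks were fused. Three readouts
carry most of the information:

* **Microhomology (MH)**: a stretch of identical sequence shared by the two
  reference flanks immediately at the fusion point, so that the junction
  aligns perfectly to both. Its length discriminates mechanisms: classical
  non-homologous end joining (NHEJ) tolerates 0–4 bp, microhomology-mediated
  end joining (MMEJ) requires ≥ 5 bp, and replication-based template
  switching (FoSTeS/MMBIR/SRS/BISRS, pooled here as "Replicative") uses MH
  of any length as its priming signature.
* **Information scars**: 1–2 nt substitutions or a lost nucleotide right at
  the junction, a hallmark compatible with NHEJ's error-prone end
  processing.
* **Local genomic architecture** of the 150-bp regions around each
  breakpoint: interspersed repeats (Alu, L1, ...), short sequence motifs
  associated with breakage and recombination, and sequences able to adopt
  non-B DNA conformations (slipped hairpins, cruciforms, triplexes,
  G-quadruplexes, Z-DNA). Same-superfamily repeats at *both* breakpoints
  additionally make nonallelic homologous recombination (NAHR) a candidate,
  provided their identity approaches the minimal efficient processing
  segment (MEPS) regime.

The package implements this analysis as a reusable pipeline and ships a
curated fixture of 24 fine-mapped microdeletions of the FOXL2 locus
(blepharophimosis syndrome; 8 deletions of the upstream regulatory domain,
16 encompassing the gene) against which every stage is validated.

## The microhomology caller

The published practice for junction analysis is a visual multiple sequence
alignment of the junction fragment against both reference flanks. That
procedure is not algorithmic, so the package fixes an operational
definition and applies it identically to observed junctions and controls:

A junction parses as *prefix of the proximal reference* + *(optional
inserted nucleotides)* + *suffix of the distal reference*. With `mp` the
longest exact prefix match and `ms` the longest exact suffix match
(junction length `n`), every switch point in the ambiguous overlap yields
the same two-sided count, so

> `mh_len = mp + ms − n` (clamped at 0),

i.e. the number of bases adjacent to the switch point that match **both**
references. Among equal-MH parses the leftmost switch point is reported —
a pure tie-break: the coordinates shift, the length (the quantity used
downstream) does not. `N` bases never match anything.

Scars are recognized within 10 bp of the expected switch point and capped
at `max_scar_mismatches = 2` events (matching the 1–2 nt scars seen at real
junctions): an isolated interior mismatch becomes a substitution event and
extension continues; a 1-bp length deficit becomes a deletion event. A
junction needing more editing than that is reported "unmappable" rather
than forced into a parse. Anchoring requires ≥ 10 exactly matching bases at
each end of the junction.

Refined breakpoints follow the convention that the proximal breakpoint is
the last nucleotide 5'-adjacent to the MH stretch and the distal breakpoint
the first nucleotide 3'-adjacent to it.

```{r caller}
case <- junction_case("demo",
  prox_seq = "GGATCCGACGTTTTTTTTTT", prox_offset = 10,
  dist_seq = "CCCCCCCACGAGTCAGTCAG", dist_offset = 10,
  junction  = "GGATCCGACGAGTCAGTCAG")
call_microhomology(case)
```

## Architecture scanning

Each 150-bp breakpoint region (75 nt each side of the breakpoint — regions
are centred, matching the control convention) is profiled for:

* **Sequence motifs** (`scan_motifs()`): IUPAC patterns from an editable
  TSV catalogue, all occurrences, both strands where flagged. The package
  bundles a documented default catalogue of well-known
  rearrangement-associated motifs (chi-like element, translin targets, Ig
  class-switch repeats, V(D)J signal sequences, topoisomerase I/II
  consensi, polymerase pause and deletion hotspots, A-tract, alternating
  purine–pyrimidine tract, minisatellite core). Any catalogue in the same
  schema can be dropped in, so a specific published motif list can be used
  unchanged.
* **Direct, inverted and mirror repeats** (`find_*_repeats()`): maximal
  disjoint arm pairs, arm ≥ 8 nt, spacer ≤ 120 nt (both arms must fit in
  the region). The exact maximality definition is documented at the top of
  `R/architecture.R` and shared verbatim with the brute-force oracles in
  the test suite. Arms with composition entropy ≤ 1 bit are suppressed:
  homopolymers and dinucleotide tracts would otherwise generate trivially
  dense calls.
* **G-quadruplex candidates** (`find_tetraplex()`): QGRS-style
  `G_x N G_x N G_x N G_x` candidates, run length ≥ 2, span ≤ 30, scored
  20 per tetrad above the minimum plus up to 10 each for loop evenness and
  loop shortness; overlapping candidates reduce to the best per locus. The
  original G-score formula is cited, not printed, in the literature this
  follows; the formula here is documented in-code and applied identically
  to observed and control regions, so enrichment comparisons are
  internally consistent.
* **Z-DNA-compatible tracts** (`find_zdna()`): maximal alternating
  purine–pyrimidine tracts of ≥ 12 nt built from GT/GC/AC steps. This is a
  deliberate, documented surrogate for statistical-mechanical Z-DNA
  scoring (out of scope): it captures the "GT-repeat" intent with a rule
  that can be brute-force verified.
* **Flanking filter** (`filter_flanking()`): a non-B feature counts for a
  breakpoint region only if its counterparts flank the breakpoint (one arm
  each side, or an arm/tract overlapping it) — features wholly on one side
  are discounted.
* **Repeat context** (`repeat_at_breakpoint()`): the annotated repeat whose
  interval contains the breakpoint, ties broken by overlap with the
  region. `pairwise_identity()` scores same-family pairs by global
  alignment (match +1, mismatch −2, gap open −5, gap extend −2; identity =
  matches / alignment columns).

## The random control population

Controls are 150-bp windows drawn uniformly from a reference sequence
(N-containing windows rejected), each treated as an artificial breakpoint
region with the breakpoint between nucleotides 75 and 76; the default size
is 500. Control *microhomology* needs two flanks, which single windows do
not provide; the package pairs window *i* with window *i + 1* (cyclically)
into 500 pseudo-junctions called with zero scar tolerance. For iid uniform
sequence the MH length is then the sum of two geometric extensions:
P(mh = 0) = (3/4)² = 0.5625 and P(mh ≤ 1) ≈ 0.84 — the control
distribution clusters at 0–1 bp, which is exactly the shape reported for
genomic random controls, and the property the test suite checks against
exact binomial intervals.

The original study drew its controls from Ensembl; the package accepts any
reference FASTA and defaults to its own synthetic locus, keeping the
pipeline download-free. Consequences: significance of the fixture's MH
excess is reproduced *directionally* (p < 10⁻⁴ across seeds), not at the
published 2.28×10⁻⁸, which is tied to the authors' specific control draw.

`fisher_exact_2x2()` computes the two-sided exact p directly from the
hypergeometric definition in log space (the sample odds ratio ad/bc is
reported alongside); `wilcoxon_rank_sum()` enumerates all label
permutations with midranks for combined n ≤ 20 and otherwise uses the
normal approximation with tie and continuity correction. Bonferroni
correction is applied over the repeat families tested (k = 2: Alu, L1) and
over the motif catalogue size for per-motif tests; the family count is a
package decision, as the published correction convention is not stated.
Whether the per-motif comparison should use presence/absence or occurrence
counts is likewise not stated; the report emits the presence-based Fisher
tests plus occurrence-density rank-sum comparisons.

## Mechanism classification

The classifier maps a junction signature to one of three groups:

| group | signature | candidates |
|---|---|---|
| 1 | mh = 0 (scar noted) | NHEJ |
| 2 | mh ≥ 1 and same-superfamily repeats at both breakpoints | NAHR / Replicative / MMEJ (mh ≥ 5) or NHEJ (mh 1–4) |
| 3 | mh ≥ 1 otherwise | Replicative / MMEJ (mh ≥ 5) or NHEJ (mh 1–4) |

"Same family" means same superfamily bucket (AluJo vs AluSz count as same;
L1PA4 vs MIRb as different) — the only mapping consistent with all 24
published calls. NAHR is never the sole candidate; repeat identity ≥ 90%
adds a MEPS-compatible note to the rationale. Same-family context with mh
1–4 bp is unobserved in the curated data; the rule
[NAHR, Replicative, NHEJ] is an extrapolation of the MH-length rules and
is flagged as such in the rationale. On the fixture the classifier
reproduces the published mechanism string for all 24 deletions
(2/9/13 per group):

```{r classify}
calls <- classify_all(load_foxl2_deletions())
glance(calls)
```

## The synthetic-data generator

`generate_locus()` builds an iid background (default GC 0.41, human-like)
with planted decoy repeat cassettes — Alu-like (300 nt), L1-like (1.5 knt),
MIR-, LTR- and DNA-transposon-like — at a default density of 0.25, roughly
the interspersed-repeat load of the studied locus. Decoys are
consensus-derived *random* cassettes, not real repeat sequence, keeping the
repository free of copied genomic data; each copy carries its own
substitution load (2–15%), so same-family copy pairs span the identity
range published for real repeat pairs at deletion breakpoints (74–96%).

`plant_deletion()` places breakpoints honoring a repeat context, enforces
exactly `mh_len` bases of identity immediately 5' of both breakpoints by
local editing of the emitted flanks, and then *edits the bases immediately
outside the stretch* so that no accidental extension exists. Because exact
extension stops at the first mismatch, blocking the two boundary bases
guarantees the planted parse is the unique maximal one — recovery is a
deterministic property, and the planted-MH sweep (0–70 bp × 20 seeds) is
required to be 100% exact, not merely frequent. Scars and insertions are
applied to the emitted junction with the same boundary discipline.
`make_fixture_cohort()` instantiates one synthetic junction per fixture
row (realizing its MH, scar, repeat-family context and identity target), so
the full pipeline can be exercised end to end without any genome download.

What the generator does **not** emulate: real repeat sequence and its
internal structure, indel mutation, nested/fragmented repeats, GC and
replication-timing heterogeneity, and genuine breakpoint-position biases.
Passing the synthetic tests therefore demonstrates that the *algorithms*
are correct under controlled truth, not that the biological enrichment
results generalize to other loci.

## Numerical and design choices

* Internal coordinates are 0-based half-open; published 1-based breakpoint
  positions are converted once at the I/O boundary. Deletion size is
  `end − start`, the definition that reproduces every published kb value.
* Fisher p-values accumulate hypergeometric terms in log space with a
  relative tolerance of 1e−7 when comparing against the observed table's
  probability (the same convention as `stats::fisher.test`, which serves
  as an independent cross-check in the tests).
* The per-region motif counts stored in the fixture are the published
  values; recounting the transcribed motif columns gives a mean of 9.90
  per region against the published mean of 9.69. The discrepancy is
  inherited from the source table and flagged here rather than resolved.
* Problem sizes in the test suite: oracle equivalence runs on 1,000 random
  strings of 30–80 nt (with G-rich strings cycled in for the quadruplex
  detector), the planted-MH sweep on a 100-kb locus, control statistics on
  500-region populations over 100 seeds — sizes chosen so the whole suite
  re-derives every claim from scratch in a few minutes on one CPU.
* Tie-breaks are fixed everywhere (leftmost switch point; highest-scoring,
  then leftmost, then longest-run quadruplex; longest-overlap repeat at a
  breakpoint) so all results are deterministic given seeds.

## Known limitations

* Complex rearrangements with more than one template switch per junction
  are out of scope; a two-deletion allele is represented as two
  independent junction cases.
* The Z-DNA and G-quadruplex rules are documented surrogates, adequate for
  internally consistent observed-vs-control comparisons but not calibrated
  thermodynamic predictors.
* The 40-motif catalogue of the original study is not recoverable from its
  body text; the bundled default catalogue is a documented stand-in with
  the same schema, and all motif operations take the catalogue as an
  argument so the exact published list can be substituted.
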