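---
title: "Finding spliceosomal introns and snRNAs in intron-poor genomes"
author: "intronoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding spliceosomal introns and snRNAs in intron-poor genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronoscope)
```

## The biological problem

Diplomonads (*Giardia*, *Spironucleus*) and parabasalids (*Trichomonas*)
carry some of the most reduced nuclear genomes known among eukaryotes, with
only a handful of spliceosomal introns each. Those few introns are highly
stereotyped: a short, strongly conserved 5' splice site (donor) beginning
`GT`, and a branch-point sequence *fused* to the 3' splice site (acceptor)
so that the branch adenosine sits at an almost fixed distance from the
terminal `AG`. In *Spironucleus*-type introns the donor consensus is
`GTAAGTY` and the fused branch-point + acceptor consensus is
`RCTAACAARHTAG`, where the branch adenosine is the A directly 5' of the
last C of the `ACTAAC`-like core. Introns are short (tens of nucleotides);
longer ones fold back on themselves so that the *spatial* distance between
donor and acceptor, after discounting nucleotides sequestered in stem-loops,
matches the plain length of the short ones.

This package implements the computational machinery to find and
characterize such introns and their splicing apparatus: degenerate-consensus
scanning, genome-wide candidate discovery, reading-frame disruption
assessment under the ciliate genetic code, RT template-switch artifact
triage of spliced-read junctions, constrained RNA folding with a
splice-site spatial-distance statistic, structured-motif search for U5
snRNA candidates plus feature annotation of U2 candidates, intron
positional-homology calls across orthologs, and the decision rules of a
spliceosomal-protein census. A seeded synthetic-data layer generates
genomes, junction sets and ortholog families with planted ground truth, so
every stage can be validated end to end.

## Coordinates and containers

All coordinates are 1-based inclusive, the native convention of
`IRanges`/`GRanges`, and the convention used in all reports (which matches
how genomic ranges are cited in the literature). Genomes are
`DNAStringSet`s; hits and candidates are `GRanges` with metadata columns;
the compiled pattern, secondary structure and synthetic-truth containers
are small S4 classes (`CompiledPattern`, `SecondaryStructure`, `TruthSet`).

## Degenerate pattern scanning

`compilePattern()` accepts IUPAC codes, explicit classes (`[T/C]`) and
bounded repeats (`{3,4}`), expanding the latter into fixed-length
alternatives; `scanMotif()` scans either or both strands with a bounded
mismatch count. Two deliberate semantics:

* a subject `N` never satisfies a pattern symbol other than `N`, so
  gap-filled assembly stretches cannot produce spurious hits;
* mismatch counting is positional with no indels, appropriate for
  fixed-length splice-site motifs.

The fused branch-point consensus circulates in two spellings that differ at
position 10 (`RCTAACAARHTAG` with `H`, and `RCTAACAARYTAG` with `Y`). Both
compile and scan identically apart from that position; the broader `H` form
is the package default and the `Y` form ships alongside it in
`defaultPatterns()`. The discrepancy is surfaced here rather than silently
resolved.

`scanMotifBrute()` is a deliberately naive per-offset re-implementation
kept as an independent oracle; the test suite requires exact agreement
between the two on randomized sequences for every pattern the pipeline
uses.

## Intron discovery

`scanGenomeForIntrons()` anchors on branch-point + acceptor matches and
searches upstream for donors, emitting every (donor, anchor) pairing whose
implied intron length lies within bounds. Defaults are 40–120 nt: the
confirmed *Spironucleus*-type introns range from 40 to 67 nt, and headroom
is left for structured introns. The sources do not state how far upstream a
donor was accepted nor how competing donors were resolved; here the window
is implied by the length bounds and *all* donor pairings are emitted ranked
by proximity to the anchor (`rank` 1 closest), replacing manual triage with
a reproducible ordering.

A displaced-acceptor mode (off by default) additionally reports candidates
whose branch-point core is separated from a `YAG` acceptor by up to 20 nt,
flagged `displaced_3ss` — the configuration seen in a confirmed 5' UTR
intron whose inserted segment folds into a stem-loop restoring branch-point
/ acceptor proximity. Such candidates are meant for folding follow-up, not
automatic acceptance.

Reading-frame disruption (`assessOrfDisruption()`) follows the ciliate
genetic code (NCBI translation table 6): `TAA` and `TAG` encode glutamine
and only `TGA` terminates, so an intron disrupts its gene only through a
frameshift (length not divisible by 3) or an in-frame `TGA` lying entirely
within the intron. Codons merely overlapping the intron boundary are not
counted; this keeps the statistic a property of the intron sequence itself.

## Junction triage and the template-switch filter

Spliced-aligner output over RNA-Seq contains abundant artifacts from
reverse-transcriptase template switching, which produces apparent junctions
between loci sharing a short direct repeat. `templateSwitchScore()` slides
a k-mer window (k = 5) over offsets −5..+5 applied identically at both
junction boundaries and reports the best identity count. Two points the
sources leave open are settled explicitly:

* whether the windows include the junction base: both anchorings are
  implemented (`anchor = "boundary"` starts at the first intronic and first
  downstream-exonic base; `"adjacent"` one base further), default
  `"boundary"`;
* the score evaluates **both** boundary-pair geometries of the
  direct-repeat model (repeat shared by intron start and downstream exon,
  or by upstream exon and intron end) and takes the maximum. A single
  geometry is not invariant under reverse-complementing the genome and
  junction at a finite offset window; the two-geometry maximum is exactly
  strand-symmetric and both geometries arise mechanistically.

`triageJunction()` computes the three rescue criteria used for manual
study: a 5/6 match of the first six intronic bases to `GTATGT` or
`GTGAGT`; a `[CT]AG` terminus; and a candidate branch point `ACT[AG]AC`
ending within the final 20 intronic nucleotides.
`filterJunctionCandidates()` partitions candidates with artifact
classification (perfect k/k repeat) taking precedence over rescue, and
reports the perfect and k−1 repeat fractions over all candidates.

## Constrained folding and the spatial-distance statistic

`foldConstrained()` is a nearest-neighbor minimum-free-energy folder with
positions forcible single-stranded — the masking applied to the donor
(7 nt) and branch-point + acceptor (13 nt) elements so predicted structure
never conscripts spliceosome-interacting bases. The model, fixed as the
package's parameter table:

* Watson–Crick stack enthalpies/free energies from the standard
  dimer table, with a single simplified value class for stacks containing a
  G:U wobble (one value for one wobble pair, one for two);
* temperature via $\Delta G(T) = \Delta H - T_K \Delta S$, supporting the
  21 °C and 37 °C settings used for organisms with different growth
  temperatures;
* purely entropic linear loop penalties (hairpin $5.0 + 0.15(L-3)$, bulge
  $3.5 + 0.3L$, internal $2.0 + 0.25L$ kcal/mol at 37 °C, scaled by
  $T_K/310.15$), linear multiloop ($a,b,c = 3.4, 0.4, 0.1$), minimum
  hairpin loop 3, interior loops capped at 30 unpaired nt, no dangles or
  coaxial stacking;
* pairs restricted to AU/UA/GC/CG/GU/UG; pseudoknots excluded.

This is intentionally simpler than a full folding engine: the pipeline
needs stem-loop presence and spans, not chemically accurate energies, and
the simple model admits an *exhaustive* reference implementation
(`foldExhaustive()`) that enumerates every structure of a short sequence
and scores it with the same table (`scoreStructure()`). The test suite
requires the dynamic program to equal that enumeration on hundreds of
random sequences. The interface is deliberately small so a full
thermodynamic backend could be substituted for real-data work.

Suboptimal structures ("the three most optimal") are enumerated
deterministically within an energy band (default 2 kcal/mol), deduplicated,
sorted by energy with ties broken by lexicographically smallest
dot-bracket.

`spatialDistance()` operationalizes the single-stranded donor-to-acceptor
distance: every maximal element closed by an outermost (top-level) base
pair — the stem *and* its enclosed loops — is excised from the path, and
what remains is the spatial distance. This arithmetic reproduces the
printed distances of the source analyses (a 63-nt intron with a 22-nt
hairpin element has spatial distance 41 nt) but the exact loop-nucleotide
accounting there is unstated, so the definition is a package convention,
stated here.

```{r fold-example}
s <- foldConstrained("GGGGAAAACCCC")[[1]]
s
spatialDistance(s)$spatial_distance
```

## U5 and U2 snRNA search

U5 snRNAs are recognizable by the invariant loop-I sequence `UGCCUUUUACY`
atop a long stem-loop, followed by an Sm protein binding site
(`RAU(4-6)GR`). `findU5Candidates()` stages the search: (1) loop-I matches
with ≤ 2 substitutions whose immediate 6-nt flanks can close ≥ 6
consecutive pairs (G:U allowed); (2) a constrained fold of the hit ± 100 nt
(loop forced single-stranded) must embed the loop in an extended stem-loop
with ≥ 3 helix segments separated by ≥ 2 internal loops — the structural
reading of the canonical 1a/1b/1c helices with internal loops IL1/IL2,
which the sources never define by sequence; (3) an Sm site downstream of
the loop's closing stem within the flank. The Sm search is anchored on the
loop rather than on the outermost predicted pair because MFE folding in
genomic context routinely extends stems with incidental flanking pairs.
Stage-1 hits failing 2 or 3 are retained flagged `partial`. These
thresholds are package conventions and are the package's answer to an
open definitional question; they are re-checkable through the standalone
predicates `u5LoopMismatches()`, `closingStemPairs()` and `smSiteHits()`.

`checkU2Features()` annotates a U2 candidate: a window able to base-pair
with the intron branch-point region leaving exactly the branch adenosine
bulged (adjacent adenosines give an indistinguishable duplex, so
uniqueness is assessed against non-adjacent alternatives), the `GCU` /
`GAUC` motifs of U2–U6 helix I, and an Sm site. Covariance-model searches
are out of scope; externally produced hits can be annotated through this
function.

## Positional homology of introns across orthologs

`callHomologousIntrons()` expresses each intron site as (protein-alignment
column of the interrupted codon, phase), making "same relative position"
well-defined across indels, and groups introns sharing both. Groups in
adjacent columns at the same phase are cross-flagged `possible_sliding` and
never merged. `protoSpliceCheck()` counts flanking-exon agreement with the
proto-splice consensus `(A/C)AG|G`; `cladePresenceSummary()` tallies
per-clade presence as numerator/denominator, excluding a species from the
denominator only when its gene copy is recorded as not found (the sources'
denominator policy is unstated; this exclusion rule is the package's).

## Spliceosomal-protein census rules

`domainFilter()` retains a candidate only with all expected conserved
domains (or all but one, flagged). `reciprocalCheck()` encodes the
reciprocal rule: original query among the top 10 BLASTp hits *and* similar
size — ± 50 aa below 300 aa, ± 20 % at 300 aa and above, both inclusive,
with the under-300 branch covering lengths up to 299 (the boundary is
unstated in the sources; this choice is documented and tested at the
boundary). Query matching is by accession with an optional alias map.
`retentionAnalysis()` computes per-organism totals, ordered-pair
containment fractions (the nestedness statistic), Venn partition counts
for declared 2- or 3-set groupings (sets may be unions or intersections of
organisms), and counts LSm/Sm-block proteins as deduplicated families via
a supplied protein-to-family map (the dedup key is a package convention;
the family identity of LSm-domain proteins is genuinely ambiguous). The
reference protein list is configuration, not a vendored table.

## The synthetic-data layer

`simulateGenome()` plants what the discovery stages assume: i.i.d.
background at configurable GC (default 0.45, a typical AT-rich protist
value), stop-free ORFs under the ciliate code on random strands, and
introns whose donor and fused branch-point + acceptor are sampled uniformly
within the consensus classes, lengths 40–120 nt. Every intron is forced to
be disruptive (frameshift or in-frame `TGA`). With `structuredFraction`,
an interior inverted repeat is planted and the constrained fold verified to
put the spatial distance inside the target band (default 35–45 nt, the
band the structured introns of these organisms converge on); generation
resamples on failure, so planted truth always satisfies the property it is
meant to test. `simulateJunctions()` overlays real junctions (planted
introns) with artifact junctions built as direct repeats at matched
offsets — perfect with probability `repeatFidelity`, otherwise an interior
single substitution with boundary extension broken, so a near-miss cannot
drift back to a perfect score at a shifted offset. Realized labels are
computed with the brute-force scorer, independent of the detector under
test. `simulateOrthologFamily()` diverges an ancestral protein by
substitutions and tracked single-residue indels and drops intron sites per
species with a loss probability. `simulateU5Genomes()` plants one designed
U5-like locus per genome and verifies its detectability in genomic context
at generation time.

What the generators do **not** emulate: repeat families, compositional
heterogeneity, sequencing error, allelic variation (a knob for duplicated
genes exists but is off by default), and real intergenic structure. Green
planted-truth tests therefore demonstrate correctness of the algorithms
under their stated assumptions, not performance on real genomes.

## Problem sizes and reproducibility

The validation suite runs at desk scale, chosen to exercise each stage
meaningfully: 1000 random 200-nt sequences for the scanner oracle, 500
random ≤ 18-nt sequences for exhaustive fold enumeration, 50 simulated
10-kb genomes with 5 planted introns each for discovery recall, 1000
labeled plus 10,000 random junctions for the template-switch filter, 20
simulated 50-kb genomes for U5 recall, and random 174 × 6 presence
matrices for the census set algebra. The genome-wide-screen emulation in
`scripts/acceptance.R` plants artifacts at the composition reported for
the real screen (about half of all candidates perfect repeats and about a
quarter near-misses). All randomness flows from explicit seeds; identical
seeds give byte-identical generator output and reports.

## Known limitations

* The energy model is a teaching-grade nearest-neighbor table; predicted
  energies are not comparable to full thermodynamic engines, only the
  structural topology is meaningful at this scale.
* Discovery at zero mismatches is exact by construction; allowing
  mismatches trades precision for sensitivity and the ranking of competing
  donors is a package convention.
* The U5 structural thresholds (helix/internal-loop counts) are
  operational definitions; genuine divergent snRNAs may fail them.
* Junction handling consumes aligner output; alignment itself, and
  covariance-model snRNA search, are out of scope by design.
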