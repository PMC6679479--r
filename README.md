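# intronoscope

Discovery and characterization of spliceosomal introns, snRNAs and
spliceosomal-protein complements in intron-poor genomes.

## The problem

Diplomonads and parabasalids (*Giardia*, *Spironucleus*, *Trichomonas*)
keep only a handful of spliceosomal introns per genome, and those introns
are rigidly built: a conserved donor site `GTAAGTY`, and a branch-point
sequence fused to the acceptor as a single motif `RCTAACAARHTAG` whose
branch adenosine sits at a near-fixed distance from the terminal `AG`.
Introns are short (40–67 nt confirmed); longer ones fold into stem-loops
that restore a short *spatial* distance between donor and acceptor. Their
splicing machinery is correspondingly reduced: divergent snRNAs that evade
standard homology search, and a spliceosomal proteome pruned to a nested
core across related lineages.

`intronoscope` is an R/Bioconductor-style toolkit for the computational
side of that biology, aimed at researchers annotating intron-poor protist
genomes:

- **Degenerate motif engine** — IUPAC patterns with classes (`[T/C]`),
  bounded repeats (`{3,4}`) and mismatch allowances; strand-aware scanning
  over `DNAStringSet`s (`compilePattern()`, `scanMotif()`).
- **Intron discovery** — genome-wide candidates anchored on the fused
  branch-point + acceptor motif with upstream donor search, length bounds,
  phase/motif annotation, and ORF-disruption calls under the ciliate
  genetic code, where TAA/TAG = Gln and TGA is the only stop
  (`scanGenomeForIntrons()`, `assessOrfDisruption()`, `annotateIntron()`).
- **Junction triage** — reverse-transcriptase template-switch artifact
  scoring by boundary direct repeats (best k-mer identity over matched
  offsets, max over both repeat geometries) and splice-signal rescue
  criteria (`templateSwitchScore()`, `triageJunction()`,
  `filterJunctionCandidates()`).
- **Constrained RNA folding** — nearest-neighbor MFE with positions forced
  single-stranded (splice-site masks), deterministic suboptimal
  enumeration, and the donor→acceptor spatial-distance statistic
  \(d_{spatial} = L - \sum_h (j_h - i_h + 1)\) over outermost stem-loop
  elements \(h\) (`foldConstrained()`, `spatialDistance()`); validated
  against an exhaustive enumeration folder (`foldExhaustive()`).
- **snRNA search** — three-stage U5 detection (loop I `UGCCUUUUACY` ≤ 2
  mismatches, ≥ 6-bp closing stem with G·U, extended stem-loop
  architecture, downstream Sm site `RAU₄₋₆GR`) and U2 feature annotation
  (branch-point pairing with a bulged branch adenosine, U2–U6 helix-I
  motifs) (`findU5Candidates()`, `checkU2Features()`).
- **Intron conservation** — positional homology across orthologs by
  (alignment column, phase), intron-sliding flags, proto-splice-site
  `(A/C)AG|G` checks, clade presence summaries
  (`callHomologousIntrons()`, `protoSpliceCheck()`,
  `cladePresenceSummary()`).
- **Protein census rules** — conserved-domain filtering, the reciprocal
  top-10 / size-tolerance rule (± 50 aa under 300 aa, ± 20 % at ≥ 300 aa),
  LSm/Sm family deduplication, nestedness and Venn retention analysis
  (`domainFilter()`, `reciprocalCheck()`, `retentionAnalysis()`).
- **Synthetic data with planted truth** — seeded generators for genomes
  with consensus-conforming introns (optionally structured to a target
  spatial-distance band), junction sets with controlled artifact rates,
  U5-like loci, and ortholog families (`simulateGenome()`,
  `simulateJunctions()`, `simulateU5Genomes()`,
  `simulateOrthologFamily()`).

## Worked example

Simulate a 10-kb genome with five planted consensus introns, rediscover
them, and fold one candidate with its splice sites masked:

```r
library(intronoscope)

tr <- simulateGenome(nContigs = 1, contigLen = 10000,
                     nGenes = 5, nIntrons = 5, seed = 7)
cand <- scanGenomeForIntrons(genomeSeqs(tr))
cand
#> GRanges object with 5 ranges and 6 metadata columns:
#>       seqnames    ranges strand |     five_ss        bp_3ss branch_a_offset
#>   [1] contig01 1144-1191      + |     GTAAGTT GCTAACAAACTAG              40
#>   [2] contig01 2729-2817      - |     GTAAGTT ACTAACAAACTAG              81
#>   [3] contig01 5522-5637      + |     GTAAGTT ACTAACAAACTAG             108
#>   [4] contig01 6480-6586      - |     GTAAGTT GCTAACAAAATAG              99
#>   [5] contig01 9333-9441      + |     GTAAGTC GCTAACAAAATAG             101
```

All five candidates coincide exactly with the planted truth (recall 1.0);
`five_ss`/`bp_3ss` are the matched motif texts and `branch_a_offset` is
the predicted branch adenosine's position within each intron. Fold the
first (48-nt) candidate with the 7-nt donor and 13-nt branch-point +
acceptor elements forced single-stranded:

```r
iseq <- cand$intron_seq[1]; n <- nchar(iseq)
st <- foldConstrained(iseq, unpaired = c(1:7, (n - 12):n), nBest = 1)[[1]]
st
#> SecondaryStructure (48 nt, -0.53 kcal/mol at 37 C)
#>  GUAAGUUGUAGAGACACACAAUCUGCCGCUUGAUCGCUAACAAACUAG
#>  .......(((((.........)))))......................
spatialDistance(st)$spatial_distance
#> [1] 29
```

One weak stem-loop spans 26 nt, so 29 of the 48 nucleotides remain on the
single-stranded donor-to-acceptor path. `runPipeline()` chains discovery,
annotation, folding and junction triage and writes GFF3/TSV reports with a
provenance header; `inst/scripts/intronoscope.R` wraps the same functions
for shell use.

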