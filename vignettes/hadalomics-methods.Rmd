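---
title: "Models and methods behind hadalomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hadalomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadalomics)
```

hadalomics implements the downstream, bespoke computational layer of a
sediment metagenome survey. This vignette explains each model and
procedure, the parameters that matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and the numerical decisions made where the design was genuinely open.

## Relative sequence abundance

Reads arrive with semicolon-delimited, rank-prefixed lineages
(`sk__...;p__...;c__...`); the sentinel `unclassified` (never an empty
string) marks unassigned reads, which keeps parsing unambiguous. At a
queried rank, the relative abundance of a taxon is
$100 \cdot n_t / N_\text{assigned}$. The denominator deliberately counts
*all* assigned reads, including those whose lineage truncates above the
queried rank: this follows the aggregation formula literally
("dividing by the total number of assigned reads") rather than
renormalising per rank, so percentage columns may sum to less than
100%. Because either convention is defensible, `renormalize = TRUE`
switches the denominator to reads resolved at the rank, and
`within = "<taxon>"` restricts both rows and denominator to a named
clade (the way eukaryote-internal percentages are reported) — both are
explicit options, never silent behaviour.

## MAG quality filtering and tiers

The retention rule is completeness ≥ 50% and contamination ≤ 10%.
Survey texts describe this cutoff both as strict inequalities and as a
tool-style cutoff (`-c 50 -x 10`); tool cutoffs are conventionally
inclusive, so inclusive boundaries are the default and
`strict = TRUE` is exposed for the other reading. Completeness tiers
(> 70%, > 90%) are strict, matching the "greater than" phrasing they
come from; a MAG at exactly 70.0% is not in the > 70 tier.

## Pathway completeness and lifestyle classification

Module completeness is the percentage of a pathway's key genes encoded
in a genome, rounded to two decimals; with four key genes and one
present the value is 25. Pathway *presence* uses a separate rule —
at least `min_markers_present` key genes detected — because survey
heat-maps typically call presence from marker detection rather than a
completeness threshold. The default is 1 marker; the shipped
Calvin-cycle (CBB) entry requires both `rbcS` and `prkB` since either
gene alone is weak evidence of the cycle.

Lifestyle flags are pure functions of pathway categories: heterotroph
⇔ any degradation pathway present; autotroph ⇔ any CO₂-fixation
pathway; mixotroph ⇔ both; aerobic ⇔ aerobic respiration; anaerobic ⇔
any anaerobic respiration pathway (DNRA, denitrification, sulfate
reduction); facultative ⇔ both; chemolithotrophy is flagged per subtype
(nitrification, CO/sulfide/H₂/iron oxidation). The invariants
*facultative ⇒ aerobic ∧ anaerobic* and *mixotroph ⇒ heterotroph ∧
autotroph* hold by construction and are property-tested.

Two catalogs ship as editable YAML. Notes on their content:

* Carbohydrate-degradation markers are CAZyme *class codes* (GH, PL,
  CE, GT, AA, CBM) matched as prefixes of annotated families, since
  degradation evidence is family-level.
* The sulfate-reduction entries follow their source labelling verbatim
  (sat/aprAB/dsrAB under "assimilatory", aprA/aprB under
  "dissimilatory") even though apr/dsr markers are conventionally
  dissimilatory; the catalog header documents this so users can edit
  rather than be silently "corrected".
* The `cox` name collision between cytochrome c oxidase (aerobic
  respiration) and carbon monoxide dehydrogenase (CODH,
  chemolithotrophic CO oxidation) is resolved by namespaced labels
  `coxA`-family vs `coxL`; annotation inputs must carry unambiguous
  labels.
* Marker sets not enumerated in the anchoring survey text
  (hydrocarbon/aromatic degradation, 3-HP, 3-HP/4-HB, methanogenesis,
  H₂ oxidation; the rTCA marker Acl shipped as its aclA/aclB subunits)
  are editable defaults drawn from common usage, not fixed science.
* The fungal catalog (nitrate/sulfate reduction, sulfide oxidation,
  organic-sulfur assimilation) runs through the same engine; there is
  no fungal-specific code path.

## Virus–host association

**Composition.** Tetranucleotide frequency vectors are computed over
*all 256* tetranucleotides by counting every window on the sequence and
its reverse complement (windows containing non-ACGT letters are
skipped); both-strand counting makes the vector exactly strand
invariant, which is why the space is not collapsed to the 136 canonical
k-mers — the symmetrisation is already in the counts, and the
acceptance threshold is calibrated to 256 components where the mean
frequency is 1/256 ≈ 0.0039. Multi-contig genomes aggregate counts
before normalising, so a MAG's signature is that of its concatenated
contigs. The distance is the mean absolute error over components,
bounded by $2/4^k$; a virus is assigned to the host with minimal $d$,
accepted only when $d < 0.0015$ — strict, following the "if d < 0.0015"
phrasing, and boundary-tested at ±ε. Viral contigs shorter than 5 kb
are skipped by default because short-sequence signatures are noisy
(the threshold is configurable down to 0). Exact ties resolve to the
lexicographically smallest host id and carry a `tied` flag.

**CRISPR.** The detector is a deliberately minimal stand-in for a
dedicated CRISPR finder: it reports arrays of ≥ 3 exact repeat copies
(23–50 bp) separated by unique 20–60 bp spacers, seeding the search at
the minimum repeat length (any longer exact repeat contains a
duplicated minimum-length prefix) and preferring longer repeats so an
array is reported once at its maximal repeat. Spacer matching scans
both strands of every virus for full-length, ungapped alignments within
a Hamming bound. The survey methods this mirrors record mismatch counts
but state no tolerance; the default `max_mismatch = 2` is a judgment
call exposed as a parameter, and the headline recovery checks run at 0.

**Similarity.** BLAST tabular rows are filtered at bit score ≥ 50 and
E-value ≤ 0.001 (inclusive, following "a threshold of 50"), then
collapsed to one edge per (virus, host) keeping the best-scoring row.

**Network.** Edges from all signals are reduced to *distinct* (virus,
host) pairs — the same pair found by two signals counts once — and
summarised as a bipartite virus-family × host-class graph whose edge
weights are pair counts. Unmapped ids group under "unclassified"; graph
vertices are side-prefixed internally so a label shared between a
family and a class cannot collide.

Coordinates are 0-based half-open throughout, strands are `+`/`−`.

## AMG flagging

A viral ORF with a CAZyme family annotation is a carbohydrate AMG; an
ORF whose orthology id appears in the nitrogen/sulfur catalog is a
nitrogen or sulfur AMG; one ORF can yield both records, and every
record's evidence field is copied from the input row, never
synthesised. The shipped N/S catalog is deliberately minimal — nitrite
reductase (nirK / K00368) and ATP sulphurylase (cysN/nodQ / K00956),
the two orthologs explicitly implicated in host nitrogen/sulfur
modulation — rather than padded with guesses; a fuller KO list drops in
as YAML. The upstream annotation threshold (E ≤ 1e-5) belongs to the
annotation tool, not this module.

## Marker utilities

Marker-hit filtering keeps hits at E ≤ 1e-5, identity ≥ 50%, coverage
≥ 30% (inclusive) and retains the best hit per query. "Coverage" is
query coverage by default — the fraction of the query ORF aligned —
with a subject-coverage mode by flag, since the source phrasing does
not specify which.

Alignment trimming keeps columns with non-gap occupancy ≥ 0.95; if
fewer than 50% of the original columns survive, the 50% highest-
occupancy columns are kept instead (`ceiling` of the count, ties to the
left-most column). This is this package's fixed, documented contract,
not a claim about any external trimming tool's version-specific
behaviour. One consequence: the conservation fallback is not idempotent
(re-trimming a rescued alignment applies the percentage to the smaller
column count), while the plain occupancy filter is — the idempotence
property is therefore stated and tested for the occupancy path.

Concatenation aligns per-marker matrices on a genome roster, inserts
all-gap blocks for missing genomes, and records 0-based half-open
partitions (written 1-based inclusive in the RAxML-style dialect).

## The synthetic-metagenome generator

The generator's defaults define the verification conditions: 5 host
genomes of 50 kb, order-3 nucleotide chains, 2 prophages per host of
5–10 kb, 3 pooled-chain decoy viruses, 5 CRISPR arrays with 30 bp
spacers at mismatch rate 0, 100,000 reads with 10% unassigned, and a
Dirichlet(5) abundance vector.

* **Host composition.** Each host's transition rows are independent
  Dirichlet draws with total concentration 4 per row (i.e. uniform
  Dirichlet). This value was chosen from a pilot calculation before the
  recovery tests were written: it yields pairwise host tetranucleotide
  MAE around 0.003 — comfortably above the 0.0015 link threshold, as
  distinct real genomes are — while a 5–10 kb subsequence of a host
  sits near 0.0004 from its source, comfortably below. Order 3 is the
  smallest order that structures tetranucleotides directly.
* **Prophages** are verbatim, non-overlapping subsequences of their
  host, guaranteeing both an exact similarity link and a small
  composition distance; **decoys** are drawn from a chain fitted to the
  pooled hosts, so they are compositionally near the community but
  linked to nothing — non-trivial negatives.
* **CRISPR arrays** are repeat–spacer–repeat–spacer–repeat (3 copies of
  a random 28 bp repeat, 2 spacers copied from random viral windows).
  Spacer windows are resampled until the spacers' first and last bases
  differ across the array; otherwise the planted repeat would not be
  maximal and a correct detector would extend it by the shared flanking
  base, shifting spacer boundaries relative to the recorded truth.
* **Annotations** plant each catalog pathway independently with
  probability 1/2 per genome and emit exactly the required markers plus
  non-marker noise genes; expected flags are derived in the generator
  from the planted categories, independently of the classifier, so the
  round trip is a real check.
* **Read assignments** are multinomial draws from the truth abundance
  vector with a fixed rounded count of unassigned reads.

Everything is seeded per stage (derived sub-seeds), so each generator
is byte-reproducible both standalone and inside the bundled run.

What the generator does *not* emulate: sequencing error, assembly and
binning artefacts, uneven coverage, real phylogenetic structure in the
lineages, partial prophage degradation, array repeat mutation, or
compositional convergence between unrelated genomes. Passing recovery
tests therefore demonstrate the correctness of the association and
classification logic under clean, separable conditions — not expected
field performance on real metagenomes, where signal overlap and noise
dominate.

## Problem sizes and determinism

The shipped tests run the generator at its default scale (5 × 50 kb,
10⁵ reads) for the recovery and determinism checks and at reduced
scales (3 × 12–15 kb, 10³–2×10⁴ reads) for structural checks; oracle
comparisons use randomized sequences up to 50 kb and assignment tables
up to 10⁴ rows. These sizes were chosen as the smallest at which every
contract is exercised meaningfully. All randomness flows through
per-stage seeds derived from the user seed; `run_pipeline()` writes a
manifest with a config hash, and two runs with identical config are
byte-identical — this is asserted file-by-file in the tests.

## Known limitations

* The CRISPR detector requires *exact* repeat copies and unique
  spacers; degenerate repeats or duplicated spacers (as occur in real
  arrays) are not found. It is a verification stand-in, not a
  replacement for a dedicated detector.
* Composition assignment reports at most one host per virus; genuinely
  ambiguous sub-threshold seconds are not reported (single-best
  assignment, ties flagged).
* The conservation fallback in alignment trimming is not idempotent
  (see above).
* The trait engine treats marker labels as exact identifiers (CAZyme
  classes as prefixes); it does not resolve synonyms or orthology —
  inputs must use catalog-consistent labels.
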