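---
title: "Methods: comparative isoform evolution across five primates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative isoform evolution across five primates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model of the data

`primatesplice` analyzes full-length transcript models observed across a
five-primate phylogeny — human (H), chimpanzee (C), gorilla (G), orangutan
(O) and rhesus macaque (M) — together with short-read replicate expression
estimates. The package's unit of analysis is the *projected transcript
model*: one isoform structure carried by a shared transcript key and
observed, via orthology mapping tables, in all five assemblies. All
internal coordinates are 0-based half-open; GTF input/output converts
to/from the 1-based inclusive convention. A configurable minimum intron
length (default 4 nt) guarantees that the two terminal dinucleotides of an
intron never overlap.

The pipeline covers seven analysis layers: structural novelty
classification, local alternative-splicing (AS) events, splice-site
canonicity and its interspecies changes, conserved vs species-specific
exon calls from mapping tables, presence/absence evolution under Wagner
parsimony, isoform/exonic-part usage dynamics, and in-silico proteomics.
A synthetic five-species generator with a truth ledger provides the
testing ground for all of them.

# Structural classification

Transcripts are compared to a reference annotation by intron chain,
ignoring 5'/3' end positions (long-read ends are variable; the intron
chain is the reproducible part of the structure). Categories are assigned
in a fixed priority order, so the assignment is a deterministic partition:

1. **FSM** — intron chain identical to a reference transcript (mono-exonic
   transcripts: contained in a same-strand reference exon);
2. **ISM** — a consecutive sub-chain of one reference transcript;
3. **NIC** — every splice site annotated on that chromosome and strand,
   but the chain or site combination is new;
4. **FUSION** — the chain spans two or more non-overlapping same-strand
   reference genes with at least one junction in each (evaluated before
   NNC so that fusion reads are reported as their own novelty class);
5. **NNC** — at least one unannotated splice site, in a transcript with
   same-strand exonic overlap;
6. **ANTISENSE**, **GENIC_INTRONIC**, **INTERGENIC** — exonic overlap
   only with opposite-strand genes; contained in a gene without exonic
   overlap; no gene overlap at all. A mono-exonic transcript that
   partially overlaps a same-strand exon without being contained in it
   falls to GENIC_INTRONIC — the smallest consistent extension of the
   mono-exon rules, which reference tools leave unspecified.

FSM and ISM count as "known", everything else as "novel". Junction
novelty is separate and exact: a junction is known iff its precise intron
interval occurs in the reference on the same strand.

# Alternative-splicing events

Events are detected by pairwise comparison of exon chains within a gene
and reported at gene level, deduplicated by (class, defining intervals).
The definitions, written to be checkable literally by a brute-force
oracle:

- **SE** — transcript A has an internal exon whose two flanking junction
  outer boundaries coincide with a single junction of B splicing directly
  across it.
- **RI** — A has one exon spanning exactly the two consecutive exons of B
  and the intron between them (outer boundaries equal).
- **A5SS / A3SS** — two junctions share one genomic boundary and differ
  at the other, and the exons abutting the differing boundaries overlap
  each other. The overlap requirement separates boundary shifts (within
  exonic context) from complete exon skipping. Donor/acceptor naming
  follows transcription orientation, so the same genomic configuration is
  A5SS on the plus strand and A3SS on the minus strand.
- **MEX** — two non-overlapping exons, each skippable against the same
  outer flanking boundaries, that never co-occur in any transcript of the
  gene. Overlapping candidate exons are excluded; this is the strictest
  common definition, chosen because looser ones admit spurious pairs in
  dense isoform sets.

Alternative first/last exons are deliberately not emitted as a class.

# Splice-site canonicity

A junction is canonical iff its (donor, acceptor) pair, read in
transcription orientation, is GT-AG, GC-AG or AT-AC. Dinucleotides
containing N are labelled noncanonical with a warning. For interspecies
comparisons, orthologous junction coordinates come from the mapping
table; each species is labelled canonical / noncanonical / missing, a
*change* flag requires at least two non-missing species that disagree,
and "canonical only in the expressing species" is the per-species
indicator used downstream to explain species-specific expression gains
mechanistically.

# Orthology: exon conservation and exonic parts

Conservation calls consume precomputed mapping tables (liftOver-style
mapped/unmapped status plus Liftoff-style alignment coverage); the
package applies the decision rule rather than re-running alignment:

- **conserved** — mapped in all four non-focal assemblies;
- **species_specific** — mapping failed in all four AND alignment
  coverage is strictly below 0.5 in all four;
- **unresolved** — everything else, including failed mappings with
  missing coverage (with a warning) and multi-locus mappings.

The strict `< 0.5` threshold makes the call monotone in coverage:
lowering coverage can never turn a species-specific exon into a conserved
one.

Exonic parts — the counting units for differential exon usage — are the
maximal sub-intervals of a gene's exon union not crossed by any exon
boundary. Flattening is built on interval disjoining
(`IRanges::disjoin`), annotates each part with its covering transcripts,
and is idempotent; parts are disjoint and their lengths sum to the exon
union length. Part coordinates live on a designated anchor frame (human
by default) with per-species projections supplied by the mapping table.

# Expression presence and Wagner parsimony

A transcript is *present* in a species under the strict criterion iff
TPM exceeds the presence threshold (default 0) in **all** replicates, and
under the lenient criterion in at least two; it is *absent* iff TPM is at
or below the absence threshold (default 0) in all replicates. Profiles
with any other pattern are ambiguous: they are kept and flagged but
excluded from parsimony and species-specific calling, because
inter-individual variability should not masquerade as evolutionary
change. The alternative presence threshold 0.1 TPM is exposed in the
configuration.

Gain/loss reconstruction runs Sankoff dynamic programming over the binary
states on the fixed rooted topology `((((H,C),G),O),M)` with configurable
gain and loss costs (default 1/1; an asymmetric 2/1 setting is supported
and tested). Because the tree has only four internal nodes, *all* optimal
labelings are enumerated by optimal backtracking: an event present in
every optimal labeling is reported as unambiguous; events that differ
between optima are each reported with `ambiguous_direction = TRUE`. The
macaque-only profile is the canonical example — a macaque terminal gain
and a great-ape stem loss tie at score 1 and cannot be distinguished.

A transcript is **species-specific** iff its strict profile is 1 in
exactly one species and 0 in the other four. The up-regulation confound
check asks whether genes expressing species-specific transcripts are
simply up-regulated in that species: gene-level log2(TPM+1) is compared
focal-vs-rest with a Welch t-test, BH-adjusted across genes, and a gene
is flagged only when adjusted p < 0.1 *and* the fold change is positive.
This replaces a negative-binomial Wald test deliberately: with three
replicates per group the decision rule (threshold and direction), not the
count model, is the operative content, and the package implements its
statistics rather than wrapping them.

# Usage dynamics

**Normalization.** TMM factors are computed from counts: the reference
sample minimizes the distance of its upper-quartile (of library-scaled
positive values) from the mean upper quartile; per-gene log-ratios M and
abundances A are formed on doubly-positive genes; 30% of M and 5% of A
are rank-trimmed two-sided; the factor is 2 to the precision-weighted
mean of the retained M values (asymptotic binomial variance weights), and
factors are rescaled to geometric mean 1. Batch structure, when present,
is corrected by per-batch median-centering on the log2(TPM+1) scale — a
deliberate, documented simplification of empirical-Bayes batch
correction, adequate for location shifts and transparent about what it
does not model (scale and covariate effects).

**Isoform usage.** IU(t, s) is transcript t's fraction of its gene's
summed abundance in sample s (missing when the gene is silent in s); by
construction IU sums to 1 per gene and sample wherever defined. Genes
whose transcripts differ only by internal boundary shifts of at most
30 nt (no junction gained or lost) are flagged as
quantification-ambiguous and excluded from usage analyses, as are exact
duplicates.

**Dominance.** Within each species, transcripts are ranked by mean IU
across replicates; ties break by higher total expression, then
lexicographic id. A gene shares its dominant isoform when one transcript
is rank 1 in all five species; the sharing fraction is recomputed along a
grid of rank1/rank2 expression fold-change thresholds, and ORF and
ordered domain-combination identity of the rank-1 transcripts is reported
where those annotations are supplied.

**Differential usage.** For each feature (transcript IU or exonic-part
usage coefficient) the ten species pairs are tested with a two-sided
Welch t-test on logit(usage + 0.01), BH-adjusted across features within
each pair. A feature is species-specific *up* (resp. *down*) for species
S iff all four pairs involving S are significant with a consistent sign
and none of the six pairs among the other species is significant. This
all-4/none-of-6 consistency rule is the package's explicit answer to a
question the underlying count-model machinery leaves open, and it is
what makes a call "species-specific" rather than merely "different
somewhere". Default expression filters: gene TPM of at least 1 in two or
more samples per species, feature expressed in two or more samples of at
least one species; groups with fewer than two usable replicates are
skipped.

# ORFs and in-silico proteomics

ORF prediction takes the longest ATG-initiated sense-strand frame ending
at the first in-frame stop (or the transcript end, flagged 3'-incomplete),
with a 50-residue default minimum and 5'-most tie-breaking — a
deterministic, standard heuristic. Tryptic digestion cleaves after K or R
except before P, emits fragments with at most two missed cleavages and
lengths in [7, 40] (typical search-engine settings; all configurable).
Peptide novelty is substring matching against the reference proteome
under I/L equivalence (the two residues are isobaric and
indistinguishable to the search engines whose behavior the in-silico
layer mirrors); multi-mapping peptides are kept and counted, not
resolved. Per gene, the analysis reports whether any peptide is novel.
Ordered domain-label combinations are compared as exact sequences against
the reference set, with the empty combination matching undomained
reference ORFs.

# Gene classes and enrichment statistics

A gene's species-specific "up" events are the union of its transcript
gains, DIU up calls and DEU up calls per species. Classes, by precedence:
`MULTI_SPECIES_UP` (events in two or more species — precedence applies
even when one of them is human), `HUMAN_SPECIFIC_UP`, `NHP_SPECIFIC_UP`,
`OTHER_CHANGES` (non-species-specific usage differences, e.g. group-level
or down calls), `CONSERVED`. The classes partition the evaluated
universe.

Enrichment uses a two-sided Fisher exact test computed by
point-probability hypergeometric summation (all tables with the observed
margins whose probability does not exceed the observed one, within a
relative tolerance of 1e-7), with OR = ad/bc and zero cells reported as
0 or infinity with a boundary flag rather than continuity-corrected —
correction is a caller's choice, not a default. The hypergeometric mode
reports the upper-tail over-representation p and observed/expected fold
change. Backgrounds are always explicit arguments. BH adjustment
delegates to `stats::p.adjust`. All-pairs rank comparisons default to
Wilcoxon rank-sum with Holm adjustment; a Dwass-Steel-Critchlow-Fligner
mode refers the tie-corrected pairwise standardized rank statistic to the
studentized range distribution.

# The synthetic generator

The generator emulates the study design — five species sharing projected
models, three RNA-seq replicates per species — at desk scale: one
kb-scale chromosome per gene neighborhood (default 300 genes), all five
genomes derived from one ancestral sequence. Neutral substitutions
(default rate 0.002/bp per species) avoid all splice-site dinucleotides,
so planted changes are the only canonicity-relevant differences. Planted
classes, each recorded in a machine-readable truth ledger:

- **Expression gains** (30, of which 10 canonicity-driven): an extra
  isoform with a private alternative donor, expressed in every replicate
  of one species and exactly zero elsewhere, at constant gene totals so
  the confound check stays negative. For canonicity-driven gains the
  private donor's GT is mutated to GA in the four non-focal genomes.
- **Exonizations** (15): a new exon carved inside an intron by planting
  AG/GT sites in the focal genome only; the mapping table marks the exon
  unmapped elsewhere with *drawn* coverage in [0, 0.45]. Coverage is
  drawn, not computed by alignment: the table's contract is to exercise
  the decision rule, not to model liftOver. A configurable fraction
  (default 0.8) is tagged with an Alu repeat interval.
- **DIU shifts** (30, usage delta +0.4), **DEU parts** (40, mixture shift
  on the inclusion isoform of a skipped exon), **dominant-isoform
  switches** (10), **unannotated genes** (5, absent from the reference
  annotation and proteome), and **NNC isoforms** (15, a private donor
  absent from the reference annotation).

Counts are negative-binomial (dispersion 0.05, per-gene log-normal means,
medians near 300 with planted genes floored at 300 so presence calls
reflect design rather than dropout); expected counts are proportional to
usage times transcript length, so TPM-scale usage fractions equal the
planted program exactly, and TPM is computed from counts with effective
length equal to transcript length (no fragment-length model — quantifier
behavior is out of scope). Batch effects are off by default and
switchable.

Two expression draws serve different analyses: presence/gain calling uses
the three-replicate design, while usage analyses (DIU, DEU, dominance)
use a six-replicate draw of the same reference — a two-sample location
test on three replicates per group has too little power for usage shifts
of 0.4 to be a meaningful recovery target, and the replicate override is
an explicit, seeded parameter of the expression simulator.

**What recovery runs score.** Sensitivity counts planted events
recovered under their own keys. Empirical FDR for usage calls is scored
at (gene, focal species) granularity: planting a +0.4 shift on one
transcript necessarily moves the usage of its sibling transcripts and
parts, so sibling calls inside a planted gene are genuine signal, not
false positives. Null fixtures (zero planted events) are required to
produce no species-specific presence calls and usage calls at no more
than the nominal FDR.

**What passing does and does not show.** The generator plants clean,
well-separated effects on short genomes with known truth; passing
demonstrates that the decision rules, statistics and data plumbing do
what they claim under the stated noise model. It does not demonstrate
robustness to mapping error, annotation incompleteness, 3' bias,
inter-individual structural variation, or quantification ambiguity beyond
the modelled boundary-shift class — all properties of real data that the
fixture intentionally does not emulate.

# Numerical and design choices, in brief

- Priority-ordered classification makes category assignment a partition;
  FUSION outranks NNC.
- Parsimony enumerates all optima (cheap at 2^4) instead of picking one,
  so direction ambiguity is explicit rather than silently resolved.
- Fisher p-values use the point-probability method with a 1e-7 relative
  tie tolerance, matching standard exact-test behavior.
- Rank ties in dominance break deterministically (expression, then id).
- logit-usage tests use a pseudo-usage of 0.01; degenerate zero-variance
  comparisons return p = 1 for equal means and p = 0 otherwise.
- Problem sizes in the shipped analyses (300-gene fixtures, 200-500
  random genes per oracle comparison, 1000 proteins for digestion
  checks) are chosen so the full suite runs in minutes on a single CPU
  while keeping every oracle comparison exhaustive where the space is
  small (all 32 leaf profiles; all 2x2 tables with margins up to 30).

# Known limitations

- Mono-exonic antisense resolution is underdetermined by the category
  scheme; the package applies its documented fallback rather than
  guessing an external tool's behavior.
- The confound check and usage tests are location tests on transformed
  quantities, not count models; with many replicates a negative-binomial
  GLM would gain power.
- Exonic-part counts derived from transcript counts assume uniform
  coverage along transcripts.
- The DSCF mode uses the large-sample studentized-range reference, not
  exact small-sample tables.
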