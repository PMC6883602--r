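---
title: "Clone-based haplotyping of duplicated Hox amplicons: models and methods"
author: "hoxclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-based haplotyping of duplicated Hox amplicons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Interspecific hybrid fish lineages — here a common carp (maternal, "COC")
by blunt snout bream (paternal, "BSB") cross and its selfed descendants —
carry several diverged copies of each Hox gene: typically two maternal
haplotypes and one paternal haplotype per gene, plus copies rearranged or
silenced during the genomic shock that follows hybridisation. The standard
assay amplifies the exon1–intron–exon2 region of each gene (~0.7–1.7 kb)
with degenerate primers, clones the product, and sequences 20–30 clones per
gene. Three questions follow from such a library:

1. **Which distinct haplotypes ("sequence types") are present**, once
   PCR/sequencing errors are filtered out?
2. **Which clones are mosaics** — recombinant clusters stitched together
   from segments of two or more haplotypes — and where are the junctions?
3. **Which copies are pseudogenes**, i.e. carry a premature in-frame stop
   codon in their spliced coding region?

`hoxclone` implements this analysis end to end, together with a fully
seeded simulator that generates hybrid clone libraries with known ground
truth, so every step can be validated by parameter recovery.

## Sequence types: collapsing a clone library

`collapse_clones()` first groups byte-identical clones. Groups below
`min_support` (default 2 clones) are then consolidated iteratively: a small
group is absorbed into the closest group of at least its own support within
`merge_radius` mismatches (global-alignment distance). The default radius
is 6: at 10^-3 errors/base over a 0.7--1.6 kb amplicon a clone carries
~1--1.6 errors on average, and 6 is the ~99.9% Poisson tail — the radius
should cover essentially every error-only clone, while haplotypes (≥5%
diverged, dozens of mismatches) remain far outside it. Protecting mosaics
is *not* the radius's job; that is what the veto below is for. Two details
matter and are deliberate:

* **Single-nucleus consolidation.** When a haplotype happens to be sampled
  by only a handful of clones, each carrying one or two random errors, no
  error-free pair may exist: every clone is a singleton. Absorption
  restricted to strictly larger groups would leave the haplotype shattered,
  so equal-support merges are allowed; and because two parallel nuclei of
  the same haplotype could each cross `min_support` and become unmergeable
  duplicates, merges happen one at a time with established groups preferred
  as absorbers. The support-weighted majority consensus then votes the
  scattered errors out; columns that remain tied (a two-member group where
  each member carries its own errors) are resolved toward a base carried by
  a *solid* group — identical-member or support ≥3 groups, whose consensus
  provably carries no member error — since related copies nearly always
  share the true base at an error position.
* **The allele-evidence veto.** A mosaic clone can sit within
  `merge_radius` of one of its donors (a terminal segment may carry only
  two diagnostic sites). Distance alone would silently absorb it as
  "error". Absorption is therefore vetoed when at least two of the small
  group's mismatches against the absorbing group sit at positions where
  *both* conflicting bases are carried by solid groups — the signature of
  an informative site between co-amplified haplotypes. A variant whose
  deviations are random bases carried by no solid group is PCR error; one
  whose deviations are shared alleles is a candidate recombinant and must
  survive to classification.

Even so, a clone beyond the radius (or a rare pair of identical errors)
can surface as a stray variant, exactly as stray variants do in real clone
surveys; the lineage summary therefore reports both the raw type count and
a curated count restricted to types with `min_support` clones.

`assign_labels()` names the types against a parental reference panel by
full-amplicon nucleotide identity: the best match at or above
`identity_floor` (default 90%) inherits the reference's label (roman
numerals `i`, `ii`, … for maternal copies, `-BSB` for the paternal copy);
additional maternal-like types continue the numbering (`iii`, `iv`, …) in
order of support; types below the floor against every reference are novel
(`-1`, `-2`, …). The 90% floor sits between within-species haplotype
divergence (~5%) and the maternal–paternal divergence (~10%) and is the
single most consequential threshold in the pipeline; it is config-exposed
and logged.

## Mosaic detection: penalised minimum-mismatch segmentation

Candidate donors (parental references plus the taxon's own non-recombinant
types) and the query are placed on common coordinates by one *joint*
multiple alignment: equal-length sets are stacked, mixed-length sets go
through MAFFT (with an internal centre-star fallback when it is absent).
A joint MSA matters more than it may seem: independently optimal pairwise
alignments can disagree about gap placement inside alignment-ambiguous
indel windows, and such mutual shifts fabricate apparent mosaic segments.
For the same reason, informative columns within 12 columns of any gap are
masked as evidence, and the simulator guarantees its diagnostic sites at
twice that distance from indels so the guarantees survive small placement
drift. Only *informative sites* — columns where at least two donors
differ — carry signal about segment origin.

`segment_query()` finds, by dynamic programming, the donor-label path over
the informative sites minimising

> mismatches + λ × (number of donor switches)

The optimum is global; ties prefer continuing the current donor, then the
donor earlier in panel order. Runs collapse into segments; any segment with
fewer than `min_diag` diagnostic sites (default 2) against an adjacent
donor is merged into its cheaper neighbour. Breakpoints are reported as
intervals between the query-evidenced diagnostic sites of the adjacent
donor pair — between those sites the donors are indistinguishable, so a
point estimate would be false precision; the true junction provably lies
inside the interval on clean data.

`classify_clone()` calls a type *recombinant* when the best multi-segment
composition beats the best single donor by at least `delta` penalised-score
units **and** the mosaic explanation itself reaches the identity floor over
informative sites (a heavily diverged sequence whose stray matches can be
chained into segments is a novel haplotype, not a recombinant); *putative*
when its best single-donor identity reaches the floor; *novel* otherwise.
Recombinant types supported by a single clone are flagged as PCR-chimera
candidates but never adjudicated — the assay cannot distinguish an in vivo
recombinant cluster from a PCR-mediated template switch.

**Choice of λ and δ.** The defaults are λ = 0.5 and δ = 1 with
`min_diag` = 2. The coupling is deliberate: a segment with *d* diagnostic
sites is only callable when the mismatches it saves exceed the switch
penalty by the margin, d − λ·switches ≥ δ. With λ = 0.5 and δ = 1 every
segment with ≥2 diagnostic sites — the identifiability minimum the
simulator also enforces — is callable, including the hardest case, a
two-site middle segment (saving 2 against two switch penalties, 2 − 1 ≥ 1),
while a single stray mismatch can never trigger a breakpoint call (maximum
saving 1 < λ + δ). Raising λ towards the number of informative sites
degrades gracefully into nearest-haplotype assignment, a property the test
suite asserts.

## Structure annotation and pseudogene calls

`annotate_structure()` transfers exon1/intron/exon2 boundaries (1-based
inclusive, exactly the convention of the published locus tables, with exon2
ending at the last amplicon base and an optional untranslated leader before
exon1) from an annotated reference by global alignment, then nudges each
boundary by at most 6 bp to the nearest canonical `GT`…`AG`. If no
canonical placement exists the copy is *unannotatable* — printed with
dashes and treated as a pseudogene, mirroring how such copies appear in the
field's tables.

`call_pseudogene()` translates the spliced coding region with the standard
nuclear code from a configurable frame offset and records every stop
strictly before the final complete codon; a terminal stop is normal
termination. Codons containing IUPAC ambiguity letters are never called
stops — a conservative rule; codons whose ambiguity *could* resolve to a
stop are flagged with a warning instead.

## Identity matrices and the clade check

`pairwise_identity()` uses global alignment (match +1, mismatch −1, gap
open −5, gap extend −1; config-exposed) and defines identity as identical
columns over columns where both sequences carry a residue, rounded half-up
to one decimal. Gap columns are excluded from the denominator by default —
the tools historically used for such tables do not state their convention,
so an include-gaps variant is provided for sensitivity checks. At the
amino-acid level a pair involving a pseudogene prints the marker `"P"`: a
truncated product has no comparable protein sequence.

`clade_partition_check()` builds a neighbour-joining tree on amino-acid
p-distances and asks, per gene family, whether some edge bipartition of the
unrooted tree separates exactly that family, with each recovered family
anchored by exactly one designated orthologue. p-distance suffices here
because the question is only whether deeply diverged gene families form
clean clades, not branch lengths or supports; model-based Bayesian
phylogenetics is out of scope by design. Pseudogenes stay in the tree,
represented by the longest stop-free prefix of their translation.

## The simulator and what passing tests mean

`simulate_parent_panel()` draws, per gene, an ancestral amplicon — random
leader (0–90 bp), exon 1 (250–450 bp), canonical `GT…AG` intron, exon 2
(180–240 bp, enough for the 60-aa homeodomain), total length uniform on
700–1600 bp — and derives haplotypes by uniform random substitution
(each maternal copy at half the configured 5% within-parent divergence from
the ancestor, the paternal copy at 10% from the maternal pair) plus
intron-only indels (0.002 events/site, 1–6 bp: the published locus tables
concentrate length variation in the intron, at about one event per
intron). Substitutions never touch the splice dinucleotides and never
create an in-frame stop; premature stops are planted explicitly in 10% of
haplotypes and recorded. A per-gene synthetic outgroup at 25%
divergence stands in for the orthologue anchor of the clade check.

`simulate_clone_library()` emits exactly `clone_depth` (default 30) clones
per gene; a planted fraction (default 10%) are mosaics of 2–4 segments cut
uniformly between informative columns, and i.i.d. substitution errors are
applied at `error_rate` (default 10^-3/base — the PCR error scale; no
published estimate exists for this assay, so the value is a free
parameter). Two identifiability rules keep the ground truth testable, in
the same spirit as drawing breakpoints only between informative sites:
every planted segment carries at least two substitution-type diagnostic
sites against *every* panel haplotype, and a mosaic is rejected (re-drawn)
if any different same-length donor composition explains its sequence
exactly — otherwise the recorded donor labels would be unidentifiable in
principle, by any method.

Determinism is strict: one top-level seed, per-gene streams hashed from
(seed, gene index, stage), so identical configurations are byte-identical
and gene subsets reproducible.

The simulator emulates clone sampling, substitution divergence, intron
indels, mosaic formation and sparse sequencing error. It does **not**
emulate chromatograms, primer bias, heteroduplex artefacts, PCR
recombination kinetics, or among-site rate variation. Passing parameter
recovery therefore shows the pipeline is correct *under its own model of
the assay*; on real libraries, systematic artefacts (e.g. template
switching hotspots) can still produce single-clone mosaics that no
statistical rule can separate from genomic recombinants — which is why
single-clone compositions carry the chimera-candidate flag.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout; exon 2 ends at the final
  amplicon base.
* Rounding of printed identities is half away from zero to one decimal
  (base R's banker's rounding would print 94.45 as 94.4).
* Collapse order, label claims, DP backtracking and novel numbering all
  use documented deterministic tie-breaks (support, then lexicographic
  sequence; donor panel order), making every result invariant to input
  order.
* Degenerate cases: a single-haplotype panel has no informative sites and
  classification falls back to nearest-haplotype; zero divergence makes
  maternal copies identical and mosaics unplantable (clones are emitted
  pure); an empty clone set, a gene/config mismatch, or an unannotatable
  reference each raise a typed error naming the offending input.

## Problem sizes used in the validation suite

Parameter-recovery checks run on 20 seeded replicates of 2-gene panels at
depth 30 (zero-noise recovery must be exact in every replicate; at
10^-3 errors/base the curated per-gene haplotype counts must be recovered
in at least 95% of replicates); the DP is checked against exhaustive
path enumeration on 200 random instances with up to 4 donors and up to 12
informative sites (instance sizes capped so enumeration stays exact); the
clade check runs on a 12-gene panel; generator calibration uses 400–1000
replicate genes. These sizes give stable Monte-Carlo estimates while
keeping the suite comfortably reproducible on a laptop.

## Known limitations

* Centre-star alignment assumes panel haplotypes are closely related; it
  is not a general MSA and would degrade below ~80% identity.
* Frame offsets other than 0 must be supplied by the caller (e.g. chosen
  by homeodomain alignment); the pipeline default assumes primer design
  placed exon 1 in frame.
* Breakpoint intervals are only as tight as the local density of
  diagnostic sites; in long intron stretches without informative columns
  the interval can span hundreds of bases — this is a property of the
  data, not of the algorithm.
* The recombinant/novel boundary (δ, `min_diag`, identity floor) is an
  operationalisation; the underlying biological distinction is not fully
  identifiable from cloned amplicons alone.
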