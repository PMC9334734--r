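---
title: "Methods: domain-signature screening, orthology vetting and domain phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-signature screening, orthology vetting and domain phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunome)
```

## The problem

Inferring immune function from a genome of an understudied lineage cannot rely
on sequence similarity alone: invertebrate immune genes are often so diverged
from their vertebrate namesakes that BLAST-style searches miss them, while
conserved protein *domains* (as integrated by InterPro from Pfam, SMART,
PANTHER, Gene3D and others) remain recognizable. This package implements the
combined strategy used for compiling invertebrate immunomes: (1) screen every
protein for family-diagnostic domain suites, (2) collapse isoform-level
matches to genes, (3) vet candidates by shared orthogroup membership with
known immune genes from reference species, (4) rescue genes that orthology
finds but domain annotation cannot, and (5) characterize the survivors by
domain architecture and distance-based phylogenetics of extracted domains.

## Rule semantics

A family rule is a small logical formula in disjunctive normal form over
domain accessions. Each clause has a label (`strict`, `alternate`, `relaxed`),
a required set, an optional forbidden set, and an optional repeat requirement:

* **AND within a clause, OR across clauses.** Comma-separated accession lists
  in published required-domain tables are conjunctions; parenthesized
  alternatives (such as the two domain suites that can identify a complement
  factor B) become alternate clauses.
* **Clause order is strict, alternate, relaxed**, and the first satisfied
  clause is reported, so a strict match always dominates.
* **Namespaces.** A required accession is satisfied whether it appears as the
  member-database signature (`SM00369`, `G3DSA:3.80.10.10`, ...) or as the
  integrated InterPro accession (`IPR003591`), because published domain lists
  freely mix both. PANTHER subfamily annotations (`PTHR10887:SF470`) also
  satisfy requirements stated at the family level (`PTHR10887`).
* **Forbidden sets** are an extension beyond the published tables, needed to
  express families defined partly by absence — "orphan TIR" proteins carrying
  a TIR domain and nothing else, or PIWI proteins that lack argonaute linker
  domains. They default to empty.
* **Repeat requirements** (`min_distinct_hits`) count distinct merged hit
  intervals of a required accession, so "contains two TIR domains" is
  expressible; overlapping fragment hits of one domain are first unioned and
  count once.
* Families are **not mutually exclusive**: one protein may legitimately match
  several lectin families, and the published counts do not imply exclusivity.

The shipped catalog mirrors the published strict/relaxed required-domain
tables of the *Aplysia* survey (139 families across sixteen functional
groups). Gene-level counts label a gene by the strongest clause among its
isoforms, and a gene matches when at least one isoform matches.

Two caveats limit exact reproduction of the published per-family counts from
real inputs: the published numbers reflect domain mining *and* orthology
vetting *and* a manual inspection step whose individual decisions are not
enumerated; and overlapping lectin families (CTLD vs CREP/FBGDC) may or may
not have been counted exclusively. The engine therefore exposes both pre- and
post-vetting counts and makes no exclusivity assumption.

## Orthology vetting, rescue, and overlap statistics

Vetting asks, per candidate gene, whether any of its isoform (or gene) ids
shares an orthogroup with a same-family reference gene; the orthogroup table
is taken at whatever id level it contains. Rescue inverts the direction:
focal-species genes co-grouped with references but missed by the domain
screen enter the immunome flagged `homology_rescued`, with clause `none`; by
construction the rescued set is disjoint from the domain-matched set.
Reference ids absent from the orthogroup table warn (once per family) and
count as no evidence. Homology-hit evidence (BLAST outfmt 6) uses best-hit
filtering with a default threshold of e-value ≤ 1e-5 and no bitscore floor —
defaults stated here because the original analysis gives none.

Orthogroup overlap statistics are parameterized rather than hard-coded, since
phrases like "common to mollusks and humans but not flies" have no single
formal reading. A named subset is any combination of `equals` (the non-empty
species set equals the stated set — used for "only"-style subsets), `all_of`,
`any_of` and `none_of`. The "common to X and human but not fly" reading used
throughout is: non-empty in at least one X column AND non-empty in human AND
empty in fly. The partition identity (single-species + multi-species = total)
is enforced by tests on random tables.

## Domain architecture

Member databases fragment repeat regions (LRRs especially) arbitrarily, so
same-label intervals that overlap *or are book-ended* (stop + 1 = start) are
unioned before any counting or extraction; merging is idempotent and
order-invariant, and a one-residue gap keeps intervals separate. Domain
regions are extracted from the longest isoform of each gene; length ties are
broken towards the lexicographically smallest protein id (deterministic, and
logged via a message). All coordinates are 1-based inclusive end-to-end; the
only half-open arithmetic happens inside `substr()` slicing and is never
exposed. Architecture patterns (dual-TIR, ROC+COR "ROCO" modules, LRR with a
cysteine-rich C-terminal flank, CARD-less RLRs, accessory Mbt/EF-hand
domains, ≥3 transmembrane segments, signal peptide) are declarative count
constraints with optional absences, so new patterns need no code.

## The distance model

Pairwise distances maximize the two-sequence likelihood under JTT+I+Γ:

$$\ell(t) = \sum_{\text{sites}} \log\Big[\, p_{inv}\,\pi_x\,\delta_{xy}
  + (1-p_{inv})\,\tfrac1k \sum_{r} \pi_x P(t\,r)_{xy} \Big]$$

with $P(\tau)=e^{Q\tau}$, $Q$ the reversible JTT generator normalized to one
expected substitution per site per unit time, and $r$ the $k$
equal-probability discrete-gamma category means. Choices worth recording:

* **JTT constants** are the published empirical exchangeabilities and
  stationary frequencies, embedded as data in `R/jtt.R`; a test asserts
  equality (up to normalization) with the constants shipped by phangorn.
* **k = 4 categories** follows the original tree-building configuration.
* **alpha defaults to 1.0**: the original methods fix `k` but never state the
  gamma shape, so a neutral default is used and exposed as a parameter.
* **p_inv defaults to 0.2**: the original methods text prints a "proportion of
  invariable sites of 2", which cannot be a proportion; it is read here as
  0.2 and exposed as a parameter.
* **Gap handling is pairwise deletion** (sites with a gap or non-standard
  residue in either sequence are dropped per pair), the standard choice for
  distance matrices; zero comparable sites is an error, not a zero.
* **Optimization** is Brent search on $t \in [10^{-8}, 50]$ to absolute
  tolerance $10^{-8}$; an estimate at the upper bound is returned as the
  bound with a saturation warning. $P(t)$ is evaluated through a precomputed
  symmetric eigendecomposition, with tiny negative round-off probabilities
  clamped to zero.

Neighbor joining uses the Studier–Keppler $Q$ criterion with a deterministic
smallest-(i, j) tie-break. Negative branch-length estimates are clamped to
zero with the deficit transferred to the sister branch, preserving the path
length between the joined nodes. On additive matrices the method is exact:
tests require Robinson–Foulds distance 0 and branch errors below $10^{-9}$
against 100 random generating trees of 8–16 taxa.

Bootstrap resamples alignment columns with replacement; the support of each
internal bipartition of the point-estimate tree is the percentage of
completed replicates containing it (replicates that fail — e.g. a pair with
no comparable sites — are skipped, logged, and excluded from the
denominator). With a fixed seed the procedure is reproducible bit-for-bit.
The original study used B = 1000 for the single-species domain tree and no
bootstrap for the larger multi-species tree; both are just parameter
settings here. Group concordance declares a group monophyletic when some
bipartition separates exactly that group, and otherwise reports members
outside the maximum-F1 covering side as outliers.

## What the synthetic generator does and does not emulate

`generate_annotation_bundle()` writes the exact dialects the parsers consume
(InterProScan TSV, `Orthogroups.tsv`, FASTA, two-column gene map, reference
YAML) for a five-species design mirroring the study layout (focal gastropod,
second gastropod, bivalve, ecdysozoan, vertebrate). Planted family genes get
their family's strict-clause accessions as non-overlapping intervals on the
longest isoform; background genes draw 0–2 decoy accessions from a pool
disjoint from the catalog, exercising non-matching paths; orthogroups tie
each planted family to fabricated reference genes in the non-focal species,
with background genes as focal singletons. Defaults (5 TLRs, 3 SRCRs, 50
background genes) are small enough that the whole screen-vet cycle runs in
well under a second. Sequence content is drawn from JTT stationary
frequencies — the rule engine reads annotations, not residues, so motif
realism is deliberately not attempted. The evolver (`evolve_sequences()`)
simulates sites independently under the same +I+Γ mixture used for
estimation, making it a valid oracle for distance and topology recovery.

The generator does **not** emulate: annotation noise (false or missing
domain calls), fragmented repeat hits, isoforms with partial domain
complements that independently match, paralog interleaving within
orthogroups, or indels (alignments are emitted gap-free; gap handling is
tested with hand-built fixtures). Passing planted-truth tests therefore
demonstrates the correctness of the pipeline's logic, not robustness of the
original annotations — on real data the screen's precision is bounded by the
annotation quality, which is why the vetting and manual-inspection stages
exist.

## Problem sizes and tolerances used in verification

The test-suite and acceptance script scale: exhaustive rule-engine oracle on
all $2^{12}$ accession subsets against a 5-rule catalog; 20 synthetic-bundle
seeds for planted-truth recovery (precision = recall = 1 required exactly);
100 additive matrices for NJ exactness; 10 seeds × 3 true distances
(0.1/0.5/1.0) at alignment length 5,000 for distance recovery (mean absolute
error < 0.05); 20 seeds of 8-taxon, 2,000-site simulations for topology
recovery (≥ 18/20 exact); 100-replicate bootstraps checked for bit-for-bit
reproducibility. These sizes keep a full verification run under a minute
while leaving each check statistically meaningful.

## Known limitations

* The published headline totals (2,241 proteins / 1,669 genes) involved
  manual curation that no deterministic rule set can replay exactly; the
  pipeline reports pre- and post-vetting totals instead.
* Rules match annotation output only; no HMM scanning of raw sequences.
* NJ is exact on additive inputs but, like all distance methods, inherits the
  noise of pairwise estimates on short alignments; ML/Bayesian tree search is
  out of scope.
* `alpha` is supplied, never estimated; model selection is out of scope.
* Running InterProScan, OrthoFinder, BLAST or an aligner is out of scope by
  design: the package treats their outputs as the interface.
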