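# immunome

Tools for surveying a proteome *in silico* for candidate innate-immune gene
families — the workflow used to compile putative immunomes for non-model
invertebrates such as the sea hare *Aplysia californica*, where most immune
genes have never been functionally characterized and must be recognized from
conserved protein domains and orthology instead.

The pipeline consumes the outputs of standard annotation tools (it never runs
them): InterProScan 5 tabular domain annotation, OrthoFinder
`Orthogroups.tsv` tables, BLAST outfmt-6 homology hits, protein FASTA and a
protein-to-gene map. On top of these it provides:

* **Rule-based domain screening.** Each gene family is defined by a
  declarative rule with a *strict* clause (diagnostic domains known from
  vertebrate orthologs) and a *relaxed* clause (family-level annotation
  tolerant of invertebrate divergence), optional alternate clauses, forbidden
  accessions and repeat requirements. A protein matches a family when some
  clause's required accession set is contained in its annotation (AND within a
  clause, OR across clauses); strict dominates relaxed. The shipped catalog
  (`inst/extdata/immune_rules.yaml`, 139 families from pattern-recognition
  receptors to complement factors) can be replaced by any user catalog.
* **Orthology vetting and rescue.** Domain-screened genes are vetted by
  whether they share an orthogroup with known reference immune genes, and
  genes invisible to domain screening (e.g. an IkB carrying only ankyrin
  repeats, or a TAB1 with only a generic phosphatase domain) are *rescued*
  when they co-occur with references. Tabular homology hits can add or confirm
  entries under e-value/bitscore thresholds.
* **Domain-architecture analytics.** Interval merging of fragmented member-
  database hits, architecture strings, extraction of named domain regions
  (e.g. TIR) from the longest isoform of each gene, declarative pattern flags
  (dual-TIR, ROC+COR, LRR C-terminal flank, ...), and cross-species
  presence/absence count matrices.
* **Distance phylogenetics of extracted domains.** Pairwise
  maximum-likelihood distances under the Jones–Taylor–Thornton amino-acid
  model with a proportion of invariable sites and k-category discrete-gamma
  rate heterogeneity (JTT+I+Γ); neighbor joining (Studier–Keppler Q
  criterion, exact on additive matrices); bootstrap branch supports; and
  group-vs-tree concordance reports. Trees are `ape::phylo` objects.
* **A synthetic-data generator** that writes complete bundles (annotation
  TSV, gene map, FASTA, orthogroups, reference catalog) with planted ground
  truth, so the whole pipeline is testable offline.

## The model behind the distances

For two aligned sequences the distance is the maximizer over `t` of the
pairwise log-likelihood

```
sum over sites  log[ p_inv * pi_x * 1(x = y)
                     + (1 - p_inv) * (1/k) * sum_r pi_x * P(t * r)_xy ]
```

where `P(tau) = exp(Q * tau)` with `Q` the reversible JTT generator normalized
to one expected substitution per site per unit time, and `r` runs over the `k`
equal-probability discrete-gamma category means (shape `alpha`). Defaults are
`k = 4`, `alpha = 1`, `p_inv = 0.2`, all configurable. Gapped or ambiguous
columns are excluded pairwise.

## Worked example

Generate a synthetic five-species study with 5 planted Toll-like receptors
and 3 scavenger-receptor (SRCR) genes among 50 background genes, then run the
full screen-vet pipeline:

```r
library(immunome)

cfg    <- sim_config(seed = 42, planted = c(TLR = 5, SRCR = 3), background = 50)
bundle <- generate_annotation_bundle(cfg, dir = tempfile())

ann  <- parse_interproscan_tsv(bundle$paths$interproscan)
map  <- load_gene_map(bundle$paths$gene_map, lengths = ann$proteins)
og   <- parse_orthogroups(bundle$paths$orthogroups)
refs <- read_reference_catalog(bundle$paths$references)

imm <- build_immunome(ann$hits, map, og, refs = refs, focal_species = "aplysia")
summary(imm)
#> Compiled immunome
#>   entries:             8
#>   distinct genes:      8
#>   families:            2
#>   strict matches:      8
#>   relaxed matches:     0
#>   orthology-supported: 8
#>   homology-rescued:    0
imm$counts
#>   family protein_count gene_count
#> 1   SRCR             3          3
#> 2    TLR             5          5
```

All eight planted genes — and nothing else — are recovered, each by a strict
clause and each supported by a shared orthogroup with its reference genes.
Orthogroup composition statistics come from the same table:

```r
overlap_stats(og, "aplysia")
#> Orthogroup overlap statistics
#>   total_orthogroups        52
#>   at_least_two_species     2  (3.8%)
#>   single_species           50  (96.2%)
#>   all_species              2  (3.8%)
#>   focal_unique             50  (96.2%)
```

(the two multi-species orthogroups are the planted TLR and SRCR families; the
50 background genes are focal-unique singletons). A bootstrapped
neighbor-joining tree of simulated domain sequences:

```r
model <- jtt_model(k = 4, alpha = 1, p_inv = 0.2)
set.seed(1); tr <- ape::unroot(ape::rtree(6)); tr$edge.length <- runif(9, .1, .4)
sim  <- evolve_sequences(tr, model, length = 300, seed = 1)
boot <- nj_bootstrap(sim$alignment, model, B = 25, seed = 1)
ape::write.tree(boot)
#> (t5:0.2219638902,(t6:0.2541675236,(t2:0.3505467414,t1:0.3709663732)100:0.147793565)100:0.3046229664,(t3:0.1969038558,t4:0.08633279182)100:0.1251280131);
```

Every internal branch of the generating topology is recovered with 100%
support. A thin command-line wrapper over the same functions lives at
`inst/scripts/immunome.R` (`screen`, `vet`, `tree`, `simulate` subcommands
driven by one YAML config).

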