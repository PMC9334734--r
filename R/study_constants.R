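#' Headline counts of the Aplysia californica immunome survey
#'
#' Integer summary counts reported for the AplCal3.0 reference proteome survey
#' that this pipeline re-implements: proteome and annotation totals, orthogroup
#' composition over the five surveyed species (human, fly, oyster, and the two
#' gastropods), and the compiled immunome totals. These are useful as worked
#' examples — e.g. the fraction of proteins with at least one annotation, or
#' the fraction of orthogroups spanning all species — and as targets when the
#' corresponding full-scale inputs are available locally.
#'
#' @return Named integer vector.
#' @export
aplysia_survey_counts <- function() {
  c(proteins_total = 26658L,
    proteins_annotated = 26209L,
    proteins_with_interpro = 22511L,
    orthogroups_total = 19353L,
    orthogroups_at_least_two_species = 12594L,
    orthogroups_all_species = 4606L,
    orthogroups_mollusk_human_not_fly = 1723L,
    orthogroups_mollusk_only = 1501L,
    orthogroups_gastropod_only = 1918L,
    orthogroups_aplysia_unique = 849L,
    immunome_proteins = 2241L,
    immunome_genes = 1669L)
}
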