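# Shared fixtures: hit-table constructors, tiny rule catalogs, random additive
# trees, and the independent brute-force rule evaluator used as an oracle.

make_hits <- function(protein_id, accs, starts = NULL, stops = NULL,
                      analysis = "Pfam") {
  n <- length(accs)
  if (n == 0L) {
    return(data.frame(protein_id = character(), analysis = character(),
                      signature_acc = character(), signature_desc = character(),
                      start = integer(), stop = integer(), score = numeric(),
                      interpro_acc = character(), interpro_desc = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(starts)) starts <- seq(1L, by = 100L, length.out = n)
  if (is.null(stops)) stops <- starts + 49L
  ipr <- ifelse(grepl("^IPR\\d{6}$", accs), accs, NA_character_)
  data.frame(protein_id = rep(protein_id, n), analysis = rep(analysis, n),
             signature_acc = ifelse(is.na(ipr), accs, paste0("SIG_", accs)),
             signature_desc = NA_character_, start = as.integer(starts),
             stop = as.integer(stops), score = 1e-5, interpro_acc = ipr,
             interpro_desc = NA_character_, stringsAsFactors = FALSE)
}

write_catalog_yaml <- function(families) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(families = families), path)
  path
}

# Rule catalog used by oracle-equivalence tests: 5 families over a 12-accession
# alphabet A01..A12, exercising strict/relaxed, alternates and forbidden sets.
oracle_catalog <- function() {
  fams <- list(
    list(family = "F1", category = "c", strict = list("A01", "A02"),
         relaxed = list("A01", "A03")),
    list(family = "F2", category = "c", strict = list("A04")),
    list(family = "F3", category = "c", strict = list("A05", "A06"),
         forbidden = list("A07")),
    list(family = "F4", category = "c", strict = list("A08", "A09", "A10"),
         alternate = list(list("A08", "A11")), relaxed = list("A08")),
    list(family = "F5", category = "c", strict = list("A12"),
         forbidden = list("A01", "A02")))
  load_rule_catalog(write_catalog_yaml(fams))
}

# Independent naive evaluator: enumerate clauses, plain set inclusion.
brute_force_match <- function(accessions, rule) {
  for (clause in rule$clauses) {
    ok <- TRUE
    for (a in clause$required) if (!(a %in% accessions)) ok <- FALSE
    for (a in clause$forbidden) if (a %in% accessions) ok <- FALSE
    if (ok) return(clause$label)
  }
  "none"
}

random_additive_tree <- function(ntaxa, min_bl = 0.1, max_bl = 1) {
  tr <- ape::unroot(ape::rtree(ntaxa))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# Compare branch lengths of two topologically identical unrooted trees by
# matching each edge to the bipartition (or pendant leaf) it induces.
edge_length_table <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    desc[[edges[e, 1]]] <- c(desc[[edges[e, 1]]], desc[[edges[e, 2]]])
  }
  keys <- character(nrow(tree$edge)); lens <- numeric(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    side <- desc[[tree$edge[e, 2]]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys[e] <- paste(sort(side), collapse = "|")
    lens[e] <- tree$edge.length[e]
  }
  stats::setNames(lens, keys)
}

max_branch_error <- function(t1, t2) {
  e1 <- edge_length_table(t1); e2 <- edge_length_table(t2)
  shared <- intersect(names(e1), names(e2))
  # the root trifurcation can split one edge across representations; compare
  # only bipartition-matched edges (all of them when topologies agree)
  max(abs(e1[shared] - e2[shared]))
}
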