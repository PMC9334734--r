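#' Load a family rule catalog
#'
#' A catalog is a YAML list of gene families, each with a category, a `strict`
#' required-accession list, optionally a `relaxed` list, optional `alternate`
#' lists (each an alternative conjunction), an optional `forbidden` list
#' applied to every clause, an optional `min_distinct_hits` repeat requirement,
#' and optional per-species `reference_genes` used for orthology vetting.
#' Clause semantics are AND within a clause and OR across clauses, evaluated in
#' order strict, alternate(s), relaxed.
#'
#' @param path Path to the YAML catalog; the default is the catalog shipped
#'   with the package, which mirrors the published strict/relaxed
#'   required-domain tables for each immune family.
#' @return Object of class `rule_catalog`: a named list of family rules.
#' @export
load_rule_catalog <- function(path = default_catalog_path()) {
  doc <- yaml::read_yaml(path)
  fams <- doc$families
  if (is.null(fams)) fams <- list()
  rules <- list()
  for (f in fams) {
    known <- c("family", "category", "strict", "relaxed", "alternate",
               "forbidden", "min_distinct_hits", "reference_genes")
    extra <- setdiff(names(f), known)
    if (length(extra)) {
      stop("family '", f$family, "': unknown field(s) ", paste(extra, collapse = ", "))
    }
    if (is.null(f$family) || !nzchar(f$family)) stop("catalog entry without a family name")
    if (f$family %in% names(rules)) stop("duplicate family '", f$family, "'")
    forbidden <- as.character(unlist(f$forbidden))
    mdh <- if (is.null(f$min_distinct_hits)) 1L else as.integer(f$min_distinct_hits)
    clauses <- list()
    add_clause <- function(label, required) {
      required <- as.character(unlist(required))
      if (!length(required)) stop("family '", f$family, "': empty required set in ",
                                  label, " clause")
      if (length(intersect(required, forbidden))) {
        stop("family '", f$family, "': required and forbidden sets overlap")
      }
      clauses[[length(clauses) + 1L]] <<- list(
        label = label, required = required, forbidden = forbidden,
        min_distinct_hits = mdh)
    }
    if (!is.null(f$strict)) add_clause("strict", f$strict)
    if (!is.null(f$alternate)) {
      alts <- f$alternate
      if (!is.list(alts[[1L]])) alts <- list(alts)  # single alternate clause
      for (a in alts) add_clause("alternate", a)
    }
    if (!is.null(f$relaxed)) add_clause("relaxed", f$relaxed)
    if (!length(clauses)) stop("family '", f$family, "': no clauses")
    rules[[f$family]] <- list(
      family = f$family,
      category = if (is.null(f$category)) NA_character_ else f$category,
      clauses = clauses,
      reference_genes = lapply(f$reference_genes, function(x) as.character(unlist(x))))
  }
  structure(rules, class = "rule_catalog")
}

#' @rdname load_rule_catalog
#' @export
default_catalog_path <- function() {
  system.file("extdata", "immune_rules.yaml", package = "immunome", mustWork = TRUE)
}

#' @export
print.rule_catalog <- function(x, ...) {
  cat("Rule catalog:", length(x), "families,",
      sum(vapply(x, function(r) length(r$clauses), 0L)), "clauses\n")
  invisible(x)
}

## All accessions a protein's hits expose: member-database signature accessions,
## InterPro accessions, and PANTHER family prefixes of subfamily ids.
protein_accessions <- function(hits) {
  acc <- c(hits$signature_acc, hits$interpro_acc)
  sf <- grep("^PTHR\\d+:SF\\d+$", hits$signature_acc, value = TRUE)
  acc <- c(acc, sub(":SF\\d+$", "", sf))
  unique(acc[!is.na(acc)])
}

## Rows of `hits` carrying the accession in either namespace (or by PANTHER
## family prefix).
hits_with_accession <- function(hits, accession) {
  sel <- hits$signature_acc == accession |
    (!is.na(hits$interpro_acc) & hits$interpro_acc == accession)
  if (grepl("^PTHR\\d+$", accession)) {
    sel <- sel | grepl(paste0("^", accession, ":SF\\d+$"), hits$signature_acc)
  }
  hits[sel, , drop = FALSE]
}

## Number of merged (overlapping/book-ended union) intervals among hits
## carrying one accession.
merged_interval_count <- function(hits) {
  if (!nrow(hits)) return(0L)
  o <- order(hits$start, hits$stop)
  s <- hits$start[o]; e <- hits$stop[o]
  n <- 1L; cur_end <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_end + 1L) { n <- n + 1L; cur_end <- e[i] }
    else cur_end <- max(cur_end, e[i])
  }
  n
}

#' Match one protein's domain hits against a family rule
#'
#' A clause matches when every required accession is present among the
#' protein's hits (in either the member-database or InterPro namespace), no
#' forbidden accession is present, and — for repeat requirements — some
#' required accession covers at least `min_distinct_hits` distinct merged hit
#' intervals. Clauses are evaluated in catalog order and the first satisfied
#' clause is reported, so a strict match dominates a relaxed one.
#'
#' @param hits Data frame of domain hits for a single protein.
#' @param rule One element of a `rule_catalog`.
#' @return List with `protein_id`, `family`, `matched`, `matched_clause_label`
#'   (`"none"` when unmatched) and `satisfied_accessions`.
#' @export
match_protein <- function(hits, rule) {
  pid <- if (nrow(hits)) unique(hits$protein_id) else NA_character_
  if (length(pid) > 1L) stop("hits must belong to a single protein")
  acc <- protein_accessions(hits)
  for (clause in rule$clauses) {
    if (!all(clause$required %in% acc)) next
    if (length(clause$forbidden) && any(clause$forbidden %in% acc)) next
    if (clause$min_distinct_hits > 1L) {
      counts <- vapply(clause$required, function(a) {
        merged_interval_count(hits_with_accession(hits, a))
      }, 0L)
      if (max(counts) < clause$min_distinct_hits) next
    }
    return(list(protein_id = pid, family = rule$family, matched = TRUE,
                matched_clause_label = clause$label,
                satisfied_accessions = intersect(acc, clause$required)))
  }
  list(protein_id = pid, family = rule$family, matched = FALSE,
       matched_clause_label = "none", satisfied_accessions = character())
}

#' Screen a whole annotated proteome against a rule catalog
#'
#' Families are not mutually exclusive: a protein may match several. Output
#' rows are deterministically ordered by (family, protein id).
#'
#' @param hits Data frame of domain hits for any number of proteins.
#' @param catalog A `rule_catalog`.
#' @return Data frame with `family`, `protein_id`, `clause` (matched clause
#'   label), one row per (family, protein) match.
#' @export
screen_proteome <- function(hits, catalog) {
  out <- data.frame(family = character(), protein_id = character(),
                    clause = character(), stringsAsFactors = FALSE)
  if (!length(catalog) || !nrow(hits)) return(out)
  by_prot <- split(hits, hits$protein_id)
  rows <- list()
  for (pid in names(by_prot)) {
    ph <- by_prot[[pid]]
    for (rule in catalog) {
      m <- match_protein(ph, rule)
      if (m$matched) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = m$family, protein_id = pid, clause = m$matched_clause_label,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out <- out[order(out$family, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse protein-level matches to gene-level counts
#'
#' A gene matches a family when at least one isoform matches; the strongest
#' isoform clause label (strict over alternate over relaxed) is propagated to
#' the gene.
#'
#' @param results Data frame from [screen_proteome()].
#' @param map A [gene_map()].
#' @return List of class `count_table` with `counts` (family, protein_count,
#'   gene_count), `genes` (family, gene_id, clause, protein_ids), and
#'   `unmapped` (protein ids absent from the map, reported separately).
#' @export
collapse_to_genes <- function(results, map) {
  gene <- genes_of(map, results$protein_id)
  unmapped <- sort(unique(results$protein_id[is.na(gene)]))
  res <- results[!is.na(gene), , drop = FALSE]
  gene <- gene[!is.na(gene)]
  strength <- c(strict = 1L, alternate = 2L, relaxed = 3L)
  genes <- list()
  counts <- list()
  for (fam in sort(unique(res$family))) {
    sel <- res$family == fam
    fam_gene <- gene[sel]
    fam_clause <- res$clause[sel]
    fam_prot <- res$protein_id[sel]
    best <- tapply(strength[fam_clause], fam_gene, min)
    prots <- tapply(fam_prot, fam_gene, function(p) paste(sort(unique(p)), collapse = ","))
    gids <- sort(names(best))
    genes[[fam]] <- data.frame(
      family = fam, gene_id = gids,
      clause = names(strength)[best[gids]],
      protein_ids = unname(prots[gids]), stringsAsFactors = FALSE)
    counts[[fam]] <- data.frame(
      family = fam, protein_count = length(unique(fam_prot)),
      gene_count = length(gids), stringsAsFactors = FALSE)
  }
  structure(list(
    counts = if (length(counts)) do.call(rbind, c(counts, make.row.names = FALSE)) else
      data.frame(family = character(), protein_count = integer(),
                 gene_count = integer(), stringsAsFactors = FALSE),
    genes = if (length(genes)) do.call(rbind, c(genes, make.row.names = FALSE)) else
      data.frame(family = character(), gene_id = character(), clause = character(),
                 protein_ids = character(), stringsAsFactors = FALSE),
    unmapped = unmapped), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Gene counts by family (", nrow(x$counts), " families):\n", sep = "")
  print(x$counts, row.names = FALSE)
  if (length(x$unmapped)) {
    cat("Unmapped proteins:", length(x$unmapped), "\n")
  }
  invisible(x)
}
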