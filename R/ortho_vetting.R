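#' Read a reference-gene catalog
#'
#' YAML mapping family -> species -> reference gene/protein ids of known
#' immune genes, used for orthogroup vetting and rescue.
#'
#' @param path YAML path.
#' @return Named list family -> named list species -> character vector.
#' @export
read_reference_catalog <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(sp) lapply(sp, function(x) unique(as.character(unlist(x)))))
}

## Orthogroup id for each queried gene/protein id (NA when absent).
orthogroup_of <- function(og, ids) {
  og$orthogroup_id[match(ids, og$gene_id)]
}

#' Vet domain-screened gene families against orthogroup membership
#'
#' Each domain-matched gene is annotated with whether any of its isoform ids
#' (or its gene id) shares an orthogroup with a same-family reference gene.
#' Reference genes absent from the orthogroup table trigger a warning and count
#' as no evidence.
#'
#' @param genes Data frame of gene-level screen results (`family`, `gene_id`,
#'   `clause`, `protein_ids`), as in `collapse_to_genes()$genes`.
#' @param map A [gene_map()].
#' @param og An `orthogroups` table.
#' @param refs Reference catalog (family -> species -> ids); may be empty.
#' @param catalog Optional `rule_catalog` supplying family categories.
#' @return Data frame of immunome entries: `gene_id`, `family`, `category`,
#'   `clause`, `orthogroup_id`, `orthology_supported`, `homology_rescued`.
#' @export
vet_families <- function(genes, map, og, refs = list(), catalog = NULL) {
  ref_species <- unique(unlist(lapply(refs, names)))
  unknown <- setdiff(ref_species, attr(og, "species"))
  if (length(unknown)) {
    stop("reference catalog names unknown species: ", paste(unknown, collapse = ", "))
  }
  categories <- if (is.null(catalog)) NULL else
    vapply(catalog, function(r) r$category, "")
  ## resolve reference orthogroups once per family (warns once per family)
  ref_ogs_by_family <- lapply(
    stats::setNames(nm = unique(genes$family)),
    function(fam) family_reference_orthogroups(og, refs, fam))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    fam <- genes$family[i]; gid <- genes$gene_id[i]
    ids <- c(gid, attr(map, "isoforms")[[gid]])
    ogs <- unique(stats::na.omit(orthogroup_of(og, ids)))
    ref_ogs <- ref_ogs_by_family[[fam]]
    shared <- intersect(ogs, ref_ogs)
    data.frame(
      gene_id = gid, family = fam,
      category = if (!is.null(categories) && fam %in% names(categories))
        categories[[fam]] else NA_character_,
      clause = genes$clause[i],
      orthogroup_id = if (length(ogs)) ogs[1] else NA_character_,
      orthology_supported = length(shared) > 0L,
      homology_rescued = FALSE, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), family = character(), category = character(),
               clause = character(), orthogroup_id = character(),
               orthology_supported = logical(), homology_rescued = logical(),
               stringsAsFactors = FALSE)
  out[order(out$family, out$gene_id), , drop = FALSE]
}

## Orthogroups containing at least one reference id of a family (warns once per
## reference id missing from the table).
family_reference_orthogroups <- function(og, refs, family) {
  fam_refs <- unlist(refs[[family]], use.names = FALSE)
  if (!length(fam_refs)) return(character())
  hit <- orthogroup_of(og, fam_refs)
  if (anyNA(hit)) {
    warning("reference gene(s) absent from orthogroup table for family '", family,
            "': ", paste(fam_refs[is.na(hit)], collapse = ", "))
  }
  unique(stats::na.omit(hit))
}

#' Rescue genes by orthology alone
#'
#' Focal-species genes that share an orthogroup with a family's reference genes
#' but were not recovered by the domain screen.
#'
#' @param family Family name.
#' @param refs Reference catalog.
#' @param og An `orthogroups` table.
#' @param already_matched Character vector of gene ids found by the domain screen.
#' @param focal_species Name of the focal species column; when `NULL`, ids from
#'   all species are eligible.
#' @param map Optional [gene_map()] used to collapse rescued protein ids to
#'   gene ids.
#' @return Character vector of rescued gene ids (disjoint from
#'   `already_matched` by construction).
#' @export
orthology_rescue <- function(family, refs, og, already_matched = character(),
                             focal_species = NULL, map = NULL) {
  ref_ogs <- family_reference_orthogroups(og, refs, family)
  if (!length(ref_ogs)) return(character())
  sel <- og$orthogroup_id %in% ref_ogs
  if (!is.null(focal_species)) sel <- sel & og$species == focal_species
  ids <- unique(og$gene_id[sel])
  fam_refs <- unlist(refs[[family]], use.names = FALSE)
  ids <- setdiff(ids, fam_refs)
  if (!is.null(map)) {
    mapped <- genes_of(map, ids)
    ids <- unique(ifelse(is.na(mapped), ids, mapped))
  }
  sort(setdiff(ids, already_matched))
}

#' Attach homology evidence from tabular hits
#'
#' Candidate genes whose best hit passes the thresholds gain homology evidence;
#' genes recovered only by homology are appended as new entries of the family
#' with clause `"none"`.
#'
#' @param entries Immunome entry data frame, see [vet_families()].
#' @param hits Data frame from [parse_homology_hits()].
#' @param family Family the hit list provides evidence for.
#' @param map A [gene_map()] resolving query protein ids to genes.
#' @param max_evalue Maximum e-value for an acceptable best hit (default 1e-5).
#' @param min_bitscore Minimum bitscore (default 0, i.e. no floor).
#' @param add_missing Append homology-only genes (default TRUE).
#' @param category Category label for appended entries.
#' @return Updated entry data frame.
#' @export
attach_homology_evidence <- function(entries, hits, family, map,
                                     max_evalue = 1e-5, min_bitscore = 0,
                                     add_missing = TRUE, category = NA_character_) {
  if (!nrow(hits)) return(entries)
  ## best hit per query: smallest evalue, ties by largest bitscore
  o <- order(hits$query_id, hits$evalue, -hits$bitscore)
  best <- hits[o, , drop = FALSE]
  best <- best[!duplicated(best$query_id), , drop = FALSE]
  pass <- best[best$evalue <= max_evalue & best$bitscore >= min_bitscore, , drop = FALSE]
  if (!nrow(pass)) return(entries)
  genes <- genes_of(map, pass$query_id)
  genes <- unique(ifelse(is.na(genes), pass$query_id, genes))
  in_fam <- entries$family == family & entries$gene_id %in% genes
  entries$homology_rescued[in_fam] <- TRUE
  if (add_missing) {
    new <- setdiff(genes, entries$gene_id[entries$family == family])
    if (length(new)) {
      entries <- rbind(entries, data.frame(
        gene_id = new, family = family, category = category, clause = "none",
        orthogroup_id = NA_character_, orthology_supported = FALSE,
        homology_rescued = TRUE, stringsAsFactors = FALSE))
    }
  }
  entries[order(entries$family, entries$gene_id), , drop = FALSE]
}

#' Compile an immunome: screen, collapse, vet, rescue
#'
#' End-to-end driver: protein-level domain screen, gene collapsing, orthogroup
#' vetting against reference genes, orthology rescue of genes missed by the
#' domain screen, and (optionally) homology evidence. Entries with no evidence
#' at all are excluded and reported in the reject slot.
#'
#' @param hits Domain hit data frame (see [parse_interproscan_tsv()]).
#' @param map A [gene_map()].
#' @param og An `orthogroups` table, or `NULL` to skip vetting.
#' @param catalog A `rule_catalog` (default: shipped catalog).
#' @param refs Reference catalog for vetting/rescue.
#' @param focal_species Focal species name for rescue.
#' @return Object of class `immunome`: list with `entries`, `counts`,
#'   `screen`, `rejects`, `unmapped`.
#' @export
build_immunome <- function(hits, map, og = NULL, catalog = load_rule_catalog(),
                           refs = list(), focal_species = NULL) {
  screen <- screen_proteome(hits, catalog)
  collapsed <- collapse_to_genes(screen, map)
  if (is.null(og)) {
    entries <- collapsed$genes
    entries$category <- vapply(entries$family, function(f) {
      if (f %in% names(catalog)) catalog[[f]]$category else NA_character_
    }, "")
    entries <- data.frame(
      gene_id = entries$gene_id, family = entries$family,
      category = entries$category, clause = entries$clause,
      orthogroup_id = NA_character_, orthology_supported = FALSE,
      homology_rescued = FALSE, stringsAsFactors = FALSE)
  } else {
    entries <- vet_families(collapsed$genes, map, og, refs, catalog)
    for (fam in names(refs)) {
      matched <- entries$gene_id[entries$family == fam]
      rescued <- orthology_rescue(fam, refs, og, matched, focal_species, map)
      if (length(rescued)) {
        entries <- rbind(entries, data.frame(
          gene_id = rescued, family = fam,
          category = if (fam %in% names(catalog)) catalog[[fam]]$category else NA_character_,
          clause = "none", orthogroup_id = orthogroup_of(og, rescued),
          orthology_supported = TRUE, homology_rescued = TRUE,
          stringsAsFactors = FALSE))
      }
    }
  }
  keep <- entries$clause != "none" | entries$orthology_supported | entries$homology_rescued
  rejects <- entries[!keep, , drop = FALSE]
  entries <- entries[keep, , drop = FALSE]
  entries <- entries[order(entries$family, entries$gene_id), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, counts = collapsed$counts, screen = screen,
                 rejects = rejects, unmapped = collapsed$unmapped),
            class = "immunome")
}

#' @export
print.immunome <- function(x, ...) {
  cat("Compiled immunome:", nrow(x$entries), "gene-family entries,",
      length(unique(x$entries$gene_id)), "genes,",
      length(unique(x$entries$family)), "families\n")
  invisible(x)
}

#' @export
summary.immunome <- function(object, ...) {
  e <- object$entries
  cat("Compiled immunome\n")
  cat("  entries:            ", nrow(e), "\n")
  cat("  distinct genes:     ", length(unique(e$gene_id)), "\n")
  cat("  families:           ", length(unique(e$family)), "\n")
  cat("  strict matches:     ", sum(e$clause == "strict"), "\n")
  cat("  relaxed matches:    ", sum(e$clause == "relaxed"), "\n")
  cat("  orthology-supported:", sum(e$orthology_supported), "\n")
  cat("  homology-rescued:   ", sum(e$homology_rescued), "\n")
  if (length(object$unmapped)) cat("  unmapped proteins:  ", length(object$unmapped), "\n")
  invisible(object)
}

#' Orthogroup overlap statistics
#'
#' Counts orthogroups by species composition: the total, those spanning at
#' least two species, those spanning all species, those unique to the focal
#' species, and any named subsets. A named subset is a list with optional
#' elements `equals` (the non-empty species set must equal this set), `all_of`
#' (every listed species present), `any_of` (at least one present) and
#' `none_of` (none present).
#'
#' @param og An `orthogroups` table.
#' @param focal_species Focal species name.
#' @param named_subsets Named list of subset definitions (see above).
#' @return Object of class `overlap_stats` (a list of counts).
#' @export
overlap_stats <- function(og, focal_species, named_subsets = list()) {
  species <- attr(og, "species")
  if (!focal_species %in% species) stop("unknown focal species '", focal_species, "'")
  for (nm in names(named_subsets)) {
    used <- unlist(named_subsets[[nm]], use.names = FALSE)
    if (length(setdiff(used, species))) {
      stop("subset '", nm, "' references unknown species: ",
           paste(setdiff(used, species), collapse = ", "))
    }
  }
  ids <- attr(og, "orthogroup_ids")
  comp <- lapply(split(og$species, og$orthogroup_id), unique)
  comp <- comp[ids[ids %in% names(comp)]]
  nsp <- lengths(comp)
  counts <- list(
    total_orthogroups = length(ids),
    at_least_two_species = sum(nsp >= 2),
    single_species = sum(nsp <= 1) + sum(!ids %in% names(comp)),
    all_species = sum(nsp == length(species)),
    focal_unique = sum(vapply(comp, function(s) identical(s, focal_species), TRUE)))
  for (nm in names(named_subsets)) {
    def <- named_subsets[[nm]]
    counts[[nm]] <- sum(vapply(comp, function(s) {
      if (!is.null(def$equals) && !setequal(s, def$equals)) return(FALSE)
      if (!is.null(def$all_of) && !all(def$all_of %in% s)) return(FALSE)
      if (!is.null(def$any_of) && !any(def$any_of %in% s)) return(FALSE)
      if (!is.null(def$none_of) && any(def$none_of %in% s)) return(FALSE)
      TRUE
    }, TRUE))
  }
  structure(counts, class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat("Orthogroup overlap statistics\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %d", nm, x[[nm]]))
    if (nm != "total_orthogroups" && x$total_orthogroups > 0) {
      cat(sprintf("  (%.1f%%)", 100 * x[[nm]] / x$total_orthogroups))
    }
    cat("\n")
  }
  invisible(x)
}
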