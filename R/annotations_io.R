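#' Parse InterProScan 5 tabular output
#'
#' Reads the 11-15 column tab-separated layout produced by InterProScan 5
#' (protein accession, MD5, length, analysis, signature accession, signature
#' description, start, stop, score, status, date, then optional InterPro
#' accession/description, GO terms and pathways). Gzip-compressed files are
#' accepted. Extra trailing columns beyond the 15 standard ones are ignored
#' with a warning.
#'
#' @param path Path to the TSV file.
#' @return List with `hits` (data frame: one row per signature match, columns
#'   `protein_id`, `analysis`, `signature_acc`, `signature_desc`, `start`,
#'   `stop`, `score`, `interpro_acc`, `interpro_desc`) and `proteins`
#'   (data frame: `protein_id`, `length`).
#' @export
parse_interproscan_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list(hits = empty_hits(), proteins = empty_proteins()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 11L)) {
    stop("line ", which(ncols < 11L)[1], ": expected at least 11 tab-separated columns")
  }
  if (any(ncols > 15L)) {
    warning("ignoring columns beyond 15 on ", sum(ncols > 15L), " line(s)")
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- parse_int_col(get(7L), path = "start")
  stop_ <- parse_int_col(get(8L), path = "stop")
  bad <- which(start > stop_)
  if (length(bad)) stop("line ", bad[1], ": start > stop")
  if (any(start < 1L)) stop("line ", which(start < 1L)[1], ": start < 1")
  score <- suppressWarnings(as.numeric(get(9L)))  # "-" -> NA (absent)
  ipr <- dash_na(get(12L))
  ok_ipr <- is.na(ipr) | grepl("^IPR\\d{6}$", ipr)
  if (!all(ok_ipr)) {
    stop("line ", which(!ok_ipr)[1], ": malformed InterPro accession '",
         ipr[which(!ok_ipr)[1]], "'")
  }
  sig <- get(5L)
  if (any(!nzchar(sig) | is.na(sig))) {
    stop("line ", which(!nzchar(sig) | is.na(sig))[1], ": empty signature accession")
  }
  hits <- data.frame(
    protein_id = get(1L), analysis = get(4L), signature_acc = sig,
    signature_desc = dash_na(get(6L)), start = start, stop = stop_,
    score = score, interpro_acc = ipr, interpro_desc = dash_na(get(13L)),
    stringsAsFactors = FALSE)
  len <- parse_int_col(get(3L), path = "length")
  per_prot <- tapply(len, hits$protein_id, unique, simplify = FALSE)
  n_len <- lengths(per_prot)
  if (any(n_len > 1L)) {
    stop("conflicting lengths for protein '", names(per_prot)[n_len > 1L][1], "'")
  }
  proteins <- data.frame(protein_id = names(per_prot),
                         length = unlist(per_prot, use.names = FALSE),
                         stringsAsFactors = FALSE)
  rownames(proteins) <- NULL
  list(hits = hits, proteins = proteins[order(proteins$protein_id), , drop = FALSE])
}

parse_int_col <- function(x, path) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) | out != suppressWarnings(as.numeric(x)))
  if (length(bad)) stop("line ", bad[1], ": non-integer ", path, " '", x[bad[1]], "'")
  out
}

dash_na <- function(x) {
  x[!is.na(x) & (x == "-" | !nzchar(x))] <- NA_character_
  x
}

empty_hits <- function() {
  data.frame(protein_id = character(), analysis = character(),
             signature_acc = character(), signature_desc = character(),
             start = integer(), stop = integer(), score = numeric(),
             interpro_acc = character(), interpro_desc = character(),
             stringsAsFactors = FALSE)
}

empty_proteins <- function() {
  data.frame(protein_id = character(), length = integer(), stringsAsFactors = FALSE)
}

#' Write domain hits in InterProScan 5 tabular layout
#'
#' Inverse of [parse_interproscan_tsv()]; used by the synthetic-data generator
#' and for round-trip testing.
#'
#' @param hits Data frame as returned in `$hits`.
#' @param proteins Data frame (`protein_id`, `length`) supplying the length column.
#' @param path Output path.
#' @export
write_interproscan_tsv <- function(hits, proteins, path) {
  len <- proteins$length[match(hits$protein_id, proteins$protein_id)]
  if (anyNA(len)) stop("every hit protein needs a length in `proteins`")
  dash <- function(x) ifelse(is.na(x), "-", as.character(x))
  rows <- paste(hits$protein_id, "md5", len, hits$analysis, hits$signature_acc,
                dash(hits$signature_desc), hits$start, hits$stop,
                dash(hits$score), "T", "01-01-2020",
                dash(hits$interpro_acc), dash(hits$interpro_desc), sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Parse an OrthoFinder-style orthogroup table
#'
#' First row is a header (`Orthogroup` then one column per species); cells are
#' comma+space separated gene/protein identifiers, empty cells meaning no genes
#' for that species.
#'
#' @param path Path to `Orthogroups.tsv` (optionally gzipped).
#' @return An object of class `orthogroups`: a long data frame
#'   (`orthogroup_id`, `species`, `gene_id`) with the ordered species vector as
#'   attribute `species` and all orthogroup ids (including all-focal ones) as
#'   attribute `orthogroup_ids`.
#' @export
parse_orthogroups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty orthogroup table")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  species <- header[-1L]
  nsp <- length(species)
  rows <- fields[-1L]
  ## Raggedness is judged on tab counts (strsplit drops trailing empty fields).
  ntabs <- vapply(gregexpr("\t", lines, fixed = TRUE), function(m) {
    sum(m > 0)
  }, 0L)[-1L]
  if (any(ntabs != nsp)) {
    stop("line ", which(ntabs != nsp)[1] + 1L, ": ragged row (", ntabs[ntabs != nsp][1],
         " tabs, expected ", nsp, ")")
  }
  nc <- lengths(rows)
  ids <- vapply(rows, `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate orthogroup id '", ids[duplicated(ids)][1], "'")
  }
  long <- list()
  for (r in seq_along(rows)) {
    cells <- c(rows[[r]][-1L], rep("", nsp - (nc[r] - 1L)))
    for (s in seq_len(nsp)) {
      genes <- trimws(strsplit(cells[s], ",", fixed = TRUE)[[1L]])
      genes <- genes[nzchar(genes)]
      if (length(genes)) {
        long[[length(long) + 1L]] <- data.frame(
          orthogroup_id = ids[r], species = species[s], gene_id = genes,
          stringsAsFactors = FALSE)
      }
    }
  }
  long <- if (length(long)) do.call(rbind, long) else
    data.frame(orthogroup_id = character(), species = character(),
               gene_id = character(), stringsAsFactors = FALSE)
  og_by_gene <- unique(long[, c("orthogroup_id", "gene_id")])
  if (anyDuplicated(og_by_gene$gene_id)) {
    stop("gene '", og_by_gene$gene_id[duplicated(og_by_gene$gene_id)][1],
         "' appears in two orthogroups")
  }
  structure(long, species = species, orthogroup_ids = ids, class = c("orthogroups", "data.frame"))
}

#' Write an orthogroup table
#'
#' @param og An `orthogroups` object.
#' @param path Output path.
#' @export
write_orthogroups <- function(og, path) {
  species <- attr(og, "species")
  ids <- attr(og, "orthogroup_ids")
  lines <- paste(c("Orthogroup", species), collapse = "\t")
  for (id in ids) {
    cells <- vapply(species, function(s) {
      paste(og$gene_id[og$orthogroup_id == id & og$species == s], collapse = ", ")
    }, "")
    lines <- c(lines, paste(c(id, cells), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein FASTA
#'
#' Sequences are upper-cased, terminal `*` stop symbols stripped, and lengths
#' recomputed. Identifiers are the first whitespace token of each header.
#'
#' @param path FASTA path (optionally gzipped).
#' @return Data frame with `protein_id`, `length`, `sequence`.
#' @export
parse_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate FASTA id '", ids[duplicated(ids)][1], "'")
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", sub("^\\*+", "", seqs))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for '", ids[!nzchar(seqs)][1], "'")
  }
  data.frame(protein_id = ids, length = nchar(seqs), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$protein_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Load a protein-to-gene map
#'
#' Two-column TSV (`protein_id`, `gene_id`, no header). Isoforms of each gene
#' are ordered by descending length when lengths are supplied, otherwise
#' lexicographically.
#'
#' @param path TSV path (optionally gzipped).
#' @param lengths Optional data frame (`protein_id`, `length`) used to order
#'   isoforms.
#' @return Object of class `gene_map`: data frame (`protein_id`, `gene_id`)
#'   with a per-gene ordered isoform list as attribute `isoforms`.
#' @export
load_gene_map <- function(path, lengths = NULL) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("protein_id", "gene_id"),
                          colClasses = "character")
  gene_map(df, lengths)
}

#' @rdname load_gene_map
#' @param df Data frame with `protein_id` and `gene_id` columns.
#' @export
gene_map <- function(df, lengths = NULL) {
  df <- df[, c("protein_id", "gene_id")]
  dup <- unique(df$protein_id[duplicated(df)])
  df <- unique(df)
  if (anyDuplicated(df$protein_id)) {
    stop("protein '", df$protein_id[duplicated(df$protein_id)][1],
         "' is mapped to two genes")
  }
  ord_len <- rep(NA_real_, nrow(df))
  if (!is.null(lengths)) {
    ord_len <- lengths$length[match(df$protein_id, lengths$protein_id)]
  }
  o <- if (all(!is.na(ord_len))) order(df$gene_id, -ord_len, df$protein_id) else
    order(df$gene_id, df$protein_id)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  iso <- split(df$protein_id, df$gene_id)
  structure(df, isoforms = iso, class = c("gene_map", "data.frame"))
}

#' Map protein ids to gene ids
#'
#' @param map A `gene_map`.
#' @param protein_ids Character vector of protein ids.
#' @return Character vector of gene ids; unmapped proteins yield `NA` (never a
#'   silent drop).
#' @export
genes_of <- function(map, protein_ids) {
  map$gene_id[match(protein_ids, map$protein_id)]
}

#' Parse tabular homology hits (BLAST outfmt 6 style)
#'
#' Twelve-column tab-separated: query, subject, percent identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path Path to the hit table (optionally gzipped).
#' @return Data frame with `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `evalue`, `bitscore`.
#' @export
parse_homology_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), alignment_length = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12L)) {
    stop("line ", which(lengths(fields) < 12L)[1], ": expected 12 columns")
  }
  get <- function(i) vapply(fields, `[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v)) stop("line ", which(is.na(v))[1], ": non-numeric ", what)
    v
  }
  pid <- num(3L, "percent identity")
  if (any(pid < 0 | pid > 100)) stop("percent identity outside [0, 100]")
  ev <- num(11L, "evalue")
  if (any(ev < 0)) stop("negative evalue")
  data.frame(query_id = get(1L), subject_id = get(2L), percent_identity = pid,
             alignment_length = as.integer(num(4L, "alignment length")),
             evalue = ev, bitscore = num(12L, "bitscore"),
             stringsAsFactors = FALSE)
}
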