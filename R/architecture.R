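#' Load a canonical domain label map
#'
#' Maps signature/InterPro accessions to canonical architecture labels (TIR,
#' LRR, ROC, COR, CT, SP, TM, ...). The shipped default collapses the leucine-
#' rich repeat subtypes to a single LRR label and keeps the cysteine-rich
#' C-terminal flank (CT) separate.
#'
#' @param path YAML file with a top-level `labels:` mapping label -> accessions.
#' @return Named character vector accession -> label.
#' @export
load_label_map <- function(path = system.file("extdata", "domain_labels.yaml",
                                              package = "immunome", mustWork = TRUE)) {
  doc <- yaml::read_yaml(path)$labels
  accs <- unlist(doc, use.names = FALSE)
  labs <- rep(names(doc), lengths(doc))
  stats::setNames(labs, accs)
}

#' Merge a protein's domain hits into labelled intervals
#'
#' Hits are mapped to canonical labels; overlapping or book-ended (stop + 1 =
#' start) intervals with the same label are unioned. Hits whose accessions are
#' not covered by the label map are ignored. Merging is idempotent and
#' order-invariant.
#'
#' @param hits Data frame of domain hits (any number of proteins).
#' @param label_map Named character vector accession -> label, see
#'   [load_label_map()].
#' @return Data frame `protein_id`, `label`, `start`, `stop`, `accessions`
#'   (comma-collapsed source accessions), sorted by (protein, start).
#' @export
merge_intervals <- function(hits, label_map = load_label_map()) {
  lab <- label_map[hits$signature_acc]
  ipr_lab <- label_map[ifelse(is.na(hits$interpro_acc), "", hits$interpro_acc)]
  lab[is.na(lab)] <- ipr_lab[is.na(lab)]
  keep <- !is.na(lab)
  hits <- hits[keep, , drop = FALSE]
  lab <- lab[keep]
  out <- list()
  if (nrow(hits)) {
    key <- paste(hits$protein_id, lab, sep = "\r")
    for (k in unique(key)) {
      sub <- hits[key == k, , drop = FALSE]
      o <- order(sub$start, sub$stop)
      s <- sub$start[o]; e <- sub$stop[o]
      acc <- ifelse(is.na(sub$interpro_acc[o]), sub$signature_acc[o],
                    paste0(sub$signature_acc[o], ",", sub$interpro_acc[o]))
      cur_s <- s[1]; cur_e <- e[1]; cur_a <- acc[1]
      for (i in seq_along(s)[-1]) {
        if (s[i] > cur_e + 1L) {
          out[[length(out) + 1L]] <- list(k, cur_s, cur_e, cur_a)
          cur_s <- s[i]; cur_e <- e[i]; cur_a <- acc[i]
        } else {
          cur_e <- max(cur_e, e[i]); cur_a <- paste(cur_a, acc[i], sep = ",")
        }
      }
      out[[length(out) + 1L]] <- list(k, cur_s, cur_e, cur_a)
    }
  }
  if (!length(out)) {
    return(data.frame(protein_id = character(), label = character(),
                      start = integer(), stop = integer(), accessions = character(),
                      stringsAsFactors = FALSE))
  }
  key <- vapply(out, `[[`, "", 1L)
  parts <- strsplit(key, "\r", fixed = TRUE)
  df <- data.frame(
    protein_id = vapply(parts, `[`, "", 1L),
    label = vapply(parts, `[`, "", 2L),
    start = vapply(out, function(x) as.integer(x[[2L]]), 0L),
    stop = vapply(out, function(x) as.integer(x[[3L]]), 0L),
    accessions = vapply(out, function(x) {
      paste(sort(unique(strsplit(x[[4L]], ",", fixed = TRUE)[[1L]])), collapse = ",")
    }, ""), stringsAsFactors = FALSE)
  df <- df[order(df$protein_id, df$start, -df$stop, df$label), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Architecture string of each protein
#'
#' Labels ordered by start coordinate; ties broken by the longer interval first.
#'
#' @param intervals Data frame from [merge_intervals()].
#' @return Named character vector protein id -> dash-separated label string.
#' @export
architecture_string <- function(intervals) {
  if (!nrow(intervals)) return(stats::setNames(character(), character()))
  o <- order(intervals$protein_id, intervals$start,
             -(intervals$stop - intervals$start))
  iv <- intervals[o, , drop = FALSE]
  vapply(split(iv$label, iv$protein_id), paste, "", collapse = "-")
}

#' Extract named domain regions from the longest isoform of each gene
#'
#' For each requested gene the longest isoform with sequence is chosen (ties
#' broken by the lexicographically smallest protein id, with a message); every
#' interval of the requested label on that isoform is emitted as a region. The
#' region id encodes the protein id and 1-based inclusive coordinates.
#'
#' @param genes Character vector of gene ids.
#' @param label Domain label to extract (e.g. `"TIR"`).
#' @param map A [gene_map()].
#' @param records Data frame with `protein_id`, `sequence` (from [parse_fasta()]).
#' @param intervals Data frame from [merge_intervals()].
#' @return Data frame `region_id`, `gene_id`, `protein_id`, `start`, `stop`,
#'   `sequence`. Genes whose chosen isoform lacks the label are reported in the
#'   `missing` attribute.
#' @export
extract_domain_regions <- function(genes, label, map, records, intervals) {
  iso <- attr(map, "isoforms")
  out <- list(); missing <- character()
  for (g in genes) {
    prots <- iso[[g]]
    if (is.null(prots)) stop("gene '", g, "' absent from the gene map")
    seqs <- records$sequence[match(prots, records$protein_id)]
    has <- !is.na(seqs)
    if (!any(has)) stop("gene '", g, "' has no isoform with sequence")
    prots <- prots[has]; seqs <- seqs[has]
    lens <- nchar(seqs)
    best <- which(lens == max(lens))
    if (length(best) > 1L) {
      best <- best[order(prots[best])][1L]
      message("gene '", g, "': isoform length tie broken towards '", prots[best], "'")
    }
    pid <- prots[best]; pseq <- seqs[best]
    iv <- intervals[intervals$protein_id == pid & intervals$label == label, , drop = FALSE]
    if (!nrow(iv)) { missing <- c(missing, g); next }
    iv <- iv[order(iv$start), , drop = FALSE]
    for (r in seq_len(nrow(iv))) {
      suffix <- if (nrow(iv) > 1L) paste0("_", r) else ""
      out[[length(out) + 1L]] <- data.frame(
        region_id = sprintf("%s|%s:%d-%d%s", g, pid, iv$start[r], iv$stop[r], suffix),
        gene_id = g, protein_id = pid, start = iv$start[r], stop = iv$stop[r],
        sequence = substr(pseq, iv$start[r], iv$stop[r]), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(region_id = character(), gene_id = character(), protein_id = character(),
               start = integer(), stop = integer(), sequence = character(),
               stringsAsFactors = FALSE)
  attr(res, "missing") <- missing
  res
}

#' Default architecture pattern catalog
#'
#' Declarative patterns over merged labelled intervals: each pattern requires
#' minimum counts per label and may forbid labels. `TM_3plus` flags proteins
#' with three or more transmembrane segments; `CARD_absent_RLR` flags RIG-I
#' C-terminal-domain proteins lacking any CARD (the invertebrate RLR
#' configuration).
#'
#' @return Named list of pattern definitions.
#' @export
default_pattern_catalog <- function() {
  list(
    dual_TIR = list(required = c(TIR = 2L)),
    ROCO = list(required = c(ROC = 1L, COR = 1L)),
    LRR_CT_flank = list(required = c(LRR = 1L, CT = 1L)),
    CARD_present = list(required = c(CARD = 1L)),
    CARD_absent_RLR = list(required = c(RLR_CTD = 1L), forbidden = "CARD"),
    Mbt_accessory = list(required = c(MBT = 1L)),
    EF_hand_accessory = list(required = c(EF = 1L)),
    TM_3plus = list(required = c(TM = 3L)),
    SP_present = list(required = c(SP = 1L))
  )
}

#' Detect named architecture patterns per protein
#'
#' @param intervals Data frame from [merge_intervals()].
#' @param patterns Pattern catalog, see [default_pattern_catalog()]. Labels
#'   referenced by a pattern must be known labels of the supplied intervals'
#'   label universe (or of the default label map).
#' @param known_labels Character vector of valid labels (defaults to the
#'   shipped label map's labels).
#' @return Data frame `protein_id`, `pattern`, one row per flag.
#' @export
detect_patterns <- function(intervals, patterns = default_pattern_catalog(),
                            known_labels = unique(load_label_map())) {
  used <- unique(unlist(lapply(patterns, function(p) c(names(p$required), p$forbidden))))
  bad <- setdiff(used, known_labels)
  if (length(bad)) stop("pattern catalog references unknown label(s): ",
                        paste(bad, collapse = ", "))
  out <- list()
  for (pid in unique(intervals$protein_id)) {
    counts <- table(intervals$label[intervals$protein_id == pid])
    for (pname in names(patterns)) {
      p <- patterns[[pname]]
      have <- vapply(names(p$required), function(l) {
        sum(counts[names(counts) == l])
      }, 0)
      if (any(have < p$required)) next
      if (!is.null(p$forbidden) && any(p$forbidden %in% names(counts))) next
      out[[length(out) + 1L]] <- data.frame(protein_id = pid, pattern = pname,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(), pattern = character(), stringsAsFactors = FALSE)
}

#' Cross-species presence/absence matrix of matched proteins
#'
#' @param screens Named list (species -> data frame from [screen_proteome()]).
#' @return Integer matrix, rows = families (union over species), columns =
#'   species; cells are matched protein counts (0 = absent).
#' @export
presence_absence <- function(screens) {
  stopifnot(length(screens) >= 1, !is.null(names(screens)))
  fams <- sort(unique(unlist(lapply(screens, function(s) s$family))))
  m <- matrix(0L, length(fams), length(screens),
              dimnames = list(fams, names(screens)))
  for (sp in names(screens)) {
    s <- screens[[sp]]
    if (!nrow(s)) next
    tab <- tapply(s$protein_id, s$family, function(p) length(unique(p)))
    m[names(tab), sp] <- as.integer(tab)
  }
  m
}
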