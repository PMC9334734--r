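#' Simulation configuration for a synthetic annotation bundle
#'
#' Defines a toy multi-species study with planted ground truth: focal-species
#' genes planted into immune families (their longest isoform carries the
#' family's diagnostic domain suite from the rule catalog), background genes
#' carrying only decoy accessions, multi-species orthogroups tying each planted
#' family to fabricated reference genes, and random protein sequences drawn
#' from the JTT stationary frequencies.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical bundles.
#' @param species Species columns of the orthogroup table (focal first by
#'   default).
#' @param focal_species Focal species name.
#' @param planted Named integer vector family -> number of planted focal genes.
#' @param background Number of background (non-immune) focal genes.
#' @param max_isoforms Maximum isoforms per gene (drawn uniformly from 1..max).
#' @param domain_width Range of planted domain interval widths (residues).
#' @param margin Residues of sequence padding around planted domains.
#' @param catalog Rule catalog supplying the planted domain suites.
#' @param architectures Optional named list family -> accession vector
#'   overriding the planted suite; every accession must belong to that family's
#'   catalog clauses.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       species = c("aplysia", "biomphalaria", "crassostrea",
                                   "drosophila", "human"),
                       focal_species = species[1],
                       planted = c(TLR = 5L, SRCR = 3L),
                       background = 50L,
                       max_isoforms = 3L,
                       domain_width = c(40L, 120L),
                       margin = 30L,
                       catalog = load_rule_catalog(),
                       architectures = NULL) {
  stopifnot(background >= 0, all(planted >= 0), max_isoforms >= 1)
  bad <- setdiff(names(planted), names(catalog))
  if (length(bad)) stop("planted families absent from catalog: ", paste(bad, collapse = ", "))
  for (fam in names(architectures)) {
    allowed <- unique(unlist(lapply(catalog[[fam]]$clauses, `[[`, "required")))
    extra <- setdiff(architectures[[fam]], allowed)
    if (length(extra)) {
      stop("architecture for '", fam, "' references accession(s) absent from its catalog clauses: ",
           paste(extra, collapse = ", "))
    }
  }
  structure(list(seed = as.integer(seed), species = species,
                 focal_species = focal_species, planted = planted,
                 background = as.integer(background),
                 max_isoforms = as.integer(max_isoforms),
                 domain_width = domain_width, margin = as.integer(margin),
                 catalog = catalog, architectures = architectures),
            class = "sim_config")
}

#' Generate a synthetic annotation bundle with planted truth
#'
#' Writes an InterProScan-style TSV, a protein-to-gene map TSV, a protein
#' FASTA, an orthogroup TSV and a reference-catalog YAML into `dir`, and
#' returns the planted truth. Every planted gene's longest isoform satisfies
#' its family's strict clause under the supplied catalog; background proteins
#' satisfy no clause (they carry 0-2 decoy accessions from a disjoint pool).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with file `paths`, the `truth` tables (genes, intervals,
#'   orthogroups), and the reference catalog.
#' @export
generate_annotation_bundle <- function(config, dir = tempfile("bundle")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  catalog <- config$catalog
  genes <- list(); hits <- list(); prots <- list(); ivs <- list()
  og_rows <- list(); refs <- list()
  gene_no <- 0L; prot_no <- 0L; og_no <- 0L
  new_gene <- function() { gene_no <<- gene_no + 1L; sprintf("LOC%06d", gene_no) }
  new_prot <- function() { prot_no <<- prot_no + 1L; sprintf("XP_%06d.1", prot_no) }
  new_og <- function() { og_no <<- og_no + 1L; sprintf("OG%07d", og_no) }

  plant_domains <- function(pid, accs) {
    w <- sample(config$domain_width[1]:config$domain_width[2], length(accs), replace = TRUE)
    gaps <- sample(1:25, length(accs), replace = TRUE)
    start <- config$margin + cumsum(gaps) + c(0L, cumsum(w[-length(w)]))
    stop_ <- start + w - 1L
    len <- max(stop_) + config$margin
    list(len = len,
         df = data.frame(protein_id = pid, analysis = "SynthScan",
                         signature_acc = paste0("SYN_", accs),
                         signature_desc = "synthetic signature",
                         start = start, stop = stop_, score = 1e-10,
                         interpro_acc = ifelse(grepl("^IPR\\d{6}$", accs), accs, NA),
                         interpro_desc = "synthetic domain",
                         stringsAsFactors = FALSE))
  }

  for (fam in names(config$planted)) {
    n <- config$planted[[fam]]
    if (n == 0L) next
    accs <- if (!is.null(config$architectures[[fam]]))
      config$architectures[[fam]] else catalog[[fam]]$clauses[[1]]$required
    og_id <- new_og()
    fam_gene_ids <- character(n)
    for (i in seq_len(n)) {
      gid <- new_gene(); fam_gene_ids[i] <- gid
      genes[[gid]] <- data.frame(gene_id = gid, family = fam,
                                 orthogroup_id = og_id, stringsAsFactors = FALSE)
      n_iso <- sample.int(config$max_isoforms, 1L)
      planted <- plant_domains(new_prot(), accs)
      iso <- data.frame(protein_id = planted$df$protein_id[1], length = planted$len,
                        stringsAsFactors = FALSE)
      hits[[length(hits) + 1L]] <- planted$df
      ivs[[length(ivs) + 1L]] <- cbind(planted$df[, c("protein_id", "start", "stop")],
                                       accession = accs, gene_id = gid, family = fam,
                                       stringsAsFactors = FALSE)
      ## shorter isoforms: no informative domains
      if (n_iso > 1L) {
        for (k in seq_len(n_iso - 1L)) {
          iso <- rbind(iso, data.frame(protein_id = new_prot(),
                                       length = max(30L, planted$len - 10L * k),
                                       stringsAsFactors = FALSE))
        }
      }
      iso$gene_id <- gid
      prots[[length(prots) + 1L]] <- iso
    }
    og_rows[[og_id]] <- stats::setNames(vector("list", length(config$species)),
                                        config$species)
    og_rows[[og_id]][[config$focal_species]] <- fam_gene_ids
    refs[[fam]] <- list()
    for (sp in setdiff(config$species, config$focal_species)) {
      rid <- sprintf("%s_%s_ref", toupper(substr(sp, 1, 2)), gsub("[^A-Za-z0-9]", "", fam))
      og_rows[[og_id]][[sp]] <- rid
      refs[[fam]][[sp]] <- rid
    }
  }

  decoy_pool <- sprintf("IPR9%05d", 1:40)  # disjoint from any catalog accession
  for (i in seq_len(config$background)) {
    gid <- new_gene(); pid <- new_prot()
    genes[[gid]] <- data.frame(gene_id = gid, family = "background",
                               orthogroup_id = NA_character_, stringsAsFactors = FALSE)
    len <- sample(150:600, 1L)
    prots[[length(prots) + 1L]] <- data.frame(protein_id = pid, length = len,
                                              gene_id = gid, stringsAsFactors = FALSE)
    n_decoy <- sample(0:2, 1L)
    if (n_decoy > 0L) {
      accs <- sample(decoy_pool, n_decoy)
      s <- sort(sample(seq_len(len - 30L), n_decoy))
      hits[[length(hits) + 1L]] <- data.frame(
        protein_id = pid, analysis = "SynthScan",
        signature_acc = paste0("SYN_", accs), signature_desc = "decoy",
        start = s, stop = pmin(len, s + 29L), score = 0.001,
        interpro_acc = accs, interpro_desc = "decoy domain",
        stringsAsFactors = FALSE)
    }
    og_id <- new_og()
    og_rows[[og_id]] <- stats::setNames(vector("list", length(config$species)),
                                        config$species)
    og_rows[[og_id]][[config$focal_species]] <- gid
    genes[[gid]]$orthogroup_id <- og_id
  }

  proteins <- do.call(rbind, prots)
  hits <- if (length(hits)) do.call(rbind, hits) else empty_hits()
  truth_genes <- do.call(rbind, genes)
  rownames(truth_genes) <- NULL

  ## Sequences from JTT stationary frequencies.
  pi <- jtt_model(k = 1, p_inv = 0)$pi
  proteins$sequence <- vapply(proteins$length, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = pi), collapse = "")
  }, "")

  paths <- list(
    interproscan = file.path(dir, "annotation.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    fasta = file.path(dir, "proteins.faa"),
    orthogroups = file.path(dir, "Orthogroups.tsv"),
    references = file.path(dir, "references.yaml"))
  write_interproscan_tsv(hits, proteins, paths$interproscan)
  utils::write.table(proteins[, c("protein_id", "gene_id")], paths$gene_map,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_fasta(proteins, paths$fasta)
  og_lines <- paste(c("Orthogroup", config$species), collapse = "\t")
  for (og_id in names(og_rows)) {
    cells <- vapply(config$species, function(sp) {
      paste(unlist(og_rows[[og_id]][[sp]]), collapse = ", ")
    }, "")
    og_lines <- c(og_lines, paste(c(og_id, cells), collapse = "\t"))
  }
  writeLines(og_lines, paths$orthogroups)
  yaml::write_yaml(refs, paths$references)

  truth_intervals <- if (length(ivs)) do.call(rbind, ivs) else NULL
  list(paths = paths, config = config,
       truth = list(genes = truth_genes, intervals = truth_intervals,
                    proteins = proteins[, c("protein_id", "gene_id", "length")]),
       references = refs)
}

#' Evolve amino-acid sequences along a tree under JTT+I+Gamma
#'
#' The root sequence is drawn from the stationary frequencies; each site draws
#' a rate from the +I+Gamma mixture (0 with probability `p_inv`, otherwise a
#' discrete-gamma category mean) and evolves independently down the tree with
#' transition matrices `P(b * r)` per branch.
#'
#' @param tree An `ape::phylo` tree with branch lengths in substitutions/site.
#' @param model An [jtt_model()].
#' @param length Number of sites (> 0).
#' @param seed Integer seed.
#' @return List with `alignment` (named character vector, one string per tip)
#'   and `true_distances` (patristic distance matrix of the tree).
#' @export
evolve_sequences <- function(tree, model = jtt_model(), length = 1000L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (length <= 0) stop("alignment length must be positive")
  set.seed(seed)
  ntip <- base::length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  ## Per-site rates from the +I+Gamma mixture.
  rates <- ifelse(stats::runif(length) < model$p_inv, 0,
                  sample(model$rates, length, replace = TRUE))
  rate_levels <- sort(unique(rates))
  seqs <- matrix(NA_integer_, nnode, length)
  seqs[root, ] <- sample.int(20L, length, replace = TRUE, prob = model$pi)
  ## Preorder: parents before children.
  edges <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    b <- tree$edge.length[which(tree$edge[, 1] == parent & tree$edge[, 2] == child)]
    child_seq <- seqs[parent, ]
    for (r in rate_levels) {
      sites <- which(rates == r)
      if (!base::length(sites) || r == 0) next
      P <- transition_prob(model, b * r)
      parent_states <- seqs[parent, sites]
      for (s in unique(parent_states)) {
        at <- sites[parent_states == s]
        child_seq[at] <- sample.int(20L, base::length(at), replace = TRUE, prob = P[s, ])
      }
    }
    seqs[child, ] <- child_seq
  }
  aln <- apply(seqs[seq_len(ntip), , drop = FALSE], 1, function(idx) {
    paste(AA_ALPHABET[idx], collapse = "")
  })
  names(aln) <- tree$tip.label
  dmat <- stats::cophenetic(tree)
  list(alignment = aln, true_distances = dmat[tree$tip.label, tree$tip.label],
       rates = rates)
}
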