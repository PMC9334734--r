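#' Pairwise maximum-likelihood distance under JTT+I+Gamma
#'
#' Estimates the expected number of substitutions per site separating two
#' aligned amino-acid sequences by maximizing the pairwise likelihood under the
#' supplied rate model. Sites where either sequence carries a gap or a
#' non-standard residue are excluded (pairwise deletion).
#'
#' @param seq_a,seq_b Aligned sequences of equal length, as single strings or
#'   character vectors of residues.
#' @param model An [jtt_model()] object.
#' @param max_dist Upper bound of the search interval (default 50); estimates
#'   hitting the bound are returned as the bound with a saturation warning.
#' @return Estimated distance in expected substitutions per site.
#' @export
ml_distance <- function(seq_a, seq_b, model = jtt_model(), max_dist = 50) {
  a <- split_residues(seq_a)
  b <- split_residues(seq_b)
  if (length(a) != length(b)) {
    stop("sequences must be aligned to equal length (", length(a), " vs ",
         length(b), ")")
  }
  ia <- match(a, AA_ALPHABET)
  ib <- match(b, AA_ALPHABET)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) stop("no comparable (gap- and ambiguity-free) sites")
  counts <- table(factor(ia[keep], levels = 1:20), factor(ib[keep], levels = 1:20))
  counts <- matrix(as.numeric(counts), 20L, 20L)
  nll <- function(t) {
    M <- site_pair_prob(model, t)
    -sum(counts * log(M))
  }
  opt <- stats::optimize(nll, interval = c(1e-8, max_dist), tol = 1e-8)
  d <- opt$minimum
  if (d > max_dist - 1e-4 && nll(max_dist) <= opt$objective + 1e-9) {
    warning("distance estimate saturated at the search bound (", max_dist, ")")
    d <- max_dist
  }
  d
}

split_residues <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) x <- strsplit(x, "")[[1L]]
  toupper(as.character(x))
}

#' Pairwise ML distance matrix for an alignment
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (or a `Biostrings::AAStringSet`).
#' @param model An [jtt_model()] object.
#' @return Symmetric numeric matrix with zero diagonal, labelled by taxa.
#' @export
ml_dist_matrix <- function(alignment, model = jtt_model()) {
  alignment <- as_alignment(alignment)
  taxa <- names(alignment)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- ml_distance(alignment[[i]], alignment[[j]], model)
      }
    }
  }
  d
}

as_alignment <- function(alignment) {
  if (inherits(alignment, "AAStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
    stop("alignment must have unique taxon names")
  }
  if (length(unique(nchar(alignment))) > 1L) {
    stop("alignment rows must have equal length")
  }
  alignment
}

#' Neighbor joining on a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. Ties are
#' broken deterministically by the smallest (row, column) index pair. Negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sister branch, so total path lengths between joined taxa are preserved.
#'
#' @param dm Symmetric distance matrix with labelled rows/columns, or a
#'   `stats::dist` object.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ## Active nodes are represented as partial newick strings.
  node <- labels
  D <- dm
  while (length(node) > 3) {
    m <- length(node)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    ## Smallest (i, j), i < j, among minimizers.
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    merged <- sprintf("(%s:%.17g,%s:%.17g)", node[i], bi, node[j], bj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    node <- c(node[keep], merged)
  }
  ## Terminal star of three nodes, closed-form branch lengths.
  b1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 node[1], b1, node[2], b2, node[3], b3)
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal branch splits the taxa into two sides; the side not containing
#' the lexicographically smallest taxon is returned, sorted, so bipartitions
#' compare canonically across trees and rootings.
#'
#' @param tree An `ape::phylo` tree.
#' @return List of sorted character vectors of tip labels.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  ## Tips below each node, by postorder accumulation over the edge matrix.
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) next
    side <- desc[[ch]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    out[[length(out) + 1L]] <- sort(side)
  }
  unique(out)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two trees.
#'
#' @param t1,t2 `ape::phylo` trees on the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must share the same leaf set")
  }
  k1 <- vapply(bipartitions(t1), paste, "", collapse = "\r")
  k2 <- vapply(bipartitions(t2), paste, "", collapse = "\r")
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Neighbor-joining tree with bootstrap branch supports
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `B` times; the support of each internal
#' bipartition of the point tree is the percentage of completed replicates
#' whose tree contains that bipartition. Supports are written to the internal
#' node labels of the returned tree.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param model An [jtt_model()] object.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed for the column resampler.
#' @return An `ape::phylo` tree with percent supports as `node.label`; the
#'   number of completed replicates is attached as attribute `"replicates"`.
#' @export
nj_bootstrap <- function(alignment, model = jtt_model(), B = 100L, seed = 1L) {
  stopifnot(B >= 1)
  alignment <- as_alignment(alignment)
  point <- nj_tree(ml_dist_matrix(alignment, model))
  rows <- lapply(alignment, function(s) strsplit(s, "")[[1L]])
  L <- length(rows[[1L]])
  keys <- vapply(bipartitions(point), paste, "", collapse = "\r")
  hits <- stats::setNames(numeric(length(keys)), keys)
  completed <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- vapply(rows, function(r) paste(r[cols], collapse = ""), "")
    tr <- tryCatch(nj_tree(ml_dist_matrix(rep_aln, model)), error = function(e) NULL)
    if (is.null(tr)) {
      message("bootstrap replicate ", b, " skipped: no comparable sites for some pair")
      next
    }
    completed <- completed + 1L
    bk <- vapply(bipartitions(tr), paste, "", collapse = "\r")
    present <- keys %in% bk
    hits[present] <- hits[present] + 1
  }
  if (completed == 0L) stop("all bootstrap replicates failed")
  support <- round(100 * hits / completed)
  point <- annotate_supports(point, keys, support)
  attr(point, "replicates") <- completed
  point
}

## Write per-bipartition supports onto the internal node labels of a tree.
annotate_supports <- function(tree, keys, support) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    desc[[edges[e, 1]]] <- c(desc[[edges[e, 1]]], desc[[edges[e, 2]]])
  }
  labels <- character(tree$Nnode)
  for (node in seq_len(tree$Nnode)) {
    side <- desc[[ntip + node]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "\r")
    if (key %in% keys) labels[node] <- as.character(support[[key]])
  }
  tree$node.label <- labels
  tree
}

#' Concordance of leaf groups with tree structure
#'
#' A group is concordant when some bipartition of the tree separates exactly
#' that group from the rest. For discordant groups, the best-covering side
#' (maximum F1 between a bipartition side and the group) is found and group
#' members outside it are reported as outliers. Singleton groups are trivially
#' concordant.
#'
#' @param tree An `ape::phylo` tree.
#' @param assignment Named character vector mapping every leaf to a group.
#' @return Data frame with columns `group`, `n`, `concordant`, `outliers`
#'   (comma-separated), `f1`.
#' @export
group_concordance <- function(tree, assignment) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(assignment))
  if (length(missing)) {
    stop("leaves without group assignment: ", paste(missing, collapse = ", "))
  }
  assignment <- assignment[tips]
  sides <- bipartitions(tree)
  ## Both orientations of every split, plus pendant "sides" for completeness.
  sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)),
             as.list(tips), lapply(tips, function(t) setdiff(tips, t)))
  groups <- sort(unique(assignment))
  res <- lapply(groups, function(g) {
    members <- tips[assignment == g]
    if (length(members) < 2L) {
      return(data.frame(group = g, n = 1L, concordant = TRUE,
                        outliers = "", f1 = 1, stringsAsFactors = FALSE))
    }
    best_f1 <- 0; best_side <- character()
    for (s in sides) {
      tp <- length(intersect(s, members))
      if (tp == 0) next
      f1 <- 2 * tp / (length(s) + length(members))
      if (f1 > best_f1) { best_f1 <- f1; best_side <- s }
    }
    conc <- isTRUE(all.equal(best_f1, 1))
    data.frame(group = g, n = length(members), concordant = conc,
               outliers = paste(sort(setdiff(members, best_side)), collapse = ","),
               f1 = best_f1, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
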