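og_from_lines <- function(lines) {
  tmp <- tempfile()
  writeLines(lines, tmp)
  parse_orthogroups(tmp)
}

test_that("vetting annotates domain-screened genes with shared-orthogroup evidence", {
  og <- og_from_lines(c(
    "Orthogroup\taplysia\thuman",
    "OG1\tgA, gB\thsTLR1",
    "OG2\tgC\t",
    "OG3\tgD\thsIKB1"))
  map <- gene_map(data.frame(protein_id = c("pA", "pB", "pC", "pD"),
                             gene_id = c("gA", "gB", "gC", "gD")))
  genes <- data.frame(family = "TLR", gene_id = c("gA", "gB", "gC"),
                      clause = "strict", protein_ids = c("pA", "pB", "pC"),
                      stringsAsFactors = FALSE)
  refs <- list(TLR = list(human = "hsTLR1"))
  entries <- vet_families(genes, map, og, refs)
  expect_equal(entries$orthology_supported[entries$gene_id %in% c("gA", "gB")],
               c(TRUE, TRUE))
  expect_false(entries$orthology_supported[entries$gene_id == "gC"])
  expect_equal(entries$orthogroup_id[entries$gene_id == "gA"], "OG1")

  # empty reference catalog: output equals the screen with all flags false
  e0 <- vet_families(genes, map, og, list())
  expect_equal(nrow(e0), 3L)
  expect_false(any(e0$orthology_supported))

  # unknown species in references is a hard error; missing reference id warns
  expect_error(vet_families(genes, map, og, list(TLR = list(mars = "x"))),
               "unknown species")
  expect_warning(vet_families(genes, map, og, list(TLR = list(human = "absent_ref"))),
                 "absent from orthogroup table")
})

test_that("orthology rescue returns co-grouped genes missed by the domain screen", {
  og <- og_from_lines(c(
    "Orthogroup\taplysia\thuman",
    "OG1\tgTAB1, gOther\thsTAB1",
    "OG2\tgX\t"))
  refs <- list(TAB1 = list(human = "hsTAB1"))
  # TAB1-style: generic-domain gene co-grouped with the human reference
  rescued <- orthology_rescue("TAB1", refs, og, already_matched = character(),
                              focal_species = "aplysia")
  expect_setequal(rescued, c("gTAB1", "gOther"))
  # rescue excludes genes already found by the screen (disjointness)
  rescued2 <- orthology_rescue("TAB1", refs, og, already_matched = "gOther",
                               focal_species = "aplysia")
  expect_equal(rescued2, "gTAB1")
  # family with no references rescues nothing
  expect_length(orthology_rescue("MyD88", refs, og, focal_species = "aplysia"), 0L)
})

test_that("rescue equals brute-force set algebra on random orthogroup tables", {
  set.seed(8)
  for (i in 1:25) {
    n_og <- sample(3:10, 1)
    lines <- "Orthogroup\tfocal\tref_sp"
    focal_by_og <- list(); ref_by_og <- list()
    for (k in seq_len(n_og)) {
      f <- sprintf("f%d_%d", k, seq_len(sample(0:3, 1)))
      r <- sprintf("r%d_%d", k, seq_len(sample(0:2, 1)))
      focal_by_og[[k]] <- f; ref_by_og[[k]] <- r
      lines <- c(lines, paste0("OG", k, "\t", paste(f, collapse = ", "),
                               "\t", paste(r, collapse = ", ")))
    }
    og <- og_from_lines(lines)
    all_refs <- unlist(ref_by_og)
    if (!length(all_refs)) next
    fam_refs <- sample(all_refs, sample(1:length(all_refs), 1))
    matched <- if (length(unlist(focal_by_og)))
      sample(unlist(focal_by_og), sample(0:2, 1)) else character()
    got <- suppressWarnings(orthology_rescue(
      "F", list(F = list(ref_sp = fam_refs)), og, matched, "focal"))
    ## oracle: union of focal members of orthogroups containing any reference
    want <- character()
    for (k in seq_len(n_og)) {
      if (any(fam_refs %in% ref_by_og[[k]])) want <- c(want, focal_by_og[[k]])
    }
    want <- sort(setdiff(unique(want), c(matched, fam_refs)))
    expect_equal(got, want)
  }
})

test_that("overlap statistics match a hand tally and satisfy the partition property", {
  og <- og_from_lines(c(
    "Orthogroup\tap\tbg\tcg\tdm\ths",
    "OG1\tg1\tg2\tg3\tg4\tg5",   # all species
    "OG2\tg6\tg7\t\t\t",          # gastropods only
    "OG3\tg8\t\t\t\t",            # focal unique
    "OG4\tg9\tg10\tg11\t\tg12",   # mollusks + human, no fly
    "OG5\t\t\t\tg13\t",           # fly only
    "OG6\tg14\tg15\tg16\t\t"))    # mollusks only
  st <- overlap_stats(og, "ap", named_subsets = list(
    mollusk_human_not_fly = list(any_of = c("ap", "bg", "cg"), all_of = "hs",
                                 none_of = "dm"),
    mollusk_only = list(equals = c("ap", "bg", "cg")),
    gastropod_only = list(equals = c("ap", "bg"))))
  expect_equal(st$total_orthogroups, 6L)
  expect_equal(st$at_least_two_species, 4L)
  expect_equal(st$all_species, 1L)
  expect_equal(st$focal_unique, 1L)
  expect_equal(st$mollusk_human_not_fly, 1L)  # only OG4; OG1 contains the fly
  expect_equal(st$mollusk_only, 1L)
  expect_equal(st$gastropod_only, 1L)
  # partition property
  expect_equal(st$at_least_two_species + st$single_species, st$total_orthogroups)
  expect_error(overlap_stats(og, "nessie"), "unknown focal species")
  expect_error(overlap_stats(og, "ap", list(x = list(equals = "venus"))),
               "unknown species")
})

test_that("partition property holds on random orthogroup tables of every shape", {
  set.seed(9)
  for (i in 1:20) {
    species <- sprintf("s%d", 1:sample(2:6, 1))
    lines <- paste(c("Orthogroup", species), collapse = "\t")
    for (k in 1:sample(1:15, 1)) {
      cells <- vapply(species, function(s) {
        if (runif(1) < 0.5) "" else paste(sprintf("%s_g%d_%d", s, k, 1:sample(1:2, 1)),
                                          collapse = ", ")
      }, "")
      lines <- c(lines, paste(c(sprintf("OG%d", k), cells), collapse = "\t"))
    }
    og <- og_from_lines(lines)
    st <- overlap_stats(og, species[1])
    expect_equal(st$at_least_two_species + st$single_species, st$total_orthogroups)
    expect_lte(st$all_species, st$total_orthogroups)
    expect_lte(st$focal_unique, st$single_species)
  }
})

test_that("overlap statistics are invariant to row and gene-list order", {
  lines <- c("Orthogroup\ta\tb",
             "OG1\tg1, g2\tg3", "OG2\tg4\t", "OG3\t\tg5, g6")
  og1 <- og_from_lines(lines)
  og2 <- og_from_lines(lines[c(1, 4, 2, 3)])
  s1 <- overlap_stats(og1, "a"); s2 <- overlap_stats(og2, "a")
  expect_equal(unclass(s1), unclass(s2))
})

test_that("homology evidence flags candidates passing thresholds and adds missing genes", {
  map <- gene_map(data.frame(protein_id = c("pF1", "pF2", "pX"),
                             gene_id = c("gFREP1", "gFREP2", "gX")))
  entries <- data.frame(gene_id = "gFREP1", family = "VIgL", category = "lectin",
                        clause = "relaxed", orthogroup_id = NA_character_,
                        orthology_supported = FALSE, homology_rescued = FALSE,
                        stringsAsFactors = FALSE)
  tmp <- tempfile()
  writeLines(c("pF1\tBgFREP\t88.1\t200\t4\t0\t1\t200\t1\t200\t1e-60\t300",
               "pF2\tBgFREP\t79.0\t180\t9\t0\t1\t180\t1\t180\t1e-40\t220",
               "pX\tBgFREP\t30.0\t80\t40\t0\t1\t80\t1\t80\t0.5\t28"), tmp)
  hits <- parse_homology_hits(tmp)
  out <- attach_homology_evidence(entries, hits, "VIgL", map)
  # both previously described genes enter the family; the weak hit does not
  expect_true(out$homology_rescued[out$gene_id == "gFREP1"])
  expect_true("gFREP2" %in% out$gene_id)
  expect_equal(out$clause[out$gene_id == "gFREP2"], "none")
  expect_false("gX" %in% out$gene_id)
  # hit above the e-value threshold gains no flag
  out2 <- attach_homology_evidence(entries, hits[3, ], "VIgL", map)
  expect_equal(out2, entries[order(entries$family, entries$gene_id), ],
               ignore_attr = TRUE)
})

test_that("homology flags equal brute-force best-hit filtering on random tables", {
  set.seed(10)
  map <- gene_map(data.frame(protein_id = sprintf("p%d", 1:8),
                             gene_id = sprintf("g%d", rep(1:4, each = 2))))
  for (i in 1:15) {
    n <- sample(5:25, 1)
    hits <- data.frame(
      query_id = sample(sprintf("p%d", 1:8), n, TRUE), subject_id = "ref",
      percent_identity = 50, alignment_length = 100L,
      evalue = 10^runif(n, -40, 0), bitscore = runif(n, 20, 300),
      stringsAsFactors = FALSE)
    entries <- data.frame(gene_id = character(), family = character(),
                          category = character(), clause = character(),
                          orthogroup_id = character(), orthology_supported = logical(),
                          homology_rescued = logical(), stringsAsFactors = FALSE)
    out <- attach_homology_evidence(entries, hits, "FAM", map, max_evalue = 1e-5)
    ## oracle: a gene is added iff some isoform's best e-value passes
    best <- tapply(hits$evalue, hits$query_id, min)
    want <- sort(unique(genes_of(map, names(best)[best <= 1e-5])))
    expect_equal(sort(out$gene_id), want)
  }
})
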