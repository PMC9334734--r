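test_that("interval merging unions overlapping and book-ended same-label hits", {
  # two LRR hits at 10-40 and 35-70 merge to 10-70
  h <- make_hits("p", c("IPR001611", "IPR001611"), starts = c(10L, 35L),
                 stops = c(40L, 70L))
  iv <- merge_intervals(h)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$stop), c(10L, 70L))
  # book-ended intervals (stop + 1 = start) merge; a gap of one residue does not
  bk <- make_hits("p", c("IPR001611", "IPR001611"), starts = c(10L, 41L),
                  stops = c(40L, 60L))
  expect_equal(nrow(merge_intervals(bk)), 1L)
  gap <- make_hits("p", c("IPR001611", "IPR001611"), starts = c(10L, 42L),
                   stops = c(40L, 60L))
  expect_equal(nrow(merge_intervals(gap)), 2L)
  # same span from two member databases -> one TIR interval, both accessions kept
  dual_db <- rbind(make_hits("p", "IPR000157", starts = 100L, stops = 220L),
                   make_hits("p", "SM00369", starts = 5L, stops = 30L))
  dual_db$signature_acc[2] <- "SM00369"
  sm_tir <- make_hits("p", "IPR000157", starts = 110L, stops = 230L)
  sm_tir$signature_acc <- "TIR_smart"
  iv2 <- merge_intervals(rbind(dual_db[1, ], sm_tir))
  tir <- iv2[iv2$label == "TIR", ]
  expect_equal(nrow(tir), 1L)
  expect_equal(c(tir$start, tir$stop), c(100L, 230L))
  expect_true(grepl("IPR000157", tir$accessions))
  # disjoint TIR hits stay separate (dual-TIR receptor architecture)
  dual <- make_hits("p", c("IPR000157", "IPR000157"), starts = c(50L, 400L),
                    stops = c(150L, 500L))
  expect_equal(nrow(merge_intervals(dual)), 2L)
})

test_that("merging is idempotent, order-invariant and matches a union oracle on random intervals", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    starts <- sample(1:300, n, replace = TRUE)
    widths <- sample(5:80, n, replace = TRUE)
    h <- make_hits("p", rep("IPR000157", n), starts = starts, stops = starts + widths)
    iv <- merge_intervals(h)
    # oracle: positional union via a coverage vector (book-ended counts as joined)
    cov <- rep(FALSE, 500)
    for (k in seq_len(n)) cov[starts[k]:(starts[k] + widths[k])] <- TRUE
    runs <- rle(cov)
    expect_equal(nrow(iv), sum(runs$values))       # one interval per coverage run
    expect_equal(sum(iv$stop - iv$start + 1), sum(cov))
    # idempotence: re-merging the merged intervals changes nothing
    h2 <- make_hits("p", rep("IPR000157", nrow(iv)), starts = iv$start, stops = iv$stop)
    expect_equal(merge_intervals(h2)[, c("start", "stop")], iv[, c("start", "stop")])
    # order invariance
    perm <- h[sample(n), ]
    expect_equal(merge_intervals(perm)[, c("start", "stop")], iv[, c("start", "stop")])
  }
})

test_that("architecture strings order labels by start with longer-first ties", {
  h <- rbind(make_hits("p", "IPR000157", starts = 200L, stops = 300L),
             make_hits("p", "IPR001611", starts = 10L, stops = 60L),
             make_hits("p", "IPR020859", starts = 200L, stops = 500L))
  s <- architecture_string(merge_intervals(h))
  expect_equal(unname(s["p"]), "LRR-ROC-TIR")  # tie at 200: ROC (longer) first
})

test_that("domain region extraction uses the longest isoform with deterministic tie-breaks", {
  map <- gene_map(data.frame(protein_id = c("iso_a", "iso_b"), gene_id = c("g1", "g1")),
                  lengths = data.frame(protein_id = c("iso_a", "iso_b"),
                                       length = c(500L, 300L)))
  seqs <- data.frame(
    protein_id = c("iso_a", "iso_b"),
    sequence = c(paste(rep("A", 500), collapse = ""), paste(rep("C", 300), collapse = "")),
    stringsAsFactors = FALSE)
  h <- make_hits("iso_a", "IPR000157", starts = 120L, stops = 260L)
  iv <- merge_intervals(h)
  reg <- extract_domain_regions("g1", "TIR", map, seqs, iv)
  expect_equal(nrow(reg), 1L)
  expect_equal(nchar(reg$sequence), 141L)  # stop - start + 1
  expect_equal(reg$protein_id, "iso_a")
  # dual-TIR gene emits two suffixed regions
  h2 <- make_hits("iso_a", c("IPR000157", "IPR000157"),
                  starts = c(50L, 400L), stops = c(150L, 480L))
  reg2 <- extract_domain_regions("g1", "TIR", map, seqs, merge_intervals(h2))
  expect_equal(nrow(reg2), 2L)
  expect_true(all(grepl("_[12]$", reg2$region_id)))
  # length tie: lexicographically smallest protein id wins, with a message
  map_tie <- gene_map(data.frame(protein_id = c("iso_b", "iso_a"), gene_id = "g1"))
  seqs_tie <- data.frame(protein_id = c("iso_a", "iso_b"),
                         sequence = c(strrep("A", 200), strrep("C", 200)),
                         stringsAsFactors = FALSE)
  expect_message(
    reg3 <- extract_domain_regions("g1", "TIR", map_tie, seqs_tie,
                                   merge_intervals(make_hits("iso_a", "IPR000157",
                                                             starts = 10L, stops = 50L))),
    "tie broken")
  expect_equal(reg3$protein_id, "iso_a")
  # a gene whose chosen isoform lacks the label is reported as missing
  reg4 <- extract_domain_regions("g1", "ROC", map, seqs, iv)
  expect_equal(nrow(reg4), 0L)
  expect_equal(attr(reg4, "missing"), "g1")
})

test_that("extracted regions equal planted substrings on a synthetic bundle", {
  bundle <- generate_annotation_bundle(sim_config(seed = 77, planted = c(TLR = 4L),
                                                  background = 10L))
  parsed <- parse_interproscan_tsv(bundle$paths$interproscan)
  fasta <- parse_fasta(bundle$paths$fasta)
  map <- load_gene_map(bundle$paths$gene_map, lengths = fasta)
  iv <- merge_intervals(parsed$hits)
  truth <- bundle$truth$intervals
  tir_truth <- truth[truth$accession == "IPR000157", ]
  genes <- unique(tir_truth$gene_id)
  reg <- extract_domain_regions(genes, "TIR", map, fasta, iv)
  expect_setequal(reg$gene_id, genes)
  for (r in seq_len(nrow(reg))) {
    want <- substr(fasta$sequence[fasta$protein_id == reg$protein_id[r]],
                   reg$start[r], reg$stop[r])
    expect_equal(reg$sequence[r], want)
    tr <- tir_truth[tir_truth$protein_id == reg$protein_id[r], ]
    expect_equal(c(reg$start[r], reg$stop[r]), c(tr$start, tr$stop))
  }
})

test_that("pattern detection flags known architectures and rejects unknown labels", {
  roco <- rbind(make_hits("p1", c("IPR020859", "IPR032171", "IPR004092",
                                  "IPR000157", "IPR001611")))
  flags <- detect_patterns(merge_intervals(roco))
  got <- flags$pattern[flags$protein_id == "p1"]
  expect_true(all(c("ROCO", "Mbt_accessory") %in% got))
  # TIR + LRR + CT flank
  ct <- make_hits("p2", c("IPR000157", "IPR001611", "IPR000483"))
  expect_true("LRR_CT_flank" %in% detect_patterns(merge_intervals(ct))$pattern)
  # RLR C-terminal domain without CARD (the gastropod RLR configuration)
  rlr <- make_hits("p3", "IPR021673")
  expect_true("CARD_absent_RLR" %in% detect_patterns(merge_intervals(rlr))$pattern)
  rlr_card <- make_hits("p4", c("IPR021673", "IPR031964"))
  f4 <- detect_patterns(merge_intervals(rlr_card))
  expect_false("CARD_absent_RLR" %in% f4$pattern)
  expect_true("CARD_present" %in% f4$pattern)
  # no intervals -> no flags; unknown label in a custom catalog -> hard error
  expect_equal(nrow(detect_patterns(merge_intervals(make_hits("p", character(0))))), 0L)
  expect_error(detect_patterns(merge_intervals(ct),
                               patterns = list(x = list(required = c(WINGS = 1L)))),
               "unknown label")
})

test_that("presence/absence matrices count matched proteins per species", {
  cat_ <- load_rule_catalog()
  sp1 <- screen_proteome(rbind(make_hits("a1", c("IPR000157", "IPR001611")),
                               make_hits("a2", c("IPR000157", "IPR001611")),
                               make_hits("a3", "IPR001190")), cat_)
  sp2 <- screen_proteome(make_hits("b1", "IPR001190"), cat_)
  m <- presence_absence(list(aplysia = sp1, oyster = sp2))
  expect_equal(m["TLR", "aplysia"], 2L)
  expect_equal(m["TLR", "oyster"], 0L)     # absent family is an explicit zero
  expect_equal(m["SRCR", "oyster"], 1L)
  # synthetic 3-species, 2-family design equals the planted design matrix
  design <- list(s1 = c(TLR = 3L, PARP = 1L), s2 = c(TLR = 0L, PARP = 2L),
                 s3 = c(TLR = 1L, PARP = 0L))
  screens <- lapply(design, function(d) {
    h <- list()
    for (k in seq_len(d[["TLR"]])) {
      h[[length(h) + 1]] <- make_hits(sprintf("tlr%d", k), c("IPR000157", "IPR001611"))
    }
    for (k in seq_len(d[["PARP"]])) {
      h[[length(h) + 1]] <- make_hits(sprintf("parp%d", k), "IPR012317")
    }
    screen_proteome(if (length(h)) do.call(rbind, h) else make_hits("x", character(0)),
                    cat_)
  })
  m2 <- presence_absence(screens)
  for (s in names(design)) {
    expect_equal(m2["TLR", s], unname(design[[s]]["TLR"]))
    expect_equal(m2["PARP", s], unname(design[[s]]["PARP"]))
  }
})
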