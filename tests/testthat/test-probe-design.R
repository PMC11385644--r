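# Probe design: target slicing, filters, specificity screen, selection,
# cross-species panels, probe assembly.

test_that("transcriptome loading groups isoforms and normalizes the alphabet", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g1|i1", "ATGCATGC", ">g1|i2", "auGC", ">g2|i1", "GGGG"), fa)
  tx <- load_transcriptome(fa)
  expect_length(tx, 2L)
  expect_length(tx[["g1"]]$isoforms, 2L)
  expect_equal(unname(tx[["g1"]]$isoforms[["g1|i2"]]), "ATGC")

  writeLines(c(">g1|i1", "ATGNAT"), fa)
  expect_error(load_transcriptome(fa), "non-ACGT")
  tx2 <- load_transcriptome(fa, mask_ambiguous = TRUE)
  expect_equal(unname(tx2[["g1"]]$isoforms[[1L]]), "ATGNAT")

  writeLines(character(0), fa)
  expect_error(load_transcriptome(fa), "empty")
  writeLines(c(">g1|i1", "ACGT", ">g1|i1", "ACGT"), fa)
  expect_error(load_transcriptome(fa), "duplicate")
})

test_that("a gene map overrides header-token grouping", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tx1", "ACGTACGT", ">tx2", "TTTTAAAA"), fa)
  tx <- load_transcriptome(fa, gene_map = data.frame(
    isoform_id = c("tx1", "tx2"), gene_id = c("geneA", "geneA")))
  expect_length(tx, 1L)
  expect_length(tx[["geneA"]]$isoforms, 2L)
})

test_that("single-isoform genes yield every sliding 30-mer", {
  set.seed(1)
  s <- random_dna(32L)
  tx <- transcriptome(c(i1 = s), "g1")
  cand <- common_30mers(tx[["g1"]])
  expect_equal(cand$start, 0:2)
  expect_equal(cand$sequence, substring(s, 1:3, 30:32))
  expect_equal(cand$gc_fraction,
               vapply(cand$sequence, function(w)
                 sum(strsplit(w, "")[[1L]] %in% c("G", "C")) / 30, 0,
                 USE.NAMES = FALSE))
})

test_that("multi-isoform candidates are the intersection of 30-mer sets", {
  # two isoforms sharing only a 40-nt exon: brute-force intersection says
  # exactly the 11 windows inside the shared exon survive
  set.seed(42)
  exon <- random_dna(40L)
  iso1 <- paste0(random_dna(80L), exon, random_dna(80L))
  iso2 <- paste0(random_dna(100L), exon, random_dna(60L))
  tx <- transcriptome(c(a = iso1, b = iso2), c("g1", "g1"))
  cand <- common_30mers(tx[["g1"]])

  kmers <- function(s) substring(s, 1:(nchar(s) - 29L), 30:nchar(s))
  expected <- intersect(kmers(iso1), kmers(iso2))
  expect_setequal(cand$sequence, expected)
  expect_equal(nrow(cand), 11L)
  expect_true(all(cand$start >= 80L & cand$start <= 90L))

  tx2 <- transcriptome(c(a = random_dna(100L), b = random_dna(100L)),
                       c("g2", "g2"))
  expect_equal(nrow(common_30mers(tx2[["g2"]])), 0L)
})

test_that("short isoforms give an empty candidate list with a warning", {
  tx <- transcriptome(c(i1 = "ACGTACGTACGT"), "g1")
  expect_warning(cand <- common_30mers(tx[["g1"]]), "shorter")
  expect_equal(nrow(cand), 0L)
})

test_that("GC and junction filters apply the stated rules inclusively", {
  half_gc <- paste0(strrep("GC", 7L), "C", "G", strrep("AT", 7L))  # 15 G/C
  all_a <- strrep("A", 30L)
  pos16_g <- paste0(strrep("A", 15L), "G", strrep("A", 14L))
  pos16_t <- paste0(strrep("A", 15L), "T", strrep("A", 14L))
  cand <- data.frame(gene_id = "g", start = c(0L, 40L, 80L, 120L),
                     sequence = c(half_gc, all_a, pos16_g, pos16_t),
                     gc_fraction = c(0.5, 0, 1 / 30, 1 / 30),
                     junction_base = substr(c(half_gc, all_a, pos16_g, pos16_t),
                                            16L, 16L),
                     stringsAsFactors = FALSE)
  expect_equal(filter_gc(cand, 0.4, 0.6)$sequence, half_gc)
  expect_equal(filter_gc(cand, 0, 1), cand)          # identity bounds
  expect_equal(filter_junction_base(cand)$sequence, c(half_gc, pos16_g))
  expect_equal(nrow(filter_junction_base(cand[0L, ])), 0L)
})

test_that("GC and junction filters commute", {
  tx <- make_random_transcriptome(5L, len = 300L, seed = 8L)
  for (g in names(tx)) {
    cand <- common_30mers(tx[[g]])
    a <- filter_junction_base(filter_gc(cand))
    b <- filter_gc(filter_junction_base(cand))
    expect_equal(a, b)
  }
})

test_that("specificity check matches a brute-force Hamming scan", {
  tx <- make_random_transcriptome(6L, len = 300L, seed = 21L)
  cand <- do.call(rbind, lapply(names(tx), function(g)
    utils::head(filter_junction_base(common_30mers(tx[[g]])), 10L)))
  for (mm in c(0L, 3L, 6L)) {
    res <- specificity_check(cand, tx, max_mismatches = mm)
    expect_identical(hit_keys(res$hits), naive_hamming_keys(cand, tx, mm))
  }
})

test_that("specificity at zero mismatches equals exact substring matching", {
  tx <- make_random_transcriptome(4L, len = 200L, seed = 5L)
  cand <- common_30mers(tx[["g1"]])[1:5, ]
  res <- specificity_check(cand, tx, max_mismatches = 0L)
  expect_true(all(res$hits$mismatches == 0L))
  for (i in seq_len(nrow(res$hits))) {
    h <- res$hits[i, ]
    iso <- tx[[h$subject_gene_id]]$isoforms[[h$subject_isoform_id]]
    expect_equal(substr(iso, h$position + 1L, h$position + 30L), h$sequence)
  }
})

test_that("foreign hits disqualify a candidate but self-hits do not", {
  set.seed(3)
  shared <- random_dna(30L)
  g1 <- paste0(random_dna(50L), shared, random_dna(50L))
  g2 <- paste0(random_dna(40L), shared, random_dna(60L))  # exact copy in g2
  tx <- transcriptome(c(a = g1, b = g2), c("g1", "g2"))
  cand <- common_30mers(tx[["g1"]])
  res <- specificity_check(cand, tx, max_mismatches = 6L)
  # the window equal to `shared` must be discarded with a 0-mismatch hit
  expect_false(shared %in% res$candidates$sequence)
  sh <- res$hits[res$hits$sequence == shared &
                   res$hits$subject_gene_id == "g2", ]
  expect_true(any(sh$mismatches == 0L))
  # candidates hitting only their own gene all survive
  own_only <- setdiff(cand$sequence,
                      res$hits$sequence[res$hits$subject_gene_id != "g1"])
  expect_true(all(own_only %in% res$candidates$sequence))
})

test_that("a foreign near-match beyond the budget is tolerated", {
  set.seed(9)
  target <- random_dna(30L)
  g1 <- paste0(random_dna(30L), target, random_dna(30L))
  g2 <- paste0(random_dna(20L), plant_mismatches(target, 7L), random_dna(40L))
  tx <- transcriptome(c(a = g1, b = g2), c("g1", "g2"))
  cand <- data.frame(gene_id = "g1", start = 30L, sequence = target,
                     gc_fraction = 0.5, junction_base = substr(target, 16L, 16L),
                     stringsAsFactors = FALSE)
  res6 <- specificity_check(cand, tx, max_mismatches = 6L)
  expect_equal(nrow(res6$candidates), 1L)   # 7-mismatch neighbor: retained
  res7 <- specificity_check(cand, tx, max_mismatches = 7L)
  expect_equal(nrow(res7$candidates), 0L)   # now inside the budget: discarded
})

test_that("select_targets returns non-overlapping, seed-stable subsets", {
  mk <- function(starts, seqs = NULL) {
    if (is.null(seqs)) {
      set.seed(100L)
      seqs <- vapply(starts, function(i) random_dna(30L), "")
    }
    data.frame(gene_id = "g", start = starts, sequence = seqs,
               gc_fraction = 0.5, junction_base = "G",
               stringsAsFactors = FALSE)
  }
  expect_warning(sel1 <- select_targets(mk(c(0L, 10L)), n = 2L, seed = 1L),
                 "non-overlapping")
  expect_equal(nrow(sel1), 1L)

  cand <- mk(seq(0L, 99L * 35L, by = 35L))  # 100 non-overlapping candidates
  sel <- select_targets(cand, n = 5L, seed = 4L)
  expect_equal(nrow(sel), 5L)
  expect_true(all(diff(sort(sel$start)) >= 30L))

  expect_equal(select_targets(cand, n = 5L, seed = 4L), sel)  # determinism
  perm <- cand[sample(nrow(cand)), ]
  expect_equal(select_targets(perm, n = 5L, seed = 4L), sel,
               ignore_attr = TRUE)                            # order-invariance
})

test_that("cross-species filter keeps conserved targets and annotates distances", {
  set.seed(17)
  target <- random_dna(30L)
  five_off <- plant_mismatches(target, 5L)
  seven_off <- plant_mismatches(target, 7L)
  cand <- data.frame(gene_id = "g", start = c(0L, 40L),
                     sequence = c(target, random_dna(30L)),
                     gc_fraction = 0.5, junction_base = "C",
                     stringsAsFactors = FALSE)
  # identical in both species: kept with distances (0, 0)
  kept <- cross_species_filter(cand[1L, ],
                               list(mouse = paste0(random_dna(20L), target),
                                    rat = paste0(target, random_dna(20L))),
                               max_mismatches = 5L)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$dist_mouse, 0L)
  expect_equal(kept$dist_rat, 0L)
  # 5 mismatches passes at budget 5; 7 fails even though species A is exact
  k5 <- cross_species_filter(cand[1L, ], list(a = target, b = five_off), 5L)
  expect_equal(nrow(k5), 1L)
  expect_equal(k5$dist_b, 5L)
  k7 <- cross_species_filter(cand[1L, ], list(a = target, b = seven_off), 5L)
  expect_equal(nrow(k7), 0L)
  expect_error(cross_species_filter(cand, list()), "named list")
  expect_error(cross_species_filter(cand, list(a = character(0))), "missing")
})

test_that("cross-reactivity categories follow the distinct-genes-hit count", {
  set.seed(23)
  t1 <- random_dna(30L); t2 <- random_dna(30L); t3 <- random_dna(30L)
  foreign <- transcriptome(
    c(fa = paste0(random_dna(30L), t1, random_dna(30L)),
      fb = paste0(random_dna(10L), plant_mismatches(t2, 2L), random_dna(50L)),
      fc = paste0(plant_mismatches(t2, 5L), random_dna(60L)),
      fd = paste0(random_dna(45L), plant_mismatches(t3, 7L), random_dna(15L))),
    c("geneA", "geneB", "geneC", "geneD"))
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       sequence = c(t1, t2, t3), stringsAsFactors = FALSE)
  cls <- classify_cross_reactivity(probes, foreign, max_mismatches = 6L)
  expect_equal(cls$category, c("cross_reactive_specific",
                               "cross_reactive_nonspecific",
                               "non_cross_reactive"))
  expect_equal(cls$hit_gene_ids, c("geneA", "geneB,geneC", ""))
  expect_equal(unname(attr(cls, "summary")), c(1, 1, 1) / 3)
})

test_that("padlock arms reverse-complement their target halves", {
  set.seed(31)
  target <- paste0(strrep("A", 15L), "G", strrep("A", 14L))
  cand <- data.frame(gene_id = "g1", start = 0L, sequence = target,
                     gc_fraction = 1 / 30, junction_base = "G",
                     stringsAsFactors = FALSE)
  p <- assemble_padlock(cand, barcode_id = "b1")
  expect_equal(p$arm3, revcomp(substr(target, 1L, 15L)))
  expect_equal(p$arm5, revcomp(substr(target, 16L, 30L)))
  # empty backbones: full sequence is just arm5 then arm3
  expect_equal(p$full_sequence, paste0(p$arm5, p$arm3))
  # round trip: complementing the arms in probe order reconstructs the target
  expect_equal(paste0(revcomp(p$arm3), revcomp(p$arm5)), target)

  tpl <- probe_template(backbone5 = "TTGC", backbone3 = "CAAG",
                        barcodes = c(b1 = "ACTG"))
  p2 <- assemble_padlock(cand, "b1", tpl)
  expect_equal(p2$full_sequence, paste0(p$arm5, "TTGC", "ACTG", "CAAG", p$arm3))
  expect_error(assemble_padlock(cand, "missing", tpl), "absent")

  # same template, two genes: probes differ only in arms and barcode slot
  other <- random_dna(30L)
  cand2 <- within(cand, {sequence <- other; gene_id <- "g2"})
  tpl2 <- probe_template(backbone5 = "TTGC", backbone3 = "CAAG",
                         barcodes = c(b1 = "ACTG", b2 = "GTCA"))
  q1 <- assemble_padlock(cand, "b1", tpl2)
  q2 <- assemble_padlock(cand2, "b2", tpl2)
  expect_equal(q1$full_sequence,
               paste0(q1$arm5, "TTGC", "ACTG", "CAAG", q1$arm3))
  expect_equal(q2$full_sequence,
               paste0(q2$arm5, "TTGC", "GTCA", "CAAG", q2$arm3))
})

test_that("the full design cascade yields per-gene probes sharing a barcode", {
  tx <- make_random_transcriptome(4L, len = 600L, seed = 77L)
  cb <- build_codebook(names(tx), 4L, 2L, seed = 2L)
  res <- design_probes(tx, cb, n_targets = 3L, seed = 10L)
  expect_true(all(c("probe_id", "gene_id", "full_sequence", "barcode_id") %in%
                    names(res$probes)))
  for (g in unique(res$probes$gene_id)) {
    pg <- res$probes[res$probes$gene_id == g, ]
    expect_length(unique(pg$barcode_id), 1L)
    expect_true(all(diff(sort(pg$start)) >= 30L))
  }
  sheet <- tempfile(fileext = ".csv")
  write_order_sheet(res$probes, sheet)
  back <- utils::read.csv(sheet, stringsAsFactors = FALSE)
  expect_equal(back$full_sequence, res$probes$full_sequence)  # verbatim export
})
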