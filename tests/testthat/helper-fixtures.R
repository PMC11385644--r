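# Fixtures are generated in code; no binary data ships with the package.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Random multi-isoform transcriptome: isoform 1 of length `len`, isoform 2
# a 70% 5' truncation, so common 30-mers are the shared prefix windows.
make_random_transcriptome <- function(n_genes, len = 1000L, seed = 1L) {
  set.seed(seed)
  iso1 <- vapply(seq_len(n_genes), function(i) random_dna(len), "")
  iso2 <- substr(iso1, 1L, round(0.7 * len))
  ids <- paste0("g", seq_len(n_genes))
  isoforms <- c(iso1, iso2)
  names(isoforms) <- c(paste0(ids, "|i1"), paste0(ids, "|i2"))
  transcriptome(isoforms, rep(ids, 2L))
}

# Substitute exactly k positions of a DNA string (never to the same base).
plant_mismatches <- function(seq, k) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  paste(chars, collapse = "")
}

# Independent brute-force Hamming scan: every window of every isoform is
# compared position by position against every candidate; returns one key
# string per (candidate, window) pair within the budget. Deliberately
# avoids the package's search path (Biostrings pattern matching).
naive_hamming_keys <- function(cands, tx, max_mm) {
  enc <- function(s) match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
  k <- nchar(cands$sequence[1L])
  C <- vapply(cands$sequence, enc, integer(k), USE.NAMES = FALSE)
  keys <- character(0)
  for (g in names(tx)) {
    for (iso in names(tx[[g]]$isoforms)) {
      t_enc <- enc(tx[[g]]$isoforms[[iso]])
      nw <- length(t_enc) - k + 1L
      if (nw < 1L) next
      mm <- matrix(0L, nw, ncol(C))
      for (j in seq_len(k))
        mm <- mm + outer(t_enc[j:(j + nw - 1L)], C[j, ], "!=")
      w <- which(mm <= max_mm, arr.ind = TRUE)
      if (nrow(w))
        keys <- c(keys, paste(cands$gene_id[w[, 2L]], cands$start[w[, 2L]],
                              g, iso, w[, 1L] - 1L, mm[w]))
    }
  }
  sort(keys)
}

hit_keys <- function(hits) {
  sort(paste(hits$gene_id, hits$start, hits$subject_gene_id,
             hits$subject_isoform_id, hits$position, hits$mismatches))
}

# Small simulated dataset shared by imaging-stage unit tests.
make_mini_sim <- function(spot_count = 40L, noise_sd = 10, crosstalk = 0.05,
                          cycle_shifts = NULL, z_planes = 1L, seed = 11L,
                          tile = 128L, nuclei_count = 5L, cb_seed = 7L,
                          n_genes = 9L, ...) {
  cb <- build_codebook(paste0("g", seq_len(n_genes)), 4L, 2L, seed = cb_seed)
  cfg <- sim_config(tile_size = c(tile, tile), grid = c(2L, 2L),
                    spot_count = spot_count, noise_sd = noise_sd,
                    crosstalk = crosstalk, cycle_shifts = cycle_shifts,
                    z_planes = z_planes, nuclei_count = nuclei_count,
                    seed = seed, ...)
  c(simulate_dataset(cfg, cb), list(codebook = cb, config = cfg))
}

# Fraction of reads matching their true gene within `radius` px.
correct_fraction <- function(reads, truth, radius = 2) {
  if (nrow(reads) == 0L) return(NA_real_)
  m <- match_reads_to_truth(reads, truth$spots, radius)
  ok <- m$matched & reads$gene == truth$spots$gene[m$truth_idx]
  mean(ok, na.rm = FALSE)
}
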