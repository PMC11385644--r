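# Padlock probe design: 30-mer target slicing, GC / ligation-junction
# filters, mismatch-tolerant specificity screening, cross-species panels,
# and chimeric probe assembly.

#' Enumerate candidate 30-mer targets common to all isoforms of a gene
#'
#' Slices the representative (longest) isoform into all overlapping k-mers
#' (positions 1-30, 2-31, ...) and keeps those that occur as an exact
#' substring of every other isoform, so a probe designed on any candidate
#' binds all described isoforms. Windows containing masked bases (`N`) are
#' skipped.
#'
#' @param gene A `gene_record` (one element of a `transcriptome`).
#' @param k Target length in nt (default 30, the padlock arm pair length).
#' @return A data.frame of candidate targets with columns `gene_id`,
#'   `start` (0-based offset on the representative isoform), `sequence`,
#'   `gc_fraction`, and `junction_base` (the base at 1-based position
#'   `ceiling(k/2) + 1`, i.e. 16 for 30-mers, where the two probe arms are
#'   ligated). Empty (with a warning) if no isoform reaches length `k`.
#' @export
common_30mers <- function(gene, k = 30L) {
  .check(inherits(gene, "gene_record"), "gene must be a gene_record")
  lens <- nchar(gene$isoforms)
  empty <- data.frame(gene_id = character(), start = integer(),
                      sequence = character(), gc_fraction = numeric(),
                      junction_base = character(), stringsAsFactors = FALSE)
  if (max(lens) < k) {
    warning(sprintf("gene %s: all isoforms shorter than %d nt; no candidates",
                    gene$gene_id, k))
    return(empty)
  }
  rep_iso <- gene$isoforms[[which.max(lens)]]
  starts <- seq_len(nchar(rep_iso) - k + 1L)
  windows <- substring(rep_iso, starts, starts + k - 1L)
  keep <- !grepl("N", windows, fixed = TRUE)
  # intersect with the k-mer set of every other isoform
  others <- gene$isoforms[-which.max(lens)]
  for (iso in others) {
    if (nchar(iso) < k) {
      keep[] <- FALSE
      break
    }
    s2 <- seq_len(nchar(iso) - k + 1L)
    kmers <- unique(substring(iso, s2, s2 + k - 1L))
    keep <- keep & (windows %in% kmers)
  }
  if (!any(keep)) return(empty)
  jpos <- k %/% 2L + 1L
  data.frame(gene_id = gene$gene_id,
             start = starts[keep] - 1L,
             sequence = windows[keep],
             gc_fraction = .gc_fraction(windows[keep]),
             junction_base = substr(windows[keep], jpos, jpos),
             stringsAsFactors = FALSE)
}

#' Filter candidate targets by GC content
#'
#' Retains candidates whose GC fraction lies inside `[gc_min, gc_max]`
#' (inclusive). Balanced GC keeps both probe arms in a workable
#' hybridization regime.
#'
#' @param candidates Candidate data.frame from [common_30mers()].
#' @param gc_min,gc_max Inclusive bounds on GC fraction (defaults 0.40-0.60).
#' @return The filtered data.frame, input order preserved.
#' @export
filter_gc <- function(candidates, gc_min = 0.40, gc_max = 0.60) {
  .check(gc_min >= 0 && gc_min <= gc_max && gc_max <= 1,
         "need 0 <= gc_min <= gc_max <= 1")
  candidates[candidates$gc_fraction >= gc_min & candidates$gc_fraction <= gc_max, ,
             drop = FALSE]
}

#' Filter candidate targets by the ligation-junction base
#'
#' Keeps only targets with C or G at 1-based position 16 of the 30-mer, the
#' base flanking the junction where the two padlock arms are ligated; the
#' ligase requires a C/G there for efficient end-joining.
#'
#' @param candidates Candidate data.frame from [common_30mers()].
#' @return The filtered data.frame, input order preserved.
#' @export
filter_junction_base <- function(candidates) {
  candidates[candidates$junction_base %in% c("C", "G"), , drop = FALSE]
}

#' Screen candidate targets for off-target hits in a transcriptome
#'
#' Each candidate is searched against the sense strand of every isoform in
#' `tx`, reporting every window within `max_mismatches` substitutions
#' (Hamming distance). Candidates with at least one hit in a gene other
#' than their own are discarded; hits within the candidate's own gene are
#' reported but do not disqualify. The mismatch budget is deliberately
#' conservative: the RNA ligase tolerates some mismatches, so near-matches
#' are treated as potential off-targets.
#'
#' @param candidates Candidate data.frame (columns `gene_id`, `sequence`, ...).
#' @param tx A `transcriptome` to screen against.
#' @param max_mismatches Maximum substitutions for a reported hit (default 6).
#' @param with_indels If `TRUE`, hits are matched under edit distance
#'   (indels count toward the budget) instead of Hamming distance; off by
#'   default so the screen matches the substitution-only model.
#' @return A list with `candidates` (the surviving rows) and `hits`, a
#'   data.frame with one row per (candidate, transcript window) hit:
#'   `gene_id`, `start`, `sequence`, `subject_gene_id`, `subject_isoform_id`,
#'   `position` (0-based window start), `mismatches`.
#' @export
specificity_check <- function(candidates, tx, max_mismatches = 6L,
                              with_indels = FALSE) {
  .check(max_mismatches >= 0L && max_mismatches <= 29L,
         "max_mismatches must be in [0, 29]")
  flat <- .flatten_transcriptome(tx)
  .check(length(flat$seq) > 0L, "empty transcriptome")
  subjects <- Biostrings::DNAStringSet(flat$seq)
  hits <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    pat <- Biostrings::DNAString(candidates$sequence[i])
    m <- Biostrings::vmatchPattern(pat, subjects,
                                   max.mismatch = max_mismatches,
                                   with.indels = with_indels)
    nh <- S4Vectors::elementNROWS(m)
    if (sum(nh) == 0L) next
    idx <- rep(seq_along(subjects), nh)
    starts <- unlist(Biostrings::startIndex(m), use.names = FALSE)
    starts <- starts[!is.na(starts)]
    mm <- mapply(function(si, st) {
      # substitution count of the un-gapped alignment starting at the hit;
      # in indel mode this upper-bounds the edit distance of the hit
      min(Biostrings::neditStartingAt(pat, subjects[[si]], starting.at = st),
          max_mismatches)
    }, idx, starts)
    hits[[i]] <- data.frame(
      gene_id = candidates$gene_id[i],
      start = candidates$start[i],
      sequence = candidates$sequence[i],
      subject_gene_id = flat$gene[idx],
      subject_isoform_id = names(flat$seq)[idx],
      position = as.integer(starts) - 1L,
      mismatches = as.integer(mm),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(hits[!vapply(hits, is.null, TRUE)],
                           list(.empty_hits())))
  key <- paste(candidates$gene_id, candidates$start, candidates$sequence)
  foreign <- unique(paste(hits$gene_id, hits$start, hits$sequence)[
    hits$subject_gene_id != hits$gene_id])
  list(candidates = candidates[!(key %in% foreign), , drop = FALSE],
       hits = hits)
}

.empty_hits <- function() {
  data.frame(gene_id = character(), start = integer(), sequence = character(),
             subject_gene_id = character(), subject_isoform_id = character(),
             position = integer(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

#' Choose a spread-out, non-overlapping subset of targets
#'
#' Picks up to `n` candidates that do not overlap on the representative
#' isoform (pairwise start difference at least the target length) and span
#' the transcript: the candidate span is divided into `n` equal bins, one
#' candidate is drawn at random from each bin, overlaps are resolved
#' greedily left-to-right, and remaining slots are topped up from the
#' leftover candidates in seeded random order. Deterministic for a fixed
#' seed and invariant to the input ordering of `candidates`.
#'
#' @param candidates Candidate data.frame with `start` and `sequence`.
#' @param n Number of targets to select (default 5).
#' @param seed Integer seed for the random draws.
#' @return A data.frame of at most `n` selected candidates ordered by
#'   `start`; a warning is issued when fewer than `n` can be placed.
#' @export
select_targets <- function(candidates, n = 5L, seed = 1L) {
  .check(n >= 1L, "n must be >= 1")
  if (nrow(candidates) == 0L) {
    warning("no candidates to select from")
    return(candidates)
  }
  k <- nchar(candidates$sequence[1L])
  cand <- candidates[order(candidates$start), , drop = FALSE]
  cand <- cand[!duplicated(cand$start), , drop = FALSE]
  lo <- min(cand$start)
  hi <- max(cand$start) + k
  edges <- seq(lo, hi, length.out = n + 1L)
  bin <- pmin(findInterval(cand$start, edges, rightmost.closed = TRUE), n)
  picked <- with_seed(seed, {
    first <- vapply(seq_len(n), function(b) {
      in_bin <- which(bin == b)
      if (length(in_bin) == 0L) NA_integer_
      else in_bin[sample.int(length(in_bin), 1L)]
    }, 0L)
    first <- sort(first[!is.na(first)])
    kept <- integer(0)
    for (i in first) {
      if (length(kept) == 0L || all(abs(cand$start[i] - cand$start[kept]) >= k))
        kept <- c(kept, i)
    }
    rest <- sample(setdiff(seq_len(nrow(cand)), kept))
    for (i in rest) {
      if (length(kept) >= n) break
      if (all(abs(cand$start[i] - cand$start[kept]) >= k))
        kept <- c(kept, i)
    }
    sort(kept)
  })
  if (length(picked) < n)
    warning(sprintf("only %d non-overlapping target(s) could be selected (requested %d)",
                    length(picked), n))
  cand[picked, , drop = FALSE]
}

#' Keep targets conserved across species orthologs
#'
#' For cross-reactive panels, retains candidates that have at least one
#' window within `max_mismatches` substitutions in the ortholog sequence(s)
#' of every listed species, and annotates the best (minimum) per-species
#' Hamming distance as columns `dist_<species>`.
#'
#' The conservation threshold is a parameter because two conventions are in
#' use: strictly fewer than six differences (`max_mismatches = 5`) and a
#' tolerance of six mismatches (`max_mismatches = 6`).
#'
#' @param candidates Candidate data.frame.
#' @param ortholog_sequences Named list: species -> character vector of
#'   ortholog transcript sequences.
#' @param max_mismatches Per-species Hamming budget (default 5).
#' @return The retained candidates with per-species distance columns.
#' @export
cross_species_filter <- function(candidates, ortholog_sequences,
                                 max_mismatches = 5L) {
  .check(is.list(ortholog_sequences) && length(ortholog_sequences) > 0L &&
           !is.null(names(ortholog_sequences)),
         "ortholog_sequences must be a non-empty named list (species -> sequences)")
  for (sp in names(ortholog_sequences)) {
    seqs <- chartr("U", "T", toupper(unlist(ortholog_sequences[[sp]])))
    .check(length(seqs) > 0L && all(nzchar(seqs)),
           sprintf("missing ortholog sequence for species '%s'", sp))
    d <- vapply(candidates$sequence, min_hamming, 0L, subjects = seqs,
                USE.NAMES = FALSE)
    candidates[[paste0("dist_", sp)]] <- d
  }
  dist_cols <- paste0("dist_", names(ortholog_sequences))
  ok <- rowSums(as.matrix(candidates[dist_cols]) <= max_mismatches,
                na.rm = FALSE) == length(dist_cols)
  ok[is.na(ok)] <- FALSE
  candidates[ok, , drop = FALSE]
}

#' Classify probes by cross-reactivity against a foreign transcriptome
#'
#' Searches each probe's target against the transcriptome of another
#' species (same mismatch-tolerant scan as [specificity_check()]) and
#' assigns one of three categories by the number of distinct genes hit:
#' exactly one gene -> `cross_reactive_specific`; more than one ->
#' `cross_reactive_nonspecific`; none -> `non_cross_reactive`.
#'
#' @param probes Data.frame with `probe_id` and target `sequence` columns
#'   (e.g. the order sheet from [design_probes()], or candidates with a
#'   `probe_id` added).
#' @param foreign_tx A `transcriptome` for the other species.
#' @param max_mismatches Hamming budget for a hit (default 6).
#' @return A data.frame `probe_id`, `category`, `n_genes_hit`,
#'   `hit_gene_ids` (comma-separated), with a `summary` attribute giving
#'   the fraction of probes per category.
#' @export
classify_cross_reactivity <- function(probes, foreign_tx, max_mismatches = 6L) {
  .check(all(c("probe_id", "sequence") %in% names(probes)),
         "probes needs columns probe_id and sequence")
  flat <- .flatten_transcriptome(foreign_tx)
  subjects <- Biostrings::DNAStringSet(flat$seq)
  res <- lapply(seq_len(nrow(probes)), function(i) {
    m <- Biostrings::vmatchPattern(Biostrings::DNAString(probes$sequence[i]),
                                   subjects, max.mismatch = max_mismatches)
    genes <- sort(unique(flat$gene[S4Vectors::elementNROWS(m) > 0L]))
    data.frame(probe_id = probes$probe_id[i],
               category = if (length(genes) == 0L) "non_cross_reactive"
                          else if (length(genes) == 1L) "cross_reactive_specific"
                          else "cross_reactive_nonspecific",
               n_genes_hit = length(genes),
               hit_gene_ids = paste(genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  tab <- table(factor(out$category,
                      levels = c("cross_reactive_specific",
                                 "cross_reactive_nonspecific",
                                 "non_cross_reactive")))
  attr(out, "summary") <- as.numeric(tab) / max(1L, nrow(out))
  names(attr(out, "summary")) <- names(tab)
  out
}

#' Probe template configuration
#'
#' Describes how a chimeric padlock probe sequence is assembled around its
#' two target-complementary arms. The layout string contains the slots
#' `{arm5}`, `{backbone5}`, `{barcode}`, `{backbone3}`, `{arm3}`; the 5'
#' arm is the reverse complement of target nt 16-30 and the 3' arm of
#' target nt 1-15, so that the two arms hybridize adjacently and the probe
#' ends meet at the ligation junction. Backbones and the barcode library
#' default to empty (panel-specific anchor/backbone sequences are supplied
#' per experiment).
#'
#' @param layout Template string with slots (default
#'   `"{arm5}{backbone5}{barcode}{backbone3}{arm3}"`).
#' @param backbone5,backbone3 Constant backbone sequences (default `""`).
#' @param barcodes Named character vector mapping `barcode_id` to the
#'   barcode anchor sequence inserted in the `{barcode}` slot, or `NULL`
#'   (slot left empty, id recorded as metadata only).
#' @param phosphorylated Logical metadata flag: padlocks need a 5'
#'   phosphate for ligation (default `TRUE`).
#' @return A list of class `probe_template`.
#' @export
probe_template <- function(layout = "{arm5}{backbone5}{barcode}{backbone3}{arm3}",
                           backbone5 = "", backbone3 = "",
                           barcodes = NULL, phosphorylated = TRUE) {
  structure(list(layout = layout, backbone5 = backbone5,
                 backbone3 = backbone3, barcodes = barcodes,
                 phosphorylated = phosphorylated),
            class = "probe_template")
}

#' Assemble a chimeric padlock probe for one target
#'
#' Builds the probe sequence from a candidate target: the 3' arm is the
#' reverse complement of target nt 1-15 and the 5' arm of nt 16-30, so
#' both arms hybridize adjacently on the mRNA with the ligatable ends at
#' the junction, and the template's backbone/barcode slots are filled in.
#'
#' @param target One-row candidate data.frame (or list) with `gene_id`,
#'   `start`, `sequence`.
#' @param barcode_id Identifier of the gene's barcode.
#' @param template A [probe_template()].
#' @param probe_id Optional probe identifier (default
#'   `"<gene>_<start>"`).
#' @return A one-row data.frame: `probe_id`, `gene_id`, `start`,
#'   `target_sequence`, `arm5`, `arm3`, `barcode_id`, `full_sequence`,
#'   `phosphorylated`.
#' @export
assemble_padlock <- function(target, barcode_id, template = probe_template(),
                             probe_id = NULL) {
  seqv <- target$sequence
  .check(length(seqv) == 1L, "assemble_padlock takes a single target")
  k <- nchar(seqv)
  half <- k %/% 2L
  arm3 <- revcomp(substr(seqv, 1L, half))
  arm5 <- revcomp(substr(seqv, half + 1L, k))
  bc <- ""
  if (!is.null(template$barcodes)) {
    .check(barcode_id %in% names(template$barcodes),
           sprintf("barcode_id '%s' absent from barcode library", barcode_id))
    bc <- unname(template$barcodes[[barcode_id]])
  }
  full <- template$layout
  slots <- c(arm5 = arm5, backbone5 = template$backbone5, barcode = bc,
             backbone3 = template$backbone3, arm3 = arm3)
  for (s in names(slots))
    full <- gsub(paste0("{", s, "}"), slots[[s]], full, fixed = TRUE)
  .check(!grepl("\\{[a-z0-9]+\\}", full),
         sprintf("unfilled template slot in layout '%s'", template$layout))
  data.frame(probe_id = if (is.null(probe_id))
               paste0(target$gene_id, "_", target$start) else probe_id,
             gene_id = target$gene_id, start = target$start,
             target_sequence = seqv, arm5 = arm5, arm3 = arm3,
             barcode_id = barcode_id, full_sequence = full,
             phosphorylated = isTRUE(template$phosphorylated),
             stringsAsFactors = FALSE)
}

#' Design a padlock probe panel for a set of genes
#'
#' Runs the full design cascade per gene: enumerate isoform-common 30-mers,
#' filter by GC content and the C/G ligation-junction rule, discard targets
#' with off-target hits elsewhere in the transcriptome, select a spread-out
#' non-overlapping subset, and assemble one probe per selected target, all
#' probes of a gene sharing the gene's barcode.
#'
#' @param tx A `transcriptome`.
#' @param codebook A `codebook` assigning each gene a barcode id (gene
#'   names are used as barcode ids); genes absent from the codebook get
#'   barcode id `NA`.
#' @param genes Genes to design for (default: all genes in `tx`).
#' @param n_targets Probes per gene (default 5).
#' @param gc_min,gc_max GC bounds (defaults 0.40-0.60).
#' @param max_mismatches Specificity budget (default 6).
#' @param template A [probe_template()].
#' @param seed Integer seed for target selection.
#' @return A list with `probes` (order-sheet data.frame), `hits` (the
#'   specificity report), and `per_gene` (candidate counts surviving each
#'   filter stage).
#' @export
design_probes <- function(tx, codebook = NULL, genes = names(tx),
                          n_targets = 5L, gc_min = 0.40, gc_max = 0.60,
                          max_mismatches = 6L, template = probe_template(),
                          seed = 1L) {
  probes <- list()
  hits <- list()
  stages <- list()
  for (g in genes) {
    .check(g %in% names(tx), sprintf("gene '%s' not in transcriptome", g))
    cand <- common_30mers(tx[[g]])
    n0 <- nrow(cand)
    cand <- filter_junction_base(filter_gc(cand, gc_min, gc_max))
    n1 <- nrow(cand)
    spec <- specificity_check(cand, tx, max_mismatches = max_mismatches)
    hits[[g]] <- spec$hits
    n2 <- nrow(spec$candidates)
    sel <- if (n2 > 0L) select_targets(spec$candidates, n = n_targets,
                                       seed = seed + match(g, genes))
           else spec$candidates
    stages[[g]] <- data.frame(gene_id = g, n_common = n0, n_filtered = n1,
                              n_specific = n2, n_selected = nrow(sel),
                              stringsAsFactors = FALSE)
    bc <- if (!is.null(codebook) && g %in% names(codebook$entries)) g
          else NA_character_
    if (nrow(sel) > 0L)
      probes[[g]] <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i)
        assemble_padlock(sel[i, ], barcode_id = bc, template = template)))
  }
  list(probes = if (length(probes)) do.call(rbind, c(probes, list(make.row.names = FALSE)))
                else NULL,
       hits = do.call(rbind, c(hits, list(make.row.names = FALSE))),
       per_gene = do.call(rbind, c(stages, list(make.row.names = FALSE))))
}

#' Write a probe order sheet to CSV
#'
#' @param probes Probe data.frame from [design_probes()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_order_sheet <- function(probes, path) {
  utils::write.csv(probes[, c("probe_id", "gene_id", "start", "full_sequence",
                              "barcode_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
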