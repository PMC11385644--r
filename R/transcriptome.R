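#' Load a transcriptome FASTA grouped by gene
#'
#' Reads a multi-isoform transcriptome FASTA and groups isoforms into gene
#' records. The gene identifier is taken from a token of the FASTA header
#' (split on `header_sep`, token `gene_field`), or from an explicit
#' isoform-to-gene map. Sequences are normalized to uppercase DNA with U
#' mapped to T. Ambiguity codes (anything outside A/C/G/T) are an error
#' unless `mask_ambiguous = TRUE`, in which case they are kept as `N` and
#' candidate windows containing them are skipped downstream.
#'
#' @param path Path to a FASTA file.
#' @param gene_map Optional data.frame with columns `isoform_id`, `gene_id`
#'   overriding header-based grouping, or a path to a TSV with those columns.
#' @param header_sep Separator used to split FASTA headers (default `"|"`).
#' @param gene_field 1-based index of the header token holding the gene id.
#' @param mask_ambiguous If `TRUE`, non-ACGT letters are masked to `N`
#'   instead of raising an error.
#' @return An object of class `transcriptome`: a named list of gene records,
#'   each a list with `gene_id` and `isoforms` (a named character vector of
#'   sequences, names are isoform ids).
#' @export
load_transcriptome <- function(path, gene_map = NULL, header_sep = "|",
                               gene_field = 1L, mask_ambiguous = FALSE) {
  .check(file.exists(path), sprintf("FASTA file not found: %s", path))
  raw <- Biostrings::readBStringSet(path)
  .check(length(raw) > 0L, sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(raw))
  .check(!anyDuplicated(ids), "duplicate isoform ids in FASTA")
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    if (mask_ambiguous) {
      seqs[bad] <- gsub("[^ACGT]", "N", seqs[bad])
    } else {
      stop(sprintf("non-ACGT characters in isoform(s) %s (set mask_ambiguous = TRUE to mask)",
                   paste(utils::head(ids[bad], 3L), collapse = ", ")), call. = FALSE)
    }
  }
  names(seqs) <- ids

  if (is.null(gene_map)) {
    genes <- vapply(strsplit(ids, header_sep, fixed = TRUE), function(tok) {
      .check(length(tok) >= gene_field,
             sprintf("header '%s' has no token %d (separator '%s')",
                     tok[1L], gene_field, header_sep))
      tok[gene_field]
    }, "")
  } else {
    if (is.character(gene_map) && length(gene_map) == 1L) {
      gene_map <- utils::read.delim(gene_map, stringsAsFactors = FALSE)
    }
    .check(all(c("isoform_id", "gene_id") %in% names(gene_map)),
           "gene_map needs columns isoform_id and gene_id")
    idx <- match(ids, gene_map$isoform_id)
    .check(!anyNA(idx), "gene_map is missing some isoforms present in the FASTA")
    genes <- gene_map$gene_id[idx]
  }

  records <- lapply(split(seq_along(ids), genes), function(i) {
    structure(list(gene_id = genes[i[1L]], isoforms = seqs[i]),
              class = "gene_record")
  })
  structure(records[unique(genes)], class = "transcriptome")
}

#' Construct a transcriptome object from in-memory sequences
#'
#' Convenience constructor used in examples, simulations and tests.
#'
#' @param isoforms Named character vector of isoform sequences.
#' @param gene_ids Character vector, same length, assigning each isoform to
#'   a gene.
#' @return A `transcriptome` object (see [load_transcriptome()]).
#' @export
transcriptome <- function(isoforms, gene_ids) {
  .check(length(isoforms) == length(gene_ids),
         "isoforms and gene_ids must have equal length")
  .check(!is.null(names(isoforms)) && !anyDuplicated(names(isoforms)),
         "isoforms must be uniquely named")
  seqs <- chartr("U", "T", toupper(isoforms))
  .check(!any(grepl("[^ACGTN]", seqs)), "sequences must be over A/C/G/T/N (U allowed)")
  records <- lapply(split(seq_along(seqs), gene_ids), function(i) {
    structure(list(gene_id = gene_ids[i[1L]], isoforms = seqs[i]),
              class = "gene_record")
  })
  structure(records[unique(gene_ids)], class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  n_iso <- sum(vapply(x, function(g) length(g$isoforms), 0L))
  cat(sprintf("<transcriptome> %d gene(s), %d isoform(s)\n", length(x), n_iso))
  invisible(x)
}

# All isoforms of a transcriptome as one named character vector, with a
# parallel gene-id vector. Used by the specificity scanner.
.flatten_transcriptome <- function(tx) {
  iso <- unlist(lapply(tx, function(g) g$isoforms))
  gene <- rep(vapply(tx, function(g) g$gene_id, ""),
              vapply(tx, function(g) length(g$isoforms), 0L))
  names(iso) <- unlist(lapply(tx, function(g) names(g$isoforms)), use.names = FALSE)
  list(seq = iso, gene = unname(gene))
}
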