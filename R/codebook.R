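# Combinatorial barcode codebooks: gene -> per-cycle color sequence.
# With x fluorophores read over N cycles the code space holds x^N barcodes.

#' Combinatorial barcode capacity
#'
#' Number of distinct barcodes available with `channels` fluorophores read
#' over `cycles` imaging cycles: `channels ^ cycles`.
#'
#' @param channels Number of detection fluorophores x (>= 1).
#' @param cycles Number of imaging cycles N (>= 1).
#' @return Integer-valued numeric `channels ^ cycles`.
#' @export
#' @examples
#' capacity(4, 4) # 256 genes with 4 colors over 4 cycles
capacity <- function(channels, cycles) {
  .check(channels >= 1L && cycles >= 1L,
         "channels and cycles must be positive integers")
  as.numeric(channels)^as.numeric(cycles)
}

#' Build a codebook assigning a distinct barcode to each gene
#'
#' Assigns every gene a distinct color sequence (one channel index per
#' cycle) drawn from the full code space in seeded random order. Genes are
#' sorted before assignment, so the result does not depend on the input
#' ordering. An optional minimum pairwise Hamming distance between
#' barcodes adds error-tolerant spacing (the default 1 is plain
#' uniqueness).
#'
#' @param gene_ids Character vector of gene identifiers (unique).
#' @param channels Number of fluorophores x.
#' @param cycles Number of cycles N.
#' @param min_pairwise_distance Minimum Hamming distance between any two
#'   assigned barcodes (default 1).
#' @param seed Integer seed.
#' @param channel_names Optional fluorophore labels (length `channels`).
#' @return An object of class `codebook`: list with `channels`, `cycles`,
#'   `channel_names`, and `entries`, a named list mapping each gene to an
#'   integer vector of 0-based channel indices of length `cycles`.
#' @export
build_codebook <- function(gene_ids, channels, cycles,
                           min_pairwise_distance = 1L, seed = 1L,
                           channel_names = NULL) {
  .check(!anyDuplicated(gene_ids), "gene_ids must be unique")
  .check(min_pairwise_distance >= 1L && min_pairwise_distance <= cycles,
         "min_pairwise_distance must be in [1, cycles]")
  cap <- capacity(channels, cycles)
  n <- length(gene_ids)
  if (n > cap)
    stop(sprintf("infeasible: %d genes exceed the code capacity %d^%d = %s",
                 n, channels, cycles, format(cap, big.mark = ",")),
         call. = FALSE)
  .check(cap <= 2^20, "code space too large to enumerate (channels^cycles > 2^20)")
  # all barcodes as rows, 0-based channel indices
  space <- as.matrix(expand.grid(rep(list(0:(channels - 1L)), cycles),
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(space) <- NULL
  ord <- with_seed(seed, sample.int(nrow(space)))
  space <- space[ord, , drop = FALSE]
  chosen <- matrix(0L, 0L, cycles)
  for (i in seq_len(nrow(space))) {
    if (nrow(chosen) == n) break
    b <- space[i, ]
    if (nrow(chosen) == 0L ||
        min(rowSums(chosen != matrix(b, nrow(chosen), cycles, byrow = TRUE))) >=
          min_pairwise_distance)
      chosen <- rbind(chosen, b)
  }
  if (nrow(chosen) < n)
    stop(sprintf("infeasible: only %d barcode(s) satisfy min pairwise distance %d for %d gene(s)",
                 nrow(chosen), min_pairwise_distance, n), call. = FALSE)
  genes <- sort(gene_ids)
  entries <- lapply(seq_len(n), function(i) as.integer(chosen[i, ]))
  names(entries) <- genes
  if (is.null(channel_names))
    channel_names <- .default_channel_names(channels)
  .check(length(channel_names) == channels,
         "channel_names must have length `channels`")
  structure(list(channels = as.integer(channels), cycles = as.integer(cycles),
                 channel_names = channel_names, entries = entries),
            class = "codebook")
}

# Default four-channel alphabet named after common detection fluorophores.
.default_channel_names <- function(channels) {
  base <- c("AF488", "Cy3", "Cy5", "AF750", "Atto425", "AF594")
  if (channels <= length(base)) base[seq_len(channels)]
  else paste0("ch", seq_len(channels) - 1L)
}

#' Construct a codebook from explicit entries
#'
#' @param entries Named list: gene -> integer vector of 0-based channel
#'   indices, all of length `cycles`.
#' @param channels,cycles Code dimensions.
#' @param channel_names Optional fluorophore labels.
#' @return A validated `codebook`.
#' @export
codebook <- function(entries, channels, cycles, channel_names = NULL) {
  if (is.null(channel_names))
    channel_names <- .default_channel_names(channels)
  cb <- structure(list(channels = as.integer(channels),
                       cycles = as.integer(cycles),
                       channel_names = channel_names,
                       entries = lapply(entries, as.integer)),
                  class = "codebook")
  validate_codebook(cb)
  cb
}

#' Validate codebook invariants
#'
#' Checks that every barcode has one channel index per cycle, indices lie
#' in `[0, channels)`, genes are unique, and barcodes are pairwise
#' distinct.
#'
#' @param cb A `codebook`.
#' @return `cb` invisibly; errors describe the first violated invariant.
#' @export
validate_codebook <- function(cb) {
  .check(inherits(cb, "codebook"), "not a codebook")
  .check(!anyDuplicated(names(cb$entries)), "duplicate gene in codebook")
  lens <- vapply(cb$entries, length, 0L)
  if (any(lens != cb$cycles))
    stop(sprintf("barcode for gene '%s' has length %d, expected %d cycle(s)",
                 names(cb$entries)[lens != cb$cycles][1L],
                 lens[lens != cb$cycles][1L], cb$cycles), call. = FALSE)
  vals <- unlist(cb$entries, use.names = FALSE)
  .check(all(vals >= 0L & vals < cb$channels),
         sprintf("channel index out of range [0, %d)", cb$channels))
  keys <- vapply(cb$entries, paste, "", collapse = ",")
  if (anyDuplicated(keys)) {
    dup <- names(cb$entries)[duplicated(keys) | duplicated(keys, fromLast = TRUE)]
    stop(sprintf("duplicate barcode shared by genes: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  .check(length(cb$channel_names) == cb$channels,
         "channel_names length must equal channels")
  invisible(cb)
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> %d gene(s), %d channel(s) x %d cycle(s) (capacity %s)\n",
              length(x$entries), x$channels, x$cycles,
              format(capacity(x$channels, x$cycles), big.mark = ",")))
  invisible(x)
}

#' Save a codebook as JSON
#'
#' Serialization is byte-stable for a given codebook: genes are written in
#' sorted order.
#'
#' @param cb A `codebook`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_codebook <- function(cb, path) {
  validate_codebook(cb)
  obj <- list(channels = cb$channels, cycles = cb$cycles,
              channel_names = cb$channel_names,
              entries = cb$entries[order(names(cb$entries))])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a codebook from JSON
#'
#' @param path Path to a JSON codebook written by [save_codebook()].
#' @return A validated `codebook`.
#' @export
load_codebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  .check(all(c("channels", "cycles", "entries") %in% names(obj)),
         "codebook JSON needs fields channels, cycles, entries")
  codebook(entries = lapply(obj$entries, as.integer),
           channels = obj$channels, cycles = obj$cycles,
           channel_names = obj$channel_names)
}

#' Read a codebook from a CSV of per-cycle color letters
#'
#' Accepts a two-column CSV (`gene`, `code`) where `code` spells one
#' channel letter per cycle (e.g. `"GR"` = green then red). Letters map to
#' channel indices via `channel_letters`.
#'
#' @param path CSV path.
#' @param channel_letters Character vector: position i is the letter of
#'   channel index i-1 (default `c("A","C","G","T")`-style four letters
#'   `c("B","G","O","R")` for blue/green/orange/red dyes).
#' @param channel_names Optional fluorophore labels.
#' @return A validated `codebook`.
#' @export
read_codebook_csv <- function(path, channel_letters = c("B", "G", "O", "R"),
                              channel_names = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check(all(c("gene", "code") %in% names(df)),
         "codebook CSV needs columns gene, code")
  cycles <- nchar(df$code[1L])
  entries <- lapply(strsplit(toupper(df$code), ""), function(letters) {
    idx <- match(letters, channel_letters) - 1L
    .check(!anyNA(idx), sprintf("unknown channel letter in code '%s'",
                                paste(letters, collapse = "")))
    idx
  })
  names(entries) <- df$gene
  codebook(entries, channels = length(channel_letters), cycles = cycles,
           channel_names = channel_names)
}
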