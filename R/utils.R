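# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not perturb user scripts.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Reverse-complement of DNA character strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode an A/C/G/T string as integers 1..4 (0 for anything else).
.dna_int <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"), nomatch = 0L)
}

#' Minimum Hamming distance of a query against all windows of subjects
#'
#' Scans every length-`nchar(query)` window of every subject sequence on the
#' sense strand and returns the smallest Hamming distance found. Used for
#' cross-species conservation screening, where the best distance is needed
#' even when it exceeds the acceptance threshold.
#'
#' @param query A single DNA string.
#' @param subjects Character vector of subject sequences.
#' @return Integer: the minimum Hamming distance over all windows, or `NA`
#'   if no subject is at least as long as the query.
#' @export
min_hamming <- function(query, subjects) {
  k <- nchar(query)
  q <- .dna_int(query)
  best <- NA_integer_
  for (s in subjects) {
    L <- nchar(s)
    if (L < k) next
    t <- .dna_int(s)
    nw <- L - k + 1L
    mm <- integer(nw)
    for (j in seq_len(k)) {
      mm <- mm + (t[j:(j + nw - 1L)] != q[j])
    }
    m <- min(mm)
    if (is.na(best) || m < best) best <- m
  }
  best
}

# GC fraction of fixed-length windows, vectorized over a character vector.
.gc_fraction <- function(seqs) {
  (nchar(seqs) - nchar(gsub("[GC]", "", seqs))) / nchar(seqs)
}

# stopifnot-style check with a readable message
.check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
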