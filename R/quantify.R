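# Cell-level quantification: classical nuclei segmentation, label
# expansion to approximate cytoplasm, read-to-cell assignment, and export
# of a cell-by-gene count matrix. External segmenters (e.g. deep-learning
# tools) can be plugged in by supplying any integer label image in place
# of the built-in watershed mask.

#' Segment nuclei with a classical watershed pipeline
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, and a
#' distance-transform watershed to split touching nuclei, followed by a
#' minimum-area filter. Deterministic and dependency-light; for difficult
#' tissue, substitute a mask from any external segmenter via
#' [label_mask()].
#'
#' @param nuclei_image 2D numeric matrix (the nuclei channel).
#' @param smooth_sigma Gaussian sigma in px (default 2).
#' @param min_area Minimum object area in px (default 50).
#' @param watershed_tolerance Height tolerance for the watershed split
#'   (default 1).
#' @return A `label_mask`: list with `mask` (integer matrix, 0 =
#'   background, labels 1..K) and `cells` (data.frame `cell_id`, `cx`,
#'   `cy` 0-based centroids, `area`).
#' @export
segment_nuclei <- function(nuclei_image, smooth_sigma = 2, min_area = 50,
                           watershed_tolerance = 1) {
  img <- nuclei_image / max(nuclei_image, 1)
  if (max(img) == min(img)) return(label_mask(matrix(0L, nrow(img), ncol(img))))
  sm <- EBImage::gblur(img, smooth_sigma)
  thr <- EBImage::otsu(EBImage::Image(sm))
  bw <- sm > thr
  if (!any(bw)) return(label_mask(matrix(0L, nrow(img), ncol(img))))
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  mask <- matrix(as.integer(labels), nrow(img), ncol(img))
  areas <- tabulate(mask)
  small <- which(areas < min_area)
  if (length(small) > 0L) mask[mask %in% small] <- 0L
  label_mask(mask)
}

#' Construct a label mask from an integer label image
#'
#' Relabels objects contiguously 1..K and computes per-label centroids and
#' areas. Accepts masks from the built-in segmentation or from external
#' tools (any integer-label image, e.g. a label TIFF).
#'
#' @param mask Integer matrix; 0 = background.
#' @return A list of class `label_mask`: `mask`, `cells` (data.frame
#'   `cell_id`, `cx`, `cy`, `area`; coordinates 0-based, x = column).
#' @export
label_mask <- function(mask) {
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  old <- sort(unique(mask[mask > 0L]))
  relab <- integer(max(mask, 1L))
  relab[old] <- seq_along(old)
  mask[mask > 0L] <- relab[mask[mask > 0L]]
  if (length(old) == 0L) {
    cells <- data.frame(cell_id = integer(0), cx = numeric(0),
                        cy = numeric(0), area = integer(0))
  } else {
    idx <- which(mask > 0L, arr.ind = TRUE)
    lab <- mask[idx]
    cells <- data.frame(
      cell_id = seq_along(old),
      cx = as.numeric(tapply(idx[, 2L] - 1L, lab, mean)),
      cy = as.numeric(tapply(idx[, 1L] - 1L, lab, mean)),
      area = as.integer(tabulate(lab, nbins = length(old))))
  }
  structure(list(mask = mask, cells = cells), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d cell(s)\n",
              nrow(x$mask), ncol(x$mask), nrow(x$cells)))
  invisible(x)
}

#' Expand labels outward to approximate cell extent
#'
#' Grows every label by up to `radius` pixels into the background without
#' crossing another label: each background pixel within `radius` of the
#' mask is assigned to its nearest label (Voronoi growth via seeded
#' propagation). Original labeled pixels are never reassigned, and the
#' expansion is monotone in `radius`.
#'
#' @param lm A `label_mask`.
#' @param radius Expansion radius in px (default 10; 0 returns the input).
#' @return A new `label_mask` with expanded labels (centroids/areas
#'   recomputed; original label identities preserved).
#' @export
expand_labels <- function(lm, radius = 10) {
  .check(radius >= 0, "radius must be >= 0")
  if (radius == 0 || nrow(lm$cells) == 0L) return(lm)
  mask <- lm$mask
  dist_bg <- EBImage::distmap(mask == 0L)   # distance of background px to mask
  region <- mask > 0L | dist_bg <= radius
  grown <- EBImage::propagate(EBImage::Image(mask * 0),
                              seeds = EBImage::Image(mask),
                              mask = region, lambda = 1e8)
  grown <- matrix(as.integer(grown), nrow(mask), ncol(mask))
  grown[mask > 0L] <- mask[mask > 0L]
  out <- label_mask(grown)
  # label_mask() relabels contiguously; original labels already are, so the
  # identity mapping is preserved
  out
}

#' Assign decoded reads to cells
#'
#' Looks up the label under each read's rounded pixel position; 0 means
#' unassigned (background). Out-of-bounds reads are kept, assigned 0,
#' with a warning.
#'
#' @param reads Read-table data.frame with `x`, `y` (0-based global px).
#' @param lm A `label_mask` (typically expanded; see [expand_labels()]).
#' @return `reads` with a `cell_id` column added.
#' @export
assign_reads <- function(reads, lm) {
  ry <- as.integer(round(reads$y)) + 1L
  rx <- as.integer(round(reads$x)) + 1L
  oob <- ry < 1L | ry > nrow(lm$mask) | rx < 1L | rx > ncol(lm$mask)
  if (any(oob))
    warning(sprintf("%d read(s) outside the mask bounds left unassigned",
                    sum(oob)))
  cell <- integer(nrow(reads))
  cell[!oob] <- lm$mask[cbind(ry[!oob], rx[!oob])]
  reads$cell_id <- cell
  reads
}

#' Build a cell-by-gene count matrix from assigned reads
#'
#' Aggregates reads with `cell_id > 0` and a decoded gene (`NO_MATCH`
#' excluded) into a sparse cells x genes count matrix with per-cell
#' metadata.
#'
#' @param reads Read table with `cell_id` and `gene` columns.
#' @param lm The `label_mask` used for assignment (defines the cell rows).
#' @param genes Gene universe for the columns (default: genes observed in
#'   `reads`; pass `names(codebook$entries)` for a fixed panel).
#' @return A list of class `cell_by_gene`: `counts` (sparse dgCMatrix,
#'   cells x genes), `cells` (metadata: centroid, area, total reads),
#'   `genes` (data.frame with per-gene totals).
#' @export
cell_by_gene <- function(reads, lm, genes = NULL) {
  ok <- reads$cell_id > 0L & reads$gene != NO_MATCH
  if (is.null(genes)) genes <- sort(unique(reads$gene[reads$gene != NO_MATCH]))
  n_cells <- nrow(lm$cells)
  counts <- Matrix::sparseMatrix(
    i = reads$cell_id[ok], j = match(reads$gene[ok], genes),
    x = rep(1L, sum(ok)), dims = c(n_cells, length(genes)),
    dimnames = list(if (n_cells) paste0("cell_", lm$cells$cell_id) else NULL,
                    genes))
  cells <- lm$cells
  cells$total_reads <- as.integer(Matrix::rowSums(counts))
  gdf <- data.frame(gene = genes,
                    total_reads = as.integer(Matrix::colSums(counts)))
  structure(list(counts = counts, cells = cells, genes = gdf),
            class = "cell_by_gene")
}

#' @export
print.cell_by_gene <- function(x, ...) {
  cat(sprintf("<cell_by_gene> %d cell(s) x %d gene(s), %d assigned read(s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Export a cell-by-gene matrix as MTX plus metadata CSVs
#'
#' Writes `matrix.mtx` (MatrixMarket), `cells.csv` and `genes.csv` into
#' `out_dir`, the interchange layout single-cell toolkits read directly.
#'
#' @param cbg A `cell_by_gene`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cell_by_gene <- function(cbg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cbg$counts, file.path(out_dir, "matrix.mtx"))
  utils::write.csv(cbg$cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(cbg$genes, file.path(out_dir, "genes.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Convert a cell-by-gene matrix to a SingleCellExperiment
#'
#' Returns a `SingleCellExperiment` with the counts assay (genes x cells,
#' the container's convention), cell metadata as `colData` and spatial
#' centroids in `colData$cx` / `colData$cy`. Requires the
#' SingleCellExperiment package (Suggests).
#'
#' @param cbg A `cell_by_gene`.
#' @return A `SingleCellExperiment`.
#' @export
as_single_cell_experiment <- function(cbg) {
  .check(requireNamespace("SingleCellExperiment", quietly = TRUE),
         "the SingleCellExperiment package is required for this export")
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::t(cbg$counts)),
    colData = S4Vectors::DataFrame(cbg$cells, row.names = rownames(cbg$counts)))
}

#' Per-gene QC metrics for a decoded read table
#'
#' Reports per-gene read counts, the fraction of `NO_MATCH` reads, and
#' quality summaries. When simulation ground truth is supplied, each read
#' is matched to the nearest true spot within `match_radius` px
#' (greedily, best quality first, one read per true spot) and per-gene
#' precision (matched reads calling the right gene / reads calling that
#' gene) and recall (true spots recovered / true spots) are added.
#'
#' @param reads Read-table data.frame.
#' @param truth Optional `sim_truth` (or data.frame with `x`, `y`,
#'   `gene`).
#' @param match_radius Matching radius in px (default 2).
#' @return A list of class `qc_report`: `summary` (overall metrics) and
#'   `per_gene` (data.frame).
#' @export
qc_report <- function(reads, truth = NULL, match_radius = 2) {
  decoded <- reads[reads$gene != NO_MATCH, , drop = FALSE]
  gene_universe <- sort(unique(c(decoded$gene,
                                 if (!is.null(truth)) {
                                   if (inherits(truth, "sim_truth"))
                                     truth$spots$gene else truth$gene
                                 })))
  per_gene <- data.frame(gene = gene_universe,
                         n_reads = as.integer(table(factor(decoded$gene,
                                                           levels = gene_universe))),
                         stringsAsFactors = FALSE)
  summary <- list(n_reads = nrow(reads),
                  n_decoded = nrow(decoded),
                  no_match_fraction = if (nrow(reads)) mean(reads$gene == NO_MATCH)
                                      else NA_real_,
                  mean_quality = if (nrow(decoded)) mean(decoded$quality_mean)
                                 else NA_real_,
                  min_quality = if (nrow(decoded)) min(decoded$quality_min)
                                else NA_real_)
  if (!is.null(truth)) {
    tspots <- if (inherits(truth, "sim_truth")) truth$spots else truth
    match <- match_reads_to_truth(reads, tspots, match_radius)
    correct <- match$matched & reads$gene == tspots$gene[match$truth_idx]
    correct[is.na(correct)] <- FALSE
    per_gene$n_true <- as.integer(table(factor(tspots$gene,
                                               levels = per_gene$gene)))
    per_gene$n_correct <- as.integer(table(factor(reads$gene[correct],
                                                  levels = per_gene$gene)))
    per_gene$precision <- ifelse(per_gene$n_reads > 0,
                                 per_gene$n_correct / per_gene$n_reads, NA)
    per_gene$recall <- ifelse(per_gene$n_true > 0,
                              per_gene$n_correct / per_gene$n_true, NA)
    summary$overall_precision <- sum(per_gene$n_correct) / max(1L, nrow(decoded))
    summary$overall_recall <- sum(per_gene$n_correct) / max(1L, nrow(tspots))
  }
  structure(list(summary = summary, per_gene = per_gene), class = "qc_report")
}

#' Match detected reads to ground-truth spots by proximity
#'
#' Greedy one-to-one matching: reads are visited in decreasing quality and
#' claim their nearest unclaimed true spot within `match_radius` px.
#'
#' @param reads Read table with `x`, `y` (and optionally `quality_mean`).
#' @param tspots Data.frame of true spots with `x`, `y`.
#' @param match_radius Maximum matching distance in px.
#' @return A list: `matched` (logical per read), `truth_idx` (index of
#'   the matched true spot or `NA`).
#' @export
match_reads_to_truth <- function(reads, tspots, match_radius = 2) {
  n <- nrow(reads)
  matched <- logical(n)
  truth_idx <- rep(NA_integer_, n)
  if (n == 0L || nrow(tspots) == 0L)
    return(list(matched = matched, truth_idx = truth_idx))
  ord <- if ("quality_mean" %in% names(reads)) order(-reads$quality_mean)
         else seq_len(n)
  taken <- logical(nrow(tspots))
  for (i in ord) {
    d2 <- (tspots$x - reads$x[i])^2 + (tspots$y - reads$y[i])^2
    d2[taken] <- Inf
    j <- which.min(d2)
    if (d2[j] <= match_radius^2) {
      matched[i] <- TRUE
      truth_idx[i] <- j
      taken[j] <- TRUE
    }
  }
  list(matched = matched, truth_idx = truth_idx)
}

#' @export
print.qc_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<qc_report> %d read(s), %d decoded (NO_MATCH fraction %.3f)\n",
              s$n_reads, s$n_decoded, s$no_match_fraction))
  if (!is.null(s$overall_precision))
    cat(sprintf("  precision %.3f, recall %.3f vs ground truth\n",
                s$overall_precision, s$overall_recall))
  invisible(x)
}
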