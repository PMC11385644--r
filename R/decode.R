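# Combinatorial decoding: per-plane normalization, spot detection on a
# max-over-cycles-and-channels reference image, per-spot intensity
# extraction, prominent-channel color calling with the per-cycle quality
# score, codebook matching, quality filtering, and CSV serialization.

NO_MATCH <- "NO_MATCH"

#' Normalize images across channels and imaging cycles
#'
#' Rescales every (cycle, channel) plane to its own percentile range: a
#' low-percentile baseline (the camera background, median by default) is
#' subtracted and the result divided by the distance to the
#' upper-percentile value, clamping at zero. This equalizes channel gains
#' and cycle-to-cycle intensity drifts so the sparse bright amplicons land
#' near 1 and background near 0 in every plane — the regime the
#' prominent-channel quality score assumes. The divisor is floor-clamped
#' to a small positive value; an all-zero plane is left at zero with a
#' warning.
#'
#' The baseline is always per plane (background drifts cycle to cycle),
#' but the scale is pooled per channel across cycles by default: a
#' channel's gain is a property of the dye and detector, not of the
#' cycle, and a channel that happens to carry few bright amplicons in one
#' cycle would otherwise have its noise floor amplified to the signal
#' level, corrupting both spot detection and the quality score.
#' `per = "plane"` restores fully independent per-(cycle, channel)
#' scaling.
#'
#' @param images List per cycle of `[Y, X, channel]` arrays, or a
#'   `registered_mosaic` (its `images` are used).
#' @param percentile Upper percentile used as the scale, in (0, 1]
#'   (default 0.999, i.e. the 99.9th percentile).
#' @param background_percentile Lower percentile subtracted as baseline
#'   (default 0.5, the per-plane median; set 0 for no subtraction).
#' @param per Pool the scale `"channel"`-wise across cycles (default) or
#'   compute it per `"plane"`.
#' @param floor Minimum divisor (default 1e-6).
#' @return List per cycle of numeric non-negative `[Y, X, channel]`
#'   arrays, values approximately in `[0, 1]` (bright outliers may
#'   exceed 1).
#' @export
normalize_images <- function(images, percentile = 0.999,
                             background_percentile = 0.5,
                             per = c("channel", "plane"), floor = 1e-6) {
  per <- match.arg(per)
  if (inherits(images, "registered_mosaic")) images <- images$images
  .check(length(images) >= 1L, "no images")
  nch <- dim(images[[1L]])[3L]
  out <- lapply(images, function(arr) array(0, dim = dim(arr)))
  for (ch in seq_len(nch)) {
    planes <- lapply(images, function(arr) {
      plane <- arr[, , ch]
      b <- stats::quantile(plane, background_percentile, names = FALSE)
      pmax(plane - b, 0)
    })
    if (per == "channel") {
      pooled <- unlist(planes, use.names = FALSE)
      if (all(pooled == 0)) {
        warning(sprintf("channel %d is all-zero; left unnormalized", ch))
        next
      }
      s <- stats::quantile(pooled, percentile, names = FALSE)
      if (s <= 0) s <- max(pooled)
      for (cyc in seq_along(images))
        out[[cyc]][, , ch] <- planes[[cyc]] / max(s, floor)
    } else {
      for (cyc in seq_along(images)) {
        if (all(planes[[cyc]] == 0)) {
          warning(sprintf("all-zero plane (cycle %d, channel %d) left unnormalized",
                          cyc, ch))
          next
        }
        s <- stats::quantile(planes[[cyc]], percentile, names = FALSE)
        if (s <= 0) s <- max(planes[[cyc]])
        out[[cyc]][, , ch] <- planes[[cyc]] / max(s, floor)
      }
    }
  }
  out
}

# sigma^2-normalized Laplacian-of-Gaussian response (positive for bright
# blobs), computed by separable Gaussian smoothing followed by a discrete
# Laplacian.
.log_response <- function(img, sigma) {
  sm <- EBImage::gblur(img, sigma, boundary = "replicate")
  lap <- matrix(0, nrow(img), ncol(img))
  n <- nrow(img); m <- ncol(img)
  up <- sm[c(1L, seq_len(n - 1L)), ]
  dn <- sm[c(seq_len(n - 1L) + 1L, n), ]
  lf <- sm[, c(1L, seq_len(m - 1L))]
  rt <- sm[, c(seq_len(m - 1L) + 1L, m)]
  lap <- up + dn + lf + rt - 4 * sm
  -sigma^2 * lap
}

#' Detect amplicon spots on normalized images
#'
#' Builds a reference image as the per-pixel maximum over all cycles and
#' the given channels (every amplicon is bright in some channel of every
#' cycle, so it is bright in the reference), computes a
#' scale-normalized Laplacian-of-Gaussian response over a small sigma
#' ladder, and keeps local maxima above `threshold`, merging detections
#' closer than `min_separation`.
#'
#' @param normalized List per cycle of `[Y, X, channel]` arrays from
#'   [normalize_images()].
#' @param channels 1-based channel indices to use (default: all but the
#'   last, which is the nuclei stain).
#' @param min_sigma,max_sigma Blob scale range in px (defaults 1 and 3).
#' @param n_scales Number of sigma steps (default 3).
#' @param threshold Minimum LoG response (default 0.05 on normalized
#'   intensities).
#' @param min_separation Minimum distance between detections, px
#'   (default 3).
#' @return A data.frame `y`, `x` (0-based global pixel coordinates) and
#'   `response`, ordered by decreasing response.
#' @export
detect_spots <- function(normalized, channels = NULL, min_sigma = 1,
                         max_sigma = 3, n_scales = 3L, threshold = 0.05,
                         min_separation = 3L) {
  .check(min_sigma > 0 && max_sigma >= min_sigma && threshold > 0,
         "detection parameters must be positive")
  nch <- dim(normalized[[1L]])[3L]
  if (is.null(channels)) channels <- seq_len(max(nch - 1L, 1L))
  ref <- NULL
  for (cyc in seq_along(normalized))
    for (ch in channels) {
      plane <- normalized[[cyc]][, , ch]
      ref <- if (is.null(ref)) plane else pmax(ref, plane)
    }
  sigmas <- seq(min_sigma, max_sigma, length.out = n_scales)
  resp <- NULL
  for (s in sigmas) {
    r <- .log_response(ref, s)
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  # local maxima: pixels equal to the neighborhood dilation of the response
  brush <- EBImage::makeBrush(2L * as.integer(min_separation) + 1L, "box")
  mx <- EBImage::dilate(resp, brush)
  is_peak <- resp >= mx & resp > threshold
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(y = numeric(0), x = numeric(0), response = numeric(0)))
  out <- data.frame(y = idx[, 1L] - 1L, x = idx[, 2L] - 1L,
                    response = resp[idx])
  out <- out[order(-out$response), , drop = FALSE]
  # greedy merge of residual close pairs (plateaus split by the dilation test)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      j <- (i + 1L):nrow(out)
      too_close <- keep[j] &
        (out$y[j] - out$y[i])^2 + (out$x[j] - out$x[i])^2 < min_separation^2
      keep[j][too_close] <- FALSE
    }
  }
  rownames(out) <- NULL
  out[keep, , drop = FALSE]
}

#' Extract per-spot channel intensities across cycles
#'
#' Means the normalized intensity over a square patch of half-width
#' `window` around each detected center, per cycle and channel; patches
#' are truncated at image borders.
#'
#' @param normalized List per cycle of `[Y, X, channel]` arrays.
#' @param centers Data.frame with 0-based `y`, `x` (from
#'   [detect_spots()]).
#' @param channels 1-based channel indices to extract (default: all but
#'   the nuclei channel).
#' @param window Patch half-width in px (default 1, i.e. 3x3; 0 = the
#'   center pixel itself).
#' @return A numeric array `[spot, cycle, channel]`.
#' @export
extract_intensities <- function(normalized, centers, channels = NULL,
                                window = 1L) {
  d <- dim(normalized[[1L]])
  if (is.null(channels)) channels <- seq_len(max(d[3L] - 1L, 1L))
  .check(all(centers$y >= 0 & centers$y <= d[1L] - 1L &
               centers$x >= 0 & centers$x <= d[2L] - 1L),
         "spot center outside image bounds")
  n <- nrow(centers)
  out <- array(0, dim = c(n, length(normalized), length(channels)))
  ry <- round(centers$y); rx <- round(centers$x)
  for (i in seq_len(n)) {
    ys <- max(0L, ry[i] - window):min(d[1L] - 1L, ry[i] + window) + 1L
    xs <- max(0L, rx[i] - window):min(d[2L] - 1L, rx[i] + window) + 1L
    for (cyc in seq_along(normalized))
      out[i, cyc, ] <- vapply(channels, function(ch)
        mean(normalized[[cyc]][ys, xs, ch]), 0)
  }
  out
}

#' Call per-cycle colors and decoding quality for spot intensities
#'
#' For each cycle, the prominent (maximum-intensity) channel is the
#' called color; its intensity is the true signal and the remaining
#' channels are background, giving the per-cycle quality
#' `signal / (signal + background)` — the prominent channel's share of
#' the total. The score is 1 for perfect decoding (one bright channel)
#' and `1/x` for `x` equally bright channels (random assignment; 0.25 in
#' four colors). Two summaries are computed per spot: the mean quality
#' across cycles and the minimum quality across cycles.
#'
#' Ties in the argmax are broken toward the lowest channel index and
#' flagged, as is an all-zero cycle (quality `1/x`).
#'
#' @param intensities A `[cycle, channel]` matrix for one spot, or a
#'   `[spot, cycle, channel]` array; values must be non-negative.
#' @return For a matrix: list with `colors` (0-based), `quality_per_cycle`,
#'   `quality_mean`, `quality_min`, `flagged`. For an array: a data.frame
#'   with one row per spot (`colors` joined as a dash-separated string).
#' @export
call_colors <- function(intensities) {
  .check(all(intensities >= 0), "negative intensity")
  if (is.matrix(intensities)) {
    res <- .call_colors_array(array(intensities, c(1L, dim(intensities))))
    return(list(colors = as.integer(strsplit(res$colors, "-")[[1L]]),
                quality_per_cycle = as.numeric(res[1L, grep("^quality_cycle",
                                                            names(res))]),
                quality_mean = res$quality_mean, quality_min = res$quality_min,
                flagged = res$flagged))
  }
  .call_colors_array(intensities)
}

.call_colors_array <- function(arr) {
  n <- dim(arr)[1L]; cycles <- dim(arr)[2L]; x <- dim(arr)[3L]
  colors <- matrix(0L, n, cycles)
  quality <- matrix(0, n, cycles)
  flagged <- rep(FALSE, n)
  for (cyc in seq_len(cycles)) {
    m <- matrix(arr[, cyc, ], n, x)
    top <- max.col(m, ties.method = "first")
    mx <- m[cbind(seq_len(n), top)]
    tot <- rowSums(m)
    ties <- rowSums(m == mx) > 1L & tot > 0
    zero <- tot == 0
    q <- ifelse(zero, 1 / x, mx / pmax(tot, .Machine$double.xmin))
    colors[, cyc] <- top - 1L
    quality[, cyc] <- q
    flagged <- flagged | ties | zero
  }
  out <- data.frame(colors = apply(colors, 1L, paste, collapse = "-"),
                    stringsAsFactors = FALSE)
  for (cyc in seq_len(cycles)) out[[paste0("quality_cycle", cyc)]] <- quality[, cyc]
  out$quality_mean <- rowMeans(quality)
  out$quality_min <- apply(quality, 1L, min)
  out$flagged <- flagged
  out
}

#' Match called color sequences to a codebook
#'
#' Exact lookup of each spot's color sequence in the decoding table; spots
#' whose sequence is absent are labeled `NO_MATCH` and kept in the table
#' for auditing rather than dropped.
#'
#' @param called Data.frame from [call_colors()] (array form), with a
#'   `colors` column of dash-separated 0-based channel indices.
#' @param cb A `codebook` with the same number of cycles.
#' @return `called` with a `gene` column prepended.
#' @export
decode_spots <- function(called, cb) {
  cycles <- length(strsplit(called$colors[1L], "-")[[1L]])
  if (nrow(called) > 0L)
    .check(cycles == cb$cycles,
           sprintf("spot color sequences have %d cycle(s), codebook has %d",
                   cycles, cb$cycles))
  keys <- vapply(cb$entries, paste, "", collapse = "-")
  lookup <- names(keys)
  names(lookup) <- keys
  gene <- unname(lookup[called$colors])
  gene[is.na(gene)] <- NO_MATCH
  cbind(data.frame(gene = gene, stringsAsFactors = FALSE), called)
}

#' Decode a registered mosaic into a read table
#'
#' Runs the full decoding stage: normalization, spot detection on the
#' max-projected reference, intensity extraction, color calling with
#' quality scores, and codebook matching.
#'
#' @param reg A `registered_mosaic` (or list per cycle of `[Y, X, channel]`
#'   arrays).
#' @param cb A `codebook`.
#' @param percentile Normalization percentile (default 0.999).
#' @param window Intensity patch half-width (default 1).
#' @param ... Further arguments passed to [detect_spots()].
#' @return A read-table data.frame: one row per detected spot with `x`,
#'   `y`, `gene`, per-cycle qualities, `quality_mean`, `quality_min`,
#'   `colors`, `flagged`.
#' @export
decode_mosaic <- function(reg, cb, percentile = 0.999, window = 1L, ...) {
  norm <- normalize_images(reg, percentile = percentile)
  channels <- seq_len(cb$channels)
  centers <- detect_spots(norm, channels = channels, ...)
  if (nrow(centers) == 0L) {
    empty <- data.frame(x = numeric(0), y = numeric(0), gene = character(0),
                        colors = character(0), stringsAsFactors = FALSE)
    for (cyc in seq_len(cb$cycles))
      empty[[paste0("quality_cycle", cyc)]] <- numeric(0)
    empty$quality_mean <- numeric(0)
    empty$quality_min <- numeric(0)
    empty$flagged <- logical(0)
    return(empty)
  }
  intens <- extract_intensities(norm, centers, channels = channels,
                                window = window)
  called <- .call_colors_array(intens)
  decoded <- decode_spots(called, cb)
  cbind(data.frame(x = centers$x, y = centers$y), decoded)
}

#' Filter a read table by decoding quality
#'
#' Retains reads whose minimum (default) or mean quality reaches
#' `min_quality`. Filtering on the minimum per-cycle quality discards any
#' read with even one ambiguous cycle and gives the more reliable table;
#' 0.5 is the customary threshold in four-color decoding.
#'
#' @param reads Read-table data.frame.
#' @param min_quality Threshold in `[1/x, 1]` (default 0.5).
#' @param mode `"minimum"` (default) or `"mean"`.
#' @param drop_no_match Also drop `NO_MATCH` rows (default `FALSE`).
#' @param verbose Log before/after counts (default `FALSE`).
#' @return The filtered read table.
#' @export
filter_reads <- function(reads, min_quality = 0.5,
                         mode = c("minimum", "mean"), drop_no_match = FALSE,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  q <- if (mode == "minimum") reads$quality_min else reads$quality_mean
  keep <- q >= min_quality
  if (drop_no_match) keep <- keep & reads$gene != NO_MATCH
  if (verbose)
    message(sprintf("quality filter (%s >= %.2f): %d / %d read(s) retained",
                    mode, min_quality, sum(keep), nrow(reads)))
  reads[keep, , drop = FALSE]
}

#' Write / read a read table as CSV
#'
#' @param reads Read-table data.frame.
#' @param path CSV path.
#' @return `path` invisibly ([write_read_table()]); the table
#'   ([read_read_table()]).
#' @export
write_read_table <- function(reads, path) {
  utils::write.csv(reads, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_read_table
#' @export
read_read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(colors = "character"))
}
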