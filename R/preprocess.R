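# Preprocessing: maximum z-projection, tile stitching with deterministic
# overlap removal, cross-cycle registration by phase correlation, and
# reslicing into uniform decoding tiles.

#' Maximum intensity projection over z
#'
#' @param stack A 2D matrix (returned unchanged) or a 3D array `[y, x, z]`.
#' @return A matrix `[y, x]` of per-pixel maxima; storage mode preserved.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  .check(is.array(stack) && length(dim(stack)) == 3L && dim(stack)[3L] >= 1L,
         "stack must be a [y, x, z] array with z >= 1")
  d <- dim(stack)
  Reduce(pmax, lapply(seq_len(d[3L]),
                      function(z) matrix(stack[, , z], d[1L], d[2L])))
}

#' Estimate the translation between two images by phase correlation
#'
#' Returns the displacement `(dy, dx)` such that `mov` is `ref` translated
#' by that amount (content moved down by `dy` rows and right by `dx`
#' columns). With `upsample > 1` the cross-correlation peak is refined by
#' a local upsampled discrete Fourier transform, giving subpixel
#' estimates with error well below `1 / upsample` on structured images.
#'
#' @param ref,mov Numeric matrices of identical dimension.
#' @param upsample Subpixel refinement factor (default 1 = integer pixels).
#' @param max_shift Optional bound: the peak is searched only among
#'   displacements with `|dy| <= max_shift` and `|dx| <= max_shift`.
#' @return Numeric `(dy, dx)`; `(0, 0)` with a warning when either image
#'   is flat (no correlation signal).
#' @export
estimate_translation <- function(ref, mov, upsample = 1L, max_shift = NULL) {
  .check(all(dim(ref) == dim(mov)), "ref and mov must have identical dimensions")
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0) {
    warning("flat image: correlation failed, returning zero shift")
    return(c(dy = 0, dx = 0))
  }
  nr <- nrow(ref); nc <- ncol(ref)
  F1 <- stats::fft(ref - mean(ref))
  F2 <- stats::fft(mov - mean(mov))
  R <- F1 * Conj(F2)
  R <- R / pmax(Mod(R), .Machine$double.eps)
  cc <- Re(stats::fft(R, inverse = TRUE))
  if (!is.null(max_shift)) {
    allowed_r <- unique(c(seq_len(min(max_shift + 1L, nr)),
                          nr - seq_len(min(max_shift, nr - 1L)) + 1L))
    allowed_c <- unique(c(seq_len(min(max_shift + 1L, nc)),
                          nc - seq_len(min(max_shift, nc - 1L)) + 1L))
    mask <- matrix(-Inf, nr, nc)
    mask[allowed_r, allowed_c] <- 0
    cc <- cc + mask
  }
  peak <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  dy <- peak[1L] - 1L; dx <- peak[2L] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  # phase-correlation peak at (dy, dx) means mov[y, x] ~ ref[y + dy, x + dx],
  # i.e. mov content sits at ref position minus (dy, dx): flip the sign to
  # report the displacement OF mov relative to ref.
  shift <- c(-dy, -dx)
  if (upsample > 1L) {
    # refine around the integer peak with a local upsampled DFT
    usfac <- upsample
    region <- ceiling(usfac * 1.5)
    dftshift <- floor(region / 2)
    roff <- dftshift - round(-shift[1L] * usfac)
    coff <- dftshift - round(-shift[2L] * usfac)
    cc_up <- Mod(.dftups(Conj(R), region, region, usfac, roff, coff))
    pk <- which(cc_up == max(cc_up), arr.ind = TRUE)[1L, ]
    shift <- -c((pk[1L] - 1L - dftshift) / usfac + (-shift[1L]),
                (pk[2L] - 1L - dftshift) / usfac + (-shift[2L]))
  }
  c(dy = unname(shift[1L]), dx = unname(shift[2L]))
}

# Upsampled DFT of a small region of the inverse transform of `inp`
# (matrix-multiply implementation; no zero padding of the full spectrum).
.dftups <- function(inp, nor, noc, usfac, roff, coff) {
  nr <- nrow(inp); nc <- ncol(inp)
  fc <- (seq_len(nc) - 1L)
  fc <- ifelse(fc > nc / 2, fc - nc, fc)
  fr <- (seq_len(nr) - 1L)
  fr <- ifelse(fr > nr / 2, fr - nr, fr)
  kernc <- exp((-2i * pi / (nc * usfac)) *
                 outer(fc, (seq_len(noc) - 1L) - coff))
  kernr <- exp((-2i * pi / (nr * usfac)) *
                 outer((seq_len(nor) - 1L) - roff, fr))
  kernr %*% inp %*% kernc
}

# Translate a matrix by integer (dy, dx), filling vacated pixels.
.shift_matrix <- function(m, dy, dx, fill = 0L) {
  out <- matrix(as.vector(m[1L]) * 0L + fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dy
  src_c <- seq_len(ncol(m)) - dx
  ok_r <- src_r >= 1L & src_r <= nrow(m)
  ok_c <- src_c >= 1L & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Stitch projected tiles of one cycle into a mosaic
#'
#' Places each tile at its metadata grid position and removes the edge
#' overlap deterministically: in overlap strips, the tile with the lower
#' `(row, col)` index wins. With `refine = TRUE`, each tile's position is
#' first corrected by phase correlation against its left/top neighbor on
#' the nominal overlap strip (translation only), recovering small stage
#' errors.
#'
#' @param tiles List of projected tiles, each a `[y, x, channel]` array
#'   (or a matrix for single-channel data), in metadata order.
#' @param metadata Data.frame with `tile`, `row`, `col`, `y0`, `x0`
#'   (0-based pixel origins), as produced by the simulator or read from a
#'   tileset directory.
#' @param mosaic_size `(Y, X)` of the output mosaic; default inferred as
#'   `max(origin) + tile size`.
#' @param refine Estimate per-tile position corrections from overlap
#'   strips (default `FALSE`: trust the metadata).
#' @param max_refine Largest position correction searched, px (default 5).
#' @return A list of class `stitched`: `mosaic` (`[Y, X, channel]` array),
#'   `positions` (possibly refined 0-based origins), `provenance`
#'   (`[Y, X]` matrix of the winning tile index per pixel).
#' @export
stitch <- function(tiles, metadata, mosaic_size = NULL, refine = FALSE,
                   max_refine = 5L) {
  tiles <- lapply(tiles, function(t) {
    if (is.matrix(t)) array(t, dim = c(dim(t), 1L)) else t
  })
  d <- dim(tiles[[1L]])
  .check(all(vapply(tiles, function(t) all(dim(t) == d), TRUE)),
         "inconsistent tile shapes")
  ty <- d[1L]; tx <- d[2L]; nch <- d[3L]
  pos <- data.frame(tile = metadata$tile, row = metadata$row,
                    col = metadata$col, y0 = metadata$y0, x0 = metadata$x0)
  if (refine) {
    flat <- lapply(tiles, function(t) {
      f <- t[, , 1L]
      if (nch > 1L) for (ch in 2L:nch) f <- f + t[, , ch]
      f
    })
    for (i in order(pos$row, pos$col)) {
      est <- list()
      left <- which(pos$row == pos$row[i] & pos$col == pos$col[i] - 1L)
      up <- which(pos$col == pos$col[i] & pos$row == pos$row[i] - 1L)
      if (length(left) == 1L) {
        ov <- (metadata$x0[left] + tx) - metadata$x0[i]  # nominal overlap width
        if (ov > 2L * max_refine) {
          # estimate_translation(a, b) = displacement of b's content, so the
          # tile's true origin is the neighbor's origin plus the nominal
          # offset minus the measured content displacement
          s <- estimate_translation(flat[[left]][, (tx - ov + 1L):tx, drop = FALSE],
                                    flat[[i]][, seq_len(ov), drop = FALSE],
                                    max_shift = max_refine)
          est[[length(est) + 1L]] <- c(pos$y0[left] - s[1L],
                                       pos$x0[left] + tx - ov - s[2L])
        }
      }
      if (length(up) == 1L) {
        ov <- (metadata$y0[up] + ty) - metadata$y0[i]
        if (ov > 2L * max_refine) {
          s <- estimate_translation(flat[[up]][(ty - ov + 1L):ty, , drop = FALSE],
                                    flat[[i]][seq_len(ov), , drop = FALSE],
                                    max_shift = max_refine)
          est[[length(est) + 1L]] <- c(pos$y0[up] + ty - ov - s[1L],
                                       pos$x0[up] - s[2L])
        }
      }
      if (length(est) > 0L) {
        corr <- round(Reduce(`+`, est) / length(est))
        pos$y0[i] <- corr[1L]
        pos$x0[i] <- corr[2L]
      }
    }
  }
  if (is.null(mosaic_size))
    mosaic_size <- c(max(pos$y0) + ty, max(pos$x0) + tx)
  Y <- mosaic_size[1L]; X <- mosaic_size[2L]
  mosaic <- array(tiles[[1L]][1L] * 0L, dim = c(Y, X, nch))
  provenance <- matrix(NA_integer_, Y, X)
  # later (higher row, col) tiles first, so lower-index tiles win overlaps
  for (i in order(pos$row, pos$col, decreasing = TRUE)) {
    ys <- pos$y0[i] + seq_len(ty); xs <- pos$x0[i] + seq_len(tx)
    keep_y <- ys >= 1L & ys <= Y; keep_x <- xs >= 1L & xs <= X
    mosaic[ys[keep_y], xs[keep_x], ] <- tiles[[i]][keep_y, keep_x, , drop = FALSE]
    provenance[ys[keep_y], xs[keep_x]] <- pos$tile[i]
  }
  structure(list(mosaic = mosaic, positions = pos, provenance = provenance),
            class = "stitched")
}

#' Register stitched mosaics across imaging cycles
#'
#' Estimates one global 2D translation per cycle relative to a reference
#' cycle by phase correlation on a designated registration channel
#' (default: the last channel, the nuclei stain, which carries
#' cycle-independent signal), then shifts all channels of each cycle by
#' the rounded estimate to bring the cycles into a common frame.
#'
#' @param mosaics List (one per cycle) of `[Y, X, channel]` arrays.
#' @param reference_cycle 1-based reference cycle (default 1).
#' @param registration_channel 1-based channel used for estimation
#'   (default: last channel).
#' @param upsample Subpixel refinement factor passed to
#'   [estimate_translation()] (default 10).
#' @return A list of class `registered_mosaic`: `images` (list per cycle,
#'   `[Y, X, channel]`, aligned), `shifts` (cycles x 2 matrix of estimated
#'   `(dy, dx)` displacements of each cycle relative to the reference),
#'   `reference_cycle`.
#' @export
register_cycles <- function(mosaics, reference_cycle = 1L,
                            registration_channel = NULL, upsample = 10L) {
  .check(length(mosaics) >= 1L, "need at least one cycle")
  d <- dim(mosaics[[1L]])
  .check(all(vapply(mosaics, function(m) all(dim(m) == d), TRUE)),
         "all cycle mosaics must share a shape")
  if (is.null(registration_channel)) registration_channel <- d[3L]
  ref <- mosaics[[reference_cycle]][, , registration_channel]
  shifts <- matrix(0, length(mosaics), 2L,
                   dimnames = list(NULL, c("dy", "dx")))
  images <- vector("list", length(mosaics))
  for (cyc in seq_along(mosaics)) {
    if (cyc == reference_cycle) {
      images[[cyc]] <- mosaics[[cyc]]
      next
    }
    s <- estimate_translation(ref, mosaics[[cyc]][, , registration_channel],
                              upsample = upsample)
    shifts[cyc, ] <- s
    si <- round(s)
    out <- mosaics[[cyc]]
    for (ch in seq_len(d[3L]))
      out[, , ch] <- .shift_matrix(mosaics[[cyc]][, , ch], -si[1L], -si[2L])
    images[[cyc]] <- out
  }
  structure(list(images = images, shifts = shifts,
                 reference_cycle = reference_cycle),
            class = "registered_mosaic")
}

#' @export
print.registered_mosaic <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat(sprintf("<registered_mosaic> %d cycle(s), %d x %d px, %d channel(s); max |shift| %.2f px\n",
              length(x$images), d[1L], d[2L], d[3L], max(abs(x$shifts))))
  invisible(x)
}

#' Reslice a registered mosaic into uniform non-overlapping decoding tiles
#'
#' Cuts the mosaic into `tile_size` tiles on a regular grid; the last
#' row/column of tiles is zero-padded to the full tile size so decoders
#' see uniform shapes. The index maps tile-local to global coordinates
#' exactly: `global = (y0, x0) + local`.
#'
#' @param reg A `registered_mosaic`.
#' @param tile_size `(y, x)` decoding tile size.
#' @return A list of class `resliced`: `tiles[[i]]` arrays
#'   `[y, x, cycle, channel]`, `index` data.frame (`tile`, `row`, `col`,
#'   `y0`, `x0`, `valid_y`, `valid_x` — the unpadded extent), and the
#'   original `mosaic_size`.
#' @export
reslice <- function(reg, tile_size = c(512L, 512L)) {
  d <- dim(reg$images[[1L]])
  .check(all(tile_size <= d[1:2]), "tile_size exceeds mosaic size")
  nrows <- ceiling(d[1L] / tile_size[1L])
  ncols <- ceiling(d[2L] / tile_size[2L])
  idx <- expand.grid(col = seq_len(ncols), row = seq_len(nrows))
  index <- data.frame(tile = seq_len(nrow(idx)), row = idx$row, col = idx$col,
                      y0 = (idx$row - 1L) * tile_size[1L],
                      x0 = (idx$col - 1L) * tile_size[2L])
  index$valid_y <- pmin(tile_size[1L], d[1L] - index$y0)
  index$valid_x <- pmin(tile_size[2L], d[2L] - index$x0)
  tiles <- lapply(seq_len(nrow(index)), function(i) {
    arr <- array(0L, dim = c(tile_size[1L], tile_size[2L], length(reg$images),
                             d[3L]))
    ys <- index$y0[i] + seq_len(index$valid_y[i])
    xs <- index$x0[i] + seq_len(index$valid_x[i])
    for (cyc in seq_along(reg$images))
      arr[seq_len(index$valid_y[i]), seq_len(index$valid_x[i]), cyc, ] <-
        reg$images[[cyc]][ys, xs, , drop = FALSE]
    arr
  })
  structure(list(tiles = tiles, index = index, mosaic_size = d[1:2]),
            class = "resliced")
}

#' Reassemble resliced tiles into per-cycle mosaics
#'
#' Inverse of [reslice()] (padding discarded); mainly used to verify that
#' coordinates survive the reslice round trip.
#'
#' @param rs A `resliced` object.
#' @return A list per cycle of `[Y, X, channel]` arrays.
#' @export
reassemble_tiles <- function(rs) {
  d4 <- dim(rs$tiles[[1L]])
  lapply(seq_len(d4[3L]), function(cyc) {
    out <- array(rs$tiles[[1L]][1L] * 0L,
                 dim = c(rs$mosaic_size[1L], rs$mosaic_size[2L], d4[4L]))
    for (i in seq_len(nrow(rs$index))) {
      ys <- rs$index$y0[i] + seq_len(rs$index$valid_y[i])
      xs <- rs$index$x0[i] + seq_len(rs$index$valid_x[i])
      out[ys, xs, ] <- rs$tiles[[i]][seq_len(rs$index$valid_y[i]),
                                     seq_len(rs$index$valid_x[i]), cyc, ,
                                     drop = FALSE]
    }
    out
  })
}

#' Write / read a registered mosaic as TIFFs plus a shifts report
#'
#' One 16-bit TIFF per (cycle, channel), named `cycle<c>_ch<ch>.tif`,
#' alongside `shifts.csv` (estimated per-cycle displacements) and
#' `registered.json` (shape metadata).
#'
#' @param reg A `registered_mosaic`.
#' @param out_dir Output directory (created if missing).
#' @param in_dir Directory written by [write_registered_mosaic()].
#' @return `out_dir` invisibly; the `registered_mosaic` on read.
#' @export
write_registered_mosaic <- function(reg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(reg$images[[1L]])
  for (cyc in seq_along(reg$images))
    for (ch in seq_len(d[3L]))
      tiff::writeTIFF(pmin(reg$images[[cyc]][, , ch], 65535) / 65535,
                      file.path(out_dir, sprintf("cycle%d_ch%d.tif", cyc, ch)),
                      bits.per.sample = 16L, compression = "none")
  utils::write.csv(data.frame(cycle = seq_len(nrow(reg$shifts)),
                              dy = reg$shifts[, 1L], dx = reg$shifts[, 2L]),
                   file.path(out_dir, "shifts.csv"), row.names = FALSE)
  jsonlite::write_json(list(cycles = length(reg$images), shape = d,
                            reference_cycle = reg$reference_cycle),
                       file.path(out_dir, "registered.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @rdname write_registered_mosaic
#' @export
read_registered_mosaic <- function(in_dir) {
  info <- jsonlite::read_json(file.path(in_dir, "registered.json"),
                              simplifyVector = TRUE)
  shifts <- utils::read.csv(file.path(in_dir, "shifts.csv"))
  images <- lapply(seq_len(info$cycles), function(cyc) {
    arr <- array(0L, dim = info$shape)
    for (ch in seq_len(info$shape[3L])) {
      f <- file.path(in_dir, sprintf("cycle%d_ch%d.tif", cyc, ch))
      .check(file.exists(f), sprintf("missing %s", basename(f)))
      arr[, , ch] <- as.integer(round(tiff::readTIFF(f) * 65535))
    }
    arr
  })
  structure(list(images = images,
                 shifts = matrix(c(shifts$dy, shifts$dx), ncol = 2L,
                                 dimnames = list(NULL, c("dy", "dx"))),
                 reference_cycle = info$reference_cycle),
            class = "registered_mosaic")
}

#' Run the full preprocessing stage on a tileset
#'
#' Maximum z-projection of every tile, per-cycle stitching, and
#' cross-cycle registration, returning decode-ready aligned mosaics.
#'
#' @param tileset A `tileset` (from [simulate_dataset()] or
#'   [read_tileset()]).
#' @param refine Refine tile positions during stitching (default `FALSE`).
#' @param reference_cycle Reference cycle for registration (default 1).
#' @param upsample Subpixel factor for shift estimation (default 10).
#' @return A `registered_mosaic`.
#' @export
preprocess_tileset <- function(tileset, refine = FALSE, reference_cycle = 1L,
                               upsample = 10L) {
  mosaics <- lapply(tileset$tiles, function(cyc_tiles) {
    proj <- lapply(cyc_tiles, function(t) {
      d <- dim(t)
      out <- array(0L, dim = c(d[1L], d[2L], d[4L]))
      for (ch in seq_len(d[4L])) out[, , ch] <- max_project(t[, , , ch])
      out
    })
    stitch(proj, tileset$metadata,
           mosaic_size = tileset$config$mosaic_size, refine = refine)$mosaic
  })
  register_cycles(mosaics, reference_cycle = reference_cycle,
                  upsample = upsample)
}
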