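# Synthetic multi-cycle, multi-channel, tiled fluorescence datasets with
# per-spot ground truth. Emulates rolling-circle-product imaging: ~1 um
# diffraction-limited spots, one bright channel per cycle per spot given by
# the gene's barcode, channel crosstalk, background and read noise, a tile
# grid with edge overlap, small per-cycle global shifts, and a nuclei
# (DAPI-like) channel carried alongside the detection channels.

#' Simulation configuration
#'
#' Geometry is defined by the tile grid: the mosaic spans
#' `tile + (n - 1) * (tile - round(tile * overlap))` pixels per axis, so
#' neighboring tiles share a 10% strip at the default overlap. Pixel
#' values are stored as 16-bit unsigned integers (clipped), matching
#' common sCMOS camera output.
#'
#' @param tile_size Tile (field-of-view) size in pixels `(y, x)` (default
#'   `c(512, 512)`).
#' @param grid Tile grid `(rows, cols)` (default `c(2, 2)`).
#' @param overlap_fraction Fractional edge overlap between neighboring
#'   tiles, in `[0, 0.5)` (default 0.10).
#' @param cycles Number of imaging cycles N (default 2).
#' @param channels Number of detection fluorophores x (default 4); a
#'   nuclei channel is always added as channel index `channels` (0-based).
#' @param z_planes Number of z planes per tile (default 3); the scene is
#'   in focus at the middle plane and signal falls off as a Gaussian in z.
#' @param spot_count Number of rolling-circle products (default 1000).
#' @param psf_sigma Gaussian spot sigma in pixels (default 1.5, a ~1 um
#'   amplicon at 3-4 px/um sampling).
#' @param spot_amplitude Peak signal above background, in counts (default 500).
#' @param crosstalk Fraction of a spot's amplitude leaking into each other
#'   detection channel, in `[0, 1)` (default 0.05).
#' @param background_level Flat background in counts (default 100).
#' @param noise_sd Gaussian read-noise standard deviation in counts
#'   (default 10).
#' @param cycle_shifts Per-cycle global `(dy, dx)` shifts in pixels
#'   (matrix cycles x 2, or `NULL` for no shift); must stay below the
#'   overlap width.
#' @param nuclei_count Number of nuclei disks (default 40).
#' @param nuclei_radius Nucleus radius in pixels (default 15).
#' @param nuclei_amplitude Nuclei-channel signal above background (default 600).
#' @param z_sigma Gaussian defocus sigma in planes (default
#'   `max(z_planes / 4, 0.5)`).
#' @param min_separation Minimum center-to-center spot distance in pixels
#'   (default `2 * psf_sigma`); set `dense = TRUE` to disable rejection.
#' @param dense If `TRUE`, spots may overlap (default `FALSE`).
#' @param spot_positions Optional data.frame `x`, `y` (0-based, may be
#'   fractional) and optionally `gene` pinning spot placement, overriding
#'   random placement.
#' @param seed Integer seed; the dataset is a deterministic function of
#'   the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tile_size = c(512L, 512L), grid = c(2L, 2L),
                       overlap_fraction = 0.10, cycles = 2L, channels = 4L,
                       z_planes = 3L, spot_count = 1000L, psf_sigma = 1.5,
                       spot_amplitude = 500, crosstalk = 0.05,
                       background_level = 100, noise_sd = 10,
                       cycle_shifts = NULL, nuclei_count = 40L,
                       nuclei_radius = 15, nuclei_amplitude = 600,
                       z_sigma = NULL, min_separation = NULL, dense = FALSE,
                       spot_positions = NULL, seed = 1L) {
  .check(overlap_fraction >= 0 && overlap_fraction < 0.5,
         "overlap_fraction must be in [0, 0.5)")
  .check(crosstalk >= 0 && crosstalk < 1, "crosstalk must be in [0, 1)")
  ov <- round(tile_size * overlap_fraction)
  step <- tile_size - ov
  mosaic <- tile_size + (grid - 1L) * step
  if (is.null(cycle_shifts)) cycle_shifts <- matrix(0, cycles, 2L)
  cycle_shifts <- matrix(cycle_shifts, ncol = 2L)
  .check(nrow(cycle_shifts) == cycles, "cycle_shifts must have one (dy, dx) row per cycle")
  .check(all(abs(cycle_shifts) < min(ov[ov > 0], tile_size)),
         "cycle shifts must be smaller than the tile overlap")
  if (is.null(z_sigma)) z_sigma <- max(z_planes / 4, 0.5)
  if (is.null(min_separation)) min_separation <- 2 * psf_sigma
  structure(list(tile_size = as.integer(tile_size), grid = as.integer(grid),
                 overlap_fraction = overlap_fraction, step = as.integer(step),
                 mosaic_size = as.integer(mosaic), cycles = as.integer(cycles),
                 channels = as.integer(channels), z_planes = as.integer(z_planes),
                 spot_count = as.integer(spot_count), psf_sigma = psf_sigma,
                 spot_amplitude = spot_amplitude, crosstalk = crosstalk,
                 background_level = background_level, noise_sd = noise_sd,
                 cycle_shifts = cycle_shifts, nuclei_count = as.integer(nuclei_count),
                 nuclei_radius = nuclei_radius, nuclei_amplitude = nuclei_amplitude,
                 z_sigma = z_sigma, min_separation = min_separation,
                 dense = isTRUE(dense), spot_positions = spot_positions,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Tile grid metadata: 1-based row/col, 0-based pixel origin of each tile.
.tile_metadata <- function(config) {
  g <- expand.grid(col = seq_len(config$grid[2L]), row = seq_len(config$grid[1L]))
  data.frame(tile = seq_len(nrow(g)), row = g$row, col = g$col,
             y0 = (g$row - 1L) * config$step[1L],
             x0 = (g$col - 1L) * config$step[2L])
}

# Render isotropic Gaussian bumps (peak `amp[i]` at 0-based, possibly
# fractional, (y0[i], x0[i])) summed into one [Y, X] matrix. The
# accumulator stays local so subassignment happens in place.
.render_gaussians <- function(Y, X, y0, x0, amp, sigma) {
  acc <- matrix(0, Y, X)
  r <- ceiling(4 * sigma)
  for (i in seq_along(y0)) {
    ys <- max(0L, floor(y0[i]) - r):min(Y - 1L, ceiling(y0[i]) + r)
    xs <- max(0L, floor(x0[i]) - r):min(X - 1L, ceiling(x0[i]) + r)
    if (length(ys) == 0L || length(xs) == 0L) next
    ky <- exp(-(ys - y0[i])^2 / (2 * sigma^2))
    kx <- exp(-(xs - x0[i])^2 / (2 * sigma^2))
    acc[ys + 1L, xs + 1L] <- acc[ys + 1L, xs + 1L] + amp[i] * outer(ky, kx)
  }
  acc
}

# Draw points uniformly in [margin, size - margin) with pairwise minimum
# distance `min_sep` (rejection sampling; errors out when geometry is
# infeasible after many tries).
.place_points <- function(n, size_yx, margin, min_sep) {
  ys <- numeric(0); xs <- numeric(0)
  lim_y <- size_yx[1L] - 1 - 2 * margin
  lim_x <- size_yx[2L] - 1 - 2 * margin
  .check(lim_y > 0 && lim_x > 0, "infeasible geometry: margin exceeds mosaic")
  tries <- 0L
  while (length(ys) < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("infeasible geometry: cannot place points at the requested separation",
           call. = FALSE)
    y <- margin + stats::runif(1L) * lim_y
    x <- margin + stats::runif(1L) * lim_x
    if (min_sep > 0 && length(ys) > 0L &&
        min((ys - y)^2 + (xs - x)^2) < min_sep^2) next
    ys <- c(ys, y); xs <- c(xs, x)
  }
  data.frame(y = ys, x = xs)
}

#' Simulate a tiled multi-cycle ISS dataset with ground truth
#'
#' Renders each rolling-circle product as a Gaussian spot that is bright,
#' in every cycle, in the channel dictated by its gene's barcode (with a
#' `crosstalk` fraction leaking into the other detection channels), adds
#' filled nuclei disks in a separate nuclei channel, applies a global
#' per-cycle shift to the whole scene, modulates signal across z planes by
#' a Gaussian defocus profile, adds flat background plus Gaussian read
#' noise, quantizes to 16-bit, and cuts the mosaic into overlapping tiles.
#'
#' @param config A [sim_config()].
#' @param codebook A `codebook`; `codebook$channels` must not exceed
#'   `config$channels` and cycle counts must agree.
#' @return A list with:
#'   \describe{
#'     \item{tileset}{class `tileset`: `tiles[[cycle]][[tile]]` integer
#'       arrays `[y, x, z, channel]` (nuclei = last channel), `metadata`
#'       (tile grid positions), `channel_names`, `config`.}
#'     \item{truth}{class `sim_truth`: `spots` (spot_id, x, y, gene,
#'       barcode string), `nuclei` (cell_id, cx, cy, radius), and
#'       `mosaic_reference[[cycle]]`, the quantized max-projected mosaic
#'       `[y, x, channel]` each cycle's tiles were cut from (shifts
#'       included) — the exact round-trip target for stitching.}
#'   }
#' @export
simulate_dataset <- function(config, codebook) {
  validate_codebook(codebook)
  .check(codebook$channels <= config$channels,
         "codebook has more channels than the simulation")
  .check(codebook$cycles == config$cycles,
         "codebook cycles must equal config cycles")
  Y <- config$mosaic_size[1L]; X <- config$mosaic_size[2L]
  nch <- config$channels + 1L   # + nuclei channel
  genes <- names(codebook$entries)

  with_seed(config$seed, {
    shift_margin <- max(abs(config$cycle_shifts))
    if (is.null(config$spot_positions)) {
      margin <- 3 * config$psf_sigma + shift_margin + 1
      pts <- .place_points(config$spot_count, c(Y, X), margin,
                           if (config$dense) 0 else config$min_separation)
      spot_gene <- genes[sample.int(length(genes), config$spot_count,
                                    replace = TRUE)]
    } else {
      pts <- data.frame(y = config$spot_positions$y, x = config$spot_positions$x)
      spot_gene <- if (!is.null(config$spot_positions$gene))
        config$spot_positions$gene
      else genes[sample.int(length(genes), nrow(pts), replace = TRUE)]
    }
    .check(all(spot_gene %in% genes), "spot gene not present in codebook")
    spots <- data.frame(spot_id = seq_len(nrow(pts)), x = pts$x, y = pts$y,
                        gene = spot_gene,
                        barcode = vapply(codebook$entries[spot_gene], paste,
                                         "", collapse = ""))
    rownames(spots) <- NULL
    nuc_margin <- config$nuclei_radius + shift_margin + 1
    nuc <- .place_points(config$nuclei_count, c(Y, X), nuc_margin,
                         2 * config$nuclei_radius + 2)
    nuclei <- data.frame(cell_id = seq_len(nrow(nuc)), cx = nuc$x, cy = nuc$y,
                         radius = rep(config$nuclei_radius, nrow(nuc)))

    barcode_mat <- do.call(rbind, codebook$entries[spot_gene])  # spots x cycles
    meta <- .tile_metadata(config)
    zmid <- (config$z_planes + 1) / 2
    fz <- exp(-((seq_len(config$z_planes) - zmid)^2) / (2 * config$z_sigma^2))

    tiles <- vector("list", config$cycles)
    mosaic_reference <- vector("list", config$cycles)
    for (cyc in seq_len(config$cycles)) {
      dy <- config$cycle_shifts[cyc, 1L]; dx <- config$cycle_shifts[cyc, 2L]
      # in-focus signal above background, one matrix per channel
      bright <- barcode_mat[, cyc] + 1L
      signal <- lapply(seq_len(config$channels), function(ch) {
        amp <- ifelse(bright == ch, config$spot_amplitude,
                      config$crosstalk * config$spot_amplitude)
        use <- amp > 0
        .render_gaussians(Y, X, spots$y[use] + dy, spots$x[use] + dx,
                          amp[use], config$psf_sigma)
      })
      # nuclei disks, shifted with the scene
      nsig <- matrix(0, Y, X)
      for (i in seq_len(nrow(nuclei))) {
        cy0 <- nuclei$cy[i] + dy; cx0 <- nuclei$cx[i] + dx
        r <- config$nuclei_radius
        ys <- max(0, floor(cy0 - r)):min(Y - 1, ceiling(cy0 + r))
        xs <- max(0, floor(cx0 - r)):min(X - 1, ceiling(cx0 + r))
        disk <- outer((ys - cy0)^2, (xs - cx0)^2, "+") <= r^2
        nsig[ys + 1L, xs + 1L][disk] <- config$nuclei_amplitude
      }
      signal[[nch]] <- nsig

      cyc_tiles <- lapply(seq_len(nrow(meta)), function(t)
        array(0L, dim = c(config$tile_size[1L], config$tile_size[2L],
                          config$z_planes, nch)))
      ref <- array(0L, dim = c(Y, X, nch))
      for (z in seq_len(config$z_planes)) {
        for (ch in seq_len(nch)) {
          plane <- config$background_level + fz[z] * signal[[ch]]
          if (config$noise_sd > 0)
            plane <- plane + matrix(stats::rnorm(Y * X, sd = config$noise_sd),
                                    Y, X)
          plane <- matrix(as.integer(pmin(pmax(round(plane), 0), 65535)), Y, X)
          ref[, , ch] <- pmax(ref[, , ch], plane)
          for (t in seq_len(nrow(meta))) {
            ys <- meta$y0[t] + seq_len(config$tile_size[1L])
            xs <- meta$x0[t] + seq_len(config$tile_size[2L])
            cyc_tiles[[t]][, , z, ch] <- plane[ys, xs]
          }
        }
      }
      tiles[[cyc]] <- cyc_tiles
      mosaic_reference[[cyc]] <- ref
    }

    list(tileset = structure(list(tiles = tiles, metadata = meta,
                                  channel_names = c(codebook$channel_names,
                                                    rep("extra", config$channels -
                                                          codebook$channels),
                                                    "DAPI"),
                                  config = config),
                             class = "tileset"),
         truth = structure(list(spots = spots, nuclei = nuclei,
                                mosaic_reference = mosaic_reference),
                           class = "sim_truth"))
  })
}

#' @export
print.tileset <- function(x, ...) {
  d <- dim(x$tiles[[1L]][[1L]])
  cat(sprintf("<tileset> %d cycle(s) x %d tile(s); tile %d x %d px, %d z plane(s), %d channel(s)\n",
              length(x$tiles), length(x$tiles[[1L]]), d[1L], d[2L], d[3L], d[4L]))
  invisible(x)
}

#' Write a tileset to a directory of TIFF files plus metadata
#'
#' One 16-bit TIFF per (cycle, tile, channel, z plane), named
#' `c<cycle>_t<tile>_ch<channel>_z<z>.tif`, alongside `metadata.csv` (tile
#' grid positions) and `tileset.json` (shapes, channel names, overlap).
#'
#' @param tileset A `tileset`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_tileset <- function(tileset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(tileset$tiles[[1L]][[1L]])
  for (cyc in seq_along(tileset$tiles))
    for (t in seq_along(tileset$tiles[[cyc]]))
      for (ch in seq_len(d[4L]))
        for (z in seq_len(d[3L]))
          tiff::writeTIFF(tileset$tiles[[cyc]][[t]][, , z, ch] / 65535,
                          file.path(out_dir, sprintf("c%d_t%d_ch%d_z%d.tif",
                                                     cyc, t, ch, z)),
                          bits.per.sample = 16L, compression = "none")
  utils::write.csv(tileset$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(cycles = length(tileset$tiles),
                            tiles = length(tileset$tiles[[1L]]),
                            tile_size = d[1:2], z_planes = d[3L],
                            channels = d[4L],
                            channel_names = tileset$channel_names,
                            overlap_fraction = tileset$config$overlap_fraction,
                            mosaic_size = tileset$config$mosaic_size),
                       file.path(out_dir, "tileset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a tileset written by [write_tileset()]
#'
#' @param in_dir Directory containing the TIFFs, `metadata.csv` and
#'   `tileset.json`.
#' @return A `tileset` (config restored with the geometry fields needed
#'   downstream).
#' @export
read_tileset <- function(in_dir) {
  meta_path <- file.path(in_dir, "metadata.csv")
  json_path <- file.path(in_dir, "tileset.json")
  .check(file.exists(meta_path), "missing metadata.csv")
  .check(file.exists(json_path), "missing tileset.json")
  info <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  meta <- utils::read.csv(meta_path)
  ts <- info$tile_size
  .check(all(meta$y0 + ts[1L] <= info$mosaic_size[1L]) &&
           all(meta$x0 + ts[2L] <= info$mosaic_size[2L]),
         "metadata positions inconsistent with tile and mosaic sizes")
  tiles <- lapply(seq_len(info$cycles), function(cyc)
    lapply(seq_len(info$tiles), function(t) {
      arr <- array(0L, dim = c(ts[1L], ts[2L], info$z_planes, info$channels))
      for (ch in seq_len(info$channels))
        for (z in seq_len(info$z_planes)) {
          f <- file.path(in_dir, sprintf("c%d_t%d_ch%d_z%d.tif", cyc, t, ch, z))
          .check(file.exists(f),
                 sprintf("missing TIFF for cycle %d, tile %d, channel %d, z %d",
                         cyc, t, ch, z))
          img <- tiff::readTIFF(f)
          .check(all(dim(img) == ts),
                 sprintf("tile shape mismatch in %s", basename(f)))
          arr[, , z, ch] <- as.integer(round(img * 65535))
        }
      arr
    }))
  structure(list(tiles = tiles, metadata = meta,
                 channel_names = info$channel_names,
                 config = list(tile_size = as.integer(ts),
                               overlap_fraction = info$overlap_fraction,
                               mosaic_size = as.integer(info$mosaic_size))),
            class = "tileset")
}
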