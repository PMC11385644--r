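# Decoding: normalization, spot detection, color calling, codebook
# matching, quality filtering, serialization.

test_that("normalization is scale invariant and equalizes channel gains", {
  set.seed(30)
  base <- matrix(100 + rexp(64 * 64, 1 / 20), 64L, 64L)
  base[cbind(sample(10:50, 12L), sample(10:50, 12L))] <- 2000
  imgs <- list(array(c(base, base * 10), dim = c(64L, 64L, 2L)))
  norm <- normalize_images(imgs)
  # a 10x gain difference vanishes: identical planes after normalization
  expect_equal(norm[[1L]][, , 1L], norm[[1L]][, , 2L], tolerance = 1e-12)
  # multiplying the input by a constant leaves the output unchanged
  norm_k <- normalize_images(list(imgs[[1L]] * 7))
  expect_equal(norm_k, norm, tolerance = 1e-12)

  zero <- list(array(0, dim = c(8L, 8L, 1L)))
  expect_warning(nz <- normalize_images(zero), "all-zero")
  expect_equal(nz[[1L]], zero[[1L]])
})

test_that("per-channel pooling keeps a sparse plane on the shared scale", {
  set.seed(31)
  bright <- matrix(100 + rnorm(64 * 64, sd = 5), 64L, 64L)
  bright[20:22, 20:22] <- 600
  dim(bright) <- c(64L, 64L, 1L)
  dark <- matrix(100 + rnorm(64 * 64, sd = 5), 64L, 64L)  # no signal this cycle
  dim(dark) <- c(64L, 64L, 1L)
  pooled <- normalize_images(list(bright, dark))
  plane <- normalize_images(list(bright, dark), per = "plane")
  # pooled: the signal-free cycle stays near zero; per-plane amplifies noise
  expect_lt(max(pooled[[2L]]), 0.2)
  expect_gt(max(plane[[2L]]), 0.5)
})

test_that("single noiseless spots are detected at their true position", {
  sim <- make_mini_sim(spot_count = 1L, noise_sd = 0, crosstalk = 0,
                       tile = 64L, nuclei_count = 0L, seed = 32L,
                       spot_positions = data.frame(x = 40, y = 52, gene = "g3"))
  # one noiseless spot leaves some channels empty; those warnings are expected
  norm <- suppressWarnings(normalize_images(preprocess_tileset(sim$tileset)))
  det <- detect_spots(norm, channels = 1:4)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$y - 52) + abs(det$x - 40), 1.5)

  blank <- list(array(0.01, dim = c(64L, 64L, 4L)))
  expect_equal(nrow(detect_spots(blank, channels = 1:4)), 0L)
})

test_that("well-separated spots are essentially all detected", {
  sim <- make_mini_sim(spot_count = 100L, seed = 33L, min_separation = 8)
  norm <- normalize_images(preprocess_tileset(sim$tileset))
  det <- detect_spots(norm, channels = 1:4)
  d2 <- vapply(seq_len(nrow(det)), function(i)
    min((sim$truth$spots$x - det$x[i])^2 + (sim$truth$spots$y - det$y[i])^2),
    0)
  expect_gte(sum(d2 <= 4), 99L)   # matched within 2 px
})

test_that("intensity extraction averages patches and respects window 0", {
  flat <- list(array(rep(c(3, 7, 1, 5), each = 16L), dim = c(4L, 4L, 4L)))
  centers <- data.frame(y = 1, x = 2)
  v <- extract_intensities(flat, centers, channels = 1:4, window = 1L)
  expect_equal(as.vector(v[1L, 1L, ]), c(3, 7, 1, 5))
  v0 <- extract_intensities(flat, centers, channels = 1:4, window = 0L)
  expect_equal(as.vector(v0[1L, 1L, ]), c(3, 7, 1, 5))
  expect_error(extract_intensities(flat, data.frame(y = 9, x = 0), 1:4),
               "bounds")

  sim <- make_mini_sim(spot_count = 10L, noise_sd = 0, crosstalk = 0,
                       seed = 34L)
  norm <- normalize_images(preprocess_tileset(sim$tileset))
  intens <- extract_intensities(norm, sim$truth$spots, channels = 1:4)
  bc <- do.call(rbind, sim$codebook$entries[sim$truth$spots$gene])
  for (cyc in 1:2)
    expect_equal(unname(max.col(matrix(intens[, cyc, ], 10L, 4L)) - 1L),
                 unname(bc[, cyc]))
})

test_that("the quality score spans [1/x, 1] with the stated extremes", {
  # equal intensities across four channels: the random-assignment floor
  eq <- call_colors(matrix(5, 2L, 4L))
  expect_equal(eq$quality_per_cycle, c(0.25, 0.25))
  expect_true(eq$flagged)
  # all signal in one channel: perfect decoding
  one <- call_colors(matrix(c(9, 0, 0, 0), 1L, 4L))
  expect_equal(one$quality_per_cycle, 1)
  expect_equal(one$colors, 0L)
  # intermediate case 3 : 1 : 0 : 0
  mid <- call_colors(matrix(c(3, 1, 0, 0), 1L, 4L))
  expect_equal(mid$quality_per_cycle, 0.75)
  # summary statistics over cycles
  two <- call_colors(rbind(c(9, 0, 0, 0), c(3, 1, 0, 0)))
  expect_equal(two$quality_mean, (1 + 0.75) / 2)
  expect_equal(two$quality_min, 0.75)
  expect_error(call_colors(matrix(-1, 1L, 4L)), "negative")
  # all-zero cycle: floor quality, flagged
  z <- call_colors(rbind(c(1, 0, 0, 0), c(0, 0, 0, 0)))
  expect_equal(z$quality_per_cycle[2L], 0.25)
  expect_true(z$flagged)
})

test_that("quality is bounded, monotone in signal, and scale invariant", {
  set.seed(35)
  for (i in 1:200) {
    x <- sample(2:6, 1L)
    v <- matrix(stats::rexp(x), 1L, x)
    q <- call_colors(v)$quality_per_cycle
    expect_gte(q, 1 / x)
    expect_lte(q, 1)
    # raising the prominent channel can only increase the quality
    v2 <- v
    v2[which.max(v)] <- v2[which.max(v)] * 1.5
    expect_gte(call_colors(v2)$quality_per_cycle, q)
    # positive rescaling changes nothing
    qk <- call_colors(v * runif(1L, 0.1, 10))
    expect_equal(qk$quality_per_cycle, q)
  }
})

test_that("codebook matching agrees with brute-force lookup and keeps NO_MATCH", {
  cb <- build_codebook(paste0("g", 1:9), 4L, 2L, seed = 36L)
  set.seed(36)
  intens <- array(stats::rexp(50L * 2L * 4L), dim = c(50L, 2L, 4L))
  called <- call_colors(intens)
  decoded <- decode_spots(called, cb)
  for (i in seq_len(nrow(decoded))) {
    colors <- as.integer(strsplit(decoded$colors[i], "-")[[1L]])
    hit <- NULL
    for (g in names(cb$entries))
      if (all(cb$entries[[g]] == colors)) hit <- g
    expect_equal(decoded$gene[i], if (is.null(hit)) "NO_MATCH" else hit)
  }
  expect_true(any(decoded$gene == "NO_MATCH"))  # 9 of 16 codes are used
  # cycle-count mismatch is an error
  cb3 <- build_codebook(paste0("g", 1:4), 4L, 3L, seed = 1L)
  expect_error(decode_spots(called, cb3), "cycle")
})

test_that("quality filtering applies the threshold to the chosen statistic", {
  reads <- data.frame(x = 1:4, y = 1:4,
                      gene = c("a", "b", "NO_MATCH", "c"),
                      quality_mean = c(0.9, 0.6, 0.8, 0.52),
                      quality_min = c(0.8, 0.49, 0.7, 0.50))
  expect_equal(filter_reads(reads, 0.5)$gene, c("a", "NO_MATCH", "c"))
  expect_equal(filter_reads(reads, 0.5, mode = "mean")$gene,
               c("a", "b", "NO_MATCH", "c"))
  expect_equal(filter_reads(reads, 0.5, drop_no_match = TRUE)$gene,
               c("a", "c"))
  expect_equal(nrow(filter_reads(reads, 0.25)), 4L)  # 1/x keeps everything
})

test_that("read tables survive a CSV round trip including NO_MATCH rows", {
  sim <- make_mini_sim(spot_count = 20L, seed = 37L)
  reads <- decode_mosaic(preprocess_tileset(sim$tileset), sim$codebook)
  f <- tempfile(fileext = ".csv")
  write_read_table(reads, f)
  back <- read_read_table(f)
  expect_equal(back$gene, reads$gene)
  expect_equal(back$colors, reads$colors)
  expect_equal(back$quality_min, reads$quality_min, tolerance = 1e-12)
  # empty table: header-only file
  f2 <- tempfile(fileext = ".csv")
  write_read_table(reads[0L, ], f2)
  expect_length(readLines(f2), 1L)
})

test_that("decoding accuracy degrades monotonically with noise and crosstalk", {
  acc <- vapply(list(c(0, 0), c(20, 0.05), c(120, 0.35)), function(p) {
    sim <- make_mini_sim(spot_count = 40L, noise_sd = p[1L],
                         crosstalk = p[2L], seed = 38L, min_separation = 8)
    reads <- decode_mosaic(preprocess_tileset(sim$tileset), sim$codebook)
    correct_fraction(reads, sim$truth)
  }, 0)
  expect_equal(acc[1L], 1)               # exact at zero noise
  expect_true(all(diff(acc) <= 0))       # non-increasing in degradation
  expect_lt(acc[3L], acc[1L])
})
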