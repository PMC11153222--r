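test_that("default parameters give the canonical epoch dimensions", {
  wc <- window_config()
  expect_identical(wc$window_samples, 345L)  # 1.35 s at 256 Hz
  expect_identical(wc$hop_samples, 89L)      # 345 - 256
  p <- stft_params()
  expect_equal(p$window, c(0.08, 0.08))      # 2-sample Hamming taps
  bb <- band_bins(p)
  expect_identical(length(bb$index), 20L)    # [20, 60) Hz at 2 Hz spacing
  expect_equal(range(bb$freq_hz), c(20, 58))
  x <- withr::with_seed(1, rnorm(345))
  M <- stft_channel(x, p)
  expect_identical(dim(M), c(20L, 344L))
  ep <- stack_channels(replicate(6, M, simplify = FALSE), 0,
                       default_channels())
  expect_identical(dim(ep), c(120L, 344L))
  expect_identical(length(ep), 41280L)
  # row block 3 (rows 41-60) is channel 3 verbatim
  expect_equal(ep[41:60, ], M, ignore_attr = TRUE)
})

test_that("stft matches a brute-force zero-padded DFT of each frame", {
  p <- stft_params()
  bb <- band_bins(p)
  for (seed in 1:3) {
    x <- withr::with_seed(seed, rnorm(345))
    fr <- matrix(0, 128, 344)
    for (f in 1:344) fr[1:2, f] <- x[f:(f + 1)] * p$window
    bf <- pmax(10 * log10(Mod(stats::mvfft(fr)[bb$index, ])^2), p$floor_db)
    expect_lt(max(abs(bf - stft_channel(x, p))), 1e-12)
  }
})

test_that("silent input floors; scaling by 10 adds exactly 20 dB", {
  p <- stft_params()
  z <- stft_channel(numeric(400), p)
  expect_true(all(z == p$floor_db))
  x <- withr::with_seed(2, rnorm(345))
  d <- stft_channel(10 * x, p) - stft_channel(x, p)
  expect_lt(max(abs(d - 20)), 1e-9)
})

test_that("frame count matches brute-force enumeration for all lengths", {
  p <- stft_params()
  for (N in 2:500) {
    brute <- 0L
    s <- 1L
    while (s + p$win_len - 1L <= N) { brute <- brute + 1L; s <- s + p$hop }
    expect_identical(n_frames(N, p), brute)
  }
  expect_identical(n_frames(1, p), 0L)
})

test_that("per-frame Parseval identity holds over the full spectrum", {
  # sum over all nfft bins of |S|^2 equals nfft * windowed-frame energy
  p_full <- stft_params(band = c(0, 128.5))
  p <- stft_params()
  x <- withr::with_seed(3, rnorm(50))
  S_half <- rtseizure:::stft_band_complex(x, p_full)  # bins 0..64
  pw <- Mod(S_half)^2
  total <- pw[1, ] + pw[65, ] + 2 * colSums(pw[2:64, ])
  frame_energy <- vapply(seq_len(ncol(pw)), function(f) {
    sum((x[f:(f + 1)] * p$window)^2)
  }, numeric(1))
  expect_lt(max(abs(total - 128 * frame_energy)), 1e-10)
})

test_that("spectrogram is shift-covariant over whole hops", {
  p <- stft_params()
  x <- withr::with_seed(4, rnorm(500))
  k <- 7L
  a <- stft_channel(x, p)
  b <- stft_channel(x[-(1:k)], p)
  expect_lt(max(abs(a[, (k + 1):ncol(b)] - b[, 1:(ncol(b) - k)])), 1e-9)
})

test_that("a tone is localized to its bin when the window resolves it", {
  p <- stft_params(win_len = 64, hop = 16, nfft = 128)
  x <- sin(2 * pi * 40 * (0:344) / 256)
  M <- stft_channel(x, p)
  bb <- band_bins(p)
  expect_equal(bb$freq_hz[which.max(rowMeans(10^(M / 10)))], 40)
})

test_that("named rhythm bands select the documented edges and bin counts", {
  expect_equal(rhythm_band("selected"), c(20, 60))
  expect_equal(rhythm_band("gamma"), c(30, 60))
  expect_equal(rhythm_band("delta"), c(1, 4))
  expect_equal(rhythm_band("theta"), c(4, 8))
  expect_equal(rhythm_band("alpha"), c(8, 12))
  expect_equal(rhythm_band("beta"), c(12, 30))
  expect_error(rhythm_band("mu"), "unknown")
  # half-open band selection: gamma has 15 bins at 2 Hz spacing
  expect_identical(length(band_bins(stft_params(band = c(30, 60)))$index), 15L)
  expect_error(band_bins(stft_params(band = c(60.5, 61))), "zero bins")
})

test_that("sliding windows enumerate exactly the complete offsets", {
  wc <- window_config()
  expect_identical(length(window_offsets(2560, wc)), 25L)   # 10 s
  expect_identical(length(window_offsets(15360, wc)), 169L) # 60 s
  expect_identical(window_offsets(256, wc), integer())      # 1 s: too short
  # brute force: offsets are 0, hop, ... with the window fully inside
  offs <- window_offsets(5000, wc)
  brute <- seq(0, 5000 - 345, by = 89)
  expect_identical(offs, as.integer(brute))
  rec <- toy_recording(seconds = 10)
  sw <- sliding_windows(rec, wc)
  expect_identical(nrow(sw), 25L)
  expect_identical(dim(sw$samples[[2]]), c(6L, 345L))
  expect_equal(sw$start_s[2], 89 / 256)
  expect_error(window_config(1.35, 1.4), "overlap")
})

test_that("window labeling follows the half-overlap rule", {
  ann <- seizure_annotation(361, 413)
  # 0.35 s overlap < 0.675 s threshold
  expect_identical(label_window(360.0, 1.35, ann), "seizure-free")
  expect_identical(label_window(362, 1.35, ann), "seizure-active")
  expect_identical(label_window(100, 1.35, seizure_annotation()),
                   "seizure-free")
  # exactly half the window inside counts as active
  expect_identical(label_window(361 - 0.675, 1.35, ann), "seizure-active")
})

test_that("epoch extraction equals per-window transforms and labels", {
  rec <- toy_recording(seconds = 8, seed = 5)
  wc <- window_config()
  p <- stft_params()
  ann <- seizure_annotation(3, 6)
  es <- extract_epochs(rec, wc, p, ann = ann)
  expect_identical(dim(es$epochs)[1:2], c(120L, 344L))
  i <- 4L
  off <- window_offsets(ncol(rec$signals), wc)[i]
  per_ch <- lapply(1:6, function(ch) {
    stft_channel(rec$signals[ch, (off + 1):(off + 345)], p)
  })
  expect_equal(es$epochs[, , i], unclass(do.call(rbind, per_ch)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(es$labels,
                   label_window(es$start_s, wc$window_s, ann))
  # epoch persistence round trip
  path <- withr::local_tempfile(fileext = ".rds")
  save_epochs(es, path)
  expect_equal(load_epochs(path), es)
})
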