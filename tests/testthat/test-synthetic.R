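short_cfg <- function(seed = 1, boost = 20, duration = 120) {
  synth_config(duration_s = duration,
               seizures = data.frame(onset_s = 40, duration_s = 30,
                                     band_boost_db = boost),
               seed = seed)
}

# independent in-band power oracle: averaged segment periodograms
welch_band_power <- function(x, fs, band, seg = 512) {
  ns <- floor(length(x) / seg)
  p <- 0
  for (i in seq_len(ns)) {
    v <- x[((i - 1) * seg + 1):(i * seg)]
    X <- fft(v)
    f <- (seq_along(v) - 1) * fs / seg
    sel <- f >= band[1] & f <= band[2]
    p <- p + sum(Mod(X[sel])^2) / seg^2
  }
  p / ns
}

test_that("the generator is reproducible and honors its annotations", {
  cfg <- short_cfg(seed = 42)
  g1 <- generate_recording(cfg)
  g2 <- generate_recording(cfg)
  expect_identical(g1$recording$signals, g2$recording$signals)
  expect_identical(g1$annotation$onset_s, 40)
  expect_identical(g1$annotation$offset_s, 70)
  expect_identical(dim(g1$recording$signals), c(6L, 30720L))
  expect_identical(g1$recording$channel_labels, default_channels())
  # no seizures: empty annotation
  g0 <- generate_recording(synth_config(duration_s = 60,
                                        seizures = data.frame(
                                          onset_s = numeric(),
                                          duration_s = numeric()),
                                        seed = 3))
  expect_identical(nrow(g0$annotation), 0L)
  # invalid intervals rejected
  expect_error(synth_config(duration_s = 50,
                            seizures = data.frame(onset_s = 40,
                                                  duration_s = 30)),
               "within")
  expect_error(synth_config(duration_s = 200,
                            seizures = data.frame(onset_s = c(10, 30),
                                                  duration_s = c(30, 20))),
               "overlap")
})

test_that("seizure in-band power boost matches its setting within 3 dB", {
  for (boost in c(6, 12, 20)) {
    for (seed in 1:5) {
      g <- generate_recording(short_cfg(seed = seed, boost = boost))
      x <- g$recording$signals[1 + seed %% 6, ]
      sez <- x[(40 * 256 + 1):(70 * 256)]
      bg <- x[c(1:(38 * 256), (72 * 256 + 1):(118 * 256))]
      measured <- 10 * log10(welch_band_power(sez, 256, c(20, 60)) /
                               welch_band_power(bg, 256, c(20, 60)))
      expect_lt(abs(measured - boost), 3)
    }
  }
})

test_that("the seizure-free background is stationary in-band", {
  g <- generate_recording(synth_config(duration_s = 150,
                                       seizures = data.frame(
                                         onset_s = numeric(),
                                         duration_s = numeric()),
                                       seed = 8))
  x <- g$recording$signals[1, ]
  p1 <- welch_band_power(x[1:(60 * 256)], 256, c(20, 60))
  p2 <- welch_band_power(x[(80 * 256 + 1):(140 * 256)], 256, c(20, 60))
  expect_lt(abs(10 * log10(p1 / p2)), 2)
})

test_that("amplitude-depression seizures suppress rather than boost power", {
  cfg <- synth_config(duration_s = 120,
                      seizures = data.frame(onset_s = 40, duration_s = 30,
                                            depression = TRUE),
                      seed = 5)
  g <- generate_recording(cfg)
  x <- g$recording$signals[1, ]
  v_sez <- var(x[(50 * 256 + 1):(70 * 256)])   # past the onset ramp
  v_bg <- var(x[1:(38 * 256)])
  expect_lt(v_sez, v_bg)
})

test_that("multi-subject datasets differ by seed and support LOSO", {
  ds <- generate_dataset(4, synth_config(duration_s = 60,
                                         seizures = data.frame(
                                           onset_s = 20, duration_s = 20),
                                         seed = 10))
  expect_identical(length(ds), 4L)
  expect_identical(names(ds), paste0("subject", 1:4))
  sigs <- lapply(ds, function(d) d$recording$signals)
  for (i in 1:3) expect_false(identical(sigs[[i]], sigs[[i + 1]]))
  expect_true(all(vapply(ds, function(d) nrow(d$annotation) >= 1,
                         logical(1))))
  folds <- loso_folds(names(ds))
  expect_identical(length(folds), 4L)
  expect_setequal(vapply(folds, `[[`, character(1), "test"), names(ds))
})

test_that("synthetic EDF trio round-trips through the package readers", {
  g <- generate_recording(synth_config(duration_s = 60,
                                       seizures = data.frame(
                                         onset_s = 15, duration_s = 20),
                                       seed = 11))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_edf(g$recording, g$annotation, dir, "s1")
  expect_true(all(file.exists(paths)))
  back <- read_edf_recording(paths[["edf"]])
  expect_identical(back$fs, 256)
  step <- 2 * max(abs(g$recording$signals)) * 1.01 / 65535
  expect_lt(max(abs(back$signals - g$recording$signals)), 1.5 * step)
  a1 <- read_annotations(paths[["summary"]], "chbmit_summary")[["s1.edf"]]
  a2 <- read_annotations(paths[["csv"]], "csv")[[1]]
  expect_identical(a1$onset_s, g$annotation$onset_s)
  expect_identical(a2$offset_s, g$annotation$offset_s)
})
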