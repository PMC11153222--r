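# engine internals exercised through rtseizure::: (the public surface is
# build_model / train_model / predict_epoch)

test_that("analytic gradients match finite differences on a small net", {
  ns <- asNamespace("rtseizure")
  net <- withr::with_seed(3, {
    ns$u_seq(list(
      ns$u_conv(1L, 3L, c(3L, 3L), c(1L, 1L), "valid"),
      ns$u_bn(3L), ns$u_relu(),
      ns$u_pool("maxpool", c(2L, 2L), c(2L, 2L), "ceil"),
      ns$u_fc(18L, 2L), ns$u_softmax()))
  })
  x <- withr::with_seed(4, array(rnorm(6 * 8 * 4), c(6, 8, 4)))
  y <- c(1, 2, 1, 2)
  loss_of <- function(nn) {
    fw <- ns$unit_forward(nn, ns$array_tensor(x), training = TRUE)
    ns$softmax_xent(fw$out$x, y, rep(1, 4))$loss
  }
  fw <- ns$unit_forward(net, ns$array_tensor(x), training = TRUE)
  sx <- ns$softmax_xent(fw$out$x, y, rep(1, 4))
  bw <- ns$unit_backward(net, sx$dlogits, fw$cache, need_dx = FALSE)
  eps <- 1e-6
  check <- function(ui, pname, g) {
    ks <- withr::with_seed(ui, sample(length(net$units[[ui]][[pname]]),
                                      min(6, length(g))))
    for (k in ks) {
      n2 <- net; n2$units[[ui]][[pname]][k] <- net$units[[ui]][[pname]][k] + eps
      n3 <- net; n3$units[[ui]][[pname]][k] <- net$units[[ui]][[pname]][k] - eps
      g_num <- (loss_of(n2) - loss_of(n3)) / (2 * eps)
      expect_lt(abs(g_num - g[k]) / max(abs(g_num), 1e-4), 1e-4)
    }
  }
  check(1, "W", bw$grads[[1]]$W)
  check(2, "gamma", bw$grads[[2]]$gamma)
  check(2, "beta", bw$grads[[2]]$beta)
  check(5, "W", bw$grads[[5]]$W)
  check(5, "b", bw$grads[[5]]$b)
})

test_that("inception block gradients are correct through all branches", {
  ns <- asNamespace("rtseizure")
  net <- withr::with_seed(5, {
    ns$u_seq(list(
      ns$u_inception(2L, list(b1 = 2L, b3r = 2L, b3 = 3L, b5r = 1L,
                              b5 = 2L, bp = 1L)),
      ns$u_pool("avgpool", c(5L, 6L), c(1L, 1L), "valid"),
      ns$u_fc(8L, 2L), ns$u_softmax()))
  })
  x <- withr::with_seed(6, matrix(rnorm(5 * 6 * 2 * 3), ncol = 2))
  tens <- ns$new_tensor(x, 3L, 5L, 6L, 2L)
  y <- c(2, 1, 2)
  loss_of <- function(nn) {
    ns$softmax_xent(ns$unit_forward(nn, tens, training = TRUE)$out$x,
                    y, rep(1, 3))$loss
  }
  fw <- ns$unit_forward(net, tens, training = TRUE)
  bw <- ns$unit_backward(net, ns$softmax_xent(fw$out$x, y,
                                              rep(1, 3))$dlogits,
                         fw$cache, need_dx = FALSE)
  eps <- 1e-6
  # one conv weight from each branch (3x3 branch and pool branch)
  paths <- list(c(2, 2), c(4, 2))    # (branch, conv-bn-relu position)
  for (p in paths) {
    g <- bw$grads[[1]][[p[1]]][[p[2]]][[1]]$W
    for (k in withr::with_seed(p[1],
                               sample(length(g), min(4, length(g))))) {
      bump <- function(nn, d) {
        nn$units[[1]]$branches[[p[1]]]$units[[p[2]]]$units[[1]]$W[k] <-
          nn$units[[1]]$branches[[p[1]]]$units[[p[2]]]$units[[1]]$W[k] + d
        nn
      }
      g_num <- (loss_of(bump(net, eps)) - loss_of(bump(net, -eps))) / (2 * eps)
      expect_lt(abs(g_num - g[k]) / max(abs(g_num), 1e-4), 1e-4)
    }
  }
})

test_that("forward pass normalizes probabilities and batches correctly", {
  m <- build_model(reduced_architecture(4), seed = 11)
  eps4 <- withr::with_seed(12, array(rnorm(120 * 344 * 4), c(120, 344, 4)))
  pr <- predict_epoch(m, eps4)
  expect_identical(nrow(pr), 4L)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  # single epoch and repeated prediction are deterministic
  one <- predict_epoch(m, eps4[, , 2])
  expect_identical(one, predict_epoch(m, eps4[, , 2]))
  expect_equal(one$probability, pr$probability[2], tolerance = 1e-12)
  # same seed, same initial network
  m2 <- build_model(reduced_architecture(4), seed = 11)
  expect_identical(predict_epoch(m2, eps4), pr)
  # shape mismatch is caught
  expect_error(predict_epoch(m, matrix(0, 60, 344)), "shape")
})

test_that("the full default architecture runs forward to 2 probabilities", {
  m <- build_model(default_architecture(), seed = 2)
  expect_gt(rtseizure:::count_params(m$net), 5e6)
  ep <- withr::with_seed(13, matrix(rnorm(120 * 344), 120))
  pr <- predict_epoch(m, ep)
  expect_identical(nrow(pr), 1L)
  expect_true(pr$label %in% detector_classes())
  expect_true(pr$probability >= 0 && pr$probability <= 1)
})

test_that("training separates a planted band-power offset and is seeded", {
  toy <- toy_epochs(n = 48)
  cfg <- train_config(epochs = 3, batch_size = 8, val_frequency = 4,
                      seed = 21)
  m <- train_model(build_model(reduced_architecture(), seed = 5),
                   toy$epochs, toy$labels, cfg)
  pr <- predict_epoch(m, toy$epochs)
  expect_identical(pr$label, toy$labels)          # 100% training accuracy
  # a held-out floor-only epoch is classified seizure-free
  ho <- withr::with_seed(22, matrix(-60 + rnorm(120 * 344, sd = 2), 120))
  expect_identical(predict_epoch(m, ho)$label, "seizure-free")
  # bitwise-identical repeat under the same seed
  m2 <- train_model(build_model(reduced_architecture(), seed = 5),
                    toy$epochs, toy$labels, cfg)
  expect_identical(m$history, m2$history)
  expect_identical(predict_epoch(m2, ho), predict_epoch(m, ho))
  # history bookkeeping: loss finite, validation rows at the set frequency
  expect_true(all(is.finite(m$history$loss)))
  val_rows <- which(!is.na(m$history$val_acc))
  expect_identical(val_rows, which(m$history$iteration %% 4 == 0))
})

test_that("the validation split is a stratified 20% hold-out", {
  toy <- toy_epochs(n = 100)
  cfg <- train_config(epochs = 1, batch_size = 32, val_frequency = 50,
                      seed = 31)
  m <- train_model(build_model(reduced_architecture(4), seed = 6),
                   toy$epochs, toy$labels, cfg)
  expect_identical(length(m$val_idx), 20L)
  expect_identical(sum(toy$labels[m$val_idx] == "seizure-active"), 10L)
})

test_that("degenerate training inputs are rejected", {
  toy <- toy_epochs(n = 8)
  m <- build_model(reduced_architecture(4), seed = 1)
  expect_error(train_model(m, toy$epochs,
                           rep("seizure-free", 8), train_config()),
               "single class")
  expect_error(train_model(m, toy$epochs, toy$labels[1:4], train_config()),
               "labels")
  expect_error(train_config(val_fraction = 0), "val_fraction")
})

test_that("test accuracy does not degrade as the planted SNR grows", {
  offsets <- c(0, 6, 20)     # dB separation between the classes
  means <- vapply(offsets, function(off) {
    accs <- vapply(1:2, function(s) {
      toy <- toy_epochs(n = 24, seed = 100 + s, offset_db = off)
      te <- toy_epochs(n = 12, seed = 200 + s, offset_db = off)
      m <- train_model(build_model(reduced_architecture(4), seed = s),
                       toy$epochs, toy$labels,
                       train_config(epochs = 4, batch_size = 6,
                                    val_frequency = 50, seed = s))
      mean(predict_epoch(m, te$epochs)$label == te$labels)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_gt(suppressWarnings(cor(means, seq_along(offsets),
                                 method = "spearman")), 0)
  expect_gt(means[3], 0.9)
})
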