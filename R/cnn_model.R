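#' Training configuration
#'
#' Defaults follow the detection pipeline's training protocol: SGD with
#' momentum 0.9, learning rate 0.01, 30 epochs, a stratified hold-out
#' validation split of 20% of the training data, and validation accuracy
#' recorded every 50 iterations.
#'
#' @param learning_rate SGD learning rate (default 0.01).
#' @param epochs passes over the training data (default 30).
#' @param val_fraction fraction held out for validation (default 0.2).
#' @param val_frequency iterations between validation evaluations (default 50).
#' @param batch_size mini-batch size (default 32).
#' @param momentum SGD momentum coefficient (default 0.9).
#' @param seed RNG seed driving the split, shuffling, and dropout.
#' @param class_weighting if `TRUE`, inverse-frequency class weights are
#'   applied in the loss (off by default).
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 30,
                         val_fraction = 0.2, val_frequency = 50,
                         batch_size = 32, momentum = 0.9, seed = 1,
                         class_weighting = FALSE) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stopf("val_fraction must be in (0, 1)")
  }
  if (epochs < 1) stopf("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 val_fraction = val_fraction,
                 val_frequency = as.integer(val_frequency),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed),
                 class_weighting = isTRUE(class_weighting)),
            class = "train_config")
}

#' Class labels used by the detector
#' @return `c("seizure-free", "seizure-active")`; the second is the positive
#'   class.
#' @export
detector_classes <- function() c("seizure-free", "seizure-active")

#' Build an (untrained) detection model from an architecture
#'
#' Instantiates the network: each convolution is followed by batch
#' normalization and ReLU; weights use seeded He-normal initialization.
#'
#' @param arch a `cnn_arch`, e.g. [default_architecture()].
#' @param seed integer seed for reproducible initialization.
#' @return object of class `cnn_model` with fields `arch`, `net`,
#'   `norm_mean` (input zero-centering constant, set by [train_model()]),
#'   `history`, `classes`.
#' @export
build_model <- function(arch, seed = 1) {
  tr <- shape_trace(arch)   # validates shape consistency before building
  fc_row <- tr[tr$kind == "fc", ][1, ]
  net <- with_seed(seed, {
    units <- list()
    cin <- arch$input_shape[3]
    for (l in arch$layers) {
      if (l$kind == "input") next
      u <- switch(l$kind,
        conv = conv_bn_relu(cin, l$channels, l$kernel, l$stride, l$pad),
        maxpool = u_pool("maxpool", l$kernel, l$stride, l$pad),
        avgpool = u_pool("avgpool", l$kernel, l$stride, l$pad),
        inception = u_inception(cin, l$alloc),
        dropout = u_dropout(l$rate),
        fc = u_fc(fc_row$in_h * fc_row$in_w * fc_row$in_c, l$channels),
        softmax = u_softmax(),
        stopf("unknown layer kind '%s'", l$kind))
      units[[length(units) + 1]] <- u
      if (!is.null(l$channels)) cin <- l$channels
    }
    u_seq(units)
  })
  structure(list(arch = arch, net = net, norm_mean = 0,
                 history = NULL, seed = seed,
                 classes = detector_classes()),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d-level architecture, %s parameters%s\n",
              n_levels(x$arch),
              format(count_params(x$net), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

# epochs: H x W x N array -> normalized batch tensor
epochs_tensor <- function(model, epochs, idx = NULL) {
  if (!is.null(idx)) epochs <- epochs[, , idx, drop = FALSE]
  tens <- array_tensor(epochs)
  tens$x <- tens$x - model$norm_mean
  tens
}

# forward in inference mode, batched; returns N x 2 probability matrix
model_probs <- function(model, epochs, batch = 128L) {
  n <- dim(epochs)[3]
  out <- matrix(0, n, length(model$classes))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    tens <- epochs_tensor(model, epochs, i:j)
    out[i:j, ] <- unit_forward(model$net, tens, training = FALSE)$out$x
    i <- j + 1L
  }
  colnames(out) <- model$classes
  out
}

#' Classify spectrogram epochs
#'
#' Deterministic inference (dropout inactive, batch-norm running statistics).
#'
#' @param model a trained `cnn_model`.
#' @param epochs one epoch matrix (rows x frames) or an array
#'   rows x frames x n.
#' @param batch inference batch size.
#' @return data.frame with `label` and `probability` (of the positive,
#'   seizure-active class), one row per epoch.
#' @export
predict_epoch <- function(model, epochs, batch = 128L) {
  if (is.matrix(epochs)) {
    epochs <- array(epochs, c(dim(epochs), 1L))
  }
  d <- dim(epochs)
  tr <- shape_trace(model$arch)
  if (d[1] != model$arch$input_shape[1] || d[2] != model$arch$input_shape[2]) {
    stopf("epoch shape %dx%d does not match model input %dx%d",
          d[1], d[2], model$arch$input_shape[1], model$arch$input_shape[2])
  }
  p <- model_probs(model, epochs, batch)
  data.frame(label = model$classes[max.col(p, ties.method = "first")],
             probability = unname(p[, 2]),
             stringsAsFactors = FALSE)
}

# cross-entropy loss + gradient at the logits for a batch
softmax_xent <- function(probs, y_idx, weights) {
  n <- nrow(probs)
  p_y <- pmax(probs[cbind(seq_len(n), y_idx)], 1e-12)
  wsum <- sum(weights)
  loss <- -sum(weights * log(p_y)) / wsum
  Y <- matrix(0, n, ncol(probs))
  Y[cbind(seq_len(n), y_idx)] <- 1
  dlogits <- (probs - Y) * (weights / wsum)
  list(loss = loss, dlogits = dlogits)
}

#' Train a detection model
#'
#' Mini-batch stochastic gradient descent with momentum on the 2-class
#' cross-entropy. The training set is zero-centered by its scalar mean
#' (stored in the model and applied at inference); the validation split is
#' stratified by label; validation accuracy is recorded every
#' `cfg$val_frequency` iterations. Fully reproducible given `cfg$seed`.
#'
#' @param model an untrained `cnn_model` from [build_model()].
#' @param epochs array rows x frames x n of spectrogram epochs.
#' @param labels character vector of length n with values in
#'   [detector_classes()].
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return the trained `cnn_model`; `$history` holds a data.frame with
#'   columns `iteration`, `epoch`, `loss`, `train_acc`, `val_acc` (`val_acc`
#'   is `NA` except on validation iterations).
#' @export
train_model <- function(model, epochs, labels, cfg = train_config(),
                        verbose = FALSE) {
  n <- dim(epochs)[3]
  if (length(labels) != n) stopf("%d labels for %d epochs", length(labels), n)
  y_all <- match(labels, model$classes)
  if (anyNA(y_all)) stopf("labels must be in {%s}",
                          paste(model$classes, collapse = ", "))
  if (length(unique(y_all)) < 2) {
    stopf("training data contains a single class; need both")
  }

  with_seed(cfg$seed, {
    # stratified validation split
    val_idx <- unlist(lapply(unique(y_all), function(k) {
      ki <- which(y_all == k)
      sample(ki, max(1L, round(cfg$val_fraction * length(ki))))
    }))
    tr_idx <- setdiff(seq_len(n), val_idx)

    model$norm_mean <- mean(epochs[, , tr_idx])

    cw <- c(1, 1)
    if (cfg$class_weighting) {
      tab <- tabulate(y_all[tr_idx], 2)
      cw <- sum(tab) / (2 * pmax(tab, 1))
    }

    net <- model$net
    vel <- NULL
    hist <- list()
    it <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      nb <- ceiling(length(ord) / cfg$batch_size)
      for (b in seq_len(nb)) {
        bi <- ord[((b - 1L) * cfg$batch_size + 1L):
                    min(b * cfg$batch_size, length(ord))]
        tens <- epochs_tensor(model, epochs, bi)
        fw <- unit_forward(net, tens, training = TRUE)
        probs <- fw$out$x
        sx <- softmax_xent(probs, y_all[bi], cw[y_all[bi]])
        if (!is.finite(sx$loss)) {
          stopf("non-finite training loss at iteration %d (lr too high?)", it)
        }
        bw <- unit_backward(net, sx$dlogits, fw$cache, need_dx = FALSE)
        upd <- walk_update(net, bw$grads, vel, cfg$learning_rate,
                           cfg$momentum)
        net <- walk_bn_update(upd$unit, bw$batch_stats)
        vel <- upd$vel
        it <- it + 1L

        acc <- mean(max.col(probs, ties.method = "first") == y_all[bi])
        val_acc <- NA_real_
        if (it %% cfg$val_frequency == 0L) {
          m2 <- model; m2$net <- net
          vp <- model_probs(m2, epochs[, , val_idx, drop = FALSE])
          val_acc <- mean(max.col(vp, ties.method = "first") ==
                            y_all[val_idx])
        }
        hist[[length(hist) + 1]] <-
          data.frame(iteration = it, epoch = ep, loss = sx$loss,
                     train_acc = acc, val_acc = val_acc)
      }
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f", ep, cfg$epochs, sx$loss))
      }
    }
    # finalize batch-norm statistics over the full training set (population
    # statistics, as the training toolbox computes after the last iteration)
    m2 <- model; m2$net <- net
    acc <- NULL; nb2 <- 0L
    i <- 1L
    while (i <= length(tr_idx)) {
      j <- min(i + cfg$batch_size - 1L, length(tr_idx))
      tens <- epochs_tensor(m2, epochs, tr_idx[i:j])
      fw <- unit_forward(net, tens, training = TRUE)
      st <- collect_bn_stats(net, fw$cache)
      st <- lapply(st, function(s) list(mu = s$mu, m2 = s$v + s$mu^2))
      acc <- if (is.null(acc)) st else {
        Map(function(a, s) list(mu = a$mu + s$mu, m2 = a$m2 + s$m2), acc, st)
      }
      nb2 <- nb2 + 1L
      i <- j + 1L
    }
    finals <- lapply(acc, function(a) {
      mu <- a$mu / nb2
      list(mu = mu, v = pmax(a$m2 / nb2 - mu^2, 0))
    })
    net <- assign_bn_stats(net, finals)

    model$net <- net
    model$history <- do.call(rbind, hist)
    model$val_idx <- sort(val_idx)
    model
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture, weights, normalization constant
#' and training history.
#'
#' @param model a `cnn_model`.
#' @param path file path (RDS).
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

# ---------------------------------------------------------------------------
# Training protocol

#' Peri-ictal training segments
#'
#' For each annotated seizure, the training protocol uses the raw EEG from
#' `pre_min` minutes before onset to `post_min` minutes after onset
#' (defaults 10 and 5), clipped to the recording and merged when seizures
#' are close together.
#'
#' @param duration_s recording duration in seconds (or an `eeg_recording`).
#' @param ann a [seizure_annotation()].
#' @param pre_min,post_min minutes before/after each onset.
#' @return data.frame with `start_s`, `end_s` (merged, sorted).
#' @export
extract_training_segments <- function(duration_s, ann, pre_min = 10,
                                      post_min = 5) {
  if (inherits(duration_s, "eeg_recording")) {
    rec <- duration_s
    duration_s <- ncol(rec$signals) / rec$fs
  }
  if (nrow(ann) == 0) {
    return(data.frame(start_s = numeric(), end_s = numeric()))
  }
  s <- pmax(0, ann$onset_s - pre_min * 60)
  e <- pmin(duration_s, ann$onset_s + post_min * 60)
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out <- list()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out[[length(out) + 1]] <- c(ms, me)
      ms <- s[i]; me <- e[i]
    }
  }
  out[[length(out) + 1]] <- c(ms, me)
  m <- do.call(rbind, out)
  data.frame(start_s = m[, 1], end_s = m[, 2])
}

#' Leave-one-subject-out folds
#'
#' @param subjects character vector of subject ids (>= 2).
#' @return list of folds, each `list(train = ..., test = ...)`; every
#'   subject is the test subject exactly once.
#' @export
loso_folds <- function(subjects) {
  subjects <- unique(subjects)
  if (length(subjects) < 2) stopf("leave-one-subject-out needs >= 2 subjects")
  lapply(subjects, function(s) {
    list(train = setdiff(subjects, s), test = s)
  })
}

#' Build a labeled training set from recordings
#'
#' Filters each recording ([apply_zero_phase()]), restricts windows to the
#' peri-ictal training segments ([extract_training_segments()]), extracts
#' spectrogram epochs and labels them. `train_stride` keeps every k-th
#' window (thinning highly overlapping windows for desk-scale training).
#'
#' @param recordings named list of `eeg_recording`.
#' @param annotations named list of [seizure_annotation()] (same names).
#' @param wcfg,p,fspec window, STFT and filter parameters.
#' @param train_stride keep every k-th eligible window (default 1 = all).
#' @param min_overlap_frac labeling threshold, see [label_window()].
#' @return list with `epochs` (rows x frames x n), `labels`, `subject`
#'   (per-epoch subject id), `start_s`.
#' @export
make_training_set <- function(recordings, annotations,
                              wcfg = window_config(),
                              p = stft_params(),
                              fspec = NULL, train_stride = 1L,
                              min_overlap_frac = 0.5) {
  stopifnot(length(recordings) >= 1,
            all(names(recordings) %in% names(annotations)))
  parts <- list()
  for (nm in names(recordings)) {
    rec <- recordings[[nm]]
    ann <- annotations[[nm]]
    if (!is.null(fspec)) rec <- apply_zero_phase(rec, fspec)
    offs <- window_offsets(ncol(rec$signals), wcfg)
    segs <- extract_training_segments(duration_s(rec), ann)
    if (nrow(segs)) {
      st <- offs / wcfg$fs
      en <- st + wcfg$window_s
      keep <- rep(FALSE, length(offs))
      for (i in seq_len(nrow(segs))) {
        keep <- keep | (st >= segs$start_s[i] & en <= segs$end_s[i])
      }
      offs <- offs[keep]
    } else {
      offs <- integer()
    }
    offs <- offs[seq_along(offs) %% train_stride == 1L %% train_stride]
    es <- extract_epochs(rec, wcfg, p, ann = ann, offsets = offs,
                         min_overlap_frac = min_overlap_frac)
    parts[[nm]] <- es
  }
  ns <- vapply(parts, function(e) length(e$start_s), integer(1))
  d1 <- dim(parts[[1]]$epochs)
  epochs <- array(0, c(d1[1], d1[2], sum(ns)))
  at <- 0L
  for (nm in names(parts)) {
    k <- length(parts[[nm]]$start_s)
    if (k) epochs[, , (at + 1):(at + k)] <- parts[[nm]]$epochs
    at <- at + k
  }
  list(epochs = epochs,
       labels = unlist(lapply(parts, `[[`, "labels"), use.names = FALSE),
       subject = rep(names(parts), ns),
       start_s = unlist(lapply(parts, `[[`, "start_s"), use.names = FALSE))
}
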