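# Architecture description: an ordered list of layer rows mirroring the
# network's layer table. Levels are numbered automatically; an inception
# block counts as depth 2 (as in the original GoogLeNet depth accounting),
# which reproduces the printed level ids 1..29 with the final fully
# connected layer at level 29. Input and softmax rows are unnumbered.

layer_row <- function(kind, kernel = NULL, stride = c(1L, 1L),
                      channels = NULL, rate = NULL, pad = NULL,
                      alloc = NULL) {
  list(kind = kind, kernel = kernel, stride = stride, channels = channels,
       rate = rate, pad = pad, alloc = alloc)
}

#' Canonical inception branch allocation
#'
#' Per-branch output channels for the four parallel branches of an inception
#' block: 1x1 conv; 1x1 reduce then 3x3 conv; 1x1 reduce then 5x5 conv;
#' 3x3 max-pool then 1x1 conv (six convolutions per block). The nine blocks
#' use the canonical GoogLeNet allocations (3a..5b), whose totals are
#' 256, 480, 512, 512, 512, 528, 832, 832, 1024.
#'
#' @param position inception index 1..9 for the canonical table, or `NULL`.
#' @param out_channels required total; for non-canonical totals a
#'   proportional split is derived (quarter 1x1, half 3x3, eighth 5x5,
#'   remainder pool branch; reducers at half the branch width).
#' @return list with `b1`, `b3r`, `b3`, `b5r`, `b5`, `bp` channel counts;
#'   `b1 + b3 + b5 + bp == out_channels`.
#' @export
inception_allocation <- function(out_channels, position = NULL) {
  canon <- list(
    list(b1 =  64, b3r =  96, b3 = 128, b5r = 16, b5 =  32, bp =  32), # 256
    list(b1 = 128, b3r = 128, b3 = 192, b5r = 32, b5 =  96, bp =  64), # 480
    list(b1 = 192, b3r =  96, b3 = 208, b5r = 16, b5 =  48, bp =  64), # 512
    list(b1 = 160, b3r = 112, b3 = 224, b5r = 24, b5 =  64, bp =  64), # 512
    list(b1 = 128, b3r = 128, b3 = 256, b5r = 24, b5 =  64, bp =  64), # 512
    list(b1 = 112, b3r = 144, b3 = 288, b5r = 32, b5 =  64, bp =  64), # 528
    list(b1 = 256, b3r = 160, b3 = 320, b5r = 32, b5 = 128, bp = 128), # 832
    list(b1 = 256, b3r = 160, b3 = 320, b5r = 32, b5 = 128, bp = 128), # 832
    list(b1 = 384, b3r = 192, b3 = 384, b5r = 48, b5 = 128, bp = 128)) # 1024
  if (!is.null(position) && position >= 1 && position <= 9) {
    a <- canon[[position]]
    if (a$b1 + a$b3 + a$b5 + a$bp == out_channels) return(a)
  }
  b1 <- max(1L, floor(out_channels / 4))
  b5 <- max(1L, floor(out_channels / 8))
  bp <- max(1L, floor(out_channels / 8))
  b3 <- out_channels - b1 - b5 - bp
  if (b3 < 1) stopf("out_channels %d too small for an inception block",
                    out_channels)
  list(b1 = b1, b3r = max(1L, floor(b3 / 2)), b3 = b3,
       b5r = max(1L, floor(b5 / 2)), b5 = b5, bp = bp)
}

new_cnn_arch <- function(rows, input_shape, n_classes = 2) {
  lvl <- 1L
  ipos <- 0L
  for (i in seq_along(rows)) {
    k <- rows[[i]]$kind
    if (k %in% c("input", "softmax")) {
      rows[[i]]$level <- NA_integer_
    } else {
      rows[[i]]$level <- lvl
      lvl <- lvl + if (k == "inception") 2L else 1L
    }
    if (k == "inception") {
      ipos <- ipos + 1L
      rows[[i]]$alloc <- rows[[i]]$alloc %||%
        inception_allocation(rows[[i]]$channels, ipos)
    }
  }
  structure(list(layers = rows, input_shape = input_shape,
                 n_classes = n_classes, n_levels = lvl - 1L),
            class = "cnn_arch")
}

#' The default 29-level inception CNN architecture
#'
#' The detection network for 120 x 344 x 1 spectrogram epochs: three
#' stand-alone convolutions (5x3, 5x3, 1x1; 64, 64, 192 channels; valid
#' padding), five max-pooling layers (1x3 s1x3, 3x3 s2, 2x2 s2, 3x3 s2,
#' 3x3 s2; ceil-mode), nine inception blocks (totals 256, 480, 512, 512,
#' 512, 528, 832, 832, 1024; same padding inside), a 7x7 average pool,
#' 40% dropout, and a 2-class fully connected + softmax head. Every
#' convolution is followed by batch normalization and ReLU.
#'
#' @return object of class `cnn_arch`.
#' @export
default_architecture <- function() {
  rows <- list(
    layer_row("input"),
    layer_row("conv",    kernel = c(5L, 3L), stride = c(1L, 1L),
              channels = 64L, pad = "valid"),
    layer_row("maxpool", kernel = c(1L, 3L), stride = c(1L, 3L), pad = "ceil"),
    layer_row("conv",    kernel = c(5L, 3L), stride = c(1L, 1L),
              channels = 64L, pad = "valid"),
    layer_row("maxpool", kernel = c(3L, 3L), stride = c(2L, 2L), pad = "ceil"),
    layer_row("conv",    kernel = c(1L, 1L), stride = c(1L, 1L),
              channels = 192L, pad = "valid"),
    layer_row("maxpool", kernel = c(2L, 2L), stride = c(2L, 2L), pad = "ceil"),
    layer_row("inception", channels = 256L),
    layer_row("inception", channels = 480L),
    layer_row("maxpool", kernel = c(3L, 3L), stride = c(2L, 2L), pad = "ceil"),
    layer_row("inception", channels = 512L),
    layer_row("inception", channels = 512L),
    layer_row("inception", channels = 512L),
    layer_row("inception", channels = 528L),
    layer_row("inception", channels = 832L),
    layer_row("maxpool", kernel = c(3L, 3L), stride = c(2L, 2L), pad = "ceil"),
    layer_row("inception", channels = 832L),
    layer_row("inception", channels = 1024L),
    layer_row("avgpool", kernel = c(7L, 7L), stride = c(1L, 1L), pad = "valid"),
    layer_row("dropout", rate = 0.4),
    layer_row("fc", channels = 2L),
    layer_row("softmax"))
  new_cnn_arch(rows, input_shape = c(120L, 344L, 1L), n_classes = 2)
}

#' A narrow desk-scale variant of the architecture
#'
#' Same operator vocabulary (valid stem convolutions + BN + ReLU, ceil-mode
#' max pooling, same-padded inception blocks, global average pool, dropout,
#' fc + softmax) but with few channels, two inception blocks, and a strided
#' first convolution, so that training on synthetic data runs in minutes on
#' one CPU. Used by the end-to-end tests and the command-line defaults for
#' simulated data; the full network is [default_architecture()].
#'
#' @param width base channel width (default 8).
#' @return object of class `cnn_arch`.
#' @export
reduced_architecture <- function(width = 8L) {
  w <- as.integer(width)
  rows <- list(
    layer_row("input"),
    layer_row("conv",    kernel = c(5L, 3L), stride = c(2L, 2L),
              channels = w, pad = "valid"),
    layer_row("maxpool", kernel = c(1L, 3L), stride = c(1L, 3L), pad = "ceil"),
    layer_row("conv",    kernel = c(5L, 3L), stride = c(1L, 1L),
              channels = w, pad = "valid"),
    layer_row("maxpool", kernel = c(3L, 3L), stride = c(2L, 2L), pad = "ceil"),
    layer_row("conv",    kernel = c(1L, 1L), stride = c(1L, 1L),
              channels = 2L * w, pad = "valid"),
    layer_row("maxpool", kernel = c(2L, 2L), stride = c(2L, 2L), pad = "ceil"),
    layer_row("inception", channels = 2L * w),
    layer_row("maxpool", kernel = c(3L, 3L), stride = c(2L, 2L), pad = "ceil"),
    layer_row("inception", channels = 4L * w),
    layer_row("avgpool", kernel = c(7L, 7L), stride = c(1L, 1L), pad = "valid"),
    layer_row("dropout", rate = 0.4),
    layer_row("fc", channels = 2L),
    layer_row("softmax"))
  new_cnn_arch(rows, input_shape = c(120L, 344L, 1L), n_classes = 2)
}

#' Highest level number of an architecture
#' @param arch a `cnn_arch`.
#' @return integer (29 for the default architecture).
#' @export
n_levels <- function(arch) arch$n_levels

# output spatial size for one dimension given pad mode
pool_out <- function(n, k, s, pad) {
  switch(pad,
    valid = floor((n - k) / s) + 1,
    ceil  = ceiling((n - k) / s) + 1,
    same  = ceiling(n / s),
    stopf("unknown pad mode '%s'", pad))
}

#' Trace input/output shapes through an architecture
#'
#' Applies the shape rules of every layer: stand-alone convolutions are
#' unpadded (valid), inception convolutions preserve spatial size (same),
#' max pooling is ceil-mode (the right/bottom edge is padded when the last
#' window overhangs), average pooling must tile exactly, the fully connected
#' layer flattens. Errors when a layer cannot consume its input shape.
#'
#' @param arch a `cnn_arch`.
#' @return data.frame with columns `level`, `kind`, `in_h`, `in_w`, `in_c`,
#'   `out_h`, `out_w`, `out_c`, `params` (layer hyperparameters, printable).
#' @export
shape_trace <- function(arch) {
  shp <- arch$input_shape
  out <- list()
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    inshp <- shp
    note <- ""
    if (l$kind == "input") {
      note <- ""
    } else if (l$kind == "conv") {
      if (identical(l$pad, "valid") &&
          (shp[1] < l$kernel[1] || shp[2] < l$kernel[2])) {
        stopf("level %s: conv kernel %dx%d larger than input %dx%d",
              l$level, l$kernel[1], l$kernel[2], shp[1], shp[2])
      }
      h <- if (identical(l$pad, "same")) ceiling(shp[1] / l$stride[1]) else
        floor((shp[1] - l$kernel[1]) / l$stride[1]) + 1
      w <- if (identical(l$pad, "same")) ceiling(shp[2] / l$stride[2]) else
        floor((shp[2] - l$kernel[2]) / l$stride[2]) + 1
      shp <- c(h, w, l$channels)
      note <- sprintf("kernel %dx%d stride %dx%d ch %d", l$kernel[1],
                      l$kernel[2], l$stride[1], l$stride[2], l$channels)
    } else if (l$kind %in% c("maxpool", "avgpool")) {
      if (l$kind == "avgpool" &&
          ((shp[1] - l$kernel[1]) %% l$stride[1] != 0 ||
           (shp[2] - l$kernel[2]) %% l$stride[2] != 0)) {
        stopf("level %s: average pool %dx%d does not tile input %dx%d",
              l$level, l$kernel[1], l$kernel[2], shp[1], shp[2])
      }
      shp <- c(pool_out(shp[1], l$kernel[1], l$stride[1], l$pad),
               pool_out(shp[2], l$kernel[2], l$stride[2], l$pad),
               shp[3])
      note <- sprintf("pool %dx%d stride %dx%d", l$kernel[1], l$kernel[2],
                      l$stride[1], l$stride[2])
    } else if (l$kind == "inception") {
      shp <- c(shp[1], shp[2], l$channels)
      a <- l$alloc
      note <- sprintf("branches %d/(%d>%d)/(%d>%d)/(pool>%d)",
                      a$b1, a$b3r, a$b3, a$b5r, a$b5, a$bp)
    } else if (l$kind == "dropout") {
      note <- sprintf("rate %d%%", round(100 * l$rate))
    } else if (l$kind == "fc") {
      shp <- c(1, 1, l$channels)
      note <- sprintf("units %d", l$channels)
    } else if (l$kind == "softmax") {
      note <- ""
    } else {
      stopf("unknown layer kind '%s'", l$kind)
    }
    if (any(shp < 1)) {
      stopf("level %s (%s): output shape collapsed to %s",
            l$level, l$kind, paste(shp, collapse = "x"))
    }
    out[[i]] <- data.frame(level = l$level, kind = l$kind,
                           in_h = inshp[1], in_w = inshp[2], in_c = inshp[3],
                           out_h = shp[1], out_w = shp[2], out_c = shp[3],
                           params = note, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Count convolution operations in an architecture
#'
#' @param arch a `cnn_arch`.
#' @return named integer vector: `standalone` (stem convolution layers) and
#'   `inception_internal` (six convolutions per inception block).
#' @export
count_convolutions <- function(arch) {
  kinds <- vapply(arch$layers, `[[`, character(1), "kind")
  c(standalone = sum(kinds == "conv"),
    inception_internal = 6L * sum(kinds == "inception"))
}

#' Print a per-level shape table
#'
#' One printed row per level number; inception blocks span two consecutive
#' levels (the depth-2 accounting of the level column), so the default
#' architecture prints 29 numbered rows plus unnumbered input and softmax
#' rows.
#'
#' @param arch a `cnn_arch`.
#' @param file connection or "" for stdout.
#' @return the expanded trace data.frame, invisibly.
#' @export
print_shape_trace <- function(arch, file = "") {
  tr <- shape_trace(arch)
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    rows[[length(rows) + 1]] <- tr[i, ]
    if (tr$kind[i] == "inception") {
      r <- tr[i, ]
      r$level <- r$level + 1L
      r$kind <- "inception (cont.)"
      rows[[length(rows) + 1]] <- r
    }
  }
  ex <- do.call(rbind, rows)
  lines <- sprintf("%3s  %-18s %-14s -> %-14s %s",
                   ifelse(is.na(ex$level), "-", ex$level), ex$kind,
                   sprintf("%dx%dx%d", ex$in_h, ex$in_w, ex$in_c),
                   sprintf("%dx%dx%d", ex$out_h, ex$out_w, ex$out_c),
                   ex$params)
  if (identical(file, "")) writeLines(lines) else writeLines(lines, file)
  invisible(ex)
}
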