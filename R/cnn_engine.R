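# ---------------------------------------------------------------------------
# A small CNN engine on base R + BLAS.
#
# A batch tensor is a list(x, n, h, w, c) where `x` is an (n*h*w) x c matrix
# of feature values; rows are ordered sample-major, then image-column-major
# (h fastest): row = (n-1)*h*w + (w_i-1)*h + h_i. Convolutions are im2col
# gathers followed by one matrix multiplication, so all heavy arithmetic is
# delegated to BLAS. The network is a tree of "units" (conv, batch norm,
# ReLU, max/avg pool, dropout, fc, softmax, seq, parallel-concat); forward
# returns a cache that backward consumes, gradients mirror the unit tree.

new_tensor <- function(x, n, h, w, c) list(x = x, n = n, h = h, w = w, c = c)

# H x W x N array (single input channel) -> batch tensor
array_tensor <- function(arr) {
  d <- dim(arr)
  if (length(d) == 2) d <- c(d, 1L)
  new_tensor(matrix(as.numeric(arr), ncol = 1L), n = d[3], h = d[1],
             w = d[2], c = 1L)
}

# spatial gather plan: output size + (Ho*Wo) x (kh*kw) index matrix into the
# H x W plane (0 marks padding)
conv_plan <- function(H, W, kh, kw, sh, sw, pad) {
  po <- function(n, k, s) pool_out(n, k, s, pad)
  Ho <- po(H, kh, sh); Wo <- po(W, kw, sw)
  if (Ho < 1 || Wo < 1) stopf("kernel %dx%d larger than input %dx%d",
                              kh, kw, H, W)
  pt <- 0L; pl <- 0L
  if (pad == "same") {
    pt <- max(0L, ((Ho - 1L) * sh + kh - H) %/% 2L)
    pl <- max(0L, ((Wo - 1L) * sw + kw - W) %/% 2L)
  }
  i <- rep(seq_len(Ho), times = Wo)
  j <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, Ho * Wo, kh * kw)
  for (dj in 0:(kw - 1L)) {
    wi <- (j - 1L) * sw + dj + 1L - pl
    for (di in 0:(kh - 1L)) {
      hi <- (i - 1L) * sh + di + 1L - pt
      ok <- hi >= 1L & hi <= H & wi >= 1L & wi <= W
      col <- dj * kh + di + 1L
      idx[ok, col] <- (wi[ok] - 1L) * H + hi[ok]
    }
  }
  list(Ho = Ho, Wo = Wo, idx = idx)
}

# batch-expanded 1-based gather index into an augmented matrix whose first
# row is the padding sentinel
batch_index <- function(plan, N, HW) {
  M <- nrow(plan$idx)
  fi <- matrix(0L, N * M, ncol(plan$idx))
  shift <- rep.int((seq_len(N) - 1L) * HW, rep.int(M, N))
  for (k in seq_len(ncol(fi))) {
    base <- rep.int(plan$idx[, k], N)
    v <- base + shift
    v[base == 0L] <- 0L
    fi[, k] <- v + 1L
  }
  fi
}

unit_plan <- function(unit, tens) {
  key <- paste(tens$h, tens$w, tens$n, sep = "x")
  env <- unit$plans
  if (is.null(env[[key]])) {
    plan <- conv_plan(tens$h, tens$w, unit$kernel[1], unit$kernel[2],
                      unit$stride[1], unit$stride[2], unit$pad)
    plan$fi <- batch_index(plan, tens$n, tens$h * tens$w)
    env[[key]] <- plan
  }
  env[[key]]
}

# ---- unit constructors ----------------------------------------------------

u_conv <- function(cin, cout, kernel, stride = c(1L, 1L), pad = "valid") {
  fan_in <- prod(kernel) * cin
  W <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
              fan_in, cout)
  list(type = "conv", cin = cin, cout = cout, kernel = kernel,
       stride = stride, pad = pad, W = W, plans = new.env(parent = emptyenv()))
}

u_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = rep(0, c),
       rmean = rep(0, c), rvar = rep(1, c), momentum = momentum, eps = eps)
}

u_relu <- function() list(type = "relu")

u_pool <- function(op, kernel, stride, pad) {
  list(type = op, kernel = kernel, stride = stride, pad = pad,
       plans = new.env(parent = emptyenv()))
}

u_dropout <- function(rate) list(type = "dropout", rate = rate)

u_fc <- function(cin, cout) {
  list(type = "fc", cin = cin, cout = cout,
       W = matrix(stats::rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout),
       b = rep(0, cout))
}

u_softmax <- function() list(type = "softmax")

u_seq <- function(units) list(type = "seq", units = units)

u_parallel <- function(branches) list(type = "parallel", branches = branches)

conv_bn_relu <- function(cin, cout, kernel, stride = c(1L, 1L),
                         pad = "valid") {
  u_seq(list(u_conv(cin, cout, kernel, stride, pad), u_bn(cout), u_relu()))
}

u_inception <- function(cin, alloc) {
  a <- alloc
  u_parallel(list(
    conv_bn_relu(cin, a$b1, c(1L, 1L), pad = "same"),
    u_seq(list(conv_bn_relu(cin, a$b3r, c(1L, 1L), pad = "same"),
               conv_bn_relu(a$b3r, a$b3, c(3L, 3L), pad = "same"))),
    u_seq(list(conv_bn_relu(cin, a$b5r, c(1L, 1L), pad = "same"),
               conv_bn_relu(a$b5r, a$b5, c(5L, 5L), pad = "same"))),
    u_seq(list(u_pool("maxpool", c(3L, 3L), c(1L, 1L), "same"),
               conv_bn_relu(cin, a$bp, c(1L, 1L), pad = "same")))))
}

# ---- forward --------------------------------------------------------------

unit_forward <- function(unit, tens, training = FALSE) {
  switch(unit$type,
    conv = {
      pl <- unit_plan(unit, tens)
      K <- ncol(pl$idx)
      Xa <- rbind(matrix(0, 1L, tens$c), tens$x)
      Xcol <- matrix(0, nrow(pl$fi), K * tens$c)
      for (k in seq_len(K)) {
        Xcol[, ((k - 1L) * tens$c + 1L):(k * tens$c)] <-
          Xa[pl$fi[, k], , drop = FALSE]
      }
      out <- new_tensor(Xcol %*% unit$W, tens$n, pl$Ho, pl$Wo, unit$cout)
      list(out = out,
           cache = list(Xcol = Xcol, pl = pl, in_dim = tens[c("n","h","w","c")]))
    },
    bn = {
      x <- tens$x
      if (training) {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc * xc)
        invstd <- 1 / sqrt(v + unit$eps)
        xhat <- sweep(xc, 2, invstd, "*")
      } else {
        invstd <- 1 / sqrt(unit$rvar + unit$eps)
        xhat <- sweep(sweep(x, 2, unit$rmean), 2, invstd, "*")
      }
      y <- sweep(sweep(xhat, 2, unit$gamma, "*"), 2, unit$beta, "+")
      out <- tens; out$x <- y
      cache <- list(xhat = xhat, invstd = invstd)
      if (training) cache$batch_stats <- list(mu = mu, v = v)
      list(out = out, cache = cache)
    },
    relu = {
      mask <- tens$x > 0
      out <- tens; out$x <- tens$x * mask
      list(out = out, cache = list(mask = mask))
    },
    maxpool = {
      pl <- unit_plan(unit, tens)
      Xa <- rbind(matrix(-Inf, 1L, tens$c), tens$x)
      m <- Xa[pl$fi[, 1L], , drop = FALSE]
      am <- matrix(pl$fi[, 1L], nrow(m), tens$c)
      for (k in seq_len(ncol(pl$fi))[-1L]) {
        cur <- Xa[pl$fi[, k], , drop = FALSE]
        sel <- cur > m
        if (any(sel)) {
          m[sel] <- cur[sel]
          am[sel] <- matrix(pl$fi[, k], nrow(m), tens$c)[sel]
        }
      }
      out <- new_tensor(m, tens$n, pl$Ho, pl$Wo, tens$c)
      list(out = out, cache = list(am = am, in_dim = tens[c("n","h","w","c")]))
    },
    avgpool = {
      pl <- unit_plan(unit, tens)
      if (any(pl$idx == 0L)) {
        stopf("average pooling window does not tile the input")
      }
      K <- ncol(pl$fi)
      Xa <- rbind(matrix(0, 1L, tens$c), tens$x)
      acc <- Xa[pl$fi[, 1L], , drop = FALSE]
      for (k in seq_len(K)[-1L]) acc <- acc + Xa[pl$fi[, k], , drop = FALSE]
      out <- new_tensor(acc / K, tens$n, pl$Ho, pl$Wo, tens$c)
      list(out = out, cache = list(pl = pl, in_dim = tens[c("n","h","w","c")]))
    },
    dropout = {
      if (training && unit$rate > 0) {
        keep <- 1 - unit$rate
        mask <- matrix((stats::runif(length(tens$x)) < keep) / keep,
                       nrow(tens$x), ncol(tens$x))
        out <- tens; out$x <- tens$x * mask
        list(out = out, cache = list(mask = mask))
      } else {
        list(out = tens, cache = list(mask = NULL))
      }
    },
    fc = {
      xf <- flatten_tensor(tens)
      y <- xf %*% unit$W
      y <- y + rep(unit$b, each = nrow(y))
      out <- new_tensor(y, tens$n, 1L, 1L, unit$cout)
      list(out = out, cache = list(xf = xf, in_dim = tens[c("n","h","w","c")]))
    },
    softmax = {
      z <- tens$x - apply(tens$x, 1, max)
      e <- exp(z)
      p <- e / rowSums(e)
      out <- tens; out$x <- p
      list(out = out, cache = list(p = p))
    },
    seq = {
      caches <- vector("list", length(unit$units))
      for (i in seq_along(unit$units)) {
        r <- unit_forward(unit$units[[i]], tens, training)
        tens <- r$out
        caches[[i]] <- r$cache
      }
      list(out = tens, cache = caches)
    },
    parallel = {
      outs <- vector("list", length(unit$branches))
      caches <- vector("list", length(unit$branches))
      for (i in seq_along(unit$branches)) {
        r <- unit_forward(unit$branches[[i]], tens, training)
        outs[[i]] <- r$out
        caches[[i]] <- r$cache
      }
      x <- do.call(cbind, lapply(outs, `[[`, "x"))
      o1 <- outs[[1L]]
      list(out = new_tensor(x, o1$n, o1$h, o1$w, ncol(x)),
           cache = list(caches = caches,
                        widths = vapply(outs, function(o) as.integer(o$c),
                                        integer(1))))
    },
    stopf("unknown unit type '%s'", unit$type))
}

flatten_tensor <- function(tens) {
  if (tens$h == 1L && tens$w == 1L) return(tens$x)
  hw <- tens$h * tens$w
  arr <- array(tens$x, c(hw, tens$n, tens$c))
  matrix(aperm(arr, c(2L, 1L, 3L)), tens$n, hw * tens$c)
}

unflatten_grad <- function(dxf, in_dim) {
  hw <- in_dim$h * in_dim$w
  if (hw == 1L) return(dxf)
  arr <- array(dxf, c(in_dim$n, hw, in_dim$c))
  matrix(aperm(arr, c(2L, 1L, 3L)), in_dim$n * hw, in_dim$c)
}

# ---- backward -------------------------------------------------------------
# returns list(dx = gradient wrt input matrix, grads = tree of parameter
# gradients). `need_dx = FALSE` skips input-gradient work at the root.

unit_backward <- function(unit, dout, cache, need_dx = TRUE) {
  switch(unit$type,
    conv = {
      dW <- crossprod(cache$Xcol, dout)
      dx <- NULL
      if (need_dx) {
        dXcol <- tcrossprod(dout, unit$W)
        idim <- cache$in_dim
        dXa <- matrix(0, idim$n * idim$h * idim$w + 1L, idim$c)
        cc <- idim$c
        for (k in seq_len(ncol(cache$pl$fi))) {
          rows <- cache$pl$fi[, k]
          dXa[rows, ] <- dXa[rows, , drop = FALSE] +
            dXcol[, ((k - 1L) * cc + 1L):(k * cc), drop = FALSE]
        }
        dx <- dXa[-1L, , drop = FALSE]
      }
      list(dx = dx, grads = list(W = dW))
    },
    bn = {
      M <- nrow(dout)
      dgamma <- colSums(dout * cache$xhat)
      dbeta <- colSums(dout)
      dx <- sweep(dout, 2, dbeta / M)
      dx <- dx - sweep(cache$xhat, 2, dgamma / M, "*")
      dx <- sweep(dx, 2, unit$gamma * cache$invstd, "*")
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta),
           batch_stats = cache$batch_stats)
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    maxpool = {
      idim <- cache$in_dim
      NHW <- idim$n * idim$h * idim$w
      C <- idim$c
      lin <- as.vector(cache$am - 1L) +
        rep.int((seq_len(C) - 1L) * NHW, rep.int(nrow(cache$am), C))
      acc <- rowsum(as.vector(dout), lin)
      dxv <- numeric(NHW * C)
      dxv[as.integer(rownames(acc))] <- acc
      list(dx = matrix(dxv, NHW, C), grads = NULL)
    },
    avgpool = {
      idim <- cache$in_dim
      K <- ncol(cache$pl$fi)
      dXa <- matrix(0, idim$n * idim$h * idim$w + 1L, idim$c)
      dk <- dout / K
      for (k in seq_len(K)) {
        rows <- cache$pl$fi[, k]
        dXa[rows, ] <- dXa[rows, , drop = FALSE] + dk
      }
      list(dx = dXa[-1L, , drop = FALSE], grads = NULL)
    },
    dropout = {
      dx <- if (is.null(cache$mask)) dout else dout * cache$mask
      list(dx = dx, grads = NULL)
    },
    fc = {
      dW <- crossprod(cache$xf, dout)
      db <- colSums(dout)
      dx <- unflatten_grad(tcrossprod(dout, unit$W), cache$in_dim)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    softmax = {
      # not used in training (loss backward starts at the logits); identity
      list(dx = dout, grads = NULL)
    },
    seq = {
      grads <- vector("list", length(unit$units))
      stats <- vector("list", length(unit$units))
      for (i in rev(seq_along(unit$units))) {
        r <- unit_backward(unit$units[[i]], dout, cache[[i]],
                           need_dx = need_dx || i > 1L)
        dout <- r$dx
        grads[i] <- list(r$grads)       # keep NULL slots (no-param units)
        stats[i] <- list(r$batch_stats)
      }
      list(dx = dout, grads = grads, batch_stats = stats)
    },
    parallel = {
      widths <- cache$widths
      ends <- cumsum(widths)
      starts <- ends - widths + 1L
      dx <- NULL
      grads <- vector("list", length(unit$branches))
      stats <- vector("list", length(unit$branches))
      for (i in seq_along(unit$branches)) {
        r <- unit_backward(unit$branches[[i]],
                           dout[, starts[i]:ends[i], drop = FALSE],
                           cache$caches[[i]], need_dx = TRUE)
        dx <- if (is.null(dx)) r$dx else dx + r$dx
        grads[i] <- list(r$grads)
        stats[i] <- list(r$batch_stats)
      }
      list(dx = dx, grads = grads, batch_stats = stats)
    },
    stopf("unknown unit type '%s'", unit$type))
}

# ---- parameter walking (SGD with momentum, running-stat updates) ----------

unit_param_names <- function(unit) {
  switch(unit$type,
         conv = "W", fc = c("W", "b"), bn = c("gamma", "beta"),
         character())
}

# f(unit, grads_node, vel_node) -> list(unit, vel); walks seq/parallel trees
walk_update <- function(unit, grads, vel, lr, momentum) {
  if (unit$type == "seq" || unit$type == "parallel") {
    kids <- if (unit$type == "seq") "units" else "branches"
    if (is.null(vel)) vel <- vector("list", length(unit[[kids]]))
    for (i in seq_along(unit[[kids]])) {
      r <- walk_update(unit[[kids]][[i]], grads[[i]], vel[[i]], lr, momentum)
      unit[[kids]][[i]] <- r$unit
      vel[i] <- list(r$vel)             # keep NULL slots aligned with units
    }
    return(list(unit = unit, vel = vel))
  }
  pn <- unit_param_names(unit)
  if (length(pn)) {
    if (is.null(vel)) vel <- stats::setNames(vector("list", length(pn)), pn)
    for (p in pn) {
      g <- grads[[p]]
      v <- vel[[p]]
      v <- if (is.null(v)) -lr * g else momentum * v - lr * g
      unit[[p]] <- unit[[p]] + v
      vel[[p]] <- v
    }
  }
  list(unit = unit, vel = vel)
}

walk_bn_update <- function(unit, stats) {
  if (unit$type == "seq" || unit$type == "parallel") {
    kids <- if (unit$type == "seq") "units" else "branches"
    for (i in seq_along(unit[[kids]])) {
      unit[[kids]][[i]] <- walk_bn_update(unit[[kids]][[i]], stats[[i]])
    }
    return(unit)
  }
  if (unit$type == "bn" && !is.null(stats)) {
    m <- unit$momentum
    unit$rmean <- m * unit$rmean + (1 - m) * stats$mu
    unit$rvar <- m * unit$rvar + (1 - m) * stats$v
  }
  unit
}

# flat list of per-batch-norm batch statistics in traversal order
collect_bn_stats <- function(unit, cache) {
  if (unit$type == "seq") {
    return(do.call(c, lapply(seq_along(unit$units), function(i) {
      collect_bn_stats(unit$units[[i]], cache[[i]])
    })))
  }
  if (unit$type == "parallel") {
    return(do.call(c, lapply(seq_along(unit$branches), function(i) {
      collect_bn_stats(unit$branches[[i]], cache$caches[[i]])
    })))
  }
  if (unit$type == "bn") return(list(cache$batch_stats))
  list()
}

assign_bn_stats <- function(unit, stats, pos = new.env()) {
  if (is.null(pos$i)) pos$i <- 0L
  if (unit$type == "seq" || unit$type == "parallel") {
    kids <- if (unit$type == "seq") "units" else "branches"
    for (i in seq_along(unit[[kids]])) {
      unit[[kids]][[i]] <- assign_bn_stats(unit[[kids]][[i]], stats, pos)
    }
    return(unit)
  }
  if (unit$type == "bn") {
    pos$i <- pos$i + 1L
    unit$rmean <- stats[[pos$i]]$mu
    unit$rvar <- stats[[pos$i]]$v
  }
  unit
}

count_params <- function(unit) {
  if (unit$type == "seq") {
    return(sum(vapply(unit$units, count_params, numeric(1))))
  }
  if (unit$type == "parallel") {
    return(sum(vapply(unit$branches, count_params, numeric(1))))
  }
  sum(vapply(unit_param_names(unit), function(p) length(unit[[p]]),
             numeric(1)))
}
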