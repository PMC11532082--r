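# Minimal reverse-mode automatic differentiation on a dynamic tape.
#
# Every operation returns an `ag_node` (an environment holding the value,
# the accumulated gradient, and vector-Jacobian callbacks into its
# parents). backward() walks the tape in reverse creation order. Nodes with
# no differentiable ancestor are constant-folded so evaluation without
# gradients carries no tape overhead. Correctness of every vjp is covered
# by finite-difference tests.

.ag <- new.env(parent = emptyenv())
.ag$n <- 0L

ag_node <- function(value, parents = list()) {
  requires <- any(vapply(parents, function(p) p$node$requires, logical(1)))
  if (!requires) parents <- list()
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$requires <- requires
  .ag$n <- .ag$n + 1L
  e$nid <- .ag$n
  class(e) <- "ag_node"
  e
}

#' @keywords internal
ag_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$requires <- TRUE
  .ag$n <- .ag$n + 1L
  e$nid <- .ag$n
  class(e) <- "ag_node"
  e
}

ag_const <- function(value) {
  if (inherits(value, "ag_node")) return(value)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$requires <- FALSE
  .ag$n <- .ag$n + 1L
  e$nid <- .ag$n
  class(e) <- "ag_node"
  e
}

vof <- function(x) if (inherits(x, "ag_node")) x$value else x

# reverse pass: accumulate gradients into every differentiable ancestor
ag_backward <- function(root, seed_grad = NULL) {
  if (is.null(seed_grad)) seed_grad <- array(1, dim = dim(root$value) %||% 1)
  # collect reachable differentiable subgraph
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack) > 0) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$nid)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1]] <- nd
    for (p in nd$parents) {
      if (p$node$requires) stack[[length(stack) + 1]] <- p$node
    }
  }
  ord <- order(vapply(nodes, function(n) n$nid, numeric(1)),
               decreasing = TRUE)
  root$grad <- seed_grad
  for (i in ord) {
    nd <- nodes[[i]]
    if (is.null(nd$grad)) next
    for (p in nd$parents) {
      if (!p$node$requires) next
      g <- p$vjp(nd$grad)
      p$node$grad <- if (is.null(p$node$grad)) g else p$node$grad + g
    }
  }
  invisible(root)
}

# ---- elementwise and linear ops -------------------------------------------

ag_add <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  ag_node(a$value + b$value, list(
    list(node = a, vjp = function(g) g),
    list(node = b, vjp = function(g) g)
  ))
}

ag_mul <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(
    list(node = a, vjp = function(g) g * bv),
    list(node = b, vjp = function(g) g * av)
  ))
}

ag_scale <- function(a, k) {
  a <- ag_const(a)
  ag_node(a$value * k, list(list(node = a, vjp = function(g) g * k)))
}

ag_matmul <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(
    list(node = a, vjp = function(g) g %*% t(bv)),
    list(node = b, vjp = function(g) t(av) %*% g)
  ))
}

# x: N x C, bias: length C
ag_add_bias <- function(x, b) {
  x <- ag_const(x); b <- ag_const(b)
  val <- sweep(x$value, 2, b$value, "+")
  ag_node(val, list(
    list(node = x, vjp = function(g) g),
    list(node = b, vjp = function(g) colSums(g))
  ))
}

ag_relu <- function(x) {
  x <- ag_const(x)
  mask <- x$value > 0
  ag_node(x$value * mask, list(list(node = x, vjp = function(g) g * mask)))
}

ag_sigmoid <- function(x) {
  x <- ag_const(x)
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(list(node = x, vjp = function(g) g * s * (1 - s))))
}

ag_concat_cols <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  ca <- ncol(a$value)
  ag_node(cbind(a$value, b$value), list(
    list(node = a, vjp = function(g) g[, seq_len(ca), drop = FALSE]),
    list(node = b, vjp = function(g) g[, -seq_len(ca), drop = FALSE])
  ))
}

ag_cols <- function(x, idx) {
  x <- ag_const(x)
  nc <- ncol(x$value)
  ag_node(x$value[, idx, drop = FALSE], list(list(
    node = x,
    vjp = function(g) {
      out <- matrix(0, nrow(g), nc)
      out[, idx] <- g
      out
    }
  )))
}

ag_dropout <- function(x, p, training) {
  x <- ag_const(x)
  if (!training || p <= 0) return(x)
  mask <- array((runif(length(x$value)) >= p) / (1 - p),
                dim = dim(x$value) %||% length(x$value))
  ag_node(x$value * mask,
          list(list(node = x, vjp = function(g) g * mask)))
}

# ---- batch normalization ---------------------------------------------------

# x: N x C matrix (or C,H,W,N array with spatial=TRUE); gamma/beta length C.
# `rs` is an environment carrying running mean/var across calls.
ag_batchnorm <- function(x, gamma, beta, rs, training,
                         momentum = 0.1, eps = 1e-5, spatial = FALSE) {
  x <- ag_const(x); gamma <- ag_const(gamma); beta <- ag_const(beta)
  xv <- x$value
  # work with channels in rows (C x M): length-C statistics then recycle
  # natively down the columns, with no sweeps or transposed copies on the
  # (large) spatial path
  if (spatial) {
    dm <- dim(xv)
    C <- dm[1]
    cm <- matrix(xv, C, prod(dm) / C)
  } else {
    C <- ncol(xv)
    cm <- t(xv)
  }
  if (training) {
    mu <- rowMeans(cm)
    va <- pmax(rowMeans(cm^2) - mu^2, 0)
    if (is.null(rs$mean)) {
      rs$mean <- mu; rs$var <- va
    } else {
      rs$mean <- (1 - momentum) * rs$mean + momentum * mu
      rs$var <- (1 - momentum) * rs$var + momentum * va
    }
  } else {
    mu <- rs$mean %||% rep(0, C)
    va <- rs$var %||% rep(1, C)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- (cm - mu) * inv
  gv <- vof(gamma)
  ym <- xhat * gv + vof(beta)
  yv <- if (spatial) array(ym, dim = dim(xv)) else t(ym)

  to_cm <- function(g) if (spatial) matrix(g, C, length(g) / C) else t(g)
  from_cm <- function(gm) if (spatial) array(gm, dim = dim(xv)) else t(gm)

  ag_node(yv, list(
    list(node = x, vjp = function(g) {
      gm <- to_cm(g)
      if (training) {
        gx <- gm * gv
        from_cm((gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)) * inv)
      } else {
        from_cm(gm * (gv * inv))
      }
    }),
    list(node = gamma, vjp = function(g) rowSums(to_cm(g) * xhat)),
    list(node = beta, vjp = function(g) rowSums(to_cm(g)))
  ))
}

# ---- convolution and pooling ----------------------------------------------

conv_out_size <- function(H, k, stride, pad) (H + 2 * pad - k) %/% stride + 1

im2col <- function(xp, k, stride, oH, oW) {
  dm <- dim(xp)
  C <- dm[1]; N <- dm[4]
  cols <- matrix(0, C * k * k, oH * oW * N)
  ri <- seq_len(C)
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      rows <- ((kj - 1) * k + (ki - 1)) * C + ri
      sub <- xp[, ki + stride * (0:(oH - 1)), kj + stride * (0:(oW - 1)), ,
                drop = FALSE]
      cols[rows, ] <- matrix(sub, C, oH * oW * N)
    }
  }
  cols
}

col2im <- function(dcols, dm, k, stride, pad, oH, oW) {
  C <- dm[1]; H <- dm[2]; W <- dm[3]; N <- dm[4]
  gp <- array(0, c(C, H + 2 * pad, W + 2 * pad, N))
  ri <- seq_len(C)
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      rows <- ((kj - 1) * k + (ki - 1)) * C + ri
      piece <- array(dcols[rows, ], c(C, oH, oW, N))
      ii <- ki + stride * (0:(oH - 1))
      jj <- kj + stride * (0:(oW - 1))
      gp[, ii, jj, ] <- gp[, ii, jj, ] + piece
    }
  }
  if (pad > 0) gp <- gp[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
  gp
}

# x: (Cin,H,W,N); w: (Cout,Cin,k,k); b: length Cout
ag_conv2d <- function(x, w, b, stride = 1, pad = 0) {
  x <- ag_const(x); w <- ag_const(w); b <- ag_const(b)
  xv <- x$value
  dm <- dim(xv)
  C <- dm[1]; H <- dm[2]; W <- dm[3]; N <- dm[4]
  wd <- dim(w$value)
  Cout <- wd[1]; k <- wd[3]
  stopifnot(wd[2] == C)
  oH <- conv_out_size(H, k, stride, pad)
  oW <- conv_out_size(W, k, stride, pad)
  if (pad > 0) {
    xp <- array(0, c(C, H + 2 * pad, W + 2 * pad, N))
    xp[, pad + seq_len(H), pad + seq_len(W), ] <- xv
  } else {
    xp <- xv
  }
  cols <- im2col(xp, k, stride, oH, oW)
  # weight as (Cout, Cin*k*k): column-major layout of (Cout,Cin,k,k) after
  # flattening dims 2:4 in (Cin, ki, kj) order matches im2col's row order
  wm <- matrix(w$value, Cout, C * k * k)
  om <- wm %*% cols + b$value
  out <- array(om, c(Cout, oH, oW, N))
  ag_node(out, list(
    list(node = x, vjp = function(g) {
      gm <- matrix(g, Cout, oH * oW * N)
      dcols <- crossprod(wm, gm)
      col2im(dcols, dm, k, stride, pad, oH, oW)
    }),
    list(node = w, vjp = function(g) {
      gm <- matrix(g, Cout, oH * oW * N)
      array(gm %*% t(cols), dim = wd)
    }),
    list(node = b, vjp = function(g) {
      rowSums(matrix(g, Cout, oH * oW * N))
    })
  ))
}

ag_maxpool <- function(x, k = 2, stride = 2, pad = 0) {
  x <- ag_const(x)
  xv <- x$value
  dm <- dim(xv)
  C <- dm[1]; H <- dm[2]; W <- dm[3]; N <- dm[4]
  oH <- conv_out_size(H, k, stride, pad)
  oW <- conv_out_size(W, k, stride, pad)
  xp <- array(-Inf, c(C, H + 2 * pad, W + 2 * pad, N))
  xp[, pad + seq_len(H), pad + seq_len(W), ] <- xv
  best <- array(-Inf, c(C, oH, oW, N))
  arg <- array(0L, c(C, oH, oW, N))
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      o <- (kj - 1) * k + ki
      sub <- xp[, ki + stride * (0:(oH - 1)), kj + stride * (0:(oW - 1)), ,
                drop = FALSE]
      upd <- sub > best
      best[upd] <- sub[upd]
      arg[upd] <- o
    }
  }
  ag_node(best, list(list(node = x, vjp = function(g) {
    gp <- array(0, c(C, H + 2 * pad, W + 2 * pad, N))
    for (kj in seq_len(k)) {
      for (ki in seq_len(k)) {
        o <- (kj - 1) * k + ki
        ii <- ki + stride * (0:(oH - 1))
        jj <- kj + stride * (0:(oW - 1))
        gp[, ii, jj, ] <- gp[, ii, jj, ] + g * (arg == o)
      }
    }
    if (pad > 0) {
      gp <- gp[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
    }
    gp
  })))
}

# global average pool: (C,H,W,N) -> N x C
ag_global_avgpool <- function(x) {
  x <- ag_const(x)
  xv <- x$value
  dm <- dim(xv)
  C <- dm[1]; HW <- dm[2] * dm[3]; N <- dm[4]
  y <- array(xv, c(C, HW, N))
  out <- matrix(0, N, C)
  for (n in seq_len(N)) out[n, ] <- rowMeans(y[, , n, drop = FALSE])
  ag_node(out, list(list(node = x, vjp = function(g) {
    aperm(array(t(g) / HW, c(C, N, dm[2], dm[3])), c(1, 3, 4, 2))
  })))
}

# broadcast an N x C vector over space: -> (C,H,W,N)
ag_broadcast_spatial <- function(v, H, W) {
  v <- ag_const(v)
  vv <- v$value
  N <- nrow(vv); C <- ncol(vv)
  out <- aperm(array(t(vv), c(C, N, H, W)), c(1, 3, 4, 2))
  ag_node(out, list(list(node = v, vjp = function(g) {
    y <- array(g, c(C, H * W, N))
    out_g <- matrix(0, N, C)
    for (n in seq_len(N)) out_g[n, ] <- rowSums(y[, , n, drop = FALSE])
    out_g
  })))
}

# channel-wise modulation of a map by an N x C vector
ag_mul_channel <- function(map, v) {
  map <- ag_const(map); v <- ag_const(v)
  mv <- map$value; vv <- v$value
  dm <- dim(mv)
  C <- dm[1]; H <- dm[2]; W <- dm[3]; N <- dm[4]
  bc <- aperm(array(t(vv), c(C, N, H, W)), c(1, 3, 4, 2))
  ag_node(mv * bc, list(
    list(node = map, vjp = function(g) g * bc),
    list(node = v, vjp = function(g) {
      y <- array(g * mv, c(C, H * W, N))
      out_g <- matrix(0, N, C)
      for (n in seq_len(N)) out_g[n, ] <- rowSums(y[, , n, drop = FALSE])
      out_g
    })
  ))
}

# ---- attention and loss ----------------------------------------------------

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# scaled dot-product cross attention on tokenized vectors.
# q, kv: N x C; each row is reshaped to T tokens x d (d = C/T, contiguous
# chunks). Returns flattened attended output, N x C.
ag_cross_attention <- function(q, kv, n_tokens) {
  q <- ag_const(q); kv <- ag_const(kv)
  qv <- q$value; kvv <- kv$value
  N <- nrow(qv); C <- ncol(qv)
  if (C %% n_tokens != 0) {
    abort(sprintf("feature length %d not divisible by %d tokens",
                  C, n_tokens), class = c("neurofuse_config_error", "neurofuse_error"))
  }
  d <- C %/% n_tokens
  to_tok <- function(v) matrix(v, n_tokens, d, byrow = TRUE)
  out <- matrix(0, N, C)
  As <- vector("list", N)
  for (n in seq_len(N)) {
    Q <- to_tok(qv[n, ]); K <- to_tok(kvv[n, ]); V <- K
    A <- softmax_rows(Q %*% t(K) / sqrt(d))
    As[[n]] <- A
    out[n, ] <- as.vector(t(A %*% V))
  }
  ag_node(out, list(
    list(node = q, vjp = function(g) {
      gq <- matrix(0, N, C)
      for (n in seq_len(N)) {
        dO <- to_tok(g[n, ])
        K <- to_tok(kvv[n, ])
        A <- As[[n]]
        dA <- dO %*% t(K)
        dS <- A * (dA - rowSums(dA * A))
        gq[n, ] <- as.vector(t(dS %*% K / sqrt(d)))
      }
      gq
    }),
    list(node = kv, vjp = function(g) {
      gk <- matrix(0, N, C)
      for (n in seq_len(N)) {
        dO <- to_tok(g[n, ])
        Q <- to_tok(qv[n, ]); K <- to_tok(kvv[n, ])
        A <- As[[n]]
        dV <- t(A) %*% dO
        dA <- dO %*% t(K)
        dS <- A * (dA - rowSums(dA * A))
        dK <- t(dS) %*% Q / sqrt(d)
        gk[n, ] <- as.vector(t(dV + dK))
      }
      gk
    })
  ))
}

# fused softmax + cross-entropy; labels: N x K one-hot (constant)
ag_softmax_ce <- function(logits, y) {
  logits <- ag_const(logits)
  p <- softmax_rows(logits$value)
  N <- nrow(p)
  loss <- -sum(y * log(pmax(p, 1e-12))) / N
  ag_node(loss, list(list(node = logits, vjp = function(g) {
    as.numeric(g) * (p - y) / N
  })))
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(p) p$value * 0)   # keeps vector/array shape
  e$v <- e$m
  e$t <- 0L
  e
}

adam_step <- function(opt, params, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * g
    opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * g^2
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(opt)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
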