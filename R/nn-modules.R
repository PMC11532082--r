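# Network building blocks: parameterized layers and the fusion modules
# (FCN block, channel-attention FEM, cross-attention FIM, MLFM).
#
# A "module builder" environment (mb) owns every parameter node so the
# optimizer can walk them; constructors register parameters under readable
# names. Module forwards take and return ag_node objects.

new_builder <- function() {
  mb <- new.env(parent = emptyenv())
  mb$params <- list()
  mb
}

reg_param <- function(mb, name, value) {
  p <- ag_param(value)
  mb$params[[name]] <- p
  p
}

init_dense_w <- function(fan_in, fan_out) {
  s <- sqrt(6 / fan_in)
  matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

init_conv_w <- function(cout, cin, k) {
  s <- sqrt(2 / (cin * k * k))
  array(rnorm(cout * cin * k * k, 0, s), c(cout, cin, k, k))
}

mod_dense <- function(mb, name, d_in, d_out) {
  W <- reg_param(mb, paste0(name, ".W"), init_dense_w(d_in, d_out))
  b <- reg_param(mb, paste0(name, ".b"), rep(0, d_out))
  list(W = W, b = b, d_in = d_in, d_out = d_out,
       forward = function(x, training = TRUE) {
         ag_add_bias(ag_matmul(x, W), b)
       })
}

mod_bn <- function(mb, name, C, spatial = FALSE) {
  gamma <- reg_param(mb, paste0(name, ".gamma"), rep(1, C))
  beta <- reg_param(mb, paste0(name, ".beta"), rep(0, C))
  rs <- new.env(parent = emptyenv())
  list(gamma = gamma, beta = beta, rs = rs,
       forward = function(x, training = TRUE) {
         ag_batchnorm(x, gamma, beta, rs, training, spatial = spatial)
       })
}

mod_conv <- function(mb, name, cin, cout, k, stride = 1, pad = 0) {
  W <- reg_param(mb, paste0(name, ".W"), init_conv_w(cout, cin, k))
  b <- reg_param(mb, paste0(name, ".b"), rep(0, cout))
  list(W = W, b = b,
       forward = function(x, training = TRUE) {
         ag_conv2d(x, W, b, stride = stride, pad = pad)
       })
}

# conv + spatial BN + optional relu, the workhorse of the CNN stages
mod_conv_bn <- function(mb, name, cin, cout, k, stride = 1, pad = 0,
                        relu = TRUE) {
  cv <- mod_conv(mb, paste0(name, ".conv"), cin, cout, k, stride, pad)
  bn <- mod_bn(mb, paste0(name, ".bn"), cout, spatial = TRUE)
  list(forward = function(x, training = TRUE) {
    h <- bn$forward(cv$forward(x, training), training)
    if (relu) ag_relu(h) else h
  })
}

# ---- FCN block -------------------------------------------------------------

# three FC layers with BN + ReLU after the first two; internal widths are
# floor(in/2) and floor(in/4) (never below 4), output width matches the
# paired CNN stage's channel count
mod_fcn_block <- function(mb, name, d_in, d_out) {
  if (d_in < 4) {
    abort(sprintf("FCN block input dimension %d < 4", d_in),
          class = c("neurofuse_config_error", "neurofuse_error"))
  }
  h1 <- max(4L, d_in %/% 2L)
  h2 <- max(4L, d_in %/% 4L)
  fc1 <- mod_dense(mb, paste0(name, ".fc1"), d_in, h1)
  bn1 <- mod_bn(mb, paste0(name, ".bn1"), h1)
  fc2 <- mod_dense(mb, paste0(name, ".fc2"), h1, h2)
  bn2 <- mod_bn(mb, paste0(name, ".bn2"), h2)
  fc3 <- mod_dense(mb, paste0(name, ".fc3"), h2, d_out)
  list(dims = c(h1, h2, d_out),
       forward = function(x, training = TRUE) {
         h <- ag_relu(bn1$forward(fc1$forward(x), training))
         h <- ag_relu(bn2$forward(fc2$forward(h), training))
         fc3$forward(h)
       })
}

# ---- Feature Enhancement Module (channel attention) ------------------------

# group channel index sets: first (C mod n) groups get one extra channel
fem_groups <- function(C, n_groups) {
  base <- C %/% n_groups
  extra <- C %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1, extra), rep(0, n_groups - extra))
  ends <- cumsum(sizes)
  purrr::map2(ends - sizes + 1, ends, seq)
}

mod_fem <- function(mb, name, C, n_groups) {
  h <- max(1L, C %/% 2L)
  fc1 <- mod_dense(mb, paste0(name, ".fc1"), C, h)
  bn1 <- mod_bn(mb, paste0(name, ".bn1"), h)
  fc2 <- mod_dense(mb, paste0(name, ".fc2"), h, C)
  bn_in <- mod_bn(mb, paste0(name, ".bn_in"), C)
  groups <- fem_groups(C, n_groups)
  gmods <- purrr::imap(groups, function(idx, i) {
    cg <- length(idx)
    list(
      fa = mod_dense(mb, sprintf("%s.g%d.fa", name, i), cg, cg),
      bn = mod_bn(mb, sprintf("%s.g%d.bn", name, i), cg),
      fb = mod_dense(mb, sprintf("%s.g%d.fb", name, i), cg, cg)
    )
  })
  reduce <- mod_dense(mb, paste0(name, ".reduce"), 2 * C, C)
  list(
    C = C, groups = groups,
    fc2 = fc2,                      # exposed for algebraic contract tests
    forward = function(x, training = TRUE, detail = FALSE) {
      wf <- ag_sigmoid(fc2$forward(
        ag_relu(bn1$forward(fc1$forward(x), training))))
      fe <- ag_mul(wf, bn_in$forward(x, training))
      parts <- purrr::imap(groups, function(idx, i) {
        g <- ag_cols(x, idx)
        gm <- gmods[[i]]
        gm$fb$forward(gm$bn$forward(gm$fa$forward(g), training))
      })
      fs1 <- purrr::reduce(parts, ag_concat_cols)
      out <- reduce$forward(ag_concat_cols(fe, fs1))
      if (detail) list(out = out, fe = fe, wf = wf, fs1 = fs1) else out
    }
  )
}

# spatial FEM: pool to a channel vector, enhance with the vector FEM,
# modulate the map channel-wise, restore C channels with a 1x1 convolution
mod_fem_spatial <- function(mb, name, C, n_groups) {
  fem <- mod_fem(mb, paste0(name, ".fem"), C, n_groups)
  conv <- mod_conv(mb, paste0(name, ".conv1x1"), C, C, 1)
  list(
    fem = fem, conv = conv,
    forward = function(map, training = TRUE) {
      v <- ag_global_avgpool(map)
      enh <- fem$forward(v, training)
      conv$forward(ag_mul_channel(map, enh), training)
    }
  )
}

# ---- Feature Interaction Module (cross attention) --------------------------

mod_fim <- function(mb, name, C, n_tokens) {
  bn_in <- mod_bn(mb, paste0(name, ".bn_in"), C)
  fc <- mod_dense(mb, paste0(name, ".fc"), C, C)
  bn_out <- mod_bn(mb, paste0(name, ".bn_out"), C)
  list(
    fc = fc,
    forward = function(own, other, training = TRUE) {
      qe <- ag_cross_attention(own, other, n_tokens)
      h <- bn_out$forward(
        fc$forward(ag_add(bn_in$forward(own, training), qe)), training)
      ag_add(h, own)
    }
  )
}

# ---- Multi-Level Fusion Module ---------------------------------------------

# FEM on each branch, FIM across branches, then concat + reduction back to
# the input shapes; disabled modules pass their input through (and own no
# parameters)
mod_mlfm <- function(mb, name, C, config) {
  use_fem <- config$use_fem
  use_fim <- config$use_fim
  fem_v <- if (use_fem) mod_fem(mb, paste0(name, ".fem_f"), C,
                                config$n_groups)
  fem_s <- if (use_fem) mod_fem_spatial(mb, paste0(name, ".fem_c"), C,
                                        config$n_groups)
  fim_f <- if (use_fim) mod_fim(mb, paste0(name, ".fim_f"), C,
                                config$fim_tokens)
  fim_c <- if (use_fim) mod_fim(mb, paste0(name, ".fim_c"), C,
                                config$fim_tokens)
  reduce_f <- mod_dense(mb, paste0(name, ".reduce_f"), 2 * C, C)
  reduce_c <- mod_conv(mb, paste0(name, ".reduce_c"), 2 * C, C, 1)
  hook <- new.env(parent = emptyenv())
  hook$calls <- 0L
  list(
    hook = hook,
    forward = function(f, cmap, training = TRUE) {
      hook$calls <- hook$calls + 1L
      f1 <- if (use_fem) fem_v$forward(f, training) else f
      c1 <- if (use_fem) fem_s$forward(cmap, training) else cmap
      cvec <- ag_global_avgpool(c1)
      if (use_fim) {
        f2 <- fim_f$forward(f1, cvec, training)
        c2 <- fim_c$forward(cvec, f1, training)
      } else {
        f2 <- f1
        c2 <- cvec
      }
      fl <- reduce_f$forward(ag_concat_cols(f1, f2))
      dm <- dim(c1$value)
      fc_map <- reduce_c$forward(
        ag_concat_channels(c1, ag_broadcast_spatial(c2, dm[2], dm[3])),
        training)
      list(f = fl, c = fc_map)
    }
  )
}

# channel concatenation of two (C,H,W,N) maps
ag_concat_channels <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[-1] == db[-1]))
  val <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  val[seq_len(da[1]), , , ] <- a$value
  val[da[1] + seq_len(db[1]), , , ] <- b$value
  ag_node(val, list(
    list(node = a, vjp = function(g) g[seq_len(da[1]), , , , drop = FALSE]),
    list(node = b, vjp = function(g) {
      g[da[1] + seq_len(db[1]), , , , drop = FALSE]
    })
  ))
}

#' Scaled dot-product cross-attention between two feature vectors
#'
#' Each row of `query` and `context` is reshaped into `n_tokens` tokens of
#' dimension `length / n_tokens`; the query tokens attend over the context
#' tokens (which serve as both key and value) with softmax(QK'/sqrt(d))V.
#'
#' @param query,context Numeric matrices, samples in rows, equal column
#'   counts divisible by `n_tokens`.
#' @param n_tokens Number of tokens per sample.
#' @return A list with `output` (same shape as `query`) and `attention`
#'   (list of per-sample `n_tokens x n_tokens` row-stochastic matrices).
#' @export
cross_attention <- function(query, context, n_tokens = 4) {
  query <- as.matrix(query); context <- as.matrix(context)
  stopifnot(ncol(query) == ncol(context))
  C <- ncol(query)
  if (C %% n_tokens != 0) {
    abort(sprintf("feature length %d not divisible by %d tokens",
                  C, n_tokens), class = c("neurofuse_config_error", "neurofuse_error"))
  }
  d <- C %/% n_tokens
  out <- matrix(0, nrow(query), C)
  att <- vector("list", nrow(query))
  for (n in seq_len(nrow(query))) {
    Q <- matrix(query[n, ], n_tokens, d, byrow = TRUE)
    K <- matrix(context[n, ], n_tokens, d, byrow = TRUE)
    A <- softmax_rows(Q %*% t(K) / sqrt(d))
    att[[n]] <- A
    out[n, ] <- as.vector(t(A %*% K))
  }
  list(output = out, attention = att)
}

#' Multi-class cross-entropy loss
#'
#' `L = -(1/N) sum_i sum_j y_ij log(p_ij)` over predicted class
#' probabilities, with probabilities clamped at 1e-12 so a zero probability
#' at the true class stays finite.
#'
#' @param p Matrix of predicted probabilities, samples in rows.
#' @param y One-hot label matrix of the same shape (or a factor/integer
#'   vector of class indices).
#' @return A single non-negative number.
#' @export
fusion_loss <- function(p, y) {
  p <- as.matrix(p)
  if (!is.matrix(y)) {
    yi <- as.integer(as.factor(y))
    y <- matrix(0, nrow(p), ncol(p))
    y[cbind(seq_len(nrow(p)), yi)] <- 1
  }
  stopifnot(all(dim(p) == dim(y)))
  -sum(y * log(pmax(p, 1e-12))) / nrow(p)
}
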