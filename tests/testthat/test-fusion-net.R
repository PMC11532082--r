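ns <- asNamespace("neurofuse")

test_that("FCN block widths follow the half/quarter rule", {
  mb <- ns$new_builder()
  blk <- ns$mod_fcn_block(mb, "b", 43, 256)
  expect_equal(blk$dims, c(21, 10, 256))
  x <- matrix(rnorm(6 * 43), 6, 43)
  out <- blk$forward(ns$ag_const(x), training = TRUE)
  expect_equal(dim(ns$vof(out)), c(6, 256))
  expect_error(ns$mod_fcn_block(mb, "bad", 3, 8),
               class = "neurofuse_config_error")
})

test_that("zero input with zero-initialized affine terms stays zero", {
  set.seed(1)
  mb <- ns$new_builder()
  blk <- ns$mod_fcn_block(mb, "b", 8, 12)
  # biases and BN shifts are zero-initialized by construction
  x <- matrix(0, 4, 8)
  out <- blk$forward(ns$ag_const(x), training = TRUE)
  expect_equal(max(abs(ns$vof(out))), 0)
})

test_that("FEM weights lie strictly in (0,1) and output keeps length", {
  set.seed(2)
  for (C in c(12, 16, 37)) {
    mb <- ns$new_builder()
    fem <- ns$mod_fem(mb, "fem", C, 3)
    x <- matrix(rnorm(5 * C), 5, C)
    det <- fem$forward(ns$ag_const(x), training = TRUE, detail = TRUE)
    wf <- ns$vof(det$wf)
    expect_true(all(wf > 0 & wf < 1))
    expect_equal(dim(ns$vof(det$out)), c(5, C))
  }
})

test_that("FEM grouping splits channels as evenly as possible", {
  expect_equal(lengths(ns$fem_groups(12, 3)), c(4, 4, 4))
  expect_equal(lengths(ns$fem_groups(16, 3)), c(6, 5, 5))
  expect_equal(unlist(ns$fem_groups(16, 3)), 1:16)
})

test_that("zeroed second FC makes the FEM gate exactly one half", {
  set.seed(3)
  C <- 12
  mb <- ns$new_builder()
  fem <- ns$mod_fem(mb, "fem", C, 3)
  mb$params[["fem.fc2.W"]]$value[] <- 0
  mb$params[["fem.fc2.b"]]$value[] <- 0
  x <- matrix(rnorm(6 * C), 6, C)
  det <- fem$forward(ns$ag_const(x), training = TRUE, detail = TRUE)
  expect_equal(unique(as.vector(ns$vof(det$wf))), 0.5)
  # F_e = 0.5 * BN(x) with the default unit/zero affine terms
  mu <- colMeans(x)
  va <- colMeans(x^2) - mu^2
  bn <- sweep(sweep(x, 2, mu), 2, sqrt(va + 1e-5), "/")
  expect_equal(ns$vof(det$fe), 0.5 * bn, tolerance = 1e-12)
})

test_that("zeroed FC collapses the FIM to its residual path", {
  set.seed(4)
  C <- 16
  mb <- ns$new_builder()
  fim <- ns$mod_fim(mb, "fim", C, 4)
  mb$params[["fim.fc.W"]]$value[] <- 0
  mb$params[["fim.fc.b"]]$value[] <- 0
  own <- matrix(rnorm(5 * C), 5, C)
  other <- matrix(rnorm(5 * C), 5, C)
  out <- fim$forward(ns$ag_const(own), ns$ag_const(other),
                     training = TRUE)
  expect_equal(ns$vof(out), own, tolerance = 1e-12)
})

test_that("generic FIM moves features and feels the other branch", {
  set.seed(5)
  C <- 16
  mb <- ns$new_builder()
  fim <- ns$mod_fim(mb, "fim", C, 4)
  own <- matrix(rnorm(5 * C), 5, C)
  other <- ns$ag_param(matrix(rnorm(5 * C), 5, C))
  out <- fim$forward(ns$ag_const(own), other, training = TRUE)
  expect_gt(max(abs(ns$vof(out) - own)), 1e-3)
  # gradient of a generic downstream scalar w.r.t. the other branch is
  # nonzero (a uniform weighting sits in batch-norm's null space, so the
  # probe weights must vary across the batch)
  ns$ag_backward(out, seed_grad = matrix(rnorm(5 * C), 5, C))
  expect_gt(max(abs(other$grad)), 1e-8)
})

test_that("cross-attention rows are stochastic and match the oracle", {
  set.seed(6)
  q <- matrix(rnorm(3 * 4), 3, 4)       # T = 2, d = 2
  k <- matrix(rnorm(3 * 4), 3, 4)
  got <- cross_attention(q, k, n_tokens = 2)
  for (n in 1:3) {
    expect_equal(rowSums(got$attention[[n]]), c(1, 1), tolerance = 1e-6)
    orc <- oracle_attention(q[n, ], k[n, ], 2)
    expect_equal(got$output[n, ], orc$output, tolerance = 1e-9)
    expect_equal(got$attention[[n]], orc$attention, tolerance = 1e-9)
  }
})

test_that("identical context tokens give uniform attention to their mean", {
  q <- matrix(rnorm(2 * 8), 2, 8)
  k <- matrix(rep(c(1, 2), each = 1, times = 8), 2, 8)
  k[1, ] <- rep(c(3, -1, 2, 0.5), 2)     # tokens (first 4) == (last 4)
  k[2, ] <- rep(c(1, 1, 0, 2), 2)
  got <- cross_attention(q, k, n_tokens = 2)
  for (n in 1:2) {
    expect_equal(got$attention[[n]],
                 matrix(0.5, 2, 2), tolerance = 1e-9)
    expect_equal(got$output[n, ], k[n, ], tolerance = 1e-9)
  }
})

test_that("attention errors when length is not divisible by tokens", {
  expect_error(cross_attention(matrix(1, 1, 6), matrix(1, 1, 6), 4),
               class = "neurofuse_config_error")
})

test_that("spatial FEM reduces to the vector FEM on constant maps", {
  set.seed(7)
  C <- 8
  mb <- ns$new_builder()
  fs <- ns$mod_fem_spatial(mb, "fs", C, 3)
  # identity 1x1 convolution so the channel modulation is observable
  wid <- array(0, c(C, C, 1, 1))
  for (c1 in seq_len(C)) wid[c1, c1, 1, 1] <- 1
  mb$params[["fs.conv1x1.W"]]$value <- wid
  u <- matrix(rnorm(3 * C), 3, C)        # per-sample channel vectors
  map <- ns$vof(ns$ag_broadcast_spatial(ns$ag_const(u), 4, 4))
  out <- ns$vof(fs$forward(ns$ag_const(map), training = TRUE))
  fem_out <- ns$vof(fs$fem$forward(ns$ag_const(u), training = TRUE))
  # map was constant over space, so out = u * fem(u) broadcast
  expect_equal(dim(out), dim(map))
  got_ratio <- out[, 1, 1, ] / t(u)       # (C x N) ratios
  expect_equal(got_ratio, t(fem_out), tolerance = 1e-9)
})

test_that("spatial FEM preserves shape and zero maps stay zero", {
  set.seed(8)
  mb <- ns$new_builder()
  fs <- ns$mod_fem_spatial(mb, "fs", 8, 3)
  map <- array(rnorm(8 * 5 * 5 * 2), c(8, 5, 5, 2))
  out <- ns$vof(fs$forward(ns$ag_const(map), training = TRUE))
  expect_equal(dim(out), dim(map))
  zmap <- array(0, c(8, 5, 5, 2))
  zout <- ns$vof(fs$forward(ns$ag_const(zmap), training = TRUE))
  expect_equal(max(abs(zout)), 0)
})

test_that("MLFM outputs preserve shapes across backbone channel counts", {
  set.seed(9)
  for (bk in c("tiny", "resnet18", "resnet50")) {
    chans <- neurofuse:::backbone_channels[[bk]][2:4]
    cfg <- fusion_config(n_classes = 3, backbone = bk)
    for (C in chans) {
      mb <- ns$new_builder()
      ml <- ns$mod_mlfm(mb, "m", C, cfg)
      f <- matrix(rnorm(2 * C), 2, C)
      cmap <- array(rnorm(C * 3 * 3 * 2, sd = .5), c(C, 3, 3, 2))
      out <- ml$forward(ns$ag_const(f), ns$ag_const(cmap),
                        training = TRUE)
      expect_equal(dim(ns$vof(out$f)), dim(f))
      expect_equal(dim(ns$vof(out$c)), dim(cmap))
    }
  }
})

test_that("disabled FEM and FIM reduce the MLFM to concat-reduction", {
  set.seed(10)
  C <- 16
  cfg <- fusion_config(n_classes = 3, backbone = "tiny",
                       use_fem = FALSE, use_fim = FALSE)
  mb <- ns$new_builder()
  ml <- ns$mod_mlfm(mb, "m", C, cfg)
  # only the two reduction layers own parameters
  expect_setequal(
    names(mb$params),
    c("m.reduce_f.W", "m.reduce_f.b", "m.reduce_c.W", "m.reduce_c.b"))
  f <- matrix(rnorm(2 * C), 2, C)
  cmap <- array(rnorm(C * 3 * 3 * 2), c(C, 3, 3, 2))
  out <- ml$forward(ns$ag_const(f), ns$ag_const(cmap), training = TRUE)
  # hand-build the expected pass-through concat-reduction
  W <- mb$params[["m.reduce_f.W"]]$value
  b <- mb$params[["m.reduce_f.b"]]$value
  expected_f <- sweep(cbind(f, f) %*% W, 2, b, "+")
  expect_equal(ns$vof(out$f), expected_f, tolerance = 1e-10)
})

test_that("forward emits stochastic probability rows and fires 3 MLFMs", {
  set.seed(11)
  cfg <- fusion_config(n_classes = 10, backbone = "tiny")
  model <- build_fusion_model(cfg)
  n <- 2
  xm <- matrix(rnorm(n * 43), n, 43)
  xs <- array(runif(n * 3 * 32 * 32), c(3, 32, 32, n))
  before <- vapply(model$mlfm, function(m) m$hook$calls, integer(1))
  out <- neurofuse:::forward_fusion(model, xm, xs, training = FALSE)
  after <- vapply(model$mlfm, function(m) m$hook$calls, integer(1))
  expect_equal(after - before, rep(1L, 3))
  expect_equal(dim(out$logits$value), c(2, 10))
  expect_equal(rowSums(out$probs), c(1, 1), tolerance = 1e-6)
})

test_that("forward validates the stack resolution", {
  cfg <- fusion_config(n_classes = 3, backbone = "tiny")
  model <- build_fusion_model(cfg)
  xm <- matrix(rnorm(2 * 43), 2, 43)
  bad <- array(runif(2 * 3 * 16 * 16), c(3, 16, 16, 2))
  expect_error(neurofuse:::forward_fusion(model, xm, bad),
               class = "neurofuse_config_error")
})

test_that("every fusion strategy and single branch completes a forward", {
  set.seed(12)
  n <- 2
  xm <- matrix(rnorm(n * 43), n, 43)
  xs <- array(runif(n * 3 * 32 * 32), c(3, 32, 32, n))
  for (strat in c("sum", "concat", "average")) {
    cfg <- fusion_config(n_classes = 4, backbone = "tiny",
                         fusion_strategy = strat)
    model <- build_fusion_model(cfg)
    out <- neurofuse:::forward_fusion(model, xm, xs)
    expect_equal(dim(out$probs), c(2, 4))
    expect_equal(rowSums(out$probs), c(1, 1), tolerance = 1e-6)
  }
  for (br in c("fcn", "cnn")) {
    cfg <- fusion_config(n_classes = 4, backbone = "tiny", branch = br)
    model <- build_fusion_model(cfg)
    out <- neurofuse:::forward_fusion(
      model, if (br == "fcn") xm else NULL,
      if (br == "cnn") xs else NULL)
    expect_equal(dim(out$probs), c(2, 4))
  }
})

test_that("a resnet18 forward composes with the fusion modules", {
  set.seed(13)
  cfg <- fusion_config(n_classes = 3, backbone = "resnet18",
                       input_resolution = 64)
  model <- build_fusion_model(cfg)
  xm <- matrix(rnorm(2 * 43), 2, 43)
  xs <- array(runif(2 * 3 * 64 * 64), c(3, 64, 64, 2))
  out <- neurofuse:::forward_fusion(model, xm, xs)
  expect_equal(dim(out$probs), c(2, 3))
  expect_equal(rowSums(out$probs), c(1, 1), tolerance = 1e-6)
})

test_that("loss closed forms and the summation oracle agree", {
  # perfect one-hot prediction: zero loss
  y <- diag(3)
  expect_equal(fusion_loss(y, y), 0)
  # uniform prediction over 10 classes: ln 10
  p <- matrix(1 / 10, 4, 10)
  y10 <- ns$yv_onehot(c(1, 4, 7, 10), 10)
  expect_equal(fusion_loss(p, y10), log(10), tolerance = 1e-12)
  # random batches match an explicit per-sample summation
  set.seed(14)
  for (rep in 1:5) {
    pr <- matrix(rexp(6 * 4), 6, 4)
    pr <- pr / rowSums(pr)
    yi <- sample(4, 6, replace = TRUE)
    yh <- ns$yv_onehot(yi, 4)
    naive <- 0
    for (i in 1:6) naive <- naive - log(pr[i, yi[i]])
    expect_equal(fusion_loss(pr, yh), naive / 6, tolerance = 1e-9)
  }
  # clamped at epsilon instead of -Inf
  pz <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_true(is.finite(fusion_loss(pz, diag(2))))
})

test_that("the fused training loss equals the loss op on probabilities", {
  set.seed(15)
  logits <- matrix(rnorm(5 * 3), 5, 3)
  y <- ns$yv_onehot(sample(3, 5, replace = TRUE), 3)
  fused <- ns$ag_softmax_ce(ns$ag_const(logits), y)
  probs <- ns$softmax_rows(logits)
  expect_equal(ns$vof(fused), fusion_loss(probs, y), tolerance = 1e-12)
})

test_that("enabling the fusion modules strictly increases parameters", {
  set.seed(16)
  base <- build_fusion_model(
    fusion_config(n_classes = 3, backbone = "tiny",
                  use_fem = FALSE, use_fim = FALSE))
  full <- build_fusion_model(fusion_config(n_classes = 3,
                                           backbone = "tiny"))
  expect_gt(n_parameters(full), n_parameters(base))
  fem_only <- build_fusion_model(
    fusion_config(n_classes = 3, backbone = "tiny", use_fim = FALSE))
  fim_only <- build_fusion_model(
    fusion_config(n_classes = 3, backbone = "tiny", use_fem = FALSE))
  expect_gt(n_parameters(full), n_parameters(fem_only))
  expect_gt(n_parameters(full), n_parameters(fim_only))
  expect_gt(n_parameters(fem_only), n_parameters(base))
  expect_gt(n_parameters(fim_only), n_parameters(base))
})
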