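# The dual-branch fusion model: configuration, CNN backbones, assembly,
# and the forward pass.

backbone_channels <- list(
  tiny = c(8, 16, 32, 64),
  resnet18 = c(64, 128, 256, 512),
  resnet34 = c(64, 128, 256, 512),
  resnet50 = c(256, 512, 1024, 2048),
  resnet101 = c(256, 512, 1024, 2048),
  vgg16 = c(64, 128, 256, 512),
  vgg19 = c(64, 128, 256, 512)
)

#' Fusion network configuration
#'
#' All architecture and training toggles of the dual-branch fusion network,
#' including every ablation axis: the CNN backbone, the feature enhancement
#' (FEM) and feature interaction (FIM) switches, the final fusion strategy,
#' and the single-branch modes used as baselines.
#'
#' @param n_classes Number of neuron types.
#' @param backbone CNN feature extractor. `"tiny"` is a light 4-stage
#'   network (channels 8/16/32/64, 32x32 input) for desk-scale work;
#'   ResNet-50 is the reference backbone at 224x224.
#' @param n_groups Number of channel groups in the FEM refinement (`N_s`).
#' @param use_fem,use_fim Enable the channel-attention enhancement and the
#'   cross-attention interaction inside each fusion module.
#' @param fusion_strategy How the final branch features combine:
#'   element-wise `"sum"` (default), `"concat"`, or `"average"`.
#' @param fim_tokens Tokens per sample in the cross-attention (`T`); stage
#'   channel counts must be divisible by it.
#' @param dropout Dropout ratio after the classifier FC layers.
#' @param pretrained Reserved flag for externally supplied backbone
#'   weights; weights are never trained here from external data.
#' @param input_resolution Side length of the projection stacks; defaults
#'   to 32 for the tiny backbone and 224 otherwise.
#' @param standardize_features Z-score the 43 morphometrics with
#'   training-fold statistics before the FCN branch.
#' @param branch `"both"` for the fusion model, `"fcn"` or `"cnn"` for a
#'   single branch alone (ablation baselines; no fusion modules are built).
#' @param n_features Length of the morphometric vector.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(n_classes,
                          backbone = c("tiny", "resnet18", "resnet34",
                                       "resnet50", "resnet101", "vgg16",
                                       "vgg19"),
                          n_groups = 3,
                          use_fem = TRUE,
                          use_fim = TRUE,
                          fusion_strategy = c("sum", "concat", "average"),
                          fim_tokens = 4,
                          dropout = 0.5,
                          pretrained = FALSE,
                          input_resolution = NULL,
                          standardize_features = TRUE,
                          branch = c("both", "fcn", "cnn"),
                          n_features = 43) {
  backbone <- match.arg(backbone)
  fusion_strategy <- match.arg(fusion_strategy)
  branch <- match.arg(branch)
  stopifnot(n_classes >= 2, n_groups >= 1, fim_tokens >= 1,
            dropout >= 0, dropout < 1, n_features >= 4)
  if (is.null(input_resolution)) {
    input_resolution <- if (backbone == "tiny") 32L else 224L
  }
  ch <- backbone_channels[[backbone]]
  if (any(ch[2:4] %% fim_tokens != 0)) {
    abort("stage channel counts must be divisible by fim_tokens",
          class = c("neurofuse_config_error", "neurofuse_error"))
  }
  structure(
    list(n_classes = as.integer(n_classes), backbone = backbone,
         n_groups = as.integer(n_groups), use_fem = use_fem,
         use_fim = use_fim, fusion_strategy = fusion_strategy,
         fim_tokens = as.integer(fim_tokens), dropout = dropout,
         pretrained = pretrained,
         input_resolution = as.integer(input_resolution),
         standardize_features = standardize_features, branch = branch,
         n_features = as.integer(n_features), channels = ch),
    class = "fusion_config"
  )
}

# ---- backbones -------------------------------------------------------------

mod_seq <- function(mods) {
  list(forward = function(x, training = TRUE) {
    for (m in mods) x <- m$forward(x, training)
    x
  })
}

mod_basic_block <- function(mb, name, cin, cout, stride) {
  c1 <- mod_conv_bn(mb, paste0(name, ".c1"), cin, cout, 3, stride, 1)
  c2 <- mod_conv_bn(mb, paste0(name, ".c2"), cout, cout, 3, 1, 1,
                    relu = FALSE)
  down <- if (stride != 1 || cin != cout) {
    mod_conv_bn(mb, paste0(name, ".down"), cin, cout, 1, stride, 0,
                relu = FALSE)
  }
  list(forward = function(x, training = TRUE) {
    h <- c2$forward(c1$forward(x, training), training)
    sk <- if (is.null(down)) x else down$forward(x, training)
    ag_relu(ag_add(h, sk))
  })
}

mod_bottleneck <- function(mb, name, cin, cmid, stride) {
  cout <- 4 * cmid
  c1 <- mod_conv_bn(mb, paste0(name, ".c1"), cin, cmid, 1, 1, 0)
  c2 <- mod_conv_bn(mb, paste0(name, ".c2"), cmid, cmid, 3, stride, 1)
  c3 <- mod_conv_bn(mb, paste0(name, ".c3"), cmid, cout, 1, 1, 0,
                    relu = FALSE)
  down <- if (stride != 1 || cin != cout) {
    mod_conv_bn(mb, paste0(name, ".down"), cin, cout, 1, stride, 0,
                relu = FALSE)
  }
  list(forward = function(x, training = TRUE) {
    h <- c3$forward(c2$forward(c1$forward(x, training), training), training)
    sk <- if (is.null(down)) x else down$forward(x, training)
    ag_relu(ag_add(h, sk))
  })
}

# returns a list of 4 stage modules, each mapping the previous feature map
# to the stage's channel count
build_backbone <- function(mb, config) {
  bk <- config$backbone
  ch <- config$channels
  if (bk == "tiny") {
    return(purrr::map(1:4, function(i) {
      cin <- if (i == 1) 3 else ch[i - 1]
      mod_conv_bn(mb, sprintf("cnn.s%d", i), cin, ch[i], 3,
                  stride = if (i == 1) 1 else 2, pad = 1)
    }))
  }
  if (bk %in% c("vgg16", "vgg19")) {
    reps <- if (bk == "vgg16") c(2, 2, 3, 3) else c(2, 2, 4, 4)
    return(purrr::map(1:4, function(i) {
      cin <- if (i == 1) 3 else ch[i - 1]
      mods <- purrr::map(seq_len(reps[i]), function(j) {
        mod_conv_bn(mb, sprintf("cnn.s%d.c%d", i, j),
                    if (j == 1) cin else ch[i], ch[i], 3, 1, 1)
      })
      list(forward = function(x, training = TRUE) {
        for (m in mods) x <- m$forward(x, training)
        ag_maxpool(x, 2, 2)
      })
    }))
  }
  # resnet family
  blocks <- switch(bk,
    resnet18 = c(2, 2, 2, 2), resnet34 = c(3, 4, 6, 3),
    resnet50 = c(3, 4, 6, 3), resnet101 = c(3, 4, 23, 3))
  bottleneck <- bk %in% c("resnet50", "resnet101")
  cmid <- c(64, 128, 256, 512)
  stem <- mod_conv_bn(mb, "cnn.stem", 3, 64, 7, 2, 3)
  stages <- purrr::map(1:4, function(i) {
    cin0 <- if (i == 1) 64 else ch[i - 1]
    mods <- purrr::map(seq_len(blocks[i]), function(j) {
      cin <- if (j == 1) cin0 else ch[i]
      stride <- if (j == 1 && i > 1) 2 else 1
      if (bottleneck) {
        mod_bottleneck(mb, sprintf("cnn.s%d.b%d", i, j), cin, cmid[i],
                       stride)
      } else {
        mod_basic_block(mb, sprintf("cnn.s%d.b%d", i, j), cin, ch[i],
                        stride)
      }
    })
    mod_seq(mods)
  })
  stage1 <- stages[[1]]
  stages[[1]] <- list(forward = function(x, training = TRUE) {
    h <- ag_maxpool(stem$forward(x, training), 3, 2, 1)
    stage1$forward(h, training)
  })
  stages
}

# ---- model -----------------------------------------------------------------

#' Build a fusion network
#'
#' Assembles the FCN branch (4 blocks over the morphometric vector, widths
#' matched to the CNN stage channels), the CNN backbone over the projection
#' stack, three fusion modules bridging the branches after CNN stages 2-4,
#' the final fusion, and a two-layer classifier. Parameter initialization
#' draws from the current RNG stream, so seed before building for
#' reproducibility.
#'
#' @param config A [fusion_config()].
#' @return A `fusion_model` object.
#' @export
build_fusion_model <- function(config) {
  stopifnot(inherits(config, "fusion_config"))
  mb <- new_builder()
  ch <- config$channels
  D <- ch[4]
  model <- list(config = config, mb = mb)

  if (config$branch != "cnn") {
    dims_in <- c(config$n_features, ch[1], ch[2], ch[3])
    model$fcn <- purrr::map(1:4, function(i) {
      mod_fcn_block(mb, sprintf("fcn.b%d", i), dims_in[i], ch[i])
    })
  }
  if (config$branch != "fcn") {
    model$cnn <- build_backbone(mb, config)
  }
  if (config$branch == "both") {
    model$mlfm <- purrr::map(1:3, function(i) {
      mod_mlfm(mb, sprintf("mlfm%d", i), ch[i + 1], config)
    })
  }
  if (config$branch != "cnn") {
    model$proj <- mod_dense(mb, "head.proj", D, D)
  }
  d_join <- if (config$branch == "both" &&
                config$fusion_strategy == "concat") 2L * D else D
  model$cls1 <- mod_dense(mb, "head.cls1", d_join, d_join)
  model$cls2 <- mod_dense(mb, "head.cls2", d_join, config$n_classes)
  model$feature_center <- NULL
  model$feature_scale <- NULL
  class(model) <- "fusion_model"
  model
}

#' Number of trainable parameters
#'
#' @param model A `fusion_model`.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$mb$params, function(p) length(p$value), numeric(1)))
}

# forward pass; x_morpho: N x n_features (already standardized),
# x_stack: (3,H,W,N) or NULL. Returns list(logits = ag_node, probs)
forward_fusion <- function(model, x_morpho, x_stack, training = FALSE) {
  config <- model$config
  branch <- config$branch
  f <- NULL; cmap <- NULL

  if (branch != "cnn") {
    stopifnot(ncol(x_morpho) == config$n_features)
    f <- ag_const(x_morpho)
  }
  if (branch != "fcn") {
    dm <- dim(x_stack)
    if (dm[1] != 3 || dm[2] != config$input_resolution) {
      abort(sprintf(
        "stack shape %s does not match configured resolution %d",
        paste(dm, collapse = "x"), config$input_resolution),
        class = c("neurofuse_config_error", "neurofuse_error"))
    }
    cmap <- ag_const(x_stack)
  }

  if (branch == "fcn") {
    for (i in 1:4) f <- model$fcn[[i]]$forward(f, training)
    fj <- model$proj$forward(f)
  } else if (branch == "cnn") {
    for (i in 1:4) cmap <- model$cnn[[i]]$forward(cmap, training)
    fj <- ag_global_avgpool(cmap)
  } else {
    f <- model$fcn[[1]]$forward(f, training)
    cmap <- model$cnn[[1]]$forward(cmap, training)
    for (i in 2:4) {
      f <- model$fcn[[i]]$forward(f, training)
      cmap <- model$cnn[[i]]$forward(cmap, training)
      fused <- model$mlfm[[i - 1]]$forward(f, cmap, training)
      f <- fused$f
      cmap <- fused$c
    }
    fl <- model$proj$forward(f)
    fc <- ag_global_avgpool(cmap)
    fj <- switch(config$fusion_strategy,
      sum = ag_add(fl, fc),
      average = ag_scale(ag_add(fl, fc), 0.5),
      concat = ag_concat_cols(fl, fc)
    )
  }

  # dropout regularizes the hidden classifier feature; the output layer's
  # logits are left intact (dropping logits would corrupt the class scores
  # with label-independent noise)
  h <- ag_dropout(model$cls1$forward(fj), config$dropout, training)
  logits <- model$cls2$forward(h)
  probs <- softmax_rows(logits$value)
  list(logits = logits, probs = probs)
}

#' Forward pass of a fusion model
#'
#' Runs the network in evaluation mode and returns class probabilities.
#'
#' @param model A `fusion_model` from [build_fusion_model()].
#' @param morpho Matrix of morphometric vectors (samples in rows). Applied
#'   standardization must match what the model was trained with; [fit()]
#'   handles this automatically.
#' @param stacks Array `(3, H, W, N)` of projection stacks (or `NULL` for
#'   the FCN-only branch).
#' @return A list with `probs` (N x n_classes, rows sum to 1) and `logits`.
#' @export
predict_fusion <- function(model, morpho = NULL, stacks = NULL) {
  out <- forward_fusion(model, morpho, stacks, training = FALSE)
  list(probs = out$probs, logits = out$logits$value)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(
    "<fusion_model> backbone %s, branch %s, %d classes, %s parameters\n",
    x$config$backbone, x$config$branch, x$config$n_classes,
    format(n_parameters(x), big.mark = ",")))
  invisible(x)
}
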