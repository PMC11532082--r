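# Training protocol (Adam, cosine learning-rate decay, mini-batches),
# stratified cross-validation, and the evaluation metrics.

#' Stratified k-fold split
#'
#' Splits sample indices into k disjoint folds whose per-class proportions
#' match the global proportions to within one sample. Reproducible for a
#' fixed seed.
#'
#' @param labels Vector of class labels, one per sample.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffling.
#' @return A list of k integer vectors (test indices per fold).
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (k > min(counts)) {
    abort(sprintf("k = %d exceeds the smallest class count (%d)",
                  k, min(counts)), class = c("neurofuse_config_error", "neurofuse_error"))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  folds <- vector("list", k)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    assign_to <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
  }
  lapply(folds, sort)
}

#' Prepare model inputs from neuron trees
#'
#' Computes the 43-metric morphometric matrix and (optionally) the
#' 3-channel projection stacks for a set of labeled trees.
#'
#' @param data A tibble with `tree` and `label` columns (e.g. from
#'   [generate_dataset()]), or a list of [neuron_tree()] objects.
#' @param labels Class labels if `data` is a plain list.
#' @param resolution Raster side length for the projection stacks.
#' @param images Render projection stacks? Set `FALSE` for FCN-only work.
#' @return A list with `morpho` (N x 43 matrix), `images`
#'   (`(3, res, res, N)` array or `NULL`), `labels` (factor), `names`.
#' @export
neuron_dataset <- function(data, labels = NULL, resolution = 32,
                           images = TRUE) {
  if (is.data.frame(data)) {
    trees <- data$tree
    if (is.null(labels)) labels <- data$label
  } else {
    trees <- data
  }
  if (is.null(labels)) {
    labels <- purrr::map_chr(trees, ~ .x$class_label %||% NA_character_)
  }
  feats <- compute_features(trees, labels)
  morpho <- as.matrix(feats[morphometric_names()])
  imgs <- if (images) render_stacks(trees, resolution) else NULL
  list(morpho = morpho, images = imgs, labels = as.factor(labels),
       names = purrr::map_chr(trees, ~ .x$name %||% "neuron"))
}

subset_dataset <- function(ds, idx) {
  list(morpho = ds$morpho[idx, , drop = FALSE],
       images = if (!is.null(ds$images)) {
         ds$images[, , , idx, drop = FALSE]
       },
       labels = factor(ds$labels[idx], levels = levels(ds$labels)),
       names = ds$names[idx])
}

standardize_morpho <- function(x, center, scale) {
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Train a fusion network
#'
#' Optimizes the network with Adam (initial learning rate `lr`, cosine
#' decay to zero over `epochs`) on mini-batches, logging per-epoch training
#' loss and accuracy (and test metrics when `eval_data` is given).
#' Morphometric inputs are z-scored with statistics of this training set
#' when the configuration asks for it.
#'
#' @param config A [fusion_config()].
#' @param data A prepared dataset from [neuron_dataset()], or a tibble of
#'   trees (prepared automatically at the configured resolution).
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate.
#' @param seed Integer seed governing initialization, shuffling, dropout.
#' @param eval_data Optional held-out dataset evaluated after each epoch.
#' @param verbose Print a line per epoch.
#' @return A `fusion_fit` object: the trained model, a `history` tibble,
#'   and the feature-scaling statistics.
#' @export
fit <- function(config, data, epochs = 100, batch_size = 16, lr = 1e-3,
                seed = 1, eval_data = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "fusion_config"))
  if (is.data.frame(data)) {
    data <- neuron_dataset(data, resolution = config$input_resolution,
                           images = config$branch != "fcn")
  }
  n <- length(data$labels)
  if (n == 0) abort("empty dataset", class = c("neurofuse_config_error", "neurofuse_error"))
  lev <- levels(data$labels)
  stopifnot(length(lev) == config$n_classes)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))

  center <- rep(0, ncol(data$morpho))
  scale <- rep(1, ncol(data$morpho))
  if (config$standardize_features) {
    center <- colMeans(data$morpho)
    scale <- pmax(apply(data$morpho, 2, sd), 1e-8)
  }
  xm <- standardize_morpho(data$morpho, center, scale)

  model <- build_fusion_model(config)
  model$feature_center <- center
  model$feature_scale <- scale
  model$levels <- lev
  opt <- adam_init(model$mb$params)

  yi <- as.integer(data$labels)
  onehot <- matrix(0, n, config$n_classes)
  onehot[cbind(seq_len(n), yi)] <- 1

  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
    ord <- sample(n)
    starts <- seq(1, n, by = batch_size)
    batches <- lapply(starts, function(s) {
      ord[s:min(s + batch_size - 1, n)]
    })
    # a trailing singleton breaks batch-norm statistics; merge it
    nb <- length(batches)
    if (nb > 1 && length(batches[[nb]]) == 1) {
      batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
      batches[nb] <- NULL
    }
    ep_loss <- 0
    ep_correct <- 0
    for (b in batches) {
      xb <- xm[b, , drop = FALSE]
      sb <- if (!is.null(data$images)) {
        data$images[, , , b, drop = FALSE]
      }
      out <- forward_fusion(model, xb, sb, training = TRUE)
      loss <- ag_softmax_ce(out$logits, onehot[b, , drop = FALSE])
      ag_backward(loss)
      adam_step(opt, model$mb$params, lr_ep)
      ep_loss <- ep_loss + loss$value * length(b)
      ep_correct <- ep_correct +
        sum(max.col(out$probs) == yi[b])
    }
    row <- tibble::tibble(epoch = ep, lr = lr_ep,
                          train_loss = ep_loss / n,
                          train_accuracy = ep_correct / n)
    if (!is.null(eval_data)) {
      fitted <- structure(
        list(model = model, config = config, history = NULL),
        class = "fusion_fit")
      pr <- predict(fitted, eval_data, type = "prob")
      yv <- as.integer(factor(eval_data$labels, levels = lev))
      row$test_loss <- fusion_loss(pr, yv_onehot(yv, config$n_classes))
      row$test_accuracy <- mean(max.col(pr) == yv)
    }
    history[[ep]] <- row
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f",
                      ep, lr_ep, row$train_loss, row$train_accuracy))
    }
  }

  structure(
    list(model = model, config = config,
         history = dplyr::bind_rows(history),
         feature_center = center, feature_scale = scale, levels = lev),
    class = "fusion_fit"
  )
}

yv_onehot <- function(yi, k) {
  m <- matrix(0, length(yi), k)
  m[cbind(seq_along(yi), yi)] <- 1
  m
}

#' Predict from a trained fusion network
#'
#' @param object A `fusion_fit` from [fit()].
#' @param newdata A dataset list from [neuron_dataset()] (fields `morpho`
#'   and, unless FCN-only, `images`).
#' @param type `"prob"` for a probability matrix, `"class"` for labels.
#' @param ... Unused.
#' @return A probability matrix (rows sum to 1) or a factor of classes.
#' @export
predict.fusion_fit <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  model <- object$model
  xm <- standardize_morpho(newdata$morpho, model$feature_center,
                           model$feature_scale)
  out <- forward_fusion(model, xm, newdata$images, training = FALSE)
  colnames(out$probs) <- model$levels
  if (type == "prob") return(out$probs)
  factor(model$levels[max.col(out$probs)], levels = model$levels)
}

# rank-form AUC; exactly the trapezoidal area under the empirical ROC
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predictions on a test set
#'
#' Computes the confusion matrix, accuracy, per-class and macro precision /
#' recall / F1, and one-vs-rest AUC (trapezoidal ROC area, computed in rank
#' form) from a fitted model and a held-out dataset.
#'
#' @param object A `fusion_fit`, or a probability matrix with class
#'   columns.
#' @param test_data A dataset list from [neuron_dataset()]; when `object`
#'   is a probability matrix, only `labels` is used.
#' @param fold_index Bookkeeping index stored in the report.
#' @return A `fold_report`: confusion matrix, `metrics` tibble (per-class
#'   precision, recall, F1, AUC), `accuracy`, and macro averages.
#' @export
evaluate <- function(object, test_data, fold_index = 1L) {
  if (inherits(object, "fusion_fit")) {
    probs <- predict(object, test_data, type = "prob")
    lev <- object$levels
  } else {
    probs <- as.matrix(object)
    lev <- colnames(probs)
  }
  truth <- factor(as.character(test_data$labels), levels = lev)
  pred <- factor(lev[max.col(probs)], levels = lev)
  cm <- table(truth = truth, prediction = pred)
  cm <- matrix(as.integer(cm), nrow = length(lev),
               dimnames = list(truth = lev, prediction = lev))

  tp <- diag(cm)
  prec <- unname(ifelse(colSums(cm) > 0, tp / colSums(cm), 0))
  rec <- unname(ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  auc <- vapply(seq_along(lev), function(j) {
    auc_rank(probs[, j], truth == lev[j])
  }, numeric(1))

  structure(
    list(
      fold_index = as.integer(fold_index),
      confusion = cm,
      accuracy = sum(tp) / sum(cm),
      metrics = tibble::tibble(class = lev, precision = prec,
                               recall = rec, f1 = f1, auc = auc,
                               support = unname(rowSums(cm))),
      macro_precision = mean(prec),
      macro_recall = mean(rec),
      macro_f1 = mean(f1)
    ),
    class = "fold_report"
  )
}

#' @export
print.fold_report <- function(x, ...) {
  cat(sprintf(
    "<fold_report %d> accuracy %.3f, macro F1 %.3f\n",
    x$fold_index, x$accuracy, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Cross-validate a fusion network
#'
#' Runs stratified k-fold cross-validation: for each fold the model is
#' trained from scratch on the remaining folds (feature standardization
#' statistics come from the training folds only) and evaluated on the
#' held-out fold.
#'
#' @param config A [fusion_config()].
#' @param data A tibble of labeled trees or a prepared [neuron_dataset()].
#' @param k Number of folds.
#' @param seed Integer seed for the folds and the per-fold training.
#' @param epochs,batch_size,lr Passed to [fit()].
#' @param verbose Print per-fold progress.
#' @return A `cv_report`: per-fold `fold_report`s plus a `summary` tibble
#'   of fold metrics and their mean and standard deviation.
#' @export
cross_validate <- function(config, data, k = 10, seed = 1, epochs = 100,
                           batch_size = 16, lr = 1e-3, verbose = FALSE) {
  if (is.data.frame(data)) {
    data <- neuron_dataset(data, resolution = config$input_resolution,
                           images = config$branch != "fcn")
  }
  folds <- stratified_folds(data$labels, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(data$labels), test_idx)
    fitted <- fit(config, subset_dataset(data, train_idx),
                  epochs = epochs, batch_size = batch_size, lr = lr,
                  seed = seed + f)
    reports[[f]] <- evaluate(fitted, subset_dataset(data, test_idx),
                             fold_index = f)
    if (verbose) {
      message(sprintf("fold %d/%d: accuracy %.3f", f, k,
                      reports[[f]]$accuracy))
    }
  }
  per_fold <- purrr::map_dfr(reports, function(r) {
    tibble::tibble(fold = r$fold_index, accuracy = r$accuracy,
                   macro_precision = r$macro_precision,
                   macro_recall = r$macro_recall, macro_f1 = r$macro_f1,
                   mean_auc = mean(r$metrics$auc, na.rm = TRUE))
  })
  structure(
    list(folds = reports, summary = per_fold, config = config, k = k,
         seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d folds: accuracy %.3f +/- %.3f, macro F1 %.3f\n",
    x$k, mean(x$summary$accuracy), sd(x$summary$accuracy),
    mean(x$summary$macro_f1)))
  invisible(x)
}
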