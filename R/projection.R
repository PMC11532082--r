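# PCA axis normalization and orthogonal projection rasterization.
#
# The CNN branch consumes a 3-channel square raster: the neuron skeleton
# drawn on the x-y, y-z, and x-z planes after rotating the cloud into its
# principal frame. One shared scale across the three views preserves the
# 3D proportions of the arbor.

# rotate coordinates into the principal frame with a deterministic sign
# convention: per axis, non-negative third moment; on a near-tie, the
# farthest-from-centroid point gets a non-negative coordinate
pca_align_coords <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (nrow(xyz) == 1) return(xc)
  cv <- crossprod(xc) / nrow(xc)
  eg <- eigen(cv, symmetric = TRUE)
  rot <- xc %*% eg$vectors
  far <- which.max(rowSums(xc^2))
  for (j in 1:3) {
    m3 <- sum(rot[, j]^3)
    flip <- if (abs(m3) > 1e-8 * max(1, sum(rot[, j]^2))^1.5) m3 < 0
            else rot[far, j] < 0
    if (isTRUE(flip)) rot[, j] <- -rot[, j]
  }
  rot
}

#' Normalize a neuron into its principal frame
#'
#' Centers the coordinates on their centroid and rotates them so that the
#' axes are the principal components in descending-variance order. Because
#' laboratories orient reconstructions arbitrarily, this gives every neuron
#' a consistent reference frame before projection. The eigenvector sign
#' ambiguity is resolved deterministically (non-negative third moment per
#' axis, falling back to the sign of the farthest node's coordinate), so a
#' rigidly rotated copy of a neuron normalizes to the same coordinates.
#' Radii are unchanged.
#'
#' @param tree A [neuron_tree()].
#' @return A [neuron_tree()] with transformed coordinates.
#' @export
pca_normalize <- function(tree) {
  validate_neuron_tree(tree)
  rot <- pca_align_coords(tree_coords(tree))
  tree$nodes$x <- rot[, 1]
  tree$nodes$y <- rot[, 2]
  tree$nodes$z <- rot[, 3]
  tree
}

# splat an anti-aliased segment onto a square canvas by dense sampling with
# bilinear weights; pixels keep the maximum coverage seen (values in [0,1])
draw_segment <- function(canvas, x0, y0, x1, y1) {
  side <- nrow(canvas)
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len / 0.4) + 1L)
  t <- seq(0, 1, length.out = n)
  px <- x0 + t * (x1 - x0)
  py <- y0 + t * (y1 - y0)
  i0 <- floor(px); j0 <- floor(py)
  fx <- px - i0; fy <- py - j0
  for (k in 0:3) {
    di <- k %% 2; dj <- k %/% 2
    w <- abs(1 - di - fx) * abs(1 - dj - fy)
    ii <- i0 + di; jj <- j0 + dj
    ok <- ii >= 1 & ii <= side & jj >= 1 & jj <= side & w > 0
    if (!any(ok)) next
    idx <- cbind(ii[ok], jj[ok])
    canvas[idx] <- pmax(canvas[idx], w[ok])
  }
  canvas
}

#' Render the three orthogonal projection views
#'
#' Draws every parent-child segment of the (typically PCA-normalized) tree
#' as a 1-pixel-wide anti-aliased line into three square rasters - the x-y,
#' y-z, and x-z views - using one isotropic fit-to-frame scale shared by all
#' views, then stacks them as a 3-channel image. Background is 0 and
#' foreground reaches 1. Node radii are not rendered; radius information
#' lives in the morphometric branch.
#'
#' @param tree A [neuron_tree()].
#' @param resolution Side length of the square raster in pixels.
#' @param pad_fraction Margin kept free on each side, as a fraction of the
#'   side length.
#' @return A `projection_stack`: a numeric array of dim
#'   `c(3, resolution, resolution)` with values in `[0, 1]` and channel
#'   order x-y, y-z, x-z.
#' @export
render_views <- function(tree, resolution = 224, pad_fraction = 0.05) {
  validate_neuron_tree(tree)
  stopifnot(resolution >= 8, pad_fraction >= 0, pad_fraction < 0.5)
  xyz <- tree_coords(tree)
  rng <- apply(xyz, 2, range)
  spans <- rng[2, ] - rng[1, ]
  max_span <- max(spans)
  usable <- (1 - 2 * pad_fraction) * (resolution - 1)
  scale <- if (max_span > 0) usable / max_span else 0
  mid <- colMeans(rng)
  # pixel coordinates, centered in the canvas
  pix <- sweep(xyz, 2, mid)
  pix <- pix * scale + (resolution + 1) / 2

  views <- list(c(1, 2), c(2, 3), c(1, 3))     # x-y, y-z, x-z
  parent <- tree$nodes$parent
  stack <- array(0, dim = c(3, resolution, resolution))
  for (v in seq_along(views)) {
    canvas <- matrix(0, resolution, resolution)
    a <- views[[v]][1]; b <- views[[v]][2]
    ch <- which(parent != 0L)
    if (length(ch) == 0) {
      canvas <- draw_segment(canvas, pix[1, a], pix[1, b],
                             pix[1, a], pix[1, b])
    } else {
      for (i in ch) {
        p <- parent[i]
        canvas <- draw_segment(canvas, pix[p, a], pix[p, b],
                               pix[i, a], pix[i, b])
      }
    }
    stack[v, , ] <- canvas
  }
  structure(stack, class = "projection_stack",
            view_order = c("x-y", "y-z", "x-z"),
            resolution = resolution)
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("<projection_stack> 3 x %d x %d, foreground pixels: %s\n",
              attr(x, "resolution"), attr(x, "resolution"),
              paste(apply(unclass(x) > 0, 1, sum), collapse = "/")))
  invisible(x)
}

#' Plot a projection stack
#'
#' Shows the three orthogonal views side by side as raster panels.
#'
#' @param object A `projection_stack` from [render_views()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot projection_stack
#' @export
autoplot.projection_stack <- function(object, ...) {
  res <- attr(object, "resolution")
  vo <- attr(object, "view_order")
  df <- purrr::map_dfr(1:3, function(v) {
    m <- unclass(object)[v, , ]
    tibble::tibble(
      view = vo[v],
      px = rep(seq_len(res), times = res),
      py = rep(seq_len(res), each = res),
      value = as.vector(m)
    )
  })
  df$view <- factor(df$view, levels = vo)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~view) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Render projection stacks for many neurons
#'
#' Convenience wrapper: PCA-normalize then rasterize each tree, returning
#' the array the CNN branch consumes.
#'
#' @param trees List of [neuron_tree()] objects or a tibble with a `tree`
#'   list column.
#' @param resolution Raster side length in pixels.
#' @param pad_fraction Margin fraction, see [render_views()].
#' @return A numeric array of dim `c(3, resolution, resolution, n)`.
#' @export
render_stacks <- function(trees, resolution = 224, pad_fraction = 0.05) {
  if (is.data.frame(trees)) trees <- trees$tree
  n <- length(trees)
  out <- array(0, dim = c(3, resolution, resolution, n))
  for (i in seq_len(n)) {
    out[, , , i] <- unclass(render_views(pca_normalize(trees[[i]]),
                                         resolution, pad_fraction))
  }
  out
}
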