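# Fixture builders used across the suite. Everything is generated in code.

# simple chain soma -> ... along given points
chain_tree <- function(pts, radius = 0.5) {
  n <- nrow(pts)
  neuron_tree(data.frame(
    id = seq_len(n), type = c(1, rep(3, n - 1)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    radius = c(1, rep(radius, n - 1)),
    parent = c(-1, seq_len(n - 1))
  ), name = "chain")
}

# one bifurcation: soma -> stem node -> two daughters (each a chain)
bif_tree <- function(d1 = c(1, 0, 0), d2 = c(0, 1, 0),
                     r_parent = 1, r_d1 = 0.5, r_d2 = 0.5) {
  neuron_tree(data.frame(
    id = 1:4,
    type = c(1, 3, 3, 3),
    x = c(0, 0, d1[1], d2[1]),
    y = c(0, 0, d1[2], d2[2]),
    z = c(0, 1, 1 + d1[3], 1 + d2[3]),
    radius = c(1, r_parent, r_d1, r_d2),
    parent = c(-1, 1, 2, 2)
  ), name = "bif")
}

# random binary tree with n_extra growth steps; every node placed at a
# random position, radii decreasing; independent of the package generator
random_binary_tree <- function(n_nodes = 50, seed = 1) {
  set.seed(seed)
  id <- 1L
  rows <- list(c(1, 1, 0, 0, 0, 2, -1))
  tips <- 1L                      # node ids that can still grow
  while (id < n_nodes) {
    g <- tips[sample.int(length(tips), 1)]
    n_child <- if (runif(1) < 0.35 && id + 2 <= n_nodes) 2 else 1
    for (k in seq_len(n_child)) {
      id <- id + 1L
      pos <- rows[[g]][3:5] + rnorm(3, sd = 3)
      rows[[id]] <- c(id, 3, pos, max(0.05, rows[[g]][6] * runif(1, .7, 1)),
                      g)
      tips <- c(tips, id)
    }
    tips <- setdiff(tips, g)
    if (length(tips) == 0) tips <- id
  }
  m <- do.call(rbind, rows)
  neuron_tree(data.frame(id = m[, 1], type = m[, 2], x = m[, 3],
                         y = m[, 4], z = m[, 5], radius = m[, 6],
                         parent = m[, 7]),
              name = sprintf("rand%d", seed))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

transform_tree <- function(tree, R = diag(3), shift = c(0, 0, 0),
                           scale = 1) {
  xyz <- as.matrix(tree$nodes[c("x", "y", "z")])
  xyz <- scale * (xyz %*% t(R))
  xyz <- sweep(xyz, 2, shift, "+")
  tree$nodes$x <- xyz[, 1]; tree$nodes$y <- xyz[, 2]
  tree$nodes$z <- xyz[, 3]
  tree$nodes$radius <- tree$nodes$radius * scale
  tree
}
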