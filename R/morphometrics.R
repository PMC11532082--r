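# Tree decomposition and the 43-metric morphometric registry.
#
# A "branch" runs from an anchor (the soma root or a bifurcation node) through
# single-child nodes to the next bifurcation or tip, anchor included, so its
# path length covers the anchor-to-first-child edge. Branch order is
# centrifugal with stems at order 1.

#' Decompose a neuron tree into branches
#'
#' @param tree A [neuron_tree()].
#' @return A tibble with one row per branch: `branch` (index), `order`
#'   (centrifugal, stems = 1), and `nodes`, a list column of internal node
#'   ids from the anchor (soma or bifurcation) to the ending bifurcation
#'   or tip.
#' @export
decompose_branches <- function(tree) {
  validate_neuron_tree(tree)
  kids <- tree_children(tree)
  root <- tree_root(tree)
  deg <- lengths(kids)
  n <- nrow(tree$nodes)
  if (n == 1) {
    return(tibble::tibble(branch = integer(), order = integer(),
                          nodes = list()))
  }

  paths <- list()
  orders <- integer()
  # queue of (anchor, first child, order)
  queue <- lapply(kids[[root]], function(ch) list(root, ch, 1L))
  while (length(queue) > 0) {
    item <- queue[[1]]; queue <- queue[-1]
    path <- c(item[[1]], item[[2]])
    cur <- item[[2]]
    while (deg[cur] == 1) {
      cur <- kids[[cur]][1]
      path <- c(path, cur)
    }
    paths[[length(paths) + 1]] <- path
    orders <- c(orders, item[[3]])
    if (deg[cur] >= 2) {
      for (ch in kids[[cur]]) {
        queue[[length(queue) + 1]] <- list(cur, ch, item[[3]] + 1L)
      }
    }
  }
  tibble::tibble(branch = seq_along(paths), order = orders, nodes = paths)
}

# per-edge table: one row per non-root node
tree_edges <- function(tree) {
  nd <- tree$nodes
  ch <- which(nd$parent != 0L)
  pa <- nd$parent[ch]
  len <- sqrt((nd$x[ch] - nd$x[pa])^2 + (nd$y[ch] - nd$y[pa])^2 +
              (nd$z[ch] - nd$z[pa])^2)
  tibble::tibble(child = ch, parent = pa, len = len,
                 r_child = nd$radius[ch], r_parent = nd$radius[pa])
}

# path distance from root, per node
node_path_distance <- function(tree) {
  nd <- tree$nodes
  ed <- tree_edges(tree)
  elen <- numeric(nrow(nd))
  elen[ed$child] <- ed$len
  out <- numeric(nrow(nd))
  ord <- order(node_depths(tree))            # parents before children
  for (i in ord) {
    p <- nd$parent[i]
    if (p != 0L) out[i] <- out[p] + elen[i]
  }
  out
}

node_depths <- function(tree) {
  parent <- tree$nodes$parent
  depth <- integer(length(parent))
  remaining <- which(parent != 0L)
  d <- 0L
  frontier <- which(parent == 0L)
  while (length(frontier) > 0) {
    depth[frontier] <- d
    frontier <- remaining[parent[remaining] %in% frontier]
    remaining <- setdiff(remaining, frontier)
    d <- d + 1L
  }
  depth
}

# tips contained in each node's subtree
subtree_tips <- function(tree) {
  kids <- tree_children(tree)
  deg <- lengths(kids)
  root <- tree_root(tree)
  tips <- as.numeric(deg == 0)
  if (nrow(tree$nodes) == 1) tips[root] <- 1
  ord <- order(node_depths(tree), decreasing = TRUE)   # leaves first
  for (i in ord) {
    if (deg[i] > 0) tips[i] <- sum(tips[kids[[i]]])
  }
  tips
}

#' Total reconstructed length
#'
#' Sum of Euclidean lengths over all parent-child segments, in the units of
#' the coordinates (micrometers for NeuroMorpho-style files).
#'
#' @param tree A [neuron_tree()].
#' @return A single non-negative number; 0 for a single-node tree.
#' @export
metric_total_length <- function(tree) {
  sum(tree_edges(tree)$len)
}

#' Per-branch contraction
#'
#' Contraction of a branch is the Euclidean distance between its endpoints
#' divided by its path length: 1 for a straight branch, smaller for
#' meandering ones. Zero-path-length branches are flagged and excluded from
#' tree-level averages.
#'
#' @param tree A [neuron_tree()].
#' @return A tibble with `branch`, `contraction`, and `defined`.
#' @export
metric_contraction <- function(tree) {
  br <- decompose_branches(tree)
  xyz <- tree_coords(tree)
  vals <- purrr::map_dbl(br$nodes, function(p) {
    pts <- xyz[p, , drop = FALSE]
    plen <- sum(sqrt(rowSums(diff(pts)^2)))
    if (plen <= 0) return(NA_real_)
    sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)) / plen
  })
  tibble::tibble(branch = br$branch, contraction = ifelse(is.na(vals), 0, vals),
                 defined = !is.na(vals))
}

# bifurcation helper: internal ids of nodes with >= 2 children (non-root)
bifurcation_nodes <- function(tree) {
  kids <- tree_children(tree)
  deg <- lengths(kids)
  setdiff(which(deg >= 2), tree_root(tree))
}

#' Partition asymmetry at each bifurcation
#'
#' For tip counts `n1`, `n2` of the two subtrees below a bifurcation, the
#' asymmetry is `|n1 - n2| / (n1 + n2 - 2)` when `n1 + n2 > 2`, else 0
#' (a fully balanced cherry).
#'
#' @param tree A [neuron_tree()].
#' @return A tibble with `node` (bifurcation id) and `asymmetry` in `[0, 1]`.
#' @export
metric_partition_asymmetry <- function(tree) {
  kids <- tree_children(tree)
  tips <- subtree_tips(tree)
  bifs <- bifurcation_nodes(tree)
  vals <- purrr::map_dbl(bifs, function(b) {
    ns <- tips[kids[[b]][1:2]]
    if (sum(ns) <= 2) 0 else abs(ns[1] - ns[2]) / (sum(ns) - 2)
  })
  tibble::tibble(node = bifs, asymmetry = vals)
}

# direction from a to b, or NULL if degenerate
unit_dir <- function(xyz, a, b) {
  v <- xyz[b, ] - xyz[a, ]
  nv <- sqrt(sum(v^2))
  if (nv <= 0) return(NULL)
  v / nv
}

angle_deg <- function(u, v) {
  d <- sum(u * v)
  d <- max(-1, min(1, d))
  acos(d) * 180 / pi
}

# walk from child c down single-child runs to the branch endpoint
branch_endpoint <- function(kids, deg, c) {
  while (deg[c] == 1) c <- kids[[c]][1]
  c
}

#' Bifurcation amplitude angles
#'
#' Angle in degrees between the two daughter directions at each bifurcation.
#' `mode = "local"` uses the immediate daughter nodes, `mode = "remote"` the
#' daughter-branch endpoints (next bifurcation or tip). Bifurcations with a
#' zero-length daughter vector are flagged undefined.
#'
#' @param tree A [neuron_tree()].
#' @param mode `"local"` or `"remote"`.
#' @return A tibble with `node`, `angle` (degrees in `[0, 180]`), `defined`.
#' @export
metric_bifurcation_angle <- function(tree, mode = c("local", "remote")) {
  mode <- match.arg(mode)
  kids <- tree_children(tree)
  deg <- lengths(kids)
  xyz <- tree_coords(tree)
  bifs <- bifurcation_nodes(tree)
  vals <- purrr::map_dbl(bifs, function(b) {
    c1 <- kids[[b]][1]; c2 <- kids[[b]][2]
    if (mode == "remote") {
      c1 <- branch_endpoint(kids, deg, c1)
      c2 <- branch_endpoint(kids, deg, c2)
    }
    u <- unit_dir(xyz, b, c1); v <- unit_dir(xyz, b, c2)
    if (is.null(u) || is.null(v)) return(NA_real_)
    angle_deg(u, v)
  })
  tibble::tibble(node = bifs, angle = ifelse(is.na(vals), 0, vals),
                 defined = !is.na(vals))
}

#' Diameter ratios at each bifurcation
#'
#' `daughter_ratio` is the larger daughter diameter over the smaller;
#' `parent_daughter_ratio` is the mean daughter diameter over the parent
#' (bifurcation node) diameter.
#'
#' @param tree A [neuron_tree()].
#' @return A tibble with `node`, `daughter_ratio`, `parent_daughter_ratio`.
#' @export
metric_diameter_ratios <- function(tree) {
  kids <- tree_children(tree)
  r <- tree$nodes$radius
  bifs <- bifurcation_nodes(tree)
  dr <- purrr::map_dbl(bifs, function(b) {
    d <- 2 * r[kids[[b]][1:2]]
    if (min(d) <= 0) NA_real_ else max(d) / min(d)
  })
  pdr <- purrr::map_dbl(bifs, function(b) {
    d <- 2 * r[kids[[b]][1:2]]
    dp <- 2 * r[b]
    if (dp <= 0) NA_real_ else mean(d) / dp
  })
  tibble::tibble(node = bifs, daughter_ratio = dr,
                 parent_daughter_ratio = pdr)
}

# Rall exponent: n with dp^n = d1^n + d2^n, bisection on [0, 5]
rall_power_one <- function(dp, d1, d2, tol = 1e-9) {
  if (dp <= 0 || d1 <= 0 || d2 <= 0) return(NA_real_)
  f <- function(n) (d1 / dp)^n + (d2 / dp)^n - 1
  lo <- 0; hi <- 5
  if (f(lo) <= 0 || f(hi) >= 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# mean over defined values; value 0 + undefined flag when none
summ <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) list(value = 0, defined = FALSE)
  else list(value = mean(v), defined = TRUE)
}

#' Names of the 43 morphometrics
#'
#' The fixed registry order of the 43 L-Measure-style morphometrics computed
#' by [compute_feature_vector()].
#'
#' @return A character vector of length 43.
#' @export
morphometric_names <- function() {
  c("Soma_Surface", "N_stems", "N_bifs", "N_branch", "N_tips",
    "Width", "Height", "Depth", "Type", "Diameter", "Diameter_pow",
    "Length", "Surface", "SectionArea", "Volume", "EucDistance",
    "PathDistance", "Branch_Order", "Terminal_degree", "TerminalSegment",
    "Taper_1", "Taper_2", "Branch_pathlength", "Contraction",
    "Fragmentation", "Daughter_Ratio", "Parent_Daughter_Ratio",
    "Partition_asymmetry", "Rall_Power", "Pk", "Pk_classic", "Pk_2",
    "Bif_ampl_local", "Bif_ampl_remote", "Bif_tilt_local",
    "Bif_tilt_remote", "Bif_torque_local", "Bif_torque_remote",
    "Last_parent_diam", "Diam_threshold", "Hillman_threshold",
    "Helix", "Fractal_Dim")
}

# length dimension (power of the length unit) of each metric, used by the
# scaling-property tests; extent metrics are only translation invariant
morphometric_dims <- function() {
  setNames(
    c(2, 0, 0, 0, 0,
      1, 1, 1, 0, 1, 1.5,
      1, 2, 2, 3, 1,
      1, 0, 0, 0,
      0, 0, 1, 0,
      0, 0, 0,
      0, 0, 0, 0, 0,
      0, 0, 0, 0, 0, 0,
      1, 1, 1,
      0, 0),
    morphometric_names()
  )
}

morphometric_extent <- function() {
  nm <- morphometric_names()
  setNames(nm %in% c("Width", "Height", "Depth"), nm)
}

#' Compute the 43-metric morphometric vector
#'
#' Reduces a reconstruction to one scalar per registry metric: counts and
#' extents as totals (or the maximum for `Branch_Order`), per-node and
#' per-branch quantities as means over their defined elements. Metrics that
#' are undefined on a degenerate tree (e.g. angle metrics without a
#' bifurcation) are emitted as 0 and flagged in the `mask` attribute so the
#' vector is always finite.
#'
#' @param tree A [neuron_tree()].
#' @return A named numeric vector of length 43 (class
#'   `morphometric_vector`) with a logical `mask` attribute that is `TRUE`
#'   where the metric was undefined and substituted with 0.
#' @export
compute_feature_vector <- function(tree) {
  validate_neuron_tree(tree)
  nd <- tree$nodes
  kids <- tree_children(tree)
  deg <- lengths(kids)
  root <- tree_root(tree)
  xyz <- tree_coords(tree)
  ed <- tree_edges(tree)
  br <- decompose_branches(tree)
  cnt <- tree_counts(tree)
  bifs <- bifurcation_nodes(tree)

  res <- list()
  put <- function(name, value, defined = TRUE) {
    res[[name]] <<- list(value = value, defined = defined)
  }
  puts <- function(name, values) {
    s <- summ(values)
    res[[name]] <<- s
  }

  put("Soma_Surface", 4 * pi * nd$radius[root]^2)
  put("N_stems", cnt$n_stems)
  put("N_bifs", cnt$n_bifurcations)
  put("N_branch", nrow(br))
  put("N_tips", cnt$n_tips)
  put("Width", diff(range(nd$x)))
  put("Height", diff(range(nd$y)))
  put("Depth", diff(range(nd$z)))
  puts("Type", if (nrow(nd) > 1) nd$type[-root] else numeric())
  puts("Diameter", 2 * ed$r_child)
  puts("Diameter_pow", (2 * ed$r_child)^1.5)
  put("Length", sum(ed$len))
  put("Surface", sum(2 * pi * ed$r_child * ed$len))
  puts("SectionArea", pi * ed$r_child^2)
  put("Volume", sum(pi * ed$r_child^2 * ed$len))
  eu <- sqrt(rowSums(sweep(xyz, 2, xyz[root, ])^2))
  puts("EucDistance", if (nrow(nd) > 1) eu[-root] else numeric())
  pd <- node_path_distance(tree)
  puts("PathDistance", if (nrow(nd) > 1) pd[-root] else numeric())
  if (nrow(br) > 0) put("Branch_Order", max(br$order))
  else put("Branch_Order", 0, defined = FALSE)
  tips <- subtree_tips(tree)
  puts("Terminal_degree", if (nrow(nd) > 1) tips[-root] else numeric())
  term <- purrr::map_lgl(br$nodes, function(p) deg[p[length(p)]] == 0)
  put("TerminalSegment", sum(term))

  # branch taper and geometry
  d_first <- purrr::map_dbl(br$nodes, ~ 2 * nd$radius[.x[1]])
  d_last <- purrr::map_dbl(br$nodes, ~ 2 * nd$radius[.x[length(.x)]])
  plen <- purrr::map_dbl(br$nodes, function(p) {
    sum(sqrt(rowSums(diff(xyz[p, , drop = FALSE])^2)))
  })
  puts("Taper_1", ifelse(plen > 0, (d_first - d_last) / plen, NA_real_))
  puts("Taper_2", ifelse(d_first > 0, (d_first - d_last) / d_first,
                         NA_real_))
  puts("Branch_pathlength", plen)
  ctr <- metric_contraction(tree)
  puts("Contraction", ifelse(ctr$defined, ctr$contraction, NA_real_))
  put("Fragmentation", nrow(ed))

  rat <- metric_diameter_ratios(tree)
  puts("Daughter_Ratio", rat$daughter_ratio)
  puts("Parent_Daughter_Ratio", rat$parent_daughter_ratio)
  pa <- metric_partition_asymmetry(tree)
  puts("Partition_asymmetry", pa$asymmetry)

  rall <- purrr::map_dbl(bifs, function(b) {
    d <- 2 * nd$radius[kids[[b]][1:2]]
    rall_power_one(2 * nd$radius[b], d[1], d[2])
  })
  puts("Rall_Power", rall)
  n_bar <- if (any(is.finite(rall))) mean(rall[is.finite(rall)]) else NA
  pk_at <- function(n) {
    purrr::map_dbl(bifs, function(b) {
      d <- 2 * nd$radius[kids[[b]][1:2]]
      dp <- 2 * nd$radius[b]
      if (dp <= 0 || !is.finite(n)) NA_real_
      else (d[1] / dp)^n + (d[2] / dp)^n
    })
  }
  puts("Pk", pk_at(n_bar))
  puts("Pk_classic", pk_at(1.5))
  puts("Pk_2", pk_at(2))

  amp_l <- metric_bifurcation_angle(tree, "local")
  amp_r <- metric_bifurcation_angle(tree, "remote")
  puts("Bif_ampl_local", ifelse(amp_l$defined, amp_l$angle, NA_real_))
  puts("Bif_ampl_remote", ifelse(amp_r$defined, amp_r$angle, NA_real_))

  # tilt: smaller angle between the extended parent direction and the two
  # daughters; remote mode uses branch anchors/endpoints for the directions
  anchor_of <- anchor_map(tree, br)
  tilt <- function(remote) {
    purrr::map_dbl(bifs, function(b) {
      pa_node <- if (remote) anchor_of[b] else nd$parent[b]
      if (pa_node == 0L) return(NA_real_)
      u <- unit_dir(xyz, pa_node, b)
      c1 <- kids[[b]][1]; c2 <- kids[[b]][2]
      if (remote) {
        c1 <- branch_endpoint(kids, deg, c1)
        c2 <- branch_endpoint(kids, deg, c2)
      }
      v1 <- unit_dir(xyz, b, c1); v2 <- unit_dir(xyz, b, c2)
      if (is.null(u) || is.null(v1) || is.null(v2)) return(NA_real_)
      min(angle_deg(u, v1), angle_deg(u, v2))
    })
  }
  puts("Bif_tilt_local", tilt(FALSE))
  puts("Bif_tilt_remote", tilt(TRUE))

  # torque: angle between the daughter plane of a bifurcation and the
  # daughter plane of its nearest ancestor bifurcation
  torque <- function(remote) {
    normal_at <- function(b) {
      c1 <- kids[[b]][1]; c2 <- kids[[b]][2]
      if (remote) {
        c1 <- branch_endpoint(kids, deg, c1)
        c2 <- branch_endpoint(kids, deg, c2)
      }
      v1 <- unit_dir(xyz, b, c1); v2 <- unit_dir(xyz, b, c2)
      if (is.null(v1) || is.null(v2)) return(NULL)
      n <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
      nn <- sqrt(sum(n^2))
      if (nn <= 1e-12) return(NULL)
      n / nn
    }
    purrr::map_dbl(bifs, function(b) {
      a <- ancestor_bifurcation(tree, kids, b)
      if (is.na(a)) return(NA_real_)
      n1 <- normal_at(b); n2 <- normal_at(a)
      if (is.null(n1) || is.null(n2)) return(NA_real_)
      acos(max(-1, min(1, abs(sum(n1 * n2))))) * 180 / pi
    })
  }
  puts("Bif_torque_local", torque(FALSE))
  puts("Bif_torque_remote", torque(TRUE))

  puts("Last_parent_diam",
       purrr::map_dbl(br$nodes[term], ~ 2 * nd$radius[.x[1]]))
  puts("Diam_threshold",
       purrr::map_dbl(br$nodes[term], ~ 2 * nd$radius[.x[2]]))

  hill <- purrr::map_dbl(bifs, function(b) {
    ends <- purrr::map_int(kids[[b]][1:2], function(c1) {
      branch_endpoint(kids, deg, c1)
    })
    if (!all(deg[ends] == 0)) return(NA_real_)
    d <- 2 * nd$radius[kids[[b]][1:2]]
    0.5 * 2 * nd$radius[b] + 0.25 * sum(d)
  })
  puts("Hillman_threshold", hill)

  puts("Helix", helix_values(tree, kids, xyz))
  fd <- fractal_dimension(tree)
  put("Fractal_Dim", if (is.na(fd)) 0 else fd, defined = !is.na(fd))

  nm <- morphometric_names()
  values <- purrr::map_dbl(nm, ~ res[[.x]]$value)
  mask <- purrr::map_lgl(nm, ~ !res[[.x]]$defined)
  structure(setNames(values, nm), mask = setNames(mask, nm),
            class = "morphometric_vector")
}

# map each node to the anchor of the branch it terminates (bif nodes only)
anchor_map <- function(tree, br) {
  out <- rep(0L, nrow(tree$nodes))
  for (p in br$nodes) out[p[length(p)]] <- p[1]
  out
}

ancestor_bifurcation <- function(tree, kids, b) {
  parent <- tree$nodes$parent
  deg <- lengths(kids)
  root <- tree_root(tree)
  j <- parent[b]
  while (j != 0L) {
    if (deg[j] >= 2 && j != root) return(j)
    j <- parent[j]
  }
  NA_integer_
}

# normalized triple product over consecutive 4-node windows along
# root-to-tip paths
helix_values <- function(tree, kids, xyz) {
  parent <- tree$nodes$parent
  out <- numeric(0)
  for (i in which(parent != 0L)) {
    p1 <- parent[i]
    p2 <- parent[p1]
    if (p2 == 0L || p1 == 0L) next
    p3 <- parent[p2]
    if (p3 == 0L) next
    v1 <- xyz[p2, ] - xyz[p3, ]
    v2 <- xyz[p1, ] - xyz[p2, ]
    v3 <- xyz[i, ] - xyz[p1, ]
    nn <- sqrt(sum(v1^2)) * sqrt(sum(v2^2)) * sqrt(sum(v3^2))
    if (nn <= 0) next
    tp <- v1[1] * (v2[2] * v3[3] - v2[3] * v3[2]) -
      v1[2] * (v2[1] * v3[3] - v2[3] * v3[1]) +
      v1[3] * (v2[1] * v3[2] - v2[2] * v3[1])
    out <- c(out, tp / nn)
  }
  out
}

# box-count dimension over dyadic scales on PCA-aligned coordinates (the
# alignment makes the estimate invariant to rigid motions of the input)
fractal_dimension <- function(tree, n_scales = 5) {
  xyz <- tree_coords(tree)
  if (nrow(xyz) < 4) return(NA_real_)
  xyz <- pca_align_coords(xyz)
  ext <- max(apply(xyz, 2, function(v) diff(range(v))))
  if (ext <= 0) return(NA_real_)
  mins <- apply(xyz, 2, min)
  counts <- integer(n_scales)
  for (k in seq_len(n_scales)) {
    s <- ext / 2^k
    ix <- floor(sweep(xyz, 2, mins) / s + 1e-9)
    counts[k] <- nrow(unique(ix))
  }
  ls <- log(2^seq_len(n_scales))
  ln <- log(counts)
  sum((ls - mean(ls)) * (ln - mean(ln))) / sum((ls - mean(ls))^2)
}

#' @export
print.morphometric_vector <- function(x, ...) {
  cat("<morphometric_vector> 43 metrics;",
      sum(attr(x, "mask")), "undefined (set to 0)\n")
  print(unclass(setNames(as.numeric(x), names(x))))
  invisible(x)
}

#' Morphometric feature table for a set of neurons
#'
#' Applies [compute_feature_vector()] to each tree and assembles a tibble
#' with one row per neuron and one column per metric, plus `name` and
#' `label` columns.
#'
#' @param trees A list of [neuron_tree()] objects, or a tibble with a
#'   `tree` list column (as returned by [generate_dataset()]).
#' @param labels Optional vector of class labels; defaults to each tree's
#'   `class_label`.
#' @return A tibble with columns `name`, `label`, and the 43 metrics.
#' @export
compute_features <- function(trees, labels = NULL) {
  if (is.data.frame(trees)) {
    if (is.null(labels) && "label" %in% names(trees)) labels <- trees$label
    trees <- trees$tree
  }
  vecs <- purrr::map(trees, compute_feature_vector)
  mat <- do.call(rbind, purrr::map(vecs, as.numeric))
  colnames(mat) <- morphometric_names()
  out <- tibble::as_tibble(mat)
  nm <- purrr::map_chr(trees, ~ .x$name %||% "neuron")
  lab <- if (!is.null(labels)) as.character(labels) else {
    purrr::map_chr(trees, ~ .x$class_label %||% NA_character_)
  }
  dplyr::bind_cols(tibble::tibble(name = nm, label = lab), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
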