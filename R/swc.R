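# SWC reconstructions as rooted trees.
#
# A neuron_tree keeps its nodes in a tibble with contiguous internal ids
# (1..n, parent 0 for the root); the ids found in the source file are kept
# in the `orig_id` column so provenance is never lost.

#' Construct a neuron tree
#'
#' A `neuron_tree` is a rooted tree of 3D sample points with radii and SWC
#' type codes. Node ids are remapped to contiguous 1-based integers; the
#' original ids are preserved in the `orig_id` column.
#'
#' @param nodes A data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (SWC column order). `parent = -1` marks the root.
#' @param name Text label for the reconstruction.
#' @param class_label Optional neuron-type label.
#' @param repair_soma If `TRUE`, extra root rows of type 1 (soma contour
#'   points, a common dialect) are attached to the first soma root instead
#'   of raising an error.
#'
#' @return An object of class `neuron_tree`: a list with a `nodes` tibble
#'   (`id`, `type`, `x`, `y`, `z`, `radius`, `parent`, `orig_id`; `parent`
#'   is 0 for the root), `name`, and `class_label`.
#' @export
#' @examples
#' nodes <- data.frame(id = 1:3, type = c(1, 3, 3), x = 0, y = 0,
#'                     z = c(0, 1, 2), radius = c(1, .5, .5),
#'                     parent = c(-1, 1, 2))
#' neuron_tree(nodes, name = "chain")
neuron_tree <- function(nodes, name = "neuron", class_label = NULL,
                        repair_soma = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes))) {
    abort(paste0("`nodes` must have columns ", paste(req, collapse = ", ")),
          class = c("neurofuse_format_error", "neurofuse_error"))
  }
  nodes <- nodes[req]
  if (nrow(nodes) == 0) {
    abort("a neuron tree must contain at least one node",
          class = c("neurofuse_format_error", "neurofuse_error"))
  }
  for (col in req) {
    if (!is.numeric(nodes[[col]])) {
      abort(sprintf("column `%s` is not numeric", col),
            class = c("neurofuse_parse_error", "neurofuse_error"))
    }
  }
  if (anyNA(nodes) || !all(is.finite(as.matrix(nodes)))) {
    abort("non-finite or missing values in node table",
          class = c("neurofuse_parse_error", "neurofuse_error"))
  }
  if (anyDuplicated(nodes$id)) {
    abort("duplicate node ids", class = c("neurofuse_format_error", "neurofuse_error"))
  }
  if (any(nodes$radius < 0)) {
    abort("negative radius", class = c("neurofuse_format_error", "neurofuse_error"))
  }
  if (any(nodes$type < 0 | nodes$type > 7)) {
    abort("SWC type codes must lie in [0, 7]",
          class = c("neurofuse_format_error", "neurofuse_error"))
  }

  root_rows <- which(nodes$parent == -1)
  if (length(root_rows) == 0) {
    abort("no root node (parent = -1)", class = c("neurofuse_structure_error", "neurofuse_error"))
  }
  if (length(root_rows) > 1) {
    extra <- root_rows[-1]
    if (repair_soma && all(nodes$type[extra] == 1) &&
        nodes$type[root_rows[1]] == 1) {
      # soma-contour dialect: re-attach extra soma roots to the first soma
      nodes$parent[extra] <- nodes$id[root_rows[1]]
    } else {
      abort("more than one root node", class = c("neurofuse_structure_error", "neurofuse_error"))
    }
  }

  # remap ids to 1..n in file order
  idx <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1 & is.na(idx))
  if (length(bad) > 0) {
    abort(sprintf("parent id %s refers to no node", nodes$parent[bad[1]]),
          class = c("neurofuse_structure_error", "neurofuse_error"))
  }
  parent <- ifelse(nodes$parent == -1, 0L, idx)

  out <- tibble::tibble(
    id = seq_len(nrow(nodes)),
    type = as.integer(nodes$type),
    x = as.double(nodes$x), y = as.double(nodes$y), z = as.double(nodes$z),
    radius = as.double(nodes$radius),
    parent = as.integer(parent),
    orig_id = as.integer(nodes$id)
  )

  tree <- structure(
    list(nodes = out, name = name, class_label = class_label),
    class = "neuron_tree"
  )
  check_connected(tree)
  tree
}

# every node must reach the root through parent links (no cycles, one tree)
check_connected <- function(tree) {
  parent <- tree$nodes$parent
  n <- length(parent)
  depth <- rep(NA_integer_, n)
  root <- which(parent == 0L)
  depth[root] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    chain <- i
    j <- i
    repeat {
      j <- parent[j]
      if (j == 0L) break
      if (!is.na(depth[j])) break
      if (j %in% chain) {
        abort("cycle detected in parent links",
              class = c("neurofuse_structure_error", "neurofuse_error"))
      }
      chain <- c(chain, j)
    }
    base <- if (j == 0L) 0L else depth[j]
    depth[rev(chain)] <- base + seq_along(chain)
  }
  invisible(tree)
}

#' Validate a neuron tree
#'
#' Re-checks every structural invariant (single root, unique ids, acyclic
#' connectivity, finite coordinates, non-negative radii). Errors with a
#' classed condition on the first violation.
#'
#' @param tree A [neuron_tree()].
#' @return `tree`, invisibly.
#' @export
validate_neuron_tree <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  nd <- tree$nodes
  if (nrow(nd) == 0) abort("empty tree", class = c("neurofuse_format_error", "neurofuse_error"))
  if (anyDuplicated(nd$id)) {
    abort("duplicate node ids", class = c("neurofuse_format_error", "neurofuse_error"))
  }
  if (sum(nd$parent == 0L) != 1L) {
    abort("tree must have exactly one root",
          class = c("neurofuse_structure_error", "neurofuse_error"))
  }
  if (any(nd$parent != 0L & !(nd$parent %in% nd$id))) {
    abort("dangling parent reference", class = c("neurofuse_structure_error", "neurofuse_error"))
  }
  if (any(nd$radius < 0) || !all(is.finite(as.matrix(nd[c("x", "y", "z")])))) {
    abort("invalid geometry", class = c("neurofuse_format_error", "neurofuse_error"))
  }
  check_connected(tree)
  invisible(tree)
}

#' Read an SWC reconstruction
#'
#' Parses the standard 7-column whitespace SWC format (`id type x y z radius
#' parent`), ignoring `#` comment lines and blank lines. Non-contiguous and
#' unordered ids are accepted and remapped internally. Extra roots of type 1
#' (soma contours) are attached to the first soma node; any other multi-root
#' file is rejected.
#'
#' @param file Path to an SWC file, or a character vector of lines.
#' @param name Label for the tree; defaults to the file name.
#' @param class_label Optional neuron-type label to attach.
#' @return A [neuron_tree()].
#' @export
read_swc <- function(file, name = NULL, class_label = NULL) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(name)) name <- sub("\\.swc$", "", basename(file))
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    if (is.null(name)) name <- "neuron"
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    abort("no data rows in SWC source", class = c("neurofuse_format_error", "neurofuse_error"))
  }
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7)) {
    abort(sprintf("line %d does not have 7 columns", which(nf != 7)[1]),
          class = c("neurofuse_parse_error", "neurofuse_error"))
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  )
  if (anyNA(m)) {
    abort("non-numeric field in SWC source", class = c("neurofuse_parse_error", "neurofuse_error"))
  }
  nodes <- tibble::tibble(
    id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4], z = m[, 5],
    radius = m[, 6], parent = m[, 7]
  )
  neuron_tree(nodes, name = name, class_label = class_label)
}

#' Write a neuron tree as SWC
#'
#' Emits contiguous 1-based ids with consistently renumbered parents.
#' Coordinates and radii are rendered with enough significant digits that
#' `read_swc(write_swc(tree))` reproduces them exactly.
#'
#' @param tree A [neuron_tree()].
#' @param file Path to write to, or `NULL` to return the lines.
#' @return Invisibly, the number of node rows written (the lines themselves
#'   when `file` is `NULL`).
#' @export
write_swc <- function(tree, file = NULL) {
  validate_neuron_tree(tree)
  nd <- tree$nodes
  num <- function(v) {
    out <- formatC(v, digits = 17, format = "g", flag = "-")
    trimws(out)
  }
  rows <- paste(nd$id, nd$type, num(nd$x), num(nd$y), num(nd$z),
                num(nd$radius), ifelse(nd$parent == 0L, -1L, nd$parent))
  out <- c(sprintf("# %s", tree$name), rows)
  if (is.null(file)) return(invisible(out))
  writeLines(out, file)
  invisible(length(rows))
}

# adjacency: list of integer child vectors per node
tree_children <- function(tree) {
  nd <- tree$nodes
  kids <- vector("list", nrow(nd))
  nz <- which(nd$parent != 0L)
  sp <- split(nd$id[nz], nd$parent[nz])
  kids[as.integer(names(sp))] <- sp
  kids
}

tree_root <- function(tree) which(tree$nodes$parent == 0L)

tree_coords <- function(tree) {
  as.matrix(tree$nodes[c("x", "y", "z")])
}

#' Count tips, bifurcations, and stems
#'
#' Topological counts of a reconstruction: tips are non-root nodes without
#' children (a lone root counts as one tip), bifurcations are non-root nodes
#' with two or more children, stems are the root's children.
#'
#' @param tree A [neuron_tree()].
#' @return A named list with `n_nodes`, `n_tips`, `n_bifurcations`, `n_stems`.
#' @export
tree_counts <- function(tree) {
  kids <- tree_children(tree)
  deg <- lengths(kids)
  root <- tree_root(tree)
  tips <- sum(deg == 0 & seq_along(deg) != root)
  if (nrow(tree$nodes) == 1) tips <- 1L
  list(
    n_nodes = nrow(tree$nodes),
    n_tips = as.integer(tips),
    n_bifurcations = as.integer(sum(deg[-root] >= 2)),
    n_stems = as.integer(deg[root])
  )
}

#' @export
print.neuron_tree <- function(x, ...) {
  cnt <- tree_counts(x)
  cat(sprintf(
    "<neuron_tree> %s%s: %d nodes, %d stems, %d bifurcations, %d tips\n",
    x$name,
    if (!is.null(x$class_label)) paste0(" [", x$class_label, "]") else "",
    cnt$n_nodes, cnt$n_stems, cnt$n_bifurcations, cnt$n_tips
  ))
  invisible(x)
}

#' @export
format.neuron_tree <- function(x, ...) {
  sprintf("<neuron_tree: %s, %d nodes>", x$name, nrow(x$nodes))
}
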