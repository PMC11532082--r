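# Synthetic neuron morphologies with class-dependent branching statistics.
#
# Growth model: stems leave the soma in random directions and elongate in
# fixed-length-ish steps with per-step angular jitter (cone sampling around
# the current direction). After every step the branch bifurcates with a
# Bernoulli probability; daughters separate by a sampled bifurcation angle
# and diameters taper at each bifurcation. Depth, per-branch step count and
# a global node budget bound the tree. Rich enough to exercise every
# registry metric (angles, taper, contraction, asymmetry all non-trivial).

#' Parameters of one synthetic morphology class
#'
#' @param label Class label.
#' @param n_stems Number of stems leaving the soma.
#' @param bifurcation_prob Probability of bifurcating after each segment.
#' @param segment_length_mean,segment_length_sd Segment length distribution
#'   (micrometers; truncated at a small positive floor).
#' @param tortuosity Per-step angular jitter scale (radians).
#' @param taper_rate Diameter multiplier applied at each bifurcation, in
#'   `(0, 1]`.
#' @param max_depth Maximum centrifugal branch order.
#' @param max_nodes Global node budget.
#' @param max_branch_steps Steps after which an unbranched run becomes a tip.
#' @param bif_angle_mean,bif_angle_sd Bifurcation amplitude distribution
#'   (degrees).
#' @param soma_radius,initial_radius Soma and stem radii (micrometers).
#' @return A `morpho_class_params` list.
#' @export
morpho_class_params <- function(label,
                                n_stems = 3,
                                bifurcation_prob = 0.25,
                                segment_length_mean = 20,
                                segment_length_sd = 4,
                                tortuosity = 0.25,
                                taper_rate = 0.85,
                                max_depth = 6,
                                max_nodes = 400,
                                max_branch_steps = 8,
                                bif_angle_mean = 60,
                                bif_angle_sd = 10,
                                soma_radius = 6,
                                initial_radius = 1.5) {
  stopifnot(
    n_stems >= 1,
    bifurcation_prob >= 0, bifurcation_prob <= 1,
    segment_length_mean > 0, segment_length_sd >= 0,
    taper_rate > 0, taper_rate <= 1,
    max_depth >= 1, max_nodes >= 2, max_branch_steps >= 1
  )
  structure(
    list(label = label, n_stems = n_stems,
         bifurcation_prob = bifurcation_prob,
         segment_length_mean = segment_length_mean,
         segment_length_sd = segment_length_sd,
         tortuosity = tortuosity, taper_rate = taper_rate,
         max_depth = max_depth, max_nodes = max_nodes,
         max_branch_steps = max_branch_steps,
         bif_angle_mean = bif_angle_mean, bif_angle_sd = bif_angle_sd,
         soma_radius = soma_radius, initial_radius = initial_radius),
    class = "morpho_class_params"
  )
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# unit vector orthogonal to u
rand_orth <- function(u) {
  v <- rnorm(3)
  v <- v - sum(v * u) * u
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(rand_orth(u))
  v / n
}

rotate_towards <- function(u, axis, angle) {
  # rotate u by `angle` in the plane spanned by u and axis (axis orth to u)
  cos(angle) * u + sin(angle) * axis
}

#' Generate one synthetic neuron
#'
#' Deterministic for a fixed `(params, seed)` pair.
#'
#' @param params A [morpho_class_params()].
#' @param seed Integer seed for this neuron's private random stream.
#' @param name Label for the tree.
#' @return A valid [neuron_tree()] with a soma root, binary bifurcations,
#'   positive monotonically tapering radii, and at most `max_nodes` nodes.
#' @export
generate_neuron <- function(params, seed, name = NULL) {
  stopifnot(inherits(params, "morpho_class_params"))
  if (params$max_nodes < 1 + params$n_stems) {
    abort("params cannot produce at least 2 nodes",
          class = c("neurofuse_format_error", "neurofuse_error"))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))

  p <- params
  rows <- list(c(1, 1, 0, 0, 0, p$soma_radius, -1))
  n_nodes <- 1L
  # branch queue entries: parent node id, position, direction, radius, depth
  queue <- list()
  for (s in seq_len(p$n_stems)) {
    queue[[s]] <- list(parent = 1L, pos = c(0, 0, 0), dir = rand_unit(),
                       radius = p$initial_radius, depth = 1L)
  }
  qi <- 1L
  while (qi <= length(queue) && n_nodes < p$max_nodes) {
    b <- queue[[qi]]; qi <- qi + 1L
    pos <- b$pos; dir <- b$dir; radius <- b$radius; parent <- b$parent
    for (step in seq_len(p$max_branch_steps)) {
      if (n_nodes >= p$max_nodes) break
      len <- max(0.1 * p$segment_length_mean,
                 rnorm(1, p$segment_length_mean, p$segment_length_sd))
      jit <- rnorm(3, 0, p$tortuosity)
      dir <- dir + jit
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir * len
      radius <- max(0.05, radius * 0.995)     # slight within-branch taper
      n_nodes <- n_nodes + 1L
      rows[[n_nodes]] <- c(n_nodes, 3, pos, radius, parent)
      parent <- n_nodes
      bifurcate <- step < p$max_branch_steps &&
        runif(1) < p$bifurcation_prob
      if (bifurcate) {
        if (b$depth < p$max_depth && n_nodes + 2 <= p$max_nodes) {
          ang <- abs(rnorm(1, p$bif_angle_mean, p$bif_angle_sd)) * pi / 180
          axis <- rand_orth(dir)
          r_new <- max(0.05, radius * p$taper_rate)
          queue[[length(queue) + 1]] <- list(
            parent = parent, pos = pos,
            dir = rotate_towards(dir, axis, ang / 2),
            radius = r_new, depth = b$depth + 1L
          )
          queue[[length(queue) + 1]] <- list(
            parent = parent, pos = pos,
            dir = rotate_towards(dir, -axis, ang / 2),
            radius = r_new, depth = b$depth + 1L
          )
        }
        break
      }
    }
  }

  m <- do.call(rbind, rows)
  nodes <- tibble::tibble(id = m[, 1], type = m[, 2], x = m[, 3],
                          y = m[, 4], z = m[, 5], radius = m[, 6],
                          parent = m[, 7])
  neuron_tree(nodes, name = name %||% sprintf("%s_seed%d", p$label, seed),
              class_label = p$label)
}

#' Generate a labeled synthetic dataset
#'
#' Balanced classes; each neuron draws from a private random stream derived
#' from `(seed, class, index)` so the dataset is reproducible and
#' order-independent.
#'
#' @param class_params A list of [morpho_class_params()].
#' @param n_per_class Number of neurons per class.
#' @param seed Integer master seed.
#' @return A tibble with columns `name`, `label`, and `tree` (list column
#'   of [neuron_tree()]).
#' @export
generate_dataset <- function(class_params, n_per_class, seed = 1) {
  stopifnot(length(class_params) >= 1, n_per_class >= 1)
  rows <- purrr::map_dfr(seq_along(class_params), function(ci) {
    p <- class_params[[ci]]
    purrr::map_dfr(seq_len(n_per_class), function(i) {
      sub_seed <- (as.double(seed) * 7919 + ci * 104729 + i * 131) %%
        2147483647
      tr <- generate_neuron(p, seed = as.integer(sub_seed),
                            name = sprintf("%s_%03d", p$label, i))
      tibble::tibble(name = tr$name, label = p$label, tree = list(tr))
    })
  })
  rows
}

#' Well-separated default class parameters
#'
#' Three (or more) synthetic classes whose expected total length and
#' bifurcation counts are separated by roughly a factor of two between
#' neighboring classes, so that simple feature thresholds can already
#' distinguish them. These are the study conditions used by the package's
#' desk-scale experiments.
#'
#' @param n_classes Number of classes (2-4).
#' @return A list of [morpho_class_params()].
#' @export
default_class_params <- function(n_classes = 3) {
  stopifnot(n_classes >= 2, n_classes <= 4)
  base <- list(
    morpho_class_params("sparse", n_stems = 2, bifurcation_prob = 0.10,
                        segment_length_mean = 12, max_depth = 4,
                        taper_rate = 0.92),
    morpho_class_params("medium", n_stems = 3, bifurcation_prob = 0.22,
                        segment_length_mean = 24, max_depth = 6,
                        taper_rate = 0.85),
    morpho_class_params("dense", n_stems = 5, bifurcation_prob = 0.45,
                        segment_length_mean = 48, max_depth = 8,
                        taper_rate = 0.75),
    morpho_class_params("giant", n_stems = 6, bifurcation_prob = 0.60,
                        segment_length_mean = 90, max_depth = 9,
                        taper_rate = 0.70)
  )
  base[seq_len(n_classes)]
}
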