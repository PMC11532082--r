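test_that("decompose_branches handles elementary topologies", {
  chain <- chain_tree(cbind(0, 0, 0:2))
  br <- decompose_branches(chain)
  expect_equal(nrow(br), 1)
  expect_equal(br$order, 1L)
  expect_equal(br$nodes[[1]], 1:3)

  bt <- bif_tree()
  br <- decompose_branches(bt)
  expect_equal(nrow(br), 3)
  expect_equal(sort(br$order), c(1L, 2L, 2L))
})

test_that("branch count matches the recursive-traversal oracle", {
  for (s in 1:6) {
    tr <- random_binary_tree(50, seed = s)
    br <- decompose_branches(tr)
    ob <- o_branches(tr)
    expect_equal(nrow(br), length(ob))
    cnt <- tree_counts(tr)
    # binary trees: one branch per stem plus two per bifurcation
    expect_equal(nrow(br), cnt$n_stems + 2 * cnt$n_bifurcations)
    # every non-soma node appears in at least one branch; interior/end
    # nodes exactly once
    non_anchor <- unlist(lapply(br$nodes, function(p) p[-1]))
    expect_equal(sort(non_anchor), setdiff(seq_len(nrow(tr$nodes)), 1L))
  }
})

test_that("total length follows the edge-sum oracle and edge cases", {
  chain <- chain_tree(cbind(0, 0, c(0, 1, 3)))
  expect_equal(metric_total_length(chain), 3.0)
  single <- neuron_tree(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                                   radius = 1, parent = -1))
  expect_equal(metric_total_length(single), 0.0)
  for (s in 1:5) {
    tr <- random_binary_tree(60, seed = s + 10)
    nd <- tr$nodes
    naive <- 0
    for (i in seq_len(nrow(nd))) {
      p <- nd$parent[i]
      if (p != 0) {
        naive <- naive + sqrt((nd$x[i] - nd$x[p])^2 +
                              (nd$y[i] - nd$y[p])^2 +
                              (nd$z[i] - nd$z[p])^2)
      }
    }
    expect_equal(metric_total_length(tr), naive, tolerance = 1e-9)
  }
})

test_that("contraction closed forms hold", {
  straight <- chain_tree(cbind(0, 0, c(0, 1, 2, 3.5)))
  expect_equal(metric_contraction(straight)$contraction, 1.0)
  elbow <- chain_tree(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(metric_contraction(elbow)$contraction, sqrt(2) / 2)
})

test_that("partition asymmetry closed forms hold", {
  bt <- bif_tree()                       # (1,1) tips
  expect_equal(metric_partition_asymmetry(bt)$asymmetry, 0)
  # (3,1) tips: extend one daughter with two further bifurcations
  nodes <- data.frame(
    id = 1:8, type = c(1, rep(3, 7)),
    x = c(0, 0, -1, 1, 2, 2, 3, 3),
    y = c(0, 0, 1, 1, 2, 0, 3, 1),
    z = 0, radius = c(1, rep(.5, 7)),
    parent = c(-1, 1, 2, 2, 4, 4, 5, 5)
  )
  tr <- neuron_tree(nodes)
  pa <- metric_partition_asymmetry(tr)
  top <- pa$asymmetry[pa$node == 2]
  expect_equal(top, 1.0)                  # |3 - 1| / (3 + 1 - 2)
})

test_that("bifurcation angles match closed forms and the dot oracle", {
  ortho <- bif_tree(d1 = c(1, 0, 0), d2 = c(0, 1, 0))
  expect_equal(metric_bifurcation_angle(ortho, "local")$angle, 90)
  opp <- bif_tree(d1 = c(1, 0, 0), d2 = c(-1, 0, 0))
  expect_equal(metric_bifurcation_angle(opp, "local")$angle, 180)
  for (s in 1:4) {
    tr <- random_binary_tree(40, seed = s + 20)
    got <- metric_bifurcation_angle(tr, "remote")
    orc <- oracle_features(tr)
    expect_equal(mean(got$angle[got$defined]),
                 orc$values[["Bif_ampl_remote"]], tolerance = 1e-9)
  }
})

test_that("diameter ratios match the direct formulas", {
  bt <- bif_tree(r_parent = 1, r_d1 = 0.5, r_d2 = 0.5)
  dr <- metric_diameter_ratios(bt)
  expect_equal(dr$daughter_ratio, 1.0)
  expect_equal(dr$parent_daughter_ratio, 0.5)
  bt2 <- bif_tree(r_parent = 1, r_d1 = 1, r_d2 = 0.5)
  expect_equal(metric_diameter_ratios(bt2)$daughter_ratio, 2.0)
})

test_that("feature vector has 43 finite entries in fixed order", {
  tr <- random_binary_tree(45, seed = 99)
  fv <- compute_feature_vector(tr)
  expect_length(fv, 43)
  expect_equal(names(fv), morphometric_names())
  expect_true(all(is.finite(fv)))
  fv2 <- compute_feature_vector(tr)
  expect_identical(as.numeric(fv), as.numeric(fv2))
})

test_that("degenerate chain emits the documented counts and masks", {
  chain <- chain_tree(cbind(0, 0, 0:3))
  fv <- compute_feature_vector(chain)
  expect_equal(unname(fv["N_bifs"]), 0)
  expect_equal(unname(fv["N_tips"]), 1)
  expect_equal(unname(fv["N_stems"]), 1)
  mask <- attr(fv, "mask")
  expect_true(mask[["Bif_ampl_local"]])   # no bifurcation: flagged, 0
  expect_equal(unname(fv["Bif_ampl_local"]), 0)
  expect_true(all(is.finite(fv)))
})

test_that("all 43 metrics agree with the brute-force oracle suite", {
  seeds <- 1:22
  sizes <- rep(c(30, 50, 70), length.out = length(seeds))
  for (i in seq_along(seeds)) {
    tr <- random_binary_tree(sizes[i], seed = 300 + seeds[i])
    fv <- compute_feature_vector(tr)
    orc <- oracle_features(tr)
    expect_equal(attr(fv, "mask"), orc$mask,
                 info = sprintf("mask mismatch, seed %d", seeds[i]))
    defined <- !orc$mask
    expect_equal(as.numeric(fv[defined]),
                 unname(orc$values[defined]),
                 tolerance = 1e-6,
                 info = sprintf("values mismatch, seed %d", seeds[i]))
  }
})

test_that("registry entries equal their standalone metric operations", {
  tr <- random_binary_tree(60, seed = 77)
  fv <- compute_feature_vector(tr)
  expect_equal(unname(fv["Length"]), metric_total_length(tr))
  ctr <- metric_contraction(tr)
  expect_equal(unname(fv["Contraction"]),
               mean(ctr$contraction[ctr$defined]))
  pa <- metric_partition_asymmetry(tr)
  expect_equal(unname(fv["Partition_asymmetry"]), mean(pa$asymmetry))
  ang <- metric_bifurcation_angle(tr, "local")
  expect_equal(unname(fv["Bif_ampl_local"]), mean(ang$angle[ang$defined]))
  dr <- metric_diameter_ratios(tr)
  expect_equal(unname(fv["Daughter_Ratio"]),
               mean(dr$daughter_ratio, na.rm = TRUE))
  cnt <- tree_counts(tr)
  expect_equal(unname(fv["N_bifs"]), cnt$n_bifurcations)
  expect_equal(unname(fv["N_tips"]), cnt$n_tips)
})

test_that("metrics are invariant to rigid motion except the extents", {
  dims <- neurofuse:::morphometric_dims()
  ext <- neurofuse:::morphometric_extent()
  for (s in 1:5) {
    tr <- random_binary_tree(50, seed = 400 + s)
    fv <- compute_feature_vector(tr)
    R <- random_rotation(seed = 500 + s)
    moved <- transform_tree(tr, R = R, shift = c(13, -7, 2))
    fv2 <- compute_feature_vector(moved)
    keep <- !ext[names(fv)]
    expect_equal(as.numeric(fv2[keep]), as.numeric(fv[keep]),
                 tolerance = 1e-6)
    # translation alone leaves even the extents unchanged
    shifted <- transform_tree(tr, shift = c(-3, 11, 5))
    fv3 <- compute_feature_vector(shifted)
    expect_equal(as.numeric(fv3), as.numeric(fv), tolerance = 1e-9)
  }
})

test_that("uniform scaling acts by the metric's length dimension", {
  dims <- neurofuse:::morphometric_dims()
  for (s in 1:3) {
    tr <- random_binary_tree(50, seed = 600 + s)
    fv <- compute_feature_vector(tr)
    sc <- 2.5
    scaled <- transform_tree(tr, scale = sc)
    fv2 <- compute_feature_vector(scaled)
    expected <- as.numeric(fv) * sc^dims[names(fv)]
    expect_equal(as.numeric(fv2), unname(expected), tolerance = 1e-6)
  }
})

test_that("branch path lengths partition the total length", {
  for (s in 1:4) {
    tr <- random_binary_tree(55, seed = 700 + s)
    br <- decompose_branches(tr)
    xyz <- as.matrix(tr$nodes[c("x", "y", "z")])
    plen <- vapply(br$nodes, function(p) {
      sum(sqrt(rowSums(diff(xyz[p, , drop = FALSE])^2)))
    }, numeric(1))
    expect_equal(sum(plen), metric_total_length(tr), tolerance = 1e-9)
  }
})
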