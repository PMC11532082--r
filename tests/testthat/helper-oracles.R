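# Independent brute-force oracles for the morphometric registry, written
# with plain recursion/loops (and prcomp for the PCA step) so they share no
# code path with the package implementation.

o_kids <- function(tree) {
  n <- nrow(tree$nodes)
  kids <- rep(list(integer()), n)
  for (i in seq_len(n)) {
    p <- tree$nodes$parent[i]
    if (p != 0) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

o_root <- function(tree) which(tree$nodes$parent == 0)

o_tipcount <- function(kids, v) {
  if (length(kids[[v]]) == 0) return(1)
  s <- 0
  for (c1 in kids[[v]]) s <- s + o_tipcount(kids, c1)
  s
}

# recursive branch enumeration: list of (path, order)
o_branches <- function(tree) {
  kids <- o_kids(tree)
  root <- o_root(tree)
  out <- list()
  walk <- function(anchor, child, ord) {
    path <- c(anchor, child)
    v <- child
    while (length(kids[[v]]) == 1) {
      v <- kids[[v]][1]
      path <- c(path, v)
    }
    out[[length(out) + 1]] <<- list(path = path, order = ord)
    for (c1 in kids[[v]]) walk(v, c1, ord + 1)
  }
  for (c1 in kids[[root]]) walk(root, c1, 1)
  out
}

o_pathdist <- function(tree, v) {
  d <- 0
  nd <- tree$nodes
  while (nd$parent[v] != 0) {
    p <- nd$parent[v]
    d <- d + sqrt(sum((c(nd$x[v], nd$y[v], nd$z[v]) -
                       c(nd$x[p], nd$y[p], nd$z[p]))^2))
    v <- p
  }
  d
}

o_mean <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) list(value = 0, defined = FALSE)
  else list(value = sum(v) / length(v), defined = TRUE)
}

o_pos <- function(tree, v) {
  c(tree$nodes$x[v], tree$nodes$y[v], tree$nodes$z[v])
}

o_angle <- function(u, v) {
  cu <- u / sqrt(sum(u^2)); cv <- v / sqrt(sum(v^2))
  acos(min(1, max(-1, sum(cu * cv)))) * 180 / pi
}

o_endpoint <- function(kids, v) {
  while (length(kids[[v]]) == 1) v <- kids[[v]][1]
  v
}

o_anc_bif <- function(tree, kids, b) {
  root <- o_root(tree)
  v <- tree$nodes$parent[b]
  while (v != 0) {
    if (v != root && length(kids[[v]]) >= 2) return(v)
    v <- tree$nodes$parent[v]
  }
  NA_integer_
}

o_rall <- function(dp, d1, d2) {
  if (dp <= 0 || d1 <= 0 || d2 <= 0) return(NA_real_)
  f <- function(n) (d1 / dp)^n + (d2 / dp)^n - 1
  if (f(0) <= 0 || f(5) >= 0) return(NA_real_)
  uniroot(f, c(0, 5), tol = 1e-12)$root
}

# PCA alignment replicated with prcomp + the package's sign convention
o_pca_align <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  pc <- prcomp(xc, center = FALSE, scale. = FALSE)
  rot <- xc %*% pc$rotation
  far <- which.max(rowSums(xc^2))
  for (j in 1:3) {
    m3 <- sum(rot[, j]^3)
    flip <- if (abs(m3) > 1e-8 * max(1, sum(rot[, j]^2))^1.5) m3 < 0
            else rot[far, j] < 0
    if (isTRUE(flip)) rot[, j] <- -rot[, j]
  }
  rot
}

o_fractal <- function(tree) {
  xyz <- cbind(tree$nodes$x, tree$nodes$y, tree$nodes$z)
  if (nrow(xyz) < 4) return(list(value = 0, defined = FALSE))
  xyz <- o_pca_align(xyz)
  ext <- 0
  for (j in 1:3) ext <- max(ext, max(xyz[, j]) - min(xyz[, j]))
  if (ext <= 0) return(list(value = 0, defined = FALSE))
  mins <- apply(xyz, 2, min)
  counts <- integer(5)
  for (k in 1:5) {
    s <- ext / 2^k
    keys <- character(nrow(xyz))
    for (i in seq_len(nrow(xyz))) {
      keys[i] <- paste(floor((xyz[i, ] - mins) / s + 1e-9), collapse = "/")
    }
    counts[k] <- length(unique(keys))
  }
  fitd <- lm(log(counts) ~ log(2^(1:5)))
  list(value = unname(coef(fitd)[2]), defined = TRUE)
}

# full 43-metric oracle; returns list(values, mask)
oracle_features <- function(tree) {
  nd <- tree$nodes
  n <- nrow(nd)
  kids <- o_kids(tree)
  root <- o_root(tree)
  brs <- o_branches(tree)
  res <- list()
  put <- function(nm, v, def = TRUE) res[[nm]] <<- list(value = v,
                                                        defined = def)
  putm <- function(nm, vs) res[[nm]] <<- o_mean(vs)

  nonroot <- setdiff(seq_len(n), root)
  elen <- vapply(nonroot, function(i) {
    sqrt(sum((o_pos(tree, i) - o_pos(tree, nd$parent[i]))^2))
  }, numeric(1))
  erad <- nd$radius[nonroot]
  bifs <- nonroot[vapply(nonroot, function(i) length(kids[[i]]) >= 2,
                         logical(1))]

  put("Soma_Surface", 4 * pi * nd$radius[root]^2)
  put("N_stems", length(kids[[root]]))
  put("N_bifs", length(bifs))
  put("N_branch", length(brs))
  n_tips <- sum(vapply(nonroot, function(i) length(kids[[i]]) == 0,
                       logical(1)))
  if (n == 1) n_tips <- 1
  put("N_tips", n_tips)
  put("Width", max(nd$x) - min(nd$x))
  put("Height", max(nd$y) - min(nd$y))
  put("Depth", max(nd$z) - min(nd$z))
  putm("Type", if (n > 1) nd$type[nonroot] else numeric())
  putm("Diameter", 2 * erad)
  putm("Diameter_pow", (2 * erad)^1.5)
  put("Length", sum(elen))
  put("Surface", sum(2 * pi * erad * elen))
  putm("SectionArea", pi * erad^2)
  put("Volume", sum(pi * erad^2 * elen))
  putm("EucDistance", vapply(nonroot, function(i) {
    sqrt(sum((o_pos(tree, i) - o_pos(tree, root))^2))
  }, numeric(1)))
  putm("PathDistance", vapply(nonroot, function(i) o_pathdist(tree, i),
                              numeric(1)))
  if (length(brs) > 0) {
    put("Branch_Order", max(vapply(brs, function(b) b$order, numeric(1))))
  } else put("Branch_Order", 0, FALSE)
  putm("Terminal_degree", vapply(nonroot, function(i) {
    o_tipcount(kids, i)
  }, numeric(1)))
  term <- vapply(brs, function(b) {
    length(kids[[b$path[length(b$path)]]]) == 0
  }, logical(1))
  put("TerminalSegment", sum(term))

  plen <- vapply(brs, function(b) {
    s <- 0
    for (i in seq_len(length(b$path) - 1)) {
      s <- s + sqrt(sum((o_pos(tree, b$path[i + 1]) -
                         o_pos(tree, b$path[i]))^2))
    }
    s
  }, numeric(1))
  d_first <- vapply(brs, function(b) 2 * nd$radius[b$path[1]], numeric(1))
  d_last <- vapply(brs, function(b) {
    2 * nd$radius[b$path[length(b$path)]]
  }, numeric(1))
  putm("Taper_1", ifelse(plen > 0, (d_first - d_last) / plen, NA))
  putm("Taper_2", ifelse(d_first > 0, (d_first - d_last) / d_first, NA))
  putm("Branch_pathlength", plen)
  contr <- vapply(seq_along(brs), function(i) {
    b <- brs[[i]]
    if (plen[i] <= 0) return(NA_real_)
    sqrt(sum((o_pos(tree, b$path[length(b$path)]) -
              o_pos(tree, b$path[1]))^2)) / plen[i]
  }, numeric(1))
  putm("Contraction", contr)
  put("Fragmentation", length(nonroot))

  dr <- pdr <- pa <- rall <- numeric(0)
  for (b in bifs) {
    d <- 2 * nd$radius[kids[[b]][1:2]]
    dp <- 2 * nd$radius[b]
    dr <- c(dr, if (min(d) > 0) max(d) / min(d) else NA)
    pdr <- c(pdr, if (dp > 0) (d[1] + d[2]) / 2 / dp else NA)
    t1 <- o_tipcount(kids, kids[[b]][1])
    t2 <- o_tipcount(kids, kids[[b]][2])
    pa <- c(pa, if (t1 + t2 > 2) abs(t1 - t2) / (t1 + t2 - 2) else 0)
    rall <- c(rall, o_rall(dp, d[1], d[2]))
  }
  putm("Daughter_Ratio", dr)
  putm("Parent_Daughter_Ratio", pdr)
  putm("Partition_asymmetry", pa)
  putm("Rall_Power", rall)
  nbar <- if (any(is.finite(rall))) mean(rall[is.finite(rall)]) else NA
  pk_of <- function(nn) {
    vapply(bifs, function(b) {
      d <- 2 * nd$radius[kids[[b]][1:2]]
      dp <- 2 * nd$radius[b]
      if (dp <= 0 || !is.finite(nn)) NA_real_
      else (d[1] / dp)^nn + (d[2] / dp)^nn
    }, numeric(1))
  }
  putm("Pk", pk_of(nbar))
  putm("Pk_classic", pk_of(1.5))
  putm("Pk_2", pk_of(2))

  ampl <- function(remote) {
    vapply(bifs, function(b) {
      c1 <- kids[[b]][1]; c2 <- kids[[b]][2]
      if (remote) { c1 <- o_endpoint(kids, c1); c2 <- o_endpoint(kids, c2) }
      v1 <- o_pos(tree, c1) - o_pos(tree, b)
      v2 <- o_pos(tree, c2) - o_pos(tree, b)
      if (sum(v1^2) == 0 || sum(v2^2) == 0) return(NA_real_)
      o_angle(v1, v2)
    }, numeric(1))
  }
  putm("Bif_ampl_local", ampl(FALSE))
  putm("Bif_ampl_remote", ampl(TRUE))

  # branch anchor of each branch-terminating node
  anchor <- rep(0, n)
  for (b in brs) anchor[b$path[length(b$path)]] <- b$path[1]
  tilt <- function(remote) {
    vapply(bifs, function(b) {
      pa_node <- if (remote) anchor[b] else nd$parent[b]
      if (pa_node == 0) return(NA_real_)
      u <- o_pos(tree, b) - o_pos(tree, pa_node)
      if (sum(u^2) == 0) return(NA_real_)
      c1 <- kids[[b]][1]; c2 <- kids[[b]][2]
      if (remote) { c1 <- o_endpoint(kids, c1); c2 <- o_endpoint(kids, c2) }
      v1 <- o_pos(tree, c1) - o_pos(tree, b)
      v2 <- o_pos(tree, c2) - o_pos(tree, b)
      if (sum(v1^2) == 0 || sum(v2^2) == 0) return(NA_real_)
      min(o_angle(u, v1), o_angle(u, v2))
    }, numeric(1))
  }
  putm("Bif_tilt_local", tilt(FALSE))
  putm("Bif_tilt_remote", tilt(TRUE))

  o_cross <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  torq <- function(remote) {
    normal <- function(b) {
      c1 <- kids[[b]][1]; c2 <- kids[[b]][2]
      if (remote) { c1 <- o_endpoint(kids, c1); c2 <- o_endpoint(kids, c2) }
      v1 <- o_pos(tree, c1) - o_pos(tree, b)
      v2 <- o_pos(tree, c2) - o_pos(tree, b)
      if (sum(v1^2) == 0 || sum(v2^2) == 0) return(NULL)
      nn <- o_cross(v1 / sqrt(sum(v1^2)), v2 / sqrt(sum(v2^2)))
      if (sqrt(sum(nn^2)) <= 1e-12) return(NULL)
      nn / sqrt(sum(nn^2))
    }
    vapply(bifs, function(b) {
      a <- o_anc_bif(tree, kids, b)
      if (is.na(a)) return(NA_real_)
      n1 <- normal(b); n2 <- normal(a)
      if (is.null(n1) || is.null(n2)) return(NA_real_)
      acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
    }, numeric(1))
  }
  putm("Bif_torque_local", torq(FALSE))
  putm("Bif_torque_remote", torq(TRUE))

  putm("Last_parent_diam", vapply(brs[term], function(b) {
    2 * nd$radius[b$path[1]]
  }, numeric(1)))
  putm("Diam_threshold", vapply(brs[term], function(b) {
    2 * nd$radius[b$path[2]]
  }, numeric(1)))

  hill <- vapply(bifs, function(b) {
    e1 <- o_endpoint(kids, kids[[b]][1])
    e2 <- o_endpoint(kids, kids[[b]][2])
    if (length(kids[[e1]]) > 0 || length(kids[[e2]]) > 0) return(NA_real_)
    d <- 2 * nd$radius[kids[[b]][1:2]]
    0.5 * 2 * nd$radius[b] + 0.25 * (d[1] + d[2])
  }, numeric(1))
  putm("Hillman_threshold", hill)

  hx <- numeric(0)
  for (i in nonroot) {
    p1 <- nd$parent[i]; if (p1 == 0) next
    p2 <- nd$parent[p1]; if (p2 == 0) next
    p3 <- nd$parent[p2]; if (p3 == 0) next
    v1 <- o_pos(tree, p2) - o_pos(tree, p3)
    v2 <- o_pos(tree, p1) - o_pos(tree, p2)
    v3 <- o_pos(tree, i) - o_pos(tree, p1)
    nn <- sqrt(sum(v1^2)) * sqrt(sum(v2^2)) * sqrt(sum(v3^2))
    if (nn <= 0) next
    hx <- c(hx, sum(o_cross(v1, v2) * v3) / nn)
  }
  putm("Helix", hx)
  res[["Fractal_Dim"]] <- o_fractal(tree)

  nm <- morphometric_names()
  list(values = setNames(vapply(nm, function(x) res[[x]]$value,
                                numeric(1)), nm),
       mask = setNames(vapply(nm, function(x) !res[[x]]$defined,
                              logical(1)), nm))
}

# tiny hand-rolled attention oracle (loops + explicit softmax)
oracle_attention <- function(qvec, kvec, n_tokens) {
  d <- length(qvec) / n_tokens
  Q <- matrix(qvec, n_tokens, d, byrow = TRUE)
  K <- matrix(kvec, n_tokens, d, byrow = TRUE)
  S <- matrix(0, n_tokens, n_tokens)
  for (i in seq_len(n_tokens)) {
    for (j in seq_len(n_tokens)) {
      S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    }
  }
  A <- matrix(0, n_tokens, n_tokens)
  for (i in seq_len(n_tokens)) {
    e <- exp(S[i, ] - max(S[i, ]))
    A[i, ] <- e / sum(e)
  }
  out <- A %*% K
  list(output = as.vector(t(out)), attention = A)
}

# central finite-difference gradient of f at param node p
fd_grad <- function(f, p, eps = 1e-5) {
  v0 <- p$value
  g <- v0 * 0
  for (i in seq_along(v0)) {
    p$value <- v0; p$value[i] <- v0[i] + eps
    fp <- f()
    p$value <- v0; p$value[i] <- v0[i] - eps
    fm <- f()
    g[i] <- (fp - fm) / (2 * eps)
  }
  p$value <- v0
  g
}
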