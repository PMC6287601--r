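# Shared fixture builders. Everything is generated in code; no binary files.

# A non-degenerate random configuration.
random_config <- function(k, sd = 1) {
  matrix(stats::rnorm(2 * k, sd = sd), k, 2)
}

# Noise-free dataset: every specimen has the same symmetric shape plus a
# constant asymmetric offset; replicates are identical. All variation is
# positional asymmetry.
pure_positional_dataset <- function(n = 6, r = 2, delta_scale = 0.05,
                                    map = default_symmetry_map(7)) {
  base <- base_lobe_shape(map$k)
  delta <- asym_direction(map, delta_scale)
  cfg <- base + delta
  coords <- array(rep(cfg, n * r), c(map$k, 2, n * r))
  landmark_dataset(coords,
                   species = rep("sp1", n * r),
                   specimen = rep(sprintf("sp1_i%02d", seq_len(n)), each = r),
                   replicate = rep(seq_len(r), times = n))
}

# A fixed unit direction in the asymmetric tangent subspace of the map
# (orthogonal to the similarity directions, so alignment preserves it).
asym_direction <- function(map, scale = 1) {
  set.seed(4242)
  base <- base_lobe_shape(map$k)
  dirs <- lobesym:::similarity_directions(map, base)
  v <- matrix(stats::rnorm(2 * map$k), 1)
  v <- lobesym:::sim_asym_perturbation(v, map, dirs)
  v <- v / sqrt(sum(v^2))
  lobesym:::unflatten_config(v[1, ]) * scale
}

# Noise-free dataset with delta = 0 and pure symmetric individual variation.
pure_individual_dataset <- function(n = 6, r = 2, dev_scale = 0.05,
                                    map = default_symmetry_map(7)) {
  base <- base_lobe_shape(map$k)
  coords <- array(0, c(map$k, 2, n * r))
  idx <- 0L
  for (i in seq_len(n)) {
    dev <- lobesym:::project_symmetric(rbind(stats::rnorm(2 * map$k,
                                                          sd = dev_scale)), map)
    cfg <- base + lobesym:::unflatten_config(dev[1, ])
    for (j in seq_len(r)) {
      idx <- idx + 1L
      coords[, , idx] <- cfg
    }
  }
  landmark_dataset(coords,
                   species = rep("sp1", n * r),
                   specimen = rep(sprintf("sp1_i%02d", seq_len(n)), each = r),
                   replicate = rep(seq_len(r), times = n))
}

# Brute-force Procrustes distance: minimum over a rotation grid.
grid_procrustes_distance <- function(A, B, step = 0.001) {
  a <- center_scale(A)$config
  b <- center_scale(B)$config
  theta <- seq(0, 2 * pi, by = step)
  vals <- vapply(theta, function(t) {
    R <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
    sum((a %*% R - b)^2)
  }, 0)
  sqrt(min(vals))
}

# Independent numerical minimization of the total squared change for
# squared-change parsimony: optimize internal-node states directly.
optim_scp_q <- function(tree, tip_data, weighted = TRUE) {
  tip_data <- as.matrix(tip_data)
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  D <- ncol(tip_data)
  len <- if (weighted) tree$edge.length else rep(1, nrow(tree$edge))
  qfun <- function(par) {
    states <- rbind(tip_data, matrix(par, nn, D))
    d <- states[tree$edge[, 1], , drop = FALSE] -
         states[tree$edge[, 2], , drop = FALSE]
    sum(d^2 / len)
  }
  init <- matrix(colMeans(tip_data), nn, D, byrow = TRUE)
  fit <- stats::optim(as.numeric(init), qfun, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  fit$value
}

# Lower-triangular Brownian-motion sampler on a tree.
bm_tips <- function(tree, D, rate = 1) {
  C <- phylo_cov(tree)
  U <- chol(C + diag(1e-12, nrow(C)))
  X <- sqrt(rate) * crossprod(U, matrix(stats::rnorm(nrow(C) * D), nrow(C), D))
  rownames(X) <- tree$tip.label
  X
}

# Ordinary (non-phylogenetic) two-block PLS r for the star-tree reduction.
plain_pls_r <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc) / (nrow(X) - 1))
  abs(drop(stats::cor(Xc %*% sv$u[, 1], Yc %*% sv$v[, 1])))
}
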