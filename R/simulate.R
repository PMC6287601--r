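#' Idealized symmetric base shapes
#'
#' Ships the default lobe-like configurations used by the simulator: a
#' 7-landmark arc (three mirror pairs flanking one axis landmark) and a
#' 15-landmark extension (seven pairs and one axis landmark), both exactly
#' symmetric about the axis x = 0 and scaled to unit centroid size.
#'
#' @param k 7 or 15.
#' @return A `k x 2` coordinate matrix.
#' @export
base_lobe_shape <- function(k = 7) {
  if (!k %in% c(7L, 15L)) stop("base shapes exist for k = 7 and k = 15 only")
  theta <- pi * (1 - (seq_len(k) - 1) / (k - 1))
  r <- 1 + 0.15 * cos(4 * theta)
  cfg <- cbind(x = r * cos(theta), y = r * sin(theta))
  ## exact symmetry: average with the mirror image under the default map
  m <- default_symmetry_map(k)
  cfg <- (cfg + reflect_relabel(cfg, m)) / 2
  center_scale(cfg)$config
}

## Orthonormal similarity (nuisance) directions at a centered, unit-size
## symmetric base shape, split by symmetry class: translation along the axis
## (y) and scaling are symmetric; translation across the axis (x) and
## infinitesimal rotation are asymmetric. Perturbations generated for the
## simulator are kept orthogonal to these, so that Procrustes alignment
## leaves the generated effects intact and ground truth is recoverable.
similarity_directions <- function(map, base) {
  k <- map$k
  b <- flatten_config(base)
  x_tr <- c(rep(1, k), rep(0, k)) / sqrt(k)
  y_tr <- c(rep(0, k), rep(1, k)) / sqrt(k)
  rot <- c(-b[(k + 1):(2 * k)], b[1:k])
  rot <- rot / sqrt(sum(rot^2))
  scale_dir <- b / sqrt(sum(b^2))
  list(sym = rbind(y_tr, scale_dir), asym = rbind(x_tr, rot))
}

## Remove the listed (orthonormal) directions from the rows of V.
project_out <- function(V, dirs) {
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    V <- V - outer(drop(V %*% u), u)
  }
  V
}

## Generator-side perturbations: subspace projection plus removal of the
## similarity directions of that subspace.
sim_sym_perturbation <- function(V, map, dirs) {
  project_out(project_symmetric(V, map), dirs$sym)
}
sim_asym_perturbation <- function(V, map, dirs) {
  project_out(project_asymmetric(V, map), dirs$asym)
}

#' Simulation parameters for the multi-species replicated design
#'
#' Bundles the study-design constants and variance components the generator
#' needs. Defaults emulate the sampling design of the motivating study: 19
#' species, 75 individuals per species, 2 digitization replicates, with
#' species-level symmetric shape and positional-asymmetry vectors evolving by
#' Brownian motion on a depth-1 tree. All scale parameters are in Procrustes
#' units of the unit-centroid-size base shape.
#'
#' @param n_species number of species (used when no tree is supplied).
#' @param n_individuals individuals (semicells) per species.
#' @param n_replicates digitizations per individual.
#' @param sigma2_sym Brownian-motion rate of the symmetric species mean,
#'   per coordinate per unit branch length.
#' @param sigma2_asym Brownian-motion rate of the species positional-asymmetry
#'   vector.
#' @param sigma_ind standard deviation of individual symmetric deviations.
#' @param sigma_fa standard deviation of individual asymmetric (fluctuating
#'   asymmetry) deviations.
#' @param sigma_me standard deviation of per-replicate digitization noise on
#'   each coordinate.
#' @param iid_asymmetry draw species asymmetry vectors independently instead
#'   of by Brownian motion (a no-phylogenetic-signal control).
#' @param base_shape symmetric `k x 2` base configuration
#'   (default [base_lobe_shape()] with `k = 7`).
#' @param map [symmetry_map()] for the base shape.
#' @param seed integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_species = 19, n_individuals = 75, n_replicates = 2,
                       sigma2_sym = 0.002, sigma2_asym = 0.002,
                       sigma_ind = 0.02, sigma_fa = 0.01, sigma_me = 0.005,
                       iid_asymmetry = FALSE,
                       base_shape = base_lobe_shape(7),
                       map = default_symmetry_map(nrow(base_shape)),
                       seed = 1) {
  stopifnot(n_species >= 2, n_individuals >= 1, n_replicates >= 1,
            sigma2_sym >= 0, sigma2_asym >= 0, sigma_ind >= 0,
            sigma_fa >= 0, sigma_me >= 0)
  structure(list(n_species = as.integer(n_species),
                 n_individuals = as.integer(n_individuals),
                 n_replicates = as.integer(n_replicates),
                 sigma2_sym = sigma2_sym, sigma2_asym = sigma2_asym,
                 sigma_ind = sigma_ind, sigma_fa = sigma_fa,
                 sigma_me = sigma_me, iid_asymmetry = iid_asymmetry,
                 base_shape = base_shape, map = map, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a pure-birth tree
#'
#' A reproducible Yule (pure-birth) tree with total depth rescaled to 1, used
#' as a stand-in phylogeny for simulation studies.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed.
#' @return A rooted, bifurcating [ape::phylo] tree with `n_species` tips.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  if (n_species < 2L) stop("n_species must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

#' Simulate species-level symmetric means and asymmetry vectors
#'
#' Species symmetric mean shapes and positional-asymmetry vectors evolve as
#' multivariate Brownian motion (independent coordinates) along the tree,
#' with deviations projected onto the symmetric and asymmetric subspaces of
#' the symmetry map so that the generated data satisfy the decomposition
#' assumptions of the object-symmetry analysis exactly by construction. With
#' `iid_asymmetry = TRUE`, asymmetry vectors are drawn independently per
#' species with variance matched to the mean tip depth (no phylogenetic
#' signal).
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param params a [sim_params()] object; its `base_shape` must be symmetric
#'   under `params$map`.
#' @param seed integer seed (defaults to `params$seed`).
#' @return A list of class `species_means_sim` with `species`, `sym_mean`
#'   (`k x 2 x S` symmetric species means), `delta` (`S x 2k` asymmetry
#'   vectors, rows named by species), `tree`, `params`.
#' @export
simulate_species_means <- function(tree, params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  map <- params$map
  base <- params$base_shape
  base_vec <- flatten_config(base)
  asym_norm <- sqrt(sum(project_asymmetric(rbind(base_vec), map)^2))
  if (asym_norm > 1e-12)
    stop("base shape must be symmetric under the map (asymmetric norm ",
         format(asym_norm), ")")
  set.seed(seed)
  C <- phylo_cov(tree)
  S <- nrow(C)
  k2 <- 2 * map$k
  U <- chol(C + diag(1e-12, S))
  bm <- function(rate) {
    Z <- matrix(stats::rnorm(S * k2), S, k2)
    sqrt(rate) * crossprod(U, Z)
  }
  dirs <- similarity_directions(map, base)
  dev_sym <- sim_sym_perturbation(bm(params$sigma2_sym), map, dirs)
  delta <- if (params$iid_asymmetry) {
    Z <- matrix(stats::rnorm(S * k2), S, k2)
    sim_asym_perturbation(sqrt(params$sigma2_asym * mean(diag(C))) * Z, map, dirs)
  } else {
    sim_asym_perturbation(bm(params$sigma2_asym), map, dirs)
  }
  rownames(delta) <- tree$tip.label
  sym_mean <- array(0, c(map$k, 2, S), dimnames = list(NULL, NULL, tree$tip.label))
  ## delta_shape: the population value of the species-asymmetry estimator —
  ## the asymmetric component of the noise-free species mean after its own
  ## symmetric superimposition (center, unit scale, rotation gauge at the
  ## species consensus). delta itself is on the raw coordinate scale of the
  ## base shape; the two differ by deterministic similarity bookkeeping.
  delta_shape <- matrix(0, S, 2 * map$k, dimnames = list(tree$tip.label, NULL))
  for (s in seq_len(S)) {
    sym_mean[, , s] <- base + unflatten_config(dev_sym[s, ])
    m_s <- sym_mean[, , s] + unflatten_config(delta[s, ])
    fit_s <- gpa(list(m_s, reflect_relabel(m_s, map)), principal_axes = FALSE,
                 symmetrize = function(x) (x + reflect_relabel(x, map)) / 2)
    delta_shape[s, ] <- project_asymmetric(
      rbind(flatten_config(fit_s$aligned[, , 1])), map)[1, ]
  }
  structure(list(species = tree$tip.label, sym_mean = sym_mean, delta = delta,
                 delta_shape = delta_shape, tree = tree, params = params),
            class = "species_means_sim")
}

#' Simulate a replicated landmark dataset with known ground truth
#'
#' Each specimen's latent shape is its species symmetric mean, plus a
#' symmetric-projected individual deviation (scale `sigma_ind`), plus the
#' species asymmetry vector, plus an asymmetric-projected fluctuating
#' asymmetry deviation (scale `sigma_fa`). Each digitization replicate adds
#' independent coordinate noise (scale `sigma_me`). The generating components
#' are returned alongside the dataset.
#'
#' @param means a [simulate_species_means()] result.
#' @param params a [sim_params()]; defaults to the one stored in `means`.
#' @param seed integer seed (defaults to `params$seed + 1`).
#' @return A list of class `synthetic_truth` with `dataset`
#'   (a [landmark_dataset()]), `means`, `latent` (`k x 2 x (S*n_ind)` latent
#'   specimen shapes), `params`, `seed`.
#' @export
simulate_dataset <- function(means, params = means$params,
                             seed = params$seed + 1L) {
  stopifnot(inherits(means, "species_means_sim"))
  map <- params$map
  k <- map$k
  S <- length(means$species)
  n_ind <- params$n_individuals
  r <- params$n_replicates
  set.seed(seed)
  dirs <- similarity_directions(map, params$base_shape)
  n_cfg <- S * n_ind * r
  coords <- array(0, c(k, 2, n_cfg))
  latent <- array(0, c(k, 2, S * n_ind))
  species <- character(n_cfg); specimen <- character(n_cfg)
  replicate <- integer(n_cfg)
  idx <- 0L
  for (s in seq_len(S)) {
    sp <- means$species[s]
    delta_cfg <- unflatten_config(means$delta[s, ])
    for (i in seq_len(n_ind)) {
      ind_dev <- sim_sym_perturbation(
        rbind(stats::rnorm(2 * k, sd = params$sigma_ind)), map, dirs)
      fa_dev <- sim_asym_perturbation(
        rbind(stats::rnorm(2 * k, sd = params$sigma_fa)), map, dirs)
      lat <- means$sym_mean[, , s] + delta_cfg +
        unflatten_config(ind_dev[1, ]) + unflatten_config(fa_dev[1, ])
      latent[, , (s - 1L) * n_ind + i] <- lat
      for (j in seq_len(r)) {
        idx <- idx + 1L
        coords[, , idx] <- lat +
          matrix(stats::rnorm(2 * k, sd = params$sigma_me), k, 2)
        species[idx] <- sp
        specimen[idx] <- sprintf("%s_i%03d", sp, i)
        replicate[idx] <- j
      }
    }
  }
  ds <- landmark_dataset(coords, species, specimen, replicate)
  structure(list(dataset = ds, means = means, latent = latent,
                 params = params, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic landmark study with ground truth\n")
  print(x$dataset)
  cat(sprintf("  true species |delta|: %s\n",
              paste(round(sqrt(rowSums(x$means$delta^2)), 4), collapse = " ")))
  invisible(x)
}
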