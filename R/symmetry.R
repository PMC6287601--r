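#' Symmetry map for object symmetry between paired sublobes
#'
#' Describes the internal bilateral symmetry of a configuration: which
#' landmarks form mirror pairs across the symmetry axis between the two
#' sublobes, and which unpaired landmarks lie on the axis itself. The axis is
#' the line x = 0 by convention: reflection negates x-coordinates, and
#' relabeling swaps the members of each pair.
#'
#' @param pairs two-column integer matrix; each row is one (lower-side,
#'   upper-side) landmark pair.
#' @param axis integer vector of on-axis landmark indices.
#' @param k total number of landmarks; `pairs` and `axis` must partition
#'   `1..k`.
#' @param roles optional character labels for the two sublobes
#'   (e.g. `c("LLS", "ULS")`).
#' @return An object of class `symmetry_map`.
#' @export
symmetry_map <- function(pairs, axis = integer(0), k, roles = c("side1", "side2")) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  axis <- as.integer(axis)
  idx <- c(as.integer(pairs), axis)
  if (nrow(pairs) < 1L) stop("at least one landmark pair is required")
  if (anyDuplicated(idx)) stop("a landmark index appears twice in the map")
  if (!setequal(idx, seq_len(k)) || length(idx) != k)
    stop("pairs and axis points must partition 1..k")
  structure(list(pairs = pairs, axis = axis, k = as.integer(k),
                 n_pairs = nrow(pairs), roles = roles),
            class = "symmetry_map")
}

#' @export
print.symmetry_map <- function(x, ...) {
  cat("Symmetry map for", x$k, "landmarks:", x$n_pairs, "pair(s),",
      length(x$axis), "axis point(s)\n")
  cat("  pairs:", paste(sprintf("(%d,%d)", x$pairs[, 1], x$pairs[, 2]),
                        collapse = " "), "\n")
  if (length(x$axis)) cat("  axis:", paste(x$axis, collapse = " "), "\n")
  invisible(x)
}

#' Default symmetry maps for the 7- and 15-landmark sublobe schemes
#'
#' The 7-landmark scheme pairs landmarks (1,7), (2,6), (3,5) with landmark 4
#' on the axis; the 15-landmark scheme pairs (1,15) ... (7,9) with landmark 8
#' on the axis. The same 7-landmark map serves the terminal-lobule blocks
#' extracted from a 15-landmark configuration.
#'
#' @param k 7 or 15.
#' @param roles passed to [symmetry_map()].
#' @return A [symmetry_map()].
#' @export
default_symmetry_map <- function(k = 7, roles = c("LLS", "ULS")) {
  if (!k %in% c(7L, 15L)) stop("default maps exist for k = 7 and k = 15 only")
  p <- (k - 1L) %/% 2L
  symmetry_map(cbind(seq_len(p), k + 1L - seq_len(p)), axis = p + 1L, k = k,
               roles = roles)
}

## Permutation taking each landmark label to its mirror partner.
map_permutation <- function(map) {
  perm <- seq_len(map$k)
  perm[map$pairs[, 1]] <- map$pairs[, 2]
  perm[map$pairs[, 2]] <- map$pairs[, 1]
  perm
}

#' Reflect a configuration and relabel paired landmarks
#'
#' Negates x-coordinates (reflection across the symmetry axis x = 0), then
#' swaps the labels within each landmark pair so that the result is
#' comparable landmark-by-landmark with the original. Applying the operation
#' twice returns the input exactly.
#'
#' @param config `k x 2` coordinate matrix.
#' @param map a [symmetry_map()] valid for this `k`.
#' @return The reflected, relabeled `k x 2` matrix.
#' @export
reflect_relabel <- function(config, map) {
  config <- as.matrix(config)
  if (nrow(config) != map$k)
    stop("configuration has ", nrow(config), " landmarks but map expects ", map$k)
  out <- config[map_permutation(map), , drop = FALSE]
  out[, 1] <- -out[, 1]
  out
}

## The reflect-relabel operation as an orthogonal involution on flattened
## (x_1..x_k, y_1..y_k) shape vectors.
reflect_operator <- function(map) {
  k <- map$k
  perm <- map_permutation(map)
  Tm <- matrix(0, 2 * k, 2 * k)
  for (j in seq_len(k)) {
    Tm[j, perm[j]] <- -1          # x block: negate and permute
    Tm[k + j, k + perm[j]] <- 1   # y block: permute only
  }
  Tm
}

## Symmetric / asymmetric subspace projections of flattened shape vectors
## (rows of V).
project_symmetric <- function(V, map) {
  Tm <- reflect_operator(map)
  (V + V %*% t(Tm)) / 2
}
project_asymmetric <- function(V, map) {
  Tm <- reflect_operator(map)
  (V - V %*% t(Tm)) / 2
}

#' Joint GPA of original and reflected/relabeled configurations
#'
#' The object-symmetry superimposition: every configuration enters the GPA
#' twice, once as digitized and once reflected and relabeled. The provisional
#' consensus is symmetrized at every iteration, so the converged consensus is
#' exactly invariant under [reflect_relabel()] and the aligned reflected copy
#' of each configuration is the reflect-relabel image of its aligned original.
#'
#' @param dataset a [landmark_dataset()].
#' @param map a [symmetry_map()] for the dataset's `k`.
#' @param ... passed to [gpa()].
#' @return A `gpa_fit` with additional fields: `map`, `n_orig` (number of
#'   original configurations; slices `1..n_orig` of `aligned` are originals,
#'   `n_orig + 1 .. 2 n_orig` their reflected copies, in the same order),
#'   and the dataset's `species`, `specimen`, `replicate`.
#' @export
joint_symmetry_gpa <- function(dataset, map, ...) {
  stopifnot(inherits(dataset, "landmark_dataset"), inherits(map, "symmetry_map"))
  if (dataset$k != map$k) stop("dataset and map disagree on k")
  n <- dataset$n
  configs <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    configs[[i]] <- dataset$coords[, , i]
    configs[[n + i]] <- reflect_relabel(dataset$coords[, , i], map)
  }
  fit <- gpa(configs, principal_axes = FALSE,
             symmetrize = function(m) (m + reflect_relabel(m, map)) / 2, ...)
  fit$map <- map
  fit$n_orig <- n
  fit$species <- dataset$species
  fit$specimen <- dataset$specimen
  fit$replicate <- dataset$replicate
  class(fit) <- c("symmetry_gpa", class(fit))
  fit
}

#' Symmetric and asymmetric shape components
#'
#' For each original configuration in a [joint_symmetry_gpa()] fit, the
#' symmetric component is the average of the aligned original and its aligned
#' reflected copy, and the asymmetric component is half their difference.
#' Symmetric + asymmetric reconstructs the aligned original exactly; the
#' symmetric component is invariant under [reflect_relabel()] and the
#' asymmetric component changes sign.
#'
#' @param fit a fit from [joint_symmetry_gpa()].
#' @return A list of class `symmetry_components` with matrices `symmetric`
#'   and `asymmetric` (`n x 2k` flattened rows, x-block then y-block), plus
#'   `aligned` (`n x 2k` originals), `map`, and the design labels.
#' @export
symmetry_components <- function(fit) {
  stopifnot(inherits(fit, "symmetry_gpa"))
  n <- fit$n_orig
  orig <- t(apply(fit$aligned[, , seq_len(n), drop = FALSE], 3, flatten_config))
  refl <- t(apply(fit$aligned[, , n + seq_len(n), drop = FALSE], 3, flatten_config))
  structure(list(
    symmetric = (orig + refl) / 2,
    asymmetric = (orig - refl) / 2,
    aligned = orig,
    map = fit$map, species = fit$species, specimen = fit$specimen,
    replicate = fit$replicate, consensus = fit$consensus
  ), class = "symmetry_components")
}

## Subspace dimensions for 2D object symmetry with p pairs and u axis points:
## both the symmetric and the asymmetric shape subspace have dimension
## 2p + u - 2, together spanning the full shape space of dimension 2k - 4.
symmetry_dims <- function(map) {
  p <- map$n_pairs
  u <- length(map$axis)
  c(sym = 2 * p + u - 2, asym = 2 * p + u - 2)
}

#' Procrustes ANOVA of object symmetry
#'
#' Partitions shape variation in a replicated digitization design into four
#' effects: symmetric shape differences among individuals; positional
#' asymmetry (the population-average asymmetry between the paired sublobes,
#' the within-configuration analog of directional asymmetry); fluctuating
#' asymmetry (individual deviations from the average asymmetry, the
#' individual-by-side interaction); and digitization (measurement) error.
#' Sums of squares are Procrustes sums of squares over the doubled
#' original-plus-reflected dataset, computed in the tangent space of the
#' joint symmetric superimposition, so that the four effects add up to the
#' total exactly in a balanced design.
#'
#' Significance is assessed by permutation: positional asymmetry by random
#' per-specimen relabeling of original vs. reflected copies (sign flips of
#' the specimen asymmetric components), the individuals effect by shuffling
#' whole specimen-replicate rows across specimens, and fluctuating asymmetry
#' by shuffling replicate-level asymmetric deviations across specimens.
#' P-values use the add-one rule, `p = (#{F* >= F} + 1) / (n_perm + 1)`.
#'
#' @param dataset a balanced [landmark_dataset()] (each specimen digitized
#'   the same number `r` of times; `r >= 2` for the error row).
#' @param map a [symmetry_map()].
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @param denominator `"fa"` tests positional asymmetry (and individuals)
#'   against the fluctuating-asymmetry mean square; `"pooled"` uses the
#'   pooled FA + error mean square.
#' @return An object of class `symmetry_anova`: list with `table` (a data
#'   frame with rows individuals, positional_asymmetry,
#'   fluctuating_asymmetry, measurement_error and columns SS, df, MS, Rsq,
#'   F, p), the component matrices, `n`, `r`, `n_perm`, `seed`, `map`.
#' @export
symmetry_anova <- function(dataset, map, n_perm = 999, seed = 1,
                           denominator = c("fa", "pooled")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  counts <- table(dataset$specimen)
  if (length(unique(as.integer(counts))) != 1L)
    stop("unbalanced design; replicates per specimen: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  r <- as.integer(counts[1])
  n <- length(counts)
  if (n < 2L) stop("at least 2 specimens are required")
  fit <- joint_symmetry_gpa(dataset, map)
  comp <- symmetry_components(fit)
  Tng <- tangent_project(fit)
  n_tot <- fit$n_orig
  S <- project_symmetric(Tng[seq_len(n_tot), , drop = FALSE], map)
  D <- project_asymmetric(Tng[seq_len(n_tot), , drop = FALSE], map)
  spec_f <- factor(dataset$specimen, levels = names(counts))
  ## Cell means per specimen
  Sbar_i <- rowsum(S, spec_f) / r
  Dbar_i <- rowsum(D, spec_f) / r
  sbar <- colMeans(S)
  dbar <- colMeans(D)
  ss <- function(M) sum(M^2)
  SS_ind <- 2 * r * ss(sweep(Sbar_i, 2, sbar))
  SS_pos <- 2 * n * r * sum(dbar^2)
  SS_fa  <- 2 * r * ss(sweep(Dbar_i, 2, dbar))
  SS_err <- 2 * (ss(S - Sbar_i[spec_f, , drop = FALSE]) +
                 ss(D - Dbar_i[spec_f, , drop = FALSE]))
  SS_tot <- SS_ind + SS_pos + SS_fa + SS_err
  dims <- symmetry_dims(map)
  df <- c(ind = (n - 1) * dims["sym"], pos = dims[["asym"]],
          fa = (n - 1) * dims["asym"], err = n * (r - 1) * sum(dims))
  names(df) <- c("ind", "pos", "fa", "err")
  MS <- c(SS_ind, SS_pos, SS_fa, SS_err) / df
  names(MS) <- names(df)
  ms_denom_pos <- if (denominator == "fa") MS["fa"] else
    (SS_fa + SS_err) / (df["fa"] + df["err"])
  F_ind <- unname(MS["ind"] / ms_denom_pos)
  F_pos <- unname(MS["pos"] / ms_denom_pos)
  F_fa <- if (r >= 2) unname(MS["fa"] / MS["err"]) else NA_real_

  set.seed(seed)
  sum_Dbar_sq <- ss(Dbar_i)
  ## Positional asymmetry: per-specimen sign flips of asymmetric components.
  E <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  Dstar <- crossprod(Dbar_i, E) / n         # 2k x n_perm permuted grand means
  nrm2 <- colSums(Dstar^2)
  SSp_pos <- 2 * n * r * nrm2
  SSp_fa <- 2 * r * (sum_Dbar_sq - n * nrm2)
  denom_p <- if (denominator == "fa") SSp_fa / df["fa"] else
    (SSp_fa + SS_err) / (df["fa"] + df["err"])
  F_pos_perm <- (SSp_pos / df["pos"]) / denom_p
  p_pos <- (sum(F_pos_perm >= F_pos) + 1) / (n_perm + 1)

  ## Individuals: shuffle the symmetric-component rows across the specimen
  ## factor (the exchangeable units under the no-individual-differences
  ## null); the asymmetric components, and hence the denominator, keep
  ## their observed grouping.
  F_ind_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_tot)
    Sb <- rowsum(S[idx, , drop = FALSE], spec_f) / r
    ssi <- 2 * r * ss(sweep(Sb, 2, sbar))
    den <- if (denominator == "fa") MS["fa"] else {
      sse <- 2 * (ss(S[idx, , drop = FALSE] - Sb[spec_f, , drop = FALSE]) +
                  ss(D - Dbar_i[spec_f, , drop = FALSE]))
      (SS_fa + sse) / (df["fa"] + df["err"])
    }
    F_ind_perm[b] <- (ssi / df["ind"]) / den
  }
  p_ind <- (sum(F_ind_perm >= F_ind) + 1) / (n_perm + 1)

  ## FA: shuffle replicate-level asymmetric deviations across specimens.
  p_fa <- NA_real_
  if (r >= 2) {
    F_fa_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_tot)
      Db <- rowsum(D[idx, , drop = FALSE], spec_f) / r
      ssf <- 2 * r * ss(sweep(Db, 2, dbar))
      sse <- 2 * (ss(S - Sbar_i[spec_f, , drop = FALSE]) +
                  ss(D[idx, , drop = FALSE] - Db[spec_f, , drop = FALSE]))
      F_fa_perm[b] <- (ssf / df["fa"]) / (sse / df["err"])
    }
    p_fa <- (sum(F_fa_perm >= F_fa) + 1) / (n_perm + 1)
  }

  tab <- data.frame(
    SS = c(SS_ind, SS_pos, SS_fa, if (r >= 2) SS_err else NA_real_),
    df = unname(c(df[c("ind", "pos", "fa")], if (r >= 2) df["err"] else NA)),
    MS = c(MS[c("ind", "pos", "fa")], if (r >= 2) MS["err"] else NA_real_),
    Rsq = c(SS_ind, SS_pos, SS_fa, if (r >= 2) SS_err else NA_real_) / SS_tot,
    F = c(F_ind, F_pos, F_fa, NA_real_),
    p = c(p_ind, p_pos, p_fa, NA_real_),
    row.names = c("individuals", "positional_asymmetry",
                  "fluctuating_asymmetry", "measurement_error")
  )
  structure(list(table = tab, components = comp, n = n, r = r,
                 n_perm = n_perm, seed = seed, map = map,
                 denominator = denominator, fit = fit,
                 error_testable = r >= 2),
            class = "symmetry_anova")
}

#' @export
print.symmetry_anova <- function(x, digits = 4, ...) {
  cat("Procrustes ANOVA of object symmetry\n")
  cat(sprintf("  %d specimen(s) x %d replicate(s); %d permutations (seed %d)\n",
              x$n, x$r, x$n_perm, x$seed))
  tab <- x$table
  tab$SS <- signif(tab$SS, digits); tab$MS <- signif(tab$MS, digits)
  tab$Rsq <- round(tab$Rsq, digits); tab$F <- signif(tab$F, digits)
  print(tab)
  if (!x$error_testable)
    cat("  note: single digitization per specimen; measurement error not",
        "estimable and the FA test is unavailable\n")
  invisible(x)
}

#' @export
summary.symmetry_anova <- function(object, ...) {
  object$table
}

#' Species-level asymmetry means
#'
#' For each species separately, the joint symmetric superimposition of its
#' configurations yields a species mean shape (replicates averaged within
#' specimens first, then specimens averaged), its reflect-relabel mirror
#' image, and the asymmetric-component vector of the mean — the positional
#' asymmetry typical of that species. Estimating the asymmetry inside each
#' species' own superimposition pins the rotational gauge at the species
#' consensus, so between-species shape differences cannot leak into the
#' asymmetry estimates; the per-species means are merged and re-superimposed
#' downstream by [mirrored_pca()].
#'
#' @param dataset a [landmark_dataset()].
#' @param map a [symmetry_map()].
#' @return An object of class `species_asym_means`: list with `species`,
#'   `mean` (`k x 2 x S` species mean configurations, each in its own
#'   symmetric superimposition frame), `mirrored` (their reflect-relabel
#'   images), `asymmetry` (`S x 2k` asymmetric-component row vectors),
#'   `specimen_asym` (per species, the specimen-level mean asymmetric
#'   components, for standard errors), `map`, `k`.
#' @export
species_asymmetry_means <- function(dataset, map) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  sp_levels <- sort(unique(dataset$species))
  S <- length(sp_levels)
  mean_arr <- array(0, c(dataset$k, 2, S),
                    dimnames = list(NULL, NULL, sp_levels))
  mirr_arr <- mean_arr
  asym <- matrix(0, S, 2 * dataset$k, dimnames = list(sp_levels, NULL))
  specimen_asym <- vector("list", S)
  names(specimen_asym) <- sp_levels
  for (s in seq_len(S)) {
    keep <- dataset$species == sp_levels[s]
    sub <- landmark_dataset(dataset$coords[, , keep, drop = FALSE],
                            dataset$species[keep], dataset$specimen[keep],
                            dataset$replicate[keep])
    fit <- joint_symmetry_gpa(sub, map)
    n <- fit$n_orig
    orig <- t(apply(fit$aligned[, , seq_len(n), drop = FALSE], 3,
                    flatten_config))
    spec_f <- factor(sub$specimen)
    spec_means <- rowsum(orig, spec_f) / as.integer(table(spec_f))
    sp_mean <- colMeans(spec_means)
    m <- unflatten_config(sp_mean)
    mean_arr[, , s] <- m
    mirr_arr[, , s] <- reflect_relabel(m, map)
    asym[s, ] <- project_asymmetric(rbind(sp_mean), map)[1, ]
    specimen_asym[[s]] <- project_asymmetric(spec_means, map)
  }
  structure(list(species = sp_levels, mean = mean_arr, mirrored = mirr_arr,
                 asymmetry = asym, specimen_asym = specimen_asym,
                 map = map, k = dataset$k),
            class = "species_asym_means")
}

#' @export
print.species_asym_means <- function(x, ...) {
  cat("Species asymmetry means:", length(x$species), "species,",
      x$k, "landmarks\n")
  nrm <- sqrt(rowSums(x$asymmetry^2))
  print(round(stats::setNames(nrm, x$species), 5))
  invisible(x)
}
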