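## Classify PCA eigenvectors as symmetric / asymmetric / mixed under the
## reflect-relabel involution.
classify_pcs <- function(rotation, map, tol = 1e-6) {
  Tm <- reflect_operator(map)
  vapply(seq_len(ncol(rotation)), function(j) {
    v <- rotation[, j]
    tv <- drop(Tm %*% v)
    nrm <- sqrt(sum(v^2))
    if (sqrt(sum((tv - v)^2)) < tol * nrm) "symmetric"
    else if (sqrt(sum((tv + v)^2)) < tol * nrm) "asymmetric"
    else "mixed"
  }, "")
}

## Fix eigenvector signs: largest-magnitude loading positive.
orient_pcs <- function(pca) {
  flip <- vapply(seq_len(ncol(pca$rotation)), function(j) {
    v <- pca$rotation[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  pca$rotation <- sweep(pca$rotation, 2, flip, `*`)
  pca$x <- sweep(pca$x, 2, flip, `*`)
  pca
}

new_morphospace <- function(pca, map, kind, labels, center_config, extra = list()) {
  ev <- pca$sdev^2
  keep <- if (max(ev) <= 0) seq_along(ev) else which(ev > max(ev) * 1e-12)
  out <- c(list(
    center = center_config,
    center_vector = pca$center,
    rotation = pca$rotation[, keep, drop = FALSE],
    eigenvalues = ev[keep],
    scores = pca$x[, keep, drop = FALSE],
    var_frac = if (sum(ev) > 0) ev[keep] / sum(ev) else rep(0, length(keep)),
    pc_class = if (is.null(map)) rep("asymmetric", length(keep))
               else classify_pcs(pca$rotation[, keep, drop = FALSE], map),
    labels = labels, map = map, kind = kind
  ), extra)
  structure(out, class = "morphospace")
}

#' Mirrored-configuration PCA morphospace
#'
#' Merges the species mean configurations with their mirrored (reflected and
#' relabeled) copies, superimposes the doubled set by [joint_symmetry_gpa()]
#' machinery, and runs a PCA of the aligned tangent coordinates. Each
#' principal component of such a doubled sample describes either purely
#' symmetric or purely asymmetric variation with respect to the sublobe
#' symmetry axis; the ideally symmetric configuration sits at the center of
#' the ordination, and the original and mirrored copies of each species sit
#' at opposite positions along every asymmetric PC.
#'
#' @param means a [species_asymmetry_means()] object.
#' @param map a [symmetry_map()]; defaults to the one stored in `means`.
#' @param class_tol relative tolerance for classifying a PC as symmetric or
#'   asymmetric under reflect-relabel; components failing both tests are
#'   labeled `mixed`.
#' @return An object of class `morphospace` with fields `center` (consensus
#'   configuration), `rotation` (eigenvectors), `eigenvalues`, `scores`
#'   (2S rows: originals then mirrors), `pc_class`, `var_frac`, `labels`,
#'   `mirror` (logical row flag).
#' @export
mirrored_pca <- function(means, map = means$map, class_tol = 1e-6) {
  stopifnot(inherits(means, "species_asym_means"))
  S <- length(means$species)
  if (S < 3L) stop("at least 3 species are required")
  configs <- vector("list", 2L * S)
  for (s in seq_len(S)) {
    configs[[s]] <- means$mean[, , s]
    configs[[S + s]] <- means$mirrored[, , s]
  }
  fit <- gpa(configs, principal_axes = FALSE,
             symmetrize = function(m) (m + reflect_relabel(m, map)) / 2)
  X <- tangent_project(fit)
  pca <- stats::prcomp(unclass(X), center = TRUE, scale. = FALSE)
  pca <- orient_pcs(pca)
  ms <- new_morphospace(pca, map, "mirrored",
                        labels = rep(means$species, 2L),
                        center_config = fit$consensus,
                        extra = list(mirror = rep(c(FALSE, TRUE), each = S)))
  ms$pc_class <- classify_pcs(ms$rotation, map, tol = class_tol)
  ms
}

#' PCA of purely asymmetric variation
#'
#' Principal components of the species asymmetric-component vectors (original
#' configurations only, no mirrors), centered at the grand mean asymmetric
#' configuration. This is the morphospace onto which the phylogeny is mapped.
#'
#' @param means a [species_asymmetry_means()] object.
#' @return An object of class `morphospace` (kind `"asymmetric"`); `scores`
#'   has one row per species.
#' @export
asymmetric_pca <- function(means) {
  stopifnot(inherits(means, "species_asym_means"))
  S <- length(means$species)
  if (S < 3L) stop("at least 3 species are required")
  pca <- stats::prcomp(means$asymmetry, center = TRUE, scale. = FALSE)
  pca <- orient_pcs(pca)
  new_morphospace(pca, means$map, "asymmetric",
                  labels = means$species,
                  center_config = unflatten_config(colMeans(means$asymmetry)))
}

#' Project a configuration into a morphospace
#'
#' For a mirrored morphospace the configuration is centered, scaled and
#' rotated onto the morphospace consensus before projection; for an
#' asymmetric morphospace the argument is taken to be a flattened
#' asymmetric-component vector.
#'
#' @param space a `morphospace`.
#' @param config `k x 2` configuration (mirrored space) or length-`2k`
#'   vector (asymmetric space).
#' @return Numeric vector of PC scores.
#' @export
project_config <- function(space, config) {
  stopifnot(inherits(space, "morphospace"))
  v <- if (space$kind == "mirrored") {
    a <- center_scale(config)$config
    a <- a %*% rotation_to(a, space$center)
    flatten_config(a)
  } else {
    as.numeric(config)
  }
  drop((v - space$center_vector) %*% space$rotation)
}

#' @export
print.morphospace <- function(x, digits = 4, ...) {
  cat(sprintf("%s morphospace: %d configuration(s), %d component(s)\n",
              if (x$kind == "mirrored") "Mirrored-configuration" else
                "Asymmetric-component",
              nrow(x$scores), ncol(x$scores)))
  df <- data.frame(eigenvalue = signif(x$eigenvalues, digits),
                   var_frac = round(x$var_frac, digits),
                   class = x$pc_class)
  rownames(df) <- colnames(x$scores)
  print(utils::head(df, 10))
  invisible(x)
}

#' Plot a morphospace
#'
#' Scatter of two PC scores; in a mirrored morphospace the mirrored copies
#' are drawn in grey and joined to their originals.
#'
#' @param x a `morphospace`.
#' @param pcs integer vector of two PC indices (default 1:2).
#' @param labels draw species labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.morphospace <- function(x, pcs = c(1, 2), labels = TRUE, ...) {
  sc <- x$scores[, pcs, drop = FALSE]
  vf <- round(100 * x$var_frac[pcs], 1)
  nm <- colnames(x$scores)[pcs]
  graphics::plot(sc, type = "n",
                 xlab = sprintf("%s (%s%%, %s)", nm[1], vf[1], x$pc_class[pcs[1]]),
                 ylab = sprintf("%s (%s%%, %s)", nm[2], vf[2], x$pc_class[pcs[2]]),
                 ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  if (!is.null(x$mirror)) {
    orig <- !x$mirror
    graphics::segments(sc[orig, 1], sc[orig, 2], sc[x$mirror, 1], sc[x$mirror, 2],
                       col = "grey85")
    graphics::points(sc[x$mirror, , drop = FALSE], pch = 19, col = "grey60")
    graphics::points(sc[orig, , drop = FALSE], pch = 19, col = "firebrick")
    if (labels) graphics::text(sc[orig, , drop = FALSE], x$labels[orig],
                               pos = 3, cex = 0.7)
  } else {
    graphics::points(sc, pch = 19, col = "firebrick")
    if (labels) graphics::text(sc, x$labels, pos = 3, cex = 0.7)
  }
  invisible(x)
}
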