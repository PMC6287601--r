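#' Center a configuration and scale it to unit centroid size
#'
#' Centroid size is the square root of the summed squared distances of the
#' landmarks from their centroid; it is the size measure removed by Procrustes
#' scaling.
#'
#' @param config numeric `k x 2` matrix of landmark coordinates.
#' @return A list with `config` (centered, unit centroid size) and
#'   `centroid_size` (the input's size).
#' @export
center_scale <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 3L) stop("configurations need at least 3 landmarks")
  ctr <- colMeans(config)
  centered <- sweep(config, 2, ctr)
  cs <- sqrt(sum(centered^2))
  if (cs < 1e-12)
    stop("degenerate configuration: all landmarks coincident (centroid size 0)")
  list(config = centered / cs, centroid_size = cs)
}

## Closed-form optimal 2D rotation of row-coordinate matrix A onto B
## (both centered). Returns the 2x2 matrix R minimizing ||A R - B||_F
## over rotations (det +1).
rotation_to <- function(A, B) {
  M <- crossprod(A, B)
  theta <- atan2(M[2, 1] - M[1, 2], M[1, 1] + M[2, 2])
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, -s_, c_), 2, 2)
}

#' Optimal superimposition rotation between two configurations
#'
#' Finds the orthogonal transform minimizing the summed squared differences
#' between `A` (rotated) and `B`. By default only proper rotations
#' (determinant +1) are allowed, as required when reflected copies of
#' configurations enter an analysis as data in their own right.
#'
#' @param A,B centered `k x 2` coordinate matrices with equal `k`, typically
#'   unit centroid size.
#' @param allow_reflection logical; also consider improper (reflecting)
#'   transforms.
#' @return A list with `rotated` (A after rotation), `rotation` (2x2 matrix),
#'   and `angle` (radians, for proper rotations).
#' @export
optimal_rotation <- function(A, B, allow_reflection = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("configurations must have the same landmarks")
  if (allow_reflection) {
    M <- crossprod(A, B)
    sv <- svd(M)
    R <- sv$u %*% t(sv$v)
  } else {
    R <- rotation_to(A, B)
  }
  list(rotated = A %*% R, rotation = R,
       angle = atan2(R[2, 1], R[1, 1]))
}

#' Generalized Procrustes analysis (GPA)
#'
#' Iterative least-squares superimposition of a sample of 2D configurations:
#' all configurations are centered and scaled to unit centroid size, rotated
#' to a provisional consensus, and the consensus is re-estimated (and rescaled
#' to unit size) until the mean squared residual stabilizes. Reflections are
#' never introduced. After convergence the consensus is optionally rotated to
#' its principal axes, for a reproducible orientation of downstream ordination
#' axes.
#'
#' @param configs list of `k x 2` matrices, or a `k x 2 x n` array.
#' @param tol convergence tolerance on the change in mean squared residual.
#' @param max_iter maximum number of alignment iterations.
#' @param principal_axes rotate the converged fit so the consensus lies along
#'   its principal axes.
#' @param symmetrize optional function applied to the provisional consensus at
#'   each iteration (used by [joint_symmetry_gpa()] to keep the consensus
#'   exactly symmetric); the result is re-centered and re-scaled internally.
#' @return An object of class `gpa_fit`: list with `aligned` (`k x 2 x n`),
#'   `consensus` (`k x 2`, unit size), `centroid_size` (original sizes),
#'   `iterations`, `converged`, `k`, `n`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 200, principal_axes = TRUE,
                symmetrize = NULL) {
  if (is.array(configs) && length(dim(configs)) == 3L)
    configs <- lapply(seq_len(dim(configs)[3]), function(i) configs[, , i])
  n <- length(configs)
  if (n < 2L) stop("GPA needs at least 2 configurations")
  ks <- vapply(configs, nrow, 0L)
  if (length(unique(ks)) != 1L) stop("all configurations must share the same k")
  k <- ks[1]
  cs <- numeric(n)
  X <- array(0, c(k, 2, n))
  for (i in seq_len(n)) {
    z <- center_scale(configs[[i]])
    X[, , i] <- z$config
    cs[i] <- z$centroid_size
  }
  normalize <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  mean_shape <- function(X) {
    m <- apply(X, c(1, 2), mean)
    if (!is.null(symmetrize)) m <- symmetrize(m)
    normalize(m)
  }
  consensus <- normalize(if (!is.null(symmetrize)) symmetrize(X[, , 1]) else X[, , 1])
  msr_prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% rotation_to(X[, , i], consensus)
    consensus_new <- mean_shape(X)
    moved <- max(abs(consensus_new - consensus))
    consensus <- consensus_new
    msr <- mean(apply(X, 3, function(a) sum((a - consensus)^2)))
    if (abs(msr_prev - msr) < tol && moved < 1e-8) { converged <- TRUE; break }
    msr_prev <- msr
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  if (principal_axes) {
    ev <- eigen(crossprod(consensus), symmetric = TRUE)
    R <- ev$vectors
    if (det(R) < 0) R[, 2] <- -R[, 2]
    consensus <- consensus %*% R
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% R
  }
  structure(list(aligned = X, consensus = consensus, centroid_size = cs,
                 iterations = iter, converged = converged, k = k, n = n),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes fit:", x$n, "configurations,", x$k, "landmarks\n")
  cat(sprintf("  converged: %s (%d iteration(s))\n", x$converged, x$iterations))
  cat(sprintf("  mean Procrustes distance to consensus: %.6g\n",
              mean(apply(x$aligned, 3, function(a) sqrt(sum((a - x$consensus)^2))))))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Square root of the minimized summed squared differences after centering,
#' scaling to unit centroid size, and optimal (proper) rotation.
#'
#' @param A,B `k x 2` coordinate matrices with equal `k`.
#' @return Non-negative scalar, symmetric in its arguments.
#' @export
procrustes_distance <- function(A, B) {
  a <- center_scale(A)$config
  b <- center_scale(B)$config
  if (!all(dim(a) == dim(b))) stop("configurations must have the same landmarks")
  sqrt(sum((a %*% rotation_to(a, b) - b)^2))
}

## Flatten a k x 2 configuration to the (x_1..x_k, y_1..y_k) vector used for
## tangent-space arithmetic, and back.
flatten_config <- function(m) as.numeric(m)
unflatten_config <- function(v) matrix(v, ncol = 2)

#' Project an aligned sample into the tangent space at the consensus
#'
#' Aligned coordinates are expressed as deviations from the consensus and
#' projected orthogonally to the consensus direction. Euclidean distances in
#' this space approximate Procrustes distances for small shape variation.
#'
#' @param fit a `gpa_fit` from [gpa()].
#' @return A numeric `n x 2k` matrix of class `tangent_coords`, with the
#'   consensus vector attached as attribute `consensus`.
#' @export
tangent_project <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  cvec <- flatten_config(fit$consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  X <- t(apply(fit$aligned, 3, flatten_config))
  D <- sweep(X, 2, flatten_config(fit$consensus))
  D <- D - outer(drop(D %*% cvec), cvec)
  structure(D, consensus = flatten_config(fit$consensus), class = "tangent_coords")
}
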