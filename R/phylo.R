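#' Phylogenetic covariance matrix under Brownian motion
#'
#' `C[i, j]` is the shared root-to-tip path length of tips `i` and `j` (the
#' depth of their most recent common ancestor); `C[i, i]` is the root-to-tip
#' path length. Under Brownian motion with rate `s2`, tip values have
#' covariance `s2 * C`.
#'
#' @param tree a rooted [ape::phylo] tree with non-negative branch lengths.
#' @return An `S x S` matrix with tip labels as dimnames.
#' @export
phylo_cov <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object")
  ## A basal polytomy is accepted as a rooted polytomy (star phylogeny);
  ## genuinely unrooted trees must be rooted upstream (midpoint/outgroup).
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  ape::vcv.phylo(tree)
}

## Weighted graph Laplacian of a tree: nodes are tips + internal nodes,
## edge weights 1 / branch length.
tree_laplacian <- function(tree, weighted = TRUE, min_branch = 1e-8) {
  len <- if (weighted) tree$edge.length else rep(1, nrow(tree$edge))
  if (any(len < min_branch)) {
    warning("branch length(s) below ", min_branch, " clamped")
    len <- pmax(len, min_branch)
  }
  w <- 1 / len
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  L <- matrix(0, n_nodes, n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    L[a, b] <- L[a, b] - w[e]; L[b, a] <- L[b, a] - w[e]
    L[a, a] <- L[a, a] + w[e]; L[b, b] <- L[b, b] + w[e]
  }
  L
}

## Quadratic form M such that the minimized total squared change equals
## sum over dimensions of  x' M x  for tip data x (per dimension).
scp_qform <- function(tree, weighted = TRUE, min_branch = 1e-8) {
  L <- tree_laplacian(tree, weighted, min_branch)
  nt <- ape::Ntip(tree)
  tt <- seq_len(nt)
  ii <- (nt + 1):nrow(L)
  Lii_inv_Lit <- solve(L[ii, ii, drop = FALSE], L[ii, tt, drop = FALSE])
  M <- L[tt, tt, drop = FALSE] - L[tt, ii, drop = FALSE] %*% Lii_inv_Lit
  list(M = M, solve_anc = -Lii_inv_Lit)
}

#' Squared-change parsimony ancestral states
#'
#' Estimates internal-node states minimizing the total squared change
#' `Q = sum over branches of |child - parent|^2 / branch length` (branch
#' lengths all 1 when `weighted = FALSE`), jointly over all dimensions of the
#' tip data. The minimizing states solve a sparse linear system (the tree's
#' weighted graph Laplacian restricted to internal nodes); with branch-length
#' weighting they coincide with maximum-likelihood ancestral states under
#' Brownian motion.
#'
#' @param tree rooted [ape::phylo] tree.
#' @param tip_data numeric matrix (`S x D`) or vector of tip values; row
#'   names, when present, are matched against the tip labels.
#' @param weighted divide squared changes by branch lengths (default `TRUE`).
#' @param min_branch branches shorter than this are clamped, with a warning.
#' @return An object of class `scp_fit`: list with `ancestral` (internal
#'   node states, `Nnode x D`), `Q` (total), `Q_per_dim`, `per_branch`
#'   (squared-change contribution of every edge), `tree`, `weighted`.
#' @export
squared_change_parsimony <- function(tree, tip_data, weighted = TRUE,
                                     min_branch = 1e-8) {
  tip_data <- as.matrix(tip_data)
  nt <- ape::Ntip(tree)
  if (nrow(tip_data) != nt) stop("tip_data must have one row per tip")
  if (!is.null(rownames(tip_data))) {
    if (!setequal(rownames(tip_data), tree$tip.label))
      stop("tip_data row names do not match tree tip labels")
    tip_data <- tip_data[tree$tip.label, , drop = FALSE]
  }
  qf <- scp_qform(tree, weighted, min_branch)
  anc <- qf$solve_anc %*% tip_data
  rownames(anc) <- as.character(nt + seq_len(tree$Nnode))
  all_states <- rbind(tip_data, anc)
  len <- if (weighted) pmax(tree$edge.length, min_branch) else
    rep(1, nrow(tree$edge))
  d <- all_states[tree$edge[, 1], , drop = FALSE] -
       all_states[tree$edge[, 2], , drop = FALSE]
  per_branch <- rowSums(d^2) / len
  Q_per_dim <- colSums(d^2 / len)
  structure(list(ancestral = anc, Q = sum(per_branch), Q_per_dim = Q_per_dim,
                 per_branch = per_branch, tree = tree, weighted = weighted),
            class = "scp_fit")
}

#' @export
print.scp_fit <- function(x, ...) {
  cat("Squared-change parsimony reconstruction\n")
  cat(sprintf("  %d tips, %d internal nodes, %s branch lengths\n",
              ape::Ntip(x$tree), x$tree$Nnode,
              if (x$weighted) "weighted by" else "ignoring"))
  cat(sprintf("  total squared change Q = %.6g\n", x$Q))
  invisible(x)
}

#' Permutation test of phylogenetic signal
#'
#' The observed total squared change `Q` from [squared_change_parsimony()] is
#' compared with its distribution under random permutation of the data across
#' the tips of the tree. Small observed `Q` (less change than expected for
#' randomly placed tips) indicates phylogenetic signal, so the test is
#' left-tailed; ties count toward the tail and the add-one rule keeps `p`
#' strictly positive.
#'
#' @param tree rooted [ape::phylo] tree.
#' @param tip_data `S x D` matrix (or vector) of tip values; rows matched to
#'   tip labels when named.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @param weighted,min_branch passed to the squared-change machinery.
#' @return An object of class `phylo_signal`: list with `Q_obs`, `Q_perm`,
#'   `p`, `n_perm`, `seed`.
#' @export
phylo_signal_test <- function(tree, tip_data, n_perm = 9999, seed = 1,
                              weighted = TRUE, min_branch = 1e-8) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  tip_data <- as.matrix(tip_data)
  if (!is.null(rownames(tip_data))) {
    if (!setequal(rownames(tip_data), tree$tip.label))
      stop("tip_data row names do not match tree tip labels")
    tip_data <- tip_data[tree$tip.label, , drop = FALSE]
  }
  M <- scp_qform(tree, weighted, min_branch)$M
  qval <- function(X) sum(X * (M %*% X))
  Q_obs <- qval(tip_data)
  set.seed(seed)
  n <- nrow(tip_data)
  Q_perm <- vapply(seq_len(n_perm), function(b)
    qval(tip_data[sample.int(n), , drop = FALSE]), 0)
  ## ties count toward the tail; the tolerance absorbs summation-order
  ## rounding so that permutation-invariant statistics give p = 1 exactly
  tol <- 1e-9 * (abs(Q_obs) + max(abs(Q_perm))) + 1e-300
  p <- (sum(Q_perm <= Q_obs + tol) + 1) / (n_perm + 1)
  structure(list(Q_obs = Q_obs, Q_perm = Q_perm, p = p,
                 n_perm = n_perm, seed = seed),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Permutation test of phylogenetic signal (squared-change parsimony)\n")
  cat(sprintf("  Q observed = %.6g; p = %.4g (%d permutations, seed %d)\n",
              x$Q_obs, x$p, x$n_perm, x$seed))
  invisible(x)
}

#' Generalized least squares mean under a phylogenetic covariance
#'
#' The GLS estimate of the ancestral (root) mean of multivariate tip data:
#' `a = (1' C^-1 1)^-1 1' C^-1 X`.
#'
#' @param C phylogenetic covariance matrix from [phylo_cov()].
#' @param X `S x D` matrix of tip values, rows ordered as `C`.
#' @param ridge added to the diagonal (with a warning) when `C` is
#'   numerically singular; `NULL` makes singularity an error.
#' @return Numeric vector of length `D`.
#' @export
phylo_gls_mean <- function(C, X, ridge = NULL) {
  X <- as.matrix(X)
  CiX <- tryCatch(solve(C, cbind(1, X)), error = function(e) {
    if (is.null(ridge)) stop("singular phylogenetic covariance; set 'ridge'")
    warning("singular phylogenetic covariance; ridge ", ridge, " applied")
    solve(C + diag(ridge, nrow(C)), cbind(1, X))
  })
  drop(colSums(CiX[, -1, drop = FALSE]) / sum(CiX[, 1]))
}

## Symmetric inverse square root of a covariance matrix, eigenvalue-floored.
inv_sqrt_mat <- function(C, floor = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Phylogenetic two-block partial least squares
#'
#' Quantifies evolutionary covariation between two blocks of species-level
#' traits while accounting for phylogeny under a Brownian-motion model. Both
#' blocks are phylogenetically transformed (GLS mean subtracted, then
#' premultiplied by the symmetric inverse square root of the phylogenetic
#' covariance), the cross-block covariance matrix is decomposed by SVD, and
#' `r_PLS` is the absolute correlation between the first pair of singular
#' axis scores. Significance comes from permuting the tip assignment of the
#' second block relative to the first. The permutation operates on the
#' phylogenetically transformed rows: under the Brownian-motion null these
#' are exchangeable, which keeps the test exact, whereas permuting raw tip
#' rows and re-whitening would manufacture spurious covariance.
#'
#' @param tree rooted [ape::phylo] tree.
#' @param blockX,blockY numeric matrices `S x D1`, `S x D2` with species as
#'   rows; row names matched to tip labels when present.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param floor eigenvalue floor for the inverse square root of the
#'   phylogenetic covariance.
#' @return An object of class `phylo_pls`: list with `r_pls`, `p`,
#'   `singular_values`, `left`/`right` (singular vectors), `scores_x`,
#'   `scores_y` (first-axis scores), `r_perm`, `n_perm`, `seed`.
#' @export
phylo_pls <- function(tree, blockX, blockY, n_perm = 999, seed = 1,
                      floor = 1e-12) {
  blockX <- as.matrix(blockX); blockY <- as.matrix(blockY)
  if (nrow(blockX) != nrow(blockY)) stop("blocks must have the same species")
  if (nrow(blockX) < 4L) stop("at least 4 species are required")
  if (!is.null(rownames(blockX)) && !is.null(rownames(blockY))) {
    if (!setequal(rownames(blockX), rownames(blockY)))
      stop("species mismatch between blocks: ",
           paste(union(setdiff(rownames(blockX), rownames(blockY)),
                       setdiff(rownames(blockY), rownames(blockX))),
                 collapse = ", "))
    blockY <- blockY[rownames(blockX), , drop = FALSE]
    if (!setequal(rownames(blockX), tree$tip.label))
      stop("species mismatch between blocks and tree: ",
           paste(union(setdiff(rownames(blockX), tree$tip.label),
                       setdiff(tree$tip.label, rownames(blockX))),
                 collapse = ", "))
    blockX <- blockX[tree$tip.label, , drop = FALSE]
    blockY <- blockY[tree$tip.label, , drop = FALSE]
  }
  C <- phylo_cov(tree)
  Ci <- inv_sqrt_mat(C, floor)
  S <- nrow(blockX)
  transform_block <- function(Z) {
    a <- phylo_gls_mean(C, Z)
    Ci %*% sweep(Z, 2, a)
  }
  pls_of <- function(Ey) {
    R12 <- crossprod(Ex, Ey) / (S - 1)
    sv <- svd(R12)
    sx <- drop(Ex %*% sv$u[, 1])
    sy <- drop(Ey %*% sv$v[, 1])
    r <- if (stats::sd(sx) == 0 || stats::sd(sy) == 0) 0
         else abs(stats::cor(sx, sy))
    list(r = r, sv = sv, sx = sx, sy = sy)
  }
  Ex <- transform_block(blockX)
  Ey <- transform_block(blockY)
  obs <- pls_of(Ey)
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(b)
    pls_of(Ey[sample.int(S), , drop = FALSE])$r, 0)
  p <- (sum(r_perm >= obs$r) + 1) / (n_perm + 1)
  structure(list(r_pls = obs$r, p = p, singular_values = obs$sv$d,
                 left = obs$sv$u, right = obs$sv$v,
                 scores_x = obs$sx, scores_y = obs$sy,
                 species = rownames(blockX), r_perm = r_perm,
                 n_perm = n_perm, seed = seed),
            class = "phylo_pls")
}

#' @export
print.phylo_pls <- function(x, ...) {
  cat("Phylogenetic two-block PLS (Brownian-motion evolutionary covariance)\n")
  cat(sprintf("  r_PLS = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$r_pls, x$p, x$n_perm, x$seed))
  invisible(x)
}

#' @export
plot.phylo_pls <- function(x, ...) {
  graphics::plot(x$scores_x, x$scores_y,
                 xlab = "Block 1, singular axis 1",
                 ylab = "Block 2, singular axis 1", pch = 19, ...)
  if (!is.null(x$species))
    graphics::text(x$scores_x, x$scores_y, x$species, pos = 3, cex = 0.7)
  graphics::abline(stats::lm(x$scores_y ~ x$scores_x), col = "grey60")
  invisible(x)
}

#' Phylomorphospace projection
#'
#' Maps a phylogeny into a morphospace: ancestral scores are reconstructed by
#' weighted squared-change parsimony from the species scores, giving the
#' branch segments to draw over an ordination.
#'
#' @param tree rooted [ape::phylo] tree whose tips match the morphospace
#'   species labels (originals only for a mirrored space).
#' @param space a `morphospace`.
#' @param pcs which score columns to project (default all).
#' @return A list of class `phylomorphospace` with `tip_scores`,
#'   `node_scores`, `edges` (the tree's edge matrix), `tree`.
#' @export
phylomorphospace <- function(tree, space, pcs = NULL) {
  stopifnot(inherits(space, "morphospace"))
  sc <- space$scores
  lab <- space$labels
  if (!is.null(space$mirror)) {
    sc <- sc[!space$mirror, , drop = FALSE]
    lab <- lab[!space$mirror]
  }
  rownames(sc) <- lab
  if (!setequal(lab, tree$tip.label))
    stop("morphospace species do not match tree tips")
  if (is.null(pcs)) pcs <- seq_len(ncol(sc))
  sc <- sc[tree$tip.label, pcs, drop = FALSE]
  fitp <- squared_change_parsimony(tree, sc)
  structure(list(tip_scores = sc, node_scores = fitp$ancestral,
                 edges = tree$edge, tree = tree, Q = fitp$Q),
            class = "phylomorphospace")
}

#' @export
plot.phylomorphospace <- function(x, pcs = c(1, 2), ...) {
  all_sc <- rbind(x$tip_scores[, pcs, drop = FALSE],
                  x$node_scores[, pcs, drop = FALSE])
  graphics::plot(all_sc, type = "n", ...)
  graphics::segments(all_sc[x$edges[, 1], 1], all_sc[x$edges[, 1], 2],
                     all_sc[x$edges[, 2], 1], all_sc[x$edges[, 2], 2],
                     col = "grey60")
  nt <- nrow(x$tip_scores)
  graphics::points(all_sc[seq_len(nt), , drop = FALSE], pch = 19, col = "firebrick")
  graphics::text(all_sc[seq_len(nt), , drop = FALSE],
                 rownames(x$tip_scores), pos = 3, cex = 0.7)
  invisible(x)
}
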