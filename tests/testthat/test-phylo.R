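test_that("phylogenetic covariance encodes shared path lengths", {
  C <- phylo_cov(read_newick("(A:1,B:1);"))
  expect_equal(unname(C), diag(2))
  C3 <- phylo_cov(read_newick("((A:1,B:1):0.5,C:1.5);"))
  expect_equal(C3["A", "B"], 0.5)
  expect_equal(C3["A", "A"], 1.5)
  expect_equal(C3["A", "C"], 0)
  Cs <- phylo_cov(read_newick("(A:1,B:1,C:1,D:1);"))
  expect_equal(unname(Cs), diag(4))
  # symmetric positive semidefinite
  expect_equal(C3, t(C3))
  expect_true(all(eigen(C3, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
})

test_that("squared-change parsimony solves the textbook cases", {
  f <- squared_change_parsimony(read_newick("(A:1,B:1);"),
                                matrix(c(0, 2), dimnames = list(c("A", "B"), NULL)))
  expect_equal(unname(f$ancestral[1, 1]), 1)
  expect_equal(f$Q, 2)
  f3 <- squared_change_parsimony(read_newick("(A:1,B:1,C:1);"),
                                 matrix(c(0, 3, 6), dimnames = list(c("A", "B", "C"), NULL)))
  expect_equal(unname(f3$ancestral[1, 1]), 3)
  expect_equal(f3$Q, 18)
  # branch-length weighting: minimize a^2/1 + (3-a)^2/2
  fw <- squared_change_parsimony(read_newick("(A:1,B:2);"),
                                 matrix(c(0, 3), dimnames = list(c("A", "B"), NULL)))
  expect_equal(unname(fw$ancestral[1, 1]), 1)
  expect_equal(fw$Q, 3)
  expect_equal(optim_scp_q(read_newick("(A:1,B:2);"),
                           matrix(c(0, 3), dimnames = list(c("A", "B"), NULL))),
               3, tolerance = 1e-8)
  # identical tips give Q = 0
  f0 <- squared_change_parsimony(read_newick("(A:1,B:1);"),
                                 matrix(c(5, 5), dimnames = list(c("A", "B"), NULL)))
  expect_equal(f0$Q, 0)
})

test_that("ancestral states match BM maximum likelihood and optimality holds", {
  skip_if_not_installed("phytools")
  set.seed(51)
  for (i in 1:5) {
    tr <- ape::rtree(7)
    x <- stats::setNames(rnorm(7), tr$tip.label)
    f <- squared_change_parsimony(tr, as.matrix(x))
    fa <- phytools::fastAnc(tr, x)
    expect_equal(unname(f$ancestral[, 1]), unname(as.numeric(fa)),
                 tolerance = 1e-8)
  }
})

test_that("Q is invariant to orthogonal rotation of multivariate tip data", {
  set.seed(52)
  tr <- ape::rtree(9)
  X <- matrix(rnorm(9 * 4), 9, 4, dimnames = list(tr$tip.label, NULL))
  Q1 <- squared_change_parsimony(tr, X)$Q
  R <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  Q2 <- squared_change_parsimony(tr, X %*% R)$Q
  expect_equal(Q1, Q2, tolerance = 1e-10)
})

test_that("signal test handles symmetric and degenerate cases by tie counting", {
  set.seed(53)
  st <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  X <- matrix(rnorm(5), dimnames = list(LETTERS[1:5], NULL))
  s <- phylo_signal_test(st, X, n_perm = 99, seed = 7)
  expect_equal(s$p, 1)
  tr <- simulate_tree(6, seed = 53)
  const <- matrix(2, 6, 3, dimnames = list(tr$tip.label, NULL))
  s0 <- phylo_signal_test(tr, const, n_perm = 99, seed = 7)
  expect_equal(s0$p, 1)
  expect_lt(s0$Q_obs, 1e-10)
})

test_that("signal test is powerful under BM and calibrated under iid data", {
  tr <- ape::stree(19, "right")
  tr$edge.length <- rep(1, nrow(tr$edge))
  set.seed(54)
  p_bm <- replicate(40, {
    X <- bm_tips(tr, D = 2)
    phylo_signal_test(tr, X, n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gte(mean(p_bm <= 0.05), 0.8)
  p_iid <- replicate(60, {
    X <- matrix(rnorm(19 * 2), 19, 2, dimnames = list(tr$tip.label, NULL))
    phylo_signal_test(tr, X, n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(p_iid <= 0.05), 0.0 - 1e-9)
  expect_lt(mean(p_iid <= 0.05), 0.2)
})

test_that("signal test is reproducible given its seed", {
  set.seed(55)
  tr <- simulate_tree(10, seed = 55)
  X <- bm_tips(tr, D = 3)
  s1 <- phylo_signal_test(tr, X, n_perm = 199, seed = 99)
  s2 <- phylo_signal_test(tr, X, n_perm = 199, seed = 99)
  expect_identical(s1$p, s2$p)
  expect_identical(s1$Q_perm, s2$Q_perm)
})

test_that("GLS mean reduces to the arithmetic mean for a star and solves by hand", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  expect_equal(phylo_gls_mean(diag(3), X), colMeans(X))
  Xc <- matrix(7, 3, 1)
  C3 <- phylo_cov(read_newick("((A:1,B:1):0.5,C:1.5);"))
  expect_equal(phylo_gls_mean(C3, Xc), 7)
  # hand-solved weighted mean: tips A,B weight 1/2 each, C weight 2/3
  expect_equal(phylo_gls_mean(C3, matrix(c(0, 0, 6))),
               (6 * (2 / 3)) / (1 / 2 + 1 / 2 + 2 / 3))
})

test_that("phylogenetic PLS detects self-covariation and respects the star reduction", {
  set.seed(56)
  tr <- simulate_tree(14, seed = 56)
  X <- bm_tips(tr, D = 5)
  self <- phylo_pls(tr, X, X, n_perm = 99, seed = 1)
  expect_equal(self$r_pls, 1, tolerance = 1e-10)
  expect_equal(self$p, 1 / 100)
  st <- ape::stree(14, "star")
  st$edge.length <- rep(1, 14)
  Xs <- matrix(rnorm(14 * 6), 14, 6, dimnames = list(st$tip.label, NULL))
  Ys <- matrix(rnorm(14 * 4), 14, 4, dimnames = list(st$tip.label, NULL))
  pp <- phylo_pls(st, Xs, Ys, n_perm = 9, seed = 1)
  expect_equal(pp$r_pls, plain_pls_r(Xs, Ys), tolerance = 1e-10)
})

test_that("phylogenetic PLS is invariant to per-block orthogonal rotations", {
  set.seed(57)
  tr <- simulate_tree(12, seed = 57)
  X <- bm_tips(tr, D = 4)
  Y <- bm_tips(tr, D = 5)
  r0 <- phylo_pls(tr, X, Y, n_perm = 9, seed = 3)$r_pls
  Rx <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  Ry <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  r1 <- phylo_pls(tr, X %*% Rx, Y %*% Ry, n_perm = 9, seed = 3)$r_pls
  expect_equal(r0, r1, tolerance = 1e-10)
})

test_that("phylogenetic PLS validates species matching", {
  set.seed(58)
  tr <- simulate_tree(6, seed = 58)
  X <- bm_tips(tr, D = 2)
  Y <- X
  rownames(Y)[1] <- "nosuch"
  expect_error(phylo_pls(tr, X, Y, n_perm = 9), "mismatch.*nosuch")
})

test_that("phylomorphospace reconstructs ancestor scores over an asymmetric ordination", {
  set.seed(59)
  p <- sim_params(n_species = 6, n_individuals = 4, n_replicates = 1, seed = 59)
  tr <- simulate_tree(6, seed = 59)
  tt <- simulate_dataset(simulate_species_means(tr, p), p)
  sm <- species_asymmetry_means(tt$dataset, default_symmetry_map(7))
  ap <- asymmetric_pca(sm)
  pm <- phylomorphospace(tr, ap)
  expect_equal(nrow(pm$node_scores), tr$Nnode)
  expect_equal(nrow(pm$tip_scores), 6)
  # root state of a single dimension equals the SCP solution
  f <- squared_change_parsimony(tr, pm$tip_scores[, 1, drop = FALSE])
  expect_equal(pm$node_scores[1, 1], f$ancestral[1, 1], tolerance = 1e-10)
})
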