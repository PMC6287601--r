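test_that("center_scale removes location and size and reports centroid size", {
  A <- matrix(c(0, 0, 2, 0, 0, 2), ncol = 2, byrow = TRUE)
  z <- center_scale(A)
  expect_equal(z$centroid_size, sqrt(sum(scale(A, scale = FALSE)^2)))
  expect_equal(colMeans(z$config), c(0, 0), tolerance = 1e-12)
  expect_equal(sum(z$config^2), 1, tolerance = 1e-12)
  # idempotence on an already unit-size centered configuration
  z2 <- center_scale(z$config)
  expect_equal(z2$config, z$config, tolerance = 1e-12)
  expect_equal(z2$centroid_size, 1, tolerance = 1e-12)
  expect_error(center_scale(matrix(1, 3, 2)), "degenerate")
})

test_that("optimal rotation recovers a known rotation exactly", {
  set.seed(21)
  A <- center_scale(random_config(5))$config
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  B <- A %*% R
  fit <- optimal_rotation(A, B)
  expect_equal(sum((fit$rotated - B)^2), 0, tolerance = 1e-20)
  expect_equal(abs(fit$angle), pi / 2, tolerance = 1e-10)
  same <- optimal_rotation(A, A)
  expect_equal(same$rotation, diag(2), tolerance = 1e-12)
  expect_error(optimal_rotation(A, A[1:4, ]), "same landmarks")
})

test_that("rotation-only fit of a mirrored target stays proper and matches grid search", {
  set.seed(22)
  A <- center_scale(random_config(5))$config
  B <- A
  B[, 1] <- -B[, 1]  # mirror image of a non-symmetric shape
  fit <- optimal_rotation(A, B)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  resid <- sqrt(sum((fit$rotated - B)^2))
  expect_gt(resid, 0.1)
  # brute-force oracle over a fine rotation grid
  oracle <- grid_procrustes_distance(A, B, step = 2 * pi / 36000)
  expect_equal(resid, oracle, tolerance = 1e-5)
})

test_that("GPA aligns copies of one shape to zero residual and a matching consensus", {
  set.seed(23)
  A <- random_config(7)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  copies <- list(A, 3 * A %*% R + 5, 0.2 * A %*% t(R) - 1)
  fit <- gpa(copies)
  d <- apply(fit$aligned, 3, function(x) sqrt(sum((x - fit$consensus)^2)))
  expect_lt(max(d), 1e-8)
  expect_true(fit$converged)
})

test_that("GPA invariants: unit sizes, consensus = mean, rotation invariance", {
  set.seed(24)
  cfgs <- lapply(1:10, function(i) base_lobe_shape(7) + random_config(7, sd = 0.05))
  fit <- gpa(cfgs)
  sizes <- apply(fit$aligned, 3, function(x) sqrt(sum(x^2)))
  cents <- apply(fit$aligned, 3, colMeans)
  expect_lt(max(abs(sizes - 1)), 1e-9)
  expect_lt(max(abs(cents)), 1e-9)
  expect_equal(apply(fit$aligned, c(1, 2), mean) /
                 sqrt(sum(apply(fit$aligned, c(1, 2), mean)^2)),
               fit$consensus, tolerance = 1e-6)
  # a globally rotated dataset yields identical pairwise aligned distances
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fit2 <- gpa(lapply(cfgs, function(x) x %*% R))
  d1 <- dist(t(apply(fit$aligned, 3, as.numeric)))
  d2 <- dist(t(apply(fit2$aligned, 3, as.numeric)))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-8)
})

test_that("GPA consensus is a fixed point under one extra iteration", {
  set.seed(25)
  cfgs <- lapply(1:10, function(i) random_config(7))
  fit <- gpa(cfgs, principal_axes = FALSE)
  rot <- lapply(seq_len(fit$n), function(i)
    optimal_rotation(fit$aligned[, , i], fit$consensus)$rotated)
  m <- Reduce(`+`, rot) / fit$n
  m <- m / sqrt(sum(m^2))
  expect_lt(max(abs(m - fit$consensus)), 1e-6)
})

test_that("Procrustes distance is a similarity-invariant semimetric", {
  set.seed(26)
  A <- random_config(6)
  expect_equal(procrustes_distance(A, A), 0, tolerance = 1e-12)
  th <- -0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(procrustes_distance(A, 2.5 * A %*% R + 3), 0, tolerance = 1e-10)
  B <- random_config(6)
  expect_equal(procrustes_distance(A, B), procrustes_distance(B, A),
               tolerance = 1e-12)
})

test_that("Procrustes distance matches the rotation-grid oracle", {
  set.seed(27)
  A <- random_config(4)
  B <- random_config(4)
  expect_equal(procrustes_distance(A, B), grid_procrustes_distance(A, B),
               tolerance = 1e-5)
})

test_that("Procrustes distance obeys the triangle inequality on random triples", {
  set.seed(28)
  for (i in 1:20) {
    A <- random_config(5); B <- random_config(5); C <- random_config(5)
    expect_lte(procrustes_distance(A, C),
               procrustes_distance(A, B) + procrustes_distance(B, C) + 1e-10)
  }
})

test_that("tangent projection is centered and tracks Procrustes distance", {
  set.seed(29)
  cfgs <- lapply(1:12, function(i) base_lobe_shape(7) + random_config(7, sd = 0.01))
  fit <- gpa(cfgs)
  tp <- tangent_project(fit)
  expect_lt(max(abs(colMeans(tp))), 1e-6)
  # the consensus itself maps to the zero vector
  fitc <- gpa(c(cfgs, list(fit$consensus)))
  tpc <- tangent_project(fitc)
  expect_lt(sqrt(sum(tpc[13, ]^2)),
            1e-4 * max(sqrt(rowSums(tpc^2))))
  # small variation: tangent distances approximate Procrustes distances
  td <- as.matrix(dist(unclass(tp)))
  for (i in 1:4) for (j in (i + 1):5) {
    pd <- procrustes_distance(cfgs[[i]], cfgs[[j]])
    expect_lt(abs(td[i, j] - pd), 1e-3 * pd + 1e-8)
  }
})
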