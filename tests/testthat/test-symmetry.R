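test_that("symmetry maps validate their partition of landmarks", {
  m <- symmetry_map(cbind(c(1, 2, 3), c(7, 6, 5)), axis = 4, k = 7)
  expect_s3_class(m, "symmetry_map")
  expect_error(symmetry_map(cbind(1, 2), axis = 2, k = 3), "twice|partition")
  expect_error(symmetry_map(cbind(1, 2), axis = integer(0), k = 3), "partition")
  m15 <- default_symmetry_map(15)
  expect_equal(m15$pairs[, 2], 15:9)
  expect_equal(m15$axis, 8L)
})

test_that("reflect_relabel negates x, swaps pair labels, and is an involution", {
  m3 <- symmetry_map(cbind(1, 3), axis = 2, k = 3)
  cfg <- matrix(c(-1, 0.2, 0, 1, 1, 0), ncol = 2, byrow = TRUE)
  out <- reflect_relabel(cfg, m3)
  expect_equal(out, matrix(c(-1, 0, 0, 1, 1, 0.2), ncol = 2, byrow = TRUE))
  # fixed point on a perfectly symmetric configuration
  m <- default_symmetry_map(7)
  base <- base_lobe_shape(7)
  expect_equal(reflect_relabel(base, m), base, tolerance = 1e-12)
  # involution on random configurations
  set.seed(31)
  for (i in 1:10) {
    cfg <- random_config(7)
    expect_identical(reflect_relabel(reflect_relabel(cfg, m), m), cfg)
  }
  expect_error(reflect_relabel(random_config(5), m), "landmarks")
})

test_that("joint symmetry GPA yields an exactly symmetric consensus", {
  set.seed(32)
  p <- sim_params(n_species = 3, n_individuals = 4, n_replicates = 2, seed = 32)
  tt <- simulate_dataset(simulate_species_means(simulate_tree(3, 32), p), p)
  m <- default_symmetry_map(7)
  fit <- joint_symmetry_gpa(tt$dataset, m)
  expect_lt(max(abs(fit$consensus - reflect_relabel(fit$consensus, m))), 1e-8)
  # reflected twins of symmetric configurations align onto their originals
  base <- base_lobe_shape(7)
  sym_ds <- landmark_dataset(array(rep(base, 4), c(7, 2, 4)),
                             rep("s", 4), rep(c("s_i1", "s_i2"), each = 2),
                             rep(1:2, 2))
  fs <- joint_symmetry_gpa(sym_ds, m)
  expect_lt(max(abs(fs$aligned[, , 1] - fs$aligned[, , 5])), 1e-9)
})

test_that("symmetric/asymmetric components reconstruct, transform, and scale correctly", {
  set.seed(33)
  p <- sim_params(n_species = 4, n_individuals = 5, n_replicates = 2, seed = 33)
  tt <- simulate_dataset(simulate_species_means(simulate_tree(4, 33), p), p)
  m <- default_symmetry_map(7)
  fit <- joint_symmetry_gpa(tt$dataset, m)
  co <- symmetry_components(fit)
  # exact reconstruction at machine precision
  expect_lt(max(abs(co$symmetric + co$asymmetric - co$aligned)), 1e-12)
  # invariance / anti-invariance under reflect-relabel
  Tm <- lobesym:::reflect_operator(m)
  expect_lt(max(abs(co$symmetric %*% t(Tm) - co$symmetric)), 1e-9)
  expect_lt(max(abs(co$asymmetric %*% t(Tm) + co$asymmetric)), 1e-9)
  # Procrustes distance original-to-mirror is twice the asymmetric norm
  n <- fit$n_orig
  for (i in 1:3) {
    d <- procrustes_distance(fit$aligned[, , i], fit$aligned[, , n + i])
    expect_equal(d, 2 * sqrt(sum(co$asymmetric[i, ]^2)), tolerance = 1e-4)
  }
})

test_that("a constructed small asymmetric offset is recovered by decomposition", {
  m <- default_symmetry_map(7)
  base <- base_lobe_shape(7)
  delta <- asym_direction(m, 0.01)
  n <- 4
  coords <- array(rep(base + delta, n), c(7, 2, n))
  ds <- landmark_dataset(coords, rep("s", n), sprintf("s_i%d", 1:n), rep(1L, n))
  fit <- joint_symmetry_gpa(ds, m)
  co <- symmetry_components(fit)
  expect_lt(max(abs(co$asymmetric[1, ] - lobesym:::flatten_config(delta))), 1e-6)
})

test_that("noise-free pure-positional data put all variance in the positional row", {
  ds <- pure_positional_dataset(n = 6, r = 2)
  an <- symmetry_anova(ds, default_symmetry_map(7), n_perm = 99, seed = 2)
  expect_equal(an$table["positional_asymmetry", "Rsq"], 1, tolerance = 1e-9)
  expect_lt(an$table["fluctuating_asymmetry", "MS"], 1e-16)
  expect_lt(an$table["measurement_error", "MS"], 1e-16)
})

test_that("noise-free pure-individual data put all variance in the individuals row", {
  set.seed(35)
  ds <- pure_individual_dataset(n = 6, r = 2)
  an <- symmetry_anova(ds, default_symmetry_map(7), n_perm = 99, seed = 2)
  expect_equal(an$table["individuals", "Rsq"], 1, tolerance = 1e-9)
})

test_that("ANOVA sums of squares are additive with the stated degrees of freedom", {
  set.seed(36)
  p <- sim_params(n_species = 2, n_individuals = 8, n_replicates = 3, seed = 36)
  tt <- simulate_dataset(simulate_species_means(simulate_tree(2, 36), p), p)
  m <- default_symmetry_map(7)
  ds <- lobesym:::dataset_for_species(tt$dataset, "t1")
  an <- symmetry_anova(ds, m, n_perm = 19, seed = 1)
  expect_equal(sum(an$table$Rsq), 1, tolerance = 1e-9)
  # k = 7, p = 3 pairs, u = 1 axis point: d_s = d_a = 5
  n <- an$n; r <- an$r
  expect_equal(an$table$df, c((n - 1) * 5, 5, (n - 1) * 5, n * (r - 1) * 10))
})

test_that("ANOVA rejects unbalanced designs and silly permutation counts", {
  ds <- pure_positional_dataset(n = 3, r = 2)
  keep <- !(ds$specimen == "sp1_i01" & ds$replicate == 2L)
  unb <- landmark_dataset(ds$coords[, , keep, drop = FALSE], ds$species[keep],
                          ds$specimen[keep], ds$replicate[keep])
  expect_error(symmetry_anova(unb, default_symmetry_map(7)), "unbalanced")
  expect_error(symmetry_anova(ds, default_symmetry_map(7), n_perm = 0), "n_perm")
})

test_that("measurement error mean square matches its expectation under pure noise", {
  # digitization noise only: E[MS_error] = 2 * sigma_me^2 in the doubled layout
  m <- default_symmetry_map(7)
  sig <- 0.004
  set.seed(37)
  ms <- replicate(30, {
    p <- sim_params(n_species = 2, n_individuals = 8, n_replicates = 2,
                    sigma2_sym = 0, sigma2_asym = 0, sigma_ind = 0,
                    sigma_fa = 0, sigma_me = sig, seed = sample.int(1e6, 1))
    tt <- simulate_dataset(simulate_species_means(simulate_tree(2, 37), p), p,
                           seed = sample.int(1e6, 1))
    ds <- lobesym:::dataset_for_species(tt$dataset, "t1")
    symmetry_anova(ds, m, n_perm = 1, seed = 1)$table["measurement_error", "MS"]
  })
  expect_equal(mean(ms), 2 * sig^2, tolerance = 0.1)
})

test_that("species asymmetry means recover sign-opposed asymmetries", {
  m <- default_symmetry_map(7)
  base <- base_lobe_shape(7)
  delta <- asym_direction(m, 0.05)
  n <- 8
  coords <- array(0, c(7, 2, 2 * n))
  for (i in 1:n) {
    coords[, , i] <- base + delta
    coords[, , n + i] <- base - delta
  }
  ds <- landmark_dataset(coords, rep(c("plus", "minus"), each = n),
                         c(sprintf("plus_i%d", 1:n), sprintf("minus_i%d", 1:n)),
                         rep(1L, 2 * n))
  sm <- species_asymmetry_means(ds, m)
  a_plus <- sm$asymmetry["plus", ]
  a_minus <- sm$asymmetry["minus", ]
  expect_equal(sqrt(sum(a_plus^2)), sqrt(sum(a_minus^2)), tolerance = 1e-6)
  cosang <- sum(a_plus * a_minus) / sqrt(sum(a_plus^2) * sum(a_minus^2))
  expect_equal(cosang, -1, tolerance = 1e-6)
  # mirrored mean's asymmetric component is the negation of the original's
  mir_vec <- lobesym:::project_asymmetric(
    rbind(lobesym:::flatten_config(sm$mirrored[, , "plus"])), m)
  expect_equal(mir_vec[1, ], -a_plus, tolerance = 1e-9, ignore_attr = TRUE)
  # a perfectly symmetric species equals its own mirror
  sym_ds <- landmark_dataset(array(rep(base, 4), c(7, 2, 4)), rep("s", 4),
                             sprintf("s_i%d", 1:4), rep(1L, 4))
  sms <- species_asymmetry_means(sym_ds, m)
  expect_lt(max(abs(sms$mean[, , 1] - sms$mirrored[, , 1])), 1e-8)
})
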