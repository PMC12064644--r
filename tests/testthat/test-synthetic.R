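test_that("noise-free generation collapses workers onto population means", {
  cfg <- synthetic_config(n_populations = 2, colonies_per_population = 3,
                          workers_per_colony = 4, pairwise_D = 5,
                          colony_sd = 0, worker_sd = 0, digitization_sd = 0,
                          latitude_gradient = 0, seed = 1)
  sim <- simulate_dataset(cfg)
  fit <- align_gpa(sim$dataset)
  pops <- fit$meta$population
  for (p in unique(pops)) {
    rows <- fit$aligned[pops == p, ]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-6)
  }
})

test_that("generation is byte-reproducible from the seed", {
  cfg <- synthetic_config(n_populations = 2, colonies_per_population = 4,
                          workers_per_colony = 3, seed = 7)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$coords, s2$dataset$coords)
  expect_identical(s1$dataset$meta, s2$dataset$meta)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(s1$dataset, p1)
  write_landmarks_csv(s2$dataset, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # different seed, different data
  s3 <- simulate_dataset(synthetic_config(n_populations = 2,
                                          colonies_per_population = 4,
                                          workers_per_colony = 3, seed = 8))
  expect_false(identical(s1$dataset$coords, s3$dataset$coords))
})

test_that("generated configurations are never degenerate", {
  sim <- simulate_dataset(synthetic_config(n_populations = 2,
                                           colonies_per_population = 5,
                                           workers_per_colony = 4,
                                           digitization_sd = 0.05, seed = 9))
  sizes <- apply(sim$dataset$coords, 1, centroid_size)
  expect_true(all(sizes > 0.1))
})

test_that("population effects live in the tangent space with exact separations", {
  cfg <- synthetic_config(n_populations = 4, pairwise_D = 6, seed = 10)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  q <- wingmorph:::similarity_basis(tr$template)
  # offsets orthogonal to translation/rotation/scale generators
  expect_lt(max(abs(crossprod(q, tr$population_means))), 1e-9)
  expect_lt(max(abs(crossprod(q, tr$gradient))), 1e-9)
  # pairwise offset norms equal D * colony-mean sd
  for (a in 1:3) for (b in (a + 1):4) {
    expect_equal(sqrt(sum((tr$population_means[, a] -
                           tr$population_means[, b])^2)),
                 6 * tr$colony_mean_sd, tolerance = 1e-9)
  }
  expect_equal(unname(tr$true_pairwise_D[1, 2]), 6)
  expect_equal(tr$true_pairwise_D, t(tr$true_pairwise_D))
  expect_equal(unname(diag(tr$true_pairwise_D)), rep(0, 4))
})

test_that("estimated Mahalanobis separation tracks the generator truth", {
  sim <- simulate_dataset(synthetic_config(n_populations = 3,
                                           colonies_per_population = 100,
                                           pairwise_D = 6, seed = 11))
  fit <- align_gpa(sim$dataset)
  st <- average_within_groups(fit, "colony_id")
  pca <- shape_pca(st$mean_shapes, m_retain = 34)
  d <- mahalanobis_pairwise(fit_lda(pca$scores, st$meta$population))
  expect_lt(mean(abs(d[upper.tri(d)] - 6) / 6), 0.2)
})

test_that("zero population effect yields chance-level cross-validation", {
  sim <- simulate_dataset(synthetic_config(n_populations = 2,
                                           colonies_per_population = 40,
                                           workers_per_colony = 6,
                                           pairwise_D = 0,
                                           latitude_gradient = 0, seed = 12))
  fit <- align_gpa(sim$dataset)
  st <- average_within_groups(fit, "colony_id")
  pca <- shape_pca(st$mean_shapes, m_retain = 20)
  acc <- loocv_lda(pca$scores, st$meta$population)$overall_accuracy
  expect_lt(abs(acc - 0.5), 2.58 * sqrt(0.25 / 80) + 0.1)
})

test_that("a strong latitude gradient is detected at the permutation floor", {
  sim <- simulate_dataset(synthetic_config(n_populations = 1,
                                           colonies_per_population = 60,
                                           latitude_gradient = 0.03,
                                           seed = 13))
  fit <- align_gpa(sim$dataset)
  st <- average_within_groups(fit, "colony_id")
  reg <- regress_shape_rrpp(st$mean_shapes,
                            st$meta[, c("latitude", "longitude")],
                            n_perm = 999, seed = 14)
  expect_equal(reg$aov_table$p_perm[1], 0.001)
})

test_that("hybrid draws interpolate between parental mean shapes", {
  cfg <- synthetic_config(n_populations = 2, colonies_per_population = 5,
                          pairwise_D = 8, seed = 15)
  sim <- simulate_dataset(cfg)
  expect_error(inject_hybrids(sim$truth, c("pop_1", "pop_2"), alpha = 1.2,
                              n = 5), "alpha")
  expect_error(inject_hybrids(sim$truth, c("pop_1", "nope"), alpha = 0.5,
                              n = 5), "parents")
  hyb <- inject_hybrids(sim$truth, c("pop_1", "pop_2"), alpha = 0.5,
                        n = 200, seed = 16)
  mean_h <- colMeans(hyb$coords)
  m1 <- sim$truth$template + sim$truth$population_means[, "pop_1"]
  m2 <- sim$truth$template + sim$truth$population_means[, "pop_2"]
  d1 <- procrustes_distance(mean_h, m1)
  d2 <- procrustes_distance(mean_h, m2)
  expect_equal(d1, d2, tolerance = 0.05)
  # alpha = 1 reproduces parent 1's mean within Monte Carlo error
  pure <- inject_hybrids(sim$truth, c("pop_1", "pop_2"), alpha = 1,
                         n = 200, seed = 17)
  expect_lt(procrustes_distance(colMeans(pure$coords), m1),
            3 * sim$truth$worker_sd / sqrt(200) * sqrt(38))
})

test_that("the full pipeline recovers the true number of populations", {
  sim <- simulate_dataset(synthetic_config(n_populations = 5,
                                           colonies_per_population = 60,
                                           pairwise_D = 6, seed = 18))
  fit <- align_gpa(sim$dataset)
  st <- average_within_groups(fit, "colony_id")
  pca <- shape_pca(st$mean_shapes, m_retain = 34)
  m_clust <- variance_threshold_components(pca$eigenvalues, 0.95)
  best <- select_model_bic(pca$scores[, seq_len(m_clust)], K_range = 1:9,
                           seed = 19)
  expect_equal(best$K, 5)
  expect_gt(cluster_agreement(max.col(best$responsibilities),
                              st$meta$population), 0.95)
})
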