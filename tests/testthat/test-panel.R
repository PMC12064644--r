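# Synthetic lineage reference: populations play the role of the four
# evolutionary lineages (A, C, M, O). No real reference coordinates are
# used anywhere.
make_lineage_reference <- function(pairwise_D = 8, colonies = 20, seed = 1) {
  cfg <- synthetic_config(n_populations = 4,
                          colonies_per_population = colonies,
                          workers_per_colony = 6,
                          pairwise_D = pairwise_D,
                          latitude_gradient = 0, seed = seed)
  sim <- simulate_dataset(cfg)
  fit <- align_gpa(sim$dataset)
  st <- average_within_groups(fit, "colony_id")
  lineage <- c(pop_1 = "A", pop_2 = "C", pop_3 = "M", pop_4 = "O")
  labels <- lineage[st$meta$population]
  list(fit = fit, samples = st, labels = labels, sim = sim,
       lineage_of = lineage)
}

test_that("a panel from well-separated lineages self-classifies correctly", {
  ref <- make_lineage_reference(pairwise_D = 8, seed = 21)
  panel <- build_panel(ref$samples$mean_shapes, ref$labels,
                       consensus = ref$fit$consensus)
  self <- assign_lineages(panel, ref$samples, already_aligned = TRUE)
  expect_gte(mean(self$predicted == ref$labels), 0.99)
  expect_equal(rowSums(as.matrix(self[, panel$classes])), rep(1, nrow(self)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(build_panel(ref$fit, rep("A", n_specimens(ref$sim$dataset))),
               "2 lineages")
})

test_that("panels round trip losslessly through the text format", {
  ref <- make_lineage_reference(seed = 22, colonies = 8)
  panel <- build_panel(ref$samples$mean_shapes, ref$labels,
                       consensus = ref$fit$consensus)
  path <- withr::local_tempfile(fileext = ".txt")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_identical(back$classes, panel$classes)
  expect_identical(back$basis, unname(panel$basis))
  expect_identical(drop(back$consensus), unname(panel$consensus))
  expect_identical(back$model$pooled_cov, unname(panel$model$pooled_cov))
  # identical assignment behavior
  unknown <- ref$samples$mean_shapes[3, ]
  expect_equal(assign_lineages(back, unknown, already_aligned = TRUE)[, back$classes],
               assign_lineages(panel, unknown, already_aligned = TRUE)[, panel$classes])
  expect_error(read_panel(withr::local_tempfile(lines = "nope")),
               "panel file")
})

test_that("assignment is invariant to rigid motion and scaling of the unknown", {
  ref <- make_lineage_reference(seed = 23, colonies = 10)
  panel <- build_panel(ref$samples$mean_shapes, ref$labels,
                       consensus = ref$fit$consensus)
  raw <- wingmorph:::config_matrix(ref$sim$dataset$coords[5, ])
  p1 <- assign_lineages(panel, raw)
  moved <- similarity_transform(raw, angle = 2.2, scale = 0.31, shift = c(8, -3))
  p2 <- assign_lineages(panel, moved)
  expect_equal(as.numeric(p1[, panel$classes]), as.numeric(p2[, panel$classes]),
               tolerance = 1e-6)
  # probability ranking preserves the raw density ranking (monotone rescaling)
  sc <- sweep(matrix(align_to_consensus(raw, panel$consensus), 1), 2,
              panel$center) %*% panel$basis
  cl <- classify_lda(panel$model, sc)
  expect_true(all(diff(cl$probabilities[1, order(cl$d2[1, ])]) <= 0))
  expect_equal(which.max(cl$probabilities[1, ]), which.min(cl$d2[1, ]))
  # wrong landmark count is rejected
  expect_error(assign_lineages(panel, matrix(rnorm(10), 5, 2)), "expects")
})

test_that("an unknown at a lineage mean is assigned to it; midpoints split", {
  set.seed(24)
  # direct score-space check of the classifier the panel uses
  x <- rbind(matrix(rnorm(30), ncol = 2),
             sweep(matrix(rnorm(30), ncol = 2), 2, -c(6, 0)))
  m <- fit_lda(x, rep(c("A", "C"), each = 15))
  mid <- colMeans(m$class_means)
  expect_equal(unname(classify_lda(m, mid)$probabilities[1, ]), c(0.5, 0.5),
               tolerance = 1e-9)
  at_a <- classify_lda(m, m$class_means["A", ])$probabilities
  expect_gt(at_a[1, "A"], 0.99)
})

test_that("hybrids are assigned to the majority parent with elevated minor probability", {
  ref <- make_lineage_reference(pairwise_D = 6, seed = 25)
  panel <- build_panel(ref$samples$mean_shapes, ref$labels,
                       consensus = ref$fit$consensus)
  hyb <- inject_hybrids(ref$sim$truth, c("pop_1", "pop_2"), alpha = 0.7,
                        n = 40, seed = 26)
  ha <- assign_lineages(panel, hyb$coords)
  pure <- inject_hybrids(ref$sim$truth, c("pop_1", "pop_2"), alpha = 1,
                         n = 40, seed = 27)
  pa <- assign_lineages(panel, pure$coords)
  expect_gt(mean(ha$predicted == "A"), 0.5)
  expect_gt(mean(ha$C), mean(pa$C))
})

test_that("unknowns drawn from one lineage are predominantly assigned to it", {
  correct <- numeric(10)
  for (s in 1:10) {
    ref <- make_lineage_reference(pairwise_D = 6, colonies = 40,
                                  seed = 300 + s)
    panel <- build_panel(ref$samples$mean_shapes, ref$labels,
                         consensus = ref$fit$consensus)
    # unknowns are sample means, as in field use: 6-worker averages
    draws <- inject_hybrids(ref$sim$truth, c("pop_1", "pop_2"), alpha = 1,
                            n = 180, seed = 400 + s)
    unknown_means <- rowsum(draws$coords, rep(1:30, each = 6)) / 6
    pa <- assign_lineages(panel, unknown_means)
    correct[s] <- mean(pa$predicted == "A")
  }
  expect_gte(mean(correct), 0.95)
})

test_that("assignment summaries produce per-population percentages", {
  pred <- c(rep("A", 17), "C",
            rep("A", 70), rep("C", 3), "O")
  pop <- c(rep("Argentina", 18), rep("Ecuador", 74))
  s <- summarize_assignments(pred, pop)
  expect_equal(unname(rowSums(s$percent)), c(100, 100), tolerance = 1e-9)
  expect_equal(s$counts["Ecuador", "O"], 1L, ignore_attr = TRUE)
  expect_equal(sum(s$overall_percent), 100, tolerance = 1e-9)
  all_a <- summarize_assignments(rep("A", 10), rep("x", 10))
  expect_equal(unname(all_a$overall_percent), 100)
  expect_error(summarize_assignments(character(0), character(0)), "no assignments")
})
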