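test_that("source community abundances are valid and deterministic", {
  src <- simulate_source_community(2, params = list(sd = 1e-12), seed = 1)
  expect_equal(src$p, c(0.5, 0.5), tolerance = 1e-9)

  a <- simulate_source_community(100, seed = 42)
  b <- simulate_source_community(100, seed = 42)
  expect_identical(a$p, b$p)
  expect_equal(sum(a$p), 1, tolerance = 1e-12)
  expect_true(all(diff(a$p) <= 0))
  expect_true(all(a$p > 0))
  expect_error(simulate_source_community(1), ">= 2")
})

test_that("lognormal source matches an independent draw-and-sort oracle", {
  src <- simulate_source_community(500, params = list(sd = 1.5), seed = 8)
  # oracle: many independent draws of sorted, normalized lognormals
  oracle <- replicate(200, {
    x <- sort(rlnorm(500, 0, 1.5), decreasing = TRUE)
    x / sum(x)
  })
  om <- rowMeans(oracle)
  ose <- apply(oracle, 1, sd)
  # rank-abundance curve within Monte-Carlo error at a spread of ranks
  ranks <- c(1, 5, 20, 100, 400)
  expect_true(all(abs(src$p[ranks] - om[ranks]) <= 4 * ose[ranks]))
})

test_that("neutral metacommunity has fixed depth and no-drift limit", {
  src <- simulate_source_community(50, seed = 2)
  tab <- simulate_neutral_metacommunity(src, m = 1, N = 200000,
                                        n_samples = 5, seed = 2)
  expect_true(all(rowSums(tab$counts) == 200000))
  rel <- relative_abundance(tab)
  # at m = 1 and large N, per-sample compositions approach the source
  se <- sqrt(src$p * (1 - src$p) / 200000)
  dev <- abs(sweep(rel, 2, src$p))
  # Dirichlet(N p) + multinomial gives roughly twice the binomial variance
  expect_true(max(sweep(dev, 2, se, "/")) <= 6)

  a <- simulate_neutral_metacommunity(src, m = 0.1, N = 1000, n_samples = 4,
                                      seed = 9)
  b <- simulate_neutral_metacommunity(src, m = 0.1, N = 1000, n_samples = 4,
                                      seed = 9)
  expect_identical(a$counts, b$counts)
  expect_error(simulate_neutral_metacommunity(src, m = 0, N = 1000, 2), "m")
  expect_error(simulate_neutral_metacommunity(src, m = 0.5, N = 5, 2), "N")
})

test_that("neutral occupancy curve matches the beta-CDF prediction", {
  # the keystone cross-module property linking generator and estimator
  src <- simulate_source_community(300, seed = 7)
  N <- 10000
  m <- 0.1
  tab <- simulate_neutral_metacommunity(src, m = m, N = N, n_samples = 200,
                                        seed = 7)
  occ <- colMeans(tab$counts > 0)
  pred <- ncm_predicted_frequency(src$p, Nm = N * m, d = 1 - 2^(-1 / N))
  expect_lt(mean(abs(occ - pred)), 0.05)
})

test_that("selection generator collapses to neutral sampling as sigma grows", {
  src <- simulate_source_community(80, seed = 3)
  tree <- simulate_birth_death_tree(80, seed = 3,
                                    tip_labels = src$taxon_ids)
  tab <- simulate_selected_metacommunity(src, tree, sigma_sel = 1e6,
                                         env = rep(0, 20), N = 50000,
                                         seed = 3)
  mean_comp <- colMeans(relative_abundance(tab))
  expect_lt(0.5 * sum(abs(mean_comp - src$p)), 0.01)  # total variation
})

test_that("selection weights are deterministic given traits and environment", {
  src <- simulate_source_community(30, seed = 4)
  tree <- simulate_birth_death_tree(30, seed = 4, tip_labels = src$taxon_ids)
  tab <- simulate_selected_metacommunity(src, tree, sigma_sel = 0.5,
                                         env = c(0.3, 0.3, -1), seed = 4)
  W <- attr(tab, "expected")
  expect_identical(W[1, ], W[2, ])
  expect_false(isTRUE(all.equal(W[1, ], W[3, ])))

  bad_tree <- tree
  bad_tree$tip.label[1] <- "NOT_A_TAXON"
  expect_error(simulate_selected_metacommunity(src, bad_tree, 0.5, 0),
               "tip")
})

test_that("pure-birth trees are ultrametric with depth 1", {
  tr2 <- simulate_birth_death_tree(2, seed = 1)
  d2 <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(d2, c(1, 1), tolerance = 1e-12)

  a <- simulate_birth_death_tree(25, seed = 6)
  b <- simulate_birth_death_tree(25, seed = 6)
  expect_identical(ape::write.tree(a), ape::write.tree(b))

  big <- simulate_birth_death_tree(100, seed = 11)
  depths <- ape::node.depth.edgelength(big)[seq_len(100)]
  expect_true(max(abs(depths - 1)) < 1e-9)
  expect_error(simulate_birth_death_tree(1), ">= 2")
})

test_that("noiseless design responses reproduce the generating polynomial", {
  design <- build_bbd_design(cultivation_factors(), n_center = 5)
  truth <- c(50, 2, -3, 1, 0.5, -0.5, 1.5, 4, -2, 3)
  y <- simulate_bbd_responses(design, truth, noise_sd = 0)
  fit <- fit_quadratic(design, y)
  expect_equal(unname(coef(fit)), truth, tolerance = 1e-9)
  expect_error(simulate_bbd_responses(design, truth[-1], 0), "10")
})

test_that("center-point responses equal the fitted intercept of the study model", {
  design <- build_bbd_design(cultivation_factors(), n_center = 5)
  y <- simulate_bbd_responses(design, eq2_coefficients(), noise_sd = 0)
  center <- rowSums(design$coded != 0) == 0
  expect_equal(unname(y[center]), rep(102.80, 5), tolerance = 1e-12)
})

test_that("noisy intercepts are unbiased over replicate simulations", {
  design <- build_bbd_design(cultivation_factors(), n_center = 5)
  truth <- eq2_coefficients()
  b0 <- vapply(1:200, function(s) {
    y <- simulate_bbd_responses(design, truth, noise_sd = 10, seed = s)
    coef(fit_quadratic(design, y))[["(Intercept)"]]
  }, numeric(1))
  se <- sd(b0) / sqrt(length(b0))
  expect_lt(abs(mean(b0) - 102.80), 2 * se + 1e-12)
})

test_that("gene-chip simulation is deterministic and rejects bad folds", {
  a <- small_chip(ct_sd = 0.3, seed = 12)
  b <- small_chip(ct_sd = 0.3, seed = 12)
  expect_identical(a$ct, b$ct)
  expect_error(small_chip(fold = c(1, -2, 0.5)), "fold")
})
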