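test_that("the three-factor design has the textbook structure", {
  design <- build_bbd_design(cultivation_factors(), n_center = 5)
  coded <- design$coded
  expect_equal(nrow(coded), 17)
  expect_equal(unname(colSums(coded)), c(0, 0, 0))
  expect_equal(unname(colSums(coded^2)), c(8, 8, 8))
  # pairwise products: sum of squares 4 per pair, by enumeration
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(sum((coded[, pr[1]] * coded[, pr[2]])^2), 4)
  }
  # 12 distinct edge runs = all (+-1, +-1, 0) permutations
  edges <- coded[rowSums(coded != 0) == 2, ]
  expect_equal(nrow(unique(edges)), 12)
  expect_error(build_bbd_design(bbd_factors("a", 0, 1, 2), 5), "3 factors")
})

test_that("coding maps study levels correctly and decode inverts code", {
  f <- cultivation_factors()
  expect_equal(as.numeric(code_point(f, c(10, 1.0, 30.5))), c(0, 0, 0))
  expect_equal(as.numeric(code_point(f, c(10, 0.5, 30.5)))[2], -1)
  expect_equal(as.numeric(code_point(f, c(10, 1.0, 30.5)))[3], 0)
  set.seed(1)
  for (i in 1:10) {
    x <- c(runif(1, -5, 25), runif(1, 0.2, 2), runif(1, 20, 40))
    expect_equal(as.numeric(decode_point(f, code_point(f, x))), x,
                 tolerance = 1e-12)
  }
})

test_that("quadratic OLS matches a direct normal-equations oracle", {
  design <- build_bbd_design(cultivation_factors(), n_center = 5)
  set.seed(3)
  y <- rnorm(17, mean = 100, sd = 15)
  fit <- fit_quadratic(design, y)
  # oracle: hand-built model matrix + solve of the normal equations
  cc <- design$coded
  X <- cbind(1, cc[, 1], cc[, 2], cc[, 3],
             cc[, 1] * cc[, 2], cc[, 1] * cc[, 3], cc[, 2] * cc[, 3],
             cc[, 1]^2, cc[, 2]^2, cc[, 3]^2)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(coef(fit)), drop(beta_oracle), tolerance = 1e-8)
  # constant response: intercept only
  fitc <- fit_quadratic(design, rep(7.5, 17))
  expect_equal(unname(coef(fitc)), c(7.5, rep(0, 9)), tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  coded <- build_bbd_design(cultivation_factors(), 5)$coded
  coded[, 3] <- coded[, 2]  # temperature duplicates mineral solution
  expect_error(fit_quadratic(coded, rnorm(17)), "collinear")
})

test_that("Type III sums of squares follow beta^2 / c_jj with c_jj = 19/80 for quadratics", {
  design <- build_bbd_design(cultivation_factors(), n_center = 5)
  # oracle: explicit inversion of the 10x10 information matrix
  X <- quadratic_model_matrix(design$coded)
  cjj <- diag(solve(t(X) %*% X))
  expect_equal(unname(cjj[8:10]), rep(19 / 80, 3), tolerance = 1e-12)
  expect_equal(unname(cjj[2:4]), rep(1 / 8, 3), tolerance = 1e-12)
  expect_equal(unname(cjj[5:7]), rep(1 / 4, 3), tolerance = 1e-12)

  set.seed(8)
  y <- rnorm(17, 100, 10)
  fit <- fit_quadratic(design, y)
  av <- anova_type3(fit)
  for (j in 2:10) {
    term <- names(coef(fit))[j]
    expect_equal(av$ss[av$term == term],
                 unname(coef(fit)[j]^2 / cjj[j]), tolerance = 1e-9)
  }
  # residual decomposition and additivity
  expect_equal(av$ss[av$term == "Residual"],
               av$ss[av$term == "Lack of fit"] +
                 av$ss[av$term == "Pure error"], tolerance = 1e-6)
  expect_equal(av$ss[av$term == "Model"] + av$ss[av$term == "Residual"],
               av$ss[av$term == "Cor total"], tolerance = 1e-6)
  expect_equal(av$df[av$term == "Residual"],
               av$df[av$term == "Lack of fit"] +
                 av$df[av$term == "Pure error"])
  # F and p reproduce the F-distribution oracle
  ms_resid <- av$ms[av$term == "Residual"]
  i <- which(av$term == "mineral_solution")
  expect_equal(av$f[i], av$ms[i] / ms_resid, tolerance = 1e-9)
  expect_equal(av$p[i], pf(av$f[i], 1, 7, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("zero coefficients give zero partial SS and noiseless data zero lack of fit", {
  design <- build_bbd_design(cultivation_factors(), n_center = 5)
  truth <- c(80, 0, -5, 0, 0, 0, 2, 0, 3, 0)
  y <- simulate_bbd_responses(design, truth, noise_sd = 0)
  av <- anova_type3(fit_quadratic(design, y))
  zero_terms <- quadratic_model_matrix(design$coded) |> colnames()
  zero_terms <- zero_terms[-1][truth[-1] == 0]
  expect_true(all(abs(av$ss[av$term %in% zero_terms]) < 1e-16))
  expect_lt(av$ss[av$term == "Lack of fit"], 1e-16)
})

test_that("partial SS do not sum to model SS in general but do without quadratics", {
  design <- build_bbd_design(cultivation_factors(), n_center = 5)
  set.seed(13)
  y <- rnorm(17, 100, 10)
  av <- anova_type3(fit_quadratic(design, y))
  terms9 <- !(av$term %in% c("Model", "Residual", "Lack of fit",
                             "Pure error", "Cor total"))
  expect_false(isTRUE(all.equal(sum(av$ss[terms9]),
                                av$ss[av$term == "Model"], tolerance = 1e-6)))
  # linear + interaction generating model, fitted with those terms orthogonal
  lin <- c(100, 3, -2, 1, 0.5, -1, 2, 0, 0, 0)
  y2 <- simulate_bbd_responses(design, lin, noise_sd = 0)
  av2 <- anova_type3(fit_quadratic(design, y2))
  expect_equal(sum(av2$ss[terms9]), av2$ss[av2$term == "Model"],
               tolerance = 1e-6)
})

test_that("published coefficients reconstruct the printed ANOVA rows", {
  design <- build_bbd_design(cultivation_factors(), n_center = 5)
  av <- anova_from_coefficients(eq2_coefficients(), design,
                                residual_ms = 176.29)
  ss <- setNames(av$ss, av$term)
  expect_equal(unname(ss["mineral_solution"]), 1711.13,
               tolerance = 0.001)  # printed value, coefficient rounding
  expect_equal(unname(ss["mineral_solution:temperature"]), 56.25,
               tolerance = 1e-9)  # exactly 4 * 3.75^2
  expect_equal(unname(ss["soil_extract"]), 8.00, tolerance = 1e-9)
  zero <- anova_from_coefficients(rep(0, 10), design)
  expect_true(all(zero$ss == 0))
})

test_that("polynomial prediction reproduces hand evaluations and is linear", {
  b <- eq2_coefficients()
  expect_identical(predict_response(b, c(0, 0, 0)), 102.80)
  # hand evaluation of the printed polynomial at (0, -1, -1)
  expect_equal(predict_response(b, c(0, -1, -1)), 164.24, tolerance = 1e-9)
  # doubling coefficients doubles the deviation from zero
  expect_equal(predict_response(2 * b, c(0.3, -0.5, 0.7)),
               2 * predict_response(b, c(0.3, -0.5, 0.7)), tolerance = 1e-9)
})

test_that("constrained optimization finds the boundary/face optimum", {
  b <- eq2_coefficients()
  f <- cultivation_factors()
  opt <- optimize_response(b, f, sense = "maximize")
  expect_equal(unname(opt$natural[2]), 0.5, tolerance = 1e-9)   # mineral %
  expect_equal(unname(opt$natural[3]), 26, tolerance = 1e-9)    # temperature
  # face-stationary closed form for the soil-extract coordinate on the
  # x2 = x3 = -1 face: dY/dx1 = b1 - b12 - b13 + 2 b11 x1 = 0
  x1_star <- -(b[2] - b[5] - b[6]) / (2 * b[8])
  expect_equal(unname(opt$coded[1]), unname(x1_star), tolerance = 1e-6)
  expect_equal(opt$value, unname(predict_response(b, c(x1_star, -1, -1))),
               tolerance = 1e-6)
  # optimum beats a dense grid of box vertices and edges
  grid <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1), c(-1, 0, 1)))
  expect_true(all(predict_response(b, grid) <= opt$value + 1e-9))
  # minimizing the negated surface lands on the same point
  opt_min <- optimize_response(-b, f, sense = "minimize")
  expect_equal(opt_min$coded, opt$coded, tolerance = 1e-6)
  expect_equal(opt_min$value, -opt$value, tolerance = 1e-9)
})
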