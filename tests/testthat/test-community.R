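test_that("rarefaction conserves depth and is the identity at full depth", {
  ot <- tiny_otu_table()
  r <- rarefy(ot, depth = 10, seed = 1)
  expect_true(all(rowSums(r$counts) == 10))
  # s1 and s2 have total 10, so they must come back unchanged
  expect_identical(r$counts["s1", ], ot$counts["s1", ])
  expect_identical(r$counts["s2", ], ot$counts["s2", ])
  expect_error(rarefy(ot, depth = 11), "s1")
  # richness can only drop
  expect_true(all(rowSums(r$counts > 0) <= rowSums(ot$counts > 0)))
})

test_that("rarefied counts match the hypergeometric expectation", {
  src <- simulate_source_community(20, seed = 2)
  tab <- simulate_neutral_metacommunity(src, m = 0.5, N = 1000,
                                        n_samples = 1, seed = 2)
  depth <- 200
  draws <- vapply(1:400, function(s) rarefy(tab, depth, seed = s)$counts[1, ],
                  numeric(20))
  expected <- depth * tab$counts[1, ] / 1000
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  nonzero <- expected > 0
  expect_true(all(abs(rowMeans(draws) - expected)[nonzero] <=
                    3 * se[nonzero] + 1e-9))
})

test_that("abundance classification applies the threshold rules and partitions", {
  counts <- matrix(as.integer(c(200, 200,       # 2% everywhere -> abundant
                                0.5, 0.5,       # 0.005% -> rare
                                50, 50,         # 0.5%  -> intermediate
                                9749.5, 9749.5) * 2), nrow = 2,
                   dimnames = list(c("s1", "s2"), paste0("o", 1:4)))
  ot <- otu_table(counts, group = c("cultivated", "control"),
                  domain = rep("prokaryote", 2))
  cls <- classify_abundance(ot)
  expect_identical(unname(cls$label),
                   c("abundant", "rare", "intermediate", "abundant"))
  expect_equal(length(cls$label), ncol(counts))  # labels partition the OTUs
  expect_error(classify_abundance(ot, rare_cut = 0.1, abundant_cut = 0.01),
               "below")
  # any-sample rule flags an OTU abundant in one sample only
  skewed <- matrix(c(150L, 0L, 9850L, 10000L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("oA", "oB")))
  ot2 <- otu_table(skewed, group = c("cultivated", "control"),
                   domain = rep("prokaryote", 2))
  expect_identical(unname(classify_abundance(ot2)$label[1]), "intermediate")
  expect_identical(unname(classify_abundance(ot2, rule = "any")$label[1]),
                   "abundant")
})

test_that("alpha diversity reproduces closed forms", {
  m <- matrix(c(10L, 10L, 10L, 10L), 1,
              dimnames = list("s1", paste0("o", 1:4)))
  ot <- otu_table(m, group = "control", domain = "prokaryote")
  expect_equal(alpha_diversity(ot, "shannon")$value, log(4),
               tolerance = 1e-9)
  expect_equal(alpha_diversity(ot, "richness")$value, 4)

  m2 <- matrix(c(5L, 3L, 2L, 1L, 1L), 1,
               dimnames = list("s1", paste0("o", 1:5)))
  ot2 <- otu_table(m2, group = "control", domain = "prokaryote")
  expect_equal(alpha_diversity(ot2, "chao1")$value, 7.0)  # 5 + 2^2/(2*1)

  # no singletons: estimator floor at observed richness
  m3 <- matrix(c(5L, 3L, 2L, 2L), 1, dimnames = list("s1", paste0("o", 1:4)))
  ot3 <- otu_table(m3, group = "control", domain = "prokaryote")
  expect_equal(alpha_diversity(ot3, "chao1")$value, 4)

  expect_error(alpha_diversity(ot, "simpson"))
  m0 <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("s1", "s2"), "o1"))
  ot0 <- otu_table(m0, group = c("control", "control"),
                   domain = rep("prokaryote", 2))
  expect_error(alpha_diversity(ot0, "richness"), "empty")
})

test_that("ACE agrees with the vegan estimator and respects its floor", {
  src <- simulate_source_community(120, seed = 31)
  tab <- simulate_neutral_metacommunity(src, m = 0.2, N = 2000,
                                        n_samples = 4, seed = 31)
  ours <- alpha_diversity(tab, "ace")$value
  veg <- apply(tab$counts, 1, function(n) vegan::estimateR(n)[["S.ACE"]])
  expect_equal(ours, unname(veg), tolerance = 1e-6)
  expect_true(all(ours >= alpha_diversity(tab, "richness")$value))
})

test_that("contribution ratio is a plain percentage with scale invariance", {
  expect_equal(contribution_ratio(3, 3), 100)
  expect_equal(contribution_ratio(2.5, 3.0), 83.3333, tolerance = 1e-4)
  expect_equal(contribution_ratio(2.5 * 7, 3.0 * 7),
               contribution_ratio(2.5, 3.0), tolerance = 1e-12)
  expect_error(contribution_ratio(1, 0), "nonzero")
})

test_that("group proportion comparison matches a hand Welch computation", {
  counts <- matrix(0L, 6, 2,
                   dimnames = list(paste0("s", 1:6), c("oA", "oB")))
  pa <- c(0.2, 0.25, 0.3, 0.5, 0.55, 0.6)
  counts[, 1] <- as.integer(round(1000 * pa))
  counts[, 2] <- 1000L - counts[, 1]
  ot <- otu_table(counts,
                  group = rep(c("cultivated", "control"), each = 3),
                  domain = rep("prokaryote", 6),
                  taxonomy = c("k__M;p__PA", "k__M;p__PB"))
  res <- compare_proportions(ot)
  row <- res[res$taxon == "PA", ]
  # closed-form Welch oracle
  va <- var(pa[1:3]); vb <- var(pa[4:6])
  se <- sqrt(va / 3 + vb / 3)
  t_oracle <- (mean(pa[1:3]) - mean(pa[4:6])) / se
  df_oracle <- (va / 3 + vb / 3)^2 /
    ((va / 3)^2 / 2 + (vb / 3)^2 / 2)
  p_oracle <- 2 * pt(abs(t_oracle), df_oracle, lower.tail = FALSE)
  expect_equal(row$t, t_oracle, tolerance = 1e-9)
  expect_equal(row$p, p_oracle, tolerance = 1e-9)
  expect_equal(row$diff, -0.3, tolerance = 1e-12)
  ci_half <- qt(0.975, df_oracle) * se
  expect_equal(c(row$ci_lo, row$ci_hi), c(-0.3 - ci_half, -0.3 + ci_half),
               tolerance = 1e-9)
  # one row per phylum
  expect_equal(nrow(res), 2)
})

test_that("identical groups give zero difference and p = 1", {
  counts <- matrix(rep(c(300L, 700L), each = 4), 4, 2,
                   dimnames = list(paste0("s", 1:4), c("oA", "oB")))
  ot <- otu_table(counts,
                  group = rep(c("cultivated", "control"), 2),
                  domain = rep("prokaryote", 4),
                  taxonomy = c("k__M;p__PA", "k__M;p__PB"))
  res <- compare_proportions(ot)
  expect_true(all(res$diff == 0))
  expect_true(all(res$p == 1))
  m1 <- matrix(c(1L, 2L), 2, 1, dimnames = list(c("s1", "s2"), "oA"))
  single <- otu_table(m1, group = c("cultivated", "control"),
                      domain = rep("prokaryote", 2),
                      taxonomy = "k__M;p__PA")
  expect_error(compare_proportions(single), ">= 2 samples")
})

test_that("abundant-subset Shannon share rises with source evenness", {
  share <- vapply(c(2, 1, 0.5, 0.1), function(sdlog) {
    src <- simulate_source_community(50, params = list(sd = sdlog), seed = 9)
    tab <- simulate_neutral_metacommunity(src, m = 0.5, N = 5000,
                                          n_samples = 10, seed = 9)
    cls <- classify_abundance(tab)
    ab <- names(cls$label)[cls$label == "abundant"]
    sub <- otu_table(tab$counts[, ab, drop = FALSE], tab$group, tab$domain)
    mean(alpha_diversity(sub, "shannon")$value) /
      mean(alpha_diversity(tab, "shannon")$value)
  }, numeric(1))
  expect_true(all(diff(share) > 0))
  expect_gt(share[length(share)], 0.99)
})
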