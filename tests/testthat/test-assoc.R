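test_that("spearman matches hand values, the mid-rank oracle and cor.test", {
  expect_equal(spearman(c(1, 2, 3, 5, 9), c(2, 4, 5, 6, 20))$rho, 1)
  expect_equal(spearman(c(1, 2, 3, 5, 9), c(2, 4, 5, 6, 20))$p, 0)
  expect_equal(spearman(c(1, 2, 3, 4), c(4, 3, 2, 1))$rho, -1)
  # tied fixture against a definition-level mid-rank computation
  x <- c(1, 1, 2, 3); y <- c(2, 3, 1, 4)
  rx <- c(1.5, 1.5, 3, 4); ry <- c(2, 3, 1, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman(x, y)$rho, oracle, tolerance = 1e-12)
  set.seed(31)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  ct <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
  st <- spearman(a, b)
  expect_equal(st$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(st$p, ct$p.value, tolerance = 1e-10)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:3, 1:3), "n >= 4")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(32)
  x <- rnorm(25); y <- rnorm(25)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman(x, y^3 + 5 * y)$rho, base$rho, tolerance = 1e-12)
  expect_equal(spearman(rank(x), y)$rho, base$rho, tolerance = 1e-12)
})

test_that("exact permutation p-values agree with enumeration for small n", {
  set.seed(33)
  x <- rnorm(6); y <- rnorm(6)
  st <- spearman(x, y, exact = TRUE)
  expect_true(st$p >= 0 && st$p <= 1)
  # perfect monotone pair: only the 2 extreme orderings reach |rho| = 1
  st1 <- spearman(1:6, 2 * (1:6), exact = TRUE)
  expect_equal(st1$p, 2 / factorial(6), tolerance = 1e-12)
  expect_error(spearman(rnorm(10), rnorm(10), exact = TRUE), "n <= 9")
})

test_that("correlation_network keeps exactly the planted edge", {
  hits <- 0L
  for (s in 1:10) {
    pr <- simulate_correlated_pair(200L, 0.9, seed = 100 + s)
    set.seed(200 + s)
    m <- matrix(rlnorm(8 * 200, sdlog = 1), nrow = 8)
    m <- rbind(m, exp(pr$x), exp(pr$y))
    rownames(m) <- sprintf("G%02d", 1:10)
    colnames(m) <- sprintf("S%03d", 1:200)
    tab <- abundance_table(sweep(m, 2, colSums(m), "/"), mode = "relative")
    net <- correlation_network(tab, rho_min = 0.6, p_max = 0.01, top_n = 10)
    if (nrow(net$edges) == 1L &&
          setequal(c(net$edges$genus_a, net$edges$genus_b), c("G09", "G10"))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("null networks are empty and trivial thresholds give the complete graph", {
  tab <- random_relative_table(15, 200, seed = 41)
  net <- correlation_network(tab, rho_min = 0.6, p_max = 0.01, top_n = 15)
  expect_equal(nrow(net$edges), 0L)
  full <- correlation_network(tab, rho_min = 0, p_max = 1, top_n = 15)
  expect_equal(nrow(full$edges), choose(15, 2))
  expect_equal(nrow(full$nodes), 15L)
  expect_true(all(abs(full$edges$rho) <= 1))
  expect_false(any(full$edges$genus_a == full$edges$genus_b))
})

test_that("kruskal_wallis matches the rank-sum oracle and handles degeneracy", {
  # hand oracle: ranks 1..9, group rank sums 6/15/24
  # H = 12/(9*10) * (36/3 + 225/3 + 576/3) - 3*10 = 7.2
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
})

test_that("kruskal_wallis with two groups is monotone in the Wilcoxon statistic", {
  set.seed(34)
  stats_pairs <- t(replicate(30, {
    a <- rnorm(8); b <- rnorm(8) + runif(1, 0, 2)
    c(H = kruskal_wallis(list(a, b))$H, W = wilcoxon_rank_sum(a, b)$W)
  }))
  # H is a monotone function of |W - n1 n2 / 2|
  dev <- abs(stats_pairs[, "W"] - 32)
  ord <- order(dev)
  expect_true(all(diff(stats_pairs[ord, "H"]) >= -1e-9))
})

test_that("wilcoxon_rank_sum exact and asymptotic paths behave as documented", {
  expect_gt(wilcoxon_rank_sum(c(1, 2, 9), c(1, 2, 9))$p, 0.9)
  # exact enumeration oracle: fully separated samples of 3 vs 3
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1, tolerance = 1e-12)
  set.seed(35)
  expect_lt(wilcoxon_rank_sum(rnorm(60), rnorm(60) + 3)$p, 1e-6)
})

test_that("pairwise trait tests flag the planted leg-muscle contrast only", {
  tpl <- small_template()
  cnt <- simulate_counts(tpl, seed = 43L)
  effects <- default_phenotype_effects()
  effects$leg_shift_sd <- 3
  ph <- simulate_phenotypes(cnt$labels, cnt$abundance, effects, seed = 44L)
  res <- pairwise_trait_tests(ph, cnt$labels)
  leg <- res[res$trait == "leg_muscle_weight" & res$group_b == 3, ]
  expect_true(all(leg$p < 0.05))
  body <- res[res$trait == "body_weight", ]
  expect_true(all(body$p > 0.001))  # no planted body-weight effect
  expect_false(attr(res, "multiplicity_corrected"))
  # identical groups (same values in every ET): p = 1 and tiers empty
  vals <- c(2350, 2420, 2480, 2510, 2550, 2610)
  ph0 <- data.frame(sample_id = sprintf("x%02d", 1:18),
                    body_weight = rep(vals, 3),
                    dressed_weight = rep(vals, 3) * 0.88,
                    eviscerated_weight = rep(vals, 3) * 0.7,
                    breast_muscle_weight = rep(vals, 3) * 0.1,
                    leg_muscle_weight = rep(vals, 3) * 0.07)
  lab0 <- stats::setNames(rep(1:3, each = 6), ph0$sample_id)
  res0 <- pairwise_trait_tests(ph0, lab0, traits = "body_weight")
  expect_true(all(res0$p > 0.9))
  expect_true(all(res0$significance == ""))
})

test_that("Welch t statistic matches the definition-level formula", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8, 10)
  ph <- data.frame(sample_id = sprintf("s%d", 1:9),
                   body_weight = c(a, b) * 100 + 2000,
                   dressed_weight = c(a, b) * 90 + 1800,
                   eviscerated_weight = c(a, b) * 80 + 1500,
                   breast_muscle_weight = c(a, b) * 10 + 200,
                   leg_muscle_weight = c(a, b) * 8 + 150)
  lab <- stats::setNames(rep(c(1L, 2L), c(4, 5)), ph$sample_id)
  res <- pairwise_trait_tests(ph, lab, traits = "body_weight")
  x <- ph$body_weight[1:4]; y <- ph$body_weight[5:9]
  se2 <- var(x) / 4 + var(y) / 5
  t_oracle <- (mean(x) - mean(y)) / sqrt(se2)
  df_oracle <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 5)^2 / 4)
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df_oracle)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
})

test_that("genus-trait correlations recover planted couplings", {
  rec <- 0L
  for (s in 1:10) {
    tpl <- small_template()
    cnt <- simulate_counts(tpl, seed = 300 + s)
    ph <- simulate_phenotypes(cnt$labels, cnt$abundance,
                              seed = 400 + s)
    rel <- to_relative(cnt$abundance)
    gtc <- genus_trait_correlations(rel, ph, genus_set = c("Lactococcus", "Bradyrhizobium"))
    row <- gtc[gtc$genus == "Lactococcus" & gtc$trait == "leg_muscle_weight", ]
    if (row$rho > 0 && row$p < 0.05) rec <- rec + 1L
  }
  expect_gte(rec, 8L)
  # exact rank transform gives rho = 1
  tab <- random_relative_table(5, 48, seed = 51)
  ph <- data.frame(sample_id = colnames(ab_values(tab)),
                   body_weight = rank(ab_values(tab)["G01", ]) + 2000,
                   dressed_weight = 2000, eviscerated_weight = 1500,
                   breast_muscle_weight = 200, leg_muscle_weight = 150)
  ph$dressed_weight <- ph$body_weight * 0.9
  ph$eviscerated_weight <- ph$body_weight * 0.7
  ph$breast_muscle_weight <- ph$body_weight * 0.1 + rnorm(48)
  ph$leg_muscle_weight <- ph$body_weight * 0.07 + rnorm(48)
  gtc <- genus_trait_correlations(tab, ph, genus_set = "G01",
                                  traits = "body_weight")
  expect_equal(gtc$rho, 1)
  expect_error(genus_trait_correlations(tab, ph[-1, ], genus_set = "G01"),
               "different samples")
})
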