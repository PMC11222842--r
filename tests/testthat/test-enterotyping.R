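test_that("jsd_distance matches hand values and the brute-force oracle", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(jsd_distance(p, p), 0)
  expect_equal(jsd_distance(c(1, 0), c(0, 1)), sqrt(log(2)), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    a <- random_dirichlet(1, rep(0.5, 6))[, 1]
    b <- random_dirichlet(1, rep(0.5, 6))[, 1]
    expect_equal(jsd_distance(a, b), brute_force_jsd(a, b), tolerance = 1e-12)
    expect_equal(jsd_distance(a, b), jsd_distance(b, a), tolerance = 1e-15)
    expect_lte(jsd_distance(a, b), sqrt(log(2)) + 1e-12)
  }
  expect_error(jsd_distance(c(0.5, 0.5), c(0.7, 0.2)), "sum to 1")
  expect_error(jsd_distance(c(1.2, -0.2), c(0.5, 0.5)), "negative")
})

test_that("sqrt-JSD satisfies the triangle inequality on random triples", {
  set.seed(6)
  for (i in 1:50) {
    x <- random_dirichlet(3, rep(0.3, 8))
    d12 <- jsd_distance(x[, 1], x[, 2])
    d13 <- jsd_distance(x[, 1], x[, 3])
    d23 <- jsd_distance(x[, 2], x[, 3])
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_lte(d23, d12 + d13 + 1e-12)
  }
})

test_that("jsd_matrix agrees with pairwise calls and bounds", {
  set.seed(7)
  m <- random_dirichlet(4, rep(0.4, 10))
  colnames(m) <- paste0("s", 1:4)
  rownames(m) <- paste0("t", 1:10)
  tab <- abundance_table(m, mode = "relative")
  d <- jsd_matrix(tab)
  expect_equal(d, t(d), tolerance = 1e-15)
  expect_equal(unname(diag(d)), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d[i, j], jsd_distance(m[, i], m[, j]), tolerance = 1e-12)
  }
  # identical samples at distance zero
  mm <- cbind(a = m[, 1], b = m[, 1])
  d2 <- jsd_matrix(abundance_table(mm, mode = "relative"))
  expect_equal(d2["a", "b"], 0)
  expect_error(jsd_matrix(tiny_counts_table()), "relative")
})

test_that("PAM separates well-separated 1D blobs and matches exhaustive search", {
  d <- dist1d(c(0, 1, 10, 11))
  fit <- pam_medoids(d, 2)
  expect_identical(fit$labels[1], fit$labels[2])
  expect_identical(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])
  oracle <- brute_force_pam(d, 2)
  expect_equal(fit$cost, oracle$cost, tolerance = 1e-12)
  expect_error(pam_medoids(d, 1), "k must")
  expect_error(pam_medoids(d, 4), "k must")
})

test_that("PAM reaches the exhaustive optimum on most small instances and never beats it", {
  set.seed(8)
  n_match <- 0L
  n_runs <- 40L
  for (i in seq_len(n_runs)) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    d <- dist1d(runif(n, 0, 10))
    fit <- pam_medoids(d, k)
    oracle <- brute_force_pam(d, k)
    expect_gte(fit$cost, oracle$cost - 1e-9)
    if (same_partition(fit$labels, oracle$labels)) n_match <- n_match + 1L
  }
  expect_gte(n_match / n_runs, 0.9)
})

test_that("PAM at k = n-1 and on duplicated data matches brute force", {
  set.seed(9)
  x <- runif(6, 0, 5)
  d <- dist1d(x)
  fit <- pam_medoids(d, 5)
  expect_true(all(tabulate(fit$labels) <= 2))
  expect_equal(fit$cost, brute_force_pam(d, 5)$cost, tolerance = 1e-12)
  # each point duplicated: optimal cost exactly doubles
  x2 <- rep(runif(4, 0, 5), each = 2)
  d2 <- dist1d(x2)
  expect_equal(pam_medoids(d2, 2)$cost, 2 * brute_force_pam(dist1d(unique(x2)), 2)$cost,
               tolerance = 1e-12)
})

test_that("calinski_harabasz ranks the true structure above alternatives", {
  # 12-point fixture: two tight, distant blobs
  x <- c(rnorm(6, 0, 0.1), rnorm(6, 20, 0.1))
  d <- dist1d(x)
  f2 <- pam_medoids(d, 2)
  f3 <- pam_medoids(d, 3)
  ch2 <- calinski_harabasz(d, f2$labels)
  ch3 <- calinski_harabasz(d, f3$labels)
  expect_gt(ch2, ch3)
  expect_gt(ch3, 0)
  # oracle: direct evaluation of the variance-decomposition formula
  d2s <- d^2
  W <- sum(sapply(1:2, function(c) {
    idx <- f2$labels == c
    sum(d2s[idx, idx]) / (2 * sum(idx))
  }))
  Tot <- sum(d2s) / (2 * 12)
  expect_equal(ch2, ((Tot - W) / 1) / (W / 10), tolerance = 1e-12)
  # degenerate: identical points within clusters
  dd <- dist1d(c(0, 0, 0, 5, 5, 5))
  fd <- pam_medoids(dd, 2)
  expect_identical(calinski_harabasz(dd, fd$labels), Inf)
})

test_that("silhouette widths match hand evaluation, conventions and cluster::silhouette", {
  d <- dist1d(c(0, 1, 10, 11))
  lab <- c(1L, 1L, 2L, 2L)
  s <- silhouette_widths(d, lab)
  expect_equal(unname(s[1]), 1 - 1 / 10.5, tolerance = 1e-12)
  expect_true(all(s >= -1 & s <= 1))
  # all points identical -> zero widths
  d0 <- matrix(0, 4, 4)
  expect_equal(unname(silhouette_widths(d0, lab)), rep(0, 4))
  skip_if_not_installed("cluster")
  set.seed(10)
  x <- runif(20)
  dr <- dist1d(x)
  labr <- sample(1:3, 20, replace = TRUE)
  labr[1:3] <- 1:3
  mine <- silhouette_widths(dr, labr)
  ref <- cluster::silhouette(labr, dmatrix = dr)[, "sil_width"]
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("random labels on structureless data give near-zero mean silhouette", {
  set.seed(12)
  n <- 200L
  x <- runif(n)
  d <- dist1d(x)
  lab <- sample(1:3, n, replace = TRUE)
  expect_lt(abs(mean(silhouette_widths(d, lab))), 0.1)
})

test_that("fit_enterotypes recovers the planted three-way structure", {
  cnt <- simulate_counts(build_default_template(), seed = 17L)
  model <- fit_enterotypes(cnt$abundance)
  expect_equal(model$k_selected, 3L)
  expect_true(same_partition(unname(model$labels[names(cnt$labels)]),
                             unname(cnt$labels)))
  expect_identical(unname(model$cluster_sizes), c(76L, 67L, 57L))
  expect_identical(model$driver_genus_per_cluster,
                   c("Streptococcus", "Candidatus Arthromitus", "Bacteroides"))
  expect_equal(names(which.max(model$ch_by_k)), "3")
  expect_true(all(model$silhouette_per_sample >= -1 &
                    model$silhouette_per_sample <= 1))
  expect_true(all(model$medoid_ids %in% names(model$labels)))
})

test_that("a two-component cohort selects k = 2", {
  tpl <- small_template(theta = 100)
  tpl$component_means[[3]] <- tpl$component_means[[1]]  # merge 3 into 1
  cnt <- simulate_counts(tpl, seed = 19L)
  model <- fit_enterotypes(cnt$abundance, k_range = 2:6)
  expect_equal(model$k_selected, 2L)
})

test_that("the fitted partition is invariant to sample order", {
  tpl <- small_template(theta = 100)
  cnt <- simulate_counts(tpl, seed = 23L)
  m1 <- fit_enterotypes(cnt$abundance, k_range = 2:4)
  set.seed(1)
  perm <- sample(ncol(ab_values(cnt$abundance)))
  shuffled <- abundance_table(ab_values(cnt$abundance)[, perm],
                              mode = "counts")
  m2 <- fit_enterotypes(shuffled, k_range = 2:4)
  ids <- names(m1$labels)
  expect_equal(m1$k_selected, m2$k_selected)
  expect_true(same_partition(unname(m1$labels[ids]), unname(m2$labels[ids])))
})

test_that("k range is shrunk with a warning for tiny cohorts", {
  tpl <- build_default_template(component_sizes = c(3L, 3L, 3L),
                                concentration = 100,
                                depth_range = c(2000L, 3000L),
                                n_filler = 20L, richness_boost = 5L)
  cnt <- simulate_counts(tpl, seed = 29L)
  expect_warning(model <- fit_enterotypes(cnt$abundance, k_range = 2:10),
                 "shrunk")
  expect_lt(model$k_selected, 9L)
})
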