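# Shared fixtures and independent oracles, all built in code at test time.

# small counts table with lineage strings (QIIME-style prefixes)
tiny_counts_table <- function() {
  m <- matrix(c(5L, 3L, 0L,
                2L, 2L, 1L,
                0L, 4L, 7L), nrow = 3L, byrow = TRUE,
              dimnames = list(c("T1", "T2", "T3"), c("S1", "S2", "S3")))
  abundance_table(m, mode = "counts", level = "genus",
                  taxonomy = c(
                    "d__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Streptococcaceae; g__Streptococcus",
                    "d__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Streptococcaceae; g__Lactococcus",
                    "d__Bacteria; p__Bacteroidota; c__Bacteroidia; o__Bacteroidales; f__Bacteroidaceae; g__Bacteroides"))
}

# a small fast cohort template for tests that only need structure
small_template <- function(theta = 60) {
  build_default_template(component_sizes = c(20L, 16L, 12L),
                         concentration = theta,
                         depth_range = c(5000L, 8000L),
                         n_filler = 40L, richness_boost = 10L)
}

# Euclidean distance matrix from 1D coordinates
dist1d <- function(x) {
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(paste0("P", seq_along(x)), paste0("P", seq_along(x)))
  d
}

# exhaustive k-medoids optimum: enumerate every medoid subset
brute_force_pam <- function(d, k) {
  n <- nrow(d)
  sets <- utils::combn(n, k)
  costs <- apply(sets, 2L, function(meds) {
    sum(apply(d[, meds, drop = FALSE], 1L, min))
  })
  best <- which.min(costs)
  meds <- sets[, best]
  list(cost = costs[best],
       labels = apply(d[, meds, drop = FALSE], 1L, which.min))
}

# brute-force sqrt-JSD: scalar loop straight from the definition
brute_force_jsd <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    m <- (p[i] + q[i]) / 2
    if (p[i] > 0) s <- s + p[i] * log(p[i] / m) / 2
    if (q[i] > 0) s <- s + q[i] * log(q[i] / m) / 2
  }
  sqrt(s)
}

# partitions equal up to label renaming?
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  all(outer(a, a, "==") == outer(b, b, "=="))
}

random_dirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = length(alpha))
  sweep(g, 2L, colSums(g), "/")
}

# relative-mode table of independent lognormal genera (closure-normalised)
random_relative_table <- function(n_taxa, n_samples, seed) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_taxa * n_samples, sdlog = 1), nrow = n_taxa,
              dimnames = list(sprintf("G%02d", seq_len(n_taxa)),
                              sprintf("S%03d", seq_len(n_samples))))
  abundance_table(sweep(m, 2L, colSums(m), "/"), mode = "relative")
}
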