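#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties receive average
#' ranks); the two-sided p-value uses the t statistic
#' rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom, the
#' standard approximation for cohort-sized n. Perfect monotone
#' association returns p = 0. For n <= 9 an exact permutation p-value
#' over all n! rank orderings is available.
#'
#' @param x,y numeric vectors of equal length `n >= 4`, neither constant.
#' @param exact compute the exact permutation p-value (n <= 9 only).
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 4L) stop("need equal-length vectors, n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman undefined for a constant vector")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 9L) stop("exact permutation p only offered for n <= 9")
    perms <- permutations_of(n)
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(stats::cor(rx, ry[perms[i, ]])) >= obs - 1e-12) cnt <- cnt + 1L
    }
    return(list(rho = rho, p = cnt / nrow(perms)))
  }
  if (abs(rho) >= 1 - 1e-12) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Genus co-occurrence network by thresholded Spearman correlation
#'
#' All pairwise Spearman correlations among the `top_n` most abundant
#' genera; edges are kept when |rho| exceeds `rho_min` and p falls below
#' `p_max` (defaults 0.6 and 0.01). Nodes carry mean relative abundance
#' (the node-size semantic of co-occurrence plots).
#'
#' @param table a relative-mode [abundance_table()].
#' @param rho_min minimum |rho| for an edge (strict).
#' @param p_max maximum p-value for an edge (strict).
#' @param top_n number of most-abundant genera to include.
#' @return list with `nodes` (data frame: `genus`, `mean_abundance`) and
#'   `edges` (data frame: `genus_a`, `genus_b`, `rho`, `p`), each
#'   unordered pair at most once.
#' @export
correlation_network <- function(table, rho_min = 0.6, p_max = 0.01,
                                top_n = 15L) {
  stopifnot(inherits(table, "abundance_table"))
  if (!identical(ab_mode(table), "relative")) {
    stop("correlation_network expects relative abundances")
  }
  v <- ab_values(table)
  means <- rowMeans(v)
  keep <- head(order(means, decreasing = TRUE), top_n)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 2L) stop("need at least two genera after the top_n cut")
  genera <- rownames(v)
  nodes <- data.frame(genus = genera, mean_abundance = means[keep],
                      row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(length(genera), 2L)
  edges <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    st <- spearman(v[a, ], v[b, ])
    if (abs(st$rho) > rho_min && st$p < p_max) {
      data.frame(genus_a = genera[a], genus_b = genera[b],
                 rho = st$rho, p = st$p, stringsAsFactors = FALSE)
    }
  })
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    edges <- data.frame(genus_a = character(), genus_b = character(),
                        rho = numeric(), p = numeric(),
                        stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on g - 1 degrees
#' of freedom. When every observation is identical the statistic is 0
#' and p = 1.
#'
#' @param groups list of >= 2 non-empty numeric vectors, total n >= 5.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) > 0L), sum(lengths(groups)) >= 5L)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1))
  g <- factor(rep.int(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Mid-rank statistic; the two-sided p-value is exact (full enumeration)
#' when the pooled sample size is at most 12 and there are no ties,
#' otherwise a normal approximation with tie-corrected variance and 0.5
#' continuity correction is used.
#'
#' @param a,b non-empty numeric vectors.
#' @return list with `W` (Mann-Whitney U of the first sample) and `p`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

significance_tier <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Pairwise Welch t-tests of traits across enterotypes
#'
#' For every trait column and every unordered pair of enterotypes, a
#' Welch two-sample t-test with significance tiers (* p < 0.05,
#' ** p < 0.01). No multiple-testing correction is applied; the returned
#' object carries `multiplicity_corrected = FALSE` as an attribute so
#' downstream consumers see the flag.
#'
#' @param phenotypes phenotype data frame (see [derive_carcass_traits()]).
#' @param labels integer enterotype index per sample, named by sample id.
#' @param traits trait columns to test (default: all weights and derived
#'   percentages present).
#' @return data frame with `trait`, `group_a`, `group_b`, `t`, `p`,
#'   `significance`.
#' @export
pairwise_trait_tests <- function(phenotypes, labels,
                                 traits = intersect(c(phenotype_trait_names,
                                                      phenotype_pct_names),
                                                    names(phenotypes))) {
  lab <- labels[phenotypes$sample_id]
  if (anyNA(lab)) stop("labels missing for some phenotype samples")
  ets <- sort(unique(lab))
  if (any(table(lab) < 2L)) stop("every enterotype needs >= 2 samples")
  pairs <- utils::combn(ets, 2L)
  rows <- list()
  for (tr in traits) {
    for (j in seq_len(ncol(pairs))) {
      a <- phenotypes[[tr]][lab == pairs[1L, j]]
      b <- phenotypes[[tr]][lab == pairs[2L, j]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        stop(sprintf("zero variance for trait '%s' in ET%d", tr,
                     pairs[1L + (stats::sd(b) == 0), j]))
      }
      tt <- stats::t.test(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, group_a = pairs[1L, j], group_b = pairs[2L, j],
        t = unname(tt$statistic), p = tt$p.value,
        significance = significance_tier(tt$p.value),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "multiplicity_corrected") <- FALSE
  out
}

#' Genus-trait Spearman correlation matrix
#'
#' Spearman rho and p for every requested genus against every trait,
#' sorted by |rho| descending within trait, with the same significance
#' tiers as [pairwise_trait_tests()].
#'
#' @param table a relative-mode [abundance_table()].
#' @param phenotypes phenotype data frame aligned with the table samples.
#' @param genus_set genera to test (default: all genera in the table).
#' @param traits trait columns to test.
#' @return data frame with `genus`, `trait`, `rho`, `p`, `significance`.
#' @export
genus_trait_correlations <- function(table, phenotypes,
                                     genus_set = NULL,
                                     traits = intersect(c(phenotype_trait_names,
                                                          phenotype_pct_names),
                                                        names(phenotypes))) {
  stopifnot(inherits(table, "abundance_table"))
  v <- ab_values(table)
  if (!setequal(colnames(v), phenotypes$sample_id)) {
    stop("abundance table and phenotype table cover different samples")
  }
  v <- v[, phenotypes$sample_id, drop = FALSE]
  if (is.null(genus_set)) genus_set <- rownames(v)
  miss <- setdiff(genus_set, rownames(v))
  if (length(miss)) stop("unknown genus: ", paste(miss, collapse = ", "))
  rows <- list()
  for (tr in traits) {
    for (g in genus_set) {
      st <- spearman(v[g, ], phenotypes[[tr]])
      rows[[length(rows) + 1L]] <- data.frame(
        genus = g, trait = tr, rho = st$rho, p = st$p,
        significance = significance_tier(st$p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$trait, -abs(out$rho)), , drop = FALSE]
}
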