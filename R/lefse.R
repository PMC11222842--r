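#' LEfSe-style differential-abundance scoring across enterotypes
#'
#' Three-gate procedure on per-million-scaled abundances: (1) a
#' Kruskal-Wallis screen per taxon across all classes at level `alpha`;
#' (2) for survivors, pairwise Wilcoxon rank-sum tests between the class
#' with the highest mean abundance and every other class — under the
#' default strict ("all-against-all") semantics a taxon passes only if
#' every pairwise p < alpha with the top class having the larger mean in
#' every pair, while the one-against-all relaxation requires this of at
#' least one pair; (3) a bootstrapped linear-discriminant effect size.
#'
#' In each of `n_boot` iterations, `ceiling(boot_fraction * n_c)`
#' samples per class are drawn without replacement, a linear
#' discriminant over the surviving taxa is fitted (first eigenvector of
#' the pooled within-class covariance against the between-class scatter,
#' scaled to unit within-class variance; a ridge of 1e-6 times the trace
#' is applied when the covariance is singular), and each surviving taxon
#' receives the effect 0.5 * (d_raw + d_lda), where d_raw is the largest
#' class-pair difference of its subsampled class means (per-million
#' scale) and d_lda is |w_f| times the largest class-pair difference of
#' the LDA-projected class means. The reported score is
#' log10(1 + mean effect over iterations). Bootstrap draws are keyed to
#' samples sorted by id, so the result is invariant to input column
#' order for a given seed.
#'
#' @param table an [abundance_table()] (counts or relative; both give
#'   identical results after per-million scaling).
#' @param labels class (enterotype) index per sample, named by sample
#'   id; every class needs at least 3 samples.
#' @param alpha significance level for both rank-test gates.
#' @param lda_threshold minimum score for the `passed` verdict (the
#'   conventional screening cut is 4.0 on the log10 scale).
#' @param n_boot bootstrap iterations.
#' @param boot_fraction per-class subsampling fraction.
#' @param strategy multi-class Wilcoxon semantics, see above.
#' @param seed integer seed for the bootstrap.
#' @return a `lefse_result` data frame with one row per taxon: `taxon`,
#'   `enriched_class`, `kw_p`, `wilcoxon_pass`, `lda_score` (NA for taxa
#'   eliminated before the LDA stage) and `passed`; parameters are
#'   attached as attributes.
#' @export
run_lefse <- function(table, labels, alpha = 0.05, lda_threshold = 4.0,
                      n_boot = 30L, boot_fraction = 2 / 3,
                      strategy = c("all_against_all", "one_against_all"),
                      seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(table, "abundance_table"))
  v <- ab_values(table)
  if (!setequal(names(labels), colnames(v))) {
    stop("labels and abundance table cover different sample sets")
  }
  ord <- sort(colnames(v))  # canonical order: seed-keyed bootstrap draws
  v <- v[, ord, drop = FALSE]
  labels <- labels[ord]
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  n_c <- table(factor(labels, levels = classes))
  if (any(n_c < 3L)) stop("every class needs at least 3 samples")

  ## per-million scaling of each sample's composition
  tot <- colSums(v)
  if (any(tot <= 0)) stop("sample with zero total abundance")
  m <- sweep(v, 2L, tot, "/") * 1e6
  taxa <- rownames(m)

  class_mean <- t(apply(m, 1L, function(x) tapply(x, labels, mean)))
  enriched <- classes[apply(class_mean, 1L, which.max)]

  kw_p <- apply(m, 1L, function(x) {
    if (length(unique(x)) == 1L) return(1)
    kruskal_wallis(split(x, labels))$p
  })

  wilcoxon_pass <- vapply(seq_along(taxa), function(f) {
    if (kw_p[f] >= alpha) return(NA)
    top <- enriched[f]
    verdicts <- vapply(setdiff(classes, top), function(other) {
      a <- m[f, labels == top]
      b <- m[f, labels == other]
      wilcoxon_rank_sum(a, b)$p < alpha && mean(a) > mean(b)
    }, logical(1L))
    if (strategy == "all_against_all") all(verdicts) else any(verdicts)
  }, logical(1L))

  survivors <- which(!is.na(wilcoxon_pass) & wilcoxon_pass)
  lda_score <- rep(NA_real_, length(taxa))
  if (length(survivors)) {
    set.seed(as.integer(seed))
    feat <- m[survivors, , drop = FALSE]
    take <- ceiling(boot_fraction * as.integer(n_c))
    eff_sum <- numeric(length(survivors))
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(seq_along(classes), function(ci) {
        pool <- which(labels == classes[ci])
        pool[sample.int(length(pool), take[ci])]
      }), use.names = FALSE)
      eff_sum <- eff_sum + lda_effect(feat[, idx, drop = FALSE], labels[idx],
                                      classes)
    }
    lda_score[survivors] <- log10(1 + pmax(eff_sum / n_boot, 0))
  }

  passed <- !is.na(lda_score) & lda_score >= lda_threshold &
    kw_p < alpha & !is.na(wilcoxon_pass) & wilcoxon_pass
  out <- data.frame(taxon = taxa, enriched_class = enriched, kw_p = kw_p,
                    wilcoxon_pass = wilcoxon_pass, lda_score = lda_score,
                    passed = passed, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("lefse_result", "data.frame"),
            alpha = alpha, lda_threshold = lda_threshold,
            n_boot = n_boot, boot_fraction = boot_fraction,
            strategy = strategy, seed = as.integer(seed))
}

## Per-taxon effect sizes for one bootstrap draw: features x samples
## matrix, class labels, full class list. Returns 0.5*(d_raw + d_lda).
lda_effect <- function(feat, lab, classes) {
  p <- nrow(feat)
  mu <- matrix(vapply(classes, function(c) rowMeans(feat[, lab == c, drop = FALSE]),
                      numeric(p)), nrow = p)
  pair_idx <- utils::combn(length(classes), 2L)
  d_raw <- apply(abs(mu[, pair_idx[1L, ], drop = FALSE] -
                       mu[, pair_idx[2L, ], drop = FALSE]),
                 1L, max)
  ## pooled within-class scatter
  sw <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    x <- feat[, lab == classes[ci], drop = FALSE]
    cen <- x - rowMeans(x)
    sw <- sw + tcrossprod(cen)
  }
  sw <- sw / max(ncol(feat) - length(classes), 1L)
  mu_all <- rowMeans(feat)
  sb <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    dm <- mu[, ci] - mu_all
    sb <- sb + sum(lab == classes[ci]) * tcrossprod(dm)
  }
  sol <- tryCatch(solve(sw, sb), error = function(e) NULL)
  if (is.null(sol)) {  # singular within-class covariance: ridge
    sw <- sw + diag(1e-6 * sum(diag(sw)) + 1e-12, p)
    sol <- solve(sw, sb)
  }
  ev <- eigen(sol)
  w <- Re(ev$vectors[, which.max(Re(ev$values))])
  denom <- sqrt(max(drop(t(w) %*% sw %*% w), .Machine$double.eps))
  w <- w / denom  # unit within-class variance along the axis
  proj <- drop(t(w) %*% mu)
  d_proj <- max(abs(proj[pair_idx[1L, ]] - proj[pair_idx[2L, ]]))
  0.5 * (d_raw + abs(w) * d_proj)
}

#' Export a LEfSe result table as TSV
#'
#' Rows are sorted by `lda_score` descending (taxa without a score
#' last), ties broken by taxon id, so enrichment bar charts can be drawn
#' directly from the file. By default only taxa passing every gate are
#' written (an all-gates-failed analysis yields a header-only file);
#' set `only_passed = FALSE` to export the full per-taxon record.
#'
#' @param result a `lefse_result` from [run_lefse()].
#' @param path output TSV path.
#' @param only_passed write only taxa with `passed = TRUE`.
#' @return `path`, invisibly.
#' @export
export_lefse <- function(result, path, only_passed = TRUE) {
  stopifnot(inherits(result, "lefse_result"))
  df <- as.data.frame(result)
  if (only_passed) df <- df[df$passed, , drop = FALSE]
  key <- ifelse(is.na(df$lda_score), -Inf, df$lda_score)
  df <- df[order(-key, df$taxon), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
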