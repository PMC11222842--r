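#' Fit enterotypes to a genus-level abundance table
#'
#' The full enterotyping procedure: Jensen-Shannon distances between
#' sample compositions, PAM clustering for each candidate k, k selection
#' by the Calinski-Harabasz index (ties broken toward the smaller k),
#' and silhouette validation at the selected k. Clusters are renumbered
#' by decreasing size, so cluster 1 ("ET1") is always the largest, and
#' each cluster is summarised by its driver genus — the genus with the
#' highest mean relative abundance among its members. Two-dimensional
#' classical multidimensional-scaling coordinates of the JSD matrix are
#' attached for plotting.
#'
#' @param table an [abundance_table()]; counts are converted to relative
#'   abundances internally.
#' @param k_range candidate cluster counts (default 2:10); shrunk with a
#'   warning if the cohort is too small.
#' @param min_abundance optional mean-relative-abundance filter: genera
#'   below this threshold are dropped before clustering (default 0, no
#'   filter).
#' @return an `enterotype_model`: list with `k_selected`, `labels`
#'   (integer 1..k per sample, size-ordered), `cluster_sizes`,
#'   `medoid_ids`, `ch_by_k`, `silhouette_mean`,
#'   `silhouette_per_sample`, `driver_genus_per_cluster`,
#'   `driver_mean_abundance`, `coords` and the distance matrix `dist`.
#' @export
fit_enterotypes <- function(table, k_range = 2:10, min_abundance = 0) {
  stopifnot(inherits(table, "abundance_table"))
  if (identical(ab_mode(table), "counts")) table <- to_relative(table)
  v <- ab_values(table)
  if (min_abundance > 0) {
    keep <- rowMeans(v) >= min_abundance
    if (sum(keep) < 2L) stop("abundance filter removed almost all genera")
    v <- v[keep, , drop = FALSE]
    table <- abundance_table(sweep(v, 2L, colSums(v), "/"), mode = "relative",
                             level = ab_level(table))
    v <- ab_values(table)
  }
  n <- ncol(v)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range >= n) || any(k_range < 2L)) {
    k_range <- k_range[k_range >= 2L & k_range < n]
    if (!length(k_range)) stop("too few samples for any requested k")
    warning("k range shrunk to ", paste(range(k_range), collapse = ".."),
            " to fit the cohort size")
  }

  d <- jsd_matrix(table)
  fits <- lapply(k_range, function(k) pam_medoids(d, k))
  ch <- vapply(seq_along(k_range), function(j) {
    calinski_harabasz(d, fits[[j]]$labels)
  }, numeric(1L))
  names(ch) <- as.character(k_range)
  best <- which.max(ch)  # first maximum = smallest k on ties
  k_sel <- k_range[best]
  fit <- fits[[best]]

  ## relabel clusters by decreasing size; ties by lowest medoid index
  sizes <- tabulate(fit$labels, nbins = k_sel)
  ord <- order(-sizes, fit$medoids)
  relabel <- integer(k_sel)
  relabel[ord] <- seq_len(k_sel)
  labels <- stats::setNames(relabel[fit$labels], colnames(v))
  medoid_ids <- fit$medoid_ids[ord]
  sizes <- sizes[ord]

  sil <- silhouette_widths(d, labels)
  drivers <- vapply(seq_len(k_sel), function(c) {
    rownames(v)[which.max(rowMeans(v[, labels == c, drop = FALSE]))]
  }, character(1L))
  driver_mean <- vapply(seq_len(k_sel), function(c) {
    mean(v[drivers[c], labels == c])
  }, numeric(1L))

  structure(list(k_selected = k_sel,
                 labels = labels,
                 cluster_sizes = sizes,
                 medoid_ids = medoid_ids,
                 ch_by_k = ch,
                 silhouette_mean = mean(sil),
                 silhouette_per_sample = sil,
                 driver_genus_per_cluster = drivers,
                 driver_mean_abundance = driver_mean,
                 coords = stats::cmdscale(d, k = 2),
                 dist = d),
            class = "enterotype_model")
}

#' @export
print.enterotype_model <- function(x, ...) {
  cat(sprintf("enterotype model: k = %d (CH-selected), mean silhouette %.3f\n",
              x$k_selected, x$silhouette_mean))
  for (c in seq_len(x$k_selected)) {
    cat(sprintf("  ET%d: n = %d, driver = %s (%.1f%%)\n", c,
                x$cluster_sizes[c], x$driver_genus_per_cluster[c],
                100 * x$driver_mean_abundance[c]))
  }
  invisible(x)
}
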