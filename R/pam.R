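#' Deterministic partitioning around medoids on a distance matrix
#'
#' Classic PAM: greedy BUILD seeding followed by steepest-descent SWAP
#' until no medoid exchange lowers the total distance of points to their
#' nearest medoid. Every tie (seed choice, swap choice, assignment) is
#' broken toward the lowest sample index, so the result is fully
#' deterministic — no random restarts.
#'
#' @param d symmetric distance matrix with zero diagonal (sample ids as
#'   dimnames are carried through).
#' @param k number of clusters, `2 <= k < n`.
#' @return list with `labels` (integer cluster index per sample, clusters
#'   numbered by ascending medoid index), `medoids` (indices into the
#'   matrix), `medoid_ids` (their dimnames, if any) and `cost` (total
#'   point-to-medoid distance).
#' @export
pam_medoids <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n")

  ## BUILD: start from the 1-medoid minimiser, then greedily add the
  ## candidate with the largest cost reduction.
  medoids <- which.min(colSums(d))
  dnear <- d[, medoids]
  while (length(medoids) < k) {
    gains <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(dnear - d[, j], 0))
    }, numeric(1L))
    best <- which.max(gains)  # which.max returns the first (lowest index) tie
    medoids <- c(medoids, best)
    dnear <- pmin(dnear, d[, best])
  }

  cost_of <- function(meds) sum(apply(d[, meds, drop = FALSE], 1L, min))
  cost <- cost_of(medoids)

  ## SWAP: steepest descent over all (medoid out, candidate in) pairs.
  repeat {
    best_cost <- cost
    best_swap <- NULL
    others <- setdiff(seq_len(n), medoids)
    for (oi in seq_along(medoids)) {
      rest <- medoids[-oi]
      dwo <- if (length(rest) == 1L) d[, rest] else
        do.call(pmin, lapply(rest, function(m) d[, m]))
      for (c in others) {
        newcost <- sum(pmin(dwo, d[, c]))
        if (newcost < best_cost - 1e-12) {
          best_cost <- newcost
          best_swap <- c(oi, c)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1L]] <- best_swap[2L]
    cost <- best_cost
  }

  medoids <- sort(medoids)
  assign <- apply(d[, medoids, drop = FALSE], 1L, which.min)  # ties: lowest medoid index
  list(labels = as.integer(assign),
       medoids = medoids,
       medoid_ids = if (!is.null(rownames(d))) rownames(d)[medoids] else NULL,
       cost = sum(d[cbind(seq_len(n), medoids[assign])]))
}

#' Calinski-Harabasz index on a distance matrix
#'
#' Distance-matrix form of the variance-ratio criterion. Using the
#' identity that a cluster's sum of squared deviations from its centroid
#' equals the sum of squared pairwise distances divided by twice its
#' size, the within-dispersion is
#' W = sum_c sum_{i<j in c} d_ij^2 / n_c, the total dispersion
#' T = sum_{i<j} d_ij^2 / n, the between-dispersion B = T - W, and
#' CH = (B / (k-1)) / (W / (n-k)). No coordinates or centroids are
#' needed, so the criterion applies directly to Jensen-Shannon
#' distances. A clustering with zero within-dispersion returns `Inf`.
#'
#' @param d symmetric distance matrix.
#' @param labels integer cluster index per sample (1..k).
#' @return the CH score (larger is better).
#' @export
calinski_harabasz <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  k <- length(unique(labels))
  if (k < 2L || n <= k) stop("need 2 <= k < n")
  d2 <- d^2
  total <- sum(d2) / (2 * n)
  w <- sum(vapply(unique(labels), function(c) {
    idx <- labels == c
    sum(d2[idx, idx]) / (2 * sum(idx))
  }, numeric(1L)))
  b <- max(total - w, 0)
  if (w == 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Silhouette widths on a distance matrix
#'
#' s(i) = (b - a) / max(a, b), where a is the mean distance of sample i
#' to the other members of its own cluster and b the smallest mean
#' distance to any other cluster. Samples in singleton clusters get
#' s = 0 by convention, as do samples with a = b = 0.
#'
#' @param d symmetric distance matrix.
#' @param labels integer cluster index per sample.
#' @return numeric vector of widths in `[-1, 1]`, named by sample id.
#' @export
silhouette_widths <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette needs at least two clusters")
  sizes <- table(factor(labels, levels = ks))
  ## mean distance from every sample to every cluster
  cl_sums <- vapply(ks, function(c) rowSums(d[, labels == c, drop = FALSE]),
                    numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(labels[i], ks)
    if (sizes[own] == 1L) { s[i] <- 0; next }
    a <- cl_sums[i, own] / (sizes[own] - 1L)
    b <- min(cl_sums[i, -own] / sizes[-own])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  stats::setNames(s, rownames(d))
}
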