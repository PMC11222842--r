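#' Alpha-diversity estimators
#'
#' Per-sample richness and evenness estimators computed from raw counts:
#' bias-corrected Chao1, the abundance-based coverage estimator (ACE),
#' Shannon entropy and the Simpson index on the probability scale
#' (1 - sum p_i^2, the probability of interspecific encounter).
#'
#' @param counts non-negative integer vector of per-taxon counts with at
#'   least one positive entry.
#' @name alpha-estimators
NULL

check_counts <- function(counts) {
  if (any(counts < 0) || !any(counts > 0)) {
    stop("counts must be non-negative with at least one positive entry")
  }
  counts[counts > 0]
}

#' @describeIn alpha-estimators bias-corrected Chao1 richness:
#'   S_obs + F1 (F1 - 1) / (2 (F2 + 1)), with F1 / F2 the singleton and
#'   doubleton counts.
#' @export
chao1 <- function(counts) {
  x <- check_counts(counts)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @describeIn alpha-estimators Chao & Lee ACE with abundance cutoff
#'   `rare_cutoff` (default 10) and the rare-taxon coefficient of
#'   variation floored at 0. When every rare taxon is a singleton the
#'   sample coverage is zero and the estimator is undefined; the Chao1
#'   value is returned instead, with attribute `fallback = TRUE` and a
#'   warning.
#' @param rare_cutoff abundance threshold separating rare from abundant
#'   taxa.
#' @export
ace <- function(counts, rare_cutoff = 10L) {
  x <- check_counts(counts)
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0L) return(as.numeric(s_abund))
  f1 <- sum(rare == 1)
  n_rare <- sum(rare)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    warning("all rare taxa are singletons; falling back to Chao1")
    out <- chao1(counts)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  i <- seq_len(rare_cutoff)
  f_i <- vapply(i, function(k) sum(rare == k), numeric(1L))
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * f_i) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' @describeIn alpha-estimators Shannon entropy
#'   H = -sum p_i log(p_i), in bits by default (base 2, the QIIME2
#'   convention) or nats with `base = exp(1)`.
#' @param base logarithm base, 2 (bits) or `exp(1)` (nats).
#' @export
shannon <- function(counts, base = 2) {
  x <- check_counts(counts)
  p <- x / sum(x)
  -sum(p * log(p, base = base))
}

#' @describeIn alpha-estimators Simpson index 1 - sum p_i^2 in `[0, 1)`.
#' @export
simpson <- function(counts) {
  x <- check_counts(counts)
  p <- x / sum(x)
  1 - sum(p^2)
}

#' Per-sample alpha-diversity table
#'
#' Computes observed richness, Chao1, ACE, Shannon (bits) and Simpson
#' for every sample of a counts-mode abundance table. Samples are not
#' rarefied beforehand; the returned data frame records each sample's
#' depth so unequal library sizes are visible downstream.
#'
#' @param table a counts-mode [abundance_table()].
#' @return data frame with one row per sample: `sample_id`, `depth`,
#'   `observed`, `chao1`, `ace`, `shannon`, `simpson` and an
#'   `ace_fallback` flag.
#' @export
alpha_diversity_table <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (!identical(ab_mode(table), "counts")) {
    stop("alpha diversity is defined on raw counts")
  }
  v <- ab_values(table)
  rows <- lapply(colnames(v), function(s) {
    x <- v[, s]
    res <- tryCatch({
      a <- withCallingHandlers(ace(x),
                               warning = function(w) invokeRestart("muffleWarning"))
      data.frame(sample_id = s, depth = sum(x), observed = sum(x > 0),
                 chao1 = chao1(x), ace = as.numeric(a),
                 shannon = shannon(x), simpson = simpson(x),
                 ace_fallback = isTRUE(attr(a, "fallback")),
                 stringsAsFactors = FALSE)
    }, error = function(e) stop(sprintf("sample '%s': %s", s, conditionMessage(e))))
    res
  })
  do.call(rbind, rows)
}
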