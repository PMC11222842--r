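#' Construct a taxon-by-sample abundance table
#'
#' The central container of the package: a non-negative taxon x sample
#' matrix with unique taxon and sample identifiers, an optional lineage
#' string per taxon, a mode flag (raw counts or relative abundances) and a
#' taxonomic level tag. All downstream stages (enterotyping, diversity,
#' differential abundance, association tests) consume this class.
#'
#' @param values numeric matrix, taxa in rows, samples in columns,
#'   all entries non-negative. Row names are taxon ids, column names
#'   sample ids (or supply `taxon_ids` / `sample_ids`).
#' @param mode `"counts"` (non-negative integers) or `"relative"`
#'   (every sample column sums to 1).
#' @param level taxonomic rank tag, e.g. `"genus"` or `"phylum"`.
#' @param taxonomy optional character vector of semicolon-delimited
#'   lineage strings, one per taxon.
#' @param taxon_ids,sample_ids optional identifier vectors overriding
#'   dimnames.
#'
#' @return An object of class `abundance_table`: the validated matrix with
#'   attributes `mode`, `level` and `taxonomy`.
#' @export
abundance_table <- function(values, mode = c("counts", "relative"),
                            level = "genus", taxonomy = NULL,
                            taxon_ids = NULL, sample_ids = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (!is.null(taxon_ids)) rownames(values) <- taxon_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("abundance_table needs taxon and sample identifiers (dimnames)")
  }
  obj <- structure(values, class = "abundance_table",
                   mode_flag = mode, level = level, taxonomy = taxonomy)
  validate_abundance_table(obj)
  obj
}

#' Validate an abundance table
#'
#' Checks the class invariants: non-negative values, integer counts in
#' counts mode, sample columns summing to one in relative mode, and
#' uniqueness of taxon and sample ids.
#'
#' @param x an `abundance_table`.
#' @return `x`, invisibly; errors describe the offending row/column.
#' @export
validate_abundance_table <- function(x) {
  v <- unclass(x)
  if (length(v) == 0L || nrow(v) == 0L || ncol(v) == 0L) {
    stop("abundance table is empty")
  }
  if (anyNA(v) || !is.numeric(v)) stop("abundance table has non-numeric or missing cells")
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
  }
  dup <- duplicated(rownames(v))
  if (any(dup)) stop(sprintf("duplicate taxon id '%s'", rownames(v)[dup][1L]))
  dup <- duplicated(colnames(v))
  if (any(dup)) stop(sprintf("duplicate sample id '%s'", colnames(v)[dup][1L]))
  mode <- attr(x, "mode_flag")
  if (identical(mode, "counts")) {
    if (any(abs(v - round(v)) > 1e-8)) {
      bad <- which(abs(v - round(v)) > 1e-8, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-integer count at taxon '%s', sample '%s'",
                   rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
    }
  } else {
    cs <- colSums(v)
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off)) {
      stop(sprintf("sample '%s' relative abundances sum to %.6g, not 1",
                   colnames(v)[off[1L]], cs[off[1L]]))
    }
  }
  tax <- attr(x, "taxonomy")
  if (!is.null(tax) && length(tax) != nrow(v)) {
    stop("taxonomy vector length does not match taxon count")
  }
  invisible(x)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (%s, level=%s)\n",
              nrow(x), ncol(x), attr(x, "mode_flag"), attr(x, "level")))
  invisible(x)
}

#' Accessors for abundance tables
#'
#' @param x an `abundance_table`.
#' @return `ab_mode()` the mode flag; `ab_level()` the rank tag;
#'   `ab_taxonomy()` the lineage strings or `NULL`; `ab_values()` the bare
#'   numeric matrix.
#' @export
ab_mode <- function(x) attr(x, "mode_flag")

#' @rdname ab_mode
#' @export
ab_level <- function(x) attr(x, "level")

#' @rdname ab_mode
#' @export
ab_taxonomy <- function(x) attr(x, "taxonomy")

#' @rdname ab_mode
#' @export
ab_values <- function(x) {
  v <- unclass(x)
  attr(v, "mode_flag") <- NULL
  attr(v, "level") <- NULL
  attr(v, "taxonomy") <- NULL
  v
}

#' Convert counts to relative abundances
#'
#' Divides every sample column by its library size so each column sums to
#' one, the scale on which Jensen-Shannon distances and enterotype
#' clustering operate.
#'
#' @param table an `abundance_table` in counts mode; every sample must have
#'   a positive total.
#' @return an `abundance_table` in relative mode, taxon order preserved.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (!identical(ab_mode(table), "counts")) {
    stop("to_relative expects a counts-mode table")
  }
  v <- ab_values(table)
  tot <- colSums(v)
  if (any(tot <= 0)) {
    stop(sprintf("sample '%s' has zero total count", colnames(v)[which(tot <= 0)[1L]]))
  }
  abundance_table(sweep(v, 2L, tot, "/"), mode = "relative",
                  level = ab_level(table), taxonomy = ab_taxonomy(table))
}

#' Collapse taxa to a higher taxonomic rank
#'
#' Sums taxa sharing the same name at the requested rank of their lineage
#' string (semicolon-delimited, optionally with `g__`-style rank
#' prefixes). Taxa whose lineage lacks that rank go into a single
#' `"unclassified"` bucket. Per-sample totals are conserved, and output
#' taxa are sorted lexicographically for deterministic ordering.
#'
#' @param table an `abundance_table` with taxonomy strings attached.
#' @param rank target rank name: one of `"kingdom"`, `"phylum"`,
#'   `"class"`, `"order"`, `"family"`, `"genus"`, `"species"`.
#' @return an `abundance_table` at the requested level.
#' @export
collapse_to_level <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  tax <- ab_taxonomy(table)
  if (is.null(tax)) stop("collapse_to_level requires taxonomy strings")
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  idx <- match(match.arg(rank, ranks), ranks)
  name_at <- vapply(strsplit(tax, ";", fixed = TRUE), function(parts) {
    if (length(parts) < idx) return("unclassified")
    nm <- trimws(parts[[idx]])
    nm <- sub("^[a-z]__", "", nm)  # QIIME-style rank prefixes
    if (nzchar(nm)) nm else "unclassified"
  }, character(1L))
  v <- ab_values(table)
  grouped <- rowsum(v, group = name_at, reorder = TRUE)
  abundance_table(grouped, mode = ab_mode(table), level = rank)
}
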