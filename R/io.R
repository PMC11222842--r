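#' Read a taxon-by-sample abundance table from TSV
#'
#' Accepts a plain tab-delimited matrix (one header row of identifiers)
#' or the QIIME2 feature-table export dialect: leading comment lines
#' starting with `#` (a `#OTU ID` header line is treated as the header,
#' not a comment) and an optional trailing `taxonomy` column when taxa
#' are rows. The table is normalised internally to taxon x sample
#' orientation.
#'
#' @param path TSV file path.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @param mode `"counts"` or `"relative"`.
#' @param level taxonomic rank tag to attach.
#' @return a validated [abundance_table()].
#' @export
read_abundance_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                                 mode = c("counts", "relative"),
                                 level = "genus") {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  lines <- readLines(path, encoding = "UTF-8")
  # keep a '#OTU ID' header (QIIME2 export), drop other leading comments
  is_comment <- startsWith(lines, "#") & !startsWith(lines, "#OTU ID")
  lines <- lines[!is_comment]
  if (length(lines) < 2L) stop(sprintf("'%s': empty table", path))
  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop(sprintf("'%s': no data columns", path))
  ids <- as.character(df[[1L]])
  dup <- duplicated(ids)
  if (any(dup)) {
    stop(sprintf("'%s': duplicate %s id '%s'", path,
                 if (orientation == "taxa_rows") "taxon" else "sample",
                 ids[dup][1L]))
  }
  # header ids must be checked before subsetting, which would uniquify them
  col_ids <- names(df)[-1L]
  dup <- duplicated(col_ids)
  if (any(dup)) {
    stop(sprintf("'%s': duplicate %s id '%s'", path,
                 if (orientation == "taxa_rows") "sample" else "taxon",
                 col_ids[dup][1L]))
  }
  body <- df[, -1L, drop = FALSE]
  taxonomy <- NULL
  tax_col <- which(tolower(names(body)) == "taxonomy")
  if (orientation == "taxa_rows" && length(tax_col)) {
    taxonomy <- as.character(body[[tax_col[1L]]])
    body <- body[, -tax_col, drop = FALSE]
  }
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num)) {
        stop(sprintf("'%s': non-numeric cell in column '%s', row %d", path,
                     names(body)[j], which(is.na(num))[1L]))
      }
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples_rows") {
    m <- t(m)
  }
  abundance_table(m, mode = mode, level = level, taxonomy = taxonomy)
}

#' Write an abundance table as TSV
#'
#' Emits a UTF-8, tab-delimited file with Unix line endings. Taxa-rows
#' output carries a leading `taxon_id` column and, when lineages are
#' attached, a trailing `taxonomy` column; samples-rows output starts
#' with a `sample_id` column.
#'
#' @param table an `abundance_table`.
#' @param path output file.
#' @param orientation `"taxa_rows"` or `"samples_rows"`.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path,
                                  orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  v <- ab_values(table)
  if (orientation == "taxa_rows") {
    df <- data.frame(taxon_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    tax <- ab_taxonomy(table)
    if (!is.null(tax)) df$taxonomy <- tax
  } else {
    tv <- t(v)
    df <- data.frame(sample_id = rownames(tv), tv, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

phenotype_trait_names <- c("body_weight", "dressed_weight", "eviscerated_weight",
                           "breast_muscle_weight", "leg_muscle_weight")
phenotype_pct_names <- c("dressed_percentage", "eviscerated_yield_percentage",
                         "leg_muscle_percentage", "breast_muscle_percentage")

#' Read / write per-sample phenotype tables
#'
#' Phenotype TSVs carry one row per sample with a `sample_id` column, the
#' five measured weights in grams (`body_weight`, `dressed_weight`,
#' `eviscerated_weight`, `breast_muscle_weight`, `leg_muscle_weight`) and,
#' optionally, the four derived carcass percentages.
#'
#' @param path TSV file path.
#' @return `read_phenotype_table()` a validated phenotype data frame;
#'   `write_phenotype_table()` the path, invisibly.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_phenotype_table(df)
  df
}

#' @rdname read_phenotype_table
#' @param phenotypes a phenotype data frame as returned by
#'   [derive_carcass_traits()] or [simulate_phenotypes()].
#' @export
write_phenotype_table <- function(phenotypes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(phenotypes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a phenotype table
#'
#' Enforces positive weights, the carcass ordering
#' eviscerated <= dressed <= body, and derived percentages in (0, 100].
#'
#' @param df phenotype data frame.
#' @return `df`, invisibly.
#' @export
validate_phenotype_table <- function(df) {
  need <- c("sample_id", phenotype_trait_names)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in phenotype table")
  for (w in phenotype_trait_names) {
    if (any(!is.finite(df[[w]]) | df[[w]] <= 0)) {
      stop(sprintf("non-positive %s for sample '%s'", w,
                   df$sample_id[which(df[[w]] <= 0)[1L]]))
    }
  }
  if (any(df$dressed_weight > df$body_weight)) {
    stop("dressed weight exceeds body weight for sample '",
         df$sample_id[which(df$dressed_weight > df$body_weight)[1L]], "'")
  }
  if (any(df$eviscerated_weight > df$dressed_weight)) {
    stop("eviscerated weight exceeds dressed weight for sample '",
         df$sample_id[which(df$eviscerated_weight > df$dressed_weight)[1L]], "'")
  }
  for (p in intersect(phenotype_pct_names, names(df))) {
    if (any(df[[p]] <= 0 | df[[p]] > 100)) {
      stop(sprintf("%s outside (0, 100] for sample '%s'", p,
                   df$sample_id[which(df[[p]] <= 0 | df[[p]] > 100)[1L]]))
    }
  }
  invisible(df)
}

#' Derive carcass-trait percentages from measured weights
#'
#' Applies the poultry carcass-evaluation conventions: dressed percentage
#' and eviscerated-yield percentage are expressed relative to live body
#' weight; breast- and leg-muscle percentages relative to eviscerated
#' weight.
#'
#' @param raw data frame with `sample_id` and the five measured weights in
#'   grams (see [read_phenotype_table()] for column names).
#' @return the input with the four percentage columns appended, validated.
#' @export
derive_carcass_traits <- function(raw) {
  validate_phenotype_table(raw)
  out <- raw
  out$dressed_percentage <- raw$dressed_weight / raw$body_weight * 100
  out$eviscerated_yield_percentage <- raw$eviscerated_weight / raw$body_weight * 100
  out$leg_muscle_percentage <- raw$leg_muscle_weight / raw$eviscerated_weight * 100
  out$breast_muscle_percentage <- raw$breast_muscle_weight / raw$eviscerated_weight * 100
  validate_phenotype_table(out)
  out
}
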