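#' Default end-to-end run configuration
#'
#' A plain named list of every pipeline setting: either simulation
#' parameters (the default cohort) or paths to abundance / phenotype /
#' label TSVs, the clustering k range, and the analysis thresholds
#' (network rho/p cuts, test level alpha, LDA score threshold). The
#' configuration round-trips losslessly through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L, out_dir = "enterotyper_run") {
  structure(list(
    simulate = TRUE,
    abundance_path = NULL,
    phenotype_path = NULL,
    labels_path = NULL,
    theta = 60,
    component_sizes = c(76L, 67L, 57L),
    depth_range = c(21243L, 59481L),
    n_filler = 100L,
    richness_boost = 30L,
    leg_shift_sd = 1.0,
    rho_lactococcus_leg = 0.35,
    rho_lactococcus_dressed = 0.25,
    rho_bradyrhizobium_yield = 0.45,
    k_min = 2L, k_max = 10L,
    rho_min = 0.6, p_max = 0.01,
    alpha = 0.05, lda_threshold = 4.0,
    network_top_n = 15L,
    seed = as.integer(seed),
    out_dir = out_dir), class = "run_config")
}

validate_run_config <- function(config) {
  stopifnot(config$alpha > 0, config$alpha < 1,
            config$rho_min >= 0, config$rho_min <= 1,
            config$p_max > 0, config$p_max <= 1,
            config$lda_threshold >= 0,
            config$k_min >= 2L, config$k_max >= config$k_min,
            config$seed >= 0L)
  invisible(config)
}

#' Read / write a run configuration file
#'
#' @param path YAML configuration file.
#' @param config a `run_config` list.
#' @return the configuration (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- default_run_config()
  for (nm in names(raw)) config[nm] <- list(raw[[nm]])  # keeps NULL entries
  config$seed <- as.integer(config$seed)
  config$component_sizes <- as.integer(config$component_sizes)
  config$depth_range <- as.integer(config$depth_range)
  for (nm in c("k_min", "k_max", "n_filler", "richness_boost", "network_top_n")) {
    config[[nm]] <- as.integer(config[[nm]])
  }
  validate_run_config(config)
  config
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  # FNV-1a over the canonical JSON encoding of the scientific settings;
  # the output location does not alter results and is excluded
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                        null = "null")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    ## 32-bit modular multiply split into 16-bit halves (doubles hold
    ## every intermediate exactly)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", (h - h %% 65536) / 65536), sprintf("%04x", h %% 65536))
}

write_stage_tsv <- function(df, path, meta) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full enterotyping pipeline
#'
#' Simulates (or loads) a cohort, fits enterotypes, computes per-sample
#' alpha diversity, trait tests, the genus co-occurrence network,
#' genus-trait correlations and the LEfSe-style differential-abundance
#' table, and writes every stage as TSV plus a JSON summary into
#' `config$out_dir`. All outputs embed the configuration hash and seed,
#' and re-running an identical configuration reproduces identical bytes.
#' A failing stage stops with a stage-named error; outputs of earlier
#' stages are retained.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return the summary list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta <- sprintf("config_hash=%s seed=%d", hash, config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("input", {
    if (isTRUE(config$simulate)) {
      template <- build_default_template(
        component_sizes = config$component_sizes,
        concentration = config$theta,
        depth_range = config$depth_range,
        n_filler = config$n_filler,
        richness_boost = config$richness_boost)
      effects <- list(leg_shift_sd = config$leg_shift_sd,
                      rho_lactococcus_leg = config$rho_lactococcus_leg,
                      rho_lactococcus_dressed = config$rho_lactococcus_dressed,
                      rho_bradyrhizobium_yield = config$rho_bradyrhizobium_yield)
      simulate_cohort(template, effects, seed = config$seed)
    } else {
      ab <- read_abundance_table(config$abundance_path)
      ph <- read_phenotype_table(config$phenotype_path)
      lab <- NULL
      if (!is.null(config$labels_path)) {
        ldf <- utils::read.delim(config$labels_path, comment.char = "#")
        lab <- stats::setNames(as.integer(ldf[[2L]]), ldf[[1L]])
      }
      list(abundance = ab, phenotypes = ph, labels = lab, seed = config$seed)
    }
  })
  write_abundance_table(cohort$abundance, file.path(out, "abundance.tsv"))
  write_phenotype_table(cohort$phenotypes, file.path(out, "phenotypes.tsv"))
  if (!is.null(cohort$labels)) {
    write_stage_tsv(data.frame(sample_id = names(cohort$labels),
                               true_component = cohort$labels),
                    file.path(out, "true_labels.tsv"), meta)
  }

  k_range <- config$k_min:config$k_max
  model <- stage("enterotype", fit_enterotypes(cohort$abundance, k_range))
  if (length(k_range) == 1L) {
    warning("k selection constrained to a single value (k = ", k_range, ")")
  }
  write_stage_tsv(data.frame(sample_id = names(model$labels),
                             enterotype = model$labels,
                             silhouette = model$silhouette_per_sample,
                             mds1 = model$coords[, 1L],
                             mds2 = model$coords[, 2L]),
                  file.path(out, "enterotypes.tsv"), meta)
  write_stage_tsv(data.frame(k = as.integer(names(model$ch_by_k)),
                             ch = model$ch_by_k),
                  file.path(out, "ch_by_k.tsv"), meta)

  div <- stage("diversity", alpha_diversity_table(cohort$abundance))
  write_stage_tsv(div, file.path(out, "diversity.tsv"), meta)

  rel <- to_relative(cohort$abundance)
  traits <- stage("trait_tests",
                  pairwise_trait_tests(cohort$phenotypes, model$labels))
  write_stage_tsv(traits, file.path(out, "trait_tests.tsv"), meta)
  net <- stage("network",
               correlation_network(rel, rho_min = config$rho_min,
                                   p_max = config$p_max,
                                   top_n = config$network_top_n))
  write_stage_tsv(net$edges, file.path(out, "network_edges.tsv"), meta)
  gtc <- stage("genus_trait",
               genus_trait_correlations(rel, cohort$phenotypes,
                                        genus_set = net$nodes$genus))
  write_stage_tsv(gtc, file.path(out, "genus_trait_correlations.tsv"), meta)

  lef <- stage("lefse",
               run_lefse(cohort$abundance, model$labels,
                         alpha = config$alpha,
                         lda_threshold = config$lda_threshold,
                         seed = config$seed))
  export_lefse(lef, file.path(out, "lefse.tsv"))

  echoed <- unclass(config)
  echoed$out_dir <- NULL  # location does not affect results
  summary <- list(
    config_hash = hash,
    seed = config$seed,
    config = echoed,
    n_samples = length(model$labels),
    k_selected = model$k_selected,
    cluster_sizes = as.integer(model$cluster_sizes),
    driver_genera = model$driver_genus_per_cluster,
    driver_mean_abundance_pct = round(100 * model$driver_mean_abundance, 4),
    silhouette_mean = model$silhouette_mean,
    n_network_edges = nrow(net$edges),
    n_lefse_passed = sum(lef$passed))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
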