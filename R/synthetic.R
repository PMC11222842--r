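#' Default community template for the simulated ileal cohort
#'
#' Builds the three-component genus-level community the simulator draws
#' from: a 200-bird cohort split 76/67/57 across three enterotype-like
#' components, each dominated by the genus that characterises it
#' (component 1: Streptococcus 17.40% with Vibrio 12.20%; component 2:
#' Candidatus Arthromitus 33.39%; component 3: Bacteroides 30.94%).
#' The remaining mass of each component is spread deterministically over
#' the other dominant ileal genera (geometric 0.85-decay weights over a
#' per-component rotation of the dominant list, 85% of the remainder)
#' and over `n_filler` low-abundance filler genera (15%, split equally).
#' Component 3 additionally reserves mass for `richness_boost` rare
#' genera (mean relative abundance 1e-4 each) so that it carries higher
#' richness, as observed for the Bacteroides-driven enterotype.
#'
#' @param component_sizes integer vector of three component sizes.
#' @param concentration Dirichlet precision theta (scalar or one value
#'   per component); larger values give tighter communities.
#' @param depth_range integer interval of per-sample sequencing depths.
#' @param n_filler number of filler genera.
#' @param richness_boost number of extra rare genera seeded only into
#'   component-3 samples.
#' @return a `community_template` list with `genus_names`,
#'   `component_means` (3 probability vectors), `component_sizes`,
#'   `concentration`, `depth_range`, `boost_genera` and `boost_mean`.
#' @export
build_default_template <- function(component_sizes = c(76L, 67L, 57L),
                                   concentration = 60,
                                   depth_range = c(21243L, 59481L),
                                   n_filler = 100L,
                                   richness_boost = 30L) {
  stopifnot(length(component_sizes) == 3L, all(component_sizes > 0),
            all(concentration > 0), length(depth_range) == 2L,
            depth_range[1L] <= depth_range[2L])
  dominants <- c("Streptococcus", "Vibrio", "Candidatus Arthromitus",
                 "Bacteroides", "Romboutsia", "Cetobacterium",
                 "Clostridium sensu stricto 1", "Terrisporobacter",
                 "Escherichia-Shigella", "Lactobacillus", "Enterococcus",
                 "Turicibacter", "Lactococcus", "Bradyrhizobium")
  fillers <- sprintf("Genus%03d", seq_len(n_filler))
  boosters <- if (richness_boost > 0L) sprintf("RareGenus%02d", seq_len(richness_boost)) else character()
  genus_names <- c(dominants, fillers, boosters)

  planted <- list(
    c(Streptococcus = 0.1740, Vibrio = 0.1220),
    c(`Candidatus Arthromitus` = 0.3339),
    c(Bacteroides = 0.3094)
  )
  boost_mean <- 1e-4
  rotations <- c(0L, 4L, 8L)  # distinct secondary profiles per component
  component_means <- lapply(1:3, function(comp) {
    mean_vec <- stats::setNames(numeric(length(genus_names)), genus_names)
    mean_vec[names(planted[[comp]])] <- planted[[comp]]
    boost_mass <- if (comp == 3L) richness_boost * boost_mean else 0
    remainder <- 1 - sum(planted[[comp]]) - boost_mass
    others <- setdiff(dominants, names(planted[[comp]]))
    rot <- rotations[comp] %% length(others)
    others <- c(others[(rot + 1L):length(others)], others[seq_len(rot)])
    w <- 0.85^(seq_along(others) - 1L)
    mean_vec[others] <- remainder * 0.85 * w / sum(w)
    mean_vec[fillers] <- remainder * 0.15 / n_filler
    if (comp == 3L && richness_boost > 0L) mean_vec[boosters] <- boost_mean
    mean_vec
  })
  structure(list(genus_names = genus_names,
                 component_means = component_means,
                 component_sizes = as.integer(component_sizes),
                 concentration = rep_len(concentration, 3L),
                 depth_range = as.integer(depth_range),
                 boost_genera = boosters,
                 boost_mean = boost_mean),
            class = "community_template")
}

## Gaussian-copula coupling: map the ranks of x onto normal scores and mix
## with independent noise so cor(coupled, x) targets Spearman rho_s.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

copula_couple <- function(x, rho_s) {
  n <- length(x)
  z <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  r <- spearman_to_pearson(rho_s)
  r * z + sqrt(1 - r^2) * stats::rnorm(n)
}

#' Simulate genus-level count tables from a community template
#'
#' For each sample of component c a composition is drawn from
#' Dirichlet(theta_c * mean_c), a sequencing depth is drawn uniformly
#' from the template depth range, and counts from
#' Multinomial(depth, composition). Component-3 samples additionally
#' receive seeded counts (1 + Poisson(3)) for each rare boost genus,
#' carved out of the drawn depth so the total stays inside the depth
#' range; this raises their observed richness without disturbing the
#' planted dominant means.
#'
#' @param template a `community_template` from [build_default_template()].
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @return list with `abundance` (counts-mode [abundance_table()]) and
#'   `labels` (integer component index per sample, named by sample id).
#' @export
simulate_counts <- function(template, seed) {
  stopifnot(inherits(template, "community_template"))
  if (any(template$concentration <= 0)) stop("concentration theta must be > 0")
  set.seed(as.integer(seed))
  genus <- template$genus_names
  n <- sum(template$component_sizes)
  labels <- rep.int(1:3, template$component_sizes)
  sample_ids <- sprintf("S%03d", seq_len(n))
  counts <- matrix(0L, nrow = length(genus), ncol = n,
                   dimnames = list(genus, sample_ids))
  n_boost <- length(template$boost_genera)
  boost_idx <- match(template$boost_genera, genus)
  for (i in seq_len(n)) {
    comp <- labels[i]
    alpha <- template$concentration[comp] * template$component_means[[comp]]
    g <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(g) <= 0) g[which.max(alpha)] <- 1  # degenerate-draw guard
    p <- g / sum(g)
    depth <- sample.int(template$depth_range[2L] - template$depth_range[1L] + 1L,
                        1L) + template$depth_range[1L] - 1L
    boost <- integer(0)
    if (comp == 3L && n_boost > 0L) {
      boost <- 1L + stats::rpois(n_boost, 3)
    }
    drawn <- stats::rmultinom(1L, size = depth - sum(boost), prob = p)[, 1L]
    if (length(boost)) drawn[boost_idx] <- drawn[boost_idx] + boost
    counts[, i] <- drawn
  }
  abundance <- abundance_table(counts, mode = "counts", level = "genus")
  list(abundance = abundance,
       labels = stats::setNames(labels, sample_ids))
}

#' Default phenotype effect configuration
#'
#' Effect sizes linking the simulated community to growth and carcass
#' traits: an additive component-3 shift on leg muscle weight (in pooled
#' standard deviations) and Gaussian-copula Spearman targets coupling
#' Lactococcus abundance to leg-muscle and dressed-weight variation and
#' Bradyrhizobium abundance to eviscerated-yield variation.
#'
#' @return a named list of effect parameters.
#' @export
default_phenotype_effects <- function() {
  list(leg_shift_sd = 1.0,
       rho_lactococcus_leg = 0.35,
       rho_lactococcus_dressed = 0.25,
       rho_bradyrhizobium_yield = 0.45)
}

#' Simulate growth-performance and carcass phenotypes
#'
#' Body weight is drawn from one shared normal distribution (no
#' enterotype effect). Dressed and eviscerated weights are proportional
#' to body weight with noisy ratios; the dressed ratio's noise is
#' copula-coupled to the rank of Lactococcus and the eviscerated ratio's
#' noise to the rank of Bradyrhizobium, so eviscerated-yield percentage
#' inherits those rank correlations. Leg muscle weight receives an
#' additive shift (`leg_shift_sd` pooled SDs) in component-3 birds and
#' Lactococcus-coupled noise. Derived percentages come from
#' [derive_carcass_traits()].
#'
#' @param labels integer component index per sample, named by sample id.
#' @param abundance counts- or relative-mode [abundance_table()] aligned
#'   with `labels`.
#' @param effects effect configuration, see [default_phenotype_effects()].
#' @param seed integer seed.
#' @return a validated phenotype data frame with raw weights (g) and
#'   derived percentages.
#' @export
simulate_phenotypes <- function(labels, abundance,
                                effects = default_phenotype_effects(),
                                seed = 1L) {
  stopifnot(inherits(abundance, "abundance_table"))
  v <- ab_values(abundance)
  if (!identical(sort(names(labels)), sort(colnames(v)))) {
    stop("labels and abundance table cover different sample sets")
  }
  labels <- labels[colnames(v)]
  n <- length(labels)
  set.seed(as.integer(seed))
  rel <- sweep(v, 2L, pmax(colSums(v), .Machine$double.eps), "/")
  lacto <- if ("Lactococcus" %in% rownames(rel)) rel["Lactococcus", ] else stats::runif(n)
  brady <- if ("Bradyrhizobium" %in% rownames(rel)) rel["Bradyrhizobium", ] else stats::runif(n)

  body <- stats::rnorm(n, mean = 2400, sd = 150)
  z_dressed <- copula_couple(lacto, effects$rho_lactococcus_dressed)
  dressed <- body * (0.88 + 0.012 * z_dressed)
  z_evis <- copula_couple(brady, effects$rho_bradyrhizobium_yield)
  evis <- dressed * (0.80 + 0.015 * z_evis)
  breast <- evis * 0.165 + 20 * stats::rnorm(n)
  z_leg <- copula_couple(lacto, effects$rho_lactococcus_leg)
  leg <- evis * 0.105 + 18 * (z_leg + effects$leg_shift_sd * (labels == 3L))

  raw <- data.frame(sample_id = names(labels),
                    body_weight = body,
                    dressed_weight = dressed,
                    eviscerated_weight = evis,
                    breast_muscle_weight = breast,
                    leg_muscle_weight = leg,
                    stringsAsFactors = FALSE)
  derive_carcass_traits(raw)
}

#' Simulate one correlated pair via a Gaussian copula
#'
#' Draws a bivariate normal sample whose Pearson correlation
#' r = 2 sin(pi * rho_s / 6) makes the population Spearman correlation
#' equal to `rho_s`; used to calibrate rank-correlation recovery.
#'
#' @param n sample size (>= 10).
#' @param rho_s target Spearman correlation, strictly inside (-1, 1).
#' @param seed integer seed.
#' @return list with numeric vectors `x` and `y` of length `n`.
#' @export
simulate_correlated_pair <- function(n, rho_s, seed = 1L) {
  if (abs(rho_s) >= 1) stop("|rho_s| must be < 1")
  stopifnot(n >= 10L)
  set.seed(as.integer(seed))
  r <- spearman_to_pearson(rho_s)
  x <- stats::rnorm(n)
  y <- r * x + sqrt(1 - r^2) * stats::rnorm(n)
  list(x = x, y = y)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper drawing counts (seed), then phenotypes (seed + 1,
#' the documented sub-stream offset).
#'
#' @inheritParams simulate_counts
#' @inheritParams simulate_phenotypes
#' @return list with `abundance`, `phenotypes`, `labels` and `seed`.
#' @export
simulate_cohort <- function(template = build_default_template(),
                            effects = default_phenotype_effects(),
                            seed = 1L) {
  seed <- as.integer(seed)
  counts <- simulate_counts(template, seed = seed)
  phen <- simulate_phenotypes(counts$labels, counts$abundance,
                              effects = effects, seed = seed + 1L)
  list(abundance = counts$abundance, phenotypes = phen,
       labels = counts$labels, seed = seed)
}
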