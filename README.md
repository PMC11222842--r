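# enterotyper

Enterotyping and trait association for poultry gut-microbiota studies.

Gut bacterial communities often fall into a small number of discrete
compositional clusters — *enterotypes* — each dominated by a single
"driver" genus. In meat ducks, enterotype membership of the ileal
microbiota has been linked to carcass traits such as leg-muscle weight,
making the enterotype a candidate biomarker for production phenotypes.
`enterotyper` implements the full analysis chain a 16S genus-level
cohort study of this kind needs:

* **Enterotyping.** Pairwise distances between samples are the square
  root of the Jensen–Shannon divergence between genus relative-abundance
  profiles, d(P,Q) = sqrt[(KL(P‖M) + KL(Q‖M))/2] with M = (P+Q)/2 — a
  bounded metric on compositions. Samples are clustered with a fully
  deterministic partitioning-around-medoids (BUILD + steepest-descent
  SWAP, lowest-index tie-breaks); the number of clusters is chosen by
  the Calinski–Harabasz variance-ratio criterion computed directly from
  the distance matrix, and validated by silhouette widths. Clusters are
  reported in decreasing size, each named by its driver genus.
* **Alpha diversity.** Observed richness, bias-corrected Chao1,
  ACE, Shannon entropy (bits) and Simpson (1 − Σp²) per sample.
* **Differential abundance.** A LEfSe-style procedure: Kruskal–Wallis
  screen, strict all-pairs Wilcoxon consistency gate, and a
  bootstrapped linear-discriminant effect size reported as
  log10(1 + effect), with the conventional screening threshold of 4.0.
* **Trait associations.** Spearman co-occurrence networks (|ρ| > 0.6,
  p < 0.01 defaults), Welch t-tests of growth and carcass traits across
  enterotypes, and genus-trait rank correlations.
* **Synthetic cohorts.** A Dirichlet-multinomial simulator that
  generates a 200-bird, three-enterotype ileal community with planted
  dominant-genus abundances, realistic sequencing depths, and
  copula-coupled phenotype effects, so the entire chain is testable
  end to end without access to sequencing data.

## Worked example

Simulate the default cohort and fit enterotypes:

```r
library(enterotyper)

cohort <- simulate_cohort(seed = 1)
model  <- fit_enterotypes(cohort$abundance)
model
#> enterotype model: k = 3 (CH-selected), mean silhouette 0.294
#>   ET1: n = 76, driver = Streptococcus (16.5%)
#>   ET2: n = 67, driver = Candidatus Arthromitus (33.1%)
#>   ET3: n = 57, driver = Bacteroides (30.6%)
```

The Calinski–Harabasz criterion is maximised at k = 3, and the three
recovered clusters match the planted 76/67/57 components exactly: the
largest is dominated by *Streptococcus* (mean relative abundance about
17%), the second by *Candidatus Arthromitus* (about 33%) and the third
by *Bacteroides* (about 31%). Downstream stages take the fitted labels:

```r
div    <- alpha_diversity_table(cohort$abundance)   # per-sample indices
tests  <- pairwise_trait_tests(cohort$phenotypes, model$labels)
lefse  <- run_lefse(cohort$abundance, model$labels, seed = 1)
sum(lefse$passed)
#> [1] 14
```

ET3 shows the highest Chao1 richness, leg-muscle weight differs between
ET3 and the other clusters while body weight does not, and the three
driver genera all pass the differential-abundance gates enriched in
their own enterotype.

The same chain runs from the shell:

```sh
Rscript inst/cli/enterotyper.R run --seed 1 --out my_run
```

which writes every stage as TSV plus a JSON summary into `my_run/`.

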