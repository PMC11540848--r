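# xqtl

Integrative proteogenomic QTL analysis in R: from isobaric (TMT)
reporter-ion quantification of proteins, through cis/trans QTL mapping of
mRNA and protein abundance, to colocalization, transcript-mediation
classification, summary-based Mendelian randomization against GWAS, and
multi-evidence candidate-gene prioritization.

## Who this is for

Groups analysing bulk-tissue molecular phenotypes — protein and/or mRNA
abundance measured across genotyped donors — who want one tested, seeded,
scriptable implementation of the full statistical chain that connects
genetic variants to molecular traits and on to disease loci. Every stage
is a tibble-in/tibble-out function, so results compose with dplyr and
plot with `autoplot()`.

## The statistics at the core

* **Quantification**: per-PSM reporter intensities are impurity-corrected
  (solve *M t = observed*), filtered (min ≥ 1000, median ≥ 5000),
  channel-normalized by trimmed medians, summarized to proteins (mean
  relative intensity × grand mean of the top-3 PSMs, log2), and bridged
  across batches on the pooled internal-standard channel.
* **Mapping**: for each trait, slopes of (factor-corrected,
  inverse-normal-transformed) abundance on dosage in a ±1 Mb cis window;
  per-trait multiplicity handled by fitting Beta(a, b) to the permutation
  distribution of the window's minimum p, giving an adjusted empirical p,
  with Storey q-values genome-wide and a Bonferroni threshold
  α/(variants × traits) for trans scans. Positive β = higher expression
  with the reference allele.
* **Colocalization**: Wakefield log-ABFs
  ½[log(V/(V+W)) + z²W/(V+W)] aggregated over single-causal-variant
  configurations into posteriors PP0–PP4 of the five hypotheses.
* **Mediation**: z-standardized drop of −log10 p of the pQTL after
  conditioning on the gene's mRNA, against a permutation null of the mRNA
  covariate; transcript-dependent when z ≤ −4.26 (= Φ⁻¹(10⁻⁵)).
* **SMR/HEIDI**: b_xy = b_GWAS/b_QTL with T_SMR = z₁²z₂²/(z₁²+z₂²) ~ χ²₁;
  HEIDI tests homogeneity of b_xy across LD partners of the instrument to
  exclude linkage.
* **Prioritization**: joint order-statistic tail probability Q of a
  gene's rank ratios across evidence sources (recursive k!·V_k formula),
  plus a PPI connectivity score (risk-gene neighbours at combined score
  ≥ 700).

A seeded synthetic-data generator (`sim_config()`, `simulate_*()`)
produces genotypes with block LD under HWE, mRNA/protein traits with a
known mediated/direct split, GWAS summaries under causal, pleiotropic,
linkage or null mechanisms, and multi-batch 11-plex PSM tables — so the
entire pipeline runs and is tested without external data.

## Worked example

Simulate a 268-sample cohort (30 genes, 10 LD blocks), correct traits,
map protein QTLs, then colocalize and classify mediation for the
significant ones:

```r
library(xqtl)
library(dplyr)

cfg  <- sim_config(n_samples = 268, n_variants = 200, n_blocks = 10,
                   n_genes = 30, maf_range = c(0.2, 0.5), seed = 42)
geno <- simulate_genotypes(cfg)
sim  <- simulate_traits(geno, cfg)

mrna    <- correct_traits(sim$mrna,    n_factors = 5)
protein <- correct_traits(sim$protein, n_factors = 5)

w    <- window_config(n_permutations = 1000)
pqtl <- map_qtl(protein, geno, w, "cis", seed = 1)
glance(pqtl)
#> # A tibble: 1 × 4
#>   n_traits n_tested n_significant   pi0
#>      <int>    <int>         <int> <dbl>
#> 1       30       30            14     1

sig <- filter(pqtl, qvalue < 0.05)
head(select(sig, trait_id, variant_id, beta, nominal_p, adjusted_p, qvalue), 4)
#> # A tibble: 4 × 6
#>   trait_id variant_id   beta   nominal_p adjusted_p    qvalue
#> 1 G003     chr3:40000  0.477 0.000000177 0.00000623 0.0000374
#> 2 G005     chr5:40000  0.332 0.0000915   0.00168    0.00631
#> 3 G006     chr6:40000  0.352 0.000849    0.0147     0.0315
#> 4 G010     chr10:40000 0.304 0.000404    0.00785    0.0196
```

14 of 30 proteins have a significant cis-pQTL at q < 0.05; each record
carries the top variant, its slope (reference-allele orientation, so
G003's protein rises by 0.48 SD per reference allele), the
beta-approximated empirical p and the q-value.

```r
med <- mediation_classify(protein, mrna, geno,
                          sig[, c("trait_id", "variant_id")], seed = 7)
mediation_summary(med, protein, mrna)
#> # A tibble: 2 × 4
#>   classification     n percent mean_cor
#> 1 dependent          8    57.1    0.569
#> 2 independent        6    42.9    0.145
```

Eight of the 14 significant pGenes are transcript-dependent (their pQTL
signal collapses when conditioning on mRNA; mean mRNA–protein r = 0.57),
six are transcript-independent (r = 0.15) — and all 14 calls match the
generator's ground truth for this seed.

Plots: `autoplot(pqtl, geno)` (effect size vs MAF), `plot_mediation(med)`
(−log10 p before vs after conditioning), `autoplot()` on coloc and SMR
results, `plot_factor_variance()` for the factor scree.

`run_pipeline(pipeline_config(out_dir = "out", seed = 1))` executes the
whole chain — simulate → quantify → correct → map (cis, trans) → coloc →
mediate → SMR → prioritize — writing every intermediate as a plain-text
table plus a manifest with parameters and checksums; reruns with the same
seed are byte-identical.

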