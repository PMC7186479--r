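# microts

Analysis of microbiome time series: compositional normalization and
ordination, non-parametric diel-periodicity screening with false discovery
rate control, and model-based inference of virus–host interaction networks.

## Who this is for

Microbial ecologists working with taxon-by-sample count tables (OTU/ASV
tables) sampled repeatedly over time — for example an amplicon survey
sampled every 4 hours over several days. Such data are compositional (reads
sum to sequencing depth), autocorrelated, and heteroscedastic, which breaks
the assumptions behind naive correlation and ordination workflows. `microts`
packages the corrective machinery in one place, together with seeded
synthetic-data generators so every step can be exercised and tested without
downloading anything.

## What is inside

**Transforms** — pseudocounts, focal log-ratio, centered log-ratio
(CLR: `ln x_i − mean_k ln x_k`, columns sum to 0), isometric log-ratio
(orthonormal re-expression of CLR), z-scores, started log `ln(x + c)`,
linear detrending.

**Dissimilarity and ordination** — Euclidean, Jaccard, Bray–Curtis
(`1 − 2 Σ min(s_i, s_j) / (Σ s_i + Σ s_j)`, flagged non-metric), Aitchison
(Euclidean on CLR); PCA, PCoA (Gower double-centering, negative eigenvalues
reported rather than repaired), metric least-squares MDS with stress
`sqrt(Σ(d − d′)² / Σ d²)`.

**Clustering** — from-scratch PAM (BUILD + SWAP), agglomerative clustering,
SSE, Calinski–Harabasz `[B/(k−1)]/[W/(n−k)]`, two silhouette variants, and a
`k` sweep table.

**Periodicity** — an umbrella rank test: for each candidate peak phase the
statistic counts observation pairs concordant with a single rise and fall
(Mann–Whitney style over phase classes), referred to a seeded permutation
null, Bonferroni-corrected over candidate peaks, then Benjamini–Hochberg
step-up FDR across taxa. Plus the cautionary random-walk demonstration of
spurious correlation in autocorrelated series.

**Virus–host module** — Lotka–Volterra dynamics
`Ḣ_i = r_i H_i (1 − ΣH/K) − H_i Σ_j M_ij φ_ij V_j`,
`V̇_j = V_j Σ_i M_ij φ_ij β_ij H_i − m_j V_j`; coexisting nested communities
by construction; inference of the weighted infection network `M̃ = M∘φ∘β`
and decay rates `m` by non-negative L1-regularized least squares on
per-capita derivative estimates, with blocked cross-validation for the
penalty and ground-truth recovery metrics.

## Worked example

Screen a synthetic 3-day diel table (19 samples, 4-h spacing) for 24-h
periodic taxa, then infer a 10x10 virus–host network from simulated
dynamics:

```r
library(microts)

ct <- gen_diel_table(diel_design(n_taxa = 50, seed = 42))
ct
#> count_table: 50 taxa x 19 samples
#> depth range: 50000 - 50000
#> times (h): 0, 4, 8, 12, 16, 20, ...

m   <- detrend_linear(clr(add_pseudocount(ct, 1)))
res <- periodicity_screen(m, period = 24, delta_t = 4,
                          alpha = 0.05, n_perm = 2000, seed = 42)
sum(res$q_rejected)
#> [1] 10
head(res[order(res$p_value), ], 3)
#>  taxon_id statistic     p_value peak_phase_class q_rejected
#>  taxon001       120 0.002998501                0       TRUE
#>  taxon002       115 0.002998501                0       TRUE
#>  taxon003       109 0.002998501                2       TRUE
```

All 10 planted periodic taxa (the generator marks them in
`attr(ct, "periodic_taxa")`) are recovered at a 5% FDR; `peak_phase_class`
maps each peak onto the 6 four-hour phase classes of the day. Ordination of
the same table:

```r
head(scree(pcoa(aitchison_dist(ct))), 3)
#>  axis variance_fraction cumulative
#>     1         0.1946520  0.1946520
#>     2         0.1672776  0.3619296
#>     3         0.1041655  0.4660950
```

Virus–host network recovery from noiseless dynamics (150 h sampled every
0.1 h, penalty chosen by blocked cross-validation):

```r
com <- sample_community(10, 10, seed = 42)
eq  <- vh_equilibrium(com)
set.seed(43)
ts  <- simulate_vh(com, eq$H_star * runif(10, 0.8, 1.2),
                   eq$V_star * runif(10, 0.8, 1.2),
                   t_end = 150, sample_times = seq(0, 150, 0.1))
inp <- percapita_derivatives(ts)
sel <- select_lambda(inp, grid = 10^seq(-8, 3, 1), folds = 5)
fit <- infer_network(inp, lambda = sel$lambda)
recovery_metrics(com, fit, support_threshold = 1e-3)
#> support F1 = 0.991, relative Frobenius error = 0.0007,
#> decay-rate error = 0.0003
```

Nearly every true infection link is recovered with the right weight; the
methods vignette (`vignettes/microbiome-time-series-methods.Rmd`) explains
the experiment design and every tolerance.

## Command line

A thin wrapper exposes the same pipelines:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/microts.R", package = "microts"))')
Rscript "$CLI" periodicity --input counts.tsv --metadata meta.tsv \
    --period 24 --delta-t 4 --alpha 0.05 --seed 1 --out results/
```

Subcommands: `transform`, `distance`, `ordinate`, `cluster`, `periodicity`,
`simulate-vh`, `infer-vh`, `fixtures`, `fig1-demo`. Every run writes a
`manifest.json` with the version, configuration and seed needed to
reproduce it.

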