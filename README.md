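# mirtinet

Scoring the influence of microRNAs on their targets through a
functional protein interaction network.

## The problem

A microRNA (miRNA) represses its target mRNAs, so a functional
miRNA-target pair should show *negative* expression correlation — but
sequence-predicted target lists (TargetScan-style `Seq` relations) are
large and noisy, and correlation alone cannot separate direct
regulation from co-variation. The idea implemented here is that a
miRNA which truly matters does not just move its target: it moves the
target's *neighborhood* in the functional protein interaction (FPI)
network, because proteins act in complexes and pathways. `mirtinet`
turns that idea into a quantitative influence score, and then uses the
resulting miRNA-target influence network as a design matrix to ask
which miRNAs explain a patient's expression profile, or the
transcriptional activity landscape of the whole network.

It is aimed at computational biologists with matched miRNA/mRNA
expression from the same cohort (e.g. a tumor profiling study), a
protein interaction network, and a sequence-based candidate target
relation.

## The score

For a candidate pair `(miR, t)` with `Seq(miR, t) = 1`, three evidence
channels are combined multiplicatively:

    miRTI(miR, t) = Corrmir(miR, t) * W(miR, t) * max_k CorrFPI(t, k)

* `Corrmir(miR, t)` — mutual information `MI(miR, t)` between the two
  expression profiles, kept only when their Pearson correlation is
  negative (repression), else 0;
* `CorrFPI(t, k)` — `MI(t, k)` for each FPI partner `k` of `t`
  (0 for non-edges); the `max` term is the target's strongest partner
  co-expression;
* `W(miR, t) = Σ_k MI(miR, k) · MI(k, t)` — the miRNA's indirect
  influence on the target through its partners.

A zero in any channel annihilates the score: no sequence support, no
repression signature, or an isolated target each give `miRTI = 0`.
MI is estimated by equal-frequency discretization (8 bins by default),
making every channel invariant under monotone transforms of
expression. Pairs above the upper quartile of positive scores form
miRNA-target modules (connected components including the FPI edges
among retained targets).

Downstream, the package:

* regresses each patient's expression profile on the miRTI columns
  with an elastic net (`alpha = 0.5`, 100-value lambda path, 10-fold
  CV at minimum MSE) to get a miRNA × patient influence matrix;
* computes per-gene transcriptional activity-center scores
  `mean_d(CorrFPI(i,d)·R(d)) · max_d(CorrFPI(i,d)·R(d))` where
  `R = -log10(p)` from a per-gene t-test, classifies principal
  regulators, and regresses the activity profile on miRTI columns;
* relates protein degree and clustering coefficient to the number of
  targeting miRNAs, with degree-preserving randomized nulls;
* evaluates influence matrices by two-group risk clustering,
  Kaplan-Meier/log-rank/hazard-ratio statistics, and cross-validated
  linear-SVM classification.

A synthetic-cohort generator with planted repression modules,
degree-coupled decoy targeting, and risk-linked survival makes the
whole pipeline testable without any external download.

## Worked example

```r
library(mirtinet)

sim <- simulate_dataset(sim_config(seed = 1))
sim
#> Synthetic cohort: 600 genes x 100 samples, 50 miRNAs
#>   1937 interaction edges; 652 candidate pairs (75 planted)

net <- build_mirti(sim$mirna, sim$mrna, sim$fpi, sim$seq)
dplyr::arrange(net, dplyr::desc(mirti))
#> # A tibble: 652 x 7
#>    mirna   target pearson corrmir     w max_corrfpi mirti
#>  1 miR-001 G0003   -0.901   0.857 16.2        0.923 12.8
#>  2 miR-001 G0009   -0.896   0.954 13.4        0.951 12.1
#>  3 miR-001 G0002   -0.911   0.939 12.8        0.945 11.4
#> # ...
```

The top-scoring pairs are exactly the planted driver-module
interactions: strong anticorrelation (`pearson ~ -0.9`), high
miRNA-target MI (`corrmir`), and a strongly co-expressed, miRNA-driven
neighborhood (`w`, `max_corrfpi`).

```r
modules <- extract_modules(net, sim$fpi)
attr(modules, "threshold")      # upper quartile of positive scores
#> [1] 1.779927
sum(modules$type == "mirna_target")
#> [1] 94

glance(topology_mirna_correlation(sim$fpi, sim$seq))
#> # A tibble: 1 x 5
#>   n_proteins degree_r  degree_p clustering_r clustering_p
#> 1        600    0.758 5.12e-113        0.274     9.34e-12
```

Hubs attract more targeting miRNAs (`degree_r = 0.76`), the coupling
the generator plants with exponent `kappa = 1`;
`randomize_for_null()` destroys it while preserving degrees.

```r
design <- build_design(net, rownames(sim$mrna))
fit <- fit_patient_influence(design, sim$mrna, enet_config(seed = 1))
fit
#> Elastic-net influence fit: 50 miRNAs x 100 response column(s)
#>   alpha = 0.5; median nonzero coefficients = 8

tumor  <- sim$ann$sample[sim$ann$class != "normal"]
normal <- sim$ann$sample[sim$ann$class == "normal"]
de   <- differential_significance(sim$mrna, tumor, normal)
prof <- classify_regulators(
  activity_scores(compute_corrfpi(sim$mrna, sim$fpi), de))
table(prof$class)
#>                     none posttranslational_center    significant_DE_center
#>                      506                       18                       76

split <- cluster_two_groups(t(sim$mirna))
logrank_hr(split, sim$ann)
#> # A tibble: 1 x 8
#>   n_high n_low chisq       p hazard_ratio hr_low hr_high degenerate
#> 1     43    57  8.43 0.00370         2.44   1.31    4.54 FALSE
```

The clustered risk groups recover the planted survival difference
(true hazard ratio 2.8; estimated 2.44, log-rank p = 0.0037).
`autoplot()` methods draw the topology trend and the influence
heatmap; `plot_km()` draws the Kaplan-Meier curves;
`tidy()`/`glance()` return tibbles for all fitted objects.

A command-line wrapper with `simulate` / `build` / `influence` /
`activity` / `topology` / `evaluate` subcommands lives at
`inst/scripts/mirti_cli.R`.

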