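# dosenet

Dosage compensation and network propagation analysis for *Drosophila*
deficiency-heterozygote (*Df/+*) expression studies.

Halving the dose of a gene rarely halves its expression. In deficiency
heterozygotes — flies carrying one deleted and one intact copy of a
chromosomal segment — one-dose genes show heterogeneous, gene-specific
responses, and the perturbation propagates into the normal-dose (two-dose)
part of the transcriptome along co-expression networks. `dosenet`
implements the full analysis chain for such a panel (21 deficiency lines
plus the parental strain, two sexes, replicated profiles, matched
DNA-seq), and ships a synthetic-data generator that plants known ground
truth so every stage can be verified without external data.

**Stages and core statistics**

1. *Dose confirmation*: reads-per-million (RPM) over deleted segments,
   wild-type vs deficiency fold differences (≈ 2 confirms heterozygous
   loss), and a windowed scan of paired coverage tracks for unannotated
   deletions.
2. *Expression substrate*: replicate QC (Spearman ρ ≥ 0.8), detection
   thresholds at 2 SD above control probes, parental/composite median
   references, and an empirical-Bayes moderated one-sample t-test
   (s̃²g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), prior fitted by moment matching
   on log s²; BH-corrected).
3. *Compensation classes*: the two-step classifier. Genes not rejecting
   LFC = −1 are **non**-compensated; rejected genes below −1 are
   **anti**-compensated; the remainder are split into **partial / full /
   over** by a bootstrap-calibrated band (mean ± 1.96·SD of the resampled
   step-2 LFC distribution, recentred at zero).
4. *Networks and propagation*: sex-specific mutual-information networks
   (Gaussian-kernel plug-in estimator, h = 0.3; pooled permutation null,
   edges at p < 0.005), degree-preserving randomization nulls, per-line
   differential expression against the composite reference, neighbor
   change probability and direction by compensation class, and
   hypergeometric protein-complex coherence.

## Worked example

A synthetic study at the default design (500 genes, 21 lines + parental,
triplicates, both sexes):

```r
library(dosenet)

cfg  <- synthetic_config(seed = 42)
sim  <- simulate_expression(cfg)
defs <- sim$truth$deficiencies
defs
#> deficiency_set: 21 lines; 194 one-dose genes in union

## 1. confirm gene dose from simulated DNA-seq coverage
tracks <- simulate_coverage(cfg, defs, "female")
tab <- dose_table(list(female = tracks), defs)
head(tab[, c("region", "rpm_df", "rpm_wt", "fold_2dec")], 3)
#>   region   rpm_df   rpm_wt fold_2dec
#> 1   Df01 9625.592 19161.51      1.99
#> 2   Df02 8215.690 16128.50      1.96
#> 3   Df03 6078.902 12571.46      2.07
summarize_dose_table(tab)      # mean 1.98, sd 0.04: dose is halved

## 2. classify dosage-compensation responses of one-dose genes
mask   <- detection_mask(sim$expr, "female")
ref    <- build_reference(sim$expr, "composite", "female")
ratios <- onedose_ratios(sim$expr, defs, "female", ref,
                         detected = mask$detected)
calls  <- classify_compensation(moderated_t(ratios, null_lfc = -1),
                                seed = 1)
calls
#> compensation_calls: 193 genes
#>    anti     non partial    full    over
#>       7     147       0      37       2
#>   step-2 band (centred): [-0.508, 0.508]
```

The class table illustrates a documented property of the two-step rule:
the step-2 band adapts to the spread of its own input, so moderate planted
"partial" effects (−0.6 here) land inside the band and are reported as
full/non — see the methods vignette for the geometry and for the separable
benchmark under which ≥ 90% of planted labels are recovered.

Mean dose response against the parental reference:

```r
lfc <- vapply(onedose_ratios(sim$expr, defs, "female",
                             build_reference(sim$expr, "parental", "female"),
                             detected = mask$detected), mean, numeric(1))
2^(-mean(lfc))
#> [1] 1.65    # ~1.6-fold mean reduction, not the naive 2-fold
```

Network inference and propagation (a scenario with strong planted
sympathetic propagation):

```r
cfg2 <- propagation_demo_config(seed = 42)
sim2 <- simulate_expression(cfg2)
res  <- run_propagation_pipeline(sim2$expr, sim2$truth$deficiencies,
                                 "female", seed = 1)
res$network_stats
#> $n_nodes 500  $n_edges 2912  $clustering 0.306
#> $avg_neighbors 11.6  $density 0.0233  $powerlaw_exponent -1.06
res$neighbor_change$by_class
#>     class n_hubs n_neighbors n_changed prob_change         p
#> 1    anti     10         127        47       0.370  2.54e-40
#> 2     non     80         931       199       0.214 2.22e-273
#> 3 partial      0           0         0          NA        NA
#> 4    full     60         749        75       0.100  1.79e-35
#> 5    over      3          57        16       0.281  1.43e-12
res$neighbor_change$global$rate
#> [1] 0.027
```

First-degree neighbors of anti-compensated genes change expression most
often (0.37 vs a global rate of 0.027) — the propagation signature.

A thin CLI wraps the same functions (`exec/dosenet`):

```sh
dosenet simulate --seed 1 --out-prefix synth
dosenet coverage --df-track synth_coverage_female_Df01.bedGraph \
    --wt-track synth_coverage_female_w1118.bedGraph \
    --regions synth_deficiencies.tsv --out dose_table.tsv
dosenet classify --matrix synth_expression.tsv \
    --deficiencies synth_deficiencies.tsv --annotation synth_genes.tsv \
    --sex female --seed 1 --out calls.tsv
dosenet network --matrix synth_expression.tsv --sex female --out edges.tsv
```

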