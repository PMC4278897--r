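# tissuespec

Tissue-specificity classification of bulk RNA-seq expression panels.

Given a gene × sample FPKM matrix spanning many tissues and a target tissue
(the motivating application is the human pancreas profiled against 26 other
tissue types), `tissuespec` assigns every gene one of six mutually exclusive
specificity categories:

| category | rule (FPKM vector *x*, target *t*, *n* tissues) |
|---|---|
| not detected | *x<sub>t</sub>* < 1 |
| tissue enriched | *x<sub>t</sub>* ≥ 5 · max<sub>j≠t</sub> *x<sub>j</sub>* |
| group enriched | a group *G* ∋ *t*, 2 ≤ \|G\| ≤ 7, with min<sub>G</sub> *x* ≥ 5 · max<sub>∉G</sub> *x* |
| tissue enhanced | *x<sub>t</sub>* ≥ 5 · mean of all *n* tissues |
| expressed in all | *x<sub>j</sub>* ≥ 1 in every tissue |
| mixed | detected, none of the above |

The first three are jointly termed **elevated**. Every gene also receives a
tissue-specific score *x<sub>t</sub>* / max<sub>j≠t</sub> *x<sub>j</sub>*.
Detection is FPKM ≥ 1 (about one mRNA per cell); all thresholds are
parameters. The combinatorial group search is implemented as an exact
sorted-prefix scan and verified in the test suite against exhaustive subset
enumeration.

Around the classifier the package provides:

- **expression I/O** — TSV readers/writers with validation, replicate
  averaging into tissue profiles, log2(x+1) transform;
- **composition** — per-category share of the target tissue's mRNA pool,
  expressed fraction, dynamic range;
- **similarity QC** — pairwise Spearman correlation between samples (all
  genes, or genes detected in either member of a pair);
- **compartments** — genes enriched in purified isolate preparations (e.g.
  pancreatic islet / exocrine fractions) but not in whole tissue, with a
  three-set Venn partition;
- **sharing network** — node/edge tables of tissue combinations carrying
  group-enriched genes (node size = √gene count);
- **synthetic data** — a generator planting genes of every category with
  configurable fold margins, replicate noise and within-lane barcode
  leakage (~0.1%), with ground truth for recovery testing;
- **pipeline** — `run_tissuespec()` drives everything from one config and
  writes a JSON manifest (parameters, version, input checksums).

Functions are data-frame-first and return tibbles, so stages chain with the
pipe; fitted result objects have `tidy()`/`glance()` methods and
`plot_*()`/`autoplot()` companions.

## Worked example

Simulate a 27-tissue panel with 2,000 planted genes, 5% replicate noise and
0.1% barcode leakage, then classify it:

```r
library(tissuespec)

sim     <- simulate_dataset(simulation_config(noise_cv = 0.05,
                                              leakage_rate = 0.001), seed = 42)
profile <- average_replicates(sim$fpkm, sim$annotation)
classes <- classify_tissue_specificity(profile, "pancreas")
glance(classes)
#> # A tibble: 1 × 9
#>   target   n_genes not_detected tissue_enriched group_enriched tissue_enhanced
#>   <chr>      <int>        <int>           <int>          <int>           <int>
#> 1 pancreas    2000          679             100            100             100
#> # ℹ 3 more variables: expressed_in_all <int>, mixed <int>, elevated <int>
```

All 300 planted elevated genes are recovered (the 679 vs 700 not-detected
difference is genes straddling the 1-FPKM cutoff under noise). The elevated
genes dominate the simulated mRNA pool, and expression spans five orders of
magnitude:

```r
glance(mrna_pool_fractions(profile, classes, "pancreas"))
#> # A tibble: 1 × 3
#>   target   elevated_n elevated_fraction
#>   <chr>         <int>             <dbl>
#> 1 pancreas        300             0.987

dynamic_range(profile, "pancreas")
#> # A tibble: 1 × 3
#>   min_detected     max   ratio
#>          <dbl>   <dbl>   <dbl>
#> 1         1.00 156643. 156521.

glance(recovery_report(sim$truth, classes))
#> # A tibble: 1 × 2
#>   n_genes accuracy
#>     <int>    <dbl>
#> 1    2000    0.986
```

Sample-level QC shows replicates of one tissue correlating near 1 and
unrelated tissues much lower:

```r
cc <- spearman_matrix(sim$fpkm)
round(unclass(cc)[c("pancreas_1", "pancreas_2", "liver_1"),
                  c("pancreas_1", "pancreas_2", "liver_1")], 3)
#>            pancreas_1 pancreas_2 liver_1
#> pancreas_1      1.000      0.999   0.346
#> pancreas_2      0.999      1.000   0.346
#> liver_1         0.346      0.346   1.000
```

## Applying it to a real panel

`run_tissuespec()` runs the whole analysis from two TSV files — an FPKM
matrix (`gene` column + one column per sample) and a sample annotation
(`sample_id`, `tissue`, `donor`, `compartment`, `lane`):

```r
run_tissuespec(list(
  matrix     = "fpkm.tsv",
  annotation = "samples.tsv",
  target     = "pancreas",
  isolates   = c("islet", "exocrine"),   # optional compartment analysis
  outdir     = "results/"
))
```

For the reference 27-tissue human panel (ArrayExpress accession
E-MTAB-1733; FPKM matrix from the Human Protein Atlas download page) this
reproduces the published pancreas numbers — the elevated census and its
enriched/group/enhanced split, the expressed fraction, the elevated share of
the mRNA pool, housekeeping and mixed counts, and the pairwise sample
correlations. The isolate FPKM values were never deposited, so compartment
results can only be validated against the synthetic generator.

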