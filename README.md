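# polyprof

Quantitative analysis of bacterial **polysome profiling** experiments:
from per-fraction RNA-seq counts of a sucrose gradient to per-gene
translation metrics and the gene features that explain them.

Polysome profiling separates a cell extract's mRNA–ribosome complexes on a
sucrose gradient by ribosome load. The gradient is collected as 24
subfractions and pooled into seven fractions — A (free mRNA and free
ribosomal subunits), B (monosome), C–G (increasingly heavy polysomes) —
and each fraction of each biological replicate is sequenced. From the
counts `N[i,j,k]` (gene × fraction × replicate), the package computes, for
every monocistronic gene:

* **Ribosome occupancy** — the percentage of mRNA copies engaged by at
  least one ribosome: `RO[i,k] = Σ_{j=B..G} p[i,j,k] = 100 − p[i,A,k]`,
  where `p` is the gene's percentage profile across fractions; reported as
  mean ± sd over replicates.
* **Peak fraction** — the translated fraction carrying the gene's largest
  mRNA share, validated by a bootstrap on residuals (1000 resamples;
  pooled residuals re-assigned to fractions); the gene is *confined* when
  the modal peak recurs in ≥ 95% of bootstrap profiles.
* **Ribosome density** — ribosomes per 100 nt of ORF from the peak
  fraction's ribosome number: `RD[i] = n_peak / L_i × 100`, bounded above
  by the theoretical packing ceiling `100/30 ≈ 3.3` ribosomes/100 nt for
  a ~30-nt footprint (densities above it are excluded).

Counts are made comparable across libraries by a three-stage
normalization: median-of-ratios size factors, rescaling by each fraction's
ribodepletion yield over the 10 ng library aliquot, and by its total RNA
over the 5 µg ribodepletion aliquot. Downstream, the package compares
translation profiles between low and high mRNA-concentration conditions
(per-fraction log ratios, relative RO changes), quantifies transcripts
from ERCC-spike-normalized qPCR Ct tables, and fits multiple linear
regression models `RO = α + Xβ + ξ` and `log RD = α + Xβ + ξ` on 17
standardized gene covariates with deviation-coded categories and stepwise
AIC selection, plus Spearman/Benjamini–Hochberg univariate screens.

A synthetic-data module (`simulate_gradient_study()`,
`simulate_covariate_study()`, `simulate_induction_pair()`,
`simulate_qpcr()`) generates all of these inputs with known ground truth,
so every estimator is validated end-to-end by parameter recovery.

## Worked example

```r
library(polyprof)

sim <- simulate_gradient_study(n_genes = 60, depth = 2e4, seed = 42)
pp <- polysome_profile(sim$counts,
                       orf_lengths = with(sim$truth$table,
                                          setNames(orf_length, gene)),
                       n_boot = 500, seed = 42)
pp
#> polysome_profile pipeline result
#> fraction_counts: 60 genes x 21 libraries (7 fractions x 3 replicates), phase: custom
#> normalized counts present (size factors 1.21, 0.397, 1.51, 3.76, ...)
#> 60 genes quantified; mean RO 89.9% (sd 7.5); 55 genes with confined peak; mean RD 0.6 ribosomes/100 nt
#> excluded: 0 low-count, 0 empty-profile, 0 outlier-RD gene(s)

head(merge(pp$metrics, sim$truth$table, by = "gene")[
  c("gene", "ro_mean", "ro_true", "peak_fraction", "peak_true", "rd")])
#>      gene  ro_mean  ro_true peak_fraction peak_true         rd
#> 1 gene001 99.49908 99.59671             D         D 0.35545024
#> 2 gene002 85.62665 86.04711             G         G 1.06761566
#> 3 gene003 92.11704 92.54190             E         E 0.45248869
#> 4 gene004 94.19107 94.43004             F         F 0.89153046
#> 5 gene005 92.66143 92.82988             B         B 0.09345794
#> 6 gene006 90.90103 89.25713             E         E         NA
```

Estimated occupancies track the simulated truth to about one percentage
point, the bootstrap-confirmed peak fractions match the true peaks, and RD
is reported only where the peak is confined (`gene006` was not). The
regression side works from any metrics table:

```r
s <- simulate_covariate_study(800, c(mrna_conc = 0.3, orf_gc = -0.2),
                              sigma = 1, seed = 1)
fit <- fit_translation_model(s$metrics, s$covariates, response = "RO",
                             select = "both")
summary(fit)   # standardized coefficients, p-values, R^2, AIC
```

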