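---
title: "Quantifying translation from polysome profiles: models and design choices"
author: "polyprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translation from polysome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyprof)
```

## The measurement

Polysome profiling separates mRNA–ribosome complexes on a sucrose gradient
by the number of bound ribosomes. The gradient is collected from the top as
24 subfractions, which are pooled into seven analysis fractions: fraction A
contains free RNAs and free 30S/50S ribosomal subunits (untranslated
material), fraction B the monosome, and C–G increasingly heavy polysomes.
Each fraction of each biological replicate is sequenced as its own library,
so the data are counts $N_{i,j,k}$ for gene $i$, fraction $j \in
\{A,\dots,G\}$, replicate $k$.

Two per-gene quantities summarize translation:

* **Ribosome occupancy (RO)** — the percentage of a gene's mRNA copies
  engaged by at least one ribosome,
  $RO_{i,k} = \sum_{j=B}^{G} p_{i,j,k} = 100 - p_{i,A,k}$,
  where $p_{i,j,k}$ is the percentage of the gene's mRNA in fraction $j$.
  The reported RO is the mean over replicates, with its sample sd.
* **Ribosome density (RD)** — ribosomes per 100 nt of ORF, computed from
  the number of ribosomes attributed to the gene's *peak fraction* (the
  translated fraction holding the largest share of its mRNA):
  $RD_i = n_{\text{peak}(i)} / L_i \times 100$ with $L_i$ the ORF length.
  The physical ceiling is $100/30 \approx 3.3$ ribosomes/100 nt for a
  ribosome footprint of about 30 nt; densities above the ceiling are
  excluded as outliers (strict inequality).

## Pooling subfractions

`classify_subfractions()` delimits fraction A as the leading block of
subfractions whose 23S/16S rRNA ratio falls outside the whole-ribosome
window (default $[1.5, 2.1]$ around the nominal 1.8). The remaining
subfractions are cut at the local minima of the total rRNA signal
(16S + 23S) after a running-mean smoothing of window 3; the first four
abundance peaks become B–E and the later peaks are pooled into F and G.
When only a single unresolved heavy-polysome tail remains after the fourth
peak, it is split at its midpoint into F and G; fewer than four resolvable
peaks is an error.

Two practical notes on this rule. First, a window-3 running mean cannot
resolve peaks narrower than about four subfractions — the shoulder windows
absorb the peak top — so six resolvable peaks require most of the gradient;
traces with very sharp, closely spaced peaks should be pooled with the
smoothing disabled upstream or gated manually. Second, the minimum
subfraction itself is assigned to the block on its lighter side; the choice
is arbitrary but deterministic and conserves all reads.

The ribosome numbers per fraction are fixed for A–E (0, 1, 2, 3, 4: the
first four peaks are the monosome and the 2-, 3- and 4-ribosome polysomes)
while F and G pool heavier polysomes whose counts depend on the gradient
and pooling. `build_ribosome_map()` defaults to F = 6 and G = 9 — midpoints
of the plausible pooled ranges 5–7 and 8–10 — and both are user-settable;
every metrics table records the map used, and RD values scale linearly with
these two entries.

## The normalization chain

Raw counts reflect sequencing depth and two bench-side dilutions, undone in
three stages (`normalize_counts()`):

1. **Library size** — median-of-ratios size factors: for library $\ell$,
   $s_\ell = \operatorname{median}_i \left( N_{i\ell} / (\prod_{\ell'}
   N_{i\ell'})^{1/L} \right)$ over genes with a positive geometric mean.
   This corrects depth and library-construction efficiency. The estimator
   is implemented here directly (and checked in the test suite against
   both a literal brute-force oracle and DESeq2's implementation); the
   median is taken in ratio space, which for an odd number of usable genes
   coincides with the log-space median.
2. **Ribodepletion yield** — library construction uses a 10 ng aliquot of
   ribodepleted RNA, so counts are multiplied by
   $q^{\text{ribo}}_{j,k} / 10\,\text{ng}$, the fraction's measured yield
   over the aliquot.
3. **Total RNA** — ribodepletion itself starts from a 5 µg aliquot of the
   fraction's total RNA, so counts are finally multiplied by
   $Q^{\text{tot}}_{j,k} / 5\,\mu\text{g}$.

The result is proportional to the number of mRNA copies of each gene in
each fraction, from which per-replicate percentage profiles are computed.
Genes with fewer than 10 reads summed over fractions in *every* replicate
are excluded up front (one replicate at the threshold retains the gene;
`filter_low_counts(scope = "library")` gives the stricter per-library
reading). A zero-total (gene, replicate) profile has no defined
percentages and is dropped from that replicate rather than imputed.

The chain has a useful exact invariance: multiplying one library's raw
counts by any constant changes its size factor by the same constant (up to
a common geometric-mean factor across libraries) and leaves all recovered
proportions unchanged, as does moving a constant between the two metadata
quantities of a library. The test suite asserts both exactly.

## Bootstrap peak calling

The peak fraction consumes only the argmax of the mean profile over B–G,
so its stability is assessed by a bootstrap on residuals
(`bootstrap_peak_fraction()`): residuals $r_{j,k} = p_{j,k} - \bar p_j$
are pooled across all seven fractions and replicates; each of 1000
bootstrap profiles adds one residual, drawn with replacement, to each
fraction mean; the peak is recorded per profile. The modal peak's relative
frequency measures confinement, and a gene is *confined* when that
frequency reaches 0.95 — the operational reading of a 95% confidence
requirement that yields a single-fraction selection rule. RD is computed
only for confined genes.

Numerical choices: bootstrap profiles are neither renormalized to sum to
100 nor clipped at zero, because renormalization cannot change an argmax
and clipping could; argmax ties break toward the lighter fraction,
deterministically. With at least two identical replicates the residual
pool is all zeros and the call is fully confined (frequency 1.0); a gene
with no translated signal and no residuals is reported as undetermined
rather than assigned a peak. Pooling residuals across fractions assumes
roughly exchangeable replicate noise between fractions; fractions with
systematically larger variability will leak variance into quieter ones,
which makes the confinement call conservative there.

## Induction comparisons and qPCR

For a gene measured at low and high mRNA concentration,
`compare_induction()` reports per-fraction log ratios of mean proportions,
$\log_2\left((\bar p^{high}_j + c)/(\bar p^{low}_j + c)\right)$ with a
pseudo-proportion $c = 0.1$ percentage points guarding empty fractions
(configurable; 0 is allowed when all fractions are populated), and the
relative RO increase $(RO^{high} - RO^{low})/RO^{low} \times 100$. The log
base is 2 by default and recorded in the output; both choices only rescale
the ratios. qPCR abundances are quantified against ERCC spike-ins added at
constant amount: per primer pair, abundance $= E^{\,Ct_{spike} -
Ct_{target}}$ with amplification efficiency $E = 2$ (perfect doubling)
unless calibrated otherwise; multiple primer pairs for one gene are pooled
by geometric mean, the natural average in fold-change space. Fraction-level
qPCR values are rescaled by each fraction's extracted total RNA over the
5 µg assay aliquot, then feed the same proportion/RO machinery as counts.

## Regression on gene covariates

`fit_translation_model()` explains RO (percent) or $\log_{10}$ RD with
nine quantitative covariates (mRNA concentration, ORF length and GC%, CAI,
distance from OriC, GRAVY hydrophobicity, 5'UTR GC% and length, TIR
folding energy) and eight qualitative ones (strand, essentiality, signal
peptide, inner-membrane protein, cell location, COG class, CsrA target,
purine/pyrimidine second 5'UTR nucleotide). Skewed positive covariates
(mRNA, ORF length, CAI, 5'UTR length) are log-transformed — base 10, a
choice made immaterial by the subsequent z-scoring — and every
quantitative column is standardized, so coefficients are comparable effect
sizes. ORF length is removed from the RD model because RD contains
$1/L_i$ by construction. Qualitative covariates are deviation (sum-to-zero)
coded: each level's coefficient is its deviation from the level average,
the reported per-level sets sum to zero exactly, and the omitted level's
p-value is not separately testable from the fit (reported as NA).

Model selection uses stepwise AIC (default: both directions from the full
model), with a qualitative covariate's columns moving as one block; the
search is deterministic given the design's column order, and the selected
model's AIC never exceeds the full model's. Genes with missing covariates
are dropped listwise and counted. Univariate screening is available via
`spearman_bh()` (Spearman rank correlations, Benjamini–Hochberg adjusted
across the covariate family).

## What the synthetic data emulate — and what they do not

The generator reproduces the statistical structure the pipeline assumes,
with known ground truth:

* **Profiles** (`simulate_fraction_profile()`): fraction A holds
  $100 - RO$; the translated mass follows a tempered binomial kernel over
  B–G, $w_j \propto \binom{5}{j} \pi^j (1-\pi)^{5-j}$ with
  $\pi = (m + 0.5)/6$ raised to the power $1/\text{spread}^2$. Spread 1 is
  the plain binomial with mode at the chosen peak, spread → 0 a point
  mass. The kernel is a modelling stand-in — real profile shapes are not
  parametric — chosen as the simplest two-parameter unimodal family on six
  bins.
* **Counts** (`simulate_counts()`): per replicate, profiles receive a
  Dirichlet perturbation (concentration $200 \times p/100$ by default,
  respecting the sum constraint with realistic overdispersion), then each
  library is a multinomial read sample over genes at 5 × 10⁴ reads,
  times a per-library distortion left for the size factors to absorb.
  Metadata (ribodepletion ng, total µg) are emitted consistently with the
  simulated mRNA masses and the realized library efficiencies, so the
  normalization chain recovers the perturbed profiles exactly in the
  no-sampling limit (`sampling = "expected"`) and in expectation
  otherwise. Defaults — 300 genes, 3 replicates, 5 × 10⁴ reads, true RO
  normal with mean 90 and sd 7 clipped to [15, 100] — mirror a
  three-replicate bacterial study with high occupancies.
* **Covariate studies** (`simulate_covariate_study()`): covariates drawn
  from log-normal/uniform/normal/multinomial marginals typical of an
  E. coli annotation; responses are linear in the standardized design with
  chosen coefficients, $RO = \mathrm{clip}(60 + 10(X\beta + \varepsilon),
  15, 100)$ and $\log_{10} RD = \log_{10}(0.45) + 0.3 (X\beta +
  \varepsilon')$. The scaling puts RO in a realistic percent range while
  keeping clipping rare; sign and significance of recovered effects are
  scale-free.
* **Induction pairs** (`simulate_induction_pair()`) move a chosen share of
  fraction-A mass into heavy fractions and multiply mRNA abundance;
  **qPCR tables** (`simulate_qpcr()`) encode abundances as
  $Ct = Ct_{spike} - \log_E(\text{abundance})$ plus normal noise.

The generator does **not** simulate translation mechanistically (no
initiation/elongation kinetics, no ribosome traffic), nor sequence-level
reads, rRNA carryover, or fraction cross-contamination. Passing
recovery tests therefore demonstrates that the estimators invert the
sampling and normalization model they assume — not that real gradients
satisfy that model; on real data the covariates of the regression are in
particular correlated in ways the independent marginals here are not.

## Validation scale and reproducibility

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in well under a minute of compute: 300-gene
gradient studies (3 replicates, 5 × 10⁴ reads/library, 1000 bootstraps)
for RO/peak recovery; 25 studies of 800 genes for regression sign
recovery at a model $R^2$ of about 0.2 (residual sd set analytically from
the chosen coefficients); 50 such studies for stepwise retention of a 0.5
standardized effect; bootstrap tie calibration at 10⁵ resamples against an
exact enumeration oracle. All randomness flows from explicit integer
seeds; repeated runs are bit-for-bit identical.

```{r example}
sim <- simulate_gradient_study(n_genes = 60, depth = 2e4, seed = 42)
pp <- polysome_profile(sim$counts,
                       orf_lengths = with(sim$truth$table,
                                          setNames(orf_length, gene)),
                       n_boot = 500, seed = 42)
pp
head(merge(pp$metrics, sim$truth$table, by = "gene")[
  c("gene", "ro_mean", "ro_true", "peak_fraction", "peak_true", "rd")])
```

## Known limitations

* RD inherits the discreteness of the ribosome map: it can only take
  values $n_j/L \times 100$, and its accuracy for F/G peaks depends
  entirely on the user-supplied extrapolated ribosome numbers.
* The confinement rule (modal bootstrap frequency ≥ 0.95) is one reading
  of a 95% criterion; a percentile-interval reading would be more lenient
  for genes with two adjacent competing fractions. The modal frequency is
  reported so users can apply their own threshold.
* Size factors assume most genes are not differentially distributed
  between libraries *after* the metadata corrections; gradients where a
  large mRNA mass share moves between fractions strain the median's
  robustness (the simulator's metadata are constructed consistently, so
  this appears on real data only).
* The low-count filter operates on summed per-replicate counts; very
  uneven fraction coverage can retain genes whose profiles rest on few
  informative fractions.
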