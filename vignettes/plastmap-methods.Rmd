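---
title: "Models and methods behind plastmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plastmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastmap)
```

# The problem

A genotype scored for the same trait in several environments traces out a
*reaction norm*: its phenotype as a function of the environment. Crop
quality traits such as rice grain chalkiness respond strongly to the
growing environment (notably filling-stage temperature), and improving the
population mean of such a trait can trade off against its *phenotypic
plasticity* — the magnitude and shape of the environmental response.
`plastmap` implements the quantitative-genetics machinery needed to
dissect that trade-off on a diversity panel phenotyped in a handful of
environments: reaction-norm decomposition, variance components and
heritability, mixed-model association mapping of the derived
sub-phenotypes, condensation of the resulting QTL into hotspots,
environment-response models, and minimal marker-set selection.

# Reaction-norm decomposition

The core model is the genotype-specific Finlay–Wilkinson regression
$$y_{ij} = \mu + g_i + (1 + b_i)\,h_j + \varepsilon_{ij},
  \qquad \varepsilon_{ij} \sim N(0, \sigma^2_i),$$
where $g_i$ is the genotype main effect (the *phenotypic mean* component),
$h_j$ the environment main effect, $1 + b_i$ the reaction-norm slope
(*linear plasticity*, LP), and the natural log of the residual variance of
accession $i$ the *nonlinear plasticity* (NLP). Identifiability requires
two conventions, imposed everywhere (estimators and generator alike):
$\sum_j h_j = 0$ and $\mathrm{mean}(b_i) = 0$; the likelihood is invariant
under $(h, 1+b) \mapsto (c\,h, (1+b)/c)$, so without the second convention
the scale of $h$ against the slopes is undefined.

Two estimators are provided.

* `fit_fw_ls()` — the two-step least-squares estimator: $h_j$ is the
  environment mean minus the grand mean (re-centred), then each accession
  is regressed on $h_j$. On complete data the mean fitted slope is exactly
  1. Accessions seen in fewer than two environments (or whose available
  $h_j$ are constant) are flagged with `NA` slopes rather than dropped.
  With exactly two environments the per-accession fit is saturated and the
  residual variance is reported as 0 (NLP $= -\infty$); NLP is only
  meaningful from three environments up.
* `fit_fw_gibbs()` — a Gibbs sampler for the Bayesian version with
  independent (identity-covariance) normal priors on $g$, $b$ and $h$,
  reporting posterior means. Numerical choices that matter:
  * scaled-inverse-$\chi^2$ priors with 0.01 prior df and diffuse scale
    ($10^3 \times$ the data variance) on the $g$ and $h$ variances, unit
    scale on the slope variance;
  * the residual variance gets 5 prior df anchored at the least-squares
    residual variance. This is negligible against the residual sum of
    squares for any ordinary panel, but it pins the chain when the model
    saturates the data (zero residual degrees of freedom), where an
    uninformative prior lets $\sigma^2_e$ random-walk away from the
    interpolating mode;
  * effect variances are floored two orders of magnitude below their
    current mean square, guarding the heavy lower tail of small-df
    inverse-$\chi^2$ draws when a hierarchy level has very few units;
  * after every sweep $h$ and $g$ are re-centred (shifts absorbed into
    $\mu$ and $g$) and the scale convention $\mathrm{mean}(b) = 0$ is
    re-imposed exactly;
  * a split-chain potential-scale-reduction diagnostic on $\sigma^2_e$ and
    $\mu$ is recorded in the output (`convergence_warning`), never
    silently discarded.

Dispersion summaries use $CV = \sigma/\mu \times 100\%$ with the sample
($n-1$) standard deviation, and the quartile coefficient of dispersion
$(Q_3 - Q_1)/(Q_3 + Q_1)$ with linear-interpolation quantiles (type 7).
Both are scale-free; CV is not translation-invariant, which is asserted in
the tests rather than assumed.

# Variance components and heritability

`fit_gxe_variance_components()` fits
`value ~ (1|Line) + (1|Env) + (1|Line:Env)` by REML. The reported
components come from an EM-REML solver on the mixed-model equations
(relative tolerance $10^{-8}$, maximum 5000 sweeps, Aitken
$\Delta^2$ extrapolation every third sweep), initialized at the ANOVA
method-of-moments estimates. On balanced data with interior moment
estimates the moment estimator *is* the REML solution, and the first EM
sweep merely confirms stationarity; generic numerical optimizers cannot
certify that equality to $10^{-6}$ because the REML surface is too flat
near the optimum. Components driven to the boundary are truncated at zero.
A parallel `lme4` fit is kept for BLUPs and likelihood-ratio tests.

With a single observation per Line-by-Env cell the interaction and
residual variances are not separable; the interaction term is dropped and
the residual reported as the confounded sum, with `VGE = NA`.

Heritability follows the entire-experiment formula
$$H^2 = \frac{V_g}{V_g + V_E + V_{GE}/m + V_e/(nm)},$$
applied exactly as written, including the environment variance in the
denominator. The printed residual term is typographically ambiguous
between $V_e/(nm)$ and $(V_e/n)\,m$; the first reading is the default
because it is the only one that shrinks with more data, and the second is
available via `ve_reading = "ve_over_n_times_m"`.

The LRT for a random term refers twice the REML log-likelihood difference
to the 50:50 mixture of $\chi^2_0$ and $\chi^2_1$ — the standard boundary
correction for a variance component under the null; plain $\chi^2_1$ is
available via `mixture = FALSE`.

# Mixed-model association

`lmm_scan()` tests each SNP under
$y = X\beta + x\beta_{snp} + u + e$, $u \sim N(0, \sigma_g^2 K)$, using
the spectral decomposition of the kinship matrix $K$. The variance ratio
$\delta = \sigma^2_e/\sigma^2_g$ is profiled by REML once under the null
model and reused for every SNP (the standard single-decomposition
approximation); exact per-SNP re-profiling is available via
`method = "exact"`. Each SNP then receives a generalized-least-squares
Wald $t$-test; with $K = I$ the scan reduces *exactly* to ordinary simple
regression, which the tests assert to $10^{-8}$.

Kinship is the standardized construction (each mean-imputed SNP column
centred and scaled to unit variance, cross-product divided by the SNP
count); the allele-frequency-centred variant is available by flag.
Missing dosages are mean-imputed per SNP before kinship and testing; the
per-SNP effective sample size $N$ counts the non-missing genotypes. The
per-SNP variance explained is
$PVE = 2f(1-f)\beta^2 / \left[2f(1-f)\beta^2 + 2f(1-f) N\,se^2\right]
     = \beta^2/(\beta^2 + N\,se^2)$.

Multiple testing uses $\alpha/n_{indep}$, with $n_{indep}$ from greedy
windowed LD pruning (1000-kb windows, 10-SNP step, $r^2 > 0.3$; within a
violating pair the lower-MAF SNP is removed, position order breaking
ties). At the published panel's 36,508 independent SNPs this yields the
familiar $1.37 \times 10^{-6}$ genome-wide threshold.

The five scan categories (phenotypic mean, linear/nonlinear plasticity,
environment-specific, condition-specific, grain width) are metadata tags
on identical machinery; condition-specific scans subset accessions by a
user-supplied genotype-defined grouping.

Population differentiation uses the two-population Weir–Cockerham
estimator computed from genotype counts; it is slightly negative under no
differentiation and reported unfloored.

# QTL atlas

The peak-to-interval rule is not part of the source analysis and had to be
fixed here: significant SNPs within 200 kb of each other (configurable)
are clustered, and the interval is the cluster span padded by half the
merge window per side. Hotspot condensation then chains QTL whose closed
intervals share at least one base pair into connected components
(`mode = "pairwise"` instead requires mutual overlap of all members);
components with $\ge 2$ members become H-QTL, and those covering more
than three member QTL are flagged key. Candidate genes are collected from
closed 20-kb windows centred on each significant SNP. Coordinates are
1-based inclusive internally; BED export converts to 0-based half-open.
Effect-sign profiles flag a SNP antagonistic when its mean-scan and
plasticity-scan effects have opposite signs beyond an $\epsilon$ of
$10^{-6}$ (configurable); haplotype contrasts use one-way ANOVA with
Tukey–Kramer family-wise adjustment, with unadjusted Welch $t$-tests
alongside.

# Environment-response models

The DIFF score is the signed difference between the phenotype in a
high-temperature reference environment and each other environment, per
accession (signed, not absolute: its natural range for percent traits is
$-100$ to $100$). The PPRE model regresses each accession's phenotype on
an environmental index (any temperature column or a derived series); the
mean per-accession $R^2$ summarises the index's contribution to
plasticity. A zero-variance response has slope 0 and $R^2$ defined as 0.
Temperature–trait and temperature–CV relationships use Pearson
correlation with two-tailed p-values across environments; bootstrap
summaries resample with replacement (default 1000 draws) under a fixed
seed. The grain-width pleiotropy regression is a simple linear model whose
$R^2 \times 100$ is the reported PVE.

# Marker selection

`lasso_select()` runs cross-validated LASSO (`glmnet`) on a candidate SNP
panel: near-duplicate SNPs ($r^2 > 0.95$) are pre-filtered keeping the
higher-MAF member, folds are a seeded random permutation (ten by
default), and the penalty is chosen at the cross-validation minimum (the
sparser one-standard-error rule by flag). `stepwise_prune()` runs backward
elimination (`MASS::stepAIC`) under the $n\log(RSS/n) + 2k$ AIC
convention, so the final AIC never exceeds the initial one. Model PVE is
the in-sample $R^2 \times 100$ of the unpenalized refit on the selected
SNPs — the convention under which marker-set PVEs are usually quoted for
such panels, reported alongside rather than instead of the
cross-validation error.
`combined_model()` fits the union of mean-component and
plasticity-component marker sets against a raw phenotype or
multi-environment BLUPs; nesting guarantees the combined in-sample PVE is
at least the larger single-set PVE.

# The synthetic panel

`simulate_genotypes()` / `simulate_environments()` /
`simulate_phenotypes()` emulate the study system — a rice mini-core
diversity panel scored for percent-scale chalkiness traits across a few
field seasons — at desk scale, with a full truth record for
parameter-recovery testing.

* **Genotypes.** Biallelic SNPs with target MAF uniform on
  $[0.05, 0.5]$, laid out in LD blocks. LD is induced by a
  block-equicorrelated latent Gaussian copula thresholded to
  Hardy–Weinberg haplotypes (two latent draws per accession), chosen so a
  single parameter (`ld_rho`) controls within-block correlation.
  Population structure follows Balding–Nichols subpopulation frequencies
  at divergence $d$, which the Fst machinery recovers to within
  Monte-Carlo error. Dosages are folded to minor-allele counts.
* **Phenotypes.** Built exactly from the reaction-norm equation. The
  genotype main effect is planted-QTL signal plus a polygenic normal term;
  the slope deviation likewise; environment effects are proportional to
  the centred mean filling-stage temperature (so warm years raise the
  trait, as in the field data) and scaled to an exact sample standard
  deviation; residuals are heteroscedastic with log-normal
  genotype-specific variances — the explicit mechanism that creates
  nonlinear plasticity, which the source model leaves implicit.
* **QTL share.** `mean_qtl_pve` is the planted-QTL share of the variance
  of the component it feeds:
  $\mathrm{var}(\text{QTL part}) = p/(1-p) \times \mathrm{var}(\text{background})$,
  and likewise for the plasticity QTL.
* **Defaults.** `mu = 40`, `env_effect_sd = 5`, `polygenic_var = 45`,
  `slope_sd = 0.25`, `residual_var = 1.2` (log-SD 0.6) put the broad-sense
  heritability of the default trait at about 0.70 — inside the 0.64–0.85
  band reported for chalkiness traits — with slope-recovery correlation
  around 0.94 at 300 accessions by 6 environments. The absolute variance
  scale was chosen jointly (scaling all components together leaves both
  $H^2$ and recovery signal-to-noise unchanged) so that essentially no
  percent-scale values reach the $[0, 100]$ clip: boundary clipping
  attenuates the slopes of extreme accessions and is a property of real
  bounded traits that the linear model cannot represent. Percent traits
  are still clipped when they do stray, and the clipped fraction is
  recorded in the truth object.
* **Seeds.** One master seed; every stage draws from a named substream,
  so genotypes, environments and phenotypes are independently
  reproducible and bit-identical under a fixed configuration.

What the generator does *not* emulate: genuine multi-trait correlation
structure among the ten chalkiness traits (each call generates one trait;
callers bind tables), recombination maps or sequence-level processes,
selection and demography beyond Balding–Nichols, and measurement error
specific to visual phenotyping. Passing recovery tests on this generator
therefore demonstrates correctness of the estimators under the stated
model, not robustness to every feature of real field data.

# Problem sizes used in the checks

The packaged checks run the decomposition at 300 accessions by 6
environments; variance-component recovery on a balanced
$200 \times 5 \times 2$ design over 20 seeds; null calibration of the
mixed-model scan on 5000 SNPs at $n = 300$; power on a planted 10%-PVE SNP
at $n = 500$ over 20 seeds; LASSO recovery of 5 causal SNPs among 500
candidates at $n = 400$ over 20 seeds; and hotspot condensation against a
brute-force oracle on 1000 random intervals. These sizes make every stage
verifiable on a laptop while keeping Monte-Carlo error well inside the
asserted tolerances. In the crossed-design recovery simulations the drawn
effects are scaled to their exact target sample variance (the same
convention the generator applies to $h_j$); otherwise the five environment
effects alone contribute $\chi^2_4$-level spread that swamps estimator
error and the check would measure the random-number generator, not REML.

# Known limitations

* The Gibbs sampler runs single-chain; the split-chain diagnostic catches
  gross non-convergence but short chains on near-saturated data should be
  inspected.
* EM-REML falls back to iteration on unbalanced data, where convergence
  can be slow near boundaries; the iteration cap raises an error carrying
  the last iterate rather than returning silently.
* The exact per-SNP variance-ratio scan (`method = "exact"`) re-profiles
  the REML criterion per SNP and is an order of magnitude slower; the
  shared-ratio default is the field-standard approximation.
* `H^2` as defined includes $V_E$ in the denominator and is therefore an
  entire-experiment quantity, lower than line-mean heritability for the
  same data.
* The QTL interval rule (merge window + padding) is a modelling choice;
  hotspot counts depend on it, and it is exposed as configuration rather
  than fixed.
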