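---
title: "Quantifying host-genetic control of the rumen microbiome"
author: "rumenQG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying host-genetic control of the rumen microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Rumen bacteria ferment fibrous feed into the volatile fatty acids, microbial
protein and vitamins that a dairy ewe turns into milk. If the host genome
exerts measurable control on the abundance of individual bacterial taxa, and
if those abundances are genetically correlated with milk composition, then
selection on the host could indirectly shape the microbial community — and
shared QTL would point at the physiological mechanisms. `rumenQG`
implements the quantitative-genetic machinery needed to ask these questions
of a dairy-sheep-style dataset: pedigree, medium-density SNP genotypes, a
16S OTU count table with taxonomy, and milk traits recorded once per ewe.

Three analyses form the core:

1. **Heritability of OTU abundance**, from a multi-trait animal model with a
   permutation-based empirical significance threshold and a Fisher-exact
   test for genus enrichment among the heritable OTU.
2. **Genetic correlations** between each heritable OTU and each dairy
   trait, from 4-trait models.
3. **Single-step GBLUP GWAS** for OTU abundances and dairy traits, with SNP
   effects back-solved from genomic breeding values, per-SNP sampling
   variances and p-values, Benjamini–Hochberg FDR, QTL-region grouping, and
   allele-substitution effects for the significant SNPs.

Because the original flock data cannot be redistributed, the package ships a
full synthetic-data generator (`simulate_dataset()`) that emulates the
statistical structure these models assume, with known ("truth") parameters,
so that every stage can be exercised and validated at desk scale.

# Models

## Compositional preprocessing

Amplicon counts are compositional: the sequencing depth is arbitrary, so
only ratios carry information. The pipeline order is fixed:

1. `filter_low_abundance()` removes OTU below 0.005% of total counts;
2. `impute_zeros()` replaces zeros by the Bayesian-multiplicative method
   with a geometric prior: in sample $k$ with depth $n_k$, a zero part $j$
   becomes $t_j\,s/(n_k+s)$ and the observed parts are multiplicatively
   shrunk, preserving all their pairwise ratios. The prior expectations
   $t_j$ are the closed per-part geometric means of the observed
   proportions across samples; the prior strength defaults to
   $s=\sqrt{D}$ for $D$ parts. Both are exposed as arguments because the
   literature names the method but not a unique prior;
3. `clr()` takes centered log-ratios, $\mathrm{clr}(x)_j = \log x_j -
   \tfrac1D\sum_l \log x_l$, so each sample's row sums to zero;
4. `standardise_columns()` scales each OTU to unit variance **without
   recentering** — the animal model's fixed effects absorb the means, and
   scaling alone matches the convention of standardising abundances to
   variance 1.

`core_microbiome()` reports OTU present in at least 90% of samples, with
the threshold computed as `ceiling(0.90 * n)` (the rounding rule is stated
because it is often left implicit: 90% of 10 samples means 9).

## The multi-trait animal model

For traits $t = 1 \dots T$ measured once on the same animals,

$$ y_t = X_t b_t + W a_t + e_t, \qquad
   a \sim N(0,\, A \otimes P), \quad e \sim N(0,\, I \otimes R), $$

with $A$ the pedigree numerator relationship matrix, $P$ and $R$ the
genetic and residual covariance matrices across traits. The population
being modelled was built by divergent selection on two traits (somatic cell
score and milk-yield persistency), so those two selection criteria lead
every model: heritabilities come from 3-trait frames (selection traits +
focal trait) and genetic correlations from 4-trait frames (selection traits
+ OTU + dairy trait). Including the selection criteria is what lets REML
account for the selection-induced distortion of the descendants'
distribution; `test-mixed_model.R` probes exactly this property on
truncation-selected simulations.

Which environmental effects enter each trait's model is the analyst's
call; `screen_fixed_effects()` reproduces the conventional screening
(per-effect F-tests across all OTU, keeping effects significant for more
than 10% of them), while the shipped frames simply encode the effect
structure directly.

Heritability is $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ and the genetic
correlation is $r_g = P_{ij}/\sqrt{P_{ii}P_{jj}}$, with delta-method
standard errors from the inverse average-information matrix; an $r_g$ is
declared non-zero when $|r_g| > 2\,\mathrm{SE}$.

## REML: algorithm and numerical choices

`reml_em()` (default 100 rounds) provides a warm start whose updates are
guaranteed to keep $P, R$ positive semi-definite and the restricted
likelihood non-decreasing; `reml_ai()` then applies average-information
(Newton-type) updates to convergence, declared when the relative change of
the stacked parameter vector falls below `tol` (default $10^{-10}$, the
convention of the variance-component software this workflow mirrors).

Internally the solver exploits two exact reductions. First, the REML
likelihood depends on the relationship matrix only through its sub-block
for recorded animals, $K = A[\mathrm{ids},\mathrm{ids}]$; a single spectral
decomposition $K = U\,\mathrm{diag}(d)\,U'$ rotates the records so the
covariance becomes block diagonal with $t \times t$ blocks $d_kP + R$.
Second, a per-iteration simultaneous diagonalization of $(P, R)$ turns
every block operation into scalar weights, so one likelihood/gradient/AI
pass costs $O(nt^2)$ — which is what makes 10,000-fold permutation refits
practical. Numerical guards, chosen once:

* after every AI step, $P$ and $R$ are projected back to the PSD cone with
  an eigenvalue floor of $10^{-8}\times$ trace;
* an AI step that would lower the likelihood is retried with
  Levenberg-style damping and step halving, then replaced by an EM step;
* when the optimum lies **on** the PSD boundary (a null OTU; an $r_g$
  pinned at $\pm 1$) projected steps crawl, so the fit is polished by
  L-BFGS on the unconstrained Cholesky parametrization $P = L_PL_P'$,
  $R = L_RL_R'$ (analytic gradients by chain rule), which reaches
  rank-deficient solutions smoothly; the AI matrix is then refreshed at the
  optimum for standard errors;
* a model with genetic and residual effects fully confounded (e.g. $K = I$
  with one record per animal) yields a singular AI matrix and is returned
  flagged unconverged with an explanatory note, not an exception.

`solve_mme()` exposes Henderson's dense mixed-model equations (with the
full inverse coefficient matrix) for prediction and for cross-checks; it
and the rotated likelihood agree to machine precision, and the likelihood
itself is tested against an independent dense-matrix implementation.

## Permutation threshold and enrichment

The null hypothesis of "no host-genetic control" for an OTU is simulated by
shuffling its abundances across individuals — fixed-effect columns and the
two selection traits stay attached to their animals — and refitting the
3-trait model (`permute_and_refit()`). With the estimates sorted in
increasing order, the threshold at error rate 5% is the lower value of the
upper 5% tail: element $n - \lfloor 0.05\,n\rfloor + 1$
(`empirical_threshold()`; ties resolved by taking that sorted element).
The number of permutations is exposed; reduced test configurations use
100–200 permutations, the study-scale convention being 10,000.

`genus_enrichment()` builds, per genus, the 2×2 table of (heritable vs not)
× (this genus vs others) and computes the two-sided Fisher exact p-value
defined as the sum of probabilities of tables no more probable than the
observed one (the convention varies between software; this is the
hypergeometric-enumeration definition, cross-checked in the tests against
an independent enumeration).

## Single-step GBLUP GWAS

The single-trait model $y = Xb + Wg + e$ with $g \sim N(0, H\sigma_g^2)$
uses the joint pedigree–genomic matrix

$$ H=\begin{pmatrix}
A_{11}-A_{12}A_{22}^{-1}A_{21}+A_{12}A_{22}^{-1}GA_{22}^{-1}A_{21} &
A_{12}A_{22}^{-1}G\\ GA_{22}^{-1}A_{21} & G\end{pmatrix}, $$

where $G$ is the VanRaden genomic matrix $ZZ'/(2\sum p_iq_i)$ ($Z$ =
allele counts centered by $2p_i$), rescaled so its average diagonal and
off-diagonal match $A_{22}$ (intercept $a$, slope $b$ solved from the 2×2
moment system) and stabilised as $(1-\alpha)(a+bG_{raw})+\alpha A_{22}$
with $\alpha = 0.05$. Allele frequencies are taken from the observed
genotyped set (base-population frequencies are not identifiable here) and
can be overridden.

`fit_ssgblup()` solves the model in GLS/variance-matrix form — identical
solutions to the mixed-model equations, but also valid when $G$ is
singular, as a raw centered $G$ always is (centered columns sum to zero).
SNP effects are back-solved from the genotyped animals' breeding values,

$$ \hat a = (1-\alpha)\,b\,\frac{1}{2\sum p_iq_i} Z'G^{-1}\hat g_2, $$

with sampling variances

$$ \mathrm{Var}(\hat a_i) = \left[\frac{(1-\alpha)b}{2\sum p_iq_i}\right]^2
   z_i'G^{-1}\!\left(G\sigma_g^2 - C^{u_2u_2}\right)G^{-1}z_i, $$

where $C^{u_2u_2}$ is the prediction-error covariance of the genotyped
animals' breeding values. Negative computed variances (possible with a
blended $G$) are floored at zero and the SNP flagged untestable, as are
SNPs whose centered column is zero. P-values are
$2(1-\Phi(|\hat a_i/\mathrm{sd}(\hat a_i)|))$, adjusted per trait by
Benjamini–Hochberg with a genome-wide threshold of FDR &lt; 0.10 and a
suggestive threshold of FDR &lt; 0.30.

QTL regions: repeatedly, the most significant remaining SNP on a
chromosome leads a region; significant SNPs within the distance limit of
the lead whose $-\log_{10}p$ reaches the upper third of the peak (i.e. at
least $2/3$ of the lead's) join it. Two conventions had to be fixed here.
The distance limit is 1 Mbp — the literature's "1000 Mbp" exceeds any
ovine chromosome and is read as a typographical slip; the limit is a
plain argument (`distance_limit`) for anyone preferring the literal value.
And "upper third of the peak" is interpreted on the $-\log_{10}p$ scale
(`peak_fraction`), since the physical-plot reading is not well defined.

Per-SNP variance explained uses windows of 20 adjacent SNPs (centered,
edge-truncated): the variance across individuals of the window's genomic
score $Z_w\hat a_w$, as a percentage of phenotypic variance; region
variance uses the union of the member windows. Centered allele counts are
used (the raw-count alternative only shifts the score by a constant per
individual when no individual is missing). `allele_substitution()` fits
the classical fixed-SNP model with a polygenic background — unit variances
by default, estimated components optionally.

# The synthetic hologenome generator

`simulate_dataset()` produces a pedigree, gene-dropped genotypes, latent
traits, OTU counts and truth records as a pure function of a
`sim_config()`. Defaults emulate the study conditions the models were
designed around: five discrete generations ending in a phenotyped cohort
of 795 ewes (pedigree ≈ 4,500), 35,492 post-QC SNPs on 26 autosomes with
founder MAF uniform on [0.05, 0.5], 2,000 OTU with a realized zero-cell
fraction calibrated to 37.5%, OTU latent heritabilities drawn as
min(Exp(mean 0.04), 0.30), and five dairy traits carrying the study's
descriptive statistics (h² 0.22–0.59). Where the study does not pin a
value, a choice was made once and documented here:

* **Family structure**: 30 sires per generation, dams sampled without
  replacement where possible, random non-selfing mating — an AI-flock-like
  assumption, configurable via `n_sires` and `n_offspring_per_mating`.
* **Breeding values** are generated by the gene-flow recursion
  $a_i = \tfrac12(a_{s}+a_{d}) + m_i$ with Mendelian variance $P/2$,
  giving covariance $A\otimes P$ exactly up to parental inbreeding, which
  is ignored in $m_i$ (mean inbreeding stays below ~1% at the default
  population sizes; the REML bias this induces is far below the
  Monte-Carlo noise of any test here). This avoids factorising $A$ for
  every replicate.
* **QTL** are attached to the simulated SNP nearest the requested
  position, with $\beta = \sqrt{f\sigma_g^2/(2pq)}$ for a requested
  variance fraction $f$, and the target's polygenic variance scaled by
  $1-f$; requested genetic correlations apply to the polygenic parts.
* **Fixed effects**: year (5), parity (3), litter size (2) and a
  days-in-milk covariate on [28, 133] act on every latent variable;
  sequencing run (6) and rumen-sampling order (8) act on OTU only. Level
  values are drawn once from a normal with SD `fe_sd` (default 0.25) times
  the latent's genetic-plus-residual SD.
* **OTU counts**: per sample, composition = softmax of the latent
  log-abundances (baseline log-means N(0, 1.5²), chosen so the community's
  base zero rate sits below the 37.5% target), counts multinomial at a
  depth uniform on [5,000, 25,000]. Zero inflation comes from subtracting
  a constant — calibrated by bisection on the expected zero fraction —
  from a random half of the latent cells; the simplest mechanism that hits
  the target sparsity.
* **Divergent selection** (`selection = "truncation"`) builds the pedigree
  generation by generation so parents can be truncation-selected on the
  first trait's phenotype. This path exists to probe the multi-trait
  model's handling of selection; it supports trait latents only (no
  planted QTL), and OTU latents are then drawn conditionally on the
  realized pedigree.

What the generator deliberately does **not** emulate: linkage
disequilibrium between markers (SNPs segregate independently, so GWAS hits
are driven by the causal SNP itself and "resolution" statements are
optimistic relative to real LD blocks), amplicon/PCR bias, overdispersion
beyond the multinomial, repeated records, and maternal or
permanent-environment effects. Passing tests therefore demonstrate that
the estimators recover the parameters of the generating model at the
stated scales — not that any particular real dataset satisfies that model.

# Problem sizes used in tests and the acceptance script

Monte-Carlo checks run at sizes chosen to make their tolerances
statistically meaningful: heritability recovery uses 2,000 records × 20
trait replicates on one pedigree (the pedigree is part of the design, so
replicates redraw effects, not the population); the permutation
calibration uses 150 records, 200 permutations and 100 null OTU; GWAS
calibration pools five simulations of 500 animals × 400 SNPs (at that
ratio the back-solved statistics are nearly independent, so a binomial
interval is the right yardstick, whereas 5,000 correlated tests on 800
animals would not be); the QTL-power check runs the full 800 × 5,000
configuration for ten seeds. The acceptance script reports the same
quantities at slightly reduced replicate counts so a full run stays within
a few minutes.

# Known limitations

* All traits of a frame must be recorded on the same animals (complete
  records); records with any missing response are dropped and counted.
* The configured OTU heritabilities are *latent* heritabilities of
  log-abundance. The observed heritability of a CLR-transformed count is
  attenuated by multinomial sampling noise and zero-censoring — strongly
  so for rare OTU — which mirrors real amplicon data and is why observed
  OTU heritabilities cluster near zero even when latent ones do not.
* The permutation stage inherits the estimation noise of small-sample
  REML: at a few hundred records the null heritability spread — and hence
  the empirical threshold — is much wider than at study scale, which is
  why thresholds from reduced runs exceed the ~0.10 seen with ~800 ewes.
* The QTL-localisation power at a QTL explaining 10% of genetic variance
  with h² = 0.25 and 800 genotyped animals is only ≈ 0.5–0.6 per
  simulation at FDR 0.10 (the back-solved z of the causal SNP is ≈
  √(n·R²) ≈ 4.5 against a BH threshold ≈ 4.3), so single-simulation
  localisation is a coin toss, and the corresponding end-to-end check is
  expected to fail at that configuration; larger QTL or more animals
  localise reliably.
* Dominance, maternal effects, metafounders and APY-type sparse inverses
  are out of scope; matrices are dense, which is exact and fast to a few
  thousand animals.
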