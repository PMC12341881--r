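---
title: "Models and methods in hairqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hairqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hairqtl` implements a complete analysis chain for the genetics of stress
hormones measured in pig hair — cortisol, cortisone, DHEA, and DHEA-S —
together with piglet backtest coping behaviour, in multi-batch cohorts of
Yorkshire x Landrace F1 barrows sourced from several breeding companies.
Because data of this kind are typically confidential, the package ships a
synthetic cohort generator with the same statistical structure, so every
stage is testable end to end. This vignette records the models, the
tunable parameters and their defaults, the numerical choices, and the
design decisions taken where the methodology left room.

## The phenotypes and their preprocessing

Hair steroid assays report a reading $S$ (pg/ml) on a reconstituted
extract. `concentration()` back-calculates the hair concentration as

$$C = S \cdot Rv \cdot df / Em \quad \text{(pg/mg)},$$

with reconstitution volume $Rv$ (0.4 ml in the reference protocol),
extraction mass $Em$ (25 mg of powdered hair), and dilution factor $df$.
Protocol write-ups are often typographically ambiguous about where $df$
sits; we place it in the numerator because a sample diluted before the
assay must be scaled back up, which is the only reading consistent with
assay practice. A switch (`df_in_numerator = FALSE`) provides the divisor
reading for comparison.

Replicate handling follows assay practice: duplicates are averaged;
for hormones whose assay is erratic (cortisone, in our motivating
setting) triplicates are run and `replicate_summary(policy = "best2of3")`
averages the two replicates with the lowest within-sample CV, found by
exhaustively enumerating the three pairs. Samples whose CV exceeds a
configurable threshold (default 15%; the acceptable range is
assay-specific and not a claim about any particular laboratory) are
flagged but retained.

Outliers are screened on the upper tail only, with a modified IQR rule:
values strictly above $Q3 + k \cdot IQR$ are removed, $k = 4.5$ by
default — deliberately permissive relative to the textbook 1.5, so only
extreme assay artefacts are lost. Quartiles use linear interpolation
(type 7), stated so boundaries are reproducible. `derive_traits()` then
builds the composites SOG (cortisol + cortisone) and SOD (DHEA + DHEA-S),
the eight-ratio panel, and natural-log transforms; ratios are computed
only where both components survived QC, and log ratios are antisymmetric
in the pair order, so the numerator choice is labelling only.

Two distributional checks support the modelling choices downstream:
`ks_normality()` (KS distance to a normal with estimated moments;
Lilliefors-style p by parametric bootstrap, because the classical KS
p-value is invalid with estimated parameters) motivates analysing levels
on the log scale, and `overdispersion_test()` (Cameron-Trivedi auxiliary
regression) documents that vocalization and struggle counts are strongly
over-dispersed relative to Poisson. Count traits are nevertheless
analysed as `log(1 + count)` in all mixed-model work, the same fallback
the motivating analyses use for bivariate runs; univariate count
heritabilities are therefore on the transformed scale, and dedicated
negative-binomial or cumulative-link mixed models are out of scope.

## Genomic relationships

`vanraden_g()` builds the method-1 genomic relationship matrix
$G = ZZ'/(2\sum_j p_j(1-p_j))$ with $Z$ the dosage matrix centred at
$2p_j$; monomorphic SNPs are dropped and missing dosages mean-imputed to
$2p_j$. Because batches belong to single companies and company gene pools
differ, `company_grm()` builds one G per company from within-company
allele frequencies and `block_combine()` assembles them block-diagonally
with between-company relationships set exactly to zero, so REML pools
within-company genetic variance. A ridge of $10^{-6}$ on the diagonal
guarantees invertibility; it is numerics, not statistics. Whether
observed or fixed (0.5) frequencies were used in the reference analyses
is not recorded; observed within-company frequencies are the default and
an argument overrides them.

## Variance components

`fit_univariate_reml()` fits the genomic animal model

$$y = \text{batch} + \beta_a \cdot \text{age} + \beta_s \cdot
\text{storage} + u + \text{litter} + \text{pen} + e, \qquad
u \sim N(0, G\sigma^2_A),$$

by restricted maximum likelihood with average-information (AI) updates:
step-halving on the AI direction, an EM-scaled fallback when the AI
matrix is not usable, and nonnegativity by boundary projection.
Convergence requires a log-likelihood change below $10^{-6}$ and a
relative gradient norm below $10^{-4}$; fits that stop short warn rather
than fail silently. Standard errors come from the inverse AI matrix, and
ratio SEs (heritability, litter fraction) by the delta method — the
reference analyses do not state how their ratio SEs were obtained, so
the delta method is our choice.

Heritability is reported against the genetic + litter + residual
variance; pen and assay-date variances are estimated but excluded from
that denominator, reproducing the three-term phenotypic-variance
definition used for these traits. A random term that pins to the zero
boundary and fails a likelihood-ratio test at 0.05 can be dropped; the
0.05 is our operationalisation of "retained only if it explains a
substantial amount of variation".

The bivariate fit stacks two traits with unstructured 2x2 covariance
matrices per term, uses pairwise-complete records, and warm-starts from
the univariate fits with covariances initialised from the observed
phenotypic correlation. Genetic correlations are constrained to
$[-1, 1]$ by projection. For likelihood-ratio tests of $r_g = 0$ the
covariance parameter is simply masked in the AI engine; for $r_g = \pm
1$ the genetic block is rank-1, which makes $\partial V/\partial\theta$
parameter-dependent, so those fits maximise the same restricted
likelihood through a bounded quasi-Newton parameterisation
(log-variances, tanh-correlations). The LRT refers
$2(\ell_\text{free} - \ell_\text{constrained})$, clipped at zero, to
$\chi^2_1$; at the $|r|=1$ boundary this is known to be conservative and
is used anyway, matching the motivating analysis. One numerical guard
deserves mention: when a covariance parameter sits on the PSD boundary,
its projected gradient cannot be driven to zero, so three consecutive
accepted steps with negligible likelihood change also terminate the fit
as converged.

## Bayesian variable-selection GWAS

`run_bayesb()` fits the whole-genome regression
$y = Xb + Z_\text{litter} + Z_\text{pen} + \sum_n m_n \beta_n \delta_n +
e$ by single-site Gibbs sampling. For each SNP the inclusion indicator
$\delta_n$ is sampled from its full conditional with $\beta_n$
integrated out analytically (this joint update avoids the mixing
pathology of naive two-block samplers), then $\beta_n \mid \delta_n = 1$
from its normal full conditional. Locus variances follow a scaled
inverse chi-square prior with $\nu_\beta = 4$ and a scale derived from a
prior genetic-variance guess — half the phenotypic variance unless
supplied — spread over the $(1-\pi)p$ SNPs expected in the model.
BayesC uses a single common effect variance; BayesCpi additionally
samples $\pi$ from $\text{Beta}(\#\text{excluded}+1,
\#\text{included}+1)$. Fixed effects have flat priors; iid random-term
and residual variances have scaled-inverse-chi-square priors with
$\nu = 4$ and data-derived scales. A divergence guard aborts if the
residual variance exceeds $10^6$ times the phenotypic variance.

The analysis protocol fixes $\pi = 0.999$ with an 80,000-iteration chain
and 5,000 burn-in (`bayesb_config("study")`). The desk profile (8,000 /
1,000) is for cohorts of a few hundred pigs and a few thousand SNPs —
the problem sizes at which the package's simulation studies run: n = 804
(12 batches of 67), p = 2,000 for recovery work, with smaller cohorts
for calibration suites. Convergence in the reference workflow was
assessed visually; we add warn-only Geweke and effective-sample-size
diagnostics.

Windows tile each chromosome in 0-based half-open bp intervals (the
convention is ours; none is stated in the source methodology). For every
retained iteration the window genomic value per pig is
$g_{w,i} = \sum_{n \in w} m_{in}\beta_n\delta_n$; the window's share of
genetic variance in that iteration is
$\mathrm{var}_i(g_w)/\mathrm{var}_i(g_\text{total})$ across pigs, and
%EGV is the posterior mean of that percentage, with iterations of zero
total genomic variance contributing zero. Window shares need not sum to
100 because window genomic values covary; tests therefore assert
equality with a brute-force oracle, not normalisation. A 1-Mb window
above 1% EGV is called a QTL.

One desk-scale caveat, documented because it is easy to trip over: with
$\pi = 0.999$ and only 2,000 SNPs, roughly two SNPs are in the model per
iteration, so on *pure-noise* data whichever window holds a lone included
noise SNP owns essentially all of that iteration's (tiny) genetic
variance, and some window will usually exceed 1% EGV even though nothing
is real. The sound null guarantees at this sparsity are different ones —
posterior inclusion probabilities stay small and the genome-wide genetic
variance collapses toward zero — and those are what the null tests
assert. At genome scale (hundreds of thousands of SNPs, hundreds in the
model per iteration) the per-window dilution makes the 1% call behave as
intended.

## The bivariate scan and the Ad statistic

`run_bivariate_bayesb()` extends the sampler to trait pairs: each SNP is
in one of four states $[\delta_{n1}, \delta_{n2}]$ with prior
probabilities $\pi^2$, $\pi(1-\pi)$, $(1-\pi)\pi$, $(1-\pi)^2$; the
state is sampled with the effect vector marginalised under the locus
covariance $G_n$, which carries an inverse Wishart prior with
$\nu_\beta + 1$ degrees of freedom refreshed from
$S_\beta + \beta_n\beta_n'$ (we read the stated "mean" of that prior as
the conventional scale parameter of the conjugate update). Pen, litter,
and residual 2x2 covariances are inverse Wishart.

Pleiotropy is summarised on 0.25-Mb windows — four times finer than the
QTL windows, because within a wide window the products of effect signs
can cancel and mask covariance. For each retained iteration the
covariance across pigs between the two traits' window genomic values is
computed; `PP_pos` and `PP_neg` are the strict-sign frequencies, with
exact zeros (no SNP of the window in either model) counting toward
neither — the only definition under which `PP_pos + PP_neg <= 1` with a
meaningful gap, and the package's central interpretive choice for this
module, since the covariance estimator is not spelled out in the source
methodology. The pleiotropy score is $Ad = |PP_\text{pos} -
PP_\text{neg}|$, which unlike `PP_pos + PP_neg` is not inflated in
SNP-dense windows; windows with $Ad > 0.02$ (a deliberately liberal,
admittedly arbitrary threshold) are flagged. Ad is exactly symmetric in
trait order as a statistic; two MCMC runs with the roles swapped agree
to Monte Carlo error.

## Fine mapping

`fit_snp_covariate()` adds a lead SNP's dosage to the fixed effects of
the animal model and reports the substitution effect with a Wald test;
for log-scale traits it converts the effect to an original-scale percent
change, $100(e^{\hat\beta}-1)$, with "reduced by X%" corresponding to
$-X$, and to implied genotype means (the heterozygote prediction at
dosage 1, minor homozygote that times $e^{\hat\beta}$).
`breed_origin_effects()` splits the dosage into copies carried on
Landrace- versus Yorkshire-origin haplotypes and tests their difference.
`variance_removed()` reruns the GWAS with the SNP as a fixed covariate
and the SNP excluded from the random set, reporting the drop in genetic
variance, chain-based heritability, and the focal window's %EGV.
`snp_company_interaction()` Wald-tests dosage-by-company terms over the
companies where the SNP segregates. `parental_freq_from_f1()` is the
exact linear map from an F1 haplotype frequency to the parental-line
frequency (each breed contributes half of all F1 haplotypes).

LD is the squared Pearson correlation of dosages (composite r²), which
needs no phase; with known phase (synthetic data)
`ld_r2_haplotype()` computes the haplotype version for comparison. Note
that pooled-haplotype r² picks up admixture LD from between-breed
frequency differences that composite r² on F1 genotypes cancels — the
two genuinely measure different things in a crossbred cohort.

A practical recommendation for small panels: when the marker panel is
desk-sized (a few thousand SNPs) and one QTL carries a large share of
the genetic variance, a GRM built *with* the focal SNP partially absorbs
its own fixed-covariate estimate (about 30% shrinkage in our
simulations); building the GRM without the focal SNP removes this. At
genome scale (hundreds of thousands of markers) the distinction is
negligible, which is why conventional workflows ignore it.

`expression_covariate_fit()` reuses the same machinery for expression
phenotypes with log2 white-blood-cell-composition covariates; zero
proportions are offset by half the minimum positive value before log2.

## Window-set enrichment

`build_window_library()` assigns annotation terms to 0.25-Mb windows
through the genes each window contains (set semantics: a window counts
once per term regardless of how many member genes it holds), keeping
terms with 11 to 8,999 windows. `rank_windows()` orders windows by %EGV
after excluding windows already significant in the GWAS (the enrichment
asks about the sub-significant tail), or by Ad with no exclusion; ties
break by chromosome and start for determinism. `combine_rankings()`
aggregates per-trait rankings by best (minimum) rank — the cited
combination procedure is not restated in the source methodology, so
best-rank was chosen and isolated behind one function so mean-rank or
interleaving can be swapped in.

`gsea_preranked()` is the classic weighted Kolmogorov-Smirnov running
sum: hits increment by normalised $|score|^p$ (degenerating to the
unweighted statistic when all scores are zero), misses decrement
uniformly, and ES is the signed maximum deviation. Because preranked
input admits no phenotype permutation, the null is term-size-matched
random window sets, seeded. NES normalises by the mean same-sign null
ES; q-values follow the standard positive/negative NES-pool procedure
(Benjamini-Hochberg over nominal p is available via `fdr_method`,
since which of the two the reference analyses used is not stated), with
significance flagged at FDR <= 0.25. An independent implementation
(`fgsea::calcGseaStat`) is used as a cross-check of the enrichment score
in the test suite, never as the implementation.

## The synthetic cohort generator

The generator emulates the study conditions the analyses assume: 15
batches of 60 or 75 F1 barrows (configurable; recovery studies use 12
batches of 67, n = 804) from 7 companies, litters of 2-4 pigs, at least
9 sires per batch, ages near 40 days, and storage times entering as a
fixed covariate. Genotypes come from per-breed founder haplotype pools
(40 per breed) built from a limited set of block haplotypes (blocks of
20 SNPs, 6 block haplotypes), which yields realistic local LD and
breed-origin phase without a recombination map — the analyses need LD
and origin labels, not recombination realism. Sires carry Yorkshire
haplotypes, dams Landrace; each pig inherits one haplotype from each by
Mendelian sampling, so half-sibs and littermates share haplotypes, and
the expected F1 carrier frequency of a planted allele is the mean of the
two pool frequencies (defaults 12.0% Landrace, 8.2% Yorkshire).

Phenotypes follow the animal model exactly: on the natural-log scale, a
planted QTL (default effect -0.35 per minor-allele copy, targeting
45.3% of genetic variance), a polygenic term over a random 10% of
non-QTL SNPs, batch effects (SD 0.2), small age (0.005/day) and storage
(-0.002/day) slopes, litter and pen effects, and residuals. The genetic
vector is rescaled so the realized sample genetic variance equals
`h2 * total_var` (defaults 0.33 x 0.12, the log-scale phenotypic
variance of hair cortisol) and the QTL's realized share equals its
target exactly — this makes per-replicate truths exact and recovery
tests sharp, at the price that the realized per-allele effect is the
nominal effect times a recorded scale factor near one. Litter (0.16)
and pen (0.05) fractions are drawn, not rescaled. The two hormone
traits share polygenic effects with correlation `rg` (default 0.6) and
common-environment (litter, pen) effects with correlation `env_rg`
(default 0.5 — related but not identical, which also keeps the
bivariate covariance matrices off the degenerate rank-1 boundary).
When trait 2 carries no QTL, its genetic vector is built by in-sample
orthogonalisation so that the *realized* genetic correlation equals `rg`
exactly — the same exact-realization philosophy as the variance
rescaling. This matters: with a sparse polygenic basis (10% of 2,000
SNPs) the realized correlation of independently drawn effect vectors
fluctuates by about +/-0.1 per replicate, so "true r_g = 0.6" would
otherwise be only an expectation, and recovery tests would confound
estimator error with generator fluctuation. The
count trait is negative binomial with a log link on the residual-free
linear predictor (marginal mean 5, variance/mean 6.3); the ordinal trait
thresholds a latent Gaussian at four ascending cut points. Assay
records invert the concentration formula with log-normal replicate
noise (CV 5%) and optional outlier injection.

What the generator does *not* emulate: genotyping and imputation error,
sequence-level mutation or recombination, selection or drift within
companies, assay plate and standard-curve structure, seasonal or
maternal dynamics, and missingness mechanisms. Passing recovery tests
therefore demonstrates that the estimators recover the generating model
when its assumptions hold at these problem sizes — not that real hair
steroid data meet those assumptions.

All randomness flows from one seed (default 20250514); pipeline stages
derive sub-seeds by a fixed splitting rule, and chains are
bit-reproducible single-threaded.

## Problem sizes used by the shipped studies

Simulation suites run at: n = 804 / p = 2,000 / 30 replicates for REML
recovery, 20 desk-profile chains for QTL recovery, n = 804 / p = 1,000
for the pleiotropy suite, n = 144 / 200 replicates for LRT null
calibration, and 200 replicates for the overdispersion and GSEA
calibration checks. These sizes are the package's chosen
simulation-study design: large enough for the Monte Carlo error of each
check to sit well inside its assertion band.

One calibration suite deserves a note on its null. The r_g = 0 LRT is
calibrated against phenotypes drawn from the fitted model class itself
(independent genetic values from N(0, G sigma2_A) per trait), not from
the SNP-effect generator: a finite sparse polygenic basis makes the
realized genetic correlation a random quantity per replicate, so
neither "independently drawn effects" (realized correlation +/-0.1,
anti-conservative) nor "exactly orthogonalised effects" (more null than
the model's null, conservative) reproduces the null the chi-squared
reference assumes. Drawing from the model class is the canonical
construction for checking an LRT's calibration.

## Known limitations

- Count and ordinal traits are analysed on transformed scales; no
  GLMM path is provided.
- The AI-REML engine handles two traits, not more.
- The bivariate sampler requires both traits observed on the same pigs
  (REML accepts pairwise-complete records).
- The r_g boundary LRT is conservative by construction.
- The 0.02 Ad threshold has no formal FDR calibration, by design.
- GO-graph propagation and leading-edge reporting are out of scope for
  the enrichment module.
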