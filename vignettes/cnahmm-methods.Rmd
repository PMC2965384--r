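---
title: "Methods: a Bayesian HMM for tumor copy number, LOH, purity and ploidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Bayesian HMM for tumor copy number, LOH, purity and ploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnahmm)
```

## The problem

SNP genotyping arrays summarize each probe by two numbers: the Log R Ratio
(LRR), a log-scale measure of total DNA dosage, and the B allele frequency
(BAF), the fraction of signal attributable to the B allele. In tumor
samples three confounders distort both tracks simultaneously:

1. **Normal DNA contamination** ($\pi_0$): admixed stromal cells pull every
   aberrant LRR toward 0 and split heterozygous BAF clusters into
   characteristic bands (a hemizygous deletion under contamination shows
   four bands from the mixed genotypes AA/A, AB/A, AB/B, BB/B).
2. **Intra-tumor heterogeneity** ($\pi_i$): at a given locus, some fraction
   of tumor cells may retain the constitutional genotype, attenuating the
   aberration locally rather than genome-wide.
3. **Ploidy / baseline error** ($\beta_0$): because arrays hybridize a
   fixed DNA mass and normalization maps intensities to a "virtual diploid"
   scale, the LRR zero line of a polyploid genome does not correspond to
   copy number 2, and an unknown global LRR shift must be inferred.

`cnahmm` models all three jointly in a single hidden Markov model, plus
GC-content wave correction and a heavy-tailed noise model, and ships a
generative simulator that mirrors the model so every estimator can be
exercised against known truth.

## Model

### State space

Each probe carries a hidden *tumor state* $x_i \in \{1, \dots, 21\}$; a
state is a tumor copy number (0–6) plus the set of allowable
(tumor, normal) genotype pairs (`build_state_table()`). States 1–11 are
copy-number alterations, 12–16 somatic LOH at rising copy number, 17–21
LOH in which the heterozygous constitutional genotype is absent
(germline-like runs of homozygosity). Tabulations of this state space in
circulation carry three typographical inconsistencies, normalized here
and unit-tested:

* the "Normal" state (3) is given the diploid pair set
  {(AA,AA),(AB,AB),(BB,BB)} consistent with its copy-number column,
* two 6n rows with truncated 5-allele strings are completed to 6 alleles
  (which also restores closure of every pair set under the A↔B swap),
* the "3n–6n germline LOH" rows take their copy number from the genotype
  string length (3–6) rather than the printed "2", following their
  descriptions.

### Emission model

Writing $\omega_i = \pi_i(1-\pi_0) + \pi_0$ for the total fraction of
cells carrying the constitutional genotype, the expected signals of a
genotype pair are

$$m_r = \omega_i\,\bar r_{x_n} + (1-\omega_i)\,\bar r_{x_t} + \beta_0 +
\beta_1 g_i, \qquad
m_b = \frac{\omega_i z_n + (1-\omega_i) z_t}
           {\omega_i x_n + (1-\omega_i) x_t},$$

where $\bar r_c$ are canonical LRR levels per copy number, $g_i$ is local
GC content, and $(z, x)$ are B-allele counts and total copies. The
observation $y_i = (r_i, b_i)$ follows, with probability $1-\eta$, a
$K$-component bivariate Student-$t$ mixture centered at
$m + \delta_k^{(l)}$ with scale $\Sigma_k^{(l)}$ and $\nu$ degrees of
freedom, marginalized over the state's genotype pairs; with probability
$\eta$ an outlier class uniform in LRR over $(r_{\min}, r_{\max})$ and in
BAF over $(0,1)$. The noise class $l \in \{1,2,3\}$ of a genotype pair is
the *position of its expected BAF band*: exactly at the lower boundary
(all-A mixed genotype, $m_b = 0$), interior, or exactly at the upper
boundary ($m_b = 1$). For an uncontaminated diploid genotype this is
exactly the constitutional class AA/AB/BB, the natural reading of the
three-valued index; but tying the class to the band rather than the
germline genotype matters once BAF clipping enters. Arrays saturate BAF at
0/1, so a band sitting exactly on a boundary carries spike-plus-half-width
noise while interior bands carry full-width noise — a property of where
the band sits, not of the germline genotype. If the class followed the
constitutional genotype, an AB-origin deletion probe in a pure tumor
(band at 0, clipped) would be forced to share the wide interior-band
scale, and a whole-genome-doubled reinterpretation — which re-sorts those
probes into homozygous-pair LOH states with boundary-class scales — would
fit the clipping artifact genuinely better, flipping baseline selection
toward spurious ploidy doubling on clean diploid data. The
exactly-at-boundary / interior dichotomy removes that freedom: every
interpretation assigns clipped bands to a boundary class and un-clipped
bands to the interior class, so ploidy selection is decided by the LRR
level structure, as it should be. (A graded cutoff such as $m_b < 0.25$
was tried and rejected: it relocates the same exploit to whichever bands
straddle the cutoff.) Pair
weights are Hardy–Weinberg at the population B-allele frequency,
renormalized within the state, or an indicator when a matched-normal
genotype is supplied. When the mixture-weighted total copy number is zero
(pure homozygous deletion) the BAF is undefined and its factor is replaced
by a uniform density.

### Chain

Tumor states and heterogeneity levels form one expanded chain over
$21 \times P$ states ($P$ = heterogeneity grid size). The switch
probability between adjacent probes is distance-dependent,
$\rho = \tfrac12\big(1 - e^{-d/2L}\big)$ with $L = 2\,\mathrm{Mb}$, and the
printed kernel ("$1-\rho$ same, $\rho$ different") is made stochastic by
splitting $\rho$ uniformly over the other states. Chromosomes restart the
chain from an initial distribution that favors the normal state 10:1 and
weights heterogeneity levels by their prior. Because the switch mass is
uniform the chain's stationary distribution is uniform; the normal-state
preference acts only at chromosome starts.

## Priors and defaults

| parameter | prior | default | why |
|---|---|---|---|
| mixture weights $w^{(l)}$ | Dirichlet($\alpha$) | $\alpha=1$ | flat (the method's standard setting) |
| offsets $\delta_k^{(l)}$ | $N(0, \tau \Sigma_k^{(l)})$ | $\tau=0.05$ | offsets stay near canonical means |
| scales $\Sigma_k^{(l)}$ | IW($\gamma$, $S$) | $\gamma=5$, $S=0.01 I$ | weakly informative |
| outlier rate $\eta$ | Beta($\alpha_\eta,\beta_\eta$) | $(1,1)$ | uniform (the method's standard setting) |
| $(\beta_0,\beta_1)$ | $N(0, \lambda_\beta I_2)$ | $\lambda_\beta=1$ | weak ridge |
| $\pi_0$ | two-level discrete | $\alpha_{\pi_0}=\beta_{\pi_0}=1$ | the method's standard masses |
| $\pi_i$ | two-level discrete | $\alpha_\pi=1, \beta_\pi=2$ | the method's standard masses |

The discrete supports are a declared package convention (the method
prescribes the masses but no supports): $\pi_0 \in \{0, 0.05, \dots, 0.90\}$ and
$\pi_i \in \{0, 0.2, 0.4, 0.6\}$, each with the first mass on 0 and the
second split evenly over the positive points. $\nu$ is fixed (default 8,
configurable), $K$ defaults to 3 with scale matrices initialized at
$c_k \cdot \mathrm{diag}(0.15^2, 0.04^2)$, $c_k$ log-spaced in
$[0.5, 2]$ — the spread breaks the permutation symmetry of a
zero-offset initialization and lets components specialize into
core/shoulder/tail noise. Canonical LRR levels default to
$\bar r = (-3.5, -0.66, 0, 0.40, 0.68, 0.85, 1.0)$ for copy numbers 0–6, a
compressive array response; they are user-overridable and residual location
error is absorbed by the $\delta$ offsets. The outlier support defaults to
a generous fixed LRR range covering any plausible array output.

## Inference

MAP-EM with the standard latent-scale construction for the Student-$t$.
The E-step runs exact scaled forward–backward over the expanded chain. All
M-step updates are exact conditional maximizations derived from the
conjugate priors, computed from closed-form sufficient statistics
(latent-scale-weighted raw moments per state–pair–component cell), so one
moment pass per iteration supports every update:

* $w$: Dirichlet-smoothed responsibilities;
* $(\delta, \Sigma)$: Normal-Inverse-Wishart posterior modes;
* $\eta$: Beta posterior mode;
* $(\beta_0, \beta_1)$: penalized weighted least squares using the full
  bivariate precision (the BAF residual enters through the
  cross-precision);
* $\pi_0$: grid maximization of the expected complete-data log posterior,
  restricted to the neighborhood of the current grid point.

Two design choices keep the optimization out of well-known traps:

* **Purity/heterogeneity confounding.** A genome-wide contamination of,
  say, 0.25 can be imitated at $\pi_0 = 0$ by giving every aberrant
  segment $\pi_i = 0.2$ ($\omega = 0.24$), and coordinate ascent cannot
  make the joint move back. Before the first iteration the marginal
  likelihood (which integrates over $\pi_i$) is therefore scanned over the
  full $\pi_0$ grid, where the exact-match candidate wins decisively;
  mid-run scans over a local window act as refinements. Scans always
  include the current point, so the penalized log-likelihood remains
  non-decreasing.
* **Purity/ploidy multimodality.** The likelihood over
  $(\pi_0, \beta_0)$ is genuinely multimodal (a contaminated diploid, a
  shifted triploid and a more contaminated tetraploid can explain the same
  data). This is explored by baseline
  restarts: `fit_with_restarts()` runs EM from each $\beta_0$ in a grid
  covering diploid through tetraploid interpretations
  ($\{0, -0.40, -0.68, +0.33\}$), keeps $\beta_0$ frozen for the first 5
  iterations so each restart settles within its own interpretation, and
  returns the fit with the greatest final penalized log-likelihood.
  `likelihood_surface()` exposes the full map for inspection.

$\beta_1$ is initialized by a genome-wide OLS regression of LRR on GC —
the wave is independent of segment structure, so the slope is clean, and
without it the mean GC effect masquerades as a copy shift during early
iterations. EM stops after 15 iterations (the method's standard setting) or at a
relative penalized log-likelihood change below $10^{-6}$.

**Model variants.** `germline` fixes $\pi_0 = 0, \beta_0 = 0`;
`ploidy_only` fixes $\pi_0 = 0$; `normal_only` fixes $\beta_0 = 0$; `full`
frees both. Beyond the stated constraints, the two no-contamination
variants also pin the heterogeneity grid to $\{0\}$: locus-level retention
of the normal genotype is the same confounder as contamination, and
leaving it free would let a "no normal DNA" variant absorb genome-wide
admixture through $\pi_i$, defeating the comparison the variants exist to
make. All variants are nested in the full model.

## Scoring

The Viterbi path over the expanded chain is run-length encoded into
segments (chromosome boundaries always split). Each segment's score is an
approximate log Bayes factor versus the normal state: the sum of per-probe
posterior log odds minus the chain's per-probe prior log odds, which is 0
under the uniform-switch kernel. The approximation is a declared package
choice, isolated in
`segment_log_bayes_factor()`. Calls are filtered at log BF ≥ 30
(natural log, the method's standard threshold; base configurable). The chromosome
number estimate is the sum over chromosomes of the probe-weighted mean
tumor copy number, rounded per chromosome; "average ploidy" is the
probe-weighted mean copy number.

## The simulator

`simulate_sample()` inverts the emission model: exponential-length state
segments, Hardy–Weinberg constitutional genotypes (restricted to
homozygous in germline-LOH segments, which define runs of homozygosity),
tumor genotypes drawn uniformly among a state's pairs compatible with the
constitutional genotype, per-segment subclonality from the model's
heterogeneity grid, Student-$t$ noise, a sinusoidal GC wave entering as
$\beta_1 g_i$ exactly as the model assumes, uniform outliers, and a
baseline shift for polyploid presets. `dilution_series()` draws one tumor
truth and re-renders observations at several normal fractions, mirroring
the laboratory mixture design (0:100 / 25:75 / 50:50 by mass); a
mass-to-cell-fraction conversion is provided because mixing by DNA mass
and by cell count differ at non-diploid ploidy, and the simulator defaults
to the cell-fraction convention the model parameterizes. Defaults state
the emulated world once: 20,000 probes over 20 equal chromosomes, 10 Mb
mean segments, LRR/BAF noise scales 0.15/0.03 with $\nu = 8$ (typical
array noise), 1% outliers, a 0.05-LRR GC wave, subclonality off (cell-line
mixtures are clonal; it is exercised by dedicated tests).

What a green test does **not** establish: the simulator draws from the
fitted model's own family, so recovery results certify the inference
machinery, not robustness to real-array pathologies (probe-specific bias,
BAF asymmetry from allele-specific hybridization, genomic waves beyond a
GC sinusoid, germline CNVs in the matched normal). BAF saturation is
emulated by clipping to [0,1]; the fitted model handles the resulting
boundary spikes through the mixture's scale components rather than point
masses — a documented approximation.

`make_confusable_sample()` constructs genomes whose purity/ploidy
interpretation is provably ambiguous (a genome-wide single-copy gain at
30% contamination with the baseline a virtual-diploid normalization would
produce): a diploid-with-LOH reading at higher contamination explains the
same band structure, and the likelihood surface shows distinct local
maxima.

## Numerical choices

* Emission mixtures are accumulated in linear space: normalized
  Student-$t$ kernels are $\le 1$, cannot overflow, and underflow only at
  astronomically large Mahalanobis distances, so the per-probe log-sum-exp
  is replaced by one `log` per probe/state. For (half-)integer exponents
  (any integer $\nu$) the kernel is evaluated with binary-exponentiation
  multiplies and at most one square root; this is exact to double
  precision (verified against the log-space reference at $10^{-10}$).
* Forward–backward uses per-probe scaling; chains of $10^6$ probes do not
  underflow. The rank-1 structure of the uniform-switch kernel makes each
  recursion $O(nS)$.
* Viterbi ties break toward the lower state index (and lower
  heterogeneity level, via column order), deterministically.
* Moment accumulation skips probe/state blocks with posterior mass below
  $10^{-12}$ (configurable); the monotonicity slack in tests is $10^{-6}$.
* Mixture weights are floored at $10^{-8}$ before normalization; $\eta$ is
  clamped to $[10^{-8}, 0.9]$.
* Degenerate zero-copy cells contribute their LRR information through a
  univariate Student-$t$; they are excluded from moment accumulation (the
  BAF residual is undefined there), a negligible approximation affecting
  only homozygous deletions in perfectly pure tumors.

## Known limitations

* Sex chromosomes are treated as ordinary diploid-normal chromosomes; no
  haploid-X state table for males.
* $\pi_i$ follows the same switch kernel as the tumor state inside the
  expanded chain; its printed prior informs only chromosome starts. The
  per-SNP i.i.d. reading of that prior is a documented alternative.
* The log Bayes factor is a posterior-odds approximation, not a marginal
  likelihood ratio.
* No raw-intensity normalization, no NGS read-count emissions, no
  multi-sample recurrence analysis.
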