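---
title: "Methods: noninvasive genetic capture-recapture with ngcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noninvasive genetic capture-recapture with ngcmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngcmr)
```

# The problem

Small, elusive carnivore populations are most practically surveyed
without handling animals: barbed-wire hair snares and scat collection
yield DNA samples whose microsatellite genotypes identify individuals.
Three statistical problems stand between the raw samples and a
population assessment:

1. **Genotyping error.** Low-template DNA suffers allelic dropout (one
   allele of a heterozygote fails to amplify), false alleles, and
   outright amplification failure, so a single PCR cannot be trusted.
2. **Individual identification.** With few, related animals, two
   siblings can share a multilocus genotype unless the locus panel is
   powerful enough; and dropout makes truly identical samples look
   different.
3. **Abundance and genetic health.** Capture histories built from
   identified individuals feed closed-population, robust-design, and
   continuous-occasion estimators; the genotypes themselves yield
   diversity, differentiation, and effective-population-size measures.

`ngcmr` implements this chain end to end, together with a
synthetic-data generator that produces all inputs with a complete truth
table, so every stage can be validated against known truth.

# Consensus genotyping

Each sample is amplified in replicate.  Per locus:

* a heterozygous allele pair seen in **two** replicates is confirmed
  (homozygous replicates showing one of its alleles are attributed to
  dropout);
* a homozygote needs **two** concordant replicates for hair and tissue
  and **three** for scat (scat DNA drops out more);
* any other disagreement is a *conflict*; conflicted or unconfirmed
  loci trigger re-amplification, up to 4 total replicates for
  hair/tissue and 6 for scat.  Loci still unresolved are recorded as
  missing -- a documented choice, since field protocols do not state a
  terminal rule.

`call_consensus()` consumes replicates progressively (two first, then
one at a time) to emulate that workflow, and never outputs an allele
absent from every replicate.

# The PIDsib locus panel

The probability that two full siblings share a single-locus genotype is

$$\mathrm{PID}_{sib} = \tfrac14 + \tfrac12\sum_i p_i^2 +
  \tfrac12\Bigl(\sum_i p_i^2\Bigr)^2 - \tfrac14\sum_i p_i^4 ,$$

the worst realistic case for mistaking two animals for one.
`pidsib_panel()` sorts loci from least to most powerful and extends the
panel until the running product drops to the threshold (default 0.03).
Building from the *weak* end makes the selected panel size
conservative: any same-sized subset is at least as powerful.  With
seven biallelic loci at equal frequencies each locus has
$\mathrm{PID}_{sib} = 0.59375$ and exactly seven loci are needed
($0.59375^7 \approx 0.026 \le 0.03$, six give $\approx 0.044$).
Panel-selection frequencies are estimated from all genotyped samples
(pre-individualization), because no individual-level frequencies exist
yet at that stage; they can be recomputed from identified individuals
afterwards for reporting.

# Dropout-aware matching

Two samples are the same individual when, over mutually scored panel
loci:

* mismatches number at most the budget (1 for panels of up to 10 loci,
  "7 of 8"; otherwise 2, "12 of 14");
* every mismatch is *dropout-explainable* -- one sample homozygous for
  an allele contained in the other's heterozygote; two distinct
  heterozygotes can never be a dropout pair;
* the PIDsib product over the *matching* compared loci stays at or
  below the threshold, so missing loci cannot silently erode the power
  to exclude siblings.

Merging is complete-linkage in canonical sample-id order: a sample
joins a cluster only if it matches **every** member.  Non-transitive
triples (A~B, B~C but A!~C) are refused and flagged for
re-amplification rather than chained, and the merge log records each
such event.  Matching compares every genotyped locus in PIDsib order
rather than only the minimal panel prefix: with the pair-specific
PIDsib condition enforced, extra loci only add power, and a missing
panel locus can be compensated instead of forcing an over-split.

Singletons (one-sample individuals) are kept only if a reliability
screen passes: each observed homozygote contributes the HWE-prior
posterior $p_A / (p_A + e_D (1 - p_A))$ against the dropout
alternative, each heterozygote contributes $1 - e_F$, and the product
must reach 0.9 with at least panel-size-minus-budget loci amplified.
This is a deliberately simplified surrogate for published
multi-replicate reliability algorithms and is documented as such.
Because the screen is applied to *consensus* genotypes -- where a
homozygote has already been confirmed twice -- the screen uses the
consensus-level dropout rate $e_D^2/2$ (two independent replicates
must drop the same allele), not the per-replicate rate; using the raw
rate would reject most honest singletons at realistic error levels.

The sex marker is carried as an ordinary non-panel locus (alleles 1 =
X, 2 = Y) with identical error handling: dropout can mis-sex a male,
as with real amelogenin-type assays, and a single confirmed X/Y call
sexes the individual male because Y cannot arise by dropout.

Cross-laboratory allele-size calibration (`calibrate_allele_sizes()`)
requires a constant per-locus offset across reference individuals and
fails loudly naming any locus where the differences disagree.

# Abundance models

## Huggins closed capture

Within a season the population is assumed closed.  The likelihood
conditions on being captured at least once, so abundance never appears
in it; first capture uses $p$, recaptures use $c$ (the behavioral
response), and both are logit-linear in covariates applied to $p$ and
$c$ equally: sex, and the snare-spacing covariate `dbar` (mean distance
from each detection snare to its nearest other snare, a proxy for local
trap density).  One occasion is one snare-check interval (6-8 days);
abundance is the Horvitz-Thompson sum $\hat N = \sum_i 1/p^*_i$ with
$p^*_i = 1 - \prod_j (1 - p_{ij})$, its variance the standard binomial
plus delta-method form, and the interval a log-normal one on
$\hat N - n$ (standard closed-capture practice).

## Robust design

Annual seasons are open between each other: survival $S$ (optionally
sex-specific) and Markovian temporary emigration with
$\gamma'' = P(\text{absent}_t \mid \text{present}_{t-1})$ and
$\gamma' = P(\text{absent}_t \mid \text{absent}_{t-1})$.  The
likelihood conditions on each individual's first-capture primary: that
primary contributes the closed conditional component, and later
primaries are evaluated by a forward recursion over the hidden states
present / absent / dead, with the secondary detection history as the
emission.  With one primary period this reduces *exactly* to the
closed fit -- a tested invariant.  The exact conditioning convention of
legacy software is internal to it and not recoverable; ours is stated
here and used consistently.  Six model structures (survival constant
or sex-specific, detection year-varying or constant, sex effect on
$p$ and $c$ jointly present or absent) are screened by likelihood-ratio
tests on nested pairs at $\alpha = 0.05$ and ranked by
$\mathrm{AIC}_c = -2\ln L + 2K + 2K(K+1)/(n_{\mathrm{eff}}-K-1)$.  The
effective sample size is the total number of detection-occasion
Bernoulli trials of observed animals -- one documented convention among
several in circulation, which is why published AICc values are not
reproduction targets.

## Continuous-occasion models (ECM / TIRM)

Pooling all capture events into one continuous occasion suits sparse
noninvasive data.  With $n$ observed individuals, $s$ total capture
events and count multiset $c_1,\dots,c_n$:

* **ECM** (even capture): $\log L(N) = \log\frac{N!}{(N-n)!} -
  s\log N$, maximized over integer $N$.
* **TIRM** (two innate rates): $n_a$ individuals at rate 1, $n_b$ at
  rate $\alpha \ge 1$.  Which individuals belong to the fast group is
  unobserved, so the likelihood *sums* over classifications:
  elementary symmetric polynomials $E_j(\alpha^{c_1},\dots,\alpha^{c_n})$
  collect the observed-side assignments and hypergeometric weights the
  unobserved side, all times $N!/(N-n)!\,R^{-s}$ with
  $R = n_a + \alpha n_b$.  At $\alpha = 1$ the Vandermonde identity
  collapses the sum and the ECM likelihood is recovered exactly, so
  ECM is a true submodel and the LRT statistic is never negative.  An
  earlier implementation that *maximized* over classifications instead
  showed a scale-independent ~10% negative bias in recovery
  simulations and was replaced.  $\alpha$ is profiled on a log grid
  with local refinement; $(N, n_b)$ are searched coarse-to-fine in
  compiled code.

Model choice uses a parametric-bootstrap LRT (null datasets from the
ECM fit; TIRM preferred at bootstrap $P < 0.05$), and the confidence
interval is a percentile parametric bootstrap from the selected model,
floored at the observed count.  All-singleton data leave abundance
unidentifiable: the MLE sits at the search bound and is flagged.

# Population-genetic statistics

* **Diversity.** Observed heterozygosity; Nei's unbiased
  $H_e = \frac{2n}{2n-1}(1 - \sum p_i^2)$; rarefied allelic richness
  $R_g = \sum_i [1 - \binom{2N-N_i}{g}/\binom{2N}{g}]$ with `g`
  defaulting to twice the smallest locus-wise sample size.
* **Differentiation.** Nei's $G_{st} = (H_t - H_s)/H_t$ (reported as
  Fst) and Hedrick's standardized
  $G''_{st} = k(H_t-H_s)/((kH_t-H_s)(1-H_s))$, $k = 2$ for pairs.
  $H_s$ and $H_t$ are aggregated across polymorphic loci *before* the
  ratio (per-locus ratios are undefined at monomorphic loci), and the
  pooled frequencies are the unweighted mean of the two populations.
  Published software implements several estimator variants; this
  definition is fixed, documented, and used consistently for all
  simulation-based checks, so bit-level agreement with any particular
  program's tables is not claimed.  Significance is by permutation of
  individuals between the pair, with the add-one rule
  $P = (1+b)/(1+n_{\mathrm{perm}})$ and a default of 999 permutations,
  making $P = 0.001$ the attainable minimum.
* **HWE / linkage equilibrium.** Monte-Carlo exact HWE test (statistic:
  heterozygote count; null: re-paired allele pool; two-sided by
  doubling the smaller tail, capped at 1; monomorphic loci return 1 by
  convention).  LE uses the sum of squared Burrows composite
  disequilibrium coefficients with one locus permuted across
  individuals.
* **LD-Ne.** Burrows $\hat\Delta$ with the $n/(n-1)$ correction gives
  $r^2$ per allele pair (HWE denominators), averaged within locus
  pairs, then combined across pairs weighted by their pairwise sample
  size $S$ -- the missing-data correction.  The sampling expectation
  $E[r^2_S] = 1/S + 3.19/S^2$ ($S \ge 30$; small-sample variant below)
  is evaluated at the harmonic-mean $S$ and subtracted;
  $\hat N_e = (1/3 + \sqrt{1/9 - 2.76\,r^2{}'})/(2 r^2{}')$, infinite
  when no drift signal remains.  Alleles below frequency 0.02 are
  screened out (a fixed, documented choice).  The CI is a
  delete-one-locus jackknife on the drift component (a parametric
  chi-square CI was considered and rejected as no more defensible at
  8-14 loci).
* **Evanno delta-K.**
  $\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / \mathrm{sd}\,L(K)$
  over replicate clustering log-likelihoods; undefined (flagged) when a
  replicate sd is zero.  The clustering runs themselves are produced by
  external software and are out of scope.
* **Relatedness.** Likelihood of each pair under the classes U, HS, FS,
  PO via their IBD coefficients $(k_0, k_1, k_2)$ and
  frequency-conditioned genotype-pair probabilities;
  $\hat r = k_1/2 + k_2$ of the ML class.  The least-related subset is
  chosen greedily by mean pairwise $\hat r$ -- exact subset
  optimization is exponential and unwarranted for its purpose
  (de-biasing clustering runs).
* **Diversity comparisons.** Kruskal-Wallis (tie-corrected) across
  populations with per-locus values as replicates -- the only reading
  under which the published comparisons have replication -- followed by
  Nemenyi all-pairs tests on the studentized range.

# The synthetic-data generator

The generator defines the study conditions; it is the source of every
test dataset.

* **Allele frequencies.** Balding-Nichols: population frequencies are
  Dirichlet draws with concentration $p(1-F)/F$ around shared ancestral
  frequencies.  Because the package *measures* differentiation as Nei's
  Gst among the sampled populations -- whose expectation under a raw
  Balding-Nichols draw is $F(1-1/k)/(1-F/k)$, noticeably below $F$ for
  small $k$ -- the generator calibrates the concentration
  ($F_{BN} = k\,t/(k-1+t)$ for target $t$) so the measured quantity
  matches the requested target.  With `target_fst = 0.2`, two
  populations and 14 loci, the mean realized Gst over replicate draws
  sits within $\pm 0.05$ of 0.2.
* **Populations.** HWE genotypes, optional full-sib families (Mendelian
  from drawn parents) for PIDsib stress tests, planar home-range
  centres, and year-to-year dynamics as survival followed by
  recruitment of new genotypes, realizing an exact abundance
  trajectory.
* **Survey.** Snares on a square grid of 8 km x 8 km (64 km^2) cells,
  one or more per cell; detection of individual $i$ at snare $s$ per
  occasion is half-normal in distance,
  $p_0 \exp(-d_{is}^2 / 2\sigma^2)$ -- the standard spatially explicit
  hazard, chosen because the field protocol implies distance-limited
  exposure but no detection model.  Occasions correspond to 6-8 day
  check intervals; ~10 checks span an August-November season.
* **Errors.** Per replicate and locus: failure with probability `e_A`;
  dropout of a uniformly chosen allele of a heterozygote with `e_D`; a
  spurious allele replacing a called allele with `e_F`, preferring a
  one-repeat-unit size neighbour.  Published per-locus error rates are
  not available for the motivating system, so presets use
  literature-typical hair/scat values (`e_D` 0.05-0.2, `e_F` ~0.01,
  `e_A` ~0.05), all config-exposed.
* **Presets.** `"nal"`: trajectory 12-13-19-25 over four seasons, eight
  moderately diverse loci (four alleles, $H_e \approx 0.56$) plus six
  low-diversity loci, two sib families; `"mrb"`: N = 86 for one season,
  14 low-diversity loci ($H_e \approx 0.33$); `"perfect"`:
  detection-saturated, error-free -- the pipeline must return the exact
  true N on it.  All randomness flows from one seed; the same
  configuration reproduces every output byte (no timestamps are
  written).

What the generator does *not* emulate: scat-dog transects, mixed or
non-target-species samples, landscape-resistance movement, electropherogram-level
artefacts, and continuous individual heterogeneity in detection beyond
the distance kernel.  Passing tests therefore demonstrate correctness
of the estimators under the stated models, not robustness to every
field pathology.

# Numerical choices

Optimization is quasi-Newton (BFGS) on logit scales with three random
restarts and numerical Hessians; detection probabilities are clamped
to $[10^{-12}, 1-10^{-12}]$; boundary fits (e.g. every animal caught
every occasion) are flagged rather than hidden.  Integer abundance
searches bound the population at `max_pop` (default three times the
observed count).  Capture-history construction collapses same-occasion
duplicates; the trajectory criterion "an increasing trend" is
operationalized as a positive least-squares slope of $\hat N_t$ on
year, since strict per-step monotonicity between adjacent true sizes of
12 and 13 is not statistically recoverable at any realistic capture
probability.

Test and acceptance problem sizes (e.g. 200 replicates for
closed-capture recovery, 100 for TIRM and robust-design recovery, 200
null datasets for test-size checks, 50 Wright-Fisher replicates for
LD-Ne) were chosen as the smallest sizes at which Monte-Carlo error is
comfortably inside each stated tolerance.

# Known limitations

* The reliability screen is a simplified surrogate; genuinely marginal
  singletons deserve re-amplification in practice.
* The robust design assumes no within-season mortality and no
  unmodeled heterogeneity beyond sex, spacing, and behavior; strong
  unmodeled heterogeneity biases Horvitz-Thompson abundance downward,
  which is precisely the case the TIRM covers.
* LD-Ne at 8-14 microsatellites is noisy (factor-of-two recovery is
  the realistic expectation) and is infinite by design when sampled
  genotypes carry no drift signal.
* Mixture (multi-animal) samples are out of scope; every sample is
  assumed to be a single individual of the target species.
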