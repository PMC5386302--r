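---
title: "Localizing rare blood-pressure variants in pedigrees: models and design"
author: "pedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing rare blood-pressure variants in pedigrees: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

pedscan implements a family-based strategy for localizing rare variants that
influence a quantitative trait, with blood pressure as the motivating
application. The strategy has four stages:

1. **Variance-component linkage.** A multipoint scan on pedigrees locates
   chromosomal regions where trait covariance tracks local allele sharing.
2. **Candidate filtering.** Coding variants under the linkage peak are
   screened by single-variant mixed-model association combined with
   family-specific linkage contributions.
3. **Risk-score conditional linkage.** A genotype risk score built from the
   selected variants is added as a covariate; the resulting drop in the
   maximum LOD is calibrated against an empirical null obtained by
   conditioning on random off-region SNPs.
4. **Rare-variant set tests.** Burden, SKAT and SKAT-O statistics under a
   polygenic covariance summarize the joint evidence of the variant set,
   with Fisher/Stouffer meta-analysis across cohorts.

A gene-dropping simulator generates complete synthetic studies with the
statistical structure these analyses assume, so every stage is testable
without access to any restricted cohort data.

# Models

## Multipoint IBD and the inheritance-vector HMM

For each family, the hidden state at a locus is the inheritance vector: one
bit per non-founder meiosis indicating which grandparental allele was
transmitted. Between adjacent positions at recombination fraction
$\theta$ (Haldane, $\theta = (1 - e^{-2d})/2$ for distance $d$ Morgans),
each bit flips independently. The emission probability of the observed
genotypes at a marker sums over all assignments of biallelic founder
alleles to the $2F$ founder allele slots that are consistent with the
genotypes; missing genotypes are marginalized. Founder allele frequencies
are estimated from the founders, smoothed by a pseudocount of 0.5.
Forward–backward then yields the exact posterior expected proportion of
alleles shared identical by descent, $\hat\pi_{ij}(t)$, for every
within-family pair at every marker and on a cM grid (default step 1 cM;
the evaluation grid always includes the marker positions).

Exact enumeration is limited to families with at most `bitCap` (default 16)
meiosis bits, i.e. eight non-founders. Larger families — including the
17-member three-generation family in the packaged study design — use a
Monte-Carlo mode: a blocked meiosis Gibbs sampler that updates, for each
parent in turn, all meiosis bits transmitting that parent's alleles by
forward-filtering backward-sampling along the chromosome, plus per-child
blocks (both meioses of one individual). Blocking is essential: the
single-meiosis sampler is reducible because founder phase can only switch
between loci by flipping several bits jointly. The blocked sampler agrees
with exact enumeration to Monte-Carlo error on every pedigree we can
enumerate; irreducibility is nevertheless not guaranteed for arbitrary
pedigrees, which is a known limitation of meiosis samplers. The default is
10,000 retained sweeps after 200 burn-in sweeps; scaled-down settings used
in the test suite are noted below.

## Variance-component linkage

At each position the trait vector of each family is modelled as
multivariate normal with covariance

$$\Sigma(t) = \Pi(t)\,\sigma^2_{QTL} + 2\Phi\,\sigma^2_G + I\,\sigma^2_E,$$

where $\Pi(t)$ holds the pairwise $\hat\pi_{ij}(t)$ (diagonal 1), $\Phi$ is
the pedigree kinship matrix and the three components are the locus-specific,
polygenic and residual variances. Both the alternative and the null
($\sigma^2_{QTL} = 0$) models are fitted by maximum likelihood — fixed
effects and the overall scale are profiled analytically, and a bounded
quasi-Newton search runs on the variance ratios with analytic gradients —
and $\mathrm{LOD}(t) = (\log L_A - \log L_0)/\ln 10$. Because the models are
nested, a negative difference can only be numerical; whenever the
$\sigma^2_{QTL}$ MLE is 0 the alternative is replaced by the null fit, so
the boundary LOD is exactly 0. Under the null the LOD follows the
half-and-half mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ asymptotically;
the acceptance suite verifies $\Pr(\mathrm{LOD} \ge 0.588) \approx 0.05$ by
simulation.

Per-family LOD scores are each family's log10 likelihood-ratio contribution
evaluated at the *overall* MLEs (not per-family MLEs); they sum exactly to
the unclipped total. This is the natural decomposition when families are
independent; other software may define family contributions differently, so
numerical agreement with any particular implementation is not asserted.

Optimizer settings: three deterministic starts for standalone fits; within
a scan each position warm-starts from its neighbour's solution plus one
fresh start. Convergence uses an L-BFGS-B relative tolerance of about
2e-9. Non-convergent positions are flagged with an `NA` LOD and a warning.

## Single-variant mixed-model association

$y = \beta_0 + \text{covariates} + \beta_1 g + \delta + \varepsilon$ with
$\delta \sim N(0, 2\Phi\sigma^2_G)$, $\varepsilon \sim N(0, I\sigma^2_E)$,
dosage $g$ coded additively on the minor allele. ML (not REML) is used for
both the null and alternative so the likelihood-ratio test
($\chi^2_1$) is valid. Missing genotypes drop the individual for that
variant; monomorphic variants are an error.

## Candidate filter, risk score and the LOD-drop null

A regional variant passes the filter when (association $p \le 0.1$ **or**
$|\hat\beta_1| \ge 5$ mmHg) **and** at least one family with family-specific
LOD $\ge 0.1$ at the peak carries it at least twice. The risk score is the
exact inner product $r_i = x_i^\top \beta$ of dosages with the marginal
single-variant estimates (missing dosages contribute 0 and are logged).
Conditioning the linkage scan on $r$ (or any covariate) absorbs it into the
fixed effects of both models.

The significance of the observed MLOD drop is assessed by re-running the
conditional scan with each of $N$ randomly sampled SNPs from *other*
chromosomes (default $N = 1000$, single-SNP covariates, MAF $\ge 0.05$,
drawn from the pruned panel) and reporting the add-one empirical p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$, which can never be 0.
Note the deliberate asymmetry, which mirrors the published design: the
observed statistic conditions on a multi-variant risk score while each null
draw conditions on a single SNP; `k > 1` random-coefficient null scores are
available for sensitivity analysis.

## Rare-variant set tests

Weights are $w_j = \mathrm{Beta}(\mathrm{MAF}_j; 1, 25) =
25(1-\mathrm{MAF}_j)^{24}$, computed within-study on founders and
non-founders together. The burden statistic collapses the set into
$b_i = \sum_j w_j g_{ij}$ and tests it as a single covariate in the mixed
model (LRT). SKAT is the variance-component score test under the
covariates-only null model: $S = G^\top \hat V^{-1}(y - X\hat\alpha)$,
$Q = \sum_j w_j^2 S_j^2$, with null distribution
$\sum_k \lambda_k \chi^2_1$ where $\lambda$ are the eigenvalues of
$W G^\top P G W$ (their sum equals the kernel trace, which the tests
check). Mixture tail probabilities use Liu–Tang–Zhang moment matching,
refined by a Kuonen saddlepoint approximation when the matched p falls
below 1e-3. SKAT-O evaluates $Q_\rho = (1-\rho)Q_{SKAT} + \rho Q_{burden}$
over the standard grid $\{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ and
combines the per-$\rho$ p-values by one-dimensional integration over the
common burden-direction $\chi^2_1$.

One asymmetry is worth stating plainly: the burden test reported by
`burdenTest` is likelihood-ratio based (so a single-variant set reproduces
`fitLmmAssoc` exactly), while the SKAT-O machinery is score based. The two
agree asymptotically but not to machine precision. Singleton $\rho$ grids
therefore return the boundary tests exactly ($\rho=0$ → SKAT, $\rho=1$ →
LRT burden), and inside a multi-point grid the $\rho = 1$ entry uses the
score form with the usual $\rho \to 0.999$ substitution in the
integration.

## Direction consistency and opposite-direction probability

For $n$ replication tests of which $k$ are direction-consistent,
`directionBinomial` returns the strict-greater tail $P(X > k)$ under
$\mathrm{Binomial}(n, 1/2)$ by default — for $n = 23, k = 16$ this is
0.0173, whereas the inclusive tail $P(X \ge 16)$ is 0.0466; both are
exposed because published analyses are not always explicit about the
convention. `oppositeDirectionProb` returns
$\Phi(-\beta^*/\mathrm{se})$; with a true effect a quarter of the trait SD
and unit standardized error this is 0.401. The unit-SE convention is a
reconstruction: the quantity is underdetermined without the replication
cohort's exact sampling configuration.

# The synthetic study design

`simConfig()` fixes the packaged study: 130 families totalling roughly 517
individuals, one of them a 17-member three-generation family; a linkage
panel of 61 markers (MAF 0.2–0.5, emulating a post-pruning panel) spanning
100 cM of the scan chromosome; 250 unlinked off-chromosome SNPs as the
resampling pool; and 21 rare coding variants in the 42–58 cM region.

The causal architecture follows the family-private mechanism the pipeline
is designed to detect: every causal variant segregates in a single family,
forced through one founding haplotype and rejection-sampled (capped at
1,000 drops, with a warning; targets are clamped to what one founder
haplotype can reach) until it meets its carrier target. The 17-member
family segregates the index variant alone — at least five carriers with a
−8 mmHg allele effect, so its carriers average about 8 mmHg below
non-carriers, the pattern the whole pipeline is meant to recover. Twenty
further families (assigned among the larger ones, where multi-carrier
segregation is possible) each carry a protective haplotype bearing *two*
coding variants (−7 and −6, or −6.5 and −7.5 mmHg) that co-segregate from
the same founder; stacked haplotypes of joint effect around −13 mmHg are
what gives the region a reproducible linkage peak at this sample size.
Six inert rare variants give the candidate filter something to reject.
Diffuse low-frequency causal variation was deliberately avoided: at
n ≈ 520 it produces almost no variance-component linkage information,
whereas family-concentrated segregation — the mechanism motivating the
method — does.

A power note that matters for interpreting the end-to-end tests: with five
to eight carriers and a realistic blood-pressure noise scale, the marginal
mixed-model estimate of a −8 mmHg effect has a standard error of roughly
3–4 mmHg, so the candidate filter's effect clause ($p \le 0.1$ or
$|\hat\beta| \ge 5$) retains the index variant in only ~70–80% of
replicates. That is a property of the stated effect size and carrier
count, not of the implementation; the recovery experiment reports it
honestly rather than inflating the planted effect.

Polygenic and residual variances default to $\sigma^2_G = 55$,
$\sigma^2_E = 70$ (heritability 0.44, within the range reported for blood
pressure in family studies). Covariate effects (intercept 102, placing the
non-carrier mean near 125 mmHg;
age +0.45 /yr; age² −0.001; BMI +0.35 per kg/m²; male +4 mmHg), ages tied
to generation depth, and a logistic treatment model in latent SBP
(roughly 20–25% treated; treatment masks observed pressures by −15/−10
mmHg, which `adjustMedication` adds back) complete the phenotype model.
Diastolic pressure is generated as a noisy linear companion of SBP so that
pulse pressure is well defined.

What the simulator does **not** emulate: population LD structure among
panel markers (founder haplotypes are drawn in linkage equilibrium, so LD
pruning is exercised only by explicitly constructed test fixtures),
ascertainment through probands, X-linked inheritance, genotyping error,
and inbreeding loops. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to those
real-data complications.

# Numerical and scale choices

- Exact HMM state space capped at 2^16; the packaged large family (22
  meiosis bits) always routes to the blocked Gibbs sampler.
- Variance ratios are bounded in [0, 200] (heritability up to ~0.995);
  profile likelihood makes the search 1–2 dimensional.
- Mixture-χ² p-values switch from moment matching to the saddlepoint below
  1e-3; eigenvalues below 1e-10 of the largest are dropped.
- The empirical LOD-drop p uses the add-one estimator.
- Test-suite problem sizes (the package's own scaling choices): linkage
  null calibration uses 50 sib-quad families, a 2 cM informative map and
  500 trait replicates; test calibration uses 1,000 replicates on 60
  three-child families; the end-to-end recovery experiment uses 25
  replicates of the full packaged study with a 5 cM scan grid, 2,000
  Gibbs sweeps for the large family and a 200-SNP resampled null (a scaled
  version of the 1,000-SNP design); the acceptance script runs the full
  study once at 2.5 cM, 10,000 sweeps and a 250-SNP null.

# Known limitations

- The blocked Gibbs sampler has no irreducibility guarantee on arbitrary
  pedigrees; for structures far from the packaged design, verify against
  exact enumeration on sub-pedigrees.
- Per-family LOD semantics are this package's definition (overall MLEs);
  they need not match other linkage software numerically.
- Pedigrees with loops (inbreeding) are rejected; marker maps must be
  strictly usable (non-decreasing cM; coincident positions are allowed and
  treated as zero-recombination intervals).
- Haplotype-based (EM) r² for pruning, marker-cluster LD modelling in the
  HMM, binary-trait tests, and genome-wide significance theory are out of
  scope.
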