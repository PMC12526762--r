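---
title: "Methods and models in steppekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models in steppekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steppekit)
```

`steppekit` implements the standard inference stack for low-coverage
ancient-genome studies: pseudo-haploid calling, f-statistics, qpWave and
qpAdm admixture models, admixture dating by ancestry-covariance decay,
IBD- and mismatch-based kinship analysis, and PCA projection, plus a
synthetic-data layer that gives every stage a known ground truth. This
vignette explains the models, the defaults and why they are set where
they are, and what the synthetic validation does and does not
demonstrate about real data.

## Data model

Genotypes live in an EIGENSTRAT-style triplet: a SNP table with genetic
positions in Morgans, a sample table, and a matrix of alt-allele counts
0/1/2 with 9 for missing. Two calling modes coexist: diploid calls
(two allele observations per genotype) and pseudo-haploid calls — a
single sequencing read's allele per site, coded homozygous (0/2). Group
allele frequencies weight each call by its ploidy, so mixed datasets
remain unbiased: a pseudo-haploid 2 is one alt allele out of one
observed, not two out of two. Chromosome labels are normalized by
stripping a leading `chr`; 23/24 are accepted but flagged non-autosomal,
and all analyses default to autosomes (how hemizygous sites should enter
a genotype matrix is left open by common practice, so we exclude them
rather than guess).

## Damage-aware pseudo-haploid calling

Post-mortem cytosine deamination converts C to U, read as T. In
single-stranded libraries this appears as C→T mismatches concentrated at
both read termini *in read orientation*: on the reference strand,
plus-strand reads show C→T and minus-strand reads show G→A. At a C/T SNP
a damaged plus-strand read is indistinguishable from a genuine T allele;
a minus-strand read cannot produce that artifact. The single-strand
calling rule therefore uses only minus-strand reads at C/T SNPs and only
plus-strand reads at G/A SNPs, removing damage-driven miscalls entirely
rather than down-weighting them. Reads below Phred 30 base or mapping
quality are excluded, one eligible allele-supporting read is sampled
uniformly per site, and sites without eligible reads are missing.

Determinism: reads are canonically sorted (strand, position in read,
base, quality) before the seeded draw, so a call depends on the read
*set* and the seed, not on input order.

`simulate_pileup` implements exactly this damage chemistry (read-space
C→T at terminal offsets, mirrored to genome space per strand), which is
what makes the package-level invariant testable: with simulated damage
only, single-strand calling yields zero damage-induced alt calls while
naive calling shows an excess equal to the injected rate times the
probability that the sampled read is a vulnerable-strand read with the
SNP inside the damaged window.

Sex is called from SNP-targeted coverage: the Y/autosome depth ratio
exceeds ~0.5 in males and ~0 in females, so the thresholds are 0.3
(male) and 0.1 (female), with the interval between left undetermined.
Panel-site depth rather than genome-wide depth is used because capture
data only measures the former.

## f-statistics and the block jackknife

For group frequencies $p_a$, the per-SNP kernels are
$f_4 = (p_a-p_b)(p_c-p_d)$, $f_3 = (p_o-p_a)(p_o-p_b)$ and
$f_2 = (p_a-p_b)^2$; estimates average the kernel over SNPs where every
involved group has data (complete case per statistic; monomorphic sites
are kept). Whenever a population appears on both sides of the product —
always for f2 and f3, and for f4 configurations with a repeated group —
its sampling noise enters both factors and inflates the expectation by
$\mathrm{Var}(\hat p)$. We subtract the unbiased estimate
$\hat p(1-\hat p)/(n-1)$, with $n$ the observed allele count, wherever a
repetition occurs, with the sign of the induced covariance. This single
rule yields the textbook heterozygosity correction for f3 and makes f2
unbiased for the squared true-frequency difference. The correction needs
$n \ge 2$; a group represented by one pseudo-haploid sample cannot be
corrected, which is why single-sample outgroup-f3 values should be read
as relative, not absolute, drift.

Standard errors come from a weighted delete-one-block jackknife. SNPs
are binned per chromosome into half-open 5 cM windows (`blgsize = 0.05`
Morgans, the field's convention) anchored at the chromosome's first SNP;
blocks never span chromosomes. With block SNP counts $m_j$, total $n$,
$h_j = n/m_j$, full estimate $\hat\theta$ and leave-one-out estimates
$\theta_{(j)}$, the pseudovalues are
$\tau_j = h_j\hat\theta - (h_j-1)\theta_{(j)}$ and
$\widehat{\mathrm{Var}} = g^{-1}\sum_j (\tau_j-\theta_J)^2/(h_j-1)$.
Z-scores are estimates in SE units, the scale on which symmetry tests
are reported.

## qpWave and qpAdm

Given left populations $l_1..l_L$ and right (reference) populations
$r_1..r_R$, the matrix $X_{ij} = f_4(l_{i+1}, l_1; r_{j+1}, r_1)$
measures how differentially each left contrast relates to each right
contrast. If the left set descends from $r+1$ independent ancestry
streams, $X$ has rank $r$. `qpwave_test` estimates the joint covariance
$Q$ of $\mathrm{vec}(X)$ with the same 5 cM block jackknife (shared
blocks across all entries, so the covariance is coherent), fits the best
rank-$r$ approximation $E$ by alternating least squares in the $Q^{-1}$
metric (SVD initialization, relative tolerance $10^{-10}$, ridge
fallback when $Q$ is near-singular), and refers
$(\mathrm{vec}(X)-\mathrm{vec}(E))^\top Q^{-1}(\cdot)$ to $\chi^2$ with
$(L-1-r)(R-1-r)$ degrees of freedom. Rank 0 with two left populations is
the cladality test.

`qpadm_fit` models a target as a $k$-source mixture. With rows
$f_4(s_i, T;\, r_{j+1}, r_1)$, the mixture condition
$p_T = \sum_i \alpha_i p_{s_i}$ makes
$\sum_i \alpha_i\,\mathrm{row}_i = 0$: the weights are the left null
vector of the rank-$(k-1)$ fitted matrix, normalized to sum 1. This
differenced construction was chosen over the equivalent un-differenced
(target+sources) × rights matrix because it is *exactly* invariant under
reordering of the right list (a linear column transform per SNP, which
the GLS objective absorbs), and because $k=1$ then collapses onto the
cladality test identically. The model p-value is the rank-$(k-1)$ test
of the same matrix, df $= R-k$. Per-weight SEs re-run the whole fit
(warm-started) with each block deleted. Weights are reported as fitted —
negative values are meaningful evidence of a misspecified source and are
flagged infeasible, not clipped. The 0.05 reporting threshold is a
convention, not hard-coded.

Nested comparison: dropping one source and moving it to the right set
gives a comparable reduced model; the difference of model chi-squares on
the difference of dfs (always 2 for three-way vs two-way) tests whether
the dropped source is required. `rotate_candidates` automates the
standard rotating scheme — each candidate in turn becomes a source while
the others join the right set — ranking models by p.

The exact df convention of the classical reference tools is not
published; our standard is internal calibration, verified by simulation:
the null rank-0 test rejects at close to nominal rate, true mixtures are
recovered within 2 jackknife SEs, and a genuinely contributing 20% third
source is detected by the nested p (all in `tests/testthat/`, which also
pins the rank statistic to an independent dense-optimizer oracle on 3×3
instances).

## Admixture dating

In an admixed genome, alleles at two loci covary around the mixture
expectation only while they sit on the same ancestry tract. Under a
single admixture pulse $T$ generations ago, local ancestry along the
genetic map is Markov with autocovariance
$\alpha(1-\alpha)e^{-T d}$ at distance $d$ Morgans — so the decay rate
of ancestry covariance *is* the admixture age in generations.

Per SNP the reference weight is $w_i = p_A(i) - p_B(i)$; per individual
the residual is $x_i = g_i/2 - \mu_i$ with
$\mu_i = \hat\alpha p_A + (1-\hat\alpha) p_B$ and $\hat\alpha$ the
individual's least-squares ancestry proportion constrained to $[0,1]$
(the mixture proportion is estimated, not supplied — it is not a dating
input). Same-chromosome SNP pairs are binned by genetic distance
(binsize 0.001 M, maxdis 0.5 M), and the bin statistic is
$\sum w_iw_jx_ix_j / \sum w_i^2w_j^2$, averaged over individuals. Pairs
are assigned by the difference of their binsize-grid cell indices, which
lets the production code accumulate per-cell sums and compute all lags
at once by FFT autocorrelation while remaining bit-for-bit equal to the
naive $O(n^2)$ pair loop (a tested equivalence, $<10^{-10}$).

The curve is fit as $A(d) = a e^{-\lambda d} + c$ by multi-start
Levenberg–Marquardt ($\lambda_0 \in \{1,10,100,1000\}$), over bins with
$d \ge$ 0.45 cM (`lovalfit`), excluding short-range background LD that
the single-pulse model does not describe; the affine offset $c$ absorbs
residual finite-sample covariance. Display-only parameters of the
classical tool (`qbin`, `runmode`) have no effect on the estimand and
are not modelled. Uncertainty is a weighted leave-one-chromosome-out
jackknife (weights = per-chromosome pair counts). Dates convert at 29
years per generation; when an archaeological date range for the sampled
individuals is given, each ±2 SE endpoint is widened by half that range.

The exact residualization of the classical implementation is not
published; the definition above is this package's own, validated by
recovery: the median estimate over 20 replicates is within 10% of truth
for $T \in \{10, 50, 100\}$ at 50 diploid individuals on 22 × 1 M
chromosomes (1,000 SNPs per chromosome — chosen because recovery is
already comfortably inside tolerance at that density).

## Kinship

**PMR.** The pairwise mismatch rate over co-called autosomal
pseudo-haploid sites scales with kinship: resampling the same genome
gives half the unrelated background $x_0$, first-degree pairs 3/4,
second-degree 7/8. $x_0$ is the *median* over all pairs (robust to a few
relatives in the cohort), and degrees are assigned to the nearest
expected ratio with midpoint cutoffs (0.625, 0.8125, 0.9375). Pairs
under 3,000 overlapping SNPs are flagged unreliable.

**Pedigree simulation.** Second-degree subtypes (grandparent–grandchild,
avuncular, half-siblings, double first cousins) are distinguished by
their IBD segment-count and length distributions, calibrated by
gene-dropping through each minimal pedigree. Crossovers follow a
two-pathway interference model: chiasmata from a stationary gamma
renewal process with shape $\nu$ (rate $2\nu(1-p_{esc})$ per Morgan,
thinned 1/2 to a gamete — simulated from a long burn-in so the process
is stationary on entry) plus a Poisson escape pathway carrying fraction
$p_{esc}$ of events. Mean crossovers per gamete equal the map length for
any $(\nu, p_{esc})$ — a tested invariant — and $\nu = 1, p_{esc} = 1$
reduces to a Poisson process. Defaults $\nu = 7.6$, $p_{esc} = 0.1$ are
literature-scale interference values; all downstream properties are
either parameter-free or self-calibrated against envelopes simulated
with the same settings. Meioses use sex-specific map lengths (female
1.25× and male 0.75× a sex-averaged baseline totalling ~35.5 M), with
crossover positions rescaled to the sex-averaged coordinate system so
both probands share one scale; pedigrees are the paternal variants, as
appropriate for a male pair sharing a Y lineage. The IBD-calling HMM
itself is out of scope: observed segments arrive as tables (or
simulation truth), and the same merge+filter is applied to observed and
simulated segments alike.

**Segment algebra.** Alternating or abutting IBD1/IBD2 segments on a
chromosome merge into one block (union length, summed SNPs, IBD2
component retained); blocks shorter than 12 cM or sparser than 220
SNPs/cM are removed — thresholds matching standard false-call filters on
the capture panel. Merge and filter are idempotent and commute with
chromosome partitioning.

**Classification.** Double first cousins are excluded outright when the
observation has no IBD2 but the simulated envelope's 5th percentile of
IBD2 length is positive. Remaining relationships are ranked by
Mahalanobis distance of (block count, total length) to each envelope's
empirical mean and covariance (+1e-6 ridge), and a relationship is
flagged excluded when the distance exceeds the envelope's own 97.5th
percentile self-distance. The distance rule is this package's explicit
criterion for "mismatch in the IBD distribution"; no published statistic
exists for it. In validation, ≥80% of fresh simulated pairs are assigned
their true subtype, with residual confusion concentrated between
avuncular and half-siblings — the two most similar distributions.

## PCA projection

The reference basis is computed only from complete-data individuals
(SNPs with any reference missingness are dropped and logged): genotypes
are centered by $2\hat p$ and scaled by $\sqrt{\hat p(1-\hat p)}$, the
top-$K$ right singular vectors are the loadings (sign convention:
largest-magnitude entry positive), and reference scores are the
projections. High-missingness individuals are placed by solving the
$K \times K$ normal equations restricted to their observed SNPs — the
least-squares projection that avoids the shrinkage toward the origin
that zero-filling would cause. A complete-data individual projects
exactly onto its reference score.

What projection noise does: at 70% missingness the score noise variance
is roughly $1/0.3$ times a complete-data individual's, and for an
i.i.d. synthetic population the reference cloud's spread *is*
complete-data noise — so projected replicates scatter wider than the
reference cloud itself. The meaningful, tested property is
unbiasedness: projected replicates center on their population's
reference centroid (≥90% within the 3 SD ellipse about that centroid
under the replicates' own covariance, and all closer to their own
centroid than to the other population's). Real reference panels, whose
clouds are spread by genuine structure rather than sampling noise,
absorb projection noise more gracefully.

## Synthetic data: what it does and does not emulate

The generator covers the statistical structure the estimators consume:

- **Admixture graphs**: ancestral frequencies uniform on (0.05, 0.95);
  Balding–Nichols drift on each edge (Beta with mean $p$, variance
  $Fp(1-p)$); admixture nodes mix parents linearly (clamped to
  [0.001, 0.999]). Second moments of all leaf frequencies — hence exact
  expected f2/f3/f4 — follow by dynamic programming from the martingale
  property of drift, giving a closed-form oracle against which the
  empirical estimators are checked to $|Z| < 4$ at $10^5$ SNPs.
- **Ancestry tracts**: a two-state Markov jump process with stationary
  distribution $(\alpha, 1-\alpha)$ and relaxation rate $T$ per Morgan —
  exactly the single-pulse exponential-decay model the dating stage
  fits, so recovery is a clean identification check. The default
  synthetic map is uniform (1 cM/Mb); empirical map irregularity is not
  modelled.
- **Pileups**: Poisson depth, uniform strand and read position,
  single-stranded-library deamination, fixed qualities above the
  cutoffs by default.

Deliberately not emulated: linkage disequilibrium within populations
(SNPs are independent given the graph), sequencing error beyond
deamination, reference bias, contamination, empirical recombination-map
structure, and continuous or multi-pulse admixture. Consequently,
passing tests demonstrate correctness of the estimators under their own
model assumptions and calibrated uncertainty at realistic scale — not
robustness to the full messiness of real ancient DNA, for which the
upstream QC steps (contamination estimation, imputation, IBD calling)
remain external.

## Numerical choices and degenerate inputs

- Jackknife requires ≥2 blocks (error below); covariances are
  ridge-regularized only when near-singular, with the epsilon logged.
- ALS rank fits: SVD init, tolerance $10^{-10}$, max $10^4$ iterations;
  jackknife refits warm-start from the full-data solution.
- Exponential fits: multi-start, $\lambda > 0$ bound, best residual
  wins; fewer than 4 usable bins is an error; one chromosome cannot be
  jackknifed.
- Zero-depth pileups, empty candidate lists, 100%-missing projections,
  indistinguishable dating references and packed-binary EIGENSTRAT all
  fail fast with specific messages.
- Every generator is reproducible from (spec, seed); the pipeline
  derives per-stage seeds from the global seed by a counter scheme so
  stages can be re-run in isolation.

## Validation scale

The test suite validates at desk scale on one CPU: 20 random graphs at
$10^5$ SNPs for the f-statistic oracle; 100 replicates each for qpAdm
recovery ($10^5$ SNPs), null calibration ($2\times10^4$ SNPs) and
nested detection ($10^5$ SNPs); 20 dating replicates per true age at 50
individuals × 22 chromosomes × 1,000 SNPs; 100-replicate kinship
envelopes with 50 fresh pairs per relationship; these sizes were chosen
so each stage's statistical tolerance is met with margin while the
whole suite stays convenient to run routinely.
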