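---
title: "Models and methods behind hzadmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hzadmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hzadmix)
```

hzadmix analyses hybrid zones from the genotypes of three groups of
individuals: two parental reference populations (A and B) and a set of
admixed candidates sampled in or near the contact zone. This vignette is
the package's own account of the models it fits, the parameters that
matter, what the built-in simulator does and does not emulate, and the
design choices made where several readings were defensible.

## Diagnostic loci and the allele-frequency differential

Parental allele frequencies are estimated per locus as allele-count
fractions within each parental group (admixed candidates never
contribute). For a biallelic locus the Gregorius–Roberds differential,
half the summed absolute frequency differences over alleles, reduces to

$$\delta = |p_A - p_B| \in [0, 1].$$

Two semantics matter at the top of the range. A *fixed difference*
(δ = 1) is decided on the observed parental allele sets being disjoint —
each group carries only one allele and they differ — not on a floating
comparison |p_A − p_B| ≥ 1 − ε. Counted frequencies make this exact and
avoid float ties; a locus at δ numerically indistinguishable from 1 but
polymorphic within a group is not fixed. Thresholds below 1
(conventionally δ ≥ 0.8) use ordinary numeric comparison.

SNP filters default to the values typical of a RADseq genotype export:
per-call depth ≥ 20 (calls below are masked to missing), locus call rate
≥ 80%, minor allele frequency ≥ 0.05, and presence of the locus in all
three groups. The filter order is fixed — depth masking, call rate, MAF,
group presence — because depth masking changes call rates; the attached
report gives sequential removal counts in that order so they are
interpretable. MAF is computed over all non-missing calls in all groups
(parental plus admixed); computing it within groups instead is a
reasonable alternative, but the whole-dataset convention matches how a
single pooled genotype export is usually filtered, and the parameter
object keeps the choice explicit.

## Hybrid index and interspecific heterozygosity

Genotypes on a diagnostic-locus set are polarized so that 2 counts the
B-associated allele — the allele commoner in the PARENTAL_B group — giving
the genotype labels AA (0), Aa (1), aa (2). Polarization is deliberately
deferred to this stage so that file I/O stays lossless.

The hybrid index $h$ of an individual is the proportion of its genome
derived from the B parent, estimated by maximum likelihood under the
standard codominant admixture model: at locus $l$ with B-polarized
parental frequencies $(p_{A,l}, p_{B,l})$, the genotype is
Binomial$(2, q_l)$ with $q_l = h\,p_{B,l} + (1-h)\,p_{A,l}$, loci
independent, parental frequencies treated as known point estimates (no
uncertainty propagation — the same convention as the codominant usage of
the method this mirrors). When every usable locus is a fixed difference
the MLE has the closed form (B-allele count)/(2 × loci) and is returned
exactly; otherwise the likelihood is maximized on [0, 1] by bounded
quasi-Newton iteration to absolute tolerance 10⁻⁶, restarted from
h₀ ∈ {0.1, 0.5, 0.9} and compared against the boundary values h = 0 and 1.
The likelihood is unimodal in h for this model; the restarts and boundary
checks only guard numerical flatness. A 2-log-likelihood-unit support
interval is located by root finding on either side of the MLE. Genotype
probabilities are floored at 10⁻¹² inside logs so that configurations
impossible under point-estimate frequencies (e.g. a B allele in an
individual with h = 0) stay finite; the flooring is counted and warned
about where it indicates model violation rather than rounding.

Interspecific heterozygosity $H$ is the proportion of non-missing
diagnostic loci with polarized call 1. At fixed loci this is exactly the
fraction of loci carrying one allele of each parental origin; at δ ≥ 0.8
loci it counts heterozygotes for the A- vs B-associated allele, the
natural extension when origin cannot be read off the allele directly.
This extension reproduces the known behaviour that non-fixed locus sets
inflate H in parental individuals (a parental heterozygote at a
shared-polymorphism locus counts toward H).

## Hybrid classification

Classes partition the (h, H) unit square totally:

* h = 0 exactly → PURE_A; h = 1 exactly → PURE_B;
* H ≥ 0.85 → F1 (the heterozygosity criterion is primary; an F1-like H
  outside the window 0.25 ≤ h ≤ 0.75 is still reported as F1, with a
  boundary flag, since no other class is biologically coherent there);
* otherwise h ≤ 0.25 → BACKCROSS_A, h ≥ 0.75 → BACKCROSS_B (the boundary
  values resolve to the backcross class), and MULTIGEN in between.

The conventional description of an F1 as "hybrid index = 0.5" is unusable
as an exact test on estimates; the H ≥ 85% criterion with an h window is
the operational rule, following the classification scheme this rule set
descends from. Note that a first-generation backcross has *expected*
h exactly at the 0.25/0.75 boundary, so roughly half of BC1 genomes
legitimately realize an ancestry on the MULTIGEN side; class-recovery
checks therefore compare estimated classes against the class implied by
the realized ground-truth ancestry, not against pedigree labels.

## Genomic clines

For each diagnostic locus, genotype is regressed on the genome-wide
hybrid index with a three-category multinomial logistic model, linear in
h:

$$\log \frac{P(Aa)}{P(AA)} = \beta_0 + \beta_1 h, \qquad
  \log \frac{P(aa)}{P(AA)} = \gamma_0 + \gamma_1 h.$$

Only the admixed group enters the fit; parental groups contribute solely
through allele frequencies. The model is fitted by maximum likelihood
(L-BFGS-B with analytic gradients) with coefficients bounded at |β| ≤ 30:
complete separation otherwise sends coefficients to infinity, and 30 on
the log-odds scale is already numerically saturated; fits on the bound
are flagged. A quadratic term in h is available (`degree` semantics are
kept configurable at the fitting level) but the default is linear — the
data sizes this method is used at rarely support more.

The neutral reference model predicts each individual's genotype at the
locus as Binomial(2, q) from its own hybrid index, i.e. the same mixing
model as the hybrid-index likelihood; within this package that is the
only self-consistent definition of "neutral introgression given h". The
observed statistic is LR = 2(lnL_fit − lnL_neutral), clamped below at 0:
the two families are not nested (at a fixed locus the neutral curve's
logit is log h − log(1−h) plus a constant, not linear in h), so small
negative values are possible and carry no evidence of deviation. The null
distribution of LR is obtained by parametric bootstrap: genotypes are
re-simulated from the neutral model at each individual's h, the cline
refitted, and

$$p_{raw} = \frac{1 + \#\{LR_s \ge LR_{obs}\}}{n_{sims} + 1},$$

the add-one estimator, so p is never zero. `n_sims` defaults to 1000
(500 is used in the calibration checks); the seed is mandatory, and each
locus uses a deterministic offset of the base seed so scans are exactly
reproducible. The same simulations classify each genotype class as
overrepresented ("+", observed count above the 97.5th percentile of the
simulated neutral counts) or underrepresented ("−", below the 2.5th),
rendered as e.g. `AA Aa- aa+` — heterozygote deficits suggesting
underdominance, disruptive selection, assortative mating or null alleles;
heterozygote excess suggesting overdominance or paralogy.

Two multiple-testing conventions are reported side by side, because both
are in common use for this analysis: the Benjamini–Yekutieli adjusted
significance level in Narum's formulation, α / Σ_{i=1..k} 1/i for a
family of k tested loci (0.013 at k = 23, 0.011 at k = 50, 0.009 at
k = 152), and Benjamini–Hochberg adjusted p-values (via `p.adjust`, with
NA p-values excluded from the effective family size).

## F_ST and PCA

Pairwise differentiation uses the Weir–Cockerham (1984) two-population,
two-allele variance components a, b, c, with per-locus θ = a/(a+b+c) and
the mean over loci as the ratio of sums Σa / Σ(a+b+c). A locus
contributes when both groups have at least two genotyped individuals.
Small negative estimates are reported unclamped. No per-locus
significance-based zeroing is applied to the mean (some pipelines zero
non-significant per-locus values before averaging; that divergence is
deliberate and documented here — it makes the estimator standard and
hand-checkable at the cost of exact parity with such pipelines).

Genotype PCA mean-centers loci and imputes missing calls to the locus
mean before singular value decomposition. Mean imputation shrinks
heavily-missing individuals toward the origin — a known qualitative
artefact, reproduced intentionally because exploratory PCAs on genotype
matrices with missing data behave exactly this way. Plumage PCA instead
centers and scales traits to unit variance (`prcomp(scale. = TRUE)`), in
two variants guarding against incomplete scores: drop rump-missing
individuals, or drop the rump trait. Component signs are fixed by forcing
the largest-magnitude loading positive, so higher PC1 is more B-type
under the package's polarity convention (higher score = more B-like);
analyses that load the A-type pole positively simply appear sign-flipped,
which the sign rule makes deterministic rather than solver-dependent.

## Plumage scoring and zone profiling

Six integer trait scores (head, chest, upper/lower abdomen, rump on 0–4;
cheek patch on 0–2) are converted to proportions by their trait maxima.
The plumage hybrid index is the unweighted mean of available trait
proportions: an unscorable rump simply drops out of the average (the only
consistent way to index every individual), and any trait can be excluded
explicitly — excluding the cheek patch is useful when that trait is
polymorphic within a parental species and inflates parental indices.

The hybrid-zone profile operationalizes what is usually done by visual
inspection of score-versus-latitude plots: an individual is
zone-defining when its plumage index lies strictly inside the
intermediate band (default 0.2–0.8), or when it shares a 0.25° latitude
bin with both a near-pure-A (< 0.1) and a near-pure-B (> 0.9) individual
(phenotype co-occurrence). Latitude bounds are the min/max over
qualifying individuals; longitude bounds the min/max of in-band
individuals inside them. Band, bin width and purity cut-offs are
parameters, since the rule is an operationalization rather than a fact of
nature.

## The simulator: what it emulates, and what it does not

The generator reproduces the statistical structure the analyses assume,
with ground truth recorded at every level:

* **Parental frequencies.** A configured fraction of loci is fixed
  (p_A, p_B) = (0, 1); a fraction is strongly differentiated with true δ
  drawn from [0.8, 0.98); the remainder draw both frequencies i.i.d. from
  Beta(0.5, 0.5) — the U-shaped spectrum typical of SNP panels, with most
  loci near fixation on one or both sides — redrawn if a pair lands at
  δ ≥ 0.8 so "weak" means weak by construction. Defaults (600 loci, 4%
  fixed, 8% strong) echo the proportions seen in RADseq hybrid-zone
  panels of a few thousand loci yielding tens of fixed differences.
* **Individuals.** Parental reference samples are Hardy–Weinberg draws.
  Admixed individuals are built by explicit pedigree (F1, F2, BC1/BC2 to
  either side, or k successive hybrid×hybrid generations) over
  per-haplotype allele *and ancestry-origin* tracking, so the recorded
  ancestry fraction is the realized allele origin, not the pedigree
  expectation — parameter-recovery tests then compare like with like.
  Gametes assort independently across loci: no linkage, no mutation,
  matching the independence assumptions of every downstream model.
* **Non-neutral loci.** Transmission distortion — a heterozygous parent
  transmits its B-origin allele with probability ½ + b — is the chosen
  mechanism because it produces exactly the genotype-frequency departures
  the cline test targets (homozygote excess, heterozygote deficit)
  without requiring a viability model.
* **Phenotype and geography.** Each plumage trait's latent value is the
  ancestry fraction plus Gaussian noise (default sd 0.1, which keeps the
  plumage-vs-genomic index correlation at the ρ ≥ 0.9 level observed in
  well-behaved scoring systems), clipped, scaled and rounded to integer
  scores; the cheek patch gets extra noise at low ancestry to emulate
  parental polymorphism in that trait. Latitude maps monotonically from
  ancestry (A-type at the northern end) with 0.2° noise; intermediates
  are placed in the middle third of the longitude range.

What it does **not** emulate: linkage disequilibrium and recombination
maps, drift since divergence (frequencies are fixed truths, not coalescent
outcomes), selection on viability, spatially explicit dispersal,
genotyping error other than missingness, and allele dropout. Passing
tests on simulated data therefore demonstrate correctness of the
estimators under their own assumptions — not robustness to the violations
real RADseq data supply.

## Numerical and testing choices

Degenerate inputs are contracts, not surprises: empty datasets, all-missing
individuals, unpolarizable loci (p_A = p_B), constant matrices and
zero-variance traits all raise named errors; boundary hybrid indices (0, 1)
are handled exactly. Test problem sizes are chosen to make the checks
sharp but quick: oracle comparisons run at 6–60 samples; calibration of
the cline test uses 200 neutral loci × 50 individuals × 500 bootstrap
replicates (the rejection count is checked against the 99% binomial
interval around 0.05); power uses 8 distorted among 40 fixed loci in an
F2 population of 50, where the neutral reference rate comes from an
otherwise identical undistorted run because distorted loci contaminate
the genome-wide h of their own run. The full suite completes in a few
minutes on one CPU.

## Known limitations

* Hybrid-index likelihoods ignore uncertainty in parental allele
  frequencies; with few parental individuals, δ and h are both noisy and
  the δ = 1 screen can admit a non-fixed locus (the filtering tests
  quantify this at realistic sample sizes).
* The neutral model conditions on the estimated h, which itself uses the
  tested loci; with few loci and strong distortion this mildly inflates
  neutral-locus rejection, visible in the power tests.
* Mean F_ST is not numerically identical to pipelines that apply
  per-locus significance zeroing before averaging.
* The classification thresholds are conventions; individuals near class
  boundaries are genuinely ambiguous and the boundary flag should be
  taken seriously rather than the label.
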