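---
title: "Methods: clonal hematopoiesis, ancestry and germline association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal hematopoiesis, ancestry and germline association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chancestry)
```

`chancestry` implements the statistical machinery for studying clonal
hematopoiesis (CH) — the clonal expansion of blood stem cells carrying
somatic driver mutations — in admixed cohorts, where CH risk, smoking,
ancestry and germline variation are entangled. This vignette explains the
models, the parameters that matter, and the design choices made where more
than one reasonable implementation exists.

## CH driver calling

A somatic record qualifies as a CH driver call when it passes four gates,
evaluated in a fixed order so rejection reasons are deterministic:

1. **panel** — the gene is in the configured rule set;
2. **reads** — at least 3 alternate-allele reads;
3. **VAF** — variant allele fraction in [0.03, 0.40], both ends inclusive
   (we read "at least 3% but not more than 40%" literally);
4. **consequence** — the variant class matches the gene's rule class:
   *whole-gene* genes (DNMT3A, TET2, TP53) accept any protein-truncating
   variant (nonsense, frameshift, splice-site) plus catalogued hotspots;
   *exon-restricted* genes (ASXL1, PPM1D) accept PTVs only in listed exons;
   *hotspot-only* genes accept only catalogued amino-acid changes.

Hotspots match on protein change when present, else on
`chrom:pos:ref:alt`, because published hotspot catalogues key on the
amino-acid change. The shipped hotspot lists are an illustrative default —
the full catalogue lives in supplementary material of the primary
literature and varies between studies — so rule sets are plain JSON that
users can replace wholesale (`ch_rules("custom", path = ...)`). A 58-gene
extension ships with the same schema; genes beyond the core 15 default to
the whole-gene PTV rule.

An individual's overall CH flag is the OR over gene flags; composite
phenotypes (e.g. SF3B1+SRSF2 splicing-factor CH) are unions of gene flags.

## Local ancestry

Window-level ancestry calls (RFMix-style MSP files) are aggregated three
ways, all **base-pair-weighted** rather than window-count-weighted, since
windows differ in length and the quantity of interest is genome
proportion:

* *global*: total bp labelled with each ancestry over both haplotypes,
  divided by twice the span;
* *interval-level*: overlap-weighted fraction across windows intersecting
  a query interval, per haplotype;
* *diplotype*: the two haplotype fractions at a locus are averaged and
  binned — European homozygous (mean ≥ 0.95, additive code 2), European
  heterozygous (0.45–0.55, code 1), non-European homozygous (≤ 0.05, code
  0, the reference), anything else unassigned and excluded from the
  additive regression. Exclusion (rather than nearest-band assignment)
  keeps the categories exactly as defined; with single-window loci the
  fractions are binary and nothing is excluded.

The source analyses do not pin down how far the "haplotype-level" region
around a driver gene extends; `interval_ancestry()` therefore takes an
explicit interval and callers choose the flank (250 kb is a reasonable
default for haplotype-scale context).

Cohort matching is exact within strata of 1-year age bins × sex
(× smoking on request), greedy within stratum under a fixed seed, ratio
configurable; the matching factors come from the study design, the
algorithm is ours since none was specified, and the balance property
(post-matching standardized differences never exceed pre-matching) is
tested.

## Firth penalized logistic regression

Associations with rare binary outcomes are fitted by maximizing the
Jeffreys-penalized log-likelihood
$l^*(\beta) = l(\beta) + \frac{1}{2}\log\det I(\beta)$
with Newton iterations (gradient tolerance $10^{-8}$, max 50 iterations,
step-halving on the early large steps). The penalty removes first-order
bias and keeps estimates finite under complete separation — the regime a
CH case count of a few thousand against a low-frequency allele lives in.

Per-term P values use the penalized likelihood-ratio test. The restricted
fit constrains the tested coefficient to zero **on the full design**, so
the Jeffreys penalty cancels between the two likelihoods; refitting on a
reduced design instead leaves a $O(\log n)$ penalty mismatch in the
statistic and visibly inflates the null (we measured genomic inflation
factors above 10 with the reduced-design variant at $n = 20{,}000$ before
settling on the profile form, which calibrates to $\lambda \approx 1$).
Wald P values are available as a cheaper fallback. Whether the original
analyses used LRT or Wald is not documented; both are exposed and they
agree closely away from separation.

The scan (`gwas_scan`) fits each variant's dosage plus covariates plus any
conditioning dosages, with significance thresholds of $5\times10^{-8}$
(genome-wide) and $1\times10^{-8}$ (exome-wide) recorded in the output.
The whole-genome leave-one-chromosome-out polygenic offset used by
REGENIE-style tools is intentionally out of scope: the per-variant Firth
test with explicit covariates is the statistic of interest here.

## Variant QC, LD and loci

QC gates (MAF ≥ 1%, Hardy–Weinberg exact P ≥ $10^{-6}$, imputation INFO
> 0.6, minor-allele count ≥ 5 in cases and controls, optional
strand-ambiguous removal) report a first-failed-gate reason and never
throw. The HWE exact test enumerates heterozygote counts given the allele
counts (no installed package provides it). LD pruning runs last — it is
order-defined — over sliding windows of 50 variants advanced by 5,
dropping the lower-MAF member of any pair with $r^2 \ge 0.1$, ties broken
by input position.

Pairwise LD uses direct haplotype counting when phase is available and a
two-locus EM (tolerance $10^{-10}$) on unphased hard calls otherwise;
$D' = D/D_{max}$ and $r^2 = D^2/(p_Aq_Ap_Bq_B)$. Genomic inflation is
$\lambda = \mathrm{median}(\chi^2_1)/0.456$, the denominator fixed at the
null median to three decimals (configurable), with a permutation mode that
shuffles case labels under a given seed. Loci are greedily seeded by
ascending P within ±1 Mb (inclusive), and a locus is novel iff no known
catalogue entry lies within ±1 Mb of its lead.

## Rare-variant collapsing and meta-analysis

Eleven qualifying-variant (QV) models ship as a JSON registry transcribing
the published thresholds: consequence class, global and per-ancestry MAF
ceilings, REVEL minimum, and an MTR gate (< 0.78 or centile < 50). Missing
REVEL/MTR **fails** the gate — conservative qualification. All models are
dominant (carrier = qualifying-allele dosage ≥ 1 in the gene) except
`rec` (dosage ≥ 2, counting unphased compound heterozygotes as carriers;
whether the original framework restricts to homozygotes is unstated, and
the dosage-sum rule is the weaker assumption). Set identities forced by
the thresholds (UR ⊆ flexdmg, ptv ⊆ ptv5pcnt, ptvraredmg = ptv ∪ raredmg)
are property-tested on randomized annotation tables whose global MAF is a
weighted mean of the per-ancestry MAFs, the consistency real annotations
have.

Per-gene tests are Fisher's exact two-sided on the carrier × case table;
reported ORs are cross-product ratios with Haldane–Anscombe 0.5
correction on zero cells (deliberately not the conditional MLE that
`fisher.test` estimates, so ORs are comparable across the pipeline).
Cross-cohort gene results combine by Cochran–Mantel–Haenszel: common OR by
the MH estimator with a Robins–Breslow–Greenland interval, chi-square from
the stratum hypergeometric means and variances (continuity correction off
by default), zero-margin strata contributing nothing.

Per-variant summary statistics combine by (i) fixed-effect IVW and (ii)
the sample-size-weighted P-value method, with Cochran's Q for
heterogeneity, and the dual-threshold rule: significant iff **both**
methods clear the stage threshold. Sample-size weights use total n by
default; effective n, $4/(1/n_{cases}+1/n_{controls})$, is a switch, since
published METAL workflows use either. Variants present in one study pass
through tagged `single-study`. Zero P values are clamped to the smallest
representable positive with a logged message.

## Telomere length and polygenic scores

Raw telomere estimates are coverage-normalized by linear residualization
on centered coverage (the least-squares slope), which zeroes the
correlation with coverage by construction; a ratio alternative
(`raw × mean/coverage`) sits behind a flag since "coverage-normalized"
admits either reading. Trimming retains values within mean ± 3 s.d.
computed once on the full input, not iteratively. PRS scoring is the raw
(non-averaged) sum of effect-allele dosage × weight, with allele
flipping when the genotype counts the other allele and missing dosages
imputed as 2 × effect-allele frequency. Validation reports the PRS effect
and both the absolute and the relative incremental $R^2$ over the
covariate-only model — "percentage improvement in $R^2$" is ambiguous
between the two, so both are emitted with the relative figure as the
headline (falling back to absolute, with a notice, when the base model is
empty).

## The synthetic-cohort generator

The generator is first-class, tested code: it is the only way to exercise
the pipeline end-to-end, because the real cohorts are controlled-access.
Its defaults encode the study conditions:

* **Admixture**: per-individual global fractions are Dirichlet(6.6, 3.1,
  0.3) draws — mean 66% Indigenous American / 31% European / 3% African.
  Each haplotype is a window-wise Markov mosaic: the first window is drawn
  from the individual's fractions and each subsequent window resamples
  with probability `switch_rate` (default 0.1), the simplest stationary
  process consistent with admixture LD. The window count defaults to 400
  equal-length windows of 100 kb — desk-scale rather than the ~40,000
  intervals of a production local-ancestry run.
* **Covariates**: age uniform on [35, 90] (the recruited adult range, with
  the sparse extreme-age tail omitted); sex Bernoulli(0.5), used only as a
  covariate; ever-smoking logistic in the European fraction
  (intercept −1.0, slope 0.8), split evenly into previous/current.
* **CH risk**: two logistic components — DNMT3A-CH and non-DNMT3A-CH —
  sharing covariate coefficients (per year of age 0.08, per unit European
  fraction 0.84, ever-smoking 0.35, per s.d. of telomere length 0.15) with
  intercepts offset by log of the DNMT3A gene weight, so germline variants
  can push the two components in opposite directions, the structure behind
  ancestry-specific variants with opposing effects on DNMT3A- versus
  non-DNMT3A-CH. The shared intercept (−9.6) puts marginal prevalence near
  3%, the admixed-cohort figure; at low prevalence the union of the two
  components is itself logistic with the shared coefficients, which is
  what makes the recovery tests well-posed.
* **Genotypes**: each allele is drawn with the frequency of the local
  ancestry of the overlying window; the default panel contains a
  EUR-enriched rare missense variant (EUR 1.62%, AMR 0.06%) with opposing
  CH effects, a common risk variant (MAF ~23%, log-OR 0.27 — the scale of
  the strongest known common CH signal), and two telomere-effect variants.
* **Telomere length**: intercept 3.9 kb, −0.02 kb per year, additive
  variant effects, Gaussian noise s.d. 0.5 kb.
* **Somatic calls**: every CH-positive individual gets one qualifying call
  per positive component (gene from the configured weights, VAF uniform on
  [0.03, 0.40], depth Poisson around the 57× cohort coverage, alternate
  reads rounded and kept inside the gates); a configurable decoy fraction
  injects records that each violate exactly one gate. The uniform VAF is a
  stand-in — the empirical VAF distribution is not published beyond its
  bounds.
* **Seeding**: each component (covariates, mosaic, genotypes, LTL, CH,
  somatic) derives its own stream from the master seed, so components can
  be regenerated independently and identical configs are byte-identical.

What the generator does **not** emulate: read-level error, phasing error,
relatedness, demography beyond the Dirichlet, age-structured recruitment,
and clonal dynamics. Passing tests therefore certify the statistical
engines and their calibration, not robustness to those real-data
complications.

## Problem sizes and numerical choices

The test suite runs the null calibration at 2,000 variants × 20,000
individuals (inflation factor required in [0.9, 1.1], KS uniformity P >
0.01), the power check at n = 60,000 with a log-OR 0.27 variant at MAF
23% over 10 replicates, and coefficient recovery at n = 50,000 over 50
replicates with 20 ancestry windows — sizes chosen so each property is
measured at the scale it claims while the whole suite stays desk-scale.
Other conventions: positions are 1-based (VCF) throughout association
code, mosaic intervals 0-based half-open (BED/MSP); dosages are hard calls
in {0,1,2} unless imputed dosages are supplied; monomorphic variants are
flagged untestable rather than dropped silently.

## Known limitations

The Firth engine is plain R (no compiled path): ~30 ms per variant at
n = 20,000 with two covariates, ample for panel-scale scans and the test
suite, but a genome-wide production scan would want the score-test
prefilter strategy of dedicated tools. The EM LD estimator assumes two
alleles and hard calls. The collapsing engine implements the
carrier-count test only — no kernel or weighted-burden variants. The
matching is greedy, not optimal, which is standard but can leave a few
unmatched individuals in sparse strata.
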