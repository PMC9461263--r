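---
title: "Methods: ancestry-aware biobank analysis with giabank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-aware biobank analysis with giabank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`giabank` implements the analytical chain an EHR-linked biobank needs
before and during ancestry-aware association analysis.  This vignette is
the package's own account of the models, the parameters that matter, the
numerical choices, and the limits of what the synthetic-data tests can
show.

## The synthetic cohort generator

Every stage is exercised on data from the `synthdata` functions, so the
statistical assumptions of the generator define what the test suite can
and cannot demonstrate.

**Population model.** K ancestral populations diverge from a shared
ancestral frequency spectrum under the Balding–Nichols construction:
per-population frequencies are Beta(p(1−F)/F, (1−p)(1−F)/F), so each
population's frequencies are centred on the ancestral value p with
spread governed by the divergence parameter F (an Fst-like quantity).
This is precisely the exchangeable-drift model that genotype PCA and
admixture estimation assume, which is the point: recovery tests measure
the estimators under their own model, not robustness to model violation.
Ancestral frequencies are drawn uniformly on (0.05, 0.95) so variants
stay informative; the unit tests cross-check realized divergence against
an independent Hudson-style Fst estimator.

**Cohorts.** Individual admixture proportions are Dirichlet draws per
labelled group; genotypes are Binomial(2, Σₖ q_ik f_kj).  Self-identified
race/ethnicity (SIRE) is attached per group and flipped to another
group's label with probability `label_noise_rate`, emulating the
imperfect correlation between social identity and genetic ancestry; the
default cohorts use 0.05.  Ages are uniform on [18, 90] (a covariate with
variance, nothing more is claimed), sex is binary Male/Female because
every downstream model codes sex as one binary covariate.

**Phenotypes.** Case status per (person, phecode) follows
`logit P(case) = β₀ + β₁[group] + β₂·I(Female) + β₃·age_std (+ Σ β_snp·g)`.
Cases receive one guaranteed ICD-coded encounter plus a Poisson number of
extras, spread over visit-like (appointment/office/hospital/procedure)
and message-like encounter types; controls receive none for that
phecode.  This makes case construction exact by design — what the
phenotype tests verify is the counting and thresholding machinery, not
robustness to miscoding.

**IBD.** Pairs inside a planted community share Poisson(within_rate)
segments, across communities Poisson(between_rate), with exponential
lengths (mean 10 cM, floored at 1 cM).  Segment *detection* is out of
scope; the package consumes segment tables.

**What the generator does not emulate.** Linkage disequilibrium (variants
are independent given ancestry), haplotype phase, recombination maps,
realistic billing sequences, and ICD rollup edge cases.  Passing tests
therefore demonstrate correctness of the algorithms under their stated
models and exact reproduction of rule arithmetic — not performance on
real array data.

## Genotype QC

Filters follow standard array practice: strand-ambiguous (A/T, C/G)
variants are dropped because their orientation cannot be reconciled
across platforms; missingness thresholds are strict inequalities (a
variant at exactly 5% missing survives a 5% filter); MAF filters read
"MAF > x" as keep-at-x.  Every filter returns a report whose removed and
retained counts reconcile exactly with the matrix dimensions, and every
filter is idempotent.

Kinship uses the KING-robust between-family estimator,
φ̂ = (N_Aa,Aa − 2 N_AA,aa)/(N_Aa⁽ⁱ⁾ + N_Aa⁽ʲ⁾) over co-observed variants:
heterozygote concordance makes it robust to population structure, and a
verbatim duplicate gives exactly 0.5.  An allele-frequency GRM backend is
provided for comparison; it is biased under structure and small samples.
Duplicate groups are resolved transitively and the sample with the
*lowest* missing rate is kept — the conventional choice; the
`drop_policy` argument reproduces the opposite reading for exact
compatibility with descriptions that state it the other way around.  The
unrelated set is built by greedily deleting the highest-degree node of
the φ ≥ 0.0884 conflict graph (ties broken by id order); this guarantees
the pairwise constraint, approximates the maximum independent set well at
biobank-typical sparsity, and is deterministic.

LD pruning implements both classic variants: pairwise r² in sliding
windows (window 100, step 5, r² > 0.1 removes the later variant of the
pair — the tie-break is part of the contract and is shared with the
brute-force oracle in the tests) and variance-inflation-factor pruning
(window 200, step 5, VIF > 1.15), where VIF comes from the inverse
window correlation matrix with a 1e-8 ridge when singular (exact copies
then show enormous finite VIFs and are removed first).  r² is computed on
mean-imputed dosages.  Physical spacing pruning keeps variants ≥ 2 kb
apart greedily left-to-right.  Mendel-error filtering is a documented
no-op without a pedigree: the synthetic cohorts are founders-only.

## GIA assignment

PCA standardizes each variant by the *joint* (study + panel) allele
frequency because the coordinate system is shared; the top components
come from one SVD of the standardized matrix.  "Cluster membership" is
operationalized as the KNN neighbour-vote fraction — the natural
quantitative reading of membership when the classifier is KNN.  k is
selected per ancestry by 10-fold cross-validation on the panel
(stratified folds so every class keeps at least k training members), with
ties toward smaller k for a smoother, deterministic boundary.  PC pairs
per ancestry are configuration, not hard-code: which components separate
an admixed group depends on the panel's variance ordering, so defaults
(PCs 1–2) are overridable per label.  The continental rule — assigned iff
exactly one membership > 0.50, Ambiguous otherwise — is monotone in the
threshold (the tests assert the Ambiguous count never drops as the
threshold rises), and the subcontinental rule uses one classifier on PCs
1–4 with the stricter > 0.90 cut; SIRE-based labelling drops classes with
≤ 20 members because vote fractions over tiny classes are noise.

## Admixture estimation

The binomial-mixture log-likelihood is maximized by EM block updates of Q
and F.  Plain EM is provably monotone but crawls near the simplex
boundary, so each iteration is SQUAREM-accelerated: two EM steps, an
extrapolation along the observed trajectory, one stabilizing EM step, and
a fallback to the unaccelerated double step whenever the extrapolated
point does not improve the log-likelihood.  The recorded trace is
therefore non-decreasing by construction while convergence is typically
an order of magnitude faster.  Parameters are clamped to [1e-9, 1−1e-9]
to keep the likelihood finite; missing dosages simply contribute nothing.
Restarts (default 5) run a short burn-in (default 30 cycles) and the best
likelihood is continued to convergence (gain < `tol`, default 1e-6,
capped at `max_iter` 2000 cycles with a warning rather than an error,
since a near-converged Q is still useful).  Q is identifiable only up to
component permutation; `match_components()` aligns against a reference by
exhaustive search over the K! permutations (fine for K ≤ 8), and all
recovery statements in tests are post-alignment.  Component labels come
from SIRE majorities applied as ordered priority rules on components not
yet labelled, with exact ties withheld with a warning rather than broken
arbitrarily.

## IBD networks

Edge weights are total genome-wide shared cM per pair; totals conserve
segment mass exactly.  Relatives at φ ≥ 0.0442 (third degree or closer)
are removed before community detection because family structure otherwise
dominates fine-scale population structure.  Communities come from
igraph's InfoMap (map-equation flow) implementation, seeded through R's
RNG for determinism.  The reporting view excludes communities with ≤ 100
members and nodes below degree 30; because published descriptions of
this rule disagree on whether degree exactly 30 stays, the comparator is
configuration (`>=` by default, `>` available) and the degree is computed
on the post-filter graph.

## Phecodes

An occurrence is a *distinct encounter* carrying ≥ 1 mapped ICD code —
two codes of the same phecode on one encounter count once, the same code
on three encounters counts three times.  Distinct encounter ids (not
distinct dates) define distinctness; dates are not reliably unique per
clinical event in EHR extracts.  The visit scope restricts to
appointment/office/hospital/procedure encounters.  With a minimum
occurrence requirement above 1, persons with intermediate counts are
*excluded* rather than treated as controls — the conservative convention,
since a person with one coded encounter is a poor control for that
phenotype; `partial = "control"` restores the permissive reading.
Case-retention curves and per-group testability filters use strict
inequalities throughout ("N-case > 50" drops a group at exactly 50).

## Association machinery

All models are plain logistic regressions fit by IRLS (`glm.fit`, max 100
iterations, tolerance 1e-8).  Complete separation is detected as any
|β̂| > 20 and, like non-convergence, flags the fit and withholds p-values
instead of reporting nonsense; per-cell failures inside scans are
recorded as missing-p rows and the scan continues, mirroring how
large-scale scans behave in practice.  Sex enters as an I(Female)
covariate; for sex-specific phecodes the fit is restricted to the
matching sex and the now-constant covariate is dropped.  SIRE adjustment
uses a categorical factor with the largest group as reference (reference
choice does not move the GIA coefficient's p-value).  The GIA scan is
one-vs-rest per group over all *assigned* individuals — Ambiguous samples
are excluded from "rest" by default (`include_ambiguous` reverses this),
since an unassignable sample is not evidence about any group contrast.
GWAS applies in-group QC (heterozygosity ± 3 SD with the SD = 0 convention
of flagging nobody, HWE p < 1e-12, in-group MAF > 1%) and uses age, sex
and within-group PCs as covariates.  Meta-analysis is fixed-effects
inverse-variance on the log-odds scale, reported only where ≥ 2 groups
contribute.  PheWAS reports both 0.05/#phecodes and 5e-8/#phecodes.
λ-GC is the median of the χ²₁ quantiles of the p-values divided by
0.4549; N_eff = 2/(1/N_cases + 1/N_controls) (the harmonic form — equal
arms give back the per-arm count).

## Problem sizes and determinism

The test and acceptance simulations are sized for a single CPU: GIA
recovery uses a 5-population panel (Fst 0.1, 200 training + 40 held-out
samples per population, 1500 variants) with a 1000-sample admixed study
cohort; admixture recovery uses Fst 0.15 with 2000 variants and 200–400
samples; the null GWAS uses 4000 variants so the median-based λ-GC has
sampling error well inside its acceptance band; the planted-variant GWAS
uses 4000 individuals.  Every random draw flows from an explicit seed and
the pipeline writes byte-identical stage outputs when re-run with the
same configuration and seed.

## Known limitations

No imputation or phasing (upstream services in practice); no IBD segment
detection; no mixed-model or saddlepoint association tests (planted
effects are large enough that plain logistic regression is appropriate);
the X chromosome is not simulated, so sex-check QC is out of scope; and
none of the recovery results transfer claims to real array data beyond
the correctness of the algorithms themselves.
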