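---
title: "Dysbiosis indices and SBP risk modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dysbiosis indices and SBP risk modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpmi)
```

## The model

Spontaneous bacterial peritonitis (SBP) in cirrhosis arises largely from
translocation of gut organisms across an impaired intestinal barrier.
Genus-level 16S profiles of affected patients show a reproducible
signature: expansion of pathobionts (*Escherichia–Shigella*,
*Klebsiella*, *Streptococcus*, *Veillonella*) and depletion of
short-chain-fatty-acid (SCFA) producers (*Prevotella*, *Roseburia*,
*Faecalibacterium*, *Bacteroides*). The SBP microbiota-derived index
condenses this signature into one number per sample,

$$\mathrm{SBP\text{-}MI} = \log_{10}
\frac{\sum_{g \in \mathrm{pathobionts}} (x_g + \varepsilon)}
     {\sum_{g \in \mathrm{SCFA\ producers}} (x_g + \varepsilon)},$$

with $x_g$ the relative abundance on the proportion scale and a
per-genus pseudocount $\varepsilon = 10^{-6}$ added to every term so the
ratio stays finite when genera are absent. Because indices are computed
on proportions, $\varepsilon$ is negligible against typical genus
abundances ($10^{-3}$–$10^{-1}$) and matters only for zeros; the same
index computed on percent-scale input would let the pseudocount distort
scores, which is why `normalize_abundance()` closes rows to 1 first.
The log-ratio form makes the index antisymmetric (swapping numerator and
denominator negates it) and subcompositionally coherent in the sense
that only the named genera enter.

The companion HBCDI is a prior index for HBV-related cirrhosis, the raw
ratio (Escherichia–Shigella + Streptococcus + Lactobacillus) /
(Ruminococcus + Prevotella + Bacteroides) — no log, no pseudocount. A
zero denominator therefore yields a flagged `NA` rather than an error or
a silent guard; an optional per-genus pseudocount can be switched on
where undefined values are unacceptable. Whether a log transform should
be applied to HBCDI when it enters regression models is not settled; the
default here is the raw ratio, and `index_definition()` lets users build
either variant (or any other ratio index, e.g. a cirrhosis dysbiosis
ratio with user-supplied genus sets).

Longitudinal change is summarized per subject as
$\Delta = \mathrm{score}_{\mathrm{follow‑up}} -
\mathrm{score}_{\mathrm{baseline}}$; rising SBP-MI means worsening
dysbiosis.

## Taxon-name resolution

Genus tables mix naming conventions (en dash vs hyphen in
*Escherichia–Shigella*; SILVA sublineages such as *Prevotella_9*). The
package canonicalizes names with an explicit alias map.  Typographic
variants are always folded.  Sublineage folding is a substantive choice
— a formula genus might mean one sublineage or the summed complex — so
it happens only under `policy = "sum_sublineages"`, where matching
columns are summed (mass is conserved exactly). Under `strict`,
unresolved formula genera are reported absent and enter the index as
zeros (the pseudocount then applies), which is statistically what an
absent column means in a genus table. Every applied mapping is recorded
in the result's resolution report.

## The risk model and its validation

With few events, ordinary maximum-likelihood logistic regression is
biased away from zero and diverges under separation. The package
implements Firth's penalized likelihood,
$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det I(\beta)$, whose score
is the modified score
$U^*(\beta) = \sum_i \{y_i - \pi_i + h_i(\tfrac12 - \pi_i)\}x_i$ with
hat values $h_i$ recomputed each iteration from a QR decomposition of
the weighted design (no approximation; the cohorts involved are small).
Newton steps use the Fisher information with step-halving whenever the
penalized likelihood would decrease.

Two numerical safeguards matter in practice. First, the Fisher
information is not the exact Hessian of $\ell^*$, so pure scoring
iterations converge only linearly near the optimum and can cycle just
above a tight tolerance; since $U^*$ *is* the exact gradient of
$\ell^*$, the engine finishes with a BFGS polish using that gradient
whenever scoring stalls, and reports convergence only when
$\max|U^*| < 10^{-8}$ and the last coefficient change is below the same
tolerance. Second, early Newton steps are capped at length 5 in
coefficient space and an exactly singular weighted information (possible
in degenerate bootstrap resamples) falls back to a tiny ridge, so the
engine never leaves the region where the penalized likelihood is
computable.

Inference defaults are internally consistent: p-values from penalized
likelihood-ratio tests (each coefficient constrained to zero, the others
re-maximized, the penalty always evaluated on the full design) and
confidence intervals from the profile penalized likelihood, found by
root bisection between the estimate and an outward-widening bracket (up
to 40 standard errors; beyond that a labelled Wald interval is
substituted with a warning). Wald versions of both are available and are
used inside bootstrap resamples, where only discrimination is measured
and the cheaper intervals change nothing. Covariates are not
standardized before fitting; the engine's estimates are exactly
equivariant under rescaling, so standardization is presentation, not
inference.

Univariable screening fits each candidate alone with the same Firth
engine (consistent with the rare-event rationale that motivates the
penalty in the first place) and keeps candidates with two-sided
$P < 0.10$ in input order.

Validation follows the usual internal-validation canon with fixed
conventions:

* **ROC/AUC** — empirical curve over observed score values under the
  convention *score ≥ cutoff ⇒ predicted positive*; AUC is the
  tie-corrected Mann–Whitney statistic (identical to the trapezoidal
  area); DeLong placement-value intervals by default.
* **Youden cutoff** — maximizes sensitivity + specificity − 1; ties
  break toward the smallest cutoff value.
* **Calibration** — slope and intercept from one logistic recalibration
  of outcomes on the logit of predicted risk; Brier score; and the
  Hosmer–Lemeshow decile statistic
  $\sum_g (O_g-E_g)^2 / (E_g(1 - E_g/n_g))$ on groups − 2 df.  The
  groups − 2 reference presumes estimated probabilities, so null
  simulations that check its size must refit a model rather than feed
  true probabilities.  With fewer distinct risk values than groups, the
  grouping collapses to unique values (df floor of 1); predictions of
  exactly 0 or 1 are clamped to $[10^{-12}, 1-10^{-12}]$ with a warning.
* **Optimism correction** — Harrell's bootstrap: the *entire* recipe,
  univariable screen included, is re-run inside every resample, because
  validating only the final model understates optimism; a flag-frozen
  variable set is available through `firth_recipe()`. Resamples with one
  outcome class are redrawn and counted. The corrected AUC is exactly
  apparent − mean(optimism).

Group-level evaluation of indices uses Kruskal–Wallis plus pairwise
Wilcoxon tests with Benjamini–Hochberg adjustment (the multiplicity
procedure is a package choice; BH is standard and less conservative than
Bonferroni), the Jonckheere–Terpstra test for ordered disease-stage
trends (the canonical rank test against an ordered alternative;
tie-corrected normal approximation, exact enumeration when total
n ≤ 12), and Spearman correlation with a Fisher-z interval
($\operatorname{atanh}\rho \pm z_{0.975}/\sqrt{n-3}$) for severity
associations.

The published risk equation ships as an immutable `sbp_rp_equation()`
with its printed coefficients; refitting always produces a new, labelled
equation. The published operating cutoff is interpreted as a threshold
on predicted *probability* (not on the linear predictor) — the natural
scale for a nomogram-accompanied model, recorded here as an interpretive
choice. Nomogram axes use the standard construction: each covariate's
contribution is shifted to zero at its minimal-contribution range
endpoint and scaled so the covariate with the largest |β| × range spans
0–100 points; total points invert exactly to predicted probability.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
patient data. It emulates the *structure* the analysis assumes, not the
measured magnitudes of any real cohort:

* **Compositions** — one Dirichlet draw per sample from a per-group
  concentration vector over a 15-genus panel (the formula genera, the
  longitudinally implicated genera, and a `Remainder` pseudo-genus
  absorbing residual mass — the smallest panel covering every named
  genus). Default concentrations are directional: pathobiont means rise
  and SCFA-producer means fall monotonically along
  HC → CC → NSBP → SBP, mirroring the staged case-control design
  (n = 40/30/40/25). Only the direction is claimed, because published
  figures constrain ordering, not magnitudes; the per-group totals are
  fixed at 20, a one-time choice giving between-subject variability
  typical of genus-level gut profiles. The Dirichlet cannot reproduce
  the heavy zero-inflation or genus-genus correlation of real 16S data,
  so passing tests demonstrate correct *mechanics* (closure, monotone
  index response, recoverable effects), not realism of any particular
  abundance value.
* **Clinical covariates** — per-group normals for INR and MELD
  truncated at physiologic floors (0.8 and 6) by rejection sampling
  (which preserves the bulk of the distribution, unlike clipping);
  Bernoulli previous-SBP history. Defaults follow the staged pattern of
  the case-control description (e.g. history prevalence 0.2 in the SBP
  group, i.e. 5 of 25); the prospective arm uses INR 1.5 ± 0.35,
  MELD 13 ± 4, history 0.15.
* **Outcomes** — Bernoulli draws from the logistic model defined by the
  shipped risk equation applied to each sample's computed SBP-MI, INR
  and history, with the true probability retained for calibration
  checks.
* **Paired follow-up** — 40 subjects split exactly 32 improved / 8
  progression; each follow-up composition is the renormalized product of
  the subject's baseline with arm-specific per-genus drift factors
  (improved: pathobionts down, SCFA producers up; progression:
  *Klebsiella* and *Haemophilus* up, beneficial commensals down). Drift
  is deterministic given the baseline, so within-pair change is driven
  entirely by the configured direction — convenient for oracle tests,
  but a simplification of real longitudinal noise.
* **Seeds** — one root seed; each stage (compositions, clinical,
  outcomes, pairs, bootstrap) draws from a deterministically derived
  child stream, so regenerating one stage never perturbs another and a
  fixed seed reproduces a cohort byte for byte.

`simulate_equation_cohort()` bypasses the compositional generator and
draws the three model covariates directly from stated marginals
(SBP-MI ~ N(−0.5, 1), INR ~ N(1.6, 0.4) truncated at 0.8,
history ~ Bernoulli(0.15)); it is the parameter-recovery benchmark used
by `scripts/acceptance.R`.

## Problem sizes and tolerances

Index arithmetic is tested to $10^{-9}$ against direct per-genus
pseudocount arithmetic; both index genus sets have four members, so a
sample with one nonzero genus per side scores
$\log_{10}((x_{\mathrm{num}}+4\varepsilon)/(x_{\mathrm{den}}+4\varepsilon))$.
The Firth engine is tested against the closed-form equivalence for a
single binary covariate (Firth = adding ½ to each cell of the 2×2
table) to $10^{-6}$, including zero cells and zero margins; profile
intervals are checked for near-nominal coverage over 400 simulations at
n = 150. Parameter recovery uses one simulated cohort of n = 20,000 —
large enough that relative errors are a few percent, small enough to fit
in seconds. Distributional checks (type-I error of the omnibus and
trend tests, null AUC, HL size) use 200–1000 replicates at n in the
hundreds-to-thousands; calibration self-consistency uses n = 10⁵. These
sizes were chosen to make sampling noise comfortably smaller than the
asserted bands while keeping the whole suite fast.

One caution on single-draw recovery bands: at n = 20,000 the relative
standard error of the binary-history coefficient is about 4%, so any
fixed few-percent band on a single simulated cohort will fail for an
appreciable fraction of seeds by noise alone even though the estimator
is unbiased — the consistency and bias properties are therefore also
tested directly.

## Known limitations

* The Dirichlet generator has no zero inflation, no genus correlation
  structure, and no sequencing-depth noise; it validates pipeline
  mechanics, not ecological realism.
* HBCDI's undefined-value behaviour under a zero denominator follows the
  raw published formula; users with sparse tables should enable the
  pseudocount guard or resolve sublineages first.
* Profile likelihood intervals assume a unimodal penalized likelihood;
  in pathological designs the bracket search falls back to Wald with a
  warning rather than failing.
* The nomogram is a points table (plus an exact inverse map), not a
  rendered graphic.
* CDR-style indices are supported only through user-supplied genus sets,
  since the package ships no authoritative taxon list for them.
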