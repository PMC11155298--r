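---
title: "Benchmark-dose modeling of expression and splicing dose-responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-dose modeling of expression and splicing dose-responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmdsplice)
```

## The problem

Toxicogenomic risk assessment increasingly derives a *point of departure*
(POD) — the dose at which a chemical first perturbs biology — from
dose-response transcriptomics rather than from apical endpoints. The
standard route models each gene's expression across a concentration series,
extracts a *benchmark dose* (BMD, with lower/upper confidence bounds BMDL
and BMDU) per gene, and aggregates genes into pathway-level BMDs whose most
sensitive members define the POD. Alternative splicing — in particular
intron retention (IR) — can shift at doses where total gene expression is
still flat, so the same machinery applied to intron-level read counts can
expose earlier perturbations. `bmdsplice` implements this whole chain for a
single-chemical in vitro design (a half-log concentration series plus
vehicle control, typically 8–9 positive doses with 4 biological
replicates), together with a seeded synthetic-data generator so that every
stage is testable without external data.

## Dose-response models and fitting

Responses are normalized `log2(count + 1)` values (per-sample
median-aligned). Each feature is fitted with a suite of continuous models
of dose $d$ (µM, natural scale):

| family | mean function | mean parameters |
|---|---|---|
| linear  | $b_0 + b_1 d$ | 2 |
| poly2   | $b_0 + b_1 d + b_2 d^2$ | 3 |
| poly3   | $b_0 + \dots + b_3 d^3$ | 4 |
| power   | $a + b\,(d/d_{\max})^p$, $p \ge 1$ | 3 |
| hill    | $v_0 + v\, d^n / (k^n + d^n)$, $n \ge 1$ | 4 |
| exp3    | $a + b\,(1 - e^{-d/c})$ | 3 |

All models assume a *constant variance*: a normal likelihood with one
residual SD $\sigma$ shared across dose groups, profiled out exactly
($\hat\sigma^2 = \mathrm{RSS}/n$), so fitting is residual-sum-of-squares
minimization. Polynomials are solved exactly by weighted least squares on
dose-group means; the nonlinear families use seeded multi-start bounded
optimization (default 10 starts: one heuristic, the rest uniform in the
parameter box, with the Hill $k$ and exp3 $c$ handled on the log scale).
Group-level sufficient statistics make each RSS evaluation $O(\#\text{dose
groups})$, which is what keeps batch runs and profile intervals cheap. The
exp3 parameterization above is this package's choice of a three-parameter
exponential; results are always labeled by family so the substitution is
transparent.

The power exponent is bounded below by 1 by default (avoiding an infinite
slope at dose 0); `power_lower = 0` relaxes this. The Hill coefficient is
likewise bounded at 1 by default.

## Model selection

Selection follows the conventional two-stage recipe:

1. **Polynomial ladder.** Linear → quadratic → cubic, preferring the higher
   adjacent degree only when the nested likelihood-ratio chi-square
   (df = 1, profiled-$\sigma$ statistic $n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$)
   has $p < 0.05$; the climb stops at the first non-significant step.
2. **AIC.** The winning polynomial is compared with the converged nonlinear
   fits by lowest AIC, where $\mathrm{AIC} = 2k - 2\ell$ and $k$ counts the
   mean parameters plus one variance parameter.

A Hill winner whose half-max dose $k$ falls below one third of the lowest
positive tested dose is *flagged*: its shape is then determined by the
extrapolation region below the data. The selector falls back to the
lowest-AIC unflagged model whose goodness-of-fit $p$ exceeds 0.05, keeping
the flagged Hill (with `hill_flagged = TRUE`) only when nothing qualifies.

Goodness of fit is a likelihood-ratio test of the selected model against
the saturated model (one mean per dose group, common $\sigma$), with
df = #groups − #mean parameters; non-positive df gives $p = 1$.

## Benchmark dose, profile bounds, rejection filters

The benchmark response (BMR) is **one residual SD**: the BMD is the
smallest positive dose at which the fitted curve departs from its control
value by $\hat\sigma$, located by log-grid bracketing and root refinement
(~1e-8 relative). The adverse direction is the sign of
$f(d_{\max}) - f(0)$.

BMDL/BMDU come from the profile likelihood: the BMD is made an explicit
parameter by tying $\sigma$ to the benchmark-response constraint
$\sigma = |f(b) - f(0)|$ and maximizing the likelihood over the remaining
mean parameters at each candidate $b$. Each bound is the dose where twice
the profile drop reaches the $\chi^2_1$ quantile at $2\cdot0.95-1 = 0.90$ —
one-sided 95% per bound, the EPA/BMDS convention. Search expands
geometrically from the BMD and closes by bisection inside
$(0, 10\,d_{\max}]$; a side that fails to close is reported `NA` and the
BMDU/BMDL ratio is treated as infinite downstream.

A numerical consequence worth knowing: because the BMR is the *estimated*
$\sigma$, whose relative uncertainty $\sim 1/\sqrt{2n}$ never vanishes, the
BMDU/BMDL ratio does not shrink to 1 on noiseless data — it settles at a
design-dependent floor (about 1.32 for 9 doses × 4 replicates and a local
dose-power of 1.5). The test suite asserts this floor analytically rather
than pretending the interval collapses.

Three rejection filters are applied in order, each failure labeled with the
first rule hit: (1) *range* — the BMD must lie within the tested positive
dose range; (2) *fit* — goodness-of-fit $p \ge 0.1$; (3) *ratio* —
BMDU/BMDL $\le 40$. "Lowest concentration" is read as the lowest positive
tested dose.

## Differential expression and prefiltering

Per-dose differential expression is a Welch t-test of each feature against
the vehicle control on the normalized log2 values, with Benjamini-Hochberg
correction across features within the contrast; a DEG requires
FDR < 0.05 **and** linear fold change > 1.5. This stage is a deliberately
self-contained stand-in for a negative-binomial GLM: the package's
contribution lies downstream of DE, and a distribution-honest two-sample
test keeps the pipeline free of heavy dependencies while preserving the
thresholds' meaning.

Features enter BMD modeling only after the ANOVA prefilter: one-way
fixed-effects ANOVA across dose groups ($p \le 0.05$) plus a maximal
absolute fold change of any positive dose versus control of at least 1.5
(computed on group means in log2 space). Degenerate zero-within-variance
features take $p = 0$ when any group mean differs and $p = 1$ otherwise —
a documented convention, not an inference.

The low-count filter removes features with fewer than 10 summed counts
across all samples of the chemical before anything else.

## Differential splicing

Percent-spliced-in is $\Psi = 100\,I/(I+E)$ per sample from inclusion and
exclusion junction reads, reported only at coverage $I+E \ge 10$ (the
threshold is configurable; the source pipeline's default is not published).
For a treated-versus-control contrast:

* the **point estimate** `dpsi_point` is the difference of group means of
  per-replicate PSI (covered replicates only);
* the **confidence rule** pools each group's reads into a
  $\mathrm{Beta}(\sum I + 1, \sum E + 1)$ posterior, draws paired samples
  of the PSI difference, and demands that the central **95%** credible
  interval exclude zero. `mv_dpsi_95` is the interval endpoint nearer zero
  when the interval excludes zero, else 0.

An event is significant when $|\mathrm{dPSI}| > 5$ percentage points and
`mv_dpsi_95 > 0`. Two design notes: pooling replicate reads under a
Beta(1, 1) prior is a simple conjugate stand-in for the replicate-weighted
posterior of junction-quantification tools, whose exact weighting is not
fully published; and the credible level is 95% *central* (two-sided).
A 90% central interval (one-sided 95% per tail) was considered and
rejected: at typical coverage the point criterion and the interval
criterion are nearly the same event, so a 90% interval would let ~10% of
truly null events through, twice the rate the pipeline's own calibration
checks demand; the two-sided 95% reading also matches the stated "95%
confidence interval" rule. The calibration test (1000 null events at depth
100, 4 vs 4) verifies the false-call rate stays at or below 5%, with ≥95%
power on planted 30-point shifts at depth 200.

Posterior draws are generated from uniform streams keyed to the sample-id
sets rather than to the control/treated roles, so swapping the group labels
negates `dpsi_point` and the draws *exactly* and preserves `mv_dpsi_95`
under the same seed.

## Pathways and the point of departure

Feature-level passing BMDs are aggregated to genes by the median (identity
for one-feature genes; intron features map to their host gene). For each
gene set, a two-tailed Fisher exact test compares the query (genes with
passing BMDs) against the background universe — by default all genes that
entered BMD analysis for that chemical and modality, the choice that makes
the test answer "are perturbed genes concentrated in this set given what
was measurable", rather than inheriting the annotation file's universe.
A pathway is significant at raw $p < 0.05$ with at least 5 query genes;
a BH-adjusted column is emitted alongside for readers who prefer it.
Pathway BMD/BMDL/BMDU are the medians over the query genes in the set
(means are also attached, since modality-comparison displays conventionally
use them).

The POD ranks significant pathways by ascending median BMD ("most
sensitive") and takes the mean of their median BMDLs over the 20 lowest;
with fewer than 20 significant pathways it falls back to the median BMDL
over all of them. Because sensitivity is ranked by BMD while the average is
taken over BMDL, the top-20 mean is not *provably* below the all-pathway
mean, but it holds on every synthetic fixture tested and is reported
alongside both the top-20 and all-pathway means so nothing is hidden.

## The synthetic generator: what it does and does not emulate

The generator states a world matching the target experimental design:
8–9 half-log-spaced concentrations plus vehicle control, 4 replicates,
negative binomial counts (dispersion 0.05 — mid-range for bulk RNA-seq)
whose log2 means follow known curves with residual SD 0.25 log2 units, and
Poisson read totals split binomially at the trajectory PSI (depths 100–200,
typical junction coverage). Each simulated feature records its generating
curve and the implied *true BMD* — the dose where the noiseless mean curve
departs one generating SD from control, solved to 1e-9 relative by a root
finder independent of the fitting engine. Doses are stored unrounded;
3-significant-figure rounding is display-only.

It deliberately does **not** emulate: read-level artifacts (no FASTQ or
alignment), batch effects, library-size trends beyond optional log-normal
factors, cytotoxicity-driven RNA degradation at high doses, or correlation
between genes. A green recovery test therefore establishes that the
modeling chain is correct and calibrated *under its own assumptions* — not
that those assumptions hold for any particular real experiment.

## Worked example

```{r example, eval = FALSE}
design <- build_design(1000, 9, 4, "diazinon")
truths <- dplyr::bind_rows(
  random_hill_truths(60, 1000, k_range = c(150, 600), seed = 2),
  null_feature_truths(240, 1000, seed = 3)
)
counts <- simulate_counts(design, truths, seed = 4)
norm <- normalize_matrix(filter_low_counts(counts))
pre <- anova_prefilter(norm, design)
bmds <- run_bmd(norm[norm$feature_id %in% pre$feature_id[pre$passes], ],
                design)
dplyr::count(bmds, filter_status)
```

## Numerical choices, in one place

* Optimizer: `nlminb`, relative tolerance 1e-12, 10 seeded starts for the
  nonlinear families; convergence failure excludes a family from selection.
* RSS floor `n * 1e-24` in the log-likelihood so exact and
  numerically-zero interpolations share one degenerate value; `sigma_hat`
  itself is reported unfloored.
* BMD root: 500-point log grid bracketing plus `uniroot` at
  `1e-12 * max dose` absolute tolerance; smallest crossing wins.
* Profile search: geometric expansion by factors of 2, log-scale bisection
  to 1e-5; lower side abandoned below `1e-6 * BMD`, upper side above
  `10 * max dose`.
* AIC ties broken toward fewer parameters.
* BH ties follow the standard step-up procedure.
* Degenerate ANOVA/Welch variances: $p \in \{0, 1\}$ by the mean-difference
  convention above.

## Known limitations

* No exp4/exp5 exponential variants and no model averaging; the suite
  covers the families the selection procedure actually discriminates at
  in vitro sample sizes.
* Non-constant variance models are out of scope (the data are log2
  transformed precisely to stabilize variance).
* The DEG stage is a Welch-test stand-in, not a count-model GLM; absolute
  DEG counts on real data will differ from count-model pipelines even
  though thresholds match.
* Splicing inference pools replicates within group; replicate-level
  biological variability beyond binomial sampling widens real posteriors
  more than these.
* Pathway enrichment treats gene sets as flat lists: no ontology-graph
  propagation.
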