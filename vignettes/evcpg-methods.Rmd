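---
title: "Methods: equivalence-based discovery of equivalently variable CpGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equivalence-based discovery of equivalently variable CpGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNA methylation at most CpG sites is either nearly constant across healthy
individuals or driven by genetics, cell composition, or age. A small set of
sites instead acquires its methylation level stochastically in early
development and then maintains it: at such sites two monozygotic (MZ)
co-twins differ as much as two strangers. Isolating these *equivalently
variable CpGs* (evCpGs) requires showing that the co-twin and unrelated-pair
difference distributions are statistically **equivalent** — a claim a
standard two-sample test can never make, since failing to reject equality is
not evidence of equality. This package implements the discovery pipeline as
an equivalence-testing problem and the analyses needed to defend a hit list
against the three confounders: measurement error, genetic control, and
aging.

## Discovery model

For probe $j$ with per-individual beta values $\beta_{ji}$ (one sample per
individual; with technical replicates, the first replicate in sheet order is
used so no individual is double-counted):

* twin differences $|\Delta\beta|^{\text{twin}}_{jf} = |\beta_{j,f1} - \beta_{j,f2}|$
  over the $n$ MZ families;
* unrelated differences over all pairs of individuals from different
  families (both co-twins participate), $\binom{2n}{2} - n$ values.

**Variability gate.** Probes with IQR $\le$ 0.07 are removed: a CpG whose
observed distribution matches a Beta with mean 0.5 and sd 0.05 — a
measurement-error-scale spread — has exactly this inter-quartile range
(`expected_error_iqr(0.5, 0.05)` = 0.0679, 0.07 to two decimals). Where
replicate data or a published ICC table is available, probes with
one-way-ANOVA ICC(1) $\le$ 0.37 are also removed. Probes failing the gate
would satisfy equivalence trivially, because both difference distributions
are pure measurement error.

**Test.** Per gated probe, a two one-sided tests (TOST) procedure on the
$\gamma$-trimmed means ($\gamma = 0.2$) using the Yuen statistic: winsorized
variances, $d_i = (n_i-1)s^2_{w,i}/(h_i(h_i-1))$, $se = \sqrt{d_1+d_2}$,
Welch–Satterthwaite degrees of freedom. $p_{\text{equiv}} =
\max(p_{\text{lower}}, p_{\text{upper}})$ for $H_0: \Delta \le -\varepsilon$
and $H_0: \Delta \ge \varepsilon$. At $\gamma = 0$ the statistic reduces
exactly to the Welch two-sample t (a frozen oracle equivalence in the test
suite). The two difference samples are treated as independent although the
unrelated sample is heavily dependent (each individual appears in $2(n-1)$
pairs); this follows the original design and is guarded by the independence
check below.

**Margin.** $\varepsilon$ is the median (type-7 interpolated quantile;
configurable) of the per-probe trimmed twin-difference means, calibrated
separately per normalization branch. Rationale: the equivalence margin
should encode "as different as co-twins typically are", and the co-twin
scale differs between normalization methods. The trimming proportion is the
standard Yuen default of 0.2; neither value is sacred and both are exposed
in `discovery_config()`.

**Decision.** Bonferroni at $\alpha/m$ with $m$ the per-branch tested count;
the final evCpG set is the intersection of the per-branch significant sets.
Normalization itself is out of scope — the pipeline consumes one
already-normalized matrix per branch.

**Streaming.** Twin/unrelated difference vectors are materialized one probe
at a time (two passes: trimmed twin means for calibration, then the TOST),
so memory is O(number of pairs) per probe and no probes-by-pairs matrix ever
exists.

### Pairing-independence check

Using *all* unrelated pairs maximizes information but violates independence.
`independence_check()` re-runs discovery against repeated random *disjoint*
matchings (each individual in at most one pair, never with its co-twin) and
reports per-CpG decision agreement with the all-pairs run. Decisions are
compared at a common nominal level rather than at each design's Bonferroni
threshold: the disjoint design has $n$ unrelated pairs instead of
$\approx 2n^2$, so corrected decisions would mostly measure the power lost
to the smaller design, not whether the dependence distorted the test — which
is the only question this check is meant to answer. Both agreement summaries
(over all tested CpGs and restricted to the evCpG set) are reported.

## Supporting analyses

**Aging.** Cross-sectional: per probe, OLS of beta on age with a sex
covariate; the age-coefficient t test is the *clock* test. The *drift* test
is a White heteroscedasticity test whose auxiliary regression uses exactly
{age, age²} (df = 2) — the quadratic term distinguishes it from
Breusch–Pagan and targets variance growing with age. Sex is deliberately in
the mean model only. Classification (clock/drift/both/neither) uses
Bonferroni across the supplied probe set at α = 0.05; the correction is a
package choice, as is restricting the auxiliary regressors to age terms.

**Replicate resolution.** Hierarchical clustering (Euclidean distance,
average linkage by default — dendrogram parameters are assumptions, exposed
as arguments) on sample columns, scored at k = the number of truth groups
with the adjusted Rand index and purity, rather than by height threshold:
reproducible and scale-free. Negative controls are the top-ranked blood
mQTL probes present in the matrix, ties at the cut-off broken
lexicographically.

**WGBS.** Per sample, in a fixed audited order: strand-concordance filter
(drop CpGs covered on both strands whose strand betas differ by more than
0.20; otherwise sum counts across strands — single-strand CpGs pass
vacuously), blacklist-interval removal, coverage ≤ 10 removal, and removal
above the per-sample 99.9% coverage quantile computed *after* the earlier
steps (the order changes the cut, so it is fixed and logged in the audit).
Twin discordance at a shared site is called at $|\Delta\beta| \ge 0.4$: the
exact enumeration of $|X_1 - X_2|/c$ for two independent Binomial(c, p)
draws with no true difference gives 0.4 as the 95% quantile at c = 10 reads.
p = 0.5 is the default because it maximizes binomial variance and hence
gives the most conservative threshold; it is exposed. Regional enrichment is
a one-sided (greater) Fisher test on the in/out-of-region discordance
counts; the odds ratio is reported as ad/bc with a flagged
Haldane–Anscombe 0.5 correction for empty cells.

**Annotation.** Category enrichment assumes the background *excludes* the
target set (the natural contrast is "selected versus gated-but-not-selected
probes"); an inclusive background is handled by subtracting the target
first. Positional enrichment merges ±500 bp windows around target sites and
Bonferroni-corrects across merged windows; with a single target per window
the test is trivially confounded by the window being centred on the target,
so multi-target windows are reported first. The [G+C] comparison uses the
tie-corrected normal-approximation Mann–Whitney test; Ns are excluded from
the denominator.

## The synthetic cohort generator

`simulate_twin_cohort()` realizes the generative structure the discovery
test assumes, with known truth labels:

* *error_only* (70%): one true level per probe shared by everyone;
* *genetic* (20%): family-level Hardy–Weinberg genotype (co-twins share it)
  shifting the true beta by a per-allele effect;
* *stochastic* (5%): independent per-individual true logit — the evCpG
  model, under which co-twins and strangers are exchangeable by
  construction;
* *mixed* (5%): genotype effect plus per-individual noise.

Observed values are inverse-logit(logit(true) + N(0, σ_meas) + batch
offset). Logit-normal noise keeps betas strictly inside (0,1) without
clipping artifacts and makes variance components analytic on the logit
scale; true betas are clamped to [0.001, 0.999] before the logit. Every
generator takes an explicit integer seed and fixing it fixes every output
bit; the RNG state of the caller is left untouched.

**Default scales.** σ_meas = 0.12 gives a beta-scale sd of ≈ 0.03 at a
mid-methylated probe, a typical array technical error. The magnitude of
evCpG variation is not published, so the default σ_stoch = 0.25 with
mid-range baselines (0.3–0.7) was fixed once as a realistic choice: it
yields beta-scale spreads of ≈ 0.06–0.13, comfortably above the IQR gate
and comparable to the methylation ranges evCpG-like sites display, while
keeping co-twin differences on the same scale the equivalence margin
calibrates to. Genetic probes draw MAF from U(0.1, 0.5) and per-allele
effects from U(0.1, 0.3). All of this is configuration, not constants.

What the generator does **not** emulate: probe-type chemistry (Infinium
I/II), cell-type mixtures, linkage disequilibrium between CpGs, bimodal
population mixtures at single probes, and normalization-method differences
(branches in tests are copies or re-simulations, not competing
normalizations). Passing tests therefore demonstrate the statistical
machinery under the assumed generative model, not robustness to every
artifact of real arrays.

The aging generator grows the drift-class logit sd linearly with age above
the measurement floor (sd = σ_meas + rate·(age − age_min)) and shifts the
clock-class logit mean linearly with age; the WGBS generator uses negative
binomial coverage (dispersion default 5 — overdispersed, as real WGBS is),
binomial strand splits and read sampling, a blacklist, forced strand
artifacts, and one discordance-enriched region whose discordant sites have
true twin differences of at least 0.5.

## Numerical conventions

* All quantiles everywhere (IQR, ε calibration, coverage cut) are type-7
  linearly interpolated order statistics.
* Degenerate cases have fixed conventions: zero Yuen se with the mean
  difference inside (−ε, ε) gives p_equiv = 0 (flagged `degenerate`); zero
  residual variance gives White p = 1 (flagged); zero-variance probes get
  concordance 0 (flagged); a region with no covered sites returns an
  explicit not-computable status rather than a p-value.
* Coordinates are 1-based inclusive internally; BED input/output is
  converted exactly once at the I/O boundary.
* Multi-flag probes are removed once, attributed to the first flag in the
  fixed order low_quality, snp, cross_reactive, chrX, chrY.

## Problem sizes used in the test suite

The packaged tests exercise the full pipeline on a 200-twin-pair, 5000-CpG
cohort (the default configuration), 100-seed WGBS enrichment runs at 5000
sites each, 5000-replicate size checks for the TOST and clock tests and
2000 for the White test at the 727-individual scale, and exhaustive Fisher
enumeration for all tables with margins up to 30. These sizes were chosen
to make Monte Carlo error small relative to the asserted tolerances while
keeping a full run in minutes on one CPU.

## Known limitations

* The equivalence test treats the unrelated-pair sample as independent; the
  independence check quantifies, but does not remove, the approximation.
* The ICC gate needs replicates or an external ICC table; without either,
  gating is IQR-only.
* Lin's concordance on the order-symmetrized pairing is a stand-in for the
  original concordance summary, whose exact definition is not public.
* Bonferroni is the only built-in multiplicity correction, matching the
  original design; FDR variants are out of scope.
* The positional-enrichment window-merging rule is one reasonable
  interpretation; alternative merge rules change which marginal windows
  survive correction.
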