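---
title: "Estimating additive and epistatic effects in QTL pyramiding lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating additive and epistatic effects in QTL pyramiding lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The experimental system

Stigma exsertion rate (SER) — the percentage of spikelets whose stigma stays
exposed after flowering — is the standard proxy for outcrossing ability in
rice, and the trait that limits hybrid seed yield in male-sterile line
breeding. Asian cultivated rice lost much of it during domestication, but
the underlying variation survives in relatives (*O. sativa* accessions,
*O. glaberrima*, the wild *O. glumaepatula*), from which quantitative trait
loci (QTLs) can be recovered as single-segment substitution lines (SSSLs):
lines carrying exactly one donor chromosome segment in an otherwise uniform
recipient genome (here Huajingxian 74, "HJX74").

Because SSSLs and the pyramiding lines bred from them are homozygous and
isogenic except for the substitution segments, phenotype differences can be
read directly as genotypic values: the design removes dominance and
background variation and leaves only additive and additive-by-additive
terms. `qtlpyramid` implements the full analysis for such a design: a
control, a set of SSSLs, and pyramids stacking 2-6 QTLs.

## The model

For a trait measured as a percentage, with control mean $P_0$:

* **single-QTL additive effect**: $a_i = \bar{y}_{\mathrm{SSSL}_i} - P_0$;
* **combination effect** of an $n$-QTL pyramid: $P_n - P_0$;
* **additive-by-additive epistasis**:
  $$ i = (P_n - P_0) - \sum_{j=1}^{n} a_j , $$
  the deviation of the observed combination effect from the additive
  prediction. Negative $i$ is less-than-additive ("diminishing returns")
  interaction; in the rice SER study every multi-QTL group shows it, and it
  grows with the number of stacked QTLs.

Because the estimate is linear in line means,
$i = P_n + (n-1)P_0 - \sum_j \bar{y}_{\mathrm{SSSL}_j}$ identically; the
package tests this algebraic identity to $10^{-10}$ and exploits it twice:

* **Season-blocked significance test.** Cropping seasons are blocks. Within
  each season $s$ we form $i_s = P_{n,s} + (n-1)P_{0,s} - \sum_j
  \mathrm{SSSL}_{j,s}$ from the season means and run a one-sample Student's
  $t$ across seasons ($df = S - 1$, $S$ = seasons). Blocking absorbs both
  season main effects and the covariance induced by the shared control term
  without requiring plant-level records. A variance-propagation alternative
  (line means treated as independent, Welch–Satterthwaite df) sits behind
  `se_method = "line_means"` for data sets without common season blocks.
* **Group-summary mode.** When only published group means are available,
  the group-average epistasis equals (group mean $- P_0$) minus the
  group-average of $\sum_j a_j$, computable from the genotype matrix and
  the known per-locus effects. This is how the packaged study fixture is
  analysed end to end without per-line data.

### Scales

Hypothesis tests default to the arcsine square-root scale
($\arcsin\sqrt{p/100}$, radians), the conventional variance-stabilising
transform for percentage traits; all *effects* are reported on the raw
percentage scale, because that is the scale on which additive effects,
combination effects and epistasis are defined and published. The mix is
deliberate and configurable (`test_scale`). One consequence worth knowing:
data that are exactly additive on the raw scale are *not* exactly additive
after transformation, so with artificial noise-free data the transformed
test sees a tiny deterministic deviation; exact-null checks belong on the
generating scale.

### Focal-QTL attribution

For a focal locus $f$ within one pyramid-size group, lines are split into
those with and without $f$. The focal locus's own epistatic contribution is
$$ i_f = \bar{i}_{\mathrm{with}} - (n-1)\,\frac{\bar{i}_{\mathrm{without}}}{n}, $$
i.e. the with-subgroup's mean epistasis minus the share expected from the
$n-1$ non-focal loci, using the focal-free subgroup's per-QTL epistasis as
their stand-in. The published per-group attributions for `qSER3a-sat`
(3.9, 0.7 and 1.4 percentage points in the 2-, 3- and 4-QTL groups) are
reproduced by exactly this decomposition and, to our knowledge, by no
simpler alternative; it remains an inference, and it assumes the non-focal
loci in focal-carrying lines behave like those in focal-free lines.
Subgroup significance uses a Welch $t$ on line-level $i$ values, since the
published figures do not state the test variant.

### Effect-level classification

The study groups QTLs into low/moderate/high effect levels without stating
a rule. `classify_effect_levels()` uses the exact one-dimensional
least-squares partition (dynamic programming over the sorted effects),
which is deterministic, optimal, and reduces to natural gap-splitting for
well-separated clusters; ties break towards the smaller upper level. All
effects equal (fewer distinct values than levels) is rejected with a
pointer to a smaller $k$ rather than returning an arbitrary degenerate
partition.

### Inferential toolkit

* **Dunnett's many-to-one test** compares each group against the control
  through the joint multivariate-$t$ distribution of the statistics with
  correlation $\rho_{jl} = \sqrt{n_j n_l / ((n_j+n_0)(n_l+n_0))}$
  (equicorrelated when balanced), evaluated by `mvtnorm`'s randomised
  quasi-Monte-Carlo integration under a locally fixed RNG state so repeat
  calls agree to ~1e-4. One treatment group reduces exactly to the pooled
  two-sample $t$. Adjusted p-values are floored at the raw p-value.
* **Duncan's multiple range test** ranks group means and compares the range
  of every rank interval of span $p$ against the least significant range
  $LSR_p = q'(\alpha, p, df)\sqrt{MSE/\tilde{n}}$, with Duncan's protected
  quantile $q'$ obtained from the studentized-range quantile at protection
  level $\alpha_p = 1-(1-\alpha)^{p-1}$ (computed, not table-lookup, via
  `qtukey`). A pair is homogeneous when some containing rank interval
  passes its range test — equivalent to the classical stepwise recursion,
  and validated against an independently coded recursive oracle. Letters
  label the inclusion-maximal homogeneous stretches; two groups reduce to
  the LSD $t$-test. Unbalanced designs use the harmonic mean group size
  $\tilde{n}$; zero error variance is rejected as degenerate.

## The synthetic-data generator

`architecture_config()` + `generate_phenotypes()` emulate the study design
so every estimator can be validated against a known truth:

* baseline $P_0 = 29.2\%$ (the HJX74 control mean), additive effects
  defaulting to the packaged 13-27 percentage-point vector, 3 cropping
  seasons, season-level Gaussian noise with SD 3 percentage points —
  roughly the replicate scatter implied by the published standard errors;
* three epistasis models: `none` (strict additivity, the null for type-I
  error studies), `pairwise` (explicit per-pair interactions, used to
  program focal-specific architectures), and `diminishing`, where each
  co-resident pair contributes $-c$ so an $n$-QTL line receives
  $-c\,n(n-1)/2$ and the per-QTL epistasis $-c(n-1)/2$ grows with $n$, the
  qualitative signature of the study. The default $c = 3.2$ puts the
  per-QTL epistasis in the observed -2 to -8 range over $n = 2..6$ while
  keeping expected values clear of the 100% ceiling (maximum expected
  ~92%); the published per-group values are not exactly quadratic in $n$,
  so no single $c$ reproduces them all, and the model is meant as a
  qualitative emulation, not a fit;
* noise is applied on the raw percentage scale and then clipped to
  $[0,100]$ with clipping counted and reported — the transform is part of
  the pipeline under test, so noise is injected upstream of it; a seed
  fully determines the output.

What the generator does **not** emulate: plant-level sampling within a
season, season-by-genotype interaction, spatial field structure,
heteroscedasticity near the scale boundaries, and line-specific epistasis
beyond the three models. Passing round-trip tests therefore demonstrates
estimator correctness, not robustness to those real-data features.

## The packaged study fixture

The genotype matrix (11 loci, 31 lines, group sizes 7/10/7/5/2) and the
group and focal-subgroup means are transcribed from the published tables
and text. The per-locus single-QTL effects were **not** published; the
packaged `qtl_metadata_reconstructed.tsv` carries a numerically
reconstructed vector, constrained so that the genotype matrix plus the
published group means reproduce every published aggregate (mean and range
of single effects, per-group and per-subgroup epistasis, attributions)
within print rounding. The reconstruction matches the published qualitative
structure (7 low / 2 moderate / 2 high levels; donor-species composition of
each level) but individual values are not identifiable from the published
aggregates and must be treated as synthetic stand-ins; the same is true of
the derived pseudo-SSSL summaries (`ser_study_ssl_summaries()`). Because the
published means are themselves rounded to one decimal, some secondary
aggregates (donor means, level means) can be off by a few tenths of a
percentage point; the analysis functions carry full precision and round
half-away-from-zero only at presentation (`round_half_up()`), matching how
such tables are printed.

## Validation choices and problem sizes

The test suite validates each estimator against an independent oracle:
noise-free round trips recover programmed effects to $10^{-10}$; the
season-blocked $t$-test's type-I error is checked over 2000 null
simulations (band 0.03-0.07 at $\alpha = 0.05$); Dunnett's family-wise
error over 1000 null data sets; Duncan letter partitions against the
recursive oracle over 100 random instances; and single-effect recovery
bias over 200 simulated panels with study-like architecture (|bias| well
under 0.5 percentage points). These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands while keeping the whole suite under
a minute of compute.

## Limitations

* Per-line raw phenotypes of the original study are not accessible, so
  per-line epistasis values and the published figure letter panels cannot
  be verified numerically; they are covered by property-based tests on
  synthetic data instead.
* The focal attribution and the epistasis-fraction denominator (the grand
  mean single-QTL effect) are inferred reading of the published
  arithmetic; both are documented above and isolated in single functions.
* The linked two-QTL segments (A35, A88) are treated as ordinary 2-QTL
  lines; a joint additive effect (`"locusA+locusB"` map entries) is
  supported when the pair has no separate SSSLs, and no attempt is made to
  partition a segment's effect between its two loci.
* Dominance and higher-order interactions are out of scope: every line in
  the design is homozygous, so only additive-by-additive terms are
  estimable.
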