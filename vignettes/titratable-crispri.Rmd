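---
title: "Titratable CRISPRi screens: models, estimators and design choices"
author: "titraCRISPR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Titratable CRISPRi screens: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titraCRISPR)
```

## The experimental system this package models

CRISPR interference (CRISPRi) represses transcription of a target gene by
parking catalytically dead Cas9 (dCas9) on the template, guided by a
single guide RNA (sgRNA) whose 20-nt spacer matches the target. Mismatches
introduced into the spacer weaken the dCas9–DNA interaction, so a *series*
of progressively mutated sgRNAs titrates knockdown strength — and, for
genes that matter to growth, titrates the growth rate of the cell carrying
it. In the pooled version of the assay, thousands of sgRNA constructs
compete in a turbidostat (a continuous-culture device that clamps optical
density so the population stays in exponential phase), samples are drawn
every two hours, the sgRNA cassette is amplified and sequenced, and each
construct's relative growth rate is read off the slope of its log relative
abundance over time. A 6-nt plasmid barcode replicated six ways gives six
*internal replicates* of every sgRNA, which is what makes it possible to
detect *escapers*: lineages that lost CRISPRi activity (sgRNA or dCas9
mutations) and quietly grow at wild-type rate, masking the fitness cost of
the knockdown.

titraCRISPR implements the complete computational side of this platform:
library design, a generative simulator used as ground truth, read
counting, growth-rate estimation with escaper correction, a statistic for
how many distinct growth levels a guide series resolves, and
gene-by-environment (GxE) interaction calls from titration-curve fits.

## Library design rules

Parent sgRNAs are found by scanning the coding sequence for CCN motifs on
the sense strand; the protospacer is the 20 nt immediately 3′ of the
motif and the spacer is its reverse complement, so spacer position −1
(PAM-proximal) pairs opposite the sense base adjacent to the motif. SG1
and SG2 are the two most start-proximal non-overlapping sites within the
first 150 bp; SG3 is the first site at 200 bp or beyond. Candidates must
have GC strictly between 45% and 80% and no run of more than four T
(a poly-T stretch terminates Pol III transcription of the sgRNA).

Off-target screening slides the protospacer over both strands of
user-supplied background sequences and demands redesign when (i) the
exact 20-mer occurs at more than one locus, (ii) a site with identity
strictly between 90% and 100% lies adjacent to a PAM, or (iii) a site
between 75% and 90% identity has a perfect PAM-proximal 8-mer
("region 1", spacer −1…−8) and an adjacent PAM. "Adjacent" is
interpreted as a CC (or GG, for antisense sites) dinucleotide within 3 nt
of the matched window on the PAM side; the printed rules leave exactly
90% identity outside both rule (ii) and rule (iii), and we preserve that
literal reading. Because a guide's own locus is a 100%-identity,
PAM-adjacent site, exact matches are handled only by rule (i), which
requires two of them.

Each of SG1 and SG3 is expanded into

* 14 **compounding** variants: complement mutations accumulated from
  −20 inward to −7 (variant *k* mutates −20…−(21−k));
* 15 **single** variants at −1, −2, −5, −8 and −10…−20;
* 5 **double** variants at −2/−12, −12/−14, −15/−17, −11/−18, −13/−19;

plus 45 scrambled negative controls (negC) drawn at random under the same
composition filters — the controls are what every growth rate is measured
against, so we require them to be synthesizable and non-targeting under
the same rules as the guides (the original protocol is silent on this;
manufacturability parity is our choice). One redundancy is inherent to
the printed design: the first compounding variant and the −20 single
mutant have identical spacers, so sequencing credits that sequence to a
single entry.

The **compact library** keeps, per gene, the SG1 and SG3 parents plus
their compounding variants with 4–10 mutations: 16 guides per gene, the
subset that concentrates the steepest part of typical titration curves.

## The simulator: what it emulates and what it does not

`simulateTruth()` + `simulateCounts()` generate the study conditions the
analysis is tested against: up to 88 genes, the full or compact library,
six barcoded internal replicates, seven glucose timepoints over 14 h
(0, 2, 4, 6, 10, 12, 14 — the 8 h point is skipped) at 0.94 doublings/h,
five glycerol timepoints (0, 2, 6, 10, 14) at 0.53 doublings/h, and one
million reads per timepoint.

Each gene × environment gets a four-parameter logistic (Hill) titration
curve on the normalized growth scale,

$$g(m) \;=\; \mathrm{min} + (\mathrm{max}-\mathrm{min})\,
\frac{m^{\,\mathrm{Hill}}}{\mathrm{IG50}^{\,\mathrm{Hill}} +
m^{\,\mathrm{Hill}}},$$

with `g(0) = min`: the unmutated parent gives the strongest knockdown and
growth recovers toward `max` as mutations accumulate. The same functional
form is used by the fitter, which makes parameter recovery well-posed;
this is a deliberate choice, since the upstream description names a
4-parameter logistic without printing its equation. Single/double
variants use a retention model: each mutated position keeps a fraction
of the knockdown ((k/20)^1.5 for position −k by default, near zero in the
seed region), and residual knockdown is the product over mutated
positions.

Lineage dynamics are exponential competition: normalized growth is
mapped to raw growth ρ = (g − 1)·|floor| with floor −1.23
doublings/generation (the raw growth of a complete kill), each
(guide, barcode) lineage's abundance evolves as `2^(ρ·generations)`
relative to the controls, replicate jitter perturbs g per lineage
(Gaussian, SD 0.01 by default, truncated to [0, 1.15]), and with
probability 0.01 a lineage escapes at a uniform random time, after which
its relative abundance freezes (growth reverts fully to wild type — a
single, complete switch). Sequencing is multinomial at fixed depth per
timepoint; an `"expected"` sampling mode emits exact expected counts for
noise-free checks. The default per-lineage escape probability is a free
simulator knob, not an empirically printed value.

Not modelled: OD-feedback dynamics, lag phase, induction kinetics, media
chemistry, PCR bias, or overdispersed sequencing (no Dirichlet component
by default). Passing tests on these simulations therefore demonstrates
the *estimators'* correctness under the stated noise model, not
robustness to every artefact of real sequencing data.

## Growth-rate estimation

For each lineage, relative frequency is
`f(t) = log2(n_sg/n_nc)_t − log2(n_sg/n_nc)_{t=0}` against a reference
control within the same barcode; the reference is the negC guide whose
provisional slope (from its share of total reads) is the median of the
controls — a stand-in for picking the centre of the control distribution.
Time is rescaled to generations before fitting, so environments with
different doubling rates are comparable.

The growth rate is the OLS slope of f over generations with a depth
truncation: points are used in schedule order until the first whose
count falls below 10; that point is kept, later ones are not. A
zero-count point (log of zero) truncates *before* itself — our documented
extension of the printed below-10 rule; a pseudocount alternative was
rejected to avoid biasing slopes of dying lineages.

Escaper correction then works per guide across its six replicate fits:
(1) drop fits with R² < 0.70 unless the slope lies within ±0.05 of zero
(flat series have legitimately poor R²); (2) Dixon's Q test at 95%
confidence (two-tailed r10 critical values 0.970/0.829/0.710/0.625 for
n = 3…6) removes at most the single most extreme replicate; (3) guides
keep their estimate only with ≥3 survivors, reported as mean ± SD/SEM.
The Q test is single-pass by design — with six replicates a second
escaper is rare, and iterated small-sample outlier removal inflates
false removals. Finally the affine rescaling maps the empirical floor
(−1.23, or the most negative fully-replicated parent in `auto` mode) to
0 and the reference to 1; values outside [0, 1] are reported, not
clipped.

`uncorrectedGrowth()` reproduces the naive comparison condition —
barcode-pooled counts, two timepoints, no filters — which overestimates
growth precisely when escapers are present.

## Resolvable growth effects

Within a gene, every pair of guides is compared by Welch's *t*-test on
replicate-level slopes (computed in closed form with Satterthwaite
degrees of freedom; `stats::t.test` serves as the oracle in the test
suite). P-values are pooled across genes and corrected with the
sequential goodness-of-fit metatest (SGoF, exact binomial variant,
one-tailed, γ = α = 0.05): while the count of sub-γ p-values
significantly exceeds its Binomial(n, γ) expectation, the smallest
remaining p-value is rejected. We chose the exact binomial over the
large-n χ² approximation because per-scope pools here are modest.

Two properties of SGoF matter for interpretation. It gains power from an
*excess* of small p-values, so a lone true positive in a small pool is
never rejected; and it always leaves a quota of sub-γ p-values
unrejected (the stopping count), so even a pool of uniformly tiny
p-values is not rejected in full. Step counts on tiny toy pools are
therefore lower than the per-pair tests alone would suggest — this is
the correction working as specified, not a defect.

The number of resolvable steps for a gene is the largest set of guides
in which *every* pair is SGoF-significant — a maximum clique in the
significance graph, solved exactly (igraph's exact clique enumeration;
verified against 2^n subset enumeration for n ≤ 12). Ties between
maximum cliques are broken by larger dynamic range of member means, then
larger variance, then lexicographic guide ids. Genes qualify only if
they carry both SG1 and SG3 titrating series and at least one parent
with normalized growth below 0.75 (the Methods' strict reading of the
threshold). The analysis runs per scope — single, compounding, all, or
compact-16 — with SGoF pooling redone within each scope. The all-guides
scope is exact but can take minutes at full scale, because dense
significance graphs contain very many tied maximum cliques; the demo
pipeline defaults to the faster scopes.

## Gene-by-environment interactions

For each gene, environment and internal replicate, the SG1 compounding
series (normalized growth vs mutation count, ≥8 points) is fitted with
the bounded logistic above: min, max ∈ [0, 1.15], IG-50 ∈ [0, 14], Hill
unbounded, starting from (meanL, meanH, 1, 6) where meanL/meanH are the
means of the three least/most mutated points. If |meanH − meanL| < 0.05
the curve is reported flat (min = meanL, max = meanH, Hill and IG-50
absent) — at the boundary value 0.05 the sigmoid is attempted. The
optimizer is `stats::nls(algorithm = "port")` (bounded nl2sol), which
interpolates noise-free logistic data exactly; `minpack.lm::nls.lm` is
the fallback on error. The reported cost is the plain sum of squared
residuals. Genes are eligible when their least-mutated measurable guide
shows normalized growth ≤ 0.75 in at least one environment and at least
three replicate fits exist per environment; per-parameter medians are
taken over replicates that carry the parameter.

Interactions are called per parameter with Welch's *t*-test over the
replicate-level estimates in the two environments; genes sigmoidal in
exactly one environment (fewer than two sigmoidal replicate fits in the
other) receive p = 0 for IG-50 and Hill — a qualitative difference that
needs no test. SGoF corrects each parameter separately across genes, and
assigned zeros are always among the rejected set (small pools could not
otherwise reject them). Classes: `min_detectable` when min differs (the
interaction is visible at maximal knockdown, as a knockout screen would
see it); `titration_only` when min does not differ but IG-50, Hill or
max does — interactions invisible to single-perturbation screens;
`none` otherwise. By construction the two positive classes partition the
genes with any significant parameter.

Because of the SGoF quota described above, a pool of 10 shifted + 10
null genes supports at most ~7 IG-50 rejections regardless of effect
size; recovery experiments at that scale should be read with this
ceiling in mind.

## Numerical and testing choices

Problem sizes in the test suite were chosen to exercise the full study
conditions while staying comfortably inside a desktop run: the recovery
experiment uses all 88 genes with the compact library (1,453 guides ×
6 barcodes) at depth 10^6 — at that depth the full 6,293-guide library
leaves too few reads per lineage for near-lethal guides to be fit beyond
2–3 truncated points, which is a property of the truncation rule, not of
the estimator. Oracle-equivalence suites run 200 randomized instances
per statistic at tolerance 1e-8; the clique solver is checked against
exhaustive subset enumeration on 200 instances with up to 12 guides. All
simulations are seed-pinned. Degenerate inputs are handled explicitly:
identical samples give Welch p = 1 (distinct constant samples p = 0),
zero-range samples are never flagged by Dixon's Q, zero-count lineages
are dropped with a logged reason, and missing parents yield partial
designs with warnings rather than errors.

## Known limitations

* The logistic form, retention model and escape process are stylized;
  real titration curves can be non-monotonic, and real escapers can be
  partial.
* Exact spacer matching has no error tolerance; reads from
  sequencing-error-prone platforms will be discarded rather than
  rescued, and the strict Q > 30 filter is applied only to the
  decision-relevant bases by default (switchable to the whole read).
* Pairwise distinguishability depends on the SGoF pool composition, so
  step counts are comparable only within the same pooling scope.
* The GxE Welch tests treat per-replicate fit parameters as independent
  samples; parameters of a logistic fit are correlated, so the
  per-parameter tests are screening calls, not joint inference.
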