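---
title: "Estimating individual street-tree growth rates from paired census snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individual street-tree growth rates from paired census snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streetgrowth)
```

## The problem

City street-tree censuses record every tree roughly once a decade, but in
older releases the recorded coordinates are unreliable, so the same physical
tree cannot be re-identified across censuses by location. `streetgrowth`
implements a coordinate-free alternative: a tree is identified by the exact
triple (ZIP Code, normalized street address, species common name). Two
snapshots a decade apart are joined on that key; the DBH difference divided
by ten years is the tree's growth rate in inches per year. Because the key
is only meaningful when it names one tree, any address that holds two or
more trees of the same species is removed from both censuses before
alignment — all copies, not all-but-one.

The package provides the full sequence as composable functions: snapshot
normalization, key-uniqueness enforcement, alignment, a staged
quality-control cascade, growth summaries, validation statistics (Theil–Sen
slope, Kendall tau-b), a standardized OLS determinants model with GVIF
collinearity screening, a residual-versus-social-vulnerability analysis, and
a synthetic-city generator with full ground truth for testing every stage.

## Normalization

Matching is exact string equality, so both snapshots must be written in one
canonical vocabulary first.

* **Addresses** are uppercased; punctuation is deleted except the hyphen in
  digit–digit building ranges ("45-47", a real addressing convention that
  distinguishes adjacent lots); ordinal suffixes are stripped from numeric
  tokens (120TH → 120); abbreviations are expanded through an explicit,
  versioned table (ST → STREET, W → WEST, ...); whitespace is collapsed.
  Every expansion target is a fixed point of the table, which makes
  normalization idempotent — a property the test suite asserts on every
  generated variant.
* **Species** common names pass through a many-to-one variant dictionary.
  Names absent from the dictionary are kept verbatim but flagged unmapped
  and excluded from linkage: a vocabulary gap must fail safe rather than
  silently matching.

Both tables ship as data (`inst/extdata/`), not code. They are declared
configuration: the canonical tables used by any given census pair are part
of the pipeline's provenance, and no claim is made that they reproduce any
particular city's unpublished cleaning rules.

## The QC cascade

Aligned pairs carry three known error classes, removed in a fixed order
(each filter refuses to run out of order, and re-running any filter on its
own output changes nothing):

1. **Negative cutoff.** Decadal growth below −5 inches is attributed to a
   same-species replacement (a mature tree felled and a sapling planted in
   its pit) or a gross recording error. Growth of exactly −5 inches is
   retained — the retained minimum rate is therefore −0.5 in/yr — because
   whole-inch rounding in two censuses can legitimately produce moderate
   apparent shrinkage.
2. **Starting-size bounds.** Trees recorded at 0 inches in the early census
   (saplings rounded down, whose relative growth is unconstrained) and at
   41 inches or more (rare giants) are removed; 1–40 inches is kept.
3. **Per-bin tail trim.** Within each 1-inch starting-DBH bin,
   `floor(0.05 n)` records with the smallest growth and the same number
   with the largest are removed. Binning by starting size matters because
   small trees genuinely grow faster; a global trim would preferentially
   delete them. `floor` makes small bins immune (a 10-record bin trims
   nothing), and ties are broken by record id so the removal is
   reproducible.

All drops are soft: every pair keeps a `qc_status`, and the step report
reconstructs the full accounting of the cascade.

### A cautionary interaction found during testing

Two degenerate behaviours of the trim are worth knowing about.

* With integer growth values, the trim boundary usually falls inside a
  large group of tied records, and the tie-break decides which of them go.
  If record ids correlate with geography — as they do in any census keyed
  in collection order — an id-ordered tie-break trims *different places*
  at the two tails and can manufacture a spatial gradient in mean growth
  out of nothing. The synthetic generator therefore assigns identity
  numbers in random order, and the residual-versus-SVI null test below
  confirms the slope is centred on zero under that condition. Analysts
  applying the cascade to real data should check their id scheme for
  spatial ordering before trusting small zone-level contrasts.
* If within-species growth variance is tiny, the fastest species *is* the
  upper tail of every bin it occupies, and the trim removes it wholesale.
  This is why the noise-free recovery check in the acceptance suite runs
  with the trim disabled: under zero variance the trim is degenerate by
  construction, and its contract is tested separately at realistic
  dispersion.

## Validation statistics

Repeat-measurement series (ground-truthing campaigns that revisit trees)
are summarized by the Theil–Sen slope — the median of all pairwise slopes,
robust to a single bad measurement — and by Kendall's tau-b between time
and DBH, which is +1 exactly when the series is strictly monotone
increasing. The tie-corrected variant is the right one here because
whole-inch DBH makes ties the norm. Both implementations are checked
against brute-force pair enumeration in the tests.

## The determinants model

Growth rate is regressed on species, tree condition and stewardship
categoricals, the surveyor class, and continuous urban-form covariates
(starting DBH as an age surrogate, built floor-area ratio, population
density, street width). Choices:

* Continuous predictors are standardized by **twice** the sample standard
  deviation, so their coefficients are directly comparable to binary
  indicator coefficients. Standardized columns have mean 0 and SD 0.5 by
  construction (asserted in tests). The sample (n−1) SD is used.
* Only the `top_k` (default 15) most abundant species keep their own
  indicator; the rest pool into "Other", which is the reference level.
  Guards use "Harmful" and surveyor class uses "NYC Parks Staff" as
  references; other factors default to the alphabetically first level.
  Reference choices are reported, not hidden in the contrast coding.
* Collinearity is screened with the generalized variance inflation factor,
  computed from the determinant ratio of the design correlation matrix.
  For a one-column term this is exactly 1/(1−R²); for multi-column
  (categorical) terms GVIF^(1/(2·df)) puts values on a comparable scale.
  The implementation is cross-checked against an independent reference
  implementation in the test suite.
* Complete-case rows only; the exclusion count is reported.
* The analysis is observational: non-significant controlled terms stay in
  the model rather than being pruned.

Group-level contrasts outside the model use a classical two-sample t-test
for two levels and one-way ANOVA with Tukey HSD for three or more,
summarized as a compact letter display built by insert–absorb (levels
sharing no letter differ at α = 0.05). A simulation in the acceptance
suite confirms the letter display holds its family-wise type-I error near
0.05 under the null.

## Residuals versus social vulnerability

The social-vulnerability index is deliberately **never** a model term. To
ask whether trees in more vulnerable neighbourhoods grow faster or slower
than the model predicts, the model is refitted without the borough term
(which would otherwise absorb exactly the between-zone structure of
interest), tree-level residuals and SVI are averaged by ZIP zone — zones
below a minimum tree count or on an explicit exclusion list are dropped
with reasons — and the zone-mean residual is regressed on zone-mean SVI.
The regression is unweighted by default; weighting by zone tree count is a
flag. A positive slope means faster-than-predicted growth where
vulnerability is higher.

## The synthetic city

The generator is first-class, tested code, and the study conditions are its
defaults:

| knob | default | why |
|---|---|---|
| annual mortality | 0.044 | published street-tree mortality estimate; implies (1−0.044)¹⁰ ≈ 64% decadal survival |
| replacement probability | 0.15 | fraction of deaths replaced in place by a same-species sapling, set so replacement false matches form roughly the share of linked pairs that ground-truthing attributes to replacements |
| duplicate-series probability | 0.15 | chance an address holds a same-species pair (series planting), the non-uniqueness failure mode |
| surveyor noise SD | 0.5 in | repeat-measurement variability before whole-inch rounding |
| circumference / digit error | 0.001 each | tape read as circumference (reported ≈ round(π·DBH)); trailing digit dropped (10 → 1); real rates unknown, nominal values documented as such |
| species table | 23 species | the 15 most abundant species with realistic frequencies, sizes and mean rates as ground truth, plus a low-frequency tail that pools into "Other" |
| size effect | −0.01 in/yr per inch | smaller (younger) trees grow faster |
| SVI effect | 0.1 in/yr per unit SVI | growth boost invisible to the model, to be recovered from residuals |

Geometry is an interleaved grid (east–west and north–south streets cross,
so both orientations occur everywhere and street orientation is not
confounded with location), with ZIP, tract and tax-lot layers as rectangle
grids. SVI follows a smooth west-to-east gradient plus tract noise, so
zone means genuinely differ. Street names deliberately repeat across
orientations; an odd/even building-number convention keeps crossing
same-named streets from sharing an address. Surveyor classes are assigned
with strong geographic concentration (volunteers dominate one borough),
reproducing the confounding of surveyor class with tree stock. True growth
is linear in time per tree — decadal differencing cannot identify
curvature, so the generator stays identifiable.

What it does **not** emulate: spatial ecology (competition, shading),
climate, correlated measurement drift between surveyors, geocoding error
(the method's premise is that coordinates are not used), and any
non-street trees. Passing tests therefore demonstrate the pipeline's
internal correctness and its behaviour under this error model, not
fidelity to any particular city's data.

Because linkage is an exact join on a key the generator emits faithfully,
recall on unique-keyed survivors is structurally 1.0; the method's failure
mode is false matches from in-place same-species replacements, which is
exactly the error class the −5-inch cutoff targets. The per-bin trim also
attenuates true spatial contrasts slightly (fast-growing zones lose more
upper-tail trees), which is why the recovered SVI slope sits somewhat
below the generative 0.1 while remaining strongly positive.

## Problem sizes and determinism

Everything is deterministic given the configuration seed. The analysis
scripts under `analysis/` run a 60 × 60-street city (~4,100 trees) so the
whole sequence reruns in well under a minute; the acceptance script and the
linkage regression test use the full ~50,000-tree configuration; the
replicate-based SVI power check uses 100 cities of ~5,600 addresses. These
sizes are the package's choices for routine reruns — all scale linearly if
larger runs are wanted.

## Known limitations

* Deterministic exact-key linkage cannot see trees whose address or species
  strings were recorded differently in the two censuses beyond what the
  normalization tables repair; there is no fuzzy fallback by design.
* The replacement false-match class is only partially removable: a small
  tree replaced by a sapling can show growth above −5 inches and survive
  the cascade, biasing species means slightly downward at realistic
  mortality.
* The −5-inch cutoff, the 0/41-inch bounds and the 5% trim are fixed
  conventions of the cascade, exposed as configuration; nothing in the
  package estimates them from data.
* Zone-level inference treats zones as independent; no spatial
  autocorrelation model is fitted.
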