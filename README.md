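# streetgrowth

Individual street-tree growth rates from paired decadal census snapshots,
without coordinates.

## The problem

Street-tree censuses record every tree about once a decade, but older
releases carry unreliable coordinates, so the same physical tree cannot be
re-identified across censuses by location. This package identifies a tree
by the exact key **(ZIP Code, normalized street address, species common
name)** instead. Any address holding two or more trees of the same species
is removed from *both* censuses (the key would be ambiguous); the remaining
records are joined one-to-one across snapshots, and each matched tree's
growth rate is

    rate (in/yr) = (DBH_late − DBH_early) / 10

with DBH in whole inches. Matched pairs then pass a staged QC cascade:

1. drop decadal growth below −5 in (in-place same-species replacements and
   gross errors; growth of exactly −5 in is kept, so the retained minimum
   rate is −0.5 in/yr);
2. drop starting DBH 0 in (rounded-down saplings) and ≥ 41 in (rare giants);
3. within each 1-inch starting-DBH bin, trim `floor(0.05·n)` records from
   each growth tail (small trees grow faster, so tails are defined within
   size class; ties break by record id).

On top of the cleaned rates the package provides Theil–Sen slopes and
Kendall tau-b for repeat-measurement validation series, a 2-SD-standardized
OLS of growth rate on species, stewardship and urban-form terms with GVIF
collinearity screening, ANOVA/Tukey group contrasts with compact letter
displays, and a residual analysis against a social-vulnerability index
(SVI is never a model term; zone-mean residuals from a borough-free fit are
regressed on zone-mean SVI). A synthetic-city generator emits census pairs
with full ground truth — mortality with same-species sapling replacement,
whole-inch rounding, surveyor noise, circumference-for-diameter and
dropped-digit entry errors, address formatting variants, series-planted
duplicates — so linkage precision/recall and rate recovery are measurable.

## Worked example

`analysis/` holds the numbered drivers (simulate → link → QC → covariates →
determinants → recovery). Running them in order on the default desk-scale
city prints, among other things:

```
city: 4136 trees planted at year 0; 59% survive the decade,
 219 replaced in place by same-species saplings.
dedupe dropped 1072 + 508 records (non-unique keys dominate);
 2064 pairs matched of 3064 / 2297 retained records (50% of the early census).
QC kept 1751 of 2064 pairs
mean rate 0.327 +/- 0.326 in/yr (min -0.5, max 8.6);
 4.2% negative, 95.7% within [0, 1] in/yr.
OLS: n = 1751, adjusted R^2 = 0.033, RMSE = 0.316 in/yr, max GVIF^(1/2df) = 1.30
residual vs SVI: slope 0.054 in/yr per unit SVI (p = 0.055, 24 zones)
linkage: precision 0.9157, recall 1.0000 (2064 pairs, 1890 persisting unique-keyed trees)
false matches by late-record event:
replacement
        174
per-species rate recovery: bias -0.019, RMSE 0.056 in/yr over 23 species
```

Reading this: the retained minimum rate is −0.5 in/yr (the −5 in cutoff);
every false match is an in-place replacement, the method's one structural
failure mode, and most of those are removed by the cascade; recall on
unique-keyed surviving trees is exactly 1 because the linkage is an exact
key join; the positive residual-vs-SVI slope recovers the growth boost the
generator ties to social vulnerability without ever showing SVI to the
model. (At this small size one circumference-entry error survives the thin
trim — the `max 8.6` — which is why the full-scale runs below use ~50,000
trees.)

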