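---
title: "Scoring children's egocentric social networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring children's egocentric social networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csnq)
```

## The measurement problem

Developmental researchers who want to quantify a young child's everyday
social environment face a roster problem: a parent can report who the child
sees in a typical week (the *name generator*) and basic demographics for each
of those people (the *name interpreter*), but turning those rosters into
comparable numbers requires a fixed metric set and a long list of small
coding rules.  `csnq` implements that scoring engine for egocentric (child-
centred) networks of *alters* — the individuals and groups a child interacts
with regularly — and the descriptive statistics usually run over a cohort of
scored networks.

An ego network here is the ego (child) record plus an alter roster.  Alters
can be persons or *group nodes* (e.g. "preschool class"): groups count toward
network size and structure but, lacking individual demographics, are excluded
from attribute-based metrics unless attributes are supplied.

## Metrics

**Size.** `N` = number of unique individuals and groups on the roster.  A
person appearing in two settings is one node with two context memberships.

**Ties and structure.** Parent interviews do not collect pairwise
acquaintance data, so alter–alter ties are *inferred from shared contexts*:
alters are tied iff the sets of settings in which each interacts with the
child intersect.  This is the central structural assumption — every activity
becomes a clique, and components are unions of overlapping contexts.  From
the tie count `T`:

* density `= 2T / (N(N-1))` (undefined below two alters),
* components `C` = connected components of the alter–alter graph (the ego is
  never a vertex, so a family sharing one context is a single component and
  `C >= 1` always),
* component ratio `= (C-1)/(N-1)`, a size-normalized fragmentation index in
  `[0, 1]`.

**Composition.** Relationship labels are classified kin/non-kin by a
configurable taxonomy (`default_taxonomy()`); kin covers the immediate and
extended family.  Alters under 13 years are children, 13 and over adults.
Relationship intensity combines three measures — activity count, parent-rated
emotional closeness, and the proportion of the child's waking hours spent
with the alter — each standardized as a z-score *across the pooled
relationships of the whole cohort*, averaged, and median-split into
high/low labels.  Proportions (kin, adult, high-intensity) divide by the
count of attribute-eligible alters, not raw `N`, so missing data shrinks the
denominator rather than biasing the numerator.

**Diversity.** For a categorical attribute with proportions `p` over the
alters, the entropy is `H = -sum(p * log2(p))` (base 2, `0·log2(0) = 0`);
`H = 0` means a homogeneous network, and `H <= log2(k)` with equality at the
uniform `k`-category profile.  Race uses one discrete category per alter,
with multi-category alters collapsed to `Mixed/Biracial`; language maps each
alter to monolingual-English / English-bilingual / non-English-monolingual /
other-multilingual / preverbal.  The E-I index `(D - S)/(D + S)` measures
homophily relative to the child: an alter is *same-race* if their category
set intersects the child's (so either component race of a biracial child
counts), and *different-speaker* iff they speak a language the child does
not (preverbal alters are same).  An alter recorded only as `Mixed/Biracial`
against a monoracial child is uncodable and reported missing rather than
guessed.  The ego never enters a composition profile, and the E-I
denominator counts codable alters only.

**Typology.** Computing racial entropy per component distinguishes *how*
diversity is patterned: `no_diversity` (overall entropy 0), `segregated`
(entropy > 0 with at least half of the components internally homogeneous),
`integrated` (entropy > 0, fewer than half homogeneous).  Two boundary
decisions are deliberate: a zero-entropy-component proportion in `(0, 0.5)`
is integrated, and the configuration "entropy > 0 but *every* component
homogeneous" (disjoint single-race components of different races) is
classified segregated with a warning — it falls outside the usual
definition's upper bound and rarely occurs in real rosters, but the
classifier must be total.

## Missing-data policy

Any metric whose required fields are absent is an explicit `NA`, never 0:
density when a roster is flagged `density_collected = FALSE` (interview
protocols differ in whether they collect context data), intensity metrics
when the three measures were not collected, diversity metrics when no alter
has a codable attribute.  Components with no race-coded member are excluded
from both sides of the zero-entropy proportion.

## Numerical choices

* Intensity z-scores use the population (n) denominator; any consistent
  choice yields identical median-split labels.
* Median ties are labelled `low` — deterministic, and with continuous
  composites an even pool splits exactly in half.
* Closeness is treated as a numeric ordinal on whatever scale the instrument
  used; z-scoring absorbs affine rescalings.
* The rank-sum test enumerates the exact permutation null for total n ≤ 20
  (two-sided by distance from the null mean, valid under ties) and otherwise
  uses the tie-corrected normal approximation.
* Spearman correlations use average ranks with the t-approximation p-value;
  pairs are deleted listwise per correlation (not per table), because some
  metrics exist only on subsets.
* "FDR correction" is Benjamini–Hochberg, applied across all cells of the
  emitted correlation table in one family; the procedure name is recorded in
  the table's metadata.
* Unknown relationship labels are an error in strict mode, non-kin with a
  warning otherwise.

## The synthetic cohort

`simulate_cohort(default_config(), seed)` generates rosters with the
statistical structure of a cross-sectional developmental sample, so the full
pipeline is testable without any human-subjects data:

* ages uniform on 6–60 months;
* network size negative-binomial (dispersion 30) with mean
  `11 + 0.2 * (age - 33)`, truncated to `[3, 40]` — the overdispersion
  reproduces a size SD near 5 at mean 11, and the age slope yields a
  size–age rank correlation near 0.6;
* a family component of kin (floor of two: mother and father) whose expected
  fraction declines with age from a nominal 0.48 (the floor lifts the
  realized cohort mean to about 0.52), plus activity contexts whose number
  grows with the non-kin count (about one setting per four non-kin alters) —
  this is what drives components up and density down as networks grow;
* kin receive systematically higher intensity measures, linking the kin and
  high-intensity proportions;
* children attend out-of-home childcare with probability rising in age
  (logistic, midpoint 30 months); attendees get a "daycare" context and a
  class group node;
* racial and linguistic mixes are drawn per ego from Dirichlet-perturbed
  urban vs suburban/rural base profiles (65% urban).  Non-kin alters track
  the ego's *own* neighborhood profile only in the urban stratum; suburban
  non-kin draw from the stratum base, so a network–neighborhood diversity
  correlation exists only among urban egos;
* 5% of alter race values and 8.5% of language values are missing at random;
  alters under 18 months are preverbal.

All draws flow from one `set.seed(seed)` stream in a fixed order, so output
is a pure function of `(config, seed)`.

What the generator does *not* emulate: household structure (kin are
attribute-independent draws), genuine multi-context alters, correlation
between a family's languages and its neighborhood, reporting biases of the
parent interview, or recruitment effects.  Passing tests therefore show the
*scoring and analysis machinery* is correct and that configured effects
propagate with the right signs and magnitudes — not that real cohorts will
show these parameter values.

## Problem sizes used in the test suite

Structural metrics are verified against brute-force oracles (boolean-closure
reachability, exhaustive pair counts, direct entropy summation, count
arithmetic for E-I) on 1,000 random rosters of up to 12 alters.  Cohort-level
emulation checks run the full pipeline on 20 independent cohorts of 280
children; smaller cohorts (25–80) back the remaining statistical checks.
These sizes give stable Monte-Carlo sign checks while keeping the suite
quick on one CPU.

## Known limitations

* Tie inference assumes everyone in a context knows everyone else, and that
  contexts are taken exactly as labelled; a babysitter at home is connected
  to the family only if given the family context.
* Whether the intensity median split should be within-protocol or per
  analysis is a caller decision: the pool is whatever cohort is passed to
  `csnq_score()` in one call.
* The closeness instrument's scale anchors are not fixed by the package.
* The typology's boundary classifications (above) are conventions; both are
  flagged so downstream users can re-bin.
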