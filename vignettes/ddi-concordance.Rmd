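---
title: "Measuring concordance between drug-interaction checkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring concordance between drug-interaction checkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiconcord)
```

## The problem

Electronic drug-interaction checkers (EDICs) answer the same clinical
question — "how severe is the interaction between drug A and drug B?" —
from different evidence bases, and they answer it inconsistently. A
pharmacovigilance analyst comparing two checkers over thousands of drug
pairs needs three things: a common severity scale, a principled agreement
statistic, and a category structure that localizes *where* the checkers
disagree. `ddiconcord` implements all three for drug catalogs organized
by ATC Level-2 pharmacotherapeutic subcategories, with a cardiovascular
category `C` (subcategories C01–C10) and an "other" category `O` of
co-prescribed drug classes (A02, A10, A12, B01, G04, M01, M04, and the
split psychotropic codes N05-1, N05-2, N06-1, N06-2).

## Severity harmonization

Checker vocabularies collapse onto an interaction-strength code 0–4:

| code | meaning            | WebMD-style label      | Drugs.com-style label |
|------|--------------------|------------------------|-----------------------|
| 0    | not found/unknown  | "0 Interactions Found" | "Unknown"             |
| 1    | minor              | "Minor"                | "Minor"               |
| 2    | moderate           | "Monitor closely"      | "Moderate"            |
| 3    | major/serious      | "Serious"              | "Major"               |
| 4    | contraindicated    | "Don't use together"   | "Major" + recommendation "Contraindicated" |

Two deliberate choices live here. First, a checker that returns no record
for a pair is treated as code 0 — "no interaction found" and "unknown"
are the same strength level, because the checkers themselves do not
distinguish an absent record from an unknown interaction. Second, the
Drugs.com-style dialect maps "Major" to 3 for *every* professional
recommendation (*Generally avoid*, *Adjust dose*, *Monitor closely*, ...)
except *Contraindicated*, which alone promotes it to 4. Where a checker's
monograph carries several recommendations, the caller decides which one
to pass; the package does not guess. Label matching is case-insensitive
and normalizes whitespace and typographic apostrophes, since the same
label circulates in several capitalizations. Dialects are data, not code:
`register_dialect()` and `read_dialects()` accept new vocabularies, so
the two built-ins are merely defaults and the rater count `n` is a true
parameter.

## Agreement strata and percentages

For exactly two raters, each pair's disagreement is the absolute code
difference, partitioning pairs into five strata: agreement (0), mild
agreement (1), mild disagreement (2), disagreement (3), strong
disagreement (4). Over the 25 ordered code pairs the strata have sizes
5/8/6/4/2 — the package's property tests enumerate this exhaustively.
The stratifier refuses more than two raters rather than inventing a
generalization of a pairwise difference. The six-way summary
(`sixway_summary()`) instead splits full agreement by its common level
and lumps *everything* else — including mild agreement — into a single
disagreement slice; both views are emitted because they answer different
questions (how far apart are the checkers vs what do they jointly know).

All percentages use half-up rounding (`percentage()`), not banker's
rounding, with decimals configurable per report (default 1; summaries of
small shares often need 2). This is the convention under which the
package's stratum tables reproduce printed agreement figures exactly,
e.g. 6056/7658 → 79.1 and 8/6056 → 0.13.

## Fleiss' kappa and its instantiations

For N pairs, n raters, l = 5 levels, with n_ij raters assigning pair i
to level j:

$$P_i = \frac{\sum_j n_{ij}^2 - n}{n(n-1)}, \qquad
\bar P = \frac{1}{N}\sum_i P_i, \qquad
p_j = \frac{\sum_i n_{ij}}{nN}, \qquad
\bar P_e = \sum_j p_j^2, \qquad
\kappa = \frac{\bar P - \bar P_e}{1-\bar P_e}.$$

The category-restricted variants — within one category's unordered pair
set, or across the product of two disjoint drug sets — are algebraically
the same statistic on a restricted row set, and the package implements
them exactly that way: `kappa_within_category()` and
`kappa_between_sets()` assemble the restricted counts matrix and call the
one engine. A property test checks this equivalence against a naive
transcription of the formulas on a thousand random matrices to 1e-12.

Numerical choices:

- **Exact accumulation.** All sums run over exact integers (held in
  doubles, far below the 2^53 exact-integer range for any plausible
  catalog); each reported quantity is a single final division, so results
  are bit-reproducible across platforms.
- **Degenerate unanimity.** If every rating lands in one level,
  $\bar P_e = 1$ and κ is 0/0. Observed agreement is then also perfect,
  so the package reports κ = 1 with `degenerate = TRUE`. Subcategory
  pairs in which both checkers answer "not found" everywhere are exactly
  this case, and reporting them as flagged perfect agreement keeps the
  kappa matrix total while letting reports distinguish trivial unanimity
  from informative agreement.
- **Imputation of unrated pairs.** Checkers answer every query; a pair
  absent from a harvested ratings file means both checkers returned "no
  interaction found", not that the pair is missing at random. Enumerated
  pairs without ratings are therefore imputed as mutual level 0 by
  default. The imputation count is carried on every result
  (`n_imputed`), and `impute = FALSE` restricts the universe to rated
  pairs for sensitivity analysis.

### Landis–Koch bands

κ is banded after rounding half-up to two decimals: negative → *poor*,
[0.00, 0.20] *slight*, (0.20, 0.40] *fair*, (0.40, 0.60] *moderate*,
(0.60, 0.80] *substantial*, (0.80, 1.00) *almost perfect*, and *perfect*
reserved for κ exactly 1 before rounding. Banding the rounded value is
what published agreement tables do in practice — it is the only scheme
under which a table can place 0.203 in *slight* and 0.212 in *fair* —
and rounding first makes the 0.20/0.40/... boundaries unambiguous.

### Which universe for the overall kappa?

Two conventions coexist for "the" within-category kappa: all
|C|(|C|−1)/2 unordered pairs, or only the cross-subcategory subset that
excludes therapeutic duplication (two drugs from the same
pharmacotherapeutic subgroup, rarely co-prescribed). At the default
catalog shape these are 9316 and 7658 pairs. Similarly the
category-product analysis can run on the full |C|·|O| product with
imputation or restricted to the rated subset. Rather than privileging
one convention, `run_pipeline()` reports all four overall kappas side by
side, each labelled with its universe size. Likewise, drugs whose full
ATC code list spans several subcategories (niacin sits in both C04 and
C10) are counted in exactly one *primary* subcategory for enumeration —
the convention under which subcategory sizes sum to the category size —
with the full ATC list retained as metadata.

## The synthetic generator

`generator_spec()` describes a two-rater dataset: subcategory sizes for
the catalog, a severity marginal for the first rater, an agreement
probability `a` with which the second rater copies the first, and a
disagreement kernel over signed code offsets for the rest. Offsets that
would leave the 0–4 scale are resampled rather than clamped to the
boundary, keeping the realized offset distribution symmetric for
interior codes instead of piling mass onto 0 and 4; the kernel assigns
no mass to offset 0, so the empirical agreement fraction converges to
`a` itself. One integer seed drives all randomness through a single
generator scope, so identical seeds give byte-identical tables.

The defaults are the study conditions the package's analyses assume: the
published ATC Level-2 subcategory sizes (8 cardiovascular subcategories,
137 drugs; 11 other subcategories, 189 drugs), a marginal of
(0.95, 0.005, 0.03, 0.01, 0.005) over levels 0–4, agreement 0.8, and a
kernel concentrated on +2 (a checker reporting *moderate* where the
other finds nothing is by far the most common real disagreement, making
mild disagreement the dominant non-agreement stratum). Under these
defaults a generated study shows ~75–80% agreement with ~90–95% of
agreements at mutual "not found" — the qualitative signature of real
checker comparisons.

What the generator does *not* emulate: pharmacological structure (which
specific pairs interact), correlation of severity across pairs sharing a
drug, and rater-specific marginals. Passing tests on generated data
therefore validates the statistical machinery — counting, restriction,
conservation, kappa arithmetic — not any claim about real checker
behaviour. Real harvested ratings enter through `read_ratings()` with
per-rater dialect assignments.

## Worked fixtures

Two deterministic fixtures ship both as constructors and as checked-in
text files (so the parsers and the computations are tested against the
same bytes; all drug identifiers are synthetic placeholders):

- `fixture_c07_c04()` — a 13 × 4 subcategory product, half mutual
  level 0, half split 0-versus-2. Hand evaluation: $\bar P = 0.5$,
  column proportions (0.75, 0, 0.25, 0, 0), $\bar P_e = 0.625$,
  κ = −1/3 — agreement worse than chance, the *poor* band. Any single
  fixed non-zero level for the disagreeing half gives the same κ; the
  0-versus-2 choice is the most common real disagreement pattern.
- `fixture_perfect_agreement()` — total agreement with mixed levels
  (κ = 1 non-degenerately) and its all-level-0 variant (κ = 1,
  degenerate).

## Problem sizes and tolerances

The test suite runs the oracle-equivalence property on 1000 random
matrices (N ≤ 20, n ∈ {2, 3}) at 1e-12, generator-recovery checks at
50,000 pairs against 3-standard-error binomial bounds, and conservation
properties across several seeds; the full suite completes in well under
a minute. Band tiling is checked on a 10,001-point grid over [−1, 1].
These sizes were chosen so every statistical bound is sharp enough to
catch a real defect while the suite stays fast enough to run on every
change.

## Limitations

- Strata are defined only for two raters; kappa itself handles any n.
- No weighted kappa and no confidence intervals for κ: the package
  targets the point statistic and its categorical decomposition.
- The package does not fetch or scrape checker websites; it analyzes
  tables you provide.
- Band boundaries follow the rounded-κ Landis–Koch convention; analyses
  requiring unrounded banding should band `glance()$kappa` themselves.
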