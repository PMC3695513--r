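---
title: "Cross-clan overlap analysis of profile-HMM domain hits"
author: "ClanOverlaps authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-clan overlap analysis of profile-HMM domain hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClanOverlaps)
```

## Motivation and model

Homology search with profile-HMMs scores a target region against a family
model and reports an E-value — the expected number of equally good matches
among random, non-homologous sequences. The null hypothesis behind that
E-value treats sequences as i.i.d. draws from a background composition.
Regions under convergent evolution break this assumption not through their
amino-acid *frequencies* but through the way residues are *arranged*:
canonical coiled-coils carry a 7-residue heptad periodicity, and multi-span
membrane proteins alternate hydrophobic and polar stretches. A
zeroth-order bias correction (HMMER3's null2) cannot model such
higher-order structure, so E-values of families rich in these regions can
be systematically optimistic.

A family library with clan annotation offers a database-scale diagnostic
without a structural benchmark. Families in different clans are curated as
unrelated, so a region matching two cross-clan families at a "significant"
E-value is suspicious: either a model was built from non-homologous seeds,
an evolutionary relationship is missing from the clan annotation, or at
least one match is a false positive. This package operationalises that
diagnostic as a pipeline over plain hit tables.

### The overlap rule

Two domain hits on the same sequence form a qualifying overlap when

* their families' *effective clans* differ — a clanless family is treated
  as a clan whose only member is itself (implemented as the deterministic
  identifier `SINGLETON:<accession>`), and
* the intersection of their *alignment* coordinate intervals covers at
  least `min_frac` (default 0.5) of the alignment of at least one of the
  two hits.

Alignment rather than envelope coordinates are used: the envelope includes
every residue with appreciable probability mass and always contains the
alignment, so envelope-based intersection would over-call overlaps from
uncertain boundary regions. The ≥ 50 % coverage requirement discards cases
that small boundary shifts could resolve. Intersections use closed-interval
arithmetic throughout: length = end − start + 1, with 1-based inclusive
coordinates as in the HMMER3 tabular output. Hits enter the analysis when
both their per-domain and per-sequence E-values are at or below the
threshold; the two thresholds are kept equal, which corresponds to
restricting the family universe to those whose curated sequence and domain
thresholds coincide. The per-domain E-value is the *independent* E-value
of the per-domain table — the variant comparable across searches; the
conditional E-value is meaningful only within an already-accepted
sequence.

Hits of the same family never pair (repeat matches along a sequence are
not evidence of miscalibration), and an overlap among three or more
families is represented as all qualifying unordered pairs.

### Winner-takes-all greedy assignment

A domain may overlap several partners, and summing overlaps per family
would count such a domain repeatedly. The greedy resolution attributes
each overlapping domain to exactly one family:

1. for every family, count its member domains involved in ≥ 1 remaining
   pair;
2. select the family with the highest count (ties break toward the
   lexicographically smallest accession — the tie rule is not dictated by
   the procedure itself and is fixed for determinism);
3. attribute those domains to the selected family;
4. delete every pair involving any of them;
5. drop families left with no overlapping domains, and repeat.

Step 4 has a consequence worth stating plainly: a domain whose every
partner belonged to an earlier-selected family disappears *unassigned*.
The attribution is therefore a partial map — each overlapping domain is
attributed at most once, and the per-family counts are not inflated by
double counting. Each iteration removes at least one pair, so termination
is immediate, and because ties break by accession the result is invariant
to the order of the input pair list (asserted by a property test).

The E-value-based alternative (`assignByEvalue`) marks, within each pair,
the hit with the *higher* per-domain E-value as the suspect; the
lower-E-value hit is presumed the genuine match. A domain losing any one
of its pairs is marked once — one confident partner suffices to cast
doubt. Exact E-value ties mark the domain of the lexicographically larger
accession, again purely for determinism.

### Clan counts, curves and labels

After assignment, each surviving family's *overlapping-clan count* is the
number of distinct effective clans over all partners of its attributed
domains; a domain overlapping several clans contributes all of them. The
distinct-union reading is the default because the quantity of interest is
breadth of promiscuity; a per-domain sum (`method = "sum"`) is available
where the total volume of cross-clan contacts matters. Families
overlapping ≥ 2 (or ≥ 3) clans form the "promiscuous" sets used
downstream.

Compositional-bias labels are computed from per-residue predictor output
(segment lists of the kind emitted by ncoils, IUPred and Phobius — running
the predictors is out of scope) clipped to seed-member regions; predicted
residues outside the curated seed regions say nothing about the model and
are ignored. A family is labelled coiled-coil (`cc20`) when ≥ 50 % of its
seed members contain ≥ 20 consecutive predicted coiled-coil residues
(inclusive comparisons at both cut-offs), `cc50` analogously at 50
residues, `dis20` for disorder, and `tmh2` when ≥ 50 % of members have
≥ 2 predicted transmembrane helices intersecting the seed region. A helix
clipped by the region boundary counts if at least one residue intersects —
helices are predictor segments, not residue runs, and per-residue counting
would penalise boundary effects. A seed member without any track record
counts as negative rather than being skipped: missing predictor output is
evidence of absence under every predictor considered here, and skipping
would bias small families toward labels. All four labels are computed
independently (`cc50` implies `cc20` arithmetically); no precedence order
is imposed among them, since a family can genuinely carry several.

Two summaries quantify concentration and enrichment. The *cumulative
overlap curve* ranks families by attributed-domain count (descending, ties
by accession) and accumulates the proportion of all attributed domains;
`familiesForFraction` reads off how many families hold, say, half of them.
The *overrepresentation curve* walks the clan-count ranking and reports,
at each rank x, the proportion of labelled families among the top x
divided by the universe proportion; at x = universe size the fold is
exactly 1, a normalisation identity asserted in the tests.

### Calibration statistics

For N family searches at per-sequence threshold $E_{seq}$ and per-domain
threshold $E_{dom}$, the expected number of false-positive domains is

$$\mathrm{E[FP]} = N \cdot E_{seq} + N \cdot E_{seq} \cdot E_{dom},$$

the first term counting expected false sequence matches across searches
and the second the expected extra false domains inside accepted sequences.
For N = 13,356 and both thresholds 0.01 this evaluates to 134.8956 ≈ 135.
The formula is implemented exactly in this two-term form; no Bonferroni
reinterpretation is applied.

Null2 bias flags mark families where, among hits at E ≤ 0.01, the
fraction with bias/bit ratio > 0.1 exceeds 0.5 — both comparisons
strict; families with no qualifying hit are excluded rather than counted
as unflagged.
`enrichmentFold`/`flagEnrichment` then compare the flag rate inside a
promiscuous set against the universe rate. Residue-level proportions
(`residueBiasProportions`, `conditionalTrackOverlap`) operate on the
per-sequence *union* of pair intersections, so a residue shared by many
pairs counts once.

Finally, `gaToEvalue` converts a curated bit-score gathering threshold x
into a database E-value via the Gumbel form $E = N e^{-\lambda (x-\tau)}$,
with the slope λ and location τ taken from the model calibration (they are
inputs here, not re-derived) and N the database size in sequences.

## The synthetic-data generator

Reference-scale inputs — a full family library searched against a
protein knowledgebase — are not reproducible at desk scale, so validation
rests on seeded synthetic scenarios with planted, exactly recoverable
structure:

* **Promiscuous families.** Each planned family receives, per planned
  partner clan, a distinct partner family and dedicated sequences; the two
  hits on each sequence share ≥ 75 % of their alignment coordinates,
  comfortably beyond the 50 % rule, so detection cannot miss them.
  Partner clans are distinct and differ from the planted family's own
  clan, and partner families are used at most once, so the greedy pass
  must select exactly the planted families and the clan count per planted
  family equals the plan. Plans require ≥ 2 partner clans because a
  1-clan plan makes the planted family and its partner symmetric and the
  recovery target ambiguous.
* **E-value structure.** Planted hits draw E-values log-uniformly in
  $[10^{-10}, 10^{-4}]$, below every analysis threshold, so filtering
  never removes planted structure; background hits draw from
  $[10^{-6}, 10^{1}]$, straddling the thresholds to exercise filtering.
  Background hits sit on disjoint intervals (two windows at least 50
  residues apart per background sequence), so they can never form
  qualifying pairs — the null scenario returns zero pairs by
  construction.
* **Labels.** Planted coiled-coil families receive contiguous
  heptad-multiple runs (4 heptads = 28 residues for `cc20`, 8 = 56 for
  `cc50`) in exactly half of their 4 seed members — deliberately at the
  inclusive ≥ 50 % boundary; other families receive a 14-residue decoy
  run, below the 20-residue cut. Disorder (30 residues) and
  transmembrane (two 21-residue helices) features are planted analogously.
* **Bias scores.** Promiscuous families' hits carry bias/bit = 0.15 for
  75 % of domains (expected), background 0.02, exercising the strict 0.1
  and 50 % cuts.
* **Enrichment planting.** With `cc_fold = f`, promiscuous families are
  labelled coiled-coil with probability $p_p$ (default 0.8) and
  background families with the probability that makes the universe rate
  $p_p / f$ in expectation, so the overrepresentation fold at the
  promiscuous-set boundary is f in expectation; sampling noise is
  averaged over seeds in the corresponding test.
* Accessions, clan ids and sequence ids are generated in sorted order so
  deterministic tie-breaking paths are actually exercised, and all
  randomness flows from one seed: the same configuration writes
  byte-identical files.

What the generator deliberately does **not** emulate: real amino-acid
sequences, HMMER3's forward-algorithm score distributions, correlated
E-values between overlapping hits, or predictor noise. Passing the
recovery tests therefore demonstrates the correctness of the bookkeeping —
detection, resolution, counting, labelling, enrichment — under known
truth, not the biological calibration claims themselves, which require the
database-scale search.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; interval length is
  end − start + 1. Interval algebra (merge, clip, intersect) is delegated
  to IRanges.
* Track normalisation merges overlapping *and adjacent* segments per
  sequence and kind and is idempotent. Adjacent predicted transmembrane
  helices would merge into one segment, but predictors always emit a loop
  between helices, so helix counting on normalised tracks is safe in
  practice.
* Hit identity: each hit gets the key
  `<seq_id>|<family_acc>|<ali_start>-<ali_end>` (exact duplicates are
  disambiguated with a `#k` suffix). Keys are assigned on the input table
  *before* E-value filtering, so a hit keeps its key across thresholds.
* All qualifying-rule comparisons are inclusive (≥) except the two null2
  cut-offs, which are strict (>); the boundary cases
  (coverage exactly 0.5, E-value exactly at threshold, member fraction
  exactly 0.5, ratio exactly 0.1) are each pinned by a test.
* Degenerate inputs are explicit: empty hit tables, comment-only files and
  empty clan maps flow through as empty results; an empty cumulative curve
  or a label universe with a zero-proportion label are errors or `NA`
  folds rather than silent zeros.
* Problem sizes in the test suite — up to 50 hits per random instance
  against the brute-force checker (1000 instances), up to 10 families per
  greedy simulation (200 instances), 20 recovery scenarios of 60 families
  and 30 enrichment scenarios of 200 families — were chosen as the
  smallest sizes that exercise every code path (multi-sequence,
  multi-clan, tie-breaking, boundary fractions) while keeping a full run
  in a few minutes.

## Limitations

* The greedy resolution is a heuristic, not an optimal cover; the
  E-value-based alternative is provided for sensitivity analysis, and on
  real data the two are expected to agree only in trend.
* Clan counts depend on clan annotation quality: a missing clan
  relationship inflates promiscuity, which is precisely the diagnostic's
  ambiguity (false positive vs. undetected homology) and cannot be
  resolved from hit tables alone.
* Labels depend on the external predictors' segment output; the package
  neither runs nor re-calibrates them.
* The expected-false-positive formula assumes independent searches and
  exact E-value calibration — its role is to provide the baseline against
  which observed overlap counts look excessive, not a fitted model.
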