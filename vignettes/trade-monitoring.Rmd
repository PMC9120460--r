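---
title: "Monitoring the arachnid trade: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring the arachnid trade: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arachnotrade)
library(dplyr)
```

## The problem

Most of the global trade in arachnids — tarantulas, scorpions, whip
scorpions — happens outside any systematic monitoring. Import ledgers such
as LEMIS (the US Fish & Wildlife Service's declared-import database) and
the CITES trade database cover only the species that cross a regulated
border under a recognised name; online shops and classified listings carry
far more species, frequently under junior synonyms, colloquial colour
names, or `"sp."` plus a locality. Estimating what is actually in trade
therefore means combining three very different evidence streams:

1. **text corpora** of saved shop pages, searched for every name a species
   has ever carried;
2. **import records**, classified by what was shipped (whole individuals
   or parts), why (commercial or not), and where it came from (wild,
   captive, seized);
3. **range assertions** — textual statements of distribution — digitised
   to country level so trade exposure and single-country endemism can be
   mapped.

`arachnotrade` implements that pipeline as composable functions over data
frames, with a seeded synthetic-data generator so every stage can be
validated against known ground truth without any downloads.

## Name resolution

The unit of identity is the *accepted name* under a reference checklist.
`load_checklist()` reads one row per accepted species, drops trinomials
(subspecies), and repairs abbreviated-genus synonyms ("G. rosea") by
substituting the first genus in the listing whose initial matches —
the same convention synonym listings themselves use. `build_name_index()`
then indexes every name (accepted and historical) after normalisation:
lower-case, authorities in parentheses stripped, non-alphanumeric
characters collapsed to single spaces. Shop text never carries
authorities, and diacritics are matched byte-for-byte after lower-casing —
collation-aware matching buys almost nothing for scientific names and
costs a great deal.

Names are grouped into *genus buckets* keyed by every leading token a
species has ever had: if a species ever belonged to a genus, a mention of
that genus triggers a search for the species' full names. Homonyms (one
name, two accepted species, e.g. across the spider and scorpion
checklists) are never silently dropped: all candidates are kept in a side
table, the resolution map flags the name as ambiguous, and a warning is
raised. *Nomen dubium* names stay in the search space by default but are
tagged, since doubtful application is a reason to annotate, not to stop
detecting.

## The matcher

Pages are cleaned (`clean_html()`) by stripping markup — including
`<script>`/`<style>` contents — and replacing every character that is not
a Unicode letter or digit with a space, collapsing runs. The operation is
idempotent and preserves casing (matching is case-insensitive; context
exports keep the original text).

`hierarchical_search()` is a two-stage fixed-string search. Stage one
finds genus tokens with a **left word boundary only**: the token must be
preceded by a space (or page start) but may continue to the right, so
genus "Neon" matches "Neonate". That asymmetry is deliberate. Short genus
names colliding with word stems is the dominant false-positive mode, and
it is *visible*: a genus with genus-only hits and no species hit anywhere
in the corpus is a removal candidate, which is exactly what the audit
report of `filter_spurious()` lists and what the shipped blocklist of 20
tokens encodes. A strict both-boundary mode exists behind a flag for users
who prefer precision over that auditability. Stage two searches, for every
mentioned genus, each full name in its bucket page-wide; a species match
requires the full binomial as a contiguous string (abbreviated or split
binomials are intentionally *not* repaired — fidelity beats recall, and
the miss modes are documented rather than patched).

The genus pre-filter is purely an optimisation: a property test asserts
that the species-detection set equals a brute-force scan of every indexed
name against every page, on hundreds of randomised corpora.

Every detection row is one genus mention carrying its context window — up
to 3 tokens before and 4 after. Species-level summaries collapse to one
row per page and name (`distinct_species_detections()`); colour counting
keeps full multiplicity, because mention counts are the unit there.

## Colour co-occurrence

Novelty sells: listings append colours ("Electric Blue") or localities to
genus names, sometimes marking undescribed forms already in trade.
`count_colour_cooccurrence()` lower-cases each context window, removes
stop words, and intersects the remainder with a colour lexicon (a packaged
single-word colour list minus terms that are only ambiguously
colour-related — "web", "jungle", "sea", …). Each *distinct* colour in a
window counts once per genus mention; a raw-multiplicity mode exists
behind a flag. Colours are matched as unigrams: cleaning destroys
punctuation but preserves adjacency, and compound colour names contribute
their informative head word ("electric") on its own. A window of 7 tokens
bounds the per-mention contribution, which the tests assert as an
invariant.

## Trade-record classification

LEMIS summaries follow three fixed rules, applied in this order:

* **Whole individuals first.** Only description codes BOD, EGL, DEA, LIV,
  SPE, SKI, TRO (dead animal, live eggs, dead specimen, live specimen,
  specimen, whole skin, entire trophy) enter individual counts; parts and
  derivatives would double-count animals. Every percentage below uses this
  filtered, quantity-weighted denominator.
* **Source.** W is wild; C, F, D, R (captive-bred, born in captivity,
  commercially bred, ranched) are captive; anything else — including blank
  — is *other*. The three classes partition the total exactly (a test
  invariant).
* **Purpose and disposition.** M, S, Y (biomedical, scientific,
  reintroduction) are non-commercial; everything else commercial.
  Disposition S marks seized shipments.

Genus summaries exclude placeholder genera ("Non-CITES entry", missing).
Missing quantities are zeroed with a logged count; negative quantities are
rejected. `nonnative_wild_exports()` joins wild-sourced records to
digitised ranges to flag individuals exported from countries where the
species is not native — species without range data land in an *unknown*
bucket rather than being branded non-native.

Species membership for the cross-source overlap uses **all** LEMIS
records, not only whole-individual rows: whether a species appears in the
ledger is a name question, while the whole-individual filter exists to
make counts of individuals meaningful.

## Integration conventions

`combine_sources()` builds one profile per accepted species under either
the `"any"` basis (matches through any historical name; used for broad
summaries) or the `"exact"` basis (current names only). The undated
contemporary snapshot is its own year class: snapshot-only species are
excluded from lag statistics and counted separately, because their first
trade year is unknown, not zero. The lag for a species described after the
cutoff (default 1999) is first dated detection year minus description
year; negative lags — detection under a name before its formal
description year, which genuinely occurs — are retained and flagged.
"Unique to a year" means the species' entire dated detection set, pooled
across sources, is that single year. Per-site richness is averaged over
sites with at least one detection (SE = sd/√n), with the all-sites mean
also reported, since either denominator is defensible.

## Range digitisation

Assertions come in four kinds, each handled literally: a *country* is
standardised against a reference table (names plus aliases,
case-insensitive; unmatched names go to a correction worklist, never
dropped silently); a *region* expands through a shipped, editable
region-to-countries map; an *island* is replaced by its sovereign country;
a *"to" span* expands geometrically. For spans we compute the convex hull
of the centroids of all listed areas' countries and add every country
whose centroid lies inside or on the hull (a hand-rolled sign-consistent
cross-product test, so boundary points count as inside). This
**centroid-in-hull rule approximates** full polygon intersection: it needs
no border geometry, behaves identically at continental scale, and
degenerates safely — fewer than three distinct or collinear centroids
yield exactly the listed set, and spans wider than 180° of longitude
(antimeridian-crossing) are flagged rather than mapped. Coordinates are
decimal degrees on the raw lon/lat plane; no projection is applied.

Endemism is cardinality-one of the digitised country set — a proxy for
vulnerability, not a biogeographic claim. `country_trade_summary()` also
offers the "popular groups" variant that drops genera with two or fewer
traded species before computing percentages.

## The synthetic study

The generators exist so the pipeline's guarantees are *testable*, and
their defaults are the study conditions:

* **Registry** (`gen_registry()`): pseudo-binomials from syllable
  alphabets disjoint from real genera and from the blocklist; genus and
  epithet alphabets are disjoint from each other and fixed-length, so no
  token is a proper prefix of another and an epithet can never trigger a
  genus match. Synonym counts are Poisson with mean 0.81, giving ≈1.8
  names per species, the level real checklists with synonymy show; half
  the synonyms are cross-genus moves and a configurable fraction are
  written abbreviated to exercise the repair.
* **Corpus** (`gen_corpus()`): pages plant accepted names or synonyms,
  colours adjacent to genus tokens (probability 0.3), `"sp."` + locality
  listings, and decoys, with listings spaced so every planted colour falls
  in exactly one context window — making planted colour counts exact
  ground truth. Adversarial mode adds left-boundary traps and split
  binomials that must surface as genus-only mentions, never species.
  Dated pages only list species already described by that year.
* **Imports** (`gen_lemis()`): 10,000 records whose code frequencies echo
  real arachnid ledgers (live-specimen dominated, ~67% wild, seizures at
  0.34%, ~92% commercial), drawn from a species pool covering 25% of the
  registry — import ledgers see far fewer species than online listings,
  and that asymmetry is what makes online-only species the dominant
  overlap class. Shipments never precede description years.
* **World and ranges** (`gen_world()`, `gen_ranges()`): countries sit in
  well-separated longitudinal clusters, one region per cluster; span
  assertions always list a whole cluster, so the planted country sets are
  exact truth independent of the hull code they test.

What the generator does **not** emulate: multilingual pages, market
dynamics over time, duplicated or fraudulent listings, name misspellings,
and real-world ambiguity in range statements. Passing the recovery tests
therefore demonstrates correctness of the machinery under clean
conditions, not robustness to messy real inputs — the fidelity tests on
constructed fixtures (left-boundary behaviour, split binomials, synonym
masking) cover the known messy modes the method deliberately inherits.

Problem sizes used throughout the test suite and the acceptance script —
120 species in 25 genera, 8 sites × 4 pages × 4 species, 10,000 import
records — were chosen as the smallest study at which every overlap class,
both snapshot classes, and all four assertion kinds are well populated.

## Reproducibility

Every generator takes an explicit seed and is fully deterministic across
platforms (no reliance on hash ordering); `run_pipeline()` is a pure
function of its inputs and configuration, writes every summary as CSV,
and records an md5 per output in a run manifest, so identical runs are
bit-identical. `scripts/acceptance.R` regenerates the whole synthetic
study from one seed and reports the headline quantities as JSON.

```{r example, eval = FALSE}
study <- generate_study(tempfile(), seed = 1)
res <- run_pipeline(study$config)
glance(res$profiles)
attr(res$lags, "summary")
endemism_summary(res$ranges)
```

## Known limitations

* Species matching requires contiguous binomials; abbreviated and split
  names on real pages are missed by design, and counts are lower bounds.
* The homonym tie-break (alphabetically first candidate, flagged) is a
  reporting convention, not a taxonomic judgement.
* Centroid-in-hull can differ from polygon intersection for spans whose
  hull clips a large country's territory without containing its centroid;
  supplying border polygons would remove the approximation but is out of
  scope here.
* Colour counting is unigram-only by default; truly compound colour names
  count as their component words.
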