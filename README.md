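# arachnotrade

Tools for quantifying the trade in arachnids — tarantulas, scorpions,
whip scorpions — by combining three evidence streams that individually
miss most of it: online shop text, US import records (LEMIS), and the
CITES trade database.

The trade in these animals is large, mostly wild-sourced, and mostly
invisible to regulatory databases: shops list species under junior
synonyms, colloquial colour names, or `"sp."` plus a locality, and import
ledgers see only what crosses a regulated border under a recognised name.
`arachnotrade` is a tidyverse-style R implementation of a monitoring
pipeline for exactly this situation. Every user-facing function takes a
data frame and returns a tibble, so stages compose with the pipe.

## What the package computes

**Name index.** From taxonomic checklists with synonym histories, a
case-insensitive index of every name a species has ever carried
(`load_checklist()`, `build_name_index()`, `resolve_names()`), with
abbreviated-genus synonyms ("G. rosea") repaired by first-initial match
and homonyms surfaced rather than dropped.

**Hierarchical keyword search.** Cleaned pages (`clean_html()`:
markup stripped, non-alphanumerics to single spaces) are scanned
genus-first, then only the full names ever housed in a mentioned genus
are searched (`hierarchical_search()`). Matching is case-insensitive
fixed-string with a left word boundary only — genus *G* at token *t*
matches iff *t* starts with *G* and is preceded by a space:

```
match(G, t_i)  ⇔  startsWith(lower(t_i), lower(G))       (genus stage)
match(G s, i)  ⇔  lower(t_i) = lower(G) ∧ startsWith(lower(t_{i+1}), lower(s))
```

The genus pre-filter never changes semantics (property-tested against a
brute-force all-names scan). Each detection carries a 3-before/4-after
context window; `filter_spurious()` removes blocklisted genus-only hits
and emits an audit of review candidates.

**Colour co-occurrence.** `count_colour_cooccurrence()` intersects
context windows with a packaged colour lexicon (minus ambiguous terms)
after stop-word removal — one count per distinct colour per genus
mention, a signal of colour-morph and possibly undescribed diversity in
trade.

**Trade-record classification.** `read_lemis()` /
`summarise_lemis()` restrict to whole-individual description codes
{BOD, EGL, DEA, LIV, SPE, SKI, TRO}, then compute quantity-weighted
percentages by source (W → wild; C, F, D, R → captive; else other),
purpose (M, S, Y → non-commercial) and seizure (disposition S), plus
per-genus wild fractions and per-origin totals;
`nonnative_wild_exports()` flags wild-sourced exports from countries
outside a species' digitised range. `read_cites()` harmonises
gross-imports exports through the same name index.

**Integration.** `combine_sources()` builds per-species profiles across
online/LEMIS/CITES under exact or any-name matching;
`count_source_overlap()`, `species_per_year()`, `description_lag()` and
`per_site_richness()` give the overlap, trend, description-to-trade lag
and per-site richness summaries.

**Range digitisation.** Textual range assertions (country, region,
"A to B" span, island) become standardised country sets
(`build_country_ranges()`); spans expand through the convex hull of
listed-area centroids (boundary-inclusive). `country_trade_summary()` and
`endemism_summary()` give per-country trade exposure and single-country
endemism.

**Synthetic studies.** Seeded generators (`generate_study()` and the
`gen_*()` family) produce checklists, shop corpora, import records and
range assertions with recorded ground truth, so the entire pipeline is
testable offline; `run_pipeline()` runs everything from one validated
config and writes CSV summaries plus a hashed run manifest.

## Worked example

```r
library(arachnotrade)

study <- generate_study(tempfile(), seed = 1)   # synthetic study, seeded
res <- run_pipeline(study$config)

glance(res$index)
#>   n_species n_names n_genus_tokens n_ambiguous mean_names_per_species
#> 1       120     228             30           0                    1.9

res$lemis
#> <lemis_summary> 447,253 whole individuals; 67.2% wild, 30.0% captive, 0.264% seized

glance(res$profiles)
#>   n_species n_online n_lemis n_cites n_online_only pct_online_only n_all_three
#> 1        87       74      30       6            52            59.8           1

attr(res$lags, "summary")[1, ]
#>   group     n mean_lag sd_lag n_within_1yr n_same_year n_snapshot_only
#> 1 all      11     4.55   6.01            6           5               0

endemism_summary(res$ranges)
#>   n_species n_endemic pct_endemic pct_under_5
#> 1       120        56        46.7         100
```

Reading this run: 120 generated species carry 228 names (≈1.9 names per
species, synonymy included). The matcher recovered 74 species from the
shop corpus; combined with the import ledger (30 species) and the CITES
table (6), 87 species are in trade and 59.8% of them appear *only*
online — the core argument for corpus-based monitoring. Of the filtered
import quantity, 67.2% is wild-sourced and 0.264% seized. Species
described after 1999 first appear in dated trade a mean of 4.55 years
after description, and 46.7% of species have a single-country range —
the trade-vulnerable class.

## Documentation

The methods vignette (`vignettes/trade-monitoring.Rmd`) explains the
matching semantics, the classification rules, the centroid-hull range
approximation, the synthetic-study design and its limits.
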