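---
title: "Curating and analysing host-preference records for holoparasitic plants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and analysing host-preference records for holoparasitic plants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostrange)
```

## The problem

Host preference underpins the ecology, distribution and conservation of
parasitic plants, yet for holoparasites it is documented almost entirely
through heterogeneous secondary sources: protologues, floras, monographs,
herbarium sheets and public observation databases. A single "host record"
may be anything from a verified excavation showing haustorial contact to a
guess at the nearest plant in a photograph. `hostrange` implements a
complete pipeline for this situation: an explicit record schema, a
deterministic confidence-rating rule engine, contextual filtering into an
analysis set, host-specificity and host-convergence statistics,
extent-of-occurrence geometry, and phylogeny-ordered interaction matrices —
together with a synthetic-data generator so each stage can be tested
against known ground truth.

## The record model

One row is one independent report of a parasite on a host. Repeated reports
under new references are new records; repeats that merely reiterate an
earlier publication are a curator judgement and are therefore only
*flagged* by `deduplicate_records()`, never removed automatically — the
automatic key (parasite species × host species-or-family × reference)
collapses exact duplicates only. Host names are assumed pre-resolved; the
package performs no synonymy matching. The reader accepts one row per
record (not one row per parasite–host pair with a reference list), column
order free, names fixed, empty string meaning missing.

## The confidence rule engine

Each record carries eleven boolean evidence flags. The engine assigns
exactly one rating per record. The criteria are, by rating:

* **High** — H1 excavated with host contact confirmed; H2 reported by an
  expert in the group; H3 herbarium sheet carries identified host material;
  H4 database observation with the connection visible in a photo.
* **Medium** — M1 direct report where excavation is unclear (the host may
  simply be the nearest plant); M2 published before 1950 without explicit
  excavation; M3 herbarium sheet names a host but carries no material; M4
  database observation with the host visible in a photo *or* whose host
  genus already has a high-rated record for this parasite.
* **Low** — L1 the author flags the report as dubious; L2 an unconfirmed
  report from a family unrelated to every other recorded host of the
  parasite; L3 a database observation without a photo whose host genus has
  no high-rated record.

The source criteria come unordered, so the engine fixes a precedence as its
own design choice, chosen to be conservative (never silently high):
P0 dubious → low; P1 any high criterion, except that *pre-1950 without
explicit excavation caps the result at medium* regardless of which high
criterion fired; P2 medium criteria; P3 low fallbacks; P4 a logged medium
default ("unmatched-evidence"). Two further operationalisations were
needed:

* **"Completely unrelated" (L2)** is read at order rank: the record's host
  family shares no order with any *other* host family recorded for that
  parasite. Order is the finest rank always present; a sole recorded
  family or an unknown order never counts as unrelated.
* **M1 versus L2.** Because medium criteria are evaluated before low
  fallbacks, an unrestricted "excavation unclear" criterion would make L2
  unreachable. M1 therefore applies only to non-database, non-herbarium
  reports whose host family *is* order-related to the parasite's other
  hosts; the unrelated complement falls through to L2.

Context is built in a first pass that applies only context-free rules
(pre-set high ratings also contribute), so the second, contextual pass is
deterministic and independent of record order — there is no fixed-point
iteration. Totality and determinism are enforced by an exhaustive test over
all valid flag combinations in all context states, and a property test
checks monotonicity: adding a high-rated congeneric host record can raise
but never lower another record's rating.

## Filtering into the analysis set

All low-confidence records are dropped. A parasite species whose entire
remaining record set is one medium-confidence report is excluded, unless
that report's host family features in a high-confidence record of at least
one *other* parasite species of the same genus, in which case it is kept
and the rescue logged. "Only one medium report" is read as *exactly one
record total, and it is medium*: a species with one medium and one high
record is kept, since the high record alone justifies retention. The
composition is idempotent, every removal is logged, and the published base
count this step was reported against differs slightly from the arithmetic
of the published tallies (2742 vs 2847 − 94 = 2753, presumably reflecting
upstream exclusions we cannot observe); the pipeline therefore always
reports its own base count and does not force agreement.

## Specificity and convergence statistics

Profiles count unique host names per parasite at species, genus and family
rank. Hosts identified only to genus count at genus and family rank; only
to family, at family rank alone — partial identification never creates
phantom names, so the monotonicity S ≥ G ≥ F is guaranteed only for
parasites whose hosts are all identified to species, and is tested there.
Medians are the standard order-statistic median (mean of the two central
values for even *n*), per lineage and overall.

The distribution plots and medians use a *well-supported subset*: a
parasite is kept iff some host species has at least two records for it or
it has a high-confidence record. The source caption can also be read as
"two records overall"; the literal same-species reading is the default and
the alternative is available as `rule = "overall"` without being endorsed.

Extreme specialists have a single exclusive host species, all records
identified to species, and that host either recorded twice or backed by a
high-confidence record; extreme generalists have hosts in six or more
families. The flags are mutually exclusive by construction.

Host-side statistics are plain distinct counts per host family (parasite
species, genera, lineages), per lineage (host-family breadth), per clade,
per Asteraceae tribe and per habit class. Disproportionality is
(parasite share) / (diversity share); a group whose parasite share equals
its diversity share scores exactly 1. Clade and tribe maps ship as
editable CSV config (`inst/extdata/host_clades.csv`,
`inst/extdata/asteraceae_tribes.csv`) rather than hard-coded tables,
because classifications change and the analysis should not. Habit
proportions count each host species once (most frequent habit wins, ties
alphabetically), with records not identified to species contributing
family-level "unknown" entries; record-level countings are exported
alongside.

## Extent of occurrence

EOO is the area of the minimum convex polygon around a species'
occurrences. Points are projected with a Lambert azimuthal equal-area
projection on the WGS84 authalic sphere (R = 6371.0072 km), centred on the
point centroid — the behaviour of rapid-conservation-assessment tooling —
and the planar hull area is returned in km². The projection centre uses
the circular mean of longitudes, which re-centres antimeridian-spanning
clouds without special-casing. Fewer than three distinct non-collinear
points give area 0 with a `degenerate` flag, and the specificity join uses
`log10(area + 1)` so those species remain plottable at 0. Tests compare
the implementation against an independently coded spherical-excess oracle
(l'Huilier fan triangulation on the same sphere): agreement is within 1 %
for polygons spanning up to ~10°, and the equatorial 1°×1° right triangle
reference case is ≈ 6182 km². Exact agreement with any particular
conservation-assessment package version is not chased; the projection is
fixed and documented instead.

## Interaction matrices

The presence matrix links parasite genera (rows, grouped by lineage) to
host families (columns) from the analysis set. Columns follow the
left-to-right tip order of the supplied family-level phylogeny as written
in the newick — no ladderization, since display order is cosmetic — with
families absent from the tree appended after the ordered columns and
reported, never dropped. Name matching is exact after whitespace and case
normalization. Top-host rankings sort by parasite-genus count with ties
broken by lineage count, then name. A cross-module test asserts that row
sums equal the genus-level aggregation of the specificity profiles.

## The synthetic generator

`generate_host_data()` emulates the *structure* of a curated holoparasite
host-record database; it is explicitly not fitted to the real data. Its
defaults are fixed once as the package's study conditions:

* nine lineages × 5 genera × 8 species (360 parasites, close to the ~370
  holoparasites with data);
* host taxonomy of 60 eudicot, 15 monocot and 3 gymnosperm families (4
  genera × 5 species each), with clade sampling weights 1 : 0.02 : 0.01 so
  monocot and gymnosperm hosts are as rare as observed;
* host-range sizes from a zero-truncated negative binomial with mean 5 and
  dispersion 1.2 — right-skewed counts ≥ 1 whose median sits well below
  the maximum, mirroring the skewed specificity distributions with few
  generalist outliers — plus a 3.5 % generalist branch drawing hosts from
  ≥ 6 families (13/373 ≈ 3.5 % extreme generalists in the curated data);
* a confidence mixture (3.3 % low, 72.7 % medium, 24.0 % high) matching
  the curated tallies 94/2071/682 of 2847;
* 90 % of records identify the host to species, 8 % to genus only;
* evidence flags generated so that *exactly one* classification rule fires
  per record (high → H1, medium → M3, low → L1), which makes engine
  agreement a sharp, all-or-nothing test;
* occurrence points uniform in a spherical disc of radius 50–1000 km
  around a random centre, so the hull area is bounded above by the known
  cap area.

What the generator does **not** emulate: taxonomic synonymy and name
errors, geographic sampling bias, correlated evidence (real records often
satisfy several criteria at once), reiterated reports across references,
and spatial clustering of occurrences. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct under its stated
assumptions, not that the curated database itself is accurate.

Parameter recovery (`recovery_report()`) measures: the overall
median-host-range error (within ±1 at 300 parasites across ten seeds);
specialist/generalist precision and recall against the true host sets
(exactly 1 under the no-noise configuration: all-high confidence and full
species-rank identification — with identification noise on, specialist
recall drops by design, since a genus-rank record hides an exclusive
host); confidence-rule agreement (100 % under one-rule evidence); and the
hull-within-disc containment of EOO. Test and acceptance runs use 48–360
parasite configurations, sizes chosen to exercise every code path while
keeping the default suite fast.

## Degenerate inputs and numerical choices

Empty record sets flow through every summary as empty tibbles; empty point
sets are an error. Unknown habit or record-type vocabulary falls back to
`unknown`/`other` with a warning (an error under `strict`). Records with
neither evidence nor a pre-set rating are reported, not guessed. Ties in
habit assignment and top-host ranking are broken deterministically
(frequency, then lexical). All randomness in the generator flows from the
single config seed; there is no hidden global RNG state left behind
(`withr::local_seed`).

## Known limitations

The rule precedence and the order-rank reading of "unrelated" are the
package's own resolutions of genuinely open wording; both are surfaced as
documented choices and stable rule identifiers rather than buried
behaviour. Dedup never removes cross-reference reiterations, which can
leave true duplicates when the same observation was published twice under
different references. EOO ignores coordinate uncertainty and sampling
bias, and a convex hull can include large uninhabited areas for disjunct
ranges. The published host-record database itself is not distributed with
the package; the four reproduction tests that need it fail with an
explanatory message until a copy is supplied in the documented schema.
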