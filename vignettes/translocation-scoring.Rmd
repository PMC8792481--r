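---
title: "Genetic suitability scoring for lion translocations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic suitability scoring for lion translocations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liontrax)
```

## The problem

Lions (*Panthera leo*) are translocated frequently — for reintroduction,
population augmentation, conflict management and commercial reasons — and the
choice of source population has genetic consequences that persist for
generations. The species carries a strong continental phylogeographic
structure: six mtDNA haplogroups (West, Central, North East, East/Southern,
South West, India) and a coarser nuclear-clade structure (West, Central,
East, Southern, India) that maps onto the two recognized subspecies,
*P. l. leo* (West and Central Africa plus India) and *P. l. melanochaita*
(East and Southern Africa). Translocations that ignore this structure risk
homogenizing clades, eroding local adaptation, and — in the worst case —
mixing subspecies.

`liontrax` implements a rule-based decision framework over this structure:
a clade-annotated registry of lion conservation units (LCUs), a hierarchical
source/target suitability classifier, and a classifier for historical
live-lion trade records from the CITES Trade Database, so that four decades
of recorded international movements can be audited against the genetic
guidelines.

## The suitability rules

For a source and a target unit, each carrying a set of mtDNA labels and a
set of nuclear-clade labels, the level is decided by precedence:

1. **India exclusion.** If exactly one side is the Indian nuclear clade, the
   pair is `NO_OPTION`, regardless of the shared subspecies: the Indian
   population is strongly differentiated and bottlenecked, and movements in
   either direction are excluded. This rule is evaluated first so that it
   can never be bypassed by the shared-subspecies path.
2. **`FIRST`** — shared nuclear clade and shared mtDNA haplogroup.
3. **`SECOND`** — shared nuclear clade, differentiated mtDNA.
4. **`THIRD`** — different nuclear clades within *P. l. melanochaita* only.
   Within *P. l. leo* the analogous cross-clade move (West ↔ Central) is
   `NO_OPTION`: the third tier is explicitly unavailable for the northern
   subspecies, whose populations are small, fragmented and more strongly
   differentiated.
5. **`NO_OPTION`** otherwise (cross-subspecies, or unknown origin).

"Shared" is non-empty set intersection throughout. This is what lets the
Kavango–Zambezi units, which naturally carry both the South West and
East/Southern haplogroups on a single Southern nuclear background, score
`FIRST` against either parent haplogroup — an overlap of mtDNA clades that
is deliberately *not* treated as a suture zone, because it is invisible in
nuclear data.

### Suture zones and directionality

Two natural suture zones are encoded: SZ1 (Sudan, South Sudan, Ethiopia;
Central × East nuclear overlap, spanning both subspecies) and SZ2 (Zambia,
Malawi, Mozambique; East × Southern). Around them the matrix is
intentionally asymmetric:

* **into** a suture zone, from a source sharing one of the overlapping
  clades, is scored *best-case* over the zone's component clades
  (`suture_into` flag);
* **out of** a suture zone is scored *worst-case* over the components
  (`suture_from` flag), because emigrants may be natural inter-clade
  hybrids;
* two units in the **same** zone score `FIRST` — the recommended practice
  of sourcing from within the zone itself.

The component profiles are defined per nuclear label, each carrying the
unit's full mtDNA set: country-scale inputs do not pair individual
haplogroups with nuclear clades, so a finer decomposition would be
invented precision. The published per-cell scores around suture zones live
in supplementary tables that state only the qualitative rule; cells where a
different operationalization could disagree carry the directionality flags
so downstream users can see exactly where the rule fired. Movement between
*different* suture zones keeps the base level with no flag — no direction
is defensible there. For SZ1, a rationale note recommends prioritizing
*P. l. leo* individuals; this is advisory, not a level change.

### Hybrid populations

Units affected by human-mediated admixture (the Kruger area and managed
metapopulation in South Africa, Zimbabwe, Eswatini, Rwanda, restored
Malawi, and Lake Nakuru–Soysambu in Kenya) keep their computed level but
carry a `hybrid_source` flag — the "faded" marking. A faded source is not a
fifth level: such populations may be usable given per-individual genetic
testing, and collapsing them into `NO_OPTION` would hide that option from
managers. Hybrid records keep their nominal clade labels plus the
introgressed mtDNA labels, which is why, e.g., Rwanda's restored population
carries both East/Southern and South West haplogroups.

## The CITES audit

The trade module reads comparative-tabulation exports, keeps live-term lion
records imported into range states in 1983–2019 with purpose in
`{N, T, B, H}` and source in `{W, F, R, C, blank}`, reconciles quantities as
the *maximum* of importer- and exporter-reported numbers (permits record
intended maxima), and consolidates four trade categories (wild/captive ×
reintroduction/commercial).

The South African managed metapopulation — wild-managed lions in small
fenced reserves, permit-coded inconsistently as wild or captive — is
recovered by a fixed clause precedence: explicit override rows first (an
auditable table with year ranges and citations, shipped with the Rwanda
restocking case), then `F`/`R` → `W2`, South African `W` after 2005 → `W2`,
South African blank source before 1995 → `W1` and from 1995 → `W2`, then
plain `W` → `W1`, `C` → `C`, else `U`. The mid-1990s cutoff is fixed at
1995 (reserves date from 1991; captive facilities were rare before 1994)
and is configurable; the `F`/`R` clause applies to all exporters by default
(the rule as stated is unscoped) with a switch restricting it to South
Africa for sensitivity analysis. Unknown (`U`) records are grouped with
captive for category purposes, mirroring how the audit folds its two
unknown-origin individuals into the captive tally.

Scoring joins each record to country profiles: the genetic attribution
country is the origin column when present and different from the exporter
(re-exports move through transit countries), else the exporter. Captive and
unknown individuals are `NO_OPTION` without exception; `W2` individuals are
reported as their own, parallel class (not folded into the four levels) and
flagged as hybrid-source, since the metapopulation mixes East/Southern and
South West haplogroups. Multi-clade countries make a record's suitability a
*best/worst* interval over the cartesian product of candidate LCU pairs;
summaries use the best case and retain the worst, and the scenario analysis
(`assume_country_clade_for_captive`) turns the captive `NO_OPTION` block
into a bounded range — the two bounds differ exactly when a multi-clade
release country (a DRC import, say) is in play.

Percentages are rounded to whole percent for parity with how such audits
are reported; raw fractions are always emitted alongside.

## The synthetic generators

Real permit tables and the full 132-unit registry are supplementary
artifacts, so the package ships seed-controlled generators whose sidecar
ground truth makes every stage testable record by record.

`simulate_registry()` draws clade labels from a synthetic vocabulary,
suture-zone units as two-nuclear-label profiles, hybrid units as
extra-haplogroup profiles, and real ISO country codes. `simulate_trade()`
constructs permit codes that deterministically produce each record's
intended class under the adjustment clauses (e.g. intended `W1` South
African rows are dated 2005 or earlier), with opt-in injection of malformed
and out-of-scope rows for filter accounting. The ground truth is emitted as
a sidecar aligned to file row order, never re-derived from the code under
test.

`replication_profile()` mirrors the audited composition in expectation:
class weights `C = 0.729`, `OVERRIDE = 0.074`, `W2 = 0.028`, `W1 = 0.167`,
`U = 0.002` reproduce the published count ratios (848/1056 captive-coded on
raw permits, 772/1056 no-option after adjustment, ≈10% `W2`), with South
Africa dominant in both the exporter pool (≈32% of exports) and the
importer pool (≈60% of imports), and permit quantities following a
truncated geometric law with mean ≈ 2 (small consignments typical of
live-animal trade, capped at 25). The importer pool for this profile covers
the southern/eastern range states the recorded flows actually enter. What
the generator does *not* emulate: year-by-year trade dynamics, unreported
or illegal movements, within-country translocations, and the real
correlation structure between exporter, importer and purpose — so passing
composition checks demonstrate the pipeline's accounting, not historical
fidelity beyond the published margins.

## Numerical and design choices

* **Determinism.** All generators are parameterized by a single integer
  seed; identical parameters and seed give byte-identical outputs, and
  report export writes no timestamps, so fixed inputs give byte-identical
  reports.
* **Problem sizes.** The exhaustive decision-tree check enumerates all 2401
  ordered pairs of non-empty label-subset profiles over a 3 × 3 vocabulary
  with an India analogue, plus suture/hybrid flag combinations; synthetic
  recovery runs at 10,000 records; composition checks at 1056 records.
  Each completes in seconds on one CPU.
* **Composition checks on records.** The ±3-point bands for the
  replication-profile shares are binomial sampling error at n = 1056
  i.i.d. draws; the generator's i.i.d. unit is the permit record, so the
  checks measure record-level shares. Quantity-weighted shares are
  unbiased for the same values but carry roughly 2.4× the variance under
  the quantity law.
* **Degenerate inputs.** Empty registries and header-only trade files are
  errors where an answer would be meaningless (matrix of nothing) and
  empty-but-valid results where a tally is meaningful (zero-record
  summaries are all-zero). Zero-quantity records are excluded with a tally,
  not errors.
* **Ties.** Country-level cells take flags from the first LCU pair
  attaining the best level (axis order), keeping the into/out-of-zone flags
  mutually exclusive by construction.
* **Country codes.** ISO-3166 alpha-2 with an alias table for informal
  names ("RSA" → ZA, "DRC" → CD); a handful of retired codes that appear in
  historical CITES reports are accepted.

## Known limitations

The packaged registry is a **country-level approximation** encoding the
facts stated in the continental synthesis; it is not the full 132-unit
table, and within-country structure (the Nigerian and Kenyan splits are
encoded; finer structure in Tanzania or Zambia is not) is coarser than what
a manager planning a specific translocation should use. Clade assignments
are inputs, not inferences — no sequence data are analysed. The audit
counts permit-intended maxima, not realized movements, and whether
historical tallies weighted importer- or exporter-reported quantities when
both exist is not recoverable from the published text; the package uses the
maximum, with an exporter-preferred alternative behind a switch. Ecological,
behavioural and socioeconomic dimensions of translocation planning are out
of scope by design.
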