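# liontrax

Genetic decision support for lion (*Panthera leo*) conservation
translocations, and a rule-based audit pipeline for four decades of
recorded international live-lion trade.

## The problem

Lion populations carry a strong continental phylogeographic structure: six
mtDNA haplogroups (West, Central, North East, East/Southern, South West,
India) over a nuclear-clade structure (West, Central, East, Southern,
India) that maps onto the two subspecies — *P. l. leo* (West/Central Africa
and India) and *P. l. melanochaita* (East/Southern Africa). Translocations
that ignore this structure risk homogenizing clades and, at worst, mixing
subspecies. `liontrax` is aimed at wildlife managers and conservation
analysts who need to (a) rank candidate source populations for a given
release site and (b) audit historical or proposed movements against the
genetic guidelines.

## What it computes

For a source unit *s* and target unit *t*, each with mtDNA label set
*M(·)* and nuclear label set *N(·)*, the suitability level is decided by
precedence:

1. India ∈ *N(s)* XOR India ∈ *N(t)* → **NO_OPTION** (the India exclusion);
2. *N(s)* ∩ *N(t)* ≠ ∅ and *M(s)* ∩ *M(t)* ≠ ∅ → **FIRST** choice;
3. *N(s)* ∩ *N(t)* ≠ ∅ → **SECOND** choice;
4. disjoint nuclear clades within *P. l. melanochaita* → **THIRD** choice
   (unavailable within *P. l. leo*);
5. otherwise → **NO_OPTION**.

Modifiers: movements *into* a natural suture zone (SZ1
Sudan/South Sudan/Ethiopia, SZ2 Zambia/Malawi/Mozambique) score best-case
over the zone's component clades; movements *out of* one score worst-case;
same-zone pairs are FIRST. Hybrid-origin populations (human-mediated
admixture) keep their level but are flagged `hybrid_source` ("faded":
usable only with per-individual genetic testing).

The CITES module reads comparative-tabulation CSV exports, applies the
audit's inclusion filters (live lions into range states, 1983–2019,
purposes N/T/B/H, sources W/F/R/C or blank), reconciles quantities as the
permit maximum, consolidates four trade categories, and adjusts source
classes to W1 (wild), W2 (South African managed-metapopulation stock), C
(captive) or U (unknown) via a fixed clause precedence plus an auditable
override table. Scored records feed quantity-weighted summaries, per-country
tables and flow edges; captive/unknown individuals are NO_OPTION without
exception, and W2 is reported as its own parallel class.

## Worked example

```r
library(liontrax)

reg <- default_registry()     # packaged country-level registry
reg
#> Lion registry: 31 LCUs across 27 countries (27 range states)

ids <- sapply(reg$records, `[[`, "id")
score_pair(reg$records[[which(ids == "TZ_block")]],
           reg$records[[which(ids == "IN_gir")]], reg$vocabulary)
#> NO_OPTION - India rule: moves between the Indian and any African population are excluded despite shared subspecies

build_matrix(reg, axis = "country")
#> Suitability matrix (country axis, 27 x 27)
#>   cell levels: FIRST=214, SECOND=35, THIRD=100, NO_OPTION=380
```

The matrix counts say: of the 729 ordered country pairs, 214 are
first-choice combinations (same nuclear clade and haplogroup, including
every diagonal cell), 380 are excluded outright (cross-subspecies pairs and
everything touching India), and the remainder are second/third-tier
fallbacks. The matrix is asymmetric only around suture zones.

Auditing a synthetic permit set drawn from the replication profile (which
mirrors the published audit composition in expectation):

```r
sim <- simulate_trade(replication_profile(n = 1056, seed = 1), reg)
f <- tempfile(fileext = ".csv"); write.csv(sim$table, f, row.names = FALSE)
sc <- score_records(
  adjust_source(filter_records(read_cites_csv(f), reg$range_states),
                default_overrides()), reg)
summarize_suitability(sc)
#> Suitability summary: 2180 individuals
#>   FIRST        250 (11%)
#>   SECOND         2 (0%)
#>   THIRD         73 (3%)
#>   W2           217 (10%)
#>   NO_OPTION   1638 (75%)
#>   top exporter: ZA 677 (31%); top importer: ZA 1223 (56%)
```

1056 permit records carried 2180 individuals; three quarters of them are
no-option (almost all captive-sourced), a tenth are the South African
managed-metapopulation class W2 recovered by the adjustment rules, and
South Africa dominates both directions of trade — the composition the
generator is built to emulate.

## Registry file format

UTF-8 delimited text (comma or tab), one row per conservation unit,
multi-valued cells `|`-separated:

```
id,name,countries,mtdna,nudna,certainty,suture_zone,hybrid_origin,managed_metapopulation,extant,notes
```

Countries are ISO-3166 alpha-2 (aliases like `RSA`, `DRC` accepted);
`certainty` is `high`/`fairly_high`/`medium`; `suture_zone` is
`none`/`SZ1`/`SZ2`. The packaged registry is a country-level approximation
of the full 132-unit table; `load_registry()` accepts the full table when
available. Override tables are CSV:
`exporter,importer,year_min,year_max,class,citation`.

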