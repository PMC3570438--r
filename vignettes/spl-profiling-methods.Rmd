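---
title: "Profiling SPL drug labels with NDF-RT and RxNorm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling SPL drug labels with NDF-RT and RxNorm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splprofiler)
```

## The profiling model

An SPL drug label is identified by its `setId` (a UUID). The package
classifies labels against two drug terminologies along three independent
routes, each producing a coverage table of the same shape: one row per
category, each row holding the number of *distinct* concept identifiers
and *distinct* setIds attached to that category, plus coverage
percentages over user-supplied universe sizes.

**Route 1 — EPC indexing.** EPC-indexing SPL documents attach one or more
External Pharmacologic Class concepts to a label, and each EPC class
carries role links into NDF-RT's Chemical Ingredient, Physiologic Effect
and Mechanism of Action hierarchies. The four row categories (EPC,
Chemical/Ingredient, PE, MoA) are derived from the *relationship* that
reached a concept, not from its name tag, and are therefore disjoint by
construction: the total concept row is a sum, while the total setId row
is a distinct union. A concept repeated under several EPC classes of one
document (shared ingredients are common) counts once per category.

**Route 2 — NDF-RT categories via RxNorm.** RxNorm's `RXNCONSO.RRF`
aggregates atoms from many source vocabularies, distinguished by the
`SAB` field. Restricting to `SAB = NDFRT` gives, per record, an RxCUI, a
NUI (the `CODE` field) and a preferred name whose trailing bracketed tag
encodes the NDF-RT category. RxCUIs are joined to setIds through the
`RXNSAT.RRF` attribute `SPL_SET_ID` (the attribute name is configuration:
the release vocabulary names it this way, but `rxnorm_store()` accepts
any `ATN`). Three categories form rows — VA Product, Chemical/Ingredient,
EPC. Two rules matter:

* *Untagged parents are excluded.* NDF-RT contains untagged drug-class
  concepts (e.g. `Mesna`) whose children are tagged VA Products. Such a
  parent is a classification node, not a product, so it enters no
  category count even when it is linked to setIds; its tagged children
  count normally.
* *Only linked concepts are counted.* A concept with no setId attachment
  contributes nothing to a mapping table; rows count concepts reachable
  from at least one label. This mirrors how the mapping totals are
  reported in the study this package reproduces (unique NUIs *with*
  setId).

Tagged categories outside the three rows (PE, MoA tags can occur on
NDFRT-sourced atoms) are kept in a separately reported "(other)" bucket,
never silently dropped.

**Route 3 — RxNorm term types.** The setId-bearing RxCUIs are classified
by term type. The SPL-derived atom itself (SAB `MTHSPL`) carries
source-specific term types, while the normalized-form types (`SBD`,
`SCD`, `IN`, ...) live on other atoms of the same RxCUI; the lookup
therefore spans all `RXNCONSO` records of the RxCUI by default, with an
optional `tty_sab` restriction. Synonym types (`SY`, `TMSY`) duplicate
other types by definition, so the total row takes distinct unions of
RxCUIs and setIds rather than sums. Term types outside the ten tabulated
ones go to the "(other)" bucket.

## Coverage arithmetic

`coverage(count, total, decimals)` is `100 * count / total` rounded
half-up, computed in integer arithmetic on the rational
(`base + (2*rem >= total)` where `base`/`rem` are the integer quotient
and remainder of `count * 100 * 10^decimals` by `total`). Two reasons for
implementing the rounding this way rather than with `round()`:

* base R rounds half to even, which disagrees with how published drug
  terminology tables are conventionally rounded (half-up);
* doing it on the rational avoids binary floating-point artefacts at
  exact `.5` boundaries.

Denominators are inputs, never constants: the study-scale universes
(47,075 NDF-RT concepts, 36,568 SPL labels, 965,968 RxNorm entries) are
what a user passes for release-scale data, while fixtures pass fixture
totals. The default is one decimal place with a per-call override (two
decimals reproduce the small-percentage cells).

## The network

Profile tables carry their underlying (concept, setId, category) link
triples, and `build_network()` turns one or more of them into a directed
graph: concept → label edges labeled with the category, one node per
distinct identifier. Node IDs are namespaced (`nui:`, `rxcui:`,
`setid:`) so the three identifier spaces cannot collide, which also makes
self-loops impossible. Direction follows the convention of drug-class
visualizations: terminology concepts are sources, labels targets.
`extract_subnetwork()` filters by edge label; SIF output is for quick
Cytoscape loading, GraphML is the lossless archival format
(`import_graphml()` restores an identical network, which the tests
verify).

## The synthetic-fixture generator

Release files for the 2012-era snapshots the original profiling study
used are retired, so corpus-scale behaviour is validated against
generated corpora with known ground truth instead. `generate_fixtures()`
emits all three formats exactly as the readers expect them — canonical
SPL XML, tabular NDF-RT, RRF with trailing pipes — with identifier shapes
mimicking the real releases (NUIs `N` + 10 digits, setIds UUIDv4, RxCUIs
small integers) so format validation is exercised, and returns the three
profile tables the corpus must produce, computed from the generator's own
assignment sets rather than by the profilers.

Default structural parameters, chosen once to mirror the qualitative
structure of real EPC-indexing data and the RxNorm crosswalk:

| parameter | default | rationale |
|---|---|---|
| EPC classes per label | 1 (60%) or 2 (40%) | labels map to "one or multiple" classes; two is common |
| role links per class per role | uniform 0–2 | small per-class link sets as in indexing files |
| setId → VA Product link rate | 0.70 | a majority of labels resolve to a product |
| setId → Chemical/Ingredient rate | 0.85 | ingredient mappings dominate the crosswalk |
| setId → EPC (direct) rate | 0.05 | direct EPC integration into RxNorm is rare |
| `multi_category_fraction` | 0.25 | a sizable minority of labels maps to >1 category |
| primary TTY weights | IN/SCD/SBD heavy | ingredient and clinical-drug types dominate |
| SY / TMSY attachment | 0.40 / 0.10 | synonyms overlap other types, Tall-Man rarely |

The generator emulates *structure*, not content: drug-name text is
synthetic, marginal rates are stationary, and no attempt is made to
reproduce release-scale counts by default. Passing tests therefore
demonstrate that the parsing, joining, set arithmetic and serialization
are correct on data with the right shape — not that any particular
release would yield any particular coverage number. The
`worked_example_fixture()` corpus complements this with the documented
example mappings (the BCG label's two EPC classes and shared
ingredients, Famotidine's two labeller setIds, the Mesna exclusion, the
Cavan-EC three-category label); identifiers the source material does not
print are synthetic placeholders of realistic shape and are documented
as such.

```{r closure}
spec <- fixture_spec(n_spl = 20, multi_category_fraction = 0.5, seed = 7)
d <- tempfile()
truth <- generate_fixtures(spec, d)
tab <- profile_by_epc(load_corpus(file.path(d, "spl")),
                      c(concept_total = 47075, setid_total = 36568))
all.equal(as.data.frame(tab$rows[, 1:3]), as.data.frame(truth$epc$rows))
```

## Numerical and degenerate-input choices

* **RRF parsing** is strict: a line's field count must match the declared
  layout (18 for RXNCONSO, 13 for RXNSAT) after consuming the single
  trailing `|`; mismatches are reported with line numbers and either
  abort or skip-with-warning. Layouts are named schemas so a future
  column addition is configuration.
* **setId normalization**: setIds compare case-insensitively after
  trimming (UUID convention); files sharing a setId merge into one
  logical document with a warning.
* **Unknown role names** in SPL files are skipped with a warning rather
  than failing the document; a document without any EPC class is an
  error, because the corpus definition requires one.
* **Hierarchy cycles**: `descendants()` runs depth-first with an on-stack
  marker, so a diamond (a concept reachable by two paths) traverses
  cleanly while a true back edge is reported as a cycle and traversed
  once. Terminologies occasionally ship cycles; aborting would be worse
  than warning.
* **Category tags** match exactly on the five release strings with
  whitespace inside brackets trimmed; case variants and unknown tags are
  `NONE`. No attempt is made to repair typos, since a silent
  misclassification is worse than an unclassified concept.
* **Empty inputs** are valid everywhere: empty files give empty stores,
  an empty corpus gives an all-zero table (denominators must still be
  positive), an empty profile gives an empty network that still exports
  well-formed files.

## Problem sizes

The test suite validates the generator/profiler closure on 50 random
corpus specifications with sizes drawn up to 1,000 labels, and one
end-to-end run at 1,247 documents — the corpus size of the EPC-indexing
snapshot the profiling design targets — which completes in a few seconds
on a single CPU. These sizes exercise every code path at and beyond the
scale of the real EPC-indexing corpus; RxNorm-release-scale inputs
(~10^6 rows) stream through the same `data.table`-indexed store and are
limited by memory, not algorithmic complexity (all joins are keyed).

## Known limitations

* The exact HL7 element paths of DailyMed indexing SPL archives vary by
  era and are not fully standardized in the wild; the canonical dialect
  is a documented convention, and mapping a real archive may require a
  YAML dialect file (`read_spl_dialect()`). The parser makes no claim of
  schema fidelity to any particular DailyMed release.
* NDF-RT is ingested as asserted facts; OWL reasoning (defined vs.
  asserted class membership) is out of scope, as the crosswalk uses
  NDF-RT as a lookup structure.
* Only `RXNCONSO.RRF` and `RXNSAT.RRF` are read; relationships
  (`RXNREL`) and semantic types (`RXNSTY`) are not modeled.
* Coverage percentages are descriptive; no statistical inference is
  attached to them.
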