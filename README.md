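# splprofiler

FDA drug product labels are distributed as Structured Product Labeling
(SPL) documents — HL7 XML files identified by a `setId` UUID. On their
own they carry little machine-readable classification, which makes it hard
to answer questions like "which labels are beta-blockers?" or "how many
labels resolve to a normalized clinical drug?". Two standard drug
terminologies fill that gap: **NDF-RT** (the VA National Drug File
Reference Terminology, whose concepts carry NUIs and embed their category
in a trailing bracketed tag such as `Famotidine [Chemical/Ingredient]`)
and **RxNorm** (NLM's normalized clinical drug nomenclature, whose
concepts carry RxCUIs and whose release files record the source vocabulary
`SAB` and term type `TTY` of every atom).

`splprofiler` crosswalks SPL labels to both terminologies along three
parallel routes and reports, for each category *c*, the coverage

```
coverage(c) = 100 * |unique identifiers in c| / N
```

(half-up rounding; *N* is the concept or label universe size supplied by
the user), where "identifiers" are NUIs/RxCUIs on the concept side and
setIds on the label side:

1. **EPC indexing** — parses External Pharmacologic Class indexing SPL
   XML: each label maps to one or more `[EPC]` classes, and each class to
   NDF-RT concepts via the role relationships `has_Chemical_Structure`,
   `has_MoA` and `has_PE`.
2. **NDF-RT categories via RxNorm** — restricts `RXNCONSO.RRF` to
   `SAB = NDFRT`, classifies each concept by its name tag
   (`VA Product`, `Chemical/Ingredient`, `EPC`), and links RxCUIs to
   setIds through the `SPL_SET_ID` attribute in `RXNSAT.RRF`. Untagged
   drug-class parents (e.g. `Mesna`, whose tagged children are VA
   Products) are excluded from category counts.
3. **RxNorm term types** — classifies the setId-bearing RxCUIs by the ten
   term types `SBD, SCD, IN, PIN, BPCK, GPCK, BN, MIN, SY, TMSY`;
   synonym types overlap the others, so totals are distinct unions.

The three link sets combine into a directed **drug/drug-class network**
(concept → label edges labeled by category), exportable as SIF or GraphML
for Cytoscape. A deterministic synthetic-corpus generator emits all three
input formats with machine-readable ground truth, and a packaged
worked-example corpus encodes the documented example mappings.

## Worked example

The packaged worked-example corpus contains the BCG vaccine label (two
EPC classes; shared ingredient concepts), the Famotidine NDF-RT atom
(RxCUI 4278 → NUI N0000006373, linked to two labeller setIds), the
untagged parent Mesna with its VA-Product child, and the Cavan-EC label
linked to one concept in each NDF-RT category:

```r
library(splprofiler)
d <- worked_example_fixture()
corpus <- load_corpus(file.path(d, "spl"))
profile_by_epc(corpus, c(concept_total = 47075, setid_total = 36568))
#>             category unique_concepts unique_setids ...
#>                  EPC               2             1
#>  Chemical/Ingredient               2             1
#>                   PE               3             1
#>                  MoA               0             0
#>                Total               7             1

store <- rxnorm_store(file.path(d, "RXNCONSO.RRF"),
                      file.path(d, "RXNSAT.RRF"))
profile_by_ndfrt(store, c(concept_total = 47075, setid_total = 36568))
#>             category unique_concepts unique_setids ...
#>           VA Product               2             2
#>  Chemical/Ingredient               2             3
#>                  EPC               1             1
#>                Total               5             4

build_network(profile_by_epc(corpus, c(concept_total = 47075,
                                       setid_total = 36568)))
#> <drug_network> 8 nodes, 7 edges
#>   edge labels: Chemical/Ingredient, EPC, PE

coverage(354, 497)   # EPC classes integrated into indexing labels
#> [1] 71.2
```

Reading the EPC table: the single BCG label contributes 2 unique EPC
NUIs, 3 physiologic-effect NUIs and 2 chemical-ingredient NUIs (the
ingredients repeat under both EPC classes and deduplicate); the total
concept row sums the four disjoint role categories while the total setId
row is a distinct union. In the NDF-RT table the Cavan-EC setId appears
in all three category rows but only once in the total (4 distinct
setIds), and Mesna is absent while its tagged child counts as a VA
Product.

## Command line

```sh
inst/exec/splprof fixtures --seed 7 --n-spl 20 --out corpus/
inst/exec/splprof report --in corpus/spl \
  --rxnconso corpus/RXNCONSO.RRF --rxnsat corpus/RXNSAT.RRF \
  --totals 47075,36568,965968 --out results/
```

`report` writes the three profile tables (TSV + JSON, the JSON carrying
the underlying link triples) and the combined network (SIF + GraphML).

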