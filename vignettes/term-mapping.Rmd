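---
title: "Cross-ontology term mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-ontology term mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontomapr)
```

## Overview

`ontomapr` models the workflow by which a curation team maps the
Experimental Factor Ontology (EFO) terms that annotate imported GWAS
catalog associations onto the disease, phenotype, measurement and trait
ontologies used by model-organism databases, and then pushes SNP-level
trait annotations through those mappings. The pipeline has three layers:
automated candidate generation (lexical and cross-reference matching), a
two-pass human curation model, and downstream application (SSSOM exchange,
annotation translation, statistics). This vignette documents the methods,
the parameters that matter, the numerical and design choices, and what the
test fixtures do and do not demonstrate.

## The lexical matching model

Every term name and synonym is reduced to a *keyword*:

1. split the text on every maximal run of non-alphanumeric characters
   (spaces and all punctuation count as separators);
2. lowercase each token, dropping empty tokens;
3. sort the tokens in code-point order (so digit tokens sort before
   letters) and concatenate them with no separator.

`"Type 2 diabetes mellitus"` becomes `2diabetesmellitustype`. The keyword
is therefore invariant under token permutation, case change and separator
substitution — exactly the variation that separates equivalent labels in
different ontologies — while remaining a strict, non-fuzzy comparison:
no stemming, stopword removal or edit-distance tolerance is applied, and
none is intended. A source term contributes the keywords of its label and
of every synonym regardless of synonym scope; scope judgment belongs to
the curation layer, not the matcher.

Matching builds a keyword index over the non-obsolete target terms and
looks up every source keyword. For each target term hit at least once, a
candidate is emitted whose **tally** is the number of distinct source
keywords that hit it (no match is 0 and never emitted; one match is 1, and
so on) and whose evidence lists those keywords. Candidates are ranked by
tally descending with ties broken by target CURIE ascending, giving a
reproducible prioritized list for curator checking.

Choices worth stating explicitly:

- **Separator inventory** is *every* non-alphanumeric character. A closed
  definition is testable; an enumerated punctuation list would not be.
- **Token order** is code-point order, deterministic and
  locale-independent (`sort(method = "radix")`).
- **Case folding** uses `tolower()`; diacritics are *not* stripped. The
  synthetic fixtures avoid diacritics accordingly.
- **Tally counts distinct source keywords**, not keyword-origin pairs: a
  synonym that re-orders the label's words produces the same keyword and
  adds nothing.
- **Obsolete terms never participate** on either side; they are retained
  in the model with a flag so files round-trip.

## Cross-reference matching

Identifiers are canonicalized to `PREFIX:local` with the prefix
upper-cased (resolving MeSH/MESH-style prefix synonymy) and OBO-style URIs
reduced to their `PREFIX_LOCAL` tail. A candidate with method `XREF`
arises from any of: a source xref equal to a target term id; a target xref
equal to the source id; a shared third-party xref (MeSH, MONDO, OMIM, …).
All prefixes are eligible mediators — no whitelist — because the mediating
CURIE is exposed in the evidence column for curator judgment. Transitive
closure through a third ontology is deliberately out of scope: only direct
identity is compared. A pair found by both the lexical and the xref route
appears once per method; the duplication is information, not noise.

## The curation model

Curation is two-pass. A first curator turns a candidate (or a hand-entered
pair) into a PROPOSED record, assigning a synonym scope: *exact* (same
meaning), *narrow* (a subset), *broad* (covers more than the term) or
*related* (closely associated, not interchangeable). A second
curator/editor then accepts, rejects, or changes the mapping; every
ACCEPTED record therefore carries both a curator and an editor. CHANGE is
modeled as reject-plus-new-record — the original is marked REJECTED with a
comment linking its replacement — so both curation passes remain auditable.
An editor identical to the curator is permitted but noted in the decision
journal. Pair uniqueness is enforced among non-rejected records; a
rejected pair may be re-proposed, which is also what a scope-only CHANGE
does internally.

Scopes map to SKOS predicates with the broad/narrow pair crossed:

| scope   | predicate          |
|---------|--------------------|
| EXACT   | `skos:exactMatch`  |
| RELATED | `skos:relatedMatch`|
| NARROW  | `skos:broadMatch`  |
| BROAD   | `skos:narrowMatch` |

The crossing follows from the direction convention: scope is assigned from
the *target* term's perspective (the source term is added as a synonym of
the target), so a NARROW synonym means the subject is narrower than the
object — which in subject-to-object predicate terms is `skos:broadMatch`.
The alternative (subject-perspective scopes) would swap the two; the
convention here is declared once and applied uniformly, including on SSSOM
import where scope is recovered from the predicate through the inverse map
(unknown predicates degrade to RELATED rather than being dropped).

## SSSOM serialization

Mapping sets serialize as SSSOM TSV: a `#`-prefixed YAML metadata block
(`mapping_set_id`, `license`, `curie_map`), then a header and one row per
record sorted by subject and object id. The two internal justification
values map to `semapv:LexicalMatching` and `semapv:ManualMappingCuration`.
Only ACCEPTED records are exported by default — published files represent
validated mappings — overridable by the `statuses` argument. Writing fails
before any output if a record uses a prefix absent from the curie map.
On import, unknown columns are preserved in a side table, unknown
justifications become MANUAL_CURATION with the original string kept in the
comment, and records are marked ACCEPTED, since published mapping files
are curated artifacts. Round-trip identity (`read(write(x)) == x` on
records and metadata) holds for self-produced files and is tested on every
fixture class.

## GWAS annotation translation

Association tables are the GWAS-catalog TSV dialect: `SNPS`,
`DISEASE/TRAIT`, `MAPPED_TRAIT_URI` (pipe- or comma-delimited URI lists),
optional background-trait URI and p-value columns. Trait URIs are
normalized to CURIEs; EFO/HP/MONDO hybrid subjects need no special
handling because mappings are keyed by full CURIE. Rows without any
parseable trait URI are skipped, warned about and counted. QTL-like names
are minted as `GWAS<row>_H` when the input carries none, mirroring the
naming used for human SNP QTLs.

Translation emits one annotation per (association, trait, qualifying
mapping) triple, deduplicated on (QTL, target term, source term), where a
qualifying mapping is ACCEPTED, lands in the requested target prefix, and
uses an allowed predicate. The default predicate set is
`skos:exactMatch` only: propagation through broad/narrow/related links is
a semantic widening the user must opt into. Background traits *are*
translated but keep a `background = TRUE` flag, leaving filtering to the
consumer; when the same triple arises from both a foreground and a
background trait, the foreground row wins deduplication. Trait ids with no
accepted mapping of any prefix surface through `detect_unmapped_terms()`,
the machine version of the new-term log a curation team monitors. Two
properties tie the module together and are verified against brute-force
oracles: translation count equals the deduplicated triple join, and every
input trait is either translated somewhere or logged unmapped — never
both, never neither.

## Mapping statistics

`mapping_stats()` counts *distinct subject terms* per target prefix — a
subject mapped to two targets in one prefix counts once, matching how
mapped-term tallies are reported — split by provenance: a subject is
`automated` if any of its accepted mappings in that prefix is
lexically-justified (automation found it, even if curators later added
manual mappings too), `manual` otherwise, so `automated + manual = total`
holds identically. The automated percentage is rounded half-up to an
integer (`floor(100·a/t + 0.5)`); base R's `round()` rounds half to even,
which would mis-render tallies landing exactly on .5, such as 139/209.
On representative published tallies — 469 CMO-mapped terms of which 77
automated, 2052 VT of which 82, 518 HPO of which 347 — this yields 16%, 4%
and 67% respectively; the test suite and acceptance script compute these
from the tallies entered as fixture input.

## Synthetic fixtures

`gen_ontology_pair()` builds a source/target pair with planted
ground-truth matches in five classes — identical labels, word
permutations, punctuation/case variants, synonym-only matches, and
xref-only pairs — plus unmatched distractors on both sides, from a word
bank of biomedical-flavored tokens. Planted labels are kept distinct at
the keyword level by rejection against a registry of used keywords;
distractor labels draw on a disjoint token namespace, so non-collision is
by construction and the matchers must recover *exactly* the truth set.
`gen_associations()` emulates the association-table shape with a
deterministic fraction of planted-unmapped traits (fabricated ids in a
`99xxxxx` range the generator never assigns) and background traits; counts
are `round(fraction × n)` half-up. Both generators are deterministic given
their seed and restore the caller's RNG state.

What the fixtures do **not** emulate: EFO-scale vocabulary (thousands of
terms, heavy synonym load), DAG structure (irrelevant to lexical/xref
matching), diacritics, and the long tail of near-miss labels that make
real curation hard. Passing the planted-truth tests shows the machinery is
correct, not that automated matching will reach any particular recall on
real ontology pairs — on real data the automated fraction varied from a
minority (trait/measurement ontologies developed for other species) to a
large majority (disease ontologies rich in shared xrefs), which is
precisely why the curation layer exists.

## Problem sizes and determinism

The test suite runs the oracle-equivalence property on 100 random ontology
pairs of up to 50×50 terms against a brute-force double loop whose keyword
derivation is written independently (code-point ordering via `utf8ToInt`,
no shared helpers); property tests use 200–300 random labels. The
acceptance script uses 40 oracle pairs, 300 labels and a 50-row
association table. These sizes exercise every code path in seconds; the
algorithms are linear in total keyword count (indexing) and in hits
(matching), so nothing changes qualitatively at larger scale.

All ordering in outputs is total: candidates by tally then target CURIE,
SSSOM rows by subject then object, unmapped logs sorted, all under radix
(C-locale) ordering — identical inputs give byte-identical outputs.

## Known limitations

- Lexical matching is exact on keywords; morphological variants
  ("diabetic" vs "diabetes") do not match and are left to curators by
  design.
- CURIE prefix reconciliation is purely case-insensitive; prefixes that
  differ beyond case (`ORDO` vs `Orphanet`) are treated as distinct, and
  no external prefix registry is consulted.
- SSSOM support covers the TSV serialization with the core column set plus
  provenance columns; JSON/RDF serializations and mapping-set merge
  semantics beyond concatenate-and-deduplicate are out of scope.
- The OBO parser models `[Term]` stanzas and the tags relevant to matching
  (`id`, `name`, `synonym`, `xref`, `is_obsolete`); relationship graphs,
  import closures and OWL axioms are out of scope.
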