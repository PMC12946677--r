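# ontomapr

Cross-ontology term mapping and annotation translation for integrating
human GWAS catalog data with model-organism knowledgebases.

## The problem

GWAS catalog associations are annotated with Experimental Factor Ontology
(EFO) terms, but model-organism databases describe disease and phenotype
with other vocabularies — Disease Ontology variants (DO/RDO), the Human
Phenotype Ontology (HPO), the Mammalian Phenotype Ontology (MP), the
Clinical Measurement Ontology (CMO) and the Vertebrate Trait Ontology (VT).
Making imported SNP–trait associations interoperable with curated rat and
mouse data requires term-level mappings from EFO into each of these, and a
way to push the EFO annotations through those mappings onto QTL-like
records. `ontomapr` implements that pipeline for curation teams:

1. **Lexical matching.** Each term label and synonym is tokenized (split on
   spaces and punctuation), lowercased, and its tokens are alphabetized and
   concatenated into a *keyword*; the keyword of a source term is compared
   against all keywords of the target ontology. Matches are tallied — no
   match is 0, one match is 1, and so on — giving curators a prioritized
   candidate list. `"Blood pressure, systolic"` and
   `"systolic blood pressure"` collapse to the same keyword
   `bloodpressuresystolic`, so word order, case and punctuation never block
   a match.
2. **XREF matching.** Database cross-references are normalized to canonical
   CURIEs (`MeSH:D006973` → `MESH:D006973`) and compared: a source xref
   equal to a target id, a target xref equal to the source id, or a shared
   third-party xref each propose a candidate.
3. **Curation.** A first curator assigns each proposed pair a synonym scope
   — exact, broad, narrow or related — and a second curator/editor accepts,
   rejects or changes it. Scopes map to SKOS predicates
   (EXACT→`skos:exactMatch`, RELATED→`skos:relatedMatch`,
   NARROW→`skos:broadMatch`, BROAD→`skos:narrowMatch`; the last two are
   crossed because scope is assigned from the target term's perspective).
4. **SSSOM exchange.** Accepted mappings are serialized as SSSOM TSV
   (metadata as `#`-prefixed YAML, semapv justification vocabulary) and
   externally curated SSSOM sets can be imported.
5. **Annotation translation.** EFO-annotated SNP associations are parsed
   from GWAS-catalog-style TSV, QTL records are minted per row, and each
   trait annotation fans out through the accepted mappings into every
   requested target ontology; traits with no accepted mapping are logged
   for curators.
6. **Reporting.** Per-target-ontology tallies of mapped source terms,
   split into automated (lexical/xref pipeline found it) versus
   manually-curated provenance, with integer automated-match percentages.

## Worked example

```r
library(ontomapr)

efo <- ontology(list(
  ontology_term("EFO:0000537", "hypertension",
                synonyms = list(synonym("high blood pressure", "EXACT")),
                xrefs = "MESH:D006973"),
  ontology_term("EFO:0004325", "systolic blood pressure")), prefix = "EFO")
doid <- ontology(list(
  ontology_term("DOID:10763", "hypertension",
                synonyms = list(synonym("HTN", "EXACT")),
                xrefs = "MESH:D006973"),
  ontology_term("DOID:1234", "something else")), prefix = "DOID")

rbind(match_ontology(efo, doid), xref_match_ontology(efo, doid))
#>     source_id source_label  target_id target_label tally  method     evidence
#> 1 EFO:0000537 hypertension DOID:10763 hypertension     1 LEXICAL hypertension
#> 2 EFO:0000537 hypertension DOID:10763 hypertension     1    XREF MESH:D006973
```

The pair is proposed twice — once per method, with the matched keyword and
the mediating CURIE as evidence. The tally of 1 means one distinct source
keyword (or one mediating xref) hit the target. Curate and export it:

```r
set <- mapping_set("https://example.org/mappings/efo-doid",
                   curie_map = list(EFO = "http://www.ebi.ac.uk/efo/EFO_",
                                    DOID = "http://purl.obolibrary.org/obo/DOID_"))
set <- decide(set, list(source_id = "EFO:0000537", source_label = "hypertension",
                        target_id = "DOID:10763", target_label = "hypertension",
                        method = "LEXICAL"),
              scope = "EXACT", curator = "curator1")
set <- review(set, "EFO:0000537", "DOID:10763", "ACCEPT", editor = "editor1")
cat(write_sssom(set))
#> # curie_map:
#> #   DOID: http://purl.obolibrary.org/obo/DOID_
#> #   EFO: http://www.ebi.ac.uk/efo/EFO_
#> #   semapv: https://w3id.org/semapv/vocab/
#> #   skos: http://www.w3.org/2004/02/skos/core#
#> # license: https://creativecommons.org/publicdomain/zero/1.0/
#> # mapping_set_id: https://example.org/mappings/efo-doid
#> subject_id   subject_label   predicate_id    object_id   object_label    mapping_justification   author_id   reviewer_id comment
#> EFO:0000537  hypertension    skos:exactMatch DOID:10763  hypertension    semapv:LexicalMatching  curator1    editor1
```

Then translate a GWAS association through the accepted mapping:

```r
gwas <- paste("SNPS\tDISEASE/TRAIT\tMAPPED_TRAIT_URI\tP-VALUE",
              "rs699\thypertension\thttp://www.ebi.ac.uk/efo/EFO_0000537\t2E-11",
              sep = "\n")
assoc <- parse_gwas_associations(text = gwas)
translate_annotations(assoc, set, "DOID")
#>   qtl_name    term_id   term_label source_term_id mapping_predicate background
#> 1  GWAS1_H DOID:10763 hypertension    EFO:0000537   skos:exactMatch      FALSE
```

The SNP's minted QTL record `GWAS1_H` now carries a `DOID:10763`
annotation with full provenance back to the EFO trait and the mapping
predicate. `detect_unmapped_terms(assoc, set)` returns the trait CURIEs
still awaiting curation, and `mapping_stats(set)` tabulates mapped-term
counts and automated percentages per target ontology.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ontomapr", package = "ontomapr"))') \
  fixtures --out-dir fx --seed 42
# then: match, export-sssom, import-sssom, translate, report, diff-new-terms
```

`fixtures` generates a synthetic source/target ontology pair with planted
ground-truth matches of every class (exact label, word permutation,
punctuation variant, synonym-only, xref-only, distractors) plus a
GWAS-style association table, so the whole pipeline can be exercised
without downloading anything.

## Package layout

- `R/ontology.R`, `R/obo-io.R` — term/ontology model, OBO flat-file I/O
- `R/keyword.R`, `R/lexical-matcher.R` — keyword normalization and matching
- `R/curie.R`, `R/xref-matcher.R` — CURIE canonicalization, XREF matching
- `R/mapping-store.R` — curation decisions, two-pass review, scope/predicate
- `R/sssom.R` — SSSOM TSV serialization
- `R/gwas.R` — association parsing, annotation translation, unmapped log
- `R/report.R` — mapping statistics
- `R/fixtures.R` — synthetic fixture generator
- `R/cli.R`, `inst/cli/ontomapr` — command-line entry point

See `vignettes/term-mapping.Rmd` for the methods account: algorithm
details, parameter defaults, design decisions and limitations.
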