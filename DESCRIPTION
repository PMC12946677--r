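Package: ontomapr
Title: Lexical and Cross-Reference Ontology Term Mapping with SSSOM
    Exchange and GWAS Annotation Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for proposing, curating, exchanging and applying
    cross-ontology term mappings in the style used by model-organism
    databases to integrate human GWAS catalog annotations. Includes an
    OBO flat-file reader/writer, a keyword-based lexical matcher
    (lowercase, strip separators, alphabetize and concatenate tokens), a
    database cross-reference (XREF) matcher, a two-pass curator/editor
    decision layer mapping synonym scopes to SKOS match predicates, SSSOM
    TSV serialization, translation of EFO-annotated GWAS SNP associations
    into annotations in mapped target ontologies, per-ontology mapping
    statistics, and a synthetic fixture generator with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
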