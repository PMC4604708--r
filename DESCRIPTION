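Package: cocite
Title: Co-Citation Based Literature Search for Evidence Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Citation-network search for finding studies eligible for
    meta-analysis and systematic reviews. Given one or more "known" seed
    articles inside a citation corpus, ranks all co-cited works by
    co-citation strength, selects screening candidates by count and
    j-index threshold rules, expands the retrieved set through direct
    (backward and forward) citations, and evaluates retrieval accuracy
    and screening efficiency against a gold-standard list of included
    studies. Includes readers for Web of Science style exports and
    generic edge lists, a JSON corpus interchange format, a synthetic
    citation-corpus generator for offline testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
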