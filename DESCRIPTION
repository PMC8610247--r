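Package: journalscreen
Title: Screening Journals for Concentrated Authorship and Editorial Favoritism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening scholarly journals for signs of editorial
    favoritism from article-level metadata. Computes authorship-concentration
    indices per journal -- the percentage of papers by the most prolific
    author (PPMP) and a sample-corrected Gini index of per-author article
    counts, with Lorenz curves -- together with publication-lag asymmetry
    between the most prolific author(s) and everyone else, a MEDLINE
    publication-type based research-article classification, empirical
    95th-percentile outlier flagging, and two citation side-metrics
    (self-citation boost; skewness and nonarticle inflation). Reads
    MEDLINE/PubMed XML or a documented CSV dialect, and ships a synthetic
    corpus generator with known ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stringi,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
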