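Package: saedr
Title: Severity Scoring of Adverse Drug Reactions by Label Propagation over
    Lexical Embedding Networks
Version: 0.1.0
Authors@R:
    person("SAEDR", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Estimates continuous severity scores for adverse drug reaction
    (ADR) terms by propagating labels from small ranked seed sets of severe
    and benign terms over a k-nearest-neighbor lexical network built from
    word embeddings.  Severity is measured as the relative rate at which
    weighted random walks started from severe versus benign seed nodes visit
    each term, stabilized by bootstrap resampling of walks, aggregated to
    preferred-term level and min-max normalized (SAEDR scores).  Severities
    are combined with drug-label ADR frequencies, sampling unreported
    frequencies from a uniform prior, into per-drug risk profile (DRIP)
    scores.  Includes readers for word2vec-style embeddings, MedDRA-style
    term tables, openFDA-dialect adverse-event case records and SIDER-style
    frequency tables; outcome-based seed ranking from case reports; grid
    search over network and seeding hyperparameters; and a synthetic-data
    generator with a planted latent severity axis for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
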