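Package: sociotypes
Title: Sociometric Status Classification from Limited Peer Nominations
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies children in classrooms into the five sociometric
    status groups (preferred, rejected, neglected, controversial, average)
    from limited "liked most" / "liked least" peer nominations, using three
    scoring systems: the standard-score method based on within-classroom
    z-scores of social preference and social impact, a fixed-cutoff binomial
    probability method, and an adjusted probability method that derives
    per-classroom binomial critical values from the voters' actual
    expansiveness.  Includes the full method-comparison apparatus:
    admissible nomination-pair enumeration per status, Cohen's kappa
    agreement (overall and one-vs-rest per type), discrepant-case
    extraction, intra-method variability audits, behavioural validation by
    one-way ANOVA with Tukey HSD or Games-Howell post-hoc tests, and a
    synthetic classroom simulator with planted sociometric structure for
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
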