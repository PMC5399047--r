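Package: txpod
Title: Transcriptomic Points of Departure from Benchmark Dose Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene benchmark dose (BMD) modeling of dose-response gene
    expression data with the Hill, power, linear and polynomial model suite,
    profile-likelihood BMDL estimation, ANOVA and shrinkage-variance (Fs)
    pre-filtering, GMT-backed pathway enrichment and pathway BMDs, eleven
    documented rules for aggregating gene and pathway BMDs into a
    transcriptomic point of departure (POD), bootstrap uncertainty for each
    rule, and a three-criterion concordance evaluation against apical PODs
    (NOAEL, LOAEL, apical BMDs). Includes EPA-style continuous and
    dichotomous model suites for apical endpoints and a synthetic-study
    generator with known ground-truth BMDs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
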