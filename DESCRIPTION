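Package: cbtvalue
Title: Value-Based Pricing of Cognitive Behavioural Therapy for Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A decision-tree cost-utility model comparing cognitive
    behavioural therapy (CBT) for adult primary-care depression against
    treatment as usual, and machinery to invert the incremental
    cost-effectiveness ratio at a willingness-to-pay threshold into a
    value-based per-session fee. Includes a suicide-aversion QALY
    extension, one-way deterministic sensitivity analysis (tornado
    tables), a long-term remission scenario, a follow-up-therapy offset
    invariance demonstration, and a seeded sampler that draws parameter
    sets from published 95% confidence intervals so the whole pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
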