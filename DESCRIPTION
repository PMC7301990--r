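Package: mgliqual
Title: Service-Quality Evaluation with Multi-Granularity Linguistic Information
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating service quality from linguistic survey data
    expressed on term sets of different granularities. Linguistic ratings and
    hesitant interval ratings are encoded as normalized trapezoidal fuzzy
    numbers, aggregated over expert panels and respondent surveys, screened
    against a reference importance scale by a componentwise similarity degree,
    and summarized as perception-expectation gaps in the SERVQUAL/5GAP
    tradition. Includes a synthetic questionnaire simulator with planted
    structure, fixtures transcribing a published teleconsultation case study,
    and a command-line interface for the screen/evaluate/simulate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
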