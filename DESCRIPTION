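Package: maabalance
Title: Master-Regulator Activity Balance Analysis for Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers mutual-information regulons for two counterposed
    transcription factors, estimates per-sample regulator activities by
    rank enrichment, computes the Mean Absolute Activity (MAA) balance
    index, and quantifies its prognostic value with Kaplan-Meier curves,
    maximally selected cut-points and Cox proportional-hazards models.
    Includes group-comparison statistics for multi-omics feature screens,
    a synthetic-cohort generator with planted ground truth for end-to-end
    validation, and a configuration-driven pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
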