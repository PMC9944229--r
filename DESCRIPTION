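Package: wfregistry
Title: Build Validated, Tested, TRS-Compatible Workflow Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for operating a workflow registry that only publishes
    reusable workflows. Workflow metadata (JSON or YAML) naming a primary
    CWL, WDL, Nextflow or Snakemake descriptor, its dependent files, authors,
    license and test cases is validated against eleven reusability
    requirements grouped by availability, validity and traceability; test
    cases are executed through the GA4GH Workflow Execution Service (WES)
    run-request protocol (with a built-in deterministic stub for offline
    operation); and accepted workflows are persisted through a pluggable
    archiver that mints DOIs, rewritten to their persistent URLs, and emitted
    as a static GA4GH Tool Registry Service (TRS) response tree that any
    plain file server can serve. A fixture generator produces synthetic
    workflow repositories with injectable defects so the whole pipeline is
    testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
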