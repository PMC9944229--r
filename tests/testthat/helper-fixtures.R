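# Shared test helpers: an in-memory randomized metadata generator for
# round-trip properties, and small builders for hand-rolled records.

minimal_metadata <- function(id = new_workflow_id(seed = 42),
                             language = wf_language("CWL", "v1.0"),
                             doi = NULL) {
  workflow_metadata(
    id = id,
    version = "1.0.0",
    license = "Apache-2.0",
    authors = list(wf_author("alice", "Alice Author")),
    name = "toy-workflow",
    readme_url = "https://example.org/repo/README.md",
    language = language,
    files = list(wf_file("https://example.org/repo/main.cwl",
                         target = "main.cwl", role = "primary")),
    testing = list(wf_test_case("t1", list(
      wf_file("https://example.org/repo/tests/params.json",
              target = "tests/params.json", role = "test",
              kind = "workflow_params")
    ))),
    doi = doi
  )
}

# Randomized but always-valid metadata: varying author counts, optional
# fields, file counts, test-case shapes, extra top-level keys.
random_valid_metadata <- function(seed) {
  withr::with_seed(seed, {
    word <- function() paste(sample(letters, sample(3:8, 1), replace = TRUE),
                             collapse = "")
    n_authors <- sample(1:3, 1)
    authors <- lapply(seq_len(n_authors), function(i) {
      wf_author(
        account = word(),
        name = paste(word(), word()),
        affiliation = if (runif(1) < 0.5) paste(word(), "institute"),
        orcid = if (runif(1) < 0.5) "0000-0002-1825-0097"
      )
    })
    n_secondary <- sample(0:3, 1)
    files <- c(
      list(wf_file(paste0("https://example.org/", word(), "/main.cwl"),
                   target = "main.cwl", role = "primary")),
      lapply(seq_len(n_secondary), function(i) {
        wf_file(paste0("https://example.org/tools/", word(), i, ".cwl"),
                target = paste0("tools/", word(), i, ".cwl"),
                role = sample(c("secondary", "other"), 1))
      })
    )
    n_tests <- sample(1:2, 1)
    testing <- lapply(seq_len(n_tests), function(i) {
      extra_data <- if (runif(1) < 0.5) list(
        wf_file(paste0("https://example.org/tests/data", i, ".txt"),
                target = paste0("tests/data", i, ".txt"),
                role = "test", kind = "data"))
      wf_test_case(paste0("case_", i), c(
        list(wf_file(paste0("https://example.org/tests/params", i, ".json"),
                     target = paste0("tests/params", i, ".json"),
                     role = "test", kind = "workflow_params")),
        extra_data
      ))
    })
    extra <- if (runif(1) < 0.5) list(zenodo_community = word()) else list()
    workflow_metadata(
      id = new_workflow_id(seed = seed + 10000L),
      version = paste(sample(0:9, 3, replace = TRUE), collapse = "."),
      license = sample(open_source_licenses(), 1),
      authors = authors,
      name = paste0(word(), "-workflow"),
      readme_url = "https://example.org/repo/README.md",
      language = wf_language(sample(c("CWL", "WDL", "NFL", "SMK"), 1), "v1.2"),
      files = files,
      testing = testing,
      doi = if (runif(1) < 0.3) "10.5072/zenodo.12345",
      extra = extra
    )
  })
}

expect_single_requirement_failure <- function(report, requirement) {
  failed <- report$results$requirement[!report$results$passed]
  expect_identical(failed, requirement)
}
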