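# Publication lifecycle: archiving with deterministic DOIs, URL rewriting,
# phase gating, atomicity of the registry output.

test_that("persisting a workflow mints a test-prefix DOI and covers every file", {
  repo <- generate_repo("CWL", seed = 71)
  meta <- read_metadata(repo$metadata_path)
  archiver <- local_archiver(withr::local_tempdir())
  receipt <- persist_files(meta, archiver)
  expect_match(receipt$doi, "^10\\.5072/")
  expect_identical(receipt$doi,
                   sprintf("10.5072/%s.1.0.0", substr(meta$id, 1, 8)))
  urls <- c(vapply(meta$files, function(f) f$url, character(1)),
            unlist(lapply(meta$testing, function(tc)
              vapply(tc$files, function(f) f$url, character(1)))))
  expect_true(all(urls %in% names(receipt$persisted_urls)))
  # persisted copies hold the original bytes
  for (u in urls) {
    expect_identical(resolve(local_resolver(), receipt$persisted_urls[[u]])$content,
                     resolve(local_resolver(), u)$content)
  }
})

test_that("persisting twice is idempotent for the same id and version", {
  repo <- generate_repo("CWL", seed = 72)
  meta <- read_metadata(repo$metadata_path)
  archiver <- local_archiver(withr::local_tempdir())
  r1 <- persist_files(meta, archiver)
  r2 <- persist_files(meta, archiver)
  expect_identical(r1$doi, r2$doi)
  expect_identical(r1$persisted_urls, r2$persisted_urls)
})

test_that("an unresolvable file aborts archiving with nothing stored", {
  repo <- generate_repo("CWL", defects = "missing-dependency", seed = 73)
  meta <- read_metadata(repo$metadata_path, strict = FALSE)
  dir <- withr::local_tempdir()
  expect_error(persist_files(meta, local_archiver(dir)),
               class = "wfr_archive_error")
  expect_length(list.files(dir, recursive = TRUE), 0)
})

test_that("rewriting swaps every file URL, sets the DOI and changes nothing else", {
  repo <- generate_repo("WDL", seed = 74)
  meta <- read_metadata(repo$metadata_path)
  receipt <- persist_files(meta, local_archiver(withr::local_tempdir()))
  rewritten <- rewrite_urls(meta, receipt)
  expect_identical(rewritten$doi, receipt$doi)
  for (i in seq_along(meta$files)) {
    expect_identical(rewritten$files[[i]]$url,
                     receipt$persisted_urls[[meta$files[[i]]$url]])
    expect_identical(rewritten$files[[i]]$target, meta$files[[i]]$target)
  }
  expect_identical(rewritten$name, meta$name)
  expect_identical(rewritten$authors, meta$authors)
  expect_identical(
    vapply(rewritten$testing, function(t) t$test_id, character(1)),
    vapply(meta$testing, function(t) t$test_id, character(1)))
  # a receipt that misses a URL is an error
  bad <- receipt
  bad$persisted_urls[[meta$files[[1]]$url]] <- NULL
  expect_error(rewrite_urls(meta, bad), class = "wfr_archive_error")
})

test_that("rewritten metadata re-validates against the archive alone", {
  repo <- generate_repo("CWL", seed = 75)
  meta <- read_metadata(repo$metadata_path)
  receipt <- persist_files(meta, local_archiver(withr::local_tempdir()))
  rewritten <- rewrite_urls(meta, receipt)
  # remove the original repository: only archived copies remain
  unlink(repo$root, recursive = TRUE)
  report <- validate_workflow(rewritten)
  expect_true(report$overall)
})

test_that("a passing fixture traverses submission, review and publication in order", {
  repo <- generate_repo("CWL", seed = 76)
  meta <- read_metadata(repo$metadata_path)
  out <- file.path(withr::local_tempdir(), "registry")
  sub <- publish_workflow(meta, wes_endpoint = stub_wes(),
                          archiver = local_archiver(withr::local_tempdir()),
                          out_dir = out, poll_interval = 0.01)
  expect_identical(sub$record$phases_entered,
                   c("submission", "review", "publication"))
  expect_identical(sub$record$phase, "publication")
  expect_identical(sub$record$events$action[1:2], c("validate", "test"))
  expect_true(all(sub$record$events$outcome[1:2] == "pass"))
  expect_true(file.exists(file.path(out, "tools", meta$id, "versions", "1.0.0",
                                    "index.json")))
  # published version document is marked verified by the registry
  vdoc <- read_registry_document(out, paste0("/tools/", meta$id, "/versions/1.0.0"))
  expect_true(vdoc$verified)
})

test_that("a validation failure halts in submission with nothing archived or emitted", {
  repo <- generate_repo("CWL", defects = "invalid-license", seed = 77)
  meta <- read_metadata(repo$metadata_path, strict = FALSE)
  out <- file.path(withr::local_tempdir(), "registry")
  archive <- withr::local_tempdir()
  sub <- publish_workflow(meta, wes_endpoint = stub_wes(),
                          archiver = local_archiver(archive), out_dir = out,
                          poll_interval = 0.01)
  expect_identical(sub$record$phase, "submission")
  expect_identical(sub$record$phases_entered, "submission")
  expect_match(sub$record$events$outcome[1], "fail: open_source_license")
  expect_false(dir.exists(out))
  expect_length(list.files(archive, recursive = TRUE), 0)
  # tests never ran after the validation gate
  expect_false("test" %in% sub$record$events$action)
})

test_that("a failing WES test halts before persistence", {
  repo <- generate_repo("CWL", defects = "wes-executor-error", seed = 78)
  meta <- read_metadata(repo$metadata_path)
  out <- file.path(withr::local_tempdir(), "registry")
  archive <- withr::local_tempdir()
  sub <- publish_workflow(meta, wes_endpoint = stub_wes(fixture_wes_script(repo)),
                          archiver = local_archiver(archive), out_dir = out,
                          poll_interval = 0.01)
  expect_identical(sub$record$phase, "submission")
  expect_match(sub$record$events$outcome[2], "EXECUTOR_ERROR")
  expect_false(dir.exists(out))
  expect_length(list.files(archive, recursive = TRUE), 0)
})

test_that("publication emits exactly two metadata documents per version", {
  repo <- generate_repo("NFL", seed = 79)
  meta <- read_metadata(repo$metadata_path)
  out <- file.path(withr::local_tempdir(), "registry")
  sub <- publish_workflow(meta, wes_endpoint = stub_wes(),
                          archiver = local_archiver(withr::local_tempdir()),
                          out_dir = out, poll_interval = 0.01)
  vdir <- file.path(out, "tools", meta$id, "versions", "1.0.0")
  expect_setequal(list.files(vdir), c("files", "tests", "index.json", "metadata.json"))
  published <- read_metadata(file.path(vdir, "metadata.json"))
  expect_identical(published$doi, sub$receipt$doi)
})

test_that("the review gate refuses an unapproved or failed submission", {
  repo <- generate_repo("CWL", seed = 80)
  meta <- read_metadata(repo$metadata_path)
  staged <- submit_workflow(meta, wes_endpoint = stub_wes(),
                            poll_interval = 0.01)
  expect_true(staged$ok)
  expect_identical(staged$record$phase, "review")

  failed <- submit_workflow(
    read_metadata(generate_repo("CWL", defects = "no-authors", seed = 81)$metadata_path,
                  strict = FALSE),
    wes_endpoint = stub_wes(), poll_interval = 0.01)
  expect_false(failed$ok)
  expect_error(approve_and_publish(failed, local_archiver(withr::local_tempdir()),
                                   file.path(withr::local_tempdir(), "reg")),
               class = "wfr_lifecycle_error")

  # the staged passing submission publishes on approval
  out <- file.path(withr::local_tempdir(), "registry")
  done <- approve_and_publish(staged, local_archiver(withr::local_tempdir()), out)
  expect_identical(done$record$phase, "publication")
  expect_true(dir.exists(out))
})

test_that("test logs are retained in the archive next to the workflow files", {
  repo <- generate_repo("CWL", seed = 82)
  meta <- read_metadata(repo$metadata_path)
  archive <- withr::local_tempdir()
  sub <- publish_workflow(meta, wes_endpoint = stub_wes(),
                          archiver = local_archiver(archive),
                          out_dir = file.path(withr::local_tempdir(), "reg"),
                          poll_interval = 0.01)
  logs <- list.files(archive, recursive = TRUE, pattern = "\\.log$")
  expect_length(logs, 1)
  expect_match(logs, "test-logs/assembly_smoke_test.log")
})
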