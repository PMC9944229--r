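# WES test execution: request construction, the stub endpoint, terminal
# state semantics, timeouts, backend substitutability.

local_fixture_meta <- function(seed = 51, defects = character()) {
  repo <- generate_repo("CWL", defects = defects, seed = seed)
  list(repo = repo, meta = read_metadata(repo$metadata_path, strict = FALSE))
}

test_that("run requests carry the params text, language and attachments", {
  fx <- local_fixture_meta()
  req <- build_run_request(fx$meta, fx$meta$testing[[1]])
  expect_identical(req$workflow_type, "CWL")
  expect_identical(req$workflow_type_version, "v1.0")
  expect_identical(req$workflow_url, fx$meta$files[[1]]$url)
  expect_match(req$workflow_params, "\"raw_reads\"")
  expect_length(req$attachments, 1)
  expect_identical(req$attachments[[1]]$target, "tests/data/reads.fq")
  expect_match(req$attachments[[1]]$content, "@read1")
  expect_null(req$workflow_engine_parameters)
})

test_that("a params-only test case yields no attachments", {
  m <- minimal_metadata()
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n": 1}', path)
  m$testing[[1]]$files[[1]]$url <- paste0("file://", path)
  req <- build_run_request(m, m$testing[[1]])
  expect_length(req$attachments, 0)
  expect_identical(req$workflow_params, '{"n": 1}\n')
})

test_that("an unresolvable test file aborts request construction", {
  m <- minimal_metadata()
  m$testing[[1]]$files[[1]]$url <- "file:///no/such/params.json"
  expect_error(build_run_request(m, m$testing[[1]]), class = "wfr_ref_error")
})

test_that("passed is equivalent to terminal state COMPLETE across all states", {
  fx <- local_fixture_meta()
  for (state in c("COMPLETE", "EXECUTOR_ERROR", "SYSTEM_ERROR", "CANCELED")) {
    endpoint <- stub_wes(list(assembly_smoke_test = state))
    req <- build_run_request(fx$meta, fx$meta$testing[[1]])
    result <- run_test(req, endpoint, poll_interval = 0.01, timeout = 5)
    expect_identical(result$state, state)
    expect_identical(result$passed, state == "COMPLETE")
  }
})

test_that("a run that never terminates times out to SYSTEM_ERROR", {
  fx <- local_fixture_meta()
  endpoint <- stub_wes(list(`*` = list(state = "COMPLETE", delay = 60)))
  req <- build_run_request(fx$meta, fx$meta$testing[[1]])
  result <- run_test(req, endpoint, poll_interval = 0.05, timeout = 0.5)
  expect_identical(result$state, "SYSTEM_ERROR")
  expect_false(result$passed)
  expect_match(result$log_excerpt, "timed out")
  expect_gte(result$duration, 0.5)
})

test_that("the stub walks QUEUED then RUNNING before its scripted terminal state", {
  fx <- local_fixture_meta()
  endpoint <- stub_wes(list(`*` = list(state = "COMPLETE", delay = 0.3)))
  req <- build_run_request(fx$meta, fx$meta$testing[[1]])
  result <- run_test(req, endpoint, poll_interval = 0.05, timeout = 10)
  expect_true(result$passed)
  polls <- endpoint$state$polls[["run-0001"]]
  expect_gte(polls, 2L)  # observed non-terminal states before completing
  expect_match(result$log_excerpt, "QUEUED")
})

test_that("concurrent stub runs have independent ids and states", {
  endpoint <- stub_wes(list(a = "COMPLETE", b = "EXECUTOR_ERROR"))
  ra <- wfregistry:::wes_submit(endpoint, list(test_id = "a"))
  rb <- wfregistry:::wes_submit(endpoint, list(test_id = "b"))
  expect_false(ra == rb)
  # zero scripted delay: the first poll already returns the terminal state
  expect_identical(wfregistry:::wes_status(endpoint, ra), "COMPLETE")
  expect_identical(wfregistry:::wes_status(endpoint, rb), "EXECUTOR_ERROR")
  expect_identical(wfregistry:::wes_status(endpoint, ra), "COMPLETE")
  expect_error(wfregistry:::wes_status(endpoint, "run-9999"), class = "wfr_ref_error")
})

test_that("run_all_tests reports every case without short-circuiting", {
  fx <- local_fixture_meta()
  meta <- fx$meta
  # add a second test case reusing the same params file
  meta$testing <- c(meta$testing, list(wf_test_case("second_case", list(
    wf_file(meta$testing[[1]]$files[[1]]$url, target = "tests/params2.json",
            role = "test", kind = "workflow_params")))))
  endpoint <- stub_wes(list(assembly_smoke_test = "EXECUTOR_ERROR",
                            second_case = "COMPLETE"))
  results <- run_all_tests(meta, endpoint, poll_interval = 0.01, timeout = 5)
  expect_length(results, 2)
  expect_false(attr(results, "passed"))
  expect_identical(vapply(results, function(r) r$state, character(1)),
                   c("EXECUTOR_ERROR", "COMPLETE"))

  all_good <- run_all_tests(meta, stub_wes(), poll_interval = 0.01, timeout = 5)
  expect_true(attr(all_good, "passed"))
})

test_that("per-test log files are written when a log directory is given", {
  fx <- local_fixture_meta()
  log_dir <- withr::local_tempdir()
  run_all_tests(fx$meta, stub_wes(), poll_interval = 0.01, timeout = 5,
                log_dir = log_dir)
  expect_true(file.exists(file.path(log_dir, "assembly_smoke_test.log")))
})

test_that("an HTTP WES serving the same state sequence matches the stub", {
  fx <- local_fixture_meta()
  req <- build_run_request(fx$meta, fx$meta$testing[[1]])

  make_http_endpoint <- function(states) {
    i <- 0L
    http_wes("https://wes.example.org/ga4gh/wes/v1",
             transport = function(method, url, body = NULL, token = NULL) {
               if (method == "POST")
                 return(list(status = 200L, body = '{"run_id": "wes-run-1"}'))
               i <<- i + 1L
               list(status = 200L,
                    body = sprintf('{"state": "%s"}', states[[min(i, length(states))]]))
             })
  }
  for (terminal in c("COMPLETE", "EXECUTOR_ERROR", "CANCELED")) {
    http_result <- run_test(req, make_http_endpoint(c("QUEUED", "RUNNING", terminal)),
                            poll_interval = 0.01, timeout = 5)
    stub_result <- run_test(req, stub_wes(list(`*` = terminal)),
                            poll_interval = 0.01, timeout = 5)
    expect_identical(http_result$state, stub_result$state, label = terminal)
    expect_identical(http_result$passed, stub_result$passed, label = terminal)
  }
})

test_that("transport failures and unknown server states map to SYSTEM_ERROR", {
  fx <- local_fixture_meta()
  req <- build_run_request(fx$meta, fx$meta$testing[[1]])
  failing <- http_wes("https://wes.example.org",
                      transport = function(method, url, body = NULL, token = NULL)
                        list(status = 503L, body = ""))
  result <- run_test(req, failing, poll_interval = 0.01, timeout = 5)
  expect_identical(result$state, "SYSTEM_ERROR")
  expect_match(result$log_excerpt, "submission failed")

  weird <- http_wes("https://wes.example.org",
                    transport = function(method, url, body = NULL, token = NULL) {
                      if (method == "POST")
                        list(status = 200L, body = '{"run_id": "r1"}')
                      else list(status = 200L, body = '{"state": "EXPLODED"}')
                    })
  result2 <- run_test(req, weird, poll_interval = 0.01, timeout = 5)
  expect_identical(result2$state, "SYSTEM_ERROR")
  expect_match(result2$log_excerpt, "unrecognized WES state")
})
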