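# GA4GH WES test execution: a test case becomes a WES run request
# (workflow URL + type, a workflow-parameters document, attachments),
# submitted to an endpoint and polled until a terminal state. A test passes
# if and only if the run reaches COMPLETE — the method deliberately judges
# the execution status, not output content. A deterministic in-process stub
# implements the minimal WES surface so the whole pipeline works offline;
# an HTTP endpoint with an injectable transport covers real WES instances.

WES_TERMINAL_STATES <- c("COMPLETE", "EXECUTOR_ERROR", "SYSTEM_ERROR", "CANCELED")

#' Build a WES run request from a test case
#'
#' The test case's workflow-parameters document becomes `workflow_params`,
#' an engine-parameters file (if present) becomes
#' `workflow_engine_parameters`, and every other test file becomes an
#' attachment at its target path. Workflow type and version mirror the
#' metadata's language.
#'
#' @param meta A [workflow_metadata()].
#' @param test One of `meta$testing`.
#' @param resolver Resolver used to fetch the test files.
#' @return An object of class `wes_run_request`.
#' @export
build_run_request <- function(meta, test, resolver = local_resolver()) {
  fetch <- function(url) {
    res <- resolve(resolver, url)
    if (!res$exists)
      wfr_abort(sprintf("test file not found: %s", url), "wfr_ref_error")
    rawToChar(res$content)
  }
  params <- NULL
  engine_params <- NULL
  attachments <- list()
  for (f in test$files) {
    kind <- f$kind %||% "data"
    if (kind == "workflow_params") {
      params <- fetch(f$url)
    } else if (kind == "engine_params") {
      engine_params <- fetch(f$url)
    } else {
      attachments[[length(attachments) + 1L]] <-
        list(target = f$target, content = fetch(f$url))
    }
  }
  if (is.null(params))
    wfr_abort(sprintf("test case %s has no workflow-parameters document",
                      test$test_id), "wfr_ref_error")
  structure(
    list(
      test_id = test$test_id,
      workflow_url = primary_file(meta)$url,
      workflow_type = meta$language$type,
      workflow_type_version = meta$language$version,
      workflow_params = params,
      workflow_engine_parameters = engine_params,
      attachments = attachments
    ),
    class = "wes_run_request"
  )
}

#' Deterministic stub WES endpoint
#'
#' Implements the minimal WES surface in-process: submitting a run returns
#' a run id; polling walks QUEUED, RUNNING, then the scripted terminal
#' state once the scripted delay has elapsed. The script maps a test id (or
#' `"*"` as a catch-all) to a terminal state and an optional delay in
#' seconds. Concurrent runs are independent.
#'
#' @param script Named list: `test_id` (or `"*"`) -> terminal state string,
#'   or `list(state =, delay =)`.
#' @return A WES endpoint usable with [run_test()]; `$log` records
#'   submissions and polls.
#' @export
stub_wes <- function(script = list(`*` = "COMPLETE")) {
  state <- new.env(parent = emptyenv())
  state$runs <- list()
  state$counter <- 0L
  state$polls <- integer()
  structure(list(script = script, state = state), class = "wes_stub")
}

wes_submit <- function(endpoint, request) UseMethod("wes_submit")
wes_status <- function(endpoint, run_id) UseMethod("wes_status")

#' @export
wes_submit.wes_stub <- function(endpoint, request) {
  st <- endpoint$state
  st$counter <- st$counter + 1L
  run_id <- sprintf("run-%04d", st$counter)
  entry <- endpoint$script[[request$test_id]] %||% endpoint$script[["*"]]
  if (is.null(entry))
    wfr_abort(sprintf("stub has no script for test %s", request$test_id),
              "wfr_ref_error")
  if (is.character(entry)) entry <- list(state = entry, delay = 0)
  st$runs[[run_id]] <- list(
    terminal = entry$state, delay = entry$delay %||% 0,
    submitted = as.numeric(Sys.time())
  )
  st$polls[[run_id]] <- 0L
  run_id
}

#' @export
wes_status.wes_stub <- function(endpoint, run_id) {
  st <- endpoint$state
  run <- st$runs[[run_id]]
  if (is.null(run))
    wfr_abort(sprintf("unknown run id: %s", run_id), "wfr_ref_error")
  st$polls[[run_id]] <- st$polls[[run_id]] + 1L
  elapsed <- as.numeric(Sys.time()) - run$submitted
  if (elapsed >= run$delay) run$terminal
  else if (st$polls[[run_id]] == 1L) "QUEUED"
  else "RUNNING"
}

#' HTTP WES endpoint
#'
#' Speaks the GA4GH WES runs protocol against a remote instance through an
#' injectable transport `function(method, url, body)` returning
#' `list(status, body)` with `body` parsed-JSON-compatible text. Unrecognized
#' or missing states from the server map to SYSTEM_ERROR (fail safe).
#'
#' @param base_url Service base URL (e.g. `https://wes.example.org/ga4gh/wes/v1`).
#' @param transport Transport function; the default uses base R connections
#'   and supports only GET polling, so supplying a transport is expected for
#'   production use.
#' @param token Optional bearer token forwarded to the transport.
#' @return A WES endpoint usable with [run_test()].
#' @export
http_wes <- function(base_url, transport = NULL, token = NULL) {
  structure(list(base_url = sub("/$", "", base_url),
                 transport = transport %||% base_wes_transport,
                 token = token),
            class = "wes_http")
}

base_wes_transport <- function(method, url, body = NULL, token = NULL) {
  if (method != "GET")
    wfr_abort("the built-in WES transport supports only GET; supply a transport function for run submission",
              "wfr_transport_error")
  con <- url(url)
  on.exit(try(close(con), silent = TRUE))
  txt <- tryCatch(paste(readLines(con, warn = FALSE), collapse = "\n"),
                  error = function(e) e)
  if (inherits(txt, "error"))
    return(list(status = 599L, body = conditionMessage(txt)))
  list(status = 200L, body = txt)
}

#' @export
wes_submit.wes_http <- function(endpoint, request) {
  body <- jsonlite::toJSON(compact(list(
    workflow_url = request$workflow_url,
    workflow_type = request$workflow_type,
    workflow_type_version = request$workflow_type_version,
    workflow_params = request$workflow_params,
    workflow_engine_parameters = request$workflow_engine_parameters,
    workflow_attachment = lapply(request$attachments, function(a)
      list(target = a$target, content = a$content))
  )), auto_unbox = TRUE)
  out <- endpoint$transport("POST", paste0(endpoint$base_url, "/runs"),
                            body = as.character(body), token = endpoint$token)
  if ((out$status %||% 599L) >= 300L)
    wfr_abort(sprintf("WES run submission failed: HTTP %s", out$status),
              "wfr_transport_error")
  parsed <- jsonlite::fromJSON(out$body, simplifyVector = FALSE)
  parsed$run_id %||% wfr_abort("WES response carried no run_id", "wfr_transport_error")
}

#' @export
wes_status.wes_http <- function(endpoint, run_id) {
  out <- endpoint$transport(
    "GET", paste0(endpoint$base_url, "/runs/", run_id, "/status"),
    body = NULL, token = endpoint$token)
  if ((out$status %||% 599L) >= 300L)
    wfr_abort(sprintf("WES status poll failed: HTTP %s", out$status),
              "wfr_transport_error")
  parsed <- jsonlite::fromJSON(out$body, simplifyVector = FALSE)
  parsed$state %||% "SYSTEM_ERROR"
}

test_result <- function(test_id, state, log_excerpt = "", duration = 0) {
  structure(
    list(test_id = test_id, state = state, passed = identical(state, "COMPLETE"),
         log_excerpt = log_excerpt, duration = duration),
    class = "wf_test_result"
  )
}

#' Run one WES test to its terminal state
#'
#' Submits the request and polls at `poll_interval` until a terminal state
#' or `timeout` seconds. A timeout yields SYSTEM_ERROR with a timeout
#' message; transport errors (after the endpoint's retries) also yield a
#' SYSTEM_ERROR result rather than an R error — an environment failure is a
#' failed test run, not an aborted one. `passed` is TRUE exactly when the
#' terminal state is COMPLETE; a state outside the WES vocabulary maps to
#' SYSTEM_ERROR.
#'
#' @param request A [build_run_request()] result.
#' @param endpoint A [stub_wes()] or [http_wes()] endpoint.
#' @param poll_interval Seconds between status polls (default 5).
#' @param timeout Overall wall-clock budget in seconds (default 3600).
#' @return A `wf_test_result` with `test_id`, `state`, `passed`,
#'   `log_excerpt`, `duration`.
#' @export
run_test <- function(request, endpoint, poll_interval = 5, timeout = 3600) {
  start <- as.numeric(Sys.time())
  finish <- function(state, log_excerpt) {
    test_result(request$test_id, state, log_excerpt,
                duration = as.numeric(Sys.time()) - start)
  }
  run_id <- tryCatch(wes_submit(endpoint, request), error = function(e) e)
  if (inherits(run_id, "error"))
    return(finish("SYSTEM_ERROR",
                  paste0("submission failed: ", conditionMessage(run_id))))
  log_lines <- c(sprintf("submitted run %s for test %s", run_id, request$test_id))
  repeat {
    state <- tryCatch(wes_status(endpoint, run_id), error = function(e) e)
    if (inherits(state, "error"))
      return(finish("SYSTEM_ERROR",
                    paste0("status poll failed: ", conditionMessage(state))))
    log_lines <- c(log_lines, sprintf("state: %s", state))
    if (state %in% WES_TERMINAL_STATES)
      return(finish(state, paste(log_lines, collapse = "\n")))
    if (!(state %in% c("QUEUED", "INITIALIZING", "RUNNING", "PAUSED", "CANCELING")))
      return(finish("SYSTEM_ERROR",
                    sprintf("unrecognized WES state: %s", state)))
    if (as.numeric(Sys.time()) - start >= timeout)
      return(finish("SYSTEM_ERROR",
                    sprintf("timed out after %gs awaiting a terminal state", timeout)))
    Sys.sleep(poll_interval)
  }
}

#' Run every test case of a metadata document
#'
#' Test cases run sequentially and never short-circuit: every case yields a
#' result even after a failure. The aggregate passes when all do.
#'
#' @inheritParams run_test
#' @param meta A [workflow_metadata()].
#' @param resolver Resolver for test files.
#' @param log_dir Optional directory; when given, one log file per test is
#'   written under it.
#' @return List of `wf_test_result`, with attribute `passed` (all passed).
#' @export
run_all_tests <- function(meta, endpoint, resolver = local_resolver(),
                          poll_interval = 5, timeout = 3600, log_dir = NULL) {
  results <- lapply(meta$testing, function(tc) {
    req <- tryCatch(build_run_request(meta, tc, resolver), error = function(e) e)
    if (inherits(req, "error")) {
      test_result(tc$test_id, "SYSTEM_ERROR",
                  paste0("request build failed: ", conditionMessage(req)))
    } else {
      run_test(req, endpoint, poll_interval = poll_interval, timeout = timeout)
    }
  })
  if (!is.null(log_dir)) {
    dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in results) {
      writeLines(
        c(sprintf("test: %s", r$test_id), sprintf("state: %s", r$state),
          sprintf("passed: %s", r$passed), "", r$log_excerpt),
        file.path(log_dir, paste0(r$test_id, ".log")))
    }
  }
  attr(results, "passed") <- all(vapply(results, function(r) r$passed, logical(1)))
  results
}

#' @export
print.wf_test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: %s (%s, %.2fs)\n", x$test_id, x$state,
              if (x$passed) "passed" else "failed", x$duration))
  invisible(x)
}
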