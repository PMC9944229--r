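# The three-phase publication lifecycle: submission (validate + test),
# review (a human gate), publication (persist files via an archiver that
# mints a DOI, rewrite metadata URLs to the persisted locations, emit the
# TRS registry). Any failure halts the pipeline in-phase; the registry
# output directory is written only after everything upstream has passed.

#' Local archiver with deterministic DOI minting
#'
#' Stores archived files under `dir/<doi-suffix>/<target>` and mints
#' deterministic DOIs `10.5072/<first 8 id chars>.<version>` in the
#' reserved test prefix namespace, so archiving the same workflow version
#' twice is idempotent. A drop-in stand-in for a data-repository backend
#' (the archiver contract is where a Zenodo-style service would plug in).
#'
#' @param dir Archive root directory.
#' @return An object of class `wf_local_archiver`.
#' @export
local_archiver <- function(dir) {
  structure(list(dir = dir), class = c("wf_local_archiver", "wf_archiver"))
}

archiver_mint_doi <- function(archiver, meta) UseMethod("archiver_mint_doi")
archiver_store <- function(archiver, meta, doi, staged) UseMethod("archiver_store")

#' @export
archiver_mint_doi.wf_local_archiver <- function(archiver, meta) {
  sprintf("10.5072/%s.%s", substr(meta$id, 1, 8), meta$version)
}

#' @export
archiver_store.wf_local_archiver <- function(archiver, meta, doi, staged) {
  record_dir <- file.path(archiver$dir, sub("^10\\.5072/", "", doi))
  # stage fully, then move into place: a failure leaves no partial archive
  tmp <- paste0(record_dir, ".staging")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE)
  urls <- character()
  for (item in staged) {
    dest <- file.path(tmp, item$target)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    writeBin(item$content, dest)
    urls[[item$url]] <- path_to_file_url(file.path(record_dir, item$target))
  }
  unlink(record_dir, recursive = TRUE)
  dir.create(dirname(record_dir), recursive = TRUE, showWarnings = FALSE)
  if (!file.rename(tmp, record_dir))
    wfr_abort(sprintf("could not move staged archive into place: %s", record_dir),
              "wfr_archive_error")
  urls
}

#' Persist a workflow's files through an archiver
#'
#' Resolves every file entry of the metadata (and every test file) and
#' hands the contents to the archiver, which mints a DOI and returns a
#' persistent URL per original URL. All-or-nothing: any unresolvable file
#' or archiver failure aborts with no partial receipt.
#'
#' @param meta A validated [workflow_metadata()].
#' @param archiver An archiver such as [local_archiver()].
#' @param resolver Resolver for the original file locations.
#' @param extra_files Optional named list `target -> content` of additional
#'   artifacts to retain alongside the workflow (e.g. test logs).
#' @return An `archive_receipt`: `$doi`, `$persisted_urls` (named map
#'   original URL -> persistent URL).
#' @export
persist_files <- function(meta, archiver, resolver = local_resolver(),
                          extra_files = NULL) {
  staged <- list()
  seen <- character()
  stage <- function(f) {
    if (f$url %in% seen) return(invisible())
    res <- resolve(resolver, f$url)
    if (!res$exists)
      wfr_abort(sprintf("cannot archive unresolvable file: %s", f$url),
                "wfr_archive_error")
    staged[[length(staged) + 1L]] <<-
      list(url = f$url, target = f$target, content = res$content)
    seen <<- c(seen, f$url)
  }
  for (f in meta$files) stage(f)
  for (tc in meta$testing) for (f in tc$files) stage(f)
  # retain the documentation too, so the published record re-validates
  # against the archive alone
  readme_res <- tryCatch(resolve(resolver, meta$readme_url),
                         error = function(e) list(exists = FALSE))
  if (!(meta$readme_url %in% seen) && readme_res$exists) {
    staged[[length(staged) + 1L]] <-
      list(url = meta$readme_url, target = basename(meta$readme_url),
           content = readme_res$content)
    seen <- c(seen, meta$readme_url)
  }
  for (target in names(extra_files %||% list())) {
    content <- extra_files[[target]]
    if (is.character(content)) content <- charToRaw(paste(content, collapse = "\n"))
    staged[[length(staged) + 1L]] <-
      list(url = paste0("about:", target), target = target, content = content)
  }
  doi <- archiver_mint_doi(archiver, meta)
  urls <- archiver_store(archiver, meta, doi, staged)
  urls <- urls[!startsWith(names(urls), "about:")]
  structure(list(doi = doi, persisted_urls = as.list(urls)),
            class = "archive_receipt")
}

#' Rewrite metadata URLs to their persisted locations
#'
#' Returns a copy of the metadata in which every file URL (workflow files
#' and test files) is replaced by its persistent URL from the receipt and
#' the DOI is set; every other field is unchanged. A receipt that does not
#' cover some file URL is an error.
#'
#' @param meta A [workflow_metadata()].
#' @param receipt A [persist_files()] receipt.
#' @return The rewritten `workflow_metadata`.
#' @export
rewrite_urls <- function(meta, receipt) {
  lookup <- function(url) {
    p <- receipt$persisted_urls[[url]]
    if (is.null(p))
      wfr_abort(sprintf("receipt does not cover file URL: %s", url),
                "wfr_archive_error")
    p
  }
  meta$files <- lapply(meta$files, function(f) { f$url <- lookup(f$url); f })
  meta$testing <- lapply(meta$testing, function(tc) {
    tc$files <- lapply(tc$files, function(f) { f$url <- lookup(f$url); f })
    tc
  })
  if (!is.null(receipt$persisted_urls[[meta$readme_url]]))
    meta$readme_url <- receipt$persisted_urls[[meta$readme_url]]
  meta$doi <- receipt$doi
  meta
}

# --- lifecycle record --------------------------------------------------------

LIFECYCLE_PHASES <- c("submission", "review", "publication")

new_lifecycle_record <- function() {
  structure(
    list(phase = "submission",
         phases_entered = "submission",
         events = data.frame(timestamp = character(), phase = character(),
                             action = character(), outcome = character(),
                             stringsAsFactors = FALSE)),
    class = "lifecycle_record"
  )
}

record_event <- function(record, action, outcome) {
  record$events[nrow(record$events) + 1L, ] <-
    list(format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"), record$phase, action, outcome)
  record
}

advance_phase <- function(record, phase) {
  stopifnot(phase %in% LIFECYCLE_PHASES)
  if (match(phase, LIFECYCLE_PHASES) < match(record$phase, LIFECYCLE_PHASES))
    wfr_abort(sprintf("lifecycle cannot move backwards: %s -> %s",
                      record$phase, phase), "wfr_lifecycle_error")
  if (!(phase %in% record$phases_entered))
    record$phases_entered <- c(record$phases_entered, phase)
  record$phase <- phase
  record
}

#' @export
print.lifecycle_record <- function(x, ...) {
  cat(sprintf("<lifecycle_record> phase: %s\n", x$phase))
  for (i in seq_len(nrow(x$events))) {
    cat(sprintf("  [%s] %-12s %-18s %s\n", x$events$timestamp[i],
                x$events$phase[i], x$events$action[i], x$events$outcome[i]))
  }
  invisible(x)
}

# --- pipeline ----------------------------------------------------------------

#' Submit a workflow: validate and test (the submission phase)
#'
#' Runs [validate_workflow()] and then [run_all_tests()]; on full success
#' the record advances to the review phase, staged for a human
#' approve-and-publish decision. Any failure leaves the record halted in
#' the submission phase with the failing step in its event log — nothing is
#' archived or emitted.
#'
#' @param meta A schema-valid [workflow_metadata()].
#' @param resolver Resolver for files.
#' @param wes_endpoint A [stub_wes()] or [http_wes()] endpoint.
#' @param poll_interval,timeout Passed to [run_all_tests()].
#' @param log_dir Optional per-test log directory.
#' @return A `wf_submission`: `$record` (lifecycle), `$meta`, `$report`,
#'   `$test_results`, `$ok`.
#' @export
submit_workflow <- function(meta, resolver = local_resolver(),
                            wes_endpoint = stub_wes(),
                            poll_interval = 5, timeout = 3600,
                            log_dir = NULL) {
  record <- new_lifecycle_record()
  report <- validate_workflow(meta, resolver)
  record <- record_event(record, "validate",
                         if (report$overall) "pass"
                         else paste0("fail: ",
                                     paste(report$results$requirement[!report$results$passed],
                                           collapse = ", ")))
  test_results <- NULL
  if (report$overall) {
    test_results <- run_all_tests(meta, wes_endpoint, resolver,
                                  poll_interval = poll_interval,
                                  timeout = timeout, log_dir = log_dir)
    passed <- attr(test_results, "passed")
    record <- record_event(record, "test",
                           if (passed) "pass"
                           else paste0("fail: ",
                                       paste(vapply(test_results, function(r)
                                         sprintf("%s=%s", r$test_id, r$state),
                                         character(1)), collapse = ", ")))
    if (passed) {
      record <- advance_phase(record, "review")
      record <- record_event(record, "stage_for_review", "awaiting approval")
    }
  }
  structure(
    list(record = record, meta = meta, report = report,
         test_results = test_results,
         ok = report$overall && isTRUE(attr(test_results, "passed"))),
    class = "wf_submission"
  )
}

#' Approve a submission and publish it (the publication phase)
#'
#' The review gate: given a staged submission that passed validation and
#' testing, persists all files through the archiver, rewrites the metadata
#' to the persisted URLs (appending the DOI), regenerates the TRS response,
#' and writes the static registry. Refuses a submission that did not pass.
#'
#' @param submission A passing [submit_workflow()] result.
#' @param archiver Archiver backend, e.g. [local_archiver()].
#' @param out_dir Registry output directory; untouched unless publication
#'   succeeds.
#' @param registry_base_url Base URL recorded in the TRS documents.
#' @param resolver Resolver for the original file locations.
#' @param verified_source Registry name recorded as TRS verification source.
#' @return The completed `wf_submission` with `$record` in the publication
#'   phase, `$published_meta`, `$receipt` and `$written` file list.
#' @export
approve_and_publish <- function(submission, archiver, out_dir,
                                registry_base_url = "https://registry.example.org",
                                resolver = local_resolver(),
                                verified_source = "wfregistry") {
  if (!isTRUE(submission$ok))
    wfr_abort("cannot publish a submission that did not pass validation and testing",
              "wfr_lifecycle_error")
  record <- submission$record
  record <- record_event(record, "approve", "approved")
  record <- advance_phase(record, "publication")

  logs <- list()
  for (r in submission$test_results %||% list()) {
    logs[[paste0("test-logs/", r$test_id, ".log")]] <-
      c(sprintf("test: %s", r$test_id), sprintf("state: %s", r$state), r$log_excerpt)
  }
  receipt <- persist_files(submission$meta, archiver, resolver,
                           extra_files = logs)
  record <- record_event(record, "persist_files", paste0("doi ", receipt$doi))

  published <- rewrite_urls(submission$meta, receipt)
  record <- record_event(record, "rewrite_urls", "rewritten to persisted URLs")

  tree <- to_trs(list(published), registry_base_url,
                 resolver = local_resolver(), verified = TRUE,
                 verified_source = verified_source)
  written <- write_registry(tree, out_dir)
  record <- record_event(record, "write_registry",
                         sprintf("%d documents", length(written)))

  submission$record <- record
  submission$published_meta <- published
  submission$receipt <- receipt
  submission$tree <- tree
  submission$written <- written
  submission
}

#' Run the full three-phase lifecycle for one workflow
#'
#' Convenience wrapper: [submit_workflow()], then — only when submission
#' passed and `approve = TRUE` — [approve_and_publish()]. The two-call form
#' exists so a human review can sit between the phases.
#'
#' @inheritParams submit_workflow
#' @inheritParams approve_and_publish
#' @param approve Automatically approve a passing submission.
#' @return A `wf_submission`; inspect `$record` for the phase reached.
#' @export
publish_workflow <- function(meta, resolver = local_resolver(),
                             wes_endpoint = stub_wes(),
                             archiver, out_dir,
                             registry_base_url = "https://registry.example.org",
                             approve = TRUE, poll_interval = 5,
                             timeout = 3600) {
  submission <- submit_workflow(meta, resolver, wes_endpoint,
                                poll_interval = poll_interval, timeout = timeout)
  if (!submission$ok || !approve) return(submission)
  approve_and_publish(submission, archiver, out_dir,
                      registry_base_url = registry_base_url,
                      resolver = resolver)
}
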