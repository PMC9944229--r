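# Resource resolution: every retrieval of workflow files and repository
# facts goes through a resolver so that remote services and local fixtures
# are interchangeable. A definitive not-found is a *result* (exists = FALSE,
# a metadata defect); a transport failure is an *error* (an environment
# defect), retried with exponential backoff before being raised.

#' Construct a resource reference
#'
#' @param url Absolute URL with scheme `http`, `https` or `file`.
#' @return An object of class `resource_ref`.
#' @export
resource_ref <- function(url) {
  scheme <- url_scheme(url)
  if (is.na(scheme) || !(scheme %in% c("http", "https", "file")))
    wfr_abort(sprintf("unsupported or missing URL scheme: %s", url),
              "wfr_ref_error")
  structure(list(url = url, scheme = scheme), class = "resource_ref")
}

as_resource_ref <- function(x) {
  if (inherits(x, "resource_ref")) x else resource_ref(x)
}

new_resolver <- function(class, ..., timeout_seconds = 10, max_retries = 3,
                         backoff_factor = 2, retry_delay = 1) {
  structure(
    list(..., timeout_seconds = timeout_seconds, max_retries = max_retries,
         backoff_factor = backoff_factor, retry_delay = retry_delay),
    class = c(class, "wf_resolver")
  )
}

#' Local filesystem resolver
#'
#' Resolves `file://` URLs directly against the filesystem. The offline
#' backend used for fixtures and archived registries.
#'
#' @param ... Configuration overrides (`timeout_seconds`, `max_retries`,
#'   `backoff_factor`, `retry_delay`).
#' @return A resolver usable with [resolve()].
#' @export
local_resolver <- function(...) new_resolver("wf_local_resolver", ...)

#' Scripted mock HTTP resolver
#'
#' An in-process stand-in for a remote file host. `responses` maps URL to
#' either content (character or raw: always served with status 200) or a
#' list with `status` (an integer vector consumed one element per request,
#' the last repeating) and optional `content`. Status 404 yields a
#' not-found; 5xx statuses are transport failures and exercise the retry
#' path.
#'
#' @param responses Named list keyed by URL.
#' @param ... Configuration overrides; tests typically set `retry_delay = 0`.
#' @return A resolver usable with [resolve()]; its `$log` environment
#'   records every request for inspection.
#' @export
mock_http_resolver <- function(responses = list(), ...) {
  state <- new.env(parent = emptyenv())
  state$hits <- character()
  state$cursor <- list()
  new_resolver("wf_mock_resolver", responses = responses, log = state, ...)
}

#' Remote HTTP resolver
#'
#' Fetches `http(s)` URLs through an injectable transport function
#' `function(url, timeout_seconds)` returning `list(status, content)` with
#' `content` a raw vector. The default transport uses base R connections.
#' `file://` URLs are delegated to the local backend so a single resolver
#' can serve mixed metadata.
#'
#' @param transport Transport function; injectable for testing.
#' @param token Optional opaque bearer token passed to the transport.
#' @param ... Configuration overrides.
#' @return A resolver usable with [resolve()].
#' @export
remote_resolver <- function(transport = NULL, token = NULL, ...) {
  new_resolver("wf_remote_resolver",
               transport = transport %||% base_http_transport,
               token = token, ...)
}

base_http_transport <- function(url, timeout_seconds = 10, token = NULL) {
  con <- url(url, open = "rb")
  on.exit(try(close(con), silent = TRUE))
  content <- tryCatch(
    readBin(con, what = "raw", n = 64 * 1024 * 1024),
    error = function(e) e
  )
  if (inherits(content, "error")) {
    msg <- conditionMessage(content)
    status <- if (grepl("404|cannot open", msg)) 404L else 599L
    return(list(status = status, content = raw()))
  }
  list(status = 200L, content = content)
}

#' Resolve a resource reference
#'
#' @param resolver A resolver from [local_resolver()], [mock_http_resolver()]
#'   or [remote_resolver()].
#' @param ref A [resource_ref()] or URL string.
#' @return `list(exists, content, length)`; `exists = FALSE` (not an error)
#'   for a definitive not-found. Transport failures raise a
#'   `wfr_transport_error` after the configured retries.
#' @export
resolve <- function(resolver, ref) UseMethod("resolve")

#' @export
resolve.wf_local_resolver <- function(resolver, ref) {
  ref <- as_resource_ref(ref)
  if (ref$scheme != "file")
    wfr_abort(sprintf("local resolver cannot fetch %s URLs", ref$scheme),
              "wfr_ref_error")
  path <- file_url_to_path(ref$url)
  if (!file.exists(path) || dir.exists(path))
    return(list(exists = FALSE, content = raw(), length = 0L))
  content <- readBin(path, what = "raw", n = file.size(path))
  list(exists = TRUE, content = content, length = length(content))
}

#' @export
resolve.wf_mock_resolver <- function(resolver, ref) {
  ref <- as_resource_ref(ref)
  fetch_once <- function() {
    resolver$log$hits <- c(resolver$log$hits, ref$url)
    entry <- resolver$responses[[ref$url]]
    if (is.null(entry)) return(list(status = 404L, content = raw()))
    if (is.character(entry)) entry <- list(status = 200L, content = entry)
    if (is.raw(entry)) entry <- list(status = 200L, content = entry)
    status <- entry$status %||% 200L
    if (length(status) > 1L) {
      i <- resolver$log$cursor[[ref$url]] %||% 1L
      resolver$log$cursor[[ref$url]] <- min(i + 1L, length(status))
      status <- status[[min(i, length(status))]]
    }
    content <- entry$content %||% raw()
    if (is.character(content)) content <- charToRaw(paste(content, collapse = "\n"))
    list(status = status, content = content)
  }
  resolve_with_retry(resolver, ref, fetch_once)
}

#' @export
resolve.wf_remote_resolver <- function(resolver, ref) {
  ref <- as_resource_ref(ref)
  if (ref$scheme == "file") return(resolve(local_resolver(), ref))
  fetch_once <- function() {
    resolver$transport(ref$url, timeout_seconds = resolver$timeout_seconds,
                       token = resolver$token)
  }
  resolve_with_retry(resolver, ref, fetch_once)
}

# Shared status-code semantics: 2xx success, 404/410 not-found, everything
# else a transport failure retried max_retries times with exponential backoff.
resolve_with_retry <- function(resolver, ref, fetch_once) {
  attempts <- resolver$max_retries + 1L
  last <- NULL
  for (attempt in seq_len(attempts)) {
    out <- tryCatch(fetch_once(), error = function(e) e)
    if (!inherits(out, "error")) {
      status <- out$status %||% 599L
      if (status >= 200L && status < 300L) {
        content <- out$content
        return(list(exists = TRUE, content = content, length = length(content)))
      }
      if (status %in% c(404L, 410L))
        return(list(exists = FALSE, content = raw(), length = 0L))
      last <- sprintf("HTTP status %d", status)
    } else {
      last <- conditionMessage(out)
    }
    if (attempt < attempts)
      Sys.sleep(resolver$retry_delay * resolver$backoff_factor^(attempt - 1L))
  }
  wfr_abort(
    sprintf("transport failure fetching %s after %d attempts: %s",
            ref$url, attempts, last),
    "wfr_transport_error", url = ref$url
  )
}

#' Check whether a reference resolves
#'
#' @inheritParams resolve
#' @return `TRUE`/`FALSE`; transport errors propagate.
#' @export
resource_exists <- function(resolver, ref) resolve(resolver, ref)$exists

# --- repository inspection ---------------------------------------------------

#' Construct a repository-facts record
#' @keywords internal
#' @noRd
repo_facts <- function(owner, repo, default_ref, license, file_listing) {
  structure(
    list(owner = owner, repo = repo, default_ref = default_ref,
         license = license, file_listing = file_listing),
    class = "repo_facts"
  )
}

# Map well-known license texts/identifiers found in a LICENSE file to an
# SPDX-style identifier; UNKNOWN when unrecognized.
detect_license_id <- function(text) {
  head_text <- paste(utils::head(strsplit(text, "\n")[[1]], 10), collapse = " ")
  patterns <- list(
    "Apache-2.0" = "Apache License.*Version 2\\.0|Apache-2\\.0",
    "MIT" = "MIT License|\\bMIT\\b",
    "GPL-3.0-only" = "GNU GENERAL PUBLIC LICENSE[^0-9]*Version 3",
    "GPL-2.0-only" = "GNU GENERAL PUBLIC LICENSE[^0-9]*Version 2",
    "LGPL-3.0-only" = "GNU LESSER GENERAL PUBLIC LICENSE[^0-9]*Version 3",
    "BSD-3-Clause" = "BSD 3-Clause|BSD-3-Clause",
    "BSD-2-Clause" = "BSD 2-Clause|BSD-2-Clause",
    "MPL-2.0" = "Mozilla Public License.*2\\.0",
    "CC0-1.0" = "CC0 1\\.0",
    "Unlicense" = "This is free and unencumbered software"
  )
  for (id in names(patterns)) {
    if (grepl(patterns[[id]], head_text, ignore.case = FALSE)) return(id)
  }
  "UNKNOWN"
}

#' Inspect a workflow repository
#'
#' Derives repository facts (owner, repo, default ref, license, file
#' listing) from a locator. Local directories (path or `file://` URL, or a
#' file within one) are inspected directly: owner/repo come from the last
#' two path segments, the default ref is `"main"`, and the license is read
#' from a `LICENSE`/`LICENSE.md`/`LICENSE.txt` file when present.
#' Hosting-service `blob`/`raw`/`tree` URL shapes are decomposed into
#' owner/repo/ref without network access.
#'
#' @param locator Directory path, `file://` URL (of the repo or a file in
#'   it), or hosting-service URL.
#' @return An object of class `repo_facts`.
#' @export
inspect_repository <- function(locator) {
  scheme <- url_scheme(locator)
  if (is.na(scheme) || scheme == "file") {
    path <- if (!is.na(scheme)) file_url_to_path(locator) else locator
    if (file.exists(path) && !dir.exists(path)) path <- dirname(path)
    if (!dir.exists(path))
      wfr_abort(sprintf("unreadable directory: %s", path), "wfr_ref_error")
    path <- normalizePath(path, winslash = "/")
    segments <- strsplit(path, "/", fixed = TRUE)[[1]]
    segments <- segments[nzchar(segments)]
    n <- length(segments)
    owner <- if (n >= 2) segments[n - 1] else "UNKNOWN"
    repo <- if (n >= 1) segments[n] else "UNKNOWN"
    listing <- sort(list.files(path, recursive = TRUE, all.files = FALSE))
    license <- "UNKNOWN"
    for (cand in c("LICENSE", "LICENSE.md", "LICENSE.txt")) {
      lp <- file.path(path, cand)
      if (file.exists(lp)) {
        license <- detect_license_id(
          paste(readLines(lp, warn = FALSE), collapse = "\n"))
        break
      }
    }
    return(repo_facts(owner, repo, "main", license, listing))
  }
  # hosting-service URL shapes:
  #   https://host/{owner}/{repo}/(blob|raw|tree)/{ref}/...
  #   https://raw.host/{owner}/{repo}/{ref}/...
  rest <- sub("^https?://[^/]+/", "", locator)
  parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
  if (length(parts) >= 4 && parts[3] %in% c("blob", "raw", "tree")) {
    return(repo_facts(parts[1], parts[2], parts[4], "UNKNOWN", character()))
  }
  if (grepl("^https?://raw\\.", locator) && length(parts) >= 3) {
    return(repo_facts(parts[1], parts[2], parts[3], "UNKNOWN", character()))
  }
  wfr_abort(sprintf("unrecognized repository locator: %s", locator),
            "wfr_ref_error")
}
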