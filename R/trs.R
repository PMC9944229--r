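# Static GA4GH TRS (Tool Registry Service) publication: published metadata
# records are transformed into a tree of path-addressed JSON documents
# (/tools, /tools/{id}, /tools/{id}/versions, /tools/{id}/versions/{v},
# plus the per-version files and tests sub-paths), written so that a plain
# static file server reproduces the TRS 2.x API.

TRS_FILE_TYPES <- c(primary = "PRIMARY_DESCRIPTOR",
                    secondary = "SECONDARY_DESCRIPTOR",
                    test = "TEST_FILE",
                    other = "OTHER")

trs_checksum <- function(content) {
  list(checksum = sha256_hex(content), type = "sha-256")
}

trs_version_doc <- function(meta, registry_base_url, verified, verified_source) {
  tool_url <- paste0(registry_base_url, "/tools/", meta$id)
  list(
    id = meta$version,
    url = paste0(tool_url, "/versions/", meta$version),
    name = meta$name,
    author = lapply(meta$authors, function(a)
      if (nzchar(a$name)) a$name else a$account),
    descriptor_type = list(meta$language$type),
    verified = isTRUE(verified),
    verified_source = if (isTRUE(verified)) list(verified_source) else list(),
    meta_version = meta$version
  )
}

trs_files_doc <- function(meta, resolver) {
  lapply(meta$files, function(f) {
    res <- resolve(resolver, f$url)
    if (!res$exists)
      wfr_abort(sprintf("cannot checksum unresolvable file: %s", f$url),
                "wfr_ref_error")
    list(path = f$target,
         file_type = unname(TRS_FILE_TYPES[[f$role]]),
         checksum = trs_checksum(res$content))
  })
}

trs_tests_doc <- function(meta, resolver) {
  lapply(meta$testing, function(tc) {
    pf <- params_file(tc)
    res <- resolve(resolver, pf$url)
    if (!res$exists)
      wfr_abort(sprintf("cannot publish unresolvable test parameters: %s", pf$url),
                "wfr_ref_error")
    content <- rawToChar(res$content)
    list(id = tc$test_id, content = content, checksum = trs_checksum(content))
  })
}

#' Build a static TRS response tree from published metadata
#'
#' Groups the metadata records by workflow id and emits, per id, a tool
#' document and a versions list, and per version the version document plus
#' exactly two sub-path documents: `/files` (every file entry with its TRS
#' file type and a sha-256 checksum) and `/tests` (the test cases'
#' parameter documents). The version path is
#' `/tools/{id}/versions/{version_id}` with the metadata version string as
#' `{version_id}`.
#'
#' @param metas List of validated [workflow_metadata()] records.
#' @param registry_base_url Base URL the registry will be served from.
#' @param resolver Resolver used to fetch file contents for checksumming.
#' @param verified Logical (recycled): whether the registry verified the
#'   version by running its tests; set by the publication pipeline.
#' @param verified_source Registry name recorded as the verification
#'   source when `verified` is TRUE.
#' @return An object of class `trs_document_tree`: `$documents` is a named
#'   list keyed by endpoint path, `$metadata_text` the co-publishable
#'   serialized metadata keyed by version path.
#' @export
to_trs <- function(metas, registry_base_url, resolver = local_resolver(),
                   verified = FALSE, verified_source = "workflow registry") {
  if (inherits(metas, "workflow_metadata")) metas <- list(metas)
  registry_base_url <- sub("/$", "", registry_base_url)
  verified <- rep_len(verified, length(metas))

  keys <- vapply(metas, function(m) paste0(m$id, "@", m$version), character(1))
  if (anyDuplicated(keys))
    wfr_abort(paste("duplicate (id, version) pairs:",
                    paste(unique(keys[duplicated(keys)]), collapse = ", ")),
              "wfr_ref_error")

  documents <- list()
  metadata_text <- list()
  ids <- unique(vapply(metas, function(m) m$id, character(1)))
  tool_docs <- list()

  for (id in ids) {
    sel <- which(vapply(metas, function(m) m$id, character(1)) == id)
    group <- metas[sel]
    tool_url <- paste0(registry_base_url, "/tools/", id)
    version_docs <- lapply(seq_along(group), function(j) {
      trs_version_doc(group[[j]], registry_base_url, verified[sel[j]],
                      verified_source)
    })
    tool_doc <- list(
      id = id,
      url = tool_url,
      name = group[[1]]$name,
      organization = group[[1]]$authors[[1]]$account,
      toolclass = list(id = "workflow", name = "Workflow",
                       description = "A computational workflow"),
      versions = version_docs
    )
    tool_docs[[length(tool_docs) + 1L]] <- tool_doc
    documents[[paste0("/tools/", id)]] <- tool_doc
    documents[[paste0("/tools/", id, "/versions")]] <- version_docs
    for (j in seq_along(group)) {
      meta <- group[[j]]
      vpath <- paste0("/tools/", id, "/versions/", meta$version)
      documents[[vpath]] <- version_docs[[j]]
      documents[[paste0(vpath, "/files")]] <- trs_files_doc(meta, resolver)
      documents[[paste0(vpath, "/tests")]] <- trs_tests_doc(meta, resolver)
      metadata_text[[vpath]] <- serialize_metadata(meta, "json")
    }
  }
  documents <- c(list("/tools" = tool_docs), documents)
  structure(list(documents = documents, metadata_text = metadata_text),
            class = "trs_document_tree")
}

#' Write a TRS tree as a static registry directory
#'
#' Each endpoint path becomes `<out_dir>/<path>/index.json`, so a static
#' file server rooted at `out_dir` reproduces the TRS API for extensionless
#' paths. The source metadata document is co-published as `metadata.json`
#' beside each version document — a published version is exactly two
#' metadata documents: the TRS response and the metadata file. Output is
#' deterministic: writing the same tree twice is byte-identical.
#'
#' @param tree A [to_trs()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths (relative to `out_dir`).
#' @export
write_registry <- function(tree, out_dir) {
  stopifnot(inherits(tree, "trs_document_tree"))
  written <- character()
  for (path in names(tree$documents)) {
    dir <- file.path(out_dir, sub("^/", "", path))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    target <- file.path(dir, "index.json")
    writeLines(as.character(jsonlite::toJSON(
      tree$documents[[path]], auto_unbox = TRUE, pretty = TRUE, digits = NA,
      null = "null")), target, useBytes = TRUE)
    written <- c(written, file.path(sub("^/", "", path), "index.json"))
  }
  for (vpath in names(tree$metadata_text)) {
    dir <- file.path(out_dir, sub("^/", "", vpath))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    target <- file.path(dir, "metadata.json")
    writeLines(tree$metadata_text[[vpath]], target, useBytes = TRUE)
    written <- c(written, file.path(sub("^/", "", vpath), "metadata.json"))
  }
  invisible(written)
}

#' Read a document back from a static registry
#'
#' Convenience accessor mirroring what a TRS client would receive from a
#' static server: the JSON at `<registry_dir>/<path>/index.json`.
#'
#' @param registry_dir Directory written by [write_registry()].
#' @param path TRS endpoint path (beginning `/tools`).
#' @return Parsed JSON document.
#' @export
read_registry_document <- function(registry_dir, path) {
  f <- file.path(registry_dir, sub("^/", "", path), "index.json")
  if (!file.exists(f))
    wfr_abort(sprintf("no document at %s", path), "wfr_ref_error")
  jsonlite::fromJSON(paste(readLines(f, warn = FALSE), collapse = "\n"),
                     simplifyVector = FALSE)
}
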