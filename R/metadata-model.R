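# Workflow metadata model: the registry record for one workflow version.
# A metadata document names, by URL, a primary workflow descriptor, its
# dependent files, authors, an open-source license, documentation, and at
# least one WES-style test case. JSON and YAML dialects round-trip.

LANGUAGE_TYPES <- c("CWL", "WDL", "NFL", "SMK", "UNKNOWN")
FILE_ROLES <- c("primary", "secondary", "test", "other")
TEST_FILE_KINDS <- c("workflow_params", "engine_params", "data")

#' Bundled open-source license identifiers
#'
#' SPDX-style identifiers accepted by the open-source-license requirement.
#' Unknown identifiers are a validation failure, not a parse failure.
#'
#' @return Character vector of license identifiers.
#' @export
open_source_licenses <- function() {
  c("Apache-2.0", "MIT", "BSD-2-Clause", "BSD-3-Clause",
    "GPL-2.0-only", "GPL-2.0-or-later", "GPL-3.0-only", "GPL-3.0-or-later",
    "LGPL-2.1-only", "LGPL-2.1-or-later", "LGPL-3.0-only", "LGPL-3.0-or-later",
    "AGPL-3.0-only", "AGPL-3.0-or-later", "MPL-2.0", "EPL-1.0", "EPL-2.0",
    "CDDL-1.0", "Artistic-2.0", "Zlib", "Unlicense", "CC0-1.0", "CC-BY-4.0",
    "CC-BY-SA-4.0", "ISC", "BSL-1.0", "EUPL-1.2", "OFL-1.1", "NCSA",
    "PostgreSQL")
}

#' Construct an author record
#'
#' @param account Hosting-service account name (required, non-empty).
#' @param name Display name; may be empty in a draft.
#' @param affiliation Optional free-text affiliation.
#' @param orcid Optional ORCID (`dddd-dddd-dddd-dddX` pattern).
#' @return An object of class `wf_author`.
#' @export
wf_author <- function(account, name = "", affiliation = NULL, orcid = NULL) {
  structure(
    list(account = account, name = name, affiliation = affiliation,
         orcid = orcid),
    class = "wf_author"
  )
}

#' Construct a workflow-language record
#'
#' @param type One of `"CWL"`, `"WDL"`, `"NFL"`, `"SMK"`, `"UNKNOWN"`.
#' @param version Language version string, or `"UNKNOWN"`.
#' @return An object of class `wf_language`.
#' @export
wf_language <- function(type = "UNKNOWN", version = "UNKNOWN") {
  structure(list(type = type, version = version), class = "wf_language")
}

#' Construct a file entry
#'
#' @param url Source location of the file (http, https or file URL).
#' @param target Registry-relative destination path (POSIX style, no leading
#'   `/`, no `..`). Defaults to the URL's basename.
#' @param role One of `"primary"`, `"secondary"`, `"test"`, `"other"`.
#' @param kind For files inside a test case: `"workflow_params"`,
#'   `"engine_params"` or `"data"`; exactly one file per test case must be
#'   the workflow-parameters document.
#' @return An object of class `wf_file`.
#' @export
wf_file <- function(url, target = NULL, role = "other", kind = NULL) {
  target <- target %||% basename(url)
  structure(list(url = url, target = target, role = role, kind = kind),
            class = "wf_file")
}

#' Construct a test case
#'
#' A test case is a WES run request in waiting: a workflow-parameters
#' document, optional engine parameters, and input data files.
#'
#' @param test_id Identifier, unique within the metadata document.
#' @param files List of [wf_file()] with roles `test`/`other`; exactly one
#'   must have `kind = "workflow_params"`.
#' @return An object of class `wf_test_case`.
#' @export
wf_test_case <- function(test_id, files) {
  structure(list(test_id = test_id, files = files), class = "wf_test_case")
}

#' Construct a workflow metadata record
#'
#' The complete registry record for one workflow version. Schema invariants
#' (exactly one primary file, unique relative targets, UUID id, dotted
#' version, one workflow-parameters document per test case) are enforced
#' unless `validate = FALSE`.
#'
#' @param id Workflow identifier (version-4 UUID string; see
#'   [new_workflow_id()]).
#' @param version Metadata version label, dotted numerics (e.g. "1.0.0").
#' @param license SPDX-style license identifier, or `"UNKNOWN"` in a draft.
#' @param authors List of [wf_author()].
#' @param name Human-readable workflow name.
#' @param readme_url URL of the workflow's documentation.
#' @param language A [wf_language()].
#' @param files List of [wf_file()]; exactly one with role `"primary"`.
#' @param testing List of [wf_test_case()]; at least one.
#' @param doi Optional persistent identifier, absent until publication.
#' @param extra Named list of unknown top-level keys preserved for
#'   round-tripping.
#' @param validate Enforce schema invariants (default `TRUE`).
#' @return An object of class `workflow_metadata`.
#' @export
workflow_metadata <- function(id, version, license, authors, name, readme_url,
                              language, files, testing, doi = NULL,
                              extra = list(), validate = TRUE) {
  meta <- structure(
    list(id = id, version = version, license = license, authors = authors,
         name = name, readme_url = readme_url, language = language,
         files = files, testing = testing, doi = doi, extra = extra),
    class = "workflow_metadata"
  )
  if (validate) {
    issues <- metadata_schema_issues(meta)
    if (length(issues) > 0L) {
      wfr_abort(
        paste0("invalid workflow metadata:\n", paste0("- ", issues, collapse = "\n")),
        "wfr_schema_error", issues = issues
      )
    }
  }
  meta
}

#' List schema violations of a metadata record
#'
#' Returns every violated invariant as a message naming the offending field
#' path; an empty character vector means the record is schema-valid. With
#' `check_ids = FALSE` the well-formedness of `id` and `version` is left to
#' [validate_workflow()] instead (used when loading deliberately defective
#' fixtures).
#'
#' @param meta A `workflow_metadata` (possibly built with `validate = FALSE`).
#' @param check_ids Also require a UUID id and dotted-numeric version.
#' @return Character vector of violation messages.
#' @export
metadata_schema_issues <- function(meta, check_ids = TRUE) {
  issues <- character()
  add <- function(msg) issues[[length(issues) + 1L]] <<- msg

  if (check_ids && !is_uuid(meta$id))
    add("id: not a version-4 UUID")
  if (check_ids && !is_dotted_version(meta$version))
    add("version: not a dotted numeric version")
  if (!nonempty_string(meta$name)) add("name: empty")
  if (!nonempty_string(meta$license)) add("license: empty")
  if (!nonempty_string(meta$readme_url)) add("readme_url: empty")

  if (!inherits(meta$language, "wf_language") ||
      !(meta$language$type %in% LANGUAGE_TYPES))
    add("language.type: not one of CWL/WDL/NFL/SMK/UNKNOWN")

  if (!is.list(meta$authors)) add("authors: not a list")
  else for (i in seq_along(meta$authors)) {
    a <- meta$authors[[i]]
    if (!nonempty_string(a$account))
      add(sprintf("authors[%d].account: empty", i))
    if (!is.null(a$orcid) && !is_orcid(a$orcid))
      add(sprintf("authors[%d].orcid: malformed", i))
  }

  if (!is.list(meta$files) || length(meta$files) == 0L) {
    add("files: empty")
  } else {
    roles <- vapply(meta$files, function(f) f$role %||% "", character(1))
    if (sum(roles == "primary") != 1L)
      add("files: exactly one entry must have role=primary")
    if (!all(roles %in% FILE_ROLES))
      add("files.role: not one of primary/secondary/test/other")
    targets <- vapply(meta$files, function(f) f$target %||% "", character(1))
    norm <- vapply(targets, normalize_target, character(1))
    bad <- which(is.na(norm) | norm != targets)
    for (i in bad) add(sprintf("files[%d].target: not a normalized relative path", i))
    if (anyDuplicated(targets))
      add("files.target: duplicate target paths")
  }

  if (!is.list(meta$testing) || length(meta$testing) == 0L) {
    add("testing: at least one test case is required")
  } else {
    ids <- vapply(meta$testing, function(t) t$test_id %||% "", character(1))
    if (anyDuplicated(ids)) add("testing.test_id: duplicate test ids")
    for (i in seq_along(meta$testing)) {
      tc <- meta$testing[[i]]
      if (!nonempty_string(tc$test_id))
        add(sprintf("testing[%d].test_id: empty", i))
      if (!is.list(tc$files) || length(tc$files) == 0L) {
        add(sprintf("testing[%d].files: empty", i))
        next
      }
      troles <- vapply(tc$files, function(f) f$role %||% "", character(1))
      if (!all(troles %in% c("test", "other")))
        add(sprintf("testing[%d].files.role: test-case files must have role test/other", i))
      kinds <- vapply(tc$files, function(f) f$kind %||% "", character(1))
      if (sum(kinds == "workflow_params") != 1L)
        add(sprintf("testing[%d].files: exactly one file must have kind=workflow_params", i))
      if (!all(kinds %in% c(TEST_FILE_KINDS, "")))
        add(sprintf("testing[%d].files.kind: unknown kind", i))
    }
  }

  if (!is.null(meta$doi) && !nonempty_string(meta$doi))
    add("doi: present but empty")
  issues
}

# --- plain-list representation (serialization order = declaration order) -----

author_to_list <- function(a) {
  compact(list(account = a$account, name = a$name,
               affiliation = a$affiliation, orcid = a$orcid))
}

file_to_list <- function(f) {
  compact(list(url = f$url, target = f$target, role = f$role, kind = f$kind))
}

metadata_to_list <- function(meta) {
  body <- compact(list(
    id = meta$id,
    version = meta$version,
    license = meta$license,
    authors = lapply(meta$authors, author_to_list),
    name = meta$name,
    readme_url = meta$readme_url,
    language = list(type = meta$language$type, version = meta$language$version),
    files = lapply(meta$files, file_to_list),
    testing = lapply(meta$testing, function(tc) {
      list(test_id = tc$test_id, files = lapply(tc$files, file_to_list))
    }),
    doi = meta$doi
  ))
  c(body, meta$extra)
}

KNOWN_TOP_KEYS <- c("id", "version", "license", "authors", "name",
                    "readme_url", "language", "files", "testing", "doi")

list_to_metadata <- function(x, validate = TRUE, check_ids = TRUE) {
  req <- function(key) {
    if (is.null(x[[key]]))
      wfr_abort(sprintf("missing required field: %s", key), "wfr_schema_error")
    x[[key]]
  }
  as_file <- function(f, where) {
    if (is.null(f$url))
      wfr_abort(sprintf("missing required field: %s.url", where), "wfr_schema_error")
    wf_file(url = f$url, target = f$target, role = f$role %||% "other",
            kind = f$kind)
  }
  meta <- structure(
    list(
      id = req("id"),
      version = req("version"),
      license = req("license"),
      authors = lapply(req("authors"), function(a) {
        wf_author(account = a$account %||% "", name = a$name %||% "",
                  affiliation = a$affiliation, orcid = a$orcid)
      }),
      name = req("name"),
      readme_url = req("readme_url"),
      language = {
        lang <- req("language")
        wf_language(type = lang$type %||% "UNKNOWN",
                    version = lang$version %||% "UNKNOWN")
      },
      files = {
        fl <- req("files")
        lapply(seq_along(fl), function(i) as_file(fl[[i]], sprintf("files[%d]", i)))
      },
      testing = lapply(req("testing"), function(tc) {
        wf_test_case(
          test_id = tc$test_id %||% "",
          files = lapply(seq_along(tc$files %||% list()), function(i) {
            as_file(tc$files[[i]], sprintf("testing.files[%d]", i))
          })
        )
      }),
      doi = x$doi,
      extra = {
        extra <- x[setdiff(names(x), KNOWN_TOP_KEYS)]
        if (length(extra) == 0L) list() else extra
      }
    ),
    class = "workflow_metadata"
  )
  if (validate) {
    issues <- metadata_schema_issues(meta, check_ids = check_ids)
    if (length(issues) > 0L) {
      wfr_abort(
        paste0("invalid workflow metadata:\n", paste0("- ", issues, collapse = "\n")),
        "wfr_schema_error", issues = issues
      )
    }
  }
  meta
}

#' Parse a workflow metadata document
#'
#' Reads a JSON or YAML metadata document into a [workflow_metadata()]
#' object. `dialect = "auto"` tries JSON first, then YAML. Unknown top-level
#' keys are preserved and re-emitted by [serialize_metadata()].
#'
#' @param text Document text (UTF-8), or a length-one path handled by
#'   [read_metadata()].
#' @param dialect `"json"`, `"yaml"` or `"auto"`.
#' @param strict When `TRUE` (default) any schema violation is an error;
#'   when `FALSE`, malformed `id`/`version` values are tolerated so the
#'   validator can report them as requirement failures.
#' @return A `workflow_metadata` object.
#' @export
parse_metadata <- function(text, dialect = c("auto", "json", "yaml"),
                           strict = TRUE) {
  dialect <- match.arg(dialect)
  parse_json <- function() jsonlite::fromJSON(text, simplifyVector = FALSE)
  parse_yaml <- function() yaml::yaml.load(text)
  x <- switch(dialect,
    json = tryCatch(parse_json(), error = function(e)
      wfr_abort(paste0("JSON parse error: ", conditionMessage(e)), "wfr_parse_error")),
    yaml = tryCatch(parse_yaml(), error = function(e)
      wfr_abort(paste0("YAML parse error: ", conditionMessage(e)), "wfr_parse_error")),
    auto = tryCatch(parse_json(), error = function(e) {
      tryCatch(parse_yaml(), error = function(e2)
        wfr_abort("document is neither valid JSON nor valid YAML", "wfr_parse_error"))
    })
  )
  if (!is.list(x) || is.null(names(x)))
    wfr_abort("document is not a mapping", "wfr_parse_error")
  list_to_metadata(x, validate = TRUE, check_ids = strict)
}

#' Serialize a workflow metadata record
#'
#' Deterministic serialization: fields appear in declaration order, `doi` is
#' omitted when absent, and serializing the same record twice is
#' byte-identical. `parse_metadata(serialize_metadata(m))` returns `m`.
#'
#' @param meta A `workflow_metadata`.
#' @param dialect `"json"` or `"yaml"`.
#' @return A single string of document text.
#' @export
serialize_metadata <- function(meta, dialect = c("json", "yaml")) {
  dialect <- match.arg(dialect)
  x <- metadata_to_list(meta)
  if (dialect == "json") {
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA))
  } else {
    yaml::as.yaml(x, indent.mapping.sequence = TRUE)
  }
}

#' Read a metadata file, auto-detecting its dialect
#'
#' Dialect is chosen by extension (`.json` vs `.yml`/`.yaml`), falling back
#' to content sniffing for other extensions.
#'
#' @inheritParams parse_metadata
#' @param path Path to a metadata file.
#' @return A `workflow_metadata` object.
#' @export
read_metadata <- function(path, strict = TRUE) {
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  ext <- tolower(tools::file_ext(path))
  dialect <- switch(ext, json = "json", yml = , yaml = "yaml", "auto")
  parse_metadata(text, dialect = dialect, strict = strict)
}

#' Write a metadata file
#'
#' @inheritParams serialize_metadata
#' @param path Destination path; extension picks the dialect unless given.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path, dialect = NULL) {
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "json") "json" else "yaml"
  }
  writeLines(serialize_metadata(meta, dialect), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.workflow_metadata <- function(x, ...) {
  cat(sprintf("<workflow_metadata> %s (version %s)\n", x$name, x$version))
  cat(sprintf("  id:       %s\n", x$id))
  cat(sprintf("  language: %s %s\n", x$language$type, x$language$version))
  cat(sprintf("  license:  %s\n", x$license))
  cat(sprintf("  authors:  %s\n",
              paste(vapply(x$authors, function(a) a$account, character(1)),
                    collapse = ", ")))
  cat(sprintf("  files:    %d (%s primary)\n", length(x$files),
              sum(vapply(x$files, function(f) f$role, character(1)) == "primary")))
  cat(sprintf("  tests:    %d\n", length(x$testing)))
  if (!is.null(x$doi)) cat(sprintf("  doi:      %s\n", x$doi))
  invisible(x)
}

primary_file <- function(meta) {
  roles <- vapply(meta$files, function(f) f$role, character(1))
  meta$files[[which(roles == "primary")[1]]]
}

params_file <- function(test_case) {
  kinds <- vapply(test_case$files, function(f) f$kind %||% "", character(1))
  test_case$files[[which(kinds == "workflow_params")[1]]]
}
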