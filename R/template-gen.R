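# Template generation: a pre-filled metadata draft from the URL of a
# primary workflow descriptor. The draft is always schema-valid but is
# expected to *fail* validation until the submitter edits it (fills in
# author names, real test inputs): drafting and validating are two steps.

#' Generate a metadata template from a primary descriptor URL
#'
#' Builds a draft [workflow_metadata()]: a fresh workflow id, version
#' `"1.0.0"`, the language detected from the descriptor, one file entry per
#' dependency the descriptor declares (entries that fail to resolve are kept,
#' with a warning, so the submitter sees the breakage), license and author
#' account pre-filled from repository facts, `readme_url` pointing at a
#' README found in the repository listing, and one stub test case for the
#' submitter to complete.
#'
#' @param primary_url URL of the main workflow descriptor (entry point).
#' @param resolver Resolver used to fetch the descriptor and dependencies.
#' @param inspector Repository inspection function (defaults to
#'   [inspect_repository()]); injectable for testing.
#' @param seed Optional seed for reproducible id generation.
#' @return A schema-valid draft `workflow_metadata`.
#' @export
make_template <- function(primary_url, resolver = local_resolver(),
                          inspector = inspect_repository, seed = NULL) {
  ref <- as_resource_ref(primary_url)
  res <- resolve(resolver, ref)
  if (!res$exists)
    wfr_abort(sprintf("primary descriptor not found: %s", ref$url),
              "wfr_ref_error")
  content <- rawToChar(res$content)
  language <- detect_language(content, basename(ref$url))
  if (language$type == "UNKNOWN")
    warning("workflow language could not be detected; template fields set to UNKNOWN")

  base_url <- dirname(ref$url)
  facts <- tryCatch(inspector(base_url), error = function(e) NULL)

  files <- list(wf_file(url = ref$url, target = basename(ref$url),
                        role = "primary"))
  if (language$type != "UNKNOWN") {
    deps <- enumerate_dependencies(content, language)
    for (i in seq_len(nrow(deps))) {
      dep_url <- if (deps$remote[i]) deps$path[i] else paste0(base_url, "/", deps$path[i])
      dep_target <- if (deps$remote[i]) basename(deps$path[i]) else deps$path[i]
      if (!resource_exists(resolver, dep_url))
        warning(sprintf("dependency does not resolve: %s", dep_url))
      files[[length(files) + 1L]] <-
        wf_file(url = dep_url, target = dep_target, role = "secondary")
    }
  }

  readme_url <- paste0(base_url, "/README.md")
  if (!is.null(facts)) {
    hit <- grep("^README", facts$file_listing, value = TRUE)
    if (length(hit) > 0) readme_url <- paste0(base_url, "/", hit[[1]])
  }

  workflow_metadata(
    id = new_workflow_id(seed),
    version = "1.0.0",
    license = if (!is.null(facts)) facts$license else "UNKNOWN",
    authors = list(wf_author(
      account = if (!is.null(facts)) facts$owner else "UNKNOWN",
      name = ""
    )),
    name = sub("\\.[^.]*$", "", basename(ref$url)),
    readme_url = readme_url,
    language = language,
    files = files,
    testing = list(wf_test_case(
      test_id = "test_1",
      files = list(wf_file(
        url = paste0(base_url, "/tests/params.json"),
        target = "tests/params.json", role = "test", kind = "workflow_params"
      ))
    ))
  )
}
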