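# Workflow-language detection, shallow syntax validation, and dependency
# enumeration for CWL, WDL, Nextflow (NFL) and Snakemake (SMK) descriptors.
# Validation is deliberately structural: deep semantics belong to each
# language's own tooling; these checks catch the defect classes a registry
# must reject (missing keys, unbalanced blocks, broken includes).

#' Detect the workflow language of a descriptor
#'
#' Detection rules, in priority order: a top-level `cwlVersion` key means
#' CWL (version taken from its value); a leading `version X` statement plus
#' a `workflow` block means WDL; a `process`/`workflow` block with Nextflow
#' idioms (channel operators, `nextflow.enable.dsl`) means NFL (version
#' from the DSL assignment when stated); `rule <name>:` blocks or the
#' filename `Snakefile` mean SMK. Anything else is UNKNOWN — detection
#' never errors.
#'
#' @param content Descriptor text.
#' @param filename Original filename, used as a hint (e.g. `Snakefile`).
#' @return A [wf_language()].
#' @export
detect_language <- function(content, filename = "") {
  lines <- strsplit(content %||% "", "\n")[[1]]

  m <- regmatches(lines, regexpr("^cwlVersion:\\s*[\"']?([^\"'#]+)", lines))
  if (length(m[lengths(m) > 0]) > 0) {
    val <- sub("^cwlVersion:\\s*[\"']?", "", m[lengths(m) > 0][[1]])
    return(wf_language("CWL", trimws(val)))
  }

  vstmt <- grep("^\\s*version\\s+[0-9A-Za-z._-]+\\s*$", lines, value = TRUE)
  if (length(vstmt) > 0 && any(grepl("^\\s*workflow\\s+\\w+\\s*\\{", lines))) {
    return(wf_language("WDL", sub("^\\s*version\\s+", "", trimws(vstmt[[1]]))))
  }

  has_block <- any(grepl("^\\s*(process|workflow)\\s+\\w*\\s*\\{", lines)) ||
    any(grepl("^\\s*workflow\\s*\\{", lines))
  nf_idiom <- any(grepl("nextflow\\.enable\\.dsl", lines)) ||
    any(grepl("Channel\\.", lines, fixed = FALSE)) ||
    any(grepl("\\.out\\b|\\|>", lines))
  if (has_block && nf_idiom) {
    dsl <- grep("nextflow\\.enable\\.dsl", lines, value = TRUE)
    version <- if (length(dsl) > 0) {
      sub(".*nextflow\\.enable\\.dsl\\s*=\\s*", "", dsl[[1]])
    } else "UNKNOWN"
    return(wf_language("NFL", trimws(version)))
  }

  if (any(grepl("^rule\\s+\\w+\\s*:", lines)) || basename(filename) == "Snakefile") {
    return(wf_language("SMK", "UNKNOWN"))
  }

  wf_language("UNKNOWN", "UNKNOWN")
}

syntax_issue <- function(severity, message, location = NA_integer_) {
  structure(list(severity = severity, message = message, location = location),
            class = "syntax_issue")
}

# Blank out string-literal contents so brace counting ignores them.
strip_string_literals <- function(text) {
  gsub('"[^"\n]*"', '""', gsub("'[^'\n]*'", "''", text))
}

count_brace_balance <- function(text) {
  bare <- strip_string_literals(text)
  chars <- strsplit(bare, "")[[1]]
  sum(chars == "{") - sum(chars == "}")
}

#' Shallow syntax validation of a workflow descriptor
#'
#' Structural checks per language. CWL: the document must parse as YAML
#' with `cwlVersion` and `class` keys, `class` one of
#' Workflow/CommandLineTool/ExpressionTool. WDL: a `version` statement must
#' be present and braces balanced. NFL: braces balanced and at least one
#' `process`/`workflow` block. SMK: at least one `rule` block with
#' consistently indented bodies. An empty issue list means the descriptor
#' passed.
#'
#' @param content Descriptor text.
#' @param language A [wf_language()] with known `type`.
#' @return List of syntax issues (each with `severity`, `message`,
#'   `location`); empty when valid.
#' @export
check_syntax <- function(content, language) {
  if (!inherits(language, "wf_language") || language$type == "UNKNOWN")
    wfr_abort("check_syntax requires a known language type", "wfr_ref_error")
  issues <- list()
  add <- function(msg, loc = NA_integer_, severity = "error") {
    issues[[length(issues) + 1L]] <<- syntax_issue(severity, msg, loc)
  }
  lines <- strsplit(content, "\n")[[1]]

  if (language$type == "CWL") {
    doc <- tryCatch(yaml::yaml.load(content), error = function(e) e)
    if (inherits(doc, "error")) {
      add(paste0("document does not parse as YAML: ", conditionMessage(doc)))
      return(issues)
    }
    if (!is.list(doc)) {
      add("document is not a YAML mapping")
      return(issues)
    }
    if (is.null(doc$cwlVersion)) add("missing key: cwlVersion")
    if (is.null(doc$class)) add("missing key: class")
    else if (!(doc$class %in% c("Workflow", "CommandLineTool", "ExpressionTool")))
      add(sprintf("class must be Workflow/CommandLineTool/ExpressionTool, got %s",
                  doc$class))
  } else if (language$type == "WDL") {
    if (!any(grepl("^\\s*version\\s+\\S+", lines)))
      add("missing version statement")
    bal <- count_brace_balance(content)
    if (bal != 0)
      add(sprintf("unbalanced braces (%+d)", bal))
  } else if (language$type == "NFL") {
    bal <- count_brace_balance(content)
    if (bal != 0)
      add(sprintf("unbalanced braces (%+d)", bal))
    if (!any(grepl("^\\s*(process|workflow)\\b", lines)))
      add("no process or workflow block")
  } else if (language$type == "SMK") {
    rule_lines <- grep("^rule\\s+\\w+\\s*:", lines)
    if (length(rule_lines) == 0) {
      add("no rule block")
    } else {
      for (rl in rule_lines) {
        body <- lines[seq_len(length(lines)) > rl]
        body <- body[cumsum(!grepl("^(\\s|$)", body)) == 0]
        body <- body[nzchar(trimws(body))]
        if (length(body) == 0) {
          add(sprintf("empty rule body after line %d", rl), rl)
        } else {
          indents <- nchar(sub("\\S.*$", "", body))
          directives <- grepl("^\\s+\\w+\\s*:", body)
          if (length(unique(indents[directives])) > 1)
            add(sprintf("inconsistent indentation in rule starting line %d", rl), rl)
        }
      }
    }
  }
  issues
}

# Recursively collect values of `run`, `$import` and `$include` keys from a
# parsed CWL document.
cwl_collect_refs <- function(node) {
  refs <- character()
  if (is.list(node)) {
    nm <- names(node)
    for (i in seq_along(node)) {
      key <- if (!is.null(nm)) nm[[i]] else ""
      val <- node[[i]]
      if (key %in% c("run", "$import", "$include") && is.character(val) &&
          length(val) == 1L) {
        refs <- c(refs, val)
      } else {
        refs <- c(refs, cwl_collect_refs(val))
      }
    }
  }
  refs
}

#' Enumerate descriptor dependencies
#'
#' Collects the files a descriptor refers to: CWL `run` targets and
#' `$import`/`$include` values; WDL `import` statements; Nextflow `include
#' ... from` paths; Snakemake `include:` directives. Output is deduplicated
#' with declaration order preserved. Absolute-URL targets are reported too,
#' flagged `remote`, so the validator can availability-check them.
#'
#' @param content Descriptor text.
#' @param language A [wf_language()] with known `type`.
#' @return Data frame with columns `path` (as written, `./` prefixes
#'   dropped) and `remote` (logical).
#' @export
enumerate_dependencies <- function(content, language) {
  if (!inherits(language, "wf_language") || language$type == "UNKNOWN")
    wfr_abort("enumerate_dependencies requires a known language type", "wfr_ref_error")
  lines <- strsplit(content, "\n")[[1]]
  refs <- switch(language$type,
    CWL = {
      doc <- tryCatch(yaml::yaml.load(content), error = function(e) NULL)
      if (is.null(doc)) character() else cwl_collect_refs(doc)
    },
    WDL = {
      m <- regmatches(lines, regexpr('^\\s*import\\s+"([^"]+)"', lines))
      vapply(m[lengths(m) > 0], function(x) sub('^\\s*import\\s+"', "", sub('"$', "", x)),
             character(1), USE.NAMES = FALSE)
    },
    NFL = {
      hits <- regmatches(lines,
        regexpr("^\\s*include\\s*\\{[^}]*\\}\\s*from\\s*['\"][^'\"]+['\"]", lines))
      vapply(hits[lengths(hits) > 0], function(x) {
        sub(".*from\\s*['\"]", "", sub("['\"]\\s*$", "", x))
      }, character(1), USE.NAMES = FALSE)
    },
    SMK = {
      m <- regmatches(lines, regexpr('^include:\\s*"([^"]+)"', lines))
      vapply(m[lengths(m) > 0], function(x) sub('^include:\\s*"', "", sub('"$', "", x)),
             character(1), USE.NAMES = FALSE)
    },
    character()
  )
  refs <- unlist(refs, use.names = FALSE) %||% character()
  # fragment-only and inline references are not files
  refs <- refs[nzchar(refs) & !startsWith(refs, "#")]
  remote <- grepl("^[A-Za-z][A-Za-z0-9+.-]*://", refs)
  # Nextflow modules may omit the extension; keep paths as written but strip ./
  refs[!remote] <- sub("^\\./", "", refs[!remote])
  keep <- !duplicated(refs)
  data.frame(path = refs[keep], remote = remote[keep],
             stringsAsFactors = FALSE)
}
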