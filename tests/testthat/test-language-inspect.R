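# Language detection, shallow syntax checks, dependency enumeration.

test_that("detection follows the priority rules for each language", {
  cases <- list(
    list(content = "cwlVersion: v1.0\nclass: Workflow\n", file = "wf.cwl",
         type = "CWL", version = "v1.0"),
    list(content = "cwlVersion: v1.2\nclass: CommandLineTool\n", file = "t.cwl",
         type = "CWL", version = "v1.2"),
    list(content = "version 1.0\n\nworkflow w {\n}\n", file = "main.wdl",
         type = "WDL", version = "1.0"),
    list(content = "nextflow.enable.dsl = 2\nworkflow {\n  Channel.of(1)\n}\n",
         file = "main.nf", type = "NFL", version = "2"),
    list(content = "process P {\n  script:\n  \"echo\"\n}\nChannel.of(1)\n",
         file = "mod.nf", type = "NFL", version = "UNKNOWN"),
    list(content = "rule all:\n    input:\n        \"x\"\n", file = "Snakefile",
         type = "SMK", version = "UNKNOWN"),
    list(content = "just some text", file = "notes.txt",
         type = "UNKNOWN", version = "UNKNOWN"),
    list(content = "", file = "", type = "UNKNOWN", version = "UNKNOWN")
  )
  for (case in cases) {
    lang <- detect_language(case$content, case$file)
    expect_identical(lang$type, case$type, label = case$file)
    expect_identical(lang$version, case$version, label = case$file)
  }
})

test_that("a Snakefile with no rule blocks is detected by filename", {
  lang <- detect_language('include: "rules/a.smk"', "Snakefile")
  expect_identical(lang$type, "SMK")
})

test_that("detection is deterministic and pure", {
  content <- "cwlVersion: v1.0\nclass: Workflow\n"
  expect_identical(detect_language(content, "a.cwl"),
                   detect_language(content, "a.cwl"))
})

test_that("fixture descriptors in every language detect as generated", {
  for (lang in c("CWL", "WDL", "NFL", "SMK")) {
    repo <- generate_repo(lang, seed = 4)
    primary <- list.files(repo$root, recursive = TRUE)
    primary <- primary[primary %in% c("main.cwl", "main.wdl", "main.nf", "Snakefile")]
    content <- paste(readLines(file.path(repo$root, primary), warn = FALSE),
                     collapse = "\n")
    expect_identical(detect_language(content, primary)$type, lang)
  }
})

test_that("CWL syntax checks require YAML, cwlVersion and a known class", {
  ok <- "cwlVersion: v1.0\nclass: Workflow\nsteps: []\n"
  expect_length(check_syntax(ok, wf_language("CWL", "v1.0")), 0)
  missing_class <- check_syntax("cwlVersion: v1.0\n", wf_language("CWL"))
  expect_length(missing_class, 1)
  expect_match(missing_class[[1]]$message, "missing key: class")
  bad_class <- check_syntax("cwlVersion: v1.0\nclass: Pipeline\n", wf_language("CWL"))
  expect_match(bad_class[[1]]$message, "class must be")
  not_yaml <- check_syntax("a: [unclosed", wf_language("CWL"))
  expect_match(not_yaml[[1]]$message, "does not parse as YAML")
})

test_that("WDL brace imbalance is counted outside string literals", {
  wdl <- 'version 1.0\nworkflow w {\n  call t { input: x = "}" }\n'
  issues <- check_syntax(wdl, wf_language("WDL", "1.0"))
  expect_length(issues, 1)
  expect_match(issues[[1]]$message, "unbalanced braces \\(\\+1\\)")
  balanced <- paste0(wdl, "}\n")
  expect_length(check_syntax(balanced, wf_language("WDL", "1.0")), 0)
  no_version <- "workflow w {\n}\n"
  expect_match(check_syntax(no_version, wf_language("WDL"))[[1]]$message,
               "missing version")
})

test_that("NFL and SMK structural checks flag their defect classes", {
  expect_length(check_syntax("workflow {\n  x\n}\n", wf_language("NFL", "2")), 0)
  expect_match(check_syntax("x = 1\n", wf_language("NFL"))[[1]]$message,
               "no process or workflow block")
  smk_ok <- "rule a:\n    input:\n        \"x\"\n    output:\n        \"y\"\n"
  expect_length(check_syntax(smk_ok, wf_language("SMK")), 0)
  smk_bad <- "rule a:\n    input:\n        \"x\"\n      output:\n        \"y\"\n"
  expect_match(check_syntax(smk_bad, wf_language("SMK"))[[1]]$message,
               "inconsistent indentation")
  expect_match(check_syntax("x = 1\n", wf_language("SMK"))[[1]]$message,
               "no rule block")
})

test_that("check_syntax refuses an UNKNOWN language", {
  expect_error(check_syntax("x", wf_language("UNKNOWN")), class = "wfr_ref_error")
})

test_that("CWL dependencies come from run and $import keys, deduplicated in order", {
  cwl <- paste(
    "cwlVersion: v1.0", "class: Workflow", "steps:",
    "  a:", "    run: tools/a.cwl", "  b:", "    run: tools/b.cwl",
    "  c:", "    run: tools/a.cwl",
    "requirements:", "  SchemaDefRequirement:", "    types:",
    "      - $import: types/record.yml", sep = "\n")
  deps <- enumerate_dependencies(cwl, wf_language("CWL", "v1.0"))
  expect_identical(deps$path, c("tools/a.cwl", "tools/b.cwl", "types/record.yml"))
  expect_identical(deps$remote, rep(FALSE, 3))
})

test_that("remote dependency targets are flagged remote", {
  cwl <- "cwlVersion: v1.0\nclass: Workflow\nsteps:\n  a:\n    run: https://example.org/t.cwl\n"
  deps <- enumerate_dependencies(cwl, wf_language("CWL", "v1.0"))
  expect_identical(deps$path, "https://example.org/t.cwl")
  expect_true(deps$remote)
})

test_that("WDL/NFL/SMK dependency statements are enumerated", {
  wdl <- 'version 1.0\nimport "tasks/align.wdl" as a\nimport "tasks/call.wdl"\nworkflow w {\n}\n'
  expect_identical(enumerate_dependencies(wdl, wf_language("WDL"))$path,
                   c("tasks/align.wdl", "tasks/call.wdl"))
  nf <- "include { A } from './modules/a.nf'\ninclude { B; C } from \"./modules/b.nf\"\n"
  expect_identical(enumerate_dependencies(nf, wf_language("NFL"))$path,
                   c("modules/a.nf", "modules/b.nf"))
  smk <- 'include: "rules/a.smk"\ninclude: "rules/b.smk"\nrule all:\n    input: []\n'
  expect_identical(enumerate_dependencies(smk, wf_language("SMK"))$path,
                   c("rules/a.smk", "rules/b.smk"))
})

test_that("a descriptor with no references yields an empty enumeration", {
  deps <- enumerate_dependencies("cwlVersion: v1.0\nclass: CommandLineTool\n",
                                 wf_language("CWL"))
  expect_identical(nrow(deps), 0L)
})

test_that("enumerated dependencies never invent paths absent from the text", {
  for (lang in c("CWL", "WDL", "NFL", "SMK")) {
    repo <- generate_repo(lang, seed = 8)
    primary_rel <- switch(lang, CWL = "main.cwl", WDL = "main.wdl",
                          NFL = "main.nf", SMK = "Snakefile")
    content <- paste(readLines(file.path(repo$root, primary_rel), warn = FALSE),
                     collapse = "\n")
    deps <- enumerate_dependencies(content, wf_language(lang, "x"))
    expect_gt(nrow(deps), 0)
    for (p in deps$path) expect_true(grepl(p, content, fixed = TRUE), label = p)
  }
})
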