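# Synthetic workflow repositories with injectable defects. The CWL shape
# mimics a small bacterial genome assembly: a primary workflow chaining
# four command-line tool steps (seqkit, fastqc, fastp, platanus_b); the
# other languages use equivalent two-module shapes. With no defects a
# repository's metadata passes all eleven requirements and its tests pass
# against a stub WES scripted COMPLETE; each defect code applies the
# minimal mutation that violates exactly one requirement.

FIXTURE_DEFECTS <- c(
  "missing-primary",          # main workflow description unavailable
  "missing-dependency",       # a dependent tool file unavailable
  "missing-test-file",        # a testing material unavailable
  "invalid-license",          # license not an open-source identifier
  "language-type-unknown",    # language type not stated
  "language-version-unknown", # language version not stated
  "syntax-error",             # primary descriptor structurally broken
  "no-authors",               # authors list emptied
  "missing-readme",           # documentation unavailable
  "bad-id",                   # workflow id not a UUID
  "bad-version",              # metadata version not dotted numerics
  "wes-executor-error",       # scripted test failure at the WES
  "wes-timeout"               # scripted run that never terminates
)

#' Defect codes recognized by the fixture generator
#'
#' One code per reusability requirement, plus WES-failure codes that leave
#' the repository intact but script the stub endpoint.
#'
#' @return Character vector of defect codes.
#' @export
fixture_defect_codes <- function() FIXTURE_DEFECTS

#' Requirement flagged by each repository defect code
#'
#' @return Named character vector: defect code -> requirement id (WES codes
#'   excluded; they surface in testing, not validation).
#' @export
defect_requirement_map <- function() {
  c(`missing-primary` = "main_workflow_description",
    `missing-dependency` = "dependent_materials",
    `missing-test-file` = "testing_materials",
    `invalid-license` = "open_source_license",
    `language-type-unknown` = "language_type",
    `language-version-unknown` = "language_version",
    `syntax-error` = "language_syntax",
    `no-authors` = "authors_maintainers",
    `missing-readme` = "documentation",
    `bad-id` = "workflow_id",
    `bad-version` = "metadata_version")
}

fixture_sources <- function(language) {
  switch(language,
    CWL = list(
      primary = "main.cwl",
      version = "v1.0",
      files = list(
        "main.cwl" = c(
          "cwlVersion: v1.0",
          "class: Workflow",
          "label: Bacterial genome assembly",
          "inputs:",
          "  raw_reads:",
          "    type: File",
          "outputs:",
          "  assembly:",
          "    type: File",
          "    outputSource: assemble/assembly",
          "steps:",
          "  stats:",
          "    run: tools/seqkit.cwl",
          "    in:",
          "      reads: raw_reads",
          "    out: [stats_tsv]",
          "  qc:",
          "    run: tools/fastqc.cwl",
          "    in:",
          "      reads: raw_reads",
          "    out: [report]",
          "  trim:",
          "    run: tools/fastp.cwl",
          "    in:",
          "      reads: raw_reads",
          "    out: [trimmed]",
          "  assemble:",
          "    run: tools/platanus_b.cwl",
          "    in:",
          "      reads: trim/trimmed",
          "    out: [assembly]"),
        "tools/seqkit.cwl" = cwl_tool("seqkit stats", "stats_tsv", "stats.tsv"),
        "tools/fastqc.cwl" = cwl_tool("fastqc", "report", "fastqc_report.html"),
        "tools/fastp.cwl" = cwl_tool("fastp", "trimmed", "trimmed.fq"),
        "tools/platanus_b.cwl" = cwl_tool("platanus_b assemble", "assembly",
                                          "assembly.fa")
      )
    ),
    WDL = list(
      primary = "main.wdl",
      version = "1.0",
      files = list(
        "main.wdl" = c(
          "version 1.0",
          "",
          'import "tools/trim.wdl" as trim_mod',
          'import "tools/assemble.wdl" as assemble_mod',
          "",
          "workflow genome_assembly {",
          "  input {",
          "    File raw_reads",
          "  }",
          "  call trim_mod.run_trim { input: reads = raw_reads }",
          "  call assemble_mod.run_assemble { input: reads = run_trim.trimmed }",
          "  output {",
          "    File assembly = run_assemble.assembly",
          "  }",
          "}"),
        "tools/trim.wdl" = wdl_task("run_trim", "fastp", "trimmed.fq", "trimmed"),
        "tools/assemble.wdl" = wdl_task("run_assemble", "platanus_b",
                                        "assembly.fa", "assembly")
      )
    ),
    NFL = list(
      primary = "main.nf",
      version = "2",
      files = list(
        "main.nf" = c(
          "nextflow.enable.dsl = 2",
          "",
          "include { TRIM } from './modules/trim.nf'",
          "include { ASSEMBLE } from './modules/assemble.nf'",
          "",
          "workflow {",
          "    reads = Channel.fromPath(params.raw_reads)",
          "    TRIM(reads)",
          "    ASSEMBLE(TRIM.out)",
          "}"),
        "modules/trim.nf" = nf_process("TRIM", "fastp", "trimmed.fq"),
        "modules/assemble.nf" = nf_process("ASSEMBLE", "platanus_b", "assembly.fa")
      )
    ),
    SMK = list(
      primary = "Snakefile",
      version = "7.32.4",
      files = list(
        "Snakefile" = c(
          'include: "rules/trim.smk"',
          'include: "rules/assemble.smk"',
          "",
          "rule all:",
          "    input:",
          '        "results/assembly.fa"'),
        "rules/trim.smk" = smk_rule("trim", "tests/data/reads.fq",
                                    "results/trimmed.fq", "fastp"),
        "rules/assemble.smk" = smk_rule("assemble", "results/trimmed.fq",
                                        "results/assembly.fa", "platanus_b")
      )
    ),
    wfr_abort(sprintf("unsupported fixture language: %s", language),
              "wfr_ref_error")
  )
}

cwl_tool <- function(cmd, out_id, out_name) {
  c("cwlVersion: v1.0",
    "class: CommandLineTool",
    sprintf("baseCommand: [%s]", gsub(" ", ", ", cmd)),
    "inputs:",
    "  reads:",
    "    type: File",
    "    inputBinding:",
    "      position: 1",
    "outputs:",
    sprintf("  %s:", out_id),
    "    type: stdout",
    sprintf("stdout: %s", out_name))
}

wdl_task <- function(name, tool, out_file, out_id) {
  c("version 1.0",
    "",
    sprintf("task %s {", name),
    "  input {",
    "    File reads",
    "  }",
    "  command <<<",
    sprintf("    %s ~{reads} > %s", tool, out_file),
    "  >>>",
    "  output {",
    sprintf("    File %s = \"%s\"", out_id, out_file),
    "  }",
    "}")
}

nf_process <- function(name, tool, out_file) {
  c(sprintf("process %s {", name),
    "    input:",
    "    path reads",
    "",
    "    output:",
    sprintf("    path '%s'", out_file),
    "",
    "    script:",
    sprintf("    \"%s $reads > %s\"", tool, out_file),
    "}")
}

smk_rule <- function(name, input, output, tool) {
  c(sprintf("rule %s:", name),
    "    input:",
    sprintf('        "%s"', input),
    "    output:",
    sprintf('        "%s"', output),
    "    shell:",
    sprintf('        "%s {input} > {output}"', tool))
}

apache2_license_text <- function() {
  c("                              Apache License",
    "                        Version 2.0, January 2004",
    "                     http://www.apache.org/licenses/",
    "",
    "Licensed under the Apache License, Version 2.0 (the \"License\");",
    "you may not use this file except in compliance with the License.")
}

#' Generate a synthetic workflow repository
#'
#' Writes a complete repository — primary descriptor, dependent tool
#' descriptors, README, Apache-2.0 LICENSE, a workflow-parameters file, a
#' tiny FASTQ input — plus a metadata document referencing everything by
#' `file://` URL, then applies each requested defect as its minimal
#' mutation. Deterministic: the same seed yields byte-identical trees.
#'
#' @param language `"CWL"`, `"WDL"`, `"NFL"` or `"SMK"`.
#' @param defects Character vector of [fixture_defect_codes()].
#' @param seed Integer seed controlling the workflow id.
#' @param dir Repository directory (created; defaults to a fresh temporary
#'   directory).
#' @return An object of class `fixture_repo` with `$root`, `$language`,
#'   `$defects`, `$metadata_path`, `$metadata` (parsed leniently).
#' @export
generate_repo <- function(language = c("CWL", "WDL", "NFL", "SMK"),
                          defects = character(), seed = 1,
                          dir = tempfile("fixrepo-")) {
  language <- match.arg(language)
  unknown <- setdiff(defects, FIXTURE_DEFECTS)
  if (length(unknown) > 0)
    wfr_abort(paste("unknown defect code(s):", paste(unknown, collapse = ", ")),
              "wfr_ref_error")
  src <- fixture_sources(language)
  dir.create(file.path(dir, "bacteria-genome"), recursive = TRUE,
             showWarnings = FALSE)
  root <- file.path(dir, "bacteria-genome")

  write_tree <- function(rel, lines) {
    path <- file.path(root, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writeLines(lines, path, useBytes = TRUE)
  }
  for (rel in names(src$files)) write_tree(rel, src$files[[rel]])
  write_tree("README.md", c(
    "# Bacterial genome assembly",
    "",
    "A small genome assembly workflow: read statistics and quality control,",
    "adapter trimming, then assembly.",
    "",
    sprintf("Written in %s. See tests/ for a runnable example.", language)))
  write_tree("LICENSE", apache2_license_text())
  write_tree("tests/params.json", c(
    "{",
    '  "raw_reads": "tests/data/reads.fq"',
    "}"))
  write_tree("tests/data/reads.fq", c(
    "@read1",
    "ACGTACGTACGTACGTACGT",
    "+",
    "IIIIIIIIIIIIIIIIIIII",
    "@read2",
    "TTGGCCAATTGGCCAATTGG",
    "+",
    "IIIIIIIIIIIIIIIIIIII"))

  furl <- function(rel) path_to_file_url(file.path(root, rel))
  secondary <- setdiff(names(src$files), src$primary)
  meta <- workflow_metadata(
    id = new_workflow_id(seed),
    version = "1.0.0",
    license = "Apache-2.0",
    authors = list(wf_author(account = "bioinfo-community",
                             name = "Fixture Maintainer",
                             affiliation = "Synthetic Data Institute",
                             orcid = "0000-0002-1825-0097")),
    name = sprintf("bacteria-genome-assembly-%s", tolower(language)),
    readme_url = furl("README.md"),
    language = wf_language(language, src$version),
    files = c(
      list(wf_file(furl(src$primary), target = src$primary, role = "primary")),
      lapply(secondary, function(rel)
        wf_file(furl(rel), target = rel, role = "secondary"))
    ),
    testing = list(wf_test_case(
      test_id = "assembly_smoke_test",
      files = list(
        wf_file(furl("tests/params.json"), target = "tests/params.json",
                role = "test", kind = "workflow_params"),
        wf_file(furl("tests/data/reads.fq"), target = "tests/data/reads.fq",
                role = "test", kind = "data")
      )
    ))
  )

  # --- defect injection: minimal mutations -----------------------------------
  if ("missing-primary" %in% defects)
    unlink(file.path(root, src$primary))
  if ("missing-dependency" %in% defects)
    unlink(file.path(root, secondary[[1]]))
  if ("missing-test-file" %in% defects)
    unlink(file.path(root, "tests/params.json"))
  if ("missing-readme" %in% defects)
    unlink(file.path(root, "README.md"))
  if ("invalid-license" %in% defects)
    meta$license <- "proprietary-eula"
  if ("language-type-unknown" %in% defects)
    meta$language$type <- "UNKNOWN"
  if ("language-version-unknown" %in% defects)
    meta$language$version <- "UNKNOWN"
  if ("no-authors" %in% defects)
    meta$authors <- list()
  if ("bad-id" %in% defects)
    meta$id <- "not-a-uuid"
  if ("bad-version" %in% defects)
    meta$version <- "one.zero"
  if ("syntax-error" %in% defects)
    corrupt_syntax(root, src$primary, language)

  metadata_path <- file.path(root, "metadata.yml")
  writeLines(serialize_metadata(meta, "yaml"), metadata_path, useBytes = TRUE)

  structure(
    list(root = root, language = wf_language(language, src$version),
         defects = defects, metadata_path = metadata_path, metadata = meta,
         seed = seed),
    class = "fixture_repo"
  )
}

corrupt_syntax <- function(root, primary, language) {
  path <- file.path(root, primary)
  lines <- readLines(path, warn = FALSE)
  lines <- switch(language,
    CWL = lines[!grepl("^class:", lines)],
    WDL = c(lines, "task broken {"),
    NFL = c(lines, "process broken {"),
    SMK = c(lines, "rule broken:")
  )
  writeLines(lines, path, useBytes = TRUE)
}

#' Stub-WES script matching a fixture's WES defect codes
#'
#' @param repo A [generate_repo()] result.
#' @return A script for [stub_wes()]: COMPLETE for every test unless a
#'   `wes-*` defect dictates otherwise.
#' @export
fixture_wes_script <- function(repo) {
  if ("wes-executor-error" %in% repo$defects) list(`*` = "EXECUTOR_ERROR")
  else if ("wes-timeout" %in% repo$defects)
    list(`*` = list(state = "COMPLETE", delay = 1e6))
  else list(`*` = "COMPLETE")
}

#' Generate a corpus of distinct fixture repositories
#'
#' @param n Number of repositories (languages cycle CWL/WDL/NFL/SMK).
#' @param seed Base seed; repository i uses `seed * 1000 + i`, so distinct
#'   seeds give distinct ids.
#' @param dir Parent directory.
#' @return List of `fixture_repo` (length `n`).
#' @export
generate_registry_corpus <- function(n, seed = 1, dir = tempfile("corpus-")) {
  stopifnot(n >= 0)
  languages <- c("CWL", "WDL", "NFL", "SMK")
  lapply(seq_len(n), function(i) {
    generate_repo(languages[[(i - 1L) %% 4L + 1L]], character(),
                  seed = seed * 1000 + i,
                  dir = file.path(dir, sprintf("repo-%03d", i)))
  })
}
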