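---
title: "Building a reusable-workflow registry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a reusable-workflow registry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfregistry)
```

## The problem and the procedure

Bioinformatics workflows written in CWL, WDL, Nextflow or Snakemake are
shared widely but reused rarely, because reuse fails on mundane grounds:
a missing license, a dangling dependency URL, an untested descriptor, an
unreachable author. `wfregistry` encodes a registry-side answer: a
workflow version is admitted to a registry only if its metadata passes
eleven machine-checkable requirements and its test cases complete through
the GA4GH WES protocol, and only then is it persisted (DOI-stamped) and
served through a static GA4GH TRS tree.

The pipeline is a forward-only, three-phase lifecycle:

1. **Submission** — `validate_workflow()` evaluates all eleven
   requirements (no short-circuiting, so the report is always complete),
   then `run_all_tests()` executes every test case sequentially through a
   WES endpoint. Any failure halts here; nothing is archived or emitted.
2. **Review** — a deliberate human gate. `submit_workflow()` stages a
   passing submission; `approve_and_publish()` is a separate call so an
   administrator's judgement can sit between them.
3. **Publication** — `persist_files()` hands every file (workflow files,
   test files, the README, and the test logs) to an archiver that mints a
   DOI; `rewrite_urls()` replaces every file URL with its persistent
   counterpart; `to_trs()` + `write_registry()` emit the static registry.

Two invariants matter most and are tested as such: *atomicity* (a failed
pipeline leaves the output directory and the archive untouched) and
*re-validation closure* (the rewritten, published metadata passes the full
validator against the archive alone, so a published record never decays
into an unreusable one as long as the archive persists).

## The metadata model

One document describes one workflow version: identity (`id`, a version-4
UUID; `version`, dotted numerics), `license` (SPDX-style identifier),
`authors`, `name`, `readme_url`, `language` (type + version), `files`
(exactly one `primary`), and `testing` (≥ 1 test case). Unknown top-level
keys are preserved verbatim, and serialization order is fixed, so
`parse_metadata(serialize_metadata(m))` is the identity in both JSON and
YAML; the test suite checks this on 100 randomized documents per dialect.

Within a test case, files carry a `kind` (`workflow_params`,
`engine_params`, `data`); exactly one file per test case must be the
workflow-parameters document. An explicit field was preferred over a
naming convention (e.g. "the file called params.json") because the WES
run request needs an unambiguous parameters document and filename
conventions differ across language communities.

Two levels of checking are deliberately distinct. *Schema* violations
(two primary files, an escaping `../` target, a malformed ORCID) reject
the document at parse time. *Requirement* failures (unknown license,
empty author name, unresolvable URL) are validator verdicts on a
schema-valid document. Identifier well-formedness sits in both layers:
`parse_metadata()` rejects a malformed `id`/`version` by default, while
`strict = FALSE` defers them to the validator so that deliberately
defective documents (fixtures, third-party submissions under triage) can
still be loaded and reported on rather than merely erroring.

## The validator's attribution rule

Every check always runs, but a check whose *subject matter* is missing
because of a defect that another requirement already reports passes with
an explanatory note instead of failing. Concretely: when the primary
descriptor is unavailable, the syntax check records "not evaluated"
rather than failing — the defect is the unavailability, and it is
reported under *Main workflow description*. Likewise, when the declared
language type is UNKNOWN, the syntax check falls back to content-based
detection so it judges syntax, not the declaration (which *Language
type* already judges). Without this rule a single injected defect would
cascade into several failed requirements and a report would conflate one
root cause with many symptoms; with it, the defect-injection property —
each minimal defect flags exactly one requirement — holds, and it is the
backbone of the test suite.

Language checks are deliberately shallow: CWL must parse as YAML with
`cwlVersion` and a known `class`; WDL needs a `version` statement and
balanced braces (counted outside string literals); Nextflow needs
balanced braces and a `process`/`workflow` block; Snakemake needs `rule`
blocks with consistent directive indentation. Deep validation belongs to
each language's own tooling; the structural layer catches the defect
classes a registry must reject while keeping the toolkit dependency-free.

## WES testing semantics

A test passes exactly when the run's terminal state is `COMPLETE`. No
output-content check is attempted: successful completion does not prove
the outputs are scientifically right, and output comparison is genuinely
hard (heuristic tools and updated databases produce legitimately
different bytes). That limitation is inherited knowingly; the registry's
claim is "this workflow runs to completion on its declared test inputs",
no more.

The runner polls the endpoint at `poll_interval` (default 5 s; tests use
sub-second values) up to `timeout` (default 3600 s, a deliberate cap so an
unresponsive executor cannot hang a submission forever); a timeout or a
transport failure yields a `SYSTEM_ERROR` *result* rather than an R error,
because an environment failure is a failed test run, not an aborted
pipeline. States outside the WES vocabulary map to `SYSTEM_ERROR` (fail
safe). The bundled `stub_wes()` implements the minimal WES surface
(submit → run id; poll → QUEUED → RUNNING → scripted terminal state after
a scripted delay) deterministically, and the suite checks that an HTTP
endpoint serving the same state sequence through an injected transport
yields identical verdicts — the backend-substitutability property that
makes offline results meaningful.

## Resolution, retries, and not-found vs failure

All file access goes through a resolver. A definitive not-found
(HTTP 404/410, missing local file) is a *result* — a metadata defect the
validator reports — while timeouts and 5xx responses are *transport
errors*, retried with exponential backoff (defaults: 10 s timeout, 3
retries, factor 2; conventional values, configurable) and then raised,
so a network outage is never misreported as a broken workflow.
Availability checks invoke the resolver without credentials:
"accessible without restriction" is operationalized as "resolvable
anonymously".

## TRS output choices

The emitted tree targets the TRS 2.x document shapes but only the paths
the registry actually needs: the tools list, per-tool and per-version
documents, and per-version `/files` and `/tests`. Endpoints with no
content here (e.g. containerfiles) are omitted rather than stubbed. Each
endpoint becomes `<out>/<path>/index.json` so static hosting serves
extensionless API paths; the source metadata document is co-published as
`metadata.json` beside the version document, making a published version
exactly two metadata documents. File checksums use sha-256 (computed by a
self-contained implementation verified against the FIPS 180-4 test
vectors) with the algorithm named in the checksum object, as TRS
requires. `verified` is set, with the registry name as
`verified_source`, only when the pipeline recorded all tests passing —
the test-before-publish guarantee expressed in a standard TRS field.

The bundled archiver stores files locally and mints deterministic DOIs
`10.5072/<first 8 id chars>.<version>` in the reserved test prefix:
valid-shaped, collision-free identifiers with no network. A production
deployment would implement the same two-function archiver contract
against a real data repository. Archived content also retains the
per-test logs permanently — execution logs are provenance, and hosted CI
logs are typically ephemeral.

## What the fixture generator emulates — and what it does not

`generate_repo()` writes a complete synthetic repository modeled on a
small bacterial genome assembly: a primary workflow chaining four named
command-line tool steps (seqkit, fastqc, fastp, platanus_b) in CWL, or
equivalent two-module shapes in WDL/Nextflow/Snakemake, plus README,
Apache-2.0 LICENSE, a parameters file and a tiny FASTQ input, and a
complete metadata document. Defect codes apply minimal mutations — one
per requirement, plus WES-failure codes that script the stub instead of
touching the repository. Generation is deterministic under a seed.

The fixtures are structurally faithful but computationally inert: the
descriptors are never executed by a real engine, containers are never
pulled, and the stub supplies run outcomes. Passing tests therefore
demonstrate the registry machinery — validation semantics, gating,
persistence, TRS layout — not that any particular workflow is
biologically correct, and real-world failure modes such as slow mirrors,
authentication walls or multi-gigabyte inputs are out of frame. Problem
sizes throughout the suite are desk-scale by design: 100-document
round-trip sweeps, corpora of 3–5 repositories, sub-second poll
intervals.

## Known limitations

* Output correctness of workflow runs is not evaluated (see above).
* Syntax validation is structural; a descriptor can pass it and still be
  rejected by its engine.
* Nextflow workflows without a DSL declaration and Snakemake workflows
  (which have no in-file language version) detect with version UNKNOWN;
  the metadata author must state the version for the validity
  requirement to pass.
* The remote resolver's default transport uses base R connections (plain
  HTTP GET); production use against authenticated or HTTPS-POST services
  is expected to inject a transport function.
* A rejected submission cannot be resumed after edits; the lifecycle
  restarts from submission, which keeps the record's forward-only
  invariant trivial to audit.
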