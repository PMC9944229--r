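# wfregistry

Workflows published on the internet are frequently unusable in practice:
the license is unclear, dependent files have moved, no test demonstrates
that the workflow still runs, and nobody is identified as responsible for
it. `wfregistry` is an R toolkit for operating a **workflow registry that
only publishes reusable workflows**. It is aimed at bioinformatics groups
and communities who want to share CWL, WDL, Nextflow or Snakemake
workflows with confidence, without building and maintaining a dynamic web
service: the registry it emits is a static file tree that any plain file
server can host.

## What the toolkit enforces

A workflow version is described by a single metadata document (JSON or
YAML) naming, by URL, its primary descriptor, dependent files, authors,
license, documentation and at least one test case. Before publication the
document must pass **eleven requirements** in three categories:

| Category     | Requirement                | Check                                              |
|--------------|----------------------------|----------------------------------------------------|
| Availability | Main workflow description  | primary descriptor resolves without restriction    |
|              | Dependent materials        | every dependent file and remote import resolves    |
|              | Testing materials          | test files resolve; each test has a params document|
|              | Open-source license        | license is a recognized open-source identifier     |
| Validity     | Language type              | CWL / WDL / NFL / SMK is stated                    |
|              | Language version           | the language version is stated                     |
|              | Language syntax            | the descriptor passes structural syntax checks     |
| Traceability | Authors and maintainers    | at least one author with account and name          |
|              | Documentation              | the README resolves                                |
|              | Workflow ID                | the id is a version-4 UUID                         |
|              | Workflow metadata version  | the version is dotted numerics                     |

Each test case is executed through the GA4GH **Workflow Execution Service
(WES)** run-request protocol and passes exactly when the run reaches the
terminal state `COMPLETE` (a deterministic in-process WES stub makes this
fully testable offline). A workflow that passes both gates moves through a
three-phase lifecycle — *submission → review → publication* — at the end
of which its files are persisted through an archiver that mints a DOI,
its metadata is rewritten to the persisted URLs, and the registry is
emitted as a static GA4GH **Tool Registry Service (TRS)** document tree:
`/tools/{id}/versions/{version_id}` plus exactly two sub-paths, `/files`
(with sha-256 checksums) and `/tests`.

## Worked example

```r
library(wfregistry)

# a synthetic workflow repository: a CWL genome-assembly workflow chaining
# seqkit, fastqc, fastp and platanus_b tool steps, with metadata and a test
repo <- generate_repo("CWL", seed = 42, dir = "demo")
meta <- read_metadata(repo$metadata_path)
print(meta)
#> <workflow_metadata> bacteria-genome-assembly-cwl (version 1.0.0)
#>   id:       04089319-0fe7-4384-b391-e288a34ec431
#>   language: CWL v1.0
#>   license:  Apache-2.0
#>   authors:  bioinfo-community
#>   files:    5 (1 primary)
#>   tests:    1

validate_workflow(meta)
#> <validation_report> overall: PASS
#>   availability: pass
#>     [x] Main workflow description
#>     [x] Dependent materials
#>     [x] Testing materials
#>     [x] Open-source license
#>   validity: pass
#>     [x] Language type
#>     [x] Language version
#>     [x] Language syntax
#>   traceability: pass
#>     [x] Authors and maintainers
#>     [x] Documentation
#>     [x] Workflow ID
#>     [x] Workflow metadata version

sub <- publish_workflow(meta, wes_endpoint = stub_wes(),
                        archiver = local_archiver("demo-archive"),
                        out_dir = "demo-registry")
sub$receipt$doi
#> [1] "10.5072/04089319.1.0.0"
```

The validation report shows every requirement with its verdict; `11/11`
passing lets the lifecycle proceed. The DOI is minted in the reserved
`10.5072` test prefix by the bundled local archiver; `demo-registry/`
now contains the static TRS tree
(`tools/<id>/versions/1.0.0/{index.json,metadata.json,files/,tests/}`).

The same flow is available from a shell via the four submission
subcommands (`exec/wfregistry make-template | validate | test |
pull-request`), plus `publish` and `fixtures`.

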