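Package: seqfarm
Title: Task Farming for Scalable Sequence-Analysis Workloads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A portable master-worker task-farming framework for protein
    sequence-analysis workloads. A reference database is preloaded as a single
    contiguous in-memory image with one bulk read and delivered to every worker
    through a binomial-tree broadcast, so the backing store is read exactly once
    per run. Workers prefetch query batches from the master to hide dispatch
    latency while balancing load dynamically, and compute kernels (a local
    Smith-Waterman aligner and a position-weight-matrix profile scanner) run as
    black boxes behind a virtual I/O contract that serves all reads from memory.
    Output records pass through a two-stage buffered store - in-memory blocks
    flushed in the background to files sharded across directories, optionally
    block-compressed - indexed by a manifest that supports reassembly and
    exactly-once verification. Includes weak-scaling workload generators
    (16 queries per core at 200 amino acids for alignment; 760 sequences per
    core for profile scanning; 10 datasets per core for multiple alignment),
    a discrete-event scheduling simulator, hit-table parsers with SQL export,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
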