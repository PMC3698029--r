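---
title: "Task farming for sequence analysis: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task farming for sequence analysis: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqfarm)
```

## The problem and the pattern

Query-parallel sequence analysis — many independent protein queries against
one shared reference — scales badly when every worker process does its own
I/O: the reference database is re-read once per process, and results arrive
as a blizzard of small uncoordinated writes. On shared (especially
distributed) filesystems both patterns serialise the run on storage.

`seqfarm` implements the wrapper architecture that avoids this, as a
portable, instrumented, deterministic reference. The compute kernel is a
black box: it receives queries and the database through in-memory endpoints
(`open_tool_io()`) and emits records the same way, so every observable I/O
decision belongs to the framework:

1. *Input*: the database becomes one contiguous byte image
   (`build_db_image()`), persisted and later preloaded with a single bulk
   read (`preload_image()`, `load_stats$reads == 1`), then replicated to
   all workers by a binomial-tree broadcast (`plan_broadcast()`).
2. *Dispatch*: a master hands out query batches dynamically; workers
   prefetch their next batch while computing (`next_assignment()`,
   `run_farm()`).
3. *Output*: records buffer in memory blocks that a background flusher
   writes, sharded across directories and optionally compressed
   (`open_store()`), under a manifest that makes the run reassemblable and
   verifiable (`reassemble()`, `verify_run()`).

## Broadcast model

For `P` participants the binomial tree delivers the payload in
`ceil(log2(P))` rounds with exactly `P - 1` point-to-point messages: in
round `r`, every virtual rank `v < 2^(r-1)` sends to `v + 2^(r-1)`. Virtual
ranks are actual ranks relabelled so the root is 0; ties break by ascending
rank. The reference transport is round-synchronous and in-process; a
distributed (MPI-style) backend can replace it behind the same
`local_transport()` contract, since `execute_broadcast()` only requires
reliable point-to-point delivery in round order. Every delivery is verified
by CRC-32 against the root's payload.

```{r}
plan <- plan_broadcast(6)
length(plan$rounds)
sum(vapply(plan$rounds, nrow, integer(1)))
```

## Dispatch protocol and its guarantees

A worker may hold `1 + prefetch_depth` batches (the one it computes plus
prefetched ones). It issues a request whenever it has no request in flight
and spare capacity; the master answers after latency λ with the lowest-id
pending batch, serving simultaneous requests in ascending worker id.
Assignments are final — a prefetched batch is never reclaimed for
rebalancing, which keeps the protocol simple and makes every schedule
reproducible.

The discrete-event simulator (`simulate_schedule()`) executes exactly this
protocol in simulated time. Its testable consequences:

* depth 0, λ = 0 is greedy list scheduling, so the makespan is within
  `(2 - 1/W)` of the brute-force optimum;
* if every batch duration is at least λ and depth ≥ 1, the prefetch issued
  at batch start is answered before the batch ends, so per-worker idle time
  between first assignment and last completion is exactly 0;
* for uniform durations and λ > 0, depth 1 never loses to depth 0.

```{r}
c(depth0 = simulate_schedule(c(2, 2, 2, 2), 2, 0, 1)$makespan,
  depth1 = simulate_schedule(c(2, 2, 2, 2), 2, 1, 1)$makespan)
```

The real execution backend in `run_farm()` runs logical workers as a
deterministic in-process loop behind the same scheduler. This is a design
choice: the module's contracts — exactly-once processing, serial
equivalence, one backing-store read, capacity limits — are scheduling
semantics, not OS facts, and an in-process loop makes them exactly
testable; an OS-process or MPI backend can be substituted behind the same
dispatch and transport interfaces without touching any contract.

## Kernels

The aligner kernel is Smith–Waterman with *linear* gap costs
(`scoring_scheme(match = 2, mismatch = -1, gap = -2)` by default). Linear
rather than affine gaps is deliberate: it keeps the exhaustive enumeration
oracle (all substring pairs × all alignment paths) tractable, so the DP can
be validated from first principles; it is a documented divergence from
production aligners, as is the absence of E-value statistics and
substitution matrices. Tie-breaks are fixed: the best-scoring DP cell with
the smallest row-major index defines the reported spans, and `sw_search()`
orders equal scores by ascending subject id.

The profiler kernel scores ungapped windows of a position weight matrix
over the 21-letter alphabet (20 amino acids + X); the leftmost best offset
wins, and a query shorter than the model is a no-hit by rule, not an error.
Both kernels emit one tab-separated record per query — `query_id,
subject_id, score, q_start, q_end, s_start, s_end, status` with 0-based
half-open spans — which is the dialect `hits_to_table()` parses.

Per-query kernel failures are recorded as manifest failure entries and the
run continues; results plus failures must cover the input ids exactly once
for `verify_run()` to pass. Crash-level fault tolerance (losing a worker
mid-batch) is out of scope; assignments are final.

## Output store

Records append to an in-memory block; when occupancy reaches
`flush_threshold × block_capacity` (default 0.9 × 4 MiB — "nearly full";
neither value is canonical, both are tunable) the block is sealed and
queued for the flusher, and a fresh block starts. R is single-threaded, so
the "background" flusher is modelled as a queue pumped off the append path:
an append only ever enqueues and returns. The no-waiting contract is
asserted by instrumentation counters (appends observed while flushes are
pending, with the pump artificially paused), not by wall-clock timing,
which would be meaningless at this scale.

Blocks go round-robin to `seq mod D` of the `D` shard directories (default
4), are optionally DEFLATE-compressed (a tag byte in the block header
leaves room for other codecs), and carry a CRC-32 of the raw record stream
— cheap, standard, adequate for corruption detection and nothing more. The
manifest (JSON) is the single authority for reassembly: records are
re-emitted sorted by query id, which defines the canonical order precisely
because block order, shard count, compression and worker interleaving are
storage details a correct run must be independent of. Blocks may interleave
records from several workers; each record carries its own worker tag.

Degenerate inputs are pinned down: a payload larger than the block capacity
is an oversize error (it could never flush); appends after finalize and
double finalize are errors; a zero-record run yields a valid manifest with
zero entries.

## Workload generators

The generators reproduce weak-scaling study conditions in which total work
grows proportionally to the core count: 16 queries per core at exactly 200
residues for the aligner workload; 760 sequences per core for the profile
workload ("approximately 760" is fixed to exactly 760 so counts are
deterministic and testable); 10 datasets per core for the multiple-alignment
workload. Where the original conditions leave the length law unstated
(profile queries, alignment dataset ancestors) the default is uniform
100–400 residues — a realistic protein-length band — and is an explicit,
documented stand-in. MSA datasets emulate the relatedness of sequences
returned by a prior alignment search: one random ancestor per dataset,
each member a 5% per-site point mutant of it.

Residues are drawn i.i.d. uniform over the 20 standard amino acids. That is
the major idealisation: real proteins have skewed composition, repeats and
domain structure, so alignment scores here are calibration-free and the
generators say nothing about biological sensitivity. Passing tests
demonstrate the *framework* contracts (counts, determinism, exactly-once
delivery, scheduling bounds, oracle-exact kernels) — not that the kernels
rank real homologs the way BLAST or HMMER would.

All generation is seeded; sub-seeds are derived per stream (CRC-32 of
seed + stream label, reduced into the positive 32-bit range) so that, for
one master seed, the database, workload and schedule randomness are
independent but individually reproducible.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use sizes chosen to exercise
every contract while keeping a full run in the order of a minute on one
core: broadcast plans exhaustively for P ≤ 128; a 50-record × 100-residue
database with 64 aligner queries for the 20 randomized
exactly-once/serial-equivalence configurations (workers 1–8, batch size
1–16, prefetch depth 0–3); 200 random pairs (lengths ≤ 40) against the
plain-R DP oracle, itself validated by exhaustive enumeration at lengths
≤ 6; scheduling instances of ≤ 8 batches × ≤ 3 workers against the
brute-force optimum. These sizes are the package's own choice of a
convincing-but-quick regression surface; nothing in the design caps the
scale.

## Known limitations

* One machine, logical workers: no network transport ships with the
  package (the contracts are backend-ready, the backends are not here).
* `page_hint` is advisory metadata only; no OS page-size (TLB) control is
  attempted, portable runtimes cannot do it unprivileged.
* Linear-gap alignment and ungapped profile windows are reference kernels,
  not drop-in replacements for BLAST/HMMER.
* Hardware-bound performance properties (bandwidth, scaling curves) are
  design rationale here, demonstrated as structural invariants (read
  counts, message counts, idle times), not as timings.
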