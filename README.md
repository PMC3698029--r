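# seqfarm

Task farming for scalable protein sequence-analysis workloads.

Large sequence-analysis campaigns — aligning millions of queries against a
reference database, scanning proteomes with domain models — are
embarrassingly parallel over queries, but naive parallelisation collapses on
shared storage: thousands of processes re-reading the same database and
dribbling small writes into one directory serialise on the filesystem, not
the CPU. The pattern that scales is a *wrapper* around an untouched
("black-box") compute kernel that takes over all of its I/O:

* **One reader, tree broadcast.** The reference database is loaded once, as
  a single contiguous in-memory image (one bulk read), and delivered to all
  `P` workers by a binomial-tree broadcast — `P − 1` messages in
  `⌈log₂ P⌉` rounds.
* **Prefetching master–worker dispatch.** Queries are batched and handed
  out on demand; a worker requests its next batch while still computing the
  current one, hiding dispatch latency and balancing the (highly variable)
  per-query runtimes.
* **Virtual kernel I/O.** The kernel reads queries and database, and writes
  results, through in-memory endpoints only — it never opens a file.
* **Two-stage buffered output.** Records accumulate in memory blocks; a
  background flusher writes nearly-full blocks — optionally
  DEFLATE-compressed — to files sharded round-robin across directories. A
  manifest indexes every block so the run can be reassembled in canonical
  order and verified record-exactly-once.

`seqfarm` implements this architecture end to end at desk scale, fully
instrumented and deterministic, with reference kernels (a Smith–Waterman
local aligner with linear gap costs, and a position-weight-matrix profile
scanner), weak-scaling workload generators, a discrete-event scheduling
simulator, output parsers with SQL export, and a command-line interface.

## The scheduling and alignment cores

Dispatch: each worker may hold `1 + prefetch_depth` batches; pending batches
go out in ascending batch id, simultaneous requests are served in ascending
worker id, and a request costs latency λ. With depth 0 this is classic
greedy list scheduling (makespan ≤ (2 − 1/W) × optimum); with depth ≥ 1 and
batch durations ≥ λ, worker idle time is exactly zero — latency is fully
hidden.

Alignment: the aligner kernel scores the standard best-local-alignment
recurrence with linear gaps,

    H(i,j) = max{ 0, H(i−1,j−1) + s(aᵢ,bⱼ), H(i−1,j) + g, H(i,j−1) + g }

with `s(a,b) = match` or `mismatch` and gap penalty `g < 0`; the profile
kernel maximises the ungapped window score `Σᵢ w[i, q(o+i)]` over offsets
`o`. Both are verified in the test suite against independent brute-force
oracles.

## Weak-scaling workload generators

`gen_workload()` reproduces the study-condition recipes that tie workload
size to core count (constant work per core):

| profile    | per core              | lengths          |
|------------|------------------------|-----------------|
| `aligner`  | 16 queries             | exactly 200 aa  |
| `profiler` | 760 sequences          | uniform 100–400 |
| `msa`      | 10 datasets (10 seqs)  | shared ancestor, 5% point mutations |

## Worked example

```r
library(seqfarm)
db  <- gen_database(50, c(80, 120), seed = 42)      # synthetic reference db
img <- build_db_image(db)                           # contiguous image + index
qs  <- gen_workload(workload_profile("aligner", cores = 1, seed = 42))$queries

m <- run_farm(farm_config(workers = 4, batch_size = 4),
              qs, img, farm_tool("aligner", top_k = 1),
              store_config(file.path(tempdir(), paste0("shard-", 1:2))))
m$totals
#> $records
#> [1] 16
#> $blocks
#> [1] 1
#> $failures
#> [1] 0
c(m$db_reads, m$broadcast$messages)   # backing-store reads; broadcast edges
#> [1] 0 4
verify_run(m, qs$id)
#> verification: PASS
#>   records: 16  failures: 0
head(hits_to_table(reassemble(m)), 3)
#>   query_id subject_id score q_start q_end s_start s_end status
#> 1  q000001   db000042     9      26    32      57    63    hit
#> 2  q000002   db000018    10     103   111      66    74    hit
#> 3  q000003   db000026    10      54    59      30    35    hit
```

The 16 queries (one core × 16) were dispatched in 4 batches over 4 workers;
every query produced exactly one record; the in-memory image needed zero
backing-store reads (`preload_image()` on a persisted image records exactly
one) and reached all 4 workers over 4 broadcast messages. The hit table
shows each query's best subject, its score, and the 0-based half-open
aligned spans. `table_to_sql()` turns it into an ANSI SQL dump.

The same pipeline runs from a shell:

```sh
seqfarm gendb   --n 50 --out db.fasta
seqfarm genwork --tool aligner --cores 1 --out queries.fasta
seqfarm run     --config run.yaml
seqfarm verify  --manifest out/shard-1/manifest.json --queries queries.fasta
```

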