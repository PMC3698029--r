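# farm: master-worker orchestration with prefetching and virtual tool I/O.

#' Configure a farm run
#'
#' @param workers Number of workers (>= 1).
#' @param batch_size Queries per dispatch batch (default 16).
#' @param prefetch_depth Extra batches a worker may hold beyond the one it
#'   is computing (default 1: one batch always in flight, hiding dispatch
#'   latency behind computation).
#' @param seed Integer seed recorded in the manifest.
#' @param dispatch_latency Simulated dispatch latency; only used by
#'   [simulate_schedule()]-backed analyses, not by real runs.
#' @return A `farm_config`.
#' @export
farm_config <- function(workers = 1L, batch_size = 16L, prefetch_depth = 1L,
                        seed = 1L, dispatch_latency = 0) {
  workers <- as.integer(workers)
  batch_size <- as.integer(batch_size)
  prefetch_depth <- as.integer(prefetch_depth)
  if (is.na(workers) || workers < 1L) stop("workers must be >= 1")
  if (is.na(batch_size) || batch_size < 1L) stop("batch_size must be >= 1")
  if (is.na(prefetch_depth) || prefetch_depth < 0L)
    stop("prefetch_depth must be >= 0")
  if (dispatch_latency < 0) stop("dispatch_latency must be >= 0")
  structure(list(workers = workers, batch_size = batch_size,
                 prefetch_depth = prefetch_depth, seed = as.integer(seed),
                 dispatch_latency = dispatch_latency),
            class = "farm_config")
}

#' Open a virtual I/O session for one batch
#'
#' The wrapper side of the black-box contract: the kernel sees three
#' endpoints — a database reader, a query reader serving the batch as FASTA
#' text, and an output writer — all served from memory, so the kernel never
#' touches the filesystem. Closing the session forwards everything written
#' to the output store, tagged with the worker and batch ids.
#'
#' @param dbimage The worker's [build_db_image()] copy.
#' @param batch_queries A [seq_set()] with the batch's sequences.
#' @param store An open [open_store()] handle.
#' @param worker_id Worker id for tagging.
#' @param batch_id Batch id for tagging.
#' @return A `tool_io` environment with `read_db()`, `read_queries()`,
#'   `write_record(query_id, payload)`, `write_failure(query_id, reason)`
#'   and `close()`.
#' @export
open_tool_io <- function(dbimage, batch_queries, store, worker_id,
                         batch_id = NA_integer_) {
  stopifnot(inherits(dbimage, "db_image"), inherits(batch_queries, "seq_set"))
  io <- new.env(parent = emptyenv())
  io$closed <- FALSE
  io$records <- list()
  io$failures <- list()
  io$reads <- list(db = 0L, queries = 0L)
  query_text <- format_fasta(batch_queries)
  io$read_db <- function() {
    if (io$closed) stop("read after close")
    io$reads$db <- io$reads$db + 1L
    dbimage
  }
  io$read_queries <- function() {
    if (io$closed) stop("read after close")
    io$reads$queries <- io$reads$queries + 1L
    query_text
  }
  io$write_record <- function(query_id, payload) {
    if (io$closed) stop("write after close")
    io$records[[length(io$records) + 1L]] <-
      list(query_id = query_id, payload = payload)
  }
  io$write_failure <- function(query_id, reason) {
    if (io$closed) stop("write after close")
    io$failures[[length(io$failures) + 1L]] <-
      list(query_id = query_id, reason = reason)
  }
  io$close <- function() {
    if (io$closed) stop("session already closed")
    for (r in io$records)
      append_record(store, worker_id, r$query_id, r$payload)
    for (f in io$failures)
      append_failure(store, f$query_id,
                     paste0("worker ", worker_id, " batch ", batch_id, ": ",
                            f$reason))
    io$closed <- TRUE
    invisible(length(io$records))
  }
  class(io) <- "tool_io"
  io
}

#' Run a task farm over a query workload
#'
#' The full wrapper pattern end to end: the database image is delivered to
#' every worker through a binomial-tree broadcast (the backing store having
#' been read at most once, by [preload_image()]); queries are split into
#' batches dispatched dynamically with prefetching; the kernel runs as a
#' black box behind [open_tool_io()]; records land in the two-stage output
#' store, and the returned manifest indexes every block for reassembly and
#' verification. The set of output records is independent of `workers`,
#' `batch_size` and `prefetch_depth`.
#'
#' The reference backend executes logical workers deterministically in one
#' process behind the same dispatch and transport contracts a distributed
#' backend would use.
#'
#' @param config A [farm_config()].
#' @param queries Non-empty [seq_set()] of query sequences.
#' @param dbimage A `db_image`, or a path to one persisted with
#'   [save_db_image()] (preloaded with a single bulk read).
#' @param tool A [farm_tool()].
#' @param store An open [open_store()] handle, or a [store_config()] (a
#'   store is opened for the run).
#' @return The run manifest, augmented with `db_reads` (backing-store reads
#'   of the database), `broadcast` (rounds/messages/receipts) and the
#'   schedule event log.
#' @examples
#' \donttest{
#' db <- gen_database(20, c(50, 80), seed = 1)
#' qs <- gen_database(8, 60, seed = 2)
#' dir <- tempfile()
#' m <- run_farm(farm_config(workers = 2, batch_size = 4),
#'               qs, build_db_image(db), farm_tool("aligner"),
#'               store_config(file.path(dir, paste0("shard-", 1:2))))
#' m$totals$records
#' }
#' @export
run_farm <- function(config, queries, dbimage, tool, store) {
  stopifnot(inherits(config, "farm_config"))
  if (!inherits(queries, "seq_set") || nrow(queries) == 0L)
    stop("queries must be a non-empty seq_set")
  if (is.character(dbimage)) dbimage <- preload_image(dbimage)
  stopifnot(inherits(dbimage, "db_image"), inherits(tool, "farm_tool"))
  if (inherits(store, "store_config")) store <- open_store(store)
  stopifnot(inherits(store, "run_store"))

  # One-reader discipline: deliver the image to all workers by tree
  # broadcast; rank 0 is the master, ranks 1..W the workers.
  plan <- plan_broadcast(config$workers + 1L, root = 0L)
  receipts <- execute_broadcast(plan, dbimage$image)
  # Each worker's copy is bit-identical to the root's (checksums verified in
  # execute_broadcast); the reference backend shares the parsed image
  # structure, which R's copy-on-write semantics keep immutable.
  worker_images <- rep(list(dbimage), config$workers)

  batches <- make_batches(queries, config$batch_size)
  sched <- new_scheduler(batches, config$workers, config$prefetch_depth)
  worker_queue <- rep(list(list()), config$workers)
  done_workers <- rep(FALSE, config$workers)
  log <- character(0)

  while (TRUE) {
    progressed <- FALSE
    for (w in seq_len(config$workers)) {
      # prefetch up to capacity
      while (!done_workers[[w]] &&
             length(worker_queue[[w]]) < 1L + config$prefetch_depth) {
        b <- next_assignment(sched, w)
        if (is.null(b)) { done_workers[[w]] <- TRUE; break }
        worker_queue[[w]] <- c(worker_queue[[w]], list(b))
        log <- c(log, sprintf("assign worker=%d batch=%d", w, b$batch_id))
      }
      if (length(worker_queue[[w]]) > 0L) {
        b <- worker_queue[[w]][[1L]]
        worker_queue[[w]] <- worker_queue[[w]][-1L]
        batch_records <- queries[match(b$query_ids, queries$id), ,
                                 drop = FALSE]
        class(batch_records) <- c("seq_set", "data.frame")
        io <- open_tool_io(worker_images[[w]], batch_records, store, w,
                           b$batch_id)
        tool_run_batch(tool, io)
        io$close()
        complete_batch(sched, w, b$batch_id)
        log <- c(log, sprintf("complete worker=%d batch=%d", w, b$batch_id))
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }

  manifest <- finalize_store(store)
  manifest$seed <- config$seed
  manifest$workers <- config$workers
  manifest$batch_size <- config$batch_size
  manifest$prefetch_depth <- config$prefetch_depth
  manifest$db_reads <- dbimage$load_stats$reads
  manifest$broadcast <- list(participants = plan$participants,
                             rounds = length(plan$rounds),
                             messages = nrow(receipts))
  manifest$log <- c(log, manifest$log)
  write_manifest(manifest, store$config$manifest_path)
}

#' Load a farm run configuration from YAML
#'
#' Expected keys: `workers`, `batch_size`, `prefetch_depth`, `seed`,
#' `tool` (`name` plus kernel parameters), `queries` (FASTA path),
#' `database` (FASTA path or persisted image path), and `store`
#' (`shard_dirs` or `root`+`n_shards`, `block_capacity`, `flush_threshold`,
#' `compression`).
#'
#' @param path YAML file path.
#' @return A list with `config` ([farm_config()]), `tool`, `queries_path`,
#'   `database_path`, `store_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  cfg <- farm_config(workers = y$workers %||% 1L,
                     batch_size = y$batch_size %||% 16L,
                     prefetch_depth = y$prefetch_depth %||% 1L,
                     seed = y$seed %||% 1L)
  if (is.null(y$tool$name)) stop("config must name a tool")
  tool <- if (y$tool$name == "profiler") {
    model <- if (!is.null(y$tool$model)) read_profile_model(y$tool$model)
             else gen_profile_model(y$tool$model_length %||% 10L,
                                    seed = cfg$seed)
    farm_tool("profiler", model = model,
              threshold = y$tool$threshold %||% 0)
  } else if (y$tool$name == "aligner") {
    farm_tool("aligner",
              scheme = scoring_scheme(y$tool$match %||% 2,
                                      y$tool$mismatch %||% -1,
                                      y$tool$gap %||% -2),
              top_k = y$tool$top_k %||% 3L,
              min_score = y$tool$min_score %||% 1)
  } else stop("unknown tool '", y$tool$name, "' in config")
  shard_dirs <- if (!is.null(y$store$shard_dirs))
    unlist(y$store$shard_dirs)
  else file.path(y$store$root %||% "seqfarm-out",
                 sprintf("shard-%d", seq_len(y$store$n_shards %||% 4L)))
  sc <- store_config(shard_dirs,
                     block_capacity = y$store$block_capacity %||%
                       4L * 1024L * 1024L,
                     flush_threshold = y$store$flush_threshold %||% 0.9,
                     compression = isTRUE(y$store$compression))
  list(config = cfg, tool = tool,
       queries_path = y$queries, database_path = y$database,
       store_config = sc)
}
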