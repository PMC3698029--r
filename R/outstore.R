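# outstore: two-stage buffered output with background flush, directory
# sharding, optional block compression, and a manifest for reassembly.
#
# Block file format (little-endian):
#   "SFBK" magic, version byte 0x01, uint32 seq, uint32 worker_id,
#   uint32 raw_size, uint32 stored_size, uint32 crc32 low-31 bits,
#   uint32 crc32 high bit, uint8 flags (bit 0 = deflate-compressed),
#   then `stored_size` payload bytes.
# The raw payload is the framed record stream: per record uint32 id length,
# id bytes, uint32 worker id, uint32 payload length, payload bytes. The
# CRC-32 is computed over the raw (uncompressed) stream.

BLOCK_MAGIC <- charToRaw("SFBK")
BLOCK_VERSION <- as.raw(1L)

#' Configure an output store
#'
#' @param shard_dirs Ordered character vector of `D >= 1` shard directories.
#'   Output block files are distributed round-robin across them, spreading
#'   load over multiple backing devices on striped filesystems.
#' @param block_capacity In-memory block size in bytes (default 4 MiB).
#' @param flush_threshold Fraction of `block_capacity` at which a block is
#'   sealed and handed to the background flusher (default 0.9 — "nearly
#'   full"); must be in `(0, 1]`.
#' @param compression Compress block payloads (DEFLATE) off the append path.
#' @param manifest_path Where [finalize_store()] writes the manifest
#'   (default `manifest.json` inside the first shard directory).
#' @return A `store_config`.
#' @export
store_config <- function(shard_dirs, block_capacity = 4L * 1024L * 1024L,
                         flush_threshold = 0.9, compression = FALSE,
                         manifest_path = NULL) {
  shard_dirs <- as.character(shard_dirs)
  if (length(shard_dirs) < 1L) stop("need at least one shard directory")
  block_capacity <- as.numeric(block_capacity)
  if (is.na(block_capacity) || block_capacity <= 0)
    stop("block_capacity must be > 0")
  if (is.na(flush_threshold) || flush_threshold <= 0 || flush_threshold > 1)
    stop("flush_threshold must be in (0, 1]")
  structure(list(shard_dirs = shard_dirs,
                 block_capacity = block_capacity,
                 flush_threshold = flush_threshold,
                 compression = isTRUE(compression),
                 manifest_path = manifest_path %||%
                   file.path(shard_dirs[[1L]], "manifest.json")),
            class = "store_config")
}

#' Shard directory for a block sequence number
#'
#' Deterministic round-robin: block `seq` goes to shard `seq mod D`.
#'
#' @param seq Non-negative block sequence number.
#' @param config A [store_config()].
#' @return The shard directory path.
#' @examples
#' shard_for(7, store_config(c("a", "b", "c")))  # "b"
#' @export
shard_for <- function(seq, config) {
  stopifnot(inherits(config, "store_config"))
  config$shard_dirs[[(seq %% length(config$shard_dirs)) + 1L]]
}

#' Open an output store
#'
#' Creates the shard directories; nothing is written to the backing store
#' until a block crosses the flush threshold or [finalize_store()] runs.
#'
#' @param config A [store_config()].
#' @param run_id Run identifier echoed into the manifest.
#' @return A `run_store` handle (environment).
#' @export
open_store <- function(config, run_id = "run") {
  stopifnot(inherits(config, "store_config"))
  for (d in config$shard_dirs) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(d)) stop("cannot create shard directory ", d)
    if (file.access(d, mode = 2L) != 0L) stop("unwritable directory ", d)
  }
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$run_id <- run_id
  e$next_seq <- 0L
  e$cur_records <- list()   # list of list(query_id, worker_id, payload)
  e$cur_bytes <- 0
  e$flush_queue <- list()   # sealed blocks awaiting background write
  e$entries <- list()       # manifest entries of flushed blocks
  e$failures <- list()
  e$finalized <- FALSE
  e$flusher_paused <- FALSE # instrumentation hook: hold the queue
  e$stats <- list(appends = 0L, flushes = 0L,
                  appends_while_flush_pending = 0L)
  e$log <- character(0)
  class(e) <- "run_store"
  e
}

store_log <- function(store, ...) {
  store$log <- c(store$log, paste0(...))
}

seal_block <- function(store, worker_id) {
  if (length(store$cur_records) == 0L) return(invisible())
  block <- list(seq = store$next_seq,
                worker_id = as.integer(worker_id),
                records = store$cur_records)
  store$next_seq <- store$next_seq + 1L
  store$cur_records <- list()
  store$cur_bytes <- 0
  store$flush_queue[[length(store$flush_queue) + 1L]] <- block
  invisible()
}

# Background-flusher pump: writes queued blocks to their shard files. Kept
# off the append path — an append only enqueues; this runs afterwards (and
# at finalize), so appends never wait on a write in progress.
pump_flusher <- function(store) {
  if (store$flusher_paused) return(invisible(0L))
  n <- 0L
  while (length(store$flush_queue) > 0L) {
    block <- store$flush_queue[[1L]]
    store$flush_queue <- store$flush_queue[-1L]
    entry <- write_block(store, block)
    store$entries[[length(store$entries) + 1L]] <- entry
    store$stats$flushes <- store$stats$flushes + 1L
    store_log(store, "flush seq=", block$seq, " path=", entry$path)
    n <- n + 1L
  }
  invisible(n)
}

frame_records <- function(records) {
  parts <- lapply(records, function(r) {
    id_raw <- charToRaw(r$query_id)
    payload_raw <- if (is.raw(r$payload)) r$payload else charToRaw(r$payload)
    c(uint32_raw(length(id_raw)), id_raw, uint32_raw(r$worker_id),
      uint32_raw(length(payload_raw)), payload_raw)
  })
  if (length(parts) == 0L) raw(0) else unlist(parts, use.names = FALSE)
}

unframe_records <- function(stream) {
  pos <- 1L
  out <- list()
  while (pos <= length(stream)) {
    id_len <- read_uint32(stream, pos); pos <- pos + 4L
    qid <- rawToChar(stream[pos:(pos + id_len - 1L)]); pos <- pos + id_len
    wid <- read_uint32(stream, pos); pos <- pos + 4L
    p_len <- read_uint32(stream, pos); pos <- pos + 4L
    payload <- if (p_len > 0L) rawToChar(stream[pos:(pos + p_len - 1L)])
               else ""
    pos <- pos + p_len
    out[[length(out) + 1L]] <- list(query_id = qid, worker_id = wid,
                                    payload = payload)
  }
  out
}

write_block <- function(store, block) {
  raw_stream <- frame_records(block$records)
  checksum <- crc32(raw_stream)
  compressed <- store$config$compression
  stored <- if (compressed) memCompress(raw_stream, type = "gzip")
            else raw_stream
  dir <- shard_for(block$seq, store$config)
  path <- file.path(dir, sprintf("block-%06d.blk", block$seq))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(BLOCK_MAGIC, con)
  writeBin(BLOCK_VERSION, con)
  writeBin(uint32_raw(block$seq), con)
  writeBin(uint32_raw(block$worker_id), con)
  writeBin(uint32_raw(length(raw_stream)), con)
  writeBin(uint32_raw(length(stored)), con)
  writeBin(uint32_raw(checksum %% 2^31), con)
  writeBin(uint32_raw(checksum %/% 2^31), con)
  writeBin(as.raw(as.integer(compressed)), con)
  if (length(stored)) writeBin(stored, con)
  list(seq = block$seq, path = path,
       record_count = length(block$records),
       query_ids = vapply(block$records, `[[`, character(1), "query_id"),
       checksum = checksum, compressed = compressed,
       raw_size = length(raw_stream))
}

read_block_file <- function(path) {
  if (!file.exists(path)) stop("missing shard file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 30L)
  if (length(header) < 30L || !identical(header[1:4], BLOCK_MAGIC))
    stop("not a block file: ", path)
  seq <- read_uint32(header, 6L)
  worker_id <- read_uint32(header, 10L)
  raw_size <- read_uint32(header, 14L)
  stored_size <- read_uint32(header, 18L)
  checksum <- read_uint32(header, 22L) + read_uint32(header, 26L) * 2^31
  flags <- as.integer(header[[30L]])
  stored <- readBin(con, "raw", n = stored_size)
  if (length(stored) != stored_size) stop("truncated block file: ", path)
  stream <- if (bitwAnd(flags, 1L))
    memDecompress(stored, type = "gzip") else stored
  if (length(stream) != raw_size || crc32(stream) != checksum)
    stop("checksum mismatch in block file: ", path)
  list(seq = seq, worker_id = worker_id, records = unframe_records(stream),
       raw_size = raw_size, compressed = bitwAnd(flags, 1L) == 1L,
       checksum = checksum)
}

#' Append one output record to the store
#'
#' The record joins the current in-memory block. When the block's occupancy
#' reaches `flush_threshold * block_capacity` it is sealed and handed to the
#' background flusher and a fresh block starts; the append itself never
#' waits for a flush.
#'
#' @param store An open [open_store()] handle.
#' @param worker_id Producing worker id.
#' @param query_id The record's query id.
#' @param payload Record content (character or raw).
#' @return Invisibly, the store.
#' @export
append_record <- function(store, worker_id, query_id, payload) {
  stopifnot(inherits(store, "run_store"))
  if (store$finalized) stop("append after finalize")
  size <- if (is.raw(payload)) length(payload)
          else nchar(payload, type = "bytes")
  if (size > store$config$block_capacity)
    stop("oversize record (", size, " bytes > block capacity ",
         store$config$block_capacity, ")")
  if (length(store$flush_queue) > 0L)
    store$stats$appends_while_flush_pending <-
      store$stats$appends_while_flush_pending + 1L
  store$cur_records[[length(store$cur_records) + 1L]] <-
    list(query_id = query_id, worker_id = as.integer(worker_id),
         payload = payload)
  store$cur_bytes <- store$cur_bytes + size
  store$stats$appends <- store$stats$appends + 1L
  if (store$cur_bytes >=
      store$config$flush_threshold * store$config$block_capacity)
    seal_block(store, worker_id)
  pump_flusher(store)  # off the append path; a paused flusher blocks nothing
  invisible(store)
}

#' Record a per-query failure
#'
#' @param store An open store.
#' @param query_id Failed query id.
#' @param reason Failure description.
#' @return Invisibly, the store.
#' @export
append_failure <- function(store, query_id, reason) {
  stopifnot(inherits(store, "run_store"))
  if (store$finalized) stop("append after finalize")
  store$failures[[length(store$failures) + 1L]] <-
    list(query_id = query_id, reason = as.character(reason))
  invisible(store)
}

#' Finalize a store and write its manifest
#'
#' Seals and flushes any partial block, drains the flusher, and writes the
#' run manifest (JSON) beside the shards. The manifest is the authority for
#' reassembly and verification. A second finalize is an error.
#'
#' @param store An open store.
#' @return The `run_manifest` (invisibly written to
#'   `config$manifest_path`).
#' @export
finalize_store <- function(store) {
  stopifnot(inherits(store, "run_store"))
  if (store$finalized) stop("store already finalized")
  seal_block(store, worker_id = 0L)
  store$flusher_paused <- FALSE
  pump_flusher(store)
  store$finalized <- TRUE
  entries <- store$entries
  manifest <- structure(list(
    run_id = store$run_id,
    config = list(shard_dirs = store$config$shard_dirs,
                  block_capacity = store$config$block_capacity,
                  flush_threshold = store$config$flush_threshold,
                  compression = store$config$compression),
    blocks = entries,
    failures = store$failures,
    totals = list(records = sum(vapply(entries, `[[`, 1L, "record_count")),
                  blocks = length(entries),
                  failures = length(store$failures)),
    stats = store$stats,
    log = store$log),
    class = "run_manifest")
  write_manifest(manifest, store$config$manifest_path)
  manifest
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  attr(manifest, "path") <- path
  invisible(manifest)
}

#' Read a run manifest from disk
#'
#' @param path Path to a `manifest.json` written by [finalize_store()].
#' @return A `run_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$blocks <- lapply(m$blocks, function(b) {
    b$query_ids <- as.character(unlist(b$query_ids))
    b
  })
  structure(m, class = "run_manifest", path = path)
}

#' Compress / decompress an output block
#'
#' Block-level DEFLATE compression as used by the background flusher,
#' exposed directly. The raw-payload checksum is preserved so a round trip
#' is verifiable: `decompress_block(compress_block(b))` reproduces the raw
#' payload bytes exactly.
#'
#' @param block A list with `payload` (raw vector), logical `compressed`,
#'   and `checksum` (CRC-32 of the raw payload; computed if missing).
#' @return The block with `payload` (de)compressed and `compressed` flipped.
#' @export
compress_block <- function(block) {
  stopifnot(is.raw(block$payload))
  if (isTRUE(block$compressed)) stop("block already compressed")
  if (is.null(block$checksum)) block$checksum <- crc32(block$payload)
  if (crc32(block$payload) != block$checksum)
    stop("checksum mismatch on compress")
  block$raw_size <- length(block$payload)
  block$payload <- memCompress(block$payload, type = "gzip")
  block$compressed <- TRUE
  block
}

#' @rdname compress_block
#' @export
decompress_block <- function(block) {
  stopifnot(is.raw(block$payload))
  if (!isTRUE(block$compressed)) stop("block is not compressed")
  raw <- tryCatch(memDecompress(block$payload, type = "gzip"),
                  error = function(e) stop("corrupted compressed payload: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.null(block$checksum) && crc32(raw) != block$checksum)
    stop("checksum error on decompress")
  block$payload <- raw
  block$compressed <- FALSE
  block
}

#' Reassemble a run's records in canonical order
#'
#' Reads every block the manifest references (verifying checksums,
#' decompressing as needed) and emits all records sorted by query id — the
#' canonical order, independent of shard count, block capacity, compression
#' and worker count.
#'
#' @param manifest A `run_manifest` or path to one.
#' @return Data frame with `query_id`, `worker_id`, `payload`, sorted by
#'   `query_id`.
#' @export
reassemble <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  recs <- list()
  for (entry in manifest$blocks) {
    block <- read_block_file(entry$path)
    if (block$checksum != entry$checksum)
      stop("manifest/block checksum disagreement for ", entry$path)
    recs <- c(recs, block$records)
  }
  if (length(recs) == 0L)
    return(data.frame(query_id = character(0), worker_id = integer(0),
                      payload = character(0), stringsAsFactors = FALSE))
  out <- data.frame(
    query_id = vapply(recs, `[[`, character(1), "query_id"),
    worker_id = vapply(recs, `[[`, 1L, "worker_id"),
    payload = vapply(recs, function(r)
      if (is.raw(r$payload)) rawToChar(r$payload) else r$payload,
      character(1)),
    stringsAsFactors = FALSE)
  out[order(out$query_id), , drop = FALSE]
}

#' Verify a run against its expected query set
#'
#' Passes iff the query ids across result blocks and failure entries cover
#' `expected_query_ids` exactly once and every referenced block file exists
#' with a verifying checksum.
#'
#' @param manifest A `run_manifest` or path.
#' @param expected_query_ids Character vector of input query ids.
#' @return A `verify_report` list: `pass`, `missing`, `duplicated`,
#'   `unexpected`, `corrupt` (paths), `n_records`, `n_failures`.
#' @export
verify_run <- function(manifest, expected_query_ids) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  seen <- unlist(lapply(manifest$blocks, `[[`, "query_ids"))
  seen <- c(seen, vapply(manifest$failures, `[[`, character(1), "query_id"))
  corrupt <- character(0)
  for (entry in manifest$blocks) {
    ok <- tryCatch({
      b <- read_block_file(entry$path)
      b$checksum == entry$checksum
    }, error = function(e) FALSE)
    if (!ok) corrupt <- c(corrupt, entry$path)
  }
  seqs <- vapply(manifest$blocks, function(b) as.numeric(b$seq), numeric(1))
  dup_seq <- any(duplicated(seqs))
  missing <- setdiff(expected_query_ids, seen)
  duplicated_ids <- unique(seen[duplicated(seen)])
  unexpected <- setdiff(seen, expected_query_ids)
  structure(list(
    pass = length(missing) == 0L && length(duplicated_ids) == 0L &&
      length(unexpected) == 0L && length(corrupt) == 0L && !dup_seq,
    missing = missing, duplicated = duplicated_ids,
    unexpected = unexpected, corrupt = corrupt,
    n_records = length(seen) - length(manifest$failures),
    n_failures = length(manifest$failures)),
    class = "verify_report")
}

#' @export
print.verify_report <- function(x, ...) {
  cat("verification:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  records:", x$n_records, " failures:", x$n_failures, "\n")
  for (f in c("missing", "duplicated", "unexpected", "corrupt"))
    if (length(x[[f]]))
      cat("  ", f, ": ", paste(x[[f]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
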