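# Two-stage buffered output store: thresholds, sharding, compression,
# manifest reassembly and verification.

test_that("store config validation and directory setup", {
  cfg <- tmp_store_config(D = 3L)
  store <- open_store(cfg)
  expect_true(all(dir.exists(cfg$shard_dirs)))
  expect_length(list.files(cfg$shard_dirs[[1L]]), 0L)
  # a run with zero records still finalizes to a valid, empty manifest
  m0 <- finalize_store(store)
  expect_equal(m0$totals$records, 0L)
  expect_equal(m0$totals$blocks, 0L)
  expect_true(verify_run(m0, character(0))$pass)
  expect_equal(nrow(reassemble(m0)), 0L)
  expect_error(store_config("d", flush_threshold = 0), "flush_threshold")
  expect_error(store_config("d", block_capacity = 0), "block_capacity")
  expect_error(store_config(character(0)), "at least one")
})

test_that("no backing-store writes before the flush threshold", {
  cfg <- tmp_store_config(D = 2L, block_capacity = 1000, flush_threshold = 0.9)
  store <- open_store(cfg)
  for (i in 1:8) append_record(store, 1L, sprintf("q%02d", i),
                               strrep("x", 100))  # 800 bytes total
  expect_length(list.files(dirname(cfg$shard_dirs[[1L]]), recursive = TRUE,
                           pattern = "\\.blk$"), 0L)
  # crossing 900 bytes seals exactly one block
  append_record(store, 1L, "q09", strrep("x", 150))
  blks <- list.files(dirname(cfg$shard_dirs[[1L]]), recursive = TRUE,
                     pattern = "\\.blk$")
  expect_length(blks, 1L)
  # all nine records were in the sealed block; finalize adds nothing new
  m <- finalize_store(store)
  expect_equal(m$totals$records, 9L)
  expect_equal(m$totals$blocks, 1L)
})

test_that("oversize records and post-finalize appends are rejected", {
  cfg <- tmp_store_config(block_capacity = 1000)
  store <- open_store(cfg)
  expect_error(append_record(store, 1L, "big", strrep("x", 1200)),
               "oversize")
  append_record(store, 1L, "ok", "payload")
  m <- finalize_store(store)
  expect_equal(m$totals$records, 1L)
  expect_error(append_record(store, 1L, "late", "x"), "after finalize")
  expect_error(finalize_store(store), "already finalized")
})

test_that("appends never wait on the flusher (instrumented)", {
  cfg <- tmp_store_config(block_capacity = 100, flush_threshold = 0.5)
  store <- open_store(cfg)
  store$flusher_paused <- TRUE   # hold the background stage artificially
  for (i in 1:20) append_record(store, 1L, sprintf("q%02d", i),
                                strrep("y", 30))
  # several blocks sealed, none written, appends kept landing
  expect_gt(length(store$flush_queue), 0L)
  expect_gt(store$stats$appends_while_flush_pending, 0L)
  expect_equal(store$stats$appends, 20L)
  expect_length(list.files(dirname(cfg$shard_dirs[[1L]]), recursive = TRUE,
                           pattern = "\\.blk$"), 0L)
  m <- finalize_store(store)  # finalize drains the queue
  expect_equal(m$totals$records, 20L)
  expect_equal(verify_run(m, sprintf("q%02d", 1:20))$pass, TRUE)
})

test_that("shard_for is deterministic round-robin", {
  cfg <- store_config(c("a", "b", "c"))
  expect_equal(shard_for(7, cfg), "b")
  dirs <- vapply(0:9, shard_for, "", config = cfg)
  expect_equal(as.vector(table(dirs)[c("a", "b", "c")]), c(4L, 3L, 3L))
  expect_true(all(vapply(0:9, shard_for, "",
                         config = store_config("only")) == "only"))
})

test_that("block compression round-trips byte-identically", {
  withr::local_seed(37)
  for (rep in 1:20) {
    payload <- as.raw(sample(0:255, sample(0:5000, 1), replace = TRUE))
    block <- list(seq = rep, worker_id = 1L, payload = payload,
                  compressed = FALSE)
    cb <- compress_block(block)
    expect_true(cb$compressed)
    back <- decompress_block(cb)
    expect_identical(back$payload, payload)
    expect_equal(back$checksum, crc32(payload))
  }
  # compressible payload actually shrinks
  motif <- charToRaw(strrep("ACDEFGHIKLMNPQRSTVWY", 512))
  cb <- compress_block(list(payload = motif, compressed = FALSE))
  expect_lt(length(cb$payload), length(motif))
  # corrupted compressed payload fails on decompress
  bad <- cb
  bad$payload[5:8] <- as.raw(0L)
  expect_error(decompress_block(bad), "corrupt|checksum")
})

test_that("storage transparency: stream independent of D, capacity, compression", {
  withr::local_seed(43)
  records <- lapply(1:40, function(i)
    list(worker = (i %% 3L) + 1L, qid = sprintf("q%03d", i),
         payload = paste0(sprintf("q%03d", i), "\tsubj\t", i, "\t0\t5\t0\t5\thit")))
  run_store_with <- function(D, capacity, compression) {
    cfg <- tmp_store_config(D = D, block_capacity = capacity,
                            compression = compression)
    store <- open_store(cfg)
    for (r in records) append_record(store, r$worker, r$qid, r$payload)
    record_view(finalize_store(store))
  }
  base <- run_store_with(1L, 1e6, FALSE)
  expect_equal(run_store_with(4L, 1e6, FALSE), base)
  expect_equal(run_store_with(4L, 200, FALSE), base)
  expect_equal(run_store_with(1L, 200, TRUE), base)
  expect_equal(run_store_with(4L, 150, TRUE), base)
})

test_that("reassemble verifies checksums and notices missing shards", {
  cfg <- tmp_store_config(D = 2L, block_capacity = 100,
                          flush_threshold = 0.5)
  store <- open_store(cfg)
  for (i in 1:10) append_record(store, 1L, sprintf("q%02d", i),
                                strrep("z", 40))
  m <- finalize_store(store)
  expect_gt(m$totals$blocks, 1L)
  r <- reassemble(m)
  expect_equal(r$query_id, sprintf("q%02d", 1:10))
  # manifest read back from disk gives the same stream
  m2 <- read_manifest(cfg$manifest_path)
  expect_equal(record_view(m2), record_view(m))
  # delete one shard file: reassemble errors naming it
  victim <- m$blocks[[2L]]$path
  unlink(victim)
  expect_error(reassemble(m), basename(victim))
  expect_false(verify_run(m, sprintf("q%02d", 1:10))$pass)
})

test_that("verify_run reports missing, duplicated and unexpected ids", {
  cfg <- tmp_store_config()
  store <- open_store(cfg)
  for (i in 1:5) append_record(store, 1L, sprintf("q%d", i), "line")
  append_failure(store, "q6", "kernel exploded")
  m <- finalize_store(store)
  expect_true(verify_run(m, sprintf("q%d", 1:6))$pass)
  expect_equal(verify_run(m, sprintf("q%d", 1:6))$n_failures, 1L)

  rep_missing <- verify_run(m, sprintf("q%d", 1:7))
  expect_false(rep_missing$pass)
  expect_equal(rep_missing$missing, "q7")

  rep_unexpected <- verify_run(m, sprintf("q%d", 1:5))
  expect_false(rep_unexpected$pass)
  expect_equal(rep_unexpected$unexpected, "q6")

  # duplicated id across blocks
  cfg2 <- tmp_store_config()
  store2 <- open_store(cfg2)
  append_record(store2, 1L, "dup", "a")
  append_record(store2, 2L, "dup", "b")
  m2 <- finalize_store(store2)
  rep_dup <- verify_run(m2, "dup")
  expect_false(rep_dup$pass)
  expect_equal(rep_dup$duplicated, "dup")
})
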