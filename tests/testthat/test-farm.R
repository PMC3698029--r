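# End-to-end farm runs: exactly-once delivery, serial equivalence,
# one-reader discipline, failure policy.

make_fixture <- function(n_queries = 8L, n_db = 12L, seed = 100L) {
  list(queries = gen_database(n_queries, c(20L, 60L), seed = seed + 1L),
       img = build_db_image(gen_database(n_db, c(20L, 60L), seed = seed)))
}

test_that("a farm run processes every query exactly once into the store", {
  fx <- make_fixture()
  m <- run_farm(farm_config(workers = 2L, batch_size = 3L),
                fx$queries, fx$img, farm_tool("aligner"),
                tmp_store_config())
  expect_equal(m$totals$records, 8L)
  expect_equal(m$totals$failures, 0L)
  r <- reassemble(m)
  expect_setequal(r$query_id, fx$queries$id)
  expect_false(any(duplicated(r$query_id)))
  expect_true(verify_run(m, fx$queries$id)$pass)
  # broadcast bookkeeping: master + 2 workers => 2 messages
  expect_equal(m$broadcast$messages, 2L)
  # schedule log has one assign and one complete per batch
  expect_equal(sum(grepl("^assign", m$log)), 3L)
  expect_equal(sum(grepl("^complete", m$log)), 3L)
  expect_error(run_farm(farm_config(), empty_set <- seq_set(character(0),
                                                            character(0)),
                        fx$img, farm_tool("aligner"), tmp_store_config()),
               "non-empty")
})

test_that("record sets are invariant to workers, batch size and depth", {
  fx <- make_fixture(n_queries = 12L)
  oracle <- record_view(run_farm(farm_config(workers = 1L, batch_size = 12L,
                                             prefetch_depth = 0L),
                                 fx$queries, fx$img, farm_tool("aligner"),
                                 tmp_store_config()))
  withr::local_seed(61)
  for (rep in 1:6) {
    cfg <- farm_config(workers = sample(1:8, 1),
                       batch_size = sample(1:16, 1),
                       prefetch_depth = sample(0:3, 1))
    got <- record_view(run_farm(cfg, fx$queries, fx$img,
                                farm_tool("aligner"), tmp_store_config()))
    expect_equal(got, oracle,
                 info = sprintf("workers=%d batch=%d depth=%d",
                                cfg$workers, cfg$batch_size,
                                cfg$prefetch_depth))
  }
})

test_that("the backing store is read exactly once regardless of workers", {
  db <- gen_database(30, c(30L, 80L), seed = 55)
  f <- withr::local_tempfile(fileext = ".img")
  save_db_image(build_db_image(db), f)
  queries <- gen_database(10, 40L, seed = 56)
  for (W in c(1L, 4L)) {
    m <- run_farm(farm_config(workers = W, batch_size = 2L),
                  queries, f, farm_tool("aligner"), tmp_store_config())
    expect_equal(m$db_reads, 1L)
    expect_equal(m$broadcast$messages, W)  # image reached all W workers
    expect_true(verify_run(m, queries$id)$pass)
  }
})

test_that("a kernel failure on one query is recorded and the run continues", {
  fx <- make_fixture()
  poison <- fx$queries$id[[3L]]
  flaky <- farm_tool("custom", fn = function(q, db, params) {
    if (q$id[[1L]] == poison) stop("synthetic kernel fault")
    paste(q$id[[1L]], "-", 1, 0, 1, 0, 1, "hit", sep = "\t")
  })
  m <- run_farm(farm_config(workers = 2L, batch_size = 3L),
                fx$queries, fx$img, flaky, tmp_store_config())
  expect_equal(m$totals$records, 7L)
  expect_equal(m$totals$failures, 1L)
  expect_equal(m$failures[[1L]]$query_id, poison)
  expect_match(m$failures[[1L]]$reason, "synthetic kernel fault")
  # results + failures still cover the input exactly once
  expect_true(verify_run(m, fx$queries$id)$pass)
})

test_that("profiler kernel runs end to end under the farm", {
  fx <- make_fixture(n_queries = 6L)
  model <- gen_profile_model(10, seed = 4)
  m <- run_farm(farm_config(workers = 3L, batch_size = 2L),
                fx$queries, fx$img,
                farm_tool("profiler", model = model, threshold = -Inf),
                tmp_store_config())
  tab <- hits_to_table(reassemble(m))
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$subject_id == model$name))
  # scan scores equal direct calls on the same queries
  for (i in seq_len(nrow(fx$queries))) {
    q <- fx$queries[i, , drop = FALSE]; class(q) <- c("seq_set", "data.frame")
    direct <- profile_scan(q, model, threshold = -Inf)
    expect_equal(tab$score[tab$query_id == q$id], direct$score,
                 tolerance = 1e-6)
  }
})

test_that("run configurations load from YAML with documented defaults", {
  dir <- withr::local_tempdir()
  qf <- file.path(dir, "q.fasta"); dbf <- file.path(dir, "db.fasta")
  write_fasta(gen_database(6, 30L, seed = 1), qf)
  write_fasta(gen_database(8, 30L, seed = 2), dbf)
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(
    workers = 2L, batch_size = 2L, seed = 9L,
    tool = list(name = "aligner", match = 3, mismatch = -2, gap = -3),
    queries = qf, database = dbf,
    store = list(root = file.path(dir, "out"), n_shards = 2L,
                 compression = TRUE)), cfg_path)
  rc <- load_run_config(cfg_path)
  expect_equal(rc$config$workers, 2L)
  expect_equal(rc$config$prefetch_depth, 1L)  # default
  expect_equal(rc$tool$params$scheme$match, 3)
  expect_true(rc$store_config$compression)
  m <- run_farm(rc$config, read_fasta(rc$queries_path),
                build_db_image(read_fasta(rc$database_path)),
                rc$tool, rc$store_config)
  expect_true(verify_run(m, read_fasta(qf)$id)$pass)
  expect_error(load_run_config(file.path(dir, "nope.yaml")), "no such")
})
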