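# Alignment and profile-scan kernels against independent oracles.

test_that("the DP oracle itself matches exhaustive enumeration on tiny strings", {
  withr::local_seed(3)
  for (rep in 1:25) {
    a <- random_aa(sample(0:6, 1))
    b <- random_aa(sample(1:6, 1))
    expect_equal(sw_dp_oracle(a, b), sw_enum_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("sw_score agrees with the independent DP oracle", {
  expect_equal(sw_score("AAAA", "AAAA")$score, 8)
  expect_equal(sw_score("", "ACDE")$score, 0)
  expect_equal(sw_score("ACGT", "AGT")$score, 4)
  expect_error(sw_score("AB1", "ACD"), "invalid residues")

  withr::local_seed(41)
  for (rep in 1:200) {
    a <- random_aa(sample(1:40, 1))
    b <- random_aa(sample(1:40, 1))
    got <- sw_score(a, b)
    expect_equal(got$score, sw_dp_oracle(a, b), info = paste(a, b))
    # symmetry and the self-alignment identity
    expect_equal(got$score, sw_score(b, a)$score)
  }
  for (rep in 1:20) {
    a <- random_aa(sample(1:30, 1))
    expect_equal(sw_score(a, a)$score, 2 * nchar(a))
  }
})

test_that("sw_score spans delimit the aligned local region", {
  withr::local_seed(51)
  for (rep in 1:50) {
    a <- random_aa(sample(5:30, 1)); b <- random_aa(sample(5:30, 1))
    r <- sw_score(a, b)
    expect_true(r$q_span[2] >= r$q_span[1] && r$q_span[1] >= 0)
    expect_true(r$q_span[2] <= nchar(a) && r$s_span[2] <= nchar(b))
    if (r$score > 0) {
      # the aligned substrings alone reproduce the score
      sub_a <- substr(a, r$q_span[1] + 1L, r$q_span[2])
      sub_b <- substr(b, r$s_span[1] + 1L, r$s_span[2])
      expect_equal(sw_dp_oracle(sub_a, sub_b), r$score)
    }
  }
})

test_that("sw_search ranking equals the brute-force all-pairs sort", {
  withr::local_seed(13)
  db <- random_seq_set(10, c(8L, 25L))
  img <- build_db_image(db)
  scheme <- scoring_scheme(2, -1, -2)
  for (rep in 1:10) {
    q <- seq_set("qq", random_aa(sample(8:25, 1)))
    hits <- sw_search(q, img, scheme, top_k = 10L, min_score = 0)
    scores <- vapply(db$residues, function(s)
      sw_dp_oracle(q$residues, s), numeric(1))
    oracle <- data.frame(subject_id = db$id, score = unname(scores))
    oracle <- oracle[order(-oracle$score, oracle$subject_id), ]
    expect_equal(hits$subject_id, oracle$subject_id)
    expect_equal(hits$score, oracle$score)
  }
  # exact self-match ranks first at len * match
  q <- seq_set("self", db$residues[[4L]])
  top <- sw_search(q, img, scheme, top_k = 1L)
  expect_equal(top$subject_id, db$id[[4L]])
  expect_equal(top$score, 2 * db$length[[4L]])
  # min_score above everything: empty
  expect_equal(nrow(sw_search(q, img, scheme, min_score = 1e6)), 0L)
  expect_error(sw_search(q, img, scheme, top_k = 0L), "top_k")
})

test_that("profile_scan equals the brute-force window oracle", {
  withr::local_seed(29)
  for (rep in 1:200) {
    L <- sample(2:8, 1)
    model <- gen_profile_model(L, seed = rep)
    q <- random_aa(sample(L:40, 1))
    got <- profile_scan(q, model, threshold = -Inf)
    oracle <- pwm_oracle(q, model$weights, model$alphabet)
    expect_equal(got$score, oracle$score, tolerance = 1e-12)
    expect_equal(got$q_start, oracle$offset)
    expect_equal(got$q_end, oracle$offset + L)
  }
})

test_that("profile_scan applies threshold, short-query and argmax rules", {
  model <- gen_profile_model(5, seed = 2)
  # a query made of the per-column argmax residues scores the row-max sum
  letters <- strsplit(model$alphabet, "")[[1L]]
  best_q <- paste(letters[apply(model$weights, 1, which.max)], collapse = "")
  r <- profile_scan(best_q, model, threshold = -Inf)
  expect_equal(r$score, sum(apply(model$weights, 1, max)), tolerance = 1e-12)
  expect_equal(r$status, "hit")
  # query shorter than the model: a no-hit, not an error
  short <- profile_scan("ACD", model)
  expect_equal(short$status, "no-hit")
  # threshold above the best window: no-hit
  high <- profile_scan(best_q, model, threshold = r$score + 1)
  expect_equal(high$status, "no-hit")
})

test_that("profile models round-trip through their text format", {
  m <- gen_profile_model(7, name = "dom7", seed = 5)
  f <- withr::local_tempfile()
  write_profile_model(m, f)
  back <- read_profile_model(f)
  expect_equal(back$name, "dom7")
  expect_equal(back$length, 7L)
  expect_equal(unname(back$weights), unname(m$weights), tolerance = 1e-12)
})

test_that("kernels behind tool_io write one record per query, deterministically", {
  withr::local_seed(19)
  db <- random_seq_set(12, c(10L, 40L))
  img <- build_db_image(db)
  batch <- random_seq_set(4, c(10L, 30L))

  run_once <- function() {
    cfg <- tmp_store_config()
    store <- open_store(cfg)
    io <- open_tool_io(img, batch, store, worker_id = 1L, batch_id = 0L)
    tool_run_batch(farm_tool("aligner"), io)
    io$close()
    reassemble(finalize_store(store))
  }
  r1 <- run_once(); r2 <- run_once()
  expect_equal(nrow(r1), 4L)
  expect_setequal(r1$query_id, batch$id)
  expect_identical(r1$payload, r2$payload)  # byte-identical records

  # profiler kernel: all queries shorter than the model yield no-hit records
  model <- gen_profile_model(50, seed = 1)
  cfg <- tmp_store_config()
  store <- open_store(cfg)
  io <- open_tool_io(img, batch, store, 1L, 0L)
  tool_run_batch(farm_tool("profiler", model = model), io)
  io$close()
  recs <- reassemble(finalize_store(store))
  expect_equal(nrow(recs), 4L)
  expect_true(all(grepl("no-hit$", recs$payload)))

  expect_error(farm_tool("blast"), "unknown kernel")
})

test_that("tool_io isolates the kernel from the filesystem", {
  # build, persist, preload, then DELETE the backing file: the kernel can
  # only be reading through the in-memory endpoints
  db <- gen_database(6, 30, seed = 8)
  f <- tempfile(fileext = ".img")
  save_db_image(build_db_image(db), f)
  img <- preload_image(f)
  unlink(f)
  batch <- gen_database(3, 25, seed = 9)
  cfg <- tmp_store_config()
  store <- open_store(cfg)
  io <- open_tool_io(img, batch, store, 1L, 0L)
  expect_equal(nrow(parse_fasta(io$read_queries())), 3L)
  tool_run_batch(farm_tool("aligner"), io)
  expect_equal(io$close(), 3L)
  expect_error(io$write_record("q", "x"), "after close")
  expect_error(io$close(), "already closed")
  m <- finalize_store(store)
  expect_equal(m$totals$records, 3L)
})
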