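# Independent oracles used across the suite. These deliberately share no
# code with the implementation: the DP oracle is plain R, the enumeration
# oracle is brute-force recursion, the schedule optimum is exhaustive.

# Plain-R dynamic-programming oracle for the best local alignment score
# (linear gaps). Validated against sw_enum_oracle on tiny strings.
sw_dp_oracle <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  n <- nchar(a); m <- nchar(b)
  if (n == 0L || m == 0L) return(0)
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- H[i, j] + if (av[[i]] == bv[[j]]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, sub, H[i, j + 1L] + gap, H[i + 1L, j] + gap)
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# Exhaustive enumeration oracle: the best local score is the maximum, over
# all substring pairs, of the best all-consuming alignment of the pair,
# floored at 0 (the empty alignment). Exponential; only for lengths <= 6.
sw_enum_oracle <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  galign <- function(x, y) {
    nx <- nchar(x); ny <- nchar(y)
    if (nx == 0L) return(ny * gap)
    if (ny == 0L) return(nx * gap)
    d <- if (substr(x, 1, 1) == substr(y, 1, 1)) match else mismatch
    max(galign(substr(x, 2, nx), substr(y, 2, ny)) + d,
        galign(substr(x, 2, nx), y) + gap,
        galign(x, substr(y, 2, ny)) + gap)
  }
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na)
    for (j1 in seq_len(nb)) for (j2 in j1:nb)
      best <- max(best, galign(substr(a, i1, i2), substr(b, j1, j2)))
  best
}

# Brute-force sliding-window oracle for profile scanning.
pwm_oracle <- function(query, weights, alphabet) {
  letters <- strsplit(alphabet, "")[[1L]]
  qv <- strsplit(query, "")[[1L]]
  L <- nrow(weights); n <- length(qv)
  if (n < L) return(NULL)
  scores <- vapply(0:(n - L), function(o) {
    sum(vapply(seq_len(L), function(i)
      weights[i, match(qv[[o + i]], letters)], numeric(1)))
  }, numeric(1))
  list(score = max(scores), offset = which.max(scores) - 1L)
}

# Exhaustive optimal makespan: batches are independent, so the optimum is
# the best max-load over all worker assignments (order within a worker is
# irrelevant). Only for small instances.
optimal_makespan <- function(durations, workers) {
  nb <- length(durations)
  if (nb == 0L) return(0)
  assign <- rep(1L, nb)
  best <- Inf
  repeat {
    loads <- vapply(seq_len(workers), function(w)
      sum(durations[assign == w]), numeric(1))
    best <- min(best, max(loads))
    i <- 1L
    while (i <= nb && assign[[i]] == workers) {
      assign[[i]] <- 1L
      i <- i + 1L
    }
    if (i > nb) break
    assign[[i]] <- assign[[i]] + 1L
  }
  best
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
               replace = TRUE), collapse = "")
}

random_seq_set <- function(n, len_range = c(5L, 30L)) {
  lens <- sample(len_range[[1L]]:len_range[[2L]], n, replace = TRUE)
  seq_set(sprintf("r%03d", seq_len(n)),
          vapply(lens, random_aa, character(1)),
          desc = ifelse(seq_len(n) %% 2L == 0L,
                        sprintf("desc %d", seq_len(n)), ""))
}

# Fresh store over tempdir shards.
tmp_store_config <- function(D = 2L, ...) {
  root <- tempfile("store")
  store_config(file.path(root, sprintf("shard-%d", seq_len(D))), ...)
}

# Load a SQL dump into sqlite (via the system python, an independent SQL
# engine) and dump every cell back as one repr()'d TSV line per row.
sqlite_roundtrip <- function(sql, table_name) {
  sql_file <- tempfile(fileext = ".sql")
  writeLines(sql, sql_file, sep = "")
  out_file <- tempfile(fileext = ".tsv")
  script <- sprintf(paste0(
    "import sqlite3\n",
    "con = sqlite3.connect(':memory:')\n",
    "con.executescript(open(%s).read())\n",
    "rows = con.execute('SELECT * FROM %s ",
    "ORDER BY query_id, score DESC, subject_id').fetchall()\n",
    "with open(%s, 'w') as fh:\n",
    "    for r in rows:\n",
    "        fh.write('\\t'.join(repr(c) for c in r) + '\\n')\n"),
    shQuote(sql_file), table_name, shQuote(out_file))
  status <- system2("python", c("-c", shQuote(script)))
  stopifnot(status == 0L)
  readLines(out_file)
}

# Canonical view of a run's output for cross-config comparison.
record_view <- function(manifest) {
  r <- reassemble(manifest)
  r <- r[order(r$query_id), c("query_id", "payload")]
  rownames(r) <- NULL
  r
}
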