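# seqio: FASTA I/O, batching, and weak-scaling workload generators.

#' Construct a sequence set
#'
#' A `seq_set` is the package's in-memory collection of named amino-acid
#' sequences: a data frame with columns `id`, `desc` and `residues` plus a
#' derived `length`. Residues are uppercase letters over the 20 standard
#' amino acids plus `X`; lowercase input is upcased with a warning; `*` and
#' any other character are rejected. Ids must be unique, non-empty tokens.
#'
#' @param id Character vector of record ids.
#' @param residues Character vector of residue strings, same length as `id`.
#' @param desc Optional character vector of free-text descriptions.
#' @return A `seq_set` data frame with columns `id`, `desc`, `residues`,
#'   `length`.
#' @examples
#' seq_set(c("q1", "q2"), c("ACDE", "GGGG"))
#' @export
seq_set <- function(id, residues, desc = character(length(id))) {
  id <- as.character(id)
  residues <- as.character(residues)
  desc <- as.character(desc)
  if (length(residues) != length(id) || length(desc) != length(id))
    stop("id, residues and desc must have equal lengths")
  if (any(is.na(id)) || any(!nzchar(id)) || any(grepl("\\s", id)))
    stop("ids must be non-empty tokens without whitespace")
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate id ", dup[[1L]])
  if (any(grepl("[a-z]", residues))) {
    warning("lowercase residues upcased")
    residues <- toupper(residues)
  }
  bad <- grepl(sprintf("[^%s]", AA_ALPHABET), residues)
  if (any(bad))
    stop("invalid residue characters in record ", id[which(bad)[1L]])
  if (any(!nzchar(residues)))
    stop("record ", id[which(!nzchar(residues))[1L]], " has an empty sequence")
  out <- data.frame(id = id, desc = desc, residues = residues,
                    length = nchar(residues), stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

empty_seq_set <- function() {
  seq_set(character(0), character(0), character(0))
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", nrow(x), "record(s)\n")
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    prev <- ifelse(show$length > 30, paste0(substr(show$residues, 1, 30), "..."),
                   show$residues)
    print(data.frame(id = show$id, length = show$length, residues = prev,
                     stringsAsFactors = FALSE), row.names = FALSE)
    if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more\n")
  }
  invisible(x)
}

#' Parse FASTA text into a sequence set
#'
#' Accepts the common protein FASTA dialect: a `>` header whose first
#' whitespace separates the id from an optional description, followed by one
#' or more (possibly wrapped) sequence lines. Blank lines are ignored.
#' Duplicate ids, residues outside the amino-acid alphabet (the error names
#' the offending line), and records with no sequence are errors.
#'
#' @param text FASTA content: a character vector of lines, or a single
#'   string containing newlines, or a connection.
#' @return A [seq_set()] in file order.
#' @examples
#' parse_fasta(">q1 first\nACDE\n>q2\nGG\nGG\n")
#' @seealso [read_fasta()] for files, [write_fasta()] for the inverse.
#' @export
parse_fasta <- function(text) {
  if (inherits(text, "connection")) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- text
  n <- length(lines)
  ids <- character(0); descs <- character(0); seqs <- character(0)
  cur_id <- NULL; cur_desc <- ""; cur_chunks <- character(0); cur_line <- 0L

  flush_record <- function() {
    if (is.null(cur_id)) return()
    s <- paste(cur_chunks, collapse = "")
    if (!nzchar(s))
      stop("record ", cur_id, " (line ", cur_line, ") has an empty sequence",
           call. = FALSE)
    ids[[length(ids) + 1L]] <<- cur_id
    descs[[length(descs) + 1L]] <<- cur_desc
    seqs[[length(seqs) + 1L]] <<- s
  }

  for (i in seq_len(n)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      flush_record()
      header <- sub("^>", "", line)
      sp <- regexpr("\\s", header)
      if (sp == -1L) { cur_id <- header; cur_desc <- "" }
      else {
        cur_id <- substr(header, 1L, sp - 1L)
        cur_desc <- trimws(substr(header, sp + 1L, nchar(header)))
      }
      if (!nzchar(cur_id))
        stop("empty id in header at line ", i, call. = FALSE)
      if (cur_id %in% ids)
        stop("duplicate id ", cur_id, call. = FALSE)
      cur_chunks <- character(0); cur_line <- i
    } else {
      if (is.null(cur_id))
        stop("sequence data before any header at line ", i, call. = FALSE)
      chunk <- gsub("\\s", "", line)
      if (grepl("[a-z]", chunk)) {
        warning("lowercase residues upcased at line ", i, call. = FALSE)
        chunk <- toupper(chunk)
      }
      if (grepl(sprintf("[^%s]", AA_ALPHABET), chunk))
        stop("invalid residue character at line ", i, call. = FALSE)
      cur_chunks[[length(cur_chunks) + 1L]] <- chunk
    }
  }
  flush_record()
  seq_set(ids, seqs, descs)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  parse_fasta(readLines(path, warn = FALSE))
}

#' Write a sequence set as FASTA
#'
#' Sequence lines are wrapped at `wrap_width` residues. The output re-parses
#' (via [parse_fasta()]) to a collection identical to the input.
#'
#' @param records A [seq_set()].
#' @param sink File path or writable connection.
#' @param wrap_width Maximum residues per sequence line (default 60).
#' @return Invisibly, the number of bytes written.
#' @export
write_fasta <- function(records, sink, wrap_width = 60L) {
  stopifnot(inherits(records, "seq_set"))
  wrap_width <- as.integer(wrap_width)
  if (is.na(wrap_width) || wrap_width < 1L) stop("wrap_width must be >= 1")
  txt <- format_fasta(records, wrap_width)
  if (is.character(sink)) {
    con <- file(sink, open = "wb")
    on.exit(close(con))
  } else con <- sink
  writeBin(charToRaw(txt), con)
  invisible(nchar(txt, type = "bytes"))
}

format_fasta <- function(records, wrap_width = 60L) {
  if (nrow(records) == 0L) return("")
  pieces <- vapply(seq_len(nrow(records)), function(i) {
    header <- if (nzchar(records$desc[[i]]))
      paste0(">", records$id[[i]], " ", records$desc[[i]])
    else paste0(">", records$id[[i]])
    s <- records$residues[[i]]
    starts <- seq(1L, nchar(s), by = wrap_width)
    body <- substring(s, starts, pmin(starts + wrap_width - 1L, nchar(s)))
    paste(c(header, body), collapse = "\n")
  }, character(1))
  paste0(paste(pieces, collapse = "\n"), "\n")
}

#' Define a weak-scaling workload profile
#'
#' Encodes the workload recipes used in weak-scaling studies of wrapped
#' sequence tools, where total work grows with the core count so per-core
#' load is constant:
#' \describe{
#'   \item{aligner}{16 queries per core, each exactly 200 amino acids —
#'     the BLAST-style search workload.}
#'   \item{profiler}{760 queries per core (the "approximately 760" of the
#'     original study is fixed to exactly 760 so counts are deterministic),
#'     lengths drawn uniformly from `query_length_range`.}
#'   \item{msa}{10 datasets per core, each a family of `seqs_per_dataset`
#'     related sequences emulating the members a prior alignment search
#'     would return (a seeded ancestor with per-sequence point mutations).}
#' }
#'
#' @param tool_kind One of `"aligner"`, `"profiler"`, `"msa"`.
#' @param cores Positive integer core count the workload is sized for.
#' @param queries_per_core Queries generated per core (aligner/profiler).
#' @param query_length Exact query length in residues (aligner).
#' @param query_length_range Inclusive length range (profiler).
#' @param datasets_per_core Datasets per core (msa).
#' @param seqs_per_dataset Sequences per msa dataset.
#' @param mutation_rate Per-site substitution probability within an msa
#'   dataset (default 0.05).
#' @param seed Integer seed; identical profile + seed gives an identical
#'   bundle.
#' @return A `workload_profile` list.
#' @examples
#' workload_profile("aligner", cores = 4)
#' @export
workload_profile <- function(tool_kind = c("aligner", "profiler", "msa"),
                             cores,
                             queries_per_core = NULL,
                             query_length = 200L,
                             query_length_range = c(100L, 400L),
                             datasets_per_core = 10L,
                             seqs_per_dataset = 10L,
                             mutation_rate = 0.05,
                             seed = 1L) {
  tool_kind <- match.arg(tool_kind)
  cores <- as.integer(cores)
  if (is.na(cores) || cores < 1L) stop("cores must be a positive integer")
  if (is.null(queries_per_core))
    queries_per_core <- switch(tool_kind, aligner = 16L, profiler = 760L,
                               msa = NA_integer_)
  counts <- c(queries_per_core = queries_per_core,
              query_length = query_length,
              datasets_per_core = datasets_per_core,
              seqs_per_dataset = seqs_per_dataset)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.na(v) && v < 1L) stop(nm, " must be strictly positive")
  }
  if (query_length_range[1] < 1L || query_length_range[2] < query_length_range[1])
    stop("query_length_range must be a valid positive range")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  structure(list(tool_kind = tool_kind, cores = cores,
                 queries_per_core = as.integer(queries_per_core),
                 query_length = as.integer(query_length),
                 query_length_range = as.integer(query_length_range),
                 datasets_per_core = as.integer(datasets_per_core),
                 seqs_per_dataset = as.integer(seqs_per_dataset),
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "workload_profile")
}

random_residues <- function(n_seq, lengths) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  vapply(seq_len(n_seq), function(i) {
    paste(sample(letters20, lengths[[i]], replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a weak-scaling workload bundle
#'
#' Realizes a [workload_profile()] into concrete sequences. Counts follow the
#' profile formulas exactly: `cores * queries_per_core` queries for aligner
#' and profiler kinds, `cores * datasets_per_core` datasets for msa. The
#' generator is deterministic for a fixed profile.
#'
#' @param profile A [workload_profile()].
#' @return A list of class `workload_bundle` with elements `profile`, and
#'   either `queries` (a [seq_set()]) or, for msa, `datasets` (a list of
#'   `seq_set`s).
#' @examples
#' w <- gen_workload(workload_profile("aligner", cores = 2))
#' nrow(w$queries)  # 32
#' @export
gen_workload <- function(profile) {
  stopifnot(inherits(profile, "workload_profile"))
  out <- with_seed(derive_seed(profile$seed, paste0("workload/", profile$tool_kind)), {
    if (profile$tool_kind == "aligner") {
      n <- profile$cores * profile$queries_per_core
      lens <- rep(profile$query_length, n)
      list(queries = seq_set(sprintf("q%06d", seq_len(n)),
                             random_residues(n, lens)))
    } else if (profile$tool_kind == "profiler") {
      n <- profile$cores * profile$queries_per_core
      lens <- sample(seq(profile$query_length_range[1],
                         profile$query_length_range[2]), n, replace = TRUE)
      list(queries = seq_set(sprintf("q%06d", seq_len(n)),
                             random_residues(n, lens)))
    } else {
      n_ds <- profile$cores * profile$datasets_per_core
      datasets <- lapply(seq_len(n_ds), function(d) {
        len <- sample(seq(profile$query_length_range[1],
                          profile$query_length_range[2]), 1L)
        ancestor <- random_residues(1L, len)
        members <- vapply(seq_len(profile$seqs_per_dataset), function(k) {
          mutate_residues(ancestor, profile$mutation_rate)
        }, character(1))
        seq_set(sprintf("d%04d_s%03d", d, seq_len(profile$seqs_per_dataset)),
                members,
                desc = rep(sprintf("dataset %d", d), profile$seqs_per_dataset))
      })
      list(datasets = datasets)
    }
  })
  structure(c(list(profile = profile), out), class = "workload_bundle")
}

# Point-mutate a residue string: each site independently substituted with
# probability `rate`, drawing uniformly from the 19 other standard residues.
mutate_residues <- function(s, rate) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  chars <- strsplit(s, "")[[1L]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    repl <- vapply(chars[hit], function(c0) {
      sample(setdiff(letters20, c0), 1L)
    }, character(1))
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic reference database
#'
#' A stand-in for a real protein reference database: `n_records` sequences
#' with unique ids, lengths drawn from `length_law`, deterministic for a
#' fixed seed.
#'
#' @param n_records Number of records (>= 1).
#' @param length_law Either a single integer (fixed length) or a length-2
#'   integer vector (inclusive uniform range).
#' @param seed Integer seed.
#' @return A [seq_set()].
#' @examples
#' db <- gen_database(10, length_law = 150, seed = 7)
#' @export
gen_database <- function(n_records, length_law = c(100L, 400L), seed = 1L) {
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 1L) stop("n_records must be >= 1")
  length_law <- as.integer(length_law)
  if (!length(length_law) %in% c(1L, 2L) || any(length_law < 1L))
    stop("length_law must be one fixed length or a positive range")
  with_seed(derive_seed(seed, "database"), {
    lens <- if (length(length_law) == 1L) rep(length_law, n_records)
            else sample(seq(length_law[1], length_law[2]), n_records,
                        replace = TRUE)
    seq_set(sprintf("db%06d", seq_len(n_records)),
            random_residues(n_records, lens))
  })
}

#' Split a sequence set into dispatch batches
#'
#' Batches are the unit of dispatch in the farm: consecutive slices of the
#' input in order, all of size `batch_size` except possibly the last. Batch
#' ids are consecutive from 0 and the query ids partition the input exactly.
#'
#' @param records A [seq_set()].
#' @param batch_size Queries per batch (>= 1).
#' @return A list of `work_batch` objects (`batch_id`, `query_ids`, `state`,
#'   `assigned_worker`).
#' @examples
#' length(make_batches(gen_database(10, 50), batch_size = 4))  # 3
#' @export
make_batches <- function(records, batch_size) {
  stopifnot(inherits(records, "seq_set"))
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L) stop("batch_size must be >= 1")
  n <- nrow(records)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = batch_size)
  lapply(seq_along(starts), function(k) {
    idx <- starts[[k]]:min(starts[[k]] + batch_size - 1L, n)
    structure(list(batch_id = k - 1L, query_ids = records$id[idx],
                   state = "pending", assigned_worker = NA_integer_),
              class = "work_batch")
  })
}

#' Write a workload bundle to disk
#'
#' Aligner/profiler bundles become a single FASTA file; msa bundles a
#' directory with one FASTA per dataset. A YAML sidecar (`<name>.yaml`)
#' records the generating profile and seed for reproducibility.
#'
#' @param bundle A [gen_workload()] result.
#' @param path Output FASTA path (aligner/profiler) or directory (msa).
#' @return Invisibly, the paths written.
#' @export
write_workload <- function(bundle, path) {
  stopifnot(inherits(bundle, "workload_bundle"))
  prof <- bundle$profile
  sidecar <- unclass(prof)
  if (prof$tool_kind == "msa") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(seq_along(bundle$datasets), function(d) {
      f <- file.path(path, sprintf("dataset-%04d.fasta", d))
      write_fasta(bundle$datasets[[d]], f)
      f
    }, character(1))
    yaml::write_yaml(sidecar, file.path(path, "workload.yaml"))
    invisible(c(files, file.path(path, "workload.yaml")))
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    write_fasta(bundle$queries, path)
    side <- paste0(sub("\\.fa(sta)?$", "", path), ".yaml")
    yaml::write_yaml(sidecar, side)
    invisible(c(path, side))
  }
}
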