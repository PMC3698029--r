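# kernels: reference black-box compute kernels behind the plug-in contract.
#
# Hit record serialization (one line per hit, tab-separated):
#   query_id  subject_id  score  q_start  q_end  s_start  s_end  status
# with 0-based half-open spans and status in {hit, no-hit}. This is the
# dialect postproc::hits_to_table() parses.

#' Define a local-alignment scoring scheme
#'
#' Linear (per-residue) gap costs, not affine: this keeps the kernel exactly
#' checkable against small enumeration oracles, at the cost of diverging
#' from production aligners.
#'
#' @param match Score for a residue match (> 0).
#' @param mismatch Score for a mismatch (<= 0).
#' @param gap Score per inserted/deleted residue (< 0).
#' @return A `scoring_scheme` list.
#' @examples
#' scoring_scheme(2, -1, -2)
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap = -2) {
  if (match <= 0) stop("match score must be positive")
  if (mismatch > 0) stop("mismatch score must be <= 0")
  if (gap >= 0) stop("gap score must be negative")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

check_residues <- function(s, what = "sequence") {
  if (grepl(sprintf("[^%s]", AA_ALPHABET), s))
    stop("invalid residues in ", what)
  s
}

#' Best local alignment score between two residue strings
#'
#' Standard best-local-alignment (Smith--Waterman) dynamic programming with
#' linear gap costs. The score is 0 when either sequence is empty (the empty
#' local alignment) and is symmetric in its two sequences.
#'
#' @param a,b Residue strings (uppercase amino-acid alphabet).
#' @param scheme A [scoring_scheme()].
#' @return List with `score` and 0-based half-open spans `q_span`
#'   (`c(start, end)` in `a`) and `s_span` (in `b`).
#' @examples
#' sw_score("AAAA", "AAAA", scoring_scheme(2, -1, -2))$score  # 8
#' @export
sw_score <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  check_residues(a, "sequence a")
  check_residues(b, "sequence b")
  r <- sw_align_cpp(a, b, scheme$match, scheme$mismatch, scheme$gap)
  list(score = r$score,
       q_span = c(r$q_start, r$q_end),
       s_span = c(r$s_start, r$s_end))
}

#' Search a database image with the local-alignment kernel
#'
#' Scores the query against every database record and returns the top
#' `top_k` subjects with score at least `min_score`, sorted by score
#' descending then subject id ascending (the deterministic tie-break).
#'
#' @param query A single-record [seq_set()] or a residue string.
#' @param dbimage A [build_db_image()] result.
#' @param scheme A [scoring_scheme()].
#' @param top_k Maximum subjects returned (>= 1).
#' @param min_score Minimum score to report.
#' @return Data frame of hits: `query_id`, `subject_id`, `score`, `q_start`,
#'   `q_end`, `s_start`, `s_end` (possibly 0 rows).
#' @export
sw_search <- function(query, dbimage, scheme = scoring_scheme(),
                      top_k = 5L, min_score = 0) {
  stopifnot(inherits(dbimage, "db_image"))
  if (dbimage$record_count == 0L) stop("empty database image")
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) stop("top_k must be >= 1")
  if (inherits(query, "seq_set")) {
    stopifnot(nrow(query) == 1L)
    qid <- query$id[[1L]]; qseq <- query$residues[[1L]]
  } else {
    qid <- "query"; qseq <- as.character(query)
  }
  subjects <- image_records(dbimage)
  hits <- lapply(seq_len(nrow(subjects)), function(i) {
    r <- sw_score(qseq, subjects$residues[[i]], scheme)
    data.frame(query_id = qid, subject_id = subjects$id[[i]],
               score = r$score,
               q_start = r$q_span[[1L]], q_end = r$q_span[[2L]],
               s_start = r$s_span[[1L]], s_end = r$s_span[[2L]],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$subject_id), , drop = FALSE]
  utils::head(hits, top_k)
}

#' Construct a profile model
#'
#' A position-specific score matrix standing in for a protein domain model:
#' `L` rows of per-residue scores over the full amino-acid alphabet.
#'
#' @param name Model name.
#' @param weights Numeric `L x A` matrix; columns named by (or ordered as)
#'   `alphabet`.
#' @param alphabet Residue alphabet string (default: 20 amino acids + X).
#' @return A `profile_model`.
#' @export
profile_model <- function(name, weights, alphabet = AA_ALPHABET) {
  weights <- as.matrix(weights)
  letters <- strsplit(alphabet, "")[[1L]]
  if (ncol(weights) != length(letters))
    stop("every weight row must cover the full alphabet (",
         length(letters), " columns)")
  if (nrow(weights) < 1L) stop("model length must be >= 1")
  colnames(weights) <- letters
  structure(list(name = as.character(name), length = nrow(weights),
                 alphabet = alphabet, weights = weights),
            class = "profile_model")
}

#' Generate a random profile model
#'
#' Weights are drawn i.i.d. uniform on `[-2, 3]`, giving windows a positive
#' expected best score while keeping most offsets unremarkable.
#'
#' @param length Model length `L`.
#' @param name Model name.
#' @param seed Integer seed.
#' @return A [profile_model()].
#' @export
gen_profile_model <- function(length, name = "pm1", seed = 1L) {
  letters <- strsplit(AA_ALPHABET, "")[[1L]]
  w <- with_seed(derive_seed(seed, paste0("profile/", name)), {
    matrix(runif(length * base::length(letters), -2, 3),
           nrow = length, ncol = base::length(letters))
  })
  profile_model(name, w)
}

#' Write / read a profile model as plain text
#'
#' Format: one header line `name <TAB> L <TAB> alphabet`, then `L` rows of
#' `|alphabet|` tab-separated weights.
#'
#' @param model A [profile_model()].
#' @param path File path.
#' @return `write_profile_model`: invisibly, `path`;
#'   `read_profile_model`: a [profile_model()].
#' @export
write_profile_model <- function(model, path) {
  stopifnot(inherits(model, "profile_model"))
  con <- file(path, "w")
  on.exit(close(con))
  cat(model$name, model$length, model$alphabet, sep = "\t", file = con)
  cat("\n", file = con)
  utils::write.table(model$weights, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_model
#' @export
read_profile_model <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) != 3L) stop("malformed profile model header")
  L <- as.integer(header[[2L]])
  w <- do.call(rbind, lapply(lines[1L + seq_len(L)], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])))
  profile_model(header[[1L]], w, header[[3L]])
}

#' Scan a query with a profile model
#'
#' Slides the model over the query and scores every ungapped window: the
#' window score at offset `o` is the sum over positions `i` of
#' `weights[i, query[o + i]]`. A hit is returned iff the best window score
#' reaches `threshold`; ties go to the leftmost offset. A query shorter
#' than the model yields a no-hit (by rule, not an error).
#'
#' @param query A single-record [seq_set()] or residue string.
#' @param model A [profile_model()].
#' @param threshold Minimum reported score.
#' @return Data frame with one row (`query_id`, `subject_id`, `score`,
#'   spans, `status`); `status` is `"hit"` or `"no-hit"`.
#' @export
profile_scan <- function(query, model, threshold = 0) {
  stopifnot(inherits(model, "profile_model"))
  if (inherits(query, "seq_set")) {
    stopifnot(nrow(query) == 1L)
    qid <- query$id[[1L]]; qseq <- query$residues[[1L]]
  } else {
    qid <- "query"; qseq <- check_residues(as.character(query))
  }
  no_hit <- data.frame(query_id = qid, subject_id = model$name, score = 0,
                       q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L,
                       status = "no-hit", stringsAsFactors = FALSE)
  if (nchar(qseq) < model$length) return(no_hit)
  r <- pwm_scan_cpp(qseq, model$weights, model$alphabet)
  if (!r$found || r$score < threshold) return(no_hit)
  data.frame(query_id = qid, subject_id = model$name, score = r$score,
             q_start = r$offset, q_end = r$offset + model$length,
             s_start = 0L, s_end = model$length,
             status = "hit", stringsAsFactors = FALSE)
}

#' Declare the tool a farm run executes
#'
#' @param kernel `"aligner"` (local alignment against the broadcast
#'   database), `"profiler"` (profile scan; supply `model`), or `"custom"`
#'   (supply `fn(query, db, params)` returning a record payload).
#' @param ... Kernel parameters: `scheme`, `top_k`, `min_score` (aligner);
#'   `model`, `threshold` (profiler); `fn` (custom).
#' @return A `farm_tool`.
#' @export
farm_tool <- function(kernel, ...) {
  params <- list(...)
  known <- c("aligner", "profiler", "custom")
  if (!kernel %in% known)
    stop("unknown kernel '", kernel, "'; available: ",
         paste(known, collapse = ", "))
  if (kernel == "profiler" && !inherits(params$model, "profile_model"))
    stop("profiler kernel requires a profile_model as `model`")
  if (kernel == "custom" && !is.function(params$fn))
    stop("custom kernel requires a function as `fn`")
  structure(list(kernel = kernel, params = params), class = "farm_tool")
}

hit_lines <- function(hits, qid) {
  if (nrow(hits) == 0L)
    return(paste(qid, "-", 0, 0L, 0L, 0L, 0L, "no-hit", sep = "\t"))
  status <- if ("status" %in% names(hits)) hits$status else
    rep("hit", nrow(hits))
  paste(hits$query_id, hits$subject_id,
        format(hits$score, trim = TRUE, scientific = FALSE),
        hits$q_start, hits$q_end, hits$s_start, hits$s_end, status,
        sep = "\t")
}

#' Run a kernel over one batch through the virtual I/O contract
#'
#' The black-box discipline: the kernel obtains its queries (as FASTA text)
#' and the database only through the `tool_io` endpoints and emits exactly
#' one result record per query (possibly `no-hit`) through the output
#' endpoint — it never touches the filesystem. A kernel error on one query
#' is recorded as a failure entry for that query and the rest of the batch
#' proceeds.
#'
#' @param tool A [farm_tool()].
#' @param io An open [open_tool_io()] session.
#' @return Invisibly, the number of records written.
#' @export
tool_run_batch <- function(tool, io) {
  stopifnot(inherits(tool, "farm_tool"), inherits(io, "tool_io"))
  queries <- parse_fasta(io$read_queries())
  p <- tool$params
  per_query <- switch(tool$kernel,
    aligner = function(q, db) {
      hits <- sw_search(q, db,
                        scheme = p$scheme %||% scoring_scheme(),
                        top_k = p$top_k %||% 3L,
                        min_score = p$min_score %||% 1)
      paste(hit_lines(hits, q$id[[1L]]), collapse = "\n")
    },
    profiler = function(q, db) {
      paste(hit_lines(profile_scan(q, p$model,
                                   threshold = p$threshold %||% 0), q$id[[1L]]),
            collapse = "\n")
    },
    custom = function(q, db) p$fn(q, db, p))
  n_written <- 0L
  db <- io$read_db()
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, , drop = FALSE]
    class(q) <- c("seq_set", "data.frame")
    qid <- q$id[[1L]]
    res <- tryCatch(per_query(q, db), error = function(e) e)
    if (inherits(res, "error")) {
      io$write_failure(qid, conditionMessage(res))
    } else {
      io$write_record(qid, res)
      n_written <- n_written + 1L
    }
  }
  invisible(n_written)
}
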