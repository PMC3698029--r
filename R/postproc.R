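# postproc: raw hit records -> tab-delimited table -> SQL dump.

HIT_COLUMNS <- c("query_id", "subject_id", "score", "q_start", "q_end",
                 "s_start", "s_end", "status")

#' Parse raw hit records into a tab-delimited hit table
#'
#' Accepts the reassembled record stream of a run (the data frame from
#' [reassemble()]) or a character vector of raw record lines in the kernel
#' dialect (8 tab-separated fields). Every well-formed line becomes a row;
#' malformed lines never abort the parse — they are collected in a reject
#' list with their line numbers. Rows are ordered by query id ascending
#' then score descending.
#'
#' @param records A [reassemble()] data frame or character vector of lines.
#' @return A `hit_table` data frame with the 8 fixed columns and an
#'   attribute `rejects` (data frame `line`, `content`, `reason`).
#' @export
hits_to_table <- function(records) {
  lines <- if (is.data.frame(records)) {
    unlist(lapply(records$payload, function(p)
      strsplit(p, "\n", fixed = TRUE)[[1L]]), use.names = FALSE)
  } else if (is.character(records)) {
    unlist(strsplit(records, "\n", fixed = TRUE), use.names = FALSE)
  } else stop("records must be a data frame or character vector")
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  rejects <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 8L) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(line = i, content = lines[[i]],
                   reason = paste0("expected 8 fields, got ", length(f)),
                   stringsAsFactors = FALSE)
      next
    }
    score <- suppressWarnings(as.numeric(f[[3L]]))
    spans <- suppressWarnings(as.integer(f[4:7]))
    if (is.na(score) || anyNA(spans)) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(line = i, content = lines[[i]],
                   reason = "non-numeric score or span",
                   stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- data.frame(query_id = f[[1L]], subject_id = f[[2L]],
                            score = score, q_start = spans[[1L]],
                            q_end = spans[[2L]], s_start = spans[[3L]],
                            s_end = spans[[4L]], status = f[[8L]],
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, rows)
         else stats::setNames(
           data.frame(character(0), character(0), numeric(0), integer(0),
                      integer(0), integer(0), integer(0), character(0),
                      stringsAsFactors = FALSE), HIT_COLUMNS)
  tab <- tab[order(tab$query_id, -tab$score), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "rejects") <- if (length(rejects)) do.call(rbind, rejects)
    else data.frame(line = integer(0), content = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  class(tab) <- c("hit_table", "data.frame")
  tab
}

#' Write a hit table as TSV
#'
#' @param table A [hits_to_table()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a hit-table TSV
#'
#' @param path TSV written by [write_hit_table()].
#' @return A `hit_table` data frame.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(query_id = "character",
                                          subject_id = "character",
                                          status = "character"))
  if (!identical(names(tab), HIT_COLUMNS))
    stop("not a hit table: wrong columns in ", path)
  class(tab) <- c("hit_table", "data.frame")
  tab
}

sql_quote <- function(x) paste0("'", gsub("'", "''", x, fixed = TRUE), "'")

sql_num <- function(x) {
  ifelse(is.na(x), "NULL", format(x, trim = TRUE, scientific = FALSE,
                                  digits = 15))
}

#' Emit a hit table as a portable SQL dump
#'
#' One `CREATE TABLE` with the 8 typed columns followed by one `INSERT` per
#' row, in ANSI syntax with single-quote escaping, so the dump loads into
#' any standard SQL engine and `SELECT count(*)` returns the row count.
#'
#' @param table A `hit_table`.
#' @param table_name Legal SQL identifier (letters, digits, underscore; not
#'   starting with a digit).
#' @return A single character string of SQL text.
#' @examples
#' cat(table_to_sql(hits_to_table("q1\tdb1\t8\t0\t4\t0\t4\thit"), "hits"))
#' @export
table_to_sql <- function(table, table_name = "hits") {
  stopifnot(is.data.frame(table))
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", table_name))
    stop("illegal SQL identifier: ", table_name)
  create <- paste0(
    "CREATE TABLE ", table_name, " (\n",
    "  query_id TEXT NOT NULL,\n",
    "  subject_id TEXT NOT NULL,\n",
    "  score REAL NOT NULL,\n",
    "  q_start INTEGER NOT NULL,\n",
    "  q_end INTEGER NOT NULL,\n",
    "  s_start INTEGER NOT NULL,\n",
    "  s_end INTEGER NOT NULL,\n",
    "  status TEXT NOT NULL\n",
    ");")
  if (nrow(table) == 0L) return(paste0(create, "\n"))
  inserts <- paste0(
    "INSERT INTO ", table_name, " VALUES (",
    sql_quote(table$query_id), ", ", sql_quote(table$subject_id), ", ",
    sql_num(table$score), ", ", sql_num(table$q_start), ", ",
    sql_num(table$q_end), ", ", sql_num(table$s_start), ", ",
    sql_num(table$s_end), ", ", sql_quote(table$status), ");")
  paste0(create, "\n", paste(inserts, collapse = "\n"), "\n")
}
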