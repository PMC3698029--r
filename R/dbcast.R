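# dbcast: contiguous database image, one-reader preload, tree broadcast.
#
# Image wire format (little-endian throughout):
#   in-memory image: "SFDB" magic, version byte 0x01, uint32 record count,
#     then per record: uint32 id length, id bytes, uint32 residue length,
#     residue bytes.
#   on-disk file:    "SFIM" magic, version byte 0x01, uint32 image size,
#     uint32 CRC-32 of the image, uint32 page hint, then the image bytes.
# Index offsets are 0-based byte positions of each record's residue payload
# inside the image.

IMAGE_MAGIC <- charToRaw("SFDB")
IMAGE_FILE_MAGIC <- charToRaw("SFIM")
IMAGE_VERSION <- as.raw(1L)

uint32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                   endian = "little")
read_uint32 <- function(raw, pos) {
  readBin(raw[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
}

#' Build a contiguous database image
#'
#' Serializes a full reference collection into one contiguous byte payload
#' with a record-offset index, so that a run can hold, checksum, broadcast
#' and share the database as a single object. Serialization is deterministic:
#' identical input gives byte-identical images.
#'
#' @param records A non-empty [seq_set()].
#' @param page_hint Advisory block size in bytes recorded in the image
#'   metadata (default 2 MiB, the large-page size that benefits TLB-bound
#'   scans on machines that support it). Purely advisory: no OS page-size
#'   manipulation is attempted.
#' @return A `db_image`: list with `image` (raw), `index` (data frame of
#'   `id`, `start`, `length`; 0-based offsets of residue payloads),
#'   `record_count`, `checksum` (CRC-32 of `image`), `page_hint`, and
#'   `load_stats` (`reads`: backing-store read calls used; 0 for in-memory
#'   builds).
#' @examples
#' img <- build_db_image(gen_database(3, 50, seed = 1))
#' img$record_count
#' @export
build_db_image <- function(records, page_hint = 2L * 1024L * 1024L) {
  stopifnot(inherits(records, "seq_set"))
  if (nrow(records) == 0L) stop("cannot build an image from an empty collection")
  n <- nrow(records)
  parts <- vector("list", 3L * n + 2L)
  parts[[1L]] <- IMAGE_MAGIC
  parts[[2L]] <- c(IMAGE_VERSION, uint32_raw(n))
  pos <- 4L + 5L  # bytes so far
  starts <- integer(n); lens <- integer(n)
  for (i in seq_len(n)) {
    id_raw <- charToRaw(records$id[[i]])
    seq_raw <- charToRaw(records$residues[[i]])
    parts[[3L * i]] <- c(uint32_raw(length(id_raw)), id_raw)
    parts[[3L * i + 1L]] <- uint32_raw(length(seq_raw))
    parts[[3L * i + 2L]] <- seq_raw
    pos <- pos + 4L + length(id_raw) + 4L
    starts[[i]] <- pos
    lens[[i]] <- length(seq_raw)
    pos <- pos + length(seq_raw)
  }
  image <- unlist(parts, use.names = FALSE)
  structure(list(image = image,
                 index = data.frame(id = records$id, start = starts,
                                    length = lens, stringsAsFactors = FALSE),
                 record_count = n,
                 checksum = crc32(image),
                 page_hint = as.integer(page_hint),
                 load_stats = list(reads = 0L)),
            class = "db_image")
}

#' @export
print.db_image <- function(x, ...) {
  cat("db_image:", x$record_count, "records,", length(x$image),
      "bytes, crc32", format(x$checksum, scientific = FALSE),
      "\n  page hint:", x$page_hint, "bytes; backing-store reads:",
      x$load_stats$reads, "\n")
  invisible(x)
}

# Parse a raw image payload back into index + record count; shared by
# preload_image and broadcast receivers.
parse_image <- function(image, page_hint = 2L * 1024L * 1024L, reads = 0L) {
  if (length(image) < 9L || !identical(image[1:4], IMAGE_MAGIC))
    stop("not a database image (bad magic)")
  if (image[[5L]] != IMAGE_VERSION)
    stop("unsupported image version")
  n <- read_uint32(image, 6L)
  pos <- 10L
  ids <- character(n); starts <- integer(n); lens <- integer(n)
  for (i in seq_len(n)) {
    id_len <- read_uint32(image, pos); pos <- pos + 4L
    ids[[i]] <- rawToChar(image[pos:(pos + id_len - 1L)]); pos <- pos + id_len
    seq_len_ <- read_uint32(image, pos); pos <- pos + 4L
    starts[[i]] <- pos - 1L  # 0-based
    lens[[i]] <- seq_len_
    pos <- pos + seq_len_
    if (pos - 1L > length(image)) stop("image truncated inside record ", i)
  }
  structure(list(image = image,
                 index = data.frame(id = ids, start = starts, length = lens,
                                    stringsAsFactors = FALSE),
                 record_count = n,
                 checksum = crc32(image),
                 page_hint = as.integer(page_hint),
                 load_stats = list(reads = as.integer(reads))),
            class = "db_image")
}

#' Extract records from a database image
#'
#' @param img A `db_image`.
#' @param ids Optional record ids (default: all, in image order).
#' @return A [seq_set()].
#' @export
image_records <- function(img, ids = NULL) {
  stopifnot(inherits(img, "db_image"))
  idx <- img$index
  if (!is.null(ids)) {
    pos <- match(ids, idx$id)
    if (anyNA(pos)) stop("id not in image: ", ids[which(is.na(pos))[1L]])
    idx <- idx[pos, , drop = FALSE]
  }
  residues <- vapply(seq_len(nrow(idx)), function(i) {
    from <- idx$start[[i]] + 1L
    rawToChar(img$image[from:(from + idx$length[[i]] - 1L)])
  }, character(1))
  seq_set(idx$id, residues)
}

#' Persist a database image to a file
#'
#' @param img A `db_image`.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @seealso [preload_image()]
#' @export
save_db_image <- function(img, path) {
  stopifnot(inherits(img, "db_image"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(IMAGE_FILE_MAGIC, con)
  writeBin(IMAGE_VERSION, con)
  writeBin(uint32_raw(length(img$image)), con)
  writeBin(uint32_raw(img$checksum %% 2^31), con)  # low 31 bits
  writeBin(uint32_raw(img$checksum %/% 2^31), con) # high bit
  writeBin(uint32_raw(img$page_hint), con)
  writeBin(img$image, con)
  invisible(path)
}

#' Preload a persisted database image with one bulk read
#'
#' The whole image payload is obtained with a single bulk read call — the
#' one-reader discipline that keeps thousands of workers from hammering a
#' shared filesystem — and verified against the stored checksum.
#' `load_stats$reads` records exactly 1 payload read.
#'
#' @param path File written by [save_db_image()].
#' @return A `db_image` equal to the persisted one.
#' @export
preload_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 21L)
  if (length(header) < 21L || !identical(header[1:4], IMAGE_FILE_MAGIC))
    stop("not a database image file: ", path)
  if (header[[5L]] != IMAGE_VERSION) stop("unsupported image file version")
  size <- read_uint32(header, 6L)
  stored_crc <- read_uint32(header, 10L) + read_uint32(header, 14L) * 2^31
  page_hint <- read_uint32(header, 18L)
  image <- readBin(con, "raw", n = size)  # the single bulk payload read
  if (length(image) != size)
    stop("corrupt image file (truncated): ", path)
  if (crc32(image) != stored_crc)
    stop("corrupt image file (checksum mismatch): ", path)
  parse_image(image, page_hint = page_hint, reads = 1L)
}

#' Plan a binomial-tree broadcast
#'
#' Computes the per-round (sender, receiver) schedule that delivers one
#' payload from a root to `participants` ranks: in round `r` every rank that
#' already holds the payload sends to the rank at virtual distance `2^r`.
#' The plan has exactly `participants - 1` messages in `ceil(log2(P))`
#' rounds — the logarithmic scaling that makes whole-database replication
#' viable at large node counts.
#'
#' @param participants Integer `P >= 1`.
#' @param root Rank (0-based, `< P`) holding the payload initially.
#' @return A `broadcast_plan`: list with `participants`, `root`, `rounds`
#'   (list of data frames with `sender`, `receiver` columns).
#' @examples
#' p <- plan_broadcast(8)
#' length(p$rounds)                      # 3
#' sum(vapply(p$rounds, nrow, 1L))       # 7
#' @export
plan_broadcast <- function(participants, root = 0L) {
  participants <- as.integer(participants)
  if (is.na(participants) || participants < 1L)
    stop("participants must be >= 1")
  root <- as.integer(root)
  if (root < 0L || root >= participants) stop("root out of range")
  n_rounds <- if (participants == 1L) 0L else ceiling(log2(participants))
  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    d <- 2^(r - 1L)
    senders_v <- seq_len(min(d, participants)) - 1L      # virtual ranks < 2^(r-1)
    receivers_v <- senders_v + d
    keep <- receivers_v < participants
    # virtual rank v corresponds to actual rank (v + root) mod P
    rounds[[r]] <- data.frame(
      sender = (senders_v[keep] + root) %% participants,
      receiver = (receivers_v[keep] + root) %% participants)
  }
  structure(list(participants = participants, root = root, rounds = rounds),
            class = "broadcast_plan")
}

#' Round-synchronous in-process broadcast transport
#'
#' The reference transport: delivers each round's messages in order, within
#' a round in plan order. `transmit` may be overridden (e.g. to inject
#' corruption or failures in tests); it receives `(sender, receiver,
#' payload)` and returns the payload as delivered.
#'
#' @param transmit Delivery function; default is the identity.
#' @return A `bcast_transport` list.
#' @export
local_transport <- function(transmit = function(sender, receiver, payload) payload) {
  structure(list(transmit = transmit), class = "bcast_transport")
}

#' Execute a broadcast plan over a transport
#'
#' Walks the plan round by round; a sender must already hold the payload
#' (the root, or a receiver of an earlier round). Every delivered copy is
#' checksummed against the root's.
#'
#' @param plan A [plan_broadcast()] result.
#' @param payload A raw vector (or character scalar, converted).
#' @param transport A [local_transport()] (default) or compatible backend.
#' @return Delivery receipts: data frame with `receiver`, `round`,
#'   `checksum`, one row per non-root participant.
#' @export
execute_broadcast <- function(plan, payload, transport = local_transport()) {
  stopifnot(inherits(plan, "broadcast_plan"))
  if (is.character(payload)) payload <- charToRaw(payload)
  stopifnot(is.raw(payload))
  root_crc <- crc32(payload)
  holds <- vector("list", plan$participants)  # by rank+1
  holds[[plan$root + 1L]] <- payload
  receipts <- list()
  for (r in seq_along(plan$rounds)) {
    msgs <- plan$rounds[[r]]
    # round-synchronous: sends of this round read state from prior rounds
    delivered <- vector("list", nrow(msgs))
    for (k in seq_len(nrow(msgs))) {
      s <- msgs$sender[[k]]; v <- msgs$receiver[[k]]
      if (is.null(holds[[s + 1L]]))
        stop("transport failure on edge ", s, " -> ", v,
             ": sender does not hold the payload")
      out <- tryCatch(transport$transmit(s, v, holds[[s + 1L]]),
                      error = function(e)
                        stop("transport failure on edge ", s, " -> ", v, ": ",
                             conditionMessage(e), call. = FALSE))
      delivered[[k]] <- out
    }
    for (k in seq_len(nrow(msgs))) {
      v <- msgs$receiver[[k]]
      got <- delivered[[k]]
      got_crc <- crc32(got)
      if (got_crc != root_crc)
        stop("checksum mismatch at receiver ", v, " (round ", r, ")")
      holds[[v + 1L]] <- got
      receipts[[length(receipts) + 1L]] <-
        data.frame(receiver = v, round = r, checksum = got_crc)
    }
  }
  if (length(receipts) == 0L)
    return(data.frame(receiver = integer(0), round = integer(0),
                      checksum = double(0)))
  do.call(rbind, receipts)
}
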