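# Master-side dispatch state and the discrete-event scheduling simulator.
#
# Dispatch protocol: a worker may hold at most 1 + prefetch_depth batches
# (the one it is computing plus prefetched ones). Pending batches are handed
# out in ascending batch_id; simultaneous requests are served in ascending
# worker id. Assignments are final: a prefetched batch is never reclaimed.

#' Create a dispatch scheduler
#'
#' Holds the master's view of batch states and per-worker holdings.
#'
#' @param batches List of batches from [make_batches()] (or an integer: that
#'   many empty placeholder batches, for scheduling-only uses).
#' @param workers Number of workers (ids `1..workers`).
#' @param prefetch_depth Extra batches a worker may hold beyond the one it
#'   is computing (>= 0; default 1).
#' @return A `farm_scheduler` environment.
#' @seealso [next_assignment()], [complete_batch()]
#' @export
new_scheduler <- function(batches, workers, prefetch_depth = 1L) {
  if (is.numeric(batches) && length(batches) == 1L)
    batches <- lapply(seq_len(batches) - 1L, function(b)
      structure(list(batch_id = b, query_ids = character(0),
                     state = "pending", assigned_worker = NA_integer_),
                class = "work_batch"))
  workers <- as.integer(workers)
  prefetch_depth <- as.integer(prefetch_depth)
  if (is.na(workers) || workers < 1L) stop("workers must be >= 1")
  if (is.na(prefetch_depth) || prefetch_depth < 0L)
    stop("prefetch_depth must be >= 0")
  e <- new.env(parent = emptyenv())
  e$batches <- batches
  e$state <- rep("pending", length(batches))
  e$assigned_worker <- rep(NA_integer_, length(batches))
  e$holding <- rep(0L, workers)      # batches currently held per worker
  e$capacity <- 1L + prefetch_depth
  e$workers <- workers
  e$done_workers <- rep(FALSE, workers)
  class(e) <- "farm_scheduler"
  e
}

#' Request the next batch for a worker
#'
#' The lowest-id pending batch transitions to assigned for this worker.
#' When no pending batches remain, an end-of-work marker (`NULL`) is
#' returned and the worker receives no further batches. A request from a
#' worker already holding its full capacity (`1 + prefetch_depth`) is a
#' protocol error.
#'
#' @param sched A [new_scheduler()].
#' @param worker_id Worker id in `1..workers`.
#' @return A `work_batch` with `state = "assigned"`, or `NULL` at
#'   end-of-work.
#' @export
next_assignment <- function(sched, worker_id) {
  stopifnot(inherits(sched, "farm_scheduler"))
  worker_id <- as.integer(worker_id)
  if (worker_id < 1L || worker_id > sched$workers)
    stop("unregistered worker ", worker_id)
  if (sched$done_workers[[worker_id]]) return(NULL)
  if (sched$holding[[worker_id]] >= sched$capacity)
    stop("protocol error: worker ", worker_id,
         " already holds its capacity of ", sched$capacity, " batches")
  pending <- which(sched$state == "pending")
  if (length(pending) == 0L) {
    sched$done_workers[[worker_id]] <- TRUE
    return(NULL)
  }
  b <- pending[[1L]]
  sched$state[[b]] <- "assigned"
  sched$assigned_worker[[b]] <- worker_id
  sched$holding[[worker_id]] <- sched$holding[[worker_id]] + 1L
  batch <- sched$batches[[b]]
  batch$state <- "assigned"
  batch$assigned_worker <- worker_id
  batch
}

#' Mark an assigned batch as completed
#'
#' @param sched A [new_scheduler()].
#' @param worker_id The worker that held the batch.
#' @param batch_id The batch id.
#' @return Invisibly, the scheduler.
#' @export
complete_batch <- function(sched, worker_id, batch_id) {
  stopifnot(inherits(sched, "farm_scheduler"))
  b <- batch_id + 1L
  if (b < 1L || b > length(sched$state)) stop("unknown batch ", batch_id)
  if (sched$state[[b]] != "assigned" ||
      sched$assigned_worker[[b]] != worker_id)
    stop("batch ", batch_id, " is not assigned to worker ", worker_id)
  sched$state[[b]] <- "done"
  sched$holding[[worker_id]] <- sched$holding[[worker_id]] - 1L
  invisible(sched)
}

#' Simulate the dispatch protocol in simulated time
#'
#' A discrete-event simulation of the prefetching master--worker protocol,
#' used to study latency hiding without running kernels. A worker issues a
#' dispatch request whenever it has no request outstanding and holds fewer
#' than `1 + prefetch_depth` batches; the request is answered after
#' `dispatch_latency` time units with the lowest-id pending batch (or
#' end-of-work). A worker starts its next held batch the moment the current
#' one finishes. With `prefetch_depth = 0` a worker can only request at
#' completion (its capacity is full while computing); with depth >= 1 the
#' request issued at batch start overlaps the computation, hiding the
#' dispatch latency.
#'
#' @param durations Non-negative batch durations, dispatched in this order.
#' @param workers Number of workers.
#' @param prefetch_depth Extra batches held beyond the current one.
#' @param dispatch_latency Simulated request-to-assignment latency
#'   (\eqn{\lambda \ge 0}).
#' @return A `schedule_result`: list with `assignments` (per-worker batch
#'   id vectors, in execution order), `start`/`finish` (per batch),
#'   `makespan`, and `idle` (per-worker idle time between first assignment
#'   and that worker's last completion).
#' @examples
#' simulate_schedule(c(2, 2, 2, 2), workers = 2, prefetch_depth = 1,
#'                   dispatch_latency = 1)$makespan  # 5
#' @export
simulate_schedule <- function(durations, workers, prefetch_depth = 1L,
                              dispatch_latency = 0) {
  if (any(durations < 0)) stop("durations must be non-negative")
  if (any(is.na(durations))) stop("durations must not contain NA")
  workers <- as.integer(workers)
  if (workers < 1L) stop("workers must be >= 1")
  lambda <- dispatch_latency
  if (lambda < 0) stop("dispatch_latency must be >= 0")
  nb <- length(durations)
  sched <- new_scheduler(nb, workers, prefetch_depth)
  capacity <- 1L + as.integer(prefetch_depth)

  # Per-worker state
  queue <- vector("list", workers)       # held batch ids awaiting execution
  current <- rep(NA_integer_, workers)   # batch id being computed
  outstanding <- rep(FALSE, workers)     # request in flight
  terminated <- rep(FALSE, workers)      # received end-of-work
  first_assign <- rep(NA_real_, workers)
  busy <- rep(0, workers)
  last_finish <- rep(NA_real_, workers)
  start_t <- rep(NA_real_, nb)
  finish_t <- rep(NA_real_, nb)
  assignments <- vector("list", workers)

  # Event list: completions rank before request answers at equal times so a
  # freed slot is visible; answers at equal times are served by worker id.
  events <- data.frame(time = numeric(0), type = integer(0),
                       worker = integer(0), batch = integer(0))
  push <- function(time, type, worker, batch = NA_integer_) {
    events[nrow(events) + 1L, ] <<- list(time, type, worker, batch)
  }
  TYPE_COMPLETE <- 0L; TYPE_ANSWER <- 1L

  held <- function(w) length(queue[[w]]) + !is.na(current[[w]])

  maybe_request <- function(w, now) {
    if (terminated[[w]] || outstanding[[w]]) return()
    if (held(w) >= capacity) return()
    outstanding[[w]] <<- TRUE
    push(now + lambda, TYPE_ANSWER, w)
  }

  start_next <- function(w, now) {
    if (!is.na(current[[w]]) || length(queue[[w]]) == 0L) return()
    b <- queue[[w]][[1L]]
    queue[[w]] <<- queue[[w]][-1L]
    current[[w]] <<- b
    start_t[[b + 1L]] <<- now
    if (is.na(first_assign[[w]])) first_assign[[w]] <- now  # defensive; set at assignment
    assignments[[w]] <<- c(assignments[[w]], b)
    push(now + durations[[b + 1L]], TYPE_COMPLETE, w, b)
    maybe_request(w, now)  # request issued at batch start (if capacity left)
  }

  for (w in seq_len(workers)) maybe_request(w, 0)

  while (nrow(events) > 0L) {
    ord <- order(events$time, events$type, events$worker)
    ev <- events[ord[[1L]], ]
    events <- events[ord[-1L], , drop = FALSE]
    w <- ev$worker; now <- ev$time
    if (ev$type == TYPE_COMPLETE) {
      b <- ev$batch
      finish_t[[b + 1L]] <- now
      busy[[w]] <- busy[[w]] + durations[[b + 1L]]
      last_finish[[w]] <- now
      complete_batch(sched, w, b)
      current[[w]] <- NA_integer_
      start_next(w, now)
      maybe_request(w, now)
    } else {
      outstanding[[w]] <- FALSE
      batch <- next_assignment(sched, w)
      if (is.null(batch)) {
        terminated[[w]] <- TRUE
      } else {
        if (is.na(first_assign[[w]])) first_assign[[w]] <- now
        queue[[w]] <- c(queue[[w]], batch$batch_id)
        start_next(w, now)
        maybe_request(w, now)
      }
    }
  }

  makespan <- if (nb == 0L) 0 else max(finish_t)
  idle <- vapply(seq_len(workers), function(w) {
    if (is.na(first_assign[[w]])) return(0)
    (last_finish[[w]] - first_assign[[w]]) - busy[[w]]
  }, numeric(1))
  structure(list(assignments = assignments, start = start_t,
                 finish = finish_t, makespan = makespan, idle = idle),
            class = "schedule_result")
}
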