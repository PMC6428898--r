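#' @title Synchronous simulation of compiled Boolean networks
#' @description Deterministic synchronous updating with clamping, trajectory
#' recording and exact point/cycle attractor detection by state hashing.
#' @name simulation
NULL

# build (and cache on the network) one big evaluation call returning the
# next state vector from `s`
network_evaluator <- function(net) {
  cached <- attr(net, "evaluator")
  if (!is.null(cached)) return(cached)
  index <- as.list(stats::setNames(seq_len(nrow(net$nodes)), net$nodes$id))
  calls <- lapply(net$nodes$id, function(id) expr_to_call(net$rules[[id]], index))
  big <- as.call(c(as.name("c"), calls))
  ids <- net$nodes$id
  function(s) {
    out <- eval(big, list(s = s))
    names(out) <- ids
    out
  }
}

check_state <- function(net, state) {
  if (length(state) != nrow(net$nodes)) {
    stop("state length ", length(state), " does not match node count ",
         nrow(net$nodes))
  }
  if (is.null(names(state))) names(state) <- net$nodes$id
  state
}

normalise_clamps <- function(net, clamps) {
  if (is.null(clamps) || length(clamps) == 0L) {
    return(stats::setNames(logical(0), character(0)))
  }
  clamps <- unlist(clamps)
  unknown <- setdiff(names(clamps), net$nodes$id)
  if (length(unknown) > 0L) {
    stop("clamp on unknown node(s): ", paste(unknown, collapse = ", "))
  }
  stats::setNames(as.logical(clamps), names(clamps))
}

apply_clamps <- function(state, clamps) {
  if (length(clamps) > 0L) state[names(clamps)] <- clamps
  state
}

#' One synchronous update step
#'
#' Every unclamped node takes the value of its update expression evaluated
#' on the previous state; clamped nodes take their clamp value (clamps also
#' dominate at step 0, i.e. apply them to the initial state before
#' stepping).
#'
#' @param net a [compile_network()] network.
#' @param state named logical vector in canonical node order.
#' @param clamps named logical vector of fixed node values (e.g. inputs,
#'   deletions); `NULL` for none.
#' @return the next state, same shape as `state`.
#' @export
step_network <- function(net, state, clamps = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  state <- check_state(net, state)
  clamps <- normalise_clamps(net, clamps)
  evalr <- network_evaluator(net)
  apply_clamps(evalr(apply_clamps(state, clamps)), clamps)
}

#' Simulate to an attractor
#'
#' Iterates the synchronous update from `init` (with `clamps` applied from
#' step 0 onwards), hashing every visited state, until a state recurs. The
#' first recurrence yields the minimal-period attractor and the transient
#' length. If no state recurs within `max_steps`, the result is an explicit
#' `budget-exceeded` outcome, never a silently truncated attractor.
#'
#' @param net a [compile_network()] network.
#' @param init named logical initial state (e.g.
#'   [default_initial_vector()]).
#' @param clamps named logical vector of clamped nodes, or `NULL`.
#' @param max_steps maximum number of update steps to take (>= 1).
#' @param record keep the full trajectory matrix (needed by the phenotype
#'   classifier); set `FALSE` to save memory on long runs.
#' @return an object of class `cdc_attractor`: a list with `kind`
#'   (`"point"`, `"cycle"` or `"budget-exceeded"`), `period`, `transient`,
#'   `states` (logical matrix, one row per attractor state, columns in
#'   canonical node order) and optionally `trajectory` (all states from
#'   step 0 up to and including the end of the first attractor traversal).
#' @export
find_attractor <- function(net, init, clamps = NULL, max_steps = 10000L,
                           record = TRUE) {
  stopifnot(inherits(net, "boolean_network"), max_steps >= 1L)
  clamps <- normalise_clamps(net, clamps)
  state <- apply_clamps(check_state(net, init), clamps)
  evalr <- network_evaluator(net)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  traj <- if (record) vector("list", 256L) else NULL
  n <- nrow(net$nodes)
  t <- 0L
  repeat {
    key <- rawToChar(as.raw(44L + state))
    first <- seen[[key]]
    if (!is.null(first)) {
      transient <- first
      period <- t - first
      states <- if (record) {
        do.call(rbind, traj[(first + 1L):t])
      } else {
        # re-simulate the attractor block only
        block <- matrix(FALSE, period, n, dimnames = list(NULL, net$nodes$id))
        block[1L, ] <- state
        if (period > 1L) {
          cur <- state
          for (i in 2:period) {
            cur <- apply_clamps(evalr(cur), clamps)
            block[i, ] <- cur
          }
        }
        block
      }
      colnames(states) <- net$nodes$id
      out <- list(
        kind = if (period == 1L) "point" else "cycle",
        period = period, transient = transient, states = states,
        initial = init)
      if (record) {
        tr <- do.call(rbind, traj[seq_len(t)])
        colnames(tr) <- net$nodes$id
        out$trajectory <- tr
      }
      return(structure(out, class = "cdc_attractor"))
    }
    seen[[key]] <- t
    if (record) {
      if (t + 1L > length(traj)) traj <- c(traj, vector("list", length(traj)))
      traj[[t + 1L]] <- state
    }
    if (t >= max_steps) {
      out <- list(kind = "budget-exceeded", period = NA_integer_,
                  transient = NA_integer_, states = NULL, initial = init,
                  max_steps = max_steps)
      return(structure(out, class = "cdc_attractor"))
    }
    state <- apply_clamps(evalr(state), clamps)
    t <- t + 1L
  }
}

#' @export
print.cdc_attractor <- function(x, ...) {
  if (x$kind == "budget-exceeded") {
    cat("no attractor found within", x$max_steps, "steps\n")
  } else {
    cat(x$kind, "attractor: period", x$period,
        "reached after a transient of", x$transient, "steps\n")
  }
  invisible(x)
}

#' Simulate under a clamp schedule
#'
#' Reproduces release-then-arrest protocols: the schedule maps step numbers
#' to clamp sets; at each listed step the active clamp set is replaced
#' (clamps are absolute, not incremental). Simulation runs for `n_steps`
#' and the full trajectory is returned.
#'
#' @param net a [compile_network()] network.
#' @param init initial state.
#' @param schedule named list: names are step numbers (as integers in
#'   character form), values are named logical clamp vectors; the entry
#'   `"0"` supplies the initial clamps.
#' @param n_steps number of steps to simulate.
#' @return logical trajectory matrix with `n_steps + 1` rows.
#' @export
simulate_schedule <- function(net, init, schedule, n_steps) {
  stopifnot(inherits(net, "boolean_network"))
  at <- as.integer(names(schedule))
  if (any(is.na(at))) stop("schedule names must be integer step numbers")
  evalr <- network_evaluator(net)
  clamps <- stats::setNames(logical(0), character(0))
  state <- check_state(net, init)
  traj <- matrix(FALSE, n_steps + 1L, nrow(net$nodes),
                 dimnames = list(NULL, net$nodes$id))
  for (t in 0:n_steps) {
    hit <- which(at == t)
    if (length(hit) == 1L) clamps <- normalise_clamps(net, schedule[[hit]])
    state <- apply_clamps(state, clamps)
    traj[t + 1L, ] <- state
    if (t < n_steps) state <- evalr(state)
  }
  traj
}

#' Extract a per-step readout table for selected nodes
#'
#' @param x a `cdc_attractor` (its attractor states, or its recorded
#'   trajectory with `from = "trajectory"`) or a logical trajectory matrix.
#' @param nodes character vector of node ids to extract.
#' @param from for attractors: `"attractor"` (default) or `"trajectory"`.
#' @return data.frame with a `step` column and one logical column per
#'   requested node, in the requested order.
#' @export
readout <- function(x, nodes, from = c("attractor", "trajectory")) {
  from <- match.arg(from)
  mat <- if (inherits(x, "cdc_attractor")) {
    if (x$kind == "budget-exceeded") stop("no attractor states to read out")
    if (from == "trajectory") {
      if (is.null(x$trajectory)) stop("attractor was computed without record = TRUE")
      x$trajectory
    } else {
      x$states
    }
  } else {
    as.matrix(x)
  }
  missing <- setdiff(nodes, colnames(mat))
  if (length(missing) > 0L) {
    hints <- unlist(lapply(missing, function(m) {
      utils::head(agrep(m, colnames(mat), max.distance = 0.3, value = TRUE), 3L)
    }))
    stop("unknown node(s): ", paste(missing, collapse = ", "),
         if (length(hints) > 0L) paste0(" (did you mean: ",
                                        paste(unique(hints), collapse = ", "), ")"))
  }
  out <- data.frame(step = seq_len(nrow(mat)) - 1L)
  for (nd in nodes) out[[nd]] <- mat[, nd]
  out
}

#' Write a readout table as TSV
#'
#' @param x see [readout()].
#' @param nodes node ids.
#' @param path output path.
#' @param ... passed to [readout()].
#' @return `path`, invisibly.
#' @export
write_readout_tsv <- function(x, nodes, path, ...) {
  tab <- readout(x, nodes, ...)
  tab[-1L] <- lapply(tab[-1L], as.integer)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
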