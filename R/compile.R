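#' @title Update-expression trees
#' @description Boolean update rules are stored as trees of
#' `AND`/`OR`/`NOT`/`CONST`/`REF` nodes, evaluated purely against the
#' previous network state.
#' @name update-expressions
#' @keywords internal
NULL

e_const <- function(value) list(op = "const", value = isTRUE(value))
e_ref <- function(node) list(op = "ref", node = node)
e_not <- function(x) list(op = "not", args = list(x))

e_junction <- function(op, args) {
  args <- args[!vapply(args, is.null, logical(1))]
  if (length(args) == 0L) {
    return(e_const(op == "and"))
  }
  if (length(args) == 1L) {
    return(args[[1L]])
  }
  list(op = op, args = args)
}
e_and <- function(...) e_junction("and", flatten_args(list(...)))
e_or <- function(...) e_junction("or", flatten_args(list(...)))

flatten_args <- function(xs) {
  out <- list()
  for (x in xs) {
    if (is.null(x)) next
    if (!is.null(x$op)) {
      out[[length(out) + 1L]] <- x
    } else {
      out <- c(out, x)
    }
  }
  out
}

expr_refs <- function(e) {
  switch(e$op,
    const = character(0),
    ref = e$node,
    unique(unlist(lapply(e$args, expr_refs)))
  )
}

expr_to_call <- function(e, index) {
  switch(e$op,
    const = e$value,
    ref = {
      i <- index[[e$node]]
      if (is.null(i)) stop("update rule references unknown node: ", e$node)
      call("[[", as.name("s"), i)
    },
    not = call("!", expr_to_call(e$args[[1L]], index)),
    and = Reduce(function(a, b) call("&&", a, b),
                 lapply(e$args, expr_to_call, index = index)),
    or = Reduce(function(a, b) call("||", a, b),
                lapply(e$args, expr_to_call, index = index)),
    stop("unknown expression op: ", e$op)
  )
}

expr_to_text <- function(e, ref_fmt = identity) {
  switch(e$op,
    const = if (e$value) "1" else "0",
    ref = ref_fmt(e$node),
    not = paste0("!", wrap(expr_to_text(e$args[[1L]], ref_fmt), e$args[[1L]])),
    and = paste(vapply(e$args, function(a) {
      wrap(expr_to_text(a, ref_fmt), a)
    }, character(1)), collapse = " & "),
    or = paste(vapply(e$args, function(a) {
      wrap(expr_to_text(a, ref_fmt), a)
    }, character(1)), collapse = " | ")
  )
}

wrap <- function(txt, e) {
  if (e$op %in% c("and", "or")) paste0("(", txt, ")") else txt
}

#' Timescale-separation delay specification
#'
#' The default rule delays all transcription reactions (catalogue category)
#' and every reaction flagged `slow` in the model file (used for the
#' coarse-grained replication/growth progression steps) by `k` steps: the
#' reaction only fires once its full update rule has held over `k + 1`
#' consecutive evaluations, which implements the requirement that slow
#' processes see a sustained input rather than a one-step pulse.
#'
#' @param sys a [rxncon_system()].
#' @param k integer delay applied to every selected reaction (default 20).
#' @param rule `"default"` (transcription + `slow`-flagged rows),
#'   `"none"`, or a named integer vector mapping reaction ids to delays.
#' @return named integer vector (reaction id -> k); possibly empty.
#' @export
delay_spec <- function(sys, k = 20L, rule = "default") {
  stopifnot(inherits(sys, "rxncon_system"))
  if (is.numeric(rule) && !is.null(names(rule))) {
    bad <- setdiff(names(rule), sys$reactions$id)
    if (length(bad) > 0L) {
      stop("delay specified for unknown reaction(s): ",
           paste(bad, collapse = ", "))
    }
    if (any(rule < 0)) stop("delays must be >= 0")
    return(vapply(rule, as.integer, integer(1)))
  }
  if (identical(rule, "none")) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (!identical(rule, "default")) stop("unknown delay rule: ", rule)
  delayed <- sys$catalogue$delayed_by_default[
    match(sys$reactions$rtype, sys$catalogue$rtype)] | sys$reactions$slow
  stats::setNames(rep(as.integer(k), sum(delayed)), sys$reactions$id[delayed])
}

presence_factor <- function(sys, comp) {
  s <- sys$states
  own <- s$variant != "global" &
    ((!is.na(s$comp_a) & s$comp_a == comp) |
       (!is.na(s$comp_b) & s$comp_b == comp))
  ids <- s$id[own]
  if (length(ids) == 0L) {
    stop("component ", comp, " has no elemental states")
  }
  e_or(lapply(ids, e_ref))
}

contingency_terms <- function(sys, target) {
  ct <- sys$contingencies
  rows <- ct[ct$target == target & ct$modifier %in% c("!", "x", "k+", "k-"), ,
             drop = FALSE]
  terms <- list()
  for (i in seq_len(nrow(rows))) {
    eff <- rows$effector[i]
    terms[[length(terms) + 1L]] <- switch(rows$modifier[i],
      "!" = e_ref(eff),
      "x" = e_not(e_ref(eff)),
      # k+/k- carry no executable semantics in the Boolean regime
      e_const(TRUE)
    )
  }
  terms
}

#' Update rule of a reaction node
#'
#' The rule conjoins the presence factors of the reaction's components
#' (each an OR over all of the component's elemental state nodes, neutrals
#' included), every `!` effector, the negation of every `x` effector and
#' references to gate nodes; `k+`/`k-` effectors contribute nothing
#' executable. Source-state gating is *not* part of the reaction rule: it
#' lives in the state rules, keeping the reaction node readable as
#' "catalytic opportunity". Macro-cycle reactions have no presence factors.
#'
#' @param sys a [rxncon_system()].
#' @param reaction reaction id.
#' @return an update-expression tree.
#' @export
reaction_update_rule <- function(sys, reaction) {
  r <- sys$reactions[sys$reactions$id == reaction, , drop = FALSE]
  if (nrow(r) != 1L) stop("unknown reaction: ", reaction)
  cat_i <- reaction_category(r$rtype, sys$catalogue)
  terms <- list()
  if (!(cat_i %in% c("macro_transition", "macro_synthesis"))) {
    terms[[length(terms) + 1L]] <- presence_factor(sys, r$a_name)
    if (r$b_name != r$a_name) {
      terms[[length(terms) + 1L]] <- presence_factor(sys, r$b_name)
    }
  }
  terms <- c(terms, contingency_terms(sys, reaction))
  e_junction("and", terms)
}

#' Update rule of an elemental-state node
#'
#' `Production OR (self AND NOT Consumption)`. Production terms require the
#' producing reaction together with all of its source (consumed) states;
#' synthesis terms require only the synthesising reaction. Consumption terms
#' require the consuming reaction with its *other* source states, or any
#' degradation reaction whose degraded set covers this state. Degradation of
#' a bound component additionally re-produces the partner's unbound neutral
#' state, so partners are never permanently sequestered in a degraded
#' complex. Mutually exclusive states may be simultaneously true: the model
#' tracks presence of states in a population, not single-molecule
#' microstates.
#'
#' @param sys a [rxncon_system()].
#' @param state canonical state id (elemental or macro-state global).
#' @return an update-expression tree.
#' @export
state_update_rule <- function(sys, state) {
  srow <- sys$states[sys$states$id == state, , drop = FALSE]
  if (nrow(srow) != 1L) stop("unknown state: ", state)
  production <- list()
  for (rid in sys$index$producers[[state]]) {
    sources <- sys$skeletons[[rid]]$consumed
    production[[length(production) + 1L]] <-
      e_junction("and", c(list(e_ref(rid)), lapply(sources, e_ref)))
  }
  for (rid in sys$index$synthesisers[[state]]) {
    production[[length(production) + 1L]] <- e_ref(rid)
  }
  # degradation of a bound partner frees this unbound locus
  if (srow$variant == "unbound") {
    for (rid in names(sys$skeletons)) {
      sk <- sys$skeletons[[rid]]
      if (length(sk$degraded) == 0L) next
      target <- sys$reactions$b_name[sys$reactions$id == rid]
      if (target == srow$comp_a) next
      for (b in sk$degraded) {
        brow <- sys$states[sys$states$id == b, , drop = FALSE]
        if (brow$variant != "bond") next
        frees <- (brow$comp_a == srow$comp_a && brow$locus_a == srow$locus_a) ||
          (identical(brow$comp_b, srow$comp_a) &&
             identical(brow$locus_b, srow$locus_a))
        if (frees) {
          production[[length(production) + 1L]] <- e_and(e_ref(rid), e_ref(b))
        }
      }
    }
  }
  consumption <- list()
  for (rid in sys$index$consumers[[state]]) {
    others <- setdiff(sys$skeletons[[rid]]$consumed, state)
    consumption[[length(consumption) + 1L]] <-
      e_junction("and", c(list(e_ref(rid)), lapply(others, e_ref)))
  }
  for (rid in sys$index$degraders[[state]]) {
    consumption[[length(consumption) + 1L]] <- e_ref(rid)
  }
  hold <- if (length(consumption) == 0L) {
    e_ref(state)
  } else {
    e_and(e_ref(state), e_not(e_junction("or", consumption)))
  }
  e_junction("or", c(production, list(hold)))
}

global_update_rule <- function(sys, gid) {
  produced <- length(sys$index$producers[[gid]]) +
    length(sys$index$synthesisers[[gid]]) +
    length(sys$index$consumers[[gid]]) > 0L
  if (produced) {
    return(state_update_rule(sys, gid))
  }
  terms <- contingency_terms(sys, gid)
  if (length(terms) > 0L) {
    return(e_junction("and", terms))  # declared output
  }
  e_ref(gid)  # pure input: holds its value, driven by clamps
}

gate_update_rule <- function(gate) {
  kids <- lapply(gate$children, e_ref)
  switch(gate$gtype,
    AND = e_junction("and", kids),
    OR = e_junction("or", kids),
    NOT = e_not(kids[[1L]])
  )
}

#' Compile a reaction-contingency system into its bipartite Boolean model
#'
#' Produces the uniquely defined parameter-free Boolean network: one node
#' per elemental state (neutrals included), per reaction, per Boolean gate
#' and per global (inputs, outputs and macro states), plus `k` delay nodes
#' per delayed reaction. Node order is canonical (states, reactions, gates,
#' globals, delays, each in system order), so compiling the same system
#' twice yields identical serialisations.
#'
#' @param sys a [rxncon_system()].
#' @param delays `"default"`, `"none"`, or a named integer vector of
#'   per-reaction delays; see [delay_spec()].
#' @param k default delay length used by the `"default"` rule.
#' @return an object of class `boolean_network` with fields `nodes`
#'   (data.frame `id`, `kind`), `rules` (named list of update-expression
#'   trees), `delays` (the applied delay vector) and `system` (provenance).
#' @examples
#' sys <- rxncon_system(data.frame(rtype = "ppi+", a_name = "A",
#'   a_locus = "b", b_name = "B", b_locus = "a"))
#' net <- compile_network(sys, delays = "none")
#' net$nodes
#' @export
compile_network <- function(sys, delays = "default", k = 20L) {
  stopifnot(inherits(sys, "rxncon_system"))
  report <- validate_system(sys)
  hard <- report[report$level == "error", , drop = FALSE]
  if (nrow(hard) > 0L) {
    stop("cannot compile: ", paste(hard$object, hard$message, collapse = "; "))
  }
  dl <- if (is.character(delays)) delay_spec(sys, k = k, rule = delays) else
    delay_spec(sys, rule = delays)

  s <- sys$states
  state_ids <- s$id[s$variant != "global"]
  reaction_ids <- sys$reactions$id
  gate_ids <- names(sys$gates)
  global_ids <- s$id[s$variant == "global"]

  nodes <- data.frame(
    id = c(state_ids, reaction_ids, gate_ids, global_ids),
    kind = c(rep("state", length(state_ids)),
             rep("reaction", length(reaction_ids)),
             rep("gate", length(gate_ids)),
             rep("global", length(global_ids))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) {
    stop("node id collision between states/reactions/gates/globals")
  }
  rules <- vector("list", nrow(nodes))
  names(rules) <- nodes$id
  for (id in state_ids) rules[[id]] <- state_update_rule(sys, id)
  for (id in reaction_ids) rules[[id]] <- reaction_update_rule(sys, id)
  for (id in gate_ids) rules[[id]] <- gate_update_rule(sys$gates[[id]])
  for (id in global_ids) rules[[id]] <- global_update_rule(sys, id)

  net <- structure(
    list(nodes = nodes, rules = rules,
         delays = stats::setNames(integer(0), character(0)), system = sys),
    class = "boolean_network")
  check_refs(net)
  if (length(dl) > 0L) net <- insert_delays(net, dl)
  net
}

check_refs <- function(net) {
  known <- net$nodes$id
  for (id in names(net$rules)) {
    missing <- setdiff(expr_refs(net$rules[[id]]), known)
    if (length(missing) > 0L) {
      stop("rule of ", id, " references unresolved node(s): ",
           paste(missing, collapse = ", "),
           " (dangling contingency effector?)")
    }
  }
  invisible(net)
}

#' Insert timescale-separation delay chains
#'
#' For each delayed reaction with delay `k`, its undelayed rule `u` moves to
#' delay node `d1`; `d(i+1) = d(i) AND u`; the reaction's new rule is
#' `d(k) AND u`. The reaction therefore fires at step `t` iff `u` held at
#' every evaluation in the window `t-k .. t` (k+1 consecutive steps), and
#' the chain resets whenever the condition lapses. Adds exactly `k` nodes
#' per delayed reaction.
#'
#' @param net a compiled [compile_network()] network without delays on the
#'   affected reactions.
#' @param delays named integer vector, reaction id -> k (k = 0 is a no-op).
#' @return the network with delay nodes appended in canonical order.
#' @export
insert_delays <- function(net, delays) {
  stopifnot(inherits(net, "boolean_network"))
  delays <- delays[delays > 0L]
  if (length(delays) == 0L) return(net)
  bad <- setdiff(names(delays),
                 net$nodes$id[net$nodes$kind == "reaction"])
  if (length(bad) > 0L) {
    stop("delay specified for unknown reaction(s): ", paste(bad, collapse = ", "))
  }
  already <- intersect(names(delays), names(net$delays))
  if (length(already) > 0L) {
    stop("reaction(s) already delayed: ", paste(already, collapse = ", "))
  }
  # keep canonical reaction order
  ord <- net$nodes$id[net$nodes$kind == "reaction"]
  delays <- delays[order(match(names(delays), ord))]
  for (rid in names(delays)) {
    k <- as.integer(delays[[rid]])
    u <- net$rules[[rid]]
    chain <- paste0(rid, "_delay", seq_len(k))
    net$rules[[chain[1L]]] <- u
    if (k > 1L) {
      for (i in 2:k) {
        net$rules[[chain[i]]] <- e_and(e_ref(chain[i - 1L]), u)
      }
    }
    net$rules[[rid]] <- e_and(e_ref(chain[k]), u)
    net$nodes <- rbind(net$nodes, data.frame(
      id = chain, kind = "delay", stringsAsFactors = FALSE))
  }
  net$delays <- c(net$delays, delays)
  rownames(net$nodes) <- NULL
  net
}

#' Default initial state vector of a compiled network
#'
#' All components are present in their native form: neutral states
#' (unbound, unmodified, presence) start true; bonds, modifications,
#' reactions, gates and delay nodes start false; globals start false except
#' for explicit overrides. The placeholder input `[Histones]`, when present,
#' is set true by default.
#'
#' @param net a [compile_network()] network.
#' @param overrides named logical vector of node values applied on top of
#'   the defaults; unknown node names are an error.
#' @return named logical vector in canonical node order.
#' @export
default_initial_vector <- function(net, overrides = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  v <- stats::setNames(rep(FALSE, nrow(net$nodes)), net$nodes$id)
  s <- net$system$states
  neutral_ids <- s$id[s$neutral]
  v[intersect(neutral_ids, names(v))] <- TRUE
  if ("[Histones]" %in% names(v)) v[["[Histones]"]] <- TRUE
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(v))
    if (length(unknown) > 0L) {
      stop("initial-vector override of unknown node(s): ",
           paste(unknown, collapse = ", "))
    }
    v[names(overrides)] <- as.logical(overrides)
  }
  v
}

#' @export
print.boolean_network <- function(x, ...) {
  census <- table(factor(x$nodes$kind,
                         c("state", "reaction", "gate", "global", "delay")))
  cat("boolean_network with", nrow(x$nodes), "nodes (",
      paste(names(census), as.integer(census), collapse = ", "), ")\n")
  invisible(x)
}

#' Per-kind node census of a compiled network
#'
#' @param net a [compile_network()] network.
#' @return named integer vector over kinds state/reaction/gate/global/delay
#'   plus `total`.
#' @export
node_census <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  kinds <- c("state", "reaction", "gate", "global", "delay")
  census <- vapply(kinds, function(k) sum(net$nodes$kind == k), integer(1))
  c(census, total = nrow(net$nodes))
}

#' Serialise a network to JSON
#'
#' Deterministic serialisation of nodes, kinds, update trees and the default
#' initial vector; identical systems compile to byte-identical JSON, which
#' is the uniqueness guarantee tests hash.
#'
#' @param net a [compile_network()] network.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
network_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  payload <- list(
    nodes = net$nodes,
    rules = lapply(net$rules, identity),
    delays = as.list(net$delays),
    initial = as.list(default_initial_vector(net))
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Export a network in the plain-text "targets, factors" format
#'
#' One line per node, `target, factor` with `&`, `|`, `!` syntax, as read by
#' common Boolean-network simulators. Node identifiers are sanitised to
#' alphanumerics/underscores; the mapping is returned as an attribute.
#'
#' @param net a [compile_network()] network.
#' @param path output file path.
#' @return invisibly, the named character vector mapping node ids to the
#'   sanitised identifiers used in the file.
#' @export
write_bnet <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  safe <- gsub("[^A-Za-z0-9_]+", "_", net$nodes$id)
  safe <- gsub("^_+|_+$", "", safe)
  safe <- make.unique(safe, sep = "_")
  map <- stats::setNames(safe, net$nodes$id)
  fmt <- function(id) map[[id]]
  lines <- c("targets, factors",
             vapply(net$nodes$id, function(id) {
               paste0(map[[id]], ", ", expr_to_text(net$rules[[id]], fmt))
             }, character(1)))
  writeLines(lines, path)
  invisible(map)
}
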