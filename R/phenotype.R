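#' @title Mutant specification and genotype-to-phenotype calls
#' @description Mutants are expressed as clamp sets: deletions force every
#' state of a component (and of its gene/mRNA) false, residue locks pin a
#' modification state and its neutral complement, overexpression pins a
#' transcription reaction true. The resulting attractor is classified into
#' viability/arrest phenotypes on the coarse-grained cycle readout.
#' @name phenotyping
NULL

#' Construct a mutant specification
#'
#' @param deletions character vector of component names to delete.
#' @param locks named logical vector of elemental-state locks (e.g. an
#'   alanine point mutant locks `X_[r]-P` to `FALSE`, a phosphomimetic to
#'   `TRUE`); modification locks imply the opposite lock on the neutral
#'   complement.
#' @param overexpress character vector of transcription reaction ids (or
#'   protein names, resolved to their transcription reactions) clamped
#'   constitutively on.
#' @param label mutant label.
#' @return object of class `mutant_spec`.
#' @export
mutant_spec <- function(deletions = character(0), locks = NULL,
                        overexpress = character(0), label = "") {
  if (is.null(locks)) locks <- stats::setNames(logical(0), character(0))
  structure(list(deletions = deletions, locks = locks,
                 overexpress = overexpress, label = label),
            class = "mutant_spec")
}

component_state_nodes <- function(sys, comp) {
  s <- sys$states
  s$id[s$variant != "global" &
         ((!is.na(s$comp_a) & s$comp_a == comp) |
            (!is.na(s$comp_b) & s$comp_b == comp))]
}

resolve_overexpression <- function(sys, entry) {
  if (entry %in% sys$reactions$id) {
    cat_i <- reaction_category(
      sys$reactions$rtype[sys$reactions$id == entry], sys$catalogue)
    if (!(cat_i %in% c("transcription", "synthesis"))) {
      stop("overexpression target ", entry,
           " is not a transcription/synthesis reaction")
    }
    return(entry)
  }
  # protein name: find the transcription reaction(s) of its gene
  cat_of <- reaction_category(sys$reactions$rtype, sys$catalogue)
  hits <- vapply(which(cat_of == "transcription"), function(i) {
    sk <- sys$skeletons[[sys$reactions$id[i]]]
    made <- unique(sys$states$comp_a[match(sk$synthesised, sys$states$id)])
    prot <- sys$components$protein[match(made, sys$components$name)]
    entry %in% prot
  }, logical(1))
  ids <- sys$reactions$id[which(cat_of == "transcription")][hits]
  if (length(ids) == 0L) {
    stop("no transcription reaction found for overexpression of ", entry)
  }
  ids
}

#' Translate a mutant specification into a clamp set
#'
#' Deletions clamp every elemental-state node of the component and of its
#' gene and mRNA (when declared) to false. Locks clamp the named state to
#' its value and, for modification states, the unmodified complement to the
#' negation. Overexpression clamps the transcription reaction node true.
#'
#' @param net a [compile_network()] network.
#' @param spec a [mutant_spec()].
#' @return named logical clamp vector.
#' @export
apply_mutant <- function(net, spec) {
  stopifnot(inherits(net, "boolean_network"), inherits(spec, "mutant_spec"))
  sys <- net$system
  clamps <- stats::setNames(logical(0), character(0))
  lock_comps <- unique(unlist(lapply(names(spec$locks), function(id) {
    p <- parse_state_id(id)
    c(p$comp_a, p$comp_b)
  })))
  conflict <- intersect(spec$deletions, lock_comps)
  if (length(conflict) > 0L) {
    stop("mutant ", spec$label, ": deletion and lock on the same component: ",
         paste(conflict, collapse = ", "))
  }
  for (comp in spec$deletions) {
    if (!(comp %in% sys$components$name)) {
      stop("deletion of unknown component: ", comp)
    }
    linked <- sys$components$name[
      sys$components$kind %in% c("gene", "mRNA") &
        !is.na(sys$components$protein) & sys$components$protein == comp]
    nodes <- unique(unlist(lapply(c(comp, linked), component_state_nodes,
                                  sys = sys)))
    clamps[nodes] <- FALSE
  }
  for (id in names(spec$locks)) {
    if (!(id %in% net$nodes$id)) stop("lock on unknown state: ", id)
    val <- spec$locks[[id]]
    clamps[id] <- val
    p <- parse_state_id(id)
    if (p$variant %in% c("modification", "unmodified")) {
      comp_id <- if (p$variant == "modification") {
        unmod_state_id(p$comp_a, p$locus_a)
      } else {
        # locking the neutral implies the lock applies to every modification
        # at the locus; handled per-mod below
        NULL
      }
      if (!is.null(comp_id) && comp_id %in% net$nodes$id) {
        clamps[comp_id] <- !val
      }
    }
  }
  for (entry in spec$overexpress) {
    for (rid in resolve_overexpression(sys, entry)) clamps[rid] <- TRUE
  }
  clamps
}

#' Coarse-grained cycle readout map
#'
#' Describes which global macro states encode the three replication cycles
#' (DNA, spindle-pole-body/nuclear division, bud/cell division), in stage
#' order, and which events mark replication completion, nuclear division
#' and cytokinesis for the DNA/nuclei bookkeeping.
#'
#' @param dna,spb,bud character vectors of macro-state node ids in stage
#'   order (first entry = start-of-cycle state).
#' @param replicated macro state marking completed DNA replication.
#' @param segregated macro state marking completed segregation/nuclear
#'   division.
#' @param division macro state marking completed cytokinesis.
#' @return object of class `cgm_map`.
#' @export
cgm_map <- function(dna, spb, bud, replicated, segregated, division) {
  structure(list(cycles = list(dna = dna, spb = spb, bud = bud),
                 replicated = replicated, segregated = segregated,
                 division = division),
            class = "cgm_map")
}

#' Default arrest-stage decision table
#'
#' Loaded from `inst/extdata/arrest_stages.yaml`: an ordered rule list
#' mapping coarse-grained point-arrest profiles to cell-cycle stages
#' (first match wins; profiles matching no rule yield stage `NA` with a
#' warning). The table is data, not code, so other cycle conventions can be
#' bound without code change.
#'
#' @param path YAML file; defaults to the packaged table.
#' @return list of rules.
#' @export
stage_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "arrest_stages.yaml", package = "rxncycle")
  }
  yaml::read_yaml(path)$rules
}

rising_edges <- function(series) {
  if (length(series) < 2L) return(0L)
  sum(series[-1L] & !series[-length(series)])
}

cycle_traversal <- function(states, cycle_nodes) {
  # TRUE iff every macro state of the cycle activates during the period and
  # first activations follow stage order cyclically (anchored at the first
  # stage's first activation)
  present <- cycle_nodes %in% colnames(states)
  if (!all(present)) stop("unmapped CGM node(s): ",
                          paste(cycle_nodes[!present], collapse = ", "))
  firsts <- vapply(cycle_nodes, function(nd) {
    hit <- which(states[, nd])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  if (anyNA(firsts)) return(FALSE)
  rot <- (firsts - firsts[1L]) %% nrow(states)
  all(diff(rot) > 0)
}

#' Classify an attractor into a phenotype call
#'
#' Cyclic attractors in which the DNA, spindle-pole-body and bud cycles all
#' complete an ordered traversal per period are viable (full cycle). Cyclic
#' attractors completing DNA replication and nuclear division but never
#' cytokinesis are lethal partial cycles (multinucleate; DNA/nuclei counts
#' unbounded). Point attractors (and residual oscillations that traverse no
#' cycle) are lethal arrests; the stage is assigned from the coarse-grained
#' profile by the data-driven decision table, and DNA/nuclei counts are
#' derived from completed replication/division events along the recorded
#' trajectory.
#'
#' @param att a [find_attractor()] result computed with `record = TRUE`.
#' @param cgm a [cgm_map()].
#' @param stages decision table, see [stage_table()].
#' @return object of class `phenotype_call`: `viability`, `mode`, `stage`,
#'   `cgm_profile` (named logical), `dna_count`, `nuclei_count`, `period`.
#' @export
classify_attractor <- function(att, cgm, stages = stage_table()) {
  stopifnot(inherits(att, "cdc_attractor"), inherits(cgm, "cgm_map"))
  if (att$kind == "budget-exceeded") {
    return(structure(list(viability = "lethal", mode = "budget-exceeded",
                          stage = NA_character_, cgm_profile = NULL,
                          dna_count = NA, nuclei_count = NA,
                          period = NA_integer_),
                     class = "phenotype_call"))
  }
  states <- att$states
  all_nodes <- unlist(cgm$cycles)
  missing <- setdiff(c(all_nodes, cgm$replicated, cgm$segregated, cgm$division),
                     colnames(states))
  if (length(missing) > 0L) {
    stop("unmapped CGM node(s): ", paste(missing, collapse = ", "))
  }
  profile <- apply(states[, all_nodes, drop = FALSE], 2L, any)

  if (att$kind == "cycle") {
    trav <- vapply(cgm$cycles, function(cyc) cycle_traversal(states, cyc),
                   logical(1))
    if (all(trav)) {
      return(structure(list(viability = "viable", mode = "full-cycle",
                            stage = NA_character_, cgm_profile = profile,
                            dna_count = 1L, nuclei_count = 1L,
                            period = att$period),
                       class = "phenotype_call"))
    }
    replicates <- any(states[, cgm$replicated])
    divides_nucleus <- any(states[, cgm$segregated])
    divides_cell <- any(states[, cgm$division])
    if (replicates && divides_nucleus && !divides_cell) {
      return(structure(list(viability = "lethal",
                            mode = "partial-cycle-multinucleate",
                            stage = NA_character_, cgm_profile = profile,
                            dna_count = "unbounded",
                            nuclei_count = "unbounded",
                            period = att$period),
                       class = "phenotype_call"))
    }
  }

  # point arrest (or residual oscillation traversing no cycle)
  traj <- if (!is.null(att$trajectory)) att$trajectory else states
  n_nd <- rising_edges(traj[, cgm$segregated])
  n_div <- rising_edges(traj[, cgm$division])
  nuclei <- max(1L, 1L + n_nd - n_div)
  dna_profile <- vapply(cgm$cycles$dna, function(nd) any(states[, nd]),
                        logical(1))
  dna_state <- if (any(dna_profile)) {
    # furthest stage along the cycle that is active
    names(dna_profile)[max(which(dna_profile))]
  } else {
    "none"
  }
  stage <- NA_character_
  for (rule in stages) {
    cond <- rule$when
    ok <- TRUE
    if (!is.null(cond$dna)) {
      labels <- stage_label(dna_state, cgm$cycles$dna)
      ok <- ok && labels %in% cond$dna
    }
    if (!is.null(cond$nuclei_min)) ok <- ok && nuclei >= cond$nuclei_min
    if (!is.null(cond$nuclei_max)) ok <- ok && nuclei <= cond$nuclei_max
    if (ok) {
      stage <- rule$stage
      break
    }
  }
  if (is.na(stage)) {
    warning("CGM profile matches no stage rule; stage set to NA")
    stage <- "NA"
  }
  structure(list(viability = "lethal", mode = "point-arrest", stage = stage,
                 cgm_profile = profile, dna_count = nuclei,
                 nuclei_count = nuclei, period = att$period),
            class = "phenotype_call")
}

# positional label of a macro state within its declared cycle
stage_label <- function(state_id, cycle_nodes) {
  if (state_id == "none") return("none")
  idx <- match(state_id, cycle_nodes)
  c("start", "early", "late", "end")[min(idx, 4L)]
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat("phenotype:", x$viability, "/", x$mode,
      if (!is.na(x$stage)) paste0("(", x$stage, " arrest)") else "",
      "DNA", x$dna_count, "nuclei", x$nuclei_count, "\n")
  invisible(x)
}

parse_mutant_row <- function(row) {
  split_field <- function(x) {
    if (is.na(x) || x == "") character(0) else
      trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  }
  locks_raw <- split_field(row$locks)
  locks <- stats::setNames(logical(0), character(0))
  for (lk in locks_raw) {
    parts <- strsplit(lk, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed lock: ", lk)
    locks[trimws(parts[1L])] <- trimws(parts[2L]) %in% c("1", "true", "TRUE")
  }
  mutant_spec(deletions = split_field(row$deletions), locks = locks,
              overexpress = split_field(row$overexpress), label = row$label)
}

#' Read a mutant benchmark table
#'
#' Tab- or comma-separated with columns `label`, `deletions` (`;`-separated
#' component names), `locks` (`;`-separated `state=0/1`), `overexpress`,
#' `expected_viability` (`viable`/`lethal`) and optional `expected_stage`.
#'
#' @param path file path.
#' @return data.frame of benchmark rows.
#' @export
read_mutant_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "#", fill = TRUE)
  need <- c("label", "expected_viability")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("mutant table lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("deletions", "locks", "overexpress", "expected_stage")) {
    if (is.null(tab[[col]])) tab[[col]] <- ""
  }
  tab
}

#' Run a mutant benchmark
#'
#' Each row is simulated from the supplied start state (conventionally the
#' wild-type nutrient-free arrest state) with nutrients clamped on and the
#' mutant clamps applied, classified, and compared to the expected
#' viability. Row failures are recorded and the run continues.
#'
#' @param net a [compile_network()] network.
#' @param rows benchmark rows, see [read_mutant_table()].
#' @param init start state (e.g. the wild-type G0 attractor state).
#' @param cgm a [cgm_map()].
#' @param base_clamps clamps applied to every run (e.g.
#'   `c("[Nutrients]" = TRUE)`).
#' @param max_steps simulation budget per mutant.
#' @param stages stage decision table.
#' @return list with `calls` (per-row data.frame: label, expected/predicted
#'   viability, mode, stage, dna, nuclei, period, correct, error) and
#'   `summary` (counts: rows, evaluated, correct, correct_lethal,
#'   correct_viable, predicted_lethal, arrest-profile census).
#' @export
benchmark_mutants <- function(net, rows, init, cgm,
                              base_clamps = c("[Nutrients]" = TRUE),
                              max_steps = 10000L, stages = stage_table()) {
  stopifnot(inherits(net, "boolean_network"))
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    res <- tryCatch({
      spec <- parse_mutant_row(row)
      clamps <- c(base_clamps, apply_mutant(net, spec))
      clamps <- clamps[!duplicated(names(clamps), fromLast = TRUE)]
      att <- find_attractor(net, init, clamps = clamps, max_steps = max_steps)
      call <- classify_attractor(att, cgm, stages)
      data.frame(label = row$label,
                 expected = row$expected_viability,
                 predicted = call$viability, mode = call$mode,
                 stage = ifelse(is.na(call$stage), "", call$stage),
                 dna = as.character(call$dna_count),
                 nuclei = as.character(call$nuclei_count),
                 period = ifelse(is.na(call$period), NA_integer_, call$period),
                 correct = identical(call$viability, row$expected_viability),
                 error = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(label = row$label, expected = row$expected_viability,
                 predicted = "", mode = "", stage = "", dna = "",
                 nuclei = "", period = NA_integer_, correct = FALSE,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    out[[i]] <- res
  }
  calls <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(label = character(0), expected = character(0),
               predicted = character(0), mode = character(0),
               stage = character(0), dna = character(0), nuclei = character(0),
               period = integer(0), correct = logical(0), error = character(0),
               stringsAsFactors = FALSE)
  arrests <- calls[calls$mode == "point-arrest", , drop = FALSE]
  census <- if (nrow(arrests) > 0L) {
    table_to_list(paste(arrests$stage, arrests$dna, arrests$nuclei, sep = "/"))
  } else {
    list()
  }
  summary <- list(
    rows = nrow(calls),
    evaluated = sum(calls$error == ""),
    correct = sum(calls$correct),
    correct_lethal = sum(calls$correct & calls$expected == "lethal"),
    correct_viable = sum(calls$correct & calls$expected == "viable"),
    predicted_lethal = sum(calls$predicted == "lethal"),
    expected_lethal = sum(calls$expected == "lethal"),
    arrest_profile_census = census
  )
  list(calls = calls, summary = summary)
}
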