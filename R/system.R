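#' Construct a reaction-contingency system
#'
#' A `rxncon_system` is the in-memory form of a reaction-contingency
#' knowledge base: components, elemental reactions, contingencies and Boolean
#' gates, together with the derived elemental-state universe, per-reaction
#' skeletons (produced/consumed/synthesised/degraded state sets) and
#' producer/consumer indexes. The macro-cycle (coarse-grained) layer is
#' carried by reactions of the `macro_transition`/`macro_synthesis`
#' categories, whose source and target are bracketed global macro states.
#'
#' @param reactions data.frame with columns `rtype`, `a_name`, `a_locus`,
#'   `b_name`, `b_locus` (loci `NA` where not applicable; `b_name` `NA` or
#'   empty for monomolecular reactions), and optionally `uid`,
#'   `no_turnover` (logical: exempt this reaction's product from the turnover
#'   rules), `slow` (logical: subject to the default timescale-separation
#'   delay) plus free annotation columns, which are preserved.
#' @param contingencies data.frame with columns `target` (reaction id, gate
#'   id `<G>` or global output id `[X]`), `modifier` (one of `!`, `x`, `k+`,
#'   `k-` for regulatory contingencies, or `AND`/`OR`/`NOT` for Boolean-gate
#'   membership rows whose target is a gate) and `effector` (canonical state
#'   id, global id or gate id). May be `NULL`/empty.
#' @param components optional data.frame with columns `name`, `kind` (one of
#'   `protein`, `gene`, `mRNA`, `multimeric-complex`, `chromosomal-feature`,
#'   `enzymatic-activity`, `small-molecule`) and `protein` (for genes/mRNAs:
#'   the linked protein component). Components referenced by reactions but
#'   not declared default to kind `protein`.
#' @param catalogue reaction-type catalogue, see [default_reaction_types()].
#' @return an object of class `rxncon_system`.
#' @examples
#' rxn <- data.frame(rtype = "ppi+", a_name = "A", a_locus = "b", b_name = "B",
#'                   b_locus = "a")
#' sys <- rxncon_system(rxn)
#' sys$reactions$id
#' @export
rxncon_system <- function(reactions, contingencies = NULL, components = NULL,
                          catalogue = default_reaction_types()) {
  check_catalogue(catalogue)
  reactions <- normalise_reactions(reactions, catalogue)
  contingencies <- normalise_contingencies(contingencies)
  components <- derive_components(reactions, components, catalogue)
  loci <- derive_loci(reactions, catalogue)
  states <- derive_states(reactions, components, loci, contingencies, catalogue)
  sys <- structure(
    list(
      components = components,
      loci = loci,
      reactions = reactions,
      contingencies = contingencies,
      states = states,
      catalogue = catalogue
    ),
    class = "rxncon_system"
  )
  sys$gates <- derive_gates(contingencies)
  sys$skeletons <- lapply(seq_len(nrow(reactions)), function(i) {
    skeleton_for_row(sys, reactions[i, , drop = FALSE])
  })
  names(sys$skeletons) <- reactions$id
  sys <- index_system(sys)
  sys
}

component_kinds <- c("protein", "gene", "mRNA", "multimeric-complex",
                     "chromosomal-feature", "enzymatic-activity",
                     "small-molecule")

empty_chr <- function(x) is.na(x) | x == ""

normalise_reactions <- function(reactions, catalogue) {
  if (is.null(reactions) || nrow(reactions) == 0L) {
    return(data.frame(id = character(0), uid = character(0),
                      rtype = character(0), a_name = character(0),
                      a_locus = character(0), b_name = character(0),
                      b_locus = character(0), no_turnover = logical(0),
                      slow = logical(0), stringsAsFactors = FALSE))
  }
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("a_locus", "b_name", "b_locus")) {
    if (is.null(reactions[[col]])) reactions[[col]] <- NA_character_
    reactions[[col]][empty_chr(reactions[[col]])] <- NA_character_
  }
  if (is.null(reactions$no_turnover)) reactions$no_turnover <- FALSE
  reactions$no_turnover[is.na(reactions$no_turnover)] <- FALSE
  if (is.null(reactions$slow)) reactions$slow <- FALSE
  reactions$slow[is.na(reactions$slow)] <- FALSE
  unknown <- !(reactions$rtype %in% catalogue$rtype)
  if (any(unknown)) {
    stop("unknown reaction type(s) in row(s) ",
         paste(which(unknown), collapse = ", "), ": ",
         paste(unique(reactions$rtype[unknown]), collapse = ", "))
  }
  # monomolecular: B defaults to A
  mono <- empty_chr(reactions$b_name)
  reactions$b_name[mono] <- reactions$a_name[mono]
  reactions$b_locus[mono] <- reactions$a_locus[mono]
  reactions$id <- reaction_id(reactions$rtype, reactions$a_name,
                              reactions$a_locus, reactions$b_name,
                              reactions$b_locus)
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  }
  if (is.null(reactions$uid)) reactions$uid <- reactions$id
  reactions$uid[empty_chr(reactions$uid)] <- reactions$id[empty_chr(reactions$uid)]
  front <- c("id", "uid", "rtype", "a_name", "a_locus", "b_name", "b_locus",
             "no_turnover", "slow")
  reactions <- reactions[, c(front, setdiff(names(reactions), front)), drop = FALSE]
  rownames(reactions) <- NULL
  reactions
}

normalise_contingencies <- function(contingencies) {
  if (is.null(contingencies) || nrow(contingencies) == 0L) {
    return(data.frame(uid = character(0), target = character(0),
                      modifier = character(0), effector = character(0),
                      stringsAsFactors = FALSE))
  }
  contingencies <- as.data.frame(contingencies, stringsAsFactors = FALSE)
  req <- c("target", "modifier", "effector")
  missing <- setdiff(req, names(contingencies))
  if (length(missing) > 0L) {
    stop("contingency table lacks columns: ", paste(missing, collapse = ", "))
  }
  ok_mod <- c("!", "x", "k+", "k-", "AND", "OR", "NOT")
  bad <- !(contingencies$modifier %in% ok_mod)
  if (any(bad)) {
    stop("unknown contingency modifier(s) in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  self <- contingencies$target == contingencies$effector
  if (any(self)) {
    stop("contingency targets its own effector in row(s) ",
         paste(which(self), collapse = ", "))
  }
  if (is.null(contingencies$uid)) {
    contingencies$uid <- sprintf("C%03d", seq_len(nrow(contingencies)))
  }
  front <- c("uid", "target", "modifier", "effector")
  contingencies <- contingencies[, c(front, setdiff(names(contingencies), front)),
                                 drop = FALSE]
  rownames(contingencies) <- NULL
  contingencies
}

reaction_category <- function(rtype, catalogue) {
  catalogue$category[match(rtype, catalogue$rtype)]
}

derive_components <- function(reactions, components, catalogue) {
  declared <- if (is.null(components) || nrow(components) == 0L) {
    data.frame(name = character(0), kind = character(0), protein = character(0),
               stringsAsFactors = FALSE)
  } else {
    components <- as.data.frame(components, stringsAsFactors = FALSE)
    if (is.null(components$protein)) components$protein <- NA_character_
    components$protein[empty_chr(components$protein)] <- NA_character_
    bad <- !(components$kind %in% component_kinds)
    if (any(bad)) {
      stop("unknown component kind(s): ",
           paste(unique(components$kind[bad]), collapse = ", "))
    }
    components[, c("name", "kind", "protein"), drop = FALSE]
  }
  if (anyDuplicated(declared$name)) {
    stop("duplicate component names: ",
         paste(unique(declared$name[duplicated(declared$name)]), collapse = ", "))
  }
  cat_of <- reaction_category(reactions$rtype, catalogue)
  macro <- cat_of %in% c("macro_transition", "macro_synthesis")
  used <- unique(c(reactions$a_name[!macro], reactions$b_name[!macro]))
  used <- used[!is.na(used) & !is_global_id(used)]
  new <- setdiff(used, declared$name)
  if (length(new) > 0L) {
    declared <- rbind(declared, data.frame(
      name = new, kind = "protein", protein = NA_character_,
      stringsAsFactors = FALSE))
  }
  linked <- declared$kind %in% c("gene", "mRNA")
  if (any(linked & is.na(declared$protein))) {
    stop("gene/mRNA components must declare their protein link: ",
         paste(declared$name[linked & is.na(declared$protein)], collapse = ", "))
  }
  missing_prot <- setdiff(declared$protein[linked], declared$name)
  if (length(missing_prot) > 0L) {
    stop("gene/mRNA linked to undeclared protein(s): ",
         paste(missing_prot, collapse = ", "))
  }
  if (any(declared$kind == "enzymatic-activity" & declared$name %in%
            declared$protein[linked])) {
    stop("an enzymatic-activity component may not have a gene/mRNA")
  }
  rownames(declared) <- NULL
  declared
}

derive_loci <- function(reactions, catalogue) {
  cat_of <- reaction_category(reactions$rtype, catalogue)
  rows <- list()
  add <- function(comp, locus, kind, row) {
    rows[[length(rows) + 1L]] <<- data.frame(
      component = comp, locus = locus, kind = kind, row = row,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(reactions))) {
    r <- reactions[i, ]
    cat_i <- cat_of[i]
    if (cat_i %in% c("bond_formation", "bond_dissociation")) {
      if (is.na(r$a_locus) || is.na(r$b_locus)) {
        stop("bond reaction in row ", i, " needs domain loci on both components")
      }
      add(r$a_name, r$a_locus, "domain", i)
      add(r$b_name, r$b_locus, "domain", i)
    } else if (cat_i %in% c("mod_addition", "mod_removal")) {
      if (is.na(r$b_locus)) {
        stop("modification reaction in row ", i, " needs a residue locus on B")
      }
      add(r$b_name, r$b_locus, "residue", i)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(component = character(0), locus = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  loci <- do.call(rbind, rows)
  key <- paste(loci$component, loci$locus)
  conflict <- tapply(loci$kind, key, function(k) length(unique(k)) > 1L)
  if (any(conflict)) {
    stop("locus used both as domain and as residue: ",
         paste(names(conflict)[conflict], collapse = ", "),
         " (bonds attach to domains, modifications to residues)")
  }
  loci <- loci[!duplicated(key), c("component", "locus", "kind"), drop = FALSE]
  rownames(loci) <- NULL
  loci
}

state_row <- function(id, variant, comp_a, locus_a = NA_character_,
                      comp_b = NA_character_, locus_b = NA_character_,
                      mod = NA_character_) {
  data.frame(id = id, variant = variant, comp_a = comp_a, locus_a = locus_a,
             comp_b = comp_b, locus_b = locus_b, mod = mod,
             neutral = variant %in% c("unbound", "unmodified", "presence"),
             stringsAsFactors = FALSE)
}

derive_states <- function(reactions, components, loci, contingencies, catalogue) {
  cat_of <- reaction_category(reactions$rtype, catalogue)
  rows <- list()
  seen <- character(0)
  push <- function(row) {
    if (!(row$id %in% seen)) {
      seen <<- c(seen, row$id)
      rows[[length(rows) + 1L]] <<- row
    }
  }
  # neutrals first, in component order
  for (comp in components$name) {
    comp_loci <- loci[loci$component == comp, , drop = FALSE]
    if (nrow(comp_loci) == 0L) {
      push(state_row(presence_state_id(comp), "presence", comp))
    } else {
      for (j in seq_len(nrow(comp_loci))) {
        l <- comp_loci[j, ]
        if (l$kind == "domain") {
          push(state_row(unbound_state_id(comp, l$locus), "unbound",
                         comp, l$locus))
        } else {
          push(state_row(unmod_state_id(comp, l$locus), "unmodified",
                         comp, l$locus))
        }
      }
    }
  }
  # non-neutral states in reaction order
  for (i in seq_len(nrow(reactions))) {
    r <- reactions[i, ]
    cat_i <- cat_of[i]
    if (cat_i %in% c("bond_formation", "bond_dissociation")) {
      push(state_row(bond_state_id(r$a_name, r$a_locus, r$b_name, r$b_locus),
                     "bond", r$a_name, r$a_locus, r$b_name, r$b_locus))
    } else if (cat_i %in% c("mod_addition", "mod_removal")) {
      mod <- catalogue$mod[match(r$rtype, catalogue$rtype)]
      push(state_row(mod_state_id(r$b_name, r$b_locus, mod), "modification",
                     r$b_name, r$b_locus, mod = mod))
    }
  }
  # globals: macro states, then globals referenced by contingencies
  macro <- cat_of %in% c("macro_transition", "macro_synthesis")
  g <- c(reactions$a_name[macro], reactions$b_name[macro])
  g <- c(g, contingencies$target, contingencies$effector)
  g <- unique(g[!is.na(g) & is_global_id(g)])
  for (gl in g) push(state_row(gl, "global", gl))
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), variant = character(0),
                      comp_a = character(0), locus_a = character(0),
                      comp_b = character(0), locus_b = character(0),
                      mod = character(0), neutral = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

derive_gates <- function(contingencies) {
  member <- contingencies$modifier %in% c("AND", "OR", "NOT")
  if (any(member & !is_gate_id(contingencies$target))) {
    stop("AND/OR/NOT rows must target a gate id (<...>): row(s) ",
         paste(which(member & !is_gate_id(contingencies$target)), collapse = ", "))
  }
  gates <- list()
  for (i in which(member)) {
    id <- contingencies$target[i]
    gtype <- contingencies$modifier[i]
    if (is.null(gates[[id]])) {
      gates[[id]] <- list(id = id, gtype = gtype, children = character(0))
    } else if (gates[[id]]$gtype != gtype) {
      stop("gate ", id, " mixes ", gates[[id]]$gtype, " and ", gtype, " rows")
    }
    gates[[id]]$children <- c(gates[[id]]$children, contingencies$effector[i])
  }
  for (g in gates) {
    if (g$gtype == "NOT" && length(g$children) != 1L) {
      stop("NOT gate ", g$id, " must have exactly one child")
    }
  }
  # acyclicity over gate-to-gate references
  if (length(gates) > 0L) {
    ids <- names(gates)
    visiting <- character(0)
    done <- character(0)
    visit <- function(id) {
      if (id %in% done) return(invisible(NULL))
      if (id %in% visiting) stop("Boolean gate cycle involving ", id)
      visiting <<- c(visiting, id)
      for (ch in gates[[id]]$children) {
        if (ch %in% ids) visit(ch)
      }
      visiting <<- setdiff(visiting, id)
      done <<- c(done, id)
      invisible(NULL)
    }
    for (id in ids) visit(id)
  }
  gates
}

skeleton_for_row <- function(sys, r) {
  cat_i <- reaction_category(r$rtype, sys$catalogue)
  empty <- list(produced = character(0), consumed = character(0),
                synthesised = character(0), degraded = character(0))
  comp_neutrals <- function(comp) {
    s <- sys$states
    s$id[s$neutral & s$comp_a == comp & s$variant != "global"]
  }
  linked_component <- function(comp, want_kind) {
    comps <- sys$components
    k <- comps$kind[match(comp, comps$name)]
    prot <- if (identical(k, "gene") || identical(k, "mRNA")) {
      comps$protein[match(comp, comps$name)]
    } else {
      comp
    }
    hit <- comps$name[comps$kind == want_kind &
                        (comps$protein %in% prot | comps$name %in% prot)]
    if (length(hit) != 1L) {
      stop("cannot resolve the ", want_kind, " linked to component ", comp)
    }
    hit
  }
  switch(cat_i,
    bond_formation = {
      empty$produced <- bond_state_id(r$a_name, r$a_locus, r$b_name, r$b_locus)
      empty$consumed <- c(unbound_state_id(r$a_name, r$a_locus),
                          unbound_state_id(r$b_name, r$b_locus))
      empty
    },
    bond_dissociation = {
      empty$produced <- c(unbound_state_id(r$a_name, r$a_locus),
                          unbound_state_id(r$b_name, r$b_locus))
      empty$consumed <- bond_state_id(r$a_name, r$a_locus, r$b_name, r$b_locus)
      empty
    },
    mod_addition = {
      mod <- sys$catalogue$mod[match(r$rtype, sys$catalogue$rtype)]
      empty$produced <- mod_state_id(r$b_name, r$b_locus, mod)
      empty$consumed <- unmod_state_id(r$b_name, r$b_locus)
      empty
    },
    mod_removal = {
      mod <- sys$catalogue$mod[match(r$rtype, sys$catalogue$rtype)]
      empty$produced <- unmod_state_id(r$b_name, r$b_locus)
      empty$consumed <- mod_state_id(r$b_name, r$b_locus, mod)
      empty
    },
    transcription = {
      empty$synthesised <- comp_neutrals(linked_component(r$b_name, "mRNA"))
      empty
    },
    translation = {
      empty$synthesised <- comp_neutrals(linked_component(r$b_name, "protein"))
      empty
    },
    synthesis = {
      empty$synthesised <- comp_neutrals(r$b_name)
      empty
    },
    degradation = {
      s <- sys$states
      own <- s$variant != "global" &
        ((!is.na(s$comp_a) & s$comp_a == r$b_name) |
           (!is.na(s$comp_b) & s$comp_b == r$b_name))
      empty$degraded <- s$id[own]
      empty
    },
    macro_transition = {
      empty$consumed <- r$a_name
      empty$produced <- r$b_name
      empty
    },
    macro_synthesis = {
      empty$synthesised <- r$b_name
      empty
    },
    stop("unhandled skeleton category: ", cat_i)
  )
}

#' Skeleton state sets of an elemental reaction
#'
#' Returns the elemental states a reaction produces, consumes, synthesises
#' and degrades, fully determined by its type and its two component specs
#' (degradation additionally enumerates the target's states from the system).
#'
#' @param sys a [rxncon_system()].
#' @param reaction a reaction id present in `sys$reactions$id`.
#' @return list with character vectors `produced`, `consumed`, `synthesised`,
#'   `degraded`.
#' @examples
#' sys <- rxncon_system(data.frame(rtype = "ppi+", a_name = "Cdc28",
#'   a_locus = "cyclin", b_name = "Cln1", b_locus = "cdc28"))
#' skeleton_states(sys, sys$reactions$id[1])
#' @export
skeleton_states <- function(sys, reaction) {
  stopifnot(inherits(sys, "rxncon_system"))
  if (!(reaction %in% sys$reactions$id)) {
    stop("unknown reaction: ", reaction)
  }
  sys$skeletons[[reaction]]
}

index_system <- function(sys) {
  producers <- list(); consumers <- list(); synthesisers <- list()
  degraders <- list()
  addto <- function(index, states, rid) {
    for (s in states) index[[s]] <- c(index[[s]], rid)
    index
  }
  for (rid in names(sys$skeletons)) {
    sk <- sys$skeletons[[rid]]
    producers <- addto(producers, sk$produced, rid)
    consumers <- addto(consumers, sk$consumed, rid)
    synthesisers <- addto(synthesisers, sk$synthesised, rid)
    degraders <- addto(degraders, sk$degraded, rid)
  }
  sys$index <- list(producers = producers, consumers = consumers,
                    synthesisers = synthesisers, degraders = degraders)
  sys
}

#' Mutual-exclusion groups of a system's elemental states
#'
#' All elemental states sharing one locus are mutually exclusive: every
#' domain locus groups its unbound neutral with all bonds attached there,
#' every residue locus groups its unmodified neutral with all modifications.
#' The groups partition the locus-bearing states (presence and global states
#' carry no locus and are excluded).
#'
#' @param sys a [rxncon_system()].
#' @return named list of character vectors, one per locus, named
#'   `Comp_[locus]`.
#' @export
mutual_exclusion_groups <- function(sys) {
  stopifnot(inherits(sys, "rxncon_system"))
  s <- sys$states
  groups <- list()
  keys <- character(0)
  push <- function(key, id) {
    if (!(key %in% keys)) {
      keys <<- c(keys, key)
      groups[[key]] <<- character(0)
    }
    groups[[key]] <<- unique(c(groups[[key]], id))
  }
  for (i in seq_len(nrow(s))) {
    row <- s[i, ]
    if (row$variant %in% c("presence", "global")) next
    push(comp_spec(row$comp_a, row$locus_a), row$id)
    if (row$variant == "bond") push(comp_spec(row$comp_b, row$locus_b), row$id)
  }
  groups
}

#' Validate the consistency of a reaction-contingency system
#'
#' Checks the structural and turnover rules of the knowledge-base layer:
#' \itemize{
#'   \item undefined or never-produced contingency effectors (dangling
#'     effectors; globals and neutral states, which are present by default,
#'     are exempt),
#'   \item modifications with neither a removal reaction nor a degradation of
#'     the carrier (turnover violations), unless the adding reaction is
#'     flagged `no_turnover`,
#'   \item synthesised components without any degradation reaction, unless
#'     the synthesising reaction is flagged `no_turnover`,
#'   \item effectors of reaction-level contingencies that are gates or states
#'     resolvable in the system.
#' }
#' Gate cycles and malformed rows are rejected at construction time and do
#' not reach this report.
#'
#' @param sys a [rxncon_system()].
#' @return a data.frame with columns `level`, `rule`, `object`, `message`;
#'   zero rows iff the system passes.
#' @export
validate_system <- function(sys) {
  stopifnot(inherits(sys, "rxncon_system"))
  findings <- list()
  note <- function(level, rule, object, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, rule = rule, object = object, message = message,
      stringsAsFactors = FALSE)
  }
  state_ids <- sys$states$id
  gate_ids <- names(sys$gates)
  producible <- unique(c(names(sys$index$producers),
                         names(sys$index$synthesisers)))

  reg <- sys$contingencies[sys$contingencies$modifier %in% c("!", "x", "k+", "k-"), ,
                           drop = FALSE]
  effectors <- unique(c(reg$effector,
                        unlist(lapply(sys$gates, `[[`, "children"))))
  for (e in effectors) {
    if (is_gate_id(e)) {
      if (!(e %in% gate_ids)) {
        note("error", "undefined-effector", e, "gate referenced but never defined")
      }
      next
    }
    if (is_global_id(e)) next
    if (!(e %in% state_ids)) {
      note("error", "undefined-effector", e,
           "state not in any reaction skeleton")
      next
    }
    neutral <- sys$states$neutral[match(e, state_ids)]
    if (!neutral && !(e %in% producible)) {
      note("warning", "dangling-effector", e,
           "effector state has no producing reaction")
    }
  }

  # turnover of covalent modifications
  cat_of <- reaction_category(sys$reactions$rtype, sys$catalogue)
  degraded_comps <- unique(sys$reactions$b_name[cat_of == "degradation"])
  for (i in which(cat_of == "mod_addition")) {
    r <- sys$reactions[i, ]
    if (isTRUE(r$no_turnover)) next
    mod <- sys$catalogue$mod[match(r$rtype, sys$catalogue$rtype)]
    ms <- mod_state_id(r$b_name, r$b_locus, mod)
    removers <- which(cat_of == "mod_removal")
    removed <- any(vapply(removers, function(j) {
      ms %in% sys$skeletons[[sys$reactions$id[j]]]$consumed
    }, logical(1)))
    if (!removed && !(r$b_name %in% degraded_comps)) {
      note("warning", "turnover", r$id,
           paste0("modification ", ms,
                  " has neither a removal reaction nor degradation of ",
                  r$b_name))
    }
  }

  # turnover of synthesised components
  for (i in which(cat_of %in% c("transcription", "translation", "synthesis"))) {
    r <- sys$reactions[i, ]
    if (isTRUE(r$no_turnover)) next
    sk <- sys$skeletons[[r$id]]
    if (length(sk$synthesised) == 0L) next
    made <- unique(sys$states$comp_a[match(sk$synthesised, sys$states$id)])
    for (comp in made) {
      if (!(comp %in% degraded_comps)) {
        note("warning", "no-degradation", r$id,
             paste0("synthesised component ", comp,
                    " has no degradation reaction"))
      }
    }
  }

  if (length(findings) == 0L) {
    return(data.frame(level = character(0), rule = character(0),
                      object = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' Census of a reaction-contingency system
#'
#' @param sys a [rxncon_system()].
#' @return list of counts: components (total and by kind), reactions (total,
#'   elemental, macro), elemental states (total, by variant), contingencies
#'   (total, by modifier), gates, globals, mutual-exclusion groups.
#' @export
system_stats <- function(sys) {
  stopifnot(inherits(sys, "rxncon_system"))
  cat_of <- reaction_category(sys$reactions$rtype, sys$catalogue)
  macro <- cat_of %in% c("macro_transition", "macro_synthesis")
  s <- sys$states
  list(
    components = nrow(sys$components),
    components_by_kind = table_to_list(sys$components$kind),
    reactions = nrow(sys$reactions),
    elemental_reactions = sum(!macro),
    macro_reactions = sum(macro),
    states = sum(s$variant != "global"),
    states_by_variant = table_to_list(s$variant),
    globals = sum(s$variant == "global"),
    contingencies = nrow(sys$contingencies),
    contingencies_by_modifier = table_to_list(sys$contingencies$modifier),
    gates = length(sys$gates),
    mutual_exclusion_groups = length(mutual_exclusion_groups(sys))
  )
}

table_to_list <- function(x) {
  if (length(x) == 0L) return(list())
  as.list(table(x))
}

#' @export
print.rxncon_system <- function(x, ...) {
  st <- system_stats(x)
  cat("rxncon_system:", st$components, "components,",
      st$elemental_reactions, "elemental +", st$macro_reactions,
      "macro reactions,", st$states, "elemental states,",
      st$contingencies, "contingencies,", st$gates, "gates,",
      st$globals, "globals\n")
  invisible(x)
}

#' Semantic equality of two systems
#'
#' Compares components, reactions (ids, flags), contingencies and catalogue,
#' ignoring row order within each table and any free annotation columns.
#'
#' @param a,b two [rxncon_system()] objects.
#' @return logical scalar.
#' @export
systems_equal <- function(a, b) {
  stopifnot(inherits(a, "rxncon_system"), inherits(b, "rxncon_system"))
  sorted <- function(df, cols) {
    df <- df[, cols, drop = FALSE]
    df[do.call(order, df), , drop = FALSE]
  }
  comp_eq <- isTRUE(all.equal(
    sorted(a$components, c("name", "kind", "protein")),
    sorted(b$components, c("name", "kind", "protein")),
    check.attributes = FALSE))
  rx_cols <- c("id", "rtype", "a_name", "a_locus", "b_name", "b_locus",
               "no_turnover", "slow")
  rx_eq <- isTRUE(all.equal(sorted(a$reactions, rx_cols),
                            sorted(b$reactions, rx_cols),
                            check.attributes = FALSE))
  ct_cols <- c("target", "modifier", "effector")
  ct_eq <- isTRUE(all.equal(sorted(a$contingencies, ct_cols),
                            sorted(b$contingencies, ct_cols),
                            check.attributes = FALSE))
  cat_cols <- c("rtype", "category", "mod", "delayed_by_default")
  cat_eq <- isTRUE(all.equal(sorted(a$catalogue, cat_cols),
                             sorted(b$catalogue, cat_cols),
                             check.attributes = FALSE))
  comp_eq && rx_eq && ct_eq && cat_eq
}
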