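#' @title Canonical naming grammar for elemental states and reactions
#'
#' @description
#' Identifiers follow a fixed textual grammar so that every object in a
#' reaction-contingency system has one greppable canonical name:
#' \itemize{
#'   \item bond between two domain loci: \code{A_[x]--B_[y]}
#'   \item unbound (neutral) domain locus: \code{A_[x]--0}
#'   \item covalent modification at a residue: \code{A_[r]-P} (suffix is the
#'         modification kind, e.g. \code{P}, \code{Ub})
#'   \item unmodified (neutral) residue: \code{A_[r]-0}
#'   \item component presence state (components without declared loci, e.g.
#'         genes, mRNAs, enzymatic activities): the bare component name \code{A}
#'   \item global input/output/macro state: \code{[Name]}
#'   \item Boolean gate: \code{<Name>}
#'   \item reaction: \code{Aspec_rtype_Bspec}, where a component spec is
#'         \code{Name} or \code{Name_[locus]}; monomolecular reactions with
#'         B identical to A collapse to \code{Aspec_rtype}.
#' }
#' @name naming
#' @keywords internal
NULL

comp_spec <- function(name, locus = NA_character_) {
  ifelse(is.na(locus) | locus == "", name, paste0(name, "_[", locus, "]"))
}

bond_state_id <- function(a, la, b, lb) {
  paste0(comp_spec(a, la), "--", comp_spec(b, lb))
}

unbound_state_id <- function(a, la) paste0(comp_spec(a, la), "--0")

mod_state_id <- function(a, ra, mod) paste0(comp_spec(a, ra), "-", mod)

unmod_state_id <- function(a, ra) paste0(comp_spec(a, ra), "-0")

presence_state_id <- function(a) a

is_global_id <- function(x) grepl("^\\[[^][]+\\]$", x)

is_gate_id <- function(x) startsWith(x, "<") & endsWith(x, ">")

reaction_id <- function(rtype, a, la, b, lb) {
  a_spec <- comp_spec(a, la)
  b_spec <- comp_spec(b, lb)
  same <- !is.na(b) & b == a & ((is.na(la) & is.na(lb)) |
    (!is.na(la) & !is.na(lb) & la == lb))
  ifelse(same | is.na(b) | b == "",
    paste0(a_spec, "_", rtype),
    paste0(a_spec, "_", rtype, "_", b_spec)
  )
}

#' Parse a canonical elemental-state identifier
#'
#' Inverts the naming grammar. Used to resolve contingency effector strings
#' against the state universe of a system.
#'
#' @param id character scalar, a canonical state identifier.
#' @return a list with elements \code{variant} (one of \code{"bond"},
#'   \code{"unbound"}, \code{"modification"}, \code{"unmodified"},
#'   \code{"presence"}, \code{"global"}), and the relevant
#'   \code{comp_a}/\code{locus_a}/\code{comp_b}/\code{locus_b}/\code{mod}
#'   fields (\code{NA} where not applicable).
#' @examples
#' parse_state_id("Cdc28_[cyclin]--Cln2_[cdc28]")
#' parse_state_id("Sic1_[t2]-P")
#' parse_state_id("[Nutrients]")
#' @export
parse_state_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, !is.na(id))
  na <- NA_character_
  out <- list(variant = na, comp_a = na, locus_a = na,
              comp_b = na, locus_b = na, mod = na)
  if (is_global_id(id)) {
    out$variant <- "global"
    out$comp_a <- id
    return(out)
  }
  spec_rx <- "([A-Za-z0-9]+)(?:_\\[([^]]+)\\])?"
  if (grepl("--", id, fixed = TRUE)) {
    halves <- strsplit(id, "--", fixed = TRUE)[[1L]]
    if (length(halves) != 2L) stop("malformed bond state id: ", id)
    m <- regmatches(halves[1L], regexec(paste0("^", spec_rx, "$"), halves[1L]))[[1L]]
    if (length(m) == 0L) stop("malformed state id: ", id)
    out$comp_a <- m[2L]
    out$locus_a <- if (m[3L] == "") na else m[3L]
    if (halves[2L] == "0") {
      out$variant <- "unbound"
    } else {
      m2 <- regmatches(halves[2L], regexec(paste0("^", spec_rx, "$"), halves[2L]))[[1L]]
      if (length(m2) == 0L) stop("malformed state id: ", id)
      out$variant <- "bond"
      out$comp_b <- m2[2L]
      out$locus_b <- if (m2[3L] == "") na else m2[3L]
    }
    return(out)
  }
  m <- regmatches(id, regexec(paste0("^", spec_rx, "(?:-([A-Za-z0-9]+))?$"), id))[[1L]]
  if (length(m) == 0L) stop("malformed state id: ", id)
  out$comp_a <- m[2L]
  out$locus_a <- if (m[3L] == "") na else m[3L]
  if (m[4L] == "") {
    if (!is.na(out$locus_a)) stop("locus without modification suffix: ", id)
    out$variant <- "presence"
  } else if (m[4L] == "0") {
    out$variant <- "unmodified"
  } else {
    out$variant <- "modification"
    out$mod <- m[4L]
  }
  out
}

#' Neutral complement of an elemental state
#'
#' Bonds map to the unbound state at each participating locus; modifications
#' map to the unmodified residue. Neutral and global states have no complement.
#'
#' @param id canonical state identifier.
#' @return character vector of neutral-complement state ids (length 0 for
#'   neutral, presence and global states).
#' @export
neutral_complement <- function(id) {
  p <- parse_state_id(id)
  switch(p$variant,
    bond = c(unbound_state_id(p$comp_a, p$locus_a),
             unbound_state_id(p$comp_b, p$locus_b)),
    modification = unmod_state_id(p$comp_a, p$locus_a),
    character(0)
  )
}
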