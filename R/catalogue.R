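#' The reaction-type catalogue
#'
#' Skeleton generation is data-driven: each reaction type maps to one of nine
#' skeleton rule templates (categories). The default catalogue covers the
#' machinery any reaction-contingency cell-cycle model needs; model files can
#' carry their own catalogue table (\code{ReactionTypeList}) to bind other
#' type names without code change.
#'
#' Categories and their skeleton rules (A and B are the two component specs):
#' \describe{
#'   \item{bond_formation}{produce \code{A_[x]--B_[y]}, consume both unbound
#'     neutrals; loci must be domains.}
#'   \item{bond_dissociation}{the reverse.}
#'   \item{mod_addition}{produce \code{B_[r]-m}, consume \code{B_[r]-0}; the
#'     modified locus must be a residue of B; A is the catalysing component.}
#'   \item{mod_removal}{the reverse.}
#'   \item{transcription}{synthesise the presence state of the mRNA linked to
#'     the gene component B.}
#'   \item{translation}{synthesise the neutral states of the protein linked to
#'     the mRNA component B.}
#'   \item{synthesis}{synthesise the neutral states of B.}
#'   \item{degradation}{degrade every elemental state of B.}
#'   \item{macro_transition}{coarse-grained cycle step: consume the global
#'     macro state named in the A slot, produce the one in the B slot;
#'     \code{macro_synthesis} produces the B state only (cycle entry).}
#' }
#'
#' @return data.frame with columns \code{rtype}, \code{category}, \code{mod}
#'   (modification kind for mod_addition/mod_removal, else \code{NA}) and
#'   \code{delayed_by_default} (whether the default delay rule applies).
#' @seealso [skeleton_states()], [delay_spec()]
#' @export
default_reaction_types <- function() {
  data.frame(
    rtype = c("ppi+", "ppi-", "P+", "P-", "Ub+", "Ub-",
              "trsc", "trsl", "syn", "deg", "mt", "msyn"),
    category = c("bond_formation", "bond_dissociation",
                 "mod_addition", "mod_removal",
                 "mod_addition", "mod_removal",
                 "transcription", "translation", "synthesis", "degradation",
                 "macro_transition", "macro_synthesis"),
    mod = c(NA, NA, "P", "P", "Ub", "Ub", NA, NA, NA, NA, NA, NA),
    delayed_by_default = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                           TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

catalogue_categories <- c(
  "bond_formation", "bond_dissociation", "mod_addition", "mod_removal",
  "transcription", "translation", "synthesis", "degradation",
  "macro_transition", "macro_synthesis"
)

check_catalogue <- function(catalogue) {
  req <- c("rtype", "category", "mod", "delayed_by_default")
  missing <- setdiff(req, names(catalogue))
  if (length(missing) > 0L) {
    stop("reaction-type catalogue lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(catalogue$category, catalogue_categories)
  if (length(bad) > 0L) {
    stop("unknown skeleton categories in catalogue: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(catalogue$rtype)) stop("duplicate reaction types in catalogue")
  needs_mod <- catalogue$category %in% c("mod_addition", "mod_removal")
  if (any(needs_mod & (is.na(catalogue$mod) | catalogue$mod == ""))) {
    stop("mod_addition/mod_removal types must declare a modification kind")
  }
  invisible(catalogue)
}
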