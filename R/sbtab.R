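#' @title SBtab-compatible model files
#'
#' @description
#' A model file is a set of SBtab tables. The native serialisation is a
#' single tab-separated text file in which each table starts with a
#' `!!SBtab ... TableType='...'` declaration line followed by a header row
#' of `!`-prefixed column names; `.xlsx`/`.xls` workbooks (one table per
#' sheet, discovered by the `!!SBtab` declaration in the first cell, never
#' by sheet name) are read through readxl when it is installed.
#'
#' Recognised tables (by `TableType`):
#' \describe{
#'   \item{ReactionList}{columns `!UID:Reaction`, `!ComponentA:Name`,
#'     `!ComponentA:Domain`, `!ComponentA:Residue`, `!Reaction` (the
#'     reaction type), `!ComponentB:Name`, `!ComponentB:Domain`,
#'     `!ComponentB:Residue`; optional `!Timescale` (`slow` marks the row for
#'     the default delay rule) and `!NoTurnover` (exempts the row's product
#'     from the turnover validation rules); any further columns are free
#'     annotation and survive a write/parse round trip.}
#'   \item{ContingencyList}{columns `!UID:Contingency`, `!Target`,
#'     `!Contingency` (the modifier: `!`, `x`, `k+`, `k-`, or `AND`/`OR`/
#'     `NOT` for Boolean-gate membership) and `!Modifier` (the effector
#'     state, input or gate).}
#'   \item{ComponentList}{optional; columns `!Name`, `!Kind`, `!Protein`.}
#'   \item{ReactionTypeList}{optional reaction-type catalogue; columns
#'     `!ReactionType`, `!Category`, `!Modification`, `!DelayedByDefault`.
#'     Absent, the default catalogue applies.}
#' }
#' @name sbtab
NULL

rx_req_cols <- c("!UID:Reaction", "!ComponentA:Name", "!ComponentA:Domain",
                 "!ComponentA:Residue", "!Reaction", "!ComponentB:Name",
                 "!ComponentB:Domain", "!ComponentB:Residue")
rx_opt_cols <- c("!Timescale", "!NoTurnover")
ct_req_cols <- c("!UID:Contingency", "!Target", "!Contingency", "!Modifier")

sbtab_table_type <- function(decl) {
  m <- regmatches(decl, regexec("TableType='([^']+)'", decl))[[1L]]
  if (length(m) == 2L) m[2L] else NA_character_
}

# split the raw cell matrix of one table into header + body data.frame
sbtab_block_df <- function(cells) {
  header_row <- which(vapply(seq_len(nrow(cells)), function(i) {
    startsWith(cells[i, 1L], "!") && !startsWith(cells[i, 1L], "!!")
  }, logical(1)))[1L]
  if (is.na(header_row)) return(NULL)
  header <- cells[header_row, ]
  keep <- header != ""
  header <- header[keep]
  body <- cells[-seq_len(header_row), keep, drop = FALSE]
  # drop fully empty and comment rows
  if (nrow(body) > 0L) {
    nonempty <- apply(body, 1L, function(r) any(r != "")) &
      !startsWith(body[, 1L], "%")
    body <- body[nonempty, , drop = FALSE]
  }
  df <- as.data.frame(body, stringsAsFactors = FALSE)
  names(df) <- header
  df
}

read_sbtab_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "%")]
  starts <- which(startsWith(lines, "!!SBtab"))
  if (length(starts) == 0L) {
    stop("no !!SBtab table declarations found in ", path)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  tables <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    type <- sbtab_table_type(block[1L])
    rows <- strsplit(block, "\t", fixed = TRUE)
    ncol <- max(vapply(rows, length, integer(1)))
    cells <- t(vapply(rows, function(r) {
      c(r, rep("", ncol - length(r)))
    }, character(ncol)))
    df <- sbtab_block_df(cells)
    if (!is.na(type) && !is.null(df)) tables[[type]] <- df
  }
  tables
}

read_sbtab_excel <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading .xls/.xlsx model files requires the readxl package")
  }
  tables <- list()
  for (sheet in readxl::excel_sheets(path)) {
    raw <- suppressMessages(readxl::read_excel(
      path, sheet = sheet, col_names = FALSE, col_types = "text"))
    if (nrow(raw) == 0L || ncol(raw) == 0L) next
    cells <- as.matrix(raw)
    cells[is.na(cells)] <- ""
    if (!startsWith(cells[1L, 1L], "!!SBtab")) next
    type <- sbtab_table_type(cells[1L, 1L])
    df <- sbtab_block_df(cells)
    if (!is.na(type) && !is.null(df)) tables[[type]] <- df
  }
  if (length(tables) == 0L) {
    stop("no sheets with an !!SBtab declaration found in ", path)
  }
  tables
}

need_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("parse error: ", table, " table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
}

truthy <- function(x) {
  tolower(trimws(x)) %in% c("x", "yes", "true", "1", "slow")
}

#' Parse an SBtab-compatible model file into a reaction-contingency system
#'
#' @param path path to a `.tsv`/`.txt` SBtab file or a `.xlsx`/`.xls`
#'   workbook (sheets discovered by their `!!SBtab` declaration line).
#' @param catalogue reaction-type catalogue to use when the file carries no
#'   `ReactionTypeList` table.
#' @return a [rxncon_system()]; row order of the sheets is preserved in the
#'   system's canonical reaction and contingency order. Malformed rows are
#'   reported with their row numbers; contingencies referencing undefined
#'   effectors are left to [validate_system()] rather than rejected.
#' @seealso [write_model()], [validate_system()]
#' @export
parse_model <- function(path, catalogue = default_reaction_types()) {
  ext <- tolower(tools::file_ext(path))
  tables <- if (ext %in% c("xls", "xlsx")) {
    read_sbtab_excel(path)
  } else {
    read_sbtab_tsv(path)
  }
  if (is.null(tables$ReactionList)) {
    stop("parse error: model file has no ReactionList table")
  }
  if (is.null(tables$ContingencyList)) {
    stop("parse error: model file has no ContingencyList table")
  }
  if (!is.null(tables$ReactionTypeList)) {
    tt <- tables$ReactionTypeList
    need_cols(tt, c("!ReactionType", "!Category"), "ReactionTypeList")
    catalogue <- data.frame(
      rtype = tt[["!ReactionType"]],
      category = tt[["!Category"]],
      mod = if (is.null(tt[["!Modification"]])) NA_character_ else
        ifelse(tt[["!Modification"]] == "", NA, tt[["!Modification"]]),
      delayed_by_default = if (is.null(tt[["!DelayedByDefault"]])) FALSE else
        truthy(tt[["!DelayedByDefault"]]),
      stringsAsFactors = FALSE)
  }
  check_catalogue(catalogue)

  rt <- tables$ReactionList
  need_cols(rt, rx_req_cols, "ReactionList")
  pick_locus <- function(domain, residue) {
    ifelse(domain != "", domain, ifelse(residue != "", residue, NA_character_))
  }
  reactions <- data.frame(
    uid = rt[["!UID:Reaction"]],
    rtype = rt[["!Reaction"]],
    a_name = rt[["!ComponentA:Name"]],
    a_locus = pick_locus(rt[["!ComponentA:Domain"]], rt[["!ComponentA:Residue"]]),
    b_name = rt[["!ComponentB:Name"]],
    b_locus = pick_locus(rt[["!ComponentB:Domain"]], rt[["!ComponentB:Residue"]]),
    no_turnover = if (is.null(rt[["!NoTurnover"]])) FALSE else truthy(rt[["!NoTurnover"]]),
    slow = if (is.null(rt[["!Timescale"]])) FALSE else truthy(rt[["!Timescale"]]),
    stringsAsFactors = FALSE)
  extra_rx <- setdiff(names(rt), c(rx_req_cols, rx_opt_cols))
  for (col in extra_rx) reactions[[col]] <- rt[[col]]

  ct <- tables$ContingencyList
  need_cols(ct, ct_req_cols, "ContingencyList")
  contingencies <- data.frame(
    uid = ct[["!UID:Contingency"]],
    target = ct[["!Target"]],
    modifier = ct[["!Contingency"]],
    effector = ct[["!Modifier"]],
    stringsAsFactors = FALSE)
  extra_ct <- setdiff(names(ct), ct_req_cols)
  for (col in extra_ct) contingencies[[col]] <- ct[[col]]
  if (nrow(contingencies) == 0L) contingencies <- NULL

  components <- NULL
  if (!is.null(tables$ComponentList) && nrow(tables$ComponentList) > 0L) {
    cl <- tables$ComponentList
    need_cols(cl, c("!Name", "!Kind"), "ComponentList")
    components <- data.frame(
      name = cl[["!Name"]],
      kind = cl[["!Kind"]],
      protein = if (is.null(cl[["!Protein"]])) NA_character_ else
        ifelse(cl[["!Protein"]] == "", NA, cl[["!Protein"]]),
      stringsAsFactors = FALSE)
  }
  if (nrow(reactions) == 0L) reactions <- NULL
  if (is.null(reactions)) {
    return(rxncon_system(NULL, contingencies, components, catalogue))
  }
  rxncon_system(reactions, contingencies, components, catalogue)
}

sbtab_decl <- function(type) {
  paste0("!!SBtab SBtabVersion='1.0' Document='rxncycle' TableType='", type,
         "' TableName='", type, "'")
}

format_table <- function(type, header, rows) {
  lines <- c(sbtab_decl(type), paste(header, collapse = "\t"))
  if (length(rows) > 0L) lines <- c(lines, rows)
  lines
}

tsv_row <- function(...) paste(vapply(list(...), function(x) {
  x <- as.character(x)
  ifelse(is.na(x), "", x)
}, character(1)), collapse = "\t")

#' Write a reaction-contingency system as an SBtab TSV model file
#'
#' Serialises components, the reaction-type catalogue, reactions and
#' contingencies as SBtab tables in one tab-separated text file. The output
#' is deterministic (system order) and `parse_model(write_model(sys))`
#' reproduces `sys` up to row order within sheets; free annotation columns
#' are written back verbatim.
#'
#' @param sys a [rxncon_system()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(sys, path) {
  stopifnot(inherits(sys, "rxncon_system"))
  lines <- character(0)

  comps <- sys$components
  lines <- c(lines, format_table(
    "ComponentList", c("!Name", "!Kind", "!Protein"),
    vapply(seq_len(nrow(comps)), function(i) {
      tsv_row(comps$name[i], comps$kind[i], comps$protein[i])
    }, character(1))), "")

  cat_tab <- sys$catalogue
  lines <- c(lines, format_table(
    "ReactionTypeList",
    c("!ReactionType", "!Category", "!Modification", "!DelayedByDefault"),
    vapply(seq_len(nrow(cat_tab)), function(i) {
      tsv_row(cat_tab$rtype[i], cat_tab$category[i], cat_tab$mod[i],
              if (cat_tab$delayed_by_default[i]) "yes" else "")
    }, character(1))), "")

  rx <- sys$reactions
  cat_of <- reaction_category(rx$rtype, sys$catalogue)
  extra_rx <- setdiff(names(rx), c("id", "uid", "rtype", "a_name", "a_locus",
                                   "b_name", "b_locus", "no_turnover", "slow"))
  locus_cols <- function(comp, locus) {
    if (is.na(locus)) return(c("", ""))
    kind <- sys$loci$kind[sys$loci$component == comp & sys$loci$locus == locus]
    if (length(kind) == 1L && kind == "residue") c("", locus) else c(locus, "")
  }
  rx_rows <- vapply(seq_len(nrow(rx)), function(i) {
    a <- locus_cols(rx$a_name[i], rx$a_locus[i])
    b <- locus_cols(rx$b_name[i], rx$b_locus[i])
    mono <- cat_of[i] %in% c("transcription", "translation", "synthesis") ||
      (rx$b_name[i] == rx$a_name[i] &&
         identical(rx$b_locus[i], rx$a_locus[i]) &&
         !(cat_of[i] %in% c("macro_transition", "macro_synthesis")))
    do.call(tsv_row, c(list(rx$uid[i], rx$a_name[i], a[1L], a[2L],
                            rx$rtype[i],
                            if (mono && cat_of[i] != "degradation") "" else rx$b_name[i],
                            b[1L], b[2L],
                            if (rx$slow[i]) "slow" else "",
                            if (rx$no_turnover[i]) "yes" else ""),
                       lapply(extra_rx, function(col) rx[[col]][i])))
  }, character(1))
  lines <- c(lines, format_table(
    "ReactionList", c(rx_req_cols[1:4], "!Reaction", rx_req_cols[6:8],
                      "!Timescale", "!NoTurnover", extra_rx),
    rx_rows), "")

  ct <- sys$contingencies
  extra_ct <- setdiff(names(ct), c("uid", "target", "modifier", "effector"))
  ct_rows <- vapply(seq_len(nrow(ct)), function(i) {
    do.call(tsv_row, c(list(ct$uid[i], ct$target[i], ct$modifier[i],
                            ct$effector[i]),
                       lapply(extra_ct, function(col) ct[[col]][i])))
  }, character(1))
  lines <- c(lines, format_table(
    "ContingencyList", c(ct_req_cols, extra_ct), ct_rows))

  writeLines(lines, path)
  invisible(path)
}
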