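#' @title Fiber and enzyme bond catalogs
#' @description Readers and validators for the two curated catalogs behind the
#'   enzyme-fiber interaction matrix: the set of glycosidic bonds present in
#'   each dietary fiber, and the set of bonds each glycoside hydrolase
#'   (EC 3.2.1.*) or polysaccharide lyase (EC 4.2.2.*) can cleave.
#' @name catalog
NULL

.gh_pl_regex <- "^(3\\.2\\.1|4\\.2\\.2)\\.[0-9]+$"

#' Test whether EC numbers belong to the GH/PL classes
#'
#' @param ec Character vector of EC numbers.
#' @return Logical vector: TRUE for glycoside hydrolases (3.2.1.*) and
#'   polysaccharide lyases (4.2.2.*).
#' @export
is_gh_pl_ec <- function(ec) grepl(.gh_pl_regex, ec)

#' Read a fiber catalog
#'
#' The fiber table is TSV with columns `name`, `abbreviation`, `bonds`
#' (semicolon-separated canonical bond tokens) and optionally `solubility`.
#' Abbreviations must be unique and every fiber must carry at least one bond.
#'
#' @param path Path to the TSV file.
#' @param sugars Controlled sugar vocabulary for bond validation.
#' @return A data.frame with columns `name`, `abbreviation`, `solubility` and
#'   a list-column `bonds` of canonical bond tokens.
#' @export
read_fiber_catalog <- function(path, sugars = df_sugar_codes()) {
  if (!file.exists(path)) stop("fiber catalog not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "abbreviation", "bonds")
  if (!all(need %in% names(tab))) {
    stop("fiber catalog must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dup <- tab$abbreviation[duplicated(tab$abbreviation)]
  if (length(dup) > 0) {
    stop("duplicate fiber abbreviation(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bonds <- lapply(seq_len(nrow(tab)), function(i) {
    parse_bond_set(tab$bonds[i], sugars = sugars,
                   where = paste0(basename(path), " line ", i + 1L))
  })
  data.frame(
    name = tab$name,
    abbreviation = tab$abbreviation,
    solubility = if ("solubility" %in% names(tab)) tab$solubility else NA_character_,
    bonds = I(bonds),
    stringsAsFactors = FALSE
  )
}

#' Read an enzyme catalog
#'
#' The enzyme table is TSV with columns `ec` and `bonds` (semicolon-separated
#' canonical bond tokens). One row per EC; ECs must match the GH/PL patterns
#' 3.2.1.* or 4.2.2.*.
#'
#' @inheritParams read_fiber_catalog
#' @return A data.frame with column `ec` and a list-column `bonds`.
#' @export
read_enzyme_catalog <- function(path, sugars = df_sugar_codes()) {
  if (!file.exists(path)) stop("enzyme catalog not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("ec", "bonds") %in% names(tab))) {
    stop("enzyme catalog must have columns: ec, bonds", call. = FALSE)
  }
  dup <- tab$ec[duplicated(tab$ec)]
  if (length(dup) > 0) {
    stop("duplicate EC(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_ec <- tab$ec[!is_gh_pl_ec(tab$ec)]
  if (length(bad_ec) > 0) {
    stop("EC(s) outside the GH (3.2.1.*) / PL (4.2.2.*) classes: ",
         paste(bad_ec, collapse = ", "), call. = FALSE)
  }
  bonds <- lapply(seq_len(nrow(tab)), function(i) {
    parse_bond_set(tab$bonds[i], sugars = sugars,
                   where = paste0(basename(path), " line ", i + 1L))
  })
  data.frame(ec = tab$ec, bonds = I(bonds), stringsAsFactors = FALSE)
}

#' Parse the fiber and enzyme catalogs together
#'
#' @param fiber_table Path to the fiber TSV.
#' @param enzyme_table Path to the enzyme TSV.
#' @param sugars Controlled sugar vocabulary.
#' @return A list with elements `fibers` and `enzymes` (see
#'   [read_fiber_catalog()] and [read_enzyme_catalog()]).
#' @export
parse_catalogs <- function(fiber_table, enzyme_table, sugars = df_sugar_codes()) {
  list(fibers = read_fiber_catalog(fiber_table, sugars = sugars),
       enzymes = read_enzyme_catalog(enzyme_table, sugars = sugars))
}

#' Load the packaged default catalog
#'
#' The default catalog covers 24 dietary fibers (inulin through resistant
#' starch) with bond sets curated from the structural chemistry of each
#' polysaccharide, plus GH/PL enzymes annotated with the bonds their EC
#' reaction cleaves. It ships as plain TSV under `inst/extdata/` so users can
#' extend or replace it.
#'
#' @return A list with `fibers` and `enzymes` data.frames.
#' @export
default_catalog <- function() {
  parse_catalogs(
    system.file("extdata", "fibers.tsv", package = "ifdp", mustWork = TRUE),
    system.file("extdata", "enzymes.tsv", package = "ifdp", mustWork = TRUE)
  )
}

#' Build the binary enzyme-fiber interaction matrix
#'
#' Entry (i, j) is 1 iff enzyme i can cleave at least one bond present in
#' fiber j, i.e. the two bond sets intersect. Enzymes whose bonds match no
#' fiber keep an all-zero row so the enzyme index always spans the full GH/PL
#' profile.
#'
#' @param fibers Fiber catalog data.frame (with `abbreviation`, `bonds`).
#' @param enzymes Enzyme catalog data.frame (with `ec`, `bonds`).
#' @return Binary integer matrix, rows = ECs, columns = fiber abbreviations.
#' @export
build_interaction_matrix <- function(fibers, enzymes) {
  if (nrow(fibers) == 0 || nrow(enzymes) == 0) {
    stop("both catalogs must be non-empty", call. = FALSE)
  }
  all_bonds <- unique(c(unlist(fibers$bonds), unlist(enzymes$bonds)))
  # indicator matrices over the shared bond universe; M = (E %*% t(F)) > 0
  eb <- vapply(enzymes$bonds, function(b) as.integer(all_bonds %in% b),
               integer(length(all_bonds)))
  fb <- vapply(fibers$bonds, function(b) as.integer(all_bonds %in% b),
               integer(length(all_bonds)))
  eb <- matrix(eb, nrow = length(all_bonds))
  fb <- matrix(fb, nrow = length(all_bonds))
  M <- (t(eb) %*% fb > 0) * 1L
  dimnames(M) <- list(enzymes$ec, fibers$abbreviation)
  M
}

#' Write / read an interaction matrix as TSV
#'
#' First column `EC`, remaining columns one per fiber abbreviation, values 0/1.
#'
#' @param M Interaction matrix (rows = ECs).
#' @param path Output path.
#' @return `write_interaction_matrix` returns `path` invisibly;
#'   `read_interaction_matrix` returns the integer matrix.
#' @export
write_interaction_matrix <- function(M, path) {
  df <- data.frame(EC = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "integer"
  rownames(M) <- df[[1]]
  if (!all(M %in% c(0L, 1L))) stop("interaction matrix must be binary", call. = FALSE)
  M
}
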