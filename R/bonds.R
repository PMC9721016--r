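#' Controlled vocabulary of monosaccharide codes
#'
#' Short codes for the sugar residues that appear as donors/acceptors of
#' glycosidic bonds in the packaged catalogs. `GlcA`/`GalA`/`ManA`/`GulA` are
#' uronic acids, `GlcNAc` is N-acetyl-glucosamine and `AnGal` is
#' 3,6-anhydro-galactose (carrageenan). Catalog parsers accept an extended
#' vocabulary via their `sugars` argument.
#'
#' @return Character vector of accepted sugar codes.
#' @export
df_sugar_codes <- function() {
  c("Glc", "Fru", "Gal", "Xyl", "Ara", "Man", "Rha", "Fuc",
    "GlcA", "GalA", "ManA", "GulA", "GlcNAc", "AnGal")
}

.bond_regex <- "^([ab])([0-9]+)-([0-9]+):([A-Za-z]+)-([A-Za-z]+)$"

#' Parse canonical glycosidic-bond tokens
#'
#' A bond is written `"<anomeric><donor_pos>-<acceptor_pos>:<donor>-<acceptor>"`,
#' e.g. `"b1-4:Glc-Glc"` for the beta-1,4 glucose-glucose linkage of cellulose.
#' Serialization is canonical: two bonds are the same bond iff their tokens are
#' equal, and parsing followed by re-serialization round-trips.
#'
#' @param tokens Character vector of bond tokens.
#' @param sugars Controlled vocabulary of sugar codes.
#' @return A data.frame with columns `anomeric`, `donor_pos`, `acceptor_pos`,
#'   `donor_sugar`, `acceptor_sugar`, `canonical`.
#' @export
parse_bond <- function(tokens, sugars = df_sugar_codes()) {
  stopifnot(is.character(tokens))
  bad <- !grepl(.bond_regex, tokens)
  if (any(bad)) {
    stop("malformed bond token(s): ", paste(tokens[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- regmatches(tokens, regexec(.bond_regex, tokens))
  out <- data.frame(
    anomeric      = vapply(m, `[`, "", 2L),
    donor_pos     = as.integer(vapply(m, `[`, "", 3L)),
    acceptor_pos  = as.integer(vapply(m, `[`, "", 4L)),
    donor_sugar   = vapply(m, `[`, "", 5L),
    acceptor_sugar = vapply(m, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(unique(c(out$donor_sugar, out$acceptor_sugar)), sugars)
  if (length(unknown) > 0) {
    stop("unknown sugar code(s): ", paste(unknown, collapse = ", "),
         " (not in the controlled vocabulary)", call. = FALSE)
  }
  out$canonical <- serialize_bond(out)
  out
}

#' Serialize parsed bonds back to canonical tokens
#'
#' @param bonds A data.frame as returned by [parse_bond()].
#' @return Character vector of canonical tokens.
#' @export
serialize_bond <- function(bonds) {
  paste0(bonds$anomeric, bonds$donor_pos, "-", bonds$acceptor_pos, ":",
         bonds$donor_sugar, "-", bonds$acceptor_sugar)
}

# Split a semicolon-separated bond-set cell into validated canonical tokens.
# `where` names the offending location in error messages (e.g. "fibers.tsv line 3").
parse_bond_set <- function(cell, sugars = df_sugar_codes(), where = NULL) {
  if (length(cell) != 1 || is.na(cell)) cell <- ""
  toks <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) {
    stop("empty bond set", if (!is.null(where)) paste0(" at ", where),
         call. = FALSE)
  }
  parsed <- tryCatch(
    parse_bond(toks, sugars = sugars),
    error = function(e) {
      stop(conditionMessage(e),
           if (!is.null(where)) paste0(" at ", where), call. = FALSE)
    }
  )
  unique(parsed$canonical)
}
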