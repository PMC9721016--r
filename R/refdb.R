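#' @title Reference protein databases
#' @description A reference database holds the protein sequences reads are
#'   aligned against, with accession-level metadata (EC annotations, length,
#'   review status). Three scopes are used: `fiber_specific` (GH/PL enzymes
#'   only, the basis of the fiber-specific profile), `complete` (all
#'   EC-annotated proteins, the basis of the complete functional profile) and
#'   `uscg_markers` (universal single-copy marker families used for
#'   normalization, with family IDs in place of ECs).
#' @name refdb
NULL

.aa_ok_regex <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Build a reference protein database
#'
#' Reads an amino-acid FASTA and an accession metadata table and assembles the
#' records admitted to the requested scope. For `fiber_specific`, only
#' accessions carrying at least one GH (3.2.1.*) or PL (4.2.2.*) EC are kept,
#' and their EC sets are restricted to those classes. For `complete`, all
#' records with a non-empty EC set are kept. For `uscg_markers` the `ecs`
#' column carries marker-family IDs and no EC pattern is enforced.
#'
#' @param fasta Path to a protein FASTA file.
#' @param metadata Path to a TSV with columns `accession`, `ecs`
#'   (semicolon-separated), `source` (`reviewed`/`unreviewed`).
#' @param scope One of `"fiber_specific"`, `"complete"`, `"uscg_markers"`.
#' @param quiet Suppress the record-count summary message.
#' @return An object of class `reference_db`: list with `records` (data.frame
#'   `accession`, `length_aa`, `source`, list-column `ecs`), `sequences`
#'   (named `AAStringSet`) and `scope`.
#' @export
build_reference_db <- function(fasta, metadata,
                               scope = c("fiber_specific", "complete", "uscg_markers"),
                               quiet = FALSE) {
  scope <- match.arg(scope)
  # the Biostrings reader silently drops invalid residue codes (warning
  # only); promote that to an error so corrupt inputs cannot slip through
  seqs <- withCallingHandlers(
    Biostrings::readAAStringSet(fasta),
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w))) {
        stop("non-amino-acid characters in FASTA: ", fasta, call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0) stop("empty FASTA: ", fasta, call. = FALSE)
  # FASTA headers may carry descriptions; the accession is the first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  chr <- as.character(seqs)
  bad_aa <- names(seqs)[!grepl(.aa_ok_regex, chr)]
  if (length(bad_aa) > 0) {
    stop("non-amino-acid characters in sequence(s): ",
         paste(bad_aa, collapse = ", "), call. = FALSE)
  }
  meta <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  need <- c("accession", "ecs", "source")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(names(seqs), meta$accession)
  if (length(missing) > 0) {
    stop("accession(s) missing from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(names(seqs), meta$accession), ]
  ecs <- lapply(strsplit(meta$ecs, ";", fixed = TRUE),
                function(x) unique(trimws(x[nzchar(trimws(x))])))
  keep <- switch(scope,
    fiber_specific = vapply(ecs, function(e) any(is_gh_pl_ec(e)), logical(1)),
    complete       = lengths(ecs) > 0,
    uscg_markers   = lengths(ecs) > 0
  )
  if (scope == "fiber_specific") {
    ecs <- lapply(ecs, function(e) e[is_gh_pl_ec(e)])
  }
  seqs <- seqs[keep]
  records <- data.frame(
    accession = names(seqs),
    length_aa = nchar(chr[keep]),
    source = meta$source[keep],
    stringsAsFactors = FALSE
  )
  records$ecs <- I(ecs[keep])
  db <- structure(list(records = records, sequences = seqs, scope = scope),
                  class = "reference_db")
  if (!quiet) {
    message(sprintf("reference_db [%s]: %d records, %d distinct annotations",
                    scope, nrow(records), length(unique(unlist(records$ecs)))))
  }
  db
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db [%s]: %d records, %d distinct annotations\n",
              x$scope, nrow(x$records), length(unique(unlist(x$records$ecs)))))
  invisible(x)
}

#' Accession-level lookup map
#'
#' @param db A `reference_db`.
#' @return Named list: accession -> list(`ecs`, `length_aa`).
#' @export
ec_map <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  out <- Map(function(e, l) list(ecs = e, length_aa = l),
             db$records$ecs, db$records$length_aa)
  names(out) <- db$records$accession
  out
}

#' Packaged universal single-copy marker family IDs
#'
#' A representative list of 76 universal single-copy gene families used for
#' copy-number normalization. The list is a synthetic stand-in (see the file
#' name): family IDs only; marker sequences are user-supplied.
#'
#' @return Character vector of 76 family IDs.
#' @export
uscg_marker_ids <- function() {
  path <- system.file("extdata", "uscg_markers_synthetic.txt",
                      package = "ifdp", mustWork = TRUE)
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
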