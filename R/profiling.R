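#' @title From reads to fiber degradation profiles
#' @description Operations turning translated-search alignments (or genome
#'   annotations) into per-sample enzyme abundance profiles and, via the
#'   enzyme-fiber interaction matrix, into inferred fiber degradation
#'   profiles (IFDPs).
#' @name profiling
NULL

#' Subsample a FASTQ file to a fixed depth
#'
#' Samples exactly `depth` reads uniformly without replacement (deterministic
#' for a fixed seed). Samples with fewer reads than `depth` are flagged
#' discarded rather than written. Paired-end mates are treated as independent
#' reads. An input at exactly `depth` reads is written through unchanged.
#'
#' @param fastq_in Input FASTQ path.
#' @param fastq_out Output FASTQ path (written only when not discarded).
#' @param depth Target read count (default 4e6).
#' @param seed Integer seed.
#' @return List with `discarded` (logical), `n_reads` (input depth), `depth`
#'   and `path` (output path or NA when discarded).
#' @export
subsample_reads <- function(fastq_in, fastq_out, depth = 4e6, seed = 1L) {
  reads <- read_fastq_checked(fastq_in)
  n <- length(reads)
  if (n < depth) {
    return(list(discarded = TRUE, n_reads = n, depth = depth, path = NA_character_))
  }
  if (n > depth) {
    idx <- sort(with_seed(seed, sample.int(n, depth)))
    reads <- reads[idx]
  }
  write_fastq(reads, fastq_out)
  list(discarded = FALSE, n_reads = n, depth = depth, path = fastq_out)
}

#' Parse a 12-column BLAST-style tabular alignment file
#'
#' Expects the standard translated-search tabular layout
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Malformed lines are rejected with their line number.
#'
#' @param path Path to the tabular file.
#' @return data.frame with columns `read_id`, `accession`, `identity_pct`,
#'   `evalue`, `bitscore`.
#' @export
parse_alignment_table <- function(path) {
  if (!file.exists(path)) stop("alignment table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(read_id = character(), accession = character(),
                      identity_pct = numeric(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("expected 12 tab-separated columns; offending line(s): ",
         paste(which(nf != 12L), collapse = ", "), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  bitscore <- suppressWarnings(as.numeric(m[, 12]))
  identity <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(evalue) | is.na(bitscore) | is.na(identity))
  if (length(bad) > 0) {
    stop("non-numeric evalue/bitscore/identity at line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(read_id = m[, 1], accession = m[, 2], identity_pct = identity,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

#' Select the best database hit per read
#'
#' Hits at or above the e-value cutoff are dropped (the cutoff is strict:
#' e-value < `evalue_max` is required). Per read the hit with the highest
#' bitscore is kept; ties are broken by lower e-value, then lexicographically
#' smallest accession, so selection is deterministic.
#'
#' @param hits data.frame as from [parse_alignment_table()] or
#'   [translated_search_naive()].
#' @param evalue_max Strict e-value cutoff (default 10).
#' @return Named character vector: read_id -> accession.
#' @export
select_best_hits <- function(hits, evalue_max = 10) {
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (nrow(hits) == 0) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$read_id, -hits$bitscore, hits$evalue, hits$accession)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$read_id), , drop = FALSE]
  stats::setNames(best$accession, best$read_id)
}

#' Aggregate read assignments into EC counts
#'
#' Reads assigned to a protein annotated with exactly one EC increment that
#' EC's count. Reads assigned to multi-EC proteins are discarded to avoid
#' ambiguity, and reported as an ambiguity fraction.
#'
#' @param assignments Named character vector read_id -> accession.
#' @param ecmap Accession map from [ec_map()].
#' @param ec_universe Optional character vector fixing the EC index of the
#'   returned count vector (zeros for unobserved ECs).
#' @return List with `counts` (named numeric), `n_assigned`, `n_ambiguous`,
#'   `ambiguity_fraction`.
#' @export
aggregate_by_ec <- function(assignments, ecmap, ec_universe = NULL) {
  accs <- unname(assignments)
  unknown <- setdiff(unique(accs), names(ecmap))
  if (length(unknown) > 0) {
    stop("accession(s) absent from the reference map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_ec <- vapply(ecmap[accs], function(x) length(x$ecs), integer(1))
  single <- n_ec == 1L
  ecs_hit <- vapply(ecmap[accs[single]], function(x) x$ecs[[1]], character(1))
  if (is.null(ec_universe)) {
    ec_universe <- sort(unique(unlist(lapply(ecmap, function(x)
      if (length(x$ecs) == 1L) x$ecs else character(0)))))
  }
  counts <- stats::setNames(numeric(length(ec_universe)), ec_universe)
  if (length(ecs_hit) > 0) {
    tab <- table(factor(ecs_hit, levels = ec_universe))
    counts[] <- as.numeric(tab)
  }
  n <- length(accs)
  n_amb <- sum(!single)
  list(counts = counts, n_assigned = n, n_ambiguous = n_amb,
       ambiguity_fraction = if (n > 0) n_amb / n else 0)
}

#' Filter low-abundance features from a profile
#'
#' A feature (EC or taxon) is removed when its within-sample relative
#' abundance is strictly below `min_rel_abundance` in at least
#' `sample_fraction` of the samples (defaults: below 0.01% in 90% of
#' samples). Filtering never increases a retained value and is idempotent.
#'
#' @param profile Numeric matrix, samples as rows, features as columns.
#' @param min_rel_abundance Relative-abundance threshold (strict "below").
#' @param sample_fraction Fraction of samples that must be below threshold.
#' @return List with `profile` (kept columns), `kept`, `removed`.
#' @export
filter_low_abundance <- function(profile, min_rel_abundance = 1e-4,
                                 sample_fraction = 0.9) {
  stopifnot(is.matrix(profile), nrow(profile) >= 1,
            min_rel_abundance > 0, min_rel_abundance < 1,
            sample_fraction > 0, sample_fraction < 1)
  rs <- rowSums(profile)
  if (any(rs == 0)) {
    stop("all-zero sample row(s): ",
         paste(rownames(profile)[rs == 0], collapse = ", "),
         " (relative abundance undefined)", call. = FALSE)
  }
  rel <- profile / rs
  frac_below <- colMeans(rel < min_rel_abundance)
  keep <- frac_below < sample_fraction
  list(profile = profile[, keep, drop = FALSE],
       kept = colnames(profile)[keep],
       removed = colnames(profile)[!keep])
}

#' Compute the inferred fiber degradation profile
#'
#' Multiplies a samples-by-enzymes profile by the binary enzyme-fiber
#' interaction matrix: IFDP[s, j] = sum_i profile[s, i] * M[i, j], i.e. the
#' per-fiber aggregation of the abundances of all enzymes that can cleave a
#' bond of that fiber. Profile ECs must be a subset of the matrix enzyme
#' index; missing matrix rows are implicit zeros for the profile but an EC in
#' the profile absent from the matrix is an error (catalog incompleteness is
#' surfaced, not silently dropped).
#'
#' @param profile Numeric matrix, samples x ECs (colnames are ECs).
#' @param M Interaction matrix (rows = ECs, cols = fiber abbreviations).
#' @return Numeric matrix samples x fibers with the `units_tag` attribute
#'   inherited from `profile` (default "counts").
#' @export
compute_ifdp <- function(profile, M) {
  stopifnot(is.matrix(profile), is.matrix(M))
  unmatched <- setdiff(colnames(profile), rownames(M))
  if (length(unmatched) > 0) {
    stop("EC(s) in profile absent from the interaction matrix: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  full <- matrix(0, nrow = nrow(profile), ncol = nrow(M),
                 dimnames = list(rownames(profile), rownames(M)))
  full[, colnames(profile)] <- profile
  out <- full %*% M
  attr(out, "units_tag") <- attr(profile, "units_tag") %||% "counts"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-copy-gene normalization of an EC count profile
#'
#' Counts are corrected for gene length (count / length, in amino acids),
#' and each sample is divided by its normalization variable: the median of
#' the length-corrected abundances of the universal single-copy marker
#' families in that sample. The result is in average-copy-number-like units:
#' a single-copy gene at the same coverage as the markers scores 1.0, and the
#' profile is invariant to scaling all counts in a sample.
#'
#' @param ec_counts Samples x genes count matrix (or a named vector for a
#'   single sample).
#' @param uscg_counts Samples x marker-family count matrix (same samples).
#' @param ec_lengths Named numeric vector of gene lengths (aa) for the
#'   columns of `ec_counts`.
#' @param uscg_lengths Named numeric vector of marker lengths (aa).
#' @return List with `profile` (normalized matrix, `units_tag = "musicc"`)
#'   and `factors` (per-sample normalization variable).
#' @export
musicc_normalize <- function(ec_counts, uscg_counts, ec_lengths, uscg_lengths) {
  if (is.null(dim(ec_counts))) ec_counts <- t(as.matrix(ec_counts))
  if (is.null(dim(uscg_counts))) uscg_counts <- t(as.matrix(uscg_counts))
  stopifnot(nrow(ec_counts) == nrow(uscg_counts),
            ncol(ec_counts) == length(ec_lengths),
            ncol(uscg_counts) == length(uscg_lengths),
            all(ec_lengths > 0), all(uscg_lengths > 0))
  lc_ec <- sweep(ec_counts, 2, ec_lengths, "/")
  lc_uscg <- sweep(uscg_counts, 2, uscg_lengths, "/")
  factors <- apply(lc_uscg, 1, stats::median)
  if (any(factors == 0)) {
    stop("normalization variable is zero for sample(s): ",
         paste(rownames(ec_counts)[factors == 0], collapse = ", "),
         " (no single-copy marker signal; sample unusable)", call. = FALSE)
  }
  out <- lc_ec / factors
  attr(out, "units_tag") <- "musicc"
  list(profile = out, factors = factors)
}

#' Fiber degradation capacity of a single genome
#'
#' For an annotated genome (EC -> gene copy count), the capacity vector is
#' the copy-count vector times the interaction matrix.
#'
#' @param genome_ec_annotations Named numeric vector, EC -> copy count.
#' @param M Interaction matrix.
#' @return Named numeric vector over the matrix's fiber index.
#' @export
genome_ifdp <- function(genome_ec_annotations, M) {
  ecs <- names(genome_ec_annotations)
  if (length(ecs) > 0 && !all(is_gh_pl_ec(ecs))) {
    stop("non-GH/PL EC(s) in genome annotation: ",
         paste(ecs[!is_gh_pl_ec(ecs)], collapse = ", "), call. = FALSE)
  }
  v <- stats::setNames(numeric(nrow(M)), rownames(M))
  common <- intersect(ecs, rownames(M))
  v[common] <- genome_ec_annotations[common]
  drop(v %*% M)
}
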