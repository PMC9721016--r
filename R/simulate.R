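#' @title Synthetic communities, reads and fixtures
#' @description Seed-deterministic generators for synthetic reads with
#'   ground-truth tables, used to validate the profiling pipeline, plus the
#'   masked-genome false-discovery experiment at desk scale. The error model
#'   is a uniform per-base substitution model (a documented simplification of
#'   platform-specific error profiles).
#' @name simulate
NULL

# One fixed codon per amino acid (first codon in lexicographic order).
# Degeneracy is irrelevant to translated matching, which works in peptide
# space after translation.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  aas <- sort(unique(gc))
  stats::setNames(vapply(aas, function(a) sort(names(gc)[gc == a])[1], ""), aas)
}

#' Reverse-translate an amino-acid sequence with a fixed codon table
#'
#' @param aa Amino-acid string.
#' @return DNA string (3x the length).
#' @export
reverse_translate <- function(aa) {
  ct <- codon_table()
  chars <- strsplit(aa, "")[[1]]
  unknown <- setdiff(unique(chars), names(ct))
  if (length(unknown) > 0) {
    stop("cannot reverse-translate symbol(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  paste0(ct[chars], collapse = "")
}

# Deterministic random protein sequences over the 20-letter alphabet.
random_proteins <- function(n, length_aa, seed = 1L, prefix = "P") {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    stats::setNames(
      vapply(seq_len(n), function(i) {
        paste0(sample(aas, length_aa, replace = TRUE), collapse = "")
      }, ""),
      paste0(prefix, seq_len(n)))
  })
}

# Apply uniform per-base substitutions to a character vector of reads.
apply_substitutions <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  widths <- nchar(reads)
  n_bases <- sum(widths)
  hit <- which(stats::runif(n_bases) < error_rate)
  if (length(hit) == 0) return(reads)
  ends <- cumsum(widths)
  read_of <- findInterval(hit - 1L, ends) + 1L
  pos_in <- hit - c(0L, ends)[read_of]
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(hit)) {
    r <- read_of[j]; p <- pos_in[j]
    old <- substr(reads[r], p, p)
    new <- sample(setdiff(bases, old), 1L)
    substr(reads[r], p, p) <- new
  }
  reads
}

#' Simulate community reads from proteins with known EC labels
#'
#' Reads are drawn from the coding sequences of the given proteins
#' (reverse-translated with a fixed codon table) with source proteins chosen
#' proportionally to `abundances`, positions uniform, both strands equally
#' likely, and uniform per-base substitution errors. A truth table recording
#' every read's source is returned (and optionally written) alongside.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param ecs Character vector of EC labels, one per protein.
#' @param abundances Non-negative weights summing to 1 (normalized if not).
#' @param n_reads Number of reads (0 gives empty outputs).
#' @param read_length Read length in nt; must not exceed the shortest coding
#'   sequence.
#' @param error_rate Per-base substitution probability in [0, 0.2].
#' @param seed Integer seed.
#' @param fastq_out,truth_out Optional output paths (FASTQ / TSV).
#' @return List with `reads` (named `DNAStringSet`) and `truth` (data.frame
#'   `read_id`, `source_accession`, `ec`, `strand`, `position`).
#' @export
generate_community_reads <- function(proteins, ecs, abundances, n_reads,
                                     read_length = 100L, error_rate = 0.005,
                                     seed = 1L, fastq_out = NULL,
                                     truth_out = NULL) {
  stopifnot(length(proteins) == length(ecs),
            length(proteins) == length(abundances),
            all(abundances >= 0), sum(abundances) > 0,
            n_reads >= 0, error_rate >= 0, error_rate <= 0.2)
  abundances <- abundances / sum(abundances)
  cds <- vapply(proteins, reverse_translate, "")
  if (n_reads > 0 && read_length > min(nchar(cds))) {
    stop("read_length (", read_length, ") exceeds the shortest coding ",
         "sequence (", min(nchar(cds)), " nt)", call. = FALSE)
  }
  if (n_reads == 0) {
    reads <- Biostrings::DNAStringSet()
    truth <- data.frame(read_id = character(), source_accession = character(),
                        ec = character(), strand = character(),
                        position = integer(), stringsAsFactors = FALSE)
  } else {
    sim <- with_seed(seed, {
      src <- sample.int(length(cds), n_reads, replace = TRUE, prob = abundances)
      maxstart <- nchar(cds)[src] - read_length + 1L
      pos <- 1L + as.integer(floor(stats::runif(n_reads) * maxstart))
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)
      seqs <- substring(cds[src], pos, pos + read_length - 1L)
      seqs <- apply_substitutions(seqs, error_rate)
      list(src = src, pos = pos, strand = strand, seqs = seqs)
    })
    reads <- Biostrings::DNAStringSet(sim$seqs)
    rc <- sim$strand == "-"
    if (any(rc)) reads[rc] <- Biostrings::reverseComplement(reads[rc])
    names(reads) <- sprintf("read_%06d", seq_len(n_reads))
    S4Vectors::mcols(reads)$qualities <- Biostrings::BStringSet(
      rep(paste(rep("I", read_length), collapse = ""), n_reads))
    truth <- data.frame(read_id = names(reads),
                        source_accession = names(proteins)[sim$src],
                        ec = ecs[sim$src], strand = sim$strand,
                        position = sim$pos, stringsAsFactors = FALSE)
  }
  if (!is.null(fastq_out)) write_fastq(reads, fastq_out)
  if (!is.null(truth_out)) {
    utils::write.table(truth, truth_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}

#' Mask annotated intervals of a genome
#'
#' Replaces the given coding intervals with `N` runs, so no residual peptide
#' seed of any length can match the masked proteins (`N` codons translate to
#' `X`, outside the database alphabet).
#'
#' @param genome DNA string (character scalar).
#' @param intervals data.frame with `start`, `end` (1-based, inclusive).
#' @return Masked genome string; the interval list is kept as the
#'   `"masked_intervals"` attribute.
#' @export
mask_genome <- function(genome, intervals) {
  stopifnot(is.character(genome), length(genome) == 1)
  len <- nchar(genome)
  if (nrow(intervals) > 0 &&
      (any(intervals$start < 1) || any(intervals$end > len) ||
       any(intervals$start > intervals$end))) {
    stop("annotation interval outside genome bounds", call. = FALSE)
  }
  for (i in seq_len(nrow(intervals))) {
    w <- intervals$end[i] - intervals$start[i] + 1L
    substr(genome, intervals$start[i], intervals$end[i]) <-
      paste(rep("N", w), collapse = "")
  }
  attr(genome, "masked_intervals") <- intervals
  genome
}

# Uniform shotgun reads from one or more genomes (weighted by length),
# both strands, with a truth table of origins.
simulate_genome_reads <- function(genomes, n_reads, read_length = 100L,
                                  error_rate = 0, seed = 1L) {
  stopifnot(is.character(genomes), !is.null(names(genomes)))
  lens <- nchar(genomes)
  if (any(lens < read_length)) {
    stop("read_length exceeds a genome length", call. = FALSE)
  }
  sim <- with_seed(seed, {
    g <- sample.int(length(genomes), n_reads, replace = TRUE,
                    prob = lens - read_length + 1)
    pos <- 1L + as.integer(floor(stats::runif(n_reads) *
                                   (lens[g] - read_length + 1L)))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(genomes[g], pos, pos + read_length - 1L)
    seqs <- apply_substitutions(seqs, error_rate)
    list(g = g, pos = pos, strand = strand, seqs = seqs)
  })
  reads <- Biostrings::DNAStringSet(sim$seqs)
  rc <- sim$strand == "-"
  if (any(rc)) reads[rc] <- Biostrings::reverseComplement(reads[rc])
  names(reads) <- sprintf("read_%06d", seq_len(n_reads))
  truth <- data.frame(read_id = names(reads), genome = names(genomes)[sim$g],
                      strand = sim$strand, position = sim$pos,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Masked-genome false-discovery experiment
#'
#' Shotgun reads are simulated once from genomes whose annotated GH/PL coding
#' intervals have been masked and once from the unmasked genomes; both read
#' sets are mapped to the reference database with the naive translated
#' matcher and best-hit selection. Any hit from the masked run is a false
#' discovery by construction; the ratio of masked to unmasked hit counts
#' estimates the mapping false-discovery rate.
#'
#' @param genomes Named character vector of genome sequences.
#' @param annotations data.frame with `genome`, `start`, `end` giving the
#'   GH/PL coding intervals.
#' @param db A `reference_db` holding the GH/PL proteins.
#' @param n_reads Reads per run (desk scale, e.g. 1e5).
#' @param read_length Read length (nt).
#' @param seed Integer seed (masked and unmasked runs use derived seeds).
#' @param min_peptide_seed Seed length for the matcher.
#' @return List with `hits_masked`, `hits_unmasked`, `fdr_estimate`,
#'   `assignments_unmasked` (read -> accession), `truth_unmasked`.
#' @export
mask_and_simulate_fdr <- function(genomes, annotations, db, n_reads = 1e5,
                                  read_length = 100L, seed = 1L,
                                  min_peptide_seed = 10L) {
  stopifnot(all(annotations$genome %in% names(genomes)))
  masked <- genomes
  for (g in unique(annotations$genome)) {
    iv <- annotations[annotations$genome == g, c("start", "end"), drop = FALSE]
    masked[g] <- mask_genome(genomes[[g]], iv)
  }
  run <- function(gn, run_seed) {
    sim <- simulate_genome_reads(gn, n_reads, read_length, seed = run_seed)
    hits <- translated_search_naive(sim$reads, db,
                                    min_peptide_seed = min_peptide_seed)
    list(assign = select_best_hits(hits), truth = sim$truth)
  }
  m <- run(masked, seed)
  u <- run(genomes, seed + 1L)
  hm <- length(m$assign)
  hu <- length(u$assign)
  list(hits_masked = hm, hits_unmasked = hu,
       fdr_estimate = if (hu > 0) hm / hu else NA_real_,
       assignments_unmasked = u$assign, truth_unmasked = u$truth)
}
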