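#' @title Naive translated search
#' @description A deliberately simple six-frame translated matcher used for
#'   fixtures and simulations, so that no external aligner binary is needed.
#'   Production pipelines should use a dedicated translated aligner and feed
#'   its 12-column tabular output to [parse_alignment_table()].
#' @name search
NULL

# Seed index: peptide k-mer -> encoded (protein, position) entries.
build_peptide_index <- function(seqs, k) {
  nk <- pmax(nchar(seqs) - k + 1L, 0L)
  prot <- rep(seq_along(seqs), nk)
  pos <- sequence(nk)
  kmers <- substring(rep(seqs, nk), pos, pos + k - 1L)
  maxl <- max(nchar(seqs)) + 1L
  code <- (prot - 1L) * maxl + pos
  list(map = split(code, kmers), maxl = maxl,
       total_aa = sum(nchar(seqs)))
}

#' Six-frame translated search against a reference database
#'
#' Each read is translated in all six frames; a candidate hit is seeded by an
#' exact peptide match of length `min_peptide_seed` to a database protein and
#' extended ungapped over the full read-protein overlap. Scoring uses
#' documented simple constants: bitscore = 2 bits per identical residue, and
#' e-value = (database residues) x (peptide length) x 2^(-bitscore). Stop
#' codons and ambiguous codons translate to `*`/`X`, which never match the
#' database alphabet, so seeds cannot cross them.
#'
#' @param reads A `DNAStringSet`, or a path to a FASTQ/FASTA file.
#' @param db A `reference_db`.
#' @param min_peptide_seed Minimum exact-match peptide seed length.
#' @param chunk_size Reads processed per chunk (memory control).
#' @return data.frame with columns `read_id`, `accession`, `evalue`,
#'   `bitscore`, `identity_pct` (one row per read-protein pair, best frame).
#' @export
translated_search_naive <- function(reads, db, min_peptide_seed = 10L,
                                    chunk_size = 5000L) {
  stopifnot(inherits(db, "reference_db"), min_peptide_seed >= 4)
  if (is.character(reads)) {
    reads <- if (grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
      read_fastq_checked(reads)
    } else {
      Biostrings::readDNAStringSet(reads)
    }
  }
  if (length(reads) == 0) {
    return(data.frame(read_id = character(), accession = character(),
                      evalue = numeric(), bitscore = numeric(),
                      identity_pct = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  k <- as.integer(min_peptide_seed)
  prot_seqs <- as.character(db$sequences)
  idx <- build_peptide_index(prot_seqs, k)
  prot_chars <- strsplit(prot_seqs, "")
  accs <- names(db$sequences)

  res <- list()
  starts_at <- seq(1L, length(reads), by = chunk_size)
  for (cs in starts_at) {
    ce <- min(cs + chunk_size - 1L, length(reads))
    x <- reads[cs:ce]
    hits <- search_chunk(x, idx, prot_chars, accs, k)
    if (!is.null(hits)) res[[length(res) + 1L]] <- hits
  }
  if (length(res) == 0) {
    return(data.frame(read_id = character(), accession = character(),
                      evalue = numeric(), bitscore = numeric(),
                      identity_pct = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

search_chunk <- function(x, idx, prot_chars, accs, k) {
  # translate all six frames; collect peptides with their read index
  peps <- character(0); ridx <- integer(0)
  for (strand in 1:2) {
    src <- if (strand == 1) x else Biostrings::reverseComplement(x)
    for (off in 0:2) {
      w <- Biostrings::width(src)
      wd <- ((w - off) %/% 3L) * 3L
      ok <- which(wd >= 3L)
      if (length(ok) == 0) next
      sub <- Biostrings::subseq(src[ok], start = off + 1L, width = wd[ok])
      p <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X")))
      peps <- c(peps, unname(p))
      ridx <- c(ridx, ok)
    }
  }
  keep <- nchar(peps) >= k
  peps <- peps[keep]; ridx <- ridx[keep]
  if (length(peps) == 0) return(NULL)

  nk <- nchar(peps) - k + 1L
  rpos <- sequence(nk)
  pep_i <- rep(seq_along(peps), nk)
  kmers <- substring(peps[pep_i], rpos, rpos + k - 1L)
  mm <- match(kmers, names(idx$map))
  sel <- which(!is.na(mm))
  if (length(sel) == 0) return(NULL)

  entries <- idx$map[mm[sel]]
  nrep <- lengths(entries)
  cand <- data.frame(
    pep_i = rep(pep_i[sel], nrep),
    rpos = rep(rpos[sel], nrep),
    code = unlist(entries, use.names = FALSE)
  )
  cand$prot <- (cand$code - 1L) %/% idx$maxl + 1L
  cand$ppos <- (cand$code - 1L) %% idx$maxl + 1L
  # leftmost seed per (read-frame, protein)
  cand <- cand[order(cand$pep_i, cand$prot, cand$rpos), ]
  cand <- cand[!duplicated(cand[c("pep_i", "prot")]), ]

  n <- nrow(cand)
  bits <- numeric(n); idpct <- numeric(n); plen <- integer(n)
  pep_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    pi <- cand$pep_i[i]
    key <- as.character(pi)
    pc <- pep_cache[[key]]
    if (is.null(pc)) {
      pc <- strsplit(peps[pi], "")[[1]]
      pep_cache[[key]] <- pc
    }
    sc <- prot_chars[[cand$prot[i]]]
    offset <- cand$ppos[i] - cand$rpos[i]
    r1 <- max(1L, 1L - offset)
    r2 <- min(length(pc), length(sc) - offset)
    seg_r <- pc[r1:r2]
    seg_s <- sc[(r1 + offset):(r2 + offset)]
    nmatch <- sum(seg_r == seg_s)
    bits[i] <- 2 * nmatch
    idpct[i] <- 100 * nmatch / (r2 - r1 + 1L)
    plen[i] <- length(pc)
  }
  out <- data.frame(
    read_id = names(x)[ridx[cand$pep_i]],
    accession = accs[cand$prot],
    evalue = idx$total_aa * plen * 2^(-bits),
    bitscore = bits,
    identity_pct = idpct,
    stringsAsFactors = FALSE
  )
  # best frame per (read, protein)
  out <- out[order(out$read_id, out$accession, -out$bitscore), ]
  out[!duplicated(out[c("read_id", "accession")]), ]
}
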