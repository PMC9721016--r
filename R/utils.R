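# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

count_lines <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    chunk <- readLines(con, n = 262144L)
    n <- n + length(chunk)
    if (length(chunk) < 262144L) break
  }
  n
}

# Read a FASTQ file into a DNAStringSet with qualities attached; wraps the
# Biostrings reader so malformed/truncated records fail with a clear message.
# Expects 4-line records (no line wrapping), which a truncated trailing
# record violates.
read_fastq_checked <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path, call. = FALSE)
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ record in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (count_lines(path) != 4L * length(reads)) {
    stop("malformed FASTQ in ", path,
         ": line count is not 4 x the number of parsed records ",
         "(truncated record?)", call. = FALSE)
  }
  reads
}

write_fastq <- function(reads, path) {
  if (length(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = S4Vectors::mcols(reads)$qualities)
  invisible(path)
}

# Samples-as-rows profile TSV (first column sample_id, remaining columns
# feature abbreviations/ECs).
write_profile_tsv <- function(profile, path) {
  df <- data.frame(sample_id = rownames(profile), profile, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
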