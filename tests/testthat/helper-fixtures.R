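# In-code fixture builders (no binary data; everything generated at test time).

write_catalog_files <- function(fibers_rows, enzymes_rows, dir = tempdir()) {
  fp <- tempfile("fibers", dir, ".tsv")
  ep <- tempfile("enzymes", dir, ".tsv")
  writeLines(c("name\tabbreviation\tbonds", fibers_rows), fp)
  writeLines(c("ec\tbonds", enzymes_rows), ep)
  list(fibers = fp, enzymes = ep)
}

# Write a protein FASTA + metadata TSV and build a reference_db.
make_protein_db <- function(proteins, ecs, scope = "fiber_specific",
                            source = "reviewed") {
  fa <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(proteins)),
                             unname(proteins))), fa)
  md <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(accession = names(proteins), ecs = ecs, source = source),
    md, sep = "\t", quote = FALSE, row.names = FALSE)
  build_reference_db(fa, md, scope = scope, quiet = TRUE)
}

# A toy genome: random flanks around the coding sequence of one GH protein.
make_gh_genome <- function(protein, flank = 3000, seed = 2) {
  gene <- reverse_translate(protein)
  set.seed(seed)
  f1 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  f2 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  list(genome = c(g1 = paste0(f1, gene, f2)),
       intervals = data.frame(genome = "g1", start = flank + 1L,
                              end = flank + nchar(gene)))
}

write_fastq_lines <- function(seqs, path, quals = NULL) {
  ids <- paste0("@r", seq_along(seqs))
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(ids, seqs, "+", quals)), path)
  path
}
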