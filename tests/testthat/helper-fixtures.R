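# Shared test helpers: temp FASTA files and random sequences.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

lib_to_tmp_fasta <- function(lib) {
  f <- tempfile(fileext = ".fasta")
  write_fasta(lib, f)
  f
}

random_aa <- function(n, pool = c("A", "R", "N", "D", "C", "Q", "E", "G",
                                  "H", "I", "L", "K", "M", "F", "P", "S",
                                  "T", "W", "Y", "V")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

make_lib <- function(residues, accessions = sprintf("S%04d", seq_along(residues))) {
  lib <- data.frame(accession = accessions, gene_id = "", species = "",
                    description = "", residues = residues,
                    stringsAsFactors = FALSE)
  class(lib) <- c("seq_library", "data.frame")
  lib
}

# A 40-residue anchor domain shared by constructed homologs so local
# alignments score well above chance.
ANCHOR <- "MKLVINGKTLKGEITVEAVDAAEAEKIFKQYANDNGVDGE"
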