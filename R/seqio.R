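# FASTA sequence libraries with UniProt-style headers, and per-residue
# disorder-score files.

#' Read a FASTA sequence library
#'
#' Reads a (multi-record) FASTA file into a sequence library. Headers are
#' parsed with [parse_uniprot_header()]; sequence lines are stripped of
#' whitespace and digits and uppercased. Records appear in file order.
#'
#' @param path Path to a FASTA file. Wrapped and unwrapped sequence lines
#'   are both accepted.
#' @return A data frame of class `seq_library` with one row per record and
#'   columns `accession`, `gene_id`, `species`, `description`, `residues`.
#' @details Residues are restricted to the 20 standard amino acids plus the
#'   ambiguity/rare codes X, B, Z, U. An entry with an empty sequence, an
#'   unrecognised residue letter, or a duplicated accession is a format
#'   error.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|O00311|CDC7_HUMAN Kinase OS=Homo sapiens GN=CDC7",
#'              "MEASLG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop("no FASTA records in ", path)
  }
  headers <- names(set)
  seqs <- as.character(set)
  recs <- lapply(seq_along(set), function(i) {
    res <- normalize_residues(seqs[[i]], headers[[i]])
    hdr <- parse_uniprot_header(headers[[i]])
    data.frame(accession = hdr$accession, gene_id = hdr$gene_id,
               species = hdr$species, description = hdr$description,
               residues = res, stringsAsFactors = FALSE)
  })
  lib <- do.call(rbind, recs)
  dup <- duplicated(lib$accession)
  if (any(dup)) {
    stop("duplicated accession in library: ",
         paste(unique(lib$accession[dup]), collapse = ", "))
  }
  class(lib) <- c("seq_library", "data.frame")
  lib
}

normalize_residues <- function(x, header) {
  res <- toupper(gsub("[[:space:][:digit:]]", "", x))
  if (nchar(res) == 0) {
    stop("empty sequence for FASTA entry '", header, "'")
  }
  letters <- strsplit(res, "")[[1]]
  bad <- which(!(letters %in% AA_ACCEPTED))
  if (length(bad) > 0) {
    stop("invalid residue '", letters[bad[1]], "' at position ", bad[1],
         " in entry '", header, "'")
  }
  res
}

#' Write a sequence library to FASTA
#'
#' Inverse of [read_fasta()]: headers are rebuilt in UniProt style
#' (`tr|ACC|ACC description OS=... GN=...`) when gene/species metadata is
#' present, otherwise as the bare accession, so that a read/write round
#' trip preserves accessions and residues exactly.
#'
#' @param lib A `seq_library` data frame.
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(lib, path, width = 60) {
  stopifnot(is.data.frame(lib), all(c("accession", "residues") %in% names(lib)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(lib))) {
    hdr <- format_header(lib[i, ])
    writeLines(paste0(">", hdr), con)
    seq <- lib$residues[i]
    starts <- seq(1, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1, nchar(seq))), con)
  }
  invisible(path)
}

format_header <- function(rec) {
  gene <- rec$gene_id %||% ""
  sp <- rec$species %||% ""
  desc <- rec$description %||% ""
  if (!nzchar(gene) && !nzchar(sp) && !nzchar(desc)) {
    return(rec$accession)
  }
  hdr <- paste0("tr|", rec$accession, "|", rec$accession, "_SYN")
  if (nzchar(desc)) hdr <- paste(hdr, desc)
  if (nzchar(sp)) hdr <- paste0(hdr, " OS=", sp)
  if (nzchar(gene)) hdr <- paste0(hdr, " GN=", gene)
  hdr
}

#' Parse a UniProt-style FASTA header
#'
#' Understands the `db|ACCESSION|ENTRYNAME` prefix used by UniProt (`sp` and
#' `tr` databases) and the `OS=` (organism species) and `GN=` (gene name)
#' tags. For plain headers the accession is the first whitespace-delimited
#' token and the remaining fields are empty.
#'
#' @param header The definition-line text after `>`.
#' @return A list with elements `accession`, `gene_id`, `species`,
#'   `description` (empty strings where absent).
#' @examples
#' parse_uniprot_header(
#'   "sp|Q8SR85|CDC71_ENCCU Cell division control protein 7 homolog 1 OS=Encephalitozoon cuniculi GN=CDC7-1")
#' @export
parse_uniprot_header <- function(header) {
  if (!is.character(header) || length(header) != 1 || !nzchar(trimws(header))) {
    stop("empty FASTA header")
  }
  header <- trimws(header)
  first <- sub("\\s.*$", "", header)
  rest <- sub("^\\S+\\s*", "", header)

  m <- regmatches(first, regexec("^[A-Za-z]+\\|([^|]+)\\|(\\S*)$", first))[[1]]
  accession <- if (length(m) == 3 && nzchar(m[2])) m[2] else first

  species <- extract_tag(rest, "OS")
  gene_id <- extract_tag(rest, "GN")
  # description = free text before the first KEY= tag
  description <- trimws(sub("\\s*\\b[A-Z]{2}=.*$", "", rest))
  list(accession = accession, gene_id = gene_id, species = species,
       description = description)
}

extract_tag <- function(x, tag) {
  # tag values run until the next XX= tag or end of line
  pat <- paste0("\\b", tag, "=(.*?)(\\s+[A-Z]{2}=.*)?$")
  m <- regmatches(x, regexec(pat, x))[[1]]
  if (length(m) >= 2) trimws(m[2]) else ""
}

#' Read a per-residue disorder score file
#'
#' Reads externally computed per-residue disorder scores (e.g. genuine
#' IUPred output) to be injected in place of the built-in predictor. Two
#' plain-text dialects are accepted: one score per line, or `index score`
#' pairs (the index column is ignored beyond dialect detection).
#'
#' @param path Path to the score file.
#' @return A numeric vector of scores in `[0, 1]`, one per residue.
#' @export
read_score_file <- function(path) {
  if (!file.exists(path)) {
    stop("score file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    stop("empty score file: ", path)
  }
  toks <- strsplit(lines, "[[:space:]]+")
  nfield <- lengths(toks)
  if (any(nfield > 2)) {
    stop("malformed score file line ", which(nfield > 2)[1], " in ", path)
  }
  indexed <- all(nfield == 2)
  if (!indexed && any(nfield != 1)) {
    stop("mixed one- and two-column lines in score file ", path)
  }
  vals <- vapply(seq_along(toks), function(i) {
    tok <- toks[[i]][if (indexed) 2 else 1]
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) {
      stop("non-numeric score '", tok, "' on line ", i, " of ", path)
    }
    v
  }, numeric(1))
  out_of_range <- which(vals < 0 | vals > 1)
  if (length(out_of_range) > 0) {
    stop("score out of [0,1] on line ", out_of_range[1], " of ", path,
         ": ", vals[out_of_range[1]])
  }
  vals
}
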