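# Homology search: optimal local alignment against every library sequence
# with Karlin-Altschul E-value statistics. A self-contained replacement for
# a BLASTP stage; an adapter for an external BLAST+ executable is optional
# and never required.

#' Homology search parameters
#'
#' @param evalue_threshold Upper E-value limit for reported hits
#'   (default `1e-10`).
#' @param max_hits Maximum number of hits returned (default 100).
#' @param matrix Substitution matrix name; only `"BLOSUM62"` is built in.
#' @param gap_open,gap_extend Affine gap penalties (positive costs; a gap of
#'   length L costs `gap_open + L * gap_extend`). Defaults 11 and 1, the
#'   standard BLOSUM62 gapped-search setting.
#' @param ka_lambda,ka_K Karlin-Altschul parameters for the E-value
#'   `E = K * m * n * exp(-lambda * S)`. Defaults are the published gapped
#'   constants for BLOSUM62 with gap penalties 11/1 (lambda = 0.267,
#'   K = 0.041). Exact numeric agreement with NCBI BLAST is not promised;
#'   the fixed constants make E-values deterministic and comparable across
#'   subjects.
#' @return A list of class `search_params`.
#' @export
search_params <- function(evalue_threshold = 1e-10, max_hits = 100,
                          matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          ka_lambda = 0.267, ka_K = 0.041) {
  stopifnot(evalue_threshold > 0, max_hits >= 1,
            gap_open > 0, gap_extend > 0, ka_lambda > 0, ka_K > 0)
  if (!identical(matrix, "BLOSUM62")) {
    stop("only the BLOSUM62 substitution matrix is built in")
  }
  structure(list(evalue_threshold = evalue_threshold, max_hits = max_hits,
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 ka_lambda = ka_lambda, ka_K = ka_K),
            class = "search_params")
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman alignment with affine gaps, delegated to
#' [Biostrings::pairwiseAlignment()]. Selenocysteine (U) scores 0 against
#' everything (see [substitution_matrix()]).
#'
#' @param query,subject Residue strings.
#' @param params A [search_params()] object.
#' @return A list with `score`, gapped `query_aln`/`subject_aln` strings and
#'   1-based inclusive `query_start`, `query_end`, `subject_start`,
#'   `subject_end`; or `NULL` when no positive-scoring local alignment
#'   exists.
#' @export
local_align <- function(query, subject, params = search_params()) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(query), Biostrings::BString(subject),
    type = "local", substitutionMatrix = substitution_matrix(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0) {
    return(NULL)
  }
  list(score = s,
       query_aln = as.character(Biostrings::pattern(pa)),
       subject_aln = as.character(Biostrings::subject(pa)),
       query_start = Biostrings::start(Biostrings::pattern(pa)),
       query_end = Biostrings::end(Biostrings::pattern(pa)),
       subject_start = Biostrings::start(Biostrings::subject(pa)),
       subject_end = Biostrings::end(Biostrings::subject(pa)))
}

#' Search a sequence library for homologs of a query
#'
#' Aligns the query locally against every library sequence and converts raw
#' scores to E-values with the Karlin-Altschul formula
#' `E = K * m * n * exp(-lambda * S)`, where `m` is the query length and
#' `n` the total residue count of the library (database-search convention,
#' so E-values are comparable across subjects). Hits with
#' `E <= evalue_threshold` are returned sorted by ascending E-value
#' (ties broken by accession) and truncated to `max_hits`.
#'
#' If the query itself is present in the library — same accession or
#' identical full sequence — its hit is assigned an E-value of exactly 0 and
#' always retained, so the query entry appears as the first row of a scan.
#'
#' @param query A single-row `seq_library` data frame (or a list with
#'   `accession` and `residues`).
#' @param library A `seq_library` data frame.
#' @param params A [search_params()] object.
#' @return A data frame of class `search_hits`, one row per hit, with
#'   columns `subject_accession`, `evalue`, `bitscore`, `raw_score`,
#'   `identity_pct`, `similarity_pct`, `query_aln`, `subject_aln`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`.
#' @export
search_homologs <- function(query, library, params = search_params()) {
  query <- as_seq_record(query)
  if (!is.data.frame(library) || nrow(library) == 0) {
    stop("library is empty")
  }
  if (!nzchar(query$residues)) {
    stop("query sequence is empty")
  }
  m <- nchar(query$residues)
  n_total <- sum(nchar(library$residues))

  rows <- lapply(seq_len(nrow(library)), function(i) {
    subj <- library[i, ]
    aln <- local_align(query$residues, subj$residues, params)
    if (is.null(aln)) {
      return(NULL)
    }
    ev <- karlin_altschul_evalue(aln$score, m, n_total, params)
    self_hit <- identical(subj$accession, query$accession) ||
      identical(subj$residues, query$residues)
    if (self_hit) {
      ev <- 0
    }
    stats <- alignment_stats(aln$query_aln, aln$subject_aln, params$matrix)
    data.frame(subject_accession = subj$accession,
               evalue = ev,
               bitscore = bit_score(aln$score, params),
               raw_score = aln$score,
               identity_pct = stats[["identity_pct"]],
               similarity_pct = stats[["similarity_pct"]],
               query_aln = aln$query_aln, subject_aln = aln$subject_aln,
               query_start = aln$query_start, query_end = aln$query_end,
               subject_start = aln$subject_start,
               subject_end = aln$subject_end,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits) || nrow(hits) == 0) {
    return(empty_hits())
  }
  hits <- hits[hits$evalue <= params$evalue_threshold | hits$evalue == 0, ,
               drop = FALSE]
  if (nrow(hits) == 0) {
    return(empty_hits())
  }
  ord <- order(hits$evalue, hits$subject_accession)
  hits <- hits[ord, , drop = FALSE]
  hits <- head(hits, params$max_hits)
  rownames(hits) <- NULL
  class(hits) <- c("search_hits", "data.frame")
  hits
}

karlin_altschul_evalue <- function(score, m, n, params) {
  params$ka_K * m * n * exp(-params$ka_lambda * score)
}

bit_score <- function(score, params) {
  (params$ka_lambda * score - log(params$ka_K)) / log(2)
}

empty_hits <- function() {
  hits <- data.frame(subject_accession = character(), evalue = numeric(),
                     bitscore = numeric(), raw_score = numeric(),
                     identity_pct = numeric(), similarity_pct = numeric(),
                     query_aln = character(), subject_aln = character(),
                     query_start = integer(), query_end = integer(),
                     subject_start = integer(), subject_end = integer(),
                     stringsAsFactors = FALSE)
  class(hits) <- c("search_hits", "data.frame")
  hits
}

as_seq_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    return(as.list(x))
  }
  stopifnot(is.list(x), !is.null(x$accession), !is.null(x$residues))
  x
}

#' Percent identity and similarity of a gapped alignment
#'
#' Identity is the fraction of columns with equal residues; similarity the
#' fraction of columns whose substitution score is positive (identities
#' included). Both denominators are the full alignment length, gap columns
#' included — one convention has to be fixed, and it is stated in the
#' output documentation.
#'
#' @param query_aln,subject_aln Equal-length gapped alignment strings.
#' @param matrix Substitution matrix name (only `"BLOSUM62"`).
#' @return Named numeric vector with `identity_pct` and `similarity_pct`
#'   in `[0, 100]`.
#' @export
alignment_stats <- function(query_aln, subject_aln, matrix = "BLOSUM62") {
  a <- strsplit(query_aln, "")[[1]]
  b <- strsplit(subject_aln, "")[[1]]
  if (length(a) != length(b)) {
    stop("gapped alignment strings differ in length")
  }
  if (length(a) == 0) {
    stop("empty alignment")
  }
  mat <- substitution_matrix()
  len <- length(a)
  no_gap <- a != "-" & b != "-"
  ident <- no_gap & a == b
  subst_pos <- no_gap & mat[cbind(match(a, rownames(mat)),
                                  match(b, colnames(mat)))] > 0
  simil <- ident | (subst_pos %in% TRUE)
  c(identity_pct = 100 * sum(ident) / len,
    similarity_pct = 100 * sum(simil, na.rm = TRUE) / len)
}

#' Run an external BLAST+ blastp search (optional adapter)
#'
#' Shells out to a `blastp` executable with XML output and parses the hits
#' into the same shape as [search_homologs()]. The built-in search never
#' requires this; the adapter exists so that users with BLAST+ installed
#' can swap in NCBI statistics. BLAST reports its own E-values, so ranks —
#' not E-values — are expected to agree with the built-in engine.
#'
#' @param query A single-row `seq_library` data frame.
#' @param library_path Path to the FASTA library (used as `-subject`).
#' @param params A [search_params()] object.
#' @param blastp Path to the blastp executable.
#' @return A `search_hits` data frame sorted by ascending E-value.
#' @export
external_blast_adapter <- function(query, library_path,
                                   params = search_params(),
                                   blastp = Sys.which("blastp")) {
  if (!nzchar(blastp)) {
    stop("blastp executable not found; use the built-in search_homologs()")
  }
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("the xml2 package is required to parse BLAST XML output")
  }
  query <- as_seq_record(query)
  qfile <- tempfile(fileext = ".fasta")
  on.exit(unlink(qfile))
  writeLines(c(paste0(">", query$accession), query$residues), qfile)
  out <- tempfile(fileext = ".xml")
  on.exit(unlink(out), add = TRUE)
  status <- system2(blastp, c("-query", qfile, "-subject", library_path,
                              "-outfmt", "5",
                              "-evalue", format(params$evalue_threshold),
                              "-max_target_seqs", params$max_hits,
                              "-out", out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) {
    stop("blastp exited with status ", status)
  }
  parse_blast_xml(out, query$accession, query$residues)
}

parse_blast_xml <- function(path, query_accession, query_residues) {
  doc <- xml2::read_xml(path)
  hits_nodes <- xml2::xml_find_all(doc, ".//Hit")
  rows <- lapply(hits_nodes, function(hit) {
    def <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_def"))
    acc <- parse_uniprot_header(def)$accession
    hsp <- xml2::xml_find_first(hit, ".//Hsp")  # best-scoring HSP only
    num <- function(tag) {
      as.numeric(xml2::xml_text(xml2::xml_find_first(hsp, paste0("./", tag))))
    }
    qseq <- xml2::xml_text(xml2::xml_find_first(hsp, "./Hsp_qseq"))
    sseq <- xml2::xml_text(xml2::xml_find_first(hsp, "./Hsp_hseq"))
    len <- num("Hsp_align-len")
    ev <- num("Hsp_evalue")
    data.frame(subject_accession = acc, evalue = ev,
               bitscore = num("Hsp_bit-score"), raw_score = num("Hsp_score"),
               identity_pct = 100 * num("Hsp_identity") / len,
               similarity_pct = 100 * num("Hsp_positive") / len,
               query_aln = qseq, subject_aln = sseq,
               query_start = num("Hsp_query-from"),
               query_end = num("Hsp_query-to"),
               subject_start = num("Hsp_hit-from"),
               subject_end = num("Hsp_hit-to"),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    return(empty_hits())
  }
  self <- hits$subject_accession == query_accession
  hits$evalue[self] <- 0
  hits <- hits[order(hits$evalue, hits$subject_accession), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("search_hits", "data.frame")
  hits
}
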