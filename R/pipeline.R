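# End-to-end runs: query + library -> homology search -> disorder traces
# -> IDS/FLEX scoring -> ranked report, plus comparative trace alignment
# for selected hits. Output is machine-readable TSV; reruns with identical
# configuration and inputs are byte-identical.

#' Assemble a run configuration
#'
#' Defaults mirror a standard screen: E-value threshold `1e-10`, at most
#' 100 hits, priority coefficient 0.5 (homology and structural order
#' weighted equally), long-disorder prediction mode, IDS threshold 0.5,
#' hits sorted by ascending E-value.
#'
#' @param query_path Query sequence: FASTA file, or plain text containing
#'   only residues.
#' @param library_path FASTA search library with UniProt-style headers.
#' @param output_dir Directory for result files (created if needed).
#' @param evalue_threshold,max_hits Search parameters (see
#'   [search_params()]).
#' @param eta FLEX priority coefficient in `[0, 1]`.
#' @param mode Built-in disorder predictor mode, `"long"` or `"short"`.
#' @param ids_threshold Disorder threshold for the IDS (strict).
#' @param sort_key `"evalue"`, `"flex"` or `"ids"`.
#' @param chain_table_path Optional chain-annotation TSV for polyprotein
#'   hits (see [read_chain_table()]).
#' @param score_dir Optional directory of per-accession score files
#'   (`<accession>.scores`) overriding the built-in predictor.
#' @param seed Seed recorded for fixture generation; the scan itself is
#'   deterministic.
#' @return A list of class `run_config`.
#' @export
run_config <- function(query_path, library_path, output_dir,
                       evalue_threshold = 1e-10, max_hits = 100,
                       eta = 0.5, mode = "long", ids_threshold = 0.5,
                       sort_key = "evalue", chain_table_path = NULL,
                       score_dir = NULL, seed = 1L) {
  mode <- match.arg(mode, c("long", "short"))
  sort_key <- match.arg(sort_key, c("evalue", "flex", "ids"))
  config <- list(query_path = query_path, library_path = library_path,
                 output_dir = output_dir,
                 evalue_threshold = evalue_threshold, max_hits = max_hits,
                 eta = eta, mode = mode, ids_threshold = ids_threshold,
                 sort_key = sort_key, chain_table_path = chain_table_path,
                 score_dir = score_dir, seed = as.integer(seed))
  class(config) <- "run_config"
  validate_config(config)
  config
}

validate_config <- function(config) {
  if (!file.exists(config$query_path)) {
    stop("query file not found: ", config$query_path)
  }
  if (!file.exists(config$library_path)) {
    stop("library file not found: ", config$library_path)
  }
  if (!is.null(config$chain_table_path) &&
      !file.exists(config$chain_table_path)) {
    stop("chain table not found: ", config$chain_table_path)
  }
  search_params(evalue_threshold = config$evalue_threshold,
                max_hits = config$max_hits)
  flex_params(eta = config$eta)
  ids_params(threshold = config$ids_threshold)
  invisible(config)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; values in `overrides` (e.g.
#' command-line flags) win over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of values taking precedence.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

read_query <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (startsWith(trimws(first[1] %||% ""), ">")) {
    lib <- read_fasta(path)
    return(lib[1, , drop = FALSE])
  }
  res <- normalize_residues(paste(readLines(path, warn = FALSE),
                                  collapse = ""), path)
  data.frame(accession = "query", gene_id = "", species = "",
             description = "", residues = res, stringsAsFactors = FALSE)
}

# Per-record disorder trace: external score file when provided, otherwise
# the built-in predictor in the configured mode.
trace_for <- function(record, config) {
  if (!is.null(config$score_dir)) {
    for (ext in c(".scores", ".txt")) {
      f <- file.path(config$score_dir, paste0(record$accession, ext))
      if (file.exists(f)) {
        return(external_trace(record, read_score_file(f)))
      }
    }
  }
  predict_trace(record, config$mode)
}

#' Run a full homolog screen
#'
#' Reads the query and library, searches for homologs, computes each hit's
#' disorder trace, IDS and FLEX score, and writes a ranked report. The
#' query entry always appears with E-value 0 (its self-hit when present in
#' the library, otherwise a synthesized row), so its FLEX score is
#' `(1 - eta) + eta * (1 - IDS/100)`. Hits on sequences with chain
#' annotations are virtually processed: their IDS is computed over the
#' mature chain overlapping the hit only.
#'
#' Files written to `output_dir`: `results.tsv` (columns `identifier`,
#' `gene_id`, `species`, `identity_pct`, `similarity_pct`, `evalue`,
#' `ids_pct`, `flex`; FLEX at 4 decimals, IDS at 3, E-values as 2-decimal
#' scientific mantissas) and `run.log` (one line per stage; no
#' timestamps, so reruns are byte-identical).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `scan_result` with `table` (full
#'   precision), `query_accession`, `traces` (per-accession disorder
#'   traces) and `config`.
#' @export
run_scan <- function(config) {
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  query <- read_query(config$query_path)
  library <- read_fasta(config$library_path)
  note("query: ", query$accession, " (", nchar(query$residues), " aa)")
  note("library: ", nrow(library), " sequences, ",
       sum(nchar(library$residues)), " residues")
  note("params: evalue_threshold=", format(config$evalue_threshold),
       " max_hits=", config$max_hits, " eta=", format(config$eta),
       " mode=", config$mode, " ids_threshold=",
       format(config$ids_threshold), " sort=", config$sort_key)

  params <- search_params(evalue_threshold = config$evalue_threshold,
                          max_hits = config$max_hits)
  hits <- search_homologs(query, library, params)
  note("search: ", nrow(hits), " hits at E <= ",
       format(config$evalue_threshold))

  chains <- if (!is.null(config$chain_table_path)) {
    read_chain_table(config$chain_table_path)
  } else {
    list()
  }
  ip <- ids_params(config$ids_threshold)
  fp <- flex_params(config$eta)

  qtrace <- trace_for(query, config)
  query_ids <- ids(qtrace, ip)
  traces <- list()
  traces[[query$accession]] <- qtrace

  self_row <- hits$evalue == 0
  scored <- lapply(which(!self_row), function(i) {
    hit <- hits[i, ]
    rec <- library[library$accession == hit$subject_accession, , drop = FALSE]
    tr <- trace_for(rec, config)
    traces[[rec$accession]] <<- tr
    ann <- chains[[rec$accession]]
    if (!is.null(ann)) {
      frag <- withCallingHandlers(
        map_hit_to_fragment(hit, ann, nchar(rec$residues)),
        warning = function(w) {
          note("polyprotein: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      hit_ids <- fragment_scores(tr, frag, ip)
      note("polyprotein: ", rec$accession, " -> ",
           if (frag$whole_sequence) "whole sequence" else frag$chain_name)
    } else {
      hit_ids <- ids(tr, ip)
    }
    cbind(hit[, c("subject_accession", "identity_pct", "similarity_pct",
                  "evalue")],
          data.frame(gene_id = rec$gene_id, species = rec$species,
                     ids_pct = hit_ids,
                     flex = flex_score(hit_ids, hit$evalue, fp),
                     stringsAsFactors = FALSE))
  })
  qrow <- data.frame(subject_accession = query$accession,
                     identity_pct = 100, similarity_pct = 100, evalue = 0,
                     gene_id = query$gene_id %||% "",
                     species = query$species %||% "",
                     ids_pct = query_ids,
                     flex = flex_score(query_ids, 0, fp),
                     stringsAsFactors = FALSE)
  if (any(self_row)) {
    sr <- hits[which(self_row)[1], ]
    qrow$identity_pct <- sr$identity_pct
    qrow$similarity_pct <- sr$similarity_pct
  }
  table <- rbind(qrow, do.call(rbind, scored))
  table <- rank_hits(table, config$sort_key)
  if (nrow(table) == 1 && nrow(hits) <= sum(self_row)) {
    warning("no hits passed the E-value threshold; report contains the ",
            "query row only")
    note("warning: no hits passed the E-value threshold")
  }
  note("scored: ", nrow(table), " rows (query included)")

  out <- file.path(config$output_dir, "results.tsv")
  write_scan_table(table, out)
  writeLines(log_lines, file.path(config$output_dir, "run.log"))
  result <- structure(list(table = table, query_accession = query$accession,
                           traces = traces, config = config),
                      class = "scan_result")
  invisible(result)
}

write_scan_table <- function(table, path) {
  formatted <- data.frame(
    identifier = table$subject_accession,
    gene_id = table$gene_id,
    species = table$species,
    identity_pct = sprintf("%.1f", table$identity_pct),
    similarity_pct = sprintf("%.1f", table$similarity_pct),
    evalue = ifelse(table$evalue == 0, "0", sprintf("%.2E", table$evalue)),
    ids_pct = sprintf("%.3f", table$ids_pct),
    flex = sprintf("%.4f", table$flex),
    stringsAsFactors = FALSE)
  write.table(formatted, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare disorder traces of selected records
#'
#' Aligns the selected accessions (query and/or hits), projects their
#' disorder traces onto the alignment columns (gaps scored exactly 0.0)
#' and calls conserved/divergent disorder segments on the query row.
#' Writes `compare_alignment.fasta`, `compare_trace_matrix.tsv` and
#' `compare_segments.tsv` to the run's output directory.
#'
#' @param config The [run_config()] of the scan being compared.
#' @param accessions Character vector (length >= 2) of record accessions;
#'   the scan query may be included under its own accession. The designated
#'   query row of the segment report is the scan query when selected,
#'   otherwise the first selected accession.
#' @return Invisibly, a list with `alignment` (`msa`), `matrix`
#'   (`aligned_trace_matrix`) and `conservation` (segment report).
#' @export
run_compare <- function(config, accessions) {
  validate_config(config)
  if (length(accessions) < 2) {
    stop("select at least two accessions to compare")
  }
  query <- read_query(config$query_path)
  library <- read_fasta(config$library_path)
  pool <- library
  if (!query$accession %in% pool$accession) {
    pool <- rbind(query, library)
    class(pool) <- c("seq_library", "data.frame")
  }
  missing <- setdiff(accessions, pool$accession)
  if (length(missing) > 0) {
    stop("unknown accession(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(pool$accession, collapse = ", "))
  }
  records <- pool[match(accessions, pool$accession), , drop = FALSE]
  aln <- align_sequences(records)
  traces <- lapply(unique(accessions), function(acc) {
    trace_for(pool[pool$accession == acc, , drop = FALSE], config)
  })
  mat <- project_traces(aln, traces)
  query_row <- if (query$accession %in% accessions) query$accession
               else accessions[1]
  cons <- disorder_conservation(mat, ids_threshold = config$ids_threshold,
                                query = query_row)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment_fasta(aln, file.path(config$output_dir,
                                       "compare_alignment.fasta"))
  write_trace_matrix(mat, file.path(config$output_dir,
                                    "compare_trace_matrix.tsv"))
  write.table(cons$segments, file.path(config$output_dir,
                                       "compare_segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(alignment = aln, matrix = mat, conservation = cons))
}
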