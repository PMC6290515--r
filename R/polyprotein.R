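# Virtual processing of viral polyprotein hits: map a homology hit to the
# mature-peptide chain it overlaps and restrict disorder metrics to that
# fragment. Chain annotations come from a local TSV mirroring UniProt
# "CHAIN" features (curated processing information is not retrieved over
# the network). All coordinates are 1-based inclusive, the UniProt
# convention.

#' Read a chain-annotation table
#'
#' Tab-separated file with header columns `accession`, `chain_name`,
#' `start`, `end` (1-based inclusive residue coordinates on the unprocessed
#' parent sequence). Rows are grouped by accession and chains sorted by
#' start; overlapping chains are permitted and flagged.
#'
#' @param path Path to the TSV file.
#' @return A named list of `chain_annotation` objects (one per accession),
#'   each with fields `accession`, `chains` (data frame `chain_name`,
#'   `start`, `end`) and `overlapping` (logical flag).
#' @export
read_chain_table <- function(path) {
  if (!file.exists(path)) {
    stop("chain table not found: ", path)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("accession", "chain_name", "start", "end")
  if (!all(required %in% names(tab))) {
    stop("chain table must have columns: ", paste(required, collapse = ", "))
  }
  bad <- which(!is.finite(tab$start) | !is.finite(tab$end) |
                 tab$start < 1 | tab$end < tab$start)
  if (length(bad) > 0) {
    stop("invalid chain coordinates in row ", bad[1], " (",
         tab$accession[bad[1]], ": ", tab$start[bad[1]], "-",
         tab$end[bad[1]], ")")
  }
  lapply(split(tab, tab$accession), function(grp) {
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    rownames(grp) <- NULL
    overlapping <- nrow(grp) > 1 &&
      any(grp$start[-1] <= grp$end[-nrow(grp)])
    structure(list(accession = grp$accession[1],
                   chains = grp[, c("chain_name", "start", "end")],
                   overlapping = overlapping),
              class = "chain_annotation")
  })
}

#' Map a homology hit to the mature-peptide chain it overlaps
#'
#' Selects the annotated chain with maximal residue overlap with the hit's
#' subject interval `[subject_start, subject_end]`; ties are broken by the
#' chain with the smaller start. When no chain overlaps (or the annotation
#' has no chains) the whole sequence is returned as a fallback with a
#' warning.
#'
#' @param hit One row of a `search_hits` data frame (or any list with
#'   `subject_start` and `subject_end`).
#' @param ann A `chain_annotation` from [read_chain_table()], or `NULL`.
#' @param parent_length Length of the unprocessed parent sequence (used by
#'   the whole-sequence fallback).
#' @return A list with `chain_name` (`NA` for the fallback), `start`,
#'   `end`, and `whole_sequence` (logical).
#' @export
map_hit_to_fragment <- function(hit, ann, parent_length) {
  stopifnot(is.numeric(parent_length), parent_length >= 1)
  fallback <- list(chain_name = NA_character_, start = 1L,
                   end = as.integer(parent_length), whole_sequence = TRUE)
  if (is.null(ann) || nrow(ann$chains) == 0) {
    warning("no chain annotation available; using the whole sequence")
    return(fallback)
  }
  if (any(ann$chains$end > parent_length)) {
    stop("chain annotation for ", ann$accession,
         " extends past the parent sequence (length ", parent_length, ")")
  }
  ov <- pmin(ann$chains$end, hit$subject_end) -
    pmax(ann$chains$start, hit$subject_start) + 1
  ov <- pmax(ov, 0)
  if (all(ov == 0)) {
    warning("hit ", hit$subject_start, "-", hit$subject_end,
            " overlaps no annotated chain of ", ann$accession,
            "; using the whole sequence")
    return(fallback)
  }
  best <- which(ov == max(ov))[1]  # chains are sorted by start: tie -> smaller start
  list(chain_name = ann$chains$chain_name[best],
       start = as.integer(ann$chains$start[best]),
       end = as.integer(ann$chains$end[best]),
       whole_sequence = FALSE)
}

#' IDS restricted to a fragment of a disorder trace
#'
#' Computes the IDS over `scores[start..end]` only, with the fragment
#' length as denominator — the metric a polyprotein hit receives after
#' virtual processing.
#'
#' @param trace A [disorder_trace()].
#' @param fragment A list or vector with `start` and `end` (1-based
#'   inclusive), e.g. from [map_hit_to_fragment()].
#' @param params An [ids_params()] object.
#' @return The fragment IDS (percent).
#' @export
fragment_scores <- function(trace, fragment, params = ids_params()) {
  stopifnot(inherits(trace, "disorder_trace"))
  start <- fragment[["start"]]
  end <- fragment[["end"]]
  l <- length(trace$scores)
  if (start < 1 || end > l || start > end) {
    stop("fragment ", start, "-", end, " is outside the trace (length ",
         l, ")")
  }
  ids(disorder_trace(trace$accession, trace$scores[start:end], trace$mode),
      params)
}
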