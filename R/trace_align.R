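# Comparative disorder-trace alignment: progressive multiple sequence
# alignment, projection of disorder traces onto alignment columns, and
# conserved/divergent disorder segment calling.
#
# The progressive MSA is built in (pairwise distances -> UPGMA guide
# tree -> profile-profile merges) so no external aligner binary is needed;
# its parameter defaults are this package's own convention, so
# alignment-dependent outputs such as segment boundaries are
# convention-bound.

#' Progressive multiple sequence alignment
#'
#' Aligns two or more protein sequences progressively: all-pairs global
#' alignments (BLOSUM62, affine gaps) give a distance matrix
#' (1 - fractional identity over the alignment length), a UPGMA tree over
#' those distances orders the merges, and profiles are merged by
#' profile-profile dynamic programming with column scores
#' `f_A' * BLOSUM62 * f_B` over residue frequency vectors (gap characters
#' contribute zero). Deterministic for a fixed input order.
#'
#' @param seqs A `seq_library` data frame with at least two rows (duplicate
#'   accessions are permitted here, e.g. to overlay a sequence with
#'   itself).
#' @param gap_open,gap_extend Affine gap penalties (positive costs;
#'   defaults 10 and 0.1).
#' @return A list of class `msa` with `row_accessions` and `rows` (equal
#'   length gapped strings, input order). Removing the gaps from row i
#'   reproduces input sequence i exactly.
#' @export
align_sequences <- function(seqs, gap_open = 10, gap_extend = 0.1) {
  stopifnot(is.data.frame(seqs))
  k <- nrow(seqs)
  if (k < 2) {
    stop("multiple alignment needs at least 2 sequences")
  }
  mat <- substitution_matrix()
  d <- pairwise_identity_distances(seqs$residues, gap_open, gap_extend)
  profiles <- lapply(seqs$residues, function(s) {
    matrix(strsplit(s, "")[[1]], nrow = 1)
  })
  members <- as.list(seq_len(k))
  if (k == 2) {
    merged <- merge_profiles(profiles[[1]], profiles[[2]], mat,
                             gap_open, gap_extend)
    order_idx <- c(1L, 2L)
  } else {
    tree <- hclust(as.dist(d), method = "average")  # UPGMA guide tree
    node_prof <- vector("list", nrow(tree$merge))
    node_members <- vector("list", nrow(tree$merge))
    fetch <- function(id) {
      if (id < 0) list(prof = profiles[[-id]], mem = -id)
      else list(prof = node_prof[[id]], mem = node_members[[id]])
    }
    for (r in seq_len(nrow(tree$merge))) {
      a <- fetch(tree$merge[r, 1])
      b <- fetch(tree$merge[r, 2])
      node_prof[[r]] <- merge_profiles(a$prof, b$prof, mat,
                                       gap_open, gap_extend)
      node_members[[r]] <- c(a$mem, b$mem)
    }
    merged <- node_prof[[nrow(tree$merge)]]
    order_idx <- node_members[[nrow(tree$merge)]]
  }
  # restore input row order
  merged <- merged[order(order_idx), , drop = FALSE]
  rows <- apply(merged, 1, paste, collapse = "")
  structure(list(row_accessions = seqs$accession, rows = unname(rows)),
            class = "msa")
}

pairwise_identity_distances <- function(residues, gap_open, gap_extend) {
  k <- length(residues)
  d <- matrix(0, k, k)
  mat <- substitution_matrix()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::BString(residues[i]), Biostrings::BString(residues[j]),
        type = "global", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_extend)
      d[i, j] <- d[j, i] <- 1 - Biostrings::pid(pa, type = "PID1") / 100
    }
  }
  d
}

# Frequency matrix (columns x alphabet) of a profile; gap characters are
# dropped from the counts, so gappy columns carry proportionally less
# weight, and frequencies are normalized by the number of profile rows.
profile_frequencies <- function(prof, alphabet) {
  nr <- nrow(prof)
  f <- matrix(0, ncol(prof), length(alphabet),
              dimnames = list(NULL, alphabet))
  for (a in alphabet) {
    f[, a] <- colSums(prof == a) / nr
  }
  f
}

# Global profile-profile alignment (Gotoh affine-gap DP, row-vectorized).
# Returns the merged character matrix with gap columns inserted.
merge_profiles <- function(pa, pb, mat, gap_open, gap_extend) {
  alphabet <- rownames(mat)
  fa <- profile_frequencies(pa, alphabet)
  fb <- profile_frequencies(pb, alphabet)
  S <- fa %*% mat %*% t(fb)  # column-pair substitution scores
  la <- ncol(pa)
  lb <- ncol(pb)
  H <- matrix(-Inf, la + 1, lb + 1)
  FM <- matrix(-Inf, la + 1, lb + 1)  # vertical-gap state
  H[1, ] <- c(0, -(gap_open + gap_extend * seq_len(lb)))
  for (i in seq_len(la)) {
    h0 <- -(gap_open + gap_extend * i)
    mrow <- H[i, 1:lb] + S[i, ]
    frow <- pmax(H[i, 2:(lb + 1)] - gap_open - gap_extend,
                 FM[i, 2:(lb + 1)] - gap_extend)
    grow <- pmax(mrow, frow)
    # best horizontal-gap entry: E[j] = max_{k<j} (X[k] - open - (j-k)*ext)
    q <- c(h0, grow[seq_len(lb - 1)] + gap_extend * seq_len(lb - 1))
    erow <- cummax(q) - gap_open - gap_extend * seq_len(lb)
    H[i + 1, ] <- c(h0, pmax(grow, erow))
    FM[i + 1, 2:(lb + 1)] <- frow
    FM[i + 1, 1] <- h0
  }
  ops <- traceback_ops(H, S, la, lb, gap_open, gap_extend)
  build_merged(pa, pb, ops)
}

# Reconstruct one optimal path from H alone: a column is either a
# substitution step or the end of a maximal gap run opened from an
# H-optimal prefix, so scanning run lengths recovers a valid path.
traceback_ops <- function(H, S, la, lb, gap_open, gap_extend, tol = 1e-7) {
  i <- la
  j <- lb
  ops <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        abs(H[i + 1, j + 1] - (H[i, j] + S[i, j])) < tol) {
      ops <- c("D", ops)
      i <- i - 1
      j <- j - 1
      next
    }
    placed <- FALSE
    if (j > 0) {
      for (g in seq_len(j)) {
        if (abs(H[i + 1, j + 1] -
                (H[i + 1, j + 1 - g] - gap_open - g * gap_extend)) < tol) {
          ops <- c(rep("B", g), ops)  # consume B columns, gap in A
          j <- j - g
          placed <- TRUE
          break
        }
      }
    }
    if (!placed && i > 0) {
      for (g in seq_len(i)) {
        if (abs(H[i + 1, j + 1] -
                (H[i + 1 - g, j + 1] - gap_open - g * gap_extend)) < tol) {
          ops <- c(rep("A", g), ops)  # consume A columns, gap in B
          i <- i - g
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      stop("internal error: profile alignment traceback failed at (",
           i, ", ", j, ")")
    }
  }
  ops
}

build_merged <- function(pa, pb, ops) {
  na <- nrow(pa)
  nb <- nrow(pb)
  out <- matrix("-", na + nb, length(ops))
  ia <- 0
  ib <- 0
  for (col in seq_along(ops)) {
    op <- ops[col]
    if (op %in% c("D", "A")) {
      ia <- ia + 1
      out[1:na, col] <- pa[, ia]
    }
    if (op %in% c("D", "B")) {
      ib <- ib + 1
      out[na + (1:nb), col] <- pb[, ib]
    }
  }
  out
}

#' Project disorder traces onto alignment columns
#'
#' Places each row's per-residue scores at its non-gap columns; gap columns
#' receive a score of exactly 0.0 — an extremely unlikely value for a real
#' residue, which makes alignment gaps visible in the aligned traces.
#' Consumers should note that 0.0 is therefore overloaded (gap versus a
#' genuinely fully ordered residue).
#'
#' @param aln An `msa` from [align_sequences()].
#' @param traces A list of [disorder_trace()] objects covering every
#'   alignment row (matched by accession; each trace must have one score
#'   per ungapped residue of its row).
#' @return A list of class `aligned_trace_matrix` with `row_accessions`
#'   and `values`, a rows x columns numeric matrix.
#' @export
project_traces <- function(aln, traces) {
  stopifnot(inherits(aln, "msa"))
  if (inherits(traces, "disorder_trace")) {
    traces <- list(traces)
  }
  trace_acc <- vapply(traces, function(t) t$accession, character(1))
  n <- length(aln$rows)
  width <- nchar(aln$rows[1])
  values <- matrix(0, n, width)
  gap <- matrix(FALSE, n, width)
  for (i in seq_len(n)) {
    acc <- aln$row_accessions[i]
    ti <- match(acc, trace_acc)
    if (is.na(ti)) {
      stop("no disorder trace supplied for alignment row ", acc)
    }
    chars <- strsplit(aln$rows[i], "")[[1]]
    non_gap <- chars != "-"
    if (sum(non_gap) != length(traces[[ti]]$scores)) {
      stop("trace length (", length(traces[[ti]]$scores),
           ") does not match ungapped row length (", sum(non_gap),
           ") for ", acc)
    }
    values[i, non_gap] <- traces[[ti]]$scores
    gap[i, !non_gap] <- TRUE
  }
  structure(list(row_accessions = aln$row_accessions, values = values,
                 gap = gap),
            class = "aligned_trace_matrix")
}

#' Disorder conservation summary and segment report
#'
#' Summarizes an aligned trace matrix per column (fraction of rows
#' disordered, mean score) and calls disordered segments on a designated
#' query row: maximal runs of columns whose query score strictly exceeds
#' the threshold. Each segment is reported in query residue coordinates
#' (1-based inclusive, gaps excluded) together with the mean fraction of
#' the other rows that are also disordered over the segment. Segments
#' whose cross-row fraction falls below `conserved_min` are flagged as
#' candidates for deletion from an expression construct (disorder present
#' in the query but not conserved in homologs).
#'
#' @param mat An `aligned_trace_matrix` from [project_traces()].
#' @param ids_threshold Disorder threshold (default 0.5, strict).
#' @param query Accession of the query row (default: first row).
#' @param conserved_min Cross-row disordered fraction below which a
#'   segment is flagged as a deletion candidate (default 0.5).
#' @return A list with `query`, `columns` (per-column data frame `column`,
#'   `frac_disordered`, `mean_score`) and `segments` (data frame `start`,
#'   `end` in query residue coordinates, `length`, `cross_fraction`,
#'   `n_other_rows`, `deletion_candidate`; `cross_fraction` and the flag
#'   are `NA` when the matrix has no other rows).
#' @export
disorder_conservation <- function(mat, ids_threshold = 0.5,
                                  query = NULL, conserved_min = 0.5) {
  stopifnot(inherits(mat, "aligned_trace_matrix"))
  query <- query %||% mat$row_accessions[1]
  qi <- match(query, mat$row_accessions)
  if (is.na(qi)) {
    stop("query row '", query, "' not in matrix; available: ",
         paste(mat$row_accessions, collapse = ", "))
  }
  v <- mat$values
  disordered <- v > ids_threshold
  columns <- data.frame(column = seq_len(ncol(v)),
                        frac_disordered = colMeans(disordered),
                        mean_score = colMeans(v))
  qdis <- v[qi, ] > ids_threshold
  segments <- call_segments(mat, qi, qdis, ids_threshold, conserved_min)
  list(query = query, columns = columns, segments = segments)
}

call_segments <- function(mat, qi, qdis, ids_threshold, conserved_min) {
  v <- mat$values
  # query gap columns carry score 0.0, so segments never span them;
  # residue numbering skips gaps via the stored gap mask
  res_index <- cumsum(!mat$gap[qi, ])
  runs <- rle(qdis)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  if (!any(keep)) {
    return(empty_segments())
  }
  starts <- starts[keep]
  ends <- ends[keep]
  n_other <- nrow(v) - 1
  segs <- lapply(seq_along(starts), function(s) {
    cols <- starts[s]:ends[s]
    if (n_other > 0) {
      other <- v[-qi, cols, drop = FALSE]
      cross <- mean(colMeans(other > ids_threshold))
    } else {
      cross <- NA_real_
    }
    data.frame(start = res_index[starts[s]], end = res_index[ends[s]],
               length = length(cols), cross_fraction = cross,
               n_other_rows = n_other,
               deletion_candidate = if (n_other > 0) cross < conserved_min
                                    else NA)
  })
  do.call(rbind, segs)
}

empty_segments <- function() {
  data.frame(start = integer(), end = integer(), length = integer(),
             cross_fraction = numeric(), n_other_rows = integer(),
             deletion_candidate = logical())
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param aln An `msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$rows)) {
    writeLines(c(paste0(">", aln$row_accessions[i]), aln$rows[i]), con)
  }
  invisible(path)
}

#' Write an aligned trace matrix as TSV
#'
#' Rows are accessions, columns alignment positions; gap cells hold 0.0.
#'
#' @param mat An `aligned_trace_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "aligned_trace_matrix"))
  df <- as.data.frame(mat$values)
  names(df) <- paste0("col", seq_len(ncol(mat$values)))
  df <- cbind(accession = mat$row_accessions, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
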