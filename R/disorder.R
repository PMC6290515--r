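# Per-residue intrinsic disorder traces and the IDS statistic.
#
# The predictor is pluggable: the built-in default is a windowed
# composition heuristic (hydropathy + net charge), and externally computed
# per-residue scores (e.g. genuine IUPred output) can be injected via
# read_score_file()/external_trace(). Every downstream module is
# predictor-agnostic.

# Kyte-Doolittle hydropathy index.
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
                   X = 0, B = -3.5, Z = -3.5, U = 2.5)

# Formal side-chain charge at neutral pH.
AA_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

# Heuristic calibration: score = clamp01(a - b * meanHydropathy
#                                          + c * |meanNetCharge|).
# Constants fixed so that low-complexity polar/charged stretches
# (E/K/S/P/Q) score above 0.5 while hydrophobic globular cores (L/I/V/F...)
# score well below it.
DISORDER_A <- 0.45
DISORDER_B <- 0.08
DISORDER_C <- 0.25

# Window sizes mirror the long/short disorder context distinction.
DISORDER_WINDOWS <- c(long = 101L, short = 25L)

#' Construct a disorder trace
#'
#' @param accession Sequence identifier the trace annotates.
#' @param scores Numeric vector of per-residue disorder scores in `[0, 1]`.
#' @param mode One of `"long"`, `"short"` (built-in predictor windows) or
#'   `"external"` (injected scores).
#' @return A list of class `disorder_trace`.
#' @export
disorder_trace <- function(accession, scores, mode = "external") {
  mode <- match.arg(mode, c("long", "short", "external"))
  scores <- as.numeric(scores)
  if (length(scores) == 0) {
    stop("disorder trace must contain at least one score")
  }
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("disorder scores must lie in [0, 1]")
  }
  structure(list(accession = accession, scores = scores, mode = mode),
            class = "disorder_trace")
}

#' Predict a per-residue disorder trace (built-in heuristic)
#'
#' Scores each residue from the amino-acid composition of a centered window
#' (truncated at the termini):
#' `clamp01(0.45 - 0.08 * meanHydropathy + 0.25 * |meanNetCharge|)` with
#' Kyte-Doolittle hydropathy. Long mode uses a 101-residue window for
#' extended disorder context, short mode a 25-residue window for short
#' disordered stretches. The heuristic separates low-complexity
#' polar/charged stretches (scores above 0.5) from hydrophobic globular
#' cores (below 0.5); it makes no claim of accuracy parity with dedicated
#' predictors such as IUPred, whose output can be injected instead with
#' [external_trace()].
#'
#' @param seq A single-row `seq_library` data frame, or a residue string.
#' @param mode `"long"` (default) or `"short"`.
#' @return A [disorder_trace()] with one score per residue.
#' @export
predict_trace <- function(seq, mode = c("long", "short")) {
  mode <- match.arg(mode)
  if (is.character(seq) && length(seq) == 1) {
    seq <- list(accession = "query", residues = seq)
  }
  seq <- as_seq_record(seq)
  letters <- strsplit(seq$residues, "")[[1]]
  l <- length(letters)
  hyd <- unname(KD_HYDROPATHY[letters])
  chg <- unname(AA_CHARGE[letters])
  chg[is.na(chg)] <- 0
  half <- (DISORDER_WINDOWS[[mode]] - 1L) %/% 2L
  # cumulative sums give O(1) truncated-window means
  ch <- c(0, cumsum(hyd))
  cc <- c(0, cumsum(chg))
  lo <- pmax(seq_len(l) - half, 1L)
  hi <- pmin(seq_len(l) + half, l)
  w <- hi - lo + 1
  mean_hyd <- (ch[hi + 1] - ch[lo]) / w
  mean_chg <- abs((cc[hi + 1] - cc[lo]) / w)
  scores <- clamp01(DISORDER_A - DISORDER_B * mean_hyd + DISORDER_C * mean_chg)
  disorder_trace(seq$accession, scores, mode)
}

#' Wrap externally computed scores as a disorder trace
#'
#' @param seq A single-row `seq_library` data frame or residue string the
#'   scores annotate.
#' @param scores Numeric scores in `[0, 1]`, one per residue (e.g. from
#'   [read_score_file()]).
#' @return A [disorder_trace()] in `"external"` mode.
#' @export
external_trace <- function(seq, scores) {
  if (is.character(seq) && length(seq) == 1) {
    seq <- list(accession = "query", residues = seq)
  }
  seq <- as_seq_record(seq)
  if (length(scores) != nchar(seq$residues)) {
    stop("score count (", length(scores), ") does not match sequence length (",
         nchar(seq$residues), ") for ", seq$accession)
  }
  disorder_trace(seq$accession, scores, "external")
}

#' IDS parameters
#'
#' @param threshold Disorder cut in `(0, 1)` above which (strictly) a
#'   residue counts as disordered. Default 0.5.
#' @return A list of class `ids_params`.
#' @export
ids_params <- function(threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold < 1)
  structure(list(threshold = threshold), class = "ids_params")
}

#' Intrinsic disorder score (IDS)
#'
#' The percentage of residues whose disorder score strictly exceeds the
#' threshold: `IDS = 100 * #(s > threshold) / l` with `l` the protein
#' length. A residue scoring exactly at the threshold does not count.
#'
#' @param trace A [disorder_trace()] (or bare numeric score vector).
#' @param params An [ids_params()] object.
#' @return IDS as a percentage in `[0, 100]`.
#' @examples
#' ids(disorder_trace("x", c(0.6, 0.4, 0.5, 0.7)))  # 50: the 0.5 is not counted
#' @export
ids <- function(trace, params = ids_params()) {
  scores <- if (inherits(trace, "disorder_trace")) trace$scores else trace
  if (length(scores) == 0) {
    stop("empty disorder trace")
  }
  100 * sum(scores > params$threshold) / length(scores)
}

#' Export a disorder trace as two-column text
#'
#' Writes `index score` lines (1-based residue index), the same dialect
#' [read_score_file()] accepts, for plotting or archival.
#'
#' @param trace A [disorder_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "disorder_trace"))
  writeLines(sprintf("%d\t%.6f", seq_along(trace$scores), trace$scores), path)
  invisible(path)
}
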