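# The hybrid FLEX score: a weighted average of a hyperbolic transform of
# the homology E-value and the intrinsic order (1 - IDS fraction).
# Higher FLEX = closer and more ordered homolog.

#' FLEX score parameters
#'
#' @param eta Priority coefficient in `[0, 1]` weighting intrinsic order
#'   against homology: `eta = 0` scores homology only, `eta = 1` intrinsic
#'   order only. Default 0.5 (both taken into account equally).
#' @param base Base of the hyperbolic transform, fixed at 0.99.
#' @return A list of class `flex_params`.
#' @export
flex_params <- function(eta = 0.5, base = 0.99) {
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) ||
      eta < 0 || eta > 1) {
    stop("eta must be a number in [0, 1]")
  }
  stopifnot(base > 0, base < 1)
  structure(list(eta = eta, base = base), class = "flex_params")
}

#' Hyperbolic transform of the E-value
#'
#' `t(E) = 1 - 0.99^((-log10(E))^2)` for `E > 0`, and `t(0) = 1` as the
#' limiting convention (the query's self-hit carries E-value 0). The
#' transform converges the extreme low-end E-value range while resolving
#' the high and middle ranges: as a function of `log10(E)` it is sigmoidal
#' and bounded in `[0, 1]`, near-linear between E-values of 1e-3 and 1e-14,
#' with the tails approaching 0 and 1. For `E >= 1` the squared exponent is
#' still nonnegative, so `t` stays in `[0, 1]` with no clamping:
#' `t(1) = 0` exactly, and `t` rises back towards 1 as E grows past 1
#' (immaterial in practice, since hits are E-value-thresholded well below
#' 1).
#'
#' @param evalue Numeric vector of E-values, each `>= 0`.
#' @param base Transform base (fixed default 0.99).
#' @return Transformed values in `[0, 1]`.
#' @export
evalue_transform <- function(evalue, base = 0.99) {
  if (any(!is.finite(evalue) | evalue < 0)) {
    stop("E-values must be finite and >= 0")
  }
  out <- ifelse(evalue == 0, 1, 1 - base^((-log10(evalue))^2))
  unname(out)
}

#' Hybrid FLEX score
#'
#' `FLEX = (1 - eta) * t(E) + eta * (1 - IDS/100)` with `t` the
#' [evalue_transform()]. IDS is supplied (and displayed) in percent but
#' enters as a fraction so that FLEX lies in `[0, 1]`. The priority
#' coefficient `eta` shifts the contribution ratio of intrinsic structural
#' order to homology.
#'
#' @param ids_pct IDS in percent, in `[0, 100]` (vectorised).
#' @param evalue E-value(s), each `>= 0`.
#' @param params A [flex_params()] object.
#' @return FLEX score(s) in `[0, 1]`.
#' @examples
#' flex_score(3.703, 1.54e-28, flex_params(eta = 0.10))  # ~0.9959
#' @export
flex_score <- function(ids_pct, evalue, params = flex_params()) {
  if (!inherits(params, "flex_params")) {
    params <- flex_params(eta = params)
  }
  if (any(!is.finite(ids_pct) | ids_pct < 0 | ids_pct > 100)) {
    stop("ids_pct must lie in [0, 100]")
  }
  (1 - params$eta) * evalue_transform(evalue, params$base) +
    params$eta * (1 - ids_pct / 100)
}

#' Rank scored hits
#'
#' Stable sort of a scored hit table: `evalue` ascending (the default
#' presentation, lowest to highest), `flex` descending, or `ids` ascending.
#' Ties are broken by accession so output order is deterministic.
#'
#' @param hits A data frame with columns `subject_accession`, `evalue`,
#'   `ids_pct` and `flex` (as produced by [run_scan()] / [score_hits()]).
#' @param sort_key One of `"evalue"`, `"flex"`, `"ids"`.
#' @return The reordered data frame.
#' @export
rank_hits <- function(hits, sort_key = c("evalue", "flex", "ids")) {
  sort_key <- match.arg(sort_key)
  ord <- switch(sort_key,
    evalue = order(hits$evalue, hits$subject_accession),
    flex = order(-hits$flex, hits$subject_accession),
    ids = order(hits$ids_pct, hits$subject_accession))
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a screen against the query's own FLEX score
#'
#' A superior homolog is a hit whose FLEX score strictly exceeds the
#' query's, computed under the same priority coefficient. For each superior
#' hit the IDS improvement is `query IDS - hit IDS` (positive when the hit
#' is more ordered).
#'
#' @param query_flex The query's FLEX score.
#' @param query_ids The query's IDS (percent).
#' @param hits Scored hit data frame with `flex` and `ids_pct` columns
#'   (the query's own row, if present, should be excluded by the caller).
#' @return A list with `n_superior` (count of superior homologs) and
#'   `ids_improvements` (numeric vector, one value per superior hit).
#' @export
screen_summary <- function(query_flex, query_ids, hits) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(n_superior = 0L, ids_improvements = numeric()))
  }
  superior <- hits$flex > query_flex
  list(n_superior = sum(superior),
       ids_improvements = query_ids - hits$ids_pct[superior])
}

#' Bucket IDS improvements in fixed-width increments
#'
#' Buckets values by their lower bound in `width`-point increments
#' (default 5), the binning used to report how much homolog IDS scores
#' improve over their queries.
#'
#' @param improvements Numeric vector of IDS improvements (percent points).
#' @param width Bin width (default 5).
#' @return A table keyed by bin lower bound.
#' @export
bin_improvements <- function(improvements, width = 5) {
  if (length(improvements) == 0) {
    return(table(numeric()))
  }
  table(floor(improvements / width) * width)
}
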