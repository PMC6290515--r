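# Deterministic synthetic homolog families with designed order/disorder
# architecture, so every pipeline stage is testable without downloads.
#
# The ancestor is built from composition pools — disordered blocks from
# low-complexity polar/charged residues, ordered blocks from hydrophobic
# residues — chosen so the built-in disorder heuristic separates the two
# block kinds cleanly (a deliberate calibration coupling between fixtures
# and predictor). Descendants apply seeded point substitutions and indels;
# no realistic evolutionary model (substitution-matrix-driven mutation,
# rate heterogeneity) is attempted.

DISORDERED_POOL <- c("E", "K", "S", "P", "Q", "G")
ORDERED_POOL <- c("L", "I", "V", "F", "W", "Y", "A", "M")

#' Specify a synthetic homolog family
#'
#' @param seed Integer seed; a single seed drives every random draw, so an
#'   identical spec yields byte-identical output.
#' @param family_size Total number of family members: the ancestor plus
#'   `family_size - 1` descendants derived from it.
#' @param ancestor_length Ancestor length in residues.
#' @param substitution_rate Per-residue substitution probability per
#'   lineage, in `[0, 1)`.
#' @param indel_rate Per-residue probability of a single-residue insertion
#'   or deletion per lineage, in `[0, 1)`.
#' @param disorder_blocks Data frame (or list of `c(start, end)` with a
#'   `kind` attribute) with columns `start`, `end`, `kind`
#'   (`"ordered"`/`"disordered"`) defining non-overlapping regions that
#'   together cover `1..ancestor_length`. The default architecture is a
#'   disordered N-terminus and linker around one ordered core
#'   (35% disordered), the shape typical of a disorder-enriched kinase.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, family_size = 6L, ancestor_length = 400L,
                         substitution_rate = 0.05, indel_rate = 0.01,
                         disorder_blocks = NULL) {
  if (is.null(disorder_blocks)) {
    disorder_blocks <- data.frame(
      start = c(1L, as.integer(0.15 * ancestor_length) + 1L,
                as.integer(0.80 * ancestor_length) + 1L),
      end = c(as.integer(0.15 * ancestor_length),
              as.integer(0.80 * ancestor_length), ancestor_length),
      kind = c("disordered", "ordered", "disordered"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.numeric(seed), family_size >= 1, ancestor_length >= 10,
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  b <- disorder_blocks[order(disorder_blocks$start), , drop = FALSE]
  if (b$start[1] != 1 || b$end[nrow(b)] != ancestor_length ||
      (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)] + 1))) {
    stop("disorder_blocks must tile 1..ancestor_length without gaps or overlap")
  }
  if (!all(b$kind %in% c("ordered", "disordered"))) {
    stop("block kind must be 'ordered' or 'disordered'")
  }
  structure(list(seed = as.integer(seed), family_size = as.integer(family_size),
                 ancestor_length = as.integer(ancestor_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate, disorder_blocks = b),
            class = "fixture_spec")
}

#' Generate a synthetic homolog family
#'
#' Builds the ancestor from the spec's block architecture and derives
#' `family_size - 1` descendants by seeded point substitutions (replacement
#' drawn from the block's own composition pool, preserving the block's
#' character) and single-residue indels. A ground-truth table records each
#' sequence's true block structure after edits, so expected IDS values are
#' known exactly.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `fixture_family` with `library` (a
#'   `seq_library` whose first record is the ancestor), `truth` (data
#'   frame `accession`, `start`, `end`, `kind` of post-edit blocks) and
#'   `spec`.
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  blocks <- spec$disorder_blocks
  labels <- character(spec$ancestor_length)
  anc <- character(spec$ancestor_length)
  for (r in seq_len(nrow(blocks))) {
    idx <- blocks$start[r]:blocks$end[r]
    pool <- if (blocks$kind[r] == "disordered") DISORDERED_POOL else ORDERED_POOL
    anc[idx] <- sample(pool, length(idx), replace = TRUE)
    labels[idx] <- blocks$kind[r]
  }
  recs <- list(list(accession = "ANC0001", letters = anc, labels = labels))
  for (d in seq_len(spec$family_size - 1L)) {
    mut <- mutate_lineage(anc, labels, spec$substitution_rate, spec$indel_rate)
    recs[[d + 1]] <- list(accession = sprintf("DES%04d", d),
                          letters = mut$letters, labels = mut$labels)
  }
  lib <- do.call(rbind, lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    data.frame(accession = r$accession, gene_id = "fam1",
               species = paste("Synthetic taxon", i),
               description = "Synthetic homolog",
               residues = paste(r$letters, collapse = ""),
               stringsAsFactors = FALSE)
  }))
  class(lib) <- c("seq_library", "data.frame")
  truth <- do.call(rbind, lapply(recs, function(r) {
    runs <- rle(r$labels)
    ends <- cumsum(runs$lengths)
    data.frame(accession = r$accession, start = ends - runs$lengths + 1,
               end = ends, kind = runs$values, stringsAsFactors = FALSE)
  }))
  structure(list(library = lib, truth = truth, spec = spec),
            class = "fixture_family")
}

mutate_lineage <- function(letters, labels, sub_rate, indel_rate) {
  l <- length(letters)
  # point substitutions: replacement from the residue's own block pool
  sub_at <- which(runif(l) < sub_rate)
  for (i in sub_at) {
    pool <- if (labels[i] == "disordered") DISORDERED_POOL else ORDERED_POOL
    letters[i] <- sample(pool, 1)
  }
  # single-residue indels, half deletions / half insertions
  indel_at <- which(runif(l) < indel_rate)
  if (length(indel_at) > 0) {
    is_del <- runif(length(indel_at)) < 0.5
    keep <- rep(TRUE, l)
    keep[indel_at[is_del]] <- FALSE
    ins_after <- indel_at[!is_del]
    new_letters <- list()
    new_labels <- list()
    for (i in seq_len(l)) {
      if (keep[i]) {
        new_letters <- c(new_letters, letters[i])
        new_labels <- c(new_labels, labels[i])
      }
      if (i %in% ins_after) {
        pool <- if (labels[i] == "disordered") DISORDERED_POOL else ORDERED_POOL
        new_letters <- c(new_letters, sample(pool, 1))
        new_labels <- c(new_labels, labels[i])
      }
    }
    letters <- unlist(new_letters)
    labels <- unlist(new_labels)
  }
  list(letters = letters, labels = labels)
}

#' Ground-truth IDS of a generated sequence
#'
#' The disordered block fraction of a family member, in percent — what
#' [ids()] must return on its generated score profile whenever the profile
#' noise keeps scores on the correct side of the threshold.
#'
#' @param family A [make_family()] result.
#' @param accession Member accession.
#' @return IDS in percent.
#' @export
truth_ids <- function(family, accession) {
  tr <- family$truth[family$truth$accession == accession, , drop = FALSE]
  if (nrow(tr) == 0) {
    stop("unknown accession: ", accession)
  }
  len <- tr$end - tr$start + 1
  100 * sum(len[tr$kind == "disordered"]) / sum(len)
}

#' Generate a per-residue disorder score profile for a family member
#'
#' Emulates what a disorder predictor would produce on the designed
#' architecture: scores drawn uniformly in `0.8 +/- noise_width` inside
#' disordered blocks and `0.2 +/- noise_width` inside ordered blocks,
#' clamped to `[0, 1]`. At the default width 0.1 every score stays on its
#' block's side of the 0.5 threshold, so the profile's IDS equals the
#' ground-truth block fraction exactly. Seeded deterministically per
#' accession from the family spec's seed.
#'
#' @param family A [make_family()] result.
#' @param accession Member accession.
#' @param noise_width Half-width of the uniform noise (default 0.1; 0
#'   gives exactly 0.8/0.2).
#' @return Numeric score vector, one per residue.
#' @export
make_score_profile <- function(family, accession, noise_width = 0.1) {
  stopifnot(inherits(family, "fixture_family"), noise_width >= 0)
  tr <- family$truth[family$truth$accession == accession, , drop = FALSE]
  if (nrow(tr) == 0) {
    stop("unknown accession: ", accession)
  }
  idx <- match(accession, family$library$accession)
  # sub-seed kept well under 2^31
  set.seed((family$spec$seed %% 1000003L) * 1009L + idx)
  l <- max(tr$end)
  kind <- character(l)
  for (r in seq_len(nrow(tr))) {
    kind[tr$start[r]:tr$end[r]] <- tr$kind[r]
  }
  center <- ifelse(kind == "disordered", 0.8, 0.2)
  clamp01(center + runif(l, -noise_width, noise_width))
}

#' Write a fixture family to disk
#'
#' Writes the family FASTA library, the ground-truth block TSV and one
#' score-profile file per member (`<accession>.scores`, the `index score`
#' dialect of [read_score_file()]).
#'
#' @param family A [make_family()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "fixture_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(family$library, file.path(dir, "family.fasta"))
  write.table(family$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (acc in family$library$accession) {
    scores <- make_score_profile(family, acc)
    writeLines(sprintf("%d\t%.6f", seq_along(scores), scores),
               file.path(dir, paste0(acc, ".scores")))
  }
  invisible(dir)
}
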