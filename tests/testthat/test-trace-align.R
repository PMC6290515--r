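test_that("identical sequences align without gaps for any family size", {
  for (k in c(2, 4)) {
    lib <- make_lib(rep(paste0(ANCHOR, "KLMNP"), k),
                    sprintf("ID%02d", seq_len(k)))
    aln <- align_sequences(lib)
    expect_length(aln$rows, k)
    expect_false(any(grepl("-", aln$rows)))
    expect_equal(unique(aln$rows), aln$rows[1])
  }
})

test_that("ungapping alignment rows reproduces the inputs exactly", {
  lib <- make_lib(c("ACDEFG", "ACDG"), c("S1", "S2"))
  aln <- align_sequences(lib)
  expect_equal(gsub("-", "", aln$rows), lib$residues)

  fam <- make_family(fixture_spec(seed = 3, family_size = 5,
                                  ancestor_length = 150, indel_rate = 0.03))
  aln2 <- align_sequences(fam$library)
  expect_equal(length(unique(nchar(aln2$rows))), 1)
  expect_equal(gsub("-", "", aln2$rows), fam$library$residues)
  expect_equal(aln2$row_accessions, fam$library$accession)
  expect_error(align_sequences(lib[1, ]), "at least 2")
})

test_that("the guide tree pairs near-identical sequences first", {
  set.seed(41)
  a <- paste0(ANCHOR, ANCHOR)
  distant <- random_aa(60)
  lib <- make_lib(c(a, distant, a), c("TWIN1", "FAR01", "TWIN2"))
  aln <- align_sequences(lib)
  rows <- setNames(aln$rows, aln$row_accessions)
  # the identical pair is merged first, so their aligned rows stay equal
  expect_equal(rows[["TWIN1"]], rows[["TWIN2"]])
})

test_that("traces project onto alignment columns with 0.0 at gaps", {
  aln <- structure(list(row_accessions = c("Q1", "S1"),
                        rows = c("AC-D", "ACDD")), class = "msa")
  traces <- list(disorder_trace("Q1", c(0.1, 0.2, 0.3)),
                 disorder_trace("S1", c(0.5, 0.6, 0.7, 0.8)))
  mat <- project_traces(aln, traces)
  expect_equal(mat$values[1, ], c(0.1, 0.2, 0.0, 0.3))
  expect_equal(mat$values[2, ], c(0.5, 0.6, 0.7, 0.8))
  expect_true(mat$gap[1, 3])

  # gapless alignment: matrix equals the stacked traces
  aln2 <- structure(list(row_accessions = c("A", "B"),
                         rows = c("ACD", "ACD")), class = "msa")
  tr2 <- list(disorder_trace("A", c(0.9, 0.1, 0.4)),
              disorder_trace("B", c(0.2, 0.3, 0.4)))
  m2 <- project_traces(aln2, tr2)
  expect_equal(m2$values, rbind(c(0.9, 0.1, 0.4), c(0.2, 0.3, 0.4)))

  expect_error(project_traces(aln, list(disorder_trace("Q1", c(0.1, 0.2)),
                                        traces[[2]])),
               "Q1")
  expect_error(project_traces(aln, traces[2]), "Q1")
})

test_that("projection conserves scores: non-gap cells reproduce each trace", {
  fam <- make_family(fixture_spec(seed = 13, family_size = 4,
                                  ancestor_length = 120, indel_rate = 0.02))
  aln <- align_sequences(fam$library)
  traces <- lapply(fam$library$accession, function(acc)
    disorder_trace(acc, make_score_profile(fam, acc)))
  mat <- project_traces(aln, traces)
  for (i in seq_along(traces)) {
    expect_equal(mat$values[i, !mat$gap[i, ]], traces[[i]]$scores)
    expect_true(all(mat$values[i, mat$gap[i, ]] == 0))
    expect_equal(sum(mat$values[i, ]), sum(traces[[i]]$scores))
  }
})

test_that("disorder segments are called on the query row in residue space", {
  mat <- structure(list(row_accessions = c("Q", "H"),
                        values = rbind(c(0.9, 0.9, 0.2, 0.8),
                                       c(0.9, 0.0, 0.0, 0.9)),
                        gap = matrix(FALSE, 2, 4)),
                   class = "aligned_trace_matrix")
  cons <- disorder_conservation(mat, ids_threshold = 0.5, query = "Q")
  expect_equal(cons$segments$start, c(1, 4))
  expect_equal(cons$segments$end, c(2, 4))
  expect_equal(cons$segments$cross_fraction, c(0.5, 1))
  expect_equal(cons$segments$deletion_candidate, c(FALSE, FALSE))
  expect_equal(cons$columns$frac_disordered, c(1, 0.5, 0, 1))

  # a homolog fully ordered where the query is disordered: all segments
  # are deletion candidates
  mat2 <- mat
  mat2$values[2, ] <- c(0.1, 0.0, 0.9, 0.2)
  cons2 <- disorder_conservation(mat2, query = "Q")
  expect_true(all(cons2$segments$deletion_candidate))

  # single-row matrix: cross-row fraction undefined but reported
  mat1 <- structure(list(row_accessions = "Q",
                         values = matrix(c(0.9, 0.2, 0.8), 1),
                         gap = matrix(FALSE, 1, 3)),
                    class = "aligned_trace_matrix")
  cons1 <- disorder_conservation(mat1, query = "Q")
  expect_equal(cons1$segments$n_other_rows, c(0, 0))
  expect_true(all(is.na(cons1$segments$cross_fraction)))

  # nothing above threshold: empty report
  mat0 <- mat
  mat0$values[1, ] <- 0.1
  expect_equal(nrow(disorder_conservation(mat0, query = "Q")$segments), 0)
  expect_error(disorder_conservation(mat, query = "Z"), "available")
})

test_that("segment coordinates skip query gap columns", {
  # query row: residues 1,2 | gap | residues 3,4; disorder on 2 and 3
  mat <- structure(list(row_accessions = c("Q", "H"),
                        values = rbind(c(0.2, 0.9, 0.0, 0.9, 0.1),
                                       c(0.9, 0.9, 0.9, 0.9, 0.9)),
                        gap = rbind(c(FALSE, FALSE, TRUE, FALSE, FALSE),
                                    rep(FALSE, 5))),
                   class = "aligned_trace_matrix")
  segs <- disorder_conservation(mat, query = "Q")$segments
  expect_equal(segs$start, c(2, 3))
  expect_equal(segs$end, c(2, 3))
})

test_that("alignment and matrix exports round-trip through text files", {
  lib <- make_lib(c("ACDEFG", "ACDG"), c("S1", "S2"))
  aln <- align_sequences(lib)
  fa <- tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, fa)
  lines <- readLines(fa)
  expect_equal(sub(">", "", lines[c(1, 3)]), c("S1", "S2"))

  traces <- list(disorder_trace("S1", runif(6)), disorder_trace("S2", runif(4)))
  mat <- project_traces(aln, traces)
  tsv <- tempfile(fileext = ".tsv")
  write_trace_matrix(mat, tsv)
  got <- read.delim(tsv)
  expect_equal(got$accession, c("S1", "S2"))
  expect_equal(unname(as.matrix(got[, -1])), unname(mat$values),
               tolerance = 1e-12)
})
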