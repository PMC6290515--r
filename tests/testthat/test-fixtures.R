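test_that("a size-one family is exactly the ancestor", {
  fam <- make_family(fixture_spec(seed = 2, family_size = 1,
                                  ancestor_length = 100,
                                  substitution_rate = 0,
                                  indel_rate = 0))
  expect_equal(nrow(fam$library), 1)
  expect_equal(fam$library$accession, "ANC0001")
  expect_equal(nchar(fam$library$residues), 100)
})

test_that("identical seeds give byte-identical families and profiles", {
  f1 <- tempfile()
  f2 <- tempfile()
  write_fasta(make_family(fixture_spec(seed = 9))$library, f1)
  write_fasta(make_family(fixture_spec(seed = 9))$library, f2)
  expect_identical(readLines(f1), readLines(f2))
  fam <- make_family(fixture_spec(seed = 9))
  expect_identical(make_score_profile(fam, "DES0002"),
                   make_score_profile(fam, "DES0002"))
  # and a different seed changes the output
  fam2 <- make_family(fixture_spec(seed = 10))
  expect_false(identical(fam$library$residues, fam2$library$residues))
})

test_that("descendant identity tracks the substitution rate", {
  fam <- make_family(fixture_spec(seed = 21, family_size = 4,
                                  ancestor_length = 500,
                                  substitution_rate = 0.05,
                                  indel_rate = 0))
  anc <- fam$library[1, ]
  # a substitution redraws from the block pool, so some draws restore the
  # original residue: expected identity is 1 - rate * (1 - 1/poolsize)
  for (d in 2:4) {
    aln <- local_align(anc$residues, fam$library$residues[d])
    st <- alignment_stats(aln$query_aln, aln$subject_aln)
    expect_gt(st[["identity_pct"]], 93)
    expect_lt(st[["identity_pct"]], 99)
  }
})

test_that("score profiles encode the designed block architecture", {
  blocks <- data.frame(start = c(1, 61), end = c(60, 200),
                       kind = c("disordered", "ordered"))
  fam <- make_family(fixture_spec(seed = 4, family_size = 1,
                                  ancestor_length = 200,
                                  disorder_blocks = blocks))
  # noise width 0: exactly 0.8 / 0.2
  p0 <- make_score_profile(fam, "ANC0001", noise_width = 0)
  expect_equal(p0, c(rep(0.8, 60), rep(0.2, 140)))
  # 60 disordered of 200 residues
  expect_equal(ids(disorder_trace("ANC0001", p0)), 30)
  expect_equal(truth_ids(fam, "ANC0001"), 30)

  all_dis <- make_family(fixture_spec(seed = 4, family_size = 1,
                                      ancestor_length = 50,
                                      disorder_blocks = data.frame(
                                        start = 1, end = 50,
                                        kind = "disordered")))
  prof <- make_score_profile(all_dis, "ANC0001")
  expect_equal(ids(disorder_trace("ANC0001", prof)), 100)
  expect_error(make_score_profile(fam, "NOPE01"), "unknown accession")
})

test_that("ground-truth IDS survives mutation and indels", {
  fam <- make_family(fixture_spec(seed = 31, family_size = 6,
                                  ancestor_length = 300, indel_rate = 0.02))
  for (acc in fam$library$accession) {
    tr <- fam$truth[fam$truth$accession == acc, ]
    expect_equal(max(tr$end), nchar(fam$library$residues[
      fam$library$accession == acc]))
    prof <- make_score_profile(fam, acc)
    expect_equal(ids(disorder_trace(acc, prof)), truth_ids(fam, acc))
  }
})

test_that("relatives outscore unrelated sequences of equal composition", {
  fam <- make_family(fixture_spec(seed = 51, family_size = 4,
                                  ancestor_length = 200))
  anc <- fam$library[1, ]
  set.seed(52)
  shuffled <- paste(sample(strsplit(anc$residues, "")[[1]]), collapse = "")
  lib <- rbind(fam$library[-1, ], make_lib(shuffled, "RND001"))
  class(lib) <- c("seq_library", "data.frame")
  hits <- search_homologs(anc, lib, search_params(evalue_threshold = 1e6))
  rel <- hits$evalue[hits$subject_accession != "RND001"]
  rnd <- hits$evalue[hits$subject_accession == "RND001"]
  if (length(rnd) == 0) rnd <- Inf  # no local similarity at all
  expect_length(rel, 3)
  expect_true(all(rel < rnd))
})

test_that("invalid fixture specs are rejected", {
  expect_error(fixture_spec(substitution_rate = 1), "substitution_rate")
  bad_blocks <- data.frame(start = c(1, 50), end = c(60, 100),
                           kind = c("disordered", "ordered"))
  expect_error(fixture_spec(ancestor_length = 100,
                            disorder_blocks = bad_blocks), "tile")
})

test_that("write_family produces a complete, reloadable file set", {
  fam <- make_family(fixture_spec(seed = 61, family_size = 3,
                                  ancestor_length = 80))
  dir <- tempfile()
  write_family(fam, dir)
  lib <- read_fasta(file.path(dir, "family.fasta"))
  expect_equal(lib$residues, fam$library$residues)
  for (acc in lib$accession) {
    scores <- read_score_file(file.path(dir, paste0(acc, ".scores")))
    expect_length(scores, nchar(lib$residues[lib$accession == acc]))
  }
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(sort(unique(truth$accession)), sort(lib$accession))
})
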