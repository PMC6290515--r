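test_that("the query's own entry gets E-value 0 and ranks first", {
  set.seed(101)
  q <- make_lib(paste0(ANCHOR, random_aa(20)), "QRY001")[1, ]
  lib <- make_lib(c(q$residues, paste0(ANCHOR, random_aa(20))),
                  c("QRY001", "OTHER1"))
  hits <- search_homologs(q, lib, search_params(evalue_threshold = 1))
  expect_equal(hits$subject_accession[1], "QRY001")
  expect_equal(hits$evalue[1], 0)
  expect_equal(hits$identity_pct[1], 100)
  expect_equal(hits$similarity_pct[1], 100)
  # identical sequence under a different accession is also a self-hit
  lib2 <- make_lib(c(q$residues, paste0(ANCHOR, random_aa(20))),
                   c("COPY01", "OTHER1"))
  hits2 <- search_homologs(q, lib2, search_params(evalue_threshold = 1))
  expect_equal(hits2$subject_accession[1], "COPY01")
  expect_equal(hits2$evalue[1], 0)
})

test_that("sequences with no positive-scoring local alignment yield no hit", {
  q <- make_lib(strrep("K", 40), "POLYK")[1, ]
  lib <- make_lib(strrep("D", 40), "POLYD")
  hits <- search_homologs(q, lib, search_params(evalue_threshold = 1e6))
  expect_equal(nrow(hits), 0)
  expect_error(search_homologs(q, lib[0, ]), "empty")
})

test_that("E-values follow Karlin-Altschul statistics", {
  p <- search_params()
  # strictly decreasing in the raw score at fixed m, n
  scores <- seq(20, 200, by = 5)
  ev <- p$ka_K * 100 * 1000 * exp(-p$ka_lambda * scores)
  expect_true(all(diff(ev) < 0))

  # doubling the library doubles every E-value (n doubles)
  set.seed(77)
  q <- make_lib(paste0(ANCHOR, random_aa(30)), "QX")[1, ]
  members <- vapply(1:4, function(i) {
    s <- strsplit(q$residues, "")[[1]]
    swap <- sample(length(s), 6)
    s[swap] <- sample(c("A", "G", "S", "T", "N", "D"), 6, replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  lib1 <- make_lib(members, sprintf("M%02d", 1:4))
  lib2 <- rbind(lib1, make_lib(members, sprintf("N%02d", 1:4)))
  class(lib2) <- c("seq_library", "data.frame")
  p_loose <- search_params(evalue_threshold = 1e6, max_hits = 100)
  h1 <- search_homologs(q, lib1, p_loose)
  h2 <- search_homologs(q, lib2, p_loose)
  for (acc in h1$subject_accession) {
    expect_equal(h2$evalue[h2$subject_accession == acc],
                 2 * h1$evalue[h1$subject_accession == acc],
                 tolerance = 1e-12)
  }
})

test_that("threshold and max_hits behave monotonically", {
  set.seed(5)
  q <- make_lib(paste0(ANCHOR, random_aa(30)), "QX")[1, ]
  members <- vapply(1:6, function(i) {
    s <- strsplit(q$residues, "")[[1]]
    swap <- sample(length(s), 3 * i)
    s[swap] <- sample(c("A", "G", "S", "T", "N", "D"), length(swap),
                      replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  lib <- make_lib(members, sprintf("M%02d", 1:6))
  strict <- search_homologs(q, lib, search_params(evalue_threshold = 1e-20,
                                                  max_hits = 100))
  loose <- search_homologs(q, lib, search_params(evalue_threshold = 1e-5,
                                                 max_hits = 100))
  # raising the threshold never removes a previously returned hit
  expect_true(all(strict$subject_accession %in% loose$subject_accession))
  # lowering max_hits returns a prefix
  capped <- search_homologs(q, lib, search_params(evalue_threshold = 1e-5,
                                                  max_hits = 2))
  expect_equal(capped$subject_accession,
               head(loose$subject_accession, 2))
})

test_that("identity and similarity percentages use the stated conventions", {
  expect_equal(alignment_stats("ACDE", "ACDE"),
               c(identity_pct = 100, similarity_pct = 100))
  # gap column counts in the denominator: 3 identities of 4 columns
  expect_equal(alignment_stats("AC-E", "ACDE"),
               c(identity_pct = 75, similarity_pct = 75))
  # K/R and R/K both score > 0 under BLOSUM62: similar but not identical
  expect_equal(alignment_stats("KR", "RK"),
               c(identity_pct = 0, similarity_pct = 100))
  expect_error(alignment_stats("AC", "ACD"), "length")
})

test_that("alignment engine matches the exhaustive oracle on small instances", {
  set.seed(31)
  p <- search_params()
  for (rep in 1:30) {
    # half the instances share a planted word so positive scores occur
    core <- random_aa(4)
    a <- if (rep %% 2) paste0(random_aa(4), core, random_aa(3)) else random_aa(11)
    b <- if (rep %% 2) paste0(random_aa(2), core, random_aa(5)) else random_aa(10)
    want <- oracle_local_score(a, b)
    got <- local_align(a, b, p)
    expect_equal(if (is.null(got)) 0 else got$score, want,
                 info = paste(a, b))
  }
})

test_that("external BLAST+ adapter ranks hits like the built-in engine", {
  # exercised only where a blastp executable exists; the built-in search
  # is the supported path everywhere
  if (!nzchar(Sys.which("blastp"))) {
    expect_true(TRUE)
    return(invisible())
  }
  set.seed(13)
  q <- make_lib(paste0(ANCHOR, random_aa(40), ANCHOR), "QRY001")[1, ]
  members <- vapply(1:5, function(i) {
    s <- strsplit(q$residues, "")[[1]]
    swap <- sample(length(s), 4 * i)
    s[swap] <- sample(c("A", "G", "S", "T", "N", "D", "E", "K"),
                      length(swap), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  lib <- make_lib(members, sprintf("M%02d", 1:5))
  f <- lib_to_tmp_fasta(lib)
  p <- search_params(evalue_threshold = 10)
  internal <- search_homologs(q, lib, p)
  external <- external_blast_adapter(q, f, p)
  shared <- intersect(internal$subject_accession, external$subject_accession)
  expect_gte(length(shared), 3)
  # E-values differ between engines; ranks of shared hits must not
  expect_equal(order(match(shared, internal$subject_accession)),
               order(match(shared, external$subject_accession)))
})
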