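test_that("FASTA reading maps the alphabet and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKV", ">P2", "mkz"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "P1")
  expect_equal(recs[[1]]$sequence, "MKV")
  # lower case upper-cased, 'z' outside the alphabet becomes 'X'
  expect_equal(recs[[2]]$sequence, "MKX")

  # alphabet-mapping oracle over all 26 letters: canonical residues survive,
  # everything else maps to X
  all26 <- paste(LETTERS, collapse = "")
  writeLines(c(">A", all26), f)
  got <- read_fasta(f)[[1]]$sequence
  expected <- vapply(LETTERS, function(ch)
    if (ch %in% c(dtamix:::AA_ALPHABET, "X")) ch else "X", "")
  expect_equal(got, paste(expected, collapse = ""))

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, out)
  back <- read_fasta(out)
  expect_equal(lapply(back, `[`, c("id", "sequence")),
               lapply(recs, `[`, c("id", "sequence")))
})

test_that("FASTA edge cases error informatively", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_equal(read_fasta(f), list())
  writeLines(c(">P1", ""), f)
  expect_error(read_fasta(f), "P1")
  expect_error(read_fasta(file.path(tempdir(), "absent.fasta")), "no such file")
})

test_that("drug tables parse, preserve order and reject bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tsmiles", "D1\tCCO", "D2\tc1ccccc1", "D3\tCC(=O)O"), f)
  drugs <- read_smiles_table(f)
  expect_equal(vapply(drugs, `[[`, "", "id"), c("D1", "D2", "D3"))
  expect_equal(drugs[[1]]$smiles, "CCO")

  writeLines(c("drug_id\tsmiles", "D1\tnot_a_mol"), f)
  expect_error(read_smiles_table(f), "row 1")
  writeLines(c("drug_id\tsmiles", "D1\tCCO", "D1\tCC"), f)
  expect_error(read_smiles_table(f), "duplicate")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_smiles_table(drugs, out)
  expect_equal(vapply(read_smiles_table(out), `[[`, "", "smiles"),
               vapply(drugs, `[[`, "", "smiles"))
})

test_that("site intervals are validated, sorted and merged", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tstart\tend", "P1\t4\t5"), f)
  expect_equal(read_sites(f)$P1, cbind(start = 4L, end = 5L))

  writeLines(c("protein_id\tstart\tend", "P1\t2\t5", "P1\t4\t8"), f)
  expect_equal(read_sites(f)$P1, cbind(start = 2L, end = 8L))

  writeLines(c("protein_id\tstart\tend", "P1\t5\t5"), f)
  expect_error(read_sites(f), "invalid site interval")
  writeLines(c("protein_id\tstart\tend", "P1\t-1\t5"), f)
  expect_error(read_sites(f), "invalid site interval")

  # merge oracle on random interval sets
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    st <- sample(0:40, n, TRUE)
    iv <- cbind(start = st, end = st + sample(1:10, n, TRUE))
    got <- dtamix:::merge_intervals(iv)
    exp <- oracle_merge_intervals(iv)
    expect_true(all(got[, 2] > got[, 1]))
    # same residue coverage and non-overlapping output
    cover <- function(m) sort(unique(unlist(
      lapply(seq_len(nrow(m)), function(i) m[i, 1]:(m[i, 2] - 1L)))))
    expect_equal(cover(got), cover(exp))
    if (nrow(got) > 1) expect_true(all(diff(got[, 1]) > 0) &&
                                     all(got[-nrow(got), 2] < got[-1, 1]))
  }
  ww <- tiny_world()
  out <- withr::local_tempfile(fileext = ".tsv")
  sites <- lapply(ww$proteins, `[[`, "sites")
  names(sites) <- vapply(ww$proteins, `[[`, "", "id")
  write_sites(sites, out)
  expect_equal(read_sites(out), sites[order(names(sites))])
})

test_that("affinity tables resolve ids and reject duplicates", {
  ww <- tiny_world()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_affinities(ww$affinities, f)
  back <- read_affinities(f, ww$drugs, ww$proteins)
  expect_equal(back, ww$affinities)
  writeLines(c("drug_id\tprotein_id\taffinity", "D1\tP1\t5", "D1\tP1\t6"), f)
  expect_error(read_affinities(f), "duplicate")
  writeLines(c("drug_id\tprotein_id\taffinity", "DX\tP1\t5"), f)
  expect_error(read_affinities(f, drugs = ww$drugs), "unknown drug_id")
})

test_that("kd_to_pkd matches the analytic transform and is decreasing", {
  expect_equal(kd_to_pkd(1e9), 0)
  expect_equal(kd_to_pkd(100), 7)
  expect_equal(kd_to_pkd(10000), 5)  # Davis labels concentrate near 5
  expect_error(kd_to_pkd(0), "positive")
  expect_error(kd_to_pkd(-3), "positive")
  kd <- sort(10^runif(50, -2, 10))
  expect_true(all(diff(kd_to_pkd(kd)) < 0))
})

test_that("cross-validation splits partition the pool correctly", {
  sp <- make_cv_splits(10, test_fraction = 0, seed = 3)
  expect_length(sp, 5L)
  expect_equal(vapply(sp, function(s) length(s$valid_indices), 0L), rep(2L, 5))
  expect_equal(make_cv_splits(10, 0, seed = 3), sp)  # deterministic

  # n = 11: fold sizes differ by at most one, pool covered exactly once
  sp11 <- make_cv_splits(11, 0, seed = 9)
  sizes <- vapply(sp11, function(s) length(s$valid_indices), 0L)
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_equal(sort(unlist(lapply(sp11, `[[`, "valid_indices"))), 1:11)

  # with a held-out test set: shared across folds, disjoint from the pool
  sp2 <- make_cv_splits(60, 1 / 6, seed = 1)
  expect_length(sp2[[1]]$test_indices, 10L)
  for (s in sp2) {
    expect_equal(s$test_indices, sp2[[1]]$test_indices)
    expect_length(intersect(s$test_indices, c(s$train_indices, s$valid_indices)), 0L)
    expect_equal(sort(c(s$train_indices, s$valid_indices)),
                 sort(setdiff(1:60, s$test_indices)))
    expect_length(intersect(s$train_indices, s$valid_indices), 0L)
  }
  expect_error(make_cv_splits(4, 0, 1), "at least 5")
})
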