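test_that("demultiplexing is exact-match only", {
  idx <- tiny_indices()
  reads <- c(make_read1("AATTT", "AAAAAAAAAA"),   # exact -> treated_rep1
             make_read1("AATTA", "AAAAAAAAAA"),   # 1 mismatch -> bad
             make_read1("GGCCA", "CCCCCCCCCC"),   # exact -> control_rep1
             "AAT")                               # too short -> bad
  sid <- demultiplex(reads, idx)
  expect_identical(sid, c("treated_rep1", NA, "control_rep1", NA))
})

test_that("tag extraction anchors on exact flanks", {
  lay <- tiny_layout()
  good <- make_read1("AATTT", "ACGTACGTAC", lay)
  expect_identical(extract_tag(good, lay), "ACGTACGTAC")
  # one substitution inside the upstream flank
  bad_flank <- sub("GATGT", "GATGA", good, fixed = TRUE)
  expect_true(is.na(extract_tag(bad_flank, lay)))
  # substitution in the downstream flank
  bad_down <- paste0(substr(good, 1, nchar(good) - 1), "A")
  expect_true(is.na(extract_tag(bad_down, lay)))
  # second upstream-flank occurrence is ambiguous
  dup <- paste0(good, lay$upstream_flank)
  expect_true(is.na(extract_tag(dup, lay)))
  # truncated tag region
  short <- substr(good, 1, nchar(good) - nchar(lay$downstream_flank) - 2)
  expect_true(is.na(extract_tag(short, lay)))
})

test_that("extraction success under errors matches the closed form", {
  # success requires both flanks intact: expected rate (1-e)^(lenU+lenD)
  cfg <- sim_config(n_mutants = 30, read_pairs_per_sample = 8000L,
                    seq_error_rate = 0.02, seed = 21)
  d <- withr::local_tempdir()
  sim <- simulate_screen(cfg, outdir = d)
  lay <- amplicon_layout()
  reads <- read_fastq(sim$files[[1]]["r1"])$seq
  ok <- !is.na(extract_tag(reads, lay))
  e <- 0.02
  expected <- (1 - e)^(nchar(lay$upstream_flank) + nchar(lay$downstream_flank))
  se <- sqrt(expected * (1 - expected) / length(reads))
  # flank errors can also relocate/duplicate the anchor; 3 SE + small slack
  expect_lt(abs(mean(ok) - expected), 3 * se + 0.01)
})

test_that("tag matching honours the distance gate and finds unique hits", {
  cat3 <- tiny_catalog()     # uptags pairwise distance 10
  hit <- match_tag("AAAAAAAAAA", cat3)
  expect_identical(hit$mutant_id, "H2A_K34E")
  expect_identical(hit$status, "matched")
  # 1 mismatch, radius 1 allowed (min distance >= 3)
  m1 <- match_tag("AAAAAAAAAT", cat3, max_mismatch = 1)
  expect_identical(m1$mutant_id, "H2A_K34E")
  # same tag at radius 0 is unknown
  m0 <- match_tag("AAAAAAAAAT", cat3, max_mismatch = 0)
  expect_identical(m0$status, "unknown")
  # gate: 1-mismatch matching on a distance-<3 catalog is a config error
  close_cat <- validate_catalog_df(data.frame(
    id = c("a", "b"), histone = "H2A", allele = c("K1A", "K2A"),
    residues = c("1", "2"),
    uptag = c("AAAAAAAAAA", "AAAAAAAATT"),
    downtag = c("CCCCCCCCCC", "GGGGGGGGGG")))
  expect_error(match_tag("AAAAAAAAAA", close_cat, max_mismatch = 1),
               "distance >= 3")
  # with the gate disabled, an equidistant query is ambiguous
  amb <- match_tag("AAAAAAAAAT", close_cat, max_mismatch = 1,
                   check_distance = FALSE)
  expect_identical(amb$status, "ambiguous")
})

test_that("unknown-tag calls agree with an exhaustive scan on random tags", {
  cfg <- sim_config(n_mutants = 60, seed = 31)
  cat0 <- generate_catalog(cfg)$catalog
  set.seed(99)
  queries <- apply(matrix(sample(c("A", "C", "G", "T"), 200 * 20, TRUE), 200),
                   1, paste, collapse = "")
  res <- match_tag(queries, cat0, max_mismatch = 0)
  scan <- vapply(queries, function(q) {
    d <- vapply(cat0$uptag, function(tg) hamming(q, tg), numeric(1))
    any(d == 0)
  }, logical(1))
  expect_identical(res$status == "matched", unname(scan))
})

test_that("count table conserves reads and is order- and mismatch-monotone", {
  cfg <- sim_config(n_mutants = 40, read_pairs_per_sample = 3000L,
                    seq_error_rate = 0.02, seed = 13)
  d <- withr::local_tempdir()
  sim <- simulate_screen(cfg, outdir = d)
  lay <- amplicon_layout()
  r1 <- vapply(sim$files, `[[`, character(1), "r1")
  ct0 <- build_count_table(r1, sim$catalog, sim$indices, lay, max_mismatch = 0)
  expect_equal(sum(ct0$matrix) + ct0$unassigned$bad_index +
                 sum(ct0$unassigned$per_sample), ct0$total_pairs)
  expect_equal(ct0$total_pairs, 4 * 3000L)
  # raising the mismatch radius never decreases any cell
  ct1 <- build_count_table(r1, sim$catalog, sim$indices, lay, max_mismatch = 1)
  expect_true(all(ct1$matrix >= ct0$matrix))
  # shuffling read order leaves the table unchanged
  fq <- read_fastq(r1[1])
  set.seed(5)
  perm <- sample(seq_along(fq$seq))
  shuf <- withr::local_tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", fq$id[perm]), fq$seq[perm], "+",
                             strrep("I", nchar(fq$seq[perm])))), shuf)
  ct_a <- build_count_table(r1[1], sim$catalog, sim$indices, lay)
  ct_b <- build_count_table(shuf, sim$catalog, sim$indices, lay)
  expect_identical(ct_a$matrix, ct_b$matrix)
})

test_that("error-free reads round-trip to the simulated counts exactly", {
  cfg <- sim_config(n_mutants = 35, read_pairs_per_sample = 2000L,
                    seq_error_rate = 0, seed = 17)
  d <- withr::local_tempdir()
  sim <- simulate_screen(cfg, outdir = d)
  r1 <- vapply(sim$files, `[[`, character(1), "r1")
  r2 <- vapply(sim$files, `[[`, character(1), "r2")
  ct <- build_count_table(r1, sim$catalog, sim$indices, amplicon_layout(),
                          r2 = r2, max_mismatch = 0)
  expect_identical(ct$matrix, sim$counts)
  expect_equal(ct$unassigned$bad_index + sum(ct$unassigned$per_sample), 0)
})

test_that("malformed FASTQ input raises hard errors", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), f)          # truncated record
  expect_error(read_fastq(f), "truncated")
  writeLines(c("@r1", "ACGT", "x", "IIII"), f)  # bad separator line
  expect_error(read_fastq(f), "malformed")
  # empty FASTQ -> all-zero table
  writeLines(character(0), f)
  ct <- build_count_table(f, tiny_catalog(), tiny_indices(), tiny_layout())
  expect_true(all(ct$matrix == 0L))
  expect_equal(ct$total_pairs, 0L)
  # mismatched pair files
  f2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), f)
  writeLines(character(0), f2)
  expect_error(build_count_table(f, tiny_catalog(), tiny_indices(),
                                 tiny_layout(), r2 = f2),
               "different numbers")
})
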