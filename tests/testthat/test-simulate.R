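cfg_small <- function(...) {
  sim_config(n_mutants = 40L, read_pairs_per_sample = 1000L, seed = 11L, ...)
}

test_that("generator is deterministic and satisfies its own contracts", {
  g1 <- generate_catalog(cfg_small())
  g2 <- generate_catalog(cfg_small())
  expect_identical(g1, g2)
  # index set of 4 samples at min pairwise Hamming >= 2, validator-approved
  expect_true(validate_index_set(g1$indices)$valid)
  expect_gte(brute_min_hamming(g1$indices$index_seq), 2)
  # tag set at distance >= 3 (brute force), enabling 1-mismatch matching
  tags <- c(g1$catalog$uptag, g1$catalog$downtag)
  expect_gte(brute_min_hamming(tags), 3)
  expect_false(anyDuplicated(tags) > 0)
})

test_that("index generation fails beyond the distance-2 code capacity", {
  expect_error(generate_catalog(sim_config(n_mutants = 5, n_replicates = 200L)),
               "distinct 5-nt indices")
})

test_that("ground truth links depletion flag and effect sign", {
  cfg <- cfg_small()
  tr <- ground_truth(generate_catalog(cfg)$catalog, cfg)
  expect_identical(tr$is_depleted, tr$true_log2_effect < 0)
  expect_true(all(tr$true_log2_effect[!tr$is_depleted] == 0))
  expect_equal(sum(tr$is_depleted), round(0.1 * 40))
})

test_that("simulate_counts reproduces the closed-form renormalisation", {
  # two mutants, equal baseline, effects (-1, 0): treated props (1/3, 2/3)
  cfg <- sim_config(n_mutants = 2, abundance_lognormal_sd = 0,
                    read_pairs_per_sample = 300L, seed = 4)
  cat2 <- generate_catalog(cfg)$catalog
  truth <- data.frame(id = cat2$id, true_log2_effect = c(-1, 0),
                      is_depleted = c(TRUE, FALSE))
  sim <- simulate_counts(cat2, truth, cfg)
  expect_equal(sim$proportions$control, c(0.5, 0.5))
  expect_equal(sim$proportions$treated, c(1 / 3, 2 / 3))
  # null case: all effects zero leaves proportions untouched
  truth0 <- data.frame(id = cat2$id, true_log2_effect = c(0, 0),
                       is_depleted = FALSE)
  sim0 <- simulate_counts(cat2, truth0, cfg)
  expect_equal(sim0$proportions$treated, sim0$proportions$control)
  # every column is a full multinomial draw
  expect_true(all(colSums(sim$counts) == 300L))
})

test_that("count sampling recovers 2^effect within Monte-Carlo error", {
  # sampling-theory oracle: across seeds, the mean treated/control proportion
  # ratio of a depleted mutant estimates 2^effect
  cfg0 <- sim_config(n_mutants = 50, read_pairs_per_sample = 20000L,
                     depleted_fraction = 0.2, seed = 1)
  cat0 <- generate_catalog(cfg0)$catalog
  truth <- ground_truth(cat0, cfg0)
  dep <- which(truth$is_depleted)[1]
  ratios <- vapply(1:40, function(s) {
    cfg <- sim_config(n_mutants = 50, read_pairs_per_sample = 20000L,
                      depleted_fraction = 0.2, seed = s)
    sim <- simulate_counts(cat0, truth, cfg)
    (sim$counts[dep, "treated_rep1"] / 20000) /
      (sim$counts[dep, "control_rep1"] / 20000) /
      (sim$proportions$treated[dep] / sim$proportions$control[dep])
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se + 1e-3)
})

test_that("FASTQ emission is deterministic, conserving, and empty-safe", {
  cfg <- cfg_small(seq_error_rate = 0.01)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_screen(cfg, outdir = d1)
  s2 <- simulate_screen(cfg, outdir = d2)
  for (sid in names(s1$files)) {
    expect_identical(readLines(gzfile(s1$files[[sid]]["r1"])),
                     readLines(gzfile(s2$files[[sid]]["r1"])))
  }
  # read-pair conservation: emitted pairs = column sums
  for (s in seq_along(s1$files)) {
    n1 <- length(read_fastq(s1$files[[s]]["r1"])$seq)
    n2 <- length(read_fastq(s1$files[[s]]["r2"])$seq)
    expect_equal(n1, sum(s1$counts[, s]))
    expect_equal(n2, n1)
  }
  # empty count table -> valid empty FASTQ pair
  sim0 <- list(counts = matrix(0L, 3, 2,
                               dimnames = list(tiny_catalog()$id,
                                               tiny_indices()$sample_id)),
               design = data.frame(sample_id = tiny_indices()$sample_id,
                                   condition = c("treated", "control"),
                                   replicate = 1L))
  d0 <- withr::local_tempdir()
  emit_fastq(tiny_catalog(), sim0, tiny_indices(), tiny_layout(),
             cfg_small(), d0)
  empty <- read_fastq(file.path(d0, "treated_rep1_R1.fastq.gz"))
  expect_length(empty$seq, 0)
})

test_that("revcomp layout stores the mate tag reverse-complemented", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AACGT"), "ACGTT")
  cfg <- sim_config(n_mutants = 2, read_pairs_per_sample = 10L, seed = 2,
                    seq_error_rate = 0)
  gen <- generate_catalog(cfg)
  truth <- ground_truth(gen$catalog, cfg)
  sim <- simulate_counts(gen$catalog, truth, cfg)
  d <- withr::local_tempdir()
  lay <- amplicon_layout(mate_revcomp = TRUE)
  emit_fastq(gen$catalog, sim, gen$indices, lay, cfg, d)
  r2 <- read_fastq(file.path(d, "treated_rep1_R2.fastq.gz"))$seq
  tags <- extract_tag(r2, lay)
  expect_true(all(tags %in% revcomp(gen$catalog$downtag)))
})
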