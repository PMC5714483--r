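toy_matrix <- function() {
  m <- matrix(0L, 3, 4, dimnames = list(
    c("H2A_K34E", "H2A_K34Q", "H2B_del29-36"),
    c("HU", "MMS", "BEN", "HT39")))
  m["H2A_K34E", "HU"] <- 2L
  m["H2A_K34Q", "HU"] <- 3L
  m["H2A_K34E", "MMS"] <- 1L
  m["H2B_del29-36", "BEN"] <- 4L
  m
}

test_that("residue severity takes the max over mutants of a residue", {
  rs <- residue_severity(toy_matrix(), tiny_catalog())
  h2a34 <- rs[rs$histone == "H2A" & rs$residue == 34, ]
  expect_equal(h2a34$HU, 3L)     # max of severities 2 and 3
  expect_equal(h2a34$MMS, 1L)    # single contributing mutant
  # a deletion allele annotates its whole residue range
  expect_equal(sum(rs$histone == "H2B"), 8L)
  expect_true(all(rs$BEN[rs$histone == "H2B"] == 4L))
  # unknown mutant is an error naming it
  bad <- toy_matrix()
  rownames(bad)[1] <- "H2A_nope"
  expect_error(residue_severity(bad, tiny_catalog()), "H2A_nope")
})

test_that("residue severity equals a brute-force group-by max on random input", {
  cfg <- sim_config(n_mutants = 50, seed = 23)
  cat0 <- generate_catalog(cfg)$catalog
  set.seed(23)
  m <- matrix(sample(0:4, 50 * 3, TRUE), 50, 3,
              dimnames = list(cat0$id, c("HU", "MMS", "BEN")))
  rs <- residue_severity(m, cat0)
  for (r in sample(nrow(rs), 10)) {
    h <- rs$histone[r]; pos <- rs$residue[r]
    touching <- cat0$id[cat0$histone == h &
                          vapply(cat0$residues_list, function(x) pos %in% x,
                                 logical(1))]
    for (cond in c("HU", "MMS", "BEN"))
      expect_equal(rs[[cond]][r], max(m[touching, cond]))
  }
  # idempotence/bound: residue severity never exceeds contributing max
  expect_true(all(rs$HU <= max(m[, "HU"])))
})

test_that("phenotype class counts follow the stress-class map", {
  m <- matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"),
                                        c("HU", "MMS", "BEN")))
  m["a", c("HU", "MMS")] <- 1L      # both DNA damage -> one class (I)
  m["b", c("HU", "BEN")] <- 2L      # DNA damage + microtubule -> II
  cc <- count_phenotype_classes(m)
  expect_identical(cc$n_classes, c(1L, 2L, 0L))
  expect_identical(cc$label, c("I", "II", NA))
  # adding an all-zero condition changes nothing
  m2 <- cbind(m, CPT = 0L)
  expect_identical(count_phenotype_classes(m2)$n_classes, cc$n_classes)
  # unmapped condition is an error
  colnames(m2)[4] <- "mystery"
  expect_error(count_phenotype_classes(m2), "mystery")
})

test_that("phenotype fraction and set relations behave exactly", {
  m0 <- matrix(0L, 10, 2, dimnames = list(paste0("m", 1:10), c("HU", "MMS")))
  f0 <- fraction_with_phenotype(m0)
  expect_equal(f0$n_with_phenotype, 0)
  expect_equal(f0$fraction, 0)
  m0[1:2, 1] <- 1L
  f2 <- fraction_with_phenotype(m0[1:3, , drop = FALSE])
  expect_equal(f2$n_with_phenotype, 2)
  expect_equal(f2$fraction, 2 / 3)

  expect_equal(subset_relation(c("a", "b"), c("a", "b", "c")),
               list(relation = "A_subset_B", a_only = 0L, b_only = 1L,
                    both = 2L))
  expect_equal(subset_relation("a", "b")$relation, "disjoint")
  expect_equal(subset_relation(c("a", "b"), c("b", "a"))$relation, "equal")
  # mirror consistency on random pairs
  set.seed(31)
  mirror <- c(A_subset_B = "B_subset_A", B_subset_A = "A_subset_B",
              equal = "equal", overlap = "overlap", disjoint = "disjoint")
  for (rep in 1:30) {
    a <- sample(letters[1:8], sample(0:6, 1))
    b <- sample(letters[1:8], sample(0:6, 1))
    expect_identical(unname(mirror[subset_relation(a, b)$relation]),
                     subset_relation(b, a)$relation)
  }
})

test_that("conservation comparison summarises groups and matches exact ranks", {
  scores <- c(a = 1, b = 2, c = 3, d = 101, e = 102, f = 103)
  cc <- data.frame(mutant_id = names(scores), n_classes = rep(c(0L, 1L), each = 3))
  out <- conservation_compare(scores, cc)
  expect_equal(out$summary$mean, c(2, 102))
  expect_equal(out$summary$sem, rep(sd(1:3) / sqrt(3), 2))
  # exact rank-permutation oracle for n = 3 vs 3, complete separation:
  # two-sided Wilcoxon p = 2 / choose(6, 3) = 0.1
  expect_equal(out$pairwise$p_value, 2 / choose(6, 3))
  # SEM of {2,4,6} = sd/sqrt(3); singleton group flagged NA
  out2 <- conservation_compare(
    c(x = 2, y = 4, z = 6, w = 9),
    data.frame(mutant_id = c("x", "y", "z", "w"),
               n_classes = c(1L, 1L, 1L, 2L)))
  expect_equal(out2$summary$sem[1], sd(c(2, 4, 6)) / sqrt(3))
  expect_true(is.na(out2$summary$sem[2]))
})

test_that("chromosome-loss rates and instability calls are strict at 4-fold", {
  expect_equal(chromosome_loss_rate(0, 200), 0)
  expect_equal(chromosome_loss_rate(5, 500), 0.01)
  expect_error(chromosome_loss_rate(1, 0), "positive")
  expect_error(chromosome_loss_rate(6, 5), "half-sectored")

  expect_true(call_unstable(0.0045, 0.001)$unstable)     # fold 4.5
  expect_false(call_unstable(0.004, 0.001)$unstable)     # exactly 4.0
  expect_false(call_unstable(0.001, 0.001)$unstable)     # fold 1
  expect_error(call_unstable(0.01, 0), "positive")
  # monotone in the mutant rate
  folds <- call_unstable(seq(0, 0.01, by = 0.001), 0.001)$unstable
  expect_true(all(diff(folds) >= 0))
  # binomial sampling oracle: estimate within 3 SE of the truth
  set.seed(77)
  r <- 0.004; n <- 10000
  est <- chromosome_loss_rate(rbinom(1, n, r), n)
  expect_lt(abs(est - r), 3 * sqrt(r * (1 - r) / n))
})

test_that("silencing calls cover LTS, ITS, LRS and WT", {
  expect_equal(call_silencing(5, 5, "telomere"), "WT")
  expect_equal(call_silencing(5 + 2, 5, "telomere", delta_cut = 1), "LTS")
  expect_equal(call_silencing(5 - 2, 5, "telomere", delta_cut = 1), "ITS")
  expect_equal(call_silencing(5 + 2, 5, "rdna", delta_cut = 1), "LRS")
  expect_equal(call_silencing(5 - 3, 5, "rdna", delta_cut = 1), "WT")
  expect_error(call_silencing(1, 1, "centromere"))

  sc <- synthetic_silencing_scores()
  calls <- silencing_calls(sc)
  tel <- calls[calls$locus == "telomere", ]
  expect_equal(sum(tel$call == "ITS"), 7)
  expect_equal(sum(tel$call == "LTS"), 6)   # 5 H2A C-term dels + H2B del29-36
  rdna <- calls[calls$locus == "rdna", ]
  expect_equal(sum(rdna$call == "LRS"), 3)  # del29-36 + 2 H2A dels
  expect_error(silencing_calls(transform(sc, locus = "telo")), "unknown locus")
})

test_that("synthetic screen reconstruction matches its designed marginals", {
  sp <- synthetic_phenotype_screen()
  fr <- fraction_with_phenotype(sp$severities)
  expect_equal(fr$n_with_phenotype, 150)
  expect_equal(fr$n_total, 570)
  hu_mut <- sum(sp$severities[, "HU"] >= 1)
  rs <- residue_severity(sp$severities, sp$catalog)
  expect_equal(hu_mut, 109)
  expect_equal(sum(rs$HU >= 1), 76)
  # UV- and CPT-sensitive sets are strict subsets of the MMS set
  sens <- function(cond) rownames(sp$severities)[sp$severities[, cond] >= 1]
  expect_equal(subset_relation(sens("UV"), sens("MMS"))$relation, "A_subset_B")
  expect_equal(subset_relation(sens("CPT"), sens("MMS"))$relation, "A_subset_B")
  # more than 60% of phenotype mutants span >= 2 stress classes
  cc <- count_phenotype_classes(sp$severities, sp$class_map)
  withp <- cc$n_classes[cc$n_classes >= 1]
  expect_gt(mean(withp >= 2), 0.6)

  cl <- chromosome_loss_analysis(synthetic_chromosome_loss())
  expect_equal(nrow(cl), 592)
  unstable <- cl[cl$unstable, ]
  expect_equal(sum(startsWith(unstable$strain_id, "H2A")), 31)
  expect_equal(sum(startsWith(unstable$strain_id, "H2B")), 17)
  expect_true(all(unstable$fold_vs_wt > 4))
})
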