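# Synthetic reconstructions of the screen's phenotype-level datasets.
#
# The study's supplementary severity, chromosome-loss and silencing tables
# are not machine-readable here, so these generators build *synthetic*
# stand-ins whose marginal composition is fixed a priori to the screen's
# reported summary figures (570-mutant severity matrix with 150 phenotype
# mutants, 109 HU-sensitive mutants over 76 residues, UV/CPT subsets of MMS,
# >60% of phenotype mutants in >= 2 stress classes; 592-strain loss assay
# with 31 H2A and 17 H2B unstable alleles). They exercise the analytics at
# realistic scale; they are not the study's data.

# first `per_res` catalog rows (in catalog order) for each given residue of
# one histone, point mutants only
point_mutants_for_residues <- function(catalog, histone, residues, per_res) {
  pt <- catalog[catalog$histone == histone &
                  lengths(catalog$residues_list) == 1L, ]
  res <- vapply(pt$residues_list, `[[`, integer(1), 1L)
  unlist(lapply(residues, function(r) {
    ids <- pt$id[res == r]
    ids[seq_len(min(per_res, length(ids)))]
  }), use.names = FALSE)
}

#' Synthetic phenotype-severity screen
#'
#' Deterministically builds a 570-mutant catalog and a severity matrix over
#' ten conditions whose composition follows the screen's reported marginals:
#' 150 mutants with at least one phenotype; 109 HU-sensitive mutants covering
#' 76 residues; UV- and CPT-sensitive sets strict subsets of the
#' MMS-sensitive set; more than 60% of phenotype mutants showing phenotypes
#' in two or more stress classes. Severity grades (1-4) are drawn
#' reproducibly from the given seed. This is a labelled synthetic stand-in,
#' not the study's severity table.
#'
#' @param seed integer seed for severity grades
#' @return list: `catalog`, `severities` (570 x 10 integer matrix),
#'   `class_map`
#' @export
synthetic_phenotype_screen <- function(seed = 20260930L) {
  cfg <- sim_config(n_mutants = 570L, seed = 101L)
  catalog <- generate_catalog(cfg)$catalog
  set.seed(seed %% .Machine$integer.max)
  conds <- default_stress_classes()$condition
  m <- matrix(0L, nrow(catalog), length(conds),
              dimnames = list(catalog$id, conds))

  # HU: 33 residues contributing two mutants + 43 contributing one = 109
  # mutants over 76 residues, all H2A point mutants
  hu_two <- point_mutants_for_residues(catalog, "H2A", 19:51, 2L)
  hu_one <- point_mutants_for_residues(catalog, "H2A", 52:94, 1L)
  hu <- c(hu_two, hu_one)
  # 41 further mutants (H2B) with non-DNA-damage phenotypes: 150 in total
  others <- point_mutants_for_residues(catalog, "H2B", 19:59, 1L)
  stopifnot(length(hu) == 109L, length(others) == 41L,
            !anyDuplicated(c(hu, others)))

  grade <- function(n) sample(1:4, n, replace = TRUE,
                              prob = c(0.35, 0.3, 0.2, 0.15))
  m[hu, "HU"] <- grade(length(hu))
  # MMS covers 80 of the HU set; UV and CPT are strict subsets of MMS
  mms <- hu[1:80]
  m[mms, "MMS"] <- grade(length(mms))
  m[mms[1:30], "UV"] <- grade(30L)
  m[mms[11:35], "CPT"] <- grade(25L)
  # second stress class for 95/150 phenotype mutants (> 60%)
  m[hu[1:70], "BEN"] <- grade(70L)
  m[others, "HT39"] <- grade(length(others))
  m[others[1:25], "TBZ"] <- grade(25L)
  # a few three- and four-class mutants
  m[hu[1:20], "LT16"] <- grade(20L)
  m[hu[1:8], "CAF"] <- grade(8L)

  list(catalog = catalog, severities = m,
       class_map = default_stress_classes())
}

#' Synthetic chromosome-loss assay table
#'
#' Deterministic sectored-colony counts for 592 H2A/H2B alleles plus wild
#' type, constructed so that exactly 31 H2A and 17 H2B alleles exceed a
#' fourfold increase in loss rate per generation over wild type (the screen's
#' reported composition). Counts are exact by construction: wild type loses
#' the marker chromosome in 8 of 4,000 first divisions; unstable strains are
#' assigned half-sectored counts above 32 of 4,000, stable strains at most
#' 28. A labelled synthetic stand-in, not the study's assay data.
#'
#' @param seed integer seed controlling which alleles are unstable
#' @return data.frame (strain_id, total_colonies, half_sectored) with a
#'   `"WT"` row
#' @export
synthetic_chromosome_loss <- function(seed = 20260930L) {
  catalog <- generate_catalog(sim_config(n_mutants = 592L, seed = 102L))$catalog
  set.seed(seed %% .Machine$integer.max)
  total <- 4000L
  wt_half <- 8L   # wild-type rate 0.002 per generation
  unstable_ids <- c(sample(catalog$id[catalog$histone == "H2A"], 31L),
                    sample(catalog$id[catalog$histone == "H2B"], 17L))
  half <- integer(nrow(catalog))
  names(half) <- catalog$id
  # stable: folds cycle over 0..3.5; unstable: folds from 4.25 upwards
  stable_ids <- setdiff(catalog$id, unstable_ids)
  half[stable_ids] <- rep_len(seq(0L, 28L, by = 4L), length(stable_ids))
  half[unstable_ids] <- 34L + 2L * (seq_along(unstable_ids) - 1L)
  rbind(
    data.frame(strain_id = "WT", total_colonies = total,
               half_sectored = wt_half, stringsAsFactors = FALSE),
    data.frame(strain_id = catalog$id, total_colonies = total,
               half_sectored = unname(half), stringsAsFactors = FALSE)
  )
}

#' Synthetic silencing reporter scores
#'
#' A small score table (colony-colour scale 0-10, higher = more reporter
#' expression = less silencing) reproducing the qualitative silencing
#' pattern of the histone tail deletions: seven H2B N-terminal deletions with
#' increased telomeric silencing (ITS), H2B del29-36 with loss of telomeric
#' and rDNA silencing, and five H2A C-terminal deletions with loss of
#' telomeric silencing of which two also lose rDNA silencing. Synthetic
#' stand-in scores, not measured data.
#'
#' @return data.frame (mutant_id, locus, score) including `"WT"` rows
#' @export
synthetic_silencing_scores <- function() {
  its <- c("H2B_del1-16", "H2B_del1-24", "H2B_del1-32", "H2B_del5-36",
           "H2B_del9-24", "H2B_del13-28", "H2B_del17-32")
  lts_h2a <- c("H2A_del114-129", "H2A_del120-129", "H2A_del124-129",
               "H2A_del116-123", "H2A_del110-117")
  rbind(
    data.frame(mutant_id = "WT", locus = c("telomere", "rdna"), score = 4),
    data.frame(mutant_id = its, locus = "telomere",
               score = seq(1.0, 2.2, length.out = length(its))),
    data.frame(mutant_id = "H2B_del29-36", locus = c("telomere", "rdna"),
               score = c(7.5, 7.0)),
    data.frame(mutant_id = lts_h2a, locus = "telomere",
               score = seq(6.5, 8.5, length.out = length(lts_h2a))),
    data.frame(mutant_id = lts_h2a[1:2], locus = "rdna", score = c(6.8, 7.2))
  )
}
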