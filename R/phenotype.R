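# Analytics over the ordinal phenotype-severity matrix, chromosome-loss
# instability calling, and silencing-phenotype classification.
#
# Severities are integers 0-4: 0 means no phenotype, 1-4 grade weak to
# strong sensitivity under a condition. Conditions are grouped into stress
# classes (DNA damage, microtubule destabilisation, temperature, other);
# "phenotype classes I-IV" label the number of distinct stress classes in
# which a mutant shows any phenotype.

#' Load a phenotype-severity matrix from TSV
#'
#' Rows = mutants (first column `id`), columns = conditions, entries integer
#' severities in 0..4.
#' @param path TSV path
#' @return integer matrix with mutant rownames
#' @export
load_phenotype_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  validate_phenotype_matrix(m)
}

validate_phenotype_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0L) stop("phenotype matrix must be non-empty")
  if (anyNA(m) || any(m < 0L) || any(m > 4L))
    stop("severities must be integers in 0..4")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("phenotype matrix needs mutant rownames and condition colnames")
  m
}

#' Default condition-to-stress-class map
#'
#' DNA-damage stresses (HU, MMS, UV, CPT), microtubule destabilisers
#' (benomyl, TBZ), temperature (39C, 16C) and other chemical stresses.
#' @return data.frame (condition, class)
#' @export
default_stress_classes <- function() {
  data.frame(
    condition = c("HU", "MMS", "UV", "CPT", "BEN", "TBZ", "HT39", "LT16",
                  "CAF", "FOR"),
    class = c(rep("DNA_damage", 4), rep("microtubule", 2),
              rep("temperature", 2), rep("other", 2)),
    stringsAsFactors = FALSE
  )
}

#' Aggregate mutant severities to residues
#'
#' For every (histone, residue, condition) the severity shown is the maximum
#' over all mutants touching that residue — when several mutants of one
#' residue have phenotypes, the strongest grade represents the residue.
#'
#' @param m phenotype matrix (mutants x conditions)
#' @param catalog a `mutant_catalog` resolving every matrix mutant
#' @return data.frame with `histone`, `residue`, then one severity column per
#'   condition
#' @export
residue_severity <- function(m, catalog) {
  m <- validate_phenotype_matrix(m)
  idx <- match(rownames(m), catalog$id)
  if (anyNA(idx))
    stop("mutant(s) absent from catalog: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "))
  lens <- lengths(catalog$residues_list[idx])
  rows <- rep(seq_len(nrow(m)), lens)
  key <- paste(rep(catalog$histone[idx], lens),
               unlist(catalog$residues_list[idx]), sep = ":")
  out <- data.frame(do.call(rbind, strsplit(sort(unique(key)), ":", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  names(out) <- c("histone", "residue")
  out$residue <- as.integer(out$residue)
  out <- out[order(out$histone, out$residue), ]
  ukey <- paste(out$histone, out$residue, sep = ":")
  for (cond in colnames(m)) {
    mx <- tapply(m[rows, cond], key, max)
    out[[cond]] <- as.integer(mx[ukey])
  }
  rownames(out) <- NULL
  out
}

#' Count distinct stress classes with a phenotype, per mutant
#'
#' A mutant's class count is the number of distinct stress classes in which
#' it has severity >= 1 under any condition; counts 1-4 carry the display
#' labels I-IV, 0 means no phenotype.
#'
#' @param m phenotype matrix
#' @param class_map data.frame (condition, class) covering every matrix
#'   condition
#' @return data.frame (mutant_id, n_classes, label)
#' @export
count_phenotype_classes <- function(m, class_map = default_stress_classes()) {
  m <- validate_phenotype_matrix(m)
  cls <- class_map$class[match(colnames(m), class_map$condition)]
  if (anyNA(cls))
    stop("condition(s) missing from class map: ",
         paste(colnames(m)[is.na(cls)], collapse = ", "))
  hit <- m >= 1L
  n_cls <- vapply(seq_len(nrow(m)), function(i)
    length(unique(cls[hit[i, ]])), integer(1))
  data.frame(mutant_id = rownames(m), n_classes = n_cls,
             label = c(NA, "I", "II", "III", "IV")[n_cls + 1L],
             stringsAsFactors = FALSE)
}

#' Fraction of mutants showing at least one phenotype
#'
#' @param m phenotype matrix
#' @return list (n_with_phenotype, n_total, fraction)
#' @export
fraction_with_phenotype <- function(m) {
  m <- validate_phenotype_matrix(m)
  n_with <- sum(apply(m, 1L, max) >= 1L)
  list(n_with_phenotype = n_with, n_total = nrow(m),
       fraction = n_with / nrow(m))
}

#' Exact set relation between two mutant sets
#'
#' @param a,b character vectors (sets over a common universe)
#' @return list with `relation` (one of `equal`, `A_subset_B`, `B_subset_A`,
#'   `overlap`, `disjoint`) and Venn counts `a_only`, `b_only`, `both`
#' @export
subset_relation <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- length(intersect(a, b))
  a_only <- length(a) - both
  b_only <- length(b) - both
  relation <-
    if (a_only == 0L && b_only == 0L) "equal"
    else if (a_only == 0L) "A_subset_B"
    else if (b_only == 0L) "B_subset_A"
    else if (both > 0L) "overlap"
    else "disjoint"
  list(relation = relation, a_only = a_only, b_only = b_only, both = both)
}

#' Compare conservation scores across phenotype-class groups
#'
#' Groups mutants by class count (0..4), summarises each group as mean, SEM
#' and n, and runs two-sided Mann-Whitney (Wilcoxon rank-sum) tests between
#' every pair of non-empty groups. Stars mark P < 0.05 (`*`) and P < 0.01
#' (`**`). SEM is flagged `NA` for groups with fewer than 2 scores.
#'
#' @param scores named numeric vector: mutant id -> conservation score
#' @param class_counts data.frame from [count_phenotype_classes()]
#' @return list with `summary` (group, n, mean, sem) and `pairwise`
#'   (group1, group2, p_value, stars)
#' @export
conservation_compare <- function(scores, class_counts) {
  cc <- class_counts$n_classes[match(names(scores), class_counts$mutant_id)]
  if (anyNA(cc))
    stop("score(s) for mutants absent from class counts: ",
         paste(names(scores)[is.na(cc)], collapse = ", "))
  groups <- split(unname(scores), cc)
  summ <- data.frame(
    group = as.integer(names(groups)),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(g)
      if (length(g) >= 2L) stats::sd(g) / sqrt(length(g)) else NA_real_,
      numeric(1)),
    row.names = NULL
  )
  pairs <- utils::combn(names(groups), 2L)
  pw <- data.frame(
    group1 = as.integer(pairs[1L, ]),
    group2 = as.integer(pairs[2L, ]),
    p_value = apply(pairs, 2L, function(pr)
      suppressWarnings(stats::wilcox.test(groups[[pr[1]]], groups[[pr[2]]],
                                          exact = NULL)$p.value))
  )
  pw$stars <- ifelse(pw$p_value < 0.01, "**",
                     ifelse(pw$p_value < 0.05, "*", ""))
  list(summary = summ, pairwise = pw)
}

#' Chromosome-loss rate per generation
#'
#' First-division loss estimator from the sectoring assay: the fraction of
#' colonies that are half-sectored.
#' @param half_sectored,total colony counts (vectorised)
#' @return rate(s) in `[0, 1]`
#' @export
chromosome_loss_rate <- function(half_sectored, total) {
  if (any(total <= 0)) stop("total colony count must be positive")
  if (any(half_sectored < 0) || any(half_sectored > total))
    stop("half-sectored count must lie in [0, total]")
  half_sectored / total
}

#' Call genome instability from loss rates
#'
#' A strain is unstable when its loss rate exceeds the wild-type rate by
#' strictly more than `fold_cut` (default 4: "more than a fourfold increase";
#' a fold of exactly 4 is not called).
#'
#' @param rate_mutant mutant loss rate(s)
#' @param rate_wt wild-type loss rate (> 0)
#' @param fold_cut fold-change cutoff (default 4, strict)
#' @return data.frame (fold, unstable)
#' @export
call_unstable <- function(rate_mutant, rate_wt, fold_cut = 4) {
  if (rate_wt <= 0) stop("wild-type rate must be positive (fold undefined)")
  fold <- rate_mutant / rate_wt
  data.frame(fold = fold, unstable = fold > fold_cut)
}

#' Chromosome-loss analysis of a sectored-colony table
#'
#' @param df data.frame (strain_id, total_colonies, half_sectored) including
#'   a wild-type row
#' @param wt_id strain_id of the wild-type row (default `"WT"`)
#' @param fold_cut strict fold cutoff (default 4)
#' @return data.frame with per-strain `rate_per_generation`, `fold_vs_wt` and
#'   `unstable` (wild-type row excluded from calls)
#' @export
chromosome_loss_analysis <- function(df, wt_id = "WT", fold_cut = 4) {
  stopifnot(all(c("strain_id", "total_colonies", "half_sectored") %in% names(df)))
  if (!wt_id %in% df$strain_id) stop("wild-type row '", wt_id, "' not found")
  df$rate_per_generation <- chromosome_loss_rate(df$half_sectored,
                                                 df$total_colonies)
  wt_rate <- df$rate_per_generation[df$strain_id == wt_id][1L]
  out <- df[df$strain_id != wt_id, ]
  call <- call_unstable(out$rate_per_generation, wt_rate, fold_cut)
  out$fold_vs_wt <- call$fold
  out$unstable <- call$unstable
  attr(out, "wt_rate") <- wt_rate
  out
}

#' Classify a silencing phenotype from reporter scores
#'
#' Scores are on a common numeric scale where higher means more reporter
#' expression, i.e. less silencing. At the telomere locus a mutant scoring
#' more than `delta_cut` above wild type has lost telomeric silencing (LTS);
#' more than `delta_cut` below means increased telomeric silencing (ITS). At
#' the rDNA locus only loss of silencing (LRS) is called.
#'
#' @param score mutant reporter score(s) (vectorised)
#' @param score_wt wild-type score at the same locus
#' @param locus `"telomere"` or `"rdna"`
#' @param delta_cut minimum score difference to call a phenotype
#' @return character vector of calls: `WT`, `LTS`, `ITS` (telomere) or `WT`,
#'   `LRS` (rDNA)
#' @export
call_silencing <- function(score, score_wt, locus = c("telomere", "rdna"),
                           delta_cut = 1) {
  locus <- match.arg(locus)
  d <- score - score_wt
  if (locus == "telomere")
    ifelse(d > delta_cut, "LTS", ifelse(-d > delta_cut, "ITS", "WT"))
  else
    ifelse(d > delta_cut, "LRS", "WT")
}

#' Silencing calls for a score table
#'
#' @param df data.frame (mutant_id, locus, score) with one wild-type row per
#'   locus (`mutant_id == wt_id`)
#' @param wt_id id of the wild-type rows (default `"WT"`)
#' @param delta_cut score difference needed to call a phenotype
#' @return data.frame (mutant_id, locus, score, call)
#' @export
silencing_calls <- function(df, wt_id = "WT", delta_cut = 1) {
  stopifnot(all(c("mutant_id", "locus", "score") %in% names(df)))
  bad <- setdiff(unique(df$locus), c("telomere", "rdna"))
  if (length(bad)) stop("unknown locus: ", paste(bad, collapse = ", "))
  out <- df[df$mutant_id != wt_id, ]
  out$call <- NA_character_
  for (loc in unique(out$locus)) {
    wt <- df$score[df$mutant_id == wt_id & df$locus == loc]
    if (length(wt) != 1L)
      stop("need exactly one wild-type row for locus ", loc)
    sel <- out$locus == loc
    out$call[sel] <- call_silencing(out$score[sel], wt, loc, delta_cut)
  }
  out
}
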