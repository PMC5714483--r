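# Depletion statistics: calling stress-sensitive mutants from treated vs.
# control bar-seq counts.
#
# The calling rule is the screen's printed one: a mutant is sensitive when
# log2 ratio < -1 AND P < 0.01 AND q < 0.01 (all strict). The per-mutant P
# comes from a two-sided exact test on the 2x2 table of (mutant reads,
# rest-of-library reads) across the two arms; q is Benjamini-Hochberg FDR. A
# Holm FWER-adjusted P is reported alongside but does not gate the call.

#' Sensitivity-calling thresholds
#'
#' @param log2_cut log2-ratio cutoff (default -1)
#' @param p_cut raw P cutoff (default 0.01)
#' @param q_cut BH q cutoff (default 0.01)
#' @return a `thresholds` list
#' @export
sensitivity_thresholds <- function(log2_cut = -1, p_cut = 0.01, q_cut = 0.01) {
  stopifnot(is.finite(log2_cut), p_cut > 0, p_cut < 1, q_cut > 0, q_cut < 1)
  structure(list(log2_cut = log2_cut, p_cut = p_cut, q_cut = q_cut),
            class = "thresholds")
}

#' Normalised log2 depletion ratio
#'
#' `log2(((t + pc) / T) / ((c + pc) / C))`: treated vs. control proportions
#' with a pseudocount. With `pseudocount = 0` and `t = c = 0` the ratio is
#' undefined and `NA` is returned.
#'
#' @param t,c mutant read counts in the treated and control samples
#'   (vectorised)
#' @param T_,C_ library sizes (assigned read totals) of the two samples
#' @param pseudocount added to both counts (default 0.5)
#' @return numeric vector of log2 ratios
#' @export
log2_ratio <- function(t, c, T_, C_, pseudocount = 0.5) {
  stopifnot(all(T_ > 0), all(C_ > 0), pseudocount >= 0,
            all(t >= 0), all(c >= 0))
  out <- log2(((t + pseudocount) / T_) / ((c + pseudocount) / C_))
  out[is.nan(out)] <- NA_real_
  out
}

#' Two-sided exact depletion test
#'
#' Exact test on the 2x2 table `[[t, T-t], [c, C-c]]` via the hypergeometric
#' distribution: with `K = t + c` mutant reads among `N = T + C` total, the
#' two-sided P is the sum of probabilities of all tables (with the same
#' margins) no more likely than the observed one — the same definition
#' `fisher.test` uses. Vectorised over mutants.
#'
#' @param t,c mutant read counts in treated and control samples
#' @param T_,C_ library sizes of the two samples
#' @return numeric vector of P values in `(0, 1]`
#' @export
depletion_test <- function(t, c, T_, C_) {
  if (any(T_ <= 0) || any(C_ <= 0))
    stop("degenerate margins: both library sizes must be positive")
  stopifnot(all(t >= 0), all(c >= 0), all(t <= T_), all(c <= C_))
  n <- max(length(t), length(c))
  t <- rep_len(t, n); c <- rep_len(c, n)
  T_ <- rep_len(T_, n); C_ <- rep_len(C_, n)
  vapply(seq_len(n), function(i) {
    K <- t[i] + c[i]
    N <- T_[i] + C_[i]
    if (K == 0L) return(1)
    lo <- max(0L, T_[i] - (N - K))
    hi <- min(T_[i], K)
    x <- lo:hi
    d <- stats::dhyper(x, K, N - K, T_[i])
    d_obs <- stats::dhyper(t[i], K, N - K, T_[i])
    min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q values mapped back to input order (delegates to
#' [stats::p.adjust()]).
#' @param p numeric vector of P values in `[0, 1]`
#' @return q values, same length and order
#' @export
adjust_fdr_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Holm FWER adjustment
#'
#' Step-down adjusted P values with monotonicity enforced, clipped at 1
#' (delegates to [stats::p.adjust()]).
#' @param p numeric vector of P values in `[0, 1]`
#' @return adjusted P values, same length and order
#' @export
adjust_fwer_holm <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Flag sensitive mutants by the printed triple rule
#'
#' Strict inequalities on all three criteria: `log2_ratio < log2_cut`,
#' `p_value < p_cut`, `q_value_fdr < q_cut`. An `NA` log2 ratio never
#' produces a sensitive call.
#'
#' @param results data.frame with columns `log2_ratio`, `p_value`,
#'   `q_value_fdr`
#' @param thresholds a [sensitivity_thresholds()]
#' @return `results` with a logical `sensitive` column
#' @export
classify_sensitive <- function(results, thresholds = sensitivity_thresholds()) {
  stopifnot(all(c("log2_ratio", "p_value", "q_value_fdr") %in% names(results)))
  sens <- results$log2_ratio < thresholds$log2_cut &
    results$p_value < thresholds$p_cut &
    results$q_value_fdr < thresholds$q_cut
  sens[is.na(sens)] <- FALSE
  results$sensitive <- sens
  results
}

#' Depletion analysis of one treated/control sample pair
#'
#' @param t,c per-mutant count vectors (named by mutant id) for the treated
#'   and control samples
#' @param thresholds a [sensitivity_thresholds()]
#' @param pseudocount pseudocount for the log2 ratio
#' @return data.frame (mutant_id, log2_ratio, p_value, q_value_fdr, p_fwer,
#'   sensitive)
#' @export
depletion_results <- function(t, c, thresholds = sensitivity_thresholds(),
                              pseudocount = 0.5) {
  if (is.null(names(t)) || !identical(names(t), names(c)))
    stop("t and c must be equally named per-mutant count vectors")
  T_ <- sum(t); C_ <- sum(c)
  p <- depletion_test(t, c, T_, C_)
  res <- data.frame(
    mutant_id = names(t),
    log2_ratio = log2_ratio(t, c, T_, C_, pseudocount),
    p_value = p,
    q_value_fdr = adjust_fdr_bh(p),
    p_fwer = adjust_fwer_holm(p),
    stringsAsFactors = FALSE
  )
  classify_sensitive(res, thresholds)
}

#' Replicate concordance of two depletion analyses
#'
#' Pearson correlation of log2 ratios (over mutants finite in both) and the
#' overlap of sensitive-candidate sets. Downstream analyses use the
#' intersection of replicate candidate sets.
#'
#' @param res1,res2 data.frames from [depletion_results()] over the same
#'   mutant universe
#' @return list: `pearson_r`, `candidates1`, `candidates2`, `intersection`,
#'   `union`, `jaccard`
#' @export
replicate_concordance <- function(res1, res2) {
  if (!setequal(res1$mutant_id, res2$mutant_id))
    stop("replicates cover different mutant universes")
  res2 <- res2[match(res1$mutant_id, res2$mutant_id), ]
  fin <- is.finite(res1$log2_ratio) & is.finite(res2$log2_ratio)
  r <- if (sum(fin) >= 2L)
    stats::cor(res1$log2_ratio[fin], res2$log2_ratio[fin]) else NA_real_
  s1 <- res1$mutant_id[res1$sensitive]
  s2 <- res2$mutant_id[res2$sensitive]
  inter <- intersect(s1, s2)
  uni <- union(s1, s2)
  list(pearson_r = r,
       candidates1 = s1, candidates2 = s2,
       intersection = inter, union = uni,
       jaccard = if (length(uni) == 0L) 1 else length(inter) / length(uni))
}

#' Full differential analysis of a bar-seq count matrix
#'
#' Analyses each replicate's treated/control pair independently (library
#' sizes are per-sample assigned totals, i.e. column sums of the supplied
#' matrix), then intersects candidate sets across replicates.
#'
#' @param counts mutants x samples integer matrix (e.g. `count_table$matrix`
#'   or [simulate_counts()] output)
#' @param design data.frame (sample_id, condition, replicate) with
#'   `condition` in treated/control
#' @param thresholds a [sensitivity_thresholds()]
#' @param pseudocount pseudocount for log2 ratios
#' @return a `barseq_diff` object: per-replicate result tables, pairwise
#'   concordance (for two replicates), and the intersection candidate set
#' @export
barseq_differential <- function(counts, design,
                                thresholds = sensitivity_thresholds(),
                                pseudocount = 0.5) {
  stopifnot(all(c("sample_id", "condition", "replicate") %in% names(design)),
            all(design$sample_id %in% colnames(counts)))
  reps <- sort(unique(design$replicate))
  per_rep <- lapply(reps, function(r) {
    trt <- design$sample_id[design$condition == "treated" & design$replicate == r]
    ctl <- design$sample_id[design$condition == "control" & design$replicate == r]
    if (length(trt) != 1L || length(ctl) != 1L)
      stop("replicate ", r, " must have exactly one treated and one control sample")
    t <- counts[, trt]; names(t) <- rownames(counts)
    c <- counts[, ctl]; names(c) <- rownames(counts)
    depletion_results(t, c, thresholds, pseudocount)
  })
  names(per_rep) <- paste0("rep", reps)
  conc <- if (length(per_rep) >= 2L)
    replicate_concordance(per_rep[[1L]], per_rep[[2L]]) else NULL
  candidates <- if (length(per_rep) == 1L)
    per_rep[[1L]]$mutant_id[per_rep[[1L]]$sensitive]
  else Reduce(intersect, lapply(per_rep, function(x) x$mutant_id[x$sensitive]))
  structure(list(per_replicate = per_rep, concordance = conc,
                 candidates = candidates, thresholds = thresholds),
            class = "barseq_diff")
}

#' @export
print.barseq_diff <- function(x, ...) {
  cat("Bar-seq differential analysis:", length(x$per_replicate),
      "replicate(s)\n")
  for (nm in names(x$per_replicate))
    cat("  ", nm, ": ", sum(x$per_replicate[[nm]]$sensitive),
        " sensitive candidates\n", sep = "")
  if (!is.null(x$concordance))
    cat("  log2 Pearson r =", round(x$concordance$pearson_r, 3),
        "; overlap =", length(x$concordance$intersection), "of",
        length(x$concordance$union), "\n")
  cat("  intersection candidate set:", length(x$candidates), "mutants\n")
  invisible(x)
}
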