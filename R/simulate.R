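# Synthetic bar-seq experiment generator.
#
# Emulates the pooled histone-mutant fitness experiment: a mutant catalog with
# unique up/down TAG barcodes, a 5-nt sample-index set at pairwise Hamming
# distance >= 2, ground-truth log2 fitness effects, multinomial read counts
# for control and treated arms at the experiment's sequencing depth, and
# paired-end FASTQ amplicon reads with substitution errors. Everything is
# deterministic under a fixed seed.

#' Simulation configuration
#'
#' Defaults describe the study conditions: a 570-mutant pool, two replicates
#' of a treated/control pair, 95,000 read pairs per sample, 10% of mutants
#' depleted with log2 effects centred at -2, and a lognormal baseline pool.
#'
#' @param n_mutants number of mutants in the pool
#' @param tag_length TAG barcode length (nt)
#' @param n_replicates replicate treated/control pairs (samples = 2x this)
#' @param read_pairs_per_sample sequencing depth per sample
#' @param depleted_fraction fraction of mutants with a true fitness defect
#' @param effect_log2_mean,effect_log2_sd normal parameters of the (negative)
#'   log2 effect of depleted mutants; draws are truncated below 0
#' @param abundance_lognormal_sd log-scale sd of baseline pool abundances
#' @param seq_error_rate per-base substitution probability in reads, in
#'   `[0, 0.1]`
#' @param seed integer seed controlling every random choice
#' @return a `sim_config` list
#' @export
sim_config <- function(n_mutants = 570L,
                       tag_length = 20L,
                       n_replicates = 2L,
                       read_pairs_per_sample = 95000L,
                       depleted_fraction = 0.1,
                       effect_log2_mean = -2,
                       effect_log2_sd = 0.4,
                       abundance_lognormal_sd = 0.5,
                       seq_error_rate = 0.005,
                       seed = 1L) {
  stopifnot(n_mutants >= 1L, tag_length >= 1L, n_replicates >= 1L,
            read_pairs_per_sample >= 1L,
            depleted_fraction >= 0, depleted_fraction <= 1,
            seq_error_rate >= 0, seq_error_rate <= 0.1,
            effect_log2_sd >= 0, abundance_lognormal_sd >= 0)
  structure(list(
    n_mutants = as.integer(n_mutants),
    tag_length = as.integer(tag_length),
    n_replicates = as.integer(n_replicates),
    n_samples = 2L * as.integer(n_replicates),
    read_pairs_per_sample = as.integer(read_pairs_per_sample),
    depleted_fraction = depleted_fraction,
    effect_log2_mean = effect_log2_mean,
    effect_log2_sd = effect_log2_sd,
    abundance_lognormal_sd = abundance_lognormal_sd,
    seq_error_rate = seq_error_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# All 5-mers whose base values (A=0,C=1,G=2,T=3) sum to 0 mod 4: a single
# parity-check code of 256 words with minimum pairwise Hamming distance 2.
index_code_words <- function() {
  g <- expand.grid(b1 = 0:3, b2 = 0:3, b3 = 0:3, b4 = 0:3)
  b5 <- (4L - (g$b1 + g$b2 + g$b3 + g$b4) %% 4L) %% 4L
  m <- cbind(as.matrix(g), b5)
  apply(m, 1L, function(r) paste(DNA_BASES[r + 1L], collapse = ""))
}

random_tags <- function(n, tag_length, min_dist = 3L) {
  draw <- function(k) {
    m <- matrix(sample(DNA_BASES, k * tag_length, replace = TRUE),
                nrow = k, ncol = tag_length)
    apply(m, 1L, paste, collapse = "")
  }
  tags <- draw(n)
  for (iter in 1:50) {
    if (length(tags) < 2L) break
    viol <- hamming_violations(tags, min_dist)
    if (nrow(viol) == 0L) break
    redo <- unique(viol$j)   # keep first of each close pair, redraw the other
    tags[redo] <- draw(length(redo))
  }
  tags
}

#' Generate a mutant catalog and sample-index set
#'
#' TAG barcodes are random `tag_length`-mers redrawn until the whole up+down
#' tag set sits at pairwise Hamming distance >= 3 (the condition under which
#' 1-mismatch tag matching is provably unambiguous). Sample indices are drawn
#' from a parity-check code of 5-mers whose minimum pairwise distance is 2.
#' Alleles are plausible point substitutions spread over the H2A/H2B residue
#' ranges, plus a few tail deletions.
#'
#' @param config a [sim_config()]
#' @return list with elements `catalog` (a `mutant_catalog`) and `indices`
#'   (a `sample_index_table`)
#' @export
generate_catalog <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_mutants

  # a few fixed tail deletions, then point substitutions cycling over residues
  dels <- data.frame(
    histone = c("H2A", "H2A", "H2B", "H2B", "H2B", "H2B"),
    allele  = c("del120-129", "del124-129", "del1-32", "del5-36",
                "del29-36", "del1-16"),
    stringsAsFactors = FALSE
  )
  dels <- dels[seq_len(min(nrow(dels), max(0L, n - 2L))), , drop = FALSE]
  n_pt <- n - nrow(dels)
  ranges <- list(H2A = 132L, H2B = 131L)
  wt_letters <- c("K", "R", "S", "T", "E", "Q", "L", "I", "V", "G")
  sub_letters <- c("A", "Q", "E", "R")
  pts <- data.frame(histone = character(n_pt), allele = character(n_pt),
                    stringsAsFactors = FALSE)
  i <- 0L; pos <- 0L
  while (i < n_pt) {
    pos <- pos + 1L
    for (h in names(ranges)) {
      res <- (pos - 1L) %% ranges[[h]] + 1L
      wt <- wt_letters[(res - 1L) %% length(wt_letters) + 1L]
      cycle <- (pos - 1L) %/% ranges[[h]]
      alt <- setdiff(sub_letters, wt)
      mut <- alt[cycle %% length(alt) + 1L]
      i <- i + 1L
      if (i > n_pt) break
      pts$histone[i] <- h
      pts$allele[i] <- sprintf("%s%d%s", wt, res, mut)
    }
  }
  ann <- rbind(pts, dels)[seq_len(n), , drop = FALSE]
  ann$id <- sprintf("%s_%s", ann$histone, ann$allele)
  # the cycling scheme can only collide if n exceeds the allele space
  if (anyDuplicated(ann$id)) stop("allele space exhausted for n_mutants = ", n)
  ann$residues <- vapply(ann$allele,
                         function(a) paste(allele_residues(a), collapse = ","),
                         character(1))

  tags <- random_tags(2L * n, config$tag_length, min_dist = 3L)
  catalog <- validate_catalog_df(data.frame(
    id = ann$id, histone = ann$histone, allele = ann$allele,
    residues = ann$residues,
    uptag = tags[seq_len(n)], downtag = tags[n + seq_len(n)],
    stringsAsFactors = FALSE
  ))

  code <- index_code_words()
  if (config$n_samples > length(code))
    stop("cannot build ", config$n_samples,
         " distinct 5-nt indices at pairwise distance >= 2 (max ",
         length(code), ")")
  chosen <- sample(code, config$n_samples)
  design <- expand.grid(condition = c("treated", "control"),
                        replicate = seq_len(config$n_replicates),
                        stringsAsFactors = FALSE)
  indices <- validate_index_table(data.frame(
    sample_id = sprintf("%s_rep%d", design$condition, design$replicate),
    index_seq = chosen,
    condition = design$condition,
    replicate = design$replicate,
    stringsAsFactors = FALSE
  ))
  list(catalog = catalog, indices = indices)
}

#' Draw ground-truth fitness effects
#'
#' A `depleted_fraction` of mutants receives a strictly negative log2 effect
#' drawn from Normal(`effect_log2_mean`, `effect_log2_sd`) truncated below 0;
#' all other mutants have effect exactly 0.
#'
#' @param catalog a `mutant_catalog`
#' @param config a [sim_config()]
#' @return data.frame (id, true_log2_effect, is_depleted)
#' @export
ground_truth <- function(catalog, config) {
  set.seed(derive_seed(config$seed, 2L))
  n <- nrow(catalog)
  n_dep <- round(config$depleted_fraction * n)
  dep_idx <- if (n_dep > 0) sample.int(n, n_dep) else integer(0)
  eff <- rep(0, n)
  if (n_dep > 0) {
    draws <- stats::rnorm(n_dep, config$effect_log2_mean, config$effect_log2_sd)
    while (any(draws >= 0))
      draws[draws >= 0] <- stats::rnorm(sum(draws >= 0),
                                        config$effect_log2_mean,
                                        config$effect_log2_sd)
    eff[dep_idx] <- draws
  }
  data.frame(id = catalog$id, true_log2_effect = eff,
             is_depleted = eff < 0, stringsAsFactors = FALSE)
}

#' Simulate per-sample read counts for the two-arm design
#'
#' Baseline pool proportions are lognormal-then-normalised; treated-arm
#' proportions are the baseline multiplied by `2^effect` and renormalised.
#' Each sample is an independent multinomial draw of
#' `read_pairs_per_sample` reads, so every column sums to the configured
#' depth.
#'
#' @param catalog a `mutant_catalog`
#' @param truth data.frame from [ground_truth()] covering every mutant
#' @param config a [sim_config()]
#' @return list with `counts` (mutants x samples integer matrix), `design`
#'   (sample_id, condition, replicate), and `proportions` (control/treated
#'   expected proportions)
#' @export
simulate_counts <- function(catalog, truth, config) {
  n <- nrow(catalog)
  if (n == 0L) stop("catalog has zero mutants")
  if (!setequal(truth$id, catalog$id))
    stop("truth must cover exactly the catalog mutants")
  set.seed(derive_seed(config$seed, 3L))
  eff <- truth$true_log2_effect[match(catalog$id, truth$id)]
  base <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_lognormal_sd)
  p_ctrl <- base / sum(base)
  w <- p_ctrl * 2^eff
  p_trt <- w / sum(w)
  design <- data.frame(
    sample_id = sprintf("%s_rep%d",
                        rep(c("treated", "control"), config$n_replicates),
                        rep(seq_len(config$n_replicates), each = 2L)),
    condition = rep(c("treated", "control"), config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), each = 2L),
    stringsAsFactors = FALSE
  )
  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(catalog$id, design$sample_id))
  for (s in seq_len(nrow(design))) {
    p <- if (design$condition[s] == "treated") p_trt else p_ctrl
    counts[, s] <- as.integer(stats::rmultinom(1L, config$read_pairs_per_sample, p))
  }
  list(counts = counts, design = design,
       proportions = list(control = p_ctrl, treated = p_trt))
}

# substitute bases at random positions of a fixed-width read block
apply_seq_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  m <- seq_char_matrix(reads)
  ncell <- length(m)
  k <- stats::rbinom(1L, ncell, error_rate)
  if (k == 0L) return(reads)
  pos <- sample.int(ncell, k)
  alt <- matrix(c("C", "G", "T",   # alternatives to A
                  "A", "G", "T",   # to C
                  "A", "C", "T",   # to G
                  "A", "C", "G"),  # to T
                nrow = 4L, byrow = TRUE)
  cur <- match(m[pos], DNA_BASES)
  m[pos] <- alt[cbind(cur, sample.int(3L, k, replace = TRUE))]
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

write_fastq_gz <- function(path, ids, seqs, qual_char = "I") {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (length(seqs) == 0L) {
    # valid empty FASTQ
    writeLines(character(0), con)
    return(invisible(path))
  }
  qual <- strrep(qual_char, nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), con, sep = "\n")
  invisible(path)
}

#' Emit paired FASTQ files for a simulated count table
#'
#' For each sample, writes `<sample_id>_R1.fastq.gz` and
#' `<sample_id>_R2.fastq.gz`. Read 1 is index + upstream flank + uptag +
#' downstream flank; read 2 carries the downtag between the same flanks
#' (reverse-complemented if the layout says so). Substitution errors are
#' applied at `config$seq_error_rate`; the quality string is constant Q40.
#' Also writes `truth.tsv` and `counts.tsv` alongside the reads.
#'
#' @param catalog a `mutant_catalog`
#' @param sim output of [simulate_counts()]
#' @param indices a `sample_index_table` covering every design sample
#' @param layout an [amplicon_layout()]
#' @param config a [sim_config()]
#' @param outdir output directory (created if needed)
#' @param truth optional [ground_truth()] table to write as the manifest
#' @return invisible list of per-sample file paths
#' @export
emit_fastq <- function(catalog, sim, indices, layout, config, outdir,
                       truth = NULL) {
  if (!all(sim$design$sample_id %in% indices$sample_id))
    stop("indices do not cover all design samples")
  if (layout$index_offset + 5L > layout_read1_length(layout))
    stop("index does not fit within the constructed read")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(config$seed, 4L))
  pad <- strrep("A", layout$index_offset)
  files <- list()
  for (s in seq_len(nrow(sim$design))) {
    sid <- sim$design$sample_id[s]
    idx <- indices$index_seq[match(sid, indices$sample_id)]
    cnt <- sim$counts[, s]
    mut_rows <- rep(seq_len(nrow(catalog)), cnt)
    if (length(mut_rows) > 1L) mut_rows <- sample(mut_rows)  # shuffle read order
    if (length(mut_rows)) {
      r1 <- paste0(pad, idx, layout$upstream_flank, catalog$uptag[mut_rows],
                   layout$downstream_flank)
      dtag <- catalog$downtag[mut_rows]
      if (layout$mate_revcomp) dtag <- revcomp(dtag)
      r2 <- paste0(layout$upstream_flank, dtag, layout$downstream_flank)
    } else {
      r1 <- r2 <- character(0)  # paste0() would coerce empty to one read
    }
    r1 <- apply_seq_errors(r1, config$seq_error_rate)
    r2 <- apply_seq_errors(r2, config$seq_error_rate)
    ids <- sprintf("sim:%s:%d/%d", sid, seq_along(mut_rows), 1L)
    f1 <- file.path(outdir, paste0(sid, "_R1.fastq.gz"))
    f2 <- file.path(outdir, paste0(sid, "_R2.fastq.gz"))
    write_fastq_gz(f1, ids, r1)
    write_fastq_gz(f2, sub("/1$", "/2", ids), r2)
    files[[sid]] <- c(r1 = f1, r2 = f2)
  }
  if (!is.null(truth))
    utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = rownames(sim$counts), sim$counts, check.names = FALSE),
    file.path(outdir, "counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(files)
}

#' Run the whole generator in one call
#'
#' Convenience wrapper: catalog + indices + ground truth + counts, and
#' (optionally) FASTQ emission.
#'
#' @param config a [sim_config()]
#' @param outdir if non-NULL, paired FASTQ plus manifests are written here
#' @return a `barseq_simulation` list: catalog, indices, truth, counts,
#'   design, proportions, files (NULL unless `outdir` given), config
#' @export
simulate_screen <- function(config = sim_config(), outdir = NULL) {
  gen <- generate_catalog(config)
  truth <- ground_truth(gen$catalog, config)
  sim <- simulate_counts(gen$catalog, truth, config)
  files <- if (!is.null(outdir))
    emit_fastq(gen$catalog, sim, gen$indices, amplicon_layout(
      tag_length = config$tag_length), config, outdir, truth = truth)
  structure(list(
    catalog = gen$catalog, indices = gen$indices, truth = truth,
    counts = sim$counts, design = sim$design, proportions = sim$proportions,
    files = files, config = config
  ), class = "barseq_simulation")
}

#' @export
print.barseq_simulation <- function(x, ...) {
  cat("Simulated bar-seq screen:", nrow(x$catalog), "mutants,",
      ncol(x$counts), "samples,", x$config$read_pairs_per_sample,
      "read pairs/sample\n")
  cat("Depleted mutants:", sum(x$truth$is_depleted), "\n")
  invisible(x)
}
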