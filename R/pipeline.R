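# End-to-end bar-seq pipeline: simulate an experiment, emit reads, rebuild
# the count table from FASTQ, and run the differential analysis.

#' Run the simulated bar-seq experiment end to end
#'
#' Generates a pool (catalog, indices, ground truth, counts), writes paired
#' FASTQ, demultiplexes and counts the reads back, runs the per-replicate
#' depletion analysis and intersects candidates across replicates, and scores
#' the candidate set against the simulation truth.
#'
#' @param config a [sim_config()]
#' @param workdir directory for FASTQ and manifests (a temporary directory by
#'   default, removed afterwards unless supplied)
#' @param max_mismatch TAG-matching tolerance passed to
#'   [build_count_table()]
#' @param thresholds a [sensitivity_thresholds()]
#' @return a `barseq_pipeline` list: simulation, count_table, diff
#'   (a `barseq_diff`), and `recovery` (sensitivity and false-discovery
#'   proportion of the intersection candidate set against truth)
#' @export
run_barseq_pipeline <- function(config = sim_config(), workdir = NULL,
                                max_mismatch = 1L,
                                thresholds = sensitivity_thresholds()) {
  cleanup <- is.null(workdir)
  if (cleanup) workdir <- tempfile("barseq_")
  on.exit(if (cleanup) unlink(workdir, recursive = TRUE))
  sim <- simulate_screen(config, outdir = workdir)
  layout <- amplicon_layout(tag_length = config$tag_length)
  r1 <- vapply(sim$files, `[[`, character(1), "r1")
  r2 <- vapply(sim$files, `[[`, character(1), "r2")
  ct <- build_count_table(r1, sim$catalog, sim$indices, layout, r2 = r2,
                          max_mismatch = max_mismatch)
  diff <- barseq_differential(ct$matrix, sim$design, thresholds)
  truth_dep <- sim$truth$id[sim$truth$is_depleted]
  called <- diff$candidates
  recovery <- list(
    sensitivity = if (length(truth_dep)) mean(truth_dep %in% called) else NA_real_,
    fdp = if (length(called)) mean(!(called %in% truth_dep)) else 0,
    n_called = length(called),
    n_true = length(truth_dep)
  )
  structure(list(simulation = sim, count_table = ct, diff = diff,
                 recovery = recovery),
            class = "barseq_pipeline")
}

#' @export
print.barseq_pipeline <- function(x, ...) {
  print(x$diff)
  cat(sprintf("Recovery vs. simulation truth: sensitivity %.3f, FDP %.3f (%d called / %d true)\n",
              x$recovery$sensitivity, x$recovery$fdp, x$recovery$n_called,
              x$recovery$n_true))
  invisible(x)
}
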