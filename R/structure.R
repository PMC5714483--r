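# Mapping phenotype residues onto the nucleosome crystal structure and
# testing whether a residue set clusters spatially.
#
# The nucleosome contains two copies of each histone; a residue therefore
# maps to all its chain instances, and the distance between two residues is
# the minimum Calpha distance over the symmetric copies. The clustering
# statistic is the mean pairwise Calpha distance of the query set, compared
# to same-size sets drawn from the same histone composition.

#' Parse Calpha coordinates from a PDB file
#'
#' Reads the file with [bio3d::read.pdb()], keeps Calpha atoms of the mapped
#' histone chains (DNA and unmapped chains are skipped silently), and
#' resolves alternate locations to the highest-occupancy record, first-listed
#' on ties. Mapped residues lacking a Calpha record are skipped with a
#' warning.
#'
#' @param path PDB file
#' @param chain_map named character vector: chain id -> histone
#'   (H2A/H2B/H3/H4)
#' @return a `residue_coords` data.frame (chain, histone, residue_number,
#'   x, y, z)
#' @export
parse_structure <- function(path, chain_map) {
  stopifnot(length(chain_map) > 0, !is.null(names(chain_map)))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$chain %in% names(chain_map) & at$type == "ATOM", , drop = FALSE]
  # residues present in a mapped chain but with no Calpha record
  all_res <- unique(paste(at$chain, at$resno))
  at <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(all_res, unique(paste(at$chain, at$resno)))
  if (length(missing_ca))
    warning("skipping residue(s) without a Calpha record: ",
            paste(missing_ca, collapse = ", "))
  # altloc: highest occupancy, then first listed
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(at$chain, at$resno, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno)), , drop = FALSE]
  out <- data.frame(
    chain = at$chain,
    histone = unname(chain_map[at$chain]),
    residue_number = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite coordinates in structure")
  out <- out[order(out$chain, out$residue_number), ]
  rownames(out) <- NULL
  class(out) <- c("residue_coords", "data.frame")
  out
}

#' Write Calpha-only PDB records
#'
#' Minimal PDB writer used to build small synthetic structures in tests and
#' examples; one `ATOM` Calpha record per row.
#'
#' @param df data.frame with columns chain, residue_number, x, y, z and
#'   optionally `occ`, `alt`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb_ca <- function(df, path) {
  occ <- if ("occ" %in% names(df)) df$occ else rep(1, nrow(df))
  alt <- if ("alt" %in% names(df)) df$alt else rep(" ", nrow(df))
  lines <- sprintf(
    "ATOM  %5d  CA %1sALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(df)), alt, df$chain, df$residue_number,
    df$x, df$y, df$z, occ, 0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a synthetic two-copy histone structure
#'
#' Random compact coordinate sets for each histone, duplicated into two
#' chains per histone (as in the nucleosome), for testing structure-mapping
#' code without the crystal structure. Purely synthetic geometry.
#'
#' @param n_per_histone residues per histone chain
#' @param histones histones to include
#' @param seed integer seed
#' @return a `residue_coords` data.frame
#' @export
synthetic_structure <- function(n_per_histone = 40L,
                                histones = c("H2A", "H2B"),
                                seed = 1L) {
  set.seed(seed)
  chains <- LETTERS[seq_len(2L * length(histones))]
  out <- do.call(rbind, lapply(seq_along(histones), function(i) {
    # a compact random walk per histone, offset per copy
    step <- matrix(stats::rnorm(3L * n_per_histone, sd = 2), ncol = 3L)
    base <- apply(step, 2L, cumsum) + 10 * i
    do.call(rbind, lapply(0:1, function(copy) {
      data.frame(chain = chains[2L * (i - 1L) + copy + 1L],
                 histone = histones[i],
                 residue_number = seq_len(n_per_histone),
                 x = base[, 1] + 25 * copy, y = base[, 2], z = base[, 3],
                 stringsAsFactors = FALSE)
    }))
  }))
  class(out) <- c("residue_coords", "data.frame")
  out
}

# minimum-over-copies Calpha distance matrix between unique
# (histone, residue) keys
residue_distance_matrix <- function(coords) {
  key <- paste(coords$histone, coords$residue_number, sep = ":")
  ukey <- unique(key)
  g <- match(key, ukey)
  D_at <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  n <- length(ukey)
  D <- matrix(0, n, n, dimnames = list(ukey, ukey))
  for (i in seq_len(n - 1L)) {
    ri <- which(g == i)
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- min(D_at[ri, which(g == j)])
    }
  }
  D
}

mean_pairwise <- function(D, idx) {
  sub <- D[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Permutation test for spatial clustering of a residue set
#'
#' Observed statistic: mean pairwise Calpha distance (in Angstrom, minimum
#' over symmetric chain copies) of the query residues. Null: sets of the same
#' size drawn uniformly without replacement from the structure's residues,
#' preserving the query's per-histone composition. The P value uses the
#' add-one permutation formula `(1 + #(null <= observed)) / (1 + n)`; with
#' `exact = TRUE` every same-composition set is enumerated instead and the P
#' value is the exact fraction of sets at or below the observed statistic.
#'
#' @param query data.frame (histone, residue) of at least 2 residues
#' @param coords a `residue_coords` table covering the query
#' @param n_permutations permutation draws (ignored when `exact = TRUE`)
#' @param seed integer seed for the draws
#' @param exact enumerate all same-composition sets (feasible for toy
#'   structures only)
#' @return a `cluster_test` list: observed_stat, null_mean, null_sd,
#'   p_value, n_permutations, seed, exact
#' @export
spatial_clustering_test <- function(query, coords, n_permutations = 10000L,
                                    seed = 1L, exact = FALSE) {
  stopifnot(all(c("histone", "residue") %in% names(query)))
  query <- unique(query[, c("histone", "residue")])
  if (nrow(query) < 2L) stop("query must contain at least 2 residues")
  D <- residue_distance_matrix(coords)
  qkey <- paste(query$histone, query$residue, sep = ":")
  missing <- setdiff(qkey, rownames(D))
  if (length(missing))
    stop("query residue(s) without coordinates: ",
         paste(missing, collapse = ", "))
  qidx <- match(qkey, rownames(D))
  observed <- mean_pairwise(D, qidx)

  pool_hist <- sub(":.*$", "", rownames(D))
  comp <- table(query$histone)
  pools <- lapply(names(comp), function(h) which(pool_hist == h))
  names(pools) <- names(comp)

  if (exact) {
    combos_per_h <- lapply(names(comp), function(h)
      utils::combn(pools[[h]], comp[[h]], simplify = FALSE))
    n_total <- prod(lengths(combos_per_h))
    if (n_total > 2e5)
      stop("exact enumeration infeasible: ", n_total, " sets")
    grid <- expand.grid(lapply(combos_per_h, seq_along))
    null_stats <- vapply(seq_len(nrow(grid)), function(r) {
      idx <- unlist(lapply(seq_along(combos_per_h), function(k)
        combos_per_h[[k]][[grid[r, k]]]))
      mean_pairwise(D, idx)
    }, numeric(1))
    p <- mean(null_stats <= observed)
    n_used <- n_total
  } else {
    set.seed(seed)
    null_stats <- vapply(seq_len(n_permutations), function(r) {
      idx <- unlist(lapply(names(pools), function(h)
        pools[[h]][sample.int(length(pools[[h]]), comp[[h]])]))
      mean_pairwise(D, idx)
    }, numeric(1))
    p <- (1 + sum(null_stats <= observed)) / (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(observed_stat = observed,
                 null_mean = mean(null_stats),
                 null_sd = stats::sd(null_stats),
                 p_value = p,
                 n_permutations = n_used,
                 seed = seed,
                 exact = exact),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("Spatial clustering permutation test\n")
  cat(sprintf("  observed mean pairwise distance: %.2f A\n", x$observed_stat))
  cat(sprintf("  null: %.2f +/- %.2f A over %d %s\n", x$null_mean, x$null_sd,
              x$n_permutations,
              if (x$exact) "enumerated sets" else "permutations"))
  cat(sprintf("  P = %.4g\n", x$p_value))
  invisible(x)
}

#' Map residue severities onto structure coordinates
#'
#' Joins a residue-severity table to the structure and assigns the two-tier
#' display band used for structure colouring: band `"high"` for severities
#' 3-4, `"low"` for 1-2. Residues with severity 0 are dropped; annotated
#' residues absent from the structure are returned in the unmapped report.
#'
#' @param res_sev data.frame with `histone`, `residue` and either a
#'   `severity` column or per-condition severity columns (as produced by
#'   [residue_severity()]), in which case the per-residue maximum is used
#' @param coords a `residue_coords` table
#' @return list: `mapped` (chain, histone, residue, severity, band, x, y, z)
#'   and `unmapped` (histone, residue, severity)
#' @export
map_annotations <- function(res_sev, coords) {
  stopifnot(all(c("histone", "residue") %in% names(res_sev)))
  if (!"severity" %in% names(res_sev)) {
    sev_cols <- setdiff(names(res_sev), c("histone", "residue"))
    res_sev$severity <- do.call(pmax, res_sev[sev_cols])
  }
  ann <- res_sev[res_sev$severity >= 1L, c("histone", "residue", "severity")]
  ckey <- paste(coords$histone, coords$residue_number, sep = ":")
  akey <- paste(ann$histone, ann$residue, sep = ":")
  hit <- akey %in% ckey
  mapped <- merge(
    data.frame(histone = ann$histone[hit], residue = ann$residue[hit],
               severity = ann$severity[hit], stringsAsFactors = FALSE),
    data.frame(chain = coords$chain, histone = coords$histone,
               residue = coords$residue_number,
               x = coords$x, y = coords$y, z = coords$z,
               stringsAsFactors = FALSE),
    by = c("histone", "residue")
  )
  mapped$band <- ifelse(mapped$severity >= 3L, "high", "low")
  mapped <- mapped[order(mapped$chain, mapped$residue), ]
  rownames(mapped) <- NULL
  list(mapped = mapped,
       unmapped = ann[!hit, , drop = FALSE])
}

#' Write a molecular-viewer attribute file
#'
#' Plain per-residue text: one `chain<TAB>residue<TAB>value` line per mapped
#' residue, loadable as a custom attribute in molecular viewers.
#'
#' @param mapped the `mapped` table from [map_annotations()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_attribute_file <- function(mapped, path) {
  lines <- sprintf("%s\t%d\t%d", mapped$chain, mapped$residue, mapped$severity)
  writeLines(lines, path)
  invisible(path)
}
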