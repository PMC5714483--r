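# Mutant catalog, sample-index table and amplicon layout: the domain objects
# shared by the simulator, the demultiplexer/counter and the phenotype
# analytics.
#
# A catalog row describes one histone mutant: its allele (point substitution
# such as K34E, tail deletion such as del29-36, or compound substitution such
# as K6,11,16Q), the protein residues the allele touches, and the pair of
# strain-specific TAG barcodes (uptag/downtag) amplified with common primers.

#' Parse an allele string into affected residue positions
#'
#' Understands three allele shapes: point substitutions (`"K34E"`), tail
#' deletions (`"del29-36"`, residues 29..36), and compound substitutions
#' (`"K6,11,16Q"`, residues 6, 11, 16).
#'
#' @param allele allele string
#' @return integer vector of 1-based residue positions (sorted, unique)
#' @export
#' @examples
#' allele_residues("K34E")
#' allele_residues("del29-36")
#' allele_residues("K6,11,16Q")
allele_residues <- function(allele) {
  stopifnot(is.character(allele), length(allele) == 1L, nzchar(allele))
  if (grepl("^del[0-9]+-[0-9]+$", allele)) {
    bounds <- as.integer(strsplit(sub("^del", "", allele), "-", fixed = TRUE)[[1]])
    if (bounds[1] > bounds[2]) stop("deletion allele with reversed bounds: ", allele)
    return(seq.int(bounds[1], bounds[2]))
  }
  if (grepl("^[A-Z][0-9]+(,[0-9]+)*[A-Z]$", allele)) {
    pos <- as.integer(strsplit(gsub("^[A-Z]|[A-Z]$", "", allele), ",", fixed = TRUE)[[1]])
    return(sort(unique(pos)))
  }
  stop("unparseable allele string: ", allele)
}

validate_catalog_df <- function(df) {
  required <- c("id", "histone", "allele", "residues", "uptag", "downtag")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    stop("duplicate mutant id(s) in catalog: ", paste(dup, collapse = ", "))
  }
  bad_hist <- setdiff(unique(df$histone), c("H2A", "H2B", "H3", "H4"))
  if (length(bad_hist))
    stop("unknown histone label(s): ", paste(bad_hist, collapse = ", "))
  for (col in c("uptag", "downtag")) {
    bad <- !is_dna(df[[col]])
    if (any(bad))
      stop("non-DNA characters in ", col, " for id(s): ",
           paste(df$id[bad], collapse = ", "))
  }
  tags <- c(df$uptag, df$downtag)
  if (anyDuplicated(tags)) {
    dup_tag <- unique(tags[duplicated(tags)])
    offenders <- df$id[df$uptag %in% dup_tag | df$downtag %in% dup_tag]
    stop("duplicate TAG barcode(s) shared by id(s): ",
         paste(offenders, collapse = ", "))
  }
  res_list <- lapply(strsplit(df$residues, ",", fixed = TRUE), as.integer)
  if (any(vapply(res_list, function(r) length(r) == 0L || anyNA(r), logical(1))))
    stop("residues column must hold comma-joined integers for every mutant")
  # deletion alleles must list exactly their deleted range
  is_del <- grepl("^del[0-9]+-[0-9]+$", df$allele)
  for (i in which(is_del)) {
    expect <- allele_residues(df$allele[i])
    if (!identical(sort(res_list[[i]]), expect))
      stop("residues for deletion allele ", df$id[i],
           " do not match its del range")
  }
  df$residues_list <- res_list
  class(df) <- c("mutant_catalog", "data.frame")
  df
}

#' Load a mutant catalog from a TSV file
#'
#' Expected columns: `id`, `histone`, `allele`, `residues` (comma-joined
#' 1-based integer positions), `uptag`, `downtag`. Barcodes must be strict
#' ACGT and unique across the whole catalog (up- and downtags jointly).
#'
#' @param path path to a tab-separated file with header
#' @return a `mutant_catalog` (data.frame subclass) with a parsed
#'   `residues_list` column
#' @export
load_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_catalog_df(df)
}

#' Write a mutant catalog to TSV
#'
#' Canonical column order; `save_catalog()` then [load_catalog()] is an
#' identity round-trip.
#' @param catalog a `mutant_catalog`
#' @param path output path
#' @return `path`, invisibly
#' @export
save_catalog <- function(catalog, path) {
  cols <- c("id", "histone", "allele", "residues", "uptag", "downtag")
  utils::write.table(as.data.frame(catalog)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.mutant_catalog <- function(x, ...) {
  cat("Mutant catalog:", nrow(x), "mutants (",
      paste(sprintf("%s: %d", names(table(x$histone)), table(x$histone)),
            collapse = ", "), ")\n")
  cat("TAG length:", unique(nchar(x$uptag)), "nt; min pairwise tag Hamming:",
      if (nrow(x) > 1) min_pairwise_hamming(c(x$uptag, x$downtag)) else NA, "\n")
  invisible(x)
}

#' Validate a sample-index set
#'
#' Sample indices are the 5-nt sequences that assign each read to its pooled
#' sample; every pair must differ at two or more positions so that a single
#' sequencing error can never convert one valid index into another.
#' Violations are reported, not raised.
#'
#' @param indices character vector of index sequences, or a data.frame with an
#'   `index_seq` column
#' @return a list with elements `valid` (logical), `violations` (data.frame of
#'   offending pairs with their distances), and `bad_length` (indices whose
#'   length is not 5)
#' @export
#' @examples
#' validate_index_set(c("AAAAA", "AATTT"))$valid
#' validate_index_set(c("AAAAA", "AAAAT"))$violations
validate_index_set <- function(indices) {
  if (is.data.frame(indices)) indices <- indices$index_seq
  if (length(indices) == 0L) stop("empty index set")
  bad_length <- indices[nchar(indices) != 5L | !is_dna(indices)]
  ok <- indices[nchar(indices) == 5L & is_dna(indices)]
  violations <- if (length(ok) >= 2L) hamming_violations(ok, 2L) else
    data.frame(i = integer(0), j = integer(0), seq_i = character(0),
               seq_j = character(0), distance = integer(0))
  list(
    valid = length(bad_length) == 0L && nrow(violations) == 0L,
    violations = violations,
    bad_length = bad_length
  )
}

#' Load a sample-index table from TSV
#'
#' Columns: `sample_id`, `index_seq` (5 nt), `condition` (`treated` or
#' `control`), `replicate` (positive integer). The index set must pass
#' [validate_index_set()].
#'
#' @param path path to TSV with header
#' @return validated `sample_index_table` data.frame
#' @export
load_index_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_index_table(df)
}

validate_index_table <- function(df) {
  required <- c("sample_id", "index_seq", "condition", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("index table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in index table")
  bad_cond <- setdiff(unique(df$condition), c("treated", "control"))
  if (length(bad_cond))
    stop("condition must be 'treated' or 'control'; got: ",
         paste(bad_cond, collapse = ", "))
  if (any(df$replicate < 1L)) stop("replicate must be a positive integer")
  rep_chk <- validate_index_set(df$index_seq)
  if (!rep_chk$valid)
    stop("index set invalid: ",
         if (length(rep_chk$bad_length)) "bad index length; " else "",
         if (nrow(rep_chk$violations))
           paste0(nrow(rep_chk$violations), " pair(s) at Hamming distance < 2"))
  class(df) <- c("sample_index_table", "data.frame")
  df
}

#' @export
save_index_table <- function(indices, path) {
  cols <- c("sample_id", "index_seq", "condition", "replicate")
  utils::write.table(as.data.frame(indices)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Common annealing sequences flanking the TAG in the amplicon, modelled on the
# yeast TAG-collection common primer pairs.
DEFAULT_UPSTREAM_FLANK <- "GATGTCCACGAGGTCTCT"
DEFAULT_DOWNSTREAM_FLANK <- "CGTACGCTGCAGGTCGAC"

#' Describe the amplicon read layout
#'
#' Read 1 carries the 5-nt sample index at `index_offset`, then the upstream
#' annealing flank, the strain TAG of `tag_length` nt, and the downstream
#' flank. Read 2 carries the partner TAG between the same flanks, optionally
#' reverse-complemented.
#'
#' @param upstream_flank,downstream_flank constant annealing sequences around
#'   the TAG (non-empty DNA)
#' @param tag_length TAG barcode length in nt (default 20, the classic yeast
#'   deletion-collection TAG length)
#' @param index_offset 0-based offset of the 5-nt index within read 1
#' @param tag_read which mate carries the counted TAG (1 or 2)
#' @param mate_revcomp is the partner TAG on the other mate stored
#'   reverse-complemented?
#' @return an `amplicon_layout` list
#' @export
amplicon_layout <- function(upstream_flank = DEFAULT_UPSTREAM_FLANK,
                            downstream_flank = DEFAULT_DOWNSTREAM_FLANK,
                            tag_length = 20L,
                            index_offset = 0L,
                            tag_read = 1L,
                            mate_revcomp = FALSE) {
  if (!is_dna(upstream_flank) || !is_dna(downstream_flank))
    stop("flanks must be non-empty ACGT strings")
  if (tag_length < 1L) stop("tag_length must be positive")
  if (index_offset < 0L) stop("index_offset must be >= 0")
  if (!tag_read %in% c(1L, 2L)) stop("tag_read must be 1 or 2")
  structure(list(
    upstream_flank = upstream_flank,
    downstream_flank = downstream_flank,
    tag_length = as.integer(tag_length),
    index_offset = as.integer(index_offset),
    tag_read = as.integer(tag_read),
    mate_revcomp = isTRUE(mate_revcomp)
  ), class = "amplicon_layout")
}

# length of a read-1 built from this layout
layout_read1_length <- function(layout) {
  layout$index_offset + 5L + nchar(layout$upstream_flank) +
    layout$tag_length + nchar(layout$downstream_flank)
}
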