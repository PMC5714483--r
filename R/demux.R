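# FASTQ demultiplexing and TAG counting.
#
# Policy (deliberate, documented): sample indices are matched exactly — at
# pairwise distance 2 a single error can leave a read equidistant from two
# valid indices, so no correction is attempted. Flanks are matched exactly.
# The only tolerance lives in TAG matching, and 1-mismatch matching is
# permitted only when the catalog's tag set provably supports it (pairwise
# Hamming distance >= 3, so 1-mismatch balls around tags are disjoint).

#' Read a FASTQ file into ids and sequences
#'
#' Accepts plain or gzip-compressed files. A record count that is not a
#' multiple of four, or malformed header/separator lines, raise a hard error
#' naming the offending record.
#'
#' @param path FASTQ path (.fastq or .fastq.gz)
#' @return list with character vectors `id` and `seq`
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at record ", length(lines) %/% 4L + 1L,
         " in ", path)
  if (length(lines) == 0L) return(list(id = character(0), seq = character(0)))
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in ", path)
  list(id = sub("^@", "", heads), seq = lines[seq(2L, length(lines), by = 4L)])
}

#' Assign reads to samples by exact index match
#'
#' Reads the 5-mer at `index_offset` of each read and matches it exactly
#' against the index table; anything else (including reads too short to carry
#' a full index) is a bad index.
#'
#' @param reads character vector of read-1 sequences
#' @param indices a `sample_index_table`
#' @param index_offset 0-based offset of the index within the read
#' @return character vector of sample ids, `NA` where the index is bad
#' @export
demultiplex <- function(reads, indices, index_offset = 0L) {
  idx <- substr(reads, index_offset + 1L, index_offset + 5L)
  sid <- indices$sample_id[match(idx, indices$index_seq)]
  sid[nchar(reads) < index_offset + 5L] <- NA_character_
  sid
}

#' Extract the TAG barcode from reads by exact flank anchoring
#'
#' Locates the upstream flank exactly, takes the following `tag_length`
#' bases, and requires the downstream flank to follow exactly. A missing
#' flank, a flank mismatch, a truncated tag region, or an ambiguous (repeated)
#' upstream flank all yield `NA`.
#'
#' @param reads character vector of read sequences
#' @param layout an [amplicon_layout()]
#' @return character vector of TAG sequences, `NA` where extraction failed
#' @export
extract_tag <- function(reads, layout) {
  fu <- layout$upstream_flank
  fd <- layout$downstream_flank
  lu <- nchar(fu)
  pos <- regexpr(fu, reads, fixed = TRUE)
  ok <- pos > 0L
  # ambiguous if the upstream flank occurs again downstream of the first hit
  rest <- substr(reads, pos + 1L, nchar(reads))
  second <- regexpr(fu, rest, fixed = TRUE)
  ok <- ok & second < 0L
  tag_start <- pos + lu
  tag <- substr(reads, tag_start, tag_start + layout$tag_length - 1L)
  ok <- ok & nchar(tag) == layout$tag_length
  after <- substr(reads, tag_start + layout$tag_length,
                  tag_start + layout$tag_length + nchar(fd) - 1L)
  ok <- ok & after == fd
  tag[!ok] <- NA_character_
  tag
}

# lookup table: every tag plus (for radius 1) every 1-mismatch variant,
# mapped to its mutant id. An exact tag always beats a neighbour key; a
# neighbour key claimed by two different mutants maps to "" (ambiguous).
tag_lookup <- function(tags, ids, max_mismatch) {
  keys <- tags
  owners <- ids
  exact <- rep(TRUE, length(tags))
  if (max_mismatch >= 1L) {
    m <- seq_char_matrix(tags)
    for (p in seq_len(ncol(m))) {
      for (b in DNA_BASES) {
        hit <- m[, p] != b
        if (!any(hit)) next
        v <- m[hit, , drop = FALSE]
        v[, p] <- b
        keys <- c(keys, do.call(paste0, as.data.frame(v, stringsAsFactors = FALSE)))
        owners <- c(owners, ids[hit])
        exact <- c(exact, rep(FALSE, sum(hit)))
      }
    }
  }
  ord <- order(!exact)   # exact keys first, so they win deduplication
  keys <- keys[ord]; owners <- owners[ord]; exact <- exact[ord]
  firstpos <- match(keys, keys)
  is_first <- firstpos == seq_along(keys)
  # a later duplicate with a different owner poisons a non-exact first key
  clash <- !is_first & owners != owners[firstpos] & !exact[firstpos]
  tab <- owners[is_first]
  names(tab) <- keys[is_first]
  tab[unique(keys[clash])] <- ""
  tab
}

#' Match extracted TAGs against the catalog
#'
#' With `max_mismatch = 0`, exact matching. With `max_mismatch = 1` the
#' catalog's full tag set (up- and downtags) must sit at pairwise Hamming
#' distance >= 3, which guarantees a unique match within radius 1; requesting
#' 1-mismatch matching on a catalog that does not satisfy this is a
#' configuration error.
#'
#' @param tags character vector of extracted TAG sequences (NA allowed)
#' @param catalog a `mutant_catalog`
#' @param max_mismatch 0 or 1
#' @param tag_set which catalog tag column to match (`"uptag"` or
#'   `"downtag"`)
#' @param check_distance verify the distance-3 gate (default TRUE)
#' @return data.frame with columns `tag`, `mutant_id` (NA when unmatched) and
#'   `status` (one of `matched`, `unknown`, `ambiguous`)
#' @export
match_tag <- function(tags, catalog, max_mismatch = 0L,
                      tag_set = c("uptag", "downtag"),
                      check_distance = TRUE) {
  tag_set <- match.arg(tag_set)
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  if (max_mismatch == 1L && check_distance) {
    md <- min_pairwise_hamming(c(catalog$uptag, catalog$downtag))
    if (md < 3L)
      stop("1-mismatch tag matching requires catalog tag distance >= 3 (got ",
           md, ")")
  }
  lut <- tag_lookup(catalog[[tag_set]], catalog$id, max_mismatch)
  hit <- unname(lut[tags])
  status <- ifelse(is.na(tags) | is.na(hit), "unknown",
                   ifelse(hit == "", "ambiguous", "matched"))
  hit[status != "matched"] <- NA_character_
  data.frame(tag = tags, mutant_id = hit, status = status,
             stringsAsFactors = FALSE)
}

#' Build the sample-by-mutant count table from paired FASTQ
#'
#' Runs demultiplexing, TAG extraction and TAG matching over read 1 of every
#' pair (read 2, when given, is checked for pairing only), and accounts for
#' every read pair exactly once: either a cell of the count matrix or one of
#' the unassigned counters (`bad_index`, `bad_flank`, `unknown_tag`,
#' `ambiguous_tag`). Read conservation (assigned + unassigned = total pairs)
#' is asserted after every run.
#'
#' @param r1 character vector of read-1 FASTQ paths
#' @param catalog a `mutant_catalog`
#' @param indices a `sample_index_table`
#' @param layout an [amplicon_layout()]
#' @param r2 optional vector of read-2 FASTQ paths (paired order with `r1`)
#' @param max_mismatch TAG matching tolerance, 0 or 1
#' @return a `count_table`: list with `matrix` (mutants x samples),
#'   `unassigned` (per-sample matrix of flank/tag failures plus global
#'   `bad_index`), and `total_pairs`
#' @export
build_count_table <- function(r1, catalog, indices, layout = amplicon_layout(),
                              r2 = NULL, max_mismatch = 0L) {
  reads <- unlist(lapply(r1, function(f) read_fastq(f)$seq), use.names = FALSE)
  if (!is.null(r2)) {
    n2 <- sum(vapply(r2, function(f) length(read_fastq(f)$seq), integer(1)))
    if (n2 != length(reads))
      stop("read 1 and read 2 files carry different numbers of records")
  }
  total <- length(reads)
  samples <- indices$sample_id
  mat <- matrix(0L, nrow(catalog), length(samples),
                dimnames = list(catalog$id, samples))
  unas <- matrix(0L, length(samples), 3L,
                 dimnames = list(samples, c("bad_flank", "unknown_tag",
                                            "ambiguous_tag")))
  bad_index <- 0L
  if (total > 0L) {
    sid <- demultiplex(reads, indices, layout$index_offset)
    bad_index <- sum(is.na(sid))
    keep <- !is.na(sid)
    reads <- reads[keep]; sid <- sid[keep]
    tag <- extract_tag(reads, layout)
    bf <- tapply(is.na(tag), sid, sum)
    unas[names(bf), "bad_flank"] <- as.integer(bf)
    keep <- !is.na(tag)
    tag <- tag[keep]; sid <- sid[keep]
    mt <- match_tag(tag, catalog, max_mismatch = max_mismatch,
                    tag_set = if (layout$tag_read == 1L) "uptag" else "downtag")
    for (st in c("unknown", "ambiguous")) {
      cnt <- tapply(mt$status == st, sid, sum)
      col <- paste0(st, "_tag")
      unas[names(cnt), col] <- unas[names(cnt), col] + as.integer(cnt)
    }
    hit <- mt$status == "matched"
    if (any(hit)) {
      tab <- table(factor(mt$mutant_id[hit], levels = catalog$id),
                   factor(sid[hit], levels = samples))
      mat <- mat + as.integer(tab)
      dim(mat) <- c(nrow(catalog), length(samples))
      dimnames(mat) <- list(catalog$id, samples)
    }
  }
  ct <- structure(list(matrix = mat,
                       unassigned = list(bad_index = bad_index,
                                         per_sample = unas),
                       total_pairs = total),
                  class = "count_table")
  stopifnot(sum(ct$matrix) + ct$unassigned$bad_index +
              sum(ct$unassigned$per_sample) == ct$total_pairs)
  ct
}

#' @export
print.count_table <- function(x, ...) {
  cat("Bar-seq count table:", nrow(x$matrix), "mutants x", ncol(x$matrix),
      "samples;", x$total_pairs, "read pairs\n")
  cat("Assigned:", sum(x$matrix), " bad index:", x$unassigned$bad_index,
      " bad flank:", sum(x$unassigned$per_sample[, "bad_flank"]),
      " unknown tag:", sum(x$unassigned$per_sample[, "unknown_tag"]),
      " ambiguous tag:", sum(x$unassigned$per_sample[, "ambiguous_tag"]), "\n")
  invisible(x)
}

#' Write a count table and its unassigned ledger to TSV
#'
#' @param ct a `count_table`
#' @param path output TSV for the matrix (rows = mutants)
#' @param ledger_path optional TSV for the unassigned ledger
#' @return `path`, invisibly
#' @export
write_count_table <- function(ct, path, ledger_path = NULL) {
  utils::write.table(
    data.frame(id = rownames(ct$matrix), ct$matrix, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ledger_path)) {
    led <- data.frame(sample_id = c(rownames(ct$unassigned$per_sample), "*"),
                      rbind(ct$unassigned$per_sample, NA),
                      bad_index = c(rep(NA, nrow(ct$unassigned$per_sample)),
                                    ct$unassigned$bad_index),
                      check.names = FALSE)
    utils::write.table(led, ledger_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
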