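#' Genomic intervals
#'
#' All coordinates in the package are 0-based, half-open (BED convention):
#' an interval covers bases `start .. end-1` and has length `end - start`.
#' Intervals are kept in plain data.frames with at least the columns
#' `species`, `chrom`, `start`, `end` and optionally `strand`; histone-domain
#' overlap logic ignores strand throughout.
#'
#' @param species character vector of species identifiers.
#' @param chrom character vector of sequence (chromosome) identifiers.
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param ... further equal-length columns carried along.
#' @return A `data.table` with one row per interval.
#' @export
gintervals <- function(species, chrom, start, end, strand = ".", ...) {
  dt <- data.table::data.table(species = as.character(species),
                               chrom = as.character(chrom),
                               start = as.numeric(start),
                               end = as.numeric(end),
                               strand = strand, ...)
  validate_intervals(dt)
  dt[]
}

validate_intervals <- function(x) {
  stopifnot(all(c("species", "chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(!(x$start >= 0 & x$start < x$end))) {
    stop("invalid interval: require 0 <= start < end")
  }
  invisible(x)
}

#' Overlap in base pairs between two intervals
#'
#' Returns 0 when the intervals sit on different species or chromosomes.
#'
#' @param a,b single-row interval data.frames (or lists with species, chrom,
#'   start, end).
#' @return integer number of shared bases.
#' @export
overlap_bp <- function(a, b) {
  if (a$species != b$species || a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Reciprocal overlap fractions
#'
#' @inheritParams overlap_bp
#' @return numeric length-2 vector: overlap as a fraction of `a`'s length and
#'   of `b`'s length.
#' @export
overlap_fraction <- function(a, b) {
  la <- a$end - a$start
  lb <- b$end - b$start
  if (la <= 0 || lb <= 0) stop("zero-length interval")
  ov <- overlap_bp(a, b)
  c(ov / la, ov / lb)
}

#' Merge an interval set into maximal disjoint runs
#'
#' Base-set union semantics: the output intervals are the maximal runs of the
#' union of covered bases, so overlapping and book-ended (`end == start`)
#' inputs coalesce into one run.
#'
#' @param x interval data.frame (single species).
#' @return merged intervals, sorted by (chrom, start), pairwise disjoint.
#' @export
merge_interval_set <- function(x) {
  x <- data.table::as.data.table(x)
  if (nrow(x) == 0) return(x)
  stopifnot(length(unique(x$species)) == 1L)
  out <- x[, {
    ir <- IRanges::reduce(to_iranges(start, end))
    list(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  }, by = c("species", "chrom")]
  data.table::setorder(out, chrom, start)
  out[, c("species", "chrom", "start", "end")][]
}

# [start,end) 0-based -> IRanges (1-based closed)
to_iranges <- function(start, end) IRanges::IRanges(start + 1L, end)

# vectorised pairwise overlap widths for matched rows
overlap_bp_vec <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Find overlaps between two interval tables
#'
#' Internal workhorse: all pairs (i, j) with >= 1 bp overlap on the same
#' species and chromosome, with overlap widths and fractions of each side.
#'
#' @param a,b interval data.frames.
#' @return data.table with columns `i`, `j`, `ov`, `frac_a`, `frac_b`.
#' @keywords internal
interval_overlaps <- function(a, b) {
  a <- data.table::as.data.table(a)
  b <- data.table::as.data.table(b)
  empty <- data.table::data.table(i = integer(), j = integer(), ov = numeric(),
                                  frac_a = numeric(), frac_b = numeric())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  keys_a <- paste(a$species, a$chrom)
  keys_b <- paste(b$species, b$chrom)
  shared <- intersect(unique(keys_a), unique(keys_b))
  if (!length(shared)) return(empty)
  res <- lapply(shared, function(k) {
    ia <- which(keys_a == k); ib <- which(keys_b == k)
    hits <- IRanges::findOverlaps(to_iranges(a$start[ia], a$end[ia]),
                                  to_iranges(b$start[ib], b$end[ib]))
    qi <- ia[S4Vectors::queryHits(hits)]
    sj <- ib[S4Vectors::subjectHits(hits)]
    data.table::data.table(i = qi, j = sj)
  })
  res <- data.table::rbindlist(res)
  if (nrow(res) == 0) return(empty)
  res[, ov := overlap_bp_vec(a$start[i], a$end[i], b$start[j], b$end[j])]
  res[, frac_a := ov / (a$end[i] - a$start[i])]
  res[, frac_b := ov / (b$end[j] - b$start[j])]
  res[]
}

#' Read/write BED intervals
#'
#' BED3/BED6(+extra) tab-separated files; coordinates pass through unchanged
#' (BED is already 0-based half-open). The `species` column is supplied by the
#' caller since BED carries no species field.
#'
#' @param path file path.
#' @param species species id to stamp on the intervals.
#' @param extra_cols optional names for columns beyond the sixth.
#' @return interval data.table.
#' @export
read_bed <- function(path, species, extra_cols = NULL) {
  x <- data.table::fread(path, header = FALSE, sep = "\t")
  base <- c("chrom", "start", "end", "name", "score", "strand")
  nm <- c(base[seq_len(min(ncol(x), 6L))], extra_cols)
  data.table::setnames(x, seq_along(nm), nm)
  x[, species := species]
  data.table::setcolorder(x, c("species", setdiff(names(x), "species")))
  validate_intervals(x)
  x[]
}

#' @rdname read_bed
#' @param x interval data.frame to write.
#' @param cols columns to write after the first three (in order).
#' @export
write_bed <- function(x, path, cols = intersect(c("name", "score", "strand"), names(x))) {
  x <- data.table::as.data.table(x)
  out <- x[, c("chrom", "start", "end", cols), with = FALSE]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
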