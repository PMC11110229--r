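#' Construct a table of genomic intervals
#'
#' Intervals are the coordinate currency of the whole pipeline: 0-based,
#' half-open `[start, end)`, with an optional strand. Empty intervals are
#' rejected (`start < end` strictly).
#'
#' @param chrom character vector of sequence identifiers.
#' @param start 0-based inclusive start positions.
#' @param end exclusive end positions.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded); recycled.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
gintervals <- function(chrom = character(), start = numeric(),
                       end = numeric(), strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  stopifnot(length(chrom) %in% c(1L, n), length(start) %in% c(1L, n),
            length(end) %in% c(1L, n))
  if (n == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  strand <- rep_len(as.character(strand), n)
  iv <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   strand = strand, stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0L) return(invisible(iv))
  if (any(!is.finite(iv$start)) || any(!is.finite(iv$end)))
    stop("interval coordinates must be finite")
  if (any(iv$start < 0))
    stop("interval start must be >= 0")
  if (any(iv$start >= iv$end))
    stop("empty or inverted interval: start must be < end")
  if (!is.null(iv$strand) && !all(iv$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(iv)
}

# 0-based half-open -> GRanges (1-based closed). Strand dropped: all bp
# accounting in this pipeline is strand-agnostic.
as_gr <- function(iv) {
  if (nrow(iv) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  )
}

gr_to_iv <- function(gr) {
  if (length(gr) == 0L) {
    return(gintervals())
  }
  iv <- gintervals(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  iv[order(iv$chrom, iv$start), , drop = FALSE]
}

#' Merge intervals into a disjoint sorted set
#'
#' Overlapping and touching half-open intervals (e.g. `[0,5)` and `[5,10)`)
#' are merged into one contiguous run, so downstream base-pair counts never
#' double-count a base.
#'
#' @param iv interval table as from [gintervals()].
#' @return interval table, sorted by chromosome then start, pairwise
#'   disjoint and non-adjacent.
#' @export
merge_intervals <- function(iv) {
  validate_intervals(iv)
  if (nrow(iv) == 0L) return(gintervals())
  gr_to_iv(GenomicRanges::reduce(as_gr(iv)))
}

#' Total length of an interval set after merging
#' @param iv interval table.
#' @return total bp covered by the union of `iv`.
#' @export
total_bp <- function(iv) {
  m <- merge_intervals(iv)
  if (nrow(m) == 0L) return(0)
  sum(m$end - m$start)
}

#' Base-pair overlap between two interval sets
#'
#' Counts the bases in the intersection of the two set unions; symmetric
#' and strand-agnostic.
#'
#' @param a,b interval tables.
#' @return non-negative bp count.
#' @export
intersect_bp <- function(a, b) {
  iv <- interval_intersect(a, b)
  if (nrow(iv) == 0L) return(0)
  sum(iv$end - iv$start)
}

#' Intersection of two interval sets as intervals
#' @param a,b interval tables.
#' @return merged interval table covering `union(a) intersect union(b)`.
#' @export
interval_intersect <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(gintervals())
  gr_to_iv(GenomicRanges::intersect(
    GenomicRanges::reduce(as_gr(a)), GenomicRanges::reduce(as_gr(b))))
}

#' Set difference of two interval sets
#' @param a,b interval tables.
#' @return merged interval table covering `union(a) minus union(b)`.
#' @export
interval_setdiff <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L) return(gintervals())
  if (nrow(b) == 0L) return(merge_intervals(a))
  gr_to_iv(GenomicRanges::setdiff(
    GenomicRanges::reduce(as_gr(a)), GenomicRanges::reduce(as_gr(b))))
}

#' Complement of an interval set within chromosome bounds
#' @param iv interval table.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return interval table covering every base of every chromosome in
#'   `chrom_lengths` not covered by `iv`.
#' @export
interval_complement <- function(iv, chrom_lengths) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  genome <- gintervals(chrom = names(chrom_lengths),
                       start = 0, end = as.numeric(chrom_lengths))
  interval_setdiff(genome, iv)
}

#' Per-window feature counts and bp coverage
#'
#' Tiles each chromosome into fixed-size windows (the last window may be
#' short) and reports, per window, the number of features whose start lies
#' in the window and the bp of the window covered by the merged feature
#' set. Summed over windows, the coverage equals the merged total of the
#' feature set on that chromosome.
#'
#' @param features interval table.
#' @param window_bp window size in bp (default 500000).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return data.frame with `chrom`, `window_start`, `window_end`,
#'   `n_features`, `covered_bp`.
#' @export
windowed_density <- function(features, window_bp = 5e5, chrom_lengths) {
  stopifnot(window_bp >= 1, !is.null(names(chrom_lengths)))
  validate_intervals(features)
  merged <- merge_intervals(features)
  out <- lapply(names(chrom_lengths), function(chr) {
    len <- as.numeric(chrom_lengths[[chr]])
    starts <- seq(0, len - 1, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    wins <- gintervals(chrom = chr, start = starts, end = ends)
    f <- features[features$chrom == chr, , drop = FALSE]
    m <- merged[merged$chrom == chr, , drop = FALSE]
    n_feat <- vapply(seq_along(starts), function(i)
      sum(f$start >= starts[i] & f$start < ends[i]), numeric(1))
    cov_bp <- vapply(seq_along(starts), function(i)
      intersect_bp(wins[i, , drop = FALSE], m), numeric(1))
    data.frame(chrom = chr, window_start = starts, window_end = ends,
               n_features = n_feat, covered_bp = cov_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
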