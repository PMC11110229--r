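#' Default partition priority order
#'
#' When a base is covered by annotations from more than one category, it is
#' assigned to the first covering category in this order; every base left
#' unassigned falls to the residual `other_DNA`.
#' @export
DEFAULT_PRIORITY <- c(
  "structural_gene", "TE", "other_repeat",
  "rRNA_eukaryotic", "rRNA_prokaryotic",
  "tRNA_nuclear", "tRNA_mitochondrial", "tRNA_plastid",
  "self_splicing_intron", "regulatory_RNA", "spliceosomal_RNA",
  "other_RNA"
)

#' Partition the genome into disjoint feature categories
#'
#' Resolves multi-category overlaps by priority: each base belongs to
#' exactly one category (the first category in `priority_order` covering
#' it), and every base covered by no category falls to `other_DNA`. The
#' partition sizes therefore sum exactly to the genome size, which is what
#' makes the bp-proportional null of [expected_overlap()] well defined.
#'
#' @param feature_sets named list of interval tables (one per category).
#' @param priority_order character vector covering all supplied
#'   categories; defaults to [DEFAULT_PRIORITY] restricted to the supplied
#'   ones.
#' @param genome_lengths named numeric vector of chromosome lengths.
#' @return object of class `nupt_partition`: list with `sizes` (named
#'   numeric, bp per category including `other_DNA`), `intervals` (named
#'   list of disjoint interval tables), `genome_size`.
#' @export
partition_genome <- function(feature_sets, priority_order = NULL,
                             genome_lengths) {
  stopifnot(length(genome_lengths) > 0, !is.null(names(genome_lengths)))
  cats <- names(feature_sets)
  if (is.null(priority_order)) {
    priority_order <- c(DEFAULT_PRIORITY[DEFAULT_PRIORITY %in% cats],
                        setdiff(cats, DEFAULT_PRIORITY))
  }
  if (!all(cats %in% priority_order))
    stop("priority_order must cover all supplied categories: missing ",
         paste(setdiff(cats, priority_order), collapse = ", "))
  for (cat in cats) {
    iv <- feature_sets[[cat]]
    validate_intervals(iv)
    if (nrow(iv) > 0L) {
      if (!all(iv$chrom %in% names(genome_lengths)))
        stop("feature on unknown chromosome in category ", cat)
      lim <- genome_lengths[iv$chrom]
      if (any(iv$end > lim))
        stop("feature beyond chromosome end in category ", cat)
    }
  }

  G <- sum(as.numeric(genome_lengths))
  assigned <- gintervals()
  intervals <- list()
  sizes <- numeric(0)
  for (cat in priority_order) {
    iv <- feature_sets[[cat]]
    if (is.null(iv)) next
    excl <- interval_setdiff(iv, assigned)
    intervals[[cat]] <- excl
    sizes[[cat]] <- if (nrow(excl)) sum(excl$end - excl$start) else 0
    if (nrow(excl)) {
      assigned <- merge_intervals(rbind(assigned[, 1:4], excl[, 1:4]))
    }
  }
  other <- interval_complement(assigned, genome_lengths)
  intervals[["other_DNA"]] <- other
  sizes[["other_DNA"]] <- if (nrow(other)) sum(other$end - other$start) else 0
  stopifnot(abs(sum(sizes) - G) < 0.5)
  structure(list(sizes = sizes, intervals = intervals, genome_size = G,
                 priority_order = priority_order),
            class = "nupt_partition")
}

#' Expected bp overlap per category under the bp-proportional null
#'
#' Under the null, a query track's bases fall into each category in
#' proportion to the category's share of the genome:
#' `E_f = T * S_f / G`. Summed over a partition that tiles the genome the
#' expected values recover `T` exactly.
#'
#' @param total_nupt_bp total bp `T` of the (merged) query track.
#' @param partition a `nupt_partition`.
#' @return named numeric vector of expected bp, one entry per category.
#' @export
expected_overlap <- function(total_nupt_bp, partition) {
  stopifnot(inherits(partition, "nupt_partition"), total_nupt_bp >= 0)
  if (partition$genome_size <= 0) stop("genome size must be positive")
  total_nupt_bp * partition$sizes / partition$genome_size
}

#' Yates-corrected chi-squared test of observed vs expected bp overlap
#'
#' Two-cell construction on a df = 1 chi-squared: inside the category
#' (O vs E) and outside (T-O vs T-E), with the continuity correction
#' `max(|O - E| - 0.5, 0)` applied to each cell deviation (clamped at
#' zero, so deviations under half a base give a statistic of exactly 0).
#'
#' @param O observed bp overlap, `0 <= O <= T`.
#' @param E expected bp overlap, `0 < E < T`.
#' @param T total query bp, `> 0`.
#' @return list with `chi2` and `p` (upper tail, df = 1).
#' @export
yates_chisq <- function(O, E, T) {
  stopifnot(T > 0, O >= 0, O <= T)
  if (E <= 0 || E >= T)
    stop("undefined test: expected overlap must satisfy 0 < E < T")
  d <- max(abs(O - E) - 0.5, 0)
  chi2 <- d^2 / E + d^2 / (T - E)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Observed vs expected bp overlap enrichment scan
#'
#' The central statistic: for each NUPT class and each category of the
#' genome partition, the observed bp overlap `O_f` is compared against the
#' bp-proportional expectation `E_f` with a Yates-corrected chi-squared
#' test. NUPT intervals are merged per class before counting so nested
#' alignments never double-count bases; when the partition tiles the
#' genome, both observed and expected values sum to the class total `T`.
#'
#' @param nupt_sets_by_class named list of interval tables (e.g. classes
#'   `I`, `II`, `unclassified`, or a single `all`).
#' @param partition a `nupt_partition`.
#' @param alpha significance level for the direction call (default 0.05).
#' @return data.frame with one row per (class, category): `class`,
#'   `category`, `observed_bp`, `expected_bp`, `log10_ratio`, `chi2`, `p`,
#'   `direction` (`enriched` / `depleted` / `ns`).
#' @export
enrichment_scan <- function(nupt_sets_by_class, partition, alpha = 0.05) {
  stopifnot(inherits(partition, "nupt_partition"))
  out <- list()
  for (cls in names(nupt_sets_by_class)) {
    nupts <- merge_intervals(nupt_sets_by_class[[cls]])
    T <- if (nrow(nupts)) sum(nupts$end - nupts$start) else 0
    if (T <= 0) stop("empty NUPT set for class ", cls)
    E <- expected_overlap(T, partition)
    for (cat in names(partition$intervals)) {
      O <- intersect_bp(nupts, partition$intervals[[cat]])
      Ef <- E[[cat]]
      if (Ef > 0 && Ef < T) {
        ts <- yates_chisq(O, Ef, T)
        chi2 <- ts$chi2; p <- ts$p
      } else {
        chi2 <- NA_real_; p <- NA_real_
      }
      dir <- "ns"
      if (!is.na(p) && p < alpha) dir <- if (O > Ef) "enriched" else "depleted"
      out[[length(out) + 1L]] <- data.frame(
        class = cls, category = cat, observed_bp = O, expected_bp = Ef,
        log10_ratio = ifelse(O > 0 & Ef > 0, log10(O / Ef), NA_real_),
        chi2 = chi2, p = p, direction = dir, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Non-exclusive per-category overlap accounting
#'
#' Reports observed bp overlap of a query track against each category's
#' raw (unpartitioned) annotation, so a base under two annotations counts
#' toward both — the multi-membership accounting style of a feature
#' summary table. No test is run in this mode; the chi-squared test is
#' meaningful only against the disjoint partition.
#'
#' @param nupts interval table of NUPTs (merged internally).
#' @param feature_sets named list of raw category interval tables.
#' @return data.frame with `category`, `observed_bp`, `feature_bp`.
#' @export
overlap_by_category <- function(nupts, feature_sets) {
  nupts <- merge_intervals(nupts)
  do.call(rbind, lapply(names(feature_sets), function(cat) {
    data.frame(category = cat,
               observed_bp = intersect_bp(nupts, feature_sets[[cat]]),
               feature_bp = total_bp(feature_sets[[cat]]),
               stringsAsFactors = FALSE)
  }))
}
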