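#' Region decomposition of a structural gene
#'
#' Decomposes a gene into promoter (flank upstream of the translation
#' start), exons, derived introns, and terminator (flank downstream of the
#' stop), strand-aware. When CDS coordinates are present in the model the
#' flanks anchor at the CDS ends (the ATG and stop codons); otherwise the
#' gene span ends are used. Flanks are truncated at chromosome edges; a
#' fully truncated flank is returned empty and flagged.
#'
#' @param gene one gene model (see [read_gff3()]).
#' @param flank_bp flank length in bp; default 1000.
#' @param chrom_length length of the gene's chromosome.
#' @return list with interval tables `promoter`, `exon`, `intron`,
#'   `terminator` and logical `truncated` (promoter/terminator hit a
#'   chromosome edge).
#' @export
gene_regions <- function(gene, flank_bp = 1000, chrom_length) {
  stopifnot(flank_bp >= 0, chrom_length >= gene$end)
  if (!(gene$strand %in% c("+", "-")))
    stop("gene ", gene$gene_id, " is unstranded; regions are direction-dependent")

  anchor5 <- if (!is.na(gene$cds_start)) gene$cds_start else gene$start
  anchor3 <- if (!is.na(gene$cds_end)) gene$cds_end else gene$end

  if (gene$strand == "+") {
    prom <- c(max(anchor5 - flank_bp, 0), anchor5)
    term <- c(anchor3, min(anchor3 + flank_bp, chrom_length))
  } else {
    prom <- c(anchor3, min(anchor3 + flank_bp, chrom_length))
    term <- c(max(anchor5 - flank_bp, 0), anchor5)
  }
  mk <- function(span) {
    if (span[2] <= span[1]) gintervals()
    else gintervals(gene$chrom, span[1], span[2], gene$strand)
  }
  truncated <- (prom[2] - prom[1] < flank_bp) || (term[2] - term[1] < flank_bp)
  exons <- if (nrow(gene$exons)) {
    ex <- merge_sorted_1chrom(gene$exons)
    ex$strand <- gene$strand
    ex
  } else {
    gintervals(gene$chrom, gene$start, gene$end, gene$strand)
  }
  list(promoter = mk(prom), exon = exons, intron = gene_introns(gene),
       terminator = mk(term), truncated = truncated)
}

#' Classify NUPT hits on structural genes
#'
#' A gene is "affected" when any NUPT base overlaps any of its regions
#' (promoter, exon, intron, terminator; >= 1 bp, no minimum fraction). A
#' NUPT spanning a region boundary contributes to every region it
#' touches. Per gene, the age classes present are condensed to an
#' exclusivity label (`I-only`, `II-only`, `unclassified-only`, `mixed`),
#' and full coverage of the gene span by the NUPT union is flagged.
#'
#' @param nupts NUPT table (from [alignment_to_nupts()]) with a `label`
#'   column of age classes (`I`, `II`, `unclassified`).
#' @param gene_models list of gene models.
#' @param flank_bp promoter/terminator flank (default 1000).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return data.frame with one row per affected gene: `gene_id`,
#'   `regions_hit` (comma list), `n_nupts`, `nupt_ids` (comma list),
#'   `classes` (comma list of classes present), `class_pattern`,
#'   `fully_covered`, `single_exon_all_plastid`.
#' @export
classify_gene_hits <- function(nupts, gene_models, flank_bp = 1000,
                               chrom_lengths) {
  stopifnot(!is.null(nupts$label))
  region_names <- c("promoter", "exon", "intron", "terminator")
  out <- list()
  for (g in gene_models) {
    if (!(g$chrom %in% names(chrom_lengths)))
      stop("gene chromosome missing from chrom_lengths: ", g$chrom)
    cand <- nupts[nupts$chrom == g$chrom &
                  nupts$end > g$start - flank_bp &
                  nupts$start < g$end + flank_bp, , drop = FALSE]
    if (nrow(cand) == 0L) next
    reg <- gene_regions(g, flank_bp, chrom_lengths[[g$chrom]])
    hit_regions <- character(0)
    hit_idx <- integer(0)
    for (rn in region_names) {
      riv <- reg[[rn]]
      if (nrow(riv) == 0L) next
      # any-bp overlap, vectorized over (candidate, region interval) pairs
      ov <- rowSums(outer(cand$start, riv$end, "<") &
                    outer(cand$end, riv$start, ">")) > 0
      if (any(ov)) {
        hit_regions <- c(hit_regions, rn)
        hit_idx <- union(hit_idx, which(ov))
      }
    }
    if (length(hit_idx) == 0L) next
    hits <- cand[sort(hit_idx), , drop = FALSE]
    classes <- sort(unique(hits$label))
    pattern <- if (length(classes) > 1L) "mixed" else paste0(classes, "-only")
    covered <- covered_bp(g$start, g$end, hits$start, hits$end)
    fully <- covered == (g$end - g$start)
    single_exon <- nrow(g$exons) <= 1L
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g$gene_id,
      regions_hit = paste(region_names[region_names %in% hit_regions],
                          collapse = ","),
      n_nupts = nrow(hits),
      nupt_ids = paste(hits$nupt_id, collapse = ","),
      classes = paste(classes, collapse = ","),
      class_pattern = pattern,
      fully_covered = fully,
      single_exon_all_plastid = fully && single_exon,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), regions_hit = character(),
                      n_nupts = integer(), nupt_ids = character(),
                      classes = character(), class_pattern = character(),
                      fully_covered = logical(),
                      single_exon_all_plastid = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# bp of [s, e) covered by the union of the clipped hit intervals
covered_bp <- function(s, e, hs, he) {
  hs <- pmax(hs, s); he <- pmin(he, e)
  keep <- he > hs
  if (!any(keep)) return(0)
  hs <- hs[keep]; he <- he[keep]
  o <- order(hs)
  hs <- hs[o]; he <- he[o]
  tot <- 0; cs <- hs[1]; ce <- he[1]
  for (i in seq_along(hs)[-1]) {
    if (hs[i] <= ce) ce <- max(ce, he[i])
    else { tot <- tot + ce - cs; cs <- hs[i]; ce <- he[i] }
  }
  tot + ce - cs
}

#' Tallies over gene impact records
#'
#' Per-region affected-gene counts (a gene hit in two regions counts once
#' in each region tally, so region tallies may exceed the distinct-gene
#' total, which is reported separately), the exclusivity partition by age
#' class (which always sums to the distinct-gene total), and full-coverage
#' accounting.
#'
#' @param records data.frame from [classify_gene_hits()].
#' @return list with `n_affected`, `by_region` (named counts),
#'   `by_class_pattern` (named counts over I-only / II-only /
#'   unclassified-only / mixed), `n_fully_covered`, `pct_fully_covered`,
#'   `max_nupts_per_gene`.
#' @export
impact_summary <- function(records) {
  if (nrow(records) == 0L)
    return(list(n_affected = 0L, by_region = integer(0),
                by_class_pattern = integer(0), n_fully_covered = 0L,
                pct_fully_covered = NA_real_, max_nupts_per_gene = 0L))
  region_names <- c("promoter", "exon", "intron", "terminator")
  regs <- strsplit(records$regions_hit, ",", fixed = TRUE)
  by_region <- vapply(region_names, function(rn)
    sum(vapply(regs, function(r) rn %in% r, logical(1))), integer(1))
  patterns <- c("I-only", "II-only", "unclassified-only", "mixed")
  by_pat <- vapply(patterns, function(p)
    sum(records$class_pattern == p), integer(1))
  stopifnot(sum(by_pat) == nrow(records))
  list(n_affected = nrow(records),
       by_region = by_region,
       by_class_pattern = by_pat,
       n_fully_covered = sum(records$fully_covered),
       pct_fully_covered = 100 * mean(records$fully_covered),
       max_nupts_per_gene = max(records$n_nupts))
}
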