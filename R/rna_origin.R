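#' Classify tRNA genes by compartment of origin via a best-hit rule
#'
#' Each query tRNA gene is assigned the compartment (nuclear,
#' mitochondrial, plastid) of its best alignment hit against a reference
#' tRNA set: the maximal bit score among hits passing the e-value cutoff,
#' with ties broken by smaller e-value, then lexicographically smallest
#' subject id. Queries with no passing hit are `unclassified`.
#'
#' @param hit_rows alignment table ([read_alignment_tab()]) of query tRNA
#'   genes vs the reference set.
#' @param subject_compartment_map named character vector (or two-column
#'   data.frame `subject_id`, `compartment`) mapping reference subjects to
#'   compartments.
#' @param evalue_cutoff maximum e-value for a hit to count; default 1e-2.
#' @param query_ids optional vector of all query ids, so queries without
#'   any hit row still receive an `unclassified` call.
#' @return data.frame with `gene_id`, `compartment`, `best_subject`,
#'   `bitscore`, `evalue`.
#' @export
classify_origin <- function(hit_rows, subject_compartment_map,
                            evalue_cutoff = 1e-2, query_ids = NULL) {
  if (is.data.frame(subject_compartment_map)) {
    subject_compartment_map <- stats::setNames(
      subject_compartment_map$compartment,
      subject_compartment_map$subject_id)
  }
  keep <- hit_rows[hit_rows$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(keep) > 0L) {
    missing <- setdiff(unique(keep$sseqid), names(subject_compartment_map))
    if (length(missing))
      stop("subject(s) missing from compartment map: ",
           paste(missing, collapse = ", "))
  }
  if (is.null(query_ids)) query_ids <- unique(hit_rows$qseqid)
  calls <- lapply(query_ids, function(q) {
    h <- keep[keep$qseqid == q, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(gene_id = q, compartment = "unclassified",
                        best_subject = NA_character_, bitscore = NA_real_,
                        evalue = NA_real_, stringsAsFactors = FALSE))
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
    best <- h[1L, ]
    data.frame(gene_id = q,
               compartment = unname(subject_compartment_map[best$sseqid]),
               best_subject = best$sseqid, bitscore = best$bitscore,
               evalue = best$evalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Map a NUPT-resident RNA gene to its donor region in the plastid genome
#'
#' The overlap between the nuclear RNA gene and the NUPT's nuclear span is
#' transferred linearly (proportionally when query and subject spans
#' differ in length, mirrored for reverse-strand NUPTs) into the NUPT's
#' plastid span; plastid annotation features overlapping the transferred
#' interval are the donor genes, and `same_category` records whether any
#' donor shares the nuclear gene's category.
#'
#' @param rna_gene list or one-row data.frame with `gene_id`, `category`,
#'   `chrom`, `start`, `end` (internal coordinates).
#' @param nupt one-row NUPT record ([alignment_to_nupts()]).
#' @param plastid_features named list of plastid interval tables per
#'   category, each with an `id` column.
#' @return data.frame with `gene_id`, `category`, `nupt_id`,
#'   `donor_start`, `donor_end`, `donor_genes` (comma list, possibly
#'   empty), `donor_categories` (comma list), `same_category`.
#' @export
map_donor <- function(rna_gene, nupt, plastid_features) {
  a <- max(rna_gene$start, nupt$start)
  b <- min(rna_gene$end, nupt$end)
  if (b <= a) stop("RNA gene does not overlap the NUPT nuclear span")
  Lq <- nupt$end - nupt$start
  Ls <- nupt$p_end - nupt$p_start
  if (nupt$strand == "+") {
    ds <- nupt$p_start + (a - nupt$start) * Ls / Lq
    de <- nupt$p_start + (b - nupt$start) * Ls / Lq
  } else {
    ds <- nupt$p_start + (nupt$end - b) * Ls / Lq
    de <- nupt$p_start + (nupt$end - a) * Ls / Lq
  }
  ds <- floor(ds); de <- ceiling(de)
  if (de <= ds) stop("zero-length donor transfer")
  donor <- gintervals(nupt$plastid_chrom, ds, de)
  hits_id <- character(0); hits_cat <- character(0)
  for (cat in names(plastid_features)) {
    fs <- plastid_features[[cat]]
    if (nrow(fs) == 0L) next
    ov <- fs$chrom == nupt$plastid_chrom & fs$end > ds & fs$start < de
    if (any(ov)) {
      hits_id <- c(hits_id, fs$id[ov])
      hits_cat <- c(hits_cat, rep(cat, sum(ov)))
    }
  }
  data.frame(gene_id = rna_gene$gene_id, category = rna_gene$category,
             nupt_id = nupt$nupt_id, donor_start = ds, donor_end = de,
             donor_genes = paste(hits_id, collapse = ","),
             donor_categories = paste(unique(hits_cat), collapse = ","),
             same_category = rna_gene$category %in% hits_cat,
             stringsAsFactors = FALSE)
}

#' Map every NUPT-resident RNA gene of a category set to its donors
#'
#' For each nuclear RNA gene overlapping at least one NUPT, the NUPT with
#' the largest overlap is used for the donor transfer.
#'
#' @param rna_sets named list of nuclear RNA-gene interval tables (with
#'   `id` columns), keyed by category.
#' @param nupts NUPT table.
#' @param plastid_features plastid annotation, as in [map_donor()].
#' @return data.frame of donor mappings (possibly zero rows).
#' @export
map_all_donors <- function(rna_sets, nupts, plastid_features) {
  out <- list()
  for (cat in names(rna_sets)) {
    fs <- rna_sets[[cat]]
    for (i in seq_len(nrow(fs))) {
      cand <- nupts[nupts$chrom == fs$chrom[i] &
                    nupts$end > fs$start[i] &
                    nupts$start < fs$end[i], , drop = FALSE]
      if (nrow(cand) == 0L) next
      ov <- pmin(cand$end, fs$end[i]) - pmax(cand$start, fs$start[i])
      best <- cand[which.max(ov), , drop = FALSE]
      gene <- list(gene_id = fs$id[i], category = cat,
                   chrom = fs$chrom[i], start = fs$start[i],
                   end = fs$end[i])
      out[[length(out) + 1L]] <- map_donor(gene, best, plastid_features)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), category = character(),
                      nupt_id = character(), donor_start = numeric(),
                      donor_end = numeric(), donor_genes = character(),
                      donor_categories = character(),
                      same_category = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Compartment census of nuclear tRNA genes and plastid-origin fraction
#'
#' Counts nuclear tRNA genes per best-hit compartment and reports the
#' fraction of plastid origin: tRNA genes residing inside NUPTs,
#' regardless of best-hit compartment (plastid-compartment NUPT genes plus
#' mitochondrial- and nuclear-compartment genes found within NUPT spans),
#' over the total, as a percentage to two decimals.
#'
#' @param origin_calls data.frame with `gene_id`, `compartment` and a
#'   logical `in_nupt` column (residence inside a NUPT span).
#' @return list with `counts` (named, per compartment), `total`,
#'   `plastid_origin_n`, `plastid_origin_pct` (two decimals).
#' @export
trna_census <- function(origin_calls) {
  if (nrow(origin_calls) == 0L) stop("no tRNA origin calls supplied")
  stopifnot(!is.null(origin_calls$in_nupt))
  counts <- table(origin_calls$compartment)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- nrow(origin_calls)
  n_po <- sum(origin_calls$in_nupt)
  list(counts = counts, total = total, plastid_origin_n = n_po,
       plastid_origin_pct = round(100 * n_po / total, 2))
}

#' Split donor-mapped genes into identically vs differently annotated
#' @param donor_mappings data.frame from [map_all_donors()].
#' @return list with `n_total`, `n_same`, `n_different`.
#' @export
donor_annotation_split <- function(donor_mappings) {
  list(n_total = nrow(donor_mappings),
       n_same = sum(donor_mappings$same_category),
       n_different = nrow(donor_mappings) - sum(donor_mappings$same_category))
}
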