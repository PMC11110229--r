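#' The genomic feature category taxonomy
#'
#' Thirteen category labels: twelve annotated feature classes plus the
#' residual `other_DNA` bucket for bases not covered by any annotation.
#' @export
NUPT_CATEGORIES <- c(
  "structural_gene", "TE", "other_repeat",
  "rRNA_eukaryotic", "rRNA_prokaryotic",
  "tRNA_nuclear", "tRNA_mitochondrial", "tRNA_plastid",
  "self_splicing_intron", "regulatory_RNA", "spliceosomal_RNA",
  "other_RNA", "other_DNA"
)

#' Read a nucleotide FASTA file
#'
#' @param path FASTA file.
#' @return list with `sequences` (named character vector) and `lengths`
#'   (named numeric vector).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("zero-length FASTA record")
  s <- as.character(seqs)
  names(s) <- ids
  list(sequences = s, lengths = stats::setNames(as.numeric(nchar(s)), ids))
}

#' Write sequences to FASTA
#' @param sequences named character vector of nucleotide sequences.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(length(sequences) > 0, !is.null(names(sequences)))
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' Read a GFF3 annotation into feature sets and gene models
#'
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. Rows of type `gene`/`mRNA`/`exon`/`CDS` are
#' assembled into structural gene models (introns are derived, never
#' stored); every other row becomes a member of a category feature set,
#' keyed by its `category` attribute when present, else by its type.
#' Exons whose `Parent` cannot be resolved are dropped with a warning and
#' counted in the `n_orphans` field.
#'
#' @param path GFF3 file.
#' @return list with `feature_sets` (named list of interval tables with an
#'   `id` column), `gene_models` (see [gene_model_table()]), and
#'   `n_orphans`.
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L)
    return(list(feature_sets = list(), gene_models = list(),
                n_orphans = 0L))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,    # 1-based closed -> 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    stringsAsFactors = FALSE
  )
  df$parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else NA_character_
  df$category <- if (!is.null(gr$category)) as.character(gr$category)
                 else NA_character_

  structural_types <- c("gene", "mRNA", "exon", "CDS")
  is_struct <- df$type %in% structural_types

  other <- df[!is_struct & !(df$type %in% c("region", "chromosome")), ,
              drop = FALSE]
  other$set <- ifelse(is.na(other$category), other$type, other$category)
  feature_sets <- lapply(split(other, other$set), function(d) {
    iv <- gintervals(chrom = d$chrom, start = d$start, end = d$end,
                     strand = d$strand)
    iv$id <- d$id
    iv
  })

  gm <- build_gene_models(df[is_struct, , drop = FALSE])
  list(feature_sets = feature_sets, gene_models = gm$models,
       n_orphans = gm$n_orphans)
}

build_gene_models <- function(df) {
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]

  # map any feature id (gene or mRNA) to its gene id
  mrna_gene <- stats::setNames(mrnas$parent, mrnas$id)
  to_gene <- function(parent) {
    ifelse(parent %in% genes$id, parent,
           unname(mrna_gene[parent]))
  }
  exon_gene <- to_gene(exons$parent)
  orphan <- is.na(exon_gene) | !(exon_gene %in% genes$id)
  n_orphans <- sum(orphan)
  if (n_orphans > 0)
    warning(n_orphans, " exon(s) with unresolvable Parent were excluded")
  exons <- exons[!orphan, , drop = FALSE]
  exon_gene <- exon_gene[!orphan]
  cds_gene <- if (nrow(cds)) to_gene(cds$parent) else character()

  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exons[exon_gene == g$id, , drop = FALSE]
    if (nrow(ex) && (any(ex$start < g$start) || any(ex$end > g$end)))
      stop("exon outside parent gene span for gene ", g$id)
    cd <- cds[cds_gene == g$id, , drop = FALSE]
    list(gene_id = g$id, chrom = g$chrom, strand = g$strand,
         start = g$start, end = g$end,
         exons = if (nrow(ex)) merge_sorted_1chrom(
           gintervals(ex$chrom, ex$start, ex$end)) else gintervals(),
         cds_start = if (nrow(cd)) min(cd$start) else NA_real_,
         cds_end = if (nrow(cd)) max(cd$end) else NA_real_)
  })
  names(models) <- genes$id
  list(models = models, n_orphans = n_orphans)
}

#' Gene models as a flat table
#' @param gene_models list of gene models from [read_gff3()].
#' @return data.frame with one row per gene (exon structure omitted).
#' @export
gene_model_table <- function(gene_models) {
  do.call(rbind, lapply(gene_models, function(g)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = g$start, end = g$end, n_exons = nrow(g$exons),
               stringsAsFactors = FALSE)))
}

#' Derived introns of a gene model
#'
#' Introns are the gene span minus the merged exons; computed on demand,
#' never stored.
#' @param gene one gene model.
#' @return interval table of introns (possibly empty).
#' @export
gene_introns <- function(gene) {
  if (nrow(gene$exons) == 0L) return(gintervals())
  ex <- merge_sorted_1chrom(gene$exons)
  s <- c(gene$start, ex$end)
  e <- c(ex$start, gene$end)
  keep <- e > s
  if (!any(keep)) return(gintervals())
  gintervals(gene$chrom, s[keep], e[keep])
}

# arithmetic union of intervals on one chromosome (no Bioc overhead;
# used in per-gene inner loops)
merge_sorted_1chrom <- function(iv) {
  if (nrow(iv) <= 1L) return(iv[, c("chrom", "start", "end")])
  o <- order(iv$start)
  s <- iv$start[o]; e <- iv$end[o]
  ms <- s[1]; me <- e[1]; out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  gintervals(iv$chrom[1], c(out_s, ms), c(out_e, me))
}

#' Write feature rows and gene models to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3
#' 1-based closed on write, so a read/write round trip preserves the file's
#' coordinates exactly.
#'
#' @param rows data.frame with `chrom`, `start`, `end`, `strand`, `type`,
#'   `id`, and optional `parent` and `category` columns (internal
#'   coordinates).
#' @param path output path.
#' @export
write_gff3 <- function(rows, path) {
  stopifnot(nrow(rows) > 0)
  attrs <- paste0("ID=", rows$id)
  if (!is.null(rows$parent)) {
    has_p <- !is.na(rows$parent)
    attrs[has_p] <- paste0(attrs[has_p], ";Parent=", rows$parent[has_p])
  }
  if (!is.null(rows$category)) {
    has_c <- !is.na(rows$category)
    attrs[has_c] <- paste0(attrs[has_c], ";category=", rows$category[has_c])
  }
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   rows$chrom, "nuptr", rows$type,
                   as.integer(rows$start + 1), as.integer(rows$end),
                   rows$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

ALN_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular alignment file (BLAST outfmt 6 dialect)
#'
#' Subject coordinates given in reverse order (reverse-strand hits) are
#' normalized to forward half-open intervals with the strand recorded in
#' `s_strand`; the original columns are retained unchanged. No rows are
#' filtered.
#'
#' @param path tab-separated file without header, 12 columns:
#'   qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore.
#' @return data.frame of alignment rows with added 0-based half-open
#'   columns `q_start0`, `q_end0`, `s_start0`, `s_end0` and `s_strand`.
#' @export
read_alignment_tab <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12), ALN_COLUMNS))
    return(out)
  }
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 12L)
    stop("expected 12 tab-separated columns, got ", ncol(d))
  names(d) <- ALN_COLUMNS
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore")
  for (cl in num_cols) {
    d[[cl]] <- suppressWarnings(as.numeric(d[[cl]]))
    if (anyNA(d[[cl]])) stop("unparsable numeric value in column ", cl)
  }
  if (any(d$pident < 0 | d$pident > 100))
    stop("percent identity outside [0, 100]")
  if (any(d$length < 1)) stop("alignment length must be >= 1")
  d$s_strand <- ifelse(d$sstart <= d$send, "+", "-")
  d$q_start0 <- d$qstart - 1
  d$q_end0 <- d$qend
  d$s_start0 <- pmin(d$sstart, d$send) - 1
  d$s_end0 <- pmax(d$sstart, d$send)
  d
}

#' Write alignment rows in the 12-column tabular dialect
#' @param rows data.frame with the 12 [ALN_COLUMNS].
#' @param path output path.
#' @export
write_alignment_tab <- function(rows, path) {
  utils::write.table(rows[, ALN_COLUMNS, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Alignment rows as NUPT records
#'
#' One NUPT per alignment row: the nuclear span is the query interval, the
#' plastid donor span is the normalized subject interval, and the percent
#' identity is taken from the row as given (never recomputed).
#'
#' @param aln alignment table from [read_alignment_tab()].
#' @return data.frame with `nupt_id`, `chrom`, `start`, `end`,
#'   `plastid_chrom`, `p_start`, `p_end`, `strand`, `pident`.
#' @export
alignment_to_nupts <- function(aln) {
  if (nrow(aln) == 0L)
    return(data.frame(nupt_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      plastid_chrom = character(), p_start = numeric(),
                      p_end = numeric(), strand = character(),
                      pident = numeric(), stringsAsFactors = FALSE))
  data.frame(
    nupt_id = sprintf("NUPT_%05d", seq_len(nrow(aln))),
    chrom = aln$qseqid, start = aln$q_start0, end = aln$q_end0,
    plastid_chrom = aln$sseqid, p_start = aln$s_start0, p_end = aln$s_end0,
    strand = aln$s_strand, pident = aln$pident,
    stringsAsFactors = FALSE
  )
}

#' Write a TSV report with a header row
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
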