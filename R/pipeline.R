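#' Pipeline run configuration
#'
#' Bundles the input paths and the analysis parameters. Defaults follow
#' the study settings: posterior threshold 0.95 for age classing, 1 kb
#' promoter/terminator flanks, 500 kb density windows, alpha 0.05, and an
#' expression threshold of 0 TPM (any nonzero TPM in any tissue counts as
#' expressed).
#'
#' @param nuclear_fasta,nuclear_gff3,plastid_fasta,plastid_gff3 genome
#'   inputs.
#' @param alignment nuclear-vs-plastid tabular alignment (outfmt 6
#'   dialect) defining the NUPTs.
#' @param trna_hits tabular alignment of nuclear tRNA genes vs the
#'   compartment-labeled reference set (optional; origin stage skipped
#'   when `NULL`).
#' @param compartment_map TSV `subject_id`, `compartment`.
#' @param tpm TPM table (optional; expression stage skipped when `NULL`).
#' @param terms gene-to-term table (optional).
#' @param out_dir report output directory.
#' @param posterior_threshold,flank_bp,window_bp,alpha,expr_threshold
#'   analysis parameters.
#' @param priority partition priority order (`NULL` = default order).
#' @param seed integer seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(nuclear_fasta, nuclear_gff3, plastid_fasta,
                       plastid_gff3, alignment, trna_hits = NULL,
                       compartment_map = NULL, tpm = NULL, terms = NULL,
                       out_dir = "results", posterior_threshold = 0.95,
                       flank_bp = 1000, window_bp = 5e5, alpha = 0.05,
                       expr_threshold = 0, priority = NULL, seed = 1L) {
  cfg <- list(nuclear_fasta = nuclear_fasta, nuclear_gff3 = nuclear_gff3,
              plastid_fasta = plastid_fasta, plastid_gff3 = plastid_gff3,
              alignment = alignment, trna_hits = trna_hits,
              compartment_map = compartment_map, tpm = tpm, terms = terms,
              out_dir = out_dir,
              posterior_threshold = posterior_threshold,
              flank_bp = flank_bp, window_bp = window_bp, alpha = alpha,
              expr_threshold = expr_threshold, priority = priority,
              seed = as.integer(seed))
  paths <- c("nuclear_fasta", "nuclear_gff3", "plastid_fasta",
             "plastid_gff3", "alignment", "trna_hits", "compartment_map",
             "tpm", "terms")
  for (p in paths) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input file for '", p, "' does not exist: ", cfg[[p]])
  }
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full NUPT characterization pipeline
#'
#' Executes, in order: input loading, age classification (Gaussian
#' mixture on percent identity + posterior assignment), windowed feature
#' densities, genome partition and overlap enrichment per age class,
#' structural-gene impact accounting, tRNA origin classification with the
#' compartment census and donor mapping of NUPT RNA genes, and the
#' expression layer. Each stage writes one or more TSV reports into
#' `out_dir`, plus a JSON manifest with input checksums and parameters.
#' Deterministic given inputs and seed; any stage error aborts the run
#' with the failing stage named.
#'
#' @param config a [run_config()].
#' @return invisible list of report paths and in-memory stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  inputs <- stage("load", {
    nuc_fa <- read_fasta(config$nuclear_fasta)
    gff <- read_gff3(config$nuclear_gff3)
    pl_gff <- read_gff3(config$plastid_gff3)
    aln <- read_alignment_tab(config$alignment)
    if (nrow(aln) == 0L) stop("alignment file defines no NUPTs")
    list(chrom_lengths = nuc_fa$lengths, gff = gff, pl_gff = pl_gff,
         aln = aln, nupts = alignment_to_nupts(aln))
  })

  ## ---- age classification --------------------------------------------
  res$classes <- stage("classify", {
    fit <- fit_identity_mixture(inputs$aln$pident, k = 2,
                                seed = config$seed)
    asg <- assign_age_class(fit, inputs$aln$pident,
                            threshold = config$posterior_threshold,
                            ids = inputs$nupts$nupt_id)
    write_tsv_report(asg, file.path(out, "nupt_classes.tsv"))
    list(fit = fit, assignments = asg)
  })
  nupts <- inputs$nupts
  nupts$label <- res$classes$assignments$label

  ## ---- windowed densities --------------------------------------------
  res$density <- stage("density", {
    dens <- windowed_density(
      gintervals(nupts$chrom, nupts$start, nupts$end),
      window_bp = config$window_bp, chrom_lengths = inputs$chrom_lengths)
    write_tsv_report(dens, file.path(out, "nupt_density.tsv"))
    dens
  })

  ## ---- partition + enrichment ----------------------------------------
  res$enrichment <- stage("enrich", {
    fsets <- pipeline_feature_sets(inputs$gff, inputs$chrom_lengths,
                                   config$flank_bp)
    part <- partition_genome(fsets, priority_order = config$priority,
                             genome_lengths = inputs$chrom_lengths)
    by_class <- split(seq_len(nrow(nupts)), nupts$label)
    sets <- lapply(by_class, function(i)
      gintervals(nupts$chrom[i], nupts$start[i], nupts$end[i]))
    sets$all <- gintervals(nupts$chrom, nupts$start, nupts$end)
    enr <- enrichment_scan(sets, part, alpha = config$alpha)
    write_tsv_report(enr, file.path(out, "enrichment.tsv"))
    sizes <- data.frame(category = names(part$sizes),
                        partition_bp = unname(part$sizes),
                        stringsAsFactors = FALSE)
    write_tsv_report(sizes, file.path(out, "partition_sizes.tsv"))
    list(partition = part, table = enr, feature_sets = fsets)
  })

  ## ---- structural-gene impact ----------------------------------------
  res$impact <- stage("impact", {
    rec <- classify_gene_hits(nupts, inputs$gff$gene_models,
                              flank_bp = config$flank_bp,
                              chrom_lengths = inputs$chrom_lengths)
    write_tsv_report(rec, file.path(out, "gene_impact.tsv"))
    summ <- impact_summary(rec)
    write_tsv_report(impact_summary_table(summ),
                     file.path(out, "impact_summary.tsv"))
    list(records = rec, summary = summ)
  })

  ## ---- RNA origin + donors -------------------------------------------
  if (!is.null(config$trna_hits) && !is.null(config$compartment_map)) {
    res$origin <- stage("origin", {
      hits <- read_alignment_tab(config$trna_hits)
      cmap <- read_tsv_report(config$compartment_map)
      trna_cats <- c("tRNA_nuclear", "tRNA_plastid", "tRNA_mitochondrial")
      trna_sets <- inputs$gff$feature_sets[
        names(inputs$gff$feature_sets) %in% trna_cats]
      trna_ids <- unlist(lapply(trna_sets, function(s) s$id),
                         use.names = FALSE)
      calls <- classify_origin(hits, cmap, query_ids = trna_ids)
      loci <- do.call(rbind, lapply(trna_sets, function(s)
        s[, c("chrom", "start", "end", "id")]))
      loci <- loci[match(calls$gene_id, loci$id), ]
      calls$in_nupt <- vapply(seq_len(nrow(calls)), function(i) {
        nn <- nupts[nupts$chrom == loci$chrom[i], , drop = FALSE]
        if (nrow(nn) == 0L) return(FALSE)
        covered_bp(loci$start[i], loci$end[i], nn$start, nn$end) ==
          loci$end[i] - loci$start[i]
      }, logical(1))
      census <- trna_census(calls)
      write_tsv_report(calls, file.path(out, "trna_origin.tsv"))
      rna_cats <- intersect(names(inputs$gff$feature_sets),
                            setdiff(NUPT_CATEGORIES,
                                    c("structural_gene", "TE",
                                      "other_repeat", "other_DNA")))
      donors <- map_all_donors(
        inputs$gff$feature_sets[rna_cats], nupts,
        inputs$pl_gff$feature_sets)
      write_tsv_report(donors, file.path(out, "donor_mapping.tsv"))
      list(calls = calls, census = census, donors = donors,
           split = donor_annotation_split(donors))
    })
  }

  ## ---- expression ------------------------------------------------------
  if (!is.null(config$tpm)) {
    res$expression <- stage("express", {
      mat <- read_tpm(config$tpm)
      expressed <- flag_expressed(mat, config$expr_threshold)
      taus <- tau_matrix(mat)
      per_gene <- data.frame(gene_id = rownames(mat),
                             expressed = unname(expressed),
                             stringsAsFactors = FALSE)
      per_gene <- merge(per_gene, taus, by = "gene_id", sort = TRUE)
      write_tsv_report(per_gene, file.path(out, "expression.tsv"))

      affected <- res$impact$records$gene_id
      bg <- rownames(mat)
      grp <- intersect(affected, bg)
      tests <- NULL
      if (length(grp) >= 2 && length(grp) < length(bg)) {
        ft <- fisher_fraction_test(sum(expressed[grp]), length(grp),
                                   sum(expressed), length(bg))
        rest <- setdiff(bg, grp)
        wt_tpm <- wilcoxon_rank_test(rowMeans(mat[grp, , drop = FALSE]),
                                     rowMeans(mat[rest, , drop = FALSE]))
        tau_g <- taus$tau[taus$gene_id %in% grp & taus$defined]
        tau_r <- taus$tau[taus$gene_id %in% rest & taus$defined]
        wt_tau <- if (length(tau_g) >= 2 && length(tau_r) >= 2)
          wilcoxon_rank_test(tau_g, tau_r) else NULL
        tests <- data.frame(
          comparison = c("expressed_fraction", "tpm_rank",
                         if (!is.null(wt_tau)) "tau_rank"),
          n_group = length(grp), n_background = length(bg),
          statistic = c(ft$odds_ratio, wt_tpm$U,
                        if (!is.null(wt_tau)) wt_tau$U),
          p = c(ft$p, wt_tpm$p, if (!is.null(wt_tau)) wt_tau$p),
          stringsAsFactors = FALSE)
        write_tsv_report(tests, file.path(out, "group_tests.tsv"))
      }
      enr <- NULL
      if (!is.null(config$terms) && length(grp) >= 1) {
        tt <- read_tsv_report(config$terms)
        enr <- term_enrichment(grp, bg, tt, alpha = config$alpha)
        write_tsv_report(enr, file.path(out, "term_enrichment.tsv"))
      }
      list(per_gene = per_gene, tests = tests, term_enrichment = enr)
    })
  }

  ## ---- manifest --------------------------------------------------------
  stage("manifest", {
    in_paths <- Filter(Negate(is.null), config[c(
      "nuclear_fasta", "nuclear_gff3", "plastid_fasta", "plastid_gff3",
      "alignment", "trna_hits", "compartment_map", "tpm", "terms")])
    manifest <- list(
      package = "nuptr",
      version = as.character(utils::packageVersion("nuptr")),
      seed = config$seed,
      parameters = config[c("posterior_threshold", "flank_bp", "window_bp",
                            "alpha", "expr_threshold")],
      inputs = lapply(in_paths, function(p)
        list(file = basename(p), md5 = unname(tools::md5sum(p))))
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(res)
}

# feature sets for the partition: structural genes with their 1 kb
# flanks, all other annotated categories as read
pipeline_feature_sets <- function(gff, chrom_lengths, flank_bp) {
  sets <- gff$feature_sets
  gm <- gene_model_table(gff$gene_models)
  if (!is.null(gm) && nrow(gm)) {
    iv <- gintervals(gm$chrom, pmax(gm$start - flank_bp, 0),
                     pmin(gm$end + flank_bp, chrom_lengths[gm$chrom]))
    iv$id <- gm$gene_id
    sets$structural_gene <- iv
  }
  sets
}

impact_summary_table <- function(summ) {
  data.frame(
    metric = c("n_affected",
               paste0("region_", names(summ$by_region)),
               paste0("pattern_", names(summ$by_class_pattern)),
               "n_fully_covered", "pct_fully_covered",
               "max_nupts_per_gene"),
    value = c(summ$n_affected, unname(summ$by_region),
              unname(summ$by_class_pattern), summ$n_fully_covered,
              summ$pct_fully_covered, summ$max_nupts_per_gene),
    stringsAsFactors = FALSE)
}
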