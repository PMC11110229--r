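#' Simulation configuration
#'
#' Defaults define the study conditions the generator emulates: a ~150 kb
#' plastid genome carrying tRNA (labeled plastid / mitochondrial /
#' nuclear by origin), prokaryotic and eukaryotic rRNA, self-splicing
#' intron and regulatory RNA genes; a multi-chromosome nuclear genome with
#' structural genes, TEs, repeats and RNA genes; and two waves of planted
#' NUPT insertions — an older, more diverged episode I (identity ~
#' N(82, 3^2)) and a younger, larger episode II (identity ~ N(97, 1.5^2)),
#' truncated to \[60, 100\]. Placement weights bias insertion sites toward
#' RNA-gene categories and away from structural genes, echoing the
#' retention biases the pipeline is designed to detect.
#'
#' @param seed integer master seed; every generator derives its stream
#'   from it, so equal seeds give byte-identical outputs.
#' @param ... overrides for any default listed below.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # plastid genome
    plastid_length = 150000,
    plastid_genes = c(tRNA_plastid = 30, tRNA_mitochondrial = 3,
                      tRNA_nuclear = 3, rRNA_prokaryotic = 4,
                      rRNA_eukaryotic = 5, self_splicing_intron = 22,
                      regulatory_RNA = 1),
    plastid_gene_len = list(tRNA_plastid = c(70, 90),
                            tRNA_mitochondrial = c(70, 90),
                            tRNA_nuclear = c(70, 90),
                            rRNA_prokaryotic = c(1200, 2900),
                            rRNA_eukaryotic = c(120, 3500),
                            self_splicing_intron = c(400, 900),
                            regulatory_RNA = c(150, 250)),
    # nuclear genome
    n_chrom = 4L,
    chrom_length = 250000,
    n_genes = 120L,
    exons_per_gene = c(1L, 6L),
    exon_len = c(150, 400),
    intron_len = c(100, 600),
    n_te = 300L, te_len = c(200, 2000),
    n_other_repeat = 60L, repeat_len = c(100, 500),
    nuclear_rna_counts = c(tRNA_nuclear = 30, tRNA_plastid = 40,
                           tRNA_mitochondrial = 10, rRNA_prokaryotic = 10,
                           rRNA_eukaryotic = 15, self_splicing_intron = 20,
                           regulatory_RNA = 8, spliceosomal_RNA = 5,
                           other_RNA = 5),
    rna_gene_len = c(70, 300),
    flank_bp = 1000,
    # NUPT episodes
    episodes = list(I = list(n = 150L, mean = 82, sd = 3),
                    II = list(n = 750L, mean = 97, sd = 1.5)),
    identity_range = c(60, 100),
    frag_len = c(100, 400),
    placement_weights = c(structural_gene = 0.2, TE = 1, other_repeat = 0.5,
                          rRNA_eukaryotic = 5, rRNA_prokaryotic = 5,
                          tRNA_nuclear = 5, tRNA_mitochondrial = 5,
                          tRNA_plastid = 5, self_splicing_intron = 5,
                          regulatory_RNA = 5, spliceosomal_RNA = 1,
                          other_RNA = 1, other_DNA = 1),
    # expression
    tissues = c("flower", "leaf", "root", "seed", "stem"),
    expr_class_props = c(silent = 0.2, uniform = 0.4, specific = 0.4),
    expr_mean_range = c(5, 200),
    expr_noise_cv = 0.1,
    specific_leak = 0.05,
    # term annotation
    n_terms = 20L,
    term_base_rate = 0.08,
    planted_term_factor = 5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

#' Mutate a sequence to a target percent identity
#'
#' Substitution-only mutation (no indels, so query and donor spans stay
#' equal length): each base is substituted independently with probability
#' `1 - target/100`, the replacement drawn uniformly from the three
#' alternative bases. Uses the current RNG stream.
#'
#' @param sequence character scalar (nucleotides).
#' @param target_identity target percent identity in (0, 100\].
#' @return list with `sequence` (mutated) and `realized_identity`
#'   (percent of bases left unchanged).
#' @export
mutate_to_identity <- function(sequence, target_identity) {
  if (target_identity <= 0 || target_identity > 100)
    stop("target identity must lie in (0, 100]")
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(bases)
  hit <- stats::runif(n) < (1 - target_identity / 100)
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    bases[hit] <- vapply(bases[hit], function(b)
      sample(setdiff(alt, b), 1L), character(1))
  }
  list(sequence = paste(bases, collapse = ""),
       realized_identity = 100 * (1 - sum(hit) / n))
}

# sequentially lay out n_features non-overlapping spans of given lengths
# along [0, total_len); errors when they cannot fit
layout_spans <- function(lengths, total_len, min_gap = 50) {
  need <- sum(lengths) + min_gap * length(lengths)
  if (need > total_len)
    stop("layout overflow: features need ", need, " bp but genome has ",
         total_len)
  slack <- total_len - sum(lengths)
  gaps <- stats::runif(length(lengths) + 1)
  gaps <- floor(gaps / sum(gaps) * (slack - min_gap * length(lengths)))
  starts <- numeric(length(lengths))
  cursor <- 0
  for (i in seq_along(lengths)) {
    cursor <- cursor + gaps[i] + min_gap
    starts[i] <- cursor
    cursor <- cursor + lengths[i]
  }
  starts
}

#' Generate the plastid genome, its annotation and the tRNA reference
#'
#' Writes `plastid.fasta`, `plastid.gff3` (RNA genes typed by category)
#' and `compartment_map.tsv` (reference tRNA subjects labeled nuclear /
#' mitochondrial / plastid, as an external tRNA database would provide).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `fasta`, `gff3`, `compartment_map` paths, the
#'   sequence, and the annotation rows.
#' @export
generate_plastid <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  seq_chars <- random_dna(config$plastid_length)

  counts <- config$plastid_genes
  cats <- rep(names(counts), counts)
  lens <- vapply(cats, function(cat) {
    r <- config$plastid_gene_len[[cat]]
    floor(stats::runif(1, r[1], r[2] + 1))
  }, numeric(1))
  rows <- NULL
  if (length(cats)) {
    ord <- sample(length(cats))
    cats <- cats[ord]; lens <- lens[ord]
    starts <- layout_spans(lens, config$plastid_length)
    rows <- data.frame(
      chrom = "plastid", start = starts, end = starts + lens,
      strand = sample(c("+", "-"), length(cats), replace = TRUE),
      type = cats,
      id = sprintf("pl_%s_%03d", cats, seq_along(cats)),
      parent = NA_character_, category = cats,
      stringsAsFactors = FALSE)
  }

  fa <- file.path(dir, "plastid.fasta")
  gff <- file.path(dir, "plastid.gff3")
  write_fasta(c(plastid = paste(seq_chars, collapse = "")), fa)
  if (!is.null(rows)) write_gff3(rows, gff)
  else writeLines("##gff-version 3", gff)

  # reference tRNA database subjects, one per compartment label in use
  comp <- c(tRNA_plastid = "plastid", tRNA_mitochondrial = "mitochondrial",
            tRNA_nuclear = "nuclear")
  ref <- data.frame(
    subject_id = c("ref_trna_plastid", "ref_trna_mito", "ref_trna_nuclear"),
    compartment = c("plastid", "mitochondrial", "nuclear"),
    stringsAsFactors = FALSE)
  cm <- file.path(dir, "compartment_map.tsv")
  write_tsv_report(ref, cm)

  list(fasta = fa, gff3 = gff, compartment_map = cm,
       sequence = seq_chars, annotation = rows, trna_compartments = comp)
}

# draw an episode identity truncated to the configured range
draw_identity <- function(mean, sd, range) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= min(range[2], 100)) return(x)
  }
}

#' Generate the nuclear genome with planted NUPTs and the truth ledger
#'
#' Plants structural genes (gene/mRNA/exon hierarchy), TEs, repeats and
#' background RNA genes; then inserts NUPTs from the two configured
#' episodes by copying plastid segments, mutating them to a drawn
#' identity, and overwriting nuclear bases at positions sampled
#' proportionally to per-category placement weights over the genome
#' partition (insertions never shift annotated coordinates). NUPT copies
#' that fully contain a plastid RNA gene deposit an identically
#' categorized nuclear RNA gene at the transferred coordinates. The truth
#' alignment table carries the exact planted coordinates and realized
#' identities; the JSON truth ledger is sufficient to score every
#' downstream module.
#'
#' @param plastid result of [generate_plastid()].
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return list of paths (`fasta`, `gff3`, `alignment`, `trna_hits`,
#'   `truth`) plus `truth` (the ledger), `chrom_lengths`, and `gene_ids`.
#' @export
generate_nuclear <- function(plastid, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 1L)
  chroms <- sprintf("chr%02d", seq_len(config$n_chrom))
  chrom_lengths <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                                   chroms)
  seqs <- lapply(chroms, function(ch) random_dna(config$chrom_length))
  names(seqs) <- chroms

  ## ---- background annotation ----------------------------------------
  runi <- function(r, n = 1) floor(stats::runif(n, r[1], r[2] + 1))
  feats <- list()  # rows for write_gff3
  queue <- list()  # (category, length, builder) per feature, then laid out
  for (i in seq_len(config$n_genes)) {
    n_ex <- runi(config$exons_per_gene)
    ex_lens <- runi(config$exon_len, n_ex)
    in_lens <- if (n_ex > 1) runi(config$intron_len, n_ex - 1) else numeric(0)
    queue[[length(queue) + 1L]] <- list(kind = "gene",
      len = sum(ex_lens) + sum(in_lens), ex_lens = ex_lens,
      in_lens = in_lens)
  }
  for (i in seq_len(config$n_te))
    queue[[length(queue) + 1L]] <- list(kind = "TE", len = runi(config$te_len))
  for (i in seq_len(config$n_other_repeat))
    queue[[length(queue) + 1L]] <- list(kind = "other_repeat",
                                        len = runi(config$repeat_len))
  for (cat in names(config$nuclear_rna_counts))
    for (i in seq_len(config$nuclear_rna_counts[[cat]]))
      queue[[length(queue) + 1L]] <- list(kind = cat,
                                          len = runi(config$rna_gene_len))
  queue <- queue[sample(length(queue))]
  per_chrom <- split(queue, rep_len(seq_len(config$n_chrom), length(queue)))

  gene_i <- 0L; te_i <- 0L; rep_i <- 0L; rna_i <- 0L
  for (ci in seq_len(config$n_chrom)) {
    q <- per_chrom[[ci]]
    lens <- vapply(q, `[[`, numeric(1), "len")
    starts <- layout_spans(lens, config$chrom_length)
    for (k in seq_along(q)) {
      it <- q[[k]]; s <- starts[k]; e <- s + it$len
      strand <- sample(c("+", "-"), 1)
      if (it$kind == "gene") {
        gene_i <- gene_i + 1L
        gid <- sprintf("gene%04d", gene_i)
        feats[[length(feats) + 1L]] <- data.frame(
          chrom = chroms[ci], start = s, end = e, strand = strand,
          type = "gene", id = gid, parent = NA_character_,
          category = NA_character_, stringsAsFactors = FALSE)
        feats[[length(feats) + 1L]] <- data.frame(
          chrom = chroms[ci], start = s, end = e, strand = strand,
          type = "mRNA", id = paste0(gid, ".t1"), parent = gid,
          category = NA_character_, stringsAsFactors = FALSE)
        cursor <- s
        for (j in seq_along(it$ex_lens)) {
          feats[[length(feats) + 1L]] <- data.frame(
            chrom = chroms[ci], start = cursor,
            end = cursor + it$ex_lens[j], strand = strand,
            type = "exon", id = sprintf("%s.t1.e%d", gid, j),
            parent = paste0(gid, ".t1"), category = NA_character_,
            stringsAsFactors = FALSE)
          cursor <- cursor + it$ex_lens[j] +
            if (j <= length(it$in_lens)) it$in_lens[j] else 0
        }
      } else if (it$kind == "TE") {
        te_i <- te_i + 1L
        feats[[length(feats) + 1L]] <- data.frame(
          chrom = chroms[ci], start = s, end = e, strand = strand,
          type = "TE", id = sprintf("te%04d", te_i),
          parent = NA_character_, category = "TE", stringsAsFactors = FALSE)
      } else if (it$kind == "other_repeat") {
        rep_i <- rep_i + 1L
        feats[[length(feats) + 1L]] <- data.frame(
          chrom = chroms[ci], start = s, end = e, strand = strand,
          type = "other_repeat", id = sprintf("rep%04d", rep_i),
          parent = NA_character_, category = "other_repeat",
          stringsAsFactors = FALSE)
      } else {
        rna_i <- rna_i + 1L
        feats[[length(feats) + 1L]] <- data.frame(
          chrom = chroms[ci], start = s, end = e, strand = strand,
          type = it$kind, id = sprintf("rna%04d", rna_i),
          parent = NA_character_, category = it$kind,
          stringsAsFactors = FALSE)
      }
    }
  }
  feat_df <- do.call(rbind, feats)

  ## ---- partition for weighted placement ------------------------------
  fsets <- background_feature_sets(feat_df, chrom_lengths, config$flank_bp)
  part <- partition_genome(fsets, genome_lengths = chrom_lengths)
  w <- config$placement_weights
  cats <- names(part$sizes)
  w <- ifelse(cats %in% names(w), w[cats], 1)
  probs <- w * part$sizes
  probs <- probs / sum(probs)

  sample_position <- function(len) {
    for (try in 1:50) {
      cat <- sample(cats, 1, prob = probs)
      iv <- part$intervals[[cat]]
      widths <- iv$end - iv$start
      row <- sample(nrow(iv), 1, prob = widths)
      pos <- floor(stats::runif(1, iv$start[row], iv$end[row]))
      chr <- iv$chrom[row]
      if (pos + len <= chrom_lengths[[chr]])
        return(list(chrom = chr, start = pos, category = cat))
    }
    stop("infeasible NUPT placement after bounded retries")
  }

  ## ---- plant NUPTs ----------------------------------------------------
  plastid_seq <- plastid$sequence
  pl_len <- length(plastid_seq)
  aln <- list(); truth_nupts <- list(); derived_rna <- list()
  nupt_i <- 0L
  for (ep in names(config$episodes)) {
    epc <- config$episodes[[ep]]
    for (i in seq_len(epc$n)) {
      nupt_i <- nupt_i + 1L
      len <- runi(config$frag_len)
      p_start <- floor(stats::runif(1, 0, pl_len - len))
      p_end <- p_start + len
      ident <- draw_identity(epc$mean, epc$sd, config$identity_range)
      strand <- sample(c("+", "-"), 1)
      seg <- plastid_seq[(p_start + 1):p_end]
      if (strand == "-") seg <- rev_comp(seg)
      mut <- mutate_to_identity(paste(seg, collapse = ""), ident)
      pos <- sample_position(len)
      s <- pos$start; e <- s + len
      seqs[[pos$chrom]][(s + 1):e] <- strsplit(mut$sequence, "",
                                               fixed = TRUE)[[1]]
      aln[[nupt_i]] <- data.frame(
        qseqid = pos$chrom, sseqid = "plastid",
        pident = round(mut$realized_identity, 2), length = len,
        mismatch = round(len * (1 - mut$realized_identity / 100)),
        gapopen = 0L, qstart = s + 1, qend = e,
        sstart = if (strand == "+") p_start + 1 else p_end,
        send = if (strand == "+") p_end else p_start + 1,
        evalue = 0, bitscore = round(1.8 * len),
        stringsAsFactors = FALSE)
      truth_nupts[[nupt_i]] <- data.frame(
        nupt_id = sprintf("NUPT_%05d", nupt_i), chrom = pos$chrom,
        start = s, end = e, p_start = p_start, p_end = p_end,
        strand = strand, episode = ep, target_identity = ident,
        realized_identity = mut$realized_identity,
        placed_category = pos$category, stringsAsFactors = FALSE)
      # deposit identically categorized RNA genes for plastid genes the
      # NUPT copy fully contains
      if (!is.null(plastid$annotation)) {
        pa <- plastid$annotation
        inside <- pa$start >= p_start & pa$end <= p_end
        for (j in which(inside)) {
          if (strand == "+") {
            ns <- s + (pa$start[j] - p_start)
            ne <- s + (pa$end[j] - p_start)
          } else {
            ns <- s + (p_end - pa$end[j])
            ne <- s + (p_end - pa$start[j])
          }
          derived_rna[[length(derived_rna) + 1L]] <- data.frame(
            chrom = pos$chrom, start = ns, end = ne, strand = strand,
            type = pa$type[j],
            id = sprintf("nupt_rna%04d", length(derived_rna) + 1L),
            parent = NA_character_, category = pa$category[j],
            donor_gene = pa$id[j], nupt_id = sprintf("NUPT_%05d", nupt_i),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  aln_df <- do.call(rbind, aln)
  truth_df <- do.call(rbind, truth_nupts)
  if (length(derived_rna)) {
    drna <- do.call(rbind, derived_rna)
    feat_df <- rbind(feat_df, drna[, names(feat_df)])
  } else drna <- NULL

  ## ---- tRNA best-hit table -------------------------------------------
  trna <- feat_df[feat_df$type %in% c("tRNA_nuclear", "tRNA_plastid",
                                      "tRNA_mitochondrial"), , drop = FALSE]
  ref_for <- c(tRNA_plastid = "ref_trna_plastid",
               tRNA_mitochondrial = "ref_trna_mito",
               tRNA_nuclear = "ref_trna_nuclear")
  hits <- NULL
  if (nrow(trna)) {
    hits <- data.frame(
      qseqid = trna$id, sseqid = unname(ref_for[trna$type]),
      pident = round(stats::runif(nrow(trna), 85, 100), 2),
      length = trna$end - trna$start, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = trna$end - trna$start,
      sstart = 1L, send = trna$end - trna$start,
      evalue = 1e-20, bitscore = round(stats::runif(nrow(trna), 80, 150)),
      stringsAsFactors = FALSE)
  }

  ## ---- write ----------------------------------------------------------
  fa <- file.path(dir, "nuclear.fasta")
  gff <- file.path(dir, "nuclear.gff3")
  aln_path <- file.path(dir, "alignment.tsv")
  hits_path <- file.path(dir, "trna_hits.tsv")
  truth_path <- file.path(dir, "truth.json")
  write_fasta(vapply(seqs, paste, character(1), collapse = ""), fa)
  write_gff3(feat_df, gff)
  write_alignment_tab(aln_df, aln_path)
  if (!is.null(hits)) write_alignment_tab(hits, hits_path)

  truth <- list(
    seed = config$seed,
    chrom_lengths = as.list(chrom_lengths),
    episode_counts = vapply(config$episodes, `[[`, integer(1), "n"),
    episode_means = vapply(config$episodes, `[[`, numeric(1), "mean"),
    placement_weights = as.list(config$placement_weights),
    nupts = truth_df,
    derived_rna = if (!is.null(drna))
      drna[, c("id", "category", "donor_gene", "nupt_id")] else NULL
  )
  jsonlite::write_json(truth, truth_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(fasta = fa, gff3 = gff, alignment = aln_path,
       trna_hits = hits_path, truth_path = truth_path, truth = truth,
       chrom_lengths = chrom_lengths,
       gene_ids = feat_df$id[feat_df$type == "gene"])
}

rev_comp <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(rev(comp[chars]))
}

# feature sets (category -> intervals) from generator annotation rows;
# structural genes enter with their 1 kb flanks, matching the accounting
# used downstream
background_feature_sets <- function(feat_df, chrom_lengths, flank_bp) {
  sets <- list()
  genes <- feat_df[feat_df$type == "gene", , drop = FALSE]
  if (nrow(genes)) {
    iv <- gintervals(genes$chrom,
                     pmax(genes$start - flank_bp, 0),
                     pmin(genes$end + flank_bp, chrom_lengths[genes$chrom]))
    iv$id <- genes$id
    sets$structural_gene <- iv
  }
  other <- feat_df[!(feat_df$type %in% c("gene", "mRNA", "exon", "CDS")), ,
                   drop = FALSE]
  for (cat in unique(other$category)) {
    d <- other[other$category == cat & !is.na(other$category), ,
               drop = FALSE]
    if (nrow(d) == 0L) next
    iv <- gintervals(d$chrom, d$start, d$end, d$strand)
    iv$id <- d$id
    sets[[cat]] <- iv
  }
  sets
}

#' Generate a tissue TPM matrix with planted specificity classes
#'
#' Three planted gene classes: silent (all-zero rows), uniform (equal
#' tissue means with multiplicative noise, Tau near 0) and specific (one
#' dominant tissue, the rest leaking a small fraction of its mean, Tau
#' near 1). Noise is Gaussian with coefficient of variation
#' `expr_noise_cv`, floored at 0.
#'
#' @param gene_ids character vector of gene ids.
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return list with `tpm` path, `truth` data.frame (`gene_id`, `class`,
#'   `dominant_tissue`), and the matrix.
#' @export
generate_expression <- function(gene_ids, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 2L)
  stopifnot(length(config$tissues) >= 2)
  n <- length(gene_ids)
  cls <- sample(names(config$expr_class_props), n, replace = TRUE,
                prob = config$expr_class_props)
  nt <- length(config$tissues)
  mat <- matrix(0, n, nt, dimnames = list(gene_ids, config$tissues))
  dom <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (cls[i] == "silent") next
    mu <- stats::runif(1, config$expr_mean_range[1],
                       config$expr_mean_range[2])
    if (cls[i] == "uniform") {
      means <- rep(mu, nt)
    } else {
      d <- sample(nt, 1)
      dom[i] <- config$tissues[d]
      means <- rep(mu * config$specific_leak, nt)
      means[d] <- mu
    }
    mat[i, ] <- pmax(stats::rnorm(nt, means, config$expr_noise_cv * means),
                     0)
  }
  path <- file.path(dir, "tpm.tsv")
  write_tpm(round(mat, 4), path)
  list(tpm = path,
       truth = data.frame(gene_id = gene_ids, class = cls,
                          dominant_tissue = dom, stringsAsFactors = FALSE),
       matrix = mat)
}

#' Generate a gene-to-term annotation table with one planted enriched term
#'
#' Terms annotate background genes at the base rate; the planted term
#' (`TERM_PLANTED`) annotates members of `enriched_genes` at
#' `planted_term_factor` times the base rate, and other genes at the base
#' rate.
#'
#' @param gene_ids background gene ids.
#' @param enriched_genes subset of `gene_ids` carrying the planted signal.
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return list with `terms` path, `planted_term` id and the table.
#' @export
generate_terms <- function(gene_ids, enriched_genes, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 3L)
  stopifnot(all(enriched_genes %in% gene_ids))
  rows <- list()
  for (t in seq_len(config$n_terms)) {
    tid <- sprintf("TERM_%03d", t)
    has <- stats::runif(length(gene_ids)) < config$term_base_rate
    for (g in gene_ids[has])
      rows[[length(rows) + 1L]] <- data.frame(gene_id = g, term_id = tid,
                                              namespace = "synthetic",
                                              stringsAsFactors = FALSE)
  }
  rate <- config$term_base_rate
  p_in <- min(1, rate * config$planted_term_factor)
  has <- ifelse(gene_ids %in% enriched_genes,
                stats::runif(length(gene_ids)) < p_in,
                stats::runif(length(gene_ids)) < rate)
  for (g in gene_ids[has])
    rows[[length(rows) + 1L]] <- data.frame(gene_id = g,
                                            term_id = "TERM_PLANTED",
                                            namespace = "synthetic",
                                            stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  path <- file.path(dir, "terms.tsv")
  write_tsv_report(tab, path)
  list(terms = path, planted_term = "TERM_PLANTED", table = tab)
}

#' Generate a complete synthetic input bundle
#'
#' Runs all generators with streams derived from the config seed and
#' writes every input the pipeline consumes into `dir`. Equal seeds give
#' byte-identical bundles.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return named list of file paths plus the truth ledger.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pl <- generate_plastid(config, dir)
  nu <- generate_nuclear(pl, config, dir)
  ex <- generate_expression(nu$gene_ids, config, dir)
  affected <- truth_affected_genes(nu)
  tm <- generate_terms(nu$gene_ids, affected, config, dir)
  list(plastid_fasta = pl$fasta, plastid_gff3 = pl$gff3,
       compartment_map = pl$compartment_map,
       nuclear_fasta = nu$fasta, nuclear_gff3 = nu$gff3,
       alignment = nu$alignment, trna_hits = nu$trna_hits,
       tpm = ex$tpm, terms = tm$terms, truth_path = nu$truth_path,
       truth = nu$truth, expression_truth = ex$truth,
       planted_term = tm$planted_term, chrom_lengths = nu$chrom_lengths)
}

# gene ids whose (flanked) span overlaps a planted NUPT, from truth alone
truth_affected_genes <- function(nu) {
  gff <- read_gff3(nu$gff3)
  nupts <- nu$truth$nupts
  affected <- character(0)
  for (g in gff$gene_models) {
    cand <- nupts[nupts$chrom == g$chrom &
                  nupts$end > g$start - 1000 &
                  nupts$start < g$end + 1000, , drop = FALSE]
    if (nrow(cand)) affected <- c(affected, g$gene_id)
  }
  affected
}
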