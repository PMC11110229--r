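#' Flag genes as expressed
#'
#' A gene is expressed when its TPM exceeds the threshold in at least one
#' tissue. The default threshold of 0 calls any nonzero TPM expressed;
#' raising the threshold can only remove genes from the expressed set.
#'
#' @param mat numeric matrix, genes x tissues, TPM values >= 0.
#' @param threshold TPM threshold (default 0; strict inequality).
#' @return named logical vector, one flag per gene.
#' @export
flag_expressed <- function(mat, threshold = 0) {
  stopifnot(is.matrix(mat) || is.data.frame(mat), threshold >= 0)
  m <- as.matrix(mat)
  if (any(m < 0)) stop("TPM values must be non-negative")
  apply(m > threshold, 1, any)
}

#' Tau tissue-specificity index
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)` over N tissues: 0 for
#' uniform expression across all tissues, 1 for expression confined to a
#' single tissue. Undefined (flagged) when the gene is silent
#' (max = 0). Scale-invariant in the expression values.
#'
#' @param values non-negative TPM values over N >= 2 tissues.
#' @return list with `tau`, `n_tissues`, `defined`.
#' @export
tau <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2L) stop("Tau requires at least 2 tissues")
  if (any(x < 0)) stop("TPM values must be non-negative")
  mx <- max(x)
  if (mx == 0)
    return(list(tau = NA_real_, n_tissues = length(x), defined = FALSE))
  list(tau = sum(1 - x / mx) / (length(x) - 1), n_tissues = length(x),
       defined = TRUE)
}

#' Tau for every row of a TPM matrix
#' @param mat genes x tissues TPM matrix.
#' @return data.frame `gene_id`, `tau`, `defined`.
#' @export
tau_matrix <- function(mat) {
  m <- as.matrix(mat)
  res <- apply(m, 1, function(r) {
    t <- tau(r)
    c(t$tau, t$defined)
  })
  data.frame(gene_id = rownames(m), tau = res[1, ],
             defined = as.logical(res[2, ]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Fisher's exact test on expressed fractions
#'
#' Two-sided Fisher test of a gene group's expressed/unexpressed split
#' against the rest of the background (group excluded from the comparison
#' margin).
#'
#' @param group_expressed,group_total expressed count and size of the
#'   group.
#' @param bg_expressed,bg_total expressed count and size of the full
#'   background (which contains the group).
#' @return list with `p`, `odds_ratio`, and the 2x2 `table`.
#' @export
fisher_fraction_test <- function(group_expressed, group_total,
                                 bg_expressed, bg_total) {
  if (group_total <= 0) stop("group_total must be positive")
  if (group_expressed > group_total)
    stop("group_expressed cannot exceed group_total")
  if (group_total > bg_total || group_expressed > bg_expressed)
    stop("group must be contained in the background")
  rest_exp <- bg_expressed - group_expressed
  rest_unexp <- (bg_total - group_total) - rest_exp
  if (rest_unexp < 0) stop("inconsistent background counts")
  tab <- matrix(c(group_expressed, group_total - group_expressed,
                  rest_exp, rest_unexp), nrow = 2, byrow = TRUE,
                dimnames = list(c("group", "rest"),
                                c("expressed", "unexpressed")))
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Wilcoxon rank-sum test (exact for small samples, midranks for ties)
#'
#' Rank-sum test with midranks for ties. For `n_a + n_b <= 12` the
#' two-sided p-value is computed by full enumeration of all label
#' permutations of the pooled sample (which remains exact under ties);
#' larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param values_a,values_b nonempty numeric vectors.
#' @return list with `U` (Mann-Whitney statistic for sample a), `p`
#'   (two-sided), `method`.
#' @export
wilcoxon_rank_test <- function(values_a, values_b) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= 12L) {
    idx <- utils::combn(na + nb, na)
    mu <- na * nb / 2
    obs_dev <- abs(U - mu)
    Us <- apply(idx, 2, function(i) sum(r[i])) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= obs_dev - 1e-9)
    list(U = U, p = p, method = "exact permutation")
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    list(U = unname(wt$statistic), p = wt$p.value,
         method = "normal approximation")
  }
}

#' Functional-term enrichment with Bonferroni correction
#'
#' For each term, a two-sided Fisher exact test of the term's frequency in
#' the gene set versus the rest of the background; p-values are Bonferroni
#' corrected over the number of terms tested (`p_adj = min(1, m * p)`),
#' and terms with `p_adj < alpha` are flagged, split into over- and
#' under-represented by the odds ratio.
#'
#' @param gene_set character vector of genes of interest (subset of
#'   `background`).
#' @param background character vector of all genes.
#' @param term_table data.frame with `gene_id` and `term_id` columns.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame with one row per term: `term_id`, `set_with`,
#'   `set_total`, `bg_with`, `bg_total`, `odds_ratio`, `p`, `p_adj`,
#'   `direction` (`over` / `under` / `ns`).
#' @export
term_enrichment <- function(gene_set, background, term_table, alpha = 0.05) {
  stopifnot(all(gene_set %in% background))
  terms <- unique(term_table$term_id)
  if (length(terms) == 0L) stop("empty term table")
  m <- length(terms)
  set_n <- length(gene_set)
  bg_n <- length(background)
  rest <- setdiff(background, gene_set)
  out <- lapply(terms, function(tm) {
    genes_with <- unique(term_table$gene_id[term_table$term_id == tm])
    a <- sum(gene_set %in% genes_with)
    c_ <- sum(rest %in% genes_with)
    tab <- matrix(c(a, set_n - a, c_, length(rest) - c_), nrow = 2,
                  byrow = TRUE)
    ft <- stats::fisher.test(tab)
    p_adj <- min(1, m * ft$p.value)
    dir <- "ns"
    if (p_adj < alpha)
      dir <- if (unname(ft$estimate) > 1) "over" else "under"
    data.frame(term_id = tm, set_with = a, set_total = set_n,
               bg_with = a + c_, bg_total = bg_n,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               p_adj = p_adj, direction = dir, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a TPM expression table
#' @param path TSV with a header row; first column gene ids, remaining
#'   columns tissue TPM values.
#' @return numeric matrix, genes x tissues.
#' @export
read_tpm <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (any(m < 0)) stop("negative TPM values in ", path)
  m
}

#' Write a TPM expression table
#' @param mat genes x tissues matrix with dimnames.
#' @param path output TSV path.
#' @export
write_tpm <- function(mat, path) {
  d <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
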