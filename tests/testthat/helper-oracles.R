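# Brute-force oracles, independent of the package's interval and test
# machinery: per-base boolean masks for overlap accounting, enumeration
# for the exact tests. Only usable on small instances.

oracle_masks <- function(iv, chrom_lengths) {
  masks <- lapply(chrom_lengths, function(len) logical(len))
  for (i in seq_len(nrow(iv))) {
    ch <- iv$chrom[i]
    masks[[ch]][(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  masks
}

oracle_overlap_bp <- function(a, b, chrom_lengths) {
  ma <- oracle_masks(a, chrom_lengths)
  mb <- oracle_masks(b, chrom_lengths)
  sum(vapply(names(chrom_lengths), function(ch)
    sum(ma[[ch]] & mb[[ch]]), numeric(1)))
}

oracle_merge <- function(iv, chrom_lengths) {
  m <- oracle_masks(iv, chrom_lengths)
  out <- list()
  for (ch in names(chrom_lengths)) {
    r <- rle(m[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# per-base category labeling under a priority order; residual other_DNA
oracle_partition_sizes <- function(feature_sets, priority, chrom_lengths) {
  label <- lapply(chrom_lengths, function(len)
    rep("other_DNA", len))
  for (cat in rev(priority)) {   # apply lowest priority first, overwrite up
    iv <- feature_sets[[cat]]
    if (is.null(iv)) next
    for (i in seq_len(nrow(iv)))
      label[[iv$chrom[i]]][(iv$start[i] + 1):iv$end[i]] <- cat
  }
  all_lab <- unlist(label, use.names = FALSE)
  counts <- table(factor(all_lab, levels = c(priority, "other_DNA")))
  stats::setNames(as.numeric(counts), names(counts))
}

# two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins (same relative tolerance convention as customary)
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_
  xs <- max(0, k - r2):min(r1, k)
  probs <- stats::dhyper(xs, r1, r2, k)
  obs <- stats::dhyper(a, r1, r2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-sided exact Wilcoxon p by full enumeration of group assignments,
# via the rank-sum statistic W (midranks under ties)
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(na)])
  mu <- na * sum(r) / length(r)
  splits <- utils::combn(length(pooled), na)
  Ws <- apply(splits, 2, function(i) sum(r[i]))
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

oracle_tau <- function(x) {
  xn <- x / max(x)
  sum(1 - xn) / (length(x) - 1)
}

random_intervals <- function(n, chrom_lengths) {
  chs <- sample(names(chrom_lengths), n, replace = TRUE)
  s <- vapply(chs, function(ch)
    sample.int(chrom_lengths[[ch]] - 1, 1) - 1, numeric(1))
  len <- vapply(chs, function(ch) sample.int(50, 1), numeric(1))
  e <- pmin(s + len, chrom_lengths[chs])
  gintervals(chs, s, e)
}
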