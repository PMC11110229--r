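mk_gene <- function(id, start, end, strand = "+", exons = NULL,
                    chrom = "chr1", cds = c(NA, NA)) {
  list(gene_id = id, chrom = chrom, strand = strand, start = start,
       end = end,
       exons = if (is.null(exons)) gintervals()
               else gintervals(chrom, exons[, 1], exons[, 2]),
       cds_start = cds[1], cds_end = cds[2])
}

mk_nupts <- function(starts, ends, labels, chrom = "chr1") {
  if (length(starts) == 0L)
    return(data.frame(nupt_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      plastid_chrom = character(), p_start = numeric(),
                      p_end = numeric(), strand = character(),
                      pident = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  data.frame(nupt_id = sprintf("N%02d", seq_along(starts)), chrom = chrom,
             start = starts, end = ends, plastid_chrom = "plastid",
             p_start = 0, p_end = ends - starts, strand = "+",
             pident = 95, label = labels, stringsAsFactors = FALSE)
}

test_that("gene regions follow strand-aware flank arithmetic", {
  g <- mk_gene("g", 1000, 2000, "+",
               exons = cbind(c(1000, 1600), c(1400, 2000)))
  r <- gene_regions(g, 1000, 10000)
  expect_equal(c(r$promoter$start, r$promoter$end), c(0, 1000))
  expect_equal(c(r$terminator$start, r$terminator$end), c(2000, 3000))
  expect_equal(c(r$intron$start, r$intron$end), c(1400, 1600))
  expect_false(r$truncated)

  # minus strand mirrors promoter and terminator
  gm <- mk_gene("g", 1000, 2000, "-")
  rm <- gene_regions(gm, 1000, 10000)
  expect_equal(c(rm$promoter$start, rm$promoter$end), c(2000, 3000))
  expect_equal(c(rm$terminator$start, rm$terminator$end), c(0, 1000))

  # truncation at the chromosome edge
  gt <- mk_gene("g", 200, 900, "+")
  rt <- gene_regions(gt, 1000, 5000)
  expect_equal(c(rt$promoter$start, rt$promoter$end), c(0, 200))
  expect_true(rt$truncated)

  expect_error(gene_regions(mk_gene("g", 10, 20, "*"), 1000, 100),
               "unstranded")
})

test_that("CDS coordinates anchor the flanks when present", {
  g <- mk_gene("g", 1000, 2000, "+", cds = c(1200, 1800))
  r <- gene_regions(g, 500, 10000)
  expect_equal(c(r$promoter$start, r$promoter$end), c(700, 1200))
  expect_equal(c(r$terminator$start, r$terminator$end), c(1800, 2300))
})

test_that("NUPT hits are classified per region with any-bp overlap", {
  cl <- c(chr1 = 20000)
  g <- mk_gene("g1", 5000, 8000, "+",
               exons = cbind(c(5000, 6500), c(6000, 8000)))
  # one NUPT spanning the exon/intron boundary, one inside the promoter
  nupts <- mk_nupts(c(5900, 4200), c(6200, 4300), c("I", "II"))
  rec <- classify_gene_hits(nupts, list(g1 = g), 1000, cl)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$regions_hit, "promoter,exon,intron")
  expect_equal(rec$n_nupts, 2)
  expect_equal(rec$class_pattern, "mixed")
  expect_false(rec$fully_covered)
})

test_that("full coverage of a single-exon gene sets both flags", {
  cl <- c(chr1 = 20000)
  g <- mk_gene("g1", 5000, 5400, "+", exons = cbind(5000, 5400))
  nupts <- mk_nupts(4900, 5600, "II")
  rec <- classify_gene_hits(nupts, list(g1 = g), 1000, cl)
  expect_true(rec$fully_covered)
  expect_true(rec$single_exon_all_plastid)
  expect_true(grepl("exon", rec$regions_hit))
})

test_that("impact summary partitions affected genes by class exclusivity", {
  cl <- c(chr1 = 1e5)
  genes <- list(
    g1 = mk_gene("g1", 10000, 11000, "+"),
    g2 = mk_gene("g2", 20000, 21000, "+"),
    g3 = mk_gene("g3", 30000, 31000, "+"),
    g4 = mk_gene("g4", 40000, 41000, "+"),
    g5 = mk_gene("g5", 90000, 91000, "+")   # not hit
  )
  nupts <- mk_nupts(
    c(10100, 20100, 30100, 40100, 40500),
    c(10200, 20200, 30200, 40200, 40600),
    c("I", "II", "unclassified", "I", "II"))
  rec <- classify_gene_hits(nupts, genes, 1000, cl)
  s <- impact_summary(rec)
  expect_equal(s$n_affected, 4)
  expect_equal(unname(s$by_class_pattern),
               c(1, 1, 1, 1))  # I-only, II-only, unclassified-only, mixed
  expect_equal(sum(s$by_class_pattern), s$n_affected)
  expect_equal(s$max_nupts_per_gene, 2)

  # order invariance of inputs
  rec2 <- classify_gene_hits(nupts[sample(5), ], rev(genes), 1000, cl)
  expect_equal(sort(rec2$gene_id), sort(rec$gene_id))
  s2 <- impact_summary(rec2)
  expect_equal(s2$by_region, s$by_region)
  expect_equal(s2$by_class_pattern, s$by_class_pattern)
})

test_that("a gene hit in promoter and terminator counts once in each tally", {
  cl <- c(chr1 = 1e5)
  g <- mk_gene("g1", 10000, 12000, "+")
  nupts <- mk_nupts(c(9500, 12100), c(9700, 12300), c("I", "I"))
  rec <- classify_gene_hits(nupts, list(g1 = g), 1000, cl)
  s <- impact_summary(rec)
  expect_equal(s$n_affected, 1)
  expect_equal(unname(s$by_region["promoter"]), 1)
  expect_equal(unname(s$by_region["terminator"]), 1)
})

test_that("full coverage agrees with a per-base oracle on toy genes", {
  set.seed(41)
  cl <- c(chr1 = 2000)
  for (rep in 1:20) {
    gs <- sample(500, 1); ge <- gs + sample(300, 1) + 50
    g <- mk_gene("g", gs, ge, "+")
    n <- sample(3, 1)
    st <- sample(1500, n); en <- st + sample(200, n) + 10
    nupts <- mk_nupts(st, pmin(en, 2000), rep("II", n))
    rec <- classify_gene_hits(nupts, list(g = g), 100, cl)
    mask <- logical(2000)
    for (i in seq_len(n)) mask[(st[i] + 1):min(en[i], 2000)] <- TRUE
    oracle_full <- all(mask[(gs + 1):ge])
    if (nrow(rec) == 0) expect_false(oracle_full)
    else expect_equal(rec$fully_covered, oracle_full)
  }
})

test_that("no NUPTs gives an empty summary", {
  s <- impact_summary(classify_gene_hits(
    mk_nupts(numeric(0), numeric(0), character(0)),
    list(g = mk_gene("g", 100, 200, "+")), 50, c(chr1 = 1000)))
  expect_equal(s$n_affected, 0)
})
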