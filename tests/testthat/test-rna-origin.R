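mk_hits <- function(q, s, bits, eval = 1e-20) {
  data.frame(qseqid = q, sseqid = s, pident = 95, length = 70,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 70,
             sstart = 1, send = 70, evalue = eval, bitscore = bits,
             stringsAsFactors = FALSE)
}

cmap <- c(s_mito = "mitochondrial", s_plastid = "plastid",
          a_pl = "plastid", b_mt = "mitochondrial")

test_that("best hit wins by bit score with stated tie-breaks", {
  h <- mk_hits(c("q1", "q1"), c("s_mito", "s_plastid"), c(90, 80))
  calls <- classify_origin(h, cmap)
  expect_equal(calls$compartment, "mitochondrial")

  # tie on bits and e-value: lexicographically smallest subject id
  h2 <- mk_hits(c("q1", "q1"), c("b_mt", "a_pl"), c(90, 90))
  expect_equal(classify_origin(h2, cmap)$compartment, "plastid")

  # order invariance
  expect_equal(classify_origin(h2[2:1, ], cmap)$compartment, "plastid")
})

test_that("queries without passing hits are unclassified", {
  h <- mk_hits("q1", "s_mito", 90, eval = 0.5)  # fails the 1e-2 cutoff
  calls <- classify_origin(h, cmap, query_ids = c("q1", "q2"))
  expect_equal(calls$compartment, c("unclassified", "unclassified"))
  expect_error(
    classify_origin(mk_hits("q1", "unknown_subject", 90), cmap),
    "missing from compartment map")
})

test_that("donor transfer maps linearly, strand-aware", {
  plastid_feats <- list(tRNA_plastid = {
    iv <- gintervals("plastid", 520, 560)
    iv$id <- "pl_trna1"
    iv
  })
  # forward NUPT: nuclear (100,200) <- plastid (500,600)
  nupt <- data.frame(nupt_id = "N1", chrom = "chr1", start = 100, end = 200,
                     plastid_chrom = "plastid", p_start = 500, p_end = 600,
                     strand = "+", pident = 95, stringsAsFactors = FALSE)
  gene <- list(gene_id = "r1", category = "tRNA_plastid", chrom = "chr1",
               start = 120, end = 160)
  d <- map_donor(gene, nupt, plastid_feats)
  expect_equal(c(d$donor_start, d$donor_end), c(520, 560))
  expect_true(d$same_category)
  expect_equal(d$donor_genes, "pl_trna1")

  # reverse NUPT: nuclear (10,20) within query (0,100), subject span
  # (100,200) reversed -> plastid (180,190)
  nupt_r <- nupt
  nupt_r$start <- 0; nupt_r$end <- 100
  nupt_r$p_start <- 100; nupt_r$p_end <- 200; nupt_r$strand <- "-"
  gene_r <- list(gene_id = "r2", category = "tRNA_plastid", chrom = "chr1",
                 start = 10, end = 20)
  d2 <- map_donor(gene_r, nupt_r, plastid_feats)
  expect_equal(c(d2$donor_start, d2$donor_end), c(180, 190))
  # transferred interval misses the plastid gene
  expect_equal(d2$donor_genes, "")
  expect_false(d2$same_category)

  expect_error(map_donor(list(gene_id = "x", category = "tRNA_plastid",
                              chrom = "chr1", start = 300, end = 400),
                         nupt, plastid_feats), "does not overlap")
})

test_that("donor mapping round-trips through a planted NUPT", {
  set.seed(51)
  for (strand in c("+", "-")) {
    for (rep in 1:10) {
      ns <- sample(1000, 1); len <- sample(100:400, 1)
      ps <- sample(1000, 1)
      nupt <- data.frame(nupt_id = "N", chrom = "chr1", start = ns,
                         end = ns + len, plastid_chrom = "plastid",
                         p_start = ps, p_end = ps + len, strand = strand,
                         pident = 95, stringsAsFactors = FALSE)
      gs <- ns + sample(len - 20, 1); ge <- min(gs + sample(20, 1) + 5,
                                                ns + len)
      gene <- list(gene_id = "g", category = "other_RNA", chrom = "chr1",
                   start = gs, end = ge)
      d <- map_donor(gene, nupt, list())
      # map the donor interval back through the inverse alignment
      back_nupt <- data.frame(nupt_id = "N", chrom = "plastid",
                              start = ps, end = ps + len,
                              plastid_chrom = "chr1", p_start = ns,
                              p_end = ns + len, strand = strand,
                              pident = 95, stringsAsFactors = FALSE)
      gene2 <- list(gene_id = "g", category = "other_RNA",
                    chrom = "plastid", start = d$donor_start,
                    end = d$donor_end)
      d2 <- map_donor(gene2, back_nupt, list())
      expect_equal(c(d2$donor_start, d2$donor_end), c(gs, ge))
    }
  }
})

test_that("census counts compartments and the NUPT-resident fraction", {
  calls <- data.frame(
    gene_id = sprintf("t%d", 1:10),
    compartment = c(rep("nuclear", 5), rep("plastid", 3),
                    rep("mitochondrial", 2)),
    in_nupt = c(TRUE, rep(FALSE, 4), TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  cen <- trna_census(calls)
  expect_equal(cen$total, 10)
  expect_equal(unname(cen$counts["plastid"]), 3)
  expect_equal(cen$plastid_origin_n, 5)
  expect_equal(cen$plastid_origin_pct, 50)
  expect_error(trna_census(calls[0, ]), "no tRNA")

  # single-compartment edge: fraction forced to 0 or 100
  one <- data.frame(gene_id = "t", compartment = "plastid", in_nupt = TRUE)
  expect_equal(trna_census(one)$plastid_origin_pct, 100)
})
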