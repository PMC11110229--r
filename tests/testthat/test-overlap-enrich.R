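test_that("partition assigns every base to exactly one category", {
  cl <- c(chr1 = 1000)
  fs <- list(A = gintervals("chr1", 0, 300))
  p <- partition_genome(fs, c("A"), cl)
  expect_equal(unname(p$sizes["A"]), 300)
  expect_equal(unname(p$sizes["other_DNA"]), 700)

  # overlapping categories resolved by priority
  fs2 <- list(A = gintervals("chr1", 100, 200),
              B = gintervals("chr1", 100, 250))
  p2 <- partition_genome(fs2, c("A", "B"), cl)
  expect_equal(unname(p2$sizes["A"]), 100)
  expect_equal(unname(p2$sizes["B"]), 50)
  expect_equal(sum(p2$sizes), 1000)

  # empty feature sets: everything other_DNA
  p3 <- partition_genome(list(), character(0), cl)
  expect_equal(unname(p3$sizes["other_DNA"]), 1000)

  expect_error(partition_genome(list(A = gintervals("chr1", 900, 1100)),
                                c("A"), cl), "beyond chromosome end")
})

test_that("partition sizes match the per-base labeling oracle", {
  set.seed(31)
  cl <- c(chrA = 600, chrB = 400)
  for (rep in 1:20) {
    fs <- list(A = random_intervals(8, cl), B = random_intervals(8, cl),
               C = random_intervals(8, cl))
    pr <- c("A", "B", "C")
    p <- partition_genome(fs, pr, cl)
    o <- oracle_partition_sizes(fs, pr, cl)
    expect_equal(p$sizes[names(o)], o)
    expect_equal(sum(p$sizes), sum(cl))
    # exclusive intervals are pairwise disjoint
    cats <- names(p$intervals)
    for (i in seq_along(cats)[-1])
      expect_equal(intersect_bp(p$intervals[[cats[i]]],
                                p$intervals[[cats[1]]]), 0)
  }
})

test_that("expected overlap is bp-proportional and sums to T", {
  cl <- c(chr1 = 1000)
  p <- partition_genome(list(A = gintervals("chr1", 0, 300)), c("A"), cl)
  e <- expected_overlap(100, p)
  expect_equal(unname(e["A"]), 30)
  expect_equal(sum(e), 100)

  # whole genome in one category
  pg <- partition_genome(list(A = gintervals("chr1", 0, 1000)), c("A"), cl)
  expect_equal(unname(expected_overlap(55, pg)["A"]), 55)

  # three categories tiling the genome
  fs <- list(A = gintervals("chr1", 0, 200), B = gintervals("chr1", 200, 700),
             C = gintervals("chr1", 700, 1000))
  p3 <- partition_genome(fs, c("A", "B", "C"), cl)
  expect_equal(sum(expected_overlap(123, p3)), 123)
})

test_that("Yates chi-squared follows the clamped two-cell formula", {
  r <- yates_chisq(30, 20, 100)
  expect_equal(r$chi2, 5.640625)
  expect_equal(r$p, pchisq(5.640625, 1, lower.tail = FALSE))
  expect_lt(abs(r$p - 0.0175), 5e-4)

  expect_equal(yates_chisq(20, 20, 100)$chi2, 0)
  expect_equal(yates_chisq(20, 20, 100)$p, 1)
  # deviations under half a base clamp to zero
  expect_equal(yates_chisq(20.3, 20, 100)$chi2, 0)
  expect_error(yates_chisq(5, 0, 100), "undefined")
  expect_error(yates_chisq(5, 100, 100), "undefined")
})

test_that("enrichment scan recovers planted placement bias", {
  set.seed(32)
  cl <- c(chr1 = 50000)
  fs <- list(X = gintervals("chr1", seq(0, 45000, by = 5000),
                            seq(0, 45000, by = 5000) + 1000),
             Y = gintervals("chr1", seq(2000, 47000, by = 5000),
                            seq(2000, 47000, by = 5000) + 1000))
  p <- partition_genome(fs, c("X", "Y"), cl)
  # place 400 NUPTs of 50 bp with 5x density of start points inside X
  w <- ifelse(seq_len(50000) %in% unlist(Map(seq, fs$X$start + 1, fs$X$end)),
              5, 1)
  starts <- sample(50000 - 50, 400, prob = w[1:(50000 - 50)]) - 1
  nupts <- gintervals("chr1", starts, starts + 50)
  scan <- enrichment_scan(list(all = nupts), p)
  expect_equal(scan$direction[scan$category == "X"], "enriched")
  expect_true(all(scan$direction[scan$category == "Y"] %in%
                    c("ns", "depleted")))
  # conservation: observed and expected both sum to T
  T <- total_bp(nupts)
  expect_equal(sum(scan$observed_bp), T)
  expect_equal(sum(scan$expected_bp), T)
})

test_that("saturated and empty NUPT sets behave as forced", {
  cl <- c(chr1 = 1000)
  fs <- list(A = gintervals("chr1", 0, 200), B = gintervals("chr1", 200, 700))
  p <- partition_genome(fs, c("A", "B"), cl)
  # NUPT set equal to the whole genome: O = E everywhere, all ns
  scan <- enrichment_scan(list(all = gintervals("chr1", 0, 1000)), p)
  expect_equal(scan$observed_bp, unname(scan$expected_bp))
  expect_true(all(scan$direction == "ns"))
  expect_true(all(scan$log10_ratio == 0))
  expect_error(enrichment_scan(list(all = gintervals()), p), "empty")
})

test_that("observed bp equals the brute-force oracle on small genomes", {
  set.seed(33)
  cl <- c(chrA = 900, chrB = 600)
  for (rep in 1:10) {
    fs <- list(A = random_intervals(6, cl), B = random_intervals(6, cl))
    p <- partition_genome(fs, c("A", "B"), cl)
    nupts <- merge_intervals(random_intervals(15, cl))
    scan <- enrichment_scan(list(all = nupts), p)
    for (cat in names(p$intervals)) {
      o <- oracle_overlap_bp(nupts, p$intervals[[cat]], cl)
      expect_equal(scan$observed_bp[scan$category == cat], o)
    }
  }
})

test_that("non-exclusive accounting counts shared bases in every category", {
  fs <- list(A = gintervals("chr1", 0, 100), B = gintervals("chr1", 50, 150))
  nupts <- gintervals("chr1", 40, 120)
  tab <- overlap_by_category(nupts, fs)
  expect_equal(tab$observed_bp[tab$category == "A"], 60)
  expect_equal(tab$observed_bp[tab$category == "B"], 70)
})
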