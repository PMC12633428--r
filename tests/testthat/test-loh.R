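test_that("LOH tract calling is exact at the 1-kb boundary", {
  ## no het sites: one whole-chromosome tract
  t0 <- callLohTracts(integer(0), 50000, chrom = "c")
  expect_equal(nrow(t0), 1)
  expect_equal(t0$class, "whole_chromosome")
  expect_equal(c(t0$start, t0$end), c(0, 50000))
  ## het sites 999 bp apart leave a 998-bp interior: no tract;
  ## 1,001 bp apart leave exactly 1,000 bp: one tract
  near <- callLohTracts(c(20000, 20999), 22000, chrom = "c",
                        minCallableFraction = 0)
  expect_false(any(near$class == "interstitial"))
  far <- callLohTracts(c(10000, 11001), 22000, chrom = "c",
                       minCallableFraction = 0)
  it <- far[far$class == "interstitial", ]
  expect_equal(nrow(it), 1)
  expect_equal(it$length, 1000)
  expect_equal(c(it$start, it$end), c(10000, 11000))
  expect_error(callLohTracts(c(10), 5, chrom = "c"), "outside")
  expect_error(callLohTracts(c(10), 100, minLen = 0, chrom = "c"), "minLen")
})

test_that("tract classification depends only on which ends are touched", {
  L <- 1e6
  expect_equal(classifyTract(0, L, L), "whole_chromosome")
  expect_equal(classifyTract(0, 50000, L), "terminal_left")
  expect_equal(classifyTract(L - 50000, L, L), "terminal_right")
  expect_equal(classifyTract(100, L - 100, L), "interstitial")
  expect_error(classifyTract(-1, 10, L))
})

test_that("callability guard suppresses tracts in unalignable regions", {
  ## a 5-kb het-free gap that is mostly unalignable must not be called
  mask <- data.frame(start = c(0, 14500), end = c(10500, 30000))
  tr <- callLohTracts(c(10000, 15001), 30000, mask = mask, chrom = "c")
  expect_false(any(tr$start == 10000 & tr$class == "interstitial"))
  ## with the guard disabled it is called
  tr0 <- callLohTracts(c(10000, 15001), 30000, mask = mask,
                       minCallableFraction = 0, chrom = "c")
  expect_true(any(tr0$start == 10000))
})

test_that("LOH summaries reproduce the worked arithmetic", {
  tr <- data.frame(chrom = paste0("c", 1:7), start = 0, end = 111000,
                   class = "terminal_left")
  s <- summarizeLoh(tr, genomeLength = 22.2e6)
  expect_equal(round(100 * s$genome_fraction_homozygous, 1), 3.5)
  expect_equal(s$per_class$n, 7)
  expect_equal(s$per_class$mean_bp, 111000)
  ## empty set
  expect_equal(summarizeLoh(tr[0, ], 1e6)$genome_fraction_homozygous, 0)
  ## mean/max over {12, 271} kb
  tr2 <- data.frame(chrom = c("a", "b"), start = 0,
                    end = c(12000, 271000), class = "terminal_left")
  s2 <- summarizeLoh(tr2, 22e6)
  expect_equal(s2$per_class$mean_bp, 141500)
  expect_equal(s2$per_class$max_bp, 271000)
  ## overlapping tracts are an error
  bad <- data.frame(chrom = "a", start = c(0, 500), end = c(1000, 1500),
                    class = "interstitial")
  expect_error(summarizeLoh(bad, 1e6), "overlap")
})

test_that("strain comparison partitions tracts by reciprocal overlap", {
  a <- data.frame(chrom = "c", start = c(0, 5000), end = c(1000, 6000))
  ## identical sets: all shared
  cmpAA <- compareStrainTracts(a, a)
  expect_equal(nrow(cmpAA$shared), 2)
  expect_length(cmpAA$unique_a, 0)
  ## disjoint sets: all unique
  b <- data.frame(chrom = "c", start = c(10000), end = c(11000))
  cmpAB <- compareStrainTracts(a, b)
  expect_equal(nrow(cmpAB$shared), 0)
  expect_length(cmpAB$unique_a, 2)
  expect_length(cmpAB$unique_b, 1)
  ## 40% reciprocal overlap: unique at the 0.5 default, shared at 0.3
  x <- data.frame(chrom = "c", start = 0, end = 1000)
  y <- data.frame(chrom = "c", start = 600, end = 1600)
  expect_equal(nrow(compareStrainTracts(x, y)$shared), 0)
  expect_equal(nrow(compareStrainTracts(x, y, reciprocalOverlap = 0.3)$shared), 1)
})

test_that("tract calls equal a brute-force scan and contain no het site", {
  set.seed(31)
  L <- 200000
  for (rep in 1:3) {
    het <- sort(sample.int(L, rpois(1, L * 0.003)))
    tr <- callLohTracts(het, L, minCallableFraction = 0, chrom = "c")
    oracle <- oracleLohScan(het, L, 1000)
    expect_equal(tr$start, oracle$start)
    expect_equal(tr$end, oracle$end)
    ## no heterozygous input site strictly inside any emitted tract
    for (i in seq_len(nrow(tr)))
      expect_equal(sum(het > tr$start[i] & het <= tr$end[i]), 0)
  }
})
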