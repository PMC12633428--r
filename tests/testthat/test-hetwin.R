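test_that("windowed heterozygosity computes per-site fractions and exclusions", {
  cl <- c(chr = 20000L)
  ## fully aligned window with no variants
  v0 <- data.frame(chrom = character(0), pos = integer(0),
                   zygosity = character(0), quality = integer(0))
  w0 <- windowedHeterozygosity(v0, cl, minAligned = 0)
  expect_equal(w0$value, c(0, 0))
  ## 271 qualifying sites over a fully aligned 10-kb window
  v <- data.frame(chrom = "chr", pos = sample.int(10000, 271),
                  zygosity = "heterozygous", quality = 60)
  w <- windowedHeterozygosity(v, cl)
  expect_equal(w$value[1], 0.0271)
  ## a window with 1,999 aligned sites is excluded; 2,000 is not
  mask <- data.frame(chrom = "chr", start = c(0, 10000), end = c(1999, 12000))
  wm <- windowedHeterozygosity(v, cl, mask = mask)
  expect_equal(wm$status, c("excluded", "ok"))
  expect_true(is.na(wm$value[1]))
  ## quality filter
  vq <- v; vq$quality <- rep(c(60, 59), length.out = 271)
  wq <- windowedHeterozygosity(vq, cl)
  expect_equal(wq$n_variant[1], sum(vq$quality >= 60))
  expect_warning(
    windowedHeterozygosity(v[, c("chrom", "pos", "zygosity")], cl),
    "quality")
})

test_that("divergence applies the half-weight rule for heterozygous sites", {
  cl <- c(chr = 1000L)
  mask <- data.frame(chrom = "chr", start = 0, end = 1000)
  v <- data.frame(chrom = "chr", pos = c(1:10, 101:110),
                  zygosity = rep(c("homozygous_diff", "heterozygous"), each = 10),
                  quality = 60)
  w <- windowedDivergence(v, cl, mask = mask, windowSize = 1000,
                          minAligned = 100)
  expect_equal(w$value, (10 + 0.5 * 10) / 1000)  # 0.015
  ## all heterozygous: k sites over n aligned gives k/(2n)
  vh <- data.frame(chrom = "chr", pos = 1:40, zygosity = "heterozygous",
                   quality = 60)
  wh <- windowedDivergence(vh, cl, windowSize = 1000, minAligned = 100)
  expect_equal(wh$value, 40 / (2 * 1000))
})

test_that("window tiling and conservation invariants hold", {
  set.seed(21)
  cl <- c(a = 95000L, b = 40000L)
  v <- data.frame(chrom = sample(c("a", "b"), 800, TRUE),
                  pos = NA, zygosity = "heterozygous", quality = 60)
  v$pos <- ifelse(v$chrom == "a", sample.int(95000, 800, TRUE),
                  sample.int(40000, 800, TRUE))
  v <- v[!duplicated(v[c("chrom", "pos")]), ]
  w <- windowedHeterozygosity(v, cl, minAligned = 0)
  ## tiling covers each chromosome exactly once, no window crosses an end
  for (ch in names(cl)) {
    ws <- w[w$chrom == ch, ]
    expect_equal(ws$start, c(0, head(ws$end, -1)))
    expect_equal(tail(ws$end, 1), unname(cl[ch]))
  }
  ## conservation: window counts sum to the number of qualifying variants
  expect_equal(sum(w$n_variant), nrow(v))
  ## per-window counts equal a position-by-position scan
  for (ch in names(cl)) {
    ws <- w[w$chrom == ch, ]
    vp <- v$pos[v$chrom == ch]
    expect_equal(ws$n_variant,
                 oracleWindowCounts(vp, rep(1, length(vp)), cl[[ch]], 10000))
  }
})

test_that("degeneracy classification matches the brute-force substitution table", {
  expect_equal(classifyDegeneracy("ATG")$class, c(0, 0, 0))
  expect_equal(classifyDegeneracy("GGG")$class, c(0, 0, 4))
  expect_equal(classifyDegeneracy("TTA")$class, c(2, 0, 2))
  ## every sense codon, against an independently coded 9-substitution oracle
  for (cod in senseCodons()) {
    expect_equal(classifyDegeneracy(cod)$class, oracleDegeneracy(cod),
                 info = cod)
  }
  expect_error(classifyDegeneracy("ATGA"), "divisible")
  expect_error(classifyDegeneracy("TGAATG"), "stop")
  expect_true(all(is.na(classifyDegeneracy("ANG")$class)))
})

test_that("degeneracy maps to genome coordinates strand-aware", {
  genome <- Biostrings::DNAStringSet(c(chr = "TTCATGGGGTTAGAA"))
  ## CDS ATGGGGTTA on the plus strand at 0-based [3,12)
  plus <- degeneracyTrack(genome, data.frame(
    tx_id = "t1", chrom = "chr", start = 3, end = 12, strand = "+"))
  expect_equal(plus$pos, 4:12)
  expect_equal(plus$class, c(0, 0, 0, 0, 0, 4, 2, 0, 2))
  ## same CDS on the minus strand of the reverse complement
  rc <- Biostrings::reverseComplement(genome[[1]])
  genome2 <- Biostrings::DNAStringSet(setNames(as.character(rc), "chr"))
  minus <- degeneracyTrack(genome2, data.frame(
    tx_id = "t1", chrom = "chr", start = 3, end = 12, strand = "-"))
  expect_equal(minus$class, c(0, 0, 0, 0, 0, 4, 2, 0, 2))
  expect_equal(minus$pos, 12:4)
})

test_that("heterozygosity by site class equals direct counts", {
  deg <- data.frame(chrom = "chr", pos = 1:2000,
                    class = rep(c(0, 4), each = 1000))
  v <- data.frame(chrom = "chr", pos = c(1:8, 1001:1030),
                  zygosity = "heterozygous", quality = 60)
  h <- hetBySiteClass(v, deg)
  expect_equal(h$value[h$class == 0], 8 / 1000)
  expect_equal(h$value[h$class == 4], 30 / 1000)
  ## with no variants every non-empty class is 0
  h0 <- hetBySiteClass(v[0, ], deg)
  expect_equal(h0$value, c(0, 0))
})
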