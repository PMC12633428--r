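test_that("zero-rate simulation reproduces the ancestor and the parents", {
  cfg <- simulationConfig(c(chr01 = 5000L), divP = 0, divS = 0,
                          hetP = 0, hetS = 0, seed = 1L)
  par <- simulateParentHaplotypes(cfg)
  anc <- as.character(par$ancestor)
  for (h in c("P1", "P2", "S1", "S2"))
    expect_identical(as.character(par[[h]]), anc)
  ## no events: A == P1 and B == S1 everywhere
  cfg2 <- simulationConfig(c(chr01 = 5000L), seed = 2L)
  sim <- simulateHybridGenome(cfg2)
  expect_identical(as.character(haplotype(sim, "A")),
                   as.character(simulateParentHaplotypes(cfg2)$P1))
  expect_identical(as.character(haplotype(sim, "B")),
                   as.character(simulateParentHaplotypes(cfg2)$S1))
})

test_that("realized divergence matches the configured rate within binomial error", {
  L <- 1e6L
  cfg <- simulationConfig(c(chr01 = L), divP = 0.027, hetP = 0, hetS = 0,
                          seed = 3L)
  par <- simulateParentHaplotypes(cfg)
  mism <- nrow(diffSites(par$P1, par$ancestor)) / L
  expect_lt(abs(mism - 0.027), 3 * sqrt(0.027 * 0.973 / L))
})

test_that("a fixed seed yields byte-identical emitted files", {
  cfg <- simulationConfig(c(chr01 = 30000L),
    events = list(list(type = "crossover", chrom = "chr01", pos = 15000)),
    seed = 9L)
  d1 <- file.path(tempdir(), "simrun1"); d2 <- file.path(tempdir(), "simrun2")
  suppressMessages({
    writeSimulation(simulateHybridGenome(cfg), d1)
    writeSimulation(simulateHybridGenome(cfg), d2)
  })
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted events rewrite sequence and truth as defined", {
  L <- 200000L
  cfg <- simulationConfig(c(chr01 = L, chr02 = L),
    events = list(
      list(type = "loh_terminal", chrom = "chr01", start = 100000,
           end = 200000, donor = "B"),
      list(type = "crossover", chrom = "chr02", pos = 80000)),
    seed = 4L)
  sim <- simulateHybridGenome(cfg)
  a <- as.character(haplotype(sim, "A")); b <- as.character(haplotype(sim, "B"))
  ## terminal LOH: A and B byte-identical on the copied suffix, not before
  expect_identical(substr(a[["chr01"]], 100001, L), substr(b[["chr01"]], 100001, L))
  expect_false(substr(a[["chr01"]], 1, 100000) == substr(b[["chr01"]], 1, 100000))
  ## reciprocal crossover: truth parent labels of A and B swap at the
  ## breakpoint in opposite directions
  tr <- truthLog(sim)$ancestry
  aT <- tr[tr$haplotype == "A" & tr$chrom == "chr02", ]
  bT <- tr[tr$haplotype == "B" & tr$chrom == "chr02", ]
  expect_equal(aT$parent, c("P", "S"))
  expect_equal(bT$parent, c("S", "P"))
  expect_equal(aT$end[1], 80000)
  expect_equal(bT$end[1], 80000)
  ## conflicting overlapping events rejected
  expect_error(simulateHybridGenome(simulationConfig(c(chr01 = L),
    events = list(
      list(type = "loh_interstitial", chrom = "chr01", start = 1000,
           end = 5000, donor = "A"),
      list(type = "loh_interstitial", chrom = "chr01", start = 4000,
           end = 9000, donor = "B")))), "overlapping")
})

test_that("variant emission honours FN/FP rates binomially", {
  cfg <- simulationConfig(c(chr01 = 500000L),
    events = list(list(type = "loh_interstitial", chrom = "chr01",
                       start = 200000, end = 250000, donor = "A")),
    seed = 5L)
  sim <- simulateHybridGenome(cfg)
  v0 <- emitVariantTable(sim)
  expect_equal(nrow(v0), nrow(diffSites(sim@haplA, sim@haplB)))
  ## zero variants inside the planted 50-kb tract
  expect_equal(sum(v0$pos > 200000 & v0$pos <= 250000), 0)
  ## FN = 0.1: emitted count within 3 binomial SDs of 0.9 n
  n <- nrow(v0)
  v1 <- emitVariantTable(sim, falseNegativeRate = 0.1)
  expect_lt(abs(nrow(v1) - 0.9 * n), 3 * sqrt(n * 0.1 * 0.9))
  ## FP adds sites roughly at the requested rate
  v2 <- emitVariantTable(sim, falsePositiveRate = 1e-4)
  expect_gt(nrow(v2), n)
  expect_error(emitVariantTable(sim, falseNegativeRate = 2))
})

test_that("depth track scales with copy number and is Poisson at dispersion 0", {
  cn <- data.frame(chrom = c("c1", "c2"), start = 0,
                   end = c(100000L, 100000L), copies = c(1L, 2L))
  set.seed(6)
  d <- simulateDepthTrack(cn, c(c1 = 100000L, c2 = 100000L), depthMean = 50)
  w <- windowedCoverage(d, windowSize = 20000)
  expect_true(all(abs(w$mean_depth[w$chrom == "c1"] - 50) < 1))
  expect_true(all(abs(w$mean_depth[w$chrom == "c2"] - 100) < 2))
  ## per-base variance ~ mean on 1e5 draws
  expect_lt(abs(var(d$c1) / 50 - 1), 0.05)
  ## overdispersion increases the variance
  set.seed(7)
  dn <- simulateDepthTrack(cn[1, ], c(c1 = 100000L), depthMean = 50,
                           depthDispersion = 0.2)
  expect_gt(var(dn$c1), 2 * 50)
})

test_that("methylation emission follows the template", {
  cfg0 <- simulationConfig(c(c = 1000L), methPlateau = 0, seed = 8L)
  m0 <- emitMethylation(cfg0, nGenes = 50)
  cpg <- m0$sites[m0$sites$context == "CpG" & m0$sites$n_reads >= 5, ]
  expect_lt(mean(cpg$frac), 0.05)      # near-zero without a plateau
  expect_equal(median(cpg$frac), 0)
  cfg <- simulationConfig(c(c = 1000L), readsPerSiteMean = 50, seed = 9L)
  m <- emitMethylation(cfg, nGenes = 400)
  apt <- m$sites[m$sites$context == "ApT", ]
  tssIdx <- match(paste(apt$chrom), m$tss$chrom)
  ## pool emitted fractions of ApT sites lying exactly at offset +180
  prof <- suppressMessages(tssMetaprofile(filterModSites(apt), m$tss, "ApT"))
  at180 <- prof$median_frac[prof$offset == 180]
  expect_lt(abs(at180 - methTemplate(180, "ApT")), 0.06)
})

test_that("designed transcripts carry the planted Kozak truth", {
  cfg <- simulationConfig(c(c = 1000L), seed = 10L)
  set.seed(10)
  tx <- emitTranscripts(cfg, nTraining = 20, nExtension = 15, nNegative = 15)
  ext <- tx$kozak[tx$kozak$class == "extension", ]
  for (i in seq_len(nrow(ext))) {
    s <- ext$seq[i]; ann <- ext$cds_start[i]; u <- ext$truth_ext_start[i]
    expect_identical(substr(s, u, u + 2), "ATG")
    expect_equal((ann - u) %% 3, 0)
    ## no in-frame stop between the true start and the annotated start
    mids <- seq(u, ann - 3, by = 3)
    cods <- substring(s, mids, mids + 2)
    expect_false(any(cods[-1] %in% c("TAA", "TAG", "TGA")))
  }
  ## training transcripts have no in-frame upstream ATG
  trn <- tx$kozak[tx$kozak$class == "training", ]
  for (i in seq_len(nrow(trn))) {
    s <- trn$seq[i]; ann <- trn$cds_start[i]
    ups <- seq(ann %% 3 + ifelse(ann %% 3 == 0, 3, 0) + 1, ann - 3, by = 3)
    ups <- seq(ann - 3, 1, by = -3)
    cods <- substring(s, ups, ups + 2)
    expect_false(any(cods == "ATG"))
  }
})
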