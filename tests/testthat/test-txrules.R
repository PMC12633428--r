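test_that("gene decoupling forms connected components of CDS overlap", {
  tx <- data.frame(tx_id = c("a", "b", "c"), gene_id = "g", chrom = "chr",
                   strand = "+")
  ## CDS overlaps a-b and b-c but not a-c: one gene
  cds <- data.frame(tx_id = c("a", "b", "c"),
                    start = c(0, 400, 900), end = c(500, 1000, 1400))
  d <- decoupleGenes(tx, cds)
  expect_equal(length(unique(d$new_gene_id)), 1)
  ## disjoint CDS: two genes
  cds2 <- data.frame(tx_id = c("a", "b"), start = c(0, 1000),
                     end = c(500, 1500))
  d2 <- decoupleGenes(tx[1:2, ], cds2)
  expect_equal(length(unique(d2$new_gene_id)), 2)
  ## single isoform: one gene; partition property
  d3 <- decoupleGenes(tx[1, ], cds[1, ])
  expect_equal(nrow(d3), 1)
  expect_setequal(d$tx_id, tx$tx_id)
  ## a CDS-less isoform joins by exonic overlap
  tx4 <- data.frame(tx_id = c("a", "b", "nc"), gene_id = "g", chrom = "chr",
                    strand = "+")
  cds4 <- data.frame(tx_id = c("a", "b"), start = c(0, 2000),
                     end = c(500, 2500))
  ex4 <- data.frame(tx_id = c("a", "b", "nc"), start = c(0, 2000, 1900),
                    end = c(600, 2600, 2300))
  d4 <- suppressMessages(decoupleGenes(tx4, cds4, ex4))
  expect_equal(d4$new_gene_id[d4$tx_id == "nc"],
               d4$new_gene_id[d4$tx_id == "b"])
})

test_that("isoform filtering applies both thresholds against the pre-filter total", {
  iso <- function(reads) data.frame(gene_id = "g",
    tx_id = sprintf("t%d", seq_along(reads)), read_count = reads)
  expect_equal(filterIsoforms(iso(c(100, 4)))$retained, c(TRUE, FALSE))
  ## 5 / 105 = 4.76% < 5%: removed despite >= 5 reads
  expect_equal(filterIsoforms(iso(c(100, 5)))$retained, c(TRUE, FALSE))
  ## 5 / 100 = 5%: retained
  expect_equal(filterIsoforms(iso(c(95, 5)))$retained, c(TRUE, TRUE))
  ## rescue of the most abundant isoform
  expect_message(f <- filterIsoforms(iso(c(3, 2))), "rescued")
  expect_equal(f$retained, c(TRUE, FALSE))
  expect_error(filterIsoforms(iso(c(0, 0))), "zero")
})

test_that("primary-isoform cascade fires the documented branches", {
  sel <- function(cds, reads) {
    selectPrimaryIsoform(data.frame(
      tx_id = sprintf("t%d", seq_along(cds)), read_count = reads,
      cds_len = cds))
  }
  expect_equal(sel(c(300, 200), c(50, 10)), list(tx_id = "t1", rule = 1L))
  expect_equal(sel(c(300, 250), c(30, 50)), list(tx_id = "t1", rule = 2L))
  expect_equal(sel(c(300, 280), c(10, 100)), list(tx_id = "t2", rule = 3L))
  expect_equal(sel(c(300, 200), c(20, 50)), list(tx_id = "t1", rule = 4L))
  ## equal CDS lengths: most abundant wins under rule 1
  expect_equal(sel(c(300, 300), c(10, 40)), list(tx_id = "t2", rule = 1L))
  expect_error(selectPrimaryIsoform(data.frame(tx_id = character(0),
    read_count = numeric(0), cds_len = numeric(0))), "empty")
})

test_that("cascade equals an independent brute-force over a small grid", {
  vals <- expand.grid(c1 = c(100, 300), c2 = c(200, 400),
                      r1 = c(1, 10, 50, 100), r2 = c(1, 10, 50, 100))
  for (i in seq_len(nrow(vals))) {
    df <- data.frame(tx_id = c("t1", "t2"),
                     read_count = c(vals$r1[i], vals$r2[i]),
                     cds_len = c(vals$c1[i], vals$c2[i]))
    got <- selectPrimaryIsoform(df)
    want <- oraclePrimary(df$tx_id, df$read_count, df$cds_len)
    expect_equal(got$tx_id, want$id, info = paste(unlist(vals[i, ]),
                                                  collapse = ","))
    expect_equal(got$rule, want$rule)
  }
})

test_that("Kozak model arithmetic matches hand calculation", {
  ## 4 training contexts, all A at offset -3, uniform elsewhere is not
  ## needed: check the pseudocount log-odds at that cell directly
  seqs <- vapply(1:4, function(i)
    paste0("CCCCCCACC", "ATG", "GGG", strrep("C", 30)), character(1))
  mod <- buildKozakModel(seqs, rep(10L, 4))
  off3 <- which(mod@window == -3)
  expect_equal(unname(mod@logOdds["A", off3]),
               log2((4 + 1) / (4 + 4) / 0.25))
  ## uniform counts + uniform background gives score 0 for any context
  uni <- new("KozakModel", window = c(-1L, 3L),
             logOdds = matrix(0, 4, 2, dimnames = list(c("A","C","G","T"), NULL)),
             background = c(A = .25, C = .25, G = .25, T = .25),
             trainingScores = c(1, 2, 3, 4), p25 = 1.75)
  expect_equal(scoreKozak(uni, "GT"), 0)
  ## p25 of {1,2,3,4} with linear interpolation
  expect_equal(uni@p25, unname(quantile(c(1, 2, 3, 4), 0.25)))
  expect_equal(uni@p25, 1.75)
})

test_that("ORF extension follows the p25-or-better rule and is idempotent", {
  set.seed(71)
  cfg <- simulationConfig(c(c = 1000L), seed = 71L)
  tx <- emitTranscripts(cfg, nTraining = 40, nExtension = 12, nNegative = 12)
  trn <- tx$kozak[tx$kozak$class == "training", ]
  mod <- buildKozakModel(trn$seq, trn$cds_start)
  ## no upstream in-frame ATG: unchanged
  r0 <- extendOrf(trn$seq[1], trn$cds_start[1], mod)
  expect_false(r0$extended)
  ext <- tx$kozak[tx$kozak$class == "extension", ]
  for (i in seq_len(nrow(ext))) {
    r <- extendOrf(ext$seq[i], ext$cds_start[i], mod)
    expect_true(r$extended)
    expect_equal(r$cds_start, ext$truth_ext_start[i])
    ## extension preserves frame and never shortens
    expect_equal((ext$cds_start[i] - r$cds_start) %% 3, 0)
    expect_lte(r$cds_start, ext$cds_start[i])
    ## idempotent: re-running extends nothing further
    r2 <- extendOrf(ext$seq[i], r$cds_start, mod)
    expect_false(r2$extended)
  }
  ## a candidate beyond an in-frame stop is ineligible
  s <- paste0("TAA", "GCCGCCACC", "ATG", "GCG", "TAG", "GCCGCCACC", "ATG",
              "GCG", strrep("GCA", 20), "TGA")
  rStop <- extendOrf(s, 31, mod)
  ## the ATG at position 13 is upstream but blocked by the TAG stop
  expect_equal(nrow(rStop$candidates), 0)
  expect_false(rStop$extended)
})

test_that("antisense lncRNA calls respect the 30% boundary and promoter classes", {
  mrna <- data.frame(tx_id = "m1", gene_id = "gm", chrom = "c", strand = "+")
  mex <- data.frame(tx_id = "m1", start = 0, end = 1000)
  lnc <- data.frame(tx_id = "l1", gene_id = "gl", chrom = "c", strand = "-")
  ## zero overlap: no call
  lex0 <- data.frame(tx_id = "l1", start = 5000, end = 6000)
  expect_equal(nrow(classifyAntisense(mrna, mex, lnc, lex0)), 0)
  ## 29% vs 30% of the mRNA transcript length
  lex29 <- data.frame(tx_id = "l1", start = 710, end = 1500)
  expect_equal(nrow(classifyAntisense(mrna, mex, lnc, lex29)), 0)
  lex30 <- data.frame(tx_id = "l1", start = 700, end = 1500)
  call30 <- classifyAntisense(mrna, mex, lnc, lex30)
  expect_equal(nrow(call30), 1)
  expect_equal(call30$overlap_fraction, 0.3)
  ## minus-strand lncRNA TSS (rightmost exon end) inside the gene body,
  ## within 300 bp of the sense TSS: bidirectional_internal
  lexBi <- data.frame(tx_id = "l1", start = -400, end = 150)
  callBi <- classifyAntisense(mrna, mex, lnc, lexBi, minOverlap = 0.1)
  expect_equal(callBi$promoter_class, "bidirectional_internal")
  ## internal but far from any sense TSS: unidirectional_internal
  lexUni <- data.frame(tx_id = "l1", start = 300, end = 900)
  callUni <- classifyAntisense(mrna, mex, lnc, lexUni, minOverlap = 0.1)
  expect_equal(callUni$promoter_class, "unidirectional_internal")
  ## TSS outside the body: adjacent
  lexAdj <- data.frame(tx_id = "l1", start = 600, end = 1200)
  callAdj <- classifyAntisense(mrna, mex, lnc, lexAdj, minOverlap = 0.1)
  expect_equal(callAdj$promoter_class, "adjacent")
  expect_error(classifyAntisense(transform(mrna, strand = NA), mex, lnc,
                                 lex30), "strand")
})
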