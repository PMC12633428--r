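## Format readers/writers and the end-to-end pipeline.
##
## Internal coordinates are 0-based half-open; VCF and GFF3 are converted
## at the boundary (1-based inclusive), BED/bedGraph pass through.

#' Read a variant table (VCF or TSV)
#'
#' VCF (detected by extension or `##fileformat` header) is parsed with
#' vcfR; zygosity derives from the first sample's GT (`0/1`-like =
#' heterozygous, `1/1`-like = homozygous_diff), multi-allelic and indel
#' records are skipped with a message. TSV needs columns `chrom`, `pos`,
#' `zygosity` and optionally `quality`.
#'
#' @param path file path.
#' @return data.frame `chrom`, `pos` (1-based), `zygosity`, `quality`.
#' @export
readVariantTable <- function(path) {
  firstLine <- readLines(path, n = 1L)
  if (grepl("\\.vcf$", path) || startsWith(firstLine, "##fileformat=VCF")) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    pos <- as.integer(fix$POS)
    if (any(is.na(pos) | pos < 1L))
      stop("VCF record ", which(is.na(pos) | pos < 1L)[1L],
           ": position must be a 1-based integer")
    gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
    snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
    gtNorm <- gsub("\\|", "/", gt)
    zyg <- ifelse(gtNorm %in% c("0/1", "1/0"), "heterozygous",
                  ifelse(gtNorm == "1/1", "homozygous_diff", NA))
    keep <- snp & !is.na(zyg)
    if (any(!keep))
      message(sum(!keep), " non-SNP or unsupported-genotype record(s) skipped")
    data.frame(chrom = fix$CHROM[keep], pos = pos[keep],
               zygosity = zyg[keep],
               quality = suppressWarnings(as.numeric(fix$QUAL[keep])),
               stringsAsFactors = FALSE)
  } else {
    d <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos", "zygosity") %in% names(d)))
      stop("TSV variant table needs columns chrom, pos, zygosity")
    if (any(d$pos < 1L)) stop("variant position must be >= 1")
    d
  }
}

#' Write a minimal VCF of heterozygous / homozygous-difference sites
#'
#' Emits a valid single-sample VCF 4.2 (REF/ALT are placeholders `N`/`A`
#' when sequence is not supplied; GT encodes zygosity).
#'
#' @param variants data.frame `chrom`, `pos`, `zygosity`, `quality`.
#' @param path output path.
#' @param chromLengths named lengths for contig headers.
#' @export
writeVariantVcf <- function(variants, path, chromLengths) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chromLengths),
                   as.integer(chromLengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample")
  gt <- ifelse(variants$zygosity == "heterozygous", "0/1", "1/1")
  rows <- sprintf("%s\t%d\t.\tN\tA\t%s\t.\t.\tGT\t%s", variants$chrom,
                  as.integer(variants$pos), as.character(variants$quality), gt)
  writeLines(c(hdr, rows), path)
}

#' Read a 3-column BED mask
#'
#' Malformed records (non-numeric coordinates, `end <= start`) are
#' rejected with a message reporting the count.
#'
#' @param path BED file (0-based half-open).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
readMaskBed <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end"),
                  colClasses = c("character", "numeric", "numeric"),
                  fill = TRUE)
  bad <- is.na(d$start) | is.na(d$end) | d$end <= d$start | d$start < 0
  if (any(bad)) message(sum(bad), " malformed BED record(s) rejected")
  d[!bad, , drop = FALSE]
}

#' Write intervals (tracts, segments) as BED
#'
#' @param intervals data.frame `chrom`, `start`, `end` and optionally a
#'   `class`/`label` column used as the BED name field.
#' @param path output path.
#' @export
writeBed <- function(intervals, path) {
  nm <- intervals$class %||% intervals$label %||% "."
  gr <- GRanges(intervals$chrom,
                IRanges(intervals$start + 1L, intervals$end))
  mcols(gr)$name <- nm
  rtracklayer::export(gr, path, format = "BED")
}

#' Write a per-base depth track as bedGraph
#'
#' @param depth named list of per-base depth vectors.
#' @param path output path.
#' @export
writeBedGraph <- function(depth, path) {
  runs <- lapply(names(depth), function(ch) {
    r <- S4Vectors::Rle(as.numeric(depth[[ch]]))
    ends <- cumsum(S4Vectors::runLength(r))
    list(chrom = rep(ch, length(ends)),
         start = ends - S4Vectors::runLength(r) + 1L, end = ends,
         score = S4Vectors::runValue(r))
  })
  gr <- GRanges(unlist(lapply(runs, `[[`, "chrom")),
                IRanges(unlist(lapply(runs, `[[`, "start")),
                        unlist(lapply(runs, `[[`, "end"))))
  mcols(gr)$score <- unlist(lapply(runs, `[[`, "score"))
  rtracklayer::export(gr, path, format = "bedGraph")
}

#' Read a bedGraph depth track into per-base vectors
#'
#' @param path bedGraph file.
#' @param chromLengths named chromosome lengths (bases not covered by a
#'   record get depth 0).
#' @return named list of numeric per-base vectors.
#' @export
readBedGraph <- function(path, chromLengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(names(chromLengths), function(ch) {
    v <- numeric(chromLengths[[ch]])
    sub <- gr[as.character(seqnames(gr)) == ch]
    for (i in seq_along(sub))
      v[start(sub)[i]:end(sub)[i]] <- sub$score[i]
    v
  })
  names(out) <- names(chromLengths)
  out
}

#' Write / read per-site modification tables
#'
#' Plain TSV with columns `chrom`, `pos` (0-based), `context`, `n_reads`,
#' `n_mod`, `frac`.
#'
#' @param sites modification table.
#' @param path file path.
#' @export
writeModSites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeModSites
#' @export
readModSites <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write gene models as GFF3 / derive TSS records from GFF3
#'
#' Minus-strand transcript starts are taken from the rightmost coordinate
#' of the feature.
#'
#' @param tss TSS records (`chrom`, `pos` 0-based, `strand`, `gene_id`,
#'   `high_confidence`).
#' @param path file path.
#' @export
writeTssGff3 <- function(tss, path) {
  s1 <- ifelse(tss$strand == "+", tss$pos + 1L, tss$pos + 1L - 99L)
  e1 <- ifelse(tss$strand == "+", tss$pos + 1L + 99L, tss$pos + 1L)
  gr <- GRanges(tss$chrom, IRanges(pmax(1L, s1), e1), strand = tss$strand)
  mcols(gr)$type <- "mRNA"
  mcols(gr)$ID <- tss$gene_id
  mcols(gr)$source <- "mosaikit"
  rtracklayer::export(gr, path, format = "GFF3")
}

#' @rdname writeTssGff3
#' @export
readTssFromGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "mRNA"]
  strand <- as.character(GenomicRanges::strand(gr))
  pos0 <- ifelse(strand == "+", start(gr) - 1L, end(gr) - 1L)
  data.frame(chrom = as.character(seqnames(gr)), pos = pos0,
             strand = strand, gene_id = as.character(gr$ID),
             high_confidence = TRUE, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to a directory
#'
#' Emits every observable of a [HybridSim-class] in standard formats:
#' haplotype and parental FASTA, heterozygous-variant VCF, truth-tract
#' BED, per-base depth bedGraph, modification-site TSV, gene-model GFF3
#' (methylation layout), transcript-model TSV, and JSON for the
#' configuration echo and truth log.
#'
#' @param sim a [HybridSim-class].
#' @param dir output directory (created if needed).
#' @param variants,depth,meth,transcripts optional precomputed emissions;
#'   generated with the defaults when `NULL`.
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, dir, variants = NULL, depth = NULL,
                            meth = NULL, transcripts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim@config
  variants <- variants %||% emitVariantTable(sim)
  depth <- depth %||% emitCoverageTrack(sim)
  meth <- meth %||% emitMethylation(cfg, nGenes = 200)
  transcripts <- transcripts %||% emitTranscripts(cfg)

  writeXStringSet(haplotype(sim, "A"), file.path(dir, "haplA.fasta"))
  writeXStringSet(haplotype(sim, "B"), file.path(dir, "haplB.fasta"))
  writeVariantVcf(variants, file.path(dir, "variants.vcf"),
                  chromLengths(sim))
  tr <- truthLog(sim)
  if (nrow(tr$loh))
    writeBed(tr$loh, file.path(dir, "truth_loh.bed"))
  writeBedGraph(depth, file.path(dir, "depth.bedGraph"))
  writeModSites(meth$sites, file.path(dir, "modsites.tsv"))
  writeTssGff3(meth$tss, file.path(dir, "genes.gff3"))
  write.table(transcripts$isoforms, file.path(dir, "isoforms.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(transcripts$kozak, file.path(dir, "kozak_transcripts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfgList <- list(chromLengths = as.list(chromLengths(sim)),
                  gcContent = cfg@gcContent, divP = cfg@divP,
                  divS = cfg@divS, hetP = cfg@hetP, hetS = cfg@hetS,
                  depthMean = cfg@depthMean,
                  depthDispersion = cfg@depthDispersion,
                  methPeriod = cfg@methPeriod,
                  methPlateau = cfg@methPlateau,
                  readsPerSiteMean = cfg@readsPerSiteMean, seed = cfg@seed)
  write_json(cfgList, file.path(dir, "config.json"), auto_unbox = TRUE,
             digits = NA)
  write_json(lapply(tr[c("ancestry", "crossovers", "loh", "copyNumber")],
                    as.list),
             file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated dataset directory back into R
#'
#' Validates that chromosome names agree between the FASTA, VCF and depth
#' members; a mismatch is an error naming the offending file.
#'
#' @param dir directory written by [writeSimulation()].
#' @return list with `haplA`, `haplB`, `variants`, `depth`, `modsites`,
#'   `tss`, `isoforms`, `kozak`, `config`, `chromLengths`.
#' @export
readBundle <- function(dir) {
  haplA <- readDNAStringSet(file.path(dir, "haplA.fasta"))
  haplB <- readDNAStringSet(file.path(dir, "haplB.fasta"))
  cl <- setNames(Biostrings::width(haplA), names(haplA))
  variants <- readVariantTable(file.path(dir, "variants.vcf"))
  if (nrow(variants) && !all(variants$chrom %in% names(cl)))
    stop("variants.vcf: chromosome names do not match the FASTA")
  cfg <- read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  depthNames <- c(paste0("A_", names(cl)), paste0("B_", names(cl)))
  depth <- readBedGraph(file.path(dir, "depth.bedGraph"),
                        setNames(rep(cl, 2L), depthNames))
  list(haplA = haplA, haplB = haplB, variants = variants, depth = depth,
       modsites = readModSites(file.path(dir, "modsites.tsv")),
       tss = readTssFromGff3(file.path(dir, "genes.gff3")),
       isoforms = read.table(file.path(dir, "isoforms.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE),
       kozak = read.table(file.path(dir, "kozak_transcripts.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE),
       config = cfg, chromLengths = cl)
}

#' Run the genome-diagnosis pipeline on a simulated hybrid
#'
#' Convenience wrapper chaining the stages on a [HybridSim-class]:
#' heterozygous variant emission, windowed heterozygosity, LOH tract
#' calling per chromosome, parent-of-origin painting of both haplotypes
#' against the parental references, switch detection, and (from the
#' emitted depth track) windowed coverage with chromosome copy-number
#' calls.
#'
#' @param sim a [HybridSim-class].
#' @param windowSize heterozygosity/divergence window (default 10 kb).
#' @param covWindowSize coverage window (default 20 kb).
#' @param delta painting threshold (default 0.01).
#' @param minAligned minimum aligned sites per window (default 2000).
#' @return list with `variants`, `het_windows`, `loh_tracts`,
#'   `segments_A`, `segments_B`, `switches`, `coverage_windows`,
#'   `copy_number`.
#' @export
analyzeHybridGenome <- function(sim, windowSize = 10000,
                                covWindowSize = 20000, delta = 0.01,
                                minAligned = 2000) {
  cl <- chromLengths(sim)
  variants <- emitVariantTable(sim)
  het <- windowedHeterozygosity(variants, cl, windowSize = windowSize,
                                minAligned = minAligned)
  tracts <- do.call(rbind, lapply(names(cl), function(ch)
    callLohTracts(variants$pos[variants$chrom == ch &
                               variants$zygosity == "heterozygous"],
                  cl[[ch]], chrom = ch)))
  paint <- lapply(c(A = "A", B = "B"), function(h) {
    w <- parentDivergenceWindows(haplotype(sim, h), sim@parents$P2,
                                 sim@parents$S2, windowSize = windowSize,
                                 minAligned = minAligned)
    segmentLabels(labelWindows(w, delta = delta))
  })
  switches <- do.call(rbind, lapply(names(cl), function(ch) {
    sA <- paint$A[paint$A$chrom == ch, , drop = FALSE]
    sB <- paint$B[paint$B$chrom == ch, , drop = FALSE]
    tr <- tracts[tracts$chrom == ch, , drop = FALSE]
    detectSwitches(sA, sB, lohTracts = tr, windowSize = windowSize)
  }))
  depth <- emitCoverageTrack(sim)
  cov <- windowedCoverage(depth, windowSize = covWindowSize)
  cn <- callChromosomeCopyNumber(cov, mode = "phased")
  list(variants = variants, het_windows = het, loh_tracts = tracts,
       segments_A = paint$A, segments_B = paint$B, switches = switches,
       coverage_windows = cov, copy_number = cn)
}
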