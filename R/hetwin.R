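## Windowed heterozygosity / divergence, degenerate-site classification.

.maskToIRanges <- function(mask, chrom, chromLength) {
  if (is.null(mask)) return(IRanges(1L, chromLength))
  m <- mask[mask$chrom == chrom, , drop = FALSE]
  if (!nrow(m)) return(IRanges())
  if (any(m$end > chromLength) || any(m$start < 0))
    stop("mask interval outside chromosome bounds on ", chrom)
  reduce(IRanges(m$start + 1L, m$end))
}

#' Tile a chromosome into non-overlapping windows
#'
#' Windows are anchored at 0 and tiled end-to-end; the last window may be
#' short. Coordinates 0-based half-open.
#'
#' @param chromLength chromosome length in bp.
#' @param windowSize window width in bp.
#' @return data.frame with columns `start`, `end`.
#' @export
tileWindows <- function(chromLength, windowSize) {
  stopifnot(windowSize > 0, chromLength > 0)
  starts <- seq.int(0L, chromLength - 1L, by = windowSize)
  data.frame(start = starts, end = pmin(starts + windowSize, chromLength))
}

## shared engine for the two window statistics
.windowStats <- function(variants, chromLengths, mask, windowSize,
                         minAligned, minQuality, weights) {
  if (!"quality" %in% names(variants)) {
    warning("no quality column; all variant sites treated as passing")
    variants$quality <- Inf
  }
  if (nrow(variants)) {
    if (!all(variants$chrom %in% names(chromLengths)))
      stop("variant table contains unknown chromosome(s)")
    if (any(variants$pos < 1) ||
        any(variants$pos > chromLengths[variants$chrom]))
      stop("variant position outside chromosome bounds")
  }
  keep <- variants$quality >= minQuality
  variants <- variants[keep, , drop = FALSE]

  res <- lapply(names(chromLengths), function(ch) {
    L <- chromLengths[[ch]]
    win <- tileWindows(L, windowSize)
    winIR <- IRanges(win$start + 1L, win$end)
    maskIR <- .maskToIRanges(mask, ch, L)
    nAligned <- integer(nrow(win))
    if (length(maskIR)) {
      ov <- findOverlaps(winIR, maskIR)
      w <- width(pintersect(winIR[queryHits(ov)], maskIR[subjectHits(ov)]))
      agg <- rowsum(w, queryHits(ov))
      nAligned[as.integer(rownames(agg))] <- agg[, 1L]
    }
    v <- variants[variants$chrom == ch, , drop = FALSE]
    nVar <- numeric(nrow(win))
    if (nrow(v)) {
      inMask <- overlapsAny(IRanges(v$pos, v$pos), maskIR)
      v <- v[inMask, , drop = FALSE]
      if (nrow(v)) {
        wgt <- weights[v$zygosity]
        if (anyNA(wgt)) stop("unknown zygosity value in variant table")
        idx <- (v$pos - 1L) %/% windowSize + 1L
        agg <- rowsum(wgt, idx)
        nVar[as.integer(rownames(agg))] <- agg[, 1L]
      }
    }
    ok <- nAligned >= minAligned
    data.frame(chrom = ch, start = win$start, end = win$end,
               n_aligned = nAligned, n_variant = nVar,
               value = ifelse(ok, nVar / pmax(nAligned, 1L), NA_real_),
               status = ifelse(ok, "ok", "excluded"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Windowed heterozygosity
#'
#' Heterozygosity per non-overlapping window: the number of qualifying
#' variant sites divided by the number of alignable (callable) sites in the
#' window. Sites outside the alignability mask or below the quality cutoff
#' are discarded; windows with fewer than `minAligned` aligned sites are
#' excluded (status `"excluded"`, value `NA`). In heterozygosity mode every
#' qualifying site counts with weight 1.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `zygosity` (`"heterozygous"` or `"homozygous_diff"`) and optionally
#'   `quality` (absent: treated as passing, with a warning).
#' @param chromLengths named chromosome lengths.
#' @param mask optional alignability mask, data.frame `chrom`, `start`,
#'   `end` (0-based half-open); `NULL` means fully alignable.
#' @param windowSize window width (default 10 kb).
#' @param minAligned minimum aligned sites per window (default 2000).
#' @param minQuality minimum site quality (default 60).
#' @return data.frame of window statistics: `chrom`, `start`, `end`,
#'   `n_aligned`, `n_variant`, `value`, `status`.
#' @examples
#' v <- data.frame(chrom = "chr01", pos = c(100, 200), zygosity =
#'   "heterozygous", quality = 60)
#' windowedHeterozygosity(v, c(chr01 = 10000L), minAligned = 0)
#' @export
windowedHeterozygosity <- function(variants, chromLengths, mask = NULL,
                                   windowSize = 10000, minAligned = 2000,
                                   minQuality = 60) {
  stopifnot(windowSize > 0)
  .windowStats(variants, chromLengths, mask, windowSize, minAligned,
               minQuality, weights = c(heterozygous = 1, homozygous_diff = 1))
}

#' Windowed divergence to a reference, with the half-weight rule
#'
#' Divergence of a strain from a reference, per window: a site where both
#' of the strain's haplotypes differ from the reference
#' (`homozygous_diff`) counts 1, a site where only one haplotype differs
#' (`heterozygous`) counts 1/2. Value is the weighted count divided by the
#' aligned sites in the window.
#'
#' @inheritParams windowedHeterozygosity
#' @return data.frame of window statistics (see
#'   [windowedHeterozygosity()]).
#' @export
windowedDivergence <- function(variants, chromLengths, mask = NULL,
                               windowSize = 10000, minAligned = 2000,
                               minQuality = 60) {
  stopifnot(windowSize > 0)
  .windowStats(variants, chromLengths, mask, windowSize, minAligned,
               minQuality, weights = c(heterozygous = 0.5, homozygous_diff = 1))
}

## ---- degenerate-site classification ----

## per-codon degeneracy classes, computed once: for each codon position the
## number of nucleotides preserving the amino acid (1 reported as 0)
.degenTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    t <- list()
    for (cod in names(gc)) {
      if (gc[[cod]] == "*") next
      cls <- integer(3)
      for (p in 1:3) {
        n <- 0L
        for (b in bases) {
          alt <- cod
          substr(alt, p, p) <- b
          if (gc[[alt]] == gc[[cod]]) n <- n + 1L
        }
        cls[p] <- if (n == 1L) 0L else n
      }
      t[[cod]] <- cls
    }
    tab <<- t
    tab
  }
})

#' Classify coding positions by degeneracy
#'
#' Labels every position of a coding sequence by its fold-degeneracy under
#' the standard genetic code: the number of nucleotides at that codon
#' position that preserve the encoded amino acid, reported as 0 when only
#' the observed nucleotide does (zero-fold), otherwise 2, 3 or 4.
#'
#' @param cds coding sequence (character scalar or `DNAString`), length a
#'   multiple of 3, first codon to last; a single trailing stop codon is
#'   allowed and its positions are labeled `NA`.
#' @return data.frame with columns `pos` (1-based position within the CDS),
#'   `codon_pos` (1..3) and `class` (0, 2, 3, 4, or `NA` for non-ACGT or
#'   stop positions).
#' @examples
#' classifyDegeneracy("ATGGGGTTA")$class  # Met 0,0,0; Gly 0,0,4; Leu 2,0,2
#' @export
classifyDegeneracy <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  tab <- .degenTable()
  gc <- Biostrings::GENETIC_CODE
  cls <- lapply(seq_along(codons), function(i) {
    cod <- codons[i]
    if (!grepl("^[ACGT]{3}$", cod)) return(rep(NA_integer_, 3))
    if (gc[[cod]] == "*") {
      if (i != length(codons))
        stop("internal stop codon at codon ", i)
      return(rep(NA_integer_, 3))
    }
    tab[[cod]]
  })
  data.frame(pos = seq_len(n), codon_pos = rep(1:3, length(codons)),
             class = unlist(cls))
}

#' Genome-coordinate degeneracy track for a set of CDS models
#'
#' Extracts each spliced CDS from the genome (strand-aware), classifies it
#' with [classifyDegeneracy()] and maps the classes back to genomic
#' positions.
#'
#' @param genome a `DNAStringSet` keyed by chromosome.
#' @param cdsExons data.frame with columns `tx_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`; multiple rows per transcript are
#'   spliced in genomic order (minus-strand transcripts read right to
#'   left).
#' @return data.frame `chrom`, `pos` (1-based genomic), `class`.
#' @export
degeneracyTrack <- function(genome, cdsExons) {
  out <- lapply(split(cdsExons, cdsExons$tx_id), function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    ch <- ex$chrom[1L]
    pos <- unlist(lapply(seq_len(nrow(ex)), function(i)
      (ex$start[i] + 1L):ex$end[i]))
    seq <- paste(vapply(seq_len(nrow(ex)), function(i)
      as.character(Biostrings::subseq(genome[[ch]], ex$start[i] + 1L, ex$end[i])),
      character(1)), collapse = "")
    if (ex$strand[1L] == "-") {
      seq <- as.character(reverseComplement(DNAStringSet(seq))[[1L]])
      pos <- rev(pos)
    }
    cls <- classifyDegeneracy(seq)$class
    data.frame(chrom = ch, pos = pos, class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Heterozygosity by degeneracy class
#'
#' For each fold class, the fraction of callable sites of that class that
#' carry a heterozygous variant.
#'
#' @param variants variant table (`chrom`, `pos` 1-based, `zygosity`).
#' @param degeneracy data.frame `chrom`, `pos` (1-based), `class` as from
#'   [degeneracyTrack()].
#' @param mask optional callable mask (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return data.frame `class`, `n_sites`, `n_het`, `value` (`NA` for empty
#'   classes).
#' @export
hetBySiteClass <- function(variants, degeneracy, mask = NULL) {
  degeneracy <- degeneracy[!is.na(degeneracy$class), , drop = FALSE]
  if (!is.null(mask)) {
    keep <- vapply(seq_len(nrow(degeneracy)), function(i) {
      m <- mask[mask$chrom == degeneracy$chrom[i], , drop = FALSE]
      any(degeneracy$pos[i] > m$start & degeneracy$pos[i] <= m$end)
    }, logical(1))
    degeneracy <- degeneracy[keep, , drop = FALSE]
  }
  hetKey <- paste(variants$chrom[variants$zygosity == "heterozygous"],
                  variants$pos[variants$zygosity == "heterozygous"])
  isHet <- paste(degeneracy$chrom, degeneracy$pos) %in% hetKey
  out <- do.call(rbind, lapply(sort(unique(degeneracy$class)), function(k) {
    sel <- degeneracy$class == k
    data.frame(class = k, n_sites = sum(sel), n_het = sum(isHet & sel),
               value = if (sum(sel)) sum(isHet & sel) / sum(sel) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
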