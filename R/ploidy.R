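## Windowed depth, chromosome copy-number calls, partial-aneuploidy
## segmentation.

#' Mean read depth in non-overlapping windows
#'
#' @param depth named list of per-base depth vectors (one per chromosome /
#'   haplotype chromosome; missing bases count 0 only if encoded as 0).
#' @param windowSize window width (default 20 kb).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `mean_depth`, `complete` (FALSE for a short final window).
#' @export
windowedCoverage <- function(depth, windowSize = 20000) {
  stopifnot(windowSize > 0)
  out <- lapply(names(depth), function(ch) {
    v <- depth[[ch]]
    L <- length(v)
    win <- tileWindows(L, windowSize)
    idx <- (seq_len(L) - 1L) %/% windowSize
    sums <- rowsum(as.numeric(v), idx)
    cnt <- tabulate(idx + 1L, nbins = nrow(win))
    data.frame(chrom = ch, start = win$start, end = win$end,
               mean_depth = as.numeric(sums) / cnt,
               complete = (win$end - win$start) == windowSize,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

## robust genome baseline: median of per-chromosome median depths after one
## pruning round dropping chromosomes whose ratio to the initial baseline
## falls outside the band
.depthBaseline <- function(chromMedians, band = c(0.75, 1.25)) {
  b0 <- median(chromMedians)
  keep <- chromMedians / b0 >= band[1L] & chromMedians / b0 <= band[2L]
  if (!any(keep)) stop("all chromosomes pruned; baseline undefined")
  median(chromMedians[keep])
}

#' Call integer chromosome copy numbers from windowed depth
#'
#' Per chromosome, the median window depth is compared to a robust genome
#' baseline: the median of per-chromosome medians after one pruning round
#' that drops chromosomes whose ratio to the initial baseline falls outside
#' `[0.75, 1.25]` (so aneuploid chromosomes do not inflate the baseline).
#' Copies = `expectedCopies * median / baseline`, rounded half away from
#' zero. In `phased` mode (reads mapped to a phased diploid assembly) a
#' normal haplotype chromosome has 1 expected copy; in `collapsed` mode
#' (haploid reference) a normal chromosome has 2.
#'
#' @param windows data.frame from [windowedCoverage()].
#' @param mode `"phased"` or `"collapsed"`.
#' @param expectedCopies copies of a normal chromosome; defaults to 1
#'   (phased) or 2 (collapsed).
#' @return data.frame `chrom`, `median_depth`, `baseline`, `ratio`,
#'   `copies`, `confidence` (fraction of windows whose implied integer
#'   equals the call), `mode`.
#' @examples
#' w <- data.frame(chrom = rep(c("c1", "c2"), each = 10),
#'                 mean_depth = rep(c(272, 528), each = 10))
#' callChromosomeCopyNumber(w, mode = "phased")$copies  # 1, 2
#' @export
callChromosomeCopyNumber <- function(windows,
                                     mode = c("phased", "collapsed"),
                                     expectedCopies = NULL) {
  mode <- match.arg(mode)
  if (is.null(expectedCopies))
    expectedCopies <- if (mode == "phased") 1L else 2L
  meds <- vapply(split(windows$mean_depth, windows$chrom), median, numeric(1))
  nWin <- table(windows$chrom)
  if (any(nWin < 5L))
    warning("chromosome(s) with fewer than 5 windows: ",
            paste(names(nWin)[nWin < 5L], collapse = ", "))
  baseline <- .depthBaseline(meds)
  out <- do.call(rbind, lapply(names(meds), function(ch) {
    ratio <- meds[[ch]] / baseline
    copies <- as.integer(.roundHalfAway(expectedCopies * ratio))
    wd <- windows$mean_depth[windows$chrom == ch]
    conf <- mean(.roundHalfAway(expectedCopies * wd / baseline) == copies)
    data.frame(chrom = ch, median_depth = meds[[ch]], baseline = baseline,
               ratio = ratio, copies = copies, confidence = conf,
               mode = mode, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## best binary split of a window-mean vector: maximal reduction in residual
## sum of squares, both sides at least minSeg windows
.bestSplit <- function(x, minSeg) {
  n <- length(x)
  if (n < 2L * minSeg) return(NULL)
  cums <- cumsum(x)
  tot <- cums[n]
  ks <- minSeg:(n - minSeg)
  mL <- cums[ks] / ks
  mR <- (tot - cums[ks]) / (n - ks)
  gain <- ks * (n - ks) / n * (mL - mR)^2
  k <- ks[which.max(gain)]
  list(k = k, meanL = cums[k] / k, meanR = (tot - cums[k]) / (n - k))
}

#' Segment a chromosome's windowed depth into copy-number segments
#'
#' Recursive binary segmentation on window means: at each level the split
#' maximizing the between-segment sum of squares is accepted iff both
#' sides span at least `minSegWindows` windows and the segment means
#' differ by at least `minEffect * baseline`; accepted splits recurse.
#' Each final segment receives an integer copy call as in
#' [callChromosomeCopyNumber()].
#'
#' @param windows data.frame from [windowedCoverage()] for one chromosome.
#' @param baseline depth per `expectedCopies` copies; default: baseline
#'   from the windows themselves is not meaningful for a single
#'   chromosome, so pass the genome baseline (e.g. from
#'   [callChromosomeCopyNumber()]); if `NULL` the chromosome median is
#'   used.
#' @param minSegWindows minimum segment length in windows (default 5).
#' @param minEffect minimum mean difference between adjacent segments, as
#'   a fraction of baseline (default 0.25).
#' @param expectedCopies copies of a normal chromosome (default 1, phased).
#' @return data.frame `chrom`, `start`, `end`, `n_windows`, `mean_depth`,
#'   `copies`.
#' @export
segmentPartialAneuploidy <- function(windows, baseline = NULL,
                                     minSegWindows = 5, minEffect = 0.25,
                                     expectedCopies = 1L) {
  stopifnot(length(unique(windows$chrom)) == 1L)
  windows <- windows[order(windows$start), , drop = FALSE]
  x <- windows$mean_depth
  if (is.null(baseline)) baseline <- median(x)

  segs <- list()
  recurse <- function(lo, hi) {       # window indices, inclusive
    sp <- .bestSplit(x[lo:hi], minSegWindows)
    if (!is.null(sp) && abs(sp$meanL - sp$meanR) >= minEffect * baseline) {
      recurse(lo, lo + sp$k - 1L)
      recurse(lo + sp$k, hi)
    } else {
      segs[[length(segs) + 1L]] <<- c(lo, hi)
    }
  }
  recurse(1L, nrow(windows))

  out <- do.call(rbind, lapply(segs, function(s) {
    m <- mean(x[s[1L]:s[2L]])
    data.frame(chrom = windows$chrom[1L],
               start = windows$start[s[1L]], end = windows$end[s[2L]],
               n_windows = s[2L] - s[1L] + 1L, mean_depth = m,
               copies = as.integer(.roundHalfAway(expectedCopies * m / baseline)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
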