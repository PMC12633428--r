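## Loss-of-heterozygosity tract calling, classification, summary,
## between-strain comparison.

#' Call maximal heterozygosity-free tracts
#'
#' Candidate tracts are the maximal intervals containing no heterozygous
#' site: between consecutive heterozygous sites the candidate is the open
#' interior (both flanking het sites excluded), and the chromosome ends
#' bound the first and last candidates. A candidate is emitted as an LOH
#' tract if its length is at least `minLen` and the fraction of callable
#' bases inside is at least `minCallableFraction`. A chromosome with no
#' heterozygous site yields a single whole-chromosome tract. Two
#' consecutive het sites 1,001 bp apart leave a 1,000-bp interior and so
#' (at the default threshold) produce a tract; 999 bp apart they do not.
#'
#' @param hetPositions integer vector of heterozygous site positions
#'   (1-based) on one chromosome; need not be sorted or unique.
#' @param chromLength chromosome length in bp.
#' @param mask optional callable mask for this chromosome: data.frame
#'   `start`, `end` (0-based half-open) or `NULL` for fully callable.
#' @param minLen minimum tract length in bp (default 1000).
#' @param minCallableFraction minimum callable fraction inside a tract
#'   (default 0.5; set 0 to disable the callability guard).
#' @param chrom chromosome name carried into the output.
#' @return data.frame of tracts: `chrom`, `start`, `end` (0-based
#'   half-open), `length`, `n_callable`, `class`.
#' @examples
#' callLohTracts(c(500, 2600), 10000, chrom = "chr01")
#' @export
callLohTracts <- function(hetPositions, chromLength, mask = NULL,
                          minLen = 1000, minCallableFraction = 0.5,
                          chrom = "chr") {
  if (minLen < 1) stop("minLen must be >= 1")
  hetPositions <- sort(unique(as.integer(hetPositions)))
  if (length(hetPositions) &&
      (hetPositions[1L] < 1L || hetPositions[length(hetPositions)] > chromLength))
    stop("heterozygous position outside chromosome")

  ## interiors between het sites in 0-based half-open coordinates: a het at
  ## 1-based p occupies [p-1, p), so the gap interior after it starts at p
  bounds <- c(0L, hetPositions, chromLength + 1L)
  starts <- bounds[-length(bounds)]            # 0, p1, p2, ...
  ends <- bounds[-1L] - 1L                     # p1-1, p2-1, ..., L
  len <- ends - starts
  keep <- len >= minLen
  if (!any(keep)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_callable = integer(0), class = character(0)))
  }
  starts <- starts[keep]; ends <- ends[keep]; len <- len[keep]

  maskIR <- if (is.null(mask)) IRanges(1L, chromLength)
            else reduce(IRanges(mask$start + 1L, mask$end))
  tractIR <- IRanges(starts + 1L, ends)
  nCallable <- integer(length(starts))
  ov <- findOverlaps(tractIR, maskIR)
  if (length(ov)) {
    w <- width(pintersect(tractIR[queryHits(ov)], maskIR[subjectHits(ov)]))
    agg <- rowsum(w, queryHits(ov))
    nCallable[as.integer(rownames(agg))] <- agg[, 1L]
  }
  keep <- nCallable / len >= minCallableFraction
  starts <- starts[keep]; ends <- ends[keep]
  len <- len[keep]; nCallable <- nCallable[keep]

  data.frame(chrom = chrom, start = starts, end = ends, length = len,
             n_callable = nCallable,
             class = vapply(seq_along(starts), function(i)
               classifyTract(starts[i], ends[i], chromLength), character(1)),
             stringsAsFactors = FALSE)
}

#' Classify a tract by its position on the chromosome
#'
#' @param start,end tract coordinates, 0-based half-open.
#' @param chromLength chromosome length.
#' @return `"whole_chromosome"` if the tract spans `[0, L)`,
#'   `"terminal_left"` / `"terminal_right"` if it touches exactly one end,
#'   `"interstitial"` otherwise.
#' @export
classifyTract <- function(start, end, chromLength) {
  if (start < 0 || end > chromLength || start >= end)
    stop("tract outside chromosome bounds")
  left <- start == 0
  right <- end == chromLength
  if (left && right) "whole_chromosome"
  else if (left) "terminal_left"
  else if (right) "terminal_right"
  else "interstitial"
}

#' Summarize an LOH tract set
#'
#' Per-class count, total/mean/max length, and the genome fraction
#' homozygous.
#'
#' @param tracts data.frame as from [callLohTracts()] (columns `chrom`,
#'   `start`, `end`, `class`); tracts must not overlap within a
#'   chromosome.
#' @param genomeLength total genome length in bp.
#' @return list with `per_class` (data.frame `class`, `n`, `total_bp`,
#'   `mean_bp`, `max_bp`) and `genome_fraction_homozygous`.
#' @examples
#' tr <- data.frame(chrom = "c", start = 0, end = 111000,
#'                  class = "terminal_left")
#' summarizeLoh(tr, 22e6)$genome_fraction_homozygous  # 111000/22e6
#' @export
summarizeLoh <- function(tracts, genomeLength) {
  if (genomeLength <= 0) stop("genomeLength must be > 0")
  if (nrow(tracts)) {
    for (ch in unique(tracts$chrom)) {
      t <- tracts[tracts$chrom == ch, , drop = FALSE]
      t <- t[order(t$start), , drop = FALSE]
      if (nrow(t) > 1L && any(t$start[-1L] < t$end[-nrow(t)]))
        stop("overlapping tracts on chromosome ", ch)
    }
  }
  len <- tracts$end - tracts$start
  perClass <- do.call(rbind, lapply(unique(tracts$class), function(k) {
    l <- len[tracts$class == k]
    data.frame(class = k, n = length(l), total_bp = sum(l),
               mean_bp = mean(l), max_bp = max(l))
  }))
  if (is.null(perClass))
    perClass <- data.frame(class = character(0), n = integer(0),
                           total_bp = numeric(0), mean_bp = numeric(0),
                           max_bp = numeric(0))
  list(per_class = perClass,
       genome_fraction_homozygous = sum(len) / genomeLength)
}

#' Partition two strains' tract sets into shared and unique
#'
#' A pair of tracts (one from each strain, same chromosome) is shared when
#' their overlap covers at least `reciprocalOverlap` of *both* tract
#' lengths. Matching is greedy on decreasing overlap; each tract is matched
#' at most once.
#'
#' @param tractsA,tractsB data.frames with `chrom`, `start`, `end`.
#' @param reciprocalOverlap reciprocal-overlap threshold (default 0.5).
#' @return list with `shared` (data.frame of matched index pairs `i_a`,
#'   `i_b` and `overlap_bp`), `unique_a`, `unique_b` (row indices).
#' @export
compareStrainTracts <- function(tractsA, tractsB, reciprocalOverlap = 0.5) {
  pairs <- NULL
  for (i in seq_len(nrow(tractsA))) {
    for (j in seq_len(nrow(tractsB))) {
      if (tractsA$chrom[i] != tractsB$chrom[j]) next
      ov <- min(tractsA$end[i], tractsB$end[j]) -
            max(tractsA$start[i], tractsB$start[j])
      if (ov <= 0) next
      la <- tractsA$end[i] - tractsA$start[i]
      lb <- tractsB$end[j] - tractsB$start[j]
      if (ov >= reciprocalOverlap * la && ov >= reciprocalOverlap * lb)
        pairs <- rbind(pairs, data.frame(i_a = i, i_b = j, overlap_bp = ov))
    }
  }
  shared <- data.frame(i_a = integer(0), i_b = integer(0),
                       overlap_bp = numeric(0))
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs$overlap_bp, pairs$i_a, pairs$i_b), , drop = FALSE]
    usedA <- usedB <- integer(0)
    for (r in seq_len(nrow(pairs))) {
      if (pairs$i_a[r] %in% usedA || pairs$i_b[r] %in% usedB) next
      shared <- rbind(shared, pairs[r, ])
      usedA <- c(usedA, pairs$i_a[r]); usedB <- c(usedB, pairs$i_b[r])
    }
  }
  list(shared = shared,
       unique_a = setdiff(seq_len(nrow(tractsA)), shared$i_a),
       unique_b = setdiff(seq_len(nrow(tractsB)), shared$i_b))
}
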