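## Parent-of-origin painting of hybrid haplotypes and switch detection.

#' Windowed divergence of one haplotype to both parental references
#'
#' Convenience wrapper: computes [windowedDivergence()] of a hybrid
#' haplotype against each parental reference (coordinate-aligned
#' sequences, e.g. from the simulator) and merges the two into
#' parent-divergence windows.
#'
#' @param hapl `DNAStringSet` of the hybrid haplotype chromosomes.
#' @param refP,refS `DNAStringSet`s of the two parental references, same
#'   names/widths as `hapl`.
#' @param mask optional alignability mask (`chrom`, `start`, `end`).
#' @param windowSize,minAligned window parameters (defaults 10 kb / 2000).
#' @return data.frame with columns `chrom`, `start`, `end`, `d_P`, `d_S`,
#'   `n_aligned_P`, `n_aligned_S`, `status`.
#' @export
parentDivergenceWindows <- function(hapl, refP, refS, mask = NULL,
                                    windowSize = 10000, minAligned = 2000) {
  cl <- setNames(Biostrings::width(hapl), names(hapl))
  dP <- windowedDivergence(diffSites(hapl, refP, zygosity = "homozygous_diff"),
                           cl, mask = mask, windowSize = windowSize,
                           minAligned = minAligned)
  dS <- windowedDivergence(diffSites(hapl, refS, zygosity = "homozygous_diff"),
                           cl, mask = mask, windowSize = windowSize,
                           minAligned = minAligned)
  data.frame(chrom = dP$chrom, start = dP$start, end = dP$end,
             d_P = dP$value, d_S = dS$value,
             n_aligned_P = dP$n_aligned, n_aligned_S = dS$n_aligned,
             status = ifelse(dP$status == "ok" & dS$status == "ok",
                             "ok", "excluded"),
             stringsAsFactors = FALSE)
}

#' Label windows by parent of origin
#'
#' A window is assigned to parent P when its divergence to the S reference
#' exceeds its divergence to the P reference by at least `delta` (and vice
#' versa); windows where the two divergences differ by less than `delta`
#' are `ambiguous`; windows failing the aligned-site filter in either
#' comparison are `unassigned`. The default `delta` of 0.01 sits between
#' the within-species heterozygosity regime (~0.006-0.0135) and the
#' between-species divergence regime (~0.027).
#'
#' @param windows data.frame as from [parentDivergenceWindows()].
#' @param delta decision threshold on `d_S - d_P` (default 0.01).
#' @return the input with a `label` column (`"P"`, `"S"`, `"ambiguous"`,
#'   `"unassigned"`).
#' @examples
#' w <- data.frame(chrom = "c", start = 0, end = 1e4, d_P = 0.0057,
#'                 d_S = 0.0284, status = "ok")
#' labelWindows(w)$label  # "P"
#' @export
labelWindows <- function(windows, delta = 0.01) {
  if (delta <= 0) stop("delta must be > 0")
  diff <- windows$d_S - windows$d_P
  lab <- ifelse(diff >= delta, "P", ifelse(-diff >= delta, "S", "ambiguous"))
  lab[windows$status != "ok" | is.na(diff)] <- "unassigned"
  windows$label <- lab
  windows
}

## smooth a per-window label vector: short P/S runs flanked on both sides
## by the same other label are absorbed; ambiguous/unassigned runs inherit
## the flanking consensus when the flanks agree
.smoothLabels <- function(lab, minRun) {
  repeat {
    r <- rle(lab)
    n <- length(r$lengths)
    if (n < 2L) break
    changed <- FALSE
    for (i in seq_len(n)) {
      left <- if (i > 1L) r$values[i - 1L] else NA
      right <- if (i < n) r$values[i + 1L] else NA
      v <- r$values[i]
      if (v %in% c("ambiguous", "unassigned")) {
        if (!is.na(left) && !is.na(right) && left == right &&
            left %in% c("P", "S")) {
          r$values[i] <- left; changed <- TRUE; break
        }
      } else if (r$lengths[i] < minRun) {
        if (!is.na(left) && !is.na(right) && left == right &&
            left %in% c("P", "S") && left != v) {
          r$values[i] <- left; changed <- TRUE; break
        }
      }
    }
    lab <- inverse.rle(r)
    if (!changed) break
  }
  lab
}

#' Segment window labels into ancestry segments
#'
#' Maximal runs of equal parent label, after smoothing: runs of P or S
#' shorter than `minRun` windows flanked on both sides by the same other
#' label are absorbed into that label, and ambiguous/unassigned windows
#' inherit the flanking consensus when both flanks agree. Ambiguous
#' windows never seed segments of their own at chromosome ends.
#'
#' @param labeled data.frame from [labelWindows()] for one haplotype
#'   (columns `chrom`, `start`, `end`, `label`, `d_P`, `d_S`).
#' @param minRun minimum run length in windows (default 3).
#' @return data.frame of segments: `chrom`, `start`, `end`, `label`,
#'   `n_windows`, `mean_d_P`, `mean_d_S`.
#' @export
segmentLabels <- function(labeled, minRun = 3) {
  out <- lapply(split(labeled, labeled$chrom), function(w) {
    w <- w[order(w$start), , drop = FALSE]
    lab <- .smoothLabels(w$label, minRun)
    r <- rle(lab)
    idxEnd <- cumsum(r$lengths)
    idxStart <- idxEnd - r$lengths + 1L
    data.frame(chrom = w$chrom[1L],
               start = w$start[idxStart], end = w$end[idxEnd],
               label = r$values, n_windows = r$lengths,
               mean_d_P = vapply(seq_along(r$values), function(i)
                 mean(w$d_P[idxStart[i]:idxEnd[i]], na.rm = TRUE), numeric(1)),
               mean_d_S = vapply(seq_along(r$values), function(i)
                 mean(w$d_S[idxStart[i]:idxEnd[i]], na.rm = TRUE), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## P/S label-change boundaries of one haplotype's segments on one
## chromosome: position interval spanning any intervening ambiguous run
.segmentBoundaries <- function(seg) {
  seg <- seg[order(seg$start), , drop = FALSE]
  inf <- seg[seg$label %in% c("P", "S"), , drop = FALSE]
  if (nrow(inf) < 2L)
    return(data.frame(lo = numeric(0), hi = numeric(0),
                      from = character(0), to = character(0)))
  chg <- which(inf$label[-1L] != inf$label[-nrow(inf)])
  data.frame(lo = inf$end[chg], hi = inf$start[chg + 1L],
             from = inf$label[chg], to = inf$label[chg + 1L],
             stringsAsFactors = FALSE)
}

#' Detect and classify ancestry switch events
#'
#' Compares the ancestry segments of the two haplotypes of one chromosome.
#' A pair of label-change boundaries, one per haplotype, within
#' `toleranceWindows` windows of each other and with opposite transitions
#' (P to S on one haplotype, S to P on the other) is a reciprocal mitotic
#' crossover. An unpaired boundary lying within tolerance of a called LOH
#' tract edge, or bordering a region where both haplotypes carry the same
#' label, is a nonreciprocal LOH switch. Anything else is unclassified.
#'
#' @param segA,segB segment data.frames (one chromosome each) from
#'   [segmentLabels()].
#' @param lohTracts optional data.frame of LOH tracts on this chromosome
#'   (`start`, `end`), as from [callLohTracts()].
#' @param toleranceWindows pairing tolerance in windows (default 1).
#' @param windowSize window width in bp used for the segments (default
#'   10 kb).
#' @return data.frame of switch events: `chrom`, `pos_lo`, `pos_hi`,
#'   `haplotypes`, `type`.
#' @export
detectSwitches <- function(segA, segB, lohTracts = NULL,
                           toleranceWindows = 1, windowSize = 10000) {
  chrom <- unique(c(segA$chrom, segB$chrom))
  if (length(chrom) != 1L)
    stop("segments from different chromosomes mixed")
  tol <- toleranceWindows * windowSize
  bA <- .segmentBoundaries(segA)
  bB <- .segmentBoundaries(segB)
  events <- NULL
  usedB <- logical(nrow(bB))

  midpoint <- function(b, i) (b$lo[i] + b$hi[i]) / 2

  for (i in seq_len(nrow(bA))) {
    paired <- FALSE
    for (j in seq_len(nrow(bB))) {
      if (usedB[j]) next
      if (abs(midpoint(bA, i) - midpoint(bB, j)) <= tol &&
          bA$from[i] == bB$to[j] && bA$to[i] == bB$from[j]) {
        events <- rbind(events, data.frame(
          chrom = chrom, pos_lo = min(bA$lo[i], bB$lo[j]),
          pos_hi = max(bA$hi[i], bB$hi[j]), haplotypes = "A,B",
          type = "reciprocal_crossover", stringsAsFactors = FALSE))
        usedB[j] <- TRUE; paired <- TRUE
        break
      }
    }
    if (!paired)
      events <- rbind(events, .classifyLoneBoundary(bA, i, segA, segB,
                                                    lohTracts, tol, chrom, "A"))
  }
  for (j in seq_len(nrow(bB))) {
    if (usedB[j]) next
    events <- rbind(events, .classifyLoneBoundary(bB, j, segB, segA,
                                                  lohTracts, tol, chrom, "B"))
  }
  if (is.null(events))
    events <- data.frame(chrom = character(0), pos_lo = numeric(0),
                         pos_hi = numeric(0), haplotypes = character(0),
                         type = character(0))
  rownames(events) <- NULL
  events[order(events$pos_lo), , drop = FALSE]
}

## an unpaired boundary: nonreciprocal LOH if at an LOH tract edge or
## bordering a region where the two haplotypes share a label
.classifyLoneBoundary <- function(b, i, segSelf, segOther, lohTracts, tol,
                                  chrom, hap) {
  mid <- (b$lo[i] + b$hi[i]) / 2
  nearTract <- FALSE
  if (!is.null(lohTracts) && nrow(lohTracts))
    nearTract <- any(abs(lohTracts$start - mid) <= tol |
                     abs(lohTracts$end - mid) <= tol)
  labelAt <- function(seg, pos) {
    hit <- seg$start <= pos & seg$end > pos
    if (any(hit)) seg$label[which(hit)[1L]] else NA_character_
  }
  sharedFlank <- FALSE
  for (probe in c(mid - tol - 1, mid + tol + 1)) {
    ls <- labelAt(segSelf, probe); lo <- labelAt(segOther, probe)
    if (!is.na(ls) && !is.na(lo) && ls == lo && ls %in% c("P", "S"))
      sharedFlank <- TRUE
  }
  type <- if (nearTract || sharedFlank) "nonreciprocal_LOH" else "unclassified"
  data.frame(chrom = chrom, pos_lo = b$lo[i], pos_hi = b$hi[i],
             haplotypes = hap, type = type, stringsAsFactors = FALSE)
}
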