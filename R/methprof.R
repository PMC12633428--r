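## Modification-call filtering, TSS-anchored metaprofiles, periodicity.

#' Filter modification sites by read coverage
#'
#' Retains sites with at least `minReads` mapped reads (sites with fewer
#' than 5 reads removed, at the default).
#'
#' @param sites data.frame with at least `n_reads` and `n_mod` columns.
#' @param minReads minimum read count (default 5).
#' @return the retained rows; the number removed is reported via a
#'   message.
#' @export
filterModSites <- function(sites, minReads = 5) {
  if (any(sites$n_reads < 0) || any(sites$n_mod < 0))
    stop("negative read counts")
  keep <- sites$n_reads >= minReads
  message(sum(!keep), " site(s) removed (fewer than ", minReads,
          " reads); ", sum(keep), " retained")
  sites[keep, , drop = FALSE]
}

#' TSS-anchored methylation metaprofile
#'
#' For every (gene, site) pair with the site inside the flank window of
#' the gene's TSS, computes the strand-aware offset (TSS at 0, downstream
#' positive: `pos - tss` on the plus strand, `tss - pos` on the minus
#' strand) and reports the median modification fraction per offset, pooled
#' over all contributing pairs. Offsets with no contributing site are
#' absent from the result. Duplicated TSS records are deduplicated.
#'
#' @param sites filtered modification table (`chrom`, `pos` 0-based,
#'   `context`, `frac` or `n_reads`/`n_mod`).
#' @param tss TSS records (`chrom`, `pos` 0-based, `strand`, `gene_id`,
#'   optional `high_confidence`).
#' @param context `"CpG"` or `"ApT"`; the site table is subset to it (an
#'   error if absent from the table).
#' @param flankUp,flankDown window extent upstream/downstream of the TSS.
#' @param highConfidenceOnly restrict to high-confidence TSSs when the
#'   column is present (default TRUE).
#' @param perGeneMedian if TRUE, take per-gene medians first and then the
#'   median across genes, instead of pooling all (gene, site) pairs
#'   (default FALSE, the pooled reading).
#' @return data.frame `offset`, `median_frac`, `n_sites`.
#' @export
tssMetaprofile <- function(sites, tss, context = c("CpG", "ApT"),
                           flankUp = 1000, flankDown = 3000,
                           highConfidenceOnly = TRUE,
                           perGeneMedian = FALSE) {
  context <- match.arg(context)
  if (!context %in% sites$context)
    stop("requested context '", context, "' not present in the site table")
  sites <- sites[sites$context == context, , drop = FALSE]
  if (!"frac" %in% names(sites))
    sites$frac <- sites$n_mod / sites$n_reads
  if (highConfidenceOnly && "high_confidence" %in% names(tss))
    tss <- tss[tss$high_confidence, , drop = FALSE]
  tss <- tss[!duplicated(tss[c("chrom", "pos", "strand")]), , drop = FALSE]

  offs <- list(); fracs <- list(); genes <- list()
  for (ch in unique(tss$chrom)) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    s <- s[order(s$pos), , drop = FALSE]
    t <- tss[tss$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(t))) {
      lo <- t$pos[i] - if (t$strand[i] == "+") flankUp else flankDown
      hi <- t$pos[i] + if (t$strand[i] == "+") flankDown else flankUp
      i1 <- findInterval(lo - 1L, s$pos) + 1L
      i2 <- findInterval(hi, s$pos)
      if (i2 < i1) next
      p <- s$pos[i1:i2]
      off <- if (t$strand[i] == "+") p - t$pos[i] else t$pos[i] - p
      offs[[length(offs) + 1L]] <- off
      fracs[[length(fracs) + 1L]] <- s$frac[i1:i2]
      genes[[length(genes) + 1L]] <- rep(i, length(off))
    }
  }
  off <- unlist(offs); frac <- unlist(fracs); gene <- unlist(genes)
  if (!length(off))
    return(data.frame(offset = integer(0), median_frac = numeric(0),
                      n_sites = integer(0)))
  if (perGeneMedian) {
    byGene <- tapply(frac, list(off, gene), median)
    med <- apply(byGene, 1L, median, na.rm = TRUE)
    n <- rowSums(!is.na(byGene))
    out <- data.frame(offset = as.integer(rownames(byGene)),
                      median_frac = unname(med), n_sites = unname(n))
  } else {
    sp <- split(frac, off)
    out <- data.frame(offset = as.integer(names(sp)),
                      median_frac = vapply(sp, median, numeric(1)),
                      n_sites = lengths(sp))
  }
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the dominant methylation period downstream of the TSS
#'
#' Takes the downstream (offset >= 0) part of a metaprofile, linearly
#' interpolates missing offsets, mean-centers, and returns the lag within
#' `lagRange` that maximizes the autocorrelation, provided that
#' autocorrelation reaches `minAutocorr`; otherwise no period is called.
#'
#' @param profile data.frame from [tssMetaprofile()].
#' @param lagRange candidate period range in bp (default 50..500).
#' @param minAutocorr minimum autocorrelation to call a period (default
#'   0.2).
#' @return one-row data.frame `period`, `autocorr`, `detected`; `period`
#'   is `NA` when no periodicity is detected.
#' @export
estimatePeriodicity <- function(profile, lagRange = c(50, 500),
                                minAutocorr = 0.2) {
  down <- profile[profile$offset >= 0 & !is.na(profile$median_frac), ,
                  drop = FALSE]
  if (nrow(down) < 3L)
    return(data.frame(period = NA_real_, autocorr = NA_real_,
                      detected = FALSE))
  grid <- seq(min(down$offset), max(down$offset))
  if (max(lagRange) >= length(grid))
    stop("lagRange outside the profile span")
  y <- approx(down$offset, down$median_frac, xout = grid)$y
  if (sd(y) == 0)
    return(data.frame(period = NA_real_, autocorr = NA_real_,
                      detected = FALSE))
  ac <- acf(y, lag.max = max(lagRange), plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- seq(lagRange[1L], lagRange[2L])
  vals <- ac[lags + 1L]
  best <- which.max(vals)
  detected <- vals[best] >= minAutocorr
  data.frame(period = if (detected) lags[best] else NA_real_,
             autocorr = vals[best], detected = detected)
}
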