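## Independent oracles and fixture builders used across the suite.

## brute-force degeneracy: enumerate the 9 single-base substitutions of a
## codon and count amino-acid-preserving nucleotides per position, using
## seqinr's translation (an independent code path from the package)
oracleDegeneracy <- function(codon) {
  aa <- function(cod) seqinr::translate(strsplit(cod, "")[[1]])
  ref <- aa(codon)
  vapply(1:3, function(p) {
    n <- 0L
    for (b in c("A", "C", "G", "T")) {
      alt <- codon
      substr(alt, p, p) <- b
      if (aa(alt) == ref) n <- n + 1L
    }
    if (n == 1L) 0L else n
  }, integer(1))
}

senseCodons <- function() {
  cods <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}

## position-by-position window count scan (no interval arithmetic)
oracleWindowCounts <- function(positions, weights, chromLength, windowSize) {
  nw <- ceiling(chromLength / windowSize)
  out <- numeric(nw)
  for (i in seq_along(positions)) {
    w <- (positions[i] - 1) %/% windowSize + 1
    out[w] <- out[w] + weights[i]
  }
  out
}

## brute-force maximal het-free runs (direct scan over candidate gaps)
oracleLohScan <- function(hetPos, L, minLen) {
  hetPos <- sort(unique(hetPos))
  if (!length(hetPos)) return(data.frame(start = 0, end = L))
  gaps <- NULL
  ## before first, between consecutive, after last (0-based half-open
  ## interiors excluding the het sites themselves)
  edges <- c(0, hetPos, L + 1)
  for (i in seq_len(length(edges) - 1)) {
    s <- edges[i]; e <- edges[i + 1] - 1
    if (e - s >= minLen) gaps <- rbind(gaps, data.frame(start = s, end = e))
  }
  if (is.null(gaps)) data.frame(start = numeric(0), end = numeric(0)) else gaps
}

## independently coded primary-isoform cascade
oraclePrimary <- function(tx_id, read_count, cds_len) {
  oAb <- order(-read_count, tx_id)
  most <- oAb[1]
  maxCds <- max(cds_len)
  cand <- which(cds_len == maxCds)
  cand <- cand[order(-read_count[cand], tx_id[cand])]
  longest <- cand[1]
  if (read_count[longest] == read_count[most])
    return(list(id = tx_id[longest], rule = 1L))
  if (read_count[longest] >= 0.5 * read_count[most])
    return(list(id = tx_id[longest], rule = 2L))
  if (cds_len[most] >= 0.8 * maxCds)
    return(list(id = tx_id[most], rule = 3L))
  list(id = tx_id[longest], rule = 4L)
}

## exhaustive best split by residual sum of squares
oracleBestSplit <- function(x, minSeg) {
  n <- length(x)
  best <- NULL; bestRss <- Inf
  for (k in minSeg:(n - minSeg)) {
    rss <- sum((x[1:k] - mean(x[1:k]))^2) +
           sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
    if (rss < bestRss) { bestRss <- rss; best <- k }
  }
  best
}

## truth parent label of windows fully inside one truth-ancestry interval
truthWindowLabels <- function(ancestry, hap, chrom, starts, ends) {
  a <- ancestry[ancestry$haplotype == hap & ancestry$chrom == chrom, ,
                drop = FALSE]
  vapply(seq_along(starts), function(i) {
    hit <- a$start <= starts[i] & a$end >= ends[i]
    if (any(hit)) a$parent[which(hit)[1]] else NA_character_
  }, character(1))
}
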