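## Transcript-curation rules: gene decoupling, isoform filtering,
## primary-isoform selection, Kozak model and ORF extension, antisense
## lncRNA classification.

## ---- gene decoupling ----

#' Decouple wrongly merged gene models
#'
#' Isoform clustering can merge neighboring genes whenever any isoforms
#' overlap on the same strand. True genes are recovered as the connected
#' components of the graph whose edges join isoform pairs sharing at least
#' 1 bp of same-strand CDS genomic overlap; each component becomes one
#' gene. An isoform without CDS inside a coding group is assigned to the
#' component with maximal exonic overlap (reported via a message).
#'
#' @param transcripts data.frame `tx_id`, `gene_id` (initial grouping),
#'   `chrom`, `strand`.
#' @param cds data.frame `tx_id`, `start`, `end` (0-based half-open
#'   genomic CDS intervals; zero rows for a non-coding isoform).
#' @param exons like `cds` but for exons (used only for CDS-less
#'   isoforms; may be NULL if all isoforms have CDS).
#' @return data.frame `tx_id`, `gene_id`, `new_gene_id`.
#' @export
decoupleGenes <- function(transcripts, cds, exons = NULL) {
  res <- lapply(split(transcripts, transcripts$gene_id), function(tx) {
    n <- nrow(tx)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union2 <- function(i, j) parent[find(i)] <<- find(j)
    iv <- lapply(tx$tx_id, function(id) {
      c1 <- cds[cds$tx_id == id, , drop = FALSE]
      if (nrow(c1)) IRanges(c1$start + 1L, c1$end) else IRanges()
    })
    coding <- lengths(iv) > 0L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (coding[i] && coding[j] &&
          sum(width(pintersect(findOverlapPairs(iv[[i]], iv[[j]])))) > 0L)
        union2(i, j)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    ## CDS-less isoforms join the component with maximal exonic overlap
    for (i in which(!coding)) {
      if (is.null(exons)) next
      e1 <- exons[exons$tx_id == tx$tx_id[i], , drop = FALSE]
      if (!nrow(e1)) next
      ir1 <- IRanges(e1$start + 1L, e1$end)
      best <- 0L; bestOv <- -1L
      for (j in which(coding)) {
        e2 <- exons[exons$tx_id == tx$tx_id[j], , drop = FALSE]
        ir2 <- IRanges(e2$start + 1L, e2$end)
        ov <- sum(width(pintersect(findOverlapPairs(ir1, ir2))))
        if (ov > bestOv) { bestOv <- ov; best <- j }
      }
      if (best > 0L && bestOv > 0L) {
        message("non-coding isoform ", tx$tx_id[i],
                " assigned by exonic overlap")
        comp[i] <- comp[best]
      }
    }
    ids <- match(comp, unique(comp))
    data.frame(tx_id = tx$tx_id, gene_id = tx$gene_id,
               new_gene_id = paste0(tx$gene_id, ".", ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## ---- isoform filtering & primary selection ----

#' Filter isoforms by read support
#'
#' Removes isoforms supported by fewer than `minReads` reads or by less
#' than `minFraction` of the total reads of the gene, the total being
#' computed *before* any removal. If every isoform would be removed, the
#' most abundant one is rescued (reported via a message).
#'
#' @param isoforms data.frame with `tx_id`, `gene_id`, `read_count`.
#' @param minReads minimum absolute read support (default 5).
#' @param minFraction minimum fraction of the gene's total reads (default
#'   0.05).
#' @return the input with a logical `retained` column.
#' @examples
#' iso <- data.frame(gene_id = "g", tx_id = c("t1", "t2"),
#'                   read_count = c(100, 4))
#' filterIsoforms(iso)$retained  # TRUE FALSE
#' @export
filterIsoforms <- function(isoforms, minReads = 5, minFraction = 0.05) {
  if (all(isoforms$read_count == 0)) stop("all isoform read counts are zero")
  res <- lapply(split(isoforms, isoforms$gene_id), function(g) {
    total <- sum(g$read_count)
    keep <- g$read_count >= minReads & g$read_count / total >= minFraction
    if (!any(keep)) {
      top <- order(-g$read_count, g$tx_id)[1L]
      keep[top] <- TRUE
      message("gene ", g$gene_id[1L], ": most abundant isoform rescued")
    }
    g$retained <- keep
    g
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select the primary isoform of a gene
#'
#' Cascade combining read abundance and coding length:
#' \enumerate{
#'   \item if the longest-CDS isoform is also the most abundant, it is
#'     primary (equal CDS lengths: the most abundant among them; remaining
#'     ties broken by lexicographic id);
#'   \item otherwise the longest-CDS isoform is primary if its read count
#'     is at least 50\% of the most abundant isoform's;
#'   \item otherwise the most abundant isoform is primary if its CDS
#'     length is at least 80\% of the longest CDS;
#'   \item otherwise the longest-CDS isoform is primary (avoiding overly
#'     short isoforms, which can be overrepresented in full-length cDNA
#'     data).
#' }
#'
#' @param isoforms data.frame with `tx_id`, `read_count`, `cds_len` for
#'   one gene (post-filtering).
#' @return list with `tx_id` of the primary isoform and `rule` (1..4).
#' @export
selectPrimaryIsoform <- function(isoforms) {
  if (!nrow(isoforms)) stop("empty isoform set")
  o <- order(-isoforms$read_count, isoforms$tx_id)
  mostAbundant <- isoforms[o[1L], ]
  maxCds <- max(isoforms$cds_len)
  cand <- isoforms[isoforms$cds_len == maxCds, , drop = FALSE]
  cand <- cand[order(-cand$read_count, cand$tx_id), , drop = FALSE]
  longest <- cand[1L, ]
  if (longest$read_count == mostAbundant$read_count)
    return(list(tx_id = longest$tx_id, rule = 1L))
  if (longest$read_count >= 0.5 * mostAbundant$read_count)
    return(list(tx_id = longest$tx_id, rule = 2L))
  if (mostAbundant$cds_len >= 0.8 * maxCds)
    return(list(tx_id = mostAbundant$tx_id, rule = 3L))
  list(tx_id = longest$tx_id, rule = 4L)
}

## ---- Kozak model & ORF extension ----

.KOZAK_WINDOW <- c(-9:-1, 3:5)

#' Extract the initiation context of a start codon
#'
#' @param seq transcript sequence (character scalar).
#' @param start 1-based position of the A of ATG within `seq`.
#' @param window integer offsets relative to that A (default
#'   `c(-9:-1, 3:5)`).
#' @return character scalar of `length(window)` bases, or `NA` if the
#'   window extends beyond the sequence.
#' @export
kozakContext <- function(seq, start, window = .KOZAK_WINDOW) {
  pos <- start + window
  if (min(pos) < 1L || max(pos) > nchar(seq)) return(NA_character_)
  paste(substring(seq, pos, pos), collapse = "")
}

#' Build a Kozak position-weight model
#'
#' Trains per-offset nucleotide frequencies (pseudocount 1) from the
#' initiation contexts of a training set of transcripts — in the intended
#' use, primary transcripts whose 5' UTR contains no in-frame upstream ATG,
#' i.e. ORFs that could not be extended — and converts them to log-odds
#' (base 2) against background nucleotide frequencies. The score of a
#' context is the sum of its per-offset log-odds; the 25th percentile of
#' the training scores (`p25`, linear interpolation) is the ORF-extension
#' threshold.
#'
#' @param sequences character vector of transcript sequences.
#' @param starts 1-based CDS start positions (A of ATG), parallel to
#'   `sequences`.
#' @param window offsets relative to the start (default `c(-9:-1, 3:5)`).
#' @param background named background frequencies for A, C, G, T (default
#'   uniform; pass genome frequencies when available).
#' @return a [KozakModel-class].
#' @export
buildKozakModel <- function(sequences, starts, window = .KOZAK_WINDOW,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25)) {
  ctx <- vapply(seq_along(sequences), function(i)
    kozakContext(sequences[i], starts[i], window), character(1))
  skipped <- sum(is.na(ctx))
  if (skipped) message(skipped, " training transcript(s) skipped (context ",
                       "shorter than the window)")
  ctx <- ctx[!is.na(ctx)]
  if (!length(ctx)) stop("empty training set")
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4L, length(window), dimnames = list(bases, NULL))
  m <- do.call(rbind, strsplit(ctx, ""))
  for (j in seq_along(window))
    counts[, j] <- counts[, j] + tabulate(match(m[, j], bases), 4L)
  freq <- (counts + 1) / (length(ctx) + 4)
  logOdds <- log2(freq / background[bases])
  model <- new("KozakModel", window = as.integer(window),
               logOdds = logOdds, background = background[bases],
               trainingScores = numeric(0), p25 = NA_real_)
  scores <- vapply(ctx, function(cc) .scoreContext(model, cc), numeric(1),
                   USE.NAMES = FALSE)
  model@trainingScores <- scores
  model@p25 <- unname(quantile(scores, 0.25))
  validObject(model)
  model
}

.scoreContext <- function(model, context) {
  b <- strsplit(context, "")[[1L]]
  idx <- match(b, rownames(model@logOdds))
  if (anyNA(idx)) return(NA_real_)
  sum(model@logOdds[cbind(idx, seq_along(idx))])
}

#' Score an initiation context against a Kozak model
#'
#' @param model a [KozakModel-class].
#' @param seq transcript sequence, or a ready-made context string of
#'   window length when `start` is `NULL`.
#' @param start 1-based position of the A of ATG (optional).
#' @return additive log-odds score in bits (`NA` if the context is
#'   unavailable).
#' @export
scoreKozak <- function(model, seq, start = NULL) {
  ctx <- if (is.null(start)) seq
         else kozakContext(seq, start, model@window)
  if (is.na(ctx)) return(NA_real_)
  .scoreContext(model, ctx)
}

## in-frame upstream ATG candidates with no intervening in-frame stop
.upstreamCandidates <- function(seq, cdsStart) {
  cands <- integer(0)
  u <- cdsStart - 3L
  blocked <- FALSE
  while (u >= 1L && !blocked) {
    cod <- substr(seq, u, u + 2L)
    if (cod %in% .STOPS) blocked <- TRUE
    else {
      if (cod == "ATG") cands <- c(u, cands)   # keep 5'-most first
      u <- u - 3L
    }
  }
  cands
}

#' Extend an ORF to an upstream in-frame start codon
#'
#' Candidate starts are in-frame upstream ATGs with no in-frame stop codon
#' between candidate and annotated start. Scanning from the 5'-most
#' candidate, the CDS is extended to the first candidate whose Kozak score
#' exceeds the model's training-score 25th percentile, or exceeds the
#' score of the annotated start itself. Re-running with the same model
#' extends nothing further.
#'
#' @param seq transcript sequence (character scalar).
#' @param cdsStart 1-based annotated CDS start within the transcript.
#' @param model a [KozakModel-class].
#' @param rule `"first"` (5'-most qualifying candidate, the default,
#'   maximal extension) or `"best"` (highest-scoring qualifying
#'   candidate).
#' @return list: `cds_start` (possibly moved), `extended` (logical),
#'   `annotated_score`, and `candidates` (data.frame `pos`, `score`,
#'   `qualifies`).
#' @export
extendOrf <- function(seq, cdsStart, model, rule = c("first", "best")) {
  rule <- match.arg(rule)
  cands <- .upstreamCandidates(seq, cdsStart)
  annScore <- scoreKozak(model, seq, cdsStart)
  if (!length(cands))
    return(list(cds_start = cdsStart, extended = FALSE,
                annotated_score = annScore,
                candidates = data.frame(pos = integer(0), score = numeric(0),
                                        qualifies = logical(0))))
  scores <- vapply(cands, function(u) scoreKozak(model, seq, u), numeric(1))
  qual <- !is.na(scores) &
    (scores > model@p25 | (!is.na(annScore) & scores > annScore))
  newStart <- cdsStart
  if (any(qual)) {
    newStart <- if (rule == "first") cands[which(qual)[1L]]
                else cands[which(qual)[which.max(scores[qual])]]
  }
  list(cds_start = newStart, extended = newStart != cdsStart,
       annotated_score = annScore,
       candidates = data.frame(pos = cands, score = scores,
                               qualifies = qual))
}

## ---- antisense lncRNA classification ----

.txLengthFromExons <- function(ex) sum(ex$end - ex$start)

.txTss <- function(tx, exons) {
  ex <- exons[exons$tx_id == tx$tx_id, , drop = FALSE]
  if (tx$strand == "+") min(ex$start) else max(ex$end) - 1L
}

#' Classify antisense lncRNA relationships
#'
#' For each protein-coding transcript, finds opposite-strand lncRNAs whose
#' exonic overlap covers at least `minOverlap` of the mRNA transcript
#' length (sum of exon widths). Each call carries a promoter class:
#' `bidirectional_internal` if the lncRNA TSS lies inside the mRNA gene
#' body and a sense isoform TSS of the same gene lies within
#' `promoterWindow` bp of it (a divergent internal promoter);
#' `unidirectional_internal` if the lncRNA TSS is inside the gene body
#' otherwise; `adjacent` if the lncRNA TSS falls within `promoterWindow`
#' of the gene body (or beyond, for a qualifying overlap from outside).
#'
#' @param mrna data.frame of coding transcripts: `tx_id`, `gene_id`,
#'   `chrom`, `strand`.
#' @param mrnaExons exon table (`tx_id`, `start`, `end`), 0-based
#'   half-open.
#' @param lnc,lncExons same for the lncRNA models.
#' @param minOverlap minimum antisense overlap fraction (default 0.30;
#'   0.29 yields no call, 0.30 does).
#' @param promoterWindow promoter pairing distance in bp (default 300).
#' @return data.frame `mrna_id`, `lnc_id`, `overlap_fraction`,
#'   `promoter_class`.
#' @export
classifyAntisense <- function(mrna, mrnaExons, lnc, lncExons,
                              minOverlap = 0.30, promoterWindow = 300) {
  if (anyNA(mrna$strand) || anyNA(lnc$strand)) stop("strand missing")
  calls <- NULL
  for (i in seq_len(nrow(mrna))) {
    mex <- mrnaExons[mrnaExons$tx_id == mrna$tx_id[i], , drop = FALSE]
    mIR <- reduce(IRanges(mex$start + 1L, mex$end))
    mLen <- sum(width(mIR))
    ## gene body over all isoforms of the gene
    gTx <- mrna$tx_id[mrna$gene_id == mrna$gene_id[i]]
    gex <- mrnaExons[mrnaExons$tx_id %in% gTx, , drop = FALSE]
    body <- c(min(gex$start), max(gex$end))
    for (j in seq_len(nrow(lnc))) {
      if (lnc$chrom[j] != mrna$chrom[i] ||
          lnc$strand[j] == mrna$strand[i]) next
      lex <- lncExons[lncExons$tx_id == lnc$tx_id[j], , drop = FALSE]
      lIR <- reduce(IRanges(lex$start + 1L, lex$end))
      ov <- sum(width(pintersect(findOverlapPairs(mIR, lIR))))
      fr <- ov / mLen
      if (fr < minOverlap) next
      lncTss <- .txTss(lnc[j, ], lncExons)
      inside <- lncTss >= body[1L] && lncTss < body[2L]
      cls <- if (inside) {
        senseTss <- vapply(gTx, function(id)
          .txTss(mrna[mrna$tx_id == id, ], mrnaExons), numeric(1))
        if (any(abs(senseTss - lncTss) <= promoterWindow))
          "bidirectional_internal" else "unidirectional_internal"
      } else if (lncTss >= body[1L] - promoterWindow &&
                 lncTss < body[2L] + promoterWindow) {
        "adjacent"
      } else "adjacent"
      calls <- rbind(calls, data.frame(
        mrna_id = mrna$tx_id[i], lnc_id = lnc$tx_id[j],
        overlap_fraction = fr, promoter_class = cls,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(calls))
    calls <- data.frame(mrna_id = character(0), lnc_id = character(0),
                        overlap_fraction = numeric(0),
                        promoter_class = character(0))
  rownames(calls) <- NULL
  calls
}
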