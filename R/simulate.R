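## Synthetic allodiploid genome generator.
##
## Sequences are manipulated internally as raw byte vectors (ASCII A/C/G/T)
## for speed; DNAStringSet only at the object boundary. Substitutions only
## (no indels), so the ancestor, the four parental haplotypes and the two
## hybrid haplotypes share one coordinate system.

.randSeqRaw <- function(L, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  .RAW_BASES[sample.int(4L, L, replace = TRUE, prob = p)]
}

## substitute each base independently with probability `rate`, new base
## uniform over the three alternatives
.mutateRaw <- function(r, rate) {
  if (rate <= 0) return(r)
  pos <- which(runif(length(r)) < rate)
  if (!length(pos)) return(r)
  cur <- match(r[pos], .RAW_BASES)
  r[pos] <- .RAW_BASES[(cur - 1L + sample.int(3L, length(pos), replace = TRUE)) %% 4L + 1L]
  r
}

.rawToDss <- function(lst) {
  DNAStringSet(vapply(lst, rawToChar, character(1)))
}

.dssToRaw <- function(dss) {
  out <- lapply(as.character(dss), charToRaw)
  names(out) <- names(dss)
  out
}

## ---- event validation (shared with SimulationConfig validity) ----

.EVENT_TYPES <- c("crossover", "loh_interstitial", "loh_terminal",
                  "loh_whole_chromosome", "aneuploidy_whole",
                  "aneuploidy_partial")

.validateEvents <- function(events, chromLengths) {
  msg <- character(0)
  lohIv <- list()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (is.null(ev$type) || !ev$type %in% .EVENT_TYPES) {
      msg <- c(msg, sprintf("event %d: unknown type '%s'", i, ev$type))
      next
    }
    if (is.null(ev$chrom) || !ev$chrom %in% names(chromLengths)) {
      msg <- c(msg, sprintf("event %d: unknown chromosome '%s'", i, ev$chrom))
      next
    }
    L <- chromLengths[[ev$chrom]]
    switch(ev$type,
      crossover = {
        if (is.null(ev$pos) || ev$pos <= 0 || ev$pos >= L)
          msg <- c(msg, sprintf("event %d: crossover position outside (0, L)", i))
      },
      loh_interstitial = ,
      loh_terminal = {
        if (is.null(ev$start) || is.null(ev$end) ||
            ev$start < 0 || ev$end > L || ev$start >= ev$end) {
          msg <- c(msg, sprintf("event %d: interval outside chromosome", i))
        } else {
          if (ev$type == "loh_terminal" && ev$start != 0 && ev$end != L)
            msg <- c(msg, sprintf("event %d: terminal LOH must touch a chromosome end", i))
          if (ev$type == "loh_interstitial" && (ev$start == 0 || ev$end == L))
            msg <- c(msg, sprintf("event %d: interstitial LOH must not touch a chromosome end", i))
          lohIv[[length(lohIv) + 1L]] <- c(ev$chrom, ev$start, ev$end)
        }
      },
      loh_whole_chromosome = {
        lohIv[[length(lohIv) + 1L]] <- c(ev$chrom, 0, L)
      },
      aneuploidy_whole = ,
      aneuploidy_partial = {
        if (is.null(ev$haplotype) || !ev$haplotype %in% c("A", "B"))
          msg <- c(msg, sprintf("event %d: aneuploidy needs haplotype 'A' or 'B'", i))
        if (is.null(ev$copies) || ev$copies < 0)
          msg <- c(msg, sprintf("event %d: copies must be >= 0", i))
        if (ev$type == "aneuploidy_partial" &&
            (is.null(ev$start) || is.null(ev$end) ||
             ev$start < 0 || ev$end > L || ev$start >= ev$end))
          msg <- c(msg, sprintf("event %d: interval outside chromosome", i))
      })
  }
  ## conflicting (overlapping) sequence-altering events on one chromosome
  if (length(lohIv) > 1L) {
    iv <- do.call(rbind, lohIv)
    for (ch in unique(iv[, 1L])) {
      sub <- iv[iv[, 1L] == ch, , drop = FALSE]
      if (nrow(sub) > 1L) {
        o <- order(as.numeric(sub[, 2L]))
        s <- as.numeric(sub[o, 2L]); e <- as.numeric(sub[o, 3L])
        if (any(s[-1L] < e[-length(e)]))
          msg <- c(msg, sprintf("overlapping LOH events on chromosome %s", ch))
      }
    }
  }
  if (length(msg)) msg else NULL
}

## ---- interval-table helpers (0-based half-open, one value column) ----

.ivSplit <- function(df, pos) {
  hit <- df$start < pos & df$end > pos
  if (!any(hit)) return(df)
  up <- df[hit, , drop = FALSE]; up$end <- pos
  dn <- df[hit, , drop = FALSE]; dn$start <- pos
  out <- rbind(df[!hit, , drop = FALSE], up, dn)
  out[order(out$start), , drop = FALSE]
}

.ivMerge <- function(df, valueCol) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$start), , drop = FALSE]
  keep <- logical(nrow(df)); keep[1L] <- TRUE
  j <- 1L
  for (i in 2:nrow(df)) {
    if (df$start[i] == df$end[j] && identical(df[[valueCol]][i], df[[valueCol]][j])) {
      df$end[j] <- df$end[i]
    } else {
      j <- i; keep[i] <- TRUE
      df[j, ] <- df[i, ]
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## overwrite [start,end) of `df` with the corresponding slice of `src`
.ivAssignFrom <- function(df, src, start, end, valueCol) {
  df <- .ivSplit(.ivSplit(df, start), end)
  src <- .ivSplit(.ivSplit(src, start), end)
  keep <- df[df$end <= start | df$start >= end, , drop = FALSE]
  ins <- src[src$start >= start & src$end <= end, , drop = FALSE]
  .ivMerge(rbind(keep, ins), valueCol)
}

## set [start,end) of `df` to a constant value
.ivSetValue <- function(df, start, end, value, valueCol) {
  df <- .ivSplit(.ivSplit(df, start), end)
  inside <- df$start >= start & df$end <= end
  df[[valueCol]][inside] <- value
  .ivMerge(df, valueCol)
}

## ---- operations ----

#' Simulate two divergent parental diploids from a common ancestor
#'
#' Generates an ancestral sequence per chromosome at the configured GC
#' content, then derives parent P (haplotypes P1, P2) and parent S
#' (haplotypes S1, S2) by independent per-site substitution: P1 and S1
#' diverge from the ancestor at rates `divP` and `divS`, and the second
#' haplotype of each parent carries an additional substitution layer at the
#' within-parent heterozygosity rate (`hetP`, `hetS`). Substitutions only,
#' so all six sequences share one coordinate system.
#'
#' @param config a [SimulationConfig-class].
#' @param setSeed set the RNG from `config@seed` first (default TRUE).
#' @return named list of `DNAStringSet`s: `ancestor`, `P1`, `P2`, `S1`, `S2`.
#' @examples
#' cfg <- simulationConfig(c(chr01 = 10000L), seed = 1L)
#' par <- simulateParentHaplotypes(cfg)
#' names(par)
#' @export
simulateParentHaplotypes <- function(config, setSeed = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (setSeed) set.seed(config@seed)
  cl <- config@chromLengths
  anc <- lapply(cl, .randSeqRaw, gc = config@gcContent)
  p1 <- lapply(anc, .mutateRaw, rate = config@divP)
  p2 <- lapply(p1, .mutateRaw, rate = config@hetP)
  s1 <- lapply(anc, .mutateRaw, rate = config@divS)
  s2 <- lapply(s1, .mutateRaw, rate = config@hetS)
  list(ancestor = .rawToDss(anc), P1 = .rawToDss(p1), P2 = .rawToDss(p2),
       S1 = .rawToDss(s1), S2 = .rawToDss(s2))
}

#' Apply planted hybrid events and build the truth log
#'
#' Initializes hybrid haplotype A from parental haplotype P1 and haplotype B
#' from S1 on every chromosome, then applies the event list in order:
#'
#' * `crossover` (`chrom`, `pos`): reciprocally exchanges the suffixes
#'   `[pos, L)` of A and B (0-based breakpoint).
#' * `loh_interstitial` / `loh_terminal` (`chrom`, `start`, `end`,
#'   `donor` = "A" or "B"): copies the donor haplotype's interval onto the
#'   other haplotype (0-based half-open).
#' * `loh_whole_chromosome` (`chrom`, `donor`): copies the whole chromosome.
#' * `aneuploidy_whole` / `aneuploidy_partial` (`chrom`, `haplotype`,
#'   `copies`, and `start`/`end` for partial): records the copy number in
#'   the truth log; depth emission multiplies accordingly.
#'
#' The truth log records parent-of-origin intervals per haplotype (which
#' crossovers and LOH rewrite), exact LOH tract coordinates with class,
#' crossover breakpoints, and per-base copy number.
#'
#' @param parents list as returned by [simulateParentHaplotypes()].
#' @param events list of event specifications (see above).
#' @param config the [SimulationConfig-class] (stored in the result; its
#'   `events` slot is ignored in favor of `events`).
#' @return a [HybridSim-class] object.
#' @export
applyHybridEvents <- function(parents, events, config) {
  stopifnot(is(config, "SimulationConfig"))
  cl <- config@chromLengths
  bad <- .validateEvents(events, cl)
  if (!is.null(bad)) stop(paste(bad, collapse = "; "))

  A <- .dssToRaw(parents$P1)
  B <- .dssToRaw(parents$S1)
  chroms <- names(cl)

  ancA <- lapply(chroms, function(ch)
    data.frame(start = 0, end = cl[[ch]], parent = "P", stringsAsFactors = FALSE))
  ancB <- lapply(chroms, function(ch)
    data.frame(start = 0, end = cl[[ch]], parent = "S", stringsAsFactors = FALSE))
  names(ancA) <- names(ancB) <- chroms

  cn <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(haplotype = c("A", "B"), chrom = ch, start = 0,
               end = cl[[ch]], copies = 1L, stringsAsFactors = FALSE)))

  crossovers <- data.frame(chrom = character(0), pos = numeric(0))
  loh <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                    donor = character(0), class = character(0))

  for (ev in events) {
    ch <- ev$chrom; L <- cl[[ch]]
    if (ev$type == "crossover") {
      x <- as.integer(ev$pos)
      idx <- (x + 1L):L
      tmp <- A[[ch]][idx]; A[[ch]][idx] <- B[[ch]][idx]; B[[ch]][idx] <- tmp
      sa <- ancA[[ch]]; sb <- ancB[[ch]]
      ancA[[ch]] <- .ivAssignFrom(sa, sb, x, L, "parent")
      ancB[[ch]] <- .ivAssignFrom(sb, sa, x, L, "parent")
      crossovers <- rbind(crossovers, data.frame(chrom = ch, pos = x))
    } else if (ev$type %in% c("loh_interstitial", "loh_terminal",
                              "loh_whole_chromosome")) {
      s <- if (ev$type == "loh_whole_chromosome") 0L else as.integer(ev$start)
      e <- if (ev$type == "loh_whole_chromosome") L else as.integer(ev$end)
      donor <- ev$donor
      idx <- (s + 1L):e
      if (donor == "A") {
        B[[ch]][idx] <- A[[ch]][idx]
        ancB[[ch]] <- .ivAssignFrom(ancB[[ch]], ancA[[ch]], s, e, "parent")
      } else {
        A[[ch]][idx] <- B[[ch]][idx]
        ancA[[ch]] <- .ivAssignFrom(ancA[[ch]], ancB[[ch]], s, e, "parent")
      }
      cls <- classifyTract(s, e, L)
      loh <- rbind(loh, data.frame(chrom = ch, start = s, end = e,
                                   donor = donor, class = cls))
    } else if (ev$type == "aneuploidy_whole") {
      hap <- ev$haplotype
      cnh <- cn[cn$haplotype == hap & cn$chrom == ch, , drop = FALSE]
      rest <- cn[!(cn$haplotype == hap & cn$chrom == ch), , drop = FALSE]
      cnh <- .ivSetValue(cnh, 0, L, as.integer(ev$copies), "copies")
      cnh$haplotype <- hap; cnh$chrom <- ch
      cn <- rbind(rest, cnh)
    } else if (ev$type == "aneuploidy_partial") {
      hap <- ev$haplotype
      cnh <- cn[cn$haplotype == hap & cn$chrom == ch, , drop = FALSE]
      rest <- cn[!(cn$haplotype == hap & cn$chrom == ch), , drop = FALSE]
      cnh <- .ivSetValue(cnh, as.integer(ev$start), as.integer(ev$end),
                         as.integer(ev$copies), "copies")
      cnh$haplotype <- hap; cnh$chrom <- ch
      cn <- rbind(rest, cnh)
    }
  }

  cn <- cn[order(cn$haplotype, match(cn$chrom, chroms), cn$start), ]
  rownames(cn) <- NULL

  ancestry <- do.call(rbind, c(
    lapply(chroms, function(ch)
      cbind(haplotype = "A", chrom = ch, ancA[[ch]])),
    lapply(chroms, function(ch)
      cbind(haplotype = "B", chrom = ch, ancB[[ch]]))))
  ancestry <- ancestry[, c("haplotype", "chrom", "start", "end", "parent")]
  rownames(ancestry) <- NULL

  truth <- list(ancestry = ancestry, crossovers = crossovers, loh = loh,
                copyNumber = cn, events = events)
  new("HybridSim", haplA = .rawToDss(A), haplB = .rawToDss(B),
      parents = parents, truth = truth, config = config)
}

#' Simulate a complete hybrid genome
#'
#' Seeds the RNG from the configuration, simulates the parental lineages
#' and applies the configured planted events. With a fixed seed the result
#' (and every file written from it) is byte-identical across runs.
#'
#' @param config a [SimulationConfig-class].
#' @return a [HybridSim-class].
#' @examples
#' cfg <- simulationConfig(c(chr01 = 20000L),
#'   events = list(list(type = "crossover", chrom = "chr01", pos = 10000)),
#'   seed = 42L)
#' sim <- simulateHybridGenome(cfg)
#' truthLog(sim)$crossovers
#' @export
simulateHybridGenome <- function(config) {
  parents <- simulateParentHaplotypes(config, setSeed = TRUE)
  applyHybridEvents(parents, config@events, config)
}

#' Coordinate-wise difference sites between two aligned sequence sets
#'
#' Compares two `DNAStringSet`s chromosome by chromosome (equal names and
#' widths required; the simulator guarantees shared coordinates) and returns
#' one variant record per mismatching position.
#'
#' @param a,b `DNAStringSet`s with identical names and widths.
#' @param zygosity label for the emitted sites: `"heterozygous"` for a
#'   self-comparison of the two haplotypes of one individual,
#'   `"homozygous_diff"` for a haplotype-vs-haploid-reference comparison.
#' @param quality quality value assigned to each site (default 60).
#' @return data.frame with columns `chrom`, `pos` (1-based), `zygosity`,
#'   `quality`.
#' @export
diffSites <- function(a, b, zygosity = c("heterozygous", "homozygous_diff"),
                      quality = 60L) {
  zygosity <- match.arg(zygosity)
  stopifnot(identical(names(a), names(b)),
            identical(Biostrings::width(a), Biostrings::width(b)))
  ra <- .dssToRaw(a); rb <- .dssToRaw(b)
  recs <- lapply(names(ra), function(ch) {
    pos <- which(ra[[ch]] != rb[[ch]])
    if (!length(pos)) return(NULL)
    data.frame(chrom = ch, pos = pos, zygosity = zygosity,
               quality = as.integer(quality), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      zygosity = character(0), quality = integer(0))
  rownames(out) <- NULL
  out
}

#' Emit the heterozygous-variant table of a simulated hybrid
#'
#' One heterozygous site per position where haplotypes A and B differ,
#' dropped with probability `falseNegativeRate`; spurious heterozygous
#' sites added at `falsePositiveRate` per base. Stands in for an upstream
#' variant caller.
#'
#' @param sim a [HybridSim-class].
#' @param falseNegativeRate,falsePositiveRate rates in \[0,1\].
#' @param quality quality value for emitted sites (default 60).
#' @return data.frame as in [diffSites()], sorted by chromosome and
#'   position.
#' @export
emitVariantTable <- function(sim, falseNegativeRate = 0,
                             falsePositiveRate = 0, quality = 60L) {
  stopifnot(falseNegativeRate >= 0, falseNegativeRate <= 1,
            falsePositiveRate >= 0, falsePositiveRate <= 1)
  v <- diffSites(sim@haplA, sim@haplB, zygosity = "heterozygous",
                 quality = quality)
  if (falseNegativeRate > 0 && nrow(v))
    v <- v[runif(nrow(v)) >= falseNegativeRate, , drop = FALSE]
  if (falsePositiveRate > 0) {
    cl <- chromLengths(sim)
    fp <- lapply(names(cl), function(ch) {
      n <- rbinom(1L, cl[[ch]], falsePositiveRate)
      if (n == 0L) return(NULL)
      taken <- v$pos[v$chrom == ch]
      pool <- setdiff(sample.int(cl[[ch]], min(cl[[ch]], n * 2L + 10L)), taken)
      if (!length(pool)) return(NULL)
      data.frame(chrom = ch, pos = sort(pool[seq_len(min(n, length(pool)))]),
                 zygosity = "heterozygous", quality = as.integer(quality),
                 stringsAsFactors = FALSE)
    })
    v <- rbind(v, do.call(rbind, fp))
  }
  v <- v[order(match(v$chrom, names(chromLengths(sim))), v$pos), , drop = FALSE]
  rownames(v) <- NULL
  v
}

## negative binomial depth, Poisson at dispersion 0
.simDepth <- function(mu, dispersion) {
  if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  else rpois(length(mu), mu)
}

#' Simulate a per-base read-depth track from a copy-number specification
#'
#' Depth at each base is drawn with mean `depthMean` times the true copy
#' number of that base, negative-binomially with overdispersion
#' `depthDispersion` (Poisson when 0).
#'
#' @param copyNumber data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `copies`, and optionally `haplotype` (in which
#'   case track names are `<haplotype>_<chrom>`).
#' @param chromLengths named lengths of the chromosomes referenced.
#' @param depthMean expected depth per copy.
#' @param depthDispersion overdispersion (0 = Poisson).
#' @return named list of integer per-base depth vectors.
#' @export
simulateDepthTrack <- function(copyNumber, chromLengths, depthMean = 50,
                               depthDispersion = 0) {
  stopifnot(depthMean >= 0)
  hasHap <- "haplotype" %in% names(copyNumber)
  key <- if (hasHap) paste(copyNumber$haplotype, copyNumber$chrom, sep = "_")
         else copyNumber$chrom
  keyLen <- if (hasHap) {
    u <- unique(data.frame(k = key, chrom = copyNumber$chrom))
    setNames(chromLengths[u$chrom], u$k)
  } else chromLengths[unique(copyNumber$chrom)]
  out <- lapply(names(keyLen), function(k) {
    L <- keyLen[[k]]
    copies <- rep.int(1, L)
    sub <- copyNumber[key == k, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      copies[(sub$start[i] + 1L):sub$end[i]] <- sub$copies[i]
    .simDepth(depthMean * copies, depthDispersion)
  })
  names(out) <- names(keyLen)
  out
}

#' Emit the read-depth track of a simulated hybrid
#'
#' Wrapper around [simulateDepthTrack()] using the truth-log copy numbers;
#' one track per haplotype chromosome, named `A_<chrom>` / `B_<chrom>`
#' (phased-assembly convention: a normal chromosome has 1 copy per
#' haplotype).
#'
#' @param sim a [HybridSim-class].
#' @param depthMean,depthDispersion override the configured depth model.
#' @return named list of integer per-base depth vectors.
#' @export
emitCoverageTrack <- function(sim, depthMean = NULL, depthDispersion = NULL) {
  cfg <- sim@config
  simulateDepthTrack(truthLog(sim)$copyNumber, chromLengths(sim),
                     depthMean = depthMean %||% cfg@depthMean,
                     depthDispersion = depthDispersion %||% cfg@depthDispersion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
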