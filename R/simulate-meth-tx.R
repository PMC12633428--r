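## Simulator: methylation observables and transcript models.

#' Methylation-fraction template around a TSS
#'
#' The generative template of modification fraction as a function of offset
#' from the TSS (TSS at 0, downstream positive). Hypomethylated promoter:
#' near-zero baseline upstream of and at the TSS. 6mA (ApT context): two
#' nucleosome-linker peaks centered at `period` and `2 * period`. 5mC (CpG
#' context): linker peaks from `3 * period` onward with heights rising
#' geometrically to `plateau`. Peaks are Gaussian bumps (sd `sigma`) on the
#' fraction scale, clipped to \[0,1\].
#'
#' @param offset integer vector of offsets relative to the TSS.
#' @param context `"CpG"` (5mC) or `"ApT"` (6mA).
#' @param period linker spacing in bp (default 180).
#' @param plateau maximum 5mC fraction (default 0.95).
#' @param sigma peak standard deviation in bp (default 20).
#' @param baseline background modification fraction (default 0.02).
#' @param peak6mA height of the two 6mA peaks (default 0.5).
#' @return numeric vector of modification fractions.
#' @examples
#' methTemplate(c(-500, 180, 360, 900), "ApT")
#' @export
methTemplate <- function(offset, context = c("CpG", "ApT"), period = 180,
                         plateau = 0.95, sigma = 20, baseline = 0.02,
                         peak6mA = 0.5) {
  context <- match.arg(context)
  stopifnot(period > 0, plateau >= 0, plateau <= 1)
  f <- rep(baseline, length(offset))
  gauss <- function(center) exp(-(offset - center)^2 / (2 * sigma^2))
  if (context == "ApT") {
    f <- f + peak6mA * (gauss(period) + gauss(2 * period))
  } else {
    kmax <- max(3L, ceiling(max(c(offset, 0)) / period) + 1L)
    for (k in 3:kmax)
      f <- f + plateau * (1 - 0.5^(k - 2)) * gauss(k * period)
  }
  pmin(pmax(f, 0), 1)
}

#' Emit per-site modification calls and TSS records
#'
#' Lays out `nGenes` genes (alternating strand) on one synthetic
#' chromosome, spaced so that metaprofile windows never overlap, places
#' CpG and ApT sites at density `siteDensity` per bp within each gene's
#' window, and draws modified-read counts binomially from the
#' [methTemplate()] fraction at each site's strand-aware TSS offset, with
#' per-site read numbers Poisson around the configured coverage.
#'
#' @param config a [SimulationConfig-class] (supplies `methPeriod`,
#'   `methPlateau`, `readsPerSiteMean`).
#' @param nGenes number of genes (default 2000).
#' @param flankUp,flankDown window extent around each TSS in bp.
#' @param siteDensity per-bp probability that a position carries a site of
#'   each context (default 0.05).
#' @return list with elements `sites` (data.frame `chrom`, `pos` 0-based,
#'   `context`, `n_reads`, `n_mod`, `frac`), `tss` (data.frame `chrom`,
#'   `pos` 0-based, `strand`, `gene_id`, `high_confidence`) and `template`
#'   (the template parameters).
#' @export
emitMethylation <- function(config, nGenes = 2000, flankUp = 1000,
                            flankDown = 3000, siteDensity = 0.05) {
  stopifnot(is(config, "SimulationConfig"), nGenes >= 1)
  span <- flankUp + flankDown + 201L
  strand <- rep(c("+", "-"), length.out = nGenes)
  block <- (seq_len(nGenes) - 1L) * span
  tssPos <- ifelse(strand == "+", block + flankUp + 100L,
                   block + flankDown + 100L)
  tss <- data.frame(chrom = "methchr", pos = tssPos, strand = strand,
                    gene_id = sprintf("G%04d", seq_len(nGenes)),
                    high_confidence = TRUE, stringsAsFactors = FALSE)

  width <- flankUp + flankDown + 1L
  offGrid <- seq(-flankUp, flankDown)
  makeSites <- function(context) {
    hit <- which(runif(nGenes * width) < siteDensity)
    gi <- (hit - 1L) %/% width + 1L
    off <- offGrid[(hit - 1L) %% width + 1L]
    pos <- ifelse(strand[gi] == "+", tssPos[gi] + off, tssPos[gi] - off)
    f <- methTemplate(off, context, period = config@methPeriod,
                      plateau = config@methPlateau)
    nReads <- rpois(length(hit), config@readsPerSiteMean)
    nMod <- rbinom(length(hit), nReads, f)
    data.frame(chrom = "methchr", pos = pos, context = context,
               n_reads = nReads, n_mod = nMod,
               frac = ifelse(nReads > 0, nMod / nReads, NA_real_),
               stringsAsFactors = FALSE)
  }
  sites <- rbind(makeSites("CpG"), makeSites("ApT"))
  sites <- sites[order(sites$context, sites$pos), ]
  rownames(sites) <- NULL
  list(sites = sites, tss = tss,
       template = list(period = config@methPeriod,
                       plateau = config@methPlateau, sigma = 20,
                       baseline = 0.02, peak6mA = 0.5,
                       chromLength = nGenes * span))
}

## ---- transcript models with designed isoform mixtures & Kozak contexts ----

.CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0), c("A", "C", "G", "T"), paste0))
.STOPS <- c("TAA", "TAG", "TGA")
.UPSTREAM_POOL <- setdiff(.CODONS, c(.STOPS, "ATG"))
.BODY_POOL <- setdiff(.CODONS, .STOPS)

.KOZAK_CONS_UP <- "GCCGCCACC"   # offsets -9..-1
.KOZAK_CONS_DOWN <- "GCG"       # offsets +3..+5

.sampleContextBases <- function(consensus, pMatch) {
  cons <- strsplit(consensus, "")[[1]]
  vapply(cons, function(b) {
    if (runif(1) < pMatch) b else sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1), USE.NAMES = FALSE)
}

## strong/weak Kozak context; frame-aligned codons may contain neither ATG
## nor a stop so planted candidates stay unambiguous
.sampleContext <- function(strength = c("strong", "weak"), pMatch = 0.9) {
  strength <- match.arg(strength)
  consUp <- if (strength == "strong") .KOZAK_CONS_UP else "TTTTTTTTT"
  consDn <- if (strength == "strong") .KOZAK_CONS_DOWN else "TTT"
  repeat {
    up <- paste(.sampleContextBases(consUp, pMatch), collapse = "")
    dn <- paste(.sampleContextBases(consDn, pMatch), collapse = "")
    cod <- c(substring(up, c(1, 4, 7), c(3, 6, 9)), dn)
    if (!any(cod %in% c(.STOPS, "ATG"))) return(list(up = up, down = dn))
  }
}

.codonRun <- function(n, pool) paste(sample(pool, n, replace = TRUE),
                                     collapse = "")

## Designed isoform-mixture scenarios; each scenario's correct outcome
## under the read-support filter and the primary-isoform cascade is known
## by construction.
.ISO_SCENARIOS <- list(
  rule1       = list(cds = c(300, 200), reads = c(50, 10),  primary = 1L),
  rule2       = list(cds = c(300, 250), reads = c(30, 50),  primary = 1L),
  rule3       = list(cds = c(300, 280), reads = c(10, 100), primary = 2L),
  rule4       = list(cds = c(300, 200), reads = c(20, 50),  primary = 1L),
  filter_reads = list(cds = c(300, 150), reads = c(100, 4), primary = 1L,
                      dropped = 2L),
  filter_frac  = list(cds = c(300, 150), reads = c(100, 5), primary = 1L,
                      dropped = 2L),
  filter_keep  = list(cds = c(300, 350), reads = c(95, 5),  primary = 2L)
)

#' Emit synthetic transcript models with designed truth
#'
#' Two independent sets:
#'
#' * **Isoform mixtures** — genes whose isoform read counts and CDS lengths
#'   instantiate each branch of the read-support filter and the
#'   primary-isoform selection cascade, with the correct outcome recorded.
#' * **Kozak transcripts** — transcript-coordinate sequences in three
#'   classes: `training` (no in-frame upstream ATG; strong initiation
#'   context), `extension` (a weak annotated start with a single strong
#'   in-frame upstream ATG and no intervening in-frame stop; the upstream
#'   position is the true start), and `negative` (a strong annotated start
#'   with a weak upstream candidate; must not be extended).
#'
#' @param config a [SimulationConfig-class] (unused fields tolerated; kept
#'   so emission shares one configuration object).
#' @param nIsoformGenes number of isoform-mixture genes (default 70).
#' @param nTraining,nExtension,nNegative sizes of the Kozak classes.
#' @return list with `isoforms` (data.frame `gene_id`, `tx_id`,
#'   `read_count`, `cds_len`, `scenario`, `truth_retained`,
#'   `truth_primary`) and `kozak` (data.frame `tx_id`, `class`, `seq`,
#'   `cds_start` 1-based within the transcript, `truth_ext_start`,
#'   `read_count`).
#' @export
emitTranscripts <- function(config, nIsoformGenes = 70, nTraining = 120,
                            nExtension = 40, nNegative = 40) {
  stopifnot(is(config, "SimulationConfig"))
  scen <- rep(names(.ISO_SCENARIOS), length.out = nIsoformGenes)
  iso <- do.call(rbind, lapply(seq_len(nIsoformGenes), function(i) {
    sc <- .ISO_SCENARIOS[[scen[i]]]
    k <- length(sc$cds)
    data.frame(gene_id = sprintf("IG%03d", i),
               tx_id = sprintf("IG%03d.%d", i, seq_len(k)),
               read_count = sc$reads, cds_len = sc$cds, scenario = scen[i],
               truth_retained = !(seq_len(k) %in% (sc$dropped %||% integer(0))),
               truth_primary = seq_len(k) == sc$primary,
               stringsAsFactors = FALSE)
  }))

  mkTx <- function(class, i) {
    k1 <- sample(4:10, 1L)
    body <- .codonRun(sample(20:50, 1L), .BODY_POOL)
    stopCod <- sample(.STOPS, 1L)
    u <- .codonRun(k1, .UPSTREAM_POOL)
    if (class == "training") {
      ctx <- .sampleContext("strong")
      seq <- paste0(u, ctx$up, "ATG", ctx$down, body, stopCod)
      cdsStart <- 3L * k1 + 9L + 1L
      extStart <- NA_integer_
    } else {
      k3 <- sample(3:8, 1L)
      fill <- .codonRun(k3, .UPSTREAM_POOL)
      upCtx <- .sampleContext(if (class == "extension") "strong" else "weak")
      annCtx <- .sampleContext(if (class == "extension") "weak" else "strong")
      seq <- paste0(u, upCtx$up, "ATG", upCtx$down, fill, annCtx$up, "ATG",
                    annCtx$down, body, stopCod)
      cdsStart <- 3L * k1 + 9L + 3L + 3L + 3L * k3 + 9L + 1L
      extStart <- if (class == "extension") 3L * k1 + 9L + 1L else NA_integer_
    }
    data.frame(tx_id = sprintf("%s%03d", toupper(substr(class, 1, 2)), i),
               class = class, seq = seq, cds_start = cdsStart,
               truth_ext_start = extStart,
               read_count = sample(10:100, 1L), stringsAsFactors = FALSE)
  }
  kozak <- rbind(
    do.call(rbind, lapply(seq_len(nTraining), function(i) mkTx("training", i))),
    do.call(rbind, lapply(seq_len(nExtension), function(i) mkTx("extension", i))),
    do.call(rbind, lapply(seq_len(nNegative), function(i) mkTx("negative", i))))
  rownames(iso) <- rownames(kozak) <- NULL
  list(isoforms = iso, kozak = kozak)
}
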