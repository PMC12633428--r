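## Central S4 classes: simulation configuration, simulated hybrid genome,
## and the Kozak position-weight model.

#' Simulation configuration for the allodiploid genome generator
#'
#' Holds every tunable of the synthetic hybrid genome: chromosome lengths,
#' base composition, the per-site substitution probability of each parental
#' lineage from their common ancestor (`divP`, `divS`), within-parent
#' heterozygosity realized as a second substitution layer on one haplotype
#' (`hetP`, `hetS`), the list of planted events (crossovers, LOH tracts,
#' aneuploidies), the depth model and the methylation template.
#'
#' Defaults emulate the regime of a hybrid of two green-algal species:
#' inter-parent divergence ~2.7% (split evenly between the two lineages),
#' within-parent heterozygosity 0.6% and 1.35%, GC content 0.64,
#' nucleosome-linker methylation period 180 bp with a 0.95 5mC plateau.
#'
#' @slot chromLengths named integer vector of chromosome lengths (bp).
#' @slot gcContent GC fraction of the ancestral sequence, in \[0,1\].
#' @slot divP,divS per-site substitution probability of parent P / S from
#'   the ancestor.
#' @slot hetP,hetS within-parent per-site heterozygosity (second haplotype
#'   of each parent).
#' @slot events list of planted events; see [applyHybridEvents()].
#' @slot depthMean expected read depth per chromosome copy.
#' @slot depthDispersion negative-binomial overdispersion; 0 means Poisson.
#' @slot methPeriod spacing (bp) between nucleosome-linker methylation
#'   peaks downstream of the TSS.
#' @slot methPlateau maximum 5mC fraction reached in gene bodies.
#' @slot readsPerSiteMean mean read coverage of modification calls per site.
#' @slot seed integer RNG seed; a fixed seed makes every emitted file
#'   byte-identical across runs.
#' @seealso [simulationConfig()], [simulateHybridGenome()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    chromLengths = "integer",
    gcContent = "numeric",
    divP = "numeric", divS = "numeric",
    hetP = "numeric", hetS = "numeric",
    events = "list",
    depthMean = "numeric",
    depthDispersion = "numeric",
    methPeriod = "numeric",
    methPlateau = "numeric",
    readsPerSiteMean = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (length(object@chromLengths) == 0L || any(object@chromLengths <= 0L))
    msg <- c(msg, "chromLengths must be positive")
  if (is.null(names(object@chromLengths)) || anyDuplicated(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must have unique names")
  for (p in c("gcContent", "divP", "divS", "hetP", "hetS", "methPlateau")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single probability in [0,1]", p))
  }
  if (object@depthMean < 0) msg <- c(msg, "depthMean must be >= 0")
  if (object@depthDispersion < 0) msg <- c(msg, "depthDispersion must be >= 0")
  if (object@methPeriod <= 0) msg <- c(msg, "methPeriod must be > 0")
  if (object@readsPerSiteMean <= 0) msg <- c(msg, "readsPerSiteMean must be > 0")
  bad <- .validateEvents(object@events, object@chromLengths)
  if (!is.null(bad)) msg <- c(msg, bad)
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param chromLengths integer vector of chromosome lengths; names default
#'   to `chr01`, `chr02`, ...
#' @param gcContent GC fraction of the ancestor (default 0.64).
#' @param divP,divS per-site divergence of each parent from the ancestor.
#'   Defaults 0.0135 each, i.e. ~2.7% between the parents.
#' @param hetP,hetS within-parent heterozygosity (defaults 0.006, 0.0135).
#' @param events list of planted events (see [applyHybridEvents()]).
#' @param depthMean expected depth per chromosome copy (default 50).
#' @param depthDispersion negative-binomial overdispersion (default 0 =
#'   Poisson).
#' @param methPeriod linker-peak spacing in bp (default 180).
#' @param methPlateau maximum 5mC fraction (default 0.95).
#' @param readsPerSiteMean mean modification-call coverage (default 30).
#' @param seed RNG seed (default 1).
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(chromLengths = c(chrA = 50000L), seed = 7L)
#' chromLengths(cfg)
#' @export
simulationConfig <- function(chromLengths,
                             gcContent = 0.64,
                             divP = 0.0135, divS = 0.0135,
                             hetP = 0.006, hetS = 0.0135,
                             events = list(),
                             depthMean = 50,
                             depthDispersion = 0,
                             methPeriod = 180,
                             methPlateau = 0.95,
                             readsPerSiteMean = 30,
                             seed = 1L) {
  chromLengths <- as.integer(chromLengths)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- sprintf("chr%02d", seq_along(chromLengths))
  new("SimulationConfig",
    chromLengths = chromLengths, gcContent = gcContent,
    divP = divP, divS = divS, hetP = hetP, hetS = hetS,
    events = events, depthMean = depthMean,
    depthDispersion = depthDispersion, methPeriod = methPeriod,
    methPlateau = methPlateau, readsPerSiteMean = readsPerSiteMean,
    seed = as.integer(seed))
}

#' Simulated hybrid diploid genome with truth log
#'
#' Produced by [simulateHybridGenome()]. Holds the two hybrid haplotypes
#' (A and B) as `DNAStringSet`s, the four parental haplotypes and ancestor,
#' and the truth log recording every planted event: parent-of-origin
#' intervals per haplotype, LOH tracts, crossover positions, and per-base
#' copy number. Coordinates in the truth log are 0-based half-open.
#'
#' @slot haplA,haplB hybrid haplotype sequences, one entry per chromosome.
#' @slot parents list of `DNAStringSet`s `P1`, `P2`, `S1`, `S2`, `ancestor`.
#' @slot truth list; see [truthLog()].
#' @slot config the [SimulationConfig-class] used.
#' @exportClass HybridSim
setClass("HybridSim",
  representation(
    haplA = "DNAStringSet",
    haplB = "DNAStringSet",
    parents = "list",
    truth = "list",
    config = "SimulationConfig"
  )
)

#' Kozak position-weight model of translation-initiation context
#'
#' Log-odds (base 2) of each nucleotide at each offset of a window around
#' the A of the ATG start codon, relative to background genome
#' frequencies, trained with pseudocount 1. The 25th percentile of the
#' training-context scores (`p25`) is the threshold used by the
#' ORF-extension rule (see [extendOrf()]).
#'
#' @slot window integer offsets relative to the A of ATG (offsets 0..2 are
#'   the invariant ATG and are excluded); default `c(-9:-1, 3:5)`.
#' @slot logOdds 4 x length(window) matrix, rows A, C, G, T.
#' @slot background named background nucleotide frequencies.
#' @slot trainingScores scores of the training contexts.
#' @slot p25 25th percentile (linear interpolation) of `trainingScores`.
#' @seealso [buildKozakModel()], [scoreKozak()]
#' @exportClass KozakModel
setClass("KozakModel",
  representation(
    window = "integer",
    logOdds = "matrix",
    background = "numeric",
    trainingScores = "numeric",
    p25 = "numeric"
  )
)

setValidity("KozakModel", function(object) {
  if (!identical(rownames(object@logOdds), c("A", "C", "G", "T")))
    return("logOdds rows must be A, C, G, T")
  if (ncol(object@logOdds) != length(object@window))
    return("logOdds must have one column per window offset")
  if (abs(sum(object@background) - 1) > 1e-6)
    return("background frequencies must sum to 1")
  if (length(object@trainingScores) &&
      abs(object@p25 - unname(quantile(object@trainingScores, 0.25))) > 1e-8)
    return("p25 must equal the 25th percentile of trainingScores")
  TRUE
})
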