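#' Accessors for simulation objects
#'
#' `chromLengths()` returns the named chromosome lengths; `truthLog()` the
#' truth log of planted events; `haplotype()` one hybrid haplotype as a
#' `DNAStringSet`.
#'
#' @param x a [SimulationConfig-class] or [HybridSim-class] object.
#' @param which `"A"` or `"B"` (for `haplotype`).
#' @return `chromLengths`: named integer vector; `truthLog`: list with
#'   elements `ancestry`, `crossovers`, `loh`, `copyNumber`;
#'   `haplotype`: `DNAStringSet`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("truthLog", function(x) standardGeneric("truthLog"))

#' @rdname accessors
#' @export
setGeneric("haplotype", function(x, which = c("A", "B"))
  standardGeneric("haplotype"))

#' @rdname accessors
setMethod("chromLengths", "SimulationConfig", function(x) x@chromLengths)

#' @rdname accessors
setMethod("chromLengths", "HybridSim", function(x) x@config@chromLengths)

#' @rdname accessors
setMethod("truthLog", "HybridSim", function(x) x@truth)

#' @rdname accessors
setMethod("haplotype", "HybridSim", function(x, which = c("A", "B")) {
  which <- match.arg(which)
  if (which == "A") x@haplA else x@haplB
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", length(object@chromLengths), "chromosome(s),",
      sum(as.numeric(object@chromLengths)), "bp total\n")
  cat(sprintf("  divergence P/S from ancestor: %.4g / %.4g; het P/S: %.4g / %.4g\n",
      object@divP, object@divS, object@hetP, object@hetS))
  cat(sprintf("  depth %g (dispersion %g); meth period %g bp, plateau %g\n",
      object@depthMean, object@depthDispersion, object@methPeriod,
      object@methPlateau))
  cat("  planted events:", length(object@events), "; seed:", object@seed, "\n")
})

setMethod("show", "HybridSim", function(object) {
  cat("HybridSim: hybrid diploid genome,",
      length(object@haplA), "chromosome(s) per haplotype\n")
  tr <- object@truth
  cat("  planted: ", nrow(tr$crossovers), " crossover(s), ",
      nrow(tr$loh), " LOH tract(s), ",
      sum(tr$copyNumber$copies != 1L), " aneuploid segment(s)\n", sep = "")
})

setMethod("show", "KozakModel", function(object) {
  cat("KozakModel: window {", paste(object@window, collapse = ","),
      "}, trained on", length(object@trainingScores), "contexts\n")
  cat(sprintf("  training score p25 = %.3f bits (range %.3f .. %.3f)\n",
      object@p25, min(object@trainingScores), max(object@trainingScores)))
})
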