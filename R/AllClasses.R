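#' @import methods
#' @importFrom stats qnorm pnorm runif rnorm rgamma rbinom rhyper setNames
#'   cor sd quantile
#' @importFrom utils write.csv read.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Simulation configuration
#'
#' Holds the full tunable-parameter set of a simulated double-knockout
#' CRISPR screen. Build instances with [simConfig()] (which fills
#' systematic-baseline defaults and validates) rather than \code{new()}.
#'
#' @slot n number of unique genes.
#' @slot coverage cells per construct in the initial library (C); the
#'   initial library size is \code{L0 = coverage * nConstructs}.
#' @slot nGuides guides per gene.
#' @slot pctGI fraction of eligible (control-free) gene pairs flagged as
#'   interacting.
#' @slot sigmaGI SD of the normal "jiggle" applied to the phenotypes of
#'   interacting pairs; controls GI magnitude.
#' @slot classFractions named fractions (\code{negative}, \code{positive},
#'   \code{wild_type}, \code{control}, \code{unknown}) summing to 1.
#' @slot muNeg,sigmaNeg,muPos,sigmaPos,sigmaWT,sigmaUnknown parameters of
#'   the per-class truncated-normal phenotype distributions.
#' @slot sigmaF SD of the log10 initial single-knockout frequency seeds;
#'   see [sigmaFFromConfidence()].
#' @slot pctHeg fraction of guides drawn from the high-efficacy
#'   distribution.
#' @slot muHigh,sigmaHigh,muLow,sigmaLow guide-efficacy truncated-normal
#'   parameters (high on \code{[0.6, 1]}, low on \code{[0, 0.6]}).
#' @slot mode \code{"CRISPRn"} (random guide efficacies) or
#'   \code{"CRISPRn-100%Eff"} (all efficacies exactly 1).
#' @slot nBottleneck bottleneck size as an integer multiple of the initial
#'   library size.
#' @slot nEncounters number of bottleneck encounters before the screen
#'   stops.
#' @slot moiLambda Poisson multiplicity-of-infection rate; the single-
#'   infection probability \code{lambda * exp(-lambda)} is the fraction of
#'   cells retained at each bottleneck.
#' @slot maxDoublings hard cap on doubling cycles.
#' @slot pseudocount pseudo-count added to relative frequencies in the log
#'   fold change; \code{NA} means use \code{1 / L0} at readout time.
#' @slot dirichletAlpha concentration of the Dirichlet allocation of
#'   within-gene (and within-pair) guide frequencies.
#' @slot seed default RNG seed for [simulateScreen()].
#' @seealso [simConfig()], [presetConfig()], [readSimConfig()]
#' @export
setClass("SimConfig",
  representation(
    n = "integer", coverage = "numeric", nGuides = "integer",
    pctGI = "numeric", sigmaGI = "numeric", classFractions = "numeric",
    muNeg = "numeric", sigmaNeg = "numeric",
    muPos = "numeric", sigmaPos = "numeric",
    sigmaWT = "numeric", sigmaUnknown = "numeric",
    sigmaF = "numeric", pctHeg = "numeric",
    muHigh = "numeric", sigmaHigh = "numeric",
    muLow = "numeric", sigmaLow = "numeric",
    mode = "character",
    nBottleneck = "numeric", nEncounters = "numeric",
    moiLambda = "numeric", maxDoublings = "integer",
    pseudocount = "numeric", dirichletAlpha = "numeric",
    seed = "integer"
  )
)

.CLASS_NAMES <- c("negative", "positive", "wild_type", "control", "unknown")
.MODES <- c("CRISPRn", "CRISPRn-100%Eff")

setValidity("SimConfig", function(object) {
  msg <- character()
  cf <- object@classFractions
  if (!identical(names(cf), .CLASS_NAMES)) {
    msg <- c(msg, "classFractions must be named negative/positive/wild_type/control/unknown")
  } else {
    if (any(cf < 0)) msg <- c(msg, "class fractions must be non-negative")
    if (abs(sum(cf) - 1) > 1e-9) {
      msg <- c(msg, sprintf("class fractions must sum to 1 (got %.10g)", sum(cf)))
    }
  }
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@nGuides < 1L) msg <- c(msg, "nGuides must be >= 1")
  if (object@coverage < 1) msg <- c(msg, "coverage must be >= 1")
  if (object@nBottleneck < 1) msg <- c(msg, "nBottleneck must be >= 1")
  if (object@nEncounters < 0) msg <- c(msg, "nEncounters must be >= 0")
  if (object@pctGI < 0 || object@pctGI > 1) msg <- c(msg, "pctGI must be in [0, 1]")
  if (object@pctHeg < 0 || object@pctHeg > 1) msg <- c(msg, "pctHeg must be in [0, 1]")
  if (!(object@sigmaF > 0)) msg <- c(msg, "sigmaF must be > 0")
  if (!(object@moiLambda > 0)) msg <- c(msg, "moiLambda must be > 0")
  if (!is.na(object@pseudocount) && !(object@pseudocount > 0)) {
    msg <- c(msg, "pseudocount must be > 0 (or NA for 1/L0)")
  }
  if (!(object@mode %in% .MODES)) {
    msg <- c(msg, sprintf("mode must be one of %s", paste(.MODES, collapse = ", ")))
  }
  if (object@maxDoublings < 0L) msg <- c(msg, "maxDoublings must be >= 0")
  if (!(object@dirichletAlpha > 0)) msg <- c(msg, "dirichletAlpha must be > 0")
  if (length(msg)) msg else TRUE
})

#' Initialized double-knockout cell library
#'
#' The complete initial state of a simulated screen: the gene panel with
#' per-class phenotypes, the gene-pair interaction map with jiggled
#' phenotypes and true GI values, the per-guide efficacy table, and the
#' construct table (one row per single- or dual-guide construct) carrying
#' Dirichlet-allocated frequencies, integer initial counts and the
#' per-construct division-probability vectors. Build with [buildLibrary()].
#'
#' @slot genePanel data.frame: \code{gene_id}, \code{gene_class}, \code{p}
#'   (theoretical phenotype), \code{f0_prime} (initial frequency seed).
#' @slot interactionMap data.frame over all unordered gene pairs
#'   (\code{k1 < k2}): interaction flag \code{I}, jiggled phenotypes
#'   \code{p1_I}, \code{p2_I}, pair frequency seed \code{f_pair}, true GI
#'   \code{pi} and its sign \code{category}.
#' @slot guideEfficacies data.frame: \code{gene_id}, \code{guide},
#'   \code{eff_class} (high/low), \code{eff} in \code{[0, 1]}.
#' @slot constructs data.frame, one row per construct (single-knockout
#'   rows first), with guide indices, efficacies, effective phenotypes,
#'   division probabilities \code{d0..d3}, relative frequency
#'   \code{f_rel0} and initial count \code{c0}.
#' @slot config the [SimConfig-class] the library was built from.
#' @export
setClass("DKOLibrary",
  representation(
    genePanel = "data.frame",
    interactionMap = "data.frame",
    guideEfficacies = "data.frame",
    constructs = "data.frame",
    config = "SimConfig"
  )
)

setValidity("DKOLibrary", function(object) {
  msg <- character()
  cfg <- object@config
  n <- cfg@n; ng <- cfg@nGuides
  expected <- n * ng + n * (n - 1L) / 2L * ng^2
  ct <- object@constructs
  if (nrow(ct) != expected) {
    msg <- c(msg, sprintf("construct table has %d rows, expected %d", nrow(ct), expected))
  }
  if (nrow(ct)) {
    dp <- as.matrix(ct[, c("d0", "d1", "d2", "d3")])
    if (any(dp < -1e-12) || any(abs(rowSums(dp) - 1) > 1e-12)) {
      msg <- c(msg, "division-probability rows must be non-negative and sum to 1")
    }
    if (abs(sum(ct$f_rel0) - 1) > 1e-9) {
      msg <- c(msg, "initial relative frequencies must sum to 1")
    }
    if (any(ct$c0 < 0)) msg <- c(msg, "initial counts must be non-negative")
  }
  if (nrow(object@genePanel) != n) msg <- c(msg, "gene panel must have n rows")
  if (any(object@genePanel$f0_prime <= 0)) msg <- c(msg, "f0_prime must be positive")
  if (length(msg)) msg else TRUE
})

#' Simulated screen result container
#'
#' A \linkS4class{SummarizedExperiment} with constructs as rows and
#' replicates as columns. Assays: \code{counts0} (initial counts, shared
#' across replicates), \code{counts2} (final counts), \code{freq0}/
#' \code{freq2} (relative frequencies) and \code{lfc} (per-construct log2
#' fold change with pseudocount). \code{rowData} carries the construct
#' annotation including the pair's true interaction \code{pi};
#' \code{metadata} holds the [SimConfig-class], the realized initial
#' library size \code{L0}, the pseudocount used, per-replicate growth logs
#' and replicate seeds. Build with [simulateScreen()].
#'
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
  msg <- character()
  need <- c("counts0", "counts2", "freq0", "freq2", "lfc")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have)) {
    msg <- c(msg, sprintf("missing assays: %s", paste(setdiff(need, have), collapse = ", ")))
  } else {
    if (!all(is.finite(SummarizedExperiment::assay(object, "lfc")))) {
      msg <- c(msg, "lfc must be finite everywhere")
    }
    f2 <- SummarizedExperiment::assay(object, "freq2")
    if (ncol(f2) && any(abs(colSums(f2) - 1) > 1e-9)) {
      msg <- c(msg, "freq2 columns must sum to 1")
    }
  }
  if (length(msg)) msg else TRUE
})
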