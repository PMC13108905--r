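#' Relative construct frequencies
#'
#' @param counts non-negative count vector with positive sum.
#' @return \code{counts / sum(counts)}.
#' @export
relativeFrequencies <- function(counts) {
  total <- sum(counts)
  if (total <= 0) {
    stop("library is extinct: all construct counts are zero")
  }
  counts / total
}

#' Per-construct log2 fold change
#'
#' Computes \code{log2((fRel2 + pseudocount) / (fRel0 + pseudocount))}
#' elementwise on relative frequencies, so library-size differences
#' between timepoints cancel and the pseudocount keeps every value
#' finite.
#'
#' @param fRel0,fRel2 equal-length relative-frequency vectors at the
#'   initial and final timepoints.
#' @param pseudocount positive pseudo-frequency.
#' @return numeric LFC vector.
#' @export
computeLFC <- function(fRel0, fRel2, pseudocount) {
  if (length(fRel0) != length(fRel2)) {
    stop("frequency vectors must have equal length")
  }
  stopifnot(pseudocount > 0)
  log2((fRel2 + pseudocount) / (fRel0 + pseudocount))
}

#' Mean LFC across replicates
#'
#' @param lfcList non-empty list of equal-length LFC vectors, or a matrix
#'   with one column per replicate.
#' @return elementwise arithmetic mean.
#' @export
aggregateReplicates <- function(lfcList) {
  if (is.matrix(lfcList)) lfcList <- asplit(lfcList, 2)
  if (!length(lfcList)) stop("no replicates to aggregate")
  lens <- lengths(lfcList)
  if (length(unique(lens)) != 1L) stop("replicate lengths differ")
  Reduce(`+`, lapply(lfcList, as.numeric)) / length(lfcList)
}

#' Simulate a full double-knockout screen
#'
#' Seeds the RNG, builds the initial library once with [buildLibrary()],
#' derives one independent growth seed per replicate, runs the
#' growth/bottleneck loop ([runScreen()]) per replicate, and assembles a
#' [ScreenExperiment-class]: replicates share the initialized library
#' (identical \code{counts0}) but grow with independent randomness, the
#' way independently transduced biological replicates share a library
#' design. The LFC pseudocount defaults to \code{1 / L0} (one cell on the
#' relative-frequency scale), which keeps non-targeting-control LFCs
#' centred at zero; override via the config.
#'
#' @param config a [SimConfig-class].
#' @param nReplicates number of independently grown replicates.
#' @param seed integer seed for the whole run; defaults to the config
#'   seed.
#' @param panelOverride optional gene-panel override, see
#'   [buildLibrary()].
#' @return a [ScreenExperiment-class] with one column per replicate.
#' @examples
#' se <- simulateScreen(simConfig(n = 8, coverage = 30), nReplicates = 2,
#'                      seed = 11)
#' se
#' @export
simulateScreen <- function(config, nReplicates = 1, seed = config@seed,
                           panelOverride = NULL) {
  stopifnot(is(config, "SimConfig"), nReplicates >= 1)
  set.seed(seed)
  library <- buildLibrary(config, panelOverride = panelOverride)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
  ct <- library@constructs
  c0 <- ct$c0
  L0 <- sum(c0)
  if (L0 <= 0) stop("initial library is empty; increase coverage")
  pseudo <- if (is.na(config@pseudocount)) 1 / L0 else config@pseudocount
  f0 <- relativeFrequencies(c0)

  counts2 <- matrix(0, nrow = nrow(ct), ncol = nReplicates)
  logs <- vector("list", nReplicates)
  doublings <- integer(nReplicates)
  bottlenecks <- integer(nReplicates)
  for (r in seq_len(nReplicates)) {
    set.seed(repSeeds[r])
    run <- runScreen(library)
    counts2[, r] <- run$counts
    logs[[r]] <- run$log
    doublings[r] <- run$doublings
    bottlenecks[r] <- run$bottlenecks
  }
  freq2 <- apply(counts2, 2, relativeFrequencies)
  lfc <- apply(freq2, 2, function(f2) computeLFC(f0, f2, pseudo))
  repNames <- sprintf("rep%d", seq_len(nReplicates))
  dimn <- list(rownames(ct), repNames)
  assays <- list(
    counts0 = matrix(c0, nrow(ct), nReplicates, dimnames = dimn),
    counts2 = `dimnames<-`(counts2, dimn),
    freq0 = matrix(f0, nrow(ct), nReplicates, dimnames = dimn),
    freq2 = `dimnames<-`(freq2, dimn),
    lfc = `dimnames<-`(lfc, dimn))

  imap <- library@interactionMap
  rd <- ct
  rd$pi <- NA_real_
  rd$I <- NA_integer_
  dko <- !is.na(ct$pair_id)
  rd$pi[dko] <- imap$pi[ct$pair_id[dko]]
  rd$I[dko] <- imap$I[ct$pair_id[dko]]
  rd$class1 <- library@genePanel$gene_class[ct$k1]
  rd$class2 <- library@genePanel$gene_class[ct$k2]

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(rd),
    colData = S4Vectors::DataFrame(
      replicate = seq_len(nReplicates),
      growth_seed = repSeeds,
      doublings = doublings,
      bottlenecks = bottlenecks,
      row.names = repNames),
    metadata = list(config = config, seed = seed, L0 = L0,
                    pseudocount = pseudo, library = library,
                    growthLogs = logs))
  new("ScreenExperiment", se)
}

#' @describeIn ScreenExperiment replicate-mean per-construct LFC.
#' @param object a \code{ScreenExperiment}.
#' @export
meanLFC <- function(object) {
  rowMeans(SummarizedExperiment::assay(object, "lfc"))
}

#' @describeIn ScreenExperiment true gene-pair interaction value per
#'   construct row (\code{NA} for single-knockout rows).
#' @export
truePi <- function(object) {
  SummarizedExperiment::rowData(object)$pi
}

#' @describeIn ScreenExperiment the simulation configuration the screen
#'   was generated from.
#' @export
screenConfig <- function(object) S4Vectors::metadata(object)$config

setMethod("show", "ScreenExperiment", function(object) {
  cfg <- screenConfig(object)
  cat("ScreenExperiment:", nrow(object), "constructs x", ncol(object),
      "replicate(s)\n")
  cat("  genes:", cfg@n, " guides/gene:", cfg@nGuides,
      " coverage:", cfg@coverage, "x\n")
  cat("  doublings per replicate:",
      paste(SummarizedExperiment::colData(object)$doublings,
            collapse = ", "), "\n")
  cat("  assays:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "),
      "\n")
})
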