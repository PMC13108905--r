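#' Write a simulated screen to disk
#'
#' Writes, under \code{dir}: \code{constructs.csv} (one row per construct
#' with gene/guide indices, classes, efficacies, effective phenotypes,
#' true interaction, initial/final counts, frequencies and per-replicate
#' plus mean LFC), \code{gene_pairs.csv} (the [scoreInteractions()]
#' table), \code{metrics.json} (the [screenMetrics()] panel),
#' \code{config.yaml}, and \code{run_log.txt} recording the total number
#' of cell doublings, bottleneck events and final library size per
#' replicate.
#'
#' @param se a [ScreenExperiment-class].
#' @param dir output directory (created if missing).
#' @param scores optional precomputed score table.
#' @param kPred,kTruth passed to [screenMetrics()].
#' @return \code{dir}, invisibly.
#' @export
writeScreenResult <- function(se, dir, scores = scoreInteractions(se),
                              kPred = 80, kTruth = 100) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  lfc <- SummarizedExperiment::assay(se, "lfc")
  counts2 <- SummarizedExperiment::assay(se, "counts2")
  tab <- data.frame(
    construct = rownames(se),
    rd[, c("construct_kind", "k1", "j1", "k2", "j2", "class1", "class2",
           "eff1", "eff2", "p1_eff", "p2_eff", "f_rel0", "c0", "pi", "I")],
    row.names = NULL)
  for (r in seq_len(ncol(se))) {
    tab[[sprintf("c2_rep%d", r)]] <- counts2[, r]
    tab[[sprintf("lfc_rep%d", r)]] <- lfc[, r]
  }
  tab$f_rel2 <- SummarizedExperiment::assay(se, "freq2")[, 1]
  tab$lfc_mean <- meanLFC(se)
  write.csv(tab, file.path(dir, "constructs.csv"), row.names = FALSE)
  write.csv(scores, file.path(dir, "gene_pairs.csv"), row.names = FALSE)
  metrics <- screenMetrics(se, scores, kPred = kPred, kTruth = kTruth)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeSimConfig(screenConfig(se), file.path(dir, "config.yaml"))

  cd <- SummarizedExperiment::colData(se)
  lines <- c(sprintf("seed: %d", S4Vectors::metadata(se)$seed),
             sprintf("initial library size L0: %d",
                     as.integer(S4Vectors::metadata(se)$L0)))
  for (r in seq_len(nrow(cd))) {
    lines <- c(lines, sprintf(
      "replicate %d: total cell doublings = %d, bottleneck events = %d, final library size = %.0f",
      r, cd$doublings[r], cd$bottlenecks[r], sum(counts2[, r])))
  }
  writeLines(lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Read back a constructs.csv written by writeScreenResult
#'
#' @param path path to a \code{constructs.csv}.
#' @return data.frame.
#' @export
readScreenTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Sweep screen parameters over a grid
#'
#' Runs one simulation per (grid point x seed) and collects the
#' [screenMetrics()] panel into a tidy data.frame, reproducing the
#' design-profiling line-plot data at user-chosen replication. Grid names
#' must be [simConfig()] argument names (e.g. \code{coverage},
#' \code{pctHeg}, \code{sigmaF}, \code{nGuides}, \code{sigmaGI},
#' \code{nBottleneck}, \code{nEncounters}). Per-cell seeds are derived
#' deterministically from \code{baseSeed} and the cell index so grid
#' points are decoupled.
#'
#' @param baseConfig a [SimConfig-class] supplying all non-swept
#'   parameters.
#' @param grid named list of parameter value vectors, expanded by
#'   [expand.grid()].
#' @param seeds integer vector; each grid point is run once per seed.
#' @param nReplicates replicates per run (2 enables the replicate
#'   correlation metric).
#' @param kPred,kTruth passed to [screenMetrics()].
#' @return data.frame: one row per grid point x seed with the swept
#'   parameters, the seed, and all metrics.
#' @export
sweepScreens <- function(baseConfig, grid, seeds = 1L, nReplicates = 1,
                         kPred = 80, kTruth = 100) {
  stopifnot(is(baseConfig, "SimConfig"))
  if (!length(grid)) stop("empty parameter grid")
  known <- names(formals(simConfig))
  bad <- setdiff(names(grid), known)
  if (length(bad)) stop("unknown sweep parameters: ",
                        paste(bad, collapse = ", "))
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  base <- .configArgs(baseConfig)
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(cells))) {
    for (s in seq_along(seeds)) {
      idx <- idx + 1L
      args <- base
      args[names(cells)] <- as.list(cells[i, , drop = FALSE])
      cfg <- do.call(simConfig, args)
      cellSeed <- (seeds[s] * 10007L + i * 101L) %% 2147483629L + 1L
      se <- simulateScreen(cfg, nReplicates = nReplicates,
                           seed = cellSeed)
      m <- screenMetrics(se, kPred = kPred, kTruth = kTruth)
      rows[[idx]] <- data.frame(cells[i, , drop = FALSE],
                                seed = seeds[s],
                                as.data.frame(m), row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

# SimConfig -> argument list for simConfig()
.configArgs <- function(config) {
  cf <- config@classFractions
  list(n = config@n, coverage = config@coverage, nGuides = config@nGuides,
       pctGI = config@pctGI, sigmaGI = config@sigmaGI,
       pctNeg = unname(cf["negative"]), pctPos = unname(cf["positive"]),
       pctWT = unname(cf["wild_type"]), pctCtrl = unname(cf["control"]),
       pctUnknown = unname(cf["unknown"]),
       muNeg = config@muNeg, sigmaNeg = config@sigmaNeg,
       muPos = config@muPos, sigmaPos = config@sigmaPos,
       sigmaWT = config@sigmaWT, sigmaUnknown = config@sigmaUnknown,
       sigmaF = config@sigmaF, pctHeg = config@pctHeg,
       muHigh = config@muHigh, sigmaHigh = config@sigmaHigh,
       muLow = config@muLow, sigmaLow = config@sigmaLow,
       mode = config@mode, nBottleneck = config@nBottleneck,
       nEncounters = config@nEncounters, moiLambda = config@moiLambda,
       maxDoublings = config@maxDoublings,
       pseudocount = config@pseudocount,
       dirichletAlpha = config@dirichletAlpha, seed = config@seed)
}
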