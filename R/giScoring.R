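#' Score genetic interactions by delta log fold change
#'
#' For every gene pair, dLFC compares the mean LFC of the pair's dual
#' constructs to the additive expectation from the two single-mutant
#' fitness values (SMF, the mean single-knockout LFC of a gene across its
#' guides): \code{dlfc = dko_lfc - smf1 - smf2}. Negative dLFC indicates
#' a synthetic-sick/lethal interaction. \code{zdlfc} is the
#' z-standardized score over all pairs (sample SD). Replicates are
#' aggregated by the mean of per-replicate LFC before scoring. Pairs
#' containing control genes are scored (they are nulls with
#' \code{pi = 0}).
#'
#' @param se a [ScreenExperiment-class] containing both single- and
#'   dual-knockout rows.
#' @return data.frame with one row per gene pair: \code{k1}, \code{k2},
#'   \code{dko_lfc}, \code{smf1}, \code{smf2}, \code{dlfc}, \code{zdlfc},
#'   \code{pi} (true interaction), \code{I}, \code{category}.
#' @seealso [screenMetrics()] for the evaluation metrics.
#' @export
scoreInteractions <- function(se) {
  stopifnot(is(se, "ScreenExperiment"))
  rd <- SummarizedExperiment::rowData(se)
  lfc <- meanLFC(se)
  sko <- rd$construct_kind == "SKO"
  if (!any(sko) || !all(tabulate(rd$k1[sko]) > 0)) {
    stop("every gene needs at least one single-knockout construct")
  }
  smf <- rowsum(lfc[sko], rd$k1[sko]) / tabulate(rd$k1[sko])
  smf <- smf[order(as.integer(rownames(smf))), 1]

  dko <- !sko
  pairId <- rd$pair_id[dko]
  dkoLfc <- rowsum(lfc[dko], pairId) / tabulate(pairId)[sort(unique(pairId))]
  ord <- order(as.integer(rownames(dkoLfc)))
  dkoLfc <- dkoLfc[ord, 1]
  pid <- as.integer(names(dkoLfc))

  imap <- S4Vectors::metadata(se)$library@interactionMap
  k1 <- imap$k1[pid]; k2 <- imap$k2[pid]
  smf1 <- smf[k1]; smf2 <- smf[k2]
  dlfc <- dkoLfc - smf1 - smf2
  data.frame(
    k1 = k1, k2 = k2, dko_lfc = unname(dkoLfc),
    smf1 = unname(smf1), smf2 = unname(smf2), dlfc = unname(dlfc),
    zdlfc = (dlfc - mean(dlfc)) / sd(dlfc),
    pi = imap$pi[pid], I = imap$I[pid], category = imap$category[pid])
}

# Pearson product-moment correlation with the guards the scoring
# pipeline needs
pearsonR <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    stop("need two equal-length vectors of length >= 3")
  }
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance")
  cor(a, b)
}

#' Precision and recall at k for negative interactions
#'
#' Truth set: the \code{kTruth} pairs with the most-negative true
#' interaction \code{pi}; prediction set: the \code{kPred} pairs with the
#' most-negative \code{dlfc}. Ties are broken by stable pair order.
#'
#' @param scores a score table from [scoreInteractions()].
#' @param kPred size of the prediction set (default 80).
#' @param kTruth size of the truth set (default 100). When fewer than
#'   \code{kTruth} pairs have strictly negative \code{pi}, the truth set
#'   is padded by the stable order among the zero-interaction pairs and a
#'   warning is raised (the count of strictly negative true interactions
#'   is itself stochastic and fluctuates around 100 under the baseline
#'   design); set \code{requireNegatives = TRUE} to error instead.
#' @param requireNegatives error rather than warn when fewer than
#'   \code{kTruth} strictly negative true interactions exist.
#' @return named numeric vector \code{c(precision, recall)} where
#'   precision divides the overlap by \code{kPred} and recall by
#'   \code{kTruth}.
#' @export
precisionRecallAtK <- function(scores, kPred = 80, kTruth = 100,
                               requireNegatives = FALSE) {
  nNeg <- sum(scores$pi < 0)
  if (nNeg < kTruth) {
    msg <- sprintf("only %d pairs with negative true GI; truth set padded to %d",
                   nNeg, kTruth)
    if (requireNegatives) stop(msg) else warning(msg)
  }
  truth <- order(scores$pi)[seq_len(kTruth)]
  pred <- order(scores$dlfc)[seq_len(kPred)]
  hits <- length(intersect(pred, truth))
  c(precision = hits / kPred, recall = hits / kTruth)
}

#' Area under the precision-recall curve for negative interactions
#'
#' Positives are the pairs with truly negative interaction
#' (\code{pi < 0}); the ranking score is \code{-dlfc}, so the most
#' synthetic-lethal predictions rank first. The area is the standard
#' step-wise PR integration \code{sum(precision_i * delta recall_i)} down
#' the ranked list (tied scores are grouped).
#'
#' @param scores a score table from [scoreInteractions()].
#' @return area under the precision-recall curve in \code{[0, 1]}.
#' @export
aucprNegative <- function(scores) {
  labels <- scores$pi < 0
  P <- sum(labels)
  if (P == 0 || P == length(labels)) {
    stop("need both negative and non-negative true interactions")
  }
  ord <- order(scores$dlfc)              # most-negative dlfc first
  lab <- labels[ord]
  score <- scores$dlfc[ord]
  tp <- cumsum(lab)
  n <- seq_along(lab)
  # keep only the last index of each tied-score block
  keep <- c(score[-1] != score[-length(score)], TRUE)
  tp <- tp[keep]; n <- n[keep]
  recall <- tp / P
  precision <- tp / n
  sum(precision * diff(c(0, recall)))
}

#' Read concentration in the top 5\% of constructs
#'
#' Sorts constructs by final count (descending) and returns the fraction
#' of all reads carried by the top \code{ceiling(frac * nConstructs)}
#' constructs. Monotone loss of library diversity over doubling cycles
#' drives this towards 1.
#'
#' @param counts final count vector with positive sum.
#' @param frac top fraction of constructs (default 0.05).
#' @return fraction of reads in \code{(0, 1]}.
#' @export
fractionReadsTop <- function(counts, frac = 0.05) {
  if (!length(counts) || sum(counts) <= 0) {
    stop("need a non-empty count vector with positive sum")
  }
  m <- ceiling(frac * length(counts))
  sum(sort(counts, decreasing = TRUE)[seq_len(m)]) / sum(counts)
}

#' Pearson correlation between two replicates
#'
#' @param se a [ScreenExperiment-class] with at least two replicate
#'   columns, or \code{rep1}/\code{rep2} given as two single-replicate
#'   screens over identical construct tables.
#' @param quantity per-construct quantity to correlate: \code{"lfc"} or
#'   \code{"freq2"}.
#' @param rep1,rep2 column indices of the two replicates.
#' @return Pearson r.
#' @export
replicateCorrelation <- function(se, quantity = c("lfc", "freq2"),
                                 rep1 = 1, rep2 = 2) {
  quantity <- match.arg(quantity)
  a <- SummarizedExperiment::assay(se, quantity)
  if (ncol(a) < max(rep1, rep2)) stop("screen has too few replicates")
  pearsonR(a[, rep1], a[, rep2])
}

#' Evaluation metrics for a simulated screen
#'
#' Computes the full metric panel from a screen and its score table:
#' Pearson r between dLFC and the simulated true interaction, precision
#' and recall at \code{kPred} against the \code{kTruth} most-negative
#' true interactions, AUC-PR for negative interactions, the fraction of
#' final reads in the top 5\% of constructs (replicate 1), and (when two
#' or more replicates are present) the replicate LFC correlation.
#'
#' @param se a [ScreenExperiment-class].
#' @param scores optional precomputed [scoreInteractions()] table.
#' @param kPred,kTruth top-k sizes for [precisionRecallAtK()].
#' @return named list of metrics.
#' @examples
#' se <- simulateScreen(simConfig(n = 20, coverage = 50, pctGI = 0.5),
#'                      nReplicates = 2, seed = 3)
#' screenMetrics(se, kPred = 4, kTruth = 5)
#' @export
screenMetrics <- function(se, scores = scoreInteractions(se),
                          kPred = 80, kTruth = 100) {
  pr <- tryCatch(suppressWarnings(precisionRecallAtK(scores, kPred, kTruth)),
                 error = function(e) c(precision = NA_real_,
                                       recall = NA_real_))
  out <- list(
    r_dlfc_pi = pearsonR(scores$dlfc, scores$pi),
    precision_at_k = unname(pr["precision"]),
    recall_at_k = unname(pr["recall"]),
    aucpr_negative = tryCatch(aucprNegative(scores),
                              error = function(e) NA_real_),
    top5_fraction = fractionReadsTop(
      SummarizedExperiment::assay(se, "counts2")[, 1]))
  out$replicate_r <- if (ncol(se) >= 2) replicateCorrelation(se) else NA_real_
  out
}
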