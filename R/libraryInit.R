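#' Exact truncated-normal sampling
#'
#' Draws from N(mu, sigma^2) conditioned on \code{[lo, hi]} by the
#' inverse-CDF method on the truncated range (not clip-after-draw), so the
#' draws are exact and reproducible given the RNG state. \code{sigma = 0}
#' degenerates to \code{mu} (which must then lie inside the interval).
#'
#' @param n number of draws.
#' @param mu,sigma mean and SD of the untruncated normal; \code{mu} may be
#'   a vector of length \code{n} (one centre per draw).
#' @param lo,hi truncation bounds, \code{lo < hi}.
#' @return numeric vector of length \code{n} with values in
#'   \code{[lo, hi]}.
#' @export
rtruncnorm <- function(n, mu, sigma, lo, hi) {
  stopifnot(lo < hi, sigma >= 0)
  if (sigma == 0) {
    if (any(mu < lo | mu > hi)) {
      stop("degenerate distribution outside [lo, hi]")
    }
    return(rep_len(mu, n))
  }
  plo <- pnorm(lo, mu, sigma)
  phi <- pnorm(hi, mu, sigma)
  if (any(phi - plo < 1e-300)) {
    stop("truncation interval has vanishing probability mass")
  }
  qnorm(runif(n, plo, phi), mu, sigma)
}

# closed-form mean of N(mu, sigma^2) truncated to [lo, hi]; used as an
# independent oracle in tests
truncnormMean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' @importFrom stats dnorm
NULL

# Dirichlet(alpha * 1_k) draw via normalized gammas
rdirichlet1 <- function(k, alpha) {
  g <- rgamma(k, shape = alpha, rate = 1)
  g / sum(g)
}

# class support intervals for phenotype sampling
.CLASS_BOUNDS <- list(
  negative  = c(-1, -0.025),
  positive  = c(0.025, 1),
  wild_type = c(-0.025, 0.025),
  unknown   = c(-0.5, 0.5)
)

#' Initialize the gene panel
#'
#' Assigns each of the \code{n} genes to a class (counts are
#' \code{round(fraction * n)} per non-wild-type class, remainder to
#' wild-type; assignment to gene indices is a seeded shuffle) and draws
#' per-class theoretical phenotypes from truncated normals:
#' negative on \code{[-1, -0.025]}, positive on \code{[0.025, 1]},
#' wild-type on \code{[-0.025, 0.025]}, unknown on \code{[-0.5, 0.5]};
#' non-targeting controls have phenotype exactly 0. Initial frequency
#' seeds are drawn as \code{log10(f0_prime) ~ N(0, sigmaF^2)}.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns \code{gene_id}, \code{gene_class},
#'   \code{p}, \code{f0_prime}.
#' @export
initGenePanel <- function(config) {
  stopifnot(is(config, "SimConfig"))
  n <- config@n
  cf <- config@classFractions
  counts <- setNames(integer(length(.CLASS_NAMES)), .CLASS_NAMES)
  for (cl in setdiff(.CLASS_NAMES, "wild_type")) {
    counts[cl] <- as.integer(round(cf[[cl]] * n))
  }
  counts["wild_type"] <- n - sum(counts)
  if (counts["wild_type"] < 0L) {
    stop("class fractions cannot be realized for n = ", n)
  }
  classes <- sample(rep(names(counts), counts))
  p <- numeric(n)
  for (cl in names(.CLASS_BOUNDS)) {
    idx <- which(classes == cl)
    if (!length(idx)) next
    par <- switch(cl,
      negative  = c(config@muNeg, config@sigmaNeg),
      positive  = c(config@muPos, config@sigmaPos),
      wild_type = c(0, config@sigmaWT),
      unknown   = c(0, config@sigmaUnknown))
    b <- .CLASS_BOUNDS[[cl]]
    p[idx] <- rtruncnorm(length(idx), par[1], par[2], b[1], b[2])
  }
  p[classes == "control"] <- 0
  f0 <- 10^rnorm(n, 0, config@sigmaF)
  data.frame(gene_id = seq_len(n), gene_class = classes, p = p,
             f0_prime = f0)
}

#' Initialize the gene-pair interaction map
#'
#' Enumerates all \code{choose(n, 2)} unordered gene pairs
#' (\code{k1 < k2}). Among the pairs containing no non-targeting control,
#' \code{round(pctGI * nEligible)} are drawn uniformly without replacement
#' and flagged interacting (\code{I = 1}); their phenotypes are resampled
#' as \code{p_i^I ~ N(p_i, sigmaGI^2)} truncated to \code{[-1, 1]},
#' independently for the two genes. Non-interacting pairs keep
#' \code{p_i^I = p_i}. The true interaction \code{pi} is computed by
#' [trueGI()] from the gene-level phenotypes, and each pair's frequency
#' seed is the mean of its genes' seeds.
#'
#' @param panel a gene panel from [initGenePanel()].
#' @param config the matching [SimConfig-class].
#' @return data.frame with one row per pair: \code{k1}, \code{k2},
#'   \code{I}, \code{p1}, \code{p2}, \code{p1_I}, \code{p2_I},
#'   \code{f_pair}, \code{pi}, \code{category}.
#' @export
initInteractionMap <- function(panel, config) {
  stopifnot(nrow(panel) >= 2)
  n <- nrow(panel)
  k2 <- rep(2:n, times = 2:n - 1L)
  k1 <- sequence(2:n - 1L)
  isCtrl <- panel$gene_class == "control"
  eligible <- !(isCtrl[k1] | isCtrl[k2])
  nGI <- as.integer(round(config@pctGI * sum(eligible)))
  if (nGI > 0L && !any(eligible)) {
    stop("pctGI > 0 but no eligible (control-free) pairs")
  }
  I <- integer(length(k1))
  if (nGI > 0L) {
    I[sample(which(eligible), nGI)] <- 1L
  }
  p1 <- panel$p[k1]
  p2 <- panel$p[k2]
  p1I <- p1
  p2I <- p2
  hit <- which(I == 1L)
  if (length(hit)) {
    p1I[hit] <- rtruncnorm(length(hit), p1[hit], config@sigmaGI, -1, 1)
    p2I[hit] <- rtruncnorm(length(hit), p2[hit], config@sigmaGI, -1, 1)
  }
  pi <- trueGI(p1, p2, p1I, p2I)
  pi[I == 0L] <- 0           # exact zero for non-interacting pairs
  data.frame(
    k1 = k1, k2 = k2, I = I, p1 = p1, p2 = p2, p1_I = p1I, p2_I = p2I,
    f_pair = (panel$f0_prime[k1] + panel$f0_prime[k2]) / 2,
    pi = pi,
    category = c("negative", "none", "positive")[sign(pi) + 2]
  )
}

#' Initialize guide efficacies
#'
#' Labels \code{round(pctHeg * n * nGuides)} of the guides (uniformly at
#' random) as high-efficacy and the rest as low-efficacy. In
#' \code{CRISPRn} mode efficacies are drawn from truncated normals:
#' high on \code{[0.6, 1]} and low on \code{[0, 0.6]}, so a high-efficacy
#' guide always outperforms a low-efficacy one. In
#' \code{CRISPRn-100\%Eff} mode every efficacy is exactly 1.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns \code{gene_id}, \code{guide},
#'   \code{eff_class}, \code{eff}.
#' @export
initGuideEfficacies <- function(config) {
  stopifnot(is(config, "SimConfig"))
  n <- config@n; ng <- config@nGuides
  total <- n * ng
  nHigh <- as.integer(round(config@pctHeg * total))
  effClass <- rep("low", total)
  effClass[sample(total, nHigh)] <- "high"
  eff <- numeric(total)
  if (config@mode == "CRISPRn-100%Eff") {
    eff[] <- 1
    effClass[] <- "high"
  } else {
    hi <- effClass == "high"
    eff[hi] <- rtruncnorm(sum(hi), config@muHigh, config@sigmaHigh, 0.6, 1)
    eff[!hi] <- rtruncnorm(sum(!hi), config@muLow, config@sigmaLow, 0, 0.6)
  }
  data.frame(gene_id = rep(seq_len(n), each = ng),
             guide = rep(seq_len(ng), n),
             eff_class = effClass, eff = eff)
}

#' Allocate construct frequencies and initial counts
#'
#' Splits each gene's frequency seed over its guides, and each pair's seed
#' over its guide pairs, by Dirichlet draws: single-knockout guide
#' frequencies are \code{f_k * Dirichlet(alpha, nGuides)} (summing exactly
#' to \code{f_k}) and dual-guide frequencies are
#' \code{f_pair * nGuides * Dirichlet(alpha, nGuides^2)}, so the average
#' frequency of a pair's dual constructs equals the average frequency of
#' its genes' single constructs. Relative frequencies divide by the global
#' sum; integer initial counts are \code{round(f_rel * L0)} with
#' \code{L0 = coverage * nConstructs} (round-half-to-even; counts of 0
#' are allowed, so constructs can drop out at low coverage). Effective
#' phenotypes multiply the (pair-jiggled, for dual constructs) phenotype
#' by the guide efficacy; each row's division-probability vector comes
#' from [dkoDivisionProbs()] with \code{p2 = 0} for single knockouts.
#'
#' @param panel gene panel from [initGenePanel()].
#' @param imap interaction map from [initInteractionMap()].
#' @param guides guide table from [initGuideEfficacies()].
#' @param config the [SimConfig-class] all inputs were built from.
#' @return data.frame with one construct per row (single-knockout rows
#'   first), columns \code{construct_kind}, \code{k1}, \code{j1},
#'   \code{k2}, \code{j2}, \code{pair_id}, \code{eff1}, \code{eff2},
#'   \code{p1_eff}, \code{p2_eff}, \code{d0..d3}, \code{fg},
#'   \code{f_rel0}, \code{c0}.
#' @export
allocateFrequencies <- function(panel, imap, guides, config) {
  n <- config@n; ng <- config@nGuides
  effMat <- matrix(guides$eff, nrow = ng)   # ng x n, [j, k]

  # single-knockout rows: gene k, guide j (guide fastest)
  skoK <- rep(seq_len(n), each = ng)
  skoJ <- rep(seq_len(ng), n)
  skoFg <- as.vector(vapply(seq_len(n), function(k) {
    panel$f0_prime[k] * rdirichlet1(ng, config@dirichletAlpha)
  }, numeric(ng)))
  skoEff <- effMat[cbind(skoJ, skoK)]
  skoP <- panel$p[skoK] * skoEff

  # dual-knockout rows: pair (k1 < k2), then j1 (slow), j2 (fast)
  npair <- nrow(imap)
  dkoPair <- rep(seq_len(npair), each = ng^2)
  dkoJ1 <- rep(rep(seq_len(ng), each = ng), npair)
  dkoJ2 <- rep(seq_len(ng), ng * npair)
  dkoFg <- as.vector(vapply(seq_len(npair), function(i) {
    imap$f_pair[i] * ng * rdirichlet1(ng^2, config@dirichletAlpha)
  }, numeric(ng^2)))
  dkoK1 <- imap$k1[dkoPair]
  dkoK2 <- imap$k2[dkoPair]
  eff1 <- effMat[cbind(dkoJ1, dkoK1)]
  eff2 <- effMat[cbind(dkoJ2, dkoK2)]
  p1eff <- imap$p1_I[dkoPair] * eff1
  p2eff <- imap$p2_I[dkoPair] * eff2

  fg <- c(skoFg, dkoFg)
  fRel <- fg / sum(fg)
  L0 <- librarySize(config)
  c0 <- round(fRel * L0)

  dp <- rbind(dkoDivisionProbs(skoP, 0), dkoDivisionProbs(p1eff, p2eff))
  nc <- length(fg)
  out <- data.frame(
    construct_kind = rep(c("SKO", "DKO"), c(length(skoFg), length(dkoFg))),
    k1 = c(skoK, dkoK1), j1 = c(skoJ, dkoJ1),
    k2 = c(rep(NA_integer_, length(skoFg)), dkoK2),
    j2 = c(rep(NA_integer_, length(skoFg)), dkoJ2),
    pair_id = c(rep(NA_integer_, length(skoFg)), dkoPair),
    eff1 = c(skoEff, eff1),
    eff2 = c(rep(NA_real_, length(skoFg)), eff2),
    p1_eff = c(skoP, p1eff),
    p2_eff = c(rep(0, length(skoFg)), p2eff),
    d0 = dp[, 1], d1 = dp[, 2], d2 = dp[, 3], d3 = dp[, 4],
    fg = fg, f_rel0 = fRel, c0 = c0)
  rownames(out) <- c(sprintf("SKO_g%d_s%d", skoK, skoJ),
                     sprintf("DKO_g%d_s%d.g%d_s%d",
                             dkoK1, dkoJ1, dkoK2, dkoJ2))
  stopifnot(nc == nConstructs(config))
  out
}

#' Build a complete initial cell library
#'
#' Runs [initGenePanel()], [initInteractionMap()],
#' [initGuideEfficacies()] and [allocateFrequencies()] in sequence under
#' the current RNG state and wraps the results in a validated
#' [DKOLibrary-class]. An optional panel override fixes gene classes
#' and/or phenotypes (rows with \code{NA} phenotype are sampled from the
#' class distribution as usual).
#'
#' @param config a [SimConfig-class].
#' @param panelOverride optional data.frame with columns \code{gene_id},
#'   \code{class} and optionally \code{p}, as read from a TSV gene-panel
#'   file; must cover all \code{n} genes.
#' @return a [DKOLibrary-class].
#' @examples
#' set.seed(7)
#' lib <- buildLibrary(simConfig(n = 6, coverage = 20))
#' lib
#' @export
buildLibrary <- function(config, panelOverride = NULL) {
  panel <- initGenePanel(config)
  if (!is.null(panelOverride)) {
    stopifnot(all(c("gene_id", "class") %in% names(panelOverride)))
    if (!setequal(panelOverride$gene_id, panel$gene_id)) {
      stop("panel override must cover gene ids 1..n exactly")
    }
    ov <- panelOverride[match(panel$gene_id, panelOverride$gene_id), ]
    panel$gene_class <- ov$class
    for (i in seq_len(nrow(panel))) {
      cl <- panel$gene_class[i]
      if (!is.null(ov$p) && !is.na(ov$p[i])) {
        panel$p[i] <- ov$p[i]
      } else if (cl == "control") {
        panel$p[i] <- 0
      } else {
        par <- switch(cl,
          negative  = c(config@muNeg, config@sigmaNeg),
          positive  = c(config@muPos, config@sigmaPos),
          wild_type = c(0, config@sigmaWT),
          unknown   = c(0, config@sigmaUnknown))
        b <- .CLASS_BOUNDS[[cl]]
        panel$p[i] <- rtruncnorm(1, par[1], par[2], b[1], b[2])
      }
    }
  }
  imap <- initInteractionMap(panel, config)
  guides <- initGuideEfficacies(config)
  constructs <- allocateFrequencies(panel, imap, guides, config)
  new("DKOLibrary", genePanel = panel, interactionMap = imap,
      guideEfficacies = guides, constructs = constructs, config = config)
}

#' @describeIn DKOLibrary the per-gene panel (class, phenotype,
#'   frequency seed).
#' @param object a \code{DKOLibrary}.
#' @export
genePanel <- function(object) object@genePanel

#' @describeIn DKOLibrary the gene-pair interaction map with true GI
#'   values.
#' @export
interactionMap <- function(object) object@interactionMap

#' @describeIn DKOLibrary the per-guide efficacy table.
#' @export
guideEfficacies <- function(object) object@guideEfficacies

#' @describeIn DKOLibrary the per-construct table (frequencies, counts,
#'   division probabilities).
#' @export
constructTable <- function(object) object@constructs
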