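#' Grow every construct for one doubling cycle
#'
#' Each of the \code{counts[i]} cells of construct \code{i} independently
#' divides 0, 1, 2 or 3 times according to the construct's
#' division-probability vector (row \code{i} of \code{divMatrix}); the new
#' count is \code{2*c1 + 4*c2 + 8*c3} where
#' \code{(c0, c1, c2, c3) ~ Multinomial(counts[i], p_y)}. The multinomial
#' is drawn by the exact sequential-binomial decomposition, vectorised
#' over constructs. Constructs at count 0 stay at 0.
#'
#' @param counts non-negative integer vector of current cell counts.
#' @param divMatrix numeric matrix, constructs x 4, rows summing to 1.
#' @return integer-valued numeric vector of post-growth counts.
#' @export
growOneCycle <- function(counts, divMatrix) {
  stopifnot(length(counts) == nrow(divMatrix), all(counts >= 0))
  n <- counts
  p0 <- divMatrix[, 1]; p1 <- divMatrix[, 2]
  p2 <- divMatrix[, 3]; p3 <- divMatrix[, 4]
  c0 <- rbinom(length(n), n, p0)
  rem <- n - c0
  den <- p1 + p2 + p3
  c1 <- rbinom(length(n), rem, ifelse(den > 0, p1 / den, 0))
  rem <- rem - c1
  den <- p2 + p3
  c2 <- rbinom(length(n), rem, ifelse(den > 0, p2 / den, 0))
  c3 <- rem - c2
  2 * c1 + 4 * c2 + 8 * c3
}

#' Multivariate-hypergeometric bottleneck downsampling
#'
#' Draws \code{nR} cells without replacement from the pooled population,
#' i.e. a multivariate hypergeometric sample with one colour per
#' construct, by sequential conditional univariate hypergeometric draws.
#' Exact, seedable, linear in the number of constructs.
#'
#' @param counts non-negative integer vector of cell counts per construct.
#' @param nR number of cells to retain; \code{0 <= nR <= sum(counts)}.
#' @return integer-valued numeric vector \code{new} with
#'   \code{new <= counts} elementwise and \code{sum(new) == nR}.
#' @export
bottleneckDownsample <- function(counts, nR) {
  total <- sum(counts)
  if (nR < 0 || nR > total) {
    stop("nR must lie between 0 and sum(counts)")
  }
  if (nR == total) return(counts)
  out <- numeric(length(counts))
  remaining <- total
  k <- nR
  for (i in seq_along(counts)) {
    if (k == 0) break
    m <- counts[i]
    remaining <- remaining - m
    if (remaining == 0) {       # last non-empty stratum takes the rest
      out[i] <- k
      k <- 0
      break
    }
    x <- rhyper(1, m, remaining, k)
    out[i] <- x
    k <- k - x
  }
  out
}

#' Cells retained at a bottleneck under Poisson MOI
#'
#' Transduction at multiplicity of infection \code{lambda} retains the
#' singly-infected fraction \code{P(X = 1) = lambda * exp(-lambda)} of the
#' current library (about 22\% at \code{lambda = 0.3}); multiple
#' infections are not modelled.
#'
#' @param D current library size.
#' @param moiLambda Poisson rate.
#' @return integer retained-cell count \code{round(lambda * exp(-lambda) * D)}.
#' @examples
#' retentionCount(1e6, 0.3)  # 222245
#' @export
retentionCount <- function(D, moiLambda = 0.3) {
  stopifnot(D >= 0)
  round(moiLambda * exp(-moiLambda) * D)
}

#' Run the growth/bottleneck selection loop
#'
#' Starting from the library's initial counts, iterates while the
#' bottleneck-encounter counter \code{ie < nEncounters} and the doubling
#' counter \code{t < maxDoublings}: (a) if the current library size
#' exceeds \code{nBottleneck * L0} (with \code{L0} the realized initial
#' size), count a bottleneck and downsample to
#' [retentionCount()] cells via [bottleneckDownsample()];
#' (b) grow every construct one cycle with [growOneCycle()]; (c) advance
#' \code{t}. The growth step always follows the bottleneck check inside
#' an iteration, so the final bottleneck is still followed by one
#' doubling. Uses the current RNG state; seed outside for
#' reproducibility.
#'
#' @param library a [DKOLibrary-class] (or any object with a
#'   \code{constructs} slot providing \code{c0} and \code{d0..d3}).
#' @return list with \code{counts} (final counts \code{C2}),
#'   \code{doublings} (total cycles run), \code{bottlenecks} (encounters)
#'   and \code{log}, a data.frame with one row per cycle
#'   (\code{t}, \code{ie}, \code{D}, \code{bottleneck}, \code{n_r},
#'   \code{D_after}).
#' @export
runScreen <- function(library) {
  stopifnot(is(library, "DKOLibrary"))
  cfg <- library@config
  ct <- library@constructs
  counts <- ct$c0
  divMatrix <- as.matrix(ct[, c("d0", "d1", "d2", "d3")])
  L0 <- sum(counts)
  threshold <- cfg@nBottleneck * L0
  t <- 0L
  ie <- 0L
  logRows <- list()
  while (ie < cfg@nEncounters && t < cfg@maxDoublings) {
    D <- sum(counts)
    fired <- D > threshold
    nR <- NA_real_
    if (fired) {
      ie <- ie + 1L
      nR <- retentionCount(D, cfg@moiLambda)
      counts <- bottleneckDownsample(counts, nR)
    }
    counts <- growOneCycle(counts, divMatrix)
    t <- t + 1L
    logRows[[t]] <- data.frame(t = t, ie = ie, D = D, bottleneck = fired,
                               n_r = nR, D_after = sum(counts))
  }
  list(counts = counts, doublings = t, bottlenecks = ie,
       log = if (t > 0L) do.call(rbind, logRows) else
         data.frame(t = integer(), ie = integer(), D = numeric(),
                    bottleneck = logical(), n_r = numeric(),
                    D_after = numeric()))
}
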