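#' Single-knockout cell-division distribution
#'
#' Probability distribution of the number of divisions \code{x} of a
#' single-knockout cell in one wild-type doubling cycle, given the
#' theoretical phenotype \code{p} of the knocked-out gene. A cell either
#' dies (\code{x = 0}, probability \code{max(-p, 0)}), divides once like a
#' wild-type cell (\code{x = 1}, probability \code{1 - abs(p)}), or divides
#' twice (\code{x = 2}, probability \code{max(p, 0)}).
#'
#' @param p numeric vector of phenotypes in \code{[-1, 1]}. Negative values
#'   increase the death probability, positive values the double-division
#'   probability; \code{p = 0} is wild-type behaviour.
#' @return a numeric matrix with one row per phenotype and columns
#'   \code{x0}, \code{x1}, \code{x2}; each row sums to 1.
#' @seealso [dkoDivisionProbs()] for the double-knockout analogue.
#' @examples
#' skoDivisionProbs(c(-0.4, 0, 1))
#' @export
skoDivisionProbs <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  if (any(abs(p) > 1)) {
    stop("phenotypes must lie in [-1, 1]")
  }
  m <- cbind(x0 = pmax(-p, 0), x1 = 1 - abs(p), x2 = pmax(p, 0))
  rownames(m) <- NULL
  m
}

#' Double-knockout cell-division distribution
#'
#' Distribution of the number of divisions \code{y} of a double-knockout
#' cell in one doubling cycle. The two single-knockout division variables
#' \code{x1}, \code{x2} (each multinoulli on \code{0:2}, see
#' [skoDivisionProbs()]) are combined under independence through
#' \code{y = 1(x1 * x2 != 0) * (x1 + x2 - 1)}, so death of either
#' knockout kills the cell, and surviving division counts add (minus the
#' shared wild-type division). Closed form:
#' \deqn{p_0 = (-p_1)_+ + (-p_2)_+ - (-p_1)_+ (-p_2)_+}
#' \deqn{p_1 = (1-|p_1|)(1-|p_2|)}
#' \deqn{p_2 = (1-|p_1|)(p_2)_+ + (p_1)_+ (1-|p_2|)}
#' \deqn{p_3 = (p_1)_+ (p_2)_+}
#' With \code{p1 = 0} (a non-targeting control) the distribution collapses
#' to the single-knockout distribution of gene 2.
#'
#' @param p1,p2 numeric vectors (recycled to common length) of the two
#'   phenotypes, each in \code{[-1, 1]}.
#' @return numeric matrix with columns \code{y0..y3}; rows sum to 1.
#' @examples
#' dkoDivisionProbs(0.4, -0.03)   # (0.030, 0.582, 0.388, 0)
#' dkoDivisionProbs(0, -0.25)     # equals skoDivisionProbs(-0.25), padded
#' @export
dkoDivisionProbs <- function(p1, p2) {
  stopifnot(is.numeric(p1), is.numeric(p2),
            all(is.finite(p1)), all(is.finite(p2)))
  if (any(abs(p1) > 1) || any(abs(p2) > 1)) {
    stop("phenotypes must lie in [-1, 1]")
  }
  n <- max(length(p1), length(p2))
  p1 <- rep_len(p1, n)
  p2 <- rep_len(p2, n)
  n1 <- pmax(-p1, 0); s1 <- 1 - abs(p1); g1 <- pmax(p1, 0)
  n2 <- pmax(-p2, 0); s2 <- 1 - abs(p2); g2 <- pmax(p2, 0)
  # death if x1 = 0 (any x2) or x2 = 0 (x1 != 0)
  y0 <- n1 * (n2 + s2 + g2) + s1 * n2 + g1 * n2
  y1 <- s1 * s2
  y2 <- s1 * g2 + g1 * s2
  y3 <- g1 * g2
  cbind(y0 = y0, y1 = y1, y2 = y2, y3 = y3)
}

#' Expected descendants per doubling cycle
#'
#' A cell dividing \code{y} times leaves \code{1(y != 0) * 2^y} descendants,
#' i.e. 0, 2, 4 or 8. This returns the expectation
#' \code{0*p0 + 2*p1 + 4*p2 + 8*p3} of a division distribution.
#'
#' @param probs numeric 4-vector, or a matrix with 4 columns (one
#'   distribution per row), as returned by [dkoDivisionProbs()].
#' @return numeric vector of expected descendant counts in \code{[0, 8]}.
#' @examples
#' expectedDescendants(c(0, 1, 0, 0))  # wild-type: 2
#' @export
expectedDescendants <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  stopifnot(ncol(probs) == 4)
  as.numeric(probs %*% c(0, 2, 4, 8))
}

#' Simulated true genetic interaction
#'
#' The ground-truth genetic interaction of a gene pair is defined on the
#' growth-rate scale as the difference in expected descendants per doubling
#' cycle between the interaction-perturbed ("jiggled") phenotype pair and
#' the base phenotype pair:
#' \deqn{\pi = E(C_y \mid p_1^I, p_2^I) - E(C_y \mid p_1, p_2)}
#' Non-interacting pairs have \code{p_i^I = p_i} and hence \code{pi = 0}.
#' \code{pi} is computed from gene-level phenotypes only; guide efficacy
#' never enters the truth value.
#'
#' @param p1,p2 base phenotypes of the two genes.
#' @param p1I,p2I interaction-jiggled phenotypes (equal to \code{p1},
#'   \code{p2} for non-interacting pairs).
#' @return numeric vector of interaction values in \code{[-8, 8]};
#'   negative values are synthetic-sick/lethal, positive are buffering.
#' @examples
#' trueGI(0.4, -0.03, 0.27, 0.01)  # -0.1506
#' @export
trueGI <- function(p1, p2, p1I, p2I) {
  expectedDescendants(dkoDivisionProbs(p1I, p2I)) -
    expectedDescendants(dkoDivisionProbs(p1, p2))
}
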