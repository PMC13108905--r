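#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig-class]. Defaults are the systematic-run
#' baseline parameterization: 120 genes at coverage 100x, 3 guides per
#' gene, 3\% interacting pairs with jiggle SD 1.5, gene classes
#' 15\%/5\%/75\%/5\% (negative/positive/wild-type/control), phenotype
#' means \eqn{\pm 0.75} (SD 0.1) for the negative/positive classes,
#' wild-type SD 0.25, \code{sigmaF = 1/3.29} (a 10-fold gap between the
#' 95th and 5th percentiles of the initial count distribution), all guides
#' fully efficient (\code{mode = "CRISPRn-100%Eff"}), bottleneck at twice
#' the initial library size with a single encounter, and MOI
#' \code{lambda = 0.3}.
#'
#' Percentage-style arguments (\code{pctGI}, \code{pctHeg} and the class
#' fractions) may be given either as fractions or as percent values; any
#' value greater than 1 is divided by 100.
#'
#' @param n number of unique genes.
#' @param coverage cells per construct in the initial library.
#' @param nGuides guides per gene.
#' @param pctGI fraction (or percent) of eligible gene pairs flagged
#'   interacting.
#' @param sigmaGI SD of the interaction jiggle.
#' @param pctNeg,pctPos,pctWT,pctCtrl,pctUnknown gene-class fractions (or
#'   percents); must sum to 1 (or 100). \code{pctWT = NA} assigns the
#'   remainder to the wild-type class.
#' @param muNeg,sigmaNeg,muPos,sigmaPos,sigmaWT,sigmaUnknown phenotype
#'   truncated-normal parameters per class.
#' @param sigmaF SD of log10 initial frequency seeds; see
#'   [sigmaFFromConfidence()].
#' @param pctHeg fraction (or percent) of high-efficacy guides.
#' @param muHigh,sigmaHigh,muLow,sigmaLow guide-efficacy parameters.
#' @param mode \code{"CRISPRn"} or \code{"CRISPRn-100%Eff"}.
#' @param nBottleneck bottleneck threshold as a multiple of the initial
#'   library size.
#' @param nEncounters bottleneck encounters before stopping.
#' @param moiLambda Poisson MOI rate.
#' @param maxDoublings cap on doubling cycles.
#' @param pseudocount LFC pseudocount; \code{NA} = \code{1/L0}.
#' @param dirichletAlpha Dirichlet concentration for guide allocation.
#' @param seed default RNG seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig()                 # baseline
#' cfg500 <- simConfig(coverage = 500)
#' @export
simConfig <- function(n = 120, coverage = 100, nGuides = 3,
                      pctGI = 0.03, sigmaGI = 1.5,
                      pctNeg = 0.15, pctPos = 0.05, pctWT = NA,
                      pctCtrl = 0.05, pctUnknown = 0,
                      muNeg = -0.75, sigmaNeg = 0.1,
                      muPos = 0.75, sigmaPos = 0.1,
                      sigmaWT = 0.25, sigmaUnknown = 0.25,
                      sigmaF = 1 / 3.29, pctHeg = 1,
                      muHigh = 0.9, sigmaHigh = 0.1,
                      muLow = 0.05, sigmaLow = 0.07,
                      mode = "CRISPRn-100%Eff",
                      nBottleneck = 2, nEncounters = 1,
                      moiLambda = 0.3, maxDoublings = 30,
                      pseudocount = NA_real_, dirichletAlpha = 100,
                      seed = 1L) {
  asFrac <- function(x) ifelse(!is.na(x) & x > 1, x / 100, x)
  pctGI <- asFrac(pctGI); pctHeg <- asFrac(pctHeg)
  cf <- c(negative = pctNeg, positive = pctPos, wild_type = pctWT,
          control = pctCtrl, unknown = pctUnknown)
  known <- sum(cf, na.rm = TRUE)
  if (known > 1 + 1e-9) cf <- cf / 100      # percent-style fractions
  if (is.na(cf[["wild_type"]])) {
    cf[["wild_type"]] <- 1 - sum(cf, na.rm = TRUE)
  }
  new("SimConfig",
      n = as.integer(n), coverage = as.numeric(coverage),
      nGuides = as.integer(nGuides),
      pctGI = as.numeric(pctGI), sigmaGI = as.numeric(sigmaGI),
      classFractions = cf,
      muNeg = muNeg, sigmaNeg = sigmaNeg, muPos = muPos,
      sigmaPos = sigmaPos, sigmaWT = sigmaWT, sigmaUnknown = sigmaUnknown,
      sigmaF = sigmaF, pctHeg = as.numeric(pctHeg),
      muHigh = muHigh, sigmaHigh = sigmaHigh, muLow = muLow,
      sigmaLow = sigmaLow, mode = mode,
      nBottleneck = as.numeric(nBottleneck),
      nEncounters = as.numeric(nEncounters),
      moiLambda = moiLambda, maxDoublings = as.integer(maxDoublings),
      pseudocount = as.numeric(pseudocount),
      dirichletAlpha = dirichletAlpha, seed = as.integer(seed))
}

.CONFIG_KEYS <- c(
  n = "n", coverage = "coverage", n_guides = "nGuides",
  pct_gi = "pctGI", sigma_gi = "sigmaGI",
  pct_neg = "pctNeg", pct_pos = "pctPos", pct_wt = "pctWT",
  pct_ctrl = "pctCtrl", pct_unknown = "pctUnknown",
  mu_neg = "muNeg", sigma_neg = "sigmaNeg",
  mu_pos = "muPos", sigma_pos = "sigmaPos",
  sigma_wt = "sigmaWT", sigma_unknown = "sigmaUnknown",
  sigma_f = "sigmaF", pct_heg = "pctHeg",
  mu_high = "muHigh", sigma_high = "sigmaHigh",
  mu_low = "muLow", sigma_low = "sigmaLow",
  mode = "mode", n_b = "nBottleneck", n_e = "nEncounters",
  moi_lambda = "moiLambda", max_doublings = "maxDoublings",
  pseudocount = "pseudocount", dirichlet_alpha = "dirichletAlpha",
  seed = "seed")

#' Read a simulation configuration from YAML or JSON
#'
#' Keys are the snake_case parameter names (\code{n}, \code{coverage},
#' \code{n_guides}, \code{pct_gi}, \code{sigma_gi}, \code{pct_neg}, ...,
#' \code{mode}, \code{n_b}, \code{n_e}, \code{moi_lambda},
#' \code{pseudocount}, \code{dirichlet_alpha}, \code{seed}). Unset keys
#' take the baseline defaults of [simConfig()]; unknown keys are an error.
#' An empty file yields the baseline configuration.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a validated [SimConfig-class].
#' @seealso [writeSimConfig()] for the inverse.
#' @export
readSimConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  vals <- vals[!vapply(vals, is.null, logical(1))]
  bad <- setdiff(names(vals), names(.CONFIG_KEYS))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  names(vals) <- .CONFIG_KEYS[names(vals)]
  do.call(simConfig, vals)
}

#' Write a simulation configuration to YAML or JSON
#'
#' @param config a [SimConfig-class].
#' @param path output path; format chosen by extension
#'   (\code{.json} vs anything else = YAML).
#' @return \code{path}, invisibly.
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(is(config, "SimConfig"))
  cf <- config@classFractions
  vals <- list(
    n = config@n, coverage = config@coverage, n_guides = config@nGuides,
    pct_gi = config@pctGI, sigma_gi = config@sigmaGI,
    pct_neg = unname(cf["negative"]), pct_pos = unname(cf["positive"]),
    pct_wt = unname(cf["wild_type"]), pct_ctrl = unname(cf["control"]),
    pct_unknown = unname(cf["unknown"]),
    mu_neg = config@muNeg, sigma_neg = config@sigmaNeg,
    mu_pos = config@muPos, sigma_pos = config@sigmaPos,
    sigma_wt = config@sigmaWT, sigma_unknown = config@sigmaUnknown,
    sigma_f = config@sigmaF, pct_heg = config@pctHeg,
    mu_high = config@muHigh, sigma_high = config@sigmaHigh,
    mu_low = config@muLow, sigma_low = config@sigmaLow,
    mode = config@mode, n_b = config@nBottleneck,
    n_e = config@nEncounters, moi_lambda = config@moiLambda,
    max_doublings = config@maxDoublings,
    pseudocount = config@pseudocount,
    dirichlet_alpha = config@dirichletAlpha, seed = config@seed)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    yaml::write_yaml(vals, path, precision = 15)
  }
  invisible(path)
}

#' Initial-count dispersion from a confidence level
#'
#' The dispersion of the initial single-knockout frequency distribution is
#' parameterised by \code{sigmaF}, the SD of the log10 frequency seeds.
#' Choosing \code{sigmaF = 1 / (2 * z)}, with \code{z} the standard-normal
#' quantile at \code{(1 + conf) / 2}, makes the gap between the upper and
#' lower \code{conf}-level percentiles of the log10 frequencies exactly
#' one decade. At \code{conf = 0.90} (z = 1.645, two-sided gap 3.29) this
#' yields the default \code{1/3.29}, i.e. a 10-fold difference between the
#' 95th and 5th percentiles of the initial count distribution.
#'
#' @param conf confidence level in (0, 1).
#' @return positive numeric \code{sigmaF}.
#' @examples
#' sigmaFFromConfidence(0.90)  # 1/3.29
#' sigmaFFromConfidence(0.80)  # 1/2.56
#' @export
sigmaFFromConfidence <- function(conf) {
  if (!is.numeric(conf) || any(conf <= 0) || any(conf >= 1)) {
    stop("conf must lie strictly between 0 and 1")
  }
  1 / (2 * qnorm((1 + conf) / 2))
}

#' Preset screen configurations
#'
#' \describe{
#'   \item{baseline}{the systematic-run baseline (the [simConfig()]
#'     defaults).}
#'   \item{mimic_shen}{120 genes, 3 guides/gene, 3\% GI, dispersion from an
#'     80\% confidence level (\code{sigmaF = 1/2.56}).}
#'   \item{mimic_doench}{28 genes, 5 guides/gene, 3\% GI,
#'     \code{sigmaF = 1/3.29}.}
#'   \item{mimic_fong}{246 genes (64 negative, 178 unknown-class with
#'     phenotypes on \code{[-0.5, 0.5]}, 4 controls), 3 guides/gene,
#'     coverage 1000x, \code{sigmaF = 1/2.56}, MOI 0.3, 3 total doublings;
#'     run with two replicates to mirror the dual-transduction design.}
#' }
#' Fields not printed for a mimicking run inherit the baseline defaults.
#'
#' @param name one of \code{"baseline"}, \code{"mimic_shen"},
#'   \code{"mimic_doench"}, \code{"mimic_fong"}.
#' @return a [SimConfig-class].
#' @examples
#' presetConfig("mimic_doench")@nGuides  # 5
#' @export
presetConfig <- function(name = c("baseline", "mimic_shen",
                                  "mimic_doench", "mimic_fong")) {
  name <- match.arg(name)
  switch(name,
    baseline = simConfig(),
    mimic_shen = simConfig(n = 120, nGuides = 3, pctGI = 0.03,
                           sigmaF = sigmaFFromConfidence(0.80)),
    mimic_doench = simConfig(n = 28, nGuides = 5, pctGI = 0.03,
                             sigmaF = sigmaFFromConfidence(0.90)),
    mimic_fong = simConfig(n = 246, nGuides = 3, coverage = 1000,
                           pctGI = 0.03,
                           pctNeg = 64 / 246, pctPos = 0, pctWT = 0,
                           pctCtrl = 4 / 246, pctUnknown = 178 / 246,
                           sigmaF = sigmaFFromConfidence(0.80),
                           moiLambda = 0.3))
}

#' @describeIn SimConfig number of constructs implied by the
#'   configuration: \code{n * nGuides + choose(n, 2) * nGuides^2}.
#' @param config,object a \code{SimConfig}.
#' @export
nConstructs <- function(config) {
  stopifnot(is(config, "SimConfig"))
  n <- config@n; ng <- config@nGuides
  as.integer(n * ng + n * (n - 1L) / 2L * ng^2)
}

#' @describeIn SimConfig requested initial library size
#'   \code{coverage * nConstructs}.
#' @export
librarySize <- function(config) {
  stopifnot(is(config, "SimConfig"))
  config@coverage * nConstructs(config)
}

setMethod("show", "SimConfig", function(object) {
  cf <- object@classFractions
  cat("SimConfig:", object@n, "genes x", object@nGuides,
      "guides/gene @", object@coverage, "x coverage\n")
  cat(sprintf("  constructs: %d (L0 = %g)\n", nConstructs(object),
              librarySize(object)))
  cat(sprintf("  classes: %.0f%% neg / %.0f%% pos / %.0f%% wt / %.0f%% ctrl / %.0f%% unk\n",
              100 * cf["negative"], 100 * cf["positive"], 100 * cf["wild_type"],
              100 * cf["control"], 100 * cf["unknown"]))
  cat(sprintf("  GI: %.1f%% of eligible pairs, sigmaGI = %g\n",
              100 * object@pctGI, object@sigmaGI))
  cat(sprintf("  guides: mode %s, %.0f%% high-efficacy; sigmaF = %g\n",
              object@mode, 100 * object@pctHeg, object@sigmaF))
  cat(sprintf("  bottleneck: > %gx L0, %g encounter(s), moi lambda = %g, max %d doublings\n",
              object@nBottleneck, object@nEncounters, object@moiLambda,
              object@maxDoublings))
})

setMethod("show", "DKOLibrary", function(object) {
  cfg <- object@config
  cat("DKOLibrary:", nrow(object@constructs), "constructs over",
      cfg@n, "genes (", sum(object@constructs$construct_kind == "SKO"),
      "SKO /", sum(object@constructs$construct_kind == "DKO"), "DKO )\n")
  cat("  interacting pairs:", sum(object@interactionMap$I == 1L),
      "of", nrow(object@interactionMap), "\n")
  cat("  initial library size:", sum(object@constructs$c0), "cells\n")
})
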