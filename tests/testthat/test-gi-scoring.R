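test_that("dLFC equals the mean-LFC deviation from additive single fitness", {
  se <- simulateScreen(smallConfig(pctGI = 0.3), seed = 50)
  sc <- scoreInteractions(se)
  rd <- SummarizedExperiment::rowData(se)
  lfc <- meanLFC(se)
  # independent recomputation with tapply
  sko <- rd$construct_kind == "SKO"
  smf <- tapply(lfc[sko], rd$k1[sko], mean)
  dkoLfc <- tapply(lfc[!sko], rd$pair_id[!sko], mean)
  i <- 37  # arbitrary pair
  expect_equal(sc$dko_lfc[i], unname(dkoLfc[as.character(i)]))
  expect_equal(sc$smf1[i], unname(smf[as.character(sc$k1[i])]))
  expect_equal(sc$dlfc, sc$dko_lfc - sc$smf1 - sc$smf2)
  expect_equal(nrow(sc), 12 * 11 / 2)
  # z-standardization
  expect_equal(mean(sc$zdlfc), 0, tolerance = 1e-9)
  expect_equal(sd(sc$zdlfc), 1, tolerance = 1e-9)
})

test_that("Pearson correlation matches the product-moment hand formula", {
  handR <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  a <- c(1, 2, 3); b <- c(2, 4, 7)
  expect_equal(dkoscreen:::pearsonR(a, b), handR(a, b))
  expect_equal(handR(a, b), 5 / sqrt(2 * 114 / 9), tolerance = 1e-12)
  expect_equal(dkoscreen:::pearsonR(a, a), 1)
  expect_equal(dkoscreen:::pearsonR(a, -a), -1)
  expect_error(dkoscreen:::pearsonR(a, c(1, 1, 1)), "zero variance")
  expect_error(dkoscreen:::pearsonR(1:2, 1:2), "length")
})

test_that("precision and recall at k follow their definitions", {
  npair <- 300
  pi <- c(seq(-2, -0.01, length.out = 150), rep(0, 100),
          seq(0.01, 1, length.out = 50))
  # perfect ranking: prediction set nested in the truth set
  perfect <- data.frame(pi = pi, dlfc = rank(pi))
  pr <- precisionRecallAtK(perfect, kPred = 80, kTruth = 100)
  expect_equal(unname(pr), c(1, 0.8))
  # nested smaller prediction set keeps precision 1
  pr2 <- precisionRecallAtK(perfect, kPred = 10, kTruth = 100)
  expect_equal(unname(pr2), c(1, 0.1))
  # constructed half-overlap: 40 truth pairs ranked first, then 40 others
  sc <- data.frame(pi = pi, dlfc = 0)
  sc$dlfc <- rank(sc$pi) + 1000          # baseline: worst ranks
  sc$dlfc[1:40] <- 1:40                  # 40 strongest truths predicted first
  sc$dlfc[201:240] <- 41:80              # then 40 null pairs
  pr3 <- precisionRecallAtK(sc, kPred = 80, kTruth = 100)
  expect_equal(unname(pr3), c(0.5, 0.4))
  # too few strictly negative truths warns (and errors in strict mode)
  few <- data.frame(pi = c(rep(-1, 50), rep(0, 100)), dlfc = runif(150))
  expect_warning(precisionRecallAtK(few, kPred = 10, kTruth = 100),
                 "padded")
  expect_error(precisionRecallAtK(few, kPred = 10, kTruth = 100,
                                  requireNegatives = TRUE))
})

test_that("random rankings recover the hypergeometric precision baseline", {
  set.seed(51)
  npair <- 7140
  pi <- c(runif(120, -3, -0.01), rep(0, npair - 120))
  prec <- replicate(300, {
    sc <- data.frame(pi = pi, dlfc = sample(npair))
    precisionRecallAtK(sc, kPred = 80, kTruth = 100)[["precision"]]
  })
  expect_lt(abs(mean(prec) - 100 / npair), 0.003)
})

test_that("negative-interaction AUC-PR behaves like a PR area", {
  # perfect separation
  sc <- data.frame(pi = c(rep(-1, 20), rep(0, 80)),
                   dlfc = c(seq(-5, -3, length.out = 20),
                            seq(-1, 2, length.out = 80)))
  expect_equal(aucprNegative(sc), 1)
  # invariant to strictly monotone transforms of the score
  sc2 <- data.frame(pi = rnorm(200), dlfc = rnorm(200))
  sc2$pi[1:40] <- -abs(sc2$pi[1:40]) - 0.1
  a1 <- aucprNegative(sc2)
  sc3 <- sc2; sc3$dlfc <- atan(sc3$dlfc / 3) * 7 - 2
  expect_equal(aucprNegative(sc3), a1, tolerance = 1e-12)
  # single positive ranked first
  sc4 <- data.frame(pi = c(-1, rep(0, 9)), dlfc = 1:10)
  expect_equal(aucprNegative(sc4), 1)
  # random scores give AUC-PR near the prevalence
  set.seed(52)
  q <- 0.1
  aucs <- replicate(200, {
    sc5 <- data.frame(pi = c(rep(-1, 50), rep(0, 450)), dlfc = rnorm(500))
    aucprNegative(sc5)
  })
  expect_lt(abs(mean(aucs) - q), 0.03)
  expect_error(aucprNegative(data.frame(pi = rep(0, 5), dlfc = rnorm(5))))
})

test_that("read concentration in the top constructs is computed over constructs", {
  expect_equal(fractionReadsTop(rep(5, 20)), 0.05)
  one <- c(100, rep(0, 19))
  expect_equal(fractionReadsTop(one), 1)
  expect_equal(fractionReadsTop(c(50, 30, 20)), 0.5)  # m = ceiling(0.15) = 1
  expect_error(fractionReadsTop(numeric(0)))
  expect_error(fractionReadsTop(c(0, 0)))
})

test_that("replicate correlation needs matching screens and finds shared signal", {
  se <- simulateScreen(smallConfig(), nReplicates = 2, seed = 53)
  r <- replicateCorrelation(se)
  expect_true(r > 0 && r < 1)
  expect_equal(replicateCorrelation(se, rep1 = 1, rep2 = 1), 1)
  expect_error(replicateCorrelation(se, rep1 = 1, rep2 = 3), "too few")
  expect_true(replicateCorrelation(se, quantity = "freq2") > 0)
})

test_that("the metric panel is assembled coherently", {
  se <- simulateScreen(simConfig(n = 20, coverage = 50, pctGI = 0.5),
                       nReplicates = 2, seed = 54)
  sc <- scoreInteractions(se)
  m <- screenMetrics(se, sc, kPred = 8, kTruth = 10)
  expect_named(m, c("r_dlfc_pi", "precision_at_k", "recall_at_k",
                    "aucpr_negative", "top5_fraction", "replicate_r"))
  expect_equal(m$r_dlfc_pi, cor(sc$dlfc, sc$pi))
  expect_true(m$top5_fraction > 0 && m$top5_fraction <= 1)
  expect_equal(m$replicate_r, replicateCorrelation(se))
})
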