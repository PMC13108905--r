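test_that("truncated-normal draws stay in range and match analytic moments", {
  set.seed(1)
  x <- rtruncnorm(5000, 0, 0.25, -0.025, 0.025)
  expect_true(all(x >= -0.025 & x <= 0.025))
  # nearly-degenerate sigma concentrates at the mean
  y <- rtruncnorm(10, -0.75, 1e-9, -1, -0.025)
  expect_equal(y, rep(-0.75, 10), tolerance = 1e-6)
  expect_equal(rtruncnorm(5, -0.5, 0, -1, 0), rep(-0.5, 5))
  # closed-form truncated-normal mean as oracle
  z <- rtruncnorm(1e5, -0.75, 0.1, -1, -0.025)
  m <- dkoscreen:::truncnormMean(-0.75, 0.1, -1, -0.025)
  expect_lt(abs(mean(z) - m), 3 * sd(z) / sqrt(length(z)))
  w <- rtruncnorm(1e5, 0.05, 0.07, 0, 0.6)
  m2 <- dkoscreen:::truncnormMean(0.05, 0.07, 0, 0.6)
  expect_lt(abs(mean(w) - m2), 3 * sd(w) / sqrt(length(w)))
  expect_error(rtruncnorm(1, 0, 1, 1, 0))
  expect_error(rtruncnorm(1, 0, 1e-3, 5, 6), "vanishing")
})

test_that("gene panel realizes class counts, supports and seeds", {
  set.seed(2)
  panel <- initGenePanel(simConfig())
  tab <- table(panel$gene_class)
  expect_equal(as.vector(tab[c("negative", "positive", "wild_type",
                               "control")]),
               c(18L, 6L, 90L, 6L))
  expect_true(all(panel$p[panel$gene_class == "control"] == 0))
  expect_true(all(panel$p[panel$gene_class == "negative"] >= -1 &
                  panel$p[panel$gene_class == "negative"] <= -0.025))
  expect_true(all(panel$p[panel$gene_class == "positive"] >= 0.025 &
                  panel$p[panel$gene_class == "positive"] <= 1))
  expect_true(all(abs(panel$p[panel$gene_class == "wild_type"]) <= 0.025))
  expect_true(all(panel$f0_prime > 0))
  # vanishing dispersion pins every frequency seed at 1
  tiny <- initGenePanel(simConfig(sigmaF = 1e-12))
  expect_equal(tiny$f0_prime, rep(1, 120), tolerance = 1e-9)
})

test_that("interaction flags are exact, control-free, and vanish with the jiggle", {
  set.seed(3)
  cfg <- toyConfig()                     # 3 genes incl. one control, pctGI = 1
  panel <- initGenePanel(cfg)
  imap <- initInteractionMap(panel, cfg)
  expect_equal(nrow(imap), 3L)
  ctrl <- panel$gene_id[panel$gene_class == "control"]
  hasCtrl <- imap$k1 == ctrl | imap$k2 == ctrl
  expect_equal(sum(imap$I), 1L)          # only the control-free pair
  expect_true(all(imap$I[hasCtrl] == 0L))
  expect_true(all(imap$pi[imap$I == 0L] == 0))
  expect_equal(imap$f_pair,
               (panel$f0_prime[imap$k1] + panel$f0_prime[imap$k2]) / 2)

  # no interactions requested
  cfg0 <- smallConfig(pctGI = 0)
  imap0 <- initInteractionMap(initGenePanel(cfg0), cfg0)
  expect_true(all(imap0$I == 0L) && all(imap0$pi == 0))

  # degenerate jiggle leaves phenotypes and interactions unchanged
  cfgEps <- smallConfig(pctGI = 0.5, sigmaGI = 1e-9)
  panelE <- initGenePanel(cfgEps)
  imapE <- initInteractionMap(panelE, cfgEps)
  expect_equal(imapE$p1_I, imapE$p1, tolerance = 1e-6)
  expect_true(all(abs(imapE$pi) < 1e-5))
})

test_that("flag counts are exact over random configurations", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(4:15, 1)
    pg <- runif(1, 0, 1)
    cfg <- simConfig(n = n, nGuides = 1, pctGI = pg, pctNeg = 0.25,
                     pctPos = 0.25, pctCtrl = 0.25, pctWT = NA)
    panel <- initGenePanel(cfg)
    imap <- initInteractionMap(panel, cfg)
    ctrl <- panel$gene_class == "control"
    eligible <- sum(!(ctrl[imap$k1] | ctrl[imap$k2]))
    expect_equal(sum(imap$I), round(pg * eligible))
    expect_true(all(imap$I[ctrl[imap$k1] | ctrl[imap$k2]] == 0L))
  }
})

test_that("guide efficacies respect mode and the 0.6 separation", {
  set.seed(5)
  g1 <- initGuideEfficacies(simConfig(mode = "CRISPRn-100%Eff", pctHeg = 0.2))
  expect_true(all(g1$eff == 1))
  cfg <- simConfig(mode = "CRISPRn", pctHeg = 0.4)
  g2 <- initGuideEfficacies(cfg)
  expect_equal(sum(g2$eff_class == "high"), round(0.4 * 120 * 3))
  expect_true(all(g2$eff[g2$eff_class == "high"] >= 0.6))
  expect_true(all(g2$eff[g2$eff_class == "low"] <= 0.6))
  expect_true(all(g2$eff >= 0 & g2$eff <= 1))
  # all-low library has mean near the truncated low-efficacy mean
  g3 <- initGuideEfficacies(simConfig(mode = "CRISPRn", pctHeg = 0))
  m <- dkoscreen:::truncnormMean(0.05, 0.07, 0, 0.6)
  expect_lt(abs(mean(g3$eff) - m), 3 * sd(g3$eff) / sqrt(nrow(g3)))
})

test_that("toy library has 18 constructs summing to the requested size", {
  set.seed(6)
  lib <- buildLibrary(toyConfig())
  ct <- constructTable(lib)
  expect_equal(nrow(ct), 18L)
  expect_equal(sum(ct$construct_kind == "SKO"), 6L)
  expect_equal(librarySize(lib@config), 1800)
  expect_lt(abs(sum(ct$c0) - 1800), 18 / 2 + 1)
  expect_equal(sum(ct$f_rel0), 1, tolerance = 1e-9)
})

test_that("frequency allocation satisfies the pair-balance identity exactly", {
  set.seed(7)
  lib <- buildLibrary(smallConfig())
  ct <- constructTable(lib)
  ng <- lib@config@nGuides
  sko <- ct[ct$construct_kind == "SKO", ]
  skoSum <- tapply(sko$fg, sko$k1, sum)
  dko <- ct[ct$construct_kind == "DKO", ]
  pairSum <- tapply(dko$fg, dko$pair_id, sum)
  imap <- interactionMap(lib)
  lhs <- (skoSum[as.character(imap$k1)] + skoSum[as.character(imap$k2)]) /
    (2 * ng)
  rhs <- unname(pairSum[as.character(seq_len(nrow(imap)))]) / ng^2
  expect_equal(unname(lhs), rhs, tolerance = 1e-12)
  # division-probability rows are distributions
  dp <- as.matrix(ct[, c("d0", "d1", "d2", "d3")])
  expect_true(all(dp >= 0))
  expect_equal(unname(rowSums(dp)), rep(1, nrow(ct)), tolerance = 1e-12)
})

test_that("construct count formula holds over random library shapes", {
  set.seed(8)
  for (i in 1:8) {
    n <- sample(2:10, 1); ng <- sample(1:5, 1)
    cfg <- simConfig(n = n, nGuides = ng, coverage = 5)
    lib <- buildLibrary(cfg)
    expect_equal(nrow(constructTable(lib)), n * ng + n * (n - 1) / 2 * ng^2)
    expect_lte(abs(sum(constructTable(lib)$c0) - librarySize(cfg)),
               nrow(constructTable(lib)) / 2)
  }
})

test_that("large Dirichlet concentration equalizes within-gene frequencies", {
  set.seed(9)
  lib <- buildLibrary(smallConfig(dirichletAlpha = 1e8))
  ct <- constructTable(lib)
  sko <- ct[ct$construct_kind == "SKO", ]
  sp <- split(sko$fg, sko$k1)
  rel <- vapply(sp, function(v) diff(range(v)) / mean(v), numeric(1))
  expect_true(all(rel < 1e-3))
})

test_that("control-partnered dual constructs share their partner's division law", {
  set.seed(10)
  cfg <- simConfig(n = 8, nGuides = 2, coverage = 20, pctGI = 0,
                   pctCtrl = 0.25, pctNeg = 0.25, pctPos = 0.125, pctWT = NA,
                   mode = "CRISPRn-100%Eff")
  lib <- buildLibrary(cfg)
  ct <- constructTable(lib)
  panel <- genePanel(lib)
  ctrl <- panel$gene_id[panel$gene_class == "control"]
  dko <- ct[ct$construct_kind == "DKO" & ct$k2 %in% ctrl &
              !(ct$k1 %in% ctrl), ]
  sko <- ct[ct$construct_kind == "SKO", ]
  for (i in seq_len(nrow(dko))) {
    partner <- sko[sko$k1 == dko$k1[i] & sko$j1 == dko$j1[i], ]
    expect_equal(unname(unlist(dko[i, c("d0", "d1", "d2", "d3")])),
                 unname(unlist(partner[, c("d0", "d1", "d2", "d3")])))
  }
})

test_that("a user panel override fixes classes and phenotypes", {
  set.seed(11)
  ov <- read.delim(system.file("extdata", "toy_panel.tsv",
                               package = "dkoscreen"))
  expect_equal(ov$p, c(-0.4, -0.03, NA))
  lib <- buildLibrary(toyConfig(), panelOverride = ov)
  panel <- genePanel(lib)
  expect_equal(panel$gene_class, c("negative", "wild_type", "control"))
  expect_equal(panel$p[1:2], c(-0.4, -0.03))
  expect_equal(panel$p[3], 0)
  imap <- interactionMap(lib)
  expect_equal(imap$I, c(1L, 0L, 0L))    # only pair (1,2) is eligible
})
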