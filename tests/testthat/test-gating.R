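test_that("cutpoint fitting: fixed, quantile and valley behave as specified", {
  expect_equal(fitCutpoint(1:10, "fixed", list(value = 2)), 2)
  expect_equal(fitCutpoint(rep(7, 200), "quantile", list(prob = 0.5)), 7)
  set.seed(1)
  x <- c(rnorm(2000, 1, 0.2), rnorm(2000, 3, 0.2))
  cut <- fitCutpoint(x, "valley")
  expect_gt(cut, 1.6)
  expect_lt(cut, 2.4)
  expect_warning(out <- fitCutpoint(rnorm(500), "valley", list(default = 9)),
                 "unimodal")
  expect_equal(out, 9)
  expect_error(fitCutpoint(rnorm(50), "valley"), "100 events")
})

test_that("gate membership is hierarchical: child counts never exceed parents", {
  s <- simulateEvents(testCohort(), "D030", 1, "surface")  # a HIGH donor
  gates <- defaultGates("surface")
  ag <- applyGates(s, gates)
  g <- gateTable(gates)
  for (i in seq_len(nrow(g))) {
    parentN <- if (g$parent[i] == "root") sum(!isBead(s)) else
      ag$counts[[g$parent[i]]]
    expect_lte(ag$counts[[g$name[i]]], parentN)
  }
})

test_that("a bright event traverses the full CD3/TCRab/CD8/CD57 chain", {
  m <- matrix(c(1e5, 5e4, 5000, 10, 5000, 5000, 10, 5000, 10, 5000, 5000),
              nrow = 1,
              dimnames = list(NULL, c("FSC-A", "SSC-A", "CD3", "CD4", "CD5",
                                      "CD8", "CD56", "CD57", "CD94", "TCRab",
                                      "KLRG1")))
  ag <- applyGates(manualSample(m), defaultGates("surface"))
  for (gate in c("lymph", "cd3", "tab", "cd8hi", "cd8t", "cd8t_57",
                 "cd8t_57_klrg1"))
    expect_true(ag$membership[1, gate], label = gate)
})

test_that("missing channels are reported by name and empty tables gate to zero", {
  m <- matrix(1, 2, 2, dimnames = list(NULL, c("FSC-A", "SSC-A")))
  expect_error(applyGates(manualSample(m), defaultGates("surface")), "CD3")
  empty <- matrix(numeric(0), 0, 11,
                  dimnames = list(NULL, c("FSC-A", "SSC-A", "CD3", "CD4",
                                          "CD5", "CD8", "CD56", "CD57",
                                          "CD94", "TCRab", "KLRG1")))
  ag <- applyGates(manualSample(empty), defaultGates("surface"))
  expect_true(all(ag$counts == 0))
})

test_that("gating agrees with event-level ground truth on well-separated mixtures", {
  co <- testCohort()
  for (id in c("D001", "D025")) {
    s <- simulateEvents(co, id, 1, "surface")
    ag <- applyGates(s, defaultGates("surface"))
    tr <- eventTruth(s)
    nb <- !isBead(s)
    agree <- function(gate, truthVec)
      mean(ag$membership[nb, gate] == truthVec[nb])
    expect_gte(agree("lymph", tr$is_lymph), 0.99)
    expect_gte(agree("cd8t_57", tr$lineage == "cd8T" & tr$cd57 & tr$is_lymph),
               0.99)
    # gamma-delta surrogate (CD3+TCRab-) matches the planted gd lineage
    expect_gte(agree("tgd", tr$lineage == "gdT" & tr$is_lymph), 0.99)
  }
})

test_that("gamma-delta surrogate frequencies track ground truth across donors", {
  co <- testCohort()
  ids <- donors(co)$donor_id[seq(1, 30, by = 3)]
  est <- tru <- numeric(0)
  for (id in ids) {
    s <- simulateEvents(co, id, 1, "surface", nEvents = 4000)
    ag <- applyGates(s, defaultGates("surface"))
    tr <- eventTruth(s)[!isBead(s), ]
    est <- c(est, ag$counts[["tgd"]] / ag$counts[["cd3"]])
    tru <- c(tru, sum(tr$lineage == "gdT") /
               sum(tr$lineage %in% c("cd4T", "cd8T", "dnT", "dpT", "gdT")))
  }
  expect_gt(stats::cor(est, tru), 0.99)
})

test_that("bead-normalised absolute counts follow the ratio formula", {
  expect_equal(absoluteCount(5000, 2500, 50), 1.0e8)  # 100 cells/uL
  expect_equal(absoluteCount(0, 1000, 50), 0)
  expect_equal(absoluteCount(5000, 5000, 50), absoluteCount(5000, 2500, 50) / 2)
  expect_error(absoluteCount(10, 0, 50), "bead")
})

test_that("feature extraction recovers a planted fraction to binomial accuracy", {
  cfg <- degenerateHighConfig(frac = 0.20, events = 50000)
  co <- simulateCohort(cfg, seed = 9)
  hi <- donors(co)$donor_id[donors(co)$group == "HIGH"]
  f <- computeFeatures(simulateEvents(co, hi, 1, "surface"))
  se <- 100 * sqrt(0.2 * 0.8 / 47500)   # ~95% of events are lymphocytes
  expect_lt(abs(f$pct_cd8cd57_of_lymph - 20), 3 * se)
})

test_that("subset fractions within TCRab+ T cells partition completely", {
  s <- simulateEvents(testCohort(), "D015", 1, "surface")
  ag <- applyGates(s, defaultGates("surface"))
  m <- ag$membership
  tab <- m[, "tab"]
  dn <- tab & !m[, "cd4hi"] & !m[, "cd8hi"]
  total <- sum(m[, "cd4t"]) + sum(m[, "cd8t"]) + sum(m[, "dpt"]) + sum(dn)
  expect_equal(100 * total / sum(tab), 100)
})

test_that("degenerate samples flag features as missing rather than zero", {
  # all-CD4 sample: CD8 denominator is empty
  m <- matrix(rep(c(1e5, 5e4, 5000, 5000, 5000, 10, 10, 10, 10, 5000, 10),
                  each = 20), nrow = 20,
              dimnames = list(NULL, c("FSC-A", "SSC-A", "CD3", "CD4", "CD5",
                                      "CD8", "CD56", "CD57", "CD94", "TCRab",
                                      "KLRG1")))
  f <- computeFeatures(manualSample(m))
  expect_true(is.na(f$cd4_cd8_ratio))
  expect_true(is.na(f$pct_cd5dim_cd857))
  expect_true(is.na(f$lymph_count_per_L))  # no beads: no absolute counts
})

test_that("feature extraction recovers planted donor fractions cohort-wide", {
  feats <- testFeatures()
  dd <- donors(testCohort())
  f1 <- feats[feats$visit == 1, ]
  planted <- 100 * dd$p_frac_cd8cd57[match(f1$donor_id, dd$donor_id)]
  nLymph <- 4000 * 0.95
  se <- 100 * sqrt(planted / 100 * (1 - planted / 100) / nLymph)
  inBand <- abs(f1$pct_cd8cd57_of_lymph - planted) <= 3 * se
  expect_gte(mean(inBand), 0.95)
})
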