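test_that("default configuration encodes the study group structure", {
  cfg <- cohortConfig()
  expect_equal(cfg$group_sizes, c(HC = 56, LOW = 51, HIGH = 34))
  expect_equal(cfg$events_surface, 50000)
  expect_equal(cfg$visit_model$n_visits, 2L)
  expect_equal(cfg$visit_model$gap_days, c(210, 960))
  # per-group %CD8+CD57+ medians on the percent scale
  mp <- cfg$marker_profile
  med <- mp$median[mp$param == "frac_cd8cd57"]
  expect_equal(100 * med[mp$group[mp$param == "frac_cd8cd57"] == "HIGH"], 9.12)
})

test_that("simulation is deterministic given config and seed", {
  cfg <- smallConfig()
  a <- simulateCohort(cfg, seed = 5)
  b <- simulateCohort(cfg, seed = 5)
  expect_identical(donors(a), donors(b))
  expect_identical(genotypes(a), genotypes(b))
  expect_identical(serologyPlates(a), serologyPlates(b))
  sa <- simulateEvents(a, "D003", 2, "surface")
  sb <- simulateEvents(b, "D003", 2, "surface")
  expect_identical(intensities(sa), intensities(sb))
  expect_identical(eventTruth(sa), eventTruth(sb))
  # a different seed changes the draws
  expect_false(identical(donors(a)$p_frac_cd8cd57,
                         donors(simulateCohort(cfg, seed = 6))$p_frac_cd8cd57))
})

test_that("donor records satisfy their invariants", {
  dd <- donors(testCohort())
  expect_true(all(is.na(dd$onset_age[dd$group == "HC"])))
  ibm <- dd$group != "HC"
  expect_true(all(dd$onset_age[ibm] <= dd$age[ibm]))
  expect_true(all(dd$visit_gap_days >= 210 & dd$visit_gap_days <= 960))
  expect_true(all(dd$mobility_aid[dd$group == "HC"] == "none"))
  # visit dates strictly increase across visits
  s1 <- simulateEvents(testCohort(), "D001", 1)
  s2 <- simulateEvents(testCohort(), "D001", 2)
  expect_true(s2@visitDate > s1@visitDate)
})

test_that("planted per-donor fractions recover the configured location", {
  cfg <- cohortConfig(group_sizes = c(HC = 200, LOW = 1, HIGH = 1),
                      events_surface = 100)
  co <- simulateCohort(cfg, seed = 11)
  dd <- donors(co)
  hc <- dd[dd$group == "HC", ]
  mp <- cfg$marker_profile
  for (param in c("frac_cd8cd57", "klrg1_57pos_cd8", "cd94_57pos_cd8")) {
    row <- mp[mp$param == param & mp$group == "HC", ]
    loc <- log(row$median / (1 - row$median))
    est <- mean(log(hc[[paste0("p_", param)]] /
                      (1 - hc[[paste0("p_", param)]])))
    se <- row$sigma / sqrt(nrow(hc))
    expect_lt(abs(est - loc), 3 * se)
  }
})

test_that("a degenerate planted fraction is recovered to binomial accuracy", {
  cfg <- degenerateHighConfig(frac = 0.20, events = 50000)
  co <- simulateCohort(cfg, seed = 3)
  hi <- donors(co)$donor_id[donors(co)$group == "HIGH"]
  s <- simulateEvents(co, hi, 1, "surface")
  tr <- eventTruth(s)[!isBead(s), ]
  lymph <- tr$is_lymph
  frac <- sum(tr$lineage == "cd8T" & tr$cd57 & lymph) / sum(lymph)
  se <- sqrt(0.2 * 0.8 / sum(lymph))
  expect_lt(abs(frac - 0.20), 3 * se)
})

test_that("zero positive fractions give all-negative ground truth", {
  cfg <- smallConfig()
  mp <- cfg$marker_profile
  zero <- c("frac_cd8cd57", "cd57_in_cd4", "cd57_in_gd",
            grep("^(cd5dim|cd94|cd56|klrg1)_", unique(mp$param), value = TRUE),
            grep("^(ifng|perf|dual|ki67)", unique(mp$param), value = TRUE))
  mp$median[mp$param %in% zero] <- 0
  cfg$marker_profile <- mp
  co <- simulateCohort(cfg, seed = 2)
  s <- simulateEvents(co, "D001", 1, "surface", nEvents = 5000)
  tr <- eventTruth(s)[!isBead(s), ]
  expect_false(any(tr$cd57))
  expect_false(any(tr$cd94))
  expect_false(any(tr$cd56))
  expect_false(any(tr$klrg1))
  expect_false(any(tr$cd5state == "dim"))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(cohortConfig(group_sizes = c(HC = 0, LOW = 1, HIGH = 1)),
               "group_sizes")
  expect_error(cohortConfig(beads_per_uL = -1), "beads_per_uL")
  cfg <- smallConfig()
  cfg$marker_profile$sigma[1] <- -0.5
  expect_error(validateConfig(cfg), "marker_profile")
  cfg <- smallConfig()
  cfg$hla_model$freq_high[1] <- cfg$hla_model$freq_high[1] + 0.5
  expect_error(validateConfig(cfg), "hla_model")
})

test_that("every patient carries two alleles per locus and carriage recovers the model", {
  co <- simulateCohort(cohortConfig(group_sizes = c(HC = 1, LOW = 200, HIGH = 1),
                                    events_surface = 100), seed = 13)
  g <- genotypes(co)
  cnt <- table(g$patient_id, g$locus)
  expect_true(all(cnt == 1))          # one row = two allele draws per locus
  expect_true(all(!is.na(g$allele1) & !is.na(g$allele2)))
  # carriage of a common allele among LOW patients ~ 1 - (1 - f)^2
  hm <- cohortConfig()$hla_model
  f <- hm$freq_low[hm$allele == "DPB1*04:01:01G"]
  gl <- g[g$locus == "DPB1" & g$group == "LOW", ]
  carr <- mean(gl$allele1 == "DPB1*04:01:01G" | gl$allele2 == "DPB1*04:01:01G")
  expected <- 1 - (1 - f)^2
  se <- sqrt(expected * (1 - expected) / nrow(gl))
  expect_lt(abs(carr - expected), 3 * se)
})

test_that("serology plates have duplicate wells, blanks and pools per isotype", {
  pl <- serologyPlates(testCohort())
  expect_setequal(unique(pl$isotype), c("panIgGMA", "IgG", "IgM", "IgA"))
  for (iso in unique(pl$isotype)) {
    p <- pl[pl$isotype == iso, ]
    expect_equal(sum(p$role == "blank"), 2)
    expect_equal(sum(p$role == "pool"), 2)
    counts <- table(p$sample_id[p$role == "patient"])
    expect_true(all(counts == 2))
  }
  expect_true(all(pl$od >= 0))
})
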