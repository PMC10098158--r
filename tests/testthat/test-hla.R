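test_that("allele frequency is the occurrence count over twice the patients", {
  expect_equal(round(100 * alleleFrequency(7, 29), 2), 12.07)
  expect_equal(round(100 * alleleFrequency(10, 72), 2), 6.94)
  expect_equal(alleleFrequency(0, 29), 0)
  expect_error(alleleFrequency(59, 29), "out of range")
})

test_that("minor-allele filtering is strict at the 2% threshold", {
  st <- data.frame(allele = c("a", "b", "c"),
                   freq_total = c(0.0694, 0.02, 0.019),
                   freq_high = c(0.12, 0.06, 0.01),
                   freq_low = c(0.035, 0.01, 0.01))
  kept <- filterMinorAlleles(st)
  expect_equal(kept$allele, "a")
  expect_equal(nrow(filterMinorAlleles(st[0, ])), 0)
  # display rule additionally requires >= 5% in either group
  st2 <- st; st2$freq_total <- c(0.0694, 0.04, 0.03)
  expect_equal(filterMinorAlleles(st2, displayRule = TRUE)$allele, c("a", "b"))
})

test_that("carriage odds ratios reproduce the published class I anchors", {
  o1 <- carriageOddsRatio(7, 29, 3, 43)
  expect_equal(round(o1$odds_ratio, 2), 4.24)   # (7x40)/(22x3)
  o2 <- carriageOddsRatio(10, 29, 7, 43)
  expect_equal(round(o2$odds_ratio, 2), 2.71)
  expect_false(o1$corrected)
  expect_true(is.finite(o1$ci_upper))
})

test_that("odds-ratio symmetry and zero-cell correction hold", {
  o <- carriageOddsRatio(5, 20, 5, 20)
  expect_equal(o$odds_ratio, 1)
  a <- carriageOddsRatio(7, 29, 3, 43)$odds_ratio
  b <- carriageOddsRatio(3, 43, 7, 29)$odds_ratio
  expect_equal(a * b, 1)
  z <- carriageOddsRatio(0, 10, 4, 12, ci = FALSE)
  expect_true(z$corrected)
  expect_true(is.finite(z$odds_ratio))
  expect_error(carriageOddsRatio(5, 0, 1, 10), "positive")
  expect_error(carriageOddsRatio(11, 10, 1, 10), "exceed")
})

test_that("the exact p matches fisher.test across random carriage tables", {
  set.seed(4)
  for (i in 1:25) {
    n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    ours <- carriageOddsRatio(a, n1, b, n2, ci = FALSE)$fisher_p
    ref <- fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2,
                              byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("the exact p equals brute-force enumeration over fixed margins", {
  # exhaustive check on all small tables: enumerate every table with the
  # observed margins, probability from binomial coefficients
  bruteP <- function(a, n1, b, n2) {
    K <- a + b; N <- n1 + n2
    support <- max(0, K - n2):min(K, n1)
    pr <- choose(n1, support) * choose(n2, K - support) / choose(N, K)
    sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
  }
  for (n1 in c(3, 5, 8)) for (n2 in c(3, 6, 8)) {
    for (a in 0:n1) for (b in 0:n2) {
      expect_equal(carriageOddsRatio(a, n1, b, n2, ci = FALSE)$fisher_p,
                   bruteP(a, n1, b, n2), tolerance = 1e-12)
    }
  }
})

test_that("a planted enrichment ranks first in the association scan", {
  mk <- function(ids, group, alleles)
    data.frame(patient_id = ids, group = group, locus = "A",
               allele1 = alleles[[1]], allele2 = alleles[[2]])
  hiIds <- sprintf("H%02d", 1:30)
  loIds <- sprintf("L%02d", 1:30)
  g <- rbind(
    mk(hiIds, "HIGH", list(c(rep("A*01:01:01G", 24), rep("A*02:01:01G", 6)),
                           rep("A*03:01:01G", 30))),
    mk(loIds, "LOW", list(c(rep("A*01:01:01G", 4), rep("A*02:01:01G", 26)),
                          rep("A*03:01:01G", 30))))
  labels <- setNames(c(rep("HIGH", 30), rep("LOW", 30)), c(hiIds, loIds))
  scan <- hlaAssociationScan(g, labels)
  expect_equal(scan$allele[1], "A*01:01:01G")
  expect_gt(scan$odds_ratio[1], 1)
  expect_lt(scan$fisher_p[1], 0.001)
})

test_that("identical group genotype compositions yield null odds ratios", {
  ids1 <- sprintf("H%02d", 1:10)
  ids2 <- sprintf("L%02d", 1:10)
  alle1 <- rep(c("B*07:02:01G", "B*08:01:01G"), 5)
  alle2 <- rep(c("B*08:01:01G", "B*44:02:01G"), 5)
  g <- rbind(data.frame(patient_id = ids1, group = "HIGH", locus = "B",
                        allele1 = alle1, allele2 = alle2),
             data.frame(patient_id = ids2, group = "LOW", locus = "B",
                        allele1 = alle1, allele2 = alle2))
  labels <- setNames(c(rep("HIGH", 10), rep("LOW", 10)), c(ids1, ids2))
  scan <- hlaAssociationScan(g, labels)
  expect_true(all(scan$odds_ratio == 1))
  expect_true(all(scan$fisher_p == 1))
})

test_that("allele frequencies at a fully typed locus sum to one", {
  co <- testCohort()
  labels <- setNames(ifelse(donors(co)$group == "HIGH", "HIGH", "LOW"),
                     donors(co)$donor_id)
  scan <- hlaAssociationScan(genotypes(co), labels, minFreq = 0)
  for (loc in unique(scan$locus))
    expect_equal(sum(scan$freq_total[scan$locus == loc]), 1)
  # every carrier contributes at least one occurrence; occurrences are
  # bounded by two per patient
  expect_true(all(scan$carriers_high <= scan$n_high))
  expect_true(all(scan$n_high <= 2 * scan$n_patients_high))
  expect_true(all(scan$carriers_high <= scan$n_patients_high))
})

test_that("degenerate single-patient groups are handled without crashing", {
  g <- data.frame(patient_id = c("H1", "L1"), group = c("HIGH", "LOW"),
                  locus = "A", allele1 = "A*01:01:01G",
                  allele2 = c("A*02:01:01G", "A*01:01:01G"))
  labels <- c(H1 = "HIGH", L1 = "LOW")
  scan <- hlaAssociationScan(g, labels)
  expect_true(all(is.finite(scan$odds_ratio)))
  expect_true(any(scan$or_corrected))
  expect_error(hlaAssociationScan(g, labels["H1"]), "no label")
  bad <- g; bad$allele1[1] <- "oops"
  expect_error(hlaAssociationScan(bad, labels), "malformed")
})
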