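test_that("SRH H statistics equal the rank-then-ANOVA oracle", {
  set.seed(17)
  for (rep in 1:20) {
    a <- gl(sample(2:4, 1), 1)
    b <- gl(sample(2:3, 1), 1)
    d <- expand.grid(a = a, b = b, r = seq_len(sample(3:5, 1)))
    y <- rnorm(nrow(d))
    if (rep %% 2 == 0) y <- round(y, 1)   # induce ties half the time
    s <- scheirerRayHare(y, d$a, d$b)
    # oracle: mid-ranks into a standard factorial aov, H = SS / (N(N+1)/12) / D
    r <- rank(y)
    N <- length(y)
    t <- table(r)
    D <- 1 - sum(t^3 - t) / (N^3 - N)
    ss <- anova(aov(r ~ d$a * d$b))$`Sum Sq`
    ms <- N * (N + 1) / 12
    expect_equal(unname(s$H), ss[1:3] / ms / D, tolerance = 1e-10)
  }
})

test_that("SRH reduces to the tie-corrected Kruskal-Wallis with one factor", {
  set.seed(3)
  y <- round(rnorm(45), 1)
  g <- gl(3, 15)
  s <- scheirerRayHare(y, g, factor(rep("all", 45)))
  expect_equal(unname(s$H["A"]),
               unname(kruskal.test(y, g)$statistic), tolerance = 1e-12)
  expect_true(is.na(s$H["B"]))
})

test_that("SRH tie correction and rank sum-of-squares additivity hold", {
  set.seed(5)
  d <- expand.grid(a = gl(3, 1), b = gl(2, 1), r = 1:6)
  y <- rnorm(nrow(d))                     # continuous: tie-free
  s <- scheirerRayHare(y, d$a, d$b)
  expect_equal(s$tie_correction, 1)
  expect_equal(unname(s$ss["A"] + s$ss["B"] + s$ss["interaction"] +
                        s$ss["residual"]),
               unname(s$ss["total"]), tolerance = 1e-8)
  # a design with an empty cell skips the interaction with a warning
  a2 <- factor(c(1, 1, 2, 2, 2, 1))
  b2 <- factor(c(1, 2, 1, 1, 1, 1))
  expect_warning(s2 <- scheirerRayHare(rnorm(6), a2, b2), "empty cells")
  expect_true(is.na(s2$H["interaction"]))
})

test_that("Dunn z is antisymmetric and matches a frozen hand computation", {
  # 3 groups of 3 with no ties: mean ranks 2, 5, 8;
  # se = sqrt((9 * 10 / 12) * (2/3)) = sqrt(5)
  y <- c(11, 12, 13, 21, 22, 23, 31, 32, 33)
  g <- gl(3, 3)
  dn <- dunnPosthoc(y, g)
  expect_equal(dn$z[1, 2], (2 - 5) / sqrt(5), tolerance = 1e-12)
  expect_equal(dn$z[1, 3], (2 - 8) / sqrt(5), tolerance = 1e-12)
  expect_equal(dn$z, -t(dn$z))
  bon <- dunnPosthoc(y, g, adjust = "bonferroni")
  expect_true(all(bon$p >= dn$p, na.rm = TRUE))
  expect_true(all(bon$p <= 1, na.rm = TRUE))
  tuk <- dunnPosthoc(y, g, adjust = "tukey")
  expect_true(all(tuk$p >= dn$p, na.rm = TRUE))
})

test_that("identical groups give zero Dunn z and p of one", {
  y <- rep(c(5, 5, 5), 2)
  dn <- dunnPosthoc(y, gl(2, 3))
  expect_equal(dn$z[1, 2], 0)
  expect_equal(dn$p[1, 2], 1)
})

test_that("compareGroups dispatches the design-matched nonparametric test", {
  set.seed(9)
  df <- data.frame(v = rnorm(40), g = gl(2, 20, labels = c("x", "y")))
  two <- compareGroups(df, "v", "g", design = "two_independent")
  expect_equal(two$test, "Mann-Whitney U")
  expect_equal(two$p, wilcox.test(v ~ g, data = df)$p.value)
  df3 <- data.frame(v = rnorm(60), g = gl(3, 20))
  k <- compareGroups(df3, "v", "g", design = "k_independent")
  expect_equal(k$test, "Kruskal-Wallis")
  expect_equal(k$p, kruskal.test(df3$v, df3$g)$p.value)
  expect_false(is.null(k$posthoc))
  fr <- data.frame(v = rnorm(30), g = gl(3, 1, 30), b = gl(10, 3))
  kp <- compareGroups(fr, "v", "g", design = "k_paired", block = "b")
  expect_equal(kp$p, friedman.test(fr$v, fr$g, fr$b)$p.value)
  fa <- data.frame(v = rnorm(36), g = gl(3, 12), b = gl(2, 6, 36))
  fac <- compareGroups(fa, "v", "g", design = "factorial", block = "b")
  expect_equal(fac$test, "Scheirer-Ray-Hare")
  expect_length(fac$p, 3)
  expect_error(compareGroups(df3, "v", "g", design = "two_independent"),
               "exactly 2 groups")
  expect_error(compareGroups(fr, "v", "g", design = "k_paired"), "block")
})

test_that("identical distributions give near-null statistics", {
  df <- data.frame(v = rep(1:10, 2), g = gl(2, 10))
  two <- compareGroups(df, "v", "g", design = "two_independent")
  expect_gt(two$p, 0.9)
  expect_equal(two$statistic, 50)   # U at its null centre n1 n2 / 2
})

test_that("a planted one-SD location shift is detected with high power", {
  set.seed(21)
  hits <- 0
  for (i in 1:100) {
    x <- rnorm(50); y <- rnorm(50, 1)
    df <- data.frame(v = c(x, y), g = gl(2, 50))
    p <- compareGroups(df, "v", "g", design = "two_independent")$p
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / 100, 0.9)
})

test_that("PCA summary reports variance shares and orthonormal loadings", {
  set.seed(2)
  x1 <- rnorm(40)
  perfect <- cbind(a = x1, b = 2 * x1 + 5)
  ps <- pcaSummary(perfect)
  expect_equal(ps$var_explained[1], 1)
  x <- matrix(rnorm(40 * 4), 40, dimnames = list(NULL, letters[1:4]))
  ps2 <- pcaSummary(x)
  expect_equal(crossprod(ps2$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(ps2$var_explained), 1)
  xc <- cbind(x, const = 1)
  expect_warning(ps3 <- pcaSummary(xc), "constant")
  expect_equal(ps3$dropped, "const")
})

test_that("paired tissue comparison reports exact p and its attainable floor", {
  blood <- data.frame(donor_id = c("P1", "P2", "P3"), pct = c(36.6, 30, 40))
  muscle <- data.frame(donor_id = c("P1", "P2", "P3"), pct = c(74.9, 60, 80))
  out <- pairedTissueCompare(blood, muscle, "pct")
  expect_equal(out$p, 0.125)                 # 1 / 2^3: all signs concordant
  expect_equal(out$min_attainable_p, 0.125)
  same <- pairedTissueCompare(blood, blood, "pct")
  expect_equal(same$p, 1)
  expect_equal(same$median_diff, 0)
  expect_error(pairedTissueCompare(blood,
                                   data.frame(donor_id = "Q9", pct = 1)),
               "no matched")
})

test_that("the n=3 exact one-tailed signed-rank p matches sign enumeration", {
  # oracle: enumerate all 2^3 sign assignments of ranks {1,2,3}; the
  # observed statistic W = 6 is attained by exactly one of 8 patterns
  signs <- expand.grid(s1 = c(0, 1), s2 = c(0, 1), s3 = c(0, 1))
  W <- as.matrix(signs) %*% 1:3
  pOracle <- mean(W >= 6)
  expect_equal(pOracle, 0.125)
  blood <- data.frame(donor_id = 1:3, f = c(1, 2, 3))
  muscle <- data.frame(donor_id = 1:3, f = c(2, 4, 6))
  expect_equal(pairedTissueCompare(blood, muscle, "f")$p, pOracle)
})
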