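test_that("describeValues pins the sample-SD (n-1) convention to the cohort", {
  t1 <- referenceCohort()
  ages <- describeValues(t1$age)
  expect_equal(round(ages$mean, 2), 61.08)
  expect_equal(round(ages$sd, 2), 12.70)
  # the n-divisor population SD gives 12.44 and must NOT match
  expect_false(round(sqrt(mean((t1$age - mean(t1$age))^2)), 2) == 12.70)

  ratios <- describeValues(t1$ratio)
  expect_equal(round(ratios$mean, 4), 0.5888)
  expect_equal(round(ratios$sd, 4), 0.1535)

  expect_equal(describeValues(rep(5, 10))$sd, 0)
  expect_error(describeValues(3), "at least 2")
})

test_that("summary-statistics ANOVA reproduces published group tables", {
  gs <- referenceGroupSummaries()
  ratioRows <- gs[gs$table == "severity" & gs$variable == "ratio", ]
  expect_equal(round(anovaFromSummary(ratioRows)$F, 2), 35.63)
  astRows <- gs[gs$variable == "ast", ]
  expect_equal(round(anovaFromSummary(astRows)$F, 3), 7.338)
  # identical group means: F = 0
  same <- data.frame(n = c(5, 7), mean = c(1, 1), sd = c(0.3, 0.4))
  expect_equal(anovaFromSummary(same)$F, 0)
  expect_error(anovaFromSummary(data.frame(n = 5, mean = 1, sd = 1)),
               "2 groups")
  expect_error(anovaFromSummary(data.frame(n = c(5, 1), mean = c(1, 2),
                                           sd = c(1, 0))),
               "n >= 2")
})

test_that("raw-data ANOVA equals the summary form and handles degeneracy", {
  expect_equal(anovaRaw(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))$F, 0)
  # no within-group variance but distinct means: explicit degenerate result
  deg <- anovaRaw(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_true(deg$degenerate)
  expect_equal(deg$F, Inf)
  expect_equal(deg$p, 0)
  # fully constant data: F undefined
  deg2 <- anovaRaw(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_true(deg2$degenerate)
  expect_true(is.nan(deg2$F))

  set.seed(51)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(3:8, k, replace = TRUE)
    labels <- rep(letters[1:k], n)
    values <- rnorm(sum(n), mean = sample(0:3, k, replace = TRUE)[
      match(labels, letters[1:k])], sd = 1)
    raw <- anovaRaw(values, labels)
    summ <- anovaFromSummary(groupSummary(labels, values))
    expect_equal(raw$F, summ$F, tolerance = 1e-10)
    expect_equal(raw$p, summ$p, tolerance = 1e-10)
    expect_equal(raw$dfBetween, summ$dfBetween)
    expect_equal(raw$dfWithin, summ$dfWithin)
    # affine invariance of F
    shifted <- anovaRaw(3.7 * values - 11, labels)
    expect_equal(shifted$F, raw$F, tolerance = 1e-8)
  }
})

test_that("LSD comparisons equal pooled-variance t tests and flag severity", {
  # two-group case: must equal the classical pooled two-sample t test
  set.seed(52)
  for (i in 1:20) {
    x <- rnorm(sample(4:9, 1), 0, 1)
    y <- rnorm(sample(4:9, 1), 0.8, 1)
    g <- groupSummary(rep(c("x", "y"), c(length(x), length(y))), c(x, y))
    lsd <- lsdPosthoc(g)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(lsd$p, tt$p.value, tolerance = 1e-10)
    expect_equal(abs(lsd$t), abs(unname(tt$statistic)), tolerance = 1e-10)
  }
  # identical means: t = 0, p = 1
  same <- data.frame(group = c("a", "b"), n = c(5, 5), mean = c(2, 2),
                     sd = c(1, 1))
  lsd0 <- lsdPosthoc(same)
  expect_equal(lsd0$t, 0)
  expect_equal(lsd0$p, 1)

  # published severity groups: mild differs from moderate and severe
  gs <- referenceGroupSummaries()
  rows <- gs[gs$table == "severity" & gs$variable == "ratio", ]
  lsd <- lsdPosthoc(rows)
  mild <- lsd[lsd$group1 == "mild" | lsd$group2 == "mild", ]
  expect_true(all(mild$significant))

  expect_error(lsdPosthoc(same, msWithin = 0, dfWithin = 8), "positive")
})

test_that("Pearson correlation matches its defining formula", {
  expect_equal(pearsonCorrelation(1:10, 2 * (1:10) + 1)$rho, 1)
  expect_equal(pearsonCorrelation(1:10, -(1:10))$rho, -1)
  set.seed(53)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- pearsonCorrelation(x, y)
    rho <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$rho, rho, tolerance = 1e-12)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    expect_equal(got$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-10)
    # symmetry and scale invariance
    expect_equal(pearsonCorrelation(y, x)$rho, got$rho)
    expect_equal(pearsonCorrelation(10 * x + 3, y)$rho, got$rho,
                 tolerance = 1e-12)
  }
  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "constant")
  expect_error(pearsonCorrelation(1:4, 1:5), "length")
})

test_that("p values render the way clinical tables print them", {
  expect_equal(formatP(c(0.001, 0.2)), c("<0.05", ">0.05"))
})
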