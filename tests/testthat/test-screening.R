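# Synthetic voltage datasets and screening statistics: generator
# determinism, ANOVA against brute-force definitional sums, residual
# diagnostics, Fisher LSD against pooled t-tests, compact-letter ranking.

# definitional one-way sums, independent of the fitted model
brute_anova <- function(values, groups) {
  groups <- as.character(groups)
  gbar <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(n * (gbar - grand)^2)
  ssw <- sum((values - gbar[groups])^2)
  k <- length(gbar); N <- length(values)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(ssb = ssb, ssw = ssw, F = F,
       p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

test_that("the generator is seed-deterministic and mean-accurate", {
  spec <- generator_spec()
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1, d2)
  d3 <- generate_dataset(generator_spec(seed = 43))
  expect_false(identical(d1$voltage_V, d3$voltage_V))
  # degenerate noise pins every replicate to its group mean
  tiny <- generate_dataset(generator_spec(sigma = 1e-12))
  mns <- reference_mean_voltages()
  for (m in names(mns))
    expect_equal(tiny$voltage_V[tiny$material == m],
                 rep(mns[[m]], 30), tolerance = 1e-9)
  # sample means land within 4 sigma / sqrt(n) of the specification
  for (m in names(mns))
    expect_lt(abs(mean(d1$voltage_V[d1$material == m]) - mns[[m]]),
              4 * spec$sigma / sqrt(spec$n_per_group))
})

test_that("the generator leaves the global RNG stream untouched", {
  set.seed(99)
  a <- stats::runif(1)
  set.seed(99)
  invisible(generate_dataset(generator_spec()))
  expect_identical(stats::runif(1), a)
})

test_that("ANOVA matches brute-force definitional sums", {
  ds <- data.frame(material = rep(c("a", "b"), each = 3),
                   voltage_V = c(1, 2, 3, 2, 3, 4))
  an <- anova_oneway(ds)
  ref <- brute_anova(ds$voltage_V, ds$material)
  expect_equal(an$SS_between, ref$ssb)
  expect_equal(an$SS_within, ref$ssw)
  expect_equal(an$F, ref$F)
  expect_equal(an$p, ref$p)
  # two-group F equals the squared pooled t statistic
  tt <- stats::t.test(voltage_V ~ material, data = ds, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2)
  expect_equal(an$p, tt$p.value)
  # identical group means: no between-group variation
  same <- data.frame(material = rep(c("a", "b"), each = 3),
                     voltage_V = rep(c(1, 2, 3), 2))
  an0 <- anova_oneway(same)
  expect_equal(an0$SS_between, 0)
  expect_equal(an0$F, 0)
  expect_equal(an0$R2, 0)
})

test_that("ANOVA invariants hold on fuzzed datasets", {
  set.seed(31)
  for (k in 1:20) {
    ng <- sample(2:6, 1)
    n <- sample(3:12, 1)
    ds <- data.frame(
      material = rep(letters[seq_len(ng)], each = n),
      voltage_V = stats::rnorm(ng * n, rep(stats::runif(ng), each = n), 0.3))
    an <- anova_oneway(ds)
    expect_equal(an$SS_total, an$SS_between + an$SS_within,
                 tolerance = 1e-12)
    expect_gte(an$R2, 0); expect_lte(an$R2, 1)
    expect_gte(an$F, 0)
    ref <- brute_anova(ds$voltage_V, ds$material)
    expect_equal(an$F, ref$F, tolerance = 1e-10)
  }
})

test_that("zero within-group variance yields an infinite F with warning", {
  ds <- data.frame(material = rep(c("a", "b"), each = 3),
                   voltage_V = rep(c(1, 2), each = 3))
  expect_warning(an <- anova_oneway(ds), "Inf")
  expect_identical(an$F, Inf)
  expect_identical(an$p, 0)
})

test_that("residual diagnostics are shift-invariant and correctly calibrated", {
  ds <- generate_dataset(generator_spec())
  d0 <- residual_diagnostics(ds)
  shifted <- ds
  shifted$voltage_V <- shifted$voltage_V + 1
  d1 <- residual_diagnostics(shifted)
  expect_equal(d0$ad_stat, d1$ad_stat)
  expect_equal(d0$levene_stat, d1$levene_stat)
  # under exact normal noise the AD test should rarely reject
  pass <- vapply(1:100, function(s)
    residual_diagnostics(generate_dataset(generator_spec(seed = s)))$ad_p > 0.05,
    logical(1))
  expect_gte(mean(pass), 0.90)
  # a 10x inflated group is flagged by the Levene test
  flag <- vapply(1:100, function(s) {
    ds <- generate_dataset(generator_spec(seed = 1000 + s))
    idx <- ds$material == "platinum"
    mu <- mean(ds$voltage_V[idx])
    ds$voltage_V[idx] <- mu + 10 * (ds$voltage_V[idx] - mu)
    residual_diagnostics(ds)$levene_p < 0.05
  }, logical(1))
  expect_gte(mean(flag), 0.90)
})

test_that("Fisher LSD agrees with the pooled two-sample t-test", {
  set.seed(17)
  ds <- data.frame(material = rep(c("a", "b"), each = 8),
                   voltage_V = stats::rnorm(16, rep(c(0.3, 0.32), each = 8),
                                            0.01))
  lsd <- fisher_lsd(ds)
  tt <- stats::t.test(voltage_V ~ material, data = ds, var.equal = TRUE)
  expect_equal(lsd$pairs$p, tt$p.value)
  expect_equal(lsd$pairs$significant, tt$p.value < 0.05)
  expect_equal(unname(lsd$pairs$diff_V),
               unname(tt$estimate[1] - tt$estimate[2]))
  # CI geometry: interval contains the difference; significance iff it
  # excludes zero (fuzzed)
  for (k in 1:10) {
    ds <- data.frame(
      material = rep(c("a", "b", "c"), each = 6),
      voltage_V = stats::rnorm(18, rep(stats::runif(3, 0.3, 0.35), each = 6),
                               0.01))
    p <- fisher_lsd(ds)$pairs
    expect_true(all(p$ci_low_V <= p$diff_V & p$diff_V <= p$ci_high_V))
    expect_equal(p$significant, p$ci_low_V > 0 | p$ci_high_V < 0)
  }
})

test_that("identical groups produce no significant pairs and one letter", {
  ds <- data.frame(material = rep(c("a", "b", "c"), each = 4),
                   voltage_V = rep(c(1, 2, 3, 4), 3))
  lsd <- fisher_lsd(ds)
  expect_false(any(lsd$pairs$significant))
  rk <- rank_materials(anova_oneway(ds), lsd)
  expect_equal(unique(rk$letters), "a")
})

test_that("fully separated materials receive five distinct letters, platinum first", {
  res <- screen_materials()
  rk <- res$ranking
  expect_equal(rk$material[1], "platinum")
  expect_equal(sort(rk$letters), letters[1:5])
  expect_true(all(res$lsd$pairs$significant))
  expect_true(all(diff(rk$mean_V) < 0))
})
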