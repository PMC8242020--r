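# Permutation engine, repeated-measures ANOVA, single-trial statistics.

test_that("exhaustive enumeration gives exact permutation p-values", {
  r <- permutation_contrast(c(1, 1, 0, 0), c("A", "A", "B", "B"),
                            levels = c("B", "A"), n_perm = "exhaustive")
  expect_equal(r$observed, 1)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$n_perm, 6)
  # all values equal: zero contrast, never significant
  r0 <- permutation_contrast(rep(3, 6), rep(c("A", "B"), 3),
                             n_perm = "exhaustive")
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1)
  expect_false(any(r0$mask))
  expect_error(permutation_contrast(1:4, c("A", "A", "A", "B")), "2 trials")
})

test_that("Monte-Carlo permutation agrees with exhaustive enumeration", {
  v <- c(2.1, 0.6, 1.4, 1.9, 0.3, -0.2, 0.8, 0.1)
  l <- rep(c("solo", "joint"), each = 4)
  pe <- permutation_contrast(v, l, levels = c("solo", "joint"),
                             n_perm = "exhaustive")$p
  pm <- permutation_contrast(v, l, levels = c("solo", "joint"),
                             n_perm = 10000, seed = 1)$p
  expect_lt(abs(pe - pm), 0.01)
})

test_that("permutation p-values are calibrated under exchangeability", {
  set.seed(14)
  n_sim <- 300
  p <- replicate(n_sim, {
    v <- rnorm(40)
    permutation_contrast(v, rep(c("solo", "joint"), 20),
                         n_perm = 100, seed = sample.int(1e6, 1))$p
  })
  rate <- mean(p <= 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  # p is roughly uniform under the null
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("pooled-datapoint and max-stat thresholds flag planted effects", {
  set.seed(15)
  d <- 30; n_tr <- 40
  v <- matrix(rnorm(d * n_tr), d, n_tr)
  lab <- rep(c("solo", "joint"), each = n_tr / 2)
  v[7, lab == "joint"] <- v[7, lab == "joint"] + 3   # one strong cell
  r <- permutation_contrast(v, lab, levels = c("solo", "joint"),
                            alpha = 0.001, n_perm = 500, seed = 2)
  expect_true(r$mask[7])
  expect_lt(sum(r$mask[-7]), 3)
  rmax <- permutation_contrast(v, lab, levels = c("solo", "joint"),
                               alpha = 0.05, n_perm = 500, seed = 2,
                               pooling = "max_stat")
  expect_true(rmax$mask[7])
  # at equal alpha, max-stat is the stricter rule
  r05 <- permutation_contrast(v, lab, levels = c("solo", "joint"),
                              alpha = 0.05, n_perm = 500, seed = 2)
  expect_gte(rmax$hi, r05$hi)
})

test_that("rm-ANOVA reproduces the paired-t identity and partial eta squared", {
  set.seed(16)
  n <- 14
  d <- data.frame(subject = rep(1:n, each = 2),
                  cond = rep(c("a", "b"), n),
                  y = rnorm(2 * n) + rep(c(0, 0.8), n))
  a <- rm_anova(d, "y", "subject", "cond")
  tt <- stats::t.test(d$y[d$cond == "b"], d$y[d$cond == "a"], paired = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
  expect_equal(a$df1, 1); expect_equal(a$df2, n - 1)
  # partial eta squared via the F/df identity
  expect_equal(a$pes, a$F / (a$F + a$df2), tolerance = 1e-9)
  # two-way within design returns all three effects
  d2 <- expand.grid(subject = 1:10, A = c("x", "y"), B = c("u", "v", "w"))
  set.seed(17)
  d2$y <- rnorm(nrow(d2)) + ifelse(d2$A == "y" & d2$B == "v", 1.5, 0)
  a2 <- rm_anova(d2, "y", "subject", c("A", "B"))
  expect_setequal(a2$effect, c("A", "B", "A:B"))
  expect_true(all(a2$pes >= 0 & a2$pes <= 1))
  expect_error(rm_anova(d2[-1, ], "y", "subject", c("A", "B")), "complete")
})

test_that("an injected interaction is detected by the within-subject ANOVA", {
  set.seed(18)
  hits <- replicate(10, {
    d <- expand.grid(subject = 1:20, visible = c("yes", "no"),
                     control = c("solo", "joint"))
    d$y <- rnorm(nrow(d), sd = 1) +
      ifelse(d$visible == "yes" & d$control == "joint", 1.8, 0)
    a <- rm_anova(d, "y", "subject", c("visible", "control"))
    a$p[a$effect == "visible:control"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("single-trial correlations separate coupled and null metrics", {
  set.seed(19)
  n_tr <- 60
  mk <- function(pair) {
    cpl <- rnorm(2 * n_tr, 0.05, 0.2)
    data.frame(pair = pair,
               condition = rep(c("joint", "solo"), each = n_tr),
               coupling = cpl,
               same = cpl,
               null_metric = rnorm(2 * n_tr))
  }
  trials <- do.call(rbind, lapply(1:8, mk))
  rs <- single_trial_coupling_correlations(trials, "same")
  expect_true(all(abs(rs$per_pair$r - 1) < 1e-9))
  rn <- single_trial_coupling_correlations(trials, "null_metric")
  expect_lt(abs(mean(rn$per_pair$r)), 0.1)
  expect_gt(rn$group$p[rn$group$test == "joint_vs_zero"], 0.05)
  # pairs with too few trials are excluded with a reason
  small <- trials[trials$pair != 1 | seq_len(nrow(trials)) %% 30 == 0, ]
  ex <- single_trial_coupling_correlations(small, "null_metric",
                                           min_trials = 10L)
  expect_true(1 %in% ex$excluded$pair)
})

test_that("regression identities hold and planted coefficients are recovered", {
  set.seed(20)
  n <- 80
  # single predictor: standardised beta equals the simple correlation
  d1 <- data.frame(pair = 1, coupling = rnorm(n), x = rnorm(n))
  d1$coupling <- d1$coupling + 0.6 * d1$x
  r1 <- single_trial_regression(d1, "x")
  expect_equal(unname(r1$per_pair[1, "x"]),
               stats::cor(d1$coupling, d1$x), tolerance = 1e-9)
  # residuals orthogonal to predictors at machine precision
  z <- scale(d1[c("coupling", "x")])
  fit <- stats::lm(z[, 1] ~ z[, 2])
  expect_lt(abs(sum(fit$residuals * z[, 2])), 1e-10)
  # planted generative model: coupling = 0.5 z(endpoint) + noise
  mk <- function(pair) {
    e <- rnorm(120); j1 <- rnorm(120); j2 <- rnorm(120)
    data.frame(pair = pair, coupling = 0.5 * e + rnorm(120, 0, sqrt(0.75)),
               endpoint = e, junk1 = j1, junk2 = j2)
  }
  trials <- do.call(rbind, lapply(1:10, mk))
  rr <- single_trial_regression(trials, c("endpoint", "junk1", "junk2"))
  g <- rr$group
  expect_lt(abs(g$beta_mean[g$predictor == "endpoint"] - 0.5), 0.1)
  expect_true(g$significant[g$predictor == "endpoint"])
  expect_lt(max(abs(g$beta_mean[g$predictor != "endpoint"])), 0.1)
  # orthogonal predictors: betas match their simple correlations
  b <- rr$per_pair[1, ]
  d1p <- trials[trials$pair == 1, ]
  expect_equal(unname(b["endpoint"]),
               stats::cor(d1p$coupling, d1p$endpoint), tolerance = 0.1)
  # a collinear design is excluded with a reason
  dd <- mk(99); dd$junk1 <- dd$endpoint
  expect_error(single_trial_regression(dd, c("endpoint", "junk1")),
               "no pair")
})
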