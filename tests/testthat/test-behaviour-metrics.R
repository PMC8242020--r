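# Controller displacement, onset/offset detection, Menger curvature,
# endpoint displacement, and HP/LP performance sorting.

test_that("displacement is the Pythagorean magnitude in percent", {
  expect_equal(displacement_series(cbind(0.3, 0.4)), 50)
  expect_equal(displacement_series(cbind(0, 0)), 0)
  expect_equal(displacement_series(cbind(1, 0)), 100)
  expect_equal(displacement_series(cbind(1, 1)), 100)  # clipped at 100
  expect_length(displacement_series(matrix(0.1, 7, 2)), 7)
})

test_that("onset is the first and offset the last supra-threshold frame", {
  d <- detect_onset_offset(c(0, 5, 12, 40, 12, 5, 0))
  expect_equal(d$onset_frame, 3L)
  expect_equal(d$offset_frame, 5L)
  expect_true(is.na(detect_onset_offset(rep(0, 10))$onset_frame))
  d2 <- detect_onset_offset(rep(50, 8))
  expect_equal(c(d2$onset_frame, d2$offset_frame), c(1L, 8L))
  # onset <= offset whenever both exist; lowering the threshold widens
  set.seed(7)
  for (i in 1:20) {
    s <- pmax(0, cumsum(rnorm(50)))
    hi <- detect_onset_offset(s, 20); lo <- detect_onset_offset(s, 5)
    if (!is.na(hi$onset_frame)) {
      expect_lte(hi$onset_frame, hi$offset_frame)
      expect_lte(lo$onset_frame, hi$onset_frame)
      expect_gte(lo$offset_frame, hi$offset_frame)
    }
  }
})

test_that("Menger curvature matches circle and circumradius oracles", {
  # points on a circle of radius 2: k = 1/2 everywhere
  th <- seq(0, 1.5 * pi, length.out = 40)
  k <- curvature(cbind(2 * cos(th), 2 * sin(th)))
  expect_equal(k$mean_k, 0.5, tolerance = 1e-9)
  expect_equal(k$k[5], sqrt(k$kx[5]^2 + k$ky[5]^2))
  # triangle (0,0),(1,0),(1,1): R = abc/(4A) = sqrt(2)/2, k = sqrt(2)
  k3 <- curvature(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(k3$k[2], sqrt(2), tolerance = 1e-12)
  # collinear points: zero curvature
  kline <- curvature(cbind(seq(0, 5, length.out = 10), 0))
  expect_true(all(kline$k[2:9] == 0))
  # stationary frames are degenerate and excluded from the mean
  krep <- curvature(rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(1, 1)))
  expect_true(is.na(krep$k[2]))
  expect_equal(krep$mean_k, sqrt(2), tolerance = 1e-12)
  expect_error(curvature(rbind(c(0, 0), c(1, 1))), "3 frames")
})

test_that("curvature is invariant under translation and rotation", {
  set.seed(12)
  traj <- apply(matrix(rnorm(40), ncol = 2), 2L, cumsum)
  k0 <- curvature(traj)$mean_k
  expect_equal(curvature(sweep(traj, 2L, c(3.2, -7.7), `+`))$mean_k, k0,
               tolerance = 1e-9 * k0)
  th <- 0.83
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(curvature(traj %*% Rm)$mean_k, k0, tolerance = 1e-9 * k0)
  # straight simulated reaches are flatter than curved ones
  straight <- cbind(seq(0, 8, length.out = 50), 0)
  arc <- cbind(8 * sin(seq(0, pi / 2, length.out = 50)),
               8 - 8 * cos(seq(0, pi / 2, length.out = 50)))
  expect_lt(curvature(straight)$mean_k, curvature(arc)$mean_k)
})

test_that("endpoint displacement is the final-frame distance, path-free", {
  traj <- rbind(c(0, 0), c(2, 2), c(3, 4))
  expect_equal(endpoint_displacement(traj, c(3, 4)), 0)
  expect_equal(endpoint_displacement(traj, c(0, 0)), 5)
  zig <- rbind(c(0, 0), c(-5, 7), c(3, 4))
  expect_equal(endpoint_displacement(zig, c(0, 0)),
               endpoint_displacement(traj, c(0, 0)))
})

test_that("HP/LP sorting works at experiment and trial level", {
  oc <- expand.grid(trial = 1:10, owner = c("solo1", "solo2", "joint"),
                    stringsAsFactors = FALSE)
  oc$visible <- TRUE
  oc$control <- "solo"
  oc$outcome <- "missed"
  oc$outcome[oc$owner == "solo1" & oc$trial <= 8] <- "correct"  # 80%
  oc$outcome[oc$owner == "solo2" & oc$trial <= 6] <- "correct"  # 60%
  oc$rt_ms <- ifelse(oc$owner == "solo1", 400, 450)
  oc$mt_ms <- 600
  s <- summarize_performance(oc)
  expect_equal(s$hp_lp$hp[s$hp_lp$metric == "accuracy_pct"], "solo1")
  expect_equal(s$hp_lp$lp[s$hp_lp$metric == "accuracy_pct"], "solo2")
  expect_equal(s$hp_lp$hp[s$hp_lp$metric == "rt_ms"], "solo1")
  acc <- s$summary$accuracy_pct[s$summary$owner == "solo1"]
  expect_equal(acc, 80)
  # exhaustive and exclusive partition
  expect_true(all(s$hp_lp$hp != s$hp_lp$lp))
  # tie on a metric breaks to the lower participant index
  oc2 <- oc
  oc2$outcome <- rep(c("correct", "missed"), length.out = nrow(oc2))
  s2 <- summarize_performance(oc2)
  expect_equal(s2$hp_lp$hp[s2$hp_lp$metric == "accuracy_pct"], "solo1")
  # trial-level sorting of a continuous metric
  oc$curv <- ifelse(oc$owner == "solo1", 0.2, 0.5)
  tl <- summarize_performance(oc, level = "trial", metric = "curv")
  expect_equal(unique(tl$hp_value), 0.2)
  expect_equal(unique(tl$lp_value), 0.5)
  # anticipation rate counts RT < 200 ms
  oc3 <- oc
  oc3$rt_ms[oc3$owner == "solo1" & oc3$trial <= 2] <- 150
  s3 <- summarize_performance(oc3)
  ant <- s3$summary$anticipation_pct[s3$summary$owner == "solo1"]
  expect_equal(ant, 20)
})
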