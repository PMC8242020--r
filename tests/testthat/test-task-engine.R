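# Session design, trial timeline, control law and game-logic scoring.

test_that("session design is counterbalanced, balanced per block, and seeded", {
  d <- generate_design(15, 64, seed = 1)
  expect_equal(nrow(d), 960)
  expect_equal(sum(d$control == "joint"), 480)
  expect_equal(sum(d$control == "solo"), 480)

  # full factorial crossing within every block
  pair_idx <- ((d$target_index - 1L) %% 4L) + 1L
  for (b in unique(d$block)) {
    sel <- d$block == b
    tab <- table(d$control[sel], pair_idx[sel], d$target_freq_hz[sel])
    expect_true(all(tab == 64 / 16))
  }
  # opposite-pair geometry and distinct tag frequencies
  expect_true(all((d$target_index - d$distractor_index) %% 8 %in% c(4)))
  expect_true(all(d$target_freq_hz != d$distractor_freq_hz))
  expect_true(all(d$delay_ms >= 500 & d$delay_ms <= 1000))

  # determinism and seed sensitivity
  expect_identical(generate_design(3, 16, seed = 7),
                   generate_design(3, 16, seed = 7))
  expect_false(identical(generate_design(3, 16, seed = 7)$target_index,
                         generate_design(3, 16, seed = 8)$target_index))

  # single block of 16: every factorial cell exactly once
  d1 <- generate_design(1, 16, seed = 0)
  cells <- interaction(d1$control, ((d1$target_index - 1L) %% 4L) + 1L,
                       d1$target_freq_hz)
  expect_equal(max(table(cells)), 1L)

  expect_error(generate_design(2, 15), "divisible")
})

test_that("trial timelines are contiguous and span 6500-7000 ms", {
  expect_equal(generate_timeline(500)$total_ms, 6500)
  expect_equal(generate_timeline(1000)$total_ms, 7000)
  tl <- generate_timeline(750)
  expect_equal(tl$total_ms, 6750)
  # contiguity: onsets are the running sum of durations
  expect_equal(unname(diff(tl$onset)),
               unname(tl$durations[-length(tl$durations)]))
  expect_equal(tl$spatial_cue_ms, 1000 + 576 + 1424 + 750)
  expect_error(generate_timeline(400), "500")
  expect_error(generate_timeline(1100), "500")
})

test_that("cursor control law gates at 10% and averages under joint control", {
  expect_equal(step_cursor(cbind(1, 0), "solo"), cbind(7.5, 0))
  # below-gate displacement produces exactly zero velocity
  expect_equal(step_cursor(cbind(0.06, 0.06), "solo"), cbind(0, 0))
  expect_equal(step_cursor(list(cbind(0.5, 0), cbind(0.3, 0)), "joint"),
               cbind(0.4 * 7.5, 0))
  # one actor below threshold stalls the joint cursor entirely
  expect_equal(step_cursor(list(cbind(0.9, 0), cbind(0.05, 0.05)), "joint"),
               cbind(0, 0))
  expect_error(step_cursor(list(cbind(1, 0)), "joint"), "two")

  # properties over random inputs: symmetry in actor order, the mean bound,
  # and solo/joint agreement for identical inputs
  set.seed(11)
  for (i in 1:20) {
    a <- matrix(stats::runif(20, -1, 1), 10)
    b <- matrix(stats::runif(20, -1, 1), 10)
    vab <- step_cursor(list(a, b), "joint")
    expect_equal(vab, step_cursor(list(b, a), "joint"))
    lohi <- range(cbind(a, b)) * 7.5
    expect_true(all(vab >= lohi[1] - 1e-12 & vab <= lohi[2] + 1e-12))
    expect_equal(step_cursor(list(a, a), "joint"), step_cursor(a, "solo"))
  }
})

test_that("game-logic scoring classifies the four outcome classes", {
  fx <- fixtures()
  oc <- fx$outcomes
  expect_setequal(oc$outcome, c("correct", "too_fast", "too_slow", "missed"))
  expect_equal(oc$outcome[oc$kind == "correct"], "correct")
  expect_equal(oc$outcome[oc$kind == "too_fast"], "too_fast")
  expect_equal(oc$outcome[oc$kind == "too_slow"], "too_slow")
  expect_equal(oc$outcome[oc$kind == "missed"], "missed")
  ok <- oc[oc$kind == "correct", ]
  expect_true(ok$rt_ms >= 200 && ok$rt_ms <= 800)
  expect_true(ok$mt_ms <= 1500)
  expect_equal(ok$completion_ms, ok$rt_ms + ok$mt_ms)
  # scoring is deterministic
  expect_identical(score_trial(fx$trajectories$correct, fx$target),
                   score_trial(fx$trajectories$correct, fx$target))
})

test_that("movement time runs from action onset to first qualifying entry", {
  const <- task_constants()
  frame_ms <- 1000 / const$frame_hz
  n <- round(const$action_ms / frame_ms)
  target <- c(8, 0)
  # onset ~400 ms, target entry ~900 ms, dwell well beyond 200 ms
  pos <- matrix(0, n + 1L, 2)
  for (f in seq_len(n)) {
    t_ms <- (f - 1L) * frame_ms
    pos[f + 1L, 1] <- if (t_ms < 400) 0
      else if (t_ms < 900) 6.9 * (t_ms - 400) / 500   # approach, outside target
      else 8                                           # inside, dwells to end
    }
  s <- score_trial(pos, target)
  expect_equal(s$outcome, "correct")
  expect_equal(s$rt_ms, 400, tolerance = frame_ms)
  expect_equal(s$mt_ms, 500, tolerance = 2 * frame_ms)
  # never dwelling 200 ms inside the target within the window -> missed
  t_rows <- (0:n) * frame_ms
  drift <- pmax(0, t_rows - 400) / 2500 * 5
  wander <- cbind(drift, drift)
  expect_equal(score_trial(wander, target)$outcome, "missed")
})
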