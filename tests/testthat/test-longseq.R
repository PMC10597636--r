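test_that("short sequences get the single degenerate window", {
  p <- plan_windows(440)
  expect_identical(nrow(p$windows), 1L)
  expect_identical(c(p$windows$start, p$windows$end), c(0L, 440L))
  expect_identical(c(p$supply$first, p$supply$last), c(0L, 405L))
  p2 <- plan_windows(200)
  expect_identical(c(p2$windows$start, p2$windows$end), c(0L, 200L))
})

test_that("the 770-base worked case follows the 55-base trim rule", {
  p <- plan_windows(770)
  expect_identical(p$windows$start, c(0L, 330L))
  expect_identical(p$windows$end, c(440L, 770L))
  # window 1 supplies 0-based starts 0..384, window 2 supplies 385..735
  expect_identical(p$supply$first, c(0L, 385L))
  expect_identical(p$supply$last, c(384L, 735L))
  expect_identical(sum(p$supply$last - p$supply$first + 1L), 736L)
})

test_that("the last window is anchored and irregular overlaps split midway", {
  p <- plan_windows(1000)
  expect_identical(p$windows$start, c(0L, 330L, 560L))
  expect_identical(p$windows$end, c(440L, 770L, 1000L))
  # irregular overlap [560, 770) of 210 bases splits at 560 + 105
  expect_identical(p$supply$first, c(0L, 385L, 665L))
  expect_identical(p$supply$last, c(384L, 664L, 965L))
})

test_that("plan parameters are validated", {
  expect_error(plan_windows(1000, shift = 440), "overlap")
  expect_error(plan_windows(1000, shift = 500), "overlap")
  expect_error(plan_windows(1000, trim = 56), "trim")
  expect_error(plan_windows(1000, window_len = 440, shift = 420, trim = 10,
                            l_a = 35), "overlap too small")
  expect_error(plan_windows(30), "shorter than l_a")
})

test_that("every start is supplied exactly once for lengths 440..5000", {
  set.seed(17)
  for (N in c(440, 441, 769, 770, 771, 880, 1100,
              sample(440:5000, 30), 4999, 5000)) {
    p <- plan_windows(N)
    starts <- unlist(lapply(seq_len(nrow(p$supply)), function(i)
      p$supply$first[i]:p$supply$last[i]))
    expect_identical(starts, 0:(N - 35L))          # covered, ordered, unique
    expect_true(all(p$supply$first >= p$windows$start))
    expect_true(all(p$supply$last <= p$windows$start + 440L - 35L))
  }
})

test_that("stitching copies assigned values and validates its inputs", {
  p1 <- plan_windows(440)
  prof <- accessfold:::new_profile("x", 35L, 100L, rnorm(406))
  expect_identical(stitch(list(prof), p1)$values, prof$values)

  p2 <- plan_windows(770)
  c1 <- accessfold:::new_profile("x", 35L, 100L, rep(1, 406))
  c2 <- accessfold:::new_profile("x", 35L, 100L, rep(2, 406))
  out <- stitch(list(c1, c2), p2)
  expect_length(out$values, 736L)
  expect_identical(out$values, c(rep(1, 385), rep(2, 351)))

  # global start index encoded in each window localises the assignment
  p3 <- plan_windows(1234)
  profs <- lapply(seq_len(nrow(p3$windows)), function(i)
    accessfold:::new_profile("x", 35L, 100L,
                             p3$windows$start[i] + 0:(440 - 35)))
  expect_identical(stitch(profs, p3)$values, as.numeric(0:(1234 - 35)))

  expect_error(stitch(list(c1), p2), "expected 2")
  bad <- accessfold:::new_profile("x", 35L, 100L, rep(1, 100))
  expect_error(stitch(list(bad, c2), p2), "expected 406")
})

test_that("predict_long equals predict_window below the model maximum", {
  cfg <- surrogate_config("fcn", embed_dim = 8, max_len = 64, l_a = 7,
                          W = 20, n_layers = 2, kernel = 3, seed = 23)
  model <- build_surrogate(cfg)
  set.seed(5)
  s <- random_seq(64, "exact")
  expect_identical(predict_long(model, s)$values,
                   predict_window(model, s)$values)
  long <- random_seq(200, "long")
  out <- predict_long(model, long, window_len = 64L, shift = 48L, trim = 8L)
  expect_length(out$values, 194L)
  expect_true(all(is.finite(out$values)))
  # values in a window's interior match that window's own prediction
  plan <- plan_windows(200, 64L, 48L, 8L, 7L)
  w2 <- seq_record("w2", substr(long$seq, plan$windows$start[2] + 1,
                                plan$windows$end[2]))
  pw2 <- predict_window(model, w2)
  a <- plan$supply$first[2]
  expect_equal(out$values[a + 1], pw2$values[a - plan$windows$start[2] + 1])
})

test_that("oracle profiles stitched from oracle windows track the full profile", {
  # span-constrained folding keeps the ensemble roughly local, so stitched
  # window oracles approximate the full-sequence oracle; residual window
  # truncation error at the default geometry is typically ~0.1-0.2 kcal/mol
  # at the median with occasional multi-kcal outliers near boundaries (the
  # reason edges are trimmed at all), so the asserted bounds are loose
  set.seed(29)
  for (N in c(900, 1050)) {
    s <- random_seq(N, "loc", p = c(.25, .25, .25, .25, 0))
    cfg <- oracle_config(l_a = 35, W = 100)
    full <- accessibility_profile(s, cfg)
    plan <- plan_windows(N)
    profs <- lapply(seq_len(nrow(plan$windows)), function(i) {
      sub <- seq_record("w", substr(s$seq, plan$windows$start[i] + 1,
                                    plan$windows$end[i]))
      accessibility_profile(sub, cfg)
    })
    stitched <- stitch(profs, plan, id = s$id)
    dif <- abs(stitched$values - full$values)
    expect_lt(stats::median(dif), 0.5)
    expect_lt(max(dif), 6)
  }
})
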