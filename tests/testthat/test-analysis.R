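test_that("response detection finds injected spikes with their latency", {
  train <- pulse_train(onset = 1000, frequency = 1, count = 5,
                       amplitude = 4.5, width = 2)
  t <- seq(0, 6000, by = 0.5)
  v <- rep(-34, length(t))

  # flat subthreshold trace: nothing fires
  s <- detect_responses(make_trace(t, v, train), train)
  expect_false(any(s$fired))
  expect_true(all(is.na(s$latency_ms)))

  # one spike injected after pulse 3 (onset 3000), crossing 0 mV at +7 ms
  v2 <- approx(x = c(0, 3005, 3007, 3009, 3015, 6000),
               y = c(-34, -34, 0, 40, -34, -34), xout = t)$y
  s <- detect_responses(make_trace(t, v2, train), train)
  expect_equal(which(s$fired), 3)
  expect_equal(s$latency_ms[3], 7, tolerance = 1e-6)

  # coarse sampling is refused
  t4 <- seq(0, 6000, by = 4)
  expect_error(detect_responses(make_trace(t4, rep(-34, length(t4)), train),
                                train),
               "too coarse")
  # trace must cover the last stimulus window
  tshort <- seq(0, 5100, by = 0.5)
  expect_error(detect_responses(make_trace(tshort, rep(-34, length(tshort)),
                                           train), train),
               "cover")
})

test_that("faithfulness is the windowed fired fraction", {
  s <- make_series(20000 + 0:9 * 1000, c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(faithfulness(s, 20000, 30000), 0.6)
  expect_equal(faithfulness(make_series(1:5 * 100, rep(TRUE, 5)), 0, 1000), 1)
  expect_equal(faithfulness(make_series(1:5 * 100, rep(FALSE, 5)), 0, 1000), 0)
  expect_error(faithfulness(s, 0, 10000), "no stimuli")

  # independent brute recount over the flags
  set.seed(99)
  fired <- runif(40) < 0.4
  s <- make_series(20000 + 0:39 * 1000, fired)
  manual <- sum(fired[1:10]) / 10
  expect_identical(faithfulness(s, 20000, 30000), manual)
})

test_that("suprathreshold areas integrate the clipped voltage", {
  train <- pulse_train(onset = 100, frequency = 5, count = 4,
                       amplitude = 4.5, width = 2)
  t <- seq(0, 900, by = 0.5)
  v <- rep(-34, length(t))
  expect_equal(response_areas(make_trace(t, v, train), train, -30),
               rep(0, 4))

  # rectangular excursion of height 8 above threshold lasting 30 ms in window 2
  v[t >= 310 & t < 340] <- -22
  a <- response_areas(make_trace(t, v, train), train, -30)
  expect_equal(a[2], 8 * 30, tolerance = 8 * 30 * 0.02)  # trapezoid edge ramps
  expect_equal(a[c(1, 3, 4)], rep(0, 3))
})

test_that("return maps reflect fixed-point and periodic area sequences", {
  train <- pulse_train(onset = 0, frequency = 1, count = 300,
                       amplitude = 4.5, width = 2)
  areas <- rep(7, 300)
  rm_ <- return_map(areas, train, window = c(100000, 300000))
  expect_true(all(rm_$A_i == 7 & rm_$A_next == 7))  # identity line

  areas2 <- rep(c(2, 9), 150)
  rm2 <- return_map(areas2, train, window = c(100000, 300000))
  expect_setequal(unique(paste(rm2$A_i, rm2$A_next)), c("2 9", "9 2"))

  expect_error(return_map(c(0, areas[-1]), train, window = c(0, 300000)),
               "zero suprathreshold area")
  expect_error(return_map(areas[1:5], train), "differ")
})

test_that("pattern classification follows firing fraction and periodicity", {
  train_times <- 20000 + 0:299 * 1000
  areas_fp <- rep(5, 300)

  s <- make_series(train_times, rep(FALSE, 300))
  expect_equal(as.character(classify_pattern(s, areas_fp)),
               "subthreshold_fixed_point")

  s <- make_series(train_times, rep(TRUE, 300))
  expect_equal(as.character(classify_pattern(s, areas_fp)),
               "suprathreshold_fixed_point")

  # alternating firing: periodic, f = 0.5 picks the subthreshold class
  s <- make_series(train_times, rep(c(TRUE, FALSE), 150))
  cls <- classify_pattern(s, areas_fp)
  expect_equal(as.character(cls), "subthreshold_periodic")
  expect_equal(attr(cls, "period"), 2L)

  # mostly firing with periodic skips: suprathreshold periodic
  s <- make_series(train_times, rep(c(TRUE, TRUE, TRUE, FALSE), 75))
  expect_equal(as.character(classify_pattern(s, areas_fp)),
               "suprathreshold_periodic")

  # aperiodic sequence: irregular
  set.seed(1)
  s <- make_series(train_times, runif(300) < 0.3)
  expect_equal(as.character(classify_pattern(s, areas_fp)), "irregular")

  expect_error(classify_pattern(make_series(train_times[1:10],
                                            rep(TRUE, 10)), areas_fp[1:10],
                                window = c(0, 10000)),
               "fewer than 20")
})

test_that("slow projection samples the slow variables at onsets", {
  train <- pulse_train(onset = 1000, frequency = 1, count = 3,
                       amplitude = 4.5, width = 2)
  t <- seq(0, 4000, by = 1)
  tr <- make_trace(t, rep(-34, length(t)), train,
                   Ca1 = 3 + t / 1e5, E_net1 = 1 - t / 1e5)
  s <- make_series(stimulus_times(train), c(TRUE, FALSE, FALSE))
  pr <- slow_projection(tr, train, s)
  expect_equal(pr$Ca, 3 + c(1000, 2000, 3000) / 1e5)
  expect_equal(pr$E_net, 1 - c(1000, 2000, 3000) / 1e5)
  expect_equal(pr$fired, c(TRUE, FALSE, FALSE))

  # a stimulus-free relaxed circuit projects to constant triples
  qs <- qss_for(41.5)
  p <- mcell_params(ag_max = 41.5)
  tr0 <- integrate_circuit(qs, p, train = NULL, t_end = 5000, step = 0.02)
  expect_lt(diff(range(tr0$Ca1)), 1e-3)
  expect_lt(diff(range(tr0$E_net1)), 5e-3)
})

test_that("increasing excitation traverses the five response classes", {
  # coarse ag_max chain; the irregular class sits between the subthreshold
  # and suprathreshold locked regimes (classes 2 and 3 interleave finely
  # around ag_max 43.5-44 in this deterministic model)
  width <- calibrated_width()
  class_at <- function(ag) {
    run <- long_run(ag, width = width)
    as.character(classify_pattern(run$series, run$series$area))
  }
  expect_equal(class_at(40.7), "subthreshold_fixed_point")
  expect_equal(class_at(44.0), "subthreshold_periodic")
  expect_equal(class_at(43.5), "irregular")
  expect_equal(class_at(48.0), "suprathreshold_periodic")
  expect_equal(class_at(53.0), "suprathreshold_fixed_point")
})
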